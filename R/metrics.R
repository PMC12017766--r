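#' Consensus-versus-truth identity
#'
#' Globally aligns the (spliced) consensus against the true mature
#' variable-domain sequence and reports three fractions: `full` = matches /
#' length(truth), where uncovered (`.`) consensus columns count as errors;
#' `covered_only` = matches / truth positions aligned to a covered consensus
#' residue; `coverage` = covered truth positions / length(truth). Matches
#' honour the scheme's equivalence sets (with the default scheme I/L
#' confusions count as correct; pass a scheme without equivalences to count
#' them as errors, as appropriate for EM-derived sequences).
#'
#' @param consensus A `fab_consensus` or a residue string (`.` = uncovered).
#' @param truth The true mature variable-domain residue string, trimmed to
#'   the domain (V start through the J segment end).
#' @param scheme A [scoring_scheme()].
#' @return List with `full`, `covered_only` (NA when nothing is covered) and
#'   `coverage`.
#' @export
consensus_identity <- function(consensus, truth, scheme = scoring_scheme()) {
  stopifnot(is.character(truth), length(truth) == 1L, nzchar(truth))
  seq <- if (inherits(consensus, "fab_consensus"))
    consensus_sequence(consensus) else consensus
  stopifnot(is.character(seq), nzchar(seq))
  al <- global_align(seq, truth, scheme)
  cch <- strsplit(seq, "", fixed = TRUE)[[1]]
  eq <- scheme$equivalence
  qi <- 1L
  matches <- 0L
  covered <- 0L
  for (op in ops_chars(al)) {
    if (op == "M" || op == "S") {
      if (cch[qi] != ".") {
        covered <- covered + 1L
        if (op == "M") matches <- matches + 1L
      }
      qi <- qi + 1L
    } else if (op == "I") {
      qi <- qi + 1L
    }
    # D: truth residue aligned to consensus gap -> uncovered
  }
  n <- nchar(truth)
  list(full = matches / n,
       covered_only = if (covered > 0) matches / covered else NA_real_,
       coverage = covered / n)
}

#' V-gene identity by alignment-score cutoff
#'
#' For each cutoff, restricts the evaluation records to cases whose
#' aggregate alignment score reaches the cutoff and reports the count, mean
#' and median of the inferred-vs-true V-gene identity. Higher alignment
#' scores indicate better-resolved inputs, so identity should rise with the
#' cutoff.
#'
#' @param records Data frame of evaluation records (needs columns
#'   `aggregate_score`, `v_identity`).
#' @param cutoffs Integer vector of score cutoffs.
#' @return Data frame with columns cutoff, n, mean, median (NA statistics
#'   where n = 0).
#' @export
vgene_identity_vs_cutoff <- function(records,
                                     cutoffs = c(0, 20, 40, 60, 80, 100)) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("aggregate_score", "v_identity") %in% names(records)))
  do.call(rbind, lapply(cutoffs, function(cut) {
    v <- records$v_identity[records$aggregate_score >= cut]
    data.frame(cutoff = cut, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_)
  }))
}

#' Spearman rank correlation
#'
#' Non-parametric rank correlation (average ranks for ties), the standard
#' measure for how alignment score tracks V-gene identity.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in \[-1, 1\].
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("rank_correlation: length mismatch")
  stopifnot(length(x) >= 3)
  stats::cor(x, y, method = "spearman")
}

#' CDR3 benchmark statistics
#'
#' Coverage fraction over all records; mean/sd of the signed length
#' difference (predicted - true) and mean sequence identity over the covered
#' records only.
#'
#' @param records Data frame with columns `cdr3_covered`,
#'   `cdr3_length_diff`, `cdr3_identity`.
#' @return List: `coverage_fraction`, `mean_length_diff`, `sd_length_diff`,
#'   `mean_identity` (NA statistics when nothing is covered).
#' @export
cdr3_stats <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            all(c("cdr3_covered", "cdr3_length_diff", "cdr3_identity") %in%
                  names(records)))
  cov <- records$cdr3_covered
  sub <- records[cov, , drop = FALSE]
  list(coverage_fraction = mean(cov),
       mean_length_diff = if (nrow(sub)) mean(sub$cdr3_length_diff)
                          else NA_real_,
       sd_length_diff = if (nrow(sub) > 1) stats::sd(sub$cdr3_length_diff)
                        else NA_real_,
       mean_identity = if (nrow(sub)) mean(sub$cdr3_identity) else NA_real_)
}
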