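#' Local (Smith-Waterman) alignment with affine gaps
#'
#' Optimal local alignment of a read against a template under the scheme's
#' substitution matrix and affine gap penalties (Gotoh algorithm). Ties at
#' the optimal score are resolved deterministically, preferring the longer
#' aligned span and then the smaller template coordinate; within the path,
#' diagonal moves are preferred over gaps.
#'
#' @param query,target Non-empty residue strings (20 amino acids + X;
#'   unknown characters are treated as X).
#' @param scheme A [scoring_scheme()].
#' @param query_ref,target_ref Optional identifiers stored on the result.
#' @return A `fab_alignment`: list with `score` (>= 0), `ops` (single string
#'   over M = match, S = mismatch, I = query insertion, D = deletion
#'   relative to the template), `read_span` and `template_span` (1-based
#'   inclusive `c(start, end)`; empty alignments have end < start), and the
#'   references.
#' @export
#' @examples
#' al <- local_align("CAKWGGDV", "YYCAKWGGDVSS", scoring_scheme())
#' al$score; al$ops
local_align <- function(query, target, scheme = scoring_scheme(),
                        query_ref = NA_character_,
                        target_ref = NA_character_) {
  stopifnot(is.character(query), is.character(target),
            nzchar(query), nzchar(target))
  res <- align_pair_cpp(seq_to_idx(query), seq_to_idx(target),
                        scheme$substitution, scheme$equivalence,
                        scheme$gap_open, scheme$gap_extend, local = TRUE)
  structure(list(read_ref = query_ref, template_ref = target_ref,
                 read_span = c(res$q_start, res$q_end),
                 template_span = c(res$t_start, res$t_end),
                 ops = res$ops, score = res$score),
            class = "fab_alignment")
}

#' Global (end-to-end) alignment
#'
#' @inheritParams local_align
#' @return A `fab_alignment` with end-to-end spans; score may be negative.
#' @export
global_align <- function(query, target, scheme = scoring_scheme(),
                         query_ref = NA_character_,
                         target_ref = NA_character_) {
  stopifnot(is.character(query), is.character(target),
            nzchar(query), nzchar(target))
  res <- align_pair_cpp(seq_to_idx(query), seq_to_idx(target),
                        scheme$substitution, scheme$equivalence,
                        scheme$gap_open, scheme$gap_extend, local = FALSE)
  structure(list(read_ref = query_ref, template_ref = target_ref,
                 read_span = c(res$q_start, res$q_end),
                 template_span = c(res$t_start, res$t_end),
                 ops = res$ops, score = res$score),
            class = "fab_alignment")
}

#' @export
print.fab_alignment <- function(x, ...) {
  cat(sprintf("fab_alignment: score %d, read %d-%d vs template %d-%d (%s)\n",
              x$score, x$read_span[1], x$read_span[2],
              x$template_span[1], x$template_span[2],
              if (nchar(x$ops) > 40) paste0(substr(x$ops, 1, 40), "...")
              else x$ops))
  invisible(x)
}

#' Global sequence identity
#'
#' End-to-end alignment identity: matched columns divided by the number of
#' aligned columns (pairwise alignment yields no dual-gap columns;
#' single-gap columns count as mismatches). Pairs within the scheme's
#' equivalence sets (default I/L) count as matches.
#'
#' @inheritParams local_align
#' @param a,b Non-empty residue strings.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' global_identity("ACDEF", "ACDEY", scoring_scheme())  # 0.8
global_identity <- function(a, b, scheme = scoring_scheme()) {
  al <- global_align(a, b, scheme)
  ops <- strsplit(al$ops, "", fixed = TRUE)[[1]]
  sum(ops == "M") / length(ops)
}

# ops string -> character vector
ops_chars <- function(al) strsplit(al$ops, "", fixed = TRUE)[[1]]
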