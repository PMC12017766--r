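# Residue pool for random draws (no X: real chains contain real residues)
AA20 <- setdiff(FAB_ALPHABET, "X")

# substitute each selected position by a uniformly drawn *different* residue
substitute_positions <- function(chars, positions) {
  for (p in positions)
    chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
  chars
}

#' Simulate a mature antibody chain
#'
#' Draws a V and J segment uniformly from the repertoire slice, a uniform
#' random CDR3 of the requested length, recombines them (V through its
#' anchor Cys, CDR3, J from its anchor W/F onward) and applies somatic
#' hypermutation: every non-anchor position is substituted independently
#' with probability `shm_rate`. Mature antibodies typically carry 1-10%
#' SHM; the default is 5%. Fully reproducible given the seed.
#'
#' @param rep A `repertoire` with anchor-annotated V and J segments.
#' @param chain_class "heavy", "kappa" or "lambda" ("light" draws from the
#'   kappa+lambda pool).
#' @param shm_rate Per-position substitution probability in \[0, 1\].
#' @param cdr3_length CDR3 length (residues strictly between the anchors).
#' @param seed Integer seed.
#' @param v_id,j_id Optional segment ids to pin the V/J draw (e.g. to
#'   emulate a specific known antibody).
#' @return A `sim_truth`: `v_id`, `j_id`, `chain_class`, `shm_rate`, `cdr3`,
#'   `mature_sequence`, `mutated_positions` (1-based), `anchor_positions`,
#'   `seed`.
#' @export
simulate_antibody <- function(rep, chain_class = "heavy", shm_rate = 0.05,
                              cdr3_length = 12L, seed = 1L,
                              v_id = NULL, j_id = NULL) {
  stopifnot(shm_rate >= 0, shm_rate <= 1, cdr3_length >= 1L)
  vs <- repertoire_segments(rep, segment_type = "V", chain_class = chain_class)
  js <- repertoire_segments(rep, segment_type = "J", chain_class = chain_class)
  if (!is.null(v_id))
    vs <- vs[vapply(vs, `[[`, "", "segment_id") == v_id]
  if (!is.null(j_id))
    js <- js[vapply(js, `[[`, "", "segment_id") == j_id]
  vs <- vs[!vapply(vs, function(s) is.na(s$anchor_index), TRUE)]
  js <- js[!vapply(js, function(s) is.na(s$anchor_index), TRUE)]
  if (!length(vs) || !length(js))
    stop("simulate_antibody: need >= 1 anchor-annotated V and J for class ",
         chain_class)
  with_seed(seed, {
    v <- vs[[sample.int(length(vs), 1L)]]
    j <- js[[sample.int(length(js), 1L)]]
    cdr3 <- paste(sample(AA20, cdr3_length, replace = TRUE), collapse = "")
    v_prefix <- substr(v$sequence, 1L, v$anchor_index)
    j_suffix <- substr(j$sequence, j$anchor_index, nchar(j$sequence))
    naive <- paste0(v_prefix, cdr3, j_suffix)
    anchors <- c(nchar(v_prefix), nchar(v_prefix) + cdr3_length + 1L)
    chars <- strsplit(naive, "", fixed = TRUE)[[1]]
    eligible <- setdiff(seq_along(chars), anchors)
    mutated <- eligible[runif(length(eligible)) < shm_rate]
    chars <- substitute_positions(chars, mutated)
    structure(list(v_id = v$segment_id, j_id = j$segment_id,
                   chain_class = v$chain_class, shm_rate = shm_rate,
                   cdr3 = substr(paste(chars, collapse = ""),
                                 anchors[1] + 1L, anchors[2] - 1L),
                   mature_sequence = paste(chars, collapse = ""),
                   mutated_positions = as.integer(mutated),
                   anchor_positions = anchors, seed = as.integer(seed)),
              class = "sim_truth")
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %s + %s [%s], SHM %.0f%%, CDR3 '%s', %d aa, seed %d\n",
              x$v_id, x$j_id, x$chain_class, 100 * x$shm_rate, x$cdr3,
              nchar(x$mature_sequence), x$seed))
  invisible(x)
}

# confidence model: correct residues draw high confidence, erroneous ones
# lower, so ALC carries signal about read accuracy (clipped to [0, 100])
sim_confidences <- function(is_error, mean_correct = 90, sd_correct = 6,
                            mean_error = 60, sd_error = 12) {
  n <- length(is_error)
  conf <- ifelse(is_error, rnorm(n, mean_error, sd_error),
                 rnorm(n, mean_correct, sd_correct))
  pmin(pmax(conf, 0), 100)
}

#' Simulate fragmented model-chain reads
#'
#' Emulates the fragmented per-chain output of de novo model building in
#' cryoEM maps: fragments with geometric-tailed lengths around
#' `mean_fragment_length` (minimum 5) are placed uniformly on the mature
#' sequence until the total residue count reaches `coverage` times the
#' sequence length. Residues are substituted independently at `error_rate`;
#' correct residues draw confidence around 90, erroneous ones around 60, so
#' ALC filtering has signal.
#'
#' @param truth A `sim_truth`.
#' @param coverage Target mean coverage (> 0).
#' @param mean_fragment_length Mean fragment length (>= 5).
#' @param error_rate Per-residue substitution probability.
#' @param seed Integer seed.
#' @return List of `sequence_read`s (source "em_model") with `truth_start`
#'   set to the fragment's true 1-based position.
#' @export
simulate_model_reads <- function(truth, coverage = 5, mean_fragment_length = 30L,
                                 error_rate = 0.1, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"), coverage > 0,
            error_rate >= 0, error_rate <= 1)
  if (mean_fragment_length < 5L)
    stop("simulate_model_reads: mean_fragment_length below minimum usable read length (5)")
  L <- nchar(truth$mature_sequence)
  target <- coverage * L
  with_seed(seed, {
    reads <- list()
    total <- 0L
    k <- 0L
    while (total < target) {
      k <- k + 1L
      len <- min(5L + rgeom(1L, 1 / (mean_fragment_length - 4L)), L)
      start <- sample.int(L - len + 1L, 1L)
      chars <- strsplit(substr(truth$mature_sequence, start,
                               start + len - 1L), "", fixed = TRUE)[[1]]
      err <- runif(len) < error_rate
      chars <- substitute_positions(chars, which(err))
      reads[[k]] <- sequence_read(
        read_id = sprintf("em%04d", k), source = "em_model",
        residues = paste(chars, collapse = ""),
        confidences = sim_confidences(err), truth_start = start)
      total <- total + len
    }
    reads
  })
}

#' Simulate de novo tryptic peptide reads
#'
#' One in-silico digest of the mature sequence: cleaved after K/R except
#' before P, with adjacent fragments merged (missed cleavage) independently
#' at `missed_cleavage_p`. Substitution errors are applied at `error_rate`
#' (confidence drawn around 60) and I<->L swaps at `il_swap_p` per I/L
#' residue; swapped residues keep high confidence since Ile and Leu have
#' identical masses and are genuinely indistinguishable to MS.
#'
#' @param truth A `sim_truth`.
#' @param missed_cleavage_p Probability of merging at each cleavage
#'   junction.
#' @param error_rate Per-residue substitution probability.
#' @param il_swap_p Per-I/L-residue swap probability.
#' @param seed Integer seed.
#' @return List of `sequence_read`s (source "ms_peptide") with `truth_start`
#'   set.
#' @export
simulate_peptide_reads <- function(truth, missed_cleavage_p = 0.2,
                                   error_rate = 0.04, il_swap_p = 0.5,
                                   seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"),
            missed_cleavage_p >= 0, missed_cleavage_p <= 1,
            error_rate >= 0, error_rate <= 1,
            il_swap_p >= 0, il_swap_p <= 1)
  s <- truth$mature_sequence
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(ch)
  # cleavage after K/R not followed by P
  sites <- which(ch[-L] %in% c("K", "R") & ch[-1] != "P")
  with_seed(seed, {
    keep <- if (length(sites)) sites[runif(length(sites)) >= missed_cleavage_p]
            else integer(0)
    starts <- c(1L, keep + 1L)
    ends <- c(keep, L)
    reads <- vector("list", length(starts))
    for (k in seq_along(starts)) {
      frag <- ch[starts[k]:ends[k]]
      err <- runif(length(frag)) < error_rate
      frag <- substitute_positions(frag, which(err))
      il <- which(frag %in% c("I", "L") & !err)
      swap <- il[runif(length(il)) < il_swap_p]
      frag[swap] <- ifelse(frag[swap] == "I", "L", "I")
      reads[[k]] <- sequence_read(
        read_id = sprintf("ms%04d", k), source = "ms_peptide",
        residues = paste(frag, collapse = ""),
        confidences = sim_confidences(err), truth_start = starts[k])
    }
    reads
  })
}

#' Simulate a polyclonal background of unrelated antibodies
#'
#' Draws `n_antibodies` independent antibodies with pairwise-distinct V
#' genes (heavy and light chain each) and generates `reads_per_antibody`
#' peptide reads per antibody (split over its two chains, pooled over
#' repeated digest replicates so missed cleavages vary). With a target
#' antibody contributing the same number of reads, `n_antibodies = 5` gives
#' the 5:1 background:target read ratio of a hard mixture experiment and
#' `n_antibodies = 1` a diffuse 1:1 background.
#'
#' @param rep A `repertoire`.
#' @param n_antibodies Number of distinct background antibodies.
#' @param reads_per_antibody Peptide reads drawn per background antibody.
#' @param seed Integer seed.
#' @param light_class Light-chain class pool for the background
#'   ("light" = kappa+lambda).
#' @param ... Passed to [simulate_peptide_reads()].
#' @return List of `sequence_read`s, each tagged with its source antibody in
#'   `$antibody`; the underlying `sim_truth`s are in attribute `truths`.
#' @export
simulate_background <- function(rep, n_antibodies = 5L,
                                reads_per_antibody = 50L, seed = 1L,
                                light_class = "light", ...) {
  stopifnot(n_antibodies >= 1L, reads_per_antibody >= 1L)
  n_hv <- length(repertoire_segments(rep, "V", "heavy"))
  n_lv <- length(repertoire_segments(rep, "V", light_class))
  if (n_hv < n_antibodies || n_lv < n_antibodies)
    stop(sprintf(
      "simulate_background: need %d distinct heavy and light V genes; have %d/%d",
      n_antibodies, n_hv, n_lv))
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max %/% 2L, 4L * n_antibodies)
  })
  reads <- list()
  truths <- list()
  used_v <- character(0)
  si <- 0L
  for (a in seq_len(n_antibodies)) {
    tag <- sprintf("background_%02d", a)
    for (cls in c("heavy", light_class)) {
      # rejection-sample a truth whose V gene is unused
      attempt <- 0L
      repeat {
        si <- si + 1L
        if (si > length(sub_seeds)) {
          sub_seeds <- c(sub_seeds, sub_seeds[length(sub_seeds)] + si +
                           seq_len(4L * n_antibodies))
        }
        tr <- simulate_antibody(rep, chain_class = cls,
                                seed = sub_seeds[si])
        attempt <- attempt + 1L
        if (!tr$v_id %in% used_v) break
        if (attempt > 200L)
          stop("simulate_background: could not draw distinct V genes")
      }
      used_v <- c(used_v, tr$v_id)
      truths[[paste(tag, cls, sep = "_")]] <- tr
      got <- list()
      digest <- 0L
      while (length(got) < ceiling(reads_per_antibody / 2)) {
        digest <- digest + 1L
        rr <- simulate_peptide_reads(tr, seed = sub_seeds[si] + digest, ...)
        got <- c(got, rr)
      }
      got <- got[seq_len(ceiling(reads_per_antibody / 2))]
      for (i in seq_along(got)) {
        got[[i]]$antibody <- tag
        got[[i]]$read_id <- sprintf("%s_%s_%03d", tag, cls, i)
      }
      reads <- c(reads, got)
    }
  }
  reads <- reads[seq_len(min(length(reads),
                             n_antibodies * reads_per_antibody))]
  attr(reads, "truths") <- truths
  reads
}

#' Pooled peptide reads over digest replicates
#'
#' Convenience wrapper: `n_replicates` independent digests of the same
#' antibody, pooled. Replicates vary in missed cleavages, so regions whose
#' fully cleaved peptides are too short for the length filter still get
#' covered by longer missed-cleavage peptides in some replicate.
#'
#' @param truth A `sim_truth`.
#' @param n_replicates Number of digest replicates.
#' @param seed Integer seed.
#' @param ... Passed to [simulate_peptide_reads()].
#' @return List of `sequence_read`s.
#' @export
simulate_ms_dataset <- function(truth, n_replicates = 8L, seed = 1L, ...) {
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max %/% 2L, n_replicates)
  })
  reads <- list()
  for (k in seq_len(n_replicates)) {
    rr <- simulate_peptide_reads(truth, seed = seeds[k], ...)
    for (i in seq_along(rr))
      rr[[i]]$read_id <- sprintf("rep%02d_%s", k, rr[[i]]$read_id)
    reads <- c(reads, rr)
  }
  reads
}
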