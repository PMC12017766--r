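#' Alignment scoring scheme
#'
#' Builds the substitution/gap scheme used by every alignment in the
#' package. The default is BLOSUM62 with affine gaps (open -12, extend -1
#' per additional gapped position) over the 20 canonical residues plus X,
#' where X scores 0 against everything. Residues within an equivalence set
#' are scored as identical: their mutual substitution score is raised to the
#' maximum of their diagonal scores and they count as matches. The default
#' equivalence set \{I, L\} reflects that isoleucine and leucine have
#' identical masses and are indistinguishable in MS-derived peptide reads;
#' pass `equivalence_sets = list()` for cryoEM model chains, where
#' side-chain density can distinguish them.
#'
#' @param matrix Name of a substitution matrix bundled with Biostrings
#'   (e.g. "BLOSUM62"), or an explicit symmetric integer matrix with
#'   dimnames covering the 21-letter alphabet.
#' @param gap_open Score for the first position of a gap (negative integer).
#' @param gap_extend Score for each additional gapped position (negative
#'   integer).
#' @param equivalence_sets List of character vectors; residues within a set
#'   are scored as identity.
#' @return A `scoring_scheme` object.
#' @export
#' @examples
#' sch <- scoring_scheme()
#' sch$substitution["I", "L"]  # raised to the I/L diagonal maximum
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = -12L,
                           gap_extend = -1L,
                           equivalence_sets = list(c("I", "L"))) {
  if (is.character(matrix)) {
    name <- matrix
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    mat <- get(name, envir = env)
  } else {
    name <- "custom"
    mat <- matrix
  }
  stopifnot(all(FAB_ALPHABET %in% rownames(mat)),
            all(FAB_ALPHABET %in% colnames(mat)))
  sub <- mat[FAB_ALPHABET, FAB_ALPHABET]
  storage.mode(sub) <- "integer"
  # X is "unknown", not "rare residue": neutral against everything
  sub["X", ] <- 0L
  sub[, "X"] <- 0L

  eq <- diag(length(FAB_ALPHABET))
  dimnames(eq) <- dimnames(sub)
  for (set in equivalence_sets) {
    stopifnot(all(set %in% FAB_ALPHABET))
    dmax <- max(diag(sub[set, set, drop = FALSE]))
    for (a in set) for (b in set) {
      if (a != b) sub[a, b] <- dmax
      eq[a, b] <- 1L
    }
    # residues in a set are interchangeable, so they must score identically
    # against every third residue (otherwise an I<->L swap would change the
    # alignment score); take the more favourable interpretation
    for (x in setdiff(FAB_ALPHABET, set)) {
      best <- max(sub[set, x])
      sub[set, x] <- best
      sub[x, set] <- best
    }
  }
  storage.mode(eq) <- "integer"
  stopifnot(isSymmetric(unname(sub)))
  stopifnot(gap_open < 0, gap_extend < 0)

  structure(list(substitution = sub, equivalence = eq,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 equivalence_sets = equivalence_sets,
                 matrix_name = name),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  eqs <- if (length(x$equivalence_sets))
    paste(vapply(x$equivalence_sets, paste, "", collapse = "/"),
          collapse = ", ") else "none"
  cat(sprintf("scoring_scheme: %s, gap open %d / extend %d, equivalences: %s\n",
              x$matrix_name, x$gap_open, x$gap_extend, eqs))
  invisible(x)
}

#' Serialize / restore a scoring scheme
#'
#' A scheme round-trips through a plain list (suitable for YAML/JSON config
#' blocks): either a matrix name or the explicit table is kept.
#'
#' @param scheme A `scoring_scheme`.
#' @return `scheme_to_config`: a plain list. `scheme_from_config`: a
#'   `scoring_scheme`.
#' @export
scheme_to_config <- function(scheme) {
  out <- list(gap_open = scheme$gap_open, gap_extend = scheme$gap_extend,
              equivalence_sets = lapply(scheme$equivalence_sets, as.character))
  if (scheme$matrix_name != "custom") {
    out$matrix <- scheme$matrix_name
  } else {
    out$matrix_table <- scheme$substitution
  }
  out
}

#' @rdname scheme_to_config
#' @param config A list as produced by [scheme_to_config()].
#' @export
scheme_from_config <- function(config) {
  mat <- if (!is.null(config$matrix_table)) config$matrix_table else config$matrix
  eqs <- lapply(config$equivalence_sets, as.character)
  scoring_scheme(matrix = mat, gap_open = config$gap_open,
                 gap_extend = config$gap_extend, equivalence_sets = eqs)
}
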