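#' Sequence read with per-residue confidence
#'
#' An error-prone amino-acid read: either a polypeptide chain (or contiguous
#' fragment) extracted from a cryoEM atomic model, or a de novo LC-MS/MS
#' peptide. Every residue carries a local confidence in \[0, 100\]; the
#' read-level ALC (Average Local Confidence) is their arithmetic mean.
#'
#' @param read_id Read identifier.
#' @param source "em_model" or "ms_peptide".
#' @param residues Residue string (20 amino acids + X).
#' @param confidences Numeric vector in \[0, 100\], one per residue.
#' @param truth_start Optional 1-based position of the read on its true
#'   source sequence (simulator bookkeeping).
#' @param antibody Optional source-antibody tag (simulator bookkeeping).
#' @return A `sequence_read` with fields `residues`, `confidences`, `alc`.
#' @export
sequence_read <- function(read_id, source, residues, confidences,
                          truth_start = NA_integer_,
                          antibody = NA_character_) {
  source <- match.arg(source, c("em_model", "ms_peptide"))
  stopifnot(is.character(residues), length(residues) == 1L, nzchar(residues))
  residues <- toupper(residues)
  confidences <- as.numeric(confidences)
  if (length(confidences) != nchar(residues))
    stop(sprintf("read %s: %d residues but %d confidences", read_id,
                 nchar(residues), length(confidences)))
  if (any(confidences < 0 | confidences > 100))
    stop(sprintf("read %s: confidences outside [0, 100]", read_id))
  structure(list(read_id = read_id, source = source, residues = residues,
                 confidences = confidences, alc = mean(confidences),
                 truth_start = truth_start, antibody = antibody),
            class = "sequence_read")
}

#' @export
print.sequence_read <- function(x, ...) {
  cat(sprintf("sequence_read %s [%s] %d aa, ALC %.1f\n", x$read_id, x$source,
              nchar(x$residues), x$alc))
  invisible(x)
}

# three-letter -> one-letter residue codes; anything else becomes X
AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M", SEC = "U", PYL = "O")

#' Extract model-chain reads from an mmCIF atomic model
#'
#' Parses a (PDBx/mmCIF) atomic model and returns one read per polypeptide
#' chain, splitting additionally at residue-number gaps so that each
#' contiguously modelled fragment aligns independently (de novo models built
#' in cryoEM maps are typically fragmented). The per-residue confidence is
#' taken from the B-factor column of the residue's representative atom (CA
#' when present, otherwise the first atom) -- de novo model builders write
#' their per-residue confidence there. If the file's maximum B-factor is
#' <= 1, all values are rescaled by 100 so confidences are always on the
#' 0-100 ALC scale. Non-standard residues map to X; waters and residues
#' without a CA atom that are not standard amino acids are skipped.
#'
#' @param mmcif_source Path to an mmCIF file.
#' @return List of `sequence_read`s (source "em_model"), possibly empty
#'   (with a warning) when the file contains no polypeptide chains.
#' @export
read_model_chains <- function(mmcif_source) {
  cif <- withCallingHandlers(
    bio3d::read.cif(mmcif_source),
    warning = function(w) invokeRestart("muffleWarning"))
  atoms <- cif$atom
  atoms <- atoms[!is.na(atoms$resno) & !atoms$resid %in% c("HOH", "WAT"), ,
                 drop = FALSE]
  # polypeptide residues: standard amino acid or any residue modelled with CA
  std <- atoms$resid %in% names(AA3TO1)
  has_ca <- ave(atoms$elety == "CA", atoms$chain, atoms$resno,
                FUN = any)
  atoms <- atoms[std | has_ca, , drop = FALSE]
  if (!nrow(atoms)) {
    warning("no polypeptide chains found in ", mmcif_source)
    return(list())
  }
  rescale <- max(atoms$b, na.rm = TRUE) <= 1
  base <- tools::file_path_sans_ext(basename(mmcif_source))

  reads <- list()
  for (ch in unique(atoms$chain)) {
    a <- atoms[atoms$chain == ch, , drop = FALSE]
    resno <- sort(unique(a$resno))
    letters <- character(length(resno))
    confs <- numeric(length(resno))
    for (k in seq_along(resno)) {
      grp <- a[a$resno == resno[k], , drop = FALSE]
      rep_atom <- if (any(grp$elety == "CA")) grp[grp$elety == "CA", ][1, ]
                  else grp[1, ]
      l <- unname(AA3TO1[rep_atom$resid])
      letters[k] <- if (is.na(l) || !l %in% FAB_ALPHABET) "X" else l
      b <- rep_atom$b
      confs[k] <- if (is.na(b)) 0 else if (rescale) b * 100 else b
    }
    confs <- pmin(pmax(confs, 0), 100)
    # split at residue-number gaps
    brk <- cumsum(c(1L, as.integer(diff(resno) != 1L)))
    for (seg in unique(brk)) {
      sel <- brk == seg
      reads[[length(reads) + 1L]] <- sequence_read(
        read_id = sprintf("%s_%s_%02d", base, ch, seg),
        source = "em_model",
        residues = paste(letters[sel], collapse = ""),
        confidences = confs[sel])
    }
  }
  message(sprintf("read_model_chains: %d read(s) from %s", length(reads),
                  basename(mmcif_source)))
  reads
}

#' Read de novo peptide reads from a delimited table
#'
#' Ingests a CSV/TSV export of de novo sequenced peptides (PEAKS-style).
#' Required columns: `peptide` (residue string; modification annotations in
#' parentheses, e.g. `N(+.98)`, are stripped) and `local_confidence`
#' (space-separated per-residue percentages). Rows whose confidence count
#' does not match the stripped peptide length are skipped and counted.
#'
#' @param table_source Path to a delimited file (`.csv` comma, otherwise
#'   tab) or a data.frame with the required columns.
#' @return List of `sequence_read`s (source "ms_peptide") with attribute
#'   `skipped` = number of malformed rows.
#' @export
read_peptide_table <- function(table_source) {
  df <- if (is.data.frame(table_source)) table_source
  else {
    sep <- if (grepl("\\.csv$", table_source, ignore.case = TRUE)) "," else "\t"
    utils::read.delim(table_source, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE)
  }
  if (!all(c("peptide", "local_confidence") %in% names(df)))
    stop("peptide table needs columns 'peptide' and 'local_confidence'")
  reads <- list()
  skipped <- 0L
  for (i in seq_len(nrow(df))) {
    pep <- gsub("\\([^)]*\\)", "", df$peptide[i])
    pep <- toupper(gsub("\\s", "", pep))
    conf <- suppressWarnings(
      as.numeric(strsplit(trimws(df$local_confidence[i]), "\\s+")[[1]]))
    if (!nzchar(pep) || anyNA(conf) || length(conf) != nchar(pep)) {
      skipped <- skipped + 1L
      next
    }
    reads[[length(reads) + 1L]] <- sequence_read(
      read_id = if ("read_id" %in% names(df)) as.character(df$read_id[i])
                else sprintf("pep%05d", i),
      source = "ms_peptide", residues = pep, confidences = conf)
  }
  if (skipped)
    message(sprintf("read_peptide_table: skipped %d malformed row(s)",
                    skipped))
  attr(reads, "skipped") <- skipped
  reads
}

#' Filter reads on ALC and length
#'
#' Keeps reads with ALC >= `cutoff_alc` and length >= `min_length` (both
#' inclusive), preserving order. These are the standard input filters for
#' template matching (defaults elsewhere: ALC 80 and length 5 for model
#' chains; ALC 90 for the guided peptide pass).
#'
#' @param reads List of `sequence_read`s.
#' @param cutoff_alc Minimum ALC in \[0, 100\].
#' @param min_length Minimum residue count (>= 1).
#' @return Filtered list, with attribute `n_removed`.
#' @export
filter_reads <- function(reads, cutoff_alc = 80, min_length = 5L) {
  stopifnot(cutoff_alc >= 0, cutoff_alc <= 100, min_length >= 1L)
  keep <- vapply(reads, function(r)
    r$alc >= cutoff_alc && nchar(r$residues) >= min_length, TRUE)
  out <- reads[keep]
  attributes(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}
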