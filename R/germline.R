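#' Germline template segment
#'
#' A single immunoglobulin germline segment (V, J, or C) or a sink sequence
#' (constant domain or antigen) used to absorb non-variable-domain reads.
#' `anchor_index` marks the conserved CDR3 anchor (1-based): the 2nd-Cys for
#' V segments, the J-Trp/Phe for J segments.
#'
#' @param segment_id Segment identifier, e.g. "IGHV5-51".
#' @param species Species name, e.g. "Homo sapiens".
#' @param chain_class One of "heavy", "kappa", "lambda" ("none" is permitted
#'   for sink segments such as antigens).
#' @param segment_type One of "V", "J", "C", "sink".
#' @param sequence Uppercase residue string over the 20 amino acids plus X.
#' @param anchor_index Optional 1-based anchor position; must be a Cys for V
#'   and a Trp/Phe for J.
#' @param anchor_flagged TRUE when anchor annotation was attempted but no
#'   candidate anchor was found (such segments need manual curation).
#' @return A `germline_segment`.
#' @export
germline_segment <- function(segment_id, species, chain_class, segment_type,
                             sequence, anchor_index = NA_integer_,
                             anchor_flagged = FALSE) {
  chain_class <- match.arg(chain_class, c("heavy", "kappa", "lambda", "none"))
  segment_type <- match.arg(segment_type, c("V", "J", "C", "sink"))
  if (chain_class == "none" && segment_type != "sink")
    stop("chain_class 'none' is only allowed for sink segments")
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- toupper(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), FAB_ALPHABET)
  if (length(bad))
    stop(sprintf("segment %s: invalid residue(s) %s", segment_id,
                 paste(bad, collapse = ", ")))
  if (!is.na(anchor_index)) {
    anchor_index <- as.integer(anchor_index)
    if (anchor_index < 1L || anchor_index > nchar(sequence))
      stop(sprintf("segment %s: anchor_index out of range", segment_id))
    res <- substr(sequence, anchor_index, anchor_index)
    if (segment_type == "V" && res != "C")
      stop(sprintf("segment %s: V anchor must be 'C', found '%s'",
                   segment_id, res))
    if (segment_type == "J" && !res %in% c("W", "F"))
      stop(sprintf("segment %s: J anchor must be 'W' or 'F', found '%s'",
                   segment_id, res))
  }
  structure(list(segment_id = segment_id, species = species,
                 chain_class = chain_class, segment_type = segment_type,
                 sequence = sequence, anchor_index = anchor_index,
                 anchor_flagged = isTRUE(anchor_flagged)),
            class = "germline_segment")
}

#' @export
print.germline_segment <- function(x, ...) {
  cat(sprintf("germline_segment %s [%s %s %s] %d aa%s%s\n", x$segment_id,
              x$species, x$chain_class, x$segment_type, nchar(x$sequence),
              if (!is.na(x$anchor_index))
                sprintf(", anchor @%d", x$anchor_index) else "",
              if (x$anchor_flagged) " (anchor FLAGGED)" else ""))
  invisible(x)
}

new_repertoire <- function(segments) {
  key <- vapply(segments, function(s)
    paste(s$species, s$segment_type, s$segment_id, sep = "\r"), "")
  if (anyDuplicated(key))
    stop(sprintf("duplicate segment(s) within (species, type): %s",
                 paste(unique(vapply(segments[duplicated(key)],
                                     `[[`, "", "segment_id")),
                       collapse = ", ")))
  structure(list(segments = segments,
                 species_set = sort(unique(vapply(segments, `[[`, "",
                                                  "species")))),
            class = "repertoire")
}

#' Load a germline template repertoire from FASTA
#'
#' Reads germline segments from a FASTA file whose headers use the
#' pipe-delimited dialect `segment_id|species|chain_class|segment_type`
#' (e.g. `>IGHV5-51|Homo sapiens|heavy|V`). Sequences are uppercased and
#' IMGT gap/stop characters (`.` and `*`) are stripped, so all coordinates
#' are over the ungapped sequence. Raw IMGT reference files must be
#' converted to this dialect first (one record per allele, header rewritten
#' from the IMGT description line).
#'
#' @param fasta_source Path to a FASTA file.
#' @param annotate If TRUE (default), CDR3 anchors are annotated on all V
#'   and J segments via [annotate_anchor()].
#' @return A `repertoire`: list of `germline_segment`s plus the species set.
#' @export
#' @examples
#' fa <- system.file("extdata", "germlines_synthetic.fasta", package = "fabseq")
#' rep <- load_germline_repertoire(fa)
#' rep
load_germline_repertoire <- function(fasta_source, annotate = TRUE) {
  set <- Biostrings::readAAStringSet(fasta_source)
  if (!length(set)) stop("no FASTA records in ", fasta_source)
  headers <- names(set)
  seqs <- as.character(set)
  segments <- vector("list", length(set))
  for (i in seq_along(set)) {
    fields <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) != 4L)
      stop(sprintf(
        "malformed FASTA header (expected 'id|species|chain_class|type'): '%s'",
        headers[i]))
    seq <- unname(gsub("[.*]", "", toupper(seqs[i])))
    if (!nzchar(seq))
      stop(sprintf("record '%s' has an empty sequence", fields[1]))
    seg <- germline_segment(fields[1], fields[2], fields[3], fields[4], seq)
    if (annotate && seg$segment_type %in% c("V", "J"))
      seg <- annotate_anchor(seg)
    segments[[i]] <- seg
  }
  new_repertoire(segments)
}

#' @export
print.repertoire <- function(x, ...) {
  tab <- table(vapply(x$segments, `[[`, "", "segment_type"),
               vapply(x$segments, `[[`, "", "chain_class"))
  cat(sprintf("repertoire: %d segments, species: %s\n", length(x$segments),
              paste(x$species_set, collapse = ", ")))
  print(tab)
  invisible(x)
}

#' Subset a repertoire
#'
#' @param rep A `repertoire`.
#' @param segment_type,chain_class,species Optional filters. `chain_class =
#'   "light"` pools kappa and lambda.
#' @return List of matching `germline_segment`s.
#' @export
repertoire_segments <- function(rep, segment_type = NULL, chain_class = NULL,
                                species = NULL) {
  segs <- rep$segments
  if (!is.null(segment_type))
    segs <- segs[vapply(segs, `[[`, "", "segment_type") %in% segment_type]
  if (!is.null(chain_class)) {
    cc <- if (identical(chain_class, "light")) c("kappa", "lambda")
          else chain_class
    segs <- segs[vapply(segs, `[[`, "", "chain_class") %in% cc]
  }
  if (!is.null(species))
    segs <- segs[vapply(segs, `[[`, "", "species") %in% species]
  segs
}

#' Annotate the conserved CDR3 anchor on a V or J segment
#'
#' For V segments the anchor is the last cysteine in the sequence (the
#' 2nd-Cys of the framework, which is the most C-terminal Cys in trimmed V
#' genes). For J segments it is the first Trp or Phe occurring in the
#' conserved `[WF]G.G` motif context when present, otherwise the first
#' Trp/Phe anywhere. Segments with no candidate anchor are returned with
#' the anchor unset and `anchor_flagged = TRUE`; reference databases
#' occasionally misplace these conserved residues, and flagged segments
#' should be curated manually. Idempotent.
#'
#' @param segment A `germline_segment` of type V or J.
#' @return The segment with `anchor_index` (1-based) and `anchor_flagged`
#'   set.
#' @export
annotate_anchor <- function(segment) {
  stopifnot(inherits(segment, "germline_segment"))
  if (!segment$segment_type %in% c("V", "J"))
    stop("annotate_anchor applies to V and J segments only")
  ch <- strsplit(segment$sequence, "", fixed = TRUE)[[1]]
  idx <- NA_integer_
  if (segment$segment_type == "V") {
    pos <- which(ch == "C")
    if (length(pos)) idx <- pos[length(pos)]
  } else {
    m <- regexpr("[WF]G.G", segment$sequence)
    if (m[1] > 0) {
      idx <- as.integer(m[1])
    } else {
      pos <- which(ch %in% c("W", "F"))
      if (length(pos)) idx <- pos[1]
    }
  }
  segment$anchor_index <- idx
  segment$anchor_flagged <- is.na(idx)
  segment
}

#' Pairwise V-gene identity
#'
#' Global-alignment sequence identity between two V segments under the
#' module's scoring scheme (by default without I/L equivalence: germline
#' comparisons are sequence-level, not mass-level). Symmetric.
#'
#' @param a,b `germline_segment`s of type V.
#' @param scheme A [scoring_scheme()].
#' @return Fraction in \[0, 1\].
#' @export
pairwise_v_identity <- function(a, b,
                                scheme = scoring_scheme(
                                  equivalence_sets = list())) {
  stopifnot(inherits(a, "germline_segment"), inherits(b, "germline_segment"),
            a$segment_type == "V", b$segment_type == "V",
            nzchar(a$sequence), nzchar(b$sequence))
  global_identity(a$sequence, b$sequence, scheme)
}

#' Repertoire baseline V-gene identity
#'
#' Mean and median pairwise sequence identity over all unordered pairs of V
#' segments in a (chain class, species) slice of the repertoire. This is
#' the expected identity of a completely random draw from the available
#' V-gene repertoire, the baseline against which inferred V-gene identity
#' is judged. For the light chain, kappa and lambda V genes are pooled.
#'
#' @param rep A `repertoire`.
#' @param chain_class "heavy" or "light" (kappa + lambda pooled), or a
#'   specific class.
#' @param species Species to slice on.
#' @param scheme A [scoring_scheme()].
#' @return List with `mean`, `median` and `n_pairs`.
#' @export
repertoire_baseline <- function(rep, chain_class, species,
                                scheme = scoring_scheme(
                                  equivalence_sets = list())) {
  vs <- repertoire_segments(rep, segment_type = "V",
                            chain_class = chain_class, species = species)
  if (length(vs) < 2L)
    stop(sprintf(
      "repertoire_baseline needs >= 2 V segments for (%s, %s); found %d",
      chain_class, species, length(vs)))
  pairs <- utils::combn(length(vs), 2L)
  ids <- apply(pairs, 2L, function(p)
    pairwise_v_identity(vs[[p[1]]], vs[[p[2]]], scheme))
  list(mean = mean(ids), median = stats::median(ids),
       n_pairs = ncol(pairs))
}
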