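#' Recombined V + CDR3 + J template
#'
#' Concatenates a V segment up to and including its conserved Cys anchor, a
#' CDR3 (or placeholder) sequence, and a J segment from its conserved
#' Trp/Phe anchor onward. The junction therefore starts with C and ends
#' with W/F by construction. Anchor columns on the recombined coordinate
#' system are recorded for CDR3 detection.
#'
#' @param v_segment,j_segment Anchor-annotated `germline_segment`s (types V
#'   and J).
#' @param cdr3 Residue string placed between the anchors (may be an X-run
#'   placeholder).
#' @param is_decoy Mark the template as a decoy.
#' @param template_id Identifier (default `<v>..<j>`).
#' @return A `recombined_template`.
#' @export
recombined_template <- function(v_segment, cdr3, j_segment, is_decoy = FALSE,
                                template_id = NULL) {
  stopifnot(inherits(v_segment, "germline_segment"),
            v_segment$segment_type == "V",
            inherits(j_segment, "germline_segment"),
            j_segment$segment_type == "J")
  if (is.na(v_segment$anchor_index) || is.na(j_segment$anchor_index))
    stop("recombined_template: V and J segments must have annotated anchors")
  stopifnot(is.character(cdr3), length(cdr3) == 1L)
  v_prefix <- substr(v_segment$sequence, 1L, v_segment$anchor_index)
  j_suffix <- substr(j_segment$sequence, j_segment$anchor_index,
                     nchar(j_segment$sequence))
  seq <- paste0(v_prefix, cdr3, j_suffix)
  structure(list(
    template_id = template_id %||%
      paste0(v_segment$segment_id, "..", j_segment$segment_id),
    v_segment = v_segment, cdr3_placeholder = cdr3, j_segment = j_segment,
    sequence = seq, is_decoy = isTRUE(is_decoy),
    chain_class = v_segment$chain_class,
    v_anchor_col = nchar(v_prefix),
    j_anchor_col = nchar(v_prefix) + nchar(cdr3) + 1L),
    class = "recombined_template")
}

#' @export
print.recombined_template <- function(x, ...) {
  cat(sprintf("recombined_template %s [%s]%s: %d aa, anchors @%d/@%d\n",
              x$template_id, x$chain_class,
              if (x$is_decoy) " (decoy)" else "",
              nchar(x$sequence), x$v_anchor_col, x$j_anchor_col))
  invisible(x)
}

# spliced consensus strictly between two columns (both excluded), including
# majority-supported insertion columns that fall between them
splice_between <- function(cons, from_col, to_col) {
  base <- strsplit(cons$consensus, "", fixed = TRUE)[[1]]
  L <- length(base)
  keys <- names(cons$insertions)
  after <- if (length(keys)) as.integer(sub("_.*", "", keys)) else integer(0)
  rank <- if (length(keys)) as.integer(sub(".*_", "", keys)) else integer(0)
  out <- character(0)
  for (j in from_col:(to_col - 1L)) {
    if (j > from_col) out <- c(out, base[j])
    sel <- which(after == j)
    for (s in sel[order(rank[sel])]) {
      ic <- cons$insertions[[s]]
      local_depth <- max(cons$depth[max(j, 1)], cons$depth[min(j + 1L, L)], 1L)
      if (ic$depth * 2L > local_depth)
        out <- c(out, argmax_residue(ic$weights, ""))
    }
  }
  paste(out, collapse = "")
}

#' Detect CDR3 between the conserved anchors
#'
#' CDR3 is covered when the consensus spans both conserved anchors: the V
#' Cys column and the J Trp/Phe column must have nonzero read depth, as must
#' every column between them (a consensus with holes inside the junction
#' does not define a CDR3 sequence). The reported sequence lies strictly
#' between the anchors (anchors excluded), with majority-supported insertion
#' columns spliced in.
#'
#' @param consensus A `fab_consensus` built on a template that contains both
#'   anchors -- normally a `recombined_template`.
#' @param v,j The V and J `germline_segment`s (anchor-annotated); used for
#'   validation when the consensus template is a `recombined_template`,
#'   required to locate anchors otherwise.
#' @return A `cdr_result`: `covered`, `sequence` (empty when not covered),
#'   `length`, `v_anchor_col`, `j_anchor_col`.
#' @export
detect_cdr3 <- function(consensus, v = NULL, j = NULL) {
  stopifnot(inherits(consensus, "fab_consensus"))
  tpl <- consensus$template
  if (inherits(tpl, "recombined_template")) {
    va <- tpl$v_anchor_col
    ja <- tpl$j_anchor_col
    v <- v %||% tpl$v_segment
    j <- j %||% tpl$j_segment
  } else {
    if (is.null(v) || is.null(j))
      stop("detect_cdr3: v and j are required for non-recombined templates")
    va <- v$anchor_index
    ja <- NA_integer_
  }
  if (is.null(v) || is.null(j) ||
      is.na(v$anchor_index) || is.na(j$anchor_index))
    stop("detect_cdr3: anchors must be annotated on both v and j")
  if (!inherits(tpl, "recombined_template")) {
    # locate the J anchor on a full-length chain template: the J suffix is
    # assumed to start at the first W/F after the V anchor
    ch <- strsplit(template_seq(tpl), "", fixed = TRUE)[[1]]
    cand <- which(ch %in% c("W", "F"))
    cand <- cand[cand > va + 1L]
    if (!length(cand)) stop("detect_cdr3: no J anchor on template")
    ja <- cand[1]
  }
  stopifnot(va >= 1L, ja > va, ja <= length(consensus$depth))
  covered <- all(consensus$depth[va:ja] > 0L)
  seq <- if (covered) splice_between(consensus, va, ja) else ""
  structure(list(covered = covered, sequence = seq, length = nchar(seq),
                 v_anchor_col = va, j_anchor_col = ja),
            class = "cdr_result")
}

#' @export
print.cdr_result <- function(x, ...) {
  if (x$covered)
    cat(sprintf("cdr_result: covered, '%s' (%d aa), anchors @%d/@%d\n",
                x$sequence, x$length, x$v_anchor_col, x$j_anchor_col))
  else cat("cdr_result: not covered\n")
  invisible(x)
}

#' Build recombined templates for the guided pass
#'
#' Constructs the primary V+CDR3+J template from the top-scoring V and J and
#' the detected CDR3; when CDR3 was not covered, a placeholder run of X of
#' `placeholder_length` is used instead (X scores 0 against everything, so
#' the junction attracts reads by flanking context rather than content).
#' With `use_decoys`, every other V segment of the repertoire is appended as
#' a decoy template, so peptides from unrelated antibodies are absorbed by
#' their own germline instead of corrupting the target consensus.
#'
#' @param top_v Anchor-annotated V `germline_segment` (the pass-one winner).
#' @param cdr3 A `cdr_result` (may be uncovered) or NULL.
#' @param top_j Anchor-annotated J `germline_segment`; required.
#' @param repertoire A `repertoire` supplying decoy V segments.
#' @param use_decoys Append decoys (default TRUE).
#' @param placeholder_length Placeholder CDR3 length when uncovered
#'   (default 12).
#' @return List of templates: the primary `recombined_template` first, then
#'   decoy `germline_segment`s flagged with `is_decoy = TRUE`.
#' @export
build_recombined_templates <- function(top_v, cdr3, top_j, repertoire,
                                       use_decoys = TRUE,
                                       placeholder_length = 12L) {
  if (is.null(top_j)) stop("build_recombined_templates: no J segment available")
  junction <- if (!is.null(cdr3) && inherits(cdr3, "cdr_result") &&
                  cdr3$covered && nzchar(cdr3$sequence)) cdr3$sequence
              else strrep("X", placeholder_length)
  primary <- recombined_template(top_v, junction, top_j)
  out <- list(primary)
  if (use_decoys) {
    vs <- repertoire_segments(repertoire, segment_type = "V")
    for (seg in vs) {
      if (seg$segment_id == top_v$segment_id &&
          seg$species == top_v$species) next
      seg$is_decoy <- TRUE
      out[[length(out) + 1L]] <- seg
    }
  }
  out
}

#' Guided second-pass assembly of peptide reads
#'
#' Filters the MS reads (default ALC cutoff 90, minimum length 5), matches
#' them against the recombined templates plus decoys and optional sinks
#' (cutoff score 10 by default), and builds the consensus on the primary
#' (non-decoy) recombined template of each chain class. Reads captured by
#' decoys or sinks are absorbed and counted, not used in the consensus.
#'
#' @param ms_reads List of `sequence_read`s (source "ms_peptide").
#' @param recombined List of templates from [build_recombined_templates()]
#'   (primaries for one or both chain classes, plus decoys); sink segments
#'   may be appended.
#' @param scheme A [scoring_scheme()]; the default I/L-equivalent scheme is
#'   appropriate for MS data.
#' @param cutoff_alc,min_length,cutoff_score Filter and matching parameters.
#' @return List per chain class present, each
#'   `list(consensus, cdr3, n_reads, empty)`, plus `matching` and `counts`.
#'   When no reads survive filtering, every chain is returned with
#'   `empty = TRUE` and a NULL consensus.
#' @export
assemble_guided <- function(ms_reads, recombined, scheme = scoring_scheme(),
                            cutoff_alc = 90, min_length = 5L,
                            cutoff_score = 10L) {
  primaries <- recombined[vapply(recombined, function(tp)
    inherits(tp, "recombined_template") && !template_is_decoy(tp), TRUE)]
  if (!length(primaries))
    stop("assemble_guided: no primary recombined template")
  kept <- filter_reads(ms_reads, cutoff_alc = cutoff_alc,
                       min_length = min_length)
  chains <- list()
  if (!length(kept)) {
    for (tp in primaries)
      chains[[chain_class_group(tp$chain_class)]] <-
        list(consensus = NULL, cdr3 = NULL, n_reads = 0L, empty = TRUE)
    return(structure(list(chains = chains, matching = NULL,
                          counts = list(input = length(ms_reads), kept = 0L)),
                     class = "guided_assembly"))
  }
  matching <- match_reads(kept, recombined, scheme, cutoff_score)
  for (tp in primaries) {
    m <- matching$matches[[tp$template_id]]
    grp <- chain_class_group(tp$chain_class)
    if (!length(m$placements)) {
      chains[[grp]] <- list(consensus = NULL, cdr3 = NULL, n_reads = 0L,
                            empty = TRUE)
    } else {
      cons <- build_consensus(m)
      chains[[grp]] <- list(consensus = cons, cdr3 = detect_cdr3(cons),
                            n_reads = length(m$placements), empty = FALSE)
    }
  }
  structure(list(chains = chains, matching = matching,
                 counts = c(list(input = length(ms_reads),
                                 kept = length(kept)), matching$counts)),
            class = "guided_assembly")
}

chain_class_group <- function(cc) if (cc == "heavy") "heavy" else "light"
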