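# --- template handling -----------------------------------------------------
# Templates fed to match_reads are germline_segments or recombined_templates.
# These helpers give them a uniform surface.

template_id <- function(x) {
  if (inherits(x, "recombined_template")) x$template_id else x$segment_id
}
template_seq <- function(x) x$sequence
template_role <- function(x) {
  if (inherits(x, "recombined_template")) "recombined" else x$segment_type
}
template_chain_class <- function(x) x$chain_class
template_is_sink <- function(x) template_role(x) %in% c("C", "sink")
template_is_decoy <- function(x) isTRUE(x$is_decoy)

#' Match reads to templates (winner-takes-all)
#'
#' Aligns every read locally against every template and assigns each read to
#' the single highest-scoring template, provided that score reaches
#' `cutoff_score` (ties go to the first template in input order). Reads
#' below the cutoff land in the discard bin. Reads won by sink templates
#' (constant domains, antigen) or decoy templates are absorbed: they are
#' placed, but flagged so they never contribute to variable-domain
#' consensus. Read counts reconcile exactly:
#' `placed + discarded == input`, with `placed = variable + sink + decoy`.
#'
#' @param reads List of `sequence_read`s.
#' @param templates Non-empty list of `germline_segment`s and/or
#'   `recombined_template`s.
#' @param scheme A [scoring_scheme()].
#' @param cutoff_score Minimum raw local alignment score for assignment
#'   (default 8, the standard first-pass cutoff; use 10 for the guided
#'   pass).
#' @return A `template_matching`: list with `matches` (one `template_match`
#'   per template: `template`, `placements`, `aggregate_score`), `discarded`
#'   (reads + their best scores) and `counts`.
#' @export
match_reads <- function(reads, templates, scheme = scoring_scheme(),
                        cutoff_score = 8L) {
  if (!length(templates)) stop("match_reads: empty template list")
  stopifnot(cutoff_score >= 0)
  tidx <- lapply(templates, function(tp) seq_to_idx(template_seq(tp)))
  tids <- vapply(templates, template_id, "")

  placements <- rep(list(list()), length(templates))
  discarded <- list()
  if (length(reads)) {
    qidx <- lapply(reads, function(r) seq_to_idx(r$residues))
    smat <- score_many_cpp(qidx, tidx, scheme$substitution,
                           scheme$gap_open, scheme$gap_extend)
    for (r in seq_along(reads)) {
      best <- which.max(smat[r, ]) # first max wins ties
      sc <- smat[r, best]
      if (sc >= cutoff_score) {
        al <- local_align(reads[[r]]$residues, template_seq(templates[[best]]),
                          scheme, query_ref = reads[[r]]$read_id,
                          target_ref = tids[best])
        stopifnot(al$score == sc)
        al$read <- reads[[r]]
        placements[[best]][[length(placements[[best]]) + 1L]] <- al
      } else {
        discarded[[length(discarded) + 1L]] <-
          list(read = reads[[r]], best_score = sc,
               best_template = tids[best])
      }
    }
  }

  matches <- vector("list", length(templates))
  for (k in seq_along(templates)) {
    matches[[k]] <- structure(
      list(template = templates[[k]], placements = placements[[k]],
           aggregate_score = sum(vapply(placements[[k]], `[[`, 0L, "score"))),
      class = "template_match")
  }
  names(matches) <- tids

  n_placed <- vapply(matches, function(m) length(m$placements), 0L)
  sink <- vapply(templates, template_is_sink, TRUE)
  decoy <- vapply(templates, template_is_decoy, TRUE)
  counts <- list(
    input = length(reads),
    placed = sum(n_placed),
    variable = sum(n_placed[!sink & !decoy]),
    sink_absorbed = sum(n_placed[sink & !decoy]),
    decoy_absorbed = sum(n_placed[decoy]),
    discarded = length(discarded))
  stopifnot(counts$placed + counts$discarded == counts$input,
            counts$variable + counts$sink_absorbed + counts$decoy_absorbed ==
              counts$placed)

  structure(list(matches = matches, discarded = discarded, counts = counts,
                 cutoff_score = cutoff_score),
            class = "template_matching")
}

#' @export
print.template_matching <- function(x, ...) {
  cat(sprintf(
    "template_matching: %d reads -> %d placed (%d variable, %d sink, %d decoy), %d discarded (cutoff %d)\n",
    x$counts$input, x$counts$placed, x$counts$variable,
    x$counts$sink_absorbed, x$counts$decoy_absorbed, x$counts$discarded,
    x$cutoff_score))
  invisible(x)
}

#' Build the confidence-weighted consensus for one template
#'
#' Each aligned read residue adds its local confidence to the weight of that
#' residue at the mapped template column; insertions create insertion
#' columns keyed by (preceding template column, rank) and deletions
#' contribute no weight. The consensus residue per column is the argmax by
#' summed weight; ties are broken in favour of the template's own residue,
#' then lexicographically. Columns covered by no read emit `.`.
#'
#' @param match A `template_match` with non-empty placements.
#' @return A `fab_consensus`: `template_ref`, `weights` (21 x L matrix),
#'   `depth` (reads contributing weight per column), `insertions` (list
#'   keyed `"<after_col>_<rank>"` with `weights` and `depth`), and
#'   `consensus` (string of length L over the template coordinates).
#' @export
build_consensus <- function(match) {
  stopifnot(inherits(match, "template_match"))
  if (!length(match$placements))
    stop("build_consensus: no placements on template ",
         template_id(match$template))
  tpl <- match$template
  tseq <- strsplit(template_seq(tpl), "", fixed = TRUE)[[1]]
  L <- length(tseq)
  W <- matrix(0, nrow = length(FAB_ALPHABET), ncol = L,
              dimnames = list(FAB_ALPHABET, NULL))
  depth <- integer(L)
  ins <- list() # key "<after>_<rank>" -> list(weights = named vec, depth)

  for (pl in match$placements) {
    stopifnot(identical(pl$template_ref, template_id(tpl)))
    rch <- strsplit(pl$read$residues, "", fixed = TRUE)[[1]]
    conf <- pl$read$confidences
    qi <- pl$read_span[1]
    tj <- pl$template_span[1]
    rank <- 0L
    for (op in ops_chars(pl)) {
      if (op == "M" || op == "S") {
        res <- rch[qi]
        if (!res %in% FAB_ALPHABET) res <- "X"
        W[res, tj] <- W[res, tj] + conf[qi]
        depth[tj] <- depth[tj] + 1L
        qi <- qi + 1L
        tj <- tj + 1L
        rank <- 0L
      } else if (op == "I") {
        rank <- rank + 1L
        key <- sprintf("%d_%d", tj - 1L, rank)
        if (is.null(ins[[key]]))
          ins[[key]] <- list(weights = structure(numeric(length(FAB_ALPHABET)),
                                                 names = FAB_ALPHABET),
                             depth = 0L)
        res <- rch[qi]
        if (!res %in% FAB_ALPHABET) res <- "X"
        ins[[key]]$weights[res] <- ins[[key]]$weights[res] + conf[qi]
        ins[[key]]$depth <- ins[[key]]$depth + 1L
        qi <- qi + 1L
      } else { # D: template column unmatched by this read
        tj <- tj + 1L
        rank <- 0L
      }
    }
  }
  stopifnot(sum(depth) + sum(vapply(ins, `[[`, 0L, "depth")) > 0L)

  cons <- vapply(seq_len(L), function(j) {
    if (depth[j] == 0L) return(".")
    argmax_residue(W[, j], tseq[j])
  }, "")

  structure(list(template_ref = template_id(tpl), template = tpl,
                 weights = W, depth = depth, insertions = ins,
                 consensus = paste(cons, collapse = "")),
            class = "fab_consensus")
}

# argmax over a named weight vector; ties prefer the template residue, then
# lexicographic order (names are sorted before which.max).
argmax_residue <- function(w, template_res) {
  top <- names(w)[w == max(w)]
  if (template_res %in% top) return(template_res)
  sort(top)[1]
}

#' @export
print.fab_consensus <- function(x, ...) {
  cat(sprintf("fab_consensus on %s: %d/%d columns covered, %d insertion column(s)\n",
              x$template_ref, sum(x$depth > 0), length(x$depth),
              length(x$insertions)))
  cat(x$consensus, "\n")
  invisible(x)
}

#' Spliced consensus sequence
#'
#' Returns the consensus string, optionally splicing in insertion columns.
#' An insertion column is included only when it is supported by a majority
#' of the reads covering the neighbouring template columns (otherwise a
#' single noisy read could lengthen the consensus).
#'
#' With `fallback = "dot"` (the default) uncovered template columns emit
#' `.`; this is the honest read-supported consensus used by the evaluation
#' metrics, where uncovered positions count as errors. With
#' `fallback = "template"` uncovered columns inherit the template residue --
#' the full-length candidate sequence a template-guided assembly reports,
#' where the germline/template carries positions no read covers.
#'
#' @param cons A `fab_consensus`.
#' @param include_insertions Splice majority-supported insertion columns.
#' @param fallback "dot" or "template" (see above).
#' @return Residue string.
#' @export
consensus_sequence <- function(cons, include_insertions = TRUE,
                               fallback = c("dot", "template")) {
  fallback <- match.arg(fallback)
  base <- strsplit(cons$consensus, "", fixed = TRUE)[[1]]
  if (fallback == "template") {
    tch <- strsplit(template_seq(cons$template), "", fixed = TRUE)[[1]]
    base[base == "."] <- tch[base == "."]
  }
  if (!include_insertions || !length(cons$insertions))
    return(paste(base, collapse = ""))
  L <- length(base)
  keys <- names(cons$insertions)
  after <- as.integer(sub("_.*", "", keys))
  rank <- as.integer(sub(".*_", "", keys))
  out <- character(0)
  for (j in 0:L) {
    if (j > 0) out <- c(out, base[j])
    sel <- which(after == j)
    if (length(sel)) {
      for (s in sel[order(rank[sel])]) {
        ic <- cons$insertions[[s]]
        local_depth <- max(cons$depth[max(j, 1)],
                           cons$depth[min(j + 1, L)], 1L)
        if (ic$depth * 2L > local_depth)
          out <- c(out, argmax_residue(ic$weights, ""))
      }
    }
  }
  paste(out, collapse = "")
}

#' Per-chain top template report
#'
#' Ranks V templates by aggregate alignment score per chain class (heavy;
#' light pooling kappa and lambda) and reports the top-scoring template and
#' the full ranked table. Chains where every V score is zero get an
#' explicit "no signal" marker (`top = NA`).
#'
#' @param matching A `template_matching` computed over a repertoire that
#'   contains V segments.
#' @return List with elements `heavy` and `light`, each
#'   `list(top, top_score, no_signal, table)`; `table` has columns
#'   template_id, chain_class, aggregate_score, n_reads.
#' @export
chain_report <- function(matching) {
  stopifnot(inherits(matching, "template_matching"))
  ms <- matching$matches
  is_v <- vapply(ms, function(m) template_role(m$template) == "V", TRUE) &
    !vapply(ms, function(m) template_is_decoy(m$template), TRUE)
  if (!any(is_v)) stop("chain_report: no V templates in matching")
  out <- list()
  for (cls in c("heavy", "light")) {
    cc <- if (cls == "heavy") "heavy" else c("kappa", "lambda")
    sel <- ms[is_v & vapply(ms, function(m)
      template_chain_class(m$template) %in% cc, TRUE)]
    if (!length(sel)) {
      out[[cls]] <- list(top = NA_character_, top_score = 0L,
                         no_signal = TRUE, table = NULL)
      next
    }
    tab <- data.frame(
      template_id = vapply(sel, function(m) template_id(m$template), ""),
      chain_class = vapply(sel, function(m)
        template_chain_class(m$template), ""),
      aggregate_score = vapply(sel, `[[`, 0, "aggregate_score"),
      n_reads = vapply(sel, function(m) length(m$placements), 0L),
      stringsAsFactors = FALSE)
    tab <- tab[order(-tab$aggregate_score,
                     seq_len(nrow(tab))), , drop = FALSE]
    rownames(tab) <- NULL
    no_signal <- tab$aggregate_score[1] == 0
    out[[cls]] <- list(
      top = if (no_signal) NA_character_ else tab$template_id[1],
      top_score = tab$aggregate_score[1],
      no_signal = no_signal, table = tab)
  }
  out
}

#' Export consensus sequences and score tables
#'
#' Writes consensus sequences as FASTA (`.`-gapped over template
#' coordinates) and per-template scores / per-column weights as CSV.
#'
#' @param consensi Named list of `fab_consensus`.
#' @param matching A `template_matching`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_assembly <- function(consensi, matching, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (length(consensi)) {
    fa <- file.path(dir, "consensus.fasta")
    seqs <- vapply(consensi, consensus_sequence, "")
    writeLines(as.vector(rbind(paste0(">", names(consensi)), seqs)), fa)
    paths <- c(paths, fa)
    wcsv <- file.path(dir, "consensus_weights.csv")
    wdf <- do.call(rbind, lapply(names(consensi), function(nm) {
      cons <- consensi[[nm]]
      data.frame(template = nm, column = seq_along(cons$depth),
                 template_residue = strsplit(template_seq(cons$template),
                                             "")[[1]],
                 consensus = strsplit(cons$consensus, "")[[1]],
                 depth = cons$depth,
                 top_weight = apply(cons$weights, 2, max))
    }))
    utils::write.csv(wdf, wcsv, row.names = FALSE)
    paths <- c(paths, wcsv)
  }
  scsv <- file.path(dir, "template_scores.csv")
  sdf <- data.frame(
    template_id = names(matching$matches),
    role = vapply(matching$matches, function(m) template_role(m$template), ""),
    chain_class = vapply(matching$matches, function(m)
      template_chain_class(m$template) %||% NA_character_, ""),
    is_decoy = vapply(matching$matches, function(m)
      template_is_decoy(m$template), TRUE),
    aggregate_score = vapply(matching$matches, `[[`, 0, "aggregate_score"),
    n_reads = vapply(matching$matches, function(m) length(m$placements), 0L))
  utils::write.csv(sdf, scsv, row.names = FALSE)
  invisible(c(paths, scsv))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
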