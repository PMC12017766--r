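# shared fixtures -----------------------------------------------------------

bundled_repertoire <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- load_germline_repertoire(
        system.file("extdata", "germlines_synthetic.fasta", package = "fabseq"))
    cache
  }
})

# scheme without I/L equivalence (EM-style) and the default MS scheme
em_scheme <- function() scoring_scheme(equivalence_sets = list())
ms_scheme <- function() scoring_scheme()

# write a small germline FASTA and return the path
write_fasta <- function(records, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(records), function(h)
    c(paste0(">", h), records[[h]]))), path)
  path
}

# a minimal single-chain mmCIF with explicit B-factors; residues is a
# character vector of three-letter codes, resno a parallel integer vector
write_mmcif <- function(chains, path = tempfile(fileext = ".cif")) {
  hdr <- c("data_fixture", "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- character(0)
  id <- 0L
  for (ch in names(chains)) {
    x <- chains[[ch]]
    for (k in seq_along(x$resid)) {
      for (atom in x$atoms[[k]]) {
        id <- id + 1L
        rows <- c(rows, sprintf(
          "ATOM %d C %s . %s %s 1 %d ? %.1f 0.0 0.0 1.00 %.2f ? %d %s %s %s 1",
          id, atom, x$resid[k], ch, x$resno[k], id * 1.5, x$b[k],
          x$resno[k], x$resid[k], ch, atom))
      }
    }
  }
  writeLines(c(hdr, rows), path)
  path
}

# simple one-atom-per-residue chain spec for write_mmcif
chain_spec <- function(resid, resno, b, atoms = NULL) {
  list(resid = resid, resno = resno, b = b,
       atoms = atoms %||% rep(list("CA"), length(resid)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random residue strings over a restricted alphabet
random_seqs <- function(n, max_len, alphabet = c("A", "C", "G", "T")) {
  replicate(n, paste(sample(alphabet, sample.int(max_len, 1), replace = TRUE),
                     collapse = ""))
}

# build a sim_truth-shaped object directly (white-box, for cleavage tests)
fake_truth <- function(mature, cdr3 = "", anchors = c(1L, 2L)) {
  structure(list(v_id = "Vx", j_id = "Jx", chain_class = "heavy",
                 shm_rate = 0, cdr3 = cdr3, mature_sequence = mature,
                 mutated_positions = integer(0), anchor_positions = anchors,
                 seed = 0L),
            class = "sim_truth")
}

# forge a template_matching with given aggregate scores (for ranking tests)
forge_matching <- function(segments, scores) {
  matches <- lapply(seq_along(segments), function(i)
    structure(list(template = segments[[i]], placements = list(),
                   aggregate_score = scores[i]),
              class = "template_match"))
  names(matches) <- vapply(segments, `[[`, "", "segment_id")
  structure(list(matches = matches, discarded = list(),
                 counts = list(input = 0L), cutoff_score = 8L),
            class = "template_matching")
}
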