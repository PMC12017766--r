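test_that("single-record FASTA loads as one V segment", {
  fa <- write_fasta(list(
    "IGHV5-51|Homo sapiens|heavy|V" = "EVQLVQSGYYCAR"))
  rep <- load_germline_repertoire(fa)
  expect_length(rep$segments, 1)
  seg <- rep$segments[[1]]
  expect_equal(seg$segment_id, "IGHV5-51")
  expect_equal(seg$chain_class, "heavy")
  expect_equal(seg$segment_type, "V")
  expect_equal(rep$species_set, "Homo sapiens")
})

test_that("bundled repertoire matches an independent FASTA parser", {
  fa <- system.file("extdata", "germlines_synthetic.fasta", package = "fabseq")
  rep <- bundled_repertoire()
  ref <- seqinr::read.fasta(fa, seqtype = "AA", as.string = TRUE)
  expect_length(rep$segments, length(ref))
  expect_equal(rep$species_set, "Homo sapiens")
  # sequences agree record by record (loader strips '.'/'*', none here)
  got <- vapply(rep$segments, `[[`, "", "sequence")
  expect_equal(unname(got), toupper(unname(vapply(ref, as.character, ""))))
})

test_that("malformed headers, duplicates and gap characters are handled", {
  expect_error(load_germline_repertoire(write_fasta(list(bad = "ACDE"))),
               "malformed")
  expect_error(load_germline_repertoire(write_fasta(list(
    "A|Homo sapiens|heavy|V" = "ACDEC",
    "A|Homo sapiens|heavy|V" = "ACDFC"))), "duplicate")
  rep <- load_germline_repertoire(write_fasta(list(
    "A|Homo sapiens|heavy|V" = "ac.de*c")))
  expect_equal(rep$segments[[1]]$sequence, "ACDEC")
})

test_that("V anchor is the last Cys; J anchor honours the [WF]G.G motif", {
  v <- germline_segment("V1", "sp", "heavy", "V", "CAAYYCAR")
  v <- annotate_anchor(v)
  expect_equal(v$anchor_index, 6L)
  expect_false(v$anchor_flagged)

  # no W/F at all -> flagged, anchor unset
  j0 <- annotate_anchor(germline_segment("J0", "sp", "kappa", "J",
                                         "GTKLEIKR"))
  expect_true(j0$anchor_flagged)
  expect_true(is.na(j0$anchor_index))

  # F in the FG.G motif wins even at position 1
  j1 <- annotate_anchor(germline_segment("J1", "sp", "kappa", "J",
                                         "FGQGTKLEIK"))
  expect_equal(j1$anchor_index, 1L)

  # motif occurrence beats an earlier bare W
  j2 <- annotate_anchor(germline_segment("J2", "sp", "kappa", "J",
                                         "WTFGQGTKVEIK"))
  expect_equal(j2$anchor_index, 3L)

  # no motif: first W/F anywhere
  j3 <- annotate_anchor(germline_segment("J3", "sp", "heavy", "J",
                                         "AAWAAF"))
  expect_equal(j3$anchor_index, 3L)

  expect_error(annotate_anchor(germline_segment("C1", "sp", "heavy", "C",
                                                "AAA")),
               "V and J")
})

test_that("annotate_anchor is idempotent", {
  segs <- repertoire_segments(bundled_repertoire(), c("V", "J"))
  for (s in segs) expect_identical(annotate_anchor(s), s)
})

test_that("anchor invariants are enforced at construction", {
  expect_error(germline_segment("V", "sp", "heavy", "V", "ACDEF",
                                anchor_index = 3),
               "must be 'C'")
  expect_error(germline_segment("J", "sp", "heavy", "J", "ACDEF",
                                anchor_index = 1),
               "'W' or 'F'")
  expect_error(germline_segment("V", "sp", "heavy", "V", "AC",
                                anchor_index = 5), "out of range")
})

test_that("pairwise V identity is symmetric and matches known cases", {
  mk <- function(id, s) germline_segment(id, "sp", "heavy", "V", s)
  a <- mk("a", "ACDEF")
  expect_equal(pairwise_v_identity(a, a), 1.0)
  b <- mk("b", "ACDFF")
  expect_equal(pairwise_v_identity(a, b), 0.8)
  expect_equal(pairwise_v_identity(b, a), pairwise_v_identity(a, b))
  # one-gap 12-mer pair: score must equal the enumeration oracle and the
  # identity is 11 matches over 12 columns
  c1 <- mk("c1", "ACDEFGHIKMWY")
  c2 <- mk("c2", "ACDEFGHIKWYA")
  sch <- em_scheme()
  expect_identical(
    global_align(c1$sequence, c2$sequence, sch)$score,
    fabseq:::oracle_global_cpp(fabseq:::seq_to_idx(c1$sequence),
                               fabseq:::seq_to_idx(c2$sequence),
                               sch$substitution, sch$gap_open,
                               sch$gap_extend))
  expect_equal(pairwise_v_identity(c1, c2), pairwise_v_identity(c2, c1))
})

test_that("repertoire baseline equals brute-force pair enumeration", {
  mk <- function(id, s, cls = "heavy")
    germline_segment(id, "sp", cls, "V", s)
  same <- new_rep <- fabseq:::new_repertoire(
    list(mk("a", "ACDEFC"), mk("b", "ACDEFC"), mk("c", "ACDEFC")))
  base <- repertoire_baseline(same, "heavy", "sp")
  expect_equal(base$mean, 1.0)
  expect_equal(base$median, 1.0)

  segs <- list(mk("a", "ACDEFGHIKL"), mk("b", "ACDEFGHIKW"),
               mk("c", "ACWEFGHLKW"))
  rep3 <- fabseq:::new_repertoire(segs)
  ids <- c(pairwise_v_identity(segs[[1]], segs[[2]]),
           pairwise_v_identity(segs[[1]], segs[[3]]),
           pairwise_v_identity(segs[[2]], segs[[3]]))
  base3 <- repertoire_baseline(rep3, "heavy", "sp")
  expect_equal(base3$mean, mean(ids))
  expect_equal(base3$median, median(ids))
  expect_equal(base3$n_pairs, 3L)

  expect_error(repertoire_baseline(
    fabseq:::new_repertoire(list(mk("a", "ACDEFC"))), "heavy", "sp"),
    ">= 2 V segments")
})

test_that("light-chain baseline pools kappa and lambda V genes", {
  rep <- bundled_repertoire()
  nk <- length(repertoire_segments(rep, "V", "kappa"))
  nl <- length(repertoire_segments(rep, "V", "lambda"))
  pooled <- repertoire_baseline(rep, "light", "Homo sapiens")
  expect_equal(pooled$n_pairs, choose(nk + nl, 2))
})
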