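mkv <- function(id, s, cls = "heavy")
  germline_segment(id, "sp", cls, "V", s)
mkread <- function(id, s, conf = 90)
  sequence_read(id, "em_model", s, rep(conf, nchar(s)))

test_that("a read lands on its unique source template; others score zero", {
  t1 <- mkv("T1", "EVQLVQSGAEVKKPGESLKISC")
  t2 <- mkv("T2", "DIVMTQSPDSLAVSLGERATIN")
  m <- match_reads(list(mkread("r1", "QSGAEVKKPG")), list(t1, t2),
                   em_scheme(), cutoff_score = 8)
  expect_length(m$matches$T1$placements, 1)
  expect_length(m$matches$T2$placements, 0)
  expect_equal(m$matches$T2$aggregate_score, 0)
  expect_gt(m$matches$T1$aggregate_score, 0)
})

test_that("sub-cutoff reads land in the discard bin", {
  t1 <- mkv("T1", "EVQLVQSGAEVKKPG")
  m <- match_reads(list(mkread("weak", "WWWWW")), list(t1), em_scheme(),
                   cutoff_score = 8)
  expect_length(m$discarded, 1)
  expect_equal(m$counts$discarded, 1L)
  expect_equal(m$counts$placed, 0L)
})

test_that("assignment equals a brute-force all-pairs argmax", {
  sch <- em_scheme()
  t1 <- mkv("T1", "EVQLVQSGAEVKKPGESLKISCKGSGYSFTSYWIGC")
  t2 <- mkv("T2", "DIVMTQSPDSLAVSLGERATINCKSSQSVLYSSNNC")
  set.seed(21)
  reads <- lapply(1:12, function(i) {
    src <- if (i %% 2) t1$sequence else t2$sequence
    start <- sample.int(nchar(src) - 9, 1)
    mkread(sprintf("r%02d", i), substr(src, start, start + 8))
  })
  m <- match_reads(reads, list(t1, t2), sch, cutoff_score = 8)
  got <- rep(NA_character_, 12)
  for (tid in names(m$matches))
    for (pl in m$matches[[tid]]$placements)
      got[match(pl$read_ref, sprintf("r%02d", 1:12))] <- tid
  for (i in 1:12) {
    s1 <- local_align(reads[[i]]$residues, t1$sequence, sch)$score
    s2 <- local_align(reads[[i]]$residues, t2$sequence, sch)$score
    want <- if (max(s1, s2) < 8) NA_character_
            else c("T1", "T2")[which.max(c(s1, s2))]
    expect_identical(got[i], want)
  }
  # conservation
  expect_equal(m$counts$placed + m$counts$discarded, 12L)
})

test_that("adding a read never decreases any aggregate score", {
  sch <- em_scheme()
  t1 <- mkv("T1", "EVQLVQSGAEVKKPGESLKISC")
  t2 <- mkv("T2", "DIVMTQSPDSLAVSLGERATIN")
  reads <- list(mkread("a", "QSGAEVKKPG"), mkread("b", "TQSPDSLAVS"),
                mkread("c", "GESLKISC"))
  before <- match_reads(reads[1:2], list(t1, t2), sch, 8)
  after <- match_reads(reads, list(t1, t2), sch, 8)
  for (tid in names(before$matches))
    expect_gte(after$matches[[tid]]$aggregate_score,
               before$matches[[tid]]$aggregate_score)
})

test_that("single-read consensus reproduces the read; uncovered columns dot", {
  tpl <- mkv("T", "EVQLVQSGAEVKKPGESLKI")
  m <- match_reads(list(mkread("r", "EVQLVQSGAE")), list(tpl), em_scheme(), 8)
  cons <- build_consensus(m$matches$T)
  expect_equal(cons$consensus, paste0("EVQLVQSGAE", strrep(".", 10)))
  expect_equal(cons$depth, c(rep(1L, 10), rep(0L, 10)))
})

test_that("higher summed confidence wins the consensus column", {
  tpl <- mkv("T", "EVQLVQSGAEVKKPGESLKI")
  # reads differ at template column 5 (Q): K at conf 90 vs R at conf 30
  r1 <- sequence_read("hi", "em_model", "EVQLKQSGAE", rep(90, 10))
  r2 <- sequence_read("lo", "em_model", "EVQLRQSGAE", rep(30, 10))
  m <- match_reads(list(r1, r2), list(tpl), em_scheme(), 8)
  cons <- build_consensus(m$matches$T)
  expect_equal(substr(cons$consensus, 5, 5), "K")
  expect_equal(cons$depth[5], 2L)
})

test_that("consensus weights equal an independent tally at known offsets", {
  sch <- em_scheme()
  tseq <- "EVQLVQSGAEVKKPGESLKI" # columns distinct enough for exact placement
  tpl <- mkv("T", tseq)
  set.seed(99)
  offs <- c(1, 4, 7, 9, 11)
  reads <- lapply(seq_along(offs), function(i) {
    len <- 8
    sequence_read(sprintf("r%d", i), "em_model",
                  substr(tseq, offs[i], offs[i] + len - 1),
                  runif(len, 60, 100))
  })
  m <- match_reads(reads, list(tpl), sch, 8)
  cons <- build_consensus(m$matches$T)
  # independent tally: error-free substring reads map 1:1 at their offsets
  W <- matrix(0, 21, nchar(tseq),
              dimnames = list(fabseq:::FAB_ALPHABET, NULL))
  depth <- integer(nchar(tseq))
  tch <- strsplit(tseq, "")[[1]]
  for (i in seq_along(reads)) {
    for (k in seq_len(nchar(reads[[i]]$residues))) {
      col <- offs[i] + k - 1
      W[tch[col], col] <- W[tch[col], col] + reads[[i]]$confidences[k]
      depth[col] <- depth[col] + 1L
    }
  }
  expect_equal(cons$weights, W)
  expect_equal(cons$depth, depth)
  expect_equal(cons$consensus,
               paste(ifelse(depth > 0, tch, "."), collapse = ""))
})

test_that("consensus ties prefer the template residue, then lexicographic", {
  w <- structure(numeric(21), names = fabseq:::FAB_ALPHABET)
  w["K"] <- 50; w["R"] <- 50
  expect_equal(fabseq:::argmax_residue(w, "R"), "R") # template wins the tie
  expect_equal(fabseq:::argmax_residue(w, "A"), "K") # lexicographic K < R
})

test_that("chain_report ranks by aggregate score and pools light classes", {
  segs <- list(mkv("HV1", "EVQAAAC"), mkv("HV2", "EVQCCCC"),
               mkv("KV1", "DIVAAAC", "kappa"), mkv("LV1", "QSVAAAC", "lambda"))
  set.seed(3)
  scores <- c(40, 90, 12, 30)
  rep_tab <- chain_report(forge_matching(segs, scores))
  expect_equal(rep_tab$heavy$top, "HV2")
  expect_equal(rep_tab$light$top, "LV1")
  expect_equal(rep_tab$light$table$template_id, c("LV1", "KV1"))
  # independent sort
  expect_equal(rep_tab$heavy$table$aggregate_score,
               sort(scores[1:2], decreasing = TRUE))

  none <- chain_report(forge_matching(segs, c(0, 0, 0, 0)))
  expect_true(none$heavy$no_signal)
  expect_true(is.na(none$light$top))
})

test_that("sink templates absorb constant-domain reads", {
  v <- mkv("V1", "EVQLVQSGAEVKKPGESLKISC")
  sink <- germline_segment("CH1", "sp", "heavy", "C",
                           "ASTKGPSVFPLAPSSKSTSGGT")
  m <- match_reads(list(mkread("fv", "QSGAEVKKPG"),
                        mkread("c1", "GPSVFPLAPS")),
                   list(v, sink), em_scheme(), 8)
  expect_equal(m$counts$sink_absorbed, 1L)
  expect_equal(m$counts$variable, 1L)
  expect_length(m$matches$CH1$placements, 1)
})
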