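anno <- function(seg) annotate_anchor(seg)
mkv2 <- function(id, s, cls = "heavy")
  anno(germline_segment(id, "sp", cls, "V", s))
mkj2 <- function(id, s, cls = "heavy")
  anno(germline_segment(id, "sp", cls, "J", s))

test_that("recombined template is V-prefix + CDR3 + J-suffix exactly", {
  v <- mkv2("V1", "EVQAVYYC")
  j <- mkj2("J1", "YFDYWGQGTLV")
  rt <- recombined_template(v, "ARDF", j)
  expect_equal(rt$sequence, paste0("EVQAVYYC", "ARDF", "WGQGTLV"))
  expect_equal(nchar(rt$sequence),
               v$anchor_index + 4 + (nchar(j$sequence) - j$anchor_index + 1))
  expect_equal(rt$v_anchor_col, 8L)
  expect_equal(rt$j_anchor_col, 13L)
  expect_equal(substr(rt$sequence, rt$v_anchor_col, rt$v_anchor_col), "C")
  expect_true(substr(rt$sequence, rt$j_anchor_col, rt$j_anchor_col)
              %in% c("W", "F"))
})

test_that("uncovered CDR3 yields an X-run placeholder of default length 12", {
  v <- mkv2("V1", "EVQAVYYC")
  j <- mkj2("J1", "YFDYWGQGTLV")
  uncov <- structure(list(covered = FALSE, sequence = "", length = 0L),
                     class = "cdr_result")
  tps <- build_recombined_templates(v, uncov, j, bundled_repertoire(),
                                    use_decoys = FALSE)
  expect_length(tps, 1)
  expect_equal(tps[[1]]$cdr3_placeholder, strrep("X", 12))
})

test_that("decoy construction appends every other V segment", {
  vs <- lapply(1:15, function(i)
    mkv2(sprintf("V%02d", i),
         paste0(paste(sample(c("E","V","Q","A","G","S","T"), 20,
                             replace = TRUE), collapse = ""), "YYC")))
  rep15 <- fabseq:::new_repertoire(c(vs, list(mkj2("J1", "YFDYWGQGTLV"))))
  tps <- build_recombined_templates(vs[[1]], NULL, rep15$segments[[16]],
                                    rep15, use_decoys = TRUE)
  expect_length(tps, 15) # 1 primary + 14 decoys
  expect_false(tps[[1]]$is_decoy)
  expect_true(all(vapply(tps[-1], function(x) isTRUE(x$is_decoy), TRUE)))
  expect_error(build_recombined_templates(vs[[1]], NULL, NULL, rep15, TRUE),
               "no J")
})

test_that("CDR3 detection spans the anchors and excludes them", {
  v <- mkv2("V1", "EVQAGSTAVYYC")
  j <- mkj2("J1", "WGQGTLVTVSS")
  rt <- recombined_template(v, "ARDF", j)
  # one read covering the whole junction
  r <- sequence_read("r", "em_model", rt$sequence,
                     rep(90, nchar(rt$sequence)))
  m <- match_reads(list(r), list(rt), em_scheme(), 8)
  cdr <- detect_cdr3(build_consensus(m$matches[[1]]))
  expect_true(cdr$covered)
  expect_equal(cdr$sequence, "ARDF")
  expect_equal(cdr$length, 4L)

  # read stops before the J anchor -> not covered, empty sequence
  r2 <- sequence_read("r2", "em_model",
                      substr(rt$sequence, 1, rt$j_anchor_col - 1),
                      rep(90, rt$j_anchor_col - 1))
  m2 <- match_reads(list(r2), list(rt), em_scheme(), 8)
  cons2 <- build_consensus(m2$matches[[1]])
  expect_equal(cons2$depth[rt$j_anchor_col], 0L)
  cdr2 <- detect_cdr3(cons2)
  expect_false(cdr2$covered)
  expect_equal(cdr2$sequence, "")
})

test_that("CDR3 coverage matches simulator ground truth over seeded cases", {
  rep <- bundled_repertoire()
  set.seed(77)
  seeds <- sample.int(1e6, 30)
  covs <- runif(30, 0.6, 3)
  n_checked <- 0
  for (i in 1:30) {
    truth <- simulate_antibody(rep, "heavy", shm_rate = 0.05,
                               cdr3_length = sample(8:16, 1), seed = seeds[i])
    v <- fabseq:::find_segment(rep, truth$v_id, "V")
    j <- fabseq:::find_segment(rep, truth$j_id, "J")
    rt <- recombined_template(v, truth$cdr3, j)
    reads <- simulate_model_reads(truth, coverage = covs[i],
                                  error_rate = 0, seed = seeds[i] + 1)
    m <- match_reads(reads, list(rt), em_scheme(), 8)
    if (!length(m$matches[[1]]$placements)) next
    cdr <- detect_cdr3(build_consensus(m$matches[[1]]))
    # ground truth from the simulator's read positions
    covvec <- integer(nchar(truth$mature_sequence))
    for (r in m$matches[[1]]$placements) {
      st <- r$read$truth_start
      covvec[st:(st + nchar(r$read$residues) - 1)] <-
        covvec[st:(st + nchar(r$read$residues) - 1)] + 1L
    }
    anch <- truth$anchor_positions
    expect_identical(cdr$covered, all(covvec[anch[1]:anch[2]] > 0))
    if (cdr$covered) {
      expect_equal(cdr$length, nchar(truth$cdr3))
      expect_equal(cdr$sequence, truth$cdr3)
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 25)
})

test_that("guided assembly recovers the exact sequence on noise-free reads", {
  rep <- bundled_repertoire()
  truth <- simulate_antibody(rep, "heavy", shm_rate = 0, seed = 5)
  v <- fabseq:::find_segment(rep, truth$v_id, "V")
  j <- fabseq:::find_segment(rep, truth$j_id, "J")
  rt <- build_recombined_templates(v, NULL, j, rep, use_decoys = TRUE)
  ms <- simulate_ms_dataset(truth, n_replicates = 10, seed = 6,
                            error_rate = 0, il_swap_p = 0)
  g <- assemble_guided(ms, rt, ms_scheme())
  h <- g$chains$heavy
  expect_false(h$empty)
  ci <- consensus_identity(h$consensus, truth$mature_sequence, ms_scheme())
  expect_equal(ci$covered_only, 1.0)
  full_seq <- consensus_sequence(h$consensus, fallback = "template")
  expect_equal(consensus_identity(full_seq, truth$mature_sequence,
                                  ms_scheme())$full, 1.0)
})

test_that("guided assembly reports an explicit empty result when nothing passes", {
  rep <- bundled_repertoire()
  v <- fabseq:::find_segment(rep, "IGHV5-51", "V")
  j <- fabseq:::find_segment(rep, "IGHJ4", "J")
  rt <- build_recombined_templates(v, NULL, j, rep, use_decoys = FALSE)
  low <- list(sequence_read("low", "ms_peptide", "EVQLVQSG", rep(50, 8)))
  g <- assemble_guided(low, rt, ms_scheme(), cutoff_alc = 90)
  expect_true(g$chains$heavy$empty)
  expect_equal(g$counts$kept, 0L)
})
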