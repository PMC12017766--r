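test_that("zero SHM reproduces the pure recombination", {
  rep <- bundled_repertoire()
  tr <- simulate_antibody(rep, "heavy", shm_rate = 0, seed = 3)
  v <- fabseq:::find_segment(rep, tr$v_id, "V")
  j <- fabseq:::find_segment(rep, tr$j_id, "J")
  naive <- paste0(substr(v$sequence, 1, v$anchor_index), tr$cdr3,
                  substr(j$sequence, j$anchor_index, nchar(j$sequence)))
  expect_equal(tr$mature_sequence, naive)
  expect_length(tr$mutated_positions, 0)
})

test_that("SHM rate 1 mutates every non-anchor position and spares anchors", {
  rep <- bundled_repertoire()
  tr0 <- simulate_antibody(rep, "heavy", shm_rate = 0, seed = 3)
  tr1 <- simulate_antibody(rep, "heavy", shm_rate = 1, seed = 3)
  expect_equal(tr1$v_id, tr0$v_id) # same segment draw under the same seed
  a <- strsplit(tr0$mature_sequence, "")[[1]]
  b <- strsplit(tr1$mature_sequence, "")[[1]]
  anch <- tr1$anchor_positions
  expect_equal(b[anch[1]], "C")
  expect_true(b[anch[2]] %in% c("W", "F"))
  nonanchor <- setdiff(seq_along(a), anch)
  expect_true(all(a[nonanchor] != b[nonanchor]))
  expect_setequal(tr1$mutated_positions, nonanchor)
})

test_that("observed SHM fraction sits within 3 binomial SD of the rate", {
  rep <- bundled_repertoire()
  p <- 0.05
  n_draws <- 400
  fracs <- vapply(seq_len(n_draws), function(i) {
    tr <- simulate_antibody(rep, "heavy", shm_rate = p, seed = 1000 + i)
    length(tr$mutated_positions) /
      (nchar(tr$mature_sequence) - 2L)
  }, 0)
  n_pos <- 115 # approximate eligible positions per draw
  se <- sqrt(p * (1 - p) / (n_draws * n_pos))
  expect_lt(abs(mean(fracs) - p), 3 * se + 1e-3)
})

test_that("generators are bit-reproducible given the seed", {
  rep <- bundled_repertoire()
  expect_identical(simulate_antibody(rep, "kappa", seed = 9),
                   simulate_antibody(rep, "kappa", seed = 9))
  tr <- simulate_antibody(rep, "heavy", seed = 9)
  expect_identical(simulate_model_reads(tr, seed = 4),
                   simulate_model_reads(tr, seed = 4))
  expect_identical(simulate_peptide_reads(tr, seed = 4),
                   simulate_peptide_reads(tr, seed = 4))
  bg <- simulate_background(rep, 2, 10, seed = 5)
  bg2 <- simulate_background(rep, 2, 10, seed = 5)
  attributes(bg) <- attributes(bg2) <- NULL
  expect_identical(bg, bg2)
})

test_that("error-free model reads are exact substrings at their true offsets", {
  rep <- bundled_repertoire()
  tr <- simulate_antibody(rep, "heavy", seed = 13)
  reads <- simulate_model_reads(tr, coverage = 5, error_rate = 0, seed = 14)
  total <- 0L
  for (r in reads) {
    expect_equal(r$residues,
                 substr(tr$mature_sequence, r$truth_start,
                        r$truth_start + nchar(r$residues) - 1))
    total <- total + nchar(r$residues)
  }
  expect_gte(total, 5 * nchar(tr$mature_sequence))
})

test_that("model-read error rate sits within 3 binomial SD of nominal", {
  rep <- bundled_repertoire()
  tr <- simulate_antibody(rep, "heavy", seed = 13)
  p <- 0.1
  nerr <- 0L
  ntot <- 0L
  for (s in 1:25) {
    reads <- simulate_model_reads(tr, coverage = 4, error_rate = p,
                                  seed = 100 + s)
    for (r in reads) {
      truth_piece <- substr(tr$mature_sequence, r$truth_start,
                            r$truth_start + nchar(r$residues) - 1)
      d <- strsplit(r$residues, "")[[1]] != strsplit(truth_piece, "")[[1]]
      nerr <- nerr + sum(d)
      ntot <- ntot + length(d)
    }
  }
  expect_lt(abs(nerr / ntot - p), 3 * sqrt(p * (1 - p) / ntot))
})

test_that("confidence tracks accuracy so ALC filtering has signal", {
  rep <- bundled_repertoire()
  tr <- simulate_antibody(rep, "heavy", seed = 13)
  reads <- simulate_model_reads(tr, coverage = 10, error_rate = 0.3, seed = 1)
  conf_err <- conf_ok <- numeric(0)
  for (r in reads) {
    truth_piece <- substr(tr$mature_sequence, r$truth_start,
                          r$truth_start + nchar(r$residues) - 1)
    d <- strsplit(r$residues, "")[[1]] != strsplit(truth_piece, "")[[1]]
    conf_err <- c(conf_err, r$confidences[d])
    conf_ok <- c(conf_ok, r$confidences[!d])
  }
  expect_gt(mean(conf_ok), mean(conf_err))
  expect_lt(abs(mean(conf_ok) - 90), 2)
  expect_lt(abs(mean(conf_err) - 60), 4)
})

test_that("tryptic cleavage cuts after K/R but not before P", {
  tr <- fake_truth("AAKGGRCC")
  reads <- simulate_peptide_reads(tr, missed_cleavage_p = 0, error_rate = 0,
                                  il_swap_p = 0, seed = 1)
  expect_equal(vapply(reads, `[[`, "", "residues"), c("AAK", "GGR", "CC"))
  expect_equal(vapply(reads, `[[`, 0L, "truth_start"), c(1L, 4L, 7L))

  trp <- fake_truth("AAKPGGRCC")
  readsp <- simulate_peptide_reads(trp, 0, 0, 0, seed = 1)
  expect_equal(vapply(readsp, `[[`, "", "residues"), c("AAKPGGR", "CC"))
})

test_that("full I/L swap exchanges every I and L", {
  tr <- fake_truth("AILKILR")
  reads <- simulate_peptide_reads(tr, missed_cleavage_p = 0, error_rate = 0,
                                  il_swap_p = 1, seed = 2)
  expect_equal(paste(vapply(reads, `[[`, "", "residues"), collapse = ""),
               "ALIKLIR")
})

test_that("missed-cleavage fraction sits within 3 binomial SD of nominal", {
  tr <- fake_truth(strrep("AAKBBK", 10)) # 19 internal junctions
  tr$mature_sequence <- gsub("B", "G", tr$mature_sequence)
  p <- 0.5
  n_junc <- 19L
  merged <- 0L
  n_seeds <- 200L
  for (s in seq_len(n_seeds)) {
    reads <- simulate_peptide_reads(tr, missed_cleavage_p = p,
                                    error_rate = 0, il_swap_p = 0, seed = s)
    merged <- merged + (n_junc - (length(reads) - 1L))
  }
  frac <- merged / (n_seeds * n_junc)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / (n_seeds * n_junc)))
})

test_that("background read counts honour the requested ratio", {
  rep <- bundled_repertoire()
  bg5 <- simulate_background(rep, n_antibodies = 5, reads_per_antibody = 20,
                             seed = 7)
  expect_length(bg5, 100) # 5:1 against a 20-read target
  bg1 <- simulate_background(rep, n_antibodies = 1, reads_per_antibody = 20,
                             seed = 7)
  expect_length(bg1, 20) # 1:1
  # distinct V genes across background antibodies
  truths <- attr(bg5, "truths")
  vh <- vapply(truths[grepl("heavy", names(truths))], `[[`, "", "v_id")
  expect_equal(anyDuplicated(vh), 0L)
  expect_error(simulate_background(rep, n_antibodies = 50, seed = 1),
               "distinct")
})
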