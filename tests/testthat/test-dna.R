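test_that("sequence validation normalizes case and names bad positions", {
  s <- nucleotide_sequence("gtac", id = "p")
  expect_equal(s$bases, "GTAC")
  expect_error(nucleotide_sequence("ACGX"), "position 4")
  expect_error(nucleotide_sequence(""), "non-empty")
})

test_that("two-bit encoding is the declared code and a bijection", {
  expect_equal(encode_binary("A"), "00")
  expect_equal(encode_binary("GTAC"), "10110001")
  set.seed(3)
  for (len in c(1, 7, 64, 301)) {
    s <- random_dna(len)
    bits <- encode_binary(s)
    expect_equal(nchar(bits), 2 * len)
    expect_equal(decode_binary(bits)$bases, s)
  }
  expect_error(decode_binary("012"), "0/1")
})

test_that("match score agrees with brute-force pairing in both modes", {
  r <- match_score("ACGT", "ACGT", mode = "identity")
  expect_equal(r$match_score, 100)
  r2 <- match_score("ACGT", "TGCA", mode = "complement")
  expect_equal(r2$match_score, 100)
  r3 <- match_score("ACGTAC", "TGCAAA", mode = "complement")
  expect_equal(r3$match_count, 4)
  expect_equal(r3$match_score, 100 * 4 / 6, tolerance = 1e-12)
  set.seed(9)
  for (i in 1:50) {
    a <- random_dna(sample(1:200, 1))
    b <- random_dna(sample(1:200, 1))
    for (mode in c("identity", "complement")) {
      got <- match_score(a, b, mode = mode)
      want <- brute_force_match(a, b, mode)
      expect_equal(got$match_count, want$count)
      expect_equal(got$min_length, want$min_length)
      expect_equal(got$match_score, want$score)
    }
  }
})

test_that("match score is symmetric for equal-length pairs", {
  set.seed(21)
  for (i in 1:20) {
    len <- sample(1:100, 1)
    a <- random_dna(len)
    b <- random_dna(len)
    for (mode in c("identity", "complement")) {
      expect_equal(match_score(a, b, mode = mode)$match_count,
                   match_score(b, a, mode = mode)$match_count)
    }
  }
})

test_that("reverse-complement pairs score 100% with target reversal", {
  set.seed(33)
  for (len in c(1, 2, 17, 100, 500)) {
    s <- random_dna(len)
    rc <- reverse_complement(s)$bases
    r <- match_score(s, rc, mode = "complement", reverse_target = TRUE)
    expect_equal(r$match_score, 100)
  }
})

test_that("proton release is linear in match count with the frozen gain", {
  model <- ion_release_model()
  expect_equal(hplus_from_hybridization(0, model), 0)
  expect_equal(hplus_from_hybridization(2e5, model),
               2 * hplus_from_hybridization(1e5, model))
  # 1e9 matches, 1 ion each, 1 uL: N_A bookkeeping
  expect_equal(hplus_from_hybridization(1e9, model),
               1.6605778811026237e-09, tolerance = 1e-12)
})

test_that("pH is the negative decade logarithm", {
  expect_equal(ph_from_h(1e-7), 7)
  expect_equal(ph_from_h(1e-4), 4)
  expect_equal(ph_from_h(1e-7 + 9e-7), 6, tolerance = 1e-12)
  expect_error(ph_from_h(0), "positive")
})

test_that("carrier shift is the linear gain on the concentration change", {
  model <- ion_release_model(charge_to_density_gain = 1e19)
  expect_equal(hybridization_to_carrier_shift(0, model), 0)
  expect_equal(hybridization_to_carrier_shift(1e-6, model), 1e13)
  expect_equal(hybridization_to_carrier_shift(2e-6, model),
               2 * hybridization_to_carrier_shift(1e-6, model))
})

test_that("end-to-end detection composes the stages and is monotone", {
  probe <- strrep("ACGT", 25)
  full <- detect_end_to_end(probe, reverse_complement(probe)$bases,
                            reverse_target = TRUE)
  none <- detect_end_to_end("AAAA", "AAAA")       # A-A never pairs
  expect_equal(none$score$match_count, 0)
  expect_equal(none$freq_shift_hz, 0)
  expect_gt(full$freq_shift_hz, 0)
  # spot check against a manual stage-by-stage composition
  model <- ion_release_model()
  sc <- match_score(probe, reverse_complement(probe)$bases,
                    reverse_target = TRUE)
  dh <- hplus_from_hybridization(sc, model)
  dn <- hybridization_to_carrier_shift(dh, model)
  n0 <- sil$residual_carrier_density * 1e4
  g <- device_geometry_for(sil)
  f0 <- resonant_frequency(lc_readout(), cq_degenerate(n0, sil, g))
  f1 <- resonant_frequency(lc_readout(), cq_degenerate(n0 + dn, sil, g))
  expect_equal(full$freq_shift_hz, f0 - f1, tolerance = 1e-12)
  expect_equal(full$ph, ph_from_h(model$baseline_h + dh))
  # pH strictly decreases as matches accumulate
  half <- detect_end_to_end(strrep("A", 100),
                            paste0(strrep("T", 50), strrep("C", 50)))
  expect_lt(full$ph, none$ph)
  expect_gt(full$freq_shift_hz, half$freq_shift_hz)
  expect_gt(half$freq_shift_hz, 0)
})

test_that("fixture pairs plant exact scores and round-trip through FASTA", {
  fx <- make_fixture_pairs(8, length = 40, mismatch_frac = 0.25, seed = 5)
  expect_equal(nrow(fx), 8)
  expect_equal(fx$expected_score_pct, rep(75, 8))
  scores <- vapply(seq_len(nrow(fx)), function(i) {
    match_score(fx$probe[i], fx$target[i])$match_score
  }, numeric(1))
  expect_equal(scores, fx$expected_score_pct)
  # determinism under the seed
  fx2 <- make_fixture_pairs(8, length = 40, mismatch_frac = 0.25, seed = 5)
  expect_identical(fx, fx2)
  # FASTA round trip preserves the pairs and their scores
  td <- withr::local_tempdir()
  p <- file.path(td, "p.fasta"); t <- file.path(td, "t.fasta")
  write_fixture_fasta(fx, p, t, file.path(td, "truth.csv"))
  pairs <- read_sequence_pairs(p, t)
  expect_length(pairs, 8)
  rescored <- hybridize_pairs(pairs)
  expect_equal(rescored$match_score_pct, fx$expected_score_pct)
  truth <- read.csv(file.path(td, "truth.csv"))
  expect_equal(truth$expected_score_pct, fx$expected_score_pct)
})
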