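test_that("tandem hairpin detection on constructed and degenerate inputs", {
  # two copies of a perfect hairpin (stem 4 incl. C:G close, loop AUCGCC)
  seq <- "GGACAUCGCCGUCCAAAGGACAUCGCCGUCC"
  mc <- foldTandemHairpins(seq)
  expect_s4_class(mc, "MotifCall")
  expect_true(mc@isCanonical)
  expect_equal(mc@spacerLen, 3L)
  expect_equal(mc@hit1$closing_pair, "C:G")
  expect_equal(mc@hit2$closing_pair, "C:G")
  # stem 4 + closing C:G (2) + loop A1 (1) + loop G4 (1) per hairpin
  expect_equal(mc@totalScore, 16)

  # homopolymer folds nothing
  expect_null(foldTandemHairpins(strrep("A", 30)))
  # a single hairpin is not a tandem motif
  expect_null(foldTandemHairpins("GGACAUCGCCGUCC"))
  expect_null(foldTandemHairpins(paste0("GGACAUCGCCGUCC", strrep("A", 17))))

  # T converts to U with a warning; other letters are an error
  expect_warning(mcT <- foldTandemHairpins(gsub("U", "T", seq)),
                 "T to U")
  expect_equal(mcT@totalScore, 16)
  expect_error(foldTandemHairpins("GGACNUCGCC"), "non-ACGU")
})

test_that("hairpin scan matches exhaustive brute force on short sequences", {
  set.seed(99)
  cases <- c(
    "GGACAUCGCCGUCCAAAGGACAUCGCCGUCC",
    "GGACAUCGCCGUCCGGACAUCGCCGUCC",     # spacer 0
    strrep("A", 30),
    strrep("GU", 20),
    vapply(1:60, function(i) randomRNA(sample(12:40, 1)), ""))
  for (s in cases) {
    mc <- foldTandemHairpins(s)
    want <- oracleTandemScore(s)
    if (is.na(want)) {
      expect_null(mc)
    } else {
      expect_equal(mc@totalScore, want, info = s)
    }
  }
})

test_that("selection without pressure leaves motif frequency at sampling noise", {
  planted <- "GGACAUCGCCGUCCAAGGACAUCGCCGUCC"
  s <- simulateSelex(poolSize = 400, rounds = 4, beta = 0, seed = 21,
                     plantedMotif = planted, plantedFrequency = 0.05)
  e <- enrichmentTable(s)
  f0 <- e$freq_round_0[1]
  f4 <- e$freq_round_4[1]
  # binomial noise over 4 neutral resampling rounds
  se <- sqrt(f0 * (1 - f0) / 400) * sqrt(4)
  expect_lt(abs(f4 - f0), 5 * se)

  # epsilon = 1: identical retention for every sequence
  s1 <- simulateSelex(poolSize = 400, rounds = 2, beta = 5, epsilon = 1,
                      seed = 22, plantedMotif = planted,
                      plantedFrequency = 0.05)
  e1 <- enrichmentTable(s1)
  expect_lt(abs(e1$freq_round_2[1] - e1$freq_round_0[1]), 5 * se)
})

test_that("strong selection enriches a planted motif monotonically (seeded)", {
  g <- genSelexPool("tandem-hairpin-pool", seed = 42)
  e <- enrichmentTable(g$experiment)
  freqs <- as.numeric(e[1, grep("freq_round", names(e))])
  expect_true(all(diff(freqs) > 0))
  expect_gt(e$fold_change[1], 5)
})

test_that("simulations are byte-identical under a fixed seed", {
  a <- genSelexPool("tandem-hairpin-pool", seed = 7)$experiment
  b <- genSelexPool("tandem-hairpin-pool", seed = 7)$experiment
  expect_identical(selexRounds(a), selexRounds(b))
  c <- genSelexPool("tandem-hairpin-pool", seed = 8)$experiment
  expect_false(identical(selexRounds(a)[[1]], selexRounds(c)[[1]]))
})

test_that("consensus logo recovers the planted loop preferences", {
  g <- genSelexPool("tandem-hairpin-pool", seed = 13)
  logo <- consensusLogo(g$experiment)
  expect_gt(logo$n_calls, 0)
  # planted loop AUCGCC: A dominates loop position 1, G position 4,
  # and both closing pairs are C:G
  for (h in c("h1", "h2")) {
    expect_equal(names(which.max(logo$heights[paste0(h, "_loop1"), ])), "A")
    expect_equal(names(which.max(logo$heights[paste0(h, "_loop4"), ])), "G")
    expect_equal(names(which.max(logo$heights[paste0(h, "_close5"), ])), "C")
    expect_equal(names(which.max(logo$heights[paste0(h, "_close3"), ])), "G")
  }
  # heights row sums equal the position's relative entropy
  expect_equal(rowSums(logo$heights), logo$ic_bits)
})

test_that("enrichment handles the all-motif and absent-feature edges", {
  planted <- "GGACAUCGCCGUCCAAGGACAUCGCCGUCC"
  s <- simulateSelex(poolSize = 50, rounds = 2, beta = 2, seed = 3,
                     plantedMotif = planted, plantedFrequency = 1)
  e <- enrichmentTable(s)
  expect_true(all(as.numeric(e[1, grep("freq_round", names(e))]) == 1))
  expect_true(is.finite(e$fold_change[1]))

  # a round with zero motif calls yields an empty logo, not an error
  s0 <- simulateSelex(poolSize = 5, seqLen = 12, rounds = 1, beta = 0,
                      seed = 5)
  logo <- consensusLogo(s0, round = 1)
  if (logo$n_calls == 0) {
    expect_equal(nrow(logo$heights), 0L)
    expect_length(logo$ic_bits, 0L)
  }
})
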