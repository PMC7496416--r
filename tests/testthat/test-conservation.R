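test_that("column profiles follow the pseudocount formula and gap rules", {
  aln <- LabeledAlignment(c(a = "A", b = "A", c = "A", d = "A"))
  p <- columnProfiles(aln, pseudocount = 0)
  expect_equal(unname(profileFreqs(p)[1, "A"]), 1.0)
  expect_equal(gapFraction(p), 0)

  aln <- LabeledAlignment(c(a = "A", b = "A", c = "-", d = "-"))
  p <- columnProfiles(aln, pseudocount = 0)
  expect_equal(unname(profileFreqs(p)[1, "A"]), 1.0)
  expect_equal(gapFraction(p), 0.5)
  expect_equal(p@nEffective, 2)

  # (2 + 0.5) / (4 + 20 * 0.5) for the majority residue
  aln <- LabeledAlignment(c(a = "A", b = "A", c = "K", d = "R"))
  p <- columnProfiles(aln, pseudocount = 0.5)
  expect_equal(unname(profileFreqs(p)[1, "A"]), 2.5 / 14)
  expect_equal(sum(profileFreqs(p)), 1)

  # subset with fewer than two members refuses
  expect_error(columnProfiles(aln, subset = "NIT-ANTAR"), "at least 2")
})

test_that("information content matches closed forms and the letter-height contract", {
  point <- LabeledAlignment(c(a = "W", b = "W", c = "W"))
  ic <- informationContent(columnProfiles(point, pseudocount = 0))
  expect_equal(scoreTable(ic)$bits, log2(20))
  expect_equal(sum(letterHeights(ic)[1, ]), log2(20))
  expect_equal(unname(letterHeights(ic)[1, "W"]), log2(20))

  # p equal to background scores zero
  even <- LabeledAlignment(setNames(AA <- c("A", "C", "D", "E", "F", "G",
    "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
    paste0("s", 1:20)))
  ic0 <- informationContent(columnProfiles(even, pseudocount = 0))
  expect_equal(scoreTable(ic0)$bits, 0)
  expect_equal(sum(letterHeights(ic0)), 0)

  # half/half on two residues against uniform: log2 10
  half <- LabeledAlignment(c(a = "Q", b = "Q", c = "R", d = "R"))
  ic2 <- informationContent(columnProfiles(half, pseudocount = 0))
  expect_equal(scoreTable(ic2)$bits, log2(10))
})

test_that("differential KL matches direct evaluation and demands pseudocounts", {
  # 0.8/0.2 on Q/R versus 0.1/0.9: 0.8*log2(8) + 0.2*log2(2/9)
  p <- setNames(numeric(20), c("A", "C", "D", "E", "F", "G", "H", "I", "K",
    "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  q <- p
  p[c("Q", "R")] <- c(0.8, 0.2)
  q[c("Q", "R")] <- c(0.1, 0.9)
  expected <- 0.8 * log2(8) + 0.2 * log2(0.2 / 0.9)
  expect_equal(klBits(p, q), expected, tolerance = 1e-12)
  expect_equal(oracleKL(p, q), expected, tolerance = 1e-12)

  # through the profile pipeline: identical groups diverge by zero
  aln <- LabeledAlignment(c(g1 = "QW", g2 = "QW", r1 = "QW", r2 = "QW"),
                          labels = c(g1 = "NIT-ANTAR", g2 = "NIT-ANTAR",
                                     r1 = "other", r2 = "other"))
  pg <- columnProfiles(aln, pseudocount = 0.5, subset = "NIT-ANTAR")
  pr <- columnProfiles(aln, pseudocount = 0.5, subset = "other")
  dk <- differentialKL(pg, pr)
  expect_equal(scoreTable(dk)$bits, c(0, 0))

  # alpha = 0 leaves zeros in the rest profile: instructive error
  pg0 <- columnProfiles(aln, pseudocount = 0, subset = "NIT-ANTAR")
  pr0 <- columnProfiles(aln, pseudocount = 0, subset = "other")
  expect_error(differentialKL(pg0, pr0), "pseudocount")
})

test_that("KL divergence is nonnegative, zero only at identity, and asymmetric", {
  set.seed(42)
  for (i in 1:200) {
    p <- randomDistribution()
    q <- randomDistribution()
    expect_gte(klBits(p, q), 0)
  }
  p <- randomDistribution()
  expect_equal(klBits(p, p), 0)
  q <- randomDistribution()
  # generic pairs are asymmetric
  expect_false(isTRUE(all.equal(klBits(p, q), klBits(q, p))))
})

test_that("conserved-position caller applies identity then chemical-class rules", {
  mk <- function(col) {
    LabeledAlignment(setNames(col, paste0("s", seq_along(col))))
  }
  # 45% K: single_residue
  aln <- mk(c(rep("K", 9), rep("D", 3), rep("E", 3), rep("G", 3), rep("S", 2)))
  call <- conservedPositions(columnProfiles(aln))
  expect_equal(call$call, "single_residue")
  expect_equal(call$top_residue, "K")

  # 30% L + 25% I + 10% V: hydrophobic class at 65%
  aln <- mk(c(rep("L", 6), rep("I", 5), rep("V", 2), rep("D", 3),
              rep("K", 2), rep("S", 2)))
  call <- conservedPositions(columnProfiles(aln))
  expect_equal(call$call, "chemical_class")
  expect_equal(call$class, "hydrophobic")
  expect_equal(call$class_freq, 0.65)

  # uniform column: none
  aln <- mk(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  expect_equal(conservedPositions(columnProfiles(aln))$call, "none")

  # gappy columns are masked, never called
  aln <- LabeledAlignment(c(s1 = "K-", s2 = "K-", s3 = "KK", s4 = "K-"))
  calls <- conservedPositions(columnProfiles(aln))
  expect_equal(calls$call[1], "single_residue")
  expect_equal(calls$call[2], "masked")
})

test_that("compositional bias is zero for exchangeable groups and signed for planted ones", {
  aln <- LabeledAlignment(c(g1 = "QW", g2 = "QW", r1 = "QW", r2 = "QW"),
                          labels = c(g1 = "NIT-ANTAR", g2 = "NIT-ANTAR",
                                     r1 = "other", r2 = "other"))
  b <- compositionalBias(aln, "NIT-ANTAR")
  expect_true(all(b$delta == 0))
  expect_true(all(b$delta >= -1 & b$delta <= 1))

  # group 100% W where overall is 50% W: delta(W) = +0.5
  aln <- LabeledAlignment(c(g1 = "W", g2 = "W", r1 = "A", r2 = "A"),
                          labels = c(g1 = "NIT-ANTAR", g2 = "NIT-ANTAR",
                                     r1 = "other", r2 = "other"))
  b <- compositionalBias(aln, "NIT-ANTAR")
  expect_equal(b$delta[b$residue == "W"], 0.5)

  expect_error(compositionalBias(aln, "missing-tag"), "NIT-ANTAR")
})

test_that("logo matrix rows reproduce per-column scores", {
  gen <- genAlignment(20, 40, 6,
                      planted = data.frame(column = 3L, residue = "W",
                                           delta = 0.8),
                      seed = 11)
  aln <- gen$alignment
  pg <- columnProfiles(aln, pseudocount = 0.5, subset = "NIT-ANTAR")
  pr <- columnProfiles(aln, pseudocount = 0.5, subset = "other")
  dk <- differentialKL(pg, pr)
  lm <- logoMatrix(dk)
  expect_equal(rowSums(as.matrix(lm[, -1])), scoreTable(dk)$bits,
               ignore_attr = TRUE)
  # TSV export is readable and identical
  f <- tempfile(fileext = ".tsv")
  logoMatrix(dk, f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), as.matrix(lm[, -1]),
               ignore_attr = TRUE)
})

test_that("tiny alignments agree with the direct-count oracle to 1e-12", {
  set.seed(7)
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "-")
  for (trial in 1:20) {
    n <- sample(2:5, 1)
    w <- sample(2:5, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(letters20, w, replace = TRUE), collapse = ""), "")
    names(seqs) <- paste0("s", seq_len(n))
    alpha <- sample(c(0, 0.5, 1), 1)
    aln <- LabeledAlignment(seqs)
    p <- columnProfiles(aln, pseudocount = alpha)
    o <- oracleProfiles(seqs, alpha)
    expect_equal(profileFreqs(p), o$freqs, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(gapFraction(p), o$gap_fraction, tolerance = 1e-12)
    ic <- informationContent(p)
    oic <- apply(o$freqs, 1, oracleKL, q = rep(1 / 20, 20))
    expect_equal(scoreTable(ic)$bits, unname(oic), tolerance = 1e-12)
  }
})
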