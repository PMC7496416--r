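test_that("a planted cross-domain salt bridge is found and classified", {
  f <- writeSaltBridgePDB(tempfile(fileext = ".pdb"), gap = 2.9)
  cs <- readCoordinates(f)
  a <- domainSpec("nit", "A", "1-1")
  b <- domainSpec("antar", "B", "2-2")
  ct <- interdomainContacts(cs, a, b)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$interaction_class, "salt_bridge_candidate")
  expect_equal(ct$min_heavy_distance, 2.9, tolerance = 1e-6)

  # translated apart beyond the cutoff: empty result
  f2 <- writeSaltBridgePDB(tempfile(fileext = ".pdb"), gap = 6.0)
  ct2 <- interdomainContacts(readCoordinates(f2), a, b)
  expect_equal(nrow(ct2), 0L)

  # empty domain selection names the spec
  expect_error(
    interdomainContacts(cs, domainSpec("nowhere", "C", "1-10"), b),
    "nowhere")
})

test_that("contact scan equals the all-pairs brute-force oracle", {
  for (seed in 1:3) {
    rs <- genRandomStructure(nPerDomain = 10, box = 12, seed = seed)
    ct <- interdomainContacts(rs$coords, rs$domainA, rs$domainB)
    oc <- oracleContacts(atoms(rs$coords), "A", c(1, 10), "B",
                         c(101, 110))
    if (is.null(oc)) {
      expect_equal(nrow(ct), 0L)
      next
    }
    expect_equal(nrow(ct), nrow(oc))
    key <- function(d) paste(d$resno_a, d$resno_b)
    expect_setequal(key(ct), key(oc))
    m <- match(key(oc), key(ct))
    expect_equal(ct$min_heavy_distance[m], oc$dist, tolerance = 1e-9)
  }
})

test_that("contact detection is symmetric and monotone in the cutoff", {
  ts <- genToyStructure(c("salt_bridge", "hbond", "vdw", "aromatic"),
                        seed = 5)
  ct <- interdomainContacts(ts$coords, ts$domainA, ts$domainB)
  swapped <- interdomainContacts(ts$coords, ts$domainB, ts$domainA)
  expect_equal(nrow(ct), nrow(swapped))
  expect_setequal(paste(ct$resno_a, ct$resno_b),
                  paste(swapped$resno_b, swapped$resno_a))
  expect_equal(sort(ct$min_heavy_distance),
               sort(swapped$min_heavy_distance))

  wide <- interdomainContacts(ts$coords, ts$domainA, ts$domainB,
                              heavyCutoff = 8)
  expect_true(all(paste(ct$resno_a, ct$resno_b) %in%
                  paste(wide$resno_a, wide$resno_b)))

  # results come back sorted by distance
  expect_false(is.unsorted(ct$min_heavy_distance))
})

test_that("planted contact types classify as constructed", {
  ts <- genToyStructure(c("salt_bridge", "hbond", "vdw", "aromatic"),
                        seed = 9)
  ct <- interdomainContacts(ts$coords, ts$domainA, ts$domainB)
  truth <- ts$truth$planted
  expect_equal(nrow(ct), nrow(truth))
  m <- match(paste(truth$resno_a, truth$resno_b),
             paste(ct$resno_a, ct$resno_b))
  expect_false(anyNA(m))
  expect_equal(ct$interaction_class[m], truth$expected_class)
})

test_that("annotation joins conservation evidence without dropping pairs", {
  gen <- genAlignment(30, 60, 10,
                      planted = data.frame(column = c(2L, 7L),
                                           residue = c("K", "E"),
                                           delta = c(0.9, 0.9)),
                      seed = 3)
  aln <- gen$alignment
  pg <- columnProfiles(aln, pseudocount = 0.5, subset = "NIT-ANTAR")
  pr <- columnProfiles(aln, pseudocount = 0.5, subset = "other")
  dk <- differentialKL(pg, pr)
  bias <- compositionalBias(aln, "NIT-ANTAR")
  calls <- conservedPositions(columnProfiles(aln))

  ts <- genToyStructure("salt_bridge", seed = 2)
  ct <- interdomainContacts(ts$coords, ts$domainA, ts$domainB)
  # Lys 1 maps to planted column 2; Glu 101 maps to planted column 7
  cmap <- c("1" = 2, "101" = 7)
  ann <- annotateContacts(ct, cmap, scores = dk, bias = bias,
                          calls = calls)
  expect_equal(nrow(ann), nrow(ct))
  expect_equal(ann$column_a, 2)
  expect_equal(ann$column_b, 7)
  expect_gt(ann$dkl_a, 0)
  expect_gt(ann$dkl_b, 0)
  expect_gt(ann$delta_a, 0.5)  # K planted at 0.9 in the group
  expect_gt(ann$delta_b, 0.5)

  # unmapped residues stay with empty annotations
  ann2 <- annotateContacts(ct, c("999" = 1), scores = dk, bias = bias)
  expect_equal(nrow(ann2), nrow(ct))
  expect_true(all(is.na(ann2$column_a)))
  expect_true(all(is.na(ann2$dkl_a)))
})
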