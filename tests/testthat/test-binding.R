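test_that("the Hill model obeys its closed-form identities", {
  expect_equal(hillModel(0, kd = 1, hillN = 1, bmax = 0.2), 0)
  expect_equal(hillModel(1, kd = 1, hillN = 1, bmax = 0.2), 0.1)
  expect_equal(hillModel(3, kd = 1, hillN = 2, bmax = 1), 0.9)
  # monotone in x
  x <- sort(runif(50, 0, 100))
  y <- hillModel(x, kd = 2.5, hillN = 1.7, bmax = 0.3)
  expect_false(is.unsorted(y))
})

test_that("noiseless curves are recovered to optimizer precision", {
  x <- rep(exp(seq(log(0.01), log(100), length.out = 12)), each = 2)
  y <- hillModel(x, kd = 1, hillN = 1, bmax = 0.1)
  fit <- fitHill(bindingCurve(x, y))
  expect_true(isConverged(fit))
  expect_equal(kd(fit), 1, tolerance = 1e-6)
  expect_equal(hillN(fit), 1, tolerance = 1e-6)
  expect_equal(bmax(fit), 0.1, tolerance = 1e-6)
})

test_that("flat curves are refused as no detectable binding", {
  gen <- genBindingCurve("unrelated-RNA", seed = 15)
  fit <- fitHill(gen$curve)
  expect_true(isRefused(fit))
  expect_false(isConverged(fit))
})

test_that("variant classification follows the 2-fold rule", {
  ref <- genBindingCurve("P1P2-nitrate", seed = 1)
  refFit <- fitHill(ref$curve)
  expect_true(isConverged(refFit))

  expect_equal(classifyVariant(refFit, refFit)$category,
               "comparable_or_better")

  weak <- genBindingCurve(params = list(kd = 2.5 * kd(refFit), hill_n = 1,
                                        bmax = 0.15, x_min = 0.02,
                                        x_max = 50, x_unit = "uM",
                                        noise_cv = 0.02), seed = 2)
  expect_equal(classifyVariant(fitHill(weak$curve), refFit)$category,
               "reduced")

  dead <- genBindingCurve("WT-no-nitrate", seed = 3)
  expect_equal(classifyVariant(fitHill(dead$curve), refFit)$category,
               "negligible")
})

test_that("fitted kd is invariant to rescaling the response amplitude", {
  gen <- genBindingCurve("P1P2-nitrate", seed = 8)
  d <- gen$curve@data
  f1 <- fitHill(gen$curve)
  f2 <- fitHill(bindingCurve(d$x, d$response * 7, d$replicate))
  expect_equal(kd(f2), kd(f1), tolerance = 1e-4)
  expect_equal(bmax(f2), 7 * bmax(f1), tolerance = 1e-4)
})

test_that("an accepted fit beats the best constant model", {
  for (seed in c(2, 4, 6)) {
    gen <- genBindingCurve("P1P2-nitrate", seed = seed)
    fit <- fitHill(gen$curve)
    y <- gen$curve@data$response
    expect_lte(fit@rss, sum((y - mean(y))^2))
  }
})

test_that("ion-response curves separate signal ions from inert ones", {
  mkIon <- function(preset, seed) genBindingCurve(preset, seed = seed)$curve
  res <- ionResponse(list(nitrate = mkIon("ion-nitrate", 31),
                          nitrite = mkIon("ion-nitrite", 32),
                          sulfate = mkIon("ion-sulfate", 33)))
  tab <- res$table
  expect_true(tab$responsive[tab$ion == "nitrate"])
  expect_true(tab$responsive[tab$ion == "nitrite"])
  expect_false(tab$responsive[tab$ion == "sulfate"])
  # nitrate half-max lands in the sub-mM range used to generate it
  expect_lt(tab$kd[tab$ion == "nitrate"], 1)
  expect_error(ionResponse(list()), "no ion curves")
  expect_error(ionResponse(list(mkIon("ion-nitrate", 31))), "named")
})

test_that("curve construction enforces the titration contract", {
  expect_error(bindingCurve(c(1, 2, 3), c(0.1, 0.2, 0.3)),
               "4 distinct")
  expect_error(bindingCurve(c(-1, 1, 2, 3, 4), rep(0.1, 5)),
               "negative")
  # raw anisotropy with an explicit baseline column is supported
  cv <- bindingCurve(c(0.1, 1, 10, 100), c(0.21, 0.25, 0.29, 0.30),
                     baseline = 0.2)
  expect_equal(cv@data$response, c(0.01, 0.05, 0.09, 0.10))
})
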