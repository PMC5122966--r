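test_that("image simulator renders exactly the ground-truth puncta", {
  # no-signal case
  sim0 <- simulateAxonImage(imageSpec(nPuncta = 0L, noiseSd = 0,
                                      background = 50, seed = 1))
  expect_equal(nrow(sim0$groundTruth), 0L)
  expect_true(all(sim0$image == 50))

  # noiseless construction: one local maximum per punctum, at its position
  spec <- imageSpec(nPuncta = 5L, noiseSd = 0, background = 20, seed = 3)
  sim <- simulateAxonImage(spec)
  expect_equal(nrow(sim$groundTruth), 5L)
  mx <- bruteForceLocalMaxima(sim$image)
  mx <- mx[sim$image[mx] > 21, , drop = FALSE]
  expect_equal(nrow(mx), 5L)
  gx <- sort(sim$groundTruth$x_um / spec@pixelSizeUm + 0.5)
  expect_true(all(abs(sort(mx[, 2]) - gx) <= 1))
})

test_that("image simulation is reproducible and conserves intensity", {
  spec <- imageSpec(nPuncta = 7L, noiseSd = 12, seed = 11)
  a <- simulateAxonImage(spec)
  b <- simulateAxonImage(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$groundTruth, b$groundTruth)

  # zero background + zero noise: total intensity equals summed ground truth
  clean <- simulateAxonImage(imageSpec(nPuncta = 6L, noiseSd = 0,
                                       background = 0, seed = 5))
  expect_equal(sum(clean$image),
               sum(clean$groundTruth$integrated_intensity),
               tolerance = 1e-3)
})

test_that("impossible puncta placements raise an informative error", {
  expect_error(
    simulateAxonImage(imageSpec(widthPx = 64L, nPuncta = 40L,
                                spacingMeanUm = 4, seed = 1)),
    "cannot place")
})

test_that("16-bit TIFF round trip preserves quantized counts", {
  sim <- simulateAxonImage(imageSpec(nPuncta = 4L, seed = 2))
  path <- withr::local_tempfile(fileext = ".tif")
  writeAxonTiff(sim$image, path)
  back <- readAxonTiff(path)
  expect_equal(back, pmin(pmax(round(sim$image), 0), 65535),
               ignore_attr = TRUE)
})

test_that("animal puncta draws follow the generative model", {
  # mean domain length ~ (n-1) x mean spacing over many animals
  spec <- populationSpec("wt", 400, seed = 42,
                         baseline = list(spacingMeanUm = 2))
  lens <- counts <- numeric(400)
  for (i in 1:400) {
    pt <- simulateAnimalPuncta(spec, i)
    lens[i] <- max(pt$axial_position_um) - min(pt$axial_position_um)
    counts[i] <- nrow(pt)
  }
  expect_equal(mean(lens / (counts - 1)), 2, tolerance = 0.05)
  expect_true(all(diff(simulateAnimalPuncta(spec, 7)$axial_position_um) > 0))

  # degenerate within-animal intensity distribution
  spec0 <- populationSpec("wt", 1, seed = 1,
                          effects = plantedEffect("intensity", var_mult = 0))
  pt <- simulateAnimalPuncta(spec0, 1)
  expect_equal(sd(pt$peak_intensity), 0)

  # stream independence: same seed, different animal index
  a <- simulateAnimalPuncta(spec, 1)
  b <- simulateAnimalPuncta(spec, 2)
  expect_false(isTRUE(all.equal(a$axial_position_um, b$axial_position_um)))
  # and full determinism per animal
  expect_identical(a, simulateAnimalPuncta(spec, 1))
})

test_that("population profiles have one 76-feature row per animal", {
  pp <- simulatePopulationProfiles(populationSpec("wt", 50, seed = 9))
  expect_equal(dim(featureMatrix(pp)), c(76L, 50L))
  expect_true(all(genotypes(pp) == "wt"))
  expect_identical(pp, simulatePopulationProfiles(populationSpec("wt", 50, seed = 9)))
})

test_that("planted generative count effect shifts the count feature", {
  base <- simulatePopulationProfiles(populationSpec("wt", 200, seed = 1))
  up <- simulatePopulationProfiles(populationSpec(
    "up", 200, effects = plantedEffect("count", shift_sd = 3), seed = 2))
  expect_gt(mean(featureMatrix(up)["f001", ]),
            mean(featureMatrix(base)["f001", ]))
  expect_gt(t.test(featureMatrix(up)["f001", ],
                   featureMatrix(base)["f001", ])$statistic, 5)
})

test_that("zero-effect populations show no feature differences beyond chance", {
  # repeated null simulation: Bonferroni-corrected two-sample tests
  hits <- vapply(1:10, function(s) {
    both <- nullPairBenchmark(nPerGroup = 60L, seed = s)
    m <- featureMatrix(both)
    ga <- genotypes(both) == "popA"
    p <- vapply(1:76, function(j) {
      if (sd(m[j, ]) == 0) return(1)
      t.test(m[j, ga], m[j, !ga])$p.value
    }, numeric(1))
    any(p < 0.05 / 76)
  }, logical(1))
  expect_lte(mean(hits), 0.2)
})

test_that("screen thresholds sort the expected fraction of animals", {
  pp <- simulatePopulationProfiles(populationSpec("wt", 200, seed = 4))
  # vacuous thresholds
  thr <- data.frame(feature = c(1L, 22L), lower = -Inf, upper = Inf)
  expect_equal(as.numeric(simulateScreen(pp, thr)), 0)
  # single one-sided threshold at the empirical 95th percentile
  x <- featureMatrix(pp)["f022", ]
  thr95 <- data.frame(feature = 22L, lower = NA, upper = quantile(x, 0.95))
  expect_equal(as.numeric(simulateScreen(pp, thr95)), mean(x > quantile(x, 0.95)))
  expect_equal(as.numeric(simulateScreen(pp, thr95)), 0.05, tolerance = 0.02)
  # threshold below the minimum sorts everyone
  thrAll <- data.frame(feature = 22L, lower = NA, upper = min(x) - 1)
  expect_equal(as.numeric(simulateScreen(pp, thrAll)), 1)
  # unknown feature id errors
  expect_error(simulateScreen(pp, data.frame(feature = 99L, upper = 1)),
               "unknown feature")
})

test_that("invalid specs are rejected", {
  expect_error(imageSpec(widthPx = 8L), "16")
  expect_error(imageSpec(psfSigmaPx = 0), "psfSigmaPx")
  expect_error(populationSpec("wt", 0), "nAnimals")
  expect_error(populationSpec("wt", 5, effects = plantedEffect("bogus", 1)),
               "unknown effect")
})
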