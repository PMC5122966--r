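test_that("the IRLS engine matches stats::glm on well-behaved data", {
  set.seed(5)
  X <- matrix(rnorm(200 * 3), 200, 3)
  y <- rbinom(200, 1, plogis(0.3 + X %*% c(1, -0.5, 0.2)))
  fit <- synProfiler:::fastLogit(X, y)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(fit$coef, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$deviance, ref$deviance, tolerance = 1e-8)
})

test_that("duplicated groups collapse to the intercept-only fixed point", {
  wt <- simulateCorrelatedProfiles(60, "wild type", seed = 3)
  m <- featureMatrix(wt)
  dup <- PhenotypeProfiles(m, paste0("dup", 1:60), "mutant",
                           n_puncta = nPuncta(wt))
  both <- combineProfiles(wt, dup)
  fit <- fitSWLR(both, "mutant", "wild type")
  expect_length(selectedFeatures(fit), 0L)
  p <- scoreProfiles(fit, both)
  expect_equal(unname(p), rep(0.5, 120), tolerance = 1e-8)
})

test_that("a single planted feature is selected first (deviance-scan oracle)", {
  for (s in c(2, 7)) {
    both <- profileBenchmark(nPerGroup = 200L, features = 9L, shiftSd = 2,
                             seed = s)
    scan <- singleFeatureDevianceScan(both, "mutant", "wild type")
    expect_equal(which.min(scan), 9L)
    fit <- fitSWLR(both, "mutant", "wild type")
    expect_equal(selectedFeatures(fit)[1L], 9L)
    bf <- fitBestFeature(both, "mutant", "wild type")
    expect_equal(selectedFeatures(bf), 9L)
  }
})

test_that("complete separation yields a step-like model with training AUC 1", {
  wt <- simulateCorrelatedProfiles(40, "wild type", seed = 11)
  mu <- simulateCorrelatedProfiles(40, "mutant", shiftFeatures = 7L,
                                   shiftSd = 30, seed = 12)
  both <- combineProfiles(wt, mu)
  fit <- fitSWLR(both, "mutant", "wild type")
  expect_true(7L %in% selectedFeatures(fit))
  p <- scoreProfiles(fit, both)
  expect_equal(rocAuc(p, genotypes(both) == "mutant")$auc, 1.0)
  expect_true(fit@separation)
  # BF is forced to the separating feature
  bf <- fitBestFeature(both, "mutant", "wild type")
  expect_equal(selectedFeatures(bf), 7L)
  expect_equal(bf@trainingAuc, 1.0)
})

test_that("scores follow the logistic closed form", {
  mk <- function(b0, b1) methods::new("SWLRModel", mutantLabel = "m",
    wtLabel = "w", features = 1L, coefficients = c(b0, b1), center = 0,
    scale = 1, devianceTrace = c(10, 5), pEnter = 0.05, pRemove = 0.1,
    nMutant = 10L, nWt = 10L, ridge = 0, separation = FALSE, seed = 0L)
  prof <- function(v) PhenotypeProfiles(matrix(c(v, rep(0, 75))),
                                        "a1", "m", n_puncta = 10L)
  # all standardized features zero, zero intercept -> 0.5
  expect_equal(unname(scoreProfiles(mk(0, 1), prof(0))), 0.5)
  # b0 = 0, b1 = 1, z = ln 3 -> 3/4
  expect_equal(unname(scoreProfiles(mk(0, 1), prof(log(3)))), 0.75)
  # intercept-only with negative intercept: sensitivity 0, specificity 1
  m0 <- methods::new("SWLRModel", mutantLabel = "m", wtLabel = "w",
                     features = integer(0), coefficients = -1,
                     center = numeric(0), scale = numeric(0),
                     devianceTrace = 10, pEnter = 0.05, pRemove = 0.1,
                     nMutant = 10L, nWt = 10L, ridge = 0, separation = FALSE,
                     seed = 0L)
  both <- combineProfiles(
    simulateCorrelatedProfiles(10, "m", seed = 1),
    simulateCorrelatedProfiles(10, "w", seed = 2))
  expect_equal(unname(sensitivitySpecificity(m0, both, "m", "w")), c(0, 1))
})

test_that("training-set scores reproduce the fitted deviance", {
  both <- profileBenchmark(nPerGroup = 80L, seed = 21)
  fit <- fitSWLR(both, "mutant", "wild type")
  keep <- genotypes(both) %in% c("mutant", "wild type")
  p <- scoreProfiles(fit, both[, keep])
  y <- as.numeric(genotypes(both[, keep]) == "mutant")
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  dev <- -2 * sum(y * log(pc) + (1 - y) * log(1 - pc))
  trace <- devianceTrace(fit)
  expect_equal(dev, trace[length(trace)], tolerance = 1e-6)
})

test_that("deviance traces never increase and end below the null", {
  for (s in 31:33) {
    both <- profileBenchmark(nPerGroup = 100L, seed = s)
    tr <- devianceTrace(fitSWLR(both, "mutant", "wild type"))
    expect_true(all(diff(tr) <= 1e-8))
    expect_lte(tr[length(tr)], tr[1L])
  }
})

test_that("standardization round-trips: rescaled inputs give identical probabilities", {
  both <- profileBenchmark(nPerGroup = 60L, seed = 41)
  fit <- fitSWLR(both, "mutant", "wild type")
  m <- featureMatrix(both)
  resc <- m * 3.7 + 11          # affine-transform every feature
  pp2 <- PhenotypeProfiles(resc, colnames(m), genotypes(both),
                           n_puncta = nPuncta(both))
  fit2 <- fitSWLR(pp2, "mutant", "wild type")
  expect_identical(selectedFeatures(fit2), selectedFeatures(fit))
  expect_equal(unname(scoreProfiles(fit2, pp2)),
               unname(scoreProfiles(fit, both)), tolerance = 1e-8)
})

test_that("single-feature entry tests hold their nominal size under the null", {
  # permutation null: rejection rate of the 1-df LR test ~ 5%
  set.seed(7)
  n <- 120
  rej <- vapply(1:300, function(i) {
    x <- rnorm(n)
    y <- sample(rep(0:1, n / 2))
    f1 <- synProfiler:::fastLogit(matrix(x), y)
    synProfiler:::lrPvalue(synProfiler:::nullDeviance(y), f1$deviance) < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("known logistic coefficients are recovered by the stepwise fit", {
  trueB <- c(1, -0.8, 0.6)
  hit <- relerr <- numeric(0)
  for (s in 1:10) {
    pp <- withr::with_seed(1000 + s, {
      M <- matrix(rnorm(1000 * 76), 1000, 76)
      y <- rbinom(1000, 1, plogis(M[, 1:3] %*% trueB))
      PhenotypeProfiles(t(M), sprintf("a%04d", 1:1000),
                        ifelse(y == 1, "mutant", "wild type"),
                        n_puncta = rep(18L, 1000))
    })
    fit <- fitSWLR(pp, "mutant", "wild type")
    sel <- selectedFeatures(fit)
    hit <- c(hit, all(1:3 %in% sel))
    bhat <- fit@coefficients[-1L][match(1:3, sel)] / fit@scale[match(1:3, sel)]
    relerr <- c(relerr, mean(abs((bhat - trueB) / trueB), na.rm = TRUE))
  }
  expect_gte(mean(hit), 0.9)
  expect_lte(mean(relerr), 0.2)
})

test_that("empty groups and missing features raise errors", {
  pp <- simulateCorrelatedProfiles(20, "wild type", seed = 1)
  expect_error(fitSWLR(pp, "missing", "wild type"), "mutant group")
  fit <- methods::new("SWLRModel", mutantLabel = "m", wtLabel = "w",
                      features = 1L, coefficients = c(0, 1), center = 0,
                      scale = 1, devianceTrace = 1, pEnter = .05, pRemove = .1,
                      nMutant = 1L, nWt = 1L, ridge = 0, separation = FALSE,
                      seed = 0L)
  bad <- featureMatrix(pp)
  bad[1, 1] <- NA
  ppBad <- PhenotypeProfiles(bad, colnames(bad), "wild type",
                             n_puncta = rep(18L, 20))
  expect_error(scoreProfiles(fit, ppBad), "non-finite")
})
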