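test_that("pooled z-scoring has the expected fixed points", {
  # three animals, one varying feature: z-scores {-1, 0, 1} (sample SD)
  m <- matrix(0, 76, 3)
  m[5, ] <- c(1, 2, 3)
  m[9, ] <- 4                      # constant feature -> dropped
  pp <- PhenotypeProfiles(m, paste0("a", 1:3), c("g1", "g2", "g3"),
                          n_puncta = rep(10L, 3))
  sm <- zscorePopulationProfiles(pp)
  expect_false(9L %in% sm$keptFeatures)
  j <- which(sm$keptFeatures == 5L)
  expect_equal(unname(sm$zMatrix[c("g1", "g2", "g3"), j]), c(-1, 0, 1))

  # animal-weighted mean of population z-vectors is the zero vector
  pp2 <- combineProfiles(
    simulatePopulationProfiles(populationSpec("wt", 30, seed = 1)),
    simulatePopulationProfiles(populationSpec(
      "mut", 50, effects = plantedEffect("count", shift_sd = 2), seed = 2)))
  sm2 <- zscorePopulationProfiles(pp2)
  wmean <- colSums(sm2$zMatrix * sm2$nAnimals[rownames(sm2$zMatrix)]) /
    sum(sm2$nAnimals)
  expect_equal(unname(wmean), rep(0, ncol(sm2$zMatrix)), tolerance = 1e-10)
})

test_that("weighted distances reduce to Euclidean under identity correlation", {
  zM <- rbind(a = rep(0, 4), b = c(3, 4, 0, 0))
  sm <- structure(list(zMatrix = zM, keptFeatures = 1:4,
                       droppedFeatures = integer(0),
                       correlation = diag(4), nAnimals = c(a = 5L, b = 5L),
                       reference = "pooled", rendering = list()),
                  class = "PopulationSummaries")
  dm <- weightedDistanceMatrix(sm)
  # identical summaries -> 0; equal weights -> plain Pythagoras
  expect_equal(dm@distance["a", "a"], 0)
  expect_equal(dm@distance["a", "b"], 5)
  expect_equal(dm@weights, rep(1, 4))
  expect_true(isSymmetric(dm@distance))
  # regression: "none" weighting equals dist() on the z-means
  expect_equal(weightedDistanceMatrix(sm, method = "none")@distance["a", "b"],
               as.numeric(dist(zM)), tolerance = 1e-12)
})

test_that("duplicated features are down-weighted by the correlation rule", {
  # 3-feature toy: features 1 and 2 perfectly correlated, 3 independent
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 1
  w <- 1 / colSums(abs(R))        # direct computation of the rule
  expect_equal(w, c(0.5, 0.5, 1))
  zM <- rbind(wt = c(0, 0, 0), mu = c(1, 1, 1))
  sm <- structure(list(zMatrix = zM, keptFeatures = 1:3,
                       droppedFeatures = integer(0), correlation = R,
                       nAnimals = c(wt = 5L, mu = 5L), reference = "pooled",
                       rendering = list()), class = "PopulationSummaries")
  dm <- weightedDistanceMatrix(sm)
  wn <- w * 3 / sum(w)
  expect_equal(dm@distance["wt", "mu"], sqrt(sum(wn * c(1, 1, 1))))
  # the duplicated pair together carries the weight of one feature
  expect_equal(sum(dm@weights[1:2]), dm@weights[3])
})

test_that("clustering merges the obvious pair first and ignores input order", {
  D <- matrix(c(0, 1, 10,
                1, 0, 10.5,
                10, 10.5, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  pd <- methods::new("PhenotypeDistance", distance = D, weights = 1,
                     featureIds = 1L, method = "none")
  hc <- hierarchicalCluster(pd)
  expect_equal(sort(cutree(hc, 2)[c("x", "y")]), c(x = 1, y = 1),
               ignore_attr = TRUE)
  # first merge joins x and y
  expect_equal(hc$height[1], 1)
  # permuting population order keeps the topology
  perm <- c("z", "x", "y")
  pd2 <- methods::new("PhenotypeDistance", distance = D[perm, perm],
                      weights = 1, featureIds = 1L, method = "none")
  hc2 <- hierarchicalCluster(pd2)
  cut2 <- cutree(hc2, 2)
  expect_true(cut2[["x"]] == cut2[["y"]] && cut2[["z"]] != cut2[["x"]])
  expect_error(hierarchicalCluster(
    methods::new("PhenotypeDistance", distance = matrix(0, 1, 1,
      dimnames = list("a", "a")), weights = 1, featureIds = 1L,
      method = "none")), "at least 2")
  # newick export carries all leaves
  nwk <- exportNewick(hc)
  expect_true(all(vapply(c("x", "y", "z"), grepl, logical(1), x = nwk)))
})

test_that("cross-model probabilities behave as designed on planted pairs", {
  mk <- function(lab, eff, s) simulatePopulationProfiles(populationSpec(
    lab, 60, effects = if (is.null(eff)) plantedEffect()
    else plantedEffect(eff, shift_sd = 2.5), seed = s))
  all <- combineProfiles(mk("wild type", NULL, 1), mk("A", "count", 2),
                         mk("Aprime", "count", 3), mk("B", "intensity", 4))
  models <- lapply(c("A", "Aprime", "B"),
                   function(m) fitSWLR(all, m, "wild type"))
  pm <- crossModelMatrix(models, all)
  expect_true(all(pm@probs >= 0 & pm@probs <= 1))
  # each model identifies its own population; wild type stays below 0.5
  for (m in c("A", "Aprime", "B")) {
    expect_gt(pm@probs[m, m], 0.5)
    expect_lt(pm@probs["wild type", m], 0.5)
  }
  # shared planted effect: A-model's best non-self pair is Aprime & vice versa
  g <- bestPairNetwork(pm)
  ed <- igraph::as_data_frame(g)
  expect_equal(ed$to[ed$from == "A"], "Aprime")
  expect_equal(ed$to[ed$from == "Aprime"], "A")
})

test_that("intercept-only models give constant probability columns", {
  m0 <- methods::new("SWLRModel", mutantLabel = "flat", wtLabel = "wild type",
                     features = integer(0), coefficients = 0,
                     center = numeric(0), scale = numeric(0),
                     devianceTrace = 1, pEnter = .05, pRemove = .1,
                     nMutant = 1L, nWt = 1L, ridge = 0, separation = FALSE,
                     seed = 0L)
  pp <- simulateCorrelatedProfiles(25, "anything", seed = 5)
  pm <- crossModelMatrix(list(m0), pp)
  expect_equal(unname(pm@probs[, "flat"]), 0.5)
})

test_that("tied best pairs are all reported and flagged", {
  probs <- matrix(c(0.9, 0.4, 0.4), 3, 1,
                  dimnames = list(c("self", "p1", "p2"), "self"))
  pm <- methods::new("ProbabilityMatrix", probs = probs,
                     selfPair = outer(rownames(probs), "self", "=="))
  ed <- igraph::as_data_frame(bestPairNetwork(pm))
  expect_equal(nrow(ed), 2L)
  expect_true(all(ed$tie))
  expect_setequal(ed$to, c("p1", "p2"))
})
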