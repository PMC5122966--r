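#' Simulate correlated synthetic feature profiles
#'
#' Draws abstract 76-feature profiles from a factor-model Gaussian: feature j
#' is \code{sqrt(rhoGlobal) g + sqrt(rhoWithin - rhoGlobal) h_cat(j) +
#' sqrt(1 - rhoWithin) e_j} with a shared global factor g, one factor per
#' registry category and independent idiosyncratic noise, giving unit
#' marginal variance, correlation \code{rhoWithin} within a feature category
#' and \code{rhoGlobal} across categories (a positive-semidefinite structure
#' by construction). Planted group effects add \code{shiftSd} marginal-SD
#' units to the named features.
#'
#' Unlike puncta-derived profiles, these features obey no exact algebraic
#' identities, so a planted shift is identifiable: this generator is the
#' basis of the model-level benchmarks (signal AUC, selection recovery,
#' SWLR-vs-BF). Values are on an abstract standardized scale; the recorded
#' \code{n_puncta} is a nominal constant.
#'
#' @param nAnimals animals to draw.
#' @param genotype genotype label.
#' @param shiftFeatures integer feature ids receiving the planted shift.
#' @param shiftSd shift in marginal-SD units.
#' @param rhoWithin within-category feature correlation (default 0.5).
#' @param rhoGlobal across-category correlation (default 0.1).
#' @param seed integer seed.
#' @return a \code{\linkS4class{PhenotypeProfiles}}.
#' @export
simulateCorrelatedProfiles <- function(nAnimals, genotype = "wild type",
                                       shiftFeatures = integer(0), shiftSd = 0,
                                       rhoWithin = 0.5, rhoGlobal = 0.1,
                                       seed = 1L) {
  stopifnot(rhoGlobal >= 0, rhoWithin >= rhoGlobal, rhoWithin < 1,
            all(shiftFeatures %in% 1:76))
  cat <- factor(featureRegistry()$category)
  nc <- nlevels(cat)
  withSeed(substreamSeed(seed, paste0("corrprof-", genotype), 0L), {
    g <- stats::rnorm(nAnimals)
    h <- matrix(stats::rnorm(nAnimals * nc), nAnimals, nc)
    e <- matrix(stats::rnorm(nAnimals * 76L), nAnimals, 76L)
    M <- sqrt(rhoGlobal) * g +
      sqrt(rhoWithin - rhoGlobal) * h[, as.integer(cat), drop = FALSE] +
      sqrt(1 - rhoWithin) * e
    if (length(shiftFeatures))
      M[, shiftFeatures] <- M[, shiftFeatures] + shiftSd
    PhenotypeProfiles(t(M),
                      animal_id = sprintf("%s_%04d", gsub("\\s+", "_", genotype),
                                          seq_len(nAnimals)),
                      genotype = genotype,
                      n_puncta = rep(18L, nAnimals))
  })
}

#' Paired-population benchmark with planted feature shifts
#'
#' The standard signal benchmark for the pairwise models: a wild-type-like
#' and a mutant group of correlated synthetic profiles
#' (\code{\link{simulateCorrelatedProfiles}}), the mutant carrying an
#' additive shift of \code{shiftSd} SD units in the named features - the
#' only columns with a systematic group difference.
#'
#' @param nPerGroup animals per group (default 200).
#' @param features integer feature ids to shift (default 1, 21 and 41:
#'   puncta number, intensity homogeneity and mean interpunctal distance).
#' @param shiftSd shift size in SD units (default 2; 0 gives a null pair).
#' @param seed master seed.
#' @param mutantLabel,wtLabel genotype labels.
#' @return a \code{\linkS4class{PhenotypeProfiles}} with both groups.
#' @export
profileBenchmark <- function(nPerGroup = 200L, features = c(1L, 21L, 41L),
                             shiftSd = 2, seed = 1L,
                             mutantLabel = "mutant", wtLabel = "wild type") {
  combineProfiles(
    simulateCorrelatedProfiles(nPerGroup, wtLabel,
                               seed = substreamSeed(seed, "bench-wt", 0L)),
    simulateCorrelatedProfiles(nPerGroup, mutantLabel, features, shiftSd,
                               seed = substreamSeed(seed, "bench-mut", 0L)))
}

#' Same-spec null population pair
#'
#' Two populations drawn from the identical puncta-level generative spec
#' under different random streams: any apparent separation between them is
#' pure sampling noise, so a sound cross-validated model should score
#' near-chance AUC.
#'
#' @param nPerGroup animals per group (default 200).
#' @param seed master seed.
#' @param labels the two genotype labels.
#' @return a \code{\linkS4class{PhenotypeProfiles}} with both populations.
#' @export
nullPairBenchmark <- function(nPerGroup = 200L, seed = 1L,
                              labels = c("popA", "popB")) {
  combineProfiles(
    simulatePopulationProfiles(
      populationSpec(labels[1L], nPerGroup, seed = substreamSeed(seed, "null-a", 0L))),
    simulatePopulationProfiles(
      populationSpec(labels[2L], nPerGroup, seed = substreamSeed(seed, "null-b", 0L))))
}

#' Combine profile containers column-wise
#'
#' @param ... \code{PhenotypeProfiles} objects sharing the feature registry.
#' @return a single \code{PhenotypeProfiles}.
#' @export
combineProfiles <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L,
            all(vapply(xs, methods::is, logical(1), "PhenotypeProfiles")))
  out <- do.call(SummarizedExperiment::cbind, xs)
  methods::as(out, "PhenotypeProfiles")
}

#' Ground-truthed detection benchmark
#'
#' Simulates a family of axon images under fixed, stated imaging conditions
#' (peak SNR well above 5, interpunctal gaps no closer than 4 PSF sigmas),
#' trains the candidate classifier on a held-out set of training images
#' labelled against their ground truth, runs the full
#' detect-classify-segment pipeline on each test image and matches detected
#' puncta to ground truth by position.
#'
#' @param nImages number of test images (default 100).
#' @param nTrain number of training images (default 12).
#' @param seed master seed.
#' @param noiseSd Gaussian noise SD (counts).
#' @param intensityMean mean punctum peak amplitude (counts); the default
#'   gives a mean peak SNR of 8.
#' @param matchTolPx match tolerance between detection and ground truth, px.
#' @return list with per-image data.frame \code{perImage} (columns
#'   \code{n_true}, \code{n_detected}, \code{n_matched}), overall
#'   \code{recall}, \code{precision}, \code{countErrorLe1} (fraction of
#'   images with |count error| <= 1), and the trained \code{model}.
#' @export
detectionBenchmark <- function(nImages = 100L, nTrain = 12L, seed = 1L,
                               noiseSd = 15, intensityMean = 120,
                               matchTolPx = 3) {
  px <- 0.16
  psf <- 1.6
  makeSpec <- function(s, n) {
    imageSpec(widthPx = 512L, heightPx = 48L, pixelSizeUm = px,
              nPuncta = n, spacingMeanUm = 4, spacingSdUm = 1.2,
              minSpacingUm = 4 * psf * px + 0.15,   # >= 4 PSF sigmas apart
              radiusMeanUm = 0.5, radiusCv = 0.25,
              intensityMean = intensityMean, intensityCv = 0.25,
              psfSigmaPx = psf, background = 100, noiseSd = noiseSd,
              seed = s)
  }
  nDraw <- function(s) withSeed(substreamSeed(s, "npuncta", 0L),
                                sample(6:16, 1L))
  # training: permissive detection, ground-truth labels, SVM
  cands <- NULL; labs <- logical(0)
  for (t in seq_len(nTrain)) {
    s <- substreamSeed(seed, "det-train", t)
    sim <- simulateAxonImage(makeSpec(s, nDraw(s)))
    cc <- detectCandidates(sim$image, nsigma = 2)
    if (!nrow(cc)) next
    labs <- c(labs, labelCandidates(cc, sim$groundTruth, px, tol_px = matchTolPx))
    cands <- rbind(cands, cc)
  }
  model <- trainClassifier(cands, labs, kernel = "linear", seed = seed)
  perImage <- data.frame(n_true = integer(nImages),
                         n_detected = integer(nImages),
                         n_matched = integer(nImages))
  for (i in seq_len(nImages)) {
    s <- substreamSeed(seed, "det-test", i)
    sim <- simulateAxonImage(makeSpec(s, nDraw(s)))
    rec <- detectPuncta(sim$image, model, px, nsigma = 3)
    nT <- nrow(sim$groundTruth); nD <- nrow(rec)
    nM <- 0L
    if (nD && nT) {
      cc <- data.frame(x_px = rec$axial_position_um / px + 0.5,
                       y_px = rec$y_um / px + 0.5)
      nM <- sum(labelCandidates(cc, sim$groundTruth, px, tol_px = matchTolPx))
    }
    perImage[i, ] <- c(nT, nD, nM)
  }
  list(perImage = perImage,
       recall = sum(perImage$n_matched) / sum(perImage$n_true),
       precision = sum(perImage$n_matched) / max(sum(perImage$n_detected), 1L),
       countErrorLe1 = mean(abs(perImage$n_detected - perImage$n_true) <= 1L),
       model = model)
}

#' Planted-group clustering benchmark
#'
#' Simulates a wild-type population plus three groups of genotypes, each
#' group sharing one planted generative effect (more puncta, brighter
#' puncta, wider spacing; effect size in between-animal SD units), builds
#' z-scored population summaries and the correlation-weighted distance
#' matrix, clusters, and scores recovery of the three groups.
#'
#' @param nPerPopulation animals per population (default 100).
#' @param popsPerGroup genotypes per effect group (default 3).
#' @param effectSd planted effect size (default 2 between-animal SDs).
#' @param seed master seed.
#' @param linkage linkage passed to \code{\link{hierarchicalCluster}}.
#' @return list with \code{profiles}, \code{summaries}, \code{distance},
#'   \code{hclust}, \code{groups} (true group of each non-wild-type
#'   population) and \code{clusters} (3-cluster cut, same order).
#' @export
clusterBenchmark <- function(nPerPopulation = 100L, popsPerGroup = 3L,
                             effectSd = 2, seed = 1L, linkage = "average") {
  params <- c("count", "intensity", "spacing")
  pops <- list(simulatePopulationProfiles(
    populationSpec("wild type", nPerPopulation,
                   seed = substreamSeed(seed, "clus-wt", 0L))))
  groups <- character(0)
  for (g in seq_along(params)) {
    for (r in seq_len(popsPerGroup)) {
      label <- sprintf("%s_up_%d", params[g], r)
      pops[[length(pops) + 1L]] <- simulatePopulationProfiles(
        populationSpec(label, nPerPopulation,
                       effects = plantedEffect(params[g], shift_sd = effectSd),
                       seed = substreamSeed(seed, label, g * 100L + r)))
      groups <- c(groups, params[g])
    }
  }
  profiles <- do.call(combineProfiles, pops)
  summaries <- zscorePopulationProfiles(profiles)
  dm <- weightedDistanceMatrix(summaries)
  hc <- hierarchicalCluster(dm, linkage = linkage)
  cut <- stats::cutree(hc, k = 3L)
  mutants <- setdiff(rownames(dm@distance), "wild type")
  list(profiles = profiles, summaries = summaries, distance = dm,
       hclust = hc, groups = stats::setNames(groups, mutants),
       clusters = cut[mutants])
}

#' Effect-magnitude severity benchmark
#'
#' Simulates populations whose planted effect magnitudes span a range, and
#' returns each population's correlation-weighted distance to wild type
#' together with its planted effect size, for checking that phenotype
#' distance tracks severity.
#'
#' @param magnitudes planted effect sizes in between-animal SD units.
#' @param nPerPopulation animals per population.
#' @param seed master seed.
#' @return data.frame with columns \code{population}, \code{magnitude},
#'   \code{distance_to_wt}.
#' @export
severityBenchmark <- function(magnitudes = c(0.5, 1, 1.5, 2, 3),
                              nPerPopulation = 100L, seed = 1L) {
  pops <- list(simulatePopulationProfiles(
    populationSpec("wild type", nPerPopulation,
                   seed = substreamSeed(seed, "sev-wt", 0L))))
  labels <- character(0)
  for (k in seq_along(magnitudes)) {
    label <- sprintf("effect_%g_sd", magnitudes[k])
    pops[[length(pops) + 1L]] <- simulatePopulationProfiles(
      populationSpec(label, nPerPopulation,
                     effects = plantedEffect(c("count", "intensity"),
                                             shift_sd = magnitudes[k]),
                     seed = substreamSeed(seed, label, k)))
    labels <- c(labels, label)
  }
  profiles <- do.call(combineProfiles, pops)
  dm <- weightedDistanceMatrix(zscorePopulationProfiles(profiles))
  data.frame(population = labels, magnitude = magnitudes,
             distance_to_wt = dm@distance[labels, "wild type"])
}
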