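#' Build a PopulationSpec
#'
#' Constructs the generative specification of one genotype's animal
#' population. Defaults describe a realistic wild-type-like axon segment:
#' around 18 puncta per animal (Poisson, truncated at >= 1), Gamma-distributed
#' interpunctal gaps of mean 1.5 um, lognormal half-max radii of mean 0.5 um
#' and lognormal peak intensities of mean 600 a.u.; between-animal CVs of
#' 10-18 percent provide the isogenic heterogeneity seen in real populations.
#'
#' @param genotype genotype label.
#' @param nAnimals number of animals.
#' @param effects data.frame with columns \code{parameter} (\code{"count"},
#'   \code{"spacing"}, \code{"size"} or \code{"intensity"}), \code{shift_sd}
#'   (shift of the animal-level mean, in units of the parameter's
#'   between-animal SD) and \code{var_mult} (multiplier on the within-animal
#'   CV; 0 makes the quantity identical across puncta of an animal).
#' @param seed master integer seed.
#' @param baseline named list overriding any of: \code{countLambda} (18),
#'   \code{countCvBetween} (0.15), \code{spacingMeanUm} (1.5),
#'   \code{spacingCvWithin} (0.45), \code{spacingCvBetween} (0.12),
#'   \code{radiusMeanUm} (0.5), \code{radiusCvWithin} (0.25),
#'   \code{radiusCvBetween} (0.10), \code{intensityMean} (600),
#'   \code{intensityCvWithin} (0.35), \code{intensityCvBetween} (0.18).
#' @return a \code{\linkS4class{PopulationSpec}}.
#' @examples
#' wt <- populationSpec("wild type", nAnimals = 10, seed = 1)
#' mut <- populationSpec("mutantA", nAnimals = 10, seed = 1,
#'                       effects = plantedEffect("count", shift_sd = 3))
#' @export
populationSpec <- function(genotype, nAnimals, effects = plantedEffect(),
                           seed = 1L, baseline = list()) {
  base <- list(countLambda = 18, countCvBetween = 0.15,
               spacingMeanUm = 1.5, spacingCvWithin = 0.45,
               spacingCvBetween = 0.12,
               radiusMeanUm = 0.5, radiusCvWithin = 0.25,
               radiusCvBetween = 0.10,
               intensityMean = 600, intensityCvWithin = 0.35,
               intensityCvBetween = 0.18)
  unknown <- setdiff(names(baseline), names(base))
  if (length(unknown)) stop("unknown baseline parameters: ",
                            paste(unknown, collapse = ", "))
  base[names(baseline)] <- baseline
  methods::new("PopulationSpec", genotype = as.character(genotype),
               nAnimals = as.integer(nAnimals), baseline = base,
               effects = effects, seed = as.integer(seed))
}

#' Describe planted genotype effects
#'
#' @param parameter generative parameter names (may be empty for a
#'   no-effect, wild-type-like spec).
#' @param shift_sd mean shifts in between-animal-SD units (recycled).
#' @param var_mult within-animal CV multipliers (recycled).
#' @return a data.frame usable as the \code{effects} of
#'   \code{\link{populationSpec}}.
#' @export
plantedEffect <- function(parameter = character(0), shift_sd = 0, var_mult = 1) {
  data.frame(parameter = as.character(parameter),
             shift_sd = rep_len(shift_sd, length(parameter)),
             var_mult = rep_len(var_mult, length(parameter)),
             stringsAsFactors = FALSE)
}

# lognormal multiplier with unit mean and the given CV
rlnormCv <- function(n, cvv) {
  if (cvv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cvv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# lognormal draws with the given mean and CV
rlnormMeanCv <- function(n, m, cvv) {
  if (cvv <= 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cvv^2))
  stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# Gamma gaps with given mean/CV, rejection-sampled above a hard minimum
rGaps <- function(n, m, cvv, minGap = 0) {
  if (n <= 0) return(numeric(0))
  if (cvv <= 0) return(rep(max(m, minGap), n))
  shape <- 1 / cvv^2
  g <- stats::rgamma(n, shape = shape, scale = m * cvv^2)
  bad <- which(g < minGap)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    g[bad] <- stats::rgamma(length(bad), shape = shape, scale = m * cvv^2)
    bad <- which(g < minGap)
    tries <- tries + 1L
  }
  if (length(bad)) g[bad] <- minGap
  g
}

effectFor <- function(spec, parameter) {
  e <- spec@effects
  row <- e[e$parameter == parameter, , drop = FALSE]
  if (!nrow(row)) list(shift = 0, varMult = 1)
  else list(shift = sum(row$shift_sd), varMult = prod(row$var_mult))
}

# half-max radius -> Gaussian sigma (exp(-r^2 / 2 sigma^2) = 1/2)
halfMaxSigma <- function(radius) radius / sqrt(2 * log(2))

#' Simulate the puncta records of one animal
#'
#' Draws one animal from a \code{\linkS4class{PopulationSpec}}: the animal's
#' latent means are drawn from the between-animal distributions (with any
#' planted effects applied), then puncta count, Gamma gaps, lognormal radii
#' and peak intensities are drawn within the animal. Each punctum is an
#' isotropic Gaussian, so its integrated intensity is
#' \code{2 * pi * peak * sigma^2} with \code{sigma} the half-max radius over
#' \code{sqrt(2 log 2)}, and the interpunctal intensity of a gap is the
#' summed tail intensity of the two flanking puncta at the gap midpoint.
#'
#' The random stream is derived by hashing (seed, genotype, animal_index), so
#' two animals of the same population are independent and a population can be
#' extended without changing earlier animals.
#'
#' @param spec a \code{PopulationSpec}.
#' @param animal_index positive integer.
#' @return data.frame of puncta records sorted by (strictly increasing)
#'   \code{axial_position_um}, with columns \code{axial_position_um},
#'   \code{radius_um}, \code{size_um2}, \code{peak_intensity},
#'   \code{integrated_intensity}, \code{interpunctal_intensity}.
#' @examples
#' simulateAnimalPuncta(populationSpec("wt", 1, seed = 7), 1)
#' @export
simulateAnimalPuncta <- function(spec, animal_index) {
  stopifnot(methods::is(spec, "PopulationSpec"), animal_index >= 1L)
  methods::validObject(spec)
  b <- spec@baseline
  s <- substreamSeed(spec@seed, spec@genotype, animal_index)
  withSeed(s, {
    eC <- effectFor(spec, "count")
    eS <- effectFor(spec, "spacing")
    eZ <- effectFor(spec, "size")
    eI <- effectFor(spec, "intensity")

    lamMean <- b$countLambda * (1 + eC$shift * b$countCvBetween)
    lamMean <- max(lamMean, 0.5)
    lam <- lamMean * rlnormCv(1, b$countCvBetween * eC$varMult)
    n <- 0L
    while (n < 1L) n <- stats::rpois(1L, lam)  # truncated at >= 1

    spacingMean <- b$spacingMeanUm * (1 + eS$shift * b$spacingCvBetween) *
      rlnormCv(1, b$spacingCvBetween)
    spacingMean <- max(spacingMean, 1e-3)
    gaps <- rGaps(n - 1L, spacingMean, b$spacingCvWithin * eS$varMult)
    start <- 2 + rGaps(1L, spacingMean, b$spacingCvWithin * eS$varMult)
    pos <- start + cumsum(c(0, gaps))

    radMean <- b$radiusMeanUm * (1 + eZ$shift * b$radiusCvBetween) *
      rlnormCv(1, b$radiusCvBetween)
    radMean <- max(radMean, 1e-3)
    rad <- rlnormMeanCv(n, radMean, b$radiusCvWithin * eZ$varMult)

    intMean <- b$intensityMean * (1 + eI$shift * b$intensityCvBetween) *
      rlnormCv(1, b$intensityCvBetween)
    intMean <- max(intMean, 1e-6)
    peak <- rlnormMeanCv(n, intMean, b$intensityCvWithin * eI$varMult)

    sigma <- halfMaxSigma(rad)
    integrated <- 2 * pi * peak * sigma^2
    gapI <- rep(NA_real_, n)
    if (n > 1L) {
      d <- gaps / 2
      gapI[-n] <- peak[-n] * exp(-d^2 / (2 * sigma[-n]^2)) +
        peak[-1L] * exp(-d^2 / (2 * sigma[-1L]^2))
    }
    data.frame(axial_position_um = pos, radius_um = rad,
               size_um2 = pi * rad^2, peak_intensity = peak,
               integrated_intensity = integrated,
               interpunctal_intensity = gapI)
  })
}

#' Simulate the phenotypic profiles of a whole population
#'
#' Runs \code{\link{simulateAnimalPuncta}} for every animal of the spec and
#' extracts each animal's 76-feature profile.
#'
#' @param spec a \code{\linkS4class{PopulationSpec}}.
#' @return a \code{\linkS4class{PhenotypeProfiles}} with
#'   \code{spec@nAnimals} columns carrying the spec's genotype label.
#' @examples
#' pp <- simulatePopulationProfiles(populationSpec("wt", 5, seed = 1))
#' dim(featureMatrix(pp))
#' @export
simulatePopulationProfiles <- function(spec) {
  stopifnot(methods::is(spec, "PopulationSpec"))
  profs <- lapply(seq_len(spec@nAnimals), function(i)
    extractProfile(simulateAnimalPuncta(spec, i)))
  m <- vapply(profs, as.numeric, numeric(76L))
  PhenotypeProfiles(
    m,
    animal_id = sprintf("%s_%04d", gsub("\\s+", "_", spec@genotype),
                        seq_len(spec@nAnimals)),
    genotype = spec@genotype,
    n_puncta = vapply(profs, function(p) as.integer(attr(p, "n_puncta")), integer(1)),
    qc_pass = vapply(profs, function(p) attr(p, "qc_pass"), logical(1)))
}

#' Plant additive shifts in named profile features
#'
#' Adds \code{shift_sd} pooled-SD units to the given features of the animals
#' of one genotype, leaving all other columns untouched. This is the
#' benchmark device for planting a known discriminative signal directly in
#' feature space (as opposed to generative effects in
#' \code{\link{populationSpec}}): the pooled per-feature SD is computed over
#' all animals before shifting.
#'
#' @param profiles a \code{PhenotypeProfiles} containing the target genotype.
#' @param genotype genotype label whose animals receive the shift.
#' @param features integer feature ids (1..76).
#' @param shift_sd shift in pooled-SD units (recycled over features).
#' @return the modified \code{PhenotypeProfiles}.
#' @export
plantFeatureShifts <- function(profiles, genotype, features, shift_sd = 2) {
  stopifnot(methods::is(profiles, "PhenotypeProfiles"),
            all(features %in% 1:76))
  shift_sd <- rep_len(shift_sd, length(features))
  m <- featureMatrix(profiles)
  cols <- genotypes(profiles) == genotype
  if (!any(cols)) stop("no animals with genotype ", genotype)
  for (k in seq_along(features)) {
    j <- features[k]
    s <- stats::sd(m[j, ], na.rm = TRUE)
    m[j, cols] <- m[j, cols] + shift_sd[k] * s
  }
  SummarizedExperiment::assay(profiles, "features") <- m
  profiles
}

#' Simulate the single-feature threshold screen
#'
#' Emulates a phenotype-threshold sort: an animal is positively sorted when
#' any of its profile features falls beyond that feature's pre-set threshold.
#' Thresholds are one- or two-sided per feature.
#'
#' @param profiles a \code{PhenotypeProfiles} (typically a wild-type-like
#'   population, to estimate the false-sort rate) or the profiles of a
#'   mutagenized population.
#' @param thresholds data.frame with columns \code{feature} (integer id
#'   1..76), and \code{lower} and/or \code{upper} bounds (\code{NA} or
#'   \code{-Inf}/\code{Inf} disables a side). An animal exceeds a threshold
#'   when a feature is strictly below \code{lower} or strictly above
#'   \code{upper}.
#' @return the fraction of animals sorted (with the logical per-animal vector
#'   as attribute \code{"sorted"}).
#' @export
simulateScreen <- function(profiles, thresholds) {
  stopifnot(methods::is(profiles, "PhenotypeProfiles"),
            is.data.frame(thresholds), "feature" %in% names(thresholds))
  if (!all(thresholds$feature %in% 1:76))
    stop("threshold references unknown feature id: ",
         paste(setdiff(thresholds$feature, 1:76), collapse = ", "))
  m <- featureMatrix(profiles)
  lower <- if ("lower" %in% names(thresholds)) thresholds$lower else rep(NA_real_, nrow(thresholds))
  upper <- if ("upper" %in% names(thresholds)) thresholds$upper else rep(NA_real_, nrow(thresholds))
  hit <- rep(FALSE, ncol(m))
  for (k in seq_len(nrow(thresholds))) {
    x <- m[thresholds$feature[k], ]
    if (is.finite(lower[k])) hit <- hit | (x < lower[k])
    if (is.finite(upper[k])) hit <- hit | (x > upper[k])
  }
  frac <- mean(hit)
  attr(frac, "sorted") <- hit
  frac
}
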