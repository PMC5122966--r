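#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Specification of a synthetic straightened-axon image
#'
#' Describes one simulated 16-bit fluorescence micrograph of a straightened
#' axon segment carrying synaptic puncta. Puncta are rendered as isotropic
#' 2-D Gaussians whose width combines the punctum's intrinsic half-max radius
#' with the optical point-spread function; background is flat with additive
#' Gaussian read noise and optional Poisson shot noise.
#'
#' @slot widthPx,heightPx image dimensions in pixels (both >= 16).
#' @slot pixelSizeUm physical pixel size, micrometres.
#' @slot nPuncta number of puncta to place (>= 0).
#' @slot spacingMeanUm,spacingSdUm mean and SD of the Gamma-distributed
#'   interpunctal gaps, micrometres.
#' @slot minSpacingUm hard lower bound on gaps (rejection sampled), um.
#' @slot radiusMeanUm,radiusCv lognormal parameters (mean, CV) of the
#'   punctum half-max radius, micrometres.
#' @slot intensityMean,intensityCv lognormal parameters (mean, CV) of the
#'   punctum peak amplitude above background, arbitrary units.
#' @slot psfSigmaPx Gaussian PSF sigma in pixels (> 0).
#' @slot background flat background level, counts.
#' @slot noiseSd additive Gaussian noise SD, counts.
#' @slot poissonNoise apply Poisson shot noise to the noiseless image first?
#' @slot seed integer random seed.
#' @export
setClass("ImageSpec", representation(
  widthPx = "integer", heightPx = "integer", pixelSizeUm = "numeric",
  nPuncta = "integer", spacingMeanUm = "numeric", spacingSdUm = "numeric",
  minSpacingUm = "numeric", radiusMeanUm = "numeric", radiusCv = "numeric",
  intensityMean = "numeric", intensityCv = "numeric", psfSigmaPx = "numeric",
  background = "numeric", noiseSd = "numeric", poissonNoise = "logical",
  seed = "integer"))

setValidity("ImageSpec", function(object) {
  msg <- character()
  if (object@widthPx < 16L || object@heightPx < 16L)
    msg <- c(msg, "widthPx and heightPx must be >= 16")
  if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
  if (object@psfSigmaPx <= 0) msg <- c(msg, "psfSigmaPx must be > 0")
  if (object@nPuncta < 0L) msg <- c(msg, "nPuncta must be >= 0")
  if (object@spacingMeanUm <= 0 || object@radiusMeanUm <= 0 ||
      object@intensityMean <= 0)
    msg <- c(msg, "all distribution scales must be > 0")
  if (object@spacingSdUm < 0 || object@radiusCv < 0 || object@intensityCv < 0 ||
      object@noiseSd < 0 || object@background < 0 || object@minSpacingUm < 0)
    msg <- c(msg, "SDs, CVs, background and noise must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic animal population
#'
#' Describes the generative model for one genotype: each animal draws its own
#' latent means (puncta count, interpunctal spacing, punctum radius, peak
#' intensity) from between-animal lognormal distributions around the baseline
#' (this is the isogenic heterogeneity), then draws its puncta from
#' within-animal distributions around those latent means. Genotype effects
#' are planted as shifts of a baseline parameter mean in units of its
#' between-animal SD, and/or multipliers on its within-animal CV.
#'
#' @slot genotype genotype label.
#' @slot nAnimals number of animals (>= 1).
#' @slot baseline named list of generative parameters; see
#'   \code{\link{populationSpec}} for names and defaults.
#' @slot effects data.frame with columns \code{parameter} (one of
#'   \code{"count"}, \code{"spacing"}, \code{"size"}, \code{"intensity"}),
#'   \code{shift_sd} and \code{var_mult}.
#' @slot seed integer master seed; per-animal substreams are derived by
#'   hashing (seed, genotype, animal index).
#' @export
setClass("PopulationSpec", representation(
  genotype = "character", nAnimals = "integer", baseline = "list",
  effects = "data.frame", seed = "integer"))

setValidity("PopulationSpec", function(object) {
  msg <- character()
  if (object@nAnimals < 1L) msg <- c(msg, "nAnimals must be >= 1")
  b <- object@baseline
  need <- c("countLambda", "countCvBetween", "spacingMeanUm",
            "spacingCvWithin", "spacingCvBetween", "radiusMeanUm",
            "radiusCvWithin", "radiusCvBetween", "intensityMean",
            "intensityCvWithin", "intensityCvBetween")
  miss <- setdiff(need, names(b))
  if (length(miss)) msg <- c(msg, paste("baseline missing:", paste(miss, collapse = ", ")))
  else {
    if (b$countLambda <= 0 || b$spacingMeanUm <= 0 || b$radiusMeanUm <= 0 ||
        b$intensityMean <= 0)
      msg <- c(msg, "baseline means must be > 0")
    if (any(unlist(b[grep("Cv", need, value = TRUE)]) < 0))
      msg <- c(msg, "baseline CVs must be >= 0")
  }
  if (nrow(object@effects)) {
    ok <- object@effects$parameter %in% c("count", "spacing", "size", "intensity")
    if (!all(ok)) msg <- c(msg, "unknown effect parameter")
    if (any(object@effects$var_mult < 0)) msg <- c(msg, "var_mult must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Container for per-animal phenotypic profiles
#'
#' A \code{SummarizedExperiment} whose single assay \code{"features"} holds
#' the 76-feature phenotypic profile of each animal (features in rows, one
#' column per animal). \code{rowData} carries the feature registry;
#' \code{colData} carries \code{animal_id}, \code{genotype}, \code{n_puncta}
#' and \code{qc_pass}.
#'
#' @seealso \code{\link{PhenotypeProfiles}} (constructor),
#'   \code{\link{extractProfile}}, \code{\link{qcFilter}}
#' @export
setClass("PhenotypeProfiles", contains = "SummarizedExperiment")

setValidity("PhenotypeProfiles", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' missing")
  else if (nrow(object) != 76L)
    msg <- c(msg, "profiles must have exactly 76 feature rows")
  else if (!identical(rownames(object), featureIds()))
    msg <- c(msg, "feature rows must be named f001..f076")
  need <- c("animal_id", "genotype", "n_puncta", "qc_pass")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData missing:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' A fitted stepwise logistic-regression phenotype model
#'
#' A pairwise mutant-versus-wild-type logistic model on standardized profile
#' features, built by forward-backward selection: a feature enters when its
#' likelihood-ratio chi-square p-value is below \code{pEnter} (the candidate
#' with the largest deviance drop is tried first) and an included feature is
#' removed when its removal p-value exceeds \code{pRemove}. Coefficients are
#' on z-scored features (training mean/SD stored), so their magnitudes are
#' comparable across features. Mutant animals are coded 1, wild type 0.
#'
#' @slot mutantLabel,wtLabel genotype labels of the two training groups.
#' @slot features integer feature ids, in order of entry.
#' @slot coefficients numeric vector: intercept followed by one coefficient
#'   per selected feature (standardized scale).
#' @slot center,scale training means and SDs of the selected features.
#' @slot devianceTrace numeric: null deviance, then deviance after each
#'   accepted forward step (non-increasing).
#' @slot pEnter,pRemove selection thresholds.
#' @slot nMutant,nWt training group sizes.
#' @slot ridge ridge stabiliser actually used (0 unless separation detected).
#' @slot separation TRUE when quasi-separation triggered the stabiliser.
#' @slot seed integer seed recorded for reproducibility.
#' @export
setClass("SWLRModel", representation(
  mutantLabel = "character", wtLabel = "character", features = "integer",
  coefficients = "numeric", center = "numeric", scale = "numeric",
  devianceTrace = "numeric", pEnter = "numeric", pRemove = "numeric",
  nMutant = "integer", nWt = "integer", ridge = "numeric",
  separation = "logical", seed = "integer"))

setValidity("SWLRModel", function(object) {
  msg <- character()
  p <- length(object@features)
  if (p > 76L) msg <- c(msg, "at most 76 features")
  if (length(object@coefficients) != p + 1L)
    msg <- c(msg, "coefficients must be intercept + one per feature")
  if (length(object@center) != p || length(object@scale) != p)
    msg <- c(msg, "center/scale must match selected features")
  if (p > 0L && any(object@scale <= 0))
    msg <- c(msg, "standardization SDs must be > 0")
  d <- object@devianceTrace
  if (length(d) && any(diff(d) > 1e-6))
    msg <- c(msg, "deviance trace must be non-increasing")
  if (length(msg)) msg else TRUE
})

#' A best-single-feature baseline model
#'
#' The logistic model on the one feature that best discriminates mutant from
#' wild type in training (highest training AUC; ties broken by the lower
#' feature id). Shares the representation of \code{\linkS4class{SWLRModel}}
#' with exactly one selected feature.
#'
#' @slot trainingAuc training AUC of the winning feature.
#' @slot criterion selection criterion label.
#' @export
setClass("BFModel", contains = "SWLRModel",
         representation(trainingAuc = "numeric", criterion = "character"))

setValidity("BFModel", function(object) {
  if (length(object@features) != 1L) "BFModel must have exactly one feature" else TRUE
})

#' Result of a stratified k-fold cross-validation
#'
#' @slot k number of folds.
#' @slot foldAuc held-out AUC of each fold.
#' @slot meanAuc,sdAuc mean and SD of the fold AUCs.
#' @slot roc list of per-fold ROC point data.frames (fpr, tpr).
#' @slot seed fold-assignment seed.
#' @export
setClass("CVResult", representation(
  k = "integer", foldAuc = "numeric", meanAuc = "numeric", sdAuc = "numeric",
  roc = "list", seed = "integer"))

setValidity("CVResult", function(object) {
  msg <- character()
  if (any(object@foldAuc < 0 | object@foldAuc > 1))
    msg <- c(msg, "fold AUCs must lie in [0,1]")
  if (abs(object@meanAuc - mean(object@foldAuc)) > 1e-8)
    msg <- c(msg, "meanAuc inconsistent with fold AUCs")
  if (length(msg)) msg else TRUE
})

#' Cross-model probability matrix
#'
#' Mean mutant-phenotype probability of every population (rows) under every
#' pairwise model (columns); self pairs (a model scoring its own training
#' mutant population) are flagged.
#'
#' @slot probs numeric matrix in [0,1], rows = populations, cols = models.
#' @slot selfPair logical matrix of the same shape.
#' @export
setClass("ProbabilityMatrix", representation(
  probs = "matrix", selfPair = "matrix"))

setValidity("ProbabilityMatrix", function(object) {
  msg <- character()
  p <- object@probs
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    msg <- c(msg, "probabilities must be finite and in [0,1]")
  if (!identical(dim(p), dim(object@selfPair)))
    msg <- c(msg, "selfPair must match probs dimensions")
  if (length(msg)) msg else TRUE
})

#' Correlation-weighted phenotype distance matrix
#'
#' Pairwise distances between genotype mean z-profiles: a standardized
#' Euclidean distance whose per-feature weights are the inverse of each
#' feature's summed absolute correlation with all features, so blocks of
#' redundant features are down-weighted rather than counted repeatedly.
#'
#' @slot distance symmetric nonnegative matrix, zero diagonal.
#' @slot weights per-feature weights used (normalized to sum to their count).
#' @slot featureIds integer ids of the features the weights refer to.
#' @slot method weighting method label.
#' @export
setClass("PhenotypeDistance", representation(
  distance = "matrix", weights = "numeric", featureIds = "integer",
  method = "character"))

setValidity("PhenotypeDistance", function(object) {
  d <- object@distance
  msg <- character()
  if (!isSymmetric(unname(d), tol = 1e-8)) msg <- c(msg, "distance must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (any(d < -1e-12)) msg <- c(msg, "distances must be nonnegative")
  if (length(msg)) msg else TRUE
})
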