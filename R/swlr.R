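# Assemble the standardized design for a mutant-vs-wild-type pair.
# Returns the animals x 76 matrix, response, pooled center/scale and the
# candidate feature ids (constant features are not candidates).
pairDesign <- function(profiles, mutant, wt) {
  stopifnot(methods::is(profiles, "PhenotypeProfiles"))
  keep <- qcPass(profiles) & genotypes(profiles) %in% c(mutant, wt)
  x <- profiles[, keep]
  g <- genotypes(x)
  if (!any(g == mutant)) stop("no QC-passing animals for mutant group '", mutant, "'")
  if (!any(g == wt)) stop("no QC-passing animals for wild-type group '", wt, "'")
  M <- t(featureMatrix(x))            # animals x features
  y <- as.numeric(g == mutant)
  center <- colMeans(M)
  scale <- apply(M, 2L, stats::sd)
  candidates <- which(scale > 0)
  Z <- sweep(M, 2L, center, "-")
  Z[, candidates] <- sweep(Z[, candidates, drop = FALSE], 2L,
                           scale[candidates], "/")
  list(Z = Z, y = y, center = center, scale = scale,
       candidates = as.integer(candidates),
       nMutant = sum(y == 1), nWt = sum(y == 0))
}

# Forward-backward stepwise driver on a standardized design. Returns the
# ordered selected set plus per-model deviances. Deterministic: candidate
# scans run in ascending feature id order, so exact ties resolve to the
# lowest id.
stepwiseSelect <- function(Z, y, candidates, pEnter, pRemove,
                           maxSteps = 20L, ridge = 1e-6) {
  selected <- integer(0)
  sep <- FALSE
  devCurrent <- nullDeviance(y)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 4L * maxSteps) break   # cycle guard
    moved <- FALSE
    # forward: candidate with the largest deviance drop, tested at pEnter
    if (length(selected) < maxSteps) {
      pool <- setdiff(candidates, selected)
      if (length(pool)) {
        devs <- vapply(pool, function(j) {
          fit <- stableLogit(Z[, c(selected, j), drop = FALSE], y, ridge)
          fit$deviance
        }, numeric(1))
        jbest <- pool[which.min(devs)]
        if (lrPvalue(devCurrent, min(devs)) < pEnter) {
          selected <- c(selected, jbest)
          devCurrent <- min(devs)
          moved <- TRUE
        }
      }
    }
    # backward: drop the least significant included feature if above pRemove
    while (length(selected) > 1L) {
      devsDrop <- vapply(seq_along(selected), function(k) {
        fit <- stableLogit(Z[, selected[-k], drop = FALSE], y, ridge)
        fit$deviance
      }, numeric(1))
      pDrop <- vapply(devsDrop, lrPvalue, numeric(1), devSmaller = devCurrent)
      worst <- which.max(pDrop)
      if (pDrop[worst] > pRemove) {
        selected <- selected[-worst]
        devCurrent <- devsDrop[worst]
        moved <- TRUE
      } else break
    }
    if (!moved) break
  }
  fit <- stableLogit(Z[, selected, drop = FALSE], y, ridge)
  sep <- isTRUE(fit$separation)
  list(selected = selected, fit = fit, separation = sep,
       ridgeUsed = fit$ridgeUsed)
}

#' Fit a pairwise stepwise logistic-regression phenotype model
#'
#' Builds the mutant phenotypic dimension: a logistic regression of
#' mutant-vs-wild-type class on z-scored profile features, with
#' forward-backward selection. At each forward step the candidate feature
#' producing the largest deviance drop enters if its likelihood-ratio
#' chi-square p-value is below \code{pEnter}; included features whose removal
#' p-value exceeds \code{pRemove} are dropped; the procedure iterates to a
#' fixed point (or the \code{maxSteps} cap). Only features that significantly
#' contribute to separating the two populations end up in the model.
#' Features are standardized on the pooled training animals so coefficient
#' magnitudes are comparable; quasi-separation triggers a small ridge
#' stabiliser (1e-6), recorded on the model.
#'
#' The stored deviance trace is the nested sequence null deviance, then the
#' deviance as each finally selected feature is added in entry order (the
#' construction shown when plotting model deviance against added features).
#'
#' @param profiles a \code{\linkS4class{PhenotypeProfiles}} containing both
#'   genotypes (non-QC animals are ignored).
#' @param mutant,wt genotype labels of the mutant and reference groups.
#' @param pEnter,pRemove entry/removal p-value thresholds (defaults 0.05
#'   and 0.10).
#' @param maxSteps cap on the number of selected features.
#' @param seed integer recorded in the model metadata (the fit itself is
#'   deterministic).
#' @return an \code{\linkS4class{SWLRModel}}.
#' @examples
#' pp <- simulatePopulationProfiles(populationSpec("wt", 40, seed = 1))
#' mu <- simulatePopulationProfiles(populationSpec(
#'   "mut", 40, effects = plantedEffect("count", shift_sd = 4), seed = 2))
#' fit <- fitSWLR(cbind(pp, mu), mutant = "mut", wt = "wt")
#' selectedFeatures(fit)
#' @export
fitSWLR <- function(profiles, mutant, wt = "wild type",
                    pEnter = 0.05, pRemove = 0.10, maxSteps = 20L,
                    seed = 0L) {
  d <- pairDesign(profiles, mutant, wt)
  st <- stepwiseSelect(d$Z, d$y, d$candidates, pEnter, pRemove, maxSteps)
  sel <- st$selected
  # nested deviance trace over the final entry order
  trace <- nullDeviance(d$y)
  for (k in seq_along(sel)) {
    fit <- stableLogit(d$Z[, sel[seq_len(k)], drop = FALSE], d$y)
    trace <- c(trace, fit$deviance)
  }
  trace <- cummin(trace)  # guard numerical jitter in the nested refits
  coefs <- st$fit$coef
  methods::new("SWLRModel",
               mutantLabel = mutant, wtLabel = wt, features = as.integer(sel),
               coefficients = as.numeric(coefs),
               center = unname(d$center[sel]), scale = unname(d$scale[sel]),
               devianceTrace = as.numeric(trace),
               pEnter = pEnter, pRemove = pRemove,
               nMutant = as.integer(d$nMutant), nWt = as.integer(d$nWt),
               ridge = as.numeric(st$ridgeUsed %||% 0),
               separation = isTRUE(st$separation), seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the best-single-feature baseline model
#'
#' Fits all 76 single-feature logistic models for the pair and returns the
#' one whose training AUC is highest (exact ties break to the lower feature
#' id). This is the best-case scenario for characterising a mutant with a
#' single metric, against which the multivariate model is compared.
#'
#' @inheritParams fitSWLR
#' @return a \code{\linkS4class{BFModel}}.
#' @export
fitBestFeature <- function(profiles, mutant, wt = "wild type", seed = 0L) {
  d <- pairDesign(profiles, mutant, wt)
  bestAuc <- -Inf
  best <- NULL
  for (j in d$candidates) {     # ascending id: ties keep the first (lowest)
    fit <- stableLogit(d$Z[, j, drop = FALSE], d$y)
    auc <- rocAuc(fit$fitted, d$y)$auc
    if (auc > bestAuc + 1e-12) {
      bestAuc <- auc
      best <- list(j = j, fit = fit)
    }
  }
  if (is.null(best)) stop("no non-constant feature available")
  methods::new("BFModel",
               mutantLabel = mutant, wtLabel = wt,
               features = as.integer(best$j),
               coefficients = as.numeric(best$fit$coef),
               center = unname(d$center[best$j]), scale = unname(d$scale[best$j]),
               devianceTrace = cummin(c(nullDeviance(d$y), best$fit$deviance)),
               pEnter = NA_real_, pRemove = NA_real_,
               nMutant = as.integer(d$nMutant), nWt = as.integer(d$nWt),
               ridge = as.numeric(best$fit$ridgeUsed %||% 0),
               separation = isTRUE(best$fit$separation),
               seed = as.integer(seed), trainingAuc = bestAuc,
               criterion = "training AUC")
}

#' Score animals under a fitted phenotype model
#'
#' Returns the probability that each animal exhibits the model's mutant
#' phenotype: \code{plogis(b0 + sum_j b_j * z_j)} with features standardized
#' by the model's stored training statistics.
#'
#' @param model an \code{SWLRModel} or \code{BFModel}.
#' @param profiles a \code{PhenotypeProfiles}; all columns are scored
#'   (animals failing QC or with non-finite selected features raise an
#'   error).
#' @param ... unused.
#' @return named numeric vector of probabilities in [0,1].
#' @rdname scoreProfiles
#' @export
setMethod("scoreProfiles", signature(model = "SWLRModel", profiles = "PhenotypeProfiles"),
  function(model, profiles, ...) {
    m <- featureMatrix(profiles)
    sel <- model@features
    if (length(sel)) {
      x <- t(m[sel, , drop = FALSE])
      if (any(!is.finite(x)))
        stop("selected features contain missing/non-finite values; apply qcFilter first")
      z <- sweep(sweep(x, 2L, model@center, "-"), 2L, model@scale, "/")
      eta <- model@coefficients[1L] + drop(z %*% model@coefficients[-1L])
    } else {
      eta <- rep(model@coefficients[1L], ncol(m))
    }
    stats::setNames(stats::plogis(eta), colnames(m))
  })

#' Sensitivity and specificity at a probability threshold
#'
#' Sensitivity is the fraction of mutant animals scored above the threshold
#' (true-positive rate); specificity the fraction of wild-type animals at or
#' below it (true-negative rate). The default threshold is a probability
#' of 50 percent.
#'
#' @param model a fitted \code{SWLRModel}/\code{BFModel}.
#' @param profiles a \code{PhenotypeProfiles} holding both groups.
#' @param mutant,wt genotype labels; default to the model's training labels.
#' @param threshold probability cutoff (default 0.5).
#' @return named numeric vector \code{c(sensitivity=, specificity=)}.
#' @export
sensitivitySpecificity <- function(model, profiles,
                                   mutant = model@mutantLabel,
                                   wt = model@wtLabel, threshold = 0.5) {
  keep <- qcPass(profiles) & genotypes(profiles) %in% c(mutant, wt)
  x <- profiles[, keep]
  p <- scoreProfiles(model, x)
  g <- genotypes(x)
  c(sensitivity = mean(p[g == mutant] > threshold),
    specificity = mean(p[g == wt] <= threshold))
}

#' @rdname selectedFeatures
#' @export
setMethod("selectedFeatures", "SWLRModel", function(object) object@features)

#' @rdname devianceTrace
#' @export
setMethod("devianceTrace", "SWLRModel", function(object) object@devianceTrace)

setMethod("show", "SWLRModel", function(object) {
  cat("SWLRModel:", object@mutantLabel, "vs", object@wtLabel, "\n")
  cat("  n =", object@nMutant, "mutant /", object@nWt, "wild type\n")
  cat("  selected features:",
      if (length(object@features)) paste(object@features, collapse = ", ")
      else "(intercept only)", "\n")
  d <- object@devianceTrace
  cat(sprintf("  deviance: %.2f (null) -> %.2f\n", d[1L], d[length(d)]))
  if (object@separation)
    cat("  note: separation detected; ridge stabiliser", object@ridge, "used\n")
})

setMethod("show", "BFModel", function(object) {
  cat("BFModel:", object@mutantLabel, "vs", object@wtLabel, "\n")
  cat(sprintf("  best feature: %d (%s), training AUC %.3f\n",
              object@features, featureRegistry()$name[object@features],
              object@trainingAuc))
})
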