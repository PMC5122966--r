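#' Stratified k-fold cross-validated AUC of a pairwise model
#'
#' Splits each group into k folds (stratified, so every fold holds roughly
#' the same class balance), re-runs the full stepwise selection and fit on
#' each training set, scores the held-out fold and computes its AUC. Because
#' selection is repeated inside every training fold, the reported AUC is free
#' of feature-selection leakage.
#'
#' @inheritParams fitSWLR
#' @param k number of folds (default 5).
#' @param method \code{"swlr"} (default) or \code{"bf"} to cross-validate
#'   the best-single-feature baseline instead.
#' @param seed integer seed controlling the fold assignment (fits are
#'   deterministic given the folds).
#' @return a \code{\linkS4class{CVResult}}.
#' @examples
#' pp <- cbind(
#'   simulatePopulationProfiles(populationSpec("wt", 30, seed = 1)),
#'   simulatePopulationProfiles(populationSpec(
#'     "mut", 30, effects = plantedEffect("intensity", shift_sd = 5), seed = 2)))
#' cv <- crossValidate(pp, "mut", "wt", k = 3, seed = 1)
#' cv@meanAuc
#' @export
crossValidate <- function(profiles, mutant, wt = "wild type", k = 5L,
                          pEnter = 0.05, pRemove = 0.10, maxSteps = 20L,
                          method = c("swlr", "bf"), seed = 1L) {
  method <- match.arg(method)
  k <- as.integer(k)
  keep <- qcPass(profiles) & genotypes(profiles) %in% c(mutant, wt)
  x <- profiles[, keep]
  g <- genotypes(x)
  nM <- sum(g == mutant); nW <- sum(g == wt)
  if (min(nM, nW) < k)
    stop("smallest group (", min(nM, nW), ") has fewer animals than k = ", k,
         "; use a smaller k")
  folds <- integer(ncol(x))
  withSeed(substreamSeed(seed, "cvfolds", 0L), {
    for (grp in c(mutant, wt)) {
      idx <- which(g == grp)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  foldAuc <- numeric(k)
  rocs <- vector("list", k)
  for (f in seq_len(k)) {
    train <- x[, folds != f]
    test <- x[, folds == f]
    model <- if (method == "swlr")
      fitSWLR(train, mutant, wt, pEnter, pRemove, maxSteps, seed = seed)
    else fitBestFeature(train, mutant, wt, seed = seed)
    p <- scoreProfiles(model, test)
    ra <- rocAuc(p, genotypes(test) == mutant)
    foldAuc[f] <- ra$auc
    rocs[[f]] <- ra$roc
  }
  methods::new("CVResult", k = k, foldAuc = foldAuc,
               meanAuc = mean(foldAuc), sdAuc = stats::sd(foldAuc),
               roc = rocs, seed = as.integer(seed))
}

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d-fold, AUC %.3f +/- %.3f (s.d. across folds)\n",
              object@k, object@meanAuc, object@sdAuc))
})
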