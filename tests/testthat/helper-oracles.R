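# Independent oracles used to freeze expected values.

# AUC by exhaustive concordant-pair counting, ties counted one half.
bruteForceAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exhaustive single-feature deviance scan: deviance of each one-feature
# logistic model, via stats::glm (independent of the package's IRLS).
singleFeatureDevianceScan <- function(profiles, mutant, wt) {
  keep <- qcPass(profiles) & genotypes(profiles) %in% c(mutant, wt)
  x <- profiles[, keep]
  M <- t(featureMatrix(x))
  y <- as.numeric(genotypes(x) == mutant)
  vapply(seq_len(ncol(M)), function(j) {
    if (stats::sd(M[, j]) == 0) return(Inf)
    suppressWarnings(stats::glm(y ~ M[, j], family = stats::binomial())$deviance)
  }, numeric(1))
}

# Brute-force strict 8-neighbourhood local maxima scan (loop form).
bruteForceLocalMaxima <- function(m) {
  out <- NULL
  for (r in 2:(nrow(m) - 1)) for (cc in 2:(ncol(m) - 1)) {
    nb <- m[(r - 1):(r + 1), (cc - 1):(cc + 1)]
    if (m[r, cc] > max(nb[-5])) out <- rbind(out, c(r, cc))
  }
  out
}

# simple puncta table builder for extraction tests
punctaTable <- function(pos, size = 1, integrated = 100, peak = 50,
                        gapI = NULL) {
  n <- length(pos)
  data.frame(axial_position_um = pos,
             size_um2 = rep_len(size, n),
             radius_um = sqrt(rep_len(size, n) / pi),
             integrated_intensity = rep_len(integrated, n),
             peak_intensity = rep_len(peak, n),
             interpunctal_intensity = if (is.null(gapI)) c(rep(10, n - 1), NA)
                                      else gapI)
}
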