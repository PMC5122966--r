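# Lean IRLS logistic fitter used by the stepwise machinery.
#
# Stepwise selection refits thousands of small logistic models inside
# cross-validation loops, so this avoids the per-call overhead of stats::glm
# while computing the same maximum-likelihood solution (cross-checked against
# glm in the test suite). `ridge` adds an L2 penalty on the non-intercept
# coefficients; the stepwise driver turns it on (1e-6) only when complete or
# quasi-complete separation is detected, to keep coefficients finite.
#
# X: design matrix WITHOUT intercept column (may have 0 columns);
# y: 0/1 response.
fastLogit <- function(X, y, ridge = 0, maxit = 60L, tol = 1e-10) {
  n <- length(y)
  p <- ncol(X)
  Xd <- cbind(1, X)
  beta <- numeric(p + 1L)
  beta[1L] <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  pen <- c(0, rep(ridge, p))
  dev <- Inf
  conv <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    newdev <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)) +
      sum(pen * beta^2)
    if (is.finite(dev) && abs(dev - newdev) < tol * (abs(dev) + 1)) {
      dev <- newdev; conv <- TRUE; break
    }
    dev <- newdev
    w <- mu * (1 - mu)
    w <- pmax(w, 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(Xd * w)
    A <- XtW %*% Xd
    diag(A) <- diag(A) + pen
    beta <- tryCatch(drop(solve(A, XtW %*% z)),
                     error = function(e) beta + NA_real_)
    if (anyNA(beta)) return(list(coef = rep(NA_real_, p + 1L), deviance = NA_real_,
                                 fitted = rep(NA_real_, n), converged = FALSE,
                                 separation = TRUE))
  }
  eta <- drop(Xd %*% beta)
  mu <- stats::plogis(eta)
  muc <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
  deviance <- -2 * sum(y * log(muc) + (1 - y) * log(1 - muc))
  # (quasi-)separation: divergent coefficients or an essentially perfect fit
  sep <- p > 0L && (!conv || max(abs(beta[-1L])) > 15 || deviance < 1e-3)
  list(coef = beta, deviance = deviance, fitted = mu, converged = conv,
       separation = sep)
}

# Fit with automatic separation handling: refit with the ridge stabiliser
# when the unpenalised fit diverges.
stableLogit <- function(X, y, ridge = 1e-6) {
  fit <- fastLogit(X, y, ridge = 0)
  if (!fit$separation && !anyNA(fit$coef)) {
    fit$ridgeUsed <- 0
    return(fit)
  }
  fit <- fastLogit(X, y, ridge = ridge, maxit = 200L)
  fit$separation <- TRUE
  fit$ridgeUsed <- ridge
  fit
}

# deviance of the intercept-only model
nullDeviance <- function(y) {
  p <- mean(y)
  if (p <= 0 || p >= 1) return(0)
  -2 * (sum(y) * log(p) + sum(1 - y) * log(1 - p))
}

# likelihood-ratio chi-square p-value, 1 df
lrPvalue <- function(devLarger, devSmaller) {
  stats::pchisq(max(devLarger - devSmaller, 0), df = 1, lower.tail = FALSE)
}
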