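#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with an arbitrary character label and an
#' integer index into a new 31-bit seed. Simulators use this to give every
#' animal its own independent random stream, so a population can be extended
#' (more animals, more genotypes) without reshuffling draws already made.
#'
#' @param seed master integer seed.
#' @param label character scalar, e.g. a genotype label.
#' @param index nonnegative integer, e.g. an animal index.
#' @return an integer in \code{[0, 2^31 - 2]} suitable for \code{set.seed()}.
#' @examples
#' substreamSeed(1L, "wild type", 1L)
#' @export
substreamSeed <- function(seed, label = "", index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1 (prime); polynomial rolling hash below this
  h <- (abs(as.numeric(seed)) %% m)
  codes <- utf8ToInt(as.character(label))
  for (cc in codes) h <- (h * 131 + cc) %% m
  h <- (h * 131 + (abs(as.numeric(index)) %% m)) %% m
  # final avalanche pass so consecutive indices land far apart
  h <- (h * 48271) %% m
  as.integer(h)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores \code{.Random.seed}, so simulator internals never
#' perturb the caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# quantile with a fixed, documented convention (linear interpolation between
# order statistics; type 7, R's default) so feature values are reproducible
# across platforms.
punctaQuantile <- function(x, p) unname(stats::quantile(x, p, type = 7, names = FALSE))

# coefficient of variation; 0 for a degenerate (zero-mean or single-value) input
cv <- function(x) {
  m <- mean(x)
  if (length(x) < 2L || m == 0) return(0)
  stats::sd(x) / m
}

# sample skewness (g1); 0 when degenerate
skewness <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (n < 3L || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

# Gini coefficient of a nonnegative vector; 0 when degenerate
gini <- function(x) {
  n <- length(x)
  if (n < 2L || mean(x) == 0) return(0)
  xs <- sort(x)
  (2 * sum(seq_len(n) * xs) / (n * sum(xs))) - (n + 1) / n
}

# Pearson correlation that returns 0 (not NA) for zero-variance input
safeCor <- function(x, y) {
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

# lag-1 autocorrelation along the given ordering; 0 when degenerate
lag1Autocor <- function(x) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(0)
  safeCor(x[-n], x[-1L])
}
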