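#' Train the punctum candidate classifier
#'
#' Fits a max-margin (support vector machine) classifier separating true
#' puncta from spurious blob candidates, on the standardized 6-descriptor
#' vectors of \code{\link{detectCandidates}}. The fitted machine is stored
#' as plain numbers (support vectors, weights, bias, standardization), so a
#' serialized model reloads to bit-identical decisions.
#'
#' @param candidates data.frame of candidates (must carry the 6 descriptor
#'   columns).
#' @param labels logical vector, \code{TRUE} for true puncta; both classes
#'   required with at least 10 examples each.
#' @param kernel \code{"linear"} (default) or \code{"radial"}.
#' @param cost SVM cost parameter.
#' @param seed integer seed (recorded; libsvm training for these kernels is
#'   deterministic given the data).
#' @return an object of class \code{punctaClassifier}.
#' @export
trainClassifier <- function(candidates, labels, kernel = c("linear", "radial"),
                            cost = 1, seed = 1L) {
  kernel <- match.arg(kernel)
  X <- as.matrix(candidates[, descriptorNames()])
  labels <- as.logical(labels)
  if (length(labels) != nrow(X)) stop("labels must match candidates")
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L) stop("no positive (true punctum) examples in training data")
  if (nNeg == 0L) stop("no negative (non-punctum) examples in training data")
  if (min(nPos, nNeg) < 10L)
    stop("need at least 10 examples per class (got ", nPos, " / ", nNeg, ")")
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0] <- 1
  Z <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  y <- factor(ifelse(labels, "punctum", "noise"), levels = c("punctum", "noise"))
  fit <- withSeed(substreamSeed(seed, "svm", 0L),
    e1071::svm(Z, y, kernel = kernel, cost = cost, scale = FALSE))
  model <- list(kernel = kernel,
                sv = unname(as.matrix(fit$SV)),
                coefs = as.numeric(fit$coefs),
                rho = as.numeric(fit$rho),
                gamma = as.numeric(fit$gamma),
                center = unname(center), scale = unname(scale),
                descriptors = descriptorNames(),
                nPos = nPos, nNeg = nNeg, cost = cost, seed = as.integer(seed))
  class(model) <- "punctaClassifier"
  # orient the decision function so positives score > 0
  d <- classifierDecision(model, X)
  if (mean(d[labels]) < mean(d[!labels])) {
    model$coefs <- -model$coefs
    model$rho <- -model$rho
  }
  model
}

# raw decision values, computed from the stored numbers (not via predict())
classifierDecision <- function(model, X) {
  Z <- sweep(sweep(as.matrix(X), 2L, model$center, "-"), 2L, model$scale, "/")
  if (model$kernel == "linear") {
    w <- drop(crossprod(model$sv, model$coefs))
    drop(Z %*% w) - model$rho
  } else {
    K <- exp(-model$gamma *
               (outer(rowSums(Z^2), rowSums(model$sv^2), "+") -
                  2 * tcrossprod(Z, model$sv)))
    drop(K %*% model$coefs) - model$rho
  }
}

#' @export
print.punctaClassifier <- function(x, ...) {
  cat("punctaClassifier:", x$kernel, "kernel,", nrow(x$sv),
      "support vectors, trained on", x$nPos, "positives /", x$nNeg,
      "negatives\n")
  invisible(x)
}

#' Classify punctum candidates
#'
#' Keeps the candidates whose SVM decision value is positive, preserving the
#' input ordering.
#'
#' @param model a \code{punctaClassifier}.
#' @param candidates data.frame with the model's descriptor columns.
#' @return the accepted subset of \code{candidates}, with a
#'   \code{decision_value} column appended.
#' @export
classifyCandidates <- function(model, candidates) {
  stopifnot(inherits(model, "punctaClassifier"))
  if (!nrow(candidates)) {
    candidates$decision_value <- numeric(0)
    return(candidates)
  }
  miss <- setdiff(model$descriptors, names(candidates))
  if (length(miss))
    stop("candidates lack descriptor columns: ", paste(miss, collapse = ", "))
  d <- classifierDecision(model, candidates[, model$descriptors])
  out <- candidates[d > 0, , drop = FALSE]
  out$decision_value <- d[d > 0]
  rownames(out) <- NULL
  out
}

#' Serialize / restore a punctum classifier as JSON
#'
#' @param model a \code{punctaClassifier}.
#' @param path JSON file path.
#' @return \code{writeClassifierJson}: the path, invisibly;
#'   \code{readClassifierJson}: the restored \code{punctaClassifier}
#'   (bit-identical decision function).
#' @export
writeClassifierJson <- function(model, path) {
  stopifnot(inherits(model, "punctaClassifier"))
  obj <- unclass(model)
  obj$sv <- apply(obj$sv, 1L, function(r) r, simplify = FALSE)
  # I(17) significant digits: doubles survive the decimal round trip exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeClassifierJson
#' @export
readClassifierJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sv <- if (is.list(obj$sv)) do.call(rbind, obj$sv) else as.matrix(obj$sv)
  obj$nPos <- as.integer(obj$nPos); obj$nNeg <- as.integer(obj$nNeg)
  obj$seed <- as.integer(obj$seed)
  class(obj) <- "punctaClassifier"
  obj
}

#' Label candidates against simulation ground truth
#'
#' Matches candidates to ground-truth puncta by nearest distance within a
#' tolerance; matched candidates are positives, the rest negatives. This is
#' how training labels are produced on synthetic data (manual curation of
#' real images plays this role in an experimental pipeline).
#'
#' @param candidates candidate data.frame (\code{x_px}, \code{y_px}).
#' @param groundTruth ground-truth data.frame (\code{x_um}, \code{y_um}).
#' @param pixelSizeUm pixel size to convert ground truth to pixels.
#' @param tol_px matching tolerance in pixels (default 2).
#' @return logical vector over candidates.
#' @export
labelCandidates <- function(candidates, groundTruth, pixelSizeUm, tol_px = 2) {
  if (!nrow(candidates)) return(logical(0))
  if (!nrow(groundTruth)) return(rep(FALSE, nrow(candidates)))
  gx <- groundTruth$x_um / pixelSizeUm + 0.5
  gy <- groundTruth$y_um / pixelSizeUm + 0.5
  lab <- rep(FALSE, nrow(candidates))
  used <- rep(FALSE, length(gx))
  d <- sqrt(outer(candidates$x_px, gx, "-")^2 + outer(candidates$y_px, gy, "-")^2)
  ord <- order(apply(d, 1L, min))
  for (i in ord) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (length(j) && is.finite(d[i, j]) && d[i, j] <= tol_px && !used[j]) {
      lab[i] <- TRUE
      used[j] <- TRUE
    }
  }
  lab
}
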