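# scale-normalized Laplacian-of-Gaussian kernel (negated so bright blobs give
# positive response); odd-sized, zero-sum.
logKernel <- function(sigma) {
  w <- max(2L, ceiling(4 * sigma))
  ax <- (-w):w
  r2 <- outer(ax^2, ax^2, "+")
  g <- exp(-r2 / (2 * sigma^2))
  k <- (2 - r2 / sigma^2) * g / (2 * pi * sigma^2)  # -sigma^2 * LoG
  k - mean(k)                                        # zero response to flat background
}

# strict local maxima over the 8-neighbourhood (border excluded)
localMaxima <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(cbind(row = integer(0), col = integer(0)))
  core <- m[2:(nr - 1), 2:(nc - 1)]
  ok <- core > m[1:(nr - 2), 2:(nc - 1)] & core > m[3:nr, 2:(nc - 1)] &
        core > m[2:(nr - 1), 1:(nc - 2)] & core > m[2:(nr - 1), 3:nc] &
        core > m[1:(nr - 2), 1:(nc - 2)] & core > m[1:(nr - 2), 3:nc] &
        core > m[3:nr, 1:(nc - 2)] & core > m[3:nr, 3:nc]
  idx <- which(ok, arr.ind = TRUE)
  cbind(row = idx[, 1L] + 1L, col = idx[, 2L] + 1L)
}

# window-based candidate descriptors; the fixed 6-descriptor set is
# peak intensity, local contrast, blob response, area at half max,
# eccentricity and local background.
candidateDescriptors <- function(image, row, col, scale, response) {
  H <- nrow(image); W <- ncol(image)
  w <- max(3L, ceiling(3 * scale))
  ys <- max(1L, row - w):min(H, row + w)
  xs <- max(1L, col - w):min(W, col + w)
  win <- image[ys, xs, drop = FALSE]
  ring <- c(win[1L, ], win[nrow(win), ], win[, 1L], win[, ncol(win)])
  bg <- stats::median(ring)
  peak <- image[row, col]
  contrast <- peak - bg
  mask <- win >= bg + 0.5 * contrast
  area <- sum(mask)
  ecc <- 0
  if (area >= 3L) {
    idx <- which(mask, arr.ind = TRUE)
    wts <- pmax(win[mask] - bg, 0)
    if (sum(wts) > 0) {
      mu <- c(sum(idx[, 1L] * wts), sum(idx[, 2L] * wts)) / sum(wts)
      dy <- idx[, 1L] - mu[1L]; dx <- idx[, 2L] - mu[2L]
      cyy <- sum(wts * dy^2) / sum(wts); cxx <- sum(wts * dx^2) / sum(wts)
      cxy <- sum(wts * dx * dy) / sum(wts)
      tr <- cxx + cyy
      det <- cxx * cyy - cxy^2
      disc <- sqrt(max(tr^2 / 4 - det, 0))
      l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
      if (l1 > 0) ecc <- sqrt(max(1 - l2 / l1, 0))
    }
  }
  c(peak_intensity = peak, local_contrast = contrast, blob_response = response,
    area_halfmax = area, eccentricity = ecc, local_background = bg)
}

descriptorNames <- function()
  c("peak_intensity", "local_contrast", "blob_response", "area_halfmax",
    "eccentricity", "local_background")

#' Detect punctum candidates by multi-scale blob response
#'
#' Convolves the image with scale-normalized Laplacian-of-Gaussian kernels
#' over a range of scales, takes strict local maxima of the (negated)
#' response above a permissive threshold, and merges maxima across scales by
#' response-ordered non-maximum suppression. The stage is deliberately
#' high-recall: over-detection is expected and pruned later by the candidate
#' classifier (\code{\link{classifyCandidates}}).
#'
#' The default threshold is \code{nsigma} times the response noise expected
#' from the image's background noise (estimated by the median absolute
#' deviation, propagated through the kernel), so it adapts to the image; on
#' a noiseless image any positive blob response qualifies.
#'
#' @param image numeric matrix (rows = y), finite.
#' @param scales LoG sigmas in pixels to scan.
#' @param nsigma threshold in units of propagated background noise
#'   (default 3; permissive).
#' @param threshold absolute response threshold overriding \code{nsigma}.
#' @return data.frame of candidates: \code{x_px}, \code{y_px},
#'   \code{scale_px}, plus the 6 descriptor columns
#'   (\code{peak_intensity}, \code{local_contrast}, \code{blob_response},
#'   \code{area_halfmax}, \code{eccentricity}, \code{local_background}).
#'   Empty (with a warning) for blank or saturated images.
#' @export
detectCandidates <- function(image, scales = c(1.6, 2.4, 3.6, 5.4),
                             nsigma = 3, threshold = NULL) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("image contains non-finite values")
  if (max(image) - min(image) <= 0) {
    warning("blank or saturated image: no candidates")
    return(emptyCandidates())
  }
  noise <- stats::mad(image)
  found <- NULL
  for (s in scales) {
    k <- logKernel(s)
    resp <- EBImage::filter2(image, k, boundary = "replicate")
    thr <- if (!is.null(threshold)) threshold
           else max(nsigma * noise * sqrt(sum(k^2)), 1e-8 * max(abs(image)), 1e-12)
    mx <- localMaxima(resp)
    if (nrow(mx)) {
      vals <- resp[mx]
      keep <- vals > thr
      if (any(keep))
        found <- rbind(found, data.frame(row = mx[keep, 1L], col = mx[keep, 2L],
                                         scale = s, response = vals[keep]))
    }
  }
  if (is.null(found) || !nrow(found)) {
    warning("no candidates above threshold")
    return(emptyCandidates())
  }
  # cross-scale non-maximum suppression, strongest response wins
  found <- found[order(-found$response, found$col, found$row), ]
  keep <- rep(TRUE, nrow(found))
  for (i in seq_len(nrow(found))) {
    if (!keep[i]) next
    if (i < nrow(found)) {
      j <- (i + 1L):nrow(found)
      d2 <- (found$row[j] - found$row[i])^2 + (found$col[j] - found$col[i])^2
      tooClose <- d2 <= max(2, 1.5 * found$scale[i])^2
      keep[j][tooClose] <- FALSE
    }
  }
  found <- found[keep, , drop = FALSE]
  found <- found[order(found$col, found$row), , drop = FALSE]
  desc <- t(vapply(seq_len(nrow(found)), function(i)
    candidateDescriptors(image, found$row[i], found$col[i],
                         found$scale[i], found$response[i]),
    numeric(6L)))
  out <- data.frame(x_px = found$col, y_px = found$row,
                    scale_px = found$scale, desc)
  rownames(out) <- NULL
  out
}

emptyCandidates <- function() {
  out <- data.frame(x_px = numeric(0), y_px = numeric(0), scale_px = numeric(0))
  for (nm in descriptorNames()) out[[nm]] <- numeric(0)
  out
}
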