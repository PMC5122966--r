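#' Build an ImageSpec
#'
#' @param widthPx,heightPx image size in pixels.
#' @param pixelSizeUm pixel size in micrometres (default 0.16, a 40x oil
#'   objective scale).
#' @param nPuncta number of puncta.
#' @param spacingMeanUm,spacingSdUm interpunctal gap distribution (Gamma).
#' @param minSpacingUm hard minimum gap (um).
#' @param radiusMeanUm,radiusCv punctum half-max radius distribution
#'   (lognormal).
#' @param intensityMean,intensityCv peak amplitude distribution (lognormal),
#'   counts above background.
#' @param psfSigmaPx Gaussian PSF sigma (pixels).
#' @param background flat background (counts).
#' @param noiseSd additive Gaussian noise SD (counts).
#' @param poissonNoise apply Poisson shot noise?
#' @param seed integer seed.
#' @return an \code{\linkS4class{ImageSpec}}.
#' @export
imageSpec <- function(widthPx = 512L, heightPx = 64L, pixelSizeUm = 0.16,
                      nPuncta = 15L, spacingMeanUm = 4, spacingSdUm = 1.2,
                      minSpacingUm = 0, radiusMeanUm = 0.5, radiusCv = 0.25,
                      intensityMean = 600, intensityCv = 0.35,
                      psfSigmaPx = 1.6, background = 100, noiseSd = 10,
                      poissonNoise = FALSE, seed = 1L) {
  methods::new("ImageSpec", widthPx = as.integer(widthPx),
               heightPx = as.integer(heightPx), pixelSizeUm = pixelSizeUm,
               nPuncta = as.integer(nPuncta), spacingMeanUm = spacingMeanUm,
               spacingSdUm = spacingSdUm, minSpacingUm = minSpacingUm,
               radiusMeanUm = radiusMeanUm, radiusCv = radiusCv,
               intensityMean = intensityMean, intensityCv = intensityCv,
               psfSigmaPx = psfSigmaPx, background = background,
               noiseSd = noiseSd, poissonNoise = poissonNoise,
               seed = as.integer(seed))
}

#' Simulate a straightened-axon fluorescence image
#'
#' Renders the spec's puncta as isotropic 2-D Gaussians along a horizontal
#' axon at mid-height: each punctum's effective sigma combines its intrinsic
#' half-max radius with the PSF
#' (\code{sigma_eff^2 = (r / sqrt(2 log 2) / pixel)^2 + psfSigma^2}), and its
#' ground-truth integrated intensity is the full Gaussian integral
#' \code{2 pi A sigma_eff^2} (pixel-area units). A flat background, optional
#' Poisson shot noise and additive Gaussian read noise complete the image.
#' Puncta are kept at least \code{4 sigma_eff} away from the lateral edges so
#' that, with zero background and noise, the total image intensity matches
#' the summed ground-truth integrals to better than 0.1 percent.
#'
#' @param spec an \code{\linkS4class{ImageSpec}}.
#' @return list with \code{image} (numeric matrix, rows = y; quantized only
#'   when written as 16-bit TIFF by \code{\link{writeAxonTiff}}) and
#'   \code{groundTruth} (data.frame: \code{x_um}, \code{y_um},
#'   \code{radius_um}, \code{peak_intensity}, \code{integrated_intensity}).
#' @examples
#' sim <- simulateAxonImage(imageSpec(nPuncta = 5L, noiseSd = 0, seed = 3))
#' nrow(sim$groundTruth)
#' @export
simulateAxonImage <- function(spec) {
  stopifnot(methods::is(spec, "ImageSpec"))
  methods::validObject(spec)
  px <- spec@pixelSizeUm
  withSeed(substreamSeed(spec@seed, "axon-image", 0L), {
    n <- spec@nPuncta
    W <- spec@widthPx; H <- spec@heightPx
    if (n > 0L) {
      rad <- rlnormMeanCv(n, spec@radiusMeanUm, spec@radiusCv)
      peak <- rlnormMeanCv(n, spec@intensityMean, spec@intensityCv)
      sigmaPx <- sqrt((halfMaxSigma(rad) / px)^2 + spec@psfSigmaPx^2)
      marginPx <- 4 * max(sigmaPx) + 1
      availUm <- (W - 2 * marginPx) * px
      needUm <- (n - 1L) * max(spec@spacingMeanUm, spec@minSpacingUm)
      if (needUm > availUm)
        stop("cannot place ", n, " puncta: expected span ",
             round(needUm, 1), " um exceeds usable width ",
             round(availUm, 1), " um (margin 4 x sigma at each edge)")
      cvS <- if (spec@spacingMeanUm > 0) spec@spacingSdUm / spec@spacingMeanUm else 0
      gaps <- NULL
      for (try in seq_len(100L)) {
        gg <- rGaps(n - 1L, spec@spacingMeanUm, cvS, spec@minSpacingUm)
        if (sum(gg) <= availUm) { gaps <- gg; break }
      }
      if (is.null(gaps))
        stop("cannot place ", n, " puncta within the image width at the ",
             "requested spacing distribution")
      span <- sum(gaps)
      startUm <- marginPx * px + ((availUm - span) / 2)
      xUm <- startUm + cumsum(c(0, gaps))
      yUm <- (H / 2 + stats::rnorm(n, 0, 1)) * px
      yUm <- pmin(pmax(yUm, marginPx * px), (H - marginPx) * px)
      gt <- data.frame(x_um = xUm, y_um = yUm, radius_um = rad,
                       peak_intensity = peak,
                       integrated_intensity = 2 * pi * peak * sigmaPx^2)
    } else {
      gt <- data.frame(x_um = numeric(0), y_um = numeric(0),
                       radius_um = numeric(0), peak_intensity = numeric(0),
                       integrated_intensity = numeric(0))
      sigmaPx <- numeric(0)
    }
    img <- matrix(0, nrow = spec@heightPx, ncol = spec@widthPx)
    if (n > 0L) {
      for (i in seq_len(n)) {
        cx <- gt$x_um[i] / px + 0.5  # pixel centres at (j - 0.5, i - 0.5)
        cy <- gt$y_um[i] / px + 0.5
        s <- sigmaPx[i]
        w <- ceiling(6 * s)
        xs <- max(1L, floor(cx - w)):min(W, ceiling(cx + w))
        ys <- max(1L, floor(cy - w)):min(H, ceiling(cy + w))
        gx <- exp(-((xs - 0.5) - (cx - 0.5))^2 / (2 * s^2))
        gy <- exp(-((ys - 0.5) - (cy - 0.5))^2 / (2 * s^2))
        img[ys, xs] <- img[ys, xs] + gt$peak_intensity[i] * outer(gy, gx)
      }
    }
    if (spec@poissonNoise)
      img <- matrix(stats::rpois(length(img), lambda = img + spec@background),
                    nrow = H) - spec@background
    img <- img + spec@background
    if (spec@noiseSd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec@noiseSd), nrow = H)
    img[img < 0] <- 0
    list(image = img, groundTruth = gt)
  })
}

#' Write an image as a 16-bit grayscale TIFF
#'
#' Values are rounded to integer counts, clamped to [0, 65535] and written
#' as 16-bit grayscale.
#'
#' @param image numeric matrix (rows = y).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeAxonTiff <- function(image, path) {
  q <- round(image)
  q[q < 0] <- 0
  q[q > 65535] <- 65535
  tiff::writeTIFF(q / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a 16-bit grayscale TIFF back into counts
#'
#' @param path TIFF file path.
#' @return numeric matrix of counts (rows = y).
#' @export
readAxonTiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m
}
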