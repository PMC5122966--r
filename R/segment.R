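#' Segment accepted candidates into quantitative puncta records
#'
#' For each accepted candidate, a local background is estimated from the
#' border ring of its window, the punctum's half-max region (pixels above
#' background + half the background-subtracted peak, connected to the peak)
#' gives its size, and its integrated intensity is the background-subtracted
#' sum over a circular aperture of radius \code{3.5 x scale} (capturing
#' essentially the whole Gaussian mass). Pixels closer to another accepted
#' peak are excluded, so overlapping regions are split by nearest-peak
#' assignment. Axial positions are the intensity-weighted x-centroids of the
#' half-max regions, converted to micrometres from the left (anterior) edge;
#' records are returned sorted anterior to posterior. The gap midpoint
#' intensity between consecutive puncta (background-subtracted) is recorded
#' as \code{interpunctal_intensity}.
#'
#' @param image numeric matrix (rows = y).
#' @param accepted accepted candidate data.frame from
#'   \code{\link{classifyCandidates}} (or any table with \code{x_px},
#'   \code{y_px}, \code{scale_px}).
#' @param pixelSizeUm pixel size in micrometres.
#' @return data.frame of puncta records: \code{axial_position_um},
#'   \code{y_um}, \code{radius_um}, \code{size_um2},
#'   \code{integrated_intensity}, \code{peak_intensity},
#'   \code{interpunctal_intensity}. Candidates whose half-max region
#'   collapses to zero pixels are dropped with a warning.
#' @export
segmentPuncta <- function(image, accepted, pixelSizeUm) {
  stopifnot(is.matrix(image), pixelSizeUm > 0)
  if (!nrow(accepted))
    return(data.frame(axial_position_um = numeric(0), y_um = numeric(0),
                      radius_um = numeric(0), size_um2 = numeric(0),
                      integrated_intensity = numeric(0),
                      peak_intensity = numeric(0),
                      interpunctal_intensity = numeric(0)))
  H <- nrow(image); W <- ncol(image)
  n <- nrow(accepted)
  px <- accepted$x_px; py <- accepted$y_px; sc <- accepted$scale_px
  rows <- list()
  for (i in seq_len(n)) {
    # window wide enough that the border ring sits in background (>= 5 sigma)
    w <- max(6L, ceiling(5 * sc[i]))
    ys <- max(1L, py[i] - w):min(H, py[i] + w)
    xs <- max(1L, px[i] - w):min(W, px[i] + w)
    win <- image[ys, xs, drop = FALSE]
    ring <- c(win[1L, ], win[nrow(win), ], win[, 1L], win[, ncol(win)])
    bg <- stats::median(ring)
    peak <- image[py[i], px[i]] - bg
    if (peak <= 0) {
      warning("candidate at x=", px[i], " has non-positive contrast; dropped")
      next
    }
    # nearest-peak ownership: exclude pixels closer to another accepted peak
    gy <- matrix(ys, nrow = length(ys), ncol = length(xs))
    gx <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    d2self <- (gy - py[i])^2 + (gx - px[i])^2
    own <- matrix(TRUE, length(ys), length(xs))
    for (j in seq_len(n)) {
      if (j == i) next
      if (abs(px[j] - px[i]) > 2L * w || abs(py[j] - py[i]) > 2L * w) next
      own <- own & (d2self <= (gy - py[j])^2 + (gx - px[j])^2)
    }
    # half-max region connected to the peak
    mask <- (win >= bg + 0.5 * peak) & own
    if (any(mask)) {
      lab <- EBImage::bwlabel(mask)
      peakLab <- lab[match(py[i], ys), match(px[i], xs)]
      mask <- if (peakLab > 0) lab == peakLab else mask & FALSE
    }
    areaPx <- sum(mask)
    if (areaPx == 0L) {
      warning("half-max region collapsed to zero pixels at x=", px[i],
              "; punctum dropped")
      next
    }
    wts <- pmax(win[mask] - bg, 0)
    if (sum(wts) == 0) wts <- rep(1, areaPx)
    cx <- sum(gx[mask] * wts) / sum(wts)
    cy <- sum(gy[mask] * wts) / sum(wts)
    aperture <- own & (d2self <= (3.5 * sc[i])^2)
    integrated <- sum(win[aperture] - bg)
    rows[[length(rows) + 1L]] <- data.frame(
      axial_position_um = (cx - 0.5) * pixelSizeUm,
      y_um = (cy - 0.5) * pixelSizeUm,
      radius_um = sqrt(areaPx / pi) * pixelSizeUm,
      size_um2 = areaPx * pixelSizeUm^2,
      integrated_intensity = max(integrated, peak),
      peak_intensity = peak)
  }
  if (!length(rows))
    return(data.frame(axial_position_um = numeric(0), y_um = numeric(0),
                      radius_um = numeric(0), size_um2 = numeric(0),
                      integrated_intensity = numeric(0),
                      peak_intensity = numeric(0),
                      interpunctal_intensity = numeric(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$axial_position_um), , drop = FALSE]
  rownames(out) <- NULL
  # interpunctal (between-puncta) intensity at gap midpoints
  m <- nrow(out)
  gapI <- rep(NA_real_, m)
  if (m > 1L) {
    globalBg <- stats::median(image)
    for (k in seq_len(m - 1L)) {
      mx <- round((out$axial_position_um[k] + out$axial_position_um[k + 1L]) /
                    (2 * pixelSizeUm) + 0.5)
      my <- round((out$y_um[k] + out$y_um[k + 1L]) / (2 * pixelSizeUm) + 0.5)
      mx <- min(max(mx, 2L), W - 1L); my <- min(max(my, 2L), H - 1L)
      gapI[k] <- max(mean(image[(my - 1L):(my + 1L), (mx - 1L):(mx + 1L)]) -
                       globalBg, 0)
    }
  }
  out$interpunctal_intensity <- gapI
  out
}

#' Run the full detection pipeline on one image
#'
#' Candidate detection, SVM pruning and segmentation in one call.
#'
#' @param image numeric matrix.
#' @param model a \code{punctaClassifier} (from \code{\link{trainClassifier}}),
#'   or \code{NULL} to skip the pruning stage (all candidates kept).
#' @param pixelSizeUm pixel size in micrometres.
#' @param ... passed to \code{\link{detectCandidates}}.
#' @return puncta record data.frame as in \code{\link{segmentPuncta}}.
#' @export
detectPuncta <- function(image, model, pixelSizeUm, ...) {
  cand <- detectCandidates(image, ...)
  acc <- if (is.null(model)) cand else classifyCandidates(model, cand)
  segmentPuncta(image, acc, pixelSizeUm)
}
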