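#' Build the average-worm schematic specification
#'
#' Condenses a population's puncta statistics into the glyph list of its
#' "average worm": the rounded mean puncta count n, with the i-th glyph's
#' size and intensity taken at quantile (n - i + 1/2) / n of the
#' population's punctum size and intensity distributions (so glyphs run
#' largest to smallest and brightest to dimmest), spaced at the mean
#' interpunctal distance. The quantile functions are linear interpolations
#' of the population's averaged per-animal percentile features.
#'
#' @param summary one genotype's rendering summary: an element of the
#'   \code{rendering} list of \code{\link{zscorePopulationProfiles}}.
#' @return an object of class \code{averageWormSpec}: list with
#'   \code{genotype}, \code{n}, \code{sizes_um2} and \code{intensities}
#'   (both nonincreasing), \code{spacing_um},
#'   \code{posterior_position_um}.
#' @export
buildAverageWorm <- function(summary) {
  stopifnot(is.list(summary), !is.null(summary$meanCount))
  n <- round(summary$meanCount)
  if (n < 1) stop("rounded mean puncta count is ", n, "; cannot build schematic")
  p <- (n - seq_len(n) + 0.5) / n          # descending quantiles
  qs <- function(tab, pp) stats::approx(tab$p, tab$q, xout = pp, rule = 2)$y
  spec <- list(genotype = summary$genotype, n = n,
               sizes_um2 = qs(summary$sizeQuantiles, p),
               intensities = qs(summary$intensityQuantiles, p),
               spacing_um = summary$meanSpacingUm,
               posterior_position_um = summary$posteriorPositionUm)
  stopifnot(all(diff(spec$sizes_um2) <= 1e-9),
            all(diff(spec$intensities) <= 1e-9))
  class(spec) <- "averageWormSpec"
  spec
}

#' @export
print.averageWormSpec <- function(x, ...) {
  cat(sprintf("averageWormSpec: %s, %d glyphs, spacing %.2f um\n",
              x$genotype, x$n, x$spacing_um))
  invisible(x)
}

#' Render an average-worm schematic as SVG
#'
#' Draws the glyphs as circles on a horizontal axis at mean-spacing
#' intervals; radius is proportional to the square root of glyph size (so
#' the drawn area tracks the punctum area) and fill colour maps intensity
#' from dim (dark blue) to bright (yellow). Output is a pure function of the
#' spec: the same spec always yields byte-identical SVG. A degenerate
#' intensity range renders in a single colour.
#'
#' @param spec an \code{averageWormSpec}.
#' @param pxPerUm drawing scale, pixels per micrometre.
#' @param path optional output file.
#' @return the SVG document as a character scalar (invisibly when written).
#' @export
renderAverageWorm <- function(spec, pxPerUm = 12, path = NULL) {
  stopifnot(inherits(spec, "averageWormSpec"))
  n <- spec$n
  ramp <- grDevices::colorRamp(c("#1B2A75", "#2E86AB", "#F6D55C"))
  irange <- range(spec$intensities)
  rel <- if (diff(irange) > 0)
    (spec$intensities - irange[1L]) / diff(irange) else rep(1, n)
  cols <- grDevices::rgb(ramp(rel), maxColorValue = 255)
  maxR <- max(sqrt(spec$sizes_um2 / pi)) * pxPerUm
  dx <- spec$spacing_um * pxPerUm
  margin <- maxR + 10
  wd <- 2 * margin + (n - 1) * dx
  ht <- 2 * margin + 30
  cy <- margin + 15
  circ <- vapply(seq_len(n), function(i) {
    sprintf('  <circle cx="%.3f" cy="%.3f" r="%.3f" fill="%s"/>',
            margin + (i - 1) * dx, cy,
            sqrt(spec$sizes_um2[i] / pi) * pxPerUm, cols[i])
  }, character(1))
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f">',
                   ceiling(wd), ceiling(ht)),
           sprintf('  <title>average worm: %s</title>', spec$genotype),
           sprintf('  <line x1="%.3f" y1="%.3f" x2="%.3f" y2="%.3f" stroke="#888" stroke-width="1"/>',
                   margin - maxR, cy, wd - margin + maxR, cy),
           circ,
           sprintf('  <text x="%.3f" y="%.3f" font-family="sans-serif" font-size="12">%s (n=%d, spacing %.2f um)</text>',
                   margin - maxR, ht - 6, spec$genotype, n, spec$spacing_um),
           '</svg>')
  doc <- paste0(paste(svg, collapse = "\n"), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    writeBin(charToRaw(doc), con)
    close(con)
    return(invisible(doc))
  }
  doc
}

#' Per-category z-magnitude summary of a population
#'
#' Aggregates a genotype's mean z-profile into the registry's six feature
#' categories (mean absolute z per category), a compact view of which aspect
#' of the phenotype - counts, sizes, intensities, spatial arrangement,
#' regional distribution or variability - is most altered.
#'
#' @param summaries a \code{PopulationSummaries}.
#' @param genotype genotype label (row of the z-matrix).
#' @return data.frame with columns \code{category}, \code{mean_abs_z},
#'   \code{n_features}.
#' @export
categoryZSummary <- function(summaries, genotype) {
  stopifnot(inherits(summaries, "PopulationSummaries"))
  z <- summaries$zMatrix[genotype, ]
  cat <- featureRegistry()$category[summaries$keptFeatures]
  agg <- tapply(abs(z), cat, mean)
  data.frame(category = names(agg), mean_abs_z = as.numeric(agg),
             n_features = as.integer(table(cat)[names(agg)]),
             row.names = NULL)
}
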