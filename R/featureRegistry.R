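#' The canonical 76-feature phenotypic registry
#'
#' Returns the fixed table of descriptive metrics computed from one animal's
#' puncta. Each row documents one feature: its id (1..76, stable within a
#' major release), name, category (\code{count}, \code{size},
#' \code{intensity}, \code{spatial}, \code{regional}, \code{variability}),
#' units, and two behavioural flags used by the extraction invariants:
#' \code{absolute_position} marks features that change when the whole pattern
#' is translated along the axon (all others are translation invariant), and
#' \code{intensity_scaling} says whether the feature scales linearly with a
#' global rescaling of fluorescence intensities (\code{"linear"}) or is
#' dimensionless in intensity (\code{"invariant"}).
#'
#' Six ids carry fixed, externally meaningful names: 1 (number of puncta),
#' 21 (puncta intensity homogeneity), 33 (intensity of posterior puncta),
#' 52 (interpunctal intensity), 55 (10th percentile of integrated intensity)
#' and 75 (number of puncta in the top 75\% of size range). The remaining ids
#' are category-structured summary statistics of the same puncta quantities
#' (sizes, integrated and peak intensities, interpunctal spacings, axial
#' positions, anterior/posterior sub-domains); the registry is data, so an
#' alternative list can be swapped in without touching the extraction code.
#'
#' Conventions: percentiles use linear interpolation between order statistics;
#' "homogeneity"/"variability" features are coefficients of variation
#' (SD/mean, 0 for degenerate input); anterior/posterior halves split the
#' synaptic domain at its axial midpoint (anterior = positions at or before
#' the midpoint); "top p\% of range" bands are relative to the min-max span
#' of the quantity within the animal (a zero span puts every punctum in the
#' band); the interpunctal intensity of a gap is the background-subtracted
#' fluorescence at the gap midpoint.
#'
#' @return a \code{data.frame} with 76 rows and columns \code{id},
#'   \code{name}, \code{category}, \code{units}, \code{absolute_position},
#'   \code{intensity_scaling}.
#' @examples
#' reg <- featureRegistry()
#' nrow(reg)
#' reg$name[reg$id == 1]
#' @export
featureRegistry <- function() {
  f <- function(id, name, category, units, absolute = FALSE,
                scaling = "invariant") {
    data.frame(id = id, name = name, category = category, units = units,
               absolute_position = absolute, intensity_scaling = scaling,
               stringsAsFactors = FALSE)
  }
  reg <- rbind(
    f(1L,  "number of puncta",                          "count",       "count"),
    f(2L,  "synaptic domain length",                    "spatial",     "um"),
    f(3L,  "puncta density",                            "count",       "count/10um"),
    f(4L,  "number of anterior puncta",                 "regional",    "count"),
    f(5L,  "number of posterior puncta",                "regional",    "count"),
    f(6L,  "posterior/anterior count ratio",            "regional",    "ratio"),
    f(7L,  "count in top 25% of intensity range",       "count",       "count"),
    f(8L,  "fraction of puncta in top 50% of size range", "count",     "fraction"),
    f(9L,  "mean punctum size",                         "size",        "um2"),
    f(10L, "SD of punctum size",                        "size",        "um2"),
    f(11L, "CV of punctum size",                        "variability", "ratio"),
    f(12L, "min punctum size",                          "size",        "um2"),
    f(13L, "max punctum size",                          "size",        "um2"),
    f(14L, "10th percentile of punctum size",           "size",        "um2"),
    f(15L, "25th percentile of punctum size",           "size",        "um2"),
    f(16L, "median punctum size",                       "size",        "um2"),
    f(17L, "75th percentile of punctum size",           "size",        "um2"),
    f(18L, "90th percentile of punctum size",           "size",        "um2"),
    f(19L, "total punctum size",                        "size",        "um2"),
    f(20L, "punctum size range",                        "size",        "um2"),
    f(21L, "puncta intensity homogeneity",              "variability", "ratio"),
    f(22L, "mean integrated intensity",                 "intensity",   "a.u.", scaling = "linear"),
    f(23L, "SD of integrated intensity",                "intensity",   "a.u.", scaling = "linear"),
    f(24L, "min integrated intensity",                  "intensity",   "a.u.", scaling = "linear"),
    f(25L, "max integrated intensity",                  "intensity",   "a.u.", scaling = "linear"),
    f(26L, "total integrated intensity",                "intensity",   "a.u.", scaling = "linear"),
    f(27L, "median integrated intensity",               "intensity",   "a.u.", scaling = "linear"),
    f(28L, "25th percentile of integrated intensity",   "intensity",   "a.u.", scaling = "linear"),
    f(29L, "75th percentile of integrated intensity",   "intensity",   "a.u.", scaling = "linear"),
    f(30L, "90th percentile of integrated intensity",   "intensity",   "a.u.", scaling = "linear"),
    f(31L, "intensity of anterior puncta",              "regional",    "a.u.", scaling = "linear"),
    f(32L, "posterior/anterior intensity ratio",        "regional",    "ratio"),
    f(33L, "intensity of posterior puncta",             "regional",    "a.u.", scaling = "linear"),
    f(34L, "mean peak intensity",                       "intensity",   "a.u.", scaling = "linear"),
    f(35L, "SD of peak intensity",                      "intensity",   "a.u.", scaling = "linear"),
    f(36L, "CV of peak intensity",                      "variability", "ratio"),
    f(37L, "max peak intensity",                        "intensity",   "a.u.", scaling = "linear"),
    f(38L, "median peak intensity",                     "intensity",   "a.u.", scaling = "linear"),
    f(39L, "mean intensity per unit size",              "intensity",   "a.u./um2", scaling = "linear"),
    f(40L, "size-intensity correlation",                "variability", "ratio"),
    f(41L, "mean interpunctal distance",                "spatial",     "um"),
    f(42L, "SD of interpunctal distance",               "spatial",     "um"),
    f(43L, "CV of interpunctal distance",               "variability", "ratio"),
    f(44L, "min interpunctal distance",                 "spatial",     "um"),
    f(45L, "max interpunctal distance",                 "spatial",     "um"),
    f(46L, "median interpunctal distance",              "spatial",     "um"),
    f(47L, "90th percentile of interpunctal distance",  "spatial",     "um"),
    f(48L, "position of first punctum",                 "spatial",     "um", absolute = TRUE),
    f(49L, "position of most posterior punctum",        "spatial",     "um", absolute = TRUE),
    f(50L, "domain midpoint position",                  "spatial",     "um", absolute = TRUE),
    f(51L, "mean axial position",                       "spatial",     "um", absolute = TRUE),
    f(52L, "interpunctal intensity",                    "intensity",   "a.u.", scaling = "linear"),
    f(53L, "CV of interpunctal intensity",              "variability", "ratio"),
    f(54L, "max interpunctal intensity",                "intensity",   "a.u.", scaling = "linear"),
    f(55L, "10th percentile of integrated intensity",   "intensity",   "a.u.", scaling = "linear"),
    f(56L, "skewness of integrated intensity",          "variability", "ratio"),
    f(57L, "skewness of punctum size",                  "variability", "ratio"),
    f(58L, "mean size of anterior puncta",              "regional",    "um2"),
    f(59L, "mean size of posterior puncta",             "regional",    "um2"),
    f(60L, "posterior/anterior size ratio",             "regional",    "ratio"),
    f(61L, "domain length per punctum",                 "spatial",     "um"),
    f(62L, "intensity centroid offset",                 "regional",    "ratio"),
    f(63L, "fraction of intensity in posterior half",   "regional",    "fraction"),
    f(64L, "Gini coefficient of integrated intensity",  "variability", "ratio"),
    f(65L, "relative position of largest punctum",      "regional",    "fraction"),
    f(66L, "relative position of brightest punctum",    "regional",    "fraction"),
    f(67L, "lag-1 autocorrelation of intensity",        "variability", "ratio"),
    f(68L, "lag-1 autocorrelation of size",             "variability", "ratio"),
    f(69L, "mean neighbour size difference",            "variability", "um2"),
    f(70L, "mean neighbour intensity difference",       "intensity",   "a.u.", scaling = "linear"),
    f(71L, "count in top 50% of intensity range",       "count",       "count"),
    f(72L, "count in bottom 25% of size range",         "count",       "count"),
    f(73L, "fraction of domain covered by puncta",      "spatial",     "fraction"),
    f(74L, "mean punctum half-max radius",              "size",        "um"),
    f(75L, "number of puncta in the top 75% of size range", "count",   "count"),
    f(76L, "count of large and bright puncta",          "count",       "count")
  )
  rownames(reg) <- featureIds()
  reg
}

#' Feature column ids \code{f001..f076}
#' @return character vector of length 76.
#' @export
featureIds <- function() sprintf("f%03d", 1:76)
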