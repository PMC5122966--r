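#' Extract the 76-feature phenotypic profile of one animal
#'
#' Computes every feature of \code{\link{featureRegistry}} from an animal's
#' puncta records. Records are re-sorted by axial position internally, so the
#' result is invariant to input order. With fewer than 5 puncta the profile
#' is returned as all-\code{NA} with \code{qc_pass = FALSE} (several features
#' are not computable; see \code{\link{qcFilter}}).
#'
#' @param puncta data.frame of puncta records with columns
#'   \code{axial_position_um}, \code{size_um2}, \code{integrated_intensity},
#'   \code{peak_intensity}, and optionally \code{radius_um} (half-max radius;
#'   reconstructed from the area if absent) and \code{interpunctal_intensity}
#'   (background-subtracted intensity at the midpoint of the gap that follows
#'   each punctum, \code{NA} for the last; taken as 0 with a warning if
#'   absent).
#' @return a named numeric vector of length 76 (\code{f001..f076}) with
#'   attributes \code{n_puncta} and \code{qc_pass}.
#' @examples
#' pt <- data.frame(axial_position_um = 1:10, size_um2 = 0.8,
#'                  integrated_intensity = 100, peak_intensity = 60)
#' pr <- extractProfile(pt)
#' pr[["f001"]]  # number of puncta
#' pr[["f002"]]  # synaptic domain length (um)
#' @export
extractProfile <- function(puncta) {
  need <- c("axial_position_um", "size_um2", "integrated_intensity",
            "peak_intensity")
  miss <- setdiff(need, names(puncta))
  if (length(miss))
    stop("puncta table missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(puncta)
  v <- stats::setNames(rep(NA_real_, 76L), featureIds())
  if (n < 5L) {
    attr(v, "n_puncta") <- n
    attr(v, "qc_pass") <- FALSE
    return(v)
  }
  ord <- order(puncta$axial_position_um)
  puncta <- puncta[ord, , drop = FALSE]
  pos  <- puncta$axial_position_um
  size <- puncta$size_um2
  ii   <- puncta$integrated_intensity
  pk   <- puncta$peak_intensity
  if (!all(is.finite(c(pos, size, ii, pk))))
    stop("puncta records contain non-finite values")
  rad <- if ("radius_um" %in% names(puncta)) puncta$radius_um else sqrt(size / pi)
  if (!"interpunctal_intensity" %in% names(puncta)) {
    warning("no interpunctal_intensity column; interpunctal intensity features set to 0")
    gapI <- rep(0, n - 1L)
  } else {
    gapI <- puncta$interpunctal_intensity[ord][-n]
    gapI[!is.finite(gapI)] <- 0
  }

  gaps <- diff(pos)
  domain <- pos[n] - pos[1L]
  mid <- (pos[1L] + pos[n]) / 2
  ant <- pos <= mid
  post <- !ant
  # in a valid record set the first punctum is anterior and the last posterior;
  # guard the degenerate all-coincident case anyway
  meanOr0 <- function(x) if (length(x)) mean(x) else 0
  ratioOr0 <- function(a, b) if (b > 0) a / b else 0
  rangeBand <- function(x, lo) {  # fraction `lo` of the min-max span and up
    r <- max(x) - min(x)
    if (r == 0) rep(TRUE, length(x)) else x >= min(x) + lo * r
  }

  v["f001"] <- n
  v["f002"] <- domain
  v["f003"] <- ratioOr0(10 * n, domain)
  v["f004"] <- sum(ant)
  v["f005"] <- sum(post)
  v["f006"] <- ratioOr0(sum(post), sum(ant))
  v["f007"] <- sum(rangeBand(ii, 0.75))
  v["f008"] <- mean(rangeBand(size, 0.50))
  v["f009"] <- mean(size)
  v["f010"] <- stats::sd(size)
  v["f011"] <- cv(size)
  v["f012"] <- min(size)
  v["f013"] <- max(size)
  v["f014"] <- punctaQuantile(size, 0.10)
  v["f015"] <- punctaQuantile(size, 0.25)
  v["f016"] <- punctaQuantile(size, 0.50)
  v["f017"] <- punctaQuantile(size, 0.75)
  v["f018"] <- punctaQuantile(size, 0.90)
  v["f019"] <- sum(size)
  v["f020"] <- max(size) - min(size)
  v["f021"] <- cv(ii)
  v["f022"] <- mean(ii)
  v["f023"] <- stats::sd(ii)
  v["f024"] <- min(ii)
  v["f025"] <- max(ii)
  v["f026"] <- sum(ii)
  v["f027"] <- punctaQuantile(ii, 0.50)
  v["f028"] <- punctaQuantile(ii, 0.25)
  v["f029"] <- punctaQuantile(ii, 0.75)
  v["f030"] <- punctaQuantile(ii, 0.90)
  v["f031"] <- meanOr0(ii[ant])
  v["f032"] <- ratioOr0(meanOr0(ii[post]), meanOr0(ii[ant]))
  v["f033"] <- meanOr0(ii[post])
  v["f034"] <- mean(pk)
  v["f035"] <- stats::sd(pk)
  v["f036"] <- cv(pk)
  v["f037"] <- max(pk)
  v["f038"] <- punctaQuantile(pk, 0.50)
  v["f039"] <- mean(ii / size)
  v["f040"] <- safeCor(size, ii)
  v["f041"] <- mean(gaps)
  v["f042"] <- stats::sd(gaps)
  v["f043"] <- cv(gaps)
  v["f044"] <- min(gaps)
  v["f045"] <- max(gaps)
  v["f046"] <- punctaQuantile(gaps, 0.50)
  v["f047"] <- punctaQuantile(gaps, 0.90)
  v["f048"] <- pos[1L]
  v["f049"] <- pos[n]
  v["f050"] <- mid
  v["f051"] <- mean(pos)
  v["f052"] <- mean(gapI)
  v["f053"] <- cv(gapI)
  v["f054"] <- max(gapI)
  v["f055"] <- punctaQuantile(ii, 0.10)
  v["f056"] <- skewness(ii)
  v["f057"] <- skewness(size)
  v["f058"] <- meanOr0(size[ant])
  v["f059"] <- meanOr0(size[post])
  v["f060"] <- ratioOr0(meanOr0(size[post]), meanOr0(size[ant]))
  v["f061"] <- domain / n
  v["f062"] <- ratioOr0(sum(ii * pos) / sum(ii) - mid, domain)
  v["f063"] <- sum(ii[post]) / sum(ii)
  v["f064"] <- gini(ii)
  v["f065"] <- ratioOr0(pos[which.max(size)] - pos[1L], domain)
  v["f066"] <- ratioOr0(pos[which.max(ii)] - pos[1L], domain)
  v["f067"] <- lag1Autocor(ii)
  v["f068"] <- lag1Autocor(size)
  v["f069"] <- mean(abs(diff(size)))
  v["f070"] <- mean(abs(diff(ii)))
  v["f071"] <- sum(rangeBand(ii, 0.50))
  v["f072"] <- sum(size <= min(size) + 0.25 * (max(size) - min(size)))
  v["f073"] <- min(1, ratioOr0(sum(2 * rad), domain))
  v["f074"] <- mean(rad)
  v["f075"] <- sum(rangeBand(size, 0.25))
  v["f076"] <- sum(size > stats::median(size) & ii > stats::median(ii))

  attr(v, "n_puncta") <- n
  attr(v, "qc_pass") <- TRUE
  v
}

#' Extract profiles for a multi-animal puncta table
#'
#' Splits a combined puncta table by \code{animal_id}, extracts one profile
#' per animal and assembles a \code{\linkS4class{PhenotypeProfiles}} object
#' (including animals failing the <5-puncta rule, flagged
#' \code{qc_pass = FALSE}; apply \code{\link{qcFilter}} to drop them).
#'
#' @param puncta data.frame as in \code{\link{extractProfile}} plus columns
#'   \code{animal_id} and optionally \code{genotype}.
#' @param genotype fallback genotype label when the table has no
#'   \code{genotype} column.
#' @return a \code{\linkS4class{PhenotypeProfiles}} object.
#' @export
extractProfiles <- function(puncta, genotype = "unknown") {
  stopifnot("animal_id" %in% names(puncta))
  ids <- unique(puncta$animal_id)
  gt <- vapply(ids, function(a) {
    if ("genotype" %in% names(puncta))
      as.character(puncta$genotype[puncta$animal_id == a][1L])
    else genotype
  }, character(1))
  profs <- lapply(ids, function(a)
    extractProfile(puncta[puncta$animal_id == a, , drop = FALSE]))
  m <- vapply(profs, as.numeric, numeric(76L))
  PhenotypeProfiles(m, animal_id = as.character(ids), genotype = gt,
                    n_puncta = vapply(profs, attr, integer(1), "n_puncta"),
                    qc_pass = vapply(profs, attr, logical(1), "qc_pass"))
}
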