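#' Construct a PhenotypeProfiles container
#'
#' @param features numeric matrix of feature values, either 76 x nAnimals
#'   (features in rows) or nAnimals x 76; rows are (re)named
#'   \code{f001..f076}.
#' @param animal_id character vector of animal identifiers.
#' @param genotype character vector (recycled) of genotype labels.
#' @param n_puncta integer vector of per-animal puncta counts.
#' @param qc_pass logical vector; defaults to \code{n_puncta >= 5}.
#' @return a \code{\linkS4class{PhenotypeProfiles}} object.
#' @examples
#' m <- matrix(rnorm(76 * 3), nrow = 76)
#' pp <- PhenotypeProfiles(m, animal_id = paste0("a", 1:3),
#'                         genotype = "wild type", n_puncta = c(10L, 12L, 9L))
#' pp
#' @export
PhenotypeProfiles <- function(features, animal_id, genotype, n_puncta,
                              qc_pass = n_puncta >= 5L) {
  if (nrow(features) != 76L && ncol(features) == 76L) features <- t(features)
  stopifnot(nrow(features) == 76L)
  n <- ncol(features)
  rownames(features) <- featureIds()
  genotype <- rep_len(as.character(genotype), n)
  if (missing(animal_id)) animal_id <- sprintf("animal%04d", seq_len(n))
  colnames(features) <- animal_id
  cd <- S4Vectors::DataFrame(animal_id = as.character(animal_id),
                             genotype = genotype,
                             n_puncta = as.integer(n_puncta),
                             qc_pass = as.logical(qc_pass),
                             row.names = animal_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = features), colData = cd,
    rowData = S4Vectors::DataFrame(featureRegistry()))
  methods::new("PhenotypeProfiles", se)
}

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "PhenotypeProfiles", function(x)
  SummarizedExperiment::assay(x, "features"))

#' @rdname genotypes
#' @export
setMethod("genotypes", "PhenotypeProfiles", function(x)
  SummarizedExperiment::colData(x)$genotype)

#' @rdname nPuncta
#' @export
setMethod("nPuncta", "PhenotypeProfiles", function(x)
  SummarizedExperiment::colData(x)$n_puncta)

#' @rdname qcPass
#' @export
setMethod("qcPass", "PhenotypeProfiles", function(x)
  SummarizedExperiment::colData(x)$qc_pass)

setMethod("show", "PhenotypeProfiles", function(object) {
  g <- table(genotypes(object))
  cat("PhenotypeProfiles: 76 features x", ncol(object), "animals\n")
  cat("  genotypes:", paste(sprintf("%s (%d)", names(g), g), collapse = ", "), "\n")
  cat("  QC pass:", sum(qcPass(object)), "/", ncol(object), "\n")
})

#' Subset profiles by genotype
#'
#' @param x a \code{PhenotypeProfiles} object.
#' @param genotype one or more genotype labels to keep.
#' @return the subsetted \code{PhenotypeProfiles}.
#' @export
subsetGenotype <- function(x, genotype) {
  stopifnot(methods::is(x, "PhenotypeProfiles"))
  keep <- genotypes(x) %in% genotype
  if (!any(keep)) stop("no animals with genotype ", paste(genotype, collapse = "/"))
  x[, keep]
}

#' Apply the minimum-puncta QC filter
#'
#' Animals whose images carry fewer than \code{min_puncta} puncta are removed,
#' because several profile features (percentiles, spacing dispersion,
#' autocorrelations) are not computable on so few records; such animals are
#' also likely very small or defective in reporter expression. The exclusions
#' are returned as an attached log.
#'
#' @param profiles a \code{PhenotypeProfiles} object.
#' @param min_puncta minimum puncta count to retain an animal (default 5;
#'   an animal with exactly \code{min_puncta} is kept).
#' @return the filtered \code{PhenotypeProfiles}, with a data.frame of
#'   exclusions (\code{animal_id}, \code{genotype}, \code{n_puncta},
#'   \code{reason}) in \code{metadata(x)$qc_exclusions}.
#' @examples
#' m <- matrix(rnorm(76 * 2), nrow = 76)
#' pp <- PhenotypeProfiles(m, paste0("a", 1:2), "wt", n_puncta = c(4L, 9L))
#' qcFilter(pp)
#' @export
qcFilter <- function(profiles, min_puncta = 5L) {
  stopifnot(methods::is(profiles, "PhenotypeProfiles"))
  np <- nPuncta(profiles)
  drop <- np < min_puncta
  log <- data.frame(
    animal_id = SummarizedExperiment::colData(profiles)$animal_id[drop],
    genotype = genotypes(profiles)[drop],
    n_puncta = np[drop],
    reason = if (any(drop)) sprintf("fewer than %d puncta", min_puncta) else character(0),
    stringsAsFactors = FALSE)
  out <- profiles[, !drop]
  S4Vectors::metadata(out)$qc_exclusions <- log
  out
}
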