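#' @rdname scoreProfiles
#' @export
setGeneric("scoreProfiles", function(model, profiles, ...)
  standardGeneric("scoreProfiles"))

#' Feature matrix accessor
#' @param x a \code{PhenotypeProfiles} object.
#' @return numeric matrix, 76 features x animals.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Genotype labels accessor
#' @param x a \code{PhenotypeProfiles} object.
#' @return character vector, one label per animal.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' Per-animal puncta count accessor
#' @param x a \code{PhenotypeProfiles} object.
#' @return integer vector.
#' @export
setGeneric("nPuncta", function(x) standardGeneric("nPuncta"))

#' QC flag accessor
#' @param x a \code{PhenotypeProfiles} object.
#' @return logical vector, TRUE for animals passing QC.
#' @export
setGeneric("qcPass", function(x) standardGeneric("qcPass"))

#' Selected feature ids of a fitted model
#' @param object a fitted model.
#' @return integer vector of feature ids.
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' Deviance trace of a fitted model
#' @param object a fitted model.
#' @return numeric vector: null deviance, then deviance after each step.
#' @export
setGeneric("devianceTrace", function(object) standardGeneric("devianceTrace"))
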