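#' Read and write puncta tables as CSV
#'
#' Columns: \code{animal_id}, \code{axial_position_um}, \code{radius_um},
#' \code{size_um2}, \code{integrated_intensity}, \code{peak_intensity},
#' \code{interpunctal_intensity} (and any extras present). Axial positions
#' are micrometres from the anterior (image-left) edge.
#'
#' @param puncta data.frame of puncta records.
#' @param path CSV file path.
#' @return \code{readPunctaCsv}: the data.frame; \code{writePunctaCsv}: the
#'   path, invisibly.
#' @export
writePunctaCsv <- function(puncta, path) {
  utils::write.csv(puncta, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePunctaCsv
#' @export
readPunctaCsv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Read and write profile tables as CSV
#'
#' The CSV carries one row per animal with columns \code{animal_id},
#' \code{genotype}, \code{qc_pass}, \code{n_puncta}, \code{f001..f076}.
#'
#' @param profiles a \code{PhenotypeProfiles}.
#' @param path CSV file path.
#' @return \code{readProfilesCsv}: a \code{PhenotypeProfiles};
#'   \code{writeProfilesCsv}: the path, invisibly.
#' @export
writeProfilesCsv <- function(profiles, path) {
  stopifnot(methods::is(profiles, "PhenotypeProfiles"))
  df <- data.frame(animal_id = SummarizedExperiment::colData(profiles)$animal_id,
                   genotype = genotypes(profiles),
                   qc_pass = qcPass(profiles),
                   n_puncta = nPuncta(profiles),
                   t(featureMatrix(profiles)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfilesCsv
#' @export
readProfilesCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("animal_id", "genotype", "qc_pass", "n_puncta", featureIds())
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("profile CSV missing columns: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  PhenotypeProfiles(t(as.matrix(df[, featureIds()])),
                    animal_id = df$animal_id, genotype = df$genotype,
                    n_puncta = df$n_puncta, qc_pass = df$qc_pass)
}

#' Serialize a fitted phenotype model to JSON
#'
#' Stores labels, ordered selected feature ids, coefficients,
#' standardization, deviance trace, thresholds and metadata; the restored
#' model scores identically.
#'
#' @param model an \code{SWLRModel} or \code{BFModel}.
#' @param path JSON file path.
#' @return \code{writeModelJson}: the path invisibly;
#'   \code{readModelJson}: the model.
#' @export
writeModelJson <- function(model, path) {
  stopifnot(methods::is(model, "SWLRModel"))
  obj <- list(type = if (methods::is(model, "BFModel")) "BFModel" else "SWLRModel",
              mutant = model@mutantLabel, wt = model@wtLabel,
              features = model@features, coefficients = model@coefficients,
              center = model@center, scale = model@scale,
              deviance_trace = model@devianceTrace,
              p_enter = model@pEnter, p_remove = model@pRemove,
              n_mutant = model@nMutant, n_wt = model@nWt,
              ridge = model@ridge, separation = model@separation,
              seed = model@seed)
  if (methods::is(model, "BFModel")) {
    obj$training_auc <- model@trainingAuc
    obj$criterion <- model@criterion
  }
  # I(17) significant digits so coefficients reload to identical scores
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  num1 <- function(x) {  # "NA"/null (e.g. BF models have no p thresholds) -> NA
    if (is.null(x) || identical(x, "NA")) NA_real_ else as.numeric(x)
  }
  common <- list(mutantLabel = o$mutant, wtLabel = o$wt,
                 features = as.integer(o$features),
                 coefficients = as.numeric(o$coefficients),
                 center = as.numeric(o$center), scale = as.numeric(o$scale),
                 devianceTrace = as.numeric(o$deviance_trace),
                 pEnter = num1(o$p_enter), pRemove = num1(o$p_remove),
                 nMutant = as.integer(o$n_mutant), nWt = as.integer(o$n_wt),
                 ridge = as.numeric(o$ridge), separation = as.logical(o$separation),
                 seed = as.integer(o$seed))
  if (identical(o$type, "BFModel"))
    do.call(methods::new, c(list("BFModel"), common,
                            list(trainingAuc = as.numeric(o$training_auc),
                                 criterion = as.character(o$criterion))))
  else do.call(methods::new, c(list("SWLRModel"), common))
}

#' Write a probability matrix as CSV
#'
#' Rows are populations, columns models; self pairs are marked in a second
#' CSV written next to it with suffix \code{.self.csv}.
#'
#' @param pm a \code{\linkS4class{ProbabilityMatrix}}.
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
writeProbabilityMatrixCsv <- function(pm, path) {
  stopifnot(methods::is(pm, "ProbabilityMatrix"))
  utils::write.csv(data.frame(population = rownames(pm@probs), pm@probs,
                              check.names = FALSE), path, row.names = FALSE)
  utils::write.csv(data.frame(population = rownames(pm@selfPair), pm@selfPair,
                              check.names = FALSE),
                   sub("\\.csv$", ".self.csv", path), row.names = FALSE)
  invisible(path)
}

#' Write a phenotype distance matrix as CSV (with a weights sidecar JSON)
#'
#' @param dm a \code{\linkS4class{PhenotypeDistance}}.
#' @param path CSV file path; the weighting record goes to
#'   \code{<path>.meta.json}.
#' @return the path, invisibly.
#' @export
writeDistanceCsv <- function(dm, path) {
  stopifnot(methods::is(dm, "PhenotypeDistance"))
  utils::write.csv(data.frame(population = rownames(dm@distance), dm@distance,
                              check.names = FALSE), path, row.names = FALSE)
  jsonlite::write_json(list(method = dm@method, feature_ids = dm@featureIds,
                            weights = dm@weights),
                       paste0(path, ".meta.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Export a model-population network as GraphML
#'
#' @param graph an \pkg{igraph} graph (e.g. from
#'   \code{\link{bestPairNetwork}}).
#' @param path output file.
#' @return the path, invisibly.
#' @export
exportGraphML <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Export the feature registry as CSV
#'
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
writeRegistryCsv <- function(path) {
  utils::write.csv(featureRegistry(), path, row.names = FALSE)
  invisible(path)
}
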