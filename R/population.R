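#' Cross-model probability matrix
#'
#' Scores every population under every pairwise model: cell (p, m) is the
#' mean mutant-phenotype probability over the QC-passing animals of
#' population p under model m. The cell where a model meets its own training
#' mutant population is flagged as a self pair.
#'
#' @param models list of fitted \code{SWLRModel}/\code{BFModel} objects.
#' @param profiles a \code{PhenotypeProfiles} holding all populations.
#' @return a \code{\linkS4class{ProbabilityMatrix}}; rows are genotypes,
#'   columns the models' mutant labels.
#' @export
crossModelMatrix <- function(models, profiles) {
  stopifnot(length(models) >= 1L, methods::is(profiles, "PhenotypeProfiles"))
  x <- profiles[, qcPass(profiles)]
  g <- genotypes(x)
  pops <- unique(g)
  cols <- vapply(models, function(m) m@mutantLabel, character(1))
  probs <- matrix(NA_real_, length(pops), length(models),
                  dimnames = list(pops, cols))
  for (j in seq_along(models)) {
    p <- scoreProfiles(models[[j]], x)
    probs[, j] <- vapply(pops, function(pp) mean(p[g == pp]), numeric(1))
  }
  selfPair <- outer(pops, cols, "==")
  dimnames(selfPair) <- dimnames(probs)
  methods::new("ProbabilityMatrix", probs = probs, selfPair = selfPair)
}

setMethod("show", "ProbabilityMatrix", function(object) {
  cat("ProbabilityMatrix:", nrow(object@probs), "populations x",
      ncol(object@probs), "models\n")
  print(round(object@probs, 3))
})

#' Best model-population pair network
#'
#' For every model, finds the population it scores highest (excluding the
#' population the model was trained on) and draws a directed edge from the
#' model's own population node to that best-scoring population. Exact ties
#' produce one edge per tied population, flagged \code{tie = TRUE}.
#'
#' @param pm a \code{\linkS4class{ProbabilityMatrix}}.
#' @return an \pkg{igraph} directed graph whose vertices are populations and
#'   whose edges carry attributes \code{prob} and \code{tie}.
#' @export
bestPairNetwork <- function(pm) {
  stopifnot(methods::is(pm, "ProbabilityMatrix"))
  probs <- pm@probs
  if (anyNA(probs)) stop("probability matrix must be complete")
  edges <- NULL
  for (j in seq_len(ncol(probs))) {
    cand <- probs[, j]
    cand[pm@selfPair[, j]] <- -Inf
    best <- max(cand)
    hits <- which(cand == best)
    edges <- rbind(edges, data.frame(
      from = colnames(probs)[j], to = rownames(probs)[hits],
      prob = best, tie = length(hits) > 1L, stringsAsFactors = FALSE))
  }
  verts <- union(rownames(probs), colnames(probs))
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = verts))
}

#' Population summaries of z-scored profiles
#'
#' z-scores every feature over the pooled set of all QC-passing animals (all
#' genotypes together, so the z-scale is common), then averages within
#' genotype. Features that are constant over the pooled animals carry no
#' information and are dropped with a log. Alongside the mean z-vector, each
#' genotype's summary carries the distributional statistics needed to render
#' its average-worm schematic (puncta count, size and intensity quantile
#' functions assembled from the per-animal percentile features, mean
#' interpunctal spacing, most-posterior-punctum position).
#'
#' @param profiles a \code{PhenotypeProfiles} with >= 2 animals.
#' @param reference \code{"pooled"} (default) to z-score against all animals,
#'   or \code{"wildtype"} to use only the reference genotype's mean/SD.
#' @param wt wild-type label used when \code{reference = "wildtype"}.
#' @return an object of class \code{PopulationSummaries}: a list with
#'   \code{zMatrix} (genotypes x kept features), \code{keptFeatures}
#'   (integer ids), \code{droppedFeatures}, \code{correlation} (feature
#'   correlation over pooled animals), \code{nAnimals} (named vector) and
#'   \code{rendering} (per-genotype stats for the schematic).
#' @export
zscorePopulationProfiles <- function(profiles, reference = c("pooled", "wildtype"),
                                     wt = "wild type") {
  reference <- match.arg(reference)
  stopifnot(methods::is(profiles, "PhenotypeProfiles"))
  x <- profiles[, qcPass(profiles)]
  if (ncol(x) < 2L) stop("need at least 2 QC-passing animals")
  M <- t(featureMatrix(x))  # animals x 76
  g <- genotypes(x)
  ref <- if (reference == "pooled") rep(TRUE, nrow(M)) else g == wt
  if (!any(ref)) stop("no animals in the z-score reference group")
  mu <- colMeans(M[ref, , drop = FALSE])
  sdv <- apply(M[ref, , drop = FALSE], 2L, stats::sd)
  kept <- which(sdv > 0)
  if (!length(kept)) stop("all features are constant; nothing to z-score")
  dropped <- setdiff(1:76, kept)
  Z <- sweep(sweep(M[, kept, drop = FALSE], 2L, mu[kept], "-"),
             2L, sdv[kept], "/")
  pops <- unique(g)
  zMatrix <- do.call(rbind, lapply(pops, function(pp)
    colMeans(Z[g == pp, , drop = FALSE])))
  rownames(zMatrix) <- pops
  corr <- stats::cor(Z)
  fm <- featureMatrix(x)
  qfun <- function(minv, qs, maxv) {
    data.frame(p = c(0, 0.10, 0.25, 0.50, 0.75, 0.90, 1),
               q = c(minv, qs, maxv))
  }
  rendering <- lapply(pops, function(pp) {
    cols <- g == pp
    av <- rowMeans(fm[, cols, drop = FALSE])
    list(genotype = pp,
         meanCount = av[["f001"]],
         meanSpacingUm = av[["f041"]],
         posteriorPositionUm = av[["f049"]],
         sizeQuantiles = qfun(av[["f012"]],
                              av[c("f014", "f015", "f016", "f017", "f018")],
                              av[["f013"]]),
         intensityQuantiles = qfun(av[["f024"]],
                                   av[c("f055", "f028", "f027", "f029", "f030")],
                                   av[["f025"]]))
  })
  names(rendering) <- pops
  structure(list(zMatrix = zMatrix, keptFeatures = as.integer(kept),
                 droppedFeatures = as.integer(dropped), correlation = corr,
                 nAnimals = vapply(pops, function(pp) sum(g == pp), integer(1)),
                 reference = reference, rendering = rendering),
            class = "PopulationSummaries")
}

#' @export
print.PopulationSummaries <- function(x, ...) {
  cat("PopulationSummaries:", nrow(x$zMatrix), "populations,",
      length(x$keptFeatures), "features kept,",
      length(x$droppedFeatures), "dropped\n")
  invisible(x)
}

#' Correlation-weighted phenotype distance matrix
#'
#' Distance between two genotypes is a standardized Euclidean distance over
#' their mean z-profiles, with per-feature weights equal to the inverse of
#' the feature's summed absolute correlation with all features,
#' \code{w_j = 1 / sum_k |r_jk|}, normalized to sum to the number of
#' features. A block of mutually redundant features thus contributes roughly
#' like a single independent feature, so no phenotype aspect is
#' over-represented. Alternatives: \code{"mahalanobis"} uses the (ridge
#' pseudo-)inverse correlation matrix; \code{"none"} uses equal weights
#' (plain Euclidean on z-means).
#'
#' @param summaries a \code{PopulationSummaries} from
#'   \code{\link{zscorePopulationProfiles}}.
#' @param correlation optional feature correlation matrix overriding the one
#'   stored in \code{summaries}.
#' @param method weighting method.
#' @return a \code{\linkS4class{PhenotypeDistance}}.
#' @export
weightedDistanceMatrix <- function(summaries, correlation = NULL,
                                   method = c("invcorsum", "mahalanobis", "none")) {
  method <- match.arg(method)
  stopifnot(inherits(summaries, "PopulationSummaries"))
  Zm <- summaries$zMatrix
  p <- ncol(Zm)
  R <- correlation %||% summaries$correlation
  if (!is.null(R) && !all(dim(R) == p))
    stop("correlation matrix must be ", p, " x ", p)
  n <- nrow(Zm)
  D <- matrix(0, n, n, dimnames = list(rownames(Zm), rownames(Zm)))
  if (method == "mahalanobis") {
    Rinv <- solve(R + diag(1e-8, p))
    for (a in seq_len(n)) for (b in seq_len(n)) if (a < b) {
      dd <- Zm[a, ] - Zm[b, ]
      D[a, b] <- D[b, a] <- sqrt(max(drop(t(dd) %*% Rinv %*% dd), 0))
    }
    w <- rep(NA_real_, p)
  } else {
    w <- if (method == "none") rep(1, p) else 1 / colSums(abs(R))
    if (any(!is.finite(w))) stop("non-finite feature weights")
    w <- w * p / sum(w)
    for (a in seq_len(n)) for (b in seq_len(n)) if (a < b) {
      dd <- Zm[a, ] - Zm[b, ]
      D[a, b] <- D[b, a] <- sqrt(sum(w * dd^2))
    }
  }
  methods::new("PhenotypeDistance", distance = D, weights = unname(w),
               featureIds = summaries$keptFeatures, method = method)
}

setMethod("show", "PhenotypeDistance", function(object) {
  cat("PhenotypeDistance (", object@method, " weighting): ",
      nrow(object@distance), " populations\n", sep = "")
  print(round(object@distance, 3))
})

#' Hierarchical clustering of genotype phenotypes
#'
#' Agglomerative clustering of the correlation-weighted phenotype distances.
#'
#' @param distance a \code{\linkS4class{PhenotypeDistance}}.
#' @param linkage linkage method: \code{"average"} (default),
#'   \code{"complete"}, \code{"single"} or \code{"ward.D2"}.
#' @return an \code{hclust} object (merge heights are the linkage distances);
#'   convert with \code{ape::as.phylo} or export with
#'   \code{\link{exportNewick}}.
#' @export
hierarchicalCluster <- function(distance,
                                linkage = c("average", "complete", "single", "ward.D2")) {
  linkage <- match.arg(linkage)
  stopifnot(methods::is(distance, "PhenotypeDistance"))
  if (nrow(distance@distance) < 2L) stop("need at least 2 populations to cluster")
  stats::hclust(stats::as.dist(distance@distance), method = linkage)
}

#' Export a dendrogram as Newick
#'
#' @param hc an \code{hclust} from \code{\link{hierarchicalCluster}}.
#' @param path output file; when missing the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
exportNewick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
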