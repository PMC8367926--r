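#' Plot identifiers of an object
#' @param x an object holding plots
#' @return character vector of plot ids, in storage order
#' @export
setGeneric("plotIds", function(x) standardGeneric("plotIds"))

#' Species identifiers of an object
#' @param x an object holding species
#' @return character vector of species ids, in storage order
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' Metric tag of a dissimilarity-like object
#' @param x the object
#' @return character scalar
#' @export
setGeneric("metricTag", function(x) standardGeneric("metricTag"))

#' @rdname plotIds
#' @export
setMethod("plotIds", "CommunityTable", function(x) rownames(x@incidence))
#' @rdname plotIds
#' @export
setMethod("plotIds", "EnvironmentTable", function(x) rownames(x@values))
#' @rdname plotIds
#' @export
setMethod("plotIds", "PlotCoordinates", function(x) rownames(x@coords))
#' @rdname plotIds
#' @export
setMethod("plotIds", "DissimilarityMatrix", function(x) rownames(x@values))
#' @rdname plotIds
#' @export
setMethod("plotIds", "PCNMBasis", function(x) rownames(x@vectors))
#' @rdname plotIds
#' @export
setMethod("plotIds", "ValidatedDataset", function(x) plotIds(x@community))

#' @rdname speciesIds
#' @export
setMethod("speciesIds", "CommunityTable", function(x) colnames(x@incidence))
#' @rdname speciesIds
#' @export
setMethod("speciesIds", "ValidatedDataset", function(x) speciesIds(x@community))

#' @rdname metricTag
#' @export
setMethod("metricTag", "DissimilarityMatrix", function(x) x@metricTag)
#' @rdname metricTag
#' @export
setMethod("metricTag", "NullEnsemble", function(x) x@metricTag)
#' @rdname metricTag
#' @export
setMethod("metricTag", "SESMatrix", function(x) x@metricTag)

#' Incidence matrix of a community table
#' @param x a CommunityTable or ValidatedDataset
#' @return base numeric matrix of 0/1 (plots x species)
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))
#' @rdname incidence
#' @export
setMethod("incidence", "CommunityTable", function(x) x@incidence)
#' @rdname incidence
#' @export
setMethod("incidence", "ValidatedDataset", function(x) x@community@incidence)

#' Extract the numeric matrix from matrix-like S4 containers
#' @param x the object
#' @param ... unused
#' @export
setMethod("as.matrix", "DissimilarityMatrix", function(x, ...) x@values)
#' @rdname as.matrix-DissimilarityMatrix-method
#' @export
setMethod("as.matrix", "CommunityTable", function(x, ...) x@incidence)
#' @rdname as.matrix-DissimilarityMatrix-method
#' @export
setMethod("as.matrix", "EnvironmentTable", function(x, ...) x@values)
#' @rdname as.matrix-DissimilarityMatrix-method
#' @export
setMethod("as.matrix", "SESMatrix", function(x, ...) x@values)
#' @rdname as.matrix-DissimilarityMatrix-method
#' @export
setMethod("as.matrix", "PCNMBasis", function(x, ...) x@vectors)

#' Convert a DissimilarityMatrix to a stats dist object
#' @param m a DissimilarityMatrix
#' @return a \code{dist}
#' @export
asDist <- function(m) stats::as.dist(m@values)

#' Environment variable classes
#' @param x an EnvironmentTable
#' @return character vector (soil/climate/geomorphology) per column
#' @export
variableClasses <- function(x) {
  stopifnot(is(x, "EnvironmentTable"))
  stats::setNames(x@variableClass, colnames(x@values))
}

#' Scale classes of PCNM eigenvectors
#' @param x a PCNMBasis
#' @return character vector per eigenvector
#' @export
scaleClasses <- function(x) {
  stopifnot(is(x, "PCNMBasis"))
  stats::setNames(x@scaleClass, colnames(x@vectors))
}

#' Eigenvalues of an ordination or PCNM basis
#' @param x the object
#' @return numeric vector, descending
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))
#' @rdname eigenValues
#' @export
setMethod("eigenValues", "PCNMBasis", function(x) x@eigenvalues)
#' @rdname eigenValues
#' @export
setMethod("eigenValues", "OrdinationResult", function(x) x@eigenvalues)

#' Site scores of an ordination
#' @param x an OrdinationResult
#' @return plots x axes matrix
#' @export
ordScores <- function(x) {
  stopifnot(is(x, "OrdinationResult"))
  x@scores
}

#' Explained variation of a constrained ordination
#' @param x an OrdinationResult
#' @return named numeric with r2 and adjR2
#' @export
explainedVariation <- function(x) {
  stopifnot(is(x, "OrdinationResult"))
  c(r2 = x@r2, adjR2 = x@adjR2)
}

#' Fractions of a variance partition
#' @param x a VariancePartition
#' @param clamp clamp negative fractions to zero for presentation
#'   (renormalizing nothing; the residual is left as computed)
#' @return named numeric of Venn-cell fractions plus residual
#' @export
partitionFractions <- function(x, clamp = FALSE) {
  stopifnot(is(x, "VariancePartition"))
  f <- x@fractions
  if (clamp) f[names(f) != "Residual"] <- pmax(f[names(f) != "Residual"], 0)
  f
}

setMethod("show", "CommunityTable", function(object) {
  m <- object@incidence
  cat(sprintf("CommunityTable: %d plots x %d species (%d presences)\n",
              nrow(m), ncol(m), sum(m)))
  cat(sprintf("  richness: %d-%d (median %g)\n",
              min(rowSums(m)), max(rowSums(m)), stats::median(rowSums(m))))
})

setMethod("show", "EnvironmentTable", function(object) {
  cat(sprintf("EnvironmentTable: %d plots x %d variables (%s)\n",
              nrow(object@values), ncol(object@values),
              paste(sprintf("%s: %d", names(table(object@variableClass)),
                            as.integer(table(object@variableClass))), collapse = ", ")))
})

setMethod("show", "DissimilarityMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat(sprintf("DissimilarityMatrix '%s': %d plots; range [%.4g, %.4g]\n",
              object@metricTag, nrow(object@values),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

setMethod("show", "ValidatedDataset", function(object) {
  cat("ValidatedDataset\n")
  cat(sprintf("  community : %d plots x %d species\n",
              nrow(object@community@incidence), ncol(object@community@incidence)))
  cat(sprintf("  phylogeny : %d tips, %d internal nodes\n",
              length(object@phylogeny$tip.label), object@phylogeny$Nnode))
  cat(sprintf("  environment: %d variables; dropped species: %d\n",
              ncol(object@environment@values), length(object@droppedSpecies)))
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf("NullEnsemble '%s': %d iterations, %d plots\n",
              object@metricTag, object@nIterations, nrow(object@observed)))
})

setMethod("show", "SESMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat(sprintf("SESMatrix '%s' (%s)\n", object@metricTag, object@signConvention))
  cat(sprintf("  mean SES %.3f; %.1f%% of pairs outside +/-1.96\n",
              mean(v, na.rm = TRUE), 100 * mean(abs(v) > 1.96, na.rm = TRUE)))
})

setMethod("show", "PCNMBasis", function(object) {
  cat(sprintf("PCNMBasis: %d eigenvectors over %d plots (threshold %.3g km)\n",
              ncol(object@vectors), nrow(object@vectors), object@threshold))
  if (any(nzchar(object@scaleClass)))
    cat(sprintf("  scale classes: %s\n",
                paste(sprintf("%s: %d", names(table(object@scaleClass)),
                              as.integer(table(object@scaleClass))), collapse = ", ")))
})

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult (%s): %d axes\n", object@method, ncol(object@scores)))
  if (!is.na(object@r2))
    cat(sprintf("  R2 = %.4f, adjusted R2 = %.4f\n", object@r2, object@adjR2))
  if (!is.na(object@stress))
    cat(sprintf("  stress = %.5f\n", object@stress))
})

setMethod("show", "SelectionTrace", function(object) {
  if (!length(object@selected)) {
    cat(sprintf("SelectionTrace: nothing selected (global p = %.4g, cap = %.4g)\n",
                object@globalP, object@cap))
  } else {
    cat(sprintf("SelectionTrace: %d selected (global p = %.4g, cap = %.4g)\n",
                length(object@selected), object@globalP, object@cap))
    print(data.frame(variable = object@selected, F = object@stepF,
                     p = object@stepP, cumAdjR2 = object@cumAdjR2))
  }
})

setMethod("show", "VariancePartition", function(object) {
  cat(sprintf("VariancePartition over {%s} (joint adjR2 = %.4f)\n",
              paste(object@setNames, collapse = ", "), object@adjR2Full))
  print(data.frame(fraction = names(object@fractions), value = object@fractions,
                   p = object@pvalues, row.names = NULL))
})

setMethod("show", "SyntheticDataset", function(object) {
  callNextMethod()
  cat(sprintf("  synthetic: w = %g, dispersal = %g km, seed = %s\n",
              object@params$filterStrength, object@params$dispersalScale,
              as.character(object@params$seed)))
})
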