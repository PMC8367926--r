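#' @import methods
#' @importFrom Matrix sparseMatrix
#' @importFrom stats cor sd var dist rnorm runif cmdscale quantile
#' @importFrom utils read.csv write.csv head
NULL

setOldClass("phylo")

#' CommunityTable: plot-by-species incidence matrix
#'
#' Stores presence/absence (0/1) of species across plots. Rows are plots,
#' columns species; row and column names carry the identifiers. Abundances
#' are collapsed to incidence at construction: every printed index in this
#' package is incidence-based.
#'
#' @slot incidence numeric matrix with entries in \{0,1\}, plot ids as
#'   rownames, species ids as colnames. Every plot must contain at least one
#'   species.
#' @export
setClass("CommunityTable", representation(incidence = "matrix"))

setValidity("CommunityTable", function(object) {
  m <- object@incidence
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "incidence must have plot rownames and species colnames")
  if (anyDuplicated(rownames(m)))
    msg <- c(msg, sprintf("duplicated plot ids: %s",
                          paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")))
  if (anyDuplicated(colnames(m)))
    msg <- c(msg, sprintf("duplicated species ids: %s",
                          paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")))
  if (!all(m %in% c(0, 1)))
    msg <- c(msg, "incidence entries must be 0 or 1")
  else if (nrow(m) > 0 && any(rowSums(m) < 1))
    msg <- c(msg, sprintf("plots with no species: %s",
                          paste(rownames(m)[rowSums(m) < 1], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' EnvironmentTable: plot-by-variable environmental data
#'
#' @slot values numeric matrix (plots x variables), no missing values.
#' @slot variableClass character, one of "soil", "climate", "geomorphology"
#'   per column.
#' @slot transformApplied character per column, one of "none", "sqrt",
#'   "cubed"; records that the pre-analysis transform has been applied at
#'   most once.
#' @export
setClass("EnvironmentTable",
         representation(values = "matrix", variableClass = "character",
                        transformApplied = "character"))

setValidity("EnvironmentTable", function(object) {
  m <- object@values
  msg <- character()
  if (is.null(rownames(m)) || is.null(colnames(m)))
    msg <- c(msg, "values must have plot rownames and variable colnames")
  if (anyNA(m)) msg <- c(msg, "missing values in environment table")
  if (length(object@variableClass) != ncol(m))
    msg <- c(msg, "variableClass must label every column")
  if (!all(object@variableClass %in% c("soil", "climate", "geomorphology")))
    msg <- c(msg, "variableClass entries must be soil/climate/geomorphology")
  if (length(object@transformApplied) != ncol(m) ||
      !all(object@transformApplied %in% c("none", "sqrt", "cubed")))
    msg <- c(msg, "transformApplied must be none/sqrt/cubed per column")
  if (length(msg)) msg else TRUE
})

#' PlotCoordinates: projected planar plot locations (km)
#'
#' @slot coords numeric matrix with columns x and y in km, plot ids as
#'   rownames. Coordinates must be finite.
#' @export
setClass("PlotCoordinates", representation(coords = "matrix"))

setValidity("PlotCoordinates", function(object) {
  m <- object@coords
  msg <- character()
  if (is.null(rownames(m))) msg <- c(msg, "coords must have plot rownames")
  if (ncol(m) != 2 || !identical(colnames(m), c("x", "y")))
    msg <- c(msg, "coords must have exactly columns x and y")
  if (!all(is.finite(m))) msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' DissimilarityMatrix: symmetric plot-by-plot dissimilarities
#'
#' @slot values symmetric numeric matrix with zero diagonal, plot ids as
#'   dimnames. Sorensen-family metrics are bounded in [0,1]; SES and
#'   geographic tags are unbounded.
#' @slot metricTag character scalar naming the index that produced the
#'   matrix.
#' @export
setClass("DissimilarityMatrix",
         representation(values = "matrix", metricTag = "character"))

setValidity("DissimilarityMatrix", function(object) {
  m <- object@values
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    msg <- c(msg, "dimnames must be identical plot ids")
  if (length(object@metricTag) != 1) msg <- c(msg, "metricTag must be scalar")
  ok <- is.finite(m)
  if (any(abs(m[ok] - t(m)[ok]) > 1e-10)) msg <- c(msg, "matrix must be symmetric")
  if (any(abs(diag(m)) > 1e-12, na.rm = TRUE)) msg <- c(msg, "diagonal must be zero")
  if (grepl("^(sorensen|phylosor)", object@metricTag) &&
      any(m[ok] < -1e-12 | m[ok] > 1 + 1e-12))
    msg <- c(msg, "Sorensen-family dissimilarities must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' ValidatedDataset: aligned community, phylogeny, environment, coordinates
#'
#' All components share an identical, identically ordered plot id vector and
#' every community species is a tip of the phylogeny (species missing from
#' the tree having been dropped or rejected at validation).
#'
#' @slot community a \linkS4class{CommunityTable}
#' @slot phylogeny an \code{ape} \code{phylo} tree
#' @slot environment an \linkS4class{EnvironmentTable}
#' @slot coordinates a \linkS4class{PlotCoordinates}
#' @slot droppedSpecies character, species removed because absent from the
#'   phylogeny
#' @export
setClass("ValidatedDataset",
         representation(community = "CommunityTable", phylogeny = "phylo",
                        environment = "EnvironmentTable",
                        coordinates = "PlotCoordinates",
                        droppedSpecies = "character"))

setValidity("ValidatedDataset", function(object) {
  msg <- character()
  p <- rownames(object@community@incidence)
  if (!identical(p, rownames(object@environment@values)) ||
      !identical(p, rownames(object@coordinates@coords)))
    msg <- c(msg, "plot ids differ across components")
  sp <- colnames(object@community@incidence)
  missing <- setdiff(sp, object@phylogeny$tip.label)
  if (length(missing))
    msg <- c(msg, sprintf("community species not in phylogeny: %s",
                          paste(head(missing, 5), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SyntheticDataset: a ValidatedDataset with simulation ground truth
#'
#' @slot nicheOptima species x niche-axis matrix of true niche optima
#' @slot seedSources species x 2 matrix of seed-source locations (km)
#' @slot params the \code{simulationParams} list that generated the data
#' @export
setClass("SyntheticDataset", contains = "ValidatedDataset",
         representation(nicheOptima = "matrix", seedSources = "matrix",
                        params = "list"))

#' NullEnsemble: per-pair null distribution summary for a beta metric
#'
#' @slot metricTag metric the ensemble was built for
#' @slot nIterations number of randomizations
#' @slot observed observed pairwise dissimilarity matrix
#' @slot nullMean,nullSd per-pair null mean and standard deviation
#' @slot draws optional array (pair draws retained when requested)
#' @slot seed RNG seed recorded for reproducibility (NA if none supplied)
#' @export
setClass("NullEnsemble",
         representation(metricTag = "character", nIterations = "integer",
                        observed = "matrix", nullMean = "matrix",
                        nullSd = "matrix", draws = "array", seed = "integer"))

setValidity("NullEnsemble", function(object) {
  msg <- character()
  if (object@nIterations < 2L) msg <- c(msg, "nIterations must be >= 2")
  if (any(object@nullSd < 0, na.rm = TRUE)) msg <- c(msg, "null sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SESMatrix: standardized effect sizes for a between-community metric
#'
#' Sign convention follows the study's inverted reading of Webb's indices:
#' positive values indicate phylogenetic evenness (observed exceeds the null
#' mean), negative values phylogenetic clustering. This is the raw
#' (observed - null mean)/null sd, i.e. -1 times Webb's NRI/NTI.
#'
#' @slot values symmetric SES matrix (diagonal NA: no information)
#' @slot metricTag one of "betaNRI", "betaNTI", or an SES-turnover tag
#' @slot nullMean,nullSd the null summaries the SES was computed from
#' @slot signConvention fixed string documenting the orientation
#' @export
setClass("SESMatrix",
         representation(values = "matrix", metricTag = "character",
                        nullMean = "matrix", nullSd = "matrix",
                        signConvention = "character"))

#' PCNMBasis: spatial eigenfunctions of the truncated distance matrix
#'
#' @slot vectors plot x k matrix of eigenvectors (unit norm), positive
#'   eigenvalues only, ordered by decreasing eigenvalue
#' @slot eigenvalues the k positive eigenvalues, descending
#' @slot threshold truncation distance t (km); distances beyond t were
#'   replaced by 4t before decomposition
#' @slot wavelength characteristic wavelength (km) per eigenvector,
#'   estimated along the minimum-spanning-tree path ordering
#' @slot scaleClass "broad", "mid" or "fine" per eigenvector ("" before
#'   classification)
#' @export
setClass("PCNMBasis",
         representation(vectors = "matrix", eigenvalues = "numeric",
                        threshold = "numeric", wavelength = "numeric",
                        scaleClass = "character"))

setValidity("PCNMBasis", function(object) {
  msg <- character()
  k <- ncol(object@vectors)
  if (length(object@eigenvalues) != k) msg <- c(msg, "one eigenvalue per vector")
  if (any(object@eigenvalues <= 0)) msg <- c(msg, "eigenvalues must be positive")
  if (is.unsorted(rev(object@eigenvalues))) msg <- c(msg, "eigenvalues must be descending")
  if (k > nrow(object@vectors) - 1) msg <- c(msg, "k must be <= n_plots - 1")
  if (length(msg)) msg else TRUE
})

#' OrdinationResult: scores, eigenvalues and tests from an ordination
#'
#' A single container for PCA, NMDS, PCoA, RDA, db-RDA and partial RDA
#' output; slots that a given method does not produce hold NA.
#'
#' @slot method which ordination produced the result
#' @slot scores plot x axis score matrix
#' @slot eigenvalues per-axis eigenvalues (descending; empty for NMDS)
#' @slot proportion,cumulative per-axis explained proportion and its
#'   cumulative sum
#' @slot axisF,axisP per-axis pseudo-F and permutation p (constrained
#'   ordinations with nPerm > 0 only)
#' @slot r2,adjR2 overall explained variation and its Ezekiel adjustment
#' @slot biplot predictor scores (correlations of predictors with axes)
#' @slot stress Kruskal stress-1 (NMDS only)
#' @slot details method-specific extras (e.g. retained PCoA axes)
#' @export
setClass("OrdinationResult",
         representation(method = "character", scores = "matrix",
                        eigenvalues = "numeric", proportion = "numeric",
                        cumulative = "numeric", axisF = "numeric",
                        axisP = "numeric", r2 = "numeric", adjR2 = "numeric",
                        biplot = "matrix", stress = "numeric",
                        details = "list"),
         prototype(r2 = NA_real_, adjR2 = NA_real_, stress = NA_real_,
                   details = list()))

setValidity("OrdinationResult", function(object) {
  msg <- character()
  ev <- object@eigenvalues
  if (length(ev) && is.unsorted(rev(ev), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be descending")
  pr <- object@proportion
  if (length(pr) && any(pr < -1e-10 | pr > 1 + 1e-10))
    msg <- c(msg, "proportions must lie in [0,1]")
  cm <- object@cumulative
  if (length(cm) > 1 && any(diff(cm) < -1e-10))
    msg <- c(msg, "cumulative proportion must be non-decreasing")
  p <- object@axisP
  if (length(p) && any(!is.na(p) & (p <= 0 | p > 1)))
    msg <- c(msg, "permutation p-values must lie in (0,1]")
  if (length(msg)) msg else TRUE
})

#' SelectionTrace: the path taken by forward selection
#'
#' @slot selected variable names in order of entry (possibly empty)
#' @slot stepF,stepP per-step partial pseudo-F and permutation p
#' @slot cumAdjR2 cumulative adjusted R2 after each step
#' @slot cap adjusted R2 of the global (all-candidates) model; the
#'   cumulative adjusted R2 may not exceed it (second stopping rule)
#' @slot globalP permutation p of the global pre-test; selection only
#'   proceeds when globalP <= alpha
#' @slot alpha the per-step significance level used
#' @export
setClass("SelectionTrace",
         representation(selected = "character", stepF = "numeric",
                        stepP = "numeric", cumAdjR2 = "numeric",
                        cap = "numeric", globalP = "numeric",
                        alpha = "numeric"))

setValidity("SelectionTrace", function(object) {
  msg <- character()
  if (length(object@stepP) && any(object@stepP > object@alpha + 1e-12))
    msg <- c(msg, "every selected step must satisfy p <= alpha")
  cm <- object@cumAdjR2
  if (length(cm) > 1 && any(diff(cm) < -1e-10))
    msg <- c(msg, "cumulative adjusted R2 must be non-decreasing")
  if (length(cm) && max(cm) > object@cap + 1e-10)
    msg <- c(msg, "cumulative adjusted R2 may not exceed the global cap")
  if (length(msg)) msg else TRUE
})

#' VariancePartition: unique and shared explained-variation fractions
#'
#' Fractions are adjusted R2 of the Venn cells of up to four predictor
#' sets, obtained by inclusion-exclusion over all subset models. Negative
#' fractions are reported as computed (flagged), not clamped; a clamped
#' presentation view is available via \code{clampFractions}.
#'
#' @slot setNames names of the explanatory sets
#' @slot fractions named numeric: one entry per Venn cell (e.g. "Climate",
#'   "Climate and Soils"), plus "Residual"
#' @slot testable logical per fraction: TRUE where a permutation test is
#'   defined (unique fractions)
#' @slot pvalues permutation p per fraction (NA where untestable)
#' @slot adjR2Full adjusted R2 of the joint model over all sets
#' @export
setClass("VariancePartition",
         representation(setNames = "character", fractions = "numeric",
                        testable = "logical", pvalues = "numeric",
                        adjR2Full = "numeric"))

setValidity("VariancePartition", function(object) {
  msg <- character()
  if (abs(sum(object@fractions) - 1) > 1e-10)
    msg <- c(msg, "fractions plus residual must sum to 1")
  p <- object@pvalues
  if (any(!is.na(p) & (p <= 0 | p > 1)))
    msg <- c(msg, "p-values must lie in (0,1]")
  if (length(msg)) msg else TRUE
})
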