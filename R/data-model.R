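## Constructors and file I/O for the domain types. All readers are strict
## about identifier uniqueness; all writers round-trip exactly (12
## significant digits for real-valued matrices, exact integers for
## incidence).

#' Construct a CommunityTable from a numeric matrix
#'
#' Counts are collapsed to presence/absence: any value > 0 becomes 1. Row
#' names are plot ids, column names species ids.
#'
#' @param mat numeric matrix, plots x species, with dimnames
#' @return a \linkS4class{CommunityTable}
#' @export
communityTable <- function(mat) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("community matrix needs plot rownames and species colnames")
  storage.mode(mat) <- "double"
  if (anyNA(mat)) stop("community matrix contains missing values")
  inc <- (mat > 0) + 0
  dimnames(inc) <- dimnames(mat)
  new("CommunityTable", incidence = inc)
}

#' Construct an EnvironmentTable
#'
#' @param mat numeric matrix, plots x variables, with dimnames
#' @param variableClass character per column: soil/climate/geomorphology
#' @param transformApplied transform record per column (default "none")
#' @return an \linkS4class{EnvironmentTable}
#' @export
environmentTable <- function(mat, variableClass,
                             transformApplied = rep("none", ncol(mat))) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (!is.null(names(variableClass)))
    variableClass <- variableClass[colnames(mat)]
  new("EnvironmentTable", values = mat,
      variableClass = unname(variableClass),
      transformApplied = unname(transformApplied))
}

#' Construct PlotCoordinates
#'
#' @param x,y numeric vectors in projected km
#' @param plotIds plot identifiers
#' @return a \linkS4class{PlotCoordinates}
#' @export
plotCoordinates <- function(x, y, plotIds) {
  m <- cbind(x = as.numeric(x), y = as.numeric(y))
  rownames(m) <- plotIds
  new("PlotCoordinates", coords = m)
}

#' Convert decimal-degree coordinates to planar km
#'
#' Local equirectangular approximation about the centroid latitude: one
#' degree of latitude is taken as 111.32 km, one degree of longitude as
#' 111.32 x cos(latitude) km. Adequate for extents of a few degrees.
#'
#' @param lon,lat decimal degrees
#' @param plotIds plot identifiers
#' @return a \linkS4class{PlotCoordinates} in km
#' @export
degreesToKm <- function(lon, lat, plotIds) {
  lat0 <- mean(lat)
  x <- (lon - mean(lon)) * 111.32 * cos(lat0 * pi / 180)
  y <- (lat - lat0) * 111.32
  message("coordinates converted from decimal degrees by local equirectangular approximation")
  plotCoordinates(x, y, plotIds)
}

.sniffSep <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line)) "\t" else ","
}

#' Read a plot x species community table from CSV/TSV
#'
#' First column holds plot ids, header row species ids; cells numeric.
#' Counts are collapsed to incidence (> 0 becomes 1). The delimiter (comma
#' or tab) is sniffed from the first line.
#'
#' @param path file path
#' @return a \linkS4class{CommunityTable}
#' @export
readCommunityTable <- function(path) {
  sep <- .sniffSep(path)
  df <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicated plot ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  sp <- colnames(df)[-1]
  if (anyDuplicated(sp))
    stop(sprintf("duplicated species ids: %s",
                 paste(unique(sp[duplicated(sp)]), collapse = ", ")))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("community cells must be numeric")
  rownames(m) <- ids
  empty <- rownames(m)[rowSums(m > 0) < 1]
  if (length(empty))
    stop(sprintf("plots with no species: %s", paste(empty, collapse = ", ")))
  communityTable(m)
}

#' Write a community table as CSV
#' @param x a CommunityTable
#' @param path output path
#' @export
writeCommunityTable <- function(x, path) {
  df <- data.frame(plot = plotIds(x), x@incidence, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a newick file
#'
#' Wraps \code{ape::read.tree} and enforces the package's invariants:
#' branch lengths present and non-negative, unique tip labels. Polytomies
#' are allowed, including at the base: the outermost newick node is taken
#' as the root by convention. \code{midpointRoot} optionally re-roots the
#' tree at the midpoint of its longest tip-to-tip path instead.
#'
#' @param path newick file path
#' @param defaultBranchLength value substituted when the file omits branch
#'   lengths (NULL = error)
#' @param midpointRoot re-root at the midpoint of the longest path
#' @return an \code{ape} \code{phylo}
#' @export
readNewickTree <- function(path, defaultBranchLength = NULL, midpointRoot = FALSE) {
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop(sprintf("malformed newick in '%s': %s", path, conditionMessage(e))))
  if (is.null(tr)) stop(sprintf("malformed newick in '%s'", path))
  if (is.null(tr$edge.length)) {
    if (is.null(defaultBranchLength))
      stop("tree has no branch lengths (supply defaultBranchLength to impute)")
    tr$edge.length <- rep(defaultBranchLength, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    if (is.null(defaultBranchLength))
      stop("tree has missing branch lengths (supply defaultBranchLength to impute)")
    tr$edge.length[is.na(tr$edge.length)] <- defaultBranchLength
  }
  if (midpointRoot) {
    tr <- phangornFreeMidpoint(tr)
    message("tree re-rooted at the midpoint of its longest path")
  }
  checkPhylogeny(tr)
  message(sprintf("read phylogeny: %d tips, %d internal nodes",
                  length(tr$tip.label), tr$Nnode))
  tr
}

## midpoint rooting without extra dependencies: root on the midpoint of the
## longest tip-to-tip path
phangornFreeMidpoint <- function(tr) {
  d <- ape::cophenetic.phylo(tr)
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  ape::root(tr, outgroup = rownames(d)[ij[1]], resolve.root = TRUE)
}

#' Validate a phylogeny against the package invariants
#' @param tree an ape phylo
#' @return the tree, invisibly
#' @export
checkPhylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label))
    stop(sprintf("duplicated tip labels: %s",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")))
  invisible(tree)
}

#' Read an environment table plus its column-class sidecar
#'
#' @param path CSV with first column plot id
#' @param classMapPath JSON sidecar mapping variable name to class
#'   (soil/climate/geomorphology)
#' @return an \linkS4class{EnvironmentTable}
#' @export
readEnvironmentTable <- function(path, classMapPath) {
  sep <- .sniffSep(path)
  df <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  cmap <- unlist(jsonlite::read_json(classMapPath, simplifyVector = TRUE))
  missing <- setdiff(colnames(m), names(cmap))
  if (length(missing))
    stop(sprintf("variables without a class label: %s", paste(missing, collapse = ", ")))
  environmentTable(m, cmap[colnames(m)])
}

#' Write an environment table and its class-map sidecar
#' @param x an EnvironmentTable
#' @param path CSV path
#' @param classMapPath JSON sidecar path
#' @export
writeEnvironmentTable <- function(x, path, classMapPath) {
  df <- data.frame(plot = plotIds(x),
                   signif(x@values, 12), check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.list(variableClasses(x)), classMapPath, auto_unbox = TRUE)
  invisible(path)
}

#' Read plot coordinates (plot,x,y CSV; km)
#' @param path CSV path
#' @return a \linkS4class{PlotCoordinates}
#' @export
readCoordinates <- function(path) {
  df <- read.csv(path, sep = .sniffSep(path), stringsAsFactors = FALSE)
  plotCoordinates(df$x, df$y, as.character(df[[1]]))
}

#' Write plot coordinates
#' @param x a PlotCoordinates
#' @param path CSV path
#' @export
writeCoordinates <- function(x, path) {
  df <- data.frame(plot = plotIds(x), signif(x@coords, 12))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a DissimilarityMatrix as square CSV with a metric comment line
#' @param x a DissimilarityMatrix
#' @param path CSV path
#' @export
writeDissimilarityMatrix <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metric: %s", x@metricTag), con)
  df <- data.frame(plot = plotIds(x), signif(x@values, 12), check.names = FALSE)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a DissimilarityMatrix written by writeDissimilarityMatrix
#' @param path CSV path
#' @return a \linkS4class{DissimilarityMatrix}
#' @export
readDissimilarityMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  tag <- sub("^# metric:\\s*", "", first)
  df <- read.csv(path, skip = 1L, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  new("DissimilarityMatrix", values = m, metricTag = tag)
}

#' Align community, phylogeny, environment and coordinates into one dataset
#'
#' Plots are aligned by id across the three tabular components (order taken
#' from the community table). Community species absent from the phylogeny
#' are dropped with a warning (policy "drop", mirroring the exclusion of
#' unplaced morphospecies from the source network) or trigger an error
#' (policy "error").
#'
#' @param community a CommunityTable
#' @param phylogeny an ape phylo
#' @param environment an EnvironmentTable
#' @param coordinates a PlotCoordinates
#' @param onMissingTip "drop" or "error"
#' @return a \linkS4class{ValidatedDataset}; the count of dropped species is
#'   \code{length(x@droppedSpecies)}
#' @export
validateDataset <- function(community, phylogeny, environment, coordinates,
                            onMissingTip = c("drop", "error")) {
  onMissingTip <- match.arg(onMissingTip)
  checkPhylogeny(phylogeny)
  p0 <- plotIds(community)
  for (comp in list(environment, coordinates)) {
    pc <- plotIds(comp)
    if (!setequal(p0, pc)) {
      d <- union(setdiff(p0, pc), setdiff(pc, p0))
      stop(sprintf("plot id sets differ; symmetric difference: %s",
                   paste(d, collapse = ", ")))
    }
  }
  env <- new("EnvironmentTable", values = environment@values[p0, , drop = FALSE],
             variableClass = environment@variableClass,
             transformApplied = environment@transformApplied)
  coo <- new("PlotCoordinates", coords = coordinates@coords[p0, , drop = FALSE])
  missing <- setdiff(speciesIds(community), phylogeny$tip.label)
  inc <- community@incidence
  if (length(missing)) {
    if (onMissingTip == "error")
      stop(sprintf("species absent from the phylogeny: %s",
                   paste(missing, collapse = ", ")))
    inc <- inc[, setdiff(colnames(inc), missing), drop = FALSE]
    warning(sprintf("dropped %d species absent from the phylogeny", length(missing)))
    empty <- rownames(inc)[rowSums(inc) < 1]
    if (length(empty))
      stop(sprintf("plots left empty after dropping unplaced species: %s",
                   paste(empty, collapse = ", ")))
  }
  new("ValidatedDataset",
      community = new("CommunityTable", incidence = inc),
      phylogeny = phylogeny, environment = env, coordinates = coo,
      droppedSpecies = missing)
}

#' Apply the pre-analysis environmental transforms
#'
#' Soil and climate variables are square-root transformed (they are
#' measured on heterogeneous, non-negative scales, and the analysis should
#' not inherit those units). Geomorphology variables are z-standardized and
#' each standardized column is augmented with its cube as an additional
#' predictor column, giving the ordinations access to non-monotone
#' responses along geomorphological gradients.
#'
#' @param environment an EnvironmentTable with no transform applied yet
#' @return a transformed \linkS4class{EnvironmentTable}; geomorphology
#'   columns gain a companion "<name>_cubed" column
#' @export
applyTransforms <- function(environment) {
  stopifnot(is(environment, "EnvironmentTable"))
  if (any(environment@transformApplied != "none"))
    stop("transforms already applied")
  m <- environment@values
  cls <- environment@variableClass
  sc <- which(cls %in% c("soil", "climate"))
  if (length(sc)) {
    neg <- which(m[, sc, drop = FALSE] < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop(sprintf("negative %s value at plot %s, variable %s",
                   cls[sc[neg[1, 2]]], rownames(m)[neg[1, 1]],
                   colnames(m)[sc[neg[1, 2]]]))
    m[, sc] <- sqrt(m[, sc])
  }
  geo <- which(cls == "geomorphology")
  outM <- m
  outCls <- cls
  outTr <- ifelse(cls %in% c("soil", "climate"), "sqrt", "cubed")
  if (length(geo)) {
    z <- scale(m[, geo, drop = FALSE])
    z[is.nan(z)] <- 0  # constant column: standardized to zeros
    outM[, geo] <- z
    cub <- z^3
    colnames(cub) <- paste0(colnames(m)[geo], "_cubed")
    outM <- cbind(outM, cub)
    outCls <- c(outCls, rep("geomorphology", length(geo)))
    outTr <- c(outTr, rep("cubed", length(geo)))
  }
  environmentTable(outM, outCls, outTr)
}
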