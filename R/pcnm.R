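## PCNM spatial eigenfunctions.
##
## Construction: Euclidean plot distances; truncation threshold t = longest
## edge of the minimum spanning tree (the smallest t keeping the neighbour
## graph connected); distances beyond t replaced by 4t; Gower double
## centering of -d^2/2; eigenvectors with positive eigenvalues retained,
## unit-normed, in decreasing eigenvalue order. Each eigenvector is
## assigned a characteristic wavelength from its sign changes along the
## minimum-spanning-tree path ordering of the plots, and binned into
## broad / mid / fine scale classes by two wavelength cutoffs.

#' Euclidean geographic distances between plots (km)
#'
#' @param coordinates a PlotCoordinates (planar km)
#' @return a \linkS4class{DissimilarityMatrix} with tag "geographic_km".
#'   Duplicate locations are allowed (distance 0) with a warning.
#' @export
geographicDistances <- function(coordinates) {
  stopifnot(is(coordinates, "PlotCoordinates"))
  m <- as.matrix(dist(coordinates@coords))
  if (any(m[upper.tri(m)] == 0))
    warning("duplicate plot coordinates (zero geographic distance)")
  new("DissimilarityMatrix", values = m, metricTag = "geographic_km")
}

#' PCNM truncation threshold from a distance matrix
#'
#' The length of the longest edge of the minimum spanning tree of the
#' complete distance graph: the smallest truncation distance that keeps
#' all plots connected.
#'
#' @param distances a DissimilarityMatrix or numeric distance matrix
#' @return threshold in the distance units
#' @export
truncationThreshold <- function(distances) {
  m <- if (is(distances, "DissimilarityMatrix")) distances@values else as.matrix(distances)
  if (nrow(m) < 2) stop("need at least two plots")
  max(vegan::spantree(stats::as.dist(m))$dist)
}

## minimum spanning tree as an edge list (vegan::spantree links)
.mstEdges <- function(m) {
  st <- vegan::spantree(stats::as.dist(m))
  cbind(from = 2:nrow(m), to = st$kid, w = st$dist)
}

## order plots along the MST: depth-first traversal from one end of the
## tree "diameter" (farthest-from-farthest vertex), the natural transect
## ordering for elongated designs
.mstPathOrder <- function(m) {
  n <- nrow(m)
  if (n == 1) return(1L)
  e <- .mstEdges(m)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- c(adj[[e[k, 1]]], e[k, 2])
    adj[[e[k, 2]]] <- c(adj[[e[k, 2]]], e[k, 1])
  }
  bfsFar <- function(s) {
    seen <- rep(FALSE, n); dd <- rep(0, n)
    q <- s; seen[s] <- TRUE; ord <- integer(0)
    while (length(q)) {
      v <- q[1]; q <- q[-1]; ord <- c(ord, v)
      for (u in adj[[v]]) if (!seen[u]) {
        seen[u] <- TRUE; dd[u] <- dd[v] + m[v, u]; q <- c(q, u)
      }
    }
    list(far = which.max(dd), ord = ord)
  }
  start <- bfsFar(1L)$far
  ## depth-first from that end
  seen <- rep(FALSE, n)
  ord <- integer(0)
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v]) next
    seen[v] <- TRUE; ord <- c(ord, v)
    nb <- adj[[v]][!seen[adj[[v]]]]
    stack <- c(stack, nb[order(m[v, nb], decreasing = TRUE)])
  }
  ord
}

#' PCNM basis from plot coordinates
#'
#' @param coordinates a PlotCoordinates (>= 3 plots, not all identical)
#' @param threshold truncation distance t (km); default = longest MST edge.
#'   \code{Inf} disables truncation, reducing the construction to a
#'   classical PCoA of the raw distances.
#' @param fillFactor distances beyond t are replaced by fillFactor * t
#'   (canonical value 4)
#' @return a \linkS4class{PCNMBasis} (scale classes unset; see
#'   \code{\link{classifyScale}})
#' @export
pcnmBasis <- function(coordinates, threshold = NULL, fillFactor = 4) {
  stopifnot(is(coordinates, "PlotCoordinates"))
  m <- as.matrix(dist(coordinates@coords))
  n <- nrow(m)
  if (n < 3) stop("need at least 3 plots")
  if (all(m == 0)) stop("all coordinates identical")
  if (is.null(threshold)) threshold <- truncationThreshold(m)
  dmod <- m
  if (is.finite(threshold)) dmod[dmod > threshold] <- fillFactor * threshold
  G <- -0.5 * dmod^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  G <- (G + t(G)) / 2
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  keep <- which(eig$values > tol)
  nNeg <- sum(eig$values < -tol)
  if (nNeg) message(sprintf("%d negative-eigenvalue axes discarded", nNeg))
  if (!length(keep)) stop("no positive eigenvalues")
  vec <- eig$vectors[, keep, drop = FALSE]
  vec <- sweep(vec, 2, sqrt(colSums(vec^2)), "/")  # unit norm
  rownames(vec) <- rownames(m)
  colnames(vec) <- paste0("PCNM", seq_along(keep))
  ord <- .mstPathOrder(m)
  pathLen <- sum(m[cbind(ord[-n], ord[-1])])
  wl <- apply(vec, 2, function(v) {
    vz <- v[ord] - mean(v)
    s <- sign(vz)
    s <- s[s != 0]
    ncross <- sum(diff(s) != 0)
    if (ncross == 0) Inf else 2 * pathLen / ncross
  })
  new("PCNMBasis", vectors = vec, eigenvalues = eig$values[keep],
      threshold = threshold, wavelength = unname(wl),
      scaleClass = rep("", length(keep)))
}

#' Assign broad/mid/fine scale classes to PCNM eigenvectors
#'
#' Each eigenvector's characteristic wavelength (estimated along the MST
#' path ordering at construction) is binned by two cutoffs: wavelengths
#' strictly above \code{boundaries[1]} are "broad", above
#' \code{boundaries[2]} "mid", the rest "fine". The default cutoffs are
#' the geometric midpoints between the square roots of the 50, 5 and
#' 0.5 km2 reference areas for broad, mid and fine structure, i.e. about
#' 3.98 and 1.26 km.
#'
#' @param basis a PCNMBasis
#' @param boundaries two decreasing wavelength cutoffs (km)
#' @return the basis with \code{scaleClass} set (sign-flip invariant)
#' @export
classifyScale <- function(basis,
                          boundaries = c(sqrt(sqrt(50) * sqrt(5)),
                                         sqrt(sqrt(5) * sqrt(0.5)))) {
  stopifnot(is(basis, "PCNMBasis"))
  if (!ncol(basis@vectors)) stop("basis has no eigenvectors")
  if (length(boundaries) != 2 || boundaries[2] > boundaries[1])
    stop("boundaries must be two decreasing wavelength cutoffs")
  wl <- basis@wavelength
  basis@scaleClass <- ifelse(wl > boundaries[1], "broad",
                             ifelse(wl > boundaries[2], "mid", "fine"))
  basis
}

#' Write a PCNM basis (vectors + metadata)
#' @param basis a PCNMBasis
#' @param path CSV path for the eigenvectors; metadata (eigenvalue,
#'   wavelength, scale class) goes to \code{sub(".csv", "_meta.csv", path)}
#' @export
writePCNMBasis <- function(basis, path) {
  df <- data.frame(plot = rownames(basis@vectors), signif(basis@vectors, 12),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- data.frame(axis = colnames(basis@vectors),
                     eigenvalue = signif(basis@eigenvalues, 12),
                     wavelength = basis@wavelength,
                     scale_class = basis@scaleClass)
  write.csv(meta, sub("\\.csv$", "_meta.csv", path), row.names = FALSE, quote = FALSE)
  invisible(path)
}
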