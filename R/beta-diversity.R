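## Taxonomic and phylogenetic beta diversity.
##
## The pairwise workhorses are the Sorensen dissimilarity
##   beta_sor = (b + c) / (2a + b + c)
## and its Simpson-based turnover component
##   beta_sim = min(b,c) / (a + min(b,c)),
## with nestedness = beta_sor - beta_sim. The phylogenetic versions replace
## the species counts a, b, c by shared and unique branch lengths derived
## from root-inclusive Faith PD:
##   a_pd = PD_i + PD_j - PD_tot,  b_pd = PD_tot - PD_j,  c_pd = PD_tot - PD_i.
## A multiple-site Sorensen summary over all plots is exposed separately.

## edge x tip incidence of a tree: entry (e, s) = 1 iff tip s descends from
## edge e's child node. Sparse; computed once per tree and cached on call
## sites that loop.
.edgeTipIncidence <- function(tree) {
  nt <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(eo$edge))) {
    p <- eo$edge[k, 1L]
    ch <- eo$edge[k, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  child <- tree$edge[, 2L]
  lens <- lengths(desc[child])
  Matrix::sparseMatrix(i = rep(seq_len(ne), lens),
                       j = unlist(desc[child]),
                       x = 1, dims = c(ne, nt),
                       dimnames = list(NULL, tree$tip.label))
}

## plots x edges presence indicator given incidence aligned to tree tips
.plotEdgeMatrix <- function(inc, tree, E = NULL) {
  if (is.null(E)) E <- .edgeTipIncidence(tree)
  P <- inc[, colnames(E)[colnames(E) %in% colnames(inc)], drop = FALSE]
  full <- matrix(0, nrow(inc), ncol(E), dimnames = list(rownames(inc), colnames(E)))
  full[, colnames(P)] <- P
  B <- as.matrix(full %*% Matrix::t(E)) > 0
  storage.mode(B) <- "double"
  B
}

#' Pairwise species-set components a, b, c
#'
#' a = shared species, b = species only in plot i, c = species only in
#' plot j. Comparing a plot with itself yields b = c = 0.
#'
#' @param community a CommunityTable
#' @param i,j plot ids or indices
#' @return named numeric c(a, b, c)
#' @export
pairComponents <- function(community, i, j) {
  inc <- incidence(community)
  xi <- .plotRow(inc, i)
  xj <- .plotRow(inc, j)
  a <- sum(xi * xj)
  c(a = a, b = sum(xi) - a, c = sum(xj) - a)
}

.plotRow <- function(inc, i) {
  if (is.character(i) && !i %in% rownames(inc))
    stop(sprintf("unknown plot '%s'", i))
  if (is.numeric(i) && (i < 1 || i > nrow(inc)))
    stop(sprintf("unknown plot index %d", i))
  inc[i, ]
}

#' Sorensen total dissimilarity from pair components
#' @param pc named numeric with a, b, c (as from \code{pairComponents})
#' @return (b + c) / (2a + b + c), in [0,1]
#' @export
sorensenTotal <- function(pc) {
  denom <- 2 * pc[["a"]] + pc[["b"]] + pc[["c"]]
  if (denom == 0) stop("Sorensen undefined: both plots empty")
  (pc[["b"]] + pc[["c"]]) / denom
}

#' Simpson-based Sorensen turnover from pair components
#'
#' The replacement part of the Sorensen dissimilarity, insensitive to
#' richness difference: min(b,c) / (a + min(b,c)). The nestedness
#' component is \code{sorensenTotal(pc) - sorensenTurnover(pc)} and is
#' always non-negative.
#'
#' @param pc named numeric with a, b, c
#' @return turnover in [0,1]
#' @export
sorensenTurnover <- function(pc) {
  if (pc[["a"]] + pc[["b"]] + pc[["c"]] == 0)
    stop("turnover undefined: both plots empty")
  mn <- min(pc[["b"]], pc[["c"]])
  if (pc[["a"]] + mn == 0) {
    if (mn == 0) return(0)  # unreachable with non-empty plots
  }
  mn / (pc[["a"]] + mn)
}

#' Root-inclusive Faith's phylogenetic diversity of a tip set
#'
#' Sum of branch lengths of all edges on the union of root-to-tip paths of
#' the set. Root-inclusive: the PD of a single tip is its full root-to-tip
#' path length, which keeps shared branch length between any two non-empty
#' communities non-negative.
#'
#' @param tipSet character vector of tip labels (non-empty)
#' @param tree an ape phylo with branch lengths
#' @return numeric branch-length sum
#' @export
faithPD <- function(tipSet, tree) {
  if (!length(tipSet)) stop("tip set is empty")
  unknown <- setdiff(tipSet, tree$tip.label)
  if (length(unknown))
    stop(sprintf("unknown tips: %s", paste(unknown, collapse = ", ")))
  E <- .edgeTipIncidence(tree)
  ind <- as.numeric(colnames(E) %in% tipSet)
  sum(tree$edge.length[as.vector(E %*% ind) > 0])
}

#' Phylogenetic pair components for two plots
#'
#' @param community a CommunityTable
#' @param tree an ape phylo covering the community species
#' @param i,j plot ids or indices
#' @return named numeric with pd_i, pd_j, pd_tot, a_pd, b_pd, c_pd
#' @export
phyloPairComponents <- function(community, tree, i, j) {
  inc <- incidence(community)
  si <- colnames(inc)[.plotRow(inc, i) > 0]
  sj <- colnames(inc)[.plotRow(inc, j) > 0]
  pdi <- faithPD(si, tree)
  pdj <- faithPD(sj, tree)
  pdt <- faithPD(union(si, sj), tree)
  c(pd_i = pdi, pd_j = pdj, pd_tot = pdt,
    a_pd = pdi + pdj - pdt, b_pd = pdt - pdj, c_pd = pdt - pdi)
}

#' PhyloSorensen total dissimilarity
#' @param ppc named numeric from \code{phyloPairComponents}
#' @return (2 pd_tot - pd_i - pd_j)/(pd_i + pd_j), in [0,1]
#' @export
phyloSorTotal <- function(ppc) {
  if (ppc[["pd_i"]] <= 0 || ppc[["pd_j"]] <= 0)
    stop("PhyloSorensen undefined for zero-PD plots")
  (2 * ppc[["pd_tot"]] - ppc[["pd_i"]] - ppc[["pd_j"]]) /
    (ppc[["pd_i"]] + ppc[["pd_j"]])
}

#' PhyloSorensen turnover (phylogenetic Simpson component)
#' @param ppc named numeric from \code{phyloPairComponents}
#' @return min(b_pd, c_pd)/(a_pd + min(b_pd, c_pd)), in [0,1]
#' @export
phyloSorTurnover <- function(ppc) {
  if (ppc[["pd_i"]] <= 0 || ppc[["pd_j"]] <= 0)
    stop("PhyloSorensen undefined for zero-PD plots")
  mn <- min(ppc[["b_pd"]], ppc[["c_pd"]])
  if (ppc[["a_pd"]] + mn <= 0) return(if (mn == 0) 0 else 1)
  mn / (ppc[["a_pd"]] + mn)
}

.sorensenFamily <- c("sorensen_total", "sorensen_turnover", "sorensen_nestedness")
.phylosorFamily <- c("phylosor_total", "phylosor_turnover", "phylosor_nestedness")

## all-pairs taxonomic components via matrix algebra
.taxPairMatrices <- function(inc) {
  a <- tcrossprod(inc)
  s <- rowSums(inc)
  list(a = a, b = matrix(s, nrow(inc), nrow(inc)) - a,
       c = t(matrix(s, nrow(inc), nrow(inc))) - a)
}

## all-pairs phylo components: shared branch length via weighted crossprod
.phyloPairMatrices <- function(inc, tree, E = NULL) {
  B <- .plotEdgeMatrix(inc, tree, E)
  len <- tree$edge.length
  pd <- as.vector(B %*% len)
  aPd <- tcrossprod(B * rep(sqrt(len), each = nrow(B)))
  pdTot <- outer(pd, pd, "+") - aPd
  list(pd = pd, aPd = aPd, pdTot = pdTot,
       bPd = pdTot - t(matrix(pd, length(pd), length(pd))),
       cPd = pdTot - matrix(pd, length(pd), length(pd)))
}

.pairwiseMetric <- function(inc, metricTag, tree = NULL, E = NULL) {
  n <- nrow(inc)
  if (metricTag %in% .sorensenFamily) {
    pm <- .taxPairMatrices(inc)
    tot <- (pm$b + pm$c) / (2 * pm$a + pm$b + pm$c)
    mn <- pmin(pm$b, pm$c)
    tur <- mn / (pm$a + mn)
    tur[pm$a + mn == 0] <- 0
  } else if (metricTag %in% .phylosorFamily) {
    if (is.null(tree)) stop(sprintf("metric '%s' requires a phylogeny", metricTag))
    pm <- .phyloPairMatrices(inc, tree, E)
    sumPd <- outer(pm$pd, pm$pd, "+")
    tot <- (2 * pm$pdTot - sumPd) / sumPd
    mn <- pmin(pm$bPd, pm$cPd)
    tur <- mn / (pm$aPd + mn)
    tur[pm$aPd + mn <= 0] <- 0
  } else stop(sprintf("unknown metric tag '%s'", metricTag))
  v <- switch(sub(".*_", "", metricTag),
              total = tot, turnover = tur, nestedness = tot - tur)
  v <- (v + t(v)) / 2           # exact symmetry against rounding
  v[v < 0 & v > -1e-14] <- 0
  diag(v) <- 0
  dimnames(v) <- list(rownames(inc), rownames(inc))
  v
}

#' All-pairs dissimilarity matrix for one metric
#'
#' @param community a CommunityTable
#' @param metricTag one of "sorensen_total", "sorensen_turnover",
#'   "sorensen_nestedness", "phylosor_total", "phylosor_turnover",
#'   "phylosor_nestedness"
#' @param phylogeny required for the phylosor tags
#' @return a \linkS4class{DissimilarityMatrix}
#' @export
dissimilarityMatrix <- function(community, metricTag, phylogeny = NULL) {
  v <- .pairwiseMetric(incidence(community), metricTag, phylogeny)
  new("DissimilarityMatrix", values = v, metricTag = metricTag)
}

#' Multiple-site Sorensen dissimilarity over all plots
#'
#' The across-all-plots summary form of the Sorensen family:
#' \deqn{\frac{\sum \min(b_{ij}, b_{ji}) + \sum \max(b_{ij}, b_{ji})}
#'   {2(\sum S_i - S_T) + \sum \min(b_{ij}, b_{ji}) + \sum \max(b_{ij}, b_{ji})}}
#' where the sums run over all plot pairs, \eqn{S_i} is the richness of
#' plot i and \eqn{S_T} the pooled richness.
#'
#' @param community a CommunityTable
#' @return numeric in [0,1]
#' @export
multiSiteSorensen <- function(community) {
  inc <- incidence(community)
  if (nrow(inc) < 2) stop("need at least two plots")
  pm <- .taxPairMatrices(inc)
  up <- upper.tri(pm$a)
  smin <- sum(pmin(pm$b[up], pm$c[up]))
  smax <- sum(pmax(pm$b[up], pm$c[up]))
  st <- sum(colSums(inc) > 0)
  (smin + smax) / (2 * (sum(rowSums(inc)) - st) + smin + smax)
}
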