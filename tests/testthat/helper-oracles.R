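# Independent oracles, coded from first principles (set operations and
# explicit root-to-tip path enumeration), deliberately avoiding the
# package's edge-incidence algebra.

oraclePairCounts <- function(spI, spJ) {
  c(a = length(intersect(spI, spJ)),
    b = length(setdiff(spI, spJ)),
    c = length(setdiff(spJ, spI)))
}

oracleSorensenTotal <- function(spI, spJ) {
  k <- oraclePairCounts(spI, spJ)
  (k["b"] + k["c"]) / (2 * k["a"] + k["b"] + k["c"])
}

oracleSorensenTurnover <- function(spI, spJ) {
  k <- oraclePairCounts(spI, spJ)
  mn <- min(k["b"], k["c"])
  if (k["a"] + mn == 0) 0 else mn / (k["a"] + mn)
}

# edges on the root-to-tip path of one tip, as "parent-child" strings
.oracleTipPathEdges <- function(tree, tip) {
  root <- length(tree$tip.label) + 1L
  nodes <- ape::nodepath(tree, from = root, to = which(tree$tip.label == tip))
  paste(nodes[-length(nodes)], nodes[-1])
}

oraclePD <- function(tipSet, tree) {
  edges <- unique(unlist(lapply(tipSet, .oracleTipPathEdges, tree = tree)))
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  sum(tree$edge.length[match(edges, key)])
}

oraclePhyloSorTotal <- function(spI, spJ, tree) {
  pdi <- oraclePD(spI, tree)
  pdj <- oraclePD(spJ, tree)
  pdt <- oraclePD(union(spI, spJ), tree)
  (2 * pdt - pdi - pdj) / (pdi + pdj)
}

oraclePhyloSorTurnover <- function(spI, spJ, tree) {
  pdi <- oraclePD(spI, tree)
  pdj <- oraclePD(spJ, tree)
  pdt <- oraclePD(union(spI, spJ), tree)
  a <- pdi + pdj - pdt
  mn <- min(pdt - pdj, pdt - pdi)
  if (a + mn <= 0) 0 else mn / (a + mn)
}

# brute-force minimax spanning-tree threshold: minimum over ALL spanning
# trees of the longest edge (enumerates edge subsets; n <= 7)
oracleThreshold <- function(m) {
  n <- nrow(m)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  best <- Inf
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    e <- pairs[sel, , drop = FALSE]
    # connectivity check by breadth-first search over the selected edges
    seen <- rep(FALSE, n)
    queue <- 1L
    seen[1L] <- TRUE
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- c(e[e[, 1] == v, 2], e[e[, 2] == v, 1])
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (all(seen))
      best <- min(best, max(m[e]))
  }
  best
}

# random community fixture over a given species pool
randomCommunity <- function(nPlots, pool, richness = NULL) {
  ns <- length(pool)
  inc <- t(vapply(seq_len(nPlots), function(i) {
    r <- if (is.null(richness)) sample(2:max(2, ns - 1), 1) else richness
    v <- numeric(ns)
    v[sample.int(ns, r)] <- 1
    v
  }, numeric(ns)))
  dimnames(inc) <- list(sprintf("p%02d", seq_len(nPlots)), pool)
  new("CommunityTable", incidence = inc)
}

smallTree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

starTree <- function(tips, len = 1) {
  txt <- paste0("(", paste0(tips, ":", len, collapse = ","), ");")
  ape::read.tree(text = txt)
}

# simple Procrustes distance after centering/scaling/rotation
procrustesError <- function(X, Y) {
  X <- scale(X, scale = FALSE); Y <- scale(Y, scale = FALSE)
  X <- X / sqrt(sum(X^2)); Y <- Y / sqrt(sum(Y^2))
  s <- svd(crossprod(Y, X))
  sqrt(max(0, 1 - sum(s$d)^2))
}
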