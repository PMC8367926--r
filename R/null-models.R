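## Null models and standardized effect sizes.
##
## Two randomizations:
##  * richness-preserving draws from the regional pool (each plot keeps its
##    observed richness; its species are drawn uniformly without
##    replacement from all species of the pool) — the null for taxonomic
##    and phylogenetic turnover;
##  * tip shuffling (labels permuted across the tips of the regional tree,
##    topology and branch lengths untouched) — the null for beta NRI/NTI.
##
## SES = (observed - null mean) / null sd, oriented so that positive values
## mean phylogenetic evenness (observed exceeds the null expectation) and
## negative values clustering; this is the inverse of Webb's NRI/NTI sign.

#' Richness-preserving randomization of a community table
#'
#' Each plot keeps its observed species richness exactly; its species are
#' drawn uniformly without replacement from the pool (by default all
#' species columns of the table).
#'
#' @param community a CommunityTable
#' @param pool optional character vector of pool species (defaults to the
#'   table's species); plot richness may not exceed the pool size
#' @return a randomized \linkS4class{CommunityTable} over the pool species
#' @export
randomizeRichness <- function(community, pool = NULL) {
  inc <- incidence(community)
  if (is.null(pool)) pool <- colnames(inc)
  np <- length(pool)
  rich <- rowSums(inc)
  if (any(rich > np))
    stop("plot richness exceeds pool size: randomization impossible")
  out <- matrix(0, nrow(inc), np, dimnames = list(rownames(inc), pool))
  for (i in seq_len(nrow(inc)))
    out[i, sample.int(np, rich[i])] <- 1
  new("CommunityTable", incidence = out)
}

#' Shuffle tip labels across a phylogeny
#'
#' Permutes the tip labels uniformly at random; topology and branch
#' lengths (hence the cophenetic-distance multiset and total branch
#' length) are unchanged.
#'
#' @param tree an ape phylo
#' @return the relabeled tree
#' @export
shuffleTips <- function(tree) {
  tree$tip.label <- sample(tree$tip.label)
  tree
}

#' Null ensemble for a pairwise turnover metric
#'
#' Generates \code{nIter} richness-preserving randomizations (taxonomic
#' tags draw from the community's species pool, phylosor tags from the full
#' tip set of the regional phylogeny) and records the per-pair null mean
#' and standard deviation of the chosen metric.
#'
#' @param community a CommunityTable
#' @param metricTag a Sorensen/PhyloSorensen family tag
#'   (see \code{\link{dissimilarityMatrix}})
#' @param nIter number of randomizations; values below 99 are accepted but
#'   flagged as low-precision for inference
#' @param phylogeny required for phylosor tags
#' @param storeDraws retain the per-iteration pairwise values (memory)
#' @param seed optional integer seed, recorded in the ensemble
#' @return a \linkS4class{NullEnsemble}
#' @export
nullTurnover <- function(community, metricTag, nIter = 999, phylogeny = NULL,
                         storeDraws = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nIter < 2) stop("nIter must be >= 2")
  if (nIter < 99)
    warning(sprintf("nIter = %d is low-precision for inference", nIter))
  phyloTag <- metricTag %in% .phylosorFamily
  if (phyloTag && is.null(phylogeny))
    stop(sprintf("metric '%s' requires a phylogeny", metricTag))
  pool <- if (phyloTag) phylogeny$tip.label else speciesIds(community)
  E <- if (phyloTag) .edgeTipIncidence(phylogeny) else NULL
  obs <- .pairwiseMetric(incidence(community), metricTag, phylogeny, E)
  n <- nrow(obs)
  s1 <- matrix(0, n, n)
  s2 <- matrix(0, n, n)
  draws <- if (storeDraws) array(NA_real_, c(n, n, nIter)) else array(NA_real_, c(0, 0, 0))
  for (it in seq_len(nIter)) {
    r <- randomizeRichness(community, pool)
    v <- .pairwiseMetric(incidence(r), metricTag, phylogeny, E)
    s1 <- s1 + v
    s2 <- s2 + v^2
    if (storeDraws) draws[, , it] <- v
  }
  mu <- s1 / nIter
  sdv <- sqrt(pmax((s2 - nIter * mu^2) / (nIter - 1), 0))
  dimnames(mu) <- dimnames(sdv) <- dimnames(obs)
  degenerate <- sum(sdv[upper.tri(sdv)] == 0)
  if (degenerate)
    message(sprintf("%d pair(s) with degenerate null sd = 0", degenerate))
  new("NullEnsemble", metricTag = metricTag, nIterations = as.integer(nIter),
      observed = obs, nullMean = mu, nullSd = sdv, draws = draws,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' 95\% null envelope of an ensemble
#'
#' @param ensemble a NullEnsemble
#' @return list with matrices \code{low} and \code{high},
#'   mean -/+ 1.96 sd. Degenerate pairs (sd = 0) collapse to [mean, mean]
#'   and are flagged with a message.
#' @export
nullEnvelope <- function(ensemble) {
  stopifnot(is(ensemble, "NullEnsemble"))
  if (any(ensemble@nullSd[upper.tri(ensemble@nullSd)] == 0))
    message("degenerate pairs: envelope collapses to the null mean")
  list(low = ensemble@nullMean - 1.96 * ensemble@nullSd,
       high = ensemble@nullMean + 1.96 * ensemble@nullSd)
}

#' SES of an ensemble's observed values against its null
#'
#' @param ensemble a NullEnsemble
#' @return an \linkS4class{SESMatrix} with tag "SES-<metric>"
#' @export
sesFromEnsemble <- function(ensemble) {
  ses <- (ensemble@observed - ensemble@nullMean) / ensemble@nullSd
  ses[ensemble@nullSd == 0] <- NA_real_
  diag(ses) <- NA_real_
  new("SESMatrix", values = ses,
      metricTag = paste0("SES-", ensemble@metricTag),
      nullMean = ensemble@nullMean, nullSd = ensemble@nullSd,
      signConvention = "positive = evenness, negative = clustering")
}

#' Mean pairwise patristic distance between two tip sets
#'
#' @param tipsI,tipsJ character vectors of tip labels (non-empty)
#' @param coph cophenetic (patristic) distance matrix over the tree tips,
#'   e.g. \code{ape::cophenetic.phylo(tree)}
#' @return mean over all cross pairs (x in i, y in j)
#' @export
interMPD <- function(tipsI, tipsJ, coph) {
  if (!length(tipsI) || !length(tipsJ)) stop("tip sets must be non-empty")
  mean(coph[tipsI, tipsJ, drop = FALSE])
}

#' Mean nearest-taxon patristic distance between two tip sets
#'
#' Symmetric average of the two directional means: for each taxon of one
#' set the distance to its nearest taxon in the other set, averaged within
#' each direction, then averaged across the two directions.
#'
#' @inheritParams interMPD
#' @return numeric >= 0
#' @export
interMNTD <- function(tipsI, tipsJ, coph) {
  if (!length(tipsI) || !length(tipsJ)) stop("tip sets must be non-empty")
  d <- coph[tipsI, tipsJ, drop = FALSE]
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

## all-pairs observed inter-MPD and inter-MNTD for an incidence matrix whose
## columns are aligned with (a subset of) the cophenetic matrix
.betaMpdMntd <- function(inc, coph) {
  sp <- colnames(inc)
  D <- coph[sp, sp]
  n <- nrow(inc)
  rich <- rowSums(inc)
  mpd <- (inc %*% D %*% t(inc)) / outer(rich, rich)
  mntd <- matrix(0, n, n, dimnames = dimnames(mpd))
  idx <- lapply(seq_len(n), function(i) which(inc[i, ] > 0))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- D[idx[[i]], idx[[j]], drop = FALSE]
    m <- (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
    mntd[i, j] <- mntd[j, i] <- m
  }
  list(mpd = mpd, mntd = mntd)
}

.betaSES <- function(community, phylogeny, which = c("mpd", "mntd"),
                     nIter = 999, seed = NULL) {
  which <- match.arg(which)
  if (!is.null(seed)) set.seed(seed)
  if (nIter < 2) stop("nIter must be >= 2")
  if (nIter < 99)
    warning(sprintf("nIter = %d is low-precision for inference", nIter))
  inc <- incidence(community)
  coph <- ape::cophenetic.phylo(phylogeny)
  ## community species must be tips; embed into the full tip pool so that
  ## the shuffle draws from the whole regional phylogeny
  pool <- phylogeny$tip.label
  full <- matrix(0, nrow(inc), length(pool),
                 dimnames = list(rownames(inc), pool))
  full[, colnames(inc)] <- inc
  D0 <- coph[pool, pool]
  obs <- .betaMpdMntd(full, D0)[[which]]
  n <- nrow(full)
  s1 <- matrix(0, n, n)
  s2 <- matrix(0, n, n)
  for (it in seq_len(nIter)) {
    ## tip shuffling = permuting the rows/columns of the patristic matrix
    ## while the communities keep their species identities
    perm <- sample.int(length(pool))
    Dp <- D0[perm, perm]
    dimnames(Dp) <- dimnames(D0)
    v <- .betaMpdMntd(full, Dp)[[which]]
    s1 <- s1 + v
    s2 <- s2 + v^2
  }
  mu <- s1 / nIter
  sdv <- sqrt(pmax((s2 - nIter * mu^2) / (nIter - 1), 0))
  ses <- (obs - mu) / sdv
  ses[sdv == 0] <- NA_real_
  diag(ses) <- NA_real_
  dimnames(ses) <- dimnames(mu) <- dimnames(sdv) <- dimnames(obs)
  new("SESMatrix", values = ses,
      metricTag = if (which == "mpd") "betaNRI" else "betaNTI",
      nullMean = mu, nullSd = sdv,
      signConvention = "positive = evenness, negative = clustering")
}

#' beta NRI: SES of between-community mean pairwise distance
#'
#' Standardized effect size of inter-community MPD against a null of
#' random tip shuffling across the regional phylogeny (basal, "tree-wide"
#' phylogenetic beta diversity). Positive values indicate phylogenetic
#' evenness between the two communities, negative values clustering.
#'
#' @param community a CommunityTable (species must be tree tips)
#' @param phylogeny the regional phylogeny
#' @param nIter null iterations (>= 99 for inference)
#' @param seed optional RNG seed
#' @return an \linkS4class{SESMatrix} with tag "betaNRI"
#' @export
betaNRI <- function(community, phylogeny, nIter = 999, seed = NULL)
  .betaSES(community, phylogeny, "mpd", nIter, seed)

#' beta NTI: SES of between-community mean nearest-taxon distance
#'
#' As \code{\link{betaNRI}} but for inter-community MNTD, sensitive to
#' clustering or evenness towards the tips of the regional phylogeny
#' (terminal phylogenetic beta diversity).
#'
#' @inheritParams betaNRI
#' @return an \linkS4class{SESMatrix} with tag "betaNTI"
#' @export
betaNTI <- function(community, phylogeny, nIter = 999, seed = NULL)
  .betaSES(community, phylogeny, "mntd", nIter, seed)

#' Long-format summary of an ensemble with envelope
#'
#' @param ensemble a NullEnsemble
#' @return data.frame with one row per unordered plot pair: observed, null
#'   mean/sd, SES and the 95\% envelope
#' @export
ensembleSummary <- function(ensemble) {
  env <- nullEnvelope(ensemble)
  ses <- sesFromEnsemble(ensemble)@values
  ids <- rownames(ensemble@observed)
  up <- which(upper.tri(ensemble@observed), arr.ind = TRUE)
  data.frame(plot_i = ids[up[, 1]], plot_j = ids[up[, 2]],
             observed = ensemble@observed[up], null_mean = ensemble@nullMean[up],
             null_sd = ensemble@nullSd[up], ses = ses[up],
             low = env$low[up], high = env$high[up])
}
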