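## Ordination: PCA, NMDS (vegan::monoMDS engine behind a best-of-starts
## wrapper), RDA by least-squares projection, db-RDA (PCoA response), the
## permutation pseudo-F test (Freedman-Lane residual permutation under a
## condition matrix) and forward selection with the double stopping rule.

.center <- function(x) sweep(as.matrix(x), 2, colMeans(as.matrix(x)))

## orthonormal basis of the column space of a centered matrix; errors on
## rank deficiency naming the dependent columns when required
.qrBasis <- function(x, requireFullRank = FALSE, what = "predictors") {
  qx <- qr(x)
  if (requireFullRank && qx$rank < ncol(x)) {
    dep <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop(sprintf("rank-deficient %s; dependent columns: %s",
                 what, paste(dep, collapse = ", ")))
  }
  qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
}

#' Principal component analysis of an environment-style matrix
#'
#' Eigen-decomposition of the correlation (default) or covariance matrix.
#' The correlation option is the collinearity-robust choice for variables
#' on heterogeneous scales.
#'
#' @param x plots x variables numeric matrix (or EnvironmentTable)
#' @param useCorrelation scale variables to unit variance first
#' @return an \linkS4class{OrdinationResult} (method "pca"); scores are the
#'   centered (and scaled) data projected on the eigenvectors
#' @export
pcaOrdination <- function(x, useCorrelation = TRUE) {
  if (is(x, "EnvironmentTable")) x <- x@values
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 variables")
  if (anyNA(x)) stop("missing values")
  sds <- apply(x, 2, sd)
  if (useCorrelation && any(sds == 0))
    stop(sprintf("zero-variance column(s) with correlation PCA: %s",
                 paste(colnames(x)[sds == 0], collapse = ", ")))
  xs <- scale(x, center = TRUE, scale = useCorrelation)
  cm <- crossprod(xs) / (nrow(x) - 1)
  eig <- eigen(cm, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  scores <- xs %*% eig$vectors
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- rownames(x)
  prop <- ev / sum(ev)
  new("OrdinationResult", method = "pca", scores = scores,
      eigenvalues = ev, proportion = prop, cumulative = cumsum(prop),
      axisF = rep(NA_real_, length(ev)), axisP = rep(NA_real_, length(ev)),
      biplot = matrix(NA_real_, 0, 0),
      details = list(rotation = eig$vectors))
}

#' Non-metric multidimensional scaling (best of random starts)
#'
#' Kruskal stress-1 NMDS via monotone regression (vegan::monoMDS engine),
#' run from \code{nStarts} random configurations; the lowest-stress
#' solution is returned, centered and rotated to its principal axes.
#'
#' @param dissimilarity a DissimilarityMatrix (or dist)
#' @param k number of dimensions
#' @param nStarts random starts (the analysis default is 1000; use fewer
#'   for exploration)
#' @param maxit iterations per start
#' @param seed optional RNG seed
#' @return an \linkS4class{OrdinationResult} (method "nmds") with stress
#' @export
nmdsOrdination <- function(dissimilarity, k = 2, nStarts = 20, maxit = 300,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- if (is(dissimilarity, "DissimilarityMatrix")) asDist(dissimilarity)
       else stats::as.dist(dissimilarity)
  if (all(d == 0)) stop("all dissimilarities are zero: NMDS degenerate")
  n <- attr(d, "Size")
  best <- NULL
  for (s in seq_len(nStarts)) {
    init <- matrix(stats::rnorm(n * k), n, k)
    fit <- vegan::monoMDS(d, y = init, k = k, model = "global",
                          maxit = maxit, smin = 1e-6, sratmax = 1 - 1e-6)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  sc <- .center(best$points)
  sc <- sc %*% svd(sc)$v   # principal-axis rotation
  colnames(sc) <- paste0("NMDS", seq_len(k))
  rownames(sc) <- attr(d, "Labels")
  new("OrdinationResult", method = "nmds", scores = sc,
      eigenvalues = numeric(0), proportion = numeric(0),
      cumulative = numeric(0), axisF = numeric(0), axisP = numeric(0),
      biplot = matrix(NA_real_, 0, 0), stress = best$stress,
      details = list(nStarts = nStarts))
}

## core RDA numerics shared by rdaFit / dbRDA / partialRDA
.rdaCore <- function(Y, X, nPerm = 0, axisTests = FALSE) {
  Y <- .center(Y)
  X <- .center(X)
  n <- nrow(Y)
  Q <- .qrBasis(X, requireFullRank = TRUE)
  m <- ncol(Q)
  if (n <= m + 1) stop("too few plots for the number of predictors")
  proj <- crossprod(Q, Y)
  fit <- Q %*% proj
  ssT <- sum(Y^2)
  ssF <- sum(fit^2)
  r2 <- ssF / ssT
  adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  sv <- svd(fit)
  lam <- sv$d^2
  keep <- which(lam > max(lam, 0) * 1e-12)
  lam <- lam[keep]
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  colnames(scores) <- paste0("RDA", seq_along(keep))
  rownames(scores) <- rownames(Y)
  prop <- lam / ssT
  axF <- axP <- rep(NA_real_, length(lam))
  ssRes <- max(ssT - ssF, 0)
  dfRes <- n - m - 1
  if (axisTests && nPerm > 0) {
    axF <- lam / (ssRes / dfRes)
    exceed <- rep(1L, length(lam))
    for (p in seq_len(nPerm)) {
      Yp <- Y[sample.int(n), , drop = FALSE]
      fp <- Q %*% crossprod(Q, Yp)
      lp <- svd(fp, nu = 0, nv = 0)$d^2
      sp <- max(sum(Yp^2) - sum(fp^2), 0)
      fperm <- lp[seq_along(lam)] / (sp / dfRes)
      exceed <- exceed + (fperm >= axF)
    }
    axP <- exceed / (nPerm + 1)
  }
  bip <- suppressWarnings(cor(X, scores))
  bip[!is.finite(bip)] <- 0
  new("OrdinationResult", method = "rda", scores = scores,
      eigenvalues = lam / (n - 1), proportion = prop, cumulative = cumsum(prop),
      axisF = axF, axisP = axP, r2 = r2, adjR2 = adj, biplot = bip,
      details = list(ssTotal = ssT, ssFit = ssF, rank = m))
}

#' Redundancy analysis (RDA)
#'
#' Least-squares projection of the centered response onto the predictor
#' column space, followed by an eigen-decomposition of the fitted values.
#' R2 = SS(fit)/SS(total); adjusted R2 by Ezekiel's formula.
#'
#' @param response plots x q numeric response matrix
#' @param predictors plots x m predictor matrix (full column rank after
#'   centering)
#' @param nPerm permutations for per-axis pseudo-F tests (0 = skip)
#' @param seed optional RNG seed for the axis tests
#' @return an \linkS4class{OrdinationResult} (method "rda")
#' @export
rdaFit <- function(response, predictors, nPerm = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .rdaCore(response, predictors, nPerm = nPerm, axisTests = nPerm > 0)
}

## principal coordinates of a dissimilarity matrix; positive eigenvalues
.pcoaAxes <- function(m, correction = c("none", "lingoes", "cailliez")) {
  correction <- match.arg(correction)
  if (correction != "none") {
    pc <- ape::pcoa(m, correction = correction)
    vec <- pc$vectors.cor
    if (is.null(vec)) vec <- pc$vectors
    lam <- pc$values$Corr_eig
    if (is.null(lam)) lam <- pc$values$Eigenvalues
    keep <- lam > max(lam) * 1e-10
    return(list(axes = vec[, keep[seq_len(ncol(vec))], drop = FALSE],
                eig = lam[keep]))
  }
  G <- -0.5 * m^2
  G <- sweep(G, 1, rowMeans(G))
  G <- sweep(G, 2, colMeans(G))
  G <- (G + t(G)) / 2
  eig <- eigen(G, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-10
  keep <- which(eig$values > tol)
  if (!length(keep)) stop("no positive eigenvalues in PCoA")
  nNeg <- sum(eig$values < -tol)
  if (nNeg) message(sprintf("%d negative PCoA eigenvalues discarded", nNeg))
  axes <- eig$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(eig$values[keep]), length(keep))
  rownames(axes) <- rownames(m)
  colnames(axes) <- paste0("PCoA", seq_along(keep))
  list(axes = axes, eig = eig$values[keep])
}

#' Distance-based redundancy analysis
#'
#' Principal coordinates analysis of the dissimilarity matrix; all axes
#' with positive eigenvalues form the response for an ordinary RDA on the
#' predictors. Constrained proportions are relative to the retained-axes
#' total variance. Negative PCoA eigenvalues are discarded (with a logged
#' count); Lingoes or Cailliez corrections are available as a toggle.
#'
#' @param dissimilarity a DissimilarityMatrix (or square matrix/dist)
#' @param predictors plots x m predictor matrix
#' @param nPerm permutations for per-axis tests (0 = skip)
#' @param correction "none" (discard negatives), "lingoes" or "cailliez"
#' @param seed optional RNG seed
#' @return an \linkS4class{OrdinationResult} (method "dbrda"); the PCoA
#'   axes are in \code{details}
#' @export
dbRDA <- function(dissimilarity, predictors, nPerm = 0,
                  correction = c("none", "lingoes", "cailliez"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- if (is(dissimilarity, "DissimilarityMatrix")) dissimilarity@values
       else as.matrix(dissimilarity)
  if (is.null(predictors) || NCOL(predictors) == 0) stop("no predictors given")
  pc <- .pcoaAxes(m, match.arg(correction))
  res <- .rdaCore(pc$axes, predictors, nPerm = nPerm, axisTests = nPerm > 0)
  res@method <- "dbrda"
  res@details$pcoaAxes <- pc$axes
  res@details$pcoaEig <- pc$eig
  res
}

#' Permutation pseudo-F test for (partial) RDA
#'
#' F = (SS_explained / m) / (SS_residual / (n - m - mc - 1)) where m and mc
#' are the ranks of the predictors and the condition. Without a condition,
#' response rows are permuted; with a condition the Freedman-Lane scheme
#' permutes the residuals of the reduced (condition-only) model.
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + nPerm).
#'
#' @param response plots x q matrix
#' @param predictors plots x m matrix
#' @param nPerm number of permutations (>= 19)
#' @param condition optional covariate matrix to partial out
#' @param seed optional RNG seed
#' @return list with elements F, p, df (c(m, residual df)), r2
#' @export
permutationPseudoF <- function(response, predictors, nPerm = 999,
                               condition = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nPerm < 19) stop("nPerm must be >= 19")
  Y <- .center(response)
  X <- .center(predictors)
  n <- nrow(Y)
  if (is.null(condition)) {
    Q <- .qrBasis(X)
    m <- ncol(Q)
    stat <- function(Yw) {
      ssF <- sum(crossprod(Q, Yw)^2)
      ssR <- max(sum(Yw^2) - ssF, 0)  # guard against negative zero
      (ssF / m) / (ssR / (n - m - 1))
    }
    fObs <- stat(Y)
    if (is.nan(fObs))  # no variation left to test
      return(list(F = NaN, p = 1, df = c(m, n - m - 1), r2 = NA_real_))
    exceed <- 1L
    for (p in seq_len(nPerm))
      exceed <- exceed + isTRUE(stat(Y[sample.int(n), , drop = FALSE]) >= fObs)
    return(list(F = fObs, p = exceed / (nPerm + 1),
                df = c(m, n - m - 1), r2 = NA_real_))
  }
  Z <- .center(condition)
  Qz <- .qrBasis(Z, requireFullRank = TRUE, what = "condition")
  mz <- ncol(Qz)
  Xr <- X - Qz %*% crossprod(Qz, X)
  Qx <- .qrBasis(cbind(Qz, Xr))
  m <- ncol(Qx) - mz
  if (m < 1) stop("predictors lie in the span of the condition")
  fitZ <- Qz %*% crossprod(Qz, Y)
  E <- Y - fitZ
  stat <- function(Yw) {
    ssFull <- sum(crossprod(Qx, Yw)^2)
    ssZ <- sum(crossprod(Qz, Yw)^2)
    ssR <- max(sum(Yw^2) - ssFull, 0)  # guard against negative zero
    ((ssFull - ssZ) / m) / (ssR / (n - mz - m - 1))
  }
  fObs <- stat(Y)
  if (is.nan(fObs))  # condition leaves no residual variation to test
    return(list(F = NaN, p = 1, df = c(m, n - mz - m - 1), r2 = NA_real_))
  exceed <- 1L
  for (p in seq_len(nPerm)) {
    Yp <- fitZ + E[sample.int(n), , drop = FALSE]
    exceed <- exceed + isTRUE(stat(Yp) >= fObs)
  }
  list(F = fObs, p = exceed / (nPerm + 1), df = c(m, n - mz - m - 1),
       r2 = NA_real_)
}

.adjR2 <- function(Y, X) {
  Y <- .center(Y)
  if (is.null(X) || NCOL(X) == 0) return(c(r2 = 0, adj = 0, m = 0))
  Q <- .qrBasis(.center(X))
  n <- nrow(Y)
  m <- ncol(Q)
  r2 <- sum(crossprod(Q, Y)^2) / sum(Y^2)
  c(r2 = r2, adj = 1 - (1 - r2) * (n - 1) / (n - m - 1), m = m)
}

#' Forward selection with the double stopping criterion
#'
#' Greedy selection among single-variable candidates: at each step the
#' candidate adding the most explained variance enters if (i) its partial
#' permutation pseudo-F test (conditioned on the variables already in) has
#' p <= alpha and (ii) the cumulative adjusted R2 does not exceed the
#' adjusted R2 of the global model on all candidates. A global pre-test of
#' all candidates jointly at alpha gates the whole procedure: without it
#' the selection's type-I error is not held at alpha.
#'
#' @param response plots x q matrix
#' @param candidates plots x k matrix; each column is one candidate
#' @param alpha per-step significance level
#' @param nPerm permutations per test
#' @param seed optional RNG seed
#' @return a \linkS4class{SelectionTrace}
#' @export
forwardSelect <- function(response, candidates, alpha = 0.05, nPerm = 999,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  candidates <- as.matrix(candidates)
  if (is.null(colnames(candidates)))
    colnames(candidates) <- paste0("V", seq_len(ncol(candidates)))
  Y <- .center(response)
  cap <- .adjR2(Y, candidates)[["adj"]]
  gp <- permutationPseudoF(Y, candidates, nPerm = nPerm)$p
  emptyTrace <- function(gated) {
    if (gated) message("global pre-test not significant: nothing selected")
    new("SelectionTrace", selected = character(0), stepF = numeric(0),
        stepP = numeric(0), cumAdjR2 = numeric(0), cap = cap,
        globalP = gp, alpha = alpha)
  }
  if (gp > alpha) return(emptyTrace(TRUE))
  remaining <- colnames(candidates)
  selected <- character(0)
  stepF <- stepP <- cumAdj <- numeric(0)
  repeat {
    if (!length(remaining)) break
    Xsel <- if (length(selected)) candidates[, selected, drop = FALSE] else NULL
    gain <- vapply(remaining, function(v) {
      .adjR2(Y, cbind(Xsel, candidates[, v]))[["r2"]]
    }, numeric(1))
    bestVar <- remaining[which.max(gain)]
    tst <- permutationPseudoF(Y, candidates[, bestVar, drop = FALSE],
                              nPerm = nPerm, condition = Xsel)
    if (tst$p > alpha) break
    newAdj <- .adjR2(Y, cbind(Xsel, candidates[, bestVar]))[["adj"]]
    if (newAdj > cap) {
      message(sprintf("'%s' passes alpha but would exceed the global adjusted R2 cap; stopping",
                      bestVar))
      break
    }
    if (length(cumAdj) && newAdj < cumAdj[length(cumAdj)]) break  # no adjusted-R2 gain
    selected <- c(selected, bestVar)
    stepF <- c(stepF, tst$F)
    stepP <- c(stepP, tst$p)
    cumAdj <- c(cumAdj, newAdj)
    remaining <- setdiff(remaining, bestVar)
  }
  if (!length(selected)) return(emptyTrace(FALSE))
  new("SelectionTrace", selected = selected, stepF = stepF, stepP = stepP,
      cumAdjR2 = cumAdj, cap = cap, globalP = gp, alpha = alpha)
}
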