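## Variance partitioning by inclusion-exclusion over adjusted R2.
##
## For explanatory sets S1..Sk (k = 2..4) every Venn cell of explained
## variation is obtained from the adjusted R2 of all subset models:
##   h(S) = adjR2(full) - adjR2(full \ S)   (variation explained only by S)
##   cell(T) = sum_{S subset of T} (-1)^{|T|-|S|} h(S)   (Mobius inversion)
## The residual is 1 - adjR2(full). Unique fractions (|T| = 1) are testable
## by a partial permutation pseudo-F conditioned on all other sets; shared
## fractions are differences of fitted models and carry no test. Fractions
## use adjusted R2 throughout (comparability across set sizes) and negative
## values are reported as computed, not clamped.

#' Partial RDA: response and predictors residualized on a condition
#'
#' @param response plots x q matrix
#' @param predictors plots x m matrix (disjoint from the condition)
#' @param condition plots x mc covariate matrix
#' @param nPerm permutations for the partial pseudo-F test (0 = skip)
#' @param seed optional RNG seed
#' @return an \linkS4class{OrdinationResult} (method "partial_rda").
#'   \code{r2} is the semi-partial R2 (conditioned explained sum of squares
#'   over the total response variation); \code{adjR2} is the semi-partial
#'   adjusted R2, adjR2(predictors+condition) - adjR2(condition);
#'   \code{details$partialR2} holds the share of the post-condition
#'   residual variation instead.
#' @export
partialRDA <- function(response, predictors, condition, nPerm = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Y <- .center(response)
  X <- .center(predictors)
  Z <- .center(condition)
  shared <- intersect(colnames(X), colnames(Z))
  if (length(shared))
    stop(sprintf("predictors and condition overlap: %s",
                 paste(shared, collapse = ", ")))
  Qz <- .qrBasis(Z, requireFullRank = TRUE, what = "condition")
  Yr <- Y - Qz %*% crossprod(Qz, Y)
  Xr <- X - Qz %*% crossprod(Qz, X)
  if (max(abs(Xr)) < 1e-12) {
    ## condition spans the predictors: nothing left to explain
    res <- new("OrdinationResult", method = "partial_rda",
               scores = matrix(0, nrow(Y), 0), eigenvalues = numeric(0),
               proportion = numeric(0), cumulative = numeric(0),
               axisF = numeric(0), axisP = numeric(0), r2 = 0, adjR2 = 0,
               biplot = matrix(NA_real_, 0, 0))
    res@details$semipartialAdjR2 <- 0
    return(res)
  }
  res <- .rdaCore(Yr, Xr, nPerm = nPerm, axisTests = nPerm > 0)
  res@method <- "partial_rda"
  ## report the semi-partial R2: explained sum of squares of the
  ## conditioned fit relative to the TOTAL response variation, the scale on
  ## which marginal and partial contributions are comparable
  res@details$partialR2 <- res@r2  # share of the post-condition residual
  res@r2 <- res@r2 * sum(Yr^2) / sum(Y^2)
  res@details$semipartialAdjR2 <-
    .adjR2(Y, cbind(Z, X))[["adj"]] - .adjR2(Y, Z)[["adj"]]
  res@adjR2 <- res@details$semipartialAdjR2
  if (nPerm > 0) {
    tst <- permutationPseudoF(Y, X, nPerm = nPerm, condition = Z)
    res@details$partialF <- tst$F
    res@details$partialP <- tst$p
  }
  res
}

.vennCellName <- function(sets) {
  if (length(sets) == 1) sets else paste(sets, collapse = " and ")
}

#' Partition explained variation among 2-4 explanatory sets
#'
#' @param response plots x q matrix (typically NMDS axes 1-2 or PCoA axes
#'   of a beta-diversity matrix)
#' @param sets named list of 2-4 predictor matrices (each full rank)
#' @param nPerm permutations for testing the unique fractions (0 = skip)
#' @param seed optional RNG seed
#' @return a \linkS4class{VariancePartition}
#' @export
partitionVariation <- function(response, sets, nPerm = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is.list(sets), length(sets) >= 2, length(sets) <= 4,
            !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, as.matrix)
  Y <- .center(response)
  k <- length(sets)
  nm <- names(sets)
  n <- nrow(Y)
  mTot <- sum(vapply(sets, ncol, 0L))
  if (n <= mTot + 1)
    stop("joint model saturated: need more plots than total predictors + 1")
  ## adjusted R2 of every non-empty subset union
  subsets <- lapply(seq_len(2^k - 1), function(code) which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0))
  adjOf <- vapply(subsets, function(ss)
    .adjR2(Y, do.call(cbind, sets[ss]))[["adj"]], numeric(1))
  codeOf <- function(ss) sum(2^(ss - 1))
  adjFull <- adjOf[codeOf(seq_len(k))]
  ## h(S) = adjFull - adj(full minus S); Mobius over subsets of T
  hOf <- function(ss) {
    rest <- setdiff(seq_len(k), ss)
    if (!length(rest)) return(adjFull)
    adjFull - adjOf[codeOf(rest)]
  }
  fractions <- numeric(0)
  testable <- logical(0)
  pv <- numeric(0)
  for (cell in subsets) {
    val <- 0
    subs <- lapply(seq_len(2^length(cell)) - 1, function(code)
      cell[bitwAnd(code, 2^(seq_along(cell) - 1)) > 0])
    for (s in subs) {
      hv <- if (length(s)) hOf(s) else 0
      val <- val + (-1)^(length(cell) - length(s)) * hv
    }
    nmCell <- .vennCellName(nm[cell])
    fractions[nmCell] <- val
    isUnique <- length(cell) == 1
    testable[nmCell] <- isUnique && nPerm > 0
    pv[nmCell] <- if (isUnique && nPerm > 0) {
      others <- do.call(cbind, sets[-cell])
      permutationPseudoF(Y, sets[[cell]], nPerm = nPerm, condition = others)$p
    } else NA_real_
  }
  neg <- names(fractions)[fractions < 0]
  if (length(neg))
    message(sprintf("negative fraction(s) reported as computed: %s",
                    paste(neg, collapse = ", ")))
  fractions["Residual"] <- 1 - adjFull
  testable["Residual"] <- FALSE
  pv["Residual"] <- NA_real_
  new("VariancePartition", setNames = nm, fractions = fractions,
      testable = testable, pvalues = pv, adjR2Full = adjFull)
}

#' Scale-stratified variance partition
#'
#' Runs \code{\link{partitionVariation}} with the spatial set restricted to
#' the PCNM eigenvectors of one scale class (broad, mid or fine), the
#' per-scale analogue of fitting space at a chosen spatial grain.
#'
#' @param response plots x q matrix
#' @param envSets named list of 1-3 environmental predictor matrices
#' @param pcnm a classified \linkS4class{PCNMBasis}
#' @param scale "broad", "mid" or "fine"
#' @param nPerm permutations for the unique-fraction tests
#' @param seed optional RNG seed
#' @return a \linkS4class{VariancePartition} whose "Space" set holds only
#'   the requested scale's eigenvectors
#' @export
scaleStratifiedPartition <- function(response, envSets, pcnm, scale,
                                     nPerm = 0, seed = NULL) {
  stopifnot(is(pcnm, "PCNMBasis"))
  if (!any(nzchar(pcnm@scaleClass)))
    stop("PCNM basis has no scale classes: run classifyScale() first")
  keep <- pcnm@scaleClass == scale
  if (!any(keep))
    stop(sprintf("no PCNM eigenvectors in scale class '%s'", scale))
  sets <- c(envSets, list(Space = pcnm@vectors[, keep, drop = FALSE]))
  partitionVariation(response, sets, nPerm = nPerm, seed = seed)
}

#' Write a VariancePartition as CSV and JSON
#' @param x a VariancePartition
#' @param path CSV path; a JSON summary goes to sub(".csv", ".json", path)
#' @export
writeVariancePartition <- function(x, path) {
  df <- data.frame(fraction = names(x@fractions), value = x@fractions,
                   p = x@pvalues, row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  jsonlite::write_json(as.list(x@fractions), sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
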