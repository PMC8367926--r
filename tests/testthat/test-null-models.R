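test_that("richness randomization preserves row sums and is uniform", {
  set.seed(31)
  cm <- randomCommunity(4, paste0("s", 1:8))
  for (rep in 1:10) {
    r <- randomizeRichness(cm)
    expect_equal(rowSums(incidence(r)), rowSums(incidence(cm)))
  }
  # a plot holding the whole pool is forced to itself
  inc <- matrix(1, 1, 4, dimnames = list("p1", paste0("s", 1:4)))
  full <- new("CommunityTable", incidence = inc)
  expect_identical(incidence(randomizeRichness(full)), inc)
  # per-species inclusion frequency ~ Binomial(n, richness/pool)
  inc3 <- rbind(p1 = c(1, 1, 1, 0, 0, 0), p2 = c(1, 1, 0, 0, 0, 0),
                p3 = c(1, 1, 1, 1, 0, 0))
  colnames(inc3) <- paste0("s", 1:6)
  cm3 <- new("CommunityTable", incidence = inc3)
  n <- 2000
  counts <- matrix(0, 3, 6)
  for (it in seq_len(n)) counts <- counts + incidence(randomizeRichness(cm3))
  p <- rowSums(inc3) / 6
  for (i in 1:3) {
    tol <- 3 * sqrt(n * p[i] * (1 - p[i]))
    expect_true(all(abs(counts[i, ] - n * p[i]) <= tol))
  }
  # richness above pool size is impossible
  expect_error(randomizeRichness(cm3, pool = c("s1", "s2")), "pool size")
})

test_that("tip shuffling preserves tree shape invariants", {
  set.seed(37)
  tr <- ape::rtree(12)
  coph <- ape::cophenetic.phylo(tr)
  for (rep in 1:5) {
    sh <- shuffleTips(tr)
    expect_setequal(sh$tip.label, tr$tip.label)
    expect_identical(sh$edge, tr$edge)
    expect_identical(sh$edge.length, tr$edge.length)
    cophS <- ape::cophenetic.phylo(sh)
    expect_equal(sort(cophS[upper.tri(cophS)]), sort(coph[upper.tri(coph)]))
    expect_equal(faithPD(sh$tip.label, sh), faithPD(tr$tip.label, tr))
  }
  # two-tip tree: swap with probability 1/2
  tr2 <- ape::read.tree(text = "(A:1,B:1);")
  n <- 2000
  swaps <- sum(vapply(seq_len(n),
                      function(i) shuffleTips(tr2)$tip.label[1] == "B", logical(1)))
  expect_lt(abs(swaps - n / 2), 3 * sqrt(n * 0.25))
})

test_that("null ensemble handles degenerate and low-precision cases", {
  # every plot holds the entire pool: nothing can vary
  inc <- matrix(1, 3, 4, dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  cm <- new("CommunityTable", incidence = inc)
  expect_warning(
    expect_message(ens <- nullTurnover(cm, "sorensen_turnover", nIter = 19),
                   "degenerate"),
    "low-precision")
  expect_true(all(ens@nullSd == 0))
  expect_true(all(ens@observed == 0))
  # nIter = 2 accepted but flagged
  expect_warning(nullTurnover(cm, "sorensen_turnover", nIter = 2),
                 "low-precision")
  expect_error(suppressWarnings(nullTurnover(cm, "sorensen_turnover", nIter = 1)),
               ">= 2")
  expect_error(suppressWarnings(nullTurnover(cm, "phylosor_turnover", nIter = 19)),
               "phylogeny")
})

test_that("inter-community MPD and MNTD match enumeration", {
  tr <- smallTree()
  coph <- ape::cophenetic.phylo(tr)
  expect_equal(interMPD("A", "A", coph), 0)
  expect_equal(interMPD(c("A", "B"), c("C", "D"), coph), 4)
  expect_equal(interMPD("A", "B", coph), 2)
  expect_equal(interMNTD(c("A", "B"), c("A", "B"), coph), 0)
  expect_equal(interMNTD(c("A", "B"), c("C", "D"), coph), 4)
  expect_equal(interMNTD(c("A", "C"), c("A", "D"), coph), 1)
  expect_error(interMNTD(character(0), "A", coph), "non-empty")
})

test_that("beta NRI equals beta NTI for single-species plots", {
  tr <- smallTree()
  inc <- rbind(p1 = c(1, 0, 0, 0), p2 = c(0, 1, 0, 0))
  colnames(inc) <- tr$tip.label
  cm <- new("CommunityTable", incidence = inc)
  nri <- suppressWarnings(betaNRI(cm, tr, nIter = 49, seed = 5))
  nti <- suppressWarnings(betaNTI(cm, tr, nIter = 49, seed = 5))
  expect_equal(as.matrix(nri)[1, 2], as.matrix(nti)[1, 2], tolerance = 1e-12)
})

test_that("clade-confined plots are phylogenetically clustered (negative SES)", {
  set.seed(41)
  tr <- ape::rphylo(40, 1, 0)
  # two plots confined to one phylogenetic neighborhood: observed
  # inter-MPD/MNTD far below the tip-shuffle null
  d <- ape::cophenetic.phylo(tr)
  close <- names(sort(d[1, ]))[1:8]
  inc <- rbind(p1 = as.numeric(tr$tip.label %in% close[1:4]),
               p2 = as.numeric(tr$tip.label %in% close[5:8]))
  colnames(inc) <- tr$tip.label
  cm <- new("CommunityTable", incidence = inc)
  nti <- suppressWarnings(betaNTI(cm, tr, nIter = 99, seed = 6))
  nri <- suppressWarnings(betaNRI(cm, tr, nIter = 99, seed = 6))
  expect_lt(as.matrix(nti)[1, 2], -1)
  expect_lt(as.matrix(nri)[1, 2], -1)
})

test_that("SES matrices are symmetric and invariant to plot order", {
  set.seed(43)
  tr <- ape::rtree(15)
  cm <- randomCommunity(5, tr$tip.label, richness = 5)
  s <- suppressWarnings(betaNTI(cm, tr, nIter = 49, seed = 9))
  m <- as.matrix(s)
  expect_equal(m, t(m))
  # relabeled plots: same values under the same seed
  inc2 <- incidence(cm)[c(3, 1, 2, 5, 4), ]
  cm2 <- new("CommunityTable", incidence = inc2)
  s2 <- suppressWarnings(betaNTI(cm2, tr, nIter = 49, seed = 9))
  expect_equal(as.matrix(s2)[rownames(m), colnames(m)], m, tolerance = 1e-10)
})

test_that("null envelope is mean +/- 1.96 sd with ~95% coverage", {
  mkEns <- function(mu, sd) {
    m <- matrix(c(0, mu, mu, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
    s <- matrix(c(0, sd, sd, 0), 2, 2, dimnames = dimnames(m))
    new("NullEnsemble", metricTag = "sorensen_turnover", nIterations = 99L,
        observed = m * 0, nullMean = m, nullSd = s, draws = array(0, c(0, 0, 0)),
        seed = NA_integer_)
  }
  env <- nullEnvelope(mkEns(0, 1))
  expect_equal(env$low[1, 2], -1.96)
  expect_equal(env$high[1, 2], 1.96)
  expect_message(env0 <- nullEnvelope(mkEns(0.5, 0)), "degenerate")
  expect_equal(env0$low[1, 2], 0.5)
  expect_equal(env0$high[1, 2], 0.5)

  # coverage: envelope from one ensemble contains ~95% of fresh null draws
  set.seed(47)
  cm <- randomCommunity(6, paste0("s", 1:20), richness = 8)
  ens <- suppressWarnings(nullTurnover(cm, "sorensen_turnover", nIter = 199))
  env <- nullEnvelope(ens)
  up <- upper.tri(ens@observed)
  nDraw <- 1000
  inside <- 0
  for (it in seq_len(nDraw)) {
    v <- as.matrix(dissimilarityMatrix(randomizeRichness(cm), "sorensen_turnover"))
    inside <- inside + mean(v[up] >= env$low[up] & v[up] <= env$high[up])
  }
  cover <- inside / nDraw
  expect_lt(abs(cover - 0.95), 3 * sqrt(0.95 * 0.05 / nDraw) + 0.02)
})

test_that("ensemble summary table carries obs, null moments, ses, envelope", {
  set.seed(53)
  cm <- randomCommunity(4, paste0("s", 1:12), richness = 5)
  ens <- suppressWarnings(nullTurnover(cm, "sorensen_turnover", nIter = 49, seed = 3))
  df <- ensembleSummary(ens)
  expect_equal(nrow(df), 6)  # 4 choose 2
  expect_named(df, c("plot_i", "plot_j", "observed", "null_mean", "null_sd",
                     "ses", "low", "high"))
  expect_equal(df$ses, (df$observed - df$null_mean) / df$null_sd)
  expect_equal(df$low, df$null_mean - 1.96 * df$null_sd)
})
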