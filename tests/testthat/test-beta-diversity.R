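test_that("pair components are exact set-intersection counts", {
  inc <- matrix(c(1, 0, 1, 1, 0, 1, 1, 0, 0, 0, 1, 1), 2, 6,
                dimnames = list(c("pi", "pj"),
                                c("A", "B", "C", "D", "E", "F")))
  # pi = {A,C,E? } build explicitly instead:
  inc <- rbind(pi = c(1, 1, 1, 0, 0, 0), pj = c(0, 1, 1, 1, 0, 0))
  colnames(inc) <- c("A", "B", "C", "D", "E", "F")
  cm <- new("CommunityTable", incidence = inc)
  expect_equal(pairComponents(cm, "pi", "pj"), c(a = 2, b = 1, c = 1))
  expect_equal(pairComponents(cm, "pi", "pi"), c(a = 3, b = 0, c = 0))
  dj <- rbind(pi = c(1, 1, 0, 0), pj = c(0, 0, 1, 1))
  colnames(dj) <- c("A", "B", "C", "D")
  disj <- new("CommunityTable", incidence = dj)
  expect_equal(pairComponents(disj, "pi", "pj"), c(a = 0, b = 2, c = 2))
  expect_error(pairComponents(cm, "pi", "nope"), "unknown plot")
})

test_that("Sorensen total and turnover match their closed forms", {
  expect_equal(sorensenTotal(c(a = 1, b = 1, c = 1)), 0.5)
  expect_equal(sorensenTotal(c(a = 2, b = 1, c = 0)), 0.2)
  expect_equal(sorensenTotal(c(a = 5, b = 0, c = 0)), 0)
  expect_equal(sorensenTurnover(c(a = 1, b = 1, c = 1)), 0.5)
  expect_equal(sorensenTurnover(c(a = 2, b = 1, c = 0)), 0)  # pure nestedness
  expect_error(sorensenTotal(c(a = 0, b = 0, c = 0)), "empty")
})

test_that("Faith PD is root-inclusive and matches path enumeration", {
  tr <- smallTree()
  expect_equal(faithPD(c("A", "B"), tr), 3)
  expect_equal(faithPD("A", tr), 2)
  expect_equal(faithPD(c("A", "B", "C", "D"), tr), 6)
  expect_error(faithPD(character(0), tr), "empty")
  expect_error(faithPD("Z", tr), "unknown")
})

test_that("phylogenetic pair components and indices match derived values", {
  tr <- smallTree()
  inc <- rbind(pi = c(1, 1, 0, 0), pj = c(0, 0, 1, 1))
  colnames(inc) <- c("A", "B", "C", "D")
  cm <- new("CommunityTable", incidence = inc)
  ppc <- phyloPairComponents(cm, tr, "pi", "pj")
  expect_equal(ppc[["pd_i"]], 3)
  expect_equal(ppc[["pd_j"]], 3)
  expect_equal(ppc[["pd_tot"]], 6)
  expect_equal(ppc[["a_pd"]], 0)
  expect_equal(phyloSorTotal(ppc), 1)
  expect_equal(phyloSorTurnover(ppc), 1)

  # single-tip plots share the root stem
  inc2 <- rbind(pi = c(1, 0, 0, 0), pj = c(0, 1, 0, 0))
  colnames(inc2) <- c("A", "B", "C", "D")
  cm2 <- new("CommunityTable", incidence = inc2)
  ppc2 <- phyloPairComponents(cm2, tr, "pi", "pj")
  expect_equal(ppc2[["pd_tot"]], 3)
  expect_equal(ppc2[["a_pd"]], 1)

  # identical plots
  ppc3 <- phyloPairComponents(cm, tr, "pi", "pi")
  expect_equal(ppc3[["b_pd"]], 0)
  expect_equal(ppc3[["c_pd"]], 0)
  expect_equal(ppc3[["a_pd"]], ppc3[["pd_i"]])
  expect_equal(phyloSorTotal(ppc3), 0)
})

test_that("all pairwise values equal the brute-force oracle on random data", {
  set.seed(101)
  for (rep in 1:5) {
    tr <- ape::rtree(6)
    cm <- randomCommunity(4, tr$tip.label)
    inc <- incidence(cm)
    spOf <- function(i) colnames(inc)[inc[i, ] > 0]
    for (tag in c("sorensen_total", "sorensen_turnover",
                  "phylosor_total", "phylosor_turnover")) {
      d <- as.matrix(dissimilarityMatrix(cm, tag, tr))
      for (i in 1:3) for (j in (i + 1):4) {
        expected <- switch(tag,
          sorensen_total = oracleSorensenTotal(spOf(i), spOf(j)),
          sorensen_turnover = oracleSorensenTurnover(spOf(i), spOf(j)),
          phylosor_total = oraclePhyloSorTotal(spOf(i), spOf(j), tr),
          phylosor_turnover = oraclePhyloSorTurnover(spOf(i), spOf(j), tr))
        expect_equal(d[i, j], unname(expected), tolerance = 1e-12)
      }
    }
  }
})

test_that("decomposition: total = turnover + nestedness, both non-negative", {
  set.seed(7)
  tr <- ape::rtree(25)
  cm <- randomCommunity(12, tr$tip.label)
  for (fam in c("sorensen", "phylosor")) {
    tot <- as.matrix(dissimilarityMatrix(cm, paste0(fam, "_total"), tr))
    tur <- as.matrix(dissimilarityMatrix(cm, paste0(fam, "_turnover"), tr))
    nes <- as.matrix(dissimilarityMatrix(cm, paste0(fam, "_nestedness"), tr))
    expect_equal(tot, tur + nes, tolerance = 1e-12)
    expect_true(all(tur >= 0) && all(nes >= -1e-12))
    expect_true(all(tot >= 0 & tot <= 1))
  }
})

test_that("phylo indices reduce to taxonomic ones on equal-branch star trees", {
  set.seed(11)
  for (rep in 1:10) {
    tr <- starTree(paste0("s", 1:15), len = runif(1, 0.5, 2))
    cm <- randomCommunity(6, tr$tip.label)
    st <- as.matrix(dissimilarityMatrix(cm, "sorensen_total"))
    pt <- as.matrix(dissimilarityMatrix(cm, "phylosor_total", tr))
    expect_equal(pt, st, tolerance = 1e-12)
    stu <- as.matrix(dissimilarityMatrix(cm, "sorensen_turnover"))
    ptu <- as.matrix(dissimilarityMatrix(cm, "phylosor_turnover", tr))
    expect_equal(ptu, stu, tolerance = 1e-12)
  }
})

test_that("adding a shared species never increases Sorensen total", {
  set.seed(13)
  for (rep in 1:20) {
    ns <- 12
    pool <- paste0("s", seq_len(ns))
    cm <- randomCommunity(2, pool)
    inc <- incidence(cm)
    free <- which(colSums(inc) < 2)
    if (!length(free)) next
    before <- sorensenTotal(pairComponents(cm, 1, 2))
    inc[, sample(free, 1)] <- 1
    after <- sorensenTotal(pairComponents(new("CommunityTable", incidence = inc), 1, 2))
    expect_lte(after, before + 1e-12)
  }
})

test_that("phylosor_total agrees with an independent implementation", {
  skip_if_not_installed("picante")
  set.seed(17)
  tr <- ape::rtree(20)
  cm <- randomCommunity(8, tr$tip.label)
  mine <- as.matrix(dissimilarityMatrix(cm, "phylosor_total", tr))
  ref <- 1 - as.matrix(picante::phylosor(incidence(cm), tr))
  off <- upper.tri(mine)
  expect_equal(mine[off], ref[off], tolerance = 1e-10)
})

test_that("dissimilarity matrices are symmetric with zero diagonal", {
  set.seed(19)
  tr <- ape::rtree(10)
  cm <- randomCommunity(5, tr$tip.label)
  d <- as.matrix(dissimilarityMatrix(cm, "phylosor_turnover", tr))
  expect_identical(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  # identical plots give a zero matrix
  inc <- matrix(rep(c(1, 0, 1, 1, 0), each = 3), 3, 5,
                dimnames = list(paste0("p", 1:3), paste0("s", 1:5)))
  z <- as.matrix(dissimilarityMatrix(new("CommunityTable", incidence = inc),
                                     "sorensen_total"))
  expect_equal(unname(z), matrix(0, 3, 3))
  expect_error(dissimilarityMatrix(cm, "phylosor_total"), "phylogeny")
  expect_error(dissimilarityMatrix(cm, "nosuch"), "unknown metric")
})

test_that("multiple-site Sorensen equals its printed formula", {
  set.seed(23)
  cm <- randomCommunity(5, paste0("s", 1:10))
  inc <- incidence(cm)
  # independent arithmetic straight from the printed expression
  smin <- smax <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    bij <- sum(inc[i, ] == 1 & inc[j, ] == 0)
    bji <- sum(inc[j, ] == 1 & inc[i, ] == 0)
    smin <- smin + min(bij, bji)
    smax <- smax + max(bij, bji)
  }
  st <- sum(colSums(inc) > 0)
  expected <- (smin + smax) / (2 * (sum(inc) - st) + smin + smax)
  expect_equal(multiSiteSorensen(cm), expected, tolerance = 1e-12)
  expect_gte(multiSiteSorensen(cm), 0)
  expect_lte(multiSiteSorensen(cm), 1)
})
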