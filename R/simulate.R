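## Metacommunity simulator with known ground truth.
##
## Chain: birth-death regional phylogeny -> Brownian niche evolution along
## it (one optimum per species per niche axis) -> landscape of plots with
## smooth sinusoidal environmental fields plus noise -> community assembly
## by weighted sampling without replacement, with weights
##   exp(-w * sum_axes (env - optimum)^2) * exp(-dist(plot, seed source)/delta).
## w = 0 and delta = Inf reduce exactly to the richness-preserving null.

#' Simulation parameter list with study-shaped defaults
#'
#' Defaults emulate the shape of a western-Amazonian plot network: 41
#' one-hectare plots over a roughly 2 x 1.5 degree extent (223 x 167 km),
#' a regional pool of 1687 species, correlated climate and soil gradients
#' running broadly west-east, and moderate environmental filtering with a
#' long-range dispersal kernel.
#'
#' @param nPlots number of plots
#' @param nSpecies regional pool size
#' @param birth,death birth-death rates for the phylogeny (birth > death)
#' @param sigma2 Brownian rate per niche axis (named: climate, soil)
#' @param extent landscape extent c(x, y) in km
#' @param wavelengths spatial wavelengths (km) of the environmental
#'   gradients, broad to fine
#' @param nVarsPerClass environmental variables per class
#'   (climate, soil, geomorphology)
#' @param betweenClassCor correlation of each variable with its class's
#'   shared gradient (0 = independent fields)
#' @param noiseSd white-noise sd added to every environmental variable
#' @param filterStrength w >= 0, Gaussian niche-match weight
#'   (inverse squared niche width)
#' @param dispersalScale delta > 0, exponential dispersal-kernel range in
#'   km (Inf = no dispersal limitation)
#' @param richness target species richness per plot
#' @param polytomyEps internal edges shorter than this are collapsed to
#'   polytomies (genus-level lack of resolution); 0 disables
#' @param seed RNG seed recorded in the output metadata
#' @return a named list of class-checked simulation parameters
#' @export
simulationParams <- function(nPlots = 41, nSpecies = 1687,
                             birth = 1, death = 0.2,
                             sigma2 = c(climate = 1, soil = 1),
                             extent = c(223, 167),
                             wavelengths = c(150, 30, 5),
                             nVarsPerClass = c(climate = 19, soil = 9,
                                               geomorphology = 4),
                             betweenClassCor = 0.6, noiseSd = 0.3,
                             filterStrength = 2, dispersalScale = 150,
                             richness = 250, polytomyEps = 0.01,
                             seed = NULL) {
  stopifnot(birth > death, death >= 0, all(sigma2 >= 0),
            filterStrength >= 0, dispersalScale > 0,
            richness <= nSpecies, all(extent > 0))
  list(nPlots = nPlots, nSpecies = nSpecies, birth = birth, death = death,
       sigma2 = sigma2, extent = extent, wavelengths = wavelengths,
       nVarsPerClass = nVarsPerClass, betweenClassCor = betweenClassCor,
       noiseSd = noiseSd, filterStrength = filterStrength,
       dispersalScale = dispersalScale, richness = richness,
       polytomyEps = polytomyEps, seed = seed)
}

#' Simulate a birth-death regional phylogeny
#'
#' Birth-death tree conditioned on the number of extant tips
#' (ape::rphylo), hence ultrametric, with an optional collapse of short
#' internal edges into polytomies to mimic genus-level lack of resolution.
#'
#' @param nSpecies number of tips
#' @param birth,death rates (birth > death >= 0)
#' @param polytomyEps collapse internal edges shorter than this fraction
#'   of tree depth (0 = keep binary)
#' @param seed optional RNG seed
#' @return an ape phylo with tips "sp1".."spN"
#' @export
simulatePhylogeny <- function(nSpecies, birth = 1, death = 0.2,
                              polytomyEps = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(birth > death, death >= 0, nSpecies >= 2)
  tr <- NULL
  for (try in 1:20) {
    tr <- tryCatch(ape::rphylo(nSpecies, birth = birth, death = death),
                   error = function(e) NULL)
    if (!is.null(tr)) break
  }
  if (is.null(tr)) stop("phylogeny simulation failed after 20 retries")
  tr$tip.label <- paste0("sp", seq_len(nSpecies))
  if (polytomyEps > 0) {
    depth <- max(ape::node.depth.edgelength(tr))
    tr <- ape::di2multi(tr, tol = polytomyEps * depth)
  }
  tr
}

#' Evolve niche optima along a phylogeny by Brownian motion
#'
#' One independent Brownian axis per entry of \code{sigma2}; a rate of 0
#' gives perfect conservatism (all tips at the root value).
#'
#' @param tree an ape phylo
#' @param sigma2 named numeric of per-axis Brownian rates (variance per
#'   unit branch length)
#' @param rootValue ancestral value per axis (recycled)
#' @param seed optional RNG seed
#' @return tips x axes matrix of niche optima
#' @export
evolveNicheTraits <- function(tree, sigma2, rootValue = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(sigma2 >= 0))
  rootValue <- rep_len(rootValue, length(sigma2))
  out <- vapply(seq_along(sigma2), function(a) {
    if (sigma2[a] == 0) rep(rootValue[a], length(tree$tip.label))
    else ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2[a]),
                         root.value = rootValue[a])[tree$tip.label]
  }, numeric(length(tree$tip.label)))
  dimnames(out) <- list(tree$tip.label,
                        names(sigma2) %||% paste0("axis", seq_along(sigma2)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## smooth sinusoidal field over (x, y): sum over the configured wavelengths
## of a sinusoid with the given orientation and phase
.sinField <- function(x, y, wavelengths, angles, phases, amps) {
  v <- 0
  for (g in seq_along(wavelengths)) {
    s <- x * cos(angles[g]) + y * sin(angles[g])
    v <- v + amps[g] * sin(2 * pi * s / wavelengths[g] + phases[g])
  }
  v
}

#' Build a synthetic landscape: plot coordinates and environment
#'
#' Plots are placed uniformly over the extent. Each environmental variable
#' is a mixture of its class's shared gradient field (weight
#' \code{sqrt(betweenClassCor)}) and an own random-orientation sinusoid
#' field, plus white noise. Shared class fields run along the x axis
#' (the study region's dominant west-east climate gradient); their values
#' at the plots are returned as the true niche fields used by assembly.
#'
#' @param params a \code{\link{simulationParams}} list
#' @param seed optional RNG seed
#' @return list with \code{coordinates} (\linkS4class{PlotCoordinates}),
#'   \code{environment} (\linkS4class{EnvironmentTable}) and
#'   \code{nicheFields} (plots x 2 matrix: true climate and soil gradient
#'   values, z-scored)
#' @export
buildLandscape <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- params$nPlots
  x <- runif(n, 0, params$extent[1])
  y <- runif(n, 0, params$extent[2])
  ids <- sprintf("plot%02d", seq_len(n))
  coords <- plotCoordinates(x, y, ids)
  wl <- params$wavelengths
  ng <- length(wl)
  classes <- rep(names(params$nVarsPerClass), params$nVarsPerClass)
  ## shared field per class: x-oriented sinusoids, fixed phase
  sharedAngles <- c(climate = 0, soil = 0, geomorphology = pi / 6)
  sharedPhase <- c(climate = 0, soil = pi / 3, geomorphology = pi / 2)
  shared <- sapply(unique(classes), function(cl)
    .sinField(x, y, wl, rep(sharedAngles[[cl]], ng),
              rep(sharedPhase[[cl]], ng), amps = 1 / seq_len(ng)))
  rho <- params$betweenClassCor
  vals <- sapply(seq_along(classes), function(v) {
    own <- .sinField(x, y, wl, angles = runif(ng, 0, pi),
                     phases = runif(ng, 0, 2 * pi), amps = 1 / seq_len(ng))
    f <- sqrt(rho) * shared[, classes[v]] + sqrt(1 - rho) * own
    f + rnorm(n, 0, params$noiseSd)
  })
  colnames(vals) <- paste0(classes, ave(seq_along(classes), classes, FUN = seq_along))
  rownames(vals) <- ids
  ## environmental measurements are non-negative quantities in the field;
  ## shift to positive scale so the sqrt transform applies
  vals <- vals - min(vals) + 1
  env <- environmentTable(vals, classes)
  niche <- scale(shared[, c("climate", "soil")])
  rownames(niche) <- ids
  list(coordinates = coords, environment = env, nicheFields = niche)
}

#' Assemble communities under environmental filtering and dispersal
#'
#' Each plot draws \code{richness} species without replacement with
#' probability proportional to
#' \code{exp(-w * sum_axes (env - optimum)^2) * exp(-d(plot, source)/delta)}
#' where the per-species seed source is a uniform random location. With
#' w = 0 and delta = Inf this is exactly the richness-preserving null.
#'
#' @param tree the regional phylogeny
#' @param nicheOptima tips x axes matrix (z-scored internally to match the
#'   z-scored niche fields)
#' @param landscape output of \code{\link{buildLandscape}}
#' @param params a \code{\link{simulationParams}} list
#' @param seed optional RNG seed
#' @return list with \code{community} (\linkS4class{CommunityTable}) and
#'   \code{seedSources} (species x 2 matrix, km)
#' @export
assembleCommunities <- function(tree, nicheOptima, landscape, params,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- tree$tip.label
  ns <- length(sp)
  if (params$richness > ns) stop("target richness exceeds pool size")
  src <- cbind(x = runif(ns, 0, params$extent[1]),
               y = runif(ns, 0, params$extent[2]))
  rownames(src) <- sp
  opt <- nicheOptima[sp, , drop = FALSE]
  opt <- apply(opt, 2, function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0)
  niche <- landscape$nicheFields
  coords <- landscape$coordinates@coords
  n <- nrow(coords)
  inc <- matrix(0, n, ns, dimnames = list(rownames(coords), sp))
  w <- params$filterStrength
  delta <- params$dispersalScale
  for (i in seq_len(n)) {
    mismatch <- rowSums((matrix(niche[i, ], ns, ncol(opt), byrow = TRUE) - opt)^2)
    lw <- -w * mismatch
    if (is.finite(delta)) {
      d <- sqrt((src[, 1] - coords[i, 1])^2 + (src[, 2] - coords[i, 2])^2)
      lw <- lw - d / delta
    }
    pr <- exp(lw - max(lw))
    inc[i, sample.int(ns, params$richness, prob = pr)] <- 1
  }
  list(community = new("CommunityTable", incidence = inc), seedSources = src)
}

#' Generate a full synthetic dataset with ground truth
#'
#' Runs the simulation chain (phylogeny, niche evolution, landscape,
#' assembly) and validates the result into a single object. The same seed
#' always produces a bit-identical dataset.
#'
#' @param params a \code{\link{simulationParams}} list
#' @param seed RNG seed (overrides \code{params$seed})
#' @return a \linkS4class{SyntheticDataset}
#' @export
generateDataset <- function(params = simulationParams(), seed = params$seed) {
  if (is.null(seed)) stop("a seed is required for reproducible generation")
  set.seed(seed)
  params$seed <- seed
  tree <- simulatePhylogeny(params$nSpecies, params$birth, params$death,
                            polytomyEps = params$polytomyEps)
  optima <- evolveNicheTraits(tree, params$sigma2)
  land <- buildLandscape(params)
  asm <- assembleCommunities(tree, optima, land, params)
  vd <- validateDataset(asm$community, tree, land$environment,
                        land$coordinates, onMissingTip = "error")
  new("SyntheticDataset", community = vd@community, phylogeny = vd@phylogeny,
      environment = vd@environment, coordinates = vd@coordinates,
      droppedSpecies = character(0), nicheOptima = optima,
      seedSources = asm$seedSources, params = params)
}
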