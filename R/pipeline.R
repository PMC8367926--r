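## Config-driven orchestration of the full analysis chain on real or
## synthetic inputs. Stages mirror the study workflow: transforms ->
## dissimilarity matrices (Sorensen/PhyloSorensen, total and turnover) ->
## NMDS -> climate PCA -> forward selection -> db-RDA with per-axis
## permutation tests -> beta NRI/NTI with null envelopes -> PCNM ->
## scale-stratified variance partitioning. Every run writes its tables and
## a manifest (seed, config, package version) to the output directory.

#' Default pipeline configuration
#'
#' Two profiles: "full" mirrors the analysis defaults (999 null
#' iterations, 1000 NMDS starts, 9999 forward-selection permutations, 1000
#' axis-test permutations, alpha 0.05); "test" scales every count down for
#' fast desk runs.
#'
#' @param profile "full" or "test"
#' @param seed mandatory RNG seed
#' @param outputDir directory for result tables (NULL = do not write)
#' @param simulation a \code{\link{simulationParams}} list (used when no
#'   input paths are given)
#' @param inputs optional named list of file paths: community, tree,
#'   environment, classMap, coordinates
#' @return a config list for \code{\link{runPipeline}}
#' @export
pipelineConfig <- function(profile = c("test", "full"), seed = 1L,
                           outputDir = NULL, simulation = simulationParams(),
                           inputs = NULL) {
  profile <- match.arg(profile)
  full <- profile == "full"
  list(profile = profile, seed = seed, outputDir = outputDir,
       simulation = simulation, inputs = inputs,
       nullIter = if (full) 999 else 99,
       nmdsStarts = if (full) 1000 else 20,
       fwPerm = if (full) 9999 else 199,
       axisPerm = if (full) 1000 else 199,
       alpha = 0.05)
}

.loadOrSimulate <- function(config) {
  if (!is.null(config$inputs)) {
    ip <- config$inputs
    for (f in c("community", "tree", "environment", "classMap", "coordinates"))
      if (!file.exists(ip[[f]]))
        stop(sprintf("missing input path for '%s': %s", f, ip[[f]]))
    validateDataset(readCommunityTable(ip$community),
                    readNewickTree(ip$tree),
                    readEnvironmentTable(ip$environment, ip$classMap),
                    readCoordinates(ip$coordinates))
  } else {
    generateDataset(config$simulation, seed = config$seed)
  }
}

#' Run the full analysis pipeline
#'
#' @param config a \code{\link{pipelineConfig}} list
#' @return invisible list bundle: dataset, dissimilarities, NMDS results,
#'   climate PCA, forward-selection trace, db-RDA, SES matrices with
#'   envelopes, PCNM basis, per-scale variance partitions, manifest
#' @export
runPipeline <- function(config = pipelineConfig()) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch({
      r <- force(expr)
      message(sprintf("[%s] done (%.1fs)", name,
                      as.numeric(Sys.time() - t0, units = "secs")))
      r
    }, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  ds <- stage("load", .loadOrSimulate(config))
  set.seed(config$seed)
  env <- stage("transforms", applyTransforms(ds@environment))
  cls <- variableClasses(env)
  envMat <- as.matrix(env)
  tags <- c("sorensen_total", "sorensen_turnover",
            "phylosor_total", "phylosor_turnover")
  diss <- stage("dissimilarity", lapply(stats::setNames(tags, tags), function(tg)
    dissimilarityMatrix(ds@community, tg, ds@phylogeny)))
  nmds <- stage("nmds", lapply(diss[c("sorensen_turnover", "phylosor_turnover")],
                               nmdsOrdination, k = 2, nStarts = config$nmdsStarts))
  climPca <- stage("climate_pca",
                   pcaOrdination(envMat[, cls == "climate", drop = FALSE]))
  fw <- stage("forward_selection", lapply(nmds, function(ord)
    forwardSelect(ordScores(ord), envMat, alpha = config$alpha,
                  nPerm = config$fwPerm)))
  dbr <- stage("dbrda", lapply(diss[c("sorensen_turnover", "phylosor_turnover")],
                               function(d) {
    sel <- fw[[if (grepl("^phylosor", metricTag(d))) "phylosor_turnover"
               else "sorensen_turnover"]]@selected
    ## empty selection: constrain on the leading environmental PCA axes so
    ## the db-RDA stays well-posed whatever the plot/variable ratio
    X <- if (length(sel)) envMat[, sel, drop = FALSE]
         else ordScores(pcaOrdination(envMat))[, 1:2, drop = FALSE]
    dbRDA(d, X, nPerm = config$axisPerm)
  }))
  ses <- stage("ses", {
    nri <- betaNRI(ds@community, ds@phylogeny, nIter = config$nullIter)
    nti <- betaNTI(ds@community, ds@phylogeny, nIter = config$nullIter)
    ens <- nullTurnover(ds@community, "phylosor_turnover",
                        nIter = config$nullIter, phylogeny = ds@phylogeny)
    list(betaNRI = nri, betaNTI = nti, turnoverEnsemble = ens,
         envelope = nullEnvelope(ens))
  })
  pcnm <- stage("pcnm", classifyScale(pcnmBasis(ds@coordinates)))
  vp <- stage("varpart", {
    envSets <- list(Climate = envMat[, cls == "climate", drop = FALSE],
                    Soils = envMat[, cls == "soil", drop = FALSE],
                    Geomorphology = envMat[, cls == "geomorphology", drop = FALSE])
    ## PCA axis 1 per environmental set, as in the study's partition models
    envAxes <- lapply(envSets, function(m)
      ordScores(pcaOrdination(m))[, 1, drop = FALSE])
    resp <- ordScores(nmds$phylosor_turnover)
    scales <- intersect(c("broad", "mid", "fine"), unique(scaleClasses(pcnm)))
    perScale <- lapply(stats::setNames(scales, scales), function(sc)
      scaleStratifiedPartition(resp, envAxes, pcnm, sc))
    full <- partitionVariation(resp, c(envAxes,
      list(Space = as.matrix(pcnm)[, seq_len(min(6, ncol(as.matrix(pcnm)))),
                                   drop = FALSE])))
    list(full = full, perScale = perScale)
  })
  manifest <- list(seed = config$seed, profile = config$profile,
                   package = as.character(utils::packageVersion("PhyloTurnover")),
                   rversion = R.version.string,
                   nPlots = length(plotIds(ds)),
                   nSpecies = length(speciesIds(ds)),
                   timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"))
  bundle <- list(dataset = ds, environment = env, dissimilarity = diss,
                 nmds = nmds, climatePca = climPca, forwardSelection = fw,
                 dbrda = dbr, ses = ses, pcnm = pcnm, varpart = vp,
                 manifest = manifest)
  if (!is.null(config$outputDir)) writePipelineBundle(bundle, config)
  invisible(bundle)
}

#' Write a pipeline bundle's tables and manifest to a directory
#' @param bundle the list returned by \code{\link{runPipeline}}
#' @param config the config that produced it
#' @export
writePipelineBundle <- function(bundle, config) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  od <- function(f) file.path(config$outputDir, f)
  for (tg in names(bundle$dissimilarity))
    writeDissimilarityMatrix(bundle$dissimilarity[[tg]], od(paste0(tg, ".csv")))
  for (nm in names(bundle$nmds)) {
    sc <- ordScores(bundle$nmds[[nm]])
    write.csv(data.frame(plot = rownames(sc), sc), od(paste0("nmds_", nm, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  write.csv(ensembleSummary(bundle$ses$turnoverEnsemble),
            od("ses_turnover_summary.csv"), row.names = FALSE, quote = FALSE)
  writePCNMBasis(bundle$pcnm, od("pcnm.csv"))
  writeVariancePartition(bundle$varpart$full, od("varpart_full.csv"))
  for (sc in names(bundle$varpart$perScale))
    writeVariancePartition(bundle$varpart$perScale[[sc]],
                           od(paste0("varpart_", sc, ".csv")))
  cfg <- config
  cfg$simulation$sigma2 <- as.list(cfg$simulation$sigma2)
  jsonlite::write_json(list(manifest = bundle$manifest,
                            config = cfg[setdiff(names(cfg), "inputs")]),
                       od("manifest.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(config$outputDir)
}
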