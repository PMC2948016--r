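#' Assemble and validate a pipeline configuration
#'
#' Orchestrates the full analysis replica: data input (a simulation config
#' or PED/MAP paths plus breed metadata), the QC cascade, diversity and
#' F-statistics, distance trees with bootstrap, PCA / between-breed PCA,
#' spatial PCA, and admixture. One master seed fans out to per-stage seeds
#' by fixed offsets so stages can be rerun in isolation.
#'
#' @param sim a [SimConfig-class], or NULL when reading files.
#' @param pedPath,mapPath,breedTablePath input paths (used when \code{sim}
#'   is NULL; \code{breedTablePath} supplies group labels and coordinates).
#' @param stages character subset of
#'   c("qc", "stats", "trees", "pca", "spca", "admixture").
#' @param minCallRate,hweQ QC cascade parameters.
#' @param nBoot bootstrap replicates for the breed tree.
#' @param maxAxes axes kept in ordinations.
#' @param admixtureK integer vector of K values.
#' @param admixtureMaxIter,admixtureStarts EM iteration cap and random
#'   restarts per K (desk-scale defaults; raise for production runs).
#' @param seed master seed.
#' @param outDir output directory (created; artifacts are TSV/Newick/JSON).
#' @return a validated configuration list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(sim = NULL, pedPath = NULL, mapPath = NULL,
                           breedTablePath = NULL,
                           stages = c("qc", "stats", "trees", "pca", "spca",
                                      "admixture"),
                           minCallRate = 0.75, hweQ = 0.05, nBoot = 100,
                           maxAxes = 10, admixtureK = 2:3,
                           admixtureMaxIter = 200, admixtureStarts = 2,
                           seed = 1L,
                           outDir = tempfile("herdstruct_run_")) {
  known <- c("qc", "stats", "trees", "pca", "spca", "admixture")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  if (is.null(sim) && (is.null(pedPath) || is.null(mapPath) ||
                       is.null(breedTablePath)))
    stop("supply either a simulation config or PED/MAP + breed table paths")
  if (!is.null(sim)) validObject(sim)
  structure(list(sim = sim, pedPath = pedPath, mapPath = mapPath,
                 breedTablePath = breedTablePath, stages = stages,
                 minCallRate = minCallRate, hweQ = hweQ, nBoot = nBoot,
                 maxAxes = maxAxes, admixtureK = admixtureK,
                 admixtureMaxIter = admixtureMaxIter,
                 admixtureStarts = admixtureStarts,
                 seed = as.integer(seed), outDir = outDir),
            class = "PipelineConfig")
}

.stageSeed <- function(seed, offset) (as.integer(seed) + offset) %% .Machine$integer.max

#' Run the full pipeline
#'
#' Stages run in the study's order (QC, polymorphism summaries, structure
#' analyses); each writes its artifacts under \code{outDir} and contributes
#' counts, headline statistics and wall time to the JSON run report. A
#' stage whose inputs were toggled off fails fast with a clear message.
#' Every artifact is reproducible from the configuration and seed alone;
#' the report carries an md5 manifest of all files written.
#'
#' @param cfg a \code{PipelineConfig} from [pipelineConfig()].
#' @return the run report (named list), invisibly written to
#'   \code{outDir/report.json}.
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg[setdiff(names(cfg), "sim")],
                 seed = cfg$seed, stages = list())
  manifest <- character(0)
  tick <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(value = val, seconds = round(proc.time()[["elapsed"]] - t0, 3))
  }
  emit <- function(path) manifest <<- c(manifest, path)
  guard <- function(stage, expr) {
    # abort with the stage name; the partial manifest is still written
    tryCatch(expr, error = function(e) {
      report$manifest <- lapply(manifest, function(p)
        list(file = basename(p), md5 = unname(tools::md5sum(p))))
      report$failedStage <- stage
      writeJsonReport(report, file.path(cfg$outDir, "report.json"))
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- input ---------------------------------------------------------------
  if (!is.null(cfg$sim)) {
    simRes <- simulatePanel(cfg$sim)
    panel <- simRes$panel
    breedInfo <- simRes$breedInfo
  } else {
    panel <- readPlink(cfg$pedPath, cfg$mapPath)
    breedInfo <- readBreedTable(cfg$breedTablePath)
  }
  report$input <- list(nSnps = nrow(panel), nIndividuals = ncol(panel),
                       nBreeds = length(breedNames(panel)))
  groupOf <- setNames(breedInfo$group, breedInfo$breed)

  # --- qc ------------------------------------------------------------------
  if ("qc" %in% cfg$stages) {
    st <- guard("qc", tick(runCascade(panel, minRate = cfg$minCallRate,
                                      qThreshold = cfg$hweQ)))
    panel <- st$value$panel
    rp <- st$value$report
    emit(writeMatrixTsv(as.matrix(table(rp@perSnp$stage)),
                        file.path(cfg$outDir, "qc_stage_counts.tsv")))
    report$stages$qc <- list(
      seconds = st$seconds, nInput = rp@nInput,
      droppedCallrate = rp@nDroppedCallrate,
      droppedMonomorphic = rp@nDroppedMonomorphic,
      droppedHwe = rp@nDroppedHwe, nRetained = rp@nRetained)
  }
  freqTab <- computeBreedFreqs(panel)

  # --- stats ---------------------------------------------------------------
  if ("stats" %in% cfg$stages) {
    st <- guard("stats", tick({
      het <- heterozygosityByBreed(panel)
      fst <- wcFstats(panel)
      fis <- fisByBreed(panel, nResample = 100,
                        snpsPerSample = min(1000, nrow(panel)),
                        seed = .stageSeed(cfg$seed, 11L))
      pw <- pairwiseFst(panel)
      list(het = het, fst = fst, fis = fis, pw = pw)
    }))
    v <- st$value
    write.table(v$het, file.path(cfg$outDir, "heterozygosity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(cfg$outDir, "heterozygosity.tsv"))
    write.table(v$fis, file.path(cfg$outDir, "fis.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit(file.path(cfg$outDir, "fis.tsv"))
    emit(writeMatrixTsv(v$pw, file.path(cfg$outDir, "pairwise_fst.tsv")))
    report$stages$stats <- list(
      seconds = st$seconds, F = v$fst$F, theta = v$fst$theta, f = v$fst$f,
      nLociUsed = v$fst$nLociUsed,
      meanHeterozygosity = mean(v$het$meanHe))
  }

  # --- trees ---------------------------------------------------------------
  if ("trees" %in% cfg$stages) {
    st <- guard("trees", tick({
      breedTree <- bootstrapSupport(freqTab, "reynolds", nBoot = cfg$nBoot,
                                    seed = .stageSeed(cfg$seed, 23L))
      asd <- asdMatrix(panel)
      indTree <- njTree(asd)
      list(breedTree = breedTree, indTree = indTree)
    }))
    emit(writeNewick(st$value$breedTree,
                     file.path(cfg$outDir, "breed_tree.nwk")))
    emit(writeNewick(st$value$indTree,
                     file.path(cfg$outDir, "individual_tree.nwk")))
    report$stages$trees <- list(
      seconds = st$seconds, nBoot = cfg$nBoot,
      minSupport = min(st$value$breedTree$node.label),
      maxSupport = max(st$value$breedTree$node.label))
  }

  # --- pca -----------------------------------------------------------------
  if ("pca" %in% cfg$stages) {
    st <- guard("pca", tick({
      pcaRes <- pcaGenotypes(panel, nAxes = cfg$maxAxes)
      bcaRes <- betweenBreedPca(panel, nAxes = cfg$maxAxes)
      list(pca = pcaRes, bca = bcaRes)
    }))
    emit(writeMatrixTsv(st$value$pca@scores,
                        file.path(cfg$outDir, "pca_scores.tsv")))
    emit(writeMatrixTsv(st$value$bca@extra$breedScores,
                        file.path(cfg$outDir, "bca_breed_scores.tsv")))
    k <- min(5, ncol(st$value$pca@loadings), ncol(st$value$bca@loadings))
    report$stages$pca <- list(
      seconds = st$seconds,
      varFraction = st$value$pca@varFraction,
      betweenBreedShare = st$value$bca@extra$variancePartition,
      axisCorrelations = compareAxes(st$value$pca, st$value$bca, k))
  }

  # --- spca ----------------------------------------------------------------
  if ("spca" %in% cfg$stages) {
    st <- guard("spca", tick({
      if (!all(c("lon", "lat") %in% names(breedInfo)) ||
          anyNA(breedInfo$lon) || anyNA(breedInfo$lat))
        stop("breed coordinates (lon, lat) are required for spatial PCA")
      coords <- data.frame(lon = breedInfo$lon, lat = breedInfo$lat,
                           row.names = breedInfo$breed)
      graph <- gabrielGraph(coords)
      spcaRes <- spca(freqTab, graph)
      list(graph = graph, spca = spcaRes,
           rgb = colorplotScores(spcaRes, k = min(3, ncol(spcaRes@scores))))
    }))
    emit(writeMatrixTsv(st$value$spca@scores,
                        file.path(cfg$outDir, "spca_scores.tsv")))
    emit(writeMatrixTsv(st$value$rgb,
                        file.path(cfg$outDir, "spca_colorplot.tsv")))
    ev <- st$value$spca@eigenvalues
    report$stages$spca <- list(
      seconds = st$seconds, nEdges = sum(st$value$graph@adjacency) / 2,
      eigenvalues = ev[seq_len(min(3, length(ev)))],
      moranAxis1 = st$value$spca@moranAxis[1])
  }

  # --- admixture -----------------------------------------------------------
  if ("admixture" %in% cfg$stages) {
    st <- guard("admixture", tick(admixtureScan(
      panel, cfg$admixtureK, maxIter = cfg$admixtureMaxIter,
      nStarts = cfg$admixtureStarts, seed = .stageSeed(cfg$seed, 37L))))
    for (nm in names(st$value$fits)) {
      emit(writeMatrixTsv(st$value$fits[[nm]]@Q,
                          file.path(cfg$outDir, paste0("Q_", nm, ".tsv"))))
    }
    report$stages$admixture <- list(
      seconds = st$seconds,
      loglik = setNames(as.list(st$value$table$loglik),
                        paste0("K", st$value$table$K)),
      converged = all(st$value$table$converged))
  }

  report$manifest <- lapply(manifest, function(p)
    list(file = basename(p), md5 = unname(tools::md5sum(p))))
  writeJsonReport(report, file.path(cfg$outDir, "report.json"))
  invisible(report)
}
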