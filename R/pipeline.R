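## End-to-end orchestration: filter -> diversity -> distances/tree/PCA ->
## core -> evaluation, with a fixed artifact layout and a run log.

#' Configure a pipeline run
#'
#' Exactly one of `input` (paths to existing genotype data) or `simulate`
#' (a [SimulationConfig-class]) must be given.
#'
#' @param input `NULL`, or a list with `genotypes` (path), `format`
#'   (`"tsv"`/`"vcf"`), optional `loci` (TSV side file) and `popmap`
#'   (two-column TSV) paths.
#' @param simulate `NULL` or a [SimulationConfig-class].
#' @param mafMin,callRateMin locus filter thresholds (defaults 0.01 / 0.5).
#' @param polymorphicOnly locus-inclusion policy of the per-region table.
#' @param coreSize target core size (`NULL` = smallest greedy-coverage-0.999
#'   size).
#' @param wMr,wSh core objective weights.
#' @param restarts,maxIter,rngSeed core search controls.
#' @return a validated config (list of class `"wildcorePipelineConfig"`).
#' @export
pipelineConfig <- function(input = NULL, simulate = NULL, mafMin = 0.01,
                           callRateMin = 0.5, polymorphicOnly = TRUE,
                           coreSize = NULL, wMr = 0.7, wSh = 0.3,
                           restarts = 1, maxIter = 500, rngSeed = 1) {
  if (is.null(input) == is.null(simulate))
    stop("exactly one of 'input' or 'simulate' must be given")
  if (!is.null(input)) {
    stopifnot(is.list(input), !is.null(input$genotypes))
    if (!file.exists(input$genotypes))
      stop("input genotype file not found: ", input$genotypes)
    for (f in c(input$loci, input$popmap))
      if (!file.exists(f)) stop("input file not found: ", f)
  } else stopifnot(is(simulate, "SimulationConfig"))
  structure(list(input = input, simulate = simulate, mafMin = mafMin,
                 callRateMin = callRateMin, polymorphicOnly = polymorphicOnly,
                 coreSize = coreSize, wMr = wMr, wSh = wSh,
                 restarts = restarts, maxIter = maxIter, rngSeed = rngSeed),
            class = "wildcorePipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load or simulate genotypes; filter loci; per-region
#' diversity table; modified Rogers accession distances; Nei population
#' distances and region NJ tree; PCA; greedy coverage curve; core
#' optimization (population priority); core NJ tree; per-region origin
#' counts; retention report; PCA overlay. Each artifact is written into
#' `outDir`; a failing stage aborts with a stage-named error and earlier
#' artifacts are retained. Re-running with the identical config reproduces
#' identical non-log artifacts.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the loaded/filtered genotypes, the core
#'   selection, and the named artifact paths.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "wildcorePipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run_log.txt")
  logLines <- c(sprintf("wildcore %s | R %s",
                        as.character(utils::packageVersion("wildcore")),
                        paste(R.version$major, R.version$minor, sep = ".")),
                sprintf("rngSeed: %s", config$rngSeed))
  art <- list()
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      writeLines(c(logLines, sprintf("FAILED at stage '%s'", name)), logPath)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    logLines <<- c(logLines, sprintf("stage %-12s %8.2fs", name,
                                     proc.time()[["elapsed"]] - s))
    out
  }

  g <- stage("load", {
    if (!is.null(config$simulate)) {
      sim <- simulateGenotypes(config$simulate)
      art$truth <- writeSimulationTruth(sim$truth,
                                         file.path(outDir, "truth.json"))
      sim$genotypes
    } else {
      gg <- readGenotypes(config$input$genotypes,
                          format = if (is.null(config$input$format)) "tsv"
                                   else config$input$format,
                          lociPath = config$input$loci)
      if (!is.null(config$input$popmap))
        gg <- attachPopulations(gg, config$input$popmap)
      gg
    }
  })
  g <- stage("filter", filterLoci(g, config$mafMin, config$callRateMin))
  art$genotypes <- file.path(outDir, "filtered_genotypes.tsv")
  stage("write", {
    writeGenotypes(g, art$genotypes, format = "tsv")
    if (!is.null(populations(g)))
      art$popmap <- writePopulations(g, file.path(outDir, "populations.tsv"))
  })
  logLines <- c(logLines, sprintf("loci kept: %d | accessions: %d",
                                  nrow(g), ncol(g)))

  stage("diversity", {
    art$table1 <- writeDiversityTable(
      summaryTable(g, config$polymorphicOnly),
      file.path(outDir, "table1_diversity.tsv"))
  })
  D <- stage("distance", modifiedRogers(g))
  art$mrDist <- writeDistanceMatrix(D, file.path(outDir, "dist_accessions_mr.tsv"))
  stage("tree", {
    DN <- neiDistance(g)
    art$neiDist <- writeDistanceMatrix(DN, file.path(outDir,
                                                      "dist_populations_nei.tsv"))
    art$regionTree <- file.path(outDir, "tree_regions.nwk")
    ape::write.tree(neighborJoining(DN), art$regionTree)
  })
  stage("pca", {
    art$pca <- writePcaScores(genoPCA(g, 2),
                               file.path(outDir, "pca_scores.tsv"),
                               labels = unname(populations(g)))
  })
  curve <- stage("coverage", coverageRanking(g))
  art$coverage <- file.path(outDir, "coverage_curve.tsv")
  write.table(curve, art$coverage, sep = "\t", quote = FALSE, row.names = FALSE)
  core <- stage("core", optimizeCore(
    g, size = config$coreSize, wMr = config$wMr, wSh = config$wSh,
    restarts = config$restarts, maxIter = config$maxIter,
    rngSeed = config$rngSeed, D = D))
  art$core <- writeCoreSelection(core, file.path(outDir, "core.json"))
  logLines <- c(logLines, sprintf("core size: %d | objective: %.6f | moves: %d",
                                  coreSize(core), core@objective,
                                  length(core@trace) - 1L))
  stage("coretree", {
    art$coreTree <- file.path(outDir, "tree_core.nwk")
    ape::write.tree(neighborJoining(D[selectedIds(core), selectedIds(core)]),
                    art$coreTree)
  })
  stage("evaluate", {
    tab2 <- withTotalsRow(countsByRegion(core, g))
    art$table2 <- file.path(outDir, "table2_origins.csv")
    write.csv(tab2, art$table2, row.names = FALSE)
    tab3 <- compareCore(g, core)
    art$table3 <- file.path(outDir, "table3_retention.csv")
    write.csv(tab3, art$table3, row.names = FALSE)
    art$overlay <- file.path(outDir, "pca_overlay.tsv")
    write.table(pcaOverlay(g, core), art$overlay, sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  logLines <- c(logLines, sprintf("total %8.2fs", proc.time()[["elapsed"]] - t0))
  writeLines(logLines, logPath)
  art$log <- logPath
  invisible(list(genotypes = g, core = core, artifacts = art))
}
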