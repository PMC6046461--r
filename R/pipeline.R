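# End-to-end orchestration on real or simulated inputs: simulate/load ->
# filter -> per-contrast DE -> ranking -> 1D enrichment -> Gsheat -> 2D
# enrichment -> comparison reports, with deterministic seeding and a
# checksum manifest.

#' Pipeline configuration
#'
#' Either file paths (counts, sample sheet, GMT) or a simulation config
#' must be supplied. The two contrasts default to the within-age sham vs
#' DOCA comparisons of the factorial design.
#'
#' @param countsPath,samplesPath,gmtPath input files (TSV counts, TSV
#'   sample sheet, GMT collection); ignored when \code{sim} is given.
#' @param sim optional \code{simConfig}; when present, inputs are
#'   simulated (a random collection of \code{nSets} sets is generated
#'   over the simulated universe).
#' @param nSets,setSizeRange collection size parameters for simulated
#'   runs.
#' @param minMean low-count filter threshold (default 10).
#' @param deFdr,gseaFdr significance thresholds (default 0.05).
#' @param nPerm permutations for the 1D enrichment stage.
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically.
#' @param outDir output directory (created if absent).
#' @return A list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(countsPath = NULL, samplesPath = NULL,
                           gmtPath = NULL, sim = NULL, nSets = 100L,
                           setSizeRange = c(10L, 50L), minMean = 10,
                           deFdr = 0.05, gseaFdr = 0.05, nPerm = 1000L,
                           seed = 1L, outDir = tempfile("csrun")) {
  if (is.null(sim) &&
      (is.null(countsPath) || is.null(samplesPath) || is.null(gmtPath)))
    stop("either file paths or a simulation config must be supplied")
  if (deFdr <= 0 || deFdr >= 1 || gseaFdr <= 0 || gseaFdr >= 1)
    stop("FDR thresholds must lie in (0,1)")
  structure(list(countsPath = countsPath, samplesPath = samplesPath,
                 gmtPath = gmtPath, sim = sim, nSets = as.integer(nSets),
                 setSizeRange = as.integer(setSizeRange),
                 minMean = minMean, deFdr = deFdr, gseaFdr = gseaFdr,
                 nPerm = as.integer(nPerm), seed = as.integer(seed),
                 outDir = outDir),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{pipelineConfig}; a
#' \code{sim:} block holds \code{simulationConfig} arguments.
#'
#' @param path YAML file.
#' @return A \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    simArgs <- y$sim
    if (!is.null(simArgs$groupSizes))
      simArgs$groupSizes <- unlist(simArgs$groupSizes)
    y$sim <- do.call(simulationConfig, simArgs)
  }
  do.call(pipelineConfig, y)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, filtering, both within-age DE contrasts,
#' ranked-list export, 1D permutation enrichment, Gsheat scoring with
#' differential set testing and enrichment-map export, 2D multi-contrast
#' enrichment with quadrant classification, contrast comparison (overlap
#' counts and rank-rank grid), PCA coordinates and MA tables. Every
#' output is a deterministic TSV under \code{outDir}; a manifest of MD5
#' checksums is written last, so identical config + seed reproduce
#' identical manifests.
#'
#' @param config a \code{pipelineConfig}.
#' @return Invisibly, a list with the manifest data.frame, the output
#'   directory and the in-memory stage results.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  out <- config$outDir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  dat <- .stage("input", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      genes <- sprintf("G%06d", seq_len(sim$nGenes))
      coll <- simulateRandomCollection(
        config$nSets, config$setSizeRange, genes,
        seed = .deriveSeed(config$seed, "collection"))
      simd <- simulateCounts(sim, coll)
      list(counts = simd$counts, sheet = simd$sheet, coll = coll,
           truth = simd$truth)
    } else {
      list(counts = readCounts(config$countsPath),
           sheet = readSampleSheet(config$samplesPath),
           coll = readGmt(config$gmtPath), truth = NULL)
    }
  })
  checkCollectionCoverage(dat$coll, rownames(dat$counts))

  filtered <- .stage("filter", {
    f <- filterLowCounts(dat$counts, config$minMean)
    message(sprintf("  %d of %d genes retained (mean count >= %g)",
                    nrow(f), nrow(dat$counts), config$minMean))
    f
  })

  contrasts <- list(
    young = c("young.sham", "young.DOCA"),
    aging = c("aging.sham", "aging.DOCA"))
  de <- .stage("de", lapply(contrasts, function(ct) {
    r <- nbExactContrast(filtered, dat$sheet, ct[1L], ct[2L])
    tb <- as.data.frame(r)
    message(sprintf("  %s vs %s: %d genes at FDR < %g", ct[2L], ct[1L],
                    sum(tb$fdr < config$deFdr), config$deFdr))
    r
  }))
  for (nm in names(de))
    writeResultsTable(as.data.frame(de[[nm]]),
                      file.path(out, paste0("de_", nm, ".tsv")))

  .stage("pca", {
    writeResultsTable(pcaCoordinates(filtered),
                      file.path(out, "pca_coordinates.tsv"))
  })

  ranks <- lapply(de, rankedList)
  for (nm in names(ranks))
    writeResultsTable(ranks[[nm]],
                      file.path(out, paste0("ranks_", nm, ".tsv")))

  enr1d <- .stage("enrichment1d", lapply(names(ranks), function(nm) {
    r <- permutationEnrichment(
      ranks[[nm]], dat$coll, nPerm = config$nPerm,
      seed = .deriveSeed(config$seed, paste0("gsea.", nm)))
    writeResultsTable(r, file.path(out, paste0("gsea1d_", nm, ".tsv")))
    r
  }))
  names(enr1d) <- names(ranks)

  gsh <- .stage("gsheat", {
    ssm <- setScoreMatrix(filtered, dat$coll)
    writeResultsTable(
      data.frame(set_name = rownames(as.matrix(ssm)), as.matrix(ssm),
                 check.names = FALSE),
      file.path(out, "gsheat_scores.tsv"))
    diffs <- lapply(contrasts, function(ct)
      differentialSets(ssm, dat$sheet, ct[1L], ct[2L]))
    for (nm in names(diffs))
      writeResultsTable(diffs[[nm]],
                        file.path(out, paste0("gsheat_diff_", nm,
                                              ".tsv")))
    hm <- topSetsHeatmap(ssm, diffs$young,
                         nTop = min(50L, nrow(diffs$young)),
                         file = file.path(out, "gsheat_heatmap.png"))
    exportEnrichmentMap(diffs$young, dat$coll, fdrCut = config$gseaFdr,
                        dir = out)
    list(scores = ssm, diffs = diffs, heatmap = hm)
  })

  two <- .stage("enrichment2d", {
    jt <- jointRanks(de$young, de$aging)
    writeResultsTable(jt, file.path(out, "joint_ranks.tsv"))
    res <- significance2d(jt, dat$coll, method = "hotelling",
                          seed = .deriveSeed(config$seed, "2d"))
    cls <- classifyQuadrants(res, fdrCut = config$gseaFdr)
    writeResultsTable(cls$table, file.path(out, "enrichment2d.tsv"))
    writeResultsTable(
      data.frame(class = names(cls$counts),
                 count = as.integer(cls$counts)),
      file.path(out, "quadrant_report.tsv"))
    list(joint = jt, results = res, classes = cls)
  })

  cmp <- .stage("compare", {
    cc <- compareContrasts(de$young, de$aging, threshold = config$deFdr)
    writeResultsTable(
      data.frame(region = names(cc$venn),
                 count = as.integer(cc$venn)),
      file.path(out, "venn_counts.tsv"))
    writeResultsTable(
      data.frame(spearman = cc$spearman),
      file.path(out, "rank_rank_spearman.tsv"))
    grid <- as.data.frame(as.table(cc$grid), stringsAsFactors = FALSE)
    names(grid) <- c("bin_young", "bin_aging", "count")
    writeResultsTable(grid, file.path(out, "rank_rank_grid.tsv"))
    cc
  })

  manifest <- .stage("manifest", {
    files <- sort(list.files(out, pattern = "\\.tsv$"))
    md5 <- tools::md5sum(file.path(out, files))
    mf <- data.frame(file = files, md5 = unname(md5),
                     stringsAsFactors = FALSE)
    cfg <- config; cfg$outDir <- NULL
    tmp <- file.path(out, "config_snapshot.txt")
    writeLines(deparse(cfg), tmp)
    mf <- rbind(mf, data.frame(file = "config_snapshot.txt",
                               md5 = unname(tools::md5sum(tmp))))
    write.table(mf, file.path(out, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    mf
  })

  invisible(list(manifest = manifest, outDir = out,
                 results = list(de = de, enrichment1d = enr1d,
                                gsheat = gsh, enrichment2d = two,
                                compare = cmp, truth = dat$truth)))
}

#' Summarize a completed pipeline run as markdown
#'
#' Reads the TSV outputs of \code{runPipeline} and writes a short
#' markdown report: DE gene counts per contrast, contrast overlap, top
#' enriched sets per stage and the quadrant class counts. Missing stage
#' outputs are listed as absent rather than failing.
#'
#' @param outDir a pipeline output directory.
#' @param file report path (default \code{report.md} inside
#'   \code{outDir}).
#' @return Invisibly, the report path.
#' @export
makeReport <- function(outDir, file = file.path(outDir, "report.md")) {
  lines <- c("# Pipeline run summary", "")
  absent <- character()
  grab <- function(name) {
    p <- file.path(outDir, name)
    if (!file.exists(p)) {
      absent <<- c(absent, name)
      return(NULL)
    }
    readResultsTable(p)
  }
  for (nm in c("young", "aging")) {
    de <- grab(paste0("de_", nm, ".tsv"))
    if (!is.null(de))
      lines <- c(lines, sprintf(
        "- DE genes (%s contrast, FDR < 0.05): %d of %d tested",
        nm, sum(de$fdr < 0.05), nrow(de)))
  }
  venn <- grab("venn_counts.tsv")
  if (!is.null(venn))
    lines <- c(lines, sprintf(
      "- Contrast overlap: %s",
      paste(sprintf("%s = %d", venn$region, venn$count),
            collapse = ", ")))
  sp <- grab("rank_rank_spearman.tsv")
  if (!is.null(sp))
    lines <- c(lines, sprintf(
      "- Rank-rank Spearman correlation: %.3f", sp$spearman[1L]))
  for (nm in c("young", "aging")) {
    g <- grab(paste0("gsea1d_", nm, ".tsv"))
    if (!is.null(g)) {
      top <- head(g$set_name, 3L)
      lines <- c(lines, sprintf(
        "- 1D enrichment (%s): %d sets at FDR < 0.05; top: %s",
        nm, sum(g$fdr < 0.05), paste(top, collapse = ", ")))
    }
  }
  qr <- grab("quadrant_report.tsv")
  if (!is.null(qr))
    lines <- c(lines, sprintf(
      "- 2D classes: %s",
      paste(sprintf("%s = %d", qr$class, qr$count), collapse = ", ")))
  if (length(absent))
    lines <- c(lines, "", "Absent stage outputs:",
               paste("-", absent))
  writeLines(lines, file)
  invisible(file)
}
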