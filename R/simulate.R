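# Negative-binomial count simulator emulating the study design: a 2x2
# age (young/aging) x treatment (sham/DOCA) factorial with groups
# young.sham n=6 and n=4 elsewhere, planted differential genes per
# within-age contrast and coherently activated gene sets.

.deriveSeed <- function(seed, what) {
  # deterministic sub-seed per component, kept inside 32-bit range
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions: group sizes (6, 4, 4, 4), a
#' log-normal baseline expression distribution, a dispersion model
#' phi = phi0 + slope/mu, modest library-size variation, 5% planted
#' differential genes per contrast at |log2FC| = 2, and 5 activated sets
#' per contrast shifted by 1 log2 unit. The 2,000-gene default keeps test
#' runs fast; \code{nGenes = 14410} reproduces the post-filter scale of
#' the motivating experiment.
#'
#' @param nGenes number of simulated genes.
#' @param groupSizes named integer vector over the four design cells
#'   (names \code{young.sham}, \code{young.DOCA}, \code{aging.sham},
#'   \code{aging.DOCA}); every group needs n >= 2.
#' @param baselineLogMean \code{c(location, scale)} of the per-gene
#'   baseline log2 mean count (normal).
#' @param dispersion \code{c(phi0, slope)} for phi = phi0 + slope/mu; the
#'   defaults (0.05, 2) are conventional for bulk tissue RNA-seq, not
#'   estimates from any particular dataset.
#' @param librarySize \code{c(location, scale)} of log-normal per-sample
#'   library-size factors (natural log).
#' @param deFraction fraction of genes planted differential in each
#'   within-age contrast.
#' @param deLog2fc magnitude of planted gene effects (log2 units).
#' @param ageEffectSd sd of gene-wise age main effects (log2 units);
#'   drawn smaller than treatment effects so the factorial structure
#'   exists without dominating.
#' @param nActiveSets number of activated sets per contrast.
#' @param setShiftDelta coherent member-wise shift for activated sets
#'   (log2 units) applied in DOCA samples of the designated age stratum.
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return A list of class \code{simConfig}.
#' @export
simulationConfig <- function(nGenes = 2000L,
                             groupSizes = c(young.sham = 6L,
                                            young.DOCA = 4L,
                                            aging.sham = 4L,
                                            aging.DOCA = 4L),
                             baselineLogMean = c(5, 2),
                             dispersion = c(0.05, 2),
                             librarySize = c(0, 0.15),
                             deFraction = 0.05,
                             deLog2fc = 2,
                             ageEffectSd = 0.25,
                             nActiveSets = 5L,
                             setShiftDelta = 1,
                             seed = 1L) {
  need <- c("young.sham", "young.DOCA", "aging.sham", "aging.DOCA")
  if (!all(need %in% names(groupSizes)))
    stop("groupSizes must name all four design cells")
  if (any(groupSizes < 2L)) stop("every group needs n >= 2")
  if (deFraction < 0 || deFraction > 1) stop("deFraction outside [0,1]")
  if (nGenes < 10L) stop("nGenes too small")
  structure(list(nGenes = as.integer(nGenes),
                 groupSizes = groupSizes[need],
                 baselineLogMean = baselineLogMean,
                 dispersion = dispersion,
                 librarySize = librarySize,
                 deFraction = deFraction,
                 deLog2fc = deLog2fc,
                 ageEffectSd = ageEffectSd,
                 nActiveSets = as.integer(nActiveSets),
                 setShiftDelta = setShiftDelta,
                 seed = as.integer(seed)),
            class = "simConfig")
}

#' Simulate a random gene-set collection
#'
#' Sets are sampled without replacement from the gene universe, with
#' sizes uniform over \code{sizeRange}.
#'
#' @param nSets number of sets (> 0).
#' @param sizeRange \code{c(min, max)} set sizes, within
#'   \code{[2, length(universe)]}.
#' @param universe character vector of gene ids.
#' @param seed integer seed.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
simulateRandomCollection <- function(nSets, sizeRange, universe, seed = 1L) {
  if (nSets <= 0L) stop("nSets must be positive")
  if (sizeRange[1L] < 2L || sizeRange[2L] > length(universe))
    stop("sizeRange must lie within [2, length(universe)]")
  set.seed(seed)
  cand <- seq.int(sizeRange[1L], sizeRange[2L])
  sizes <- cand[sample.int(length(cand), nSets, replace = TRUE)]
  sets <- lapply(sizes, function(k) sample(universe, k))
  names(sets) <- sprintf("SET%04d", seq_len(nSets))
  GeneSetCollection(sets,
                    setNames(rep("simulated", nSets), names(sets)))
}

#' Simulate counts with planted effects
#'
#' Counts are drawn NB(mu_gs, phi_g) with
#' log2 mu_gs = baseline_g + log2 libsize_s + age effect + planted
#' treatment effects. Planted differential genes receive a signed
#' \code{deLog2fc} shift in DOCA samples of their age stratum; activated
#' sets receive a coherent member-wise \code{setShiftDelta} shift in the
#' same way. The per-gene dispersion is phi0 + slope/mu evaluated at the
#' baseline mean.
#'
#' @param config a \code{simConfig} from \code{simulationConfig}.
#' @param collection optional \linkS4class{GeneSetCollection} over the
#'   simulated universe (gene ids \code{G000001}...). When supplied,
#'   \code{nActiveSets} sets per contrast are activated.
#' @return List with \code{counts} (matrix), \code{sheet} (sample sheet
#'   data.frame), and \code{truth} (planted gene/set effects per
#'   contrast).
#' @export
simulateCounts <- function(config, collection = NULL) {
  stopifnot(inherits(config, "simConfig"))
  gs <- config$groupSizes
  nG <- config$nGenes
  genes <- sprintf("G%06d", seq_len(nG))
  groups <- rep(names(gs), gs)
  samples <- paste0("S", sprintf("%02d", seq_along(groups)), "_", groups)
  sheet <- data.frame(
    sample_id = samples,
    age_group = sub("\\..*$", "", groups),
    treatment = sub("^.*\\.", "", groups),
    stringsAsFactors = FALSE)

  set.seed(.deriveSeed(config$seed, "baseline"))
  baseline <- rnorm(nG, config$baselineLogMean[1L],
                    config$baselineLogMean[2L])
  ageEff <- rnorm(nG, 0, config$ageEffectSd)
  set.seed(.deriveSeed(config$seed, "libsize"))
  libFac <- rlnorm(length(samples), config$librarySize[1L],
                   config$librarySize[2L])

  # planted differential genes, one draw per within-age contrast
  nDE <- round(config$deFraction * nG)
  truth <- list(deGenes = list(), activeSets = list())
  effect <- matrix(0, nG, length(samples),
                   dimnames = list(genes, samples))
  for (ct in c("young", "aging")) {
    set.seed(.deriveSeed(config$seed, paste0("de.", ct)))
    if (nDE > 0L) {
      idx <- sample.int(nG, nDE)
      sgn <- sample(c(-1, 1), nDE, replace = TRUE)
      fc <- sgn * config$deLog2fc
      truth$deGenes[[ct]] <- data.frame(gene_id = genes[idx],
                                        log2fc = fc,
                                        stringsAsFactors = FALSE)
      doca <- groups == paste0(ct, ".DOCA")
      effect[idx, doca] <- effect[idx, doca] + fc
    } else {
      truth$deGenes[[ct]] <- data.frame(gene_id = character(),
                                        log2fc = numeric())
    }
  }

  # coherently activated sets
  for (ct in c("young", "aging")) {
    if (!is.null(collection) && config$nActiveSets > 0L) {
      set.seed(.deriveSeed(config$seed, paste0("sets.", ct)))
      pick <- sample(names(collection),
                     min(config$nActiveSets, length(collection)))
      dir <- sample(c(-1, 1), length(pick), replace = TRUE)
      truth$activeSets[[ct]] <- data.frame(set_name = pick,
                                           direction = dir,
                                           stringsAsFactors = FALSE)
      doca <- groups == paste0(ct, ".DOCA")
      for (i in seq_along(pick)) {
        mem <- intersect(collection@sets[[pick[i]]], genes)
        if (!length(mem))
          stop("activated set ", pick[i], " has no genes in the universe")
        effect[mem, doca] <- effect[mem, doca] +
          dir[i] * config$setShiftDelta
      }
    } else {
      truth$activeSets[[ct]] <- data.frame(set_name = character(),
                                           direction = numeric())
    }
  }

  aging <- sheet$age_group == "aging"
  log2mu <- baseline + outer(ageEff, as.numeric(aging)) + effect +
    matrix(log2(libFac), nG, length(samples), byrow = TRUE)
  mu <- 2^log2mu
  phi <- config$dispersion[1L] + config$dispersion[2L] / 2^baseline
  set.seed(.deriveSeed(config$seed, "counts"))
  counts <- matrix(rnbinom(length(mu), mu = mu,
                           size = rep(1 / phi, length(samples))),
                   nG, length(samples), dimnames = list(genes, samples))
  list(counts = .validateCounts(counts), sheet = sheet, truth = truth)
}

#' Simulate a phenotype summary table from true cell parameters
#'
#' Draws per-animal values N(mean, sd), then reports the observed cell
#' mean, SEM = sd_hat/sqrt(n) and n -- the printed-table substrate that
#' \code{anovaFromSummaries} consumes.
#'
#' @param trueCellMeans named numeric vector over the four design cells
#'   (same names as \code{groupSizes}).
#' @param trueSd common within-cell sd (> 0).
#' @param groupSizes named integer vector of cell sizes (all >= 2).
#' @param endpoint endpoint label for the output rows.
#' @param seed integer seed.
#' @return Summary-stats data.frame (endpoint, age_group, treatment,
#'   mean, sem, n).
#' @export
simulatePhenotypeSummaries <- function(trueCellMeans, trueSd, groupSizes,
                                       endpoint = "endpoint",
                                       seed = 1L) {
  if (trueSd <= 0) stop("trueSd must be positive")
  if (any(groupSizes < 2L)) stop("every cell needs n >= 2")
  cells <- names(trueCellMeans)
  if (is.null(cells) || !setequal(cells, names(groupSizes)))
    stop("trueCellMeans and groupSizes must name the same cells")
  set.seed(seed)
  rows <- lapply(cells, function(cl) {
    n <- groupSizes[[cl]]
    x <- rnorm(n, trueCellMeans[[cl]], trueSd)
    data.frame(endpoint = endpoint,
               age_group = sub("\\..*$", "", cl),
               treatment = sub("^.*\\.", "", cl),
               mean = mean(x),
               sem = max(sd(x), 1e-12) / sqrt(n),
               n = n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
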