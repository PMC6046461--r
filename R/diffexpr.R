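# Per-contrast differential expression: low-count filtering, TMM-style
# normalization, a negative-binomial exact test on library-equalized
# pseudo-counts, BH adjustment, and the signed inverse-p ranking metric.

#' Filter genes by mean count
#'
#' Retains exactly the genes whose mean count across all samples is at
#' least \code{minMean}; genes averaging below the threshold are excluded
#' prior to differential analysis. Order is preserved; the operation is
#' idempotent.
#'
#' @param counts count matrix (or SummarizedExperiment).
#' @param minMean minimum mean count (default 10).
#' @return Filtered matrix (possibly 0-row, with a warning).
#' @export
filterLowCounts <- function(counts, minMean = 10) {
  rc <- .resolveCounts(counts)
  m <- rc$counts
  keep <- rowMeans(m) >= minMean
  if (!any(keep)) warning("no genes pass the mean-count filter")
  m[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M scale factors
#'
#' Between-sample scaling factors computed as the trimmed mean of
#' gene-wise log2 ratios (M-values) of library-size-normalized counts
#' against a reference sample, excluding the most extreme 30% of M-values
#' and 5% of average abundances on each side, then rescaled to geometric
#' mean 1. The reference is the sample whose upper-quartile normalized
#' count is closest to the mean upper quartile.
#'
#' @param counts count matrix.
#' @param trimLogratio two-sided trim fraction on M-values (default 0.3).
#' @param trimAbundance two-sided trim fraction on abundance (default
#'   0.05).
#' @return data.frame with \code{sample_id}, \code{library_size},
#'   \code{scale_factor}; factors are positive with geometric mean 1.
#' @export
tmmFactors <- function(counts, trimLogratio = 0.3, trimAbundance = 0.05) {
  counts <- .resolveCounts(counts)$counts
  lib <- colSums(counts)
  zero <- lib == 0
  if (any(zero))
    stop("sample has all-zero counts: ", colnames(counts)[zero][1L])
  cpm <- sweep(counts, 2L, lib, "/")
  uq <- apply(cpm, 2L, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(s) {
    if (s == ref) return(1)
    ok <- counts[, s] > 0 & counts[, ref] > 0
    if (!any(ok)) return(1)
    M <- log2(cpm[ok, s] / cpm[ok, ref])
    A <- 0.5 * log2(cpm[ok, s] * cpm[ok, ref])
    keep <- M >= quantile(M, trimLogratio) &
      M <= quantile(M, 1 - trimLogratio) &
      A >= quantile(A, trimAbundance) &
      A <= quantile(A, 1 - trimAbundance)
    if (!any(keep)) return(1)
    2^mean(M[keep])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  data.frame(sample_id = colnames(counts), library_size = lib,
             scale_factor = f, stringsAsFactors = FALSE)
}

# Conditional NB exact test for one gene: given the two group sums of
# equalized pseudo-counts and a dispersion, the two-sided p-value is the
# total conditional probability of splits as or less probable than the
# observed one. At phi = 0 the conditional law is Binomial(S, nA/n).
.exactTestP <- function(sA, sB, nA, nB, phi) {
  S <- round(sA + sB)
  if (S <= 0) return(1)
  aObs <- min(max(round(sA), 0L), S)
  m <- S / (nA + nB)
  if (S > 20000) {
    # enumerate only where mass is non-negligible (window is wide enough
    # that truncation error is far below machine precision)
    fA <- nA / (nA + nB)
    v <- S * fA * (1 - fA) * (1 + phi * m)
    lo <- max(0L, floor(S * fA - 50 * sqrt(v) - 50))
    hi <- min(S, ceiling(S * fA + 50 * sqrt(v) + 50))
    a <- seq.int(min(lo, aObs), max(hi, aObs))
  } else a <- 0:S
  if (phi < 1e-12) {
    lp <- dbinom(a, S, nA / (nA + nB), log = TRUE)
  } else {
    r <- 1 / phi
    lp <- dnbinom(a, size = nA * r, mu = nA * m, log = TRUE) +
      dnbinom(S - a, size = nB * r, mu = nB * m, log = TRUE)
  }
  lp <- lp - max(lp)
  p <- exp(lp)
  obs <- p[match(aObs, a)]
  min(1, sum(p[p <= obs * (1 + 1e-8)]) / sum(p))
}

# Method-of-moments common dispersion on equalized pseudo-counts:
# per gene, (within-group variance - mean)/mean^2 per group, pooled by
# degrees of freedom, then averaged across genes. Negative per-gene
# values are kept in the average (truncating at zero would bias upward).
.commonDispersion <- function(pseudo, idxA, idxB) {
  est <- function(x) {
    m <- mean(x)
    if (m <= 0) return(NA_real_)
    (var(x) - m) / m^2
  }
  dfA <- length(idxA) - 1L
  dfB <- length(idxB) - 1L
  phiG <- apply(pseudo, 1L, function(y) {
    a <- est(y[idxA]); b <- est(y[idxB])
    if (is.na(a) && is.na(b)) return(NA_real_)
    sum(c(dfA * a, dfB * b), na.rm = TRUE) /
      sum(c(dfA, dfB)[!is.na(c(a, b))])
  })
  common <- mean(phiG, na.rm = TRUE)
  list(common = max(common, 1e-6, na.rm = TRUE), geneWise = phiG,
       df = dfA + dfB)
}

#' Negative-binomial exact test between two groups
#'
#' Classic two-group exact test for overdispersed counts: per-sample
#' counts are scaled to a common (geometric-mean) effective library size
#' using TMM factors, a common dispersion is estimated by the method of
#' moments, and each gene's p-value is the conditional probability, given
#' the two-group sum, of splits as or more extreme than the observed one
#' under the negative binomial. Fold changes are log2 ratios of
#' normalized group means with a 0.5 prior count; FDR is Benjamini-
#' Hochberg; the per-gene ranking score is sign(log2FC)/p.
#'
#' @param counts filtered count matrix (or SummarizedExperiment).
#' @param sheet sample sheet; groups are matched against
#'   \code{sampleGroups(sheet)} (or a \code{group} column if present).
#' @param groupA,groupB group labels; fold changes are B over A.
#' @param dispersionMode \code{"common"} (one dispersion for all genes)
#'   or \code{"shrunk"} (gene-wise moment estimates shrunk toward the
#'   common value with 20 prior degrees of freedom).
#' @param allowSingleSample permit 1-sample groups (no within-group
#'   variance; dispersion must then be supplied via \code{fixedPhi}).
#'   Intended for small worked examples, not analysis.
#' @param fixedPhi optional fixed dispersion overriding estimation.
#' @return A \linkS4class{ContrastResult}.
#' @export
nbExactContrast <- function(counts, sheet = NULL, groupA, groupB,
                            dispersionMode = c("common", "shrunk"),
                            allowSingleSample = FALSE,
                            fixedPhi = NULL) {
  dispersionMode <- match.arg(dispersionMode)
  rc <- .resolveCounts(counts, sheet)
  counts <- rc$counts; sheet <- rc$sheet
  if (is.null(sheet)) stop("a sample sheet is required")
  grp <- if ("group" %in% names(sheet))
    setNames(sheet$group, sheet$sample_id) else sampleGroups(sheet)
  grp <- grp[colnames(counts)]
  idxA <- which(grp == groupA)
  idxB <- which(grp == groupB)
  if (!length(idxA)) stop("group not found in sheet: ", groupA)
  if (!length(idxB)) stop("group not found in sheet: ", groupB)
  if ((length(idxA) < 2L || length(idxB) < 2L) && !allowSingleSample)
    stop("both groups need >= 2 samples")
  sub <- counts[, c(idxA, idxB), drop = FALSE]
  nA <- length(idxA); nB <- length(idxB)
  iA <- seq_len(nA); iB <- nA + seq_len(nB)

  fac <- tmmFactors(sub)
  effLib <- fac$library_size * fac$scale_factor
  target <- exp(mean(log(effLib)))
  pseudo <- sweep(sub, 2L, target / effLib, "*")

  if (!is.null(fixedPhi)) {
    phi <- rep(fixedPhi, nrow(sub))
  } else {
    if (nA < 2L || nB < 2L)
      stop("dispersion cannot be estimated from single-sample groups; ",
           "supply fixedPhi")
    d <- .commonDispersion(pseudo, iA, iB)
    phi <- if (dispersionMode == "common")
      rep(d$common, nrow(sub))
    else {
      gw <- ifelse(is.na(d$geneWise), d$common, d$geneWise)
      pmax((20 * d$common + d$df * gw) / (20 + d$df), 1e-6)
    }
  }

  mA <- rowMeans(pseudo[, iA, drop = FALSE])
  mB <- rowMeans(pseudo[, iB, drop = FALSE])
  log2fc <- log2((mB + 0.5) / (mA + 0.5))
  pv <- vapply(seq_len(nrow(sub)), function(g) {
    .exactTestP(sum(pseudo[g, iA]), sum(pseudo[g, iB]), nA, nB, phi[g])
  }, numeric(1))
  fdr <- bhAdjust(pv)
  tb <- data.frame(gene_id = rownames(sub),
                   mean_count = (mA + mB) / 2,
                   log2fc = log2fc,
                   p_value = pv,
                   fdr = fdr,
                   rank_score = signedInversePRank(log2fc, pv),
                   stringsAsFactors = FALSE)
  rownames(tb) <- NULL
  new("ContrastResult", table = tb, groupA = groupA, groupB = groupB)
}

#' Signed inverse-p ranking score
#'
#' The pre-ranked-list metric: genes are ordered from most up-regulated
#' to most down-regulated by multiplying the sign of the log2 fold change
#' by the inverse of the p-value. A zero fold change scores 0; p-values
#' are floored at 1e-300 so the score stays finite.
#'
#' @param log2fc numeric vector of log2 fold changes.
#' @param p numeric vector of p-values in [0, 1].
#' @return Numeric score vector, same length.
#' @export
signedInversePRank <- function(log2fc, p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p outside [0,1]")
  sign(log2fc) / pmax(p, 1e-300)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone, clipped to 1, input order
#' restored), with input validation.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted values, same order as input.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p outside [0,1]")
  p.adjust(p, method = "BH")
}

#' Build the ordered pre-ranked gene list of a contrast
#'
#' Genes ordered most up-regulated first by the signed inverse-p score;
#' ties (identical p and sign) are broken by |log2FC| descending then
#' gene id, so the ordering is deterministic.
#'
#' @param result a \linkS4class{ContrastResult}.
#' @return data.frame with \code{gene_id} and \code{score}, strictly
#'   ordered.
#' @export
rankedList <- function(result) {
  tb <- as.data.frame(result)
  o <- order(-tb$rank_score, -abs(tb$log2fc), tb$gene_id)
  data.frame(gene_id = tb$gene_id[o], score = tb$rank_score[o],
             stringsAsFactors = FALSE)
}

#' Compare two contrasts: overlap counts and rank-rank structure
#'
#' Counts genes significant (FDR below \code{threshold}) in only A, only
#' B, or both, and summarizes transcriptome-wide agreement with a 2D
#' histogram of rank-score ranks plus their Spearman correlation.
#'
#' @param resultA,resultB \linkS4class{ContrastResult} objects over the
#'   same gene universe.
#' @param threshold FDR significance threshold (default 0.05).
#' @param bins number of bins per axis of the rank-rank histogram.
#' @return List with \code{venn} (uniqueA/uniqueB/shared counts),
#'   \code{spearman}, and \code{grid} (bins x bins count matrix).
#' @export
compareContrasts <- function(resultA, resultB, threshold = 0.05,
                             bins = 50L) {
  ta <- as.data.frame(resultA); tb <- as.data.frame(resultB)
  common <- intersect(ta$gene_id, tb$gene_id)
  if (!length(common)) stop("contrast gene universes are disjoint")
  ta <- ta[match(common, ta$gene_id), ]
  tb <- tb[match(common, tb$gene_id), ]
  sigA <- common[ta$fdr < threshold]
  sigB <- common[tb$fdr < threshold]
  rA <- rank(ta$rank_score)
  rB <- rank(tb$rank_score)
  cutA <- cut(rA, breaks = seq(0.5, length(common) + 0.5,
                               length.out = bins + 1L))
  cutB <- cut(rB, breaks = seq(0.5, length(common) + 0.5,
                               length.out = bins + 1L))
  list(venn = c(uniqueA = length(setdiff(sigA, sigB)),
                uniqueB = length(setdiff(sigB, sigA)),
                shared = length(intersect(sigA, sigB))),
       spearman = cor(rA, rB, method = "spearman"),
       grid = unclass(table(cutA, cutB)))
}

#' PCA coordinates of log2-CPM expression
#'
#' Reporting utility for sample-level ordination: counts per million on
#' log2 scale (0.5 prior), restricted to the \code{nTop} most variable
#' genes, gene-centred, projected by principal components.
#'
#' @param counts count matrix (or SummarizedExperiment).
#' @param nTop number of most-variable genes used (default 500).
#' @return data.frame of sample coordinates on PC1..PC4 (or fewer) with
#'   a \code{percentVar} attribute.
#' @export
pcaCoordinates <- function(counts, nTop = 500L) {
  m <- .resolveCounts(counts)$counts
  cpm <- log2(sweep(m, 2L, colSums(m) / 1e6, "/") + 0.5)
  v <- apply(cpm, 1L, var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(nTop, nrow(cpm)))]
  x <- t(cpm[keep, , drop = FALSE] -
           rowMeans(cpm[keep, , drop = FALSE]))
  pc <- prcomp(x, center = FALSE)
  k <- min(4L, ncol(pc$x))
  out <- data.frame(sample_id = rownames(pc$x),
                    pc$x[, seq_len(k), drop = FALSE],
                    stringsAsFactors = FALSE)
  attr(out, "percentVar") <-
    100 * pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2)
  rownames(out) <- NULL
  out
}
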