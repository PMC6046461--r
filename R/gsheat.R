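# Gsheat: per-sample gene-set activation scored as the sum of
# within-sample expression ranks of member genes, differential set
# testing with a moderated t, top-set heat map ordering, and
# enrichment-map network export.

#' Rank genes within each sample
#'
#' Per sample, genes are ranked from least expressed (rank 1) to most
#' expressed (rank N); ties receive average fractional ranks so the
#' per-sample rank sum is exactly N(N+1)/2. Ranks are taken on raw
#' counts: any per-sample monotone transform (CPM scaling, log) leaves
#' them unchanged, so normalization cannot alter Gsheat results.
#'
#' @param counts count matrix (or SummarizedExperiment) with >= 2 genes.
#' @return Numeric matrix of the same shape holding within-sample ranks.
#' @export
rankWithinSample <- function(counts) {
  m <- .resolveCounts(counts)$counts
  if (nrow(m) < 2L) stop("ranking needs at least 2 genes")
  apply(m, 2L, rank)
}

#' Per-sample gene-set rank-sum scores
#'
#' For each gene set and each sample, sums the within-sample ranks of the
#' set's member genes present in the matrix. Members absent from the
#' matrix contribute nothing; sets with fewer than 2 present members are
#' skipped with a warning.
#'
#' @param counts count matrix (or SummarizedExperiment).
#' @param collection a \linkS4class{GeneSetCollection}.
#' @return A \linkS4class{SetScoreMatrix}.
#' @export
setScoreMatrix <- function(counts, collection) {
  stopifnot(is(collection, "GeneSetCollection"))
  m <- .resolveCounts(counts)$counts
  ranks <- rankWithinSample(m)
  present <- lapply(geneIds(collection),
                    function(mem) intersect(mem, rownames(m)))
  k <- lengths(present)
  drop <- k < 2L
  if (all(drop)) stop("no set has >= 2 members in the count matrix")
  if (any(drop))
    warning(sum(drop), " set(s) with < 2 present members skipped: ",
            paste(head(names(present)[drop], 5L), collapse = ", "))
  present <- present[!drop]
  scores <- t(vapply(present,
                     function(mem) colSums(ranks[mem, , drop = FALSE]),
                     numeric(ncol(m))))
  dimnames(scores) <- list(names(present), colnames(m))
  new("SetScoreMatrix", scores = scores,
      membersUsed = setNames(as.integer(k[!drop]), names(present)),
      nGenes = nrow(m))
}

#' Normalized set scores
#'
#' Raw rank-sum scores divided by their null expectation k(N+1)/2, so a
#' set at the null midpoint scores 1.0. Useful for cross-set comparison;
#' the raw score is the defining quantity and drives all testing.
#'
#' @param scores a \linkS4class{SetScoreMatrix}.
#' @return Numeric matrix of normalized scores.
#' @export
normalizedSetScores <- function(scores) {
  stopifnot(is(scores, "SetScoreMatrix"))
  k <- scores@membersUsed
  sweep(scores@scores, 1L, k * (scores@nGenes + 1) / 2, "/")
}

# Moment-matched scaled-inverse-chi-square prior for set-score
# variances: if s2 ~ s02 * F(df, d0) marginally, then
# mean = s02*d0/(d0-2) and var/mean^2 = 2*(df+d0-2)/(df*(d0-4));
# inverting the second moment gives d0, the first gives s02.
.estimateVarPrior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  m <- mean(s2)
  if (length(s2) < 3L || m <= 0) return(list(d0 = Inf, s02 = max(m, 0)))
  cc <- var(s2) / m^2
  if (!is.finite(cc) || cc * df <= 2) return(list(d0 = Inf, s02 = m))
  d0 <- (2 * df - 4 + 4 * cc * df) / (cc * df - 2)
  if (!is.finite(d0) || d0 <= 0) return(list(d0 = Inf, s02 = m))
  s02 <- if (d0 > 2) m * (d0 - 2) / d0 else m
  list(d0 = d0, s02 = s02)
}

#' Differential gene-set activation between two groups
#'
#' Two-sample test on the per-sample set scores. The moderated t shrinks
#' per-set pooled variances toward a prior estimated across sets by
#' moment matching of the variance distribution (scaled inverse
#' chi-square), adding the prior degrees of freedom to the test; with
#' fewer than 10 sets it falls back to the ordinary pooled-variance t.
#'
#' @param scores a \linkS4class{SetScoreMatrix}.
#' @param sheet sample sheet for the score columns.
#' @param groupA,groupB group labels (as in \code{sampleGroups}); the
#'   reported effect is B minus A.
#' @param method \code{"moderated_t"} (default) or \code{"ordinary_t"}.
#' @return data.frame per set: \code{set_name}, \code{mean_a},
#'   \code{mean_b}, \code{t}, \code{df}, \code{p}, \code{fdr}, ordered
#'   as the score matrix.
#' @export
differentialSets <- function(scores, sheet, groupA, groupB,
                             method = c("moderated_t", "ordinary_t")) {
  method <- match.arg(method)
  stopifnot(is(scores, "SetScoreMatrix"))
  sm <- scores@scores
  grp <- if ("group" %in% names(sheet))
    setNames(sheet$group, sheet$sample_id) else sampleGroups(sheet)
  grp <- grp[colnames(sm)]
  iA <- which(grp == groupA); iB <- which(grp == groupB)
  if (length(iA) < 2L || length(iB) < 2L)
    stop("both groups need >= 2 samples")
  nA <- length(iA); nB <- length(iB)
  mA <- rowMeans(sm[, iA, drop = FALSE])
  mB <- rowMeans(sm[, iB, drop = FALSE])
  vA <- apply(sm[, iA, drop = FALSE], 1L, var)
  vB <- apply(sm[, iB, drop = FALSE], 1L, var)
  df <- nA + nB - 2L
  s2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / df
  if (method == "moderated_t" && nrow(sm) >= 10L) {
    pr <- .estimateVarPrior(s2, df)
    if (is.finite(pr$d0)) {
      s2t <- (pr$d0 * pr$s02 + df * s2) / (pr$d0 + df)
      dfT <- df + pr$d0
    } else {
      s2t <- rep(pr$s02, length(s2))
      dfT <- Inf
    }
  } else {
    s2t <- s2
    dfT <- df
  }
  se <- sqrt(s2t * (1 / nA + 1 / nB))
  delta <- mB - mA
  t <- ifelse(delta == 0, 0, delta / se)
  t[is.na(t)] <- 0
  p <- 2 * pt(-abs(t), dfT)
  p <- pmin(pmax(p, 1e-300), 1)
  out <- data.frame(set_name = rownames(sm), mean_a = mA, mean_b = mB,
                    t = t, df = dfT, p = p, fdr = bhAdjust(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Order the most significant sets for heat-map display
#'
#' Takes the \code{nTop} sets with smallest p, z-scores each row across
#' samples, and clusters rows and columns by average-linkage hierarchical
#' clustering on Euclidean distance. Optionally renders the yellow-high /
#' dark-red-low heat map to a file.
#'
#' @param scores a \linkS4class{SetScoreMatrix}.
#' @param diffResult output of \code{differentialSets} over the same
#'   sets.
#' @param nTop number of sets to display (<= number tested).
#' @param file optional path; when given, a PNG/SVG heat map is written.
#' @return List: \code{matrix} (z-scored, rows/cols in dendrogram
#'   order), \code{rowOrder}, \code{colOrder}, \code{rowClust},
#'   \code{colClust}.
#' @export
topSetsHeatmap <- function(scores, diffResult, nTop = 50L, file = NULL) {
  stopifnot(is(scores, "SetScoreMatrix"))
  if (nTop > nrow(diffResult))
    stop("nTop exceeds the number of tested sets")
  top <- diffResult$set_name[order(diffResult$p)][seq_len(nTop)]
  m <- scores@scores[top, , drop = FALSE]
  sds <- apply(m, 1L, sd)
  z <- (m - rowMeans(m)) / ifelse(sds > 0, sds, 1)
  rowCl <- hclust(dist(z), method = "average")
  colCl <- hclust(dist(t(z)), method = "average")
  ordered <- z[rowCl$order, colCl$order, drop = FALSE]
  if (!is.null(file)) {
    pal <- grDevices::colorRampPalette(
      c("darkred", "red", "orange", "yellow"))(100)
    try(pheatmap::pheatmap(
      z, color = pal, clustering_method = "average",
      filename = file, silent = TRUE), silent = TRUE)
  }
  list(matrix = ordered, rowOrder = rowCl$order, colOrder = colCl$order,
       rowClust = rowCl, colClust = colCl)
}

#' Export an enrichment-map network
#'
#' Nodes are sets significant below \code{fdrCut}; edges connect set
#' pairs whose member Jaccard overlap reaches \code{jaccardCut}. The
#' node/edge tables are written as TSV importable by graph tools.
#'
#' @param diffResult output of \code{differentialSets}.
#' @param collection the \linkS4class{GeneSetCollection} the sets came
#'   from.
#' @param fdrCut node significance threshold (default 0.05).
#' @param jaccardCut minimum Jaccard overlap for an edge (default 0.25).
#' @param dir optional output directory; when given, writes
#'   \code{enrichment_map_nodes.tsv} and \code{enrichment_map_edges.tsv}.
#' @return List with \code{nodes} and \code{edges} data.frames (either
#'   may be 0-row).
#' @export
exportEnrichmentMap <- function(diffResult, collection, fdrCut = 0.05,
                                jaccardCut = 0.25, dir = NULL) {
  stopifnot(is(collection, "GeneSetCollection"))
  sig <- diffResult[diffResult$fdr < fdrCut, , drop = FALSE]
  nodes <- data.frame(set_name = sig$set_name, fdr = sig$fdr,
                      direction = ifelse(sig$t >= 0, "up", "down"),
                      stringsAsFactors = FALSE)
  edges <- data.frame(set_a = character(), set_b = character(),
                      jaccard = numeric(), stringsAsFactors = FALSE)
  if (nrow(nodes) > 1L) {
    mem <- geneIds(collection)[nodes$set_name]
    pairs <- utils::combn(nrow(nodes), 2L)
    jac <- apply(pairs, 2L, function(ij) {
      a <- mem[[ij[1L]]]; b <- mem[[ij[2L]]]
      length(intersect(a, b)) / length(union(a, b))
    })
    keep <- jac >= jaccardCut
    if (any(keep))
      edges <- data.frame(set_a = nodes$set_name[pairs[1L, keep]],
                          set_b = nodes$set_name[pairs[2L, keep]],
                          jaccard = jac[keep], stringsAsFactors = FALSE)
  }
  if (!is.null(dir)) {
    writeResultsTable(nodes, file.path(dir, "enrichment_map_nodes.tsv"))
    writeResultsTable(edges, file.path(dir, "enrichment_map_edges.tsv"))
  }
  list(nodes = nodes, edges = edges)
}
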