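# Two-dimensional multi-contrast enrichment: genes ranked in each of two
# contrasts and pasted side by side; per-set signed mean-rank
# displacement on each axis, Hotelling T-squared or permutation
# significance, quadrant classification, and a miRNA-target mode.

#' Joint rank table over two contrasts
#'
#' Restricts both contrasts to their common gene universe and ranks
#' genes within each contrast ascending by the signed inverse-p score
#' (most down-regulated = rank 1, average ranks at ties).
#'
#' @param resultA,resultB \linkS4class{ContrastResult} objects.
#' @return data.frame with \code{gene_id}, \code{rank1}, \code{rank2},
#'   \code{score1}, \code{score2}; attribute \code{nDropped} counts
#'   genes absent from one contrast.
#' @export
jointRanks <- function(resultA, resultB) {
  ta <- as.data.frame(resultA); tb <- as.data.frame(resultB)
  common <- intersect(ta$gene_id, tb$gene_id)
  if (length(common) < 2L)
    stop("fewer than 2 genes shared between the contrasts")
  ta <- ta[match(common, ta$gene_id), ]
  tb <- tb[match(common, tb$gene_id), ]
  out <- data.frame(gene_id = common,
                    rank1 = rank(ta$rank_score),
                    rank2 = rank(tb$rank_score),
                    score1 = ta$rank_score,
                    score2 = tb$rank_score,
                    stringsAsFactors = FALSE)
  attr(out, "nDropped") <-
    (nrow(as.data.frame(resultA)) - length(common)) +
    (nrow(as.data.frame(resultB)) - length(common))
  out
}

#' Scaled mean-rank displacement of a set on both axes
#'
#' For each contrast d, s_d = 2 (meanrank_d(members) - (N+1)/2) / N: a
#' signed score in (-1, 1) measuring how far the set's members sit above
#' (positive) or below (negative) the middle of the ranking. The whole
#' universe scores 0 on both axes.
#'
#' @param table joint rank table from \code{jointRanks}.
#' @param members character vector of member gene ids (>= 2 present).
#' @return Named numeric vector \code{c(s1, s2)}, or NULL (with a
#'   warning) when fewer than 2 members are present.
#' @export
score2d <- function(table, members) {
  idx <- which(table$gene_id %in% members)
  if (length(idx) < 2L) {
    warning("fewer than 2 set members present; set skipped")
    return(NULL)
  }
  N <- nrow(table)
  c(s1 = 2 * (mean(table$rank1[idx]) - (N + 1) / 2) / N,
    s2 = 2 * (mean(table$rank2[idx]) - (N + 1) / 2) / N)
}

.quadrantOf <- function(s1, s2) {
  paste(ifelse(s1 >= 0, "up", "down"), ifelse(s2 >= 0, "up", "down"),
        sep = "-")
}

#' Two-dimensional set significance
#'
#' Tests each set's joint displacement on the two rank axes. The default
#' engine compares member vs non-member 2D rank vectors with a
#' two-sample Hotelling T-squared (F approximation); the permutation
#' engine resamples member labels and compares the displacement
#' magnitude sqrt(s1^2 + s2^2), p = (1 + #\{null >= observed\})/(B + 1).
#' A singular pooled covariance (e.g., perfectly correlated contrasts)
#' falls back to permutation with a warning. FDR is Benjamini-Hochberg
#' over tested sets.
#'
#' @param table joint rank table from \code{jointRanks}.
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param method \code{"hotelling"} (default) or \code{"permutation"}.
#' @param nPerm permutations for the permutation engine.
#' @param seed integer seed (required for the permutation engine).
#' @param minSize minimum present members per set (default 10).
#' @return data.frame per tested set: \code{set_name}, \code{s1},
#'   \code{s2}, \code{magnitude}, \code{quadrant}, \code{p}, \code{fdr},
#'   \code{size_used}.
#' @export
significance2d <- function(table, collection,
                           method = c("hotelling", "permutation"),
                           nPerm = 1000L, seed = NULL, minSize = 10L) {
  method <- match.arg(method)
  stopifnot(is(collection, "GeneSetCollection"))
  if (method == "permutation" && is.null(seed))
    stop("the permutation engine requires a seed")
  N <- nrow(table)
  R <- cbind(table$rank1, table$rank2)
  inSet <- lapply(geneIds(collection),
                  function(m) which(table$gene_id %in% m))
  k <- lengths(inSet)
  if (any(k < 2L))
    warning(sum(k < 2L), " set(s) with < 2 present members skipped: ",
            paste(head(names(collection)[k < 2L], 5L), collapse = ", "))
  keep <- names(collection)[k >= minSize]
  if (!length(keep)) stop("no set has enough present members")
  if (!is.null(seed)) set.seed(seed)
  permP <- function(idx, obsMag) {
    kk <- length(idx)
    null <- vapply(seq_len(nPerm), function(i) {
      j <- sample.int(N, kk)
      sqrt(sum((2 * (colMeans(R[j, , drop = FALSE]) - (N + 1) / 2) /
                  N)^2))
    }, numeric(1))
    (1 + sum(null >= obsMag)) / (nPerm + 1)
  }
  rows <- lapply(keep, function(nm) {
    idx <- inSet[[nm]]
    s <- 2 * (colMeans(R[idx, , drop = FALSE]) - (N + 1) / 2) / N
    mag <- sqrt(sum(s^2))
    p <- NA_real_
    if (method == "hotelling") {
      n1 <- length(idx); n2 <- N - n1
      d <- colMeans(R[idx, , drop = FALSE]) -
        colMeans(R[-idx, , drop = FALSE])
      S1 <- stats::cov(R[idx, , drop = FALSE])
      S2 <- stats::cov(R[-idx, , drop = FALSE])
      Sp <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
      det_ <- det(Sp)
      scale_ <- Sp[1L, 1L] * Sp[2L, 2L]
      if (!is.finite(det_) || scale_ <= 0 || det_ < 1e-10 * scale_) {
        warning("singular pooled covariance for ", nm,
                "; falling back to permutation")
        if (is.null(seed))
          stop("permutation fallback requires a seed")
        p <- permP(idx, mag)
      } else {
        T2 <- (n1 * n2 / (n1 + n2)) *
          drop(t(d) %*% solve(Sp, d))
        Fst <- (n1 + n2 - 3) / (2 * (n1 + n2 - 2)) * T2
        p <- pf(Fst, 2, n1 + n2 - 3, lower.tail = FALSE)
      }
    } else {
      p <- permP(idx, mag)
    }
    data.frame(set_name = nm, s1 = unname(s[1L]), s2 = unname(s[2L]),
               magnitude = mag, quadrant = .quadrantOf(s[1L], s[2L]),
               p = max(p, 1e-300), size_used = length(idx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p)
  out <- out[, c("set_name", "s1", "s2", "magnitude", "quadrant", "p",
                 "fdr", "size_used")]
  rownames(out) <- NULL
  out
}

#' Classify sets into multi-contrast response classes
#'
#' Significant sets (fdr below \code{fdrCut}) are labeled by which axes
#' show a material displacement (|s| >= \code{sCut}): both positive =
#' both-up, both negative = both-down, opposite signs = discordant, one
#' axis only = contrast-specific; everything else is unclassified.
#'
#' @param results output of \code{significance2d}.
#' @param fdrCut FDR threshold (default 0.05).
#' @param sCut per-axis displacement threshold (default 0.1).
#' @return List: \code{table} (input plus a \code{class} column) and
#'   \code{counts} (named vector of class counts).
#' @export
classifyQuadrants <- function(results, fdrCut = 0.05, sCut = 0.1) {
  cls <- vapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    if (r$fdr >= fdrCut) return("unclassified")
    a1 <- abs(r$s1) >= sCut; a2 <- abs(r$s2) >= sCut
    if (a1 && a2) {
      if (r$s1 >= 0 && r$s2 >= 0) "both-up"
      else if (r$s1 < 0 && r$s2 < 0) "both-down"
      else "discordant"
    } else if (a1) "contrast1-specific"
    else if (a2) "contrast2-specific"
    else "unclassified"
  }, character(1))
  lev <- c("both-up", "both-down", "contrast1-specific",
           "contrast2-specific", "discordant", "unclassified")
  out <- results
  out$class <- cls
  list(table = out,
       counts = table(factor(cls, levels = lev)))
}

#' miRNA-target two-dimensional enrichment
#'
#' Runs \code{significance2d} on a collection of miRNA target sets
#' (keyed by miRNA name) and additionally reports the miRNAs whose
#' target sets fall in the down-down quadrant at the FDR cut --
#' coherent down-shift of a target set in both contrasts being the
#' signature of miRNA-mediated repression.
#'
#' @param table joint rank table from \code{jointRanks}.
#' @param targetCollection \linkS4class{GeneSetCollection} of target
#'   sets keyed by miRNA.
#' @param fdrCut FDR threshold for the down-down report (default 0.05).
#' @param ... passed to \code{significance2d}.
#' @return List: \code{results} (per-miRNA data.frame),
#'   \code{downDown} (miRNA names), \code{nDownDown}.
#' @export
mirnaTargetMode <- function(table, targetCollection, fdrCut = 0.05,
                            ...) {
  res <- significance2d(table, targetCollection, ...)
  dd <- res$set_name[res$quadrant == "down-down" & res$fdr < fdrCut]
  list(results = res, downDown = dd, nDownDown = length(dd))
}
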