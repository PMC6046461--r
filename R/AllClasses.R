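#' @import methods
#' @importFrom stats median p.adjust pf pt pnbinom dnbinom dpois dbinom
#'   quantile rnorm rnbinom rlnorm sd var cor prcomp dist hclust cutree
#'   optimize setNames runif
#' @importFrom utils read.delim write.table head
NULL

#' Gene-set collection
#'
#' A named collection of gene sets, each a character vector of gene
#' identifiers with a free-text description, as read from a GMT file.
#' Identifiers are opaque strings: no namespace translation is attempted,
#' so the collection and any count matrix it is used with must already
#' share an identifier space.
#'
#' @slot sets named list of character vectors (deduplicated, non-empty).
#' @slot descriptions named character vector parallel to \code{sets}.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", descriptions = "character"),
  validity = function(object) {
    msg <- character()
    nm <- names(object@sets)
    if (is.null(nm) || anyDuplicated(nm))
      msg <- c(msg, "set names must be present and unique")
    if (any(!vapply(object@sets, is.character, logical(1))))
      msg <- c(msg, "all sets must be character vectors")
    if (any(lengths(object@sets) == 0L))
      msg <- c(msg, "empty gene sets are not allowed")
    if (any(vapply(object@sets, anyDuplicated, integer(1)) > 0L))
      msg <- c(msg, "sets must not contain duplicated members")
    if (length(object@descriptions) != length(object@sets))
      msg <- c(msg, "descriptions must parallel sets")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional named character vector of descriptions;
#'   defaults to empty strings.
#' @return A \linkS4class{GeneSetCollection}.
#' @examples
#' gsc <- GeneSetCollection(list(SETA = c("g1", "g2"), SETB = c("g2", "g3")))
#' length(gsc)
#' @export
GeneSetCollection <- function(sets, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  new("GeneSetCollection", sets = sets,
      descriptions = setNames(as.character(descriptions), names(sets)))
}

#' @describeIn GeneSetCollection-class number of sets
#' @param x a GeneSetCollection
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn GeneSetCollection-class set names
#' @export
setMethod("names", "GeneSetCollection", function(x) names(x@sets))

#' Member gene ids of the sets in a collection
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @return Named list of character vectors.
#' @export
geneIds <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  x@sets
}

#' Set descriptions of a collection
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @return Named character vector.
#' @export
setDescriptions <- function(x) {
  stopifnot(is(x, "GeneSetCollection"))
  x@descriptions
}

#' @describeIn GeneSetCollection-class subset by name or index
#' @param i index or names
#' @param j unused
#' @param ... unused
#' @param drop unused
#' @export
setMethod("[", "GeneSetCollection", function(x, i, j, ..., drop = FALSE) {
  GeneSetCollection(x@sets[i], x@descriptions[i])
})

#' @describeIn GeneSetCollection-class extract one set's members
#' @export
setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

setMethod("show", "GeneSetCollection", function(object) {
  sz <- lengths(object@sets)
  cat("GeneSetCollection with", length(object@sets), "sets;",
      "sizes", min(sz), "-", max(sz), "\n")
  nm <- head(names(object@sets), 3L)
  cat("  e.g.", paste(nm, collapse = ", "),
      if (length(object@sets) > 3L) "..." else "", "\n")
})

#' Per-gene results of a two-group differential-expression contrast
#'
#' Holds, for one contrast (group B over group A), the per-gene mean
#' normalized count, log2 fold change, exact-test p-value, BH-adjusted FDR
#' and the signed inverse-p ranking score sign(log2FC)/p used to build
#' pre-ranked gene lists.
#'
#' @slot table data.frame with columns gene_id, mean_count, log2fc,
#'   p_value, fdr, rank_score.
#' @slot groupA,groupB group labels (fold changes are B over A).
#' @export
setClass("ContrastResult",
  representation(table = "data.frame", groupA = "character",
                 groupB = "character"),
  validity = function(object) {
    need <- c("gene_id", "mean_count", "log2fc", "p_value", "fdr",
              "rank_score")
    msg <- character()
    if (!all(need %in% names(object@table)))
      msg <- c(msg, paste("table must have columns:",
                          paste(need, collapse = ", ")))
    else {
      tb <- object@table
      if (anyDuplicated(tb$gene_id))
        msg <- c(msg, "duplicated gene_id")
      if (any(tb$p_value < 0 | tb$p_value > 1, na.rm = TRUE))
        msg <- c(msg, "p_value outside [0,1]")
      if (any(tb$fdr < 0 | tb$fdr > 1, na.rm = TRUE))
        msg <- c(msg, "fdr outside [0,1]")
      bad <- tb$log2fc != 0 & sign(tb$rank_score) != sign(tb$log2fc)
      if (any(bad, na.rm = TRUE))
        msg <- c(msg, "rank_score sign must match log2fc sign")
    }
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "ContrastResult", function(object) {
  tb <- object@table
  cat("ContrastResult:", object@groupB, "vs", object@groupA,
      sprintf("(%d genes, %d at FDR < 0.05)\n", nrow(tb),
              sum(tb$fdr < 0.05, na.rm = TRUE)))
})

#' @describeIn ContrastResult-class the per-gene result table
#' @param x a ContrastResult
#' @param ... unused
#' @export
setMethod("as.data.frame", "ContrastResult", function(x, ...) x@table)

#' Contrast group labels
#'
#' @param x a \linkS4class{ContrastResult}.
#' @return Character vector \code{c(groupA, groupB)}.
#' @export
contrastGroups <- function(x) {
  stopifnot(is(x, "ContrastResult"))
  c(x@groupA, x@groupB)
}

#' Per-sample gene-set rank-sum score matrix (Gsheat)
#'
#' Rows are gene sets, columns samples; each entry is the sum of the
#' within-sample expression ranks of the set's member genes present in the
#' count matrix. For a set with k present members in an N-gene matrix the
#' score lies in [k(k+1)/2, k(2N-k+1)/2].
#'
#' @slot scores numeric matrix, sets x samples.
#' @slot membersUsed named integer vector: members found in the matrix.
#' @slot nGenes number of genes ranked (N).
#' @export
setClass("SetScoreMatrix",
  representation(scores = "matrix", membersUsed = "integer",
                 nGenes = "integer"),
  validity = function(object) {
    msg <- character()
    k <- object@membersUsed
    N <- object@nGenes
    if (length(k) != nrow(object@scores))
      msg <- c(msg, "membersUsed must parallel score rows")
    else {
      lo <- k * (k + 1) / 2
      hi <- k * (2 * N - k + 1) / 2
      out <- object@scores < lo - 1e-9 | object@scores > hi + 1e-9
      if (any(out))
        msg <- c(msg, "scores outside attainable rank-sum range")
    }
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "SetScoreMatrix", function(object) {
  cat("SetScoreMatrix:", nrow(object@scores), "sets x",
      ncol(object@scores), "samples, over", object@nGenes, "genes\n")
})

#' @describeIn SetScoreMatrix-class underlying score matrix
#' @param x a SetScoreMatrix
#' @export
setMethod("as.matrix", "SetScoreMatrix", function(x) x@scores)

#' @describeIn SetScoreMatrix-class dimensions
#' @export
setMethod("dim", "SetScoreMatrix", function(x) dim(x@scores))

#' Number of set members found in the ranked matrix
#'
#' @param x a \linkS4class{SetScoreMatrix}.
#' @return Named integer vector, one entry per set row.
#' @export
membersUsed <- function(x) {
  stopifnot(is(x, "SetScoreMatrix"))
  x@membersUsed
}
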