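# Readers and writers for the external formats the pipeline touches.
# All files are tab-separated UTF-8 without quoting (the GMT convention);
# counts may alternatively arrive as a MatrixMarket triplet.

.validateCounts <- function(counts, what = "count matrix") {
  if (!is.matrix(counts)) stop(what, " must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop(what, " must have gene and sample names")
  dupg <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dupg))
    stop("duplicated gene id in ", what, ": ", dupg[1L])
  dups <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dups))
    stop("duplicated sample id in ", what, ": ", dups[1L])
  if (ncol(counts) < 2L) stop(what, " must have at least 2 samples")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop(what, " must be non-negative and finite")
  if (any(counts != round(counts)))
    stop(what, " must contain integral counts")
  storage.mode(counts) <- "double"
  counts
}

#' Read a gene-level count matrix
#'
#' TSV layout: gene ids in the first column, sample ids in the header.
#' MatrixMarket layout: a \code{.mtx} file accompanied by
#' \code{<path>.rownames} and \code{<path>.colnames} files holding one id
#' per line.
#'
#' @param path file path (the \code{.mtx} file for matrixmarket layout).
#' @param layout \code{"tsv"} or \code{"matrixmarket"}.
#' @return A validated numeric matrix of non-negative integral counts with
#'   gene rownames and sample colnames.
#' @export
readCounts <- function(path, layout = c("tsv", "matrixmarket")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "tsv") {
    df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                     check.names = FALSE, colClasses = "character")
    if (ncol(df) < 3L) stop("count TSV needs >= 1 gene column + 2 samples")
    genes <- df[[1L]]
    m <- suppressWarnings(
      vapply(df[-1L], as.numeric, numeric(nrow(df))))
    if (nrow(df) == 1L) m <- matrix(m, nrow = 1L,
                                    dimnames = list(NULL, names(df)[-1L]))
    if (anyNA(m)) {
      bad <- which(apply(is.na(m), 1L, any))[1L]
      stop("non-numeric count at data line ", bad, " of ", path)
    }
    rownames(m) <- genes
  } else {
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (nrow(m) != length(rn) || ncol(m) != length(cn))
      stop("MatrixMarket dimensions disagree with row/col name files")
    dimnames(m) <- list(rn, cn)
  }
  .validateCounts(m)
}

#' Write a count matrix as TSV
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeCounts <- function(counts, path) {
  counts <- .validateCounts(counts)
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns \code{sample_id}, \code{age_group} (young/aging) and
#' \code{treatment} (sham/DOCA).
#'
#' @param path file path.
#' @return data.frame with the three columns, ids unique.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  need <- c("sample_id", "age_group", "treatment")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  df
}

#' Write a sample sheet as TSV
#' @param sheet sample sheet data.frame.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSampleSheet <- function(sheet, path) {
  write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Combined group label per sample
#'
#' Convenience factor combining the two design factors into labels such as
#' \code{young.sham}, the grouping used to define contrasts.
#'
#' @param sheet sample sheet data.frame.
#' @return Named character vector, one label per sample.
#' @export
sampleGroups <- function(sheet) {
  setNames(paste(sheet$age_group, sheet$treatment, sep = "."),
           sheet$sample_id)
}

#' Read a GMT gene-set file
#'
#' Broad-dialect GMT: one set per line, tab-separated fields
#' \code{name}, \code{description}, then member gene ids. Duplicate
#' members within a line are removed with a warning; duplicate set names
#' are an error.
#'
#' @param path file path.
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  descs <- character(length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " (", f[1L],
              "): duplicated members removed")
      members <- unique(members)
    }
    if (!length(members)) stop("GMT line ", i, " defines an empty set")
    nms[i] <- f[1L]; descs[i] <- f[2L]; sets[[i]] <- members
  }
  if (anyDuplicated(nms))
    stop("duplicated set name in GMT: ", nms[duplicated(nms)][1L])
  names(sets) <- nms
  GeneSetCollection(sets, setNames(descs, nms))
}

#' Write a GeneSetCollection as GMT
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeGmt <- function(collection, path) {
  stopifnot(is(collection, "GeneSetCollection"))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, collection@descriptions[[nm]], collection@sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Warn when a collection barely overlaps a count matrix
#'
#' Gene ids are opaque strings and no translation is performed, so a
#' collection and matrix in different namespaces would silently produce
#' empty intersections. If under half of the collection's distinct members
#' appear among the matrix genes a warning is raised.
#'
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param geneIds character vector of matrix gene ids.
#' @return Invisibly, the fraction of collection members present.
#' @export
checkCollectionCoverage <- function(collection, geneIds) {
  members <- unique(unlist(geneIds(collection), use.names = FALSE))
  frac <- mean(members %in% geneIds)
  if (frac < 0.5)
    warning(sprintf(
      "only %.0f%% of collection members appear in the count matrix; %s",
      100 * frac, "check that gene identifier namespaces match"))
  invisible(frac)
}

#' Read a phenotype summary-statistics table
#'
#' TSV with columns \code{endpoint}, \code{age_group}, \code{treatment},
#' \code{mean}, \code{sem}, \code{n} -- the printed per-cell summaries
#' (mean, SEM, sample size) from which factorial ANOVA and pairwise tests
#' are reconstructed.
#'
#' @param path file path.
#' @return data.frame; per cell, \code{n >= 2} and \code{sem > 0}.
#' @export
readSummaryStats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  need <- c("endpoint", "age_group", "treatment", "mean", "sem", "n")
  if (!all(need %in% names(df)))
    stop("summary table must have columns: ", paste(need, collapse = ", "))
  if (any(df$n < 2)) stop("each cell needs n >= 2")
  if (any(df$sem <= 0)) stop("each cell needs sem > 0")
  df
}

#' Write a table of records as deterministic TSV
#'
#' Column order follows the data.frame; numeric columns are formatted at a
#' fixed number of significant digits so that byte-identical output is
#' reproducible across runs.
#'
#' @param records data.frame (possibly 0-row).
#' @param path output path.
#' @param digits significant digits for numeric columns (default 6).
#' @return Invisibly, \code{path}.
#' @export
writeResultsTable <- function(records, path, digits = 6L) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]]))
      out[[j]] <- signif(out[[j]], digits)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results TSV written by \code{writeResultsTable}
#' @param path file path.
#' @return data.frame.
#' @export
readResultsTable <- function(path) {
  read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
             check.names = FALSE)
}

# Accept either a plain matrix + sheet, or a SummarizedExperiment whose
# colData carries the sheet columns.
.resolveCounts <- function(counts, sheet = NULL) {
  if (is(counts, "SummarizedExperiment")) {
    cd <- as.data.frame(SummarizedExperiment::colData(counts))
    if (is.null(sheet)) {
      cd$sample_id <- colnames(counts)
      sheet <- cd
    }
    counts <- SummarizedExperiment::assay(counts, 1L)
  }
  list(counts = .validateCounts(counts), sheet = sheet)
}

#' Bundle counts and sample annotations as a SummarizedExperiment
#'
#' @param counts validated count matrix.
#' @param sheet sample sheet with a row per matrix column.
#' @return A \code{SummarizedExperiment} with assay \code{counts}.
#' @export
asCountsExperiment <- function(counts, sheet) {
  counts <- .validateCounts(counts)
  idx <- match(colnames(counts), sheet$sample_id)
  if (anyNA(idx)) stop("sample sheet is missing samples: ",
                       paste(colnames(counts)[is.na(idx)], collapse = ", "))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(sheet[idx, , drop = FALSE],
                                   row.names = colnames(counts)))
}
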