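# Reconstruction of factorial phenotype statistics from published
# per-cell summaries (mean, SEM, n): two-factor ANOVA with
# percent-of-total-variation per effect, Welch t from summaries, and
# family-wise BH adjustment. Both tests depend on the data only through
# the summaries, so any full dataset realizing them gives identical
# results.

#' Two-factor ANOVA from per-cell summaries
#'
#' Fits the 2x2 cell-mean model by weighted least squares with effect
#' coding and reports Type III (marginal) sums of squares for age,
#' disease and their interaction, each as a percentage of total SS, with
#' F and p against the residual mean square. The within-cell SS is
#' recovered from the SEMs as sum (n_i - 1) n_i SEM_i^2. For a balanced
#' design the effect SS are orthogonal and sum (with residual) to the
#' total; mild imbalance makes the decomposition approximate, matching
#' standard Type III practice.
#'
#' @param table summary-stats data.frame for one endpoint: columns
#'   \code{age_group}, \code{treatment}, \code{mean}, \code{sem},
#'   \code{n}, forming a complete 2x2 grid with n >= 2 per cell.
#' @return data.frame with a row per effect (interaction, age, disease)
#'   plus residual: \code{ss}, \code{df}, \code{percent_variation},
#'   \code{f_stat}, \code{p}.
#' @export
anovaFromSummaries <- function(table) {
  need <- c("age_group", "treatment", "mean", "sem", "n")
  if (!all(need %in% names(table)))
    stop("summary table must have columns: ", paste(need, collapse = ", "))
  if (nrow(table) != 4L ||
      nrow(unique(table[, c("age_group", "treatment")])) != 4L)
    stop("a complete 2x2 grid (4 distinct cells) is required")
  if (any(table$n < 2)) stop("each cell needs n >= 2")
  if (any(table$sem <= 0)) stop("each cell needs sem > 0")

  ages <- sort(unique(table$age_group))
  trts <- sort(unique(table$treatment))
  a <- ifelse(table$age_group == ages[2L], 1, -1)
  d <- ifelse(table$treatment == trts[2L], 1, -1)
  X <- cbind(intercept = 1, age = a, disease = d, interaction = a * d)
  W <- diag(table$n)
  M <- t(X) %*% W %*% X
  beta <- solve(M, t(X) %*% W %*% table$mean)
  Ci <- solve(M)
  ssEff <- drop(beta)^2 / diag(Ci)

  within <- sum((table$n - 1) * table$n * table$sem^2)
  gm <- sum(table$n * table$mean) / sum(table$n)
  between <- sum(table$n * (table$mean - gm)^2)
  total <- within + between
  dfRes <- sum(table$n) - 4L
  msRes <- within / dfRes

  eff <- c("interaction", "age", "disease")
  ss <- ssEff[eff]
  f <- ss / msRes
  data.frame(effect = c(eff, "residual"),
             ss = c(ss, within),
             df = c(1L, 1L, 1L, dfRes),
             percent_variation = 100 * c(ss, within) / total,
             f_stat = c(f, NA),
             p = c(pf(f, 1, dfRes, lower.tail = FALSE), NA),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Welch two-sample t-test from summaries
#'
#' t = (mean2 - mean1)/sqrt(sem1^2 + sem2^2), with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. Depends only on the
#' printed summaries.
#'
#' @param mean1,sem1,n1 first group's mean, SEM and size.
#' @param mean2,sem2,n2 second group's mean, SEM and size.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
welchTFromSummaries <- function(mean1, sem1, n1, mean2, sem2, n2) {
  if (sem1 <= 0 || sem2 <= 0) stop("SEMs must be positive")
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  v1 <- sem1^2; v2 <- sem2^2
  t <- (mean2 - mean1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = min(1, 2 * pt(-abs(t), df)))
}

#' BH adjustment within endpoint families
#'
#' Applies the Benjamini-Hochberg step-up adjustment separately within
#' each declared family of endpoint p-values.
#'
#' @param p numeric vector of p-values.
#' @param family vector (same length) of family labels.
#' @return Numeric vector of q-values, input order preserved.
#' @export
familyBh <- function(p, family) {
  if (length(p) != length(family))
    stop("p and family must have the same length")
  q <- numeric(length(p))
  for (f in unique(family)) {
    i <- family == f
    q[i] <- bhAdjust(p[i])
  }
  q
}

#' Run the summary ANOVA across all endpoints of a table
#'
#' Convenience wrapper mirroring a printed summary table's layout: one
#' output row per endpoint with the percent variation and p of each
#' effect.
#'
#' @param table summary-stats data.frame with an \code{endpoint} column.
#' @return data.frame, one row per endpoint, columns
#'   \code{interaction_percent}, \code{interaction_p},
#'   \code{age_percent}, \code{age_p}, \code{disease_percent},
#'   \code{disease_p}.
#' @export
anovaTable <- function(table) {
  rows <- lapply(split(table, table$endpoint), function(tb) {
    a <- anovaFromSummaries(tb)
    g <- function(e, col) a[a$effect == e, col]
    data.frame(endpoint = tb$endpoint[1L],
               interaction_percent = g("interaction", "percent_variation"),
               interaction_p = g("interaction", "p"),
               age_percent = g("age", "percent_variation"),
               age_p = g("age", "p"),
               disease_percent = g("disease", "percent_variation"),
               disease_p = g("disease", "p"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
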