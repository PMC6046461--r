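test_that("mean-count filter keeps exactly genes at or above threshold", {
  m <- matrix(c(9, 10, 11,   # mean 10: retained
                0, 0, 29,    # mean 9.67: excluded
                10, 10, 10), 3L, 3L, byrow = TRUE,
              dimnames = list(c("keepEdge", "dropBurst", "keepFlat"),
                              paste0("s", 1:3)))
  f <- filterLowCounts(m, 10)
  expect_identical(rownames(f), c("keepEdge", "keepFlat"))
  expect_identical(filterLowCounts(f, 10), f)   # idempotent
  z <- matrix(0, 2L, 2L, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_warning(out <- filterLowCounts(z, 10), "no genes")
  expect_identical(nrow(out), 0L)
})

test_that("TMM factors are 1 under symmetry and pure scaling", {
  set.seed(1)
  base <- rpois(100, 50)
  m <- cbind(s1 = base, s2 = base)
  rownames(m) <- paste0("g", 1:100)
  expect_equal(tmmFactors(m)$scale_factor, c(1, 1))
  m2 <- cbind(s1 = base, s2 = 2 * base)
  rownames(m2) <- paste0("g", 1:100)
  expect_equal(tmmFactors(m2)$scale_factor, c(1, 1))
  bad <- cbind(s1 = base, s2 = 0 * base)
  rownames(bad) <- paste0("g", 1:100)
  expect_error(tmmFactors(bad), "s2")
})

test_that("TMM matches a literal trimmed-mean computation", {
  set.seed(8)
  m <- matrix(rpois(300, 60), 100L, 3L,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:3)))
  m[1L, 2L] <- 5000  # one inflated gene in sample 2
  got <- tmmFactors(m)$scale_factor
  # independent re-derivation, written longhand
  lib <- colSums(m)
  cpm <- sweep(m, 2L, lib, "/")
  uq <- apply(cpm, 2L, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  raw <- sapply(seq_len(3L), function(s) {
    if (s == ref) return(1)
    ok <- m[, s] > 0 & m[, ref] > 0
    M <- log2(cpm[ok, s]) - log2(cpm[ok, ref])
    A <- (log2(cpm[ok, s]) + log2(cpm[ok, ref])) / 2
    keep <- rep(TRUE, length(M))
    keep[M < quantile(M, 0.3) | M > quantile(M, 0.7)] <- FALSE
    keep[A < quantile(A, 0.05) | A > quantile(A, 0.95)] <- FALSE
    2^mean(M[keep])
  })
  expect_equal(got, raw / exp(mean(log(raw))), tolerance = 1e-12)
})

test_that("exact test reduces to the conditional binomial at zero dispersion", {
  fx <- onePairCounts(0, 10)
  r <- nbExactContrast(fx$counts, fx$sheet, "young.sham", "young.DOCA",
                       allowSingleSample = TRUE, fixedPhi = 0)
  expect_equal(as.data.frame(r)$p_value[1L], 2 * 0.5^10,
               tolerance = 1e-12)
  # off-centre split: oracle by direct binomial enumeration
  fx2 <- onePairCounts(3, 11)
  r2 <- nbExactContrast(fx2$counts, fx2$sheet, "young.sham",
                        "young.DOCA", allowSingleSample = TRUE,
                        fixedPhi = 0)
  pr <- dbinom(0:14, 14, 0.5)
  oracle <- sum(pr[pr <= pr[4L] * (1 + 1e-8)])
  expect_equal(as.data.frame(r2)$p_value[1L], oracle, tolerance = 1e-12)
})

test_that("identical groups give log2FC 0 and p 1", {
  set.seed(2)
  base <- rpois(40, 30)
  m <- matrix(rep(base, 4L), 40L, 4L,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:4)))
  sheet <- data.frame(sample_id = colnames(m), age_group = "young",
                      treatment = rep(c("sham", "DOCA"), each = 2L))
  r <- as.data.frame(nbExactContrast(m, sheet, "young.sham",
                                     "young.DOCA"))
  expect_equal(r$log2fc, rep(0, 40L))
  expect_equal(r$p_value, rep(1, 40L))
})

test_that("p-values are invariant under relabeling samples within groups", {
  fx <- randomCountsFixture(60L, c(3L, 3L), seed = 5L)
  r1 <- nbExactContrast(fx$counts, fx$sheet, "young.sham", "young.DOCA")
  perm <- c(2L, 3L, 1L, 6L, 4L, 5L)  # shuffle within each group
  m2 <- fx$counts[, perm]
  sheet2 <- fx$sheet[perm, ]
  r2 <- nbExactContrast(m2, sheet2, "young.sham", "young.DOCA")
  expect_equal(as.data.frame(r1)$p_value, as.data.frame(r2)$p_value)
})

test_that("exact test broadly agrees with an established NB exact test", {
  cfg <- simulationConfig(nGenes = 500L, deFraction = 0.05,
                          deLog2fc = 2, nActiveSets = 0L, seed = 17L)
  sim <- simulateCounts(cfg)
  f <- filterLowCounts(sim$counts)
  mine <- as.data.frame(nbExactContrast(f, sim$sheet, "young.sham",
                                        "young.DOCA"))
  keep <- sim$sheet$age_group == "young"
  dge <- edgeR::DGEList(f[, sim$sheet$sample_id[keep]],
                        group = sim$sheet$treatment[keep])
  dge <- edgeR::calcNormFactors(dge)
  dge <- edgeR::estimateCommonDisp(dge)
  et <- edgeR::exactTest(dge, pair = c("sham", "DOCA"))
  expect_gt(cor(-log10(mine$p_value), -log10(et$table$PValue),
                method = "spearman"), 0.95)
  expect_gt(cor(mine$log2fc, et$table$logFC), 0.98)
})

test_that("signed inverse-p scoring follows the ranking rule", {
  expect_equal(signedInversePRank(1.5, 0.02), 50)
  expect_equal(signedInversePRank(-0.5, 0.5), -2)
  expect_equal(signedInversePRank(0, 0.9), 0)
  expect_true(is.finite(signedInversePRank(2, 0)))
  expect_error(signedInversePRank(1, 1.2), "0,1")
})

test_that("rank ordering equals significance ordering within sign", {
  set.seed(11)
  p <- runif(50)
  fc <- rnorm(50)
  sc <- signedInversePRank(fc, p)
  up <- fc > 0
  expect_identical(order(sc[up], decreasing = TRUE), order(p[up]))
  expect_identical(order(sc[!up]), order(p[!up]))
})

test_that("BH adjustment matches the hand step-up and validates input", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5L)), rep(1, 5L))
  expect_error(bhAdjust(c(0.1, 1.7)), "0,1")
  set.seed(21)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1L))
    expect_equal(bhAdjust(p), bruteForceBH(p))
  }
})

test_that("contrast comparison identities hold", {
  fx <- randomCountsFixture(80L, c(3L, 3L), seed = 9L)
  r <- nbExactContrast(fx$counts, fx$sheet, "young.sham", "young.DOCA")
  self <- compareContrasts(r, r)
  expect_equal(unname(self$venn[c("uniqueA", "uniqueB")]), c(0L, 0L))
  expect_equal(self$spearman, 1)
  flip <- as.data.frame(r)
  flip$log2fc <- -flip$log2fc
  flip$rank_score <- -flip$rank_score
  rf <- new("ContrastResult", table = flip, groupA = "a", groupB = "b")
  expect_equal(compareContrasts(r, rf)$spearman, -1)
  other <- as.data.frame(r)
  other$gene_id <- paste0("zz", other$gene_id)
  ro <- new("ContrastResult", table = other, groupA = "a", groupB = "b")
  expect_error(compareContrasts(r, ro), "disjoint")
})

test_that("planted contrast overlap is recovered within tolerance", {
  # plant each contrast's genes; overlap arises from independent draws
  cfg <- simulationConfig(nGenes = 1000L, deFraction = 0.1,
                          deLog2fc = 3, seed = 19L, nActiveSets = 0L,
                          groupSizes = c(young.sham = 6L,
                                         young.DOCA = 6L,
                                         aging.sham = 6L,
                                         aging.DOCA = 6L))
  sim <- simulateCounts(cfg)
  f <- filterLowCounts(sim$counts)
  ry <- nbExactContrast(f, sim$sheet, "young.sham", "young.DOCA")
  ra <- nbExactContrast(f, sim$sheet, "aging.sham", "aging.DOCA")
  cc <- compareContrasts(ry, ra)
  planted <- intersect(sim$truth$deGenes$young$gene_id,
                       sim$truth$deGenes$aging$gene_id)
  planted <- planted[planted %in% rownames(f)]
  expect_gt(cc$venn[["shared"]], 0.8 * length(planted) - 2)
  expect_lt(cc$venn[["shared"]], 1.2 * length(planted) + 5)
})

test_that("PCA coordinates are centered and sized to the samples", {
  fx <- randomCountsFixture(600L, c(4L, 4L), seed = 23L)
  pc <- pcaCoordinates(fx$counts, nTop = 100L)
  expect_identical(nrow(pc), 8L)
  expect_equal(colSums(as.matrix(pc[, -1L])), rep(0, 4L),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_true(all(attr(pc, "percentVar") >= 0))
})
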