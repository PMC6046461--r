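fourGene <- matrix(c(5, 1, 10, 3,
                     5, 1, 10, 3), 4L, 2L,
                   dimnames = list(c("gA", "gB", "gC", "gD"),
                                   c("s1", "s2")))

test_that("within-sample ranking follows expression with average ties", {
  r <- rankWithinSample(fourGene)
  expect_equal(r[, "s1"], c(gA = 3, gB = 1, gC = 4, gD = 2))
  tied <- matrix(c(2, 2, 5), 3L, 1L)
  tied <- cbind(tied, tied)
  dimnames(tied) <- list(c("a", "b", "c"), c("s1", "s2"))
  expect_equal(rankWithinSample(tied)[, 1L], c(a = 1.5, b = 1.5, c = 3))
  set.seed(43)
  m <- matrix(rpois(200, 20), 20L, 10L,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  expect_equal(colSums(rankWithinSample(m)), rep(20 * 21 / 2, 10L),
               ignore_attr = TRUE)
})

test_that("set scores are rank sums with conservation identities", {
  coll <- GeneSetCollection(list(AC = c("gA", "gC"),
                                 ALL = c("gA", "gB", "gC", "gD")))
  ssm <- setScoreMatrix(fourGene, coll)
  expect_equal(as.matrix(ssm)["AC", "s1"], 3 + 4, ignore_attr = TRUE)
  expect_equal(as.matrix(ssm)["ALL", ], c(s1 = 10, s2 = 10))
  # partition of the universe: scores add to N(N+1)/2 per sample
  part <- GeneSetCollection(list(p1 = c("gA", "gB"), p2 = c("gC", "gD")))
  ps <- as.matrix(setScoreMatrix(fourGene, part))
  expect_equal(colSums(ps), c(s1 = 10, s2 = 10))
})

test_that("scores are invariant under per-sample monotone transforms", {
  set.seed(45)
  m <- matrix(rpois(500, 30), 50L, 10L,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:10)))
  coll <- simulateRandomCollection(8L, c(5L, 20L), rownames(m),
                                   seed = 46L)
  base <- as.matrix(setScoreMatrix(m, coll))
  expect_equal(as.matrix(setScoreMatrix(m * 10, coll)), base)
  cpmish <- round(sweep(m, 2L, colSums(m), "/") * 1e6)
  # per-sample scaling by library size preserves within-sample order
  expect_equal(as.matrix(setScoreMatrix(cpmish, coll)), base)
})

test_that("raising member counts never decreases the set score", {
  set.seed(47)
  m <- matrix(rpois(300, 25), 30L, 10L,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  mem <- c("g3", "g7", "g11", "g20")
  coll <- GeneSetCollection(list(S = mem))
  before <- as.matrix(setScoreMatrix(m, coll))
  m2 <- m
  m2[mem, ] <- m2[mem, ] + 15
  after <- as.matrix(setScoreMatrix(m2, coll))
  expect_true(all(after >= before))
})

test_that("sets without enough present members are skipped or fatal", {
  coll <- GeneSetCollection(list(ok = c("gA", "gB"), gone = c("q1", "q2"),
                                 lone = c("gA", "zz")))
  expect_warning(ssm <- setScoreMatrix(fourGene, coll), "skipped")
  expect_identical(rownames(as.matrix(ssm)), "ok")
  none <- GeneSetCollection(list(gone = c("q1", "q2")))
  expect_error(suppressWarnings(setScoreMatrix(fourGene, none)),
               "no set")
})

test_that("normalized scores are 1 at the null expectation", {
  set.seed(48)
  m <- matrix(rpois(1000, 30), 100L, 10L,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:10)))
  coll <- simulateRandomCollection(30L, c(10L, 30L), rownames(m),
                                   seed = 49L)
  ns <- normalizedSetScores(setScoreMatrix(m, coll))
  expect_lt(abs(mean(ns) - 1), 0.1)
})

test_that("identical groups give t = 0 and p = 1", {
  m <- matrix(rep(c(10, 20, 30), each = 6L), 3L, 6L, byrow = TRUE,
              dimnames = list(paste0("set", 1:3), paste0("s", 1:6)))
  ssm <- new("SetScoreMatrix", scores = m,
             membersUsed = setNames(rep(2L, 3L), rownames(m)),
             nGenes = 50L)
  sheet <- data.frame(sample_id = colnames(m), age_group = "young",
                      treatment = rep(c("sham", "DOCA"), each = 3L))
  ds <- differentialSets(ssm, sheet, "young.sham", "young.DOCA",
                         method = "ordinary_t")
  expect_equal(ds$t, rep(0, 3L))
  expect_equal(ds$p, rep(1, 3L))
})

test_that("ordinary t equals the textbook two-sample t", {
  set.seed(51)
  for (i in 1:100) {
    nA <- sample(3:6, 1L); nB <- sample(3:6, 1L)
    m <- matrix(rnorm(12 * (nA + nB), 100, 10), 12L, nA + nB,
                dimnames = list(paste0("set", 1:12),
                                paste0("s", seq_len(nA + nB))))
    ssm <- new("SetScoreMatrix", scores = m,
               membersUsed = setNames(rep(3L, 12L), rownames(m)),
               nGenes = 1000L)
    sheet <- data.frame(sample_id = colnames(m), age_group = "young",
                        treatment = rep(c("sham", "DOCA"), c(nA, nB)))
    ds <- differentialSets(ssm, sheet, "young.sham", "young.DOCA",
                           method = "ordinary_t")
    ref <- t.test(m[1L, seq_len(nA)], m[1L, nA + seq_len(nB)],
                  var.equal = TRUE)
    expect_equal(-ds$t[1L], unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ds$p[1L], ref$p.value, tolerance = 1e-12)
  }
})

test_that("moderated t tracks an established empirical-Bayes t", {
  set.seed(53)
  m <- matrix(rnorm(80 * 10, 500, 40), 80L, 10L,
              dimnames = list(paste0("set", 1:80), paste0("s", 1:10)))
  m[1:5, 6:10] <- m[1:5, 6:10] + 120
  ssm <- new("SetScoreMatrix", scores = m,
             membersUsed = setNames(rep(4L, 80L), rownames(m)),
             nGenes = 2000L)
  sheet <- data.frame(sample_id = colnames(m), age_group = "young",
                      treatment = rep(c("sham", "DOCA"), each = 5L))
  ds <- differentialSets(ssm, sheet, "young.sham", "young.DOCA")
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, rep(0:1, each = 5L))))
  expect_gt(cor(ds$p, fit$p.value[, 2L]), 0.99)
  expect_true(all(ds$fdr[1:5] < 0.05))
})

test_that("top-set ordering and clustering behave on constructed input", {
  set.seed(55)
  m <- matrix(rnorm(20 * 6, 300, 30), 20L, 6L,
              dimnames = list(paste0("set", 1:20), paste0("s", 1:6)))
  m[, 6L] <- m[, 5L]          # duplicated sample pair
  m[7L, ] <- 400              # constant row
  ssm <- new("SetScoreMatrix", scores = m,
             membersUsed = setNames(rep(3L, 20L), rownames(m)),
             nGenes = 1000L)
  sheet <- data.frame(sample_id = colnames(m), age_group = "young",
                      treatment = rep(c("sham", "DOCA"), each = 3L))
  ds <- differentialSets(ssm, sheet, "young.sham", "young.DOCA")
  hm <- topSetsHeatmap(ssm, ds, nTop = 20L)
  expect_setequal(rownames(hm$matrix), ds$set_name)
  expect_equal(unname(hm$matrix["set7", ]), rep(0, 6L))
  # duplicated samples merge first (at height 0) in the column dendrogram
  expect_equal(sort(hm$colClust$merge[1L, ]), c(-6L, -5L))
  expect_equal(hm$colClust$height[1L], 0)
  expect_error(topSetsHeatmap(ssm, ds, nTop = 99L), "exceeds")
})

test_that("enrichment-map export applies FDR and Jaccard rules", {
  diffRes <- data.frame(
    set_name = c("A", "B", "C", "D"),
    mean_a = 1, mean_b = 2, t = c(3, -3, 3, 1), df = 8,
    p = c(0.001, 0.001, 0.001, 0.9),
    fdr = c(0.01, 0.01, 0.01, 0.9), stringsAsFactors = FALSE)
  coll <- GeneSetCollection(list(
    A = paste0("g", 1:10), B = paste0("h", 1:10),
    C = paste0("g", 1:20), D = paste0("g", 1:5)))
  em <- exportEnrichmentMap(diffRes, coll)
  expect_setequal(em$nodes$set_name, c("A", "B", "C"))
  expect_identical(em$nodes$direction[em$nodes$set_name == "B"], "down")
  # A subset of C with |A|=10, |C|=20: jaccard 0.5; B disjoint
  expect_identical(nrow(em$edges), 1L)
  expect_equal(em$edges$jaccard, 0.5)
  same <- exportEnrichmentMap(
    diffRes[1:2, ],
    GeneSetCollection(list(A = paste0("g", 1:10),
                           B = paste0("g", 1:10))))
  expect_equal(same$edges$jaccard, 1)
  none <- exportEnrichmentMap(diffRes[4L, , drop = FALSE], coll)
  expect_identical(nrow(none$nodes), 0L)
  expect_identical(nrow(none$edges), 0L)
})
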