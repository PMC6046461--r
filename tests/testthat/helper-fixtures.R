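# Shared fixture builders: everything is generated in code at test time.

# tiny two-sample count matrix with a 1-vs-1 contrast sheet; the filler
# gene mirrors the focal gene so both library sizes are equal
onePairCounts <- function(a, b) {
  m <- matrix(c(a, b, b, a), 2L, 2L,
              dimnames = list(c("gX", "gFill"), c("s1", "s2")))
  sheet <- data.frame(sample_id = c("s1", "s2"), age_group = "young",
                      treatment = c("sham", "DOCA"),
                      stringsAsFactors = FALSE)
  list(counts = m, sheet = sheet)
}

# random counts with a factorial sheet
randomCountsFixture <- function(nGenes = 50L, groupSizes = c(3L, 3L),
                                lambda = 50, seed = 1L) {
  set.seed(seed)
  n <- sum(groupSizes)
  m <- matrix(rpois(nGenes * n, lambda), nGenes, n,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(n))))
  sheet <- data.frame(
    sample_id = colnames(m),
    age_group = "young",
    treatment = rep(c("sham", "DOCA"), groupSizes),
    stringsAsFactors = FALSE)
  list(counts = m, sheet = sheet)
}

# independent brute-force BH step-up: q_(i) = min over j >= i of p_(j)*m/j
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o[i:m]] * m / (i:m)))
  }
  q
}

# independent running-sum oracle: literal walk down the list
bruteForceES <- function(scores, isHit, weightExponent = 1) {
  N <- length(scores)
  k <- sum(isHit)
  w <- abs(scores)^weightExponent
  hitTotal <- sum(w[isHit])
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (isHit[i]) run <- run + w[i] / hitTotal
    else run <- run - 1 / (N - k)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# reconstruct n observations with exactly the given mean and sd
reconstructCell <- function(n, mean, sd, seed = 1L) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / sd(x)
  x * sd + mean
}

# full reconstructed dataset for a 2x2 summary table
reconstructDesign <- function(tb, seed = 1L) {
  rows <- lapply(seq_len(nrow(tb)), function(i) {
    y <- reconstructCell(tb$n[i], tb$mean[i], tb$sem[i] * sqrt(tb$n[i]),
                         seed = seed + i)
    data.frame(y = y, age = tb$age_group[i], trt = tb$treatment[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$age <- factor(out$age)
  out$trt <- factor(out$trt)
  out
}

# summary table for the septal-thickness (IVSd) printed row
ivsdTable <- function() {
  data.frame(
    endpoint = "IVSd",
    age_group = c("young", "young", "aging", "aging"),
    treatment = c("sham", "DOCA", "sham", "DOCA"),
    mean = c(0.69, 1.02, 0.67, 1.01),
    sem = c(0.03, 0.05, 0.03, 0.03),
    n = c(6L, 6L, 6L, 8L),
    stringsAsFactors = FALSE)
}
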