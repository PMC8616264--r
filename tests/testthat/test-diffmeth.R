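test_that("size factors follow median-of-ratios with geometric mean 1", {
  counts <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2,
                   dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  s <- size_factors(counts)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  expect_equal(prod(s), 1)
  # identical samples
  same <- cbind(s1 = c(5, 9, 2), s2 = c(5, 9, 2))
  rownames(same) <- paste0("f", 1:3)
  expect_equal(unname(size_factors(same)), c(1, 1))
  # all-zero-containing features only
  z <- matrix(c(0, 1, 1, 0), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_error(size_factors(z), "pseudo-reference")
})

test_that("size factors recover simulated library sizes within 5%", {
  isl <- make_islands(2000)
  sim <- simulate_counts(count_sim_config(seed = 31, planted_fraction = 0),
                         isl)
  s <- size_factors(sim$matrix)
  truth <- sim$truth$libsize
  truth <- truth / exp(mean(log(truth)))
  expect_lt(max(abs(s / truth - 1)), 0.05)
})

test_that("dispersion estimates floor on constant data, track NB truth", {
  const <- matrix(7L, 20, 6,
                  dimnames = list(paste0("f", 1:20), paste0("s", 1:6)))
  m <- feature_count_matrix(const, rep("island", 20), rep(c("a", "b"), 3))
  a <- estimate_dispersions(m, s = setNames(rep(1, 6), paste0("s", 1:6)))
  expect_true(all(a == 1e-8))

  isl <- make_islands(800)
  sim <- simulate_counts(count_sim_config(seed = 17, dispersion = 0.1,
                                          planted_fraction = 0), isl)
  a <- estimate_dispersions(sim$matrix)
  expect_gt(median(a), 0.05)
  expect_lt(median(a), 0.2)

  one <- feature_count_matrix(
    matrix(1:4, 2, 2, dimnames = list(c("f1", "f2"), c("s1", "s2"))),
    c("island", "island"), c("a", "b"))
  expect_error(estimate_dispersions(one), "at least 2")
})

test_that("a case group with all-zero counts is called hypomethylated", {
  set.seed(40)
  counts <- matrix(rpois(40, 50), 10, 4)
  counts[1, 1:2] <- 0L  # cases
  dimnames(counts) <- list(sprintf("chr1:%d-%d", 1:10 * 100,
                                   1:10 * 100 + 50),
                           c("c1", "c2", "n1", "n2"))
  m <- feature_count_matrix(counts, rep("island", 10),
                            c("case", "case", "control", "control"))
  fit <- nb_wald_test(m)
  expect_lt(fit$results$log2fc[1], 0)
  expect_equal(fit$results$direction[1], "hypo")
})

test_that("NB Wald results agree with an independent DESeq2 run", {
  skip_if_not_installed("DESeq2")
  isl <- make_islands(300)
  sim <- simulate_counts(count_sim_config(seed = 5,
                                          planted_fraction = 0.1), isl)
  m <- sim$matrix
  fit <- nb_wald_test(m)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m$counts,
    data.frame(condition = factor(m$group, levels = c("control", "case"))),
    ~condition)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  res <- DESeq2::results(dds)
  sf <- DESeq2::sizeFactors(dds)
  expect_equal(unname(fit$size_factors),
               unname(sf / exp(mean(log(sf)))), tolerance = 1e-6)
  expect_lt(mean(abs(fit$results$log2fc - res$log2FoldChange),
                 na.rm = TRUE), 0.05)
  ours <- call_dmcgi(fit)$hyper
  theirs <- rownames(res)[!is.na(res$padj) & res$padj < 0.1 &
                            res$log2FoldChange > 1]
  jac <- length(intersect(ours, theirs)) / length(union(ours, theirs))
  expect_gt(jac, 0.9)
})

test_that("empirical FDR stays near nominal with 10% planted features", {
  isl <- make_islands(1000)
  fdp <- sens <- numeric(5)
  for (i in 1:5) {
    sim <- simulate_counts(count_sim_config(seed = 300 + i), isl)
    fit <- nb_wald_test(sim$matrix)
    hyper <- call_dmcgi(fit)$hyper
    fdp[i] <- length(setdiff(hyper, sim$truth$planted_hyper)) /
      max(1, length(hyper))
    sens[i] <- length(intersect(hyper, sim$truth$planted_hyper)) /
      length(sim$truth$planted_hyper)
  }
  expect_lte(mean(fdp), 0.15)
  expect_gte(mean(sens), 0.9)
})

test_that("BH adjustment reproduces the worked step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.037), 0.037)
  # missing p-values are excluded from m and passed through as NA
  q <- bh_adjust(c(0.01, NA, 0.02, 0.03, 0.5))
  expect_true(is.na(q[2]))
  expect_equal(q[-2], c(0.04, 0.04, 0.04, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with the brute-force step-up oracle", {
  set.seed(55)
  for (rep in 1:40) {
    p <- runif(sample(1:50, 1))^sample(c(1, 2, 3), 1)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("DMCGI calling applies both gates strictly", {
  r <- data.frame(
    feature_id = paste0("f", 1:5),
    log2fc = c(2, 1, 1.5, -2, 0.5),
    qvalue = c(0.05, 0.05, 0.1, 0.001, 0.0001),
    stringsAsFactors = FALSE)
  calls <- call_dmcgi(r)
  expect_equal(calls$hyper, "f1")      # f2: fc == 2 excluded; f3: q == 0.1
  expect_equal(calls$hypo, "f4")
  expect_length(intersect(calls$hyper, calls$hypo), 0)
})

test_that("top features rank by fold change with q then id tie-breaks", {
  r <- data.frame(
    feature_id = c("b", "a", "c", "d"),
    log2fc = c(3, 3, 2.5, 4),
    qvalue = c(0.01, 0.02, 0.001, 0.05),
    stringsAsFactors = FALSE)
  pool <- r$feature_id
  expect_equal(top_features(r, 1, candidates = pool), "d")
  expect_equal(top_features(r, 3, candidates = pool), c("d", "b", "a"))
  # stable under row permutations
  for (i in 1:5) {
    perm <- r[sample(nrow(r)), ]
    expect_equal(top_features(perm, 3, candidates = pool),
                 c("d", "b", "a"))
  }
  expect_error(top_features(r, 9, candidates = pool), "exceeds")
})
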