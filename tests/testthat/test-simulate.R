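test_that("count simulation is deterministic under seed, distinct across seeds", {
  isl <- make_islands(50)
  cfg <- count_sim_config(seed = 9, n_cases = 4, n_controls = 4)
  s1 <- simulate_counts(cfg, isl)
  s2 <- simulate_counts(cfg, isl)
  expect_identical(s1$matrix$counts, s2$matrix$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_counts(count_sim_config(seed = 10, n_cases = 4,
                                         n_controls = 4), isl)
  expect_false(identical(s1$matrix$counts, s3$matrix$counts))
})

test_that("truth sets are disjoint island subsets of the emitted features", {
  isl <- make_islands(200)
  cfg <- count_sim_config(seed = 3, planted_fraction = 0.2,
                          hypo_fraction = 0.1)
  sim <- simulate_counts(cfg, isl)
  tr <- sim$truth
  expect_true(all(c(tr$planted_hyper, tr$planted_hypo) %in%
                    rownames(sim$matrix$counts)))
  expect_length(intersect(tr$planted_hyper, tr$planted_hypo), 0)
  expect_equal(length(tr$planted_hyper) + length(tr$planted_hypo),
               round(0.2 * 200))
})

test_that("simulated counts match NB mean and variance at 10,000 draws", {
  isl <- make_islands(3)
  cfg <- count_sim_config(seed = 21, n_cases = 2, n_controls = 10000,
                          libsize_range = c(1, 1), planted_fraction = 0,
                          baseline_mean = 2, dispersion = 0.05)
  sim <- simulate_counts(cfg, isl)
  ctrl <- sim$matrix$counts[, sim$matrix$group == "control"]
  mu <- 2 * 30  # island class bias
  v <- mu + 0.05 * mu^2
  for (i in 1:3) {
    expect_equal(mean(ctrl[i, ]), mu, tolerance = 0.02)
    expect_equal(var(ctrl[i, ]), v, tolerance = 0.1)
  }
})

test_that("planted fold change shifts case means by the configured factor", {
  isl <- make_islands(100)
  cfg <- count_sim_config(seed = 5, n_cases = 50, n_controls = 50,
                          libsize_range = c(1, 1),
                          planted_fraction = 0.2, planted_fc = 4)
  sim <- simulate_counts(cfg, isl)
  m <- sim$matrix
  planted <- rownames(m$counts) %in% sim$truth$planted_hyper
  ratio <- rowMeans(m$counts[, m$group == "case"]) /
    rowMeans(m$counts[, m$group == "control"])
  expect_equal(median(ratio[planted]), 4, tolerance = 0.15)
  expect_equal(median(ratio[!planted]), 1, tolerance = 0.15)
})

test_that("impossible count configs are rejected", {
  expect_error(count_sim_config(planted_fraction = 1.5))
  expect_error(count_sim_config(planted_fc = -1))
  isl <- make_islands(5)
  expect_error(
    simulate_counts(count_sim_config(n_features = 10), isl), "features")
})

test_that("beta simulation plants tumor-only island effects in [0,1]", {
  isl <- make_islands(40)
  csim <- simulate_counts(count_sim_config(seed = 2, planted_fraction = 0.25),
                          isl)
  bcfg <- beta_sim_config(seed = 2, groups = c(tumor = 6, normal = 6,
                                               pbmc = 8))
  bm <- simulate_betas(bcfg, isl$feature_id, csim$truth)
  expect_true(all(bm$betas >= 0 & bm$betas <= 1))
  expect_setequal(bm$planted_islands, csim$truth$planted_hyper)

  planted_rows <- bm$site_island %in% bm$planted_islands
  tumor_cols <- bm$group == "tumor"
  expect_gt(mean(bm$betas[planted_rows, tumor_cols]) -
              mean(bm$betas[planted_rows, !tumor_cols]), 0.25)
  # unplanted islands show no group difference beyond noise
  expect_lt(abs(mean(bm$betas[!planted_rows, tumor_cols]) -
                  mean(bm$betas[!planted_rows, !tumor_cols])), 0.05)
})

test_that("beta config guards the [0,1] mean constraint and island cover", {
  expect_error(beta_sim_config(base_beta = 0.9, delta = 0.35), "outside")
  isl <- make_islands(10)
  sim <- simulate_counts(count_sim_config(seed = 1, planted_fraction = 0.5),
                         isl)
  expect_error(
    simulate_betas(beta_sim_config(), isl$feature_id[1:2], sim$truth),
    "planted")
})

test_that("spike-in Ct model matches its closed-form identities", {
  # full recovery, no noise: enriched equals input
  s <- simulate_spikein(1, 1, ct_input = 25, noise_sd = 0)
  expect_equal(s$ct_meth_enriched, 25)
  # half recovery at base 2 costs exactly one cycle
  s <- simulate_spikein(0.5, 0.5, ct_input = 25, noise_sd = 0)
  expect_equal(s$ct_meth_enriched, 26)
  expect_error(simulate_spikein(0, 0.1), "zero capture efficiency")
  # deterministic under seed when noisy
  n1 <- simulate_spikein(0.2, 0.001, noise_sd = 0.3, seed = 4)
  n2 <- simulate_spikein(0.2, 0.001, noise_sd = 0.3, seed = 4)
  expect_identical(n1, n2)
})

test_that("simulation writers produce round-trippable plain-text files", {
  isl <- make_islands(20)
  sim <- simulate_counts(count_sim_config(seed = 6, n_cases = 3,
                                          n_controls = 3), isl)
  dir <- withr::local_tempdir()
  paths <- write_count_sim(sim, dir)
  back <- read_count_matrix(paths["counts"], paths["samples"])
  expect_identical(back$counts, sim$matrix$counts)
  expect_identical(back$group, sim$matrix$group)

  bm <- simulate_betas(beta_sim_config(seed = 6,
                                       groups = c(tumor = 3, normal = 3,
                                                  pbmc = 3)),
                       isl$feature_id, sim$truth)
  bpaths <- write_beta_sim(bm, dir)
  bback <- read_beta_matrix(bpaths["betas"], bpaths["samples"])
  expect_equal(bback$betas, bm$betas)
  expect_equal(unname(bback$site_island), unname(bm$site_island))
})
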