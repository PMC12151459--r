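test_that("knockdown design replicates scaled identity blocks", {
  expect_equal(unname(make_knockdown_design(2, 1)), -diag(2))
  P <- make_knockdown_design(2, 2)
  expect_equal(unname(P), cbind(-diag(2), -diag(2)))
  expect_equal(colnames(P), c("G1_r1", "G2_r1", "G1_r2", "G2_r2"))
  P3 <- make_knockdown_design(3, 1)
  expect_true(all(colSums(P3 != 0) == 1))
  expect_equal(sum(P3), -3)
  expect_error(make_knockdown_design(3, 1, magnitude = 0),
               class = "bigsm_degenerate_perturbation")
})

test_that("steady-state response solves the linear model", {
  expect_equal(steady_state_response(-diag(2), -diag(2)), -diag(2),
               ignore_attr = TRUE)
  A <- matrix(c(-1, 0.5, 0, -1), 2, 2)       # hand inversion of a triangular A
  expect_equal(steady_state_response(A, -diag(2)),
               matrix(c(-1, -0.5, 0, -1), 2, 2), ignore_attr = TRUE)
  expect_equal(steady_state_response(A, matrix(0, 2, 2)), matrix(0, 2, 2),
               ignore_attr = TRUE)
  expect_error(steady_state_response(matrix(1, 2, 2), -diag(2)),
               "singular", class = "bigsm_singular_matrix")
})

test_that("SNR follows the chi-square-quantile definition and its scaling laws", {
  Y <- diag(c(2, 1))
  expect_equal(snr_from_noise_variance(Y, 1, 0.05),
               1 / sqrt(qchisq(0.95, df = 4)))
  expect_equal(snr_from_noise_variance(Y, 1, 0.05), 0.3247, tolerance = 1e-3)
  expect_equal(snr_from_noise_variance(Y, 2, 0.05),
               snr_from_noise_variance(Y, 1, 0.05) / sqrt(2))
  expect_equal(snr_from_noise_variance(3 * Y, 1, 0.05),
               3 * snr_from_noise_variance(Y, 1, 0.05))
  expect_error(snr_from_noise_variance(Y, -1), class = "bigsm_invalid_config")
})

test_that("noise-variance calibration inverts the SNR definition", {
  Y <- diag(c(2, 1))
  snr <- 1 / sqrt(qchisq(0.95, df = 4))
  expect_equal(noise_variance_for_snr(Y, snr, 0.05), 1, tolerance = 1e-12)
  expect_equal(noise_variance_for_snr(Y, 1) / noise_variance_for_snr(Y, 10), 100)
  expect_error(noise_variance_for_snr(matrix(0, 2, 2), 1),
               class = "bigsm_degenerate_response")
})

test_that("SNR calibration round-trips to 1e-10 relative error", {
  set.seed(42)
  for (k in 1:10) {
    Y0 <- matrix(rnorm(30), 5, 6)
    s <- runif(1, 0.01, 10)
    conf <- runif(1, 0.01, 0.2)
    lam <- noise_variance_for_snr(Y0, s, conf)
    expect_equal(snr_from_noise_variance(Y0, lam, conf), s, tolerance = 1e-10)
  }
})

test_that("generated networks carry the exact configured link count", {
  A <- generate_network(sim_config(n_genes = 50, avg_links_per_gene = 3, seed = 1))
  off <- row(A) != col(A)
  expect_equal(sum(A[off] != 0), 150)
  expect_equal(sum(A[off] != 0) / 50, 3)
  A0 <- generate_network(sim_config(n_genes = 10, avg_links_per_gene = 0, seed = 2))
  expect_true(all(A0[row(A0) != col(A0)] == 0))
  expect_true(all(diag(A0) < 0))
  expect_true(all(Re(eigen(A0, only.values = TRUE)$values) < 0))
})

test_that("generated networks are stable, invertible and seed-deterministic", {
  cfg <- sim_config(n_genes = 20, avg_links_per_gene = 3, seed = 7)
  A <- generate_network(cfg)
  expect_true(all(Re(eigen(A, only.values = TRUE)$values) < 0))
  expect_gt(min(svd(A)$d), 1e-6)
  expect_true(all(diag(A) < 0))
  expect_identical(A, generate_network(cfg))
  expect_error(sim_config(n_genes = 5, avg_links_per_gene = 5),
               class = "bigsm_invalid_config")
})

test_that("regulator out-degrees are right-skewed under preferential attachment", {
  skews <- sapply(1:10, function(s) {
    A <- generate_network(sim_config(n_genes = 50, seed = s))
    d <- colSums(A != 0) - 1                 # off-diagonal out-degree
    mean((d - mean(d))^3) / sd(d)^3
  })
  expect_gt(mean(skews), 0.5)
})

test_that("simulated datasets satisfy the model and the seed contract", {
  cfg <- sim_config(n_genes = 10, snr = Inf, seed = 3)
  sim <- simulate_dataset(cfg)
  expect_equal(sim$Y, sim$Y0)
  expect_equal(sim$noise_variance, 0)
  # rearranged model: A Y + P = 0 without noise
  expect_lt(max(abs(sim$network %*% sim$Y + sim$design)), 1e-8)
  cfg2 <- sim_config(n_genes = 10, snr = 1, seed = 3)
  expect_identical(simulate_dataset(cfg2)$Y, simulate_dataset(cfg2)$Y)
})

test_that("noise realisations match the calibrated variance and zero mean", {
  # 1000 Monte Carlo datasets; pooled noise stats must match lambda
  ratios <- means <- numeric(1000)
  for (k in 1:1000) {
    sim <- simulate_dataset(sim_config(n_genes = 20, snr = 1, seed = k))
    E <- sim$Y - sim$Y0
    ratios[k] <- mean(E^2) / sim$noise_variance
    means[k] <- mean(E) / sqrt(sim$noise_variance)
  }
  expect_equal(mean(ratios), 1, tolerance = 0.05)
  # standardised grand mean has SE 1/sqrt(1000 * 400)
  expect_lt(abs(mean(means)), 4 / sqrt(1000 * 400))
})
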