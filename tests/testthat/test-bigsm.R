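test_that("design matrix is the negated transpose of the expression data", {
  expect_equal(design_from_data(matrix(1:4, 2, byrow = TRUE)),
               matrix(c(-1, -3, -2, -4), 2, byrow = TRUE))
  expect_equal(design_from_data(matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(dim(design_from_data(matrix(0, 3, 6))), c(6, 3))
})

test_that("posterior update reproduces scalar algebra and the prior-dominated limit", {
  up <- posterior_update(matrix(1), 1, alpha = 1, beta = 1)
  expect_equal(up$Sigma, matrix(0.5))
  expect_equal(up$mu, 0.5)
  # huge prior precision prunes the link
  set.seed(1)
  H <- matrix(rnorm(20), 10, 2)
  up <- posterior_update(H, rnorm(10), alpha = c(1e12, 1), beta = 1)
  expect_lt(abs(up$mu[1]), 1e-4)
  expect_lt(up$Sigma[1, 1], 1e-11)
})

test_that("posterior update agrees with the joint-conditioning oracle", {
  for (s in 1:25) {
    set.seed(s)
    N <- sample(2:8, 1)
    M <- sample(N:(2 * N), 1)
    H <- matrix(rnorm(M * N), M, N)
    p <- rnorm(M)
    alpha <- runif(N, 0.1, 10)
    beta <- runif(1, 0.5, 5)
    up <- posterior_update(H, p, alpha, beta)
    or <- oracle_posterior(H, p, alpha, beta)
    expect_lt(max(abs(up$mu - or$mu)), 1e-8)
    expect_lt(max(abs(up$Sigma - or$Sigma)), 1e-8)
    expect_equal(up$Sigma, t(up$Sigma))
    expect_true(all(eigen(up$Sigma, only.values = TRUE)$values > 0))
  }
})

test_that("log evidence matches the standard normal base case and is maximal at p = 0", {
  expect_equal(log_evidence(matrix(0), 0, alpha = 1, beta = 1, form = "direct"),
               -0.5 * log(2 * pi))
  set.seed(2)
  H <- matrix(rnorm(12), 6, 2)
  alpha <- c(1, 2)
  L0 <- log_evidence(H, rep(0, 6), alpha, 1)
  expect_gt(L0, log_evidence(H, rnorm(6), alpha, 1))
})

test_that("direct and Woodbury evidence forms agree to 1e-8", {
  for (s in 1:20) {
    prob <- random_row_problem(s, M = sample(4:10, 1), N = sample(2:6, 1))
    alpha <- runif(ncol(prob$H), 0.01, 100)
    beta <- runif(1, 0.1, 50)
    expect_equal(log_evidence(prob$H, prob$p, alpha, beta, form = "direct"),
                 log_evidence(prob$H, prob$p, alpha, beta, form = "woodbury"),
                 tolerance = 1e-8)
  }
})

test_that("hyperparameter updates match the closed-form fixed-point formulas", {
  hp <- update_hyperparameters(mu = 0.5, sigma_diag = 0.5, alpha = 1,
                               H = matrix(1), p = 1, beta = 1)
  expect_equal(hp$alpha, 2)
  expect_equal(hp$beta, 2)
  # exact zero mean prunes to the cap
  hp0 <- update_hyperparameters(mu = c(0, 0.5), sigma_diag = c(0.5, 0.5),
                                alpha = c(1, 1), H = matrix(rnorm(4), 2), p = c(1, 0),
                                beta = 1)
  expect_equal(hp0$alpha[1], 1e12)
})

test_that("converged hyperparameters are stationary points of the evidence", {
  for (s in 1:8) {
    prob <- random_row_problem(100 + s, M = 8, N = 6, k = 2, noise_sd = 0.1)
    rp <- infer_row(prob$H, prob$p, max_iter = 500, tol = 1e-10)
    grad <- fd_evidence_gradient(prob$H, prob$p, rp$alpha, rp$beta)
    expect_lt(max(abs(grad)), 1e-4)
  }
})

test_that("a single iteration is one posterior update plus one hyperparameter update", {
  prob <- random_row_problem(11)
  rp <- infer_row(prob$H, prob$p, max_iter = 1)
  beta0 <- nrow(prob$H) / sum(prob$p^2)
  up <- posterior_update(prob$H, prob$p, rep(1, ncol(prob$H)), beta0)
  hp <- update_hyperparameters(up$mu, diag(up$Sigma), rep(1, ncol(prob$H)),
                               prob$H, prob$p, beta0)
  expect_equal(rp$mu, up$mu)
  expect_equal(rp$sigma_diag, diag(up$Sigma))
  expect_equal(rp$alpha, hp$alpha)
  expect_equal(rp$beta, hp$beta)
  expect_equal(rp$iterations_run, 1L)
})

test_that("evidence does not decrease from start to convergence", {
  ok <- sapply(1:50, function(s) {
    prob <- random_row_problem(1000 + s, M = 10, N = 6, k = 2, noise_sd = 0.2)
    tr <- infer_row(prob$H, prob$p, max_iter = 35)$evidence_trace
    tr[length(tr)] >= tr[1]
  })
  expect_true(all(ok))
})

test_that("a sparse row is recovered exactly from a noiseless square system", {
  set.seed(5)
  N <- 8
  H <- matrix(rnorm(N * N), N, N)
  a <- c(1.2, -0.7, 0, 0, 0.9, 0, 0, 0)
  p <- as.vector(H %*% a)
  rp <- infer_row(H, p, max_iter = 35)
  expect_lt(sqrt(sum((rp$mu - a)^2)) / sqrt(sum(a^2)), 1e-3)
})

test_that("full-network inference recovers constructed ground truths", {
  # identity system
  post <- infer_grn(-diag(3), -diag(3))
  expect_lt(max(abs(point_estimate(post) + diag(3))), 1e-3)
  # noiseless simulated network
  sim <- noiseless_sim(10, seed = 4)
  post <- infer_grn(sim$Y, sim$design)
  expect_gt(cor(as.vector(point_estimate(post)), as.vector(sim$network)), 0.999)
})

test_that("rows decouple: permuting rows of P permutes the inferred rows", {
  sim <- noiseless_sim(6, seed = 9)
  perm <- c(3, 1, 2, 6, 5, 4)
  post <- infer_grn(sim$Y, sim$design)
  post_perm <- infer_grn(sim$Y, sim$design[perm, ])
  expect_equal(unname(post_perm$mean), unname(post$mean[perm, ]))
  expect_error(infer_grn(matrix(0, 2, 3), matrix(0, 3, 2)), "2x3",
               class = "bigsm_dimension")
})

test_that("inference is deterministic and the point estimate is the mean block", {
  sim <- simulate_dataset(sim_config(n_genes = 8, snr = 1, seed = 12))
  p1 <- infer_grn(sim$Y, sim$design)
  p2 <- infer_grn(sim$Y, sim$design)
  expect_identical(p1, p2)
  expect_identical(point_estimate(p1), p1$mean)
})
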