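# Independent oracles used across the suite. These deliberately take a
# different algebraic route than the implementation they check.

# Bayesian linear model posterior by explicit joint-Gaussian conditioning:
# (a, p) are jointly Gaussian with cov(a) = Lambda^-1, cov(p) = H Lambda^-1 H'
# + beta^-1 I, cross-cov(a, p) = Lambda^-1 H'; condition a on p by dense
# inversion. No use of the (Lambda + beta H'H)^-1 form.
oracle_posterior <- function(H, p, alpha, beta) {
  Linv <- diag(1 / alpha, length(alpha))
  S_pp <- H %*% Linv %*% t(H) + diag(1 / beta, nrow(H))
  S_ap <- Linv %*% t(H)
  K <- S_ap %*% solve(S_pp)
  list(mu = as.vector(K %*% p),
       Sigma = Linv - K %*% t(S_ap))
}

# AUROC by explicit threshold sweep + trapezoid over the ROC curve, with ties
# admitted simultaneously (equivalent to the midrank Mann-Whitney value).
oracle_auc_sweep <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tpr <- c(0, cumsum(y)[last] / sum(y))
  fpr <- c(0, cumsum(!y)[last] / sum(!y))
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Central finite-difference gradient of the log evidence with respect to
# each prior precision and the noise precision, with steps scaled to the
# parameter magnitude.
fd_evidence_gradient <- function(H, p, alpha, beta) {
  g <- numeric(length(alpha) + 1)
  for (i in seq_along(alpha)) {
    h <- 1e-5 * max(alpha[i], 1)
    ap <- am <- alpha
    ap[i] <- alpha[i] + h
    am[i] <- alpha[i] - h
    g[i] <- (log_evidence(H, p, ap, beta) - log_evidence(H, p, am, beta)) / (2 * h)
  }
  h <- 1e-5 * max(beta, 1)
  g[length(g)] <- (log_evidence(H, p, alpha, beta + h) -
                     log_evidence(H, p, alpha, beta - h)) / (2 * h)
  g
}

# Small random row problem with a sparse true coefficient vector.
random_row_problem <- function(seed, M = 8, N = 5, k = 2, noise_sd = 0.05) {
  set.seed(seed)
  H <- matrix(rnorm(M * N), M, N)
  a <- numeric(N)
  a[sample.int(N, k)] <- runif(k, 0.5, 1.5) * sample(c(-1, 1), k, TRUE)
  p <- as.vector(H %*% a) + rnorm(M, sd = noise_sd)
  list(H = H, p = p, a = a)
}

# Noiseless simulated instance (shared by several files).
noiseless_sim <- function(n_genes, seed) {
  simulate_dataset(sim_config(n_genes = n_genes, snr = Inf, seed = seed))
}
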