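#' Row-problem design matrix from expression data
#'
#' The network model Y = -A^{-1}P + E rearranges row-wise to p = H a + e with
#' H = -t(Y): each row a of the network is a sparse regression of that gene's
#' perturbation profile on the (negated, transposed) expression matrix.
#'
#' @param Y N x M expression matrix.
#' @return M x N design matrix H = -t(Y).
#' @export
design_from_data <- function(Y) {
  if (!all(is.finite(Y)))
    stop_bigsm("invalid_config", "expression matrix contains non-finite entries")
  -t(Y)
}

# Inverse of a symmetric positive-definite matrix by Cholesky, with
# escalating absolute diagonal jitter (1e-12 up to 1e-6) before failing.
spd_inverse <- function(G) {
  for (jit in c(0, 10^seq(-12, -6))) {
    R <- tryCatch(chol(G + diag(jit, nrow(G))), error = function(e) NULL)
    if (!is.null(R)) return(chol2inv(R))
  }
  stop_bigsm("numerical_failure",
             "posterior precision matrix not positive definite after jitter escalation")
}

#' Gaussian posterior of one network row
#'
#' With a zero-mean Gaussian prior of precision `alpha[i]` on each link and
#' i.i.d. Gaussian noise of precision `beta`, the posterior of the row vector
#' a given p = H a + e is Gaussian with covariance
#' `Sigma = (diag(alpha) + beta * t(H) H)^{-1}` and mean
#' `mu = beta * Sigma t(H) p`.
#'
#' @param H M x N design matrix.
#' @param p length-M perturbation vector (one row of P).
#' @param alpha length-N vector of positive prior precisions.
#' @param beta positive noise precision.
#' @return list with `mu` (length N) and `Sigma` (N x N).
#' @export
posterior_update <- function(H, p, alpha, beta) {
  stopifnot(nrow(H) == length(p), ncol(H) == length(alpha))
  if (any(alpha <= 0) || beta <= 0)
    stop_bigsm("invalid_config", "alpha and beta must be positive")
  G <- diag(alpha, ncol(H)) + beta * crossprod(H)
  Sigma <- spd_inverse(G)
  mu <- as.vector(beta * Sigma %*% crossprod(H, p))
  list(mu = mu, Sigma = Sigma)
}

#' Log marginal likelihood (evidence) of one network row
#'
#' Integrating the row vector out of the likelihood leaves
#' `p ~ N(0, C)` with `C = beta^{-1} I_M + H diag(alpha)^{-1} t(H)`, so
#' `L = -M/2 log(2 pi) - 1/2 log|C| - 1/2 t(p) C^{-1} p`.
#' `form = "direct"` builds the M x M covariance explicitly;
#' `form = "woodbury"` evaluates the identical quantity through the N x N
#' posterior precision (matrix determinant lemma + Woodbury identity), which
#' is cheaper when N < M and numerically robust for large alpha.
#'
#' @inheritParams posterior_update
#' @param form evaluation route, `"woodbury"` (default) or `"direct"`.
#' @return the scalar log evidence.
#' @export
log_evidence <- function(H, p, alpha, beta, form = c("woodbury", "direct")) {
  form <- match.arg(form)
  M <- nrow(H)
  if (form == "direct") {
    C <- diag(1 / beta, M) + tcrossprod(sweep(H, 2, sqrt(alpha), "/"))
    R <- tryCatch(chol(C), error = function(e)
      stop_bigsm("numerical_failure", "marginal covariance not positive definite"))
    z <- backsolve(R, p, transpose = TRUE)
    -0.5 * M * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
  } else {
    G <- diag(alpha, ncol(H)) + beta * crossprod(H)
    R <- tryCatch(chol(G), error = function(e)
      stop_bigsm("numerical_failure", "posterior precision not positive definite"))
    logdetC <- -M * log(beta) + 2 * sum(log(diag(R))) - sum(log(alpha))
    Hp <- crossprod(H, p)
    mu <- beta * backsolve(R, backsolve(R, Hp, transpose = TRUE))
    quad <- beta * sum(p * (p - as.vector(H %*% mu)))
    -0.5 * (M * log(2 * pi) + logdetC + quad)
  }
}

#' Evidence-maximisation update of the hyperparameters
#'
#' Setting the alpha- and beta-gradients of the log evidence to zero gives the
#' classical fixed-point updates: with `gamma_i = 1 - alpha_i * Sigma_ii` (the
#' effective number of parameters claimed by link i),
#' `alpha_i <- gamma_i / mu_i^2` and
#' `beta <- (M - sum(gamma)) / ||p - H mu||^2`.
#' Precisions are clamped to `[alpha_floor, alpha_cap]`; a link whose mean
#' underflows to zero jumps to the cap (soft pruning, the column is retained).
#' If the beta denominator `M - sum(gamma)` is not positive the previous beta
#' is kept with a warning (the model is near interpolation).
#'
#' @param mu,sigma_diag posterior mean and covariance diagonal from
#'   [posterior_update()].
#' @param alpha current prior precisions.
#' @param H,p the row problem.
#' @param beta current noise precision.
#' @param alpha_cap,alpha_floor clamp bounds for both precisions.
#' @return list with `alpha` (length N) and `beta` (scalar).
#' @export
update_hyperparameters <- function(mu, sigma_diag, alpha, H, p, beta,
                                   alpha_cap = 1e12, alpha_floor = 1e-12) {
  M <- nrow(H)
  gamma <- 1 - alpha * sigma_diag
  gamma <- pmin(pmax(gamma, 0), 1)
  alpha_new <- gamma / mu^2
  alpha_new[!is.finite(alpha_new)] <- alpha_cap
  alpha_new <- pmin(pmax(alpha_new, alpha_floor), alpha_cap)
  resid2 <- sum((p - as.vector(H %*% mu))^2)
  denom <- M - sum(gamma)
  if (denom <= 0) {
    warning("beta update denominator non-positive (model near interpolation); keeping previous beta")
    beta_new <- beta
  } else {
    beta_new <- denom / resid2
    if (!is.finite(beta_new)) beta_new <- alpha_cap
    beta_new <- min(max(beta_new, alpha_floor), alpha_cap)
  }
  list(alpha = alpha_new, beta = beta_new)
}

#' Infer the posterior of one network row
#'
#' Iterates [posterior_update()] and [update_hyperparameters()] starting from
#' unit prior precisions (alpha = 1) and a data-scaled noise precision
#' `beta = M / ||p||^2` (the precision of a null model treating all of p as
#' noise; a unit start over-shrinks weak links on low-noise data and prunes
#' them before beta can adapt). Each iteration computes the posterior at the
#' current hyperparameters, records the log evidence, then refreshes the
#' hyperparameters. By default exactly `max_iter` iterations are run; setting
#' `tol` enables early stopping when `max |delta log(alpha)| < tol`.
#'
#' @param H M x N design matrix (from [design_from_data()]).
#' @param p length-M perturbation vector.
#' @param max_iter iteration cap (default 35; 10-50 is a sensible range,
#'   larger networks need more).
#' @param tol optional early-stopping tolerance on the log-precision change;
#'   `NULL` (default) disables early stopping.
#' @param alpha0,beta0 initial precisions; `beta0 = NULL` (default) uses
#'   `M / ||p||^2`.
#' @param alpha_cap,alpha_floor precision clamp bounds.
#' @return object of class `row_posterior`: `mu`, `sigma_diag`, `alpha`,
#'   `beta`, `evidence_trace`, `iterations_run`.
#' @export
infer_row <- function(H, p, max_iter = 35L, tol = NULL,
                      alpha0 = 1, beta0 = NULL,
                      alpha_cap = 1e12, alpha_floor = 1e-12) {
  if (max_iter < 1) stop_bigsm("invalid_config", "max_iter must be >= 1")
  N <- ncol(H)
  alpha <- rep(alpha0, N)
  beta <- if (is.null(beta0)) {
    if (sum(p^2) > 0) nrow(H) / sum(p^2) else 1
  } else beta0
  trace <- numeric(max_iter)
  it <- 0L
  up <- NULL
  for (k in seq_len(max_iter)) {
    it <- k
    up <- posterior_update(H, p, alpha, beta)
    trace[k] <- log_evidence(H, p, alpha, beta)
    hp <- update_hyperparameters(up$mu, diag(up$Sigma), alpha, H, p, beta,
                                 alpha_cap = alpha_cap, alpha_floor = alpha_floor)
    delta <- max(abs(log(hp$alpha) - log(alpha)))
    alpha <- hp$alpha
    beta <- hp$beta
    if (!is.null(tol) && delta < tol) break
  }
  structure(list(mu = up$mu, sigma_diag = diag(up$Sigma),
                 alpha = alpha, beta = beta,
                 evidence_trace = trace[seq_len(it)], iterations_run = it),
            class = "row_posterior")
}

#' Infer a full network posterior from expression and perturbation data
#'
#' Builds H = -t(Y) once and solves the N independent row problems
#' `P[i, ] = H a_i + e`; row i of the result describes the regulators of gene
#' i. Entry (i, j) of `mean` / `variance` is the posterior mean / variance of
#' the regulation of target gene i (row) by regulator gene j (column).
#'
#' @param Y N x M expression (fold-change) matrix.
#' @param P N x M perturbation design matrix.
#' @inheritParams infer_row
#' @return object of class `grn_posterior`: `mean`, `variance`, `row_alphas`
#'   (all N x N), `row_betas`, `iterations` (length N), `evidence` (list of
#'   per-row traces), `gene_names`, `config`.
#' @export
infer_grn <- function(Y, P, max_iter = 35L, tol = NULL,
                      alpha_cap = 1e12, alpha_floor = 1e-12) {
  if (!identical(dim(Y), dim(P)))
    stop_bigsm("dimension", "Y is %s but P is %s",
               paste(dim(Y), collapse = "x"), paste(dim(P), collapse = "x"))
  N <- nrow(Y)
  genes <- rownames(Y)
  if (is.null(genes)) genes <- paste0("G", seq_len(N))
  H <- design_from_data(Y)
  mean_m <- variance_m <- alphas <- matrix(NA_real_, N, N,
                                           dimnames = list(genes, genes))
  betas <- iters <- numeric(N)
  evid <- vector("list", N)
  for (i in seq_len(N)) {
    rp <- withCallingHandlers(
      tryCatch(infer_row(H, P[i, ], max_iter = max_iter, tol = tol,
                         alpha_cap = alpha_cap, alpha_floor = alpha_floor),
               bigsm_numerical_failure = function(e)
                 stop_bigsm("numerical_failure", "row %d (%s): %s",
                            i, genes[i], conditionMessage(e))),
      warning = function(w) {
        warning(sprintf("row %d (%s): %s", i, genes[i], conditionMessage(w)),
                call. = FALSE)
        invokeRestart("muffleWarning")
      })
    mean_m[i, ] <- rp$mu
    variance_m[i, ] <- rp$sigma_diag
    alphas[i, ] <- rp$alpha
    betas[i] <- rp$beta
    iters[i] <- rp$iterations_run
    evid[[i]] <- rp$evidence_trace
  }
  structure(list(mean = mean_m, variance = variance_m,
                 row_alphas = alphas, row_betas = betas,
                 iterations = iters, evidence = evid, gene_names = genes,
                 config = list(max_iter = max_iter, tol = tol,
                               alpha_cap = alpha_cap, alpha_floor = alpha_floor)),
            class = "grn_posterior")
}

#' Point estimate of an inferred network posterior
#'
#' The inferred network is the matrix of posterior means: for a Gaussian
#' posterior the mean is also the mode, so this is the maximum-a-posteriori
#' network under the learned hyperparameters.
#'
#' @param post a `grn_posterior` from [infer_grn()].
#' @return N x N matrix of posterior mean link weights.
#' @export
point_estimate <- function(post) {
  stopifnot(inherits(post, "grn_posterior"))
  post$mean
}

#' @export
print.grn_posterior <- function(x, ...) {
  N <- nrow(x$mean)
  cat(sprintf("GRN posterior over %d genes (%d candidate links)\n", N, N * N))
  cat(sprintf("  iterations per row: %s | links at precision cap: %d\n",
              paste(range(x$iterations), collapse = "-"),
              sum(x$row_alphas >= x$config$alpha_cap)))
  cat(sprintf("  mean |posterior mean|: %.4g | mean posterior variance: %.4g\n",
              mean(abs(x$mean)), mean(x$variance)))
  invisible(x)
}

#' @export
print.row_posterior <- function(x, ...) {
  cat(sprintf("Row posterior over %d links; %d iterations, beta = %.4g\n",
              length(x$mu), x$iterations_run, x$beta))
  invisible(x)
}
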