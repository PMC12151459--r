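#' Simulation configuration
#'
#' Bundles the settings of one synthetic benchmark instance: a scale-free
#' ground-truth network of `n_genes` genes with `avg_links_per_gene`
#' off-diagonal regulatory links per gene on average, single-gene knockdown
#' perturbations replicated `replicates` times, and additive i.i.d. Gaussian
#' measurement noise calibrated so the data attain the requested
#' signal-to-noise ratio `snr` (see [noise_variance_for_snr()]).
#'
#' @param n_genes number of genes N (>= 2).
#' @param avg_links_per_gene average number of off-diagonal links per gene;
#'   the generated network carries exactly `round(avg_links_per_gene * n_genes)`
#'   links. Default 3, the typical sparsity of biological regulatory networks.
#' @param snr target signal-to-noise ratio; `Inf` disables noise.
#' @param replicates number of technical replicates r (>= 1); data matrices
#'   are N x rN.
#' @param seed integer master seed; topology, weights and noise use
#'   independently derived streams.
#' @param weight_low,weight_high magnitude range of off-diagonal link weights,
#'   drawn uniformly with random sign.
#' @param confidence_level confidence level of the chi-square quantile in the
#'   SNR definition (default 0.05).
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_dataset()], [generate_network()]
#' @export
sim_config <- function(n_genes, avg_links_per_gene = 3, snr = 1,
                       replicates = 1L, seed = 1L,
                       weight_low = 0.1, weight_high = 1,
                       confidence_level = 0.05) {
  n_genes <- as.integer(n_genes)
  replicates <- as.integer(replicates)
  if (is.na(n_genes) || n_genes < 2)
    stop_bigsm("invalid_config", "n_genes must be an integer >= 2")
  if (avg_links_per_gene < 0 ||
      round(avg_links_per_gene * n_genes) > n_genes * (n_genes - 1))
    stop_bigsm("invalid_config",
               "requested %d links exceed the %d available off-diagonal slots",
               round(avg_links_per_gene * n_genes), n_genes * (n_genes - 1))
  if (replicates < 1)
    stop_bigsm("invalid_config", "replicates must be >= 1")
  if (!(snr > 0))
    stop_bigsm("invalid_config", "snr must be positive (Inf allowed)")
  if (confidence_level <= 0 || confidence_level >= 1)
    stop_bigsm("invalid_config", "confidence_level must lie in (0, 1)")
  if (weight_low <= 0 || weight_high < weight_low)
    stop_bigsm("invalid_config", "need 0 < weight_low <= weight_high")
  structure(list(n_genes = n_genes,
                 avg_links_per_gene = avg_links_per_gene,
                 snr = snr, replicates = replicates,
                 seed = as.integer(seed),
                 weight_low = weight_low, weight_high = weight_high,
                 confidence_level = confidence_level),
            class = "sim_config")
}

# Directed topology with exactly n_links off-diagonal edges. Regulators
# (columns) are chosen by preferential attachment on current out-degree,
# targets uniformly; no self-loops, no duplicate edges.
draw_topology <- function(n_genes, n_links) {
  adj <- matrix(FALSE, n_genes, n_genes)
  if (n_links == 0) return(adj)
  out_deg <- rep(0, n_genes)
  placed <- 0L
  stalls <- 0L
  while (placed < n_links) {
    j <- sample.int(n_genes, 1L, prob = out_deg + 1)
    avail <- which(!adj[, j])
    avail <- avail[avail != j]
    if (length(avail) == 0L) {
      stalls <- stalls + 1L
      if (stalls > 1000L) {  # regulator saturated repeatedly: fill uniformly
        free <- which(!adj & row(adj) != col(adj))
        slot <- if (length(free) == 1L) free else sample(free, 1L)
        adj[slot] <- TRUE
        out_deg[col(adj)[slot]] <- out_deg[col(adj)[slot]] + 1
        placed <- placed + 1L
      }
      next
    }
    i <- if (length(avail) == 1L) avail else sample(avail, 1L)
    adj[i, j] <- TRUE
    out_deg[j] <- out_deg[j] + 1
    placed <- placed + 1L
  }
  adj
}

is_stable <- function(A) {
  all(Re(eigen(A, only.values = TRUE)$values) < 0)
}

min_singular <- function(A) min(svd(A, nu = 0, nv = 0)$d)

#' Generate a sparse, stable ground-truth regulatory network
#'
#' Draws a directed scale-free topology (preferential attachment on the
#' regulator choice) with exactly `round(avg_links_per_gene * n_genes)`
#' off-diagonal links, link weights uniform in magnitude over
#' `[weight_low, weight_high]` with random sign, and self-degradation
#' (diagonal) fixed at -1. Entry `A[i, j]` is the signed regulation of target
#' gene i (row) by regulator gene j (column). If the matrix is not Hurwitz
#' stable the off-diagonal entries are damped by 0.9 (up to 50 times); if
#' stability or invertibility (smallest singular value > 1e-6) still fails
#' the topology is redrawn, up to 20 times.
#'
#' @param config a [sim_config()].
#' @return N x N numeric matrix with gene names `G1..GN` as dimnames; all
#'   eigenvalues have negative real part and the smallest singular value
#'   exceeds 1e-6.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$n_genes
  L <- round(config$avg_links_per_gene * N)
  genes <- paste0("G", seq_len(N))
  set.seed(config$seed)
  streams <- sample.int(2147483000L, 2L)
  for (attempt in 0:19) {
    set.seed((streams[1] + attempt) %% 2147483647L)
    adj <- draw_topology(N, L)
    set.seed((streams[2] + attempt) %% 2147483647L)
    A <- matrix(0, N, N, dimnames = list(genes, genes))
    nz <- which(adj)
    A[nz] <- runif(length(nz), config$weight_low, config$weight_high) *
      sample(c(-1, 1), length(nz), replace = TRUE)
    diag(A) <- -1
    off <- row(A) != col(A)
    for (damp in 0:50) {
      if (damp > 0) A[off] <- A[off] * 0.9
      if (is_stable(A) && min_singular(A) > 1e-6) return(A)
    }
  }
  stop_bigsm("generation_failure",
             "no stable invertible network after 20 topologies (seed %d)",
             config$seed)
}

#' Single-gene knockdown perturbation design
#'
#' Builds the perturbation matrix of the standard knockdown experiment: each
#' gene is perturbed once per replicate block, so the design is `replicates`
#' horizontal copies of `magnitude` times the identity. Knockdowns are encoded
#' with a negative magnitude (default -1).
#'
#' @param n_genes number of genes N.
#' @param replicates number of technical replicates r.
#' @param magnitude nonzero perturbation strength on the fold-change scale.
#' @param gene_names optional character vector of N gene names.
#' @return N x (r*N) matrix; columns are named `<gene>_r<k>`.
#' @export
make_knockdown_design <- function(n_genes, replicates = 1L, magnitude = -1,
                                  gene_names = NULL) {
  if (n_genes < 1 || replicates < 1)
    stop_bigsm("invalid_config", "n_genes and replicates must be >= 1")
  if (magnitude == 0)
    stop_bigsm("degenerate_perturbation", "perturbation magnitude must be nonzero")
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n_genes))
  P <- do.call(cbind, replicate(replicates, magnitude * diag(n_genes),
                                simplify = FALSE))
  dimnames(P) <- list(gene_names,
                      paste0(rep(gene_names, replicates), "_r",
                             rep(seq_len(replicates), each = n_genes)))
  P
}

#' Noise-free steady-state response to a perturbation design
#'
#' Under the linearised steady-state model dy/dt = A y + p = 0, the response
#' to perturbation p is y = -A^{-1} p; column-wise over a design P this gives
#' Y0 = -A^{-1} P.
#'
#' @param A N x N network matrix (invertible).
#' @param P N x M perturbation design.
#' @return N x M response matrix Y0.
#' @export
steady_state_response <- function(A, P) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop_bigsm("dimension", "A must be square")
  if (nrow(P) != nrow(A))
    stop_bigsm("dimension", "P has %d rows but A is %d x %d",
               nrow(P), nrow(A), ncol(A))
  smin <- min_singular(A)
  if (smin < .Machine$double.eps * nrow(A) * max(abs(A)))
    stop_bigsm("singular_matrix",
               "A is numerically singular (smallest singular value %.3e)", smin)
  Y0 <- -solve(A, P)
  dimnames(Y0) <- dimnames(P)
  Y0
}

chi2_quantile <- function(confidence_level, df) {
  stats::qchisq(1 - confidence_level, df = df)
}

#' Signal-to-noise ratio of an expression matrix
#'
#' SNR is defined as `sigma_min(Y) / sqrt(lambda * q)`, where `sigma_min` is
#' the smallest singular value of Y, `lambda` the per-entry noise variance and
#' `q` the upper chi-square quantile at the given confidence level with
#' N*M degrees of freedom (N genes, M experiments). The chi-square term is the
#' high-probability bound on the Frobenius norm of the Gaussian noise matrix,
#' so SNR compares the weakest signal direction against the noise magnitude.
#'
#' @param Y N x M expression matrix.
#' @param noise_variance per-entry noise variance lambda (> 0).
#' @param confidence_level confidence level of the chi-square quantile.
#' @return the scalar SNR.
#' @export
snr_from_noise_variance <- function(Y, noise_variance, confidence_level = 0.05) {
  if (!(noise_variance > 0))
    stop_bigsm("invalid_config", "noise_variance must be positive")
  if (confidence_level <= 0 || confidence_level >= 1)
    stop_bigsm("invalid_config", "confidence_level must lie in (0, 1)")
  q <- chi2_quantile(confidence_level, length(Y))
  min_singular(Y) / sqrt(noise_variance * q)
}

#' Noise variance attaining a target SNR
#'
#' Inverts the SNR definition: `lambda = sigma_min(Y0)^2 / (snr^2 * q)`.
#' Calibration is done on the noise-free response matrix Y0, so a round trip
#' through [snr_from_noise_variance()] reproduces the target exactly.
#'
#' @param Y0 N x M noise-free response matrix (nonzero).
#' @param snr_target target SNR (> 0, finite).
#' @param confidence_level confidence level of the chi-square quantile.
#' @return the per-entry noise variance lambda.
#' @export
noise_variance_for_snr <- function(Y0, snr_target, confidence_level = 0.05) {
  if (!(snr_target > 0) || !is.finite(snr_target))
    stop_bigsm("invalid_config", "snr_target must be positive and finite")
  smin <- min_singular(Y0)
  if (smin <= 0)
    stop_bigsm("degenerate_response",
               "response matrix has zero smallest singular value")
  q <- chi2_quantile(confidence_level, length(Y0))
  smin^2 / (snr_target^2 * q)
}

#' Simulate a complete benchmark instance
#'
#' Generates a ground-truth network, a single-gene knockdown design, the
#' noise-free steady-state response Y0 = -A^{-1} P, and the measured
#' fold-change matrix Y = Y0 + E where E is i.i.d. zero-mean Gaussian with
#' variance calibrated to the configured SNR. With `snr = Inf` the data are
#' noise-free and `noise_variance` is 0.
#'
#' @param config a [sim_config()].
#' @return a list of class `grn_sim` with elements `network` (N x N truth),
#'   `design` (N x M), `Y` (N x M measured), `Y0` (noise-free), `snr_target`,
#'   `noise_variance`, `replicates`, `seed`, `confidence_level`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  A <- generate_network(config)
  P <- make_knockdown_design(config$n_genes, config$replicates,
                             magnitude = -1, gene_names = rownames(A))
  Y0 <- steady_state_response(A, P)
  if (is.finite(config$snr)) {
    lambda <- noise_variance_for_snr(Y0, config$snr, config$confidence_level)
    set.seed(derive_seed(config$seed, 104729L))
    E <- matrix(stats::rnorm(length(Y0), sd = sqrt(lambda)),
                nrow(Y0), ncol(Y0))
    Y <- Y0 + E
  } else {
    lambda <- 0
    Y <- Y0
  }
  dimnames(Y) <- dimnames(Y0)
  structure(list(network = A, design = P, Y = Y, Y0 = Y0,
                 snr_target = config$snr, noise_variance = lambda,
                 replicates = config$replicates, seed = config$seed,
                 confidence_level = config$confidence_level),
            class = "grn_sim")
}

# Deterministic auxiliary seed, kept inside 32-bit integer range.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 48271 + salt) %% 2147483647)
}

#' @export
print.grn_sim <- function(x, ...) {
  cat(sprintf("Simulated GRN benchmark instance: %d genes, %d experiment(s)\n",
              nrow(x$Y), ncol(x$Y)))
  cat(sprintf("  links: %d off-diagonal | target SNR: %s | noise variance: %.4g\n",
              sum(x$network[row(x$network) != col(x$network)] != 0),
              format(x$snr_target), x$noise_variance))
  cat(sprintf("  replicates: %d | seed: %d\n", x$replicates, x$seed))
  invisible(x)
}
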