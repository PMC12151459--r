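# End-to-end benchmark driver: simulate networks, run the selected inference
# methods at each noise level, evaluate against the simulated truth.

#' Benchmark specification
#'
#' Defaults mirror the main simulated benchmark: 20 networks of 50 genes with
#' 3 links/gene, one replicate, SNR levels 1, 0.1 and 0.01, self-loops
#' excluded from evaluation.
#'
#' @param n_networks number of ground-truth networks per noise level.
#' @param n_genes genes per network.
#' @param snr_levels vector of positive signal-to-noise ratios.
#' @param replicates technical replicates.
#' @param methods subset of `"bigsm"`, `"lsco"`, `"zscore"`, `"lasso"`.
#' @param seed master seed; all per-cell seeds derive from it.
#' @param self_loops include diagonal entries in evaluation?
#' @param avg_links_per_gene network sparsity.
#' @param max_iter iteration cap for the Bayesian method.
#' @return a `benchmark_spec` list.
#' @export
benchmark_spec <- function(n_networks = 20L, n_genes = 50L,
                           snr_levels = c(1, 0.1, 0.01), replicates = 1L,
                           methods = c("bigsm", "lsco", "zscore"),
                           seed = 1L, self_loops = FALSE,
                           avg_links_per_gene = 3, max_iter = 35L) {
  if (n_networks < 1) stop_bigsm("invalid_config", "n_networks must be >= 1")
  if (length(snr_levels) == 0 || any(!(snr_levels > 0)))
    stop_bigsm("invalid_config", "snr_levels must be nonempty and positive")
  known <- c("bigsm", "lsco", "zscore", "lasso")
  if (length(methods) == 0 || !all(methods %in% known))
    stop_bigsm("invalid_config", "methods must be a nonempty subset of {%s}",
               paste(known, collapse = ", "))
  structure(list(n_networks = as.integer(n_networks),
                 n_genes = as.integer(n_genes),
                 snr_levels = snr_levels, replicates = as.integer(replicates),
                 methods = methods, seed = as.integer(seed),
                 self_loops = isTRUE(self_loops),
                 avg_links_per_gene = avg_links_per_gene,
                 max_iter = as.integer(max_iter)),
            class = "benchmark_spec")
}

#' Run one inference method on a dataset
#'
#' Thin dispatcher shared by [run_benchmark()] and the command-line driver.
#'
#' @param method one of `"bigsm"`, `"lsco"`, `"zscore"`, `"lasso"`.
#' @param Y,P data matrices.
#' @param max_iter iteration cap (bigsm only).
#' @param seed seed for seeded sub-procedures (lasso folds).
#' @return N x N weight matrix (posterior mean for bigsm).
#' @export
infer_with_method <- function(method, Y, P, max_iter = 35L, seed = 1L) {
  switch(method,
    bigsm = point_estimate(infer_grn(Y, P, max_iter = max_iter)),
    lsco = lsco_inference(Y, P)$weights,
    zscore = zscore_inference(Y, P)$weights,
    lasso = lasso_inference(Y, P, seed = seed)$weights,
    stop_bigsm("invalid_config", "unknown method '%s'", method))
}

#' Run a full simulated benchmark
#'
#' For each network and SNR level: simulate data (the ground-truth network is
#' shared across noise levels; noise streams are derived deterministically
#' from the master seed), run every method, and evaluate. Per-stage timings
#' are logged to stderr; a failing cell is recorded with NA metrics and the
#' run continues.
#'
#' @param spec a [benchmark_spec()].
#' @param out_dir optional directory: simulated bundles and the results table
#'   are written beneath it.
#' @param verbose log progress to stderr?
#' @return data.frame with columns `method`, `network`, `snr`, `aupr`,
#'   `auroc`, `max_f1`.
#' @export
run_benchmark <- function(spec, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(spec, "benchmark_spec"))
  set.seed(spec$seed)
  net_seeds <- sample.int(2147480000L, spec$n_networks)
  rows <- vector("list", spec$n_networks * length(spec$snr_levels) *
                   length(spec$methods))
  k <- 0L
  for (nk in seq_len(spec$n_networks)) {
    cfg <- sim_config(n_genes = spec$n_genes,
                      avg_links_per_gene = spec$avg_links_per_gene,
                      snr = Inf, replicates = spec$replicates,
                      seed = net_seeds[nk])
    A <- generate_network(cfg)
    P <- make_knockdown_design(spec$n_genes, spec$replicates,
                               gene_names = rownames(A))
    Y0 <- steady_state_response(A, P)
    for (si in seq_along(spec$snr_levels)) {
      snr <- spec$snr_levels[si]
      lambda <- noise_variance_for_snr(Y0, snr, cfg$confidence_level)
      set.seed(derive_seed(net_seeds[nk], 104729L + si))
      Y <- Y0 + matrix(stats::rnorm(length(Y0), sd = sqrt(lambda)),
                       nrow(Y0), ncol(Y0))
      dimnames(Y) <- dimnames(Y0)
      if (!is.null(out_dir)) {
        sim <- structure(list(network = A, design = P, Y = Y, Y0 = Y0,
                              snr_target = snr, noise_variance = lambda,
                              replicates = spec$replicates,
                              seed = net_seeds[nk],
                              confidence_level = cfg$confidence_level),
                         class = "grn_sim")
        write_benchmark_bundle(sim, file.path(out_dir,
                                              sprintf("net%02d_snr%g", nk, snr)))
      }
      for (m in spec$methods) {
        k <- k + 1L
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch({
          W <- infer_with_method(m, Y, P, max_iter = spec$max_iter,
                                 seed = derive_seed(net_seeds[nk], 31L + si))
          ev <- evaluate_grn(W, A, include_self_loops = spec$self_loops)
          c(ev$aupr, ev$auroc, ev$max_f1)
        }, error = function(e) {
          if (verbose)
            message(sprintf("[bigsm] FAILED net %d snr %g method %s: %s",
                            nk, snr, m, conditionMessage(e)))
          c(NA_real_, NA_real_, NA_real_)
        })
        if (verbose)
          message(sprintf("[bigsm] net %d/%d snr %g %-6s %5.2fs  AUPR %.3f AUROC %.3f F1 %.3f",
                          nk, spec$n_networks, snr, m,
                          proc.time()[["elapsed"]] - t0, res[1], res[2], res[3]))
        rows[[k]] <- data.frame(method = m, network = nk, snr = snr,
                                aupr = res[1], auroc = res[2], max_f1 = res[3],
                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out, file.path(out_dir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
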