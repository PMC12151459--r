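# Threshold-sweep benchmarking of inferred networks against a gold standard,
# plus kernel-density comparison of inferred and true edge-weight
# distributions.

# Accept raw matrices as well as the package's result objects.
as_weight_matrix <- function(x) {
  if (inherits(x, "grn_posterior")) return(x$mean)
  if (inherits(x, "baseline_result")) return(x$weights)
  if (inherits(x, "grn_sim")) return(x$network)
  if (is.matrix(x)) return(x)
  stop_bigsm("invalid_config", "cannot interpret object of class '%s' as a weight matrix",
             class(x)[1])
}

#' Evaluate an inferred network against the ground truth
#'
#' Links are ranked by absolute predicted weight and swept over every distinct
#' threshold; the truth is binarised at exactly zero. AUROC is computed by the
#' rank (Mann-Whitney) formulation with midrank tie handling, AUPR by the
#' trapezoid rule over the precision-recall sweep (tied predictions are
#' admitted simultaneously), and max F1 as the sweep maximum. Self-loops
#' (diagonal entries) are excluded by default, matching the harder benchmark
#' setting in which trivially predictable self-regulation is removed.
#'
#' @param predicted N x N weight matrix (or a `grn_posterior` /
#'   `baseline_result`, whose point estimate is used).
#' @param truth N x N ground-truth matrix (or a `grn_sim`).
#' @param include_self_loops keep diagonal entries in the candidate set?
#' @return object of class `eval_result`: `aupr`, `auroc`, `max_f1`,
#'   `pr_points`, `roc_points`, `include_self_loops`, `n_true_links`,
#'   `n_candidates`.
#' @export
evaluate_grn <- function(predicted, truth, include_self_loops = FALSE) {
  pred <- as_weight_matrix(predicted)
  tru <- as_weight_matrix(truth)
  if (!identical(dim(pred), dim(tru)))
    stop_bigsm("dimension", "predicted is %s but truth is %s",
               paste(dim(pred), collapse = "x"), paste(dim(tru), collapse = "x"))
  keep <- if (include_self_loops) rep(TRUE, length(pred)) else
    as.vector(row(pred) != col(pred))
  s <- abs(as.vector(pred)[keep])
  y <- as.vector(tru)[keep] != 0
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0 || n0 == 0)
    stop_bigsm("undefined_metric",
               "need both true links and true non-links among evaluated entries (%d links of %d)",
               n1, n1 + n0)
  r <- rank(s)                                 # midranks for ties
  auroc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  o <- order(s, decreasing = TRUE)
  ss <- s[o]
  ys <- y[o]
  last <- which(c(ss[-1] != ss[-length(ss)], TRUE))  # end of each tie group
  TP <- cumsum(ys)[last]
  FP <- cumsum(!ys)[last]
  prec <- TP / (TP + FP)
  rec <- TP / n1
  fpr <- FP / n0
  f1 <- ifelse(TP > 0, 2 * prec * rec / (prec + rec), 0)
  pr_points <- cbind(recall = c(0, rec), precision = c(prec[1], prec))
  roc_points <- cbind(fpr = c(0, fpr), tpr = c(0, rec))
  structure(list(aupr = pracma::trapz(pr_points[, 1], pr_points[, 2]),
                 auroc = auroc,
                 max_f1 = max(f1),
                 pr_points = pr_points, roc_points = roc_points,
                 include_self_loops = include_self_loops,
                 n_true_links = n1, n_candidates = n1 + n0),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("Network evaluation over %d candidate links (%d true, self-loops %s)\n",
              x$n_candidates, x$n_true_links,
              if (x$include_self_loops) "included" else "excluded"))
  cat(sprintf("  AUPR %.4f | AUROC %.4f | max F1 %.4f\n",
              x$aupr, x$auroc, x$max_f1))
  invisible(x)
}

#' Chance-level (and boundary) sanity check for the ranking metrics
#'
#' Draws random ground-truth networks (about three links per gene,
#' self-loops excluded) and scores them with uniform random predictions
#' (`mode = "random"`), with their own absolute weights (`"perfect"`), or
#' with reversed perfect scores (`"inverted"`), returning the mean AUROC over
#' `reps` repetitions. Random scoring should sit at 0.5, perfect at 1,
#' inverted at 0.
#'
#' @param n network size (>= 10).
#' @param seed integer seed.
#' @param reps repetitions (default 200).
#' @param mode scoring mode.
#' @return mean AUROC.
#' @export
random_baseline_check <- function(n, seed = 1L, reps = 200L,
                                  mode = c("random", "perfect", "inverted")) {
  mode <- match.arg(mode)
  if (n < 10) stop_bigsm("invalid_config", "n must be >= 10")
  set.seed(seed)
  L <- round(3 * n)
  vals <- vapply(seq_len(reps), function(k) {
    tru <- matrix(0, n, n)
    off <- which(row(tru) != col(tru))
    tru[sample(off, L)] <- stats::runif(L, 0.1, 1) * sample(c(-1, 1), L, TRUE)
    scores <- switch(mode,
      random = matrix(stats::runif(n * n), n, n),
      perfect = abs(tru),
      inverted = max(abs(tru)) - abs(tru))
    evaluate_grn(scores, tru, include_self_loops = FALSE)$auroc
  }, numeric(1))
  mean(vals)
}

gaussian_kde <- function(x, bw, grid) {
  vapply(grid, function(g) mean(stats::dnorm(g - x, sd = bw)), numeric(1))
}

#' Compare the weight density of an inferred network with the truth
#'
#' Both weight samples are min-max normalised with the TRUE network's minimum
#' and maximum, then shifted back to the sample's own pre-normalisation mean,
#' putting them on a common scale without moving their centres. Gaussian
#' kernel density estimates (Silverman's rule-of-thumb bandwidth) are fitted
#' to all N^2 entries of each matrix on a shared 512-point grid spanning both
#' supports plus three bandwidths, and the L1 distance between the two
#' densities is returned; smaller means the inferred weight distribution
#' matches the true one more closely.
#'
#' @param truth N x N ground-truth matrix (or `grn_sim`).
#' @param predicted N x N inferred weight matrix (or result object).
#' @return object of class `density_comparison`: `grid`, `true_pdf`,
#'   `predicted_pdf`, `l1_distance`, `normalization` (true min/max and both
#'   sample means).
#' @export
density_compare <- function(truth, predicted) {
  tru <- as_weight_matrix(truth)
  pred <- as_weight_matrix(predicted)
  if (!identical(dim(pred), dim(tru)))
    stop_bigsm("dimension", "predicted is %s but truth is %s",
               paste(dim(pred), collapse = "x"), paste(dim(tru), collapse = "x"))
  tmin <- min(tru)
  tmax <- max(tru)
  if (tmax == tmin)
    stop_bigsm("degenerate_normalization",
               "true network is constant; min-max normalisation undefined")
  normalize <- function(x) {
    z <- (as.vector(x) - tmin) / (tmax - tmin)
    z - mean(z) + mean(x)
  }
  tv <- normalize(tru)
  pv <- normalize(pred)
  bw_t <- stats::bw.nrd0(tv)
  bw_p <- stats::bw.nrd0(pv)
  h <- max(bw_t, bw_p)
  grid <- seq(min(tv, pv) - 3 * h, max(tv, pv) + 3 * h, length.out = 512)
  f_t <- gaussian_kde(tv, bw_t, grid)
  f_p <- gaussian_kde(pv, bw_p, grid)
  structure(list(grid = grid, true_pdf = f_t, predicted_pdf = f_p,
                 l1_distance = pracma::trapz(grid, abs(f_t - f_p)),
                 normalization = list(true_min = tmin, true_max = tmax,
                                      true_mean = mean(tru),
                                      predicted_mean = mean(pred))),
            class = "density_comparison")
}

#' @export
print.density_comparison <- function(x, ...) {
  cat(sprintf("Weight-density comparison on a %d-point grid: L1 distance %.4f\n",
              length(x$grid), x$l1_distance))
  invisible(x)
}
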