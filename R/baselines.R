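# Baseline inference methods used as comparators in the benchmark:
# least squares (LSCO family), knockdown z-scores, and the lasso.

baseline_result <- function(weights, method, params = list()) {
  structure(list(weights = weights, method = method, params = params),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("%s inference: %d x %d weight matrix (%d nonzero)\n",
              x$method, nrow(x$weights), ncol(x$weights), sum(x$weights != 0)))
  invisible(x)
}

#' Least-squares network inference
#'
#' Solves each row problem p = H a (H = -t(Y)) by ordinary least squares,
#' using the Moore-Penrose pseudo-inverse so rank-deficient designs get the
#' minimum-norm solution. Continuous weights are returned; sparsification is
#' left to the evaluation threshold sweep (the "cut-off" of the LSCO family).
#'
#' @param Y N x M expression matrix.
#' @param P N x M perturbation design.
#' @return a `baseline_result` with the N x N weight matrix.
#' @export
lsco_inference <- function(Y, P) {
  if (!identical(dim(Y), dim(P)))
    stop_bigsm("dimension", "Y is %s but P is %s",
               paste(dim(Y), collapse = "x"), paste(dim(P), collapse = "x"))
  H <- design_from_data(Y)
  W <- t(MASS::ginv(H) %*% t(P))      # rows: a_i = pinv(H) p_i
  dimnames(W) <- list(rownames(Y), rownames(Y))
  baseline_result(W, "lsco")
}

#' Z-score network inference
#'
#' Standardises each gene's expression profile across all experiments
#' (sample standard deviation), then scores link (i, j) as the mean
#' standardised response of gene i over the experiments in which gene j is
#' perturbed (nonzero entries of row j of P). A strongly displaced response
#' of gene i under knockdown of gene j marks j as a likely regulator of i,
#' with the sign carrying activation/inhibition.
#'
#' @inheritParams lsco_inference
#' @return a `baseline_result`; rows of Y with zero standard deviation yield
#'   zero weights with a warning.
#' @export
zscore_inference <- function(Y, P) {
  if (!identical(dim(Y), dim(P)))
    stop_bigsm("dimension", "Y is %s but P is %s",
               paste(dim(Y), collapse = "x"), paste(dim(P), collapse = "x"))
  N <- nrow(Y)
  mu <- rowMeans(Y)
  sdev <- apply(Y, 1, stats::sd)
  flat <- sdev == 0
  if (any(flat)) {
    warning(sprintf("%d gene row(s) have zero standard deviation; their weights are set to 0",
                    sum(flat)))
    sdev[flat] <- 1
  }
  Z <- (Y - mu) / sdev
  Z[flat, ] <- 0
  W <- matrix(0, N, N, dimnames = list(rownames(Y), rownames(Y)))
  for (j in seq_len(N)) {
    cols <- which(P[j, ] != 0)
    if (length(cols))
      W[, j] <- rowMeans(Z[, cols, drop = FALSE])
  }
  baseline_result(W, "zscore")
}

#' Lasso network inference
#'
#' Solves each row problem by l1-penalised regression,
#' `min 1/2 ||p - H a||^2 + lambda ||a||_1`, via glmnet (no intercept, no
#' standardisation; glmnet's penalty is rescaled by the number of
#' measurements so `lambda` is on the objective above). The penalty is chosen
#' per row by cross-validation over the grid (`selection = "cv"`, default,
#' with seeded folds) or fixed at `lambda_fixed` (`selection = "fixed"`).
#' Single-replicate knockdown designs leave some training folds with a
#' constant response, where cross-validation is undefined; such rows fall
#' back to the fixed penalty (`lambda_fixed` if given, otherwise 1% of that
#' row's smallest fully-sparsifying penalty).
#'
#' @inheritParams lsco_inference
#' @param lambda_grid nonnegative penalty grid; `NULL` lets glmnet build its
#'   own path (cv selection only).
#' @param selection `"cv"` or `"fixed"`.
#' @param lambda_fixed penalty used when `selection = "fixed"`.
#' @param nfolds cross-validation folds.
#' @param seed seed for the fold assignment (deterministic results).
#' @return a `baseline_result` with the selected penalty per row in `params`.
#' @export
lasso_inference <- function(Y, P, lambda_grid = NULL,
                            selection = c("cv", "fixed"),
                            lambda_fixed = NULL, nfolds = 5L, seed = 1L) {
  selection <- match.arg(selection)
  if (!identical(dim(Y), dim(P)))
    stop_bigsm("dimension", "Y is %s but P is %s",
               paste(dim(Y), collapse = "x"), paste(dim(P), collapse = "x"))
  if (!is.null(lambda_grid) && (length(lambda_grid) == 0 || any(lambda_grid < 0)))
    stop_bigsm("invalid_config", "lambda_grid must be nonempty and nonnegative")
  if (selection == "fixed" && is.null(lambda_fixed))
    stop_bigsm("invalid_config", "selection = 'fixed' requires lambda_fixed")
  H <- design_from_data(Y)
  M <- nrow(H)
  N <- ncol(H)
  W <- matrix(0, N, N, dimnames = list(rownames(Y), rownames(Y)))
  chosen <- numeric(N)
  fit_fixed <- function(p, s) {
    # a short decreasing path down to s helps the coordinate descent warm-start
    path <- sort(unique(c(s * c(8, 4, 2, 1), s + 1e-3)), decreasing = TRUE)
    fit <- glmnet::glmnet(H, p, lambda = path, intercept = FALSE,
                          standardize = FALSE, thresh = 1e-12)
    # exact refit at s; suppress glmnet's lambda-interpolation chatter
    as.vector(suppressWarnings(
      stats::coef(fit, s = s, exact = TRUE, x = H, y = p,
                  intercept = FALSE, standardize = FALSE,
                  thresh = 1e-12)))[-1]
  }
  for (i in seq_len(N)) {
    p <- P[i, ]
    if (selection == "cv") {
      set.seed(derive_seed(seed, 7907L + i))
      foldid <- sample(rep_len(seq_len(nfolds), M))
      lam <- if (is.null(lambda_grid)) NULL else
        sort(unique(lambda_grid / M), decreasing = TRUE)
      cv <- tryCatch(
        glmnet::cv.glmnet(H, p, lambda = lam, foldid = foldid,
                          intercept = FALSE, standardize = FALSE,
                          thresh = 1e-10),
        error = function(e) NULL)
      if (!is.null(cv)) {
        W[i, ] <- as.vector(stats::coef(cv, s = "lambda.min"))[-1]
        chosen[i] <- cv$lambda.min * M
      } else {
        lam_fb <- if (!is.null(lambda_fixed)) lambda_fixed else
          0.01 * max(abs(crossprod(H, p)))
        W[i, ] <- fit_fixed(p, lam_fb / M)
        chosen[i] <- lam_fb
      }
    } else {
      s <- lambda_fixed / M
      W[i, ] <- fit_fixed(p, s)
      chosen[i] <- lambda_fixed
    }
  }
  baseline_result(W, "lasso",
                  params = list(selection = selection, lambda = chosen,
                                nfolds = nfolds, seed = seed))
}
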