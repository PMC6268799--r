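#' Leave-one-out cross-validation Q-squared
#'
#' For each training sample, the model is refit on the remaining samples
#' and used to predict the held-out response. PRESS is the sum of squared
#' out-of-fold prediction errors and `Q2 = 1 - PRESS / TSS` with TSS about
#' the full-sample mean.
#'
#' @param X numeric matrix (samples x descriptors).
#' @param y numeric response vector.
#' @param fitter function `(X, y) -> list` with `intercept` and
#'   `coefficients` (e.g. a [fit_pls()] wrapper).
#' @return list with `q2`, `press`, `predictions` (out-of-fold).
#' @export
loo_q2 <- function(X, y, fitter = function(Xt, yt) fit_pls(Xt, yt)) {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 3) stop("leave-one-out needs at least 3 samples")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    fit <- tryCatch(fitter(X[-i, , drop = FALSE], y[-i]),
                    error = function(e) {
                      stop("refit failed on fold ", i, ": ",
                           conditionMessage(e))
                    })
    preds[i] <- fit$intercept + sum(fit$coefficients * X[i, ])
  }
  press <- sum((preds - y)^2)
  tss <- sum((y - mean(y))^2)
  list(q2 = 1 - press / tss, press = press, predictions = preds)
}

#' Wherry adjustment of a squared correlation statistic
#'
#' `adj = 1 - (1 - stat) (n - 1) / (n - p - 1)`, applied alike to R-squared
#' and to the cross-validated Q-squared, with `p` the number of model
#' terms.
#'
#' @param stat the unadjusted statistic.
#' @param n number of samples.
#' @param p number of model terms (descriptors).
#' @return the adjusted statistic.
#' @examples
#' adjusted(0.8, 41, 9)  # 0.7419
#' @export
adjusted <- function(stat, n, p) {
  if (n - p - 1 <= 0) stop("n must exceed p + 1")
  1 - (1 - stat) * (n - 1) / (n - p - 1)
}

#' Standard deviation of fit residuals
#'
#' Sample standard deviation (n-1 denominator) about the residual mean;
#' this is the SD_res used by the two-sigma outlier rule.
#'
#' @param residuals numeric vector of residuals (calculated minus
#'   experimental).
#' @return the standard deviation.
#' @export
residual_sd <- function(residuals) {
  if (length(residuals) < 2) stop("need at least 2 residuals")
  stats::sd(residuals)
}

#' Flag outliers by the two-sigma residual rule
#'
#' A compound is an outlier when the absolute value of its residual exceeds
#' twice the residual standard deviation.
#'
#' @param residuals numeric residual vector, named by compound id (or ids
#'   supplied separately).
#' @param sd_res the residual standard deviation, typically
#'   [residual_sd()] of the same vector.
#' @param ids compound identifiers aligned with `residuals`.
#' @return the ids of flagged compounds.
#' @export
find_outliers <- function(residuals, sd_res = residual_sd(residuals),
                          ids = names(residuals) %||% seq_along(residuals)) {
  stopifnot(sd_res >= 0)
  ids[abs(residuals) > 2 * sd_res]
}

#' Pairwise Pearson cross-correlation matrix
#'
#' Computes the symmetric matrix of Pearson correlations across a set of
#' equal-length columns (descriptor occupancy vectors, the potency vector,
#' or per-model residual vectors), mirroring the published
#' descriptor-versus-potency cross-correlation tables.
#'
#' @param columns a named list of numeric vectors, or a matrix/data.frame.
#' @return correlation matrix with unit diagonal.
#' @export
cross_correlation <- function(columns) {
  M <- if (is.list(columns) && !is.data.frame(columns)) {
    do.call(cbind, columns)
  } else {
    as.matrix(columns)
  }
  v <- apply(M, 2, stats::var)
  if (any(v == 0)) {
    stop("zero-variance column(s): ",
         paste(colnames(M)[v == 0], collapse = ", "))
  }
  stats::cor(M)
}

#' Fisher F statistic of a regression
#'
#' `F = (R2 / p) / ((1 - R2) / (n - p - 1))`.
#'
#' @param r2 squared correlation coefficient of the fit.
#' @param n number of samples.
#' @param p number of model terms.
#' @return the F statistic.
#' @export
f_statistic <- function(r2, n, p) {
  if (n - p - 1 <= 0) stop("n must exceed p + 1")
  if (r2 >= 1) stop("r2 must be below 1")
  (r2 / p) / ((1 - r2) / (n - p - 1))
}

#' Full validation report for a fitted model
#'
#' Bundles the internal-validation statistics (R2 and its adjustment,
#' leave-one-out Q2 and its adjustment, standard error of estimate, F),
#' the residual vector, its standard deviation, and the two-sigma outlier
#' set.
#'
#' @param X training matrix (samples x selected descriptors).
#' @param y observed activities.
#' @param fitter model-fitting function as in [loo_q2()].
#' @param ids compound identifiers.
#' @return an object of class `validation_report`.
#' @export
validation_report <- function(X, y, fitter = function(Xt, yt) fit_pls(Xt, yt),
                              ids = seq_along(y)) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  fit <- fitter(X, y)
  fitted <- fit$intercept + drop(X %*% fit$coefficients)
  residuals <- stats::setNames(fitted - y, ids)
  rss <- sum(residuals^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  cv <- loo_q2(X, y, fitter)
  sdr <- residual_sd(residuals)
  structure(list(
    r2 = r2,
    r2_adj = adjusted(r2, n, p),
    q2 = cv$q2,
    q2_adj = adjusted(cv$q2, n, p),
    se = sqrt(rss / (n - p - 1)),
    f_stat = f_statistic(min(r2, 1 - 1e-15), n, p),
    press = cv$press,
    residuals = residuals,
    sd_res = sdr,
    outlier_ids = find_outliers(residuals, sdr, ids),
    n = n, p = p,
    intercept = fit$intercept,
    coefficients = fit$coefficients
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: n = %d, p = %d\n", x$n, x$p))
  cat(sprintf("  R2 = %.3f (adj %.3f)   Q2 = %.3f (adj %.3f)\n",
              x$r2, x$r2_adj, x$q2, x$q2_adj))
  cat(sprintf("  SE = %.3f   F = %.2f   SD_res = %.2f\n",
              x$se, x$f_stat, x$sd_res))
  if (length(x$outlier_ids)) {
    cat("  outliers (|residual| > 2 SD_res):",
        paste(x$outlier_ids, collapse = ", "), "\n")
  } else {
    cat("  no outliers\n")
  }
  invisible(x)
}
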