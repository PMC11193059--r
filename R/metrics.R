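#' Affinity evaluation metrics
#'
#' The five standard measures used to score binding-affinity regression:
#' root mean square error, mean absolute error, standard deviation of the
#' residuals after a least-squares linear recalibration of the predictions
#' (SD), concordance index (CI), and Pearson correlation. Lower RMSE/MAE/SD
#' and higher CI/R indicate a better model.
#'
#' @param y numeric vector of observed affinities (-log molar units).
#' @param yhat numeric vector of predicted affinities, same length.
#' @return A single numeric value.
#' @name dta_metrics
NULL

check_pair <- function(y, yhat) {
  stopifnot(is.numeric(y), is.numeric(yhat))
  if (length(y) != length(yhat) || length(y) == 0L) {
    stop("y and yhat must be non-empty vectors of equal length")
  }
}

#' @rdname dta_metrics
#' @export
dta_rmse <- function(y, yhat) {
  check_pair(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' @rdname dta_metrics
#' @export
dta_mae <- function(y, yhat) {
  check_pair(y, yhat)
  mean(abs(y - yhat))
}

#' @rdname dta_metrics
#' @details
#' The concordance index is computed over all ordered pairs with strictly
#' greater observed affinity (`y_i > y_j`); tied observations contribute no
#' pair. A pair scores 1 when the predictions agree in direction, 0.5 when
#' the predictions tie, and 0 otherwise. A constant predictor therefore
#' scores exactly 0.5. All observations equal is an error: no pair
#' qualifies and the index is undefined.
#' @export
concordance_index <- function(y, yhat) {
  check_pair(y, yhat)
  dy <- outer(y, y, `-`)       # dy[i,j] = y_i - y_j
  qual <- dy > 0
  z <- sum(qual)
  if (z == 0L) {
    stop("concordance index undefined: no pair with distinct observed values")
  }
  dp <- outer(yhat, yhat, `-`)
  sum(ifelse(dp[qual] > 0, 1, ifelse(dp[qual] == 0, 0.5, 0))) / z
}

#' @rdname dta_metrics
#' @export
pearson_r <- function(y, yhat) {
  check_pair(y, yhat)
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    stop("Pearson correlation undefined for constant input")
  }
  stats::cor(y, yhat)
}

#' @rdname dta_metrics
#' @details
#' SD regresses `y` on `yhat` by ordinary least squares (`y ~ a*yhat + b`)
#' and reports `sqrt(sum(residuals^2) / (N - 1))` — the spread left after
#' the best affine recalibration of the predictions.
#' @export
sd_metric <- function(y, yhat) {
  check_pair(y, yhat)
  if (length(y) < 3L) stop("sd_metric needs at least 3 observations")
  if (stats::sd(yhat) == 0) {
    stop("sd_metric undefined: constant predictions admit no regression line")
  }
  fit <- stats::lm(y ~ yhat)
  sqrt(sum(stats::residuals(fit)^2) / (length(y) - 1))
}

#' Full metric report
#'
#' Computes all five metrics for one prediction set.
#'
#' @inheritParams dta_metrics
#' @return An object of class `metric_report`: list with `rmse`, `mae`,
#'   `sd`, `ci`, `r`, `n`.
#' @export
metric_report <- function(y, yhat) {
  structure(list(rmse = dta_rmse(y, yhat), mae = dta_mae(y, yhat),
                 sd = sd_metric(y, yhat), ci = concordance_index(y, yhat),
                 r = pearson_r(y, yhat), n = length(y)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat(sprintf("Affinity prediction metrics (n = %d)\n", x$n))
  cat(sprintf("  RMSE %.*f  MAE %.*f  SD %.*f  CI %.*f  R %.*f\n",
              digits, x$rmse, digits, x$mae, digits, x$sd,
              digits, x$ci, digits, x$r))
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(rmse = x$rmse, mae = x$mae, sd = x$sd, ci = x$ci, r = x$r,
             n = x$n)
}

#' Per-complex top-1 tally across models
#'
#' For each complex, the model whose prediction is closest in absolute
#' error to the observed affinity is awarded one count. Ties go to the
#' first-listed model and are flagged.
#'
#' @param predictions numeric matrix or data frame, one column per model,
#'   one row per complex.
#' @param y observed affinities, length `nrow(predictions)`.
#' @return A list with `counts` (named integer vector per model) and
#'   `n_ties` (number of complexes whose best error was shared).
#' @export
top1_tally <- function(predictions, y) {
  m <- as.matrix(predictions)
  stopifnot(nrow(m) == length(y), ncol(m) >= 1L)
  if (is.null(colnames(m))) colnames(m) <- paste0("model", seq_len(ncol(m)))
  err <- abs(m - y)
  best <- apply(err, 1L, which.min)
  ties <- apply(err, 1L, function(e) sum(e == min(e)) > 1L)
  counts <- integer(ncol(m))
  names(counts) <- colnames(m)
  tab <- table(factor(colnames(m)[best], levels = colnames(m)))
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, n_ties = sum(ties))
}
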