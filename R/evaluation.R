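# Evaluation machinery: RMSE, coefficient of determination, 70/30 splits
# with half-up rounding of the train count, 10-fold partitions, held-out
# evaluation with identity-line diagnostics, model ranking, descriptive
# statistics, correlation analysis, and frozen-model transfer validation.

#' Root mean squared error
#'
#' `RMSE = sqrt(mean((measured - estimated)^2))`, in grams when applied to
#' fruit weight.
#'
#' @param measured,estimated numeric vectors of equal positive length.
#' @return non-negative scalar.
#' @export
#' @examples
#' rmse(c(2, 4), c(3, 1))   # sqrt(5)
rmse <- function(measured, estimated) {
  if (length(measured) != length(estimated))
    stop("rmse: length mismatch")
  if (length(measured) == 0L) stop("rmse: empty input")
  sqrt(mean((measured - estimated)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` about the mean of the measured series; can
#' be negative for estimators worse than the mean.
#'
#' @param measured,estimated numeric vectors of equal length, n >= 2;
#'   `measured` must not be constant.
#' @return dimensionless scalar <= 1.
#' @export
r_squared <- function(measured, estimated) {
  if (length(measured) != length(estimated))
    stop("r_squared: length mismatch")
  if (length(measured) < 2L) stop("r_squared: need n >= 2")
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) stop("r_squared: constant measured series")
  1 - sum((measured - estimated)^2) / ss_tot
}

#' Random 70/30 (or other fraction) train/test split
#'
#' The train count is `round_half_up(train_fraction * n)`; half-up
#' rounding is the unique rule reproducing all published partition sizes
#' (1028 -> 720/308, 518 -> 363, 508 -> 356, 530 -> 371, 486 -> 340).
#' Selection is uniform without replacement and deterministic per seed.
#'
#' @param records data.frame of fruit records (n >= 2).
#' @param train_fraction proportion in (0, 1), default 0.7.
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames forming an exact
#'   partition of `records`.
#' @export
split_dataset <- function(records, train_fraction = 0.7, seed = 1L) {
  n <- nrow(records)
  if (n < 2L) stop("split_dataset: need at least 2 records")
  if (!(train_fraction > 0 && train_fraction < 1))
    stop("split_dataset: train_fraction must be in (0, 1)")
  n_train <- floor(train_fraction * n + 0.5)
  if (n_train <= 0L || n_train >= n)
    stop("split_dataset: degenerate split (empty train or test)")
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = records[idx, , drop = FALSE],
       test = records[-idx, , drop = FALSE],
       train_idx = sort(idx))
}

#' Shuffled k-fold partition of 1..n
#'
#' @param n number of observations, `n >= k`.
#' @param k folds (default 10).
#' @param seed shuffle seed.
#' @return list of `k` disjoint integer index vectors of size
#'   `floor(n/k)` or `ceiling(n/k)` whose union is `1..n`.
#' @export
kfold_indices <- function(n, k = 10L, seed = 1L) {
  if (n < k) stop("kfold_indices: n must be >= k")
  perm <- with_seed(seed, sample.int(n))
  split(perm, rep_len(seq_len(k), n))
}

#' Fit on the train partition and report metrics on both partitions
#'
#' Besides train/test RMSE and R-squared, reports the identity-line
#' regression of measured on estimated test values (slope, intercept) and
#' two-sided p-values for slope = 1 and intercept = 0: a well-calibrated
#' estimator should not deviate significantly from the 1:1 line.
#'
#' @param fit_fn function taking a records data.frame and returning a
#'   fitted model with a `predict(model, newdata)` method.
#' @param records full cohort (>= 10 rows).
#' @param train_fraction,seed split parameters, see [split_dataset()].
#' @param label optional model label carried into the report.
#' @return list of class `eval_report`.
#' @export
evaluate_model <- function(fit_fn, records, train_fraction = 0.7,
                           seed = 1L, label = NULL) {
  assert_records(records, 10L)
  parts <- split_dataset(records, train_fraction, seed)
  model <- fit_fn(parts$train)
  pred_train <- predict(model, parts$train)
  pred_test <- predict(model, parts$test)
  ident <- lm.fit(cbind(1, pred_test), parts$test$weight_g)
  co <- unname(ident$coefficients)
  res <- ident$residuals
  n <- length(res)
  sigma2 <- sum(res^2) / (n - 2)
  XtXinv <- chol2inv(chol(crossprod(cbind(1, pred_test))))
  se <- sqrt(sigma2 * diag(XtXinv))
  t_int <- co[1] / se[1]
  t_slp <- (co[2] - 1) / se[2]
  structure(list(label = label %||% (if (!is.null(model$family)) model$family else "model"),
                 model = model,
                 rmse_train = rmse(parts$train$weight_g, pred_train),
                 rmse_test = rmse(parts$test$weight_g, pred_test),
                 r2_train = r_squared(parts$train$weight_g, pred_train),
                 r2_test = r_squared(parts$test$weight_g, pred_test),
                 n_train = nrow(parts$train), n_test = nrow(parts$test),
                 identity_slope = co[2], identity_intercept = co[1],
                 identity_p_slope = 2 * pt(-abs(t_slp), n - 2),
                 identity_p_intercept = 2 * pt(-abs(t_int), n - 2)),
            class = "eval_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s: train RMSE %.4f g / R2 %.4f; test RMSE %.4f g / R2 %.4f (n = %d/%d)\n",
              x$label, x$rmse_train, x$r2_train, x$rmse_test, x$r2_test,
              x$n_train, x$n_test))
  invisible(x)
}

#' Rank evaluation reports and return the winner
#'
#' Ranks by training RMSE ascending; ties break toward higher training
#' R-squared, then toward earlier position in the input (model-family
#' declaration order).
#'
#' @param reports non-empty list of `eval_report` objects.
#' @return the winning report, with the full ranking (integer permutation)
#'   as attribute `"ranking"`.
#' @export
select_best <- function(reports) {
  if (length(reports) == 0L) stop("select_best: empty report collection")
  rmse_v <- vapply(reports, function(r) r$rmse_train, numeric(1))
  r2_v <- vapply(reports, function(r) r$r2_train, numeric(1))
  ord <- order(rmse_v, -r2_v, seq_along(reports))
  structure(reports[[ord[1]]], ranking = ord)
}

#' Descriptive statistics per variable
#'
#' @param records fruit records (n >= 2).
#' @return data.frame with one row per variable (`length_mm`,
#'   `diameter_mm`, `weight_g`) and columns `mean`, `sd`, `se`, `min`,
#'   `max`, `skewness` (moment coefficient `m3 / m2^(3/2)`); `sd` is the
#'   unbiased sample standard deviation and `se = sd / sqrt(n)`.
#' @export
descriptive_stats <- function(records) {
  assert_records(records, 2L)
  vars <- c("length_mm", "diameter_mm", "weight_g")
  out <- do.call(rbind, lapply(vars, function(v) {
    x <- records[[v]]
    n <- length(x)
    m2 <- mean((x - mean(x))^2)
    m3 <- mean((x - mean(x))^3)
    data.frame(variable = v, n = n, mean = mean(x), sd = sd(x),
               se = sd(x) / sqrt(n), min = min(x), max = max(x),
               skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrix over (L, D, FW) with significance
#'
#' @param records fruit records (n >= 3).
#' @param alpha significance level (default 0.01, two-sided).
#' @return list with `r` (3x3 symmetric, unit diagonal), `p` (two-sided
#'   p-values from the t-distribution), `significant` (logical, p < alpha)
#'   and `n`.
#' @export
correlation_matrix <- function(records, alpha = 0.01) {
  assert_records(records, 3L)
  vars <- c("length_mm", "diameter_mm", "weight_g")
  X <- as.matrix(records[vars])
  if (any(apply(X, 2, sd) == 0))
    stop("correlation_matrix: constant variable")
  n <- nrow(X)
  r <- cor(X)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  diag(p) <- 0
  list(r = r, p = p, significant = p < alpha, n = n)
}

#' Apply a frozen model to new cohorts without refitting
#'
#' Transfer validation: the model fitted on a development cohort is
#' evaluated as-is on each validation cohort, reporting per-cohort RMSE
#' and R-squared (one row per cohort, the shape of a published
#' cross-season validation table).
#'
#' @param model any fitted plumfw weight model.
#' @param cohorts named list of fruit-record data.frames.
#' @return data.frame with columns `cohort`, `n`, `rmse_g`, `r2`.
#' @export
transfer_validate <- function(model, cohorts) {
  if (!is.list(cohorts) || length(cohorts) == 0L)
    stop("transfer_validate: cohorts must be a non-empty list")
  nm <- names(cohorts) %||% paste0("cohort", seq_along(cohorts))
  out <- do.call(rbind, lapply(seq_along(cohorts), function(i) {
    rec <- cohorts[[i]]
    assert_records(rec, 2L)
    pred <- predict(model, rec)
    data.frame(cohort = nm[i], n = nrow(rec),
               rmse_g = rmse(rec$weight_g, pred),
               r2 = r_squared(rec$weight_g, pred))
  }))
  rownames(out) <- NULL
  out
}
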