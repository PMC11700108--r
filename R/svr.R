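# Epsilon-insensitive support vector regression on (L, D) features.
# The dual is solved by a compiled SMO solver (maximal-violating-pair
# working set, LIBSVM-style 2n formulation). Features are min-max
# normalized to [0, 1] internally — the convention of the reference
# PUK-SVR implementation, whose default kernel shape (omega = sigma = 1)
# is calibrated to that scale; the target stays in grams so epsilon has
# weight units.

#' Fit epsilon-SVR for fruit weight
#'
#' @param records data.frame with `length_mm`, `diameter_mm`, `weight_g`.
#' @param kernel `"RBF"`, `"PUK"` or `"POLY2"` (degree-2 polynomial).
#' @param c box penalty, > 0. The published comparison grid uses
#'   0.1, 1 and 10; arbitrary positive values are accepted.
#' @param epsilon insensitive-tube half width in grams (default 0.001).
#' @param gamma RBF inverse width on the internally min-max-normalized
#'   feature scale; default `1/(2*d)` with d = 2 features.
#' @param omega,sigma PUK shape parameters (default 1, 1).
#' @param tol KKT gap tolerance for the SMO solver.
#' @param max_iter SMO iteration cap; exceeding it is an error.
#' @return object of class `fw_svr` carrying the dual coefficients
#'   (`beta = alpha - alpha*`), support vectors, bias, scaling and the
#'   attained dual objective.
#' @export
fit_svr <- function(records, kernel = c("PUK", "RBF", "POLY2"),
                    c = 1, epsilon = 0.001, gamma = NULL,
                    omega = 1, sigma = 1, tol = 1e-6, max_iter = 2e6) {
  assert_records(records, 2L)
  kernel <- match.arg(kernel)
  if (c <= 0) stop("fit_svr: penalty c must be > 0")
  if (is.null(gamma)) gamma <- 1 / (2 * 2)
  X <- cbind(records$length_mm, records$diameter_mm)
  mu <- apply(X, 2, min)
  sds <- apply(X, 2, max) - mu
  sds[sds == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  y <- records$weight_g
  K <- kernel_matrix(Xs, Xs, kernel, gamma = gamma, omega = omega,
                     sigma = sigma)
  sol <- .cpp_svr_smo(K, y, c, epsilon, tol, as.integer(max_iter))
  if (!sol$converged)
    stop(sprintf("fit_svr: SMO did not converge in %d iterations (gap %.3g)",
                 as.integer(max_iter), sol$gap))
  sv <- which(abs(sol$beta) > 1e-12)
  structure(list(kernel = kernel, c = c, epsilon = epsilon,
                 gamma = gamma, omega = omega, sigma = sigma,
                 beta = sol$beta[sv], sv_X = Xs[sv, , drop = FALSE],
                 bias = sol$bias, x_center = mu, x_scale = sds,
                 n_sv = length(sv), objective = sol$objective,
                 iterations = sol$iterations, gap = sol$gap,
                 beta_full = sol$beta, alpha = sol$alpha,
                 alpha_star = sol$alpha_star,
                 family = sprintf("svr_%s_c%g", kernel, c)),
            class = "fw_svr")
}

#' @export
predict.fw_svr <- function(object, newdata, ...) {
  X <- cbind(newdata$length_mm, newdata$diameter_mm)
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  if (object$n_sv == 0L) return(rep(object$bias, nrow(Xs)))
  Kx <- kernel_matrix(Xs, object$sv_X, object$kernel, gamma = object$gamma,
                      omega = object$omega, sigma = object$sigma)
  drop(Kx %*% object$beta) + object$bias
}

#' @export
print.fw_svr <- function(x, ...) {
  cat(sprintf("<fw_svr> kernel %s, c = %g, epsilon = %g, %d SVs, dual obj %.6g\n",
              x$kernel, x$c, x$epsilon, x$n_sv, x$objective))
  invisible(x)
}

#' Grid search over SVR kernels and penalties by 10-fold cross-validation
#'
#' Evaluates every kernel x c combination by k-fold cross-validated RMSE
#' and returns the winning model refitted on all records plus the full
#' grid report. Solver failures in a cell are recorded in the report, not
#' fatal.
#'
#' @param records training records (>= 20 rows).
#' @param kernels kernel names to try.
#' @param c_values penalty values to try.
#' @param k folds (default 10).
#' @param seed fold-assignment seed.
#' @param ... passed to [fit_svr()] (epsilon, PUK/RBF parameters, ...).
#' @return list with `best` (an `fw_svr`), `report` (data.frame
#'   kernel, c, cv_rmse, error), `kernel`, `c`.
#' @export
grid_search_svr <- function(records, kernels = c("RBF", "PUK", "POLY2"),
                            c_values = c(0.1, 1, 10), k = 10L, seed = 1L,
                            ...) {
  assert_records(records, 20L)
  folds <- kfold_indices(nrow(records), k = k, seed = seed)
  grid <- expand.grid(kernel = kernels, c = c_values,
                      stringsAsFactors = FALSE)
  cv_rmse <- rep(NA_real_, nrow(grid))
  errs <- rep(NA_character_, nrow(grid))
  for (g in seq_len(nrow(grid))) {
    res <- tryCatch({
      preds <- numeric(nrow(records))
      for (fold in folds) {
        m <- fit_svr(records[-fold, , drop = FALSE],
                     kernel = grid$kernel[g], c = grid$c[g], ...)
        preds[fold] <- predict(m, records[fold, , drop = FALSE])
      }
      rmse(records$weight_g, preds)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) errs[g] <- res else cv_rmse[g] <- res
  }
  report <- cbind(grid, cv_rmse = cv_rmse, error = errs)
  if (all(is.na(cv_rmse))) stop("grid_search_svr: every grid cell failed")
  best_i <- which.min(cv_rmse)
  best <- fit_svr(records, kernel = grid$kernel[best_i], c = grid$c[best_i],
                  ...)
  list(best = best, report = report,
       kernel = grid$kernel[best_i], c = grid$c[best_i])
}
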