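# Weight estimators: five allometric forms and multiple linear regression.
# All models share the `predict(model, newdata)` interface on data frames
# with columns length_mm, diameter_mm, plus the convenience predict_fw().

#' Fit one allometric weight-dimension form by least squares
#'
#' Fits `FW = a + b * f(L, D)` for one of the five dimension combinations
#' (see [form_basis()]) with the exact closed-form simple-regression
#' solution, which is also the RMSE-minimizing least-squares fit.
#'
#' @param records data.frame with `length_mm`, `diameter_mm`, `weight_g`.
#' @param form one of `"LD"`, `"L3"`, `"D3"`, `"LD2"`, `"L2D"`.
#' @return object of class `fw_form` with coefficients `a` (g) and `b`.
#' @export
fit_form <- function(records, form) {
  assert_records(records, 2L)
  form <- match.arg(form, .gen_forms)
  f <- form_basis(form)
  x <- f(records$length_mm, records$diameter_mm)
  y <- records$weight_g
  vx <- var(x)
  if (!is.finite(vx) || vx <= 0)
    stop("fit_form: constant basis values, singular system")
  b <- cov(x, y) / vx
  a <- mean(y) - b * mean(x)
  structure(list(form = form, a = a, b = b, family = paste0("form_", form)),
            class = "fw_form")
}

#' @export
predict.fw_form <- function(object, newdata, ...) {
  f <- form_basis(object$form)
  object$a + object$b * f(newdata$length_mm, newdata$diameter_mm)
}

#' @export
print.fw_form <- function(x, ...) {
  cat(sprintf("<fw_form> FW = %.4f + %.4f * %s\n", x$a, x$b, x$form))
  invisible(x)
}

#' Fit the multiple linear regression FW = b0 + b1 L + b2 D
#'
#' Ordinary least squares via QR on the full design matrix.
#'
#' @param records data.frame with `length_mm`, `diameter_mm`, `weight_g`.
#' @return object of class `fw_mlr` with `beta0`, `beta1`, `beta2`.
#' @export
fit_mlr <- function(records) {
  assert_records(records, 3L)
  X <- cbind(1, records$length_mm, records$diameter_mm)
  fit <- lm.fit(X, records$weight_g)
  if (fit$rank < 3L)
    stop("fit_mlr: rank-deficient design (L collinear with D?)")
  beta <- unname(fit$coefficients)
  structure(list(beta0 = beta[1], beta1 = beta[2], beta2 = beta[3],
                 family = "mlr"),
            class = "fw_mlr")
}

#' @export
predict.fw_mlr <- function(object, newdata, ...) {
  object$beta0 + object$beta1 * newdata$length_mm +
    object$beta2 * newdata$diameter_mm
}

#' @export
print.fw_mlr <- function(x, ...) {
  cat(sprintf("<fw_mlr> FW = %.3f L + %.3f D + %.3f\n",
              x$beta1, x$beta2, x$beta0))
  invisible(x)
}

#' Predict fresh weight at given dimensions
#'
#' Convenience wrapper around the `predict` methods for scalar or vector
#' L and D in millimetres.
#'
#' @param model any fitted plumfw weight model.
#' @param L,D fruit length and diameter, mm (> 0).
#' @return estimated FW in grams.
#' @export
#' @examples
#' m <- structure(list(form = "LD", a = -4.494, b = 0.0225), class = "fw_form")
#' predict_fw(m, 25.74, 24.50)
predict_fw <- function(model, L, D) {
  stopifnot(all(L > 0), all(D > 0))
  predict(model, data.frame(length_mm = L, diameter_mm = D))
}
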