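# One-hidden-layer perceptron (2-h-1) for fruit weight: tangent-sigmoid
# hidden activation, linear output, trained by full-batch resilient
# back-propagation (iRprop-) on standardized features and target, with
# early stopping on a held-out 15% of the training records.

mlp_forward <- function(Xs, par) {
  Z <- Xs %*% t(par$W1) + matrix(par$b1, nrow(Xs), length(par$b1),
                                 byrow = TRUE)
  A <- tanh(Z)
  list(pred = drop(A %*% par$w2) + par$b2, A = A)
}

mlp_grad <- function(Xs, ys, par) {
  fw <- mlp_forward(Xs, par)
  n <- nrow(Xs)
  d <- (fw$pred - ys) / n              # d(MSE/2)/dpred
  dA <- outer(d, par$w2)
  dZ <- dA * (1 - fw$A^2)
  list(W1 = t(dZ) %*% Xs, b1 = colSums(dZ),
       w2 = drop(t(fw$A) %*% d), b2 = sum(d),
       loss = mean((fw$pred - ys)^2) / 2)
}

#' Fit a 2-h-1 multilayer perceptron for fruit weight
#'
#' @param records data.frame with `length_mm`, `diameter_mm`, `weight_g`.
#' @param hidden_neurons hidden layer size h in `[1, 20]`.
#' @param seed integer seed (weight initialization and validation split);
#'   the fit is a pure function of (records, hyperparameters, seed).
#' @param epochs full-batch epoch cap (default 2000).
#' @param patience early-stopping patience in epochs on the held-out
#'   validation loss (default 50).
#' @param val_fraction fraction of records held out for early stopping
#'   (default 0.15; with fewer than 10 records the training loss is
#'   monitored instead).
#' @return object of class `fw_mlp`; field `topology` is the usual
#'   `"2-h-1"` string.
#' @export
fit_mlp <- function(records, hidden_neurons = 3L, seed = 1L,
                    epochs = 2000L, patience = 50L, val_fraction = 0.15) {
  assert_records(records, 4L)
  h <- as.integer(hidden_neurons)
  if (h < 1L || h > 20L) stop("fit_mlp: hidden_neurons must be in [1, 20]")
  X <- cbind(records$length_mm, records$diameter_mm)
  y <- records$weight_g
  mu <- colMeans(X); sds <- apply(X, 2, sd); sds[sds == 0] <- 1
  ymu <- mean(y); ysd <- sd(y); if (ysd == 0) ysd <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  ys <- (y - ymu) / ysd
  n <- nrow(Xs)

  with_seed(seed, {
    val_idx <- if (n >= 10L) sample.int(n, max(1L, round(val_fraction * n)))
               else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- Xs[tr_idx, , drop = FALSE]; ytr <- ys[tr_idx]
    Xva <- Xs[val_idx, , drop = FALSE]; yva <- ys[val_idx]

    par <- list(W1 = matrix(runif(h * 2, -0.5, 0.5), h, 2),
                b1 = runif(h, -0.5, 0.5),
                w2 = runif(h, -0.5, 0.5), b2 = runif(1, -0.5, 0.5))
    step <- lapply(par, function(p) p * 0 + 0.01)
    prev <- lapply(par, function(p) p * 0)
    best_par <- par; best_val <- Inf; stall <- 0L
    for (ep in seq_len(epochs)) {
      gr <- mlp_grad(Xtr, ytr, par)
      for (nm in c("W1", "b1", "w2", "b2")) {
        sgn <- sign(gr[[nm]] * prev[[nm]])
        step[[nm]] <- pmin(pmax(step[[nm]] * ifelse(sgn > 0, 1.2,
                                                    ifelse(sgn < 0, 0.5, 1)),
                                1e-8), 1)
        g <- gr[[nm]]
        g[sgn < 0] <- 0                      # iRprop-: forget bad direction
        par[[nm]] <- par[[nm]] - sign(g) * step[[nm]]
        prev[[nm]] <- g
      }
      monitor <- if (length(val_idx)) {
        mean((mlp_forward(Xva, par)$pred - yva)^2) / 2
      } else gr$loss
      if (monitor < best_val - 1e-12) {
        best_val <- monitor; best_par <- par; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    if (!is.finite(best_val))
      stop("fit_mlp: non-finite loss (bad scaling?)")
    structure(list(W1 = best_par$W1, b1 = best_par$b1,
                   w2 = best_par$w2, b2 = best_par$b2,
                   x_center = mu, x_scale = sds, y_center = ymu,
                   y_scale = ysd, hidden_neurons = h,
                   topology = sprintf("2-%d-1", h),
                   val_mse = best_val, epochs_run = ep,
                   family = sprintf("mlp_h%d", h)),
              class = "fw_mlp")
  })
}

#' @export
predict.fw_mlp <- function(object, newdata, ...) {
  X <- cbind(newdata$length_mm, newdata$diameter_mm)
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  mlp_forward(Xs, object)$pred * object$y_scale + object$y_center
}

#' @export
print.fw_mlp <- function(x, ...) {
  cat(sprintf("<fw_mlp> topology %s, %d epochs, val MSE %.4g\n",
              x$topology, x$epochs_run, x$val_mse))
  invisible(x)
}

#' Sweep the hidden-layer size and keep the best topology
#'
#' Fits `2-h-1` networks for every h in `h_range` and selects the one with
#' the lowest early-stopping validation RMSE (in grams).
#'
#' @param records training records.
#' @param h_range candidate hidden sizes (default 1:20).
#' @param seed seed shared by all fits.
#' @param ... passed to [fit_mlp()].
#' @return list with `best` (an `fw_mlp`), `topology` (e.g. `"2-3-1"`) and
#'   `report` (data.frame h, val_rmse_g).
#' @export
tune_mlp <- function(records, h_range = 1:20, seed = 1L, ...) {
  fits <- lapply(h_range, function(h)
    fit_mlp(records, hidden_neurons = h, seed = seed, ...))
  val_rmse <- vapply(fits, function(f) sqrt(2 * f$val_mse) * f$y_scale,
                     numeric(1))
  best_i <- which.min(val_rmse)
  list(best = fits[[best_i]], topology = fits[[best_i]]$topology,
       report = data.frame(h = h_range, val_rmse_g = val_rmse))
}
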