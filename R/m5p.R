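# M5-style model tree for fruit weight. Construction follows the classic
# M5/M5' recipe: grow by standard-deviation-reduction splits on L or D,
# stop when a node's target SD falls below 5% of the root SD or the node
# is too small; fit a linear model over (L, D) at every node; prune
# bottom-up comparing each node's compensated model error against its
# subtree; optionally smooth leaf predictions toward the root.

m5_linear <- function(records) {
  X <- cbind(1, records$length_mm, records$diameter_mm)
  fit <- tryCatch(lm.fit(X, records$weight_g), error = function(e) NULL)
  if (is.null(fit) || fit$rank < 3L || anyNA(fit$coefficients)) {
    beta <- c(mean(records$weight_g), 0, 0)   # degenerate node: mean model
    p <- 1L
  } else {
    beta <- unname(fit$coefficients)
    p <- 3L
  }
  list(beta = beta, p = p)
}

m5_predict_lm <- function(model, records) {
  model$beta[1] + model$beta[2] * records$length_mm +
    model$beta[3] * records$diameter_mm
}

# compensated estimated absolute error: MAE * (n + p) / (n - p)
m5_model_error <- function(model, records) {
  n <- nrow(records)
  p <- model$p
  mae <- mean(abs(records$weight_g - m5_predict_lm(model, records)))
  if (n <= p) Inf else mae * (n + p) / (n - p)
}

m5_best_split <- function(records, min_instances) {
  y <- records$weight_g
  n <- length(y)
  sd_node <- sd(y)
  best <- NULL
  for (attr in c("length_mm", "diameter_mm")) {
    x <- records[[attr]]
    ux <- sort(unique(x))
    if (length(ux) < 2L) next
    thresholds <- (ux[-1] + ux[-length(ux)]) / 2
    for (thr in thresholds) {
      left <- x <= thr
      nl <- sum(left); nr <- n - nl
      if (nl < min_instances || nr < min_instances) next
      sdr <- sd_node - (nl / n) * sd(y[left]) - (nr / n) * sd(y[!left])
      if (is.null(best) || sdr > best$sdr)
        best <- list(attr = attr, threshold = thr, sdr = sdr)
    }
  }
  best
}

m5_grow <- function(records, min_instances, root_sd) {
  node <- list(n = nrow(records), model = m5_linear(records))
  if (nrow(records) < 2L * min_instances || sd(records$weight_g) < 0.05 * root_sd) {
    node$leaf <- TRUE
    return(node)
  }
  split <- m5_best_split(records, min_instances)
  if (is.null(split) || split$sdr <= 0) {
    node$leaf <- TRUE
    return(node)
  }
  left <- records[[split$attr]] <= split$threshold
  node$leaf <- FALSE
  node$split_attr <- split$attr
  node$split_threshold <- split$threshold
  node$left <- m5_grow(records[left, , drop = FALSE], min_instances, root_sd)
  node$right <- m5_grow(records[!left, , drop = FALSE], min_instances, root_sd)
  node
}

m5_prune <- function(node, records) {
  model_err <- m5_model_error(node$model, records)
  if (node$leaf) {
    node$est_error <- model_err
    return(node)
  }
  left_sel <- records[[node$split_attr]] <= node$split_threshold
  node$left <- m5_prune(node$left, records[left_sel, , drop = FALSE])
  node$right <- m5_prune(node$right, records[!left_sel, , drop = FALSE])
  nl <- sum(left_sel); nr <- sum(!left_sel)
  subtree_err <- (nl * node$left$est_error + nr * node$right$est_error) /
    (nl + nr)
  # tolerance absorbs floating-point noise on exactly-fitted subtrees
  if (model_err <= subtree_err * (1 + 1e-9) + 1e-12) {
    node <- list(n = node$n, model = node$model, leaf = TRUE,
                 est_error = model_err)
  } else {
    node$est_error <- subtree_err
  }
  node
}

m5_predict_node <- function(node, records, smoothing_k) {
  if (node$leaf) return(m5_predict_lm(node$model, records))
  left <- records[[node$split_attr]] <= node$split_threshold
  out <- numeric(nrow(records))
  for (side in c("left", "right")) {
    sel <- if (side == "left") left else !left
    if (!any(sel)) next
    child <- node[[side]]
    p <- m5_predict_node(child, records[sel, , drop = FALSE], smoothing_k)
    if (!is.na(smoothing_k)) {
      # smooth the child prediction toward this node's linear model
      pn <- m5_predict_lm(node$model, records[sel, , drop = FALSE])
      p <- (child$n * p + smoothing_k * pn) / (child$n + smoothing_k)
    }
    out[sel] <- p
  }
  out
}

#' Fit an M5-style model tree for fruit weight
#'
#' @param records data.frame with `length_mm`, `diameter_mm`, `weight_g`;
#'   at least `2 * min_instances` rows.
#' @param min_instances minimum records per leaf (default 4).
#' @param smoothing logical; smooth predictions from leaf to root with
#'   constant `smoothing_k` (default TRUE).
#' @param smoothing_k smoothing constant (default 15).
#' @param prune logical; bottom-up error-based pruning (default TRUE).
#' @return object of class `fw_m5p`. `n_leaves` counts the retained
#'   leaves; a globally linear target collapses to a single leaf whose
#'   model equals the MLR fit.
#' @export
fit_m5p <- function(records, min_instances = 4L, smoothing = TRUE,
                    smoothing_k = 15, prune = TRUE) {
  assert_records(records, 2L * min_instances)
  root_sd <- sd(records$weight_g)
  tree <- m5_grow(records, min_instances, root_sd)
  if (prune) tree <- m5_prune(tree, records)
  count_leaves <- function(n) if (n$leaf) 1L else
    count_leaves(n$left) + count_leaves(n$right)
  structure(list(tree = tree, min_instances = min_instances,
                 smoothing = smoothing, smoothing_k = smoothing_k,
                 n_leaves = count_leaves(tree), family = "m5p"),
            class = "fw_m5p")
}

#' @export
predict.fw_m5p <- function(object, newdata, smoothing = object$smoothing,
                           ...) {
  k <- if (isTRUE(smoothing)) object$smoothing_k else NA_real_
  m5_predict_node(object$tree, newdata, k)
}

#' @export
print.fw_m5p <- function(x, ...) {
  cat(sprintf("<fw_m5p> %d leaves, min %d instances, smoothing %s\n",
              x$n_leaves, x$min_instances,
              if (x$smoothing) sprintf("on (k = %g)", x$smoothing_k) else "off"))
  invisible(x)
}
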