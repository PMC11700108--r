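# Colour-agnostic fruit segmentation: RGB -> CIELAB, 2-cluster K-means on
# the chromatic (a*, b*) channels only, border-based background selection,
# then morphological cleanup. Lightness L* is deliberately excluded so
# the mask is robust to smooth illumination changes, and clustering on
# chroma makes the chain work identically for green, yellow and red fruit.

#' Convert an sRGB image to CIELAB (D65)
#'
#' @param image RGB array (height, width, 3), intensities in `[0, 1]`,
#'   interpreted as sRGB with D65 reference white.
#' @return array (height, width, 3) of class `lab_image`; channels are
#'   L* (0-100), a*, b*.
#' @export
#' @examples
#' lab <- rgb_to_lab(array(1, c(2, 2, 3)))  # white: L* = 100, a* = b* = 0
rgb_to_lab <- function(image) {
  assert_rgb_image(image)
  d <- dim(image)
  flat <- matrix(image, d[1] * d[2], 3L)
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  out <- array(lab, c(d[1], d[2], 3L))
  dimnames(out) <- list(NULL, NULL, c("L", "a", "b"))
  structure(out, class = "lab_image")
}

#' K-means clustering of the chromatic channels
#'
#' Lloyd iterations on the per-pixel (a*, b*) feature vectors. L* is
#' excluded from the features. Initialization is farthest-point from a
#' seeded random start; assignment ties break toward the lower cluster
#' index; iteration cap 300. Deterministic for fixed seed.
#'
#' @param lab a `lab_image` from [rgb_to_lab()].
#' @param k number of clusters (default 2: fruit vs background).
#' @param seed integer seed for the initial center choices.
#' @param max_iter Lloyd iteration cap per start.
#' @param nstart number of seeded restarts; the labelling with the lowest
#'   within-cluster sum of squares wins (guards against local optima on
#'   small or pathological chroma distributions).
#' @return integer matrix (height, width) of cluster labels in `1..k`,
#'   with the `k x 2` centers as attribute `"centers"`.
#' @export
cluster_ab <- function(lab, k = 2L, seed = 1L, max_iter = 300L,
                       nstart = 5L) {
  stopifnot(inherits(lab, "lab_image"))
  if (k < 2L) stop("cluster_ab: k must be >= 2")
  h <- dim(lab)[1]; w <- dim(lab)[2]
  X <- cbind(as.vector(lab[, , 2]), as.vector(lab[, , 3]))
  if (nrow(unique(X)) < k)
    stop("cluster_ab: degenerate image, fewer than k distinct chroma values")
  starts <- with_seed(seed, sample.int(nrow(X), nstart, replace = TRUE))

  lloyd_from <- function(first_px) {
    # farthest-point completion of the initial centers
    centers <- matrix(NA_real_, k, 2L)
    centers[1L, ] <- X[first_px, ]
    mind <- (X[, 1] - centers[1, 1])^2 + (X[, 2] - centers[1, 2])^2
    for (j in seq_len(k - 1L) + 1L) {
      centers[j, ] <- X[which.max(mind), ]
      dj <- (X[, 1] - centers[j, 1])^2 + (X[, 2] - centers[j, 2])^2
      mind <- pmin(mind, dj)
    }
    labels <- integer(nrow(X))
    for (it in seq_len(max_iter)) {
      dmat <- vapply(seq_len(k), function(j)
        (X[, 1] - centers[j, 1])^2 + (X[, 2] - centers[j, 2])^2,
        numeric(nrow(X)))
      new_labels <- max.col(-dmat, ties.method = "first")
      if (identical(new_labels, labels)) break
      labels <- new_labels
      for (j in seq_len(k)) {
        idx <- labels == j
        if (any(idx)) {
          centers[j, ] <- colMeans(X[idx, , drop = FALSE])
        } else {
          # empty cluster: restart it at the point farthest from its center
          d_all <- (X[, 1] - centers[j, 1])^2 + (X[, 2] - centers[j, 2])^2
          centers[j, ] <- X[which.max(d_all), ]
        }
      }
    }
    wcss <- sum(vapply(seq_len(k), function(j) {
      idx <- labels == j
      if (!any(idx)) return(0)
      sum(sweep(X[idx, , drop = FALSE], 2, centers[j, ])^2)
    }, numeric(1)))
    list(labels = labels, centers = centers, wcss = wcss)
  }

  best <- NULL
  for (s in starts) {
    run <- lloyd_from(s)
    if (is.null(best) || run$wcss < best$wcss) best <- run
  }
  structure(matrix(best$labels, h, w), centers = best$centers)
}

#' Select the fruit cluster from a two-cluster label image
#'
#' The cluster owning the majority of the image-border pixels is declared
#' background; the other is the fruit. The rule is invariant to label
#' order.
#'
#' @param labels integer matrix of per-pixel labels; exactly two labels
#'   must be present.
#' @return a `labeled_mask`: list with `mask` (logical matrix, TRUE =
#'   fruit), `cluster_labels`, and `steps_applied`.
#' @export
select_fruit_cluster <- function(labels) {
  present <- sort(unique(as.vector(labels)))
  if (length(present) != 2L)
    stop("select_fruit_cluster: expected exactly 2 clusters, found ",
         length(present))
  h <- nrow(labels); w <- ncol(labels)
  border <- c(labels[1, ], labels[h, ], labels[, 1], labels[, w])
  counts <- vapply(present, function(l) sum(border == l), integer(1))
  if (counts[1] == counts[2])
    stop("select_fruit_cluster: border ownership is tied; cannot identify background")
  background <- present[which.max(counts)]
  fruit <- present[present != background]
  structure(list(mask = labels == fruit,
                 cluster_labels = labels,
                 steps_applied = "select_fruit_cluster"),
            class = "labeled_mask")
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "labeled_mask")) mask$mask
  else if (is.logical(mask) && is.matrix(mask)) mask
  else stop("expected a labeled_mask or a logical matrix")
}

disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2, ]
  as.matrix(g)
}

#' Morphological cleanup of a raw fruit mask
#'
#' Applies morphological opening (erosion then dilation) with a disk
#' structuring element, fills interior holes, and retains the largest
#' 8-connected component. Closing (dilation then erosion) is exposed as an
#' alternative since published descriptions of the cleanup are ambiguous
#' about the operation order.
#'
#' @param mask a `labeled_mask` or logical matrix.
#' @param disk_radius_px structuring-element radius in pixels (default 5).
#' @param operation `"opening"` (default) or `"closing"`.
#' @return a `labeled_mask` with exactly one connected foreground
#'   component and updated `steps_applied`.
#' @export
refine_mask <- function(mask, disk_radius_px = 5L,
                        operation = c("opening", "closing")) {
  operation <- match.arg(operation)
  m <- as_mask_matrix(mask)
  prev_steps <- if (inherits(mask, "labeled_mask")) mask$steps_applied else character(0)
  se <- disk_offsets(disk_radius_px)
  m2 <- if (operation == "opening") {
    .cpp_binary_morph(.cpp_binary_morph(m, se, 0L), se, 1L)
  } else {
    .cpp_binary_morph(.cpp_binary_morph(m, se, 1L), se, 0L)
  }
  if (!any(m2))
    stop("refine_mask: mask is empty after ", operation,
         " (fruit smaller than the structuring element?)")
  # hole filling: background components not touching the border are holes
  bg <- .cpp_label_components(!m2, 4L)
  h <- nrow(m2); w <- ncol(m2)
  outside <- unique(c(bg[1, ], bg[h, ], bg[, 1], bg[, w]))
  outside <- outside[outside != 0L]
  m3 <- m2 | !(matrix(bg %in% c(0L, outside), h, w))
  # largest connected component (8-connectivity)
  comp <- .cpp_label_components(m3, 8L)
  sizes <- tabulate(comp[comp > 0L])
  m4 <- comp == which.max(sizes)
  if (all(m4[1, ]) && all(m4[h, ]) && all(m4[, 1]) && all(m4[, w]))
    stop("refine_mask: foreground touches all four borders (frame-filling fruit)")
  structure(list(mask = m4,
                 cluster_labels = if (inherits(mask, "labeled_mask"))
                   mask$cluster_labels else NULL,
                 steps_applied = c(prev_steps, operation, "fill_holes",
                                   "largest_component")),
            class = "labeled_mask")
}

#' Segment a single-fruit image into a binary mask
#'
#' Full chain: [rgb_to_lab()] -> [cluster_ab()] (k = 2) ->
#' [select_fruit_cluster()] -> [refine_mask()].
#'
#' @param image RGB array, single fruit on a near-uniform light background.
#' @param seed integer seed for the clustering initialization.
#' @param disk_radius_px cleanup structuring-element radius.
#' @param operation cleanup operation, see [refine_mask()].
#' @return a `labeled_mask`.
#' @export
segment <- function(image, seed = 1L, disk_radius_px = 5L,
                    operation = "opening") {
  lab <- rgb_to_lab(image)
  labels <- cluster_ab(lab, k = 2L, seed = seed)
  raw <- select_fruit_cluster(labels)
  refine_mask(raw, disk_radius_px = disk_radius_px, operation = operation)
}
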