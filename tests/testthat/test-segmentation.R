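test_that("rgb_to_lab follows the sRGB/D65 convention", {
  img <- array(0, c(1, 3, 3))
  img[1, 1, ] <- c(1, 1, 1)       # white
  img[1, 2, ] <- c(0, 0, 0)       # black
  img[1, 3, ] <- c(0.5, 0.5, 0.5) # mid gray
  lab <- rgb_to_lab(img)
  expect_equal(as.numeric(lab[1, 1, 1]), 100, tolerance = 1e-6)
  expect_equal(as.numeric(lab[1, 1, 2:3]), c(0, 0), tolerance = 1e-6)
  expect_equal(as.numeric(lab[1, 2, ]), c(0, 0, 0), tolerance = 1e-6)
  # achromatic ramp: a*, b* stay ~0, L* strictly increasing
  ramp <- array(rep(seq(0.1, 0.9, by = 0.1), 3), c(1, 9, 3))
  rl <- rgb_to_lab(ramp)
  expect_true(all(abs(rl[1, , 2:3]) < 1e-6))
  expect_true(all(diff(rl[1, , 1]) > 0))
  expect_error(rgb_to_lab(array(0, c(2, 2, 2))), "RGB")
})

test_that("cluster_ab recovers well-separated chroma populations", {
  # two chroma populations at (-20, 20) and (0, 0), within-class spread 1:
  # centers must land within 0.5 of the population means (small-instance
  # behaviour checked against exhaustive search below)
  withr::with_seed(4, {
    n <- 200
    ab <- rbind(cbind(rnorm(n, -20, 1), rnorm(n, 20, 1)),
                cbind(rnorm(n, 0, 1), rnorm(n, 0, 1)))
  })
  lab <- structure(array(c(rep(50, 2 * n), ab[, 1], ab[, 2]), c(2 * n, 1, 3)),
                   class = "lab_image")
  labels <- cluster_ab(lab, k = 2, seed = 1)
  centers <- attr(labels, "centers")
  ord <- order(centers[, 1])
  expect_lt(max(abs(centers[ord[1], ] - c(-20, 20))), 0.5)
  expect_lt(max(abs(centers[ord[2], ] - c(0, 0))), 0.5)
})

test_that("cluster_ab finds the exact optimum on a 4-pixel image", {
  lab <- structure(array(c(rep(50, 4), 0, 0, 10, 10, 0, 0, 10, 10),
                         c(2, 2, 3)), class = "lab_image")
  labels <- cluster_ab(lab, k = 2, seed = 3)
  expect_true(labels[1, 1] == labels[2, 1] && labels[1, 2] == labels[2, 2] &&
                labels[1, 1] != labels[1, 2])
})

test_that("cluster_ab attains the exhaustive-search optimum on tiny images", {
  # oracle: enumerate all 2-partitions of <= 16 points, compare WCSS
  wcss <- function(X, assign) {
    sum(vapply(unique(assign), function(g) {
      sub <- X[assign == g, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }
  for (seed in 1:4) {
    withr::with_seed(seed, {
      n <- 8
      ab <- matrix(rnorm(2 * n, 0, 5), n, 2)
    })
    lab <- structure(array(c(rep(50, n), ab[, 1], ab[, 2]), c(n, 1, 3)),
                     class = "lab_image")
    labels <- cluster_ab(lab, k = 2, seed = seed)
    got <- wcss(ab, as.vector(labels))
    best <- Inf
    for (code in 1:(2^(n - 1) - 1)) {
      assign <- as.integer(intToBits(code))[1:n]
      if (length(unique(assign)) == 2L) best <- min(best, wcss(ab, assign))
    }
    expect_equal(got, best, tolerance = 1e-8)
  }
})

test_that("degenerate single-chroma images are rejected", {
  img <- array(0.9, c(8, 8, 3))
  expect_error(segment(img), "degenerate|distinct")
})

test_that("border-majority rule identifies the background, label-order invariant", {
  labels <- matrix(1L, 30, 30)
  labels[ellipse_mask(30, 30, 8, 6)] <- 2L
  mk <- select_fruit_cluster(labels)
  expect_identical(mk$mask, labels == 2L)
  inverted <- 3L - labels
  expect_identical(select_fruit_cluster(inverted)$mask, mk$mask)
})

test_that("fruit owning a border minority is still the fruit", {
  # fruit cluster occupies ~30% of border pixels
  labels <- matrix(1L, 20, 20)
  labels[1:6, ] <- 2L            # fruit touches the whole top edge
  border <- c(labels[1, ], labels[20, ], labels[, 1], labels[, 20])
  expect_lt(mean(border == 2L) , 0.5)
  expect_identical(select_fruit_cluster(labels)$mask, labels == 2L)
  expect_error(select_fruit_cluster(matrix(1L, 5, 5)), "exactly 2")
})

test_that("refine_mask removes speckle, fills holes, keeps the ellipse", {
  h <- 120; w <- 120
  clean <- ellipse_mask(h, w, 35, 25)
  ref <- refine_mask(clean, 5)
  expect_gt(iou(ref$mask, clean), 0.98)   # opening only nibbles the rim
  # 20 isolated noise pixels vanish
  noisy <- clean
  withr::with_seed(9, {
    bg <- which(!clean & !ellipse_mask(h, w, 45, 35))
    noisy[sample(bg, 20)] <- TRUE
  })
  expect_identical(refine_mask(noisy, 5)$mask, ref$mask)
  # 10x10 interior hole is filled back to the solid area
  holed <- clean
  holed[55:64, 55:64] <- FALSE
  expect_identical(sum(refine_mask(holed, 5)$mask), sum(ref$mask))
  expect_error(refine_mask(matrix(FALSE, 20, 20), 5), "empty")
  tiny <- matrix(FALSE, 20, 20); tiny[10, 10] <- TRUE
  expect_error(refine_mask(tiny, 5), "empty")
})

test_that("segmentation round-trips rendered fruit across all hues", {
  im <- imaging_spec()
  for (hue in c("green", "yellow", "red")) {
    r <- render_fruit_image(fruit_truth(26, 23, 20, hue), im, seed = 1)
    mk <- segment(r$image, seed = 1)
    expect_gt(iou(mk$mask, r$manifest$mask), 0.98)
    expect_identical(length(count_components(mk$mask)), 1L)
  }
})

test_that("mask is invariant to smooth lighting gradients", {
  im_flat <- imaging_spec()
  im_grad <- imaging_spec(illumination_gradient = 0.3)
  tr <- fruit_truth(26, 23, -15, "yellow")
  a <- segment(render_fruit_image(tr, im_flat)$image, seed = 1)
  b <- segment(render_fruit_image(tr, im_grad)$image, seed = 1)
  expect_lt(abs(sum(b$mask) / sum(a$mask) - 1), 0.02)
})

test_that("steps_applied records the cleanup chain", {
  im <- imaging_spec()
  mk <- segment(render_fruit_image(fruit_truth(25, 22), im)$image, seed = 1)
  expect_identical(mk$steps_applied,
                   c("select_fruit_cluster", "opening", "fill_holes",
                     "largest_component"))
})
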