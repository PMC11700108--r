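# Metric morphometry: pixel-to-millimetre calibration from a reference
# square and moment-based extraction of fruit length and equatorial
# diameter from the binary mask.

#' Compute the pixel-to-millimetre scale from a calibration image
#'
#' Segments the dark reference square by midpoint intensity thresholding,
#' keeps the largest dark component, and estimates the side length as the
#' mean of the bounding-box row and column extents (pixel counts).
#' `mm_per_px = square_side_mm / side_px`.
#'
#' @param calibration_image RGB array containing one dark square on a
#'   light background.
#' @param square_side_mm physical side of the square (default 10 mm).
#' @param source label recorded for provenance.
#' @return list of class `calibration_scale` with `mm_per_px`, `side_px`,
#'   `source`.
#' @export
compute_scale <- function(calibration_image, square_side_mm = 10,
                          source = "calibration") {
  assert_rgb_image(calibration_image)
  gray <- (calibration_image[, , 1] + calibration_image[, , 2] +
           calibration_image[, , 3]) / 3
  thr <- (min(gray) + max(gray)) / 2
  dark <- gray < thr
  if (!any(dark)) stop("compute_scale: no dark square found")
  comp <- .cpp_label_components(dark, 8L)
  sizes <- tabulate(comp[comp > 0L])
  sq <- comp == which.max(sizes)
  h <- nrow(sq); w <- ncol(sq)
  if (any(sq[1, ]) || any(sq[h, ]) || any(sq[, 1]) || any(sq[, w]))
    stop("compute_scale: square touches the image border")
  rows <- range(which(apply(sq, 1, any)))
  cols <- range(which(apply(sq, 2, any)))
  side_px <- mean(c(diff(rows) + 1, diff(cols) + 1))
  structure(list(mm_per_px = square_side_mm / side_px,
                 side_px = side_px, source = source),
            class = "calibration_scale")
}

#' Extract metric fruit dimensions from a binary mask
#'
#' The major axis is the principal direction of the second central moments
#' of the foreground. L is the maximum extent of the foreground projected
#' on that axis; D the extent on the perpendicular (equatorial) axis; both
#' are measured on pixel centers with a +1 px end-correction (an n-pixel
#' run has extent n) and scaled by `mm_per_px`. Axes are ordered so that
#' `length_mm >= diameter_mm`; near-circular masks with degenerate moments
#' fall back to the image axes.
#'
#' @param mask a `labeled_mask` or logical matrix.
#' @param scale a `calibration_scale`, or a number interpreted as mm/px.
#' @return list of class `fruit_morphometry` with `length_mm`,
#'   `diameter_mm`, `orientation_deg`, `area_px`.
#' @export
extract_dimensions <- function(mask, scale) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stop("extract_dimensions: empty mask")
  mm_per_px <- if (inherits(scale, "calibration_scale")) scale$mm_per_px
               else as.numeric(scale)
  stopifnot(mm_per_px > 0)
  idx <- which(m, arr.ind = TRUE)
  ypix <- idx[, 1]; xpix <- idx[, 2]
  xc <- xpix - mean(xpix); yc <- ypix - mean(ypix)
  mu20 <- mean(xc^2); mu02 <- mean(yc^2); mu11 <- mean(xc * yc)
  if (abs(mu11) < 1e-12 && abs(mu20 - mu02) < 1e-12) {
    theta <- 0                      # degenerate (near-circular): image axes
  } else {
    theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  }
  pr_major <- xc * cos(theta) + yc * sin(theta)
  pr_minor <- -xc * sin(theta) + yc * cos(theta)
  L_px <- diff(range(pr_major)) + 1
  D_px <- diff(range(pr_minor)) + 1
  orientation <- theta * 180 / pi
  if (D_px > L_px) {
    tmp <- L_px; L_px <- D_px; D_px <- tmp
    orientation <- orientation + 90
  }
  orientation <- ((orientation + 90) %% 180) - 90   # normalize to (-90, 90]
  structure(list(length_mm = L_px * mm_per_px,
                 diameter_mm = D_px * mm_per_px,
                 orientation_deg = orientation,
                 area_px = nrow(idx)),
            class = "fruit_morphometry")
}

#' Measure a single-fruit image: segmentation plus dimension extraction
#'
#' @param image RGB array with one fruit.
#' @param scale a `calibration_scale` (or mm/px number).
#' @param seed clustering seed, see [segment()].
#' @param ... passed to [segment()].
#' @return a `fruit_morphometry`.
#' @export
measure_image <- function(image, scale, seed = 1L, ...) {
  extract_dimensions(segment(image, seed = seed, ...), scale)
}

#' Measure a directory of fruit images against one calibration image
#'
#' Per-image failures are logged (as warnings) and skipped; the run
#' continues.
#'
#' @param dir directory of single-fruit PNG images.
#' @param calibration_path path of the calibration-square PNG.
#' @param seed clustering seed.
#' @return data.frame with columns `image_id`, `length_mm`, `diameter_mm`,
#'   `orientation_deg`, `area_px`.
#' @export
measure_directory <- function(dir, calibration_path, seed = 1L) {
  if (!file.exists(calibration_path))
    stop("measure_directory: missing calibration image ", calibration_path)
  scale <- compute_scale(read_image(calibration_path))
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  files <- files[normalizePath(files) != normalizePath(calibration_path)]
  rows <- lapply(files, function(f) {
    tryCatch({
      morpho <- measure_image(read_image(f), scale, seed = seed)
      data.frame(image_id = basename(f),
                 length_mm = morpho$length_mm,
                 diameter_mm = morpho$diameter_mm,
                 orientation_deg = morpho$orientation_deg,
                 area_px = morpho$area_px)
    }, error = function(e) {
      warning("measure_directory: skipping ", basename(f), ": ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
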