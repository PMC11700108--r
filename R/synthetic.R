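# Synthetic data: tabular (L, D, FW) cohorts and rendered single-fruit
# scenes with ground truth, emulating the published descriptive statistics
# of four plum/greengage genotypes sampled in 2019 and 2021.

.gen_forms <- c("LD", "L3", "D3", "LD2", "L2D")

#' Basis function of an allometric form
#'
#' Maps a form name to its dimension combination: `LD` = L*D, `L3` = L^3,
#' `D3` = D^3, `LD2` = L*D^2, `L2D` = L^2*D.
#'
#' @param form one of `"LD"`, `"L3"`, `"D3"`, `"LD2"`, `"L2D"`.
#' @return a function `f(L, D)`.
#' @export
form_basis <- function(form) {
  form <- match.arg(form, .gen_forms)
  switch(form,
         LD  = function(L, D) L * D,
         L3  = function(L, D) L^3,
         D3  = function(L, D) D^3,
         LD2 = function(L, D) L * D^2,
         L2D = function(L, D) L^2 * D)
}

#' Statistical recipe for one synthetic genotype cohort
#'
#' A cohort spec captures everything needed to emulate one genotype's
#' measured population: truncated-normal moments and bounds for fruit
#' length L and equatorial diameter D (mm), their correlation, and an
#' allometric law `FW = gen_a + gen_b * f(L, D) + N(0, noise_sd)` (g)
#' generating fresh weight, clipped below at `fw_floor`.
#'
#' @param name cohort label.
#' @param n number of fruits (>= 2).
#' @param L_mean,L_sd,L_min,L_max length moments and truncation bounds (mm).
#' @param D_mean,D_sd,D_min,D_max diameter moments and bounds (mm).
#' @param rho_LD Pearson correlation between L and D, `|rho_LD| < 1`.
#'   Defaults to 0.8: the source populations show strong positive L-D
#'   association but no printed coefficient.
#' @param gen_form allometric form of the generating law (see [form_basis()]).
#' @param gen_a,gen_b intercept (g) and slope (g per form unit).
#' @param noise_sd additive Gaussian noise SD on FW (g), >= 0.
#' @param fw_floor lower clip for FW (g), > 0.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(name, n, L_mean, L_sd, D_mean, D_sd,
                        L_min, L_max, D_min, D_max,
                        rho_LD = 0.8, gen_form = "LD",
                        gen_a = 0, gen_b = 1, noise_sd = 0.5,
                        fw_floor = 0.1) {
  spec <- list(name = as.character(name), n = as.integer(n),
               L_mean = L_mean, L_sd = L_sd, D_mean = D_mean, D_sd = D_sd,
               L_min = L_min, L_max = L_max, D_min = D_min, D_max = D_max,
               rho_LD = rho_LD, gen_form = match.arg(gen_form, .gen_forms),
               gen_a = gen_a, gen_b = gen_b, noise_sd = noise_sd,
               fw_floor = fw_floor)
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n < 2L) stop("cohort_spec: n must be >= 2")
    if (L_sd <= 0 || D_sd <= 0) stop("cohort_spec: all sd must be > 0")
    if (!(L_min < L_mean && L_mean < L_max))
      stop("cohort_spec: need L_min < L_mean < L_max")
    if (!(D_min < D_mean && D_mean < D_max))
      stop("cohort_spec: need D_min < D_mean < D_max")
    if (abs(rho_LD) >= 1) stop("cohort_spec: |rho_LD| must be < 1")
    if (noise_sd < 0) stop("cohort_spec: noise_sd must be >= 0")
    if (fw_floor <= 0) stop("cohort_spec: fw_floor must be > 0")
  })
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %s: n=%d, L %.2f+-%.2f [%.2f, %.2f] mm, D %.2f+-%.2f [%.2f, %.2f] mm\n",
              x$name, x$n, x$L_mean, x$L_sd, x$L_min, x$L_max,
              x$D_mean, x$D_sd, x$D_min, x$D_max))
  cat(sprintf("  FW = %.4f + %.4f * %s + N(0, %.3f), floor %.2f g, rho_LD %.2f\n",
              x$gen_a, x$gen_b, x$gen_form, x$noise_sd, x$fw_floor, x$rho_LD))
  invisible(x)
}

#' Built-in cohort specs for the five published plum datasets
#'
#' Per-genotype moments and bounds follow the published descriptive table
#' for the 2019 Gavali development cohort and the 2021 Gavali, Ghandi,
#' Shahryari and Jangali validation cohorts (the printed "SE" dispersion is
#' treated as a standard deviation; a genuine standard error at n ~ 500
#' would be an order of magnitude smaller than the printed 1.2-2.6 mm).
#' The FW generating law of each cohort is that genotype's best-fitting
#' published allometric model: `FW = 0.0225*(L*D) - 4.4940` for 2019, and
#' `L*D^2` laws for the 2021 genotypes. Noise SDs equal the published
#' training RMSE of those fitted models.
#'
#' @return named list of [cohort_spec()] objects:
#'   `gavali_2019`, `gavali_2021`, `ghandi_2021`, `shahryari_2021`,
#'   `jangali_2021`.
#' @export
plum_cohort_specs <- function() {
  list(
    gavali_2019 = cohort_spec("gavali_2019", 1028,
      L_mean = 25.74, L_sd = 1.64, D_mean = 24.50, D_sd = 1.84,
      L_min = 21.13, L_max = 32.22, D_min = 19.17, D_max = 30.55,
      gen_form = "LD", gen_a = -4.4940, gen_b = 0.0225, noise_sd = 0.5),
    gavali_2021 = cohort_spec("gavali_2021", 518,
      L_mean = 26.11, L_sd = 1.96, D_mean = 25.73, D_sd = 2.01,
      L_min = 20.44, L_max = 30.88, D_min = 18.58, D_max = 30.80,
      gen_form = "LD2", gen_a = 0.1243, gen_b = 0.0005, noise_sd = 0.3924),
    ghandi_2021 = cohort_spec("ghandi_2021", 508,
      L_mean = 22.44, L_sd = 2.06, D_mean = 21.95, D_sd = 2.11,
      L_min = 15.92, L_max = 26.97, D_min = 16.03, D_max = 27.07,
      gen_form = "LD2", gen_a = -0.0388, gen_b = 0.0006, noise_sd = 0.3235),
    shahryari_2021 = cohort_spec("shahryari_2021", 530,
      L_mean = 23.58, L_sd = 2.31, D_mean = 21.78, D_sd = 2.55,
      L_min = 16.74, L_max = 29.22, D_min = 13.29, D_max = 28.33,
      gen_form = "LD2", gen_a = -0.0132, gen_b = 0.0006, noise_sd = 0.4055),
    jangali_2021 = cohort_spec("jangali_2021", 486,
      L_mean = 15.12, L_sd = 1.19, D_mean = 13.52, D_sd = 1.19,
      L_min = 11.15, L_max = 19.00, D_min = 8.22, D_max = 16.66,
      gen_form = "LD2", gen_a = -0.0375, gen_b = 0.0005, noise_sd = 0.0822,
      fw_floor = 0.05)
  )
}

#' Generate a tabular fruit cohort from a statistical recipe
#'
#' Draws (L, D) from a correlated bivariate normal with the spec's moments,
#' rejection-truncated to the spec's bounds, then generates
#' `FW = gen_a + gen_b * f(L, D) + N(0, noise_sd)` clipped below at
#' `fw_floor`. Identical `(spec, seed)` give identical output.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return data.frame of class `fruit_cohort` with columns `length_mm`,
#'   `diameter_mm`, `weight_g` and exactly `spec$n` rows.
#' @export
#' @examples
#' spec <- plum_cohort_specs()$gavali_2019
#' cohort <- generate_tabular_cohort(spec, seed = 1)
#' colMeans(cohort)
generate_tabular_cohort <- function(spec, seed) {
  validate_cohort_spec(spec)
  n <- spec$n
  budget <- 1000L * n        # total draws allowed for rejection sampling
  with_seed(seed, {
    chol12 <- spec$rho_LD
    chol22 <- sqrt(1 - spec$rho_LD^2)
    L <- numeric(0); D <- numeric(0)
    drawn <- 0L
    while (length(L) < n) {
      m <- min(max(2L * n, 100L), budget - drawn)
      if (m <= 0L)
        stop("generate_tabular_cohort: rejection budget exceeded; ",
             "truncation bounds are infeasible for the stated moments")
      z1 <- rnorm(m); z2 <- rnorm(m)
      Lc <- spec$L_mean + spec$L_sd * z1
      Dc <- spec$D_mean + spec$D_sd * (chol12 * z1 + chol22 * z2)
      keep <- Lc >= spec$L_min & Lc <= spec$L_max &
              Dc >= spec$D_min & Dc <= spec$D_max
      L <- c(L, Lc[keep]); D <- c(D, Dc[keep])
      drawn <- drawn + m
    }
    L <- L[seq_len(n)]; D <- D[seq_len(n)]
    f <- form_basis(spec$gen_form)
    FW <- spec$gen_a + spec$gen_b * f(L, D) + rnorm(n, 0, spec$noise_sd)
    FW <- pmax(FW, spec$fw_floor)
    structure(data.frame(length_mm = L, diameter_mm = D, weight_g = FW),
              class = c("fruit_cohort", "data.frame"),
              cohort_name = spec$name, seed = as.integer(seed))
  })
}

assert_records <- function(records, n_min = 1L) {
  need <- c("length_mm", "diameter_mm", "weight_g")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must be a data.frame with columns length_mm, diameter_mm, weight_g")
  if (nrow(records) < n_min)
    stop(sprintf("need at least %d records, got %d", n_min, nrow(records)))
  invisible(records)
}

#' Write / read a fruit cohort as CSV
#'
#' The on-disk dialect is a plain CSV with header
#' `length_mm,diameter_mm,weight_g`.
#'
#' @param records a fruit cohort data.frame.
#' @param path CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the cohort.
#' @export
write_cohort <- function(records, path) {
  assert_records(records)
  write.csv(records[c("length_mm", "diameter_mm", "weight_g")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  records <- read.csv(path)
  assert_records(records)
  structure(records, class = c("fruit_cohort", "data.frame"))
}

# ---- image rendering --------------------------------------------------------

#' Ground truth for one rendered fruit
#'
#' @param L_mm,D_mm fruit length (major) and equatorial diameter (minor), mm;
#'   `L_mm >= D_mm > 0`.
#' @param orientation_deg major-axis angle from the image x-axis, degrees.
#' @param hue_class fruit colour class: `"green"`, `"yellow"` or `"red"`.
#' @return object of class `fruit_truth`.
#' @export
fruit_truth <- function(L_mm, D_mm, orientation_deg = 0,
                        hue_class = c("green", "yellow", "red")) {
  hue_class <- match.arg(hue_class)
  if (!(L_mm >= D_mm && D_mm > 0))
    stop("fruit_truth: need L_mm >= D_mm > 0 (length is the major dimension)")
  structure(list(L_mm = L_mm, D_mm = D_mm,
                 orientation_deg = orientation_deg, hue_class = hue_class),
            class = "fruit_truth")
}

#' Imaging geometry and sensor model for the renderer
#'
#' @param image_width_px,image_height_px frame size in pixels.
#' @param mm_per_px metric scale (mm per pixel), > 0.
#' @param background_gray background intensity in `[0, 1]` (near-white
#'   matte stage).
#' @param illumination_gradient fractional intensity drop from the left to
#'   the right edge of the frame (0 = flat lighting).
#' @param sensor_noise_sd additive Gaussian sensor noise SD, intensity units.
#' @param include_calibration_square reserved flag for batch renders.
#' @param square_side_mm side of the calibration square, mm (default 10).
#' @return object of class `imaging_spec`.
#' @export
imaging_spec <- function(image_width_px = 256L, image_height_px = 256L,
                         mm_per_px = 0.2, background_gray = 0.92,
                         illumination_gradient = 0, sensor_noise_sd = 0,
                         include_calibration_square = FALSE,
                         square_side_mm = 10) {
  if (mm_per_px <= 0) stop("imaging_spec: mm_per_px must be > 0")
  structure(list(image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 mm_per_px = mm_per_px, background_gray = background_gray,
                 illumination_gradient = illumination_gradient,
                 sensor_noise_sd = sensor_noise_sd,
                 include_calibration_square = include_calibration_square,
                 square_side_mm = square_side_mm),
            class = "imaging_spec")
}

.hue_base <- list(green  = c(0.33, 0.55, 0.25),
                  yellow = c(0.88, 0.78, 0.22),
                  red    = c(0.72, 0.16, 0.18))

#' Render a single-fruit top-view scene with ground truth
#'
#' Renders one (super)elliptical fruit with hue-class-dependent colouring
#' and radial shading on a light matte background, with an optional smooth
#' illumination gradient and additive sensor noise. The returned manifest
#' carries the truth, the metric scale, and the exact rasterized fruit mask
#' used for round-trip validation of segmentation and morphometry.
#'
#' @param truth a [fruit_truth()].
#' @param imaging an [imaging_spec()].
#' @param seed integer seed (sensor noise only); equal inputs and seed give
#'   bit-identical images.
#' @param superellipse_n superellipse exponent (2 = ellipse); larger values
#'   give boxier fruit for shape-robustness tests.
#' @return list of class `rendered_fruit` with `image` (RGB array) and
#'   `manifest` (truth, mm_per_px, mask, area_px).
#' @export
render_fruit_image <- function(truth, imaging, seed = 1,
                               superellipse_n = 2) {
  stopifnot(inherits(truth, "fruit_truth"), inherits(imaging, "imaging_spec"))
  w <- imaging$image_width_px; h <- imaging$image_height_px
  a <- (truth$L_mm / imaging$mm_per_px) / 2   # semi-major, px
  b <- (truth$D_mm / imaging$mm_per_px) / 2   # semi-minor, px
  th <- truth$orientation_deg * pi / 180
  # rotated half-extents along the frame axes
  ext_x <- sqrt((a * cos(th))^2 + (b * sin(th))^2)
  ext_y <- sqrt((a * sin(th))^2 + (b * cos(th))^2)
  cx <- w / 2; cy <- h / 2
  if (cx - ext_x < 1 || cx + ext_x > w - 1 || cy - ext_y < 1 || cy + ext_y > h - 1)
    stop("render_fruit_image: fruit does not fit inside the frame")

  # pixel centers
  x <- matrix(rep(seq_len(w) - 0.5, each = h), h, w) - cx
  y <- matrix(rep(seq_len(h) - 0.5, times = w), h, w) - cy
  u <- (x * cos(th) + y * sin(th)) / a
  v <- (-x * sin(th) + y * cos(th)) / b
  r <- (abs(u)^superellipse_n + abs(v)^superellipse_n)^(1 / superellipse_n)
  mask <- r <= 1

  base <- .hue_base[[truth$hue_class]]
  img <- array(imaging$background_gray, c(h, w, 3))
  shade <- 1 - 0.3 * pmin(r, 1)^2             # radial shading toward the rim
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- base[ch] * shade[mask]
    img[, , ch] <- plane
  }
  if (imaging$illumination_gradient != 0) {
    g <- matrix(rep(seq(1, 1 - imaging$illumination_gradient, length.out = w),
                    each = h), h, w)
    for (ch in 1:3) img[, , ch] <- img[, , ch] * g
  }
  if (imaging$sensor_noise_sd > 0) {
    img <- with_seed(seed, {
      img + array(rnorm(length(img), 0, imaging$sensor_noise_sd), dim(img))
    })
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img,
                 manifest = list(truth = truth,
                                 mm_per_px = imaging$mm_per_px,
                                 mask = mask, area_px = sum(mask),
                                 seed = as.integer(seed))),
            class = "rendered_fruit")
}

#' Render the 10 x 10 mm black calibration square
#'
#' A black square of side `square_side_mm / mm_per_px` pixels centered on
#' the light background; optionally with 1-px linear anti-aliased edges.
#'
#' @param imaging an [imaging_spec()]; uses `square_side_mm` and the frame.
#' @param antialias logical; if TRUE edge pixels carry fractional coverage.
#' @return RGB image array.
#' @export
render_calibration_image <- function(imaging, antialias = FALSE) {
  stopifnot(inherits(imaging, "imaging_spec"))
  w <- imaging$image_width_px; h <- imaging$image_height_px
  side <- imaging$square_side_mm / imaging$mm_per_px
  if (side > w - 4 || side > h - 4)
    stop("render_calibration_image: square does not fit inside the frame")
  cx <- w / 2; cy <- h / 2
  xs <- seq_len(w) - 0.5; ys <- seq_len(h) - 0.5
  if (antialias) {
    covx <- pmin(pmax(side / 2 - abs(xs - cx) + 0.5, 0), 1)
    covy <- pmin(pmax(side / 2 - abs(ys - cy) + 0.5, 0), 1)
    cover <- outer(covy, covx)
  } else {
    inx <- xs >= cx - side / 2 & xs < cx + side / 2
    iny <- ys >= cy - side / 2 & ys < cy + side / 2
    cover <- outer(as.numeric(iny), as.numeric(inx))
  }
  val <- imaging$background_gray * (1 - cover)   # 0 inside the square
  array(rep(val, 3L), c(h, w, 3))
}
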