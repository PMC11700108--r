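test_that("generated cohorts reproduce the spec'd moments", {
  spec <- plum_cohort_specs()$gavali_2019
  cohort <- generate_tabular_cohort(spec, seed = 11)
  expect_s3_class(cohort, "fruit_cohort")
  expect_identical(nrow(cohort), 1028L)
  # sample means within 2 SE of the stated population means
  se_L <- spec$L_sd / sqrt(spec$n)
  se_D <- spec$D_sd / sqrt(spec$n)
  expect_lt(abs(mean(cohort$length_mm) - 25.74), 2 * se_L)
  expect_lt(abs(mean(cohort$diameter_mm) - 24.50), 2 * se_D)
  expect_true(all(cohort$length_mm >= spec$L_min & cohort$length_mm <= spec$L_max))
  expect_true(all(cohort$diameter_mm >= spec$D_min & cohort$diameter_mm <= spec$D_max))
})

test_that("emulation property: moments and correlation track the spec", {
  for (seed in c(3, 17)) {
    spec <- cohort_spec("emul", 800, L_mean = 24, L_sd = 2, D_mean = 22,
                        D_sd = 2.2, L_min = 16, L_max = 32, D_min = 14,
                        D_max = 30, rho_LD = 0.75, gen_form = "LD",
                        gen_a = -4, gen_b = 0.02, noise_sd = 0.4)
    cohort <- generate_tabular_cohort(spec, seed)
    expect_lt(abs(mean(cohort$length_mm) / spec$L_mean - 1), 0.05)
    expect_lt(abs(mean(cohort$diameter_mm) / spec$D_mean - 1), 0.05)
    expect_lt(abs(sd(cohort$length_mm) / spec$L_sd - 1), 0.05)
    expect_lt(abs(sd(cohort$diameter_mm) / spec$D_sd - 1), 0.05)
    expect_lt(abs(cor(cohort$length_mm, cohort$diameter_mm) - 0.75), 0.05)
  }
})

test_that("noise-free generating law is exact and generation is deterministic", {
  spec <- cohort_spec("exact", 50, L_mean = 25, L_sd = 1.5, D_mean = 23,
                      D_sd = 1.5, L_min = 20, L_max = 30, D_min = 18,
                      D_max = 28, gen_form = "LD", gen_a = 0, gen_b = 1,
                      noise_sd = 0)
  a <- generate_tabular_cohort(spec, 5)
  expect_equal(a$weight_g, a$length_mm * a$diameter_mm)
  b <- generate_tabular_cohort(spec, 5)
  expect_identical(a, b)
  expect_false(identical(a, generate_tabular_cohort(spec, 6)))
})

test_that("fitting the generating form recovers (a, b) within 3 SE", {
  # oracle: least-squares theory SEs from the simple regression of FW on L*D
  spec <- cohort_spec("recov", 2000, L_mean = 25.74, L_sd = 1.64,
                      D_mean = 24.50, D_sd = 1.84, L_min = 21.13,
                      L_max = 32.22, D_min = 19.17, D_max = 30.55,
                      gen_form = "LD", gen_a = -4.4940, gen_b = 0.0225,
                      noise_sd = 0.5)
  cohort <- generate_tabular_cohort(spec, 21)
  fit <- fit_form(cohort, "LD")
  x <- cohort$length_mm * cohort$diameter_mm
  ols <- summary(lm(weight_g ~ x, data = cbind(cohort, x = x)))$coefficients
  expect_lt(abs(fit$a - (-4.4940)), 3 * ols[1, 2])
  expect_lt(abs(fit$b - 0.0225), 3 * ols[2, 2])
})

test_that("infeasible truncation bounds exhaust the rejection budget", {
  # huge dispersions against needle-thin windows: joint acceptance ~ 2e-8,
  # far below the 1000-draws-per-record budget
  spec <- cohort_spec("tight", 100, L_mean = 25, L_sd = 50, D_mean = 23,
                      D_sd = 50, L_min = 24.99, L_max = 25.01,
                      D_min = 22.99, D_max = 23.01, rho_LD = 0,
                      noise_sd = 0)
  expect_error(generate_tabular_cohort(spec, 1), "budget")
})

test_that("cohort CSV round trip preserves the dialect and values", {
  cohort <- make_records(20, seed = 2, noise_sd = 0.1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  expect_identical(readLines(path, n = 1L), "length_mm,diameter_mm,weight_g")
  back <- read_cohort(path)
  expect_equal(back$weight_g, cohort$weight_g, tolerance = 1e-12)
})

test_that("rendered fruit area matches the ellipse formula", {
  im <- imaging_spec(image_width_px = 320, image_height_px = 320,
                     mm_per_px = 0.1)
  r <- render_fruit_image(fruit_truth(25, 20), im, seed = 1)
  expect_equal(r$manifest$area_px, pi * 125 * 100, tolerance = 0.02)
})

test_that("noiseless scene has one constant background colour disjoint from fruit", {
  im <- imaging_spec(sensor_noise_sd = 0, illumination_gradient = 0)
  r <- render_fruit_image(fruit_truth(25, 22, hue_class = "green"), im)
  mask <- r$manifest$mask
  cols <- apply(r$image, 3, identity)          # n x 3
  bg <- unique(cols[!mask, , drop = FALSE])
  expect_identical(nrow(bg), 1L)
  fruit <- cols[as.vector(mask), , drop = FALSE]
  expect_gt(min(colSums((t(fruit) - as.numeric(bg))^2)), 0.01)
})

test_that("rendering is deterministic per seed and errors on oversized fruit", {
  im <- imaging_spec(sensor_noise_sd = 0.02)
  tr <- fruit_truth(26, 24, orientation_deg = 30, hue_class = "red")
  expect_identical(render_fruit_image(tr, im, seed = 7)$image,
                   render_fruit_image(tr, im, seed = 7)$image)
  expect_false(identical(render_fruit_image(tr, im, seed = 7)$image,
                         render_fruit_image(tr, im, seed = 8)$image))
  too_big <- fruit_truth(60, 50)
  expect_error(render_fruit_image(too_big, imaging_spec(mm_per_px = 0.2)),
               "fit")
})

test_that("fruit_truth enforces the L >= D > 0 invariant", {
  expect_error(fruit_truth(20, 25), "L_mm >= D_mm")
  expect_error(fruit_truth(20, 0), "L_mm >= D_mm")
  expect_silent(fruit_truth(20, 20))
})

test_that("calibration square side is square_side_mm / mm_per_px pixels", {
  for (mpp in c(0.1, 0.05)) {
    im <- imaging_spec(image_width_px = 320, image_height_px = 320,
                       mm_per_px = mpp)
    img <- render_calibration_image(im)
    dark <- img[, , 1] < 0.5
    expect_identical(sum(apply(dark, 2, any)), as.integer(10 / mpp))
    expect_identical(sum(apply(dark, 1, any)), as.integer(10 / mpp))
  }
  expect_error(render_calibration_image(imaging_spec(mm_per_px = 0.01)),
               "fit")
})
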