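test_that("rmse and r_squared match hand-computed fixtures", {
  expect_identical(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(2, 4), c(3, 1)), sqrt(5), tolerance = 1e-12)
  expect_identical(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1.1, 1.9, 3.2)), 0.97,
               tolerance = 1e-12)
  expect_lt(r_squared(c(1, 2, 3), c(3, 1, 2)), 0)
  expect_error(rmse(1:3, 1:2), "length")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(r_squared(rep(1, 5), rnorm(5)), "constant")
})

test_that("70/30 splitting reproduces the published partition sizes", {
  sizes <- list(c(1028, 720, 308), c(518, 363, 155), c(508, 356, 152),
                c(530, 371, 159), c(486, 340, 146), c(10, 7, 3))
  for (s in sizes) {
    rec <- make_records(s[1], seed = 1)
    parts <- split_dataset(rec, 0.7, seed = 2)
    expect_identical(nrow(parts$train), as.integer(s[2]))
    expect_identical(nrow(parts$test), as.integer(s[3]))
    expect_identical(sort(c(parts$train_idx, setdiff(seq_len(s[1]), parts$train_idx))),
                     seq_len(s[1]))
  }
  # deterministic per seed
  a <- split_dataset(make_records(50, seed = 1), seed = 9)
  b <- split_dataset(make_records(50, seed = 1), seed = 9)
  expect_identical(a$train_idx, b$train_idx)
  expect_error(split_dataset(make_records(2, seed = 1), train_fraction = 0.1),
               "degenerate")
})

test_that("kfold_indices forms exact partitions with balanced folds", {
  f20 <- kfold_indices(20, 10, seed = 1)
  expect_identical(lengths(f20), setNames(rep(2L, 10), as.character(1:10)))
  f23 <- kfold_indices(23, 10, seed = 1)
  expect_true(all(lengths(f23) %in% 2:3))
  expect_identical(sum(lengths(f23)), 23L)
  for (seed in 1:3) {
    n <- sample(15:60, 1)
    k <- sample(2:10, 1)
    folds <- kfold_indices(n, k, seed)
    expect_identical(sort(unname(unlist(folds))), seq_len(n))
  }
  expect_error(kfold_indices(5, 10), ">= k")
})

test_that("evaluate_model is exact on a noise-free law and calibrated on noise", {
  spec <- cohort_spec("nf", 200, L_mean = 25, L_sd = 1.6, D_mean = 24,
                      D_sd = 1.8, L_min = 20, L_max = 30, D_min = 19,
                      D_max = 29, gen_form = "LD", gen_a = -4.494,
                      gen_b = 0.0225, noise_sd = 0)
  cohort <- generate_tabular_cohort(spec, 30)
  rep0 <- evaluate_model(function(r) fit_form(r, "LD"), cohort, seed = 1)
  expect_equal(rep0$r2_train, 1, tolerance = 1e-9)
  expect_equal(rep0$r2_test, 1, tolerance = 1e-9)
  expect_lt(rep0$rmse_train + rep0$rmse_test, 1e-9)

  # noisy law: average test RMSE tracks sigma, identity line near (1, 0)
  spec$noise_sd <- 0.5
  rmses <- slopes <- ints <- numeric(25)
  for (s in seq_len(25)) {
    cohort <- generate_tabular_cohort(spec, 100 + s)
    r <- evaluate_model(function(x) fit_form(x, "LD"), cohort, seed = s)
    rmses[s] <- r$rmse_test; slopes[s] <- r$identity_slope
    ints[s] <- r$identity_intercept
  }
  expect_lt(abs(mean(rmses) / 0.5 - 1), 0.15)
  expect_lt(abs(mean(slopes) - 1), 0.05)
  expect_lt(abs(mean(ints)), 0.2)
})

test_that("select_best ranks by train RMSE with R2 and order tie-breaks", {
  mk <- function(label, rmse, r2)
    structure(list(label = label, rmse_train = rmse, r2_train = r2),
              class = "eval_report")
  reports <- list(mk("a", 0.50, 0.93), mk("b", 0.49, 0.90), mk("c", 0.55, 0.95))
  expect_identical(select_best(reports)$label, "b")
  ties <- list(mk("a", 0.5, 0.93), mk("b", 0.5, 0.94))
  expect_identical(select_best(ties)$label, "b")
  equal <- list(mk("a", 0.5, 0.9), mk("b", 0.5, 0.9))
  expect_identical(select_best(equal)$label, "a")   # declaration order
  expect_identical(select_best(list(mk("x", 1, 0)))$label, "x")
  expect_error(select_best(list()), "empty")
})

test_that("descriptive_stats reports standard unbiased moments", {
  rec <- data.frame(length_mm = c(1, 2, 3), diameter_mm = c(2, 2, 2),
                    weight_g = c(1, 1, 4))
  st <- descriptive_stats(rec)
  L <- st[st$variable == "length_mm", ]
  expect_equal(L$mean, 2)
  expect_equal(L$sd, 1)
  expect_equal(L$se, 1 / sqrt(3), tolerance = 1e-12)
  expect_identical(c(L$min, L$max), c(1, 3))
  expect_equal(L$skewness, 0)
  expect_equal(st[st$variable == "diameter_mm", "sd"], 0)
  # synthetic development cohort mean within 2 SE of the stated mean
  cohort <- generate_tabular_cohort(plum_cohort_specs()$gavali_2019, 3)
  stL <- descriptive_stats(cohort)[1, ]
  expect_lt(abs(stL$mean - 25.74), 2 * 1.64 / sqrt(1028))
})

test_that("correlation_matrix flags strong associations and respects the null", {
  rec <- make_records(30, seed = 31)
  rec$weight_g <- 2 * rec$length_mm          # perfectly linear pair
  cm <- correlation_matrix(rec)
  expect_equal(cm$r["length_mm", "weight_g"], 1, tolerance = 1e-12)
  expect_identical(diag(cm$r), setNames(rep(1, 3), colnames(cm$r)))
  expect_equal(cm$r, t(cm$r), tolerance = 1e-15)
  expect_true(cm$significant["length_mm", "weight_g"])
  # independent pairs: |r| < 0.12 at nearly all seeds (n = 500)
  hits <- 0L
  for (s in 1:20) {
    withr::with_seed(s, {
      ind <- data.frame(length_mm = rnorm(500, 25), diameter_mm = rnorm(500, 24),
                        weight_g = rnorm(500, 9))
    })
    cmi <- correlation_matrix(ind)
    if (abs(cmi$r["length_mm", "weight_g"]) < 0.12) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
  expect_error(correlation_matrix(data.frame(length_mm = rep(1, 5),
                                             diameter_mm = 1:5,
                                             weight_g = 1:5)), "constant")
})

test_that("transfer validation propagates a frozen model across cohorts", {
  base <- cohort_spec("A", 400, L_mean = 25, L_sd = 1.6, D_mean = 24,
                      D_sd = 1.8, L_min = 20, L_max = 30, D_min = 19,
                      D_max = 29, gen_form = "LD", gen_a = -4.494,
                      gen_b = 0.0225, noise_sd = 0.4)
  dev <- generate_tabular_cohort(base, 1)
  model <- fit_form(dev, "LD")
  same_law <- generate_tabular_cohort(base, 2)
  shifted <- same_law
  shifted$weight_g <- shifted$weight_g + 1
  tv <- transfer_validate(model, list(same = same_law, shifted = shifted,
                                      dev = dev))
  expect_identical(nrow(tv), 3L)
  # same generating law: R2 within simulation error of the source cohort
  r2_dev <- tv$r2[tv$cohort == "dev"]
  expect_lt(abs(tv$r2[tv$cohort == "same"] - r2_dev), 0.05)
  # +1 g intercept shift: RMSE grows to ~ sqrt(sigma^2 + 1)
  rmse_same <- tv$rmse_g[tv$cohort == "same"]
  expect_equal(tv$rmse_g[tv$cohort == "shifted"],
               sqrt(rmse_same^2 + 1), tolerance = 0.05)
  expect_error(transfer_validate(model, list()), "non-empty")
})
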