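# End-to-end orchestration of the simulated study: materialize synthetic
# cohorts (and optionally rendered images), measure images, fit the full
# model grid on the development cohort, evaluate, pick a winner, and
# transfer-validate on the remaining cohorts. All randomness flows from
# one root seed through named substreams (see derive_seed()).

#' Default study configuration
#'
#' The default reproduces the published study design in silico: the five
#' built-in genotype cohorts ([plum_cohort_specs()]), a 70/30 split, the
#' 3 x 3 SVR grid, an M5 model tree, an MLP, and the five allometric
#' forms, with the first cohort (2019 Gavali) as the development cohort.
#'
#' @param seed root seed (mandatory for every run).
#' @param n_override optional integer: scale every cohort down to this
#'   size (for quick runs and tests).
#' @return nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L, n_override = NULL) {
  specs <- plum_cohort_specs()
  if (!is.null(n_override)) {
    specs <- lapply(specs, function(s) { s$n <- as.integer(n_override); s })
  }
  structure(list(
    seed = as.integer(seed),
    cohorts = specs,
    development_cohort = names(specs)[1],
    imaging = imaging_spec(),
    split = list(train_fraction = 0.7),
    models = list(
      forms = .gen_forms,
      mlr = TRUE,
      svr = list(kernels = c("RBF", "PUK", "POLY2"),
                 c_values = c(0.1, 1, 10), epsilon = 0.001),
      mlp = list(hidden_neurons = 3L),
      m5p = list(min_instances = 4L, smoothing = TRUE)
    ),
    images = list(enabled = FALSE, n_images = 10L)
  ), class = "run_config")
}

#' Read a study configuration from a JSON file
#'
#' The JSON mirrors [default_config()]; omitted entries fall back to the
#' defaults. Cohort entries are validated through [cohort_spec()].
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$seed)) stop("read_config: seed is mandatory")
  config <- default_config(seed = raw$seed)
  if (!is.null(raw$cohorts)) {
    config$cohorts <- lapply(seq_len(nrow(raw$cohorts)), function(i)
      do.call(cohort_spec, as.list(raw$cohorts[i, ])))
    names(config$cohorts) <- vapply(config$cohorts, `[[`, "", "name")
    config$development_cohort <- raw$development_cohort %||%
      names(config$cohorts)[1]
  }
  for (field in c("split", "models", "images")) {
    if (!is.null(raw[[field]]))
      config[[field]] <- utils::modifyList(config[[field]], raw[[field]])
  }
  if (!config$development_cohort %in% names(config$cohorts))
    stop("read_config: development_cohort does not resolve to a cohort")
  config
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(config[setdiff(names(config), "imaging")],
                           auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", derive_seed(0L, as.character(json)))
}

#' Materialize all synthetic inputs of a study
#'
#' Writes one CSV per cohort (dialect `length_mm,diameter_mm,weight_g`),
#' and, when image rendering is enabled in the config, a set of rendered
#' fruit PNGs with JSON ground-truth manifests plus the calibration-square
#' image. Idempotent: rerunning with the same config yields byte-identical
#' CSVs.
#'
#' @param config a `run_config`.
#' @param out_dir output directory (created if absent).
#' @return invisible list with `cohorts` (list of data.frames) and paths.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("run_simulate: cannot create ", out_dir)
  hash <- config_hash(config)
  cohorts <- lapply(config$cohorts, function(spec)
    generate_tabular_cohort(spec, derive_seed(config$seed,
                                              paste0("simulate/", spec$name))))
  paths <- vapply(names(cohorts), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_cohort(cohorts[[nm]], p)
    p
  }, character(1))
  image_paths <- character(0)
  if (isTRUE(config$images$enabled)) {
    dev <- cohorts[[config$development_cohort]]
    n_img <- min(config$images$n_images, nrow(dev))
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    hues <- c("green", "yellow", "red")
    for (i in seq_len(n_img)) {
      L <- max(dev$length_mm[i], dev$diameter_mm[i])
      D <- min(dev$length_mm[i], dev$diameter_mm[i])
      sub <- derive_seed(config$seed, paste0("render/", i))
      orient <- with_seed(sub, runif(1, -45, 45))
      truth <- fruit_truth(L, D, orientation_deg = orient,
                           hue_class = hues[(i - 1L) %% 3L + 1L])
      rend <- render_fruit_image(truth, config$imaging, seed = sub)
      p <- file.path(img_dir, sprintf("fruit_%03d.png", i))
      write_image(rend$image, p)
      jsonlite::write_json(list(image_id = basename(p), L_mm = L, D_mm = D,
                                orientation_deg = orient,
                                hue_class = truth$hue_class,
                                mm_per_px = config$imaging$mm_per_px,
                                config_hash = hash),
                           sub("\\.png$", ".json", p), auto_unbox = TRUE,
                           digits = NA)
      image_paths <- c(image_paths, p)
    }
    write_image(render_calibration_image(config$imaging),
                file.path(img_dir, "calibration.png"))
  }
  jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                            cohorts = as.list(vapply(cohorts, nrow, 1L))),
                       file.path(out_dir, "simulate_manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(cohorts = cohorts, csv_paths = paths,
                 image_paths = image_paths, config_hash = hash))
}

#' Measure a rendered image set against its calibration image
#'
#' Thin orchestration wrapper around [measure_directory()] that writes the
#' morphometry CSV (`image_id,length_mm,diameter_mm,orientation_deg,area_px`).
#'
#' @param config a `run_config` (supplies the segmentation seed).
#' @param image_dir directory of fruit PNGs.
#' @param calibration_path calibration-square PNG.
#' @param out_csv output CSV path.
#' @return the morphometry data.frame, invisibly.
#' @export
run_measure <- function(config, image_dir, calibration_path,
                        out_csv = file.path(image_dir, "morphometry.csv")) {
  stopifnot(inherits(config, "run_config"))
  res <- measure_directory(image_dir, calibration_path,
                           seed = derive_seed(config$seed, "measure"))
  write.csv(res, out_csv, row.names = FALSE, quote = FALSE)
  invisible(res)
}

#' Run the full simulated study
#'
#' Generates (or accepts) all cohorts, fits every configured model family
#' on the development cohort's training partition, evaluates on the
#' held-out partition, selects the winner by training RMSE, and
#' transfer-validates every model on the remaining cohorts without
#' refitting. Emits `models.csv` (one row per model: the shape of the
#' published per-model results tables), `svr_grid.csv` (the 3 x 3
#' kernel-by-penalty cross-validation report), `transfer.csv` (model x
#' cohort) and `summary.json`.
#'
#' @param config a `run_config`.
#' @param out_dir output directory.
#' @param cohorts optional pre-built named list of cohorts (defaults to
#'   simulating them from the config).
#' @return list with `reports`, `winner`, `models_table`, `svr_grid`,
#'   `transfer_table`, `config_hash`.
#' @export
run_study <- function(config, out_dir = NULL, cohorts = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  if (is.null(cohorts)) {
    cohorts <- lapply(config$cohorts, function(spec)
      generate_tabular_cohort(spec, derive_seed(config$seed,
                                                paste0("simulate/", spec$name))))
  }
  dev <- cohorts[[config$development_cohort]]
  others <- cohorts[setdiff(names(cohorts), config$development_cohort)]
  split_seed <- derive_seed(config$seed, "split")
  frac <- config$split$train_fraction

  fitters <- list()
  for (form in config$models$forms)
    fitters[[paste0("form_", form)]] <- local({
      fo <- form
      function(records) fit_form(records, fo)
    })
  if (isTRUE(config$models$mlr)) fitters$mlr <- fit_mlr
  svr_grid <- NULL
  if (!is.null(config$models$svr)) {
    svr_cfg <- config$models$svr
    svr_seed <- derive_seed(config$seed, "svr_grid")
    fitters$svr <- function(records) {
      gs <- grid_search_svr(records, kernels = svr_cfg$kernels,
                            c_values = svr_cfg$c_values,
                            seed = svr_seed, epsilon = svr_cfg$epsilon)
      svr_grid <<- gs$report
      gs$best
    }
  }
  if (!is.null(config$models$mlp)) {
    mlp_seed <- derive_seed(config$seed, "mlp")
    fitters$mlp <- function(records)
      fit_mlp(records, hidden_neurons = config$models$mlp$hidden_neurons,
              seed = mlp_seed)
  }
  if (!is.null(config$models$m5p))
    fitters$m5p <- function(records)
      fit_m5p(records, min_instances = config$models$m5p$min_instances,
              smoothing = isTRUE(config$models$m5p$smoothing))

  reports <- lapply(names(fitters), function(nm)
    evaluate_model(fitters[[nm]], dev, train_fraction = frac,
                   seed = split_seed, label = nm))
  names(reports) <- names(fitters)
  winner <- select_best(reports)

  models_table <- do.call(rbind, lapply(reports, function(r)
    data.frame(model = r$label, rmse_train = r$rmse_train,
               rmse_test = r$rmse_test, r2_train = r$r2_train,
               r2_test = r$r2_test, identity_slope = r$identity_slope,
               identity_intercept = r$identity_intercept)))
  rownames(models_table) <- NULL

  transfer_table <- NULL
  if (length(others)) {
    transfer_table <- do.call(rbind, lapply(reports, function(r) {
      tv <- transfer_validate(r$model, others)
      cbind(model = r$label, tv)
    }))
    rownames(transfer_table) <- NULL
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(models_table, file.path(out_dir, "models.csv"),
              row.names = FALSE)
    if (!is.null(svr_grid))
      write.csv(svr_grid, file.path(out_dir, "svr_grid.csv"),
                row.names = FALSE)
    if (!is.null(transfer_table))
      write.csv(transfer_table, file.path(out_dir, "transfer.csv"),
                row.names = FALSE)
    jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                              development_cohort = config$development_cohort,
                              winner = winner$label,
                              winner_rmse_train = winner$rmse_train,
                              winner_r2_train = winner$r2_train),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(reports = reports, winner = winner, models_table = models_table,
       svr_grid = svr_grid, transfer_table = transfer_table,
       config_hash = hash)
}
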