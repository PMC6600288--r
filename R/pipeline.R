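#' Run the full adulteration-quantification workflow
#'
#' Reproduces the study design end to end: simulate (or accept) a spectra
#' table, split it into calibration and validation sets stratified by
#' concentration, apply SNV per spectrum, fit a full-spectrum PLS
#' calibration, run BOSS wavenumber selection on the calibration set, fit
#' the reduced PLS model on the selected wavenumbers (its factor count
#' re-selected by cross-validation on the subset), and evaluate both
#' models with RMSECV/R^2 on calibration and RMSEP/R^2 on validation.
#' Validation samples never influence preprocessing (SNV is row-local),
#' selection or factor choice.
#'
#' @param data Optional spectra tibble; when `NULL` a dataset is simulated
#'   from `design`, `oils`, `grid` and `artifacts`.
#' @param design,oils,grid,artifacts Simulation inputs, see
#'   [simulate_adulteration()]; ignored when `data` is given.
#' @param per_level Calibration samples per concentration level.
#' @param apply_snv Apply SNV preprocessing (disable for ablation runs).
#' @param n_subsets,top_fraction,n_folds,max_factors,choice_rule,draw_pool
#'   BOSS and cross-validation settings, see [run_boss()].
#' @param seed Single integer seeding simulation, split, folds and BOSS.
#' @param outdir Optional directory; when given, writes `report.json`,
#'   `predictions.csv` and `iterations.csv`.
#' @return An object of class `boss_pls_report` with `tidy()`, `glance()`
#'   and `autoplot()` methods.
#' @export
run_pipeline <- function(data = NULL, design = adulteration_design(),
                         oils = default_oil_library(), grid = make_grid(),
                         artifacts = artifact_model(), per_level = 3,
                         apply_snv = TRUE, n_subsets = 1000,
                         top_fraction = 0.10, n_folds = 5, max_factors = 15,
                         choice_rule = c("first_local_min", "global_min"),
                         draw_pool = c("top", "all"), seed = 1,
                         outdir = NULL) {
  choice_rule <- match.arg(choice_rule)
  draw_pool <- match.arg(draw_pool)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 4)

  if (is.null(data)) {
    data <- simulate_adulteration(design, oils, grid, artifacts,
                                  seed = seeds[1])
  }
  split <- split_calibration(data, per_level = per_level, seed = seeds[2])
  cal <- if (apply_snv) snv(split$calibration) else split$calibration
  val <- if (apply_snv) snv(split$validation) else split$validation

  X_cal <- as_spectra_matrix(cal)
  y_cal <- spectra_response(cal)
  X_val <- as_spectra_matrix(val)
  y_val <- spectra_response(val)
  folds <- make_folds(nrow(X_cal), n_folds, seed = seeds[3])

  eval_model <- function(idx, label) {
    Xc <- X_cal[, idx, drop = FALSE]
    a <- select_n_factors(Xc, y_cal, max_factors = max_factors,
                          folds = folds)
    fit <- fit_pls(Xc, y_cal, ncomp = as.integer(a))
    pred_cal <- fit$fitted
    pred_val <- predict(fit, X_val[, idx, drop = FALSE])
    list(
      label = label,
      n_variables = length(idx),
      n_factors = as.integer(a),
      rmsecv = attr(a, "rmsecv"),
      r2_calibration = r_squared(y_cal, pred_cal),
      rmsep = rmsep(y_val, pred_val),
      r2_validation = r_squared(y_val, pred_val),
      fit = fit,
      pred_cal = pred_cal,
      pred_val = pred_val
    )
  }

  full <- eval_model(seq_len(ncol(X_cal)), "PLS (full spectrum)")
  boss_fit <- run_boss(X_cal, y_cal, n_subsets = n_subsets,
                       top_fraction = top_fraction, n_folds = n_folds,
                       max_factors = max_factors, seed = seeds[4],
                       choice_rule = choice_rule, draw_pool = draw_pool)
  boss_fit$selected_wavenumbers <-
    spectra_wavenumbers(cal)[boss_fit$selected_idx]
  reduced <- eval_model(boss_fit$selected_idx, "BOSS-PLS")

  predictions <- dplyr::bind_rows(
    tibble::tibble(sample_id = cal$sample_id, set = "calibration",
                   y_true = y_cal, y_pred_full = full$pred_cal,
                   y_pred_boss = reduced$pred_cal),
    tibble::tibble(sample_id = val$sample_id, set = "validation",
                   y_true = y_val, y_pred_full = full$pred_val,
                   y_pred_boss = reduced$pred_val)
  )

  report <- structure(list(
    n_calibration = nrow(cal),
    n_validation = nrow(val),
    preprocessing = if (apply_snv) "snv" else "none",
    selected_wavenumbers = boss_fit$selected_wavenumbers,
    full = full[c("label", "n_variables", "n_factors", "r2_calibration",
                  "rmsecv", "r2_validation", "rmsep")],
    boss = reduced[c("label", "n_variables", "n_factors", "r2_calibration",
                     "rmsecv", "r2_validation", "rmsep")],
    boss_result = boss_fit,
    predictions = predictions,
    calibration_ids = sort(cal$sample_id),
    config = list(per_level = per_level, apply_snv = apply_snv,
                  n_subsets = n_subsets, top_fraction = top_fraction,
                  n_folds = n_folds, max_factors = max_factors,
                  choice_rule = choice_rule, draw_pool = draw_pool,
                  seed = seed),
    version = as.character(utils::packageVersion("bosspls")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "boss_pls_report")

  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
tidy.boss_pls_report <- function(x, ...) {
  row <- function(m, wns) {
    tibble::tibble(
      model = m$label,
      wavenumbers = wns,
      n_variables = m$n_variables,
      n_factors = m$n_factors,
      r2_calibration = m$r2_calibration,
      rmsecv = m$rmsecv,
      r2_validation = m$r2_validation,
      rmsep = m$rmsep
    )
  }
  dplyr::bind_rows(
    row(x$full, "full spectrum"),
    row(x$boss, paste(sprintf("%.2f", x$selected_wavenumbers),
                      collapse = "; "))
  )
}

#' @export
glance.boss_pls_report <- function(x, ...) {
  tibble::tibble(
    n_calibration = x$n_calibration,
    n_validation = x$n_validation,
    n_selected = x$boss$n_variables,
    chosen_iteration = x$boss_result$chosen_iteration,
    rmsecv_boss = x$boss$rmsecv,
    rmsep_boss = x$boss$rmsep,
    rmsep_full = x$full$rmsep,
    r2_validation_boss = x$boss$r2_validation
  )
}

#' @export
print.boss_pls_report <- function(x, ...) {
  cat("Adulteration calibration report (",
      x$n_calibration, " calibration / ", x$n_validation,
      " validation samples)\n\n", sep = "")
  print(as.data.frame(
    tidy(x)[, c("model", "n_variables", "n_factors", "r2_calibration",
                "rmsecv", "r2_validation", "rmsep")]
  ), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Measured-versus-predicted plot
#'
#' @param object A `boss_pls_report`.
#' @param model `"boss"` (default) or `"full"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.boss_pls_report <- function(object, model = c("boss", "full"),
                                     ...) {
  model <- match.arg(model)
  d <- object$predictions
  d$y_pred <- if (model == "boss") d$y_pred_boss else d$y_pred_full
  ggplot2::ggplot(d, ggplot2::aes(.data$y_true, .data$y_pred,
                                  colour = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "measured adulteration (% v/v)",
                  y = "predicted adulteration (% v/v)",
                  colour = NULL)
}

#' Tabulate several pipeline reports side by side
#'
#' Binds the `tidy()` rows of each report into one comparison table. All
#' reports must have been computed on the identical calibration/validation
#' split, otherwise their metrics are not comparable.
#'
#' @param reports List of `boss_pls_report` objects.
#' @return A tibble with one row per model per report.
#' @export
compare_models <- function(reports) {
  if (inherits(reports, "boss_pls_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1,
            all(vapply(reports, inherits, logical(1), "boss_pls_report")))
  ids <- lapply(reports, `[[`, "calibration_ids")
  if (length(unique(ids)) != 1) {
    stop("reports were computed on different calibration/validation splits.",
         call. = FALSE)
  }
  dplyr::bind_rows(lapply(seq_along(reports), function(i) {
    dplyr::mutate(tidy(reports[[i]]), run = i, .before = 1)
  }))
}

# serializable view of a report: everything except volatile metadata and
# the bulky fitted objects
report_core <- function(report) {
  tr <- report$boss_result$trajectory
  list(
    n_calibration = report$n_calibration,
    n_validation = report$n_validation,
    preprocessing = report$preprocessing,
    selected_wavenumbers = report$selected_wavenumbers,
    full = report$full,
    boss = report$boss,
    chosen_iteration = report$boss_result$chosen_iteration,
    trajectory = tr[, c("iteration", "n_draws", "n_support",
                        "mean_top_size", "best_rmsecv", "best_n_vars",
                        "best_ncomp")],
    config = report$config,
    version = report$version
  )
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  core <- report_core(report)
  core$created <- report$created
  jsonlite::write_json(core, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(report$predictions, file.path(outdir, "predictions.csv"),
                   progress = FALSE)
  readr::write_csv(report_core(report)$trajectory,
                   file.path(outdir, "iterations.csv"), progress = FALSE)
  invisible(report)
}
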