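# End-to-end driver: simulate (or read) -> clean -> trend selection ->
# periodic terms -> learning curves -> covariation, with per-stage record
# accounting and deterministic behaviour given (config, seed).

#' Run the full analysis pipeline
#'
#' Executes every stage in the study's analysis order on a provided or
#' freshly simulated dataset and returns a run report that reconstructs
#' which records reached each model. Identical `(config, seed)` inputs give
#' identical reports.
#'
#' @param config a [simulation_config()] (used to simulate when `dataset`
#'   is NULL, and for thresholds like sessions per day).
#' @param dataset optional raw `study_dataset`; when NULL a cohort is
#'   simulated from `config`.
#' @param out_dir optional directory; when set, cleaned data, coefficient
#'   tables, learning curves, and the report are written (CSV/JSON).
#' @param alpha significance level for trend selection, periodic-term
#'   retention, and forwarding predictors to lagged models.
#' @param min_steps,min_per_hour cleaning thresholds (defaults 100 steps,
#'   25 assessments/hour).
#' @return list of class `"cogema_run"`: `cleaning` report, `selections`
#'   (per outcome), `periodic` (per outcome), `starting_points`, `curves`,
#'   `covariation`, `counts`, `seed`.
#' @export
run_pipeline <- function(config = simulation_config(), dataset = NULL,
                         out_dir = NULL, alpha = 0.05, min_steps = 100,
                         min_per_hour = 25) {
  truth <- NULL
  if (is.null(dataset)) {
    sim <- generate_cohort(config)
    dataset <- sim$dataset
    truth <- sim$truth
  }
  cl <- clean_dataset(dataset, min_steps = min_steps,
                      min_per_hour = min_per_hour)
  ds <- cl$dataset
  outcomes <- c("dprime", "mood", "steps", "heart_rate")
  selections <- list()
  periodic <- list()
  final_fits <- list()
  for (oc in outcomes) {
    selections[[oc]] <- select_trend(ds, oc, alpha = alpha)
    periodic[[oc]] <- periodic_analysis(ds, selections[[oc]], alpha = alpha)
    final_fits[[oc]] <- periodic[[oc]]$final_fit
  }
  starting_points <- extract_intercepts(selections$dprime$selected)
  curves <- fit_learning_curves(ds, starting_points)
  residuals <- build_residuals(final_fits, curves = curves)
  covar <- covariation_pipeline(residuals, curves, alpha = alpha,
                                n_required = config$sessions_per_day)
  counts <- list(
    cleaning = cl$report,
    model_obs = vapply(final_fits, function(f) f$n_obs, numeric(1)),
    residual_days = nrow(residuals),
    residual_days_post_learning =
      nrow(exclude_learning_period(residuals, curves))
  )
  report <- structure(list(
    cleaning = cl$report,
    selections = lapply(selections, function(s) s$table),
    selected_degrees = vapply(selections,
                              function(s) s$selected$spec$degree,
                              numeric(1)),
    periodic_retained = lapply(periodic, function(p) p$retained),
    starting_points = starting_points,
    curves = curves,
    curve_summary = list(
      n_adequate = sum(curves$fit_adequate),
      mean_rate = mean(curves$learning_rate_90, na.rm = TRUE),
      mean_day = mean(curves$learning_day_90, na.rm = TRUE),
      mean_stable_max = mean(curves$stable_max[curves$fit_adequate],
                             na.rm = TRUE)
    ),
    covariation = covariation_tables(covar),
    counts = counts, seed = as.integer(config$seed),
    package_version = as.character(utils::packageVersion("cogema"))
  ), class = "cogema_run")
  # full objects kept out of the printable report but returned for
  # programmatic use
  attr(report, "objects") <- list(dataset = ds, truth = truth,
                                  selections = selections,
                                  periodic = periodic,
                                  final_fits = final_fits,
                                  residuals = residuals, covar = covar)
  if (!is.null(out_dir)) write_run(report, out_dir)
  report
}

covariation_tables <- function(covar) {
  grab <- function(x) if (is.null(x)) NULL else x$table
  list(
    concurrent = grab(covar$concurrent),
    lagged = lapply(covar$lagged, grab),
    concurrent_post_learning = grab(covar$concurrent_post_learning),
    lagged_post_learning = lapply(covar$lagged_post_learning, grab),
    complete_days = grab(covar$complete_days),
    significant_predictors = covar$significant_predictors,
    significant_predictors_post_learning =
      covar$significant_predictors_post_learning
  )
}

write_run <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- attr(report, "objects")
  write_dataset(obj$dataset, file.path(out_dir, "cleaned"))
  if (!is.null(obj$truth)) {
    write_ground_truth(obj$truth, file.path(out_dir, "cleaned"))
  }
  write.csv(report$curves, file.path(out_dir, "learning_curves.csv"),
            row.names = FALSE)
  write.csv(report$starting_points,
            file.path(out_dir, "starting_points.csv"), row.names = FALSE)
  for (oc in names(report$selections)) {
    write.csv(report$selections[[oc]],
              file.path(out_dir, paste0("trend_selection_", oc, ".csv")),
              row.names = FALSE)
  }
  strip <- rapply(unclass(report), function(x) x, how = "replace")
  jsonlite::write_json(strip, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.cogema_run <- function(x, ...) {
  cat("<cogema pipeline run>\n")
  cat("  selected trend degrees:",
      paste(names(x$selected_degrees), x$selected_degrees, sep = "=",
            collapse = ", "), "\n")
  cs <- x$curve_summary
  cat(sprintf("  learning: %d adequate fits, mean 90%% rate %.1f assessments (day %.1f), mean stable max %.2f\n",
              cs$n_adequate, cs$mean_rate, cs$mean_day, cs$mean_stable_max))
  cat(sprintf("  residual days: %d (%d after learning-period exclusion)\n",
              x$counts$residual_days,
              x$counts$residual_days_post_learning))
  if (!is.null(x$covariation$concurrent)) {
    cat("  concurrent covariation (mood ~ fluctuations):\n")
    print(x$covariation$concurrent, digits = 3, row.names = FALSE)
  }
  invisible(x)
}
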