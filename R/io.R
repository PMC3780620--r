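## Round-trip readers and writers: trial tables and predictions as CSV,
## fits as JSON, pipeline configuration as YAML or JSON.

trial_columns <- c("subject_id", "experiment", "block_index",
                   "condition_label", "trial_index_in_block",
                   "trial_type", "color", "true_count", "response",
                   "valid")

#' Read and write trial tables
#'
#' Comma-separated UTF-8 with a header and exactly the columns
#' `subject_id, experiment, block_index, condition_label,
#' trial_index_in_block, trial_type, color, true_count, response,
#' valid`; a missing response (timeout) is encoded as an empty field.
#'
#' @param trials trial data frame.
#' @param path file path.
#' @return `read_trials` returns the trial data frame; `write_trials`
#'   invisibly returns `path`.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(trial_columns %in% names(trials)))
  utils::write.csv(trials[, trial_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(subject_id = "character"))
  missing_cols <- setdiff(trial_columns, names(x))
  if (length(missing_cols)) {
    stop("trial table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x$response <- suppressWarnings(as.integer(x$response))
  x$valid <- as.logical(x$valid)
  if (any(!is.na(x$response) & !x$valid)) {
    stop("invalid trials must have missing responses")
  }
  x[, trial_columns]
}

#' Write per-trial predictions as CSV
#'
#' @param predictions output of [run_session()].
#' @param path file path.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.csv(predictions, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a fit to JSON
#'
#' Stores the model, fitted and fixed parameters, MSE, BIC, offset and
#' per-block category counts — everything needed to report or resume a
#' fitting run (per-trial predictions are regenerable via
#' [predict.observer_fit()]).
#'
#' @param fit an `observer_fit`.
#' @param path file path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "observer_fit"))
  jsonlite::write_json(list(
    model = fit$model,
    subject_id = fit$trials$subject_id[1],
    coef = as.list(fit$coef),
    hp = unclass(fit$hp),
    mse = fit$mse, n = fit$n, bic = fit$bic, offset = fit$offset,
    n_categories_per_block = fit$n_categories_per_block
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) jsonlite::fromJSON(path)

#' Read a pipeline configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON file of named settings: design
#' overrides (see [make_design()]), hyperparameter values, particle
#' counts, fitter bounds/restarts, seeds.
#'
#' @param path config file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format: ", ext)
  }
}
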