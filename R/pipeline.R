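## Pipeline drivers tying the stages together: simulate a cohort,
## fit both observers per subject, analyze, compare. Each stage is
## deterministic given its master seed (per-subject stream seeds are
## derived by a documented splitting scheme) and can write its outputs
## to files for a resumable run.

#' Simulate a cohort for one experiment
#'
#' Generates `n_subjects` independent sessions of the given design and
#' fills in responses with the supplied responder. Subject stream seeds
#' are derived deterministically from `seed` and the subject id.
#'
#' @param experiment_id `"exp1"`, `"exp2"` or `"exp3"`.
#' @param n_subjects number of simulated subjects.
#' @param responder a responder spec (default: the rational ideal
#'   observer with default hyperparameters).
#' @param seed master integer seed.
#' @param design optional design override (default
#'   `make_design(experiment_id)`).
#' @param dir optional output directory; per-subject CSVs are written
#'   there as `<experiment>_<subject>.csv`.
#' @return Combined trial data frame for all subjects.
#' @examples
#' \donttest{
#' trials <- simulate_experiment("exp1", n_subjects = 2, seed = 1,
#'                               responder = responder_global_mean())
#' }
#' @export
simulate_experiment <- function(experiment_id, n_subjects,
                                responder = responder_ideal(),
                                seed = NULL, design = NULL, dir = NULL) {
  if (is.null(design)) design <- make_design(experiment_id)
  subjects <- sprintf("s%02d", seq_len(n_subjects))
  out <- lapply(subjects, function(s) {
    s_seed <- split_seed(seed, paste0(experiment_id, s))
    trials <- generate_session(design, s, seed = s_seed)
    trials <- simulate_responses(trials, responder,
                                 seed = split_seed(seed,
                                                   paste0("resp", s)))
    if (!is.null(dir)) {
      if (!dir.exists(dir)) {
        stop("output directory does not exist: ", dir)
      }
      write_trials(trials, file.path(dir,
                                     sprintf("%s_%s.csv",
                                             experiment_id, s)))
    }
    trials
  })
  do.call(rbind, out)
}

#' Fit both observers to every subject of a cohort
#'
#' Runs [fit_observer()] per subject for the requested models. With
#' `dir` set, each fit is written as JSON and subjects with an existing
#' output file are skipped (resumable runs).
#'
#' @param trials combined trial data frame (single experiment).
#' @param models character subset of `c("rational", "exemplar")`.
#' @param control a [fit_control()] configuration.
#' @param seed master integer seed for the optimizer restarts.
#' @param dir optional output directory for per-subject fit JSON.
#' @param verbose log per-subject progress to stderr.
#' @return A list with `fits` (named list per model of per-subject
#'   `observer_fit`s) and, when both models are fitted, `comparison`
#'   (the [compare_group()] result).
#' @export
fit_experiment <- function(trials, models = c("rational", "exemplar"),
                           control = fit_control(), seed = NULL,
                           dir = NULL, verbose = FALSE) {
  models <- match.arg(models, several.ok = TRUE)
  subjects <- sort(unique(trials$subject_id))
  fits <- lapply(models, function(m) {
    res <- lapply(subjects, function(s) {
      if (!is.null(dir)) {
        fp <- file.path(dir, sprintf("fit_%s_%s.json", m, s))
        if (file.exists(fp)) return(NULL)
      }
      fit <- fit_observer(trials[trials$subject_id == s, ], model = m,
                          control = control,
                          seed = split_seed(seed, paste0(m, s)))
      if (verbose) {
        message(sprintf("fit %s %s: MSE %.3f, params %s", m, s,
                        fit$mse,
                        paste(sprintf("%s=%.3g", names(fit$coef),
                                      fit$coef), collapse = " ")))
      }
      if (!is.null(dir)) write_fit_json(fit, fp)
      fit
    })
    names(res) <- subjects
    res[!vapply(res, is.null, logical(1))]
  })
  names(fits) <- models
  out <- list(fits = fits)
  if (all(c("rational", "exemplar") %in% models)) {
    common <- intersect(names(fits$rational), names(fits$exemplar))
    if (length(common) >= 5) {
      out$comparison <- compare_group(fits$rational[common],
                                      fits$exemplar[common])
    }
  }
  out
}
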