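## Per-subject maximum-likelihood fitting of the rational observer and
## the exemplar baseline, with BIC-based model comparison.
##
## Following the standard fitting convention, each subject's counts and
## responses are recentered by the subject's mean true count so the
## prior mean mu0 = 0; lam = 1 and b0 = 10 are held fixed. The free
## parameters (alpha, a0, eta0, sigma_y for the rational model; a0,
## eta0, sigma_y for the exemplar model) minimize the mean-squared error
## between particle-filter predictions and responses, which is the
## Gaussian maximum-likelihood objective. Common random numbers (a fixed
## filter seed per evaluation) make the objective deterministic.

#' Recenter a subject's trials
#'
#' Subtracts the subject's mean true count (over valid trials) from both
#' the counts and the responses, so that the observer's prior mean can
#' be fixed at 0 during fitting.
#'
#' @param trials one subject's trial data frame.
#' @return A list with `trials` (shifted copy) and the numeric `offset`;
#'   `uncenter(trials, offset)` is the inverse.
#' @export
recenter_trials <- function(trials) {
  keep <- trials$valid
  if (!any(keep)) stop("subject has no valid trials to recenter on")
  offset <- mean(trials$true_count[keep])
  trials$true_count <- trials$true_count - offset
  trials$response <- trials$response - offset
  list(trials = trials, offset = offset)
}

#' @rdname recenter_trials
#' @param offset the offset returned by `recenter_trials`.
#' @export
uncenter <- function(trials, offset) {
  trials$true_count <- trials$true_count + offset
  trials$response <- trials$response + offset
  trials
}

#' Fitting configuration
#'
#' @param n_particles particles per objective evaluation.
#' @param restarts number of optimizer starts (the first two are a
#'   canonical mid-range point and a prior-dominated corner that
#'   approximates the constant-mean predictor; the rest are random
#'   within bounds).
#' @param maxit Nelder-Mead iterations per start.
#' @param filter_seed seed fixed across objective evaluations (common
#'   random numbers).
#' @param bounds named list of `c(lower, upper)` for `alpha`, `a0`,
#'   `eta0`, `sigma_y`; `alpha` and `eta0` are searched on a log scale.
#' @param alpha_exemplar concentration used by the exemplar model's
#'   prediction weights (effectively infinite).
#' @param fixed named list of parameters held fixed (`mu0`, `lam`, `b0`,
#'   `n_colors`).
#' @return A list of class `"fit_control"`.
#' @export
fit_control <- function(n_particles = 200, restarts = 3, maxit = 100,
                        filter_seed = 1L,
                        bounds = list(alpha = c(1e-3, 1e3),
                                      a0 = c(0.5, 50),
                                      eta0 = c(1e-2, 1e2),
                                      sigma_y = c(0.5, 30)),
                        alpha_exemplar = 1e8,
                        fixed = list(mu0 = 0, lam = 1, b0 = 10,
                                     n_colors = 3)) {
  structure(list(n_particles = n_particles, restarts = restarts,
                 maxit = maxit, filter_seed = filter_seed,
                 bounds = bounds, alpha_exemplar = alpha_exemplar,
                 fixed = fixed),
            class = "fit_control")
}

free_param_names <- function(model) {
  if (model == "rational") c("alpha", "a0", "eta0", "sigma_y")
  else c("a0", "eta0", "sigma_y")
}

log_scaled <- c(alpha = TRUE, a0 = FALSE, eta0 = TRUE, sigma_y = FALSE)

## parameter vector <-> unconstrained optimizer coordinates
to_unconstrained <- function(par, control) {
  vapply(names(par), function(nm) {
    b <- control$bounds[[nm]]
    v <- par[[nm]]
    if (log_scaled[[nm]]) { v <- log(v); b <- log(b) }
    p <- (v - b[1]) / (b[2] - b[1])
    stats::qlogis(min(max(p, 1e-6), 1 - 1e-6))
  }, numeric(1))
}

from_unconstrained <- function(u, nms, control) {
  par <- vapply(seq_along(nms), function(i) {
    b <- control$bounds[[nms[i]]]
    if (log_scaled[[nms[i]]]) b <- log(b)
    v <- b[1] + stats::plogis(u[i]) * (b[2] - b[1])
    if (log_scaled[[nms[i]]]) v <- exp(v)
    v
  }, numeric(1))
  names(par) <- nms
  par
}

build_hp <- function(par, model, control) {
  fx <- control$fixed
  alpha <- if (model == "rational") par[["alpha"]] else control$alpha_exemplar
  hyperparams(alpha = alpha, a0 = par[["a0"]], b0 = fx$b0,
              eta0 = par[["eta0"]], mu0 = fx$mu0, lam = fx$lam,
              sigma_y = par[["sigma_y"]], n_colors = fx$n_colors)
}

#' Fit the rational or exemplar observer to one subject
#'
#' Minimizes the mean-squared error between the observer's trial-wise
#' particle-filter predictions and the subject's responses over the free
#' parameters, from multiple restarts of a bounded Nelder-Mead search on
#' transformed coordinates. The exemplar model runs the same machinery
#' with every trial forced into its own category and the concentration
#' parameter removed from the free set.
#'
#' @param trials one subject's trial data frame (columns as in
#'   [generate_session()], with responses).
#' @param model `"rational"` or `"exemplar"`.
#' @param control a [fit_control()] configuration.
#' @param seed optional integer seed for the restart draws.
#' @return An object of class `"observer_fit"` with components `model`,
#'   `coef` (free parameters), `hp` (full hyperparameters), `mse`, `n`
#'   (valid responded trials), `bic`, `offset`, `predictions` (raw-scale
#'   per-trial estimates), `n_categories_per_block`, `trials`, and
#'   `control`. Standard methods (`print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `simulate`, `plot`) apply.
#' @export
fit_observer <- function(trials, model = c("rational", "exemplar"),
                         control = fit_control(), seed = NULL) {
  model <- match.arg(model)
  if (length(unique(trials$subject_id)) > 1) {
    stop("'trials' must contain a single subject; fit subjects separately")
  }
  rc <- recenter_trials(trials)
  ctr <- rc$trials
  usable <- ctr$valid & !is.na(ctr$response)
  n <- sum(usable)
  if (n < 1) stop("no valid responded trials to fit")
  resp <- ctr$response[usable]
  nms <- free_param_names(model)
  force_new <- model == "exemplar"
  # the all-singletons filter is deterministic: one particle suffices
  np <- if (force_new) 1L else control$n_particles

  objective <- function(u) {
    par <- from_unconstrained(u, nms, control)
    hp <- build_hp(par, model, control)
    pred <- run_session(ctr, hp, n_particles = np,
                        seed = control$filter_seed, force_new = force_new)
    m <- mean((pred$estimate[usable] - resp)^2)
    if (!is.finite(m)) Inf else m
  }

  starts <- make_starts(nms, control, seed)
  best <- NULL
  for (s in starts) {
    u0 <- to_unconstrained(s, control)
    opt <- tryCatch(
      stats::optim(u0, objective, method = "Nelder-Mead",
                   control = list(maxit = control$maxit)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer restarts failed")

  par <- from_unconstrained(best$par, nms, control)
  hp <- build_hp(par, model, control)
  pred <- run_session(ctr, hp, n_particles = np,
                      seed = control$filter_seed, force_new = force_new)
  mse <- mean((pred$estimate[usable] - resp)^2)
  p <- length(nms)
  bic <- n * log(mse) + p * log(n)
  pred_raw <- pred
  pred_raw$estimate <- pred$estimate + rc$offset
  structure(list(model = model, coef = par, hp = hp, mse = mse, n = n,
                 bic = bic, offset = rc$offset, predictions = pred_raw,
                 n_categories_per_block = attr(pred, "block_modal_K"),
                 trials = trials, usable = usable, control = control),
            class = "observer_fit")
}

make_starts <- function(nms, control, seed) {
  mid <- list(alpha = 1, a0 = 4, eta0 = 1, sigma_y = 5)
  corner <- list(alpha = 1, a0 = 10, eta0 = 100, sigma_y = 30)
  starts <- list(mid[nms], corner[nms])
  extra <- max(0, control$restarts - 2)
  if (extra > 0) {
    rs <- with_seed(seed, lapply(seq_len(extra), function(i) {
      s <- lapply(nms, function(nm) {
        b <- control$bounds[[nm]]
        if (log_scaled[[nm]]) exp(stats::runif(1, log(b[1]), log(b[2])))
        else stats::runif(1, b[1], b[2])
      })
      names(s) <- nms
      s
    }))
    starts <- c(starts, rs)
  }
  starts[seq_len(max(1, control$restarts))]
}

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf("%s observer fit: %d trials, MSE = %.3f, BIC = %.2f\n",
              x$model, x$n, x$mse, x$bic))
  cat("Parameters:\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' @export
summary.observer_fit <- function(object, ...) {
  cat(sprintf("Fitted %s observer (subject %s)\n", object$model,
              object$trials$subject_id[1]))
  print(round(object$coef, 4))
  cat(sprintf("n = %d valid trials, offset = %.2f\n", object$n,
              object$offset))
  cat(sprintf("MSE = %.4f, RMSE = %.3f, BIC = %.3f\n", object$mse,
              sqrt(object$mse), object$bic))
  cat("Categories per block (modal, end of block):\n")
  print(object$n_categories_per_block)
  invisible(object)
}

#' @export
coef.observer_fit <- function(object, ...) object$coef

#' @export
fitted.observer_fit <- function(object, ...) object$predictions$estimate

#' @export
residuals.observer_fit <- function(object, ...) {
  r <- object$trials$response - object$predictions$estimate
  r[!object$usable] <- NA_real_
  r
}

#' Predict observer estimates for a trial stream
#'
#' Runs the fitted observer over `newdata` (recentered by that stream's
#' own mean true count, matching the fitting convention) and returns
#' raw-scale per-trial estimates.
#'
#' @param object an `observer_fit`.
#' @param newdata trial data frame; defaults to the fitted trials.
#' @param ... unused.
#' @return Numeric vector of per-trial estimates.
#' @export
predict.observer_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  rc <- recenter_trials(newdata)
  force_new <- object$model == "exemplar"
  pred <- run_session(rc$trials, object$hp,
                      n_particles = if (force_new) 1L else
                        object$control$n_particles,
                      seed = object$control$filter_seed,
                      force_new = force_new)
  pred$estimate + rc$offset
}

#' @export
simulate.observer_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    mu <- fitted(object)
    out <- as.data.frame(lapply(seq_len(nsim), function(i) {
      round(mu + stats::rnorm(length(mu), 0, sqrt(object$mse)))
    }))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' @export
plot.observer_fit <- function(x, ...) {
  ok <- x$usable
  plot(x$predictions$estimate[ok], x$trials$response[ok],
       xlab = "model estimate", ylab = "response",
       main = sprintf("%s observer fit", x$model), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Compare a rational and an exemplar fit of the same subject
#'
#' Uses the Bayesian information criterion approximation to the Bayes
#' factor: `BIC = n log(MSE) + p log(n)` (Gaussian plug-in likelihood,
#' shared constants dropped), and
#' `log BF = (BIC_exemplar - BIC_rational) / 2`. Positive values favor
#' the rational model.
#'
#' @param fit_rational,fit_exemplar `observer_fit` objects for the same
#'   trials.
#' @return A list of class `"model_comparison"`: `log_bf`,
#'   `bic_rational`, `bic_exemplar`, `mse_rational`, `mse_exemplar`,
#'   `n`.
#' @export
compare_models <- function(fit_rational, fit_exemplar) {
  stopifnot(inherits(fit_rational, "observer_fit"),
            inherits(fit_exemplar, "observer_fit"))
  if (fit_rational$model != "rational" || fit_exemplar$model != "exemplar") {
    stop("arguments must be a rational fit and an exemplar fit, in order")
  }
  if (fit_rational$n != fit_exemplar$n ||
      !identical(fit_rational$trials$true_count,
                 fit_exemplar$trials$true_count)) {
    stop("the two fits must be based on the same trials")
  }
  structure(list(log_bf = (fit_exemplar$bic - fit_rational$bic) / 2,
                 bic_rational = fit_rational$bic,
                 bic_exemplar = fit_exemplar$bic,
                 mse_rational = fit_rational$mse,
                 mse_exemplar = fit_exemplar$mse,
                 n = fit_rational$n),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("log Bayes factor (rational vs exemplar): %.3f\n", x$log_bf))
  cat(sprintf("  BIC rational %.2f (MSE %.3f) | BIC exemplar %.2f (MSE %.3f), n = %d\n",
              x$bic_rational, x$mse_rational, x$bic_exemplar,
              x$mse_exemplar, x$n))
  invisible(x)
}

#' Per-block inferred category counts
#'
#' The modal number of occupied categories across particles at the end
#' of each block, plus the subject-level median. For an exemplar fit
#' every entry equals the number of trials in the block.
#'
#' @param fit an `observer_fit`.
#' @return A list with `per_block` (integer vector) and `median`.
#' @export
count_categories <- function(fit) {
  stopifnot(inherits(fit, "observer_fit"))
  k <- fit$n_categories_per_block
  list(per_block = k, median = stats::median(k))
}

#' Group-level comparison of rational and exemplar fits
#'
#' @param fits_rational,fits_exemplar lists of `observer_fit` objects,
#'   one pair per subject.
#' @return A list of class `"group_comparison"`: per-subject `log_bf`,
#'   the Wilcoxon signed-rank `statistic` and `p_value` of the log Bayes
#'   factors against 0, and the `median_n_categories` preferred by the
#'   rational fits.
#' @export
compare_group <- function(fits_rational, fits_exemplar) {
  stopifnot(length(fits_rational) == length(fits_exemplar))
  log_bf <- mapply(function(r, e) compare_models(r, e)$log_bf,
                   fits_rational, fits_exemplar)
  sr <- signed_rank_test(log_bf)
  med_k <- stats::median(unlist(lapply(fits_rational,
                                       function(f) f$n_categories_per_block)))
  structure(list(log_bf = log_bf, statistic = sr$statistic,
                 p_value = sr$p_value, median_n_categories = med_k),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group model comparison over %d subjects\n", length(x$log_bf)))
  cat(sprintf("  median log BF (rational vs exemplar) = %.3f\n",
              stats::median(x$log_bf)))
  cat(sprintf("  Wilcoxon signed-rank V = %.1f, p = %.4g\n",
              x$statistic, x$p_value))
  cat(sprintf("  median inferred categories per block = %.1f\n",
              x$median_n_categories))
  invisible(x)
}
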