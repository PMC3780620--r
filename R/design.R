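## Experiment designs and trial-stream generation.
##
## Each experiment interleaves blocks of two conditions. Within a block,
## counts on "baseline" trials are drawn from one Gaussian and counts on
## "alternative" trials from another; each trial type is tagged by a
## distinct circle color. Counts are rounded to the nearest integer and
## truncated to [10, 100].

#' Construct one condition of an estimation experiment
#'
#' @param label condition name.
#' @param baseline_mean,baseline_sd Gaussian parameters of the baseline
#'   count distribution.
#' @param alt_mean,alt_sd Gaussian parameters of the alternative count
#'   distribution.
#' @param truncation length-2 bounds for validation.
#' @return A list of class `"condition_spec"`.
#' @export
condition_spec <- function(label, baseline_mean, baseline_sd,
                           alt_mean, alt_sd, truncation = c(10, 100)) {
  stopifnot(baseline_sd > 0, alt_sd > 0)
  if (baseline_mean < truncation[1] || baseline_mean > truncation[2] ||
      alt_mean < truncation[1] || alt_mean > truncation[2]) {
    stop("condition means must lie within the truncation bounds")
  }
  structure(list(label = label,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 alt_mean = alt_mean, alt_sd = alt_sd),
            class = "condition_spec")
}

#' Standard experiment designs
#'
#' Returns the design of one of the three two-condition estimation
#' experiments. All share the block structure: 8 blocks per condition,
#' 20 trials per block (10 baseline, 10 alternative, randomly
#' interleaved), counts truncated to [10, 100], 3 available colors.
#'
#' * `exp1` — baseline N(65, 10^2); alternatives N(55, 10^2) ("High mean
#'   alternative", high overlap) and N(35, 10^2) ("Low mean alternative",
#'   low overlap).
#' * `exp2` — baseline N(65, 20^2); alternatives at mean 35 with SD 20
#'   ("High variance", high overlap) and SD 10 ("Low variance").
#' * `exp3` — baseline N(50, 10^2); alternatives N(60, 10^2) ("Low mean
#'   alternative", high overlap) and N(80, 10^2) ("High mean
#'   alternative").
#'
#' @param experiment_id one of `"exp1"`, `"exp2"`, `"exp3"`.
#' @param overrides optional named list overriding design fields
#'   (`n_blocks_per_condition`, `trials_per_block`,
#'   `n_baseline_per_block`, `truncation`, `n_colors_total`,
#'   `conditions`), e.g. as read by [read_config()].
#' @return A list of class `"experiment_design"` with fields
#'   `experiment`, `conditions`, `n_blocks_per_condition`,
#'   `trials_per_block`, `n_baseline_per_block`, `truncation`,
#'   `n_colors_total`.
#' @examples
#' d <- make_design("exp1")
#' vapply(d$conditions, `[[`, numeric(1), "alt_mean")
#' @export
make_design <- function(experiment_id = c("exp1", "exp2", "exp3"),
                        overrides = NULL) {
  experiment_id <- match.arg(experiment_id)
  conditions <- switch(experiment_id,
    exp1 = list(
      condition_spec("high_mean_alt", 65, 10, 55, 10),
      condition_spec("low_mean_alt", 65, 10, 35, 10)),
    exp2 = list(
      condition_spec("high_var_alt", 65, 20, 35, 20),
      condition_spec("low_var_alt", 65, 20, 35, 10)),
    exp3 = list(
      condition_spec("low_mean_alt", 50, 10, 60, 10),
      condition_spec("high_mean_alt", 50, 10, 80, 10)))
  design <- structure(list(experiment = experiment_id,
                           conditions = conditions,
                           n_blocks_per_condition = 8L,
                           trials_per_block = 20L,
                           n_baseline_per_block = 10L,
                           truncation = c(10, 100),
                           n_colors_total = 3L),
                      class = "experiment_design")
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(design))
    if (length(unknown)) {
      stop("unknown design override(s): ", paste(unknown, collapse = ", "))
    }
    design[names(overrides)] <- overrides
  }
  if (design$n_baseline_per_block > design$trials_per_block) {
    stop("n_baseline_per_block must not exceed trials_per_block")
  }
  if (design$truncation[1] >= design$truncation[2]) {
    stop("truncation bounds must be increasing")
  }
  design
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Experiment design '%s': %d blocks/condition x %d trials (%d baseline)\n",
              x$experiment, x$n_blocks_per_condition, x$trials_per_block,
              x$n_baseline_per_block))
  for (cs in x$conditions) {
    cat(sprintf("  %-14s baseline N(%g, %g^2), alternative N(%g, %g^2)\n",
                cs$label, cs$baseline_mean, cs$baseline_sd,
                cs$alt_mean, cs$alt_sd))
  }
  invisible(x)
}

#' Draw stimulus counts from a truncated, rounded Gaussian
#'
#' Counts are Gaussian draws rounded to the nearest integer and
#' truncated to the design bounds. With `method = "clamp"` (default)
#' out-of-bounds draws are clamped to the nearest bound after rounding;
#' with `method = "resample"` they are redrawn until in bounds.
#'
#' @param n number of draws.
#' @param mean,sd Gaussian parameters (`sd > 0`).
#' @param truncation length-2 numeric bounds.
#' @param method truncation semantics, `"clamp"` or `"resample"`.
#' @return Integer vector of length `n`, all within bounds.
#' @export
draw_count <- function(n, mean, sd, truncation = c(10, 100),
                       method = c("clamp", "resample")) {
  method <- match.arg(method)
  stopifnot(sd > 0)
  lo <- truncation[1]; hi <- truncation[2]
  x <- round(stats::rnorm(n, mean, sd))
  if (method == "clamp") {
    x <- pmin(pmax(x, lo), hi)
  } else {
    bad <- which(x < lo | x > hi)
    while (length(bad)) {
      x[bad] <- round(stats::rnorm(length(bad), mean, sd))
      bad <- bad[x[bad] < lo | x[bad] > hi]
    }
  }
  as.integer(x)
}

#' Moments of the truncated, rounded count distribution
#'
#' Exact mean and standard deviation of [draw_count()] with
#' `method = "clamp"`, computed by summing the Gaussian mass assigned to
#' each integer in the truncation range (boundary integers absorb the
#' tails).
#'
#' @inheritParams draw_count
#' @return Named numeric vector with elements `mean` and `sd`.
#' @export
count_moments <- function(mean, sd, truncation = c(10, 100)) {
  lo <- truncation[1]; hi <- truncation[2]
  k <- lo:hi
  p <- stats::pnorm(k + 0.5, mean, sd) - stats::pnorm(k - 0.5, mean, sd)
  p[1] <- stats::pnorm(lo + 0.5, mean, sd)
  p[length(p)] <- 1 - stats::pnorm(hi - 0.5, mean, sd)
  m <- sum(k * p)
  v <- sum((k - m)^2 * p)
  c(mean = m, sd = sqrt(v))
}

#' Generate one subject's trial stream
#'
#' Builds the full session for a design: `n_blocks_per_condition` blocks
#' of each condition in a random order; within each block, baseline and
#' alternative trials randomly interleaved, each trial type tagged by
#' one of two distinct colors drawn without replacement from the
#' `n_colors_total` available colors. Counts are drawn per
#' [draw_count()]. Responses are left missing (`NA`) and all trials
#' marked valid.
#'
#' @param design an [make_design()] design.
#' @param subject_id subject identifier.
#' @param seed optional integer seed for reproducibility.
#' @param truncation_method passed to [draw_count()].
#' @return A data frame with one row per trial and columns `subject_id`,
#'   `experiment`, `block_index`, `condition_label`,
#'   `trial_index_in_block`, `trial_type`, `color`, `true_count`,
#'   `response`, `valid`.
#' @examples
#' trials <- generate_session(make_design("exp1"), "s01", seed = 1)
#' nrow(trials)  # 16 blocks x 20 trials
#' @export
generate_session <- function(design, subject_id, seed = NULL,
                             truncation_method = c("clamp", "resample")) {
  stopifnot(inherits(design, "experiment_design"))
  truncation_method <- match.arg(truncation_method)
  with_seed(seed, {
    cond_labels <- vapply(design$conditions, `[[`, character(1), "label")
    block_conds <- sample(rep(seq_along(design$conditions),
                              design$n_blocks_per_condition))
    blocks <- lapply(seq_along(block_conds), function(b) {
      cs <- design$conditions[[block_conds[b]]]
      npb <- design$trials_per_block
      nb <- design$n_baseline_per_block
      type <- sample(c(rep("baseline", nb), rep("alternative", npb - nb)))
      cols <- sample(design$n_colors_total, 2L)
      x_base <- draw_count(nb, cs$baseline_mean, cs$baseline_sd,
                           design$truncation, truncation_method)
      x_alt <- draw_count(npb - nb, cs$alt_mean, cs$alt_sd,
                          design$truncation, truncation_method)
      x <- integer(npb)
      x[type == "baseline"] <- x_base
      x[type == "alternative"] <- x_alt
      data.frame(subject_id = as.character(subject_id),
                 experiment = design$experiment,
                 block_index = b,
                 condition_label = cs$label,
                 trial_index_in_block = seq_len(npb),
                 trial_type = type,
                 color = ifelse(type == "baseline", cols[1], cols[2]),
                 true_count = x,
                 response = NA_integer_,
                 valid = TRUE,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, blocks)
  })
}

## Run code with a temporary RNG state when seed is given.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

## Deterministic seed splitting: derive a stream seed from a master seed
## and a label, keeping the result within 32-bit integer range.
split_seed <- function(seed, label) {
  if (is.null(seed)) return(NULL)
  ch <- utf8ToInt(as.character(label))
  h <- sum(ch * 31^((seq_along(ch) - 1) %% 5))
  as.integer((as.double(seed) * 7919 + h) %% 2147483647)
}
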