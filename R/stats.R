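## Behavioral statistics battery: subject exclusion, condition means,
## paired and one-sample t-tests with Cohen's d, Fisher-z sequential
## correlations, and the Wilcoxon signed-rank test. Applicable
## identically to human or simulated response tables.

usable_rows <- function(trials) trials$valid & !is.na(trials$response)

## alternative-condition true mean per (experiment, condition_label)
alt_mean_lookup <- function(trials, designs = NULL) {
  if (is.null(designs)) {
    ids <- unique(trials$experiment)
    designs <- lapply(ids, make_design)
    names(designs) <- ids
  }
  out <- list()
  for (id in names(designs)) {
    for (cs in designs[[id]]$conditions) {
      out[[paste(id, cs$label, sep = "|")]] <-
        c(alt = cs$alt_mean, base = cs$baseline_mean)
    }
  }
  out
}

#' Exclude subjects with outlying estimation errors
#'
#' Per subject, computes the mean absolute distance of responses from
#' the alternative condition's true mean over valid alternative trials,
#' pooling trials across all supplied experiments; subjects whose error
#' exceeds the across-subject mean by more than two across-subject
#' standard deviations are excluded. With zero spread across subjects,
#' nobody is excluded.
#'
#' @param trials pooled trial data frame (possibly several experiments).
#' @param designs optional named list of designs (by experiment id);
#'   defaults to [make_design()] on the experiment ids present.
#' @return A list with `kept` and `excluded` subject ids and the
#'   per-subject `errors`.
#' @export
exclude_subjects <- function(trials, designs = NULL) {
  subs <- sort(unique(trials$subject_id))
  if (length(subs) < 3) {
    stop("at least 3 subjects are required for the exclusion rule")
  }
  lut <- alt_mean_lookup(trials, designs)
  rows <- usable_rows(trials) & trials$trial_type == "alternative"
  key <- paste(trials$experiment, trials$condition_label, sep = "|")
  err_trial <- abs(trials$response -
                     vapply(key, function(k) lut[[k]][["alt"]], numeric(1)))
  errors <- vapply(subs, function(s) {
    i <- rows & trials$subject_id == s
    mean(err_trial[i])
  }, numeric(1))
  names(errors) <- subs
  cut <- mean(errors) + 2 * stats::sd(errors)
  excluded <- subs[errors > cut]
  list(kept = setdiff(subs, excluded), excluded = excluded,
       errors = errors)
}

#' Per-subject and group condition means
#'
#' Computes each subject's mean response over valid trials of the given
#' type and condition, then the group mean and standard error over
#' subjects (subjects, not pooled trials, are the unit of analysis).
#'
#' @param trials trial data frame.
#' @param trial_type `"baseline"` or `"alternative"`.
#' @param condition condition label (`NULL` = all conditions pooled).
#' @return A list with `subject_means` (named vector), `mean`, `sem`,
#'   `n`.
#' @export
condition_means <- function(trials, trial_type = "baseline",
                            condition = NULL) {
  rows <- usable_rows(trials) & trials$trial_type == trial_type
  if (!is.null(condition)) rows <- rows & trials$condition_label == condition
  if (!any(rows)) stop("no valid responded trials in the requested cell")
  sm <- tapply(trials$response[rows], trials$subject_id[rows], mean)
  sm <- sm[order(names(sm))]
  n <- length(sm)
  sem <- if (n > 1) stats::sd(sm) / sqrt(n) else {
    warning("single subject: SEM reported as 0")
    0
  }
  list(subject_means = sm, mean = mean(sm), sem = sem, n = n)
}

#' Paired t-test with Cohen's d
#'
#' Standard two-sided paired t-test; the effect size is
#' `d = mean(diff) / sd(diff)` (equivalently `t / sqrt(n)`).
#'
#' @param a,b equal-length paired vectors of subject-level scores.
#' @return A list with `t`, `df`, `p`, `d`, `mean_diff`.
#' @export
paired_tests <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    stop("zero-variance differences: paired t-test undefined")
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = mean(d) / stats::sd(d), mean_diff = mean(d))
}

#' One-sample t-test with Cohen's d
#'
#' @param x vector of subject-level scores.
#' @param mu null value (e.g. the true condition mean).
#' @return A list with `t`, `df`, `p`, `d`, `mean`.
#' @export
one_sample_test <- function(x, mu = 0) {
  stopifnot(length(x) >= 2)
  if (stats::sd(x) == 0) stop("zero-variance sample: t-test undefined")
  tt <- stats::t.test(x, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = (mean(x) - mu) / stats::sd(x), mean = mean(x))
}

#' Sequential correlations between trial types
#'
#' For each subject and condition, pairs every trial of the target type
#' with the most recent preceding trial of the other type within the
#' same block (which may lie several trials back; pairs never cross
#' block boundaries, and the first trials of a block with no preceding
#' other-type trial are skipped). Computes the Pearson correlation of
#' the paired responses per subject, Fisher z-transforms it
#' (`z = atanh(r)`), and tests the subject-level z values against 0 with
#' a one-sample t-test per condition.
#'
#' @param trials trial data frame.
#' @param direction `"alt_to_base"` (baseline trials paired with the
#'   preceding alternative trial) or `"base_to_alt"`.
#' @param min_pairs minimum usable pairs per subject and condition;
#'   subjects below it are dropped with a warning.
#' @return A list of per-condition results, each with `z` (named
#'   per-subject vector), `t`, `df`, `p`, `d`, `n`.
#' @export
sequential_correlations <- function(trials,
                                    direction = c("alt_to_base",
                                                  "base_to_alt"),
                                    min_pairs = 3) {
  direction <- match.arg(direction)
  target <- if (direction == "alt_to_base") "baseline" else "alternative"
  other <- setdiff(c("baseline", "alternative"), target)
  ord <- order(trials$subject_id, trials$block_index,
               trials$trial_index_in_block)
  trials <- trials[ord, ]
  conds <- sort(unique(trials$condition_label))
  out <- list()
  for (cond in conds) {
    zs <- c()
    for (s in sort(unique(trials$subject_id))) {
      tt <- trials[trials$subject_id == s &
                     trials$condition_label == cond, ]
      pairs_x <- c(); pairs_y <- c()
      for (b in unique(tt$block_index)) {
        bb <- tt[tt$block_index == b, ]
        last_other <- NA_real_
        for (i in seq_len(nrow(bb))) {
          ok <- bb$valid[i] && !is.na(bb$response[i])
          if (bb$trial_type[i] == target) {
            if (ok && !is.na(last_other)) {
              pairs_x <- c(pairs_x, last_other)
              pairs_y <- c(pairs_y, bb$response[i])
            }
          } else if (ok) {
            last_other <- bb$response[i]
          }
        }
      }
      if (length(pairs_y) < min_pairs) {
        warning(sprintf("subject %s dropped in condition %s: %d pairs",
                        s, cond, length(pairs_y)))
        next
      }
      r <- suppressWarnings(stats::cor(pairs_x, pairs_y))
      if (is.na(r)) next
      r <- min(max(r, -1 + 1e-12), 1 - 1e-12)
      zs[s] <- atanh(r)
    }
    res <- if (length(zs) >= 2 && stats::sd(zs) > 0) {
      one_sample_test(zs, 0)
    } else {
      list(t = NA_real_, df = NA_real_, p = NA_real_, d = NA_real_,
           mean = if (length(zs)) mean(zs) else NA_real_)
    }
    out[[cond]] <- c(list(z = zs, n = length(zs)), res)
  }
  out
}

#' Wilcoxon signed-rank test against zero
#'
#' Two-sided signed-rank test; zeros are dropped and ties handled by
#' the standard normal approximation with continuity correction (exact
#' distribution when there are no ties).
#'
#' @param x numeric vector (e.g. per-subject log Bayes factors), at
#'   least 5 values.
#' @return A list with `statistic` (V) and `p_value`.
#' @export
signed_rank_test <- function(x) {
  if (length(x) < 5) stop("signed-rank test requires at least 5 values")
  wt <- suppressWarnings(stats::wilcox.test(x, mu = 0, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Full behavioral statistics report for one experiment
#'
#' Runs the whole battery on one experiment's trial table: per-condition
#' baseline and alternative means (subject-level), the paired t-test
#' comparing baseline estimates between conditions, one-sample t-tests
#' of each cell against its true generating mean, and the Fisher-z
#' sequential correlations in both directions.
#'
#' @param trials one experiment's trial data frame.
#' @param design the experiment design (defaults to
#'   `make_design(experiment id in the table)`).
#' @return A list of class `"stats_report"`.
#' @export
analyze_experiment <- function(trials, design = NULL) {
  expid <- unique(trials$experiment)
  if (length(expid) != 1) {
    stop("'trials' mixes experiments; analyze one experiment at a time ",
         "or subset first")
  }
  if (is.null(design)) design <- make_design(expid)
  conds <- vapply(design$conditions, `[[`, character(1), "label")
  cell <- function(type, cond) condition_means(trials, type, cond)
  baseline <- lapply(conds, function(cc) cell("baseline", cc))
  alternative <- lapply(conds, function(cc) cell("alternative", cc))
  names(baseline) <- names(alternative) <- conds
  common <- Reduce(intersect, lapply(baseline, function(x)
    names(x$subject_means)))
  paired <- paired_tests(baseline[[1]]$subject_means[common],
                         baseline[[2]]$subject_means[common])
  vs_true <- lapply(conds, function(cc) {
    cs <- design$conditions[[match(cc, conds)]]
    list(baseline = one_sample_test(baseline[[cc]]$subject_means,
                                    cs$baseline_mean),
         alternative = one_sample_test(alternative[[cc]]$subject_means,
                                       cs$alt_mean))
  })
  names(vs_true) <- conds
  structure(list(experiment = expid,
                 conditions = conds,
                 baseline = baseline,
                 alternative = alternative,
                 paired_baseline = paired,
                 vs_true = vs_true,
                 seq_alt_to_base = sequential_correlations(trials,
                                                           "alt_to_base"),
                 seq_base_to_alt = sequential_correlations(trials,
                                                           "base_to_alt")),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("Behavioral statistics: %s (%d subjects)\n", x$experiment,
              x$baseline[[1]]$n))
  for (cc in x$conditions) {
    cat(sprintf("  %-14s baseline mean %.2f (SEM %.2f) | alternative mean %.2f (SEM %.2f)\n",
                cc, x$baseline[[cc]]$mean, x$baseline[[cc]]$sem,
                x$alternative[[cc]]$mean, x$alternative[[cc]]$sem))
  }
  p <- x$paired_baseline
  cat(sprintf("  paired t (baseline %s vs %s): t(%d) = %.2f, p = %.4f, d = %.2f\n",
              x$conditions[1], x$conditions[2], p$df, p$t, p$p, p$d))
  for (cc in x$conditions) {
    v <- x$vs_true[[cc]]$baseline
    cat(sprintf("  baseline vs true (%s): t(%d) = %.2f, p = %.4f, d = %.2f\n",
                cc, v$df, v$t, v$p, v$d))
  }
  for (cc in names(x$seq_alt_to_base)) {
    s <- x$seq_alt_to_base[[cc]]
    cat(sprintf("  seq corr alt->base (%s): mean z = %.3f, t = %.2f, p = %.4f\n",
                cc, mean(s$z), s$t, s$p))
  }
  invisible(x)
}
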