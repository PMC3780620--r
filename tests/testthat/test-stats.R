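# Behavioral statistics battery against closed-form and permutation
# oracles.

make_table <- function(subjects, trials_per_subject = 8,
                       experiment = "exp1", seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(subjects, function(s) {
    n <- trials_per_subject
    data.frame(subject_id = s, experiment = experiment,
               block_index = rep(1:2, each = n / 2),
               condition_label = "high_mean_alt",
               trial_index_in_block = rep(seq_len(n / 2), 2),
               trial_type = rep(c("baseline", "alternative"),
                                length.out = n),
               color = rep(c(1L, 2L), length.out = n),
               true_count = sample(40:90, n, TRUE),
               response = sample(40:90, n, TRUE),
               valid = TRUE, stringsAsFactors = FALSE)
  }))
}

test_that("paired t-test and Cohen's d match the closed form", {
  diffs <- c(1, 1, 1, 2)
  b <- rnorm(4)
  res <- paired_tests(b + diffs, b)
  n <- 4
  t_hand <- mean(diffs) / (sd(diffs) / sqrt(n))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, n - 1)
  expect_equal(res$p, 2 * pt(-abs(t_hand), n - 1), tolerance = 1e-12)
  expect_equal(res$d, mean(diffs) / sd(diffs), tolerance = 1e-12)
  expect_equal(res$d, res$t / sqrt(n), tolerance = 1e-12)
  # sign flip flips t, keeps p
  flip <- paired_tests(b, b + diffs)
  expect_equal(flip$t, -res$t)
  expect_equal(flip$p, res$p)
  expect_error(paired_tests(b, b), "zero-variance")
})

test_that("one-sample test matches the closed form", {
  x <- c(2.2, 3.8, 1.4, 5.0, 2.6)
  res <- one_sample_test(x, mu = 2)
  expect_equal(res$t, (mean(x) - 2) / (sd(x) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$d, (mean(x) - 2) / sd(x), tolerance = 1e-12)
})

test_that("condition means average subjects, not pooled trials", {
  tab <- make_table(c("a", "b"), trials_per_subject = 8, seed = 2)
  # unbalance: drop half of subject b's baseline trials
  drop <- which(tab$subject_id == "b" & tab$trial_type == "baseline")[1:2]
  tab$valid[drop] <- FALSE
  tab$response[drop] <- NA
  cm <- condition_means(tab, "baseline", "high_mean_alt")
  ok <- tab$valid & tab$trial_type == "baseline"
  by_subj <- tapply(tab$response[ok], tab$subject_id[ok], mean)
  expect_equal(unname(cm$subject_means), unname(by_subj[c("a", "b")]))
  expect_equal(cm$mean, mean(by_subj))
  expect_false(isTRUE(all.equal(cm$mean, mean(tab$response[ok]))))
  expect_warning(condition_means(tab[tab$subject_id == "a", ],
                                 "baseline"), "single subject")
  expect_error(condition_means(tab, "baseline", "no_such"), "no valid")
})

test_that("statistics are invariant to row order", {
  tab <- simulate_experiment(
    "exp1", 5, responder_prototype(noise_sd = 4), seed = 7,
    design = make_design("exp1",
                         overrides = list(n_blocks_per_condition = 2L)))
  set.seed(4)
  perm <- sample(nrow(tab))
  a <- analyze_experiment(tab)
  b <- analyze_experiment(tab[perm, ])
  expect_equal(b$baseline[[1]]$mean, a$baseline[[1]]$mean)
  expect_equal(b$paired_baseline$t, a$paired_baseline$t)
  expect_equal(b$seq_alt_to_base[[1]]$t, a$seq_alt_to_base[[1]]$t)
})

test_that("sequential pairing uses the most recent other-type trial and
           never crosses blocks", {
  # hand-built table: one subject, two blocks
  tab <- data.frame(
    subject_id = "s", experiment = "exp1",
    block_index = c(1, 1, 1, 1, 1, 2, 2, 2),
    condition_label = "high_mean_alt",
    trial_index_in_block = c(1:5, 1:3),
    trial_type = c("baseline", "alternative", "alternative", "baseline",
                   "baseline", "baseline", "alternative", "baseline"),
    color = 1L,
    true_count = 50L,
    response = c(60L, 40L, 42L, 61L, 59L, 63L, 45L, 62L),
    valid = TRUE, stringsAsFactors = FALSE)
  # pairs alt->base: block 1: (42,61), (42,59); block 2: (45,62);
  # block-initial baselines (resp 60, 63) have no preceding alternative
  got <- sequential_correlations(tab, "alt_to_base", min_pairs = 3)
  r_hand <- cor(c(42, 42, 45), c(61, 59, 62))
  expect_equal(unname(got$high_mean_alt$z["s"]), atanh(r_hand),
               tolerance = 1e-12)
  # direction base->alt: pairs (60,40),(60,42) in block 1, (63,45) block 2
  got2 <- sequential_correlations(tab, "base_to_alt", min_pairs = 3)
  expect_equal(unname(got2$high_mean_alt$z["s"]),
               atanh(cor(c(60, 60, 63), c(40, 42, 45))), tolerance = 1e-12)
  # subjects with too few pairs are dropped with a warning
  expect_warning(sequential_correlations(tab, "alt_to_base",
                                         min_pairs = 5), "dropped")
})

test_that("shared within-block drift yields positive group z", {
  set.seed(12)
  tabs <- lapply(sprintf("s%02d", 1:12), function(s) {
    tab <- make_table(s, 20, seed = sample.int(1e6, 1))
    for (b in unique(tab$block_index)) {
      i <- tab$block_index == b
      drift <- cumsum(rnorm(sum(i), 0, 6))
      tab$response[i] <- round(60 + drift + rnorm(sum(i), 0, 2))
    }
    tab
  })
  tab <- do.call(rbind, tabs)
  res <- sequential_correlations(tab, "alt_to_base")$high_mean_alt
  expect_gt(res$t, 2)
  expect_lt(res$p, 0.05)
  expect_gt(mean(res$z), 0)
})

test_that("signed-rank test matches an exact sign-flip permutation oracle", {
  perm_oracle <- function(x) {
    x <- x[x != 0]
    n <- length(x)
    r <- rank(abs(x))
    v_obs <- sum(r[x > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- signs %*% r
    mean(abs(v_all - n * (n + 1) / 4) >= abs(v_obs - n * (n + 1) / 4) - 1e-9)
  }
  set.seed(21)
  for (i in 1:20) {
    x <- round(rnorm(14, sample(c(-0.5, 0, 0.6), 1), 1), 3)
    got <- signed_rank_test(x)
    expect_lt(abs(got$p_value - perm_oracle(x)), 0.02)
  }
  # symmetric values: p near 1; all-positive: minimal statistic side
  sym <- c(-3, -2, -1, 1, 2, 3)
  expect_gt(signed_rank_test(sym)$p_value, 0.8)
  pos <- c(1, 2, 3, 4, 5, 6)
  expect_lt(signed_rank_test(pos)$p_value, 0.05)
  expect_error(signed_rank_test(c(1, 2)), "at least 5")
})

test_that("subject exclusion flags only outlying estimation error", {
  # accurate simulated subjects plus one uniform-random responder
  set.seed(31)
  subs <- sprintf("s%02d", 1:8)
  tab <- do.call(rbind, lapply(subs, function(s) {
    d <- make_design("exp1",
                     overrides = list(n_blocks_per_condition = 2L))
    tr <- generate_session(d, s, seed = match(s, subs))
    tr$response <- as.integer(pmin(pmax(
      round(tr$true_count + rnorm(nrow(tr), 0, 3)), 10), 99))
    tr
  }))
  bad <- tab$subject_id == "s08"
  tab$response[bad] <- sample(10:99, sum(bad), TRUE)
  res <- exclude_subjects(tab)
  expect_equal(res$excluded, "s08")
  expect_equal(sort(res$kept), sprintf("s%02d", 1:7))
  # invariance to row order
  res2 <- exclude_subjects(tab[rev(seq_len(nrow(tab))), ])
  expect_equal(res2$excluded, res$excluded)
  # identical errors: nobody excluded
  tab$response <- as.integer(tab$true_count + 5L)
  tab$response <- pmin(tab$response, 99L)
  expect_length(exclude_subjects(tab)$excluded, 0)
  expect_error(exclude_subjects(tab[tab$subject_id %in% c("s01", "s02"), ]),
               "3 subjects")
})

test_that("the full battery runs on a simulated cohort with the
           regularization signature", {
  trials <- simulate_experiment(
    "exp1", 8, responder_ideal(n_particles = 100), seed = 5)
  rep <- analyze_experiment(trials)
  expect_s3_class(rep, "stats_report")
  expect_output(print(rep), "paired t")
  expect_true(is.finite(rep$paired_baseline$t))
  expect_equal(rep$baseline[[1]]$n, 8)
  # alternative-trial estimates track the generating means broadly
  expect_lt(abs(rep$alternative[["low_mean_alt"]]$mean - 35), 8)
  expect_lt(abs(rep$alternative[["high_mean_alt"]]$mean - 55), 8)
})
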