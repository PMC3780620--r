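# Partition enumeration, the particle filter and the estimator,
# checked against each other and against analytic limits.

test_that("enumeration covers all partitions and normalizes", {
  hp <- default_hp()
  ep1 <- enumerate_posterior(5, 1L, hp)
  expect_equal(length(ep1$partitions), 1L)
  expect_equal(ep1$prob, 1)
  ep3 <- enumerate_posterior(c(-4, 0, 6), c(1L, 2L, 1L), hp)
  expect_equal(length(ep3$partitions), 5L)  # Bell(3)
  expect_equal(sum(ep3$prob), 1, tolerance = 1e-12)
  expect_equal(length(enumerate_posterior(rnorm(5), rep(1L, 5),
                                          hp)$partitions), 52L)  # Bell(5)
  expect_error(enumerate_posterior(rnorm(13), rep(1L, 13), hp), "12")
})

test_that("extreme concentrations force all-singletons or one category", {
  x <- c(-8, 1, 7, 3)
  cl <- c(1L, 2L, 3L, 1L)
  hi <- enumerate_posterior(x, cl, default_hp(alpha = 1e10))
  top <- hi$partitions[[which.max(hi$prob)]]
  expect_equal(top, 1:4)
  expect_gt(max(hi$prob), 0.999)
  lo <- enumerate_posterior(x, cl, default_hp(alpha = 1e-12))
  expect_equal(lo$partitions[[which.max(lo$prob)]], rep(1L, 4))
  expect_gt(max(lo$prob), 0.999)
})

test_that("particle filter tracks the enumeration oracle", {
  # expected category count and per-trial estimates within Monte-Carlo
  # error of the exact values on random 6-trial streams
  set.seed(31)
  for (rep in 1:5) {
    x <- round(rnorm(6, 0, 12))
    cl <- sample(3, 6, replace = TRUE)
    hp <- default_hp(alpha = runif(1, 0.2, 2),
                     eta0 = runif(1, 0.1, 1))
    ex <- enumerate_predictions(x, cl, hp)
    tr <- one_block_trials(x, cl)
    reps <- vapply(1:4, function(s) {
      p <- run_session(tr, hp, n_particles = 4000, seed = s)
      c(p$estimate, p$expected_n_categories[6])
    }, numeric(7))
    mu <- rowMeans(reps)
    se <- apply(reps, 1, sd) / sqrt(ncol(reps)) + 1e-4
    expect_true(all(abs(mu[1:6] - ex$estimate) < 4 * se[1:6]))
    expect_lt(abs(mu[7] - ex$expected_K), 4 * se[7])
  }
})

test_that("R and compiled engines implement the same filter", {
  set.seed(13)
  x <- round(rnorm(8, 0, 12))
  cl <- sample(3, 8, replace = TRUE)
  hp <- default_hp(alpha = 0.8)
  tr <- one_block_trials(x, cl)
  ex <- enumerate_predictions(x, cl, hp)
  pr <- run_session(tr, hp, n_particles = 3000, seed = 2, engine = "r")
  pc <- run_session(tr, hp, n_particles = 3000, seed = 2, engine = "cpp")
  expect_equal(pr$estimate, ex$estimate, tolerance = 0.02)
  expect_equal(pc$estimate, ex$estimate, tolerance = 0.02)
  expect_equal(pr$expected_n_categories[8], ex$expected_K, tolerance = 0.05)
  expect_equal(pc$expected_n_categories[8], ex$expected_K, tolerance = 0.05)
})

test_that("merging limit matches the single-category conjugate model", {
  hp <- default_hp(alpha = 1e-8, eta0 = 0.5)
  d <- make_design("exp1", overrides = list(n_blocks_per_condition = 1L))
  tr <- generate_session(d, "s", seed = 2)
  tr$true_count <- tr$true_count - mean(tr$true_count)
  p <- run_session(tr, hp, n_particles = 30, seed = 1)
  single <- numeric(nrow(tr))
  st <- empty_stats(hp$n_colors)
  for (t in seq_len(nrow(tr))) {
    if (t > 1 && tr$block_index[t] != tr$block_index[t - 1]) {
      st <- empty_stats(hp$n_colors)
    }
    pp <- posterior_params(st, hp)
    df <- 2 * pp$a
    v <- if (df > 2) pp$beta * df / (df - 2) else pp$beta
    y <- tr$true_count[t]
    single[t] <- (hp$sigma_y^2 * pp$mu_hat + v * y) / (v + hp$sigma_y^2)
    st <- update_stats(st, y, tr$color[t])
  }
  expect_equal(p$estimate, single, tolerance = 1e-6)
  expect_true(all(attr(p, "block_modal_K") == 1))
})

test_that("exemplar limit: huge alpha reproduces forced singletons", {
  hp <- default_hp(alpha = 1e8, eta0 = 0.5)
  d <- make_design("exp1", overrides = list(n_blocks_per_condition = 1L))
  tr <- generate_session(d, "s", seed = 5)
  tr$true_count <- tr$true_count - mean(tr$true_count)
  rational <- run_session(tr, hp, n_particles = 200, seed = 3)
  exemplar <- run_session(tr, hp, n_particles = 1, seed = 4,
                          force_new = TRUE)
  expect_equal(rational$estimate, exemplar$estimate, tolerance = 1e-4)
  expect_true(all(attr(exemplar, "block_modal_K") == 20))
})

test_that("sensory-noise limits bracket the estimate", {
  hp0 <- default_hp(sigma_y = 1e-9)
  ps <- init_particles(10, hp0)
  step <- particle_filter_step(ps, x = 4, color = 2L)
  expect_equal(step$prediction$estimate, 4, tolerance = 1e-6)
  ps <- step$particles
  expect_equal(estimate_count(ps, y = -7, color = 1L)$estimate, -7,
               tolerance = 1e-6)
  # uninformative signal: estimate ignores y
  hpI <- default_hp(sigma_y = 1e9, eta0 = 1)
  psI <- init_particles(5, hpI)
  psI <- particle_filter_step(psI, x = 10, color = 1L)$particles
  e1 <- estimate_count(psI, y = -50, color = 1L)$estimate
  e2 <- estimate_count(psI, y = 50, color = 1L)$estimate
  expect_equal(e1, e2, tolerance = 1e-4)
})

test_that("the estimate is a convex combination of component means", {
  set.seed(77)
  for (i in 1:40) {
    hp <- default_hp(alpha = runif(1, 0, 3), sigma_y = runif(1, 1, 15),
                     eta0 = runif(1, 0.05, 2))
    ps <- init_particles(3, hp)
    for (t in seq_len(sample(1:6, 1))) {
      ps <- particle_filter_step(ps, rnorm(1, 0, 12),
                                 sample(3, 1))$particles
    }
    y <- rnorm(1, 0, 20)
    pred <- estimate_count(ps, y, sample(3, 1))
    mus <- unlist(lapply(ps$particles, function(p) {
      c(vapply(p$cats, function(st) posterior_params(st, hp)$mu_hat,
               numeric(1)),
        posterior_params(empty_stats(hp$n_colors), hp)$mu_hat)
    }))
    lo <- min(mus, y); hi <- max(mus, y)
    expect_gte(pred$estimate, lo - 1e-8)
    expect_lte(pred$estimate, hi + 1e-8)
    expect_equal(sum(pred$category_post), 1, tolerance = 1e-8)
  }
})

test_that("session driver enforces ordering, resets and determinism", {
  hp <- default_hp()
  d <- make_design("exp1", overrides = list(n_blocks_per_condition = 2L))
  tr <- generate_session(d, "s", seed = 7)
  expect_error(run_session(tr[rev(seq_len(nrow(tr))), ], hp, 10),
               "sorted")
  p1 <- run_session(tr, hp, n_particles = 100, seed = 5)
  p2 <- run_session(tr, hp, n_particles = 100, seed = 5)
  expect_identical(p1$estimate, p2$estimate)
  # with per-block resets, block predictions ignore earlier blocks
  b4 <- tr[tr$block_index == 4, ]
  p4 <- run_session(b4, hp, n_particles = 100, seed = 5)
  expect_equal(p1$estimate[tr$block_index == 4], p4$estimate,
               tolerance = 1e-9)
  # empty session
  p0 <- run_session(tr[0, ], hp, 10)
  expect_equal(nrow(p0), 0L)
})

test_that("constant streams drive predictions to the stimulus value", {
  # prior mean 0, stimulus fixed at 65: predictions approach 65 as the
  # category accumulates evidence
  hp <- default_hp(eta0 = 0.2)
  tr <- one_block_trials(rep(65, 20), rep(1L, 20))
  p <- run_session(tr, hp, n_particles = 200, seed = 1)
  expect_lt(abs(p$estimate[20] - 65), abs(p$estimate[2] - 65))
  expect_lt(abs(p$estimate[20] - 65), 1)
})

test_that("higher-overlap alternatives regularize baseline estimates more", {
  # the qualitative signature on the first design: baseline predictions
  # sit lower when the alternative distribution overlaps the baseline
  hp <- hyperparams()
  d <- make_design("exp1")
  pull <- c(high_mean_alt = 0, low_mean_alt = 0)
  nrep <- 150  # sessions; 8 blocks per condition each
  for (rep in 1:nrep) {
    tr <- generate_session(d, "s", seed = 400 + rep)
    tr$true_count <- tr$true_count - mean(tr$true_count)
    p <- run_session(tr, hp, n_particles = 200, seed = rep)
    b <- tr$trial_type == "baseline"
    for (cc in names(pull)) {
      i <- b & tr$condition_label == cc
      pull[cc] <- pull[cc] + mean(p$estimate[i] - tr$true_count[i]) / nrep
    }
  }
  expect_lt(pull["high_mean_alt"], pull["low_mean_alt"])
})
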