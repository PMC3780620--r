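## Posterior inference over partitions and trial-wise count estimates.
##
## Three routes with identical probability kernels:
##  * enumerate_posterior()/enumerate_predictions(): exact sums over all
##    set partitions, feasible for a handful of trials; the oracle.
##  * particle_filter_step()/estimate_count(): pure-R Rao-Blackwellized
##    sequential importance resampling on an explicit particle list.
##  * run_session(): full-session driver; its default engine is the
##    compiled filter in src/filter.cpp, with engine = "r" running the
##    reference implementation step by step.
##
## Pre-feedback estimates marginalize the sensory signal by moment-
## matching each category's Student-t count predictive to a Gaussian
## (variance = scale^2 * dof/(dof - 2), falling back to scale^2 when
## dof <= 2), which makes the estimate a closed-form mixture of
## precision-weighted combinations of category means and the signal.

## Per-category prediction ingredients shared by every route.
category_components <- function(stats, color, y, hp, prior_p) {
  pp <- posterior_params(stats, hp)
  df <- 2 * pp$a
  v <- if (df > 2) pp$beta * df / (df - 2) else pp$beta
  sy2 <- hp$sigma_y^2
  colp <- color_predictive(stats, color, hp)
  list(
    w = prior_p * colp * stats::dnorm(y, pp$mu_hat, sqrt(v + sy2)),
    m = (sy2 * pp$mu_hat + v * y) / (v + sy2),
    g = prior_p * colp * exp(count_predictive_logpdf(y, stats, hp))
  )
}

## Candidate-category weights for one particle (or one partition).
## Returns per-candidate prediction weight w, component mean m, and
## feedback weight g(x) evaluated at x (if given).
candidate_table <- function(cats, color, y, x, hp) {
  sizes <- vapply(cats, `[[`, numeric(1), "M")
  prior <- crp_prior(sizes, hp$alpha)  # length K+1 (last = new)
  K <- length(cats)
  all_cats <- c(cats, list(empty_stats(hp$n_colors)))
  w <- m <- g <- numeric(K + 1)
  sy2 <- hp$sigma_y^2
  for (k in seq_len(K + 1)) {
    st <- all_cats[[k]]
    pp <- posterior_params(st, hp)
    df <- 2 * pp$a
    v <- if (df > 2) pp$beta * df / (df - 2) else pp$beta
    colp <- color_predictive(st, color, hp)
    w[k] <- prior[k] * colp * stats::dnorm(y, pp$mu_hat, sqrt(v + sy2))
    m[k] <- (sy2 * pp$mu_hat + v * y) / (v + sy2)
    if (!is.null(x)) {
      g[k] <- prior[k] * colp * exp(count_predictive_logpdf(x, st, hp))
    }
  }
  list(w = w, m = m, g = g)
}

#' Initialize a particle set
#'
#' @param n_particles number of particles.
#' @param hp a [hyperparams()] object.
#' @return A list of class `"particle_set"` whose `particles` element
#'   holds, per particle, the assignment history `assign`, the list of
#'   per-category statistics `cats`, and a `log_w` importance weight.
#' @export
init_particles <- function(n_particles, hp) {
  one <- list(assign = integer(0), cats = list(), log_w = 0)
  structure(list(hp = hp,
                 particles = rep(list(one), n_particles)),
            class = "particle_set")
}

particle_weights <- function(ps) {
  lw <- vapply(ps$particles, `[[`, numeric(1), "log_w")
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Bayes estimate of the current count from a particle set
#'
#' Forms the pre-feedback posterior-mean estimate of the true count
#' given the sensory signal `y` and trial color: for every particle and
#' every candidate category (occupied plus new), weights combine the CRP
#' seating prior, the color predictive, and the marginal density of `y`
#' under the moment-matched count predictive convolved with sensory
#' noise; component means are precision-weighted combinations of the
#' category predictive mean and `y`.
#'
#' @param particles a [init_particles()] particle set.
#' @param y sensory signal (finite numeric).
#' @param color trial color.
#' @param hp hyperparameters (defaults to the set's own).
#' @return A list of class `"trial_prediction"`: `estimate`,
#'   `category_post` (candidate posterior aggregated over particles by
#'   category creation order, last entry = new category), and
#'   `expected_n_categories` (current, pre-feedback).
#' @export
estimate_count <- function(particles, y, color, hp = particles$hp) {
  stopifnot(inherits(particles, "particle_set"), is.finite(y))
  W <- particle_weights(particles)
  kmax <- max(vapply(particles$particles, function(p) length(p$cats), integer(1)))
  post <- numeric(kmax + 1)
  est <- 0
  for (i in seq_along(particles$particles)) {
    p <- particles$particles[[i]]
    tab <- candidate_table(p$cats, color, y, NULL, hp)
    wk <- tab$w
    tot <- sum(wk)
    if (tot <= 0) {
      pred <- y
      wk[] <- 0
      wk[length(wk)] <- 1
    } else {
      wk <- wk / tot
      pred <- sum(wk * tab$m)
    }
    est <- est + W[i] * pred
    idx <- c(seq_along(p$cats), kmax + 1)  # align 'new' to last slot
    post[idx] <- post[idx] + W[i] * wk
  }
  structure(list(estimate = est, category_post = post,
                 expected_n_categories = sum(W * vapply(
                   particles$particles, function(p) length(p$cats),
                   integer(1)))),
            class = "trial_prediction")
}

#' One particle-filter step
#'
#' Computes the pre-feedback prediction from `(y, color)` via
#' [estimate_count()], then (if feedback `x` is supplied) lets every
#' particle sample its assignment for the trial from the conditional
#' posterior, reweights particles by the marginal likelihood of
#' `(x, color)`, and applies systematic resampling when the effective
#' sample size falls below half the particle count.
#'
#' @param particles a [init_particles()] particle set.
#' @param x observed true count (feedback), or `NULL` for a
#'   prediction-only step.
#' @param color trial color.
#' @param y sensory signal; defaults to `x`.
#' @param force_new force the assignment to a new category (the
#'   exemplar, all-singletons limit).
#' @return A list with elements `particles` (updated set) and
#'   `prediction` (the pre-feedback `"trial_prediction"`).
#' @export
particle_filter_step <- function(particles, x, color, y = x,
                                 force_new = FALSE) {
  hp <- particles$hp
  prediction <- estimate_count(particles, y, color, hp)
  if (is.null(x)) {
    return(list(particles = particles, prediction = prediction))
  }
  for (i in seq_along(particles$particles)) {
    p <- particles$particles[[i]]
    tab <- candidate_table(p$cats, color, y, x, hp)
    g <- tab$g
    tot <- sum(g)
    K <- length(p$cats)
    if (force_new) {
      z <- K + 1L
    } else if (tot <= 0) {
      z <- K + 1L
      tot <- 1e-300
    } else {
      z <- sample.int(K + 1L, 1L, prob = g)
    }
    p$log_w <- p$log_w + log(tot)
    if (z > K) p$cats[[z]] <- empty_stats(hp$n_colors)
    p$cats[[z]] <- update_stats(p$cats[[z]], x, color)
    p$assign <- c(p$assign, z)
    particles$particles[[i]] <- p
  }
  W <- particle_weights(particles)
  if (1 / sum(W^2) < length(W) / 2 && length(W) > 1) {
    idx <- systematic_resample(W)
    particles$particles <- lapply(particles$particles[idx], function(p) {
      p$log_w <- 0
      p
    })
  }
  list(particles = particles, prediction = prediction)
}

systematic_resample <- function(W) {
  n <- length(W)
  u <- (stats::runif(1) + seq_len(n) - 1) / n
  findInterval(u, cumsum(W), left.open = TRUE) + 1L
}

#' Run the observer over a full session of trials
#'
#' Applies the particle filter trial by trial in presentation order with
#' the sensory signal pinned to the true count (`y_t = x_t`), resetting
#' the particle set (fresh prior beliefs) at block boundaries by
#' default.
#'
#' @param trials trial data frame as produced by [generate_session()]
#'   (columns `block_index`, `trial_index_in_block`, `color`,
#'   `true_count` are used).
#' @param hp a [hyperparams()] object.
#' @param n_particles number of particles.
#' @param seed optional integer seed.
#' @param reset_per_block reset beliefs at block boundaries (default
#'   `TRUE`).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation via [particle_filter_step()]).
#' @param force_new all-singletons (exemplar) assignment.
#' @return A data frame with one row per trial: `estimate`,
#'   `expected_n_categories`, `map_n_categories`, plus the trial key
#'   columns of `trials`. Per-block modal category counts at block end
#'   are attached as attribute `"block_modal_K"`.
#' @export
run_session <- function(trials, hp, n_particles = 1000, seed = NULL,
                        reset_per_block = TRUE,
                        engine = c("cpp", "r"), force_new = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(hp, "numbayes_hp"))
  if (nrow(trials) == 0) {
    out <- trials[, intersect(c("subject_id", "block_index",
                                "trial_index_in_block"), names(trials)),
                  drop = FALSE]
    out$estimate <- numeric(0)
    out$expected_n_categories <- numeric(0)
    out$map_n_categories <- numeric(0)
    attr(out, "block_modal_K") <- numeric(0)
    return(out)
  }
  ord <- order(trials$block_index, trials$trial_index_in_block)
  if (any(ord != seq_len(nrow(trials)))) {
    stop("'trials' must be sorted by presentation order ",
         "(block_index, trial_index_in_block)")
  }
  with_seed(seed, {
    if (engine == "cpp") {
      res <- .filter_session_cpp(as.numeric(trials$true_count),
                                 as.integer(trials$color),
                                 as.integer(trials$block_index),
                                 unclass(hp), as.integer(n_particles),
                                 reset_per_block, force_new)
      est <- res$estimate
      ek <- res$expected_n_categories
      mk <- res$map_n_categories
      bmk <- res$block_end_modal_K
    } else {
      T <- nrow(trials)
      est <- ek <- mk <- numeric(T)
      bmk <- numeric(0)
      ps <- init_particles(n_particles, hp)
      for (t in seq_len(T)) {
        if (t > 1 && reset_per_block &&
            trials$block_index[t] != trials$block_index[t - 1]) {
          ps <- init_particles(n_particles, hp)
        }
        step <- particle_filter_step(ps, trials$true_count[t],
                                     trials$color[t],
                                     force_new = force_new)
        ps <- step$particles
        est[t] <- step$prediction$estimate
        W <- particle_weights(ps)
        Ks <- vapply(ps$particles, function(p) length(p$cats), integer(1))
        ek[t] <- sum(W * Ks)
        tab <- tapply(W, Ks, sum)
        mk[t] <- as.numeric(names(tab)[which.max(tab)])
        if (t == T || trials$block_index[t + 1] != trials$block_index[t]) {
          bmk <- c(bmk, mk[t])
        }
      }
    }
    keep <- intersect(c("subject_id", "experiment", "block_index",
                        "condition_label", "trial_index_in_block",
                        "trial_type"), names(trials))
    out <- cbind(trials[, keep, drop = FALSE],
                 data.frame(estimate = est,
                            expected_n_categories = ek,
                            map_n_categories = mk))
    attr(out, "block_modal_K") <- as.numeric(bmk)
    out
  })
}

## ---- exact enumeration -------------------------------------------------

## All restricted growth strings of length t (canonical set partitions).
rgs_partitions <- function(t) {
  if (t == 0) return(list(integer(0)))
  out <- list(integer(0))
  for (i in seq_len(t)) {
    nxt <- list()
    for (z in out) {
      kmax <- if (length(z)) max(z) else 0L
      for (k in seq_len(kmax + 1L)) nxt[[length(nxt) + 1L]] <- c(z, k)
    }
    out <- nxt
  }
  out
}

#' Exact posterior over set partitions of a short trial sequence
#'
#' Computes, by explicit enumeration of all set partitions (guarded to
#' at most 12 trials), the posterior probability of every partition of
#' the observed `(count, color)` pairs under the CRP mixture: the CRP
#' prior of the partition times each category's exchangeable joint
#' predictive of its members.
#'
#' @param x numeric vector of observed counts.
#' @param color integer vector of colors.
#' @param hp a [hyperparams()] object.
#' @return A list of class `"partition_posterior"`: `partitions` (list
#'   of assignment vectors in restricted-growth form), `log_weight`,
#'   `prob` (normalized), `expected_K`.
#' @export
enumerate_posterior <- function(x, color, hp) {
  t <- length(x)
  stopifnot(length(color) == t)
  if (t > 12) stop("exact enumeration limited to 12 trials (Bell growth)")
  parts <- rgs_partitions(t)
  lw <- vapply(parts, function(z) partition_logweight(z, x, color, hp),
               numeric(1))
  pr <- exp(lw - max(lw))
  pr <- pr / sum(pr)
  structure(list(partitions = parts, log_weight = lw, prob = pr,
                 expected_K = sum(pr * vapply(parts, max, numeric(1)))),
            class = "partition_posterior")
}

partition_logweight <- function(z, x, color, hp) {
  cats <- list()
  lp <- 0
  for (i in seq_along(z)) {
    sizes <- vapply(cats, `[[`, numeric(1), "M")
    prior <- crp_prior(sizes, hp$alpha)
    k <- z[i]
    if (k > length(cats)) cats[[k]] <- empty_stats(hp$n_colors)
    pk <- prior[min(k, length(prior))]
    if (pk <= 0) return(-Inf)
    lp <- lp + log(pk) +
      log(color_predictive(cats[[k]], color[i], hp)) +
      count_predictive_logpdf(x[i], cats[[k]], hp)
    cats[[k]] <- update_stats(cats[[k]], x[i], color[i])
  }
  lp
}

#' Exact per-trial predictions by partition enumeration
#'
#' For each trial `t`, marginalizes the pre-feedback estimate over the
#' exact posterior on partitions of trials `1..t-1`, using the same
#' per-category prediction components as the particle filter. The
#' brute-force counterpart of [run_session()] for short sequences
#' (single block; no resets).
#'
#' @inheritParams enumerate_posterior
#' @return A list with `estimate` (per-trial exact estimates) and
#'   `expected_K` (exact posterior expected number of categories after
#'   all trials).
#' @export
enumerate_predictions <- function(x, color, hp) {
  t <- length(x)
  if (t > 12) stop("exact enumeration limited to 12 trials (Bell growth)")
  est <- numeric(t)
  for (i in seq_len(t)) {
    if (i == 1) {
      tab <- candidate_table(list(), color[i], x[i], NULL, hp)
      est[i] <- sum(tab$w * tab$m) / sum(tab$w)
      next
    }
    post <- enumerate_posterior(x[seq_len(i - 1)], color[seq_len(i - 1)], hp)
    num <- 0
    for (j in seq_along(post$partitions)) {
      if (post$prob[j] == 0) next
      cats <- stats_from_partition(post$partitions[[j]],
                                   x[seq_len(i - 1)],
                                   color[seq_len(i - 1)], hp)
      tab <- candidate_table(cats, color[i], x[i], NULL, hp)
      num <- num + post$prob[j] * sum(tab$w * tab$m) / sum(tab$w)
    }
    est[i] <- num
  }
  final <- enumerate_posterior(x, color, hp)
  list(estimate = est, expected_K = final$expected_K)
}

stats_from_partition <- function(z, x, color, hp) {
  cats <- list()
  for (i in seq_along(z)) {
    k <- z[i]
    if (k > length(cats)) cats[[k]] <- empty_stats(hp$n_colors)
    cats[[k]] <- update_stats(cats[[k]], x[i], color[i])
  }
  cats
}
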