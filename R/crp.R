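## Conjugate probability kernel for the CRP mixture observer:
## CRP prior over partitions, Dirichlet-multinomial color predictive,
## and normal-inverse-gamma Student-t count predictive with incremental
## sufficient statistics.

#' Observer hyperparameters
#'
#' Bundles the prior and noise parameters of the ideal observer. The
#' count dimension of each latent category carries a normal-inverse-gamma
#' prior on its mean and variance: `mu0` and `eta0` (a pseudo-count) set
#' the prior on the category mean, `a0` and `b0` the inverse-gamma
#' shape/scale on the category variance. Colors follow a symmetric
#' Dirichlet prior with parameter `lam` over `n_colors` colors. `alpha`
#' is the Chinese restaurant process concentration (larger values favor
#' more categories; `alpha -> Inf` is the exemplar limit) and `sigma_y`
#' the sensory noise standard deviation.
#'
#' Defaults mirror the fitting convention used throughout the package:
#' responses and counts are recentered per subject so `mu0 = 0`, and
#' `lam = 1`, `b0 = 10` are held fixed. The remaining defaults describe
#' a representative observer: a modest simplicity bias (`alpha = 0.5`),
#' a weak prior on the category mean (`eta0 = 0.05`, which with
#' `a0 = 4`, `b0 = 10` gives a fresh-category predictive spanning the
#' plausible recentered count range, SD about 14), and moderate sensory
#' noise (`sigma_y = 5`).
#'
#' @param alpha CRP concentration, `>= 0`.
#' @param a0 inverse-gamma shape parameter, `> 0`. The predictive for an
#'   empty category is Student-t with `a0` degrees of freedom.
#' @param b0 inverse-gamma scale parameter, `> 0`; sets the prior scale
#'   of the category variance.
#' @param eta0 prior pseudo-count on the category mean, `> 0`.
#' @param mu0 prior category mean.
#' @param lam symmetric Dirichlet parameter for the color distribution.
#' @param sigma_y sensory noise standard deviation, `> 0`.
#' @param n_colors number of distinct colors `C` (at least 2).
#' @return An object of class `"numbayes_hp"`: a named list of the
#'   validated parameters.
#' @examples
#' hp <- hyperparams(alpha = 1, a0 = 4, sigma_y = 5)
#' hp$alpha
#' @export
hyperparams <- function(alpha = 0.5, a0 = 4, b0 = 10, eta0 = 0.05,
                        mu0 = 0, lam = 1, sigma_y = 5, n_colors = 3) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (alpha < 0) stop("'alpha' must be non-negative")
  if (a0 <= 0) stop("'a0' must be positive")
  if (b0 <= 0) stop("'b0' must be positive")
  if (eta0 <= 0) stop("'eta0' must be positive")
  if (lam <= 0) stop("'lam' must be positive")
  if (sigma_y <= 0) stop("'sigma_y' must be positive")
  n_colors <- as.integer(n_colors)
  if (n_colors < 2L) stop("'n_colors' must be at least 2")
  structure(list(alpha = alpha, a0 = a0, b0 = b0, eta0 = eta0,
                 mu0 = mu0, lam = lam, sigma_y = sigma_y,
                 n_colors = n_colors),
            class = "numbayes_hp")
}

#' @export
print.numbayes_hp <- function(x, ...) {
  cat("Observer hyperparameters:\n")
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

#' Serialize hyperparameters to/from JSON
#'
#' @param hp a [hyperparams()] object.
#' @param path file path; for `hp_from_json`, a path or JSON string.
#' @return `hp_to_json` invisibly returns `path`; `hp_from_json` returns
#'   a `"numbayes_hp"` object.
#' @export
hp_to_json <- function(hp, path) {
  stopifnot(inherits(hp, "numbayes_hp"))
  jsonlite::write_json(unclass(hp), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname hp_to_json
#' @export
hp_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  do.call(hyperparams, x)
}

#' Empty per-category sufficient statistics
#'
#' A category's state is fully summarized by the number of member trials
#' `M`, per-color co-occurrence counts `N_c`, the running mean of member
#' counts `mean_x`, and the running sum of squared deviations `sse_x`.
#'
#' @param n_colors number of colors.
#' @return A list of class `"category_stats"`.
#' @export
empty_stats <- function(n_colors = 3) {
  structure(list(M = 0L, N_c = integer(n_colors), mean_x = 0, sse_x = 0),
            class = "category_stats")
}

#' Add or remove one observation from category statistics
#'
#' Welford one-pass recurrences, exactly reversible: `downdate_stats`
#' after `update_stats` with the same observation restores the prior
#' state (up to floating-point rounding of the running moments).
#'
#' @param stats a [empty_stats()] object.
#' @param x observed count (possibly recentered).
#' @param color integer color index in `1..n_colors`.
#' @return Updated `"category_stats"`.
#' @export
update_stats <- function(stats, x, color) {
  color <- as.integer(color)
  if (color < 1L || color > length(stats$N_c)) {
    stop("'color' out of range")
  }
  M <- stats$M + 1L
  delta <- x - stats$mean_x
  mean_x <- stats$mean_x + delta / M
  sse_x <- stats$sse_x + delta * (x - mean_x)
  stats$M <- M
  stats$N_c[color] <- stats$N_c[color] + 1L
  stats$mean_x <- mean_x
  stats$sse_x <- sse_x
  stats
}

#' @rdname update_stats
#' @export
downdate_stats <- function(stats, x, color) {
  color <- as.integer(color)
  if (stats$M == 0L) stop("cannot downdate empty category statistics")
  if (stats$N_c[color] == 0L) {
    stop("no observation of this color was added to the category")
  }
  M <- stats$M - 1L
  if (M == 0L) {
    out <- empty_stats(length(stats$N_c))
    return(out)
  }
  mean_x <- (stats$M * stats$mean_x - x) / M
  sse_x <- stats$sse_x - (x - mean_x) * (x - stats$mean_x)
  stats$M <- M
  stats$N_c[color] <- stats$N_c[color] - 1L
  stats$mean_x <- mean_x
  stats$sse_x <- max(sse_x, 0)
  stats
}

#' Chinese restaurant process seating probabilities
#'
#' Probability that the next trial joins each existing category or opens
#' a new one: an occupied category of size `M_k` is chosen with
#' probability `M_k / (t - 1 + alpha)` and a new category with
#' probability `alpha / (t - 1 + alpha)`, where `t - 1` is the number of
#' trials seated so far. The first trial opens the first category with
#' probability 1.
#'
#' @param category_sizes integer vector of occupied-category sizes (may
#'   be empty).
#' @param alpha concentration parameter, `>= 0`.
#' @return Probability vector of length `length(category_sizes) + 1`;
#'   the last entry is the new-category probability.
#' @examples
#' crp_prior(c(3), alpha = 1)    # 3/4, 1/4
#' crp_prior(integer(0), 2)      # first trial: 1
#' @export
crp_prior <- function(category_sizes, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0) {
    stop("'alpha' must be a single non-negative number")
  }
  if (length(category_sizes) == 0L) return(1)
  if (any(category_sizes < 1)) stop("category sizes must be >= 1")
  tm1 <- sum(category_sizes)
  c(category_sizes, alpha) / (tm1 + alpha)
}

#' Dirichlet-multinomial color predictive
#'
#' Posterior predictive probability that a category emits a given color:
#' `(lam + N_ck) / (C * lam + M_k)`. Sums to one over colors.
#'
#' @param stats category statistics.
#' @param color integer color in `1..n_colors`.
#' @param hp a [hyperparams()] object.
#' @return A probability.
#' @export
color_predictive <- function(stats, color, hp) {
  color <- as.integer(color)
  C <- hp$n_colors
  if (color < 1L || color > C) stop("'color' out of range")
  (hp$lam + stats$N_c[color]) / (C * hp$lam + stats$M)
}

#' Posterior normal-inverse-gamma parameters of a category
#'
#' Updates the prior `(mu0, eta0, a0, b0)` with the category's
#' sufficient statistics:
#' `eta = M + eta0`, `mu_hat = (eta0*mu0 + M*mean_x)/eta`,
#' `a = (M + a0)/2`,
#' `b = b0 + sse_x/2 + M*eta0*(mu0 - mean_x)^2/(2*eta)`,
#' and the squared predictive scale `beta = b*(1 + eta)/(a*eta)`.
#' The posterior predictive for a new member count is Student-t with
#' `2a` degrees of freedom, location `mu_hat` and scale `sqrt(beta)`.
#'
#' @inheritParams color_predictive
#' @return A list with elements `mu_hat`, `eta`, `a`, `b`, `beta`.
#' @export
posterior_params <- function(stats, hp) {
  M <- stats$M
  eta <- M + hp$eta0
  mu_hat <- (hp$eta0 * hp$mu0 + M * stats$mean_x) / eta
  a <- (M + hp$a0) / 2
  b <- hp$b0 + stats$sse_x / 2 +
    M * hp$eta0 * (hp$mu0 - stats$mean_x)^2 / (2 * eta)
  list(mu_hat = mu_hat, eta = eta, a = a, b = b,
       beta = b * (1 + eta) / (a * eta))
}

#' Student-t posterior predictive log-density for a count
#'
#' Log density of the category's posterior predictive at `x`: Student-t
#' with `2a_k` degrees of freedom, location `mu_hat_k` and scale
#' `sqrt(beta_k)` (see [posterior_params()]).
#'
#' @param x count value (finite numeric).
#' @inheritParams color_predictive
#' @return Log density at `x`.
#' @export
count_predictive_logpdf <- function(x, stats, hp) {
  if (!all(is.finite(x))) stop("'x' must be finite")
  pp <- posterior_params(stats, hp)
  s <- sqrt(pp$beta)
  stats::dt((x - pp$mu_hat) / s, df = 2 * pp$a, log = TRUE) - log(s)
}

## Joint log-predictive of a set of (x, color) observations assigned to
## one category, computed sequentially. Exchangeable: order-invariant.
joint_logpred_one_category <- function(x, color, hp) {
  st <- empty_stats(hp$n_colors)
  lp <- 0
  for (i in seq_along(x)) {
    lp <- lp + log(color_predictive(st, color[i], hp)) +
      count_predictive_logpdf(x[i], st, hp)
    st <- update_stats(st, x[i], color[i])
  }
  lp
}
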