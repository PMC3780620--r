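## Simulated responders. Every responder answers trial by trial in
## presentation order, learning only from feedback (the true count) on
## earlier trials, exactly as a participant would.

#' Responder specifications
#'
#' Construct a responder for [simulate_responses()]:
#'
#' * `responder_ideal()` — the rational CRP-mixture ideal observer: its
#'   response on each trial is the particle-filter estimate (see
#'   [run_session()]) plus Gaussian response noise.
#' * `responder_exemplar()` — the all-singletons (exemplar) limit of the
#'   same observer: every trial occupies its own category.
#' * `responder_prototype()` — color-prototype baseline: responds with
#'   the running mean of previous same-color true counts in the current
#'   block (falling back to the session running mean, then to the
#'   midpoint of the count range).
#' * `responder_global_mean()` — responds with the running mean of all
#'   previous true counts in the session (midpoint of the count range on
#'   the first trial).
#'
#' The observer-based responders operate on the recentered scale used
#' for model fitting when `recenter = TRUE` (counts shifted by the
#' session mean so the prior mean `mu0 = 0` refers to a typical count);
#' responses are shifted back before being returned.
#'
#' @param hp observer [hyperparams()].
#' @param noise_sd response-noise standard deviation.
#' @param n_particles particles for the observer-based responders.
#' @param recenter run the observer on session-mean-centered counts.
#' @param clamp clamp responses to the two-digit range `[10, 99]`
#'   mirroring the keyboard interface; set `FALSE` to disable.
#' @return A list of class `"responder"`.
#' @export
responder_ideal <- function(hp = hyperparams(), noise_sd = 2,
                            n_particles = 1000, recenter = TRUE,
                            clamp = TRUE) {
  structure(list(kind = "ideal_observer", hp = hp, noise_sd = noise_sd,
                 n_particles = n_particles, recenter = recenter,
                 clamp = clamp, force_new = FALSE),
            class = "responder")
}

#' @rdname responder_ideal
#' @export
responder_exemplar <- function(hp = hyperparams(alpha = 1e8), noise_sd = 2,
                               recenter = TRUE, clamp = TRUE) {
  structure(list(kind = "exemplar", hp = hp, noise_sd = noise_sd,
                 n_particles = 1, recenter = recenter,
                 clamp = clamp, force_new = TRUE),
            class = "responder")
}

#' @rdname responder_ideal
#' @export
responder_prototype <- function(noise_sd = 0, clamp = TRUE) {
  structure(list(kind = "color_prototype", noise_sd = noise_sd,
                 clamp = clamp),
            class = "responder")
}

#' @rdname responder_ideal
#' @export
responder_global_mean <- function(noise_sd = 0, clamp = TRUE) {
  structure(list(kind = "global_mean", noise_sd = noise_sd,
                 clamp = clamp),
            class = "responder")
}

#' Fill in a responder's estimates for a trial stream
#'
#' Computes block-sequential responses (feedback = the true count) for
#' every valid trial and returns the trial table with the `response`
#' column filled. Deterministic given `seed`.
#'
#' @param trials trial data frame from [generate_session()].
#' @param responder a responder from [responder_ideal()] and friends.
#' @param seed optional integer seed.
#' @return The trial data frame with integer responses.
#' @export
simulate_responses <- function(trials, responder, seed = NULL) {
  if (!inherits(responder, "responder")) {
    stop("'responder' must be a responder specification; see ?responder_ideal")
  }
  with_seed(seed, {
    est <- switch(responder$kind,
      ideal_observer = ,
      exemplar = {
        offset <- if (isTRUE(responder$recenter)) {
          mean(trials$true_count)
        } else 0
        centered <- trials
        centered$true_count <- trials$true_count - offset
        pred <- run_session(centered, responder$hp,
                            n_particles = responder$n_particles,
                            force_new = responder$force_new)
        pred$estimate + offset
      },
      color_prototype = prototype_estimates(trials),
      global_mean = global_mean_estimates(trials),
      stop("unknown responder kind: ", responder$kind))
    if (responder$noise_sd > 0) {
      est <- est + stats::rnorm(nrow(trials), 0, responder$noise_sd)
    }
    resp <- round(est)
    if (isTRUE(responder$clamp)) resp <- pmin(pmax(resp, 10), 99)
    trials$response <- ifelse(trials$valid, as.integer(resp), NA_integer_)
    trials
  })
}

## Running mean of previous same-color counts within the block.
prototype_estimates <- function(trials) {
  n <- nrow(trials)
  est <- numeric(n)
  global_sum <- 0; global_n <- 0
  block_sums <- NULL
  for (t in seq_len(n)) {
    if (t == 1 || trials$block_index[t] != trials$block_index[t - 1]) {
      block_sums <- list()
    }
    key <- as.character(trials$color[t])
    if (!is.null(block_sums[[key]])) {
      est[t] <- block_sums[[key]][1] / block_sums[[key]][2]
    } else if (global_n > 0) {
      est[t] <- global_sum / global_n
    } else {
      est[t] <- 55
    }
    prev <- block_sums[[key]]
    if (is.null(prev)) prev <- c(0, 0)
    block_sums[[key]] <- prev + c(trials$true_count[t], 1)
    global_sum <- global_sum + trials$true_count[t]
    global_n <- global_n + 1
  }
  est
}

global_mean_estimates <- function(trials) {
  n <- nrow(trials)
  x <- trials$true_count
  csum <- cumsum(x)
  est <- c(55, csum[-n] / seq_len(n - 1))
  est
}
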