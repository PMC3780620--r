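# Shared fixtures: small trial tables and random category statistics.

default_hp <- function(...) {
  args <- utils::modifyList(list(alpha = 1, a0 = 4, b0 = 10, eta0 = 1,
                                 mu0 = 0, lam = 1, sigma_y = 5,
                                 n_colors = 3), list(...))
  do.call(hyperparams, args)
}

# Random category statistics built from actual observations, so the
# incremental and batch views agree by construction.
random_stats <- function(n, hp = default_hp(), sd = 10) {
  st <- empty_stats(hp$n_colors)
  xs <- rnorm(n, 0, sd)
  cs <- sample(hp$n_colors, n, replace = TRUE)
  for (i in seq_len(n)) st <- update_stats(st, xs[i], cs[i])
  list(stats = st, x = xs, color = cs)
}

# Minimal single-block trial table.
one_block_trials <- function(x, color, block = 1L, subject = "s1") {
  data.frame(subject_id = subject, experiment = "exp1",
             block_index = as.integer(block), condition_label = "c",
             trial_index_in_block = seq_along(x),
             trial_type = "baseline", color = as.integer(color),
             true_count = x, response = NA_integer_, valid = TRUE,
             stringsAsFactors = FALSE)
}
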