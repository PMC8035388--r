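# Shared fixtures, built in code and cached per test run.

# small study: 4 participants x 2 days x 6 one-minute blocks
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- task_config(block_duration = 60, n_blocks = 6)
      cache <<- simulate_study(4, config = cfg, seed = 42)
    }
    cache
  }
})

small_dataset <- function() {
  st <- small_study()
  new_dataset(st$events, st$drt, st$snapshots)
}

# hand-built DRT log with controlled omission rates per difficulty
drt_log_with_rates <- function(pid, day, rates, n_per_cond = 20) {
  difficulty <- c(3, 5, 7)
  do.call(rbind, lapply(seq_along(difficulty), function(i) {
    n_om <- round(rates[i] * n_per_cond)
    data.frame(participant_id = pid, day = day, block = i,
               difficulty = difficulty[i],
               prompt_t = seq(4, by = 4, length.out = n_per_cond),
               rt_ms = ifelse(seq_len(n_per_cond) <= n_om, NA, 400),
               omission = as.integer(seq_len(n_per_cond) <= n_om))
  }))
}

# plain LMM-style frame with known structure for model oracles
toy_model_frame <- function(n_per = 50, n_participants = 6, seed = 99,
                            sigma = 0.2, tau = 0) {
  set.seed(seed)
  d <- expand.grid(trial = seq_len(n_per),
                   participant_id = sprintf("S%d", seq_len(n_participants)))
  d$x <- rnorm(nrow(d))
  u <- rnorm(n_participants, 0, tau)
  names(u) <- sprintf("S%d", seq_len(n_participants))
  d$rt_ms <- exp(6 + 0.1 * d$x + u[d$participant_id] +
                   rnorm(nrow(d), 0, sigma))
  d$omission <- rbinom(nrow(d), 1, 0.2)
  d
}
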