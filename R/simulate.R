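# Headless simulator of the UAV-refuelling task plus DRT.
#
# The scientific contract is the task dynamics (5%/s fuel drain, 25% refuel
# zone, spawn/refuel ranges, payoffs, 3-5 s uniform DRT prompts); the
# operator is a parametric noisy-memory agent. Internally the simulator is
# event-driven on a fixed 0.1 s tick: operator action times are drawn as
# geometric inter-tick gaps (equivalent to a per-tick Bernoulli process),
# fuel trajectories are piecewise linear between state changes, and crash
# times are solved analytically. step_dynamics() implements the literal
# per-tick physics for unit-level reasoning about the dynamics.

TICK <- 0.1

ceil_tick <- function(t) ceiling(t / TICK - 1e-9) * TICK

#' Pseudo-random difficulty schedule
#'
#' Draws the block difficulty sequence: every consecutive non-overlapping
#' triple of blocks is a random permutation of the easy (3 UAV), medium
#' (5 UAV) and hard (7 UAV) conditions.
#'
#' @param n_blocks number of blocks; must be divisible by 3.
#' @param seed integer seed; the same seed always yields the same schedule.
#' @return integer vector of length `n_blocks` with values in {3, 5, 7}.
#' @examples
#' draw_block_schedule(21, seed = 1)
#' @export
draw_block_schedule <- function(n_blocks, seed) {
  if (n_blocks %% 3 != 0)
    stop("n_blocks must be divisible by 3")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  as.integer(unlist(lapply(seq_len(n_blocks / 3),
                           function(i) sample(c(3L, 5L, 7L)))))
}

#' Initialise simulator state
#'
#' @param config a [task_config()].
#' @return a `sim_state` list: clock, per-UAV position/heading/fuel/
#'   hovered-before flag, cumulative score.
#' @export
new_sim_state <- function(config) {
  n <- config$n_uavs
  structure(list(
    clock = 0,
    x = runif(n, 0, config$screen[1]),
    y = runif(n, 0, config$screen[2]),
    heading = runif(n, 0, 2 * pi),
    fuel = runif(n, config$spawn_fuel_range[1], config$spawn_fuel_range[2]),
    hovered = rep(FALSE, n),
    uav_id = seq_len(n),
    next_id = n + 1L,
    score = 0,
    events = NULL
  ), class = "sim_state")
}

# Reflect coordinates into [0, L] (triangle-wave folding), flipping the
# direction cosine where an odd number of reflections occurred.
reflect_axis <- function(z, L) {
  m <- z %% (2 * L)
  flip <- m > L
  m[flip] <- 2 * L - m[flip]
  list(pos = m, flipped = flip)
}

#' Advance the task physics by one step
#'
#' Moves every UAV `uav_speed * dt` pixels along its heading, reflecting at
#' the screen boundaries; drains fuel by `fuel_drain_rate * dt`; any UAV
#' whose tank empties emits a Miss Refuel (MR) event and is immediately
#' replaced by a fresh UAV with spawn-range fuel and random heading.
#'
#' @param state a `sim_state`.
#' @param dt step length in seconds (> 0).
#' @param config a [task_config()].
#' @return the advanced `sim_state`; newly emitted MR events are appended to
#'   `state$events` (data frame: t, event_type, uav_id, fuel_at_event,
#'   points) and reflected in `state$score`.
#' @export
step_dynamics <- function(state, dt, config) {
  stopifnot(dt > 0)
  n <- config$n_uavs
  dx <- reflect_axis(state$x + cos(state$heading) * config$uav_speed * dt,
                     config$screen[1])
  dy <- reflect_axis(state$y + sin(state$heading) * config$uav_speed * dt,
                     config$screen[2])
  state$x <- dx$pos
  state$y <- dy$pos
  # reflection flips the relevant direction component
  h <- state$heading
  cosh_ <- ifelse(dx$flipped, -cos(h), cos(h))
  sinh_ <- ifelse(dy$flipped, -sin(h), sin(h))
  state$heading <- atan2(sinh_, cosh_)
  state$fuel <- state$fuel - config$fuel_drain_rate * dt
  state$clock <- state$clock + dt
  crashed <- which(state$fuel <= 0)
  if (length(crashed)) {
    ev <- data.frame(
      t = rep(state$clock, length(crashed)),
      event_type = rep("MR", length(crashed)),
      uav_id = state$uav_id[crashed],
      fuel_at_event = rep(0, length(crashed)),
      points = rep(unname(config$payoffs[["MR"]]), length(crashed))
    )
    state$events <- rbind(state$events, ev)
    state$score <- state$score + sum(ev$points)
    k <- length(crashed)
    state$fuel[crashed] <- runif(k, config$spawn_fuel_range[1],
                                 config$spawn_fuel_range[2])
    state$x[crashed] <- runif(k, 0, config$screen[1])
    state$y[crashed] <- runif(k, 0, config$screen[2])
    state$heading[crashed] <- runif(k, 0, 2 * pi)
    state$hovered[crashed] <- FALSE
    state$uav_id[crashed] <- state$next_id + seq_len(k) - 1L
    state$next_id <- state$next_id + k
  }
  state
}

#' Classify an operator interaction
#'
#' Scoring rules: a click refuels only when fuel is strictly below the
#' refuel threshold (Hit Refuel), otherwise it is a False-Alarm Refuel; a
#' sustained hover reveals the gauge and scores as Hit Hover Over below the
#' threshold and False-Alarm Hover Over at or above it; the first hover on
#' a UAV is a free gauge read and is unscored.
#'
#' @param kind `"hover"` or `"click"`.
#' @param fuel fuel fraction at the moment of interaction, in \[0, 1\].
#' @param first_hover is this the UAV's free first hover?
#' @param config a [task_config()].
#' @return one of `"FAHO"`, `"FAR"`, `"HHO"`, `"HR"`, or `NA_character_`
#'   for an unscored first hover.
#' @export
classify_interaction <- function(kind = c("hover", "click"), fuel,
                                 first_hover = FALSE,
                                 config = task_config()) {
  kind <- match.arg(kind)
  if (!is.finite(fuel) || fuel < 0 || fuel > 1)
    stop("fuel must lie in [0, 1]")
  thr <- config$refuel_threshold
  if (kind == "click") {
    if (fuel < thr) "HR" else "FAR"
  } else if (first_hover) {
    NA_character_
  } else if (fuel < thr) "HHO" else "FAHO"
}

# ---------------------------------------------------------------------------
# Event-driven block simulation.
#
# Returns the block's scored events and a fuel schedule (piecewise-linear
# change points per UAV slot) from which fuels at arbitrary times can be
# evaluated.

simulate_block_events <- function(config, policy) {
  n <- config$n_uavs
  drain <- config$fuel_drain_rate
  dur <- config$block_duration
  noise_sd <- policy$memory_noise * policy$load_scaling^(n - 3)

  fuel <- runif(n, config$spawn_fuel_range[1], config$spawn_fuel_range[2])
  tf <- rep(0, n)               # time at which `fuel` was recorded
  est <- fuel                   # free initial gauge reads: estimates = truth
  te <- rep(0, n)
  tcheck <- rep(0, n)           # time of last gauge read (trusted estimate)
  hovered <- rep(TRUE, n)       # first hovers consumed at block start
  uid <- seq_len(n)
  next_id <- n + 1L

  # fuel schedule change points, per slot (block start, refuels, respawns)
  sched_t <- lapply(seq_len(n), function(k) 0)
  sched_f <- lapply(seq_len(n), function(k) fuel[k])
  sched_id <- lapply(seq_len(n), function(k) uid[k])

  ev_t <- numeric(0); ev_type <- character(0)
  ev_id <- integer(0); ev_fuel <- numeric(0)

  push_event <- function(t, type, id, f) {
    ev_t[length(ev_t) + 1L] <<- t
    ev_type[length(ev_type) + 1L] <<- type
    ev_id[length(ev_id) + 1L] <<- id
    ev_fuel[length(ev_fuel) + 1L] <<- f
  }
  push_sched <- function(k, t, f) {
    sched_t[[k]][length(sched_t[[k]]) + 1L] <<- t
    sched_f[[k]][length(sched_f[[k]]) + 1L] <<- f
    sched_id[[k]][length(sched_id[[k]]) + 1L] <<- uid[k]
  }

  # operator action times on the tick grid (per-tick Bernoulli process)
  p_act <- min(1, policy$check_rate * TICK)
  if (p_act > 0) {
    n_max <- ceiling(dur / TICK)
    gaps <- rgeom(ceiling(p_act * n_max) + 30L, p_act) + 1L
    act_times <- cumsum(gaps) * TICK
    while (length(act_times) && max(act_times) <= dur) {
      more <- rgeom(30L, p_act) + 1L
      act_times <- c(act_times, max(act_times) + cumsum(more) * TICK)
    }
    act_times <- act_times[act_times <= dur]
  } else act_times <- numeric(0)

  # crash processing up to time `until`
  run_crashes <- function(until) {
    repeat {
      ct <- tf + fuel / drain
      k <- which.min(ct)
      if (ct[k] > until) break
      t_ev <- min(ceil_tick(ct[k]), dur)
      push_event(t_ev, "MR", uid[k], 0)
      fuel[k] <<- runif(1, config$spawn_fuel_range[1],
                        config$spawn_fuel_range[2])
      tf[k] <<- ct[k]
      uid[k] <<- next_id; next_id <<- next_id + 1L
      est[k] <<- mean(config$spawn_fuel_range)
      te[k] <<- ct[k]
      tcheck[k] <<- ct[k]
      hovered[k] <<- FALSE
      push_sched(k, ct[k], fuel[k])
    }
  }

  for (t in act_times) {
    run_crashes(t)
    # drift internal estimates forward to t (operator knows the drain rate)
    dt_e <- t - te
    est <- pmin(1, pmax(0, est - drain * dt_e +
                          rnorm(n, 0, noise_sd * sqrt(pmax(dt_e, 0)))))
    te <- rep(t, n)
    # lapse: estimated-critical UAVs may be neglected this action
    crit <- est < policy$refuel_trigger
    neglected <- crit & (runif(n) < policy$lapse_prob)
    ord <- order(est)
    cand <- ord[!neglected[ord]]
    k <- if (length(cand)) cand[1] else ord[1]
    f_now <- fuel[k] - drain * (t - tf[k])
    if (f_now <= 0) next  # crash pending; handled before next action
    do_click <- function(f_at) {
      type <- classify_interaction("click", f_at, FALSE, config)
      push_event(t, type, uid[k], f_at)
      if (type == "HR") {
        gain <- runif(1, config$refuel_gain_range[1],
                      config$refuel_gain_range[2])
        fuel[k] <<- min(1, f_at + gain)
        tf[k] <<- t
        est[k] <<- fuel[k]
        tcheck[k] <<- t
        push_sched(k, t, fuel[k])
      } else {
        est[k] <<- f_at  # error feedback reveals the true level
        tcheck[k] <<- t
      }
    }
    if (est[k] < policy$refuel_trigger &&
        t - tcheck[k] <= policy$verify_horizon) {
      # recently checked and low: refuel without re-checking
      do_click(f_now)
    } else {
      # hover: reveals the gauge (sustained >= hover_min by construction)
      if (!hovered[k]) {
        hovered[k] <- TRUE          # free first gauge read, unscored
        est[k] <- f_now
      } else {
        type <- classify_interaction("hover", f_now, FALSE, config)
        push_event(t, type, uid[k], f_now)
        est[k] <- f_now
      }
      tcheck[k] <- t
      if (f_now < policy$refuel_trigger) do_click(f_now)
    }
  }
  run_crashes(dur)

  events <- data.frame(t = ev_t, event_type = ev_type, uav_id = ev_id,
                       fuel_at_event = ev_fuel,
                       points = unname(config$payoffs[ev_type]))
  events <- events[order(events$t), , drop = FALSE]
  rownames(events) <- NULL
  list(events = events,
       schedule = list(t = sched_t, f = sched_f, id = sched_id,
                       drain = drain))
}

# Evaluate all on-screen fuels (and UAV ids) at a time point from a block's
# piecewise-linear fuel schedule.
fuels_at <- function(schedule, t) {
  n <- length(schedule$t)
  f <- numeric(n); id <- integer(n)
  for (k in seq_len(n)) {
    i <- findInterval(t + 1e-9, schedule$t[[k]])
    i <- max(i, 1L)
    f[k] <- max(0, schedule$f[[k]][i] - schedule$drain * (t - schedule$t[[k]][i]))
    id[k] <- schedule$id[[k]][i]
  }
  list(fuel = f, uav_id = id)
}

# Vectorized variant: fuels and ids for a whole vector of query times;
# returns matrices (time x slot).
fuels_at_many <- function(schedule, times) {
  n <- length(schedule$t)
  f <- matrix(0, length(times), n)
  id <- matrix(0L, length(times), n)
  for (k in seq_len(n)) {
    i <- pmax(findInterval(times + 1e-9, schedule$t[[k]]), 1L)
    f[, k] <- pmax(0, schedule$f[[k]][i] -
                     schedule$drain * (times - schedule$t[[k]][i]))
    id[, k] <- schedule$id[[k]][i]
  }
  list(fuel = f, uav_id = id)
}

# ---------------------------------------------------------------------------
# DRT generation

# Prompt onsets: consecutive onsets separated by iid Uniform(isi_range)
# draws, the first drawn from block/session start. Stops at session_length
# or after n_prompts onsets.
draw_prompt_onsets <- function(session_length, isi_range,
                               n_prompts = NULL) {
  onsets <- numeric(0)
  t <- runif(1, isi_range[1], isi_range[2])
  while (t <= session_length) {
    onsets[length(onsets) + 1L] <- t
    if (!is.null(n_prompts) && length(onsets) >= n_prompts) break
    t <- t + runif(1, isi_range[1], isi_range[2])
  }
  onsets
}

# Draw omissions (sequential, via previous-trial dependence) and truncated
# log-normal RTs for a set of prompts with evaluated covariates.
draw_drt_outcomes <- function(eta_rt, eta_om, gamma_missprev, model, config) {
  n <- length(eta_rt)
  omission <- logical(n)
  prev <- 0
  for (i in seq_len(n)) {
    p <- plogis(eta_om[i] + gamma_missprev * prev)
    omission[i] <- runif(1) < p
    prev <- as.numeric(omission[i])
  }
  rt_ms <- rep(NA_real_, n)
  resp <- !omission
  if (any(resp)) {
    ub <- log(config$response_window * 1000)
    mu <- eta_rt[resp]
    pu <- pnorm(ub, mu, model$residual_sd)
    u <- runif(sum(resp)) * pu
    rt_ms[resp] <- exp(qnorm(u, mu, model$residual_sd))
  }
  list(omission = omission, rt_ms = rt_ms)
}

#' Generate a DRT prompt stream with simulated outcomes
#'
#' Prompt onsets are separated by independent Uniform(`isi_range`) draws
#' (mean inter-stimulus interval about 4 s under the defaults). For each
#' prompt, an omission is drawn from the logistic occurrence sub-model and,
#' when responded, the RT from the log-normal intensity sub-model truncated
#' at the response window.
#'
#' @param session_length length of the stream in seconds.
#' @param workload_trace `NULL` (covariate-free stream) or a
#'   `function(times)` returning a data frame with columns `wf_std`,
#'   `hho3s`, `far3s`, `d2`, `d4`, `block0` giving the generative
#'   covariates at each prompt time.
#' @param model a [workload_model()].
#' @param seed integer seed.
#' @param config a [task_config()] (timing parameters).
#' @param subject_intercept participant random intercept on log-RT, log-ms.
#' @param n_prompts optional cap on the number of prompts.
#' @return data frame: prompt_t, rt_ms (NA on omission), omission.
#' @examples
#' s <- generate_drt_stream(200, NULL, workload_model(), seed = 1)
#' mean(diff(s$prompt_t))  # about 4 s
#' @export
generate_drt_stream <- function(session_length, workload_trace = NULL,
                                model = workload_model(), seed = 1,
                                config = task_config(),
                                subject_intercept = 0, n_prompts = NULL) {
  stopifnot(session_length > config$isi_range[2])
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  onsets <- draw_prompt_onsets(session_length, config$isi_range, n_prompts)
  if (is.null(workload_trace)) {
    cov <- data.frame(wf_std = 0, hho3s = 0, far3s = 0, d2 = 0, d4 = 0,
                      block0 = 0)[rep(1, length(onsets)), , drop = FALSE]
  } else {
    cov <- workload_trace(onsets)
  }
  eta_rt <- model$rt_intercept + subject_intercept +
    model$beta_difficulty[1] * cov$d2 + model$beta_difficulty[2] * cov$d4 +
    model$beta_block * cov$block0 + model$beta_weightfuel * cov$wf_std +
    model$beta_hho3s * cov$hho3s + model$beta_far3s * cov$far3s
  eta_om <- model$gamma_intercept +
    model$gamma_difficulty[1] * cov$d2 + model$gamma_difficulty[2] * cov$d4 +
    model$gamma_block * cov$block0 + model$gamma_weightfuel * cov$wf_std +
    model$gamma_hho3s * cov$hho3s + model$gamma_far3s * cov$far3s
  out <- draw_drt_outcomes(eta_rt, eta_om, model$gamma_missprev, model,
                           config)
  data.frame(prompt_t = onsets, rt_ms = out$rt_ms,
             omission = as.integer(out$omission))
}

# ---------------------------------------------------------------------------

#' Simulate a complete study
#'
#' Composes the block simulator, operator policy and generative workload
#' model into a full study: each participant completes `n_days` sessions of
#' `config$n_blocks` two-minute blocks whose difficulties (3/5/7 UAVs)
#' follow the pseudo-random triple schedule. Per participant, an
#' independent RNG stream is derived from the study seed, so adding
#' participants never perturbs earlier ones.
#'
#' @param n_participants number of simulated operators.
#' @param config a [task_config()]; `n_uavs` is overridden per block by the
#'   difficulty schedule.
#' @param policy an [operator_policy()].
#' @param model a [workload_model()].
#' @param seed integer study seed.
#' @param n_days sessions per participant.
#' @param out_dir if non-NULL, the three logs are also written as CSV
#'   (`events.csv`, `drt.csv`, `snapshots.csv`).
#' @return a list of class `sim_study`: `events` (scored task events),
#'   `drt` (prompt log), `snapshots` (per-prompt fuel vectors), `truth`
#'   (the generative [workload_model()], for recovery tests), `seed`.
#' @export
simulate_study <- function(n_participants, config = task_config(),
                           policy = operator_policy(),
                           model = workload_model(), seed = 1,
                           n_days = 2, out_dir = NULL) {
  stopifnot(n_participants >= 1)
  ev_all <- vector("list", n_participants)
  drt_all <- vector("list", n_participants)
  snap_all <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    pid <- sprintf("P%02d", i)
    set.seed(derive_seed(seed, i))
    u_i <- rnorm(1, 0, model$subject_sd)
    ev_p <- list(); drt_p <- list(); snap_p <- list()
    for (day in seq_len(n_days)) {
      sched <- as.integer(unlist(lapply(seq_len(config$n_blocks / 3),
                                        function(j) sample(c(3L, 5L, 7L)))))
      if (config$n_blocks %% 3 != 0)
        sched <- sample(rep(c(3L, 5L, 7L), length.out = config$n_blocks))
      for (b in seq_len(config$n_blocks)) {
        diffic <- sched[b]
        cfg_b <- config; cfg_b$n_uavs <- diffic
        blk <- simulate_block_events(cfg_b, policy)
        onsets <- draw_prompt_onsets(config$block_duration, config$isi_range)
        np <- length(onsets)
        if (np == 0) next
        fuels <- fuels_at_many(blk$schedule, onsets)
        wf <- (rowMeans(fuels$fuel^model$wf_exponent))^(1 / model$wf_exponent)
        cnt <- function(type) {
          tt <- sort(blk$events$t[blk$events$event_type == type])
          if (!length(tt)) return(numeric(np))
          findInterval(onsets + 1e-9, tt) - findInterval(onsets - 3 + 1e-9, tt)
        }
        hho3 <- cnt("HHO")
        far3 <- cnt("FAR")
        d2 <- as.numeric(diffic == 5); d4 <- as.numeric(diffic == 7)
        eta_rt <- model$rt_intercept + u_i +
          model$beta_difficulty[1] * d2 + model$beta_difficulty[2] * d4 +
          model$beta_block * (b - 1) +
          model$beta_weightfuel * (wf - model$wf_center) / model$wf_scale +
          model$beta_hho3s * hho3 + model$beta_far3s * far3
        eta_om <- model$gamma_intercept +
          model$gamma_difficulty[1] * d2 + model$gamma_difficulty[2] * d4 +
          model$gamma_block * (b - 1) +
          model$gamma_weightfuel * (wf - model$wf_center) / model$wf_scale +
          model$gamma_hho3s * hho3 + model$gamma_far3s * far3
        out <- draw_drt_outcomes(eta_rt, eta_om, model$gamma_missprev,
                                 model, config)
        nev <- nrow(blk$events)
        if (nev > 0)
          ev_p[[length(ev_p) + 1L]] <- data.frame(
            participant_id = pid, day = day, block = b, difficulty = diffic,
            t = round(blk$events$t, 1), event_type = blk$events$event_type,
            uav_id = blk$events$uav_id,
            fuel_at_event = round(blk$events$fuel_at_event, 6),
            points = blk$events$points)
        # timestamps at sub-ms resolution, RTs at microseconds, fuels at
        # 1e-6 of a tank: exact decimal text round-trips through CSV
        drt_p[[length(drt_p) + 1L]] <- data.frame(
          participant_id = pid, day = day, block = b, difficulty = diffic,
          prompt_t = round(onsets, 4), rt_ms = round(out$rt_ms, 3),
          omission = as.integer(out$omission))
        snap_p[[length(snap_p) + 1L]] <- data.frame(
          participant_id = pid, day = day, block = b, difficulty = diffic,
          prompt_t = rep(round(onsets, 4), each = diffic),
          uav_id = as.integer(t(fuels$uav_id)),
          fuel = round(as.numeric(t(fuels$fuel)), 6))
      }
    }
    ev_all[[i]] <- do.call(rbind, ev_p)
    drt_all[[i]] <- do.call(rbind, drt_p)
    snap_all[[i]] <- do.call(rbind, snap_p)
  }
  study <- structure(list(
    events = do.call(rbind, ev_all),
    drt = do.call(rbind, drt_all),
    snapshots = do.call(rbind, snap_all),
    truth = model, seed = seed
  ), class = "sim_study")
  rownames(study$events) <- rownames(study$drt) <-
    rownames(study$snapshots) <- NULL
  if (!is.null(out_dir)) write_logs(study, out_dir)
  study
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulated workload study\n")
  cat(sprintf("  participants: %d   days: %d\n",
              length(unique(x$drt$participant_id)),
              length(unique(x$drt$day))))
  cat(sprintf("  task events:  %d\n", nrow(x$events)))
  cat(sprintf("  DRT prompts:  %d (omission rate %.3f)\n",
              nrow(x$drt), mean(x$drt$omission)))
  invisible(x)
}
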