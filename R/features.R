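# Per-trial predictor construction: windowed event flags/counts, the
# weighted fuel level (power mean), the last-checked fuel rank, previous
# omission, and within-participant standardization.

#' Weighted fuel level (power mean of order p)
#'
#' Aggregates the fuel fractions of all on-screen UAVs into a single value
#' `(sum(f^p) / K)^(1/p)` — the power (Minkowski) mean of order `p` of the
#' `K` fuel levels. Exponents `p < 1` weight low fuel levels more heavily,
#' so the statistic drops sharply when any one UAV nears a crash; `p = 1`
#' is the arithmetic mean.
#'
#' @param fuels numeric vector of fuel fractions in \[0, 1\], one per
#'   on-screen UAV.
#' @param p power-mean exponent, nonzero (default 1/4).
#' @return a single fuel fraction in \[0, 1\].
#' @examples
#' weight_fuel(c(0.0625, 1), p = 1/4)  # ((0.5 + 1)/2)^4 = 0.31640625
#' weight_fuel(c(0.2, 0.4, 0.9), p = 1)  # arithmetic mean
#' @export
weight_fuel <- function(fuels, p = 1 / 4) {
  if (length(fuels) == 0) stop("at least one UAV fuel level is required")
  if (any(!is.finite(fuels)) || any(fuels < 0) || any(fuels > 1))
    stop("all fuel levels must lie in [0, 1]")
  if (p == 0) stop("exponent p must be nonzero")
  (sum(fuels^p) / length(fuels))^(1 / p)
}

#' Rank of the checked UAV's fuel
#'
#' Ascending rank (1 = lowest) of the hovered UAV's fuel among all
#' on-screen fuels at the hover instant; ties take the minimum rank.
#'
#' @param fuels fuel fractions of all on-screen UAVs.
#' @param hovered_index index into `fuels` of the hovered UAV.
#' @return integer rank in `1..length(fuels)`.
#' @examples
#' ord_fuel(c(0.1, 0.2, 0.3), 2)  # 2
#' ord_fuel(c(0.2, 0.2, 0.5), 1)  # 1 (tie takes the minimum rank)
#' @export
ord_fuel <- function(fuels, hovered_index) {
  stopifnot(length(fuels) >= 1,
            hovered_index >= 1, hovered_index <= length(fuels))
  as.integer(rank(fuels, ties.method = "min")[hovered_index])
}

#' Previous-trial omission flag
#'
#' @param trial a single-trial data frame row with a defined
#'   `prev_omission` (first-of-block trials must be excluded upstream).
#' @return 0/1 flag.
#' @export
miss_prev_drt <- function(trial) {
  if (is.na(trial$prev_omission))
    stop("prev_omission undefined; run exclude_trials() first")
  as.integer(trial$prev_omission)
}

#' Windowed event flags and counts for one trial
#'
#' An event at time `t` falls in the window iff
#' `prompt_t - w < t <= prompt_t` within the same (participant, day,
#' block): half-open, so events simultaneous with the prompt count (they
#' precede the response).
#'
#' @param trial single-trial row (participant_id, day, block, prompt_t).
#' @param events task-event log.
#' @param w window length, seconds.
#' @return named list: per event type, `count` and `flag`.
#' @export
window_events <- function(trial, events, w) {
  stopifnot(w > 0)
  sel <- events$participant_id == trial$participant_id &
    events$day == trial$day & events$block == trial$block &
    events$t > trial$prompt_t - w & events$t <= trial$prompt_t
  counts <- table(factor(events$event_type[sel], levels = EVENT_TYPES))
  list(count = as.integer(counts),
       flag = as.integer(counts > 0),
       types = EVENT_TYPES)
}

#' Within-participant z-standardization
#'
#' Centers and scales a column to mean 0, SD 1 (sample, n-1 denominator)
#' separately for each participant. Zero-variance participants get zeros
#' with a warning.
#'
#' @param x numeric column.
#' @param participant grouping vector, same length as `x`.
#' @return the standardized column.
#' @export
zstandardize_within_participant <- function(x, participant) {
  stopifnot(length(x) == length(participant))
  out <- x
  warned <- FALSE
  for (p in unique(participant)) {
    i <- participant == p
    s <- sd(x[i], na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      out[i] <- ifelse(is.na(x[i]), NA_real_, 0)
      warned <- TRUE
    } else {
      out[i] <- (x[i] - mean(x[i], na.rm = TRUE)) / s
    }
  }
  if (warned)
    warning("zero-variance participant(s): standardized values set to 0")
  out
}

# fuels of on-screen UAVs at time `t`, reconstructed from the event log by
# linear drain extrapolation from each UAV's last observation at or before
# t (clamped to [0, 1]). Crashed UAVs (last event MR) and UAVs whose
# extrapolated fuel has reached zero are no longer on screen and are
# dropped, as are UAVs never observed in the block (their level is
# unknowable from interaction-only logs). Used when no simulator snapshot
# log is available.
reconstruct_fuels <- function(block_events, t, drain = 0.05,
                              n_uavs = NULL, exclude_id = NULL) {
  ev <- block_events[block_events$t <= t, ]
  if (nrow(ev) == 0) return(numeric(0))
  last <- ev[!duplicated(ev$uav_id, fromLast = TRUE), ]
  last <- last[last$event_type != "MR", ]
  if (!is.null(exclude_id)) last <- last[last$uav_id != exclude_id, ]
  if (nrow(last) == 0) return(numeric(0))
  # a refuel (HR) changes fuel by an unobserved gain; treat the post-HR
  # level as unknown-high (midpoint of possible post-refuel levels)
  f0 <- ifelse(last$event_type == "HR",
               pmin(1, last$fuel_at_event + 0.75), last$fuel_at_event)
  f <- f0 - drain * (t - last$t)
  keep <- f > 0
  last <- last[keep, , drop = FALSE]; f <- f[keep]
  if (!is.null(n_uavs) && nrow(last) > n_uavs) {
    recent <- order(last$t, decreasing = TRUE)[seq_len(n_uavs)]
    f <- f[recent]
  }
  pmin(1, f)
}

#' Build the per-trial feature table
#'
#' Computes, for every retained trial: occurrence flags for the five event
#' types in windows of `windows` seconds before the prompt; counts of HHO,
#' FAHO and FAR events in the 3 s window; the weighted fuel level at the
#' prompt (power mean of order `exponent`, from the simulator's snapshot
#' log when available, otherwise by drain extrapolation from the last
#' logged interaction per UAV); the fuel rank of the last-checked UAV
#' (`NA` when no hover occurred in the 3 s window); and the previous-trial
#' omission flag.
#'
#' @param dataset a `drt_dataset` (after exclusions for modelling use).
#' @param windows window lengths in seconds (default 3, 4, 5).
#' @param exponent power-mean exponent for the weighted fuel level.
#' @param standardize if TRUE, z-standardize `weightfuel`, `hho3s` and
#'   `far3s` within participant (columns `*_z`).
#' @param compute_ordfuel compute the last-checked fuel rank (per-trial
#'   reconstruction; skip when the rank predictor is not needed).
#' @return a data frame keyed by (participant_id, day, block, trial_index)
#'   with columns `<type>_w<w>` (flags), `hho3s`, `faho3s`, `far3s`,
#'   `weightfuel`, `ordfuel`, `missprevdrt`, plus carried labels.
#' @export
build_feature_table <- function(dataset, windows = c(3, 4, 5),
                                exponent = 1 / 4, standardize = FALSE,
                                compute_ordfuel = TRUE) {
  tr <- dataset$trials
  ev <- dataset$events
  n <- nrow(tr)
  out <- tr[, c("participant_id", "day", "block", "difficulty",
                "trial_index", "prompt_t", "rt_ms", "omission",
                "prev_omission")]
  for (w in windows) for (ty in EVENT_TYPES)
    out[[paste0(tolower(ty), "_w", w)]] <- integer(n)
  out$hho3s <- integer(n); out$faho3s <- integer(n); out$far3s <- integer(n)
  out$weightfuel <- NA_real_; out$ordfuel <- NA_integer_

  tk <- paste(tr$participant_id, tr$day, tr$block)
  ev_split <- split(ev, paste(ev$participant_id, ev$day, ev$block))
  have_snap <- !is.null(dataset$snapshots) && nrow(dataset$snapshots) > 0

  if (have_snap) {
    # vectorized power mean per prompt from the snapshot fuel vectors
    sn <- dataset$snapshots
    g <- paste(sn$participant_id, sn$day, sn$block,
               sprintf("%.4f", sn$prompt_t))
    s <- rowsum(sn$fuel^exponent, g)
    m <- rowsum(rep(1, nrow(sn)), g)
    wf <- (s[, 1] / m[, 1])^(1 / exponent)
    out$weightfuel <- unname(
      wf[paste(tk, sprintf("%.4f", tr$prompt_t))])
  }

  for (key in unique(tk)) {
    rows <- which(tk == key)
    bev <- ev_split[[key]]
    prompts <- tr$prompt_t[rows]
    if (!is.null(bev) && nrow(bev)) {
      for (ty in EVENT_TYPES) {
        tt <- sort(bev$t[bev$event_type == ty])
        if (!length(tt)) next
        n_le <- function(x) findInterval(x + 1e-9, tt)
        for (w in windows) {
          cnt <- n_le(prompts) - n_le(prompts - w)
          out[[paste0(tolower(ty), "_w", w)]][rows] <- as.integer(cnt > 0)
          if (w == 3) {
            if (ty == "HHO") out$hho3s[rows] <- cnt
            if (ty == "FAHO") out$faho3s[rows] <- cnt
            if (ty == "FAR") out$far3s[rows] <- cnt
          }
        }
      }
    }
    if (!have_snap && !is.null(bev) && nrow(bev)) {
      for (j in seq_along(rows))
        if (length(fuels <- reconstruct_fuels(bev, prompts[j],
                                              n_uavs = tr$difficulty[rows[j]])))
          out$weightfuel[rows[j]] <- weight_fuel(fuels, exponent)
    }
    if (compute_ordfuel && !is.null(bev) && nrow(bev)) {
      hov_all <- bev[bev$event_type %in% c("HHO", "FAHO"), ]
      if (nrow(hov_all)) {
        ht <- hov_all$t
        for (j in seq_along(rows)) {
          t0 <- prompts[j]
          in_w <- which(ht > t0 - 3 & ht <= t0)
          if (!length(in_w)) next
          h <- hov_all[in_w[which.max(ht[in_w])], ]
          others <- reconstruct_fuels(bev, h$t,
                                      n_uavs = tr$difficulty[rows[j]] - 1,
                                      exclude_id = h$uav_id)
          out$ordfuel[rows[j]] <- ord_fuel(c(h$fuel_at_event, others), 1L)
        }
      }
    }
  }
  out$missprevdrt <- as.integer(out$prev_omission)
  if (standardize) {
    for (col in c("weightfuel", "hho3s", "far3s"))
      out[[paste0(col, "_z")]] <- zstandardize_within_participant(
        as.numeric(out[[col]]), out$participant_id)
  }
  rownames(out) <- NULL
  out
}
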