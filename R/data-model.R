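# Log schemas, trial construction and the study's exclusion filters.

EVENT_COLS <- c("participant_id", "day", "block", "difficulty", "t",
                "event_type", "uav_id", "fuel_at_event", "points")
DRT_COLS <- c("participant_id", "day", "block", "difficulty", "prompt_t",
              "rt_ms", "omission")
SNAP_COLS <- c("participant_id", "day", "block", "difficulty", "prompt_t",
               "uav_id", "fuel")

#' Write study logs as CSV
#'
#' Writes `events.csv`, `drt.csv` and (when present) `snapshots.csv` into
#' `dir`. Writing then reading reproduces the dataset exactly.
#'
#' @param x a `sim_study` or `drt_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_logs <- function(x, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  wr <- function(df, f) {
    path <- file.path(dir, f)
    ok <- tryCatch({write.csv(df, path, row.names = FALSE, na = ""); TRUE},
                   error = function(e) FALSE)
    if (!ok) stop("failed to write ", path)
  }
  wr(x$events, "events.csv")
  wr(if (!is.null(x$drt)) x$drt else trials_to_drt_log(x$trials), "drt.csv")
  if (!is.null(x$snapshots)) wr(x$snapshots, "snapshots.csv")
  invisible(dir)
}

trials_to_drt_log <- function(trials) {
  trials[, DRT_COLS]
}

read_log_file <- function(path, cols, what) {
  if (!file.exists(path)) stop("missing ", what, " log: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("malformed ", what, " log ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df[, cols]
}

#' Read study logs into a dataset
#'
#' Parses the event and DRT CSV logs (plus the optional per-prompt fuel
#' snapshot log), validates their schemas, and builds one trial per DRT
#' prompt. The returned dataset carries a provenance audit trail that the
#' exclusion filters append to.
#'
#' @param dir directory containing `events.csv` and `drt.csv` (and
#'   optionally `snapshots.csv`), as written by [write_logs()].
#' @return a `drt_dataset`: `events`, `trials`, `snapshots` (or NULL),
#'   `provenance`.
#' @export
read_logs <- function(dir) {
  events <- read_log_file(file.path(dir, "events.csv"), EVENT_COLS, "event")
  bad <- setdiff(unique(events$event_type), EVENT_TYPES)
  if (length(bad))
    stop("unknown event_type in event log: ", paste(bad, collapse = ", "))
  drt <- read_log_file(file.path(dir, "drt.csv"), DRT_COLS, "DRT")
  snap_path <- file.path(dir, "snapshots.csv")
  snapshots <- if (file.exists(snap_path))
    read_log_file(snap_path, SNAP_COLS, "snapshot") else NULL
  new_dataset(events, drt, snapshots, source = dir)
}

#' Build a dataset from in-memory logs
#'
#' @param events task-event log (see [simulate_study()] for the schema).
#' @param drt DRT prompt log.
#' @param snapshots optional per-prompt fuel snapshot log.
#' @param source provenance label.
#' @return a `drt_dataset`.
#' @export
new_dataset <- function(events, drt, snapshots = NULL,
                        source = "in-memory") {
  if (is.null(events))
    events <- as.data.frame(setNames(rep(list(logical(0)),
                                         length(EVENT_COLS)), EVENT_COLS))
  trials <- build_trials(drt)
  structure(list(
    events = events,
    trials = trials,
    snapshots = snapshots,
    provenance = list(source = source,
                      steps = data.frame(step = "ingest",
                                         trials_removed = 0L,
                                         trials_retained = nrow(trials)))
  ), class = "drt_dataset")
}

#' @export
print.drt_dataset <- function(x, ...) {
  cat("DRT dataset (", x$provenance$source, ")\n", sep = "")
  cat(sprintf("  trials: %d   events: %d   participants: %d\n",
              nrow(x$trials), nrow(x$events),
              length(unique(x$trials$participant_id))))
  print(x$provenance$steps, row.names = FALSE)
  invisible(x)
}

#' Construct trials from a DRT prompt log
#'
#' A trial is the interval between two DRT prompts. One trial is built per
#' prompt, indexed from 1 within each (participant, day, block);
#' `prev_omission` copies the previous trial's omission flag within the
#' block and is `NA` for the first trial.
#'
#' @param drt_log data frame with the DRT log schema.
#' @return trial data frame adding `trial_index` and `prev_omission`.
#' @export
build_trials <- function(drt_log) {
  if (nrow(drt_log) == 0) {
    out <- drt_log
    out$trial_index <- integer(0)
    out$prev_omission <- integer(0)
    return(out)
  }
  ord <- order(drt_log$participant_id, drt_log$day, drt_log$block,
               drt_log$prompt_t)
  out <- drt_log[ord, ]
  key <- paste(out$participant_id, out$day, out$block)
  dup <- ave(out$prompt_t, key, FUN = function(z) duplicated(z))
  if (any(dup > 0))
    stop("duplicate prompt times within a block")
  out$trial_index <- as.integer(ave(seq_along(key), key,
                                    FUN = seq_along))
  out$prev_omission <- as.integer(ave(out$omission, key, FUN = function(z)
    c(NA, head(z, -1))))
  rownames(out) <- NULL
  out
}

record_step <- function(dataset, step, removed) {
  dataset$provenance$steps <- rbind(
    dataset$provenance$steps,
    data.frame(step = step, trials_removed = as.integer(removed),
               trials_retained = nrow(dataset$trials)))
  dataset
}

#' Remove high-omission participant-days
#'
#' A participant-day is removed when its omission rate exceeds `threshold`
#' in at least `min_conditions` of the three difficulty conditions
#' (strictly "more than" the threshold). Applied per day, since different
#' participants can fail the rule on different days.
#'
#' @param dataset a `drt_dataset`.
#' @param threshold omission-rate cutoff (default 0.45).
#' @param min_conditions number of difficulty conditions that must exceed
#'   the cutoff (default 2).
#' @return the filtered dataset; `$removal_report` lists removed
#'   participant-days.
#' @export
exclude_participants <- function(dataset, threshold = 0.45,
                                 min_conditions = 2) {
  tr <- dataset$trials
  if (nrow(tr) == 0) {
    dataset$removal_report <- data.frame(participant_id = character(0),
                                         day = integer(0))
    return(record_step(dataset, "exclude_participants", 0L))
  }
  rates <- aggregate(omission ~ participant_id + day + difficulty,
                     data = tr, FUN = mean)
  flags <- aggregate(omission ~ participant_id + day, data = rates,
                     FUN = function(r) sum(r > threshold))
  bad <- flags[flags$omission >= min_conditions,
               c("participant_id", "day")]
  n0 <- nrow(tr)
  if (nrow(bad)) {
    drop <- paste(tr$participant_id, tr$day) %in%
      paste(bad$participant_id, bad$day)
    dataset$trials <- tr[!drop, ]
    keep_ev <- !(paste(dataset$events$participant_id, dataset$events$day)
                 %in% paste(bad$participant_id, bad$day))
    dataset$events <- dataset$events[keep_ev, ]
  }
  dataset$removal_report <- bad
  record_step(dataset, "exclude_participants", n0 - nrow(dataset$trials))
}

#' Remove first-of-block and interaction-starved trials
#'
#' Drops (a) the first trial of every block, whose previous-trial
#' information is unavailable, and (b) trials whose most recent operator
#' interaction (any hover or click) precedes the prompt by more than
#' `max_gap` seconds or is absent entirely.
#'
#' @param dataset a `drt_dataset`.
#' @param max_gap maximum allowed gap, seconds (default 100).
#' @return the filtered dataset with updated provenance.
#' @export
exclude_trials <- function(dataset, max_gap = 100) {
  tr <- dataset$trials
  n0 <- nrow(tr)
  if (n0 == 0) return(record_step(dataset, "exclude_trials", 0L))
  first <- tr$trial_index == 1L
  ev <- dataset$events[dataset$events$event_type %in% INTERACTION_TYPES, ]
  gap_ok <- logical(n0)
  ek <- paste(ev$participant_id, ev$day, ev$block)
  tk <- paste(tr$participant_id, tr$day, tr$block)
  ev_split <- split(ev$t, ek)
  for (key in unique(tk)) {
    idx <- which(tk == key)
    times <- ev_split[[key]]
    if (is.null(times)) next  # interaction-free block
    times <- sort(times)
    pos <- findInterval(tr$prompt_t[idx] + 1e-9, times)
    has <- pos >= 1
    gap_ok[idx[has]] <-
      (tr$prompt_t[idx][has] - times[pos[has]]) <= max_gap
  }
  keep <- !first & gap_ok
  dataset$trials <- tr[keep, ]
  rownames(dataset$trials) <- NULL
  dataset$trial_removal <- data.frame(
    first_of_block = sum(first),
    no_recent_interaction = sum(!gap_ok & !first))
  record_step(dataset, "exclude_trials", n0 - nrow(dataset$trials))
}
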