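# Descriptive outputs: AIC/BIC comparison ladders, effect-size summaries,
# the power-mean exponent sweep, and the overload (UAV explosion)
# comparison between event-based and refined predictor sets.

#' Per-block aggregates for the descriptive ladders
#'
#' Collapses a dataset to one row per participant x day x block with the
#' block score (`points`) and the count of each event type, the dependent
#' variables of the points/task-events model ladders.
#'
#' @param dataset a `drt_dataset` or `sim_study`.
#' @return data frame: participant_id, day, block, difficulty, points,
#'   n_FAHO .. n_MR.
#' @export
block_summaries <- function(dataset) {
  ev <- dataset$events
  tr <- if (!is.null(dataset$trials)) dataset$trials else dataset$drt
  keys <- unique(tr[, c("participant_id", "day", "block", "difficulty")])
  ek <- paste(ev$participant_id, ev$day, ev$block)
  kk <- paste(keys$participant_id, keys$day, keys$block)
  out <- keys
  out$points <- 0
  for (ty in EVENT_TYPES) out[[paste0("n_", ty)]] <- 0L
  for (i in seq_len(nrow(keys))) {
    sub <- ev[ek == kk[i], ]
    out$points[i] <- sum(sub$points)
    if (nrow(sub)) {
      cnt <- table(factor(sub$event_type, levels = EVENT_TYPES))
      for (ty in EVENT_TYPES) out[[paste0("n_", ty)]][i] <- cnt[[ty]]
    }
  }
  rownames(out) <- NULL
  out
}

ladder_fit <- function(response_col, family, terms, data) {
  data$.y <- data[[response_col]]
  spec <- model_spec(if (family == "linear") "points" else "event_count",
                     family, terms, random = TRUE,
                     label = paste(terms, collapse = "+"))
  f <- as.formula(paste(".y ~",
                        if (length(terms)) paste(terms, collapse = " + ")
                        else "1", "+ (1 | participant_id)"))
  if (family == "linear") {
    fit <- suppressMessages(lme4::lmer(f, data = data, REML = FALSE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
  } else {
    fit <- suppressMessages(lme4::glmer(f, data = data, family = poisson(),
      control = lme4::glmerControl(calc.derivs = FALSE,
                                   check.conv.singular = "ignore")))
  }
  ll <- as.numeric(logLik(fit))
  new_fit(spec, fit, ll, attr(logLik(fit), "df"), nobs(fit),
          list(flags = mer_flags(fit)))
}

#' AIC/BIC model-comparison ladder
#'
#' Fits a ladder of nested random-intercept models to one or more
#' dependent variables and tabulates AIC/BIC with best-model markers. The
#' default ladder is difficulty, difficulty + day, difficulty x day; the
#' time-on-task ladder (difficulty + day, + block, + day x block) can be
#' requested instead. Linear fits are used for `points` and log-RT,
#' Poisson fits for event counts, binomial for omissions.
#'
#' @param data model frame (e.g. [block_summaries()] output, or a trial
#'   table for DRT responses).
#' @param responses named character vector mapping response columns to
#'   families (`"linear"`, `"poisson"`, `"binomial"`).
#' @param ladder list of character vectors of fixed terms, one per model.
#' @return a `comparison_table` data frame of AIC/BIC cells per response,
#'   with `best_AIC`/`best_BIC` markers and deltas (interpret differences
#'   of 2-7 as weak support, > 7 as essentially none).
#' @export
ladder_report <- function(data,
                          responses = c(points = "linear"),
                          ladder = list(c("difficulty"),
                                        c("difficulty", "day"),
                                        c("difficulty", "day",
                                          "difficulty:day"))) {
  data <- prepare_model_frame(data)
  rows <- list()
  for (resp in names(responses)) {
    fam <- responses[[resp]]
    for (li in seq_along(ladder)) {
      terms <- ladder[[li]]
      label <- paste(terms, collapse = "+")
      cell <- tryCatch({
        fit <- if (fam == "binomial") {
          d2 <- data; d2$.y <- d2[[resp]]
          f <- as.formula(paste(".y ~", paste(terms, collapse = " + "),
                                "+ (1 | participant_id)"))
          m <- suppressMessages(lme4::glmer(f, data = d2,
            family = binomial(),
            control = lme4::glmerControl(calc.derivs = FALSE,
                                         check.conv.singular = "ignore")))
          ll <- as.numeric(logLik(m))
          new_fit(model_spec("omission", "binomial", terms), m, ll,
                  attr(logLik(m), "df"), nobs(m),
                  list(flags = mer_flags(m)))
        } else ladder_fit(resp, fam, terms, data)
        information_criteria(fit)
      }, error = function(e) c(AIC = NA_real_, BIC = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, model = label, AIC = cell[["AIC"]],
        BIC = cell[["BIC"]])
    }
  }
  out <- do.call(rbind, rows)
  out$dAIC <- ave(out$AIC, out$response,
                  FUN = function(z) z - min(z, na.rm = TRUE))
  out$dBIC <- ave(out$BIC, out$response,
                  FUN = function(z) z - min(z, na.rm = TRUE))
  out$best_AIC <- out$dAIC == 0
  out$best_BIC <- out$dBIC == 0
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Effect-size report for the refined predictors
#'
#' Fits, separately per day, a two-part log-normal model, an LMM (log-RT)
#' and a binomial GLMM (omissions) with the weighted fuel level, HHO and
#' FAR 3-s counts (z-standardized within participant), block and
#' difficulty as predictors and a participant random intercept. Reports
#' unstandardized coefficients; the block entry is the cumulative effect
#' of completing all 21 blocks (coefficient x 20 block increments), and an
#' approximate millisecond-scale effect exp(b0 + beta) - exp(b0) at the
#' baseline profile is attached for the log-RT models.
#'
#' @param features feature table from [build_feature_table()] with
#'   `standardize = TRUE`.
#' @param per_day fit each day separately (default TRUE).
#' @param n_blocks session length used for the cumulative block effect.
#' @return data frame: day, model (tpm/lmm/glmm), term, estimate, se,
#'   cumulative (block only), approx_ms (log-RT models).
#' @export
effect_report <- function(features, per_day = TRUE, n_blocks = 21) {
  terms <- c("weightfuel_z", "hho3s_z", "far3s_z", "block", "difficulty")
  stopifnot(all(c("weightfuel_z", "hho3s_z", "far3s_z") %in%
                  names(features)))
  features <- prepare_model_frame(features)
  features <- features[!is.na(features$weightfuel_z), ]
  days <- if (per_day) sort(unique(features$day)) else NA
  rows <- list()
  for (d in days) {
    sub <- if (is.na(d)) features else features[features$day == d, ]
    tpm <- fit_tpm(model_spec("logRT", "two_part_lognormal", terms), sub)
    lmm <- fit_lmm(model_spec("logRT", "linear", terms),
                   sub[sub$omission == 0, ])
    glmm <- fit_glmm(model_spec("omission", "binomial", terms), sub)
    for (m in c("tpm", "lmm", "glmm")) {
      co <- switch(m, tpm = tpm$intensity$coefficients,
                   lmm = lmm$coefficients, glmm = glmm$coefficients)
      b0 <- co$estimate[co$term == "(Intercept)"]
      co$day <- d
      co$model <- m
      co$cumulative <- ifelse(co$term == "block",
                              co$estimate * (n_blocks - 1), NA)
      co$approx_ms <- if (m %in% c("tpm", "lmm"))
        ifelse(co$term == "(Intercept)", NA,
               exp(b0 + ifelse(is.na(co$cumulative), co$estimate,
                               co$cumulative)) - exp(b0))
      else NA
      rows[[length(rows) + 1L]] <- co
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("day", "model", "term", "estimate", "se", "cumulative",
          "approx_ms")]
}

#' Power-mean exponent sensitivity sweep
#'
#' Recomputes the weighted-fuel predictor for each exponent, reruns the
#' refined cross-validation once per exponent (labelling the variant
#' `WFp=<p>`), and summarises each variant's inclusion among top-ranked
#' specs and the mean MSD of the full spec.
#'
#' @param dataset a `drt_dataset` after exclusions.
#' @param plan a [make_folds()] plan.
#' @param exponents power-mean exponents (default 1/8, 1/4, 2, 4).
#' @param other_predictors further optional predictors swept alongside the
#'   weighted-fuel variant.
#' @param family `"lmm"` or `"tpm"`.
#' @return list with one element per exponent: the `cv_result`, its
#'   [rank_and_stability()] summary, the weighted-fuel inclusion frequency
#'   among top specs, and the mean MSD of the spec containing all
#'   predictors.
#' @export
exponent_sweep <- function(dataset, plan,
                           exponents = c(1 / 8, 1 / 4, 2, 4),
                           other_predictors = c("hho3s_z", "far3s_z"),
                           family = c("lmm", "tpm")) {
  family <- match.arg(family)
  out <- list()
  for (p in exponents) {
    feats <- build_feature_table(dataset, windows = 3, exponent = p,
                                 standardize = TRUE)
    feats <- feats[!is.na(feats$weightfuel_z), ]
    wf_name <- "weightfuel_z"
    specs <- enumerate_specs(c(wf_name, other_predictors),
                             response = "logRT",
                             family = if (family == "tpm")
                               "two_part_lognormal" else "linear")
    cv <- normalize_msd(run_cv(feats, specs, plan, response = "logRT",
                               family = family))
    rs <- rank_and_stability(cv, top_frac = 0.25)
    full <- paste(c("difficulty", "block", wf_name, other_predictors),
                  collapse = "+")
    out[[paste0("p=", format(p))]] <- list(
      exponent = p, cv = cv, summary = rs,
      wf_inclusion_top = rs$inclusion[wf_name, "overall"],
      full_spec_msd = rs$ranking$msd[rs$ranking$predictors == full])
  }
  out
}

#' Count UAV explosions after each prompt
#'
#' Adds `mr_post5`: the number of Miss Refuel (crash) events in the
#' `window` seconds after each DRT prompt — the observable indicator of
#' cognitive overload.
#'
#' @param features feature table (or trial table).
#' @param events task-event log.
#' @param window seconds after the prompt (default 5).
#' @return `features` with the `mr_post5` column.
#' @export
explosion_counts <- function(features, events, window = 5) {
  mr <- events[events$event_type == "MR", ]
  tk <- paste(features$participant_id, features$day, features$block)
  mr_split <- split(mr$t, paste(mr$participant_id, mr$day, mr$block))
  out <- integer(nrow(features))
  for (key in unique(tk)) {
    idx <- which(tk == key)
    tt <- mr_split[[key]]
    if (is.null(tt)) next
    tt <- sort(tt)
    out[idx] <- findInterval(features$prompt_t[idx] + window + 1e-9, tt) -
      findInterval(features$prompt_t[idx] + 1e-9, tt)
  }
  features$mr_post5 <- out
  features
}

#' Event-based vs refined predictors of cognitive overload
#'
#' Fits two zero-inflated Poisson models of the number of exploded UAVs in
#' the 5 s after the DRT prompt — one with the event-occurrence flags
#' (HHO, FAHO, FAR, HR in the 3 s window), one with the refined set
#' (weighted fuel, HHO and FAR counts) — each with difficulty and block,
#' separately per day, and reports AIC/BIC with the winner.
#'
#' @param features feature table with `mr_post5` (see
#'   [explosion_counts()]).
#' @param event_terms,refined_terms predictor sets to compare.
#' @return data frame: day, model, AIC, BIC, winner flags; attribute
#'   `fits` carries the underlying `wcv_fit`s.
#' @export
overload_comparison <- function(features,
                                event_terms = c("hho_w3", "faho_w3",
                                                "far_w3", "hr_w3"),
                                refined_terms = c("weightfuel_z",
                                                  "hho3s_z", "far3s_z")) {
  stopifnot("mr_post5" %in% names(features))
  rows <- list(); fits <- list()
  for (d in sort(unique(features$day))) {
    sub <- features[features$day == d, ]
    sub <- sub[!is.na(sub$weightfuel_z), ]
    for (set in c("event", "refined")) {
      terms <- c(if (set == "event") event_terms else refined_terms,
                 "difficulty", "block")
      fit <- fit_zip(model_spec("explosions", "zero_inflated_poisson",
                                terms), sub)
      fits[[paste(set, d)]] <- fit
      ic <- if ("degenerate" %in% fit$flags)
        c(AIC = NA_real_, BIC = NA_real_) else information_criteria(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        day = d, model = set, AIC = ic[["AIC"]], BIC = ic[["BIC"]],
        degenerate = "degenerate" %in% fit$flags)
    }
  }
  out <- do.call(rbind, rows)
  out$best_AIC <- suppressWarnings(
    ave(out$AIC, out$day, FUN = function(z) {
      if (all(is.na(z))) return(rep(NA_real_, length(z)))
      as.numeric(z == min(z, na.rm = TRUE))
    })) > 0
  attr(out, "fits") <- fits
  out
}
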