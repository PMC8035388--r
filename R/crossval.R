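# Between-subject cross-validated model selection: participant folds,
# exhaustive additive predictor-subset enumeration, train-on-one-fold /
# test-on-the-pooled-rest prediction, MSD/NMSD scoring, ranking and
# per-fold stability. The inverted 20/80 split (train one fold of ~20% of
# participants, test on the remaining 80%) is the default; a conventional
# 80/20 split is available with `invert = FALSE`.

#' Assign participants to cross-validation folds
#'
#' Random, seeded partition into `k` folds of as-equal-as-possible size
#' (sizes differ by at most one).
#'
#' @param participants vector of participant ids.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return a `fold_plan` data frame: participant_id, fold.
#' @examples
#' table(make_folds(sprintf("P%02d", 1:39), 5, seed = 1)$fold)  # 8,8,8,8,7
#' @export
make_folds <- function(participants, k = 5, seed = 1) {
  participants <- unique(participants)
  n <- length(participants)
  if (n < k) stop("fewer participants than folds")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  perm <- sample(participants)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  structure(data.frame(participant_id = perm,
                       fold = rep(seq_len(k), times = sizes)),
            class = c("fold_plan", "data.frame"))
}

#' Enumerate candidate model specifications
#'
#' All `2^m` subsets of the `m` optional predictors, each fit together
#' with the always-included terms (difficulty and block by default), plus
#' four baseline models: difficulty + block, block only, difficulty only,
#' and intercept only. Additive fixed effects and a participant random
#' intercept throughout.
#'
#' @param optional_predictors character vector of optional predictor
#'   column names.
#' @param always terms included in every non-baseline spec.
#' @param response,family passed to [model_spec()].
#' @return list of [model_spec()]s; with `m` optional predictors,
#'   `2^m + 4` specs.
#' @export
enumerate_specs <- function(optional_predictors,
                            always = c("difficulty", "block"),
                            response = "logRT", family = "linear") {
  stopifnot(!anyDuplicated(optional_predictors))
  m <- length(optional_predictors)
  specs <- list()
  if (m > 0) {
    for (i in seq_len(2^m) - 1L) {
      incl <- optional_predictors[bitwAnd(i, 2^(seq_len(m) - 1L)) > 0]
      specs[[length(specs) + 1L]] <-
        model_spec(response, family, c(always, incl))
    }
  }
  baselines <- list(always, always[2], always[1], character(0))
  for (b in baselines)
    specs[[length(specs) + 1L]] <- model_spec(response, family, b)
  specs
}

#' Run the between-subject cross-validation
#'
#' For each training fold and candidate spec: fit on the training
#' participants only, predict the held-out participants with fixed effects
#' alone, and record the mean squared deviation (MSD) between observed and
#' predicted response — log-RT for the linear and two-part families
#' (responded trials only), the 0/1 omission indicator against the
#' predicted probability for the binomial family.
#'
#' @param data per-trial model frame (feature table) containing the
#'   response columns and every predictor named by the specs.
#' @param specs list of [model_spec()]s, e.g. from [enumerate_specs()].
#' @param plan a [make_folds()] plan.
#' @param response `"logRT"` or `"omission"`.
#' @param family `"lmm"`, `"glmm"` or `"tpm"` (the two-part path scores
#'   log-RT only).
#' @param invert if TRUE (default) each fold in turn is the training set
#'   and the pooled remaining folds the test set; if FALSE the conventional
#'   direction.
#' @return a `cv_result` data frame: fold, spec, predictors, msd, plus
#'   attributes carrying the spec list.
#' @export
run_cv <- function(data, specs, plan, response = c("logRT", "omission"),
                   family = c("lmm", "glmm", "tpm"), invert = TRUE) {
  response <- match.arg(response)
  family <- match.arg(family)
  data <- prepare_model_frame(data)
  if (response == "logRT" && family == "glmm")
    stop("glmm path scores omissions; use lmm or tpm for logRT")
  if (response == "omission" && family != "glmm")
    stop("omissions are scored with the binomial glmm path")
  folds <- sort(unique(plan$fold))
  rows <- list()
  for (f in folds) {
    train_ids <- plan$participant_id[plan$fold == f]
    if (!invert) train_ids <- plan$participant_id[plan$fold != f]
    train <- data[data$participant_id %in% train_ids, , drop = FALSE]
    test <- data[!(data$participant_id %in% train_ids), , drop = FALSE]
    if (response == "logRT") {
      train_fit <- train[train$omission == 0 & !is.na(train$rt_ms), ,
                         drop = FALSE]
      test <- test[test$omission == 0 & !is.na(test$rt_ms), , drop = FALSE]
      obs <- log(test$rt_ms)
    } else {
      train_fit <- train
      obs <- test$omission
    }
    for (s in seq_along(specs)) {
      spec <- specs[[s]]
      msd <- tryCatch({
        fit <- switch(family,
                      lmm = fit_lmm(spec, train_fit),
                      tpm = fit_tpm(spec, train),
                      glmm = fit_glmm(spec, train_fit))
        pred <- predict_fixed(fit, test)
        mean((obs - pred)^2)
      }, error = function(e) {
        warning(sprintf("fold %d, spec '%s': fit failed (%s)", f,
                        spec$label, conditionMessage(e)))
        NA_real_
      })
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, spec = spec$label,
        predictors = paste(spec$fixed_terms, collapse = "+"),
        msd = msd)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "specs") <- specs
  attr(out, "response") <- response
  attr(out, "family") <- family
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Normalize MSD to NMSD
#'
#' Subtracts a centering constant from every (fold, spec) MSD cell. The
#' default centers on the grand mean over all folds and specs of the
#' analysis, which preserves nonzero differences between per-spec means;
#' `center = "per_fold"` instead subtracts each fold's across-spec mean,
#' removing between-fold level differences. Ranking of per-spec means is
#' unchanged by grand-mean centering.
#'
#' @param cv a `cv_result` from [run_cv()].
#' @param center `"grand"` or `"per_fold"`.
#' @return the `cv_result` with an `nmsd` column.
#' @export
normalize_msd <- function(cv, center = c("grand", "per_fold")) {
  center <- match.arg(center)
  if (center == "grand") {
    cv$nmsd <- cv$msd - mean(cv$msd, na.rm = TRUE)
  } else {
    cv$nmsd <- cv$msd - ave(cv$msd, cv$fold,
                            FUN = function(z) mean(z, na.rm = TRUE))
  }
  cv
}

spec_has <- function(predictors, term) {
  vapply(strsplit(predictors, "+", fixed = TRUE),
         function(z) term %in% z, logical(1))
}

#' Rank specs and summarise per-fold stability
#'
#' Orders specs by increasing mean NMSD across folds and reports, for each
#' optional predictor, its inclusion frequency among the top-decile specs
#' overall and within each fold's own ranking; folds whose top set
#' disagrees with the overall top set are flagged.
#'
#' @param cv a `cv_result` with NMSD (see [normalize_msd()]).
#' @param top_frac fraction of specs counted as "top" (default 0.1, at
#'   least one spec).
#' @return list: `ranking` (spec table sorted by mean NMSD), `inclusion`
#'   (per-predictor top-set inclusion frequencies, overall and per fold),
#'   `discordant_folds`, `best_spec_by_fold`.
#' @export
rank_and_stability <- function(cv, top_frac = 0.1) {
  if (is.null(cv$nmsd)) cv <- normalize_msd(cv)
  agg <- aggregate(cbind(msd, nmsd) ~ spec + predictors, data = cv,
                   FUN = function(z) mean(z, na.rm = TRUE), na.action = NULL)
  agg <- agg[order(agg$nmsd), ]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  terms <- unique(unlist(strsplit(agg$predictors, "+", fixed = TRUE)))
  terms <- setdiff(terms, "")
  n_top <- max(1L, floor(nrow(agg) * top_frac))
  top_overall <- agg$predictors[seq_len(n_top)]
  folds <- sort(unique(cv$fold))
  incl <- lapply(terms, function(term) {
    per_fold <- vapply(folds, function(f) {
      sub <- cv[cv$fold == f & !is.na(cv$msd), ]
      sub <- sub[order(sub$msd), ]
      mean(spec_has(sub$predictors[seq_len(min(n_top, nrow(sub)))], term))
    }, numeric(1))
    c(overall = mean(spec_has(top_overall, term)),
      setNames(per_fold, paste0("fold", folds)))
  })
  inclusion <- do.call(rbind, incl)
  rownames(inclusion) <- terms
  best_by_fold <- vapply(folds, function(f) {
    sub <- cv[cv$fold == f & !is.na(cv$msd), ]
    sub$predictors[which.min(sub$msd)]
  }, character(1))
  discordant <- folds[best_by_fold != agg$predictors[1]]
  list(ranking = agg,
       inclusion = as.data.frame(inclusion),
       discordant_folds = discordant,
       best_spec_by_fold = setNames(best_by_fold, paste0("fold", folds)))
}
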