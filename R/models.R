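# Model fitting: random-intercept LMMs for log-RT, binomial/Poisson GLMMs,
# two-part log-normal models (independent occurrence and intensity
# sub-models) and zero-inflated Poisson fits, all by maximum likelihood so
# AIC/BIC are comparable across fixed-effect sets. lme4 and glmmTMB stand
# behind the standard fits; the two-part composition, information-criteria
# bookkeeping and fixed-effects-only prediction are defined here.

#' Model specification
#'
#' @param response one of `"logRT"`, `"omission"`, `"event_count"`,
#'   `"points"`, `"explosions"`.
#' @param family one of `"linear"`, `"binomial"`, `"poisson"`,
#'   `"two_part_lognormal"`, `"zero_inflated_poisson"`.
#' @param fixed_terms character vector of fixed-effect terms (additive).
#'   `"difficulty"` is coded as a factor with 3 UAVs as the reference level
#'   (dummies = +2 UAVs, +4 UAVs). Interactions may be given with `:` or
#'   `*` notation for the descriptive ladders.
#' @param random include a participant random intercept?
#' @param label optional display label.
#' @return a `model_spec`.
#' @export
model_spec <- function(response, family, fixed_terms = character(0),
                       random = TRUE, label = NULL) {
  response <- match.arg(response, c("logRT", "omission", "event_count",
                                    "points", "explosions"))
  family <- match.arg(family, c("linear", "binomial", "poisson",
                                "two_part_lognormal",
                                "zero_inflated_poisson"))
  if (is.null(label))
    label <- if (length(fixed_terms))
      paste(fixed_terms, collapse = "+") else "1"
  structure(list(response = response, family = family,
                 fixed_terms = fixed_terms, random = random,
                 label = label),
            class = "model_spec")
}

response_var <- function(response) {
  switch(response,
         logRT = "log(rt_ms)",
         omission = "omission",
         event_count = "n_events",
         points = "points",
         explosions = "mr_post5")
}

spec_formula <- function(spec, random = spec$random) {
  rhs <- if (length(spec$fixed_terms))
    paste(spec$fixed_terms, collapse = " + ") else "1"
  if (random) rhs <- paste(rhs, "+ (1 | participant_id)")
  as.formula(paste(response_var(spec$response), "~", rhs))
}

# difficulty as a factor with 3 UAVs as the reference level
prepare_model_frame <- function(data) {
  if ("difficulty" %in% names(data) && !is.factor(data$difficulty))
    data$difficulty <- factor(data$difficulty, levels = c(3, 5, 7))
  data
}

new_fit <- function(spec, fit, ll, k, n, extra = list()) {
  co <- if (inherits(fit, "merMod")) {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               row.names = NULL)
  } else if (inherits(fit, c("lm", "glm"))) {
    s <- summary(fit)$coefficients
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               row.names = NULL)
  } else NULL
  vc <- if (inherits(fit, "merMod")) {
    v <- as.data.frame(lme4::VarCorr(fit))
    setNames(v$vcov, paste(v$grp, ifelse(is.na(v$var1), "", v$var1)))
  } else NULL
  structure(c(list(spec = spec, fit = fit, coefficients = co,
                   varcomp = vc, loglik = ll, k = k, n = n,
                   AIC = -2 * ll + 2 * k, BIC = -2 * ll + k * log(n)),
              extra),
            class = "wcv_fit")
}

#' @export
print.wcv_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s ~ %s\n", x$spec$family, x$spec$response,
              x$spec$label))
  cat(sprintf("  logLik %.2f  k %d  n %d  AIC %.1f  BIC %.1f\n",
              x$loglik, x$k, x$n, x$AIC, x$BIC))
  if (!is.null(x$flags) && length(x$flags))
    cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

mer_flags <- function(fit) {
  flags <- character(0)
  msgs <- fit@optinfo$conv$lme4$messages
  if (!is.null(msgs)) flags <- c(flags, "non-convergence")
  if (lme4::isSingular(fit)) flags <- c(flags, "singular-variance")
  flags
}

#' Fit a random-intercept linear mixed model
#'
#' Maximum likelihood (not REML), so information criteria are comparable
#' across models differing in fixed effects. With `random = FALSE` the fit
#' reduces to ordinary least squares.
#'
#' @param spec a [model_spec()] with `family = "linear"`.
#' @param data model frame; `logRT` responses use `log(rt_ms)`.
#' @return a `wcv_fit`: coefficients and SEs, variance components, exact
#'   log-likelihood, AIC/BIC (k counts fixed effects plus variance
#'   components), convergence flags.
#' @export
fit_lmm <- function(spec, data) {
  data <- prepare_model_frame(data)
  if (spec$random) {
    fit <- suppressMessages(lme4::lmer(
      spec_formula(spec), data = data, REML = FALSE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
    ll <- as.numeric(logLik(fit))
    k <- attr(logLik(fit), "df")
    new_fit(spec, fit, ll, k, nobs(fit), list(flags = mer_flags(fit)))
  } else {
    fit <- lm(spec_formula(spec, random = FALSE), data = data)
    ll <- as.numeric(logLik(fit))
    new_fit(spec, fit, ll, attr(logLik(fit), "df"), nobs(fit),
            list(flags = character(0)))
  }
}

#' Fit a random-intercept generalized linear mixed model
#'
#' Logit link for binomial responses (per-trial Bernoulli), log link for
#' Poisson counts; the participant intercept is integrated by the Laplace
#' approximation. With `random = FALSE` the fit reduces to a GLM.
#'
#' @param spec a [model_spec()] with family `"binomial"` or `"poisson"`.
#' @param data model frame.
#' @return a `wcv_fit`.
#' @export
fit_glmm <- function(spec, data) {
  data <- prepare_model_frame(data)
  fam <- switch(spec$family, binomial = binomial(), poisson = poisson(),
                stop("fit_glmm requires a binomial or poisson spec"))
  if (spec$random) {
    fit <- suppressMessages(lme4::glmer(
      spec_formula(spec), data = data, family = fam,
      control = lme4::glmerControl(calc.derivs = FALSE,
                                   check.conv.singular = "ignore")))
    ll <- as.numeric(logLik(fit))
    k <- attr(logLik(fit), "df")
    new_fit(spec, fit, ll, k, nobs(fit), list(flags = mer_flags(fit)))
  } else {
    fit <- glm(spec_formula(spec, random = FALSE), data = data,
               family = fam)
    ll <- as.numeric(logLik(fit))
    new_fit(spec, fit, ll, attr(logLik(fit), "df"), nobs(fit),
            list(flags = character(0)))
  }
}

#' Fit a two-part log-normal model
#'
#' Joint model for semicontinuous DRT outcomes: a Bernoulli occurrence
#' sub-model for omissions (logit link) and a log-normal intensity
#' sub-model for RTs on responded trials, each with its own fixed effects
#' and an independent participant random intercept. Because the sub-models
#' share no parameters, the joint log-likelihood is exactly the sum of the
#' two sub-likelihoods.
#'
#' @param spec a [model_spec()] with `family = "two_part_lognormal"`;
#'   `fixed_terms` are used in both sub-models.
#' @param data model frame with `rt_ms` and `omission` columns.
#' @return a `wcv_fit` with `$occurrence` and `$intensity` sub-fits.
#' @export
fit_tpm <- function(spec, data) {
  data <- prepare_model_frame(data)
  # constant occurrence (e.g. no omissions at all) cannot support a random
  # intercept; fall back to the plain GLM for that degenerate sub-model
  occ_random <- spec$random && length(unique(data$omission)) > 1
  occ_spec <- model_spec("omission", "binomial", spec$fixed_terms,
                         occ_random, paste0(spec$label, " (occurrence)"))
  int_spec <- model_spec("logRT", "linear", spec$fixed_terms,
                         spec$random, paste0(spec$label, " (intensity)"))
  occ <- suppressWarnings(fit_glmm(occ_spec, data))
  int <- fit_lmm(int_spec, data[data$omission == 0, , drop = FALSE])
  # no shared parameters: the joint likelihood factorizes exactly
  ll <- occ$loglik + int$loglik
  new_fit(spec, NULL, ll, occ$k + int$k, nrow(data),
          list(occurrence = occ, intensity = int,
               flags = unique(c(occ$flags, int$flags))))
}

#' Fit a zero-inflated Poisson model
#'
#' Mixture of structural zeros (logit sub-model) and a Poisson count
#' sub-model (log link) with shared covariates; the participant random
#' intercept enters the count part.
#'
#' @param spec a [model_spec()] with `family = "zero_inflated_poisson"`;
#'   the response column is `mr_post5` (UAV explosions in the 5 s after
#'   the prompt).
#' @param data model frame.
#' @return a `wcv_fit`; `$flags` contains `"degenerate"` when the response
#'   is all zeros.
#' @export
fit_zip <- function(spec, data) {
  data <- prepare_model_frame(data)
  if (all(data$mr_post5 == 0)) {
    return(new_fit(spec, NULL, NA_real_, 0L, nrow(data),
                   list(flags = "degenerate")))
  }
  rhs <- if (length(spec$fixed_terms))
    paste(spec$fixed_terms, collapse = " + ") else "1"
  zif <- as.formula(paste("~", rhs))
  f <- as.formula(paste("mr_post5 ~", rhs,
                        if (spec$random) "+ (1 | participant_id)" else ""))
  fit <- suppressWarnings(glmmTMB::glmmTMB(
    f, ziformula = zif, family = poisson(), data = data))
  ll <- as.numeric(logLik(fit))
  k <- attr(logLik(fit), "df")
  flags <- if (isTRUE(fit$sdr$pdHess)) character(0) else "non-convergence"
  co <- tryCatch({
    s <- summary(fit)$coefficients$cond
    data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
               row.names = NULL)
  }, error = function(e) NULL)
  out <- new_fit(spec, fit, ll, k, nobs(fit), list(flags = flags))
  if (!is.null(co)) out$coefficients <- co
  out
}

#' Information criteria
#'
#' `AIC = -2 loglik + 2 k`, `BIC = -2 loglik + k log(n)`; `k` counts all
#' estimated parameters, variance components included. Model differences
#' of 2-7 indicate some support for the poorer model, larger differences
#' essentially none.
#'
#' @param fit a `wcv_fit`.
#' @return named vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(fit) {
  if (fit$n == 0) stop("no observations")
  c(AIC = -2 * fit$loglik + 2 * fit$k,
    BIC = -2 * fit$loglik + fit$k * log(fit$n))
}

#' Information-criteria comparison of several fits
#'
#' @param fits named list of `wcv_fit`s fit to the same data.
#' @return data frame with AIC/BIC, differences to the best model, and
#'   best-model markers per criterion.
#' @export
ic_table <- function(fits) {
  tab <- data.frame(
    model = if (!is.null(names(fits))) names(fits)
            else vapply(fits, function(f) f$spec$label, character(1)),
    AIC = vapply(fits, function(f) unname(information_criteria(f)["AIC"]),
                 numeric(1)),
    BIC = vapply(fits, function(f) unname(information_criteria(f)["BIC"]),
                 numeric(1)))
  tab$dAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  tab$dBIC <- tab$BIC - min(tab$BIC, na.rm = TRUE)
  tab$best_AIC <- tab$dAIC == 0
  tab$best_BIC <- tab$dBIC == 0
  tab
}

#' Fixed-effects-only prediction for unseen participants
#'
#' Predicts using fixed effects alone: random intercepts of unseen
#' participants are set to their population mean of zero, so predictions
#' do not depend on which participant a row belongs to. Binomial
#' predictions are probabilities, linear predictions log-RT, two-part
#' predictions the intensity sub-model's log-RT.
#'
#' @param fit a `wcv_fit`.
#' @param newdata model frame for participants not seen in training.
#' @return numeric vector of predictions.
#' @export
predict_fixed <- function(fit, newdata) {
  newdata <- prepare_model_frame(newdata)
  if (identical(fit$spec$family, "two_part_lognormal"))
    return(predict_fixed(fit$intensity, newdata))
  m <- fit$fit
  if (inherits(m, "merMod")) {
    unname(predict(m, newdata = newdata, re.form = NA,
                   type = "response"))
  } else if (inherits(m, "glm")) {
    unname(predict(m, newdata = newdata, type = "response"))
  } else if (inherits(m, "lm")) {
    unname(predict(m, newdata = newdata))
  } else stop("cannot predict from this fit")
}
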