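test_that("fixed-effects fit with no random term matches closed-form least squares", {
  d <- toy_model_frame(tau = 0)
  spec <- model_spec("logRT", "linear", "x", random = FALSE)
  fit <- fit_lmm(spec, d)
  X <- cbind(1, d$x)
  beta <- solve(t(X) %*% X, t(X) %*% log(d$rt_ms))  # (X'X)^-1 X'y oracle
  expect_equal(unname(fit$coefficients$estimate), as.numeric(beta),
               tolerance = 1e-10)
  # mixed fit on exchangeable data pins the intercept variance near 0
  fitm <- fit_lmm(model_spec("logRT", "linear", "x"), d)
  expect_lt(fitm$varcomp[["participant_id (Intercept)"]], 1e-4)
  expect_equal(fitm$coefficients$estimate, fit$coefficients$estimate,
               tolerance = 1e-3)
})

test_that("constant response collapses to a degenerate intercept fit", {
  d <- toy_model_frame()
  d$rt_ms <- exp(6)
  fit <- fit_lmm(model_spec("logRT", "linear", character(0)), d)
  expect_equal(fit$coefficients$estimate[1], 6)
  expect_lt(sum(fit$varcomp), 1e-8)
})

test_that("intercept-only GLMs recover link-transformed means", {
  d <- data.frame(participant_id = "S1",
                  omission = rep(c(1L, 0L), c(30, 70)),
                  n_events = rpois(100, 2))
  fitb <- fit_glmm(model_spec("omission", "binomial", character(0),
                              random = FALSE), d)
  expect_equal(fitb$coefficients$estimate[1], qlogis(0.3),
               tolerance = 1e-8)
  fitp <- fit_glmm(model_spec("event_count", "poisson", character(0),
                              random = FALSE), d)
  expect_equal(fitp$coefficients$estimate[1], log(mean(d$n_events)),
               tolerance = 1e-8)
})

test_that("two-part likelihood factorizes and reduces to the LMM without omissions", {
  d <- toy_model_frame(tau = 0.1)
  tpm <- fit_tpm(model_spec("logRT", "two_part_lognormal", "x"), d)
  expect_equal(tpm$loglik, tpm$occurrence$loglik + tpm$intensity$loglik)
  expect_identical(tpm$k, tpm$occurrence$k + tpm$intensity$k)
  # no omissions: intensity coefficients equal the plain LMM's
  d0 <- d; d0$omission <- 0L
  tpm0 <- fit_tpm(model_spec("logRT", "two_part_lognormal", "x"), d0)
  lmm0 <- fit_lmm(model_spec("logRT", "linear", "x"), d0)
  expect_equal(tpm0$intensity$coefficients$estimate,
               lmm0$coefficients$estimate, tolerance = 1e-10)
  # covariate-free occurrence part: intercept = logit of omission rate
  tpm1 <- fit_tpm(model_spec("logRT", "two_part_lognormal", character(0),
                             random = FALSE), d)
  expect_equal(tpm1$occurrence$coefficients$estimate[1],
               qlogis(mean(d$omission)), tolerance = 1e-6)
})

test_that("TPM and LMM intensity coefficients agree on simulated study data", {
  st <- small_study()
  ds <- exclude_trials(exclude_participants(
    new_dataset(st$events, st$drt, st$snapshots)))
  ft <- build_feature_table(ds, windows = 3, standardize = TRUE,
                            compute_ordfuel = FALSE)
  terms <- c("difficulty", "block", "weightfuel_z", "hho3s_z")
  tpm <- fit_tpm(model_spec("logRT", "two_part_lognormal", terms), ft)
  lmm <- fit_lmm(model_spec("logRT", "linear", terms),
                 ft[ft$omission == 0, ])
  expect_equal(tpm$intensity$coefficients$estimate,
               lmm$coefficients$estimate, tolerance = 1e-3)
})

test_that("information criteria follow their definitions and deltas", {
  f <- list(spec = model_spec("logRT", "linear"), loglik = -100,
            k = 3L, n = 100L)
  class(f) <- "wcv_fit"
  ic <- information_criteria(f)
  expect_equal(unname(ic["AIC"]), 206)
  expect_equal(unname(ic["BIC"]), 200 + 3 * log(100))
  tab <- ic_table(list(a = f, b = f))
  expect_equal(tab$dAIC, c(0, 0))
  expect_true(all(tab$best_AIC))
  f$n <- 0L
  expect_error(information_criteria(f), "no observations")
})

test_that("adding a predictor never decreases the maximized log-likelihood", {
  d <- toy_model_frame(tau = 0.15)
  d$z <- rnorm(nrow(d))
  lls <- sapply(list(character(0), "x", c("x", "z")), function(tm)
    fit_lmm(model_spec("logRT", "linear", tm), d)$loglik)
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("fixed-effects prediction ignores participant identity", {
  d <- toy_model_frame(tau = 0.3)
  fit <- fit_lmm(model_spec("logRT", "linear", "x"), d)
  nd <- data.frame(x = c(-1, 0, 1), participant_id = "UNSEEN1")
  nd2 <- nd; nd2$participant_id <- c("U2", "U3", "U4")
  expect_identical(predict_fixed(fit, nd), predict_fixed(fit, nd2))
  # intercept-only: constant prediction for every new row
  fit0 <- fit_lmm(model_spec("logRT", "linear", character(0)), d)
  p0 <- predict_fixed(fit0, nd)
  expect_equal(p0, rep(fit0$coefficients$estimate[1], 3))
  # binomial with intercept 0 predicts probability one half
  db <- data.frame(participant_id = rep(c("a", "b"), each = 50),
                   omission = rep(c(0L, 1L), 50))
  fb <- fit_glmm(model_spec("omission", "binomial", character(0),
                            random = FALSE), db)
  expect_equal(predict_fixed(fb, nd)[1], 0.5, tolerance = 1e-8)
})

test_that("zero-inflated Poisson reduces to Poisson without inflation and flags degenerate data", {
  set.seed(14)
  d <- data.frame(participant_id = rep(sprintf("S%d", 1:6), each = 60))
  d$x <- rnorm(nrow(d))
  d$mr_post5 <- rpois(nrow(d), exp(-0.5 + 0.4 * d$x))
  zip <- fit_zip(model_spec("explosions", "zero_inflated_poisson", "x",
                            random = FALSE), d)
  pois <- fit_glmm(model_spec("event_count", "poisson", "x",
                              random = FALSE),
                   transform(d, n_events = mr_post5))
  co <- zip$coefficients
  expect_equal(co$estimate[co$term == "x"],
               pois$coefficients$estimate[2], tolerance = 0.1)
  d0 <- d; d0$mr_post5 <- 0L
  z0 <- fit_zip(model_spec("explosions", "zero_inflated_poisson", "x"), d0)
  expect_true("degenerate" %in% z0$flags)
})

test_that("recovery: study-scale fit returns generative coefficients within 3 SE", {
  cfg <- task_config(block_duration = 60, n_blocks = 9)
  st <- simulate_study(12, config = cfg, seed = 31, n_days = 2)
  ds <- exclude_trials(exclude_participants(
    new_dataset(st$events, st$drt, st$snapshots)))
  ft <- build_feature_table(ds, windows = 3, compute_ordfuel = FALSE)
  tru <- st$truth
  ft$wf_s <- (ft$weightfuel - tru$wf_center) / tru$wf_scale
  fit <- fit_lmm(model_spec("logRT", "linear",
                            c("difficulty", "block", "wf_s", "hho3s",
                              "far3s")),
                 ft[ft$omission == 0, ])
  co <- fit$coefficients
  truth <- c(difficulty5 = tru$beta_difficulty[1],
             difficulty7 = tru$beta_difficulty[2],
             block = tru$beta_block,
             wf_s = tru$beta_weightfuel,
             hho3s = tru$beta_hho3s,
             far3s = tru$beta_far3s)
  for (term in names(truth)) {
    est <- co$estimate[co$term == term]
    se <- co$se[co$term == term]
    expect_lt(abs(est - truth[[term]]), 3 * se)
  }
  # omission sub-model recovery via the binomial GLMM
  gfit <- fit_glmm(model_spec("omission", "binomial",
                              c("difficulty", "block", "wf_s", "hho3s",
                                "far3s", "missprevdrt")), ft)
  gco <- gfit$coefficients
  gtruth <- c(wf_s = tru$gamma_weightfuel,
              missprevdrt = tru$gamma_missprev)
  for (term in names(gtruth)) {
    est <- gco$estimate[gco$term == term]
    se <- gco$se[gco$term == term]
    expect_lt(abs(est - gtruth[[term]]), 3 * se)
  }
})
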