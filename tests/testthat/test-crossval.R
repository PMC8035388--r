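test_that("folds partition participants into near-equal groups", {
  p39 <- sprintf("P%02d", 1:39)  # study size after day-1 removals
  f <- make_folds(p39, 5, seed = 3)
  expect_setequal(as.integer(table(f$fold)), c(8, 8, 8, 8, 7))
  expect_setequal(f$participant_id, p39)
  p46 <- sprintf("P%02d", 1:46)
  f2 <- make_folds(p46, 5, seed = 3)
  expect_setequal(as.integer(table(f2$fold)), c(10, 9, 9, 9, 9))
  expect_identical(make_folds(p46, 5, seed = 3), f2)
  expect_error(make_folds(p39[1:4], 5), "fewer participants")
})

test_that("spec enumeration counts 2^m subsets plus four baselines", {
  s5 <- enumerate_specs(paste0("e", 1:5))
  expect_length(s5, 36)
  s6 <- enumerate_specs(paste0("e", 1:6))
  expect_length(s6, 68)
  s0 <- enumerate_specs(character(0))
  expect_length(s0, 4)
  expect_setequal(vapply(s0, `[[`, character(1), "label"),
                  c("difficulty+block", "block", "difficulty", "1"))
  # every non-baseline spec carries the always-included terms
  expect_true(all(vapply(s5[1:32], function(s)
    all(c("difficulty", "block") %in% s$fixed_terms), logical(1))))
})

test_that("deterministic responses give zero out-of-sample MSD", {
  d <- expand.grid(trial = 1:20,
                   participant_id = sprintf("S%d", 1:10))
  d$rt_ms <- exp(6)
  d$omission <- 0L
  plan <- make_folds(unique(d$participant_id), 5, seed = 1)
  cv <- suppressWarnings(  # lm warns about the intentionally perfect fit
    run_cv(d, list(model_spec("logRT", "linear", character(0),
                              random = FALSE)),
           plan, "logRT", "lmm"))
  expect_equal(cv$msd, rep(0, 5), tolerance = 1e-12)
})

test_that("intercept-only test MSD obeys the bias-variance identity", {
  set.seed(5)
  d <- expand.grid(trial = 1:30, participant_id = sprintf("S%d", 1:6))
  d$rt_ms <- exp(rnorm(nrow(d), 6, 0.3))
  d$omission <- 0L
  plan <- make_folds(unique(d$participant_id), 3, seed = 2)
  cv <- run_cv(d, list(model_spec("logRT", "linear", character(0),
                                  random = FALSE)),
               plan, "logRT", "lmm")
  for (f in 1:3) {
    train_ids <- plan$participant_id[plan$fold == f]
    tr <- log(d$rt_ms[d$participant_id %in% train_ids])
    te <- log(d$rt_ms[!(d$participant_id %in% train_ids)])
    oracle <- mean((te - mean(tr))^2)  # = var(te) + (mean gap)^2
    expect_equal(cv$msd[cv$fold == f], oracle, tolerance = 1e-10)
    expect_gte(oracle, mean((te - mean(te))^2) - 1e-12)
  }
})

test_that("no participant appears on both sides of any CV cell", {
  ds <- exclude_trials(exclude_participants(small_dataset()))
  ft <- build_feature_table(ds, windows = 3, standardize = TRUE,
                            compute_ordfuel = FALSE)
  ft1 <- ft[ft$day == 1, ]
  plan <- make_folds(unique(ft1$participant_id), 2, seed = 1)
  for (f in 1:2) {
    train_ids <- plan$participant_id[plan$fold == f]
    test_ids <- setdiff(unique(ft1$participant_id), train_ids)
    expect_length(intersect(train_ids, test_ids), 0)
  }
  # standardization is per participant, so it cannot leak across folds:
  # standardizing before splitting equals standardizing folds separately
  z_all <- zstandardize_within_participant(ft1$weightfuel,
                                           ft1$participant_id)
  ids1 <- plan$participant_id[plan$fold == 1]
  sub <- ft1$participant_id %in% ids1
  z_sub <- zstandardize_within_participant(ft1$weightfuel[sub],
                                           ft1$participant_id[sub])
  expect_equal(z_all[sub], z_sub)
})

test_that("NMSD recenters without changing the ranking", {
  cv <- structure(data.frame(fold = c(1, 1), spec = c("a", "b"),
                             predictors = c("a", "b"),
                             msd = c(0.5, 0.7)),
                  class = c("cv_result", "data.frame"))
  out <- normalize_msd(cv)
  expect_equal(out$nmsd, c(-0.1, 0.1))
  cv2 <- structure(data.frame(fold = rep(1:2, each = 3),
                              spec = rep(c("a", "b", "c"), 2),
                              predictors = rep(c("a", "b", "c"), 2),
                              msd = c(0.4, 0.5, 0.9, 0.2, 0.6, 0.7)),
                   class = c("cv_result", "data.frame"))
  out2 <- normalize_msd(cv2)
  m_msd <- tapply(out2$msd, out2$spec, mean)
  m_nmsd <- tapply(out2$nmsd, out2$spec, mean)
  expect_equal(cor(rank(m_msd), rank(m_nmsd)), 1)
  expect_equal(mean(out2$nmsd), 0)
  # equal MSDs give all-zero NMSD
  cv3 <- cv; cv3$msd <- c(0.5, 0.5)
  expect_equal(normalize_msd(cv3)$nmsd, c(0, 0))
  # per-fold centering zeroes each fold's mean
  pf <- normalize_msd(cv2, center = "per_fold")
  expect_equal(as.numeric(tapply(pf$nmsd, pf$fold, mean)), c(0, 0))
})

test_that("ranking and stability summaries identify included predictors", {
  cv <- structure(
    data.frame(fold = rep(1:2, each = 3),
               spec = rep(c("difficulty+block+wf", "difficulty+block",
                            "1"), 2),
               predictors = rep(c("difficulty+block+wf",
                                  "difficulty+block", "1"), 2),
               msd = c(0.1, 0.2, 0.9, 0.15, 0.25, 0.8)),
    class = c("cv_result", "data.frame"))
  rs <- rank_and_stability(normalize_msd(cv), top_frac = 0.34)
  expect_identical(rs$ranking$predictors[1], "difficulty+block+wf")
  expect_equal(rs$inclusion["wf", "overall"], 1)
  expect_length(rs$discordant_folds, 0)
  expect_true(all(rs$best_spec_by_fold == "difficulty+block+wf"))
})
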