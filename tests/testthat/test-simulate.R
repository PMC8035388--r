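test_that("block schedule makes every consecutive triple a permutation of {3,5,7}", {
  expect_error(draw_block_schedule(20, seed = 1), "divisible by 3")
  s3 <- draw_block_schedule(3, seed = 5)
  expect_setequal(s3, c(3, 5, 7))
  s21 <- draw_block_schedule(21, seed = 5)
  expect_length(s21, 21)
  for (i in seq_len(7))
    expect_setequal(s21[(3 * i - 2):(3 * i)], c(3, 5, 7))
  expect_identical(draw_block_schedule(21, seed = 5), s21)
  expect_false(identical(draw_block_schedule(21, seed = 6), s21))
})

test_that("step_dynamics moves, drains, crashes and respawns", {
  cfg <- task_config(n_uavs = 1)
  set.seed(1)
  st <- new_sim_state(cfg)
  # place away from walls, heading along +x
  st$x <- 500; st$y <- 500; st$heading <- 0; st$fuel <- 1.0
  st2 <- step_dynamics(st, dt = 1, cfg)
  expect_equal(st2$x - st$x, 75)          # 75 pixels per second
  expect_equal(st2$y, st$y)
  expect_equal(st2$fuel, 0.95)            # 5% of tank per second
  expect_null(st2$events)

  # near-empty tank: MR emitted, replacement UAV appears immediately
  st$fuel <- 0.05
  st3 <- step_dynamics(st, dt = 1, cfg)
  expect_identical(st3$events$event_type, "MR")
  expect_identical(st3$events$points, unname(cfg$payoffs[["MR"]]))
  expect_length(st3$fuel, 1)              # UAV count constant
  expect_gte(st3$fuel, cfg$spawn_fuel_range[1])
  expect_lte(st3$fuel, cfg$spawn_fuel_range[2])
  expect_false(st3$uav_id == st$uav_id)

  # reflection keeps positions inside the screen
  st$x <- cfg$screen[1] - 10; st$heading <- 0; st$fuel <- 1
  st4 <- step_dynamics(st, dt = 1, cfg)
  expect_lte(st4$x, cfg$screen[1])
  expect_equal(st4$x, cfg$screen[1] - 65)  # reflected remainder
})

test_that("score accumulates exactly the payoffs of emitted events", {
  cfg <- task_config(n_uavs = 5)
  set.seed(3)
  st <- new_sim_state(cfg)
  for (i in 1:400) st <- step_dynamics(st, 0.5, cfg)
  expect_gt(nrow(st$events), 0)            # crashes happened
  expect_identical(st$score, sum(st$events$points))
})

test_that("interaction classification follows the 25% gauge rule", {
  cfg <- task_config()
  expect_identical(classify_interaction("click", 0.20, config = cfg), "HR")
  expect_identical(classify_interaction("click", 0.30, config = cfg), "FAR")
  expect_identical(classify_interaction("click", 0.25, config = cfg), "FAR")
  expect_identical(classify_interaction("hover", 0.10, config = cfg), "HHO")
  expect_identical(classify_interaction("hover", 0.80, config = cfg), "FAHO")
  expect_true(is.na(classify_interaction("hover", 0.10, first_hover = TRUE,
                                         config = cfg)))
  expect_error(classify_interaction("click", 1.2, config = cfg), "0, 1")
})

test_that("DRT prompt cadence is uniform 3-5 s with mean near 4 s", {
  s <- generate_drt_stream(50000, NULL, workload_model(), seed = 7,
                           n_prompts = 10001)
  isi <- diff(s$prompt_t)
  expect_gte(length(isi), 10000)
  isi <- isi[1:10000]
  expect_equal(mean(isi), 4, tolerance = 0.05 / 4)
  expect_gte(min(isi), 3)
  expect_lte(max(isi), 5)
  ks <- suppressWarnings(stats::ks.test(isi, "punif", 3, 5))
  expect_gt(ks$p.value, 0.01)
})

test_that("generative DRT model reduces correctly at its boundaries", {
  # omission probability forced to ~0: no omissions
  m0 <- workload_model(gamma_intercept = -50, gamma_missprev = 0)
  s0 <- generate_drt_stream(2000, NULL, m0, seed = 3)
  expect_identical(sum(s0$omission), 0L)
  # zero covariate effects: log RT is normal(rt_intercept, residual_sd)
  rt <- log(s0$rt_ms)
  expect_equal(mean(rt), m0$rt_intercept, tolerance = 0.02)
  expect_equal(sd(rt), m0$residual_sd, tolerance = 0.1)
  # responses never exceed the response window
  expect_lte(max(s0$rt_ms), task_config()$response_window * 1000)
})

test_that("simulated studies are reproducible and participant-stable", {
  cfg <- task_config(block_duration = 30, n_blocks = 3)
  a <- simulate_study(2, config = cfg, seed = 9, n_days = 1)
  b <- simulate_study(2, config = cfg, seed = 9, n_days = 1)
  expect_identical(a$events, b$events)
  expect_identical(a$drt, b$drt)
  expect_setequal(unique(a$drt$participant_id), c("P01", "P02"))
  # adding a participant leaves earlier participants' streams untouched
  c3 <- simulate_study(3, config = cfg, seed = 9, n_days = 1)
  expect_identical(a$drt, c3$drt[c3$drt$participant_id %in% c("P01", "P02"), ])
})

test_that("an idle operator produces starvation: only crashes occur", {
  cfg <- task_config(block_duration = 120, n_blocks = 3)
  idle <- operator_policy(check_rate = 0)
  st <- simulate_study(1, config = cfg, policy = idle, seed = 4, n_days = 1)
  expect_true(all(st$events$event_type == "MR"))
  expect_gt(nrow(st$events), 0)
})

test_that("fuel stays in [0,1] everywhere and crashes increase with load", {
  st <- small_study()
  expect_true(all(st$events$fuel_at_event >= 0 &
                    st$events$fuel_at_event <= 1))
  expect_true(all(st$snapshots$fuel >= 0 & st$snapshots$fuel <= 1))
  # mean MR count per block non-decreasing in difficulty, many seeds
  cfg <- task_config(block_duration = 60)
  pol <- operator_policy()
  mr_rate <- sapply(c(3, 5, 7), function(n) {
    cfg$n_uavs <- n
    mean(sapply(1:20, function(s) {
      set.seed(1000 + s)
      ev <- workloadcv:::simulate_block_events(cfg, pol)$events
      sum(ev$event_type == "MR")
    }))
  })
  expect_true(all(diff(mr_rate) >= 0))
})
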