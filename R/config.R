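#' Task configuration for the UAV-refuelling simulator
#'
#' Bundles the fixed parameters of the refuelling task: fuel dynamics,
#' interaction scoring thresholds, screen geometry, block structure, the
#' payoff scheme and the DRT prompt timing. Defaults reproduce the study
#' conditions: fuel depletes at 5% of the tank per second, refuelling
#' succeeds only in the lower 25% of the gauge, fresh UAVs spawn with
#' 70-100% fuel, refuels restore 50-100% of a full tank, UAVs move at 75
#' pixels per second on a 1920 x 1080 screen, blocks last 120 s (21 per
#' session), and DRT prompts arrive every 3-5 s (uniform), vibrating for
#' 1 s with a 2.5 s response window.
#'
#' @param n_uavs number of UAVs on screen (3, 5 or 7; the difficulty
#'   manipulation).
#' @param fuel_drain_rate fraction of a full tank burned per second.
#' @param refuel_threshold fuel fraction below which a refuel click scores
#'   as a hit.
#' @param spawn_fuel_range interval of spawn fuel fractions for fresh UAVs.
#' @param refuel_gain_range interval of tank fractions restored by a refuel.
#' @param uav_speed UAV speed in pixels per second.
#' @param screen screen size in pixels, `c(width, height)`.
#' @param hover_min seconds a hover must be sustained to reveal the gauge.
#' @param block_duration block length in seconds.
#' @param n_blocks blocks per session (must be divisible by 3).
#' @param payoffs named vector of points per event type; must contain
#'   exactly FAHO, FAR, HHO, HR, MR.
#' @param isi_range interval (seconds) of the uniform inter-stimulus
#'   interval between DRT prompts.
#' @param stimulus_duration DRT vibration duration in seconds.
#' @param response_window seconds after prompt onset within which a response
#'   counts; later or absent responses are omissions.
#' @return an object of class `task_config` (a validated list).
#' @examples
#' cfg <- task_config(n_uavs = 5)
#' cfg$payoffs[["HR"]]
#' @export
task_config <- function(n_uavs = 5,
                        fuel_drain_rate = 0.05,
                        refuel_threshold = 0.25,
                        spawn_fuel_range = c(0.70, 1.00),
                        refuel_gain_range = c(0.50, 1.00),
                        uav_speed = 75,
                        screen = c(1920, 1080),
                        hover_min = 0.3,
                        block_duration = 120,
                        n_blocks = 21,
                        payoffs = c(FAHO = -50, FAR = -500, HHO = 50,
                                    HR = 2000, MR = -1000),
                        isi_range = c(3, 5),
                        stimulus_duration = 1,
                        response_window = 2.5) {
  stopifnot(
    n_uavs >= 1,
    fuel_drain_rate > 0, fuel_drain_rate <= 1,
    refuel_threshold > 0, refuel_threshold <= 1,
    length(spawn_fuel_range) == 2, all(spawn_fuel_range > 0),
    all(spawn_fuel_range <= 1), diff(spawn_fuel_range) >= 0,
    length(refuel_gain_range) == 2, all(refuel_gain_range > 0),
    all(refuel_gain_range <= 1), diff(refuel_gain_range) >= 0,
    uav_speed > 0, length(screen) == 2, all(screen > 0),
    hover_min > 0, block_duration > 0, n_blocks >= 1,
    length(isi_range) == 2, diff(isi_range) >= 0,
    stimulus_duration > 0, response_window > 0
  )
  if (isi_range[1] < stimulus_duration)
    stop("isi_range minimum must be at least stimulus_duration")
  if (!setequal(names(payoffs), EVENT_TYPES))
    stop("payoffs must contain exactly the five event types ",
         paste(EVENT_TYPES, collapse = ", "))
  structure(list(
    n_uavs = as.integer(n_uavs),
    fuel_drain_rate = fuel_drain_rate,
    refuel_threshold = refuel_threshold,
    spawn_fuel_range = spawn_fuel_range,
    refuel_gain_range = refuel_gain_range,
    uav_speed = uav_speed,
    screen = screen,
    hover_min = hover_min,
    block_duration = block_duration,
    n_blocks = as.integer(n_blocks),
    payoffs = payoffs[EVENT_TYPES],
    isi_range = isi_range,
    stimulus_duration = stimulus_duration,
    response_window = response_window
  ), class = "task_config")
}

#' Parametric operator policy
#'
#' A noisy-memory heuristic standing in for a human operator. The agent
#' keeps drifting internal estimates of every UAV's fuel level (reset to
#' truth on each gauge check), acts at a fixed average rate, always attends
#' to the UAV with the lowest estimated fuel, clicks directly when that
#' estimate is below its refuel trigger and hovers to check otherwise, and
#' occasionally lapses, neglecting a critical UAV. Estimate drift grows
#' with the number of UAVs on screen, emulating memory load.
#'
#' @param check_rate mean operator actions (hover or click) per second.
#' @param memory_noise standard deviation of fuel-estimate drift per
#'   square-root second, in fuel fraction, at 3 UAVs.
#' @param load_scaling multiplicative factor applied to `memory_noise` per
#'   additional UAV beyond 3.
#' @param refuel_trigger estimated-fuel threshold below which the agent
#'   clicks to refuel.
#' @param lapse_prob probability per action that an estimated-critical UAV
#'   is neglected.
#' @param verify_horizon seconds within which a previous gauge check is
#'   trusted; a low estimate older than this is re-checked (hover) before
#'   the refuel click, reproducing the natural check-then-refuel loop.
#' @return an object of class `operator_policy`.
#' @export
operator_policy <- function(check_rate = 0.6,
                            memory_noise = 0.08,
                            load_scaling = 1.15,
                            refuel_trigger = 0.25,
                            lapse_prob = 0.05,
                            verify_horizon = 4) {
  stopifnot(check_rate >= 0, memory_noise >= 0, load_scaling >= 0,
            refuel_trigger >= 0, lapse_prob >= 0, lapse_prob <= 1,
            verify_horizon >= 0)
  structure(list(check_rate = check_rate,
                 memory_noise = memory_noise,
                 load_scaling = load_scaling,
                 refuel_trigger = refuel_trigger,
                 lapse_prob = lapse_prob,
                 verify_horizon = verify_horizon),
            class = "operator_policy")
}

#' Generative workload model for DRT outcomes
#'
#' Ground truth for simulated DRT performance. Omissions follow a logistic
#' sub-model and response times, given a response, a log-normal intensity
#' sub-model truncated at the response window; both are driven by the same
#' per-prompt covariates: difficulty dummies (+2 UAVs, +4 UAVs relative to
#' 3 UAVs), block number, the weighted fuel level (power mean, scaled by
#' fixed constants `wf_center`/`wf_scale`), counts of hit hover-overs and
#' false-alarm refuels in the preceding 3 s, and (omissions only) whether
#' the previous prompt was omitted. Default magnitudes mimic the reported
#' approximate effects: roughly -40 ms of log-RT per unit of weighted fuel,
#' +40 ms per extra HHO or FAR event, +45/+65 ms for the difficulty steps
#' and ~75 ms accumulated across 21 blocks (on a ~450 ms baseline).
#'
#' Coefficients are on the natural-log scale of RT in milliseconds
#' (intensity) and on the log-odds scale (occurrence).
#'
#' @param rt_intercept baseline mean log-RT (log ms).
#' @param subject_sd SD of the participant random intercept (log ms).
#' @param beta_difficulty length-2 vector: effects of +2 and +4 UAVs.
#' @param beta_block effect per block increment (block - 1).
#' @param beta_weightfuel,beta_hho3s,beta_far3s covariate effects on log-RT;
#'   weighted fuel enters as (wf - wf_center)/wf_scale, the counts raw.
#' @param residual_sd residual SD of log-RT.
#' @param gamma_intercept,gamma_difficulty,gamma_block,gamma_weightfuel,
#'   gamma_hho3s,gamma_far3s,gamma_missprev occurrence (omission)
#'   sub-model coefficients, logit scale.
#' @param wf_center,wf_scale fixed standardization constants for the
#'   weighted-fuel covariate.
#' @param wf_exponent power-mean exponent used by the generator.
#' @return an object of class `workload_model`.
#' @export
workload_model <- function(rt_intercept = log(450),
                           subject_sd = 0.15,
                           beta_difficulty = c(0.09, 0.13),
                           beta_block = 0.0035,
                           beta_weightfuel = -0.08,
                           beta_hho3s = 0.08,
                           beta_far3s = 0.08,
                           residual_sd = 0.30,
                           gamma_intercept = qlogis(0.10),
                           gamma_difficulty = c(0.30, 0.60),
                           gamma_block = 0.010,
                           gamma_weightfuel = -0.30,
                           gamma_hho3s = 0.10,
                           gamma_far3s = 0.10,
                           gamma_missprev = 0.80,
                           wf_center = 0.45,
                           wf_scale = 0.14,
                           wf_exponent = 1 / 4) {
  stopifnot(residual_sd > 0, subject_sd >= 0,
            length(beta_difficulty) == 2, length(gamma_difficulty) == 2,
            wf_scale > 0, wf_exponent != 0)
  structure(list(
    rt_intercept = rt_intercept, subject_sd = subject_sd,
    beta_difficulty = beta_difficulty, beta_block = beta_block,
    beta_weightfuel = beta_weightfuel, beta_hho3s = beta_hho3s,
    beta_far3s = beta_far3s, residual_sd = residual_sd,
    gamma_intercept = gamma_intercept, gamma_difficulty = gamma_difficulty,
    gamma_block = gamma_block, gamma_weightfuel = gamma_weightfuel,
    gamma_hho3s = gamma_hho3s, gamma_far3s = gamma_far3s,
    gamma_missprev = gamma_missprev,
    wf_center = wf_center, wf_scale = wf_scale, wf_exponent = wf_exponent
  ), class = "workload_model")
}

# Derive a reproducible 32-bit sub-seed from a study seed and an index, so
# each participant gets an independent stream and adding participants never
# perturbs earlier ones.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 99991) %% 2147483647L)
}
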