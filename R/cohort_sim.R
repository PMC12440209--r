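# Virtual T1D cohort generator: a minimal 6-state glucose-insulin plant
# (fixed-step RK4, compiled) with circadian variability, meal/carb-count
# noise, and open-loop standard-bolus dosing. Also serves as the plant for
# the paired closed-loop evaluation of the bolus-adjustment algorithm.
#
# Plant equations (G glucose mg/dL, X remote insulin action 1/min, Q1/Q2 gut
# glucose mass mg, I1/I2 subcutaneous insulin U; m(t) = 1 + a_c sin(2*pi*
# (t - phi_c)/24 h) the circadian multiplier on insulin action and gut
# transfer):
#   dG/dt  = -p1 (G - G_b) - m(t) X G + f m(t) Q2 / (tau_m V)
#   dX/dt  = -p2 X + p2 S_I I2 / tau_i
#   dQ1/dt = -m(t) Q1 / tau_m          (+ carb impulses, mg)
#   dQ2/dt =  m(t) (Q1 - Q2) / tau_m
#   dI1/dt = -I1 / tau_i               (+ bolus impulses, U)
#   dI2/dt =  (I1 - I2) / tau_i
# Basal insulin is implicit in the steady-state construction: with no inputs
# the fasting equilibrium is G = G_b exactly.

#' Simulation scenario
#'
#' Defaults encode the study conditions: 10 adults, 120 days, three meals per
#' day at nominal times with uniform +/-20 min timing jitter and +/-20%
#' content variation, carbohydrate misestimation ~ Normal(0, 0.2) truncated
#' at +/-0.4 (i.e. within +/-40%), CGM sampled every 5 minutes with additive
#' Gaussian sensor noise.
#'
#' @param n_patients,n_days,meals_per_day cohort dimensions.
#' @param meal_times nominal meal hours (length `meals_per_day`).
#' @param meal_carbs nominal carbohydrates per meal, g.
#' @param time_jitter_min uniform meal-time jitter half-width, minutes.
#' @param content_var uniform meal-content variation half-width (fraction).
#' @param misest_sd,misest_max carb misestimation: Normal sd and truncation
#'   bound (fractions of the actual meal).
#' @param sensor_sd CGM additive noise sd, mg/dL.
#' @param seed master seed recorded in every output.
#' @export
sim_scenario <- function(n_patients = 10, n_days = 120, meals_per_day = 3,
                         meal_times = c(8, 13, 20),
                         meal_carbs = c(50, 70, 60),
                         time_jitter_min = 20, content_var = 0.2,
                         misest_sd = 0.2, misest_max = 0.4, sensor_sd = 5,
                         seed = 1) {
  stopifnot(length(meal_times) == meals_per_day,
            length(meal_carbs) == meals_per_day,
            misest_max > 0, misest_sd >= 0)
  structure(list(n_patients = n_patients, n_days = n_days,
                 meals_per_day = meals_per_day, meal_times = meal_times,
                 meal_carbs = meal_carbs, time_jitter_min = time_jitter_min,
                 content_var = content_var, misest_sd = misest_sd,
                 misest_max = misest_max, sensor_sd = sensor_sd, seed = seed),
            class = "sim_scenario")
}

#' Construct a virtual patient
#'
#' @param patient_id character id.
#' @param g_b basal (fasting) glucose, mg/dL.
#' @param s_i insulin sensitivity (integrated action per unit).
#' @param p1 glucose effectiveness, 1/min.
#' @param p2 insulin action decay, 1/min.
#' @param f carbohydrate bioavailability (0-1).
#' @param tau_m meal absorption time constant, min.
#' @param tau_i subcutaneous insulin time constant, min.
#' @param v glucose distribution volume, dL.
#' @param a_c circadian amplitude (fraction, 0-0.5).
#' @param phi_c circadian phase, hours.
#' @param therapy a [therapy_params()].
#' @export
virtual_patient <- function(patient_id, g_b, s_i, p1, p2, f, tau_m, tau_i, v,
                            a_c, phi_c, therapy) {
  stopifnot(p1 > 0, p2 > 0, s_i > 0, tau_m > 0, tau_i > 0, v > 0,
            a_c >= 0, a_c <= 0.5)
  structure(list(patient_id = patient_id, g_b = g_b, s_i = s_i, p1 = p1,
                 p2 = p2, f = f, tau_m = tau_m, tau_i = tau_i, v = v,
                 a_c = a_c, phi_c = phi_c, therapy = therapy),
            class = "virtual_patient")
}

patient_params <- function(p) {
  c(p$p1, p$p2, p$s_i, p$f, p$tau_m, p$tau_i, p$v, p$g_b, p$a_c, p$phi_c)
}

#' Plant derivatives at one state
#'
#' Thin wrapper over the compiled right-hand side, for inspection and
#' testing; the simulator integrates in compiled code.
#'
#' @param state numeric length-6 state `c(G, X, Q1, Q2, I1, I2)`.
#' @param patient a [virtual_patient()].
#' @param t_min minutes of simulation time (enters the circadian
#'   multiplier).
#' @return length-6 rate-of-change vector.
#' @export
derivatives <- function(state, patient, t_min = 0) {
  r <- cpp_derivatives(as.numeric(state), patient_params(patient), t_min)
  names(r) <- c("G", "X", "Q1", "Q2", "I1", "I2")
  r
}

# log-uniform draw
rlunif <- function(n, lo, hi) exp(runif(n, log(lo), log(hi)))

#' Draw a virtual patient from the documented parameter ranges
#'
#' One seeded draw per patient; therapy CR/CF are derived from the patient's
#' physiology (CR = V S_I G_b / (1000 f), CF = S_I G_b) with a log-uniform
#' misspecification factor in [0.8, 1.25] emulating imperfect clinical
#' titration.
#'
#' @param patient_id character id.
#' @param seed integer seed.
#' @export
draw_virtual_patient <- function(patient_id, seed) {
  set.seed(seed)
  g_b <- runif(1, 110, 135)
  s_i <- rlunif(1, 0.22, 0.45)
  p1 <- rlunif(1, 0.003, 0.007)
  p2 <- rlunif(1, 0.012, 0.025)
  f <- runif(1, 0.85, 0.95)
  tau_m <- rlunif(1, 30, 60)
  tau_i <- rlunif(1, 40, 70)
  v <- rlunif(1, 90, 140)
  a_c <- runif(1, 0.1, 0.3)
  phi_c <- runif(1, 0, 24)
  # insulin action in the plant scales with ambient glucose, so a clinically
  # titrated CR sits above the fasting-derived value
  cr_true <- 1.1 * v * s_i * g_b / (1000 * f)
  cf_true <- s_i * g_b
  mis <- rlunif(2, 0.8, 1.25)
  virtual_patient(patient_id, g_b, s_i, p1, p2, f, tau_m, tau_i, v, a_c,
                  phi_c,
                  therapy_params(cr = cr_true * mis[1], cf = cf_true * mis[2]))
}

# truncated normal by rejection (vectorized over n)
rtnorm <- function(n, sd, bound) {
  x <- rnorm(n, 0, sd)
  while (any(bad <- abs(x) > bound)) x[bad] <- rnorm(sum(bad), 0, sd)
  x
}

# all stochastic inputs of one patient-run, drawn up front so that paired
# runs (different dosing policies, same seed) see identical conditions
draw_scenario_inputs <- function(scenario, seed) {
  set.seed(seed)
  n_meals <- scenario$n_days * scenario$meals_per_day
  day <- rep(seq_len(scenario$n_days), each = scenario$meals_per_day)
  slot <- rep(seq_len(scenario$meals_per_day), scenario$n_days)
  minute <- (day - 1) * 1440 + scenario$meal_times[slot] * 60 +
    round(runif(n_meals, -scenario$time_jitter_min, scenario$time_jitter_min))
  actual <- scenario$meal_carbs[slot] *
    (1 + runif(n_meals, -scenario$content_var, scenario$content_var))
  eps <- rtnorm(n_meals, scenario$misest_sd, scenario$misest_max)
  announced <- actual * (1 + eps)
  total_min <- scenario$n_days * 1440 + 360  # 6-h tail closes the last windows
  noise <- rnorm(total_min / 5 + 1, 0, scenario$sensor_sd)
  list(meals = data.frame(minute = minute, actual = actual,
                          announced = announced),
       noise = noise, total_min = total_min)
}

clip_sensor <- function(g) pmin(pmax(g, 20.5), 599.5)

#' Standard open-loop dosing policy
#'
#' Doses every meal with the standard bolus calculator on the announced
#' carbohydrates (clamped at zero).
#' @export
standard_policy <- function(ctx) {
  max(0, standard_bolus(ctx$cho_announced, ctx$therapy, ctx$cgm_meal))
}

#' Simulate one patient over a scenario
#'
#' Fixed-step RK4 at a 1-minute internal step; CGM sampled every 5 minutes
#' with additive Gaussian noise and clipped to the sensor range. Each meal is
#' dosed by `policy` (default: the standard bolus on announced carbs); the
#' plant receives the actual carbs. All stochastic inputs come from one
#' seeded per-patient stream drawn before integration, so two runs with the
#' same seed but different policies face identical conditions.
#'
#' @param patient a [virtual_patient()].
#' @param scenario a [sim_scenario()].
#' @param seed integer seed for this patient-run.
#' @param policy function(ctx) -> bolus units; see [standard_policy()] for
#'   the context fields.
#' @param start_time POSIXct timestamp of simulation minute 0.
#' @param rk_step internal RK4 step, minutes.
#' @return a [patient_record()]; the per-meal delivered boluses appear as
#'   bolus events at meal onset.
#' @export
simulate_patient <- function(patient, scenario, seed,
                             policy = standard_policy,
                             start_time = as.POSIXct("2024-01-01 00:00:00",
                                                     tz = "UTC"),
                             rk_step = 1) {
  inp <- draw_scenario_inputs(scenario, seed)
  params <- patient_params(patient)
  total_min <- inp$total_min
  g_min <- numeric(total_min + 1)
  g_min[1] <- patient$g_b
  state <- c(patient$g_b, 0, 0, 0, 0, 0)
  t_cur <- 0
  pending_mg <- numeric(0); pending_u <- numeric(0)
  bolus_rows <- list()

  advance <- function(state, t_cur, dt) {
    cpp_sim_segment(state, params, t_cur, dt, if (length(pending_mg)) 0 else
      numeric(0), pending_mg, if (length(pending_u)) 0 else numeric(0),
      pending_u, rk_step)
  }
  meals <- inp$meals[order(inp$meals$minute), , drop = FALSE]
  for (j in seq_len(nrow(meals))) {
    t_m <- meals$minute[j]
    seg <- advance(state, t_cur, t_m - t_cur)
    g_min[(t_cur + 2):(t_m + 1)] <- seg$g[-1]
    state <- seg$state
    pending_mg <- numeric(0); pending_u <- numeric(0)
    slot_m <- floor(t_m / 5)  # 0-based grid slot at/just before the meal
    cgm_hist <- clip_sensor(g_min[seq(1, slot_m * 5 + 1, by = 5)] +
                              inp$noise[seq_len(slot_m + 1)])
    ctx <- list(cgm_meal = cgm_hist[slot_m + 1],
                cgm_history = cgm_hist, slot = slot_m,
                cho_announced = meals$announced[j],
                therapy = patient$therapy, patient_id = patient$patient_id,
                t_min = t_m, meal_index = j,
                hour = floor((t_m %% 1440) / 60),
                boluses = do.call(rbind, bolus_rows))
    units <- max(0, policy(ctx))
    pending_mg <- meals$actual[j] * 1000
    pending_u <- units
    bolus_rows[[j]] <- data.frame(minute = t_m, units = units)
    t_cur <- t_m
  }
  seg <- advance(state, t_cur, total_min - t_cur)
  g_min[(t_cur + 2):(total_min + 1)] <- seg$g[-1]

  slots <- seq(1, total_min + 1, by = 5)
  sensor <- clip_sensor(g_min[slots] + inp$noise)
  trace <- glucose_trace(start_time, sensor, step = 5, validate = FALSE)
  boluses <- if (length(bolus_rows)) do.call(rbind, bolus_rows) else
    data.frame(minute = numeric(0), units = numeric(0))
  record <- patient_record(
    patient$patient_id, trace,
    meals = data.frame(time = start_time + meals$minute * 60,
                       cho_announced = meals$announced,
                       cho_actual = meals$actual),
    boluses = data.frame(time = start_time + boluses$minute * 60,
                         units = boluses$units),
    therapy = patient$therapy)
  attr(record, "seed") <- seed
  record
}

#' Generate a virtual cohort
#'
#' Draws `n_patients` virtual patients (one seeded draw each) and simulates
#' every patient over the scenario under the given dosing policy.
#'
#' @param scenario a [sim_scenario()].
#' @param policy dosing policy passed to [simulate_patient()].
#' @return list of [patient_record()] with attributes `manifest` (data.frame
#'   of all drawn parameters, one row per patient) and `patients` (the
#'   [virtual_patient()] objects, reusable for paired runs).
#' @export
generate_cohort <- function(scenario, policy = standard_policy) {
  records <- vector("list", scenario$n_patients)
  patients <- vector("list", scenario$n_patients)
  manifest <- list()
  for (i in seq_len(scenario$n_patients)) {
    pid <- sprintf("sim%02d", i)
    patients[[i]] <- draw_virtual_patient(
      pid, derive_seed(scenario$seed, "patient", i))
    records[[i]] <- simulate_patient(
      patients[[i]], scenario, derive_seed(scenario$seed, "run", i), policy)
    p <- patients[[i]]
    manifest[[i]] <- data.frame(patient_id = pid, g_b = p$g_b, s_i = p$s_i,
                                p1 = p$p1, p2 = p$p2, f = p$f,
                                tau_m = p$tau_m, tau_i = p$tau_i, v = p$v,
                                a_c = p$a_c, phi_c = p$phi_c,
                                cr = p$therapy$cr, cf = p$therapy$cf,
                                seed = derive_seed(scenario$seed, "run", i))
  }
  names(records) <- vapply(patients, `[[`, "", "patient_id")
  attr(records, "manifest") <- do.call(rbind, manifest)
  attr(records, "patients") <- patients
  attr(records, "scenario") <- scenario
  records
}
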