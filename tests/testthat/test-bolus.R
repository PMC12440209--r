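test_that("the standard bolus formula reproduces its worked examples", {
  expect_equal(standard_bolus(60, therapy_params(10, 30), 180), 7.0)
  expect_equal(standard_bolus(0, therapy_params(10, 30), 150), 0)
  expect_equal(standard_bolus(50, therapy_params(10, 25), 100), 3.0)
})

test_that("the logistic sigmoid is exact, symmetric and saturation-safe", {
  expect_equal(sigmoid(0), 0.5)
  for (x in c(-3, -0.5, 0.2, 7)) expect_equal(sigmoid(x) + sigmoid(-x), 1)
  expect_lt(abs(sigmoid(40) - 1), 1e-12)
  expect_equal(sigmoid(-800), 0)  # no overflow
})

test_that("the adjustment factor is centred in normalized mode, saturates literally", {
  th <- therapy_params(10, 40, cgm_target = 150)
  cfg <- bolus_config()
  expect_equal(adjustment_factor(150, th, cfg), 0)
  # strictly increasing in meal glucose
  af <- vapply(seq(80, 280, by = 20), adjustment_factor, numeric(1),
               therapy = th, config = cfg)
  expect_true(all(diff(af) > 0))
  expect_true(all(af > -1 & af < 1))
  # literal mode: both sigmoids saturate at raw mg/dL inputs
  lit <- adjustment_factor(150, th, bolus_config(mode = "literal"))
  expect_equal(lit, 1.0, tolerance = 1e-12)
})

test_that("the modified bolus scales MIB by (1 + adjustment factor)", {
  expect_equal(modified_bolus(6, 0), 6)
  expect_equal(modified_bolus(6, -0.5), 3.0)
  for (af in c(-0.99, -0.3, 0.4, 0.99))
    expect_true(modified_bolus(6, af) > 0 && modified_bolus(6, af) < 12)
})

test_that("the CGM trend is the OLS slope over the final hour", {
  # linear decline of 1 mg/dL per minute (5 per slot)
  expect_equal(cgm_trend(seq(200, by = -5, length.out = 72)), -1.0)
  expect_equal(cgm_trend(rep(140, 72)), 0.0)
  set.seed(8)
  noisy <- 100 + 0.8 * seq(0, 355, by = 5) + rnorm(72, 0, 2)
  expect_equal(cgm_trend(noisy), 0.8, tolerance = 0.12)
  expect_error(cgm_trend(c(rep(NA, 71), 100)), "fewer than 2")
})

test_that("insulin on board decays linearly to zero over the DIA", {
  t0 <- as.POSIXct("2024-01-01 12:00:00", tz = "UTC")
  expect_equal(insulin_on_board(t0, 5, t0, dia = 4), 5)
  expect_equal(insulin_on_board(t0, 5, t0 + 2 * 3600, dia = 4), 2.5)
  expect_equal(insulin_on_board(t0, 5, t0 + 4 * 3600, dia = 4), 0)
  expect_equal(insulin_on_board(t0, 5, t0 + 9 * 3600, dia = 4), 0)
  # future boluses contribute nothing
  expect_equal(insulin_on_board(t0 + 3600, 5, t0, dia = 4), 0)
})

test_that("the final-bolus gating follows prediction and trend branches", {
  cfg <- bolus_config()
  no_event <- final_bolus(4, 5, 0, 0, -1, 1, cfg)
  expect_equal(no_event$b_final, 5)           # MIB unchanged
  expect_equal(no_event$branch, "no_event")
  s1_down <- final_bolus(4, 5, 1, 0, -0.5, 1, cfg)
  expect_equal(s1_down$b_final, 4 * 1.02 - 1) # 3.08 U
  clamp <- final_bolus(0.5, 5, 1, 0, -0.5, 2, cfg)
  expect_equal(clamp$b_final, 0)
  s1_up <- final_bolus(4, 5, 1, 1, 0.3, 1, cfg)
  expect_equal(s1_up$b_final, 4)              # B_mod, no IOB term
  expect_equal(s1_up$branch, "S1_up")         # S1 precedence over S2
  s2_down <- final_bolus(4, 5, 0, 1, -0.5, 1, cfg)
  expect_equal(s2_down$b_final, 4 * 1.01 - 1)
  # slope exactly 0 follows the non-falling branch
  expect_equal(final_bolus(4, 5, 1, 0, 0, 1, cfg)$branch, "S1_up")
})

test_that("B_final is never negative with the clamp on", {
  cfg <- bolus_config()
  set.seed(12)
  for (i in 1:50) {
    r <- final_bolus(runif(1, 0, 3), runif(1, 0, 3), rbinom(1, 1, 0.5),
                     rbinom(1, 1, 0.5), rnorm(1), runif(1, 0, 6), cfg)
    expect_gte(r$b_final, 0)
  }
})

test_that("single-meal recommendations carry full provenance", {
  fit <- planted_fit()
  hist <- 130 + cumsum(rnorm(72, 0, 1))
  rec <- recommend_bolus(fit, hist, cho = 60, meal_hour = 12,
                         therapy = therapy_params(10, 40),
                         prior_bolus_min = 120, prior_bolus_units = 4)
  expect_s3_class(rec, "bolus_recommendation")
  expect_length(rec$features, 13)
  expect_equal(rec$iob, 4 * (1 - 120 / 240))
  expect_true(rec$branch %in% c("no_event", "S1_down", "S1_up", "S2_down",
                                "S2_up"))
  expect_gte(rec$b_final, 0)
  expect_error(recommend_bolus(fit, hist[1:50], 60, 12,
                               therapy_params(10, 40)),
               "72")
})

test_that("a null intervention reproduces the open-loop run bit-exactly", {
  fit <- planted_fit()
  # alpha = gamma = 1, zero adjustment factor, IOB removed via huge scales
  cfg <- bolus_config(alpha = 1, gamma = 1)
  null_policy <- function(ctx) {
    mib <- max(0, standard_bolus(ctx$cho_announced, ctx$therapy,
                                 ctx$cgm_meal))
    b_mod <- modified_bolus(mib, 0)
    final_bolus(b_mod, mib, 1, 0, -1, 0, cfg)$b_final
  }
  p <- draw_virtual_patient("vp", 42)
  sc <- sim_scenario(n_patients = 1, n_days = 3, seed = 5)
  before <- simulate_patient(p, sc, seed = 55)
  after <- simulate_patient(p, sc, seed = 55, policy = null_policy)
  expect_identical(before$trace$values, after$trace$values)
  expect_identical(before$boluses, after$boluses)
})

test_that("paired closed-loop runs share meal and noise draws", {
  p <- draw_virtual_patient("vp", 43)
  sc <- sim_scenario(n_patients = 1, n_days = 2, seed = 6)
  r1 <- simulate_patient(p, sc, seed = 77)
  r2 <- simulate_patient(p, sc, seed = 77,
                         policy = function(ctx) 0)  # no insulin at all
  expect_identical(r1$meals, r2$meals)  # identical scenario draws
  expect_false(identical(r1$trace$values, r2$trace$values))
})
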