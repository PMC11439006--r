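test_that("canopy absorption follows the power-law closure form", {
  lettuce <- mec_crop("lettuce")
  expect_equal(canopy_absorption(lettuce$t_A, lettuce), lettuce$a_max)
  expect_equal(canopy_absorption(0, lettuce), 0)
  expect_equal(canopy_absorption(lettuce$t_M, lettuce), lettuce$a_max)
  # hand evaluation of the piecewise formula at the half-closure point
  lin <- mec_crop_parameters("lin", t_A = 20, t_Q = 30, t_E = 0, t_M = 30,
                             f_E = 1, w_C = 0.4, cue_max = 0.6,
                             a_max = 0.9, a_exponent = 1,
                             cqy_coeffs = matrix(0, 5, 5))
  expect_equal(canopy_absorption(10, lin), 0.45)
  expect_error(canopy_absorption(-1, lettuce), "t must be >= 0")
  # monotone and bounded
  a <- canopy_absorption(seq(0, 30, 0.5), lettuce)
  expect_true(all(diff(a) >= 0))
  expect_true(all(a >= 0 & a <= lettuce$a_max))
})

test_that("canopy quantum yield matches an independent surface evaluation", {
  for (id in c("lettuce", "wheat", "soybean")) {
    crop <- mec_crop(id)
    env <- environment_state(500, 1200)
    got <- canopy_quantum_yield(env, 1, crop)
    # independent oracle: explicit double loop over the basis terms
    xb <- c(1 / 500, 1, 500, 500^2, 500^3)
    yb <- c(1 / 1200, 1, 1200, 1200^2, 1200^3)
    want <- 0
    for (i in 1:5) for (j in 1:5)
      want <- want + crop$cqy_coeffs[i, j] * xb[i] * yb[j]
    expect_equal(got, max(0, want), tolerance = 1e-12)
  }
})

test_that("quantum yield is time-independent before senescence and ramps after", {
  wheat <- mec_crop("wheat")  # declining crop
  env <- environment_state(500, 1200)
  base <- canopy_quantum_yield(env, 1, wheat)
  expect_equal(canopy_quantum_yield(env, wheat$t_Q - 5, wheat), base)
  expect_equal(canopy_quantum_yield(env, wheat$t_Q, wheat), base)
  expect_equal(canopy_quantum_yield(env, wheat$t_M, wheat),
               base * wheat$cqy_min)
  mid <- (wheat$t_Q + wheat$t_M) / 2
  expect_equal(canopy_quantum_yield(env, mid, wheat),
               base * (1 + wheat$cqy_min) / 2)
  # non-declining crop ignores t entirely
  lettuce <- mec_crop("lettuce")
  expect_equal(canopy_quantum_yield(env, lettuce$t_M, lettuce),
               canopy_quantum_yield(env, 0, lettuce))
})

test_that("evaluation outside the validity box warns and clamps", {
  lettuce <- mec_crop("lettuce")
  expect_warning(
    lo <- canopy_quantum_yield(environment_state(5000, 525), 1, lettuce),
    "validity box")
  edge <- canopy_quantum_yield(
    environment_state(lettuce$ppf_range[2], 525), 1, lettuce)
  expect_equal(lo, edge)
  expect_error(canopy_quantum_yield(environment_state(0, 525), 1, lettuce))
})

test_that("carbon use efficiency is constant or declines linearly after t_Q", {
  lettuce <- mec_crop("lettuce")
  expect_equal(carbon_use_efficiency(c(0, 15, 30), lettuce),
               rep(lettuce$cue_max, 3))
  soy <- mec_crop("soybean")
  expect_equal(carbon_use_efficiency(soy$t_M, soy), soy$cue_min)
  # linear-interpolation oracle at the midpoint
  expect_equal(carbon_use_efficiency((soy$t_Q + soy$t_M) / 2, soy),
               (soy$cue_max + soy$cue_min) / 2)
})

test_that("daily carbon gain carries the 0.0036 unit conversion", {
  crop <- unit_crop()
  env <- environment_state(ppf = 1, co2 = 400, photoperiod = 24)
  expect_equal(daily_carbon_gain(1, env, crop), 0.0864, tolerance = 1e-12)
  expect_equal(daily_carbon_gain(1, environment_state(0, 400, 24), crop), 0)
  # growth rate composes the three sub-models exactly
  lettuce <- mec_crop("lettuce")
  env2 <- environment_state(225, 525)
  t <- 20
  want <- (lettuce$m_molar_C / lettuce$w_C) * 0.0036 * 16 *
    carbon_use_efficiency(t, lettuce) * canopy_absorption(t, lettuce) *
    225 * canopy_quantum_yield(env2, t, lettuce)
  expect_equal(areal_growth_rate(t, env2, lettuce), want, tolerance = 1e-12)
})

test_that("growth rate is linear in photoperiod and zero without light", {
  lettuce <- mec_crop("lettuce")
  t <- seq(0, 30, 1)
  r8 <- areal_growth_rate(t, environment_state(225, 525, 8), lettuce)
  r16 <- areal_growth_rate(t, environment_state(225, 525, 16), lettuce)
  expect_equal(r16, 2 * r8)
  expect_equal(areal_growth_rate(t, environment_state(225, 525, 0), lettuce),
               rep(0, length(t)))
})

test_that("simulated MEC curves integrate the rate correctly", {
  # constant-rate closed form through the unit crop
  crop <- unit_crop(w_C = 0.5, t_M = 10)
  env <- environment_state(1, 400, 24)
  curve <- simulate_mec(env, crop, seq(0, 10, 0.5))
  c_rate <- (12.011 / 0.5) * 0.0864
  expect_equal(tail(curve$biomass_total, 1), c_rate * 10, tolerance = 1e-12)
  # f_E = 1 and t_E = 0 make edible identical to total
  expect_equal(curve$biomass_edible, curve$biomass_total)

  # fine-step Euler integration oracle for lettuce
  lettuce <- mec_crop("lettuce")
  env2 <- environment_state(225, 525)
  curve2 <- simulate_mec(env2, lettuce, dt = 0.1)
  tg <- seq(0, 30, 0.001)
  euler <- sum(areal_growth_rate(tg[-length(tg)], env2, lettuce) * 0.001)
  expect_equal(tail(curve2$biomass_total, 1), euler, tolerance = 5e-3)
  # invariants
  expect_true(all(diff(curve2$biomass_total) >= 0))
  expect_true(all(curve2$biomass_edible <= curve2$biomass_total + 1e-9))
  # grid-refinement convergence at the default step
  fine <- simulate_mec(env2, lettuce, dt = 0.05)
  expect_lt(abs(tail(fine$biomass_total, 1) - tail(curve2$biomass_total, 1)) /
              tail(fine$biomass_total, 1), 1e-3)
})

test_that("grids beyond maturity are truncated with a warning", {
  lettuce <- mec_crop("lettuce")
  expect_warning(curve <- simulate_mec(environment_state(225, 525), lettuce,
                                       seq(0, 40, 0.5)),
                 "truncating")
  expect_equal(max(curve$t_dae), lettuce$t_M)
})

test_that("edible biomass starts accumulating at organ formation", {
  tomato <- mec_crop("tomato")
  curve <- simulate_mec(environment_state(500, 1200), tomato, dt = 0.25)
  expect_equal(curve$biomass_edible[curve$t_dae <= tomato$t_E],
               rep(0, sum(curve$t_dae <= tomato$t_E)))
  after <- curve$biomass_edible[curve$t_dae > tomato$t_E + 1]
  expect_true(all(diff(after) > 0))
  # allocation fraction bounds the edible share of late growth
  inc_e <- diff(tail(curve$biomass_edible, 10))
  inc_t <- diff(tail(curve$biomass_total, 10))
  expect_equal(inc_e / inc_t, rep(tomato$f_E, 9), tolerance = 1e-9)
})

test_that("all nine bundled crops load and validate", {
  for (id in mec_crops()) {
    crop <- mec_crop(id)
    expect_s3_class(crop, "mec_crop")
    expect_identical(crop$crop_id, id)
    expect_true(crop$t_A <= crop$t_M)
  }
  expect_error(mec_crop("kale"), "unknown crop")
})
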