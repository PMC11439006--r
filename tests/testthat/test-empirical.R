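test_that("plant nitrogen mass is the fresh-weight x fraction product", {
  expect_equal(plant_nitrogen_mass(0, 0.004), 0)
  expect_equal(plant_nitrogen_mass(100, 0.0036), 0.36)
  expect_equal(plant_nitrogen_mass(20, 0.005), 0.1)
  expect_error(plant_nitrogen_mass(-1, 0.1), ">= 0")
})

test_that("empirical NUE divides biomass gain by interval-mean nitrogen", {
  s <- measurement_series(data.frame(
    t = c(10, 15), n_plants = 5,
    fresh_weight = c(10, 30), fw_sd = 0,
    dry_biomass = c(1, 3), biomass_sd = 0,
    n_fraction_fw = c(0.05, 1 / 60), n_fraction_sd = 0),
    condition = "normal")   # m_N = 0.5 at both harvests
  expect_equal(empirical_nue(s, 10, 15), 4)
  s2 <- measurement_series(data.frame(
    t = c(0, 7), n_plants = 5,
    fresh_weight = c(10, 30), fw_sd = 0,
    dry_biomass = c(2, 5), biomass_sd = 0,
    n_fraction_fw = c(0.02, 0.02), n_fraction_sd = 0),
    condition = "other")    # m_N 0.2 -> 0.6
  expect_equal(empirical_nue(s2, 0, 7), 3 / 0.4)
  # unchanged biomass gives zero
  s3 <- toy_series()
  s3$dry_biomass <- rep(2, 3)
  expect_equal(empirical_nue(measurement_series(as.data.frame(s3)), 10, 15), 0)
  expect_error(empirical_nue(s, 15, 10), "t1 < t2")
})

test_that("empirical RNAR is the mean log rate of nitrogen increase", {
  s <- measurement_series(data.frame(
    t = c(0, 7), n_plants = 5,
    fresh_weight = c(10, 20), fw_sd = 0,
    dry_biomass = c(1, 2), biomass_sd = 0,
    n_fraction_fw = c(0.01, 0.01), n_fraction_sd = 0),
    condition = "other")    # m_N doubles over 7 d
  expect_equal(empirical_rnar(s, 0, 7), log(2) / 7)
  s2 <- measurement_series(data.frame(
    t = c(5, 10), n_plants = 5,
    fresh_weight = c(10, 30), fw_sd = 0,
    dry_biomass = c(1, 2), biomass_sd = 0,
    n_fraction_fw = c(0.01, 0.01), n_fraction_sd = 0),
    condition = "other")    # 0.1 -> 0.3 over 5 d
  expect_equal(empirical_rnar(s2, 5, 10), log(3) / 5)
  s3 <- measurement_series(data.frame(
    t = c(5, 10), n_plants = 5,
    fresh_weight = c(10, 10), fw_sd = 0,
    dry_biomass = c(1, 2), biomass_sd = 0,
    n_fraction_fw = c(0.01, 0.01), n_fraction_sd = 0),
    condition = "other")
  expect_equal(empirical_rnar(s3, 5, 10), 0)
})

test_that("empirical productivity and its propagated error are correct", {
  s <- measurement_series(data.frame(
    t = c(0, 5), n_plants = 5,
    fresh_weight = c(20, 20), fw_sd = 0,
    dry_biomass = c(1, 2), biomass_sd = 0,
    n_fraction_fw = c(0.01, 0.01), n_fraction_sd = 0),
    condition = "other")    # dm_B = 1 g over 5 d, mean m_N = 0.2 g
  p <- empirical_productivity(s)
  expect_equal(p$productivity, 1.0)
  expect_equal(p$propagated_sd, 0)
  expect_equal(p$t_mid, 2.5)
  expect_error(empirical_productivity(s[1, ]), "at least 2")

  # Monte-Carlo propagation oracle on a noisy two-interval table
  s2 <- toy_series()
  p2 <- empirical_productivity(s2)
  set.seed(99)
  nmc <- 1e5
  mc_sd <- vapply(1:2, function(i) {
    b1 <- rnorm(nmc, s2$dry_biomass[i], s2$biomass_sd[i])
    b2 <- rnorm(nmc, s2$dry_biomass[i + 1], s2$biomass_sd[i + 1])
    n1 <- rnorm(nmc, s2$m_N[i], s2$m_N_sd[i])
    n2 <- rnorm(nmc, s2$m_N[i + 1], s2$m_N_sd[i + 1])
    dt <- s2$t[i + 1] - s2$t[i]
    sd((b2 - b1) / dt / ((n1 + n2) / 2))
  }, numeric(1))
  expect_equal(p2$propagated_sd, mc_sd, tolerance = 0.05)
})

test_that("derived interval series are invariant under time shifts", {
  s <- toy_series()
  shifted <- as.data.frame(s)
  shifted$t <- shifted$t + 13
  s2 <- measurement_series(shifted)
  expect_equal(empirical_nue_series(s)$value, empirical_nue_series(s2)$value)
  expect_equal(empirical_rnar_series(s)$value,
               empirical_rnar_series(s2)$value)
  expect_equal(empirical_productivity(s)$productivity,
               empirical_productivity(s2)$productivity)
})

test_that("mass rescaling leaves RNAR and NUE unchanged when joint", {
  s <- toy_series()
  scaled <- as.data.frame(s)
  scaled$fresh_weight <- scaled$fresh_weight * 3
  scaled$dry_biomass <- scaled$dry_biomass * 3
  scaled$fw_sd <- scaled$fw_sd * 3
  scaled$biomass_sd <- scaled$biomass_sd * 3
  scaled$m_N <- scaled$m_N_sd <- NULL   # re-derive from the scaled masses
  s2 <- measurement_series(scaled)
  expect_equal(empirical_rnar_series(s2)$value,
               empirical_rnar_series(s)$value)
  expect_equal(empirical_nue_series(s2)$value, empirical_nue_series(s)$value)
})

test_that("interval productivity converges to the model rate as spacing shrinks", {
  truth <- lettuce_truth()
  layout <- cultivation_layout()
  dense <- generate_experiment(list(normal = truth), layout,
                               harvest_times = seq(10, 30, 0.5),
                               n_per_harvest = 1,
                               noise = list(biomass_cv = 0, nfrac_cv = 0),
                               seed = 1, dt = 0.02)
  p <- empirical_productivity(dense$normal)
  want <- nitrogen_productivity(p$t_mid, truth)
  expect_equal(p$productivity, want, tolerance = 0.01)
})

test_that("the measurement loader enforces its schema and round-trips", {
  scen <- default_lettuce_scenario()
  dat <- generate_experiment(
    list(deficient = default_np_parameters("deficient"),
         normal = default_np_parameters("normal")),
    scen$layout, scen$harvest_times, n_per_harvest = 6,
    noise = list(biomass_cv = 0.1, nfrac_cv = 0.1), seed = 4)
  path <- tempfile(fileext = ".csv")
  write_measurements(dat, path)
  back <- load_measurements(path)
  expect_named(back, c("deficient", "normal"))
  for (cond in names(dat)) {
    expect_equal(back[[cond]]$dry_biomass, dat[[cond]]$dry_biomass)
    expect_equal(back[[cond]]$m_N, dat[[cond]]$m_N)
    expect_identical(attr(back[[cond]], "condition"), cond)
  }

  # empty file is a schema error
  empty <- tempfile(fileext = ".csv")
  writeLines("condition,t", empty)
  expect_error(load_measurements(empty), "schema error")
  # a missing mandatory column is reported by name
  df <- read.csv(path)
  df$dry_biomass <- NULL
  broken <- tempfile(fileext = ".csv")
  write.csv(df, broken, row.names = FALSE)
  expect_error(load_measurements(broken), "dry_biomass")
  expect_error(load_measurements(tempfile()), "not found")
})

test_that("sowing-based times convert to emergence-based on load", {
  s <- toy_series()
  path <- tempfile(fileext = ".csv")
  write_measurements(list(normal = s), path)
  back <- load_measurements(path,
                            measurement_schema(time_basis = "d_AS"))
  expect_equal(back$normal$t, s$t - 3)
})

test_that("extra columns survive as auxiliary data", {
  s <- toy_series()
  df <- cbind(condition = "normal", as.data.frame(s),
              nitrate_mM = c(1, 0.8, 0.6), ph = c(6, 6.1, 6.3))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  back <- load_measurements(path)
  expect_equal(attr(back$normal, "aux")$nitrate_mM, c(1, 0.8, 0.6))
})
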