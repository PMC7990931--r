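test_that("generators are bit-reproducible and respect degenerate settings", {
  cfg <- sim_config(seed = 3)
  g1 <- gen_isoscape(cfg)
  g2 <- gen_isoscape(cfg)
  expect_identical(g1, g2)
  s1 <- gen_specimens(cfg, g1)
  s2 <- gen_specimens(cfg, g1)
  expect_identical(s1, s2)

  flat <- sim_config(seed = 3, lat_slope = 0, front_step = 0, noise_sd = 0,
                     land_fraction = 0)
  gf <- gen_isoscape(flat)
  expect_true(all(gf$values == flat$base))
})

test_that("the front step shows up as the north-south mean difference", {
  cfg <- sim_config(seed = 13, front_step = -3, front_lat = 40,
                    noise_sd = 0.1, land_fraction = 0)
  g <- gen_isoscape(cfg)
  north <- g$lat >= 40
  obs <- mean(g$values[north, ]) - mean(g$values[!north, ])
  expected <- -3 + cfg$lat_slope * (mean(g$lat[north]) - mean(g$lat[!north]))
  expect_equal(obs, expected, tolerance = 0.05)
})

test_that("noise-free specimens invert exactly to their true seawater value", {
  cfg <- sim_config(seed = 7, meas_sd = 0, noise_sd = 0)
  g <- gen_isoscape(cfg)
  sim <- gen_specimens(cfg, g)
  calib <- calibration_model(beta0_mean = cfg$beta0, beta1_mean = cfg$beta1)
  expect_equal(invert_calibration(sim$records$d18O_p, calib),
               sim$truth$true_m, tolerance = 1e-10)
})

test_that("regenerating the grid alone does not shift cohort draws", {
  cfg <- sim_config(seed = 21, land_fraction = 0)
  g <- gen_isoscape(cfg)
  gen_isoscape(cfg)  # extra grid call must not perturb the specimen stream
  s1 <- gen_specimens(cfg, g)
  s2 <- gen_specimens(cfg, g)
  expect_identical(s1, s2)
  expect_error(
    gen_specimens(sim_config(seed = 21, groups = data.frame(
      label = "dry", n = 5L, lat_lo = 85, lat_hi = 89,
      year_lo = 2000L, year_hi = 2010L, age_lo = 3, age_hi = 10,
      d13c_offset = 0)), g),
    "no non-missing cells")
})

test_that("OLS on simulated pairs recovers the forward calibration", {
  cfg <- sim_config(seed = 101, groups = data.frame(
    label = c("north", "south"), n = c(100L, 100L),
    lat_lo = c(50, 5), lat_hi = c(75, 35),
    year_lo = 1950L, year_hi = 2013L, age_lo = 3, age_hi = 35,
    d13c_offset = 0))
  g <- gen_isoscape(cfg)
  sim <- gen_specimens(cfg, g)
  fit <- stats::lm(sim$records$d18O_p ~ sim$truth$true_m)
  cf <- summary(fit)$coefficients
  expect_lt(abs(cf[1, "Estimate"] - cfg$beta0) / cf[1, "Std. Error"], 3)
  expect_lt(abs(cf[2, "Estimate"] - cfg$beta1) / cf[2, "Std. Error"], 3)
})

test_that("temporal trend fit recovers the configured Suess rate", {
  cfg <- sim_config(seed = 103, groups = data.frame(
    label = "pool", n = 200L, lat_lo = 5, lat_hi = 75,
    year_lo = 1940L, year_hi = 2013L, age_lo = 3, age_hi = 35,
    d13c_offset = 0))
  g <- gen_isoscape(cfg)
  sim <- gen_specimens(cfg, g)
  mid <- as.numeric(deposition_midpoint(sim$records$year_of_death,
                                        sim$records$age_years))
  fit <- fit_temporal_trend(sim$records$d13C_sc, mid)
  # standard error of the OLS slope for the 3-SE recovery window
  lmfit <- summary(stats::lm(sim$records$d13C_sc ~ mid))$coefficients
  expect_lt(abs(fit$slope - cfg$suess_rate) / lmfit[2, "Std. Error"], 3)
})

test_that("groups astride a 2 per-mil front are separated by the rank test", {
  hits <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(seed = 1000 + seed, front_step = -2, front_lat = 40,
                      groups = data.frame(
                        label = c("north", "south"), n = c(8L, 8L),
                        lat_lo = c(45, 5), lat_hi = c(75, 35),
                        year_lo = 1950L, year_hi = 2013L,
                        age_lo = 3, age_hi = 35, d13c_offset = 0))
    g <- gen_isoscape(cfg)
    sim <- gen_specimens(cfg, g)
    p <- kruskal_wallis(split(sim$records$d18O_p, sim$records$region))$p_value
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / 20, 0.9)
})

test_that("coverage is exact in the noise-free limit and for very wide CIs", {
  noiseless <- sim_config(seed = 11, meas_sd = 0, beta0_sd = 0, beta1_sd = 0,
                          noise_sd = 0)
  expect_equal(coverage_experiment(noiseless, ci_level = 0.95)$coverage, 1)
  cfg <- sim_config(seed = 12)
  expect_equal(coverage_experiment(cfg, ci_level = 1 - 1e-12)$coverage, 1)
})

test_that("nominal 95% assignment coverage holds on a moderate cohort", {
  cfg <- sim_config(seed = 31, noise_sd = 0, groups = data.frame(
    label = c("north", "south"), n = c(150L, 150L),
    lat_lo = c(50, 5), lat_hi = c(75, 35),
    year_lo = 1950L, year_hi = 2013L, age_lo = 3, age_hi = 35,
    d13c_offset = 0))
  cov <- coverage_experiment(cfg, ci_level = 0.95)
  expect_equal(cov$n, 300L)
  # binomial 99.9% window around 0.95 at n = 300 is about +/- 0.04
  expect_gt(cov$coverage, 0.91)
  expect_lt(cov$coverage, 0.99)
})
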