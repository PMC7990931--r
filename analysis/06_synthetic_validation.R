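#!/usr/bin/env Rscript
# End-to-end validation on synthetic data: 95% CI assignment coverage on a
# 1000-whale cohort, forward-calibration recovery by OLS on 200 simulated
# (seawater, tissue) pairs, and recovery of the -0.023 per mil/yr Suess
# drift from simulated d13C series.

library(orcascape)

dir.create("results", showWarnings = FALSE)

two_bands <- function(n_each) data.frame(
  label = c("north", "south"), n = n_each,
  lat_lo = c(50, 5), lat_hi = c(75, 35),
  year_lo = 1950L, year_hi = 2013L, age_lo = 3, age_hi = 35,
  d13c_offset = 0)

cov <- coverage_experiment(sim_config(seed = 71, noise_sd = 0,
                                      groups = two_bands(500L)),
                           ci_level = 0.95)
cat(sprintf("95%% CI assignment coverage: %.3f (n = %d whales)\n",
            cov$coverage, cov$n))

cfg <- sim_config(seed = 73, groups = two_bands(100L))
grid <- gen_isoscape(cfg)
sim <- gen_specimens(cfg, grid)
cf <- summary(stats::lm(sim$records$d18O_p ~ sim$truth$true_m))$coefficients
cat(sprintf("recovered calibration (n = %d): beta0 = %.2f +/- %.2f (true 18.73), beta1 = %.2f +/- %.2f (true 0.81)\n",
            nrow(sim$records), cf[1, 1], cf[1, 2], cf[2, 1], cf[2, 2]))

mid <- as.numeric(deposition_midpoint(sim$records$year_of_death,
                                      sim$records$age_years))
trend <- fit_temporal_trend(sim$records$d13C_sc, mid)
se_slope <- summary(stats::lm(sim$records$d13C_sc ~ mid))$coefficients[2, 2]
cat(sprintf("recovered Suess rate: %.4f +/- %.4f per mil/yr (true -0.023)\n",
            trend$slope, se_slope))

utils::write.csv(data.frame(
  quantity = c("coverage_95ci", "beta0_hat", "beta0_se", "beta1_hat",
               "beta1_se", "suess_rate_hat", "suess_rate_se"),
  value = c(cov$coverage, cf[1, 1], cf[1, 2], cf[2, 1], cf[2, 2],
            trend$slope, se_slope)),
  "results/synthetic_validation.csv", row.names = FALSE)
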