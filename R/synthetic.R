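#' Simulation configuration
#'
#' Study conditions for the synthetic isoscape and cohorts used to validate
#' the assignment procedure end-to-end. The isoscape emulates the North
#' Atlantic sea-surface delta-18O field: a latitudinal decline of a few per
#' mil plus a sharp negative step at the Gulf Stream front, small spatial
#' noise, and a fraction of land/no-data cells. Specimens are generated by
#' the forward calibration model (tissue = beta0 + beta1 * seawater value +
#' measurement noise) and their delta-13C carries the configured Suess
#' drift backwards from the reference year.
#'
#' @param seed Integer master seed; component sub-streams are derived from
#'   it deterministically, so regenerating the grid alone does not shift
#'   cohort draws.
#' @param n_lat,n_lon Grid shape.
#' @param lat_range,lon_range Degree spans of the grid (cell centers).
#' @param base Isoscape value at latitude 0, per mil.
#' @param lat_slope Latitudinal gradient, per mil per degree.
#' @param front_lat Latitude of the sharp front, degrees.
#' @param front_step Step added north of (at or above) the front, per mil;
#'   may be 0.
#' @param noise_sd Spatial noise SD, per mil.
#' @param land_fraction Fraction of cells set missing (land).
#' @param beta0,beta1 True calibration intercept/slope of the forward model.
#' @param beta0_sd,beta1_sd Calibration parameter SDs (used when
#'   `draw_calibration` is TRUE, and by the estimation side).
#' @param meas_sd Tissue measurement noise SD, per mil.
#' @param draw_calibration Draw per-whale calibration parameters from their
#'   distributions when generating tissue values (the data-generating
#'   process assumed by the propagated CI), rather than using the means.
#' @param suess_rate,ref_year True Suess drift, per mil/yr, and reference
#'   year.
#' @param d13c_base Baseline delta-13C at the reference year, per mil.
#' @param d13c_sd Individual delta-13C noise SD, per mil.
#' @param groups Data frame of cohort groups: `label`, `n`, `lat_lo`,
#'   `lat_hi` (home-latitude band), `year_lo`, `year_hi`, `age_lo`,
#'   `age_hi`, `d13c_offset` (group-level diet offset).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_lat = 60L, n_lon = 60L,
                       lat_range = c(0, 80), lon_range = c(-80, 0),
                       base = 1.2, lat_slope = -0.03,
                       front_lat = 42, front_step = -1.5,
                       noise_sd = 0.15, land_fraction = 0.1,
                       beta0 = 18.73, beta1 = 0.81,
                       beta0_sd = 0.30, beta1_sd = 0.23,
                       meas_sd = 0.22, draw_calibration = FALSE,
                       suess_rate = -0.023, ref_year = 2013,
                       d13c_base = -13.5, d13c_sd = 0.3,
                       groups = data.frame(
                         label = c("north", "south"),
                         n = c(10L, 10L),
                         lat_lo = c(50, 5), lat_hi = c(75, 35),
                         year_lo = 1950L, year_hi = 2013L,
                         age_lo = 3, age_hi = 35,
                         d13c_offset = 0)) {
  stopifnot(n_lat >= 2L, n_lon >= 2L, all(groups$n >= 1L),
            land_fraction >= 0, land_fraction < 1)
  structure(list(seed = as.integer(seed), n_lat = as.integer(n_lat),
                 n_lon = as.integer(n_lon), lat_range = lat_range,
                 lon_range = lon_range, base = base, lat_slope = lat_slope,
                 front_lat = front_lat, front_step = front_step,
                 noise_sd = noise_sd, land_fraction = land_fraction,
                 beta0 = beta0, beta1 = beta1,
                 beta0_sd = beta0_sd, beta1_sd = beta1_sd,
                 meas_sd = meas_sd, draw_calibration = draw_calibration,
                 suess_rate = suess_rate, ref_year = ref_year,
                 d13c_base = d13c_base, d13c_sd = d13c_sd,
                 groups = groups),
            class = "sim_config")
}

# deterministic per-component sub-seed, kept below 2^31
sub_seed <- function(seed, component) {
  offs <- c(grid = 104729L, specimens = 224737L, coverage = 350377L)
  (as.integer(seed) %% 1000003L) * 1009L + offs[[component]]
}

#' Generate a synthetic isoscape
#'
#' value(lat) = base + lat_slope * lat + front_step * [lat >= front_lat]
#' + Normal(0, noise_sd) per cell, with a `land_fraction` share of cells
#' set missing at random. Bit-reproducible given the config seed.
#'
#' @param config A [sim_config()].
#' @return An [isoscape_grid()].
#' @export
gen_isoscape <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sub_seed(config$seed, "grid"))
  lat <- seq(config$lat_range[1L], config$lat_range[2L],
             length.out = config$n_lat)
  lon <- seq(config$lon_range[1L], config$lon_range[2L],
             length.out = config$n_lon)
  det <- config$base + config$lat_slope * lat +
    config$front_step * (lat >= config$front_lat)
  values <- matrix(det, nrow = config$n_lat, ncol = config$n_lon) +
    matrix(stats::rnorm(config$n_lat * config$n_lon, 0, config$noise_sd),
           nrow = config$n_lat)
  if (config$land_fraction > 0) {
    land <- stats::runif(config$n_lat * config$n_lon) < config$land_fraction
    values[matrix(land, nrow = config$n_lat)] <- NA_real_
  }
  isoscape_grid(lat, lon, values)
}

#' Generate a synthetic specimen cohort with ground truth
#'
#' Each simulated whale is given a true home cell drawn uniformly from the
#' non-missing cells of its group's latitude band; its true seawater value
#' is the grid value there; its measured tissue value is
#' `beta0 + beta1 * m + Normal(0, meas_sd)` (with per-whale draws of beta0
#' and beta1 when `draw_calibration` is set); and its raw delta-13C is the
#' reference-year baseline plus the group diet offset, the Suess drift
#' evaluated at the deposition midpoint, and individual noise.
#'
#' @param config A [sim_config()].
#' @param grid An [isoscape_grid()], normally from [gen_isoscape()] with
#'   the same config.
#' @return List with `records` (specimen data frame as from
#'   [read_specimens()]) and `truth` (data frame `specimen_id`, `lat_idx`,
#'   `lon_idx`, `lat`, `lon`, `true_m`).
#' @export
gen_specimens <- function(config, grid) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sub_seed(config$seed, "specimens"))
  recs <- list(); truths <- list()
  for (g in seq_len(nrow(config$groups))) {
    grp <- config$groups[g, ]
    in_band <- grid$lat >= grp$lat_lo & grid$lat <= grp$lat_hi
    cells <- which(!is.na(grid$values) &
                     matrix(in_band, nrow = length(grid$lat),
                            ncol = length(grid$lon)))
    if (length(cells) == 0L) {
      stop("config error: no non-missing cells in latitude band of group ",
           grp$label, call. = FALSE)
    }
    n <- grp$n
    pick <- cells[sample.int(length(cells), n, replace = TRUE)]
    lat_idx <- (pick - 1L) %% length(grid$lat) + 1L
    lon_idx <- (pick - 1L) %/% length(grid$lat) + 1L
    true_m <- grid$values[pick]
    b0 <- if (config$draw_calibration) {
      stats::rnorm(n, config$beta0, config$beta0_sd)
    } else rep(config$beta0, n)
    b1 <- if (config$draw_calibration) {
      stats::rnorm(n, config$beta1, config$beta1_sd)
    } else rep(config$beta1, n)
    x <- b0 + b1 * true_m + stats::rnorm(n, 0, config$meas_sd)
    year <- sample(seq(grp$year_lo, grp$year_hi), n, replace = TRUE)
    age <- round(stats::runif(n, grp$age_lo, grp$age_hi))
    mid <- year - age / 2
    d13c <- config$d13c_base + grp$d13c_offset +
      config$suess_rate * (mid - config$ref_year) +
      stats::rnorm(n, 0, config$d13c_sd)
    ids <- sprintf("SIM-%s-%03d", grp$label, seq_len(n))
    recs[[g]] <- data.frame(specimen_id = ids, region = grp$label,
                            tissue = "dentine", year_of_death = year,
                            age_years = age, d18O_p = x, d13C_sc = d13c,
                            stranding_group = NA_character_,
                            stringsAsFactors = FALSE)
    truths[[g]] <- data.frame(specimen_id = ids, lat_idx = lat_idx,
                              lon_idx = lon_idx, lat = grid$lat[lat_idx],
                              lon = grid$lon[lon_idx], true_m = true_m,
                              stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, recs), truth = do.call(rbind, truths))
}

#' End-to-end coverage of the CI assignment procedure
#'
#' Simulates a cohort whose tissue values are generated under the same
#' calibration uncertainties the estimator propagates (per-whale parameter
#' draws plus measurement noise), runs the full estimate-and-assign chain,
#' and returns the fraction of whales whose true home cell falls inside
#' their assignment mask. At a well-calibrated `ci_level` this fraction
#' should match the nominal level up to Monte-Carlo error.
#'
#' @param config A [sim_config()]; its group sizes set the number of
#'   whales (>= 200 recommended). `draw_calibration` is forced on.
#' @param ci_level Confidence level of the assignment interval.
#' @return List: `coverage` (fraction), `n` (number of whales).
#' @export
coverage_experiment <- function(config, ci_level = 0.95) {
  config$draw_calibration <- TRUE
  grid <- gen_isoscape(config)
  sim <- gen_specimens(config, grid)
  calib <- calibration_model(beta0_mean = config$beta0,
                             beta0_sd = config$beta0_sd,
                             beta1_mean = config$beta1,
                             beta1_sd = config$beta1_sd,
                             meas_sd = config$meas_sd)
  est <- estimate_marine(sim$records, calib, ci_level = ci_level)
  # 1e-9 per-mil slack so the zero-width CI of a noise-free configuration
  # still contains its own value despite floating-point round-off
  hit <- mapply(function(lo, hi, li, lj) {
    v <- grid$values[li, lj]
    !is.na(v) && v >= lo - 1e-9 && v <= hi + 1e-9
  }, est$ci_lo, est$ci_hi, sim$truth$lat_idx, sim$truth$lon_idx)
  list(coverage = mean(hit), n = nrow(est))
}
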