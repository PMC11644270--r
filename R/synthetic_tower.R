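#' @importFrom stats rnorm runif rbinom rexp sd cor quantile
NULL

# Interpolate 12 monthly anchor values to a daily trajectory (piecewise
# linear between month centres, wrapping December -> January).
monthly_anchors_to_daily <- function(anchors, n_days, start_doy = 1) {
  stopifnot(length(anchors) == 12)
  centers <- c(15.5, 45, 74.5, 105, 135.5, 166, 196.5, 227.5, 258, 288.5,
               319, 349.5)
  x <- c(centers[12] - 365, centers, centers[1] + 365)
  y <- c(anchors[12], anchors, anchors[1])
  doy <- ((start_doy - 1 + seq_len(n_days) - 1) %% 365) + 1
  stats::approx(x, y, xout = doy)$y
}

#' Prescribed parameter trajectories for the synthetic tower
#'
#' Holds per-day trajectories of all DT-RH parameters plus the observation
#' noise and missing-data settings: the ground truth against which parameter
#' recovery is scored. Each parameter may be a scalar (constant through the
#' simulation), a vector of 12 monthly anchors (interpolated linearly between
#' month centres), or a length-`n_days` daily vector.
#'
#' @param n_days Number of simulated days.
#' @param e0_day,e0_night Temperature sensitivities (K).
#' @param r_ref_day,r_ref_night Base respiration rates (umol C m^-2 s^-1).
#' @param alpha Quantum yield (umol C J^-1).
#' @param beta0 Light-saturated uptake (umol C m^-2 s^-1).
#' @param k VPD sensitivity (hPa^-1).
#' @param epsilon Humidity-modifier sign, +1 or -1 (site constant).
#' @param noise_sd Gaussian observation noise on NEE (umol C m^-2 s^-1).
#' @param missing_fraction Fraction of records flagged gap-filled
#'   (`qc_nee = 1`), drawn in short bursts.
#' @param seed RNG seed for noise and missingness.
#'
#' @return A list of class `synthetic_truth` with a day-indexed `trajectories`
#'   tibble and scalar settings.
#' @export
synthetic_truth <- function(n_days, e0_day = 150, e0_night = 320,
                            r_ref_day = 3, r_ref_night = 3, alpha = 0.04,
                            beta0 = 20, k = 0.1, epsilon = 1L,
                            noise_sd = 1, missing_fraction = 0.1,
                            seed = 1L) {
  stopifnot(n_days >= 1, noise_sd >= 0,
            missing_fraction >= 0, missing_fraction <= 1,
            epsilon %in% c(-1, 1))
  daily <- function(x, name) {
    if (length(x) == 1) return(rep(x, n_days))
    if (length(x) == 12) return(monthly_anchors_to_daily(x, n_days))
    if (length(x) == n_days) return(x)
    stop("synthetic_truth: '", name,
         "' must be scalar, 12 monthly anchors, or length n_days")
  }
  traj <- tibble::tibble(
    day = seq_len(n_days),
    e0_day = daily(e0_day, "e0_day"),
    e0_night = daily(e0_night, "e0_night"),
    r_ref_day = daily(r_ref_day, "r_ref_day"),
    r_ref_night = daily(r_ref_night, "r_ref_night"),
    alpha = daily(alpha, "alpha"),
    beta0 = daily(beta0, "beta0"),
    k = daily(k, "k")
  )
  if (any(traj$e0_day <= 0 | traj$e0_night <= 0 | traj$r_ref_day <= 0 |
            traj$r_ref_night <= 0 | traj$alpha <= 0 | traj$beta0 <= 0 |
            traj$k < 0)) {
    stop("synthetic_truth: parameter trajectories violate positivity")
  }
  structure(list(trajectories = traj, epsilon = as.integer(epsilon),
                 noise_sd = noise_sd, missing_fraction = missing_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Default seasonal truth scenario
#'
#' A temperate-site scenario with the daytime temperature sensitivity peaking
#' June-September while the nighttime sensitivity is lowest then, so that the
#' day-night ratio dE0 exceeds 1 in the shoulder seasons and converges toward
#' 1 in summer. Respiration base rates and canopy parameters follow a growing
#' season cycle.
#'
#' @inheritParams synthetic_truth
#' @param ... Overrides passed to [synthetic_truth()].
#' @return A `synthetic_truth`.
#' @export
default_truth <- function(n_days = 365, seed = 1L, ...) {
  args <- list(
    n_days = n_days,
    e0_day = c(100, 105, 115, 130, 145, 160, 165, 162, 155, 135, 115, 103),
    e0_night = c(330, 325, 310, 280, 230, 190, 180, 182, 195, 250, 300, 325),
    r_ref_day = c(1.2, 1.3, 1.7, 2.3, 3.1, 3.8, 4.2, 4.0, 3.4, 2.5, 1.7, 1.3),
    r_ref_night = c(1.1, 1.2, 1.6, 2.2, 3.0, 3.7, 4.1, 3.9, 3.3, 2.4, 1.6, 1.2),
    alpha = c(0.025, 0.027, 0.032, 0.04, 0.048, 0.055, 0.058, 0.056, 0.05,
              0.04, 0.03, 0.026),
    beta0 = c(6, 7, 10, 14, 19, 24, 26, 25, 21, 15, 9, 7),
    k = 0.1, seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_truth, args)
}

# Saturation vapour pressure (hPa) over water, Magnus form.
sat_vp <- function(tair) 6.1078 * exp(17.269 * tair / (tair + 237.3))

#' Generate synthetic meteorological drivers
#'
#' Builds a half-hourly driver series for one site: shortwave radiation from
#' solar geometry (declination/zenith) with autocorrelated cloud dimming,
#' air temperature as a seasonal plus diurnal sinusoid (lagging solar noon)
#' with AR(1) day-to-day weather noise, relative humidity anti-correlated
#' with the diurnal temperature excursion, VPD from temperature and RH via
#' saturation vapour pressure, and intermittent precipitation.
#'
#' @param n_days Number of days (1 to 3660).
#' @param latitude Site latitude (decimal degrees, southern negative).
#' @param seed RNG seed; the series is reproducible bit-for-bit.
#' @param start_date First simulated day (default "2015-01-01").
#' @param step_minutes 30 (default) or 60.
#' @param sw_threshold Day/night radiation cut passed to [flag_day_night()].
#'
#' @return A [flux_series()] with drivers and day/night flags, `nee` missing.
#' @export
generate_drivers <- function(n_days, latitude = 45, seed = 1L,
                             start_date = "2015-01-01", step_minutes = 30,
                             sw_threshold = 20) {
  if (n_days < 1 || n_days > 3660) stop("generate_drivers: n_days out of range")
  if (abs(latitude) > 90) stop("generate_drivers: invalid latitude")
  set.seed(seed)
  per_day <- 24 * 60 / step_minutes
  n <- n_days * per_day
  t0 <- as.POSIXct(paste(start_date, "00:00"), tz = "UTC")
  ts <- t0 + (seq_len(n) - 1) * step_minutes * 60
  day_idx <- rep(seq_len(n_days), each = per_day)
  doy0 <- as.integer(strftime(t0, "%j", tz = "UTC"))
  doy <- ((doy0 - 1 + day_idx - 1) %% 365) + 1
  hour <- (as.numeric(ts - t0, units = "hours") %% 24) + step_minutes / 120

  # solar geometry: declination and cosine of zenith angle
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  lat_r <- latitude * pi / 180
  hang <- (hour - 12) * 15 * pi / 180
  cosz <- pmax(0, sin(lat_r) * sin(decl) + cos(lat_r) * cos(decl) * cos(hang))

  # daily cloud transmission, AR(1) in the open interval (0.25, 1)
  cl <- numeric(n_days)
  cl[1] <- 0.8
  innov <- rnorm(n_days, 0, 0.15)
  for (d in 2:max(2, n_days)) cl[d] <- 0.75 * cl[d - 1] + 0.25 * 0.8 + innov[d]
  cl <- pmin(1, pmax(0.25, cl))
  sw_in <- 1000 * cosz * cl[day_idx]

  # temperature: seasonal + diurnal (peak mid-afternoon) + AR(1) weather;
  # the seasonal amplitude follows a maritime-temperate gradient so that
  # winter temperatures at mid latitudes stay near freezing rather than
  # deeply below it (see the methods vignette)
  mat <- 26 - 0.38 * abs(latitude)
  seas_amp <- 1 + 0.15 * abs(latitude)
  phase <- if (latitude >= 0) 0 else 182.5
  t_seas <- mat - seas_amp * cos(2 * pi * (doy - 15 - phase) / 365)
  diur_amp <- 3 + 5 * cl[day_idx]   # clearer days have larger diurnal range
  t_diur <- diur_amp / 2 * cos(2 * pi * (hour - 14.5) / 24)
  w <- numeric(n_days)
  winnov <- rnorm(n_days, 0, 1.2)
  w[1] <- winnov[1]
  for (d in 2:max(2, n_days)) w[d] <- 0.8 * w[d - 1] + winnov[d]
  tair <- t_seas + t_diur + w[day_idx] + rnorm(n, 0, 0.3)

  # precipitation: wet days, bursts within the day
  wet <- rbinom(n_days, 1, 0.25) == 1
  precip <- numeric(n)
  if (any(wet)) {
    for (d in which(wet)) {
      idx <- which(day_idx == d)
      k_events <- sample(1:6, 1)
      at <- sample(idx, k_events)
      precip[at] <- precip[at] + rexp(k_events, rate = 0.8)
    }
  }

  # relative humidity: daily base (higher on wet days), anti-correlated with
  # the within-day temperature excursion
  rh_base <- 68 + 12 * wet[day_idx] + rep(rnorm(n_days, 0, 6), each = per_day)
  daymean_t <- rep(tapply(tair, day_idx, mean), each = per_day)
  rh <- pmin(100, pmax(15, rh_base - 3.2 * (tair - daymean_t)))
  vpd <- pmax(0, sat_vp(tair) * (1 - rh / 100))

  series <- flux_series(
    tibble::tibble(timestamp = ts, tair = tair, sw_in = sw_in, vpd = vpd,
                   rh = rh, precip = precip),
    site_id = sprintf("SYN-%02d", seed %% 100), latitude = latitude)
  flag_day_night(series, sw_threshold)
}

# Window-mean daytime RH per record under the fitter's own moving-window
# scheme: each record takes the daytime-mean RH of the window whose centre
# is nearest (the same assignment rule the ER reconstruction uses).
window_rh_bar <- function(series, spec = window_spec()) {
  wins <- make_windows(series, spec)
  dof <- day_offset(series)
  if (nrow(wins) == 0) {
    return(rep(mean(series$rh[series$is_day], na.rm = TRUE), nrow(series)))
  }
  wmeans <- vapply(seq_len(nrow(wins)), function(w) {
    sel <- dof >= wins$start_day[w] & dof < wins$end_day[w] & series$is_day
    if (any(sel)) mean(series$rh[sel], na.rm = TRUE) else NA_real_
  }, numeric(1))
  centers <- (wins$start_day + wins$end_day) / 2
  nearest <- vapply(dof + 0.5, function(d) which.min(abs(d - centers)),
                    integer(1))
  out <- wmeans[nearest]
  out[is.na(out)] <- mean(series$rh[series$is_day], na.rm = TRUE)
  out
}

#' Generate NEE from prescribed truth over a driver series
#'
#' Evaluates the DT-RH forward model with the truth's per-day parameter
#' trajectories on each record (daytime: light response plus humidity-scaled
#' respiration; nighttime: the two-parameter respiration term), adds Gaussian
#' observation noise, and flags a fraction of records as gap-filled
#' (`qc_nee = 1`) in short bursts. The window-mean RH entering the humidity
#' factor is the 7-day centred daytime mean, the same scheme the fitter uses.
#' The noise-free NEE, per-record window-mean RH, and the truth object are
#' stored in the `truth` attribute for later scoring.
#'
#' @param drivers A driver [flux_series()] from [generate_drivers()].
#' @param truth A [synthetic_truth()] whose trajectories cover the span.
#'
#' @return The series with `nee` and `qc_nee` populated.
#' @export
generate_nee <- function(drivers, truth) {
  per_day <- 24 * 60 / attr(drivers, "step_minutes")
  n_days <- nrow(drivers) / per_day
  if (nrow(truth$trajectories) < n_days) {
    stop("generate_nee: truth trajectories cover ",
         nrow(truth$trajectories), " days but drivers span ", n_days)
  }
  day_idx <- rep(seq_len(n_days), each = per_day)
  tr <- truth$trajectories[day_idx, ]
  rh_bar <- window_rh_bar(drivers)
  is_day <- drivers$is_day

  er_day <- lloyd_taylor(tr$r_ref_day, tr$e0_day, drivers$tair) *
    humidity_factor(truth$epsilon, drivers$rh, rh_bar)
  beta <- beta_of_vpd_vec(tr$beta0, tr$k, drivers$vpd)
  gpp <- tr$alpha * beta * drivers$sw_in / (tr$alpha * drivers$sw_in + beta)
  er_night <- lloyd_taylor(tr$r_ref_night, tr$e0_night, drivers$tair)
  nee_true <- ifelse(is_day, -gpp + er_day, er_night)
  er_true <- ifelse(is_day, er_day, er_night)

  set.seed(truth$seed)
  nee <- nee_true + rnorm(length(nee_true), 0, truth$noise_sd)
  qc <- integer(length(nee))
  n_miss <- round(truth$missing_fraction * length(nee))
  if (n_miss > 0) {
    flagged <- logical(length(nee))
    while (sum(flagged) < n_miss) {
      start <- sample.int(length(nee), 1)
      len <- 1 + stats::rgeom(1, prob = 0.15)
      flagged[start:min(length(nee), start + len - 1)] <- TRUE
    }
    qc[flagged] <- 1L
  }
  rec <- tibble::as_tibble(drivers)
  rec$nee <- nee
  rec$qc_nee <- qc
  out <- rewrap(rec, drivers)
  truth$record_truth <- tibble::tibble(nee_true = nee_true,
                                       er_true = er_true, rh_bar = rh_bar,
                                       day = day_idx)
  attr(out, "truth") <- truth
  out
}

# beta_of_vpd with vector beta0/k (per-record trajectories)
beta_of_vpd_vec <- function(beta0, k, vpd, constants = model_constants()) {
  ifelse(vpd > constants$vpd0, beta0 * exp(-k * (vpd - constants$vpd0)), beta0)
}

#' Simulate a complete synthetic tower year
#'
#' Convenience wrapper: [generate_drivers()] then [generate_nee()].
#'
#' @inheritParams generate_drivers
#' @param truth A [synthetic_truth()]; defaults to [default_truth()] over
#'   `n_days`.
#' @return A [flux_series()] with NEE and a `truth` attribute.
#' @export
simulate_tower <- function(n_days = 365, latitude = 45, seed = 1L,
                           truth = default_truth(n_days, seed = seed),
                           step_minutes = 30) {
  drivers <- generate_drivers(n_days, latitude, seed,
                              step_minutes = step_minutes)
  generate_nee(drivers, truth)
}
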