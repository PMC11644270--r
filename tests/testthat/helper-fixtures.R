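# Shared fixtures for the test suite. Everything is generated in code; the
# heavier simulated series are built once per test run and memoised here.

# day offset (0-based) of each record from the series' first calendar day
dof_of <- function(series) {
  t0 <- as.POSIXct(format(series$timestamp[1], "%Y-%m-%d"), tz = "UTC")
  floor(as.numeric(series$timestamp - t0, units = "days"))
}

# slice a series to day offsets [from, to)
slice_days <- function(series, from, to) {
  d <- dof_of(series)
  series[d >= from & d < to, ]
}

# a small constant-parameter tower with precomputed moving-window RH means,
# used by the fitting tests (noise controlled by the caller)
make_tower <- function(n_days, noise_sd, seed = 3, latitude = 45,
                       missing_fraction = 0, e0_day = 150, e0_night = 320,
                       ...) {
  tr <- synthetic_truth(n_days, e0_day = e0_day, e0_night = e0_night,
                        noise_sd = noise_sd,
                        missing_fraction = missing_fraction, seed = seed,
                        ...)
  s <- simulate_tower(n_days, latitude = latitude, seed = seed, truth = tr)
  s$rh_bar <- dnrflux:::window_rh_bar(s)
  s
}

# memoised 60-day noise-free series shared across fitting tests
noise_free_tower <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_tower(60, noise_sd = 0)
    cache
  }
})

# hand-built driver window with constant drivers: q/tair/vpd/rh cycles that
# make every parameter identifiable, plus NEE from explicit model algebra
make_day_window <- function(dp, np, seed = 1, n_days = 7, noise_sd = 0) {
  set.seed(seed)
  per_day <- 48
  n <- n_days * per_day
  ts <- as.POSIXct("2015-06-01", tz = "UTC") + (seq_len(n) - 1) * 1800
  hour <- ((seq_len(n) - 1) %% per_day) / 2
  q <- pmax(0, 800 * sin(pi * (hour - 5) / 14)) *
    rep(runif(n_days, 0.6, 1), each = per_day)
  tair <- 15 + 6 * sin(pi * (hour - 8) / 14) + rep(rnorm(n_days, 0, 1.5),
                                                   each = per_day)
  rh <- pmin(100, pmax(20, 70 - 2.5 * (tair - 15) + rnorm(n, 0, 3)))
  vpd <- pmax(0, 6.1078 * exp(17.269 * tair / (tair + 237.3)) *
                (1 - rh / 100))
  is_day <- q > 20
  rh_bar <- mean(rh[is_day])
  nee <- predict_nee(dp, np, q, tair, vpd, rh, rh_bar, is_day) +
    rnorm(n, 0, noise_sd)
  s <- flux_series(tibble::tibble(timestamp = ts, nee = nee, tair = tair,
                                  sw_in = q, vpd = vpd, rh = rh),
                   site_id = "WIN", latitude = 45)
  rec <- tibble::as_tibble(s)
  rec$is_day <- is_day
  dnrflux:::rewrap(rec, s)
}
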