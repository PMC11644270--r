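test_that("moving windows enumerate as documented", {
  s <- make_tower(30, noise_sd = 0, seed = 1)
  w <- make_windows(s, window_spec(7, 5))
  expect_identical(w$start_day, c(0L, 5L, 10L, 15L, 20L))
  expect_identical(w$end_day, w$start_day + 7L)
  expect_equal(as.numeric(w$center_date - as.POSIXct("2015-01-01", tz = "UTC"),
                          units = "days"),
               w$start_day + 3.5)
  # disjoint tiling when step equals window length
  wt <- make_windows(s, window_spec(5, 5))
  expect_identical(wt$start_day, seq(0L, 25L, 5L))
  # series shorter than a window yields no windows
  s3 <- make_tower(3, noise_sd = 0, seed = 1)
  expect_identical(nrow(make_windows(s3, window_spec(7, 5))), 0L)
})

test_that("nighttime fits recover truth on noise-free windows and agree with least squares", {
  s <- noise_free_tower()
  cfg <- fit_config(n_iter = 3000, seed = 5)
  w <- slice_days(s, 20, 27)
  mc <- fit_night_window(w, cfg, seed = 5)
  ls <- fit_night_window(w, cfg, method = "nls", seed = 5)
  expect_null(mc$skip_reason)
  expect_equal(mc$params$r_ref_night, 3, tolerance = 0.01)
  expect_equal(mc$params$e0_night, 320, tolerance = 0.01)
  expect_equal(unlist(mc$params), unlist(ls$params), tolerance = 0.01)
  # determinism
  mc2 <- fit_night_window(w, cfg, seed = 5)
  expect_identical(unlist(mc$params), unlist(mc2$params))
})

test_that("night fit skip rules fire on data that cannot identify E0", {
  s <- noise_free_tower()
  w <- slice_days(s, 20, 27)
  rec <- tibble::as_tibble(w)
  rec$tair <- 10  # isothermal window
  iso <- dnrflux:::rewrap(rec, w)
  out <- fit_night_window(iso, fit_config(n_iter = 1000, seed = 1))
  expect_null(out$params)
  expect_match(out$skip_reason, "temperature spread")
  few <- w[w$is_day | seq_len(nrow(w)) < 10, ]
  out2 <- fit_night_window(few, fit_config(n_iter = 1000, seed = 1))
  expect_match(out2$skip_reason, "insufficient nighttime")
})

test_that("daytime fits recover all five parameters on constructed noise-free windows", {
  dp <- day_params(0.05, 25, 0.15, 2.8, 190)
  np <- night_params(3, 310)
  w <- make_day_window(dp, np, seed = 21)
  cfg <- fit_config(n_iter = 4000, seed = 9)
  mc <- fit_day_window(w, 1L, cfg, seed = 9)
  ls <- fit_day_window(w, 1L, cfg, method = "nls", seed = 9)
  expect_null(mc$skip_reason)
  truth <- c(0.05, 25, 0.15, 2.8, 190)
  got <- unlist(mc$params)[1:5]
  expect_equal(unname(got), truth, tolerance = 0.05)
  expect_equal(unname(unlist(ls$params)[1:5]), truth, tolerance = 1e-4)
  # determinism of the sampler
  mc2 <- fit_day_window(w, 1L, cfg, seed = 9)
  expect_identical(unlist(mc$params), unlist(mc2$params))
})

test_that("k is pinned to zero when the VPD-limited branch is never active", {
  dp <- day_params(0.05, 25, 0.15, 2.8, 190)
  np <- night_params(3, 310)
  w <- make_day_window(dp, np, seed = 22)
  rec <- tibble::as_tibble(w)
  rec$vpd <- pmin(rec$vpd, 9.5)
  w2 <- dnrflux:::rewrap(rec, w)
  out <- fit_day_window(w2, 1L, fit_config(n_iter = 1500, seed = 2), seed = 2)
  expect_true(out$k_pinned)
  expect_identical(out$params$k, 0)
})

test_that("epsilon follows the sign of the standardized-respiration/RH correlation", {
  rh <- seq(40, 80, length.out = 10)
  expect_identical(as.integer(estimate_epsilon(2 - 0.01 * rh, rh)), -1L)
  expect_identical(as.integer(estimate_epsilon(1 + 0.01 * rh, rh)), 1L)
  # exactly zero correlation takes the "otherwise" branch
  expect_identical(as.integer(estimate_epsilon(rep(1.5, 10), rh)), 1L)
  expect_warning(out <- estimate_epsilon(c(1, 2), c(50, 60)), "fewer than 5")
  expect_identical(as.integer(out), 1L)
})

test_that("NT baseline shares the nighttime estimates and reconstructs ER everywhere", {
  s <- noise_free_tower()
  cfg <- fit_config(n_iter = 2000, seed = 3)
  spec <- window_spec()
  nt <- fit_nt_baseline(s, spec, cfg)
  w1 <- slice_days(s, nt$start_day[2], nt$end_day[2])
  direct <- fit_night_window(w1, cfg, method = "nls",
                             seed = cfg$seed + 7919L * 2L)
  expect_equal(nt$e0_night[2], direct$params$e0_night)
  expect_equal(nt$r_ref_night[2], direct$params$r_ref_night)
  er <- estimate_er_series(nt, s)
  dof <- dof_of(s)
  covered <- dof >= min(nt$start_day) & dof < max(nt$end_day)
  expect_true(all(!is.na(er$er[covered])))
  expect_true(all(is.na(er$er[!covered])))
  expect_true(all(er$er >= 0, na.rm = TRUE))
})

test_that("DT baseline fixes E0 from the night fit per window", {
  s <- noise_free_tower()
  cfg <- fit_config(n_iter = 2000, seed = 3)
  dt <- fit_dt_baseline(s, window_spec(), cfg)
  nt <- fit_nt_baseline(s, window_spec(), cfg)
  expect_equal(dt$e0, nt$e0_night)
  expect_true(any(!is.na(dt$r_ref_day)))
  er <- estimate_er_series(dt, s)
  expect_true(all(er$er >= 0, na.rm = TRUE))
})

test_that("full DT-RH partition is deterministic and reconstructs ER within coverage", {
  s <- make_tower(30, noise_sd = 0.5, seed = 17, missing_fraction = 0.05)
  cfg <- fit_config(n_iter = 1500, seed = 17)
  f1 <- partition_dtrh(s, config = cfg, epsilon = 1L)
  f2 <- partition_dtrh(s, config = cfg, epsilon = 1L)
  expect_identical(tibble::as_tibble(f1), tibble::as_tibble(f2))
  expect_identical(nrow(f1), 5L)
  expect_true(all(!is.na(f1$e0_day)))
  expect_true(all(f1$e0_day_lo <= f1$e0_day & f1$e0_day <= f1$e0_day_hi))
  expect_true(all(f1$e0_night_lo <= f1$e0_night &
                    f1$e0_night <= f1$e0_night_hi))
  er <- estimate_er_series(f1, s)
  truth_er <- attr(s, "truth")$record_truth$er_true
  ok <- !is.na(er$er)
  expect_gt(cor(er$er[ok], truth_er[ok]), 0.95)
  # identical fit sets imply zero NT-vs-reference bias
  expect_equal(er_bias_ignoring_delta(s, f1, f1), 0)
})

test_that("aggregated ER integrates carbon consistently", {
  er <- tibble::tibble(
    timestamp = as.POSIXct("2015-01-01", tz = "UTC") + (0:47) * 1800,
    is_day = FALSE, er = 2)
  agg <- aggregate_er(er, step_minutes = 30)
  expect_equal(agg$monthly$er_mean, 2)
  # 2 umol m-2 s-1 for one day = 2e-6 mol * 12.011 g * 86400 s
  expect_equal(agg$monthly$er_gc, 2 * 86400 * 12.011e-6)
  expect_identical(agg$monthly$n_gap, 0L)
})
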