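mk_monthly <- function(e0_day, e0_night, site_id = "S1", year = 2015L) {
  tibble::tibble(site_id = site_id, year = year,
                 month = seq_along(e0_day), e0_day = e0_day,
                 e0_night = e0_night, delta_e0 = e0_night / e0_day,
                 n_windows_day = 1L, n_windows_night = 1L)
}

test_that("monthly aggregation averages converged window estimates", {
  fits <- tibble::tibble(
    window_id = 1:4,
    center_date = as.POSIXct(c("2015-06-05", "2015-06-20", "2015-07-03",
                               "2015-07-20"), tz = "UTC"),
    e0_day = c(180, 220, 200, 240), e0_night = c(300, 340, 310, 330),
    converged_day = c(TRUE, TRUE, TRUE, FALSE),
    converged_night = c(TRUE, TRUE, TRUE, TRUE))
  m <- monthly_aggregate(fits, site_id = "X")
  expect_equal(m$e0_day[m$month == 6], 200)
  expect_equal(m$e0_night[m$month == 6], 320)
  expect_equal(m$delta_e0[m$month == 6], 320 / 200)
  # non-converged day window excluded, night window kept
  expect_equal(m$e0_day[m$month == 7], 200)
  expect_equal(m$e0_night[m$month == 7], 320)
  expect_identical(m$n_windows_day[m$month == 7], 1L)
  expect_identical(m$n_windows_night[m$month == 7], 2L)
  # single window passes straight through
  m1 <- monthly_aggregate(fits[1, ], site_id = "X")
  expect_equal(m1$e0_day, 180)
})

test_that("seasonal CV reproduces hand-computed values and is scale invariant", {
  m <- mk_monthly(rep(c(100, 300), 6), rep(250, 12))
  # sd of six 100s and six 300s = sqrt(120000/11), mean 200
  expect_equal(seasonal_cv(m, "day"), 100 * sqrt(120000 / 11) / 200)
  expect_equal(seasonal_cv(m, "day"), 52.22, tolerance = 1e-3)
  expect_equal(seasonal_cv(m, "night"), 0)
  m10 <- mk_monthly(10 * rep(c(100, 300), 6), rep(250, 12))
  expect_equal(seasonal_cv(m10, "day"), seasonal_cv(m, "day"))
  # too few months
  short <- mk_monthly(c(100, 300, NA, NA, NA, NA, NA, NA, 100, 300, NA, NA),
                      rep(250, 12))
  expect_true(is.na(seasonal_cv(short, "day")))
})

test_that("seasonal amplitude is max minus min, order free, missing safe", {
  expect_equal(seasonal_amplitude(rep(1.4, 12)), 0)
  d <- c(2, 2, 2, 2, 2, 1, 1, 1, 1, 2, 2, 2)
  expect_equal(seasonal_amplitude(d), 1)
  set.seed(1)
  expect_equal(seasonal_amplitude(sample(d)), 1)
  expect_true(is.na(seasonal_amplitude(c(1, 2, rep(NA, 10)))))
  expect_gte(seasonal_amplitude(runif(12, 1, 3)), 0)
})

test_that("per-biome day-night comparison behaves like a Welch test", {
  m <- mk_monthly(rep(200, 12), rep(200, 12))
  m$biome <- "ENF"
  out <- day_night_test(m)
  expect_equal(out$t, 0)
  expect_equal(out$p, 1)
  # antisymmetry: swapping day and night negates t
  m2 <- mk_monthly(rep(c(180, 220), 6), rep(c(300, 340), 6))
  m2$biome <- "DBF"
  sw <- m2
  sw$e0_day <- m2$e0_night; sw$e0_night <- m2$e0_day
  expect_equal(day_night_test(m2)$t, -day_night_test(sw)$t)
  expect_identical(day_night_test(m2)$direction, "night_higher")
  # insufficient groups skipped
  tiny <- m2[1:2, ]
  expect_true(is.na(day_night_test(tiny)$p))
})

test_that("a strong planted day-night difference is detected in every biome", {
  set.seed(31)
  rows <- lapply(c("ENF", "DBF", "GRA"), function(b) {
    n <- 200
    tibble::tibble(site_id = "S", year = 2015L, month = 1L,
                   e0_day = rnorm(n, 150, 30), e0_night = rnorm(n, 300, 60),
                   delta_e0 = NA_real_, n_windows_day = 1L,
                   n_windows_night = 1L, biome = b)
  })
  out <- day_night_test(dplyr::bind_rows(rows))
  expect_true(all(out$p < 0.001))
  expect_true(all(out$difference > 0))
})

test_that("latitudinal bins fold hemispheres and conserve sites", {
  sm <- tibble::tibble(latitude = c(43.7, -43.7, 5, 12, 67, -8),
                       asv_delta = c(1, 2, 0.3, 0.5, 2.5, 0.4))
  b <- latitudinal_bins(sm)
  expect_identical(sum(b$n), nrow(sm))
  b40 <- b[b$lat_lo == 40, ]
  expect_equal(b40$mean_asv, 1.5)
  expect_identical(b40$n, 2L)
  expect_identical(b40$lat_bin, "[40,50)")
})

test_that("a planted latitudinal trend appears in the bin means", {
  set.seed(7)
  lat <- runif(60, 5, 65)
  sm <- tibble::tibble(latitude = lat,
                       asv_delta = 0.03 * lat + rnorm(60, 0, 0.05))
  b <- latitudinal_bins(sm)
  expect_true(all(diff(b$mean_asv[order(b$lat_lo)]) > 0))
})

test_that("climate bins use 4 degC x 1 mm/day cells and keep empty cells", {
  sm <- tibble::tibble(mat = c(5.2, 6.1, 13.0), map_mm_day = c(2.3, 2.9, 0.4),
                       asv_delta = c(1, 2, 3))
  b <- climate_bins(sm)
  cell <- b[b$mat_lo == 4 & b$p_lo == 2, ]
  expect_equal(cell$mean_asv, 1.5)
  expect_identical(cell$n, 2L)
  empty <- b[b$mat_lo == 8 & b$p_lo == 1, ]
  expect_identical(empty$n, 0L)
  expect_true(is.na(empty$mean_asv))
  expect_identical(sum(b$n), nrow(sm))
  # a planted gradient along the temperature axis shows in the cell means
  set.seed(3)
  sm2 <- tibble::tibble(mat = runif(80, 0, 20), map_mm_day = 1.5,
                        asv_delta = 2 - 0.08 * runif(80, 0, 20))
  sm2$asv_delta <- 2 - 0.08 * sm2$mat + rnorm(80, 0, 0.02)
  b2 <- climate_bins(sm2)
  means <- b2$mean_asv[b2$n > 0][order(b2$mat_lo[b2$n > 0])]
  expect_true(all(diff(means) < 0))
})

test_that("thermal regions follow the 2 and 17 degC boundaries", {
  expect_identical(thermal_region(1), "boreal")
  expect_identical(thermal_region(2), "temperate")
  expect_identical(thermal_region(17), "temperate")
  expect_identical(thermal_region(17.01), "tropical")
  expect_identical(thermal_region(c(-10, 10, 25)),
                   c("boreal", "temperate", "tropical"))
})
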