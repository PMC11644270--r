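test_that("Lloyd-Taylor respiration returns r_ref at the reference temperature", {
  expect_identical(lloyd_taylor(2, 200, 15), 2)
  set.seed(1)
  r_ref <- runif(50, 0.1, 20)
  e0 <- runif(50, 10, 600)
  for (i in 1:50) {
    expect_equal(lloyd_taylor(r_ref[i], e0[i], 15), r_ref[i],
                 tolerance = 1e-14)
  }
  # E0 = 0 removes the temperature dependence entirely
  expect_equal(lloyd_taylor(2, 0, 35), 2)
})

test_that("Lloyd-Taylor matches a hand evaluation and is monotone in tair", {
  # 2 * exp(200 * (1/61.02 - 1/71.02)), evaluated independently
  expect_equal(lloyd_taylor(2, 200, 25), 2 * exp(200 * (1 / 61.02 - 1 / 71.02)),
               tolerance = 1e-12)
  expect_equal(lloyd_taylor(2, 200, 25), 3.1729, tolerance = 1e-4)
  tgrid <- seq(-20, 40, by = 0.5)
  r <- lloyd_taylor(1.5, 250, tgrid)
  expect_true(all(diff(r) > 0))
  # higher E0 raises respiration above T_ref and lowers it below
  lo <- lloyd_taylor(2, 100, tgrid)
  hi <- lloyd_taylor(2, 400, tgrid)
  expect_true(all(hi[tgrid > 15] > lo[tgrid > 15]))
  expect_true(all(hi[tgrid < 15] < lo[tgrid < 15]))
  expect_error(lloyd_taylor(2, 200, -50), "t0")
})

test_that("humidity factor is centred, signed, and floored at zero", {
  expect_identical(humidity_factor(1, 60, 60), 1)
  expect_equal(humidity_factor(1, 90, 60), 0.5)
  expect_equal(humidity_factor(-1, 90, 60), 1.5)
  expect_warning(out <- humidity_factor(1, 130, 60), "floored")
  expect_identical(out, 0)
  expect_error(humidity_factor(1, 50, 0), "positive")
  # epsilon flip mirrors the deviation around 1
  rh <- c(40, 55, 70, 85)
  expect_equal(humidity_factor(1, rh, 60) - 1, -(humidity_factor(-1, rh, 60) - 1))
})

test_that("VPD-limited beta has two branches continuous at the threshold", {
  expect_identical(beta_of_vpd(10, 0.2, 8), 10)
  expect_equal(beta_of_vpd(10, 0.1, 20), 10 * exp(-1), tolerance = 1e-12)
  expect_equal(beta_of_vpd(10, 0.1, 10), 10)
  expect_equal(beta_of_vpd(10, 0.1, 10 + 1e-9) / 10, 1, tolerance = 1e-8)
  v <- seq(0, 40, by = 0.25)
  expect_true(all(diff(beta_of_vpd(15, 0.3, v)) <= 0))
})

test_that("light response is hyperbolic with the documented landmarks", {
  expect_identical(light_response(0.05, 20, 0), 0)
  expect_equal(light_response(0.05, 20, 400), 10)  # half-saturation q = beta/alpha
  expect_equal(light_response(0.05, 20, 1e6), 20, tolerance = 1e-3)
  q <- seq(0, 2000, by = 10)
  lr <- light_response(0.05, 20, q)
  expect_true(all(lr <= pmin(0.05 * q, 20) + 1e-12))
  expect_true(all(diff(lr) > 0))
})

test_that("predicted NEE splits into day and night branches correctly", {
  dp <- day_params(0.05, 20, 0.1, 2.5, 180)
  np <- night_params(3, 300)
  # night at reference temperature is exactly r_ref_night
  expect_equal(predict_nee(dp, np, 0, 15, 5, 60, 60, FALSE), 3)
  # day with no light and rh at the window mean is pure respiration
  expect_equal(predict_nee(dp, np, 0, 25, 5, 60, 60, TRUE),
               lloyd_taylor(2.5, 180, 25))
  # nighttime prediction ignores radiation, VPD, and humidity
  base <- predict_nee(dp, np, 0, 10, 5, 60, 60, FALSE)
  for (args in list(c(500, 10, 5, 60), c(0, 10, 25, 60), c(0, 10, 5, 95))) {
    expect_identical(predict_nee(dp, np, args[1], args[2], args[3], args[4],
                                 60, FALSE), base)
  }
  # release convention flips the GPP term only
  upt <- predict_nee(dp, np, 500, 20, 5, 60, 60, TRUE)
  rel <- predict_nee(dp, np, 500, 20, 5, 60, 60, TRUE,
                     sign_convention = "release")
  er <- daytime_er(dp, 20, 60, 60)
  expect_equal(upt + rel, 2 * er)
})

test_that("predicted daytime NEE matches an independent re-evaluation of the model", {
  dp <- day_params(0.04, 18, 0.15, 3.2, 210, epsilon = -1L)
  np <- night_params(2.8, 350)
  set.seed(42)
  q <- runif(200, 0, 900); tair <- runif(200, 2, 32)
  vpd <- runif(200, 0, 30); rh <- runif(200, 30, 95); rh_bar <- 62
  got <- predict_nee(dp, np, q, tair, vpd, rh, rh_bar, rep(TRUE, 200))
  # spreadsheet-style re-evaluation, term by term
  beta <- ifelse(vpd > 10, 18 * exp(-0.15 * (vpd - 10)), 18)
  gpp <- 0.04 * beta * q / (0.04 * q + beta)
  er <- 3.2 * exp(210 * (1 / (15 + 46.02) - 1 / (tair + 46.02))) *
    pmax(0, 1 + (rh - 62) / 62)
  expect_equal(got, -gpp + er, tolerance = 1e-10)
})

test_that("daytime ER is the humidity-scaled respiration term alone", {
  dp <- day_params(0.05, 20, 0.1, 2.5, 180)
  expect_equal(daytime_er(dp, 15, 60, 60), 2.5)
  tgrid <- seq(0, 35, by = 1)
  er <- daytime_er(dp, tgrid, 60, 60)
  expect_true(all(diff(er) > 0))
})
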