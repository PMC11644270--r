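test_that("CSV round trip preserves the series", {
  s <- make_tower(4, noise_sd = 0.5, seed = 11, missing_fraction = 0.05)
  s$rh_bar <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write_fluxnet_csv(s, path)
  hdr <- readLines(path, n = 1)
  expect_match(hdr, "TIMESTAMP_START")
  expect_match(hdr, "NEE_VUT_USTAR50")
  back <- read_fluxnet_csv(path, site_id = attr(s, "site_id"),
                           latitude = attr(s, "latitude"))
  expect_equal(back$timestamp, s$timestamp)
  for (col in c("nee", "tair", "sw_in", "vpd", "rh", "precip")) {
    expect_equal(back[[col]], s[[col]], tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(back$qc_nee, s$qc_nee)
  expect_equal(attr(back, "step_minutes"), 30)
})

test_that("missing sentinel and malformed input are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "TIMESTAMP_START,NEE_VUT_USTAR50,TA_F,SW_IN_F,VPD_F,RH,P_F,NEE_VUT_USTAR50_QC",
    "201501010000,-9999,5.2,0,1.1,80,0,0",
    "201501010030,1.4,5.0,0,1.0,-9999,0,0"), path)
  s <- read_fluxnet_csv(path)
  expect_true(is.na(s$nee[1]))
  expect_true(is.na(s$rh[2]))
  expect_false(is.na(s$nee[2]))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TIMESTAMP_START,NEE_VUT_USTAR50,TA_F,SW_IN_F,VPD_F",
               "2015,1,1,0,1"), bad)
  expect_error(read_fluxnet_csv(bad), "timestamp")

  miss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TIMESTAMP_START,TA_F,SW_IN_F,VPD_F", "201501010000,5,0,1"),
             miss)
  expect_error(read_fluxnet_csv(miss), "missing required column")

  gap <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "TIMESTAMP_START,NEE_VUT_USTAR50,TA_F,SW_IN_F,VPD_F,RH,P_F,NEE_VUT_USTAR50_QC",
    "201501010000,1,5,0,1,80,0,0",
    "201501010030,1,5,0,1,80,0,0",
    "201501010230,1,5,0,1,80,0,0"), gap)
  expect_error(read_fluxnet_csv(gap), "step")
})

test_that("RH gap-fill recovers a planted deterministic relation and touches nothing else", {
  s <- make_tower(10, noise_sd = 0, seed = 5)
  rec <- tibble::as_tibble(s)
  rec$rh <- pmin(100, pmax(0, 100 - rec$vpd))  # plant rh = 100 - vpd
  set.seed(99)
  holes <- sample(nrow(rec), round(0.1 * nrow(rec)))
  truth_rh <- rec$rh
  rec$rh[holes] <- NA
  s2 <- dnrflux:::rewrap(rec, s)
  filled <- gap_fill_rh(s2, seed = 7)
  expect_false(anyNA(filled$rh))
  # untouched where present
  expect_identical(filled$rh[-holes], rec$rh[-holes])
  # planted relation recovered within 1% of scale
  expect_lt(max(abs(filled$rh[holes] - truth_rh[holes])), 1)
  expect_true(all(filled$rh >= 0 & filled$rh <= 100))
  # determinism and identity
  filled2 <- gap_fill_rh(s2, seed = 7)
  expect_identical(filled$rh, filled2$rh)
  expect_identical(gap_fill_rh(s)$rh, s$rh)
  # too little training data
  tiny <- s2[1:120, ]
  rec_t <- tibble::as_tibble(tiny); rec_t$rh[1:90] <- NA
  expect_error(gap_fill_rh(dnrflux:::rewrap(rec_t, tiny)), "100")
})

test_that("day/night flagging uses a strict radiation threshold and partitions all records", {
  s <- make_tower(3, noise_sd = 0, seed = 2)
  rec <- tibble::as_tibble(s)
  rec$sw_in <- c(0, 25, 20, rec$sw_in[-(1:3)])
  s2 <- flag_day_night(dnrflux:::rewrap(rec, s), sw_threshold = 20)
  expect_false(s2$is_day[1])
  expect_true(s2$is_day[2])
  expect_false(s2$is_day[3])   # boundary is night: strict inequality
  counts <- attr(s2, "day_night_counts")
  expect_identical(sum(counts), nrow(s2))
  expect_false(anyNA(s2$is_day))
})

test_that("QC filtering masks NEE but keeps drivers", {
  s <- make_tower(5, noise_sd = 0.5, seed = 4)
  rec <- tibble::as_tibble(s)
  rec$qc_nee <- rep(c(0L, 1L), length.out = nrow(rec))
  s2 <- dnrflux:::rewrap(rec, s)
  f <- qc_filter(s2, max_qc = 0L)
  expect_true(all(is.na(f$nee[f$qc_nee == 1])))
  expect_identical(f$nee[f$qc_nee == 0], s2$nee[f$qc_nee == 0])
  expect_identical(f$tair, s2$tair)
  expect_identical(sum(!is.na(f$nee)), sum(rec$qc_nee == 0))
  # permissive threshold is the identity
  expect_identical(qc_filter(s2, max_qc = 99L)$nee, s2$nee)
})

test_that("flux_series validates physical ranges and time structure", {
  ts <- as.POSIXct("2015-01-01", tz = "UTC") + c(0, 1800, 3600)
  ok <- tibble::tibble(timestamp = ts, tair = 5, sw_in = 0, vpd = 1)
  expect_s3_class(flux_series(ok), "flux_series")
  bad_sw <- ok; bad_sw$sw_in <- c(-1, 0, 0)
  expect_error(flux_series(bad_sw), "sw_in")
  bad_t <- ok; bad_t$timestamp <- ts[c(1, 3, 2)]
  expect_error(flux_series(bad_t), "increasing")
  expect_error(flux_series(ok, biome = "XYZ"), "biome")
})
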