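#' @importFrom rlang .data
#' @importFrom stats predict complete.cases
NULL

BIOME_CODES <- c("CRO", "DBF", "EBF", "ENF", "MF", "GRA", "SAV", "SH", "WET")

#' Construct a flux series
#'
#' A `flux_series` is a tibble of half-hourly (or hourly) tower records —
#' `timestamp`, `nee`, `tair`, `sw_in`, `vpd`, `rh`, `precip`, `qc_nee`,
#' `is_day` — carrying site metadata (`site_id`, `latitude`, `longitude`,
#' `biome`, `step_minutes`) as attributes. Timestamps are interval starts in
#' local standard time (represented as UTC POSIXct), strictly increasing at a
#' constant step.
#'
#' @param records A data frame with at least `timestamp`, `tair`, `sw_in`,
#'   `vpd`; missing optional columns (`nee`, `rh`, `precip`, `qc_nee`,
#'   `is_day`) are added as NA/defaults.
#' @param site_id Site identifier string.
#' @param latitude,longitude Site coordinates (decimal degrees).
#' @param biome One of the nine ecosystem codes
#'   CRO, DBF, EBF, ENF, MF, GRA, SAV, SH, WET (or NA).
#' @param validate Check physical-range and time-structure invariants.
#'
#' @return A `flux_series` object.
#' @export
flux_series <- function(records, site_id = "SYN", latitude = NA_real_,
                        longitude = NA_real_, biome = NA_character_,
                        validate = TRUE) {
  records <- tibble::as_tibble(records)
  for (col in c("nee", "rh", "precip")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  if (!"qc_nee" %in% names(records)) records$qc_nee <- 0L
  if (!"is_day" %in% names(records)) records$is_day <- NA
  records <- records[, c("timestamp", "nee", "tair", "sw_in", "vpd", "rh",
                         "precip", "qc_nee", "is_day")]
  dt <- diff(as.numeric(records$timestamp))
  if (length(dt) == 0) stop("flux_series: need at least two records")
  step_minutes <- dt[1] / 60
  if (validate) {
    if (any(dt <= 0)) stop("flux_series: timestamps must be strictly increasing")
    if (any(abs(dt - dt[1]) > 1e-6)) {
      stop("flux_series: non-constant timestamp step")
    }
    if (!step_minutes %in% c(30, 60)) {
      stop("flux_series: step must be 30 or 60 minutes, got ", step_minutes)
    }
    if (!is.na(biome) && !biome %in% BIOME_CODES) {
      stop("flux_series: unknown biome code '", biome, "'")
    }
    if (any(records$sw_in < 0, na.rm = TRUE)) stop("flux_series: sw_in < 0")
    if (any(records$vpd < 0, na.rm = TRUE)) stop("flux_series: vpd < 0")
    if (any(records$precip < 0, na.rm = TRUE)) stop("flux_series: precip < 0")
    if (any(records$rh < 0 | records$rh > 100, na.rm = TRUE)) {
      stop("flux_series: rh outside [0, 100]")
    }
  }
  structure(records,
            class = c("flux_series", class(tibble::tibble()))) |>
    set_flux_attrs(site_id = site_id, latitude = latitude,
                   longitude = longitude, biome = biome,
                   step_minutes = step_minutes)
}

set_flux_attrs <- function(x, ...) {
  dots <- list(...)
  for (nm in names(dots)) attr(x, nm) <- dots[[nm]]
  x
}

# Rebuild a flux_series around a modified records tibble, keeping metadata.
rewrap <- function(records, template) {
  structure(tibble::as_tibble(records),
            class = class(template),
            site_id = attr(template, "site_id"),
            latitude = attr(template, "latitude"),
            longitude = attr(template, "longitude"),
            biome = attr(template, "biome"),
            step_minutes = attr(template, "step_minutes"),
            truth = attr(template, "truth"))
}

#' @export
print.flux_series <- function(x, ...) {
  cat(sprintf("<flux_series> site %s (lat %.2f), %d records at %d-min step\n",
              attr(x, "site_id"), attr(x, "latitude"), nrow(x),
              as.integer(attr(x, "step_minutes"))))
  NextMethod()
}

#' Default FLUXNET2015 column mapping
#'
#' Maps internal field names to the FLUXNET2015 column headers used on disk.
#' Override individual entries to read files with other naming schemes.
#'
#' @param ... Named overrides, e.g. `nee = "NEE_VUT_REF"`.
#' @return Named character vector internal-name -> file column.
#' @export
fluxnet_columns <- function(...) {
  map <- c(timestamp = "TIMESTAMP_START", nee = "NEE_VUT_USTAR50",
           tair = "TA_F", sw_in = "SW_IN_F", vpd = "VPD_F", rh = "RH",
           precip = "P_F", qc_nee = "NEE_VUT_USTAR50_QC")
  dots <- c(...)
  map[names(dots)] <- dots
  map
}

#' Read a FLUXNET2015-style half-hourly CSV
#'
#' Parses a comma-separated file with a `TIMESTAMP_START` column in
#' `YYYYMMDDHHMM` form, maps columns per `column_map`, converts the missing
#' sentinel to NA, and validates the time structure.
#'
#' @param path File path.
#' @param column_map Named vector from [fluxnet_columns()].
#' @param missing_code Missing-value sentinel (default -9999).
#' @param site_id,latitude,longitude,biome Site metadata attached to the
#'   result.
#'
#' @return A [flux_series()].
#' @export
read_fluxnet_csv <- function(path, column_map = fluxnet_columns(),
                             missing_code = -9999, site_id = "SITE",
                             latitude = NA_real_, longitude = NA_real_,
                             biome = NA_character_) {
  if (!file.exists(path)) stop("read_fluxnet_csv: no such file: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  required <- c("timestamp", "nee", "tair", "sw_in", "vpd")
  missing_cols <- setdiff(column_map[required], names(raw))
  if (length(missing_cols) > 0) {
    stop("read_fluxnet_csv: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  take <- function(field) {
    col <- column_map[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NULL
  }
  ts_raw <- take("timestamp")
  ts_chr <- sprintf("%012.0f", ts_raw)
  ts <- as.POSIXct(ts_chr, format = "%Y%m%d%H%M", tz = "UTC")
  if (any(is.na(ts))) {
    bad <- which(is.na(ts))[1]
    stop("read_fluxnet_csv: malformed timestamp in data row ", bad,
         ": ", ts_raw[bad])
  }
  desent <- function(x) {
    if (is.null(x)) return(NULL)
    x[!is.na(x) & x == missing_code] <- NA_real_
    x
  }
  rec <- tibble::tibble(
    timestamp = ts,
    nee = desent(take("nee")),
    tair = desent(take("tair")),
    sw_in = desent(take("sw_in")),
    vpd = desent(take("vpd"))
  )
  for (field in c("rh", "precip")) {
    v <- desent(take(field))
    rec[[field]] <- if (is.null(v)) NA_real_ else v
  }
  qc <- take("qc_nee")
  rec$qc_nee <- if (is.null(qc)) 0L else as.integer(ifelse(
    !is.na(qc) & qc == missing_code, NA, qc))
  rec <- rec[order(rec$timestamp), ]
  if (anyDuplicated(rec$timestamp)) {
    stop("read_fluxnet_csv: duplicate timestamps")
  }
  flux_series(rec, site_id = site_id, latitude = latitude,
              longitude = longitude, biome = biome)
}

#' Write a flux series as FLUXNET-dialect CSV
#'
#' Inverse of [read_fluxnet_csv()]: standard column headers, timestamps as
#' `YYYYMMDDHHMM`, NA encoded as the missing sentinel.
#'
#' @param series A [flux_series()].
#' @param path Output file path.
#' @param missing_code Sentinel written for missing values (default -9999).
#' @return `path`, invisibly.
#' @export
write_fluxnet_csv <- function(series, path, missing_code = -9999) {
  map <- fluxnet_columns()
  out <- tibble::tibble(
    TIMESTAMP_START = format(series$timestamp, "%Y%m%d%H%M")
  )
  for (field in c("nee", "tair", "sw_in", "vpd", "rh", "precip")) {
    v <- series[[field]]
    v[is.na(v)] <- missing_code
    out[[map[[field]]]] <- v
  }
  qc <- series$qc_nee
  qc[is.na(qc)] <- missing_code
  out[[map[["qc_nee"]]]] <- qc
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Gap-fill relative humidity from temperature and VPD
#'
#' Trains a random-forest regression of RH on (tair, vpd) over records where
#' RH is present and predicts the missing values, clamped to [0, 100].
#' Non-missing values are never modified; the fill is deterministic for a
#' fixed seed.
#'
#' @param series A [flux_series()].
#' @param seed Integer RNG seed for the forest.
#' @param ntree Number of trees (default 200).
#'
#' @return The series with `rh` gap-filled.
#' @export
gap_fill_rh <- function(series, seed = 1L, ntree = 200) {
  miss <- is.na(series$rh)
  if (!any(miss)) return(series)
  train <- !miss & !is.na(series$tair) & !is.na(series$vpd)
  if (sum(train) < 100) {
    stop("gap_fill_rh: need >= 100 records with rh present, have ",
         sum(train))
  }
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = data.frame(tair = series$tair[train], vpd = series$vpd[train]),
    y = series$rh[train], ntree = ntree)
  pred_idx <- miss & !is.na(series$tair) & !is.na(series$vpd)
  pred <- predict(fit, data.frame(tair = series$tair[pred_idx],
                                  vpd = series$vpd[pred_idx]))
  rec <- tibble::as_tibble(series)
  rec$rh[pred_idx] <- pmin(100, pmax(0, unname(pred)))
  rewrap(rec, series)
}

#' Flag day and night records by shortwave radiation
#'
#' `is_day = sw_in > sw_threshold` (strict). The returned series carries the
#' day/night counts in its `day_night_counts` attribute.
#'
#' @param series A [flux_series()].
#' @param sw_threshold Radiation threshold (W m^-2); default 20, a common
#'   micrometeorological day/night cut.
#'
#' @return The series with `is_day` set.
#' @export
flag_day_night <- function(series, sw_threshold = 20) {
  if (any(is.na(series$sw_in))) {
    stop("flag_day_night: sw_in must be present on all records")
  }
  rec <- tibble::as_tibble(series)
  rec$is_day <- rec$sw_in > sw_threshold
  out <- rewrap(rec, series)
  attr(out, "day_night_counts") <- c(day = sum(rec$is_day),
                                     night = sum(!rec$is_day))
  out
}

#' Mask gap-filled NEE by quality flag
#'
#' Records whose `qc_nee` exceeds `max_qc` have `nee` set to missing so that
#' only (sufficiently) measured fluxes enter parameter fitting; driver
#' columns are retained for forward prediction.
#'
#' @param series A [flux_series()].
#' @param max_qc Highest acceptable QC flag (default 0: measured data only).
#'
#' @return The filtered series.
#' @export
qc_filter <- function(series, max_qc = 0L) {
  rec <- tibble::as_tibble(series)
  drop <- !is.na(rec$qc_nee) & rec$qc_nee > max_qc
  rec$nee[drop] <- NA_real_
  rewrap(rec, series)
}
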