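#' Aggregate window fits to monthly temperature sensitivities
#'
#' Monthly `e0_day` and `e0_night` are arithmetic means of the converged
#' window estimates whose centre dates fall in the month; the day-night
#' ratio `delta_e0 = e0_night / e0_day` is computed from the monthly means
#' (not averaged over window ratios, which amplifies noise when `e0_day` is
#' small). Months without any window carry missing values.
#'
#' @param fits A `window_fits` tibble from [partition_dtrh()].
#' @param require_converged Use only windows whose sampler converged
#'   (default TRUE; non-converged estimates are still reported by the
#'   fitter but excluded here).
#' @param site_id Site label for the output (defaults to the fits' site).
#'
#' @return Tibble `site_id`, `year`, `month`, `e0_day`, `e0_night`,
#'   `delta_e0`, `n_windows_day`, `n_windows_night`.
#' @export
monthly_aggregate <- function(fits, require_converged = TRUE,
                              site_id = attr(fits, "site_id")) {
  if (is.null(site_id)) site_id <- "SITE"
  use_day <- !is.na(fits$e0_day) &
    (!require_converged | (!is.na(fits$converged_day) & fits$converged_day))
  use_night <- !is.na(fits$e0_night) &
    (!require_converged |
       (!is.na(fits$converged_night) & fits$converged_night))
  tb <- tibble::tibble(
    year = as.integer(format(fits$center_date, "%Y")),
    month = as.integer(format(fits$center_date, "%m")),
    e0_day = ifelse(use_day, fits$e0_day, NA_real_),
    e0_night = ifelse(use_night, fits$e0_night, NA_real_))
  out <- tb |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(
      n_windows_day = sum(!is.na(.data$e0_day)),
      n_windows_night = sum(!is.na(.data$e0_night)),
      e0_day = ifelse(.data$n_windows_day[1] > 0,
                      mean(.data$e0_day, na.rm = TRUE), NA_real_),
      e0_night = ifelse(.data$n_windows_night[1] > 0,
                        mean(.data$e0_night, na.rm = TRUE), NA_real_),
      .groups = "drop") |>
    dplyr::mutate(delta_e0 = .data$e0_night / .data$e0_day,
                  site_id = site_id) |>
    dplyr::select("site_id", "year", "month", "e0_day", "e0_night",
                  "delta_e0", "n_windows_day", "n_windows_night")
  out
}

#' Seasonal coefficient of variation of monthly E0
#'
#' `100 * sd / mean` over the available monthly values of one site-year,
#' using the sample standard deviation. Requires at least `min_months`
#' non-missing months.
#'
#' @param monthly A monthly tibble for one site-year
#'   (from [monthly_aggregate()]).
#' @param which One of `"day"`, `"night"`, `"delta"`.
#' @param min_months Minimum non-missing months (default 8).
#'
#' @return CV in percent, or NA when too few months are available.
#' @export
seasonal_cv <- function(monthly, which = c("day", "night", "delta"),
                        min_months = 8) {
  which <- match.arg(which)
  x <- switch(which, day = monthly$e0_day, night = monthly$e0_night,
              delta = monthly$delta_e0)
  x <- x[!is.na(x)]
  if (length(x) < min_months) return(NA_real_)
  100 * sd(x) / mean(x)
}

#' Seasonal amplitude of the day-night sensitivity ratio
#'
#' The difference between the highest and lowest monthly
#' `e0_night / e0_day` ratios within a calendar year.
#'
#' @param delta_e0 Monthly ratio values of one site-year (vector, may
#'   contain NA).
#' @param min_months Minimum non-missing months (default 8).
#'
#' @return The amplitude (dimensionless), or NA when too few months.
#' @export
seasonal_amplitude <- function(delta_e0, min_months = 8) {
  x <- delta_e0[!is.na(delta_e0)]
  if (length(x) < min_months) return(NA_real_)
  max(x) - min(x)
}

#' Per-site-year seasonal summary
#'
#' Computes the seasonal CV of daytime, nighttime and ratio series and the
#' seasonal amplitude of the ratio for every site-year in a monthly table.
#'
#' @param monthly Output of [monthly_aggregate()] (possibly several sites /
#'   years bound together).
#' @param min_months Minimum non-missing months per statistic (default 8).
#'
#' @return Tibble `site_id`, `year`, `cv_day`, `cv_night`, `cv_delta`,
#'   `asv_delta`, `n_months`.
#' @export
seasonal_summary <- function(monthly, min_months = 8) {
  monthly |>
    dplyr::group_by(.data$site_id, .data$year) |>
    dplyr::summarise(
      cv_day = seasonal_cv(dplyr::pick(dplyr::everything()), "day",
                           min_months),
      cv_night = seasonal_cv(dplyr::pick(dplyr::everything()), "night",
                             min_months),
      cv_delta = seasonal_cv(dplyr::pick(dplyr::everything()), "delta",
                             min_months),
      asv_delta = seasonal_amplitude(.data$delta_e0, min_months),
      n_months = sum(!is.na(.data$delta_e0)),
      .groups = "drop")
}

#' Day-versus-night E0 comparison per biome
#'
#' Welch two-sample t-test of monthly nighttime against daytime E0 within
#' each biome group. Groups with fewer than `min_n` records on either side
#' are skipped.
#'
#' @param monthly A monthly E0 table with a `biome` column added.
#' @param min_n Minimum records per side (default 3).
#'
#' @return Tibble `biome`, `n`, `mean_day`, `mean_night`, `difference`
#'   (night minus day), `t`, `p`, `direction`.
#' @export
day_night_test <- function(monthly, min_n = 3) {
  stopifnot("biome" %in% names(monthly))
  monthly |>
    dplyr::group_by(.data$biome) |>
    dplyr::group_modify(function(g, key) {
      d <- g$e0_day[!is.na(g$e0_day)]
      n <- g$e0_night[!is.na(g$e0_night)]
      if (length(d) < min_n || length(n) < min_n) {
        return(tibble::tibble(n = nrow(g), mean_day = NA_real_,
                              mean_night = NA_real_, difference = NA_real_,
                              t = NA_real_, p = NA_real_,
                              direction = NA_character_))
      }
      tt <- tryCatch(stats::t.test(n, d, var.equal = FALSE),
                     error = function(e) NULL)
      if (is.null(tt)) {
        # degenerate (essentially constant) samples: no evidence of any
        # difference when the means agree
        tt <- list(statistic = c(t = (mean(n) - mean(d)) /
                                   max(1e-12, abs(mean(d)))),
                   p.value = if (isTRUE(all.equal(mean(n), mean(d)))) 1 else 0)
      }
      m_day <- mean(d); m_night <- mean(n)
      tibble::tibble(
        n = nrow(g), mean_day = m_day, mean_night = m_night,
        difference = m_night - m_day, t = unname(tt$statistic),
        p = tt$p.value,
        direction = ifelse(m_night > m_day, "night_higher", "day_higher"))
    }) |>
    dplyr::ungroup()
}

#' Latitudinal binning of seasonal amplitudes
#'
#' Bins site summaries at 10-degree intervals of absolute latitude
#' (hemispheres folded together) and reports per-bin means of the
#' multi-year seasonal amplitude, overall and per biome when a `biome`
#' column is present.
#'
#' @param summaries Tibble with `latitude` and `asv_delta` (one row per
#'   site or site-year), optionally `biome`.
#'
#' @return Tibble `lat_bin` (label), `lat_lo`, `biome` (or "all"),
#'   `mean_asv`, `n`.
#' @export
latitudinal_bins <- function(summaries) {
  stopifnot(all(abs(summaries$latitude) <= 90, na.rm = TRUE))
  lo <- 10 * floor(abs(summaries$latitude) / 10)
  tb <- summaries |>
    dplyr::mutate(lat_lo = lo,
                  lat_bin = sprintf("[%d,%d)", lo, lo + 10),
                  biome = if ("biome" %in% names(summaries))
                    .data$biome else "all")
  tb |>
    dplyr::group_by(.data$lat_bin, .data$lat_lo, .data$biome) |>
    dplyr::summarise(mean_asv = mean(.data$asv_delta, na.rm = TRUE),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$lat_lo, .data$biome)
}

#' Climate-space binning of seasonal amplitudes
#'
#' Bins site summaries on a rectangular mean-annual-temperature by
#' mean-daily-precipitation grid (4 degrees C by 1 mm/day cells) and
#' reports the per-cell mean amplitude and site count; empty cells within
#' the occupied range carry a count of 0 and a missing mean.
#'
#' @param summaries Tibble with `mat` (degrees C), `map_mm_day`
#'   (mm per day), `asv_delta`.
#' @param t_width,p_width Cell widths (defaults 4 and 1).
#'
#' @return Tibble `mat_lo`, `p_lo`, `mean_asv`, `n` covering the full
#'   rectangular grid spanned by the data.
#' @export
climate_bins <- function(summaries, t_width = 4, p_width = 1) {
  mat_lo <- t_width * floor(summaries$mat / t_width)
  p_lo <- p_width * floor(summaries$map_mm_day / p_width)
  occupied <- tibble::tibble(mat_lo = mat_lo, p_lo = p_lo,
                             asv = summaries$asv_delta) |>
    dplyr::group_by(.data$mat_lo, .data$p_lo) |>
    dplyr::summarise(mean_asv = mean(.data$asv, na.rm = TRUE),
                     n = dplyr::n(), .groups = "drop")
  grid <- tidyr::expand_grid(
    mat_lo = seq(min(mat_lo), max(mat_lo), by = t_width),
    p_lo = seq(min(p_lo), max(p_lo), by = p_width))
  grid |>
    dplyr::left_join(occupied, by = c("mat_lo", "p_lo")) |>
    dplyr::mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
}

#' Thermal region from mean annual temperature
#'
#' Boreal below 2 degrees C, temperate from 2 to 17 inclusive, tropical
#' above 17.
#'
#' @param mat Mean annual temperature (degrees C); vectorised.
#' @return Character vector in {"boreal", "temperate", "tropical"}.
#' @export
#' @examples
#' thermal_region(c(1, 2, 17, 17.01))
thermal_region <- function(mat) {
  stopifnot(all(is.finite(mat)))
  ifelse(mat < 2, "boreal", ifelse(mat <= 17, "temperate", "tropical"))
}
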