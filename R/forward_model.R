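#' Model constants for the DT-RH partitioning model
#'
#' The three fixed constants of the DT-RH model: the reference temperature of
#' the Lloyd-Taylor respiration function, its low-temperature offset, and the
#' vapour-pressure-deficit threshold above which light-saturated uptake is
#' down-regulated.
#'
#' @param t_ref Reference temperature (degrees C) at which respiration equals
#'   `r_ref`. Default 15.
#' @param t0 Lloyd-Taylor temperature offset (degrees C), kept constant at
#'   -46.02. All air temperatures entering the model must exceed `t0`.
#' @param vpd0 VPD threshold (hPa) for the exponential down-regulation of the
#'   light-saturated uptake rate. Default 10.
#'
#' @return A list of class `model_constants`.
#' @export
#' @examples
#' model_constants()
model_constants <- function(t_ref = 15, t0 = -46.02, vpd0 = 10) {
  stopifnot(is.numeric(t_ref), is.numeric(t0), is.numeric(vpd0), t0 < t_ref)
  structure(list(t_ref = t_ref, t0 = t0, vpd0 = vpd0),
            class = "model_constants")
}

#' Daytime parameter set of the DT-RH model
#'
#' @param alpha Canopy-scale quantum yield (umol C J^-1), the initial slope of
#'   the light-response curve. Must be positive.
#' @param beta0 Maximum CO2 uptake at light saturation and low VPD
#'   (umol C m^-2 s^-1). Must be positive.
#' @param k Sensitivity of the light-saturated uptake to VPD above the
#'   threshold (hPa^-1). Must be non-negative.
#' @param r_ref_day Daytime base respiration at the reference temperature
#'   (umol C m^-2 s^-1). Must be positive.
#' @param e0_day Daytime apparent temperature sensitivity of respiration (K).
#'   Must be positive.
#' @param epsilon Site-specific sign (+1 or -1) of the relative-humidity
#'   respiration modifier.
#'
#' @return A list of class `day_params`.
#' @export
day_params <- function(alpha, beta0, k, r_ref_day, e0_day, epsilon = 1L) {
  stopifnot(alpha > 0, beta0 > 0, k >= 0, r_ref_day > 0, e0_day > 0,
            epsilon %in% c(-1, 1))
  structure(list(alpha = alpha, beta0 = beta0, k = k, r_ref_day = r_ref_day,
                 e0_day = e0_day, epsilon = as.integer(epsilon)),
            class = "day_params")
}

#' Nighttime parameter set of the DT-RH model
#'
#' @param r_ref_night Nighttime base respiration at the reference temperature
#'   (umol C m^-2 s^-1). Must be positive.
#' @param e0_night Nighttime apparent temperature sensitivity (K). Must be
#'   positive.
#'
#' @return A list of class `night_params`.
#' @export
night_params <- function(r_ref_night, e0_night) {
  stopifnot(r_ref_night > 0, e0_night > 0)
  structure(list(r_ref_night = r_ref_night, e0_night = e0_night),
            class = "night_params")
}

#' Lloyd-Taylor respiration function
#'
#' Respiration as an exponential function of air temperature,
#' `r_ref * exp(e0 * (1/(t_ref - t0) - 1/(tair - t0)))`. At `tair = t_ref` the
#' function returns `r_ref` for any `e0`; for `e0 > 0` it is strictly
#' increasing in temperature.
#'
#' @param r_ref Base respiration at the reference temperature
#'   (umol C m^-2 s^-1), positive.
#' @param e0 Apparent temperature sensitivity (K), non-negative.
#' @param tair Air temperature (degrees C); vectorised. Must exceed
#'   `constants$t0`.
#' @param constants A [model_constants()] object.
#'
#' @return Respiration flux (umol C m^-2 s^-1), same length as `tair`.
#' @export
#' @examples
#' lloyd_taylor(2, 200, c(5, 15, 25))
lloyd_taylor <- function(r_ref, e0, tair, constants = model_constants()) {
  if (any(tair <= constants$t0, na.rm = TRUE)) {
    stop("lloyd_taylor: tair must exceed t0 = ", constants$t0, " degC")
  }
  r_ref * exp(e0 * (1 / (constants$t_ref - constants$t0) -
                      1 / (tair - constants$t0)))
}

#' Relative-humidity respiration modifier
#'
#' The multiplicative humidity factor `fh = 1 - epsilon * (rh - rh_bar) /
#' rh_bar`, where `rh_bar` is the mean relative humidity of the fitting
#' window. Equals 1 when `rh = rh_bar`. The raw expression can turn negative
#' (epsilon = +1 and rh > 2 * rh_bar); because respiration cannot be negative
#' the factor is floored at zero and a warning is issued when the floor
#' engages.
#'
#' @param epsilon Sign parameter, +1 or -1.
#' @param rh Relative humidity (percent); vectorised.
#' @param rh_bar Window-mean relative humidity (percent), strictly positive.
#'
#' @return Dimensionless factor, same length as `rh`.
#' @export
#' @examples
#' humidity_factor(1, c(30, 60, 90), 60)
humidity_factor <- function(epsilon, rh, rh_bar) {
  stopifnot(epsilon %in% c(-1, 1))
  if (any(rh_bar <= 0, na.rm = TRUE)) {
    stop("humidity_factor: rh_bar must be positive")
  }
  fh <- 1 - epsilon * (rh - rh_bar) / rh_bar
  neg <- !is.na(fh) & fh < 0
  if (any(neg)) {
    warning("humidity_factor: ", sum(neg), " value(s) floored at 0")
    fh[neg] <- 0
  }
  fh
}

#' VPD-limited light-saturated uptake rate
#'
#' `beta = beta0 * exp(-k * (vpd - vpd0))` above the VPD threshold and
#' `beta0` below it; continuous at the threshold and non-increasing in VPD.
#'
#' @param beta0 Uptake rate at low VPD (umol C m^-2 s^-1), positive.
#' @param k VPD sensitivity (hPa^-1), non-negative.
#' @param vpd Vapour pressure deficit (hPa); vectorised.
#' @param constants A [model_constants()] object (supplies `vpd0`).
#'
#' @return beta (umol C m^-2 s^-1), same length as `vpd`.
#' @export
beta_of_vpd <- function(beta0, k, vpd, constants = model_constants()) {
  stopifnot(beta0 > 0, k >= 0)
  ifelse(vpd > constants$vpd0,
         beta0 * exp(-k * (vpd - constants$vpd0)),
         beta0)
}

#' Rectangular-hyperbola light response
#'
#' Gross uptake `alpha * beta * q / (alpha * q + beta)`: zero in darkness,
#' initial slope `alpha`, asymptote `beta`, half-saturation at
#' `q = beta / alpha`.
#'
#' @param alpha Quantum yield (umol C J^-1), positive.
#' @param beta Light-saturated uptake (umol C m^-2 s^-1), positive;
#'   vectorised (recycled against `q`).
#' @param q Global radiation (W m^-2), non-negative; vectorised.
#'
#' @return Gross uptake flux (umol C m^-2 s^-1), unsigned (magnitude).
#' @export
light_response <- function(alpha, beta, q) {
  stopifnot(alpha > 0, all(beta > 0), all(q >= 0, na.rm = TRUE))
  alpha * beta * q / (alpha * q + beta)
}

#' Predicted NEE from the DT-RH model
#'
#' Daytime: `NEE = -GPP + ER` where GPP is the VPD-limited light response and
#' ER the Lloyd-Taylor term scaled by the humidity factor. Nighttime: the
#' two-parameter Lloyd-Taylor term alone (no humidity factor). Uptake is
#' negative under the default sign convention; `sign_convention = "release"`
#' flips the GPP sign for data where uptake is recorded positive.
#'
#' @param dp A [day_params()] object.
#' @param np A [night_params()] object.
#' @param q Global radiation (W m^-2); vectorised with the other drivers.
#' @param tair Air temperature (degrees C).
#' @param vpd Vapour pressure deficit (hPa).
#' @param rh Relative humidity (percent).
#' @param rh_bar Window-mean relative humidity (percent).
#' @param is_day Logical; daytime records use the full model, nighttime
#'   records the nighttime respiration only.
#' @param constants A [model_constants()] object.
#' @param sign_convention `"uptake_negative"` (default) or `"release"`.
#'
#' @return Predicted NEE (umol C m^-2 s^-1).
#' @export
predict_nee <- function(dp, np, q, tair, vpd, rh, rh_bar, is_day,
                        constants = model_constants(),
                        sign_convention = c("uptake_negative", "release")) {
  sign_convention <- match.arg(sign_convention)
  s <- if (sign_convention == "uptake_negative") -1 else 1
  n <- length(tair)
  out <- numeric(n)
  if (any(is_day)) {
    beta <- beta_of_vpd(dp$beta0, dp$k, vpd[is_day], constants)
    gpp <- light_response(dp$alpha, beta, q[is_day])
    er <- daytime_er(dp, tair[is_day], rh[is_day], rh_bar, constants)
    out[is_day] <- s * gpp + er
  }
  if (any(!is_day)) {
    out[!is_day] <- lloyd_taylor(np$r_ref_night, np$e0_night,
                                 tair[!is_day], constants)
  }
  out
}

#' Daytime ecosystem respiration under the DT-RH model
#'
#' The respiration term of the daytime model only: the Lloyd-Taylor response
#' at `(r_ref_day, e0_day)` scaled by the humidity factor.
#'
#' @inheritParams predict_nee
#' @param tair Air temperature (degrees C).
#' @param rh Relative humidity (percent).
#'
#' @return ER (umol C m^-2 s^-1).
#' @export
daytime_er <- function(dp, tair, rh, rh_bar, constants = model_constants()) {
  lloyd_taylor(dp$r_ref_day, dp$e0_day, tair, constants) *
    humidity_factor(dp$epsilon, rh, rh_bar)
}
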