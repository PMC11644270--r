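#' Moving-window scheme
#'
#' Parameters are estimated in windows of `window_days` advanced by
#' `step_days` (defaults 7 and 5: overlapping 7-day windows re-estimated
#' every 5 days, indexed by window centre). Both numbers are configurable
#' because the opposite reading (5-day windows every 7 days) is equally
#' admissible; see the methods vignette.
#'
#' @param window_days Window length in days (default 7).
#' @param step_days Advance between successive windows (default 5).
#' @param min_day_obs Minimum valid daytime NEE records per window (default 50).
#' @param min_night_obs Minimum valid nighttime NEE records (default 30).
#' @param min_tair_spread Minimum nighttime air-temperature range (degrees C)
#'   for E0 identifiability (default 2).
#'
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(window_days = 7, step_days = 5, min_day_obs = 50,
                        min_night_obs = 30, min_tair_spread = 2) {
  stopifnot(window_days >= step_days, step_days >= 1)
  structure(list(window_days = window_days, step_days = step_days,
                 min_day_obs = min_day_obs, min_night_obs = min_night_obs,
                 min_tair_spread = min_tair_spread),
            class = "window_spec")
}

#' Fitting configuration
#'
#' Uniform prior bounds and sampler settings for the window fits. Bounds
#' span published flux-partitioning ranges and act as uniform priors for the
#' Metropolis sampler and as box constraints for the least-squares route.
#'
#' @param e0_bounds Bounds on E0 (K), default c(10, 600).
#' @param r_ref_bounds Bounds on R_ref (umol C m^-2 s^-1).
#' @param alpha_bounds Bounds on the quantum yield (umol C J^-1).
#' @param beta0_bounds Bounds on light-saturated uptake (umol C m^-2 s^-1).
#' @param k_bounds Bounds on the VPD coefficient (hPa^-1).
#' @param n_iter Metropolis sweeps (default 10000).
#' @param burn_in Fraction of sweeps discarded (default 0.5).
#' @param thin Post-burn-in thinning interval (default 5).
#' @param n_init Random starting points scored to initialise a fit.
#' @param seed Base RNG seed; each window derives its own seed from it.
#'
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(e0_bounds = c(10, 600), r_ref_bounds = c(0.01, 50),
                       alpha_bounds = c(1e-4, 0.25),
                       beta0_bounds = c(0.5, 100), k_bounds = c(0, 2),
                       n_iter = 10000, burn_in = 0.5, thin = 5,
                       n_init = 300, seed = 1L) {
  chk <- function(b) stopifnot(length(b) == 2, is.finite(b), b[1] < b[2])
  chk(e0_bounds); chk(r_ref_bounds); chk(alpha_bounds); chk(beta0_bounds)
  chk(k_bounds)
  stopifnot(n_iter >= 200, burn_in > 0, burn_in < 1, thin >= 1)
  structure(list(e0_bounds = e0_bounds, r_ref_bounds = r_ref_bounds,
                 alpha_bounds = alpha_bounds, beta0_bounds = beta0_bounds,
                 k_bounds = k_bounds, n_iter = as.integer(n_iter),
                 burn_in = burn_in, thin = as.integer(thin),
                 n_init = as.integer(n_init), seed = as.integer(seed)),
            class = "fit_config")
}

#' Enumerate moving windows over a series
#'
#' Windows of `window_days` start every `step_days` from the first record's
#' day; a final partial window shorter than `window_days` is dropped. Each
#' window is labelled by its centre date.
#'
#' @param series A [flux_series()].
#' @param spec A [window_spec()].
#'
#' @return Tibble with `window_id`, `start_day`, `end_day` (0-based,
#'   exclusive), and `center_date`.
#' @export
make_windows <- function(series, spec = window_spec()) {
  t0 <- as.POSIXct(format(series$timestamp[1], "%Y-%m-%d"), tz = "UTC")
  n_days <- ceiling(as.numeric(series$timestamp[nrow(series)] - t0,
                               units = "days") + 1e-9)
  if (n_days < spec$window_days) {
    return(tibble::tibble(window_id = integer(), start_day = integer(),
                          end_day = integer(),
                          center_date = as.POSIXct(character(), tz = "UTC")))
  }
  starts <- seq(0, n_days - spec$window_days, by = spec$step_days)
  tibble::tibble(
    window_id = seq_along(starts),
    start_day = as.integer(starts),
    end_day = as.integer(starts + spec$window_days),
    center_date = t0 + (starts + spec$window_days / 2) * 86400
  )
}

# 0-based day offset of each record from the first record's calendar day
day_offset <- function(series) {
  t0 <- as.POSIXct(format(series$timestamp[1], "%Y-%m-%d"), tz = "UTC")
  floor(as.numeric(series$timestamp - t0, units = "days"))
}

# ---- Metropolis sampler -------------------------------------------------

# Adaptive random-walk Metropolis under a box (uniform prior). The first
# half of burn-in uses component-wise proposals with per-component scale
# adaptation; the empirical covariance of that phase then drives joint
# multivariate-normal proposals (Haario-style), whose global scale keeps
# adapting until burn-in ends. Proposals outside the box are rejected.
# The reported acceptance rate is the post-burn-in joint rate.
run_metropolis <- function(log_post, theta0, lower, upper, n_iter, burn_in,
                           thin) {
  p <- length(theta0)
  theta <- theta0
  lp <- log_post(theta)
  scales <- (upper - lower) / 20
  n_burn <- floor(n_iter * burn_in)
  n_phase_a <- floor(n_burn / 2)
  keep <- seq(n_burn + 1, n_iter, by = thin)
  chain <- matrix(NA_real_, length(keep), p)
  k_row <- 1L
  hist_a <- matrix(NA_real_, n_phase_a, p)
  acc_win <- integer(p); prop_win <- integer(p)

  for (it in seq_len(n_phase_a)) {
    for (j in seq_len(p)) {
      cand <- theta
      cand[j] <- theta[j] + rnorm(1, 0, scales[j])
      prop_win[j] <- prop_win[j] + 1L
      if (cand[j] >= lower[j] && cand[j] <= upper[j]) {
        lp_cand <- log_post(cand)
        if (is.finite(lp_cand) && log(runif(1)) < lp_cand - lp) {
          theta <- cand; lp <- lp_cand
          acc_win[j] <- acc_win[j] + 1L
        }
      }
    }
    hist_a[it, ] <- theta
    if (it %% 50 == 0) {
      rate <- acc_win / pmax(1, prop_win)
      scales <- pmin(scales * exp(rate - 0.35), upper - lower)
      acc_win[] <- 0L; prop_win[] <- 0L
    }
  }

  # joint proposal shape from phase-A history (jitter guards degeneracy)
  cv <- stats::cov(hist_a[max(1, n_phase_a - 1000):n_phase_a, , drop = FALSE])
  cv <- cv + diag(pmax(1e-12, (scales / 50)^2), p)
  ch <- tryCatch(chol(cv), error = function(e) diag(sqrt(diag(cv)), p))
  s_glob <- 2.38 / sqrt(p)
  acc_j <- 0L; prop_j <- 0L; acc_post <- 0L; prop_post <- 0L

  for (it in seq(n_phase_a + 1, n_iter)) {
    cand <- theta + s_glob * drop(rnorm(p) %*% ch)
    prop_j <- prop_j + 1L
    inside <- all(cand >= lower & cand <= upper)
    accepted <- FALSE
    if (inside) {
      lp_cand <- log_post(cand)
      if (is.finite(lp_cand) && log(runif(1)) < lp_cand - lp) {
        theta <- cand; lp <- lp_cand; accepted <- TRUE
      }
    }
    if (accepted) acc_j <- acc_j + 1L
    if (it <= n_burn && it %% 50 == 0) {
      s_glob <- s_glob * exp(acc_j / max(1, prop_j) - 0.25)
      acc_j <- 0L; prop_j <- 0L
    }
    if (it > n_burn) {
      prop_post <- prop_post + 1L
      if (accepted) acc_post <- acc_post + 1L
      if ((it - n_burn - 1) %% thin == 0) {
        chain[k_row, ] <- theta
        k_row <- k_row + 1L
      }
    }
  }
  list(chain = chain, acceptance = acc_post / max(1, prop_post))
}

# Geweke-style z for a single chain: first 10% vs last 50%, standard errors
# from batch means to absorb residual autocorrelation.
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5, n_batch = 10) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[seq(n - floor(frac2 * n) + 1, n)]
  bm_se <- function(v) {
    nb <- min(n_batch, max(2, floor(length(v) / 2)))
    bm <- tapply(v, cut(seq_along(v), nb, labels = FALSE), mean)
    sd(bm) / sqrt(nb)
  }
  se <- sqrt(bm_se(a)^2 + bm_se(b)^2)
  if (!is.finite(se) || se == 0) return(0)
  (mean(a) - mean(b)) / se
}

# Best of n_init uniform draws inside the box by residual sum of squares,
# refined by a bounded quasi-Newton descent so the sampler starts at the
# posterior mode and its burn-in adaptation tunes the scales there.
init_by_search <- function(rss_fun, lower, upper, n_init) {
  p <- length(lower)
  draws <- matrix(runif(n_init * p), n_init, p)
  draws <- sweep(sweep(draws, 2, upper - lower, "*"), 2, lower, "+")
  rss <- apply(draws, 1, rss_fun)
  top <- order(rss)[seq_len(min(5, n_init))]
  best <- draws[top[1], ]; best_rss <- rss[top[1]]
  boxed <- function(th) {
    if (any(th < lower | th > upper)) Inf else rss_fun(th)
  }
  for (i in top) {
    ref <- tryCatch(
      stats::optim(draws[i, ], boxed,
                   control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(ref) && is.finite(ref$value) && ref$value < best_rss) {
      best <- ref$par; best_rss <- ref$value
    }
  }
  pmin(upper, pmax(lower, best))
}

# Profiled-sigma Gaussian log-likelihood: -(n/2) log RSS.
profiled_loglik <- function(rss, n) -n / 2 * log(rss)

# ---- Night fit ----------------------------------------------------------

#' Fit the nighttime respiration model in one window
#'
#' Estimates `(r_ref_night, e0_night)` from valid nighttime NEE via the
#' two-parameter Lloyd-Taylor model, by adaptive random-walk Metropolis
#' (`method = "mcmc"`, posterior medians and 95% credible intervals) or by
#' bounded nonlinear least squares (`method = "nls"`, the deterministic
#' route). Windows with too few observations or an air-temperature spread
#' below `spec$min_tair_spread` are skipped.
#'
#' @param window A [flux_series()] slice (one window of records).
#' @param config A [fit_config()].
#' @param constants A [model_constants()].
#' @param spec A [window_spec()] (supplies the skip thresholds).
#' @param method `"mcmc"` or `"nls"`.
#' @param seed RNG seed for this window (defaults to `config$seed`).
#'
#' @return A list: `params` ([night_params()] or NULL), `ci` (2x2 matrix),
#'   `diagnostics`, `skip_reason` (NULL if fitted).
#' @export
fit_night_window <- function(window, config = fit_config(),
                             constants = model_constants(),
                             spec = window_spec(), method = c("mcmc", "nls"),
                             seed = config$seed) {
  method <- match.arg(method)
  ok <- !window$is_day & !is.na(window$nee) & !is.na(window$tair)
  n <- sum(ok)
  if (n < spec$min_night_obs) {
    return(list(params = NULL, skip_reason = sprintf(
      "insufficient nighttime observations (%d < %d)", n,
      spec$min_night_obs)))
  }
  tair <- window$tair[ok]; nee <- window$nee[ok]
  if (diff(range(tair)) < spec$min_tair_spread) {
    return(list(params = NULL,
                skip_reason = "insufficient temperature spread"))
  }
  c1 <- 1 / (constants$t_ref - constants$t0) - 1 / (tair - constants$t0)
  rss_fun <- function(th) sum((nee - th[1] * exp(th[2] * c1))^2)
  lower <- c(config$r_ref_bounds[1], config$e0_bounds[1])
  upper <- c(config$r_ref_bounds[2], config$e0_bounds[2])

  if (method == "nls") {
    fit <- fit_nls(nee ~ r_ref * exp(e0 * c1),
                   data = data.frame(nee = nee, c1 = c1),
                   par_names = c("r_ref", "e0"), lower = lower,
                   upper = upper, rss_fun = rss_fun, seed = seed,
                   n_init = config$n_init)
    if (is.null(fit)) {
      return(list(params = NULL, skip_reason = "nls did not converge"))
    }
    est <- fit$est
    return(list(params = night_params(est[1], est[2]),
                ci = fit$ci,
                diagnostics = list(n_obs = n, method = "nls",
                                   rmse = sqrt(rss_fun(est) / n),
                                   converged = TRUE,
                                   acceptance = NA_real_, geweke = NA_real_),
                skip_reason = NULL))
  }

  set.seed(seed)
  theta0 <- init_by_search(rss_fun, lower, upper, config$n_init)
  lp <- function(th) profiled_loglik(rss_fun(th), n)
  mc <- run_metropolis(lp, theta0, lower, upper, config$n_iter,
                       config$burn_in, config$thin)
  med <- apply(mc$chain, 2, stats::median)
  ci <- apply(mc$chain, 2, quantile, c(0.025, 0.975))
  gz <- geweke_z(mc$chain[, 2])
  conv <- mc$acceptance >= 0.1 && mc$acceptance <= 0.6 && abs(gz) < 2
  list(params = night_params(med[1], med[2]),
       ci = ci,
       diagnostics = list(n_obs = n, method = "mcmc",
                          rmse = sqrt(rss_fun(med) / n),
                          converged = conv, acceptance = mc$acceptance,
                          geweke = gz),
       skip_reason = NULL)
}

# Bounded Levenberg-Marquardt via minpack.lm with a random-search start;
# returns NULL when no start converges.
fit_nls <- function(formula, data, par_names, lower, upper, rss_fun, seed,
                    n_init) {
  set.seed(seed)
  starts <- list(init_by_search(rss_fun, lower, upper, n_init),
                 (lower + upper) / 2)
  best <- NULL; best_rss <- Inf
  for (st in starts) {
    names(st) <- par_names
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(formula, data = data, start = as.list(st),
                          lower = lower, upper = upper,
                          control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- rss_fun(unname(stats::coef(fit)))
      if (rss < best_rss) {
        best <- fit; best_rss <- rss
      }
    }
  }
  if (is.null(best)) return(NULL)
  est <- stats::coef(best)
  se <- tryCatch(suppressWarnings(
    summary(best)$coefficients[, "Std. Error"]),
    error = function(e) rep(NA_real_, length(est)))
  ci <- rbind(est - 1.96 * se, est + 1.96 * se)
  rownames(ci) <- c("2.5%", "97.5%")
  list(est = unname(est), ci = ci)
}

# ---- Day fit ------------------------------------------------------------

#' Fit the full DT-RH daytime model in one window
#'
#' Estimates `(alpha, beta0, k, r_ref_day, e0_day)` from valid daytime NEE
#' with the humidity-modifier sign `epsilon` held fixed; the window-mean RH
#' entering the humidity factor is the mean daytime RH of the window. When
#' no record exceeds the VPD threshold the `k` coefficient is unidentifiable
#' and is pinned to 0 (flagged `k_pinned`).
#'
#' @inheritParams fit_night_window
#' @param epsilon Humidity-modifier sign, +1 or -1.
#'
#' @return A list like [fit_night_window()]'s, with `rh_bar` added.
#' @export
fit_day_window <- function(window, epsilon = 1L, config = fit_config(),
                           constants = model_constants(),
                           spec = window_spec(), method = c("mcmc", "nls"),
                           seed = config$seed) {
  method <- match.arg(method)
  ok <- window$is_day & !is.na(window$nee) & !is.na(window$tair) &
    !is.na(window$sw_in) & !is.na(window$vpd) & !is.na(window$rh)
  n <- sum(ok)
  if (n < spec$min_day_obs) {
    return(list(params = NULL, skip_reason = sprintf(
      "insufficient daytime observations (%d < %d)", n, spec$min_day_obs)))
  }
  q <- window$sw_in[ok]
  if (max(q) < 100) {
    return(list(params = NULL, skip_reason = "insufficient radiation spread"))
  }
  tair <- window$tair[ok]; vpd <- window$vpd[ok]
  rh <- window$rh[ok]; nee <- window$nee[ok]
  # per-record window-mean RH when precomputed for the whole series (keeps
  # overlapping windows mutually consistent); otherwise this window's mean
  rh_bar <- if ("rh_bar" %in% names(window)) window$rh_bar[ok] else mean(rh)
  c1 <- 1 / (constants$t_ref - constants$t0) - 1 / (tair - constants$t0)
  fh <- pmax(0, 1 - epsilon * (rh - rh_bar) / rh_bar)
  dvpd <- pmax(0, vpd - constants$vpd0)
  k_pinned <- all(dvpd <= 0)

  pred <- function(alpha, beta0, k, r_ref, e0) {
    beta <- beta0 * exp(-k * dvpd)
    -alpha * beta * q / (alpha * q + beta) + r_ref * exp(e0 * c1) * fh
  }
  if (k_pinned) {
    par_names <- c("alpha", "beta0", "r_ref", "e0")
    lower <- c(config$alpha_bounds[1], config$beta0_bounds[1],
               config$r_ref_bounds[1], config$e0_bounds[1])
    upper <- c(config$alpha_bounds[2], config$beta0_bounds[2],
               config$r_ref_bounds[2], config$e0_bounds[2])
    rss_fun <- function(th) sum((nee - pred(th[1], th[2], 0, th[3], th[4]))^2)
    expand <- function(th) c(th[1], th[2], 0, th[3], th[4])
  } else {
    par_names <- c("alpha", "beta0", "k", "r_ref", "e0")
    lower <- c(config$alpha_bounds[1], config$beta0_bounds[1],
               config$k_bounds[1], config$r_ref_bounds[1],
               config$e0_bounds[1])
    upper <- c(config$alpha_bounds[2], config$beta0_bounds[2],
               config$k_bounds[2], config$r_ref_bounds[2],
               config$e0_bounds[2])
    rss_fun <- function(th) {
      sum((nee - pred(th[1], th[2], th[3], th[4], th[5]))^2)
    }
    expand <- identity
  }

  finish <- function(est5, ci5, diag) {
    list(params = day_params(est5[1], est5[2], est5[3], est5[4], est5[5],
                             epsilon),
         ci = ci5, rh_bar = mean(rh_bar), k_pinned = k_pinned,
         diagnostics = diag, skip_reason = NULL)
  }

  if (method == "nls") {
    df <- data.frame(nee = nee, q = q, c1 = c1, fh = fh, dvpd = dvpd)
    form <- if (k_pinned) {
      nee ~ -alpha * beta0 * q / (alpha * q + beta0) +
        r_ref * exp(e0 * c1) * fh
    } else {
      nee ~ -alpha * (beta0 * exp(-k * dvpd)) * q /
        (alpha * q + beta0 * exp(-k * dvpd)) + r_ref * exp(e0 * c1) * fh
    }
    fit <- fit_nls(form, df, par_names, lower, upper, rss_fun, seed,
                   config$n_init)
    if (is.null(fit)) {
      return(list(params = NULL, skip_reason = "nls did not converge"))
    }
    est5 <- expand(fit$est)
    ci5 <- expand_ci(fit$ci, k_pinned)
    return(finish(est5, ci5, list(
      n_obs = n, method = "nls", rmse = sqrt(rss_fun(fit$est) / n),
      converged = TRUE, acceptance = NA_real_, geweke = NA_real_)))
  }

  set.seed(seed)
  theta0 <- init_by_search(rss_fun, lower, upper, max(config$n_init, 500))
  lp <- function(th) profiled_loglik(rss_fun(th), n)
  mc <- run_metropolis(lp, theta0, lower, upper, config$n_iter,
                       config$burn_in, config$thin)
  med <- apply(mc$chain, 2, stats::median)
  ci <- apply(mc$chain, 2, quantile, c(0.025, 0.975))
  gz <- geweke_z(mc$chain[, ncol(mc$chain)])
  conv <- mc$acceptance >= 0.1 && mc$acceptance <= 0.6 && abs(gz) < 2
  finish(expand(med), expand_ci(ci, k_pinned), list(
    n_obs = n, method = "mcmc", rmse = sqrt(rss_fun(med) / n),
    converged = conv, acceptance = mc$acceptance, geweke = gz))
}

# Insert a degenerate k column into a 2 x 4 CI matrix when k was pinned.
expand_ci <- function(ci, k_pinned) {
  if (!k_pinned) return(ci)
  cbind(ci[, 1:2, drop = FALSE], matrix(0, 2, 1), ci[, 3:4, drop = FALSE])
}

#' Determine the site-level humidity-modifier sign
#'
#' The sign is set by the Pearson correlation of the standardized daytime
#' respiration rate (window-mean daytime ER divided by R_ref,day) against the
#' window-mean RH across windows: -1 for a negative correlation, +1
#' otherwise (including an exactly zero correlation). Fewer than 5 windows
#' default to +1 with a warning.
#'
#' @param std_resp Standardized respiration rate per window.
#' @param rh_means Window-mean RH per window.
#'
#' @return -1L or +1L, with the correlation in attribute `correlation`.
#' @export
estimate_epsilon <- function(std_resp, rh_means) {
  keep <- is.finite(std_resp) & is.finite(rh_means)
  if (sum(keep) < 5) {
    warning("estimate_epsilon: fewer than 5 windows; defaulting to +1")
    return(structure(1L, correlation = NA_real_))
  }
  r <- suppressWarnings(cor(std_resp[keep], rh_means[keep]))
  if (is.na(r)) r <- 0
  structure(if (r < 0) -1L else 1L, correlation = r)
}

# Preliminary DT-style pass: nighttime NLS fit per window gives e0; the
# standardized daytime respiration DER/R_ref,day = mean over daytime records
# of exp(e0 * c1) is correlated with window-mean RH to fix epsilon.
site_epsilon <- function(series, spec = window_spec(),
                         config = fit_config(),
                         constants = model_constants()) {
  wins <- make_windows(series, spec)
  dof <- day_offset(series)
  std_resp <- rh_means <- rep(NA_real_, nrow(wins))
  for (w in seq_len(nrow(wins))) {
    sl <- series[dof >= wins$start_day[w] & dof < wins$end_day[w], ]
    nf <- fit_night_window(sl, config, constants, spec, method = "nls",
                           seed = config$seed + w)
    if (is.null(nf$params)) next
    ok <- sl$is_day & !is.na(sl$tair) & !is.na(sl$rh)
    if (sum(ok) < 10) next
    c1 <- 1 / (constants$t_ref - constants$t0) -
      1 / (sl$tair[ok] - constants$t0)
    std_resp[w] <- mean(exp(nf$params$e0_night * c1))
    rh_means[w] <- mean(sl$rh[ok])
  }
  estimate_epsilon(std_resp, rh_means)
}

# ---- Whole-series fitting -----------------------------------------------

empty_fit_row <- function() {
  tibble::tibble(
    window_id = integer(), center_date = as.POSIXct(character(), tz = "UTC"),
    start_day = integer(), end_day = integer(),
    n_day_obs = integer(), n_night_obs = integer(),
    alpha = double(), beta0 = double(), k = double(),
    r_ref_day = double(), e0_day = double(), e0_day_lo = double(),
    e0_day_hi = double(), r_ref_night = double(), e0_night = double(),
    e0_night_lo = double(), e0_night_hi = double(), rh_bar = double(),
    rmse_day = double(), rmse_night = double(),
    acceptance_day = double(), acceptance_night = double(),
    converged_day = logical(), converged_night = logical(),
    skip_day = character(), skip_night = character())
}

#' Fit the DT-RH model over a series in moving windows
#'
#' Runs the full day/night-resolved pipeline: determines the site humidity
#' sign `epsilon` (unless supplied), then fits the nighttime two-parameter
#' model and the daytime five-parameter model in every moving window. One
#' output row per window; skipped fits carry their reason and NA estimates.
#'
#' @param series A [flux_series()] with `is_day` flags and NEE.
#' @param spec A [window_spec()].
#' @param config A [fit_config()].
#' @param constants A [model_constants()].
#' @param epsilon Fixed humidity sign; NULL (default) estimates it from
#'   preliminary DT-style fits.
#' @param method `"mcmc"` (default) or `"nls"` for both fits.
#' @param verbose Emit one message per skipped window.
#'
#' @return A `window_fits` tibble with attributes `epsilon`, `method`,
#'   `site_id`.
#' @export
partition_dtrh <- function(series, spec = window_spec(),
                           config = fit_config(),
                           constants = model_constants(), epsilon = NULL,
                           method = c("mcmc", "nls"), verbose = FALSE) {
  method <- match.arg(method)
  if (all(is.na(series$is_day))) {
    stop("partition_dtrh: run flag_day_night() first")
  }
  if (is.null(epsilon)) {
    epsilon <- site_epsilon(series, spec, config, constants)
  }
  if (!"rh_bar" %in% names(series)) {
    series$rh_bar <- window_rh_bar(series, spec)
  }
  wins <- make_windows(series, spec)
  dof <- day_offset(series)
  rows <- vector("list", nrow(wins))
  for (w in seq_len(nrow(wins))) {
    sl <- series[dof >= wins$start_day[w] & dof < wins$end_day[w], ]
    seed_w <- config$seed + 7919L * w
    nf <- fit_night_window(sl, config, constants, spec, method,
                           seed = seed_w)
    df <- fit_day_window(sl, epsilon, config, constants, spec, method,
                         seed = seed_w + 1L)
    if (verbose) {
      for (sr in c(nf$skip_reason, df$skip_reason)) {
        message(sprintf("window %d (%s): %s", w,
                        format(wins$center_date[w], "%Y-%m-%d"), sr))
      }
    }
    rows[[w]] <- tibble::tibble(
      window_id = wins$window_id[w], center_date = wins$center_date[w],
      start_day = wins$start_day[w], end_day = wins$end_day[w],
      n_day_obs = if (is.null(df$params)) NA_integer_ else
        df$diagnostics$n_obs,
      n_night_obs = if (is.null(nf$params)) NA_integer_ else
        nf$diagnostics$n_obs,
      alpha = if (is.null(df$params)) NA_real_ else df$params$alpha,
      beta0 = if (is.null(df$params)) NA_real_ else df$params$beta0,
      k = if (is.null(df$params)) NA_real_ else df$params$k,
      r_ref_day = if (is.null(df$params)) NA_real_ else df$params$r_ref_day,
      e0_day = if (is.null(df$params)) NA_real_ else df$params$e0_day,
      e0_day_lo = if (is.null(df$params)) NA_real_ else
        df$ci[1, ncol(df$ci)],
      e0_day_hi = if (is.null(df$params)) NA_real_ else
        df$ci[2, ncol(df$ci)],
      r_ref_night = if (is.null(nf$params)) NA_real_ else
        nf$params$r_ref_night,
      e0_night = if (is.null(nf$params)) NA_real_ else nf$params$e0_night,
      e0_night_lo = if (is.null(nf$params)) NA_real_ else nf$ci[1, 2],
      e0_night_hi = if (is.null(nf$params)) NA_real_ else nf$ci[2, 2],
      rh_bar = if (is.null(df$params)) NA_real_ else df$rh_bar,
      rmse_day = if (is.null(df$params)) NA_real_ else df$diagnostics$rmse,
      rmse_night = if (is.null(nf$params)) NA_real_ else
        nf$diagnostics$rmse,
      acceptance_day = if (is.null(df$params)) NA_real_ else
        df$diagnostics$acceptance,
      acceptance_night = if (is.null(nf$params)) NA_real_ else
        nf$diagnostics$acceptance,
      converged_day = if (is.null(df$params)) NA else
        df$diagnostics$converged,
      converged_night = if (is.null(nf$params)) NA else
        nf$diagnostics$converged,
      skip_day = if (is.null(df$skip_reason)) NA_character_ else
        df$skip_reason,
      skip_night = if (is.null(nf$skip_reason)) NA_character_ else
        nf$skip_reason)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_fit_row()
  structure(out, class = c("window_fits", class(out)),
            epsilon = as.integer(epsilon), method = "dtrh",
            fit_method = method, site_id = attr(series, "site_id"),
            spec = spec)
}

#' Nighttime (NT) baseline partitioner
#'
#' The classical nighttime method: `(r_ref, e0)` from nighttime data per
#' window, daytime ER extrapolated with the same parameters applied to
#' daytime air temperature (no humidity factor, single diel E0).
#'
#' @inheritParams partition_dtrh
#' @param method `"nls"` (default, the classical deterministic fit) or
#'   `"mcmc"`.
#' @return A `window_fits` tibble (night columns populated) with
#'   `method = "nt"`.
#' @export
fit_nt_baseline <- function(series, spec = window_spec(),
                            config = fit_config(),
                            constants = model_constants(),
                            method = c("nls", "mcmc")) {
  method <- match.arg(method)
  wins <- make_windows(series, spec)
  dof <- day_offset(series)
  rows <- vector("list", nrow(wins))
  for (w in seq_len(nrow(wins))) {
    sl <- series[dof >= wins$start_day[w] & dof < wins$end_day[w], ]
    nf <- fit_night_window(sl, config, constants, spec, method,
                           seed = config$seed + 7919L * w)
    rows[[w]] <- tibble::tibble(
      window_id = wins$window_id[w], center_date = wins$center_date[w],
      start_day = wins$start_day[w], end_day = wins$end_day[w],
      r_ref_night = if (is.null(nf$params)) NA_real_ else
        nf$params$r_ref_night,
      e0_night = if (is.null(nf$params)) NA_real_ else nf$params$e0_night,
      rmse_night = if (is.null(nf$params)) NA_real_ else
        nf$diagnostics$rmse,
      skip_night = if (is.null(nf$skip_reason)) NA_character_ else
        nf$skip_reason)
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("window_fits", class(out)), method = "nt",
            fit_method = method, site_id = attr(series, "site_id"))
}

#' Daytime (DT) baseline partitioner
#'
#' The classical daytime method: `e0` from the nighttime fit per window,
#' then `(alpha, beta0, k, r_ref)` from the daytime light-response model
#' with that `e0` held fixed and no humidity factor. ER uses the
#' daytime-derived `r_ref` with the night-derived `e0` at all hours.
#'
#' @inheritParams fit_nt_baseline
#' @return A `window_fits` tibble with `method = "dt"`.
#' @export
fit_dt_baseline <- function(series, spec = window_spec(),
                            config = fit_config(),
                            constants = model_constants(),
                            method = c("nls", "mcmc")) {
  method <- match.arg(method)
  wins <- make_windows(series, spec)
  dof <- day_offset(series)
  rows <- vector("list", nrow(wins))
  for (w in seq_len(nrow(wins))) {
    sl <- series[dof >= wins$start_day[w] & dof < wins$end_day[w], ]
    seed_w <- config$seed + 7919L * w
    nf <- fit_night_window(sl, config, constants, spec, method,
                           seed = seed_w)
    row <- tibble::tibble(
      window_id = wins$window_id[w], center_date = wins$center_date[w],
      start_day = wins$start_day[w], end_day = wins$end_day[w],
      alpha = NA_real_, beta0 = NA_real_, k = NA_real_,
      r_ref_day = NA_real_, e0 = NA_real_,
      skip = if (is.null(nf$skip_reason)) NA_character_ else nf$skip_reason)
    if (!is.null(nf$params)) {
      dfit <- fit_day_fixed_e0(sl, nf$params$e0_night, config, constants,
                               spec, seed = seed_w + 1L)
      row$e0 <- nf$params$e0_night
      if (!is.null(dfit)) {
        row$alpha <- dfit[1]; row$beta0 <- dfit[2]; row$k <- dfit[3]
        row$r_ref_day <- dfit[4]
      } else {
        row$skip <- "daytime nls did not converge"
      }
    }
    rows[[w]] <- row
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("window_fits", class(out)), method = "dt",
            fit_method = method, site_id = attr(series, "site_id"))
}

# Daytime light-response fit with e0 fixed and no humidity factor; returns
# c(alpha, beta0, k, r_ref) or NULL.
fit_day_fixed_e0 <- function(window, e0, config, constants, spec, seed) {
  ok <- window$is_day & !is.na(window$nee) & !is.na(window$tair) &
    !is.na(window$sw_in) & !is.na(window$vpd)
  n <- sum(ok)
  if (n < spec$min_day_obs) return(NULL)
  q <- window$sw_in[ok]
  if (max(q) < 100) return(NULL)
  tair <- window$tair[ok]; vpd <- window$vpd[ok]; nee <- window$nee[ok]
  c1 <- 1 / (constants$t_ref - constants$t0) - 1 / (tair - constants$t0)
  dvpd <- pmax(0, vpd - constants$vpd0)
  er_t <- exp(e0 * c1)
  df <- data.frame(nee = nee, q = q, dvpd = dvpd, er_t = er_t)
  if (all(dvpd <= 0)) {
    # VPD-limited branch never active: k unidentifiable, pinned to 0
    rss_fun <- function(th) {
      sum((nee - (-th[1] * th[2] * q / (th[1] * q + th[2]) +
                    th[3] * er_t))^2)
    }
    lower <- c(config$alpha_bounds[1], config$beta0_bounds[1],
               config$r_ref_bounds[1])
    upper <- c(config$alpha_bounds[2], config$beta0_bounds[2],
               config$r_ref_bounds[2])
    fit <- fit_nls(
      nee ~ -alpha * beta0 * q / (alpha * q + beta0) + r_ref * er_t,
      df, c("alpha", "beta0", "r_ref"), lower, upper, rss_fun, seed,
      config$n_init)
    if (is.null(fit)) return(NULL)
    return(c(fit$est[1], fit$est[2], 0, fit$est[3]))
  }
  rss_fun <- function(th) {
    beta <- th[2] * exp(-th[3] * dvpd)
    sum((nee - (-th[1] * beta * q / (th[1] * q + beta) + th[4] * er_t))^2)
  }
  lower <- c(config$alpha_bounds[1], config$beta0_bounds[1],
             config$k_bounds[1], config$r_ref_bounds[1])
  upper <- c(config$alpha_bounds[2], config$beta0_bounds[2],
             config$k_bounds[2], config$r_ref_bounds[2])
  fit <- fit_nls(
    nee ~ -alpha * (beta0 * exp(-k * dvpd)) * q /
      (alpha * q + beta0 * exp(-k * dvpd)) + r_ref * er_t,
    df, c("alpha", "beta0", "k", "r_ref"), lower, upper, rss_fun, seed,
    config$n_init)
  if (is.null(fit)) NULL else fit$est
}

# ---- ER reconstruction --------------------------------------------------

#' Reconstruct the half-hourly ER series from window fits
#'
#' Each record takes the parameters of the nearest fitted window centre
#' (among windows whose relevant fit succeeded) provided the record lies
#' inside the span covered by the windows; records outside coverage get
#' missing ER. DT-RH fits use day parameters (with the humidity factor and
#' the fitted window-mean RH) for daytime records and night parameters
#' otherwise; NT fits use the nighttime parameters at all hours; DT fits use
#' the daytime `r_ref` with the night-derived `e0` at all hours.
#'
#' @param fits A `window_fits` tibble from [partition_dtrh()],
#'   [fit_nt_baseline()] or [fit_dt_baseline()].
#' @param series The [flux_series()] the fits came from.
#' @param constants A [model_constants()].
#'
#' @return Tibble `timestamp`, `is_day`, `er` (umol C m^-2 s^-1).
#' @export
estimate_er_series <- function(fits, series,
                               constants = model_constants()) {
  method <- attr(fits, "method")
  dof <- day_offset(series)
  er <- rep(NA_real_, nrow(series))
  covered <- dof >= min(fits$start_day) & dof < max(fits$end_day)
  day_mid <- dof + 0.5
  pick <- function(ok_rows) {
    # nearest fitted window centre per record, NA outside window coverage
    if (!any(ok_rows)) return(rep(NA_integer_, nrow(series)))
    idx <- which(ok_rows)
    centers <- (fits$start_day[idx] + fits$end_day[idx]) / 2
    left <- pmax(1, pmin(length(centers), findInterval(day_mid, centers)))
    right <- pmin(length(centers), left + 1)
    use_right <- abs(day_mid - centers[right]) < abs(day_mid - centers[left])
    nearest <- idx[ifelse(use_right, right, left)]
    nearest[!covered] <- NA_integer_
    nearest
  }
  c1 <- 1 / (constants$t_ref - constants$t0) -
    1 / (series$tair - constants$t0)
  if (method == "nt") {
    w <- pick(!is.na(fits$e0_night))
    has <- !is.na(w)
    er[has] <- fits$r_ref_night[w[has]] *
      exp(fits$e0_night[w[has]] * c1[has])
  } else if (method == "dt") {
    w <- pick(!is.na(fits$e0) & !is.na(fits$r_ref_day))
    has <- !is.na(w)
    er[has] <- fits$r_ref_day[w[has]] * exp(fits$e0[w[has]] * c1[has])
  } else {
    epsilon <- attr(fits, "epsilon")
    spec <- attr(fits, "spec")
    rh_bar <- if ("rh_bar" %in% names(series)) series$rh_bar else
      window_rh_bar(series, if (is.null(spec)) window_spec() else spec)
    okd <- !is.na(fits$e0_day)
    wd <- pick(okd)
    hd <- !is.na(wd) & series$is_day & !is.na(series$rh)
    fh <- pmax(0, 1 - epsilon * (series$rh[hd] - rh_bar[hd]) / rh_bar[hd])
    er[hd] <- fits$r_ref_day[wd[hd]] * exp(fits$e0_day[wd[hd]] * c1[hd]) * fh
    okn <- !is.na(fits$e0_night)
    wn <- pick(okn)
    hn <- !is.na(wn) & !series$is_day
    er[hn] <- fits$r_ref_night[wn[hn]] * exp(fits$e0_night[wn[hn]] * c1[hn])
  }
  tibble::tibble(timestamp = series$timestamp, is_day = series$is_day,
                 er = er)
}

#' Aggregate an ER series to monthly and annual scales
#'
#' @param er_tbl Output of [estimate_er_series()].
#' @param step_minutes Record step, for carbon integration.
#'
#' @return A list with `monthly` and `annual` tibbles: mean flux
#'   (umol C m^-2 s^-1), integrated carbon (g C m^-2, over non-missing
#'   records), record and gap counts.
#' @export
aggregate_er <- function(er_tbl, step_minutes = 30) {
  step_sec <- step_minutes * 60
  by_month <- er_tbl |>
    dplyr::mutate(year = as.integer(format(.data$timestamp, "%Y")),
                  month = as.integer(format(.data$timestamp, "%m"))) |>
    dplyr::group_by(.data$year, .data$month) |>
    dplyr::summarise(
      er_mean = mean(.data$er, na.rm = TRUE),
      er_gc = sum(.data$er, na.rm = TRUE) * step_sec * 12.011e-6,
      n = dplyr::n(), n_gap = sum(is.na(.data$er)), .groups = "drop")
  by_year <- by_month |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(er_mean = stats::weighted.mean(.data$er_mean,
                                                    .data$n - .data$n_gap),
                     er_gc = sum(.data$er_gc), n = sum(.data$n),
                     n_gap = sum(.data$n_gap), .groups = "drop")
  list(monthly = by_month, annual = by_year)
}

#' Annual ER bias of the single-sensitivity NT method
#'
#' Percent difference of annual ER between the NT baseline (one diel
#' temperature sensitivity, extrapolated from nighttime fits) and the DT-RH
#' reconstruction, computed over the records where both are defined:
#' `100 * (ER_NT - ER_DTRH) / ER_DTRH`.
#'
#' @param series The [flux_series()] both fits cover.
#' @param fits_dtrh DT-RH `window_fits`.
#' @param fits_nt NT `window_fits`.
#' @param constants A [model_constants()].
#'
#' @return Percent bias (scalar).
#' @export
er_bias_ignoring_delta <- function(series, fits_dtrh, fits_nt,
                                   constants = model_constants()) {
  er_d <- estimate_er_series(fits_dtrh, series, constants)$er
  er_n <- estimate_er_series(fits_nt, series, constants)$er
  both <- !is.na(er_d) & !is.na(er_n)
  if (!any(both)) stop("er_bias_ignoring_delta: no overlapping coverage")
  100 * (sum(er_n[both]) - sum(er_d[both])) / sum(er_d[both])
}
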