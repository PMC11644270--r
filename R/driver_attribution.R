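#' Default covariate family grouping
#'
#' Assigns each site-level covariate to the climate, vegetation, or soil
#' family used when importance shares are grouped.
#'
#' @return Named character vector covariate -> family.
#' @export
covariate_families <- function() {
  c(mat = "climate", tair = "climate", tday = "climate", tnight = "climate",
    tmax = "climate", tmin = "climate", dtr = "climate", par = "climate",
    vpd = "climate", spei = "climate", precip = "climate",
    tair_asv = "climate", precip_asv = "climate", vpd_asv = "climate",
    ndvi = "vegetation", ndvi_asv = "vegetation", lai = "vegetation",
    lnc = "vegetation", lpc = "vegetation", lnp = "vegetation",
    sla = "vegetation", ldmc = "vegetation",
    swc = "soil", soc = "soil")
}

#' Synthetic site-year feature table with planted structure
#'
#' Builds a covariate table driven by two latent factors (a thermal axis
#' and a moisture axis) plus independent noise, and a seasonal-amplitude
#' response that is a linear function of the latent factors. Used to
#' exercise the attribution chain where the truth is known.
#'
#' @param n Number of site-years.
#' @param seed RNG seed.
#' @param effect Coefficients of the response on the two latent factors
#'   (default c(0.14, -0.14)).
#' @param noise_sd Residual noise on the response (default 0.1).
#' @param intercept Response intercept (default 1; amplitudes are
#'   non-negative in practice, the response is floored at 0).
#' @param cov_noise Multiplier on the idiosyncratic covariate noise
#'   (default 1: realistic scatter; small values give an almost rank-two
#'   table).
#'
#' @return Tibble with `asv_delta` (response), the covariates of
#'   [covariate_families()], and the latent factors as attributes
#'   `latent_1` and `latent_2`.
#' @export
generate_site_table <- function(n, seed = 1L, effect = c(0.14, -0.14),
                                noise_sd = 0.1, intercept = 1,
                                cov_noise = 1) {
  set.seed(seed)
  f1 <- rnorm(n)   # thermal axis
  f2 <- rnorm(n)   # moisture axis
  covs <- covariate_families()
  # loading of each covariate on (f1, f2): climate loads on f1, moisture-ish
  # variables on f2, vegetation on both, soil weakly on f2
  l1 <- c(mat = 0.95, tair = 0.9, tday = 0.9, tnight = 0.85, tmax = 0.9,
          tmin = 0.8, dtr = 0.5, par = 0.7, vpd = 0.6, spei = -0.2,
          precip = 0.1, tair_asv = -0.6, precip_asv = 0.1, vpd_asv = 0.4,
          ndvi = 0.5, ndvi_asv = -0.4, lai = 0.5, lnc = 0.3, lpc = 0.25,
          lnp = 0.2, sla = 0.3, ldmc = -0.3, swc = -0.1, soc = -0.3)
  l2 <- c(mat = 0.05, tair = 0.1, tday = 0.05, tnight = 0.15, tmax = -0.1,
          tmin = 0.2, dtr = -0.4, par = -0.3, vpd = -0.6, spei = 0.8,
          precip = 0.9, tair_asv = 0.1, precip_asv = 0.7, vpd_asv = -0.5,
          ndvi = 0.5, ndvi_asv = 0.3, lai = 0.5, lnc = 0.2, lpc = 0.3,
          lnp = -0.2, sla = 0.2, ldmc = -0.2, swc = 0.85, soc = 0.5)
  tab <- tibble::tibble(.rows = n)
  for (v in names(covs)) {
    tab[[v]] <- l1[[v]] * f1 + l2[[v]] * f2 +
      rnorm(n, 0, cov_noise * sqrt(max(0.05, 1 - l1[[v]]^2 - l2[[v]]^2)))
  }
  resp <- intercept + effect[1] * f1 + effect[2] * f2 + rnorm(n, 0, noise_sd)
  tab <- dplyr::mutate(tab, asv_delta = pmax(0, resp), .before = 1)
  attr(tab, "latent_1") <- f1
  attr(tab, "latent_2") <- f2
  tab
}

#' Principal component decomposition of the covariate table
#'
#' Standardizes the covariates (zero mean, unit variance) and extracts the
#' leading principal components, with per-variable contribution percentages
#' to each dimension and the average-contribution reference line `100 / p`.
#'
#' @param table A site feature table; every column except `response_col` is
#'   treated as a covariate. Must be free of missing values (impute first,
#'   e.g. per-biome medians).
#' @param n_components Number of components to retain (default 2).
#' @param response_col Name of the response column excluded from the PCA
#'   (default `"asv_delta"`).
#'
#' @return A list of class `pca_decomposition`: `scores` (n x k),
#'   `loadings` (p x k, orthonormal), `explained_pct`, `contributions`
#'   (percent, columns sum to 100), `avg_contribution`.
#' @export
pca_decompose <- function(table, n_components = 2,
                          response_col = "asv_delta") {
  x <- as.data.frame(table[, setdiff(names(table), response_col)])
  if (nrow(x) < 10) stop("pca_decompose: need at least 10 rows")
  if (nrow(x) < n_components) stop("pca_decompose: more components than rows")
  if (anyNA(x)) stop("pca_decompose: missing covariates; impute first")
  drop_const <- vapply(x, function(v) sd(v) == 0, logical(1))
  x <- x[, !drop_const, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$rotation))
  expl <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  contrib <- 100 * sweep(pc$rotation[, seq_len(k), drop = FALSE]^2, 2,
                         colSums(pc$rotation[, seq_len(k), drop = FALSE]^2),
                         "/")
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 loadings = pc$rotation[, seq_len(k), drop = FALSE],
                 explained_pct = expl,
                 contributions = contrib,
                 avg_contribution = 100 / ncol(x)),
            class = "pca_decomposition")
}

# Small-sample corrected Akaike information criterion.
aicc <- function(fit) {
  k <- attr(stats::logLik(fit), "df")
  n <- stats::nobs(fit)
  stats::AIC(fit) + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc-ranked linear models on the leading components
#'
#' Fits the candidate set {Dim1 + Dim2, Dim1, Dim2} of linear models for
#' the seasonal-amplitude response on the first two principal-component
#' scores and ranks them by the small-sample corrected AIC.
#'
#' @param response Response vector (one value per row of the score matrix).
#' @param scores Score matrix with at least two columns (from
#'   [pca_decompose()]).
#'
#' @return Tibble ranked by ascending AICc: `model`, `aicc`, `delta_aicc`,
#'   `r2`, `p`, `coef_dim1`, `se_dim1`, `coef_dim2`, `se_dim2`.
#' @export
glm_aicc_rank <- function(response, scores) {
  stopifnot(ncol(scores) >= 2, nrow(scores) == length(response))
  d <- data.frame(y = response, dim1 = scores[, 1], dim2 = scores[, 2])
  forms <- list("Dim1 + Dim2" = y ~ dim1 + dim2, "Dim1" = y ~ dim1,
                "Dim2" = y ~ dim2)
  rows <- lapply(names(forms), function(nm) {
    fit <- stats::lm(forms[[nm]], data = d)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    pval <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    co <- sm$coefficients
    get <- function(term, col) {
      if (term %in% rownames(co)) co[term, col] else NA_real_
    }
    tibble::tibble(
      model = nm, aicc = aicc(fit), r2 = sm$r.squared, p = unname(pval),
      coef_dim1 = get("dim1", 1), se_dim1 = get("dim1", 2),
      coef_dim2 = get("dim2", 1), se_dim2 = get("dim2", 2))
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$aicc)
  out$delta_aicc <- out$aicc - out$aicc[1]
  dplyr::relocate(out, "delta_aicc", .after = "aicc")
}

#' Random-forest permutation importance of the covariates
#'
#' Fits a random forest of the seasonal-amplitude response on all
#' covariates and reports the out-of-bag permutation importance (increase
#' in mean squared error when a predictor is permuted), plus importance
#' shares grouped by covariate family, normalized to sum to 100 percent
#' (negative raw importances are truncated at zero before normalization).
#'
#' @param table A site feature table with `asv_delta` and covariates.
#' @param seed RNG seed (the ranking is deterministic given the seed).
#' @param ntree Number of trees (default 500).
#' @param families Covariate -> family map (default
#'   [covariate_families()]); covariates absent from the map fall into
#'   family "other".
#'
#' @return A list: `importance` tibble (`covariate`, `inc_mse`, `share_pct`,
#'   `family`) sorted by decreasing importance, and `family_shares` tibble
#'   summing to 100.
#' @export
rf_importance <- function(table, seed = 1L, ntree = 500,
                          families = covariate_families()) {
  stopifnot(nrow(table) >= 30)
  y <- table$asv_delta
  if (sd(y) == 0) warning("rf_importance: constant response")
  x <- as.data.frame(table[, setdiff(names(table), "asv_delta")])
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = ntree,
                                    importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  fam <- unname(families[names(imp)])
  fam[is.na(fam)] <- "other"
  pos <- pmax(0, imp)
  share <- if (sum(pos) > 0) 100 * pos / sum(pos) else pos
  tb <- tibble::tibble(covariate = names(imp), inc_mse = unname(imp),
                       share_pct = unname(share), family = fam) |>
    dplyr::arrange(dplyr::desc(.data$inc_mse))
  fam_tb <- tb |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(share_pct = sum(.data$share_pct), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$share_pct))
  list(importance = tb, family_shares = fam_tb)
}
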