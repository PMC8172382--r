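# broom-style tidiers for the package's fitted objects.

#' Tidy a fitted variogram model
#'
#' @param x A [variogram_model()].
#' @param ... Unused.
#' @return A tibble with one row per parameter (`nugget`, `partial_sill`,
#'   `distance_param_km`) and columns `term`, `estimate`.
#' @export
tidy.variogram_model <- function(x, ...) {
  tibble::tibble(
    term = c("nugget", "partial_sill", "distance_param_km"),
    estimate = c(x$nugget, x$psill, x$range_par))
}

#' Glance at a fitted variogram model
#'
#' @param x A [variogram_model()].
#' @param ... Unused.
#' @return A one-row tibble: `sill`, `effective_range_km` (about 3a),
#'   `scale`, and — for WLS fits — `wrss`, `n_bins`, `estimator`,
#'   `converged`, `degenerate`.
#' @export
glance.variogram_model <- function(x, ...) {
  tibble::tibble(
    sill = x$nugget + x$psill,
    effective_range_km = 3 * x$range_par,
    scale = x$scale,
    wrss = x$wrss %||% NA_real_,
    n_bins = x$n_bins %||% NA_integer_,
    estimator = x$estimator %||% NA_character_,
    converged = x$converged %||% NA,
    degenerate = x$degenerate %||% NA)
}

#' Tidy a spatial LMM fit
#'
#' @param x A [fit_spatial_lmm()] object.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`
#'   (Wald z) per fixed effect. Hypothesis tests of fixed effects should
#'   use [lrt_fixed_effect()] on ML fits.
#' @export
tidy.spatial_lmm <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta),
                 std.error = unname(x$beta_se),
                 statistic = unname(x$beta / x$beta_se))
}

#' Glance at a spatial LMM fit
#'
#' @param x A [fit_spatial_lmm()] object.
#' @param ... Unused.
#' @return A one-row tibble: variance components, Matern parameters,
#'   `logLik`, `method`, `nobs`, `converged`.
#' @export
glance.spatial_lmm <- function(x, ...) {
  tibble::tibble(sigma2_s = x$sigma2_s, sigma2_n = x$sigma2_n,
                 phi_km = x$phi, nu = x$nu, logLik = x$loglik,
                 method = x$method, nobs = x$nobs, converged = x$converged)
}

#' Tidy a cross-validation report
#'
#' @param x A [cross_validate()] object.
#' @param ... Unused.
#' @return The per-site tibble (`observed`, `predicted`,
#'   `kriging_variance`, `sspe`).
#' @export
tidy.kriging_cv <- function(x, ...) x$sites

#' Glance at a cross-validation report
#'
#' @param x A [cross_validate()] object.
#' @param ... Unused.
#' @return A one-row tibble: `median_sspe`, `lower`, `upper`,
#'   `expected_median`, `verdict`, `n`.
#' @export
glance.kriging_cv <- function(x, ...) {
  tibble::tibble(median_sspe = x$median_sspe,
                 lower = x$interval[1], upper = x$interval[2],
                 expected_median = x$expected_median,
                 verdict = x$verdict, n = x$n)
}

#' Tidy a forward-selection result
#'
#' @param x A [forward_select_with_fdr()] object.
#' @param ... Unused.
#' @return The per-test tibble with LRT statistics, raw and BH-adjusted
#'   p-values, and selection flags.
#' @export
tidy.fdr_selection <- function(x, ...) x$tests

#' Glance at a forward-selection result
#'
#' @param x A [forward_select_with_fdr()] object.
#' @param ... Unused.
#' @return A one-row tibble: `n_tested`, `n_selected`, `alpha`, plus the
#'   final refit's [glance.spatial_lmm()] columns.
#' @export
glance.fdr_selection <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_tested = nrow(x$tests),
                   n_selected = length(x$selected), alpha = x$alpha),
    glance(x$fit))
}
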