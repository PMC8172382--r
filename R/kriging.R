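# Ordinary kriging (point, grid, block), leave-one-out cross-validation with
# the median-SSPE model diagnostic, median-unbiased back-transformation and
# kriging-variance masking.
#
# The ordinary kriging system in semivariance form is
#   [ Gamma  1 ] [ lambda ]   [ gamma0 ]
#   [ 1^T    0 ] [ psi    ] = [ 1      ]
# prediction = sum(lambda * z); variance = sum(lambda * gamma0) + psi.

ok_system <- function(D, model) {
  n <- nrow(D)
  G <- semivariance_matrix(D, model)
  K <- rbind(cbind(G, 1), c(rep(1, n), 0))
  K
}

check_duplicates_nugget <- function(data, D, model) {
  if (model$nugget == 0 && any(D[upper.tri(D)] == 0)) {
    idx <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
    ids <- if ("site_id" %in% names(data)) {
      paste(data$site_id[idx[, 1]], data$site_id[idx[, 2]], sep = "/")
    } else {
      paste(idx[, 1], idx[, 2], sep = "/")
    }
    abort(paste0("Ordinary kriging system singular: duplicate locations with ",
                 "zero nugget at sites ", paste(head(ids, 5), collapse = ", "), "."))
  }
}

#' Ordinary kriging at target locations
#'
#' Best linear unbiased prediction under a locally constant unknown mean:
#' weights solve the ordinary kriging equations built from the fitted
#' variogram model on great-circle distances, subject to the unbiasedness
#' constraint that the weights sum to 1. The kriging variance
#' \eqn{\sigma^2_K = \sum_i \lambda_i \gamma(x_0, x_i) + \psi} is the
#' minimised expected squared prediction error; it depends on the sampling
#' configuration and the variogram only, not on the observed values.
#'
#' @param data Data frame of observations with `lon`, `lat` and the value
#'   column (analysis scale).
#' @param model A [variogram_model()].
#' @param target Target location(s): `c(lon, lat)` or a data frame with
#'   `lon`, `lat`.
#' @param value Value column (tidy-eval), default `value`.
#' @param neighborhood `Inf` (default; all observations — global ordinary
#'   kriging) or an integer: use only the nearest-n observations per target.
#' @return A tibble with one row per target: `lon`, `lat`, `prediction`,
#'   `variance`, `lagrange`, and a list-column `weights` (kriging weights
#'   \eqn{\lambda_i}, in data row order for the sites used).
#' @export
ordinary_krige <- function(data, model, target, value = value,
                           neighborhood = Inf) {
  stopifnot(inherits(model, "variogram_model"))
  z <- dplyr::pull(data, {{ value }})
  n <- length(z)
  if (n < 2) abort("Ordinary kriging needs at least 2 observations.")
  tgt <- as_lonlat_matrix(target)
  D <- gc_distance_km(data)
  check_duplicates_nugget(data, D, model)
  D0 <- gc_distance_km(data, tgt)   # n x m
  m <- nrow(tgt)
  use_all <- !is.finite(neighborhood) || neighborhood >= n
  res <- tibble::tibble(lon = tgt[, 1], lat = tgt[, 2],
                        prediction = NA_real_, variance = NA_real_,
                        lagrange = NA_real_, weights = vector("list", m))
  if (use_all) {
    K <- ok_system(D, model)
    G0 <- rbind(semivariance_matrix(D0, model), rep(1, m))
    sol <- solve(K, G0)
    lam <- sol[1:n, , drop = FALSE]
    psi <- sol[n + 1, ]
    res$prediction <- as.vector(crossprod(lam, z))
    res$variance <- pmax(colSums(lam * G0[1:n, , drop = FALSE]) + psi, 0)
    res$lagrange <- psi
    res$weights <- lapply(seq_len(m), function(j) lam[, j])
  } else {
    k <- as.integer(neighborhood)
    for (j in seq_len(m)) {
      sel <- order(D0[, j])[seq_len(k)]
      Kj <- ok_system(D[sel, sel, drop = FALSE], model)
      g0 <- c(semivariance_matrix(D0[sel, j, drop = FALSE], model), 1)
      sol <- solve(Kj, g0)
      lam <- sol[1:k]; psi <- sol[k + 1]
      res$prediction[j] <- sum(lam * z[sel])
      res$variance[j] <- max(sum(lam * g0[1:k]) + psi, 0)
      res$lagrange[j] <- psi
      w <- numeric(n); w[sel] <- lam
      res$weights[[j]] <- w
    }
  }
  res
}

# chi-square(1 df) median: expected median SSPE under a valid model
#' Expected median standardized squared prediction error
#'
#' Under a valid variogram model with normally distributed kriging errors
#' the standardized squared prediction errors are approximately squared
#' standard normal (chi-square, 1 df) variables, whose median is
#' `qchisq(0.5, 1)` = 0.455 (3 d.p.).
#' @return The analytic median of the chi-square(1) distribution.
#' @export
sspe_expected_median <- function() qchisq(0.5, df = 1)

#' Null interval for the median SSPE
#'
#' Distribution-free order-statistic confidence interval for the sample
#' median of `n` iid squared-standard-normal draws: the k-th order statistic
#' of n uniforms is Beta(k, n - k + 1), so the interval endpoints are
#' chi-square(1) quantiles evaluated at Beta quantiles of the median ranks.
#'
#' @param n Number of cross-validation sites.
#' @param level Coverage level (default 0.95).
#' @return `c(lower, upper)`.
#' @export
sspe_null_interval <- function(n, level = 0.95) {
  a <- (1 - level) / 2
  k_lo <- floor((n + 1) / 2)
  k_hi <- ceiling((n + 1) / 2)
  c(lower = qchisq(qbeta(a, k_lo, n - k_lo + 1), df = 1),
    upper = qchisq(qbeta(1 - a, k_hi, n - k_hi + 1), df = 1))
}

#' Leave-one-out cross-validation of a variogram model
#'
#' Each observation is removed in turn and predicted from the rest by
#' ordinary kriging under `model`. The standardized squared prediction
#' error (SSPE) for site i is
#' \eqn{\theta_i = (z_i - \hat Z_{-i}(x_i))^2 / \sigma^2_{K,-i}}. Under a
#' valid model the median SSPE is expected to be `qchisq(0.5, 1)` = 0.455;
#' the observed median is compared with the 95% order-statistic null
#' interval ([sspe_null_interval()]) to give a consistency verdict.
#'
#' The default `"fast"` method computes all leave-one-out errors from a
#' single inverse of the bordered covariance-form kriging matrix
#' (\eqn{e_i = (A^{-1}\tilde z)_i / (A^{-1})_{ii}},
#' \eqn{\sigma^2_{K,-i} = 1/(A^{-1})_{ii}}); `"brute"` refits the kriging
#' system per site and is provided as an independent check.
#'
#' @param data Observations (`lon`, `lat`, value column).
#' @param model A [variogram_model()].
#' @param value Value column (tidy-eval).
#' @param level Interval coverage (default 0.95).
#' @param method `"fast"` (default) or `"brute"`.
#' @return An object of class `kriging_cv`: list with `sites` (tibble:
#'   `observed`, `predicted`, `kriging_variance`, `sspe`), `median_sspe`,
#'   `interval`, `expected_median`, `verdict` (`"consistent"` /
#'   `"inconsistent"`), `n`, `estimator`.
#' @export
cross_validate <- function(data, model, value = value, level = 0.95,
                           method = c("fast", "brute")) {
  method <- match.arg(method)
  z <- dplyr::pull(data, {{ value }})
  n <- length(z)
  if (n < 10) abort("Cross-validation needs at least 10 observations.")
  D <- gc_distance_km(data)
  check_duplicates_nugget(data, D, model)
  if (method == "fast") {
    sill <- model$nugget + model$psill
    C <- model$psill * exp(-D / model$range_par)
    diag(C) <- sill
    A <- rbind(cbind(C, 1), c(rep(1, n), 0))
    B <- tryCatch(solve(A), error = function(e)
      abort("Kriging matrix singular in cross-validation."))
    d <- diag(B)[1:n]
    err <- as.vector(B[1:n, , drop = FALSE] %*% c(z, 0)) / d
    kv <- 1 / d
    pred <- z - err
  } else {
    pred <- kv <- numeric(n)
    for (i in seq_len(n)) {
      r <- ordinary_krige(data[-i, , drop = FALSE], model,
                          c(data$lon[i], data$lat[i]), value = {{ value }})
      pred[i] <- r$prediction; kv[i] <- r$variance
    }
    err <- z - pred
  }
  if (any(kv <= 0)) {
    abort("Zero or negative leave-one-out kriging variance: model degenerate for cross-validation.")
  }
  sspe <- err^2 / kv
  med <- median(sspe)
  int <- sspe_null_interval(n, level)
  structure(list(
    sites = tibble::tibble(observed = z, predicted = pred,
                           kriging_variance = kv, sspe = sspe),
    median_sspe = med, interval = int,
    expected_median = sspe_expected_median(),
    verdict = if (med >= int[1] && med <= int[2]) "consistent" else "inconsistent",
    n = n, level = level, estimator = model$estimator %||% NA_character_),
    class = "kriging_cv")
}

#' @export
print.kriging_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out cross-validation (n = %d)\n", x$n))
  cat(sprintf("  median SSPE = %.4f (expected %.3f under a valid model)\n",
              x$median_sspe, x$expected_median))
  cat(sprintf("  %.0f%% null interval: [%.4f, %.4f] -> %s\n",
              100 * x$level, x$interval[1], x$interval[2], x$verdict))
  invisible(x)
}

#' Select a variogram model by cross-validation
#'
#' Implements the estimator-selection rule: the Matheron estimator is the
#' most statistically efficient, so its fitted model is adopted whenever its
#' leave-one-out median SSPE is consistent with a valid model (inside the
#' 95% null interval); the robust alternatives are then not considered.
#' Otherwise the robust-estimator fits are cross-validated and the model
#' whose median SSPE is closest to the expected 0.455 is returned (with a
#' warning flag if none validates).
#'
#' @param data Observations (`lon`, `lat`, value column).
#' @param candidates Named list of fitted [variogram_model()]s; must
#'   contain `"matheron"`. Typical names: `matheron`, `cressie_hawkins`,
#'   `dowd`.
#' @param value Value column (tidy-eval).
#' @param level Interval coverage for the consistency check.
#' @return A list of class `model_selection`: `model`, `estimator`,
#'   `reports` (named list of [cross_validate()] results computed),
#'   `validated` (logical), `rationale`.
#' @export
select_model <- function(data, candidates, value = value, level = 0.95) {
  if (!"matheron" %in% names(candidates)) {
    abort("candidates must include a 'matheron' fit.")
  }
  reports <- list()
  reports$matheron <- cross_validate(data, candidates$matheron,
                                     value = {{ value }}, level = level)
  if (reports$matheron$verdict == "consistent") {
    return(structure(list(
      model = candidates$matheron, estimator = "matheron",
      reports = reports, validated = TRUE,
      rationale = "Matheron fit consistent in cross-validation; robust alternatives not considered."),
      class = "model_selection"))
  }
  others <- setdiff(names(candidates), "matheron")
  if (length(others) == 0) {
    warn("Matheron fit inconsistent and no robust candidates supplied.")
    return(structure(list(model = candidates$matheron, estimator = "matheron",
                          reports = reports, validated = FALSE,
                          rationale = "Only candidate; inconsistent."),
                     class = "model_selection"))
  }
  for (nm in others) {
    reports[[nm]] <- cross_validate(data, candidates[[nm]],
                                    value = {{ value }}, level = level)
  }
  target <- sspe_expected_median()
  meds <- vapply(reports[others], function(r) r$median_sspe, numeric(1))
  pick <- others[which.min(abs(meds - target))]
  validated <- reports[[pick]]$verdict == "consistent"
  if (!validated) warn("No candidate model validates; returning the closest to 0.455.")
  structure(list(
    model = candidates[[pick]], estimator = pick, reports = reports,
    validated = validated,
    rationale = sprintf(
      "Matheron fit inconsistent (median SSPE %.3f); '%s' selected with median SSPE %.3f, closest to %.3f.",
      reports$matheron$median_sspe, pick, reports[[pick]]$median_sspe, target)),
    class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Variogram model selection\n  chosen estimator:", x$estimator, "\n")
  cat("  ", x$rationale, "\n", sep = "")
  print(x$model)
  invisible(x)
}

#' Krige a prediction grid
#'
#' Ordinary kriging of every grid node, with median-unbiased
#' back-transformation for log-scale analyses: when `scale = "log_e"` the
#' prediction map is the exponential of the log-scale kriging prediction
#' (a median-unbiased predictor for skewed variables), while the kriging
#' variance map remains on the log_e scale, since the kriging variance
#' cannot be meaningfully back-transformed.
#'
#' @param data Observations (`lon`, `lat`, value column on analysis scale).
#' @param model A [variogram_model()].
#' @param grid Data frame of grid nodes (`lon`, `lat`).
#' @param value Value column (tidy-eval).
#' @param scale `"original"` or `"log_e"`; defaults to `model$scale`.
#' @param neighborhood As in [ordinary_krige()].
#' @return A tibble of class `kriging_grid`: `lon`, `lat`, `prediction`
#'   (back-transformed when log-scale), `variance` (analysis scale).
#'   Nodes whose kriging system fails are returned with `NA` rather than
#'   aborting the map.
#' @export
krige_grid <- function(data, model, grid, value = value, scale = NULL,
                       neighborhood = Inf) {
  if (nrow(grid) == 0) abort("Prediction grid is empty.")
  scale <- scale %||% model$scale
  res <- tryCatch(
    ordinary_krige(data, model, grid, value = {{ value }},
                   neighborhood = neighborhood),
    error = function(e) NULL)
  if (is.null(res)) {
    # fall back to per-node so isolated failures are marked missing
    res <- purrr::map_dfr(seq_len(nrow(grid)), function(j) {
      r <- tryCatch(
        ordinary_krige(data, model, c(grid$lon[j], grid$lat[j]),
                       value = {{ value }}, neighborhood = neighborhood),
        error = function(e) tibble::tibble(
          lon = grid$lon[j], lat = grid$lat[j], prediction = NA_real_,
          variance = NA_real_, lagrange = NA_real_, weights = list(NULL)))
      r
    })
  }
  out <- tibble::tibble(lon = res$lon, lat = res$lat,
                        prediction = res$prediction, variance = res$variance)
  if (scale == "log_e") out$prediction <- exp(out$prediction)
  structure(out, class = c("kriging_grid", class(tibble::tibble()))) |>
    set_attrs(scale = scale)
}

#' Mask grid nodes with excessive kriging variance
#'
#' Flags nodes where the kriging variance strictly exceeds `fraction`
#' (default 0.75) of the variance of the data themselves — areas where
#' sampling is too sparse for the predictions to be shown.
#'
#' @param grid A [krige_grid()] result (or any tibble with a `variance`
#'   column).
#' @param data_variance Variance of the analysed variable on the analysis
#'   scale (> 0).
#' @param fraction Masking threshold as a fraction of `data_variance`.
#' @return `grid` with a logical `masked` column added.
#' @export
variance_mask <- function(grid, data_variance, fraction = 0.75) {
  if (!is.finite(data_variance) || data_variance <= 0) {
    abort("data_variance must be positive.")
  }
  grid$masked <- grid$variance > fraction * data_variance
  grid
}

#' Block kriging of the mean over a polygon
#'
#' Predicts the spatial mean of the variable over a region (for example an
#' administrative unit) by ordinary block kriging: the block is discretised
#' into regular interior nodes, the right-hand side uses point-to-block
#' mean semivariances \eqn{\bar\gamma(x_i, B)} and the block variance
#' subtracts the within-block mean semivariance \eqn{\bar\gamma(B, B)}:
#' \deqn{\sigma^2_B = \sum_i \lambda_i \bar\gamma(x_i, B) + \psi - \bar\gamma(B, B).}
#'
#' @param data Observations (`lon`, `lat`, value column).
#' @param model A [variogram_model()].
#' @param polygon A polygon: matrix/data frame of (lon, lat) vertices, or a
#'   list of rings (first outer, others holes) as returned by
#'   [read_polygons_geojson()].
#' @param value Value column (tidy-eval).
#' @param spacing_km Discretisation node spacing in km. Default: 1 km, or
#'   finer so that the block holds at least 100 interior nodes.
#' @return A one-row tibble: `prediction`, `variance`, `n_nodes`,
#'   `spacing_km`; kriging weights in attribute `"weights"`.
#' @export
block_krige <- function(data, model, polygon, value = value,
                        spacing_km = NULL) {
  z <- dplyr::pull(data, {{ value }})
  n <- length(z)
  nodes <- discretize_polygon(polygon, spacing_km)
  D <- gc_distance_km(data)
  check_duplicates_nugget(data, D, model)
  Dn <- gc_distance_km(data, nodes)            # n x q
  gbar_data <- rowMeans(semivariance_matrix(Dn, model))
  Dq <- gc_distance_km(nodes)
  gbar_block <- mean(semivariance_matrix(Dq, model))
  K <- ok_system(D, model)
  sol <- solve(K, c(gbar_data, 1))
  lam <- sol[1:n]; psi <- sol[n + 1]
  out <- tibble::tibble(
    prediction = sum(lam * z),
    variance = max(sum(lam * gbar_data) + psi - gbar_block, 0),
    n_nodes = nrow(nodes), spacing_km = attr(nodes, "spacing_km"))
  attr(out, "weights") <- lam
  out
}

# Regular lon/lat node grid inside a polygon (holes respected).
discretize_polygon <- function(polygon, spacing_km = NULL) {
  rings <- as_polygon_rings(polygon)
  outer <- rings[[1]]
  bbox <- c(range(outer[, 1]), range(outer[, 2]))
  if (is.null(spacing_km)) {
    spacing_km <- 1
    repeat {
      nodes <- polygon_grid(rings, bbox, spacing_km)
      if (nrow(nodes) >= 100 || spacing_km < 0.01) break
      spacing_km <- spacing_km / 2
    }
  } else {
    nodes <- polygon_grid(rings, bbox, spacing_km)
  }
  if (nrow(nodes) == 0) {
    abort("Polygon contains no interior nodes at the given spacing; use a finer spacing_km.")
  }
  set_attrs(nodes, spacing_km = spacing_km)
}

polygon_grid <- function(rings, bbox, spacing_km) {
  km_per_deg_lat <- pi * 6378.137 / 180
  mid_lat <- mean(bbox[3:4])
  dlat <- spacing_km / km_per_deg_lat
  dlon <- spacing_km / (km_per_deg_lat * max(cos(mid_lat * pi / 180), 1e-6))
  lons <- if (bbox[1] + dlon / 2 >= bbox[2]) mean(bbox[1:2]) else
    seq(bbox[1] + dlon / 2, bbox[2], by = dlon)
  lats <- if (bbox[3] + dlat / 2 >= bbox[4]) mean(bbox[3:4]) else
    seq(bbox[3] + dlat / 2, bbox[4], by = dlat)
  g <- expand.grid(lon = lons, lat = lats, KEEP.OUT.ATTRS = FALSE)
  keep <- point_in_polygon(g, rings)
  tibble::as_tibble(g[keep, , drop = FALSE])
}
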