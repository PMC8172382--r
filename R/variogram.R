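# Empirical variogram estimation and exponential model fitting.
# Lags are great-circle distances in km; semivariances are in squared units
# of the analysis-scale variable.

#' Exponential variogram model
#'
#' Container for the parameters of the exponential nugget model
#' \deqn{\gamma(h) = c_0 + c\,(1 - e^{-h/a}), \quad h > 0;\qquad \gamma(0)=0,}
#' with nugget `c0`, partial sill `c` (sill = `c0 + c`) and distance
#' parameter `a` in km (effective range about `3a`). The exponential family
#' is used because it yields positive-definite covariance matrices for
#' great-circle distances on the sphere.
#'
#' @param nugget Nugget variance c0 (>= 0), squared value units.
#' @param psill Partial sill c (>= 0), squared value units.
#' @param range_par Distance parameter a in km (> 0 whenever `psill > 0`).
#' @param scale Analysis scale the model refers to: `"original"` or `"log_e"`.
#' @return An object of class `variogram_model`.
#' @examples
#' m <- variogram_model(nugget = 0.2, psill = 0.8, range_par = 30)
#' exponential_semivariance(c(0, 30, 90), m)
#' @export
variogram_model <- function(nugget, psill, range_par,
                            scale = c("original", "log_e")) {
  scale <- match.arg(scale)
  if (!is.finite(nugget) || nugget < 0) abort("nugget must be finite and >= 0.")
  if (!is.finite(psill) || psill < 0) abort("psill must be finite and >= 0.")
  if (psill > 0 && (!is.finite(range_par) || range_par <= 0)) {
    abort("range_par must be > 0 when psill > 0.")
  }
  structure(
    list(nugget = nugget, psill = psill, range_par = range_par, scale = scale),
    class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat("Exponential variogram model (", x$scale, " scale)\n", sep = "")
  cat(sprintf("  nugget c0 = %.6g, partial sill c = %.6g, distance parameter a = %.6g km\n",
              x$nugget, x$psill, x$range_par))
  if (!is.null(x$wrss)) {
    cat(sprintf("  fitted by WLS: weighted RSS = %.4g over %d bins (%s estimator)%s\n",
                x$wrss, x$n_bins, x$estimator %||% "?",
                if (isTRUE(x$degenerate)) " [degenerate: c ~ 0]" else ""))
  }
  invisible(x)
}

#' Exponential semivariance function
#'
#' Evaluates the exponential model at lag `h` (km). By the variogram
#' convention the value at `h = 0` is exactly 0; the nugget `c0` is the
#' limit as `h` approaches 0 from above.
#'
#' @param h Non-negative lag distance(s), km.
#' @param model A [variogram_model()].
#' @return Semivariance(s), squared value units.
#' @export
exponential_semivariance <- function(h, model) {
  stopifnot(inherits(model, "variogram_model"))
  if (any(h < 0)) abort("Lag distances must be non-negative.")
  g <- model$nugget + model$psill * (1 - exp(-h / model$range_par))
  g[h == 0] <- 0
  g
}

# model semivariance matrix for a distance matrix in km; gamma(0) = 0
semivariance_matrix <- function(D, model) {
  G <- model$nugget + model$psill * (1 - exp(-D / model$range_par))
  G[D == 0] <- 0
  G
}

#' Empirical variogram on great-circle distances
#'
#' Forms semivariance estimates from all pairwise comparisons among
#' observations up to `max_lag_km`, in contiguous half-open lag bins
#' `[lower, upper)` of width `bin_width_km` starting at 0. Three estimators
#' are available:
#' \describe{
#'   \item{matheron}{the standard method-of-moments estimator,
#'     \eqn{\hat\gamma = \frac{1}{2N}\sum d_i^2};}
#'   \item{cressie_hawkins}{\eqn{\hat\gamma = \big(\frac{1}{N}\sum
#'     \sqrt{|d_i|}\big)^4 / \big(2\,(0.457 + 0.494/N)\big)}, robust to
#'     marginal outliers;}
#'   \item{dowd}{\eqn{\hat\gamma = 2.198\,\mathrm{med}(|d_i|)^2 / 2},
#'     robust to both marginal and spatial outliers.}
#' }
#' Each bin's representative lag is the mean of its member pair distances,
#' not the bin midpoint. Empty bins are reported with `npairs = 0` and
#' `NA` semivariance, and are excluded from model fitting.
#'
#' @param data Data frame with `lon`, `lat` and the value column.
#' @param value Value column (tidy-eval), default `value`. Must already be
#'   on the analysis scale (see [choose_scale()]).
#' @param max_lag_km Maximum lag distance, km; must be a positive multiple
#'   of `bin_width_km`. The source surveys used 330 km (Ethiopia) and
#'   100 km (Malawi).
#' @param bin_width_km Lag bin width, km (default 10).
#' @param estimator One of `"matheron"`, `"cressie_hawkins"`, `"dowd"`.
#' @return A tibble of class `empirical_variogram` with columns
#'   `bin_lower`, `bin_upper`, `lag` (mean pair distance, km), `gamma`,
#'   `npairs`, and attributes `estimator`, `bin_width_km`, `max_lag_km`,
#'   `n_sites`.
#' @export
empirical_variogram <- function(data, value = value, max_lag_km = 100,
                                bin_width_km = 10,
                                estimator = c("matheron", "cressie_hawkins", "dowd")) {
  estimator <- match.arg(estimator)
  z <- dplyr::pull(data, {{ value }})
  if (!all(is.finite(z))) abort("Values must be finite.")
  n <- length(z)
  if (n < 30) warn("Fewer than 30 samples: variogram estimates will be unstable.")
  nbins <- max_lag_km / bin_width_km
  if (!isTRUE(all.equal(nbins, round(nbins))) || max_lag_km <= 0) {
    abort("max_lag_km must be a positive multiple of bin_width_km.")
  }
  nbins <- as.integer(round(nbins))
  D <- gc_distance_km(data)
  iu <- which(upper.tri(D))
  d_km <- D[iu]
  dz <- (rep(z, times = n)[iu] - rep(z, each = n)[iu])
  keep <- d_km < max_lag_km
  d_km <- d_km[keep]; dz <- dz[keep]
  bin <- findInterval(d_km, seq(0, max_lag_km, by = bin_width_km),
                      rightmost.closed = FALSE)
  est_fun <- switch(estimator,
    matheron = function(d) sum(d^2) / (2 * length(d)),
    cressie_hawkins = function(d) {
      N <- length(d)
      mean(sqrt(abs(d)))^4 / (2 * (0.457 + 0.494 / N))
    },
    dowd = function(d) 2.198 * median(abs(d))^2 / 2)
  out <- tibble::tibble(
    bin_lower = seq(0, max_lag_km - bin_width_km, by = bin_width_km),
    bin_upper = seq(bin_width_km, max_lag_km, by = bin_width_km),
    lag = NA_real_, gamma = NA_real_, npairs = 0L)
  for (b in unique(bin)) {
    db <- d_km[bin == b]; zb <- dz[bin == b]
    out$lag[b] <- mean(db)
    out$gamma[b] <- est_fun(zb)
    out$npairs[b] <- length(zb)
  }
  if (all(out$npairs == 0L)) abort("All lag bins are empty up to max_lag_km.")
  structure(out,
            class = c("empirical_variogram", class(tibble::tibble()))) |>
    set_attrs(estimator = estimator, bin_width_km = bin_width_km,
              max_lag_km = max_lag_km, n_sites = n)
}

set_attrs <- function(x, ...) {
  dots <- list(...)
  for (nm in names(dots)) attr(x, nm) <- dots[[nm]]
  x
}

#' Fit an exponential variogram model by weighted least squares
#'
#' Minimises \eqn{\sum_j w_j (\hat\gamma_j - \gamma(h_j; c_0, c, a))^2} over
#' the occupied lag bins, subject to \eqn{c_0, c \ge 0}, \eqn{a > 0}.
#' The default weights are \eqn{w_j = N_j / \gamma(h_j;\theta)^2}
#' (pair count over squared model semivariance), updated over
#' `reweight_rounds` rounds of iterative reweighting; `weights = "npairs"`
#' gives plain pair-count weighting. Optimisation is bounded quasi-Newton
#' (L-BFGS-B) from `n_starts` starting points derived from bin statistics;
#' ties are broken by lowest weighted RSS, then lowest nugget.
#'
#' @param emp An [empirical_variogram()].
#' @param init Optional [variogram_model()] used as the first start.
#' @param weights `"npairs_over_gamma2"` (default) or `"npairs"`.
#' @param n_starts Number of starting points (default 5).
#' @param reweight_rounds Iterative reweighting rounds (default 3).
#' @return A [variogram_model()] carrying fit diagnostics: `wrss`,
#'   `converged`, `n_bins`, `estimator`, and `degenerate = TRUE` (with a
#'   warning) when the fitted partial sill collapses to ~0.
#' @export
fit_exponential_wls <- function(emp, init = NULL,
                                weights = c("npairs_over_gamma2", "npairs"),
                                n_starts = 5, reweight_rounds = 3) {
  weights <- match.arg(weights)
  stopifnot(inherits(emp, "empirical_variogram"))
  ok <- emp$npairs > 0L & is.finite(emp$gamma)
  h <- emp$lag[ok]; g <- emp$gamma[ok]; N <- as.numeric(emp$npairs[ok])
  if (length(h) < 3) abort("Need at least 3 occupied lag bins to fit a model.")
  max_lag <- attr(emp, "max_lag_km")
  sill0 <- mean(g[h >= stats::quantile(h, 2 / 3)])
  c0_0 <- max(min(g[which.min(h)], sill0), 0)
  start0 <- c(c0 = 0.5 * c0_0, c = max(sill0 - 0.5 * c0_0, 0.1 * sill0),
              a = max_lag / 3)
  if (!is.null(init)) {
    start0 <- c(c0 = init$nugget, c = max(init$psill, 1e-8), a = init$range_par)
  }
  starts <- list(
    start0,
    c(start0[1], start0[2], start0[3] / 4),
    c(start0[1], start0[2], start0[3] * 3),
    c(0.1 * sill0, 0.9 * sill0, max_lag / 6),
    c(0.5 * sill0, 0.5 * sill0, max_lag / 2))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  lower <- c(0, 0, 1e-3)
  upper <- c(Inf, Inf, 20 * max_lag)
  gmod <- function(th) th[1] + th[2] * (1 - exp(-h / th[3]))
  obj <- function(th, w) sum(w * (g - gmod(th))^2)
  best <- NULL
  for (s in starts) {
    th <- pmin(pmax(s, lower + c(0, 0, 0)), c(10 * sill0 + 1, 10 * sill0 + 1, upper[3]))
    conv <- FALSE
    for (round in seq_len(if (weights == "npairs") 1L else reweight_rounds)) {
      w <- if (weights == "npairs") N else N / pmax(gmod(th), 1e-12)^2
      fit <- tryCatch(
        optim(th, obj, w = w, method = "L-BFGS-B", lower = lower,
              upper = upper, control = list(maxit = 500)),
        error = function(e) NULL)
      if (is.null(fit)) break
      th <- fit$par
      conv <- fit$convergence == 0
    }
    if (is.null(fit)) next
    w_final <- if (weights == "npairs") N else N / pmax(gmod(th), 1e-12)^2
    cand <- list(par = th, wrss = obj(th, w_final), conv = conv)
    if (is.null(best) || cand$wrss < best$wrss - 1e-12 ||
        (abs(cand$wrss - best$wrss) <= 1e-12 && cand$par[1] < best$par[1])) {
      best <- cand
    }
  }
  if (is.null(best)) abort("WLS variogram fit failed from every starting point.")
  m <- variogram_model(nugget = unname(best$par[1]),
                       psill = unname(best$par[2]),
                       range_par = unname(best$par[3]), scale = "original")
  m$wrss <- best$wrss
  m$converged <- best$conv
  m$n_bins <- length(h)
  m$estimator <- attr(emp, "estimator")
  m$degenerate <- best$par[2] <= 1e-8 * (best$par[1] + best$par[2] + 1e-300)
  if (m$degenerate) warn("Fitted partial sill is ~0 (pure-nugget model).")
  m
}

#' Matern correlation function
#'
#' \deqn{\rho(h) = \frac{2^{1-\nu}}{\Gamma(\nu)}\left(\frac{h}{\phi}\right)^{\nu}
#'   K_\nu\!\left(\frac{h}{\phi}\right)}
#' with \eqn{\rho(0) = 1}. `nu = 0.5` gives the exponential correlation
#' `exp(-h/phi)`. For very large `nu` (> 50), where Bessel evaluation
#' overflows, the unscaled Gaussian limit `exp(-h^2 / (4 nu phi^2))` is
#' returned with a warning.
#'
#' @param h Non-negative distance(s), km.
#' @param phi Distance parameter, km (> 0).
#' @param nu Smoothness parameter (> 0).
#' @return Correlation(s) in (0, 1].
#' @export
matern_correlation <- function(h, phi, nu) {
  if (any(h < 0)) abort("Distances must be non-negative.")
  if (phi <= 0 || nu <= 0) abort("phi and nu must be positive.")
  if (nu > 50) {
    warn("nu > 50: returning the Gaussian-limit approximation.")
    return(exp(-h^2 / (4 * nu * phi^2)))
  }
  u <- h / phi
  r <- rep(1, length(u))
  pos <- u > 0
  if (nu == 0.5) {
    r[pos] <- exp(-u[pos])
  } else {
    r[pos] <- (2^(1 - nu) / gamma(nu)) * u[pos]^nu * besselK(u[pos], nu)
  }
  r
}

# Matern correlation matrix for a km distance matrix
matern_matrix <- function(D, phi, nu) {
  R <- matrix(matern_correlation(as.vector(D), phi, nu), nrow = nrow(D))
  R
}
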