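# Linear mixed models with a Matern-correlated spatial random effect:
#   y = X beta + u + e,  Var(y) = sigma2_s R(phi, nu) + sigma2_n I
# with R built from great-circle distances. Variance parameters are
# estimated by (RE)ML on a profiled likelihood: writing
# V = sigma2 * W, W = tau R + (1 - tau) I, the overall scale sigma2 has a
# closed-form maximiser, leaving a 2-parameter search over
# (logit tau, log phi) per candidate nu. Fixed effects are then the
# generalised (weighted) least-squares solution under the fitted V, with
# standard errors from (X' V^-1 X)^-1.

lmm_profile_loglik <- function(z, D, X, y, nu, method) {
  # z = c(qlogis(tau), log(phi)); returns list(loglik, beta, se, ...)
  tau <- stats::plogis(z[1]); phi <- exp(z[2])
  n <- length(y); p <- ncol(X)
  W <- tau * matern_matrix(D, phi, nu)
  diag(W) <- diag(W) + (1 - tau) + 1e-10
  U <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(U)) return(list(loglik = -Inf))
  logdetW <- 2 * sum(log(diag(U)))
  Xs <- backsolve(U, X, transpose = TRUE)
  ys <- backsolve(U, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  beta <- backsolve(R, backsolve(R, crossprod(Xs, ys), transpose = TRUE))
  r <- ys - Xs %*% beta
  rss <- sum(r^2)
  if (method == "ML") {
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetW + n)
  } else {
    sigma2 <- rss / (n - p)
    logdetXtX <- 2 * sum(log(diag(R)))
    ll <- -0.5 * ((n - p) * log(2 * pi) + (n - p) * log(sigma2) +
                    logdetW + logdetXtX + (n - p))
  }
  vcov_beta <- sigma2 * chol2inv(R)
  list(loglik = ll, beta = drop(beta), vcov_beta = vcov_beta,
       sigma2 = sigma2, tau = tau, phi = phi)
}

#' Fit a spatial linear mixed model with Matern correlation
#'
#' Fits `formula` to georeferenced data with a spatially correlated random
#' effect: `Var(y) = sigma2_s R(phi, nu) + sigma2_n I`, `R` the Matern
#' correlation matrix on great-circle distances (km). Variance parameters
#' are estimated by residual maximum likelihood (`method = "REML"`,
#' default) or maximum likelihood (`"ML"`, required for likelihood-ratio
#' tests of fixed effects); fixed effects are then estimated by weighted
#' (generalised) least squares under the fitted covariance, with standard
#' errors from \eqn{(X^T V^{-1} X)^{-1}}.
#'
#' The Matern smoothness `nu` is weakly identified from typical survey
#' data, so it is profiled over a small discrete grid (default
#' `c(0.25, 0.5, 1, 2)`) and the best value reported; pass a single value
#' to fix it. Optimisation over (logit of the spatial variance proportion,
#' log phi) uses Nelder-Mead from `n_starts` starting points; ties are
#' broken by highest log-likelihood, then smallest `phi`.
#'
#' @param data Data frame with `lon`, `lat`, the response and predictors.
#'   The response must already be on its analysis scale (log_e where
#'   appropriate, e.g. serum/plasma Se biomarkers).
#' @param formula Model formula, e.g. `log_biomarker ~ grain_value`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param nu Matern smoothness grid to profile over.
#' @param n_starts Number of optimiser starting points (default 3).
#' @return An object of class `spatial_lmm`: fixed effects `beta` with
#'   `beta_se` and `vcov_beta`, variance components `sigma2_s`,
#'   `sigma2_n`, Matern `phi` (km) and `nu`, `loglik`, `method`, `nobs`,
#'   `formula`, `converged`.
#' @export
fit_spatial_lmm <- function(data, formula, method = c("REML", "ML"),
                            nu = c(0.25, 0.5, 1, 2), n_starts = 3) {
  method <- match.arg(method)
  mf <- model.frame(formula, data = data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  if (n < 10) abort("Need at least 10 observations.")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", "), "."))
  }
  if (nrow(mf) != nrow(data)) {
    abort("Missing values in response or predictors; supply complete cases.")
  }
  D <- gc_distance_km(data)
  maxd <- max(D)
  starts <- list(c(stats::qlogis(0.5), log(maxd / 10)),
                 c(stats::qlogis(0.8), log(maxd / 4)),
                 c(stats::qlogis(0.2), log(maxd / 40)))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  best <- NULL
  for (nuk in nu) {
    for (s in starts) {
      opt <- tryCatch(
        optim(s, function(z) -lmm_profile_loglik(z, D, X, y, nuk, method)$loglik,
              method = "Nelder-Mead",
              control = list(maxit = 500, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(opt)) next
      fit <- lmm_profile_loglik(opt$par, D, X, y, nuk, method)
      fit$nu <- nuk
      fit$converged <- opt$convergence == 0
      better <- is.null(best) || fit$loglik > best$loglik + 1e-9 ||
        (abs(fit$loglik - best$loglik) <= 1e-9 && fit$phi < best$phi)
      if (better) best <- fit
    }
  }
  if (is.null(best) || !is.finite(best$loglik)) {
    abort("Spatial LMM optimisation failed to converge from every start.")
  }
  structure(list(
    beta = setNames(best$beta, colnames(X)),
    beta_se = setNames(sqrt(diag(best$vcov_beta)), colnames(X)),
    vcov_beta = best$vcov_beta,
    sigma2_s = best$sigma2 * best$tau,
    sigma2_n = best$sigma2 * (1 - best$tau),
    phi = best$phi, nu = best$nu,
    loglik = best$loglik, method = method, nobs = n,
    formula = formula, converged = best$converged),
    class = "spatial_lmm")
}

#' @export
print.spatial_lmm <- function(x, ...) {
  cat(sprintf("Spatial LMM (%s), n = %d, logLik = %.3f\n",
              x$method, x$nobs, x$loglik))
  cat("  ", deparse(x$formula), "\n", sep = "")
  est <- cbind(Estimate = x$beta, `Std. Error` = x$beta_se)
  print(round(est, 5))
  cat(sprintf("  sigma2_s = %.5g, sigma2_n = %.5g, phi = %.4g km, nu = %.3g\n",
              x$sigma2_s, x$sigma2_n, x$phi, x$nu))
  invisible(x)
}

#' Log-likelihood ratio test between nested spatial LMMs
#'
#' `L = 2 (logLik_full - logLik_null)` referred to the chi-square
#' distribution with degrees of freedom equal to the difference in fixed-
#' effect count. Both fits must use `method = "ML"`: REML log-likelihoods
#' of models with different fixed effects are not comparable.
#'
#' @param fit_full,fit_null [fit_spatial_lmm()] fits; the null model's
#'   fixed effects must be a subset of the full model's.
#' @return A one-row tibble: `statistic` (L), `df`, `p.value`.
#' @export
lrt_fixed_effect <- function(fit_full, fit_null) {
  stopifnot(inherits(fit_full, "spatial_lmm"), inherits(fit_null, "spatial_lmm"))
  if (fit_full$method != "ML" || fit_null$method != "ML") {
    abort("Likelihood-ratio tests of fixed effects require ML fits (refit with method = 'ML').")
  }
  df <- length(fit_full$beta) - length(fit_null$beta)
  if (df < 0) abort("fit_null has more fixed effects than fit_full; swap the arguments.")
  L <- 2 * (fit_full$loglik - fit_null$loglik)
  p <- if (df == 0) 1 else pchisq(L, df = df, lower.tail = FALSE)
  tibble::tibble(statistic = L, df = df, p.value = p)
}

#' Tail probability of a log-likelihood ratio statistic
#'
#' Upper-tail chi-square probability for an observed L statistic, as used
#' when reporting [lrt_fixed_effect()] results.
#'
#' @param L Observed log-likelihood ratio statistic (>= 0).
#' @param df Degrees of freedom (difference in fixed-effect count).
#' @return P(chi-square_df >= L).
#' @examples
#' lrt_pvalue(14.48)   # 1.4e-4
#' lrt_pvalue(11.56)   # 6.7e-4
#' @export
lrt_pvalue <- function(L, df = 1) {
  if (any(L < 0)) abort("L must be non-negative.")
  pchisq(L, df = df, lower.tail = FALSE)
}

#' Forward covariate selection with FDR control
#'
#' Considers predictors in the stated order; each is tested against the
#' current model by a likelihood-ratio test (ML fits) and retained
#' provisionally if `p < 0.05`. The p-values of all tests performed are
#' then evaluated as a family under Benjamini-Hochberg FDR control at
#' `q = alpha`; the final model keeps only the FDR-surviving predictors
#' and is refit (REML by default).
#'
#' @param data Data frame with `lon`, `lat`, response and predictors.
#' @param response Response column name (character); analysis scale.
#' @param predictors_in_order Character vector of predictor names, in
#'   testing order (e.g. environment: MAP, MAT, TI; soil: pH, SOC).
#' @param alpha FDR level (default 0.05).
#' @param nu,n_starts Passed to [fit_spatial_lmm()].
#' @param refit_method Method for the final refit (default `"REML"`).
#' @return An object of class `fdr_selection`: `tests` (tibble with
#'   `predictor`, `statistic`, `df`, `p.value`, `p.adjusted`,
#'   `retained_initial`, `selected`), `selected` (character), `fit`
#'   (final refit).
#' @export
forward_select_with_fdr <- function(data, response, predictors_in_order,
                                    alpha = 0.05, nu = c(0.25, 0.5, 1, 2),
                                    n_starts = 3, refit_method = "REML") {
  if (length(predictors_in_order) == 0) abort("No predictors supplied.")
  current <- character(0)
  fml <- function(preds) {
    rhs <- if (length(preds) == 0) "1" else paste(preds, collapse = " + ")
    as.formula(paste(response, "~", rhs))
  }
  fit_cur <- fit_spatial_lmm(data, fml(current), method = "ML", nu = nu,
                             n_starts = n_starts)
  tests <- purrr::map_dfr(predictors_in_order, function(pr) {
    fit_try <- fit_spatial_lmm(data, fml(c(current, pr)), method = "ML",
                               nu = nu, n_starts = n_starts)
    lr <- lrt_fixed_effect(fit_try, fit_cur)
    keep <- lr$p.value < 0.05
    if (keep) {
      current <<- c(current, pr)
      fit_cur <<- fit_try
    }
    dplyr::mutate(lr, predictor = pr, retained_initial = keep,
                  .before = 1)
  })
  tests$p.adjusted <- p.adjust(tests$p.value, method = "BH")
  tests$selected <- tests$retained_initial & tests$p.adjusted <= alpha
  selected <- tests$predictor[tests$selected]
  fit <- fit_spatial_lmm(data, fml(selected), method = refit_method,
                         nu = nu, n_starts = n_starts)
  structure(list(tests = tests, selected = selected, fit = fit,
                 alpha = alpha, response = response),
            class = "fdr_selection")
}

#' @export
print.fdr_selection <- function(x, ...) {
  cat(sprintf("Forward selection with BH-FDR control at q = %.2f\n", x$alpha))
  print(as.data.frame(x$tests[, c("predictor", "statistic", "df", "p.value",
                                  "p.adjusted", "selected")]), digits = 4)
  cat("Selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Link enumeration areas to their nearest grain sample
#'
#' Joins each enumeration-area record to the great-circle-nearest grain
#' sample (regardless of crop) and records the linkage distance in km.
#' The median linkage distance is stored in attribute
#' `"median_distance_km"`.
#'
#' @param ea_table Enumeration areas (`lon`, `lat`, ...).
#' @param grain_table Grain survey (`lon`, `lat`, ...); columns other than
#'   coordinates are carried over with a `grain_` prefix.
#' @return `ea_table` plus `nearest_site_id`, `distance_km` and prefixed
#'   grain columns.
#' @export
nearest_grain_link <- function(ea_table, grain_table) {
  if (nrow(ea_table) == 0 || nrow(grain_table) == 0) {
    abort("Both tables must be non-empty.")
  }
  D <- gc_distance_km(ea_table, grain_table)
  j <- max.col(-D, ties.method = "first")
  ids <- if ("site_id" %in% names(grain_table)) grain_table$site_id else
    as.character(seq_len(nrow(grain_table)))
  carry <- grain_table[j, setdiff(names(grain_table), c("lon", "lat", "site_id")),
                       drop = FALSE]
  names(carry) <- paste0("grain_", names(carry))
  out <- dplyr::bind_cols(
    ea_table,
    tibble::tibble(nearest_site_id = ids[j],
                   distance_km = D[cbind(seq_len(nrow(ea_table)), j)]),
    carry)
  set_attrs(out, median_distance_km = median(out$distance_km))
}
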