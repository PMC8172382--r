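# Synthetic surveys with known ground truth. The generators mirror the
# statistical structure the analysis assumes: a stationary Gaussian (or
# log-Gaussian) concentration field with nugget + exponential covariance on
# great-circle distances; coverage sampling with close pairs; covariates
# linearly linked to the response over a Matern-correlated residual field;
# and enumeration-area biomarker means regressed on the nearest grain
# sample. Every generator is deterministic given its seed.

#' Specification of a stationary random concentration field
#'
#' @param mean Field mean on the analysis (Gaussian) scale.
#' @param model A [variogram_model()] giving nugget `c0`, partial sill `c`
#'   and distance parameter `a` (km) of the exponential covariance
#'   `C(h) = c exp(-h/a)` (plus `c0` at h = 0).
#' @param log_scale If `TRUE` the Gaussian field lives on the log_e scale
#'   and simulated concentrations are its exponential.
#' @param seed Integer seed; the same seed always reproduces the same draw.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(mean = 0, model, log_scale = FALSE, seed = 1L) {
  stopifnot(inherits(model, "variogram_model"))
  structure(list(mean = mean, model = model, log_scale = isTRUE(log_scale),
                 seed = as.integer(seed)),
            class = "field_spec")
}

#' Simulate a Gaussian random field at given locations
#'
#' Draws one realisation of a multivariate normal with constant mean and
#' covariance `C(h) = (c0 + c)` at `h = 0`, `c exp(-h/a)` for `h > 0`
#' (great-circle `h`; the exponential family is positive definite on the
#' sphere). Dense Cholesky factorisation with an additive diagonal jitter
#' of `1e-10 (c0 + c)` is used. With `log_scale = TRUE` the exponential of
#' the draw is returned.
#'
#' @param locations Data frame with `lon`, `lat`.
#' @param spec A [field_spec()].
#' @return Numeric vector of simulated values, one per location.
#' @export
simulate_gaussian_field <- function(locations, spec) {
  stopifnot(inherits(spec, "field_spec"))
  n <- nrow(as_lonlat_matrix(locations))
  c0 <- spec$model$nugget; cc <- spec$model$psill; a <- spec$model$range_par
  vals <- withr::with_seed(spec$seed, {
    if (cc == 0) {
      spec$mean + sqrt(c0) * rnorm(n)
    } else {
      D <- gc_distance_km(locations)
      if (c0 == 0 && any(D[upper.tri(D)] == 0)) {
        abort("Duplicate locations require a positive nugget (c0 > 0).")
      }
      C <- cc * exp(-D / a)
      diag(C) <- c0 + cc + 1e-10 * (c0 + cc)
      U <- tryCatch(chol(C), error = function(e)
        abort("Covariance matrix not positive definite after jitter; check model parameters."))
      spec$mean + drop(crossprod(U, rnorm(n)))
    }
  })
  if (spec$log_scale) exp(vals) else vals
}

# draw a zero-mean Matern-correlated effect (used inside seeded contexts)
simulate_matern_effect <- function(locations, sigma2, phi, nu) {
  n <- nrow(as_lonlat_matrix(locations))
  if (sigma2 == 0) return(rep(0, n))
  D <- gc_distance_km(locations)
  C <- sigma2 * matern_matrix(D, phi, nu)
  diag(C) <- diag(C) + 1e-10 * sigma2
  U <- tryCatch(chol(C), error = function(e)
    abort("Matern covariance not positive definite after jitter."))
  drop(crossprod(U, rnorm(n)))
}

#' Survey sampling design: coverage sampling with close pairs
#'
#' `n_main` sites spread over the frame by compact-strata coverage sampling
#' (k-means strata of a dense uniform point set; stratum centroids become
#' sites), plus `n_close_pairs` extra sites each placed at a great-circle
#' distance within `[pair_min_m, pair_max_m]` of a distinct, randomly
#' chosen main site. Close pairs (default 100-1,000 m) support estimation
#' of short-range variogram structure that spread sites alone cannot see.
#'
#' @param frame Sampling frame polygon: matrix/data frame of (lon, lat)
#'   vertices or list of rings.
#' @param n_main Number of main (coverage) sites.
#' @param n_close_pairs Number of close-pair sites (`<= n_main`).
#' @param pair_min_m,pair_max_m Close-pair distance bounds, metres.
#' @param seed Integer seed.
#' @return An object of class `survey_design`.
#' @export
survey_design <- function(frame, n_main, n_close_pairs = 0,
                          pair_min_m = 100, pair_max_m = 1000, seed = 1L) {
  rings <- as_polygon_rings(frame)
  if (n_close_pairs > n_main) abort("n_close_pairs must be <= n_main.")
  if (!(pair_min_m > 0 && pair_min_m < pair_max_m)) {
    abort("Require 0 < pair_min_m < pair_max_m.")
  }
  structure(list(frame = rings, n_main = as.integer(n_main),
                 n_close_pairs = as.integer(n_close_pairs),
                 pair_min_m = pair_min_m, pair_max_m = pair_max_m,
                 seed = as.integer(seed)),
            class = "survey_design")
}

#' Generate survey site locations for a design
#'
#' @param design A [survey_design()].
#' @return Tibble: `site_id`, `role` (`"main"`/`"close_pair"`), `lon`,
#'   `lat`, `parent_id` (`NA` for main sites).
#' @export
generate_survey_locations <- function(design) {
  stopifnot(inherits(design, "survey_design"))
  rings <- design$frame
  outer <- rings[[1]]
  diag_m <- great_circle_distance(c(min(outer[, 1]), min(outer[, 2])),
                                  c(max(outer[, 1]), max(outer[, 2])))
  if (design$n_close_pairs > 0 && diag_m < design$pair_min_m) {
    abort("Frame too small to hold a close pair at pair_min_m.")
  }
  withr::with_seed(design$seed, {
    cand <- runif_in_polygon(max(5000L, 30L * design$n_main), rings)
    km <- stats::kmeans(cand, centers = design$n_main, iter.max = 100,
                        nstart = 1)
    ctr <- km$centers
    ok <- point_in_polygon(ctr, rings)
    for (i in which(!ok)) {
      members <- which(km$cluster == i)
      d2 <- (cand[members, 1] - ctr[i, 1])^2 + (cand[members, 2] - ctr[i, 2])^2
      ctr[i, ] <- cand[members[which.min(d2)], ]
    }
    main <- tibble::tibble(
      site_id = sprintf("M%04d", seq_len(design$n_main)),
      role = "main", lon = as.numeric(ctr[, 1]), lat = as.numeric(ctr[, 2]),
      parent_id = NA_character_)
    if (design$n_close_pairs > 0) {
      parents <- sample.int(design$n_main, design$n_close_pairs)
      cp <- purrr::map_dfr(seq_along(parents), function(k) {
        p <- c(main$lon[parents[k]], main$lat[parents[k]])
        for (try in 1:200) {
          b <- runif(1, 0, 360)
          d <- runif(1, design$pair_min_m, design$pair_max_m)
          q <- geosphere::destPoint(p, b, d)
          if (point_in_polygon(matrix(q, ncol = 2), rings)) {
            return(tibble::tibble(site_id = sprintf("C%04d", k),
                                  role = "close_pair", lon = q[1], lat = q[2],
                                  parent_id = main$site_id[parents[k]]))
          }
        }
        abort("Could not place a close pair inside the frame; frame too small or thin.")
      })
      main <- dplyr::bind_rows(main, cp)
    }
    main
  })
}

# uniform points inside a polygon by rejection from the bounding box
runif_in_polygon <- function(n, rings) {
  outer <- rings[[1]]
  bb <- c(range(outer[, 1]), range(outer[, 2]))
  got <- matrix(numeric(0), ncol = 2)
  while (nrow(got) < n) {
    m <- ceiling(1.5 * (n - nrow(got)) + 10)
    pts <- cbind(runif(m, bb[1], bb[2]), runif(m, bb[3], bb[4]))
    got <- rbind(got, pts[point_in_polygon(pts, rings), , drop = FALSE])
  }
  got[seq_len(n), , drop = FALSE]
}

#' Generate a survey with covariates linked to the response
#'
#' Covariates are drawn as independent Gaussian fields (one
#' [variogram_model()] each); the response is
#' `X beta + u + eps`, with `u` a zero-mean Matern-correlated spatial
#' effect (`sigma_s^2`, `matern_phi`, `matern_nu`) and `eps` iid
#' `N(0, noise_sd^2)`. The generating truth is stored in attribute
#' `"truth"` so downstream fits can be checked by parameter recovery.
#'
#' @param design A [survey_design()].
#' @param beta Coefficients: intercept followed by one slope per covariate.
#' @param covariate_models List of [variogram_model()]s, one per covariate
#'   (names become column names; default `x1`, `x2`, ...).
#' @param sigma_s Spatial effect standard deviation.
#' @param matern_phi,matern_nu Matern parameters of the spatial effect
#'   (km; smoothness).
#' @param noise_sd Independent noise standard deviation.
#' @param seed Integer seed (fields and noise; site placement uses the
#'   design's own seed).
#' @return Tibble: site columns plus covariates and `value`;
#'   attribute `"truth"`.
#' @export
generate_covariate_survey <- function(design, beta, covariate_models,
                                      sigma_s, matern_phi, matern_nu = 0.5,
                                      noise_sd = 0, seed = 1L) {
  k <- length(covariate_models)
  if (length(beta) != k + 1) {
    abort("length(beta) must equal number of covariates + 1 (intercept).")
  }
  sites <- generate_survey_locations(design)
  nm <- names(covariate_models) %||% paste0("x", seq_len(k))
  nm[nm == ""] <- paste0("x", which(nm == ""))
  out <- withr::with_seed(seed, {
    X <- vapply(seq_len(k), function(j) {
      simulate_matern_field_from_model(sites, covariate_models[[j]])
    }, numeric(nrow(sites)))
    u <- simulate_matern_effect(sites, sigma_s^2, matern_phi, matern_nu)
    eps <- if (noise_sd > 0) rnorm(nrow(sites), 0, noise_sd) else 0
    resp <- beta[1] + as.vector(X %*% beta[-1]) + u + eps
    cov_tbl <- tibble::as_tibble(as.data.frame(X))
    names(cov_tbl) <- nm
    dplyr::bind_cols(sites, cov_tbl, tibble::tibble(value = resp))
  })
  set_attrs(out, truth = list(beta = beta, sigma_s = sigma_s,
                              matern_phi = matern_phi, matern_nu = matern_nu,
                              noise_sd = noise_sd,
                              covariate_models = covariate_models))
}

# draw a zero-mean field with exponential nugget covariance from a
# variogram model (inside a seeded context)
simulate_matern_field_from_model <- function(locations, model) {
  n <- nrow(locations)
  if (model$psill == 0) return(sqrt(model$nugget) * rnorm(n))
  D <- gc_distance_km(locations)
  C <- model$psill * exp(-D / model$range_par)
  diag(C) <- model$nugget + model$psill + 1e-10 * (model$nugget + model$psill)
  drop(crossprod(chol(C), rnorm(n)))
}

#' Generate an enumeration-area biomarker survey
#'
#' Places `n_ea` enumeration-area centroids uniformly in the frame, links
#' each to its great-circle-nearest grain sample, and draws
#' `log_biomarker = beta0 + beta1 * grain_value + u + eps`, with `u` a
#' Matern-correlated spatial effect and `eps` iid `N(0, sigma_n^2)`.
#'
#' @param grain_table Grain survey (`lon`, `lat`, `value` on the analysis
#'   scale, optionally `site_id`).
#' @param n_ea Number of enumeration areas (>= 3).
#' @param beta0,beta1 Intercept and slope of the biomarker regression on
#'   nearest-grain concentration.
#' @param matern_phi,matern_nu Matern parameters of the spatial effect.
#' @param sigma_s,sigma_n Spatial and independent standard deviations.
#' @param seed Integer seed.
#' @param frame Optional polygon for centroid placement; default is the
#'   bounding box of `grain_table`.
#' @return Tibble: `ea_id`, `lon`, `lat`, `log_biomarker`,
#'   `nearest_site_id`, `distance_m`, `grain_value`; attribute `"truth"`.
#' @export
generate_biomarker_survey <- function(grain_table, n_ea, beta0, beta1,
                                      matern_phi, matern_nu = 0.5,
                                      sigma_s = 0.1, sigma_n = 0.1,
                                      seed = 1L, frame = NULL) {
  if (nrow(grain_table) == 0) abort("grain_table is empty.")
  if (n_ea < 3) abort("n_ea must be at least 3 for any downstream model fit.")
  if (is.null(frame)) {
    frame <- cbind(
      c(min(grain_table$lon), max(grain_table$lon), max(grain_table$lon),
        min(grain_table$lon)),
      c(min(grain_table$lat), min(grain_table$lat), max(grain_table$lat),
        max(grain_table$lat)))
  }
  rings <- as_polygon_rings(frame)
  withr::with_seed(seed, {
    ctr <- runif_in_polygon(n_ea, rings)
    eas <- tibble::tibble(ea_id = sprintf("EA%04d", seq_len(n_ea)),
                          lon = ctr[, 1], lat = ctr[, 2])
    D <- gc_distance_km(eas, grain_table)
    j <- max.col(-D, ties.method = "first")
    ids <- if ("site_id" %in% names(grain_table)) grain_table$site_id else
      as.character(seq_len(nrow(grain_table)))
    u <- simulate_matern_effect(eas, sigma_s^2, matern_phi, matern_nu)
    eps <- if (sigma_n > 0) rnorm(n_ea, 0, sigma_n) else 0
    gv <- grain_table$value[j]
    out <- dplyr::mutate(eas,
      nearest_site_id = ids[j],
      distance_m = D[cbind(seq_len(n_ea), j)] * 1000,
      grain_value = gv,
      log_biomarker = beta0 + beta1 * gv + u + eps)
    set_attrs(out, truth = list(beta0 = beta0, beta1 = beta1,
                                matern_phi = matern_phi,
                                matern_nu = matern_nu,
                                sigma_s = sigma_s, sigma_n = sigma_n))
  })
}

#' A rectangular lon/lat sampling frame
#'
#' Convenience constructor for a rectangular frame of a given size (km)
#' anchored at a lower-left corner in the mid-latitude band (|lat| <= 40
#' degrees, avoiding strong metric distortion).
#'
#' @param width_km,height_km Frame extent, km.
#' @param lon0,lat0 Lower-left corner, decimal degrees.
#' @return A 4 x 2 matrix of (lon, lat) vertices.
#' @export
square_frame <- function(width_km = 300, height_km = width_km,
                         lon0 = 34, lat0 = -14) {
  if (abs(lat0) > 40) abort("Anchor the frame in the |lat| <= 40 band.")
  km_per_deg <- pi * 6378.137 / 180
  dlat <- height_km / km_per_deg
  dlon <- width_km / (km_per_deg * cos((lat0 + dlat / 2) * pi / 180))
  cbind(c(lon0, lon0 + dlon, lon0 + dlon, lon0),
        c(lat0, lat0, lat0 + dlat, lat0 + dlat))
}

#' Write the generating truth of a synthetic table to YAML
#'
#' @param table A generator output carrying a `"truth"` attribute.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(table, path) {
  tr <- attr(table, "truth")
  if (is.null(tr)) abort("Table carries no 'truth' attribute.")
  tr <- purrr::map(tr, function(x) {
    if (inherits(x, "variogram_model")) unclass(x) else
      if (is.list(x)) purrr::map(x, unclass) else x
  })
  yaml::write_yaml(tr, path)
  invisible(path)
}
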