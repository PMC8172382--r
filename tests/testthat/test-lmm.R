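test_that("with no spatial structure the spatial LMM reduces to ordinary least squares", {
  set.seed(171)
  n <- 120
  d <- tibble::tibble(lon = 34 + runif(n), lat = -14 + runif(n),
                      x = rnorm(n))
  d$y <- 1.5 + 2 * d$x + rnorm(n, sd = 0.5)
  fit <- fit_spatial_lmm(d, y ~ x, method = "ML", nu = 0.5, n_starts = 2)
  ols <- lm(y ~ x, data = d)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-3)
  # nearly all variance assigned to the nugget component
  expect_lt(fit$sigma2_s / (fit$sigma2_s + fit$sigma2_n), 0.2)
})

test_that("ML log-likelihood equals the hand-computed multivariate normal density", {
  # 5-point toy with nu = 1/2 and no nugget: covariance is exactly the
  # exponential covariance used by the field simulator
  d <- tibble::tibble(lon = c(34, 34.2, 34.5, 34.9, 35.4),
                      lat = c(-14, -13.8, -14.1, -13.7, -14.2),
                      y = c(0.3, -0.5, 1.1, 0.2, -0.9))
  X <- cbind(1, c(1, 2, 3, 4, 5))
  tau <- 0.95; phi <- 20
  z <- c(qlogis(tau), log(phi))
  D <- gc_distance_km(d)
  prof <- geograin:::lmm_profile_loglik(z, D, X, d$y, nu = 0.5, method = "ML")
  # independent hand computation of the profiled MVN log-density
  W <- tau * exp(-D / phi); diag(W) <- 1 + 1e-10
  V <- prof$sigma2 * W
  r <- d$y - X %*% prof$beta
  ll_hand <- -0.5 * (5 * log(2 * pi) + determinant(V)$modulus[1] +
                       t(r) %*% solve(V, r))
  expect_equal(prof$loglik, as.numeric(ll_hand), tolerance = 1e-6)
})

test_that("REML log-likelihood is invariant to shifting the response by a constant", {
  survey <- sim_survey(n_main = 60, n_close = 0, seed = 181)
  bio <- generate_biomarker_survey(survey, n_ea = 60, beta0 = 4, beta1 = 0.1,
                                   matern_phi = 25, sigma_s = 0.15,
                                   sigma_n = 0.1, seed = 182)
  f1 <- fit_spatial_lmm(bio, log_biomarker ~ grain_value, nu = 0.5,
                        n_starts = 1)
  shifted <- dplyr::mutate(bio, log_biomarker = log_biomarker + 10)
  f2 <- fit_spatial_lmm(shifted, log_biomarker ~ grain_value, nu = 0.5,
                        n_starts = 1)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(unname(f2$beta["(Intercept)"] - f1$beta["(Intercept)"]), 10,
               tolerance = 1e-4)
})

test_that("doubling the response doubles effects and SEs, quadruples variances, keeps tests unchanged", {
  survey <- sim_survey(n_main = 60, n_close = 0, seed = 191)
  bio <- generate_biomarker_survey(survey, n_ea = 80, beta0 = 4, beta1 = 0.1,
                                   matern_phi = 25, sigma_s = 0.15,
                                   sigma_n = 0.1, seed = 192)
  doubled <- dplyr::mutate(bio, log_biomarker = 2 * log_biomarker)
  fits <- purrr::map(list(bio, doubled), function(dd) {
    full <- fit_spatial_lmm(dd, log_biomarker ~ grain_value, method = "ML",
                            nu = 0.5, n_starts = 1)
    null <- fit_spatial_lmm(dd, log_biomarker ~ 1, method = "ML",
                            nu = 0.5, n_starts = 1)
    list(full = full, lrt = lrt_fixed_effect(full, null))
  })
  expect_equal(unname(fits[[2]]$full$beta), 2 * unname(fits[[1]]$full$beta),
               tolerance = 1e-3)
  expect_equal(unname(fits[[2]]$full$beta_se),
               2 * unname(fits[[1]]$full$beta_se), tolerance = 1e-3)
  expect_equal(fits[[2]]$full$sigma2_s + fits[[2]]$full$sigma2_n,
               4 * (fits[[1]]$full$sigma2_s + fits[[1]]$full$sigma2_n),
               tolerance = 1e-3)
  expect_equal(fits[[2]]$lrt$p.value, fits[[1]]$lrt$p.value, tolerance = 1e-4)
})

test_that("likelihood-ratio test guards and chi-square tail arithmetic", {
  survey <- sim_survey(n_main = 40, n_close = 0, seed = 201)
  bio <- generate_biomarker_survey(survey, n_ea = 40, beta0 = 4, beta1 = 0.1,
                                   matern_phi = 25, seed = 202)
  reml <- fit_spatial_lmm(bio, log_biomarker ~ grain_value, nu = 0.5,
                          n_starts = 1)
  expect_error(lrt_fixed_effect(reml, reml), "ML")
  ml <- fit_spatial_lmm(bio, log_biomarker ~ grain_value, method = "ML",
                        nu = 0.5, n_starts = 1)
  same <- lrt_fixed_effect(ml, ml)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
})

test_that("printed likelihood-ratio statistics give the published tail probabilities", {
  # single-df chi-square upper tails at 2 significant figures
  expect_equal(signif(pchisq(14.48, df = 1, lower.tail = FALSE), 2), 1.4e-4)
  expect_equal(signif(pchisq(11.56, df = 1, lower.tail = FALSE), 2), 6.7e-4)
})

test_that("slope recovery: covariate-survey fits cover the true slopes", {
  des <- survey_design(square_frame(250), n_main = 200, seed = 211)
  cov_models <- list(x1 = variogram_model(0.2, 0.8, 40),
                     x2 = variogram_model(1, 0, 1))
  beta <- c(1, 0.5, -0.3)
  hits <- sapply(1:10, function(s) {
    tb <- generate_covariate_survey(des, beta = beta, cov_models,
                                    sigma_s = 0.3, matern_phi = 30,
                                    noise_sd = 0.2, seed = 400 + s)
    fit <- fit_spatial_lmm(tb, value ~ x1 + x2, nu = 0.5, n_starts = 1)
    all(abs(fit$beta[2:3] - beta[2:3]) <= 2 * fit$beta_se[2:3])
  })
  expect_gte(mean(hits), 0.8)
})

test_that("BH step-up matches the brute-force textbook definition", {
  # worked example: all three rejected since p_(3) = 0.04 <= 3 * 0.05 / 3
  p <- c(0.01, 0.02, 0.04)
  expect_identical(brute_bh_reject(p, 0.05), rep(TRUE, 3))
  expect_identical(unname(p.adjust(p, "BH") <= 0.05), rep(TRUE, 3))
  set.seed(221)
  for (i in 1:50) {
    m <- sample(3:12, 1)
    p <- round(runif(m), 3)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(unname(p.adjust(p, "BH") <= q), brute_bh_reject(p, q))
  }
})

test_that("forward selection keeps a strong predictor and controls false selection under the null", {
  des <- survey_design(square_frame(200), n_main = 100, seed = 231)
  cov_models <- list(x1 = variogram_model(1, 0, 1),
                     x2 = variogram_model(1, 0, 1),
                     x3 = variogram_model(1, 0, 1))
  # strong effect on x1 only
  strong <- sapply(1:5, function(s) {
    tb <- generate_covariate_survey(des, beta = c(0, 1, 0, 0), cov_models,
                                    sigma_s = 0.2, matern_phi = 20,
                                    noise_sd = 0.3, seed = 500 + s)
    sel <- forward_select_with_fdr(tb, "value", c("x1", "x2", "x3"),
                                   nu = 0.5, n_starts = 1)
    "x1" %in% sel$selected
  })
  expect_true(all(strong))
  # global null: selections should be rare
  null_sel <- sapply(1:10, function(s) {
    tb <- generate_covariate_survey(des, beta = c(0, 0, 0, 0), cov_models,
                                    sigma_s = 0.2, matern_phi = 20,
                                    noise_sd = 0.3, seed = 600 + s)
    sel <- forward_select_with_fdr(tb, "value", c("x1", "x2", "x3"),
                                   nu = 0.5, n_starts = 1)
    length(sel$selected)
  })
  expect_lte(sum(null_sel) / (10 * 3), 0.1)
})

test_that("nearest-grain linkage matches the exhaustive scan and handles edge cases", {
  survey <- sim_survey(n_main = 50, n_close = 0, seed = 241)
  set.seed(242)
  eas <- tibble::tibble(ea_id = sprintf("E%02d", 1:30),
                        lon = 34 + runif(30, 0, 2.5),
                        lat = -14 + runif(30, 0, 2.5))
  linked <- nearest_grain_link(eas, survey)
  oracle <- brute_nearest(eas, survey)
  expect_identical(linked$nearest_site_id, survey$site_id[oracle])
  expect_equal(attr(linked, "median_distance_km"),
               median(linked$distance_km))
  # single grain site: everything links to it
  one <- survey[3, ]
  l1 <- nearest_grain_link(eas, one)
  expect_true(all(l1$nearest_site_id == one$site_id))
  # co-located enumeration area: zero distance
  co <- tibble::tibble(ea_id = "E00", lon = survey$lon[1], lat = survey$lat[1])
  expect_equal(nearest_grain_link(co, survey)$distance_km, 0)
})

test_that("tidiers return broom-shaped tibbles", {
  survey <- sim_survey(n_main = 40, n_close = 0, seed = 251)
  bio <- generate_biomarker_survey(survey, n_ea = 40, beta0 = 4, beta1 = 0.1,
                                   matern_phi = 25, seed = 252)
  fit <- fit_spatial_lmm(bio, log_biomarker ~ grain_value, nu = 0.5,
                         n_starts = 1)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic"))
  expect_identical(nrow(td), 2L)
  gl <- glance(fit)
  expect_identical(gl$method, "REML")
  emp <- empirical_variogram(survey, max_lag_km = 100, bin_width_km = 10)
  vm <- fit_exponential_wls(emp)
  expect_named(tidy(vm), c("term", "estimate"))
  expect_identical(glance(vm)$estimator, "matheron")
  cv <- cross_validate(survey, vm)
  expect_identical(nrow(tidy(cv)), nrow(survey))
  expect_true(glance(cv)$verdict %in% c("consistent", "inconsistent"))
})
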