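test_that("kriging weights sum to 1 and reproduce data exactly with zero nugget", {
  survey <- sim_survey(n_main = 60, n_close = 0, nugget = 0, psill = 1,
                       range_km = 40, seed = 61)
  m <- variogram_model(0, 1, 40)
  targets <- bbox_grid(survey, 40)
  res <- ordinary_krige(survey, m, targets)
  for (w in res$weights) expect_lt(abs(sum(w) - 1), 1e-8)
  # at a datum: exact interpolation, zero variance
  at_datum <- ordinary_krige(survey, m, c(survey$lon[5], survey$lat[5]))
  expect_equal(at_datum$prediction, survey$value[5], tolerance = 1e-8)
  expect_lt(at_datum$variance, 1e-8)
})

test_that("three points under a pure-nugget model: simple mean and closed-form variance", {
  data <- tibble::tibble(lon = c(34, 34.3, 34.6), lat = c(-14, -14, -14),
                         value = c(1, 3, 8))
  m <- variogram_model(0.6, 0, 1)
  res <- ordinary_krige(data, m, c(34.3, -13.5))
  expect_equal(res$weights[[1]], rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(res$prediction, mean(data$value), tolerance = 1e-10)
  expect_equal(res$variance, 0.6 * (1 + 1 / 3), tolerance = 1e-10)
  expect_equal(res$lagrange, 0.6 / 3, tolerance = 1e-10)
})

test_that("kriging variance is independent of the observed values", {
  survey <- sim_survey(n_main = 70, n_close = 10, seed = 71)
  m <- variogram_model(0.2, 0.8, 30)
  grid <- bbox_grid(survey, 50)
  v1 <- krige_grid(survey, m, grid)$variance
  set.seed(99)
  permuted <- dplyr::mutate(survey, value = sample(value))
  v2 <- krige_grid(permuted, m, grid)$variance
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("duplicate sites with zero nugget are reported as singular", {
  data <- tibble::tibble(site_id = c("a", "b", "c"),
                         lon = c(34, 34, 35), lat = c(-14, -14, -14),
                         value = 1:3)
  expect_error(ordinary_krige(data, variogram_model(0, 1, 10), c(34.5, -14)),
               "duplicate locations")
})

test_that("nearest-n neighbourhood kriging approximates global kriging", {
  survey <- sim_survey(n_main = 90, n_close = 10, seed = 81)
  m <- variogram_model(0.2, 0.8, 30)
  tgt <- c(mean(survey$lon), mean(survey$lat))
  g_all <- ordinary_krige(survey, m, tgt)
  g_nn <- ordinary_krige(survey, m, tgt, neighborhood = 64)
  expect_lt(abs(sum(g_nn$weights[[1]]) - 1), 1e-8)
  expect_equal(g_nn$prediction, g_all$prediction, tolerance = 0.05)
})

test_that("fast leave-one-out cross-validation equals brute-force refitting", {
  survey <- sim_survey(n_main = 50, n_close = 10, seed = 91)
  m <- variogram_model(0.2, 0.8, 30)
  fast <- cross_validate(survey, m, method = "fast")
  brute <- cross_validate(survey, m, method = "brute")
  expect_equal(fast$sites$predicted, brute$sites$predicted, tolerance = 1e-8)
  expect_equal(fast$sites$kriging_variance, brute$sites$kriging_variance,
               tolerance = 1e-8)
  expect_equal(fast$median_sspe, brute$median_sspe, tolerance = 1e-8)
})

test_that("SSPE of one site equals 1 when the error equals the kriging standard error", {
  survey <- sim_survey(n_main = 40, n_close = 0, seed = 95)
  m <- variogram_model(0.2, 0.8, 30)
  cv <- cross_validate(survey, m)
  i <- 7
  se <- sqrt(cv$sites$kriging_variance[i])
  modified <- survey
  modified$value[i] <- cv$sites$predicted[i] + se
  # prediction of site i from the others is unchanged by changing z_i
  cv2 <- cross_validate(modified, m)
  expect_equal(cv2$sites$sspe[i], 1, tolerance = 1e-6)
})

test_that("an inflated sill halves the median SSPE below the null interval", {
  survey <- sim_survey(n_main = 250, n_close = 50, seed = 101)
  good <- variogram_model(0.2, 0.8, 30)
  inflated <- variogram_model(0.4, 1.6, 30)
  cv_g <- cross_validate(survey, good)
  cv_i <- cross_validate(survey, inflated)
  expect_equal(cv_i$median_sspe, cv_g$median_sspe / 2, tolerance = 1e-6)
  expect_lt(cv_i$median_sspe, cv_i$interval[1])
  expect_identical(cv_i$verdict, "inconsistent")
})

test_that("model selection returns the Matheron fit when it validates, else the robust fit closest to 0.455", {
  survey <- sim_survey(n_main = 200, n_close = 40, seed = 111)
  good <- variogram_model(0.2, 0.8, 30)
  good_cv <- cross_validate(survey, good)
  expect_identical(good_cv$verdict, "consistent")
  sel <- select_model(survey, list(matheron = good,
                                   dowd = variogram_model(0.4, 1.6, 30)))
  expect_identical(sel$estimator, "matheron")
  expect_length(sel$reports, 1L)   # robust fits untouched

  # force the Matheron candidate to fail: the closest-to-0.455 robust wins
  bad <- variogram_model(0.8, 3.2, 30)       # sill x4: median SSPE ~ 0.455/4
  near <- variogram_model(0.21, 0.84, 30)    # ~5% inflated: close to valid
  far <- variogram_model(0.5, 2.0, 30)
  sel2 <- suppressWarnings(
    select_model(survey, list(matheron = bad, dowd = near,
                              cressie_hawkins = far)))
  expect_identical(sel2$estimator, "dowd")
})

test_that("outlier contamination steers selection to a robust estimator in most seeds", {
  picks <- sapply(1:8, function(s) {
    survey <- sim_survey(n_main = 150, n_close = 30, seed = 120 + s)
    contaminated <- survey
    set.seed(s)
    bad <- sample(nrow(survey), ceiling(0.05 * nrow(survey)))
    contaminated$value[bad] <- contaminated$value[bad] * 10
    fits <- purrr::map(
      purrr::set_names(c("matheron", "cressie_hawkins", "dowd")),
      function(est) fit_exponential_wls(
        empirical_variogram(contaminated, max_lag_km = 100, bin_width_km = 10,
                            estimator = est)))
    sel <- suppressWarnings(select_model(contaminated, fits))
    sel$estimator
  })
  expect_gt(mean(picks != "matheron"), 0.5)
})

test_that("grid kriging back-transforms log-scale predictions median-unbiasedly", {
  # constant samples predict the constant everywhere
  const <- tibble::tibble(lon = 34 + runif(30), lat = -14 + runif(30),
                          value = 2.5)
  kg <- krige_grid(const, variogram_model(0.3, 0.2, 20),
                   bbox_grid(const, 30), scale = "original")
  expect_equal(kg$prediction, rep(2.5, nrow(kg)), tolerance = 1e-8)
  expect_true(all(kg$variance > 0))
  # log-scale: prediction 0 on the log scale back-transforms to 1
  two <- tibble::tibble(lon = c(34, 35), lat = c(-14, -14), value = c(1, 1))
  kg2 <- krige_grid(two, variogram_model(0.1, 0.1, 20),
                    tibble::tibble(lon = 34.5, lat = -14), scale = "log_e")
  expect_equal(kg2$prediction, exp(1))  # log-prediction is 1 here
  lg <- krige_grid(dplyr::mutate(two, value = 0),
                   variogram_model(0.1, 0.1, 20),
                   tibble::tibble(lon = 34.5, lat = -14), scale = "log_e")
  expect_equal(lg$prediction, 1)

  # median-unbiasedness on a log-normal field at held-out sites
  all_sites <- sim_survey(n_main = 600, n_close = 0, nugget = 0.1,
                          psill = 0.4, range_km = 40, mean = 1,
                          seed = 131, log_scale = TRUE)
  hold <- 501:600
  train <- all_sites[-hold, ]
  train$z <- log(train$value)
  emp <- empirical_variogram(train, value = z, max_lag_km = 100,
                             bin_width_km = 10)
  fit <- fit_exponential_wls(emp)
  kg3 <- krige_grid(train, fit, all_sites[hold, ], value = z,
                    scale = "log_e")
  ratio <- median(kg3$prediction) / median(all_sites$value[hold])
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)
})

test_that("variance masking uses a strict threshold at the stated fraction", {
  g <- tibble::tibble(lon = 1:4, lat = 1:4,
                      prediction = 0, variance = c(0.74, 0.75, 0.76, 1) * 2)
  gm <- variance_mask(g, data_variance = 2, fraction = 0.75)
  expect_identical(gm$masked, c(FALSE, FALSE, TRUE, TRUE))
  expect_error(variance_mask(g, 0), "positive")
})

test_that("sparsely sampled extrapolation areas are masked while data-dense areas are not", {
  # cluster all samples in the west half; predict over the whole frame
  survey <- sim_survey(n_main = 80, n_close = 10, frame_km = 150, seed = 141)
  m <- variogram_model(0.2, 0.8, 30)
  far_grid <- dplyr::mutate(bbox_grid(survey, 25), lon = lon + 4) # ~400 km east
  near_grid <- bbox_grid(survey, 25)
  kg <- variance_mask(
    krige_grid(survey, m, dplyr::bind_rows(near_grid, far_grid)),
    data_variance = var(survey$value))
  near_masked <- kg$masked[seq_len(nrow(near_grid))]
  far_masked <- kg$masked[-seq_len(nrow(near_grid))]
  expect_lt(mean(near_masked), 0.2)
  expect_equal(mean(far_masked), 1)
})

test_that("block kriging: a one-node block equals point kriging; constant fields krige to the constant", {
  survey <- sim_survey(n_main = 60, n_close = 10, seed = 151)
  m <- variogram_model(0.2, 0.8, 30)
  tiny <- square_frame(0.8, 0.8, lon0 = 35, lat0 = -13.5)
  bk <- block_krige(survey, m, tiny, spacing_km = 5)  # one interior node
  expect_identical(bk$n_nodes, 1L)
  nodes <- geograin:::discretize_polygon(tiny, 5)
  pk <- ordinary_krige(survey, m, c(nodes$lon[1], nodes$lat[1]))
  expect_equal(bk$prediction, pk$prediction, tolerance = 1e-6)
  expect_equal(bk$variance, pk$variance, tolerance = 1e-6)

  const <- dplyr::mutate(survey, value = 4.2)
  bkc <- block_krige(const, m, square_frame(40, 40, 34.5, -13.8),
                     spacing_km = 8)
  expect_equal(bkc$prediction, 4.2, tolerance = 1e-8)
})

test_that("block variance is below the centroid point variance and discretization converges", {
  survey <- sim_survey(n_main = 100, n_close = 20, seed = 161)
  m <- variogram_model(0.2, 0.8, 30)
  diffs <- ratio <- numeric(5)
  for (b in 1:5) {
    block <- square_frame(50, 50, lon0 = 34.2 + 0.3 * b, lat0 = -14 + 0.2 * b)
    bk1 <- block_krige(survey, m, block, spacing_km = 10)
    bk2 <- block_krige(survey, m, block, spacing_km = 5)
    centroid <- c(mean(block[, 1]), mean(block[, 2]))
    pk <- ordinary_krige(survey, m, centroid)
    ratio[b] <- bk2$variance / pk$variance
    diffs[b] <- abs(bk1$prediction - bk2$prediction) /
      max(abs(bk2$prediction), 1e-9)
  }
  expect_lt(mean(ratio), 1)          # averaging reduces prediction variance
  expect_true(all(diffs < 0.01))     # spacing s vs s/2: < 1% change
})

test_that("SSPE null interval is centred on the chi-square(1) median and shrinks with n", {
  expect_equal(sspe_expected_median(), qchisq(0.5, 1))
  i100 <- sspe_null_interval(100)
  i1000 <- sspe_null_interval(1000)
  expect_lt(i100[1], 0.455); expect_gt(i100[2], 0.455)
  expect_lt(diff(i1000), diff(i100))
})
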