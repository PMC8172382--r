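# Shared fixtures: everything is generated in code at test time.

# A simulated survey with known exponential variogram ground truth.
sim_survey <- function(n_main = 150, n_close = 30, nugget = 0.2, psill = 0.8,
                       range_km = 30, mean = 0, frame_km = 300, seed = 1,
                       log_scale = FALSE) {
  frame <- square_frame(frame_km)
  sites <- generate_survey_locations(
    survey_design(frame, n_main = n_main, n_close_pairs = n_close,
                  seed = seed))
  spec <- field_spec(mean = mean,
                     model = variogram_model(nugget, psill, range_km),
                     log_scale = log_scale, seed = seed + 1000L)
  sites$value <- simulate_gaussian_field(sites, spec)
  sites
}

# Brute-force Matheron variogram: explicit double loop over all pairs.
brute_matheron <- function(data, max_lag_km, bin_width_km) {
  n <- nrow(data)
  nbins <- as.integer(round(max_lag_km / bin_width_km))
  sums <- counts <- lag_sums <- numeric(nbins)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- great_circle_distance(c(data$lon[i], data$lat[i]),
                                 c(data$lon[j], data$lat[j])) / 1000
      if (d >= max_lag_km) next
      b <- floor(d / bin_width_km) + 1
      sums[b] <- sums[b] + (data$value[i] - data$value[j])^2
      counts[b] <- counts[b] + 1
      lag_sums[b] <- lag_sums[b] + d
    }
  }
  list(gamma = ifelse(counts > 0, sums / (2 * counts), NA_real_),
       npairs = counts,
       lag = ifelse(counts > 0, lag_sums / counts, NA_real_))
}

# Textbook Benjamini-Hochberg step-up by brute-force enumeration: find the
# largest i with p_(i) <= i q / m and reject all hypotheses with p <= p_(i).
brute_bh_reject <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[p <= ps[k]] <- TRUE
  rej
}

# Exhaustive nearest-neighbour scan.
brute_nearest <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    d <- vapply(seq_len(nrow(b)), function(j) {
      great_circle_distance(c(a$lon[i], a$lat[i]), c(b$lon[j], b$lat[j]))
    }, numeric(1))
    which.min(d)
  }, integer(1))
}
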