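options(mixrange.verbose = FALSE)

# Small survey used by several test files: coarse lattice, fast to krige.
small_design <- function(seed = 11) {
  survey_design(lon_min = 120, lon_max = 123, lat_min = 27, lat_max = 30,
                station_spacing = 0.5, seed = seed)
}

small_survey <- function(seed = 11) {
  generate_survey(small_design(seed))
}

# Independent dense ordinary-kriging solve used as oracle for <= 10
# stations; deliberately re-derived from the covariance equations rather
# than calling the package's solver.
ok_oracle <- function(lon, lat, z, model, plon, plat) {
  n <- length(z)
  cov_fun <- function(h) {
    total <- model$nugget + model$psill
    s <- switch(model$family,
      exponential = 1 - exp(-h / model$range),
      gaussian = 1 - exp(-(h / model$range)^2),
      spherical = ifelse(h >= model$range, 1,
                         1.5 * h / model$range - 0.5 * (h / model$range)^3))
    ifelse(h > 0, total - (model$nugget + model$psill * s), total)
  }
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      h <- sqrt((lon[i] - lon[j])^2 + (lat[i] - lat[j])^2)
      A[i, j] <- cov_fun(h)
    }
  }
  A[n + 1, 1:n] <- 1; A[1:n, n + 1] <- 1
  vapply(seq_along(plon), function(p) {
    b <- c(cov_fun(sqrt((lon - plon[p])^2 + (lat - plat[p])^2)), 1)
    w <- solve(A, b)
    sum(w[1:n] * z)
  }, numeric(1))
}
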