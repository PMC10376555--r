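make_stations <- function(n, seed, value_fun = function(lon, lat) 0) {
  set.seed(seed)
  lon <- runif(n, 120, 123)
  lat <- runif(n, 27, 30)
  data.frame(season = "spring", lon = lon, lat = lat,
             biomass = 1, temperature = value_fun(lon, lat),
             salinity = 34, depth = 50)
}

test_that("empirical semivariogram of a constant variable is zero", {
  st <- make_stations(30, 1)
  ev <- empirical_semivariogram(st, "temperature")
  expect_true(all(ev$gamma[ev$n_pairs > 0] == 0))
})

test_that("pair counts across bins respect the counting identity", {
  st <- make_stations(40, 2, function(lon, lat) lon + lat)
  n <- nrow(st)
  ev <- empirical_semivariogram(st, "temperature")
  expect_lte(sum(ev$n_pairs), n * (n - 1) / 2)
  d <- stats::dist(cbind(st$lon, st$lat))
  ev_full <- empirical_semivariogram(st, "temperature",
                                     max_dist = max(d) + 1e-9)
  expect_equal(sum(ev_full$n_pairs), n * (n - 1) / 2)
})

test_that("white noise has a flat semivariogram at its variance", {
  st <- expand.grid(lon = seq(120, 127, 0.5), lat = seq(26, 35, 0.5))
  st$season <- "spring"
  set.seed(123)
  st$temperature <- rnorm(nrow(st), sd = 2)  # variance 4
  ev <- empirical_semivariogram(st, "temperature")
  ok <- ev$n_pairs > 0
  expect_true(all(abs(ev$gamma[ok] - 4) / 4 < 0.25))
})

test_that("a noise-free spherical semivariogram is recovered exactly", {
  truth <- variogram_model("spherical", nugget = 0.3, psill = 2.1, range = 1.4)
  ev <- structure(list(dist = seq(0.1, 3, length.out = 12),
                       gamma = variogram_gamma(truth, seq(0.1, 3, length.out = 12)),
                       n_pairs = rep(50L, 12)),
                  class = "empirical_variogram")
  fit <- fit_variogram(ev, "spherical")
  expect_equal(fit$nugget, truth$nugget, tolerance = 1e-6)
  expect_equal(fit$psill, truth$psill, tolerance = 1e-6)
  expect_equal(fit$range, truth$range, tolerance = 1e-6)
})

test_that("an all-zero semivariogram yields the nugget-only model", {
  ev <- structure(list(dist = seq(0.1, 1.2, 0.1), gamma = rep(0, 12),
                       n_pairs = rep(10L, 12)),
                  class = "empirical_variogram")
  fit <- fit_variogram(ev)
  expect_equal(fit$nugget, 0)
  expect_equal(fit$psill, 0)
})

test_that("variogram models satisfy their shape invariants", {
  h <- seq(0, 10, 0.01)
  for (fam in c("exponential", "spherical", "gaussian")) {
    m <- variogram_model(fam, nugget = 0.5, psill = 2, range = 1.3)
    g <- variogram_gamma(m, h)
    expect_equal(g[1], m$nugget)
    expect_true(all(diff(g) >= -1e-12))
    expect_equal(g[length(g)], m$nugget + m$psill, tolerance = 1e-2)
  }
})

test_that("kriging a constant field predicts the constant everywhere", {
  st <- make_stations(20, 3, function(lon, lat) 7.5)
  m <- variogram_model("exponential", nugget = 0.1, psill = 1, range = 1)
  grid <- grid_spec(120.2, 27.2, 10, 10, 0.25)
  f <- krige_ordinary(st, "temperature", m, grid)
  expect_true(all(abs(f$values - 7.5) < 1e-8))
})

test_that("with zero nugget kriging interpolates the observations exactly", {
  st <- make_stations(15, 4, function(lon, lat) sin(lon) + cos(lat))
  m <- variogram_model("exponential", nugget = 0, psill = 2, range = 1)
  w <- mixrange:::kriging_weights(st, "temperature", m, st$lon, st$lat)
  pred <- as.vector(crossprod(w, st$temperature))
  expect_true(all(abs(pred - st$temperature) < 1e-8))
})

test_that("two stations give half weights at their midpoint", {
  st <- data.frame(season = "spring", lon = c(120, 121), lat = c(28, 28),
                   biomass = 1, temperature = c(3, 9), salinity = 34,
                   depth = 50)
  m <- variogram_model("spherical", nugget = 0.2, psill = 1, range = 2)
  w <- mixrange:::kriging_weights(st, "temperature", m, 120.5, 28)
  expect_equal(as.vector(w), c(0.5, 0.5), tolerance = 1e-10)
})

test_that("kriging weights sum to one at every prediction cell", {
  st <- make_stations(25, 5, function(lon, lat) lon * lat)
  m <- variogram_model("exponential", nugget = 0.3, psill = 1.5, range = 0.8)
  grid <- grid_spec(119.5, 26.5, 15, 12, 0.3)
  ctr <- grid_centers(grid)
  w <- mixrange:::kriging_weights(st, "temperature", m, ctr$lon, ctr$lat)
  expect_true(all(abs(colSums(w) - 1) < 1e-8))
})

test_that("kriging matches a brute-force dense solve for small n", {
  for (seed in 1:3) {
    st <- make_stations(8, seed, function(lon, lat) 2 * lon - lat^2)
    m <- variogram_model("exponential", nugget = 0.1, psill = 1, range = 0.9)
    grid <- grid_spec(120, 27, 6, 5, 0.5)
    f <- krige_ordinary(st, "temperature", m, grid)
    ctr <- grid_centers(grid)
    oracle <- ok_oracle(st$lon, st$lat, st$temperature, m, ctr$lon, ctr$lat)
    expect_true(all(abs(f$values - oracle) < 1e-10))
  }
})

test_that("duplicate station coordinates are averaged, not fatal", {
  st <- make_stations(10, 6, function(lon, lat) lon)
  dup <- st[1, ]; dup$temperature <- st$temperature[1] + 2
  st2 <- rbind(st, dup)
  m <- variogram_model("exponential", nugget = 0, psill = 1, range = 1)
  grid <- grid_spec(120, 27, 5, 5, 0.5)
  expect_silent(f <- krige_ordinary(st2, "temperature", m, grid))
  expect_true(all(is.finite(f$values)))
})

test_that("interpolation recovers a noise-free linear temperature field", {
  d <- small_design()
  fs <- field_spec(
    temperature = list(base = 18, lat_gradient = -0.8,
                       seasonal_offsets = c(spring = 1, summer = 8,
                                            autumn = 3, winter = -4),
                       noise_sd = 0, noise_corr_length = 0.5),
    salinity = list(background = 34, plumes = list(), noise_sd = 0,
                    noise_corr_length = 0.5),
    depth = list(nearshore = 20, offshore_gradient = 15, roughness_sd = 0,
                 noise_corr_length = 0.5))
  st <- generate_survey(d, field_spec = fs)
  cfg <- run_config(resolution = 0.1)
  fields <- interpolate_survey(st[st$season == "spring", ], "spring", cfg)
  ctr <- grid_centers(fields$temperature$grid)
  lat_ref <- (27 + 30) / 2
  truth <- 18 - 0.8 * (ctr$lat - lat_ref) + 1
  expect_true(all(abs(fields$temperature$values - truth) < 0.05))
  # all four fields share one grid, and reruns are identical
  expect_true(all(vapply(fields, function(f)
    identical(f$grid, fields$biomass$grid), logical(1))))
  fields2 <- interpolate_survey(st[st$season == "spring", ], "spring", cfg)
  expect_identical(fields[], fields2[])
})

test_that("predictions stay within the observation range plus 3 sill SDs", {
  st <- small_survey()
  cfg <- run_config(resolution = 0.15)
  fields <- interpolate_survey(st, "winter", cfg)
  models <- attr(fields, "variograms")
  for (v in c("temperature", "salinity", "depth")) {
    obs <- st[st$season == "winter", v]
    sill <- models[[v]]$nugget + models[[v]]$psill
    expect_true(all(fields[[v]]$values >= min(obs) - 3 * sqrt(sill)))
    expect_true(all(fields[[v]]$values <= max(obs) + 3 * sqrt(sill)))
  }
})
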