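#' Empirical semivariogram
#'
#' Method-of-moments estimator: for each distance bin,
#' `gamma_hat(h) = sum((z_i - z_j)^2) / (2 * N_bin)` over station pairs
#' whose separation falls in the bin. Distances are Euclidean in degrees
#' (planar convention used throughout the package).
#'
#' @param stations station table (one season).
#' @param variable column name to analyse.
#' @param n_bins number of distance bins (default 12).
#' @param max_dist largest lag considered; default half the maximum
#'   pairwise distance.
#' @return an object of class `empirical_variogram` with `dist` (bin
#'   centers), `gamma` (semivariance estimates) and `n_pairs`.
#' @export
empirical_semivariogram <- function(stations, variable, n_bins = 12,
                                    max_dist = NULL) {
  z <- stations[[variable]]
  if (is.null(z)) stop("no column '", variable, "' in station table")
  keep <- is.finite(z)
  z <- z[keep]
  lon <- stations$lon[keep]; lat <- stations$lat[keep]
  n <- length(z)
  if (n < 10) stop("need at least 10 stations with '", variable, "'")

  d <- as.vector(stats::dist(cbind(lon, lat)))
  dz2 <- as.vector(stats::dist(z))^2
  if (is.null(max_dist)) max_dist <- max(d) / 2
  brk <- seq(0, max_dist, length.out = n_bins + 1)
  bin <- findInterval(d, brk, left.open = TRUE, rightmost.closed = FALSE)
  sel <- bin >= 1 & bin <= n_bins & d > 0
  bin <- bin[sel]; dz2 <- dz2[sel]

  np <- tabulate(bin, nbins = n_bins)
  if (all(np < 2)) stop("fewer than 2 pairs in every distance bin")
  sums <- vapply(seq_len(n_bins),
                 function(b) sum(dz2[bin == b]), numeric(1))
  gamma <- ifelse(np > 0, sums / (2 * np), NA_real_)
  structure(list(dist = (brk[-1] + brk[-(n_bins + 1)]) / 2,
                 gamma = gamma, n_pairs = np, max_dist = max_dist,
                 variable = variable),
            class = "empirical_variogram")
}

#' Variogram model
#'
#' @param family "spherical", "exponential" or "gaussian".
#' @param nugget nugget variance (>= 0).
#' @param psill partial sill (>= 0); the total sill is `nugget + psill`.
#' @param range range parameter (> 0), degrees.
#' @return an object of class `variogram_model`.
#' @export
variogram_model <- function(family = c("exponential", "spherical", "gaussian"),
                            nugget, psill, range) {
  family <- match.arg(family)
  stopifnot(nugget >= 0, psill >= 0, range > 0)
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range),
            class = "variogram_model")
}

#' Evaluate a variogram model
#'
#' `gamma(0) = nugget` (strictly at zero lag), nondecreasing in h, and
#' `gamma(h) -> nugget + psill` as h grows.
#'
#' @param model a [variogram_model()].
#' @param h distances (>= 0).
#' @return semivariances.
#' @export
variogram_gamma <- function(model, h) {
  s <- switch(model$family,
    exponential = 1 - exp(-h / model$range),
    gaussian = 1 - exp(-(h / model$range)^2),
    spherical = ifelse(h >= model$range, 1,
                       1.5 * h / model$range - 0.5 * (h / model$range)^3)
  )
  model$nugget + model$psill * s
}

# Covariance implied by the model: C(h) = sill_total - gamma(h), with
# C(0) = nugget + psill (the nugget sits on the diagonal only).
variogram_cov <- function(model, h) {
  total <- model$nugget + model$psill
  g <- switch(model$family,
    exponential = 1 - exp(-h / model$range),
    gaussian = 1 - exp(-(h / model$range)^2),
    spherical = ifelse(h >= model$range, 1,
                       1.5 * h / model$range - 0.5 * (h / model$range)^3)
  )
  ifelse(h > 0, total - (model$nugget + model$psill * g), total)
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares with weights equal to the per-bin pair counts,
#' minimized by L-BFGS-B from five fixed initializations (no random
#' state); the best objective wins and ties go to the smallest range
#' parameter, so the fit is deterministic. A degenerate input (all
#' semivariances zero) returns the nugget-only model (0, 0).
#'
#' @param ev an [empirical_semivariogram()] result.
#' @param family model family.
#' @return a [variogram_model()].
#' @export
fit_variogram <- function(ev, family = c("exponential", "spherical", "gaussian")) {
  family <- match.arg(family)
  ok <- ev$n_pairs > 0 & is.finite(ev$gamma)
  if (sum(ok) < 3) stop("need at least 3 nonempty semivariogram bins")
  h <- ev$dist[ok]; g <- ev$gamma[ok]; w <- ev$n_pairs[ok]

  if (all(g <= 0)) {
    return(structure(list(family = family, nugget = 0, psill = 0,
                          range = max(h)), class = "variogram_model"))
  }

  obj <- function(p) {
    m <- list(family = family, nugget = p[1], psill = p[2], range = p[3])
    sum(w * (g - variogram_gamma(m, h))^2)
  }
  gmax <- max(g); hmax <- max(h)
  inits <- list(c(0, gmax, hmax / 3),
                c(gmax / 2, gmax / 2, hmax / 3),
                c(0, gmax, hmax),
                c(gmax / 10, gmax, hmax / 10),
                c(0, gmax / 2, hmax / 2))
  best <- NULL
  for (p0 in inits) {
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B",
                   lower = c(0, 0, hmax * 1e-4),
                   upper = c(gmax * 3, gmax * 3, hmax * 10),
                   control = list(factr = 10, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 && fit$par[3] < best$par[3])) {
      best <- fit
    }
  }
  if (is.null(best)) stop("variogram fit failed from all initializations")
  variogram_model(family, nugget = best$par[1], psill = best$par[2],
                  range = best$par[3])
}

# Average duplicate coordinates so the kriging system is nonsingular.
dedupe_stations <- function(lon, lat, z) {
  key <- paste(lon, lat)
  if (!anyDuplicated(key)) return(list(lon = lon, lat = lat, z = z))
  agg <- tapply(z, key, mean)
  first <- !duplicated(key)
  mr_log("kriging: averaged %d duplicate coordinate(s)", sum(!first))
  k <- key[first]
  list(lon = lon[first], lat = lat[first], z = as.numeric(agg[k]))
}

#' Ordinary kriging onto a grid
#'
#' Solves the ordinary-kriging system (model covariances plus the
#' unbiasedness constraint, so weights sum to one at every prediction
#' point) for every cell center of the grid. With a zero nugget the
#' predictor interpolates the observations exactly. Duplicate station
#' coordinates are averaged before solving.
#'
#' @param stations station table (one season).
#' @param variable column to interpolate.
#' @param model a [variogram_model()].
#' @param grid target [grid_spec()].
#' @param clip_zero clip negative predictions to zero (used for biomass).
#' @return an [new_field()] on `grid`.
#' @export
krige_ordinary <- function(stations, variable, model, grid,
                           clip_zero = FALSE) {
  z <- stations[[variable]]
  if (is.null(z)) stop("no column '", variable, "' in station table")
  keep <- is.finite(z)
  s <- dedupe_stations(stations$lon[keep], stations$lat[keep], z[keep])
  n <- length(s$z)
  if (n < 3) stop("need at least 3 stations to krige")

  ctr <- grid_centers(grid)
  if (model$nugget + model$psill <= 0) {
    # zero total sill (constant variable): every cell predicts the mean
    pred <- rep(mean(s$z), nrow(ctr))
    if (clip_zero) pred <- pmax(pred, 0)
    return(new_field(grid, pred, variable))
  }
  D <- as.matrix(stats::dist(cbind(s$lon, s$lat)))
  K <- matrix(0, n + 1, n + 1)
  K[1:n, 1:n] <- variogram_cov(model, D)
  K[n + 1, 1:n] <- 1
  K[1:n, n + 1] <- 1

  dx <- outer(s$lon, ctr$lon, "-")
  dy <- outer(s$lat, ctr$lat, "-")
  B <- rbind(variogram_cov(model, sqrt(dx^2 + dy^2)),
             rep(1, nrow(ctr)))
  W <- solve(K, B)
  pred <- as.vector(crossprod(W[1:n, , drop = FALSE], s$z))
  if (clip_zero) pred <- pmax(pred, 0)
  new_field(grid, pred, variable)
}

# Kriging weights at arbitrary prediction points (used by tests and the
# weight-normalization invariant).
kriging_weights <- function(stations, variable, model, lon, lat) {
  z <- stations[[variable]]
  keep <- is.finite(z)
  s <- dedupe_stations(stations$lon[keep], stations$lat[keep], z[keep])
  n <- length(s$z)
  if (model$nugget + model$psill <= 0) {
    return(matrix(1 / n, n, length(lon)))
  }
  D <- as.matrix(stats::dist(cbind(s$lon, s$lat)))
  K <- matrix(0, n + 1, n + 1)
  K[1:n, 1:n] <- variogram_cov(model, D)
  K[n + 1, 1:n] <- 1
  K[1:n, n + 1] <- 1
  dx <- outer(s$lon, lon, "-")
  dy <- outer(s$lat, lat, "-")
  B <- rbind(variogram_cov(model, sqrt(dx^2 + dy^2)), rep(1, length(lon)))
  W <- solve(K, B)
  W[1:n, , drop = FALSE]
}

#' Interpolate all survey variables for one season
#'
#' Runs the semivariogram -> WLS fit -> ordinary kriging chain for
#' biomass and the three factors on a shared grid. Fitted variogram
#' parameters are logged and returned as an attribute.
#'
#' @param stations full station table.
#' @param season season label to interpolate.
#' @param config a [run_config()].
#' @param grid optional [grid_spec()]; default covers the season's
#'   stations at `config$resolution`.
#' @return named list of four fields (`biomass`, `temperature`,
#'   `salinity`, `depth`) with attribute `variograms`.
#' @export
interpolate_survey <- function(stations, season, config = run_config(),
                               grid = NULL) {
  st <- stations[stations$season == season, , drop = FALSE]
  if (nrow(st) == 0) stop("no stations for season '", season, "'")
  if (is.null(grid)) {
    grid <- grid_for_bbox(min(st$lon), max(st$lon), min(st$lat), max(st$lat),
                          resolution = config$resolution)
  }
  vars <- c("biomass", "temperature", "salinity", "depth")
  models <- list()
  fields <- lapply(vars, function(v) {
    ev <- empirical_semivariogram(st, v)
    m <- fit_variogram(ev, config$variogram_family)
    models[[v]] <<- m
    mr_log("kriging %s/%s: %s nugget=%.4g psill=%.4g range=%.4g",
           season, v, m$family, m$nugget, m$psill, m$range)
    krige_ordinary(st, v, m, grid, clip_zero = (v == "biomass"))
  })
  names(fields) <- vars
  attr(fields, "variograms") <- models
  fields
}
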