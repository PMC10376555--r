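#' Survey design for a fixed-station trawl lattice
#'
#' Describes a regular station grid of the kind used by large-area
#' fisheries resource surveys: one station every `station_spacing`
#' degrees in both longitude and latitude, revisited once per season.
#' The default bounding box and half-degree spacing give the classic
#' 19 x 15 = 285 station lattice of an East China Sea shelf survey.
#'
#' @param lon_min,lon_max,lat_min,lat_max survey bounding box, decimal
#'   degrees.
#' @param station_spacing lattice spacing in degrees (default 0.5, i.e.
#'   a station at each 30' interval).
#' @param seasons character vector of season labels.
#' @param seed integer seed; all randomness of the generator flows from it.
#' @return an object of class `survey_design`.
#' @export
survey_design <- function(lon_min = 120, lon_max = 127,
                          lat_min = 26, lat_max = 35,
                          station_spacing = 0.5,
                          seasons = c("spring", "summer", "autumn", "winter"),
                          seed = 1L) {
  stopifnot(lon_max > lon_min, lat_max > lat_min, station_spacing > 0,
            length(seasons) >= 1)
  structure(
    list(lon_min = lon_min, lon_max = lon_max,
         lat_min = lat_min, lat_max = lat_max,
         station_spacing = station_spacing,
         seasons = as.character(seasons), seed = as.integer(seed)),
    class = "survey_design"
  )
}

#' Station coordinates of a survey design
#'
#' @param design a [survey_design()].
#' @return data.frame with `lon`, `lat`; `(floor(dlat/spacing)+1) *
#'   (floor(dlon/spacing)+1)` rows.
#' @export
design_stations <- function(design) {
  nx <- floor((design$lon_max - design$lon_min) / design$station_spacing + 1e-9) + 1
  ny <- floor((design$lat_max - design$lat_min) / design$station_spacing + 1e-9) + 1
  lon <- design$lon_min + (seq_len(nx) - 1) * design$station_spacing
  lat <- design$lat_min + (seq_len(ny) - 1) * design$station_spacing
  data.frame(lon = rep(lon, times = ny), lat = rep(lat, each = nx))
}

#' Environmental field specification
#'
#' Parameters of the three synthetic bottom-layer fields. Temperature is
#' a latitudinal gradient plus a per-season offset plus spatially
#' correlated noise. Salinity is a high oceanic background (34 per mille
#' by default) with localized low-salinity river-plume depressions whose
#' centers drop below 10 per mille, emulating estuarine dilution.
#' Depth deepens offshore (eastward) from a nearshore value, with
#' correlated roughness; it is clamped strictly positive.
#'
#' @param temperature list: `base` (deg C at the reference latitude, the
#'   bounding-box midpoint), `lat_gradient` (deg C per degree latitude),
#'   `seasonal_offsets` (named numeric, one per season), `noise_sd`
#'   (deg C), `noise_corr_length` (degrees).
#' @param salinity list: `background` (per mille), `plumes` (list of
#'   `list(lon, lat, radius, min)`), `noise_sd`, `noise_corr_length`.
#' @param depth list: `nearshore` (m at the western edge),
#'   `offshore_gradient` (m per degree longitude), `roughness_sd` (m),
#'   `noise_corr_length` (degrees).
#' @return an object of class `field_spec`.
#' @export
field_spec <- function(
    temperature = list(base = 18, lat_gradient = -0.8,
                       seasonal_offsets = c(spring = 1, summer = 8,
                                            autumn = 3, winter = -4),
                       noise_sd = 0.5, noise_corr_length = 0.5),
    salinity = list(background = 34,
                    plumes = list(list(lon = 122.2, lat = 31.5,
                                       radius = 1.0, min = 6)),
                    noise_sd = 0.15, noise_corr_length = 0.5),
    depth = list(nearshore = 20, offshore_gradient = 15,
                 roughness_sd = 3, noise_corr_length = 0.5)) {
  for (p in salinity$plumes) {
    stopifnot(p$min >= 0, salinity$background > p$min, p$radius > 0)
  }
  stopifnot(depth$nearshore > 0, temperature$noise_corr_length > 0,
            salinity$noise_corr_length > 0, depth$noise_corr_length > 0)
  structure(list(temperature = temperature, salinity = salinity, depth = depth),
            class = "field_spec")
}

#' Biomass preference specification
#'
#' Biomass density at a station is the product of per-factor Gaussian
#' suitability kernels (each `exp(-((v - preferred)/tolerance)^2 / 2)`),
#' a season-specific aggregation (hotspot) kernel, and multiplicative
#' lognormal noise, floored at a detectability minimum. Default presets
#' place spring/autumn hotspots offshore and split, and summer/winter
#' hotspots inshore and compact, emulating the seasonal inshore/offshore
#' aggregation of a reproductive-cycle fish; the summer hotspot overlaps
#' the default river plume so that the within-range salinity
#' distribution is multimodal.
#'
#' @param preferences named list (one entry per season) of lists
#'   `temperature`, `salinity`, `depth`, each `c(preferred =, tolerance =)`.
#' @param hotspots named list (one entry per season) of data.frames with
#'   columns `lon`, `lat`, `radius` (degrees).
#' @param noise_sdlog lognormal SD of the multiplicative noise.
#' @param floor minimum reported density (detectability floor).
#' @return an object of class `biomass_spec`.
#' @export
biomass_spec <- function(preferences = NULL, hotspots = NULL,
                         noise_sdlog = 0.6, floor = 1e-4) {
  stopifnot(noise_sdlog >= 0, floor >= 0)
  if (is.null(preferences)) preferences <- default_preferences()
  if (is.null(hotspots)) hotspots <- default_hotspots()
  for (season in names(preferences)) {
    for (f in preferences[[season]]) stopifnot(f[["tolerance"]] > 0)
  }
  structure(list(preferences = preferences, hotspots = hotspots,
                 noise_sdlog = noise_sdlog, floor = floor),
            class = "biomass_spec")
}

default_preferences <- function() {
  pref <- function(t, tt, s, ts, d, td) {
    list(temperature = c(preferred = t, tolerance = tt),
         salinity    = c(preferred = s, tolerance = ts),
         depth       = c(preferred = d, tolerance = td))
  }
  list(
    spring = pref(19.3, 2.0, 34.2, 2.0, 85, 15),
    summer = pref(22.0, 3.0, 31.0, 8.0, 45, 18),
    autumn = pref(20.3, 2.5, 33.5, 3.0, 70, 18),
    winter = pref(16.0, 2.5, 33.0, 5.0, 50, 20)
  )
}

default_hotspots <- function() {
  list(
    spring = data.frame(lon = c(124.5, 125.3), lat = c(28.5, 32.0),
                        radius = c(1.2, 1.2)),
    summer = data.frame(lon = 122.4, lat = 31.0, radius = 1.3),
    autumn = data.frame(lon = c(124.0, 125.5), lat = c(27.5, 31.5),
                        radius = c(1.2, 1.2)),
    winter = data.frame(lon = 121.8, lat = 28.0, radius = 1.3)
  )
}

# Gaussian-kernel smoothing of a white-noise grid with exact per-cell
# variance normalization (zero-padded convolution divided by the square
# root of the truncated sum of squared weights), so margins stay unit
# Gaussian right up to the borders. A cheap stand-in for a stationary
# random field with the requested correlation length: deterministic
# given the seed, fast, and smooth enough for kriging to have structure
# to recover.
smooth_noise <- function(n_cols, n_rows, sigma_cells, seed) {
  z <- with_seed(seed, matrix(stats::rnorm(n_cols * n_rows), n_rows, n_cols))
  if (sigma_cells > 0) {
    hw <- max(1L, ceiling(3 * sigma_cells))
    k <- stats::dnorm(seq(-hw, hw), sd = sigma_cells)
    csq <- cumsum(k^2)
    total <- csq[length(k)]
    axis_smooth <- function(m) {
      n <- ncol(m)
      # variance of the truncated sums at each position along the axis
      denom <- rep(total, n)
      edge <- seq_len(min(hw, n))
      denom[edge] <- denom[edge] - csq[hw + 1 - edge]
      denom[n + 1 - edge] <- denom[n + 1 - edge] - csq[hw + 1 - edge]
      out <- t(apply(m, 1, function(row) {
        ext <- c(rep(0, hw), row, rep(0, hw))
        stats::convolve(ext, k, type = "filter")
      }))
      sweep(out, 2, sqrt(denom), "/")
    }
    z <- axis_smooth(z)        # smooth along rows (across columns)
    z <- t(axis_smooth(t(z)))  # smooth along columns
  }
  z
}

seed_table <- function(design) {
  vars <- c("temperature", "salinity", "depth", "biomass")
  n <- length(design$seasons) * length(vars)
  seeds <- derive_seeds(design$seed, n)
  m <- matrix(seeds, nrow = length(vars),
              dimnames = list(vars, design$seasons))
  m
}

# Deterministic (noise-free) parts of the three fields at arbitrary points.
field_mean_at <- function(spec, variable, lon, lat, season_offset = 0,
                          lon_min = min(lon), lat_ref = mean(range(lat))) {
  switch(variable,
    temperature = spec$temperature$base +
      spec$temperature$lat_gradient * (lat - lat_ref) + season_offset,
    salinity = {
      bg <- spec$salinity$background
      dip <- rep(0, length(lon))
      for (p in spec$salinity$plumes) {
        d <- sqrt((lon - p$lon)^2 + (lat - p$lat)^2)
        dip <- pmax(dip, (bg - p$min) * exp(-0.5 * (d / (p$radius / 2))^2))
      }
      bg - dip
    },
    depth = spec$depth$nearshore +
      spec$depth$offshore_gradient * (lon - lon_min),
    stop("unknown variable: ", variable)
  )
}

#' Generate the three environmental fields for one season
#'
#' @param design a [survey_design()].
#' @param spec a [field_spec()].
#' @param grid a [grid_spec()] covering the design's bounding box.
#' @param seed integer seed (defaults to the design's).
#' @param season season label (defaults to the design's first season).
#' @return named list of three [new_field()] objects: `temperature`,
#'   `salinity`, `depth`.
#' @export
generate_fields <- function(design, spec, grid, seed = design$seed,
                            season = design$seasons[[1]]) {
  stopifnot(inherits(design, "survey_design"), inherits(spec, "field_spec"),
            inherits(grid, "grid_spec"))
  if (!season %in% design$seasons)
    stop("season '", season, "' not in design seasons")
  ctr <- grid_centers(grid)
  if (grid$lon_min > design$lon_min + 1e-9 || grid$lat_min > design$lat_min + 1e-9 ||
      grid$lon_min + grid$n_cols * grid$resolution < design$lon_max - 1e-9 ||
      grid$lat_min + grid$n_rows * grid$resolution < design$lat_max - 1e-9)
    stop("grid does not cover the survey bounding box")

  design2 <- design; design2$seed <- as.integer(seed)
  seeds <- seed_table(design2)
  lat_ref <- (design$lat_min + design$lat_max) / 2
  s_off <- spec$temperature$seasonal_offsets
  off <- if (season %in% names(s_off)) s_off[[season]] else 0

  noise <- function(variable, sd, corr) {
    if (sd <= 0) return(0)
    m <- smooth_noise(grid$n_cols, grid$n_rows, corr / grid$resolution,
                      seeds[variable, season])
    sd * as.vector(t(m))  # row-major: lon fastest
  }

  temp <- field_mean_at(spec, "temperature", ctr$lon, ctr$lat, off,
                        design$lon_min, lat_ref) +
    noise("temperature", spec$temperature$noise_sd,
          spec$temperature$noise_corr_length)
  sal <- field_mean_at(spec, "salinity", ctr$lon, ctr$lat) +
    noise("salinity", spec$salinity$noise_sd, spec$salinity$noise_corr_length)
  sal <- pmax(sal, 0)
  dep <- field_mean_at(spec, "depth", ctr$lon, ctr$lat,
                       lon_min = design$lon_min) +
    noise("depth", spec$depth$roughness_sd, spec$depth$noise_corr_length)
  dep <- pmax(dep, 1)

  list(temperature = new_field(grid, temp, "temperature", "degC"),
       salinity    = new_field(grid, sal, "salinity", "permille"),
       depth       = new_field(grid, dep, "depth", "m"))
}

#' Generate a synthetic multi-season station table
#'
#' One row per station per season. Factor values are the generated
#' fields sampled at the station coordinates; biomass is the preference
#' suitability times the seasonal hotspot kernel times lognormal noise.
#'
#' @param design a [survey_design()].
#' @param field_spec a [field_spec()].
#' @param biomass_spec a [biomass_spec()].
#' @param seed integer seed (defaults to the design's).
#' @return data.frame with columns `season`, `lon`, `lat`, `biomass`,
#'   `temperature`, `salinity`, `depth`.
#' @export
generate_survey <- function(design, field_spec = mixrange::field_spec(),
                            biomass_spec = mixrange::biomass_spec(),
                            seed = design$seed) {
  stopifnot(inherits(design, "survey_design"))
  st <- design_stations(design)
  grid <- grid_for_bbox(design$lon_min, design$lon_max,
                        design$lat_min, design$lat_max, resolution = 0.1)
  design2 <- design; design2$seed <- as.integer(seed)
  seeds <- seed_table(design2)

  out <- lapply(design$seasons, function(season) {
    fields <- generate_fields(design, field_spec, grid, seed = seed,
                              season = season)
    tv <- field_at(fields$temperature, st$lon, st$lat)
    sv <- field_at(fields$salinity, st$lon, st$lat)
    dv <- field_at(fields$depth, st$lon, st$lat)

    pref <- biomass_spec$preferences[[season]]
    suit <- rep(1, nrow(st))
    if (!is.null(pref)) {
      vals <- list(temperature = tv, salinity = sv, depth = dv)
      for (f in names(pref)) {
        p <- pref[[f]]
        suit <- suit * exp(-0.5 * ((vals[[f]] - p[["preferred"]]) /
                                     p[["tolerance"]])^2)
      }
    }
    hs <- biomass_spec$hotspots[[season]]
    agg <- rep(1, nrow(st))
    if (!is.null(hs) && nrow(hs) > 0) {
      agg <- rep(0, nrow(st))
      for (i in seq_len(nrow(hs))) {
        d <- sqrt((st$lon - hs$lon[i])^2 + (st$lat - hs$lat[i])^2)
        agg <- pmax(agg, exp(-0.5 * (d / hs$radius[i])^2))
      }
    }
    noise <- if (biomass_spec$noise_sdlog > 0) {
      with_seed(seeds["biomass", season],
                exp(stats::rnorm(nrow(st), 0, biomass_spec$noise_sdlog)))
    } else rep(1, nrow(st))
    biomass <- pmax(suit * agg * noise, biomass_spec$floor)

    data.frame(season = season, lon = st$lon, lat = st$lat,
               biomass = biomass, temperature = tv, salinity = sv,
               depth = dv)
  })
  validate_station_table(do.call(rbind, out))
}
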