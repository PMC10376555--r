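#' Validate a station table
#'
#' Checks the invariants every downstream stage relies on: the
#' documented columns are present, no duplicate (season, lon, lat),
#' all factor values finite, biomass and salinity non-negative, depth
#' strictly positive.
#'
#' @param stations data.frame with columns `season`, `lon`, `lat`,
#'   `biomass`, `temperature`, `salinity`, `depth`.
#' @return the validated data.frame, invisibly classed `station_table`.
#' @export
validate_station_table <- function(stations) {
  required <- c("season", "lon", "lat", "biomass",
                "temperature", "salinity", "depth")
  missing <- setdiff(required, names(stations))
  if (length(missing) > 0)
    stop("station table is missing column(s): ", paste(missing, collapse = ", "))
  key <- paste(stations$season, stations$lon, stations$lat)
  if (anyDuplicated(key))
    stop("duplicate (season, lon, lat) rows in station table")
  num <- c("lon", "lat", "biomass", "temperature", "salinity", "depth")
  for (col in num) {
    if (!is.numeric(stations[[col]]))
      stop("column '", col, "' is not numeric")
  }
  if (any(stations$biomass < 0)) stop("negative biomass density")
  if (any(stations$salinity < 0)) stop("negative salinity")
  if (any(stations$depth <= 0)) stop("non-positive depth")
  class(stations) <- unique(c("station_table", class(stations)))
  stations
}

#' Read a station table from CSV
#'
#' Expects the header `season, lon, lat, biomass, temperature, salinity,
#' depth` (any column order). Rows with missing factor values are
#' dropped with a logged count; structural problems (missing columns,
#' negative biomass) are errors.
#'
#' @param path CSV file path.
#' @return a validated station table (data.frame).
#' @export
read_station_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("season", "lon", "lat", "biomass",
                "temperature", "salinity", "depth")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("station CSV is missing column(s): ", paste(missing, collapse = ", "))
  num <- c("lon", "lat", "biomass", "temperature", "salinity", "depth")
  complete <- stats::complete.cases(df[num])
  if (any(!complete)) {
    mr_log("read_station_table: dropped %d row(s) with missing values",
           sum(!complete))
    df <- df[complete, , drop = FALSE]
    rownames(df) <- NULL
  }
  validate_station_table(df)
}

#' Write a station table to CSV
#'
#' @param stations a station table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_station_table <- function(stations, path) {
  stations <- validate_station_table(stations)
  cols <- c("season", "lon", "lat", "biomass",
            "temperature", "salinity", "depth")
  utils::write.csv(format(stations[cols], digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration for the analysis pipeline
#'
#' @param resolution interpolation grid resolution in degrees.
#' @param fraction biomass share defining the main range (default 0.80).
#' @param multiplier interval half-width in component SDs (default 1).
#' @param k_max maximum mixture components tried by BIC selection.
#' @param k_fixed optional named list `factor -> season -> k` fixing the
#'   component count instead of BIC selection; `NULL` selects by BIC.
#' @param variogram_family one of "exponential", "spherical", "gaussian".
#' @param factors environmental factor columns analysed by the pipeline.
#' @param report_digits decimals for rendered ratio tables.
#' @param seed integer seed for the EM restarts.
#' @return an object of class `run_config`.
#' @export
run_config <- function(resolution = 0.05, fraction = 0.80, multiplier = 1,
                       k_max = 4, k_fixed = NULL,
                       variogram_family = c("exponential", "spherical", "gaussian"),
                       factors = c("temperature", "salinity", "depth"),
                       report_digits = 2, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1, multiplier > 0, k_max >= 1,
            resolution > 0, length(factors) >= 1)
  structure(
    list(resolution = resolution, fraction = fraction,
         multiplier = multiplier, k_max = as.integer(k_max),
         k_fixed = k_fixed, variogram_family = match.arg(variogram_family),
         factors = factors, report_digits = report_digits,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

# ---- GeoJSON mask serialization --------------------------------------

# Directed boundary edges of the true-cell region, oriented with the
# region on the left, chained into closed rings. At ambiguous corners
# (diagonally touching cells) the leftmost turn is taken, which keeps
# 4-connected components in separate rings; outer rings come out
# counter-clockwise and holes clockwise.
mask_rings <- function(mask) {
  g <- mask$grid
  m <- matrix(mask$membership, nrow = g$n_rows, ncol = g$n_cols, byrow = TRUE)
  if (!any(m)) return(list())
  pad <- matrix(FALSE, g$n_rows + 2, g$n_cols + 2)
  pad[2:(g$n_rows + 1), 2:(g$n_cols + 1)] <- m

  # vertices keyed by integer corner coordinates (i along lon, j along lat)
  edges <- list()
  for (j in seq_len(g$n_rows)) {
    for (i in seq_len(g$n_cols)) {
      if (!m[j, i]) next
      x0 <- i - 1L; x1 <- i; y0 <- j - 1L; y1 <- j
      if (!pad[j, i + 1])     edges[[length(edges) + 1]] <- c(x0, y0, x1, y0) # south
      if (!pad[j + 1, i + 2]) edges[[length(edges) + 1]] <- c(x1, y0, x1, y1) # east
      if (!pad[j + 2, i + 1]) edges[[length(edges) + 1]] <- c(x1, y1, x0, y1) # north
      if (!pad[j + 1, i])     edges[[length(edges) + 1]] <- c(x0, y1, x0, y0) # west
    }
  }
  E <- do.call(rbind, edges)
  key <- function(x, y) paste(x, y)
  from <- key(E[, 1], E[, 2])
  by_from <- split(seq_len(nrow(E)), from)
  used <- rep(FALSE, nrow(E))

  rings <- list()
  for (start in seq_len(nrow(E))) {
    if (used[start]) next
    ring <- list(E[start, 1:2])
    cur <- start
    repeat {
      used[cur] <- TRUE
      ring[[length(ring) + 1]] <- E[cur, 3:4]
      if (all(E[cur, 3:4] == E[start, 1:2])) break  # ring closed
      nxt_ids <- by_from[[key(E[cur, 3], E[cur, 4])]]
      nxt_ids <- nxt_ids[!used[nxt_ids]]
      if (length(nxt_ids) == 0) break
      if (length(nxt_ids) == 1) {
        cur <- nxt_ids
      } else {
        # ambiguous corner: take the leftmost turn relative to incoming
        din <- c(E[cur, 3] - E[cur, 1], E[cur, 4] - E[cur, 2])
        turn <- vapply(nxt_ids, function(id) {
          dout <- c(E[id, 3] - E[id, 1], E[id, 4] - E[id, 2])
          din[1] * dout[2] - din[2] * dout[1]  # cross product; left > 0
        }, numeric(1))
        cur <- nxt_ids[which.max(turn)]
      }
    }
    coords <- do.call(rbind, ring)
    rings[[length(rings) + 1]] <- coords
  }
  # convert corner indices to lon/lat
  lapply(rings, function(r) {
    cbind(lon = g$lon_min + r[, 1] * g$resolution,
          lat = g$lat_min + r[, 2] * g$resolution)
  })
}

#' Write a spatial mask as GeoJSON
#'
#' True cells are merged by 4-connectivity into polygon rings whose
#' coordinates are cell-corner lon/lat; each ring becomes one Feature in
#' a FeatureCollection. An empty mask writes a collection with zero
#' features.
#'
#' @param mask an [new_mask()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "mr_mask"))
  rings <- mask_rings(mask)
  if (length(rings) == 0) mr_log("write_mask: mask '%s' is empty", mask$label)
  features <- lapply(rings, function(r) {
    list(type = "Feature",
         properties = list(label = mask$label),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(r)),
                                                   function(i) c(r[i, 1], r[i, 2])))))
  })
  gj <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read GeoJSON polygon rings
#'
#' @param path GeoJSON FeatureCollection path written by [write_mask()].
#' @return list of coordinate matrices (lon, lat), one per ring.
#' @export
read_mask_rings <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  rings <- list()
  for (f in gj$features) {
    for (ring in f$geometry$coordinates) {
      coords <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
      colnames(coords) <- c("lon", "lat")
      rings[[length(rings) + 1]] <- coords
    }
  }
  rings
}

#' Rasterize polygon rings onto a grid
#'
#' A cell is a member if its center lies inside an odd number of rings
#' (even-odd rule), so outer rings and holes need no explicit pairing.
#' Rasterizing the rings written by [write_mask()] onto the same grid
#' reproduces the original mask exactly: cell centers never fall on ring
#' edges because edges lie on the corner lattice.
#'
#' @param rings list of (lon, lat) coordinate matrices.
#' @param grid a [grid_spec()].
#' @param label mask label.
#' @return an [new_mask()] object.
#' @export
rasterize_rings <- function(rings, grid, label = "") {
  ctr <- grid_centers(grid)
  inside <- rep(0L, nrow(ctr))
  for (r in rings) {
    n <- nrow(r)
    if (all(r[1, ] == r[n, ])) r <- r[-n, , drop = FALSE]
    n <- nrow(r)
    cross <- rep(FALSE, nrow(ctr))
    j <- n
    for (i in seq_len(n)) {
      yi <- r[i, 2]; yj <- r[j, 2]
      if (yi != yj) {
        hit <- ((yi > ctr$lat) != (yj > ctr$lat)) &
          (ctr$lon < r[i, 1] + (r[j, 1] - r[i, 1]) * (ctr$lat - yi) / (yj - yi))
        cross <- xor(cross, hit)
      }
      j <- i
    }
    inside <- inside + cross
  }
  new_mask(grid, inside %% 2L == 1L, label)
}
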