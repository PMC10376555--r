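#' Main biomass range of a gridded field
#'
#' The main range is the superlevel set holding at least `fraction`
#' (default 80%) of the total biomass: cells are ranked by value and the
#' threshold is the largest value t such that cells with value >= t hold
#' at least the requested share. All cells tied at the threshold are
#' included, so the rule is deterministic and the returned mask's mass
#' share is always >= `fraction`. No morphological smoothing is applied;
#' fragmentation of the raw superlevel set is left visible.
#'
#' @param biomass a biomass [new_field()] with non-negative values.
#' @param fraction biomass share in (0, 1), default 0.80.
#' @return an [new_mask()] labelled "biomass".
#' @export
biomass_main_range <- function(biomass, fraction = 0.80) {
  stopifnot(inherits(biomass, "mr_field"), fraction > 0, fraction < 1)
  v <- biomass$values
  if (any(v < 0)) stop("biomass field has negative values")
  total <- sum(v)
  if (total <= 0) stop("biomass field is all zero; no range definable")
  ord <- order(v, decreasing = TRUE)
  cum <- cumsum(v[ord])
  k <- which(cum >= fraction * total)[1]
  t <- v[ord[k]]
  new_mask(biomass$grid, v >= t, "biomass")
}

#' Stations holding the top share of biomass
#'
#' Station-level analogue of [biomass_main_range()]: stations are ranked
#' by density and the smallest prefix whose cumulative biomass reaches
#' `fraction` of the season total is returned, extended through ties at
#' the cutoff density.
#'
#' @param stations station table.
#' @param season season label.
#' @param fraction biomass share in (0, 1).
#' @return subset of the station table (with factor values), ordered by
#'   decreasing density.
#' @export
station_main_range <- function(stations, season, fraction = 0.80) {
  stopifnot(fraction > 0, fraction < 1)
  st <- stations[stations$season == season, , drop = FALSE]
  if (nrow(st) == 0) stop("no stations for season '", season, "'")
  total <- sum(st$biomass)
  if (total <= 0) stop("season '", season, "' has zero total biomass")
  ord <- order(st$biomass, decreasing = TRUE)
  cum <- cumsum(st$biomass[ord])
  k <- which(cum >= fraction * total)[1]
  t <- st$biomass[ord[k]]
  st[st$biomass >= t, , drop = FALSE][order(-st$biomass[st$biomass >= t]), ,
                                      drop = FALSE]
}
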