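#' Spatial envelope of factor intervals
#'
#' A cell belongs to the envelope iff its field value lies in any of the
#' intervals (closed endpoints): the union over mixture components of
#' the per-component `mean +/- sd` bands, mapped back to space.
#'
#' @param field an [new_field()].
#' @param intervals data.frame with `lower`, `upper` columns (as from
#'   [main_intervals()]), or an empty/NULL set for an empty mask.
#' @param label mask label.
#' @return an [new_mask()].
#' @export
factor_range_mask <- function(field, intervals, label = field$variable) {
  stopifnot(inherits(field, "mr_field"))
  member <- rep(FALSE, length(field$values))
  if (!is.null(intervals) && nrow(intervals) > 0) {
    for (i in seq_len(nrow(intervals))) {
      if (intervals$lower[i] > intervals$upper[i])
        stop("interval with lower > upper")
      member <- member | (field$values >= intervals$lower[i] &
                            field$values <= intervals$upper[i])
    }
  }
  new_mask(field$grid, member, label)
}

#' Point-count area of a mask
#'
#' The number of true cells: the package's unit of area. On a regular
#' point array the count is proportional to the underlying area, which
#' is how irregular-polygon areas are approximated throughout.
#'
#' @param mask an [new_mask()].
#' @return integer cell count.
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "mr_mask"))
  sum(mask$membership)
}

#' Intersection of masks
#'
#' @param masks list of [new_mask()] objects on one shared grid.
#' @param label label of the result.
#' @return an [new_mask()]: cell-wise conjunction.
#' @export
intersect_masks <- function(masks, label = NULL) {
  stopifnot(length(masks) >= 1)
  g <- masks[[1]]$grid
  member <- rep(TRUE, n_cells(g))
  for (m in masks) {
    stopifnot(inherits(m, "mr_mask"))
    if (!same_grid(m$grid, g)) stop("masks are on different grids")
    member <- member & m$membership
  }
  if (is.null(label))
    label <- paste(vapply(masks, `[[`, character(1), "label"),
                   collapse = " ∩ ")
  new_mask(g, member, label)
}

#' Composite fitness index
#'
#' Geometric mean of the effective ratio and the coverage ratio,
#' combining an envelope's accuracy (how much of it is occupied habitat)
#' with its importance (how much of the habitat it captures) into one
#' score.
#'
#' @param r_effective effective ratio in `[0, 1]`.
#' @param r_covering coverage ratio in `[0, 1]`.
#' @return `sqrt(r_effective * r_covering)`.
#' @export
composite_index <- function(r_effective, r_covering) {
  stopifnot(all(r_effective >= 0), all(r_covering >= 0))
  sqrt(r_effective * r_covering)
}

#' Overlap statistics between a factor envelope and the biomass range
#'
#' Point-count areas and the three ratios:
#' `R_effective = A_effective / A_env` (how accurately the envelope
#' identifies occupied habitat), `R_covering = A_effective / A_bio`
#' (how much of the habitat the envelope captures), and the composite
#' fitness index, their geometric mean.
#'
#' @param env_mask factor envelope mask (`A_env > 0`).
#' @param bio_mask biomass main-range mask (`A_bio > 0`).
#' @param label combination label.
#' @param season season label.
#' @return data.frame row of class `overlap_stats` with `A_env`,
#'   `A_bio`, `A_effective`, `R_effective`, `R_covering`, `I_comp`.
#' @export
overlap_stats <- function(env_mask, bio_mask, label = env_mask$label,
                          season = "") {
  stopifnot(inherits(env_mask, "mr_mask"), inherits(bio_mask, "mr_mask"))
  if (!same_grid(env_mask$grid, bio_mask$grid))
    stop("envelope and biomass masks are on different grids")
  a_env <- mask_area(env_mask)
  a_bio <- mask_area(bio_mask)
  if (a_env == 0) stop("envelope mask '", label, "' has zero area")
  if (a_bio == 0) stop("biomass mask has zero area")
  a_eff <- mask_area(intersect_masks(list(env_mask, bio_mask)))
  re <- a_eff / a_env
  rc <- a_eff / a_bio
  out <- data.frame(season = season, label = label,
                    A_env = a_env, A_bio = a_bio, A_effective = a_eff,
                    R_effective = re, R_covering = rc,
                    I_comp = composite_index(re, rc))
  class(out) <- c("overlap_stats", class(out))
  out
}

#' Relative coverage decline
#'
#' Signed relative change `(after - before) / before` of a coverage
#' ratio when an envelope is intersected with additional factors;
#' non-positive whenever intersection shrinks coverage.
#'
#' @param before coverage before combining (> 0).
#' @param after coverage after combining.
#' @return signed fraction.
#' @export
coverage_decline <- function(before, after) {
  if (any(before <= 0)) stop("'before' coverage must be positive")
  (after - before) / before
}

#' Seasonal mean and SD
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator),
#' the convention of the printed summary rows.
#'
#' @param values numeric vector (n >= 2 for the SD).
#' @return list with `mean`, `sd`.
#' @export
season_summary <- function(values) {
  if (length(values) < 2) stop("need at least 2 values for the SD")
  list(mean = mean(values), sd = stats::sd(values))
}

pair_label <- function(a, b) paste(a, b, sep = " ∩ ")

#' Full single/pair/triple overlap table for one season
#'
#' Computes overlap statistics for every single factor envelope, every
#' pairwise intersection, and the all-factor intersection against the
#' biomass range, plus the coverage-decline entries: for each pair, the
#' decline relative to each constituent single factor; for the full
#' combination, the decline relative to each constituent pair. Declines
#' are computed from full-precision coverages, never from rounded
#' report values.
#'
#' @param bio_mask biomass main-range mask.
#' @param factor_masks named list of factor envelope masks.
#' @param season season label.
#' @return list with `stats` (one `overlap_stats` row per combination)
#'   and `declines` (data.frame: `combination`, `constituent`, `before`,
#'   `after`, `decline`).
#' @export
full_overlap_table <- function(bio_mask, factor_masks, season = "") {
  stopifnot(length(factor_masks) >= 1)
  labels <- names(factor_masks)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("factor_masks must be a named list")

  combos <- list()
  for (f in labels) combos[[f]] <- list(members = f, mask = factor_masks[[f]])
  if (length(labels) >= 2) {
    prs <- utils::combn(labels, 2, simplify = FALSE)
    for (p in prs) {
      combos[[pair_label(p[1], p[2])]] <-
        list(members = p,
             mask = intersect_masks(factor_masks[p], pair_label(p[1], p[2])))
    }
  }
  if (length(labels) >= 3) {
    all_lab <- paste(labels, collapse = " ∩ ")
    combos[[all_lab]] <- list(members = labels,
                              mask = intersect_masks(factor_masks, all_lab))
  }

  stats <- do.call(rbind, lapply(names(combos), function(lab) {
    overlap_stats(combos[[lab]]$mask, bio_mask, lab, season)
  }))

  cov_of <- function(lab) stats$R_covering[stats$label == lab]
  declines <- list()
  add_decline <- function(combination, constituent) {
    before <- cov_of(constituent); after <- cov_of(combination)
    declines[[length(declines) + 1]] <<- data.frame(
      season = season, combination = combination, constituent = constituent,
      before = before, after = after,
      decline = coverage_decline(before, after))
  }
  if (length(labels) >= 2) {
    for (p in utils::combn(labels, 2, simplify = FALSE)) {
      for (f in p) add_decline(pair_label(p[1], p[2]), f)
    }
  }
  if (length(labels) >= 3) {
    all_lab <- paste(labels, collapse = " ∩ ")
    for (p in utils::combn(labels, 2, simplify = FALSE)) {
      add_decline(all_lab, pair_label(p[1], p[2]))
    }
  }
  list(stats = stats,
       declines = if (length(declines)) do.call(rbind, declines) else NULL)
}
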