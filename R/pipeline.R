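#' Run the full range-overlap pipeline
#'
#' Per season: interpolate biomass and the three factors by ordinary
#' kriging, delineate the main biomass range (top `fraction` of mass),
#' decompose each factor's within-range distribution into normal
#' mixture components, map the component intervals to spatial envelope
#' masks, and compute all single/pair/triple overlap statistics and
#' coverage declines. Seasons are processed independently; a failure in
#' one season is logged and the others proceed. The whole run is
#' deterministic for a fixed config and station table.
#'
#' @param config a [run_config()].
#' @param stations a validated station table covering >= 1 season with
#'   >= 20 stations each.
#' @return an object of class `run_result`: `config`, `seasons` (per
#'   season: fields' variogram parameters, biomass mask, per-factor
#'   `mixture_fit` and intervals, envelope masks, overlap stats and
#'   declines), plus pooled `stats` and `declines` data.frames.
#' @export
run_pipeline <- function(config, stations) {
  stations <- validate_station_table(stations)
  seasons <- unique(stations$season)
  factors <- config$factors

  results <- list()
  for (season in seasons) {
    n_st <- sum(stations$season == season)
    if (n_st < 20) {
      mr_log("season '%s' skipped: only %d stations", season, n_st)
      next
    }
    res <- tryCatch({
      fields <- interpolate_survey(stations, season, config)
      bio_mask <- biomass_main_range(fields$biomass, config$fraction)
      fits <- list(); intervals <- list(); masks <- list()
      for (f in factors) {
        vals <- collect_in_range_values(fields[[f]], bio_mask)
        k_fix <- config$k_fixed[[f]][[season]]
        fit <- if (is.null(k_fix)) {
          select_k(vals, config$k_max, seed = config$seed)
        } else {
          fit_mixture_em(vals, k_fix, seed = config$seed)
        }
        iv <- main_intervals(fit, multiplier = config$multiplier)
        fits[[f]] <- fit
        intervals[[f]] <- iv
        masks[[f]] <- factor_range_mask(fields[[f]], iv, f)
      }
      ov <- full_overlap_table(bio_mask, masks, season)
      list(season = season, variograms = attr(fields, "variograms"),
           bio_mask = bio_mask, fits = fits, intervals = intervals,
           masks = masks, stats = ov$stats, declines = ov$declines)
    }, error = function(e) {
      mr_log("season '%s' aborted: %s", season, conditionMessage(e))
      NULL
    })
    if (!is.null(res)) results[[season]] <- res
  }
  if (length(results) == 0) stop("no season completed the pipeline")

  structure(
    list(config = config,
         seasons = results,
         stats = do.call(rbind, lapply(results, `[[`, "stats")),
         declines = do.call(rbind, lapply(results, `[[`, "declines")),
         provenance = list(seed = config$seed,
                           n_stations = nrow(stations),
                           package_version =
                             as.character(utils::packageVersion("mixrange")))),
    class = "run_result"
  )
}

fmt_ratio <- function(x, digits = 2) {
  formatC(round_half_away(x, digits), format = "f", digits = digits)
}

render_label <- function(x) {
  abbrev <- c(temperature = "Temp.", salinity = "Sali.", depth = "Depth")
  parts <- strsplit(x, " ∩ ", fixed = TRUE)[[1]]
  paste(ifelse(parts %in% names(abbrev), abbrev[parts], parts),
        collapse = " ∩ ")
}

with_summary_rows <- function(df, value_cols, digits = 2, integer_cols = NULL) {
  if (nrow(df) < 2) return(df)  # Average/SD rows need >= 2 seasons
  out <- df
  avg <- df[1, , drop = FALSE]; sdr <- df[1, , drop = FALSE]
  avg[1, ] <- NA; sdr[1, ] <- NA
  avg$Item <- "Average"; sdr$Item <- "SD"
  for (col in value_cols) {
    s <- season_summary(as.numeric(df[[col]]))
    if (col %in% integer_cols) {
      avg[[col]] <- round_half_away(s$mean, 0)
      sdr[[col]] <- round_half_away(s$sd, 0)
    } else {
      avg[[col]] <- s$mean
      sdr[[col]] <- s$sd
    }
  }
  rbind(out, avg, sdr)
}

#' Render the report tables of a pipeline run
#'
#' Writes the seven CSV table analogues: one mixture-parameter table per
#' factor (season, proportion, distribution type, mean +/- SD, range),
#' the single-factor overlap table (effective areas, effective ratios,
#' coverage ratios), the multi-factor overlap table, the
#' coverage-decline table, and the composite-index table — each with
#' Average and SD rows recomputed from the full-precision season values.
#' Ratios and declines are printed with exactly `report_digits` decimals
#' (half away from zero); areas as integers. A `manifest.json` records
#' the config and seed.
#'
#' @param result a `run_result`.
#' @param outdir output directory (created if missing).
#' @return invisible character vector of the files written.
#' @export
render_tables <- function(result, outdir) {
  stopifnot(inherits(result, "run_result"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dg <- result$config$report_digits
  seasons <- names(result$seasons)
  factors <- result$config$factors
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    files <<- c(files, path)
  }

  # mixture tables (one per factor)
  for (f in factors) {
    rows <- do.call(rbind, lapply(seasons, function(s) {
      iv <- result$seasons[[s]]$intervals[[f]]
      data.frame(Season = s,
                 Proportion = fmt_ratio(iv$prop, dg),
                 Distribution.Type = "norm",
                 Average = paste0(fmt_ratio(iv$mean, dg), " ± ",
                                  fmt_ratio(iv$sd, dg)),
                 Range = paste0(fmt_ratio(iv$lower, dg), "~",
                                fmt_ratio(iv$upper, dg)))
    }))
    emit(rows, paste0("mixture_", f, ".csv"))
  }

  stats <- result$stats
  # single-factor overlap table
  single <- data.frame(Item = seasons)
  for (f in factors) {
    sel <- stats[stats$label == f, ]
    sel <- sel[match(seasons, sel$season), ]
    single[[paste0("Effective.Area.", render_label(f))]] <- sel$A_effective
    single[[paste0("Effective.Ratio.", render_label(f))]] <- sel$R_effective
    single[[paste0("Coverage.Ratio.", render_label(f))]] <- sel$R_covering
  }
  single <- with_summary_rows(single, setdiff(names(single), "Item"),
                              dg, grep("Area", names(single), value = TRUE))
  for (col in grep("Ratio", names(single), value = TRUE))
    single[[col]] <- fmt_ratio(as.numeric(single[[col]]), dg)
  emit(single, "overlap_single.csv")

  # multi-factor overlap table (absent for single-factor configs)
  multi_labs <- setdiff(unique(stats$label), factors)
  if (length(multi_labs) > 0) {
    multi <- data.frame(Item = seasons)
    for (lab in multi_labs) {
      sel <- stats[stats$label == lab, ]
      sel <- sel[match(seasons, sel$season), ]
      multi[[paste0("Effective.Area.", render_label(lab))]] <- sel$A_effective
      multi[[paste0("Coverage.Ratio.", render_label(lab))]] <- sel$R_covering
    }
    multi <- with_summary_rows(multi, setdiff(names(multi), "Item"),
                               dg, grep("Area", names(multi), value = TRUE))
    for (col in grep("Ratio", names(multi), value = TRUE))
      multi[[col]] <- fmt_ratio(as.numeric(multi[[col]]), dg)
    emit(multi, "overlap_multi.csv")
  }

  # coverage-decline table
  dec <- result$declines
  if (!is.null(dec)) {
    wide <- data.frame(Item = seasons)
    combos <- unique(dec[, c("combination", "constituent")])
    for (i in seq_len(nrow(combos))) {
      sel <- dec[dec$combination == combos$combination[i] &
                   dec$constituent == combos$constituent[i], ]
      sel <- sel[match(seasons, sel$season), ]
      wide[[paste0(render_label(combos$combination[i]), " | ",
                   render_label(combos$constituent[i]))]] <- sel$decline
    }
    wide <- with_summary_rows(wide, setdiff(names(wide), "Item"), dg)
    for (col in setdiff(names(wide), "Item"))
      wide[[col]] <- fmt_ratio(as.numeric(wide[[col]]), dg)
    emit(wide, "coverage_decline.csv")
  }

  # composite-index table
  comp <- data.frame(Item = seasons)
  for (f in factors) {
    sel <- stats[stats$label == f, ]
    sel <- sel[match(seasons, sel$season), ]
    comp[[paste0(render_label(f), ".Composite.Index")]] <- sel$I_comp
  }
  comp <- with_summary_rows(comp, setdiff(names(comp), "Item"), dg)
  for (col in setdiff(names(comp), "Item"))
    comp[[col]] <- fmt_ratio(as.numeric(comp[[col]]), dg)
  emit(comp, "composite_index.csv")

  manifest <- list(config = unclass(result$config),
                   provenance = result$provenance)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, null = "null",
                              digits = NA),
             file.path(outdir, "manifest.json"))
  files <- c(files, file.path(outdir, "manifest.json"))
  invisible(files)
}
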