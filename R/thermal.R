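#' Thermal-stress configuration
#'
#' Defaults follow the Florida Reef Tract climatology used in summer 2015
#' bleaching work: maximum monthly mean (MMM, August) 28.7 C, heat-stress
#' accumulation threshold MMM + 1 = 29.7 C, local bleaching threshold
#' 30.5 C, and exceedance counters at 30.5/31/32/33 C.
#'
#' @param mmm maximum monthly mean climatological temperature (C).
#' @param dhw_threshold accumulation threshold for degree heating weeks;
#'   must exceed `mmm`.
#' @param bleaching_threshold local bleaching threshold (C), reported for
#'   context.
#' @param exceedance_thresholds temperatures (C) whose exceedance hours are
#'   counted.
#' @param min_hours_per_day minimum hourly observations for a day to enter
#'   daily statistics.
#' @param dhw_mode `"hotspot"` accumulates `T - mmm` over observations with
#'   `T >= dhw_threshold` (NOAA-style); `"excess"` accumulates
#'   `T - dhw_threshold`.
#' @param sanity_band plausible temperature band (C); values outside error.
#' @return a list of class `thermal_config`.
#' @export
thermal_config <- function(mmm = 28.7, dhw_threshold = 29.7,
                           bleaching_threshold = 30.5,
                           exceedance_thresholds = c(30.5, 31, 32, 33),
                           min_hours_per_day = 20,
                           dhw_mode = c("hotspot", "excess"),
                           sanity_band = c(15, 40)) {
  dhw_mode <- match.arg(dhw_mode)
  if (dhw_threshold <= mmm) stop("dhw_threshold must exceed mmm")
  structure(list(mmm = mmm, dhw_threshold = dhw_threshold,
                 bleaching_threshold = bleaching_threshold,
                 exceedance_thresholds = sort(exceedance_thresholds),
                 min_hours_per_day = min_hours_per_day,
                 dhw_mode = dhw_mode, sanity_band = sanity_band),
            class = "thermal_config")
}

validate_series <- function(series, cfg) {
  check_columns(series, c("site_id", "timestamp", "temp_c"),
                "temperature table")
  if (nrow(series) == 0) stop("temperature table is empty")
  if (any(!is.finite(series$temp_c))) stop("non-finite temperatures")
  if (any(series$temp_c < cfg$sanity_band[1] |
          series$temp_c > cfg$sanity_band[2]))
    stop(sprintf("temperatures outside the sanity band [%g, %g] C",
                 cfg$sanity_band[1], cfg$sanity_band[2]))
  ord <- tapply(as.numeric(series$timestamp), series$site_id,
                function(t) all(diff(t) > 0))
  if (any(!ord))
    stop("timestamps must be strictly increasing within site(s): ",
         paste(names(ord)[!ord], collapse = ", "))
  invisible(series)
}

clip_window <- function(series, window) {
  if (is.null(window)) return(series)
  ts <- series$timestamp
  series[ts >= window[1] & ts <= window[2], , drop = FALSE]
}

#' Per-site thermal summary statistics
#'
#' For each site over the analysis window: mean, sd, mean daily range
#' (daily max - daily min, over days with at least `min_hours_per_day`
#' observations), overall maximum, hours above each exceedance threshold
#' (count of hourly observations strictly above it), and degree heating
#' weeks.
#'
#' @param series temperature table (site_id, timestamp, temp_c).
#' @param cfg a [thermal_config()].
#' @param window optional POSIXct (start, end) pair.
#' @return data frame, one row per site.
#' @export
summarize_sites <- function(series, cfg = thermal_config(), window = NULL) {
  validate_series(series, cfg)
  series <- clip_window(series, window)
  sites <- unique(series$site_id)
  dhw <- degree_heating_weeks(series, cfg)
  rows <- lapply(sites, function(sid) {
    x <- series[series$site_id == sid, ]
    if (nrow(x) == 0) stop("empty series for site ", sid)
    day <- as.Date(x$timestamp, tz = "UTC")
    nh <- table(day)
    keep_days <- names(nh)[nh >= cfg$min_hours_per_day]
    rng <- if (length(keep_days) > 0) {
      dmax <- tapply(x$temp_c[day %in% keep_days],
                     droplevels(factor(day[day %in% keep_days])), max)
      dmin <- tapply(x$temp_c[day %in% keep_days],
                     droplevels(factor(day[day %in% keep_days])), min)
      mean(dmax - dmin)
    } else NA_real_
    hrs <- vapply(cfg$exceedance_thresholds,
                  function(th) sum(x$temp_c > th), numeric(1))
    out <- data.frame(site_id = sid, avg = mean(x$temp_c),
                      sd = stats::sd(x$temp_c), daily_range = rng,
                      max = max(x$temp_c), stringsAsFactors = FALSE)
    for (i in seq_along(cfg$exceedance_thresholds))
      out[[sprintf("hrs_gt_%g", cfg$exceedance_thresholds[i])]] <- hrs[i]
    out$dhw <- dhw[sid]
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Degree heating weeks per site
#'
#' Accumulated thermal stress in C-weeks over hourly observations at or
#' above the accumulation threshold (MMM + 1 by default). In `"hotspot"`
#' mode each qualifying hour contributes `(T - mmm) / (7 * 24)`; in
#' `"excess"` mode it contributes `(T - dhw_threshold) / (7 * 24)`.
#'
#' @param series temperature table (site_id, timestamp, temp_c).
#' @param cfg a [thermal_config()].
#' @param window optional POSIXct (start, end) pair.
#' @return named numeric vector of C-weeks per site. Gaps longer than 24 h
#'   raise a warning with a gap inventory; the statistic uses the available
#'   points.
#' @export
degree_heating_weeks <- function(series, cfg = thermal_config(),
                                 window = NULL) {
  validate_series(series, cfg)
  series <- clip_window(series, window)
  sites <- unique(series$site_id)
  out <- vapply(sites, function(sid) {
    x <- series[series$site_id == sid, ]
    gaps <- diff(as.numeric(x$timestamp)) / 3600
    if (any(gaps > 24)) {
      at <- x$timestamp[which(gaps > 24)]
      warning(sprintf("site %s has %d gap(s) longer than 24 h (first at %s)",
                      sid, sum(gaps > 24), format(at[1])))
    }
    hot <- x$temp_c >= cfg$dhw_threshold
    base <- if (cfg$dhw_mode == "hotspot") cfg$mmm else cfg$dhw_threshold
    # each observation represents one logging interval, so the statistic is
    # stable under cadence refinement
    dt_hours <- if (nrow(x) > 1) stats::median(gaps) else 1
    sum(x$temp_c[hot] - base) * dt_hours / (7 * 24)
  }, numeric(1))
  stats::setNames(out, sites)
}

#' Principal component analysis of daily mean temperatures across sites
#'
#' Builds the sites x days matrix of daily means (days with at least
#' `min_hours_per_day` observations), restricts to days covered by every
#' retained site, centres each day, and runs PCA. Sites missing more than
#' 20% of the candidate days are excluded with a message.
#'
#' @param series temperature table (site_id, timestamp, temp_c).
#' @param cfg a [thermal_config()].
#' @param max_missing_frac site exclusion threshold on missing days.
#' @return list: `scores` (site coordinates on PCs), `explained_variance`
#'   (fractions summing to 1), `days`, `excluded_sites`.
#' @export
daily_mean_pca <- function(series, cfg = thermal_config(),
                           max_missing_frac = 0.2) {
  validate_series(series, cfg)
  day <- as.Date(series$timestamp, tz = "UTC")
  key <- interaction(series$site_id, day, drop = TRUE)
  counts <- tapply(series$temp_c, key, length)
  means <- tapply(series$temp_c, key, mean)
  parts <- do.call(rbind, strsplit(names(means), "\\."))
  dm <- data.frame(site_id = parts[, 1], day = parts[, 2],
                   n = as.integer(counts), mean = as.numeric(means),
                   stringsAsFactors = FALSE)
  dm <- dm[dm$n >= cfg$min_hours_per_day, ]
  all_days <- sort(unique(dm$day))
  cover <- tapply(dm$day, dm$site_id, function(d) length(unique(d)))
  frac <- 1 - cover / length(all_days)
  excluded <- names(frac)[frac > max_missing_frac]
  if (length(excluded) > 0)
    message("excluding site(s) missing >", 100 * max_missing_frac,
            "% of days: ", paste(excluded, collapse = ", "))
  dm <- dm[!(dm$site_id %in% excluded), ]
  sites <- unique(dm$site_id)
  if (length(sites) < 2) stop("need at least 2 sites for PCA")
  common <- Reduce(intersect, tapply(dm$day, dm$site_id, unique))
  if (length(common) < 2) stop("fewer than 2 days shared by all sites")
  dm <- dm[dm$day %in% common, ]
  mat <- matrix(NA_real_, length(sites), length(common),
                dimnames = list(sites, sort(common)))
  mat[cbind(dm$site_id, dm$day)] <- dm$mean
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, explained_variance = ev, days = sort(common),
       excluded_sites = excluded)
}
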