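#' Split a daily series into season-year cumulative curves
#'
#' Seasonal (July-start) years are used in the Southern Hemisphere so the
#' austral summer is not split across calendar years; Northern-Hemisphere
#' season years begin 1 January. Each season year is mapped onto a uniform
#' 365-day grid (29 February dropped) and the within-year cumulative sum of
#' the forcing is returned. Missing days contribute zero to the cumulative
#' sum (the conservative default) and are counted in the coverage report.
#'
#' @param dates `Date` vector (strictly increasing).
#' @param values Numeric forcing values, same length as `dates`. `NA`
#'   allowed (treated as missing).
#' @param hemisphere `"N"` or `"S"`.
#' @param max_missing_frac Season years with more than this fraction of
#'   missing days are excluded with a warning (default 0.2).
#' @param complete_only Keep only season years whose 365-day span lies
#'   inside the data range (default TRUE).
#' @return Tibble with columns `season_year`, `day_index` (1..365),
#'   `value`, `cumulative`, plus an attribute `coverage` (tibble of
#'   season_year, n_missing).
#' @export
season_year_split <- function(dates, values, hemisphere = c("N", "S"),
                              max_missing_frac = 0.2, complete_only = TRUE) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(dates, "Date"), length(dates) == length(values))
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("dates must be strictly increasing", call. = FALSE)
  }
  mo <- as.integer(format(dates, "%m"))
  dy <- as.integer(format(dates, "%d"))
  yr <- as.integer(format(dates, "%Y"))
  leap <- mo == 2L & dy == 29L
  dates <- dates[!leap]; values <- values[!leap]
  mo <- mo[!leap]; yr <- yr[!leap]

  season_year <- if (hemisphere == "N") yr else ifelse(mo >= 7L, yr, yr - 1L)
  start <- if (hemisphere == "N") {
    as.Date(sprintf("%d-01-01", season_year))
  } else {
    as.Date(sprintf("%d-07-01", season_year))
  }
  # day index on the 365-day grid: calendar offset minus a leap day if one
  # falls inside [start, date). N years can contain Feb 29 of the season
  # year itself; S (July-start) years can contain Feb 29 of the next year.
  offset <- as.integer(dates - start)
  leap_year <- if (hemisphere == "N") season_year else season_year + 1L
  mar1 <- as.Date(sprintf("%d-03-01", leap_year))
  leap_inside <- as.integer(.is_leap(leap_year) & dates >= mar1)
  day_index <- offset - leap_inside + 1L

  df <- tibble::tibble(season_year = season_year, day_index = day_index,
                       value = values)
  df <- df[df$day_index >= 1 & df$day_index <= 365, ]

  if (complete_only) {
    rng <- range(c(dates))
    keep_years <- vapply(unique(df$season_year), function(y) {
      s <- if (hemisphere == "N") as.Date(sprintf("%d-01-01", y)) else
        as.Date(sprintf("%d-07-01", y))
      s >= rng[1] && (s + 360) <= rng[2] # allow a few trailing missing days
    }, logical(1))
    df <- df[df$season_year %in% unique(df$season_year)[keep_years], ]
  }
  if (nrow(df) == 0) stop("no complete season year in the series", call. = FALSE)

  full <- tidyr::expand_grid(season_year = sort(unique(df$season_year)),
                             day_index = 1:365)
  full <- dplyr::left_join(full, df, by = c("season_year", "day_index"))
  coverage <- dplyr::summarise(dplyr::group_by(full, .data$season_year),
                               n_missing = sum(is.na(.data$value)),
                               .groups = "drop")
  bad <- coverage$season_year[coverage$n_missing > max_missing_frac * 365]
  if (length(bad) > 0) {
    warning("season year(s) excluded for missing data: ",
            paste(bad, collapse = ", "), call. = FALSE)
    full <- full[!full$season_year %in% bad, ]
    coverage <- coverage[!coverage$season_year %in% bad, ]
  }
  full <- dplyr::mutate(dplyr::group_by(full, .data$season_year),
                        cumulative = cumsum(ifelse(is.na(.data$value), 0,
                                                   .data$value)))
  full <- dplyr::ungroup(full)
  attr(full, "coverage") <- coverage
  attr(full, "hemisphere") <- hemisphere
  full
}

#' Climatological mean cumulative curve
#'
#' Day-wise arithmetic mean of the per-year cumulative curves.
#'
#' @param curves Output of [season_year_split()] (or any tibble with
#'   `season_year`, `day_index`, `cumulative`).
#' @return Tibble with `day_index`, `cumulative` (the mean curve) and
#'   `n_years`.
#' @export
climatological_mean <- function(curves) {
  stopifnot(is.data.frame(curves),
            all(c("season_year", "day_index", "cumulative") %in% names(curves)))
  ny <- length(unique(curves$season_year))
  if (ny < 2) stop("need >= 2 season years for a climatology", call. = FALSE)
  days <- table(curves$season_year)
  if (length(unique(as.integer(days))) != 1) {
    stop("mismatched day grids across season years", call. = FALSE)
  }
  out <- dplyr::summarise(dplyr::group_by(curves, .data$day_index),
                          cumulative = mean(.data$cumulative),
                          .groups = "drop")
  out$n_years <- ny
  dplyr::arrange(out, .data$day_index)
}

#' Fractional accumulation window of a cumulative curve
#'
#' Characterizes seasonality as the time a climatological cumulative curve
#' takes to accumulate the central `fraction` of its annual total: the 50\%
#' window runs from the 25\% to the 75\% crossing of the maximum value, the
#' 80\% window from 10\% to 90\%. Crossing days are found by linear
#' interpolation between the daily points of the curve (with an implicit
#' origin at day 0, cumulative 0); a short window means forcing is
#' concentrated in a small part of the year.
#'
#' For signed forcing (e.g. zonal wind stress) the net cumulative curve may
#' be non-monotone; the first crossing of each threshold is used and a
#' `monotone` flag is returned.
#'
#' @param mean_curve Tibble with `day_index` and `cumulative` (e.g. from
#'   [climatological_mean()]), or a numeric cumulative vector on days
#'   1..365.
#' @param fraction Central accumulated fraction, typically 0.5 or 0.8.
#' @return Tibble with `fraction`, `start_day`, `end_day`, `length_days`,
#'   `monotone`. Days are reported at 0.1-day resolution.
#' @export
accumulation_window <- function(mean_curve, fraction = 0.5) {
  if (is.data.frame(mean_curve)) {
    stopifnot(all(c("day_index", "cumulative") %in% names(mean_curve)))
    mean_curve <- dplyr::arrange(mean_curve, .data$day_index)
    cum <- mean_curve$cumulative
    day <- mean_curve$day_index
  } else {
    cum <- as.numeric(mean_curve)
    day <- seq_along(cum)
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  total <- cum[length(cum)]
  if (!is.finite(total) || total <= 0) {
    stop("undefined window: final accumulation must be > 0", call. = FALSE)
  }
  monotone <- !is.unsorted(cum)
  lo_thr <- (1 - fraction) / 2 * total
  hi_thr <- (1 + fraction) / 2 * total
  # curve starts at (day0, 0) where day0 = first day - 1
  d <- c(day[1] - 1, day)
  v <- c(0, cum)
  cross <- function(thr) {
    k <- which(v >= thr)[1]
    if (is.na(k)) return(NA_real_)
    if (k == 1) return(d[1])
    d[k - 1] + (thr - v[k - 1]) / (v[k] - v[k - 1]) * (d[k] - d[k - 1])
  }
  lo_cross <- cross(lo_thr)
  hi_cross <- cross(hi_thr)
  # report at 0.1-day resolution (half-up); the length is rounded from the
  # exact crossing difference, not from the rounded endpoints
  rnd <- function(x) floor(x * 10 + 0.5) / 10
  tibble::tibble(fraction = fraction, start_day = rnd(lo_cross),
                 end_day = rnd(hi_cross),
                 length_days = rnd(hi_cross - lo_cross),
                 monotone = monotone)
}

#' SST-difference upwelling index
#'
#' Daily upwelling index as the temperature difference between an offshore
#' and a nearshore location: under the default convention the index is
#' `offshore - nearshore`, positive when the nearshore water is colder
#' (active upwelling). Set `positive_when_nearshore_colder = FALSE` for the
#' reversed sign.
#'
#' @param dates Date vector shared by both series.
#' @param nearshore_sst,offshore_sst Numeric SST series, deg C.
#' @param positive_when_nearshore_colder Sign convention flag
#'   (default TRUE).
#' @return Tibble with `date` and `value` (deg C difference).
#' @export
upwelling_index_sst <- function(dates, nearshore_sst, offshore_sst,
                                positive_when_nearshore_colder = TRUE) {
  if (length(nearshore_sst) != length(offshore_sst) ||
      length(dates) != length(nearshore_sst)) {
    stop("date mismatch: series must share one date vector", call. = FALSE)
  }
  v <- offshore_sst - nearshore_sst
  if (!positive_when_nearshore_colder) v <- -v
  tibble::tibble(date = dates, value = v)
}

#' Box average of a gridded field
#'
#' Unweighted mean over grid cells whose centres fall inside a closed
#' latitude/longitude box, per time step. Missing cells are excluded from
#' each day's mean. The input is the long-format (time, lat, lon, value)
#' table that ERDDAP CSV exports produce.
#'
#' @param grid Data frame with columns `time`, `lat`, `lon`, `value`.
#' @param lat_range,lon_range Numeric length-2 bounds (closed box, any
#'   order).
#' @return Tibble with `time` and `value` (daily box mean).
#' @export
box_average <- function(grid, lat_range, lon_range) {
  stopifnot(is.data.frame(grid),
            all(c("time", "lat", "lon", "value") %in% names(grid)))
  latr <- sort(lat_range); lonr <- sort(lon_range)
  inside <- grid$lat >= latr[1] & grid$lat <= latr[2] &
    grid$lon >= lonr[1] & grid$lon <= lonr[2]
  if (!any(inside)) stop("empty intersection: no grid cell centres in box",
                         call. = FALSE)
  sub <- grid[inside, ]
  dplyr::summarise(dplyr::group_by(sub, .data$time),
                   value = mean(.data$value, na.rm = TRUE),
                   .groups = "drop")
}

#' Monthly climatology
#'
#' Mean per calendar month across years (e.g. for monthly chlorophyll-a),
#' plus the per-year monthly traces used for plotting.
#'
#' @param dates Date vector (one entry per month of data).
#' @param values Numeric monthly values.
#' @return List with `climatology` (tibble: month 1..12, mean, n_years)
#'   and `by_year` (tibble: year, month, value).
#' @export
monthly_climatology <- function(dates, values) {
  stopifnot(inherits(dates, "Date"), length(dates) == length(values))
  if (length(dates) < 12) stop("need >= 12 months of data", call. = FALSE)
  by_year <- tibble::tibble(
    year = as.integer(format(dates, "%Y")),
    month = as.integer(format(dates, "%m")),
    value = values
  )
  clim <- dplyr::summarise(dplyr::group_by(by_year, .data$month),
                           mean = mean(.data$value, na.rm = TRUE),
                           n_years = sum(!is.na(.data$value)),
                           .groups = "drop")
  list(climatology = dplyr::arrange(clim, .data$month), by_year = by_year)
}

#' Salinity-chlorophyll Pearson correlation
#'
#' Pearson product-moment correlation between two date-aligned series
#' (e.g. sea surface salinity and chlorophyll-a), with the two-sided
#' p-value from [stats::cor.test()].
#'
#' @param x,y Numeric series, aligned on the same dates; `NA` pairs are
#'   dropped.
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
salinity_chl_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("series must be date-aligned (equal length)",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 aligned, non-missing pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in a series", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
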