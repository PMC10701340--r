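#' Population specification for the morphology simulator
#'
#' Defines the generative truth for one whale population: total length
#' distribution, standardized (fraction-of-TL) means and SDs for the skull
#' and fluke measures, a BAI target, and per-measurement allometric slopes
#' (slope 1 = isometry).
#'
#' @param label Population label.
#' @param n_whales Number of whales.
#' @param tl_mean,tl_sd Total length mean and SD, metres.
#' @param std_means Named vector of standardized means (fractions of TL)
#'   for `RB`, `JL`, `EE`, `Tail`, `Fs`, `Fw`; each in (0, 1).
#' @param std_sds Named vector of standardized SDs, same names.
#' @param bai_mean,bai_sd BAI target mean and SD (unitless).
#' @param slopes Named vector of allometric slopes, same names as
#'   `std_means` (default all 1).
#' @return List of class `population_spec`.
#' @export
population_spec <- function(label, n_whales, tl_mean, tl_sd,
                            std_means, std_sds, bai_mean, bai_sd,
                            slopes = NULL) {
  meas <- c("RB", "JL", "EE", "Tail", "Fs", "Fw")
  stopifnot(all(meas %in% names(std_means)), all(meas %in% names(std_sds)))
  if (any(std_means[meas] <= 0) || any(std_means[meas] >= 1)) {
    stop("standardized means must be in (0, 1)", call. = FALSE)
  }
  if (any(std_sds[meas] < 0) || tl_sd < 0 || bai_sd < 0) {
    stop("SDs must be >= 0", call. = FALSE)
  }
  if (is.null(slopes)) slopes <- stats::setNames(rep(1, length(meas)), meas)
  structure(list(label = label, n_whales = as.integer(n_whales),
                 tl_mean = tl_mean, tl_sd = tl_sd,
                 std_means = std_means[meas], std_sds = std_sds[meas],
                 bai_mean = bai_mean, bai_sd = bai_sd,
                 slopes = slopes[meas]),
            class = "population_spec")
}

#' Default three-population specifications
#'
#' Illustrative presets for three blue whale populations feeding in
#' seasonally contrasting coastal systems: a migratory eastern-boundary
#' upwelling population ("ENP", n = 31), a resident population in a
#' low-seasonality bight ("NZ", n = 17), and a migratory Patagonian
#' population ("Chile", n = 15). Total lengths centre near 22 m in all
#' three; the resident population carries higher body condition
#' (BAI gap about 1.3 over ENP) and slightly larger standardized skull
#' and fluke measures (gaps of order 0.01), while the Patagonian
#' population has the longest standardized tail. The magnitudes are
#' chosen to be field-plausible for desk-scale simulation, not
#' reproductions of any measured population.
#'
#' @return Named list of three [population_spec()] objects.
#' @export
default_population_specs <- function() {
  sds <- c(RB = 0.010, JL = 0.010, EE = 0.006, Tail = 0.012,
           Fs = 0.012, Fw = 0.005)
  base <- c(RB = 0.200, JL = 0.220, EE = 0.100, Tail = 0.250,
            Fs = 0.220, Fw = 0.065)
  list(
    ENP = population_spec("ENP", 31, tl_mean = 22.36, tl_sd = 1.5,
                          std_means = base, std_sds = sds,
                          bai_mean = 18.6, bai_sd = 1.0),
    NZ = population_spec("NZ", 17, tl_mean = 21.87, tl_sd = 1.5,
                         std_means = base + c(RB = 0.012, JL = 0.018,
                                              EE = 0.011, Tail = 0.005,
                                              Fs = 0.015, Fw = 0.005),
                         std_sds = sds, bai_mean = 19.94, bai_sd = 1.0),
    Chile = population_spec("Chile", 15, tl_mean = 21.93, tl_sd = 1.5,
                            std_means = base + c(RB = 0.010, JL = 0.010,
                                                 EE = 0.009, Tail = 0.012,
                                                 Fs = 0.004, Fw = 0.001),
                            std_sds = sds, bai_mean = 18.26, bai_sd = 1.0)
  )
}

# Smooth dorsal width profile: an ellipse-like shape over the body axis,
# returned as fractions of TL at the 19 standard stations, scaled so the
# record's BAI equals `bai` exactly.
.width_profile_for_bai <- function(bai, head_tail_range = c(0.20, 0.90)) {
  s <- width_stations()
  g <- sqrt(pmax(0, 1 - (2 * s - 1)^2)) # unit semi-elliptical shape
  # BAI of widths c*g*TL: SA = TL^2 * c * trapz(g over in-range stations)
  lo <- head_tail_range[1]; hi <- head_tail_range[2]
  keep <- s >= lo - 1e-9 & s <= hi + 1e-9
  x <- s[keep]; gk <- g[keep]
  a_g <- sum(diff(x) * (utils::head(gk, -1) + utils::tail(gk, -1)) / 2)
  c_scale <- bai * (hi - lo)^2 / (100 * a_g)
  c_scale * g
}

#' Simulate true whale morphology
#'
#' Draws whales from a set of population specifications. TL is Normal per
#' population; each part follows the allometric relation
#' `measurement = a * TL^slope` with lognormal scatter, where `a` is set so
#' the standardized value at the population's mean TL equals the spec mean.
#' Draws violating anatomical bounds (part >= whole, or non-positive) are
#' rejected and resampled; the rejection count is reported as an attribute.
#' Widths follow a smooth elliptical profile scaled so each whale's BAI is
#' Normal(bai_mean, bai_sd).
#'
#' @param specs A list of [population_spec()]s
#'   (default [default_population_specs()]).
#' @param seed Integer seed.
#' @return Tibble with one row per whale: `whale_id`, `population`, `TL`,
#'   the six measurements in metres, `BAI`, and the 19 width columns
#'   `w05`...`w95` (metres). Attribute `n_rejected` counts resampled draws.
#' @export
simulate_morphology <- function(specs = default_population_specs(), seed = 1) {
  set.seed(seed)
  meas <- c("RB", "JL", "EE", "Tail", "Fs", "Fw")
  n_rejected <- 0L
  rows <- lapply(specs, function(sp) {
    stopifnot(inherits(sp, "population_spec"))
    n <- sp$n_whales
    tl <- stats::rnorm(n, sp$tl_mean, sp$tl_sd)
    while (any(bad <- tl <= 5)) { # whales shorter than 5 m are rejected
      n_rejected <<- n_rejected + sum(bad)
      tl[bad] <- stats::rnorm(sum(bad), sp$tl_mean, sp$tl_sd)
    }
    out <- tibble::tibble(
      whale_id = sprintf("%s_%02d", sp$label, seq_len(n)),
      population = sp$label, TL = tl
    )
    for (m in meas) {
      slope <- sp$slopes[[m]]
      a <- sp$std_means[[m]] * sp$tl_mean^(1 - slope)
      mu <- a * tl^slope
      cv <- sp$std_sds[[m]] / sp$std_means[[m]]
      sdlog <- sqrt(log(1 + cv^2))
      v <- mu * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
      while (any(bad <- v <= 0 | v >= tl)) {
        n_rejected <<- n_rejected + sum(bad)
        v[bad] <- mu[bad] * stats::rlnorm(sum(bad), -sdlog^2 / 2, sdlog)
      }
      out[[m]] <- v
    }
    bai <- stats::rnorm(n, sp$bai_mean, sp$bai_sd)
    while (any(bad <- bai <= 0)) {
      n_rejected <<- n_rejected + sum(bad)
      bai[bad] <- stats::rnorm(sum(bad), sp$bai_mean, sp$bai_sd)
    }
    out$BAI <- bai
    wfrac <- t(vapply(bai, .width_profile_for_bai, numeric(19)))
    w <- wfrac * tl
    colnames(w) <- names(width_stations())
    dplyr::bind_cols(out, tibble::as_tibble(w))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Default UAS platform presets
#'
#' Flight metadata and known-sized calibration objects for three platform
#' archetypes used in blue whale photogrammetry campaigns: a small
#' hexacopter calibrated against a research vessel (18.62 m), a pair of
#' hexacopters calibrated against floating boards (1.48 m, 1.27 m), and a
#' consumer quadcopter calibrated against vessel-mounted and floating
#' boards (4.41 m, 2.00 m).
#'
#' @return Tibble with one row per platform: `platform_id`, `altitude`,
#'   `focal_length`, `sensor_width`, `image_width`, `image_height`,
#'   `altimeter`, and a list-column `known_sizes` (metres).
#' @export
default_platforms <- function() {
  tibble::tibble(
    platform_id = c("APH22", "LemHexAlta", "P4S"),
    altitude = c(40, 45, 35),
    focal_length = c(25, 35, 8.8),
    sensor_width = c(17.3, 23.5, 13.2),
    image_width = c(4608, 6000, 5472),
    image_height = c(3456, 4000, 3648),
    altimeter = c("barometer", "laser", "barometer"),
    known_sizes = list(c(18.62), c(1.48, 1.27), c(4.41, 2.00))
  )
}

#' Simulate UAS observation of true morphology
#'
#' Passes true metric morphology through a platform measurement-error model
#' (`observed = true * (1 + b) + Normal(0, sigma^2)` independently per
#' measurement), converts to pixels with the flight's ground sampling
#' distance, and emits matching calibration observations of the platform's
#' known-sized objects under the same error model.
#'
#' @param truth Tibble from [simulate_morphology()] (or same shape).
#' @param platform One row of [default_platforms()] (or same columns).
#' @param b Proportional bias of the platform.
#' @param sigma Additive measurement scatter, metres (>= 0).
#' @param n_calibration Number of calibration measurements to emit
#'   (cycled over the platform's known object sizes).
#' @param quality_probs Probabilities of quality scores 1, 2, 3
#'   (default `c(0.7, 0.25, 0.05)`). Scores are drawn independently for
#'   each named measurement; the width stations share a single per-image
#'   body-condition score, mirroring how images are ranked in practice.
#' @param seed Integer seed.
#' @return List with `records` (long tibble: whale_id, image_id,
#'   population, platform_id, flight metadata, measurement, value (px),
#'   unit, quality, is_calf) and `calibrations` (tibble: platform_id,
#'   known_m, measured_m, altitude, altimeter).
#' @export
simulate_uas_observation <- function(truth, platform, b = 0, sigma = 0,
                                     n_calibration = 50,
                                     quality_probs = c(0.7, 0.25, 0.05),
                                     seed = 1) {
  stopifnot(sigma >= 0, is.data.frame(truth))
  set.seed(seed)
  meas_cols <- c("TL", "RB", "JL", "EE", "Tail", "Fs", "Fw",
                 names(width_stations()))
  meas_cols <- intersect(meas_cols, names(truth))
  gsd <- ground_sampling_distance(platform$altitude, platform$focal_length,
                                  platform$sensor_width, platform$image_width)
  long <- tidyr::pivot_longer(
    truth[, c("whale_id", "population", meas_cols)],
    dplyr::all_of(meas_cols), names_to = "measurement", values_to = "true_m"
  )
  observed_m <- long$true_m * (1 + b) +
    stats::rnorm(nrow(long), 0, sigma)
  # named measurements are scored individually; all width stations of an
  # image share one body-condition score
  is_width <- long$measurement %in% names(width_stations())
  quality <- integer(nrow(long))
  quality[!is_width] <- sample(1:3, sum(!is_width), replace = TRUE,
                               prob = quality_probs)
  whales <- unique(long$whale_id)
  bc_score <- stats::setNames(
    sample(1:3, length(whales), replace = TRUE, prob = quality_probs), whales)
  quality[is_width] <- bc_score[long$whale_id[is_width]]
  records <- tibble::tibble(
    whale_id = long$whale_id,
    image_id = paste0(long$whale_id, "_img1"),
    population = long$population,
    platform_id = platform$platform_id,
    altitude = platform$altitude,
    focal_length = platform$focal_length,
    sensor_width = platform$sensor_width,
    image_width = platform$image_width,
    image_height = platform$image_height,
    altimeter = platform$altimeter,
    measurement = long$measurement,
    value = observed_m / gsd,
    unit = "px",
    quality = quality,
    is_calf = FALSE
  )
  sizes <- rep_len(unlist(platform$known_sizes), n_calibration)
  calibrations <- tibble::tibble(
    platform_id = platform$platform_id,
    known_m = sizes,
    measured_m = sizes * (1 + b) + stats::rnorm(n_calibration, 0, sigma),
    altitude = platform$altitude,
    altimeter = platform$altimeter
  )
  list(records = records, calibrations = calibrations)
}

#' Forcing specification for the daily-series simulator
#'
#' @param n_years Number of season years (>= 1).
#' @param base Constant daily baseline.
#' @param amplitude Multiplier on the seasonal (von Mises density) shape.
#' @param kappa Seasonal concentration (0 = flat year; larger = forcing
#'   concentrated around `peak_day`).
#' @param peak_day Day of the season year (1..365) of peak forcing.
#' @param noise_sd Daily Gaussian noise SD (>= 0).
#' @param hemisphere `"N"` or `"S"` (sets the season-year convention tag
#'   and the calendar start of generated dates).
#' @param start_year First calendar year of the series.
#' @return List of class `forcing_spec`.
#' @export
forcing_spec <- function(n_years = 10, base = 0.2, amplitude = 10,
                         kappa = 1, peak_day = 182, noise_sd = 0,
                         hemisphere = c("N", "S"), start_year = 2010) {
  hemisphere <- match.arg(hemisphere)
  if (n_years < 1) stop("n_years must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_years = as.integer(n_years), base = base,
                 amplitude = amplitude, kappa = kappa, peak_day = peak_day,
                 noise_sd = noise_sd, hemisphere = hemisphere,
                 start_year = as.integer(start_year)),
            class = "forcing_spec")
}

#' von Mises density on the 365-day year
#'
#' Seasonal intensity shape: the circular von Mises density with
#' concentration `kappa`, mapped onto days 1..365 and normalized so it
#' integrates to 1 over the year (i.e. a daily probability mass when
#' multiplied by 1 day).
#'
#' @param day Day of year (numeric, may be fractional).
#' @param peak_day Location of the peak.
#' @param kappa Concentration (>= 0; 0 gives the uniform 1/365).
#' @return Density per day.
#' @export
von_mises_day_density <- function(day, peak_day, kappa) {
  theta <- 2 * pi * (day - peak_day) / 365
  exp(kappa * cos(theta)) / (2 * pi * besselI(kappa, 0)) * (2 * pi / 365)
}

#' Simulate a daily forcing series with tunable seasonality
#'
#' Daily value = `base + amplitude * vonMises(day; peak_day, kappa)
#' + Normal(0, noise_sd^2)`, over `n_years` consecutive season years on a
#' real calendar (leap days receive the 28 February intensity and are
#' dropped again by [season_year_split()]).
#'
#' @param spec A [forcing_spec()].
#' @param seed Integer seed.
#' @return Tibble with `date`, `value`, and attributes `hemisphere` and
#'   `spec`.
#' @export
simulate_forcing <- function(spec = forcing_spec(), seed = 1) {
  stopifnot(inherits(spec, "forcing_spec"))
  set.seed(seed)
  start <- if (spec$hemisphere == "N") {
    as.Date(sprintf("%d-01-01", spec$start_year))
  } else {
    as.Date(sprintf("%d-07-01", spec$start_year))
  }
  end <- if (spec$hemisphere == "N") {
    as.Date(sprintf("%d-12-31", spec$start_year + spec$n_years - 1L))
  } else {
    as.Date(sprintf("%d-06-30", spec$start_year + spec$n_years))
  }
  dates <- seq(start, end, by = "day")
  # day-of-season-year on the 365-day grid
  doy <- as.integer(format(dates, "%j"))
  leap <- format(dates, "%m-%d") == "02-29"
  doy[doy > 59 & .is_leap(as.integer(format(dates, "%Y")))] <-
    doy[doy > 59 & .is_leap(as.integer(format(dates, "%Y")))] - 1L
  doy[leap] <- 59L # leap day carries the 28 Feb intensity
  if (spec$hemisphere == "S") {
    doy <- ifelse(doy >= 182, doy - 181L, doy + 184L)
  }
  value <- spec$base +
    spec$amplitude * von_mises_day_density(doy, spec$peak_day, spec$kappa) +
    stats::rnorm(length(dates), 0, spec$noise_sd)
  out <- tibble::tibble(date = dates, value = value)
  attr(out, "hemisphere") <- spec$hemisphere
  attr(out, "spec") <- spec
  out
}

.is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Emit a full synthetic bundle
#'
#' Generates the complete set of inputs the pipeline consumes — true
#' morphology, per-platform UAS observations and calibration objects, and
#' three daily forcing regions with contrasting seasonal concentration —
#' with ground truth always attached.
#'
#' @param specs Population specifications (default
#'   [default_population_specs()]); populations are assigned to the default
#'   platforms in order, recycled.
#' @param b,sigma Per-platform bias and scatter; scalars or vectors
#'   recycled over platforms. Defaults `b = 0.02`, `sigma = 0.05` m.
#' @param forcing_kappas Named vector of seasonal concentrations for the
#'   generated forcing regions (default
#'   `c(Monterey = 3, STB = 0.5, Corcovado = 0.3)` — one strongly seasonal
#'   eastern-boundary system and two weakly seasonal ones).
#' @param n_calibration Calibration objects per platform (default 50).
#' @param noise_sd Daily forcing noise SD (default 0.05).
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, the bundle is also
#'   written as CSV files.
#' @return List with `truth`, `records`, `calibrations`, `forcing`
#'   (named list of daily series), and `platform_truth` (tibble of the
#'   generative b and sigma per platform).
#' @export
simulate_bundle <- function(specs = default_population_specs(),
                            b = 0.02, sigma = 0.05,
                            forcing_kappas = c(Monterey = 3, STB = 0.5,
                                               Corcovado = 0.3),
                            n_calibration = 50, noise_sd = 0.05, seed = 1,
                            out_dir = NULL) {
  truth <- simulate_morphology(specs, seed = seed)
  platforms <- default_platforms()
  np <- nrow(platforms)
  b <- rep_len(b, np); sigma <- rep_len(sigma, np)
  pops <- names(specs)
  plat_of_pop <- rep_len(seq_len(np), length(pops))
  records <- list(); calibrations <- list()
  for (i in seq_along(pops)) {
    j <- plat_of_pop[i]
    sim <- simulate_uas_observation(
      truth[truth$population == pops[i], ], platforms[j, ],
      b = b[j], sigma = sigma[j], n_calibration = n_calibration,
      seed = seed + 100 + i
    )
    records[[i]] <- sim$records
    calibrations[[i]] <- sim$calibrations
  }
  hemis <- c(Monterey = "N", STB = "S", Corcovado = "S")
  forcing <- lapply(seq_along(forcing_kappas), function(i) {
    nm <- names(forcing_kappas)[i]
    h <- if (nm %in% names(hemis)) hemis[[nm]] else "N"
    simulate_forcing(
      forcing_spec(n_years = 10, kappa = forcing_kappas[[i]],
                   peak_day = 182, noise_sd = noise_sd, hemisphere = h),
      seed = seed + 200 + i
    )
  })
  names(forcing) <- names(forcing_kappas)
  out <- list(
    truth = truth,
    records = dplyr::bind_rows(records),
    calibrations = dplyr::bind_rows(calibrations),
    forcing = forcing,
    platform_truth = tibble::tibble(platform_id = platforms$platform_id,
                                    b = b, sigma = sigma)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    utils::write.csv(out$records, file.path(out_dir, "records.csv"),
                     row.names = FALSE)
    utils::write.csv(out$calibrations,
                     file.path(out_dir, "calibrations.csv"), row.names = FALSE)
    utils::write.csv(out$platform_truth,
                     file.path(out_dir, "platform_truth.csv"),
                     row.names = FALSE)
    for (nm in names(forcing)) {
      df <- forcing[[nm]]
      df$hemisphere <- attr(forcing[[nm]], "hemisphere")
      utils::write.csv(df, file.path(out_dir, paste0("forcing_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}
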