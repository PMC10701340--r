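#' Run configuration
#'
#' Assembles all stage options for the end-to-end pipelines. Defaults
#' mirror the full analysis: 1e6 ANOVA replicates, 95% HPDI, BAI over the
#' 20-90% body range, accumulation fractions 0.5 and 0.8.
#'
#' @param seed Master integer seed; every stochastic stage derives its
#'   seed from it.
#' @param n_reps Monte Carlo ANOVA replicates.
#' @param hpdi_prob HPDI probability mass.
#' @param head_tail_range BAI integration range.
#' @param max_images_per_whale Image cap in [filter_records()].
#' @param n_draws Posterior predictive draws per image.
#' @param window_fractions Accumulation fractions for the ocean pipeline.
#' @param measurements Measurements compared by the Monte Carlo ANOVA
#'   (`TL` and `BAI` on their natural scales; the others standardized).
#' @param out_dir Optional output directory for CSV summaries.
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1, n_reps = 1e6, hpdi_prob = 0.95,
                       head_tail_range = c(0.20, 0.90),
                       max_images_per_whale = 5, n_draws = 2000,
                       window_fractions = c(0.5, 0.8),
                       measurements = c("TL", "BAI", "RB_std", "JL_std",
                                        "EE_std", "Tail_std", "Fs_std"),
                       out_dir = NULL) {
  structure(list(seed = as.integer(seed), n_reps = n_reps,
                 hpdi_prob = hpdi_prob, head_tail_range = head_tail_range,
                 max_images_per_whale = max_images_per_whale,
                 n_draws = n_draws, window_fractions = window_fractions,
                 measurements = measurements, out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}

.stage_error <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the morphology pipeline end to end
#'
#' Sequences quality filtering, pixel-to-metre conversion, per-platform
#' error-model calibration, posterior predictive summaries per whale,
#' Monte Carlo ANOVA population comparison, log-log allometry and a
#' Dixon's Q outlier screen, returning a result bundle with a
#' machine-readable run manifest.
#'
#' @param records Long digitized record table (see [filter_records()] and
#'   [convert_records()] for required columns), or a path to its CSV.
#' @param calibrations Calibration table (`platform_id`, `known_m`,
#'   `measured_m`), or a path to its CSV.
#' @param config A [run_config()].
#' @return List of class `morphology_result`: `posteriors` (per whale x
#'   measurement summaries), `anova` (contrast table + fits), `allometry`,
#'   `dixon`, `audit`, `error_models`, `manifest`.
#' @export
run_morphology_pipeline <- function(records, calibrations,
                                    config = run_config()) {
  if (is.character(records)) {
    if (!file.exists(records)) stop("input file not found: ", records,
                                    call. = FALSE)
    records <- tibble::as_tibble(utils::read.csv(records))
  }
  if (is.character(calibrations)) {
    if (!file.exists(calibrations)) stop("input file not found: ",
                                         calibrations, call. = FALSE)
    calibrations <- tibble::as_tibble(utils::read.csv(calibrations))
  }
  stages <- character(0)

  filt <- .stage_error("filter", filter_records(records,
                                                config$max_images_per_whale))
  stages <- c(stages, "filter")

  converted <- .stage_error("convert", convert_records(filt$records))
  per_image <- .stage_error("convert",
                            morphology_per_image(converted,
                                                 config$head_tail_range))
  stages <- c(stages, "convert")

  fits <- .stage_error("calibrate",
                       fit_error_models(calibrations, seed = config$seed))
  stages <- c(stages, "calibrate")

  posteriors <- .stage_error("posterior", {
    meas_cols <- intersect(c("TL", "RB", "JL", "EE", "Tail", "Fs", "Fw",
                             names(width_stations())),
                           names(per_image))
    rows <- lapply(seq_len(nrow(per_image)), function(i) {
      obs <- unlist(per_image[i, meas_cols])
      plat <- as.character(per_image$platform_id[i])
      if (!plat %in% names(fits)) {
        stop("missing calibration for platform: ", plat, call. = FALSE)
      }
      ps <- posterior_predict_image(obs, fits[[plat]],
                                    n_draws = config$n_draws,
                                    seed = config$seed + i,
                                    head_tail_range = config$head_tail_range)
      ps$whale_id <- per_image$whale_id[i]
      ps$image_id <- per_image$image_id[i]
      ps$population <- per_image$population[i]
      ps
    })
    combine_image_posteriors(dplyr::bind_rows(rows))
  })
  stages <- c(stages, "posterior")

  anova <- .stage_error("mc_anova", {
    keep <- posteriors[posteriors$measurement %in% config$measurements, ]
    mc_anova_table(keep, mc_config(n_reps = config$n_reps,
                                   hpdi_prob = config$hpdi_prob,
                                   seed = config$seed))
  })
  stages <- c(stages, "mc_anova")

  point <- tidyr::pivot_wider(posteriors[, c("whale_id", "population",
                                             "measurement", "posterior_mean")],
                              names_from = "measurement",
                              values_from = "posterior_mean")
  allom_meas <- intersect(c("RB", "JL", "EE", "Tail", "Fs", "Fw"),
                          names(point))
  allometry <- .stage_error("allometry", dplyr::bind_rows(lapply(
    unique(point$population), function(p) {
      sub <- point[point$population == p, ]
      dplyr::bind_rows(lapply(allom_meas, function(m) {
        dplyr::mutate(allometry_fit(sub[[m]], sub$TL),
                      population = p, measurement = m, .before = 1)
      }))
    })))
  stages <- c(stages, "allometry")

  dixon <- .stage_error("dixon", dplyr::bind_rows(lapply(
    unique(point$population), function(p) {
      sub <- point[point$population == p, ]
      dplyr::bind_rows(lapply(intersect(config$measurements,
                                        c(names(point))), function(m) {
        # samples outside 3..30 are outside the test's validity; record the
        # screen as not performed rather than aborting the pipeline
        d <- tryCatch(dixon_q(sub[[m]]), error = function(e) {
          list(statistic = NA_real_, critical = NA_real_, outlier = NA,
               performed = FALSE)
        })
        tibble::tibble(population = p, measurement = m,
                       statistic = d$statistic, critical = d$critical,
                       outlier = d$outlier, performed = d$performed)
      }))
    })))
  stages <- c(stages, "dixon")

  manifest <- list(
    pipeline = "morphology",
    seed = config$seed,
    n_reps = config$n_reps,
    hpdi_prob = config$hpdi_prob,
    stages = stages,
    n_whales = length(unique(posteriors$whale_id)),
    package_version = as.character(utils::packageVersion("whalemorph")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  out <- list(posteriors = posteriors, anova = anova, allometry = allometry,
              dixon = dixon, audit = filt$audit, error_models = fits,
              manifest = manifest)
  class(out) <- "morphology_result"
  if (!is.null(config$out_dir)) .write_morphology_outputs(out, config$out_dir)
  out
}

.write_morphology_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$posteriors,
                   file.path(out_dir, "posterior_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(result$anova$contrasts,
                   file.path(out_dir, "population_contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(result$allometry, file.path(out_dir, "allometry.csv"),
                   row.names = FALSE)
  utils::write.csv(result$dixon, file.path(out_dir, "dixon_screen.csv"),
                   row.names = FALSE)
  utils::write.csv(result$audit, file.path(out_dir, "filter_audit.csv"),
                   row.names = FALSE)
  manifest <- result$manifest
  manifest$stages <- paste(manifest$stages, collapse = ";")
  utils::write.csv(tibble::as_tibble(manifest),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Run the ocean (seasonality) pipeline
#'
#' For each region: season-year split, cumulative climatological mean and
#' fractional accumulation windows; optionally a monthly chlorophyll-a
#' climatology and a salinity-chlorophyll correlation when those series
#' are supplied.
#'
#' @param forcing Named list of regions; each element either a tibble with
#'   `date`, `value` (and attribute or column `hemisphere`) or a path to
#'   such a CSV.
#' @param hemispheres Named character vector (`"N"`/`"S"`) per region;
#'   used when a series does not carry its own hemisphere.
#' @param chl Optional tibble/path with monthly `date`, `value`
#'   chlorophyll-a.
#' @param sss_chl Optional tibble/path with aligned daily `sss` and `chl`
#'   columns.
#' @param config A [run_config()].
#' @return List of class `ocean_result`: `climatologies` (per region),
#'   `windows` (tidy tibble), `chl_climatology`, `sss_chl`, `manifest`.
#' @export
run_ocean_pipeline <- function(forcing, hemispheres = NULL, chl = NULL,
                               sss_chl = NULL, config = run_config()) {
  stopifnot(is.list(forcing), !is.null(names(forcing)))
  forcing <- lapply(forcing, function(f) {
    if (is.character(f)) {
      if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
      tibble::as_tibble(utils::read.csv(f, colClasses = c(date = "Date")))
    } else f
  })
  regions <- names(forcing)
  climatologies <- list()
  windows <- list()
  for (r in regions) {
    f <- forcing[[r]]
    hemi <- attr(f, "hemisphere") %||%
      (if ("hemisphere" %in% names(f)) f$hemisphere[1] else NULL) %||%
      (if (!is.null(hemispheres)) hemispheres[[r]] else "N")
    curves <- .stage_error(paste0("season_split:", r),
                           season_year_split(f$date, f$value, hemi))
    clim <- .stage_error(paste0("climatology:", r),
                         climatological_mean(curves))
    climatologies[[r]] <- clim
    windows[[r]] <- dplyr::bind_rows(lapply(config$window_fractions,
                                            function(fr) {
      dplyr::mutate(accumulation_window(clim, fr), region = r, .before = 1)
    }))
  }
  windows <- dplyr::bind_rows(windows)

  chl_clim <- NULL
  if (!is.null(chl)) {
    if (is.character(chl)) {
      chl <- tibble::as_tibble(utils::read.csv(chl,
                                               colClasses = c(date = "Date")))
    }
    chl_clim <- .stage_error("chl_climatology",
                             monthly_climatology(chl$date, chl$value))
  }
  sss_cor <- NULL
  if (!is.null(sss_chl)) {
    if (is.character(sss_chl)) {
      sss_chl <- tibble::as_tibble(utils::read.csv(sss_chl))
    }
    sss_cor <- .stage_error("sss_chl",
                            salinity_chl_correlation(sss_chl$sss,
                                                     sss_chl$chl))
  }
  manifest <- list(
    pipeline = "ocean", seed = config$seed,
    regions = paste(regions, collapse = ";"),
    fractions = paste(config$window_fractions, collapse = ";"),
    package_version = as.character(utils::packageVersion("whalemorph")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  out <- list(climatologies = climatologies, windows = windows,
              chl_climatology = chl_clim, sss_chl = sss_cor,
              manifest = manifest)
  class(out) <- "ocean_result"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(windows,
                     file.path(config$out_dir, "accumulation_windows.csv"),
                     row.names = FALSE)
    for (r in regions) {
      utils::write.csv(climatologies[[r]],
                       file.path(config$out_dir,
                                 paste0("climatology_", r, ".csv")),
                       row.names = FALSE)
    }
  }
  out
}

#' Plot regional cumulative climatologies with accumulation windows
#'
#' A small report figure in the style of a per-region seasonality panel:
#' the climatological-mean cumulative forcing curve with the 50% (dark)
#' and wider (light) accumulation windows shaded.
#'
#' @param ocean_result An `ocean_result` from [run_ocean_pipeline()].
#' @param file Optional path; when given the figure is saved there.
#' @return The ggplot object, invisibly.
#' @export
plot_seasonality <- function(ocean_result, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  clim <- dplyr::bind_rows(lapply(names(ocean_result$climatologies),
                                  function(r) {
    dplyr::mutate(ocean_result$climatologies[[r]], region = r)
  }))
  win <- ocean_result$windows
  win$shade <- ifelse(win$fraction == min(win$fraction), "narrow", "wide")
  p <- ggplot2::ggplot(clim, ggplot2::aes(x = .data$day_index,
                                          y = .data$cumulative)) +
    ggplot2::geom_rect(data = win[win$shade == "wide", ],
                       ggplot2::aes(xmin = .data$start_day,
                                    xmax = .data$end_day),
                       ymin = -Inf, ymax = Inf, fill = "grey85",
                       inherit.aes = FALSE) +
    ggplot2::geom_rect(data = win[win$shade == "narrow", ],
                       ggplot2::aes(xmin = .data$start_day,
                                    xmax = .data$end_day),
                       ymin = -Inf, ymax = Inf, fill = "grey65",
                       inherit.aes = FALSE) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "Day of season year",
                  y = "Cumulative forcing (climatological mean)") +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 9, height = 3.2)
  invisible(p)
}
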