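#' Fit the per-platform photogrammetric error model
#'
#' Calibrates a measurement-error model for one UAS platform from images of
#' known-sized objects. The observation model is
#' \deqn{measured = true \times (1 + b) + \epsilon,\qquad
#'       \epsilon \sim N(0, \sigma^2),}
#' with a proportional bias \eqn{b} and additive scatter \eqn{\sigma}
#' (metres). Priors are weakly informative: \eqn{b \sim N(0, 0.1^2)} and
#' \eqn{\sigma \sim} Half-Normal with scale defaulting to 5\% of the median
#' known length. The joint posterior is evaluated on a dense
#' \eqn{b \times \sigma} grid and sampled i.i.d. (with within-cell jitter),
#' which is deterministic given `seed` and needs no convergence monitoring;
#' a boundary check guards against an under-sized grid.
#'
#' @param calibrations Data frame with columns `known_m` and `measured_m`
#'   (metres), one row per calibration measurement for a single platform.
#'   A `platform_id` column, if present, must be constant.
#' @param prior_b_sd Prior SD of the proportional bias (default 0.1).
#' @param sigma_prior_scale Half-Normal prior scale for \eqn{\sigma};
#'   default `0.05 * median(known_m)`.
#' @param n_samples Number of posterior draws to return (>= 1000).
#' @param grid_n Grid resolution per axis (default 301).
#' @param seed Integer seed; draws are reproducible given it.
#'
#' @return An object of class `platform_error_posterior`: a list with
#'   `samples` (tibble of `b`, `sigma` draws), `platform_id`, the prior
#'   settings, and the grid diagnostics.
#' @export
fit_error_model <- function(calibrations, prior_b_sd = 0.1,
                            sigma_prior_scale = NULL,
                            n_samples = 4000, grid_n = 301, seed = 1) {
  stopifnot(is.data.frame(calibrations))
  if (nrow(calibrations) < 1) {
    stop("missing calibration data: need >= 1 observation for the platform",
         call. = FALSE)
  }
  need <- c("known_m", "measured_m")
  miss <- setdiff(need, names(calibrations))
  if (length(miss) > 0) {
    stop("calibrations is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  k <- calibrations$known_m
  m <- calibrations$measured_m
  if (any(!is.finite(k)) || any(k <= 0) || any(!is.finite(m)) || any(m <= 0)) {
    stop("known_m and measured_m must be finite and > 0", call. = FALSE)
  }
  platform_id <- if ("platform_id" %in% names(calibrations)) {
    u <- unique(calibrations$platform_id)
    if (length(u) > 1) {
      stop("fit_error_model() fits one platform at a time; got: ",
           paste(u, collapse = ", "), call. = FALSE)
    }
    as.character(u)
  } else NA_character_
  if (n_samples < 1000) stop("n_samples must be >= 1000", call. = FALSE)
  if (is.null(sigma_prior_scale)) sigma_prior_scale <- 0.05 * stats::median(k)

  n <- length(k)
  # Least-squares centre of the b grid and a scatter scale for its span.
  b_hat <- sum(k * (m - k)) / sum(k^2)
  resid <- m - k * (1 + b_hat)
  s_resid <- max(stats::sd(resid), 1e-6 * stats::median(k))
  if (!is.finite(s_resid)) s_resid <- 1e-6 * stats::median(k)
  se_b <- s_resid / sqrt(sum(k^2))
  half_b <- max(8 * se_b, 0.02)
  b_grid <- seq(b_hat - half_b, b_hat + half_b, length.out = grid_n)
  sig_max <- max(4 * s_resid, 3 * sigma_prior_scale)
  sig_min <- sig_max / 1e4
  sigma_grid <- exp(seq(log(sig_min), log(sig_max), length.out = grid_n))

  # Log posterior on the grid. SSE(b) is quadratic in (1 + b).
  sum_m2 <- sum(m^2); sum_mk <- sum(m * k); sum_k2 <- sum(k^2)
  one_b <- 1 + b_grid
  sse_b <- sum_m2 - 2 * one_b * sum_mk + one_b^2 * sum_k2
  sse_b <- pmax(sse_b, 0)
  lp <- matrix(0, nrow = grid_n, ncol = grid_n) # rows b, cols sigma
  log_prior_b <- stats::dnorm(b_grid, 0, prior_b_sd, log = TRUE)
  log_prior_s <- stats::dnorm(sigma_grid, 0, sigma_prior_scale, log = TRUE) +
    log(sigma_grid) # half-normal on sigma; + log(sigma) Jacobian for the log grid
  for (j in seq_along(sigma_grid)) {
    s2 <- sigma_grid[j]^2
    lp[, j] <- -n * log(sigma_grid[j]) - sse_b / (2 * s2) +
      log_prior_b + log_prior_s[j]
  }
  lp <- lp - max(lp)
  post <- exp(lp)
  post <- post / sum(post)

  # Boundary diagnostic: posterior mass should not pile up on the grid edge
  # (the sigma lower edge is legitimately loaded when the data are
  # error-free, so only the outer edges are flagged).
  edge_mass <- sum(post[c(1, grid_n), ]) + sum(post[, grid_n])
  if (edge_mass > 0.01) {
    warning("posterior mass on the grid boundary (", signif(edge_mass, 2),
            "); widen the grid or priors", call. = FALSE)
  }

  set.seed(seed)
  idx <- sample.int(grid_n^2, n_samples, replace = TRUE, prob = as.numeric(post))
  bi <- ((idx - 1) %% grid_n) + 1
  sj <- ((idx - 1) %/% grid_n) + 1
  db <- b_grid[2] - b_grid[1]
  b_draw <- b_grid[bi] + stats::runif(n_samples, -db / 2, db / 2)
  # jitter sigma multiplicatively (log-spaced grid), keeping sigma > 0
  log_step <- log(sigma_grid[2]) - log(sigma_grid[1])
  s_draw <- sigma_grid[sj] * exp(stats::runif(n_samples, -log_step / 2, log_step / 2))

  structure(list(
    samples = tibble::tibble(b = b_draw, sigma = s_draw),
    platform_id = platform_id,
    n_calibrations = n,
    prior = list(b_sd = prior_b_sd, sigma_scale = sigma_prior_scale),
    grid = list(b_range = range(b_grid), sigma_range = range(sigma_grid),
                edge_mass = edge_mass),
    seed = seed
  ), class = "platform_error_posterior")
}

#' Fit error models for every platform in a calibration table
#'
#' @param calibrations Data frame with `platform_id`, `known_m`,
#'   `measured_m`.
#' @param seed Base seed; platform fits use `seed`, `seed + 1`, ...
#' @param ... Passed to [fit_error_model()].
#' @return Named list of `platform_error_posterior` objects.
#' @export
fit_error_models <- function(calibrations, seed = 1, ...) {
  stopifnot(is.data.frame(calibrations), "platform_id" %in% names(calibrations))
  platforms <- sort(unique(as.character(calibrations$platform_id)))
  out <- lapply(seq_along(platforms), function(i) {
    fit_error_model(calibrations[calibrations$platform_id == platforms[i], ],
                    seed = seed + i - 1, ...)
  })
  names(out) <- platforms
  out
}

#' @export
print.platform_error_posterior <- function(x, ...) {
  cat("Platform error posterior",
      if (!is.na(x$platform_id)) paste0("(", x$platform_id, ")"), "\n")
  cat(sprintf("  calibrations: %d\n", x$n_calibrations))
  cat(sprintf("  bias b:  mean %.4f, sd %.4f\n",
              mean(x$samples$b), stats::sd(x$samples$b)))
  cat(sprintf("  sigma:   mean %.4f m, sd %.4f m\n",
              mean(x$samples$sigma), stats::sd(x$samples$sigma)))
  invisible(x)
}

#' Posterior predictive distribution of a true measurement
#'
#' Inverts the platform error model for one observed photogrammetric
#' length: for each posterior draw \eqn{(b_j, \sigma_j)} an observation
#' error \eqn{\epsilon_j \sim N(0, \sigma_j^2)} is drawn and the true
#' length reconstructed as \eqn{(observed - \epsilon_j)/(1 + b_j)}. The
#' sample of reconstructions is the posterior predictive distribution of
#' the true value; its mean and variance parameterize the downstream
#' Monte Carlo ANOVA.
#'
#' @param observed Observed length, metres (scalar).
#' @param posterior A `platform_error_posterior`.
#' @param n_draws Number of predictive draws (>= 100).
#' @param seed Integer seed.
#' @param return_draws Keep the raw draws in the result?
#' @return List with `mean`, `variance`, `n_draws`, and (optionally)
#'   `draws`.
#' @export
posterior_predict <- function(observed, posterior, n_draws = 2000, seed = 1,
                              return_draws = FALSE) {
  stopifnot(inherits(posterior, "platform_error_posterior"),
            is.numeric(observed), length(observed) == 1, is.finite(observed))
  if (n_draws < 100) {
    stop("insufficient draws: n_draws must be >= 100", call. = FALSE)
  }
  set.seed(seed)
  ns <- nrow(posterior$samples)
  idx <- if (n_draws <= ns) sample.int(ns, n_draws) else
    sample.int(ns, n_draws, replace = TRUE)
  b <- posterior$samples$b[idx]
  s <- posterior$samples$sigma[idx]
  eps <- stats::rnorm(n_draws, 0, s)
  draws <- (observed - eps) / (1 + b)
  out <- list(mean = mean(draws), variance = stats::var(draws),
              n_draws = n_draws)
  if (return_draws) out$draws <- draws
  out
}

#' Posterior predictive summaries for a whale's full measurement set
#'
#' Applies the error model jointly to all measurements of one image:
#' posterior draws of (b, sigma) are shared across measurements (the
#' platform bias applies to the whole image) while the additive error is
#' drawn independently per measurement. Derived quantities — TL-standardized
#' measures and BAI — are computed per joint draw, so their uncertainty is
#' a genuine transformation of the joint length draws rather than a
#' first-order approximation.
#'
#' @param observed Named numeric vector of observed metric values for one
#'   image; must include `TL`, may include `RB`, `JL`, `EE`, `Tail`, `Fs`,
#'   `Fw` and width stations `w05`...`w95`.
#' @param posterior A `platform_error_posterior` for the image's platform.
#' @param n_draws Predictive draws (>= 100).
#' @param seed Integer seed.
#' @param head_tail_range BAI range, see [compute_bai()].
#' @return Tibble with columns `measurement`, `posterior_mean`,
#'   `posterior_variance`. Raw measurements are reported in metres;
#'   standardized measures are suffixed `_std`; `BAI` is unitless and
#'   present when the in-range width stations are.
#' @export
posterior_predict_image <- function(observed, posterior, n_draws = 2000,
                                    seed = 1,
                                    head_tail_range = c(0.20, 0.90)) {
  stopifnot(is.numeric(observed), !is.null(names(observed)))
  if (n_draws < 100) {
    stop("insufficient draws: n_draws must be >= 100", call. = FALSE)
  }
  observed <- observed[is.finite(observed)]
  if (length(observed) == 0) {
    stop("no finite measurements to predict from", call. = FALSE)
  }
  has_tl <- "TL" %in% names(observed)
  set.seed(seed)
  ns <- nrow(posterior$samples)
  idx <- sample.int(ns, n_draws, replace = n_draws > ns)
  b <- posterior$samples$b[idx]
  s <- posterior$samples$sigma[idx]
  draws <- vapply(names(observed), function(nm) {
    (observed[[nm]] - stats::rnorm(n_draws, 0, s)) / (1 + b)
  }, numeric(n_draws))
  colnames(draws) <- names(observed)

  out <- tibble::tibble(
    measurement = colnames(draws),
    posterior_mean = unname(colMeans(draws)),
    posterior_variance = unname(apply(draws, 2, stats::var))
  )

  # TL-standardized measures and BAI need a usable TL on this image
  std_measures <- if (has_tl) {
    intersect(c("RB", "JL", "EE", "Tail", "Fs"), colnames(draws))
  } else character(0)
  if (length(std_measures) > 0) {
    std <- draws[, std_measures, drop = FALSE] / draws[, "TL"]
    out <- dplyr::bind_rows(out, tibble::tibble(
      measurement = paste0(std_measures, "_std"),
      posterior_mean = unname(colMeans(std)),
      posterior_variance = unname(apply(std, 2, stats::var))
    ))
  }

  stations <- width_stations()
  lo <- head_tail_range[1]; hi <- head_tail_range[2]
  need <- names(stations)[stations >= lo - 1e-9 & stations <= hi + 1e-9]
  if (has_tl && all(need %in% colnames(draws))) {
    bai <- vapply(seq_len(n_draws), function(i) {
      compute_bai(draws[i, "TL"], draws[i, need], head_tail_range)
    }, numeric(1))
    out <- dplyr::bind_rows(out, tibble::tibble(
      measurement = "BAI",
      posterior_mean = mean(bai),
      posterior_variance = stats::var(bai)
    ))
  }
  out
}

#' Combine per-image posterior summaries into one per whale
#'
#' When a whale has several usable images, the per-image posterior
#' summaries are combined by averaging the posterior means and pooling the
#' variances as (mean of within-image variances) + (between-image variance
#' of the means). With a single image this is the identity.
#'
#' @param summaries Tibble with columns `whale_id`, `measurement`,
#'   `posterior_mean`, `posterior_variance` (one row per image x
#'   measurement); extra grouping columns (e.g. `population`) are carried
#'   through if constant within whale.
#' @return Tibble with one row per whale x measurement.
#' @export
combine_image_posteriors <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  extra <- setdiff(names(summaries),
                   c("whale_id", "image_id", "measurement",
                     "posterior_mean", "posterior_variance"))
  grouped <- dplyr::group_by(summaries, .data$whale_id, .data$measurement)
  out <- dplyr::summarise(
    grouped,
    dplyr::across(dplyr::all_of(extra), dplyr::first),
    n_images = dplyr::n(),
    pooled_mean = mean(.data$posterior_mean),
    pooled_variance = mean(.data$posterior_variance) +
      (if (dplyr::n() > 1) stats::var(.data$posterior_mean) *
         (dplyr::n() - 1) / dplyr::n() else 0),
    .groups = "drop"
  )
  dplyr::rename(out, posterior_mean = "pooled_mean",
                posterior_variance = "pooled_variance")
}
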