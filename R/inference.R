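#' Highest posterior density interval
#'
#' The shortest contiguous interval of the sorted sample containing
#' `ceiling(prob * n)` points; ties are broken by taking the earliest such
#' window.
#'
#' @param samples Numeric vector (length >= 2 after removing NA).
#' @param prob Probability mass, in (0, 1). Default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
hpdi <- function(samples, prob = 0.95) {
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 2) stop("hpdi needs >= 2 finite samples", call. = FALSE)
  if (!is.numeric(prob) || prob <= 0 || prob >= 1) {
    stop("prob must be in (0, 1)", call. = FALSE)
  }
  s <- sort(samples)
  m <- ceiling(prob * n)
  if (m >= n) return(c(s[1], s[n]))
  widths <- s[m:n] - s[1:(n - m + 1)]
  # earliest window among ties, with a relative tolerance so evenly spaced
  # samples (all windows equal up to floating error) resolve to the first
  tol <- max(abs(widths)) * 1e-12
  i <- which(widths <= min(widths) + tol)[1]
  c(s[i], s[i + m - 1])
}

#' Monte Carlo ANOVA configuration
#'
#' @param n_reps Number of ANOVA replicates (default 1e6, the full
#'   analysis scale; tests typically use 1e4).
#' @param hpdi_prob HPDI probability mass (default 0.95).
#' @param seed Integer seed.
#' @param coding `"cell_means"` (one coefficient per population, the
#'   default, so coefficient differences are group-mean contrasts) or
#'   `"reference"` (treatment coding against `reference_population`).
#' @param reference_population Reference level for `"reference"` coding;
#'   default the first population alphabetically.
#' @param block_size Replicates evaluated per vectorised block.
#' @return A list of class `mc_anova_config`.
#' @export
mc_config <- function(n_reps = 1e6, hpdi_prob = 0.95, seed = 1,
                      coding = c("cell_means", "reference"),
                      reference_population = NULL, block_size = 20000L) {
  if (!is.numeric(n_reps) || n_reps < 1) {
    stop("config error: n_reps must be >= 1", call. = FALSE)
  }
  if (hpdi_prob <= 0 || hpdi_prob >= 1) {
    stop("config error: hpdi_prob must be in (0, 1)", call. = FALSE)
  }
  structure(list(n_reps = as.integer(n_reps), hpdi_prob = hpdi_prob,
                 seed = as.integer(seed), coding = match.arg(coding),
                 reference_population = reference_population,
                 block_size = as.integer(block_size)),
            class = "mc_anova_config")
}

#' Monte Carlo ANOVA with propagated measurement uncertainty
#'
#' Compares one morphological measurement across populations while
#' propagating each whale's photogrammetric uncertainty. In every
#' replicate a value is drawn for each whale from
#' `Normal(posterior_mean, posterior_variance)` and a one-way ANOVA of
#' measurement on population is fitted (cell-means coding, whose
#' coefficients are exactly the per-population means of that replicate's
#' draws). The reported coefficients are averages over replicates; each
#' pairwise population contrast carries the HPDI of its replicate
#' distribution and is flagged significant when that interval excludes 0.
#' Draws are not truncated at zero (the Normal parameterization is used
#' as stated); any negative draws are counted and reported.
#'
#' @param data Data frame with columns `population`, `posterior_mean`,
#'   `posterior_variance`, one row per whale (optionally `whale_id`).
#' @param config An [mc_config()] list.
#' @return Object of class `mc_anova`: list with `coefficients` (tibble:
#'   population, estimate, lower, upper), `contrasts` (tibble: pair,
#'   difference, lower, upper, significant), `n_reps`, `hpdi_prob`,
#'   `n_negative_draws`, `seed`.
#' @export
mc_anova <- function(data, config = mc_config()) {
  stopifnot(is.data.frame(data))
  need <- c("population", "posterior_mean", "posterior_variance")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(data$posterior_variance < 0)) {
    stop("posterior_variance must be >= 0", call. = FALSE)
  }
  pop <- factor(data$population)
  counts <- table(pop)
  if (length(counts) < 2) {
    stop("degenerate design: need >= 2 populations", call. = FALSE)
  }
  if (any(counts < 2)) {
    stop("degenerate design: population(s) with < 2 whales: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  groups <- levels(pop)
  g <- length(groups)
  mu <- data$posterior_mean
  sdv <- sqrt(data$posterior_variance)
  n <- length(mu)
  reps <- config$n_reps
  pairs <- utils::combn(groups, 2)
  pair_names <- paste(pairs[2, ], pairs[1, ], sep = "-") # later level minus earlier

  coef_draws <- matrix(NA_real_, nrow = g, ncol = reps,
                       dimnames = list(groups, NULL))
  n_neg <- 0L
  set.seed(config$seed)
  done <- 0L
  while (done < reps) {
    b <- min(config$block_size, reps - done)
    draws <- matrix(stats::rnorm(n * b, mean = mu, sd = sdv), nrow = n)
    n_neg <- n_neg + sum(draws < 0)
    gm <- rowsum(draws, pop) / as.numeric(counts) # g x b group means
    coef_draws[, (done + 1):(done + b)] <- gm[groups, , drop = FALSE]
    done <- done + b
  }

  diff_draws <- coef_draws[pairs[2, ], , drop = FALSE] -
    coef_draws[pairs[1, ], , drop = FALSE]
  rownames(diff_draws) <- pair_names

  coef_hpdi <- t(apply(coef_draws, 1, hpdi, prob = config$hpdi_prob))
  contrast_hpdi <- t(apply(diff_draws, 1, hpdi, prob = config$hpdi_prob))

  coefficients <- tibble::tibble(
    population = groups,
    estimate = unname(rowMeans(coef_draws)),
    lower = unname(coef_hpdi[, 1]),
    upper = unname(coef_hpdi[, 2])
  )
  if (config$coding == "reference") {
    ref <- config$reference_population %||% groups[1]
    if (!ref %in% groups) stop("unknown reference population: ", ref,
                               call. = FALSE)
    shift <- coef_draws[ref, ]
    adj <- sweep(coef_draws, 2, shift)
    adj[ref, ] <- shift # intercept = reference mean, others = offsets
    coef_hpdi <- t(apply(adj, 1, hpdi, prob = config$hpdi_prob))
    coefficients <- tibble::tibble(
      population = ifelse(groups == ref, paste0("(Intercept:", ref, ")"),
                          groups),
      estimate = unname(rowMeans(adj)), lower = unname(coef_hpdi[, 1]),
      upper = unname(coef_hpdi[, 2])
    )
  }
  contrasts <- tibble::tibble(
    pair = pair_names,
    difference = unname(rowMeans(diff_draws)),
    lower = unname(contrast_hpdi[, 1]),
    upper = unname(contrast_hpdi[, 2])
  )
  contrasts$significant <- contrasts$lower > 0 | contrasts$upper < 0

  structure(list(coefficients = coefficients, contrasts = contrasts,
                 n_reps = reps, hpdi_prob = config$hpdi_prob,
                 n_negative_draws = n_neg, seed = config$seed),
            class = "mc_anova")
}

#' @export
print.mc_anova <- function(x, ...) {
  cat(sprintf("Monte Carlo ANOVA (%s replicates, %.0f%% HPDI)\n",
              format(x$n_reps, big.mark = ","), 100 * x$hpdi_prob))
  cat("Averaged coefficients:\n")
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 4)
  cat("Pairwise contrasts:\n")
  df <- as.data.frame(x$contrasts)
  df$significant <- ifelse(df$significant, "*", "")
  print(df, row.names = FALSE, digits = 4)
  if (x$n_negative_draws > 0) {
    cat(sprintf("note: %d negative draws occurred (not truncated)\n",
                x$n_negative_draws))
  }
  invisible(x)
}

#' Monte Carlo ANOVA over a table of measurements
#'
#' Runs [mc_anova()] for each distinct `measurement` in a long posterior
#' summary table and binds the contrasts into one tidy table (the shape of
#' a published population-comparison table).
#'
#' @param summaries Tibble with columns `measurement`, `population`,
#'   `posterior_mean`, `posterior_variance`.
#' @param config An [mc_config()].
#' @return List with `contrasts` (tibble with `measurement` column) and
#'   `fits` (named list of `mc_anova` objects).
#' @export
mc_anova_table <- function(summaries, config = mc_config()) {
  stopifnot(is.data.frame(summaries), "measurement" %in% names(summaries))
  meas <- unique(summaries$measurement)
  fits <- lapply(seq_along(meas), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    mc_anova(summaries[summaries$measurement == meas[i], ], cfg)
  })
  names(fits) <- meas
  contrasts <- dplyr::bind_rows(
    lapply(meas, function(m) {
      dplyr::mutate(fits[[m]]$contrasts, measurement = m, .before = 1)
    })
  )
  list(contrasts = contrasts, fits = fits)
}

#' Log-log allometric scaling fit
#'
#' Ordinary least squares of `log(measurement)` on `log(TL)`. A slope of 1
#' is isometry (proportional scaling with body length); slopes whose
#' confidence interval lies entirely above or below 1 are classified as
#' positive or negative allometry.
#'
#' @param measurement Positive numeric vector of point estimates, metres.
#' @param TL Positive numeric vector of total lengths, metres.
#' @param level Confidence level for the slope interval (default 0.95).
#' @return Tibble with `slope`, `intercept`, `slope_lower`, `slope_upper`,
#'   `classification`, `n`, `r_squared`.
#' @export
allometry_fit <- function(measurement, TL, level = 0.95) {
  if (length(measurement) != length(TL)) {
    stop("measurement and TL must have equal length", call. = FALSE)
  }
  ok <- is.finite(measurement) & is.finite(TL)
  measurement <- measurement[ok]; TL <- TL[ok]
  if (any(measurement <= 0) || any(TL <= 0)) {
    stop("log-domain error: all values must be > 0", call. = FALSE)
  }
  if (length(TL) < 3) stop("allometry_fit needs >= 3 whales", call. = FALSE)
  fit <- stats::lm(log(measurement) ~ log(TL))
  slope <- unname(stats::coef(fit)[2])
  ci <- suppressWarnings(stats::confint(fit, 2, level = level))
  lo <- ci[1]; hi <- ci[2]
  # Perfect (zero-residual) fits have an undefined t interval; the slope is
  # then known exactly.
  if (!is.finite(lo) || !is.finite(hi) || is.nan(lo)) { lo <- slope; hi <- slope }
  classification <- if (lo > 1) "positive allometry"
  else if (hi < 1) "negative allometry"
  else "isometry"
  tibble::tibble(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    slope_lower = lo, slope_upper = hi,
    classification = classification,
    n = length(TL),
    r_squared = suppressWarnings(summary(fit)$r.squared)
  )
}

# Two-tailed critical values for Dixon's r10 (classic Q) statistic,
# n = 3..30 (Rorabacher 1991, Anal. Chem. 63:139-146).
.dixon_critical <- local({
  tab <- cbind(
    `0.1` = c(0.941, 0.765, 0.642, 0.560, 0.507, 0.468, 0.437, 0.412,
              0.392, 0.376, 0.361, 0.349, 0.338, 0.329, 0.320, 0.313,
              0.306, 0.300, 0.295, 0.290, 0.285, 0.281, 0.277, 0.273,
              0.269, 0.266, 0.263, 0.260),
    `0.05` = c(0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466,
               0.444, 0.426, 0.410, 0.396, 0.384, 0.374, 0.365, 0.356,
               0.349, 0.342, 0.337, 0.331, 0.326, 0.321, 0.317, 0.312,
               0.308, 0.305, 0.301, 0.298),
    `0.01` = c(0.994, 0.926, 0.821, 0.740, 0.680, 0.634, 0.598, 0.568,
               0.542, 0.522, 0.503, 0.488, 0.475, 0.463, 0.452, 0.442,
               0.433, 0.425, 0.418, 0.411, 0.404, 0.399, 0.393, 0.388,
               0.384, 0.380, 0.376, 0.372)
  )
  rownames(tab) <- as.character(3:30)
  tab
})

#' Dixon's Q outlier test
#'
#' The classic r10 ratio for small samples (3 <= n <= 30): the gap between
#' the suspect extreme and its nearest neighbour divided by the sample
#' range. Both extremes are screened and the larger ratio is tested
#' two-sided against the embedded critical table.
#'
#' @param values Numeric vector, 3 to 30 finite values.
#' @param alpha Significance level: one of 0.10, 0.05 (default), 0.01.
#' @return List with `statistic` (Q), `suspect` (the tested value),
#'   `side` (`"low"`/`"high"`), `critical`, `alpha`, `n`, `outlier`
#'   (logical) and `performed` (FALSE when the range is zero, in which
#'   case no test is possible and `outlier` is NA).
#' @examples
#' dixon_q(c(1, 2, 3, 4, 10)) # Q = 6/9 = 0.667, retained at alpha 0.05
#' @export
dixon_q <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 30) {
    stop("unsupported n: Dixon's Q requires 3 <= n <= 30 (got ", n, ")",
         call. = FALSE)
  }
  a <- as.character(alpha)
  if (!a %in% colnames(.dixon_critical)) {
    stop("alpha must be one of 0.1, 0.05, 0.01", call. = FALSE)
  }
  s <- sort(values)
  rng <- s[n] - s[1]
  if (rng == 0) {
    return(list(statistic = NA_real_, suspect = s[1], side = NA_character_,
                critical = unname(.dixon_critical[as.character(n), a]),
                alpha = alpha, n = n, outlier = NA, performed = FALSE))
  }
  q_low <- (s[2] - s[1]) / rng
  q_high <- (s[n] - s[n - 1]) / rng
  if (q_high >= q_low) {
    q <- q_high; suspect <- s[n]; side <- "high"
  } else {
    q <- q_low; suspect <- s[1]; side <- "low"
  }
  crit <- unname(.dixon_critical[as.character(n), a])
  list(statistic = q, suspect = suspect, side = side, critical = crit,
       alpha = alpha, n = n, outlier = q > crit, performed = TRUE)
}
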