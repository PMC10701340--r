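# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# A minimal long record table: one whale, one image, the named
# measurements plus all 19 width stations, in pixels under a 0.05 m/px GSD
# flight (altitude 100 m, sensor 10 mm, focal 10 mm, 2000 px wide).
make_records <- function(whale_id = "w1", image_id = "img1",
                         population = "A", platform_id = "P1",
                         TL = 20, widths = rep(2, 19),
                         quality = 1L, is_calf = FALSE) {
  meas <- c(TL = TL, RB = 0.2 * TL, JL = 0.22 * TL, EE = 0.1 * TL,
            Tail = 0.25 * TL, Fs = 0.22 * TL, Fw = 0.065 * TL)
  w <- widths
  names(w) <- names(width_stations())
  vals <- c(meas, w)
  gsd <- 100 * (10 / 10) / 2000 # 0.05 m/px
  tibble::tibble(
    whale_id = whale_id, image_id = image_id, population = population,
    platform_id = platform_id,
    altitude = 100, focal_length = 10, sensor_width = 10,
    image_width = 2000, image_height = 1500, altimeter = "laser",
    measurement = names(vals), value = as.numeric(vals) / gsd, unit = "px",
    quality = quality, is_calf = is_calf
  )
}

# Error-free calibration table for one platform.
make_calibrations <- function(platform_id = "P1", n = 20,
                              sizes = c(4.41, 2.00), b = 0, sigma = 0,
                              seed = 1) {
  set.seed(seed)
  known <- rep_len(sizes, n)
  tibble::tibble(
    platform_id = platform_id, known_m = known,
    measured_m = known * (1 + b) + stats::rnorm(n, 0, sigma),
    altitude = 40, altimeter = "laser"
  )
}

# Posterior-summary table for mc_anova tests.
make_posteriors <- function(means_by_pop, variance = 0) {
  dplyr::bind_rows(lapply(names(means_by_pop), function(p) {
    mu <- means_by_pop[[p]]
    tibble::tibble(whale_id = paste0(p, seq_along(mu)), population = p,
                   posterior_mean = mu, posterior_variance = variance)
  }))
}
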