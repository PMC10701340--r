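test_that("ground sampling distance follows the lens geometry", {
  expect_equal(ground_sampling_distance(100, 10, 10, 1000), 0.1)
  # independent hand calculation: altitude * (sensor/focal) / width
  expect_equal(ground_sampling_distance(37.5, 8.8, 13.2, 5472),
               37.5 * (13.2 / 8.8) / 5472)
  expect_error(ground_sampling_distance(0, 10, 10, 1000), "altitude")
  expect_error(ground_sampling_distance(100, -1, 10, 1000), "focal")
  expect_error(ground_sampling_distance(100, 10, 0, 1000), "sensor")
  expect_error(ground_sampling_distance(100, 10, 10, 0), "image_width")
})

test_that("pixel lengths convert linearly to metres", {
  expect_equal(pixels_to_meters(0, 100, 10, 10, 1000), 0)
  expect_equal(pixels_to_meters(300, 100, 10, 10, 2000), 15)
  # doubling altitude doubles the metric length
  expect_equal(pixels_to_meters(123, 200, 10, 10, 2000),
               2 * pixels_to_meters(123, 100, 10, 10, 2000))
  expect_error(pixels_to_meters(-1, 100, 10, 10, 1000), "non-negative")
})

test_that("BAI matches the rectangle-body closed form and degenerates to 0", {
  # constant width 2 m over TL 20 m: SA = 0.7*20*2 = 28, BAI = 100*28/14^2
  expect_equal(compute_bai(20, rep(2, 19)), 100 * 28 / (0.7 * 20)^2,
               tolerance = 1e-12)
  expect_equal(compute_bai(20, rep(0, 19)), 0)
})

test_that("BAI trapezoid converges to the quadrature oracle on an ellipse", {
  TL <- 20; bmax <- 2
  wfun <- function(x) 2 * bmax * sqrt(pmax(0, 1 - (2 * x / TL - 1)^2))
  w19 <- wfun(width_stations() * TL)
  bai19 <- compute_bai(TL, w19)
  # oracle: fine-grid numerical integration of the analytic profile
  xs <- seq(0.2 * TL, 0.9 * TL, length.out = 20001)
  sa <- sum(diff(xs) * (wfun(xs)[-1] + wfun(xs)[-length(xs)]) / 2)
  bai_oracle <- 100 * sa / (0.7 * TL)^2
  # trapezoid error bound at h = 0.05 TL for this curvature
  expect_lt(abs(bai19 - bai_oracle), 0.15)
  # 190-station refinement over the same integration range shrinks the
  # error (convergence property)
  xk <- seq(0.2, 0.9, length.out = 190) * TL
  wk <- wfun(xk)
  sa190 <- sum(diff(xk) * (utils::head(wk, -1) + utils::tail(wk, -1)) / 2)
  bai190 <- 100 * sa190 / (0.7 * TL)^2
  expect_lt(abs(bai190 - bai_oracle), abs(bai19 - bai_oracle))
})

test_that("BAI is invariant under uniform rescaling of all inputs", {
  set.seed(7)
  w <- runif(19, 1, 3)
  base <- compute_bai(21.3, w)
  for (c in c(0.1, 2, 17.3)) {
    expect_equal(compute_bai(21.3 * c, w * c), base, tolerance = 1e-12)
  }
})

test_that("BAI errors on missing interior stations and bad ranges", {
  w <- width_stations() * 0 + 2
  w["w50"] <- NA
  expect_error(compute_bai(20, w), "incomplete")
  expect_error(compute_bai(20, rep(2, 19), c(0.22, 0.9)), "multiples")
  expect_error(compute_bai(-1, rep(2, 19)), "TL")
  # stations outside the range may be absent
  inr <- width_stations() >= 0.2 - 1e-9 & width_stations() <= 0.9 + 1e-9
  expect_equal(compute_bai(20, (width_stations() * 0 + 2)[inr]),
               compute_bai(20, rep(2, 19)))
})

test_that("TL standardization is a scale-free ratio", {
  expect_equal(unname(standardize_by_tl(c(RB = 4), 20)), 0.2)
  expect_equal(unname(standardize_by_tl(c(RB = 20), 20)), 1.0)
  m <- c(RB = 4.2, JL = 4.6, EE = 2.1)
  expect_equal(standardize_by_tl(m * 3, 20 * 3), standardize_by_tl(m, 20))
  expect_error(standardize_by_tl(m, 0), "TL")
})

test_that("quality filter drops poor scores, calves, and caps images", {
  # per-measurement quality-3 drop
  rec <- dplyr::bind_rows(lapply(1:4, function(i) {
    r <- make_records(whale_id = paste0("w", i), image_id = paste0("i", i))
    r$quality[r$measurement == "TL"] <- c(1L, 2L, 3L, 3L)[i]
    r
  }))
  out <- filter_records(rec)
  tl_kept <- out$records[out$records$measurement == "TL", ]
  expect_equal(nrow(tl_kept), 2)
  expect_true(all(out$audit$reason[out$audit$measurement == "TL"] ==
                    "quality_3"))

  # calf removal: 2 calves among 17 whales
  rec <- dplyr::bind_rows(lapply(1:17, function(i) {
    make_records(whale_id = paste0("w", i), image_id = paste0("i", i),
                 is_calf = i <= 2)
  }))
  out <- filter_records(rec)
  expect_equal(length(unique(out$records$whale_id)), 15)

  # image cap: 7 images, cap 5, best quality first then record order
  rec <- dplyr::bind_rows(lapply(1:7, function(i) {
    r <- make_records(whale_id = "w1", image_id = paste0("i", i))
    r$quality <- c(2L, 1L, 2L, 1L, 2L, 1L, 2L)[i]
    r
  }))
  out <- filter_records(rec, max_images_per_whale = 5)
  kept <- unique(out$records$image_id)
  expect_length(kept, 5)
  # quality-1 images i2, i4, i6 first; then quality-2 by order: i1, i3
  expect_setequal(kept, c("i2", "i4", "i6", "i1", "i3"))
})

test_that("quality filter never grows the data and is idempotent", {
  set.seed(11)
  rec <- dplyr::bind_rows(lapply(1:6, function(i) {
    r <- make_records(whale_id = paste0("w", ceiling(i / 3)),
                      image_id = paste0("i", i),
                      is_calf = i == 6)
    r$quality <- sample(1:3, nrow(r), replace = TRUE)
    r
  }))
  once <- filter_records(rec, max_images_per_whale = 2)
  expect_lte(nrow(once$records), nrow(rec))
  twice <- filter_records(once$records, max_images_per_whale = 2)
  expect_equal(twice$records, once$records)
  expect_equal(nrow(twice$audit), 0)
  expect_error(filter_records(dplyr::mutate(rec, quality = quality + 3L)),
               "quality")
})

test_that("record conversion and per-image morphology recover the truth", {
  rec <- make_records(TL = 20, widths = rep(2, 19))
  conv <- convert_records(rec)
  per <- morphology_per_image(conv)
  expect_equal(per$TL, 20)
  expect_equal(per$RB_std, 0.2)
  expect_equal(per$BAI, 100 * 28 / 196, tolerance = 1e-12)
  # metre-unit rows pass through unscaled
  rec_m <- dplyr::mutate(rec, value = value * 0.05, unit = "m")
  expect_equal(convert_records(rec_m)$value_m, conv$value_m)
})
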