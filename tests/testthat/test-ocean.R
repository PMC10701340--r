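test_that("season years follow the hemisphere convention", {
  dates <- seq(as.Date("2014-07-01"), as.Date("2016-06-30"), by = "day")
  out <- season_year_split(dates, rep(1, length(dates)), "S")
  # 2015-06-30 belongs to season year 2014; 2015-07-01 starts 2015
  expect_setequal(unique(out$season_year), c(2014, 2015))
  expect_equal(out$day_index[1], 1) # 2014-07-01
  d365 <- out[out$season_year == 2014 & out$day_index == 365, ]
  expect_equal(nrow(d365), 1)
  # relabeling N vs S changes year boundaries, never the daily values
  datesN <- seq(as.Date("2014-01-01"), as.Date("2015-12-31"), by = "day")
  vals <- rnorm(length(datesN))
  n <- season_year_split(datesN, vals, "N")
  expect_equal(sort(n$value[!is.na(n$value)]), sort(
    vals[format(datesN, "%m-%d") != "02-29"]))
})

test_that("cumulative curves are running sums with missing days as zero", {
  dates <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  out <- season_year_split(dates, rep(1, 365), "N")
  expect_equal(out$cumulative, 1:365)
  # a gap contributes zero and is reported in the coverage attribute
  keep <- c(1:99, 110:365)
  out <- season_year_split(dates[keep], rep(1, length(keep)), "N")
  expect_equal(max(out$cumulative), 355)
  expect_true(all(diff(out$cumulative) >= 0))
  cov <- attr(out, "coverage")
  expect_equal(cov$n_missing, 10)
})

test_that("leap days are dropped for a uniform 365-day grid", {
  dates <- seq(as.Date("2016-01-01"), as.Date("2016-12-31"), by = "day")
  expect_equal(length(dates), 366)
  out <- season_year_split(dates, rep(1, 366), "N")
  expect_equal(nrow(out), 365)
  expect_equal(out$cumulative[365], 365)
})

test_that("years with excessive gaps are excluded with a warning", {
  dates <- seq(as.Date("2014-01-01"), as.Date("2015-12-31"), by = "day")
  vals <- rep(1, length(dates))
  vals[format(dates, "%Y") == "2014"][1:200] <- NA
  expect_warning(out <- season_year_split(dates, vals, "N"), "excluded")
  expect_equal(unique(out$season_year), 2015)
})

test_that("the climatological mean is the day-wise average", {
  curves <- tibble::tibble(
    season_year = rep(c(2010, 2011), each = 365),
    day_index = rep(1:365, 2),
    value = 1,
    cumulative = c(1:365, 2 * (1:365))
  )
  cm <- climatological_mean(curves)
  expect_equal(cm$cumulative, 1.5 * (1:365))
  # idempotence on identical years
  curves$cumulative <- rep(1:365, 2)
  expect_equal(climatological_mean(curves)$cumulative, 1:365)
  expect_error(climatological_mean(curves[1:365, ]), ">= 2")
  expect_error(climatological_mean(curves[-1, ]), "mismatched")
})

test_that("climatological mean tracks the generative expectation", {
  set.seed(20)
  spec <- forcing_spec(n_years = 10, base = 0.5, amplitude = 8, kappa = 1.5,
                       peak_day = 150, noise_sd = 0.3)
  f <- simulate_forcing(spec, seed = 20)
  curves <- season_year_split(f$date, f$value, "N")
  cm <- climatological_mean(curves)
  expected <- cumsum(0.5 + 8 * von_mises_day_density(1:365, 150, 1.5))
  # 3 SE bound on the day-wise mean of 10 noisy cumulative sums
  se <- 0.3 * sqrt(1:365) / sqrt(10)
  expect_true(all(abs(cm$cumulative - expected) < 3.5 * se + 1e-9))
})

test_that("accumulation windows match the stated analytic cases", {
  const <- accumulation_window(cumsum(rep(1, 365)), 0.5)
  expect_equal(const$length_days, 182.5)
  expect_equal(const$start_day, 91.3) # 91.25 at 0.1-day resolution
  imp <- rep(0, 365); imp[100] <- 7
  w <- accumulation_window(cumsum(imp), 0.5)
  # all mass inside one day: the window is degenerate within that day
  expect_lte(w$length_days, 0.5)
  expect_equal(floor(w$start_day), 99)
  expect_error(accumulation_window(rep(0, 365), 0.5), "undefined")
  expect_error(accumulation_window(cumsum(rep(1, 365)), 1.5), "fraction")
})

test_that("the von Mises window matches numerical CDF inversion", {
  kappa <- 2
  daily <- von_mises_day_density(1:365, 182, kappa)
  win <- accumulation_window(cumsum(daily), 0.5)
  # oracle: invert the analytic intensity CDF on a fine grid
  fine <- seq(0.5, 365.5, length.out = 400001)
  dens <- von_mises_day_density(fine, 182, kappa)
  cdf <- cumsum(dens) * (fine[2] - fine[1])
  cdf <- cdf / cdf[length(cdf)]
  q <- function(p) fine[which(cdf >= p)[1]]
  oracle <- q(0.75) - q(0.25)
  expect_lt(abs(win$length_days - oracle), 1)
})

test_that("windows nest and shrink with seasonal concentration", {
  set.seed(8)
  for (i in 1:100) {
    daily <- runif(365, 0, 1) + 5 * von_mises_day_density(1:365,
                                                          sample(365, 1),
                                                          runif(1, 0, 3))
    cum <- cumsum(daily)
    w50 <- accumulation_window(cum, 0.5)
    w80 <- accumulation_window(cum, 0.8)
    expect_lte(w80$start_day, w50$start_day)
    expect_gte(w80$end_day, w50$end_day)
  }
  lens <- sapply(c(0, 0.5, 1, 2, 4), function(k) {
    accumulation_window(cumsum(von_mises_day_density(1:365, 182, k)),
                        0.5)$length_days
  })
  expect_true(all(diff(lens) < 0))
})

test_that("the SST upwelling index follows its sign convention", {
  d <- as.Date("2015-01-01") + 0:2
  out <- upwelling_index_sst(d, c(16, 16, 16), c(18, 18, 18))
  expect_equal(out$value, rep(2, 3))
  expect_equal(upwelling_index_sst(d, c(16, 17, 15), c(16, 17, 15))$value,
               rep(0, 3))
  rev <- upwelling_index_sst(d, c(16, 16, 16), c(18, 18, 18),
                             positive_when_nearshore_colder = FALSE)
  expect_equal(rev$value, rep(-2, 3))
  expect_error(upwelling_index_sst(d, c(16, 16), c(18, 18, 18)), "mismatch")
})

test_that("box averages use cell centres inside the closed box", {
  grid <- tidyr::expand_grid(time = as.Date("2015-01-01") + 0:1,
                             lat = c(-42.5, -44.5), lon = c(-73.5, -74.5))
  grid$value <- rep(c(1, 2, 3, 4), 2)
  out <- box_average(grid, c(-45, -42), c(-75, -73))
  expect_equal(out$value, c(2.5, 2.5))
  # missing cells are excluded from that day's mean
  grid$value[1:2] <- NA
  out <- box_average(grid, c(-45, -42), c(-75, -73))
  expect_equal(out$value[1], mean(c(3, 4)))
  expect_error(box_average(grid, c(0, 1), c(0, 1)), "empty intersection")
  # constant field averages to itself
  grid$value <- 5
  expect_equal(box_average(grid, c(-45, -42), c(-75, -73))$value, c(5, 5))
})

test_that("monthly climatology averages calendar months across years", {
  dates <- seq(as.Date("2014-01-15"), as.Date("2015-12-15"), by = "month")
  vals <- rep(1:12, 2)
  out <- monthly_climatology(dates, vals)
  expect_equal(out$climatology$mean, as.numeric(1:12))
  vals2 <- c(1, rep(0, 11), 3, rep(0, 11))
  out2 <- monthly_climatology(dates, vals2)
  expect_equal(out2$climatology$mean[1], 2)
  expect_error(monthly_climatology(dates[1:6], vals[1:6]), ">= 12")
})

test_that("the climatology peak month matches the generative cycle", {
  set.seed(9)
  dates <- seq(as.Date("2012-01-15"), as.Date("2019-12-15"), by = "month")
  months <- as.integer(format(dates, "%m"))
  hits <- replicate(200, {
    # noise small enough that the January peak is identifiable over the
    # 0.2-unit gap to its neighbouring months (8 years of data)
    vals <- 2 + 1.5 * cos(2 * pi * (months - 1) / 12) + rnorm(length(dates), 0, 0.2)
    cl <- monthly_climatology(dates, vals)$climatology
    cl$month[which.max(cl$mean)] == 1
  })
  expect_gte(mean(hits), 0.95)
})

test_that("Pearson correlation matches the product-moment formula", {
  expect_equal(salinity_chl_correlation(1:10, 1:10)$r, 1)
  expect_equal(salinity_chl_correlation(1:10, -2 * (1:10) + 3)$r, -1)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 3, 5, 4)
  # hand computation of the product-moment formula
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  out <- salinity_chl_correlation(x, y)
  expect_equal(out$r, r_hand)
  expect_equal(out$n, 5)
  expect_error(salinity_chl_correlation(rep(1, 5), y), "zero variance")
  expect_error(salinity_chl_correlation(1:2, 2:3), ">= 3")
})
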