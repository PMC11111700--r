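test_that("peak day is the earliest maximum of the year's valid data", {
  d <- as.Date("2001-01-01") + c(50, 149, 209, 300)
  expect_equal(find_peak_day(d, c(0.2, 0.5, 0.9, 0.4)), d[3])
  expect_equal(find_peak_day(d, c(0.2, 0.9, 0.9, 0.4)), d[2])  # tie: earliest
  expect_true(is.na(find_peak_day(as.Date(character(0)), numeric(0))))
})

test_that("segment assembly uses calendar day counts from the window origin", {
  dates <- as.Date(c("2000-11-15", "2001-03-01", "2001-10-01", "2002-02-01"))
  vals <- c(0.2, 0.4, 0.5, 0.1)
  peak <- as.Date("2001-07-19")  # DOY 200 of a non-leap year
  g <- assemble_growth_segment(dates, vals, 2001L, peak)
  expect_equal(g$t, c(45, 151))
  expect_equal(g$value, c(0.2, 0.4))
  expect_equal(attr(g, "origin"), as.Date("2000-10-01"))
  w <- assemble_withering_segment(dates, vals, 2001L, peak)
  expect_equal(w$t, c(74, 197))
  expect_equal(w$value, c(0.5, 0.1))
})

test_that("segments truncate at record edges and may be empty", {
  dates <- as.Date(c("2001-02-01", "2001-05-01"))
  g <- assemble_growth_segment(dates, c(0.3, 0.6), 2001L, as.Date("2001-07-01"))
  expect_equal(nrow(g), 2L)  # no previous-year part available
  empty <- assemble_growth_segment(dates, c(NA, NA), 2001L, as.Date("2001-07-01"))
  expect_equal(nrow(empty), 0L)
  # peak on Dec 31: withering keeps only Jan-Mar of the following year
  w <- assemble_withering_segment(as.Date(c("2001-12-30", "2002-02-01")),
                                  c(0.5, 0.2), 2001L, as.Date("2001-12-31"))
  expect_equal(w$date, as.Date("2002-02-01"))
})

test_that("quartic fitting matches the normal-equations oracle and recovers exact quartics", {
  set.seed(21)
  origin <- as.Date("2000-10-01")
  for (rep in 1:25) {
    n <- sample(10:40, 1)
    span <- sample(100:300, 1)
    t <- sort(sample(0:span, n))
    x <- 2 * t / span - 1
    beta <- runif(5, -0.3, 0.3)
    y <- cbind(1, x, x^2, x^3, x^4) %*% beta + rnorm(n, 0, 0.02)
    seg <- data.frame(date = origin + t, t = t, value = as.vector(y))
    attr(seg, "origin") <- origin
    attr(seg, "window_end") <- origin + span
    fit <- fit_quartic(seg)
    expect_identical(fit$status, "fitted")
    expect_equal(fit$coefficients, oracle_quartic(t, as.vector(y), span),
                 tolerance = 1e-8)
  }
  # noiseless quartic data are reproduced with negligible residuals
  t <- seq(0, 200, by = 10)
  x <- 2 * t / 200 - 1
  y <- 0.4 + 0.2 * x - 0.1 * x^2 + 0.05 * x^3 + 0.3 * x^4
  seg <- data.frame(date = origin + t, t = t, value = y)
  attr(seg, "origin") <- origin; attr(seg, "window_end") <- origin + 200
  fit <- fit_quartic(seg)
  expect_lt(max(abs(evaluate_segment(fit, origin + t) - y)), 1e-8)
  expect_equal(fit$coefficients, c(0.4, 0.2, -0.1, 0.05, 0.3), tolerance = 1e-8)
})

test_that("constant data fit a constant and sparse or degenerate segments fall back", {
  origin <- as.Date("2000-10-01")
  seg <- data.frame(date = origin + (1:20) * 10, t = (1:20) * 10, value = rep(0.3, 20))
  attr(seg, "origin") <- origin; attr(seg, "window_end") <- origin + 210
  fit <- fit_quartic(seg)
  expect_lt(max(abs(evaluate_segment(fit, origin + seq(5, 200, 5)) - 0.3)), 1e-9)

  four <- seg[1:4, ]
  attr(four, "origin") <- origin; attr(four, "window_end") <- origin + 210
  expect_identical(fit_quartic(four)$status, "fallback")

  onedate <- data.frame(date = rep(origin, 12), t = rep(0, 12), value = runif(12))
  attr(onedate, "origin") <- origin; attr(onedate, "window_end") <- origin + 210
  expect_identical(fit_quartic(onedate)$status, "fallback")
})

test_that("pixel-year reconstruction clamps and leaves fallback segments missing", {
  big <- structure(list(coefficients = c(1.4, 0, 0, 0, 0),
                        time_origin = as.Date("2000-10-01"), time_scale = 300,
                        support_n = 20L, status = "fitted"),
                   class = "segment_fit")
  fb <- structure(list(coefficients = rep(NA_real_, 5),
                       time_origin = as.Date("2001-07-01"), time_scale = 270,
                       support_n = 2L, status = "fallback"),
                  class = "segment_fit")
  ry <- reconstruct_pixel_year(big, fb, 2001L, as.Date("2001-07-01"))
  expect_equal(length(ry$values), 365L)
  pre <- ry$dates <= as.Date("2001-07-01")
  expect_true(all(ry$values[pre] == 1.0))       # 1.4 clamped to 1
  expect_true(all(is.na(ry$values[!pre])))      # fallback half deferred
})

test_that("residual gaps are filled by the adjacent-four-year mean with Feb 29 mapping", {
  dates <- seq(as.Date("2000-01-01"), as.Date("2004-12-31"), by = "day")
  md <- format(dates, "%m-%d")
  yr <- as.integer(format(dates, "%Y"))
  vals <- rep(0.5, length(dates))
  by_year <- c("2000" = 0.2, "2001" = 0.3, "2003" = 0.4, "2004" = 0.5)
  vals[md == "06-15"] <- by_year[as.character(yr[md == "06-15"])]
  vals[md == "06-15" & yr == 2002] <- NA        # gap with 4 donors
  vals[md == "02-29"] <- NA                     # leap day gap (2000, 2004)
  vals[md == "02-28"] <- 0.32
  cube <- make_cube(dates, vals)
  filled <- fill_residual_gaps(cube)
  expect_equal(missing_count(filled), 0L)
  expect_equal(filled$values[dates == as.Date("2002-06-15"), 1, 1], 0.35)
  # Feb 29 2002 does not exist; Feb 29 2000 uses Feb 28 of 2001/2002 (non-leap)
  expect_equal(filled$values[dates == as.Date("2000-02-29"), 1, 1], 0.32)

  # a two-year record: the gap's only donor is the following year
  d2 <- seq(as.Date("2002-01-01"), as.Date("2003-12-31"), by = "day")
  v2 <- rep(0.5, length(d2))
  v2[d2 == as.Date("2003-06-15")] <- 0.4
  v2[d2 == as.Date("2002-06-15")] <- NA
  f2 <- fill_residual_gaps(make_cube(d2, v2))
  expect_equal(f2$values[d2 == as.Date("2002-06-15"), 1, 1], 0.4)
  # a gap with no donor in any adjacent year is a hard error
  bad <- vals; bad[md == "06-15"] <- NA
  expect_error(fill_residual_gaps(make_cube(dates, bad)), "no adjacent-year donor")
})

test_that("full reconstruction is gap-free, deterministic, and fills a dead year", {
  scene <- demo_scene(seed = 5, nlat = 4, nlon = 4)
  cube <- scene$observed
  # kill one pixel's entire middle year
  yr <- format(cube$dates, "%Y") == "2002"
  v <- cube$values; v[yr, 2, 2] <- NA
  cube <- daily_vi_cube(cube$grid, cube$dates, v)
  mask <- identify_valid(cube)
  r1 <- reconstruct_cube(cube, mask)
  expect_equal(missing_count(r1), 0L)
  expect_true(all(r1$values >= -1 & r1$values <= 1))
  r2 <- reconstruct_cube(cube, mask)
  expect_identical(r1$values, r2$values)
  # the dead pixel-year is the mean of its adjacent-year reconstructions
  d <- which(r1$dates == as.Date("2002-08-01"))
  donors <- r1$values[r1$dates %in% as.Date(c("2001-08-01", "2003-08-01")), 2, 2]
  expect_equal(r1$values[d, 2, 2], mean(donors), tolerance = 1e-12)
})

test_that("keeping observations passes valid days through unchanged", {
  scene <- demo_scene(seed = 9, nlat = 2, nlon = 2)
  mask <- identify_valid(scene$observed)
  rec <- reconstruct_cube(scene$observed, mask,
                          reconstruction_config(keep_observations = TRUE))
  full <- rec$dates %in% scene$observed$dates
  kept <- mask$labels == 1L
  expect_equal(rec$values[full, , ][kept], scene$observed$values[kept])
})
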