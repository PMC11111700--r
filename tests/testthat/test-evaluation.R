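test_that("metrics reproduce hand-computed examples", {
  expect_equal(as.numeric(percent_bias(0.55, 0.5)), 10.0)
  expect_equal(as.numeric(percent_bias(c(0.3, 0.4), c(0.3, 0.4))), 0.0)
  expect_equal(as.numeric(percent_bias(c(0.2, 0.6), c(0.4, 0.5))), -15.0)
  expect_equal(r_squared(c(0.25, 0.35, 0.6), c(0.2, 0.4, 0.6)), 0.9375)
  obs <- c(0.2, 0.4, 0.6)
  expect_equal(r_squared(obs, obs), 1.0)
  expect_equal(r_squared(rep(mean(obs), 3), obs), 0.0)
  a <- c(0.1, 0.3, 0.2, 0.5)
  expect_equal(pearson_r(a, 2 * a + 1), 1.0)
  expect_equal(pearson_r(c(0, 1), c(1, 0)), -1.0)
  expect_equal(mae(a, a + 0.1), 0.1)
  expect_equal(rmse(a, a + 0.1), 0.1)
})

test_that("degenerate metric inputs are signalled and zero references skipped", {
  expect_error(r_squared(c(0.1, 0.2), c(0.3, 0.3)), "constant")
  expect_error(pearson_r(c(0.1, 0.1), c(0.2, 0.3)), "constant")
  expect_error(percent_bias(c(0.1, 0.2), c(0, 0)), "nonzero")
  pb <- percent_bias(c(0.2, 0.55), c(0, 0.5))
  expect_equal(as.numeric(pb), 10.0)
  expect_equal(attr(pb, "n_skipped_zero_ref"), 1L)
})

test_that("metric invariants hold on random vectors", {
  set.seed(33)
  for (rep in 1:200) {
    n <- sample(3:40, 1)
    a <- runif(n, -1, 1)
    b <- runif(n, 0.05, 1)
    expect_gte(rmse(a, b), mae(a, b))
    expect_true(abs(pearson_r(a, b)) <= 1 + 1e-12)
    expect_lte(r_squared(a, b), 1)
    cc <- runif(1, 0.1, 10)
    expect_equal(as.numeric(percent_bias(cc * a, cc * b)),
                 as.numeric(percent_bias(a, b)), tolerance = 1e-9)
  }
})

test_that("per-pixel metric maps match brute-force computation", {
  set.seed(4)
  dates <- as.Date("2001-01-01") + 0:49
  rec <- array(runif(100, 0.1, 0.9), c(50, 1, 2))
  obs <- rec + array(rnorm(100, 0, 0.05), c(50, 1, 2))
  obs <- pmin(pmax(obs, 0.05), 1)
  crec <- daily_vi_cube(toy_grid(1, 2), dates, rec)
  cobs <- daily_vi_cube(toy_grid(1, 2), dates, obs)
  mm <- pixelwise_metrics(crec, cobs)
  for (j in 1:2) {
    o <- oracle_metrics(rec[, 1, j], obs[, 1, j])
    expect_equal(mm$r[1, j], o$r, tolerance = 1e-12)
    expect_equal(mm$r2[1, j], o$r2, tolerance = 1e-12)
    expect_equal(mm$mae[1, j], o$mae, tolerance = 1e-12)
    expect_equal(mm$rmse[1, j], o$rmse, tolerance = 1e-12)
    expect_equal(mm$pb[1, j], o$pb, tolerance = 1e-12)
  }
  expect_error(pixelwise_metrics(crec, daily_vi_cube(toy_grid(1, 2), dates + 1, obs)),
               "do not match")
})

test_that("identical cubes score perfectly and masked mode flags empty pixels", {
  dates <- as.Date("2001-01-01") + 0:29
  vals <- array(runif(60, 0.2, 0.8), c(30, 1, 2))
  cube <- daily_vi_cube(toy_grid(1, 2), dates, vals)
  mm <- pixelwise_metrics(cube, cube)
  expect_true(all(mm$r2 == 1))
  expect_true(all(mm$rmse == 0))
  expect_true(all(mm$pb == 0))
  mask <- all_valid_mask(cube)
  mask$labels[, 1, 2] <- 0L  # no valid days at pixel 2
  mm2 <- pixelwise_metrics(cube, cube, mask = mask)
  expect_true(mm2$flag[1, 2])
  expect_true(is.na(mm2$r2[1, 2]))
})

test_that("quality rules classify pixels and report area proportions", {
  mm <- structure(list(
    r = matrix(c(0.8, 0.6, 0.3), 3, 1), r2 = matrix(c(0.8, 0.8, 0.8), 3, 1),
    mae = matrix(0.02, 3, 1), rmse = matrix(c(0.05, 0.05, 0.3), 3, 1),
    pb = matrix(c(0.5, 2, 0.5), 3, 1), n = matrix(100L, 3, 1),
    flag = matrix(FALSE, 3, 1), grid = toy_grid(3, 1)), class = "metric_map")
  qc <- quality_classification(mm, "self")
  expect_identical(as.vector(qc$pass), c(TRUE, FALSE, FALSE))
  expect_equal(qc$proportion, 1 / 3)
  qm <- quality_classification(mm, "modis")
  expect_identical(as.vector(qm$pass), c(TRUE, TRUE, FALSE))
  mm$pb[] <- 0.5; mm$rmse[] <- 0.05; mm$r2[] <- 0.8
  expect_equal(quality_classification(mm, "self")$proportion, 1.0)
})

test_that("latitudinal profiles aggregate rows over non-flagged pixels", {
  mm <- structure(list(
    r = matrix(0.5, 3, 2), r2 = matrix(0.5, 3, 2), mae = matrix(0.1, 3, 2),
    rmse = matrix(0.1, 3, 2),
    pb = matrix(c(0.2, 1, 5, 0.4, 3, 7), 3, 2), n = matrix(10L, 3, 2),
    flag = matrix(FALSE, 3, 2), grid = toy_grid(3, 2)), class = "metric_map")
  prof <- latitudinal_profile(mm, "pb")
  expect_equal(prof$mean, c(0.3, 2, 6))
  expect_equal(prof$sd, apply(matrix(c(0.2, 1, 5, 0.4, 3, 7), 3, 2), 1, sd))
  mm$pb[] <- 0.7
  expect_true(all(latitudinal_profile(mm, "pb")$sd == 0))
})

test_that("monthly compositing takes per-month maxima and is order independent", {
  dates <- as.Date(c("2001-01-05", "2001-01-15", "2001-01-25",
                     "2001-02-03", "2001-02-04"))
  cube <- make_cube(dates, c(0.2, 0.6, 0.4, NA, NA))
  mc <- mvc_monthly_composite(cube)
  expect_equal(mc$values[1, 1, 1], 0.6)
  expect_true(is.na(mc$values[2, 1, 1]))
  # relabeling days within the month leaves the composite unchanged
  cube2 <- make_cube(dates, c(0.6, 0.4, 0.2, NA, NA))
  expect_equal(mvc_monthly_composite(cube2)$values, mc$values)
  # a gap-free cube composites with no absent cells
  scene <- demo_scene(seed = 2, nlat = 2, nlon = 2)
  mask <- identify_valid(scene$observed)
  rec <- reconstruct_cube(scene$observed, mask)
  expect_false(anyNA(mvc_monthly_composite(rec)$values))
})

test_that("nearest-neighbour regridding matches exhaustive search", {
  dates <- as.Date("2001-01-01") + 0:4
  src_grid <- grid_spec(30, 30.5, 100, 100.5, cell_size = 1 / 12)
  vals <- array(runif(5 * 6 * 6), c(5, 6, 6))
  src <- daily_vi_cube(src_grid, dates, vals)
  tgt <- grid_spec(30, 30.5, 100, 100.5, cell_size = 0.05)
  out <- regrid_nearest(src, tgt)
  slat <- lat_centers(src_grid); slon <- lon_centers(src_grid)
  tlat <- lat_centers(tgt); tlon <- lon_centers(tgt)
  for (i in seq_along(tlat)) for (j in seq_along(tlon)) {
    best <- c(which.min(abs(slat - tlat[i])), which.min(abs(slon - tlon[j])))
    expect_equal(out$values[, i, j], vals[, best[1], best[2]])
  }
  # identical grids: identity
  same <- regrid_nearest(src, src_grid)
  expect_equal(same$values, vals)
  far <- grid_spec(0, 1, 0, 1, cell_size = 0.05)
  expect_error(regrid_nearest(src, far), "overlap")
})
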