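# Small in-code fixtures shared across test files.

toy_grid <- function(nlat = 1L, nlon = 1L, lat0 = 30, lon0 = 100, cell = 0.05) {
  grid_spec(lat0, lat0 + nlat * cell, lon0, lon0 + nlon * cell, cell_size = cell)
}

# cube from a per-pixel list of value vectors (one per date)
make_cube <- function(dates, values, nlat = 1L, nlon = 1L) {
  if (is.vector(values)) values <- array(values, c(length(values), 1L, 1L))
  daily_vi_cube(toy_grid(nlat, nlon), as.Date(dates), values)
}

# random small cube: <= 3 pixels, n_months consecutive months, random
# missingness, values in [0, 1] with occasional exact zeros
random_small_cube <- function(n_months = 18L, npix = NULL) {
  if (is.null(npix)) npix <- sample(1:3, 1)
  first <- as.Date(sprintf("%d-%02d-01", sample(1998:2015, 1), sample(1:12, 1)))
  last_excl <- seq(first, by = "month", length.out = n_months + 1)[n_months + 1]
  dates <- seq(first, last_excl - 1, by = "day")
  # random date-axis gaps (allowed on input)
  keep <- sort(sample(seq_along(dates), max(2L, round(length(dates) * stats::runif(1, 0.5, 1)))))
  dates <- dates[keep]
  vals <- array(stats::runif(length(dates) * npix), c(length(dates), 1L, npix))
  vals[stats::runif(length(vals)) < stats::runif(1, 0.1, 0.5)] <- NA_real_
  vals[stats::runif(length(vals)) < 0.02] <- 0
  daily_vi_cube(toy_grid(1L, npix), dates, vals)
}

# a mask labelling every non-missing day valid
all_valid_mask <- function(cube) {
  labels <- array(0L, dim(cube$values))
  labels[!is.na(cube$values)] <- 1L
  months <- vigapfill:::month_table(cube$dates)
  structure(list(labels = labels,
                 month_flags = array(0L, c(nrow(months), dim(labels)[2], dim(labels)[3])),
                 months = months, dates = cube$dates, grid = cube$grid),
            class = "validity_mask")
}

# monthly_vi_cube built directly from a [month x pixel] value matrix
make_monthly_series <- function(values, start_year = 2000L, start_month = 1L) {
  values <- as.matrix(values)
  nm <- nrow(values)
  starts <- seq(as.Date(sprintf("%04d-%02d-01", start_year, start_month)),
                by = "month", length.out = nm)
  structure(list(
    months = data.frame(year = as.integer(format(starts, "%Y")),
                        month = as.integer(format(starts, "%m"))),
    values = array(values, c(nm, 1L, ncol(values))),
    grid = toy_grid(1L, ncol(values))),
    class = "monthly_vi_cube")
}
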