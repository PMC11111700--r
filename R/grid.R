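#' Regular latitude/longitude grid specification
#'
#' Describes a cell-centre registered regular grid. The published extent is
#' interpreted as the outer cell edges, so cell centres run from
#' `lat_min + cell_size/2` to `lat_max - cell_size/2` (and likewise for
#' longitude). Latitude is always stored south-to-north ascending.
#'
#' @param lat_min,lat_max,lon_min,lon_max Outer grid edges in degrees.
#' @param cell_size Cell size in degrees (default 0.05, the climate modeling
#'   grid resolution).
#' @param lat_count,lon_count Optional cell counts; derived from the extent
#'   when omitted and checked against it (tolerance: half a cell) when given.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(lat_min, lat_max, lon_min, lon_max,
                      cell_size = 0.05,
                      lat_count = NULL, lon_count = NULL) {
  stopifnot(lat_max > lat_min, lon_max > lon_min, cell_size > 0)
  derive <- function(lo, hi) as.integer(round((hi - lo) / cell_size))
  if (is.null(lat_count)) lat_count <- derive(lat_min, lat_max)
  if (is.null(lon_count)) lon_count <- derive(lon_min, lon_max)
  lat_count <- as.integer(lat_count)
  lon_count <- as.integer(lon_count)
  if (lat_count < 1L || lon_count < 1L)
    stop("grid must contain at least one cell in each dimension")
  if (abs(lat_count * cell_size - (lat_max - lat_min)) > cell_size / 2)
    stop("lat_count * cell_size does not match the latitude extent")
  if (abs(lon_count * cell_size - (lon_max - lon_min)) > cell_size / 2)
    stop("lon_count * cell_size does not match the longitude extent")
  structure(
    list(lat_min = lat_min, lat_max = lat_max,
         lon_min = lon_min, lon_max = lon_max,
         cell_size = cell_size,
         lat_count = lat_count, lon_count = lon_count),
    class = "grid_spec")
}

#' Default grid covering China at 0.05 degrees
#'
#' Reproduces the published product grid: 18.16-53.56 deg N,
#' 73.44-135.09 deg E, 0.05 degree cells (708 x 1233 cells).
#'
#' @return A `grid_spec`.
#' @export
china_grid <- function() {
  grid_spec(18.16, 53.56, 73.44, 135.09, cell_size = 0.05)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A `grid_spec`.
#' @return Numeric vector of cell-centre latitudes (ascending) or longitudes.
#' @export
lat_centers <- function(grid) {
  grid$lat_min + (seq_len(grid$lat_count) - 0.5) * grid$cell_size
}

#' @rdname lat_centers
#' @export
lon_centers <- function(grid) {
  grid$lon_min + (seq_len(grid$lon_count) - 0.5) * grid$cell_size
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells @ %g deg, lat [%g, %g], lon [%g, %g]\n",
              x$lat_count, x$lon_count, x$cell_size,
              x$lat_min, x$lat_max, x$lon_min, x$lon_max))
  invisible(x)
}

#' Daily vegetation-index cube
#'
#' The central container: daily VI values on a regular grid with a true
#' calendar (Gregorian, leap years honoured) time axis. Values are unpacked
#' physical VI in [-1, 1]; missing observations are `NA`. Gaps in the date
#' axis are allowed on input but a reconstructed cube must be daily-complete.
#'
#' @param grid A `grid_spec`.
#' @param dates `Date` vector, strictly increasing, no duplicates.
#' @param values Numeric array `[time, lat, lon]`; `NA` marks missing.
#' @return An object of class `daily_vi_cube`.
#' @export
daily_vi_cube <- function(grid, dates, values) {
  stopifnot(inherits(grid, "grid_spec"), inherits(dates, "Date"))
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("values must be a 3-d array [time, lat, lon]")
  if (!identical(dim(values),
                 c(length(dates), grid$lat_count, grid$lon_count)))
    stop("values dimensions do not match dates/grid: got [",
         paste(dim(values), collapse = ", "), "], expected [",
         length(dates), ", ", grid$lat_count, ", ", grid$lon_count, "]")
  if (anyNA(dates)) stop("dates contain NA")
  if (length(dates) > 1L && any(diff(as.numeric(dates)) <= 0))
    stop("dates must be strictly increasing with no duplicates")
  if (!all(is.na(values))) {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] < -1 || rng[2] > 1)
      stop(sprintf("values outside [-1, 1]: range [%g, %g]", rng[1], rng[2]))
  }
  structure(list(grid = grid, dates = dates, values = values),
            class = "daily_vi_cube")
}

#' @export
print.daily_vi_cube <- function(x, ...) {
  n <- length(x$values)
  miss <- sum(is.na(x$values))
  cat(sprintf("<daily_vi_cube> %d days (%s .. %s), %d x %d pixels, %.1f%% missing\n",
              length(x$dates), min(x$dates), max(x$dates),
              x$grid$lat_count, x$grid$lon_count, 100 * miss / n))
  invisible(x)
}

#' Number of missing values in a cube
#' @param cube A `daily_vi_cube`.
#' @return Integer count of `NA` cells.
#' @export
missing_count <- function(cube) sum(is.na(cube$values))

#' Product file name for a yearly slice
#'
#' Renders the published per-year file-name template
#' `"Daily_Gap-filled_NDVI_YYYY.nc4"`.
#'
#' @param year Integer 4-digit year.
#' @return File name string.
#' @export
product_file_name <- function(year) {
  year <- as.integer(year)
  stopifnot(length(year) == 1L, !is.na(year), year >= 1000L, year <= 9999L)
  sprintf("Daily_Gap-filled_NDVI_%04d.nc4", year)
}

# contiguous calendar-month table spanning a date range
month_table <- function(dates) {
  first <- as.Date(format(min(dates), "%Y-%m-01"))
  last <- as.Date(format(max(dates), "%Y-%m-01"))
  starts <- seq(first, last, by = "month")
  data.frame(year = as.integer(format(starts, "%Y")),
             month = as.integer(format(starts, "%m")))
}

# month index (into month_table rows) of each date
month_index <- function(dates, months) {
  key <- paste(format(dates, "%Y"), format(dates, "%m"), sep = "-")
  mkey <- sprintf("%04d-%02d", months$year, months$month)
  match(key, mkey)
}
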