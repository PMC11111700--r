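#' Read a daily VI cube from NetCDF-4
#'
#' Accepts either float storage or packed integer storage with a
#' `scale_factor` attribute (applied automatically on read, so returned
#' values are physical VI). Missing sentinels become `NA`. A descending
#' latitude axis is flipped to the internal south-to-north convention.
#'
#' @param path Path to a NetCDF file with a `(time, lat, lon)` variable.
#' @param variable Variable name (default `"NDVI"`).
#' @return A [daily_vi_cube()].
#' @export
read_daily_cube <- function(path, variable = "NDVI") {
  if (!file.exists(path)) stop("file not found: ", path)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (!variable %in% names(nc$var))
    stop("variable '", variable, "' not found in ", path,
         " (has: ", paste(names(nc$var), collapse = ", "), ")")
  v <- nc$var[[variable]]
  dn <- vapply(v$dim, function(d) d$name, character(1))
  lat_name <- dn[grepl("^lat", dn, ignore.case = TRUE)][1]
  lon_name <- dn[grepl("^lon", dn, ignore.case = TRUE)][1]
  time_name <- dn[grepl("^time", dn, ignore.case = TRUE)][1]
  if (any(is.na(c(lat_name, lon_name, time_name))))
    stop("variable '", variable, "' lacks time/lat/lon dimensions")

  lat <- as.vector(ncdf4::ncvar_get(nc, lat_name))
  lon <- as.vector(ncdf4::ncvar_get(nc, lon_name))
  tvals <- as.vector(ncdf4::ncvar_get(nc, time_name))
  tunits <- ncdf4::ncatt_get(nc, time_name, "units")
  dates <- nc_time_to_date(tvals, if (tunits$hasatt) tunits$value else NULL)
  if (anyDuplicated(dates) || (length(dates) > 1 && any(diff(as.numeric(dates)) <= 0)))
    stop("time axis is not strictly increasing")

  # ncvar_get applies scale_factor/add_offset and maps sentinels to NA
  raw <- ncdf4::ncvar_get(nc, variable, collapse_degen = FALSE)
  # reorder to [time, lat, lon]
  perm <- match(c(time_name, lat_name, lon_name), dn)
  vals <- aperm(raw, perm)

  flip_lat <- length(lat) > 1 && lat[1] > lat[2]
  if (flip_lat) {
    lat <- rev(lat)
    vals <- vals[, rev(seq_along(lat)), , drop = FALSE]
  }
  cs <- if (length(lat) > 1) stats::median(diff(lat)) else
    if (length(lon) > 1) stats::median(diff(lon)) else 0.05
  grid <- grid_spec(lat_min = min(lat) - cs / 2, lat_max = max(lat) + cs / 2,
                    lon_min = min(lon) - cs / 2, lon_max = max(lon) + cs / 2,
                    cell_size = cs)
  daily_vi_cube(grid, dates, vals)
}

#' Write a daily VI cube to NetCDF-4
#'
#' Writes the variable with dimensions `(time, lat, lon)` and CF-style
#' "days since" time units. When `packed = TRUE` values are stored as 16-bit
#' signed integers with `scale_factor = 0.001` and fill sentinel -32768,
#' the convention used for released VI climate-data records.
#'
#' @param cube A [daily_vi_cube()].
#' @param path Output file path, or (with `split_by_year = TRUE`) an output
#'   directory receiving one `Daily_Gap-filled_NDVI_YYYY.nc4` file per year.
#' @param packed Store packed integers (default `TRUE`).
#' @param variable Variable name (default `"NDVI"`).
#' @param split_by_year Write one file per calendar year, named by
#'   [product_file_name()].
#' @return Invisibly, the path(s) written.
#' @export
write_daily_cube <- function(cube, path, packed = TRUE, variable = "NDVI",
                             split_by_year = FALSE) {
  stopifnot(inherits(cube, "daily_vi_cube"))
  rng <- range(cube$values, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < -1 || rng[2] > 1))
    stop("cube values outside [-1, 1] cannot be written")

  if (split_by_year) {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    years <- as.integer(format(cube$dates, "%Y"))
    paths <- character(0)
    for (y in unique(years)) {
      idx <- which(years == y)
      sub <- daily_vi_cube(cube$grid, cube$dates[idx],
                           cube$values[idx, , , drop = FALSE])
      p <- file.path(path, product_file_name(y))
      write_daily_cube(sub, p, packed = packed, variable = variable)
      paths <- c(paths, p)
    }
    return(invisible(paths))
  }

  epoch <- as.Date("1970-01-01")
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lon_centers(cube$grid))
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lat_centers(cube$grid))
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(cube$dates - epoch),
                               unlim = TRUE, calendar = "standard")
  # fastest-varying dimension first => file layout NDVI(time, lat, lon)
  if (packed) {
    var <- ncdf4::ncvar_def(variable, units = "1",
                            dim = list(dim_lon, dim_lat, dim_time),
                            missval = -32768L, prec = "short",
                            longname = "normalized difference vegetation index")
  } else {
    var <- ncdf4::ncvar_def(variable, units = "1",
                            dim = list(dim_lon, dim_lat, dim_time),
                            missval = -9999, prec = "double",
                            longname = "normalized difference vegetation index")
  }
  nc <- ncdf4::nc_create(path, var, force_v4 = TRUE)
  on.exit(ncdf4::nc_close(nc))
  out <- aperm(cube$values, c(3L, 2L, 1L))  # [lon, lat, time]
  if (packed) {
    packed_vals <- as.integer(round(out / 0.001))
    packed_vals[is.na(out)] <- -32768L
    dim(packed_vals) <- dim(out)
    ncdf4::ncvar_put(nc, var, packed_vals)
    ncdf4::ncatt_put(nc, var, "scale_factor", 0.001, prec = "double")
  } else {
    ncdf4::ncvar_put(nc, var, out)
  }
  invisible(path)
}

nc_time_to_date <- function(tvals, units) {
  if (is.null(units)) stop("time variable has no units attribute")
  m <- regmatches(units, regexec("^(\\w+) since ([0-9]{4}-[0-9]{2}-[0-9]{2})", units))[[1]]
  if (length(m) < 3) stop("unsupported time units: ", units)
  step <- tolower(m[2])
  origin <- as.Date(m[3])
  mult <- switch(step, days = 1, day = 1,
                 hours = 1 / 24, hour = 1 / 24,
                 seconds = 1 / 86400, second = 1 / 86400,
                 stop("unsupported time step: ", step))
  origin + round(tvals * mult)
}
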