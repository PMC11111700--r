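#' Configuration of the valid-data identification screens
#'
#' Two screens classify every daily observation. Stage 1 compares each day of
#' a target month against the reference set of its three-month sliding window
#' (the fundamental processing unit, FPU): the month maxima of the previous,
#' target and next months plus the two pairwise means with the target month —
#' up to five references, `V_max`. A day is valid when its absolute percent
#' bias to at least one reference is within `t1`. Stage 2 invalidates a whole
#' pixel-month when it has no data at all, or when the percent bias between
#' its monthly maximum and the mean monthly maximum of the same calendar
#' month in the adjacent four years (two before, two after) exceeds `t2`.
#'
#' The defaults `t1 = 20` and `t2 = 39` are the thresholds calibrated from
#' long-term monthly-maximum reference data (see [calibrate_thresholds()]).
#'
#' @param t1 Day-level percent-bias threshold (percent, > 0).
#' @param t2 Month-level interannual percent-bias threshold (percent, > 0).
#' @param semantics `"any"` (default): a day is valid if at least one
#'   reference is within `t1`; `"all"`: every reference must be within `t1`.
#' @return An `identification_config` list.
#' @export
identification_config <- function(t1 = 20, t2 = 39,
                                  semantics = c("any", "all")) {
  stopifnot(t1 > 0, t2 > 0)
  structure(list(t1 = t1, t2 = t2,
                 semantics = match.arg(semantics),
                 fpu_months = 3L, neighbor_years = 4L),
            class = "identification_config")
}

#' Monthly maxima of a daily cube
#'
#' The per pixel, per calendar month maximum over non-missing daily values
#' (`NDVI_max`); `NA` when the month has no data. The month axis is the
#' contiguous sequence of calendar months spanning the cube's date range.
#'
#' @param cube A [daily_vi_cube()].
#' @return A `monthly_vi_cube`: list with `months` (data frame of year,
#'   month), `values` array `[month, lat, lon]`, and `grid`.
#' @export
monthly_maxima <- function(cube) {
  months <- month_table(cube$dates)
  mi <- month_index(cube$dates, months)
  nm <- nrow(months)
  vals <- array(NA_real_, c(nm, cube$grid$lat_count, cube$grid$lon_count))
  for (k in seq_len(nm)) {
    idx <- which(mi == k)
    if (!length(idx)) next
    slab <- cube$values[idx, , , drop = FALSE]
    mx <- apply(slab, c(2, 3), function(v)
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
    vals[k, , ] <- mx
  }
  structure(list(months = months, values = vals, grid = cube$grid),
            class = "monthly_vi_cube")
}

#' Reference set of a three-month sliding window
#'
#' Builds the `V_max` reference collection for a target month: the monthly
#' maxima of the previous, target and next months, plus the mean of
#' (previous, target) and of (target, next). Members whose inputs are absent
#' (record edges, empty months) are omitted, so the set holds up to five
#' values and exactly five when all three maxima exist.
#'
#' @param prev_max,target_max,next_max Monthly maxima (`NA` when absent).
#' @return Numeric vector of 1-5 reference values.
#' @export
build_fpu_references <- function(prev_max, target_max, next_max) {
  if (is.na(prev_max) && is.na(target_max) && is.na(next_max))
    stop("all three monthly maxima are absent; no references can be built")
  refs <- c(prev_max, target_max, next_max)
  if (!is.na(prev_max) && !is.na(target_max))
    refs <- c(refs, (prev_max + target_max) / 2)
  if (!is.na(target_max) && !is.na(next_max))
    refs <- c(refs, (target_max + next_max) / 2)
  refs[!is.na(refs)]
}

#' Stage-1 validity of a single daily value
#'
#' Percent bias of the value against each nonzero reference; valid when the
#' smallest (semantics `"any"`) or largest (semantics `"all"`) absolute
#' percent bias does not exceed `t1`. Zero-valued references have undefined
#' percent bias and are skipped; if every reference is zero the day is
#' invalid (with a warning), since a barren reference level cannot vouch for
#' a nonzero observation.
#'
#' @param value Non-missing daily VI value.
#' @param refs Reference vector from [build_fpu_references()].
#' @param t1 Percent threshold.
#' @param semantics `"any"` or `"all"`.
#' @return `"valid"` or `"invalid"`.
#' @export
day_validity <- function(value, refs, t1, semantics = "any") {
  stopifnot(!is.na(value), length(refs) >= 1L)
  refs <- refs[refs != 0]
  if (!length(refs)) {
    warning("all references are zero; day classified invalid")
    return("invalid")
  }
  pb <- abs((value - refs) / refs) * 100
  ok <- if (semantics == "any") min(pb) <= t1 else max(pb) <= t1
  if (ok) "valid" else "invalid"
}

#' Stage-2 validity of a pixel-month
#'
#' A month is invalid with reason `"no-data"` when it has no observations,
#' and with reason `"interannual-PB-exceeded"` when the percent bias between
#' its maximum and the mean of the same calendar month's maxima in the
#' adjacent four years exceeds `t2`. With no neighbour maxima (or a zero
#' neighbour mean) the interannual test is skipped and the month passes.
#'
#' @param target_max Monthly maximum of the target month (`NA` if absent).
#' @param neighbor_year_maxima Maxima of the same calendar month in years
#'   y-2, y-1, y+1, y+2 (available subset; `NA`s dropped).
#' @param t2 Percent threshold.
#' @return List with `invalid` (logical) and `reason` (`"no-data"`,
#'   `"interannual-PB-exceeded"` or `"none"`).
#' @export
month_validity <- function(target_max, neighbor_year_maxima, t2) {
  if (is.na(target_max))
    return(list(invalid = TRUE, reason = "no-data"))
  nb <- neighbor_year_maxima[!is.na(neighbor_year_maxima)]
  if (!length(nb))
    return(list(invalid = FALSE, reason = "none"))
  m <- mean(nb)
  if (m == 0)
    return(list(invalid = FALSE, reason = "none"))
  pb <- abs((target_max - m) / m) * 100
  if (pb > t2)
    list(invalid = TRUE, reason = "interannual-PB-exceeded")
  else
    list(invalid = FALSE, reason = "none")
}

#' Classify every daily observation as valid, invalid or missing
#'
#' Applies the stage-1 sliding-window screen to every non-missing day, then
#' overrides with the stage-2 month-level flags: every non-missing day of an
#' invalid month is invalid. Missing days stay missing. Stage-2 monthly
#' maxima are computed from the raw non-missing data, so the two screens are
#' independent.
#'
#' @param cube A [daily_vi_cube()].
#' @param config An [identification_config()].
#' @return A `validity_mask`: list with `labels` (integer array
#'   `[time, lat, lon]`, 0 = missing, 1 = valid, 2 = invalid), `month_flags`
#'   (integer array `[month, lat, lon]`, 0 = none, 1 = no-data,
#'   2 = interannual-PB-exceeded), `months`, `dates`, `grid`.
#' @export
identify_valid <- function(cube, config = identification_config()) {
  stopifnot(inherits(cube, "daily_vi_cube"),
            inherits(config, "identification_config"))
  mm <- monthly_maxima(cube)
  months <- mm$months
  nm <- nrow(months)
  mi <- month_index(cube$dates, months)
  nlat <- cube$grid$lat_count
  nlon <- cube$grid$lon_count

  labels <- array(0L, dim(cube$values))
  month_flags <- array(0L, c(nm, nlat, nlon))
  day_idx_by_month <- split(seq_along(cube$dates), factor(mi, levels = seq_len(nm)))

  # month indices of the same calendar month in years y-2, y-1, y+1, y+2
  neighbor_idx <- lapply(seq_len(nm), function(k) {
    y <- months$year[k]; mo <- months$month[k]
    j <- which(months$month == mo & months$year %in% (y + c(-2L, -1L, 1L, 2L)))
    j
  })

  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    mx <- mm$values[, i, j]
    for (k in seq_len(nm)) {
      # stage 2: month-level screen
      nb <- mx[neighbor_idx[[k]]]
      mv <- month_validity(mx[k], nb, config$t2)
      if (mv$invalid)
        month_flags[k, i, j] <- if (mv$reason == "no-data") 1L else 2L

      days <- day_idx_by_month[[k]]
      if (!length(days)) next
      v <- cube$values[days, i, j]
      obs <- which(!is.na(v))
      if (!length(obs)) next
      if (mv$invalid) {
        labels[days[obs], i, j] <- 2L
        next
      }
      # stage 1: FPU percent-bias screen
      prev <- if (k > 1L) mx[k - 1L] else NA_real_
      nxt <- if (k < nm) mx[k + 1L] else NA_real_
      refs <- build_fpu_references(prev, mx[k], nxt)
      refs <- refs[refs != 0]
      if (!length(refs)) {
        labels[days[obs], i, j] <- 2L
        next
      }
      for (d in obs) {
        pb <- abs((v[d] - refs) / refs) * 100
        ok <- if (config$semantics == "any") min(pb) <= config$t1
              else max(pb) <= config$t1
        labels[days[d], i, j] <- if (ok) 1L else 2L
      }
    }
  }
  structure(list(labels = labels, month_flags = month_flags,
                 months = months, dates = cube$dates, grid = cube$grid),
            class = "validity_mask")
}

#' @export
print.validity_mask <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<validity_mask> %d days x %d x %d px: %.1f%% valid, %.1f%% invalid, %.1f%% missing\n",
              length(x$dates), dim(x$labels)[2], dim(x$labels)[3],
              100 * sum(x$labels == 1L) / n, 100 * sum(x$labels == 2L) / n,
              100 * sum(x$labels == 0L) / n))
  invisible(x)
}

#' Write a validity mask to NetCDF-4
#'
#' Day labels are stored as a byte variable (0 = missing, 1 = valid,
#' 2 = invalid) plus a monthly flag variable on a month axis.
#'
#' @param mask A `validity_mask`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_validity_mask <- function(mask, path) {
  epoch <- as.Date("1970-01-01")
  grid <- mask$grid
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lon_centers(grid))
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lat_centers(grid))
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(mask$dates - epoch), calendar = "standard")
  mstart <- as.Date(sprintf("%04d-%02d-01", mask$months$year, mask$months$month))
  dim_month <- ncdf4::ncdim_def("month", "days since 1970-01-01",
                                as.numeric(mstart - epoch), calendar = "standard")
  v1 <- ncdf4::ncvar_def("label", "1", list(dim_lon, dim_lat, dim_time),
                         missval = -1L, prec = "byte",
                         longname = "0=missing 1=valid 2=invalid")
  v2 <- ncdf4::ncvar_def("month_flag", "1", list(dim_lon, dim_lat, dim_month),
                         missval = -1L, prec = "byte",
                         longname = "0=none 1=no-data 2=interannual-PB-exceeded")
  nc <- ncdf4::nc_create(path, list(v1, v2), force_v4 = TRUE)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v1, aperm(mask$labels, c(3, 2, 1)))
  ncdf4::ncvar_put(nc, v2, aperm(mask$month_flags, c(3, 2, 1)))
  invisible(path)
}

#' Read a validity mask written by [write_validity_mask()]
#' @param path NetCDF file path.
#' @return A `validity_mask`.
#' @export
read_validity_mask <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lat <- as.vector(ncdf4::ncvar_get(nc, "lat"))
  lon <- as.vector(ncdf4::ncvar_get(nc, "lon"))
  dates <- nc_time_to_date(as.vector(ncdf4::ncvar_get(nc, "time")),
                           ncdf4::ncatt_get(nc, "time", "units")$value)
  mdates <- nc_time_to_date(as.vector(ncdf4::ncvar_get(nc, "month")),
                            ncdf4::ncatt_get(nc, "month", "units")$value)
  cs <- if (length(lat) > 1) stats::median(diff(lat)) else 0.05
  grid <- grid_spec(min(lat) - cs / 2, max(lat) + cs / 2,
                    min(lon) - cs / 2, max(lon) + cs / 2, cell_size = cs)
  labels <- aperm(ncdf4::ncvar_get(nc, "label", collapse_degen = FALSE), c(3, 2, 1))
  flags <- aperm(ncdf4::ncvar_get(nc, "month_flag", collapse_degen = FALSE), c(3, 2, 1))
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 month_flags = array(as.integer(flags), dim(flags)),
                 months = data.frame(year = as.integer(format(mdates, "%Y")),
                                     month = as.integer(format(mdates, "%m"))),
                 dates = dates, grid = grid),
            class = "validity_mask")
}

#' Calibrate the screening thresholds from a monthly-maximum reference
#'
#' Reproduces the threshold-derivation procedure: from a long-term monthly
#' maximum VI reference series, `t1` is estimated as the mean absolute
#' percent bias between adjacent-month maxima over all pixels and
#' consecutive-month pairs, and `t2` as the mean over pixels of each pixel's
#' maximum adjacent-month absolute percent bias. Pairs with a missing value
#' or zero denominator are skipped.
#'
#' @param monthly_max_reference A `monthly_vi_cube` (e.g. from
#'   [monthly_maxima()] or [mvc_monthly_composite()]) spanning several years.
#' @return Named numeric vector `c(t1 = ..., t2 = ...)` in percent.
#' @export
calibrate_thresholds <- function(monthly_max_reference) {
  stopifnot(inherits(monthly_max_reference, "monthly_vi_cube"))
  vals <- monthly_max_reference$values
  nm <- dim(vals)[1]
  if (nm < 2L) stop("reference must span at least two consecutive months")
  all_pb <- numeric(0)
  pixel_max <- numeric(0)
  for (i in seq_len(dim(vals)[2])) for (j in seq_len(dim(vals)[3])) {
    v <- vals[, i, j]
    prev <- v[-nm]; curr <- v[-1]
    use <- !is.na(prev) & !is.na(curr) & prev != 0
    if (!any(use)) next
    pb <- abs((curr[use] - prev[use]) / prev[use]) * 100
    all_pb <- c(all_pb, pb)
    pixel_max <- c(pixel_max, max(pb))
  }
  if (!length(all_pb)) stop("no usable consecutive-month pairs in reference")
  c(t1 = mean(all_pb), t2 = mean(pixel_max))
}
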