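#' Configuration of the segmented quartic reconstruction
#'
#' Each pixel-year is split at the date of its maximum valid VI (the annual
#' greenness peak) into a growth and a withering stage. The growth segment
#' pools valid observations from October-December of the previous year and
#' January up to the peak of the current year; the withering segment pools
#' the days after the peak through December plus January-March of the
#' following year. Each segment is fitted by a least-squares quartic
#' polynomial on a time axis rescaled to [-1, 1] over the segment window;
#' segments with fewer than `min_points` valid observations fall back to the
#' adjacent-four-year mean fill.
#'
#' @param min_points Minimum valid observations per segment fit (>= 5, the
#'   quartic identifiability bound; default 10 to guard against wild
#'   extrapolation).
#' @param clamp_range Output range; fitted values are clamped to it.
#' @param keep_observations If `TRUE`, originally valid observations are kept
#'   and only invalid/missing days take fitted values. Default `FALSE`: the
#'   fitted curve replaces all days.
#' @return A `reconstruction_config` list.
#' @export
reconstruction_config <- function(min_points = 10L,
                                  clamp_range = c(-1, 1),
                                  keep_observations = FALSE) {
  min_points <- as.integer(min_points)
  stopifnot(min_points >= 5L, length(clamp_range) == 2L,
            clamp_range[1] < clamp_range[2])
  structure(list(min_points = min_points, clamp_range = clamp_range,
                 keep_observations = keep_observations,
                 neighbor_years = 4L, tie_break = "earliest-peak"),
            class = "reconstruction_config")
}

#' Date of the annual greenness peak
#'
#' The date of the maximum valid value within one pixel-year; ties are broken
#' by the earliest date.
#'
#' @param dates `Date` vector of valid observations in the year.
#' @param values Their VI values.
#' @return The peak `Date`, or `NA` (class `Date`) when the year has no
#'   valid data (an unfittable year, handled downstream by the
#'   adjacent-year fill).
#' @export
find_peak_day <- function(dates, values) {
  keep <- !is.na(values)
  if (!any(keep)) return(as.Date(NA))
  dates <- dates[keep]; values <- values[keep]
  o <- order(dates)
  dates <- dates[o]; values <- values[o]
  dates[which.max(values)]  # which.max returns the first (earliest) maximum
}

#' Assemble the growth-stage data segment
#'
#' Valid observations in October-December of `year - 1` united with those
#' from January 1 of `year` up to (and including) the peak. The time
#' coordinate is days since October 1 of `year - 1`.
#'
#' @param dates,values Dated valid observations of one pixel (any range).
#' @param year Target year.
#' @param peak Peak date within `year`.
#' @return Data frame with columns `date`, `t` (days since window origin)
#'   and `value`; attributes `origin` and `window_end` delimit the segment
#'   window.
#' @export
assemble_growth_segment <- function(dates, values, year, peak) {
  origin <- as.Date(sprintf("%04d-10-01", year - 1L))
  keep <- !is.na(values) &
    ((dates >= origin & dates <= as.Date(sprintf("%04d-12-31", year - 1L))) |
       (dates >= as.Date(sprintf("%04d-01-01", year)) & dates <= peak))
  seg <- data.frame(date = dates[keep],
                    t = as.numeric(dates[keep] - origin),
                    value = values[keep])
  attr(seg, "origin") <- origin
  attr(seg, "window_end") <- peak
  seg
}

#' Assemble the withering-stage data segment
#'
#' Valid observations after the peak through December 31 of `year`, united
#' with January-March of `year + 1`. The time coordinate is days since the
#' peak date.
#'
#' @inheritParams assemble_growth_segment
#' @return Data frame as in [assemble_growth_segment()]; the window runs from
#'   the peak to March 31 of `year + 1`.
#' @export
assemble_withering_segment <- function(dates, values, year, peak) {
  origin <- peak
  window_end <- as.Date(sprintf("%04d-03-31", year + 1L))
  keep <- !is.na(values) &
    ((dates > peak & dates <= as.Date(sprintf("%04d-12-31", year))) |
       (dates >= as.Date(sprintf("%04d-01-01", year + 1L)) & dates <= window_end))
  seg <- data.frame(date = dates[keep],
                    t = as.numeric(dates[keep] - origin),
                    value = values[keep])
  attr(seg, "origin") <- origin
  attr(seg, "window_end") <- window_end
  seg
}

#' Least-squares quartic fit of one data segment
#'
#' Fits a degree-4 polynomial by ordinary least squares. For numerical
#' conditioning the time axis is affinely rescaled to [-1, 1] over the
#' segment window before fitting; the origin and scale are stored so
#' evaluation is exact. Segments with fewer than `min_points` observations,
#' fewer than 5 distinct dates, or a rank-deficient design fall back
#' (`status = "fallback"`), to be filled from adjacent years instead.
#'
#' @param segment Data frame from the segment assemblers (columns `t`,
#'   `value`; attributes `origin`, `window_end`).
#' @param config A [reconstruction_config()].
#' @return A `segment_fit`: list with `coefficients` (5 values, ascending
#'   degree), `time_origin` (`Date`), `time_scale` (window length, days),
#'   `support_n`, `status` (`"fitted"` or `"fallback"`).
#' @export
fit_quartic <- function(segment, config = reconstruction_config()) {
  origin <- attr(segment, "origin")
  span <- as.numeric(attr(segment, "window_end") - origin)
  n <- nrow(segment)
  fallback <- structure(list(coefficients = rep(NA_real_, 5),
                             time_origin = origin, time_scale = span,
                             support_n = n, status = "fallback"),
                        class = "segment_fit")
  if (n < config$min_points || span <= 0) return(fallback)
  if (length(unique(segment$t)) < 5L) return(fallback)
  x <- 2 * segment$t / span - 1
  X <- cbind(1, x, x^2, x^3, x^4)
  fit <- stats::lm.fit(X, segment$value)
  beta <- fit$coefficients
  if (anyNA(beta) || any(!is.finite(beta))) return(fallback)
  structure(list(coefficients = unname(beta),
                 time_origin = origin, time_scale = span,
                 support_n = n, status = "fitted"),
            class = "segment_fit")
}

#' Evaluate a segment fit at calendar dates
#'
#' @param fit A `segment_fit` with `status = "fitted"`.
#' @param dates `Date` vector.
#' @return Fitted VI values (unclamped).
#' @export
evaluate_segment <- function(fit, dates) {
  stopifnot(inherits(fit, "segment_fit"), fit$status == "fitted")
  x <- 2 * as.numeric(dates - fit$time_origin) / fit$time_scale - 1
  b <- fit$coefficients
  b[1] + x * (b[2] + x * (b[3] + x * (b[4] + x * b[5])))
}

#' Reconstruct one pixel-year from its two segment fits
#'
#' Days from January 1 to the peak are evaluated from the growth polynomial,
#' days after the peak from the withering polynomial; values are clamped to
#' the configured range. Days under a fallback segment are left missing for
#' the adjacent-year fill.
#'
#' @param growth_fit,withering_fit `segment_fit` objects.
#' @param year Target year.
#' @param peak Peak date in `year`.
#' @param config A [reconstruction_config()].
#' @return Named list: `dates` (every day of `year`) and `values` (`NA`
#'   under fallback segments).
#' @export
reconstruct_pixel_year <- function(growth_fit, withering_fit, year, peak,
                                   config = reconstruction_config()) {
  days <- seq(as.Date(sprintf("%04d-01-01", year)),
              as.Date(sprintf("%04d-12-31", year)), by = "day")
  out <- rep(NA_real_, length(days))
  pre <- days <= peak
  if (growth_fit$status == "fitted")
    out[pre] <- evaluate_segment(growth_fit, days[pre])
  if (withering_fit$status == "fitted")
    out[!pre] <- evaluate_segment(withering_fit, days[!pre])
  out <- pmin(pmax(out, config$clamp_range[1]), config$clamp_range[2])
  list(dates = days, values = out)
}

#' Fill residual gaps from the adjacent four years
#'
#' Each missing (pixel, date) is replaced by the mean of the reconstructed
#' values on the matching calendar day in years y-2, y-1, y+1, y+2 (the
#' available subset); February 29 maps to February 28 in non-leap neighbour
#' years. Only fit-stage values are used as donors, so the result does not
#' depend on fill order. Errors if some gap has no donor in any of the four
#' neighbour years.
#'
#' @param cube A partially reconstructed [daily_vi_cube()] (daily-complete
#'   date axis, `NA` runs where both segment fits fell back).
#' @return A gap-free [daily_vi_cube()].
#' @export
fill_residual_gaps <- function(cube) {
  vals <- cube$values
  if (!anyNA(vals)) return(cube)
  dates <- cube$dates
  years <- as.integer(format(dates, "%Y"))
  monthday <- format(dates, "%m-%d")
  # donor day index for (year, month-day), Feb 29 -> Feb 28 in non-leap years
  date_key <- paste(years, monthday)
  lookup <- function(y, md) {
    if (md == "02-29" && !is_leap(y)) md <- "02-28"
    match(paste(y, md), date_key)
  }
  donor <- array(NA_integer_, c(length(dates), 4L))
  for (d in seq_along(dates)) {
    nb <- years[d] + c(-2L, -1L, 1L, 2L)
    donor[d, ] <- vapply(nb, lookup, integer(1), md = monthday[d])
  }
  out <- vals
  failed <- character(0)
  nlat <- dim(vals)[2]; nlon <- dim(vals)[3]
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    v <- vals[, i, j]
    gaps <- which(is.na(v))
    if (!length(gaps)) next
    for (d in gaps) {
      src <- donor[d, ]
      cand <- v[src[!is.na(src)]]
      cand <- cand[!is.na(cand)]
      if (!length(cand)) {
        failed <- c(failed, sprintf("pixel (%d, %d) %s", i, j,
                                    format(dates[d])))
      } else {
        out[d, i, j] <- mean(cand)
      }
    }
  }
  if (length(failed))
    stop("no adjacent-year donor for ", length(failed), " pixel-dates, e.g. ",
         paste(utils::head(failed, 5), collapse = "; "))
  daily_vi_cube(cube$grid, dates, out)
}

is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0

#' Reconstruct a gap-free daily cube
#'
#' Runs the full per-pixel, per-year reconstruction: peak finding on valid
#' data, growth/withering segment assembly, quartic fits, evaluation, and
#' the adjacent-four-year fill for whatever the fits could not cover. The
#' output covers every day between the first and last input date with no
#' missing values.
#'
#' @param cube A [daily_vi_cube()] (gaps in the date axis allowed).
#' @param mask A `validity_mask` from [identify_valid()], aligned with
#'   `cube`.
#' @param config A [reconstruction_config()].
#' @return A gap-free [daily_vi_cube()] with attribute `fit_stats`
#'   (data frame: per-pixel counts of fitted/fallback segments and the mean
#'   absolute growth/withering discontinuity at the peak).
#' @export
reconstruct_cube <- function(cube, mask, config = reconstruction_config()) {
  stopifnot(inherits(cube, "daily_vi_cube"), inherits(mask, "validity_mask"))
  if (!identical(dim(cube$values), dim(mask$labels)) ||
      !identical(cube$dates, mask$dates))
    stop("mask is not aligned with the cube")

  out_dates <- seq(min(cube$dates), max(cube$dates), by = "day")
  in_pos <- match(cube$dates, out_dates)
  nlat <- cube$grid$lat_count; nlon <- cube$grid$lon_count
  out <- array(NA_real_, c(length(out_dates), nlat, nlon))
  all_years <- sort(unique(as.integer(format(cube$dates, "%Y"))))
  out_years <- as.integer(format(out_dates, "%Y"))

  n_fitted <- matrix(0L, nlat, nlon)
  n_fallback <- matrix(0L, nlat, nlon)
  jump_sum <- matrix(0, nlat, nlon)
  jump_n <- matrix(0L, nlat, nlon)

  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    lab <- mask$labels[, i, j]
    vidx <- which(lab == 1L)
    vdates <- cube$dates[vidx]
    vvals <- cube$values[vidx, i, j]
    vyears <- as.integer(format(vdates, "%Y"))
    for (y in all_years) {
      ysel <- vyears == y
      yslots <- which(out_years == y)
      if (!any(ysel)) { n_fallback[i, j] <- n_fallback[i, j] + 2L; next }
      peak <- find_peak_day(vdates[ysel], vvals[ysel])
      gseg <- assemble_growth_segment(vdates, vvals, y, peak)
      wseg <- assemble_withering_segment(vdates, vvals, y, peak)
      gfit <- fit_quartic(gseg, config)
      wfit <- fit_quartic(wseg, config)
      n_fitted[i, j] <- n_fitted[i, j] +
        sum(gfit$status == "fitted", wfit$status == "fitted")
      n_fallback[i, j] <- n_fallback[i, j] +
        sum(gfit$status == "fallback", wfit$status == "fallback")
      if (gfit$status == "fitted" && wfit$status == "fitted") {
        jump <- abs(evaluate_segment(gfit, peak) - evaluate_segment(wfit, peak))
        jump_sum[i, j] <- jump_sum[i, j] + jump
        jump_n[i, j] <- jump_n[i, j] + 1L
      }
      ry <- reconstruct_pixel_year(gfit, wfit, y, peak, config)
      keep <- ry$dates >= min(out_dates) & ry$dates <= max(out_dates)
      out[match(ry$dates[keep], out_dates), i, j] <- ry$values[keep]
    }
  }
  if (config$keep_observations) {
    obs <- which(mask$labels == 1L)
    # map (time in cube) positions into the daily-complete axis
    full_lab <- array(0L, dim(out))
    full_lab[in_pos, , ] <- mask$labels
    full_vals <- array(NA_real_, dim(out))
    full_vals[in_pos, , ] <- cube$values
    keep <- full_lab == 1L
    out[keep] <- full_vals[keep]
  }
  partial <- daily_vi_cube(cube$grid, out_dates, out)
  result <- fill_residual_gaps(partial)
  attr(result, "fit_stats") <- data.frame(
    fitted_segments = as.integer(n_fitted),
    fallback_segments = as.integer(n_fallback),
    mean_peak_discontinuity = ifelse(jump_n > 0, jump_sum / pmax(jump_n, 1L), NA_real_)
  )
  result
}
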