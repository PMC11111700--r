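#' Validation metrics
#'
#' The five criteria used to score a reconstruction against a comparison
#' series: Pearson correlation `r`, coefficient of determination
#' `R^2 = 1 - SSres/SStot` (residuals of the reconstruction about the
#' observations, total sum of squares about the observed mean), mean absolute
#' error, root mean square error, and percent bias
#' `PB = mean((rec - ref)/ref) * 100`. Pairs with a missing member are
#' dropped; for `percent_bias`, pairs with a zero reference are additionally
#' skipped and their count reported as attribute `n_skipped_zero_ref`.
#'
#' @param rec Reconstructed values.
#' @param ref,obs Comparison values (`obs` emphasises the asymmetric role in
#'   `r_squared` and `percent_bias`: the denominator/variance baseline).
#' @return A single numeric value (percent for `percent_bias`).
#' @name metrics
NULL

paired <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  list(a = a[keep], b = b[keep])
}

#' @rdname metrics
#' @export
percent_bias <- function(rec, ref) {
  p <- paired(rec, ref)
  nz <- p$b != 0
  if (!any(nz)) stop("no pairs with nonzero reference; percent bias undefined")
  structure(mean((p$a[nz] - p$b[nz]) / p$b[nz]) * 100,
            n_skipped_zero_ref = sum(!nz))
}

#' @rdname metrics
#' @export
r_squared <- function(rec, obs) {
  p <- paired(rec, obs)
  if (length(p$a) < 2L) stop("need at least 2 pairs for R^2")
  ss_tot <- sum((p$b - mean(p$b))^2)
  if (ss_tot == 0) stop("observations are constant; R^2 undefined")
  1 - sum((p$b - p$a)^2) / ss_tot
}

#' @rdname metrics
#' @export
pearson_r <- function(rec, ref) {
  p <- paired(rec, ref)
  if (length(p$a) < 2L) stop("need at least 2 pairs for r")
  if (stats::sd(p$a) == 0 || stats::sd(p$b) == 0)
    stop("constant input; correlation undefined")
  stats::cor(p$a, p$b)
}

#' @rdname metrics
#' @export
mae <- function(rec, ref) {
  p <- paired(rec, ref)
  if (!length(p$a)) stop("no complete pairs")
  mean(abs(p$a - p$b))
}

#' @rdname metrics
#' @export
rmse <- function(rec, ref) {
  p <- paired(rec, ref)
  if (!length(p$a)) stop("no complete pairs")
  sqrt(mean((p$a - p$b)^2))
}

#' Per-pixel metric maps
#'
#' Computes the full metric set for every pixel between two aligned cubes.
#' With a validity mask, only days labelled valid enter the comparison
#' (self-validation against the original valid observations); without one,
#' all days with both values present are used (dataset inter-comparison).
#' Pixels with fewer than `min_n` usable pairs, or constant series, are
#' flagged insufficient (`NA` metrics, `flag = TRUE`).
#'
#' @param recon,reference Aligned [daily_vi_cube()]s (same grid and dates).
#' @param mask Optional `validity_mask` aligned with `reference`.
#' @param min_n Minimum pairs per pixel (default 2).
#' @return A `metric_map`: list of `[lat, lon]` matrices `r`, `r2`, `mae`,
#'   `rmse`, `pb`, `n`, logical `flag`, plus the `grid`.
#' @export
pixelwise_metrics <- function(recon, reference, mask = NULL, min_n = 2L) {
  if (!identical(dim(recon$values), dim(reference$values)) ||
      !identical(recon$dates, reference$dates))
    stop("recon and reference grids/date ranges do not match")
  if (!is.null(mask) && !identical(mask$dates, reference$dates))
    stop("mask does not match the reference date axis")
  nlat <- recon$grid$lat_count; nlon <- recon$grid$lon_count
  m <- function() matrix(NA_real_, nlat, nlon)
  res <- list(r = m(), r2 = m(), mae = m(), rmse = m(), pb = m(),
              n = matrix(0L, nlat, nlon),
              flag = matrix(TRUE, nlat, nlon), grid = recon$grid)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    a <- recon$values[, i, j]
    b <- reference$values[, i, j]
    keep <- !is.na(a) & !is.na(b)
    if (!is.null(mask)) keep <- keep & mask$labels[, i, j] == 1L
    a <- a[keep]; b <- b[keep]
    res$n[i, j] <- length(a)
    if (length(a) < min_n || stats::sd(b) == 0 || stats::sd(a) == 0) next
    res$flag[i, j] <- FALSE
    res$r[i, j] <- stats::cor(a, b)
    res$r2[i, j] <- 1 - sum((b - a)^2) / sum((b - mean(b))^2)
    res$mae[i, j] <- mean(abs(a - b))
    res$rmse[i, j] <- sqrt(mean((a - b)^2))
    nz <- b != 0
    res$pb[i, j] <- if (any(nz)) mean((a[nz] - b[nz]) / b[nz]) * 100 else NA_real_
  }
  structure(res, class = "metric_map")
}

#' Quality classification of a metric map
#'
#' Applies a named quality rule to every non-flagged pixel and reports the
#' passing proportion. Rule `"self"` (reconstruction vs original valid data):
#' |PB| < 1%, RMSE < 0.08 and R^2 > 0.5. Rule `"modis"` (inter-comparison
#' with an independent daily product): r > 0.5, |PB| < 50% and RMSE < 0.2.
#'
#' @param metrics A `metric_map` from [pixelwise_metrics()].
#' @param rule `"self"` or `"modis"`, or a function of a one-row metric list.
#' @return List with `pass` (logical `[lat, lon]`; `NA` for flagged pixels)
#'   and `proportion` (share of non-flagged pixels passing).
#' @export
quality_classification <- function(metrics, rule = c("self", "modis")) {
  stopifnot(inherits(metrics, "metric_map"))
  if (is.character(rule)) {
    rule <- switch(match.arg(rule),
      self = function(m) abs(m$pb) < 1 & m$rmse < 0.08 & m$r2 > 0.5,
      modis = function(m) m$r > 0.5 & abs(m$pb) < 50 & m$rmse < 0.2)
  }
  pass <- rule(metrics)
  pass[metrics$flag] <- NA
  n_ok <- sum(!metrics$flag)
  list(pass = pass,
       proportion = if (n_ok) sum(pass, na.rm = TRUE) / n_ok else NA_real_)
}

#' Latitudinal profile of a metric map
#'
#' Row-wise (one 0.05 degree grid row per band) mean and standard deviation
#' over non-flagged pixels.
#'
#' @param metrics A `metric_map`.
#' @param field Which metric (`"r"`, `"r2"`, `"mae"`, `"rmse"`, `"pb"`).
#' @return Data frame with `lat` (band centre), `mean`, `sd`, `n`.
#' @export
latitudinal_profile <- function(metrics, field = "pb") {
  stopifnot(inherits(metrics, "metric_map"), field %in% c("r", "r2", "mae", "rmse", "pb"))
  vals <- metrics[[field]]
  vals[metrics$flag] <- NA
  data.frame(
    lat = lat_centers(metrics$grid),
    mean = apply(vals, 1, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)),
    sd = apply(vals, 1, function(v) if (sum(!is.na(v)) < 2) NA_real_ else stats::sd(v, na.rm = TRUE)),
    n = apply(vals, 1, function(v) sum(!is.na(v)))
  )
}

#' Monthly maximum-value composite
#'
#' The per pixel-month maximum over non-missing days (the MVC method used to
#' build monthly VI products); absent when the month has no data. A gap-free
#' daily cube therefore composites with no absent cells.
#'
#' @param cube A [daily_vi_cube()].
#' @return A `monthly_vi_cube` (see [monthly_maxima()]).
#' @export
mvc_monthly_composite <- function(cube) monthly_maxima(cube)

#' Nearest-neighbour regridding
#'
#' Assigns to each target cell the value of the source cell whose centre is
#' nearest the target cell centre (independently in latitude and longitude on
#' the regular grids); ties go to the smaller index. Used to bring coarser
#' comparison products onto the 0.05 degree grid.
#'
#' @param cube A [daily_vi_cube()] or `monthly_vi_cube` on a source grid.
#' @param target A `grid_spec` overlapping the source grid.
#' @return The same kind of cube on the target grid.
#' @export
regrid_nearest <- function(cube, target) {
  stopifnot(inherits(target, "grid_spec"))
  src <- cube$grid
  if (src$lat_max <= target$lat_min || src$lat_min >= target$lat_max ||
      src$lon_max <= target$lon_min || src$lon_min >= target$lon_max)
    stop("source and target grids do not overlap")
  nearest <- function(src_c, tgt_c)
    vapply(tgt_c, function(x) which.min(abs(src_c - x)), integer(1))
  li <- nearest(lat_centers(src), lat_centers(target))
  lj <- nearest(lon_centers(src), lon_centers(target))
  vals <- cube$values[, li, lj, drop = FALSE]
  if (inherits(cube, "daily_vi_cube"))
    daily_vi_cube(target, cube$dates, vals)
  else
    structure(list(months = cube$months, values = vals, grid = target),
              class = "monthly_vi_cube")
}

#' Write a metric map as CSV
#'
#' One row per pixel with cell-centre coordinates and all metrics.
#'
#' @param metrics A `metric_map`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_metric_csv <- function(metrics, path) {
  grid <- metrics$grid
  df <- expand.grid(lat = lat_centers(grid), lon = lon_centers(grid))
  for (f in c("r", "r2", "mae", "rmse", "pb", "n"))
    df[[f]] <- as.vector(metrics[[f]])
  df$flag <- as.vector(metrics$flag)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
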