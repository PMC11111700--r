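#' Run the full reconstruction pipeline
#'
#' Wires the stages together: identify valid data, reconstruct a gap-free
#' cube, and (optionally) self-evaluate against the original valid
#' observations. Writes per-year product files named
#' `Daily_Gap-filled_NDVI_YYYY.nc4`, the validity mask, and a JSON run
#' report. Deterministic for a fixed input and configuration.
#'
#' @param input A [daily_vi_cube()] or a path to a NetCDF file readable by
#'   [read_daily_cube()].
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param identification An [identification_config()].
#' @param reconstruction A [reconstruction_config()].
#' @param evaluate Run the self-validation metrics (default `TRUE`).
#' @param rule Quality rule for [quality_classification()].
#' @param variable NetCDF variable name when `input` is a path.
#' @return Invisibly, a list: `cube` (gap-free output), `mask`, `metrics`
#'   (or `NULL`), and `report` (valid-data fraction, fallback counts, metric
#'   summaries, file paths).
#' @export
run_pipeline <- function(input, out_dir = NULL,
                         identification = identification_config(),
                         reconstruction = reconstruction_config(),
                         evaluate = TRUE, rule = "self",
                         variable = "NDVI") {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cube <- stage("input", {
    if (is.character(input)) read_daily_cube(input, variable) else {
      stopifnot(inherits(input, "daily_vi_cube")); input
    }
  })
  mask <- stage("identify", identify_valid(cube, identification))
  recon <- stage("reconstruct", reconstruct_cube(cube, mask, reconstruction))
  fit_stats <- attr(recon, "fit_stats")

  metrics <- NULL
  report <- list(
    n_days = length(cube$dates),
    n_pixels = cube$grid$lat_count * cube$grid$lon_count,
    valid_fraction = mean(mask$labels == 1L),
    invalid_fraction = mean(mask$labels == 2L),
    missing_fraction = mean(mask$labels == 0L),
    fallback_segments = sum(fit_stats$fallback_segments),
    fitted_segments = sum(fit_stats$fitted_segments),
    output_missing = missing_count(recon)
  )
  if (evaluate) {
    metrics <- stage("evaluate", {
      full <- align_to(cube, recon$dates)
      full_mask <- align_mask_to(mask, recon$dates)
      pixelwise_metrics(recon, full, mask = full_mask)
    })
    qc <- quality_classification(metrics, rule)
    report$self_r2_mean <- mean(metrics$r2[!metrics$flag])
    report$self_rmse_mean <- mean(metrics$rmse[!metrics$flag])
    report$self_pb_mean <- mean(metrics$pb[!metrics$flag])
    report$high_quality_proportion <- qc$proportion
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    report$product_files <- as.character(
      write_daily_cube(recon, out_dir, packed = TRUE, split_by_year = TRUE))
    report$mask_file <- write_validity_mask(
      mask, file.path(out_dir, "validity_mask.nc4"))
    report_path <- file.path(out_dir, "run_report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
    report$report_file <- report_path
  }
  invisible(list(cube = recon, mask = mask, metrics = metrics,
                 report = report))
}

# expand a cube onto a daily-complete date axis (NA where absent)
align_to <- function(cube, dates) {
  vals <- array(NA_real_, c(length(dates), dim(cube$values)[2], dim(cube$values)[3]))
  vals[match(cube$dates, dates), , ] <- cube$values
  daily_vi_cube(cube$grid, dates, vals)
}

align_mask_to <- function(mask, dates) {
  labels <- array(0L, c(length(dates), dim(mask$labels)[2], dim(mask$labels)[3]))
  labels[match(mask$dates, dates), , ] <- mask$labels
  structure(list(labels = labels, month_flags = mask$month_flags,
                 months = mask$months, dates = dates, grid = mask$grid),
            class = "validity_mask")
}
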