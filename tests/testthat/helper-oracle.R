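# Independent brute-force oracles, written as literal transcriptions of the
# screening rules and standard formulas; deliberately share no code with the
# package internals.

# Literal day/month screening: for every pixel, every calendar month in the
# record, find the monthly maxima, build the (up to) five-member reference
# set of the three-month window, screen each day by percent bias against at
# least one reference (threshold t1), then invalidate whole months that have
# no data or whose maximum deviates from the mean same-calendar-month
# maximum of years y-2, y-1, y+1, y+2 by more than t2 percent.
oracle_identify <- function(cube, t1 = 20, t2 = 39) {
  dates <- cube$dates
  ym <- format(dates, "%Y-%m")
  yr <- as.integer(format(dates, "%Y"))
  mo <- as.integer(format(dates, "%m"))
  # contiguous month sequence over the record span
  seq_start <- as.Date(format(min(dates), "%Y-%m-01"))
  seq_end <- as.Date(format(max(dates), "%Y-%m-01"))
  mseq <- seq(seq_start, seq_end, by = "month")
  mkeys <- format(mseq, "%Y-%m")
  nlat <- dim(cube$values)[2]; nlon <- dim(cube$values)[3]
  labels <- array(0L, dim(cube$values))

  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    series <- cube$values[, i, j]
    mmax <- sapply(mkeys, function(k) {
      v <- series[ym == k]
      v <- v[!is.na(v)]
      if (length(v)) max(v) else NA_real_
    })
    for (k in seq_along(mkeys)) {
      in_month <- which(ym == mkeys[k] & !is.na(series))
      # month-level screen
      this_year <- as.integer(substr(mkeys[k], 1, 4))
      this_mon <- as.integer(substr(mkeys[k], 6, 7))
      nbv <- c()
      for (dy in c(-2, -1, 1, 2)) {
        key <- sprintf("%04d-%02d", this_year + dy, this_mon)
        pos <- which(mkeys == key)
        if (length(pos) && !is.na(mmax[pos])) nbv <- c(nbv, mmax[pos])
      }
      month_bad <- FALSE
      if (is.na(mmax[k])) {
        month_bad <- TRUE
      } else if (length(nbv) && mean(nbv) != 0) {
        if (abs((mmax[k] - mean(nbv)) / mean(nbv)) * 100 > t2) month_bad <- TRUE
      }
      if (month_bad) {
        labels[in_month, i, j] <- 2L
        next
      }
      # day-level screen against the three-month window references
      refs <- c()
      if (k > 1 && !is.na(mmax[k - 1])) refs <- c(refs, mmax[k - 1])
      refs <- c(refs, mmax[k])
      if (k < length(mkeys) && !is.na(mmax[k + 1])) refs <- c(refs, mmax[k + 1])
      if (k > 1 && !is.na(mmax[k - 1]))
        refs <- c(refs, (mmax[k - 1] + mmax[k]) / 2)
      if (k < length(mkeys) && !is.na(mmax[k + 1]))
        refs <- c(refs, (mmax[k] + mmax[k + 1]) / 2)
      refs <- refs[refs != 0]
      for (d in in_month) {
        if (length(refs) == 0) { labels[d, i, j] <- 2L; next }
        pbs <- abs((series[d] - refs) / refs) * 100
        labels[d, i, j] <- if (any(pbs <= t1)) 1L else 2L
      }
    }
  }
  labels
}

# normal-equations quartic fit on the segment's own [-1, 1] rescaled axis
oracle_quartic <- function(t, values, span) {
  x <- 2 * t / span - 1
  X <- cbind(1, x, x^2, x^3, x^4)
  as.vector(solve(t(X) %*% X, t(X) %*% values))
}

# brute-force metric set on two vectors
oracle_metrics <- function(a, b) {
  n <- length(a)
  list(
    r = sum((a - mean(a)) * (b - mean(b))) /
      (sqrt(sum((a - mean(a))^2)) * sqrt(sum((b - mean(b))^2))),
    r2 = 1 - sum((b - a)^2) / sum((b - mean(b))^2),
    mae = sum(abs(a - b)) / n,
    rmse = sqrt(sum((a - b)^2) / n),
    pb = sum((a[b != 0] - b[b != 0]) / b[b != 0] * 100) / sum(b != 0)
  )
}
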