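# Preprocessing: zero-phase Butterworth filtering, transient trimming,
# Z-score outlier censoring, min-max scaling, grey relational analysis, and
# the histogram-binned stratified train/test split.

#' Band-pass filter an MMG series (5-100 Hz, zero phase)
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (zero-phase), so windowed features stay time-aligned with torque.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz; must exceed 200 Hz so the 100 Hz band edge
#'   is below Nyquist.
#' @param lo,hi Band edges in Hz.
#' @return Filtered series, same length as `x`.
#' @export
bandpass_mmg <- function(x, fs, lo = 5, hi = 100) {
  assert_finite(x, "x")
  if (fs <= 2 * hi) abort("`fs` must exceed twice the upper band edge")
  bp <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  filtfilt_padded(bp, x)
}

#' Low-pass filter a torque series (5 Hz, zero phase)
#'
#' @inheritParams bandpass_mmg
#' @param cutoff Cut-off frequency in Hz.
#' @return Filtered series, same length as `x`.
#' @export
lowpass_torque <- function(x, fs, cutoff = 5) {
  assert_finite(x, "x")
  if (fs <= 2 * cutoff) abort("`fs` must exceed twice the cutoff")
  lp <- signal::butter(4, cutoff / (fs / 2), type = "low")
  filtfilt_padded(lp, x)
}

#' Trim head/tail transients from a recording
#'
#' Removes the torque-development and relaxation transients: the first
#' `head_s` and last `tail_s` seconds are dropped from both channels
#' identically (default 6 s each, so a 30 s trial keeps 18 s).
#'
#' @param rec An `mmg_recording`.
#' @param head_s,tail_s Seconds to drop at each end.
#' @return The trimmed `mmg_recording`.
#' @export
trim_transients <- function(rec, head_s = 6, tail_s = 6) {
  n <- length(rec$mmg)
  drop_head <- round(head_s * rec$fs)
  drop_tail <- round(tail_s * rec$fs)
  if (n <= drop_head + drop_tail) {
    abort("recording shorter than head_s + tail_s; nothing would remain")
  }
  keep <- seq.int(drop_head + 1L, n - drop_tail)
  rec$mmg <- rec$mmg[keep]
  rec$torque <- rec$torque[keep]
  if (!is.null(rec$mmg_axes)) rec$mmg_axes <- rec$mmg_axes[keep, , drop = FALSE]
  rec
}

#' Z-score a feature table and censor outlier rows
#'
#' Every column (12 features + target) is standardized with the mean and
#' standard deviation of the full table; any row with |z| > `threshold` in
#' any column is then dropped. The whole window is removed, not the single
#' cell, because one aberrant feature marks the segment as artifactual.
#'
#' @param table Feature table (12 features + `Torque`).
#' @param threshold Z-score magnitude above which a row is censored.
#' @return A list with `table` (Z-scored, censored tibble), `state` (a
#'   `norm_state` holding the fitted per-column mean/sd), and `removed`
#'   (number of rows dropped).
#' @export
zscore_censor <- function(table, threshold = 3) {
  if (nrow(table) < 2) abort("need at least 2 rows")
  cols <- intersect(TABLE_COLUMNS, names(table))
  m <- as.matrix(table[cols])
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  bad <- sdv <= 0 | !is.finite(sdv)
  if (any(bad)) {
    abort(paste0("zero-variance column(s): ", paste(cols[bad], collapse = ", ")))
  }
  z <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  keep <- rowSums(abs(z) > threshold) == 0
  out <- table[keep, , drop = FALSE]
  out[cols] <- as.data.frame(z[keep, , drop = FALSE])
  list(
    table = tibble::as_tibble(out),
    state = structure(
      list(step = "zscore", columns = cols, center = mu, scale = sdv),
      class = "norm_state"
    ),
    removed = sum(!keep)
  )
}

#' Min-max scale a feature table to [0, 1]
#'
#' @param table Feature table.
#' @return A list with `table` (scaled tibble) and `state` (a `norm_state`
#'   with per-column min/max).
#' @export
minmax_scale <- function(table) {
  cols <- intersect(TABLE_COLUMNS, names(table))
  m <- as.matrix(table[cols])
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  flat <- hi <= lo
  if (any(flat)) {
    abort(paste0("constant column(s) cannot be scaled: ",
                 paste(cols[flat], collapse = ", ")))
  }
  out <- table
  out[cols] <- as.data.frame(sweep(sweep(m, 2, lo), 2, hi - lo, "/"))
  list(
    table = tibble::as_tibble(out),
    state = structure(
      list(step = "minmax", columns = cols, min = lo, max = hi),
      class = "norm_state"
    )
  )
}

#' Invert a normalization step
#'
#' @param table A table previously transformed with the state's step.
#' @param state A `norm_state` from [zscore_censor()] or [minmax_scale()].
#' @return The table on the original scale.
#' @export
unscale <- function(table, state) {
  cols <- intersect(state$columns, names(table))
  m <- as.matrix(table[cols])
  out <- table
  if (state$step == "minmax") {
    m <- sweep(sweep(m, 2, (state$max - state$min)[cols], "*"), 2,
               state$min[cols], "+")
  } else {
    m <- sweep(sweep(m, 2, state$scale[cols], "*"), 2, state$center[cols], "+")
  }
  out[cols] <- as.data.frame(m)
  tibble::as_tibble(out)
}

#' @export
print.norm_state <- function(x, ...) {
  cat(sprintf("<norm_state: %s> %d columns\n", x$step, length(x$columns)))
  invisible(x)
}

#' Grey relational degree between two series
#'
#' Grey relational analysis similarity: with per-point deviations
#' `d_i = |x_i - y_i|`, the grey relational coefficient is
#' `GRC_i = (d_min + zeta * d_max) / (d_i + zeta * d_max)` and the degree is
#' their mean. Both series should already be on a comparable (e.g. [0, 1])
#' scale. Identical series give 1; the distinguishing coefficient `zeta`
#' defaults to the conventional 0.5.
#'
#' @param x,y Numeric series of equal length.
#' @param zeta Distinguishing coefficient in (0, 1].
#' @return A scalar in (0, 1].
#' @export
grey_relational_degree <- function(x, y, zeta = 0.5) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  assert_finite(x, "x"); assert_finite(y, "y")
  d <- abs(x - y)
  dmax <- max(d)
  if (dmax == 0) return(1)
  mean((min(d) + zeta * dmax) / (d + zeta * dmax))
}

#' Split specification for binning and the stratified split
#'
#' @param n_bins Number of target bins (default 50).
#' @param bin_width Width of each bin on the [0, 1] target scale (default
#'   0.02); `n_bins * bin_width` must cover [0, 1].
#' @param train_frac Fraction of each bin allocated to training.
#' @param seed Integer seed for the within-bin assignment.
#' @return A list of class `split_spec`.
#' @export
split_spec <- function(n_bins = 50L, bin_width = 0.02, train_frac = 0.7,
                       seed = 1L) {
  if (n_bins * bin_width < 1 - 1e-9) abort("bins must cover [0, 1]")
  if (train_frac <= 0 || train_frac >= 1) abort("`train_frac` must be in (0, 1)")
  structure(
    list(n_bins = as.integer(n_bins), bin_width = bin_width,
         train_frac = train_frac, seed = as.integer(seed)),
    class = "split_spec"
  )
}

# Half-open bin assignment [k*w, (k+1)*w), last bin closed at the top.
bin_index <- function(target, spec) {
  b <- floor(target / spec$bin_width) + 1L
  pmin.int(pmax.int(b, 1L), spec$n_bins)
}

#' Per-bin grey relational profile of a feature against the target
#'
#' Rows are assigned to target-value bins; within each bin the grey
#' relational degree between the feature and target sub-series is computed.
#' This is the binned relevance profile used to screen features before
#' model-based selection.
#'
#' @param feature,target Numeric series on the [0, 1] scale.
#' @param spec A [split_spec()].
#' @param zeta Distinguishing coefficient.
#' @return A tibble with one row per bin: `bin`, `lo`, `hi`, `count`, `grd`
#'   (`NA` for empty bins).
#' @export
binned_grd_profile <- function(feature, target, spec = split_spec(),
                               zeta = 0.5) {
  if (length(feature) != length(target)) abort("length mismatch")
  b <- bin_index(target, spec)
  purrr::map_dfr(seq_len(spec$n_bins), function(k) {
    idx <- which(b == k)
    tibble::tibble(
      bin = k,
      lo = (k - 1) * spec$bin_width,
      hi = k * spec$bin_width,
      count = length(idx),
      grd = if (length(idx) > 0) {
        grey_relational_degree(feature[idx], target[idx], zeta)
      } else {
        NA_real_
      }
    )
  })
}

#' Histogram-binned stratified train/test split for a continuous target
#'
#' Rows are binned by target value (half-open bins of width `bin_width`, the
#' last bin closed); within every bin, `round(train_frac * count)`
#' (round-half-up) rows go to training and the remainder to test, with the
#' within-bin assignment drawn under `spec$seed`. Single-row bins go to
#' training. This equalizes the target distribution across the two subsets.
#'
#' @param table Feature table whose `Torque` column is already on [0, 1].
#' @param spec A [split_spec()].
#' @return A list with integer row-index vectors `train` and `test`
#'   (disjoint, exhaustive).
#' @export
stratified_binned_split <- function(table, spec = split_spec()) {
  target <- table$Torque
  if (is.null(target)) abort("table must have a `Torque` column")
  if (any(target < 0 | target > 1)) abort("target must be on [0, 1]")
  b <- bin_index(target, spec)
  train <- integer(0)
  withr::with_seed(spec$seed, {
    for (k in sort(unique(b))) {
      idx <- which(b == k)
      n_tr <- round_half_up(spec$train_frac * length(idx))
      n_tr <- max(min(n_tr, length(idx)), if (length(idx) == 1) 1L else 0L)
      picked <- idx[sample.int(length(idx), n_tr)]  # never sample(idx, ...)
      train <- c(train, picked)
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(table)), train))
}
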