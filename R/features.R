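# Sliding-window MMG feature extraction: the 12 time- and frequency-domain
# features plus the windowed torque target.
#
# Spectral features share one estimator: a Hann-tapered periodogram of each
# 100 ms window, zero-padded to 256 points (~3.9 Hz grid at 1 kHz) and
# restricted to the 5-100 Hz MMG band. MPF uses the power spectrum, the
# spectral centroid/spread the magnitude spectrum — the conventional split
# that keeps the two features distinct.

#' Sliding-window specification
#'
#' @param win_ms Window duration in milliseconds (default 100).
#' @param overlap_frac Fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @param fs Sampling rate in Hz.
#' @return A list of class `window_spec` with derived `win` and `stride` in
#'   samples.
#' @export
window_spec <- function(win_ms = 100, overlap_frac = 0.5, fs = 1000) {
  win <- round(win_ms * fs / 1000)
  if (win < 2) abort("window must span at least 2 samples")
  if (overlap_frac < 0 || overlap_frac >= 1) abort("`overlap_frac` must be in [0, 1)")
  stride <- max(1L, round(win * (1 - overlap_frac)))
  structure(
    list(win_ms = win_ms, overlap_frac = overlap_frac, fs = fs,
         win = as.integer(win), stride = as.integer(stride)),
    class = "window_spec"
  )
}

#' Window start/stop indices for a series of length n
#'
#' Half-open `[start, stop)` in 0-based sample coordinates, mirroring the
#' arithmetic `count = floor((n - win) / stride) + 1`; a trailing partial
#' window is dropped. The returned tibble uses 1-based inclusive `first` /
#' `last` columns for direct R subsetting.
#'
#' @param n Series length in samples.
#' @param spec A [window_spec()].
#' @return Tibble with columns `window`, `first`, `last`.
#' @export
window_indices <- function(n, spec) {
  if (n < spec$win) abort("series shorter than one window")
  count <- (n - spec$win) %/% spec$stride + 1L
  first <- (seq_len(count) - 1L) * spec$stride + 1L
  tibble::tibble(window = seq_len(count), first = first,
                 last = first + spec$win - 1L)
}

#' Hann-tapered periodogram restricted to the MMG band
#'
#' The window is mean-preserved (no detrending), Hann-tapered, zero-padded to
#' `nfft` points and Fourier transformed. One-sided power densities use the
#' standard taper-power normalization, so the integral of `power` over
#' frequency approximates the window variance for band-limited input. The
#' grid is then restricted to `[band_lo, band_hi]`; every downstream spectral
#' feature sees only this slice.
#'
#' @param w Numeric window.
#' @param fs Sampling rate in Hz.
#' @param nfft Zero-padded FFT length.
#' @param band_lo,band_hi Analysis band in Hz.
#' @return A list of class `mmg_spectrum` with `freqs`, `power`, `magnitude`,
#'   and `df` (grid step in Hz).
#' @export
estimate_spectrum <- function(w, fs, nfft = 256L, band_lo = 5, band_hi = 100) {
  n <- length(w)
  if (n < 2) abort("window too short")
  taper <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))  # Hann
  xw <- c(w * taper, rep(0, nfft - n))
  X <- stats::fft(xw)
  k <- seq_len(nfft %/% 2)  # positive frequencies, DC excluded
  freqs <- k * fs / nfft
  u <- sum(taper^2)
  power <- 2 * Mod(X[k + 1])^2 / (fs * u)
  magnitude <- Mod(X[k + 1])
  keep <- freqs >= band_lo & freqs <= band_hi
  structure(
    list(freqs = freqs[keep], power = power[keep],
         magnitude = magnitude[keep], df = fs / nfft),
    class = "mmg_spectrum"
  )
}

#' Time-domain window features
#'
#' `feat_rms()` is the root-mean-square amplitude, the canonical motor-unit
#' activity index. `feat_zcr()` counts strict sign changes per second (zeros
#' inherit the previous nonzero sign). `feat_mobility()` is the Hjorth
#' mobility, `sqrt(var(diff(w)) / var(w)) * fs` — a dominant-angular-frequency
#' proxy in 1/s; an all-constant window returns 0.
#'
#' @param w Numeric window.
#' @param fs Sampling rate in Hz.
#' @return A scalar.
#' @export
feat_rms <- function(w) sqrt(mean(w^2))

#' @rdname feat_rms
#' @export
feat_zcr <- function(w, fs) {
  s <- sign(w)
  # zeros inherit the previous nonzero sign
  for (i in seq_along(s)) if (s[i] == 0) s[i] <- if (i > 1) s[i - 1] else 0
  changes <- sum(s[-1] != s[-length(s)] & s[-1] != 0 & s[-length(s)] != 0)
  changes / (length(w) / fs)
}

#' @rdname feat_rms
#' @export
feat_mobility <- function(w, fs) {
  v0 <- var(w)
  if (v0 <= 0) return(0)
  sqrt(var(diff(w)) / v0) * fs
}

#' Spectral window features
#'
#' All operate on an [estimate_spectrum()] object, i.e. on the 5-100 Hz grid
#' only. `feat_mpf()` is the power-weighted mean frequency; `feat_mdf()` the
#' smallest grid frequency where cumulative power reaches half the total;
#' `feat_spc()` / `feat_spsp()` the centroid and spread of the magnitude
#' spectrum; `feat_spflt()` the flatness (geometric over arithmetic mean of
#' power, zero bins floored near machine epsilon); `feat_spflx()` the L2 norm
#' of the difference of L1-normalized magnitude spectra of consecutive
#' windows (`NULL` previous spectrum, i.e. the first window of a trial,
#' gives 0). `feat_band_energy()` is the fraction of 5-100 Hz power inside
#' `[lo, hi)`; the three named bands are Tremor 5-12, LowerBand 12-40,
#' HighBand 40-100 Hz and partition unity.
#'
#' @param spec,spec_prev `mmg_spectrum` objects.
#' @param lo,hi Band edges in Hz (half-open `[lo, hi)`; `hi` at the top of
#'   the analysis band is closed).
#' @return A scalar. All-zero windows give 0 for every spectral feature.
#' @export
feat_mpf <- function(spec) {
  tot <- sum(spec$power)
  if (tot <= 0) return(0)
  sum(spec$freqs * spec$power) / tot
}

#' @rdname feat_mpf
#' @export
feat_mdf <- function(spec) {
  tot <- sum(spec$power)
  if (tot <= 0) return(0)
  spec$freqs[which(cumsum(spec$power) >= tot / 2)[1]]
}

#' @rdname feat_mpf
#' @export
feat_spc <- function(spec) {
  tot <- sum(spec$magnitude)
  if (tot <= 0) return(0)
  sum(spec$freqs * spec$magnitude) / tot
}

#' @rdname feat_mpf
#' @export
feat_spsp <- function(spec) {
  tot <- sum(spec$magnitude)
  if (tot <= 0) return(0)
  ctr <- sum(spec$freqs * spec$magnitude) / tot
  sqrt(sum((spec$freqs - ctr)^2 * spec$magnitude) / tot)
}

#' @rdname feat_mpf
#' @export
feat_spflt <- function(spec) {
  p <- spec$power
  if (sum(p) <= 0) return(0)
  p <- pmax(p, .Machine$double.eps * max(p))
  exp(mean(log(p))) / mean(p)
}

#' @rdname feat_mpf
#' @export
feat_spflx <- function(spec, spec_prev = NULL) {
  if (is.null(spec_prev)) return(0)
  tot <- sum(spec$magnitude)
  tot_prev <- sum(spec_prev$magnitude)
  if (tot <= 0 || tot_prev <= 0) return(0)
  sqrt(sum((spec$magnitude / tot - spec_prev$magnitude / tot_prev)^2))
}

#' @rdname feat_mpf
#' @export
feat_band_energy <- function(spec, lo, hi) {
  tot <- sum(spec$power)
  if (tot <= 0) return(0)
  top <- max(spec$freqs)
  mask <- spec$freqs >= lo & (spec$freqs < hi | (hi >= top & spec$freqs <= hi))
  sum(spec$power[mask]) / tot
}

#' Extract the full windowed feature table from a recording
#'
#' Slides `spec` over an (already filtered and trimmed) recording and
#' computes, per window, the 12 MMG features of the transverse-axis signal
#' and the target `Torque` = RMS of the torque channel over the same window.
#' Column order is fixed:
#' `RMS, HighBand, LowerBand, Tremor, SPFlx, MDF, SPC, SPsp, MPF, ZCR,
#' Mobility, SPFlt, Torque`.
#'
#' @param rec An `mmg_recording` (filter and trim first; see
#'   [bandpass_mmg()], [lowpass_torque()], [trim_transients()]).
#' @param spec A [window_spec()]; its `fs` is overridden by the recording's.
#' @return A tibble with one row per window and the 13 fixed columns.
#' @export
#' @examples
#' rec <- simulate_recording(synth_config(trial_s = 16, seed = 1))
#' rec$mmg <- bandpass_mmg(rec$mmg, rec$fs)
#' rec$torque <- lowpass_torque(rec$torque, rec$fs)
#' tab <- extract_feature_table(trim_transients(rec, 3, 3))
extract_feature_table <- function(rec, spec = window_spec(fs = rec$fs)) {
  spec$fs <- rec$fs
  spec$win <- as.integer(round(spec$win_ms * rec$fs / 1000))
  spec$stride <- max(1L, as.integer(round(spec$win * (1 - spec$overlap_frac))))
  idx <- window_indices(length(rec$mmg), spec)
  prev_spec <- NULL
  rows <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    w <- rec$mmg[idx$first[i]:idx$last[i]]
    tw <- rec$torque[idx$first[i]:idx$last[i]]
    sp <- estimate_spectrum(w, rec$fs)
    rows[[i]] <- c(
      RMS = feat_rms(w),
      HighBand = feat_band_energy(sp, 40, 100),
      LowerBand = feat_band_energy(sp, 12, 40),
      Tremor = feat_band_energy(sp, 5, 12),
      SPFlx = feat_spflx(sp, prev_spec),
      MDF = feat_mdf(sp),
      SPC = feat_spc(sp),
      SPsp = feat_spsp(sp),
      MPF = feat_mpf(sp),
      ZCR = feat_zcr(w, rec$fs),
      Mobility = feat_mobility(w, rec$fs),
      SPFlt = feat_spflt(sp),
      Torque = feat_rms(tw)
    )
    prev_spec <- sp
  }
  out <- tibble::as_tibble(as.data.frame(do.call(rbind, rows)))
  out[TABLE_COLUMNS]
}
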