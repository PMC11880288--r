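# Synthetic NMES-MMG / torque generator.
#
# Emulates the statistical structure of stimulation-evoked recordings: a
# smooth ramp-plateau-release torque profile, and band-limited (5-100 Hz)
# stochastic MMG whose amplitude envelope and low/high band-power balance
# covary monotonically with torque. Morphological realism (twitch shapes,
# stimulation artifacts) is deliberately out of scope.

#' Configuration for the synthetic recording generator
#'
#' @param fs Sampling rate in Hz.
#' @param trial_s Trial duration in seconds. The torque profile always uses a
#'   6 s rise and a 6 s release, so trials shorter than about 13 s are not
#'   meaningful.
#' @param n_trials Number of trials (used by [pipeline_simulate()]).
#' @param coupling_gain Dimensionless gain (>= 0) scaling how strongly the MMG
#'   amplitude envelope tracks torque: the instantaneous MMG standard
#'   deviation is `noise_sd * (1 + coupling_gain * torque / torque_max)`.
#' @param spectral_shift_gain Dimensionless gain (>= 0) scaling the
#'   torque-dependent shift of MMG band power from the 12-40 Hz band towards
#'   the 40-100 Hz band.
#' @param noise_sd Baseline MMG standard deviation (acceleration, arbitrary
#'   units) at zero torque.
#' @param torque_max Plateau torque in N.m.
#' @param n_axes Number of accelerometer axes to synthesize. Only the first
#'   (transverse) axis carries the torque coupling and is the one the feature
#'   pipeline consumes; extra axes are independent nuisance channels.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(fs = 1000, trial_s = 30, n_trials = 1,
                         coupling_gain = 2, spectral_shift_gain = 1,
                         noise_sd = 0.02, torque_max = 8,
                         n_axes = 1, seed = 1L) {
  cfg <- list(
    fs = fs, trial_s = trial_s, n_trials = n_trials,
    coupling_gain = coupling_gain, spectral_shift_gain = spectral_shift_gain,
    noise_sd = noise_sd, torque_max = torque_max,
    n_axes = n_axes, seed = as.integer(seed)
  )
  for (nm in setdiff(names(cfg), "seed")) assert_scalar(cfg[[nm]], nm)
  if (cfg$fs <= 0) abort("`fs` must be positive")
  if (cfg$trial_s <= 0) abort("`trial_s` must be positive")
  if (cfg$coupling_gain < 0 || cfg$spectral_shift_gain < 0) {
    abort("gains must be non-negative")
  }
  if (cfg$noise_sd <= 0) abort("`noise_sd` must be positive")
  if (cfg$n_axes < 1) abort("`n_axes` must be >= 1")
  structure(cfg, class = "synth_config")
}

# Smooth ramp-plateau-release torque profile on [0, trial_s]: raised-cosine
# 6 s rise and release (matching the head/tail trimming convention) and a
# plateau carrying a slow (< 0.5 Hz, ~8%) potentiation/fatigue drift plus
# ~2% faster (< 1 Hz) jitter, as stimulation-evoked torque does over a
# sustained train. Always non-negative.
torque_profile <- function(n, fs, torque_max, rise_s = 6, fall_s = 6,
                           drift_sd = 0.08, jitter_sd = 0.02) {
  t <- (seq_len(n) - 1) / fs
  dur <- (n - 1) / fs
  shape <- rep(1, n)
  rising <- t < rise_s
  shape[rising] <- 0.5 * (1 - cos(pi * t[rising] / rise_s))
  falling <- t > dur - fall_s
  shape[falling] <- 0.5 * (1 - cos(pi * (dur - t[falling]) / fall_s))
  slow <- function(cutoff_hz, target_sd) {
    x <- filtfilt_padded(
      signal::butter(2, min(0.99, cutoff_hz / (fs / 2)), type = "low"),
      rnorm(n)
    )
    x / max(sd(x), .Machine$double.eps) * target_sd
  }
  wander <- slow(0.5, drift_sd) + slow(1, jitter_sd)
  pmax(torque_max * shape * (1 + wander), 0)
}

# Unit-variance band-limited Gaussian noise.
band_noise <- function(n, fs, lo, hi) {
  bp <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- filtfilt_padded(bp, rnorm(n))
  x / sd(x)
}

#' Simulate one synchronized MMG/torque recording
#'
#' Torque follows a smooth trapezoid (6 s rise, plateau with slow jitter, 6 s
#' release). MMG is a sum of three band-limited Gaussian components (tremor
#' 5-12 Hz, slow-twitch 12-40 Hz, fast-twitch 40-100 Hz) with pointwise unit
#' variance, scaled by the torque-tracking envelope
#' `noise_sd * (1 + coupling_gain * torque / torque_max)`. The relative weight
#' of the 40-100 Hz component grows with torque as
#' `1 + spectral_shift_gain * torque / torque_max`, shifting spectral mass
#' upward at high effort. With both gains at zero the MMG carries no torque
#' information.
#'
#' @param cfg A [synth_config()].
#' @param trial Trial number (offsets the seed so trials are independent but
#'   jointly reproducible).
#' @param level Plateau torque as a fraction of `torque_max` for this trial
#'   (a graded stimulation intensity). The MMG coupling always references
#'   absolute torque against `torque_max`, so lower-level trials produce
#'   proportionally weaker MMG.
#'
#' @return An object of class `mmg_recording`: a list with elements `mmg`
#'   (numeric vector, transverse axis), `torque` (numeric vector, N.m), `fs`,
#'   `meta`, and optionally `mmg_axes` (matrix of extra axes).
#' @export
#' @examples
#' rec <- simulate_recording(synth_config(trial_s = 20, seed = 42))
#' print(rec)
simulate_recording <- function(cfg, trial = 1L, level = 1) {
  if (!inherits(cfg, "synth_config")) cfg <- do.call(synth_config, cfg)
  if (level <= 0 || level > 1) abort("`level` must be in (0, 1]")
  n <- round(cfg$fs * cfg$trial_s)
  withr::with_seed(derive_seed(cfg$seed, trial), {
    torque <- torque_profile(n, cfg$fs, cfg$torque_max * level)
    tau <- torque / cfg$torque_max
    tre <- band_noise(n, cfg$fs, 5, 12)
    lo <- band_noise(n, cfg$fs, 12, 40)
    hi <- band_noise(n, cfg$fs, 40, 100)
    w_tre <- 0.4
    w_lo <- 1
    w_hi <- 0.8 * (1 + cfg$spectral_shift_gain * tau)
    mix <- (w_tre * tre + w_lo * lo + w_hi * hi) /
      sqrt(w_tre^2 + w_lo^2 + w_hi^2)
    # Amplitude-normalize the carrier by its own local RMS (tracked below
    # 12 Hz, i.e. just under the 100 ms analysis-window scale) so the
    # instantaneous standard deviation equals the torque-tracking envelope
    # (a raw Gaussian carrier's windowed RMS wanders around it instead).
    lp <- signal::butter(2, 12 / (cfg$fs / 2), type = "low")
    local_rms <- sqrt(pmax(filtfilt_padded(lp, mix^2), 0.04))
    env <- cfg$noise_sd * (1 + cfg$coupling_gain * tau)
    mmg <- env * mix / local_rms
    extra <- NULL
    if (cfg$n_axes > 1) {
      extra <- vapply(
        seq_len(cfg$n_axes - 1L),
        function(i) cfg$noise_sd * band_noise(n, cfg$fs, 5, 100),
        numeric(n)
      )
    }
    structure(
      list(
        mmg = mmg, torque = torque, fs = cfg$fs,
        meta = list(
          trial = as.integer(trial), posture = "neutral", angle_deg = 90,
          subject = "synthetic", seed = cfg$seed
        ),
        mmg_axes = extra
      ),
      class = "mmg_recording"
    )
  })
}

#' @export
print.mmg_recording <- function(x, ...) {
  cat(sprintf(
    "<mmg_recording> %d samples @ %g Hz (%.1f s), torque range [%.2f, %.2f] N.m\n",
    length(x$mmg), x$fs, length(x$mmg) / x$fs, min(x$torque), max(x$torque)
  ))
  invisible(x)
}

#' @export
as_tibble.mmg_recording <- function(x, ...) {
  tb <- tibble::tibble(
    time_s = (seq_along(x$mmg) - 1) / x$fs,
    mmg = x$mmg,
    torque = x$torque
  )
  if (!is.null(x$mmg_axes)) {
    extra <- tibble::as_tibble(as.data.frame(x$mmg_axes), .name_repair = "minimal")
    names(extra) <- paste0("mmg_axis", seq_len(ncol(extra)) + 1L)
    tb <- dplyr::bind_cols(tb, extra)
  }
  tb
}

#' Write / read a recording as CSV with a JSON metadata sidecar
#'
#' The CSV has columns `time_s,mmg,torque` (plus any extra axes); metadata is
#' written next to it as `<path>.json`.
#'
#' @param rec An `mmg_recording`.
#' @param path Output CSV path.
#' @return `path`, invisibly (`write_recording`); an `mmg_recording`
#'   (`read_recording`).
#' @export
write_recording <- function(rec, path) {
  utils::write.csv(as_tibble.mmg_recording(rec), path, row.names = FALSE)
  jsonlite::write_json(
    c(rec$meta, list(fs = rec$fs)),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  d <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  fs <- if (!is.null(meta$fs)) meta$fs else 1 / stats::median(diff(d$time_s))
  meta$fs <- NULL
  structure(
    list(mmg = d$mmg, torque = d$torque, fs = fs, meta = meta, mmg_axes = NULL),
    class = "mmg_recording"
  )
}

#' Generate a feature table with known ground truth
#'
#' Direct tabular generator for optimizer validation: 12 feature columns with
#' the standard MMG feature names, of which only `informative_idx` drive the
#' target. The target is a weighted mixture of smooth monotone transforms of
#' the informative columns plus one pairwise interaction, with additive
#' Gaussian noise, min-max scaled to [0, 1]. The first index listed receives
#' the largest weight, so placing the RMS column (index 1) first makes it the
#' dominant predictor. All other columns are independent uniform noise.
#'
#' @param n_rows Number of rows (>= 50).
#' @param informative_idx Integer indices in 1..12 of the truly informative
#'   features (default: RMS, HighBand, LowerBand, SPFlx — the columns a real
#'   stimulation study finds most torque-linked).
#' @param noise_sd Additive Gaussian noise on the raw target before scaling.
#' @param seed Integer seed.
#'
#' @return A list with `table` (tibble, 12 features + `Torque`) and `truth`
#'   (list with `informative_idx` and `generating_function`).
#' @export
#' @examples
#' ds <- make_feature_dataset(200, informative_idx = c(1, 2), seed = 3)
#' dplyr::glimpse(ds$table)
make_feature_dataset <- function(n_rows, informative_idx = c(1L, 2L, 3L, 5L),
                                 noise_sd = 0.1, seed = 1L) {
  if (n_rows < 50) abort("`n_rows` must be >= 50")
  informative_idx <- as.integer(informative_idx)
  if (length(informative_idx) == 0 ||
      any(informative_idx < 1 | informative_idx > 12) ||
      anyDuplicated(informative_idx)) {
    abort("`informative_idx` must be distinct indices in 1..12")
  }
  transforms <- list(
    function(x) x,
    function(x) x^2,
    function(x) sqrt(x),
    function(x) 1 / (1 + exp(-6 * (x - 0.5)))
  )
  withr::with_seed(as.integer(seed), {
    X <- matrix(runif(n_rows * 12), nrow = n_rows,
                dimnames = list(NULL, MMG_FEATURES))
    k <- length(informative_idx)
    w <- 1 / (seq_len(k))^0.5  # decreasing weights, first index dominant
    y <- rep(0, n_rows)
    for (j in seq_len(k)) {
      g <- transforms[[(j - 1L) %% length(transforms) + 1L]]
      y <- y + w[j] * g(X[, informative_idx[j]])
    }
    if (k >= 2) {
      y <- y + 0.5 * X[, informative_idx[1]] * X[, informative_idx[2]]
    }
    y <- y + rnorm(n_rows, sd = noise_sd)
    y <- (y - min(y)) / (max(y) - min(y))
    table <- tibble::as_tibble(as.data.frame(X))
    table$Torque <- y
    list(
      table = table,
      truth = list(
        informative_idx = informative_idx,
        generating_function = sprintf(
          "sum_j w_j g_j(x_j) over {%s} + 0.5 interaction + N(0, %g), min-max scaled",
          paste(MMG_FEATURES[informative_idx], collapse = ","), noise_sd
        )
      )
    )
  })
}
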