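# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom stats runif var sd rnorm predict coef lm median quantile
#' @importFrom tibble as_tibble
#' @importFrom ggplot2 autoplot
#' @importFrom utils head tail
NULL

# Canonical feature column order used by every table in the package.
# Torque (the target) is always the last column.
MMG_FEATURES <- c(
  "RMS", "HighBand", "LowerBand", "Tremor", "SPFlx", "MDF",
  "SPC", "SPsp", "MPF", "ZCR", "Mobility", "SPFlt"
)
TABLE_COLUMNS <- c(MMG_FEATURES, "Torque")

assert_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite and numeric", what))
  }
  invisible(x)
}

assert_scalar <- function(x, what) {
  if (length(x) != 1) abort(sprintf("`%s` must be a single value", what))
  assert_finite(x, what)
}

# Zero-phase forward-backward filtering with odd-reflection edge padding, so
# that constant offsets and slow components survive the turn-around at the
# signal ends (plain forward-backward filtering rings at the edges).
filtfilt_padded <- function(filt, x) {
  n <- length(x)
  # generous pad: slow filters (5 Hz at 1 kHz) need several hundred samples
  # to settle from zero initial conditions
  pad <- min(n - 1L, 1000L)
  if (pad < 1L) abort("signal too short to filter")
  left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xp <- c(left, x, right)
  yp <- signal::filtfilt(filt, xp)
  yp[seq(pad + 1L, pad + n)]
}

# Deterministic fan-out of one master seed into per-stage seeds. Keeps every
# derived seed a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  as.integer((s * 48271 + 7919 * as.numeric(offset)) %% 2147483647)
}

feature_matrix <- function(table) {
  missing <- setdiff(TABLE_COLUMNS, names(table))
  if (length(missing) > 0) {
    abort(paste0("feature table is missing columns: ", paste(missing, collapse = ", ")))
  }
  as.matrix(table[MMG_FEATURES])
}

round_half_up <- function(x) floor(x + 0.5)
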