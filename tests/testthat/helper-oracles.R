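# Independent brute-force oracles used to cross-check every feature
# operator, the grey relational degree, and one EO update. These are
# deliberately written as plain loops over the defining formulas and share
# no code with the package internals.

oracle_rms <- function(w) {
  acc <- 0
  for (v in w) acc <- acc + v * v
  sqrt(acc / length(w))
}

oracle_zcr <- function(w, fs) {
  prev <- 0
  count <- 0
  for (v in w) {
    s <- if (v > 0) 1 else if (v < 0) -1 else prev
    if (prev != 0 && s != 0 && s != prev) count <- count + 1
    if (s != 0) prev <- s
  }
  count / (length(w) / fs)
}

oracle_mobility <- function(w, fs) {
  if (stats::var(w) <= 0) return(0)
  d <- w[-1] - w[-length(w)]
  sqrt(stats::var(d) / stats::var(w)) * fs
}

oracle_mpf <- function(freqs, power) {
  num <- 0; den <- 0
  for (k in seq_along(freqs)) {
    num <- num + freqs[k] * power[k]
    den <- den + power[k]
  }
  if (den <= 0) 0 else num / den
}

oracle_mdf <- function(freqs, power) {
  tot <- sum(power)
  if (tot <= 0) return(0)
  acc <- 0
  for (k in seq_along(freqs)) {
    acc <- acc + power[k]
    if (acc >= tot / 2) return(freqs[k])
  }
  freqs[length(freqs)]
}

oracle_spc <- function(freqs, mag) {
  if (sum(mag) <= 0) 0 else sum(freqs * mag) / sum(mag)
}

oracle_spsp <- function(freqs, mag) {
  if (sum(mag) <= 0) return(0)
  c0 <- oracle_spc(freqs, mag)
  sqrt(sum((freqs - c0)^2 * mag) / sum(mag))
}

oracle_spflt <- function(power) {
  if (sum(power) <= 0) return(0)
  p <- pmax(power, .Machine$double.eps * max(power))
  exp(sum(log(p)) / length(p)) / (sum(p) / length(p))
}

oracle_spflx <- function(mag, mag_prev) {
  if (is.null(mag_prev)) return(0)
  a <- mag / sum(mag)
  b <- mag_prev / sum(mag_prev)
  acc <- 0
  for (k in seq_along(a)) acc <- acc + (a[k] - b[k])^2
  sqrt(acc)
}

oracle_band <- function(freqs, power, lo, hi) {
  top <- max(freqs)
  num <- 0
  for (k in seq_along(freqs)) {
    in_band <- freqs[k] >= lo && (freqs[k] < hi || (hi >= top && freqs[k] <= hi))
    if (in_band) num <- num + power[k]
  }
  num / sum(power)
}

oracle_grd <- function(x, y, zeta = 0.5) {
  d <- abs(x - y)
  if (max(d) == 0) return(1)
  grc <- numeric(length(d))
  for (i in seq_along(d)) {
    grc[i] <- (min(d) + zeta * max(d)) / (d[i] + zeta * max(d))
  }
  mean(grc)
}

# Straight-line replay of one EO position update, consuming RNG draws in the
# documented order (pool index, lambda vector, r vector, r1, r2 — per
# solution). Must be called under the same RNG state as the implementation.
oracle_eo_update <- function(population, pool, iter, max_iter,
                             a1 = 2, a2 = 1, GP = 0.5, V = 1) {
  n_pop <- nrow(population)
  dim <- ncol(population)
  t_iter <- (1 - iter / max_iter)^(a2 * iter / max_iter)
  out <- matrix(NA_real_, n_pop, dim)
  for (i in seq_len(n_pop)) {
    ceq <- pool[sample.int(5, 1), ]
    lambda <- runif(dim)
    r <- runif(dim)
    r1 <- runif(1)
    r2 <- runif(1)
    for (d in seq_len(dim)) {
      f_d <- a1 * sign(r[d] - 0.5) * (exp(-lambda[d] * t_iter) - 1)
      gcp <- if (r2 >= GP) 0.5 * r1 else 0
      g_d <- gcp * (ceq[d] - lambda[d] * population[i, d]) * f_d
      c_new <- ceq[d] + (population[i, d] - ceq[d]) * f_d +
        g_d / (lambda[d] * V) * (1 - f_d)
      out[i, d] <- min(max(c_new, 0), 1)
    }
  }
  out
}

# Windowed RMS used by the synthetic-signal coupling checks.
windowed_rms <- function(x, win = 100, stride = 50) {
  starts <- seq(1, length(x) - win + 1, stride)
  vapply(starts, function(i) sqrt(mean(x[i:(i + win - 1)]^2)), numeric(1))
}

# Small standard feature table builder for model/optimizer tests.
toy_table <- function(n = 120, seed = 1, informative = c(1L, 2L),
                      noise_sd = 0.05) {
  make_feature_dataset(n, informative_idx = informative,
                       noise_sd = noise_sd, seed = seed)$table
}
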