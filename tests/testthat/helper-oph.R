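# Shared fixtures and independent oracles.

# instrument with all stochastic and background terms switched off
noiseless_config <- function(...) {
  instrument_config(noise_sd_v = 0, ambient_dc_v = 0, ambient_flicker = 0,
                    ...)
}

# brute-force single-frequency correlation: multiply by sin/cos at f and
# integrate over whole cycles (independent of the FFT path)
bf_correlation_amplitude <- function(x, fs, f) {
  cycles <- floor(length(x) * f / fs)
  n <- round(cycles * fs / f)
  t <- (seq_len(n) - 1) / fs
  s <- sum(x[seq_len(n)] * sin(2 * pi * f * t))
  c <- sum(x[seq_len(n)] * cos(2 * pi * f * t))
  2 * sqrt(s^2 + c^2) / n
}

# exhaustive two-sided permutation p by explicit enumeration over all
# subsets encoded as bitmasks (independent of combn-based enumeration)
bf_permutation_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) != na) next
    total <- total + 1L
    stat <- abs(mean(pool[idx]) - mean(pool[-idx]))
    if (stat >= obs - 1e-9 * max(obs, 1)) hits <- hits + 1L
  }
  hits / total
}

# noiseless simulated ratio at a pH, through the full chain
simulated_ratio <- function(ph, model = fluorescein_model(),
                            config = noiseless_config()) {
  a <- demodulate(simulate_acquisition(ph, model, config))
  compute_ratio(a$f520, a$f550)
}

# calibration fitted from noiseless simulated buffers
simulated_calibration <- function(levels = c(4.5, 5.5, 6.5, 7.5), ...) {
  fit_calibration(vapply(levels, simulated_ratio, numeric(1), ...), levels)
}
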