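# Independent oracles and small fixture builders used across the suite.

# Rayleigh test of circular uniformity (Zar's approximation for the p value).
rayleigh_test_p <- function(phases) {
  n <- length(phases)
  rbar <- Mod(mean(exp(1i * phases)))
  z <- n * rbar^2
  exp(sqrt(1 + 4 * n + 4 * (n^2 - (n * rbar)^2)) - (1 + 2 * n))
}

# A tiny epoch set holding given per-sensor waveforms, replicated over trials.
# waves: list of numeric vectors (one per sensor), all the same length.
make_epochs <- function(waves, fs = 480, n_trials = 2, t0_ms = -1000,
                        categories = NULL) {
  n_sens <- length(waves)
  n_time <- length(waves[[1]])
  sig <- array(0, c(n_trials, n_sens, n_time))
  for (m in seq_len(n_sens)) {
    sig[, m, ] <- matrix(waves[[m]], n_trials, n_time, byrow = TRUE)
  }
  time_ms <- t0_ms + (seq_len(n_time) - 1) * 1000 / fs
  categories <- categories %||% rep(c("indoor", "outdoor"),
                                    length.out = n_trials)
  info <- data.frame(trial = seq_len(n_trials), category = categories,
                     condition = "control", subject = 1L,
                     stringsAsFactors = FALSE)
  epoch_set(sig, time_ms, fs, info, grid_layout(n_sens))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A synthetic tf_rep built directly from an amplitude array (for decoder
# tests that do not need a signal-level provenance).
make_tf <- function(amplitude, freqs, time_ms, categories,
                    condition = "control") {
  n_trials <- dim(amplitude)[1]
  info <- data.frame(trial = seq_len(n_trials), category = categories,
                     condition = condition, subject = 1L,
                     presentation = stats::ave(seq_len(n_trials), categories,
                                               FUN = seq_along),
                     stringsAsFactors = FALSE)
  structure(list(amplitude = amplitude, freqs = freqs, time_ms = time_ms,
                 info = info, layout = grid_layout(dim(amplitude)[2]),
                 sfreq = 250, baseline = c(-500, -100)),
            class = "tf_rep")
}

# Noise-only feature array: trials x sensors x freqs x 1 time point.
noise_tf <- function(n_per = 20, n_sens = 8, freqs = seq(13, 79, by = 2),
                     seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  amp <- array(stats::rnorm(n * n_sens * length(freqs)),
               c(n, n_sens, length(freqs), 1))
  make_tf(amp, freqs, 0, rep(c("indoor", "outdoor"), each = n_per))
}

# A synthetic phase series whose phase advances linearly at `freq` Hz
# (a perfect oscillation), for coupling tests with controlled ground truth.
make_phase_series <- function(n_trials, n_sens, freq = 6, rate = 250,
                              t_range = c(3000, 8000), phi0 = 0) {
  time_ms <- seq(t_range[1], t_range[2], by = 1000 / rate)
  ph <- wrap_pi(2 * pi * freq * time_ms / 1000 + phi0)
  arr <- array(rep(ph, each = n_trials * n_sens),
               c(n_trials, n_sens, length(time_ms)))
  info <- data.frame(trial = seq_len(n_trials),
                     category = "indoor", condition = "configural",
                     subject = 1L, stringsAsFactors = FALSE)
  structure(list(phase = arr, time_ms = time_ms, freq = freq, info = info,
                 layout = grid_layout(n_sens)),
            class = "phase_series")
}
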