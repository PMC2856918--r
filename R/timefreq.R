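# Morlet wavelet time-frequency analysis: spectral amplitude, baseline
# normalization, rate conversion, zero-phase filtering, instantaneous phase.

#' Morlet wavelet specification
#'
#' The complex Morlet wavelet
#' \deqn{w(f,t) = (2\pi\sigma_t^2)^{-1/2} \exp(-t^2/2\sigma_t^2)
#'   \exp(2 i \pi f t)}
#' with a fixed ratio \eqn{f/\sigma_f = 7} (where
#' \eqn{\sigma_f = 1/(2\pi\sigma_t)}), evaluated on a frequency grid of 1 Hz
#' steps over 2-20 Hz and 2 Hz steps over 21-79 Hz (49 bins; 38 of them in
#' the 13-79 Hz classifier feature band).
#'
#' @param f0_ratio cycles parameter, the ratio `f / sigma_f` (default 7).
#' @param freqs frequency grid in Hz; default as above.
#' @return object of class `wavelet_spec` with derived per-frequency
#'   `sigma_f` and `sigma_t`.
#' @export
wavelet_spec <- function(f0_ratio = 7,
                         freqs = c(seq(2, 20, by = 1), seq(21, 79, by = 2))) {
  freqs <- as.numeric(freqs)
  if (any(diff(freqs) <= 0)) stop("frequency grid must be strictly increasing")
  if (any(freqs <= 0)) stop("frequencies must be positive")
  sigma_f <- freqs / f0_ratio
  sigma_t <- 1 / (2 * pi * sigma_f)
  structure(list(f0_ratio = f0_ratio, freqs = freqs,
                 sigma_f = sigma_f, sigma_t = sigma_t),
            class = "wavelet_spec")
}

# Complex Morlet coefficients for a time x series matrix, one frequency.
# FFT-based circular convolution; normalized so a unit-amplitude sinusoid at
# the wavelet's centre frequency yields unit modulus. The 1000 ms epoch
# margins absorb the wrap-around.
cwt_matrix <- function(x, fs, freq, f0_ratio) {
  n <- nrow(x)
  nu <- (seq_len(n) - 1) / n * fs
  nu[nu > fs / 2] <- nu[nu > fs / 2] - fs     # signed frequency axis
  sigma_f <- freq / f0_ratio
  h <- 2 * exp(-(nu - freq)^2 / (2 * sigma_f^2))
  xf <- stats::mvfft(x)
  stats::mvfft(xf * h, inverse = TRUE) / n
}

# Guard against epochs shorter than the wavelet support at a frequency.
check_wavelet_support <- function(n_time, fs, freq, f0_ratio) {
  support <- 6 * (f0_ratio / (2 * pi * freq))      # +/- 3 sigma_t, seconds
  if (n_time / fs < support) {
    stop(sprintf(paste0("epoch (%.2f s) shorter than the wavelet support ",
                        "(%.2f s) at %g Hz: edge effects would dominate"),
                 n_time / fs, support, freq))
  }
}

#' Single-trial spectral amplitude by continuous wavelet transform
#'
#' Computes the modulus of the complex Morlet coefficients for every trial,
#' sensor and grid frequency. Amplitude is linear in the input signal. By
#' default the native time axis is kept; passing `times_ms` evaluates the
#' amplitude at those times only (by linear interpolation from the native
#' grid), which is how the pipeline keeps large cohorts in memory.
#'
#' @param epochs an [epoch_set()].
#' @param spec a [wavelet_spec()].
#' @param times_ms optional times (ms) at which to retain amplitude.
#' @param chunk trials per FFT batch.
#' @return object of class `tf_rep`: `amplitude` array
#'   `trials x sensors x frequencies x time`, plus the frequency grid, time
#'   axis, metadata and layout carried over from the epochs.
#' @export
cwt_amplitude <- function(epochs, spec = wavelet_spec(), times_ms = NULL,
                          chunk = 8) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(spec, "wavelet_spec"))
  n_trials <- dim(epochs$signal)[1]
  n_sens <- dim(epochs$signal)[2]
  n_time <- dim(epochs$signal)[3]
  check_wavelet_support(n_time, epochs$sfreq, min(spec$freqs), spec$f0_ratio)
  native <- is.null(times_ms)
  out_t <- if (native) epochs$time_ms else as.numeric(times_ms)
  if (any(out_t < epochs$time_ms[1] | out_t > epochs$time_ms[n_time])) {
    stop("requested times outside the epoch")
  }
  n_out <- length(out_t)
  amp <- array(NA_real_, c(n_trials, n_sens, length(spec$freqs), n_out))
  nu <- (seq_len(n_time) - 1) / n_time * epochs$sfreq
  nu[nu > epochs$sfreq / 2] <- nu[nu > epochs$sfreq / 2] - epochs$sfreq
  dur_s <- n_time / epochs$sfreq
  divs <- Filter(function(m) n_time %% m == 0, seq_len(n_time))
  starts <- seq(1, n_trials, by = chunk)
  for (s in starts) {
    tr <- s:min(s + chunk - 1, n_trials)
    # time x (trial, sensor) matrix for this chunk
    x <- matrix(aperm(epochs$signal[tr, , , drop = FALSE], c(3, 2, 1)),
                n_time, n_sens * length(tr))
    xf <- stats::mvfft(x)
    for (k in seq_along(spec$freqs)) {
      h <- 2 * exp(-(nu - spec$freqs[k])^2 / (2 * spec$sigma_f[k]^2))
      if (native) {
        a <- Mod(stats::mvfft(xf * h, inverse = TRUE) / n_time)
      } else {
        # zoom transform: the coefficient spectrum is confined to a narrow
        # Gaussian band around the centre frequency, so invert only that
        # band at a decimated length (a divisor of n, >= 24 sigma_f of
        # bandwidth) and interpolate the smooth amplitude envelope.
        need <- min(max(ceiling(24 * spec$sigma_f[k] * dur_s), 96), n_time)
        m <- divs[divs >= need][1]
        if (m == n_time) {
          a <- Mod(stats::mvfft(xf * h, inverse = TRUE) / n_time)
          ad <- a
          td <- epochs$time_ms
        } else {
          jc <- round(spec$freqs[k] * dur_s)
          bins <- ((jc - m %/% 2 + 0:(m - 1)) %% n_time) + 1
          z <- xf[bins, , drop = FALSE] * h[bins]
          ad <- Mod(stats::mvfft(z, inverse = TRUE) / n_time)
          td <- epochs$time_ms[1] + (0:(m - 1)) * (n_time / m) * 1000 / epochs$sfreq
        }
        j0 <- findInterval(out_t, td)
        j0 <- pmin(pmax(j0, 1L), length(td) - 1L)
        v1 <- (out_t - td[j0]) / (td[j0 + 1] - td[j0])
        v1 <- pmin(pmax(v1, 0), 1)
        a <- ad[j0, , drop = FALSE] * (1 - v1) +
          ad[j0 + 1L, , drop = FALSE] * v1
      }
      # a: time_out x (sensor, trial) -> fill [trial, sensor, k, time]
      amp[tr, , k, ] <- aperm(array(a, c(n_out, n_sens, length(tr))),
                              c(3, 2, 1))
    }
  }
  structure(list(amplitude = amp, freqs = spec$freqs, time_ms = out_t,
                 info = epochs$info, layout = epochs$layout,
                 sfreq = epochs$sfreq, baseline = NULL),
            class = "tf_rep")
}

#' @export
print.tf_rep <- function(x, ...) {
  d <- dim(x$amplitude)
  cat(sprintf("<tf_rep> %d trials x %d sensors x %d freqs x %d times\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  freqs %g-%g Hz; time %g..%g ms; baseline %s\n",
              min(x$freqs), max(x$freqs), min(x$time_ms), max(x$time_ms),
              if (is.null(x$baseline)) "not removed"
              else paste(x$baseline, collapse = "..")))
  invisible(x)
}

#' Baseline-normalize a time-frequency representation
#'
#' Subtracts, per trial, sensor and frequency, the mean spectral amplitude
#' over the baseline window (default 500 to 100 ms before sample onset).
#' Idempotent: the baseline-window mean of the output is zero.
#'
#' @param tf a `tf_rep`.
#' @param window baseline window in ms, default `c(-500, -100)`.
#' @return baseline-normalized `tf_rep`.
#' @export
baseline_normalize <- function(tf, window = c(-500, -100)) {
  stopifnot(inherits(tf, "tf_rep"))
  idx <- which(tf$time_ms >= window[1] & tf$time_ms <= window[2])
  if (length(idx) == 0) stop("baseline window outside the represented times")
  base <- apply(tf$amplitude[, , , idx, drop = FALSE], c(1, 2, 3), mean)
  tf$amplitude <- sweep(tf$amplitude, c(1, 2, 3), base, "-")
  tf$baseline <- window
  tf
}

#' Downsample a time-frequency representation
#'
#' Converts the time axis to `target` Hz by linear interpolation onto a
#' uniform grid starting at the first represented time (480 to 250 Hz is not
#' an integer decimation, so interpolation is used for any rate).
#'
#' @param tf a `tf_rep` on a uniform time axis.
#' @param target output rate, Hz (must not exceed the source rate).
#' @return `tf_rep` on the target grid.
#' @export
downsample_tf <- function(tf, target = 250) {
  stopifnot(inherits(tf, "tf_rep"))
  dt <- diff(tf$time_ms)
  if (max(abs(dt - dt[1])) > 1e-6) stop("time axis must be uniform")
  src <- 1000 / dt[1]
  if (target > src + 1e-9) stop("target rate exceeds source rate")
  grid <- seq(tf$time_ms[1], tf$time_ms[length(tf$time_ms)], by = 1000 / target)
  d <- dim(tf$amplitude)
  m <- matrix(tf$amplitude, prod(d[1:3]), d[4])
  i0 <- findInterval(grid, tf$time_ms)
  i0 <- pmin(pmax(i0, 1L), d[4] - 1L)
  w1 <- (grid - tf$time_ms[i0]) / (tf$time_ms[i0 + 1] - tf$time_ms[i0])
  w1 <- pmin(pmax(w1, 0), 1)
  out <- m[, i0, drop = FALSE] * rep(1 - w1, each = nrow(m)) +
    m[, i0 + 1L, drop = FALSE] * rep(w1, each = nrow(m))
  tf$amplitude <- array(out, c(d[1:3], length(grid)))
  tf$time_ms <- grid
  tf
}

#' Zero-phase high-pass filter
#'
#' Forward-backward (two-pass) Butterworth high-pass: zero net phase shift,
#' DC removed. Applied before instantaneous theta phase estimation.
#'
#' @param epochs an [epoch_set()].
#' @param cutoff high-pass cutoff, Hz (default 3).
#' @param order filter order of one pass (default 4).
#' @return filtered `epoch_set`.
#' @export
zero_phase_highpass <- function(epochs, cutoff = 3, order = 4) {
  stopifnot(inherits(epochs, "epoch_set"))
  nyq <- epochs$sfreq / 2
  if (cutoff >= nyq) stop("cutoff must be below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / nyq, type = "high")
  d <- dim(epochs$signal)
  m <- matrix(aperm(epochs$signal, c(3, 1, 2)), d[3], d[1] * d[2])
  for (j in seq_len(ncol(m))) m[, j] <- signal::filtfilt(bf, m[, j])
  epochs$signal <- aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
  epochs
}

#' Instantaneous theta phase
#'
#' Phase of the complex Morlet coefficient at a single theta frequency,
#' wrapped to (-pi, pi], reported on a uniform 250 Hz grid (nearest native
#' sample; phase is scale invariant, so wavelet normalization is immaterial).
#'
#' @param epochs an [epoch_set()], already high-pass filtered at 3 Hz.
#' @param theta_freq requested frequency, Hz; must lie on the wavelet grid.
#' @param spec a [wavelet_spec()].
#' @param target_rate output rate of the phase series, Hz.
#' @return object of class `phase_series`: array `trials x sensors x time`
#'   in radians plus the time axis and frequency.
#' @export
instantaneous_phase <- function(epochs, theta_freq, spec = wavelet_spec(),
                                target_rate = 250) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!any(abs(spec$freqs - theta_freq) < 1e-9)) {
    stop(sprintf("frequency %g Hz is not on the wavelet grid", theta_freq))
  }
  d <- dim(epochs$signal)
  check_wavelet_support(d[3], epochs$sfreq, theta_freq, spec$f0_ratio)
  grid <- seq(epochs$time_ms[1], epochs$time_ms[d[3]], by = 1000 / target_rate)
  nearest <- round(stats::approx(epochs$time_ms, seq_len(d[3]), xout = grid,
                          rule = 2)$y)
  phase <- array(NA_real_, c(d[1], d[2], length(grid)))
  for (s in seq(1, d[1], by = 8)) {
    tr <- s:min(s + 7, d[1])
    x <- matrix(aperm(epochs$signal[tr, , , drop = FALSE], c(3, 2, 1)),
                d[3], d[2] * length(tr))
    co <- cwt_matrix(x, epochs$sfreq, theta_freq, spec$f0_ratio)
    ph <- wrap_pi(Arg(co[nearest, , drop = FALSE]))
    phase[tr, , ] <- aperm(array(ph, c(length(grid), d[2], length(tr))),
                           c(3, 2, 1))
  }
  structure(list(phase = phase, time_ms = grid, freq = theta_freq,
                 info = epochs$info, layout = epochs$layout),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("<phase_series> %g Hz, %d trials x %d sensors x %d times\n",
              x$freq, d[1], d[2], d[3]))
  invisible(x)
}
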