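# Synthetic cohort generator: multichannel epochs with known category
# patterns, theta-coupled replay events, and behavioral accuracies.

#' Generator parameters
#'
#' Defines one simulated study. The defaults emulate the reference design:
#' 9 s epochs (1 s pre-stimulus baseline, 3 s sample presentation, 5 s
#' maintenance), 20 trials per category (indoor/outdoor) per condition
#' (control / nonconfigural / configural), 8 subjects, 480 Hz sampling, and a
#' 64-sensor grid. Each (category, condition) pair receives a distinct
#' 13-79 Hz spectral pattern, planted during the sample window and re-injected
#' during maintenance as theta-phase-coupled replay bursts.
#'
#' `replay_rate` and `coupling_kappa` may be scalars or named per-condition
#' vectors; control trials carry no replay by default (`replay_rate` 0).
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_trials_per_category trials per category per condition (>= 2).
#' @param n_sensors number of sensors (64 grid default; 275 helmet supported).
#' @param sampling_rate acquisition rate, Hz.
#' @param epoch_window epoch limits in ms relative to sample onset.
#' @param theta_freq frequency of the planted ongoing theta oscillation, Hz.
#' @param theta_amp theta amplitude relative to the unit-variance 1/f noise.
#' @param theta_sensors integer indices of the sensors carrying coherent
#'   theta (default: a contiguous 12-sensor block chosen by
#'   [default_theta_cluster()]).
#' @param replay_rate replay events per second of maintenance, per condition.
#' @param coupling_kappa von Mises concentration of event phases, per
#'   condition (`kappa >= 0`; 0 means phase-uniform replay).
#' @param coupling_mu preferred theta phase of replay events, radians.
#' @param burst_duration duration of one replay burst, ms.
#' @param pattern_snr amplitude of the category pattern relative to the noise
#'   standard deviation, during both the sample window and replay bursts.
#' @param pattern_onset_ms latency of the category-specific response after
#'   sample onset (category-selective cortical responses emerge a couple of
#'   hundred ms post-stimulus, so pre-stimulus time points carry no category
#'   information).
#' @param pattern_ramp_ms raised-cosine rise/fall time of the sample-window
#'   pattern envelope.
#' @param noise_exponent spectral slope of the 1/f background noise.
#' @param noise_gain_sd log-sd of the slow multiplicative cortical-state
#'   gain on the background noise (0 disables; 0.5 gives the roughly
#'   +/- 50 percent single-trial power fluctuations typical of ongoing
#'   M/EEG activity).
#' @param noise_gain_hz bandwidth of the gain fluctuations, Hz.
#' @param noise_gain_global fraction of gain variance shared across sensors.
#' @param kappa_spread relative spread of per-subject kappa multipliers
#'   (0 = all subjects share `coupling_kappa`).
#' @param behav_base,behav_slope,behav_noise behavioral accuracy model:
#'   `accuracy = behav_base + behav_slope * kappa_configural + noise`.
#' @param rng_seed integer master seed; all randomness derives from it.
#' @return an object of class `generator_params`.
#' @export
generator_params <- function(n_subjects = 8,
                             n_trials_per_category = 20,
                             n_sensors = 64,
                             sampling_rate = 480,
                             epoch_window = c(-1000, 8000),
                             theta_freq = 6,
                             theta_amp = 2,
                             theta_sensors = NULL,
                             replay_rate = c(control = 0,
                                             nonconfigural = 0.8,
                                             configural = 1.2),
                             coupling_kappa = c(control = 0,
                                                nonconfigural = 4,
                                                configural = 8),
                             coupling_mu = 0,
                             burst_duration = 250,
                             pattern_snr = 2,
                             pattern_onset_ms = 200,
                             pattern_ramp_ms = 100,
                             noise_exponent = 1,
                             noise_gain_sd = 0.5,
                             noise_gain_hz = 0.5,
                             noise_gain_global = 0.5,
                             kappa_spread = 0,
                             behav_base = 0.8,
                             behav_slope = 0,
                             behav_noise = 0.02,
                             rng_seed = 1) {
  replay_rate <- per_condition(replay_rate, "replay_rate")
  coupling_kappa <- per_condition(coupling_kappa, "coupling_kappa")
  if (any(replay_rate < 0)) stop("replay_rate must be >= 0")
  if (any(coupling_kappa < 0)) stop("coupling_kappa must be >= 0")
  if (n_trials_per_category < 2) stop("n_trials_per_category must be >= 2")
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (sampling_rate <= 0 || theta_freq <= 0) stop("rates must be positive")
  if (burst_duration <= 0) stop("burst_duration must be positive")
  if (pattern_snr < 0) stop("pattern_snr must be >= 0")
  if (!(epoch_window[1] <= -1000 && epoch_window[2] >= 8000)) {
    stop("epoch_window must span baseline (-1000..0), sample (0..3000), ",
         "and maintenance (3000..8000) ms")
  }
  if (is.null(theta_sensors)) theta_sensors <- default_theta_cluster(n_sensors)
  if (any(theta_sensors < 1 | theta_sensors > n_sensors)) {
    stop("theta_sensors out of range")
  }
  structure(
    list(n_subjects = n_subjects,
         n_trials_per_category = n_trials_per_category,
         n_sensors = n_sensors,
         sampling_rate = sampling_rate,
         epoch_window = epoch_window,
         theta_freq = theta_freq,
         theta_amp = theta_amp,
         theta_sensors = as.integer(theta_sensors),
         replay_rate = replay_rate,
         coupling_kappa = coupling_kappa,
         coupling_mu = coupling_mu,
         burst_duration = burst_duration,
         pattern_snr = pattern_snr,
         pattern_onset_ms = pattern_onset_ms,
         pattern_ramp_ms = pattern_ramp_ms,
         noise_exponent = noise_exponent,
         noise_gain_sd = noise_gain_sd,
         noise_gain_hz = noise_gain_hz,
         noise_gain_global = noise_gain_global,
         kappa_spread = kappa_spread,
         behav_base = behav_base,
         behav_slope = behav_slope,
         behav_noise = behav_noise,
         rng_seed = as.integer(rng_seed)),
    class = "generator_params"
  )
}

#' Default coherent-theta sensor cluster
#'
#' A contiguous 12-sensor block (3 x 4 on grid layouts) near the centre of
#' the array; these sensors carry the coherent theta oscillation that replay
#' events are phase-locked to.
#'
#' @param n_sensors total sensor count.
#' @return integer sensor indices.
#' @export
default_theta_cluster <- function(n_sensors) {
  side <- ceiling(sqrt(n_sensors))
  rows <- floor(side / 2) + (-1:1)
  cols <- floor(side / 2) + (-1:2)
  idx <- as.vector(outer(cols, rows, function(c, r) r * side + c + 1))
  idx <- idx[idx >= 1 & idx <= n_sensors]
  sort(as.integer(idx))
}

# Slow multiplicative gain field (sensors x time): lognormal cortical-state
# fluctuations of the background amplitude, band-limited below gain_hz,
# partially coherent across sensors. These large, slow single-trial power
# fluctuations are what keep off-replay classifier outputs variable.
state_gain <- function(n_time, n_sens, fs, sd_g, gain_hz, w_global) {
  if (sd_g <= 0) return(matrix(1, n_sens, n_time))
  w <- matrix(stats::rnorm(n_time * (n_sens + 1)), n_time, n_sens + 1)
  f <- c(0, seq_len(n_time - 1)) / n_time * fs
  f <- pmin(f, fs - f)
  lp <- exp(-f^2 / (2 * gain_hz^2))
  z <- Re(stats::mvfft(stats::mvfft(w) * lp, inverse = TRUE)) / n_time
  z <- sweep(z, 2, apply(z, 2, stats::sd), "/")
  zz <- sqrt(w_global) * z[, n_sens + 1] +
    sqrt(1 - w_global) * z[, seq_len(n_sens), drop = FALSE]
  exp(sd_g * t(zz) - sd_g^2 / 2)
}

# 1/f noise: spectrally shaped white noise, unit variance per column.
pink_noise <- function(n_time, n_series, exponent, fs) {
  w <- matrix(stats::rnorm(n_time * n_series), n_time, n_series)
  if (exponent == 0) return(w)
  wf <- stats::mvfft(w)
  f <- c(0, seq_len(n_time - 1)) / n_time * fs
  f <- pmin(f, fs - f)                      # two-sided frequency magnitude
  shape <- c(0, 1 / f[-1]^(exponent / 2))
  x <- Re(stats::mvfft(wf * shape, inverse = TRUE)) / n_time
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

# Draw a distinct spectral pattern for one (category, condition) pair:
# a handful of 13-79 Hz carriers with random amplitudes and phases, projected
# onto a random contiguous sensor block. Carrier pools are disjoint across
# the six (condition, category) cells: condition-specific category codes,
# the regime in which cross-condition specificity is a meaningful contrast.
draw_pattern <- function(category, condition, n_sensors, n_carriers = 4) {
  grid_hi <- seq(13, 79, by = 2)            # carriers within the feature band
  cell <- (match(condition, CONDITIONS) - 1) * 2 + match(category, CATEGORIES)
  pool <- grid_hi[seq_along(grid_hi) %% 6 == (cell - 1) %% 6]
  carriers <- sort(sample(pool, n_carriers))
  amps <- stats::runif(n_carriers, 0.5, 1)
  phases <- stats::runif(n_carriers, 0, 2 * pi)
  side <- ceiling(sqrt(n_sensors))
  block <- min(4, side)
  r0 <- sample(0:(side - block), 1)
  c0 <- sample(0:(side - block), 1)
  cells <- as.vector(outer(c0 + 0:(block - 1), r0 + 0:(block - 1),
                           function(c, r) r * side + c + 1))
  cells <- cells[cells <= n_sensors]
  weights <- numeric(n_sensors)
  weights[cells] <- stats::runif(length(cells), 0.5, 1)
  list(category = category, condition = condition,
       carriers = carriers, amps = amps, phases = phases,
       weights = weights)
}

# Carrier waveform of a pattern, normalized to unit RMS.
pattern_waveform <- function(pat, t_s) {
  x <- numeric(length(t_s))
  for (i in seq_along(pat$carriers)) {
    x <- x + pat$amps[i] * cos(2 * pi * pat$carriers[i] * t_s + pat$phases[i])
  }
  x / sqrt(sum(pat$amps^2) / 2)
}

# Theta-locked replay event times for one (condition, category) cell:
# Poisson count over the maintenance interval, each event assigned a phase
# drawn from von Mises(mu, kappa) and placed at the time where the planted
# theta oscillation attains that phase, on a uniformly chosen cycle.
draw_events <- function(rate, kappa, mu, theta_freq, phi0,
                        window_s, maintenance_s) {
  n_ev <- stats::rpois(1, rate * maintenance_s)
  if (n_ev == 0) {
    return(data.frame(onset_ms = numeric(0), phase = numeric(0)))
  }
  psi <- rvonmises(n_ev, mu, kappa)
  t_ev <- numeric(n_ev)
  for (i in seq_len(n_ev)) {
    # solve 2*pi*f*t + phi0 = psi (mod 2*pi) for t within the window
    k_lo <- ceiling((2 * pi * theta_freq * window_s[1] - psi[i] + phi0) / (2 * pi))
    k_hi <- floor((2 * pi * theta_freq * window_s[2] - psi[i] + phi0) / (2 * pi))
    k <- if (k_hi > k_lo) sample(k_lo:k_hi, 1) else k_lo
    t_ev[i] <- (psi[i] - phi0 + 2 * pi * k) / (2 * pi * theta_freq)
  }
  ord <- order(t_ev)
  data.frame(onset_ms = t_ev[ord] * 1000, phase = psi[ord])
}

#' Generate one synthetic subject
#'
#' Builds the full epoch set for one subject: all three conditions, both
#' categories, `n_trials_per_category` trials each. Background is
#' unit-variance 1/f noise on every sensor plus a coherent theta oscillation
#' on the `theta_sensors` cluster (theta phase is common to all trials of a
#' subject, i.e. stimulus-locked). During the sample window (0-3000 ms) the
#' (category, condition) spectral pattern is added at `pattern_snr`. During
#' maintenance (3000-8000 ms), replay bursts re-inject the same pattern for
#' `burst_duration` ms at theta phases drawn from von
#' Mises(`coupling_mu`, `coupling_kappa`). Replay is trial-coherent: the
#' event train is drawn once per (condition, category) cell and expressed in
#' every trial of that cell, which is the regime in which a
#' 20-of-20-trials reactivation criterion has detection power.
#'
#' @param params a [generator_params()] object.
#' @param subject_index subject number (1-based); determines the subject's
#'   RNG stream.
#' @param kappa_scale internal per-subject multiplier on `coupling_kappa`
#'   (set by [generate_cohort()] when `kappa_spread > 0`).
#' @return list with elements `epochs` (an [epoch_set()]) and `truth`
#'   (ground-truth record: per-trial replay events with planted phases,
#'   per-condition kappa actually used, theta phase offset, the spectral
#'   patterns, and the subject's behavioral accuracy).
#' @export
generate_subject <- function(params, subject_index, kappa_scale = 1) {
  stopifnot(inherits(params, "generator_params"))
  seed <- derive_seed(params$rng_seed, 101, subject_index)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  fs <- params$sampling_rate
  t_ms <- seq(params$epoch_window[1], params$epoch_window[2] - 1000 / fs,
              by = 1000 / fs)
  t_s <- t_ms / 1000
  n_time <- length(t_ms)
  n_sens <- params$n_sensors
  n_per <- params$n_trials_per_category
  layout <- if (n_sens == 275) helmet_layout(275) else grid_layout(n_sens)

  phi0 <- stats::runif(1, -pi, pi)          # subject's theta phase offset
  theta_wave <- params$theta_amp * cos(2 * pi * params$theta_freq * t_s + phi0)
  theta_mat <- matrix(0, n_sens, n_time)
  theta_mat[params$theta_sensors, ] <- rep(theta_wave,
                                           each = length(params$theta_sensors))

  kap <- params$coupling_kappa * kappa_scale
  half_burst_s <- params$burst_duration / 2000
  ev_window_s <- c(3 + half_burst_s, 8 - half_burst_s)
  # sample-window envelope: category response rises pattern_onset_ms after
  # picture onset with a raised-cosine ramp, and falls at sample offset
  on <- params$pattern_onset_ms
  rmp <- params$pattern_ramp_ms
  sample_env <- numeric(n_time)
  up <- t_ms >= on & t_ms < on + rmp
  sample_env[up] <- 0.5 - 0.5 * cos(pi * (t_ms[up] - on) / rmp)
  sample_env[t_ms >= on + rmp & t_ms < 3000 - rmp] <- 1
  dn <- t_ms >= 3000 - rmp & t_ms < 3000
  sample_env[dn] <- 0.5 + 0.5 * cos(pi * (t_ms[dn] - (3000 - rmp)) / rmp)

  n_trials_total <- 3 * 2 * n_per
  signal <- array(0, c(n_trials_total, n_sens, n_time))
  info <- data.frame(trial = integer(0), category = character(0),
                     condition = character(0), subject = integer(0),
                     presentation = integer(0), stringsAsFactors = FALSE)
  events_all <- NULL
  patterns <- list()
  trial_i <- 0L

  for (cond in CONDITIONS) {
    for (cat in CATEGORIES) {
      pat <- draw_pattern(cat, cond, n_sens)
      patterns[[paste(cond, cat, sep = ".")]] <- pat
      carrier <- pattern_waveform(pat, t_s)

      # cell base: theta + sample pattern + replay bursts (shared by trials)
      base <- theta_mat
      base <- base + params$pattern_snr *
        outer(pat$weights, carrier * sample_env)
      ev <- draw_events(params$replay_rate[[cond]], kap[[cond]],
                        params$coupling_mu, params$theta_freq, phi0,
                        ev_window_s, 5)
      if (nrow(ev) > 0) {
        burst_env <- numeric(n_time)
        for (j in seq_len(nrow(ev))) {
          idx <- which(abs(t_ms - ev$onset_ms[j]) <= params$burst_duration / 2)
          burst_env[idx] <- pmax(burst_env[idx], tukey_window(length(idx)))
        }
        base <- base + params$pattern_snr *
          outer(pat$weights, carrier * burst_env)
      }

      for (p in seq_len(n_per)) {
        trial_i <- trial_i + 1L
        noise <- t(pink_noise(n_time, n_sens, params$noise_exponent, fs))
        g <- state_gain(n_time, n_sens, fs, params$noise_gain_sd,
                        params$noise_gain_hz, params$noise_gain_global)
        signal[trial_i, , ] <- base + noise * g
        info <- rbind(info, data.frame(
          trial = trial_i, category = cat, condition = cond,
          subject = subject_index, presentation = p,
          stringsAsFactors = FALSE))
        if (nrow(ev) > 0) {
          events_all <- rbind(events_all, data.frame(
            subject = subject_index, condition = cond, category = cat,
            trial = trial_i, onset_ms = ev$onset_ms, phase = ev$phase,
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  if (is.null(events_all)) {
    events_all <- data.frame(subject = integer(0), condition = character(0),
                             category = character(0), trial = integer(0),
                             onset_ms = numeric(0), phase = numeric(0),
                             stringsAsFactors = FALSE)
  }

  accuracy <- params$behav_base +
    params$behav_slope * kap[["configural"]] +
    stats::rnorm(1, 0, params$behav_noise)
  accuracy <- min(max(accuracy, 0), 1)

  epochs <- epoch_set(signal, t_ms, fs, info, layout)
  truth <- list(subject = subject_index, events = events_all,
                kappa = kap, mu = params$coupling_mu, phi0 = phi0,
                patterns = patterns, accuracy = accuracy, seed = seed)
  list(epochs = epochs, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Calls [generate_subject()] with deterministic per-subject seeds derived
#' from `rng_seed`. When `kappa_spread > 0`, per-subject multipliers spread
#' the coupling concentration evenly over
#' `1 +/- kappa_spread`, which (with `behav_slope > 0`) yields the linear
#' coupling-behavior dependence used by the correlation-recovery tests.
#'
#' @param params a [generator_params()] object.
#' @return list of per-subject lists (`epochs`, `truth`), length
#'   `n_subjects`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  scales <- if (params$kappa_spread > 0 && params$n_subjects > 1) {
    1 + params$kappa_spread * seq(-1, 1, length.out = params$n_subjects)
  } else rep(1, params$n_subjects)
  scales <- pmax(scales, 0)
  lapply(seq_len(params$n_subjects), function(s) {
    generate_subject(params, s, kappa_scale = scales[s])
  })
}

# Save/restore the global RNG state so generator calls are pure functions of
# their seed without disturbing the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
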