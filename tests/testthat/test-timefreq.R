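# Morlet time-frequency stack: grid geometry, analytic wavelet responses,
# normalization, rate conversion, filtering, and phase estimation.

fs <- 480
t_ms <- seq(-1000, 8000 - 1000 / fs, by = 1000 / fs)
t_s <- t_ms / 1000

test_that("the frequency grid has 49 bins, 38 of them in the feature band", {
  spec <- wavelet_spec()
  expect_length(spec$freqs, 49)
  expect_equal(sum(spec$freqs >= 2 & spec$freqs <= 20), 19)
  expect_equal(sum(spec$freqs >= 21 & spec$freqs <= 79), 30)
  expect_equal(sum(spec$freqs >= 13 & spec$freqs <= 79), 38)
})

test_that("the cycles ratio fixes sigma_f and sigma_t (7 Hz -> 1 Hz, 1/(2 pi) s)", {
  spec <- wavelet_spec()
  k <- which(spec$freqs == 7)
  expect_equal(spec$sigma_f[k], 1)
  expect_equal(spec$sigma_t[k], 1 / (2 * pi))
})

test_that("zero signal transforms to zero amplitude and amplitude is linear", {
  ep <- make_epochs(list(numeric(length(t_ms))), n_trials = 1)
  tf <- cwt_amplitude(ep)
  expect_true(all(tf$amplitude == 0))

  x <- cos(2 * pi * 10 * t_s) + 0.3 * sin(2 * pi * 31 * t_s)
  ep1 <- make_epochs(list(x), n_trials = 1)
  ep2 <- make_epochs(list(2 * x), n_trials = 1)
  a1 <- cwt_amplitude(ep1)$amplitude
  a2 <- cwt_amplitude(ep2)$amplitude
  expect_equal(a2, 2 * a1, tolerance = 1e-10)
})

test_that("a pure sinusoid gives the closed-form Gaussian frequency response", {
  f0 <- 10
  ep <- make_epochs(list(cos(2 * pi * f0 * t_s)), n_trials = 1)
  spec <- wavelet_spec()
  tf <- cwt_amplitude(ep, spec)
  mid <- which(tf$time_ms > 2000 & tf$time_ms < 6000)
  resp <- apply(tf$amplitude[1, 1, , mid], 1, mean)
  expect_equal(spec$freqs[which.max(resp)], f0)
  # oracle: response of the bin at f to a tone at f0 is
  # exp(-(f0 - f)^2 / (2 sigma_f(f)^2)), up to normalization
  oracle <- exp(-(f0 - spec$freqs)^2 / (2 * spec$sigma_f^2))
  near <- which(abs(spec$freqs - f0) <= 4)
  expect_equal(resp[near] / max(resp), oracle[near] / max(oracle),
               tolerance = 0.02)
  # unit-amplitude tone -> unit modulus at its own bin
  expect_equal(max(resp), 1, tolerance = 0.01)
})

test_that("epochs shorter than the wavelet support are refused", {
  ep <- make_epochs(list(rnorm(480)), n_trials = 1)   # 1 s epoch
  expect_error(cwt_amplitude(ep), "support")
})

test_that("baseline normalization subtracts the window mean and is idempotent", {
  freqs <- c(13, 20)
  amp <- array(3, c(2, 1, 2, 50))
  tms <- seq(-500, -500 + 49 * 4, by = 4)
  tf <- make_tf(amp, freqs, tms, c("indoor", "outdoor"))
  out <- baseline_normalize(tf, c(-500, -100))
  expect_true(all(out$amplitude == 0))

  amp2 <- array(5, c(2, 1, 2, 200))
  tms2 <- seq(-600, -600 + 199 * 4, by = 4)
  inside <- tms2 >= -500 & tms2 <= -100
  amp2[, , , inside] <- 3
  tf2 <- make_tf(amp2, freqs, tms2, c("indoor", "outdoor"))
  out2 <- baseline_normalize(tf2, c(-500, -100))
  expect_equal(unique(as.vector(out2$amplitude[, , , inside])), 0)
  expect_equal(unique(as.vector(out2$amplitude[, , , !inside])), 2)
  expect_equal(baseline_normalize(out2, c(-500, -100))$amplitude,
               out2$amplitude)

  expect_error(baseline_normalize(tf2, c(-5000, -4000)), "baseline window")
})

test_that("downsampling to 250 Hz yields the 4 ms grid and preserves content", {
  # 9 s at 480 Hz -> 2250 output samples
  x <- sin(2 * pi * 17 * t_s)
  ep <- make_epochs(list(x), n_trials = 1)
  tf <- cwt_amplitude(ep, wavelet_spec(freqs = c(17, 40)))
  dn <- downsample_tf(tf, 250)
  expect_equal(length(dn$time_ms), 2250)
  expect_equal(unique(round(diff(dn$time_ms), 9)), 4)

  # constant series stays constant
  cst <- make_tf(array(2.5, c(1, 1, 1, length(t_ms))), 13, t_ms, "indoor")
  expect_true(all(abs(downsample_tf(cst, 250)$amplitude - 2.5) < 1e-9))

  # band-limited amplitude envelope: analytic oracle, < 1% error
  env <- 2 + sin(2 * pi * 10 * t_s)
  tfe <- make_tf(array(env, c(1, 1, 1, length(t_ms))), 13, t_ms, "indoor")
  dne <- downsample_tf(tfe, 250)
  oracle <- 2 + sin(2 * pi * 10 * dne$time_ms / 1000)
  expect_lt(max(abs(dne$amplitude[1, 1, 1, ] - oracle)) / max(env), 0.01)

  expect_error(downsample_tf(tf, 960), "target rate")
})

test_that("zero-phase high-pass preserves 6 Hz phase, kills DC, attenuates 1 Hz", {
  x6 <- cos(2 * pi * 6 * t_s + 0.7)
  ep <- make_epochs(list(x6 + 2), n_trials = 1)      # with a DC offset
  hp <- zero_phase_highpass(ep, 3)
  mid <- which(t_ms > 1000 & t_ms < 7000)
  # phase via analytic-signal oracle: projection onto quadrature pair
  seg <- hp$signal[1, 1, mid]
  c1 <- sum(seg * cos(2 * pi * 6 * t_s[mid]))
  s1 <- sum(seg * sin(2 * pi * 6 * t_s[mid]))
  expect_lt(abs(wrap_pi(atan2(-s1, c1) - 0.7)), 0.05)
  # DC removed
  expect_lt(max(abs(hp$signal[1, 1, mid] - x6[mid])), 0.05)

  x1 <- cos(2 * pi * 1 * t_s)
  hp1 <- zero_phase_highpass(make_epochs(list(x1), n_trials = 1), 3)
  expect_lt(max(abs(hp1$signal[1, 1, mid])), 0.1)    # > 90% attenuation

  expect_error(zero_phase_highpass(ep, 300), "Nyquist")
})

test_that("instantaneous phase tracks a theta oscillation", {
  x <- cos(2 * pi * 6 * t_s)
  ep <- make_epochs(list(x), n_trials = 1)
  ph <- instantaneous_phase(ep, 6)
  mid <- which(ph$time_ms > 1000 & ph$time_ms < 7000)
  # phase ~ 0 at cosine peaks
  peaks <- mid[abs((ph$time_ms[mid] / 1000) %% (1 / 6)) < 1e-9]
  expect_lt(max(abs(ph$phase[1, 1, peaks])), 0.06)
  # unwrapped phase advances at 2 pi f per second, +/- 1%
  un <- ph$phase[1, 1, mid]
  un <- un + 2 * pi * cumsum(c(0, diff(un) < -pi))
  slope <- coef(lm(un ~ I(ph$time_ms[mid] / 1000)))[2]
  expect_lt(abs(slope - 2 * pi * 6) / (2 * pi * 6), 0.01)

  # sin lags cos by pi/2 at the same frequency
  eps <- make_epochs(list(sin(2 * pi * 6 * t_s)), n_trials = 1)
  phs <- instantaneous_phase(eps, 6)
  d <- wrap_pi(ph$phase[1, 1, mid] - phs$phase[1, 1, mid])
  expect_lt(max(abs(d - pi / 2)), 0.02)

  expect_error(instantaneous_phase(ep, 6.5), "not on the wavelet grid")
})

test_that("phase of planted theta is recovered within 0.15 rad RMS at SNR 2", {
  p <- generator_params(n_subjects = 1, n_trials_per_category = 3,
                        theta_amp = 2, rng_seed = 21)
  gs <- generate_subject(p, 1)
  hp <- zero_phase_highpass(gs$epochs)
  ph <- instantaneous_phase(hp, p$theta_freq)
  ev <- gs$truth$events
  sens <- p$theta_sensors[1]
  idx <- round(approx(ph$time_ms, seq_along(ph$time_ms),
                      xout = ev$onset_ms)$y)
  rows <- match(ev$trial, ph$info$trial)
  meas <- ph$phase[cbind(rows, sens, idx)]
  expect_lt(sqrt(mean(wrap_pi(meas - ev$phase)^2)), 0.15)
})
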