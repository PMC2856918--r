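# Phase-locking statistics: the PLV formula, arcsine normalization,
# small-N bias, condition contrasts, cluster permutation, circular-shift
# nulls, and the behavior correlation.

test_that("PLV matches its closed-form values", {
  expect_equal(plv(rep(1.3, 7)), 1)
  expect_equal(plv(c(0, pi)), 0)
  expect_equal(plv(c(0, pi / 2)), 1 / sqrt(2))
  expect_true(is.na(plv(0.4)))               # one event: excluded
  expect_equal(plv(0.4, min_events = 1), 1)
})

test_that("PLV is invariant under a global phase rotation", {
  set.seed(3)
  ph <- rvonmises(50, 1, 2)
  for (rot in c(-2, 0.5, 3)) {
    expect_equal(plv(wrap_pi(ph + rot)), plv(ph), tolerance = 1e-12)
  }
})

test_that("arcsine transform maps {0, 0.5, 1} to {-pi/2, 0, pi/2} monotonically", {
  expect_equal(arcsine_z(c(0, 0.5, 1)), c(-pi / 2, 0, pi / 2))
  x <- seq(0, 1, by = 0.01)
  expect_true(all(diff(arcsine_z(x)) > 0))
  expect_error(arcsine_z(1.2), "\\[0, 1\\]")
})

test_that("uniform-phase PLV shows the expected small-N bias, not coupling", {
  # for N uniform phases E[PLV] ~ sqrt(pi)/2 / sqrt(N)
  set.seed(8)
  for (N in c(4, 8, 16, 64)) {
    m <- mean(replicate(3000, plv(runif(N, -pi, pi))))
    expect_lt(abs(m - sqrt(pi) / 2 / sqrt(N)), 0.015)
  }
})

test_that("the PLV table reads phases at event times and excludes sparse trials", {
  ps <- make_phase_series(n_trials = 3, n_sens = 2)
  # trial 1: events at theta peaks (phase 0); trial 2: two opposed phases;
  # trial 3: single event -> excluded
  ev <- data.frame(
    trial = c(1, 1, 1, 2, 2, 3),
    time_ms = c(4000, 4000 + 1000 / 6, 4000 + 2000 / 6,
                5000, 5000 + 500 / 6, 6000))
  tab <- event_plv_table(ev, ps)
  # phases are read at the nearest 4 ms sample, so allow that discretization
  t1 <- tab[tab$trial == 1, ]
  expect_equal(t1$plv, rep(1, 2), tolerance = 2e-3)
  expect_equal(t1$n_events, rep(3, 2))
  t2 <- tab[tab$trial == 2, ]
  expect_equal(t2$plv, rep(0, 2), tolerance = 0.05)
  expect_true(all(is.na(tab$plv[tab$trial == 3])))
})

test_that("paired sensor contrast finds planted coupling differences", {
  set.seed(5)
  n_sub <- 8; n_sens <- 16
  za <- matrix(rnorm(n_sub * n_sens, 0, 0.1), n_sub, n_sens)
  zb <- za + matrix(rnorm(n_sub * n_sens, 0, 0.1), n_sub, n_sens)
  zb[, 1:4] <- zb[, 1:4] + 1                  # planted effect, B > A
  ct <- coupling_contrast(zb, za)
  expect_setequal(order(ct$p)[1:4], 1:4)
  expect_true(all(ct$t[1:4] > 0))
  expect_error(coupling_contrast(za, za), "zero variance")
  expect_error(coupling_contrast(za[1, , drop = FALSE],
                                 zb[1, , drop = FALSE]), "2 subjects")
})

test_that("sensor-wise contrast has ~5% type-I rate under the null", {
  set.seed(6)
  hits <- 0; total <- 0
  for (r in 1:100) {
    za <- matrix(rnorm(8 * 16), 8, 16)
    zb <- matrix(rnorm(8 * 16), 8, 16)
    ct <- coupling_contrast(za, zb)
    hits <- hits + sum(ct$p < 0.05); total <- total + 16
  }
  expect_lt(abs(hits / total - 0.05), 4 * sqrt(0.05 * 0.95 / total))
})

grid_adj <- sensor_adjacency(grid_layout(64))

test_that("clusters below eight adjacent sensors are never reported", {
  set.seed(9)
  za <- matrix(rnorm(8 * 64, 0, 0.05), 8, 64)
  zb <- za + matrix(rnorm(8 * 64, 0, 0.05), 8, 64)
  seven <- c(1:4, 9:11)                       # 7 mutually adjacent sensors
  zb[, seven] <- zb[, seven] + 2
  cl <- cluster_permutation(zb, za, grid_adj, n_perm = 500, seed = 2)
  expect_equal(nrow(cl), 0)
})

test_that("a planted 20-sensor effect is recovered with small permutation p", {
  set.seed(10)
  za <- matrix(rnorm(8 * 64, 0, 0.1), 8, 64)
  zb <- za + matrix(rnorm(8 * 64, 0, 0.1), 8, 64)
  planted <- as.vector(outer(0:4, 0:3 * 8, "+")) + 1   # 5x4 block
  zb[, planted] <- zb[, planted] + 1
  cl <- cluster_permutation(zb, za, grid_adj, n_perm = 500, seed = 3)
  expect_gte(nrow(cl), 1)
  expect_lte(min(cl$p), 0.01)
  big <- attr(cl, "sensors")[[which.max(cl$n_sensors)]]
  expect_true(all(planted %in% big))
  expect_equal(cl$direction[which.max(cl$n_sensors)], "A>B")
})

test_that("cluster permutation validates its inputs", {
  za <- matrix(rnorm(8 * 64), 8, 64)
  expect_error(cluster_permutation(za, za + 1, grid_adj, n_perm = 100),
               "at least 500")
  bad <- grid_adj; bad[1, 2] <- !bad[1, 2]
  expect_error(cluster_permutation(za, za + 1, bad, n_perm = 500),
               "symmetric")
})

test_that("cluster statistics are equivariant under sensor relabelling", {
  set.seed(12)
  za <- matrix(rnorm(6 * 64, 0, 0.1), 6, 64)
  zb <- za + matrix(rnorm(6 * 64, 0, 0.1), 6, 64)
  zb[, 1:12] <- zb[, 1:12] + 1.5
  perm <- sample(64)
  cl1 <- cluster_permutation(zb, za, grid_adj, n_perm = 500, seed = 4)
  cl2 <- cluster_permutation(zb[, perm], za[, perm],
                             grid_adj[perm, perm], n_perm = 500, seed = 4)
  expect_equal(nrow(cl1), nrow(cl2))
  expect_equal(sort(cl1$mass), sort(cl2$mass), tolerance = 1e-10)
  s1 <- sort(attr(cl1, "sensors")[[1]])
  s2 <- sort(perm[attr(cl2, "sensors")[[1]]])
  expect_equal(s1, s2)
})

test_that("circular-shift permutation detects locked events and validates input", {
  ps <- make_phase_series(n_trials = 10, n_sens = 3)
  locked <- do.call(rbind, lapply(1:10, function(tr) {
    data.frame(trial = tr, time_ms = 3500 + (0:4) * 1000 / 6)
  }))
  out <- within_subject_permutation(locked, ps, n_perm = 200, seed = 5)
  expect_true(all(out$p <= 0.02))
  expect_error(within_subject_permutation(locked, ps, n_perm = 50),
               "at least 100")
  none <- data.frame(trial = integer(0), time_ms = numeric(0))
  expect_message(res <- within_subject_permutation(none, ps, n_perm = 200),
                 "no trial")
  expect_null(res)
})

test_that("circular-shift p values are not extreme for unlocked events", {
  set.seed(13)
  ps <- make_phase_series(n_trials = 12, n_sens = 2)
  ev <- do.call(rbind, lapply(1:12, function(tr) {
    data.frame(trial = tr, time_ms = sort(runif(6, 3100, 7900)))
  }))
  out <- within_subject_permutation(ev, ps, n_perm = 300, seed = 6)
  expect_true(all(out$p > 0.001))
})

test_that("behavior correlation flags only real, adjacent structure", {
  set.seed(14)
  z <- matrix(rnorm(8 * 64, 0, 0.05), 8, 64)
  acc <- seq(0.6, 0.95, length.out = 8)
  planted <- as.vector(outer(0:3, 0:2 * 8, "+")) + 17   # 12 adjacent sensors
  z[, planted] <- z[, planted] + outer(acc, rep(1, length(planted)))
  bc <- behavior_correlation(z, acc, grid_adj)
  expect_length(bc$clusters, 1)
  expect_true(all(planted %in% bc$clusters[[1]]))
  # perfect linear dependence -> r = 1
  z1 <- matrix(rep(acc, 64), 8, 64)
  bc1 <- behavior_correlation(z1, acc, grid_adj)
  expect_equal(max(abs(bc1$map$r - 1)), 0)
  expect_error(behavior_correlation(z, rep(0.8, 8), grid_adj), "constant")
  expect_error(behavior_correlation(z[1:2, ], acc[1:2], grid_adj),
               "3 subjects")
})

test_that("estimated PLV rises with kappa and recovers the preferred phase", {
  # measured-phase parameter recovery on planted events (single sensor chain);
  # the full kappa ladder is exercised by the acceptance suite
  kappas <- c(0, 20)
  mean_plv <- numeric(length(kappas))
  mu_hat <- NA_real_
  for (i in seq_along(kappas)) {
    p <- generator_params(
      n_subjects = 1, n_trials_per_category = 4,
      replay_rate = 1.6, coupling_kappa = kappas[i], coupling_mu = 1,
      rng_seed = 40 + i)
    gs <- generate_subject(p, 1)
    hp <- zero_phase_highpass(gs$epochs)
    ph <- instantaneous_phase(hp, 6)
    sens <- p$theta_sensors[1]
    ev <- gs$truth$events
    idx <- round(approx(ph$time_ms, seq_along(ph$time_ms),
                        xout = ev$onset_ms)$y)
    rows <- match(ev$trial, ph$info$trial)
    meas <- ph$phase[cbind(rows, sens, idx)]
    pv <- tapply(meas, ev$trial, function(x) plv(x))
    mean_plv[i] <- mean(unlist(pv), na.rm = TRUE)
    if (kappas[i] == 20) mu_hat <- circ_mean(meas)
  }
  expect_true(all(diff(mean_plv) >= 0))
  expect_lt(abs(wrap_pi(mu_hat - 1)), 0.2)
})
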