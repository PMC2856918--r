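# Theta phase coupling of reactivations: per-trial phase-locking values,
# arcsine normalization, sensor-level condition contrasts, cluster-based
# permutation control, within-subject circular-shift nulls, and
# brain-behavior correlation.

#' Phase-locking value
#'
#' Modulus of the mean unit phasor, \eqn{|\sum_n e^{i\phi_n}| / N}: 1 for
#' perfect phase alignment, near 0 for uniformly spread phases. Trials with
#' fewer than `min_events` phases carry no information about alignment
#' (a single event gives PLV 1 trivially) and yield `NA`, which the table
#' builders treat as an excluded trial.
#'
#' @param phases event phases in radians.
#' @param min_events minimum number of events for a defined PLV (default 2).
#' @return value in `[0, 1]`, or `NA` for an excluded trial.
#' @export
plv <- function(phases, min_events = 2) {
  if (length(phases) < min_events) return(NA_real_)
  Mod(mean(exp(1i * phases)))
}

#' Arcsine (variance-stabilizing) transform of a PLV
#'
#' `z = asin(2 * PLV - 1)`, strictly increasing from -pi/2 (PLV 0) through 0
#' (PLV 0.5) to pi/2 (PLV 1).
#'
#' @param plv value(s) in `[0, 1]` (`NA` passed through).
#' @return z in `[-pi/2, pi/2]`.
#' @export
arcsine_z <- function(plv) {
  bad <- !is.na(plv) & (plv < 0 | plv > 1)
  if (any(bad)) stop("PLV must lie in [0, 1]")
  asin(2 * plv - 1)
}

#' Per-trial PLV table from events and a phase series
#'
#' Looks up the instantaneous phase at each event time (nearest sample of
#' the phase series) for every sensor, and computes per-trial PLV and its
#' arcsine transform.
#'
#' @param events data frame with columns `trial`, `time_ms` (e.g. from
#'   [merge_reactivation_events()], or ground-truth event lists).
#' @param phases a `phase_series` (one theta frequency).
#' @param min_events minimum events per trial for a defined PLV.
#' @return data frame `trial`, `sensor`, `freq`, `n_events`, `plv`, `z`;
#'   excluded trials appear with `NA` plv/z.
#' @export
event_plv_table <- function(events, phases, min_events = 2) {
  stopifnot(inherits(phases, "phase_series"))
  trials <- sort(unique(events$trial))
  n_sens <- dim(phases$phase)[2]
  out <- vector("list", length(trials))
  for (k in seq_along(trials)) {
    tr <- trials[k]
    tt <- events$time_ms[events$trial == tr]
    idx <- round(stats::approx(phases$time_ms, seq_along(phases$time_ms),
                               xout = tt, rule = 2)$y)
    row <- match(tr, phases$info$trial)
    if (is.na(row)) stop("event trial not present in the phase series")
    ph <- matrix(phases$phase[row, , idx], n_sens, length(idx))
    n_ev <- length(idx)
    pv <- if (n_ev < min_events) rep(NA_real_, n_sens) else
      Mod(rowMeans(exp(1i * ph)))
    out[[k]] <- data.frame(trial = tr, sensor = seq_len(n_sens),
                           freq = phases$freq, n_events = n_ev,
                           plv = pv, z = arcsine_z(pv))
  }
  do.call(rbind, out)
}

# Subject x sensor matrix of trial-mean z values for one condition.
subject_sensor_z <- function(plv_tab) {
  ok <- !is.na(plv_tab$z)
  t <- plv_tab[ok, , drop = FALSE]
  agg <- stats::aggregate(t$z, list(subject = t$subject, sensor = t$sensor),
                          mean)
  subs <- sort(unique(agg$subject))
  n_sens <- max(agg$sensor)
  m <- matrix(NA_real_, length(subs), n_sens)
  m[cbind(match(agg$subject, subs), agg$sensor)] <- agg$x
  rownames(m) <- subs
  m
}

#' Sensor-wise paired contrast of phase locking between conditions
#'
#' Trial-mean z values are averaged within subject and sensor for each
#' condition; subjects are the paired units. Two-sided paired t test per
#' sensor.
#'
#' @param z_a,z_b subject x sensor matrices of trial-mean z (aligned rows),
#'   e.g. from [subject_sensor_z()].
#' @return data frame `sensor`, `t`, `p`, `mean_diff`.
#' @export
coupling_contrast <- function(z_a, z_b) {
  if (!all(dim(z_a) == dim(z_b))) stop("condition matrices must be aligned")
  n_sub <- nrow(z_a)
  if (n_sub < 2) stop("need at least 2 subjects")
  d <- z_a - z_b
  mu <- colMeans(d)
  sdv <- apply(d, 2, stats::sd)
  if (all(sdv == 0)) stop("zero variance of paired differences")
  tt <- mu / (sdv / sqrt(n_sub))
  data.frame(sensor = seq_len(ncol(z_a)), t = tt,
             p = 2 * stats::pt(-abs(tt), df = n_sub - 1), mean_diff = mu)
}

# t map for sign-flipped differences (rows: subjects).
tmap_from_diff <- function(d) {
  mu <- colMeans(d)
  sdv <- apply(d, 2, stats::sd)
  sdv[sdv == 0] <- Inf
  mu / (sdv / sqrt(nrow(d)))
}

# Candidate clusters at a threshold: connected sets of significant sensors
# with at least min_size members; returns list of index vectors.
find_clusters <- function(pvals, adjacency, alpha, min_size) {
  sig <- !is.na(pvals) & pvals < alpha
  if (!any(sig)) return(list())
  comps <- connected_components(sig, adjacency)
  comps[vapply(comps, length, 1L) >= min_size]
}

#' Cluster-based nonparametric permutation test over sensors
#'
#' Controls the multiple-comparisons problem of sensor-wise contrasts:
#' sensors significant at `alpha` are grouped into connected clusters under
#' the layout adjacency; candidate clusters need at least `min_size`
#' (default 8) mutually adjacent members; each cluster's mass (summed |t|)
#' is compared against the distribution of maximal cluster masses obtained
#' by flipping condition labels within subjects.
#'
#' @param z_a,z_b subject x sensor matrices of trial-mean z.
#' @param adjacency symmetric logical sensor adjacency matrix.
#' @param n_perm number of permutations (>= 500 recommended; smaller values
#'   are refused).
#' @param alpha cluster-forming threshold on the sensor-wise p value.
#' @param min_size minimum cluster extent in sensors.
#' @param seed RNG seed for the permutation draws.
#' @return object of class `cluster_result`: data frame with one row per
#'   candidate cluster (`id`, `n_sensors`, `mass`, `p`, `direction`) and a
#'   `sensors` attribute listing the member indices; zero rows when no
#'   candidate cluster exists.
#' @export
cluster_permutation <- function(z_a, z_b, adjacency, n_perm = 1000,
                                alpha = 0.05, min_size = 8, seed = 1) {
  if (n_perm < 500) stop("n_perm must be at least 500")
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency must be symmetric")
  }
  d <- z_a - z_b
  n_sub <- nrow(d)
  obs <- coupling_contrast(z_a, z_b)
  clus <- find_clusters(obs$p, adjacency, alpha, min_size)
  res <- data.frame(id = integer(0), n_sensors = integer(0),
                    mass = numeric(0), p = numeric(0),
                    direction = character(0))
  members <- list()
  if (length(clus) > 0) {
    mass_obs <- vapply(clus, function(ix) sum(abs(obs$t[ix])), 0)
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed)
    null_max <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      flip <- sample(c(-1, 1), n_sub, replace = TRUE)
      tp <- tmap_from_diff(d * flip)
      pp <- 2 * stats::pt(-abs(tp), df = n_sub - 1)
      cl <- find_clusters(pp, adjacency, alpha, min_size)
      null_max[b] <- if (length(cl) == 0) 0 else
        max(vapply(cl, function(ix) sum(abs(tp[ix])), 0))
    }
    pvals <- vapply(mass_obs, function(m) {
      (1 + sum(null_max >= m)) / (n_perm + 1)
    }, 0)
    res <- data.frame(
      id = seq_along(clus),
      n_sensors = vapply(clus, length, 1L),
      mass = mass_obs, p = pvals,
      direction = vapply(clus, function(ix) {
        if (mean(obs$t[ix]) > 0) "A>B" else "B>A"
      }, ""))
    members <- clus
  }
  structure(res, class = c("cluster_result", "data.frame"),
            sensors = members, n_perm = n_perm, alpha = alpha,
            min_size = min_size)
}

#' Within-subject circular-shift permutation test of phase locking
#'
#' Estimates, per sensor, the probability of the observed phase locking
#' under a null that preserves each trial's inter-event structure: every
#' trial's event train is circularly shifted against its phase series by an
#' independent uniform random offset, and the statistic is recomputed. The
#' statistic is the arcsine-z of the PLV over all events pooled across
#' trials: a circular shift rotates every phase within a trial by a common
#' angle, which leaves within-trial PLVs untouched when theta is
#' near-sinusoidal, so only a cross-trial consistency statistic gives the
#' shift null any power. The p value is the fraction of null statistics at
#' least as large as the observed one.
#'
#' @param events data frame `trial`, `time_ms` of reactivation events.
#' @param phases a `phase_series`.
#' @param n_perm number of shifts (>= 100; fewer is refused as unstable).
#' @param window time window (ms) within which events live and shifts wrap
#'   (default the maintenance interval 3000-8000 ms).
#' @param min_events minimum events for an included trial.
#' @param seed RNG seed.
#' @return data frame `sensor`, `z_obs`, `p`; `NULL` (with a message) when
#'   no trial has enough events.
#' @export
within_subject_permutation <- function(events, phases, n_perm = 1000,
                                       window = c(3000, 8000),
                                       min_events = 2, seed = 1) {
  stopifnot(inherits(phases, "phase_series"))
  if (n_perm < 100) stop("n_perm must be at least 100 for a stable p value")
  trials <- sort(unique(events$trial))
  keep <- trials[vapply(trials, function(tr) {
    sum(events$trial == tr) >= min_events
  }, TRUE)]
  if (length(keep) == 0) {
    message("no trial has enough events; nothing to test")
    return(NULL)
  }
  t_idx <- which(phases$time_ms >= window[1] & phases$time_ms < window[2])
  n_win <- length(t_idx)
  n_sens <- dim(phases$phase)[2]
  # per-trial event offsets within the window (sample indices)
  ev_off <- lapply(keep, function(tr) {
    tt <- events$time_ms[events$trial == tr]
    idx <- round(stats::approx(phases$time_ms[t_idx], seq_len(n_win),
                               xout = tt, rule = 2)$y)
    idx
  })
  rows <- match(keep, phases$info$trial)
  if (anyNA(rows)) stop("event trial not present in the phase series")
  pooled_z <- function(shifts) {
    acc <- matrix(0 + 0i, n_sens, 1)
    n_tot <- 0
    for (k in seq_along(keep)) {
      idx <- ((ev_off[[k]] - 1 + shifts[k]) %% n_win) + 1
      ph <- matrix(phases$phase[rows[k], , t_idx[idx]], n_sens, length(idx))
      acc <- acc + rowSums(exp(1i * ph))
      n_tot <- n_tot + length(idx)
    }
    arcsine_z(Mod(acc) / n_tot)
  }
  z_obs <- pooled_z(rep(0L, length(keep)))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  exceed <- numeric(n_sens)
  for (b in seq_len(n_perm)) {
    shifts <- sample.int(n_win, length(keep), replace = TRUE) - 1L
    exceed <- exceed + (pooled_z(shifts) >= z_obs)
  }
  data.frame(sensor = seq_len(n_sens), z_obs = as.vector(z_obs),
             p = exceed / n_perm)
}

#' Correlation between phase locking and behavioral accuracy
#'
#' Pearson correlation, per sensor, between subjects' trial-mean z values
#' and their behavioral accuracy. Sensors are flagged when `r` exceeds
#' `r_thresh` and the two-tailed p value is below `alpha`; flagged sensor
#' sets are reported only when at least `min_cluster` of them are mutually
#' adjacent.
#'
#' @param z subject x sensor matrix of trial-mean z.
#' @param accuracy per-subject behavioral accuracy (must vary).
#' @param adjacency sensor adjacency matrix.
#' @param r_thresh correlation threshold (default 0.7).
#' @param alpha two-tailed significance level.
#' @param min_cluster minimum adjacent flagged sensors for a reported set.
#' @return list: `map` (data frame `sensor`, `r`, `p`, `flagged`) and
#'   `clusters` (list of flagged sensor index sets of size >= min_cluster).
#' @export
behavior_correlation <- function(z, accuracy, adjacency, r_thresh = 0.7,
                                 alpha = 0.05, min_cluster = 8) {
  if (nrow(z) < 3) stop("need at least 3 subjects")
  if (length(accuracy) != nrow(z)) stop("one accuracy value per subject")
  if (stats::sd(accuracy) == 0) {
    stop("behavioral accuracy is constant; correlation undefined")
  }
  n_sens <- ncol(z)
  r <- numeric(n_sens); p <- numeric(n_sens)
  for (s in seq_len(n_sens)) {
    if (stats::sd(z[, s]) == 0) { r[s] <- NA; p[s] <- NA; next }
    ct <- stats::cor.test(z[, s], accuracy, method = "pearson")
    r[s] <- unname(ct$estimate); p[s] <- ct$p.value
  }
  flagged <- !is.na(r) & r > r_thresh & p < alpha
  comps <- if (any(flagged)) connected_components(flagged, adjacency) else
    list()
  comps <- comps[vapply(comps, length, 1L) >= min_cluster]
  list(map = data.frame(sensor = seq_len(n_sens), r = r, p = p,
                        flagged = flagged),
       clusters = comps)
}
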