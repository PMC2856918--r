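# Time-point-wise multivariate pattern classification: univariate feature
# selection, a small feedforward network trained by conjugate gradients,
# leave-one-out cross-validation, and single-trial maintenance testing.

# Amplitude feature matrix (trials x selected bins) at one time point.
feature_matrix <- function(tf, time_idx, sensors, freq_idx) {
  n_trials <- dim(tf$amplitude)[1]
  m <- matrix(NA_real_, n_trials, length(sensors))
  for (j in seq_along(sensors)) {
    m[, j] <- tf$amplitude[, sensors[j], freq_idx[j], time_idx]
  }
  m
}

#' Select discriminative sensor/frequency features
#'
#' Univariate feature selection at one training time point: every
#' (sensor, frequency) bin in the 13-79 Hz feature band is tested with a
#' two-tailed paired t test between categories (indoor trial i paired with
#' outdoor trial i by presentation index), and bins with `p < alpha` are
#' kept. Low-frequency bins (2-12 Hz) are never used. Selection is repeated
#' independently at every training time point.
#'
#' @param tf a baseline-normalized `tf_rep`.
#' @param time_point training time, ms (must be on the represented axis).
#' @param labels per-trial categories; default taken from `tf$info$category`.
#' @param alpha two-tailed selection level (default 0.05).
#' @param freq_band frequency band eligible for features, Hz.
#' @return object of class `feature_mask`: data frame of selected
#'   `sensor`/`freq` indices with their t statistics and p values;
#'   attributes carry the time point and alpha.
#' @export
select_features <- function(tf, time_point, labels = NULL, alpha = 0.05,
                            freq_band = c(13, 79)) {
  stopifnot(inherits(tf, "tf_rep"))
  if (alpha <= 0) stop("alpha = 0 selects no features; training refused")
  labels <- labels %||% tf$info$category
  ti <- which(abs(tf$time_ms - time_point) < 1e-6)
  if (length(ti) != 1) stop("time_point not on the represented time axis")
  fi <- which(tf$freqs >= freq_band[1] & tf$freqs <= freq_band[2])
  ii <- which(labels == "indoor")
  oi <- which(labels == "outdoor")
  n_pairs <- min(length(ii), length(oi))
  if (n_pairs < 2) stop("need at least 2 trials per category")
  ii <- ii[seq_len(n_pairs)]
  oi <- oi[seq_len(n_pairs)]
  # trials x sensors x freqs slab at the training time
  d <- dim(tf$amplitude)
  slab <- array(tf$amplitude[, , fi, ti], c(d[1], d[2], length(fi)))
  diffs <- slab[ii, , , drop = FALSE] - slab[oi, , , drop = FALSE]
  dm <- matrix(diffs, n_pairs, length(fi) * dim(slab)[2])
  mu <- colMeans(dm)
  sdv <- sqrt(pmax(colSums(dm^2) - n_pairs * mu^2, 0) / (n_pairs - 1))
  tstat <- mu / (sdv / sqrt(n_pairs))
  pval <- 2 * stats::pt(-abs(tstat), df = n_pairs - 1)
  keep <- which(pval < alpha)
  if (length(keep) == 0) stop("no features selected at alpha = ", alpha)
  sens <- ((keep - 1) %% dim(slab)[2]) + 1
  frq <- fi[((keep - 1) %/% dim(slab)[2]) + 1]
  mask <- data.frame(sensor = sens, freq_idx = frq, freq = tf$freqs[frq],
                     t = tstat[keep], p = pval[keep])
  structure(mask, class = c("feature_mask", "data.frame"),
            time_point = time_point, alpha = alpha, n_pairs = n_pairs)
}

# ---- feedforward network internals -----------------------------------------

net_unpack <- function(w, p, h, k) {
  i <- 0
  W1 <- matrix(w[i + seq_len(p * h)], p, h); i <- i + p * h
  b1 <- w[i + seq_len(h)]; i <- i + h
  W2 <- matrix(w[i + seq_len(h * k)], h, k); i <- i + h * k
  b2 <- w[i + seq_len(k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

net_forward <- function(w, X, np, h, k) {
  nt <- net_unpack(w, np, h, k)
  H <- sigmoid(sweep(X %*% nt$W1, 2, nt$b1, "+"))
  Y <- sigmoid(sweep(H %*% nt$W2, 2, nt$b2, "+"))
  list(H = H, Y = Y, nt = nt)
}

net_loss <- function(w, X, Tg, np, h, k) {
  sum((net_forward(w, X, np, h, k)$Y - Tg)^2)
}

net_grad <- function(w, X, Tg, np, h, k) {
  f <- net_forward(w, X, np, h, k)
  dY <- 2 * (f$Y - Tg) * f$Y * (1 - f$Y)
  dH <- (dY %*% t(f$nt$W2)) * f$H * (1 - f$H)
  c(as.vector(crossprod(X, dH)), colSums(dH),
    as.vector(crossprod(f$H, dY)), colSums(dY))
}

#' Train a pattern classifier at one time point
#'
#' Feedforward network with the selected features as inputs, one hidden
#' layer of 20 logistic units, and 2 logistic output units with targets
#' (1, 0) for indoor and (0, 1) for outdoor. Trained by minimizing the sum
#' of squared output errors with a conjugate-gradient method with restarts
#' (Beale-Sorenson updates via [stats::optim()]), stopped after `n_iter`
#' iterations (20, deliberately early). Inputs are the raw
#' baseline-normalized amplitudes of the selected bins.
#'
#' @param tf a baseline-normalized `tf_rep`.
#' @param mask a [select_features()] mask.
#' @param labels per-trial categories; default `tf$info$category`.
#' @param seed RNG seed for the small uniform weight initialization.
#' @param n_hidden hidden units (default 20).
#' @param n_iter conjugate-gradient iterations (default 20).
#' @return object of class `mvpc`.
#' @export
train_classifier <- function(tf, mask, labels = NULL, seed = 1,
                             n_hidden = 20, n_iter = 20) {
  stopifnot(inherits(tf, "tf_rep"), inherits(mask, "feature_mask"))
  labels <- labels %||% tf$info$category
  if (min(table(factor(labels, CATEGORIES))) < 2) {
    stop("need at least 2 exemplars per category")
  }
  tp <- attr(mask, "time_point")
  ti <- which(abs(tf$time_ms - tp) < 1e-6)
  X <- feature_matrix(tf, ti, mask$sensor, mask$freq_idx)
  # raw baseline-normalized amplitudes are fed to the network; rescaling is
  # deliberately not applied (see the centred-corner note in the vignette)
  center <- rep(0, ncol(X))
  scale <- rep(1, ncol(X))
  Tg <- cbind(as.numeric(labels == "indoor"), as.numeric(labels == "outdoor"))
  np <- ncol(X)
  n_w <- (np + 1) * n_hidden + (n_hidden + 1) * 2
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w0 <- stats::runif(n_w, -0.5, 0.5)
  opt <- stats::optim(w0, fn = net_loss, gr = net_grad,
                      X = X, Tg = Tg, np = np, h = n_hidden, k = 2,
                      method = "CG",
                      control = list(maxit = n_iter, type = 3))
  structure(list(weights = opt$par, mask = mask, center = center,
                 scale = scale, n_hidden = n_hidden, n_iter = n_iter,
                 time_point = tp, seed = seed, loss = opt$value,
                 condition = unique(tf$info$condition)),
            class = "mvpc")
}

#' @export
print.mvpc <- function(x, ...) {
  cat(sprintf(
    "<mvpc> trained at %g ms (%s): %d features -> %d hidden -> 2, SSE %.4f\n",
    x$time_point, paste(x$condition, collapse = "/"), nrow(x$mask),
    x$n_hidden, x$loss))
  invisible(x)
}

#' Classifier outputs for trials at given times
#'
#' @param object an `mvpc`.
#' @param tf a `tf_rep` containing the classifier's feature bins.
#' @param times_ms times at which to evaluate (default: the training time).
#' @param ... unused.
#' @return array `trials x 2 x times` of raw outputs in `[0, 1]`
#'   (columns: indoor, outdoor unit).
#' @export
predict.mvpc <- function(object, tf, times_ms = NULL, ...) {
  stopifnot(inherits(tf, "tf_rep"))
  times_ms <- times_ms %||% object$time_point
  miss <- setdiff(object$mask$freq_idx, seq_along(tf$freqs))
  if (length(miss) > 0 || max(object$mask$sensor) > dim(tf$amplitude)[2]) {
    stop("classifier feature mask references bins absent from the tf input")
  }
  ti <- match(round(times_ms, 6), round(tf$time_ms, 6))
  if (anyNA(ti)) stop("requested time not on the represented axis")
  n_trials <- dim(tf$amplitude)[1]
  np <- nrow(object$mask)
  # features for all requested times at once: (trial, time) x feature
  X <- matrix(NA_real_, n_trials * length(ti), np)
  for (j in seq_len(np)) {
    X[, j] <- tf$amplitude[, object$mask$sensor[j], object$mask$freq_idx[j],
                           ti]
  }
  X <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  Y <- net_forward(object$weights, X, np, object$n_hidden, 2)$Y
  out <- aperm(array(Y, c(n_trials, length(ti), 2)), c(1, 3, 2))
  dimnames(out) <- list(NULL, CATEGORIES, NULL)
  out
}

#' Leave-one-out cross-validated decoding accuracy
#'
#' For each trial in turn: re-run feature selection on the remaining trials
#' only, train the network on them, and classify the held-out trial by the
#' larger output unit. The held-out trial never influences feature selection
#' or weights. Returns the mean held-out accuracy.
#'
#' @param tf a baseline-normalized `tf_rep` for one condition.
#' @param time_point training time, ms.
#' @param labels per-trial categories; default `tf$info$category`.
#' @param alpha feature-selection level.
#' @param seed base RNG seed (one derived seed per fold).
#' @param n_hidden,n_iter network size and training length.
#' @return accuracy in `[0, 1]`.
#' @export
loocv_accuracy <- function(tf, time_point, labels = NULL, alpha = 0.05,
                           seed = 1, n_hidden = 20, n_iter = 20) {
  stopifnot(inherits(tf, "tf_rep"))
  labels <- labels %||% tf$info$category
  n <- length(labels)
  if (n < 4) stop("need at least 4 trials for LOOCV")
  if (min(table(factor(labels, CATEGORIES))) < 2) {
    stop("degenerate fold: need both categories represented")
  }
  # restrict to the training time point once; folds then copy one slab only
  ti <- which(abs(tf$time_ms - time_point) < 1e-6)
  if (length(ti) != 1) stop("time_point not on the represented time axis")
  tf1 <- tf
  tf1$amplitude <- tf$amplitude[, , , ti, drop = FALSE]
  tf1$time_ms <- time_point
  correct <- logical(n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    tf_tr <- tf1
    tf_tr$amplitude <- tf1$amplitude[keep, , , , drop = FALSE]
    tf_tr$info <- tf1$info[keep, , drop = FALSE]
    mask <- select_features(tf_tr, time_point, labels[keep], alpha)
    clf <- train_classifier(tf_tr, mask, labels[keep],
                            seed = derive_seed(seed, 7, i),
                            n_hidden = n_hidden, n_iter = n_iter)
    tf_te <- tf1
    tf_te$amplitude <- tf1$amplitude[i, , , , drop = FALSE]
    tf_te$info <- tf1$info[i, , drop = FALSE]
    y <- predict(clf, tf_te)[1, , 1]
    correct[i] <- CATEGORIES[which.max(y)] == labels[i]
  }
  mean(correct)
}

#' Default maintenance test grid
#'
#' 250 evenly spaced time points spanning the maintenance interval after
#' excluding its first and last 250 ms (3250-7750 ms, about 18 ms spacing),
#' snapped to the represented time axis.
#'
#' @param time_ms represented time axis.
#' @param n number of test points.
#' @param window maintenance sub-window, ms.
#' @return vector of test times on the axis.
#' @export
maintenance_test_points <- function(time_ms, n = 250,
                                    window = c(3250, 7750)) {
  raw <- seq(window[1], window[2], length.out = n)
  idx <- round(stats::approx(time_ms, seq_along(time_ms), xout = raw,
                             rule = 2)$y)
  time_ms[idx]
}

# The output-threshold decision rule: a trial is correct at a time point iff
# the output unit matching its true category exceeds the threshold; outputs
# exceeding it on both units are ambiguous and not counted correct.
threshold_correct <- function(out_indoor, out_outdoor, category,
                              threshold = 0.95) {
  own <- ifelse(category == "indoor", out_indoor, out_outdoor)
  other <- ifelse(category == "indoor", out_outdoor, out_indoor)
  ambiguous <- own > threshold & other > threshold
  list(correct = as.integer(own > threshold & !ambiguous),
       ambiguous = ambiguous)
}

#' Classify maintenance-period activity trial by trial
#'
#' Applies a trained classifier at each test time point of the maintenance
#' interval and applies the 0.95 output threshold: a trial is counted
#' correct at a time point iff the output unit matching its true category
#' exceeds 0.95 (trials where both outputs exceed 0.95 are flagged
#' `ambiguous` and not counted correct).
#'
#' @param clf an `mvpc`.
#' @param tf a baseline-normalized `tf_rep` of the tested condition.
#' @param test_points test times, ms; default [maintenance_test_points()]
#'   on `tf$time_ms`.
#' @param labels true categories; default `tf$info$category`.
#' @param threshold output threshold (default 0.95).
#' @return data frame with one row per trial x time point: `trial`,
#'   `time_ms`, `out_indoor`, `out_outdoor`, `correct` (0/1), `ambiguous`.
#' @export
classify_maintenance <- function(clf, tf, test_points = NULL, labels = NULL,
                                 threshold = 0.95) {
  stopifnot(inherits(clf, "mvpc"), inherits(tf, "tf_rep"))
  labels <- labels %||% tf$info$category
  test_points <- test_points %||% maintenance_test_points(tf$time_ms)
  y <- predict(clf, tf, times_ms = test_points)
  n_trials <- dim(y)[1]
  n_t <- length(test_points)
  own <- ifelse(labels == "indoor", 1L, 2L)
  own_out <- matrix(NA_real_, n_trials, n_t)
  other_out <- matrix(NA_real_, n_trials, n_t)
  for (i in seq_len(n_trials)) {
    own_out[i, ] <- y[i, own[i], ]
    other_out[i, ] <- y[i, 3L - own[i], ]
  }
  amb <- own_out > threshold & other_out > threshold
  corr <- own_out > threshold & !amb
  data.frame(
    trial = rep(tf$info$trial, times = n_t),
    time_ms = rep(test_points, each = n_trials),
    out_indoor = as.vector(matrix(y[, 1, ], n_trials, n_t)),
    out_outdoor = as.vector(matrix(y[, 2, ], n_trials, n_t)),
    correct = as.integer(as.vector(corr)),
    ambiguous = as.vector(amb),
    category = rep(labels, times = n_t),
    clf_time = clf$time_point
  )
}
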