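# Reactivation statistics: binomial significance of correct-trial counts,
# Bonferroni-corrected detection of reactivation times, counting, and
# condition contrasts.

#' Binomial test specification for reactivation detection
#'
#' @param n trials per category (default 20).
#' @param r chance probability of a correct output (default 0.5).
#' @param n_time_points,n_classifiers the multiple-comparison family:
#'   maintenance test points times classifiers (default 250 x 11).
#' @param family_alpha family-wise level (default 0.05).
#' @return object of class `binomial_test_spec`; `corrected_alpha` is
#'   `family_alpha / (n_time_points * n_classifiers)`.
#' @export
binomial_test_spec <- function(n = 20, r = 0.5, n_time_points = 250,
                               n_classifiers = 11, family_alpha = 0.05) {
  if (!(r > 0 && r < 1)) stop("chance probability must lie in (0, 1)")
  if (n < 1) stop("n must be positive")
  fam <- n_time_points * n_classifiers
  if (fam < 1) stop("family size must be positive")
  structure(list(n = n, r = r, n_time_points = n_time_points,
                 n_classifiers = n_classifiers, family_alpha = family_alpha,
                 family_size = fam,
                 corrected_alpha = family_alpha / fam),
            class = "binomial_test_spec")
}

#' Bonferroni-corrected per-comparison threshold
#'
#' `family_alpha / (n_time_points * n_classifiers)`; with the defaults,
#' 0.05 / (250 x 11) = 1.8e-5.
#'
#' @param spec a [binomial_test_spec()].
#' @return the corrected per-test alpha.
#' @export
corrected_threshold <- function(spec = binomial_test_spec()) {
  stopifnot(inherits(spec, "binomial_test_spec"))
  spec$corrected_alpha
}

#' One-tailed binomial p value for a correct-trial count
#'
#' Upper-tail probability of observing at least `C` correct of `n` trials at
#' chance `r`. The working method is the normal approximation to the
#' binomial (no continuity correction); `method = "exact"` gives the exact
#' binomial tail used as the referee in tests.
#'
#' @param C observed number of correct trials, `0 <= C <= n`.
#' @param spec a [binomial_test_spec()].
#' @param method `"normal"` (default) or `"exact"`.
#' @return the one-tailed p value.
#' @export
binomial_pvalue <- function(C, spec = binomial_test_spec(),
                            method = c("normal", "exact")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "binomial_test_spec"))
  if (any(C < 0 | C > spec$n)) stop("C must lie in [0, n]")
  if (method == "normal") {
    z <- (C - spec$n * spec$r) / sqrt(spec$n * spec$r * (1 - spec$r))
    stats::pnorm(z, lower.tail = FALSE)
  } else {
    stats::pbinom(C - 1, spec$n, spec$r, lower.tail = FALSE)
  }
}

#' Smallest significant correct-trial count
#'
#' The minimal `C` whose one-tailed p value falls below the corrected
#' threshold (20 of 20 under the reference design, by both the exact
#' binomial and the normal approximation).
#'
#' @param spec a [binomial_test_spec()].
#' @param method p-value method passed to [binomial_pvalue()].
#' @return integer count, or `NA` if no count passes.
#' @export
min_significant_count <- function(spec = binomial_test_spec(),
                                  method = "normal") {
  p <- binomial_pvalue(0:spec$n, spec, method = method)
  hit <- which(p < spec$corrected_alpha)
  if (length(hit) == 0) return(NA_integer_)
  hit[1] - 1L
}

#' Detect reactivation time points
#'
#' Groups thresholded classifier output records by subject, trained/tested
#' condition, category, classifier and test time, counts correct trials,
#' and declares a reactivation time wherever the count's one-tailed
#' normal-approximation p value falls below the corrected threshold.
#'
#' @param records row-bound [classify_maintenance()] outputs, with columns
#'   `subject`, `cond_train`, `cond_test`, `category`, `clf_time`, `trial`,
#'   `time_ms`, `correct`.
#' @param spec a [binomial_test_spec()]; its `n` must equal the trial count
#'   per group.
#' @return object of class `reactivation_set`: `times` (one row per
#'   reactivation time with count and p value) and `events` (one row per
#'   correct trial at each reactivation time).
#' @export
detect_reactivations <- function(records, spec = binomial_test_spec()) {
  need <- c("subject", "cond_train", "cond_test", "category", "clf_time",
            "trial", "time_ms", "correct")
  if (!all(need %in% names(records))) {
    stop("records must contain columns: ", paste(need, collapse = ", "))
  }
  key <- interaction(records$subject, records$cond_train, records$cond_test,
                     records$category, records$clf_time, records$time_ms,
                     drop = TRUE)
  cnt <- tapply(records$correct, key, sum)
  ntr <- tapply(records$correct, key, length)
  if (length(unique(ntr)) > 1) {
    stop("inconsistent trial counts across time points")
  }
  if (unique(ntr) != spec$n) {
    stop(sprintf("records have %d trials per group but spec$n = %d",
                 unique(ntr), spec$n))
  }
  first <- !duplicated(key)
  meta <- records[first, c("subject", "cond_train", "cond_test", "category",
                           "clf_time", "time_ms")]
  meta <- meta[match(names(cnt), key[first]), ]
  p <- binomial_pvalue(as.integer(cnt), spec)
  hit <- p < spec$corrected_alpha
  times <- cbind(meta[hit, , drop = FALSE],
                 data.frame(C = as.integer(cnt)[hit], p = p[hit]))
  rownames(times) <- NULL
  ev_key <- key %in% names(cnt)[hit] & records$correct == 1
  events <- records[ev_key, c("subject", "cond_train", "cond_test",
                              "category", "clf_time", "trial", "time_ms")]
  rownames(events) <- NULL
  structure(list(times = times, events = events, spec = spec),
            class = "reactivation_set")
}

#' @export
print.reactivation_set <- function(x, ...) {
  cat(sprintf("<reactivation_set> %d reactivation times, %d trial events\n",
              nrow(x$times), nrow(x$events)))
  invisible(x)
}

#' Count reactivations per group
#'
#' Totals of significant reactivation time points, aggregated over the
#' requested grouping columns. Totals collapse consistently: summing a
#' finer table over the extra columns reproduces the coarser one.
#'
#' @param rs a [detect_reactivations()] result.
#' @param by grouping columns of `rs$times`.
#' @param clf_range only classifiers trained within this window (ms) are
#'   counted; default 44-764 ms (the post-onset classifiers).
#' @return data frame of group keys plus `count`.
#' @export
count_reactivations <- function(rs, by = c("subject", "cond_train",
                                           "cond_test", "category"),
                                clf_range = c(44, 764)) {
  stopifnot(inherits(rs, "reactivation_set"))
  t <- rs$times
  t <- t[t$clf_time >= clf_range[1] & t$clf_time <= clf_range[2], ,
         drop = FALSE]
  if (nrow(t) == 0) {
    out <- stats::setNames(
      data.frame(matrix(character(0), 0, length(by)), count = integer(0)),
      c(by, "count"))
    return(out)
  }
  agg <- stats::aggregate(t$time_ms, t[by], FUN = length)
  names(agg)[ncol(agg)] <- "count"
  agg
}

#' Merge reactivation events across classifiers
#'
#' Builds the per-trial event list used by the phase-coupling stage: the
#' union over classifiers trained 44-764 ms of each trial's correct-output
#' reactivation events, with duplicate (trial, time) detections from
#' different classifiers collapsed to a single event.
#'
#' @param rs a [detect_reactivations()] result.
#' @param clf_range classifier training window, ms.
#' @param within_condition keep only events where the tested condition
#'   equals the training condition (default `TRUE`).
#' @return data frame `subject`, `cond_test`, `category`, `trial`,
#'   `time_ms`, one row per distinct event.
#' @export
merge_reactivation_events <- function(rs, clf_range = c(44, 764),
                                      within_condition = TRUE) {
  stopifnot(inherits(rs, "reactivation_set"))
  e <- rs$events
  e <- e[e$clf_time >= clf_range[1] & e$clf_time <= clf_range[2], ,
         drop = FALSE]
  if (within_condition) e <- e[e$cond_train == e$cond_test, , drop = FALSE]
  e <- e[, c("subject", "cond_test", "category", "trial", "time_ms")]
  e <- unique(e)
  e <- e[order(e$subject, e$cond_test, e$trial, e$time_ms), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Paired one-tailed comparison of per-subject reactivation counts
#'
#' @param x,y per-subject totals for the two sides of the contrast
#'   (`x` hypothesized larger), aligned by subject.
#' @return list with `t`, `df`, `p` (one-tailed, `x > y`), and the mean
#'   difference.
#' @export
compare_counts <- function(x, y) {
  if (length(x) != length(y)) stop("count vectors must be aligned by subject")
  if (length(x) < 2) stop("need at least 2 subjects")
  d <- x - y
  if (stats::sd(d) == 0) {
    stop("zero variance of paired differences; t test undefined")
  }
  ht <- stats::t.test(x, y, paired = TRUE, alternative = "greater")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d))
}
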