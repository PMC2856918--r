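# The epoch container: trials x sensors x time with metadata.

#' Construct an epoch set
#'
#' The basic data container of the package: a `trials x sensors x time` signal
#' array with a millisecond time axis (relative to sample onset), per-trial
#' metadata, and a sensor layout.
#'
#' @param signal numeric array `trials x sensors x time`.
#' @param time_ms strictly increasing, uniformly spaced time axis in ms.
#' @param sfreq sampling rate in Hz; must match the time-axis spacing.
#' @param info data frame with one row per trial; must contain columns
#'   `trial`, `category`, `condition`, `subject`.
#' @param layout sensor layout data frame (`sensor`, `x`, `y`) with
#'   `n_sensors` rows.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(signal, time_ms, sfreq, info, layout) {
  stopifnot(is.array(signal), length(dim(signal)) == 3)
  n_trials <- dim(signal)[1]
  n_sensors <- dim(signal)[2]
  n_time <- dim(signal)[3]
  if (length(time_ms) != n_time) stop("time axis length does not match signal")
  dt <- diff(time_ms)
  if (any(dt <= 0)) stop("time axis must be strictly increasing")
  if (max(abs(dt - 1000 / sfreq)) > 1e-6) {
    stop("time axis spacing does not match the sampling rate")
  }
  need <- c("trial", "category", "condition", "subject")
  if (!all(need %in% names(info))) {
    stop("info must contain columns: ", paste(need, collapse = ", "))
  }
  if (nrow(info) != n_trials) stop("metadata length must equal trial count")
  if (nrow(layout) != n_sensors) stop("layout rows must equal sensor count")
  if (anyDuplicated(layout$sensor)) stop("duplicate sensor ids in layout")
  structure(
    list(signal = signal, time_ms = as.numeric(time_ms), sfreq = sfreq,
         info = info, layout = layout),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<epoch_set> %d trials x %d sensors x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sfreq))
  cat(sprintf("  time %g .. %g ms; conditions: %s\n",
              x$time_ms[1], x$time_ms[length(x$time_ms)],
              paste(unique(x$info$condition), collapse = ", ")))
  invisible(x)
}

# Subset an epoch set by trial index, keeping metadata in step.
subset_epochs <- function(epochs, trials) {
  epochs$signal <- epochs$signal[trials, , , drop = FALSE]
  epochs$info <- epochs$info[trials, , drop = FALSE]
  epochs$info$trial <- epochs$info$trial
  rownames(epochs$info) <- NULL
  epochs
}
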