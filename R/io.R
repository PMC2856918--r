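# Persistence: chunked binary epoch container with JSON sidecar, sensor
# layout as tab-separated text, pipeline configuration as YAML.

#' Write an epoch set to disk
#'
#' Stores the signal as one little-endian float64 chunk per trial
#' (`trial_0001.bin`, sensor-major), with a `meta.json` sidecar carrying the
#' time axis, sampling rate and trial metadata, and the sensor layout as
#' tab-separated text (`layout.tsv`: sensor id, x, y). Lossless round trip
#' with [read_epochs()].
#'
#' @param epochs an [epoch_set()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$signal)
  meta <- list(
    format = "thetareplay-epochs", version = 1L,
    n_trials = d[1], n_sensors = d[2], n_time = d[3],
    sfreq = epochs$sfreq,
    time_start_ms = epochs$time_ms[1],
    info = epochs$info,
    chunks = sprintf("trial_%04d.bin", seq_len(d[1]))
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  utils::write.table(epochs$layout, file.path(path, "layout.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (i in seq_len(d[1])) {
    con <- file(file.path(path, meta$chunks[i]), "wb")
    writeBin(as.vector(epochs$signal[i, , ]), con, size = 8,
             endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read an epoch set from disk
#'
#' @param path directory written by [write_epochs()].
#' @return an [epoch_set()].
#' @export
read_epochs <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stop("missing field/file: meta.json")
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  need <- c("n_trials", "n_sensors", "n_time", "sfreq", "time_start_ms",
            "info", "chunks")
  miss <- setdiff(need, names(meta))
  if (length(miss) > 0) {
    stop("epoch container schema mismatch; missing field: ",
         paste(miss, collapse = ", "))
  }
  lf <- file.path(path, "layout.tsv")
  if (!file.exists(lf)) stop("missing field/file: layout.tsv")
  layout <- utils::read.table(lf, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  if (anyDuplicated(layout$sensor)) stop("duplicate sensor ids in layout")
  d <- c(meta$n_trials, meta$n_sensors, meta$n_time)
  signal <- array(NA_real_, d)
  for (i in seq_len(d[1])) {
    f <- file.path(path, meta$chunks[i])
    if (!file.exists(f) || file.info(f)$size != d[2] * d[3] * 8) {
      stop("truncated or missing chunk: ", meta$chunks[i])
    }
    con <- file(f, "rb")
    signal[i, , ] <- matrix(readBin(con, "double", d[2] * d[3], size = 8,
                                    endian = "little"), d[2], d[3])
    close(con)
  }
  time_ms <- meta$time_start_ms + (seq_len(d[3]) - 1) * 1000 / meta$sfreq
  info <- as.data.frame(meta$info, stringsAsFactors = FALSE)
  epoch_set(signal, time_ms, meta$sfreq, info, layout)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config a [pipeline_config()] object.
#' @return `read_pipeline_config` returns a validated [pipeline_config()];
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- unclass(config)
  plain$generator <- lapply(unclass(plain$generator), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}
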