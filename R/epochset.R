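#' Construct an epoch set
#'
#' An `epoch_set` holds segmented single-trial EEG voltages on a
#' trial x channel x time grid together with the per-trial covariates the
#' regression designs are built from.
#'
#' @param data numeric array `[trial, channel, time]`, voltages in microvolts.
#' @param channels character vector of unique channel names, one per second
#'   array dimension.
#' @param times numeric vector of sample times in ms relative to the locking
#'   event; must be strictly increasing and uniformly spaced at `1000/fs`.
#' @param fs sampling rate in Hz.
#' @param trial_table data.frame of per-trial covariates, rows aligned with
#'   the trial axis of `data`.
#' @param subject subject identifier (scalar).
#' @param task task label (scalar), e.g. `"gonogo"`.
#' @param log character vector of applied-operation records (provenance).
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, channels, times, fs, trial_table,
                      subject = NA_character_, task = NA_character_,
                      log = character()) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array [trial, channel, time]")
  if (dim(data)[2] != length(channels))
    stop("channel axis length ", dim(data)[2], " does not match ",
         length(channels), " channel names")
  if (dim(data)[3] != length(times))
    stop("time axis length ", dim(data)[3], " does not match ",
         length(times), " time points")
  if (anyDuplicated(channels))
    stop("channel names must be unique")
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("`times` must be strictly increasing")
    if (max(abs(dt - 1000 / fs)) > 1e-6)
      stop("`times` must be uniformly spaced at 1000/fs ms")
  }
  if (!is.data.frame(trial_table))
    stop("`trial_table` must be a data.frame")
  if (nrow(trial_table) != dim(data)[1])
    stop("trial_table has ", nrow(trial_table), " rows but data has ",
         dim(data)[1], " trials")
  structure(
    list(data = data, channels = as.character(channels),
         times = as.numeric(times), fs = fs,
         trial_table = trial_table,
         subject = subject, task = task, log = log),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> subject:", x$subject, " task:", x$task, "\n")
  cat("  ", d[1], "trials x", d[2], "channels x", d[3], "samples @",
      x$fs, "Hz  [", min(x$times), ",", max(x$times), "] ms\n")
  if (length(x$log)) cat("  ops:", paste(x$log, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.epoch_set <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]

log_op <- function(x, msg) {
  x$log <- c(x$log, msg)
  x
}

#' Write an epoch bundle to disk
#'
#' The bundle is a directory holding a JSON manifest (sampling rate, channel
#' names, time axis, subject, task, operations log), the voltage array as
#' little-endian float32 in trial-fastest column order, and the trial table
#' as TSV. The layout is plain-text-plus-raw-floats so bundles diff cleanly
#' and can be read from any language.
#'
#' @param epochs an [epoch_set].
#' @param path directory to create (must not be an existing non-bundle file).
#' @return `path`, invisibly.
#' @seealso [read_bundle()]
#' @export
write_bundle <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "sterp-epoch-bundle-v1",
    dims = dim(epochs$data),
    channels = epochs$channels,
    times = epochs$times,
    fs = epochs$fs,
    subject = epochs$subject,
    task = epochs$task,
    log = epochs$log)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 4L, endian = "little")
  utils::write.table(epochs$trial_table, file.path(path, "trial_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an epoch bundle from disk
#'
#' @param path bundle directory written by [write_bundle()].
#' @return An [epoch_set]. Voltages come back as float32-quantized values;
#'   a round trip is lossless at float32 precision.
#' @export
read_bundle <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  dims <- as.integer(manifest$dims)
  nval <- prod(dims)
  binf <- file.path(path, "data.bin")
  if (file.info(binf)$size != 4L * nval)
    stop("data.bin holds ", file.info(binf)$size / 4, " float32 values, ",
         "manifest dims ", paste(dims, collapse = "x"), " require ", nval)
  con <- file(binf, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = nval, size = 4L, endian = "little")
  tt <- utils::read.delim(file.path(path, "trial_table.tsv"),
                          stringsAsFactors = FALSE)
  if (nrow(tt) != dims[1])
    stop("trial_table has ", nrow(tt), " rows but manifest declares ",
         dims[1], " trials")
  epoch_set(array(vals, dim = dims), manifest$channels, manifest$times,
            manifest$fs, tt, subject = manifest$subject, task = manifest$task,
            log = as.character(unlist(manifest$log)))
}
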