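#' Multichannel recording container
#'
#' Bundles a continuous multichannel time-series with its sampling rate,
#' channel layout and per-trial event markers. Samples are stored
#' time-by-channel (one column per channel) so single-channel derivations
#' are contiguous in memory.
#'
#' @param samples Numeric matrix, time points in rows, one column per
#'   channel. Column names are taken as channel names if `channel_names`
#'   is missing.
#' @param fs Sampling rate in Hz.
#' @param channel_names Character vector of channel labels.
#' @param neighbour_map Named list mapping a channel label to the labels of
#'   its spatial neighbours (four for a Hjorth Laplacian derivation).
#' @param events Tibble with columns `type` (e.g. `target_on`,
#'   `move_init`, `move_end`), `time_s` and `trial_index`.
#' @param ground_truth Optional tibble of per-trial generative ground truth
#'   (present on simulated recordings).
#'
#' @return An object of class `bd_recording`.
#' @export
new_recording <- function(samples, fs, channel_names = colnames(samples),
                          neighbour_map = list(), events = NULL,
                          ground_truth = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) abort("`samples` must be a numeric matrix.")
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(ncol(samples)))
  }
  if (length(channel_names) != ncol(samples)) {
    abort("`channel_names` must name every column of `samples`.")
  }
  colnames(samples) <- channel_names
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number.")
  }
  missing_nb <- setdiff(unlist(neighbour_map), channel_names)
  if (length(missing_nb)) {
    abort(paste0("neighbour_map references absent channel(s): ",
                 paste(missing_nb, collapse = ", ")))
  }
  if (is.null(events)) {
    events <- tibble(type = character(), time_s = numeric(),
                     trial_index = integer())
  }
  events <- as_tibble(events)
  t_max <- (nrow(samples) - 1) / fs
  if (nrow(events) && any(events$time_s < 0 | events$time_s > t_max)) {
    abort("event timestamps fall outside the record.")
  }
  structure(
    list(samples = samples, fs = fs, channel_names = channel_names,
         neighbour_map = neighbour_map, events = events,
         ground_truth = ground_truth),
    class = "bd_recording"
  )
}

#' @export
print.bd_recording <- function(x, ...) {
  cat(sprintf("<bd_recording> %d channels x %.1f s @ %g Hz (%d events)\n",
              ncol(x$samples), nrow(x$samples) / x$fs, x$fs, nrow(x$events)))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a recording as CSV plus JSON sidecar
#'
#' The sample matrix goes to `<path>.csv` (one column per channel); sampling
#' rate, channel names, neighbour map and the event table go to
#' `<path>.json`.
#'
#' @param rec A [new_recording()] object.
#' @param path Output stem (without extension).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns a `bd_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "bd_recording"))
  data.table::fwrite(as.data.frame(rec$samples), paste0(path, ".csv"))
  meta <- list(fs = rec$fs, channel_names = rec$channel_names,
               neighbour_map = rec$neighbour_map,
               events = rec$events)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  samples <- as.matrix(data.table::fread(paste0(path, ".csv")))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_recording(samples, fs = meta$fs, channel_names = meta$channel_names,
                neighbour_map = as.list(meta$neighbour_map),
                events = as_tibble(meta$events))
}
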