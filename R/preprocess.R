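#' Hjorth approximation of the surface Laplacian
#'
#' Spatial high-pass derivation: the centre electrode minus the mean of its
#' four nearest neighbours, sample-wise. Emphasises local (e.g. motor
#' cortical) sources over volume-conducted activity.
#'
#' @param rec A [new_recording()] object whose `neighbour_map` lists exactly
#'   four neighbours for `centre`.
#' @param centre Channel label to derive (e.g. `"C3"`).
#' @return Numeric vector, one sample per time point of `rec`.
#' @export
hjorth_laplacian <- function(rec, centre) {
  stopifnot(inherits(rec, "bd_recording"))
  if (!centre %in% rec$channel_names) {
    abort(paste0("centre channel '", centre, "' is not in the recording."))
  }
  nb <- rec$neighbour_map[[centre]]
  if (is.null(nb) || length(nb) != 4L) {
    abort(paste0("'", centre, "' must map to exactly 4 neighbours."))
  }
  missing_nb <- setdiff(nb, rec$channel_names)
  if (length(missing_nb)) {
    abort(paste0("missing neighbour channel(s): ",
                 paste(missing_nb, collapse = ", ")))
  }
  rec$samples[, centre] - rowMeans(rec$samples[, nb, drop = FALSE])
}

#' Bipolar re-reference
#'
#' Difference of two channels (`a - b`), cancelling any additive artifact
#' common to both — the derivation used for depth-probe LFP, referencing a
#' working site against a site at the opposite end of the probe.
#'
#' @inheritParams hjorth_laplacian
#' @param ch_a,ch_b Channel labels; must differ.
#' @return Numeric vector of `a - b` samples.
#' @export
bipolar_rereference <- function(rec, ch_a, ch_b) {
  stopifnot(inherits(rec, "bd_recording"))
  if (identical(ch_a, ch_b)) abort("`ch_a` and `ch_b` must be different channels.")
  missing_ch <- setdiff(c(ch_a, ch_b), rec$channel_names)
  if (length(missing_ch)) {
    abort(paste0("missing channel(s): ", paste(missing_ch, collapse = ", ")))
  }
  rec$samples[, ch_a] - rec$samples[, ch_b]
}

# Steady-state initial conditions for an IIR filter (the classic
# companion-matrix construction), so a step input produces no transient.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  rhs <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(comp), rhs)
}

# Zero-phase (forward-backward) IIR filtering with odd-reflection padding
# and steady-state initial conditions scaled to the first/last sample.
filtfilt_fb <- function(b, a, x) {
  n <- length(x)
  nfilt <- max(length(a), length(b))
  padlen <- min(n - 1, max(3 * (nfilt - 1), 96))
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- .iir_filter(b, a, ext, zi * ext[1])
  y <- rev(.iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Filter chain: 30 Hz low-pass, resample to 500 Hz, 10 Hz high-pass
#'
#' Applies the band-limiting chain used before time-frequency
#' decomposition: a zero-phase 4th-order Butterworth low-pass at 30 Hz at
#' the native rate (doubling as the anti-alias filter), resampling to
#' 500 Hz (integer decimation when the ratio is integral, polyphase
#' resampling otherwise), then a zero-phase 4th-order Butterworth
#' high-pass at 10 Hz. Zero-phase application preserves event alignment;
#' the effective order is doubled.
#'
#' @param x Numeric series at `fs_in`.
#' @param fs_in Input sampling rate in Hz; must be at least 1000.
#' @return List with `series` (numeric, length `round(length(x) * 500 /
#'   fs_in)`) and `fs` (500).
#' @export
filter_chain <- function(x, fs_in) {
  if (!is.numeric(x) || !length(x)) abort("`x` must be a non-empty numeric series.")
  if (fs_in < 1000) abort("`fs_in` must be at least 1000 Hz.")
  fs_out <- 500
  lp <- signal::butter(4, 30 / (fs_in / 2), type = "low")
  y <- filtfilt_fb(lp$b, lp$a, x)
  n_out <- round(length(x) * fs_out / fs_in)
  if (fs_in %% fs_out == 0) {
    k <- fs_in %/% fs_out
    y <- y[seq(1, length(y), by = k)]
  } else {
    y <- signal::resample(y, p = fs_out, q = fs_in)
  }
  length(y) <- n_out
  if (anyNA(y)) y[is.na(y)] <- 0
  hp <- signal::butter(4, 10 / (fs_out / 2), type = "high")
  y <- filtfilt_fb(hp$b, hp$a, y)
  list(series = y, fs = fs_out)
}

#' Extract 2 s event-locked trial windows
#'
#' Cuts one fixed-length window per movement-initiation event, centred on
#' the event. Events too close to the record edges (closer than the window
#' half-width plus the edge-exclusion margin, inside which filter edge
#' effects live) are skipped, not fatal; the skips are recorded in the
#' `skipped` attribute.
#'
#' @param x Numeric series.
#' @param fs Sampling rate of `x` in Hz.
#' @param events Numeric vector of event times in seconds, or an event
#'   tibble as held by [new_recording()] (rows with `type == "move_init"`
#'   are used).
#' @param halfwidth_s Window half-width in seconds (default 1, i.e. 2 s
#'   windows).
#' @param edge_exclude_s Margin at each record edge excluded from analysis
#'   (default 0.25 s).
#' @return Tibble with `trial_index`, `time_s`, `start_sample` (1-based
#'   index of the first window sample), `t0_index` (1-based index of the
#'   event sample within the window) and a `samples` list-column, each of
#'   length `2 * halfwidth_s * fs`. Attribute `skipped` is a tibble of
#'   skipped events with reasons.
#' @export
extract_windows <- function(x, fs, events, halfwidth_s = 1,
                            edge_exclude_s = 0.25) {
  if (is.data.frame(events)) {
    ev <- dplyr::filter(events, .data$type == "move_init")
    times <- ev$time_s
    idx <- ev$trial_index
  } else {
    times <- as.numeric(events)
    idx <- seq_along(times)
  }
  hw <- round(halfwidth_s * fs)
  n <- length(x)
  centre <- round(times * fs)            # 0-based sample of the event
  start <- centre - hw + 1               # 1-based first sample
  end <- centre + hw
  lo <- floor(edge_exclude_s * fs)
  ok <- start > lo & end <= n - lo
  skipped <- tibble(trial_index = idx[!ok], time_s = times[!ok],
                    reason = ifelse(start[!ok] <= lo,
                                    "insufficient pre-event margin",
                                    "insufficient post-event margin"))
  out <- tibble(
    trial_index = idx[ok],
    time_s = times[ok],
    start_sample = start[ok],
    t0_index = hw + 1L,
    samples = lapply(which(ok), function(i) x[start[i]:end[i]])
  )
  attr(out, "skipped") <- skipped
  attr(out, "fs") <- fs
  attr(out, "halfwidth_s") <- halfwidth_s
  out
}

#' Z-score a trial window
#'
#' Normalises a window by its own mean and standard deviation, so every
#' trial enters the time-frequency decomposition on a common scale.
#'
#' @param x Numeric window.
#' @return Numeric window with mean 0 and SD 1.
#' @export
zscore_window <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("zero-variance window cannot be z-scored.")
  (x - mean(x)) / s
}

#' @rdname zscore_window
#' @param windows A window tibble from [extract_windows()].
#' @return `zscore_windows()`: the same tibble with each `samples` entry
#'   normalised.
#' @export
zscore_windows <- function(windows) {
  windows$samples <- lapply(windows$samples, zscore_window)
  windows
}
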