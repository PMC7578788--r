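# Morlet scale for an analysis frequency under the omega0 convention:
# the Fourier factor maps scale to the wavelet's peak frequency.
morlet_scale <- function(freq_hz, omega0 = 6) {
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freq_hz)
}

#' Morlet wavelet transform
#'
#' Continuous wavelet transform with a complex Morlet wavelet of
#' nondimensional frequency `omega0 = 6`, unit-energy normalised, computed
#' by frequency-domain multiplication (the signal is zero-padded past the
#' wavelet support, so the result equals a linear, non-circular
#' convolution). An e-folding cone-of-influence mask marks
#' boundary-contaminated coefficients at each scale.
#'
#' @param x Numeric window (typically z-scored, see [zscore_window()]).
#' @param fs Sampling rate in Hz.
#' @param freqs Analysis frequencies in Hz, strictly increasing, below the
#'   Nyquist frequency. Default: 15-25 Hz in 1 Hz steps, the beta band.
#' @param omega0 Morlet nondimensional frequency (default 6).
#' @return List of class `bd_cwt`: `coefs` (complex, freqs x times), `coi`
#'   (logical, `TRUE` where the coefficient lies inside the
#'   cone of influence, i.e. is boundary-contaminated), `freqs`, `fs`.
#' @export
morlet_transform <- function(x, fs, freqs = 15:25, omega0 = 6) {
  if (!is.numeric(x) || length(x) < 8) abort("`x` must be a numeric series.")
  if (is.unsorted(freqs, strictly = TRUE)) abort("`freqs` must be strictly increasing.")
  if (max(freqs) >= fs / 2) abort("analysis frequencies must lie below Nyquist.")
  if (min(freqs) <= 0) abort("analysis frequencies must be positive.")
  n <- length(x)
  scales <- morlet_scale(freqs, omega0)
  support <- ceiling(5 * sqrt(2) * max(scales) * fs)
  m <- stats::nextn(n + 2 * support, c(2, 3, 5))
  xf <- fft(c(x, rep(0, m - n)))
  omega_k <- 2 * pi * fs * c(0:floor(m / 2), -(ceiling(m / 2) - 1):-1) / m
  coefs <- matrix(0i, length(freqs), n)
  for (j in seq_along(freqs)) {
    s <- scales[j]
    kern <- sqrt(s) * pi^(-0.25) * sqrt(2 * pi) *
      exp(-(s * omega_k - omega0)^2 / 2) * (omega_k > 0)
    w <- fft(xf * kern, inverse = TRUE) / m
    coefs[j, ] <- w[seq_len(n)]
  }
  t_idx <- seq_len(n)
  efold <- outer(sqrt(2) * scales * fs, rep(1, n))
  coi <- sweep(efold, 2, t_idx - 1, ">") |
    sweep(efold, 2, n - t_idx, ">")
  structure(list(coefs = coefs, coi = coi, freqs = freqs, fs = fs),
            class = "bd_cwt")
}

#' Log power of wavelet coefficients
#'
#' Natural log of the squared coefficient magnitude with a small floor
#' (`eps = 1e-12`) so silent signals stay finite; coefficients inside the
#' cone of influence are masked `NA` and excluded downstream. The natural
#' log makes amplitude ratios exact offsets: scaling a signal by `g`
#' shifts its log power by `2 * log(g)`.
#'
#' @param coefs Complex coefficient matrix, or a `bd_cwt` object from
#'   [morlet_transform()].
#' @param coi Optional logical mask matching `coefs`; `TRUE` entries are
#'   masked. Taken from the `bd_cwt` object when one is supplied.
#' @param eps Power floor.
#' @return Numeric matrix of log power, `NA` where masked.
#' @export
log_power <- function(coefs, coi = NULL, eps = 1e-12) {
  if (inherits(coefs, "bd_cwt")) {
    coi <- coi %||% coefs$coi
    coefs <- coefs$coefs
  }
  lp <- log(Re(coefs)^2 + Im(coefs)^2 + eps)
  if (!is.null(coi)) lp[coi] <- NA_real_
  lp
}

#' Time-frequency decomposition of a window set
#'
#' Batched composition of [morlet_transform()] and [log_power()] over the
#' windows of a trial set, returning per-trial log-power maps aligned to
#' movement initiation. All windows share one FFT plan, which is what makes
#' session-scale decomposition affordable.
#'
#' @param windows Window tibble from [extract_windows()] (z-score applied
#'   here unless `normalise = FALSE`).
#' @param freqs Analysis grid in Hz (default 15-25 in 1 Hz steps).
#' @param omega0 Morlet nondimensional frequency.
#' @param normalise Z-score each window first (default `TRUE`).
#' @return Object of class `bd_tfmap`: `logpower` (array trials x freqs x
#'   times), `freqs`, `times` (seconds relative to movement initiation),
#'   `coi` (freqs x times logical), `trial_index`, `band` (range of
#'   `freqs`).
#' @export
tf_decompose <- function(windows, freqs = 15:25, omega0 = 6,
                         normalise = TRUE) {
  fs <- attr(windows, "fs")
  if (is.null(fs)) abort("`windows` must come from extract_windows().")
  if (max(freqs) >= fs / 2) abort("analysis frequencies must lie below Nyquist.")
  n <- length(windows$samples[[1]])
  ntr <- nrow(windows)
  xs <- matrix(unlist(windows$samples), n, ntr)
  if (normalise) {
    mu <- colMeans(xs)
    sg <- sqrt(colMeans(xs^2) - mu^2) * sqrt(n / (n - 1))
    if (any(sg == 0)) abort("zero-variance window cannot be z-scored.")
    xs <- sweep(sweep(xs, 2, mu, "-"), 2, sg, "/")
  }
  scales <- morlet_scale(freqs, omega0)
  support <- ceiling(5 * sqrt(2) * max(scales) * fs)
  m <- stats::nextn(n + 2 * support, c(2, 3, 5))
  xf <- mvfft(rbind(xs, matrix(0, m - n, ntr)))
  omega_k <- 2 * pi * fs * c(0:floor(m / 2), -(ceiling(m / 2) - 1):-1) / m
  lp <- array(NA_real_, c(ntr, length(freqs), n))
  for (j in seq_along(freqs)) {
    s <- scales[j]
    kern <- sqrt(s) * pi^(-0.25) * sqrt(2 * pi) *
      exp(-(s * omega_k - omega0)^2 / 2) * (omega_k > 0)
    w <- mvfft(xf * kern, inverse = TRUE) / m
    w <- w[seq_len(n), , drop = FALSE]
    lp[, j, ] <- t(log(Re(w)^2 + Im(w)^2 + 1e-12))
  }
  t_idx <- seq_len(n)
  efold <- outer(sqrt(2) * scales * fs, rep(1, n))
  coi <- sweep(efold, 2, t_idx - 1, ">") | sweep(efold, 2, n - t_idx, ">")
  for (j in seq_along(freqs)) lp[, j, coi[j, ]] <- NA_real_
  t0 <- windows$t0_index[1]
  structure(
    list(logpower = lp, freqs = freqs, times = (t_idx - t0) / fs,
         coi = coi, trial_index = windows$trial_index,
         band = range(freqs)),
    class = "bd_tfmap"
  )
}

#' @export
print.bd_tfmap <- function(x, ...) {
  cat(sprintf("<bd_tfmap> %d trials x %d freqs (%g-%g Hz) x %d times (%.2f..%.2f s)\n",
              dim(x$logpower)[1], dim(x$logpower)[2], min(x$freqs),
              max(x$freqs), dim(x$logpower)[3], min(x$times), max(x$times)))
  invisible(x)
}

#' Pre-movement window specification
#'
#' Where the per-trial pre-movement beta statistic is read from, relative
#' to movement initiation. `reaction_time` mode (human) averages over each
#' trial's full reaction-time interval `[-rt, 0)`; `fixed` mode (cat)
#' averages over a configured window placed from EMG-informed timing,
#' e.g. `-400..-200` ms before paw lift.
#'
#' @param mode `"reaction_time"` or `"fixed"`.
#' @param fixed_start_ms,fixed_end_ms Fixed window bounds in ms relative to
#'   movement initiation (negative = before); required in `fixed` mode,
#'   must be entirely pre-movement with positive duration.
#' @return A list of class `bd_window_spec`.
#' @export
premovement_window_spec <- function(mode = c("reaction_time", "fixed"),
                                    fixed_start_ms = NULL,
                                    fixed_end_ms = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(fixed_start_ms) || is.null(fixed_end_ms)) {
      abort("fixed mode needs `fixed_start_ms` and `fixed_end_ms`.")
    }
    if (fixed_end_ms > 0 || fixed_start_ms >= fixed_end_ms) {
      abort("fixed window must be entirely pre-movement with positive duration.")
    }
  }
  structure(list(mode = mode, fixed_start_ms = fixed_start_ms,
                 fixed_end_ms = fixed_end_ms), class = "bd_window_spec")
}

#' Per-trial pre-movement beta power
#'
#' Mean log power over the beta band and the trial's pre-movement interval
#' (`[-rt, 0)` in reaction-time mode, the configured window in fixed mode),
#' excluding cone-of-influence bins. Trials whose valid region is empty are
#' flagged missing (`NA`), not zero. A reaction time longer than the
#' pre-event half-window is truncated to the overlap and logged in the
#' `truncated` column.
#'
#' @param tf A `bd_tfmap` from [tf_decompose()].
#' @param trials Trial tibble carrying `trial_index` and `rt_ms` (needed in
#'   reaction-time mode).
#' @param spec A [premovement_window_spec()].
#' @return Tibble `trial_index`, `beta_logpower`, `n_bins`, `truncated`.
#' @export
premovement_beta <- function(tf, trials,
                             spec = premovement_window_spec("reaction_time")) {
  stopifnot(inherits(tf, "bd_tfmap"), inherits(spec, "bd_window_spec"))
  times <- tf$times
  out <- purrr::map(seq_along(tf$trial_index), function(i) {
    id <- tf$trial_index[i]
    if (spec$mode == "reaction_time") {
      rt <- trials$rt_ms[match(id, trials$trial_index)] / 1000
      if (is.na(rt)) return(list(id, NA_real_, 0L, FALSE))
      lo <- -rt; hi <- 0
    } else {
      lo <- spec$fixed_start_ms / 1000; hi <- spec$fixed_end_ms / 1000
    }
    truncated <- lo < min(times)
    sel <- times >= max(lo, min(times)) & times < hi
    if (!any(sel)) return(list(id, NA_real_, 0L, truncated))
    vals <- tf$logpower[i, , sel]
    list(id, mean(vals, na.rm = TRUE), sum(!is.na(vals)), truncated)
  })
  tibble(
    trial_index = purrr::map_int(out, ~ as.integer(.x[[1]])),
    beta_logpower = purrr::map_dbl(out, 2),
    n_bins = purrr::map_int(out, ~ as.integer(.x[[3]])),
    truncated = purrr::map_lgl(out, 4)
  )
}
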