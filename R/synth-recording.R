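#' Neural generator configuration
#'
#' Parameters of the coupled synthetic recording: sampling rate, channel
#' layout (a centre channel plus its four Laplacian neighbours), the beta
#' rhythm (a 20 Hz amplitude-modulated carrier riding on 1/f^alpha
#' background noise) and its movement-locked desynchronization. The rhythm
#' is tonic across the trial; the epoch gain scales it during the
#' pre-movement interval only, and from `desync_onset_ms` (relative to
#' movement initiation) until movement end the amplitude is multiplied by
#' `1 - desync_depth`.
#'
#' @param fs_raw Sampling rate in Hz (human EEG default 2500; cat LFP is
#'   acquired at 30000).
#' @param channel_names Channel labels; the first is the channel of
#'   interest.
#' @param neighbour_map Named list mapping the centre channel to its four
#'   neighbours.
#' @param beta_freq_hz Carrier frequency (default 20, centre of the
#'   15-25 Hz band).
#' @param beta_amp Carrier amplitude on the centre channel, in units of
#'   the (unit-SD) background noise. The default places the rhythm about
#'   20 dB above the 1/f floor at the carrier frequency after the
#'   Laplacian derivation and filter chain.
#' @param beta_epoch_gain Named multipliers of the pre-movement beta
#'   amplitude per epoch; unnamed epochs default to 1.
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha background.
#' @param desync_depth Movement-related amplitude suppression fraction in
#'   `[0, 1]`.
#' @param desync_onset_ms Suppression onset relative to movement
#'   initiation (ms; negative = before).
#' @param neighbour_gain Fraction of the beta component reaching the
#'   neighbour channels by volume conduction.
#' @param window_halfwidth_s Analysis-window half-width (s).
#' @return A validated list of class `bd_neural_config`.
#' @export
neural_config <- function(fs_raw = 2500,
                          channel_names = c("C3", "FC1", "FC5", "CP1", "CP5"),
                          neighbour_map = list(C3 = c("FC1", "FC5", "CP1", "CP5")),
                          beta_freq_hz = 20,
                          beta_amp = 3.5,
                          beta_epoch_gain = c(EA = 0.8),
                          noise_exponent = 1.5,
                          desync_depth = 0.5,
                          desync_onset_ms = 0,
                          neighbour_gain = 0.3,
                          window_halfwidth_s = 1) {
  if (fs_raw < 4 * beta_freq_hz) {
    abort("`fs_raw` must be at least 4x the beta carrier frequency.")
  }
  if (any(beta_epoch_gain <= 0)) abort("epoch gains must be positive.")
  if (desync_depth < 0 || desync_depth > 1) {
    abort("`desync_depth` must be in [0, 1].")
  }
  if (beta_amp < 0) abort("`beta_amp` must be non-negative.")
  structure(as.list(environment()), class = "bd_neural_config")
}

# 1/f^alpha background noise by spectral synthesis, flattened below
# `f_floor` so the series has finite variance; unit SD on output. Pairs of
# channels share one inverse FFT: with an unconstrained complex Gaussian
# spectrum, the real and imaginary parts of the inverse transform are two
# independent real noises with the target spectrum.
pink_noise <- function(n, n_chan, alpha, fs, f_floor = 1) {
  m <- stats::nextn(n, c(2, 3, 5))
  f <- (0:(m - 1)) * fs / m
  f[1] <- Inf                                   # drop DC
  shape <- pmax(f, f_floor)^(-alpha / 2)
  shape[f > fs / 2] <- 0                        # one-sided spectrum (and DC)
  out <- matrix(0, n, n_chan)
  for (p in seq_len(ceiling(n_chan / 2))) {
    spec <- complex(real = rnorm(m), imaginary = rnorm(m)) * shape
    z <- fft(spec, inverse = TRUE) / sqrt(m)
    j <- 2 * p - 1
    out[, j] <- Re(z)[seq_len(n)]
    if (j + 1 <= n_chan) out[, j + 1] <- Im(z)[seq_len(n)]
  }
  sweep(out, 2, apply(out, 2, sd), "/")
}

#' Simulate a coupled multichannel recording
#'
#' Lays the trials of a behavioural session out on a continuous timeline
#' (one non-overlapping slot per trial, with enough margin for 2 s
#' analysis windows), then synthesises each channel as unit-SD 1/f^alpha
#' noise plus the beta rhythm: full amplitude on the centre channel, an
#' attenuated copy on the neighbours (so a Laplacian derivation is
#' meaningful), per-trial random carrier phase, pre-movement epoch gain
#' and movement-locked desynchronization as configured. Event markers
#' (`target_on`, `move_init`, `move_end`) are embedded per trial, with
#' movement initiation aligned to the 500 Hz grid the filter chain
#' resamples to.
#'
#' @param trials Trial tibble with `trial_index`, `epoch`, `rt_ms`,
#'   `duration_ms` (e.g. from [simulate_behavior()] or
#'   [simulate_cat_stream()]).
#' @param cfg A [neural_config()].
#' @param seed Integer seed.
#' @return A [new_recording()] whose `ground_truth` tibble holds the
#'   per-trial true amplitude multiplier and event times.
#' @export
simulate_recording <- function(trials, cfg = neural_config(), seed = 1) {
  stopifnot(inherits(cfg, "bd_neural_config"))
  need <- c("trial_index", "epoch", "rt_ms", "duration_ms")
  if (!all(need %in% names(trials))) {
    abort("`trials` must carry trial_index, epoch, rt_ms and duration_ms.")
  }
  if (anyNA(trials$rt_ms) || anyNA(trials$duration_ms) ||
      any(trials$rt_ms <= 0) || any(trials$duration_ms <= 0)) {
    abort("trial reaction times and durations must be present and positive.")
  }
  fs <- cfg$fs_raw
  k500 <- max(1, round(fs / 500))
  to_grid <- function(x) round(x / k500) * k500
  hw_n <- round(cfg$window_halfwidth_s * fs)
  ntr <- nrow(trials)
  rt_n <- to_grid(round(trials$rt_ms / 1000 * fs))
  dur_n <- to_grid(round(trials$duration_ms / 1000 * fs))
  if (any(rt_n >= fs * 10) || any(dur_n >= fs * 10)) {
    abort("trial event times would overlap adjacent trials.")
  }
  # one slot per trial holds its events; analysis windows may reach into
  # neighbouring slots, but the slot margins guarantee they only ever see
  # neighbouring TONIC rhythm (a neighbour's pre-movement gain or
  # movement desynchronization segment stays outside the 2 s window).
  # The record gets tonic lead-in/out padding covering a full window
  # half-width plus the filter edge margin.
  pre_n <- rt_n + to_grid(round(0.1 * fs))
  post_n <- dur_n + to_grid(round((cfg$window_halfwidth_s - 0.1) * fs))
  slot_n <- pre_n + post_n
  lead_n <- to_grid(hw_n + round(0.3 * fs))
  slot_start <- lead_n + c(0, cumsum(slot_n))[seq_len(ntr)]   # 0-based
  n <- lead_n + sum(slot_n) + lead_n
  move_n <- slot_start + pre_n                          # 0-based event samples
  target_n <- move_n - rt_n
  end_n <- move_n + dur_n
  gains <- rep(1, ntr)
  hit <- match(as.character(trials$epoch), names(cfg$beta_epoch_gain))
  gains[!is.na(hit)] <- cfg$beta_epoch_gain[hit[!is.na(hit)]]
  desync_n <- round(cfg$desync_onset_ms / 1000 * fs)

  withr::with_seed(stage_seed(seed, "recording"), {
    noise <- pink_noise(n, length(cfg$channel_names), cfg$noise_exponent, fs)
    phi <- runif(ntr + 2, 0, 2 * pi)
    # piecewise-constant amplitude envelope per trial slot (tonic rhythm;
    # epoch gain over the pre-movement interval, desynchronization from
    # desync_onset to movement end), tonic in the lead-in/out padding
    b1 <- target_n - slot_start
    b2 <- pmin(pmax(pre_n + desync_n, b1), pre_n + dur_n)
    b3 <- pre_n + dur_n
    seg_len <- rbind(b1, b2 - b1, b3 - b2, slot_n - b3)
    seg_amp <- rbind(rep(1, ntr), gains, rep(1 - cfg$desync_depth, ntr),
                     rep(1, ntr))
    env <- c(rep(1, lead_n), rep(as.vector(seg_amp), as.vector(seg_len)),
             rep(1, lead_n)) * cfg$beta_amp
    carrier <- sin(2 * pi * cfg$beta_freq_hz * (0:(n - 1)) / fs +
                     rep(phi, c(lead_n, slot_n, lead_n)))
    beta <- env * carrier
    centre <- cfg$channel_names[1]
    samples <- noise
    samples[, 1] <- samples[, 1] + beta
    if (ncol(samples) > 1) {
      for (j in 2:ncol(samples)) {
        samples[, j] <- samples[, j] + cfg$neighbour_gain * beta
      }
    }
    colnames(samples) <- cfg$channel_names
    events <- tibble(
      type = rep(c("target_on", "move_init", "move_end"), each = ntr),
      time_s = c(target_n, move_n, end_n) / fs,
      trial_index = rep(trials$trial_index, 3)
    ) %>% arrange(.data$time_s)
    gt <- tibble(
      trial_index = trials$trial_index, epoch = trials$epoch,
      beta_gain = gains, amp = cfg$beta_amp * gains,
      phase_rad = phi[1 + seq_len(ntr)],
      target_on_s = target_n / fs, move_init_s = move_n / fs,
      move_end_s = end_n / fs
    )
    new_recording(samples, fs = fs, channel_names = cfg$channel_names,
                  neighbour_map = cfg$neighbour_map, events = events,
                  ground_truth = gt)
  })
}
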