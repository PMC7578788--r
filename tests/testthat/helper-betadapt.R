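# Shared builders for the suite. Heavy end-to-end statistical checks use
# a 1000 Hz acquisition rate (the filter chain's minimum) to keep
# session-scale simulation affordable; everything else about those runs is
# the full pipeline at study size (72 trials per epoch).

small_task <- function(n = 60, epoch_len = 20, ...) {
  task_config(n_baseline = n, n_adaptation = n, n_washout = n,
              epoch_len = epoch_len, ...)
}

noise_free_params <- function(...) {
  adaptation_params(motor_noise_sd_deg = 0, rt_sd_ms = 0, dur_sd_ms = 0, ...)
}

# straight synthetic reach towards `angle_deg` (degrees from vertical,
# counterclockwise positive), sampled every `step_px` out to `r_max`
straight_reach <- function(angle_deg, r_max = 320, step_px = 4) {
  r <- seq(0, r_max, by = step_px)
  a <- angle_deg * pi / 180
  data.frame(x = -r * sin(a), y = r * cos(a), t = seq_along(r) - 1)
}

# one full human session -> covariate-adjusted EA-vs-Baseline contrast.
# The spine of the statistical acceptance properties: behaviour ->
# recording -> Laplacian -> filter chain -> windows -> Morlet -> per-trial
# beta -> ANCOVA.
ea_contrast_run <- function(seed, gains = c(EA = 0.8),
                            rt_offsets = c(EA = 30, EAft = 15)) {
  trials <- simulate_behavior(
    task_config(),
    adaptation_params(rt_epoch_offsets_ms = rt_offsets),
    seed = seed
  )
  trials <- dplyr::filter(trials, epoch != "none")
  cfg <- neural_config(fs_raw = 1000, beta_epoch_gain = gains)
  rec <- simulate_recording(trials, cfg, seed = seed + 1)
  filt <- filter_chain(hjorth_laplacian(rec, "C3"), rec$fs)
  win <- extract_windows(filt$series, filt$fs, rec$events)
  pb <- premovement_beta(tf_decompose(win), trials)
  ct <- epoch_contrast(dplyr::left_join(trials, pb, by = "trial_index"))
  ea <- dplyr::filter(tidy(ct), epoch_a == "Baseline", epoch_b == "EA")
  list(deficit = -ea$estimate, p_bonferroni = ea$p_bonferroni, contrast = ct)
}

# brute-force time-domain Morlet convolution: explicit wavelet sampled out
# to +/- 5 e-folding times, direct sum per output sample
morlet_oracle <- function(x, fs, freqs, omega0 = 6) {
  n <- length(x)
  dt <- 1 / fs
  out <- matrix(0i, length(freqs), n)
  for (j in seq_along(freqs)) {
    s <- (omega0 + sqrt(2 + omega0^2)) / (4 * pi * freqs[j])
    half <- ceiling(5 * sqrt(2) * s / dt)
    tt <- (-half:half) * dt
    psi <- s^(-0.5) * pi^(-0.25) * exp(1i * omega0 * tt / s - tt^2 / (2 * s^2))
    for (k in seq_len(n)) {
      m <- k + (-half:half)
      ok <- m >= 1 & m <= n
      out[j, k] <- sum(x[m[ok]] * Conj(psi[ok])) * dt
    }
  }
  out
}
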