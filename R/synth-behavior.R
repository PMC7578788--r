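#' Joystick task configuration
#'
#' Geometry and schedule of the visuomotor rotation session: three blocks
#' (baseline, adaptation under a clockwise cursor rotation, washout), four
#' diagonal targets presented pseudorandomly in balanced blocks, a 5-px
#' movement-initiation zone and a 750 ms speed prompt.
#'
#' @param n_baseline,n_adaptation,n_washout Trials per block.
#' @param rotation_deg Cursor rotation applied during adaptation, in
#'   degrees; positive values denote a clockwise rotation.
#' @param target_angles_deg Target directions in degrees from vertical.
#' @param boundary_radius_px Radius of the task arena.
#' @param init_threshold_px Movement-initiation threshold.
#' @param max_trial_ms Slow-trial prompt threshold (trials beyond it are
#'   flagged, nothing more).
#' @param block_size Trials per pseudorandom target block; must be a
#'   multiple of the number of targets.
#' @param epoch_len Trials per analysis epoch (default 72).
#' @return A validated list of class `bd_task_config`.
#' @export
task_config <- function(n_baseline = 200, n_adaptation = 200,
                        n_washout = 200, rotation_deg = 30,
                        target_angles_deg = c(45, 135, 225, 315),
                        boundary_radius_px = 300, init_threshold_px = 5,
                        max_trial_ms = 750, block_size = 20,
                        epoch_len = 72) {
  if (any(c(n_baseline, n_adaptation, n_washout) <= 0)) {
    abort("trial counts must be positive.")
  }
  if (!is.finite(rotation_deg)) abort("`rotation_deg` must be finite.")
  if (init_threshold_px <= 0) abort("`init_threshold_px` must be positive.")
  if (block_size %% length(target_angles_deg) != 0) {
    abort("`block_size` must be divisible by the number of targets.")
  }
  if (epoch_len <= 0) abort("`epoch_len` must be positive.")
  structure(as.list(environment()), class = "bd_task_config")
}

#' Adaptation learner parameters
#'
#' Single-rate error-driven state-space learner plus kinematic noise. The
#' internal estimate `x` starts at 0; on each trial the perceived error is
#' `e_n = r_n - x_n + eps` (with `r_n` the active rotation and `eps` motor
#' noise) and the state updates as `x_{n+1} = A x_n + B (r_n - x_n)`, which
#' produces the exponential error decay during adaptation and the negative
#' aftereffect at washout. Reaction times and durations are drawn from
#' normal distributions with per-epoch additive shifts.
#'
#' @param retention Retention factor `A` in `[0, 1]`.
#' @param learning_rate Error-correction rate `B` in `[0, 1]`.
#' @param motor_noise_sd_deg Per-trial motor noise SD (degrees).
#' @param rt_base_ms,rt_sd_ms Reaction-time distribution (ms).
#' @param dur_base_ms,dur_sd_ms Reach-duration distribution (ms).
#' @param rt_epoch_offsets_ms,dur_epoch_offsets_ms Named numeric vectors of
#'   additive per-epoch shifts (ms), e.g. `c(EA = 30)`.
#' @return A validated list of class `bd_adaptation_params`.
#' @export
adaptation_params <- function(retention = 0.99, learning_rate = 0.08,
                              motor_noise_sd_deg = 4,
                              rt_base_ms = 350, rt_sd_ms = 50,
                              dur_base_ms = 300, dur_sd_ms = 40,
                              rt_epoch_offsets_ms = c(EA = 30, EAft = 15),
                              dur_epoch_offsets_ms = c(EA = 20, EAft = 10)) {
  if (retention < 0 || retention > 1) abort("`retention` must be in [0, 1].")
  if (learning_rate < 0 || learning_rate > 1) {
    abort("`learning_rate` must be in [0, 1].")
  }
  if (any(c(motor_noise_sd_deg, rt_sd_ms, dur_sd_ms) < 0)) {
    abort("standard deviations must be non-negative.")
  }
  structure(as.list(environment()), class = "bd_adaptation_params")
}

epoch_offset <- function(epoch, offsets) {
  out <- rep(0, length(epoch))
  hit <- match(as.character(epoch), names(offsets))
  out[!is.na(hit)] <- offsets[hit[!is.na(hit)]]
  out
}

#' Simulate a visuomotor adaptation session
#'
#' Runs the state-space learner over a baseline/adaptation/washout
#' schedule and returns one row per trial, including the generative ground
#' truth (`state_deg`, `perceived_error_deg`). The reported endpoint error
#' is `-e_n`, so adaptation errors are negative (clockwise) under a
#' positive (clockwise) rotation and the washout aftereffect has the
#' opposite sign.
#'
#' @param task A [task_config()].
#' @param params An [adaptation_params()].
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return Tibble with columns `trial_index`, `phase`, `epoch`,
#'   `target_deg`, `endpoint_error_deg`, `rt_ms`, `duration_ms`,
#'   `category`, `slow_trial`, `state_deg`, `perceived_error_deg`.
#' @export
simulate_behavior <- function(task = task_config(),
                              params = adaptation_params(), seed = 1) {
  stopifnot(inherits(task, "bd_task_config"),
            inherits(params, "bd_adaptation_params"))
  n <- task$n_baseline + task$n_adaptation + task$n_washout
  phase <- rep(c("baseline", "adaptation", "washout"),
               c(task$n_baseline, task$n_adaptation, task$n_washout))
  r <- ifelse(phase == "adaptation", task$rotation_deg, 0)
  withr::with_seed(stage_seed(seed, "behavior"), {
    targets <- unlist(lapply(seq_len(ceiling(n / task$block_size)), function(b) {
      sample(rep(task$target_angles_deg,
                 task$block_size / length(task$target_angles_deg)))
    }))[seq_len(n)]
    eps <- rnorm(n, 0, params$motor_noise_sd_deg)
    x <- numeric(n)
    e <- numeric(n)
    xi <- 0
    for (i in seq_len(n)) {
      x[i] <- xi
      e[i] <- r[i] - xi + eps[i]
      xi <- params$retention * xi + params$learning_rate * (r[i] - xi)
    }
    trials <- tibble(
      trial_index = seq_len(n), phase = phase, target_deg = targets,
      endpoint_error_deg = -e, category = "n/a",
      state_deg = x, perceived_error_deg = e
    )
    trials <- assign_epochs(trials, task$epoch_len)
    rt <- rnorm(n, params$rt_base_ms +
                  epoch_offset(trials$epoch, params$rt_epoch_offsets_ms),
                params$rt_sd_ms)
    dur <- rnorm(n, params$dur_base_ms +
                   epoch_offset(trials$epoch, params$dur_epoch_offsets_ms),
                 params$dur_sd_ms)
    trials %>%
      mutate(rt_ms = pmax(rt, 100), duration_ms = pmax(dur, 80),
             slow_trial = .data$rt_ms + .data$duration_ms > task$max_trial_ms) %>%
      select("trial_index", "phase", "epoch", "target_deg",
             "endpoint_error_deg", "rt_ms", "duration_ms", "category",
             "slow_trial", "state_deg", "perceived_error_deg")
  })
}

#' Simulate a cat prism reach session
#'
#' Hit/miss/reject trial stream for the reach-retrieve task: a baseline
#' block, a prism block that ends after a run of consecutive accurate
#' reaches (emulating adaptation within roughly ten trials under the
#' default decaying miss probability), and a short post-prism block
#' carrying the aftereffect. Miss rates may be scalars, per-trial vectors
#' or functions of the within-phase trial number.
#'
#' @param n_baseline Baseline trials (default 20).
#' @param miss_rate_baseline,miss_rate_prism,miss_rate_post Per-phase miss
#'   probabilities; scalar, vector (recycled/truncated to the phase), or
#'   `function(k)` of the within-phase trial number.
#' @param n_post Post-prism trials.
#' @param consecutive_hits_to_end Consecutive prism hits that end the
#'   prism phase (default 20).
#' @param max_prism_trials Cap on prism trials; hitting it flags the
#'   session as non-converged (attribute `converged`).
#' @param rt_base_ms,rt_sd_ms,dur_base_ms,dur_sd_ms Kinematic
#'   distributions (ms).
#' @param seed Integer seed.
#' @return Tibble `trial_index`, `phase`, `outcome`, `rt_ms`,
#'   `duration_ms`, `epoch` (Baseline / EA / LA mapping: pre-prism hits,
#'   prism misses, prism hits), with attribute `converged`.
#' @export
simulate_cat_stream <- function(n_baseline = 20,
                                miss_rate_baseline = 0.05,
                                miss_rate_prism = function(k) 0.9 * exp(-(k - 1) / 4),
                                miss_rate_post = function(k) 0.8 * exp(-(k - 1) / 3),
                                n_post = 20,
                                consecutive_hits_to_end = 20,
                                max_prism_trials = 200,
                                rt_base_ms = 450, rt_sd_ms = 60,
                                dur_base_ms = 350, dur_sd_ms = 50,
                                seed = 1) {
  if (n_baseline <= 0 || n_post < 0 || max_prism_trials <= 0) {
    abort("phase schedule is invalid.")
  }
  rate_at <- function(rate, k) {
    p <- if (is.function(rate)) rate(k) else
      if (length(rate) >= k) rate[k] else rate[length(rate)]
    min(max(p, 0), 1)
  }
  withr::with_seed(stage_seed(seed, "cat"), {
    phase <- character(0); outcome <- character(0)
    for (k in seq_len(n_baseline)) {
      phase <- c(phase, "baseline")
      outcome <- c(outcome,
                   if (runif(1) < rate_at(miss_rate_baseline, k)) "miss" else "hit")
    }
    streak <- 0L; k <- 0L; converged <- FALSE
    while (k < max_prism_trials) {
      k <- k + 1L
      miss <- runif(1) < rate_at(miss_rate_prism, k)
      phase <- c(phase, "prism")
      outcome <- c(outcome, if (miss) "miss" else "hit")
      streak <- if (miss) 0L else streak + 1L
      if (streak >= consecutive_hits_to_end) { converged <- TRUE; break }
    }
    for (k in seq_len(n_post)) {
      phase <- c(phase, "post_prism")
      outcome <- c(outcome,
                   if (runif(1) < rate_at(miss_rate_post, k)) "miss" else "hit")
    }
    n <- length(phase)
    out <- tibble(
      trial_index = seq_len(n), phase = phase, outcome = outcome,
      rt_ms = pmax(rnorm(n, rt_base_ms, rt_sd_ms), 100),
      duration_ms = pmax(rnorm(n, dur_base_ms, dur_sd_ms), 80),
      epoch = factor(dplyr::case_when(
        phase == "baseline" & outcome == "hit" ~ "Baseline",
        phase == "prism" & outcome == "miss" ~ "EA",
        phase == "prism" & outcome == "hit" ~ "LA",
        TRUE ~ "none"
      ), levels = epoch_levels())
    )
    attr(out, "converged") <- converged
    out
  })
}

#' Write / read a trial table
#'
#' Plain-CSV exchange format for behavioural trial tables (one row per
#' trial, the columns produced by [simulate_behavior()] and downstream
#' annotations such as `beta_logpower`).
#'
#' @param trials Trial tibble.
#' @param path CSV path.
#' @export
write_trials <- function(trials, path) {
  data.table::fwrite(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  out <- as_tibble(data.table::fread(path))
  if ("epoch" %in% names(out)) {
    out$epoch <- factor(out$epoch, levels = epoch_levels())
  }
  out
}
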