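# Angles are measured in degrees from vertical (up), counterclockwise
# positive, so a clockwise displacement is negative -- the sign convention
# of the endpoint-error measure.
wrap_180 <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

point_angle_deg <- function(x, y) wrap_180(atan2(-x, y) * 180 / pi)

#' Detect movement initiation from a cursor trajectory
#'
#' First timestamp at which the cursor's Euclidean distance from the start
#' position strictly exceeds the threshold (default 5 px, the task's
#' "zero zone").
#'
#' @param trajectory Data frame with columns `x`, `y` (pixels) and `t`
#'   (timestamps); the first row is the start position.
#' @param threshold_px Initiation threshold in pixels.
#' @return The initiation timestamp, or `NA` if the threshold is never
#'   exceeded.
#' @export
detect_movement_init <- function(trajectory, threshold_px = 5) {
  if (!nrow(trajectory)) abort("empty trajectory.")
  stopifnot(all(c("x", "y", "t") %in% names(trajectory)))
  d <- sqrt((trajectory$x - trajectory$x[1])^2 +
              (trajectory$y - trajectory$y[1])^2)
  if (d[1] > threshold_px) {
    abort("trajectory must start within the threshold of its origin.")
  }
  i <- which(d > threshold_px)
  if (!length(i)) return(NA_real_)
  trajectory$t[i[1]]
}

#' Endpoint error at the task-arena boundary
#'
#' Signed angular displacement between the reach direction and the target
#' when the trajectory first crosses the boundary circle, with the crossing
#' point linearly interpolated between the straddling samples. Angles are
#' measured from vertical, and clockwise displacement is negative.
#'
#' @param trajectory Data frame with columns `x`, `y` in pixels, centred on
#'   the start position.
#' @param target_deg Target direction in degrees from vertical
#'   (counterclockwise positive).
#' @param boundary_radius_px Radius of the task arena in pixels.
#' @return Signed error in degrees, wrapped to (-180, 180]. `NA` with a
#'   warning if the trajectory never crosses the boundary (incomplete
#'   trial).
#' @export
compute_endpoint_error <- function(trajectory, target_deg,
                                   boundary_radius_px) {
  if (!nrow(trajectory)) abort("empty trajectory.")
  r <- sqrt(trajectory$x^2 + trajectory$y^2)
  i <- which(r >= boundary_radius_px)
  if (!length(i)) {
    warn("trajectory never crosses the boundary; incomplete trial.")
    return(NA_real_)
  }
  i <- i[1]
  if (i == 1L) {
    xc <- trajectory$x[1]; yc <- trajectory$y[1]
  } else {
    # solve |p1 + lambda (p2 - p1)| = R on the straddling segment
    x1 <- trajectory$x[i - 1]; y1 <- trajectory$y[i - 1]
    dx <- trajectory$x[i] - x1; dy <- trajectory$y[i] - y1
    aa <- dx^2 + dy^2
    bb <- 2 * (x1 * dx + y1 * dy)
    cc <- x1^2 + y1^2 - boundary_radius_px^2
    lam <- (-bb + sqrt(bb^2 - 4 * aa * cc)) / (2 * aa)
    xc <- x1 + lam * dx; yc <- y1 + lam * dy
  }
  wrap_180(point_angle_deg(xc, yc) - target_deg)
}

#' Classify cat reach trials
#'
#' Applies the rejection rules of the reach-retrieve task: a trial is
#' `rejected` when its reaction time is shorter than 150 ms, its duration
#' exceeds the session mean by more than 2 standard deviations, a
#' late-correction or noise-artifact flag is set, or its duration is
#' missing (reason `"incomplete"`). Surviving trials keep their observed
#' `hit`/`miss` outcome.
#'
#' @param trials Tibble with `rt_ms`, `duration_ms`, `outcome`
#'   (`"hit"`/`"miss"`) and optional logical columns `late_correction`,
#'   `noise_artifact`.
#' @param rt_floor_ms Reaction-time floor (default 150 ms).
#' @param duration_stats Optional list `(mean, sd)` of session durations;
#'   computed from the supplied trials when absent (the per-animal rule).
#' @return The tibble with `category` and `reject_reason` columns.
#' @export
classify_trials <- function(trials, rt_floor_ms = 150,
                            duration_stats = NULL) {
  stopifnot(all(c("rt_ms", "duration_ms", "outcome") %in% names(trials)))
  lc <- trials[["late_correction"]] %||% rep(FALSE, nrow(trials))
  na_flag <- trials[["noise_artifact"]] %||% rep(FALSE, nrow(trials))
  if (is.null(duration_stats)) {
    duration_stats <- list(mean = mean(trials$duration_ms, na.rm = TRUE),
                           sd = sd(trials$duration_ms, na.rm = TRUE))
  }
  lim <- duration_stats$mean + 2 * duration_stats$sd
  reason <- dplyr::case_when(
    is.na(trials$duration_ms) ~ "incomplete",
    trials$rt_ms < rt_floor_ms ~ "reaction time below floor",
    trials$duration_ms > lim ~ "duration beyond 2 SD",
    lc ~ "late correction",
    na_flag ~ "noise artifact",
    TRUE ~ NA_character_
  )
  trials %>%
    mutate(category = if_else(is.na(reason), .data$outcome, "rejected"),
           reject_reason = reason)
}

#' Assign the five adaptation epochs
#'
#' Deterministic epoch labelling of a baseline/adaptation/washout session:
#' Baseline is the final `epoch_len` baseline trials, EA/LA the first/last
#' `epoch_len` adaptation trials, EAft/LAft the first/last `epoch_len`
#' washout trials; everything else is `"none"`. The early epochs are taken
#' as the first `epoch_len` trials after each perturbation change, and the
#' "errors beyond 2 SD of baseline" property is reported as a QC fraction
#' by [epoch_definitions()] rather than used as a selection filter.
#'
#' @param trials Trial tibble with `phase` in
#'   `baseline`/`adaptation`/`washout`, ordered by trial.
#' @param epoch_len Trials per epoch (default 72).
#' @return The tibble with an `epoch` factor column.
#' @export
assign_epochs <- function(trials, epoch_len = 72) {
  n_by <- table(factor(trials$phase,
                       levels = c("baseline", "adaptation", "washout")))
  if (n_by[["baseline"]] < epoch_len) {
    abort("baseline phase shorter than one epoch.")
  }
  if (any(n_by[c("adaptation", "washout")] < epoch_len)) {
    abort("adaptation/washout phase shorter than one epoch.")
  }
  idx <- seq_len(nrow(trials))
  within_phase <- stats::ave(idx, trials$phase, FUN = seq_along)
  phase_n <- as.vector(n_by[trials$phase])
  epoch <- rep("none", nrow(trials))
  epoch[trials$phase == "baseline" &
          within_phase > phase_n - epoch_len] <- "Baseline"
  epoch[trials$phase == "adaptation" & within_phase <= epoch_len] <- "EA"
  epoch[trials$phase == "adaptation" &
          within_phase > phase_n - epoch_len] <- "LA"
  epoch[trials$phase == "washout" & within_phase <= epoch_len] <- "EAft"
  epoch[trials$phase == "washout" &
          within_phase > phase_n - epoch_len] <- "LAft"
  mutate(trials, epoch = factor(epoch, levels = epoch_levels()))
}

#' Epoch definitions with QC fractions
#'
#' Tabulates the member trial indices of each epoch and, for the early
#' epochs (EA, EAft), the fraction of member trials whose endpoint error
#' lies strictly beyond 2 SD of the Baseline-epoch mean -- the property the
#' early epochs are expected to exhibit.
#'
#' @inheritParams assign_epochs
#' @return Tibble `epoch`, `start_index`, `end_index`, `n`,
#'   `trial_indices` (list-column), `qc_fraction_beyond_2sd`.
#' @export
epoch_definitions <- function(trials, epoch_len = 72) {
  if (!"epoch" %in% names(trials)) trials <- assign_epochs(trials, epoch_len)
  if (!"trial_index" %in% names(trials)) {
    trials$trial_index <- seq_len(nrow(trials))
  }
  base <- dplyr::filter(trials, .data$epoch == "Baseline")
  mu <- mean(base$endpoint_error_deg)
  sg <- sd(base$endpoint_error_deg)
  trials %>%
    dplyr::filter(.data$epoch != "none") %>%
    group_by(epoch = factor(.data$epoch, levels = setdiff(epoch_levels(), "none"))) %>%
    summarise(
      start_index = min(.data$trial_index),
      end_index = max(.data$trial_index),
      n = dplyr::n(),
      trial_indices = list(.data$trial_index),
      qc_fraction_beyond_2sd = if (dplyr::cur_group()$epoch %in% c("EA", "EAft")) {
        mean(abs(.data$endpoint_error_deg - mu) > 2 * sg)
      } else NA_real_,
      .groups = "drop"
    )
}
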