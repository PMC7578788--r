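test_that("movement initiation uses a strict distance threshold", {
  traj <- data.frame(x = c(0, 3, 4), y = c(0, 4, 4), t = c(0, 1, 2))
  # (3,4) sits at exactly 5 px -- not an initiation; (4,4) is
  expect_equal(detect_movement_init(traj, 5), 2)
  still <- data.frame(x = c(0, 1, -1, 0.5), y = c(0, 1, 0.5, -1), t = 0:3)
  expect_true(is.na(detect_movement_init(still, 5)))
  expect_error(detect_movement_init(data.frame(x = numeric(0),
                                               y = numeric(0),
                                               t = numeric(0)), 5),
               "empty")
})

test_that("movement initiation matches a per-sample brute-force scan", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      traj <- data.frame(x = cumsum(rnorm(200, 0, 2)),
                         y = cumsum(rnorm(200, 0, 2)), t = 0:199)
      traj$x <- traj$x - traj$x[1]; traj$y <- traj$y - traj$y[1]
      got <- detect_movement_init(traj, 5)
      d <- sqrt(traj$x^2 + traj$y^2)
      want <- NA_real_
      for (i in seq_len(nrow(traj))) if (d[i] > 5) { want <- traj$t[i]; break }
      expect_identical(got, want)
    }
  })
})

test_that("endpoint error follows the clockwise-negative sign convention", {
  expect_equal(compute_endpoint_error(straight_reach(45), 45, 300), 0,
               tolerance = 1e-9)
  # crossing 30 degrees clockwise of the target
  expect_equal(compute_endpoint_error(straight_reach(15), 45, 300), -30,
               tolerance = 1e-9)
  expect_equal(compute_endpoint_error(straight_reach(80), 45, 300), 35,
               tolerance = 1e-9)
  # wrapping: 350 vs 10 is a 20 degree difference, not 340
  expect_equal(compute_endpoint_error(straight_reach(-10), 10, 300), -20,
               tolerance = 1e-9)
  short <- straight_reach(45, r_max = 100)
  expect_warning(err <- compute_endpoint_error(short, 45, 300), "boundary")
  expect_true(is.na(err))
})

test_that("endpoint error is rotation-equivariant", {
  withr::with_seed(22, {
    for (rep in 1:10) {
      ang <- runif(1, -180, 180); delta <- runif(1, -180, 180)
      base <- compute_endpoint_error(straight_reach(ang), 45, 300)
      rot <- compute_endpoint_error(straight_reach(ang + delta), 45 + delta, 300)
      expect_equal(rot, base, tolerance = 1e-9)
    }
  })
})

test_that("boundary crossing matches a densely-resampled oracle", {
  dense_oracle <- function(traj, target, radius) {
    xs <- numeric(0); ys <- numeric(0)
    for (i in 2:nrow(traj)) {
      lam <- seq(0, 1, length.out = 2000)
      xs <- c(xs, traj$x[i - 1] + lam * (traj$x[i] - traj$x[i - 1]))
      ys <- c(ys, traj$y[i - 1] + lam * (traj$y[i] - traj$y[i - 1]))
    }
    j <- which(sqrt(xs^2 + ys^2) >= radius)[1]
    ang <- atan2(-xs[j], ys[j]) * 180 / pi
    w <- (ang - target + 180) %% 360 - 180
    if (w == -180) 180 else w
  }
  withr::with_seed(23, {
    for (rep in 1:10) {
      # wandering but outward piecewise-linear path
      n <- 40
      r <- seq(0, 330, length.out = n) + c(0, runif(n - 1, -12, 12))
      th <- (runif(1, -180, 180) + cumsum(rnorm(n, 0, 4))) * pi / 180
      traj <- data.frame(x = -r * sin(th), y = r * cos(th))
      got <- compute_endpoint_error(traj, 45, 300)
      want <- dense_oracle(traj, 45, 300)
      expect_equal(got, want, tolerance = 0.05)
    }
  })
})

test_that("cat trial classification applies every rejection rule", {
  stats0 <- list(mean = 300, sd = 50)
  base <- tibble::tibble(rt_ms = 200, duration_ms = 300, outcome = "hit")
  expect_equal(classify_trials(dplyr::mutate(base, rt_ms = 149),
                               duration_stats = stats0)$category, "rejected")
  expect_equal(classify_trials(dplyr::mutate(base, rt_ms = 150),
                               duration_stats = stats0)$category, "hit")
  # duration at mean + 1.9 SD survives; beyond 2 SD does not
  expect_equal(classify_trials(dplyr::mutate(base, duration_ms = 395),
                               duration_stats = stats0)$category, "hit")
  expect_equal(classify_trials(dplyr::mutate(base, duration_ms = 401),
                               duration_stats = stats0)$category, "rejected")
  miss <- classify_trials(dplyr::mutate(base, outcome = "miss"),
                          duration_stats = stats0)
  expect_equal(miss$category, "miss")
  inc <- classify_trials(dplyr::mutate(base, duration_ms = NA_real_),
                         duration_stats = stats0)
  expect_equal(inc$reject_reason, "incomplete")
})

test_that("a fixture with planted violations is rejected exactly", {
  withr::with_seed(24, {
    n <- 100
    trials <- tibble::tibble(
      rt_ms = runif(n, 200, 400),
      duration_ms = runif(n, 250, 350),
      outcome = sample(c("hit", "miss"), n, TRUE),
      late_correction = FALSE, noise_artifact = FALSE
    )
    stats0 <- list(mean = 300, sd = 50)
    bad_rt <- 1:7; bad_dur <- 11:16; bad_flag <- 21:25
    trials$rt_ms[bad_rt] <- 149
    trials$duration_ms[bad_dur] <- 300 + 2 * 50 + 1
    trials$late_correction[bad_flag] <- TRUE
    cl <- classify_trials(trials, duration_stats = stats0)
    expect_equal(sum(cl$category == "rejected"),
                 length(c(bad_rt, bad_dur, bad_flag)))
    expect_true(all(cl$category[c(bad_rt, bad_dur, bad_flag)] == "rejected"))
    # never hit/miss when a rejection rule fires
    expect_false(any(cl$category[cl$rt_ms < 150] %in% c("hit", "miss")))
  })
})

test_that("the five epochs are the deterministic 72-trial index sets", {
  trials <- simulate_behavior(task_config(), seed = 30)
  ep <- epoch_definitions(trials)
  expect_equal(ep$epoch, factor(c("Baseline", "EA", "LA", "EAft", "LAft"),
                                levels = levels(ep$epoch)))
  expect_equal(ep$start_index, c(129L, 201L, 329L, 401L, 529L))
  expect_equal(ep$end_index, c(200L, 272L, 400L, 472L, 600L))
  expect_true(all(ep$n == 72))
  expect_equal(ep$trial_indices[[2]], 201:272)
  # early/late pairs never overlap when the phase has >= 144 trials
  expect_equal(intersect(ep$trial_indices[[2]], ep$trial_indices[[3]]),
               integer(0))
  expect_error(assign_epochs(tibble::tibble(phase = rep("baseline", 10)), 72),
               "shorter")
})

test_that("QC fractions report trials beyond 2 SD of baseline", {
  withr::with_seed(31, {
    trials <- simulate_behavior(task_config(), noise_free_params(), seed = 31)
    trials$endpoint_error_deg <- rnorm(600, 0, 1)
    trials$endpoint_error_deg[trials$epoch == "EA"] <- -30
    ep <- epoch_definitions(trials)
    expect_equal(ep$qc_fraction_beyond_2sd[ep$epoch == "EA"], 1.0)
    expect_true(is.na(ep$qc_fraction_beyond_2sd[ep$epoch == "Baseline"]))
    # brute-force per-trial threshold count on a noisy session
    noisy <- simulate_behavior(task_config(), seed = 32)
    epn <- epoch_definitions(noisy)
    base <- noisy$endpoint_error_deg[noisy$epoch == "Baseline"]
    lim <- c(mean(base) - 2 * sd(base), mean(base) + 2 * sd(base))
    for (e in c("EA", "EAft")) {
      errs <- noisy$endpoint_error_deg[noisy$epoch == e]
      want <- mean(errs < lim[1] | errs > lim[2])
      expect_equal(epn$qc_fraction_beyond_2sd[epn$epoch == e], want)
    }
  })
})
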