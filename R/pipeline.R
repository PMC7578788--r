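#' Run configuration
#'
#' Bundles every stage's configuration for a reproducible end-to-end run.
#' In `human` mode the pre-movement statistic is read over each trial's
#' full reaction time and the epoch contrast spans the five epochs; in
#' `cat` mode the statistic comes from a fixed EMG-informed window, the
#' contrast spans Baseline/EA/LA only, and the balanced bootstrap is run.
#'
#' @param mode `"human"` or `"cat"`.
#' @param task A [task_config()] (human mode).
#' @param adaptation An [adaptation_params()] (human mode).
#' @param cat_args List of arguments to [simulate_cat_stream()] (cat
#'   mode).
#' @param neural A [neural_config()].
#' @param window_spec A [premovement_window_spec()]; defaults follow the
#'   mode (full reaction time for humans, a 200 ms window 400-200 ms
#'   before paw lift for cats).
#' @param freqs Analysis frequency grid in Hz.
#' @param seed Integer seed driving every stochastic stage.
#' @param output_dir Where [run_pipeline()] writes its artifacts.
#' @return A list of class `bd_run_config`.
#' @export
run_config <- function(mode = c("human", "cat"), task = task_config(),
                       adaptation = adaptation_params(), cat_args = list(),
                       neural = neural_config(), window_spec = NULL,
                       freqs = 15:25, seed = 1, output_dir = tempfile("bdrun")) {
  mode <- match.arg(mode)
  if (is.null(window_spec)) {
    window_spec <- if (mode == "human") {
      premovement_window_spec("reaction_time")
    } else {
      premovement_window_spec("fixed", fixed_start_ms = -400,
                              fixed_end_ms = -200)
    }
  }
  structure(list(mode = mode, task = task, adaptation = adaptation,
                 cat_args = cat_args, neural = neural,
                 window_spec = window_spec, freqs = freqs, seed = seed,
                 output_dir = output_dir),
            class = "bd_run_config")
}

config_from_yaml <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  y <- yaml::read_yaml(path)
  args <- list(mode = y$mode %||% "human")
  if (!is.null(y$task)) args$task <- do.call(task_config, y$task)
  if (!is.null(y$adaptation)) {
    args$adaptation <- do.call(adaptation_params, y$adaptation)
  }
  if (!is.null(y$neural)) {
    ny <- y$neural
    if (!is.null(ny$beta_epoch_gain)) {
      ny$beta_epoch_gain <- unlist(ny$beta_epoch_gain)
    }
    if (!is.null(ny$neighbour_map)) {
      ny$neighbour_map <- lapply(ny$neighbour_map, unlist)
    }
    if (!is.null(ny$channel_names)) ny$channel_names <- unlist(ny$channel_names)
    args$neural <- do.call(neural_config, ny)
  }
  if (!is.null(y$cat)) args$cat_args <- y$cat
  if (!is.null(y$window)) {
    args$window_spec <- do.call(premovement_window_spec, y$window)
  }
  if (!is.null(y$freqs)) args$freqs <- unlist(y$freqs)
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$output_dir)) args$output_dir <- y$output_dir
  do.call(run_config, args)
}

# simulate -> derive -> filter -> window -> decompose -> per-trial beta;
# the shared spine of run_pipeline() and the CLI subcommands.
analyse_session <- function(trials, cfg) {
  rec <- simulate_recording(trials, cfg$neural, seed = cfg$seed)
  centre <- cfg$neural$channel_names[1]
  series <- if (length(cfg$neural$neighbour_map[[centre]] %||% character(0)) == 4) {
    hjorth_laplacian(rec, centre)
  } else if (length(cfg$neural$channel_names) >= 2) {
    bipolar_rereference(rec, centre, tail(cfg$neural$channel_names, 1))
  } else {
    rec$samples[, centre]
  }
  filt <- filter_chain(series, rec$fs)
  win <- extract_windows(filt$series, filt$fs, rec$events,
                         halfwidth_s = cfg$neural$window_halfwidth_s)
  tf <- tf_decompose(win, freqs = cfg$freqs)
  beta <- premovement_beta(tf, trials, cfg$window_spec)
  list(recording = rec, windows = win, tf = tf,
       trials = left_join(trials, beta, by = "trial_index"))
}

#' Run the full pipeline
#'
#' Simulates a session (human joystick or cat prism mode), synthesises the
#' coupled recording, derives and filters the channel of interest,
#' extracts movement-locked windows, computes per-trial pre-movement beta
#' power, and runs the mode's statistical battery. All intermediate tables
#' and a provenance record (config hash, seed, package version) are
#' written to `cfg$output_dir`; re-running the same config reproduces
#' byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list: `trials` (with `beta_logpower`), `epochs`,
#'   `contrast`, `correlations`, `regression` (human), `bootstrap` (cat),
#'   `output_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "bd_run_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  stage <- "simulate"
  res <- tryCatch({
    if (cfg$mode == "human") {
      trials <- simulate_behavior(cfg$task, cfg$adaptation, seed = cfg$seed)
      epochs <- epoch_definitions(trials, cfg$task$epoch_len)
    } else {
      trials <- do.call(simulate_cat_stream,
                        c(cfg$cat_args, list(seed = cfg$seed)))
      trials <- classify_trials(
        mutate(trials, outcome = .data$outcome), duration_stats = NULL)
      epochs <- trials %>%
        dplyr::filter(.data$epoch != "none", .data$category != "rejected") %>%
        group_by(.data$epoch) %>%
        summarise(n = dplyr::n(), trial_indices = list(.data$trial_index),
                  .groups = "drop")
    }
    logf("simulate: %d trials (mode %s, seed %d)", nrow(trials), cfg$mode,
         cfg$seed)
    stage <- "preprocess/spectral"
    ana <- analyse_session(trials, cfg)
    trials <- ana$trials
    n_skip <- nrow(attr(ana$windows, "skipped"))
    logf("windows: %d extracted, %d skipped", nrow(ana$windows), n_skip)
    stage <- "stats"
    use <- if (cfg$mode == "cat") {
      dplyr::filter(trials, .data$epoch %in% c("Baseline", "EA", "LA"),
                    .data$category != "rejected")
    } else {
      dplyr::filter(trials, .data$epoch != "none")
    }
    use$epoch <- droplevels(factor(use$epoch))
    contrast <- epoch_contrast(use)
    correlations <- correlate_beta_kinematics(use)
    regression <- if (cfg$mode == "human") regress_beta_error(use) else NULL
    boot <- if (cfg$mode == "cat") {
      bootstrap_balanced(use, seed = cfg$seed)
    } else NULL
    list(trials = trials, epochs = epochs, contrast = contrast,
         correlations = correlations, regression = regression,
         bootstrap = boot)
  }, error = function(e) {
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)))
  })

  write_trials(res$trials, file.path(cfg$output_dir, "trials.csv"))
  ep <- res$epochs
  ep$trial_indices <- vapply(ep$trial_indices, function(i)
    paste(i, collapse = ";"), character(1))
  data.table::fwrite(ep, file.path(cfg$output_dir, "epochs.csv"))
  stats_out <- list(
    mode = cfg$mode,
    omnibus = res$contrast$omnibus,
    pairwise = res$contrast$pairwise,
    adjusted_means = res$contrast$adjusted,
    covariates = res$contrast$covariates,
    correlations = res$correlations
  )
  if (!is.null(res$regression)) stats_out$regression <- res$regression
  if (!is.null(res$bootstrap)) {
    stats_out$bootstrap <- list(conditions = res$bootstrap$conditions,
                                pairwise = res$bootstrap$pairwise)
  }
  jsonlite::write_json(stats_out, file.path(cfg$output_dir, "stats.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows",
                       na = "null")
  provenance <- list(
    package = "betadapt",
    version = as.character(utils::packageVersion("betadapt")),
    seed = cfg$seed, mode = cfg$mode,
    config_hash = config_hash(cfg)
  )
  jsonlite::write_json(provenance,
                       file.path(cfg$output_dir, "provenance.json"),
                       auto_unbox = TRUE)
  logf("done")
  invisible(c(res, list(output_dir = cfg$output_dir)))
}

# order-stable structural hash of the config (no serialization of
# environments: functions are hashed by their deparsed body)
config_hash <- function(cfg) {
  canon <- rapply(unclass(cfg), function(x) {
    if (is.function(x)) paste(deparse(x), collapse = "") else x
  }, how = "replace")
  canon$output_dir <- NULL
  txt <- paste(deparse(canon), collapse = "")
  sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997 + 1)) %% 2^31
}
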