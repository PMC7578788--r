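#' Tidy an epoch-contrast result
#'
#' @param x A `bd_contrast` from [epoch_contrast()].
#' @param ... Unused.
#' @return The Bonferroni-adjusted pairwise contrast table as a tibble.
#' @export
tidy.bd_contrast <- function(x, ...) x$pairwise

#' @rdname tidy.bd_contrast
#' @return `glance()`: a one-row tibble with the omnibus partial F test
#'   for the epoch factor and the model size.
#' @export
glance.bd_contrast <- function(x, ...) {
  bind_cols(x$omnibus, tibble(n = x$n, df_residual = x$df_residual,
                              n_epochs = length(x$levels)))
}

#' Tidy a balanced-bootstrap result
#'
#' @param x A `bd_bootstrap` from [bootstrap_balanced()].
#' @param ... Unused.
#' @return The pairwise difference table with percentile CIs.
#' @export
tidy.bd_bootstrap <- function(x, ...) x$pairwise

#' @rdname tidy.bd_bootstrap
#' @export
glance.bd_bootstrap <- function(x, ...) {
  tibble(n_boot = x$n_boot, m = x$m,
         n_conditions = nrow(x$conditions), flag = x$flag)
}

#' Plot a session's endpoint-error course
#'
#' Trial-by-trial endpoint error with phase boundaries: exponential decay
#' of the (clockwise, negative) error during adaptation, negative
#' aftereffect on washout.
#'
#' @param trials Trial tibble from [simulate_behavior()].
#' @return A ggplot object.
#' @export
plot_endpoint_errors <- function(trials) {
  breaks <- cumsum(rle(trials$phase)$lengths)
  ggplot2::ggplot(trials,
                  ggplot2::aes(x = .data$trial_index,
                               y = .data$endpoint_error_deg)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = head(breaks, -1) + 0.5,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "trial", y = "endpoint error (deg)",
                  title = "Endpoint error across adaptation") +
    ggplot2::theme_minimal()
}

#' Spectrogram of a time-frequency map
#'
#' Trial-averaged log power aligned to movement initiation (time 0);
#' cone-of-influence bins are blank.
#'
#' @param object A `bd_tfmap` from [tf_decompose()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bd_tfmap <- function(object, ...) {
  mp <- apply(object$logpower, c(2, 3), mean, na.rm = TRUE)
  df <- tidyr::expand_grid(freq = object$freqs, time = object$times)
  df$logpower <- as.vector(t(mp))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$freq,
                                   fill = .data$logpower)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(x = "time from movement initiation (s)",
                  y = "frequency (Hz)", fill = "ln power") +
    ggplot2::theme_minimal()
}

#' Adjusted epoch means with pairwise significance
#'
#' @param object A `bd_contrast` from [epoch_contrast()].
#' @param ... Unused.
#' @return A ggplot object of covariate-adjusted epoch means.
#' @export
autoplot.bd_contrast <- function(object, ...) {
  adj <- object$adjusted
  adj$epoch <- factor(adj$epoch, levels = object$levels)
  se <- summary(object$fit)$sigma / sqrt(adj$n)
  adj$se <- se
  ggplot2::ggplot(adj, ggplot2::aes(x = .data$epoch, y = .data$adj_mean)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$adj_mean - .data$se,
                                        ymax = .data$adj_mean + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "adjusted mean beta log power") +
    ggplot2::theme_minimal()
}

#' Bootstrap condition means
#'
#' @param object A `bd_bootstrap` from [bootstrap_balanced()].
#' @param ... Unused.
#' @return A ggplot object of bootstrap means with +/- 1 SE bars.
#' @export
autoplot.bd_bootstrap <- function(object, ...) {
  cd <- object$conditions
  ggplot2::ggplot(cd, ggplot2::aes(x = .data$condition,
                                   y = .data$boot_mean)) +
    ggplot2::geom_col(fill = "darkorange", alpha = 0.8) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$boot_mean - .data$boot_se,
                                        ymax = .data$boot_mean + .data$boot_se),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "bootstrap mean beta log power") +
    ggplot2::theme_minimal()
}
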