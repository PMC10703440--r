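#' Plot a psychometric function from raw trials
#'
#' Proportion of up-choices per signed coherence, optionally split by the
#' previous stimulus category, the standard behavioral read-out of history
#' bias.
#'
#' @param trials Trial tibble.
#' @param by_prev_category Split curves by the previous stimulus category
#'   (default `TRUE`; previous zero-coherence trials are dropped).
#' @return A ggplot object.
#' @export
plot_psychometric <- function(trials, by_prev_category = TRUE) {
  tb <- trials |>
    dplyr::group_by(.data$subject, .data$environment, .data$block) |>
    dplyr::mutate(prev_cat = dplyr::lag(
      ifelse(.data$coherence > 0, .data$category, 0), default = 0)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$choice))
  if (by_prev_category) {
    tb <- dplyr::filter(tb, .data$prev_cat != 0)
    tb$prev_cat <- factor(tb$prev_cat, levels = c(-1, 1),
                          labels = c("previous down", "previous up"))
  }
  agg <- tb |>
    dplyr::group_by(.data$environment, .data$signed_stim,
                    dplyr::across(dplyr::any_of(
                      if (by_prev_category) "prev_cat" else character(0)))) |>
    dplyr::summarise(p_up = mean(.data$choice == 1), n = dplyr::n(),
                     .groups = "drop")
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$signed_stim, y = .data$p_up)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~environment) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "signed coherence", y = "P(choice = up)") +
    ggplot2::theme_minimal()
  if (by_prev_category) {
    p <- p + ggplot2::aes(colour = .data$prev_cat) +
      ggplot2::labs(colour = NULL)
  }
  p
}

#' Plot a single-trial bias series
#'
#' @param object A `bias_series` tibble from [single_trial_bias()] /
#'   [bin_bias()].
#' @param ... Unused.
#' @return A ggplot object: bias per trial, coloured by tercile bin when
#'   present.
#' @export
autoplot.bias_series <- function(object, ...) {
  object <- dplyr::group_by(object, .data$subject) |>
    dplyr::mutate(trial_idx = dplyr::row_number()) |>
    dplyr::ungroup()
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$trial_idx, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::facet_wrap(~subject, scales = "free_x") +
    ggplot2::labs(x = "trial", y = "single-trial bias δ") +
    ggplot2::theme_minimal()
  if ("bin" %in% names(object)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$bin), size = 0.8) +
      ggplot2::labs(colour = "bias bin")
  } else {
    p + ggplot2::geom_point(size = 0.8)
  }
}

#' Plot a regression coefficient trace
#'
#' @param object A `regression_trace` tibble from [regress_amplitude()] or
#'   [regress_slope()].
#' @param ... Unused.
#' @return A ggplot object of coefficient estimates over time per term.
#' @export
autoplot.regression_trace <- function(object, ...) {
  if ("choices" %in% names(object)) {
    object <- dplyr::filter(object, .data$choices %in% c("all", "mean"))
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$estimate,
                                       colour = .data$term)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_vline(xintercept = c(0, 0.75), linetype = 3,
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from evidence onset (s)",
                  y = "regression coefficient (z units)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cluster-based permutation test
#'
#' @param object A `cluster_test` from [cluster_permutation_1d()].
#' @param times Optional time axis (defaults to sample index).
#' @param ... Unused.
#' @return A ggplot object: the t-statistic trace with significant clusters
#'   (p < 0.05) shaded.
#' @export
autoplot.cluster_test <- function(object, times = NULL, ...) {
  times <- times %||% seq_along(object$t)
  df <- tibble::tibble(time = times, t = object$t)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$t)) +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$threshold,
                        linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "t statistic") +
    ggplot2::theme_minimal()
  sig <- object$clusters[object$clusters$p.value < 0.05, , drop = FALSE]
  if (!is.null(sig) && nrow(sig) > 0) {
    shade <- tibble::tibble(xmin = times[sig$start], xmax = times[sig$end])
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE, alpha = 0.2, fill = "firebrick",
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf)
    )
  }
  p
}
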