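#' Per-trial lateralization epochs
#'
#' Container for trial-wise lateralization time courses: a trials x
#' timepoints matrix with a common time axis (seconds relative to evidence
#' onset, typically 25-ms steps), an explicit coding convention and a
#' baseline window. Under the `vs_up_hand` coding, values are lateralization
#' relative to the hand that maps to up-choices in the block; more negative
#' values mean preparation toward the up choice.
#'
#' @param y Numeric matrix, trials in rows, timepoints in columns.
#' @param times Strictly increasing numeric time axis, length `ncol(y)`.
#' @param coding `"vs_up_hand"` or `"vs_button_press"`.
#' @param baseline_window Two-element window (s) used for baseline measures;
#'   default `c(-0.35, -0.10)`.
#' @param trial_info Optional tibble of per-trial metadata (one row per
#'   epoch row).
#' @return An object of class `neural_epochs`.
#' @export
neural_epochs <- function(y, times, coding = c("vs_up_hand", "vs_button_press"),
                          baseline_window = c(-0.35, -0.10),
                          trial_info = NULL) {
  coding <- match.arg(coding)
  y <- as.matrix(y)
  if (length(times) != ncol(y)) {
    stop("`times` must have one entry per column of `y`", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(trial_info) && nrow(trial_info) != nrow(y)) {
    stop("`trial_info` must have one row per epoch", call. = FALSE)
  }
  structure(
    list(y = y, times = as.numeric(times), coding = coding,
         baseline_window = baseline_window, trial_info = trial_info),
    class = "neural_epochs"
  )
}

#' @export
print.neural_epochs <- function(x, ...) {
  cat(sprintf("<neural_epochs> %d trials x %d timepoints (%.3f to %.3f s), coding %s\n",
              nrow(x$y), ncol(x$y), min(x$times), max(x$times), x$coding))
  invisible(x)
}

#' Turn epochs into a long tibble
#'
#' @param x A [neural_epochs] object.
#' @param ... Unused.
#' @return Tibble with `epoch`, `time`, `value` (plus any trial metadata).
#' @export
tidy.neural_epochs <- function(x, ...) {
  out <- tibble::tibble(
    epoch = rep(seq_len(nrow(x$y)), times = ncol(x$y)),
    time = rep(x$times, each = nrow(x$y)),
    value = as.vector(x$y)
  )
  if (!is.null(x$trial_info)) {
    out <- dplyr::bind_cols(
      out,
      x$trial_info[rep(seq_len(nrow(x$y)), times = ncol(x$y)), , drop = FALSE]
    )
  }
  out
}

baseline_columns <- function(epochs) {
  which(epochs$times >= epochs$baseline_window[1] - 1e-9 &
          epochs$times <= epochs$baseline_window[2] + 1e-9)
}

#' Mean lateralization over the baseline window
#'
#' @param epochs A [neural_epochs] object.
#' @return One value per trial: the epoch averaged over the baseline window
#'   (default -0.35 to -0.10 s before evidence onset).
#' @export
baseline_amplitude <- function(epochs) {
  rowMeans(epochs$y[, baseline_columns(epochs), drop = FALSE])
}

#' Decibel transform of power relative to baseline
#'
#' `10 * log10(power / baseline)`: the standard normalisation of
#' time-frequency power by the trial-averaged baseline power before
#' computing lateralization.
#'
#' @param power,baseline_power Positive power values (vectors recycle).
#' @return Power change in dB.
#' @examples
#' db_transform(10, 1) # 10
#' db_transform(0.5, 1) # about -3.01
#' @export
db_transform <- function(power, baseline_power) {
  if (any(power <= 0) || any(baseline_power <= 0)) {
    stop("power and baseline must be strictly positive", call. = FALSE)
  }
  10 * log10(power / baseline_power)
}

#' Previous-choice rebound template
#'
#' The post-movement beta rebound spills from the previous trial into the
#' current epoch with a sign tied to the previous response hand. Its
#' template is estimated as the trial-averaged epoch coded relative to the
#' previous choice (each epoch multiplied by the previous-choice code before
#' averaging) and normalised to a unit vector.
#'
#' @param epochs A [neural_epochs] object.
#' @param prev_choice Previous-choice codes (+1/-1; 0 rows are ignored).
#'   Defaults to `epochs$trial_info$prev_choice`.
#' @return Unit-norm numeric vector over the epoch's timepoints.
#' @export
rebound_template <- function(epochs, prev_choice = NULL) {
  prev_choice <- prev_choice %||% epochs$trial_info$prev_choice
  if (is.null(prev_choice) || length(prev_choice) != nrow(epochs$y)) {
    stop("`prev_choice` must supply one code per epoch", call. = FALSE)
  }
  keep <- prev_choice != 0
  r <- colMeans(epochs$y[keep, , drop = FALSE] * prev_choice[keep])
  nrm <- sqrt(sum(r^2))
  if (nrm == 0) stop("rebound template is identically zero", call. = FALSE)
  r / nrm
}

#' Project out the beta-rebound component
#'
#' Removes from each epoch its projection onto a unit-norm rebound template
#' `r`: \eqn{y^* = y - (y^\top r)\, r}. The operation is an orthogonal
#' projection, hence idempotent, and the residual is orthogonal to `r`.
#'
#' @param epochs A [neural_epochs] object or a numeric matrix/vector.
#' @param r Unit-norm template over the same timepoints (see
#'   [rebound_template()]).
#' @return Same type as the input, with the rebound component removed.
#' @examples
#' remove_rebound(c(1, 1), c(1, 0)) # c(0, 1)
#' @export
remove_rebound <- function(epochs, r) {
  if (abs(sum(r^2) - 1) > 1e-8) {
    stop("`r` must be a unit vector", call. = FALSE)
  }
  if (inherits(epochs, "neural_epochs")) {
    epochs$y <- remove_rebound(epochs$y, r)
    return(epochs)
  }
  y <- epochs
  if (is.null(dim(y))) return(y - sum(y * r) * r)
  if (ncol(y) != length(r)) stop("length mismatch", call. = FALSE)
  y - (y %*% r) %*% t(r)
}

#' Define the linear build-up window from a bilinear fit
#'
#' Fits a continuous two-segment (hinge) regression to the trial-averaged
#' lateralization over the evidence interval,
#' \eqn{y(t) = b_0 + b_1 t + b_2 \max(0, t - \tau)}, with the breakpoint
#' \eqn{\tau} searched over the observed timepoints, and derives the window
#' used to quantify the build-up of lateralization: it starts a buffer
#' (default 250 ms) after the breakpoint and ends a buffer (default 50 ms)
#' before the time of the signal minimum.
#'
#' @param timecourse Trial-averaged lateralization values.
#' @param times Matching time axis (s).
#' @param evidence_interval Interval over which the hinge is fitted and the
#'   breakpoint searched (default `c(0, 0.75)` s).
#' @param buffer_start,buffer_end Buffers after the breakpoint and before
#'   the minimum (defaults 0.25 and 0.05 s).
#' @param search_min Interval within which the minimum is located (default
#'   from evidence onset to the end of the epoch).
#' @return List of class `ramp_window`: `start`, `end`, `breakpoint`,
#'   `minimum_time`, `degenerate` (breakpoint at the search-grid boundary,
#'   indicating no real kink). Errors if the window is empty.
#' @examples
#' t <- seq(0, 1.5, by = 0.025)
#' y <- -pmax(0, t - 0.33); y[t > 0.8975] <- y[t == 0.8975]
#' bilinear_window(y, t)
#' @export
bilinear_window <- function(timecourse, times,
                            evidence_interval = c(0, 0.75),
                            buffer_start = 0.25, buffer_end = 0.05,
                            search_min = NULL) {
  stopifnot(length(timecourse) == length(times))
  in_ev <- which(times >= evidence_interval[1] - 1e-9 &
                   times <= evidence_interval[2] + 1e-9)
  if (length(in_ev) < 4) stop("too few timepoints in the evidence interval",
                              call. = FALSE)
  tt <- times[in_ev]
  yy <- timecourse[in_ev]
  grid <- tt[2:(length(tt) - 1)] # interior breakpoints only
  sse <- vapply(grid, function(tau) {
    X <- cbind(1, tt, pmax(0, tt - tau))
    fit <- stats::lm.fit(X, yy)
    sum(fit$residuals^2)
  }, numeric(1))
  # first breakpoint within numerical tolerance of the optimum (ties resolve
  # to the earliest candidate, which also catches an exactly linear input)
  best <- which(sse <= min(sse) + 1e-10 * (1 + min(sse)))[1]
  breakpoint <- grid[best]
  sse_line <- {
    fit <- stats::lm.fit(cbind(1, tt), yy)
    sum(fit$residuals^2)
  }
  degenerate <- best %in% c(1L, length(grid)) ||
    (sse_line - min(sse)) <= 1e-6 * (1 + sse_line)

  search_min <- search_min %||% c(evidence_interval[1], max(times))
  in_min <- which(times >= search_min[1] - 1e-9 & times <= search_min[2] + 1e-9)
  minimum_time <- times[in_min][which.min(timecourse[in_min])]

  start <- breakpoint + buffer_start
  end <- minimum_time - buffer_end
  if (start >= end) {
    stop(sprintf("empty build-up window: start %.4f >= end %.4f", start, end),
         call. = FALSE)
  }
  structure(
    list(start = start, end = end, breakpoint = breakpoint,
         minimum_time = minimum_time, degenerate = degenerate),
    class = "ramp_window"
  )
}

#' @export
print.ramp_window <- function(x, ...) {
  cat(sprintf("<ramp_window> [%.4f, %.4f] s (breakpoint %.4f, minimum %.4f)%s\n",
              x$start, x$end, x$breakpoint, x$minimum_time,
              if (x$degenerate) " [degenerate hinge]" else ""))
  invisible(x)
}

#' Choice-balanced average of a bias bin
#'
#' Within a bias bin the behavioral choice is correlated with the bias, so a
#' raw bin average confounds bias-related and choice-related lateralization.
#' This routine removes the choice confound by resampling: every draw keeps
#' all trials of the minority choice plus an equally sized random subset
#' (without replacement) of the majority choice, epochs are averaged within
#' the draw, and the draw averages are averaged over `n_draws` repetitions.
#'
#' @param y Epoch matrix for the trials of one bin (rows = trials).
#' @param choice Choice codes (+1/-1) for those trials.
#' @param n_draws Number of resampling draws (default 1000).
#' @param seed Integer seed.
#' @return Averaged time course (one value per timepoint). Errors if the
#'   bin contains only one choice.
#' @export
choice_balanced_subsample <- function(y, choice, n_draws = 1000, seed = 1) {
  y <- as.matrix(y)
  stopifnot(length(choice) == nrow(y))
  n_up <- sum(choice == 1)
  n_dn <- sum(choice == -1)
  if (n_up == 0 || n_dn == 0) {
    stop("bin contains only one choice; cannot balance", call. = FALSE)
  }
  minority <- if (n_up <= n_dn) 1 else -1
  idx_min <- which(choice == minority)
  idx_maj <- which(choice == -minority)
  m <- length(idx_min)
  sum_min <- colSums(y[idx_min, , drop = FALSE])
  with_seed(seed, {
    acc <- numeric(ncol(y))
    for (i in seq_len(n_draws)) {
      pick <- if (length(idx_maj) == m) idx_maj else sample(idx_maj, m)
      acc <- acc + (sum_min + colSums(y[pick, , drop = FALSE])) / (2 * m)
    }
    acc / n_draws
  })
}

#' Bias-locked lateralization time course
#'
#' Combines the (choice-balanced) average epochs of the low and high bias
#' bins into a single trace coded toward the bias direction: the low bin is
#' sign-flipped and averaged with the high bin, \eqn{(-y_{low} + y_{high})/2}.
#' Negative values mean lateralization toward the direction of the bias.
#'
#' @param low_bin,high_bin Averaged time courses of the two outer bias bins,
#'   both coded relative to the up-coding hand.
#' @return Time course of the same length.
#' @export
bias_locked_average <- function(low_bin, high_bin) {
  stopifnot(length(low_bin) == length(high_bin))
  (-low_bin + high_bin) / 2
}

#' Slope of a time course within a window
#'
#' Ordinary least-squares slope of the values against time, restricted to
#' `window` (a [ramp_window] or a two-element numeric interval).
#'
#' @param timecourse Numeric values.
#' @param times Matching time axis.
#' @param window A `ramp_window` or `c(start, end)` in seconds.
#' @return Slope in units per second.
#' @examples
#' t <- seq(0, 1, by = 0.025)
#' ramp_slope(-2 * t, t, c(0.2, 0.8)) # -2
#' @export
ramp_slope <- function(timecourse, times, window) {
  if (inherits(window, "ramp_window")) window <- c(window$start, window$end)
  idx <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(idx) < 3) stop("need at least 3 samples inside the window",
                            call. = FALSE)
  tt <- times[idx]
  yy <- timecourse[idx]
  sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
}
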