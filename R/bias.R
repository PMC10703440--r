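#' Cross-fitted single-trial bias estimates
#'
#' Computes \eqn{\delta(h_t)} for every trial using parameters fitted
#' *without* that trial's block: for each block, the model (at the selected
#' order) is refitted on the remaining blocks of the same subject and
#' environment, and the held-out block's biases are evaluated from those
#' training weights. This cross-fitting guarantees that the single-trial
#' estimates are not contaminated by the data they are later used to
#' predict. Positive values are a bias toward the up choice.
#'
#' @param trials Trial tibble.
#' @param order Either a single model order for all groups, or a
#'   `model_order` tibble from [select_model_order()] (its `n_use` column is
#'   used).
#' @param restarts,seed Passed to [fit_history_model()].
#' @return A tibble of class `bias_series` aligned with `trials` (keys
#'   `subject`, `session`, `block`, `environment`, `trial`) with columns
#'   `delta` (the cross-fitted bias) and `fold` (the held-out block whose
#'   training fit produced the weights).
#' @examples
#' \donttest{
#' sim <- simulate_experiment(1, environments = "neutral", coefs = NULL,
#'                            blocks = 3, seed = 1)
#' bias <- single_trial_bias(sim$trials, order = 1)
#' head(bin_bias(bias))
#' }
#' @export
single_trial_bias <- function(trials, order, restarts = 2, seed = 1) {
  groups <- dplyr::distinct(trials, .data$subject, .data$environment)
  out <- purrr::pmap(groups, function(subject, environment) {
    tb <- trials[trials$subject == subject &
                   trials$environment == environment, , drop = FALSE]
    n <- lookup_order(order, subject, environment)
    blocks <- sort(unique(tb$block))
    if (length(blocks) < 2) {
      stop("cross-fitted bias needs at least two blocks per environment",
           call. = FALSE)
    }
    per_block <- purrr::map(blocks, function(b) {
      train <- tb[tb$block != b, , drop = FALSE]
      test <- tb[tb$block == b, , drop = FALSE]
      fit <- fit_history_model(train, n_lags = n, restarts = restarts,
                               seed = derive_seed(seed, b + 31 * subject))
      H <- history_matrix(test, n)
      tibble::tibble(
        subject = test$subject,
        session = test$session,
        block = test$block,
        environment = test$environment,
        trial = test$trial,
        delta = as.numeric(bias_term(fit$params, H)),
        fold = b
      )
    })
    dplyr::bind_rows(per_block)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("bias_series", class(out))
  out
}

lookup_order <- function(order, subject, environment) {
  if (is.numeric(order) && length(order) == 1) return(as.integer(order))
  stopifnot(inherits(order, "model_order") || is.data.frame(order))
  row <- order[order$subject == subject & order$environment == environment, ]
  if (nrow(row) != 1) {
    stop(sprintf("no model order for subject %s / %s", subject, environment),
         call. = FALSE)
  }
  as.integer(row$n_use)
}

#' Bin single-trial biases into terciles
#'
#' Splits each subject's bias values (pooled across environments) into three
#' bins of (as near as possible) equal size at the 33% and 66% quantiles:
#' `low` (bias toward down), `medium` (little bias), `high` (bias toward
#' up). Ties at a bin boundary are assigned stably by trial order, so bin
#' sizes never differ by more than the number of tied values.
#'
#' @param bias A `bias_series` tibble from [single_trial_bias()] (any tibble
#'   with `subject` and `delta` columns works).
#' @param bins Number of bins (default 3).
#' @return The input with an ordered factor column `bin` added.
#' @export
bin_bias <- function(bias, bins = 3) {
  bins <- assert_count(bins, "bins")
  if (any(dplyr::count(bias, .data$subject)$n < bins)) {
    stop("need at least as many trials as bins per subject", call. = FALSE)
  }
  labels <- if (bins == 3) c("low", "medium", "high") else
    paste0("bin", seq_len(bins))
  out <- bias |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(bin = factor(labels[dplyr::ntile(.data$delta, bins)],
                               levels = labels, ordered = TRUE)) |>
    dplyr::ungroup()
  class(out) <- unique(c("bias_series", class(out)))
  out
}
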