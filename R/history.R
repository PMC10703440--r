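#' Build the history design matrix
#'
#' For every trial, the history vector
#' \eqn{h_t = (c_{t-1}, \ldots, c_{t-n}, z_{t-1}, \ldots, z_{t-n})} collects
#' the previous `n` choices and previous `n` stimulus categories, coded
#' up = +1 / down = -1. Zero-coherence stimuli are coded 0 (the stimulus
#' carried no direction signal), while the choices made on such trials enter
#' the choice kernel unchanged. Lags reaching before the first trial of a
#' block are coded 0; history never crosses block boundaries.
#'
#' @param trials Trial tibble with `choice`, `category`, `coherence` and the
#'   block keys `subject`, `environment`, `block` (rows ordered by trial
#'   within block).
#' @param n_lags Model order `n >= 0`.
#' @return A numeric matrix with `nrow(trials)` rows and `2 * n_lags`
#'   columns: `choice_lag1..n`, then `stim_lag1..n`.
#' @examples
#' env <- environment_spec("neutral", blocks = 1)
#' tr <- simulate_choices(simulate_stimuli(env, 1), model_params(), 2)
#' head(history_matrix(tr, 2))
#' @export
history_matrix <- function(trials, n_lags) {
  n_lags <- if (n_lags == 0) 0L else assert_count(n_lags, "n_lags")
  n <- nrow(trials)
  if (n_lags == 0L) return(matrix(numeric(0), nrow = n, ncol = 0))
  key <- paste(trials$subject %||% 1, trials$environment %||% "e",
               trials$block %||% 1, sep = "\r")
  z <- ifelse(trials$coherence > 0, trials$category, 0)
  ch <- as.numeric(trials$choice)
  ch[is.na(ch)] <- 0 # no-response trials contribute no choice signal
  H <- matrix(0, nrow = n, ncol = 2L * n_lags)
  for (k in seq_len(n_lags)) {
    idx <- seq_len(n) - k
    ok <- idx >= 1 & key == c(rep(NA, k), key[seq_len(n - k)])[seq_len(n)]
    ok[is.na(ok)] <- FALSE
    H[ok, k] <- ch[idx[ok]]
    H[ok, n_lags + k] <- z[idx[ok]]
  }
  colnames(H) <- c(paste0("choice_lag", seq_len(n_lags)),
                   paste0("stim_lag", seq_len(n_lags)))
  H
}

#' History vector for a single trial
#'
#' Extracts \eqn{h_t} for one trial (indexed within the full table); a
#' convenience wrapper around [history_matrix()].
#'
#' @inheritParams history_matrix
#' @param t Row index of the trial in `trials`.
#' @return Numeric vector of length `2 * n_lags`.
#' @export
history_vector <- function(trials, t, n_lags) {
  stopifnot(t >= 1, t <= nrow(trials))
  unname(drop(history_matrix(trials, n_lags)[t, , drop = FALSE]))
}
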