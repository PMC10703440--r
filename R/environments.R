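#' Define a sensory environment
#'
#' A sensory environment is a first-order Markov process on the stimulus
#' category (motion direction, up = +1 / down = -1) with a fixed probability
#' `p_rep` that the category repeats from one trial to the next. Three named
#' environments are used throughout: `repetitive` (`p_rep = 0.8`), `neutral`
#' (`p_rep = 0.5`) and `alternating` (`p_rep = 0.2`). Trials are organised in
#' blocks (99 trials by default) and each block carries a balanced set of
#' motion coherences (0, 3, 9, 27 and 81 percent by default, as unsigned
#' fractions).
#'
#' @param name One of `"repetitive"`, `"neutral"`, `"alternating"`.
#' @param p_rep Repetition probability in `[0, 1]`. Defaults to 0.8 / 0.5 /
#'   0.2 for the three named environments.
#' @param coherence_levels Unsigned motion coherences as fractions; must
#'   include the levels to balance within each block. A 0 level denotes pure
#'   noise trials whose stimulus-history code is 0.
#' @param trials_per_block Trials per block (default 99).
#' @param blocks Number of blocks (default 6, as in a full per-environment
#'   session set).
#'
#' @return An object of class `environment_spec`.
#' @examples
#' environment_spec("repetitive")
#' environment_spec("neutral", blocks = 2)
#' @export
environment_spec <- function(name = c("repetitive", "neutral", "alternating"),
                             p_rep = NULL,
                             coherence_levels = c(0, 0.03, 0.09, 0.27, 0.81),
                             trials_per_block = 99,
                             blocks = 6) {
  name <- match.arg(name)
  if (is.null(p_rep)) {
    p_rep <- c(repetitive = 0.8, neutral = 0.5, alternating = 0.2)[[name]]
  }
  assert_scalar_prob(p_rep, "p_rep")
  trials_per_block <- assert_count(trials_per_block, "trials_per_block")
  blocks <- assert_count(blocks, "blocks")
  if (!is.numeric(coherence_levels) || any(coherence_levels < 0) ||
      any(coherence_levels > 1) || anyDuplicated(coherence_levels)) {
    stop("`coherence_levels` must be distinct fractions in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      name = name,
      p_rep = p_rep,
      coherence_levels = sort(coherence_levels),
      trials_per_block = trials_per_block,
      blocks = blocks
    ),
    class = "environment_spec"
  )
}

#' @export
print.environment_spec <- function(x, ...) {
  cat(sprintf(
    "<environment_spec> %s: p_rep = %.2f, %d block(s) x %d trials, coherences {%s}\n",
    x$name, x$p_rep, x$blocks, x$trials_per_block,
    paste(x$coherence_levels, collapse = ", ")
  ))
  invisible(x)
}
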