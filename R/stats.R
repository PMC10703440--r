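#' One-sample (sign-flip) permutation test
#'
#' Nonparametric test of whether a statistic of paired differences (or any
#' values exchangeable around zero) differs from zero. The null distribution
#' is built by randomly flipping the sign of each value; the p-value uses
#' the add-one rule \eqn{p = (1 + \#\{null \ge observed\}) / (N + 1)}, so
#' the smallest attainable p is \eqn{1/(N+1)}.
#'
#' @param x Numeric vector (e.g. per-subject effects or paired differences).
#' @param statistic Function mapping a vector to a scalar (default `mean`).
#' @param tails `"two"`, `"greater"` or `"less"`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List of class `permutation_test`: `observed`, `p.value`,
#'   `n_perm`, `tails`, `null` (the permutation distribution).
#' @examples
#' set.seed(1)
#' permutation_test(rnorm(20, 0.8), n_perm = 500, seed = 2)$p.value
#' @export
permutation_test <- function(x, statistic = mean,
                             tails = c("two", "greater", "less"),
                             n_perm = 10000, seed = 1) {
  tails <- match.arg(tails)
  n_perm <- assert_count(n_perm, "n_perm")
  obs <- statistic(x)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      statistic(x * sample(c(-1, 1), length(x), replace = TRUE))
    }, numeric(1))
  })
  p <- switch(tails,
    two = (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1),
    greater = (1 + sum(null >= obs)) / (n_perm + 1),
    less = (1 + sum(null <= obs)) / (n_perm + 1)
  )
  structure(
    list(observed = obs, p.value = p, n_perm = n_perm, tails = tails,
         null = null),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> observed = %.4g, p = %.4g (%s-tailed, N = %d)\n",
              x$observed, x$p.value, x$tails, x$n_perm))
  invisible(x)
}

#' @export
tidy.permutation_test <- function(x, ...) {
  tibble::tibble(estimate = x$observed, p.value = x$p.value,
                 n_perm = x$n_perm, tails = x$tails)
}

#' Cluster-based permutation test on a 1-D time course
#'
#' Controls the family-wise error of a per-timepoint paired test across a
#' time axis. A one-sample t statistic is computed per timepoint across
#' subjects; contiguous runs of same-sign suprathreshold t values form
#' clusters with mass equal to the summed t; each observed cluster mass is
#' compared against the permutation distribution of the maximum absolute
#' cluster mass under random per-subject sign flips.
#'
#' @param mat Subjects x timepoints matrix of effect values (e.g. per-subject
#'   contrast time courses).
#' @param threshold Cluster-forming threshold on |t|; default the two-tailed
#'   t critical value at `p < 0.05` with `nrow(mat) - 1` df.
#' @param n_perm Number of sign-flip permutations (default 1000).
#' @param seed Integer seed.
#' @param times Optional time axis for labelling clusters.
#' @return List of class `cluster_test`: `clusters` (tibble with `start`,
#'   `end` indices, `time_start`/`time_end` if `times` given, `mass`,
#'   `p.value`), `threshold`, `t` (per-timepoint statistics), `null_max`
#'   (the permutation null). No suprathreshold points gives an empty
#'   cluster table.
#' @export
cluster_permutation_1d <- function(mat, threshold = NULL, n_perm = 1000,
                                   seed = 1, times = NULL) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  threshold <- threshold %||% stats::qt(0.975, n - 1)
  # sign flips leave the column sums of squares invariant, so the whole
  # permutation family of t statistics reduces to one matrix product
  css <- colSums(mat^2)
  t_from_means <- function(mu) {
    v <- (css - n * mu^2) / (n - 1)
    mu / sqrt(v / n)
  }
  t_obs <- t_from_means(colMeans(mat))
  obs <- find_clusters(t_obs, threshold)
  null_max <- with_seed(seed, {
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    mu_perm <- flips %*% mat / n
    vapply(seq_len(n_perm), function(i) {
      max_cluster_mass(t_from_means(mu_perm[i, ]), threshold)
    }, numeric(1))
  })
  if (nrow(obs) > 0) {
    obs$p.value <- vapply(obs$mass, function(m) {
      (1 + sum(null_max >= abs(m))) / (n_perm + 1)
    }, numeric(1))
    if (!is.null(times)) {
      obs$time_start <- times[obs$start]
      obs$time_end <- times[obs$end]
    }
  }
  structure(
    list(clusters = obs, threshold = threshold, t = t_obs,
         null_max = null_max, n_perm = n_perm),
    class = "cluster_test"
  )
}

# largest absolute cluster mass (fast path used inside the permutation loop)
max_cluster_mass <- function(t, threshold) {
  t[is.na(t)] <- 0
  above <- abs(t) > threshold
  if (!any(above)) return(0)
  sgn <- sign(t) * above
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  csum <- c(0, cumsum(t))
  keep <- runs$values != 0
  max(abs(csum[ends[keep] + 1] - csum[ends[keep] - runs$lengths[keep] + 1]))
}

# maximal contiguous same-sign runs of |t| > threshold
find_clusters <- function(t, threshold) {
  above <- abs(t) > threshold
  above[is.na(above)] <- FALSE # constant columns yield undefined t
  t[is.na(t)] <- 0
  sgn <- sign(t) * above
  runs <- rle(sgn)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values != 0
  tibble::tibble(
    start = starts[keep],
    end = ends[keep],
    mass = purrr::map2_dbl(starts[keep], ends[keep], ~ sum(t[.x:.y]))
  )
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s), |t| threshold %.3f, N = %d\n",
              nrow(x$clusters), x$threshold, x$n_perm))
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' @export
tidy.cluster_test <- function(x, ...) x$clusters

#' Rayleigh test of circular uniformity
#'
#' Tests whether a sample of angles is clustered around a common direction.
#' Computes the mean resultant length \eqn{\bar{R}}, the Rayleigh statistic
#' \eqn{z = n \bar{R}^2}, and the standard series approximation of the
#' p-value \eqn{p = \exp(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n))} with
#' \eqn{R = n\bar{R}}.
#'
#' @param angles Angles in radians, `n >= 3`.
#' @return Tibble: `r_bar`, `statistic` (z), `p.value`, `n`,
#'   `mean_direction`.
#' @examples
#' rayleigh_test(rep(0.5, 10))
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 3) stop("need at least 3 angles", call. = FALSE)
  C <- mean(cos(angles)); S <- mean(sin(angles))
  r_bar <- sqrt(C^2 + S^2)
  z <- n * r_bar^2
  R <- n * r_bar
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  tibble::tibble(
    r_bar = r_bar, statistic = z, p.value = min(1, p), n = n,
    mean_direction = atan2(S, C)
  )
}

#' Paired Hotelling T-squared test on 2-D observations
#'
#' One-sample Hotelling test on the pairwise differences of paired
#' bivariate observations (e.g. (stimulus-weight, choice-weight) points per
#' subject in two environments): \eqn{T^2 = n\, \bar{d}^\top S^{-1} \bar{d}}
#' with the usual F transform \eqn{F = \frac{n - p}{p(n - 1)} T^2} on
#' `(p, n - p)` degrees of freedom.
#'
#' @param x,y n x 2 matrices of paired observations. Alternatively pass the
#'   difference matrix as `x` and omit `y`.
#' @return Tibble: `statistic` (T2), `f`, `df1`, `df2`, `p.value`, `n`.
#' @examples
#' set.seed(1)
#' hotelling_paired(matrix(rnorm(60, 1), 30), matrix(rnorm(60), 30))
#' @export
hotelling_paired <- function(x, y = NULL) {
  d <- if (is.null(y)) as.matrix(x) else as.matrix(x) - as.matrix(y)
  n <- nrow(d); p <- ncol(d)
  if (n <= p) stop("need more pairs than dimensions", call. = FALSE)
  dbar <- colMeans(d)
  if (all(dbar == 0)) {
    return(tibble::tibble(statistic = 0, f = 0, df1 = p, df2 = n - p,
                          p.value = 1, n = n))
  }
  S <- stats::cov(d)
  if (abs(det(S)) < 1e-14) stop("singular covariance of differences",
                                call. = FALSE)
  t2 <- n * drop(t(dbar) %*% solve(S, dbar))
  f <- (n - p) / (p * (n - 1)) * t2
  tibble::tibble(
    statistic = t2, f = f, df1 = p, df2 = n - p,
    p.value = stats::pf(f, p, n - p, lower.tail = FALSE), n = n
  )
}
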