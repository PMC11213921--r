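## Bootstrap randomization tests, grand means with bootstrap CIs, and
## Bonferroni adjustment -- the statistical machinery used throughout
## the behavioral and imaging analyses.

#' Paired bootstrap randomization test
#'
#' Tests whether paired differences have mean zero using the statistic
#' \eqn{T = |\bar{x}| / (\sigma_x / \sqrt{n})}, where \eqn{\sigma_x} uses
#' the \eqn{n-1} denominator. The null distribution is generated by
#' random sign flips of the differences; two-tailedness is carried by
#' the absolute value in \eqn{T}. The p-value is
#' \code{max(count_ge, 1) / B}, so the smallest achievable p is
#' exactly \code{1/B}. Resamples that tie the observed statistic count
#' toward the numerator (conservative).
#'
#' @param x numeric vector of paired differences, length >= 2.
#' @param B number of random sign-flip resamples (default 1e7 as used
#'   for inference on the real data; tests use far fewer).
#' @param seed integer seed; all randomness is local to the call.
#' @return an object of class \code{"randomization_result"}: a list with
#'   \code{T_observed}, \code{B}, \code{count_ge}, \code{p},
#'   \code{scheme} and \code{seed}.
#' @examples
#' paired_randomization_test(c(1, 2, 3), B = 1e4, seed = 1)
#' @export
paired_randomization_test <- function(x, B = 1e7, seed = 1) {
  x <- as.numeric(x)
  n <- length(x)
  .check(n >= 2, "need at least 2 paired differences")
  .check(all(is.finite(x)), "differences must be finite")
  .check(B >= 1, "B must be >= 1")
  s <- stats::sd(x)
  .check(s > 0, "degenerate statistic: zero-variance differences")
  T_obs <- abs(mean(x)) / (s / sqrt(n))
  count <- with_seed(seed, {
    total <- 0L
    done <- 0
    chunk <- max(1, min(1e6 %/% n, B))
    while (done < B) {
      b <- min(chunk, B - done)
      signs <- matrix(sample(c(-1, 1), n * b, replace = TRUE), nrow = n)
      xs <- signs * x
      m <- colMeans(xs)
      v <- (colSums(xs * xs) - n * m * m) / (n - 1)
      Tb <- abs(m) / sqrt(v / n)
      total <- total + sum(Tb >= T_obs - 1e-12)
      done <- done + b
    }
    total
  })
  structure(list(T_observed = T_obs, B = B, count_ge = count,
                 p = max(count, 1) / B, scheme = "sign-flip", seed = seed),
            class = "randomization_result")
}

#' Two-sample bootstrap randomization test
#'
#' Tests for a difference in means between independent groups using
#' \eqn{T = |\bar{z} - \bar{y}| / \sqrt{\sigma_z^2/n + \sigma_y^2/m}}
#' (Welch-style denominator, \eqn{n-1} variance). The null distribution
#' is generated by random reassignments of group labels preserving the
#' group sizes. p-value convention as in
#' \code{\link{paired_randomization_test}}.
#'
#' @param z,y numeric vectors, each of length >= 2.
#' @inheritParams paired_randomization_test
#' @return a \code{"randomization_result"} (see
#'   \code{\link{paired_randomization_test}}).
#' @examples
#' two_sample_randomization_test(c(0, 1), c(10, 11), B = 1e4, seed = 1)
#' @export
two_sample_randomization_test <- function(z, y, B = 1e7, seed = 1) {
  z <- as.numeric(z); y <- as.numeric(y)
  n <- length(z); m <- length(y)
  .check(n >= 2 && m >= 2, "both groups need at least 2 observations")
  .check(all(is.finite(c(z, y))), "observations must be finite")
  denom_obs <- sqrt(stats::var(z) / n + stats::var(y) / m)
  .check(denom_obs > 0, "degenerate statistic: zero pooled variance")
  T_obs <- abs(mean(z) - mean(y)) / denom_obs
  pool <- c(z, y)
  N <- n + m
  count <- with_seed(seed, {
    total <- 0L
    done <- 0
    chunk <- max(1, min(1e6 %/% N, B))
    while (done < B) {
      b <- min(chunk, B - done)
      # column-wise random permutations via ranks of iid uniforms:
      # the n smallest uniforms in a column define that resample's z group
      u <- matrix(stats::runif(N * b), nrow = N)
      r <- apply(u, 2, order)
      zi <- matrix(pool[r[seq_len(n), , drop = FALSE]], nrow = n)
      yi <- matrix(pool[r[n + seq_len(m), , drop = FALSE]], nrow = m)
      mz <- colMeans(zi); my <- colMeans(yi)
      vz <- (colSums(zi * zi) - n * mz * mz) / (n - 1)
      vy <- (colSums(yi * yi) - m * my * my) / (m - 1)
      Tb <- abs(mz - my) / sqrt(vz / n + vy / m)
      total <- total + sum(Tb >= T_obs - 1e-12, na.rm = TRUE)
      done <- done + b
    }
    total
  })
  structure(list(T_observed = T_obs, B = B, count_ge = count,
                 p = max(count, 1) / B, scheme = "label-permutation",
                 seed = seed),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("Randomization test (%s): T = %.4g, p = %.4g (B = %g)\n",
              x$scheme, x$T_observed, x$p, x$B))
  invisible(x)
}

#' Grand mean with bootstrap confidence interval
#'
#' The grand mean is the mean of animal means; the 95% interval is the
#' 2.5/97.5 percentile of bootstrap-resampled grand means.
#'
#' @param animal_means numeric vector, one mean per animal.
#' @param n_boot bootstrap sample count (default 5000).
#' @param seed integer seed.
#' @return list with \code{mean}, \code{ci95} (length-2),
#'   \code{n_boot}, and \code{degenerate} flag (TRUE when only one
#'   animal is supplied, in which case the interval collapses to the
#'   point).
#' @export
grand_mean_ci <- function(animal_means, n_boot = 5000, seed = 1) {
  x <- as.numeric(animal_means)
  .check(length(x) >= 1, "need at least one animal mean")
  .check(all(is.finite(x)), "animal means must be finite")
  gm <- mean(x)
  if (length(x) == 1) {
    return(list(mean = gm, ci95 = c(gm, gm), n_boot = n_boot,
                degenerate = TRUE))
  }
  boots <- with_seed(seed, {
    idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                  nrow = length(x))
    colMeans(matrix(x[idx], nrow = length(x)))
  })
  ci <- unname(stats::quantile(boots, c(0.025, 0.975), type = 7))
  list(mean = gm, ci95 = ci, n_boot = n_boot, degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param m_comparisons number of comparisons (default: number of
#'   p-values supplied).
#' @return adjusted p-values, \code{pmin(1, p * m)}.
#' @export
bonferroni <- function(p_values, m_comparisons = length(p_values)) {
  .check(m_comparisons >= 1, "m_comparisons must be >= 1")
  .check(all(p_values >= 0 & p_values <= 1), "p-values must lie in [0, 1]")
  pmin(1, p_values * m_comparisons)
}
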