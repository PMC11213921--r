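#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# stopifnot-style check with a formatted message
.check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

# Run `expr` under a locally-seeded RNG without touching the caller's
# global random state. All exported stochastic functions route through
# this so randomness is fully threaded from explicit seeds.
with_seed <- function(seed, expr) {
  .check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
         "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a parent seed (keeps results
# of independent sub-generators decoupled while staying < 2^31).
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 7919) %% 2147483647
}

# Separable 1-D convolution of each column of `x` with kernel `k`
# (odd length), with the requested boundary mode. Used by the spatial
# filters; exact (direct) convolution, no FFT rounding surprises.
conv1_cols <- function(x, k, boundary = c("reflect", "zero", "renorm")) {
  boundary <- match.arg(boundary)
  n <- nrow(x); hw <- (length(k) - 1L) %/% 2L
  .check(length(k) %% 2L == 1L, "kernel length must be odd")
  if (boundary == "reflect") {
    idx <- c(rev(seq_len(min(hw, n))), seq_len(n), n + 1 - rev(seq_len(min(hw, n))))
    # pad by reflection (no repeated edge sample beyond what's available)
    top <- pmin(pmax(rev(seq_len(hw) + 1L), 1L), n)
    bot <- pmin(pmax(n - seq_len(hw), 1L), n)
    xp <- rbind(x[top, , drop = FALSE], x, x[bot, , drop = FALSE])
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) {
      out <- out + k[j] * xp[(j - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  } else {
    # zero padding; optionally renormalize partial kernels at the edges
    xp <- rbind(matrix(0, hw, ncol(x)), x, matrix(0, hw, ncol(x)))
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) {
      out <- out + k[j] * xp[(j - 1L) + seq_len(n), , drop = FALSE]
    }
    if (boundary == "renorm") {
      # effective kernel mass at each output position
      ones <- rbind(matrix(0, hw, 1), matrix(1, n, 1), matrix(0, hw, 1))
      mass <- vapply(seq_len(n), function(i) {
        sum(k * ones[(i):(i + 2L * hw), 1])
      }, numeric(1))
      out <- out / mass
    }
    out
  }
}

# Gaussian kernel of standard deviation `sd` (in samples), truncated at
# `radius` samples (default 4 sd), renormalized to unit mass.
gaussian_kernel <- function(sd, radius = ceiling(4 * sd)) {
  .check(sd > 0, "kernel sd must be positive")
  t <- seq.int(-radius, radius)
  k <- exp(-0.5 * (t / sd)^2)
  k / sum(k)
}

# population (divide-by-n) variance/sd along rows of a matrix
.rowsd_pop <- function(x) {
  m <- rowMeans(x)
  sqrt(pmax(rowMeans(x * x) - m * m, 0))
}

# row-wise medians of a numeric matrix via one radix sort
# (vectorized; base R has no rowMedians)
.row_medians <- function(D) {
  m <- nrow(D); n <- ncol(D)
  if (m == 0) return(numeric(0))
  v <- as.vector(t(D)) # row-major
  ord <- order(rep(seq_len(m), each = n), v, method = "radix")
  S <- matrix(v[ord], m, n, byrow = TRUE)
  if (n %% 2 == 1) S[, (n + 1) / 2] else (S[, n / 2] + S[, n / 2 + 1]) / 2
}
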