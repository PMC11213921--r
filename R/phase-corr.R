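## Rigid translation estimation by phase correlation, with subpixel
## peak interpolation, and Fourier-domain application of (possibly
## fractional) shifts. stats::fft supplies the transforms.

#' Estimate the rigid shift between two images by phase correlation
#'
#' Returns the translation \code{c(dy, dx)} such that shifting
#' \code{moving} by \code{-c(dy, dx)} (see \code{\link{fourier_shift}})
#' best aligns it to \code{fixed}; equivalently, \code{moving} looks
#' like \code{fixed} displaced by \code{(dy, dx)}. Integer circular
#' shifts are recovered exactly; subpixel shifts are estimated by
#' parabolic interpolation around the correlation peak. A flat (zero
#' variance) image yields a zero shift with a warning.
#'
#' @param fixed,moving numeric matrices of identical size.
#' @return numeric \code{c(dy, dx)}.
#' @export
phase_correlate <- function(fixed, moving) {
  .check(is.matrix(fixed) && is.matrix(moving) &&
           all(dim(fixed) == dim(moving)), "images must be same-size matrices")
  if (stats::sd(fixed) == 0 || stats::sd(moving) == 0) {
    warning("flat frame: returning zero shift")
    return(c(dy = 0, dx = 0))
  }
  Fa <- stats::fft(fixed)
  Fb <- stats::fft(moving)
  R <- Fa * Conj(Fb)
  mag <- Mod(R)
  mag[mag < 1e-15] <- 1
  r <- Re(stats::fft(R / mag, inverse = TRUE)) / length(fixed)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  n <- nrow(r); m <- ncol(r)
  # parabolic subpixel refinement along each axis (circular indexing)
  sub <- function(vm1, v0, vp1) {
    den <- vm1 - 2 * v0 + vp1
    if (abs(den) < 1e-12) 0 else 0.5 * (vm1 - vp1) / den
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dy <- (pk[1] - 1) + sub(r[wrap(pk[1] - 1, n), pk[2]], r[pk[1], pk[2]],
                          r[wrap(pk[1] + 1, n), pk[2]])
  dx <- (pk[2] - 1) + sub(r[pk[1], wrap(pk[2] - 1, m)], r[pk[1], pk[2]],
                          r[pk[1], wrap(pk[2] + 1, m)])
  if (dy > n / 2) dy <- dy - n
  if (dx > m / 2) dx <- dx - m
  # the correlation peak sits at minus the displacement of `moving`
  c(dy = unname(-dy), dx = unname(-dx))
}

#' Translate an image by a (fractional) shift in the Fourier domain
#'
#' Shifts the image content by \code{shift = c(dy, dx)} pixels
#' (positive = down/right) with circular boundary conditions; the
#' subpixel interpolation used when applying alignment shifts.
#'
#' @param img numeric matrix.
#' @param shift numeric \code{c(dy, dx)}.
#' @return shifted matrix.
#' @export
fourier_shift <- function(img, shift) {
  n <- nrow(img); m <- ncol(img)
  ky <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  if (n == 1) ky <- 0
  kx <- c(0:floor((m - 1) / 2), -(ceiling((m - 1) / 2):1))
  if (m == 1) kx <- 0
  py <- exp(-2i * pi * ky * shift[1] / n)
  px <- exp(-2i * pi * kx * shift[2] / m)
  Re(stats::fft(stats::fft(img) * outer(py, px), inverse = TRUE)) / (n * m)
}
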