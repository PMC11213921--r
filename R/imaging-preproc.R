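## Raw stimulus stacks -> aligned, detrended dF/F0 movies.
## Fixed order of operations: denoise -> detrend -> align -> temporal
## box filter -> dF/F0 -> (repetition averaging).

#' Construct a calcium movie
#'
#' @param stack height x width x time numeric array of raw
#'   fluorescence.
#' @param stimulus stimulus label.
#' @param onset_frame 1-based index of the first stimulus frame; must
#'   be >= 6 so five pre-stimulus baseline frames exist.
#' @param frame_rate acquisition rate in Hz (1 Hz in the confocal
#'   protocol this emulates).
#' @return object of class \code{"calcium_movie"}.
#' @export
calcium_movie <- function(stack, stimulus, onset_frame, frame_rate = 1) {
  .check(is.array(stack) && length(dim(stack)) == 3,
         "stack must be a 3-D array (height x width x time)")
  .check(all(is.finite(stack)), "intensities must be finite")
  .check(onset_frame >= 6, "onset_frame must be >= 6 (5 baseline frames)")
  .check(onset_frame <= dim(stack)[3], "onset_frame beyond movie end")
  structure(list(stack = stack, stimulus = stimulus,
                 onset_frame = as.integer(onset_frame),
                 frame_rate = frame_rate),
            class = "calcium_movie")
}

#' @export
print.calcium_movie <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("calcium_movie '%s': %d x %d px, %d frames @ %g Hz, onset %d\n",
              x$stimulus, d[1], d[2], d[3], x$frame_rate, x$onset_frame))
  invisible(x)
}

# 3x3 median of every frame via a vectorized odd-even transposition
# sort over the 9 shifted copies (replicate boundary). Exact.
.median3x3 <- function(frame) {
  n <- nrow(frame); m <- ncol(frame)
  sh <- function(dy, dx) {
    ri <- pmin(pmax(seq_len(n) + dy, 1), n)
    ci <- pmin(pmax(seq_len(m) + dx, 1), m)
    frame[ri, ci, drop = FALSE]
  }
  v <- list(sh(-1, -1), sh(-1, 0), sh(-1, 1),
            sh(0, -1), sh(0, 0), sh(0, 1),
            sh(1, -1), sh(1, 0), sh(1, 1))
  for (pass in 1:9) {
    start <- if (pass %% 2 == 1) 1 else 2
    for (i in seq(start, 8, by = 2)) {
      lo <- pmin(v[[i]], v[[i + 1]])
      hi <- pmax(v[[i]], v[[i + 1]])
      v[[i]] <- lo; v[[i + 1]] <- hi
    }
  }
  v[[5]]
}

# separable Gaussian blur (reflect boundary)
.gblur <- function(frame, sd) {
  k <- gaussian_kernel(sd)
  t(conv1_cols(t(conv1_cols(frame, k, "reflect")), k, "reflect"))
}

#' Spatial denoising: 3x3 median then Gaussian blur
#'
#' Applied frame by frame: a 3-by-3 median filter (kills isolated shot
#' noise) followed by a 2-D Gaussian filter of s.d. 1 px (reflect
#' boundary).
#'
#' @param m a \code{\link{calcium_movie}}.
#' @param gaussian_sd Gaussian s.d. in pixels.
#' @return denoised \code{calcium_movie}.
#' @export
denoise_frames <- function(m, gaussian_sd = 1) {
  .check(inherits(m, "calcium_movie"), "m must be a calcium_movie")
  d <- dim(m$stack)
  .check(d[1] >= 3 && d[2] >= 3, "frames must be at least 3 x 3")
  out <- m$stack
  for (t in seq_len(d[3])) {
    out[, , t] <- .gblur(.median3x3(m$stack[, , t]), gaussian_sd)
  }
  m$stack <- out
  m
}

#' Remove a linear bleaching trend
#'
#' Fits a line to the per-frame median pixel intensity and subtracts
#' the slope component \code{a * t} (zero-based frame index) from every
#' pixel; the intercept is preserved so F0 stays on the raw intensity
#' scale. After detrending the median-trace slope is ~0.
#'
#' @param m a \code{\link{calcium_movie}}.
#' @return detrended movie; the fitted slope is attached as attribute
#'   \code{"bleach_slope"}.
#' @export
detrend_bleach <- function(m) {
  .check(inherits(m, "calcium_movie"), "m must be a calcium_movie")
  T_ <- dim(m$stack)[3]
  .check(T_ >= 3, "need at least 3 frames")
  med <- apply(m$stack, 3, stats::median)
  t0 <- seq_len(T_) - 1
  a <- stats::cov(t0, med) / stats::var(t0)
  m$stack <- m$stack - rep(a * t0, each = prod(dim(m$stack)[1:2]))
  attr(m, "bleach_slope") <- a
  m
}

#' Rigid frame alignment by phase correlation
#'
#' Each frame's translation is estimated by phase correlation against
#' the stimulus-mean template and removed with subpixel (Fourier)
#' interpolation. Flat frames get zero shift with a warning.
#'
#' @param m a \code{\link{calcium_movie}}.
#' @param min_shift shifts smaller than this (in px, either axis) are
#'   treated as zero and not resampled; avoids churning already-aligned
#'   frames through interpolation for sub-noise estimates.
#' @return aligned movie with per-frame shifts (frames x 2 matrix,
#'   \code{dy}, \code{dx}) attached as attribute \code{"shifts"}.
#' @export
align_frames <- function(m, min_shift = 0.05) {
  .check(inherits(m, "calcium_movie"), "m must be a calcium_movie")
  T_ <- dim(m$stack)[3]
  .check(T_ >= 2, "need at least 2 frames")
  template <- apply(m$stack, c(1, 2), mean)
  shifts <- matrix(0, T_, 2, dimnames = list(NULL, c("dy", "dx")))
  for (t in seq_len(T_)) {
    s <- phase_correlate(template, m$stack[, , t])
    if (max(abs(s)) < min_shift) s <- c(dy = 0, dx = 0)
    shifts[t, ] <- s
    if (any(s != 0)) {
      m$stack[, , t] <- fourier_shift(m$stack[, , t], -s)
    }
  }
  attr(m, "shifts") <- shifts
  m
}

#' Relative fluorescence change (dF/F0)
#'
#' Applies a trailing temporal box filter (3 frames: each frame
#' averaged with its two predecessors; renormalized partial windows at
#' the movie start, no phantom frames), then computes per-pixel
#' \eqn{\Delta F/F_0 = (F - F_0)/F_0} with
#' \eqn{F_0} the mean of the \code{baseline_frames} frames immediately
#' preceding stimulus onset (of the same filtered trace). Pixels whose
#' baseline falls below an epsilon guard (1e-6 of the dynamic range)
#' are masked \code{NA} and counted.
#'
#' @param m a \code{\link{calcium_movie}}.
#' @param box_frames temporal box width (default 3).
#' @param baseline_frames number of pre-onset baseline frames (5).
#' @return object of class \code{"dff_movie"}: list with \code{stack}
#'   (dF/F0), \code{F0}, \code{stimulus}, \code{onset_frame},
#'   \code{frame_rate}, \code{n_masked}.
#' @export
delta_f_over_f <- function(m, box_frames = 3, baseline_frames = 5) {
  .check(inherits(m, "calcium_movie"), "m must be a calcium_movie")
  d <- dim(m$stack)
  .check(m$onset_frame >= baseline_frames + 1,
         "onset_frame must leave room for the baseline window")
  npix <- d[1] * d[2]
  P <- matrix(m$stack, npix, d[3]) # pixels x time
  # trailing box: frame t averages frames (t - box + 1) .. t, so the
  # pre-onset baseline window never mixes in post-onset frames
  cs <- cbind(0, t(apply(P, 1, cumsum)))
  Pf <- matrix(0, npix, d[3])
  for (t in seq_len(d[3])) {
    lo <- max(t - box_frames + 1, 1)
    Pf[, t] <- (cs[, t + 1] - cs[, lo]) / (t - lo + 1)
  }
  bl <- (m$onset_frame - baseline_frames):(m$onset_frame - 1)
  F0 <- rowMeans(Pf[, bl, drop = FALSE])
  eps <- 1e-6 * max(diff(range(m$stack)), 1e-12)
  bad <- F0 <= eps
  dff <- (Pf - F0) / F0
  dff[bad, ] <- NA_real_
  structure(list(stack = array(dff, d), F0 = matrix(F0, d[1], d[2]),
                 stimulus = m$stimulus, onset_frame = m$onset_frame,
                 frame_rate = m$frame_rate, n_masked = sum(bad)),
            class = "dff_movie")
}

#' Average two preprocessed repetitions
#'
#' Registers set b onto set a (rigid phase correlation on the time-mean
#' images) and returns the frame-wise mean.
#'
#' @param dff_a,dff_b \code{"dff_movie"} objects of the same stimulus
#'   and shape.
#' @return averaged \code{dff_movie}; registration shift attached as
#'   attribute \code{"registration_shift"}.
#' @export
average_repetitions <- function(dff_a, dff_b) {
  .check(inherits(dff_a, "dff_movie") && inherits(dff_b, "dff_movie"),
         "inputs must be dff_movie objects")
  .check(identical(dim(dff_a$stack), dim(dff_b$stack)), "shape mismatch")
  .check(identical(dff_a$stimulus, dff_b$stimulus),
         "repetitions must share the stimulus")
  ma <- apply(dff_a$stack, c(1, 2), mean)
  mb <- apply(dff_b$stack, c(1, 2), mean)
  s <- phase_correlate(ma, mb)
  if (max(abs(s)) < 0.05) s <- c(dy = 0, dx = 0)
  b <- dff_b$stack
  if (any(s != 0)) {
    for (t in seq_len(dim(b)[3])) b[, , t] <- fourier_shift(b[, , t], -s)
  }
  dff_a$stack <- (dff_a$stack + b) / 2
  attr(dff_a, "registration_shift") <- s
  dff_a
}

#' Full preprocessing chain for one stimulus stack
#'
#' denoise -> detrend -> align -> dF/F0, in that (fixed) order.
#'
#' @param m a \code{\link{calcium_movie}}.
#' @param denoise,detrend,align stage toggles (all on by default;
#'   useful for noiseless synthetic input).
#' @inheritParams delta_f_over_f
#' @return a \code{"dff_movie"} with a \code{log} attribute recording
#'   per-frame shifts, the fitted bleach slope and the masked-pixel
#'   count.
#' @export
preprocess_movie <- function(m, denoise = TRUE, detrend = TRUE,
                             align = TRUE, box_frames = 3,
                             baseline_frames = 5) {
  if (denoise) m <- denoise_frames(m)
  slope <- NA_real_
  if (detrend) {
    m <- detrend_bleach(m)
    slope <- attr(m, "bleach_slope")
  }
  shifts <- NULL
  if (align) {
    m <- align_frames(m)
    shifts <- attr(m, "shifts")
  }
  dff <- delta_f_over_f(m, box_frames, baseline_frames)
  attr(dff, "log") <- list(bleach_slope = slope, shifts = shifts,
                           n_masked = dff$n_masked)
  dff
}
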