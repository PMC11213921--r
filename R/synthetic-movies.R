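## Planted-cell calcium movies with known ground truth: Gaussian-disc
## cell bodies whose time courses follow parameterized response motifs
## (phasic, sustained, delayed, inhibitory), plus shot-like Gaussian
## noise, a linear bleaching trend, and rigid frame jitter.

#' Library of temporal response motif templates
#'
#' Each template is a function of time since stimulus onset (in
#' seconds; negative = pre-stimulus, response 0) returning a bounded
#' dimensionless modulation in [-1, 1]. The library covers the
#' canonical classes seen in antennal-lobe projection neurons: two
#' excitatory phasic shapes, a sustained response, a delayed response,
#' two inhibitory shapes, and a silent (flat) motif for unresponsive
#' cells.
#'
#' @return named list of functions \code{f(t_s)}.
#' @export
motif_templates <- function() {
  ramp <- function(t, tau) 1 - exp(-pmax(t, 0) / tau)
  shape <- function(t, rise, decay, delay = 0, sign = 1) {
    ts <- pmax(t - delay, 0)
    on <- as.numeric(t >= delay)
    raw <- on * ramp(ts, rise) * exp(-ts / decay)
    pk <- max(raw, 1e-12)
    sign * raw / pk
  }
  list(
    phasic_fast = function(t) shape(t, rise = 0.6, decay = 2.5),
    phasic_slow = function(t) shape(t, rise = 1.5, decay = 6),
    sustained = function(t) shape(t, rise = 2, decay = 60),
    delayed = function(t) shape(t, rise = 1.5, decay = 8, delay = 5),
    inhibitory_phasic = function(t) shape(t, rise = 1, decay = 6, sign = -1),
    inhibitory_sustained = function(t) shape(t, rise = 2.5, decay = 80,
                                             sign = -1),
    silent = function(t) rep(0, length(t))
  )
}

# evaluate a motif id over frame times; errors name a missing id
.motif_course <- function(library, id, t_s) {
  f <- library[[id]]
  if (is.null(f)) stop(sprintf("motif id '%s' missing from library", id),
                       call. = FALSE)
  f(t_s)
}

#' Imaging scene specification
#'
#' @param frame_shape c(height, width) in pixels.
#' @param n_cells number of planted cell bodies.
#' @param cell_radius_px cell radius in pixels (Gaussian disc,
#'   sigma = radius / 2).
#' @param n_frames frames per stimulus movie.
#' @param onset_frame 1-based stimulus onset (>= 6).
#' @param frame_rate Hz (default 1, as in the confocal protocol).
#' @param stimuli character vector of stimulus labels.
#' @param motif_assignment n_cells x n_stimuli character matrix of
#'   motif ids (columns named by stimulus). Default: random responsive
#'   motifs drawn at generation time.
#' @param amplitude peak dF/F-scale response per cell (scalar or
#'   length n_cells).
#' @param baseline mean resting intensity (arbitrary units).
#' @param noise_sd Gaussian noise s.d. in intensity units.
#' @param bleach_slope intensity change per frame (negative =
#'   bleaching).
#' @param jitter_px maximum rigid shift per frame (integer pixels).
#' @param seed integer seed.
#' @return object of class \code{"scene_spec"}.
#' @export
scene_spec <- function(frame_shape = c(64, 64), n_cells = 10,
                       cell_radius_px = 3, n_frames = 40,
                       onset_frame = 11, frame_rate = 1,
                       stimuli = c("Lct", "Laa", "LaaLct"),
                       motif_assignment = NULL, amplitude = 0.8,
                       baseline = 100, noise_sd = 2,
                       bleach_slope = 0, jitter_px = 0, seed = 1) {
  .check(length(frame_shape) == 2 && all(frame_shape >= 8),
         "frame_shape must be (height, width), each >= 8")
  .check(n_cells >= 1 && n_frames >= 10 && cell_radius_px > 0,
         "all counts must be positive (>= 10 frames)")
  .check(onset_frame >= 6, "onset_frame must be >= 6 (5 baseline frames)")
  .check(onset_frame < n_frames, "onset_frame must precede the movie end")
  .check(noise_sd >= 0 && jitter_px >= 0, "noise_sd and jitter_px must be >= 0")
  if (!is.null(motif_assignment)) {
    motif_assignment <- as.matrix(motif_assignment)
    .check(nrow(motif_assignment) == n_cells &&
             ncol(motif_assignment) == length(stimuli),
           "motif_assignment must be n_cells x n_stimuli")
    colnames(motif_assignment) <- stimuli
  }
  if (length(amplitude) == 1) amplitude <- rep(amplitude, n_cells)
  .check(length(amplitude) == n_cells, "amplitude must be scalar or per-cell")
  structure(list(frame_shape = frame_shape, n_cells = n_cells,
                 cell_radius_px = cell_radius_px, n_frames = n_frames,
                 onset_frame = as.integer(onset_frame),
                 frame_rate = frame_rate, stimuli = stimuli,
                 motif_assignment = motif_assignment,
                 amplitude = amplitude, baseline = baseline,
                 noise_sd = noise_sd, bleach_slope = bleach_slope,
                 jitter_px = as.integer(jitter_px), seed = seed),
            class = "scene_spec")
}

# rejection-sample non-overlapping cell centers (distance > 2 r + 1)
.place_cells <- function(n_cells, shape, radius) {
  margin <- radius + 1
  centers <- matrix(NA_real_, 0, 2)
  tries <- 0
  while (nrow(centers) < n_cells) {
    cand <- c(stats::runif(1, margin, shape[1] - margin),
              stats::runif(1, margin, shape[2] - margin))
    ok <- nrow(centers) == 0 ||
      min(sqrt(rowSums(sweep(centers, 2, cand)^2))) > 2 * radius + 1
    if (ok) centers <- rbind(centers, cand)
    tries <- tries + 1
    if (tries > 20000) {
      stop("could not place non-overlapping cells; reduce n_cells or radius",
           call. = FALSE)
    }
  }
  dimnames(centers) <- list(NULL, c("y", "x"))
  centers
}

#' Generate planted-cell calcium movies with ground truth
#'
#' One movie per stimulus. Each cell is an isotropic Gaussian disc
#' (sigma = radius/2) at a center placed so cells never overlap; the
#' pixel time course is
#' \code{baseline * (1 + amplitude * disc * motif(t - onset)) +
#' bleach_slope * t + noise}, with an integer rigid shift per frame of
#' at most \code{jitter_px} applied to the noise-free scene before
#' noise is added. All randomness flows from \code{spec$seed}; a fixed
#' seed reproduces the stacks bit-identically.
#'
#' @param spec a \code{\link{scene_spec}}. When its
#'   \code{motif_assignment} is NULL, motifs are drawn uniformly from
#'   the responsive (non-silent) templates.
#' @param motif_library named list of motif functions (default
#'   \code{\link{motif_templates}()}).
#' @return list with \code{movies} (named list of
#'   \code{\link{calcium_movie}}, one per stimulus) and
#'   \code{ground_truth} (cell centers, motif assignment, amplitudes,
#'   per-stimulus jitter shifts).
#' @export
generate_calcium_movies <- function(spec, motif_library = motif_templates()) {
  .check(inherits(spec, "scene_spec"), "spec must be a scene_spec")
  h <- spec$frame_shape[1]; w <- spec$frame_shape[2]
  with_seed(spec$seed, {
    centers <- .place_cells(spec$n_cells, spec$frame_shape,
                            spec$cell_radius_px)
    assign_mat <- spec$motif_assignment
    if (is.null(assign_mat)) {
      responsive <- setdiff(names(motif_library), "silent")
      assign_mat <- matrix(sample(responsive,
                                  spec$n_cells * length(spec$stimuli),
                                  replace = TRUE),
                           spec$n_cells, length(spec$stimuli),
                           dimnames = list(NULL, spec$stimuli))
    } else {
      for (id in unique(as.vector(assign_mat))) {
        .motif_course(motif_library, id, 0) # error early on unknown ids
      }
    }
    sigma <- spec$cell_radius_px / 2
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    discs <- lapply(seq_len(spec$n_cells), function(c_) {
      d <- exp(-((yy - centers[c_, 1])^2 + (xx - centers[c_, 2])^2) /
                 (2 * sigma^2))
      d[d < 1e-3] <- 0 # compact support: cells end, background is flat
      d
    })
    t_s <- (seq_len(spec$n_frames) - spec$onset_frame) / spec$frame_rate
    jitters <- list()
    movies <- lapply(spec$stimuli, function(stim) {
      courses <- vapply(seq_len(spec$n_cells), function(c_) {
        .motif_course(motif_library, assign_mat[c_, stim], t_s)
      }, numeric(spec$n_frames)) # frames x cells
      jit <- if (spec$jitter_px > 0) {
        matrix(sample(seq.int(-spec$jitter_px, spec$jitter_px),
                      2 * spec$n_frames, replace = TRUE),
               spec$n_frames, 2, dimnames = list(NULL, c("dy", "dx")))
      } else {
        matrix(0L, spec$n_frames, 2, dimnames = list(NULL, c("dy", "dx")))
      }
      jitters[[stim]] <<- jit
      stack <- array(0, c(h, w, spec$n_frames))
      for (t in seq_len(spec$n_frames)) {
        mod <- matrix(0, h, w)
        for (c_ in seq_len(spec$n_cells)) {
          if (courses[t, c_] != 0) {
            mod <- mod + spec$amplitude[c_] * discs[[c_]] * courses[t, c_]
          }
        }
        frame <- spec$baseline * (1 + mod) + spec$bleach_slope * (t - 1)
        if (any(jit[t, ] != 0)) {
          ri <- pmin(pmax(seq_len(h) - jit[t, 1], 1), h)
          ci <- pmin(pmax(seq_len(w) - jit[t, 2], 1), w)
          frame <- frame[ri, ci]
        }
        if (spec$noise_sd > 0) {
          frame <- frame + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
        }
        stack[, , t] <- frame
      }
      calcium_movie(stack, stim, spec$onset_frame, spec$frame_rate)
    })
    names(movies) <- spec$stimuli
    list(movies = movies,
         ground_truth = list(centers = centers,
                             motif_assignment = assign_mat,
                             amplitude = spec$amplitude,
                             jitter = jitters))
  })
}
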