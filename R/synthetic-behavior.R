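## Synthetic foraging trajectories: agents choose among four patches
## with probabilities given by the cue-integration model evaluated at
## known ground-truth reliabilities, then dwell near the chosen patch
## (Ornstein-Uhlenbeck attraction) and occasionally re-draw a target.
## Used for parameter-recovery tests of the choice model.

#' Agent simulation specification
#'
#' @param n_agents number of animals.
#' @param n_frames frames per animal.
#' @param fps frame rate (frames/s).
#' @param arena_diameter arena diameter (cm; default 90 as in the
#'   choice assay).
#' @param true_C ground-truth reliabilities (4 positive values, one per
#'   information class).
#' @param W_set availability matrices per sensory condition (see
#'   \code{\link{default_availability}}).
#' @param patch_centers 4 x 2 matrix of patch centers with patch-label
#'   rownames; default: the four patches at 90-degree spacing near the
#'   wall (center radius 32 cm in a 90 cm arena).
#' @param switching_rate per-frame probability of re-drawing the target
#'   patch. The default (0.001) gives long dwells so that transit time
#'   between patches contributes little to occupancy.
#' @param ou_theta per-frame Ornstein-Uhlenbeck pull toward the target.
#' @param ou_sd per-frame positional noise (cm).
#' @param seed integer seed.
#' @return object of class \code{"agent_spec"}.
#' @export
agent_spec <- function(n_agents = 50, n_frames = 10000, fps = 25,
                       arena_diameter = 90,
                       true_C = c(1, 1, 1, 1),
                       W_set = default_availability(),
                       patch_centers = NULL,
                       switching_rate = 1e-3,
                       ou_theta = 0.12, ou_sd = 0.6,
                       seed = 1) {
  .check(n_agents >= 1 && n_frames >= 1 && fps > 0, "counts must be positive")
  .check(length(true_C) == 4 && all(true_C > 0), "true_C must be 4 positive values")
  .check(switching_rate >= 0 && switching_rate <= 1,
         "switching_rate must be a probability")
  r <- arena_diameter / 2
  arena <- list(center = c(0, 0), radius = r)
  if (is.null(patch_centers)) {
    pr <- r - 13 # patch center radius: ~7 cm wall distance + container
    ang <- c(0, pi / 2, pi, 3 * pi / 2)
    patch_centers <- cbind(x = pr * cos(ang), y = pr * sin(ang))
    rownames(patch_centers) <- PATCHES
  }
  config <- patch_config(patch_centers, arena)
  # validity of W_set is checked through the cue model
  invisible(cue_model(true_C, W_set))
  structure(list(n_agents = n_agents, n_frames = n_frames, fps = fps,
                 arena = arena, config = config, true_C = true_C,
                 W_set = W_set, switching_rate = switching_rate,
                 ou_theta = ou_theta, ou_sd = ou_sd, seed = seed),
            class = "agent_spec")
}

#' Generate choice trajectories with known ground truth
#'
#' Each agent repeatedly draws a target patch with the model
#' probabilities \code{P_x} (evaluated at \code{true_C} and the
#' condition's availability matrix; a degenerate all-zero availability
#' simply yields uniform targets), performs an Ornstein-Uhlenbeck walk
#' attracted to the current target's center, and re-draws the target
#' with probability \code{switching_rate} per frame. Positions are
#' reflected at the arena wall. With long dwells the stationary
#' quarter occupancy converges to \code{P_x}.
#'
#' @param spec an \code{\link{agent_spec}}.
#' @param condition which availability matrix in \code{spec$W_set} to
#'   simulate under.
#' @return list with \code{trajectories} (a
#'   \code{\link{trajectory_set}}), \code{ground_truth} (list:
#'   \code{true_C}, \code{true_score}, \code{P_x}, condition), and
#'   \code{config} (the \code{\link{patch_config}}).
#' @export
generate_choice_trajectories <- function(spec, condition = 1) {
  .check(inherits(spec, "agent_spec"), "spec must be an agent_spec")
  model <- cue_model(spec$true_C, spec$W_set)
  P <- patch_probabilities(model, condition)
  centers <- spec$config$centers[names(P), , drop = FALSE]
  n <- spec$n_agents; T_ <- spec$n_frames
  r <- spec$arena$radius
  pos <- with_seed(spec$seed, {
    x <- stats::runif(n, -r / 2, r / 2)
    y <- stats::runif(n, -r / 2, r / 2)
    target <- sample.int(4, n, replace = TRUE, prob = P)
    X <- matrix(0, T_, n); Y <- matrix(0, T_, n)
    for (t in seq_len(T_)) {
      switch_now <- stats::runif(n) < spec$switching_rate
      if (any(switch_now)) {
        target[switch_now] <- sample.int(4, sum(switch_now),
                                         replace = TRUE, prob = P)
      }
      x <- x + spec$ou_theta * (centers[target, 1] - x) +
        stats::rnorm(n, 0, spec$ou_sd)
      y <- y + spec$ou_theta * (centers[target, 2] - y) +
        stats::rnorm(n, 0, spec$ou_sd)
      # reflect at the circular wall
      d <- sqrt(x^2 + y^2)
      out <- d > r
      if (any(out)) {
        scale <- (2 * r - d[out]) / d[out]
        x[out] <- x[out] * scale
        y[out] <- y[out] * scale
      }
      X[t, ] <- x; Y[t, ] <- y
    }
    lapply(seq_len(n), function(i) cbind(x = X[, i], y = Y[, i]))
  })
  trajs <- trajectory_set(pos, spec$fps, seq_len(n), spec$arena)
  cond_name <- if (is.character(condition)) condition else
    names(spec$W_set)[condition]
  list(trajectories = trajs,
       ground_truth = list(true_C = spec$true_C,
                           true_score = log10(spec$true_C),
                           P_x = P, condition = cond_name),
       config = spec$config)
}
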