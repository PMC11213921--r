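## Behavioral arm: trajectory smoothing, visit-density maps on a
## 1000 x 1000 grid, and per-patch quarter occupancies.

#' Construct a trajectory set
#'
#' @param positions list of per-animal n x 2 matrices (x, y), or a
#'   single matrix for one animal.
#' @param fps frame rate (frames/s), constant across animals.
#' @param animal_ids optional ids; default 1..n.
#' @param arena optional list with \code{center} (x, y) and
#'   \code{radius}; used to map coordinates onto the density grid.
#' @return object of class \code{"trajectory_set"}.
#' @export
trajectory_set <- function(positions, fps, animal_ids = NULL, arena = NULL) {
  if (is.matrix(positions)) positions <- list(positions)
  .check(length(positions) >= 1, "need at least one trajectory")
  positions <- lapply(positions, function(p) {
    p <- as.matrix(p)
    .check(ncol(p) == 2, "positions must be n x 2 (x, y)")
    .check(all(is.finite(p)), "positions must be finite")
    colnames(p) <- c("x", "y")
    p
  })
  .check(is.numeric(fps) && fps > 0, "fps must be positive")
  if (is.null(animal_ids)) animal_ids <- seq_along(positions)
  names(positions) <- animal_ids
  structure(list(positions = positions, fps = fps, arena = arena),
            class = "trajectory_set")
}

#' Temporally smooth trajectories with a Gaussian kernel
#'
#' Each coordinate is convolved with a truncated, renormalized Gaussian
#' spanning \code{half_width_s * fps} frames on each side with
#' \code{sigma_s * fps} frames standard deviation (defaults: half-width
#' 2 s, sigma 2/3 s). Edges use renormalized partial kernels, so a
#' constant trajectory passes through unchanged everywhere.
#'
#' @param trajs a \code{\link{trajectory_set}}.
#' @param half_width_s kernel half-width in seconds.
#' @param sigma_s kernel standard deviation in seconds.
#' @return smoothed \code{trajectory_set}.
#' @export
smooth_trajectory <- function(trajs, half_width_s = 2, sigma_s = 2 / 3) {
  .check(inherits(trajs, "trajectory_set"), "trajs must be a trajectory_set")
  hw <- round(half_width_s * trajs$fps)
  sd_f <- sigma_s * trajs$fps
  k <- gaussian_kernel(sd_f, radius = hw)
  out <- lapply(trajs$positions, function(p) {
    .check(nrow(p) > 2 * hw + 1,
           "trajectory shorter than the smoothing kernel support")
    conv1_cols(p, k, boundary = "renorm")
  })
  trajectory_set(out, trajs$fps, names(trajs$positions), trajs$arena)
}

#' Visit-density map
#'
#' Coordinates are linearly rescaled from the arena bounding box onto a
#' \code{grid_size} x \code{grid_size} grid; one unit of mass is
#' deposited per frame at the binned position; the accumulated counts
#' are smoothed with a 2-D Gaussian kernel (s.d. \code{sd_px} grid
#' pixels, filter size grid size minus one) and divided by the frame
#' count. The kernel is clipped at the grid edge (mass near the border
#' may be lost; normalization is by frame count, not retained mass).
#' With \code{per_animal = TRUE} the pooled grid is the mean of the
#' per-animal maps.
#'
#' @param trajs a \code{\link{trajectory_set}} whose arena is set (or
#'   supply \code{arena}).
#' @param sd_px kernel standard deviation in grid pixels (default 78).
#' @param grid_size grid side length (default 1000).
#' @param arena list with \code{center} and \code{radius} overriding
#'   the trajectory set's arena.
#' @param per_animal keep the individual maps as well.
#' @return object of class \code{"density_map"}: list with \code{grid}
#'   (pooled), optional \code{per_animal} maps, \code{n_clipped}
#'   out-of-grid positions (clipped, counted), grid geometry.
#' @export
visit_density <- function(trajs, sd_px = 78, grid_size = 1000,
                          arena = NULL, per_animal = FALSE) {
  .check(inherits(trajs, "trajectory_set"), "trajs must be a trajectory_set")
  arena <- if (!is.null(arena)) arena else trajs$arena
  .check(!is.null(arena), "an arena (center, radius) is required")
  n_clipped <- 0L
  maps <- lapply(trajs$positions, function(p) {
    # linear rescale of the arena bounding box onto [1, grid_size]
    gx <- 1 + (p[, 1] - (arena$center[1] - arena$radius)) /
      (2 * arena$radius) * (grid_size - 1)
    gy <- 1 + (p[, 2] - (arena$center[2] - arena$radius)) /
      (2 * arena$radius) * (grid_size - 1)
    ix <- round(gx); iy <- round(gy)
    out_of_grid <- ix < 1 | ix > grid_size | iy < 1 | iy > grid_size
    n_clipped <<- n_clipped + sum(out_of_grid)
    ix <- pmin(pmax(ix, 1), grid_size)
    iy <- pmin(pmax(iy, 1), grid_size)
    counts <- matrix(tabulate(iy + (ix - 1) * grid_size,
                              nbins = grid_size^2),
                     grid_size, grid_size) # rows = y, cols = x
    .smooth2d_fft(counts, sd_px, radius = (grid_size - 1) %/% 2) / nrow(p)
  })
  if (n_clipped > 0) {
    warning(sprintf("%d positions outside grid were clipped", n_clipped))
  }
  pooled <- Reduce(`+`, maps) / length(maps)
  structure(list(grid = pooled,
                 per_animal = if (per_animal) maps else NULL,
                 n_clipped = n_clipped, grid_size = grid_size,
                 sd_px = sd_px, arena = arena),
            class = "density_map")
}

# FFT-based separable 2-D Gaussian smoothing with zero padding
# (kernel clipped at the grid edge). `radius` is the kernel half-size.
.smooth2d_fft <- function(x, sd_px, radius) {
  k <- gaussian_kernel(sd_px, radius = radius)
  n <- nrow(x)
  L <- 2^ceiling(log2(n + length(k) - 1))
  kp <- c(k, rep(0, L - length(k)))
  Fk <- stats::fft(kp)
  conv_cols <- function(m) {
    mp <- rbind(m, matrix(0, L - n, ncol(m)))
    y <- Re(stats::mvfft(stats::mvfft(mp) * Fk, inverse = TRUE)) / L
    y[radius + seq_len(n), , drop = FALSE]
  }
  t(conv_cols(t(conv_cols(x))))
}

#' Patch configuration for quarter analysis
#'
#' @param centers 4 x 2 matrix of patch centers (x, y) in arena
#'   coordinates, with rownames giving the patch labels.
#' @param arena list with \code{center} and \code{radius}.
#' @return object of class \code{"patch_config"}.
#' @export
patch_config <- function(centers, arena) {
  centers <- as.matrix(centers)
  .check(nrow(centers) == 4 && ncol(centers) == 2,
         "centers must be 4 x 2 (x, y)")
  .check(!is.null(rownames(centers)), "centers must have patch-label rownames")
  .check(setequal(rownames(centers), PATCHES),
         "patch labels must be Lvs, Lct, LvsLct, Ctr")
  d <- sqrt(rowSums(sweep(centers, 2, arena$center)^2))
  .check(all(d < arena$radius), "patch centers must lie inside the arena")
  structure(list(centers = centers, arena = arena), class = "patch_config")
}

# angle of each patch center around the arena center
.patch_angles <- function(config) {
  atan2(config$centers[, 2] - config$arena$center[2],
        config$centers[, 1] - config$arena$center[1])
}

# wedge index (into config$centers rows) for points (x, y):
# quarters are bounded by the two diagonals through the arena center,
# i.e. each point belongs to the patch whose center angle is nearest
.wedge_of <- function(x, y, config) {
  ang <- atan2(y - config$arena$center[2], x - config$arena$center[1])
  pa <- .patch_angles(config)
  d <- sapply(pa, function(a) {
    w <- abs(ang - a) %% (2 * pi)
    pmin(w, 2 * pi - w)
  })
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  max.col(-d, ties.method = "first")
}

#' Quarter occupancies from a density map
#'
#' The arena is divided into four quarters centered on the patches
#' (bounded by the diagonals through the arena center); per-quarter
#' mass is normalized to sum 1 and reported in canonical patch order
#' (Lvs, Lct, LvsLct, Ctr) regardless of the physical patch placement,
#' so trials with rotated configurations pool directly.
#'
#' @param map a \code{\link{density_map}}.
#' @param config a \code{\link{patch_config}} (same arena).
#' @return named numeric vector of four occupancy fractions summing
#'   to 1.
#' @export
quarter_occupancy <- function(map, config) {
  .check(inherits(map, "density_map"), "map must be a density_map")
  .check(inherits(config, "patch_config"), "config must be a patch_config")
  g <- map$grid_size
  # grid coordinates of every cell, mapped back to arena coordinates
  cx <- config$arena$center[1] - config$arena$radius +
    (seq_len(g) - 1) / (g - 1) * 2 * config$arena$radius
  cy <- config$arena$center[2] - config$arena$radius +
    (seq_len(g) - 1) / (g - 1) * 2 * config$arena$radius
  wedge <- .wedge_of(rep(cx, each = g), rep(cy, times = g), config)
  # grid rows = y, cols = x: cell (iy, ix) is element iy + (ix-1)*g
  mass <- vapply(1:4, function(w) sum(map$grid[wedge == w]), numeric(1))
  tot <- sum(mass)
  .check(tot > 0, "density map has zero total mass")
  occ <- mass / tot
  names(occ) <- rownames(config$centers)
  occ[PATCHES]
}

#' Per-animal quarter occupancies from frame counts
#'
#' Fast per-animal occupancy: the fraction of (smoothed) trajectory
#' frames falling in each patch quarter. The quarter boundaries are
#' straight lines through the arena center, so this agrees with
#' \code{\link{quarter_occupancy}} of the spatially smoothed density
#' map to well below fitting tolerance while being much cheaper for
#' many-animal datasets.
#'
#' @param trajs a \code{\link{trajectory_set}}.
#' @param config a \code{\link{patch_config}}.
#' @return animals x 4 matrix of occupancy fractions (canonical patch
#'   order), rows summing to 1.
#' @export
occupancy_from_frames <- function(trajs, config) {
  .check(inherits(trajs, "trajectory_set"), "trajs must be a trajectory_set")
  out <- t(vapply(trajs$positions, function(p) {
    w <- .wedge_of(p[, 1], p[, 2], config)
    occ <- tabulate(w, nbins = 4) / nrow(p)
    names(occ) <- rownames(config$centers)
    occ[PATCHES]
  }, numeric(4)))
  colnames(out) <- PATCHES
  out
}

#' Read / write trajectory CSV
#'
#' Long format: \code{animal_id, frame, x_px, y_px}.
#' @param path file path.
#' @param trajs a \code{\link{trajectory_set}} (for writing).
#' @param fps frame rate to attach on read.
#' @param arena arena to attach on read.
#' @return a \code{trajectory_set} (read) or invisibly the path
#'   (write).
#' @export
read_trajectories_csv <- function(path, fps, arena = NULL) {
  d <- utils::read.csv(path)
  .check(all(c("animal_id", "frame", "x_px", "y_px") %in% names(d)),
         "CSV must have columns animal_id, frame, x_px, y_px")
  ids <- unique(d$animal_id)
  pos <- lapply(ids, function(id) {
    di <- d[d$animal_id == id, ]
    di <- di[order(di$frame), ]
    .check(!is.unsorted(di$frame, strictly = TRUE),
           "frame index must be strictly increasing per animal")
    cbind(x = di$x_px, y = di$y_px)
  })
  trajectory_set(pos, fps, ids, arena)
}

#' @rdname read_trajectories_csv
#' @export
write_trajectories_csv <- function(trajs, path) {
  rows <- do.call(rbind, lapply(names(trajs$positions), function(id) {
    p <- trajs$positions[[id]]
    data.frame(animal_id = id, frame = seq_len(nrow(p)),
               x_px = p[, 1], y_px = p[, 2])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
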