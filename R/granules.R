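## Activity-granule segmentation: Voronoi partition seeded at the
## regional extrema of the s.d.-projection, iterative boundary
## refinement by root-median-squared trace error, small-granule
## fusion, and Otsu-based active/inactive calls.

#' Standard-deviation projection across a stimulus set
#'
#' Per-pixel standard deviation (population form, divide by n) over
#' the concatenated frames of all stimulus movies -- not the mean of
#' per-stimulus projections.
#'
#' @param dff_set list of \code{"dff_movie"} (or \code{calcium_movie})
#'   objects sharing the frame shape.
#' @return numeric matrix.
#' @export
sd_projection <- function(dff_set) {
  if (inherits(dff_set, "dff_movie") || inherits(dff_set, "calcium_movie")) {
    dff_set <- list(dff_set)
  }
  .check(length(dff_set) >= 1, "need at least one movie")
  d <- dim(dff_set[[1]]$stack)[1:2]
  s1 <- matrix(0, d[1], d[2]); s2 <- matrix(0, d[1], d[2]); n <- 0
  for (m in dff_set) {
    .check(all(dim(m$stack)[1:2] == d), "frame shapes differ")
    s1 <- s1 + rowSums(m$stack, dims = 2)
    s2 <- s2 + rowSums(m$stack^2, dims = 2)
    n <- n + dim(m$stack)[3]
  }
  mu <- s1 / n
  sqrt(pmax(s2 / n - mu^2, 0))
}

# 3x3 max (or min) filter with replicate boundary
.extreme3x3 <- function(x, op = pmax) {
  n <- nrow(x); m <- ncol(x)
  out <- x
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ri <- pmin(pmax(seq_len(n) + dy, 1), n)
    ci <- pmin(pmax(seq_len(m) + dx, 1), m)
    out <- op(out, x[ri, ci])
  }
  out
}

# 8-connected components of a logical matrix (BFS); returns an integer
# label matrix (0 = background). Intended for sparse candidate masks.
.label8 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  nxt <- 0L
  idx <- which(mask)
  for (p in idx) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p
    lab[p] <- nxt
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      qy <- ((q - 1L) %% n) + 1L
      qx <- ((q - 1L) %/% n) + 1L
      for (dy in -1:1) for (dx in -1:1) {
        yy <- qy + dy; xx <- qx + dx
        if (yy < 1 || yy > n || xx < 1 || xx > m) next
        r <- yy + (xx - 1L) * n
        if (mask[r] && lab[r] == 0L) {
          lab[r] <- nxt
          queue <- c(queue, r)
        }
      }
    }
  }
  lab
}

#' Regional extrema of an image
#'
#' 8-connected regional maxima and minima: a maximal connected plateau
#' all of whose outside neighbors are strictly lower (maxima) or
#' strictly higher (minima). Each plateau contributes one seed at its
#' centroid.
#'
#' @param image numeric matrix (non-constant).
#' @return data.frame with columns \code{y}, \code{x} (plateau
#'   centroids, possibly fractional) and \code{type}
#'   (\code{"max"}/\code{"min"}).
#' @export
find_extrema <- function(image) {
  .check(is.matrix(image) && all(is.finite(image)),
         "image must be a finite numeric matrix")
  .check(stats::sd(image) > 0, "no extrema: constant image")
  seeds_of <- function(img, type) {
    cand <- img == .extreme3x3(img, pmax)
    # a candidate adjacent to an equal-valued non-candidate belongs to
    # a plateau that also touches a strictly greater pixel: the whole
    # plateau is not a regional maximum
    repeat {
      leak <- cand & .extreme3x3(ifelse(cand, -Inf, img), pmax) == img
      if (!any(leak)) break
      cand[leak] <- FALSE
    }
    lab <- .label8(cand)
    k <- max(lab)
    if (k == 0) return(NULL)
    ys <- ((which(lab > 0) - 1L) %% nrow(img)) + 1L
    xs <- ((which(lab > 0) - 1L) %/% nrow(img)) + 1L
    l <- lab[lab > 0]
    data.frame(y = tapply(ys, l, mean), x = tapply(xs, l, mean),
               type = type, row.names = NULL)
  }
  rbind(seeds_of(image, "max"), seeds_of(-image, "min"))
}

#' Granule map
#'
#' Integer label image (0 = outside mask) partitioning the field into
#' activity granules, with each granule's seed type recorded
#' (maximum-seeded granules are the response-carrying units;
#' minimum-seeded granules model the low-activity background between
#' them and are excluded from response statistics).
#'
#' @param labels integer matrix of granule ids.
#' @param seed_type character vector indexed by granule id
#'   (\code{"max"}/\code{"min"}).
#' @param seeds the seed table the map was built from.
#' @return object of class \code{"granule_map"}.
#' @export
granule_map <- function(labels, seed_type, seeds = NULL) {
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  .check(all(ids <= length(seed_type)), "seed_type too short for label ids")
  structure(list(labels = labels, seed_type = seed_type, seeds = seeds,
                 ids = ids,
                 sizes = stats::setNames(tabulate(labels, length(seed_type)),
                                         seq_along(seed_type))),
            class = "granule_map")
}

#' @export
print.granule_map <- function(x, ...) {
  cat(sprintf("granule_map: %d granules (%d max-seeded) on %d x %d px\n",
              length(x$ids), sum(x$seed_type[x$ids] == "max"),
              nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Voronoi partition from seed points
#'
#' Labels every pixel (inside the optional mask) with the id of its
#' nearest seed (Euclidean distance; ties go to the lowest seed id).
#' This is the Voronoi diagram dual to the Delaunay triangulation of
#' the seeds, evaluated on the pixel lattice.
#'
#' @param seeds data.frame with \code{y}, \code{x}, \code{type} (from
#'   \code{\link{find_extrema}}).
#' @param shape c(height, width).
#' @param mask optional logical matrix; pixels outside get label 0.
#' @return a \code{\link{granule_map}}.
#' @export
voronoi_partition <- function(seeds, shape, mask = NULL) {
  .check(nrow(seeds) >= 1, "need at least one seed")
  n <- shape[1]; m <- shape[2]
  yy <- rep(seq_len(n), times = m)
  xx <- rep(seq_len(m), each = n)
  D <- outer(yy, seeds$y, function(a, b) (a - b)^2) +
    outer(xx, seeds$x, function(a, b) (a - b)^2)
  lab <- matrix(max.col(-D, ties.method = "first"), n, m)
  if (!is.null(mask)) lab[!mask] <- 0L
  granule_map(lab, as.character(seeds$type), seeds)
}

# neighbor offsets of the 8-neighborhood as (dy, dx) pairs
.NB8 <- cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
              dx = c(-1, 0, 1, -1, 1, -1, 0, 1))

# root median squared error between two traces
.rmedse <- function(a, b) sqrt(stats::median((a - b)^2))

# pixels x time matrix of the concatenated stimulus set
.concat_traces <- function(dff_set) {
  if (inherits(dff_set, "dff_movie") || inherits(dff_set, "calcium_movie")) {
    dff_set <- list(dff_set)
  }
  do.call(cbind, lapply(dff_set, function(m) {
    d <- dim(m$stack)
    matrix(m$stack, d[1] * d[2], d[3])
  }))
}

#' Refine granule boundaries by trace similarity
#'
#' For every pixel on a border between two granules, compares the root
#' median squared error (over the concatenated stimulus set) between
#' the pixel's trace and (a) its home granule's mean trace and (b)
#' each neighboring granule's mean trace; the pixel moves to the
#' neighbor when that error is strictly smaller. Reassignments are
#' applied synchronously at the end of each iteration (raster order
#' has no effect) and granule mean traces are recomputed once per
#' iteration. Iterates until no pixel moves or \code{max_iter}.
#' Finally, granules smaller than \code{min_size} pixels are fused
#' into the neighbor sharing the longest border; granules emptied
#' during refinement are dropped (and counted in the log attribute).
#'
#' @param gmap a \code{\link{granule_map}}.
#' @param dff_set list of \code{"dff_movie"} objects (shape matching
#'   the map).
#' @param max_iter maximum refinement iterations (default 50).
#' @param min_size minimum granule size in pixels (default 5).
#' @return refined \code{\link{granule_map}} with attribute
#'   \code{"refine_log"} (iterations used, moves per iteration,
#'   emptied/fused granule ids).
#' @export
refine_boundaries <- function(gmap, dff_set, max_iter = 50, min_size = 5) {
  .check(inherits(gmap, "granule_map"), "gmap must be a granule_map")
  P <- .concat_traces(dff_set)
  lab <- gmap$labels
  n <- nrow(lab); m <- ncol(lab)
  .check(nrow(P) == n * m, "dff_set shape does not match the map")
  moves <- integer(0)
  emptied <- integer(0)
  for (it in seq_len(max_iter)) {
    means <- rowsum(P, group = as.vector(lab))
    cnt <- tabulate(as.vector(lab), nbins = max(lab))
    present <- sort(unique(as.vector(lab[lab > 0])))
    means <- means[rownames(means) != "0", , drop = FALSE]
    means <- means / cnt[as.integer(rownames(means))]
    mrow <- stats::setNames(seq_len(nrow(means)),
                            rownames(means))
    # boundary pixels: any 8-neighbor with a different positive label
    nb_labs <- vector("list", 8)
    is_boundary <- matrix(FALSE, n, m)
    for (k in seq_len(8)) {
      ri <- seq_len(n) + .NB8[k, 1]
      ci <- seq_len(m) + .NB8[k, 2]
      ok_r <- ri >= 1 & ri <= n
      ok_c <- ci >= 1 & ci <= m
      sh <- matrix(0L, n, m)
      sh[ok_r, ok_c] <- lab[ri[ok_r], ci[ok_c]]
      nb_labs[[k]] <- sh
      is_boundary <- is_boundary | (sh != lab & sh > 0L & lab > 0L)
    }
    bidx <- which(is_boundary)
    if (!length(bidx)) break
    # task list: every (boundary pixel, home-or-neighbor granule) pair;
    # all root-median-squared errors computed in one vectorized pass
    nb_mat <- vapply(nb_labs, function(s) s[bidx], integer(length(bidx)))
    nb_mat <- cbind(lab[bidx], nb_mat) # column 1 = home
    task_p <- rep(seq_along(bidx), times = ncol(nb_mat))
    task_l <- as.vector(nb_mat)
    keep_t <- task_l > 0L & !duplicated(cbind(task_p, task_l))
    task_p <- task_p[keep_t]; task_l <- task_l[keep_t]
    D <- (P[bidx[task_p], , drop = FALSE] -
            means[mrow[as.character(task_l)], , drop = FALSE])^2
    err <- sqrt(.row_medians(D))
    is_home <- task_l == lab[bidx[task_p]]
    e_home <- numeric(length(bidx))
    e_home[task_p[is_home]] <- err[is_home]
    nb_sel <- !is_home
    best_err <- rep(Inf, length(bidx))
    best_lab <- integer(length(bidx))
    if (any(nb_sel)) {
      # iterate tasks once to take the per-pixel neighbor minimum
      op <- task_p[nb_sel]; ol <- task_l[nb_sel]; oe <- err[nb_sel]
      o <- order(op, oe, ol, method = "radix")
      first <- !duplicated(op[o])
      best_err[op[o][first]] <- oe[o][first]
      best_lab[op[o][first]] <- ol[o][first]
    }
    move_sel <- best_lab > 0L & best_err < e_home
    new_lab <- lab
    new_lab[bidx[move_sel]] <- best_lab[move_sel]
    moved <- sum(move_sel)
    moves <- c(moves, moved)
    lab <- new_lab
    gone <- setdiff(present, unique(as.vector(lab)))
    if (length(gone)) emptied <- c(emptied, gone)
    if (moved == 0L) break
  }
  fused <- integer(0)
  repeat {
    sizes <- tabulate(as.vector(lab), nbins = length(gmap$seed_type))
    small <- which(sizes > 0 & sizes < min_size)
    if (!length(small) || length(unique(as.vector(lab[lab > 0]))) <= 1) break
    g <- small[1]
    # neighbor sharing the longest border (counted over 8-neighbor pairs)
    border <- integer(0)
    gpix <- which(lab == g)
    for (k in seq_len(8)) {
      qy <- ((gpix - 1L) %% n) + 1L + .NB8[k, 1]
      qx <- ((gpix - 1L) %/% n) + 1L + .NB8[k, 2]
      ok <- qy >= 1 & qy <= n & qx >= 1 & qx <= m
      val <- lab[cbind(qy[ok], qx[ok])]
      border <- c(border, val[val > 0L & val != g])
    }
    if (!length(border)) break
    tgt <- as.integer(names(which.max(table(border))))
    lab[lab == g] <- tgt
    fused <- c(fused, g)
  }
  out <- granule_map(lab, gmap$seed_type, gmap$seeds)
  attr(out, "refine_log") <- list(iterations = length(moves),
                                  moves = moves, emptied = emptied,
                                  fused = fused)
  out
}

#' Otsu threshold on a numeric vector
#'
#' 256-bin histogram over the observed range; returns the threshold
#' maximizing between-class variance (midpoint of the optimal bin
#' edge).
#'
#' @param x numeric values.
#' @param bins histogram bins (default 256).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(x, bins = 256) {
  x <- x[is.finite(x)]
  .check(length(x) >= 2, "need at least 2 values")
  r <- range(x)
  .check(diff(r) > 0, "constant input has no Otsu threshold")
  edges <- seq(r[1], r[2], length.out = bins + 1)
  h <- tabulate(pmin(findInterval(x, edges, rightmost.closed = TRUE), bins),
                nbins = bins)
  p <- h / sum(h)
  centers <- (edges[-1] + edges[-(bins + 1)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  sb <- sigma_b[-bins]
  # the criterion is flat across empty histogram gaps: take the
  # midpoint of the maximal plateau
  ks <- which(sb >= max(sb) - 1e-15 * abs(max(sb)))
  mean(edges[range(ks) + 1])
}

#' Call granules active or inactive for one stimulus
#'
#' Applies Otsu's method (256-bin histogram) to the granule response
#' magnitudes; a granule is active when its magnitude exceeds the
#' threshold. Granules excluded by \code{exclude} (e.g.
#' minimum-seeded or outside-mask granules) are never active. If all
#' magnitudes are equal no threshold exists: everything is called
#' inactive with a warning.
#'
#' @param magnitudes named numeric vector of per-granule window-mean
#'   dF/F0.
#' @param exclude logical vector (same length) of granules barred from
#'   being active.
#' @param min_magnitude response floor in dF/F0 units (default 0.02):
#'   Otsu always splits a distribution, so on a stimulus that evokes
#'   no response the threshold would land inside the noise; requiring
#'   the magnitude to also exceed a small physical response floor
#'   keeps silent preparations silent.
#' @return logical vector of active flags.
#' @export
call_active <- function(magnitudes, exclude = NULL, min_magnitude = 0.02) {
  .check(length(magnitudes) >= 2, "need at least 2 granules")
  if (length(unique(magnitudes)) == 1) {
    warning("all magnitudes equal: calling all granules inactive")
    return(rep(FALSE, length(magnitudes)))
  }
  thr <- max(otsu_threshold(magnitudes), min_magnitude)
  active <- magnitudes > thr
  if (!is.null(exclude)) active[exclude] <- FALSE
  active
}

#' Per-granule response traces and magnitudes
#'
#' Mean dF/F0 trace over each granule's pixels, the window-mean
#' magnitude, and the Otsu active call. The call is made on magnitude
#' alone: after boundary refinement a minimum-seeded granule can end up
#' owning genuinely responsive pixels, so seed type is reported (for
#' downstream filtering of background granules from pooled statistics)
#' but does not bar a granule from being active; only mask-excluded
#' granules (label 0) never appear.
#'
#' @param gmap a \code{\link{granule_map}}.
#' @param dff a \code{"dff_movie"} for one stimulus.
#' @param window analysis window length in frames after onset (default
#'   10).
#' @return data.frame (granule, stimulus, seed_type, size, magnitude,
#'   active) with the traces in attribute \code{"traces"} (granules x
#'   frames).
#' @export
granule_responses <- function(gmap, dff, window = 10) {
  .check(inherits(gmap, "granule_map"), "gmap must be a granule_map")
  d <- dim(dff$stack)
  P <- matrix(dff$stack, d[1] * d[2], d[3])
  keep <- as.vector(gmap$labels) > 0
  means <- rowsum(P[keep, , drop = FALSE], as.vector(gmap$labels)[keep])
  cnt <- tabulate(as.vector(gmap$labels), nbins = length(gmap$seed_type))
  ids <- as.integer(rownames(means))
  means <- means / cnt[ids]
  win <- dff$onset_frame:min(dff$onset_frame + window - 1, d[3])
  mag <- rowMeans(means[, win, drop = FALSE])
  st <- gmap$seed_type[ids]
  act <- call_active(mag)
  out <- data.frame(granule = ids, stimulus = dff$stimulus,
                    seed_type = st, size = cnt[ids], magnitude = mag,
                    active = act, row.names = NULL)
  attr(out, "traces") <- means
  out
}

#' Segment a stimulus set into activity granules
#'
#' Full chain: s.d.-projection over the concatenated stimulus set ->
#' regional extrema (after an optional light Gaussian smoothing of the
#' projection to suppress single-pixel noise extrema) -> Voronoi
#' partition -> boundary refinement -> small-granule fusion.
#'
#' @param dff_set list of \code{"dff_movie"} objects.
#' @param mask optional logical matrix restricting the field (e.g. the
#'   antennal lobe outline); no automatic anatomy detection is
#'   attempted.
#' @param smooth_sd Gaussian s.d. (px) applied to the s.d.-projection
#'   before extrema detection; 0 disables.
#' @param max_iter,min_size see \code{\link{refine_boundaries}}.
#' @return a refined \code{\link{granule_map}}.
#' @export
segment_granules <- function(dff_set, mask = NULL, smooth_sd = 1,
                             max_iter = 50, min_size = 5) {
  proj <- sd_projection(dff_set)
  if (smooth_sd > 0) proj <- .gblur(proj, smooth_sd)
  seeds <- find_extrema(proj)
  gmap <- voronoi_partition(seeds, dim(proj), mask)
  refine_boundaries(gmap, dff_set, max_iter = max_iter,
                    min_size = min_size)
}
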