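## Cross-animal response matrices, VRC-elbow k-means clustering of
## odor response vectors, mixture-specific units, and repetition
## consistency of spatial response maps.

#' Assemble a response matrix
#'
#' Rows are units (granules within an animal), columns are stimuli,
#' entries are window-mean dF/F0.
#'
#' @param values units x stimuli numeric matrix (column names =
#'   stimulus labels).
#' @param animal_id per-row animal identifier.
#' @param phenotype optional per-row phenotype label.
#' @return object of class \code{"response_matrix"}.
#' @export
response_matrix <- function(values, animal_id, phenotype = NULL) {
  values <- as.matrix(values)
  .check(!anyNA(values), "response matrix must have no missing entries")
  .check(length(animal_id) == nrow(values), "one animal id per row")
  structure(list(values = values, animal_id = animal_id,
                 phenotype = phenotype, normalized = FALSE),
            class = "response_matrix")
}

#' Normalize a response matrix
#'
#' Per animal: subtract the animal's minimum (making entries
#' non-negative), square-root transform, then center the animal's
#' entries to mean 0 and scale to s.d. 1. Per row (unit): rescale the
#' range to [-1, 1]. Constant rows map to all-zeros with a warning.
#'
#' @param raw a \code{\link{response_matrix}}.
#' @return normalized \code{response_matrix} (\code{normalized} flag
#'   set).
#' @export
normalize_matrix <- function(raw) {
  .check(inherits(raw, "response_matrix"), "raw must be a response_matrix")
  v <- raw$values
  for (id in unique(raw$animal_id)) {
    rows <- raw$animal_id == id
    a <- v[rows, , drop = FALSE]
    a <- sqrt(a - min(a))
    a <- (a - mean(a)) / stats::sd(a)
    v[rows, ] <- a
  }
  const <- 0L
  for (i in seq_len(nrow(v))) {
    r <- range(v[i, ])
    if (diff(r) == 0) {
      v[i, ] <- 0
      const <- const + 1L
    } else {
      v[i, ] <- 2 * (v[i, ] - r[1]) / diff(r) - 1
    }
  }
  if (const > 0) warning(sprintf("%d constant row(s) mapped to zeros", const))
  out <- raw
  out$values <- v
  out$normalized <- TRUE
  out
}

#' Variance Ratio Criterion
#'
#' \deqn{VRC(k) = \frac{SSB (N - k)}{SSW (k - 1)}}
#' with \eqn{SSB = \sum_c n_c \|\bar{x}_c - \bar{x}\|^2} (between-
#' cluster variance) and \eqn{SSW = \sum_c \sum_{x \in c}
#' \|x - \bar{x}_c\|^2} (within-cluster variance); the
#' Calinski-Harabasz index.
#'
#' @param points N x p numeric matrix.
#' @param labels length-N cluster assignment (>= 2 non-empty
#'   clusters).
#' @return scalar VRC; \code{Inf} (with a flag attribute) when
#'   SSW = 0.
#' @export
vrc <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  N <- nrow(points)
  .check(k >= 2, "need at least 2 clusters")
  .check(all(tabulate(labels, k) > 0), "clusters must be non-empty")
  gm <- colMeans(points)
  cm <- rowsum(points, labels) / tabulate(labels, k)
  ssb <- sum(tabulate(labels, k) * rowSums(sweep(cm, 2, gm)^2))
  ssw <- sum((points - cm[labels, , drop = FALSE])^2)
  if (ssw == 0) {
    return(structure(Inf, degenerate = TRUE))
  }
  ssb * (N - k) / (ssw * (k - 1))
}

# k-means with best-of-`replicates` random initializations (Lloyd
# batch phase via stats::kmeans) plus an online single-point
# reassignment phase after batch convergence.
.kmeans_online <- function(x, k, replicates = 50, iter_max = 1e6) {
  best <- NULL
  draw_init <- function() {
    for (try in 1:50) {
      init <- x[sample.int(nrow(x), k), , drop = FALSE]
      if (!anyDuplicated(init)) return(init)
    }
    # duplicated rows in the data: jitter the colliding centers
    init[duplicated(init), ] <- init[duplicated(init), , drop = FALSE] +
      stats::rnorm(sum(duplicated(init)) * ncol(x), 0, 1e-8)
    init
  }
  for (r in seq_len(replicates)) {
    init <- draw_init()
    km <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = min(iter_max, 1000),
                    algorithm = "Lloyd"))
    cl <- km$cluster
    centers <- km$centers
    sizes <- tabulate(cl, k)
    # online phase: move single points, updating means immediately
    for (pass in 1:20) {
      changed <- FALSE
      for (i in seq_len(nrow(x))) {
        d <- rowSums(sweep(centers, 2, x[i, ])^2)
        j <- which.min(d)
        ci <- cl[i]
        if (j != ci && sizes[ci] > 1) {
          centers[ci, ] <- (centers[ci, ] * sizes[ci] - x[i, ]) /
            (sizes[ci] - 1)
          centers[j, ] <- (centers[j, ] * sizes[j] + x[i, ]) /
            (sizes[j] + 1)
          sizes[ci] <- sizes[ci] - 1L
          sizes[j] <- sizes[j] + 1L
          cl[i] <- j
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    tw <- sum((x - centers[cl, , drop = FALSE])^2)
    if (is.null(best) || tw < best$tot_withinss) {
      best <- list(cluster = cl, centers = centers, tot_withinss = tw)
    }
  }
  best
}

#' Elbow of a VRC curve
#'
#' Returns the k whose curve point lies farthest (perpendicular
#' distance) from the chord connecting the first and last finite curve
#' points; ties break to the smallest k. Non-finite VRC values are
#' excluded with a warning.
#'
#' @param curve list/data.frame with components \code{k} and
#'   \code{vrc}.
#' @return chosen k.
#' @export
choose_k_elbow <- function(curve) {
  k <- curve$k
  v <- curve$vrc
  fin <- is.finite(v)
  if (!all(fin)) {
    warning("non-finite VRC values excluded from the chord")
    k <- k[fin]; v <- v[fin]
  }
  .check(length(k) >= 2, "need at least 2 finite curve points")
  p1 <- c(k[1], v[1])
  p2 <- c(k[length(k)], v[length(k)])
  dv <- p2 - p1
  nrm <- sqrt(sum(dv^2))
  d <- if (nrm == 0) {
    rep(0, length(k))
  } else {
    abs(dv[2] * (k - p1[1]) - dv[1] * (v - p1[2])) / nrm
  }
  k[which.max(d)] # which.max takes the first (smallest k) on ties
}

#' VRC curve over a k range
#'
#' Runs replicated k-means at each k and records the criterion.
#'
#' @param points N x p matrix (already in the clustering space).
#' @param k_range integer vector of candidate k (default 2:20).
#' @param replicates k-means restarts per k.
#' @param seed integer seed.
#' @return data.frame (k, vrc) of class \code{"vrc_curve"} with the
#'   per-k fits in attribute \code{"fits"}.
#' @export
vrc_curve <- function(points, k_range = 2:20, replicates = 50, seed = 1) {
  points <- as.matrix(points)
  k_range <- k_range[k_range < nrow(points)]
  .check(length(k_range) >= 2, "k_range must keep at least 2 values below N")
  fits <- with_seed(seed, {
    lapply(k_range, function(k) .kmeans_online(points, k, replicates))
  })
  v <- vapply(seq_along(k_range), function(i) {
    as.numeric(vrc(points, fits[[i]]$cluster))
  }, numeric(1))
  out <- data.frame(k = k_range, vrc = v)
  class(out) <- c("vrc_curve", "data.frame")
  attr(out, "fits") <- fits
  out
}

# project rows into PC space retaining >= `retain` cumulative variance
.pca_project <- function(x, retain) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot < 1e-20) { # zero-variance input: a single flat component
    return(list(scores = pc$x[, 1, drop = FALSE], npc = 1L, pca = pc))
  }
  cum <- cumsum(pc$sdev^2) / tot
  npc <- which(cum >= retain)[1]
  list(scores = pc$x[, seq_len(npc), drop = FALSE], npc = npc, pca = pc)
}

#' Cluster odor response vectors
#'
#' Projects the normalized response matrix into PC space (retaining
#' PCs that cumulatively explain at least \code{variance_retained} of
#' the variance), runs replicated k-means with an online update phase
#' for each k in \code{k_range}, picks k at the VRC elbow, and returns
#' per-row labels plus per-cluster mean response vectors (the odor
#' response vectors).
#'
#' @param mat a normalized \code{\link{response_matrix}}.
#' @param k_range candidate cluster counts (default 2:20).
#' @param variance_retained PCA threshold (default 0.99).
#' @param replicates k-means restarts per k (500 for full analyses;
#'   smaller values are adequate for well-separated data).
#' @param seed integer seed.
#' @return list with \code{k}, \code{labels}, \code{centroids}
#'   (cluster x stimuli mean response vectors), \code{curve}
#'   (\code{vrc_curve}), \code{n_pcs}.
#' @export
cluster_vectors <- function(mat, k_range = 2:20, variance_retained = 0.99,
                            replicates = 50, seed = 1) {
  .check(inherits(mat, "response_matrix"), "mat must be a response_matrix")
  .check(isTRUE(mat$normalized), "normalize_matrix() must be applied first")
  .check(nrow(mat$values) > min(k_range), "fewer rows than clusters")
  pr <- .pca_project(mat$values, variance_retained)
  curve <- vrc_curve(pr$scores, k_range, replicates, seed)
  k <- choose_k_elbow(curve)
  fit <- attr(curve, "fits")[[match(k, curve$k)]]
  centroids <- rowsum(mat$values, fit$cluster) /
    tabulate(fit$cluster, k)
  list(k = k, labels = fit$cluster, centroids = centroids,
       curve = curve, n_pcs = pr$npc)
}

#' Fraction of mixture-specific units
#'
#' Among units responding to a two-component mixture, the proportion
#' that respond to neither component alone.
#'
#' @param active logical units x stimuli matrix with stimulus column
#'   names.
#' @param mixture mixture stimulus name.
#' @param components character vector of the two component names.
#' @return proportion in [0, 1]; \code{NA} (with a warning) when no
#'   unit responds to the mixture.
#' @export
mixture_specific_fraction <- function(active, mixture, components) {
  .check(all(c(mixture, components) %in% colnames(active)),
         "active flags must cover the mixture and both components")
  .check(length(components) == 2, "exactly two components expected")
  resp <- active[, mixture]
  denom <- sum(resp)
  if (denom == 0) {
    warning("no units respond to the mixture: fraction undefined")
    return(NA_real_)
  }
  num <- sum(resp & !active[, components[1]] & !active[, components[2]])
  num / denom
}

#' Consistency of spatial response maps across repetitions
#'
#' Per animal: each trial's mean-intensity map is rescaled to [0, 1]
#' and treated as one observation (pixels = features); PCA retains at
#' least \code{variance_retained} (default 0.95) of the variance;
#' Euclidean distances in PC space give the mean within-odor and
#' between-odor distances; average linkage yields the hierarchical
#' cluster tree and its cophenetic correlation.
#'
#' @param maps named list: odor -> list of trial maps (numeric
#'   matrices of one shape). At least 2 odors with >= 2 trials each
#'   for within-odor distances.
#' @param variance_retained PCA threshold.
#' @return list with \code{within}, \code{between} (mean distances),
#'   \code{tree} (hclust), \code{cophenetic} (correlation),
#'   \code{dist} (full distance matrix), \code{odor} (per-map odor
#'   labels), \code{n_pcs}.
#' @export
consistency_analysis <- function(maps, variance_retained = 0.95) {
  .check(is.list(maps) && length(maps) >= 2, "need maps for >= 2 odors")
  odor <- rep(names(maps), vapply(maps, length, integer(1)))
  flat <- do.call(rbind, lapply(unlist(maps, recursive = FALSE),
                                function(m) {
    r <- range(m)
    v <- if (diff(r) == 0) m * 0 else (m - r[1]) / diff(r)
    as.vector(v)
  }))
  pr <- .pca_project(flat, variance_retained)
  D <- as.matrix(stats::dist(pr$scores))
  same <- outer(odor, odor, `==`)
  ut <- upper.tri(D)
  within_vals <- D[ut & same]
  between_vals <- D[ut & !same]
  tree <- stats::hclust(stats::as.dist(D), method = "average")
  coph <- suppressWarnings(
    stats::cor(stats::cophenetic(tree), stats::as.dist(D)))
  list(within = if (length(within_vals)) mean(within_vals) else NA_real_,
       between = mean(between_vals), tree = tree, cophenetic = coph,
       dist = D, odor = odor, n_pcs = pr$npc)
}

#' Export an hclust tree as Newick text
#'
#' @param tree an \code{hclust} object.
#' @param labels optional tip labels.
#' @return Newick string.
#' @export
tree_newick <- function(tree, labels = NULL) {
  .check(requireNamespace("ape", quietly = TRUE),
         "the 'ape' package is required for Newick export")
  if (!is.null(labels)) tree$labels <- labels
  if (is.null(tree$labels)) tree$labels <- as.character(seq_len(nrow(tree$merge) + 1))
  ape::write.tree(ape::as.phylo(tree))
}
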