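## Temporal response motifs: clustering of z-scored (unit, stimulus)
## dF/F0 profiles, per-unit motif triplets, motif-transition maps, and
## leave-one-out diagonal-LDA phenotype classification.

#' Assemble a profile matrix
#'
#' Rows are (unit, stimulus) observations, columns are frames; each
#' row is z-scored (mean 0, s.d. 1). Constant rows are rejected.
#'
#' @param profiles rows x frames numeric matrix of dF/F0 traces.
#' @param unit per-row unit identifier.
#' @param stimulus per-row stimulus label.
#' @param animal per-row animal identifier.
#' @param phenotype optional per-row phenotype label.
#' @param zscore z-score rows (default TRUE; set FALSE if rows are
#'   already standardized).
#' @return object of class \code{"profile_matrix"}.
#' @export
profile_matrix <- function(profiles, unit, stimulus, animal = NULL,
                           phenotype = NULL, zscore = TRUE) {
  profiles <- as.matrix(profiles)
  .check(ncol(profiles) >= 3, "rows must span at least 3 frames")
  .check(length(unit) == nrow(profiles) &&
           length(stimulus) == nrow(profiles),
         "unit and stimulus must be given per row")
  if (zscore) {
    sds <- apply(profiles, 1, stats::sd)
    .check(all(sds > 0), "constant profile rows cannot be z-scored")
    profiles <- (profiles - rowMeans(profiles)) / sds
  }
  structure(list(profiles = profiles, unit = unit, stimulus = stimulus,
                 animal = animal, phenotype = phenotype),
            class = "profile_matrix")
}

# order motif ids by (peak sign, |peak|, peak latency), all ascending:
# inhibitory motifs first, then weak-to-strong, early peaks first
# within equal magnitude
.motif_order <- function(templates) {
  peak_idx <- apply(abs(templates), 1, which.max)
  peak <- templates[cbind(seq_len(nrow(templates)), peak_idx)]
  order(sign(peak), abs(peak), peak_idx)
}

#' Cluster temporal response motifs
#'
#' Same machinery as \code{\link{cluster_vectors}} (PCA retaining >=
#' 99% variance, replicated k-means with online phase, VRC-elbow k):
#' rows are (unit, stimulus) z-profiles. The resulting motifs are
#' re-indexed by (peak sign, peak magnitude, peak latency) ascending
#' so ids are comparable across runs. A near-degenerate input (all
#' rows one template, SSW ~ 0) is flagged and k forced to the minimum
#' of \code{k_range}.
#'
#' @param pm a \code{\link{profile_matrix}}.
#' @param k_range candidate k (default 2:20).
#' @param variance_retained PCA threshold (default 0.99).
#' @param replicates k-means restarts per k.
#' @param seed integer seed.
#' @return object of class \code{"motif_set"}: list with \code{k},
#'   \code{assignment} (per-row motif id), \code{templates} (motif x
#'   frames mean z-profiles, re-indexed), \code{curve}, \code{pm}
#'   (the input), \code{degenerate} flag.
#' @export
cluster_motifs <- function(pm, k_range = 2:20, variance_retained = 0.99,
                           replicates = 50, seed = 1) {
  .check(inherits(pm, "profile_matrix"), "pm must be a profile_matrix")
  x <- pm$profiles
  .check(nrow(x) > min(k_range), "fewer rows than clusters")
  pr <- .pca_project(x, variance_retained)
  degenerate <- FALSE
  tot_var <- sum(scale(pr$scores, scale = FALSE)^2)
  if (tot_var < 1e-10 * nrow(x)) {
    degenerate <- TRUE
    k <- min(k_range)
    assignment <- rep(seq_len(k), length.out = nrow(x))
    curve <- NULL
  } else {
    curve <- vrc_curve(pr$scores, k_range, replicates, seed)
    if (all(!is.finite(curve$vrc))) {
      degenerate <- TRUE
      k <- min(k_range)
      assignment <- attr(curve, "fits")[[1]]$cluster
    } else {
      k <- choose_k_elbow(curve)
      assignment <- attr(curve, "fits")[[match(k, curve$k)]]$cluster
    }
  }
  templates <- rowsum(x, assignment) / tabulate(assignment, k)
  ord <- .motif_order(templates)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  structure(list(k = k, assignment = relabel[assignment],
                 templates = templates[ord, , drop = FALSE],
                 curve = curve, pm = pm, degenerate = degenerate),
            class = "motif_set")
}

#' Per-unit motif triplets
#'
#' The ordered motif assignment of each unit across the three
#' stimuli. Units missing any stimulus row are excluded (and listed
#' in attribute \code{"excluded"}).
#'
#' @param mset a \code{"motif_set"} (from
#'   \code{\link{cluster_motifs}}).
#' @param stimuli ordered stimulus labels (default Lct, Laa, LaaLct).
#' @return data.frame with \code{unit}, optional \code{animal} /
#'   \code{phenotype}, and one motif column per stimulus.
#' @export
motif_triplets <- function(mset, stimuli = c("Lct", "Laa", "LaaLct")) {
  .check(inherits(mset, "motif_set"), "mset must be a motif_set")
  pm <- mset$pm
  units <- unique(pm$unit)
  rows <- lapply(units, function(u) {
    sel <- pm$unit == u
    st <- pm$stimulus[sel]
    if (!all(stimuli %in% st)) return(NULL)
    ms <- vapply(stimuli, function(s) {
      mset$assignment[sel][match(s, st)]
    }, integer(1))
    d <- data.frame(unit = u, t(ms))
    names(d)[-1] <- stimuli
    if (!is.null(pm$animal)) d$animal <- pm$animal[sel][1]
    if (!is.null(pm$phenotype)) d$phenotype <- pm$phenotype[sel][1]
    d
  })
  keep <- !vapply(rows, is.null, logical(1))
  out <- do.call(rbind, rows[keep])
  attr(out, "excluded") <- units[!keep]
  out
}

#' Motif-transition probability maps
#'
#' For each animal and each ordered stimulus pair, the k x k matrix of
#' joint motif-transition proportions over that animal's units (each
#' matrix sums to 1).
#'
#' @param triplets triplet table from \code{\link{motif_triplets}}
#'   (needs an \code{animal} column; a single pseudo-animal is assumed
#'   if absent).
#' @param k number of motifs.
#' @param stimulus_pairs list of ordered pairs (default Lct->Laa,
#'   Lct->LaaLct, Laa->LaaLct).
#' @return object of class \code{"transition_maps"}: named list per
#'   animal, each a list with \code{matrices} (one k x k matrix per
#'   pair), \code{phenotype}, \code{n_units}.
#' @export
transition_probabilities <- function(triplets, k,
                                     stimulus_pairs = list(
                                       c("Lct", "Laa"),
                                       c("Lct", "LaaLct"),
                                       c("Laa", "LaaLct"))) {
  if (is.null(triplets$animal)) triplets$animal <- "animal1"
  animals <- unique(triplets$animal)
  out <- lapply(animals, function(a) {
    tr <- triplets[triplets$animal == a, ]
    mats <- lapply(stimulus_pairs, function(pr) {
      M <- matrix(0, k, k,
                  dimnames = list(from = seq_len(k), to = seq_len(k)))
      for (i in seq_len(nrow(tr))) {
        M[tr[[pr[1]]][i], tr[[pr[2]]][i]] <- M[tr[[pr[1]]][i], tr[[pr[2]]][i]] + 1
      }
      M / max(sum(M), 1)
    })
    names(mats) <- vapply(stimulus_pairs, paste, collapse = "->",
                          FUN.VALUE = character(1))
    list(matrices = mats,
         phenotype = if (!is.null(tr$phenotype)) tr$phenotype[1] else NA,
         n_units = nrow(tr))
  })
  names(out) <- animals
  structure(out, class = "transition_maps")
}

# flatten an animal's transition matrices into one feature vector
.tmap_features <- function(tmaps) {
  t(vapply(tmaps, function(a) unlist(lapply(a$matrices, as.vector)),
           numeric(length(as.vector(tmaps[[1]]$matrices[[1]])) *
                     length(tmaps[[1]]$matrices))))
}

#' Diagonal linear discriminant analysis
#'
#' Two-class (or multi-class) LDA with a shared diagonal covariance
#' matrix: per-feature variance pooled within classes, class priors
#' set uniform (compensating unequal group sizes). Ties in the
#' discriminant score predict the globally rarer class.
#'
#' @param x training feature matrix.
#' @param y class labels.
#' @return object of class \code{"diag_lda"}.
#' @export
diagonal_lda <- function(x, y) {
  x <- as.matrix(x)
  y <- factor(y)
  .check(nlevels(y) >= 2, "training data must contain >= 2 classes")
  means <- rowsum(x, y) / as.vector(table(y))
  resid <- x - means[y, , drop = FALSE]
  pooled <- colSums(resid^2) / (nrow(x) - nlevels(y))
  pooled[pooled < 1e-12] <- 1e-12
  rare <- names(which.min(table(y)))
  structure(list(means = means, pooled_var = pooled,
                 levels = levels(y), rare = rare),
            class = "diag_lda")
}

#' @export
predict.diag_lda <- function(object, newdata, ...) {
  newdata <- matrix(newdata, ncol = length(object$pooled_var))
  scores <- -vapply(seq_along(object$levels), function(c_) {
    rowSums(sweep(newdata, 2, object$means[c_, ])^2 /
              rep(object$pooled_var, each = nrow(newdata)))
  }, numeric(nrow(newdata)))
  scores <- matrix(scores, nrow = nrow(newdata))
  apply(scores, 1, function(s) {
    best <- which(s == max(s))
    if (length(best) > 1) object$rare else object$levels[best]
  })
}

#' Leave-one-out phenotype classification from motif transitions
#'
#' Features are the flattened per-animal transition matrices. For each
#' fold, PCA is fit on the training animals only (retaining at least
#' \code{variance_retained}, default 0.83, of the variance), a
#' diagonal-covariance linear discriminant with uniform class priors
#' is trained, and the held-out animal is predicted.
#'
#' @param tmaps a \code{"transition_maps"} object whose animals carry
#'   phenotype labels (or supply \code{phenotypes}).
#' @param phenotypes optional per-animal labels overriding those in
#'   \code{tmaps}.
#' @param variance_retained PCA threshold (default 0.83).
#' @param pca_per_fold fit the PCA inside each training fold (default
#'   TRUE; FALSE reuses a PCA fit on all animals).
#' @return list with \code{predictions}, \code{truth},
#'   \code{confusion} (truth x predicted), \code{accuracy}.
#' @export
classify_phenotype_loo <- function(tmaps, phenotypes = NULL,
                                   variance_retained = 0.83,
                                   pca_per_fold = TRUE) {
  X <- .tmap_features(tmaps)
  y <- if (!is.null(phenotypes)) phenotypes else
    vapply(tmaps, function(a) as.character(a$phenotype), character(1))
  y <- factor(y)
  .check(all(table(y) >= 2), "need >= 2 animals per phenotype")
  n <- nrow(X)
  preds <- character(n)
  pr_all <- if (!pca_per_fold) .pca_project(X, variance_retained) else NULL
  for (i in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), i)
    .check(nlevels(droplevels(y[tr_idx])) >= 2,
           "a training fold contains a single class")
    if (pca_per_fold) {
      pr <- .pca_project(X[tr_idx, , drop = FALSE], variance_retained)
      tr <- pr$scores
      te <- predict(pr$pca, X[i, , drop = FALSE])[, seq_len(pr$npc),
                                                  drop = FALSE]
    } else {
      tr <- pr_all$scores[tr_idx, , drop = FALSE]
      te <- pr_all$scores[i, , drop = FALSE]
    }
    fit <- diagonal_lda(tr, y[tr_idx])
    preds[i] <- predict(fit, te)
  }
  confusion <- table(truth = y, predicted = factor(preds, levels(y)))
  list(predictions = preds, truth = as.character(y),
       confusion = confusion, accuracy = mean(preds == as.character(y)))
}
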