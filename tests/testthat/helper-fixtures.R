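# Shared fixture builders. Everything is generated in code at test
# time; no stored binary data.

# single-cue availability: one information class advertised at one patch
single_cue_W <- function(class_idx = 1, patch = "Lvs") {
  W <- matrix(0, 4, 4,
              dimnames = list(c("Lvs", "Lct", "LvsLct", "Ctr"),
                              c("socio_visual", "food_visual",
                                "socio_olfactory", "food_olfactory")))
  W[patch, class_idx] <- 1
  W
}

# profile rows drawn from the motif template library plus noise
template_rows <- function(n_rows, n_frames = 40, onset = 11,
                          noise_sd = 0.05, templates = NULL, seed = 1) {
  lib <- motif_templates()
  if (is.null(templates)) templates <- setdiff(names(lib), "silent")
  t_s <- seq_len(n_frames) - onset
  withr::with_seed(seed, {
    truth <- rep(seq_along(templates), length.out = n_rows)
    rows <- t(vapply(truth, function(i) {
      lib[[templates[i]]](t_s) + stats::rnorm(n_frames, 0, noise_sd)
    }, numeric(n_frames)))
    list(rows = rows, truth = truth, templates = templates)
  })
}

# small planted-cell scene with excitatory motifs only (every cell
# detectable by an intensity-based active call)
excitatory_scene <- function(n_cells = 10, shape = c(64, 64),
                             noise_sd = 2, seed = 1, ...) {
  exc <- c("phasic_fast", "phasic_slow", "sustained", "delayed")
  assign_mat <- withr::with_seed(seed, {
    matrix(sample(exc, n_cells * 3, replace = TRUE), n_cells, 3)
  })
  scene_spec(frame_shape = shape, n_cells = n_cells, noise_sd = noise_sd,
             motif_assignment = assign_mat, seed = seed + 1, ...)
}

# triplet populations with planted interaction structure:
# "synergy" = weak components / strong mixture motifs,
# "antagonism" = the reverse, "flat" = mixture-neutral
triplet_population <- function(n_animals, style, phen, n_units = 40,
                               seed = 1) {
  patterns <- switch(style,
    synergy = rbind(c(1, 1, 6), c(2, 1, 6), c(1, 2, 5), c(3, 3, 4),
                    c(2, 2, 2), c(4, 4, 4)),
    antagonism = rbind(c(6, 6, 1), c(5, 6, 2), c(6, 5, 1), c(4, 4, 3),
                       c(2, 2, 2), c(4, 4, 4)))
  w <- c(0.3, 0.2, 0.2, 0.1, 0.1, 0.1)
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_animals), function(a) {
      idx <- sample(nrow(patterns), n_units, replace = TRUE, prob = w)
      data.frame(unit = paste0(phen, a, "_", seq_len(n_units)),
                 Lct = patterns[idx, 1], Laa = patterns[idx, 2],
                 LaaLct = patterns[idx, 3],
                 animal = paste0(phen, a), phenotype = phen)
    }))
  })
}

# exhaustive sign-flip oracle for the paired randomization test
enumerate_paired_p <- function(x) {
  n <- length(x)
  T_obs <- abs(mean(x)) / (sd(x) / sqrt(n))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  Ts <- apply(signs, 1, function(s) {
    xs <- s * x
    abs(mean(xs)) / (sd(xs) / sqrt(n))
  })
  mean(Ts >= T_obs - 1e-12)
}

# exhaustive label-assignment oracle for the two-sample test
enumerate_two_sample_p <- function(z, y) {
  n <- length(z); m <- length(y)
  pool <- c(z, y)
  T_of <- function(zi, yi) {
    abs(mean(zi) - mean(yi)) / sqrt(var(zi) / n + var(yi) / m)
  }
  T_obs <- T_of(z, y)
  combs <- utils::combn(n + m, n)
  Ts <- apply(combs, 2, function(ix) T_of(pool[ix], pool[-ix]))
  mean(Ts >= T_obs - 1e-12)
}

# direct (dense, loop-based) VRC for cross-checking the fast path
brute_force_vrc <- function(points, labels) {
  points <- as.matrix(points)
  ids <- unique(labels)
  N <- nrow(points)
  k <- length(ids)
  gm <- colMeans(points)
  ssb <- 0
  ssw <- 0
  for (c_ in ids) {
    xs <- points[labels == c_, , drop = FALSE]
    cm <- colMeans(xs)
    ssb <- ssb + nrow(xs) * sum((cm - gm)^2)
    for (i in seq_len(nrow(xs))) ssw <- ssw + sum((xs[i, ] - cm)^2)
  }
  ssb * (N - k) / (ssw * (k - 1))
}
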