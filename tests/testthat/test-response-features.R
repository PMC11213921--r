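test_that("normalization contract: per-animal transform then row rescale to [-1, 1]", {
  set.seed(1)
  vals <- matrix(runif(40, 0, 2), 10, 4)
  rm_ <- response_matrix(vals, animal_id = rep(c("a", "b"), each = 5))
  norm <- normalize_matrix(rm_)
  # every non-constant row spans exactly [-1, 1]
  expect_true(all(abs(apply(norm$values, 1, min) + 1) < 1e-12))
  expect_true(all(abs(apply(norm$values, 1, max) - 1) < 1e-12))

  # hand computation on a 2x2 single-animal matrix with entries {0, 1}
  m2 <- response_matrix(matrix(c(0, 1, 1, 0), 2, 2), animal_id = c("a", "a"))
  n2 <- normalize_matrix(m2)
  # sqrt({0,1}) = {0,1}; z-scaling maps to +/- 1 pattern; row rescale
  # preserves the order: row 1 = (-1, +1), row 2 = (+1, -1)
  expect_equal(unname(n2$values[1, ]), c(-1, 1))
  expect_equal(unname(n2$values[2, ]), c(1, -1))

  # duplicating one animal's rows leaves its normalized values unchanged
  vals3 <- rbind(vals, vals[1:5, ])
  rm3 <- response_matrix(vals3, animal_id = c(rep(c("a", "b"), each = 5),
                                              rep("c", 5)))
  n3 <- normalize_matrix(rm3)
  expect_equal(n3$values[1:5, ], norm$values[1:5, ], tolerance = 1e-12)

  # constant row maps to zeros with a warning
  rmc <- response_matrix(rbind(c(1, 1, 1), c(0, 2, 4)),
                         animal_id = c("a", "a"))
  expect_warning(nc <- normalize_matrix(rmc), "constant")
  expect_equal(unname(nc$values[1, ]), c(0, 0, 0))
})

test_that("VRC reproduces hand cases and the brute-force oracle", {
  pts <- matrix(c(0, 1, 10, 11), 4, 1)
  expect_equal(vrc(pts, c(1, 1, 2, 2)), 200) # SSB=100, SSW=1
  pts2 <- matrix(c(0, 2, 10, 12), 4, 1)
  expect_equal(vrc(pts2, c(1, 1, 2, 2)), 50) # SSB=100, SSW=4

  # random instances against an independent double-loop implementation
  set.seed(2)
  for (rep_ in 1:10) {
    n <- sample(20:200, 1)
    p <- sample(1:5, 1)
    k <- sample(2:6, 1)
    x <- matrix(rnorm(n * p), n, p)
    lbl <- sample(k, n, replace = TRUE)
    while (length(unique(lbl)) < 2) lbl <- sample(k, n, replace = TRUE)
    expect_equal(vrc(x, lbl), brute_force_vrc(x, lbl), tolerance = 1e-10)
  }

  # exchangeable data: random labels give VRC ~ 1, below the true split
  set.seed(3)
  x <- matrix(c(rnorm(100, 0), rnorm(100, 8)), ncol = 1)
  true_lbl <- rep(1:2, each = 100)
  rand_vrcs <- replicate(50, vrc(x, sample(true_lbl)))
  expect_lt(abs(mean(rand_vrcs) - 1), 0.5)
  expect_gt(vrc(x, true_lbl), max(rand_vrcs))

  # SSW = 0 flags a degenerate (infinite) criterion
  v <- vrc(matrix(c(0, 0, 5, 5), 4, 1), c(1, 1, 2, 2))
  expect_true(is.infinite(v))
})

test_that("elbow selection: ties, corners, and scale invariance", {
  # exactly linear curve: zero distance everywhere, tie -> smallest k
  lin <- list(k = 2:20, vrc = seq(100, 10, length.out = 19))
  expect_equal(choose_k_elbow(lin), 2)

  # piecewise-linear corner at k = 6
  kk <- 2:20
  v <- ifelse(kk <= 6, 100 + (kk - 2) * 50, 300 - (kk - 6) * 5)
  expect_equal(choose_k_elbow(list(k = kk, vrc = v)), 6)

  # convex exponential decay: interior elbow, invariant to joint
  # rescaling of both axes
  v2 <- 500 * exp(-0.4 * (kk - 2))
  k_sel <- choose_k_elbow(list(k = kk, vrc = v2))
  expect_gt(k_sel, 2)
  expect_lt(k_sel, 20)
  k_scaled <- choose_k_elbow(list(k = kk * 3, vrc = v2 * 3))
  expect_equal(k_scaled, k_sel * 3)

  # non-finite values are dropped with a warning
  v3 <- v2
  v3[4] <- Inf
  expect_warning(k3 <- choose_k_elbow(list(k = kk, vrc = v3)), "non-finite")
  expect_true(k3 %in% kk[-4])
})

test_that("response-vector clustering recovers planted archetypes", {
  set.seed(4)
  arch <- matrix(rnorm(6 * 9), 6, 9) # 6 archetype response vectors
  rows <- arch[rep(1:6, each = 30), ] + matrix(rnorm(180 * 9, 0, 0.05),
                                               180, 9)
  truth <- rep(1:6, each = 30)
  rm_ <- response_matrix(abs(rows), animal_id = rep(1:6, 30))
  norm <- normalize_matrix(rm_)
  res <- cluster_vectors(norm, replicates = 15, seed = 5)
  expect_equal(res$k, 6)
  skip_if_not_installed("mclust")
  expect_gt(mclust::adjustedRandIndex(res$labels, truth), 0.95)
})

test_that("clustering is deterministic and duplication-invariant", {
  set.seed(6)
  arch <- matrix(rnorm(3 * 5, sd = 2), 3, 5)
  rows <- abs(arch[rep(1:3, each = 20), ] +
                matrix(rnorm(60 * 5, 0, 0.05), 60, 5))
  norm <- normalize_matrix(response_matrix(rows, animal_id = rep(1, 60)))
  r1 <- cluster_vectors(norm, k_range = 2:8, replicates = 10, seed = 7)
  r2 <- cluster_vectors(norm, k_range = 2:8, replicates = 10, seed = 7)
  expect_identical(r1$labels, r2$labels)

  # duplicated dataset: k-means at fixed k gives identical centroids
  # (the VRC elbow itself may move, since doubling N rescales the
  # curve and chord distance is not invariant to VRC-axis scaling)
  x1 <- norm$values
  x2 <- rbind(x1, x1)
  f1 <- withr::with_seed(9, locustal:::.kmeans_online(x1, 3, replicates = 10))
  f2 <- withr::with_seed(9, locustal:::.kmeans_online(x2, 3, replicates = 10))
  o1 <- f1$centers[order(f1$centers[, 1]), ]
  o3 <- f2$centers[order(f2$centers[, 1]), ]
  expect_equal(unname(o1), unname(o3), tolerance = 1e-6)
})

test_that("mixture-specific fractions count correctly", {
  act <- cbind(Laa = c(TRUE, TRUE, FALSE, FALSE, TRUE),
               Lct = c(TRUE, FALSE, FALSE, FALSE, TRUE),
               LaaLct = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # responders to mixture: 4; mixture-only (no Laa, no Lct): rows 3, 4
  expect_equal(mixture_specific_fraction(act, "LaaLct", c("Laa", "Lct")),
               0.5)
  # every mixture responder also responds to a component -> 0
  act2 <- act
  act2[, "Laa"] <- act2[, "LaaLct"]
  expect_equal(mixture_specific_fraction(act2, "LaaLct", c("Laa", "Lct")), 0)
  # no mixture responders -> undefined
  act3 <- act
  act3[, "LaaLct"] <- FALSE
  expect_warning(
    expect_true(is.na(mixture_specific_fraction(act3, "LaaLct",
                                                c("Laa", "Lct")))),
    "undefined")

  # planted population: 20% mixture-specific among mixture responders
  set.seed(8)
  n <- 400
  mix_resp <- rep(TRUE, n)
  specific <- rbinom(n, 1, 0.2) == 1
  actp <- cbind(Laa = !specific & rbinom(n, 1, 0.7) == 1,
                Lct = !specific, LaaLct = mix_resp)
  actp[specific, c("Laa", "Lct")] <- FALSE
  f <- mixture_specific_fraction(actp, "LaaLct", c("Laa", "Lct"))
  ci <- qbinom(c(0.005, 0.995), n, 0.2) / n
  expect_gte(f, ci[1])
  expect_lte(f, ci[2])
})

test_that("consistency analysis separates within- from between-odor distances", {
  mk_map <- function(base, noise = 0) {
    base + matrix(rnorm(length(base), 0, noise), nrow(base))
  }
  set.seed(9)
  bases <- lapply(1:3, function(i) matrix(runif(64), 8, 8))
  names(bases) <- c("Laa", "Hex", "Oct")

  # identical within, distinct across: within = 0, tree groups odors
  maps0 <- lapply(bases, function(b) list(b, b, b))
  res0 <- consistency_analysis(maps0)
  expect_equal(res0$within, 0, tolerance = 1e-9)
  expect_gt(res0$between, 0)
  expect_gt(res0$cophenetic, 0.99)

  # all maps identical: all distances zero
  same <- list(a = list(bases[[1]], bases[[1]]),
               b = list(bases[[1]], bases[[1]]))
  res_same <- consistency_analysis(same)
  expect_equal(max(res_same$dist), 0, tolerance = 1e-9)

  # noisy odor-specific patterns: margin grows as noise shrinks
  margin <- vapply(c(0.5, 0.1), function(ns) {
    mapsn <- lapply(bases, function(b) lapply(1:4, function(i) mk_map(b, ns)))
    r <- consistency_analysis(mapsn)
    r$between - r$within
  }, numeric(1))
  expect_true(all(margin > 0))
  expect_gt(margin[2], margin[1])

  # Newick export of the tree
  skip_if_not_installed("ape")
  nwk <- tree_newick(res0$tree, labels = paste0(res0$odor, seq_along(res0$odor)))
  expect_match(nwk, "^\\(.*\\);$")
})
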