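arena <- list(center = c(0, 0), radius = 45)

four_patches <- function() {
  ang <- c(0, pi / 2, pi, 3 * pi / 2)
  ctr <- cbind(x = 32 * cos(ang), y = 32 * sin(ang))
  rownames(ctr) <- c("Lvs", "Lct", "LvsLct", "Ctr")
  patch_config(ctr, arena)
}

test_that("trajectory smoothing preserves constants and straight lines", {
  fps <- 25
  n <- 500
  const <- trajectory_set(cbind(rep(3, n), rep(-2, n)), fps, arena = arena)
  sm <- smooth_trajectory(const)
  expect_equal(sm$positions[[1]], const$positions[[1]], tolerance = 1e-12)

  line <- trajectory_set(cbind(seq_len(n) * 0.1, seq_len(n) * -0.05), fps,
                         arena = arena)
  sml <- smooth_trajectory(line)
  hw <- 2 * fps
  interior <- (hw + 1):(n - hw)
  expect_lt(max(abs(sml$positions[[1]][interior, ] -
                      line$positions[[1]][interior, ])), 1e-9)
})

test_that("a unit step smooths to the direct convolution of the stated kernel", {
  fps <- 10
  n <- 200
  k_at <- 100
  x <- c(rep(0, k_at - 1), rep(1, n - k_at + 1))
  traj <- trajectory_set(cbind(x, x * 0), fps, arena = arena)
  sm <- smooth_trajectory(traj)$positions[[1]][, 1]
  # independent direct convolution with the truncated renormalized kernel
  hw <- 2 * fps
  sd_f <- (2 / 3) * fps
  kk <- exp(-0.5 * ((-hw:hw) / sd_f)^2)
  kk <- kk / sum(kk)
  direct <- vapply(seq_len(n), function(i) {
    idx <- (i - hw):(i + hw)
    ok <- idx >= 1 & idx <= n
    sum(kk[ok] * x[idx[ok]]) / sum(kk[ok])
  }, numeric(1))
  expect_equal(sm, direct, tolerance = 1e-10)
  # at the step frame the kernel straddles the jump: value near midpoint
  expect_equal(sm[k_at], direct[k_at], tolerance = 1e-12)
  expect_lt(abs(sm[k_at] - 0.5), 0.05)
  # too-short trajectory errors
  short <- trajectory_set(cbind(1:10, 1:10), fps, arena = arena)
  expect_error(smooth_trajectory(short), "shorter")
})

test_that("visit density deposits unit mass per frame and is linear in animals", {
  gs <- 200
  still <- trajectory_set(cbind(rep(0, 50), rep(0, 50)), 25, arena = arena)
  dm <- visit_density(still, sd_px = 15, grid_size = gs)
  # stationary animal at the center: one Gaussian of total mass ~ 1
  expect_equal(sum(dm$grid), 1, tolerance = 1e-6)
  pk <- which(dm$grid == max(dm$grid), arr.ind = TRUE)[1, ]
  expect_equal(unname(pk), c((gs + 1) / 2, (gs + 1) / 2), tolerance = 1)

  # off-center fixed point: argmax lands on its bin
  off <- trajectory_set(cbind(rep(20, 40), rep(-10, 40)), 25, arena = arena)
  dmo <- visit_density(off, sd_px = 8, grid_size = gs)
  pko <- which(dmo$grid == max(dmo$grid), arr.ind = TRUE)[1, ]
  exp_x <- round(1 + (20 + 45) / 90 * (gs - 1))
  exp_y <- round(1 + (-10 + 45) / 90 * (gs - 1))
  expect_equal(unname(pko), c(exp_y, exp_x), tolerance = 1)

  # pooled map equals the mean of the per-animal maps
  two <- trajectory_set(list(cbind(rep(10, 30), rep(10, 30)),
                             cbind(rep(-10, 30), rep(-10, 30))),
                        25, arena = arena)
  dm2 <- visit_density(two, sd_px = 10, grid_size = gs, per_animal = TRUE)
  expect_equal(dm2$grid,
               (dm2$per_animal[[1]] + dm2$per_animal[[2]]) / 2,
               tolerance = 1e-12)
})

test_that("visit density is invariant to frame order and clips outside positions", {
  set.seed(1)
  p <- cbind(runif(100, -40, 40), runif(100, -40, 40))
  d1 <- visit_density(trajectory_set(p, 25, arena = arena),
                      sd_px = 10, grid_size = 150)
  d2 <- visit_density(trajectory_set(p[sample(100), ], 25, arena = arena),
                      sd_px = 10, grid_size = 150)
  expect_equal(d1$grid, d2$grid, tolerance = 1e-12)

  outside <- trajectory_set(cbind(c(0, 500), c(0, 0)), 25, arena = arena)
  expect_warning(d3 <- visit_density(outside, sd_px = 10, grid_size = 100),
                 "clipped")
  expect_equal(d3$n_clipped, 1L)
})

test_that("quarter occupancies normalize, localize, and realign under rotation", {
  cfg <- four_patches()
  gs <- 250
  # uniform map -> 0.25 each
  um <- structure(list(grid = matrix(1, gs, gs), grid_size = gs,
                       sd_px = 1, arena = arena),
                  class = "density_map")
  occ <- quarter_occupancy(um, cfg)
  expect_equal(unname(occ), rep(0.25, 4), tolerance = 0.01)
  expect_equal(sum(occ), 1)

  # all mass at the Lct patch center -> (0, 1, 0, 0)
  still <- trajectory_set(cbind(rep(0, 40), rep(32, 40)), 25, arena = arena)
  dm <- visit_density(still, sd_px = 5, grid_size = gs)
  occ2 <- quarter_occupancy(dm, cfg)
  expect_gt(occ2["Lct"], 0.999)

  # rotated patch configuration: canonical output unchanged
  ang <- c(0, pi / 2, pi, 3 * pi / 2) + pi / 2
  rot_centers <- cbind(x = 32 * cos(ang), y = 32 * sin(ang))
  rownames(rot_centers) <- c("Lvs", "Lct", "LvsLct", "Ctr")
  cfg_rot <- patch_config(rot_centers, arena)
  # the same physical mass now sits in Lvs's rotated quarter
  occ3 <- quarter_occupancy(dm, cfg_rot)
  expect_gt(occ3["Lvs"], 0.999)
})

test_that("occupancy tables sum to one and follow patch relabeling", {
  cfg <- four_patches()
  set.seed(2)
  trajs <- trajectory_set(lapply(1:3, function(i) {
    cbind(runif(200, -40, 40), runif(200, -40, 40))
  }), 25, arena = arena)
  occ <- occupancy_from_frames(trajs, cfg)
  expect_equal(unname(rowSums(occ)), rep(1, 3))
  # permuting which physical patch carries which label permutes columns
  perm_centers <- cfg$centers[c(2, 1, 4, 3), ]
  rownames(perm_centers) <- rownames(cfg$centers)
  occ_perm <- occupancy_from_frames(trajs, patch_config(perm_centers, arena))
  expect_equal(unname(occ_perm[, "Lvs"]), unname(occ[, "Lct"]))
  expect_equal(unname(occ_perm[, "LvsLct"]), unname(occ[, "Ctr"]))
})

test_that("frame-count occupancy agrees with the smoothed density-map route", {
  cfg <- four_patches()
  set.seed(3)
  spec <- agent_spec(n_agents = 2, n_frames = 4000, true_C = c(6, 1, 1, 1),
                     seed = 11)
  g <- generate_choice_trajectories(spec, "VisOlf")
  occ_fast <- colMeans(occupancy_from_frames(g$trajectories, g$config))
  dm <- visit_density(g$trajectories, sd_px = 78, grid_size = 1000)
  occ_map <- quarter_occupancy(dm, g$config)
  expect_lt(max(abs(occ_fast - occ_map)), 0.02)
})

test_that("trajectory CSV round trips", {
  set.seed(4)
  trajs <- trajectory_set(list(a1 = cbind(rnorm(20), rnorm(20)),
                               a2 = cbind(rnorm(20), rnorm(20))),
                          25, animal_ids = c("a1", "a2"), arena = arena)
  path <- tempfile(fileext = ".csv")
  write_trajectories_csv(trajs, path)
  back <- read_trajectories_csv(path, 25, arena)
  expect_equal(back$positions[["a1"]][, 1], trajs$positions[["a1"]][, 1],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(names(back$positions), c("a1", "a2"))
})
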