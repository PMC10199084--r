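random_frame <- function(n = 12) matrix(rnorm(n * 3), ncol = 3)

test_that("Kabsch superposition removes rigid motion exactly", {
  set.seed(1)
  ref <- random_frame(20)
  self <- kabsch_superpose(ref, ref)
  expect_equal(self$rmsd, 0)
  expect_equal(det(self$rotation), 1)

  shifted <- sweep(ref, 2, c(-1, -2, -3)) # reference translated by (1,2,3)
  expect_equal(kabsch_superpose(shifted, ref)$rmsd, 0)

  rot <- random_rotation()
  expect_lt(kabsch_superpose(ref %*% rot + 0.5, ref)$rmsd, 1e-10)
})

test_that("Kabsch RMSD equals the quaternion eigenvalue oracle on random instances", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    ref <- random_frame(n)
    mob <- ref %*% random_rotation() +
      matrix(rnorm(n * 3, 0, 0.2), ncol = 3) + rnorm(3)
    fit <- kabsch_superpose(mob, ref)
    expect_equal(fit$rmsd, quaternion_rmsd(mob, ref), tolerance = 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("Kabsch RMSD agrees with an established structural-bioinformatics fit", {
  skip_if_not_installed("bio3d")
  set.seed(9)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    ref <- random_frame(n)
    mob <- ref %*% random_rotation() + matrix(rnorm(n * 3, 0, 0.3), ncol = 3)
    ours <- kabsch_superpose(mob, ref)$rmsd
    theirs <- bio3d::rmsd(as.numeric(t(ref)), as.numeric(t(mob)), fit = TRUE)
    expect_lt(abs(ours - theirs), 5.1e-4) # bio3d reports 3 decimals

  }
})

test_that("RMSD is symmetric and invariant under a common rigid transform", {
  set.seed(3)
  a <- random_frame(15)
  b <- a + matrix(rnorm(45, 0, 0.1), ncol = 3)
  expect_equal(kabsch_superpose(a, b)$rmsd, kabsch_superpose(b, a)$rmsd,
               tolerance = 1e-12)
  rot <- random_rotation()
  expect_equal(kabsch_superpose(a %*% rot + 2, b %*% rot + 2)$rmsd,
               kabsch_superpose(a, b)$rmsd, tolerance = 1e-12)
  # superposed RMSD never exceeds the raw RMSD
  for (i in 1:20) {
    p <- random_frame(10); q <- random_frame(10)
    raw <- sqrt(mean(rowSums((p - q)^2)))
    expect_lte(kabsch_superpose(p, q)$rmsd, raw + 1e-12)
  }
  expect_error(kabsch_superpose(random_frame(5), random_frame(6)), "atom counts")
})

test_that("collinear geometries fall back to a flagged translation-only fit", {
  line <- cbind(0:4, 0, 0)
  fit <- kabsch_superpose(line + 1, line)
  expect_true(fit$degenerate)
  expect_equal(fit$rmsd, 0)
})

test_that("RMSD series is zero for static and rigid-motion trajectories", {
  set.seed(5)
  static <- generate_trajectory(trajectory_spec(n_atoms = 10, n_frames = 5,
                                                fluctuation_sd = 0, seed = 2))
  expect_equal(rmsd_series(static)$value, rep(0, 5))
  rigid <- generate_trajectory(trajectory_spec(
    n_atoms = 10, n_frames = 5, fluctuation_sd = 0,
    rigid_motion = list(rotation_rate = 15, translation_rate = 0.3), seed = 2))
  expect_lt(max(rmsd_series(rigid)$value), 1e-10)
})

test_that("fluctuating-trajectory RMSD matches an independent resimulation of its statistics", {
  sigma <- 0.04
  traj <- generate_trajectory(trajectory_spec(n_atoms = 50, n_frames = 2000,
                                              fluctuation_sd = sigma, seed = 31))
  mean_rmsd <- mean(rmsd_series(traj)$value[-1])
  # Monte-Carlo oracle: same statistics, simulated directly without the
  # package generator (reference + jitter on both frames of each pair)
  set.seed(99)
  n <- 50
  ref <- matrix(runif(n * 3, 0, 3), ncol = 3)
  oracle <- replicate(300, {
    a <- ref + matrix(rnorm(n * 3, 0, sigma), ncol = 3)
    b <- ref + matrix(rnorm(n * 3, 0, sigma), ncol = 3)
    quaternion_rmsd(a, b)
  })
  expect_equal(mean_rmsd, mean(oracle), tolerance = 0.05)
})

test_that("RMSF closed forms: static zero, two-point oscillation, Gaussian jitter", {
  static <- generate_trajectory(trajectory_spec(n_atoms = 8, n_frames = 6,
                                                fluctuation_sd = 0, seed = 4))
  expect_equal(rmsf_per_atom(static), rep(0, 8))

  # one atom oscillating +/- d along x amid many static atoms (the static
  # cloud pins the superposition, so the oscillating atom keeps its motion)
  set.seed(17)
  d <- 0.01
  base <- rbind(c(0, 0, 0), matrix(runif(300, 5, 40), ncol = 3))
  osc <- lapply(1:10, function(i) {
    xyz <- base
    xyz[1, 1] <- xyz[1, 1] + d * (-1)^i
    structure_frame(xyz)
  })
  rmsf <- rmsf_per_atom(trajectory(osc))
  expect_equal(rmsf[1], d, tolerance = 0.02)
  expect_lt(max(rmsf[-1]), d / 10)

  # isotropic jitter sd sigma per coordinate -> RMSF ~ sigma * sqrt(3)
  sigma <- 0.03
  traj <- generate_trajectory(trajectory_spec(n_atoms = 50, n_frames = 2000,
                                              fluctuation_sd = sigma, seed = 8))
  rmsf <- rmsf_per_atom(traj)
  expect_equal(mean(rmsf), sigma * sqrt(3), tolerance = 0.05)
  expect_error(rmsf_per_atom(trajectory(list(structure_frame(base)),
                                        times = 0)), "2 frames")
})

test_that("radius of gyration matches closed forms and transforms correctly", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  two <- matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 0.5) # two unit masses at distance 1
  a <- 2
  cube <- as.matrix(expand.grid(c(0, a), c(0, a), c(0, a)))
  expect_equal(radius_of_gyration(cube), a * sqrt(3) / 2)
  # mass weighting: all mass on one atom collapses Rg to zero
  heavy <- structure_frame(two, masses = c(1e12, 1))
  expect_lt(radius_of_gyration(heavy), 1e-5)
  # invariance under rigid transforms, linear under scaling
  set.seed(6)
  xyz <- random_frame(17)
  rot <- random_rotation()
  expect_equal(radius_of_gyration(xyz %*% rot + 5), radius_of_gyration(xyz))
  expect_equal(radius_of_gyration(3 * xyz), 3 * radius_of_gyration(xyz))
  # agrees with direct summation
  centred <- sweep(xyz, 2, colMeans(xyz))
  expect_equal(radius_of_gyration(xyz), sqrt(sum(centred^2) / nrow(xyz)))
})

test_that("hydrogen-bond counting follows the distance and angle criterion", {
  # D at origin, H on the D->A axis, A at 0.28 nm: one bond
  xyz <- matrix(c(0, 0, 0,
                  0.1, 0, 0,
                  0.28, 0, 0), 3, 3, byrow = TRUE)
  frame <- structure_frame(xyz)
  donors <- matrix(c(1L, 2L), 1)
  expect_equal(count_hbonds(frame, donors, 3L), 1)
  # too far
  xyz[3, 1] <- 0.40
  expect_equal(count_hbonds(structure_frame(xyz), donors, 3L), 0)
  # angle beyond 30 degrees
  xyz[3, ] <- c(0.2, 0.2, 0) # 45 degrees off the D-H direction
  expect_equal(count_hbonds(structure_frame(xyz), donors, 3L), 0)
  # criterion is configurable
  expect_equal(count_hbonds(structure_frame(xyz), donors, 3L,
                            hbond_criterion(max_da_distance = 0.5,
                                            max_angle = 60)), 1)
  expect_error(count_hbonds(frame, matrix(c(1L, 9L), 1), 3L), "out of range")
  expect_error(count_hbonds(frame, matrix(c(1L, 1L), 1), 3L), "distinct")
})

test_that("hydrogen-bond counts equal the exhaustive triple scan on random frames", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(6:30, 1)
    xyz <- matrix(runif(n * 3, 0, 0.8), ncol = 3)
    n_don <- sample(1:5, 1)
    donors <- cbind(sample(n, n_don), sample(n, n_don))
    donors <- donors[donors[, 1] != donors[, 2], , drop = FALSE]
    if (nrow(donors) == 0) next
    acceptors <- sample(n, sample(1:6, 1))
    expect_equal(
      count_hbonds(structure_frame(xyz), donors, acceptors),
      brute_force_hbonds(xyz, donors, acceptors))
  }
})

test_that("series summaries use the population sd and honour the equilibration skip", {
  const <- frame_series(0:9, rep(2.5, 10))
  s <- series_summary(const)
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, 0)

  s123 <- series_summary(frame_series(0:2, c(1, 2, 3)))
  expect_equal(s123$mean, 2)
  expect_equal(s123$sd, sqrt(2 / 3))
  expect_equal(s123$min, 1)
  expect_equal(s123$n, 3)

  skipped <- series_summary(frame_series(0:4, c(100, 100, 1, 2, 3)),
                            equilibration_skip = 2)
  expect_equal(skipped$mean, 2)
  expect_error(series_summary(const, equilibration_skip = 100), "no frames")

  set.seed(21)
  noisy <- frame_series(1:4000, rnorm(4000, 0.37, 0.03))
  s <- series_summary(noisy)
  se <- 0.03 / sqrt(4000)
  expect_lt(abs(s$mean - 0.37), 3 * se)
})

test_that("XVG series parse, skip metadata lines and round-trip", {
  path <- tempfile(fileext = ".xvg")
  writeLines(c("# Generated toy series", "@ title \"RMSD\"",
               "0.0 0.12", "10.0 0.15", "20.0 0.14"), path)
  s <- parse_xvg(path, "rmsd_nm")
  expect_equal(s$time, c(0, 10, 20))
  expect_equal(s$value, c(0.12, 0.15, 0.14))
  expect_equal(attr(s, "observable"), "rmsd_nm")

  comments_only <- tempfile(fileext = ".xvg")
  writeLines(c("# a", "@ b"), comments_only)
  expect_error(parse_xvg(comments_only), "no data lines")

  rt <- tempfile(fileext = ".xvg")
  write_xvg(s, rt, title = "round trip")
  back <- parse_xvg(rt, "rmsd_nm")
  expect_equal(back$time, s$time)
  expect_equal(back$value, s$value)
})
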