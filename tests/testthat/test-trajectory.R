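test_that("superposition recovers rigid transforms exactly", {
  set.seed(1)
  P <- matrix(rnorm(30), ncol = 3)
  # identity case
  fit <- superpose(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)
  # rigidly rotated + translated copy
  R <- random_rotation(); tr <- c(5, -2, 9)
  Q <- P %*% t(R) + rep(tr, each = nrow(P))
  fit <- superpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-8)
  expect_equal(fit$transform(Q), P, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
})

test_that("superposition RMSD is symmetric and rigid-invariant", {
  set.seed(2)
  for (k in 1:5) {
    A <- matrix(rnorm(30), ncol = 3)
    B <- matrix(rnorm(30), ncol = 3)
    expect_equal(superpose(A, B)$rmsd, superpose(B, A)$rmsd,
                 tolerance = 1e-10)
    R <- random_rotation()
    expect_equal(superpose(A %*% t(R) + 3, B %*% t(R) + 3)$rmsd,
                 superpose(A, B)$rmsd, tolerance = 1e-8)
  }
})

test_that("superposition rejects reflections and degenerate input", {
  set.seed(3)
  A <- matrix(rnorm(30), ncol = 3)
  mirrored <- A %*% diag(c(1, 1, -1))
  fit <- superpose(A, mirrored)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)
  expect_gt(fit$rmsd, 0)  # a proper rotation cannot undo a mirror
  expect_error(superpose(A[1:2, ], A[1:2, ]), ">= 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "rank-deficient")
})

test_that("Kabsch agrees with bio3d on a standard fit", {
  set.seed(4)
  A <- matrix(rnorm(60), ncol = 3)
  B <- A + matrix(rnorm(60, sd = 0.3), ncol = 3)
  ours <- superpose(A, B)$rmsd
  ref <- bio3d::rmsd(as.vector(t(A)), as.vector(t(B)), fit = TRUE)
  expect_lt(abs(ours - ref), 6e-4)  # bio3d rounds to 3 decimals
})

test_that("RMSD series: frozen and single-frame cases, analytic wobble mean", {
  s <- gen_bead_tetramer(n_monomers = 1, n_residues = 60,
                         target_dipole = 0, seed = 5)
  frozen <- trajectory(s, replicate(5, coords(s), simplify = FALSE))
  expect_equal(rmsd_series(frozen), rep(0, 5), tolerance = 1e-10)
  single <- trajectory(s, list(coords(s)))
  expect_equal(rmsd_series(single), 0, tolerance = 1e-10)

  # independent Gaussian wobble: frame-vs-reference displacement has
  # variance 2 sigma^2 per axis, so E[RMSD] ~ sigma * sqrt(6)
  sigma <- 0.8
  tr <- gen_wobble_trajectory(s, n_frames = 2000, sigma = sigma, seed = 6)
  series <- rmsd_series(tr, reference = 1, align = "calpha")
  expect_equal(mean(series[-1]), sigma * sqrt(6), tolerance = 0.05)
})

test_that("RMSF of an isotropic wobble equals sigma * sqrt(3)", {
  s <- gen_bead_tetramer(n_monomers = 1, n_residues = 40,
                         target_dipole = 0, seed = 7)
  tr <- gen_wobble_trajectory(s, n_frames = 1500, sigma = 1.0, seed = 8)
  prof <- rmsf(tr, trim = 0.1)
  expect_equal(mean(prof$per_residue$rmsf), sqrt(3), tolerance = 0.05)
  # frozen trajectory has zero fluctuation
  frozen <- trajectory(s, replicate(4, coords(s), simplify = FALSE))
  expect_equal(max(rmsf(frozen, trim = 0)$per_residue$rmsf), 0,
               tolerance = 1e-10)
})

test_that("RMSF is invariant under global rigid motion of the frames", {
  s <- gen_bead_tetramer(n_monomers = 1, n_residues = 40,
                         target_dipole = 0, seed = 9)
  plain <- gen_wobble_trajectory(s, n_frames = 300, sigma = 1.0, seed = 10)
  moved <- gen_wobble_trajectory(s, n_frames = 300, sigma = 1.0, seed = 10,
                                 rigid_motion = TRUE)
  p1 <- rmsf(plain, trim = 0)$per_residue$rmsf
  p2 <- rmsf(moved, trim = 0)$per_residue$rmsf
  expect_equal(p1, p2, tolerance = 0.02)
})

test_that("mean squared displacement equals the summed per-axis variances", {
  s <- gen_bead_tetramer(n_monomers = 2, n_residues = 100,
                         target_dipole = 0, seed = 11)
  tr <- gen_wobble_trajectory(s, n_frames = 300, sigma = 1.0, seed = 12)
  prof <- rmsf(tr, align = "all", trim = 0)
  nat <- nrow(s$atoms)
  v <- sapply(1:3, function(ax)
    apply(tr$coords[, ax, ], 1, function(x) mean((x - mean(x))^2)))
  expect_equal(mean(prof$per_atom^2), mean(rowSums(v)), tolerance = 0.03)
})

test_that("equilibration trim behaves as a prefix drop", {
  s <- gen_bead_tetramer(n_monomers = 1, n_residues = 30,
                         target_dipole = 0, seed = 13)
  tr <- gen_wobble_trajectory(s, n_frames = 50, sigma = 0.5, seed = 14)
  p0 <- rmsf(tr, trim = 0)
  expect_equal(p0$n_frames_used, 50)
  p10 <- rmsf(tr, trim = 0.1)
  expect_equal(p10$n_frames_used, 45)
  p_abs <- rmsf(tr, trim = 5)
  expect_equal(p_abs$per_residue$rmsf, p10$per_residue$rmsf)
  expect_error(rmsf(tr, trim = 50), "trim")
  expect_error(rmsf(tr, trim = 49), ">= 2 frames")
})

test_that("per-loop RMSF summarizes the configured residue ranges", {
  s <- gen_bead_tetramer(n_monomers = 2, n_residues = 100,
                         target_dipole = 0, seed = 15)
  tr <- gen_wobble_trajectory(s, n_frames = 400, sigma = 0.4,
                              loops = default_loops(),
                              loop_sigma = c(1.2, 0.8), seed = 16)
  lr <- loop_rmsf(rmsf(tr, trim = 0.1))
  expect_named(lr, c("L3,4", "L5,6"))
  expect_equal(unname(lr[1]), 1.2 * sqrt(3), tolerance = 0.06)
  expect_equal(unname(lr[2]), 0.8 * sqrt(3), tolerance = 0.06)
  # monomer scoping restricts the average
  one <- loop_rmsf(rmsf(tr, trim = 0.1),
                   list(loop_definition("L3,4", 35, 45, monomers = "A")))
  expect_false(is.na(one))
  expect_error(loop_definition("bad", 45, 35), "reversed")
})

test_that("trajectory dipole statistics: static replication and charge checks", {
  s <- gen_bead_tetramer(n_monomers = 2, n_residues = 40,
                         target_dipole = 120, seed = 17)
  static <- trajectory(s, replicate(6, coords(s), simplify = FALSE))
  st <- trajectory_dipole_stats(static, trim = 0)
  expect_equal(st$sd, 0, tolerance = 1e-10)
  expect_equal(st$mean, 120, tolerance = 1e-6)
  expect_equal(dim(st$series), c(6L, 2L))

  uncharged <- s; uncharged$atoms$charge <- 0
  tr0 <- trajectory(uncharged, replicate(3, coords(s), simplify = FALSE))
  expect_error(trajectory_dipole_stats(tr0), "configuration error")
})
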