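# Insertion depth, tilt angle, topology histograms, APL, stability QC.

# A toy bilayer: PS phosphates in both leaflets plus a one-atom "protein"
# reference whose depth is controlled directly.
depth_toy <- function(ref_z, n_ps = 4) {
  atoms <- data.frame(
    atom_name = c("CA", rep("P", 2 * n_ps)),
    residue_name = c("GLY", rep("SOPS", 2 * n_ps)),
    residue_seq = c(253, 1000 + seq_len(2 * n_ps)))
  xy <- cbind(10 * seq_len(2 * n_ps), 10)
  frames <- lapply(ref_z, function(z) {
    rbind(c(30, 30, z),
          cbind(xy, rep(c(20, -20), each = n_ps)))
  })
  make_traj(atoms, frames, box = c(90, 90, 90))
}

test_that("insertion depth is signed toward the membrane midplane", {
  traj <- depth_toy(c(-20, -12, -25))
  sys <- traj$system
  ref <- 1L
  ph <- which(sys$atoms$atom_name == "P")
  dep <- insertion_depth(traj, ref, ph, headgroup_idx = ph)
  # lower-leaflet plane at -20: on-plane -> 0, inside -> +8, outside -> -5
  expect_equal(dep$depth, c(0, 8, -5))
  expect_equal(dep$plane_z, rep(-20, 3))
})

test_that("insertion depth is invariant to a global z shift", {
  traj <- depth_toy(c(-12, -14))
  shifted <- traj
  shifted$coords[, 3, ] <- shifted$coords[, 3, ] + 7.5
  ph <- which(traj$system$atoms$atom_name == "P")
  d1 <- insertion_depth(traj, 1L, ph, ph)
  d2 <- insertion_depth(shifted, 1L, ph, ph)
  expect_equal(d1$depth, d2$depth)
})

test_that("empty phosphate selections are rejected", {
  traj <- depth_toy(-12)
  ph <- which(traj$system$atoms$atom_name == "P")
  expect_error(insertion_depth(traj, 1L, integer(0), ph), "phosphate")
  expect_error(insertion_depth(traj, integer(0), ph, ph), "reference")
})

test_that("tilt angle follows the membrane-normal convention", {
  expect_equal(tilt_angle(tilt_toy(c(0, 0, 1)))$tilt, 0)
  expect_equal(tilt_angle(tilt_toy(c(1, 0, 0)))$tilt, 90)
  expect_equal(tilt_angle(tilt_toy(c(1, 0, 1)))$tilt, 45)
  # axis pointing downward folds back into [0, 90]
  expect_equal(tilt_angle(tilt_toy(c(0, 0, -1)))$tilt, 0)
  # complementary (in-plane) convention
  expect_equal(tilt_angle(tilt_toy(c(1, 0, 1)),
                          convention = "in_plane")$tilt, 45)
  expect_equal(tilt_angle(tilt_toy(c(0, 0, 1)),
                          convention = "in_plane")$tilt, 90)
})

test_that("tilt is invariant to translation and rotation about z", {
  traj <- tilt_toy(c(1, 0.4, 1.2))
  base <- tilt_angle(traj)$tilt
  shifted <- traj
  shifted$coords <- shifted$coords + array(rep(c(5, -3, 12),
                                               each = dim(traj$coords)[1]),
                                           dim(traj$coords))
  expect_equal(tilt_angle(shifted)$tilt, base)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rotated <- traj
  rotated$coords[, , 1] <- traj$coords[, , 1] %*% t(Rz)
  expect_equal(tilt_angle(rotated)$tilt, base)
  expect_error(tilt_angle(traj, upper_residues = c(239, 999)), "999")
})

test_that("planted tilt is recovered exactly on the rigid scaffold", {
  sim <- simulate_trajectory(synthetic_params(
    n_frames = 5, tilt_mean = 37, tilt_sd = 0, depth_sd = 0, seed = 21))
  expect_equal(tilt_angle(sim$trajectory)$tilt, rep(37, 5), tolerance = 1e-8)
})

test_that("topology histograms pool counts and report pooled means", {
  h1 <- topology_histogram(rep(5, 10), rep(38, 10))
  expect_equal(sum(h1$counts), 10)
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(h1$depth_mean, 5)
  expect_equal(h1$tilt_mean, 38)
  h2 <- topology_histogram(list(rep(5, 10), rep(8, 6)),
                           list(rep(38, 10), rep(48, 6)))
  expect_equal(sum(h2$counts), 16)
  expect_equal(h2$counts[h2$counts > 0], c(10, 6))
  # out-of-range frames are clamped, never dropped
  expect_message(h3 <- topology_histogram(c(5, 99), c(38, 38)), "clamped")
  expect_equal(sum(h3$counts), 2)
})

test_that("area per lipid matches box area over leaflet counts", {
  comp <- reference_composition("phorbol")
  atoms <- data.frame(atom_name = "P", residue_name = "SOPS",
                      residue_seq = 1000)
  frames <- replicate(4, matrix(c(1, 1, -20), 1), simplify = FALSE)
  traj <- make_traj(atoms, frames, box = c(60, 60, 90))
  apl <- area_per_lipid(traj, comp)
  expect_equal(apl$lower, rep(3600 / 59, 4))
  expect_equal(apl$lower[1], 61.02, tolerance = 1e-4)
  expect_equal(apl$upper, rep(3600 / 66, 4))
  # doubling the lateral area doubles APL
  traj2 <- make_traj(atoms, frames, box = c(120, 60, 90))
  expect_equal(area_per_lipid(traj2, comp)$lower, 2 * apl$lower)
})

test_that("stability_check flags drift and passes constants", {
  t <- seq(0, 200, by = 0.2)
  st <- stability_check(rep(8, length(t)), t, window_ns = 100)
  expect_equal(st$verdict, "stable")
  expect_equal(st$slope, 0)
  st2 <- stability_check(8 + 1 * t, t, window_ns = 100, tolerance = 0.01)
  expect_equal(st2$verdict, "drifting")
  expect_equal(st2$slope, 1, tolerance = 1e-9)
  expect_error(stability_check(rep(1, 10), 1:10, window_ns = 100), "window")
})

test_that("AR(1) noise about a fixed mean is called stable almost always", {
  # depth-like fluctuations: stationary sd 0.5 A, correlation time ~0.3 ns
  t <- (0:999) * 0.1
  phi <- 0.7
  innov_sd <- 0.5 * sqrt(1 - phi^2)
  verdicts <- vapply(1:200, function(s) {
    set.seed(4000 + s)
    x <- as.numeric(stats::arima.sim(list(ar = phi), 1000, sd = innov_sd))
    stability_check(8 + x, t, window_ns = 50)$verdict
  }, "")
  expect_gte(mean(verdicts == "stable"), 0.95)
})
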