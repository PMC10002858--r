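# Distance series, occupancy, lifetimes, classification, multivalency.

test_that("distance_series takes the pairwise minimum per frame", {
  atoms <- data.frame(
    atom_name = c("NZ", "P", "P"),
    residue_name = c("LYS", "SOPS", "SOPS"),
    residue_seq = c(256, 1001, 1002))
  frames <- replicate(10, rbind(c(30, 30, 0), c(34, 30, 0), c(39, 30, 0)),
                      simplify = FALSE)
  traj <- make_traj(atoms, frames)
  expect_equal(distance_series(traj, 1, 2), rep(4, 10))
  # two candidate atoms at 5 and 9 A -> the 5 A one wins
  frames2 <- replicate(3, rbind(c(30, 30, 0), c(35, 30, 0), c(39, 30, 0)),
                       simplify = FALSE)
  traj2 <- make_traj(atoms, frames2)
  expect_equal(distance_series(traj2, 1, 2:3), rep(5, 3))
  expect_error(distance_series(traj, integer(0), 1), "non-empty")
})

test_that("distance_series equals exhaustive pair enumeration", {
  set.seed(9)
  atoms <- data.frame(
    atom_name = c("N", "CA", "C", "P", "P", "P", "P"),
    residue_name = c(rep("GLY", 3), rep("SOPS", 4)),
    residue_seq = c(1, 1, 1, 1001:1004))
  box <- c(15, 18, 22)
  frames <- replicate(25, sweep(matrix(runif(21), ncol = 3), 2, box, `*`),
                      simplify = FALSE)
  traj <- make_traj(atoms, frames, box = box)
  got <- distance_series(traj, 1:3, 4:7)
  want <- vapply(seq_along(frames), function(i) {
    min(outer(1:3, 4:7, Vectorize(function(a, b) {
      brute_min_image(frames[[i]][a, ], frames[[i]][b, ], box)
    })))
  }, 0)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("hand-built 10-frame fixture has occupancy one half", {
  fx <- worked_fixtures(withr::local_tempdir())
  traj <- read_frames(fx[["occupancy10"]])
  sel <- mini_selections(traj$system)
  rec <- contact_records(traj, sel, cutoff = 6)
  occ <- occupancy(rec)
  row <- occ[occ$protein_group == "K256_NZ" & occ$lipid_class == "PS", ]
  expect_equal(row$occupancy_fraction, 0.5)
  # boundary is inclusive: at cutoff 5 the d = 5 frames still bind
  rec5 <- contact_records(traj, sel, cutoff = 5)
  occ5 <- occupancy(rec5)
  expect_equal(occ5$occupancy_fraction[occ5$protein_group == "K256_NZ"], 0.5)
  # and at 4.999 they do not
  rec49 <- contact_records(traj, sel, cutoff = 4.999)
  occ49 <- occupancy(rec49)
  expect_equal(occ49$occupancy_fraction[occ49$protein_group == "K256_NZ"], 0)
})

test_that("the no-contact fixture produces all-zero tables without error", {
  fx <- worked_fixtures(withr::local_tempdir())
  traj <- read_frames(fx[["empty"]])
  rec <- contact_records(traj, mini_selections(traj$system))
  occ <- occupancy(rec)
  expect_true(all(occ$occupancy_fraction == 0))
  expect_equal(nrow(lifetime_table(rec)), 0)
})

test_that("class-level occupancy uses union semantics across molecules", {
  # two lipids bound on disjoint frame sets covering 30% and 20%
  mk_rec <- function(bound, mol) {
    structure(list(protein_group = "K271_NZ", lipid_class = "PS",
                   lipid_molecule_id = mol,
                   distance = ifelse(bound, 4, 10), bound = bound,
                   cutoff = 6), class = "contact_record")
  }
  b1 <- rep(FALSE, 100); b1[1:30] <- TRUE
  b2 <- rep(FALSE, 100); b2[61:80] <- TRUE
  rec <- structure(list(mk_rec(b1, 1L), mk_rec(b2, 2L)),
                   class = "contact_set", time = 0:99, dt = 1)
  expect_equal(occupancy(rec)$occupancy_fraction, 0.5)
  by_mol <- occupancy_by_molecule(rec)
  expect_equal(sort(by_mol$occupancy_fraction), c(0.2, 0.3))
})

test_that("occupancy is monotone non-decreasing in the cutoff", {
  sim <- simulate_trajectory(synthetic_params(
    n_frames = 120, seed = 13,
    contact_plan = data.frame(groups = "K271_NZ", lipid_class = "PS",
                              occupancy = 0.4, mean_lifetime_ns = 2)))
  prev <- -1
  for (cut in c(3, 4.5, 6, 8, 12)) {
    rec <- contact_records(sim$trajectory, synthetic_selections(),
                           cutoff = cut, lipid_classes = "PS")
    occ <- occupancy(rec)
    val <- occ$occupancy_fraction[occ$protein_group == "K271_NZ"]
    expect_gte(val, prev)
    prev <- val
  }
})

test_that("lifetimes segment bound runs and honour gap bridging", {
  b <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(lifetimes(b, dt = 2)$segments, c(6, 4))
  expect_equal(lifetimes(rep(FALSE, 5), dt = 2)$segments, numeric(0))
  expect_equal(lifetimes(rep(FALSE, 5), dt = 2)$max_continuous, 0)
  # gap of one frame bridged into a single segment spanning it
  b2 <- c(TRUE, TRUE, FALSE, TRUE)
  expect_equal(lifetimes(b2, dt = 2, gap_tolerance_frames = 1)$segments, 8)
  expect_equal(lifetimes(b2, dt = 2, gap_tolerance_frames = 0)$segments,
               c(4, 2))
  # bridging never merges across gaps longer than the tolerance
  b3 <- c(TRUE, FALSE, FALSE, TRUE)
  expect_equal(lifetimes(b3, dt = 1, gap_tolerance_frames = 1)$segments,
               c(1, 1))
  expect_equal(lifetimes(b3, dt = 1, gap_tolerance_frames = 2)$segments, 4)
})

test_that("gap bridging matches exhaustive segment enumeration", {
  # oracle: mark every unbound run of length <= g flanked by bound frames
  enumerate_segments <- function(b, g, dt) {
    n <- length(b)
    keep <- b
    i <- 1
    while (i <= n) {
      if (!b[i]) {
        j <- i
        while (j < n && !b[j + 1]) j <- j + 1
        if (i > 1 && j < n && (j - i + 1) <= g) keep[i:j] <- TRUE
        i <- j + 1
      } else i <- i + 1
    }
    r <- rle(keep)
    r$lengths[r$values] * dt
  }
  set.seed(101)
  for (trial in 1:200) {
    b <- runif(30) < 0.4
    g <- sample(0:3, 1)
    expect_equal(lifetimes(b, dt = 0.5, gap_tolerance_frames = g)$segments,
                 enumerate_segments(b, g, 0.5))
  }
})

test_that("total bound time never exceeds the trajectory span and matches occupancy", {
  sim <- simulate_trajectory(synthetic_params(
    n_frames = 400, seed = 17,
    contact_plan = data.frame(groups = "K275_NZ", lipid_class = "PS",
                              occupancy = 0.5, mean_lifetime_ns = 3)))
  rec <- contact_records(sim$trajectory, synthetic_selections(),
                         lipid_classes = "PS",
                         molecule_ids = sim$truth$planted_molecule_id)
  rec <- Filter(function(r) r$protein_group == "K275_NZ", rec)
  ls <- lifetimes(rec[[1]]$bound, dt = sim$trajectory$dt)
  T_total <- 400 * sim$trajectory$dt
  expect_lte(ls$total_bound, T_total)
  # single tracked molecule, gap 0: occupancy == total_bound / T
  expect_equal(mean(rec[[1]]$bound), ls$total_bound / T_total)
})

test_that("multivalency counts simultaneous engagements", {
  fx <- worked_fixtures(withr::local_tempdir())
  traj <- read_frames(fx[["bridge"]])
  rec <- contact_records(traj, mini_selections(traj$system))
  mv <- multivalency(rec)
  lip_mol <- as.character(unique(
    traj$system$atoms$molecule_id[traj$system$atoms$segment_kind == "lipid"]))
  expect_equal(unname(mv$lipid_counts[1, lip_mol]), 2L)
  # one group, one lipid -> counts never exceed 1
  traj1 <- read_frames(fx[["occupancy10"]])
  mv1 <- multivalency(contact_records(traj1, mini_selections(traj1$system)))
  expect_true(all(mv1$lipid_counts <= 1))
  expect_true(all(mv1$group_counts <= 1))
})

test_that("planted bridging episodes are recovered at their stationary rate", {
  p_bridge <- 0.3
  sim <- simulate_trajectory(synthetic_params(
    n_frames = 3000, seed = 29,
    contact_plan = data.frame(groups = "K271_NZ+K275_NZ",
                              lipid_class = "PS", occupancy = p_bridge,
                              mean_lifetime_ns = 2)))
  rec <- contact_records(sim$trajectory, synthetic_selections(),
                         lipid_classes = "PS",
                         molecule_ids = sim$truth$planted_molecule_id)
  mv <- multivalency(rec)
  frac <- mean(mv$lipid_counts[, as.character(sim$truth$planted_molecule_id)] >= 2)
  se <- two_state_se(p_bridge, 2, sim$trajectory$dt, 3000)
  expect_lt(abs(frac - p_bridge), 3 * se)
})
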