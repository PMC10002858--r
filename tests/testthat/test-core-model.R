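# Static topology, selections and leaflet assignment.

test_that("md_system validates and classifies atoms", {
  atoms <- data.frame(
    atom_name = c("N", "CA", "C", "P", "O3"),
    residue_name = c("GLY", "GLY", "GLY", "SOPS", "CHL1"),
    residue_seq = c(1, 1, 1, 100, 101))
  sys <- md_system(atoms)
  expect_equal(sys$atoms$segment_kind,
               c("protein", "protein", "protein", "lipid", "lipid"))
  expect_equal(sys$atoms$lipid_class, c(NA, NA, NA, "PS", "CHOL"))
  expect_equal(sys$atoms$atom_index, 1:5)
  expect_equal(sys$atoms$molecule_id, c(1, 1, 1, 2, 3))
  expect_warning(
    md_system(data.frame(atom_name = "X1", residue_name = "WAT2",
                         residue_seq = 1)),
    "unknown residue")
  # molecule_id groups must be homogeneous
  atoms$molecule_id <- 1
  expect_error(md_system(atoms), "mixes residue names")
})

test_that("resolve_selection finds exact atom sets and fails loudly", {
  comp <- reference_composition("phorbol")
  sys <- synthetic_system(comp)
  spec <- selection_spec(list(
    list(name = "chol_O3", role = "lipid_probe",
         atoms = list(list(lipid_class = "CHOL", atom_name = "O3"))),
    list(name = "G253", role = "reference",
         atoms = list(list(residue_seq = 253, atom_name = "CA")))
  ))
  res <- resolve_selection(sys, spec)
  # 14 upper + 13 lower cholesterol molecules, one O3 each
  expect_length(res$chol_O3, 27)
  expect_length(res$G253, 1)
  expect_equal(sys$atoms$residue_seq[res$G253], 253)
  # deterministic, sorted, idempotent
  expect_equal(res$chol_O3, sort(res$chol_O3))
  expect_identical(resolve_selection(sys, spec), res)
  # order of groups does not change per-group results
  res_rev <- resolve_selection(sys, selection_spec(list(
    list(name = "G253", role = "reference",
         atoms = list(list(residue_seq = 253, atom_name = "CA"))),
    list(name = "chol_O3", role = "lipid_probe",
         atoms = list(list(lipid_class = "CHOL", atom_name = "O3")))
  )))
  expect_equal(res_rev$chol_O3, res$chol_O3)

  bad <- selection_spec(list(
    list(name = "missing", role = "protein_probe",
         atoms = list(list(residue_seq = 999, atom_name = "N")))))
  expect_error(resolve_selection(sys, bad), "missing.*residue_seq=999")
})

test_that("only lower-leaflet cholesterols are counted in a planted frame", {
  comp <- reference_composition("phorbol")
  sim <- simulate_trajectory(synthetic_params(
    composition = comp, n_frames = 1, seed = 3))
  traj <- sim$trajectory
  res <- resolve_selection(traj$system, synthetic_selections())
  leaf <- leaflet_assign(traj$system, frame_coords(traj, 1), res$headgroups)
  chol_mols <- unique(traj$system$atoms$molecule_id[res$CHOL])
  expect_equal(sum(leaf[as.character(chol_mols)] == "lower"), 13)
})

test_that("leaflet assignment splits by headgroup z about the midplane", {
  atoms <- data.frame(atom_name = c("P", "P"),
                      residue_name = c("SOPS", "SOPS"),
                      residue_seq = c(100, 101))
  sys <- md_system(atoms)
  xyz <- rbind(c(10, 10, 20), c(10, 10, -20))
  leaf <- leaflet_assign(sys, xyz, 1:2)
  expect_equal(unname(leaf), c("upper", "lower"))
  # every lipid gets a leaflet
  expect_setequal(names(leaf), as.character(unique(sys$atoms$molecule_id)))
  expect_error(leaflet_assign(sys, xyz, 1L), "no headgroup atom")
})

test_that("planted leaflet populations are recovered exactly under z-noise", {
  comp <- reference_composition("phorbol")  # 66 upper / 59 lower
  sim <- simulate_trajectory(synthetic_params(
    composition = comp, n_frames = 3, lipid_z_sd = 2, seed = 11))
  traj <- sim$trajectory
  res <- resolve_selection(traj$system, synthetic_selections())
  for (i in seq_len(n_frames(traj))) {
    leaf <- leaflet_assign(traj$system, frame_coords(traj, i),
                           res$headgroups)
    expect_equal(sum(leaf == "upper"), 66)
    expect_equal(sum(leaf == "lower"), 59)
  }
})

test_that("composition -> synthetic system -> counts round-trips exactly", {
  for (which in c("phorbol", "bryostatin")) {
    comp <- reference_composition(which)
    sim <- simulate_trajectory(synthetic_params(
      composition = comp, n_frames = 1, seed = 5))
    res <- resolve_selection(sim$trajectory$system, synthetic_selections())
    got <- leaflet_class_counts(sim$trajectory$system,
                                frame_coords(sim$trajectory, 1),
                                res$headgroups)
    got <- got[match(comp$lipid_class, got$lipid_class), ]
    expect_equal(got$upper, comp$upper)
    expect_equal(got$lower, comp$lower)
  }
})
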