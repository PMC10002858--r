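# Composition builder and the synthetic trajectory generator.

test_that("build_composition uses largest-remainder rounding", {
  comp <- build_composition(c(A = 0.5, B = 0.5), c(10, 7))
  expect_equal(comp$upper, c(5, 5))
  expect_equal(comp$lower, c(4, 3))  # tie broken by class order
  single <- build_composition(c(PS = 1), c(10, 10))
  expect_equal(single$upper, 10)
  expect_equal(composition_percentages(single)$upper_pct, 100)
  # each leaflet sums exactly to its total
  set.seed(3)
  fr <- runif(7); fr <- fr / sum(fr); names(fr) <- lipid_classes()
  comp2 <- build_composition(fr, c(66, 59))
  expect_equal(sum(comp2$upper), 66)
  expect_equal(sum(comp2$lower), 59)
  expect_error(build_composition(c(A = 0.7, B = 0.2), c(5, 5)), "sum to 1")
})

test_that("largest-remainder allocation of printed percentages reproduces counts", {
  # the published tables state target percentages; allocating them onto
  # the leaflet totals must reproduce the published counts
  for (which in c("phorbol", "bryostatin")) {
    comp <- reference_composition(which)
    pct <- composition_percentages(comp)
    for (leaf in c("upper", "lower")) {
      total <- sum(comp[[leaf]])
      fr <- pct[[paste0(leaf, "_pct")]] / 100
      fr <- fr / sum(fr)
      names(fr) <- comp$lipid_class
      got <- build_composition(fr, c(total, total))
      expect_equal(unname(got$upper), comp[[leaf]],
                   info = paste(which, leaf))
    }
  }
})

test_that("the generator is deterministic given the seed", {
  p <- synthetic_params(n_frames = 5, seed = 123,
                        contact_plan = data.frame(
                          groups = "K256_NZ", lipid_class = "CHOL",
                          occupancy = 0.5, mean_lifetime_ns = 1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_trajectory(p, out_dir = d1)
  s2 <- simulate_trajectory(p, out_dir = d2)
  expect_identical(s1$trajectory$coords, s2$trajectory$coords)
  for (f in c("frames.pdb", "frames.gro", "ground_truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  s3 <- simulate_trajectory(synthetic_params(n_frames = 5, seed = 124))
  expect_false(identical(s1$trajectory$coords, s3$trajectory$coords))
})

test_that("the analyzed bound series reproduces the planted chain exactly", {
  sim <- simulate_trajectory(synthetic_params(
    n_frames = 600, seed = 31,
    contact_plan = data.frame(groups = "L250_N", lipid_class = "CHOL",
                              occupancy = 0.5, mean_lifetime_ns = 4)))
  rec <- contact_records(sim$trajectory, synthetic_selections(),
                         lipid_classes = "CHOL",
                         molecule_ids = sim$truth$planted_molecule_id)
  rec <- Filter(function(r) r$protein_group == "L250_N", rec)
  expect_identical(rec[[1]]$bound, sim$truth$chains[, 1])
  # realized lifetimes in the truth equal the analyzed segments
  ls <- lifetimes(rec[[1]]$bound, dt = sim$trajectory$dt)
  expect_equal(ls$segments, sim$truth$realized_lifetimes[[1]])
})

test_that("the absorbing limit stays bound for the whole run", {
  sim <- simulate_trajectory(synthetic_params(
    n_frames = 50, seed = 37,
    contact_plan = data.frame(groups = "K271_NZ", lipid_class = "PS",
                              occupancy = 0.99, mean_lifetime_ns = Inf)))
  expect_equal(sim$truth$realized_occupancy, 1)
  rec <- contact_records(sim$trajectory, synthetic_selections(),
                         lipid_classes = "PS",
                         molecule_ids = sim$truth$planted_molecule_id)
  rec <- Filter(function(r) r$protein_group == "K271_NZ", rec)
  expect_true(all(rec[[1]]$bound))
})

test_that("parameter validation rejects infeasible settings", {
  plan <- function(...) data.frame(groups = "K271_NZ", lipid_class = "PS",
                                   occupancy = 0.5, mean_lifetime_ns = 10,
                                   ...)
  expect_error(synthetic_params(contact_plan = {
    p <- plan(); p$occupancy <- 0; p
  }), "occupancy")
  expect_error(synthetic_params(contact_plan = {
    p <- plan(); p$mean_lifetime_ns <- 0.05; p
  }, dt = 0.1), "exceed dt")
  expect_error(synthetic_params(box = c(20, 20, 90)), "too small")
  expect_error(synthetic_params(contact_plan = rbind(
    plan(lipid_index = 1), plan(lipid_index = 1))), "several entries")
  expect_error(synthetic_params(contact_plan = plan(lipid_index = 99)),
               "index 99")
})

test_that("distinct planted pairs get distinct lipid molecules by default", {
  sim <- simulate_trajectory(synthetic_params(
    n_frames = 10, seed = 41,
    contact_plan = data.frame(
      groups = c("K271_NZ", "K275_NZ"), lipid_class = "PS",
      occupancy = c(0.4, 0.6), mean_lifetime_ns = 2)))
  expect_length(unique(sim$truth$planted_molecule_id), 2)
})

test_that("the three-atom fixture parses as written", {
  fx <- worked_fixtures(withr::local_tempdir())
  sys <- read_structure(fx[["three_atoms"]])
  expect_equal(n_atoms(sys), 3)
  expect_equal(sys$atoms$atom_name, c("N", "CA", "C"))
  expect_equal(unique(sys$atoms$residue_name), "GLY")
})
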