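# Interaction-energy decomposition: pinned Coulomb value, symmetry,
# exact E_total identity, the whole-system oracle cross-check, and the
# engineered sign/trend behaviour on entrance trajectories.

test_that("far-apart neutral groups have exactly zero interaction energy", {
  s <- mk_system(rbind(c(0, 0, 0), c(30, 0, 0)), eps = 0.3,
                 groups = c("ligand-head", "membrane"))
  e <- interaction_energy(s, group_a = 1L, group_b = 2L)
  expect_identical(unname(e), c(0, 0))
})

test_that("a +1/-1 pair at 10 A gives E_elec = -33.206 kcal/mol", {
  s <- mk_system(rbind(c(0, 0, 0), c(10, 0, 0)), charges = c(1, -1), eps = 0)
  e <- interaction_energy(s, group_a = 1L, group_b = 2L, cutoff = FALSE)
  expect_equal(unname(e[1]), -33.20636, tolerance = 1e-9)
  expect_equal(unname(e[2]), 0)
})

test_that("interaction energy is symmetric and rejects overlapping groups", {
  sys <- build_system(toy_layout(), ligand_spec(), seed = 1)
  lig <- group_indices(sys, "ligand")
  rec <- group_indices(sys, "receptor")
  e1 <- interaction_energy(sys, group_a = lig, group_b = rec)
  e2 <- interaction_energy(sys, group_a = rec, group_b = lig)
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_error(interaction_energy(sys, group_a = lig, group_b = c(lig[1], rec)),
               "disjoint")
})

test_that("cross-group energy equals the whole-minus-parts oracle", {
  # for pairwise potentials: E_AB = E(A+B) - E(A) - E(B), all pairs included
  sys <- build_system(toy_layout(), ligand_spec(), seed = 1)
  lig <- group_indices(sys, "ligand")
  rec <- group_indices(sys, "receptor")
  nb <- function(idx) {
    sub <- sys
    sub$positions <- sys$positions[idx, , drop = FALSE]
    sub$charges <- sys$charges[idx]; sub$lj_epsilon <- sys$lj_epsilon[idx]
    sub$lj_sigma <- sys$lj_sigma[idx]; sub$masses <- sys$masses[idx]
    sub$restrained <- sys$restrained[idx]
    sub$ref_positions <- sys$ref_positions[idx, , drop = FALSE]
    sub$restraint_k <- 0
    keep <- sys$bonds[, 1] %in% idx & sys$bonds[, 2] %in% idx
    sub$bonds <- matrix(match(sys$bonds[keep, ], idx), ncol = 2)
    sub$bond_k <- sys$bond_k[keep]; sub$bond_r0 <- sys$bond_r0[keep]
    sub$groups <- sys$groups[idx]; sub$n <- length(idx)
    e <- compute_forces(sub, all_pairs = TRUE)$energy
    e$e_lj + e$e_coulomb
  }
  sys$restraint_k <- 0
  e_cross <- sum(interaction_energy(sys, group_a = lig, group_b = rec))
  oracle <- nb(seq_len(sys$n)) - nb(lig) - nb(rec)
  expect_equal(e_cross, oracle, tolerance = 1e-9)
})

test_that("profiles satisfy E_total = E_elec + E_vdw exactly at every sample", {
  sys <- funnel_system()
  st <- sim_state(sys, maxwell_velocities(sys, 300, 2))
  out <- step_langevin(sys, st, 2000, seed = 13, traj_every = 100)
  prof <- energy_profile(sys, attr(out, "trajectory"))
  expect_identical(prof$E_total, prof$E_elec + prof$E_vdw)
  expect_equal(nrow(prof), 21)
})

test_that("a static trajectory yields a constant profile and stride subsamples it", {
  sys <- build_system(toy_layout(), ligand_spec(), seed = 1)
  tr <- list(times = c(0, 1, 2, 3),
             coords = array(rep(sys$positions, each = 4), c(4, sys$n, 3)))
  class(tr) <- "cg_trajectory"
  prof <- energy_profile(sys, tr)
  expect_equal(length(unique(prof$E_total)), 1)
  prof2 <- energy_profile(sys, tr, stride = 2)
  expect_equal(nrow(prof2), 2)
})

test_that("frame/particle mismatches are reported with the frame named", {
  sys <- build_system(toy_layout(), ligand_spec(), seed = 1)
  tr <- list(times = 0, coords = array(0, c(1, 5, 3)))
  class(tr) <- "cg_trajectory"
  expect_error(energy_profile(sys, tr), "5 particles")
  tr2 <- list(times = c(0, 1),
              coords = array(rep(sys$positions, each = 2), c(2, sys$n, 3)))
  tr2$coords[2, 1, 1] <- Inf
  class(tr2) <- "cg_trajectory"
  expect_error(energy_profile(sys, tr2), "frame 2")
})

test_that("vdW energy trends downhill as the ligand enters the funnel", {
  sys <- funnel_system()
  cfg <- sumd_config(site_center = c(0, 0, 0), slice_length = 200L,
                     arrival_radius = 4, record_every = 50L,
                     max_total_steps = 30000L, seed_base = 2L)
  res <- supervise(sys, config = cfg)
  expect_identical(res$termination, "arrived")
  prof <- energy_profile(sys, res$trajectory)
  # smoothed vdW at the end (tail buried in the attractive interior) is well
  # below its value outside the receptor
  sm <- smooth_profile(prof, 9)
  expect_lt(tail(sm$E_vdw, 1), head(sm$E_vdw, 1))
})

test_that("a like-charged rim makes the electrostatic term positive during entry", {
  # head (-1) approaching the extracellular rim (-0.3 per helix top):
  # repulsive, so the electrostatic term starts positive during early entry
  lay <- receptor_layout(rim_charge = -0.3, up_plug = FALSE)
  sys <- build_system(lay, ligand_spec(head_charge = -1), seed = 1)
  sys <- place_ligand(sys, "extracellular", "head_first", seed = 1)
  e <- interaction_energy(sys, cutoff = FALSE)
  expect_gt(e[["E_elec"]], 0)
})
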