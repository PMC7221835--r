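# BAOAB propagator: deterministic limits, NVE reduction, momentum
# conservation, equipartition, blow-up diagnostics, and checkpointing.

test_that("zero forces, zero velocities, T = 0 leave the state unchanged except time", {
  s <- mk_system(rbind(c(0, 0, 0), c(50, 0, 0)), eps = 0, charges = 0)
  st <- sim_state(s)
  out <- step_langevin(s, st, 100, dt = 0.01, temperature = 0, friction = 0)
  expect_identical(out$positions, st$positions)
  expect_identical(out$velocities, st$velocities)
  expect_equal(out$time, 1)
  expect_equal(out$step, 100L)
})

test_that("T = 0, friction = 0 reduces to velocity Verlet with tiny energy drift", {
  s <- mk_system(rbind(c(0, 0, 0), c(3.4, 0, 0)), eps = 0.2, sigma = 3.0,
                 bonds = matrix(c(1L, 2L), 1, 2), bond_k = 30, bond_r0 = 3)
  st <- sim_state(s, matrix(c(0.1, -0.1, 0, 0, 0, 0), 2, 3))
  e0 <- total_energy(s, st)
  out <- step_langevin(s, st, 1000, dt = 0.002, temperature = 0, friction = 0)
  expect_lt(abs(total_energy(s, out) - e0), 1e-4)
})

test_that("total momentum is conserved to round-off in the NVE limit", {
  s <- random_cluster(6, 3)
  s$restrained <- rep(FALSE, s$n)
  st <- sim_state(s, maxwell_velocities(s, 100, 9))
  p0 <- colSums(s$masses * st$velocities)
  out <- step_langevin(s, st, 500, dt = 0.002, temperature = 0, friction = 0)
  p1 <- colSums(s$masses * out$velocities)
  expect_equal(p1, p0, tolerance = 1e-10)
})

test_that("stochastic trajectories are reproducible for a fixed seed", {
  sys <- build_system(toy_layout(), ligand_spec(), seed = 1)
  st <- sim_state(sys, maxwell_velocities(sys, 300, 5))
  a <- step_langevin(sys, st, 300, seed = 21)
  b <- step_langevin(sys, st, 300, seed = 21)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  c <- step_langevin(sys, st, 300, seed = 22)
  expect_false(identical(c$positions, a$positions))
})

test_that("long thermostatted runs satisfy equipartition within 5%", {
  pos <- cbind(seq(0, 12, 3), 0, 0)
  s <- mk_system(pos, eps = 0.2, sigma = 3.6, masses = 40,
                 bonds = cbind(1:4, 2:5), bond_k = rep(30, 4),
                 bond_r0 = rep(3, 4))
  st <- sim_state(s, maxwell_velocities(s, 300, 1))
  st <- step_langevin(s, st, 5000, seed = 2)        # equilibrate
  ke <- 0; nrep <- 100
  for (i in seq_len(nrep)) {
    st <- step_langevin(s, st, 1000, seed = 1000 + i)
    ke <- ke + sum(0.5 * s$masses * rowSums(st$velocities^2)) / 418.4
  }
  kT_half <- 0.5 * 0.001987204259 * 300
  expect_equal(ke / nrep / (3 * s$n), kT_half, tolerance = 0.05)
})

test_that("restrained particles are tethered, not frozen", {
  s <- mk_system(rbind(c(0, 0, 0)), eps = 0.2, restrained = TRUE,
                 restraint_k = 10)
  st <- sim_state(s)
  out <- step_langevin(s, st, 2000, seed = 4)
  # it moved...
  expect_false(identical(out$positions, st$positions))
  # ...but stays near its tether (3 kT/k ~ 0.18 A^2 per dof; 3 A is generous)
  expect_lt(sqrt(sum((out$positions - s$ref_positions)^2)), 3)
})

test_that("dynamics blow-up aborts with a diagnostic suggesting smaller dt", {
  # a stiff bond stepped far above its stability limit grows without bound
  s <- mk_system(rbind(c(0, 0, 0), c(6, 0, 0)), eps = 0, masses = 20,
                 bonds = matrix(c(1L, 2L), 1, 2), bond_k = 100, bond_r0 = 3)
  st <- sim_state(s)
  expect_error(step_langevin(s, st, 10000, dt = 0.5, temperature = 0,
                             friction = 0), "smaller dt")
})

test_that("checkpoint round trip is bit-exact and replays the same stream", {
  sys <- build_system(toy_layout(), ligand_spec(), seed = 1)
  st <- sim_state(sys, maxwell_velocities(sys, 300, 7))
  st <- step_langevin(sys, st, 100, seed = 31)

  cp <- save_checkpoint(st, index = 3L)
  path <- tempfile(fileext = ".cpt")
  write_checkpoint(cp, path)
  cp2 <- read_checkpoint(path)
  expect_identical(cp2$index, 3L)
  restored <- restore_checkpoint(cp2)
  expect_identical(restored$positions, st$positions)
  expect_identical(restored$velocities, st$velocities)
  expect_identical(restored$rng_label, st$rng_label)

  # restoring then propagating 0 steps reproduces the snapshot exactly
  same <- step_langevin(sys, restored, 0, seed = 99)
  expect_identical(same$positions, st$positions)

  # same stream reproduces the original continuation; a new seed diverges
  cont1 <- step_langevin(sys, st, 200, seed = 77)
  cont2 <- step_langevin(sys, restored, 200, seed = 77)
  expect_identical(cont1$positions, cont2$positions)
  cont3 <- step_langevin(sys, restored, 200, seed = 78)
  expect_false(identical(cont3$positions, cont1$positions))
})

test_that("corrupted checkpoint files fail loudly", {
  path <- tempfile(fileext = ".cpt")
  writeLines("not a checkpoint", path)
  expect_error(read_checkpoint(path), "checkpoint")
  saveRDS(list(format = "something-else"), path)
  expect_error(read_checkpoint(path), "format tag")
})
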