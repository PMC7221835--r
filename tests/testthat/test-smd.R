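# Steered pulling: pull-atom selection, anchor kinematics, spring-force
# recording, and the schedule bookkeeping.

test_that("select_pull_atoms picks the beads leading in the pulling direction", {
  pos <- cbind(seq(0, 12, 3), 0, 0)   # collinear 5-bead chain along +x
  s <- mk_system(pos, groups = c("ligand-head", rep("ligand-tail", 4)))
  expect_identical(select_pull_atoms(s, direction_spec("x", c(1, 0, 0))), 5L)
  expect_identical(select_pull_atoms(s, direction_spec("-x", c(-1, 0, 0))), 1L)
  expect_identical(select_pull_atoms(s, direction_spec("x", c(1, 0, 0)), 2),
                   c(5L, 4L))

  # L-shaped ligand, 45-degree pull: maximal (x+y)/sqrt(2) projection wins
  L <- rbind(c(0, 0, 0), c(3, 0, 0), c(6, 0, 0), c(6, 3, 0), c(6, 6, 0))
  sL <- mk_system(L, groups = c("ligand-head", rep("ligand-tail", 4)))
  u <- c(1, 1, 0) / sqrt(2)
  brute <- which.max(as.numeric(sweep(L, 2, colMeans(L)) %*% u))
  expect_identical(select_pull_atoms(sL, direction_spec("diag", u)),
                   as.integer(brute))

  # deterministic tie-break by ascending index
  tie <- mk_system(rbind(c(0, 0, 0), c(0, 3, 0)),
                   groups = c("ligand-head", "ligand-tail"))
  expect_identical(select_pull_atoms(tie, direction_spec("x", c(1, 0, 0))), 1L)

  s2 <- mk_system(pos, groups = rep("membrane", 5), restrained = rep(TRUE, 5))
  expect_error(select_pull_atoms(s2, direction_spec("x", c(1, 0, 0))),
               "ligand")
})

test_that("spring force on a frozen ligand ramps as k*v*t (210 pN at 1 ns)", {
  lay <- toy_layout()
  sys <- build_system(lay, ligand_spec(masses = 1e12), seed = 1)
  sch <- pull_schedule(k_pN = 70, v_ms = 0.3, duration_ps = 1000,
                       record_every = 500)
  run <- run_smd(sys, direction = gate_directions(lay)[["TM1-TM7"]],
                 schedule = sch, seed = 1, temperature = 0, friction = 0)
  last <- tail(run$record, 1)
  fmag <- sqrt(last$fx_pN^2 + last$fy_pN^2 + last$fz_pN^2)
  expect_equal(fmag, 70 * mps_to_angps(0.3) * 1000, tolerance = 1e-3)
})

test_that("v -> 0 limit: anchor stationary, work about zero", {
  lay <- toy_layout()
  sys <- build_system(lay, ligand_spec(), seed = 1)
  sch <- pull_schedule(k_pN = 70, v_ms = 1e-9, duration_ps = 50,
                       record_every = 10)
  run <- run_smd(sys, direction = gate_directions(lay)[["TM1-TM7"]],
                 schedule = sch, seed = 3)
  expect_lt(max(dist(as.matrix(run$record[, c("ax", "ay", "az")]))), 1e-6)
  # only the restoring spring acts: net work stays at the thermal scale
  # (a few kT), far below the several-kcal/mol scale of a real pull
  expect_lt(abs(integrate_work(run$record, "kcal_mol")), 1.5)
})

test_that("anchor path is exact and the record length matches the schedule", {
  lay <- toy_layout()
  sys <- build_system(lay, ligand_spec(), seed = 1)
  d <- gate_directions(lay)[["TM4-TM5"]]
  sch <- pull_schedule(k_pN = 70, v_ms = 3, duration_ps = 40,
                       record_every = 25)
  run <- run_smd(sys, direction = d, schedule = sch, seed = 5, dt = 0.01)
  rec <- run$record
  expect_equal(nrow(rec), floor(40 / (0.01 * 25)) + 1)
  expect_true(all(diff(rec$t_ps) > 0))
  # anchor(t) = anchor(0) + v*t*u, exactly as recorded
  expected <- cbind(rec$ax[1] + 0.03 * rec$t_ps * d$unit_vector[1],
                    rec$ay[1] + 0.03 * rec$t_ps * d$unit_vector[2],
                    rec$az[1] + 0.03 * rec$t_ps * d$unit_vector[3])
  expect_equal(as.matrix(rec[, c("ax", "ay", "az")]), expected,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("recorded spring force replays from anchor and COM to round-off", {
  lay <- toy_layout()
  sys <- build_system(lay, ligand_spec(), seed = 1)
  run <- run_smd(sys, direction = gate_directions(lay)[["TM1-TM7"]],
                 schedule = pull_schedule(duration_ps = 60), seed = 9)
  rec <- run$record
  k_kcal <- pn_to_kcal(70)
  replay <- kcal_to_pn(k_kcal * (as.matrix(rec[, c("ax", "ay", "az")]) -
                                   as.matrix(rec[, c("cx", "cy", "cz")])))
  expect_equal(as.matrix(rec[, c("fx_pN", "fy_pN", "fz_pN")]), replay,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("force record and trajectory share timestamps", {
  lay <- toy_layout()
  sys <- build_system(lay, ligand_spec(), seed = 1)
  run <- run_smd(sys, direction = gate_directions(lay)[["UP"]],
                 schedule = pull_schedule(duration_ps = 30), seed = 2)
  expect_equal(run$trajectory$times, run$record$t_ps)
})

test_that("overdamped free ligand reaches a drag-limited steady force", {
  # free-floating ligand, no scaffold: at steady state the spring balances
  # the Langevin drag gamma_eff * v with gamma_eff = friction * total mass
  lig_pos <- cbind(c(0, 3, 6), 0, 0)
  s <- mk_system(lig_pos, eps = 0.2, sigma = 3.6, masses = 40,
                 bonds = cbind(1:2, 2:3), bond_k = rep(30, 2),
                 bond_r0 = rep(3, 2),
                 groups = c("ligand-head", rep("ligand-tail", 2)))
  s$layout <- receptor_layout()   # only for the escape-bound bookkeeping
  v_angps <- 0.5; friction <- 20
  sch <- pull_schedule(k_pN = 200, v_ms = v_angps / 0.01,
                       duration_ps = 45, record_every = 50)
  run <- run_smd(s, direction = direction_spec("x", c(1, 0, 0)),
                 schedule = sch, seed = 8, temperature = 0,
                 friction = friction)
  drag_kcal <- friction * sum(s$masses) * v_angps / 418.4
  tail_f <- mean(tail(run$record$fx_pN, 4))
  expect_equal(tail_f, kcal_to_pn(drag_kcal), tolerance = 0.05)
})
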