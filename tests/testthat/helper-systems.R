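# Small hand-built particle systems used across the tests; everything is
# generated in code at test time.

# bare particle system without receptor scaffolding
mk_system <- function(positions, charges = 0, eps = 0.2, sigma = 3.5,
                      masses = 40, bonds = matrix(integer(0), 0, 2),
                      bond_k = numeric(0), bond_r0 = numeric(0),
                      restrained = NULL, restraint_k = 0,
                      groups = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(restrained)) restrained <- rep(FALSE, n)
  if (is.null(groups)) groups <- rep("ligand-tail", n)
  s <- list(positions = positions, charges = rep_len(charges, n),
            lj_epsilon = rep_len(eps, n), lj_sigma = rep_len(sigma, n),
            masses = rep_len(masses, n), bonds = bonds,
            bond_k = bond_k, bond_r0 = bond_r0, restrained = restrained,
            ref_positions = positions, restraint_k = restraint_k,
            groups = groups, n = n)
  class(s) <- "particle_system"
  s
}

# a random jumbled cluster for force-gradient property checks
random_cluster <- function(n, seed, charged = TRUE) {
  set.seed(seed)
  pos <- matrix(runif(3 * n, 0, 8), n, 3)
  # keep particles apart so LJ gradients are well-conditioned
  for (i in seq_len(50)) {
    d <- as.matrix(dist(pos))
    diag(d) <- Inf
    if (min(d) > 2.0) break
    worst <- which(d == min(d), arr.ind = TRUE)[1, ]
    pos[worst[1], ] <- pos[worst[1], ] + runif(3, -1, 1)
  }
  mk_system(pos,
            charges = if (charged) sample(c(-1, 0, 1), n, TRUE) * 0.5 else 0,
            eps = runif(n, 0.05, 0.4), sigma = runif(n, 2.5, 4),
            masses = runif(n, 10, 90),
            bonds = if (n >= 2) matrix(c(1L, 2L), 1, 2) else
              matrix(integer(0), 0, 2),
            bond_k = if (n >= 2) 25 else numeric(0),
            bond_r0 = if (n >= 2) 3 else numeric(0),
            restrained = c(rep(FALSE, n - 1), TRUE), restraint_k = 8)
}

# total (potential + kinetic) energy in kcal/mol
total_energy <- function(system, state) {
  pot <- compute_forces(system, state)$energy$e_total
  kin <- sum(0.5 * system$masses * rowSums(state$velocities^2)) / 418.4
  pot + kin
}

# the standard toy receptor used in pathway tests: gate TM1-TM7 widened 1.5x
toy_layout <- function(...) widen_gate(receptor_layout(...), "TM1-TM7", 1.5)

# funnel system with the ligand staged outside the widened gate
funnel_system <- function(seed = 1) {
  lay <- funnel_layout()
  sys <- build_system(lay, ligand_spec(), seed = seed)
  place_ligand(sys, "outside_gate", "tail_first", gate = "TM1-TM7",
               seed = seed)
}
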