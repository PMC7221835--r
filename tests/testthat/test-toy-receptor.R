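# Synthetic receptor generator: determinism, geometry invariants, ligand
# placement semantics, and the static ground-truth barrier oracle.

test_that("build_system is deterministic and partitions particles correctly", {
  lay <- toy_layout()
  lig <- ligand_spec()
  s1 <- build_system(lay, lig, seed = 1)
  s2 <- build_system(lay, lig, seed = 1)
  expect_identical(s1$positions, s2$positions)

  # ligand is exactly the unrestrained set
  lig_idx <- group_indices(s1, "ligand")
  expect_identical(which(!s1$restrained), lig_idx)
  expect_length(lig_idx, lig$n_beads)
  expect_identical(sort(unique(s1$groups[lig_idx])),
                   c("ligand-head", "ligand-tail"))
  expect_equal(sum(s1$groups == "ligand-head"), 1)

  # group labels partition all particles; counts track the layout
  expect_equal(length(s1$groups), s1$n)
  expect_equal(sum(startsWith(s1$groups, "helix")) %% lay$n_helices, 0)

  # minimum-separation invariant at build time
  d <- dist(s1$positions)
  expect_gte(min(d), 0.5 * min(s1$lj_sigma))
})

test_that("helix_radius and gap_widths are reconciled consistently", {
  lay <- receptor_layout(gap_widths = c(2, 3, 2, 2, 2, 2, 2))
  expect_equal(lay$helix_radius,
               sum(lay$gap_widths + lay$pillar_sigma) / (2 * pi))
  # supplying a radius rescales gaps proportionally
  lay2 <- receptor_layout(gap_widths = c(2, 3, 2, 2, 2, 2, 2),
                          helix_radius = 10)
  expect_equal(lay2$helix_radius, 10)
  expect_equal(lay2$gap_widths[2] / lay2$gap_widths[1], 3 / 2)
  expect_error(receptor_layout(n_helices = 2), "n_helices")
  expect_error(receptor_layout(gap_widths = c(1, -1)), "gap_widths")
  expect_error(receptor_layout(pocket_radius = 99), "pocket_radius")
})

test_that("ligand placement honours site and orientation semantics", {
  lay <- toy_layout()
  lig <- ligand_spec(n_beads = 4)
  sys <- build_system(lay, lig, seed = 1)

  b <- place_ligand(sys, "bound", "tail_first", gate = "TM1-TM7", seed = 1)
  lig_idx <- group_indices(b, "ligand")
  com <- center_of_mass(b$positions, b$masses, lig_idx)
  expect_lte(sqrt(sum((com - lay$pocket_center)^2)), lay$pocket_radius)

  o <- place_ligand(sys, "outside_gate", "tail_first", gate = "TM1-TM7",
                    seed = 1)
  ang <- which(gate_labels(lay) == "TM1-TM7")
  gate_point <- lay$pocket_center +
    lay$helix_radius * gate_directions(lay)[["TM1-TM7"]]$unit_vector
  head_idx <- which(o$groups == "ligand-head")
  tail_idx <- setdiff(group_indices(o, "ligand"), head_idx)
  d_head <- sqrt(sum((o$positions[head_idx, ] - gate_point)^2))
  d_tail <- min(sqrt(rowSums(
    (o$positions[tail_idx, , drop = FALSE] -
       matrix(gate_point, length(tail_idx), 3, byrow = TRUE))^2)))
  expect_lt(d_tail, d_head)

  # head_first is the exact chain reversal of tail_first
  h <- place_ligand(sys, "outside_gate", "head_first", gate = "TM1-TM7",
                    seed = 1)
  li <- group_indices(sys, "ligand")
  expect_equal(h$positions[li, ], o$positions[rev(li), ], tolerance = 1e-12)

  e <- place_ligand(sys, "extracellular", "tail_first", seed = 1)
  come <- center_of_mass(e$positions, e$masses, li)
  expect_gt(come[3], lay$membrane_z_range[2])
})

test_that("unplaceable ligand fails with a diagnostic naming the site", {
  # a ligand so fat that every site clashes with the scaffold
  expect_error(build_system(toy_layout(), ligand_spec(sigma = 60), seed = 1),
               "steric clash")
  lay <- toy_layout()
  sys <- build_system(lay, ligand_spec(), seed = 1)
  sys$lj_sigma[group_indices(sys, "ligand")] <- 60
  expect_error(place_ligand(sys, "outside_gate", seed = 1), "outside_gate")
})

test_that("static barriers: zero-interaction ligand, symmetry, argmin, monotonicity", {
  # no LJ, no charge -> no barriers anywhere
  ghost <- ligand_spec(n_beads = 2, head_charge = 0, head_epsilon = 0,
                       tail_bead_epsilon = 0)
  b0 <- ground_truth_barriers(receptor_layout(), ghost)
  expect_true(all(abs(b0) < 1e-12))

  # symmetric layout: all lateral gates equal within 1%
  lay <- receptor_layout()
  b <- ground_truth_barriers(lay, ligand_spec())
  lateral <- b[gate_labels(lay)]
  expect_lte(max(lateral) / min(lateral), 1.01)

  # widened gate is the argmin among all directions
  bw <- ground_truth_barriers(toy_layout(), ligand_spec())
  expect_identical(names(which.min(bw)), "TM1-TM7")

  # widening a single gate never increases its barrier
  for (f in c(1.2, 1.5, 2)) {
    bf <- ground_truth_barriers(widen_gate(receptor_layout(), 3, f),
                                ligand_spec())
    expect_lte(bf[["TM3-TM4"]], b[["TM3-TM4"]] + 1e-9)
  }
})

test_that("permuting gap labels permutes barrier estimates identically", {
  g <- c(2.2, 2.5, 2.8, 2.4, 2.6, 2.3, 2.7)
  b1 <- ground_truth_barriers(receptor_layout(gap_widths = g), ligand_spec())
  shift <- c(g[-1], g[1])   # rotate gates by one position
  b2 <- ground_truth_barriers(receptor_layout(gap_widths = shift),
                              ligand_spec())
  lab <- gate_labels(receptor_layout())
  # membrane sheets sit on a square grid, so rotational symmetry is only
  # approximate far from the path; allow a small relative tolerance
  expect_equal(unname(b2[lab[1:6]]), unname(b1[lab[2:7]]), tolerance = 1e-3)
  expect_equal(unname(b2[lab[7]]), unname(b1[lab[1]]), tolerance = 1e-3)
})
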