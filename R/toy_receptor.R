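# Synthetic coarse-grained receptor: a ring of transmembrane-helix-like
# pillars around a central binding pocket, embedded in a two-sheet membrane
# slab, optionally capped by an extracellular plug that blocks vertical
# access.  Lateral inter-helix gates have configurable widths; the widest
# gate is the engineered lowest-barrier exit, giving a ground truth against
# which pathway ranking can be checked.

#' Describe the geometry of the synthetic helix-ring receptor
#'
#' The receptor is a ring of `n_helices` rigid vertical pillars (columns of
#' overlapping Lennard-Jones beads) around a central pocket.  Adjacent pillars
#' are separated by "gates" whose surface-to-surface arc widths are given by
#' `gap_widths` (gate `k` lies between helix `k` and helix `k+1`, the last
#' gate closing the ring).  The ring radius is derived from the gap widths and
#' the pillar diameter; if `helix_radius` is supplied instead, the gaps are
#' rescaled proportionally to fit that circumference.  An extracellular plug
#' (a disc of beads over the pocket, mimicking an N-terminal domain that
#' occludes vertical access) is on by default.
#'
#' @param n_helices number of pillars (>= 3), default 7.
#' @param gap_widths numeric vector of gate arc widths in A (recycled to
#'   `n_helices`).  Exactly one gate may additionally be flagged widest via
#'   [widen_gate()].
#' @param helix_radius optional ring radius in A; if `NULL` (default) derived
#'   from `gap_widths`.
#' @param pocket_center 3-vector, A.
#' @param pocket_radius pocket radius in A; must be smaller than the ring
#'   radius.
#' @param membrane_z_range length-2 interval in A spanned by the membrane slab
#'   (and the pillars).
#' @param up_plug logical; add the extracellular plug disc.
#' @param plug_strength multiplier on the plug bead LJ well depth.
#' @param attractor_charge charge (e) of an optional restrained bead at the
#'   pocket centre; `0` (default) omits the bead.  A small opposite charge to
#'   the ligand head turns the receptor into a gentle binding funnel for
#'   entrance simulations.
#' @param rim_charge charge (e) placed on the extracellular-most bead of each
#'   pillar; models a charged extracellular rim.
#' @param pillar_sigma,pillar_epsilon,pillar_spacing LJ size (A), well depth
#'   (kcal/mol) and vertical bead spacing (A) of the pillar beads.
#' @return object of class `receptor_layout`.
#' @seealso [ligand_spec()], [build_system()], [ground_truth_barriers()]
#' @export
receptor_layout <- function(n_helices = 7,
                            gap_widths = 2.5,
                            helix_radius = NULL,
                            pocket_center = c(0, 0, 0),
                            pocket_radius = 3.5,
                            membrane_z_range = c(-11, 11),
                            up_plug = TRUE,
                            plug_strength = 1.0,
                            attractor_charge = 0,
                            rim_charge = 0,
                            pillar_sigma = 4.6,
                            pillar_epsilon = 0.30,
                            pillar_spacing = 2.2) {
  n_helices <- as.integer(n_helices)
  if (n_helices < 3) stop("n_helices must be >= 3")
  gap_widths <- rep_len(as.numeric(gap_widths), n_helices)
  if (any(gap_widths <= 0)) stop("all gap_widths must be > 0")
  if (length(membrane_z_range) != 2 || diff(membrane_z_range) <= 0)
    stop("membrane_z_range must be an increasing length-2 interval")

  circumference <- sum(gap_widths + pillar_sigma)
  radius <- circumference / (2 * pi)
  if (!is.null(helix_radius)) {
    # rescale gaps proportionally so the requested radius closes the ring
    target <- 2 * pi * helix_radius - n_helices * pillar_sigma
    if (target <= 0) stop("helix_radius too small for the pillar diameters")
    gap_widths <- gap_widths * target / sum(gap_widths)
    radius <- helix_radius
  }
  if (pocket_radius >= radius)
    stop("pocket_radius must be smaller than the ring (helix) radius")

  out <- list(n_helices = n_helices, gap_widths = gap_widths,
              helix_radius = radius, pocket_center = as.numeric(pocket_center),
              pocket_radius = pocket_radius,
              membrane_z_range = as.numeric(membrane_z_range),
              up_plug = isTRUE(up_plug), plug_strength = plug_strength,
              attractor_charge = attractor_charge, rim_charge = rim_charge,
              pillar_sigma = pillar_sigma, pillar_epsilon = pillar_epsilon,
              pillar_spacing = pillar_spacing, widest = NA_integer_)
  class(out) <- "receptor_layout"
  out
}

#' Widen one gate of a receptor layout
#'
#' Multiplies the arc width of a single gate by `factor` and flags it as the
#' designated widest (lowest-barrier) gate.  Only one gate may carry the flag.
#'
#' @param layout a [receptor_layout()].
#' @param gate gate index (1..n_helices) or label such as `"TM1-TM7"`.
#' @param factor multiplicative widening, default 1.5.
#' @return modified `receptor_layout` (ring radius re-derived).
#' @export
widen_gate <- function(layout, gate, factor = 1.5) {
  stopifnot(inherits(layout, "receptor_layout"))
  k <- if (is.character(gate)) match(gate, gate_labels(layout)) else as.integer(gate)
  if (is.na(k) || k < 1 || k > layout$n_helices) stop("unknown gate: ", gate)
  g <- layout$gap_widths
  g[k] <- g[k] * factor
  out <- receptor_layout(
    n_helices = layout$n_helices, gap_widths = g,
    pocket_center = layout$pocket_center, pocket_radius = layout$pocket_radius,
    membrane_z_range = layout$membrane_z_range, up_plug = layout$up_plug,
    plug_strength = layout$plug_strength,
    attractor_charge = layout$attractor_charge, rim_charge = layout$rim_charge,
    pillar_sigma = layout$pillar_sigma, pillar_epsilon = layout$pillar_epsilon,
    pillar_spacing = layout$pillar_spacing)
  out$widest <- k
  out
}

#' Binding-funnel layout preset for entrance simulations
#'
#' The receptor layout used for supervised-entrance experiments: the
#' designated gate is widened (default 2x) so it is clearly traversable, and
#' a weakly charged attractor bead at the pocket centre gives the ligand head
#' a gentle electrostatic funnel towards the site.  The attraction is kept
#' weak (default 0.1 e against the unit-charged head) so that transport is
#' diffusion-dominated: the regime distance supervision is designed to
#' accelerate.
#'
#' @param gate gate to widen, default `"TM1-TM7"`.
#' @param widen_factor gate widening, default 2.
#' @param attractor_charge attractor bead charge, e.
#' @param ... further arguments passed to [receptor_layout()].
#' @return a `receptor_layout`.
#' @export
funnel_layout <- function(gate = "TM1-TM7", widen_factor = 2,
                          attractor_charge = 0.1, ...) {
  widen_gate(receptor_layout(attractor_charge = attractor_charge, ...),
             gate, widen_factor)
}

#' Gate labels of a layout
#'
#' Gate `k` separates helix `k` from helix `k+1`; the ring-closing gate
#' between the last helix and helix 1 is labelled in the GPCR convention
#' `"TM1-TM<n>"` (for 7 helices, `"TM1-TM7"`).
#'
#' @param layout a [receptor_layout()].
#' @return character vector of gate labels.
#' @export
gate_labels <- function(layout) {
  n <- layout$n_helices
  vapply(seq_len(n), function(k) {
    j <- if (k == n) 1L else k + 1L
    paste0("TM", min(k, j), "-TM", max(k, j))
  }, character(1))
}

# pillar centre angles and gate bisector angles (radians)
.ring_angles <- function(layout) {
  w_pillar <- layout$pillar_sigma
  arc <- layout$gap_widths + w_pillar
  # pillar k occupies an arc of w_pillar followed by gate k
  starts <- c(0, cumsum(arc))[seq_len(layout$n_helices)]
  circ <- sum(arc)
  pillar_ang <- (starts + w_pillar / 2) / circ * 2 * pi
  gate_ang <- (starts + w_pillar + layout$gap_widths / 2) / circ * 2 * pi
  list(pillar = pillar_ang, gate = gate_ang)
}

#' Exit direction unit vectors of a layout
#'
#' Lateral gate directions are the outward bisectors of each adjacent helix
#' pair in the membrane plane; `"UP"` is the +z extracellular exit.
#'
#' @param layout a [receptor_layout()].
#' @param labels which direction labels to return; default the lateral gates
#'   plus `"UP"`.
#' @return named list of [direction_spec()] objects.
#' @export
gate_directions <- function(layout, labels = NULL) {
  ang <- .ring_angles(layout)$gate
  gl <- gate_labels(layout)
  dirs <- lapply(seq_along(gl), function(k)
    direction_spec(gl[k], c(cos(ang[k]), sin(ang[k]), 0)))
  names(dirs) <- gl
  dirs$UP <- direction_spec("UP", c(0, 0, 1))
  if (!is.null(labels)) {
    missing <- setdiff(labels, names(dirs))
    if (length(missing)) stop("unknown direction labels: ",
                              paste(missing, collapse = ", "))
    dirs <- dirs[labels]
  }
  dirs
}

#' Describe the bead-chain ligand
#'
#' The ligand is a linear chain of beads: one charged "head" bead (bead 1,
#' abstracting a phosphate-like polar group) followed by hydrophobic "tail"
#' beads with a deeper LJ well.  This abstracts lipid-like agonists with a
#' polar head and a long hydrophobic tail.
#'
#' @param n_beads chain length (>= 2), default 3.
#' @param head_charge head bead charge in e, default -1.
#' @param tail_bead_epsilon LJ well depth of tail beads, kcal/mol.
#' @param head_epsilon LJ well depth of the head bead, kcal/mol.
#' @param sigma LJ size of all ligand beads, A.
#' @param bond_length equilibrium bond length, A.
#' @param bond_k harmonic bond constant, kcal/mol/A^2 (energy `0.5*k*(r-r0)^2`).
#' @param masses per-bead masses in amu (recycled).
#' @return object of class `ligand_spec`.
#' @export
ligand_spec <- function(n_beads = 3, head_charge = -1,
                        tail_bead_epsilon = 0.35, head_epsilon = 0.15,
                        sigma = 3.6, bond_length = 3.0, bond_k = 30,
                        masses = 40) {
  n_beads <- as.integer(n_beads)
  if (n_beads < 2) stop("n_beads must be >= 2")
  out <- list(n_beads = n_beads, head_charge = head_charge,
              tail_bead_epsilon = tail_bead_epsilon,
              head_epsilon = head_epsilon, sigma = sigma,
              bond_length = bond_length, bond_k = bond_k,
              masses = rep_len(as.numeric(masses), n_beads))
  class(out) <- "ligand_spec"
  out
}

# hexagonal-ish grid of points inside an annulus (r_in <= r <= r_out), z fixed
.disc_points <- function(r_in, r_out, spacing, z) {
  xs <- seq(-r_out, r_out, by = spacing)
  pts <- expand.grid(x = xs, y = xs)
  r <- sqrt(pts$x^2 + pts$y^2)
  keep <- r >= r_in & r <= r_out
  cbind(pts$x[keep], pts$y[keep], z)
}

# scaffold beads (everything except the ligand) at their reference positions
.build_scaffold <- function(layout) {
  ang <- .ring_angles(layout)$pillar
  zr <- layout$membrane_z_range
  zs <- seq(zr[1], zr[2], by = layout$pillar_spacing)
  pos <- NULL; grp <- character(0)
  sig <- numeric(0); eps <- numeric(0); chg <- numeric(0); mas <- numeric(0)
  add <- function(p, g, s, e, q, m) {
    pos <<- rbind(pos, p)
    k <- nrow(p)
    grp <<- c(grp, rep(g, k)); sig <<- c(sig, rep(s, k))
    eps <<- c(eps, rep(e, k)); chg <<- c(chg, rep(q, k))
    mas <<- c(mas, rep(m, k))
  }
  R <- layout$helix_radius
  cc <- layout$pocket_center
  for (k in seq_len(layout$n_helices)) {
    p <- cbind(cc[1] + R * cos(ang[k]), cc[2] + R * sin(ang[k]), cc[3] + zs)
    add(p, paste0("helix", k), layout$pillar_sigma, layout$pillar_epsilon,
        0, 72)
    if (layout$rim_charge != 0) {
      # charged extracellular rim bead on top of each pillar
      chg[length(chg)] <- layout$rim_charge
    }
  }
  memb_in <- R + 0.5 * layout$pillar_sigma + 0.5
  for (z in zr) {
    p <- .disc_points(memb_in, memb_in + 8, 5.0, cc[3] + z)
    p[, 1] <- p[, 1] + cc[1]; p[, 2] <- p[, 2] + cc[2]
    add(p, "membrane", 5.0, 0.25, 0, 90)
  }
  if (layout$up_plug) {
    p <- .disc_points(0, R - 0.5, 4.5, cc[3] + zr[2] + 2.5)
    p[, 1] <- p[, 1] + cc[1]; p[, 2] <- p[, 2] + cc[2]
    add(p, "plug", 4.5, 0.30 * layout$plug_strength, 0, 60)
  }
  if (layout$attractor_charge != 0) {
    add(matrix(cc, 1, 3), "attractor", 3.0, 0.05, layout$attractor_charge, 50)
  }
  dimnames(pos) <- NULL
  list(pos = pos, group = grp, sigma = sig, epsilon = eps, charge = chg,
       mass = mas)
}

# ligand bead coordinates for a chain with COM `com`, axis unit vector `u`
# (pointing towards the "target": the gate or site) and orientation.
# tail_first: tail beads (2..n) sit at larger projection on u than the head.
.ligand_chain <- function(ligand, com, u, orientation) {
  n <- ligand$n_beads
  s <- if (orientation == "tail_first") 1 else -1
  # bead i offset: head (i=1) at -s*(n-1)/2*b ... last tail at +s*(n-1)/2*b
  off <- (seq_len(n) - (n + 1) / 2) * ligand$bond_length * s
  sweep(outer(off, u), 2, com, `+`)
}

#' Build the full particle system
#'
#' Assembles scaffold (pillars, membrane sheets, optional plug and attractor)
#' and ligand into one [particle system][build_system].  All scaffold beads
#' are restrained by harmonic tethers to their build positions; the ligand is
#' free.  The ligand starts at the bound site (pocket centre), tail pointing
#' at the widest gate (or gate 1 when none is flagged).
#'
#' @param layout a [receptor_layout()].
#' @param ligand a [ligand_spec()].
#' @param seed integer seed used for clash-resolving jitter during ligand
#'   placement; the build is deterministic for a fixed seed.
#' @param restraint_k scaffold tether force constant, kcal/mol/A^2.
#' @return object of class `particle_system`: a list with `positions` (N x 3),
#'   `charges`, `lj_epsilon`, `lj_sigma`, `masses`, `bonds` (two-column index
#'   matrix), `bond_k`, `bond_r0`, `restrained` (logical), `ref_positions`,
#'   `restraint_k`, `groups` (per-particle label: `helix<k>`, `membrane`,
#'   `plug`, `attractor`, `ligand-head`, `ligand-tail`), and the `layout` and
#'   `ligand` descriptions.
#' @export
build_system <- function(layout, ligand, seed = 1L, restraint_k = 10) {
  stopifnot(inherits(layout, "receptor_layout"), inherits(ligand, "ligand_spec"))
  sc <- .build_scaffold(layout)
  n_sc <- nrow(sc$pos)
  n_lig <- ligand$n_beads
  lig_groups <- c("ligand-head", rep("ligand-tail", n_lig - 1))
  lig_eps <- c(ligand$head_epsilon, rep(ligand$tail_bead_epsilon, n_lig - 1))
  lig_chg <- c(ligand$head_charge, rep(0, n_lig - 1))
  bonds <- cbind(n_sc + seq_len(n_lig - 1), n_sc + seq_len(n_lig - 1) + 1)
  sys <- list(
    positions = rbind(sc$pos, matrix(0, n_lig, 3)),
    charges = c(sc$charge, lig_chg),
    lj_epsilon = c(sc$epsilon, lig_eps),
    lj_sigma = c(sc$sigma, rep(ligand$sigma, n_lig)),
    masses = c(sc$mass, ligand$masses),
    bonds = bonds,
    bond_k = rep(ligand$bond_k, nrow(bonds)),
    bond_r0 = rep(ligand$bond_length, nrow(bonds)),
    restrained = c(rep(TRUE, n_sc), rep(FALSE, n_lig)),
    ref_positions = rbind(sc$pos, matrix(0, n_lig, 3)),
    restraint_k = restraint_k,
    groups = c(sc$group, lig_groups),
    layout = layout, ligand = ligand, n = n_sc + n_lig)
  class(sys) <- "particle_system"
  gate <- if (is.na(layout$widest)) 1L else layout$widest
  place_ligand(sys, site = "bound", orientation = "tail_first", gate = gate,
               seed = seed)
}

#' @export
print.particle_system <- function(x, ...) {
  cat("particle_system:", x$n, "beads (",
      sum(!x$restrained), "ligand,", sum(x$restrained), "scaffold )\n")
  cat("  groups:", paste(names(table(x$groups)), collapse = ", "), "\n")
  invisible(x)
}

#' Indices of a particle group
#'
#' @param system a `particle_system`.
#' @param group group label; `"ligand"` matches both ligand groups,
#'   `"receptor"` matches every non-ligand group.
#' @return integer index vector.
#' @export
group_indices <- function(system, group) {
  if (group == "ligand") return(which(startsWith(system$groups, "ligand")))
  if (group == "receptor") return(which(!startsWith(system$groups, "ligand")))
  idx <- which(system$groups == group)
  if (!length(idx)) stop("no particles in group: ", group)
  idx
}

#' Place the ligand at a named site
#'
#' Repositions the ligand chain (the scaffold is untouched) at one of:
#' `"bound"` (COM at the pocket centre), `"outside_gate"` (just outside the
#' given lateral gate, in the membrane plane), or `"extracellular"` (above the
#' plug on the pocket axis).  `orientation = "tail_first"` points the
#' hydrophobic tail at the gate/pocket; `"head_first"` reverses the chain
#' about the same axis.  Steric clashes with the scaffold are resolved by up
#' to 100 seeded jitter retries, after which an error names the offending
#' pair and the site.
#'
#' @param system a `particle_system`.
#' @param site `"bound"`, `"outside_gate"` or `"extracellular"`.
#' @param orientation `"tail_first"` or `"head_first"`.
#' @param gate gate index or label (used by `"bound"` and `"outside_gate"`);
#'   default the layout's widest gate, else gate 1.
#' @param seed integer seed for the jitter stream.
#' @param standoff distance outside the ring for `"outside_gate"`, A.
#' @return the modified `particle_system`.
#' @export
place_ligand <- function(system, site = c("bound", "outside_gate", "extracellular"),
                         orientation = c("tail_first", "head_first"),
                         gate = NULL, seed = 1L, standoff = 6) {
  site <- match.arg(site)
  orientation <- match.arg(orientation)
  layout <- system$layout; ligand <- system$ligand
  if (is.null(gate)) gate <- if (is.na(layout$widest)) 1L else layout$widest
  k <- if (is.character(gate)) match(gate, gate_labels(layout)) else as.integer(gate)
  if (is.na(k) || k < 1 || k > layout$n_helices) stop("unknown gate: ", gate)
  ang <- .ring_angles(layout)$gate[k]
  u_gate <- c(cos(ang), sin(ang), 0)
  cc <- layout$pocket_center
  R <- layout$helix_radius

  if (site == "bound") {
    com <- cc; u <- u_gate
  } else if (site == "outside_gate") {
    com <- cc + (R + 0.5 * layout$pillar_sigma + standoff) * u_gate
    u <- -u_gate                       # tail points inward, at the gate
  } else {
    top <- layout$membrane_z_range[2] +
      (if (layout$up_plug) 2.5 + 4.5 else 0) + standoff
    com <- cc + c(0, 0, top)
    u <- c(0, 0, -1)                   # tail points down at the pocket
  }

  lig_idx <- group_indices(system, "ligand")
  sc_idx <- which(system$restrained)
  sc_pos <- system$positions[sc_idx, , drop = FALSE]
  # pair-specific contact threshold: half the mixed LJ diameter
  thr2 <- outer(system$lj_sigma[lig_idx], system$lj_sigma[sc_idx],
                function(a, b) (0.25 * (a + b))^2)
  set.seed(seed)
  for (try in 0:100) {
    jit <- if (try == 0) c(0, 0, 0) else runif(3, -1, 1) * min(2, 0.05 * try)
    p <- .ligand_chain(ligand, com + jit, u, orientation)
    d2 <- outer(rowSums(p^2), rowSums(sc_pos^2), `+`) - 2 * p %*% t(sc_pos)
    if (all(d2 >= thr2)) {
      system$positions[lig_idx, ] <- p
      system$ref_positions[lig_idx, ] <- p
      return(system)
    }
  }
  worst <- which.min(d2 - thr2)
  wi <- arrayInd(worst, dim(d2))
  stop(sprintf(paste0("cannot place ligand at site '%s' without steric clash ",
                      "(ligand bead %d vs scaffold bead %d, %.2f A apart)"),
               site, wi[1], sc_idx[wi[2]], sqrt(max(d2[worst], 0))))
}

#' Static energy barrier of each exit direction
#'
#' Rigidly translates the ligand chain (oriented tail-first along the exit
#' line) from the pocket centre outwards along each direction, evaluating the
#' ligand-scaffold nonbonded interaction energy at each displacement, and
#' reports the maximum excess over the bound-pose energy.  This is the
#' brute-force ground-truth oracle against which dynamical pathway rankings
#' are compared: the widest gate must have the smallest static barrier.
#'
#' @param layout a [receptor_layout()].
#' @param ligand a [ligand_spec()].
#' @param directions optional named list of [direction_spec()]; default all
#'   lateral gates plus `"UP"`.
#' @param step scan step in A.
#' @param max_dist scan range beyond the ring radius, A.
#' @return named numeric vector of barrier heights (kcal/mol), one per
#'   direction.
#' @export
ground_truth_barriers <- function(layout, ligand, directions = NULL,
                                  step = 0.25, max_dist = 12) {
  sys <- build_system(layout, ligand, seed = 1L)
  if (is.null(directions)) directions <- gate_directions(layout)
  lig_idx <- group_indices(sys, "ligand")
  sc_idx <- group_indices(sys, "receptor")
  disp <- seq(0, layout$helix_radius + max_dist, by = step)
  out <- vapply(directions, function(d) {
    u <- d$unit_vector
    e <- vapply(disp, function(s) {
      p <- sys$positions
      p[lig_idx, ] <- .ligand_chain(ligand, layout$pocket_center + s * u, u,
                                    "tail_first")
      sum(interaction_energy(sys, p, lig_idx, sc_idx, cutoff = FALSE))
    }, numeric(1))
    max(e) - e[1]
  }, numeric(1))
  setNames(out, names(directions))
}
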