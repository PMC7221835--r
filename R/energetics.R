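# Ligand-receptor interaction-energy profiles along trajectories, split
# into electrostatic and van der Waals contributions.  Interaction energy is
# the cross-group nonbonded pair sum only (no bonded or restraint terms);
# the same switching cutoff as the dynamics engine is used by default, with
# an exact no-cutoff mode for tests.

#' Cross-group interaction energy
#'
#' Sums pairwise Coulomb and Lennard-Jones terms across two disjoint particle
#' groups (intra-group terms excluded); symmetric in group order.
#'
#' @param system a `particle_system`.
#' @param positions N x 3 matrix, a `sim_state`, or `NULL` for the system's
#'   current positions.
#' @param group_a,group_b group labels (see [group_indices()]) or integer
#'   index vectors.
#' @param cutoff apply the engine's switching cutoff (default `TRUE`).
#' @return named numeric vector `c(E_elec, E_vdw)` in kcal/mol.
#' @export
interaction_energy <- function(system, positions = NULL, group_a = "ligand",
                               group_b = "receptor", cutoff = TRUE) {
  pos <- if (is.null(positions)) system$positions
         else if (inherits(positions, "sim_state")) positions$positions
         else as.matrix(positions)
  ia <- if (is.character(group_a)) group_indices(system, group_a) else as.integer(group_a)
  ib <- if (is.character(group_b)) group_indices(system, group_b) else as.integer(group_b)
  if (length(intersect(ia, ib)))
    stop("groups overlap: interaction energy needs disjoint groups")
  e <- pair_interaction_cpp(pos, system$charges, system$lj_epsilon,
                            system$lj_sigma, ia, ib, .default_cutoff,
                            .default_switch, isTRUE(cutoff))
  c(E_elec = e[1], E_vdw = e[2])
}

#' Interaction-energy profile along a trajectory
#'
#' Evaluates [interaction_energy()] on every `stride`-th frame.  At every
#' sample `E_total` is computed as `E_elec + E_vdw` in that order, so the
#' decomposition identity holds exactly.
#'
#' @param system a `particle_system`.
#' @param trajectory a `cg_trajectory` (from [step_langevin()], [run_smd()]
#'   or [supervise()]).
#' @param group_a,group_b groups, as in [interaction_energy()].
#' @param stride frame stride (default 1).
#' @param cutoff apply the switching cutoff.
#' @return data.frame of class `energy_profile`: `t_ps`, `E_elec`, `E_vdw`,
#'   `E_total` (kcal/mol).
#' @export
energy_profile <- function(system, trajectory, group_a = "ligand",
                           group_b = "receptor", stride = 1L, cutoff = TRUE) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  nf <- dim(trajectory$coords)[1]
  if (dim(trajectory$coords)[2] != system$n)
    stop(sprintf("trajectory has %d particles but the system has %d",
                 dim(trajectory$coords)[2], system$n))
  idx <- seq(1, nf, by = stride)
  rows <- lapply(idx, function(f) {
    p <- trajectory$coords[f, , ]
    if (!all(is.finite(p)))
      stop("non-finite coordinates in trajectory frame ", f)
    e <- interaction_energy(system, p, group_a, group_b, cutoff = cutoff)
    data.frame(t_ps = trajectory$times[f], E_elec = e[["E_elec"]],
               E_vdw = e[["E_vdw"]])
  })
  out <- do.call(rbind, rows)
  out$E_total <- out$E_elec + out$E_vdw
  class(out) <- c("energy_profile", "data.frame")
  out
}

#' Running-mean smoothing of an energy profile
#'
#' Centred running mean over `window` samples (shrinking at the edges),
#' applied to each energy column; used for display, never for the
#' decomposition identity.
#'
#' @param profile an `energy_profile`.
#' @param window window width in samples (default 50).
#' @return smoothed `energy_profile`.
#' @export
smooth_profile <- function(profile, window = 50L) {
  sm <- function(x) {
    n <- length(x); h <- window %/% 2
    vapply(seq_len(n), function(i)
      mean(x[max(1, i - h):min(n, i + h)]), numeric(1))
  }
  out <- profile
  for (cl in c("E_elec", "E_vdw", "E_total")) out[[cl]] <- sm(profile[[cl]])
  out
}
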