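# Langevin dynamics engine: CHARMM-style pairwise Lennard-Jones (with
# Lorentz-Berthelot mixing) + Coulomb nonbonded terms under a 10-12 A
# switching cutoff, harmonic bonds and scaffold position restraints,
# propagated with the BAOAB splitting.  At T = 0 and friction = 0 the
# propagator reduces exactly to velocity Verlet.
#
# Nonbonded pairs in which BOTH particles are restrained scaffold beads are
# excluded by default: the scaffold geometry is maintained by its tethers,
# and the ligand-scaffold interactions are the ones that matter for egress.
# `all_pairs = TRUE` restores the full pair sum (used by analysis oracles).

.default_cutoff <- 12
.default_switch <- 10

.ff_args <- function(system, all_pairs = FALSE, cutoff = TRUE) {
  list(q = system$charges, eps = system$lj_epsilon, sig = system$lj_sigma,
       mass = system$masses,
       restrained = as.integer(system$restrained),
       refpos = system$ref_positions, k_restraint = system$restraint_k,
       bonds = if (nrow(system$bonds)) system$bonds else
         matrix(integer(0), 0, 2),
       bond_k = system$bond_k, bond_r0 = system$bond_r0,
       cutoff = .default_cutoff, switch_on = .default_switch,
       use_cutoff = isTRUE(cutoff), all_pairs = isTRUE(all_pairs))
}

#' Create a simulation state
#'
#' @param system a `particle_system`.
#' @param velocities N x 3 velocities in A/ps; default zero.
#' @param time,step elapsed time (ps) and step count.
#' @param rng_label opaque label of the random stream last used to propagate
#'   this state (an integer seed); `NA` for a fresh state.
#' @return object of class `sim_state`.
#' @export
sim_state <- function(system, velocities = NULL, time = 0, step = 0L,
                      rng_label = NA_integer_) {
  n <- system$n
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  stopifnot(identical(dim(velocities), c(n, 3L)) ||
              identical(dim(velocities), as.integer(c(n, 3))))
  out <- list(positions = system$positions, velocities = velocities,
              time = time, step = as.integer(step), rng_label = rng_label)
  class(out) <- "sim_state"
  out
}

#' Maxwell-Boltzmann velocities
#'
#' Draws per-particle velocities from the Maxwell-Boltzmann distribution at
#' `temperature`, used to initialise or decorrelate dynamics.
#'
#' @param system a `particle_system`.
#' @param temperature K.
#' @param seed integer seed.
#' @return N x 3 velocity matrix, A/ps.
#' @export
maxwell_velocities <- function(system, temperature, seed) {
  set.seed(seed)
  sd_v <- sqrt(.KB * temperature * .KCAL_TO_AKMA / system$masses)
  matrix(rnorm(3 * system$n), system$n, 3) * sd_v
}

#' Forces and energy decomposition
#'
#' Evaluates per-particle forces (exact negative gradients of the reported
#' energy) and the energy components for a configuration.
#'
#' @param system a `particle_system`.
#' @param state a `sim_state`, or an N x 3 position matrix; default the
#'   system's build positions.
#' @param all_pairs include scaffold-scaffold nonbonded pairs.
#' @param cutoff logical; apply the 10-12 A switching cutoff (default) or
#'   evaluate all pairs exactly.
#' @return list with `forces` (N x 3, kcal/mol/A) and `energy`, an
#'   `energy_terms` list (`e_bond`, `e_lj`, `e_coulomb`, `e_restraint`,
#'   `e_total`; kcal/mol, `e_total` the exact sum of the components).
#' @export
compute_forces <- function(system, state = NULL, all_pairs = FALSE,
                           cutoff = TRUE) {
  pos <- if (is.null(state)) system$positions
         else if (inherits(state, "sim_state")) state$positions
         else as.matrix(state)
  a <- .ff_args(system, all_pairs, cutoff)
  r <- ff_eval_cpp(pos, a$q, a$eps, a$sig, a$mass, a$restrained, a$refpos,
                   a$k_restraint, a$bonds, a$bond_k, a$bond_r0, a$cutoff,
                   a$switch_on, a$use_cutoff, a$all_pairs)
  energy <- list(e_bond = r$e_bond, e_lj = r$e_lj, e_coulomb = r$e_coulomb,
                 e_restraint = r$e_restraint)
  energy$e_total <- energy$e_bond + energy$e_lj + energy$e_coulomb +
    energy$e_restraint
  class(energy) <- "energy_terms"
  list(forces = r$forces, energy = energy)
}

# shared driver around the C++ propagator; returns the raw result list
.propagate <- function(system, state, n_steps, dt, temperature, friction,
                       seed, record_every = 0L, traj_every = 0L,
                       pull = NULL, monitor = NULL, all_pairs = FALSE) {
  stopifnot(inherits(state, "sim_state"), dt > 0, friction >= 0)
  if (is.null(seed)) {
    if (temperature > 0 && friction > 0)
      stop("a seed is required for stochastic dynamics")
    seed <- 0L
  }
  a <- .ff_args(system, all_pairs = all_pairs)
  p <- pull %||% list(idx = integer(0), k = 0, anchor0 = c(0, 0, 0),
                      dir = c(0, 0, 1), v = 0)
  m <- monitor %||% list(site = c(0, 0, 0), lig = integer(0),
                         radius = 0, every = 0L, stop = FALSE)
  r <- langevin_cpp(state$positions, state$velocities, a$q, a$eps, a$sig,
                    a$mass, a$restrained, a$refpos, a$k_restraint, a$bonds,
                    a$bond_k, a$bond_r0, a$cutoff, a$switch_on, a$use_cutoff,
                    a$all_pairs, as.integer(n_steps), dt, temperature,
                    friction, as.numeric(seed), as.integer(record_every),
                    as.integer(traj_every), !is.null(pull),
                    as.integer(p$idx), p$k, p$anchor0, p$dir, p$v,
                    !is.null(monitor), m$site, as.integer(m$lig), m$radius,
                    as.integer(m$every), isTRUE(m$stop), 1e8)
  if (r$blowup)
    stop("dynamics blew up (non-finite or huge energy); try a smaller dt")
  r$seed <- seed
  r
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Propagate Langevin dynamics
#'
#' Advances the state by `n_steps` BAOAB Langevin steps.  Restrained scaffold
#' particles are harmonically tethered to their reference positions (they are
#' mobile, not frozen).  Deterministic for a fixed `seed`; with
#' `temperature = 0` and `friction = 0` the integrator is velocity Verlet and
#' no random numbers are consumed.
#'
#' @param system a `particle_system`.
#' @param state a `sim_state`.
#' @param n_steps number of steps.
#' @param dt timestep, ps (default 0.01).
#' @param temperature K.
#' @param friction Langevin collision frequency, 1/ps.
#' @param seed integer seed for the thermostat noise stream (required when
#'   `temperature > 0` and `friction > 0`).
#' @param traj_every if > 0, keep a trajectory frame every so many steps.
#' @return a `sim_state`; when `traj_every > 0` it carries a `trajectory`
#'   attribute (class `cg_trajectory`: list of `times` and a
#'   frames x N x 3 coordinate array).
#' @export
step_langevin <- function(system, state, n_steps, dt = 0.01,
                          temperature = 300, friction = 5, seed = NULL,
                          traj_every = 0L) {
  r <- .propagate(system, state, n_steps, dt, temperature, friction, seed,
                  traj_every = traj_every)
  out <- state
  out$positions <- r$positions
  out$velocities <- r$velocities
  out$step <- state$step + r$steps_done
  out$time <- state$time + r$steps_done * dt
  out$rng_label <- r$seed
  if (traj_every > 0) {
    attr(out, "trajectory") <- .traj_from_raw(r, system$n, dt, state$time,
                                              as.integer(traj_every))
  }
  out
}

.traj_from_raw <- function(r, n, dt, t0, traj_every) {
  nf <- r$n_frames
  coords <- array(t(r$trajectory[seq_len(nf), , drop = FALSE]),
                  dim = c(n, 3, nf))
  coords <- aperm(coords, c(3, 1, 2))
  out <- list(times = t0 + (seq_len(nf) - 1) * traj_every * dt,
              coords = coords)
  class(out) <- "cg_trajectory"
  out
}

#' Checkpoints
#'
#' A checkpoint is a bit-exact snapshot of a `sim_state` plus a monotonically
#' increasing index.  Restoring and re-propagating with the same seed
#' reproduces the original continuation exactly; a different seed diverges.
#' On disk the checkpoint is a tagged, versioned RDS file; loading a file
#' without the tag fails explicitly.
#'
#' @param state a `sim_state`.
#' @param index checkpoint index.
#' @return `save_checkpoint`: an object of class `checkpoint`;
#'   `restore_checkpoint`: the stored `sim_state`.
#' @export
save_checkpoint <- function(state, index = 1L) {
  stopifnot(inherits(state, "sim_state"))
  out <- list(format = "egressr-checkpoint-v1", index = as.integer(index),
              state = state)
  class(out) <- "checkpoint"
  out
}

#' @rdname save_checkpoint
#' @param checkpoint a `checkpoint` object.
#' @export
restore_checkpoint <- function(checkpoint) {
  if (!inherits(checkpoint, "checkpoint") ||
      !identical(checkpoint$format, "egressr-checkpoint-v1"))
    stop("not a valid egressr checkpoint")
  checkpoint$state
}

#' @rdname save_checkpoint
#' @param path file path.
#' @export
write_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
read_checkpoint <- function(path) {
  cp <- tryCatch(readRDS(path), error = function(e)
    stop("corrupted or unreadable checkpoint file: ", path, call. = FALSE))
  if (!is.list(cp) || !identical(cp$format, "egressr-checkpoint-v1"))
    stop("file is not an egressr checkpoint (missing format tag): ", path)
  class(cp) <- "checkpoint"
  cp
}
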