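# Constant-velocity steered pulling: a virtual harmonic spring whose anchor
# moves at constant speed along a chosen exit direction, attached to the
# centre of mass of the ligand beads selected for that direction.

#' Pulling direction
#'
#' @param label direction label (e.g. `"TM1-TM7"`, `"UP"`, or custom).
#' @param unit_vector 3-vector; normalised internally (must be non-zero).
#' @return object of class `direction_spec`.
#' @export
direction_spec <- function(label, unit_vector) {
  u <- as.numeric(unit_vector)
  nrm <- sqrt(sum(u^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("direction vector must be non-zero")
  out <- list(label = as.character(label), unit_vector = u / nrm)
  class(out) <- "direction_spec"
  out
}

#' Pulling schedule
#'
#' The virtual-spring protocol: spring constant `k` in pN/A and pulling speed
#' `v` stated in m/s (converted internally via 1 m/s = 0.01 A/ps, exactly).
#' The defaults keep the experimental spring stiffness (70 pN/A) and scale
#' the protocol to the toy receptor: 3 m/s for 750 ps moves the anchor
#' 22.5 A, enough to carry the ligand from the pocket centre through a gate
#' and clear of the ring.  Slower, longer protocols (e.g. `v_ms = 0.3`,
#' `duration_ps = 15000`) are available through the same arguments.
#'
#' @param k_pN spring constant, pN/A.
#' @param v_ms pulling speed, m/s.
#' @param duration_ps pull duration, ps.
#' @param record_every record the force every so many steps.
#' @return object of class `pull_schedule` (with the speed also stored in
#'   A/ps as `v_angps`).
#' @export
pull_schedule <- function(k_pN = 70, v_ms = 3, duration_ps = 750,
                          record_every = 20L) {
  stopifnot(k_pN > 0, v_ms > 0, duration_ps > 0, record_every >= 1)
  out <- list(k_pN = k_pN, v_ms = v_ms, v_angps = mps_to_angps(v_ms),
              duration_ps = duration_ps, record_every = as.integer(record_every))
  class(out) <- "pull_schedule"
  out
}

#' Select the ligand beads to pull for a direction
#'
#' Returns the `n_atoms` ligand beads with the largest projection onto the
#' pulling direction, measured from the ligand centre of mass (ties broken by
#' ascending bead index).  Pulling the beads that lead in the exit direction
#' avoids rotating the ligand or wedging it in the pocket.
#'
#' @param system a `particle_system`.
#' @param direction a [direction_spec()].
#' @param n_atoms how many beads to pull (default 1).
#' @return integer vector of particle indices (into the system).
#' @export
select_pull_atoms <- function(system, direction, n_atoms = 1L) {
  lig <- group_indices(system, "ligand")
  if (!length(lig)) stop("system has no ligand beads")
  if (length(lig) < n_atoms)
    stop("ligand has fewer beads than n_atoms")
  com <- center_of_mass(system$positions, system$masses, lig)
  rel <- sweep(system$positions[lig, , drop = FALSE], 2, com)
  proj <- as.numeric(rel %*% direction$unit_vector)
  lig[order(-proj, seq_along(lig))][seq_len(n_atoms)]
}

#' Run one constant-velocity steered pull
#'
#' The spring anchor starts at the pulled-group COM and advances at exactly
#' `v` along the direction; at every recorded step the spring force equals
#' `k * (anchor - pulled_COM)` as a full 3-vector.  If the ligand leaves the
#' simulation bounds the record is truncated and flagged.
#'
#' @param system a `particle_system` with the ligand at the bound site.
#' @param state a `sim_state` (default: fresh zero-velocity state).
#' @param direction a [direction_spec()].
#' @param schedule a [pull_schedule()].
#' @param seed integer seed for the thermostat.
#' @param n_pull_atoms beads to pull (see [select_pull_atoms()]).
#' @param dt,temperature,friction dynamics parameters.
#' @param traj_every keep trajectory frames every so many steps (default: the
#'   schedule's `record_every`).
#' @return list of class `smd_run` with `record` (a `force_record`
#'   data.frame: `t_ps`, anchor `ax..az`, pulled-COM `cx..cz`, spring force
#'   `fx_pN..fz_pN`), `trajectory`, `state` (final), `direction`,
#'   `pull_atoms` and a `truncated` flag.
#' @export
run_smd <- function(system, state = NULL, direction, schedule = pull_schedule(),
                    seed = 1L, n_pull_atoms = 1L, dt = 0.01,
                    temperature = 300, friction = 5, traj_every = NULL) {
  stopifnot(inherits(direction, "direction_spec"),
            inherits(schedule, "pull_schedule"))
  if (is.null(state)) state <- sim_state(system)
  pull_atoms <- select_pull_atoms(system, direction, n_pull_atoms)
  w <- system$masses[pull_atoms]
  anchor0 <- as.numeric(w %*% state$positions[pull_atoms, , drop = FALSE] / sum(w))
  n_steps <- round(schedule$duration_ps / dt)
  traj_every <- as.integer(traj_every %||% schedule$record_every)

  # truncation bound: well beyond any exit
  layout <- system$layout
  r_max <- layout$helix_radius + 25

  r <- .propagate(system, state, n_steps, dt, temperature, friction, seed,
                  record_every = schedule$record_every,
                  traj_every = traj_every,
                  pull = list(idx = pull_atoms,
                              k = pn_to_kcal(schedule$k_pN),
                              anchor0 = anchor0,
                              dir = direction$unit_vector,
                              v = schedule$v_angps),
                  monitor = list(site = layout$pocket_center,
                                 lig = group_indices(system, "ligand"),
                                 radius = 0, every = 0L, stop = FALSE))
  rec <- r$record[seq_len(r$n_record), , drop = FALSE]
  colnames(rec) <- c("t_ps", "ax", "ay", "az", "cx", "cy", "cz",
                     "fx_pN", "fy_pN", "fz_pN")
  rec <- as.data.frame(rec)
  rec[, 8:10] <- kcal_to_pn(rec[, 8:10])

  # truncate after escape beyond the bounds, if any
  truncated <- FALSE
  d_com <- sqrt((rec$cx - layout$pocket_center[1])^2 +
                (rec$cy - layout$pocket_center[2])^2 +
                (rec$cz - layout$pocket_center[3])^2)
  esc <- which(d_com > r_max)
  if (length(esc)) {
    rec <- rec[seq_len(esc[1]), , drop = FALSE]
    truncated <- TRUE
    warning("ligand left the simulation bounds; force record truncated")
  }
  class(rec) <- c("force_record", "data.frame")
  attr(rec, "direction") <- direction$label
  attr(rec, "schedule") <- schedule
  attr(rec, "truncated") <- truncated

  final <- state
  final$positions <- r$positions; final$velocities <- r$velocities
  final$step <- state$step + r$steps_done
  final$time <- state$time + r$steps_done * dt
  final$rng_label <- r$seed
  out <- list(record = rec,
              trajectory = .traj_from_raw(r, system$n, dt, state$time,
                                          traj_every),
              state = final, direction = direction, pull_atoms = pull_atoms,
              truncated = truncated, seed = seed)
  class(out) <- "smd_run"
  out
}

#' Build a force record from raw series
#'
#' Assembles (and validates) a `force_record` from time, anchor, pulled-COM
#' and spring-force series; mainly used for analysing externally produced
#' pulling logs and in tests.
#'
#' @param t_ps time, ps (strictly increasing).
#' @param anchor,com n x 3 matrices, A.
#' @param force_pN n x 3 matrix, pN.
#' @param direction optional direction label.
#' @return a `force_record` data.frame.
#' @export
force_record <- function(t_ps, anchor, com, force_pN, direction = NA_character_) {
  anchor <- as.matrix(anchor); com <- as.matrix(com)
  force_pN <- as.matrix(force_pN)
  n <- length(t_ps)
  stopifnot(nrow(anchor) == n, nrow(com) == n, nrow(force_pN) == n)
  if (n >= 2 && any(diff(t_ps) <= 0)) stop("times must be strictly increasing")
  rec <- data.frame(t_ps = t_ps, ax = anchor[, 1], ay = anchor[, 2],
                    az = anchor[, 3], cx = com[, 1], cy = com[, 2],
                    cz = com[, 3], fx_pN = force_pN[, 1],
                    fy_pN = force_pN[, 2], fz_pN = force_pN[, 3])
  class(rec) <- c("force_record", "data.frame")
  attr(rec, "direction") <- direction
  rec
}
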