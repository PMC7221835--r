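# Supervised molecular dynamics: unbiased dynamics run in short slices
# under a tabu-like distance-supervision rule.  Each slice starts from a
# checkpoint; a slice is accepted iff the ligand-site distance at its end
# improves (d_end < d_start - eps, or beats the best distance seen so far),
# otherwise the checkpoint is restored, velocities are resampled with the
# next seed (never reusing a seed at the same checkpoint), and the slice is
# retried.  No biasing force is ever applied, so every accepted slice is an
# ordinary unbiased trajectory segment.

#' Supervision configuration
#'
#' @param site_center binding-site centre, 3-vector A.
#' @param slice_length steps per supervision slice.
#' @param arrival_radius ligand-site COM distance below which the ligand has
#'   arrived, A.
#' @param epsilon minimum required approach per accepted slice, A.
#' @param max_consecutive_rejects reject cap at one checkpoint before giving
#'   up.
#' @param max_total_steps budget of accepted steps.
#' @param seed_base,seed_increment attempt `k` (over the whole run) uses seed
#'   `seed_base + k * seed_increment`, so every attempt has a distinct seed.
#' @param dt,temperature,friction dynamics parameters.
#' @param record_every record a trajectory frame and distance sample every so
#'   many steps (must divide `slice_length`).
#' @return object of class `sumd_config`.
#' @export
sumd_config <- function(site_center = c(0, 0, 0), slice_length = 500L,
                        arrival_radius = 4, epsilon = 0.1,
                        max_consecutive_rejects = 30L,
                        max_total_steps = 200000L, seed_base = 1L,
                        seed_increment = 1L, dt = 0.01, temperature = 300,
                        friction = 5, record_every = 100L) {
  stopifnot(slice_length >= 1, arrival_radius > 0, epsilon >= 0,
            record_every >= 1, slice_length %% record_every == 0)
  out <- list(site_center = as.numeric(site_center),
              slice_length = as.integer(slice_length),
              arrival_radius = arrival_radius, epsilon = epsilon,
              max_consecutive_rejects = as.integer(max_consecutive_rejects),
              max_total_steps = as.integer(max_total_steps),
              seed_base = as.integer(seed_base),
              seed_increment = as.integer(seed_increment), dt = dt,
              temperature = temperature, friction = friction,
              record_every = as.integer(record_every))
  class(out) <- "sumd_config"
  out
}

.lig_site_distance <- function(system, positions, site) {
  lig <- group_indices(system, "ligand")
  com <- center_of_mass(positions, system$masses, lig)
  sqrt(sum((com - site)^2))
}

#' Run distance-supervised dynamics
#'
#' Drives the ligand towards the binding site by supervision alone (see the
#' module comment above); terminates when the ligand arrives, the reject cap
#' is hit, or the step budget is exhausted.  Deterministic given the seed
#' policy in `config`.
#'
#' @param system a `particle_system` with the ligand outside the arrival
#'   radius (e.g. placed with `site = "outside_gate"`).
#' @param state optional starting `sim_state`; default fresh Maxwell
#'   velocities drawn with `seed_base`.
#' @param config a [sumd_config()].
#' @param supervised set `FALSE` to accept every slice (plain MD in the same
#'   slice harness, used for paired comparisons).
#' @param store_checkpoints keep, for every accepted slice, the exact state
#'   it was propagated from and its seed (enables bias-free replay checks).
#' @return object of class `sumd_result`: `trajectory` (accepted frames),
#'   `distances` (data.frame `t_ps`, `d_A` on accepted frames), `attempts`
#'   (data.frame `slice`, `attempt`, `seed`, `accepted`, `d_start`, `d_end`),
#'   `termination` (`"arrived"`, `"reject_cap"` or `"step_budget"`),
#'   `restarts`, `accepted_steps`, `final_state`, `config`, and (optionally)
#'   `slice_inputs`.
#' @export
supervise <- function(system, state = NULL, config, supervised = TRUE,
                      store_checkpoints = FALSE) {
  stopifnot(inherits(config, "sumd_config"))
  if (is.null(state)) {
    state <- sim_state(system,
                       maxwell_velocities(system, config$temperature,
                                          config$seed_base))
  }
  d0 <- .lig_site_distance(system, state$positions, config$site_center)
  if (d0 <= config$arrival_radius)
    stop("ligand already within the arrival radius at start")

  best <- d0
  attempts <- list(); slice_inputs <- list()
  frames <- list(); frame_times <- numeric(0); dists <- numeric(0)
  attempt_counter <- 0L; consec <- 0L; slice <- 0L
  accepted_steps <- 0L; restarts <- 0L
  termination <- NULL
  lig <- group_indices(system, "ligand")

  repeat {
    slice <- slice + 1L
    cp <- save_checkpoint(state, slice)
    d_start <- .lig_site_distance(system, state$positions, config$site_center)
    accepted <- FALSE
    while (!accepted) {
      attempt_counter <- attempt_counter + 1L
      seed <- config$seed_base + attempt_counter * config$seed_increment
      st <- restore_checkpoint(cp)
      if (consec > 0L) {
        # rejected before: decorrelate by resampling velocities
        st$velocities <- maxwell_velocities(system, config$temperature, seed)
      }
      new <- step_langevin(system, st, config$slice_length, dt = config$dt,
                           temperature = config$temperature,
                           friction = config$friction, seed = seed,
                           traj_every = config$record_every)
      d_end <- .lig_site_distance(system, new$positions, config$site_center)
      accepted <- !supervised || d_end < d_start - config$epsilon || d_end < best
      attempts[[attempt_counter]] <- data.frame(
        slice = slice, attempt = attempt_counter, seed = seed,
        accepted = accepted, d_start = d_start, d_end = d_end)
      if (accepted) {
        tr <- attr(new, "trajectory")
        keep <- -1L  # drop the duplicated slice-start frame
        frames[[slice]] <- tr$coords[keep, , , drop = FALSE]
        frame_times <- c(frame_times, tr$times[keep])
        dists <- c(dists, apply(tr$coords[keep, , , drop = FALSE], 1, function(p)
          .lig_site_distance(system, p, config$site_center)))
        if (store_checkpoints)
          slice_inputs[[slice]] <- list(state = st, seed = seed)
        attr(new, "trajectory") <- NULL
        state <- new
        best <- min(best, d_end)
        accepted_steps <- accepted_steps + config$slice_length
        consec <- 0L
      } else {
        restarts <- restarts + 1L
        consec <- consec + 1L
        if (consec >= config$max_consecutive_rejects) {
          termination <- "reject_cap"
          break
        }
      }
    }
    if (!is.null(termination)) break
    if (d_end <= config$arrival_radius) { termination <- "arrived"; break }
    if (accepted_steps >= config$max_total_steps) {
      termination <- "step_budget"; break
    }
  }

  n_lig <- system$n
  coords <- if (length(frames)) {
    arr <- array(0, dim = c(length(frame_times), n_lig, 3))
    at <- 0L
    for (f in frames) {
      nf <- dim(f)[1]
      if (nf) arr[at + seq_len(nf), , ] <- f
      at <- at + nf
    }
    arr
  } else array(0, dim = c(0, n_lig, 3))
  trajectory <- list(times = frame_times, coords = coords)
  class(trajectory) <- "cg_trajectory"

  out <- list(trajectory = trajectory,
              distances = data.frame(t_ps = frame_times, d_A = dists),
              attempts = do.call(rbind, attempts),
              termination = termination, restarts = restarts,
              accepted_steps = accepted_steps, final_state = state,
              config = config, supervised = supervised,
              start_distance = d0)
  if (store_checkpoints) out$slice_inputs <- slice_inputs
  class(out) <- "sumd_result"
  out
}

#' @export
print.sumd_result <- function(x, ...) {
  cat(sprintf(paste0("sumd_result: %s after %d accepted steps ",
                     "(%d restarts); d: %.2f -> %.2f A\n"),
              x$termination, x$accepted_steps, x$restarts, x$start_distance,
              tail(x$distances$d_A, 1)))
  invisible(x)
}

#' Ligand-site distance series of a supervised run
#'
#' @param result a `sumd_result`.
#' @return data.frame (`t_ps`, `d_A`) over accepted frames; time monotone,
#'   distances non-negative.
#' @export
distance_series <- function(result) {
  stopifnot(inherits(result, "sumd_result"))
  if (!nrow(result$distances)) stop("result has no accepted frames")
  result$distances
}

#' Continue a supervised run with plain (unsupervised) dynamics
#'
#' Propagates the final accepted state with ordinary Langevin dynamics (no
#' supervision, no restarts), extending the trajectory and distance series.
#'
#' @param result a `sumd_result`.
#' @param system the owning `particle_system`.
#' @param extra_steps steps of plain MD to append (0 returns the result
#'   unchanged).
#' @param seed integer seed for the continuation.
#' @return the extended `sumd_result` (termination tag preserved; a
#'   `plain_md_steps` field records the continuation length).
#' @export
switch_to_plain_md <- function(result, system, extra_steps, seed = 1L) {
  stopifnot(inherits(result, "sumd_result"))
  extra_steps <- as.integer(extra_steps)
  if (extra_steps == 0L) {
    result$plain_md_steps <- 0L
    return(result)
  }
  cfg <- result$config
  new <- step_langevin(system, result$final_state, extra_steps, dt = cfg$dt,
                       temperature = cfg$temperature, friction = cfg$friction,
                       seed = seed, traj_every = cfg$record_every)
  tr <- attr(new, "trajectory")
  keep <- -1L
  add_coords <- tr$coords[keep, , , drop = FALSE]
  add_times <- tr$times[keep]
  add_d <- apply(add_coords, 1, function(p)
    .lig_site_distance(system, p, cfg$site_center))
  result$trajectory$coords <- .abind_frames(result$trajectory$coords, add_coords)
  result$trajectory$times <- c(result$trajectory$times, add_times)
  result$distances <- rbind(result$distances,
                            data.frame(t_ps = add_times, d_A = add_d))
  attr(new, "trajectory") <- NULL
  result$final_state <- new
  result$plain_md_steps <- extra_steps
  result
}

.abind_frames <- function(a, b) {
  out <- array(0, dim = c(dim(a)[1] + dim(b)[1], dim(a)[2], 3))
  if (dim(a)[1]) out[seq_len(dim(a)[1]), , ] <- a
  if (dim(b)[1]) out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

#' First-passage steps to the binding site
#'
#' Convenience wrapper for paired supervised vs plain comparisons: runs
#' [supervise()] (or its accept-everything plain-MD counterpart) and returns
#' the number of accepted steps at arrival, or the step budget when the run
#' did not arrive.
#'
#' @param system,state,config as in [supervise()].
#' @param supervised logical.
#' @return list with `steps`, `arrived`, `termination`.
#' @export
first_passage_steps <- function(system, state = NULL, config,
                                supervised = TRUE) {
  res <- supervise(system, state, config, supervised = supervised)
  arrived <- identical(res$termination, "arrived")
  list(steps = if (arrived) res$accepted_steps else config$max_total_steps,
       arrived = arrived, termination = res$termination)
}
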