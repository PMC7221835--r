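# Pipeline orchestration: a config-first surface tying the stages into the
# two experiments — the multi-direction SMD comparison and the supervised
# entrance run — with explicit seeds and a JSON manifest of every output.

#' Assemble a run configuration
#'
#' All seeds are explicit (no wall-clock seeding); every artifact of a run
#' is derived from this object.  `smd$repeats` defaults to 3: replicate
#' pulls are the unit of evidence for pathway ranking, a single pull is not
#' trusted.
#'
#' @param layout a [receptor_layout()]; the default widens gate `"TM1-TM7"`
#'   by 1.5x, making it the engineered lowest-barrier exit.
#' @param ligand a [ligand_spec()].
#' @param dynamics list: `dt` (ps), `temperature` (K), `friction` (1/ps).
#' @param smd list: `schedule` ([pull_schedule()]), `directions` (labels;
#'   default the five canonical ones), `repeats`, `n_pull_atoms`.
#' @param sumd list of [sumd_config()] arguments (site centre defaults to
#'   the pocket centre); plus `gate`, `orientation` for the starting
#'   placement.
#' @param seed base integer seed.
#' @param outdir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(layout = NULL, ligand = ligand_spec(),
                       dynamics = list(), smd = list(), sumd = list(),
                       seed = 1L, outdir = tempfile("egressr-run-")) {
  if (is.null(layout)) layout <- widen_gate(receptor_layout(), "TM1-TM7", 1.5)
  dynamics <- modifyList(list(dt = 0.01, temperature = 300, friction = 5),
                         dynamics)
  smd <- modifyList(list(schedule = pull_schedule(),
                         directions = c("TM1-TM7", "TM1-TM2", "UP",
                                        "TM4-TM5", "TM5-TM6"),
                         repeats = 3L, n_pull_atoms = 1L), smd)
  if (smd$repeats < 1) stop("smd$repeats must be >= 1")
  sumd <- modifyList(list(gate = NULL, orientation = "tail_first",
                          site_center = layout$pocket_center,
                          slice_length = 500L, arrival_radius = 4,
                          epsilon = 0.1, max_consecutive_rejects = 30L,
                          max_total_steps = 200000L, record_every = 100L),
                     sumd)
  out <- list(layout = layout, ligand = ligand, dynamics = dynamics,
              smd = smd, sumd = sumd, seed = as.integer(seed),
              outdir = outdir)
  class(out) <- "run_config"
  out
}

#' Read a run configuration from YAML or JSON
#'
#' Recognised top-level keys: `layout` ([receptor_layout()] arguments plus
#' optional `widen: {gate, factor}`), `ligand` ([ligand_spec()] arguments),
#' `dynamics`, `smd` (with `schedule` holding [pull_schedule()] arguments),
#' `sumd`, `seed`, `outdir`.  Malformed files fail with the parser's
#' line/field diagnostics.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(cfg)) stop("config must be a mapping: ", path)
  unknown <- setdiff(names(cfg), c("layout", "ligand", "dynamics", "smd",
                                   "sumd", "seed", "outdir"))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  layout <- NULL
  if (!is.null(cfg$layout)) {
    widen <- cfg$layout$widen
    cfg$layout$widen <- NULL
    layout <- do.call(receptor_layout, cfg$layout)
    if (!is.null(widen))
      layout <- do.call(widen_gate, c(list(layout), widen))
  }
  ligand <- if (is.null(cfg$ligand)) ligand_spec()
            else do.call(ligand_spec, cfg$ligand)
  smd <- cfg$smd %||% list()
  if (!is.null(smd$schedule)) smd$schedule <- do.call(pull_schedule, smd$schedule)
  run_config(layout = layout, ligand = ligand,
             dynamics = cfg$dynamics %||% list(), smd = smd,
             sumd = cfg$sumd %||% list(), seed = cfg$seed %||% 1L,
             outdir = cfg$outdir %||% tempfile("egressr-run-"))
}

.write_manifest <- function(config, extra, path) {
  manifest <- c(list(package = "egressr",
                     version = as.character(utils::packageVersion("egressr")),
                     seed = config$seed,
                     dynamics = config$dynamics), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Build and write the system
#'
#' Builds the configured receptor-membrane-ligand system and writes
#' `system.xyz`, `system.json` and `manifest.json` to the output directory.
#' Byte-identical outputs for a fixed seed.
#'
#' @param config a [run_config()].
#' @return the `particle_system`, invisibly; files under `config$outdir`.
#' @export
cmd_build <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  sys <- build_system(config$layout, config$ligand, seed = config$seed)
  write_system(sys, file.path(config$outdir, "system"))
  .write_manifest(config, list(command = "build", n_particles = sys$n),
                  file.path(config$outdir, "manifest.json"))
  invisible(sys)
}

#' Multi-direction SMD comparison
#'
#' Runs `repeats` seeded pulls along each configured direction from the
#' bound pose, writes every force record
#' (`smd_<direction>_rep<k>.csv`), the aggregated comparison table
#' (`comparison.csv`), and the ranked verdict into `manifest.json`.  A
#' replicate that fails is recorded and excluded with a warning; the command
#' fails only if a direction loses all of its replicates.
#'
#' @param config a [run_config()].
#' @return a [rank_pathways()] result with the comparison table attached.
#' @export
cmd_smd_compare <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  sys <- build_system(config$layout, config$ligand, seed = config$seed)
  dirs <- gate_directions(config$layout, config$smd$directions)
  dyn <- config$dynamics
  profiles <- list(); failures <- list()
  for (d in dirs) {
    ok <- 0
    for (rep in seq_len(config$smd$repeats)) {
      seed <- config$seed + 1000L * match(d$label, names(dirs)) + rep
      run <- tryCatch(
        run_smd(sys, direction = d, schedule = config$smd$schedule,
                seed = seed, n_pull_atoms = config$smd$n_pull_atoms,
                dt = dyn$dt, temperature = dyn$temperature,
                friction = dyn$friction),
        error = function(e) e)
      if (inherits(run, "error")) {
        warning(sprintf("replicate %d of %s failed and was excluded: %s",
                        rep, d$label, conditionMessage(run)))
        failures[[length(failures) + 1]] <-
          list(direction = d$label, rep = rep, error = conditionMessage(run))
        next
      }
      ok <- ok + 1
      fname <- file.path(config$outdir,
                         sprintf("smd_%s_rep%d.csv",
                                 gsub("[^A-Za-z0-9]", "_", d$label), rep))
      write_force_record(run$record, fname)
      profiles[[length(profiles) + 1]] <- work_profile(run$record, d$label)
    }
    if (ok == 0)
      stop("direction ", d$label, " lost all replicates")
  }
  comparison <- direction_comparison(profiles)
  ranking <- rank_pathways(comparison)
  write.csv(ranking$table, file.path(config$outdir, "comparison.csv"),
            row.names = FALSE)
  .write_manifest(config,
                  list(command = "smd_compare",
                       directions = names(dirs),
                       repeats = config$smd$repeats,
                       schedule = unclass(config$smd$schedule),
                       winner = ranking$winner,
                       runner_up_equivalent = ranking$runner_up_equivalent,
                       order = ranking$order,
                       failures = failures),
                  file.path(config$outdir, "manifest.json"))
  ranking
}

#' Supervised entrance run
#'
#' Places the ligand outside the configured gate, runs [supervise()], and
#' writes the attempt log (`sumd_attempts.csv`), the accepted trajectory
#' (`sumd_trajectory.xyz`), the distance series (`sumd_distances.csv`), the
#' ligand-receptor energy profile (`sumd_energy.csv`) and the manifest.
#' When `reference_poses` is supplied (list of coordinate matrices in the
#' system frame), COM pose distances of the final ligand pose are written to
#' `pose_distances.csv`.
#'
#' @param config a [run_config()].
#' @param reference_poses optional named list of reference pose coordinate
#'   matrices.
#' @return the `sumd_result`, invisibly.
#' @export
cmd_sumd <- function(config, reference_poses = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  sys <- build_system(config$layout, config$ligand, seed = config$seed)
  sys <- place_ligand(sys, site = "outside_gate",
                      orientation = config$sumd$orientation,
                      gate = config$sumd$gate, seed = config$seed)
  dyn <- config$dynamics
  scfg <- sumd_config(site_center = config$sumd$site_center,
                      slice_length = config$sumd$slice_length,
                      arrival_radius = config$sumd$arrival_radius,
                      epsilon = config$sumd$epsilon,
                      max_consecutive_rejects = config$sumd$max_consecutive_rejects,
                      max_total_steps = config$sumd$max_total_steps,
                      seed_base = config$seed, dt = dyn$dt,
                      temperature = dyn$temperature, friction = dyn$friction,
                      record_every = config$sumd$record_every)
  res <- supervise(sys, config = scfg)
  write.csv(res$attempts, file.path(config$outdir, "sumd_attempts.csv"),
            row.names = FALSE)
  write.csv(res$distances, file.path(config$outdir, "sumd_distances.csv"),
            row.names = FALSE)
  if (nrow(res$distances))
    write_trajectory_xyz(res$trajectory, sys$groups,
                         file.path(config$outdir, "sumd_trajectory.xyz"))
  if (dim(res$trajectory$coords)[1] >= 1) {
    prof <- energy_profile(sys, res$trajectory)
    write_energy_profile(prof, file.path(config$outdir, "sumd_energy.csv"))
  }
  extra <- list(command = "sumd", termination = res$termination,
                restarts = res$restarts,
                accepted_steps = res$accepted_steps,
                sumd = unclass(scfg))
  if (!is.null(reference_poses)) {
    lig <- group_indices(sys, "ligand")
    final_pose <- res$final_state$positions[lig, , drop = FALSE]
    pd <- data.frame(
      ligand = "ligand", reference = names(reference_poses),
      pdb_id = "synthetic",
      distance_A = vapply(reference_poses, function(p)
        pose_distance(final_pose, p, sys$masses[lig]), numeric(1)))
    write.csv(pd, file.path(config$outdir, "pose_distances.csv"),
              row.names = FALSE)
    extra$mean_pose_distance_A <- mean(pd$distance_A)
  }
  .write_manifest(config, extra, file.path(config$outdir, "manifest.json"))
  invisible(res)
}
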