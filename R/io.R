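# File formats: XYZ coordinates/trajectories with group tags, a JSON
# topology sidecar (charges/LJ/bonds/restraints), force-record CSV, a
# NAMD-style SMD log dialect, and YAML/JSON run configuration.

#' Write/read XYZ coordinates
#'
#' Standard XYZ: atom count line, comment line, then `<tag> x y z` rows.
#' Group labels serve as element-like tags.  `write_xyz` can append frames
#' to build a trajectory file; `read_xyz` returns all frames.
#'
#' @param positions N x 3 matrix, A.
#' @param labels per-particle tags.
#' @param path file path.
#' @param comment comment-line text.
#' @param append append as an extra frame.
#' @return `write_xyz`: the path, invisibly.  `read_xyz`: list with `labels`
#'   and `frames` (list of N x 3 matrices).
#' @export
write_xyz <- function(positions, labels, path, comment = "", append = FALSE) {
  positions <- as.matrix(positions)
  lines <- c(nrow(positions), comment,
             sprintf("%s %.10g %.10g %.10g", labels, positions[, 1],
                     positions[, 2], positions[, 3]))
  if (append) cat(lines, file = path, sep = "\n", append = TRUE)
  else writeLines(lines, path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list(); labels <- NULL; i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(parts) < 4)
    if (length(bad))
      stop("malformed XYZ row at line ", i + 1 + bad[1])
    labels <- vapply(parts, `[[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + n
  }
  list(labels = labels, frames = frames)
}

#' Write/read a full particle system (XYZ + JSON topology sidecar)
#'
#' Coordinates and group tags go to `<stem>.xyz`; charges, LJ parameters,
#' masses, bonds, restraint flags and the layout/ligand descriptions go to
#' `<stem>.json`.
#'
#' @param system a `particle_system`.
#' @param stem output path stem (no extension).
#' @return `write_system`: the stem, invisibly; `read_system`: the
#'   reconstructed `particle_system`.
#' @export
write_system <- function(system, stem) {
  write_xyz(system$positions, system$groups, paste0(stem, ".xyz"),
            comment = "egressr particle system")
  topo <- list(format = "egressr-topology-v1",
               charges = system$charges, lj_epsilon = system$lj_epsilon,
               lj_sigma = system$lj_sigma, masses = system$masses,
               bonds = system$bonds, bond_k = system$bond_k,
               bond_r0 = system$bond_r0, restrained = system$restrained,
               restraint_k = system$restraint_k,
               ref_positions = system$ref_positions,
               groups = system$groups,
               layout = unclass(system$layout),
               ligand = unclass(system$ligand))
  jsonlite::write_json(topo, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_system
#' @export
read_system <- function(stem) {
  xyz <- read_xyz(paste0(stem, ".xyz"))
  topo <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  if (!identical(topo$format, "egressr-topology-v1"))
    stop("not an egressr topology file: ", stem, ".json")
  layout <- topo$layout; class(layout) <- "receptor_layout"
  ligand <- topo$ligand; class(ligand) <- "ligand_spec"
  sys <- list(positions = xyz$frames[[1]], charges = topo$charges,
              lj_epsilon = topo$lj_epsilon, lj_sigma = topo$lj_sigma,
              masses = topo$masses,
              bonds = matrix(as.integer(topo$bonds), ncol = 2),
              bond_k = topo$bond_k, bond_r0 = topo$bond_r0,
              restrained = topo$restrained,
              ref_positions = matrix(as.numeric(topo$ref_positions),
                                     ncol = 3),
              restraint_k = topo$restraint_k, groups = topo$groups,
              layout = layout, ligand = ligand,
              n = length(topo$charges))
  class(sys) <- "particle_system"
  sys
}

#' Write a trajectory to XYZ
#'
#' @param trajectory a `cg_trajectory`.
#' @param labels per-particle tags.
#' @param path file path.
#' @export
write_trajectory_xyz <- function(trajectory, labels, path) {
  stopifnot(inherits(trajectory, "cg_trajectory"))
  if (file.exists(path)) file.remove(path)
  for (f in seq_len(dim(trajectory$coords)[1])) {
    write_xyz(trajectory$coords[f, , ], labels, path,
              comment = sprintf("t= %.6g ps", trajectory$times[f]),
              append = f > 1)
  }
  invisible(path)
}

#' Write/read force records
#'
#' Two dialects are supported.  `"csv"` is the full record with header
#' `t_ps,ax,ay,az,cx,cy,cz,fx_pN,fy_pN,fz_pN`.  `"namd"` mirrors the
#' line-oriented SMD output of MD engines:
#' `SMD <step> <cx> <cy> <cz> <fx> <fy> <fz>` (step = time/dt; forces pN).
#' The namd dialect carries no anchor positions, so those columns are `NA`
#' after reading it; all shared fields round-trip losslessly.
#'
#' @param record a `force_record`.
#' @param path file path.
#' @param dialect `"csv"` or `"namd"`.
#' @param dt timestep used to convert between time and step in the namd
#'   dialect, ps.
#' @return `write_force_record`: the path invisibly; `read_force_record` /
#'   [parse_smd_log()]: a `force_record`.
#' @export
write_force_record <- function(record, path, dialect = c("csv", "namd"),
                               dt = 0.01) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    write.csv(as.data.frame(record), path, row.names = FALSE)
  } else {
    lines <- sprintf("SMD %d %.10g %.10g %.10g %.10g %.10g %.10g",
                     as.integer(round(record$t_ps / dt)), record$cx,
                     record$cy, record$cz, record$fx_pN, record$fy_pN,
                     record$fz_pN)
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_force_record
#' @export
read_force_record <- function(path, dialect = c("csv", "namd"), dt = 0.01) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- read.csv(path)
    need <- c("t_ps", "ax", "ay", "az", "cx", "cy", "cz", "fx_pN", "fy_pN",
              "fz_pN")
    missing <- setdiff(need, names(df))
    if (length(missing))
      stop("force-record CSV lacks columns: ", paste(missing, collapse = ", "))
    rec <- df[need]
  } else {
    lines <- readLines(path)
    keep <- which(startsWith(trimws(lines), "SMD"))
    parts <- strsplit(trimws(lines[keep]), "\\s+")
    bad <- which(lengths(parts) != 8)
    if (length(bad))
      stop(sprintf("malformed SMD line %d: expected 8 fields, got %d",
                   keep[bad[1]], lengths(parts)[bad[1]]))
    num <- t(vapply(parts, function(p) as.numeric(p[2:8]), numeric(7)))
    if (any(!is.finite(num)))
      stop("non-numeric field in SMD line ",
           keep[which(rowSums(!is.finite(num)) > 0)[1]])
    rec <- data.frame(t_ps = num[, 1] * dt, ax = NA_real_, ay = NA_real_,
                      az = NA_real_, cx = num[, 2], cy = num[, 3],
                      cz = num[, 4], fx_pN = num[, 5], fy_pN = num[, 6],
                      fz_pN = num[, 7])
  }
  class(rec) <- c("force_record", "data.frame")
  rec
}

#' Parse an SMD force log
#'
#' Thin dispatcher over [read_force_record()] for externally produced
#' pulling logs.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"namd"`.
#' @param dt timestep for the namd dialect, ps.
#' @return a `force_record`.
#' @export
parse_smd_log <- function(path, dialect = c("csv", "namd"), dt = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path)
  read_force_record(path, dialect, dt)
}

#' Write an energy profile to CSV
#'
#' @param profile an `energy_profile`.
#' @param path file path.
#' @export
write_energy_profile <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
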