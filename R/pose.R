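# Centre-of-mass pose geometry: COM-COM distances between a simulated final
# pose and reference (crystal) poses expressed in a common frame, and their
# per-ligand aggregation.  COM distance is used instead of RMSD because
# simulated and crystal ligands need not share an atom mapping; no
# superposition is performed, poses must already share a frame.

#' Mass-weighted centre of mass
#'
#' @param positions N x 3 matrix, A.
#' @param masses length-N masses, amu.
#' @param subset optional index vector selecting the group.
#' @return 3-vector, A.
#' @export
center_of_mass <- function(positions, masses, subset = NULL) {
  positions <- as.matrix(positions)
  if (is.null(dim(positions))) positions <- matrix(positions, 1)
  if (!is.null(subset)) {
    positions <- positions[subset, , drop = FALSE]
    masses <- masses[subset]
  }
  if (!nrow(positions)) stop("empty particle subset")
  m <- sum(masses)
  if (m <= 0) stop("total mass must be positive")
  as.numeric(masses %*% positions) / m
}

#' COM-COM pose distance
#'
#' Euclidean distance between the centres of mass of two poses; invariant to
#' particle permutation within each pose and to any common rigid motion.
#'
#' @param pose_a,pose_b coordinate matrices (n x 3), A.
#' @param masses_a,masses_b per-particle masses; default unit masses.
#' @return distance in A.
#' @export
pose_distance <- function(pose_a, pose_b, masses_a = NULL, masses_b = NULL) {
  pose_a <- as.matrix(pose_a); pose_b <- as.matrix(pose_b)
  if (is.null(masses_a)) masses_a <- rep(1, nrow(pose_a))
  if (is.null(masses_b)) masses_b <- rep(1, nrow(pose_b))
  ca <- center_of_mass(pose_a, masses_a)
  cb <- center_of_mass(pose_b, masses_b)
  sqrt(sum((ca - cb)^2))
}

#' Pose-distance table
#'
#' Validates a table of (ligand, reference, source id, distance) rows: the
#' distances between a ligand's simulated final pose and each reference
#' (crystal) pose.  Distances must be non-negative and each
#' (ligand, reference, pdb_id) combination unique.
#'
#' @param df data.frame with columns `ligand`, `reference`, `pdb_id`,
#'   `distance_A`.
#' @return the validated data.frame, class `pose_distance_table`.
#' @export
pose_distance_table <- function(df) {
  need <- c("ligand", "reference", "pdb_id", "distance_A")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("pose-distance table lacks columns: ", paste(missing, collapse = ", "))
  if (any(df$distance_A < 0)) stop("distances must be non-negative")
  key <- paste(df$ligand, df$reference, df$pdb_id)
  if (anyDuplicated(key))
    stop("duplicate (ligand, reference, pdb_id) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  class(df) <- c("pose_distance_table", "data.frame")
  df
}

#' Read a pose-distance table from CSV
#'
#' @param path CSV file with header
#'   `ligand,reference,pdb_id,distance_A`.
#' @return a [pose_distance_table()].
#' @export
read_pose_table <- function(path) {
  pose_distance_table(read.csv(path, stringsAsFactors = FALSE))
}

#' The packaged reference pose-distance table
#'
#' Distances (A) between the SuMD final pose of each lipid-receptor agonist
#' and the corresponding crystal ligands, shipped as a plain-text fixture.
#'
#' @return a [pose_distance_table()].
#' @export
reference_pose_table <- function() {
  read_pose_table(system.file("extdata", "table1_pose_distances.csv",
                              package = "egressr", mustWork = TRUE))
}

# round half away from zero (the convention used for reported averages)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Mean reference distance of a ligand
#'
#' Arithmetic mean of one ligand's pose distances over all its reference
#' structures, rounded half-away-from-zero to `digits` decimals (the
#' convention of the reported per-ligand averages).
#'
#' @param table a [pose_distance_table()].
#' @param ligand_label ligand to aggregate.
#' @param digits decimals to round to (default 1).
#' @return mean distance in A.
#' @export
mean_reference_distance <- function(table, ligand_label, digits = 1) {
  rows <- table$distance_A[table$ligand == ligand_label]
  if (!length(rows))
    stop("unknown ligand '", ligand_label, "'; available: ",
         paste(unique(table$ligand), collapse = ", "))
  round_half_away(mean(rows), digits)
}
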