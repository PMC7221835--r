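# Pulling-work analysis: the componentwise trapezoidal work integral
# W = sum_i (F(i)+F(i+1))/2 . (r(i+1)-r(i)) taken against the pulled-COM
# displacement, maximal restraint force as a friction/steric proxy,
# replicate aggregation, and pathway ranking by mean work with a
# max-force tie-break for statistically equivalent pathways.

#' Trapezoidal pulling work
#'
#' Integrates the spring force against the pulled-COM displacement with the
#' componentwise trapezoid rule:
#' `W = sum (Fx_mid*dx + Fy_mid*dy + Fz_mid*dz)` over consecutive samples.
#' Work accumulates along the path the ligand actually travels, so spring
#' stretch does not count as distance.
#'
#' @param record a `force_record`.
#' @param units `"pN_A"` (default) or `"kcal_mol"` (1 kcal/mol = 69.479 pN A).
#' @param cumulative if `TRUE`, return the running cumulative work at every
#'   sample (first element 0) instead of the total.
#' @return numeric scalar (or vector when `cumulative`).
#' @export
integrate_work <- function(record, units = c("pN_A", "kcal_mol"),
                           cumulative = FALSE) {
  units <- match.arg(units)
  if (nrow(record) < 2) stop("force record needs at least 2 samples")
  if (any(diff(record$t_ps) <= 0)) stop("times must be strictly increasing")
  fmid <- function(f) (f[-1] + f[-length(f)]) / 2
  dW <- fmid(record$fx_pN) * diff(record$cx) +
    fmid(record$fy_pN) * diff(record$cy) +
    fmid(record$fz_pN) * diff(record$cz)
  w <- if (cumulative) c(0, cumsum(dW)) else sum(dW)
  if (units == "kcal_mol") w <- pn_to_kcal(w)
  w
}

#' Maximal restraint force
#'
#' Maximum of the spring-force vector magnitude over a record; a proxy for
#' the friction/steric resistance of the pathway.
#'
#' @param record a `force_record`.
#' @return pN.
#' @export
max_force <- function(record) {
  if (nrow(record) < 1) stop("empty force record")
  max(sqrt(record$fx_pN^2 + record$fy_pN^2 + record$fz_pN^2))
}

#' Per-repeat work profile
#'
#' Bundles one pull's cumulative work curve, total work and maximal force.
#'
#' @param record a `force_record`.
#' @param direction direction label; default the record's own.
#' @return object of class `work_profile`: list with `direction`, `curve`
#'   (data.frame `t_ps`, `displacement_A` from the pull start,
#'   `W_pN_A`, `W_kcal`), `total_pN_A`, `total_kcal`, `fmax_pN`.
#' @export
work_profile <- function(record, direction = NULL) {
  direction <- direction %||% attr(record, "direction")
  cum <- integrate_work(record, cumulative = TRUE)
  disp <- sqrt((record$cx - record$cx[1])^2 + (record$cy - record$cy[1])^2 +
               (record$cz - record$cz[1])^2)
  out <- list(direction = direction,
              curve = data.frame(t_ps = record$t_ps, displacement_A = disp,
                                 W_pN_A = cum, W_kcal = pn_to_kcal(cum)),
              total_pN_A = cum[length(cum)],
              total_kcal = pn_to_kcal(cum[length(cum)]),
              fmax_pN = max_force(record))
  class(out) <- "work_profile"
  out
}

#' Aggregate replicate pulls of one direction
#'
#' Arithmetic mean and sample SD of the total works and maximal forces of
#' replicate pulls along one direction.  A single repeat yields SD 0 with a
#' degenerate flag.
#'
#' @param profiles list of [work_profile()] objects sharing one direction.
#' @return one-row data.frame: `direction`, `n_repeats`, `mean_W_kcal`,
#'   `sd_W_kcal`, `mean_Fmax_pN`, `sd_Fmax_pN`, `sd_degenerate`.
#' @export
aggregate_direction <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  dirs <- unique(vapply(profiles, `[[`, character(1), "direction"))
  if (length(dirs) != 1)
    stop("mixed direction labels: ", paste(dirs, collapse = ", "))
  W <- vapply(profiles, `[[`, numeric(1), "total_kcal")
  Fm <- vapply(profiles, `[[`, numeric(1), "fmax_pN")
  degen <- length(W) < 2
  data.frame(direction = dirs, n_repeats = length(W),
             mean_W_kcal = mean(W), sd_W_kcal = if (degen) 0 else sd(W),
             mean_Fmax_pN = mean(Fm), sd_Fmax_pN = if (degen) 0 else sd(Fm),
             sd_degenerate = degen)
}

#' Build a direction comparison table
#'
#' @param profiles list of [work_profile()] objects (any mix of directions).
#' @return data.frame with one row per direction (see
#'   [aggregate_direction()]), class `direction_comparison`.
#' @export
direction_comparison <- function(profiles) {
  dirs <- vapply(profiles, `[[`, character(1), "direction")
  rows <- lapply(split(profiles, factor(dirs, levels = unique(dirs))),
                 aggregate_direction)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("direction_comparison", "data.frame")
  out
}

# two directions are statistically equivalent when their mean works differ
# by no more than the larger of their SDs
.equivalent <- function(a, b) {
  abs(a$mean_W_kcal - b$mean_W_kcal) <= max(a$sd_W_kcal, b$sd_W_kcal)
}

#' Rank candidate pathways
#'
#' Orders directions by ascending mean pulling work.  Adjacent pathways whose
#' mean works lie within the larger of the two SDs are treated as
#' statistically equivalent and re-ordered by ascending mean maximal force
#' (then label).  The verdict names the winner (smallest work, and among
#' equivalent candidates the smallest friction) and whether the runner-up is
#' statistically equivalent to it.
#'
#' @param comparison a [direction_comparison()] (>= 2 directions).
#' @return list of class `pathway_ranking` with `order` (ranked labels),
#'   `table` (comparison re-ordered, with a `rank` column), `winner`,
#'   `runner_up_equivalent`.
#' @export
rank_pathways <- function(comparison) {
  stopifnot(nrow(comparison) >= 2)
  tab <- comparison[order(comparison$mean_W_kcal, comparison$direction), ,
                    drop = FALSE]
  # stable bubble passes: swap equivalent neighbours with lower max force up
  repeat {
    swapped <- FALSE
    for (i in seq_len(nrow(tab) - 1)) {
      a <- tab[i, ]; b <- tab[i + 1, ]
      if (.equivalent(a, b) &&
          (b$mean_Fmax_pN < a$mean_Fmax_pN ||
           (b$mean_Fmax_pN == a$mean_Fmax_pN && b$direction < a$direction))) {
        tab[c(i, i + 1), ] <- tab[c(i + 1, i), ]
        swapped <- TRUE
      }
    }
    if (!swapped) break
  }
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  out <- list(order = tab$direction, table = tab, winner = tab$direction[1],
              runner_up_equivalent = .equivalent(tab[1, ], tab[2, ]))
  class(out) <- "pathway_ranking"
  out
}

#' @export
print.pathway_ranking <- function(x, ...) {
  cat("Pathway ranking (ascending mean pulling work):\n")
  print(x$table[, c("rank", "direction", "n_repeats", "mean_W_kcal",
                    "sd_W_kcal", "mean_Fmax_pN")], row.names = FALSE)
  cat(sprintf("winner: %s%s\n", x$winner,
              if (x$runner_up_equivalent)
                " (runner-up statistically equivalent)" else ""))
  invisible(x)
}
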