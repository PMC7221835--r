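# Display of pulling and entrance runs: force-time and cumulative-work
# panels per direction, and the three-curve interaction-energy profile.

#' Force-time curves of replicate pulls
#'
#' @param records list of `force_record` objects (one or more replicates).
#' @param main plot title.
#' @importFrom graphics plot lines legend par abline
#' @importFrom grDevices rainbow
#' @export
plot_force_time <- function(records, main = "SMD restraint force") {
  if (inherits(records, "force_record")) records <- list(records)
  fmag <- lapply(records, function(r) sqrt(r$fx_pN^2 + r$fy_pN^2 + r$fz_pN^2))
  cols <- rainbow(length(records))
  plot(NA, xlim = range(unlist(lapply(records, `[[`, "t_ps"))),
       ylim = range(unlist(fmag)), xlab = "time (ps)", ylab = "|F| (pN)",
       main = main)
  for (i in seq_along(records)) lines(records[[i]]$t_ps, fmag[[i]], col = cols[i])
  invisible(NULL)
}

#' Cumulative pulling-work curves per direction
#'
#' One panel of cumulative work against pulled-COM displacement; replicates
#' of the same direction share a colour.
#'
#' @param profiles list of [work_profile()] objects.
#' @export
plot_work_curves <- function(profiles) {
  dirs <- vapply(profiles, `[[`, character(1), "direction")
  cols <- setNames(rainbow(length(unique(dirs))), unique(dirs))
  xr <- range(unlist(lapply(profiles, function(p) p$curve$displacement_A)))
  yr <- range(unlist(lapply(profiles, function(p) p$curve$W_kcal)))
  plot(NA, xlim = xr, ylim = yr, xlab = "pulled-COM displacement (A)",
       ylab = "cumulative work (kcal/mol)", main = "Pulling work by direction")
  for (p in profiles)
    lines(p$curve$displacement_A, p$curve$W_kcal, col = cols[p$direction])
  legend("topleft", legend = names(cols), col = cols, lty = 1, bty = "n")
  invisible(NULL)
}

#' Ligand-receptor interaction-energy profile plot
#'
#' Total interaction energy with its electrostatic and van der Waals
#' contributions, optionally smoothed with a running mean.
#'
#' @param profile an `energy_profile`.
#' @param window running-mean window in samples (`0` disables smoothing).
#' @export
plot_energy_profile <- function(profile, window = 50L) {
  if (window > 0) profile <- smooth_profile(profile, window)
  yr <- range(profile$E_elec, profile$E_vdw, profile$E_total)
  plot(profile$t_ps, profile$E_total, type = "l", col = "darkgreen",
       ylim = yr, xlab = "time (ps)", ylab = "energy (kcal/mol)",
       main = "Ligand-receptor interaction energy")
  lines(profile$t_ps, profile$E_elec, col = "blue")
  lines(profile$t_ps, profile$E_vdw, col = "orange")
  abline(h = 0, lty = 3)
  legend("bottomleft", legend = c("total", "electrostatic", "van der Waals"),
         col = c("darkgreen", "blue", "orange"), lty = 1, bty = "n")
  invisible(NULL)
}
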