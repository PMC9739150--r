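# Partial mass-density profiles along the membrane normal, in the
# convention of the GROMACS density tool: slab bins along Z, per-frame
# XY box area (the ensemble is semi-isotropically coupled, so the area
# fluctuates), averaged over frames.

#' Partial mass-density profile along the membrane normal
#'
#' Per frame, each selected atom's mass is assigned to its membrane-frame Z
#' bin and divided by the slab volume (box XY area x bin width); profiles
#' are then averaged over frames. Densities are reported in amu/Angstrom^3
#' (`unit = "kg.m-3"` converts by 1 amu/A^3 = 1660.539 kg/m^3).
#'
#' @param traj a trajectory with a defined box.
#' @param group_sel non-empty atom selection.
#' @param bin_width Z bin width in Angstrom (default 1).
#' @param mframe a [membrane_frame()] placing Z = 0 at the bilayer center
#'   (or `NULL` for laboratory Z).
#' @param zlim optional Z range; defaults to the group's span padded to the
#'   bin grid.
#' @param unit `"amu.A-3"` (default) or `"kg.m-3"`.
#' @return data.frame of class `"density_profile"`: `z` (bin centers) and
#'   `density`; attributes `bin_width`, `unit`, `n_frames`, `group_mass`.
#' @export
density_profile <- function(traj, group_sel, bin_width = 1.0, mframe = NULL,
                            zlim = NULL, unit = c("amu.A-3", "kg.m-3")) {
  unit <- match.arg(unit)
  if (is.null(traj$box)) stop("density_profile() needs box dimensions")
  idx <- resolve_selection(group_sel, traj$topology)
  if (length(idx) == 0) stop("empty group selection")
  stopifnot(bin_width > 0)
  m <- traj$topology$mass[idx]
  nf <- n_frames(traj)
  zall <- membrane_z(mframe, traj$xyz[idx, 3, , drop = TRUE])
  zall <- matrix(zall, nrow = length(idx))
  if (is.null(zlim)) zlim <- range(zall)
  edges <- seq(floor(zlim[1] / bin_width) * bin_width,
               ceiling(zlim[2] / bin_width) * bin_width + bin_width,
               by = bin_width)
  nb <- length(edges) - 1L
  acc <- numeric(nb)
  for (f in seq_len(nf)) {
    area <- traj$box[f, 1] * traj$box[f, 2]
    bi <- findInterval(zall[, f], edges, rightmost.closed = TRUE)
    ok <- bi >= 1L & bi <= nb
    prof <- numeric(nb)
    tab <- tapply(m[ok], bi[ok], sum)
    prof[as.integer(names(tab))] <- tab
    acc <- acc + prof / (area * bin_width)
  }
  dens <- acc / nf
  if (unit == "kg.m-3") dens <- dens * 1660.539
  out <- data.frame(z = (edges[-1] + edges[-length(edges)]) / 2,
                    density = dens)
  class(out) <- c("density_profile", "data.frame")
  attr(out, "bin_width") <- bin_width
  attr(out, "unit") <- unit
  attr(out, "n_frames") <- nf
  attr(out, "group_mass") <- sum(m)
  out
}

#' Membrane-normal level of the terminal acyl carbon
#'
#' Mean and standard deviation over frames of the terminal carbon's Z in
#' the membrane frame - the readout showing that acyl tails of any length
#' reach the same cavity-ceiling level.
#'
#' @param traj a trajectory.
#' @param terminal_c_sel single-atom selection.
#' @param mframe a [membrane_frame()] or `NULL`.
#' @return list with `mean`, `sd` (Angstrom) and the per-frame `z` series.
#' @export
terminal_z_level <- function(traj, terminal_c_sel, mframe = NULL) {
  i <- .resolve1(terminal_c_sel, traj$topology, "terminal carbon")
  z <- membrane_z(mframe, as.numeric(traj$xyz[i, 3, ]))
  list(mean = mean(z), sd = if (length(z) > 1) sd(z) else NA_real_, z = z)
}
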