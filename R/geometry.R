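#' Center of mass of a selection
#'
#' @param xyz `n x 3` coordinate matrix (Angstrom).
#' @param idx atom indices (non-empty).
#' @param masses per-atom masses for the full coordinate set; when `NULL`
#'   the unweighted mean is returned.
#' @return length-3 vector (Angstrom).
#' @export
center_of_mass <- function(xyz, idx = seq_len(nrow(xyz)), masses = NULL) {
  if (length(idx) == 0) stop("empty selection in center_of_mass()")
  x <- xyz[idx, , drop = FALSE]
  if (is.null(masses)) return(colMeans(x))
  w <- masses[idx]
  colSums(x * w) / sum(w)
}

#' Interatomic distance
#'
#' Plain Euclidean distance; no periodic wrapping (frames are assumed
#' pre-centered so the complex is whole within the box).
#'
#' @param xyz `n x 3` coordinate matrix.
#' @param i,j atom indices.
#' @return distance in Angstrom.
#' @export
atom_distance <- function(xyz, i, j) {
  if (i == j) warning("atom_distance(): i == j, returning 0")
  sqrt(sum((xyz[i, ] - xyz[j, ])^2))
}

#' Angle at a vertex atom
#'
#' Angle a-b-c with the vertex at `b`, in degrees within \[0, 180\].
#'
#' @param xyz `n x 3` coordinate matrix.
#' @param a,b,c atom indices; `b` is the vertex.
#' @return angle in degrees.
#' @export
atom_angle <- function(xyz, a, b, c) {
  v1 <- xyz[a, ] - xyz[b, ]
  v2 <- xyz[c, ] - xyz[b, ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero-length vector in atom_angle()")
  cosv <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Membrane frame from lipid phosphorus atoms
#'
#' Defines Z = 0 at the bilayer center: `z_origin` is the mean Z of the lipid
#' phosphorus atoms (averaged over frames for a trajectory). The membrane
#' normal is the laboratory Z axis, matching the convention of
#' protein-centered bilayer simulations.
#'
#' @param x a trajectory or an `n x 3` coordinate matrix.
#' @param lipid_p_idx selection (indices or expression) of lipid P atoms.
#' @return list of class `"membrane_frame"` with `z_origin` (Angstrom) and
#'   `normal_axis = "z"`.
#' @export
membrane_frame <- function(x, lipid_p_idx) {
  if (inherits(x, "traj")) {
    idx <- resolve_selection(lipid_p_idx, x$topology)
    if (length(idx) == 0) stop("empty lipid selection in membrane_frame()")
    z_origin <- mean(x$xyz[idx, 3, ])
  } else {
    idx <- lipid_p_idx
    if (length(idx) == 0) stop("empty lipid selection in membrane_frame()")
    z_origin <- mean(x[idx, 3])
  }
  structure(list(z_origin = z_origin, normal_axis = "z"),
            class = "membrane_frame")
}

#' Map laboratory Z to membrane-frame Z
#' @param mframe a [membrane_frame()] (or `NULL` for the identity).
#' @param z laboratory Z coordinates (Angstrom).
#' @return membrane-frame Z (0 at bilayer center).
#' @export
membrane_z <- function(mframe, z) {
  if (is.null(mframe)) z else z - mframe$z_origin
}

#' Orient a structure by the principal axis of its TM helices
#'
#' Rotates coordinates so the first principal axis of the transmembrane
#' C-alpha cloud lies along +Z, with the sign chosen so that `up_idx` (the
#' cavity-ceiling atoms) ends up at larger Z than `down_idx` (the catalytic
#' site) - the teepee topology with its bottleneck on the extracellular side.
#' Used to evaluate the ceiling offset D1 on a crystal structure that carries
#' no bilayer to define the membrane normal.
#'
#' @param x a trajectory or an `n x 3` coordinate matrix.
#' @param tm_ca_idx selection of TM C-alpha atoms (>= 3, non-collinear).
#' @param up_idx,down_idx selections fixing the sign of +Z (optional; when
#'   absent the sign of the first principal axis is arbitrary).
#' @return the rotated object, same type as `x`.
#' @export
orient_by_principal_axis <- function(x, tm_ca_idx, up_idx = NULL,
                                     down_idx = NULL) {
  is_traj <- inherits(x, "traj")
  top <- if (is_traj) x$topology else NULL
  resolve <- function(s) if (is_traj) resolve_selection(s, top) else s
  ca <- resolve(tm_ca_idx)
  if (length(ca) < 3) stop("need >= 3 TM C-alpha atoms")
  ref <- if (is_traj) frame_xyz(x, 1L) else x
  X <- ref[ca, , drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  if (sv$d[2] < 1e-8 * sv$d[1]) stop("degenerate (collinear) C-alpha cloud")
  # columns: new x <- PC2, new y <- PC3, new z <- PC1
  M <- cbind(sv$v[, 2], sv$v[, 3], sv$v[, 1])
  if (det(M) < 0) M[, 2] <- -M[, 2]
  rot <- function(m) m %*% M
  if (!is.null(up_idx) && !is.null(down_idx)) {
    r <- rot(ref)
    zup <- mean(r[resolve(up_idx), 3])
    zdn <- mean(r[resolve(down_idx), 3])
    if (zup < zdn) {         # flip 180 degrees about the new x axis
      M[, 2] <- -M[, 2]; M[, 3] <- -M[, 3]
    }
  }
  if (is_traj) {
    out <- x
    for (f in seq_len(n_frames(x))) out$xyz[, , f] <- x$xyz[, , f] %*% M
    out
  } else {
    x %*% M
  }
}

#' Kabsch minimum RMSD between two coordinate sets
#'
#' Root-mean-square deviation after the optimal rigid superposition
#' (rotation + translation), mass-unweighted, computed with the Kabsch
#' SVD construction.
#'
#' @param xyz_a,xyz_b `n x 3` coordinate matrices.
#' @param idx optional common atom indices (>= 3 atoms).
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(xyz_a, xyz_b, idx = NULL) {
  if (!is.null(idx)) {
    xyz_a <- xyz_a[idx, , drop = FALSE]
    xyz_b <- xyz_b[idx, , drop = FALSE]
  }
  if (nrow(xyz_a) != nrow(xyz_b)) stop("coordinate sets differ in size")
  if (nrow(xyz_a) < 3) stop("need >= 3 atoms for superposition")
  A <- sweep(xyz_a, 2, colMeans(xyz_a))
  B <- sweep(xyz_b, 2, colMeans(xyz_b))
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Ar <- A %*% t(R)
  sqrt(mean(rowSums((Ar - B)^2)))
}

#' C-alpha RMSD time series against the first frame
#'
#' @param traj a trajectory.
#' @param idx selection of atoms (default `"name CA and protein"`).
#' @return numeric vector, one RMSD (Angstrom) per frame; the first entry
#'   is 0.
#' @export
rmsd_vs_start <- function(traj, idx = "name CA and protein") {
  ai <- resolve_selection(idx, traj$topology)
  ref <- frame_xyz(traj, 1L)
  vapply(seq_len(n_frames(traj)),
         function(f) kabsch_rmsd(frame_xyz(traj, f), ref, ai),
         numeric(1))
}
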