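# Time-averaged protein-ligand interaction fingerprints: heavy-atom contact
# maps, hydrogen-bond occupancies ("lifetimes", fraction of frames), and
# pi-cation lifetimes between an Arg guanidinium and an aromatic ring.

.heavy <- function(top, idx) idx[top$element[idx] != "H"]

.res_key <- function(top, idx)
  paste0(top$chain[idx], ":", top$resname[idx], top$resid[idx])

#' Protein-ligand heavy-atom contact map
#'
#' For every (protein residue, ligand heavy atom) pair, the fraction of
#' frames in which at least one heavy-atom pair lies within `cutoff`
#' (default 4 Angstrom, the intermolecular acyl-chain/protein contact
#' cutoff). Hydrogens are excluded on both sides.
#'
#' @param traj a trajectory.
#' @param ligand_sel,protein_sel selections (non-empty after removing
#'   hydrogens).
#' @param cutoff contact distance in Angstrom (> 0).
#' @return matrix of class `"contact_map"`; rows are protein residues
#'   (`chain:RESNAMEresid`), columns ligand atom names, values in \[0, 1\].
#' @export
contact_map <- function(traj, ligand_sel, protein_sel, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  top <- traj$topology
  lig <- .heavy(top, resolve_selection(ligand_sel, top))
  prot <- .heavy(top, resolve_selection(protein_sel, top))
  if (length(lig) == 0) stop("empty ligand selection")
  if (length(prot) == 0) stop("empty protein selection")
  res <- .res_key(top, prot)
  ures <- unique(res)
  counts <- matrix(0L, length(ures), length(lig),
                   dimnames = list(ures, top$name[lig]))
  nf <- n_frames(traj)
  cut2 <- cutoff^2
  for (f in seq_len(nf)) {
    xyz <- traj$xyz[, , f]
    P <- xyz[prot, , drop = FALSE]
    L <- xyz[lig, , drop = FALSE]
    # squared cross-distances, protein x ligand
    d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
    hit <- d2 < cut2
    for (r in seq_along(ures)) {
      rows <- which(res == ures[r])
      counts[r, ] <- counts[r, ] +
        (colSums(hit[rows, , drop = FALSE]) > 0)
    }
  }
  structure(counts / nf, class = c("contact_map", "matrix"),
            cutoff = cutoff, n_frames = nf)
}

.bonded_hydrogens <- function(traj, donor_idx, h_max = 1.25) {
  top <- traj$topology
  h_idx <- which(top$element == "H")
  if (length(h_idx) == 0) return(setNames(list(), character(0)))
  xyz <- frame_xyz(traj, 1L)
  out <- lapply(donor_idx, function(d) {
    dd <- sqrt(colSums((t(xyz[h_idx, , drop = FALSE]) - xyz[d, ])^2))
    h_idx[dd <= h_max]
  })
  names(out) <- as.character(donor_idx)
  out
}

#' Hydrogen-bond occupancies
#'
#' A frame counts for a (donor, hydrogen, acceptor) triple when the
#' donor-acceptor distance is at most `d_max` and the H-D-A angle at most
#' `angle_max` (the geometric criterion of the standard GROMACS H-bond
#' tool). Lifetime is occupancy: counted frames / total frames. Hydrogens
#' are assigned to donor heavy atoms by covalent distance in the first
#' frame; donors without a bonded hydrogen are skipped with a warning.
#'
#' @param traj a trajectory.
#' @param donors_sel selection of donor heavy atoms (N/O with bound H).
#' @param acceptors_sel selection of acceptor heavy atoms.
#' @param d_max donor-acceptor distance cutoff in Angstrom (default 3.5).
#' @param angle_max H-D-A angle cutoff in degrees (default 30).
#' @return data.frame of class `"hbond_records"`: donor/hydrogen/acceptor
#'   serials and residue keys, plus `lifetime`; only records with
#'   `lifetime > 0` are returned.
#' @export
find_hbonds <- function(traj, donors_sel, acceptors_sel,
                        d_max = 3.5, angle_max = 30) {
  top <- traj$topology
  don <- .heavy(top, resolve_selection(donors_sel, top))
  acc <- .heavy(top, resolve_selection(acceptors_sel, top))
  if (length(don) == 0 || length(acc) == 0)
    stop("empty donor or acceptor selection")
  hmap <- .bonded_hydrogens(traj, don)
  no_h <- vapply(hmap, length, integer(1)) == 0
  if (any(no_h))
    warning(sum(no_h), " donor(s) without a bonded hydrogen skipped")
  don <- don[!no_h]; hmap <- hmap[!no_h]
  nf <- n_frames(traj)
  rows <- list()
  for (k in seq_along(don)) {
    d <- don[k]
    for (h in hmap[[k]]) {
      for (a in acc) {
        if (a == d) next
        da <- .atom_series(traj, a) - .atom_series(traj, d)
        dist_da <- sqrt(colSums(da^2))
        vh <- .atom_series(traj, h) - .atom_series(traj, d)
        nh <- sqrt(colSums(vh^2))
        cosv <- colSums(vh * da) / (nh * dist_da)
        ang <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
        life <- mean(dist_da <= d_max & ang <= angle_max)
        if (life > 0)
          rows[[length(rows) + 1L]] <- data.frame(
            donor = top$serial[d], hydrogen = top$serial[h],
            acceptor = top$serial[a],
            donor_res = .res_key(top, d), acceptor_res = .res_key(top, a),
            donor_name = top$name[d], acceptor_name = top$name[a],
            lifetime = life)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor = integer(0), hydrogen = integer(0),
               acceptor = integer(0), donor_res = character(0),
               acceptor_res = character(0), donor_name = character(0),
               acceptor_name = character(0), lifetime = numeric(0))
  class(out) <- c("hbond_records", "data.frame")
  attr(out, "criteria") <- list(d_max = d_max, angle_max = angle_max)
  out
}

#' Filter hydrogen bonds by reporting lifetime
#'
#' Keeps records with `lifetime > min_lifetime` (strict, default 10
#' percent). Given a list of record tables from several trajectories, a
#' record (by donor/acceptor residue pair) is kept everywhere if it passes
#' in at least one trajectory.
#'
#' @param records an `hbond_records` data.frame, or a list of them.
#' @param min_lifetime reporting threshold in \[0, 1\].
#' @return filtered records (same type as the input).
#' @export
filter_hbonds <- function(records, min_lifetime = 0.10) {
  if (is.data.frame(records))
    return(records[records$lifetime > min_lifetime, , drop = FALSE])
  keys <- lapply(records, function(r) paste(r$donor_res, r$acceptor_res))
  pass <- unique(unlist(Map(function(r, k) k[r$lifetime > min_lifetime],
                            records, keys)))
  Map(function(r, k) r[k %in% pass, , drop = FALSE], records, keys)
}

#' Pi-cation lifetime between a cation group and an aromatic ring
#'
#' A frame counts when the distance from the cation position (centroid of
#' `cation_sel`, e.g. the Arg guanidinium carbon) to the ring centroid is at
#' most `d_max` and the angle between the ring-plane normal and the
#' centroid-to-cation vector is at most `tilt_max`, i.e. the cation stacks
#' above the ring face.
#'
#' @param traj a trajectory.
#' @param cation_sel selection of the cation group (centroid used).
#' @param ring_sel selection of >= 5 ring atoms defining a plane.
#' @param d_max centroid distance cutoff in Angstrom (default 6).
#' @param tilt_max tilt cutoff in degrees (default 45).
#' @return list of class `"pi_cation_record"` with `lifetime`, the per-frame
#'   logical `state`, and the criterion used.
#' @export
pi_cation <- function(traj, cation_sel, ring_sel, d_max = 6.0,
                      tilt_max = 45) {
  top <- traj$topology
  cat_idx <- resolve_selection(cation_sel, top)
  ring <- resolve_selection(ring_sel, top)
  if (length(ring) < 5) stop("ring selection needs >= 5 atoms")
  if (length(cat_idx) == 0) stop("empty cation selection")
  nf <- n_frames(traj)
  state <- logical(nf)
  for (f in seq_len(nf)) {
    xyz <- traj$xyz[, , f]
    ctr <- colMeans(xyz[ring, , drop = FALSE])
    R <- sweep(xyz[ring, , drop = FALSE], 2, ctr)
    sv <- svd(R)
    if (sv$d[2] < 1e-6 * sv$d[1])
      stop("near-degenerate ring plane at frame ", f)
    normal <- sv$v[, 3]
    cat_pos <- colMeans(xyz[cat_idx, , drop = FALSE])
    v <- cat_pos - ctr
    dist <- sqrt(sum(v^2))
    cosv <- abs(sum(v * normal)) / dist   # normal sign is arbitrary
    tilt <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
    state[f] <- dist <= d_max && tilt <= tilt_max
  }
  structure(list(lifetime = mean(state), state = state,
                 criteria = list(d_max = d_max, tilt_max = tilt_max)),
            class = "pi_cation_record")
}
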