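# Core reactivity geometry: cavity fitness (D1), nucleophilic-attack
# proximity (D2) and Buergi-Dunitz angle, reactive-state classification,
# summary statistics with conditional averaging, 2D density modes and the
# in-silico selectivity profile.

#' Reactive-state criteria
#'
#' A trajectory frame is *reactive* when the nucleophile-carbonyl distance
#' D2 is below `d2_max` and the Buergi-Dunitz attack angle exceeds
#' `abd_min`; it is *improper* when D2 is below `d2_max` but the angle is
#' below `abd_min`. Inequalities are strict: frames exactly at a threshold
#' are neither.
#'
#' @param d2_max maximum nucleophile-carbonyl C distance in Angstrom
#'   (default 6, the van der Waals contact range).
#' @param abd_min minimum attack angle in degrees (default 90; the ideal
#'   Buergi-Dunitz approach is near 107 degrees but can relax toward 90 in
#'   enzyme active sites, remaining obtuse).
#' @return list of class `"reactivity_criteria"`.
#' @export
reactivity_criteria <- function(d2_max = 6, abd_min = 90) {
  stopifnot(d2_max > 0, abd_min > 0, abd_min < 180)
  structure(list(d2_max = d2_max, abd_min = abd_min),
            class = "reactivity_criteria")
}

.zseries <- function(traj, idx) traj$xyz[idx, 3, ]

# 3 x n_frames coordinate series of one atom (robust to 1-frame drop)
.atom_series <- function(traj, i) matrix(traj$xyz[i, , ], nrow = 3)

#' Cavity-fitness parameter D1
#'
#' Per-frame Z offset between the acyl tail's terminal carbon and the center
#' of mass of the cavity ceiling (the Ser/Val/Ser triad closing the TM
#' teepee on the extracellular side), both in the membrane frame. Negative
#' values mean the tail tip sits below the ceiling.
#'
#' @param traj a trajectory.
#' @param terminal_c_sel selection resolving to exactly one atom (the
#'   terminal acyl carbon).
#' @param ceiling_sel non-empty selection of ceiling heavy atoms; the COM is
#'   mass-weighted.
#' @param mframe a [membrane_frame()] or `NULL` (D1 is a Z difference, so
#'   the frame offset cancels; the argument keeps the interface uniform).
#' @return numeric vector, one D1 (Angstrom) per frame.
#' @export
compute_d1 <- function(traj, terminal_c_sel, ceiling_sel, mframe = NULL) {
  tip <- .resolve1(terminal_c_sel, traj$topology, "terminal carbon")
  ceil <- resolve_selection(ceiling_sel, traj$topology)
  if (length(ceil) == 0) stop("empty ceiling selection")
  w <- traj$topology$mass[ceil]
  zc <- apply(traj$xyz[ceil, 3, , drop = FALSE], 3,
              function(z) sum(z * w) / sum(w))
  as.numeric(.zseries(traj, tip) - zc)
}

#' Nucleophile-carbonyl distance D2
#'
#' Per-frame distance between the catalytic nucleophile atom (Cys SG, or the
#' Ser hydroxyl O of a catalytically dead mutant) and the acyl thioester
#' carbonyl carbon.
#'
#' @param traj a trajectory.
#' @param nucleophile_sel,carbonyl_c_sel selections resolving to exactly one
#'   atom each.
#' @return numeric vector of distances (Angstrom), one per frame.
#' @export
compute_d2 <- function(traj, nucleophile_sel, carbonyl_c_sel) {
  i <- .resolve1(nucleophile_sel, traj$topology, "nucleophile")
  j <- .resolve1(carbonyl_c_sel, traj$topology, "carbonyl carbon")
  sqrt(colSums((.atom_series(traj, i) - .atom_series(traj, j))^2))
}

#' Buergi-Dunitz attack angle
#'
#' Per-frame angle Nu...C=O with the vertex at the carbonyl carbon: the
#' approach angle of the nucleophile onto the carbonyl relative to the C=O
#' bond.
#'
#' @param traj a trajectory.
#' @param nucleophile_sel,carbonyl_c_sel,carbonyl_o_sel single-atom
#'   selections.
#' @return numeric vector of angles in degrees, one per frame.
#' @export
compute_abd <- function(traj, nucleophile_sel, carbonyl_c_sel,
                        carbonyl_o_sel) {
  nu <- .resolve1(nucleophile_sel, traj$topology, "nucleophile")
  cc <- .resolve1(carbonyl_c_sel, traj$topology, "carbonyl carbon")
  oo <- .resolve1(carbonyl_o_sel, traj$topology, "carbonyl oxygen")
  v1 <- .atom_series(traj, nu) - .atom_series(traj, cc)
  v2 <- .atom_series(traj, oo) - .atom_series(traj, cc)
  n1 <- sqrt(colSums(v1^2)); n2 <- sqrt(colSums(v2^2))
  if (any(n1 == 0) || any(n2 == 0))
    stop("zero-length vector in compute_abd()")
  cosv <- colSums(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosv))) * 180 / pi
}

#' Classify frames as reactive / improper
#'
#' @param d2 numeric D2 series (Angstrom).
#' @param abd numeric attack-angle series (degrees), same length.
#' @param criteria a [reactivity_criteria()].
#' @return data.frame with logical columns `reactive` and `improper`.
#' @export
classify_reactive <- function(d2, abd, criteria = reactivity_criteria()) {
  if (length(d2) != length(abd))
    stop("d2 and abd series differ in length (", length(d2), " vs ",
         length(abd), ")")
  close_enough <- d2 < criteria$d2_max
  data.frame(reactive = close_enough & abd > criteria$abd_min,
             improper = close_enough & abd < criteria$abd_min)
}

#' Full per-frame reactivity series for one system
#'
#' Convenience wrapper computing D1, D2 and the attack angle and classifying
#' every frame.
#'
#' @param traj a trajectory.
#' @param sel named list with selections `terminal_c`, `ceiling`,
#'   `nucleophile`, `carbonyl_c`, `carbonyl_o`.
#' @param mframe optional [membrane_frame()].
#' @param criteria a [reactivity_criteria()].
#' @return data.frame of class `"reactivity_series"` with columns
#'   `frame, time, d1, d2, abd, reactive, improper`.
#' @export
reactivity_series <- function(traj, sel, mframe = NULL,
                              criteria = reactivity_criteria()) {
  d1 <- compute_d1(traj, sel$terminal_c, sel$ceiling, mframe)
  d2 <- compute_d2(traj, sel$nucleophile, sel$carbonyl_c)
  abd <- compute_abd(traj, sel$nucleophile, sel$carbonyl_c, sel$carbonyl_o)
  cl <- classify_reactive(d2, abd, criteria)
  out <- data.frame(frame = seq_along(d1), time = traj$time,
                    d1 = d1, d2 = d2, abd = abd,
                    reactive = cl$reactive, improper = cl$improper)
  class(out) <- c("reactivity_series", "data.frame")
  attr(out, "criteria") <- criteria
  out
}

#' Summary statistics with conditional averaging
#'
#' D1 is averaged over all frames; D2 and the attack angle are averaged over
#' the close-approach frames only (`d2 < d2_max`), the convention used when
#' tabulating per-run means. Standard deviations are sample (n-1) and this
#' choice is recorded in the `sd_type` field. When no frame satisfies the
#' condition the conditional fields are `NA` and `conditional_defined` is
#' `FALSE`.
#'
#' @param series a [reactivity_series()] (or any data.frame with columns
#'   `d1, d2, abd, reactive, improper`).
#' @param criteria a [reactivity_criteria()].
#' @param condition `"d2"` (default) restricts the D2/angle averages to
#'   frames with `d2 < d2_max`; `"reactive"` restricts them to reactive
#'   frames instead.
#' @return one-row data.frame with columns `d1_mean, d1_sd, d2_mean, d2_sd,
#'   abd_mean, abd_sd, reactive_fraction, improper_fraction, n_frames,
#'   conditional_defined, sd_type`.
#' @export
summarize_reactivity <- function(series, criteria = reactivity_criteria(),
                                 condition = c("d2", "reactive")) {
  condition <- match.arg(condition)
  if (nrow(series) < 1) stop("empty reactivity series")
  keep <- if (condition == "d2") series$d2 < criteria$d2_max
          else series$reactive
  defined <- any(keep)
  sd1 <- function(x) if (length(x) > 1) sd(x) else NA_real_
  data.frame(
    d1_mean = mean(series$d1), d1_sd = sd1(series$d1),
    d2_mean = if (defined) mean(series$d2[keep]) else NA_real_,
    d2_sd = if (defined) sd1(series$d2[keep]) else NA_real_,
    abd_mean = if (defined) mean(series$abd[keep]) else NA_real_,
    abd_sd = if (defined) sd1(series$abd[keep]) else NA_real_,
    reactive_fraction = mean(series$reactive),
    improper_fraction = mean(series$improper),
    n_frames = nrow(series),
    conditional_defined = defined,
    sd_type = "sample")
}

#' Fraction of reactive frames
#' @param flags logical vector of per-frame reactive flags.
#' @return numeric in \[0, 1\].
#' @export
reactive_fraction <- function(flags) {
  if (length(flags) == 0) stop("empty flag series")
  mean(flags)
}

#' In-silico selectivity profile across acyl chain lengths
#'
#' Normalizes per-chain-length reactive (and improper) state fractions so
#' each column sums to 100 percent, making the bars comparable across
#' lengths. An all-zero column yields all-zero percentages with a warning.
#'
#' @param reactive named numeric vector of reactive fractions, one per chain
#'   length label (e.g. `c(C12 = 0.05, ...)`).
#' @param improper optional matching vector of improper-angle fractions.
#' @return data.frame of class `"selectivity_profile"` with columns `chain`,
#'   `reactive_fraction`, `normalized_reactive_pct` and (when given)
#'   `improper_fraction`, `normalized_improper_pct`.
#' @export
selectivity_profile <- function(reactive, improper = NULL) {
  if (length(reactive) == 0 || !any(is.finite(reactive)))
    stop("need at least one finite fraction")
  if (any(reactive < 0, na.rm = TRUE)) stop("negative reactive fraction")
  norm <- function(f) {
    s <- sum(f)
    if (s == 0) {
      warning("all fractions zero; normalized profile is all zero")
      f * 0
    } else 100 * f / s
  }
  out <- data.frame(chain = names(reactive),
                    reactive_fraction = as.numeric(reactive),
                    normalized_reactive_pct = norm(as.numeric(reactive)))
  if (!is.null(improper)) {
    if (any(improper < 0, na.rm = TRUE)) stop("negative improper fraction")
    out$improper_fraction <- as.numeric(improper)
    out$normalized_improper_pct <- norm(as.numeric(improper))
  }
  class(out) <- c("selectivity_profile", "data.frame")
  out
}

#' 2D histogram of (D2, attack angle) states and its mode
#'
#' Bins the joint distribution of the two reactivity coordinates; the mode
#' is the center of the maximal-count bin, ties broken toward the lowest D2
#' and then the lowest angle. Replicate runs may be concatenated into the
#' input series before binning.
#'
#' @param d2 D2 series (Angstrom).
#' @param abd attack-angle series (degrees), same length.
#' @param d2_bin,abd_bin bin widths (defaults 0.25 Angstrom, 5 degrees).
#' @return list of class `"density2d"`: `d2_edges`, `abd_edges`, `counts`
#'   (matrix, D2 rows x angle columns) and `mode = c(d2, abd)`.
#' @export
density2d <- function(d2, abd, d2_bin = 0.25, abd_bin = 5) {
  if (length(d2) == 0) stop("empty series")
  if (length(d2) != length(abd)) stop("series length mismatch")
  stopifnot(d2_bin > 0, abd_bin > 0)
  e1 <- seq(floor(min(d2) / d2_bin) * d2_bin,
            ceiling(max(d2) / d2_bin) * d2_bin + d2_bin, by = d2_bin)
  e2 <- seq(floor(min(abd) / abd_bin) * abd_bin,
            ceiling(max(abd) / abd_bin) * abd_bin + abd_bin, by = abd_bin)
  i1 <- findInterval(d2, e1, rightmost.closed = TRUE)
  i2 <- findInterval(abd, e2, rightmost.closed = TRUE)
  counts <- matrix(0L, length(e1) - 1L, length(e2) - 1L)
  for (k in seq_along(i1))
    counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1L
  mx <- max(counts)
  hits <- which(counts == mx, arr.ind = TRUE)
  # tie-break: lowest d2 bin, then lowest angle bin
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  b <- hits[1, ]
  mode <- c(d2 = (e1[b[1]] + e1[b[1] + 1L]) / 2,
            abd = (e2[b[2]] + e2[b[2] + 1L]) / 2)
  structure(list(d2_edges = e1, abd_edges = e2, counts = counts,
                 mode = mode),
            class = "density2d")
}
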