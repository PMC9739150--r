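# End-to-end orchestration: load systems from a config (YAML file or R
# list), fail fast on unresolvable selections, run every analysis, and
# emit CSV tables plus a JSON manifest. Outputs are deterministic for a
# fixed config, so reruns are byte-identical.

.default_thresholds <- function() {
  list(d2_max = 6, abd_min = 90, contact_cutoff = 4,
       hbond_d_max = 3.5, hbond_angle_max = 30, hbond_min_lifetime = 0.10,
       pi_cation_d_max = 6, pi_cation_tilt_max = 45,
       density_bin_width = 1)
}

#' Assemble a run configuration
#'
#' @param systems list of systems; each element either a
#'   `synthetic_system`, or a list with `label`, `trajectory` (path or
#'   [trajectory()]) and optional `topology` path.
#' @param selections named list of selection strings (`ceiling`,
#'   `nucleophile`, `carbonyl_c`, `carbonyl_o`, `terminal_c`, `ligand`,
#'   `protein`, `lipid_p`, and optionally the H-bond / pi-cation
#'   selections). Defaults come from synthetic systems when present.
#' @param thresholds named list overriding the documented defaults
#'   (D2 < 6 Angstrom, angle > 90 degrees, 4 Angstrom contacts, 3.5
#'   Angstrom / 30 degree H-bonds, 6 Angstrom / 45 degree pi-cation, 1
#'   Angstrom density bins, 10 percent H-bond reporting).
#' @param output_dir directory for CSV/JSON outputs (`NULL` = no files).
#' @param seed integer recorded in the manifest (the analyses themselves
#'   are deterministic).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(systems, selections = NULL, thresholds = list(),
                       output_dir = NULL, seed = 1L) {
  th <- utils::modifyList(.default_thresholds(), thresholds)
  structure(list(systems = systems, selections = selections,
                 thresholds = th, output_dir = output_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with fields `systems` (list of
#'   `label`/`trajectory`/`topology`), `selections`, `thresholds`,
#'   `output_dir`, `seed`.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(systems = y$systems, selections = y$selections,
             thresholds = if (is.null(y$thresholds)) list() else
               y$thresholds,
             output_dir = y$output_dir,
             seed = if (is.null(y$seed)) 1L else y$seed)
}

.load_system <- function(sys, default_sel) {
  if (inherits(sys, "synthetic_system"))
    return(list(label = sys$label, traj = sys$traj,
                selections = sys$selections))
  traj <- sys$trajectory
  if (is.character(traj))
    traj <- read_trajectory(traj, topology =
                              if (!is.null(sys$topology))
                                read_structure(sys$topology)$topology)
  list(label = sys$label, traj = traj,
       selections = if (!is.null(sys$selections)) sys$selections
                    else default_sel)
}

.check_selections <- function(sel, top, label) {
  needed <- c("ceiling", "nucleophile", "carbonyl_c", "carbonyl_o",
              "terminal_c", "ligand", "protein", "lipid_p")
  for (nm in needed) {
    if (is.null(sel[[nm]]))
      stop("system '", label, "': missing selection '", nm, "'")
    n <- length(resolve_selection(sel[[nm]], top))
    if (n == 0 && nm != "lipid_p")
      stop("system '", label, "': selection '", nm,
           "' resolves to no atoms")
  }
}

#' Run the full analysis over all configured systems
#'
#' Per system: the per-frame reactivity series, summary statistics with
#' conditional averaging, the (D2, angle) 2D density and its mode, the
#' heavy-atom contact map, H-bond and pi-cation lifetimes, and the acyl
#' membrane-normal density profile. Across systems: the normalized
#' in-silico selectivity profile. All thresholds and the seed are echoed
#' into a JSON manifest. Every selection is resolved against its topology
#' before any computation starts.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return invisible list with `systems` (per-system results), `profile`
#'   (a [selectivity_profile()]), `summary` (one row per system) and
#'   `manifest`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  th <- config$thresholds
  crit <- reactivity_criteria(th$d2_max, th$abd_min)
  loaded <- lapply(config$systems, .load_system, config$selections)
  for (s in loaded) .check_selections(s$selections, s$traj$topology,
                                      s$label)
  out_dir <- config$output_dir
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    if (!is.null(out_dir))
      write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  results <- list()
  for (s in loaded) {
    sel <- s$selections
    traj <- s$traj
    mf <- tryCatch(membrane_frame(traj, sel$lipid_p),
                   error = function(e) NULL)
    series <- reactivity_series(traj, sel, mf, crit)
    smry <- summarize_reactivity(series, crit)
    smry <- cbind(label = s$label, smry)
    dens2 <- density2d(series$d2, series$abd)
    cmap <- contact_map(traj, sel$ligand, sel$protein, th$contact_cutoff)
    hb <- if (!is.null(sel$hbond_donors))
      find_hbonds(traj, sel$hbond_donors, sel$hbond_acceptors,
                  th$hbond_d_max, th$hbond_angle_max) else NULL
    pc <- if (!is.null(sel$pi_cation_cation))
      pi_cation(traj, sel$pi_cation_cation, sel$pi_cation_ring,
                th$pi_cation_d_max, th$pi_cation_tilt_max) else NULL
    dprof <- if (!is.null(traj$box))
      density_profile(traj, sel$ligand, th$density_bin_width, mf) else NULL
    emit(series, paste0(s$label, "_series.csv"))
    emit(as.data.frame(as.table(unclass(cmap)),
                       responseName = "frequency"),
         paste0(s$label, "_contacts.csv"))
    if (!is.null(hb)) emit(as.data.frame(hb),
                           paste0(s$label, "_hbonds.csv"))
    if (!is.null(dprof)) emit(dprof, paste0(s$label, "_density.csv"))
    results[[s$label]] <- list(label = s$label, series = series,
                               summary = smry, density2d = dens2,
                               contact_map = cmap, hbonds = hb,
                               pi_cation = pc, density_profile = dprof)
  }
  summary_tab <- do.call(rbind, lapply(results, `[[`, "summary"))
  rownames(summary_tab) <- NULL
  fr <- vapply(results, function(r) r$summary$reactive_fraction,
               numeric(1))
  im <- vapply(results, function(r) r$summary$improper_fraction,
               numeric(1))
  profile <- selectivity_profile(fr, im)
  emit(summary_tab, "summary.csv")
  emit(profile, "selectivity_profile.csv")
  manifest <- list(package = "acylselect",
                   version = as.character(utils::packageVersion(
                     "acylselect")),
                   seed = config$seed, thresholds = th,
                   sd_type = "sample",
                   systems = vapply(loaded, `[[`, character(1), "label"))
  if (!is.null(out_dir))
    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(systems = results, profile = profile,
                 summary = summary_tab, manifest = manifest))
}

#' Reference geometry of a single (crystal) structure
#'
#' Orients the structure by the principal axis of its transmembrane
#' C-alpha cloud (a crystal carries no bilayer to define the membrane
#' normal), then computes the three reactivity scalars once. The
#' nucleophile defaults to the Ser hydroxyl O when residue 156 is SER (the
#' catalytically dead mutant trapped in the crystal) and to the Cys SG
#' otherwise.
#'
#' @param structure path to a PDB/GRO file, or a one-frame [trajectory()].
#' @param selections named list with `tm_ca`, `ceiling`, `carbonyl_c`,
#'   `carbonyl_o`, `terminal_c`, and optionally `nucleophile` (overrides
#'   the residue-156 default) and `catalytic_resid` (default 156).
#' @return list with `d1`, `d2` (Angstrom) and `abd` (degrees).
#' @export
run_crystal_reference <- function(structure, selections) {
  traj <- if (is.character(structure)) read_structure(structure) else
    structure
  top <- traj$topology
  res_cat <- if (is.null(selections$catalytic_resid)) 156L else
    selections$catalytic_resid
  nuc <- selections$nucleophile
  if (is.null(nuc)) {
    resname <- unique(top$resname[top$resid == res_cat &
                                    top$resname %in% .AMINO3])
    if (length(resname) != 1)
      stop("cannot identify catalytic residue ", res_cat)
    nuc <- paste("resid", res_cat, "and name",
                 if (resname == "SER") "OG" else "SG")
  }
  oriented <- orient_by_principal_axis(traj, selections$tm_ca,
                                       up_idx = selections$ceiling,
                                       down_idx = paste("resid", res_cat))
  list(d1 = compute_d1(oriented, selections$terminal_c,
                       selections$ceiling)[1],
       d2 = compute_d2(oriented, nuc, selections$carbonyl_c)[1],
       abd = compute_abd(oriented, nuc, selections$carbonyl_c,
                         selections$carbonyl_o)[1])
}
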