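#' Analysis configuration
#'
#' Collects every tunable of the per-system analysis pipeline. The default
#' window convention mirrors common practice for equilibrated trajectories:
#' the terminal fraction of the trajectory is sampled with a fixed number
#' of equally spaced snapshots.
#'
#' @param last_fraction Fraction of the trajectory (by frame count, from the
#'   end) to analyse (default 1.0 = all frames).
#' @param n_snapshots Number of equally spaced snapshots to draw from the
#'   window (default 200; capped at the window size by the caller erroring).
#' @param n_bins Density-profile bins (default 100).
#' @param probe_profile "AA" (0.14 nm probe) or "CG" (0.265 nm probe).
#' @param contact_prefilter,contact_cutoff,occupancy_min Contact extraction
#'   parameters, nm / fraction.
#' @param core_radius,rim_distance Order-parameter region parameters, nm.
#' @param seed Seed echoed into the report (analysis itself is
#'   deterministic).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(last_fraction = 1.0, n_snapshots = 200,
                            n_bins = 100, probe_profile = c("AA", "CG"),
                            contact_prefilter = 1.0, contact_cutoff = 0.4,
                            occupancy_min = 0.5, core_radius = 3.0,
                            rim_distance = 1.4, seed = 1L) {
  probe_profile <- match.arg(probe_profile)
  stopifnot(last_fraction > 0, last_fraction <= 1, n_snapshots >= 1)
  structure(list(last_fraction = last_fraction,
                 n_snapshots = as.integer(n_snapshots),
                 n_bins = as.integer(n_bins), probe_profile = probe_profile,
                 contact_prefilter = contact_prefilter,
                 contact_cutoff = contact_cutoff,
                 occupancy_min = occupancy_min, core_radius = core_radius,
                 rim_distance = rim_distance, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Subsample the terminal analysis window of a trajectory
#'
#' Takes the last `last_fraction` of the frames and returns `n_snapshots`
#' of them at equal index spacing (all of them when the window holds
#' exactly `n_snapshots` frames).
#'
#' @param x A `trajectory`.
#' @param config An [analysis_config()].
#' @return A `trajectory` with `n_snapshots` frames.
#' @export
select_analysis_window <- function(x, config = analysis_config()) {
  nf <- n_frames(x)
  nw <- max(1L, round(config$last_fraction * nf))
  window <- (nf - nw + 1L):nf
  if (config$n_snapshots > nw)
    stop("analysis window has ", nw, " frames but ", config$n_snapshots,
         " snapshots were requested")
  # equal-interval extraction: stride nw/n, exactly uniform when divisible
  idx <- window[ceiling(seq(nw / config$n_snapshots, nw,
                            length.out = config$n_snapshots))]
  subset_frames(x, idx)
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(list(value = expr, error = NULL),
                  error = function(e) list(value = NULL,
                                           error = conditionMessage(e)))
  report$metrics[[name]] <- res$value
  if (!is.null(res$error)) {
    report$stage_errors[[name]] <- res$error
    report$partial <- TRUE
  }
  report
}

#' Run the full nanodisc analysis pipeline on one trajectory
#'
#' Reorients every frame (bilayer normal to z, major axis to x), then
#' computes: phosphate peak-to-peak thickness, per-axis and mean diameters
#' from both the protein-maxima and the lipid 1 kg/m^3 threshold methods,
#' radius of gyration, mean SASA, backbone RMSD (mean +/- sd), inter-chain
#' contacts with classification, order-parameter profiles (full/core/rim)
#' and escaped lipids. Stages fail independently: an error in one metric is
#' recorded in `stage_errors` and the remaining stages still run (the
#' report is then flagged partial).
#'
#' @param x A `trajectory`, or a path readable by [read_structure()].
#' @param label System label ("n-P"/"n-A"); inferred as "unknown" if absent.
#' @param config An [analysis_config()].
#' @param topology Passed to [read_structure()] when `x` is a DCD path.
#' @return An `analysis_report` list with `label`, `config`, `metrics`
#'   (units embedded in the names), `stage_errors` and `partial`.
#' @export
run_analysis <- function(x, label = "unknown", config = analysis_config(),
                         topology = NULL) {
  if (is.character(x)) x <- read_structure(x, topology = topology)
  nw <- max(1L, round(config$last_fraction * n_frames(x)))
  cfg <- config
  if (cfg$n_snapshots > nw) cfg$n_snapshots <- nw
  x <- select_analysis_window(x, cfg)
  x <- reorient(x)$traj
  lipid_sel <- select_atoms(x, resname = "DMPC")
  protein_sel <- setdiff(seq_len(n_atoms(x)), lipid_sel)
  has_belt <- length(protein_sel) > 0
  report <- structure(list(label = label, config = cfg,
                           metrics = list(), stage_errors = list(),
                           partial = FALSE, package_version =
                             as.character(utils::packageVersion("discbelt"))),
                      class = "analysis_report")
  p_sel <- intersect(lipid_sel, select_atoms(x, atom_name = "P"))
  report <- run_stage(report, "thickness_nm", {
    prof <- mass_density_profile(x, p_sel, axis = "z", n_bins = cfg$n_bins)
    bilayer_thickness(prof)
  })
  for (ax in c("x", "y")) {
    if (has_belt)
      report <- run_stage(report, paste0("diameter_protein_", ax, "_nm"), {
        prof <- symmetrize_profile(mass_density_profile(
          x, protein_sel, axis = ax, n_bins = cfg$n_bins))
        diameter_from_protein(prof)
      })
    report <- run_stage(report, paste0("diameter_lipid_", ax, "_nm"), {
      prof <- symmetrize_profile(mass_density_profile(
        x, lipid_sel, axis = ax, n_bins = cfg$n_bins))
      diameter_from_lipid(prof)
    })
  }
  m <- report$metrics
  if (has_belt && !is.null(m$diameter_protein_x_nm) &&
      !is.null(m$diameter_protein_y_nm))
    report$metrics$diameter_protein_mean_nm <-
      average_diameter(m$diameter_protein_x_nm, m$diameter_protein_y_nm,
                       "protein_maxima")$mean
  if (!is.null(m$diameter_lipid_x_nm) && !is.null(m$diameter_lipid_y_nm))
    report$metrics$diameter_lipid_mean_nm <-
      average_diameter(m$diameter_lipid_x_nm, m$diameter_lipid_y_nm,
                       "lipid_threshold")$mean
  report <- run_stage(report, "radius_of_gyration_nm",
                      radius_of_gyration(x))
  report <- run_stage(report, "sasa_nm2",
                      nanodisc_sasa_series(x, probe_profile =
                                             cfg$probe_profile)$mean)
  if (has_belt) {
    report <- run_stage(report, "backbone_rmsd", {
      rs <- backbone_rmsd_series(x)
      list(mean_nm = rs$mean, sd_nm = if (is.na(rs$sd)) 0 else rs$sd,
           formatted = format_rmsd(rs))
    })
    report <- run_stage(report, "contacts", {
      rec <- interchain_contacts(x, prefilter = cfg$contact_prefilter,
                                 cutoff = cfg$contact_cutoff,
                                 occupancy_min = cfg$occupancy_min)
      s <- summarize_contacts(rec, label)
      list(records = rec, summary = unclass(s))
    })
    report <- run_stage(report, "order_parameters",
                        scd_region_profiles(x, core_radius = cfg$core_radius,
                                            rim_distance = cfg$rim_distance,
                                            reoriented = TRUE))
  } else {
    report <- run_stage(report, "order_parameters",
                        scd_profile(x, reoriented = TRUE))
  }
  report <- run_stage(report, "escaped_lipid_ids",
                      detect_escaped_lipids(x, lipid_sel))
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis report for", x$label,
      if (x$partial) "(partial)\n" else "\n")
  for (nm in names(x$metrics)) {
    v <- x$metrics[[nm]]
    if (is.numeric(v) && length(v) == 1)
      cat(sprintf("  %-28s %.3f\n", nm, v))
  }
  if (length(x$stage_errors))
    cat("  failed stages:", paste(names(x$stage_errors), collapse = ", "),
        "\n")
  invisible(x)
}

#' Serialise an analysis report to JSON
#' @param report An `analysis_report` (or list of them).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep)
  else if (is.object(x)) unclass(x) else x
}

#' Compare parallel and antiparallel analysis reports
#'
#' Produces the standard configuration comparison: contact-count ratios per
#' category (mean antiparallel over mean parallel across the common lipid
#' counts), per-carbon order-parameter differences, a side-by-side RMSD
#' table, and linear trends of diameter, SASA and Rg against lipid count.
#'
#' @param reports_parallel,reports_antiparallel Named lists of
#'   `analysis_report`s keyed by lipid count, or data.frames of
#'   pre-computed contact summaries (columns as in
#'   [apoe_contact_counts()]), in which case only the contact comparison is
#'   produced.
#' @return List with `contact_ratios`, and (when full reports are given)
#'   `delta_scd`, `rmsd_table`, `trends`.
#' @export
compare_configurations <- function(reports_parallel, reports_antiparallel) {
  if (is.data.frame(reports_parallel)) {
    return(list(contact_ratios =
                  configuration_comparison(reports_parallel,
                                           reports_antiparallel)))
  }
  pull <- function(reports, mode) {
    do.call(rbind, lapply(names(reports), function(nm) {
      s <- reports[[nm]]$metrics$contacts$summary
      data.frame(n_lipids = as.integer(nm), mode = mode,
                 polar_total = s$polar_total, ionic = s$ionic,
                 nonspecific = s$nonspecific, nonpolar = s$nonpolar,
                 total = s$total, stringsAsFactors = FALSE)
    }))
  }
  p <- pull(reports_parallel, "parallel")
  a <- pull(reports_antiparallel, "antiparallel")
  out <- list(contact_ratios = configuration_comparison(p, a))
  common <- intersect(names(reports_parallel), names(reports_antiparallel))
  if (length(common)) {
    out$delta_scd <- lapply(setNames(common, common), function(nm) {
      pp <- reports_parallel[[nm]]$metrics$order_parameters
      pa <- reports_antiparallel[[nm]]$metrics$order_parameters
      delta_scd(pp[pp$region == "full", ], pa[pa$region == "full", ])
    })
  }
  grab <- function(reports, metric)
    vapply(reports, function(r) {
      v <- r$metrics[[metric]]
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
  rmsd_row <- function(reports, mode)
    data.frame(n_lipids = as.integer(names(reports)), mode = mode,
               rmsd = vapply(reports, function(r) {
                 b <- r$metrics$backbone_rmsd
                 if (is.null(b)) NA_character_ else b$formatted
               }, character(1)), stringsAsFactors = FALSE)
  out$rmsd_table <- rbind(rmsd_row(reports_parallel, "parallel"),
                          rmsd_row(reports_antiparallel, "antiparallel"))
  out$trends <- lapply(list(parallel = reports_parallel,
                            antiparallel = reports_antiparallel),
                       function(reports) {
    n <- as.integer(names(reports))
    res <- list()
    for (metric in c("diameter_protein_mean_nm", "sasa_nm2",
                     "radius_of_gyration_nm")) {
      v <- grab(reports, metric)
      ok <- !is.na(v)
      if (sum(ok) >= 2 && length(unique(n[ok])) >= 2)
        res[[metric]] <- linear_trend(n[ok], v[ok])
    }
    res
  })
  out
}
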