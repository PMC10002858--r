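# End-to-end orchestration: contacts -> topology -> heatmaps -> QC,
# with config validation and a run manifest.

.config_keys <- c(
  "structure", "frames", "format", "synthetic", "selections", "cutoff",
  "gap_frames", "stride", "seed", "out_dir", "bin_width", "lipid_classes",
  "recenter", "depth_ref_group", "phosphate_group", "headgroup_group",
  "composition", "qc_window_ns", "qc_tolerance"
)

#' Validate a pipeline run configuration
#'
#' @param config Named list (or path to a YAML/JSON file). Allowed keys:
#'   `structure`/`frames`/`format` (input files) or `synthetic` (list of
#'   [synthetic_params()] arguments); `selections` (`"synthetic"`,
#'   `"charmm36"` or a file path); `cutoff` (Angstrom, default 6);
#'   `gap_frames` (default 0); `stride` (default 1); `seed`; `out_dir`
#'   (required); `bin_width` (default 1); `lipid_classes` (default PS and
#'   CHOL); `recenter` (default FALSE); `depth_ref_group`,
#'   `phosphate_group`, `headgroup_group` (selection group names for the
#'   depth stage); `composition` (`"phorbol"`, `"bryostatin"` or counts
#'   for the APL stage); `qc_window_ns`, `qc_tolerance`
#'   (see [stability_check()]). Unknown keys are rejected.
#' @return The completed config list (defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(format = "auto", selections = "synthetic", cutoff = 6,
                   gap_frames = 0, stride = 1, seed = 1, bin_width = 1,
                   lipid_classes = c("PS", "CHOL"), recenter = FALSE,
                   depth_ref_group = "G253_CA", phosphate_group = "PS",
                   headgroup_group = "headgroups",
                   qc_window_ns = 100, qc_tolerance = 0.01)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  if (is.null(config$out_dir)) stop("config needs 'out_dir'")
  if (config$cutoff <= 0) stop("cutoff must be > 0")
  if (config$gap_frames < 0) stop("gap_frames must be >= 0")
  if (config$stride < 1) stop("stride must be >= 1")
  if (config$bin_width <= 0) stop("bin_width must be > 0")
  has_files <- !is.null(config$structure) || !is.null(config$frames)
  if (is.null(config$synthetic) && is.null(config$frames)) {
    stop("config needs either 'frames' (+ optional 'structure') or 'synthetic'")
  }
  if (!is.null(config$synthetic) && has_files) {
    stop("config has both file inputs and 'synthetic'")
  }
  config
}

.selection_from_config <- function(config) {
  if (config$selections %in% c("synthetic", "charmm36")) {
    read_selection_spec(default_selection_path(config$selections))
  } else {
    read_selection_spec(config$selections)
  }
}

.composition_from_config <- function(config, synthetic_comp = NULL) {
  cmp <- config$composition
  if (is.null(cmp)) return(synthetic_comp)
  if (is.character(cmp)) return(reference_composition(cmp))
  membrane_composition(upper = unlist(cmp$upper), lower = unlist(cmp$lower))
}

#' Run the full analysis pipeline
#'
#' Executes contacts, topology, heatmap and QC stages in order and writes
#' CSV/grid outputs plus a JSON run manifest to `out_dir`. Reruns with the
#' same config and seed produce identical CSV outputs.
#'
#' @param config Config list or path, see [validate_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(
    package = as.character(utils::packageVersion("membcontacts")),
    r_version = R.version.string,
    config = config[setdiff(names(config), "out_dir")],
    stages = list()
  )
  comp <- NULL
  traj <- stage("input", {
    if (!is.null(config$synthetic)) {
      args <- config$synthetic
      if (!is.null(args$composition) && is.character(args$composition)) {
        args$composition <- reference_composition(args$composition)
      }
      if (!is.null(args$contact_plan)) {
        args$contact_plan <- as.data.frame(args$contact_plan)
      }
      if (is.null(args$seed)) args$seed <- config$seed
      sim <- simulate_trajectory(do.call(synthetic_params, args))
      comp <- do.call(synthetic_params, args)$composition
      sim$trajectory
    } else {
      sys <- if (!is.null(config$structure)) {
        read_structure(config$structure, config$format)
      } else NULL
      read_frames(config$frames, system = sys, format = config$format)
    }
  })
  if (config$stride > 1) {
    traj <- subset_frames(traj, seq(1, n_frames(traj), by = config$stride))
  }
  sel <- stage("input", .selection_from_config(config))
  resolved <- stage("input", resolve_selection(traj$system, sel))
  add_output <- function(stage_name, file, rows) {
    manifest$stages[[stage_name]]$outputs <<-
      c(manifest$stages[[stage_name]]$outputs,
        stats::setNames(list(list(path = file, rows = rows)), basename(file)))
  }

  # --- contacts -------------------------------------------------------
  stage("contacts", {
    rec <- contact_records(traj, sel, cutoff = config$cutoff,
                           lipid_classes = config$lipid_classes)
    occ <- occupancy(rec)
    f <- file.path(out, "occupancy.csv")
    write_table(occ, f); add_output("contacts", f, nrow(occ))
    occ_m <- occupancy_by_molecule(rec)
    occ_m <- occ_m[occ_m$occupancy_fraction > 0, , drop = FALSE]
    f <- file.path(out, "occupancy_by_molecule.csv")
    write_table(occ_m, f); add_output("contacts", f, nrow(occ_m))
    lt <- lifetime_table(rec, gap_tolerance_frames = config$gap_frames)
    f <- file.path(out, "lifetimes.csv")
    write_table(lt, f); add_output("contacts", f, nrow(lt))
    mv <- if (length(rec)) multivalency(rec)$summary else
      data.frame(entity = character(), kind = character(),
                 bound_frames = integer(), multivalent_frames = integer(),
                 multivalent_fraction = numeric())
    f <- file.path(out, "multivalency.csv")
    write_table(mv, f); add_output("contacts", f, nrow(mv))
  })

  # --- topology -------------------------------------------------------
  stage("topology", {
    hg <- resolved[[config$headgroup_group]]
    ref <- resolved[[config$depth_ref_group]]
    ph <- resolved[[config$phosphate_group]]
    if (is.null(hg) || is.null(ref) || is.null(ph)) {
      stop("selection groups for depth not found (need '",
           config$headgroup_group, "', '", config$depth_ref_group,
           "', '", config$phosphate_group, "')")
    }
    dep <- insertion_depth(traj, ref, ph, hg)
    f <- file.path(out, "depth.csv")
    write_table(dep, f); add_output("topology", f, nrow(dep))
    til <- tilt_angle(traj)
    f <- file.path(out, "tilt.csv")
    write_table(til, f); add_output("topology", f, nrow(til))
    th <- topology_histogram(dep$depth, til$tilt)
    f <- file.path(out, "topology_hist.txt")
    write_grid(heatmap_grid(th$counts, th$depth_edges, th$tilt_edges), f)
    add_output("topology", f, sum(th$counts))
    manifest$stages$topology$depth_mean <- th$depth_mean
    manifest$stages$topology$tilt_mean <- th$tilt_mean
  })

  # --- heatmaps -------------------------------------------------------
  stage("heatmap", {
    hg <- resolved[[config$headgroup_group]]
    lip_groups <- selection_by_role(sel, "lipid_probe")
    overlay <- mean_protein_positions(traj, recenter = config$recenter)
    f <- file.path(out, "protein_positions.csv")
    write_table(overlay, f); add_output("heatmap", f, nrow(overlay))
    for (cls in config$lipid_classes) {
      grp <- NULL
      for (g in names(lip_groups)) {
        cl <- traj$system$atoms$lipid_class[resolved[[g]]]
        if (all(cl == cls)) { grp <- g; break }
      }
      if (is.null(grp)) next
      grid <- lipid_heatmap(traj, resolved[[grp]], headgroup_idx = hg,
                            bin_width = config$bin_width,
                            recenter = config$recenter)
      grid$overlay <- overlay[, c("label", "x", "y")]
      f <- file.path(out, paste0("heatmap_", cls, ".txt"))
      write_grid(grid, f); add_output("heatmap", f, sum(grid$counts))
    }
  })

  # --- qc -------------------------------------------------------------
  stage("qc", {
    comp_qc <- .composition_from_config(config, comp)
    qc <- rmsd_series(traj)
    names(qc) <- c("time", "rmsd")
    if (!is.null(comp_qc)) {
      apl <- area_per_lipid(traj, comp_qc)
      qc$apl_upper <- apl$upper
      qc$apl_lower <- apl$lower
    }
    f <- file.path(out, "qc.csv")
    write_table(qc, f); add_output("qc", f, nrow(qc))
    dep <- utils::read.csv(file.path(out, "depth.csv"))
    span <- diff(range(dep$time))
    if (span > config$qc_window_ns) {
      st <- stability_check(dep$depth, dep$time,
                            window_ns = config$qc_window_ns,
                            tolerance = config$qc_tolerance)
      manifest$stages$qc$depth_stability <- st
    }
  })

  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(config[sort(names(config))], cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
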