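## default pipeline configuration; user configs are validated against this
## template (unknown keys rejected)
default_pipeline_config <- function() {
  list(
    seed = 1,
    out_dir = "emegfem_run",
    phantom = list(radii = c(92, 84, 72, 66),
                   tissues = c("scalp", "skull", "csf", "gm"),
                   conductivities = c(0.43, 0.0033, 1.79, 0.33),
                   voxel_size = 5, shape = c(40, 40, 40),
                   n_eeg = 32, n_meg = 64, meg_standoff = 25,
                   meg_type = "magnetometer", baseline = 50),
    mesh = list(node_shift_factor = 0.33, source_spacing = 10),
    forward = list(tol = 1e-9),
    ied = list(onset_position = c(-35, 15, 20), onset_moment = c(30, 20, 30),
               peak_position = c(38, -12, 18), peak_moment = c(20, -35, 25),
               delay = 23, n_trials = 10, snr_eeg = 5, snr_meg = 5),
    inverse = list(threshold_fraction = 0.85, analysis_latencies = c(-7, -23),
                   min_cluster_size = 5, roi_extents = c(160, 82, 28)),
    modalities = c("eeg", "meg")
  )
}

validate_config <- function(config, template = default_pipeline_config()) {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown))
    stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      bad <- setdiff(names(config[[nm]]), names(template[[nm]]))
      if (length(bad))
        stopf("unknown config key(s) in '%s': %s", nm, paste(bad, collapse = ", "))
      template[[nm]] <- modifyList(template[[nm]], config[[nm]])
    } else template[[nm]] <- config[[nm]]
  }
  template
}

#' Run the full phantom-to-ROI pipeline
#'
#' Executes phantom generation, meshing, forward modeling, interictal
#' discharge simulation, combined-modality sLORETA localization at the
#' configured latencies, and ROI-cuboid export, persisting every
#' intermediate artifact with content hashes into a run manifest. Reruns
#' with the same configuration and seed are bit-identical for the
#' deterministic stages.
#'
#' @param config nested configuration list, or path to a YAML file; see
#'   `emegfem:::default_pipeline_config()` for the schema and defaults.
#' @return The run manifest (list), invisibly; artifacts and
#'   `manifest.json` are written under `config$out_dir`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg, stages = list())
  t_all <- proc.time()[3]
  artifact <- function(name, obj, writer = write_container, file = paste0(name, ".rds")) {
    path <- file.path(cfg$out_dir, file)
    writer(obj, path)
    list(file = file, md5 = unname(tools::md5sum(path)))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- c(res$meta %||% list(),
                                  list(seconds = round(proc.time()[3] - t0, 2)))
    res$value
  }

  ph <- stage("phantom", {
    spec <- sphere_spec(radii = cfg$phantom$radii, tissues = cfg$phantom$tissues,
                        conductivities = cfg$phantom$conductivities)
    grid <- voxelize_sphere_model(spec, cfg$phantom$voxel_size, cfg$phantom$shape)
    sensors <- make_sensor_array(spec, cfg$phantom$n_eeg, cfg$phantom$n_meg,
                                 cfg$phantom$meg_standoff, cfg$phantom$meg_type,
                                 cfg$phantom$baseline)
    list(value = list(spec = spec, grid = grid, sensors = sensors),
         meta = list(grid = artifact("grid", grid, write_labeled_grid, "grid.nii"),
                     sensors = artifact("sensors", sensors, write_sensor_array,
                                        "sensors.txt")))
  })

  msh <- stage("mesh", {
    mesh <- build_hex_mesh(ph$grid, cfg$mesh$node_shift_factor)
    tab <- ph$spec$shells$conductivity
    names(tab) <- as.character(ph$spec$shells$label)
    mesh <- assign_conductivities(mesh, tab)
    gm_label <- ph$spec$shells$label[nrow(ph$spec$shells)]
    src <- build_source_space(mesh, gm_label, cfg$mesh$source_spacing)
    list(value = list(mesh = mesh, src = src),
         meta = list(mesh = artifact("mesh", mesh[c("nodes", "elements", "labels", "tensors")]),
                     source_space = artifact("source_space", src)))
  })

  fwd <- stage("forward", {
    K <- assemble_stiffness(msh$mesh)
    te <- if ("eeg" %in% cfg$modalities)
      eeg_transfer(K, ph$sensors, msh$mesh, tol = cfg$forward$tol) else NULL
    tm <- if ("meg" %in% cfg$modalities)
      meg_transfer(K, ph$sensors, msh$mesh, tol = cfg$forward$tol) else NULL
    lf <- compute_leadfields(te, tm, msh$src, msh$mesh)
    list(value = lf,
         meta = list(leadfields = artifact("leadfields",
                                           lf[c("L", "modality", "channel_names", "units")])))
  })

  ied <- stage("ied", {
    cfgi <- cfg$ied
    simcfg <- spike_sim_config(
      dipole_source(cfgi$onset_position, cfgi$onset_moment),
      dipole_source(cfgi$peak_position, cfgi$peak_moment),
      delay = cfgi$delay, n_trials = cfgi$n_trials,
      snr_eeg = cfgi$snr_eeg, snr_meg = cfgi$snr_meg, seed = cfg$seed)
    trials <- simulate_ied_recordings(fwd, simcfg)
    ev <- average_spikes(trials)
    list(value = list(trials = trials, evoked = ev),
         meta = list(evoked = artifact("evoked",
                                       ev[c("data", "channel_meta", "sampling_rate", "time_zero")])))
  })

  loc <- stage("localize", {
    parts <- list()
    sel_e <- ied$evoked$channel_meta$modality == "eeg"
    split_ev <- function(sel) evoked_data(ied$evoked$data[sel, , drop = FALSE],
                                          ied$evoked$channel_meta[sel, ],
                                          ied$evoked$sampling_rate, ied$evoked$time_zero)
    if ("eeg" %in% cfg$modalities) parts$eeg <- split_ev(sel_e)
    if ("meg" %in% cfg$modalities) parts$meg <- split_ev(!sel_e)
    joint <- combine_emeg(eeg = parts$eeg, meg = parts$meg,
                          eeg_lf = if (!is.null(parts$eeg)) subset_leadfield(fwd, "eeg"),
                          meg_lf = if (!is.null(parts$meg)) subset_leadfield(fwd, "meg"))
    icfg <- inverse_config(threshold_fraction = cfg$inverse$threshold_fraction,
                           analysis_latencies = cfg$inverse$analysis_latencies,
                           min_cluster_size = cfg$inverse$min_cluster_size)
    ests <- lapply(cfg$inverse$analysis_latencies, function(lat) {
      est <- sloreta(joint$leadfield, evoked_topography(joint$evoked, lat),
                     icfg, latency = lat)
      threshold_clusters(est, icfg)
    })
    meta <- list()
    for (i in seq_along(ests))
      meta[[sprintf("clusters_%dms", round(cfg$inverse$analysis_latencies[i]))]] <-
        artifact(sprintf("clusters_%d", i), ests[[i]], write_cluster_report,
                 sprintf("clusters_%dms.tsv", round(cfg$inverse$analysis_latencies[i])))
    list(value = ests, meta = meta)
  })

  rois <- stage("roi", {
    boxes <- list()
    for (est in loc)
      if (length(est$clusters))
        boxes[[length(boxes) + 1]] <- roi_box(est$clusters[[1]]$peak_position,
                                              cfg$inverse$roi_extents)
    list(value = boxes,
         meta = list(roi = artifact("roi", boxes, write_roi_boxes, "roi_boxes.tsv")))
  })

  manifest$n_roi <- length(rois)
  manifest$total_seconds <- round(proc.time()[3] - t_all, 2)
  manifest$estimates <- lapply(loc, function(e)
    list(latency = e$latency, modality = e$modality_set,
         n_clusters = length(e$clusters),
         max_f = max(e$f)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Generate the canonical test fixture bundle
#'
#' Builds the phantom, sensors, leadfields and simulated recordings used by
#' the test suite, at two sizes: `"small"` (coarse mesh, quick) and
#' `"medium"` (finer mesh). The bundle regenerates bit-identically from the
#' seed; a manifest lists every file with its hash.
#'
#' @param size `"small"` or `"medium"`.
#' @param seed RNG seed.
#' @param out_dir output directory.
#' @return manifest list, invisibly.
#' @export
generate_fixtures <- function(size = c("small", "medium"), seed = 1,
                              out_dir = tempfile("fixtures")) {
  size <- match.arg(size)
  cfg <- list(seed = seed, out_dir = out_dir)
  if (size == "medium")
    cfg$phantom <- list(voxel_size = 4, shape = c(50, 50, 50), n_eeg = 48, n_meg = 96)
  run_pipeline(cfg)
}
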