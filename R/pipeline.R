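#' Default pipeline configuration
#'
#' Nested list mirroring the YAML configuration file: sections `filters`,
#' `aorta`, `clustering`, `cleaning`, `geometry`, `blood`, `wall`,
#' `windkessel`, `inflow`, `solver`, `crop`, `window` and `seed`.  Any
#' subset can be overridden from a YAML file ([read_config()]); values not
#' mentioned keep these defaults.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    window = c(0, 255),
    crop = list(enabled = FALSE, fractions = c(0.2, 0.8, 0.2, 0.8, 0, 1)),
    filters = list(nlm_strength = 2, nlm_template = 5, nlm_search = 7,
                   frangi_alpha = 0.5, frangi_beta = 0.5, frangi_gamma = 15,
                   frangi_scales = 1:6, frangi_cutoff = 0.05,
                   area_threshold = 900,
                   grey_thresholds = seq(125, 145, by = 5)),
    aorta = list(slice_range = 5:9, r_min = 25, r_max = 60,
                 canny = c(50, 150), min_support = 0.3),
    clustering = list(eps = 1.6, min_pts = 2),
    cleaning = list(root_eps = 7, root_min_pts = 700,
                    vessel_eps = 1.5, vessel_min_pts = 3),
    geometry = list(spacing = 0.01, trim_nodes = 5, smooth_sigma = NULL,
                    prune_spurs = 6, surface_sigma = 0.8,
                    min_terminal = 0.2),
    blood = list(rho = 1.06, mu = 0.04),
    wall = list(k1 = 2e7, k2 = -22.53, k3 = 8.65e5,
                P0_mmHg = 280 / 3, Pext_mmHg = 0, b = 2, Gamma = 0),
    windkessel = list(diastolic = 80, systolic = 120,
                      Qcor_left = 2.5, Qcor_right = 1.2,
                      murray_power = 2.27,
                      C1_total = 5e-7, C2_total = 5e-6,
                      Pven = 5, plv_scale_left = 0.5, plv_scale_right = 0.2),
    inflow = list(period = 0.8, waveform_csv = NULL),
    solver = list(dt = 1e-4, cycles = 5, newton_tol = 1e-8,
                  periodicity_tol = 0.005, mode = "pulsatile")
  )
}

#' Read a YAML configuration file
#'
#' @param path YAML file; sections as in [default_config()].
#' @return configuration list with defaults filled in.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  modifyList(cfg, user)
}

cfg_objects <- function(config) {
  f <- config$filters
  w <- config$wall
  list(
    filters = filter_params(nlm_strength = f$nlm_strength,
                            nlm_template = f$nlm_template,
                            nlm_search = f$nlm_search,
                            frangi_alpha = f$frangi_alpha,
                            frangi_beta = f$frangi_beta,
                            frangi_gamma = f$frangi_gamma,
                            frangi_scales = f$frangi_scales,
                            frangi_cutoff = f$frangi_cutoff,
                            area_threshold = f$area_threshold,
                            grey_thresholds = f$grey_thresholds),
    cluster = cluster_params(config$clustering$eps, config$clustering$min_pts),
    blood = blood_properties(config$blood$rho, config$blood$mu),
    wall = wall_law(k1 = w$k1, k2 = w$k2, k3 = w$k3,
                    P0 = mmHg_to_dyn(w$P0_mmHg),
                    Pext = mmHg_to_dyn(w$Pext_mmHg),
                    b = w$b, Gamma = w$Gamma,
                    Pcollapse = if (!is.null(w$Pcollapse_mmHg))
                      mmHg_to_dyn(w$Pcollapse_mmHg) else NULL),
    targets = perfusion_targets(config$windkessel$diastolic,
                                config$windkessel$systolic,
                                config$windkessel$Qcor_left,
                                config$windkessel$Qcor_right))
}

#' Run the full CT-to-cFFR pipeline
#'
#' Executes, in order: volume input (DICOM directory or in-memory volume),
#' optional crop and windowing, the per-slice filtering chain, aortic
#' reference detection, multi-threshold DBSCAN segmentation, voxel-volume
#' cleaning, skeletonisation, branch splitting, surface extraction, radius
#' estimation, 1D meshing (per coronary side), the coupled 1D-0D solver,
#' and the cFFR evaluation.  A run manifest records per-stage status,
#' timings and artefact paths; the manifest is written even when a stage
#' fails.  The pipeline is deterministic for fixed input, configuration
#' and seed.
#'
#' @param input a directory of DICOM slices or an [image_volume()].
#' @param config configuration list (see [default_config()]).
#' @param out_dir optional directory for stage artefacts and the manifest.
#' @param location optional cFFR query point passed to [compute_cffr()];
#'   default is the node of minimum lumen radius of each side.
#' @param sides which coronary sides to solve (default both).
#' @return list with `results` (per side: `ffr_solution` and `cffr_result`),
#'   `mesh` (per side), `tree`, `segmentation`, `reference`, `manifest`.
#' @export
run_pipeline <- function(input, config = default_config(), out_dir = NULL,
                         location = NULL, sides = c("left", "right")) {
  set.seed(as.integer(config$seed))
  manifest <- list(software = "autoffr",
                   version = as.character(utils::packageVersion("autoffr")),
                   seed = config$seed,
                   input = if (is.character(input)) input else "<in-memory volume>",
                   config = config, stages = list())
  t_all <- proc.time()[3]
  artefacts <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  record <- function(stage, status, t0, output = NULL, error = NULL) {
    manifest$stages[[stage]] <<- list(
      status = status, seconds = round(proc.time()[3] - t0, 2),
      output = output, error = error)
    if (!is.null(out_dir))
      jsonlite::write_json(manifest[names(manifest) != "config"],
                           file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, null = "null", digits = NA)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      record(name, "failed", t0, error = conditionMessage(res))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(res)), call. = FALSE)
    }
    record(name, "ok", t0)
    res
  }
  obj <- cfg_objects(config)

  vol <- stage("input", {
    v <- if (is.character(input)) read_dicom_series(input, config$window)
         else normalize_volume(input, config$window)
    if (isTRUE(config$crop$enabled)) {
      v <- crop_cardiac_region(v, matrix(config$crop$fractions, nrow = 2))
    }
    v
  })
  pre <- stage("image_pre", preprocess_volume(vol, obj$filters))
  ref <- stage("aorta_ref", detect_aorta_center(
    vol, config$aorta$slice_range, config$aorta$r_min, config$aorta$r_max,
    config$aorta$canny, config$aorta$min_support))
  seg <- stage("coronary_cluster",
               segment_coronary(vol, obj$filters, obj$cluster, ref, pre = pre))

  sides <- match.arg(sides, several.ok = TRUE)
  side_masks <- attr(seg, "sides")
  results <- list()
  meshes <- list()
  trees <- list()
  refpt_world <- voxel_to_world(
    matrix(c(ref$center["row"], ref$center["col"], mean(ref$slices_used)),
           ncol = 3), vol$spacing, vol$origin)

  # regularisation strength scales with the measured image noise (no
  # smoothing of an already-clean mask), capped at 0.8 voxels
  sigma_reg <- if (is.null(config$geometry$smooth_sigma))
    min(0.8, 0.08 * stats::median(pre$sigma)) else config$geometry$smooth_sigma

  for (side in sides) {
    mask <- side_masks[[side]]
    cleaned <- stage(paste0("clean_", side), clean_voxel_volume(
      mask, config$cleaning$root_eps, config$cleaning$root_min_pts,
      config$cleaning$vessel_eps, config$cleaning$vessel_min_pts))
    cleaned <- stage(paste0("regularize_", side),
                     regularize_mask(cleaned, sigma_reg))
    skel <- stage(paste0("skeleton_", side), extract_skeleton(cleaned))
    tree <- stage(paste0("branches_", side),
                  split_branches(skel, config$geometry$prune_spurs))
    surf <- stage(paste0("surface_", side),
                  extract_surface(cleaned, config$geometry$surface_sigma))
    tree <- stage(paste0("radii_", side), estimate_radii(tree, surf))
    mesh <- stage(paste0("mesh_", side), build_mesh1d(
      tree, config$geometry$spacing, config$geometry$trim_nodes,
      root_point = refpt_world,
      min_terminal = config$geometry$min_terminal))
    trees[[side]] <- tree
    meshes[[side]] <- mesh

    sol <- stage(paste0("solve_", side), {
      Rcor <- total_resistance(obj$targets, side)
      plv <- default_plv_waveform(side,
        scale = if (side == "left") config$windkessel$plv_scale_left
                else config$windkessel$plv_scale_right,
        period = config$inflow$period)
      beds <- distribute_terminals(mesh, Rcor, config$windkessel$murray_power,
                                   obj$blood, obj$wall,
                                   config$windkessel$C1_total,
                                   config$windkessel$C2_total,
                                   config$windkessel$Pven, plv)
      mean_q <- if (side == "left") obj$targets$Qcor_left
                else obj$targets$Qcor_right
      inflow <- if (!is.null(config$inflow$waveform_csv)) {
        tab <- read.csv(config$inflow$waveform_csv)
        inflow_waveform(tab, config$inflow$period, side)
      } else if (identical(config$solver$mode, "steady")) mean_q
      else default_inflow_waveform(side, mean_q, config$inflow$period)
      scfg <- solver_config(dt = config$solver$dt,
                            cycles = config$solver$cycles,
                            newton_tol = config$solver$newton_tol,
                            periodicity_tol = config$solver$periodicity_tol)
      solve_1d0d(mesh, inflow, beds, obj$blood, obj$wall, scfg,
                 mode = config$solver$mode)
    })
    cffr <- stage(paste0("cffr_", side), compute_cffr(sol, location))
    results[[side]] <- list(solution = sol, cffr = cffr)
  }
  manifest$seconds_total <- round(proc.time()[3] - t_all, 2)
  out <- list(results = results, mesh = meshes, tree = trees,
              segmentation = seg, reference = ref, manifest = manifest)
  if (!is.null(out_dir)) write_outputs(out, out_dir)
  invisible(out)
}

#' Write pipeline outputs
#'
#' Persists the cFFR summary as JSON, the centreline with radii as CSV,
#' the centreline as an ASCII VTK polyline, the 1D meshes as JSON and a
#' plain-text log of the manifest.
#'
#' @param run result of [run_pipeline()].
#' @param out_dir output directory.
#' @param overwrite overwrite existing files (default TRUE).
#' @return invisibly, the written paths.
#' @export
write_outputs <- function(run, out_dir, overwrite = TRUE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(result = file.path(out_dir, "cffr.json"),
             centreline = file.path(out_dir, "centreline.csv"),
             vtk = file.path(out_dir, "centreline.vtk"),
             log = file.path(out_dir, "run.log"))
  if (!overwrite && any(file.exists(paths)))
    stop("output files exist and overwrite = FALSE: ",
         paste(paths[file.exists(paths)], collapse = ", "))
  res <- lapply(run$results, function(r)
    list(cffr = r$cffr$cffr, Pd_mean_mmHg = r$cffr$Pd_mean,
         Pa_mean_mmHg = r$cffr$Pa_mean, vessel = r$cffr$vessel,
         x_cm = r$cffr$x))
  jsonlite::write_json(res, paths["result"], auto_unbox = TRUE, digits = NA)
  tab <- centreline_table(run$tree)
  write.csv(tab, paths["centreline"], row.names = FALSE)
  write_vtk_polyline(run$tree, paths["vtk"])
  for (side in names(run$mesh))
    write_mesh1d_json(run$mesh[[side]],
                      file.path(out_dir, sprintf("mesh_%s.json", side)))
  writeLines(c(sprintf("autoffr run, seed %s", run$manifest$seed),
               vapply(names(run$manifest$stages), function(s)
                 sprintf("%-20s %-7s %8.2fs %s", s,
                         run$manifest$stages[[s]]$status,
                         run$manifest$stages[[s]]$seconds,
                         if (!is.null(run$manifest$stages[[s]]$error))
                           run$manifest$stages[[s]]$error else ""),
                 character(1))),
             paths["log"])
  invisible(paths)
}

centreline_table <- function(trees) {
  do.call(rbind, lapply(names(trees), function(side) {
    tree <- trees[[side]]
    do.call(rbind, lapply(seq_along(tree$branches), function(b) {
      br <- tree$branches[[b]]
      if (!nrow(br$points)) return(NULL)
      data.frame(side = side, branch_id = b,
                 x_mm = br$points[, 1], y_mm = br$points[, 2],
                 z_mm = br$points[, 3],
                 radius_mm = if (is.null(br$radius)) NA_real_ else br$radius)
    }))
  }))
}

write_vtk_polyline <- function(trees, path) {
  pts <- list(); lines <- list(); off <- 0L
  for (side in names(trees)) {
    for (br in trees[[side]]$branches) {
      n <- nrow(br$points)
      if (!n) next
      pts[[length(pts) + 1L]] <- br$points
      lines[[length(lines) + 1L]] <- c(n, off + 0:(n - 1))
      off <- off + n
    }
  }
  allp <- do.call(rbind, pts)
  con <- file(path, "w")
  writeLines(c("# vtk DataFile Version 3.0", "autoffr centreline", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(allp))), con)
  writeLines(apply(allp, 1, function(p) paste(format(p), collapse = " ")), con)
  total <- sum(vapply(lines, length, integer(1)))
  writeLines(sprintf("LINES %d %d", length(lines), total), con)
  for (l in lines) writeLines(paste(l, collapse = " "), con)
  close(con)
  invisible(path)
}
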