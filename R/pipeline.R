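#' Run configuration for the end-to-end pipeline
#'
#' Validates and normalises a pipeline configuration, either given as a
#' named list or loaded from a YAML file.  Recognised fields:
#' `segmentations` (character vector of motion-grid CSV paths),
#' `ct_wall` / `ct_calcification` (point-cloud paths, optional),
#' `n_heights`, `m_circ` (homogeneous grid dims), `coverage_threshold`,
#' `capture_radius`, `min_patch_elements`, registration `bounds`
#' (`rot_deg`, `trans_mm`, `scale`, `shear`), `seed`, `out_dir`.
#'
#' @param config named list or path to a YAML file.
#' @return validated config list (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$segmentations) || !length(config$segmentations))
    stop("config needs at least one segmentation path")
  defaults <- list(n_heights = NULL, m_circ = 36L, coverage_threshold = 0.5,
                   capture_radius = NULL, min_patch_elements = 1L,
                   seed = 1L, out_dir = NULL,
                   bounds = list(rot_deg = 30, trans_mm = 20,
                                 scale = c(0.8, 1.2), shear = 0.2))
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  structure(config, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow on one acquisition: read all
#' segmentations, build the averaged model, compute strain amplitudes for
#' the averaged model and every single segmentation, rigidly register each
#' geometry to the CT wall cloud over all frames (geometry comparison;
#' best/worst segmentation by rigid RMSE), affinely register the averaged
#' model for calcification mapping, classify elements against the
#' calcification cloud, compute distribution indices and the one-sided
#' Mann-Whitney comparison.  When no CT clouds are configured the
#' registration, classification and comparison stages are marked skipped.
#'
#' @param config a [run_config()] (list or YAML path accepted).
#' @return the run manifest (list); artifacts and `manifest.json` are
#'   written to `out_dir` when configured.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  manifest <- list(package_version = as.character(utils::packageVersion("aaastrain")),
                   config = unclass(config), stages = list())
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  persist <- function(obj, name) {
    if (!is.null(out_dir))
      jsonlite::write_json(obj, file.path(out_dir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA, na = "null")
  }
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "failed",
                                      error = conditionMessage(err))
    persist(manifest, "manifest")
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) fail(stage, e))
    manifest$stages[[stage]] <<- list(status = "ok",
                                      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  segs <- timed("ingest", {
    lapply(seq_along(config$segmentations), function(k)
      read_motion_grid(config$segmentations[[k]],
                       segmentation_id = sprintf("seg%02d", k)))
  })
  avg <- timed("average", {
    average_segmentations(segs, n_H = config$n_heights, m_H = config$m_circ)
  })
  strains <- timed("strain", {
    amps_avg <- strain_amplitudes(strain_series(avg$model))
    amps_seg <- lapply(segs, function(s) strain_amplitudes(strain_series(s)))
    list(averaged = amps_avg, per_seg = amps_seg)
  })

  have_ct <- !is.null(config$ct_wall)
  bounds <- icp_bounds(config$bounds$rot_deg, config$bounds$trans_mm,
                       config$bounds$scale, config$bounds$shear)
  if (!have_ct) {
    for (st in c("register_rigid", "register_affine", "classify", "report"))
      manifest$stages[[st]] <- list(status = "skipped",
                                    reason = "no CT clouds configured")
    manifest$results <- list(
      averaged_amplitudes = summary_amps(strains$averaged))
    persist(manifest, "manifest")
    return(invisible(manifest))
  }

  wall <- read_point_cloud(config$ct_wall, "wall")
  calc <- if (!is.null(config$ct_calcification))
    read_point_cloud(config$ct_calcification, "calcification") else NULL

  rigid <- timed("register_rigid", {
    per_seg <- lapply(segs, select_best_frame, static = wall, mode = "rigid",
                      bounds = bounds)
    avg_reg <- select_best_frame(avg$model, wall, mode = "rigid",
                                 bounds = bounds)
    list(per_seg = per_seg, averaged = avg_reg)
  })
  seg_rmse <- vapply(rigid$per_seg, function(r) r$best$final_rmse, numeric(1))
  best_id <- which.min(seg_rmse)
  worst_id <- which.max(seg_rmse)

  affine <- timed("register_affine", {
    bf <- rigid$averaged$best_frame
    icp(frame_nodes(avg$model, bf), wall, "affine", bounds = bounds)
  })

  labels <- timed("classify", {
    bf <- rigid$averaged$best_frame
    nodes_reg <- apply_transform(affine$params, frame_nodes(avg$model, bf))
    ## default capture radius: wide enough to bridge the residual surface
    ## offset between the registered modalities, never below half the
    ## calcification point spacing
    capture <- config$capture_radius
    if (is.null(capture) && !is.null(calc))
      capture <- max(median_spacing(as.matrix(calc)) / 2,
                     median_spacing(as.matrix(wall)))
    classify_elements(build_quad_mesh(avg$model), nodes_reg, calc,
                      threshold = config$coverage_threshold,
                      capture_radius = capture,
                      min_patch_elements = config$min_patch_elements)
  })

  report <- timed("report", {
    make_region_report(strains, labels, best_id, worst_id)
  })

  manifest$results <- list(
    rigid_rmse_per_segmentation = seg_rmse,
    rigid_rmse_averaged = rigid$averaged$best$final_rmse,
    hausdorff_averaged = rigid$averaged$best$hausdorff$symmetric,
    best_segmentation = best_id, worst_segmentation = worst_id,
    best_frame_averaged = rigid$averaged$best_frame,
    affine_rmse = affine$final_rmse,
    n_calcified = sum(report$labels$calcified),
    n_non_calcified = sum(!report$labels$calcified),
    indices = report$indices, tests = report$tests)
  if (!is.null(out_dir)) {
    write.csv(report$labels, file.path(out_dir, "element_labels.csv"),
              row.names = FALSE)
    write.csv(report$indices, file.path(out_dir, "distribution_indices.csv"),
              row.names = FALSE)
  }
  persist(manifest, "manifest")
  invisible(manifest)
}

summary_amps <- function(amps) {
  keep <- !amps$degenerate
  list(mean_amp22_pct = 100 * mean(amps$amp22[keep]),
       mean_amp11_pct = 100 * mean(amps$amp11[keep]))
}

## distribution indices + Mann-Whitney comparison for the averaged model and
## the best / worst single segmentation (labels from the averaged mesh apply
## to single segmentations only when the meshes match; otherwise skipped)
make_region_report <- function(strains, labels, best_id, worst_id) {
  amp <- strains$averaged
  di <- distribution_indices(amp, labels)
  keep <- !amp$degenerate
  tests <- list()
  for (comp in c("11", "22")) {
    a <- amp[[paste0("amp", comp)]]
    calc <- a[keep & labels$calcified]
    nocalc <- a[keep & !labels$calcified]
    tests[[paste0("eps", comp)]] <-
      if (length(calc) && length(nocalc)) mannwhitney_left(calc, nocalc)
      else list(p_value = NA_real_, note = "empty region")
  }
  normality <- list()
  a22 <- amp$amp22[keep & labels$calcified]
  if (length(a22) >= 5L) normality$calcified_amp22 <- ks_normality(a22)
  a22n <- amp$amp22[keep & !labels$calcified]
  if (length(a22n) >= 5L) normality$non_calcified_amp22 <- ks_normality(a22n)
  list(indices = di, tests = tests, normality = normality, labels = labels,
       best_segmentation = best_id, worst_segmentation = worst_id)
}
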