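# End-to-end planning: load -> segment -> skeletonize -> tree -> path ->
# instructions -> export, with a provenance log of every parameter and
# per-stage diagnostics.

#' Planning configuration
#'
#' One flat, serializable record of every tunable parameter of the pipeline,
#' mirrored by the command-line flags. Stored as YAML by
#' [write_plan_config()] so a run's provenance is a single small artifact.
#'
#' @param scales_mm tubularity scales (mm).
#' @param tau appearance-map threshold, `"auto"` for per-volume Otsu.
#' @param grow_hu HU ceiling for seeded region growing.
#' @param spur_min_length_mm skeleton spur pruning threshold.
#' @param setback_mm,fov_deg virtual-camera parameters.
#' @param close_mm close-bifurcation flag distance.
#' @param merge_close merge close consecutive bifurcations into one step.
#' @param formats roadmap export formats.
#' @param seed RNG seed for seeded stages.
#' @return A `plan_config` list.
#' @export
plan_config <- function(scales_mm = c(0.5, 1, 2, 4, 8), tau = "auto",
                        grow_hu = -950, spur_min_length_mm = 3,
                        setback_mm = 5, fov_deg = 120, close_mm = 6,
                        merge_close = FALSE,
                        formats = c("json", "txt"), seed = 1L) {
  cfg <- list(scales_mm = scales_mm, tau = tau, grow_hu = grow_hu,
              spur_min_length_mm = spur_min_length_mm,
              setback_mm = setback_mm, fov_deg = fov_deg,
              close_mm = close_mm, merge_close = merge_close,
              formats = formats, seed = as.integer(seed))
  for (f in c("scales_mm", "spur_min_length_mm", "setback_mm", "fov_deg",
              "close_mm"))
    if (any(!is.numeric(cfg[[f]])) || any(cfg[[f]] < 0))
      stop(f, " must be non-negative numeric")
  structure(cfg, class = "plan_config")
}

#' @rdname plan_config
#' @param cfg a `plan_config`.
#' @param path YAML file.
#' @export
write_plan_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname plan_config
#' @export
read_plan_config <- function(path) {
  do.call(plan_config, yaml::read_yaml(path))
}

#' Run the full planning pipeline
#'
#' Executes load -> segment -> skeletonize -> tree -> plan -> encode ->
#' export. Any stage failure aborts with the stage name; a lesion outside
#' the volume bounds is rejected before any computation.
#'
#' @param volume a [ct_volume()] or a path loadable by [load_volume()].
#' @param lesion world-mm lesion point.
#' @param config a [plan_config()].
#' @param out_dir output directory; `NULL` skips all file output.
#' @param seed_voxel optional 0-based trachea voxel (skips auto-detection).
#' @return List with `mask`, `tree`, `path`, `roadmap`, `log` (per-stage
#'   provenance records) and `files`.
#' @export
run_plan <- function(volume, lesion, config = plan_config(), out_dir = NULL,
                     seed_voxel = NULL) {
  log <- list(config = unclass(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  vol <- stage("load",
    if (inherits(volume, "ct_volume")) volume else load_volume(volume))
  b <- volume_bounds(vol)
  if (any(lesion < b["lo", ]) || any(lesion > b["hi", ]))
    stop("lesion ", paste(round(lesion, 1), collapse = ", "),
         " outside volume bounds")
  log$load <- list(dim = dim(vol$voxels), spacing = vol$spacing)

  mask <- stage("segment",
    segment_airways(vol, scales_mm = config$scales_mm, tau = config$tau,
                    seed = seed_voxel, grow_hu = config$grow_hu))
  log$segment <- c(list(tau = mask$tau, seed = mask$seed), mask$diagnostics)

  tree <- stage("tree", {
    skel <- skeletonize(mask)
    graph <- build_skeleton_graph(skel)
    graph <- prune_spurs(graph, config$spur_min_length_mm)
    seed_world <- world_from_voxel(vol, mask$seed)
    direct_from_root(graph, seed_world)
  })
  log$tree <- list(n_nodes = nrow(tree$nodes),
                   n_leaves = sum(tree$nodes$kind == "leaf"),
                   max_level = max(tree$nodes$level),
                   discarded_edges = length(tree$diagnostics$discarded_edges))

  path <- stage("plan", {
    anchor <- closest_airway_point(tree, lesion)
    p <- root_path(tree, anchor)
    p$lesion <- lesion
    p
  })
  log$plan <- list(n_segments = length(path$segments),
                   gap_mm = path$anchor$gap_mm)

  roadmap <- stage("encode",
    encode_instructions(path, tree, setback_mm = config$setback_mm,
                        fov_deg = config$fov_deg, close_mm = config$close_mm,
                        merge_close = config$merge_close))
  log$encode <- list(n_instructions = length(roadmap$instructions))

  files <- character(0)
  if (!is.null(out_dir)) {
    stage("export", {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      f_mask <- file.path(out_dir, "mask.nii.gz")
      write_volume(array(as.integer(mask$mask), dim(mask$mask)), f_mask,
                   affine = mask$affine, datatype = "uint8")
      f_tree <- file.path(out_dir, "tree.json")
      write_tree_json(tree, f_tree)
      f_path <- file.path(out_dir, "path.json")
      write_path_json(path, f_path)
      f_rm <- export_roadmap(roadmap, out_dir, formats = config$formats,
                             allow_empty = TRUE)
      f_log <- file.path(out_dir, "provenance.json")
      jsonlite::write_json(log, f_log, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
      files <<- c(f_mask, f_tree, f_path, f_rm, f_log)
    })
  }
  list(mask = mask, tree = tree, path = path, roadmap = roadmap,
       log = log, files = files)
}

#' Phantom demonstration run
#'
#' Generates a phantom CT, plants a lesion near a random leaf, runs the full
#' pipeline, and writes every artifact (volume, ground truth, mask, tree,
#' path, roadmap, provenance).
#'
#' @param seed phantom + lesion RNG seed.
#' @param out_dir output directory; `NULL` for in-memory only.
#' @param levels phantom generations.
#' @param shape,spacing phantom grid.
#' @param noise_sd additive noise (HU).
#' @param plane_mode branching-plane convention, see
#'   [generate_phantom_spec()].
#' @param config a [plan_config()].
#' @return The [run_plan()] result plus `spec`, `truth`, `lesion`,
#'   `true_leaf` (the planted lesion's nearest ground-truth leaf node id).
#' @export
run_phantom_demo <- function(seed = 1L, out_dir = NULL, levels = 4L,
                             shape = c(128L, 128L, 128L), spacing = c(1, 1, 1),
                             noise_sd = 0, plane_mode = "camera",
                             config = plan_config(seed = seed)) {
  hu <- phantom_hu_model(noise_sd = noise_sd)
  spec <- generate_phantom_spec(levels, seed = seed, hu_model = hu,
                                plane_mode = plane_mode)
  vol <- rasterize_phantom(spec, shape, spacing)
  truth <- truth_tree(spec)
  leaves <- truth$nodes[truth$nodes$kind == "leaf", ]
  pick <- with_seed(seed + 1000L, {
    i <- sample(nrow(leaves), 1L)
    offset <- stats::rnorm(3)
    list(i = i, offset = offset / vnorm(offset) * 2)
  })
  leaf <- leaves[pick$i, ]
  lesion <- c(leaf$x, leaf$y, leaf$z) + pick$offset
  res <- run_plan(vol, lesion, config = config, out_dir = out_dir)
  if (!is.null(out_dir)) {
    write_volume(vol, file.path(out_dir, "volume.nii.gz"))
    write_tree_json(truth, file.path(out_dir, "truth.json"))
    res$files <- c(res$files, file.path(out_dir, c("volume.nii.gz",
                                                   "truth.json")))
  }
  res$spec <- spec
  res$truth <- truth
  res$lesion <- lesion
  res$true_leaf <- leaf$id
  res
}

#' Centerline accuracy of an extracted tree against a phantom spec
#'
#' Root-mean-square distance from every polyline point of the extracted tree
#' to the nearest ground-truth branch axis.
#'
#' @param tree an extracted `airway_tree`.
#' @param spec the generating [generate_phantom_spec()].
#' @return RMS distance in mm.
#' @export
centerline_rms <- function(tree, spec) {
  seg <- phantom_segments(spec)[, 1:6, drop = FALSE]
  pts <- do.call(rbind, lapply(which(!is.na(tree$nodes$parent)), function(ch) {
    tree$segments[[tree$nodes$parent[ch], ch]]
  }))
  d <- cpp_min_dist_to_segments(pts, seg)
  sqrt(mean(d^2))
}
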