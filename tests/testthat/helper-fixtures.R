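# Shared fixtures, cached per test session (several files reuse the same
# segmented phantom; segmentation at 128^3 is the expensive step).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# levels-3 world-alternating phantom, rasterized and segmented
fix_segmented_phantom <- function() {
  cached("seg3", {
    spec <- generate_phantom_spec(3, seed = 2)
    vol <- rasterize_phantom(spec)
    mask <- segment_airways(vol)
    list(spec = spec, vol = vol, mask = mask,
         truth = truth_tree(spec),
         truth_lumen = phantom_lumen_mask(spec))
  })
}

# extracted airway tree of the same phantom
fix_extracted_tree <- function() {
  cached("tree3", {
    fx <- fix_segmented_phantom()
    skel <- skeletonize(fx$mask)
    graph <- prune_spurs(build_skeleton_graph(skel), 3)
    tree <- direct_from_root(graph,
                             world_from_voxel(fx$vol, fx$mask$seed))
    list(skel = skel, graph = graph, tree = tree)
  })
}

# camera-alternating truth tree for instruction tests (no rasterization)
fix_camera_truth <- function(levels = 5, seed = 3) {
  cached(paste0("cam", levels, "_", seed),
         truth_tree(generate_phantom_spec(levels, seed = seed,
                                          plane_mode = "camera",
                                          jitter_sd = 0)))
}

# straight-tube mask along z
fix_tube_mask <- function(dims = c(33L, 33L, 60L), r = 4, k0 = 10, k1 = 50,
                          center = c(16, 16)) {
  idx <- expand.grid(i = 0:(dims[1] - 1), j = 0:(dims[2] - 1),
                     k = 0:(dims[3] - 1))
  array((idx$i - center[1])^2 + (idx$j - center[2])^2 <= r^2 &
          idx$k >= k0 & idx$k < k1, dim = dims)
}

# brute-force closest-anchor oracle: plain double loop over edges and points
brute_force_anchor <- function(tree, lesion) {
  best <- NULL
  for (ch in sort(which(!is.na(tree$nodes$parent)))) {
    par <- tree$nodes$parent[ch]
    poly <- tree$segments[[par, ch]]
    for (i in seq_len(nrow(poly))) {
      d <- sqrt(sum((poly[i, ] - lesion)^2))
      if (is.null(best) || d < best$d - 1e-12) {
        best <- list(d = d, edge = c(par, ch), index = i)
      }
    }
  }
  best
}

# brute-force quadrant oracle: count per-point memberships one at a time
brute_force_quadrant <- function(pts, distal) {
  counts <- c(I = 0L, II = 0L, III = 0L, IV = 0L)
  one <- function(x, y) {
    if (x >= 0 && y >= 0) "I" else if (x < 0 && y >= 0) "II"
    else if (x < 0 && y < 0) "III" else "IV"
  }
  for (i in seq_len(nrow(pts)))
    counts[one(pts[i, 1], pts[i, 2])] <- counts[one(pts[i, 1], pts[i, 2])] + 1L
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) top else one(distal[1], distal[2])
}

# synthetic projected_segment for label tests
proj_stub <- function(pts, child_id = NA_integer_) {
  pts <- matrix(pts, ncol = 2)
  colnames(pts) <- c("x", "y")
  p <- structure(list(child_id = child_id, points2d = pts,
                      n_dropped = 0L, distal_point2d = pts[nrow(pts), ],
                      mean_angle_deg = atan2(mean(pts[, 2]),
                                             mean(pts[, 1])) * 180 / pi),
                 class = "projected_segment")
  p$quadrant_counts <- bronchonav:::quadrant_counts(pts)
  p$quadrant <- assign_quadrant(p)
  p
}

gen_dicom_fixture <- function(mode) {
  dir <- tempfile(paste0("dcm_", mode, "_"))
  dir.create(dir)
  status <- system2("python",
                    c(shQuote(test_path("gen-dicom.py")), shQuote(dir), mode),
                    stdout = FALSE, stderr = FALSE)
  if (!identical(status, 0L)) stop("pydicom fixture generation failed")
  dir
}
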