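# Synthetic branching-airway phantoms with exact ground truth.
#
# A phantom is a recursive binary tree of straight capsule branches: dark
# lumen (air), bright wall, parenchyma-like background, optional Gaussian
# noise. It stands in for patient CT in every test of the pipeline.

#' Default HU model for phantom rasterization
#'
#' Air-filled lumen at -1000 HU, soft-tissue-like wall at -100 HU on a
#' parenchyma background of -850 HU; all values within the plausible CT
#' range.
#'
#' @param lumen,wall,background tissue intensities (HU).
#' @param wall_thickness_mm airway wall thickness.
#' @param noise_sd additive Gaussian noise standard deviation (HU).
#' @export
phantom_hu_model <- function(lumen = -1000, wall = -100, background = -850,
                             wall_thickness_mm = 2, noise_sd = 0) {
  list(lumen = lumen, wall = wall, background = background,
       wall_thickness_mm = wall_thickness_mm, noise_sd = noise_sd)
}

# Camera frame shared with the instruction encoder: given a view direction,
# "up" is the patient-superior axis orthogonalized against it (anterior-axis
# fallback when nearly parallel) and "right" completes the frame.
camera_frame_axes <- function(view_dir) {
  v <- normalize(view_dir)
  ref <- if (abs(sum(v * AXIS_SUPERIOR)) > 0.99) AXIS_ANTERIOR else AXIS_SUPERIOR
  up <- normalize(ref - sum(ref * v) * v)
  list(view = v, up = up, right = cross3(v, up))
}

#' Generate a synthetic airway-tree specification
#'
#' Builds a recursive binary tree of straight branches: the trachea plus
#' `levels - 1` further generations (2^levels - 1 branches). Children rotate
#' off the parent direction by `±branch_angle_deg` within a branching plane
#' that alternates per generation, plus angular jitter. Geometry defaults are
#' anatomically plausible at a 128^3 mm-resolution grid.
#'
#' @param levels number of branch generations (>= 1; 1 = trachea only).
#' @param branch_angle_deg half-angle between each child and the parent axis.
#' @param length_ratio,radius_ratio child-to-parent scale factors.
#' @param jitter_sd angular jitter standard deviation in degrees.
#' @param seed RNG seed; identical (parameters, seed) pairs give bit-identical
#'   specs and noise fields.
#' @param trachea_length_mm,trachea_radius_mm root branch geometry.
#' @param root_start,root_dir trachea origin (world mm) and unit direction;
#'   the default runs inferior from near the grid top of a 128 mm cube.
#' @param hu_model see [phantom_hu_model()].
#' @param plane_mode `"world"` alternates branching planes between the
#'   patient x (coronal-ish) and y (sagittal-ish) axes; `"camera"` alternates
#'   between the right and up axes of an endoluminal camera aligned with the
#'   parent branch, so that sibling separations alternate exactly between the
#'   camera's horizontal and vertical image axes.
#' @param close_bifurcation optional `list(level =, length_mm =)`: the first
#'   branch of that generation is shortened to `length_mm`, placing its
#'   distal bifurcation abnormally close to its parent bifurcation (the
#'   three-lumen projection condition).
#' @return An object of class `phantom_tree`: `branches` data frame (id,
#'   parent, level, start, unit direction, length, radius), `hu_model`,
#'   `params`, `seed`.
#' @export
generate_phantom_spec <- function(levels,
                                  branch_angle_deg = 35,
                                  length_ratio = 0.75,
                                  radius_ratio = 0.79,
                                  jitter_sd = 3,
                                  seed = 1L,
                                  trachea_length_mm = 40,
                                  trachea_radius_mm = 8,
                                  root_start = c(64, 64, 120),
                                  root_dir = c(0, 0, -1),
                                  hu_model = phantom_hu_model(),
                                  plane_mode = c("world", "camera"),
                                  close_bifurcation = NULL) {
  stopifnot(levels >= 1, radius_ratio > 0, radius_ratio <= 1,
            length_ratio > 0, trachea_length_mm > 0, trachea_radius_mm > 0)
  plane_mode <- match.arg(plane_mode)
  root_dir <- normalize(root_dir)

  with_seed(seed, {
    br <- data.frame(id = 1L, parent = NA_integer_, level = 0L,
                     x0 = root_start[1], y0 = root_start[2], z0 = root_start[3],
                     dx = root_dir[1], dy = root_dir[2], dz = root_dir[3],
                     length_mm = trachea_length_mm,
                     radius_mm = trachea_radius_mm)
    if (levels > 1) {
      for (lev in seq_len(levels - 1L)) {
        parents <- br[br$level == lev - 1L, ]
        first_of_level <- TRUE
        for (p in seq_len(nrow(parents))) {
          par <- parents[p, ]
          pd <- c(par$dx, par$dy, par$dz)
          pstart <- c(par$x0, par$y0, par$z0) + par$length_mm * pd

          if (plane_mode == "world") {
            axis <- if (lev %% 2L == 1L) c(1, 0, 0) else c(0, 1, 0)
            u <- axis - sum(axis * pd) * pd
            if (vnorm(u) < 1e-6) {
              axis <- if (lev %% 2L == 1L) c(0, 1, 0) else c(1, 0, 0)
              u <- axis - sum(axis * pd) * pd
            }
            u <- normalize(u)
          } else {
            fr <- camera_frame_axes(pd)
            u <- if (lev %% 2L == 1L) fr$right else fr$up
          }

          theta <- branch_angle_deg * pi / 180
          for (sgn in c(1, -1)) {
            cd <- cos(theta) * pd + sgn * sin(theta) * u
            if (jitter_sd > 0) {
              pert <- stats::rnorm(3, 0, tan(jitter_sd * pi / 180))
              pert <- pert - sum(pert * cd) * cd
              cd <- normalize(cd + pert)
            }
            len <- par$length_mm * length_ratio
            if (!is.null(close_bifurcation) &&
                lev == close_bifurcation$level && first_of_level) {
              len <- close_bifurcation$length_mm
              first_of_level <- FALSE
            }
            br <- rbind(br, data.frame(
              id = nrow(br) + 1L, parent = par$id, level = lev,
              x0 = pstart[1], y0 = pstart[2], z0 = pstart[3],
              dx = cd[1], dy = cd[2], dz = cd[3],
              length_mm = len,
              radius_mm = par$radius_mm * radius_ratio))
          }
        }
      }
    }
    structure(list(
      branches = br,
      hu_model = hu_model,
      params = list(levels = levels, branch_angle_deg = branch_angle_deg,
                    length_ratio = length_ratio, radius_ratio = radius_ratio,
                    jitter_sd = jitter_sd, plane_mode = plane_mode,
                    close_bifurcation = close_bifurcation),
      seed = seed), class = "phantom_tree")
  })
}

#' @export
print.phantom_tree <- function(x, ...) {
  cat(sprintf("<phantom_tree> %d branches, %d levels, seed %d\n",
              nrow(x$branches), x$params$levels, x$seed))
  invisible(x)
}

phantom_segments <- function(spec) {
  b <- spec$branches
  cbind(b$x0, b$y0, b$z0,
        b$x0 + b$length_mm * b$dx,
        b$y0 + b$length_mm * b$dy,
        b$z0 + b$length_mm * b$dz,
        b$radius_mm,
        spec$hu_model$wall_thickness_mm)
}

#' Rasterize a phantom specification into a CT volume
#'
#' Voxels within a branch's lumen radius of its axis take the lumen HU, a
#' shell of the wall thickness takes the wall HU, everything else the
#' background HU; Gaussian noise (if any) is added last, seeded from the
#' spec, so the volume is deterministic. Branches thinner than one voxel at
#' the requested grid are dropped with a warning.
#'
#' @param spec a [generate_phantom_spec()] result.
#' @param shape grid dimensions.
#' @param spacing voxel spacing in mm (all > 0).
#' @return A [ct_volume()] with an axis-aligned affine (origin at world 0).
#' @export
rasterize_phantom <- function(spec, shape = c(128L, 128L, 128L),
                              spacing = c(1, 1, 1)) {
  if (any(spacing <= 0)) stop("spacing must be positive")
  seg <- phantom_segments(spec)
  thin <- seg[, 7] < max(spacing)
  if (any(thin)) {
    warning(sum(thin), " branch(es) thinner than one voxel truncated")
    seg <- seg[!thin, , drop = FALSE]
  }
  ext <- (shape - 1L) * spacing
  ends <- rbind(seg[, 1:3, drop = FALSE], seg[, 4:6, drop = FALSE])
  if (any(ends < 0) || any(t(ends) > ext))
    warning("phantom tree extends beyond the grid; branches truncated")
  lab <- cpp_rasterize_tubes(as.integer(shape), spacing, c(0, 0, 0), seg)
  hu <- spec$hu_model
  vox <- array(hu$background, dim = shape)
  vox[lab == 1L] <- hu$wall
  vox[lab == 2L] <- hu$lumen
  if (hu$noise_sd > 0)
    vox <- vox + with_seed(spec$seed,
      array(stats::rnorm(length(vox), 0, hu$noise_sd), dim = shape))
  affine <- diag(c(spacing, 1))
  ct_volume(vox, affine)
}

#' Ground-truth lumen mask of a phantom
#'
#' @param spec,shape,spacing as in [rasterize_phantom()].
#' @param min_radius_mm keep only branches at least this thick (useful for
#'   scoring segmentations on resolvable branches).
#' @return Logical 3D array, `TRUE` inside the lumen.
#' @export
phantom_lumen_mask <- function(spec, shape = c(128L, 128L, 128L),
                               spacing = c(1, 1, 1), min_radius_mm = 0) {
  seg <- phantom_segments(spec)
  seg <- seg[seg[, 7] >= min_radius_mm, , drop = FALSE]
  seg[, 8] <- 0
  lab <- cpp_rasterize_tubes(as.integer(shape), spacing, c(0, 0, 0), seg)
  array(lab == 2L, dim = shape)
}

#' Ground-truth airway tree of a phantom
#'
#' Builds the analytic [airway tree][airway_tree]: one node at the trachea
#' origin (root) and one at each branch endpoint (bifurcation or leaf), with
#' edge polylines sampling each branch axis.
#'
#' @param spec a [generate_phantom_spec()] result.
#' @param samples_per_mm polyline sampling density along each branch.
#' @return An `airway_tree` (see [direct_from_root()]).
#' @export
truth_tree <- function(spec, samples_per_mm = 1) {
  b <- spec$branches
  nb <- nrow(b)
  # node 1 = trachea origin; node (1 + branch id) = branch distal endpoint
  n_nodes <- nb + 1L
  pos <- matrix(0, n_nodes, 3L)
  pos[1L, ] <- c(b$x0[1], b$y0[1], b$z0[1])
  has_child <- b$id %in% b$parent
  kind <- character(n_nodes)
  kind[1L] <- "root"
  level <- integer(n_nodes)
  parent_node <- rep(NA_integer_, n_nodes)
  edges <- vector("list", nb)
  for (i in seq_len(nb)) {
    node <- i + 1L
    endp <- c(b$x0[i], b$y0[i], b$z0[i]) +
      b$length_mm[i] * c(b$dx[i], b$dy[i], b$dz[i])
    pos[node, ] <- endp
    kind[node] <- if (has_child[i]) "bifurcation" else "leaf"
    level[node] <- b$level[i] + 1L
    from <- if (is.na(b$parent[i])) 1L else b$parent[i] + 1L
    parent_node[node] <- from
    k <- max(2L, ceiling(b$length_mm[i] * samples_per_mm) + 1L)
    t <- seq(0, 1, length.out = k)
    poly <- cbind(b$x0[i] + t * (endp[1] - b$x0[i]),
                  b$y0[i] + t * (endp[2] - b$y0[i]),
                  b$z0[i] + t * (endp[3] - b$z0[i]))
    # first point = parent node position (branch start == parent endpoint)
    edges[[i]] <- list(from = from, to = node, polyline = poly)
  }
  nodes <- data.frame(id = seq_len(n_nodes),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      kind = kind, level = level, parent = parent_node,
                      stringsAsFactors = FALSE)
  new_airway_tree(nodes, edges, root_id = 1L)
}
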