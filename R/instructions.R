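# Quadrant-based navigation instructions.
#
# At each bifurcation along the navigation path, a virtual endoluminal camera
# is placed a few mm proximal to the bifurcation point, looking toward it.
# The child centerline segments are perspective-projected; each child is
# assigned the image quadrant holding most of its projected points
# (I = up-right, II = up-left, III = down-left, IV = down-right, centered at
# the projected bifurcation point). Dropping the word the two children share
# yields the simplified command ("go up", "go left", ...).

QUADRANT_LABELS <- c(I = "up-right", II = "up-left",
                     III = "down-left", IV = "down-right")
INSTRUCTION_TEXTS <- c("go up", "go down", "go left", "go right",
                       "go up-right", "go up-left", "go down-left",
                       "go down-right")

#' Virtual camera at a path bifurcation
#'
#' The camera sits `setback_mm` proximal to the bifurcation point (the distal
#' end of segment `S_d`), clamped to the segment start, and views toward it.
#' "Up" is the patient-superior axis orthogonalized against the view
#' direction, falling back to the patient-anterior axis when the view is
#' near-vertical (|view . superior| > 0.99); the projected bifurcation point
#' is the principal point (0, 0) by construction.
#'
#' @param path a [root_path()] result.
#' @param d segment level whose distal node is the bifurcation (1-based).
#' @param setback_mm camera distance proximal to the bifurcation.
#' @param fov_deg full field-of-view cone angle, in (0, 180).
#' @return An object of class `camera_pose`: `position`, `view_dir`, `up`,
#'   `right`, `fov_deg`, `principal_point`.
#' @export
bifurcation_camera <- function(path, d, setback_mm = 5, fov_deg = 120) {
  n <- length(path$segments)
  if (d < 1L || d > n) stop("no segment at level ", d)
  if (path$n_children[d + 1L] < 2L)
    stop("node at level ", d, " is not a bifurcation")
  if (fov_deg <= 0 || fov_deg >= 180) stop("fov_deg must be in (0, 180)")
  poly <- path$segments[[d]]
  p_bif <- poly[nrow(poly), ]

  # walk back along the polyline to the setback arc length (clamped)
  pos <- poly[1L, ]
  if (nrow(poly) >= 2L) {
    acc <- 0
    pos_found <- FALSE
    for (i in seq(nrow(poly) - 1L, 1L)) {
      step <- vnorm(poly[i, ] - poly[i + 1L, ])
      if (acc + step >= setback_mm) {
        t <- (setback_mm - acc) / step
        pos <- poly[i + 1L, ] + t * (poly[i, ] - poly[i + 1L, ])
        pos_found <- TRUE
        break
      }
      acc <- acc + step
    }
    if (!pos_found) pos <- poly[1L, ]
  }
  dv <- p_bif - pos
  view <- if (vnorm(dv) > 1e-9) normalize(dv)
          else normalize(poly[nrow(poly), ] - poly[max(1L, nrow(poly) - 1L), ])
  fr <- camera_frame_axes(view)
  structure(list(position = pos, view_dir = fr$view, up = fr$up,
                 right = fr$right, fov_deg = fov_deg,
                 principal_point = c(0, 0), bifurcation = p_bif),
            class = "camera_pose")
}

#' @export
print.camera_pose <- function(x, ...) {
  cat(sprintf("<camera_pose> at (%.1f, %.1f, %.1f), fov %.0f deg\n",
              x$position[1], x$position[2], x$position[3], x$fov_deg))
  invisible(x)
}

#' Project a child centerline segment through a camera
#'
#' Pinhole perspective projection onto the plane perpendicular to the view
#' direction: a point with camera coordinates (cx, cy, cz), cz > 0, maps to
#' (cx/cz, cy/cz) minus the principal point. Points behind the camera or
#' outside the field-of-view cone are dropped (and counted); if nothing
#' remains the segment is not visible, which signals a camera placement or
#' geometry problem.
#'
#' @param cam a [bifurcation_camera()] pose.
#' @param polyline k x 3 world-mm matrix of centerline points.
#' @param child_id node id carried along for reporting.
#' @return An object of class `projected_segment`: `points2d` (normalized
#'   image coordinates, x right / y up), `quadrant`, `quadrant_counts`,
#'   `mean_angle_deg`, `distal_point2d`, `n_dropped`, `child_id`.
#' @export
project_segment <- function(cam, polyline, child_id = NA_integer_) {
  if (is.null(dim(polyline)) || nrow(polyline) == 0L)
    stop("polyline is empty")
  rel <- sweep(polyline, 2L, cam$position)
  cx <- rel %*% cam$right
  cy <- rel %*% cam$up
  cz <- rel %*% cam$view_dir
  tanfov <- tan(cam$fov_deg / 2 * pi / 180)
  keep <- cz > 1e-9
  x <- cx[keep] / cz[keep]
  y <- cy[keep] / cz[keep]
  infov <- sqrt(x^2 + y^2) <= tanfov
  pts <- cbind(x = x[infov] - cam$principal_point[1],
               y = y[infov] - cam$principal_point[2])
  if (nrow(pts) == 0L)
    stop("segment not visible", if (!is.na(child_id))
      paste0(" (child node ", child_id, ")") else "")
  proj <- structure(list(child_id = child_id, points2d = pts,
                         n_dropped = nrow(polyline) - nrow(pts),
                         distal_point2d = pts[nrow(pts), ],
                         mean_angle_deg =
                           atan2(mean(pts[, 2]), mean(pts[, 1])) * 180 / pi),
                    class = "projected_segment")
  proj$quadrant_counts <- quadrant_counts(pts)
  proj$quadrant <- assign_quadrant(proj)
  proj
}

quadrant_of_points <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  ifelse(x >= 0 & y >= 0, "I",
         ifelse(x < 0 & y >= 0, "II",
                ifelse(x < 0, "III", "IV")))
}

quadrant_counts <- function(pts) {
  q <- factor(quadrant_of_points(pts), levels = c("I", "II", "III", "IV"))
  c(table(q))
}

#' Assign a projected segment to its majority quadrant
#'
#' Quadrants about the principal point are half-open: I (x >= 0, y >= 0),
#' II (x < 0, y >= 0), III (x < 0, y < 0), IV (x >= 0, y < 0). The quadrant
#' holding most projected points wins; ties break to the quadrant of the most
#' distal projected point (the direction actually steered toward).
#'
#' @param proj a [project_segment()] result (or any list with `points2d` and
#'   `distal_point2d`).
#' @return One of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
assign_quadrant <- function(proj) {
  if (nrow(proj$points2d) == 0L) stop("segment not visible")
  counts <- quadrant_counts(proj$points2d)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1L) return(top)
  quadrant_of_points(matrix(proj$distal_point2d, 1L))
}

#' @export
print.projected_segment <- function(x, ...) {
  cat(sprintf("<projected_segment> child %s: quadrant %s (counts %s)\n",
              x$child_id, x$quadrant,
              paste(sprintf("%s=%d", names(x$quadrant_counts),
                            x$quadrant_counts), collapse = " ")))
  invisible(x)
}

quadrant_half <- function(q) {
  list(vertical = ifelse(q %in% c("I", "II"), "up", "down"),
       horizontal = ifelse(q %in% c("I", "IV"), "right", "left"))
}

#' Simplified instruction pair for two sibling segments
#'
#' Each quadrant carries a two-word label (I up-right, II up-left, III
#' down-left, IV down-right); the word the two siblings share is dropped.
#' Siblings in different vertical halves give "go up" / "go down"; else, in
#' different horizontal halves, "go right" / "go left" (diagonal pairs use
#' the vertical rule). Siblings in the same quadrant are ordered by their
#' mean angle inside it and split along the axis of larger separation of
#' their mean projected points.
#'
#' @param onpath,sibling [project_segment()] results.
#' @return List with `onpath_text`, `sibling_text` and the full quadrant
#'   `onpath_label`, `sibling_label`.
#' @export
label_pair <- function(onpath, sibling) {
  qa <- onpath$quadrant; qb <- sibling$quadrant
  ha <- quadrant_half(qa); hb <- quadrant_half(qb)
  if (ha$vertical != hb$vertical) {
    ta <- paste("go", ha$vertical); tb <- paste("go", hb$vertical)
  } else if (ha$horizontal != hb$horizontal) {
    ta <- paste("go", ha$horizontal); tb <- paste("go", hb$horizontal)
  } else {
    ma <- colMeans(onpath$points2d)
    mb <- colMeans(sibling$points2d)
    dxy <- abs(ma - mb)
    if (dxy[1] > dxy[2]) {
      ta <- if (ma[1] >= mb[1]) "go right" else "go left"
      tb <- if (ma[1] >= mb[1]) "go left" else "go right"
    } else {
      ta <- if (ma[2] >= mb[2]) "go up" else "go down"
      tb <- if (ma[2] >= mb[2]) "go down" else "go up"
    }
  }
  list(onpath_text = ta, sibling_text = tb,
       onpath_label = unname(QUADRANT_LABELS[qa]),
       sibling_label = unname(QUADRANT_LABELS[qb]))
}

#' Encode a navigation path as an instruction roadmap
#'
#' Emits one instruction per internal bifurcation of the path (count =
#' number of segments - 1), ordered proximal to distal and enumerated by
#' bronchial level. Non-binary bifurcations are flagged and labeled by the
#' on-path child's full quadrant name. When the next path bifurcation lies
#' within `close_mm` of the current one the `close_levels` flag is set (two
#' branching levels may appear as three lumens in one projection); with
#' `merge_close = TRUE` such consecutive steps collapse into a single
#' instruction aimed at the on-path grandchild.
#'
#' @param path a [root_path()] result.
#' @param tree the `airway_tree` the path was planned in.
#' @param setback_mm,fov_deg camera parameters (see [bifurcation_camera()]).
#' @param close_mm distance threshold for the close-levels flag.
#' @param merge_close collapse close consecutive bifurcations into one step.
#' @return An object of class `roadmap`: `instructions` (list of level,
#'   node id, on-path child, labels, text, flags), `projections`
#'   (per-bifurcation camera + projected segments for rendering), `anchor`,
#'   `config`, `n_segments`.
#' @export
encode_instructions <- function(path, tree, setback_mm = 5, fov_deg = 120,
                                close_mm = 6, merge_close = FALSE) {
  n <- length(path$segments)
  instructions <- list()
  projections <- list()
  if (n >= 2L) {
    bif_pts <- lapply(seq_len(n), function(d) {
      p <- path$segments[[d]]
      p[nrow(p), ]
    })
    for (d in seq_len(n - 1L)) {
      node <- path$node_ids[d + 1L]
      onpath_child <- path$node_ids[d + 2L]
      kids <- tree$children[[node]]
      cam <- bifurcation_camera_any(path, d, setback_mm, fov_deg)
      projs <- lapply(kids, function(ch)
        tryCatch(project_segment(cam, tree$segments[[node, ch]], ch),
                 error = function(e)
                   stop("bifurcation at node ", node, " (level ", d, "): ",
                        conditionMessage(e))))
      names(projs) <- as.character(kids)
      onpath_proj <- projs[[as.character(onpath_child)]]
      sibs <- projs[names(projs) != as.character(onpath_child)]

      non_binary <- length(kids) > 2L
      degenerate <- length(kids) < 2L
      if (length(sibs) == 1L && !non_binary) {
        lp <- label_pair(onpath_proj, sibs[[1L]])
        text <- lp$onpath_text
        labels <- stats::setNames(
          c(lp$onpath_label, lp$sibling_label),
          c(as.character(onpath_child), names(sibs)))
      } else {
        # non-binary (or degenerate) node: full quadrant name of the
        # on-path child versus the union of siblings
        text <- paste("go", QUADRANT_LABELS[onpath_proj$quadrant])
        labels <- vapply(projs, function(p)
          unname(QUADRANT_LABELS[p$quadrant]), character(1))
      }
      close_levels <- FALSE
      if (d < n - 1L)
        close_levels <- vnorm(bif_pts[[d + 1L]] - bif_pts[[d]]) < close_mm

      instructions[[d]] <- list(
        level = d, node_id = node, onpath_child = onpath_child,
        labels = labels, text = unname(text),
        flags = list(non_binary = non_binary, degenerate = degenerate,
                     close_levels = close_levels, merged = FALSE))
      projections[[d]] <- list(camera = cam, segments = projs,
                               onpath_child = onpath_child)
    }

    if (merge_close) {
      merged <- list()
      d <- 1L
      while (d <= length(instructions)) {
        ins <- instructions[[d]]
        if (isTRUE(ins$flags$close_levels) && d + 1L <= length(instructions)) {
          nxt <- instructions[[d + 1L]]
          # one instruction spanning both levels, aimed at the grandchild:
          # project the on-path centerline across both bifurcations
          cam <- projections[[d]]$camera
          node1 <- ins$node_id
          child1 <- ins$onpath_child
          gchild <- nxt$onpath_child
          poly <- rbind(tree$segments[[node1, child1]],
                        tree$segments[[nxt$node_id, gchild]])
          pr <- project_segment(cam, poly, gchild)
          ins$text <- paste("go", unname(QUADRANT_LABELS[pr$quadrant]))
          ins$flags$merged <- TRUE
          ins$merged_levels <- c(ins$level, nxt$level)
          merged[[length(merged) + 1L]] <- ins
          d <- d + 2L
        } else {
          merged[[length(merged) + 1L]] <- ins
          d <- d + 1L
        }
      }
      instructions <- merged
    }
  }
  structure(list(instructions = instructions, projections = projections,
                 anchor = path$anchor, lesion = path$lesion,
                 config = list(setback_mm = setback_mm, fov_deg = fov_deg,
                               close_mm = close_mm,
                               merge_close = merge_close),
                 n_segments = n),
            class = "roadmap")
}

# camera that tolerates non-binary and degenerate internal nodes
bifurcation_camera_any <- function(path, d, setback_mm, fov_deg) {
  if (path$n_children[d + 1L] >= 2L)
    return(bifurcation_camera(path, d, setback_mm, fov_deg))
  # degenerate internal node: same geometry without the child-count check
  fake <- path
  fake$n_children[d + 1L] <- 2L
  bifurcation_camera(fake, d, setback_mm, fov_deg)
}

#' @export
print.roadmap <- function(x, ...) {
  cat(sprintf("<roadmap> %d instruction(s) over %d segment(s)\n",
              length(x$instructions), x$n_segments))
  for (i in seq_along(x$instructions)) {
    ins <- x$instructions[[i]]
    flags <- c(if (isTRUE(ins$flags$non_binary)) "non-binary",
               if (isTRUE(ins$flags$close_levels)) "close-levels",
               if (isTRUE(ins$flags$merged)) "merged")
    cat(sprintf("  %d. [level %d] %s%s\n", i, ins$level, ins$text,
                if (length(flags)) paste0(" (", paste(flags, collapse = ", "),
                                          ")") else ""))
  }
  invisible(x)
}
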