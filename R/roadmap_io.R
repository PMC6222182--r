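# Roadmap export: machine-readable JSON, numbered plain-text instructions,
# and a schematic PNG mosaic (projected child points on a quadrant cross,
# one panel per bifurcation).

#' Export a roadmap
#'
#' Writes `roadmap.json` (full projection geometry; reloadable with
#' [read_roadmap_json()]), `roadmap.txt` (one numbered instruction per line)
#' and, when requested, one schematic PNG per bifurcation plus a combined
#' `mosaic.png`.
#'
#' @param rm a [encode_instructions()] roadmap.
#' @param out_dir output directory (created if missing).
#' @param formats subset of `"json"`, `"txt"`, `"png"`.
#' @param allow_empty permit exporting a roadmap with no instructions.
#' @return Character vector of written files, invisibly.
#' @export
export_roadmap <- function(rm, out_dir, formats = c("json", "txt", "png"),
                           allow_empty = FALSE) {
  if (length(rm$instructions) == 0L && !allow_empty)
    stop("roadmap is empty (anchor within the trachea segment?); ",
         "set allow_empty = TRUE to export anyway")
  formats <- match.arg(formats, c("json", "txt", "png"), several.ok = TRUE)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  written <- character(0)

  if ("json" %in% formats) {
    f <- file.path(out_dir, "roadmap.json")
    write_roadmap_json(rm, f)
    written <- c(written, f)
  }
  if ("txt" %in% formats) {
    f <- file.path(out_dir, "roadmap.txt")
    lines <- vapply(seq_along(rm$instructions), function(i) {
      ins <- rm$instructions[[i]]
      lvl <- if (!is.null(ins$merged_levels))
        paste(ins$merged_levels, collapse = "+") else ins$level
      sprintf("%d. [level %s] %s", i, lvl, ins$text)
    }, character(1))
    writeLines(lines, f)
    written <- c(written, f)
  }
  if ("png" %in% formats && length(rm$instructions) > 0L) {
    for (i in seq_along(rm$instructions)) {
      f <- file.path(out_dir, sprintf("bifurcation_%02d.png", i))
      grDevices::png(f, width = 480, height = 480)
      plot_bifurcation_panel(rm, i)
      grDevices::dev.off()
      written <- c(written, f)
    }
    f <- file.path(out_dir, "mosaic.png")
    k <- length(rm$instructions)
    ncol <- ceiling(sqrt(k))
    nrow <- ceiling(k / ncol)
    grDevices::png(f, width = 360 * ncol, height = 360 * nrow)
    op <- graphics::par(mfrow = c(nrow, ncol))
    for (i in seq_len(k)) plot_bifurcation_panel(rm, i)
    graphics::par(op)
    grDevices::dev.off()
    written <- c(written, f)
  }
  invisible(written)
}

# one quadrant panel: child point clouds, quadrant cross, chosen direction
plot_bifurcation_panel <- function(rm, i) {
  ins <- rm$instructions[[i]]
  pr <- rm$projections[[ins$level]]
  allpts <- do.call(rbind, lapply(pr$segments, function(s) s$points2d))
  lim <- max(abs(allpts), 0.2) * 1.1
  graphics::plot(NA, xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
                 xlab = "", ylab = "",
                 main = sprintf("%d. level %s: %s", i,
                                if (!is.null(ins$merged_levels))
                                  paste(ins$merged_levels, collapse = "+")
                                else ins$level,
                                ins$text))
  graphics::abline(h = 0, v = 0, lty = 3, col = "grey50")
  cols <- grDevices::hcl.colors(max(2L, length(pr$segments)), "Dark 3")
  for (s in seq_along(pr$segments)) {
    seg <- pr$segments[[s]]
    onpath <- identical(seg$child_id, pr$onpath_child)
    graphics::points(seg$points2d, col = cols[s], pch = if (onpath) 19 else 1,
                     cex = 0.8)
  }
  op_seg <- pr$segments[[as.character(pr$onpath_child)]]
  m <- colMeans(op_seg$points2d)
  graphics::arrows(0, 0, m[1], m[2], length = 0.1, lwd = 2)
}

#' Write / read the roadmap JSON
#'
#' @param rm a roadmap.
#' @param file JSON path.
#' @return `file` invisibly (writer); a `roadmap` (reader).
#' @export
write_roadmap_json <- function(rm, file) {
  ser_proj <- lapply(rm$projections, function(p) list(
    camera = list(position = unname(p$camera$position),
                  view_dir = unname(p$camera$view_dir),
                  up = unname(p$camera$up),
                  right = unname(p$camera$right),
                  fov_deg = p$camera$fov_deg,
                  principal_point = unname(p$camera$principal_point),
                  bifurcation = unname(p$camera$bifurcation)),
    onpath_child = p$onpath_child,
    segments = lapply(p$segments, function(s) list(
      child_id = s$child_id,
      points2d = unname(s$points2d),
      n_dropped = s$n_dropped,
      distal_point2d = unname(s$distal_point2d),
      mean_angle_deg = s$mean_angle_deg,
      quadrant = s$quadrant,
      quadrant_counts = as.list(s$quadrant_counts)))))
  anchor <- if (is.null(rm$anchor)) NULL else
    list(edge = unname(rm$anchor$edge), point_index = rm$anchor$point_index,
         point = unname(rm$anchor$point), gap_mm = rm$anchor$gap_mm)
  obj <- list(instructions = rm$instructions, projections = ser_proj,
              anchor = anchor, lesion = rm$lesion, config = rm$config,
              n_segments = rm$n_segments)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_roadmap_json
#' @export
read_roadmap_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  num <- function(x) unlist(x, use.names = FALSE)
  instructions <- lapply(obj$instructions, function(ins) {
    out <- list(level = ins$level, node_id = ins$node_id,
                onpath_child = ins$onpath_child,
                labels = stats::setNames(num(lapply(ins$labels, identity)),
                                         names(ins$labels)),
                text = ins$text,
                flags = lapply(ins$flags, isTRUE))
    if (!is.null(ins$merged_levels)) out$merged_levels <- num(ins$merged_levels)
    out
  })
  projections <- lapply(obj$projections, function(p) {
    cam <- structure(list(position = num(p$camera$position),
                          view_dir = num(p$camera$view_dir),
                          up = num(p$camera$up),
                          right = num(p$camera$right),
                          fov_deg = p$camera$fov_deg,
                          principal_point = num(p$camera$principal_point),
                          bifurcation = num(p$camera$bifurcation)),
                     class = "camera_pose")
    segs <- lapply(p$segments, function(s) {
      pts <- do.call(rbind, lapply(s$points2d, num))
      colnames(pts) <- c("x", "y")
      structure(list(child_id = s$child_id, points2d = pts,
                     n_dropped = s$n_dropped,
                     distal_point2d = num(s$distal_point2d),
                     mean_angle_deg = s$mean_angle_deg,
                     quadrant = s$quadrant,
                     quadrant_counts =
                       unlist(s$quadrant_counts)),
                class = "projected_segment")
    })
    names(segs) <- names(p$segments)
    list(camera = cam, segments = segs, onpath_child = p$onpath_child)
  })
  anchor <- if (is.null(obj$anchor)) NULL else
    structure(list(edge = c(parent = obj$anchor$edge[[1]],
                            child = obj$anchor$edge[[2]]),
                   point_index = obj$anchor$point_index,
                   point = num(obj$anchor$point),
                   gap_mm = obj$anchor$gap_mm),
              class = "anchor_point")
  structure(list(instructions = instructions, projections = projections,
                 anchor = anchor, lesion = num(obj$lesion),
                 config = obj$config, n_segments = obj$n_segments),
            class = "roadmap")
}
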