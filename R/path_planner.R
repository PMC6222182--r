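# Path planning: from a lesion point to the closest airway point, and from
# the trachea root to that anchor.

#' Closest airway point to a lesion
#'
#' Scans every polyline point of every tree edge and returns the global
#' minimizer of the Euclidean distance to the lesion. Distance is
#' point-to-sampled-polyline (one sample per skeleton voxel), matching the
#' discrete centerline encoding; ties break deterministically on the lowest
#' edge id (the edge's child node id), then the lowest point index.
#'
#' @param tree an `airway_tree`.
#' @param lesion world-mm point.
#' @return An object of class `anchor_point`: `edge` (parent, child node
#'   ids), `point_index` (1-based index into the edge polyline), `point`
#'   (world mm), `gap_mm` (lesion-to-anchor distance).
#' @export
closest_airway_point <- function(tree, lesion) {
  if (nrow(tree$nodes) == 0L) stop("empty tree")
  childs <- which(!is.na(tree$nodes$parent))
  if (length(childs) == 0L) stop("tree has no edges")
  best <- NULL
  for (ch in sort(childs)) {
    par <- tree$nodes$parent[ch]
    poly <- tree$segments[[par, ch]]
    d2 <- (poly[, 1] - lesion[1])^2 + (poly[, 2] - lesion[2])^2 +
      (poly[, 3] - lesion[3])^2
    i <- which.min(d2)   # lowest index wins ties within an edge
    if (is.null(best) || d2[i] < best$d2) {
      best <- list(d2 = d2[i], edge = c(parent = par, child = ch),
                   point_index = i, point = poly[i, ])
    }
  }
  structure(list(edge = best$edge, point_index = best$point_index,
                 point = best$point, gap_mm = sqrt(best$d2)),
            class = "anchor_point")
}

#' @export
print.anchor_point <- function(x, ...) {
  cat(sprintf("<anchor_point> edge %d->%d, point %d, gap %.2f mm\n",
              x$edge[1], x$edge[2], x$point_index, x$gap_mm))
  invisible(x)
}

#' Navigation path from the trachea root to an anchor
#'
#' Walks the unique tree path from the root to the anchor's edge; the final
#' segment is truncated at the anchor point. Each segment S_d carries the
#' centerline polyline between bifurcation points at consecutive levels;
#' its level is the level of its distal node, so levels run 1..n. Junction
#' points are owned by the distal segment: each segment's first point is the
#' bifurcation it leaves.
#'
#' @param tree an `airway_tree`.
#' @param anchor an [closest_airway_point()] result.
#' @return An object of class `navigation_path`: `segments` (list of k x 3
#'   polylines), `levels`, `node_ids` (root..distal), `n_children` per path
#'   node in the tree, `anchor`, `lesion` (if known).
#' @export
root_path <- function(tree, anchor) {
  par <- anchor$edge[["parent"]]; ch <- anchor$edge[["child"]]
  n <- nrow(tree$nodes)
  if (ch > n || is.na(tree$nodes$parent[ch]) || tree$nodes$parent[ch] != par)
    stop("anchor edge not in tree")
  chain <- ch
  v <- ch
  while (!is.na(tree$nodes$parent[v])) {
    v <- tree$nodes$parent[v]
    chain <- c(v, chain)
  }
  if (chain[1L] != tree$root_id) stop("anchor not reachable from root")
  segments <- vector("list", length(chain) - 1L)
  for (s in seq_len(length(chain) - 1L)) {
    a <- chain[s]; b <- chain[s + 1L]
    poly <- tree$segments[[a, b]]
    if (s == length(chain) - 1L)
      poly <- poly[seq_len(anchor$point_index), , drop = FALSE]
    segments[[s]] <- poly
  }
  structure(list(segments = segments,
                 levels = seq_len(length(segments)),
                 node_ids = chain,
                 n_children = lengths(tree$children)[chain],
                 anchor = anchor,
                 lesion = NULL),
            class = "navigation_path")
}

#' @export
print.navigation_path <- function(x, ...) {
  cat(sprintf("<navigation_path> %d segments, anchor gap %.2f mm\n",
              length(x$segments), x$anchor$gap_mm))
  invisible(x)
}

#' Serialize / load a navigation path as JSON
#'
#' @param path_obj a `navigation_path`.
#' @param file JSON file path.
#' @return `file` invisibly (writer); a `navigation_path` (reader).
#' @export
write_path_json <- function(path_obj, file) {
  obj <- list(
    segments = lapply(path_obj$segments, unname),
    levels = path_obj$levels,
    node_ids = path_obj$node_ids,
    n_children = unname(path_obj$n_children),
    anchor = list(edge = unname(path_obj$anchor$edge),
                  point_index = path_obj$anchor$point_index,
                  point = unname(path_obj$anchor$point),
                  gap_mm = path_obj$anchor$gap_mm),
    lesion = path_obj$lesion)
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_path_json
#' @export
read_path_json <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  anchor <- structure(list(
    edge = c(parent = obj$anchor$edge[1], child = obj$anchor$edge[2]),
    point_index = obj$anchor$point_index,
    point = obj$anchor$point,
    gap_mm = obj$anchor$gap_mm), class = "anchor_point")
  segs <- obj$segments
  if (is.array(segs) && length(dim(segs)) == 3L)
    segs <- lapply(seq_len(dim(segs)[1]), function(i) segs[i, , ])
  if (!is.list(segs)) segs <- list(segs)
  structure(list(segments = lapply(segs, function(s) matrix(s, ncol = 3)),
                 levels = obj$levels,
                 node_ids = obj$node_ids,
                 n_children = obj$n_children,
                 anchor = anchor,
                 lesion = obj$lesion),
            class = "navigation_path")
}
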