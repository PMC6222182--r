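# Centerline skeletonization and encoding of the airway tree.
#
# The segmentation mask is thinned to a 1-voxel-wide medial curve, the curve
# is condensed to a branch graph (branching-point clusters become nodes,
# degree-2 chains become edges), spurs are pruned, and the graph is directed
# away from the trachea by depth-first search into a rooted (binary) tree.
# The tree is held as the pair of matrices used throughout the package: a
# binary node-adjacency matrix and a matrix of 3D centerline segments.

#' Skeletonize an airway mask
#'
#' 3D topology-preserving curve thinning (26-connectivity object, 6 background)
#' of a single-component binary mask.
#'
#' @param mask an `airway_mask` from [segment_airways()] or a logical array.
#' @return An object of class `skeleton_voxels`: `points` (m x 3 integer,
#'   0-based voxel indices), `degree` (per-point 26-neighbor counts inside the
#'   skeleton), `dims`, `affine`.
#' @export
skeletonize <- function(mask) {
  affine <- diag(4)
  if (inherits(mask, "airway_mask")) {
    affine <- mask$affine
    mask <- mask$mask
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask is empty")
  lab <- cpp_label_components(mask, dim(mask), 26L)
  if (length(attr(lab, "sizes")) > 1L)
    stop("mask must be a single 26-connected component (found ",
         length(attr(lab, "sizes")), ")")
  skel <- cpp_skeletonize(mask, dim(mask))
  deg <- cpp_neighbor_count(skel, dim(skel))
  idx <- which(skel)
  pts <- arrayInd(idx, dim(skel)) - 1L
  structure(list(points = pts, degree = deg[idx], dims = dim(skel),
                 affine = affine),
            class = "skeleton_voxels")
}

#' @export
print.skeleton_voxels <- function(x, ...) {
  cat(sprintf("<skeleton_voxels> %d points (%d branch points, %d endpoints)\n",
              nrow(x$points), sum(x$degree >= 3), sum(x$degree == 1)))
  invisible(x)
}

#' Condense a skeleton into an undirected branch graph
#'
#' Maximal 26-connected clusters of skeleton voxels with degree >= 3 collapse
#' into single branching nodes; degree-1 (and isolated) voxels become end
#' nodes; maximal degree-2 chains become edges carrying their ordered voxel
#' chain as a world-mm polyline. Every skeleton voxel lands in exactly one
#' node cluster or one edge chain.
#'
#' @param skel a [skeletonize()] result.
#' @param affine voxel-to-world affine (defaults to the skeleton's).
#' @return An object of class `skeleton_graph`: `nodes` (id, world position,
#'   cluster size), `edges` (id, from, to, length_mm), `polylines` (list of
#'   k x 3 world-mm matrices, endpoints at the node positions).
#' @export
build_skeleton_graph <- function(skel, affine = skel$affine) {
  pts <- skel$points
  m <- nrow(pts)
  dims <- skel$dims
  lin <- pts[, 1] + dims[1] * (pts[, 2] + dims[2] * pts[, 3])  # 0-based linear
  o <- order(lin)
  lin_sorted <- lin[o]
  find_pt <- function(l) {
    i <- findInterval(l, lin_sorted)
    ifelse(i > 0L & lin_sorted[pmax(i, 1L)] == l, o[pmax(i, 1L)], NA_integer_)
  }

  skel_arr <- array(FALSE, dims)
  skel_arr[pts + 1L] <- TRUE
  comp <- cpp_label_components(skel_arr, dims, 26L)
  if (length(attr(comp, "sizes")) > 1L)
    stop("skeleton is disconnected (", length(attr(comp, "sizes")),
         " components)")

  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  neighbor_ids <- function(i) {
    q <- sweep(offs, 2, as.numeric(pts[i, ]), `+`)
    ok <- q[, 1] >= 0 & q[, 1] < dims[1] & q[, 2] >= 0 & q[, 2] < dims[2] &
      q[, 3] >= 0 & q[, 3] < dims[3]
    q <- q[ok, , drop = FALSE]
    r <- find_pt(q[, 1] + dims[1] * (q[, 2] + dims[2] * q[, 3]))
    r[!is.na(r)]
  }
  nbrs <- lapply(seq_len(m), neighbor_ids)
  deg <- lengths(nbrs)

  world <- function(i) {
    w <- t(affine[1:3, 1:3] %*% t(pts[i, , drop = FALSE])) +
      matrix(affine[1:3, 4], length(i), 3L, byrow = TRUE)
    w
  }

  # --- node clusters ---------------------------------------------------
  node_of <- rep(NA_integer_, m)          # point -> node id
  clusters <- list()
  is_branch <- deg >= 3L
  seen <- rep(FALSE, m)
  for (i in seq_len(m)) {
    if (!is_branch[i] || seen[i]) next
    stack <- i; seen[i] <- TRUE; members <- integer(0)
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      members <- c(members, p)
      for (q in nbrs[[p]])
        if (is_branch[q] && !seen[q]) { seen[q] <- TRUE; stack <- c(stack, q) }
    }
    clusters[[length(clusters) + 1L]] <- members
  }
  for (i in seq_len(m))
    if (deg[i] <= 1L) clusters[[length(clusters) + 1L]] <- i
  for (ci in seq_along(clusters)) node_of[clusters[[ci]]] <- ci

  n_nodes <- length(clusters)
  node_pos <- t(vapply(clusters, function(mem)
    colMeans(world(mem)), numeric(3)))

  # --- edge chains ------------------------------------------------------
  chain_used <- rep(FALSE, m)   # degree-2 voxels consumed by a chain
  edges_from <- integer(0); edges_to <- integer(0)
  chains <- list()
  add_edge <- function(a, b, chain) {
    edges_from <<- c(edges_from, a); edges_to <<- c(edges_to, b)
    chains[[length(chains) + 1L]] <<- chain
  }

  is_node_pt <- !is.na(node_of)
  direct_pairs <- character(0)
  for (i in seq_len(m)) {
    if (!is_node_pt[i]) next
    for (q in nbrs[[i]]) {
      if (is_node_pt[q]) {
        a <- node_of[i]; b <- node_of[q]
        if (a < b) {   # direct node-node contact, once per node pair
          key <- paste0(a, "_", b)
          if (!(key %in% direct_pairs)) {
            direct_pairs <- c(direct_pairs, key)
            add_edge(a, b, integer(0))
          }
        }
      } else if (!chain_used[q]) {
        # walk the degree-2 chain starting at q
        chain <- integer(0)
        prev <- i; cur <- q
        repeat {
          chain <- c(chain, cur); chain_used[cur] <- TRUE
          nxt <- setdiff(nbrs[[cur]], prev)
          # prefer non-chain continuation deterministically
          nxt <- nxt[!(nxt %in% chain)]
          if (length(nxt) == 0L) { endnode <- NA_integer_; break }
          nx <- nxt[[1L]]
          if (is_node_pt[nx]) { endnode <- node_of[nx]; break }
          prev <- cur; cur <- nx
        }
        if (is.na(endnode)) {
          # chain ran into itself (cycle without node): close on start node
          endnode <- node_of[i]
        }
        add_edge(node_of[i], endnode, chain)
      }
    }
  }

  # leftover pure cycles (no node voxel at all): promote one voxel per cycle
  leftover <- which(!is_node_pt & !chain_used & deg == 2L)
  while (length(leftover)) {
    s <- leftover[[1L]]
    node_of[s] <- n_nodes + 1L
    n_nodes <- n_nodes + 1L
    clusters[[n_nodes]] <- s
    node_pos <- rbind(node_pos, world(s))
    is_node_pt[s] <- TRUE
    chain <- integer(0)
    prev <- s; cur <- nbrs[[s]][[1L]]
    while (!is_node_pt[cur]) {
      chain <- c(chain, cur); chain_used[cur] <- TRUE
      nxt <- setdiff(nbrs[[cur]], c(prev, chain))
      if (length(nxt) == 0L) break
      prev <- cur; cur <- nxt[[1L]]
    }
    add_edge(node_of[s], node_of[s], chain)
    leftover <- which(!is_node_pt & !chain_used & deg == 2L)
  }

  polylines <- vector("list", length(chains))
  lens <- numeric(length(chains))
  for (e in seq_along(chains)) {
    mid <- if (length(chains[[e]])) world(chains[[e]]) else NULL
    poly <- rbind(node_pos[edges_from[e], , drop = FALSE], mid,
                  node_pos[edges_to[e], , drop = FALSE])
    polylines[[e]] <- unname(poly)
    lens[e] <- polyline_length(poly)
  }

  nodes <- data.frame(id = seq_len(n_nodes),
                      x = node_pos[, 1], y = node_pos[, 2], z = node_pos[, 3],
                      n_voxels = lengths(clusters))
  edges <- if (length(chains))
    data.frame(id = seq_along(chains), from = edges_from, to = edges_to,
               length_mm = lens)
  else data.frame(id = integer(0), from = integer(0), to = integer(0),
                  length_mm = numeric(0))
  structure(list(nodes = nodes, edges = edges, polylines = polylines,
                 chain_voxels = sum(lengths(chains)),
                 cluster_voxels = sum(lengths(clusters))),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

graph_degree <- function(graph) {
  tabulate(c(graph$edges$from, graph$edges$to), nbins = nrow(graph$nodes))
}

#' Remove short terminal spurs from a branch graph
#'
#' Iteratively deletes leaf edges shorter than `min_length_mm` (thinning
#' artifacts near the airway wall), then merges the resulting pass-through
#' (degree-2) nodes by concatenating their two edges. Idempotent at the
#' fixed point. A spur's length is the arc length of skeletal material
#' outside its attachment cluster: the link from the (possibly wide)
#' branching-cluster centroid to the first chain voxel is not counted, so a
#' fat carina cannot promote its own thinning artifact to a branch.
#'
#' @param graph a [build_skeleton_graph()] result.
#' @param min_length_mm spur length threshold; 0 leaves the graph unchanged.
#' @return A pruned `skeleton_graph`.
#' @export
prune_spurs <- function(graph, min_length_mm = 3) {
  if (min_length_mm <= 0) return(graph)
  spur_length <- function(e, leaf_at_from) {
    poly <- graph$polylines[[e]]
    # drop the centroid-attachment link at the cluster end when a real
    # chain exists (2-point polylines have no chain to trim)
    if (nrow(poly) > 2L) {
      poly <- if (leaf_at_from) poly[-nrow(poly), , drop = FALSE]
              else poly[-1L, , drop = FALSE]
    }
    polyline_length(poly)
  }
  repeat {
    changed <- FALSE
    deg <- graph_degree(graph)
    # drop short leaf edges whose interior end stays branching
    drop <- logical(nrow(graph$edges))
    for (e in seq_len(nrow(graph$edges))) {
      a <- graph$edges$from[e]; b <- graph$edges$to[e]
      leaf_end <- (deg[a] == 1L) || (deg[b] == 1L)
      if (leaf_end && spur_length(e, deg[a] == 1L) < min_length_mm &&
          nrow(graph$edges) > 1L) {
        # removing must not orphan both ends
        other <- if (deg[a] == 1L) b else a
        if (deg[other] >= 2L) { drop[e] <- TRUE; changed <- TRUE }
      }
    }
    if (any(drop)) {
      graph$edges <- graph$edges[!drop, , drop = FALSE]
      graph$polylines <- graph$polylines[!drop]
    }
    # merge pass-through nodes (exactly two distinct incident edges)
    deg <- graph_degree(graph)
    mergeable <- which(deg == 2L)
    merged_any <- FALSE
    for (v in mergeable) {
      inc <- which(graph$edges$from == v | graph$edges$to == v)
      if (length(inc) != 2L) next   # self-loop counted twice
      e1 <- inc[1]; e2 <- inc[2]
      p1 <- graph$polylines[[e1]]
      p2 <- graph$polylines[[e2]]
      # orient both to run through v: end of p1 at v, start of p2 at v
      if (graph$edges$from[e1] == v) {
        p1 <- p1[nrow(p1):1, , drop = FALSE]
        a <- graph$edges$to[e1]
      } else a <- graph$edges$from[e1]
      if (graph$edges$to[e2] == v) {
        p2 <- p2[nrow(p2):1, , drop = FALSE]
        b <- graph$edges$from[e2]
      } else b <- graph$edges$to[e2]
      poly <- rbind(p1, p2[-1L, , drop = FALSE])
      graph$edges$from[e1] <- a
      graph$edges$to[e1] <- b
      graph$polylines[[e1]] <- poly
      graph$edges$length_mm[e1] <- polyline_length(poly)
      graph$edges <- graph$edges[-e2, , drop = FALSE]
      graph$polylines <- graph$polylines[-e2]
      merged_any <- TRUE
      changed <- TRUE
      break  # degrees changed; recompute
    }
    if (!changed) break
  }
  graph$edges$id <- seq_len(nrow(graph$edges))
  graph
}

# ---------------------------------------------------------------------------
# rooted airway tree

# Construct the canonical airway_tree object from a node table and an edge
# list (each: from, to, polyline oriented from -> to). Node levels/kinds are
# recomputed from the topology.
new_airway_tree <- function(nodes, edges, root_id, diagnostics = list()) {
  n <- nrow(nodes)
  adjacency <- matrix(0L, n, n)
  segments <- matrix(vector("list", n * n), n, n)
  children <- rep(list(integer(0)), n)
  parent <- rep(NA_integer_, n)
  for (e in edges) {
    adjacency[e$from, e$to] <- 1L
    adjacency[e$to, e$from] <- 1L
    segments[[e$from, e$to]] <- e$polyline
    segments[[e$to, e$from]] <- e$polyline[nrow(e$polyline):1, , drop = FALSE]
    children[[e$from]] <- c(children[[e$from]], e$to)
    parent[e$to] <- e$from
  }
  level <- rep(NA_integer_, n)
  level[root_id] <- 0L
  queue <- root_id
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (ch in children[[v]]) {
      level[ch] <- level[v] + 1L
      queue <- c(queue, ch)
    }
  }
  kind <- ifelse(lengths(children) >= 2L, "bifurcation",
                 ifelse(lengths(children) == 1L, "internal", "leaf"))
  kind[root_id] <- "root"
  nodes$kind <- kind
  nodes$level <- level
  nodes$parent <- parent
  nodes$n_children <- lengths(children)
  structure(list(nodes = nodes, adjacency = adjacency, segments = segments,
                 root_id = root_id, children = children,
                 diagnostics = diagnostics),
            class = "airway_tree")
}

#' @export
print.airway_tree <- function(x, ...) {
  cat(sprintf(
    "<airway_tree> %d nodes (root %d), %d bifurcations, %d leaves, max level %d\n",
    nrow(x$nodes), x$root_id, sum(x$nodes$kind == "bifurcation"),
    sum(x$nodes$kind == "leaf"), max(x$nodes$level)))
  invisible(x)
}

#' Direct a branch graph from the trachea into a rooted airway tree
#'
#' The root is the graph node nearest the trachea seed (tie-break: most
#' superior, then lowest id). A depth-first traversal orients every edge away
#' from the root; edges that would close a cycle are discarded and recorded
#' in the diagnostics. Node levels increase by one per edge from the root
#' (root = 0); nodes with more than two children are kept and flagged
#' non-binary.
#'
#' @param graph a (pruned) [build_skeleton_graph()] result.
#' @param trachea_seed_world world-mm position of the trachea entry point.
#' @return An object of class `airway_tree`: `nodes` (id, position, kind in
#'   root/bifurcation/internal/leaf, level, parent), binary `adjacency`
#'   matrix, `segments` matrix of polylines, `root_id`, `diagnostics`
#'   (discarded cycle edges, non-binary node ids).
#' @export
direct_from_root <- function(graph, trachea_seed_world) {
  if (nrow(graph$nodes) == 0L) stop("empty graph")
  d2 <- (graph$nodes$x - trachea_seed_world[1])^2 +
    (graph$nodes$y - trachea_seed_world[2])^2 +
    (graph$nodes$z - trachea_seed_world[3])^2
  cand <- which(d2 == min(d2))
  if (length(cand) > 1L) cand <- cand[order(-graph$nodes$z[cand], cand)]
  root <- cand[[1L]]

  n <- nrow(graph$nodes)
  # incidence: for each node, (edge id, other node), children visited in
  # descending edge length for a deterministic traversal
  inc <- rep(list(NULL), n)
  for (e in seq_len(nrow(graph$edges))) {
    a <- graph$edges$from[e]; b <- graph$edges$to[e]
    inc[[a]] <- rbind(inc[[a]], c(e, b))
    inc[[b]] <- rbind(inc[[b]], c(e, a))
  }

  visited <- rep(FALSE, n)
  edge_used <- rep(FALSE, nrow(graph$edges))
  discarded <- integer(0)
  tree_edges <- list()
  stack <- root
  visited[root] <- TRUE
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    ie <- inc[[v]]
    if (is.null(ie)) next
    ord <- order(-graph$edges$length_mm[ie[, 1]], ie[, 2])
    for (r in ord) {
      e <- ie[r, 1]; w <- ie[r, 2]
      if (edge_used[e]) next
      edge_used[e] <- TRUE
      if (visited[w]) {
        discarded <- c(discarded, e)
        next
      }
      visited[w] <- TRUE
      poly <- graph$polylines[[e]]
      if (graph$edges$from[e] != v) poly <- poly[nrow(poly):1, , drop = FALSE]
      tree_edges[[length(tree_edges) + 1L]] <-
        list(from = v, to = w, polyline = poly)
      stack <- c(stack, w)
    }
  }
  keep <- which(visited)
  remap <- match(seq_len(n), keep)
  nodes <- data.frame(id = seq_along(keep),
                      x = graph$nodes$x[keep], y = graph$nodes$y[keep],
                      z = graph$nodes$z[keep])
  tree_edges <- lapply(tree_edges, function(e)
    list(from = remap[e$from], to = remap[e$to], polyline = e$polyline))
  tree <- new_airway_tree(nodes, tree_edges, root_id = remap[root],
                          diagnostics = list(
                            discarded_edges = discarded,
                            unreached_nodes = sum(!visited)))
  tree$diagnostics$non_binary_nodes <-
    tree$nodes$id[tree$nodes$n_children > 2L]
  tree
}

#' Encode / decode the two-adjacency-matrix form of an airway tree
#'
#' `encode_adjacency` returns the binary node-connectivity matrix and the
#' matrix of 3D centerline segments; `decode_adjacency` reconstructs an
#' identical tree from them.
#'
#' @param tree an `airway_tree`.
#' @param nodes node table with `id`, `x`, `y`, `z`.
#' @param adjacency symmetric binary matrix.
#' @param segments matrix of polylines (nonzero pattern = adjacency pattern).
#' @param root_id root node id.
#' @return `encode_adjacency`: `list(adjacency, segments)`;
#'   `decode_adjacency`: an `airway_tree`.
#' @export
encode_adjacency <- function(tree) {
  list(adjacency = tree$adjacency, segments = tree$segments)
}

#' @rdname encode_adjacency
#' @export
decode_adjacency <- function(nodes, adjacency, segments, root_id) {
  n <- nrow(nodes)
  edges <- list()
  visited <- rep(FALSE, n)
  visited[root_id] <- TRUE
  queue <- root_id
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    for (w in which(adjacency[v, ] == 1L)) {
      if (visited[w]) next
      visited[w] <- TRUE
      edges[[length(edges) + 1L]] <-
        list(from = v, to = w, polyline = segments[[v, w]])
      queue <- c(queue, w)
    }
  }
  new_airway_tree(nodes[, c("id", "x", "y", "z")], edges, root_id)
}

#' Check the structural invariants of an airway tree
#'
#' @param tree an `airway_tree`.
#' @return Character vector of violated invariants (empty when valid).
#' @export
validate_airway_tree <- function(tree) {
  issues <- character(0)
  adj <- tree$adjacency
  n <- nrow(tree$nodes)
  if (!isTRUE(all.equal(adj, t(adj)))) issues <- c(issues, "adjacency not symmetric")
  if (any(diag(adj) != 0)) issues <- c(issues, "nonzero adjacency diagonal")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    filled <- !is.null(tree$segments[[i, j]])
    if (filled != (adj[i, j] == 1L)) {
      issues <- c(issues, "segment pattern != adjacency pattern")
      break
    }
  }
  # polyline endpoints within a voxel diagonal of their node positions
  pos <- as.matrix(tree$nodes[, c("x", "y", "z")])
  for (i in seq_len(n)) {
    ch <- tree$children[[i]]
    for (j in ch) {
      p <- tree$segments[[i, j]]
      if (is.null(p)) next
      if (vnorm(p[1, ] - pos[i, ]) > 2 || vnorm(p[nrow(p), ] - pos[j, ]) > 2)
        issues <- c(issues, sprintf("polyline %d->%d detached from nodes", i, j))
    }
  }
  if (sum(is.na(tree$nodes$parent)) != 1L)
    issues <- c(issues, "not exactly one root")
  if (any(tree$nodes$level[tree$root_id] != 0L))
    issues <- c(issues, "root level != 0")
  ok_lvl <- is.na(tree$nodes$parent) |
    tree$nodes$level == tree$nodes$level[tree$nodes$parent] + 1L
  if (!all(ok_lvl, na.rm = TRUE))
    issues <- c(issues, "level(child) != level(parent) + 1")
  if (any(is.na(tree$nodes$level)))
    issues <- c(issues, "unreachable nodes from root")
  leaves <- tree$nodes$kind == "leaf"
  if (any(lengths(tree$children)[leaves] != 0L))
    issues <- c(issues, "leaf with children")
  unique(issues)
}

# canonical level-tagged form for isomorphism checks
tree_canonical <- function(tree, node) {
  ch <- tree$children[[node]]
  if (length(ch) == 0L) return("()")
  sub <- sort(vapply(ch, function(c) tree_canonical(tree, c), character(1)))
  paste0("(", paste(sub, collapse = ""), ")")
}

#' Level-tagged tree isomorphism
#'
#' Two airway trees are considered isomorphic when their rooted branching
#' topologies match (children unordered); geometry is ignored.
#'
#' @param a,b `airway_tree` objects.
#' @return `TRUE`/`FALSE`.
#' @export
tree_isomorphic <- function(a, b) {
  identical(tree_canonical(a, a$root_id), tree_canonical(b, b$root_id))
}

# ---------------------------------------------------------------------------
# JSON serialization

#' Write / read an airway tree as JSON
#'
#' Nodes (id, position, kind, level), adjacency as a sparse pair list, and
#' per-pair polyline arrays; the reader reconstructs an identical tree.
#'
#' @param tree an `airway_tree`.
#' @param path JSON file path.
#' @return `path` invisibly (writer); an `airway_tree` (reader).
#' @export
write_tree_json <- function(tree, path) {
  pairs <- which(upper.tri(tree$adjacency) & tree$adjacency == 1L,
                 arr.ind = TRUE)
  # orient each pair parent -> child
  seg <- apply(pairs, 1, function(ij) {
    i <- ij[1]; j <- ij[2]
    if (!is.na(tree$nodes$parent[j]) && tree$nodes$parent[j] == i)
      list(from = i, to = j, polyline = tree$segments[[i, j]])
    else
      list(from = j, to = i, polyline = tree$segments[[j, i]])
  })
  obj <- list(
    nodes = tree$nodes[, c("id", "x", "y", "z", "kind", "level")],
    root_id = tree$root_id,
    edges = lapply(seg, function(e)
      list(from = unname(e$from), to = unname(e$to),
           polyline = unname(e$polyline))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(obj$nodes)
  ed <- obj$edges
  if (is.data.frame(ed)) {
    edges <- lapply(seq_len(nrow(ed)), function(i)
      list(from = ed$from[i], to = ed$to[i],
           polyline = matrix(unlist(ed$polyline[[i]]), ncol = 3)))
  } else {
    edges <- lapply(ed, function(e)
      list(from = e$from, to = e$to,
           polyline = matrix(unlist(e$polyline), ncol = 3)))
  }
  new_airway_tree(nodes[, c("id", "x", "y", "z")], edges,
                  root_id = obj$root_id)
}
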