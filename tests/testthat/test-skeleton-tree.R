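# Skeletonization, branch-graph building, pruning, rooting, and the
# two-adjacency-matrix encoding.

test_that("a filled tube thins to a near-axial single chain", {
  mask <- fix_tube_mask()
  skel <- skeletonize(mask)
  # chain: no branch points, exactly two endpoints
  expect_equal(sum(skel$degree >= 3), 0L)
  expect_equal(sum(skel$degree == 1), 2L)
  # RMS distance to the true axis (x = y = 16) within 1 voxel
  rms <- sqrt(mean((skel$points[, 1] - 16)^2 + (skel$points[, 2] - 16)^2))
  expect_lte(rms, 1)
  # single voxel mask is its own skeleton
  m1 <- array(FALSE, c(3, 3, 3)); m1[2, 2, 2] <- TRUE
  s1 <- skeletonize(m1)
  expect_equal(unname(s1$points), matrix(c(1L, 1L, 1L), 1))
  expect_error(skeletonize(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("a Y-shaped mask yields one branching cluster and three ends", {
  fx <- fix_segmented_phantom()
  # restrict to a levels=2 phantom: one bifurcation
  spec <- generate_phantom_spec(2, seed = 3, jitter_sd = 0)
  mask <- phantom_lumen_mask(spec)
  skel <- skeletonize(mask)
  graph <- prune_spurs(build_skeleton_graph(skel, diag(4)), 3)
  deg <- bronchonav:::graph_degree(graph)
  expect_equal(sum(deg >= 3), 1L)
  expect_equal(sum(deg == 1), 3L)
  expect_equal(nrow(graph$edges), 3L)
})

test_that("straight-chain graph keeps every voxel and both ends", {
  mask <- fix_tube_mask(c(15L, 15L, 60L), r = 2, k0 = 5, k1 = 55,
                        center = c(7, 7))
  skel <- skeletonize(mask)
  graph <- build_skeleton_graph(skel, diag(4))
  expect_equal(nrow(graph$nodes), 2L)
  expect_equal(nrow(graph$edges), 1L)
  # conservation: every skeleton voxel in exactly one chain or cluster
  expect_equal(graph$chain_voxels + graph$cluster_voxels, nrow(skel$points))
})

test_that("skeleton voxels partition exactly into chains and clusters", {
  fx <- fix_extracted_tree()
  graph <- build_skeleton_graph(fx$skel)
  expect_equal(graph$chain_voxels + graph$cluster_voxels,
               nrow(fx$skel$points))
})

test_that("spur pruning removes short leaves, is idempotent, and 0 is identity", {
  # hand-built graph: long path with a 2 mm spur off its middle node
  nodes <- data.frame(id = 1:4,
                      x = c(0, 10, 20, 10), y = c(0, 0, 0, 2), z = 0,
                      n_voxels = 1L)
  poly <- function(a, b) rbind(a, b)
  graph <- structure(list(
    nodes = nodes,
    edges = data.frame(id = 1:3, from = c(1L, 2L, 2L), to = c(2L, 3L, 4L),
                       length_mm = c(10, 10, 2)),
    polylines = list(poly(c(0, 0, 0), c(10, 0, 0)),
                     poly(c(10, 0, 0), c(20, 0, 0)),
                     poly(c(10, 0, 0), c(10, 2, 0))),
    chain_voxels = 0L, cluster_voxels = 4L), class = "skeleton_graph")
  pruned <- prune_spurs(graph, 5)
  expect_equal(nrow(pruned$edges), 1L)   # spur gone, pass-through merged
  expect_equal(pruned$edges$length_mm, 20)
  expect_identical(prune_spurs(graph, 0), graph)
  expect_equal(prune_spurs(pruned, 5), pruned)
})

test_that("rooting orients edges, assigns levels, and breaks cycles", {
  # Y graph rooted at a leaf end
  nodes <- data.frame(id = 1:4, x = c(0, 0, -5, 5), y = 0,
                      z = c(20, 10, 0, 0), n_voxels = 1L)
  graph <- structure(list(
    nodes = nodes,
    edges = data.frame(id = 1:3, from = c(1L, 2L, 2L), to = c(2L, 3L, 4L),
                       length_mm = c(10, 11.18, 11.18)),
    polylines = list(rbind(c(0, 0, 20), c(0, 0, 10)),
                     rbind(c(0, 0, 10), c(-5, 0, 0)),
                     rbind(c(0, 0, 10), c(5, 0, 0))),
    chain_voxels = 0L, cluster_voxels = 4L), class = "skeleton_graph")
  tree <- direct_from_root(graph, c(0, 0, 21))
  expect_equal(tree$nodes$level[tree$root_id], 0L)
  expect_equal(sort(tree$nodes$level), c(0L, 1L, 2L, 2L))
  expect_equal(tree$nodes$kind[tree$root_id], "root")
  expect_length(validate_airway_tree(tree), 0L)

  # add a cycle edge: output stays acyclic with exactly one discarded edge
  gc <- graph
  gc$edges <- rbind(gc$edges,
                    data.frame(id = 4L, from = 3L, to = 4L, length_mm = 10))
  gc$polylines <- c(gc$polylines, list(rbind(c(-5, 0, 0), c(5, 0, 0))))
  tree2 <- direct_from_root(gc, c(0, 0, 21))
  expect_length(tree2$diagnostics$discarded_edges, 1L)
  expect_length(validate_airway_tree(tree2), 0L)
  expect_error(direct_from_root(structure(list(
    nodes = nodes[0, ], edges = graph$edges[0, ], polylines = list()),
    class = "skeleton_graph"), c(0, 0, 0)), "empty")
})

test_that("clean phantom tree is isomorphic to ground truth with low RMS", {
  fx <- fix_segmented_phantom()
  ext <- fix_extracted_tree()
  expect_true(tree_isomorphic(ext$tree, fx$truth))
  expect_lte(centerline_rms(ext$tree, fx$spec), sqrt(3))
  expect_length(validate_airway_tree(ext$tree), 0L)
  # levels sum to a binary-tree profile: 8 leaf nodes for levels=4 would be
  # 2^3; here levels=3 gives 4 leaves
  expect_equal(sum(ext$tree$nodes$kind == "leaf"), 4L)
})

test_that("adjacency encoding round-trips the tree exactly", {
  tree <- fix_camera_truth(4)
  enc <- encode_adjacency(tree)
  # 3-node path example: 2 ones above the diagonal
  spec1 <- generate_phantom_spec(1, seed = 1)
  t1 <- truth_tree(spec1)
  e1 <- encode_adjacency(t1)
  expect_equal(sum(e1$adjacency[upper.tri(e1$adjacency)]), 1L)
  # nonzero pattern of the segment matrix equals the adjacency pattern
  filled <- matrix(!vapply(enc$segments, is.null, logical(1)),
                   nrow(enc$adjacency))
  expect_equal(filled, enc$adjacency == 1L)
  # decode -> identical tree
  back <- decode_adjacency(tree$nodes, enc$adjacency, enc$segments,
                           tree$root_id)
  expect_equal(back$nodes$level, tree$nodes$level)
  expect_equal(back$nodes$kind, tree$nodes$kind)
  expect_equal(back$adjacency, tree$adjacency)
  expect_equal(back$segments, tree$segments)
})

test_that("tree JSON serialization round-trips", {
  tree <- fix_extracted_tree()$tree
  f <- tempfile(fileext = ".json")
  write_tree_json(tree, f)
  back <- read_tree_json(f)
  expect_equal(back$adjacency, tree$adjacency)
  expect_equal(back$nodes$level, tree$nodes$level)
  expect_equal(back$root_id, tree$root_id)
  for (ch in which(!is.na(tree$nodes$parent)))
    expect_equal(back$segments[[tree$nodes$parent[ch], ch]],
                 tree$segments[[tree$nodes$parent[ch], ch]],
                 tolerance = 1e-9)
})
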