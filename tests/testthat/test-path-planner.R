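# Lesion anchoring and root-path extraction.

test_that("a lesion on a centerline point anchors there with zero gap", {
  tree <- fix_camera_truth(4)
  poly <- tree$segments[[tree$nodes$parent[5], 5]]
  lesion <- poly[4, ]
  a <- closest_airway_point(tree, lesion)
  expect_equal(a$gap_mm, 0)
  expect_equal(unname(a$point), unname(lesion))
})

test_that("ties break to the lowest edge id then lowest point index", {
  # two-branch toy tree with a lesion equidistant from two points
  nodes <- data.frame(id = 1:3, x = c(0, -10, 10), y = 0, z = c(0, -10, -10))
  edges <- list(
    list(from = 1L, to = 2L, polyline = rbind(c(0, 0, 0), c(-10, 0, -10))),
    list(from = 1L, to = 3L, polyline = rbind(c(0, 0, 0), c(10, 0, -10))))
  tree <- bronchonav:::new_airway_tree(nodes, edges, 1L)
  a <- closest_airway_point(tree, c(0, 0, -10))  # equidistant from both tips
  expect_equal(unname(a$edge), c(1L, 2L))        # lower child id wins
  # equidistant between first and last point of one edge
  b <- closest_airway_point(tree, c(-5, 5, -5))
  expect_equal(b$point_index, 1L)                # lower index wins
})

test_that("anchors equal the brute-force scan on random lesions", {
  tree <- fix_extracted_tree()$tree
  set.seed(99)
  for (i in 1:200) {
    lesion <- runif(3, c(20, 20, 10), c(108, 108, 120))
    a <- closest_airway_point(tree, lesion)
    bf <- brute_force_anchor(tree, lesion)
    expect_equal(unname(a$edge), unname(bf$edge))
    expect_equal(a$point_index, bf$index)
    expect_equal(a$gap_mm, bf$d, tolerance = 1e-9)
  }
})

test_that("root path is the unique tree path with monotone levels", {
  tree <- fix_camera_truth(5)
  leaves <- which(tree$nodes$kind == "leaf")
  set.seed(7)
  for (leaf in sample(leaves, 5)) {
    lesion <- unlist(tree$nodes[leaf, c("x", "y", "z")])
    a <- closest_airway_point(tree, lesion)
    p <- root_path(tree, a)
    expect_equal(p$node_ids[1], tree$root_id)
    expect_equal(p$levels, seq_along(p$segments))
    # consecutive segments share an endpoint
    for (s in seq_len(length(p$segments) - 1)) {
      expect_equal(p$segments[[s]][nrow(p$segments[[s]]), ],
                   p$segments[[s + 1]][1, ])
    }
    # cross-check against igraph shortest path on the undirected tree
    g <- igraph::graph_from_adjacency_matrix(tree$adjacency, "undirected")
    ig <- as.integer(igraph::shortest_paths(g, tree$root_id,
                                            a$edge[["child"]])$vpath[[1]])
    expect_equal(p$node_ids, ig)
  }
})

test_that("anchor on the trachea edge yields a single-segment path", {
  tree <- fix_camera_truth(4)
  # mid-trachea point
  poly <- tree$segments[[tree$root_id, which(tree$nodes$level == 1L)]]
  mid <- poly[ceiling(nrow(poly) / 2), ]
  p <- root_path(tree, closest_airway_point(tree, mid + c(3, 0, 0)))
  expect_length(p$segments, 1L)
  # final polyline is truncated at the anchor point
  expect_equal(p$segments[[1]][nrow(p$segments[[1]]), ],
               unname(p$anchor$point))
})

test_that("levels=4 phantom lesion near a known leaf routes to that leaf", {
  tree <- fix_camera_truth(4)
  leaves <- tree$nodes[tree$nodes$kind == "leaf", ]
  leaf <- leaves[3, ]
  lesion <- c(leaf$x, leaf$y, leaf$z) + c(1, 1, -1)
  p <- root_path(tree, closest_airway_point(tree, lesion))
  expect_length(p$segments, 4L)
  expect_equal(p$node_ids[length(p$node_ids)], leaf$id)
  # concatenated point count conserves per-segment counts
  total <- sum(vapply(p$segments, nrow, integer(1)))
  expect_equal(nrow(do.call(rbind, p$segments)), total)
})

test_that("invalid anchors are rejected", {
  tree <- fix_camera_truth(3)
  bad <- structure(list(edge = c(parent = 5L, child = 2L), point_index = 1L,
                        point = c(0, 0, 0), gap_mm = 0),
                   class = "anchor_point")
  expect_error(root_path(tree, bad), "not in tree")
})

test_that("path JSON round-trips", {
  tree <- fix_camera_truth(4)
  leaf <- tree$nodes[tree$nodes$kind == "leaf", ][2, ]
  p <- root_path(tree, closest_airway_point(tree, c(leaf$x, leaf$y, leaf$z)))
  p$lesion <- c(leaf$x, leaf$y, leaf$z)
  f <- tempfile(fileext = ".json")
  write_path_json(p, f)
  back <- read_path_json(f)
  expect_equal(length(back$segments), length(p$segments))
  for (i in seq_along(p$segments))
    expect_equal(back$segments[[i]], unname(p$segments[[i]]))
  expect_equal(back$anchor$gap_mm, p$anchor$gap_mm)
  expect_equal(back$lesion, p$lesion)
})
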