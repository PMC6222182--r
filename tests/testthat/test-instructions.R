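# Virtual-camera projection, quadrant voting, and instruction wording.

test_that("camera orthogonality, clamping, and the vertical-view fallback", {
  tree <- fix_camera_truth(4)
  leaf <- tree$nodes[tree$nodes$kind == "leaf", ][1, ]
  p <- root_path(tree, closest_airway_point(tree,
                                            c(leaf$x, leaf$y, leaf$z)))
  # trachea runs straight inferior: up falls back to the anterior axis
  cam <- bifurcation_camera(p, 1)
  expect_equal(unname(cam$view_dir), c(0, 0, -1), tolerance = 1e-9)
  expect_equal(unname(cam$up), c(0, -1, 0), tolerance = 1e-9)
  # setback longer than the segment clamps to the segment start
  cam2 <- bifurcation_camera(p, 2, setback_mm = 1e4)
  expect_equal(unname(cam2$position), unname(p$segments[[2]][1, ]))
  # orthogonality across random paths and levels
  set.seed(31)
  trees <- lapply(1:5, function(s)
    truth_tree(generate_phantom_spec(4, seed = s, jitter_sd = 4)))
  count <- 0
  for (tr in trees) {
    leaves <- tr$nodes[tr$nodes$kind == "leaf", ]
    for (li in seq_len(nrow(leaves))) {
      les <- unlist(leaves[li, c("x", "y", "z")])
      pp <- root_path(tr, closest_airway_point(tr, les))
      for (d in seq_len(length(pp$segments) - 1)) {
        cc <- bifurcation_camera(pp, d)
        expect_lt(abs(sum(cc$view_dir * cc$up)), 1e-9)
        count <- count + 1
      }
    }
  }
  expect_gte(count, 100)
  # leaf level is rejected
  expect_error(bifurcation_camera(p, length(p$segments)), "not a bifurcation")
})

test_that("pinhole projection arithmetic and scale invariance", {
  cam <- structure(list(position = c(0, 0, 0), view_dir = c(0, 1, 0),
                        up = c(0, 0, 1), right = c(1, 0, 0) * -1,
                        fov_deg = 120, principal_point = c(0, 0)),
                   class = "camera_pose")
  cam$right <- bronchonav:::cross3(cam$view_dir, cam$up)
  # point on the optical axis projects to the principal point
  pr <- project_segment(cam, rbind(c(0, 10, 0)))
  expect_equal(unname(pr$points2d[1, ]), c(0, 0))
  # camera coordinates (1, 1, 1) -> image (1, 1)
  q <- cam$position + cam$right + cam$up + cam$view_dir
  pr2 <- project_segment(cam, rbind(q))
  expect_equal(unname(pr2$points2d[1, ]), c(1, 1))
  # doubling all distances from the camera preserves projected directions
  set.seed(5)
  pts <- matrix(runif(60, -5, 5), ncol = 3)
  pts[, 2] <- abs(pts[, 2]) + 1  # keep in front
  a1 <- project_segment(cam, pts)
  a2 <- project_segment(cam, 2 * pts)
  expect_equal(a1$points2d, a2$points2d, tolerance = 1e-9)
  # points behind the camera are dropped and counted
  behind <- rbind(c(0, -5, 0), c(0, 5, 0))
  pr3 <- project_segment(cam, behind)
  expect_equal(pr3$n_dropped, 1L)
  expect_error(project_segment(cam, rbind(c(0, -5, 0))), "not visible")
})

test_that("majority voting matches the worked quadrant example", {
  # five points in quadrant I, two in IV -> assigned to I
  pts <- rbind(matrix(c(runif(5, 0.1, 1), runif(5, 0.1, 1)), ncol = 2),
               matrix(c(runif(2, 0.1, 1), runif(2, -1, -0.1)), ncol = 2))
  p <- proj_stub(pts)
  expect_equal(unname(p$quadrant_counts), c(5L, 0L, 0L, 2L))
  expect_equal(p$quadrant, "I")
  # all points at (0.3, 0.4) -> I
  expect_equal(proj_stub(rbind(c(0.3, 0.4), c(0.3, 0.4)))$quadrant, "I")
  # ties break to the most distal projected point's quadrant
  tie <- rbind(c(0.5, 0.5), c(-0.5, -0.5))
  expect_equal(proj_stub(tie)$quadrant, "III")
  expect_equal(proj_stub(tie[2:1, ])$quadrant, "I")
})

test_that("vectorized quadrant assignment equals brute-force counting", {
  set.seed(12)
  for (i in 1:300) {
    n <- sample(1:40, 1)
    pts <- matrix(runif(2 * n, -1, 1), ncol = 2)
    expect_identical(proj_stub(pts)$quadrant,
                     brute_force_quadrant(pts, pts[n, ]))
  }
})

test_that("label simplification drops the shared quadrant word", {
  in_q <- function(q) {
    centers <- list(I = c(0.5, 0.5), II = c(-0.5, 0.5),
                    III = c(-0.5, -0.5), IV = c(0.5, -0.5))
    proj_stub(rbind(centers[[q]], centers[[q]] * 1.2))
  }
  # I vs IV share "right": vertical split
  lp <- label_pair(in_q("I"), in_q("IV"))
  expect_equal(lp$onpath_text, "go up")
  expect_equal(lp$sibling_text, "go down")
  expect_equal(lp$onpath_label, "up-right")
  # II vs I share "up": horizontal split
  lp2 <- label_pair(in_q("II"), in_q("I"))
  expect_equal(lp2$onpath_text, "go left")
  expect_equal(lp2$sibling_text, "go right")
  # I/II vs III/IV -> up vs down
  lp3 <- label_pair(in_q("II"), in_q("III"))
  expect_equal(lp3$onpath_text, "go up")
  expect_equal(lp3$sibling_text, "go down")
  # diagonal pair uses the vertical rule
  lp4 <- label_pair(in_q("I"), in_q("III"))
  expect_equal(c(lp4$onpath_text, lp4$sibling_text), c("go up", "go down"))
  # same quadrant: split along the axis of larger mean separation
  a <- proj_stub(rbind(c(0.55, 0.1), c(0.45, 0.1)))
  b <- proj_stub(rbind(c(0.1, 0.55), c(0.1, 0.45)))
  lp5 <- label_pair(a, b)
  expect_true(all(c(lp5$onpath_text, lp5$sibling_text) %in%
                    c("go right", "go left", "go up", "go down")))
  expect_false(lp5$onpath_text == lp5$sibling_text)
  a2 <- proj_stub(rbind(c(0.9, 0.1), c(0.8, 0.12)))
  b2 <- proj_stub(rbind(c(0.1, 0.12), c(0.2, 0.1)))
  lp6 <- label_pair(a2, b2)   # x-separation dominates
  expect_equal(c(lp6$onpath_text, lp6$sibling_text), c("go right", "go left"))
})

test_that("instruction words come from the fixed vocabulary", {
  tree <- fix_camera_truth(5)
  leaves <- tree$nodes[tree$nodes$kind == "leaf", ]
  for (li in c(2, 9, 14)) {
    les <- unlist(leaves[li, c("x", "y", "z")])
    p <- root_path(tree, closest_airway_point(tree, les))
    rmp <- encode_instructions(p, tree)
    for (ins in rmp$instructions)
      expect_true(ins$text %in% bronchonav:::INSTRUCTION_TEXTS)
  }
})

test_that("camera-alternating phantoms alternate horizontal/vertical words", {
  tree <- fix_camera_truth(5)
  leaves <- tree$nodes[tree$nodes$kind == "leaf", ]
  set.seed(21)
  for (li in sample(nrow(leaves), 6)) {
    les <- unlist(leaves[li, c("x", "y", "z")])
    p <- root_path(tree, closest_airway_point(tree, les))
    rmp <- encode_instructions(p, tree)
    fams <- vapply(rmp$instructions, function(i)
      if (i$text %in% c("go left", "go right")) "H"
      else if (i$text %in% c("go up", "go down")) "V" else "?", character(1))
    expect_equal(fams, rep(c("H", "V"), length.out = length(fams)))
  }
})

test_that("instruction count is segments minus one; trachea anchor gives none", {
  tree <- fix_camera_truth(4)
  poly <- tree$segments[[tree$root_id, which(tree$nodes$level == 1L)]]
  p1 <- root_path(tree, closest_airway_point(tree, poly[3, ] + c(2, 0, 0)))
  rm1 <- encode_instructions(p1, tree)
  expect_length(rm1$instructions, 0L)
  leaf <- tree$nodes[tree$nodes$kind == "leaf", ][1, ]
  p2 <- root_path(tree, closest_airway_point(tree,
                                             c(leaf$x, leaf$y, leaf$z)))
  rm2 <- encode_instructions(p2, tree)
  expect_length(rm2$instructions, length(p2$segments) - 1L)
})

test_that("close bifurcations are flagged and optionally merged", {
  spec <- generate_phantom_spec(4, seed = 5, plane_mode = "camera",
                                jitter_sd = 0,
                                close_bifurcation = list(level = 2,
                                                         length_mm = 4))
  tree <- truth_tree(spec)
  b <- spec$branches
  short_id <- b$id[b$level == 2 & b$length_mm == 4][1]
  desc <- short_id
  repeat {
    kids <- b$id[!is.na(b$parent) & b$parent %in% desc]
    if (!length(setdiff(kids, desc))) break
    desc <- union(desc, kids)
  }
  leafb <- b[b$id %in% desc & !(b$id %in% b$parent), ][1, ]
  lesion <- c(leafb$x0, leafb$y0, leafb$z0) +
    leafb$length_mm * c(leafb$dx, leafb$dy, leafb$dz)
  p <- root_path(tree, closest_airway_point(tree, lesion))
  rm1 <- encode_instructions(p, tree, close_mm = 6)
  flags <- vapply(rm1$instructions, function(i) i$flags$close_levels,
                  logical(1))
  expect_equal(which(flags), 2L)     # the step before the close bifurcation
  rm2 <- encode_instructions(p, tree, close_mm = 6, merge_close = TRUE)
  expect_length(rm2$instructions, length(rm1$instructions) - 1L)
  merged <- rm2$instructions[[2]]
  expect_true(merged$flags$merged)
  expect_equal(merged$merged_levels, c(2, 3))
  # with a tighter threshold nothing is close
  rm3 <- encode_instructions(p, tree, close_mm = 2)
  expect_false(any(vapply(rm3$instructions, function(i)
    i$flags$close_levels, logical(1))))
})

test_that("mirror, roll, and rescale equivariances hold exactly", {
  set.seed(77)
  opposite <- c("go up" = "go down", "go down" = "go up",
                "go left" = "go right", "go right" = "go left",
                "go up-right" = "go down-left",
                "go down-left" = "go up-right",
                "go up-left" = "go down-right",
                "go down-right" = "go up-left")
  swap_lr <- c("go up" = "go up", "go down" = "go down",
               "go left" = "go right", "go right" = "go left",
               "go up-right" = "go up-left", "go up-left" = "go up-right",
               "go down-left" = "go down-right",
               "go down-right" = "go down-left")
  for (rep in 1:60) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    a <- matrix(runif(2 * n1, -1, 1), ncol = 2)
    b <- matrix(runif(2 * n2, -1, 1), ncol = 2)
    base <- label_pair(proj_stub(a), proj_stub(b))
    # mirror across the vertical (up) axis: x -> -x
    mir <- label_pair(proj_stub(cbind(-a[, 1], a[, 2])),
                      proj_stub(cbind(-b[, 1], b[, 2])))
    expect_equal(mir$onpath_text, unname(swap_lr[base$onpath_text]))
    expect_equal(mir$sibling_text, unname(swap_lr[base$sibling_text]))
    # 180-degree roll: (x, y) -> (-x, -y)
    rot <- label_pair(proj_stub(-a), proj_stub(-b))
    expect_equal(rot$onpath_text, unname(opposite[base$onpath_text]))
    expect_equal(rot$sibling_text, unname(opposite[base$sibling_text]))
    # positive rescaling changes nothing
    s <- runif(1, 0.1, 50)
    scl <- label_pair(proj_stub(s * a), proj_stub(s * b))
    expect_identical(scl$onpath_text, base$onpath_text)
    expect_identical(scl$sibling_text, base$sibling_text)
  }
})

test_that("scene-level mirror reflection swaps left and right words", {
  tree <- fix_camera_truth(4)
  leaf <- tree$nodes[tree$nodes$kind == "leaf", ][2, ]
  p <- root_path(tree, closest_airway_point(tree, c(leaf$x, leaf$y, leaf$z)))
  rm1 <- encode_instructions(p, tree)
  # reflect the whole phantom across the x = 64 plane (the camera vertical
  # plane at the carina) and re-run
  spec <- generate_phantom_spec(4, seed = 3, plane_mode = "camera",
                                jitter_sd = 0)
  spec$branches$x0 <- 128 - spec$branches$x0
  spec$branches$dx <- -spec$branches$dx
  tree_m <- truth_tree(spec)
  lesion_m <- c(128 - leaf$x, leaf$y, leaf$z)
  p_m <- root_path(tree_m, closest_airway_point(tree_m, lesion_m))
  rm_m <- encode_instructions(p_m, tree_m)
  swap_lr <- c("go up" = "go up", "go down" = "go down",
               "go left" = "go right", "go right" = "go left")
  for (i in seq_along(rm1$instructions))
    expect_equal(rm_m$instructions[[i]]$text,
                 unname(swap_lr[rm1$instructions[[i]]$text]))
})

test_that("roadmap export writes text/JSON, honors format flags, round-trips", {
  tree <- fix_camera_truth(4)
  leaf <- tree$nodes[tree$nodes$kind == "leaf", ][1, ]
  p <- root_path(tree, closest_airway_point(tree, c(leaf$x, leaf$y, leaf$z)))
  rmp <- encode_instructions(p, tree)
  d1 <- tempfile("rm_txt_")
  files <- export_roadmap(rmp, d1, formats = c("json", "txt"))
  expect_false(any(grepl("\\.png$", files)))
  expect_length(readLines(file.path(d1, "roadmap.txt")),
                length(rmp$instructions))
  back <- read_roadmap_json(file.path(d1, "roadmap.json"))
  expect_equal(length(back$instructions), length(rmp$instructions))
  for (i in seq_along(rmp$instructions)) {
    expect_equal(back$instructions[[i]]$text, rmp$instructions[[i]]$text)
    expect_equal(back$instructions[[i]]$flags, rmp$instructions[[i]]$flags)
  }
  for (i in seq_along(rmp$projections)) {
    expect_equal(back$projections[[i]]$camera$position,
                 unname(rmp$projections[[i]]$camera$position))
    for (s in names(rmp$projections[[i]]$segments))
      expect_equal(back$projections[[i]]$segments[[s]]$points2d,
                   rmp$projections[[i]]$segments[[s]]$points2d,
                   tolerance = 1e-12)
  }
  expect_equal(back$n_segments, rmp$n_segments)
  # png panels appear only when requested
  d2 <- tempfile("rm_png_")
  files2 <- export_roadmap(rmp, d2, formats = c("txt", "png"))
  expect_true(file.exists(file.path(d2, "mosaic.png")))
  expect_length(list.files(d2, pattern = "bifurcation_.*png"),
                length(rmp$instructions))
  # empty roadmap is rejected unless allowed
  pt <- root_path(tree, closest_airway_point(
    tree, tree$segments[[tree$root_id, which(tree$nodes$level == 1)]][2, ]))
  rme <- encode_instructions(pt, tree)
  expect_error(export_roadmap(rme, tempfile()), "empty")
  expect_silent(export_roadmap(rme, tempfile(), formats = "txt",
                               allow_empty = TRUE))
})
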