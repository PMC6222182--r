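# CT volume I/O, coordinate transforms, surface meshing, OBJ export.

test_that("affine transforms are exact inverses and honor spacing", {
  aff <- diag(4)
  aff[1:3, 4] <- c(10, 20, 30)
  vol <- ct_volume(array(0, c(4, 4, 4)), aff)
  expect_equal(world_from_voxel(vol, c(0, 0, 0)), c(10, 20, 30))

  aff2 <- diag(c(0.5, 1, 1, 1))
  vol2 <- ct_volume(array(0, c(8, 8, 8)), aff2)
  expect_equal(world_from_voxel(vol2, c(1, 0, 0)) -
                 world_from_voxel(vol2, c(0, 0, 0)),
               c(0.5, 0, 0))

  # oblique affine round trip on random points
  set.seed(42)
  aff3 <- diag(4)
  aff3[1:3, 1:3] <- matrix(rnorm(9), 3) + diag(3) * 3
  aff3[1:3, 4] <- rnorm(3, sd = 20)
  vol3 <- ct_volume(array(0, c(4, 4, 4)), aff3)
  pts <- matrix(runif(300, -10, 50), ncol = 3)
  back <- voxel_from_world(vol3, world_from_voxel(vol3, pts))
  expect_lt(max(abs(back - pts)), 1e-6)

  expect_error(ct_volume(array(0, c(2, 2, 2)), matrix(0, 4, 4)), "singular")
})

test_that("NIfTI round trip preserves voxels, spacing, and affine", {
  spec <- generate_phantom_spec(2, seed = 7, trachea_length_mm = 12,
                                trachea_radius_mm = 3,
                                root_start = c(16, 16, 28))
  vol <- rasterize_phantom(spec, c(48L, 48L, 64L), c(0.7, 0.7, 0.5))
  expect_equal(unname(vol$spacing), c(0.7, 0.7, 0.5))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  vol2 <- load_volume(f, "nifti")
  expect_equal(dim(vol2$voxels), dim(vol$voxels))
  expect_lt(max(abs(vol2$voxels - vol$voxels)), 1e-4)
  expect_lt(max(abs(vol2$affine - vol$affine)), 1e-4)
  expect_equal(unname(vol2$spacing), c(0.7, 0.7, 0.5), tolerance = 1e-5)
})

test_that("DICOM series load sorts slices spatially and rescales to HU", {
  dir <- gen_dicom_fixture("series")
  vol <- load_volume(dir, "dicom_dir")
  expect_equal(dim(vol$voxels), c(8L, 6L, 3L))
  # stored value 0 + slope 1 / intercept -1024, slice k adds 100k;
  # InstanceNumber is anti-correlated with position, so correct HU per
  # slice proves spatial sorting
  expect_equal(vol$voxels[1, 1, ], c(-1024, -924, -824))
  # affine reproduces the slice origins and pixel spacing
  expect_equal(world_from_voxel(vol, c(0, 0, 0)), c(10, 20, 30))
  expect_equal(world_from_voxel(vol, c(0, 0, 2)), c(10, 20, 35))
  expect_equal(unname(vol$spacing), c(0.5, 0.7, 2.5))
})

test_that("single-slice DICOM with slope 1 / intercept -1024 maps 1024 to 0 HU", {
  dir <- gen_dicom_fixture("onepix")
  vol <- load_volume(dir, "dicom_dir")
  expect_true(all(vol$voxels == 0))
})

test_that("mixed series and missing rescale tags are rejected", {
  expect_error(load_volume(gen_dicom_fixture("mixed"), "dicom_dir"),
               "mixed DICOM series")
  expect_error(load_volume(gen_dicom_fixture("noslope"), "dicom_dir"),
               "Rescale")
})

test_that("surface of a single voxel is a ~1 mm cube and input is not mutated", {
  m <- array(FALSE, c(5, 5, 5))
  m[3, 3, 3] <- TRUE
  m0 <- m
  mesh <- extract_surface(m)
  bb <- apply(mesh$vertices, 2, function(v) diff(range(v)))
  expect_equal(unname(bb), c(1, 1, 1), tolerance = 1e-9)
  expect_identical(m, m0)
  expect_error(extract_surface(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("cylinder surface area is within 15% of the analytic value", {
  mask <- fix_tube_mask()
  mesh <- extract_surface(mask)
  analytic <- 2 * pi * 4 * 40 + 2 * pi * 16  # lateral + caps
  expect_lt(abs(mesh_area(mesh) - analytic) / analytic, 0.15)
})

test_that("OBJ write/read round trip is the identity", {
  mesh <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.5, -2)),
                   matrix(c(1L, 2L, 3L), 1))
  f <- tempfile(fileext = ".obj")
  write_obj(mesh, f)
  lines <- readLines(f)
  expect_length(grep("^v ", lines), 3L)
  expect_length(grep("^f ", lines), 1L)
  back <- read_obj(f)
  expect_equal(back$vertices, mesh$vertices, tolerance = 1e-9)
  expect_identical(back$faces, mesh$faces)

  big <- extract_surface(fix_tube_mask())
  f2 <- tempfile(fileext = ".obj")
  write_obj(big, f2)
  back2 <- read_obj(f2)
  expect_lt(max(abs(back2$vertices - big$vertices)), 1e-6)
  expect_identical(back2$faces, big$faces)

  expect_error(tri_mesh(diag(3), matrix(integer(0), ncol = 3)), "no faces")
  expect_error(tri_mesh(diag(3), matrix(c(1L, 1L, 2L), 1)), "degenerate")
  expect_error(tri_mesh(diag(3), matrix(c(1L, 2L, 4L), 1)), "out of range")
})
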