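test_that("surface extraction recovers shape, topology and multiplicity", {
  # voxelized sphere R = 50: one watertight chi = 2 mesh, V within 2%
  vx <- sphere_scene(R = 50, spacing = 2.5)
  meshes <- extract_surface(lumen_solid(otsu_mask(vx$apical)))
  expect_length(meshes, 1)
  m <- meshes[[1]]
  expect_true(is_watertight(m))
  expect_identical(euler_characteristic(m), 2L)
  expect_lt(abs(volume_area(m)$V / 5.235988e5 - 1), 0.02)

  # voxelized torus: chi = 0
  vt <- cached("scene_torus", voxelize(synthetic_scene(
    shape_spec("torus", R = 40, tube_r = 15), voxel_spacing = rep(1.5, 3))))
  mt <- extract_surface(lumen_solid(otsu_mask(vt$apical)))
  expect_length(mt, 1)
  expect_identical(euler_characteristic(mt[[1]]), 0L)

  # two disjoint spheres: two meshes
  v2 <- cached("scene_2spheres", voxelize(synthetic_scene(
    list(shape_spec("sphere", R = 12, center = c(-22, 0, 0)),
         shape_spec("sphere", R = 12, center = c(22, 0, 0))),
    voxel_spacing = rep(1.5, 3))))
  m2 <- extract_surface(lumen_solid(otsu_mask(v2$apical)))
  expect_length(m2, 2)

  # empty mask: empty list
  empty <- segmentation_mask(array(0L, c(8, 8, 8)), rep(1, 3))
  expect_length(extract_surface(empty), 0)
})

test_that("border-touching components are closed by padding", {
  a <- array(FALSE, c(12, 12, 12))
  a[1:6, 4:9, 4:9] <- TRUE   # touches the x = 1 border
  meshes <- extract_surface(a, spacing = rep(1, 3), smooth_sigma = 0,
                            taubin_iterations = 0)
  expect_length(meshes, 1)
  expect_true(is_watertight(meshes[[1]]))
  expect_identical(euler_characteristic(meshes[[1]]), 2L)
})

test_that("clean_mesh leaves a clean icosphere unchanged in volume and chi", {
  m <- unit_icosphere(3)
  m2 <- clean_mesh(m, tol = 1e-4)
  expect_identical(euler_characteristic(m2), 2L)
  expect_lt(abs(volume_area(m2)$V / volume_area(m)$V - 1), 0.001)
})

test_that("clean_mesh removes duplicated faces, restoring chi = 2", {
  t <- icosphere(1, 1)
  td <- t
  td$faces <- rbind(td$faces, td$faces[1, ])
  expect_false(is_watertight(td))
  tc <- lumentopo:::drop_duplicate_faces(td)
  expect_identical(euler_characteristic(tc), 2L)
})

test_that("short-edge collapse decimates a dense extraction within 1% volume", {
  vx <- sphere_scene(R = 50, spacing = 2.5)
  m <- extract_surface(lumen_solid(otsu_mask(vx$apical)))[[1]]
  v_pre <- volume_area(m)$V
  mc <- clean_mesh(m, min_voxel_len = 2.5)   # tolerance 2 x voxel
  expect_lt(nrow(mc$faces), nrow(m$faces))
  expect_true(is_watertight(mc))
  expect_identical(euler_characteristic(mc), 2L)
  expect_lt(abs(volume_area(mc)$V / v_pre - 1), 0.01)
  # no remaining edge shorter than the tolerance except protected ones;
  # the bulk of the histogram must sit above it
  de <- lumentopo:::directed_edges(mc$faces)
  len <- sqrt(rowSums((mc$vertices[de[, 1], ] - mc$vertices[de[, 2], ])^2))
  expect_lt(mean(len < 2 * 2.5), 0.02)
})

test_that("clean_mesh preserves the genus of a high-genus surface", {
  w <- ref_wiffle(4)
  wc <- clean_mesh(w, tol = 0.02)
  expect_identical(mesh_genus(wc), 3L)
  expect_lt(abs(volume_area(wc)$V / volume_area(w)$V - 1), 0.01)
})

test_that("split_lobules counts closed components and reports defects", {
  meshes <- list(icosphere(5, 2), icosphere(3, 2), icosphere(2, 2))
  ls <- split_lobules(meshes)
  expect_identical(ls$N, 3L)

  # one closed high-genus component is still a single lobule
  expect_identical(split_lobules(list(ref_wiffle(4)))$N, 1L)
  expect_identical(split_lobules(list(icosphere(1, 2)))$N, 1L)

  broken <- icosphere(1, 2)
  broken$faces <- broken$faces[-1, , drop = FALSE]
  expect_warning(ls2 <- split_lobules(list(broken, icosphere(1, 2))),
                 "non-watertight")
  expect_identical(ls2$N, 1L)
})

test_that("mesh PLY and OFF round trips preserve geometry and topology", {
  m <- ref_torus()
  pf <- withr::local_tempfile(fileext = ".ply")
  write_ply(m, pf)
  mp <- read_ply(pf)
  expect_identical(euler_characteristic(mp), 0L)
  expect_equal(mp$vertices, m$vertices, tolerance = 1e-12)
  of <- withr::local_tempfile(fileext = ".off")
  write_off(m, of)
  mo <- read_off(of)
  expect_equal(volume_area(mo)$V, volume_area(m)$V, tolerance = 1e-12)
})
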