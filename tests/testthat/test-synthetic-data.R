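test_that("generated meshes carry the intended topology and geometry", {
  # sphere: chi = 2 and V within 1% of (4/3) pi R^3
  s <- gen_mesh(shape_spec("sphere", R = 50), resolution = 4)
  expect_identical(euler_characteristic(s), 2L)
  expect_lt(abs(volume_area(s)$V / 5.235988e5 - 1), 0.01)

  # torus: chi = 0, g = 1
  t <- ref_torus()
  expect_identical(euler_characteristic(t), 0L)
  expect_identical(mesh_genus(t), 1L)

  # wiffle ball with 4 passages: g = 3, chi = -4
  w <- ref_wiffle(4)
  expect_identical(mesh_genus(w), 3L)
  expect_identical(euler_characteristic(w), -4L)
})

test_that("angle-defect Gauss-Bonnet sum matches 2*pi*chi for every family", {
  meshes <- list(unit_icosphere(3), ref_torus(), ref_wiffle(4),
                 gen_mesh(shape_spec("spherocylinder", R = 1, L_over_r = 5)))
  for (m in meshes) {
    gb <- gauss_bonnet_check(m)
    expect_lt(gb$residual, 1e-6 * abs(gb$expected) + 1e-6)
  }
})

test_that("degenerate shape specs are rejected with a message", {
  expect_error(shape_spec("wiffle_ball", R = 10, h_s = 12), "degenerate")
  expect_error(shape_spec("wiffle_ball", R = 10, n_passages = 4,
                          d_over_R = 1.2), "degenerate")
  expect_error(shape_spec("wiffle_ball", R = 10, n_passages = 50,
                          d_over_R = 0.9), "degenerate")
  expect_error(shape_spec("sphere", R = -1), "positive")
  expect_error(shape_spec("spherocylinder", R = 1, L_over_r = -2), "L_over_r")
  expect_error(shape_spec("torus", R = 1, tube_r = 2), "tube_r")
})

test_that("generated meshes are watertight with at least 500 faces", {
  for (m in list(unit_icosphere(3), ref_torus(), ref_wiffle(2)))
    expect_true(is_watertight(m))
  expect_gte(nrow(ref_wiffle(2)$faces), 500)
  expect_warning(gen_mesh(shape_spec("sphere", R = 1), resolution = 1),
                 "fewer than 500 faces")
})

test_that("voxelization records ground truth and respects grid bounds", {
  vx <- sphere_scene(R = 50, spacing = 2.5)
  expect_identical(vx$truth$N, 1L)
  expect_identical(vx$truth$g, 0L)
  expect_equal(vx$truth$V, 4 / 3 * pi * 50^3)

  two <- voxelize(synthetic_scene(
    list(shape_spec("sphere", R = 12, center = c(-22, 0, 0)),
         shape_spec("sphere", R = 12, center = c(22, 0, 0))),
    voxel_spacing = rep(2, 3)))
  expect_identical(two$truth$N, 2L)

  expect_error(voxelize(synthetic_scene(shape_spec("sphere", R = 30),
                                        voxel_spacing = rep(2, 3)),
                        grid_dim = c(10, 10, 10)),
               "exceed")
})

test_that("overlapping specs are rejected unless explicitly allowed", {
  expect_error(synthetic_scene(
    list(shape_spec("sphere", R = 12), shape_spec("sphere", R = 12,
                                                  center = c(5, 0, 0))),
    voxel_spacing = rep(2, 3)), "overlap")
  expect_s3_class(synthetic_scene(
    list(shape_spec("sphere", R = 12), shape_spec("sphere", R = 12,
                                                  center = c(5, 0, 0))),
    voxel_spacing = rep(2, 3), allow_overlap = TRUE), "synthetic_scene")
})

test_that("identical seeds give bit-identical scenes", {
  mk <- function() voxelize(synthetic_scene(shape_spec("sphere", R = 15),
                                            voxel_spacing = rep(1.5, 3),
                                            noise_sd = 5, seed = 11))
  a <- mk(); b <- mk()
  expect_identical(a$apical$data, b$apical$data)
  expect_identical(a$whole_tissue$data, b$whole_tissue$data)
})

test_that("fusion series expose the constructed N and g sequences", {
  tr <- gen_fusion_series("trans", n_steps = 5, seed = 1)
  expect_identical(attr(tr, "N_true"), c(2L, 2L, 1L, 1L, 1L))
  expect_identical(attr(tr, "g_true"), rep(0L, 5))
  ci <- gen_fusion_series("cis", n_steps = 5, seed = 1)
  expect_identical(attr(ci, "N_true"), rep(1L, 5))
  expect_identical(attr(ci, "g_true"), c(0L, 0L, 1L, 1L, 1L))
  expect_error(gen_fusion_series("trans", n_steps = 2), "n_steps")
})

test_that("trans series conserves total lumen volume across the merge", {
  tr <- gen_fusion_series("trans", n_steps = 5, seed = 1)
  vols <- vapply(tr, function(sc)
    sum(vapply(sc$specs, function(s) lumentopo:::shape_truth(s)$V,
               numeric(1))), numeric(1))
  expect_true(all(abs(vols / vols[1] - 1) < 0.02))
})
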