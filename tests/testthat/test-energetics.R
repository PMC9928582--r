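test_that("per-face mean curvature is consistent and locally accurate", {
  ico <- unit_icosphere(4)
  fc <- face_mean_curvature(ico)
  # exact bookkeeping: sum H_i A_i = M
  expect_equal(sum(fc$H * fc$A), integral_mean_curvature(ico),
               tolerance = 1e-12)
  # H ~ 1/R = 1 with small spread on a quasi-uniform sphere
  expect_lt(abs(mean(fc$H) - 1), 0.01)
  expect_lt(stats::sd(fc$H) / mean(fc$H), 0.05)
  # cylinder tube: H ~ 1/(2r) away from the caps
  sc <- spherocylinder_mesh(1, 10, n_theta = 64)
  fcs <- face_mean_curvature(sc)
  cz <- (sc$vertices[sc$faces[, 1], 3] + sc$vertices[sc$faces[, 2], 3] +
         sc$vertices[sc$faces[, 3], 3]) / 3
  tube <- abs(cz) < 4
  expect_lt(abs(mean(fcs$H[tube]) - 0.5), 0.02)
  # cube: H ~ 0 on planar face interiors (all curvature is on edges)
  cube_fc <- face_mean_curvature(unit_cube_mesh())
  expect_equal(sum(cube_fc$H * cube_fc$A),
               integral_mean_curvature(unit_cube_mesh()), tolerance = 1e-12)
})

test_that("bending energy of a sphere is 4*pi plus the topological term", {
  be0 <- bending_energy(unit_icosphere(4), 0)
  expect_lt(abs(be0$total / (4 * pi) - 1), 0.01)
  be1 <- bending_energy(unit_icosphere(4), 1)
  expect_lt(abs(be1$total / (8 * pi) - 1), 0.01)
  # torus: N - g = 0, topological term vanishes for any rigidity
  bt <- bending_energy(ref_torus(), c(-2, 0.7, 5))
  expect_true(all(bt$topological_term == 0))
  expect_equal(bt$total, bt$bending_term)
})

test_that("bending term is invariant under uniform rescaling", {
  for (m in list(unit_icosphere(3), ref_torus())) {
    b1 <- bending_energy(m, 0)$bending_term
    m2 <- m
    m2$vertices <- m$vertices * 41.7
    b2 <- bending_energy(m2, 0)$bending_term
    expect_lt(abs(b2 / b1 - 1), 1e-8)
  }
})

test_that("Gauss-Bonnet residual is at floating-point level on exact meshes", {
  tet <- tetrahedron_mesh()
  gb <- gauss_bonnet_check(tet)
  expect_equal(gb$defect_sum, 4 * pi, tolerance = 1e-12)
  expect_equal(gauss_bonnet_check(ref_torus())$defect_sum, 0,
               tolerance = 1e-9)
  gbw <- gauss_bonnet_check(ref_wiffle(4))
  expect_equal(gbw$defect_sum, -8 * pi, tolerance = 1e-6)
})

test_that("fusion energy changes follow the topological formulas", {
  expect_equal(fusion_energy_change("trans", 0), -4 * pi)
  expect_equal(fusion_energy_change("trans", -1), 0)
  expect_equal(fusion_energy_change("cis", 0), 0)
  expect_equal(fusion_energy_change("cis", 2), -8 * pi)
  expect_equal(fusion_energy_change("trans", c(-1, 0, 1)),
               -4 * pi * c(0, 1, 2))
})

test_that("mesh-based trans fusion energy matches the analytic change", {
  # two unit spheres merge into the volume-equivalent sphere
  two <- list(unit_icosphere(4), unit_icosphere(4))
  one <- list(icosphere(2^(1 / 3), 4))
  for (kk in c(-1.5, -0.5, 0, 1)) {
    dE <- bending_energy(one, kk)$total - bending_energy(two, kk)$total
    ref <- fusion_energy_change("trans", kk)
    if (abs(ref) > 1e-9) {
      expect_lt(abs(dE / ref - 1), 0.05)
    } else {
      expect_lt(abs(dE), 0.05 * 4 * pi)
    }
  }
})

test_that("region classification matches the signs of the energy changes", {
  expect_identical(classify_region(-1.5), "I")
  expect_identical(classify_region(-0.5), "II")
  expect_identical(classify_region(0.5), "III")
  expect_identical(classify_region(c(-1, 0)), c("marginal", "marginal"))
  kk <- c(-3, -1.2, -0.7, -0.2, 0.3, 2)
  reg <- classify_region(kk)
  tr <- fusion_energy_change("trans", kk)
  ci <- fusion_energy_change("cis", kk)
  expect_identical(reg == "I", tr > 0 & ci > 0)
  expect_identical(reg == "II", tr < 0 & ci >= 0)
  expect_identical(reg == "III", tr < 0 & ci < 0)
})

test_that("energy time series spans the requested rigidity family", {
  frames <- list(list(unit_icosphere(2), unit_icosphere(2)),
                 list(unit_icosphere(2)))
  et <- energy_timeseries(frames, kbar_over_k = c(-0.5, 0.5), times = c(0, 1))
  expect_identical(nrow(et), 4L)
  # the energy drop across the trans fusion is steeper at higher kbar/kappa
  drop_lo <- diff(et$total[et$kbar_over_k == -0.5])
  drop_hi <- diff(et$total[et$kbar_over_k == 0.5])
  expect_lt(drop_hi, drop_lo)
  expect_lt(drop_hi, 0)
})
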