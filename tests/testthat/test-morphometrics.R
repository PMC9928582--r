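test_that("Euler characteristic and genus follow V - E + F on exact meshes", {
  tet <- tetrahedron_mesh()
  expect_identical(euler_characteristic(tet), 2L)   # 4 - 6 + 4
  expect_identical(euler_characteristic(ref_torus()), 0L)
  expect_identical(euler_characteristic(ref_wiffle(4)), -4L)
  expect_identical(genus_from_chi(2L), 0L)
  expect_identical(genus_from_chi(0L), 1L)
  expect_identical(genus_from_chi(-4L), 3L)
  expect_error(genus_from_chi(1L), "odd")
  expect_error(genus_from_chi(4L), "chi > 2")
})

test_that("volume and area are exact on polyhedra and convergent on spheres", {
  cube <- unit_cube_mesh()
  va <- volume_area(cube)
  expect_equal(va$V, 1)
  expect_equal(va$A, 6)
  ico <- unit_icosphere(4)
  va2 <- volume_area(ico)
  expect_lt(abs(va2$V / (4 / 3 * pi) - 1), 0.005)
  expect_lt(abs(va2$A / (4 * pi) - 1), 0.005)
  # zero-area faces are rejected
  sliver <- tetrahedron_mesh()
  sliver$vertices[4, ] <- sliver$vertices[1, ]
  expect_error(volume_area(sliver), "zero-area")
  # inward orientation is flipped with a warning
  flipped <- cube
  flipped$faces <- flipped$faces[, c(1, 3, 2)]
  expect_warning(vf <- volume_area(flipped), "orient")
  expect_equal(vf$V, 1)
})

test_that("integral mean curvature converges to closed forms", {
  # sphere R = 1: M -> 4*pi
  expect_lt(abs(integral_mean_curvature(unit_icosphere(4)) / (4 * pi) - 1),
            0.01)
  # torus R0 = 2, a = 1: M -> 2*pi^2*R0
  expect_lt(abs(integral_mean_curvature(ref_torus()) / (2 * pi^2 * 2) - 1),
            0.01)
  # spherocylinder r = 1, L = 10: M -> pi*10 + 4*pi
  sc <- spherocylinder_mesh(1, 10, n_theta = 64)
  expect_lt(abs(integral_mean_curvature(sc) / (pi * 10 + 4 * pi) - 1), 0.01)
})

test_that("lobule metrics hit the sphere anchor and family closed forms", {
  lm <- lobule_metrics(icosphere(37, 4))   # any radius: v = m = 1, g = 0
  expect_lt(abs(lm$v - 1), 0.01)
  expect_lt(abs(lm$m - 1), 0.01)
  expect_identical(lm$g, 0L)

  sc <- lobule_metrics(spherocylinder_mesh(1, 200, n_theta = 48))
  ref <- spherocylinder_vm(200)
  expect_lt(abs(sc$v / ref$v - 1), 0.01)   # ~ 0.149
  expect_lt(abs(sc$m / ref$m - 1), 0.01)   # ~ 5.07

  tm <- lobule_metrics(ref_torus())        # closed forms: v ~ 0.599, m ~ 1.253
  expect_lt(abs(tm$v / 0.5992622 - 1), 0.01)
  expect_lt(abs(tm$m / 1.2533141 - 1), 0.01)
  expect_identical(tm$g, 1L)
})

test_that("v and m are scale invariant and v obeys the isoperimetric bound", {
  for (m in list(unit_icosphere(3), ref_torus(), ref_wiffle(4),
                 spherocylinder_mesh(1, 10, 48))) {
    lm1 <- lobule_metrics(m)
    m2 <- m
    m2$vertices <- m$vertices * 173.2
    lm2 <- lobule_metrics(m2)
    expect_lt(abs(lm2$v - lm1$v), 1e-12)
    expect_lt(abs(lm2$m - lm1$m), 1e-12)
    expect_lte(lm1$v, 1)
  }
  # equality approached only by the sphere
  expect_gt(lobule_metrics(unit_icosphere(4))$v, 0.99)
})

test_that("topology is invariant under mesh refinement", {
  expect_identical(mesh_genus(icosphere(1, 2)), mesh_genus(icosphere(1, 4)))
  w1 <- gen_mesh(shape_spec("wiffle_ball", R = 1, h_s = 0.1, n_passages = 4,
                            d_over_R = 0.3), resolution = 20)
  expect_identical(mesh_genus(w1), mesh_genus(ref_wiffle(4)))
})

test_that("the lumen volume filter excludes lobules below 100 um^3", {
  lob <- data.frame(V = c(50, 99.9, 100, 250), g = c(0L, 0L, 0L, 1L),
                    v = c(1, 1, 0.9, 0.5), m = c(1, 1, 1.1, 2))
  expect_message(kept <- filter_lobules(lob), "excluding 2")
  expect_identical(nrow(kept), 2L)
  expect_true(all(kept$V >= 100))
  # all above threshold: identity; empty input: empty output
  expect_identical(filter_lobules(lob[lob$V >= 100, ]), lob[lob$V >= 100, ])
  expect_identical(nrow(filter_lobules(lob[0, ])), 0L)
})

test_that("aggregation uses volume-weighted averages and total genus", {
  lob <- data.frame(V = c(100, 300), g = c(0L, 0L), v = c(1.0, 0.5),
                    m = c(1, 2))
  st <- aggregate_lobules(lob)
  expect_equal(st$v_avg, 0.625)
  expect_equal(st$m_avg, 1.75)
  expect_identical(st$N, 2L)
  # single lobule: average equals the lobule value
  st1 <- aggregate_lobules(lob[1, ])
  expect_equal(st1$v_avg, 1)
  # three g = 1 lobules: g_total = 3, N = 3
  lob3 <- data.frame(V = rep(10, 3), g = rep(1L, 3), v = rep(0.6, 3),
                     m = rep(1.2, 3))
  st3 <- aggregate_lobules(lob3)
  expect_identical(st3$g_total, 3L)
  expect_identical(st3$N, 3L)
  # zero lobules: flagged with N = 0 and NA averages
  st0 <- aggregate_lobules(lob[0, ])
  expect_identical(st0$N, 0L)
  expect_true(is.na(st0$v_avg))
})

test_that("cell height is the sphere-equivalent radius difference", {
  expect_equal(cell_height(4 * pi * 100^2, 4 * pi * 90^2), 10)
  expect_equal(cell_height(4 * pi, 4 * pi), 0)
  expect_equal(cell_height(4 * pi, pi), 0.5)
  expect_error(cell_height(1, 2), "exceeds")
  expect_error(cell_height(1, 0), "positive")
})
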