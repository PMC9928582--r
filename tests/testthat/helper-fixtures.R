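# session-scoped fixture cache: expensive meshes/scenes are built once per
# test run and shared across test files
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

unit_icosphere <- function(subdiv = 4) {
  cached(paste0("ico", subdiv), icosphere(1, subdiv))
}

ref_torus <- function() cached("torus21", torus_mesh(2, 1, n_major = 96))

ref_wiffle <- function(n = 4) {
  cached(paste0("wiffle", n),
         gen_mesh(shape_spec("wiffle_ball", R = 1, h_s = 0.1,
                             n_passages = n, d_over_R = 0.3),
                  resolution = 24))
}

# noiseless voxelized sphere scene + derived products
sphere_scene <- function(R = 50, spacing = 2.5) {
  key <- paste0("scene_sphere_", R, "_", spacing)
  cached(key, voxelize(synthetic_scene(shape_spec("sphere", R = R),
                                       voxel_spacing = rep(spacing, 3))))
}

sphere_snapshot <- function(R = 50, spacing = 2.5) {
  key <- paste0("snap_sphere_", R, "_", spacing)
  cached(key, suppressMessages(run_snapshot(sphere_scene(R, spacing))))
}

trans_series_result <- function() {
  cached("trans_result", {
    series <- gen_fusion_series("trans", n_steps = 5, seed = 1)
    list(series = series,
         result = suppressMessages(run_timeseries(series)))
  })
}

cis_series_result <- function() {
  cached("cis_result", {
    series <- gen_fusion_series("cis", n_steps = 5, seed = 1)
    list(series = series,
         result = suppressMessages(run_timeseries(series)))
  })
}

# unit cube [0,1]^3 triangulated into 12 outward-oriented triangles
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  surface_mesh(v, f)
}

tetrahedron_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3))
  surface_mesh(v, f)
}
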