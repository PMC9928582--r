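#' Synthetic fusion time series with known topological ground truth
#'
#' Constructs a list of scenes emulating the two fusion modes observed in
#' organoid morphogenesis, as geometric morphs (not mechanical simulations):
#'
#' * `trans`: two spherical lumens of radius `r0` approach and merge into a
#'   single spherocylinder-like body at the merge frame (dN = -1, genus
#'   unchanged). Post-merge frames relax towards a single sphere. The total
#'   enclosed volume is conserved exactly by construction: the post-merge
#'   tube radius is solved from pi*r^2*L + (4/3)*pi*r^3 = 2 * (4/3)*pi*r0^3.
#' * `cis`: a single capped tube bent into a circular arc closes on itself
#'   at the self-contact frame, creating a passage (dg = +1, N unchanged).
#'
#' @param mode `"trans"` or `"cis"`.
#' @param n_steps number of frames (>= 3).
#' @param seed RNG seed recorded into each scene (noise reproducibility).
#' @param r0 sphere radius (trans) / tube radius (cis), um.
#' @param voxel_spacing per-scene voxel spacing (um).
#' @param noise_sd additive intensity noise passed to the scenes.
#' @return list of [synthetic_scene()]s with attributes `N_true` and
#'   `g_true` (integer vectors, one entry per frame).
#' @examples
#' series <- gen_fusion_series("trans", n_steps = 5, seed = 1)
#' attr(series, "N_true")
#' @export
gen_fusion_series <- function(mode = c("trans", "cis"), n_steps = 5L,
                              seed = 1L, r0 = 20,
                              voxel_spacing = rep(r0 / 16, 3),
                              noise_sd = 0) {
  mode <- match.arg(mode)
  n_steps <- as.integer(n_steps)
  if (n_steps < 3L) stop("n_steps must be >= 3")
  merge_at <- n_steps %/% 2L + 1L   # first merged/closed frame
  scenes <- vector("list", n_steps)

  if (mode == "trans") {
    n_pre <- merge_at - 1L
    # closest approach stays > 2 apical shell widths so the pre-merge
    # frames segment as two separate lobules at the default resolution
    gaps <- seq(0.6 * r0, 0.3 * r0, length.out = n_pre)
    v_total <- 2 * (4 / 3) * pi * r0^3
    n_post <- n_steps - n_pre
    # merged body: spherocylinder shrinking in length, radius solved to
    # conserve the total lumen volume; final frame is the volume-equivalent
    # sphere (L = 0)
    Ls <- seq(1.6 * r0, 0, length.out = n_post)
    for (t in seq_len(n_steps)) {
      if (t < merge_at) {
        half <- r0 + gaps[t] / 2
        specs <- list(shape_spec("sphere", R = r0, center = c(-half, 0, 0)),
                      shape_spec("sphere", R = r0, center = c(half, 0, 0)))
      } else {
        L <- Ls[t - n_pre]
        r <- solve_tube_radius(v_total, L)
        specs <- if (L > 0)
          list(shape_spec("spherocylinder", R = r, L_over_r = L / r,
                          axis = c(1, 0, 0)))
        else list(shape_spec("sphere", R = r))
      }
      scenes[[t]] <- synthetic_scene(specs, voxel_spacing, noise_sd,
                                     seed = seed + t)
    }
    N_true <- as.integer(ifelse(seq_len(n_steps) < merge_at, 2L, 1L))
    g_true <- rep(0L, n_steps)
  } else {
    R0 <- 2.2 * r0                   # bending ring radius
    arcs <- c(seq(200, 280, length.out = merge_at - 1L),
              rep(360, n_steps - merge_at + 1L))
    for (t in seq_len(n_steps)) {
      specs <- list(shape_spec("torus", R = R0, tube_r = r0,
                               arc_deg = arcs[t]))
      scenes[[t]] <- synthetic_scene(specs, voxel_spacing, noise_sd,
                                     seed = seed + t)
    }
    N_true <- rep(1L, n_steps)
    g_true <- as.integer(ifelse(seq_len(n_steps) < merge_at, 0L, 1L))
  }
  attr(scenes, "N_true") <- N_true
  attr(scenes, "g_true") <- g_true
  attr(scenes, "mode") <- mode
  scenes
}

# radius of a spherocylinder of length L with prescribed volume
# pi r^2 L + (4/3) pi r^3 = V  (monotone in r, unique positive root)
solve_tube_radius <- function(V, L) {
  if (L <= 0) return((3 * V / (4 * pi))^(1 / 3))
  f <- function(r) pi * r^2 * L + 4 / 3 * pi * r^3 - V
  stats::uniroot(f, c(1e-6, (3 * V / (4 * pi))^(1 / 3) + L), tol = 1e-12)$root
}
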