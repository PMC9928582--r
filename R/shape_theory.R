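#' Reduced volume and curvature of a spherocylinder
#'
#' Closed forms for a cylinder of length L = L_over_r * r capped by
#' hemispheres (r = 1 without loss of generality; v and m are
#' scale-invariant): V = pi*L + 4*pi/3, A = 2*pi*L + 4*pi, and
#' M = pi*L + 4*pi (mean curvature 1/(2r) on the tube, 1/r on the caps).
#'
#' @param L_over_r aspect ratio(s), >= 0; 0 is the sphere limit (v = m = 1).
#' @return data.frame with columns `L_over_r`, `v`, `m`.
#' @examples
#' spherocylinder_vm(c(0, 10, 200))
#' @export
spherocylinder_vm <- function(L_over_r) {
  if (any(L_over_r < 0)) stop("L_over_r must be >= 0")
  L <- L_over_r
  V <- pi * L + 4 * pi / 3
  A <- 2 * pi * L + 4 * pi
  M <- pi * L + 4 * pi
  data.frame(L_over_r = L, v = reduced_volume(V, A),
             m = reduced_curvature(M, A))
}

#' Invert the spherocylinder branch for a target reduced volume
#'
#' Root-finds the aspect ratio whose reduced volume equals `target_v` and
#' returns it with the corresponding reduced curvature. v decreases
#' monotonically from 1 (sphere) along the branch, so the root is unique.
#'
#' @param target_v target reduced volume in (0, 1].
#' @param tol root tolerance on v.
#' @return list with `L_over_r` and `m`.
#' @examples
#' solve_spherocylinder_for_v(0.15)$m  # about 5
#' @export
solve_spherocylinder_for_v <- function(target_v, tol = 1e-6) {
  if (target_v <= 0 || target_v > 1) stop("target_v must be in (0, 1]")
  if (target_v == 1) return(list(L_over_r = 0, m = 1))
  fn <- function(L) spherocylinder_vm(L)$v - target_v
  hi <- 1
  while (fn(hi) > 0) hi <- hi * 2
  if (hi > 2^40) stop("no root found")
  r <- stats::uniroot(fn, c(0, hi), tol = 1e-12)
  if (abs(r$f.root) > tol) stop("root did not converge to tolerance")
  list(L_over_r = r$root, m = spherocylinder_vm(r$root)$m)
}

#' Reduced volume/curvature of a wiffle ball (numeric)
#'
#' Builds the wiffle-ball mesh (spherical shell of relative thickness
#' `h_s_over_R` pierced by `n_passages` passages of relative diameter
#' `d_over_R`) and evaluates the mesh morphometrics on it. The genus is
#' `n_passages - 1`.
#'
#' @param n_passages number of passages (>= 1).
#' @param d_over_R passage diameter / outer radius.
#' @param h_s_over_R shell thickness / outer radius.
#' @param resolution grid cells per radius for the implicit meshing.
#' @return one-row data.frame: `v`, `m`, `g` (plus `V`, `A`, `M`, `chi`).
#' @export
wiffleball_vm <- function(n_passages = 4L, d_over_R = 0.15,
                          h_s_over_R = 0.1, resolution = 48L) {
  spec <- shape_spec("wiffle_ball", R = 1, h_s = h_s_over_R,
                     n_passages = n_passages, d_over_R = d_over_R)
  m <- gen_mesh(spec, resolution = resolution)
  lm <- lobule_metrics(m)
  lm[, c("v", "m", "g", "V", "A", "M", "chi")]
}

#' Guide curve: spherocylinder branch
#'
#' @param L_over_r aspect ratios to sample (default a log-spaced sweep from
#'   sphere to long tube).
#' @return data.frame (`family`, `param`, `v`, `m`) ordered by parameter.
#' @export
spherocylinder_curve <- function(L_over_r = c(0, exp(seq(log(0.1), log(500),
                                                         length.out = 60)))) {
  vm <- spherocylinder_vm(L_over_r)
  data.frame(family = "spherocylinder", param = L_over_r, v = vm$v, m = vm$m)
}

#' Guide curve: wiffle-ball branch
#'
#' Sweeps a wiffle-ball parameter and evaluates (v, m) on constructed
#' meshes. The default sweeps the passage diameter at four passages; the
#' shell thickness can be swept instead.
#'
#' @param d_over_R passage-diameter sweep values.
#' @param n_passages passages (fixed along the sweep).
#' @param h_s_over_R shell thickness ratio(s); scalar or same length as
#'   `d_over_R`.
#' @param resolution implicit meshing resolution.
#' @return data.frame (`family`, `param`, `v`, `m`) ordered by parameter.
#' @export
wiffleball_curve <- function(d_over_R = seq(0.1, 0.6, by = 0.1),
                             n_passages = 4L, h_s_over_R = 0.1,
                             resolution = 40L) {
  h <- rep_len(h_s_over_R, length(d_over_R))
  rows <- lapply(seq_along(d_over_R), function(i) {
    vm <- wiffleball_vm(n_passages, d_over_R[i], h[i], resolution)
    data.frame(family = "wiffle_ball", param = d_over_R[i],
               v = vm$v, m = vm$m)
  })
  do.call(rbind, rows)
}

#' Shape diagram of organoid states over guide curves
#'
#' Plots measured organoid states at their volume-weighted (\<v\>, \<m\>)
#' over the spherocylinder / wiffle-ball guide branches; in trajectory mode
#' time-ordered states are connected.
#'
#' @param states data.frame with columns `v_avg`, `m_avg` (and optionally
#'   `time_h`), e.g. rows from [aggregate_lobules()].
#' @param curves data.frame of guide curves (rows from
#'   [spherocylinder_curve()] / [wiffleball_curve()]), or `NULL` for points
#'   only.
#' @param trajectory connect states in time order.
#' @return a ggplot object.
#' @export
plot_shape_diagram <- function(states, curves = spherocylinder_curve(),
                               trajectory = FALSE) {
  p <- ggplot2::ggplot()
  if (!is.null(curves) && nrow(curves) > 0)
    p <- p + ggplot2::geom_path(
      data = curves,
      ggplot2::aes(x = .data$m, y = .data$v, linetype = .data$family))
  if (trajectory && nrow(states) > 1)
    p <- p + ggplot2::geom_path(
      data = states, ggplot2::aes(x = .data$m_avg, y = .data$v_avg),
      colour = "grey50")
  p + ggplot2::geom_point(
        data = states,
        ggplot2::aes(x = .data$m_avg, y = .data$v_avg),
        colour = "#1f77b4") +
    ggplot2::labs(x = "reduced curvature ⟨m⟩",
                  y = "reduced volume ⟨v⟩") +
    ggplot2::coord_cartesian(ylim = c(0, 1.05)) +
    ggplot2::theme_minimal()
}
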