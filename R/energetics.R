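#' Per-face mean curvature and area
#'
#' Distributes the edge-dihedral mean-curvature measure (1/2 * l_e *
#' theta_e) over the two faces adjacent to each edge (half each), so that
#' sum(H_i * A_i) over faces equals the integral mean curvature exactly.
#' H_i is the distributed measure divided by the face area.
#'
#' @param mesh a watertight, oriented `surface_mesh`.
#' @return data.frame with per-face `H` (1/um) and `A` (um^2).
#' @export
face_mean_curvature <- function(mesh) {
  d <- mesh_defects(mesh)
  if (!is.null(d)) stop("mesh is not a closed oriented manifold: ", d)
  ed <- edge_dihedrals(mesh)
  A <- face_areas(mesh)
  w <- 0.5 * ed$length * ed$theta     # edge measure, sums to M
  HA <- rep(0, nrow(mesh$faces))
  acc1 <- tapply(w / 2, ed$face1, sum)
  acc2 <- tapply(w / 2, ed$face2, sum)
  HA[as.integer(names(acc1))] <- HA[as.integer(names(acc1))] + acc1
  HA[as.integer(names(acc2))] <- HA[as.integer(names(acc2))] + acc2
  data.frame(H = HA / A, A = A)
}

#' Discrete Helfrich bending energy of a lobule set
#'
#' The bending energy of a fluid surface is E_b = integral of
#' (kappa * H^2 + kappa_bar * K) dA. By Gauss-Bonnet the Gaussian term only
#' depends on the topology, integral K dA = 4*pi*(N - g), so the scaled
#' energy is estimated from the triangulations as
#' E_b / kappa = sum_i H_i^2 A_i + 4*pi*(kbar/kappa)*(N - g), with i
#' traversing all faces of all lobules.
#'
#' @param lobules list of watertight `surface_mesh` (or a `lobule_set`, or a
#'   single mesh).
#' @param kbar_over_k reduced Gaussian rigidity values (vectorized).
#' @return data.frame with one row per `kbar_over_k`: `kbar_over_k`,
#'   `bending_term`, `topological_term`, `total`, `N`, `g_total`.
#' @examples
#' bending_energy(icosphere(1, 3), kbar_over_k = c(0, 1))
#' @export
bending_energy <- function(lobules, kbar_over_k = 0) {
  if (inherits(lobules, "surface_mesh")) lobules <- list(lobules)
  if (inherits(lobules, "lobule_set")) lobules <- lobules$lobules
  if (length(lobules) < 1) stop("need at least one lobule")
  bend <- 0
  gtot <- 0L
  for (m in lobules) {
    fc <- face_mean_curvature(m)
    bend <- bend + sum(fc$H^2 * fc$A)
    gtot <- gtot + mesh_genus(m)
  }
  N <- length(lobules)
  topo <- 4 * pi * kbar_over_k * (N - gtot)
  data.frame(kbar_over_k = kbar_over_k, bending_term = bend,
             topological_term = topo, total = bend + topo,
             N = N, g_total = gtot)
}

#' Bending-energy change of a fusion event
#'
#' Topological bookkeeping of the Helfrich energy across a fusion, in units
#' of kappa: a trans fusion (two lobules merging, dN = -1) releases
#' Delta E_b / kappa = -4*pi*(1 + kbar/kappa); a cis fusion (one passage
#' forming, dg = +1) releases Delta E_b / kappa = -4*pi*(kbar/kappa).
#' Neck-geometry corrections beyond the topological terms are not modelled.
#'
#' @param mode `"trans"` or `"cis"`.
#' @param kbar_over_k reduced Gaussian rigidity (vectorized).
#' @return Delta E_b / kappa (numeric).
#' @examples
#' fusion_energy_change("trans", 0)   # -4*pi
#' fusion_energy_change("cis", 0)     # 0
#' @export
fusion_energy_change <- function(mode = c("trans", "cis"), kbar_over_k) {
  mode <- match.arg(mode)
  if (mode == "trans") -4 * pi * (1 + kbar_over_k) else -4 * pi * kbar_over_k
}

#' Classify the reduced Gaussian rigidity into the fusion state diagram
#'
#' Region I (kbar/kappa < -1): neither fusion mode lowers the energy, an
#' ensemble of spheres is stable. Region II (-1 < kbar/kappa < 0): only
#' trans fusion is favoured, producing few lobules of spherical topology.
#' Region III (kbar/kappa > 0): both modes are favoured, producing
#' high-genus wiffle-ball-like lobules. The boundary values -1 and 0 are
#' reported as `"marginal"` (the inequalities are strict).
#'
#' @param kbar_over_k reduced Gaussian rigidity (vectorized).
#' @return character vector: `"I"`, `"II"`, `"III"` or `"marginal"`.
#' @export
classify_region <- function(kbar_over_k) {
  out <- character(length(kbar_over_k))
  out[kbar_over_k < -1] <- "I"
  out[kbar_over_k > -1 & kbar_over_k < 0] <- "II"
  out[kbar_over_k > 0] <- "III"
  out[kbar_over_k %in% c(-1, 0)] <- "marginal"
  out
}

#' Energy traces over a time series of lobule sets
#'
#' Evaluates [bending_energy()] per frame for each requested reduced
#' Gaussian rigidity, reproducing a family of E_b/kappa(t) curves.
#'
#' @param frames list of lobule lists (one per frame).
#' @param kbar_over_k vector of reduced Gaussian rigidities.
#' @param times frame times (hours).
#' @return long data.frame: `time_h`, `kbar_over_k`, `bending_term`,
#'   `topological_term`, `total`.
#' @export
energy_timeseries <- function(frames, kbar_over_k = c(-1.5, -0.5, 0, 0.5, 1),
                              times = NULL) {
  if (is.null(times)) times <- seq_along(frames)
  rows <- lapply(seq_along(frames), function(i) {
    be <- bending_energy(frames[[i]], kbar_over_k)
    cbind(data.frame(time_h = times[i]), be)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
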