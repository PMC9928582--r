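#' Reduced volume
#'
#' v = 3 * sqrt(4*pi) * V / A^(3/2); equals 1 for a sphere and is < 1 for
#' every other closed surface (isoperimetric deficit).
#'
#' @param V enclosed volume (um^3).
#' @param A surface area (um^2).
#' @return dimensionless reduced volume.
#' @export
reduced_volume <- function(V, A) 3 * sqrt(4 * pi) * V / A^(3 / 2)

#' Reduced curvature
#'
#' m = M / sqrt(4*pi*A), with M the integral mean curvature; equals 1 for a
#' sphere.
#'
#' @param M integral mean curvature (um).
#' @param A surface area (um^2).
#' @return dimensionless reduced curvature.
#' @export
reduced_curvature <- function(M, A) M / sqrt(4 * pi * A)

#' Per-lobule topology and shape metrics
#'
#' Computes, for one closed apical surface: volume V, area A, integral mean
#' curvature M, Euler characteristic chi, genus g = 1 - chi/2, reduced
#' volume v and reduced curvature m.
#'
#' @param mesh a watertight `surface_mesh`.
#' @return one-row data.frame with columns `V`, `A`, `M`, `chi`, `g`, `v`,
#'   `m`.
#' @examples
#' lobule_metrics(icosphere(radius = 10, subdivisions = 3))
#' @export
lobule_metrics <- function(mesh) {
  va <- volume_area(mesh)
  M <- integral_mean_curvature(mesh)
  chi <- euler_characteristic(mesh)
  data.frame(V = va$V, A = va$A, M = M, chi = chi,
             g = genus_from_chi(chi),
             v = reduced_volume(va$V, va$A),
             m = reduced_curvature(M, va$A))
}

#' Metrics table for a set of lobules
#'
#' @param lobules list of `surface_mesh`, or a `lobule_set`.
#' @param sample sample identifier recorded in the table.
#' @return data.frame with one row per lobule (`sample`, `lobule_id`, and
#'   the [lobule_metrics()] columns).
#' @export
lobule_table <- function(lobules, sample = "sample") {
  if (inherits(lobules, "lobule_set")) lobules <- lobules$lobules
  if (length(lobules) == 0)
    return(data.frame(sample = character(), lobule_id = integer(),
                      V = numeric(), A = numeric(), M = numeric(),
                      chi = integer(), g = integer(), v = numeric(),
                      m = numeric()))
  rows <- lapply(seq_along(lobules), function(i)
    cbind(data.frame(sample = sample, lobule_id = i),
          lobule_metrics(lobules[[i]])))
  do.call(rbind, rows)
}

#' Exclude lobules below the minimum lumen volume
#'
#' Lobules with lumen volume below `min_volume` (default 100 um^3, roughly a
#' single-cell-sized vesicle) are excluded before any aggregate quantity is
#' computed; exclusions are reported via a message.
#'
#' @param lobules data.frame with a `V` column (e.g. from [lobule_table()]).
#' @param min_volume exclusion threshold (um^3).
#' @return filtered data.frame.
#' @export
filter_lobules <- function(lobules, min_volume = 100) {
  drop <- lobules$V < min_volume
  if (any(drop))
    message("filter_lobules: excluding ", sum(drop), " lobule(s) with V = ",
            paste(signif(lobules$V[drop], 4), collapse = ", "), " um^3")
  lobules[!drop, , drop = FALSE]
}

#' Organoid-level aggregate state
#'
#' N is the lobule count (after volume filtering), total genus is the sum of
#' per-lobule genera, and the shape averages are volume-weighted:
#' \<v\> = sum(v_i V_i) / sum(V_i), and likewise \<m\>.
#'
#' @param lobules filtered per-lobule metrics data.frame.
#' @param time time of the observation (hours), recorded as `time_h`.
#' @return one-row data.frame: `time_h`, `N`, `g_total`, `v_avg`, `m_avg`,
#'   `V_total`. With zero lobules the averages are `NA` (flagged by
#'   `N = 0`).
#' @export
aggregate_lobules <- function(lobules, time = NA_real_) {
  n <- nrow(lobules)
  if (n == 0)
    return(data.frame(time_h = time, N = 0L, g_total = 0L,
                      v_avg = NA_real_, m_avg = NA_real_, V_total = 0))
  Vt <- sum(lobules$V)
  data.frame(time_h = time, N = as.integer(n),
             g_total = as.integer(sum(lobules$g)),
             v_avg = sum(lobules$v * lobules$V) / Vt,
             m_avg = sum(lobules$m * lobules$V) / Vt,
             V_total = Vt)
}

#' Epithelial cell height from enclosed areas
#'
#' Difference of the sphere-equivalent radii of the outer and inner (apical)
#' boundaries: h = sqrt(A_outer / 4 pi) - sqrt(A_inner / 4 pi).
#'
#' @param A_outer area enclosed by the outer boundary (um^2).
#' @param A_inner area enclosed by the apical boundary (um^2), `<= A_outer`.
#' @return cell height (um).
#' @examples
#' cell_height(4 * pi * 100^2, 4 * pi * 90^2)  # 10
#' @export
cell_height <- function(A_outer, A_inner) {
  if (any(A_inner <= 0)) stop("A_inner must be positive")
  if (any(A_inner > A_outer)) stop("A_inner exceeds A_outer")
  sqrt(A_outer / (4 * pi)) - sqrt(A_inner / (4 * pi))
}
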