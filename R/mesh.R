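#' Closed triangle surface mesh
#'
#' Constructs a `surface_mesh`, the container used throughout the package for
#' apical (lumen) surfaces and tissue outer boundaries. Vertices are in
#' physical units (micrometres); faces are triples of vertex indices with a
#' consistent orientation (outward normals for a surface enclosing a solid).
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (um).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param validate if `TRUE` (default) check watertightness and orientation
#'   consistency: every undirected edge must be shared by exactly two faces,
#'   traversed in opposite directions.
#' @return an object of class `surface_mesh` with elements `vertices` and
#'   `faces`.
#' @examples
#' m <- icosphere(radius = 1, subdivisions = 2)
#' euler_characteristic(m)
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "surface_mesh")
  if (validate) {
    chk <- mesh_defects(m)
    if (!is.null(chk)) stop("invalid surface_mesh: ", chk)
  }
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  chi <- tryCatch(euler_characteristic(x), error = function(e) NA_integer_)
  cat(sprintf("surface_mesh: %d vertices, %d faces, chi = %s\n",
              nrow(x$vertices), nrow(x$faces),
              ifelse(is.na(chi), "?", chi)))
  invisible(x)
}

# undirected edge keys (numeric, exact below 2^53) for the 3 directed edges
# of every face, stacked as blocks of nrow(faces)
directed_edges <- function(faces) {
  rbind(faces[, 1:2, drop = FALSE],
        faces[, 2:3, drop = FALSE],
        faces[, c(3L, 1L), drop = FALSE])
}

edge_keys <- function(e, nv) {
  pmin(e[, 1], e[, 2]) * (nv + 1) + pmax(e[, 1], e[, 2])
}

# NULL if the mesh is a closed, consistently oriented 2-manifold; otherwise a
# short description of the first defect found
mesh_defects <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) < 4L) return("fewer than 4 faces")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    return("face with repeated vertex")
  de <- directed_edges(f)
  nv <- nrow(mesh$vertices)
  ku <- edge_keys(de, nv)
  o <- sort(ku)
  n <- length(o)
  i1 <- seq(1, n - 1, by = 2)
  paired <- n %% 2 == 0 && all(o[i1] == o[i1 + 1]) &&
    !anyDuplicated(o[i1])
  if (!paired)
    return("edge(s) not shared by exactly 2 faces")
  kd <- de[, 1] * (nv + 1) + de[, 2]
  if (anyDuplicated(kd))
    return("inconsistent orientation (repeated directed edge)")
  NULL
}

#' Test whether a mesh is watertight
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces with opposite traversal directions (closed, orientable 2-manifold).
#'
#' @param mesh a `surface_mesh`.
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) is.null(mesh_defects(mesh))

#' Euler characteristic of a triangle mesh
#'
#' Computes chi = V - E + F of a closed triangulated surface. For a closed
#' orientable surface chi is even and relates to the genus via g = 1 - chi/2.
#'
#' @param mesh a watertight `surface_mesh`.
#' @return integer Euler characteristic.
#' @export
euler_characteristic <- function(mesh) {
  d <- mesh_defects(mesh)
  if (!is.null(d)) stop("mesh is not a closed manifold: ", d)
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  ne <- 3L * nf / 2L
  as.integer(nv - ne + nf)
}

#' Genus from the Euler characteristic
#'
#' g = 1 - chi/2 for a closed orientable surface.
#'
#' @param chi even integer Euler characteristic, chi <= 2.
#' @return integer genus (>= 0).
#' @export
genus_from_chi <- function(chi) {
  if (length(chi) != 1L || is.na(chi)) stop("chi must be a single integer")
  if (chi %% 2 != 0) stop("odd Euler characteristic: mesh defect")
  if (chi > 2) stop("chi > 2 is not a connected closed orientable surface")
  as.integer(1 - chi / 2)
}

#' Genus of a mesh
#'
#' @param mesh a watertight `surface_mesh`.
#' @return integer genus.
#' @export
mesh_genus <- function(mesh) genus_from_chi(euler_characteristic(mesh))

#' Enclosed volume and surface area
#'
#' Volume by the divergence theorem (sum of signed tetrahedron volumes
#' against the origin); area as the sum of triangle areas. If the signed
#' volume is negative the orientation is flipped with a warning.
#'
#' @param mesh a watertight, outward-oriented `surface_mesh`.
#' @return list with elements `V` (um^3) and `A` (um^2).
#' @export
volume_area <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cr <- cross3(p2, p3)
  vol <- sum(p1 * cr) / 6
  if (vol < 0) {
    warning("negative signed volume: mesh oriented inward, flipping")
    vol <- -vol
  }
  n <- cross3(p2 - p1, p3 - p1)
  areas <- 0.5 * sqrt(rowSums(n^2))
  if (any(areas <= 0)) stop("mesh has zero-area faces")
  list(V = vol, A = sum(areas))
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

face_normals <- function(mesh, normalize = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- cross3(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
              v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  if (normalize) n <- n / sqrt(rowSums(n^2))
  n
}

face_areas <- function(mesh) {
  0.5 * sqrt(rowSums(face_normals(mesh, normalize = FALSE)^2))
}

# For each undirected edge: the two adjacent face ids, the directed edge
# (u -> v) as traversed by face1, length, and signed dihedral angle theta
# (positive where the surface is convex with respect to the outward normal).
edge_dihedrals <- function(mesh) {
  f <- mesh$faces
  nf <- nrow(f)
  nv <- nrow(mesh$vertices)
  de <- directed_edges(f)
  fid <- rep.int(seq_len(nf), 3L)
  ku <- edge_keys(de, nv)
  o <- order(ku)
  # after ordering, rows 2t-1 and 2t are the two halfedges of edge t
  i1 <- o[seq(1, length(o), by = 2)]
  i2 <- o[seq(2, length(o), by = 2)]
  u <- de[i1, 1]; w <- de[i1, 2]
  fa <- fid[i1]; fb <- fid[i2]
  v <- mesh$vertices
  evec <- v[w, , drop = FALSE] - v[u, , drop = FALSE]
  len <- sqrt(rowSums(evec^2))
  ehat <- evec / len
  n <- face_normals(mesh)
  n1 <- n[fa, , drop = FALSE]
  n2 <- n[fb, , drop = FALSE]
  sn <- rowSums(cross3(n1, n2) * ehat)
  cs <- rowSums(n1 * n2)
  theta <- atan2(sn, pmin(pmax(cs, -1), 1))
  list(u = u, v = w, face1 = fa, face2 = fb, length = len, theta = theta)
}

#' Integral mean curvature of a mesh
#'
#' Edge-dihedral estimator M = 1/2 * sum_e l_e * theta_e, with l_e the edge
#' length and theta_e the signed dihedral angle (convex positive for outward
#' normals). Converges to the integral of the mean curvature H (mean of the
#' principal curvatures) over the surface; for a sphere of radius R it
#' approaches 4*pi*R.
#'
#' @param mesh a watertight, oriented `surface_mesh`.
#' @return numeric, integral mean curvature (um).
#' @export
integral_mean_curvature <- function(mesh) {
  d <- mesh_defects(mesh)
  if (!is.null(d)) stop("mesh is not a closed oriented manifold: ", d)
  ed <- edge_dihedrals(mesh)
  0.5 * sum(ed$length * ed$theta)
}

#' Angle-defect Gauss-Bonnet residual
#'
#' Sums the vertex angle defects (2*pi minus incident face angles), which for
#' any closed triangulated surface equals 2*pi*chi exactly; the residual
#' |sum - 2*pi*chi| measures only floating-point error and serves as an
#' integrity check of the discrete Gaussian curvature (the total of which is
#' 4*pi*(N - g) summed over N lobules of total genus g).
#'
#' @param mesh a watertight `surface_mesh`.
#' @return list with `defect_sum`, `expected` (2*pi*chi) and `residual`.
#' @export
gauss_bonnet_check <- function(mesh) {
  chi <- euler_characteristic(mesh)
  ds <- angle_defect_sum(mesh)
  list(defect_sum = ds, expected = 2 * pi * chi,
       residual = abs(ds - 2 * pi * chi))
}

angle_defect_sum <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ang <- matrix(0, nrow(f), 3)
  for (s in 1:3) {
    a <- v[f[, s], , drop = FALSE]
    b <- v[f[, s %% 3 + 1], , drop = FALSE]
    c <- v[f[, (s + 1) %% 3 + 1], , drop = FALSE]
    e1 <- b - a
    e2 <- c - a
    cosang <- rowSums(e1 * e2) /
      (sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)))
    ang[, s] <- acos(pmin(pmax(cosang, -1), 1))
  }
  acc <- tapply(as.vector(ang), as.vector(f), sum)
  # only vertices referenced by faces carry curvature
  sum(2 * pi - acc)
}
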