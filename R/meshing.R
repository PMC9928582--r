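#' Extract closed triangle surfaces from a segmentation mask
#'
#' Each connected foreground component is meshed independently: its binary
#' indicator is padded (so border-touching components close), optionally
#' regularised with a small Gaussian filter, and the 0.5 level set is
#' extracted by marching tetrahedra, yielding a watertight, outward-oriented
#' mesh in physical units. Light Taubin smoothing relaxes the voxel
#' staircase without volume loss.
#'
#' @param mask a `segmentation_mask` (or 3D logical array, with `spacing`).
#' @param spacing voxel spacing, required when `mask` is a plain array.
#' @param origin physical position of voxel (1,1,1).
#' @param smooth_sigma Gaussian pre-smoothing sd in voxels (0 disables).
#' @param taubin_iterations Taubin lambda-mu smoothing iterations.
#' @param min_voxels components smaller than this are skipped (with a
#'   message); sub-resolution blobs cannot carry a meaningful surface.
#' @return list of `surface_mesh` objects (empty list for an empty mask).
#' @export
extract_surface <- function(mask, spacing = NULL, origin = NULL,
                            smooth_sigma = 1, taubin_iterations = 10L,
                            min_voxels = 8L) {
  if (inherits(mask, "segmentation_mask")) {
    labels <- mask$labels
    spacing <- mask$spacing
    origin <- mask$origin %||% c(0, 0, 0)
  } else {
    if (is.null(spacing)) stop("spacing required for a plain array mask")
    labels <- label_components_cpp(as.logical(mask), dim(mask), 26L)
    origin <- origin %||% c(0, 0, 0)
  }
  nlab <- max(labels)
  if (nlab == 0) return(list())
  d <- dim(labels)
  out <- list()
  for (lb in seq_len(nlab)) {
    sel <- which(labels == lb)
    if (length(sel) < min_voxels) {
      message("extract_surface: skipping component ", lb, " (",
              length(sel), " voxels, below min_voxels)")
      next
    }
    coord <- arrayInd(sel, d)
    margin <- ceiling(3 * smooth_sigma) + 2
    lo <- pmax(apply(coord, 2, min) - margin, 1)
    hi <- pmin(apply(coord, 2, max) + margin, d)
    sub <- array(0, hi - lo + 1 + 2)  # +2: one-voxel closing pad each side
    idx <- cbind(coord[, 1] - lo[1] + 2, coord[, 2] - lo[2] + 2,
                 coord[, 3] - lo[3] + 2)
    sub[idx] <- 1
    fld <- if (smooth_sigma > 0)
      gaussian_smooth3d_cpp(sub, dim(sub), smooth_sigma) else sub
    res <- marching_tetrahedra_cpp(fld, dim(sub), 0.5)
    if (nrow(res$faces) == 0) {
      message("extract_surface: component ", lb,
              " vanished under smoothing; skipped")
      next
    }
    # index space of `sub` (0-based) -> original voxel index -> physical
    v <- res$vertices
    for (ax in 1:3)
      v[, ax] <- origin[ax] + (v[, ax] - 1 + lo[ax] - 1) * spacing[ax]
    m <- surface_mesh(v, res$faces)
    if (taubin_iterations > 0)
      m <- taubin_smooth(m, iterations = taubin_iterations)
    out[[length(out) + 1]] <- m
  }
  out
}

#' Taubin lambda-mu mesh smoothing
#'
#' Alternates a shrinking Laplacian step (`lambda`) and an inflating step
#' (`mu`), which smooths without the systematic volume loss of plain
#' Laplacian smoothing. Connectivity, and hence topology, is untouched.
#'
#' @param mesh a `surface_mesh`.
#' @param iterations number of lambda+mu passes.
#' @param lambda positive smoothing step.
#' @param mu negative inflation step (|mu| slightly > lambda).
#' @return smoothed `surface_mesh`.
#' @export
taubin_smooth <- function(mesh, iterations = 10L, lambda = 0.5, mu = -0.53) {
  v <- mesh$vertices
  f <- mesh$faces
  de <- directed_edges(f)
  # symmetric neighbour structure from directed edges (each appears once)
  src <- c(de[, 1], de[, 2])
  dst <- c(de[, 2], de[, 1])
  deg <- tabulate(src, nbins = nrow(v))
  step <- function(v, w) {
    nb <- rowsum(v[dst, , drop = FALSE], src, reorder = TRUE)
    # rowsum drops absent indices; meshes here reference all vertices
    v + w * (nb / deg - v)
  }
  for (it in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  mesh$vertices <- v
  mesh
}

#' Clean a mesh: deduplicate, collapse short edges, fix degenerate faces
#'
#' Mirrors the standard post-extraction cleanup: remove duplicated vertices
#' and faces, collapse edges shorter than `2 * min_voxel_len` (collapses
#' that would change the topology are skipped), and resolve near-degenerate
#' (obtuse, max angle > 175 degrees) triangles by edge flips. Watertightness
#' and Euler characteristic are preserved; enclosed volume drift is checked
#' to stay below 1%.
#'
#' @param mesh a watertight `surface_mesh`.
#' @param min_voxel_len minimum voxel length of the source image (um); the
#'   collapse tolerance is twice this value.
#' @param tol collapse tolerance override (um).
#' @param max_passes upper bound on collapse sweeps.
#' @return cleaned `surface_mesh`.
#' @export
clean_mesh <- function(mesh, min_voxel_len = NULL, tol = NULL,
                       max_passes = 30L) {
  if (is.null(tol)) {
    if (is.null(min_voxel_len)) stop("supply min_voxel_len or tol")
    tol <- 2 * min_voxel_len
  }
  v0 <- volume_area(mesh)$V
  chi0 <- euler_characteristic(mesh)
  mesh <- merge_duplicate_vertices(mesh)
  mesh <- drop_duplicate_faces(mesh)
  mesh <- collapse_short_edges(mesh, tol, max_passes)
  mesh <- fix_obtuse_faces(mesh)
  chi1 <- euler_characteristic(mesh)
  if (chi1 != chi0)
    warning("clean_mesh changed Euler characteristic: ", chi0, " -> ", chi1)
  v1 <- volume_area(mesh)$V
  drift <- abs(v1 - v0) / v0
  if (drift >= 0.01)
    warning(sprintf("clean_mesh volume drift %.2f%% exceeds 1%%", 100 * drift))
  mesh
}

merge_duplicate_vertices <- function(mesh, digits = 9L) {
  v <- mesh$vertices
  key <- apply(round(v, digits), 1, paste, collapse = "_")
  first <- match(key, key)
  if (all(first == seq_len(nrow(v)))) return(mesh)
  newid <- match(first, unique(first))
  mesh$vertices <- v[unique(first), , drop = FALSE]
  f <- matrix(newid[mesh$faces], ncol = 3)
  storage.mode(f) <- "integer"
  mesh$faces <- f
  drop_degenerate_faces(mesh)
}

drop_degenerate_faces <- function(mesh) {
  f <- mesh$faces
  bad <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  if (any(bad)) mesh$faces <- f[!bad, , drop = FALSE]
  mesh
}

drop_duplicate_faces <- function(mesh) {
  f <- mesh$faces
  key <- apply(f, 1, function(r) paste(sort(r), collapse = "_"))
  dup <- duplicated(key)
  if (any(dup)) mesh$faces <- f[!dup, , drop = FALSE]
  mesh
}

# greedy per-pass collapse of edges shorter than tol; a collapse is applied
# only when the link condition holds (the neighbourhoods of the endpoints
# share exactly the two opposite vertices), which preserves manifoldness and
# Euler characteristic
collapse_short_edges <- function(mesh, tol, max_passes = 30L) {
  for (pass in seq_len(max_passes)) {
    v <- mesh$vertices
    f <- mesh$faces
    nv <- nrow(v)
    de <- directed_edges(f)
    ku <- edge_keys(de, nv)
    fid <- rep.int(seq_len(nrow(f)), 3L)
    o <- order(ku)
    i1 <- o[seq(1, length(o), by = 2)]
    i2 <- o[seq(2, length(o), by = 2)]
    ea <- de[i1, 1]; eb <- de[i1, 2]
    # opposite vertices of the two faces flanking each undirected edge
    fs1 <- rowSums(f[fid[i1], , drop = FALSE])
    fs2 <- rowSums(f[fid[i2], , drop = FALSE])
    opp1 <- as.integer(fs1 - ea - eb)
    opp2 <- as.integer(fs2 - ea - eb)
    len <- sqrt(rowSums((v[ea, , drop = FALSE] - v[eb, , drop = FALSE])^2))
    short <- which(len < tol)
    if (length(short) == 0) break
    short <- short[order(len[short])]
    # link condition via common-neighbour counts: entry (a, b) of the
    # squared adjacency matrix counts shared neighbours; a manifold-safe
    # collapse requires exactly the 2 opposite vertices in common
    A <- Matrix::sparseMatrix(i = c(ea, eb), j = c(eb, ea),
                              x = 1, dims = c(nv, nv))
    A2 <- A %*% A
    ncommon <- A2[cbind(ea[short], eb[short])]
    ok <- short[ncommon == 2]
    if (length(ok) == 0) break
    touched <- rep(FALSE, nv)
    map <- seq_len(nv)
    newpos <- v
    any_collapse <- FALSE
    # face lists per vertex, for volume-preserving vertex placement
    vf <- split(rep.int(seq_len(nrow(f)), 3L), as.vector(f))
    vfn <- as.integer(names(vf))
    vfi <- integer(nv); vfi[vfn] <- seq_along(vfn)
    for (q in ok) {
      a <- ea[q]; b <- eb[q]
      if (touched[a] || touched[b] || touched[opp1[q]] || touched[opp2[q]])
        next
      newpos[a, ] <- collapse_position(v, f, vf[[vfi[a]]], vf[[vfi[b]]], a, b)
      map[b] <- a
      touched[c(a, b, opp1[q], opp2[q])] <- TRUE
      any_collapse <- TRUE
    }
    if (!any_collapse) break
    f2 <- matrix(map[f], ncol = 3)
    storage.mode(f2) <- "integer"
    mesh$vertices <- newpos
    mesh$faces <- f2
    mesh <- drop_degenerate_faces(mesh)
    mesh <- drop_duplicate_faces(mesh)
  }
  compact_mesh(mesh)
}

# position for the merged vertex of an (a, b) edge collapse that preserves
# the enclosed volume: the signed volume of the merged one-ring is linear in
# the new position p, so p = midpoint + t * S solves it exactly, where S is
# the summed area vector of the retained ring faces
collapse_position <- function(v, f, fa, fb, a, b) {
  ring <- unique(c(fa, fb))
  tri <- f[ring, , drop = FALSE]
  keep <- !((tri[, 1] == a | tri[, 2] == a | tri[, 3] == a) &
            (tri[, 1] == b | tri[, 2] == b | tri[, 3] == b))
  mid <- (v[a, ] + v[b, ]) / 2
  # 6 x enclosed-volume contribution of the ring before the collapse
  p1 <- v[tri[, 1], , drop = FALSE]
  p2 <- v[tri[, 2], , drop = FALSE]
  p3 <- v[tri[, 3], , drop = FALSE]
  v_before <- sum(p1 * cross3(p2, p3))
  # after: merged vertex p in place of a/b; contribution p . S + const,
  # with S = sum of (q x r) over retained faces, q, r the other vertices
  tri2 <- tri[keep, , drop = FALSE]
  S <- c(0, 0, 0)
  cst <- 0
  for (i in seq_len(nrow(tri2))) {
    tr <- tri2[i, ]
    w <- which(tr == a | tr == b)
    xyz <- v[tr, , drop = FALSE]
    if (length(w) != 1) { cst <- cst + sum(xyz[1, ] * crossv(xyz[2, ], xyz[3, ])); next }
    o <- xyz[-w, , drop = FALSE]
    S <- S + if (w == 1) crossv(o[1, ], o[2, ])
         else if (w == 2) crossv(o[2, ], o[1, ])
         else crossv(o[1, ], o[2, ])
  }
  s2 <- sum(S^2)
  if (s2 < 1e-20) return(mid)
  t <- (v_before - cst - sum(mid * S)) / s2
  p <- mid + t * S
  # a wild offset signals a nearly degenerate ring; fall back to midpoint
  if (sum((p - mid)^2) > sum((v[a, ] - v[b, ])^2)) return(mid)
  p
}

crossv <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# drop unreferenced vertices, reindex faces
compact_mesh <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  if (length(used) == nrow(mesh$vertices)) return(mesh)
  newid <- integer(nrow(mesh$vertices))
  newid[used] <- seq_along(used)
  mesh$vertices <- mesh$vertices[used, , drop = FALSE]
  f <- matrix(newid[mesh$faces], ncol = 3)
  storage.mode(f) <- "integer"
  mesh$faces <- f
  mesh
}

# resolve triangles whose largest angle exceeds `deg` by flipping their
# longest edge when the flip is valid (keeps a closed manifold)
fix_obtuse_faces <- function(mesh, deg = 175) {
  limit <- deg * pi / 180
  for (round in 1:5) {
    v <- mesh$vertices
    f <- mesh$faces
    nv <- nrow(v)
    maxang <- rep(0, nrow(f))
    for (s in 1:3) {
      a <- v[f[, s], , drop = FALSE]
      b <- v[f[, s %% 3 + 1], , drop = FALSE]
      c <- v[f[, (s + 1) %% 3 + 1], , drop = FALSE]
      e1 <- b - a; e2 <- c - a
      cosang <- rowSums(e1 * e2) / (sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)))
      maxang <- pmax(maxang, acos(pmin(pmax(cosang, -1), 1)))
    }
    bad <- which(maxang > limit)
    if (length(bad) == 0) break
    de <- directed_edges(f)
    nvp <- nv + 1
    ku <- de[, 1] * nvp + de[, 2]
    rk <- de[, 2] * nvp + de[, 1]
    mate <- match(rk, ku)            # opposite halfedge row
    fid <- rep.int(seq_len(nrow(f)), 3L)
    changed <- FALSE
    donef <- rep(FALSE, nrow(f))
    allk <- unique(pmin(de[, 1], de[, 2]) * nvp + pmax(de[, 1], de[, 2]))
    for (q in bad) {
      if (donef[q]) next
      # longest edge of face q
      rows <- c(q, q + nrow(f), q + 2 * nrow(f))
      el <- sqrt(rowSums((v[de[rows, 1], , drop = FALSE] -
                          v[de[rows, 2], , drop = FALSE])^2))
      r <- rows[which.max(el)]
      r2 <- mate[r]
      g <- fid[r2]
      if (donef[g] || g == q) next
      u1 <- de[r, 1]; u2 <- de[r, 2]
      a <- setdiff(f[q, ], c(u1, u2))
      b <- setdiff(f[g, ], c(u1, u2))
      if (length(a) != 1 || length(b) != 1 || a == b) next
      newk <- min(a, b) * nvp + max(a, b)
      if (newk %in% allk) next       # flip would duplicate an existing edge
      f[q, ] <- c(u1, b, a)
      f[g, ] <- c(u2, a, b)
      donef[c(q, g)] <- TRUE
      changed <- TRUE
      allk <- c(allk, newk)
    }
    if (!changed) break
    storage.mode(f) <- "integer"
    mesh$faces <- f
  }
  mesh
}

#' Split apical surfaces into epithelial lobules
#'
#' Each closed apical component is one epithelial lobule; the lobule count N
#' together with the per-lobule genus defines the organoid topology.
#' Non-watertight components are excluded with a defect report.
#'
#' @param apical_meshes list of `surface_mesh` (apical surfaces).
#' @param outer `surface_mesh` of the tissue outer boundary (optional).
#' @return a `lobule_set`: list with `lobules`, `outer`, and `N`.
#' @export
split_lobules <- function(apical_meshes, outer = NULL) {
  keep <- list()
  for (i in seq_along(apical_meshes)) {
    d <- mesh_defects(apical_meshes[[i]])
    if (is.null(d)) {
      keep[[length(keep) + 1]] <- apical_meshes[[i]]
    } else {
      warning("excluding non-watertight apical component ", i, ": ", d)
    }
  }
  structure(list(lobules = keep, outer = outer, N = length(keep)),
            class = "lobule_set")
}

#' @export
print.lobule_set <- function(x, ...) {
  cat(sprintf("lobule_set: N = %d lobule(s)%s\n", x$N,
              if (is.null(x$outer)) "" else " + outer boundary"))
  invisible(x)
}
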