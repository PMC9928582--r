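#' 3D intensity image with voxel spacing
#'
#' @param data 3D numeric array of intensities.
#' @param spacing 3-vector of voxel spacing (um), strictly positive.
#' @param origin physical position of voxel (1,1,1) (um).
#' @param channel channel label, e.g. `"whole_tissue"` or `"apical"`.
#' @return a `voxel_image`.
#' @export
voxel_image <- function(data, spacing, origin = c(0, 0, 0),
                        channel = c("whole_tissue", "apical")) {
  channel <- match.arg(channel)
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), channel = channel),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  cat(sprintf("voxel_image [%s]: %s voxels, spacing (%s) um\n", x$channel,
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 4), collapse = ", ")))
  invisible(x)
}

#' Synthetic imaging scene
#'
#' A set of ground-truth shapes plus acquisition parameters, ready to be
#' voxelized into a two-channel stack. Shapes must be pairwise disjoint
#' unless `allow_overlap = TRUE` (used by fusion configurations).
#'
#' @param specs list of [shape_spec()] objects.
#' @param voxel_spacing 3-vector (um).
#' @param noise_sd additive Gaussian intensity noise (sd, intensity units).
#' @param seed integer RNG seed for the noise.
#' @param cell_height tissue thickness around each lumen (um); sets the
#'   whole-tissue channel extent.
#' @param apical_style `"podxl"` (bright shell only, as for a fixed-sample
#'   apical marker) or `"actin"` (bright shell over dim tissue, as for a
#'   live cytoskeletal stain).
#' @param allow_overlap permit overlapping specs.
#' @return a `synthetic_scene`.
#' @export
synthetic_scene <- function(specs, voxel_spacing = c(1.3, 1.3, 1.25),
                            noise_sd = 0, seed = 1L, cell_height = 8,
                            apical_style = c("podxl", "actin"),
                            allow_overlap = FALSE) {
  apical_style <- match.arg(apical_style)
  if (inherits(specs, "shape_spec")) specs <- list(specs)
  stopifnot(all(vapply(specs, inherits, TRUE, "shape_spec")))
  if (any(voxel_spacing <= 0)) stop("voxel spacing must be strictly positive")
  if (!allow_overlap && length(specs) > 1) {
    for (i in seq_along(specs)) for (j in seq_len(i - 1)) {
      d <- sqrt(sum((specs[[i]]$center - specs[[j]]$center)^2))
      if (d < bounding_radius(specs[[i]]) + bounding_radius(specs[[j]]))
        stop("specs ", j, " and ", i, " may overlap; set allow_overlap = TRUE ",
             "for fusion configurations")
    }
  }
  structure(list(specs = specs, voxel_spacing = as.numeric(voxel_spacing),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 cell_height = cell_height, apical_style = apical_style),
            class = "synthetic_scene")
}

bounding_radius <- function(spec) {
  switch(spec$family,
    sphere = spec$R,
    spherocylinder = spec$R * (1 + spec$L_over_r / 2),
    torus = spec$R + spec$tube_r,
    wiffle_ball = spec$R)
}

#' Voxelize a synthetic scene into a two-channel stack
#'
#' Produces the apical channel (thin bright shell on the lumen surfaces,
#' optionally over dim tissue) and the whole-tissue channel (lumens inflated
#' by the cell height), both with optional additive Gaussian noise, plus a
#' ground-truth record of per-lobule topology and geometry.
#'
#' @param scene a [synthetic_scene()].
#' @param shell_halfwidth half-width of the apical shell (um); default one
#'   voxel (the largest spacing component).
#' @param grid_dim optional explicit grid size; shapes plus margin must fit
#'   or voxelization is rejected.
#' @param margin_voxels background margin around the tissue (>= 2).
#' @return list with `apical` and `whole_tissue` (`voxel_image`s) and
#'   `truth` (list: `N`, per-lobule `g`, `V`, `A`).
#' @examples
#' sc <- synthetic_scene(shape_spec("sphere", R = 20), voxel_spacing = rep(2, 3))
#' vx <- voxelize(sc)
#' vx$truth$N
#' @export
voxelize <- function(scene, shell_halfwidth = NULL, grid_dim = NULL,
                     margin_voxels = 3L) {
  stopifnot(inherits(scene, "synthetic_scene"))
  sp <- scene$voxel_spacing
  if (is.null(shell_halfwidth)) shell_halfwidth <- max(sp)
  margin_voxels <- max(2L, as.integer(margin_voxels))
  centers <- do.call(rbind, lapply(scene$specs, `[[`, "center"))
  rads <- vapply(scene$specs, bounding_radius, numeric(1))
  pad <- scene$cell_height + shell_halfwidth
  lo <- apply(centers - rads - pad, 2, min) - margin_voxels * sp
  hi <- apply(centers + rads + pad, 2, max) + margin_voxels * sp
  need <- ceiling((hi - lo) / sp) + 1
  if (is.null(grid_dim)) {
    grid_dim <- as.integer(need)
  } else {
    grid_dim <- as.integer(grid_dim)
    if (any(grid_dim < need))
      stop("shapes (plus margin) exceed the requested grid: need at least ",
           paste(need, collapse = " x "))
  }
  origin <- lo
  ax <- origin[1] + (seq_len(grid_dim[1]) - 1) * sp[1]
  ay <- origin[2] + (seq_len(grid_dim[2]) - 1) * sp[2]
  az <- origin[3] + (seq_len(grid_dim[3]) - 1) * sp[3]
  pts <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  sdf <- rep(Inf, nrow(pts))
  for (s in scene$specs) sdf <- pmin(sdf, sdf_shape(s, pts))

  w <- shell_halfwidth
  shell <- abs(sdf) <= w
  tissue <- sdf > w & sdf <= scene$cell_height
  interior <- sdf < -w
  apical <- rep(10, nrow(pts))
  if (scene$apical_style == "actin") apical[tissue] <- 60
  apical[interior] <- 15
  apical[shell] <- 220
  whole <- 10 + 190 * (sdf <= scene$cell_height)
  if (scene$noise_sd > 0) {
    set.seed(scene$seed)
    apical <- apical + stats::rnorm(length(apical), 0, scene$noise_sd)
    whole <- whole + stats::rnorm(length(whole), 0, scene$noise_sd)
  }
  dim(apical) <- grid_dim
  dim(whole) <- grid_dim

  truth <- list(
    N = length(scene$specs),
    g = vapply(scene$specs, function(s) shape_truth(s)$g, integer(1)),
    V = vapply(scene$specs, function(s) shape_truth(s)$V, numeric(1)),
    A = vapply(scene$specs, function(s) shape_truth(s)$A, numeric(1)))

  list(apical = voxel_image(apical, sp, origin, "apical"),
       whole_tissue = voxel_image(whole, sp, origin, "whole_tissue"),
       truth = truth)
}

#' Write a voxel image as multi-page TIFF
#'
#' One page per z-plane, 16-bit; voxel spacing, origin, channel and the
#' intensity scaling are recorded in a JSON sidecar (`<path>.json`).
#'
#' @param img a `voxel_image`.
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_voxel_tiff <- function(img, path) {
  a <- img$data
  rng <- range(a)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(dim(a)[3]), function(k) (a[, , k] - rng[1]) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(spacing = img$spacing, origin = img$origin,
               channel = img$channel,
               intensity_min = rng[1], intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a voxel image from multi-page TIFF
#'
#' Restores spacing/origin/intensity scaling from the JSON sidecar written
#' by [write_voxel_tiff()]; `spacing` overrides metadata if given.
#'
#' @param path `.tif` path.
#' @param spacing optional 3-vector overriding stored voxel spacing.
#' @return a `voxel_image`.
#' @export
read_voxel_tiff <- function(path, spacing = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar) else NULL
  if (is.null(meta) && is.null(spacing))
    stop("no spacing metadata for TIFF; pass `spacing`")
  a <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) a[, , k] <- pages[[k]]
  if (!is.null(meta)) a <- a * meta$intensity_scale + meta$intensity_min
  voxel_image(a,
              spacing = spacing %||% meta$spacing,
              origin = if (is.null(meta)) c(0, 0, 0) else meta$origin,
              channel = if (is.null(meta)) "whole_tissue" else meta$channel)
}

#' Write a scene's channels and ground truth to a directory
#'
#' @param vox output of [voxelize()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return named vector of written paths, invisibly.
#' @export
write_scene <- function(vox, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(prefix, "_apical.tif"))
  p2 <- file.path(dir, paste0(prefix, "_whole.tif"))
  p3 <- file.path(dir, paste0(prefix, "_truth.json"))
  write_voxel_tiff(vox$apical, p1)
  write_voxel_tiff(vox$whole_tissue, p2)
  jsonlite::write_json(vox$truth, p3, auto_unbox = TRUE, digits = NA)
  invisible(c(apical = p1, whole_tissue = p2, truth = p3))
}
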