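#' Default pipeline configuration
#'
#' Collects every tunable stage parameter. Thresholding defaults follow the
#' two acquisition styles: plain Otsu for fixed-sample-style channels,
#' multi-Otsu (3 classes lowest / 4 classes highest) for live actin-style
#' stacks.
#'
#' @param ... named overrides of the defaults.
#' @return a named list (class `lumentopo_config`).
#' @export
default_config <- function(...) {
  cfg <- list(
    binning = 1L,                    # x-y block binning factor
    threshold_whole = "otsu",        # "otsu" | "multiotsu3"
    threshold_apical = "otsu",       # "otsu" | "multiotsu4"
    connectivity = 26L,
    lumen_shell_halfwidth_vox = 1L,  # apical shell half-width, voxels
    smooth_sigma = 1,                # voxels, pre-meshing regularisation
    taubin_iterations = 10L,
    clean_tolerance_factor = 2,      # x min voxel length
    clean_meshes = FALSE,            # decimation optional: metrics do not need it
    min_lobule_volume = 100,         # um^3
    shrinkage_factor = 1,            # 0.603 for cleared fixed samples
    kbar_over_k = c(-1.5, -0.5, 0, 0.5, 1),
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "lumentopo_config")
}

segment_channel <- function(img, method, connectivity) {
  switch(method,
    otsu = otsu_mask(img, connectivity = connectivity),
    multiotsu3 = multiotsu_mask(img, classes = 3, take = "lowest",
                                connectivity = connectivity),
    multiotsu4 = multiotsu_mask(img, classes = 4, take = "highest",
                                connectivity = connectivity),
    stop("unknown threshold method: ", method))
}

#' Run the snapshot pipeline on one two-channel stack
#'
#' Full chain for a single timepoint: (optional) x-y binning, thresholding
#' of both channels, lumen-solid recovery from the apical shell, marching-
#' tetrahedra surface extraction, (optional) mesh cleanup, per-lobule
#' morphometrics, the lumen-volume filter, and organoid-level aggregation.
#'
#' @param input output of [voxelize()], a list with `apical` and
#'   `whole_tissue` `voxel_image`s, or a [synthetic_scene()] (voxelized on
#'   the fly).
#' @param config a [default_config()] list.
#' @param sample sample identifier for the tables.
#' @param time observation time (hours).
#' @return list: `lobule_table` (filtered per-lobule metrics), `organoid`
#'   (one-row aggregate), `lobules` (meshes), `outer` (mesh or NULL), `log`
#'   (provenance list).
#' @export
run_snapshot <- function(input, config = default_config(),
                         sample = "sample", time = NA_real_) {
  if (inherits(input, "synthetic_scene")) input <- voxelize(input)
  stopifnot(is.list(input), !is.null(input$apical))
  apical <- input$apical
  whole <- input$whole_tissue
  if (config$binning > 1L) {
    apical <- bin_xy(apical, config$binning)
    if (!is.null(whole)) whole <- bin_xy(whole, config$binning)
  }
  am <- segment_channel(apical, config$threshold_apical, config$connectivity)
  lum <- lumen_solid(am, config$lumen_shell_halfwidth_vox, config$connectivity)
  lob_meshes <- extract_surface(lum, smooth_sigma = config$smooth_sigma,
                                taubin_iterations = config$taubin_iterations)
  if (isTRUE(config$clean_meshes)) {
    tol <- config$clean_tolerance_factor * min(apical$spacing)
    lob_meshes <- lapply(lob_meshes, clean_mesh, tol = tol)
  }
  outer <- NULL
  if (!is.null(whole)) {
    wm <- segment_channel(whole, config$threshold_whole, config$connectivity)
    om <- extract_surface(wm, smooth_sigma = config$smooth_sigma,
                          taubin_iterations = config$taubin_iterations)
    if (length(om) > 0) outer <- om[[which.max(vapply(om, function(m)
      volume_area(m)$V, numeric(1)))]]
  }
  ls <- split_lobules(lob_meshes, outer)
  lt <- lobule_table(ls, sample = sample)
  if (config$shrinkage_factor < 1)
    lt <- apply_shrinkage_correction(lt, config$shrinkage_factor)
  keep <- lt$V >= config$min_lobule_volume
  lt_f <- filter_lobules(lt, config$min_lobule_volume)
  org <- aggregate_lobules(lt_f, time = time)
  org <- cbind(data.frame(sample = sample), org)
  list(lobule_table = lt_f,
       organoid = org,
       lobules = ls$lobules[keep],
       outer = outer,
       log = list(config = unclass(config),
                  apical_provenance = am$provenance,
                  n_excluded = sum(!keep)))
}

#' Run the time-series pipeline
#'
#' Applies [run_snapshot()] to each frame, then derives the fusion counters
#' (Phi, Psi), the normalized lobule count, the bending-energy traces for
#' each requested reduced Gaussian rigidity, and the shape-diagram
#' trajectory.
#'
#' @param inputs list of frames: [synthetic_scene()]s or [voxelize()]
#'   outputs, time-ordered.
#' @param config a [default_config()] list.
#' @param times frame times (hours); defaults to 0, 1, 2, ...
#' @param sample sample identifier.
#' @return list: `states` (per-frame aggregates with `Phi`/`Psi`),
#'   `normalized_N`, `energy` (long data.frame over `kbar_over_k`),
#'   `trajectory` (`time_h`, `v_avg`, `m_avg`), `frames` (per-frame
#'   snapshot results).
#' @export
run_timeseries <- function(inputs, config = default_config(), times = NULL,
                           sample = "sample") {
  if (is.null(times)) times <- seq_along(inputs) - 1
  stopifnot(length(times) == length(inputs), !is.unsorted(times))
  frames <- lapply(seq_along(inputs), function(i)
    run_snapshot(inputs[[i]], config, sample = sample, time = times[i]))
  states <- do.call(rbind, lapply(frames, `[[`, "organoid"))
  states <- count_fusions(states)
  energy <- energy_timeseries(lapply(frames, `[[`, "lobules"),
                              kbar_over_k = config$kbar_over_k,
                              times = times)
  list(states = states,
       normalized_N = normalized_lobule_count(states),
       energy = energy,
       trajectory = states[, c("time_h", "v_avg", "m_avg")],
       frames = frames)
}

#' Write pipeline outputs to a directory
#'
#' Writes the per-lobule and organoid CSV tables, per-lobule PLY meshes and
#' the resolved configuration (JSON) for auditability.
#'
#' @param result output of [run_snapshot()] or [run_timeseries()].
#' @param dir output directory (created).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_results <- function(result, dir, prefix = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  wcsv <- function(df, name) {
    p <- file.path(dir, paste0(prefix, "_", name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    p
  }
  if (!is.null(result$states)) {          # time series
    paths <- c(paths, wcsv(result$states, "states"),
               wcsv(result$energy, "energy"),
               wcsv(result$trajectory, "trajectory"))
    cfg <- result$frames[[1]]$log$config
  } else {
    paths <- c(paths, wcsv(result$lobule_table, "lobules"),
               wcsv(result$organoid, "organoid"))
    for (i in seq_along(result$lobules)) {
      p <- file.path(dir, sprintf("%s_lobule%d.ply", prefix, i))
      write_ply(result$lobules[[i]], p)
      paths <- c(paths, p)
    }
    cfg <- result$log$config
  }
  pj <- file.path(dir, paste0(prefix, "_config.json"))
  jsonlite::write_json(cfg, pj, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, pj))
}

#' @useDynLib lumentopo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom Matrix sparseMatrix
NULL
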