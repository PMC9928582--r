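#' Write a mesh to PLY (ASCII)
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path (`.ply`).
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply",
    "format ascii 1.0",
    "comment produced by lumentopo",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header"), con)
  writeLines(apply(format(v, digits = 17, scientific = FALSE, trim = TRUE),
                   1, paste, collapse = " "), con)
  writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read a mesh from ASCII PLY
#'
#' Minimal reader for the ASCII PLY files written by [write_ply()] (and other
#' ASCII PLYs whose vertex element starts with x, y, z).
#'
#' @param path file path.
#' @param validate passed to [surface_mesh()].
#' @return a `surface_mesh`.
#' @export
read_ply <- function(path, validate = TRUE) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("^format ascii", lines[2]))
    stop("not an ASCII PLY file: ", path)
  hend <- match("end_header", lines)
  header <- lines[seq_len(hend)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", header, value = TRUE)))
  vl <- lines[hend + seq_len(nv)]
  fl <- lines[hend + nv + seq_len(nf)]
  v <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))), ncol = length(strsplit(trimws(vl[1]), "\\s+")[[1]]), byrow = TRUE)[, 1:3, drop = FALSE]
  fraw <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))), ncol = 4, byrow = TRUE)
  if (any(fraw[, 1] != 3L)) stop("only triangle faces are supported")
  surface_mesh(v, fraw[, 2:4, drop = FALSE] + 1L, validate = validate)
}

#' Write a mesh to OFF
#'
#' @param mesh a `surface_mesh`.
#' @param path output file path (`.off`).
#' @return `path`, invisibly.
#' @export
write_off <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("OFF", sprintf("%d %d 0", nrow(v), nrow(f))), con)
  writeLines(apply(format(v, digits = 17, scientific = FALSE, trim = TRUE),
                   1, paste, collapse = " "), con)
  writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  invisible(path)
}

#' Read a mesh from OFF
#'
#' @param path file path.
#' @param validate passed to [surface_mesh()].
#' @return a `surface_mesh`.
#' @export
read_off <- function(path, validate = TRUE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vl <- lines[2 + seq_len(nv)]
  fl <- lines[2 + nv + seq_len(nf)]
  v <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))), ncol = 3, byrow = TRUE)
  fraw <- matrix(as.integer(unlist(strsplit(trimws(fl), "\\s+"))), ncol = 4, byrow = TRUE)
  if (any(fraw[, 1] != 3L)) stop("only triangle faces are supported")
  surface_mesh(v, fraw[, 2:4, drop = FALSE] + 1L, validate = validate)
}
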