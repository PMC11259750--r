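# File interchange: NIfTI volumes, PLY/STL meshes, TCK streamlines,
# CSV manifests/landmarks, JSON ground-truth sidecars.

#' Write a label map as NIfTI-1
#' @param map a \code{label_map}.
#' @param path output path (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
write_label_map <- function(map, path) {
  img <- RNifti::asNifti(array(as.integer(map$voxels), dim(map$voxels)))
  img <- RNifti::`sform<-`(img, structure(map$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label map from NIfTI-1
#' @param path NIfTI file.
#' @return a \code{label_map}.
#' @export
read_label_map <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  label_map(array(as.integer(img), dim(img)[1:3]), affine = aff)
}

#' Write a tensor field as a 6-volume NIfTI-1 series
#'
#' Components are stored in lower-triangular order
#' (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz), recorded in the header description
#' field.
#'
#' @param field a \code{tensor_field}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_tensor_field <- function(field, path) {
  img <- RNifti::asNifti(field$D)
  img <- RNifti::`sform<-`(img, structure(field$affine, code = 2L))
  img$descrip <- "tensor lower-tri: Dxx Dxy Dyy Dxz Dyz Dzz"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a tensor field from a 6-volume NIfTI-1 series
#' @param path NIfTI file.
#' @return a \code{tensor_field}.
#' @export
read_tensor_field <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4 || d[4] != 6) stop("expected a 6-volume tensor series")
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = dim(aff))
  tensor_field(array(as.numeric(img), d), affine = aff)
}

#' Write a mesh as ASCII PLY
#' @param mesh a \code{surface_mesh}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII PLY mesh
#' @param path PLY file.
#' @return a \code{surface_mesh}.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face", lines, value = TRUE)[1]))
  hdr_end <- which(lines == "end_header")[1]
  verts <- do.call(rbind, lapply(lines[(hdr_end + 1):(hdr_end + nv)],
                                 function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  faces <- do.call(rbind, lapply(lines[(hdr_end + nv + 1):(hdr_end + nv + nf)],
                                 function(l) as.integer(strsplit(trimws(l), "\\s+")[[1]][2:4])))
  surface_mesh(verts, faces + 1L)
}

#' Write a mesh as ASCII STL
#' @param mesh a \code{surface_mesh}.
#' @param path output path.
#' @param name solid name in the STL header.
#' @return the path, invisibly.
#' @export
write_stl <- function(mesh, path, name = "mesh") {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  n <- cross3_rows(b - a, c3 - a)
  nn <- row_norms(n)
  n <- n / ifelse(nn > 0, nn, 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  for (i in seq_len(nrow(a))) {
    writeLines(c(sprintf("facet normal %g %g %g", n[i, 1], n[i, 2], n[i, 3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", a[i, 1], a[i, 2], a[i, 3]),
                 sprintf("    vertex %g %g %g", b[i, 1], b[i, 2], b[i, 3]),
                 sprintf("    vertex %g %g %g", c3[i, 1], c3[i, 2], c3[i, 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Write a tract set in TCK format with a CSV manifest
#'
#' Streamlines are written in the MRtrix track-file layout (text header,
#' little-endian float32 triplets, NaN-separated, Inf-terminated) alongside
#' a CSV manifest of tract id, length, and stop reasons.
#'
#' @param tracts a \code{tract_set}.
#' @param path output .tck path; the manifest is written next to it with a
#'   .csv extension unless \code{manifest} is given.
#' @param manifest optional manifest path.
#' @return the TCK path, invisibly.
#' @export
write_tck <- function(tracts, path, manifest = NULL) {
  n <- length(tracts$streamlines)
  hdr <- c("mrtrix tracks", "datatype: Float32LE", sprintf("count: %d", n))
  # the offset counts its own header line, so size it to a fixed point
  base <- sum(nchar(hdr)) + length(hdr) + nchar("END\n")
  off <- 0L
  repeat {
    off_line <- sprintf("file: . %d", off)
    new_off <- base + nchar(off_line) + 1L
    if (new_off == off) break
    off <- new_off
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(c(hdr, off_line), collapse = "\n"), "\nEND\n"), con,
            eos = NULL)
  for (s in tracts$streamlines) {
    writeBin(as.numeric(t(s$points)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  if (is.null(manifest)) manifest <- sub("\\.tck$", ".csv", path)
  reasons <- vapply(tracts$streamlines,
                    function(s) paste(s$stop_reasons, collapse = "|"),
                    character(1))
  utils::write.csv(data.frame(tract = seq_len(n),
                              length_mm = tracts$lengths,
                              stop_reasons = reasons),
                   manifest, row.names = FALSE)
  invisible(path)
}

#' Read streamlines from a TCK file
#' @param path .tck file.
#' @return list of point matrices (mm).
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- ""
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "\n") break
      line <- paste0(line, ch)
    }
    if (line == "END") break
    hdr <- c(hdr, line)
  }
  off <- as.integer(sub(".*file: \\. ", "",
                        grep("^file:", hdr, value = TRUE)[1]))
  seek(con, off)
  raw_len <- file.size(path) - off
  vals <- readBin(con, "numeric", n = raw_len / 4, size = 4,
                  endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  breaks <- which(!is.finite(pts[, 1]))
  out <- list()
  start <- 1
  for (b in breaks) {
    if (b > start) out[[length(out) + 1]] <- pts[start:(b - 1), , drop = FALSE]
    start <- b + 1
    if (is.infinite(pts[b, 1])) break
  }
  out
}

#' Write landmarks or centres as CSV (id, x, y, z in mm)
#' @param points n x 3 matrix.
#' @param path output CSV.
#' @param ids optional identifiers.
#' @return the path, invisibly.
#' @export
write_landmarks <- function(points, path, ids = seq_len(nrow(points))) {
  utils::write.csv(data.frame(id = ids, x = points[, 1], y = points[, 2],
                              z = points[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read landmarks from CSV (id, x, y, z)
#' @param path CSV file.
#' @return n x 3 matrix with rownames from the id column.
#' @export
read_landmarks <- function(path) {
  d <- utils::read.csv(path)
  m <- as.matrix(d[, c("x", "y", "z")])
  rownames(m) <- d$id
  m
}

#' Write phantom ground truth as a JSON sidecar
#' @param phantom a \code{muscle_phantom} (or any list with a \code{truth}
#'   element).
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(phantom, path) {
  truth <- if (!is.null(phantom$truth)) phantom$truth else phantom
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
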