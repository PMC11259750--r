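#' Label map container
#'
#' A 3D integer label volume with a voxel-to-world affine. Labels follow the
#' phantom convention 0 = background, 1 = muscle, 2 = aponeurosis, 3 = bone,
#' but any non-negative integer coding is accepted.
#'
#' @param voxels 3D integer array of tissue labels.
#' @param affine 4x4 voxel-to-world transform (0-based voxel index to mm,
#'   NIfTI convention: the affine maps indices to voxel centres). Defaults to
#'   \code{diag(voxel_mm)} with zero origin.
#' @param voxel_mm isotropic voxel size in mm, used when \code{affine} is not
#'   given.
#' @param label_names optional named character vector mapping label values to
#'   tissue names.
#' @return An object of class \code{label_map}.
#' @export
label_map <- function(voxels, affine = NULL, voxel_mm = 1,
                      label_names = c("0" = "background", "1" = "muscle",
                                      "2" = "aponeurosis", "3" = "bone")) {
  if (length(dim(voxels)) != 3L) stop("'voxels' must be a 3D array")
  if (any(voxels < 0, na.rm = TRUE)) stop("labels must be non-negative")
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_mm, 3), 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine[1:3, 1:3])) < 1e-12) {
    stop("'affine' must be an invertible 4x4 transform")
  }
  structure(list(voxels = voxels, affine = affine, label_names = label_names),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("label_map: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  tab <- table(x$voxels)
  for (lab in names(tab)) {
    nm <- if (lab %in% names(x$label_names)) x$label_names[[lab]] else "?"
    cat(sprintf("  label %s (%s): %d voxels\n", lab, nm, tab[[lab]]))
  }
  invisible(x)
}

#' Triangulated surface mesh
#'
#' @param vertices n x 3 matrix of vertex coordinates in mm.
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @return An object of class \code{surface_mesh} with a \code{closed} flag
#'   (every edge shared by exactly two faces).
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (ncol(vertices) != 3) stop("'vertices' must be n x 3")
  if (nrow(faces) == 0) stop("mesh has no faces")
  if (min(faces) < 1 || max(faces) > nrow(vertices)) {
    stop("face indices out of range")
  }
  m <- structure(list(vertices = vertices, faces = faces, closed = NA),
                 class = "surface_mesh")
  m$closed <- is_closed_mesh(m)
  m
}

is_closed_mesh <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, %s, %d component(s)\n",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(x$closed)) "closed" else "open",
              mesh_components(x)))
  invisible(x)
}

#' Number of connected components of a mesh (vertex connectivity).
#' @param mesh a \code{surface_mesh}.
#' @return integer component count.
#' @export
mesh_components <- function(mesh) {
  n <- nrow(mesh$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh$faces
  for (k in seq_len(nrow(f))) {
    a <- find(f[k, 1]); b <- find(f[k, 2]); c3 <- find(f[k, 3])
    parent[b] <- a
    parent[c3] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  length(unique(roots[unique(as.vector(f))]))
}

# --- isosurface extraction -------------------------------------------------

# Tetrahedral decomposition of the unit cube around the main diagonal 0-7.
# Corner numbering: bit 0 = x, bit 1 = y, bit 2 = z.
.tet_table <- matrix(c(0, 1, 3, 7,
                       0, 1, 5, 7,
                       0, 2, 3, 7,
                       0, 2, 6, 7,
                       0, 4, 5, 7,
                       0, 4, 6, 7), ncol = 4, byrow = TRUE)

#' Extract an isosurface mesh from a label map
#'
#' Builds the binary mask of one label and triangulates its 0.5-isosurface in
#' world coordinates. The surface is extracted with a marching-tetrahedra
#' scheme (each grid cell split into six tetrahedra around its main diagonal),
#' a watertight variant of marching cubes with no ambiguous configurations.
#' The volume is padded with background so that surfaces close at the grid
#' boundary.
#'
#' @param map a \code{label_map}.
#' @param label integer label to surface.
#' @param smoothing_iters number of Laplacian smoothing iterations applied to
#'   the extracted mesh (default 0; smoothing changes enclosed volume).
#' @return A \code{surface_mesh} in mm. Disconnected masks yield a mesh with
#'   several components; a message reports the count.
#' @export
surface_from_labels <- function(map, label, smoothing_iters = 0L) {
  stopifnot(inherits(map, "label_map"))
  mask <- map$voxels == label
  if (!any(mask)) stop(sprintf("label %s not present in map", label))
  mesh <- isosurface(array(as.numeric(mask), dim(mask)), map$affine,
                     iso = 0.5, pad_value = 0)
  if (is.null(mesh)) stop("empty surface for label ", label)
  if (smoothing_iters > 0) mesh <- smooth_mesh(mesh, smoothing_iters)
  nc <- mesh_components(mesh)
  if (nc > 1) message(sprintf("surface for label %s has %d connected components", label, nc))
  mesh
}

# Marching tetrahedra over a scalar field. `affine` maps 0-based voxel
# indices of `vol` to world mm. Returns a surface_mesh or NULL if empty.
isosurface <- function(vol, affine, iso = 0.5, pad_value = NULL) {
  d <- dim(vol)
  if (is.null(pad_value)) pad_value <- min(vol) - 1
  padded <- array(pad_value, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol
  nx <- d[1] + 2L; ny <- d[2] + 2L; nz <- d[3] + 2L

  inside <- padded >= iso
  # cell origin linear indices (1-based within padded array)
  ii <- seq_len(nx - 1L); jj <- seq_len(ny - 1L); kk <- seq_len(nz - 1L)
  i0 <- rep(ii, times = (ny - 1L) * (nz - 1L))
  j0 <- rep(rep(jj, each = nx - 1L), times = nz - 1L)
  k0 <- rep(kk, each = (nx - 1L) * (ny - 1L))
  lin0 <- i0 + (j0 - 1L) * nx + (k0 - 1L) * nx * ny
  corner_off <- integer(8)
  for (c8 in 0:7) {
    corner_off[c8 + 1] <- bitwAnd(c8, 1L) +
      bitwAnd(bitwShiftR(c8, 1L), 1L) * nx +
      bitwAnd(bitwShiftR(c8, 2L), 1L) * nx * ny
  }
  s <- integer(length(lin0))
  for (c8 in 1:8) s <- s + inside[lin0 + corner_off[c8]]
  active <- which(s > 0L & s < 8L)
  if (length(active) == 0) return(NULL)
  lin0 <- lin0[active]
  i0 <- i0[active]; j0 <- j0[active]; k0 <- k0[active]

  A3 <- affine[1:3, 1:3]
  origin <- affine[1:3, 4]
  # world coords of a corner given cell origin vectors and corner id
  corner_world <- function(cells, c8) {
    bx <- bitwAnd(c8, 1L)
    by <- bitwAnd(bitwShiftR(c8, 1L), 1L)
    bz <- bitwAnd(bitwShiftR(c8, 2L), 1L)
    # padded 1-based -> original 0-based index: subtract 2
    idx <- cbind(i0[cells] + bx - 2L, j0[cells] + by - 2L, k0[cells] + bz - 2L)
    sweep(idx %*% t(A3), 2, origin, "+")
  }
  corner_val <- function(cells, c8) padded[lin0[cells] + corner_off[c8 + 1L]]

  edge_point <- function(cells, ca, cb) {
    va <- corner_val(cells, ca); vb <- corner_val(cells, cb)
    t <- (iso - va) / (vb - va)
    pa <- corner_world(cells, ca); pb <- corner_world(cells, cb)
    pa + t * (pb - pa)
  }

  tri_list <- vector("list", 0)
  n_active <- length(lin0)
  all_cells <- seq_len(n_active)
  for (tet in seq_len(nrow(.tet_table))) {
    cn <- .tet_table[tet, ]
    inA <- inside[lin0 + corner_off[cn[1] + 1L]]
    inB <- inside[lin0 + corner_off[cn[2] + 1L]]
    inC <- inside[lin0 + corner_off[cn[3] + 1L]]
    inD <- inside[lin0 + corner_off[cn[4] + 1L]]
    code <- inA + 2L * inB + 4L * inC + 8L * inD
    for (cd in 1:14) {
      cells <- all_cells[code == cd]
      if (length(cells) == 0) next
      bits <- c(bitwAnd(cd, 1L), bitwAnd(bitwShiftR(cd, 1L), 1L),
                bitwAnd(bitwShiftR(cd, 2L), 1L), bitwAnd(bitwShiftR(cd, 3L), 1L))
      ins <- cn[bits == 1L]
      outs <- cn[bits == 0L]
      # reference direction: from inside centroid to outside centroid
      ref <- Reduce(`+`, lapply(outs, function(c8) corner_world(cells, c8))) / length(outs) -
        Reduce(`+`, lapply(ins, function(c8) corner_world(cells, c8))) / length(ins)
      if (length(ins) == 1L || length(ins) == 3L) {
        apex <- if (length(ins) == 1L) ins else outs
        others <- if (length(ins) == 1L) outs else ins
        p1 <- edge_point(cells, apex, others[1])
        p2 <- edge_point(cells, apex, others[2])
        p3 <- edge_point(cells, apex, others[3])
        tri_list[[length(tri_list) + 1L]] <- orient_tris(p1, p2, p3, ref)
      } else {
        P <- ins[1]; Q <- ins[2]; R <- outs[1]; S <- outs[2]
        pr <- edge_point(cells, P, R)
        ps <- edge_point(cells, P, S)
        qr <- edge_point(cells, Q, R)
        qs <- edge_point(cells, Q, S)
        # quad in cyclic order pr - qr - qs - ps
        tri_list[[length(tri_list) + 1L]] <- orient_tris(pr, qr, qs, ref)
        tri_list[[length(tri_list) + 1L]] <- orient_tris(pr, qs, ps, ref)
      }
    }
  }
  if (length(tri_list) == 0) return(NULL)
  tris <- do.call(rbind, tri_list)  # (3*ntri) x 3, grouped per triangle
  build_mesh_from_tris(tris)
}

# Orient triangles (p1,p2,p3 are n x 3 blocks) so normals align with ref;
# returns a (3n) x 3 matrix with vertex rows v1a,v1b,v1c,v2a,...
orient_tris <- function(p1, p2, p3, ref) {
  n <- cross3_rows(p2 - p1, p3 - p1)
  flip <- rowSums(n * ref) < 0
  tmp <- p2[flip, , drop = FALSE]
  p2[flip, ] <- p3[flip, , drop = FALSE]
  p3[flip, ] <- tmp
  nt <- nrow(p1)
  out <- matrix(0, 3 * nt, 3)
  out[seq(1, 3 * nt, by = 3), ] <- p1
  out[seq(2, 3 * nt, by = 3), ] <- p2
  out[seq(3, 3 * nt, by = 3), ] <- p3
  out
}

build_mesh_from_tris <- function(tris) {
  key <- paste(tris[, 1], tris[, 2], tris[, 3])
  uk <- !duplicated(key)
  verts <- tris[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  faces <- matrix(idx, ncol = 3, byrow = TRUE)
  # drop degenerate triangles (repeated vertices or zero area)
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  if (!all(degen)) faces <- faces[!degen, , drop = FALSE]
  a <- verts[faces[, 1], , drop = FALSE]
  b <- verts[faces[, 2], , drop = FALSE]
  c3 <- verts[faces[, 3], , drop = FALSE]
  area2 <- row_norms(cross3_rows(b - a, c3 - a))
  faces <- faces[area2 > 1e-12, , drop = FALSE]
  surface_mesh(verts, faces)
}

#' Laplacian mesh smoothing
#'
#' Umbrella-operator smoothing: each vertex moves a fraction \code{lambda}
#' toward the mean of its neighbours, repeated \code{iterations} times.
#' Smoothing shrinks the mesh slightly, which changes enclosed volume, so
#' surface extraction leaves it off by default.
#'
#' @param mesh a \code{surface_mesh}.
#' @param iterations number of smoothing passes.
#' @param lambda step fraction in (0, 1].
#' @return the smoothed \code{surface_mesh}.
#' @export
smooth_mesh <- function(mesh, iterations = 1L, lambda = 0.5) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
             f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)])
  e <- unique(e)
  deg <- tabulate(e[, 1], nbins = nrow(v))
  ids <- sort(unique(e[, 1]))
  for (it in seq_len(iterations)) {
    nb_sum <- matrix(0, nrow(v), 3)
    for (cc in 1:3) {
      nb_sum[ids, cc] <- rowsum(v[e[, 2], cc], e[, 1], reorder = TRUE)
    }
    mean_nb <- nb_sum / pmax(deg, 1)
    v <- v + lambda * (mean_nb - v)
  }
  surface_mesh(v, f)
}

#' Volume enclosed by a closed mesh
#'
#' Signed-volume sum over origin-anchored tetrahedra (divergence theorem),
#' returned as a positive volume in cm^3. Orientation of the input faces is
#' irrelevant: the absolute total is reported.
#'
#' @param mesh a closed \code{surface_mesh} with coordinates in mm.
#' @return volume in cm^3.
#' @export
enclosed_volume <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!isTRUE(mesh$closed)) {
    stop("mesh is not closed; close the surface or use a voxel-count volume")
  }
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  signed <- rowSums(a * cross3_rows(b, c3)) / 6
  abs(sum(signed)) / 1000
}

#' Total surface area of a mesh in mm^2
#' @param mesh a \code{surface_mesh}.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  sum(row_norms(cross3_rows(b - a, c3 - a))) / 2
}

# --- point / triangle proximity -------------------------------------------

# Squared distance from a single point to each triangle (A, B, C row blocks),
# via the closest-point-on-triangle construction (barycentric clamping).
point_triangle_dist2 <- function(p, A, B, C) {
  n <- nrow(A)
  P <- matrix(p, n, 3, byrow = TRUE)
  ab <- B - A; ac <- C - A; ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- P - B
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- P - C
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  Q <- matrix(NA_real_, n, 3)
  done <- rep(FALSE, n)
  set_q <- function(mask, val) {
    mask <- mask & !done
    if (any(mask)) {
      Q[mask, ] <<- val[mask, , drop = FALSE]
      done[mask] <<- TRUE
    }
  }
  set_q(d1 <= 0 & d2 <= 0, A)
  set_q(d3 >= 0 & d4 <= d3, B)
  set_q(d6 >= 0 & d5 <= d6, C)
  tab <- d1 / (d1 - d3)
  set_q(vc <= 0 & d1 >= 0 & d3 <= 0, A + tab * ab)
  tac <- d2 / (d2 - d6)
  set_q(vb <= 0 & d2 >= 0 & d6 <= 0, A + tac * ac)
  tbc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  set_q(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + tbc * (C - B))
  if (!all(done)) {
    denom <- va + vb + vc
    v <- vb / denom; w <- vc / denom
    rest <- !done
    Q[rest, ] <- A[rest, , drop = FALSE] + v[rest] * ab[rest, , drop = FALSE] +
      w[rest] * ac[rest, , drop = FALSE]
  }
  rowSums((P - Q)^2)
}

mesh_face_corners <- function(mesh) {
  list(A = mesh$vertices[mesh$faces[, 1], , drop = FALSE],
       B = mesh$vertices[mesh$faces[, 2], , drop = FALSE],
       C = mesh$vertices[mesh$faces[, 3], , drop = FALSE])
}

# Precomputed face centroids and circumradius bounds for fast culling.
mesh_proximity_index <- function(mesh) {
  fc <- mesh_face_corners(mesh)
  centroid <- (fc$A + fc$B + fc$C) / 3
  r <- pmax(row_norms(fc$A - centroid),
            row_norms(fc$B - centroid),
            row_norms(fc$C - centroid))
  list(corners = fc, centroid = centroid, radius = r)
}

#' Faces of a mesh within a distance of a point
#'
#' Uses exact point-to-triangle distance (not centroid distance), so the
#' result does not depend on triangulation density.
#'
#' @param mesh a \code{surface_mesh}.
#' @param point_mm 3-vector in mm.
#' @param radius_mm search radius in mm (> 0).
#' @param index optional precomputed proximity index (internal reuse).
#' @return integer vector of face indices (possibly empty).
#' @export
faces_within <- function(mesh, point_mm, radius_mm, index = NULL) {
  if (radius_mm <= 0) stop("'radius_mm' must be > 0")
  if (is.null(index)) index <- mesh_proximity_index(mesh)
  d2c <- row_norms(sweep(index$centroid, 2, point_mm))
  cand <- which(d2c - index$radius <= radius_mm)
  if (length(cand) == 0) return(integer(0))
  d2 <- point_triangle_dist2(point_mm,
                             index$corners$A[cand, , drop = FALSE],
                             index$corners$B[cand, , drop = FALSE],
                             index$corners$C[cand, , drop = FALSE])
  cand[sqrt(d2) <= radius_mm]
}

#' Minimum distance from a point to a mesh surface
#' @param mesh a \code{surface_mesh}.
#' @param point_mm 3-vector in mm.
#' @param index optional precomputed proximity index.
#' @return distance in mm.
#' @export
point_mesh_distance <- function(mesh, point_mm, index = NULL) {
  if (is.null(index)) index <- mesh_proximity_index(mesh)
  d2c <- row_norms(sweep(index$centroid, 2, point_mm))
  upper <- min(d2c + index$radius)
  cand <- which(d2c - index$radius <= upper)
  d2 <- point_triangle_dist2(point_mm,
                             index$corners$A[cand, , drop = FALSE],
                             index$corners$B[cand, , drop = FALSE],
                             index$corners$C[cand, , drop = FALSE])
  sqrt(min(d2))
}

#' Apply a rigid (or general affine) transform to a mesh
#' @param mesh a \code{surface_mesh}.
#' @param rotation 3x3 matrix.
#' @param translation 3-vector in mm.
#' @return the transformed \code{surface_mesh}.
#' @export
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- sweep(mesh$vertices %*% t(rotation), 2, translation, "+")
  surface_mesh(v, mesh$faces)
}
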