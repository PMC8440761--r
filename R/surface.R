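# Smooth level-set surface extraction. The triangulated surface is taken
# from the real-valued probability map at the percentile threshold level,
# never from a binarized mask, so the mesh follows the sub-voxel position
# of the level set instead of stair-stepping along voxel faces. The
# implementation is marching tetrahedra: each cell of the dual grid
# (corners at voxel centers) is split into six tetrahedra sharing a main
# diagonal, and the level set is interpolated linearly along tetrahedron
# edges. Shared cell faces receive identical edge decompositions, so the
# triangle soup is watertight wherever the level set stays inside the grid.

# six-tetrahedra decomposition of the unit cell, corners numbered
# 1:(0,0,0) 2:(1,0,0) 3:(1,1,0) 4:(0,1,0) 5:(0,0,1) 6:(1,0,1) 7:(1,1,1) 8:(0,1,1)
tet_table <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                   c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
cube_offsets <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

#' Extract a level-set triangle surface from a probability map
#'
#' Triangulates the `eps = t` level set of the real-valued class map at the
#' threshold mapped from percentile `P`, with vertices at physical
#' coordinates (voxel centers sit at `(index - 0.5) * spacing`).
#'
#' @param map a [probability_map] (or a bare 3D numeric array).
#' @param class_i class whose map is contoured (default foreground).
#' @param P percentile in (0, 100); the contour level is
#'   [percentile_to_threshold]`(P)`.
#' @param spacing per-axis voxel size; defaults to the map's spacing.
#' @param level directly supplied contour level, overriding `P`.
#' @return object of class `triangle_mesh`: `vertices` is a `3T x 3` matrix
#'   (consecutive triples form triangles), plus `level` and `spacing`.
#' @export
extract_surface <- function(map, class_i = NULL, P = 50, spacing = NULL,
                            level = NULL) {
  if (inherits(map, "probability_map")) {
    vol <- class_map(map, class_i)
    spacing <- spacing %||% map$spacing
  } else {
    vol <- check_volume3d(map)
    spacing <- spacing %||% c(1, 1, 1)
  }
  spacing <- check_spacing(spacing)
  from_percentile <- is.null(level)
  level <- level %||% percentile_to_threshold(P)
  rng <- range(vol)
  if (level <= rng[1] || level >= rng[2])
    stop(sprintf("empty surface: level %g outside the open data range (%g, %g)",
                 level, rng[1], rng[2]), call. = FALSE)
  mesh <- marching_tetrahedra(vol, level, spacing)
  mesh$percentile <- if (from_percentile) P else NA_real_
  mesh
}

marching_tetrahedra <- function(vol, level, spacing = c(1, 1, 1)) {
  d <- dim(vol); nx <- d[1]; ny <- d[2]; nz <- d[3]
  if (any(d < 2)) stop("need at least 2 voxels per axis", call. = FALSE)
  v <- as.vector(vol)
  base <- as.matrix(expand.grid(i = seq_len(nx - 1), j = seq_len(ny - 1),
                                k = seq_len(nz - 1)))
  lin <- function(i, j, k) i + (j - 1) * nx + (k - 1L) * nx * ny
  corner <- vapply(1:8, function(c)
    lin(base[, 1] + cube_offsets[c, 1], base[, 2] + cube_offsets[c, 2],
        base[, 3] + cube_offsets[c, 3]), numeric(nrow(base)))
  if (!is.matrix(corner)) corner <- matrix(corner, ncol = 8)

  coord <- function(idx) {
    i <- (idx - 1) %% nx + 1
    j <- ((idx - 1) %/% nx) %% ny + 1
    k <- (idx - 1) %/% (nx * ny) + 1
    cbind((i - 0.5) * spacing[1], (j - 0.5) * spacing[2], (k - 0.5) * spacing[3])
  }
  # linear interpolation along an edge crossing the level set
  ipoint <- function(a, b) {
    fa <- v[a]; fb <- v[b]
    w <- (level - fa) / (fb - fa)
    coord(a) * (1 - w) + coord(b) * w
  }

  tris <- vector("list", 64)
  nt <- 0
  for (t in seq_len(nrow(tet_table))) {
    idx <- corner[, tet_table[t, ], drop = FALSE]
    ins <- matrix(v[idx] >= level, ncol = 4)
    code <- ins[, 1] + 2 * ins[, 2] + 4 * ins[, 3] + 8 * ins[, 4]
    active <- code > 0 & code < 15
    if (!any(active)) next
    idx <- idx[active, , drop = FALSE]
    code <- code[active]
    for (cc in unique(code)) {
      rows <- which(code == cc)
      sub <- idx[rows, , drop = FALSE]
      bits <- as.logical(bitwAnd(cc, c(1L, 2L, 4L, 8L)))
      inside <- which(bits); outside <- which(!bits)
      if (length(inside) == 1 || length(inside) == 3) {
        if (length(inside) == 1) { a <- sub[, inside]; o <- sub[, outside, drop = FALSE] }
        else                     { a <- sub[, outside]; o <- sub[, inside, drop = FALSE] }
        p1 <- ipoint(a, o[, 1]); p2 <- ipoint(a, o[, 2]); p3 <- ipoint(a, o[, 3])
        ref <- coord(a)
        sgn <- if (length(inside) == 1) -1 else 1   # orient away from inside
        nt <- nt + 1
        tris[[nt]] <- orient_tris(p1, p2, p3, ref, sgn)
      } else {  # 2 in / 2 out: quad split into two triangles
        a1 <- sub[, inside[1]];  a2 <- sub[, inside[2]]
        b1 <- sub[, outside[1]]; b2 <- sub[, outside[2]]
        q1 <- ipoint(a1, b1); q2 <- ipoint(a1, b2)
        q3 <- ipoint(a2, b2); q4 <- ipoint(a2, b1)
        ref <- (coord(a1) + coord(a2)) / 2
        nt <- nt + 1; tris[[nt]] <- orient_tris(q1, q2, q3, ref, -1)
        nt <- nt + 1; tris[[nt]] <- orient_tris(q1, q3, q4, ref, -1)
      }
    }
  }
  verts <- do.call(rbind, tris[seq_len(nt)])
  structure(list(vertices = verts, n_triangles = as.integer(nrow(verts) / 3),
                 level = level, spacing = spacing),
            class = "triangle_mesh")
}

# flip winding so the normal points away from (sgn = -1) or toward
# (sgn = +1) the reference point; returns stacked vertex rows (3 per tri)
orient_tris <- function(p1, p2, p3, ref, sgn) {
  n <- vcross(p2 - p1, p3 - p1)
  cen <- (p1 + p2 + p3) / 3
  flip <- sgn * rowSums(n * (ref - cen)) < 0
  if (any(flip)) { tmp <- p2[flip, , drop = FALSE]
    p2[flip, ] <- p3[flip, , drop = FALSE]; p3[flip, ] <- tmp }
  m <- nrow(p1)
  out <- matrix(0, 3 * m, 3)
  out[seq(1, 3 * m, 3), ] <- p1
  out[seq(2, 3 * m, 3), ] <- p2
  out[seq(3, 3 * m, 3), ] <- p3
  out
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Total area of a triangle mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return total surface area in squared physical units.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices
  i1 <- seq(1, nrow(V), 3)
  n <- vcross(V[i1 + 1, , drop = FALSE] - V[i1, , drop = FALSE],
              V[i1 + 2, , drop = FALSE] - V[i1, , drop = FALSE])
  sum(sqrt(rowSums(n^2))) / 2
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d triangles, level = %.4g, area = %.4g\n",
              x$n_triangles, x$level, mesh_area(x)))
  invisible(x)
}

#' Write a triangle mesh as binary STL
#'
#' Little-endian binary STL; facet normals are recomputed from the triangle
#' winding. Coordinates are in the physical units of the mesh spacing.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @export
write_stl <- function(mesh, path) {
  V <- mesh$vertices
  ntri <- nrow(V) %/% 3
  i1 <- seq(1, nrow(V), 3)
  n <- vcross(V[i1 + 1, , drop = FALSE] - V[i1, , drop = FALSE],
              V[i1 + 2, , drop = FALSE] - V[i1, , drop = FALSE])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  # 12 floats per facet: normal, v1, v2, v3
  dat <- rbind(t(n), t(V[i1, , drop = FALSE]),
               t(V[i1 + 1, , drop = FALSE]), t(V[i1 + 2, , drop = FALSE]))
  r48 <- writeBin(as.numeric(dat), raw(), size = 4, endian = "little")
  facet <- matrix(r48, nrow = 48)
  facet <- rbind(facet, matrix(as.raw(0), 2, ntri))  # attribute byte count
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("voxuq level-set surface, level=%g", mesh$level))
  writeBin(c(hdr, raw(80 - length(hdr))), con)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  writeBin(as.vector(facet), con)
  invisible(path)
}

# minimal binary STL reader (round-trip checks)
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  dat <- readBin(con, "raw", ntri * 50)
  m <- matrix(dat, nrow = 50)
  fl <- readBin(as.vector(m[1:48, ]), "numeric", 12 * ntri, size = 4,
                endian = "little")
  fl <- matrix(fl, nrow = 12)
  verts <- matrix(0, 3 * ntri, 3)
  verts[seq(1, 3 * ntri, 3), ] <- t(fl[4:6, , drop = FALSE])
  verts[seq(2, 3 * ntri, 3), ] <- t(fl[7:9, , drop = FALSE])
  verts[seq(3, 3 * ntri, 3), ] <- t(fl[10:12, , drop = FALSE])
  structure(list(vertices = verts, n_triangles = ntri, level = NA_real_,
                 spacing = c(1, 1, 1)), class = "triangle_mesh")
}
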