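#' Build the cubical cell complex of a regular 3-D Cartesian grid
#'
#' A regular Cartesian grid with `counts = c(nx, ny, nz)` vertices per axis is
#' treated as a cell complex: vertices (0-cells), axis-aligned edges (1-cells),
#' faces (2-cells) and cubes (3-cells), all with edge length `spacing`.
#'
#' Cell enumeration is deterministic and 1-based: within each family the index
#' runs lexicographically with x fastest, then y, then z.  Edges are grouped by
#' axis (all x-edges, then y-edges, then z-edges) and faces by normal axis
#' (x-normal faces spanning y-z first, then y-normal, then z-normal).
#' Orientations are fixed: edges point along the positive axis, faces follow
#' the right-hand rule with normal along the positive remaining axis, and
#' cubes are positively oriented.
#'
#' @param counts integer vector of length 3, vertices per axis (each >= 2).
#' @param spacing grid edge length (> 0), in the physical units of the input
#'   coordinates (Angstrom for molecular use).
#' @param origin coordinate of vertex (1,1,1); default `c(0,0,0)`.
#' @return an object of class `grid_complex` with fields `counts`, `spacing`,
#'   `origin`, `cell_counts` (N_k for k = 0..3) and enumeration bookkeeping.
#' @examples
#' gc <- build_grid_complex(c(3, 3, 3), spacing = 0.5)
#' gc$cell_counts  # 27 vertices, ..., 8 cubes
#' @export
build_grid_complex <- function(counts, spacing = 1, origin = c(0, 0, 0)) {
  counts <- as.integer(counts)
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 2L))
    stop("invalid grid: 'counts' must be three integers >= 2")
  if (!is.numeric(spacing) || length(spacing) != 1L || !is.finite(spacing) ||
      spacing <= 0)
    stop("invalid grid: 'spacing' must be a positive number")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("invalid grid: 'origin' must be a finite 3-vector")
  nx <- counts[1]; ny <- counts[2]; nz <- counts[3]
  # per-axis edge/face family dimensions
  e_dims <- list(x = c(nx - 1L, ny, nz),
                 y = c(nx, ny - 1L, nz),
                 z = c(nx, ny, nz - 1L))
  f_dims <- list(x = c(nx, ny - 1L, nz - 1L),   # x-normal: spans y,z
                 y = c(nx - 1L, ny, nz - 1L),
                 z = c(nx - 1L, ny - 1L, nz))
  n_e <- vapply(e_dims, prod, numeric(1))
  n_f <- vapply(f_dims, prod, numeric(1))
  cell_counts <- c(prod(counts), sum(n_e), sum(n_f),
                   prod(counts - 1L))
  structure(list(
    counts = counts, spacing = spacing, origin = origin,
    cell_counts = as.numeric(cell_counts),
    edge_dims = e_dims, edge_offsets = c(0, cumsum(n_e))[1:3],
    face_dims = f_dims, face_offsets = c(0, cumsum(n_f))[1:3],
    orientation = "positive-axis"
  ), class = "grid_complex")
}

#' @export
print.grid_complex <- function(x, ...) {
  cat("cubical grid complex:", paste(x$counts, collapse = " x "),
      "vertices, spacing", format(x$spacing), "\n")
  cat("  cells (k = 0..3):", paste(x$cell_counts, collapse = ", "),
      " Euler characteristic",
      x$cell_counts[1] - x$cell_counts[2] + x$cell_counts[3] - x$cell_counts[4],
      "\n")
  invisible(x)
}

# linear index (1-based) of lattice point (i,j,k) (1-based) in a box `dims`
.lin_index <- function(i, j, k, dims) {
  i + dims[1] * (j - 1L) + dims[1] * dims[2] * (k - 1L)
}

# inverse: 1-based (i,j,k) triples for linear ids in a box
.lin_unindex <- function(id, dims) {
  id0 <- id - 1L
  i <- id0 %% dims[1]
  j <- (id0 %/% dims[1]) %% dims[2]
  k <- id0 %/% (dims[1] * dims[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

# grids of all (i,j,k) (1-based) in a box, x fastest
.lattice_grid <- function(dims) {
  cbind(
    rep_len(seq_len(dims[1]), prod(dims)),
    rep_len(rep(seq_len(dims[2]), each = dims[1]), prod(dims)),
    rep(seq_len(dims[3]), each = dims[1] * dims[2])
  )
}

#' Signed incidence (discrete differential) operator of the grid complex
#'
#' Returns the sparse matrix \eqn{D_k} storing the signed incidence between
#' (k+1)-cells and k-cells, i.e. the transpose of the cell boundary operator:
#' the discrete exterior derivative mapping k-forms to (k+1)-forms.  Entries
#' are exactly -1, 0, +1 and the composition of consecutive operators is
#' identically zero.
#'
#' @param complex a [build_grid_complex()] object.
#' @param k degree, 0, 1 or 2.
#' @return a `dgCMatrix` of dimension N_{k+1} x N_k.
#' @export
incidence_matrix <- function(complex, k) {
  stopifnot(inherits(complex, "grid_complex"))
  if (!(length(k) == 1L && k %in% 0:2))
    stop("degree error: k must be 0, 1 or 2")
  n <- complex$counts
  if (k == 0L) .incidence_d0(complex)
  else if (k == 1L) .incidence_d1(complex)
  else .incidence_d2(complex)
}

.incidence_d0 <- function(gc) {
  n <- gc$counts
  rows <- integer(0); cols <- integer(0); vals <- integer(0)
  for (ax in 1:3) {
    ed <- gc$edge_dims[[ax]]
    off <- gc$edge_offsets[ax]
    ijk <- .lattice_grid(ed)
    eid <- off + seq_len(prod(ed))
    step <- c(0L, 0L, 0L); step[ax] <- 1L
    v0 <- .lin_index(ijk[, 1], ijk[, 2], ijk[, 3], n)
    v1 <- .lin_index(ijk[, 1] + step[1], ijk[, 2] + step[2],
                     ijk[, 3] + step[3], n)
    rows <- c(rows, eid, eid)
    cols <- c(cols, v0, v1)
    vals <- c(vals, rep(-1L, length(eid)), rep(1L, length(eid)))
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = as.numeric(vals),
                       dims = c(gc$cell_counts[2], gc$cell_counts[1]))
}

# edge id helper: axis in 1:3, lattice point of edge start
.edge_id <- function(gc, ax, i, j, k) {
  gc$edge_offsets[ax] + .lin_index(i, j, k, gc$edge_dims[[ax]])
}

.incidence_d1 <- function(gc) {
  rows <- integer(0); cols <- integer(0); vals <- integer(0)
  # face with normal along `ax` at lattice point (i,j,k) spans axes (a, b)
  # where (ax, a, b) is a cyclic permutation of (1,2,3); boundary circulation:
  #  +a-edge at base, +b-edge shifted by a, -a-edge shifted by b, -b-edge at base
  cyc <- list(c(2L, 3L), c(3L, 1L), c(1L, 2L))
  for (ax in 1:3) {
    fd <- gc$face_dims[[ax]]
    off <- gc$face_offsets[ax]
    ijk <- .lattice_grid(fd)
    fid <- off + seq_len(prod(fd))
    a <- cyc[[ax]][1]; b <- cyc[[ax]][2]
    sa <- c(0L, 0L, 0L); sa[a] <- 1L
    sb <- c(0L, 0L, 0L); sb[b] <- 1L
    e1 <- .edge_id(gc, a, ijk[, 1], ijk[, 2], ijk[, 3])
    e2 <- .edge_id(gc, b, ijk[, 1] + sa[1], ijk[, 2] + sa[2], ijk[, 3] + sa[3])
    e3 <- .edge_id(gc, a, ijk[, 1] + sb[1], ijk[, 2] + sb[2], ijk[, 3] + sb[3])
    e4 <- .edge_id(gc, b, ijk[, 1], ijk[, 2], ijk[, 3])
    m <- length(fid)
    rows <- c(rows, fid, fid, fid, fid)
    cols <- c(cols, e1, e2, e3, e4)
    vals <- c(vals, rep(1L, m), rep(1L, m), rep(-1L, m), rep(-1L, m))
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = as.numeric(vals),
                       dims = c(gc$cell_counts[3], gc$cell_counts[2]))
}

.face_id <- function(gc, ax, i, j, k) {
  gc$face_offsets[ax] + .lin_index(i, j, k, gc$face_dims[[ax]])
}

.incidence_d2 <- function(gc) {
  cd <- gc$counts - 1L
  ijk <- .lattice_grid(cd)
  cid <- seq_len(prod(cd))
  rows <- integer(0); cols <- integer(0); vals <- integer(0)
  for (ax in 1:3) {
    step <- c(0L, 0L, 0L); step[ax] <- 1L
    f0 <- .face_id(gc, ax, ijk[, 1], ijk[, 2], ijk[, 3])
    f1 <- .face_id(gc, ax, ijk[, 1] + step[1], ijk[, 2] + step[2],
                   ijk[, 3] + step[3])
    rows <- c(rows, cid, cid)
    cols <- c(cols, f0, f1)
    vals <- c(vals, rep(-1L, length(cid)), rep(1L, length(cid)))
  }
  Matrix::sparseMatrix(i = rows, j = cols, x = as.numeric(vals),
                       dims = c(gc$cell_counts[4], gc$cell_counts[3]))
}

# --- cell coordinate helpers --------------------------------------------------

#' Primal vertex coordinates
#'
#' Coordinates of all grid vertices in enumeration order (x fastest).
#' @param complex a grid complex.
#' @return an N_0 x 3 matrix.
#' @export
vertex_coordinates <- function(complex) {
  ijk <- .lattice_grid(complex$counts)
  sweep((ijk - 1) * complex$spacing, 2, complex$origin, `+`)
}

#' Dual point (3-cell center) coordinates
#'
#' Coordinates of the centers of all cubes, the vertices of the dual grid.
#' @param complex a grid complex.
#' @return an N_3 x 3 matrix.
#' @export
dual_coordinates <- function(complex) {
  ijk <- .lattice_grid(complex$counts - 1L)
  sweep((ijk - 0.5) * complex$spacing, 2, complex$origin, `+`)
}

# vertex ids (columns) of every k-cell, one row per cell: N_k x 2^k matrix
.cell_vertices <- function(gc, k) {
  n <- gc$counts
  if (k == 0L) {
    matrix(seq_len(gc$cell_counts[1]), ncol = 1)
  } else if (k == 1L) {
    out <- matrix(0L, gc$cell_counts[2], 2)
    for (ax in 1:3) {
      ed <- gc$edge_dims[[ax]]
      ijk <- .lattice_grid(ed)
      step <- c(0L, 0L, 0L); step[ax] <- 1L
      rows <- gc$edge_offsets[ax] + seq_len(prod(ed))
      out[rows, 1] <- .lin_index(ijk[, 1], ijk[, 2], ijk[, 3], n)
      out[rows, 2] <- .lin_index(ijk[, 1] + step[1], ijk[, 2] + step[2],
                                 ijk[, 3] + step[3], n)
    }
    out
  } else if (k == 2L) {
    out <- matrix(0L, gc$cell_counts[3], 4)
    cyc <- list(c(2L, 3L), c(3L, 1L), c(1L, 2L))
    for (ax in 1:3) {
      fd <- gc$face_dims[[ax]]
      ijk <- .lattice_grid(fd)
      a <- cyc[[ax]][1]; b <- cyc[[ax]][2]
      sa <- c(0L, 0L, 0L); sa[a] <- 1L
      sb <- c(0L, 0L, 0L); sb[b] <- 1L
      rows <- gc$face_offsets[ax] + seq_len(prod(fd))
      # corner order: (0,0), (a,0), (0,b), (a,b) -- multilinear corner order
      out[rows, 1] <- .lin_index(ijk[, 1], ijk[, 2], ijk[, 3], n)
      out[rows, 2] <- .lin_index(ijk[, 1] + sa[1], ijk[, 2] + sa[2],
                                 ijk[, 3] + sa[3], n)
      out[rows, 3] <- .lin_index(ijk[, 1] + sb[1], ijk[, 2] + sb[2],
                                 ijk[, 3] + sb[3], n)
      out[rows, 4] <- .lin_index(ijk[, 1] + sa[1] + sb[1], ijk[, 2] + sa[2] + sb[2],
                                 ijk[, 3] + sa[3] + sb[3], n)
    }
    out
  } else {
    cd <- gc$counts - 1L
    ijk <- .lattice_grid(cd)
    out <- matrix(0L, gc$cell_counts[4], 8)
    corner <- 1L
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      out[, corner] <- .lin_index(ijk[, 1] + dx, ijk[, 2] + dy, ijk[, 3] + dz, n)
      corner <- corner + 1L
    }
    out
  }
}

# cube ids (columns) incident to every k-cell; 0 marks a missing cube
# (cell on the grid boundary).  N_k x 2^(3-k) matrix.
.cell_cubes <- function(gc, k) {
  n <- gc$counts; cd <- gc$counts - 1L
  cube_at <- function(i, j, k3) {
    ok <- i >= 1L & i <= cd[1] & j >= 1L & j <= cd[2] & k3 >= 1L & k3 <= cd[3]
    out <- integer(length(i))
    out[ok] <- .lin_index(i[ok], j[ok], k3[ok], cd)
    out
  }
  if (k == 3L) {
    matrix(seq_len(gc$cell_counts[4]), ncol = 1)
  } else if (k == 2L) {
    out <- matrix(0L, gc$cell_counts[3], 2)
    for (ax in 1:3) {
      fd <- gc$face_dims[[ax]]
      ijk <- .lattice_grid(fd)
      step <- c(0L, 0L, 0L); step[ax] <- 1L
      rows <- gc$face_offsets[ax] + seq_len(prod(fd))
      out[rows, 1] <- cube_at(ijk[, 1] - step[1], ijk[, 2] - step[2],
                              ijk[, 3] - step[3])
      out[rows, 2] <- cube_at(ijk[, 1], ijk[, 2], ijk[, 3])
    }
    out
  } else if (k == 1L) {
    out <- matrix(0L, gc$cell_counts[2], 4)
    cyc <- list(c(2L, 3L), c(3L, 1L), c(1L, 2L))
    for (ax in 1:3) {
      ed <- gc$edge_dims[[ax]]
      ijk <- .lattice_grid(ed)
      a <- cyc[[ax]][1]; b <- cyc[[ax]][2]
      sa <- c(0L, 0L, 0L); sa[a] <- 1L
      sb <- c(0L, 0L, 0L); sb[b] <- 1L
      rows <- gc$edge_offsets[ax] + seq_len(prod(ed))
      corner <- 1L
      for (db in 0:1) for (da in 0:1) {
        out[rows, corner] <- cube_at(
          ijk[, 1] - (1L - da) * sa[1] - (1L - db) * sb[1],
          ijk[, 2] - (1L - da) * sa[2] - (1L - db) * sb[2],
          ijk[, 3] - (1L - da) * sa[3] - (1L - db) * sb[3])
        corner <- corner + 1L
      }
    }
    out
  } else {
    ijk <- .lattice_grid(n)
    out <- matrix(0L, gc$cell_counts[1], 8)
    corner <- 1L
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      out[, corner] <- cube_at(ijk[, 1] - 1L + dx, ijk[, 2] - 1L + dy,
                               ijk[, 3] - 1L + dz)
      corner <- corner + 1L
    }
    out
  }
}

#' Geometry of a single cell
#'
#' Returns the vertex ids, centroid, primal k-measure and dual corner points
#' (centers of incident cubes) of one cell.  For interior cells the dual cell
#' is an axis-aligned box of measure `spacing^(3-k)`; cells on the grid
#' boundary have fewer incident cubes and a proportionally reduced dual
#' measure.
#'
#' @param complex a grid complex.
#' @param k degree 0..3.
#' @param cell_id cell index (1-based) within degree k.
#' @return list with `vertices`, `centroid`, `primal_measure`, `dual_corners`
#'   (matrix of incident cube centers) and `dual_measure`.
#' @export
cell_geometry <- function(complex, k, cell_id) {
  stopifnot(inherits(complex, "grid_complex"), k %in% 0:3)
  if (!(length(cell_id) == 1L && cell_id >= 1 &&
        cell_id <= complex$cell_counts[k + 1]))
    stop("cell index out of range")
  verts <- .cell_vertices(complex, k)[cell_id, ]
  vc <- vertex_coordinates(complex)[verts, , drop = FALSE]
  cubes <- .cell_cubes(complex, k)[cell_id, ]
  cubes <- cubes[cubes > 0L]
  dc <- dual_coordinates(complex)[cubes, , drop = FALSE]
  ell <- complex$spacing
  list(vertices = verts,
       centroid = colMeans(vc),
       primal_measure = ell^k,
       dual_corners = dc,
       dual_measure = ell^(3 - k) * length(cubes) / 2^(3 - k))
}
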