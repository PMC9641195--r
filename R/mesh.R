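#' Triangle surface mesh
#'
#' Container for an indexed triangle surface: a matrix of 3D vertex
#' positions (millimetres) and a matrix of vertex-index triples whose
#' order defines the face winding. Winding is the sole carrier of
#' orientation information in this package; facet normals stored in STL
#' files are discarded on read and recomputed from winding on demand.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param name optional free-text label.
#' @param validate check the mesh invariants (finite coordinates, indices
#'   in range, no face repeating a vertex). Default `TRUE`.
#' @return An object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `name`.
#' @examples
#' m <- cube_mesh(10)
#' m
#' mesh_volume(m)
#' @export
triangle_mesh <- function(vertices, faces, name = "", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (length(vertices) == 0L) vertices <- matrix(numeric(0), 0L, 3L)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (length(faces) == 0L) faces <- matrix(integer(0), 0L, 3L)
  if (ncol(vertices) != 3L) stop("'vertices' must have 3 columns")
  if (ncol(faces) != 3L) stop("'faces' must have 3 columns")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (validate) {
    if (!all(is.finite(vertices))) stop("non-finite vertex coordinate")
    if (nrow(faces) > 0L) {
      if (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(vertices))
        stop("face index out of range")
      if (any(faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
              faces[, 1L] == faces[, 3L]))
        stop("degenerate face: repeated vertex index within a face")
    }
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)[1L]),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("Triangle surface mesh",
      if (nzchar(x$name)) paste0("'", x$name, "'") else "", "\n")
  cat(sprintf("  %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$vertices) > 0L) {
    r <- apply(x$vertices, 2L, range)
    cat(sprintf("  bounding box [%.2f, %.2f] x [%.2f, %.2f] x [%.2f, %.2f] mm\n",
                r[1, 1], r[2, 1], r[1, 2], r[2, 2], r[1, 3], r[2, 3]))
  }
  invisible(x)
}

# Per-face unit normals from winding; zero vector for degenerate faces.
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  n <- cross3(a, b)
  len <- sqrt(rowSums(n * n))
  ok <- len > 0
  n[ok, ] <- n[ok, , drop = FALSE] / len[ok]
  n[!ok, ] <- 0
  list(normal = n, double_area = len)
}

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# Exact (or tolerance-grid) vertex key used for merging and duplicate counts.
vertex_key <- function(vertices, tolerance = 0) {
  if (tolerance > 0) {
    v <- round(vertices / tolerance)
  } else {
    v <- vertices
  }
  # %a formatting is an exact binary representation, so exact merges never
  # confuse coordinates that differ below decimal print precision.
  paste(sprintf("%a", v[, 1L]), sprintf("%a", v[, 2L]), sprintf("%a", v[, 3L]))
}

#' Mesh validity diagnostics
#'
#' Computes the topological checks a signed-volume computation depends on:
#' the polygon-summation volume of a surface is only the enclosed volume
#' when the surface is closed (watertight: every edge shared by exactly two
#' faces) and consistently oriented (each shared edge traversed in opposite
#' directions by its two faces).
#'
#' @param mesh a [triangle_mesh()].
#' @param tolerance merge tolerance (mm) used when counting duplicate
#'   vertices; 0 means exact coordinate equality.
#' @return An object of class `mesh_diagnostics`: a list with
#'   `is_watertight`, `is_orientation_consistent`, `n_degenerate_faces`,
#'   `n_duplicate_vertices`, plus edge counts.
#' @examples
#' d <- mesh_diagnostics(cube_mesh(10))
#' d$is_watertight
#' @export
mesh_diagnostics <- function(mesh, tolerance = 0) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  nf <- nrow(f)
  if (nf == 0L) {
    return(structure(list(is_watertight = FALSE,
                          is_orientation_consistent = TRUE,
                          n_degenerate_faces = 0L,
                          n_duplicate_vertices = as.integer(
                            sum(duplicated(vertex_key(mesh$vertices, tolerance)))),
                          n_edges = 0L, n_boundary_edges = 0L),
                     class = "mesh_diagnostics"))
  }
  ed <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  lo <- pmin(ed[, 1L], ed[, 2L])
  hi <- pmax(ed[, 1L], ed[, 2L])
  ukey <- lo * (max(hi) + 1) + hi        # undirected edge key
  dkey <- ed[, 1L] * (max(ed) + 1) + ed[, 2L]  # directed edge key
  cnt <- table(ukey)
  watertight <- all(cnt == 2L)
  # Consistent orientation: the two faces at an edge traverse it in opposite
  # directions, i.e. no directed edge occurs twice.
  oriented <- !anyDuplicated(dkey)
  fn <- face_normals(mesh)
  structure(list(
    is_watertight = watertight,
    is_orientation_consistent = oriented,
    n_degenerate_faces = as.integer(sum(fn$double_area == 0)),
    n_duplicate_vertices = as.integer(
      sum(duplicated(vertex_key(mesh$vertices, tolerance)))),
    n_edges = length(cnt),
    n_boundary_edges = as.integer(sum(cnt == 1L))
  ), class = "mesh_diagnostics")
}

#' @export
print.mesh_diagnostics <- function(x, ...) {
  cat("Mesh diagnostics\n")
  cat(sprintf("  watertight:             %s\n", x$is_watertight))
  cat(sprintf("  orientation consistent: %s\n", x$is_orientation_consistent))
  cat(sprintf("  degenerate faces:       %d\n", x$n_degenerate_faces))
  cat(sprintf("  duplicate vertices:     %d\n", x$n_duplicate_vertices))
  cat(sprintf("  edges: %d (%d boundary)\n", x$n_edges, x$n_boundary_edges))
  invisible(x)
}

#' Axis-aligned cube mesh
#'
#' A 12-facet closed cube with outward winding, mainly useful as a fixture
#' with exactly known volume.
#'
#' @param side edge length in mm.
#' @param origin corner with the smallest coordinates.
#' @return a [triangle_mesh()].
#' @export
cube_mesh <- function(side = 10, origin = c(0, 0, 0)) {
  s <- side
  v <- matrix(c(0, 0, 0,  s, 0, 0,  s, s, 0,  0, s, 0,
                0, 0, s,  s, 0, s,  s, s, s,  0, s, s),
              ncol = 3L, byrow = TRUE)
  v <- sweep(v, 2L, as.numeric(origin), "+")
  f <- matrix(c(1, 3, 2,  1, 4, 3,   # bottom (z = 0), outward = -z
                5, 6, 7,  5, 7, 8,   # top, outward = +z
                1, 2, 6,  1, 6, 5,   # y = 0 side
                2, 3, 7,  2, 7, 6,   # x = s side
                3, 4, 8,  3, 8, 7,   # y = s side
                4, 1, 5,  4, 5, 8),  # x = 0 side
              ncol = 3L, byrow = TRUE)
  triangle_mesh(v, f, name = sprintf("cube_%gmm", s))
}
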