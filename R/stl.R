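#' Read an STL surface mesh
#'
#' Reads the stereolithography (STL) surface-geometry exchange format in
#' either dialect. Auto-detection checks whether the file begins with a
#' valid `solid` ASCII structure and falls back to binary otherwise (many
#' binary exporters also write "solid" into the 80-byte header, so the
#' check looks for ASCII facet structure, not just the keyword).
#'
#' Positions are merged into one vertex record per unique position
#' (bitwise-exact by default, optionally within `merge_tolerance`); face
#' winding is preserved exactly as stored. Stored facet normals are
#' discarded: orientation information is taken from winding alone.
#'
#' @param path file path.
#' @param dialect `"auto"` (default), `"ascii"` or `"binary"`.
#' @param merge_tolerance vertex merge tolerance in mm; 0 = exact.
#' @return a [triangle_mesh()].
#' @seealso [write_stl()]
#' @export
read_stl <- function(path, dialect = c("auto", "ascii", "binary"),
                     merge_tolerance = 0) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") dialect <- detect_stl_dialect(path)
  tri <- if (dialect == "ascii") read_stl_ascii(path) else read_stl_binary(path)
  mesh_from_triangle_soup(tri, merge_tolerance,
                          name = sub("\\.stl$", "", basename(path),
                                     ignore.case = TRUE))
}

detect_stl_dialect <- function(path) {
  n <- min(file.size(path), 4096L)
  head <- readBin(path, "raw", n)
  if (any(head == as.raw(0L))) return("binary")
  txt <- rawToChar(head)
  lines <- strsplit(txt, "\r?\n")[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[1L], "solid")) return("binary")
  if (length(lines) == 1L) return("ascii")  # tiny/empty solid
  if (startsWith(lines[2L], "facet") || startsWith(lines[2L], "endsolid"))
    return("ascii")
  "binary"
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  vl <- grep("^vertex([[:space:]]|$)", trimmed)
  fl <- grep("^facet([[:space:]]|$)", trimmed)
  if (length(vl) %% 3L != 0L)
    stop(sprintf("ASCII STL parse error: %d vertex lines (not a multiple of 3)",
                 length(vl)))
  if (length(fl) != length(vl) / 3L)
    stop(sprintf(
      "ASCII STL parse error: %d 'facet' lines but %d vertex triples",
      length(fl), length(vl) / 3L))
  if (length(vl) == 0L)
    return(matrix(numeric(0), 0L, 3L))
  toks <- strsplit(trimmed[vl], "[[:space:]]+")
  nt <- lengths(toks)
  if (any(nt != 4L)) {
    bad <- vl[which(nt != 4L)[1L]]
    stop(sprintf("ASCII STL parse error at line %d: expected 'vertex x y z'", bad))
  }
  m <- matrix(suppressWarnings(as.numeric(t(vapply(toks, `[`, character(3L), 2:4)))),
              ncol = 3L, byrow = FALSE)
  if (anyNA(m)) {
    bad <- vl[which(rowSums(is.na(m)) > 0)[1L]]
    stop(sprintf("ASCII STL parse error at line %d: non-numeric coordinate", bad))
  }
  m
}

read_stl_binary <- function(path) {
  size <- file.size(path)
  if (size < 84)
    stop(sprintf("binary STL parse error: file is %d bytes, header needs 84", size))
  raw <- readBin(path, "raw", size)
  nf <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
  if (is.na(nf) || nf < 0L)
    stop("binary STL parse error: facet count does not fit a signed 32-bit integer")
  expected <- 84 + 50 * as.numeric(nf)
  if (size < expected)
    stop(sprintf(
      "binary STL parse error: %d facets declared need %d bytes, file has %d (truncated at facet %d)",
      nf, expected, size, (size - 84) %/% 50 + 1))
  if (nf == 0L) return(matrix(numeric(0), 0L, 3L))
  base <- 84 + (seq_len(nf) - 1) * 50
  idx <- rep(base, each = 48L) + seq_len(48L)   # 12 float32 per record
  vals <- readBin(raw[idx], "double", size = 4L, n = 12L * nf, endian = "little")
  rec <- matrix(vals, ncol = 12L, byrow = TRUE)
  if (!all(is.finite(rec[, 4:12])))
    stop("binary STL parse error: non-finite vertex coordinate")
  # columns 1:3 are the stored normal, ignored by design
  tri <- matrix(0, 3L * nf, 3L)
  tri[seq(1L, by = 3L, length.out = nf), ] <- rec[, 4:6, drop = FALSE]
  tri[seq(2L, by = 3L, length.out = nf), ] <- rec[, 7:9, drop = FALSE]
  tri[seq(3L, by = 3L, length.out = nf), ] <- rec[, 10:12, drop = FALSE]
  tri
}

# tri: (3*nfaces) x 3 matrix of vertex positions in face-stream order.
mesh_from_triangle_soup <- function(tri, merge_tolerance = 0, name = "") {
  nf <- nrow(tri) %/% 3L
  if (nf == 0L)
    return(triangle_mesh(matrix(numeric(0), 0L, 3L),
                         matrix(integer(0), 0L, 3L), name = name))
  key <- vertex_key(tri, merge_tolerance)
  first <- !duplicated(key)
  id <- match(key, key[first])
  vertices <- tri[first, , drop = FALSE]
  faces <- matrix(id, ncol = 3L, byrow = TRUE)
  # merging can collapse sliver triangles to repeated indices; drop them
  deg <- faces[, 1L] == faces[, 2L] | faces[, 2L] == faces[, 3L] |
    faces[, 1L] == faces[, 3L]
  if (any(deg)) {
    warning(sprintf("dropped %d degenerate face(s) after vertex merge", sum(deg)))
    faces <- faces[!deg, , drop = FALSE]
  }
  triangle_mesh(vertices, faces, name = name)
}

#' Write an STL surface mesh
#'
#' Binary files follow the de-facto standard little-endian layout: 80-byte
#' header, uint32 facet count, then 50-byte records (normal, three
#' vertices as float32, 2-byte attribute word written as zero). Normals
#' are recomputed from winding. A write/read round trip reproduces the
#' face geometry to 32-bit float precision (binary) or to the printed
#' decimal precision (ASCII, 17 significant digits, i.e. exactly).
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  dialect <- match.arg(dialect)
  nf <- nrow(mesh$faces)
  fn <- face_normals(mesh)$normal
  v1 <- mesh$vertices[mesh$faces[, 1L], , drop = FALSE]
  v2 <- mesh$vertices[mesh$faces[, 2L], , drop = FALSE]
  v3 <- mesh$vertices[mesh$faces[, 3L], , drop = FALSE]
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "chambervol binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    if (nf > 0L) {
      rec <- cbind(fn, v1, v2, v3)           # nf x 12 float32 payload
      f4 <- writeBin(as.numeric(t(rec)), raw(), size = 4L, endian = "little")
      out <- raw(50L * nf)                    # attribute words stay zero
      pos <- rep((seq_len(nf) - 1L) * 50L, each = 48L) + seq_len(48L)
      out[pos] <- f4
      writeBin(out, con)
    }
  } else {
    solid <- if (nzchar(mesh$name)) mesh$name else "mesh"
    num <- function(m) sprintf("%.17g %.17g %.17g", m[, 1L], m[, 2L], m[, 3L])
    body <- if (nf > 0L) {
      as.vector(rbind(
        paste0("  facet normal ", num(fn)),
        "    outer loop",
        paste0("      vertex ", num(v1)),
        paste0("      vertex ", num(v2)),
        paste0("      vertex ", num(v3)),
        "    endloop",
        "  endfacet"))
    } else character(0)
    writeLines(c(paste("solid", solid), body, paste("endsolid", solid)), path)
  }
  invisible(path)
}
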