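#' Triangle mesh container
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return A `tri_mesh` object.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L)
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  if (any(!is.finite(vertices))) stop("non-finite vertex coordinates", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh: %d vertices, %d faces>\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Watertightness check
#'
#' A closed orientable triangle shell has every edge shared by exactly two
#' faces in opposite directions and Euler characteristic 2 (genus 0).
#'
#' @param mesh A `tri_mesh`.
#' @return List with `watertight` (logical), `euler`, `boundary_edges`.
#' @export
mesh_watertight <- function(mesh) {
  f <- mesh$faces
  half <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(half[, 1], half[, 2]), pmax(half[, 1], half[, 2]))
  counts <- table(key)
  boundary <- sum(counts == 1L)
  manifold <- all(counts == 2L)
  v_used <- length(unique(as.vector(f)))
  e <- length(counts)
  euler <- v_used - e + nrow(f)
  list(
    watertight = manifold && boundary == 0L,
    euler = euler,
    boundary_edges = boundary
  )
}

#' Export a triangle mesh
#'
#' Binary STL by default; OBJ and PLY are ASCII. Units are mm throughout;
#' STL stores float32 coordinates.
#'
#' @param mesh A `tri_mesh` with at least one face.
#' @param path Output file path.
#' @param format `"stl"`, `"obj"` or `"ply"` (default from the file
#'   extension, falling back to STL).
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"))
  if (nrow(mesh$faces) == 0L || nrow(mesh$vertices) == 0L) {
    stop("cannot export an empty mesh", call. = FALSE)
  }
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("stl", "obj", "ply")) ext else "stl"
  }
  format <- tolower(format)
  switch(format,
    stl = write_stl_binary(mesh, path),
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path),
    stop("unknown mesh format: ", format, call. = FALSE)
  )
  invisible(path)
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("femplate binary STL (mm)", width = 80, flag = "-"))
  writeBin(header[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  nrm <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  # 12 floats per facet: normal + three vertices
  block <- t(cbind(nrm,
                   v[f[, 1], , drop = FALSE],
                   v[f[, 2], , drop = FALSE],
                   v[f[, 3], , drop = FALSE]))
  for (i in seq_len(nf)) {
    writeBin(as.numeric(block[, i]), con, size = 4L, endian = "little")
    writeBin(as.integer(0L), con, size = 2L, endian = "little")
  }
  invisible(path)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# femplate OBJ export (mm)", con)
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0", "comment femplate export (mm)",
    sprintf("element vertex %d", nrow(mesh$vertices)),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nrow(mesh$faces)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  writeLines(sprintf("%.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d",
                     mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read a triangle mesh
#'
#' Reads binary/ASCII STL, OBJ and ASCII PLY files written by
#' [export_mesh()] (and by other standard writers of the same dialects).
#' STL triangle soup is welded back into an indexed mesh on exact
#' float32 coordinate matches.
#'
#' @param path File path.
#' @param format Override the extension-derived format.
#' @return A `tri_mesh`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
    stl = read_stl(path),
    obj = read_obj(path),
    ply = read_ply(path),
    stop("unknown mesh format: ", format, call. = FALSE)
  )
}

read_stl <- function(path) {
  head <- readBin(path, "raw", n = 512L)
  is_ascii <- identical(rawToChar(head[1:5]), "solid") &&
    grepl("facet", rawToChar(head), fixed = TRUE, useBytes = TRUE)
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vx <- lines[grepl("^\\s*vertex", lines)]
    xyz <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80L)
    nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    xyz <- matrix(0, nf * 3L, 3L)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
      readBin(con, "integer", n = 1L, size = 2L, endian = "little")
      xyz[(i - 1L) * 3L + 1:3, ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
    }
  }
  key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
  uid <- !duplicated(key)
  verts <- xyz[uid, , drop = FALSE]
  index <- match(key, key[uid])
  faces <- matrix(index, ncol = 3L, byrow = TRUE)
  tri_mesh(verts, faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[grepl("^v ", lines)]
  fl <- lines[grepl("^f ", lines)]
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(p) as.numeric(p[2:4])))
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p) {
    as.integer(sub("/.*$", "", p[2:4]))
  }))
  tri_mesh(verts, faces)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nv <- as.integer(sub("element vertex ", "", lines[grepl("^element vertex", lines)]))
  nf <- as.integer(sub("element face ", "", lines[grepl("^element face", lines)]))
  start <- which(lines == "end_header") + 1L
  verts <- do.call(rbind, lapply(strsplit(lines[start:(start + nv - 1L)], "\\s+"),
                                 function(p) as.numeric(p[1:3])))
  fl <- lines[(start + nv):(start + nv + nf - 1L)]
  faces <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(p) {
    as.integer(p[2:4]) + 1L
  }))
  tri_mesh(verts, faces)
}
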