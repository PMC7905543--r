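#' Triangle mesh container
#'
#' Fragment surface geometry in millimetres. Vertices are an ordered n x 3
#' matrix and faces are triples of 1-based vertex indices. Vertex order is
#' the identity correspondence across poses of the same fragment, so
#' duplicate vertices are deliberately never merged by the readers.
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param name fragment identifier string.
#' @return object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, name = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || nrow(vertices) < 3L || anyNA(vertices)) {
    stop("vertices must be a numeric n x 3 matrix with n >= 3 and no missing values")
  }
  if (ncol(faces) != 3L || nrow(faces) < 1L || anyNA(faces)) {
    stop("empty mesh: faces must be an m x 3 index matrix with m >= 1")
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop(sprintf("face indices out of range [1, %d]", nrow(vertices)))
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Mesh diameter (bounding-box diagonal)
#' @param mesh `triangle_mesh` or point matrix.
#' @return diagonal length of the axis-aligned bounding box, mm.
#' @export
mesh_diameter <- function(mesh) {
  V <- if (inherits(mesh, "triangle_mesh")) mesh$vertices else as.matrix(mesh)
  rng <- apply(V, 2, range)
  sqrt(sum((rng[2, ] - rng[1, ])^2))
}

#' Apply a rigid transform to a mesh
#' @param mesh `triangle_mesh`.
#' @param tf `rigid_transform`.
#' @return transformed `triangle_mesh` (faces and name unchanged).
#' @export
transform_mesh <- function(mesh, tf) {
  triangle_mesh(rt_apply(tf, mesh$vertices), mesh$faces, mesh$name)
}

#' Read a triangle mesh from STL or PLY
#'
#' Supports binary and ASCII STL and ASCII PLY. STL stores three vertices
#' per facet; these are kept unmerged so that vertex order remains a stable
#' correspondence. PLY vertices are kept in file order.
#'
#' @param path file path; format chosen by extension (`.stl`, `.ply`).
#' @param name fragment identifier; defaults to the file name sans extension.
#' @return `triangle_mesh`.
#' @export
read_mesh <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         stl = read_stl(path, name),
         ply = read_ply(path, name),
         stop(sprintf("unsupported mesh format '.%s' (expected .stl or .ply)", ext)))
}

read_stl <- function(path, name) {
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", n = 512L)
  head_txt <- rawToChar(head_raw[head_raw != as.raw(0)], multiple = FALSE)
  is_ascii <- grepl("^\\s*solid", head_txt) && grepl("facet|endsolid", head_txt)
  close(con); on.exit()
  if (is_ascii) read_stl_ascii(path, name) else read_stl_binary(path, name)
}

read_stl_ascii <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L) stop(sprintf("empty mesh: no facets in ASCII STL '%s'", path))
  if (length(vlines) %% 3L != 0L) {
    stop(sprintf("malformed ASCII STL '%s': vertex count %d not a multiple of 3",
                 path, length(vlines)))
  }
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(f) as.numeric(f[2:4]))
  V <- do.call(rbind, nums)
  if (anyNA(V)) stop(sprintf("malformed ASCII STL '%s': non-numeric vertex coordinates", path))
  nf <- nrow(V) / 3L
  F <- matrix(seq_len(3L * nf), ncol = 3, byrow = TRUE)
  triangle_mesh(V, F, name)
}

read_stl_binary <- function(path, name) {
  size <- file.size(path)
  if (size < 84) stop(sprintf("truncated binary STL '%s': %d bytes < 84-byte header", path, size))
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (nf <= 0L) stop(sprintf("empty mesh: binary STL '%s' declares %d facets", path, nf))
  expected <- 84 + 50 * as.double(nf)
  if (size < expected) {
    stop(sprintf("truncated binary STL '%s': %d bytes, %d facets require %.0f",
                 path, size, nf, expected))
  }
  V <- matrix(0, nrow = 3L * nf, ncol = 3)
  for (i in seq_len(nf)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    readBin(con, "raw", n = 2L)  # attribute byte count
    V[(3L * i - 2L):(3L * i), ] <- matrix(rec[4:12], ncol = 3, byrow = TRUE)
  }
  F <- matrix(seq_len(3L * nf), ncol = 3, byrow = TRUE)
  triangle_mesh(V, F, name)
}

read_ply <- function(path, name) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply") {
    stop(sprintf("malformed PLY '%s': missing 'ply' magic", path))
  }
  hdr_end <- match("end_header", trimws(lines))
  if (is.na(hdr_end)) stop(sprintf("malformed PLY '%s': no end_header", path))
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (!any(grepl("^format\\s+ascii", hdr))) {
    stop(sprintf("unsupported PLY '%s': only ASCII PLY is handled", path))
  }
  els <- grep("^element\\s", hdr)
  counts <- list()
  for (i in els) {
    f <- strsplit(hdr[i], "\\s+")[[1]]
    counts[[f[2]]] <- as.integer(f[3])
  }
  nv <- counts[["vertex"]]; nf <- counts[["face"]]
  if (is.null(nv) || is.null(nf)) stop(sprintf("malformed PLY '%s': need vertex and face elements", path))
  if (nf < 1L) stop(sprintf("empty mesh: PLY '%s' has no faces", path))
  body <- trimws(lines[(hdr_end + 1L):length(lines)])
  body <- body[nzchar(body)]
  if (length(body) < nv + nf) stop(sprintf("truncated PLY '%s'", path))
  vparts <- strsplit(body[seq_len(nv)], "\\s+")
  V <- do.call(rbind, lapply(vparts, function(f) as.numeric(f[1:3])))
  if (anyNA(V)) stop(sprintf("malformed PLY '%s': non-numeric vertex coordinates", path))
  fparts <- strsplit(body[nv + seq_len(nf)], "\\s+")
  tris <- list()
  for (f in fparts) {
    k <- as.integer(f[1])
    idx <- as.integer(f[2:(k + 1)]) + 1L  # PLY is 0-based
    if (anyNA(idx) || k < 3L) stop(sprintf("malformed PLY '%s': bad face record", path))
    # fan-triangulate polygons
    for (j in seq_len(k - 2L)) tris[[length(tris) + 1L]] <- c(idx[1], idx[j + 1L], idx[j + 2L])
  }
  triangle_mesh(V, do.call(rbind, tris), name)
}

#' Write a triangle mesh as ASCII STL
#' @param mesh `triangle_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mesh_stl <- function(mesh, path) {
  V <- mesh$vertices; F <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$name), con)
  for (i in seq_len(nrow(F))) {
    a <- V[F[i, 1], ]; b <- V[F[i, 2], ]; d <- V[F[i, 3], ]
    n <- c((b[2] - a[2]) * (d[3] - a[3]) - (b[3] - a[3]) * (d[2] - a[2]),
           (b[3] - a[3]) * (d[1] - a[1]) - (b[1] - a[1]) * (d[3] - a[3]),
           (b[1] - a[1]) * (d[2] - a[2]) - (b[2] - a[2]) * (d[1] - a[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[1], n[2], n[3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", c(a[1], b[1], d[1]),
                         c(a[2], b[2], d[2]), c(a[3], b[3], d[3])),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines(sprintf("endsolid %s", mesh$name), con)
  invisible(path)
}

#' Read a rigid pose from JSON
#'
#' Expects `{"matrix": [[...4x4 row-major...]], "units": "mm"}` with the
#' convention `v' = R v + t`.
#'
#' @param path JSON file path.
#' @return `rigid_transform`.
#' @export
read_pose <- function(path) {
  if (!file.exists(path)) stop(sprintf("pose file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$matrix)) stop(sprintf("invalid pose '%s': missing 'matrix' field", path))
  M <- as.matrix(obj$matrix)
  if (!all(dim(M) == c(4L, 4L))) stop(sprintf("invalid pose '%s': matrix is not 4x4", path))
  rt_from_homogeneous(M)
}

#' Write a rigid pose to JSON
#' @param tf `rigid_transform`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pose <- function(tf, path) {
  M <- rt_to_homogeneous(tf)
  jsonlite::write_json(list(matrix = M, units = "mm"), path,
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
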