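#' Read a triangle mesh from STL, PLY or OBJ
#'
#' Supports ASCII and binary STL, ASCII and binary little-endian PLY, and
#' OBJ files restricted to `v`/`f` records (1-based indices, the standard
#' dialect). Coordinates are taken verbatim as millimetres. STL carries no
#' index sharing, so on load vertices closer than 1e-6 mm are merged to
#' recover connectivity. Degenerate faces are dropped with a warning.
#'
#' @param path Path to the mesh file.
#' @param format One of `"auto"` (from the file extension), `"stl"`,
#'   `"ply"`, `"obj"`.
#' @param name Label for the mesh; defaults to the file name.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply", "obj"),
                      name = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: file not found: ", path)
  if (format == "auto") format <- format_from_ext(path)
  if (is.null(name)) name <- basename(path)
  m <- switch(format,
              stl = read_stl(path),
              ply = read_ply(path),
              obj = read_obj(path))
  triangle_mesh(m$vertices, m$faces, name = name)
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' Round-trip `read_mesh(write_mesh(m))` reproduces vertices to float
#' precision (exactly, for the ASCII writers used here, which print full
#' double precision) and identical faces.
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path.
#' @param format As in [read_mesh()].
#' @param binary Write the binary variant (STL and PLY only). Binary STL
#'   stores single-precision floats, so round trips are exact only to about
#'   1e-7 relative precision.
#' @return Invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply", "obj"),
                       binary = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- format_from_ext(path)
  if (nrow(mesh$vertices) == 0 || nrow(mesh$faces) == 0)
    stop("refusing to write an empty mesh")
  switch(format,
         stl = if (binary) write_stl_binary(mesh, path) else
           write_stl_ascii(mesh, path),
         ply = if (binary) write_ply_binary(mesh, path) else
           write_ply_ascii(mesh, path),
         obj = write_obj(mesh, path))
  invisible(path)
}

format_from_ext <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("stl", "ply", "obj"))
    stop("cannot infer mesh format from extension: ", path)
  ext
}

# ---- STL ---------------------------------------------------------------

# merge vertices within tolerance (grid snap at tol) and reindex faces
merge_vertices <- function(tri_verts, tol = 1e-6) {
  key <- paste(round(tri_verts[, 1] / tol), round(tri_verts[, 2] / tol),
               round(tri_verts[, 3] / tol))
  idx <- match(key, key)                  # first occurrence per key
  keep <- sort(unique(idx))
  remap <- match(idx, keep)
  verts <- tri_verts[keep, , drop = FALSE]
  faces <- matrix(remap, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}

stl_is_ascii <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 512)
  printable <- head[head >= as.raw(0x20) & head <= as.raw(0x7e)]
  txt <- rawToChar(printable)
  startsWith(trimws(tolower(txt)), "solid") && grepl("facet", tolower(txt))
}

read_stl <- function(path) {
  if (stl_is_ascii(path)) read_stl_ascii(path) else read_stl_binary(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0 || length(vlines) %% 3 != 0)
    stop("malformed ASCII STL: vertex count not a multiple of 3 in ", path)
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(tok)
    as.numeric(tok[2:4]))
  tv <- do.call(rbind, nums)
  if (any(!is.finite(tv))) stop("malformed ASCII STL: non-numeric vertex")
  merge_vertices(tv)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nfaces <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (is.na(nfaces) || nfaces <= 0) stop("malformed binary STL: ", path)
  rec <- readBin(con, "raw", nfaces * 50L)
  if (length(rec) < nfaces * 50L) stop("truncated binary STL: ", path)
  recmat <- matrix(rec, nrow = 50L)
  fbytes <- as.vector(recmat[1:48, , drop = FALSE])
  vals <- readBin(fbytes, "numeric", n = 12L * nfaces, size = 4,
                  endian = "little")
  vm <- matrix(vals, ncol = 12, byrow = TRUE)     # normal + 3 vertices
  tv <- matrix(0, nrow = 3 * nfaces, ncol = 3)
  tv[seq(1, 3 * nfaces, by = 3), ] <- vm[, 4:6, drop = FALSE]
  tv[seq(2, 3 * nfaces, by = 3), ] <- vm[, 7:9, drop = FALSE]
  tv[seq(3, 3 * nfaces, by = 3), ] <- vm[, 10:12, drop = FALSE]
  merge_vertices(tv)
}

write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", mesh$name), con)
  fmt <- paste0("facet normal %.9g %.9g %.9g\n outer loop\n",
                "  vertex %.17g %.17g %.17g\n  vertex %.17g %.17g %.17g\n",
                "  vertex %.17g %.17g %.17g\n endloop\nendfacet")
  body <- sprintf(fmt, n[, 1], n[, 2], n[, 3],
                  v[f[, 1], 1], v[f[, 1], 2], v[f[, 1], 3],
                  v[f[, 2], 1], v[f[, 2], 2], v[f[, 2], 3],
                  v[f[, 3], 1], v[f[, 3], 2], v[f[, 3], 3])
  writeLines(body, con)
  writeLines(sprintf("endsolid %s", mesh$name), con)
}

write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- face_normals(mesh)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  rec <- cbind(n, v[f[, 1], , drop = FALSE], v[f[, 2], , drop = FALSE],
               v[f[, 3], , drop = FALSE])
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(rec[i, ]), con, size = 4, endian = "little")
    writeBin(as.integer(0L), con, size = 2, endian = "little")
  }
}

face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

# ---- PLY ---------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(raw, type, n = 1L) {
  size <- ply_type_size[[type]]
  what <- if (type %in% c("float", "float32", "double", "float64"))
    "numeric" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint",
                          "uint32"))
  readBin(raw, what, n = n, size = size, signed = if (size < 4) signed else TRUE,
          endian = "little")
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is ASCII lines regardless of body format
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("malformed PLY header: ", path)
    hdr <- c(hdr, line)
    if (trimws(line) == "end_header") break
  }
  if (trimws(hdr[1]) != "ply") stop("not a PLY file: ", path)
  fmt_line <- grep("^format", trimws(hdr), value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  # parse elements / properties
  elements <- list()
  cur <- NULL
  for (line in trimws(hdr)) {
    tok <- strsplit(line, "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3],
               value_type = tok[4])
      } else {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY lacks vertex/face elements: ", path)

  if (fmt == "ascii") {
    lines <- readLines(con, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    out <- ply_parse_ascii(elements, lines)
  } else {
    raw <- readBin(con, "raw", n = file.size(path))
    out <- ply_parse_binary(elements, raw)
  }
  out
}

ply_parse_ascii <- function(elements, lines) {
  pos <- 1L
  verts <- NULL
  faces <- list()
  for (el in elements) {
    if (el$count == 0) next
    chunk <- lines[pos:(pos + el$count - 1)]
    pos <- pos + el$count
    toks <- strsplit(trimws(chunk), "\\s+")
    if (el$name == "vertex") {
      names_ <- vapply(el$props, `[[`, "", "name")
      ix <- match(c("x", "y", "z"), names_)
      if (any(is.na(ix))) stop("PLY vertex element lacks x/y/z")
      verts <- t(vapply(toks, function(tk) as.numeric(tk[ix]), numeric(3)))
    } else if (el$name == "face") {
      for (tk in toks) {
        cnt <- as.integer(tk[1])
        idx <- as.integer(tk[2:(1 + cnt)]) + 1L  # PLY is 0-based
        if (cnt >= 3)
          for (k in seq_len(cnt - 2))
            faces[[length(faces) + 1]] <- idx[c(1, k + 1, k + 2)]
      }
    }
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

ply_parse_binary <- function(elements, raw) {
  offset <- 0L
  verts <- NULL
  faces <- list()
  for (el in elements) {
    if (el$name == "vertex") {
      sizes <- vapply(el$props, function(p) ply_type_size[[p$type]], 1L)
      stride <- sum(sizes)
      offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
      block <- raw[(offset + 1):(offset + stride * el$count)]
      bm <- matrix(block, nrow = stride)
      names_ <- vapply(el$props, `[[`, "", "name")
      get_col <- function(nm) {
        j <- match(nm, names_)
        if (is.na(j)) stop("PLY vertex element lacks ", nm)
        bytes <- as.vector(bm[(offs[j] + 1):(offs[j] + sizes[j]), ,
                              drop = FALSE])
        ply_read_scalar(bytes, el$props[[j]]$type, n = el$count)
      }
      verts <- cbind(get_col("x"), get_col("y"), get_col("z"))
      offset <- offset + stride * el$count
    } else if (el$name == "face") {
      p <- el$props[[1]]
      if (!p$list) stop("PLY face element must be a list property")
      csz <- ply_type_size[[p$count_type]]
      vsz <- ply_type_size[[p$value_type]]
      for (i in seq_len(el$count)) {
        cnt <- ply_read_scalar(raw[(offset + 1):(offset + csz)], p$count_type)
        offset <- offset + csz
        idx <- ply_read_scalar(raw[(offset + 1):(offset + cnt * vsz)],
                               p$value_type, n = cnt) + 1L
        offset <- offset + cnt * vsz
        if (cnt >= 3)
          for (k in seq_len(cnt - 2))
            faces[[length(faces) + 1]] <- idx[c(1, k + 1, k + 2)]
      }
    } else {
      stop("unsupported PLY element in binary file: ", el$name)
    }
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

write_ply_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment %s", mesh$name),
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  v <- mesh$vertices
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh$faces - 1L
  writeLines(sprintf("3 %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}

write_ply_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           sprintf("comment %s", mesh$name),
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices",
           "end_header")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
  f <- mesh$faces - 1L
  for (i in seq_len(nrow(f))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(f[i, ]), con, size = 4, endian = "little")
  }
}

# ---- OBJ ---------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vlines <- lines[startsWith(lines, "v ")]
  flines <- lines[startsWith(lines, "f ")]
  if (length(vlines) == 0 || length(flines) == 0)
    stop("OBJ file has no v/f records: ", path)
  verts <- t(vapply(strsplit(vlines, "\\s+"), function(tk)
    as.numeric(tk[2:4]), numeric(3)))
  faces <- list()
  for (ln in flines) {
    tok <- strsplit(ln, "\\s+")[[1]][-1]
    idx <- as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1))
    if (any(is.na(idx)) || any(idx <= 0L))
      stop("OBJ face index error (indices are 1-based, got ",
           paste(idx, collapse = " "), ")")
    if (any(idx > nrow(verts)))
      stop("OBJ face index out of range")
    if (length(idx) >= 3)
      for (k in seq_len(length(idx) - 2))
        faces[[length(faces) + 1]] <- idx[c(1, k + 1, k + 2)]
  }
  list(vertices = verts, faces = do.call(rbind, faces))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", mesh$name), con)
  v <- mesh$vertices
  writeLines(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]), con)
  f <- mesh$faces
  writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
}
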