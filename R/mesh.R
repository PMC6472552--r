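#' Triangle surface mesh
#'
#' The basic geometry carrier of the package: a set of 3-D vertices (in
#' millimetres) and triangular faces given as 1-based vertex index triples.
#' Faces must reference valid vertices and have three distinct indices;
#' degenerate faces are dropped with a warning.
#'
#' @param vertices Numeric matrix with 3 columns (x, y, z in mm).
#' @param faces Integer matrix with 3 columns of 1-based vertex indices.
#' @param name Free-text label carried through the pipeline.
#' @return An object of class `triangle_mesh`: a list with elements
#'   `vertices`, `faces`, `name`.
#' @export
triangle_mesh <- function(vertices, faces, name = "") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("vertices must have 3 columns")
  if (nrow(vertices) > 0 && !all(is.finite(vertices)))
    stop("vertex coordinates must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0) {
    if (ncol(faces) != 3L)
      stop("faces must have 3 columns")
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range [1, ", nrow(vertices), "]")
    degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
      faces[, 1] == faces[, 3]
    if (any(degen)) {
      warning(sum(degen), " degenerate face(s) dropped")
      faces <- faces[!degen, , drop = FALSE]
    }
  }
  structure(list(vertices = vertices, faces = faces, name = as.character(name)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh '%s': %d vertices, %d faces%s\n",
              x$name, nrow(x$vertices), nrow(x$faces),
              if (mesh_is_closed(x)) " (closed)" else ""))
  invisible(x)
}

# undirected edge list (each row i < j), one row per unique edge
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# number of boundary (non-manifold or open) edges: undirected edges not
# shared by exactly two faces
mesh_boundary_edge_count <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(0L)
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  sum(tab != 2L)
}

#' Test whether a mesh is closed and consistently wound
#'
#' A closed mesh has every edge shared by exactly two faces with opposite
#' orientation (consistent winding), so that an enclosed volume is defined.
#'
#' @param mesh A [triangle_mesh()].
#' @return Logical scalar.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  dir_key <- paste(e[, 1], e[, 2])
  if (anyDuplicated(dir_key)) return(FALSE) # inconsistent winding
  und_key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(und_key) == 2L)
}

# per-face areas and the total surface area
mesh_face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Surface area of a mesh
#'
#' @param mesh A [triangle_mesh()].
#' @return Total triangle area in mm^2.
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))
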