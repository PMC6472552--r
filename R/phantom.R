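# icosahedron subdivision sphere; deterministic, consistently outward wound
unit_icosphere <- function(subdivisions = 3) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    ue <- !duplicated(key)
    mid_id <- match(key, key[ue]) + nv
    mids <- (v[e[ue, 1], , drop = FALSE] + v[e[ue, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  list(vertices = v, faces = f)
}

#' Closed ellipsoid surface mesh
#'
#' Icosphere-based triangulation of an axis-aligned ellipsoid; the basic
#' fixture generator (a sphere is the `semi_axes = c(r, r, r)` case).
#'
#' @param semi_axes Semi-axis lengths (x, y, z) in mm.
#' @param center Centre (mm).
#' @param subdivisions Icosphere subdivision level (level n has
#'   `20 * 4^n` faces).
#' @param name Mesh label.
#' @param flip Reverse the winding (inward normals), used for the inner
#'   sheet of shell meshes.
#' @return A closed [triangle_mesh()].
#' @export
ellipsoid_mesh <- function(semi_axes, center = c(0, 0, 0), subdivisions = 3,
                           name = "ellipsoid", flip = FALSE) {
  s <- unit_icosphere(subdivisions)
  v <- sweep(sweep(s$vertices, 2, semi_axes, `*`), 2, center, `+`)
  f <- if (flip) s$faces[, c(1, 3, 2)] else s$faces
  triangle_mesh(v, f, name = name)
}

# closed shell: outward outer surface + inward-flipped inner surface.
# Encloses the region between the two ellipsoids (volume V_out - V_in).
shell_mesh <- function(outer_semi, inner_semi, center = c(0, 0, 0),
                       subdivisions = 3, name = "shell") {
  outer <- ellipsoid_mesh(outer_semi, center, subdivisions, name)
  inner <- ellipsoid_mesh(inner_semi, center, subdivisions, name,
                          flip = TRUE)
  n_out <- nrow(outer$vertices)
  mesh <- triangle_mesh(rbind(outer$vertices, inner$vertices),
                        rbind(outer$faces, inner$faces + n_out),
                        name = name)
  attr(mesh, "n_outer_vertices") <- n_out
  mesh
}

#' Synthetic abdomen phantom specification
#'
#' Describes a deterministic nested-ellipsoid stand-in for a segmented
#' supine abdomen: an abdominal-wall shell, a solid viscera surface, and a
#' thin deflated peritoneal cavity hugging the viscera (cavity thickness
#' `gap`, offset `gap / 2` from the viscera surface). The +y axis is
#' anterior. All dimensions in mm. The defaults are human-abdomen scale;
#' tests use smaller spec instances.
#'
#' @param wall_outer Outer semi-axes of the wall (x lateral, y anterior,
#'   z cranio-caudal).
#' @param wall_thickness Wall shell thickness.
#' @param viscera Viscera semi-axes.
#' @param gap Deflated cavity thickness.
#' @param resolution Icosphere subdivision level per surface (default 4).
#' @param seed Reserved for derived randomised fixtures; the phantom
#'   itself is fully deterministic.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(wall_outer = c(160, 120, 260), wall_thickness = 15,
                         viscera = c(120, 85, 210), gap = 3,
                         resolution = 4, seed = 0) {
  spec <- list(wall_outer = as.numeric(wall_outer),
               wall_thickness = as.numeric(wall_thickness),
               viscera = as.numeric(viscera), gap = as.numeric(gap),
               resolution = as.integer(resolution), seed = as.integer(seed))
  wall_inner <- spec$wall_outer - spec$wall_thickness
  pneumo_outer <- spec$viscera + 1.5 * spec$gap
  if (any(spec$viscera <= 0) || any(wall_inner <= 0) || spec$gap <= 0)
    stop("phantom dimensions must be positive")
  if (any(pneumo_outer >= wall_inner))
    stop("intersecting shells: cavity outer surface must lie strictly ",
         "inside the wall")
  structure(spec, class = "phantom_spec")
}

#' Generate the phantom meshes
#'
#' @param spec A [phantom_spec()].
#' @return A list of closed [triangle_mesh()]es `wall`, `viscera`,
#'   `pneumo`, plus the `spec`. The wall and pneumo are two-sheet shells
#'   (outward outer surface, inward inner surface).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  wall <- shell_mesh(spec$wall_outer, spec$wall_outer - spec$wall_thickness,
                     subdivisions = spec$resolution, name = "wall")
  viscera <- ellipsoid_mesh(spec$viscera, subdivisions = spec$resolution,
                            name = "viscera")
  pneumo <- shell_mesh(spec$viscera + 1.5 * spec$gap,
                       spec$viscera + 0.5 * spec$gap,
                       subdivisions = spec$resolution, name = "pneumo")
  list(wall = wall, viscera = viscera, pneumo = pneumo, spec = spec)
}

#' Analytic insufflation displacement field
#'
#' Maps an experimental pressure (mmHg) to an anterior displacement
#' amplitude `A(p) = max_amplitude * p / max_pressure` with a quadratic
#' anterior falloff: a vertex at anterior height y on a sheet of y
#' semi-axis b moves by `A(p) * (max(0, y) / b)^2` along +y, so the
#' posterior half-space stays put (the fixed supine back) and the
#' mid-anterior apex moves the full amplitude. This emulates reported
#' insufflation displacements of up to about 4 cm without claiming
#' anatomical truth.
#'
#' @param max_amplitude Peak anterior displacement at `max_pressure` (mm).
#' @param max_pressure Pressure at which the peak is reached (mmHg).
#' @param compression Fraction of the amplitude by which the cavity's inner
#'   (viscera-hugging) sheet moves posteriorly, emulating viscera
#'   compression under insufflation (default 0.5: insufflation both lifts
#'   the wall and squeezes the viscera).
#' @return An `inflation_field` list with an `amplitude(p)` function.
#' @export
inflation_field <- function(max_amplitude = 40, max_pressure = 16,
                            compression = 0.5) {
  stopifnot(max_amplitude > 0, max_pressure > 0, compression >= 0,
            compression < 1)
  structure(list(max_amplitude = max_amplitude, max_pressure = max_pressure,
                 compression = compression,
                 amplitude = function(p) max_amplitude * p / max_pressure),
            class = "inflation_field")
}

# displace the anterior (+y) vertices of selected rows by A * (y/b)^2
displace_anterior <- function(verts, rows, amplitude, b) {
  y <- verts[rows, 2]
  t <- pmax(0, y / b)
  verts[rows, 2] <- y + amplitude * t^2
  verts
}

#' Analytically inflated reference meshes
#'
#' Stands in for the insufflated ground-truth CT meshes: the outer cavity
#' sheet and both wall sheets are displaced anteriorly by the inflation
#' field at the given pressure, while the viscera-hugging inner cavity
#' sheet recedes posteriorly by the field's compression fraction (the
#' viscera are squeezed by the gas). The posterior half-space stays put.
#' The cavity volume strictly increases with pressure.
#'
#' @param phantom A [make_phantom()] result.
#' @param pressure Experimental pressure in mmHg.
#' @param field An [inflation_field()].
#' @return A list with the displaced `pneumo` and `wall` meshes, the
#'   `pressure` and the displacement `amplitude` (mm).
#' @export
make_inflated_reference <- function(phantom, pressure,
                                    field = inflation_field()) {
  stopifnot(pressure >= 0)
  A <- field$amplitude(pressure)
  spec <- phantom$spec
  b_po <- spec$viscera[2] + 1.5 * spec$gap
  b_wi <- spec$wall_outer[2] - spec$wall_thickness
  b_wo <- spec$wall_outer[2]
  # the cavity's outer sheet must stay inside the (equally displaced) wall
  # inner sheet at the anterior apex
  if (A > 0 && b_po + A > b_wi + A * (b_po / b_wi)^2 &&
      b_po + A - (b_wi + A * (b_po / b_wi)^2) > (b_wi - b_po))
    stop("inflation amplitude ", signif(A, 4),
         " mm causes cavity/wall self-intersection")
  pneumo <- phantom$pneumo
  n_out <- attr(pneumo, "n_outer_vertices")
  pneumo$vertices <- displace_anterior(pneumo$vertices, seq_len(n_out), A,
                                       b_po)
  b_pi <- spec$viscera[2] + 0.5 * spec$gap
  pneumo$vertices <- displace_anterior(
    pneumo$vertices, (n_out + 1):nrow(pneumo$vertices),
    -field$compression * A, b_pi)
  wall <- phantom$wall
  nw_out <- attr(wall, "n_outer_vertices")
  wall$vertices <- displace_anterior(wall$vertices, seq_len(nw_out), A, b_wo)
  wall$vertices <- displace_anterior(
    wall$vertices, (nw_out + 1):nrow(wall$vertices), A, b_wi)
  pneumo$name <- sprintf("pneumo_ref_%gmmHg", pressure)
  wall$name <- sprintf("wall_ref_%gmmHg", pressure)
  list(pneumo = pneumo, wall = wall, pressure = pressure, amplitude = A)
}

#' Canonical landmark vertices on the phantom wall
#'
#' Places the five protocol landmarks at fixed parametric positions on the
#' wall's outer sheet: xiphisternum cranial-anterior midline, pubic
#' symphysis caudal-anterior midline, umbilicus at the anterior apex, and
#' the two ASIS lateral-caudal, mirror-symmetric about the midsagittal
#' plane (+x is the subject's right).
#'
#' @param phantom A [make_phantom()] result.
#' @return A [landmark_set()] of vertex indices into the wall mesh.
#' @export
make_landmarked_wall <- function(phantom) {
  wall <- phantom$wall
  n_out <- attr(wall, "n_outer_vertices")
  semi <- phantom$spec$wall_outer
  snap <- function(u) {
    u <- u / sqrt(sum(u^2))
    q <- u / sqrt(sum((u / semi)^2))   # point on the ellipsoid along u
    d2 <- rowSums(sweep(wall$vertices[seq_len(n_out), , drop = FALSE],
                        2, q)^2)
    which.min(d2)
  }
  landmark_set(xs = snap(c(0, 0.6, 0.8)),
               ps = snap(c(0, 0.6, -0.8)),
               umbilicus = snap(c(0, 1, 0)),
               asis_r = snap(c(0.7, 0.35, -0.62)),
               asis_l = snap(c(-0.7, 0.35, -0.62)))
}
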