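#' Save / load a simulation scene as a JSON descriptor
#'
#' The full scene (particle arrays, constraints, clusters, skin bindings,
#' provenance) is written as a single JSON document with full-precision
#' numbers; no bespoke binary format is used.
#'
#' @param scene A [build_scene()] result.
#' @param path Output path (`.json`).
#' @return `save_scene` invisibly returns `path`; `load_scene` returns the
#'   scene.
#' @export
save_scene <- function(scene, path) {
  enc_mesh <- function(m) list(vertices = m$vertices, faces = m$faces,
                               name = m$name)
  skins <- lapply(scene$skins, function(s) list(
    index = s$binding$index, weights = s$binding$weights,
    offsets = as.vector(s$binding$offsets),
    offsets_dim = dim(s$binding$offsets),
    faces = s$binding$faces, name = s$binding$name,
    particle_index = s$particle_index, mesh = enc_mesh(s$mesh)))
  doc <- list(
    particles = list(positions = scene$particles$positions,
                     previous_positions = scene$particles$previous_positions,
                     inverse_mass = scene$particles$inverse_mass,
                     radius = scene$particles$radius,
                     body = scene$particles$body,
                     rest_positions = scene$particles$rest_positions),
    distance = scene$constraints$distance[c("i", "j", "rest_length",
                                            "stiffness")],
    volume = scene$constraints$volume[c("faces", "rest_volume",
                                        "pressure_factor", "stiffness")],
    clusters = lapply(scene$constraints$clusters, function(cl) list(
      members = cl$members, rest_offsets = cl$rest_offsets,
      rest_centroid = cl$rest_centroid, stiffness = cl$stiffness)),
    skins = skins,
    provenance = scene$provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_scene
#' @export
load_scene <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- doc$particles
  state <- particle_system(p$positions, p$inverse_mass, p$radius, p$body,
                           p$previous_positions)
  state$rest_positions <- as.matrix(p$rest_positions)
  dist <- distance_constraints(doc$distance$i, doc$distance$j,
                               doc$distance$rest_length,
                               doc$distance$stiffness)
  vol <- volume_constraint(doc$volume$faces, doc$volume$rest_volume,
                           doc$volume$pressure_factor, doc$volume$stiffness)
  # jsonlite may simplify the cluster list to a data frame of list columns
  unwrap <- function(x) if (is.list(x) && length(x) == 1) x[[1]] else x
  cl_list <- if (is.data.frame(doc$clusters))
    split(doc$clusters, seq_len(nrow(doc$clusters))) else doc$clusters
  clusters <- lapply(cl_list, function(cl) {
    members <- as.integer(unlist(cl$members))
    offs <- as.matrix(unwrap(cl$rest_offsets))
    centroid <- as.numeric(unlist(cl$rest_centroid))
    shape_cluster(members, sweep(offs, 2, -centroid),
                  as.numeric(unwrap(cl$stiffness)))
  })
  skins <- lapply(doc$skins, function(s) {
    binding <- structure(list(
      index = as.matrix(s$index), weights = as.matrix(s$weights),
      offsets = array(as.numeric(s$offsets), dim = s$offsets_dim),
      faces = as.matrix(s$faces), name = s$name), class = "skin_binding")
    list(binding = binding, particle_index = as.integer(s$particle_index),
         mesh = triangle_mesh(s$mesh$vertices, s$mesh$faces, s$mesh$name))
  })
  structure(list(particles = state,
                 constraints = list(distance = dist, volume = vol,
                                    clusters = clusters, collide = TRUE),
                 skins = skins, provenance = doc$provenance),
            class = "pneumo_scene")
}
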