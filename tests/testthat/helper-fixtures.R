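# shared small fixtures, built in code

# regular n-gon approximating a circle
circle_poly <- function(center = c(0, 0), radius = 1, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = center[1] + radius * cos(th), y = center[2] + radius * sin(th))
}

disc_ann <- function(center, radius, id = "disc", n = 64) {
  spatial_annotation(id, circle_poly(center, radius, n))
}

unit_square_ann <- function(id = "sq", side = 1, at = c(0, 0)) {
  spatial_annotation(id, cbind(at[1] + c(0, side, side, 0),
                               at[2] + c(0, 0, side, side)))
}

# small screening scene reused across tests: 4x4 mm lattice, central disc
small_scene <- function(disc_radius = 300, distance = "1500um", resolution = "100um") {
  coords <- make_lattice("4mm", "4mm")
  ds <- lattice_dataset(coords)
  ann <- disc_ann(c(2000, 2000), disc_radius)
  cfg <- gradient_config(distance, resolution)
  field <- annotation_distance(ann, ds, max_distance = cfg$distance)
  list(coords = coords, ds = ds, ann = ann, cfg = cfg, field = field)
}
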