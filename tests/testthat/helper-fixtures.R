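# Shared fixtures, built once per test run. Geometry/mesh construction is
# deterministic, so caching is purely a speed concern.

fixture_env <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

fx_slab <- function() fx("slab", function() build_slab_geometry())

fx_slab_elec <- function() fx("slab_elec", function() {
  g <- build_slab_geometry()
  place_electrodes(g, default_electrodes(g))
})

# coarse mesh for structural mesh tests (fast)
fx_mesh_coarse <- function() fx("mesh_coarse", function() {
  generate_mesh(fx_slab_elec(), resolution = 2)
})

# small homogeneous ball mesh for the point-source oracle
fx_ball <- function(R = 20, h = 1.4) fx("ball", function() {
  xs <- seq(-R - h, R + h, by = h)
  m <- mesh_box(xs, xs, xs)
  cen <- cortistim:::elem_centroids(m)
  keep <- sqrt(rowSums(cen^2)) <= R
  mesh_subset(m, keep)
})

# synthetic threshold-record table for reporting tests
fx_records <- function() {
  base <- expand.grid(id = 1:6, layer = c("L5", "L3"),
                      polarity = c("anodal", "cathodal"),
                      stringsAsFactors = FALSE)
  base$neuron <- paste0(base$layer, "_", base$id)
  base$region <- c("C", "L", "B", "BS", "OB", "OC")[base$id]
  base$side <- 1
  base$plane <- 1L
  base$s <- base$sw <- base$id
  base$x <- base$id; base$y <- 0; base$z <- 25
  base$threshold <- NA_real_
  base$excitable <- FALSE
  base$init_category <- NA_character_
  base
}
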