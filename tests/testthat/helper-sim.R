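# Shared fixture builders: a small synthetic section with everything the
# diagnostics need (grid, beads, graph, rendered image).
make_section <- function(seed = 1L, n_rows = 20L, n_cols = 20L,
                         n_bead_types = 30L, non_decode_rate = 0.03,
                         artifacts = list(), noise = TRUE, ...) {
  cfg <- simulation_config(seed = seed, n_rows = n_rows, n_cols = n_cols,
                           n_bead_types = n_bead_types,
                           non_decode_rate = non_decode_rate,
                           artifacts = artifacts, ...)
  layout <- chip_layout("synthetic", 1, 1, 1, n_cols, n_rows,
                        bead_pitch = cfg$bead_pitch,
                        bead_radius = cfg$bead_radius)
  grid <- nominal_positions(layout, origin = c(cfg$margin, cfg$margin))
  beads <- assign_bead_types(grid, cfg)
  graph <- build_neighbour_graph(grid)
  image <- render_section_image(beads, cfg, noise = noise)
  inj <- inject_artifacts(image, beads, artifacts, graph = graph,
                          config = cfg)
  list(cfg = cfg, layout = layout, grid = grid, beads = inj$beads,
       graph = graph, image = inj$image, truth = inj$truth)
}

# brute-force hex adjacency from centre distances (independent oracle)
brute_adjacency <- function(grid, pitch, tol = 1e-9) {
  n <- nrow(grid)
  d <- as.matrix(stats::dist(cbind(grid$x, grid$y)))
  lapply(seq_len(n), function(i)
    as.integer(which(abs(d[i, ] - pitch) < tol)))
}

# intensities / recorded-id matrices in grid order for remap tests
grid_matrix <- function(beads, col, n_rows, n_cols) {
  matrix(beads[[col]], n_rows, n_cols, byrow = TRUE)
}
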