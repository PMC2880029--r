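#' Synthetic section simulation configuration
#'
#' Defines the ground-truthed study conditions for a simulated BeadArray
#' section: grid size, bead-type assignment, log-scale intensity model,
#' background, rendering geometry and injected artefacts.
#'
#' The intensity model is hierarchical on the log2 scale: each bead-type
#' draws a mean from `N(log2_mean, log2_between_sd)` and each replicate
#' bead deviates from its type mean by `N(0, log2_within_sd)`.  Rendered
#' spot peak density equals `peak_scale` times the bead's linear
#' intensity.  Non-decoded beads still fluoresce at a low fixed level
#' (decoding failure is independent of hybridization brightness).
#'
#' @param seed RNG seed making the whole dataset reproducible.
#' @param n_rows,n_cols Bead grid dimensions of the simulated segment.
#' @param n_bead_types Number of distinct bead-types.
#' @param non_decode_rate Probability a bead fails decoding.
#' @param log2_mean,log2_between_sd Location/spread of type means (log2).
#' @param log2_within_sd Replicate spread within a type (log2).
#' @param background_level,background_sd Gaussian background floor in
#'   pixel units, clipped at 0.
#' @param bead_pitch,bead_radius Lattice spacing and rendered spot radius
#'   in pixels.
#' @param peak_scale Spot peak density per unit linear intensity.
#' @param nondecoded_level Linear intensity of non-decoded beads.
#' @param margin Pixels between the grid bounding box and the image edge;
#'   must exceed 8 so every bead's 17x17 window fits.
#' @param artifacts List of [artifact_spec()]s to inject.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_rows = 60L, n_cols = 60L,
                              n_bead_types = 150L, non_decode_rate = 0.03,
                              log2_mean = 10, log2_between_sd = 1.5,
                              log2_within_sd = 0.25,
                              background_level = 400, background_sd = 10,
                              bead_pitch = 6, bead_radius = 2.5,
                              peak_scale = 1, nondecoded_level = 150,
                              margin = 12, artifacts = list()) {
  stopifnot(n_bead_types >= 1, non_decode_rate >= 0, non_decode_rate <= 1,
            log2_between_sd >= 0, log2_within_sd >= 0, background_sd >= 0,
            margin > 8)
  structure(list(seed = as.integer(seed), n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols),
                 n_bead_types = as.integer(n_bead_types),
                 non_decode_rate = non_decode_rate, log2_mean = log2_mean,
                 log2_between_sd = log2_between_sd,
                 log2_within_sd = log2_within_sd,
                 background_level = background_level,
                 background_sd = background_sd, bead_pitch = bead_pitch,
                 bead_radius = bead_radius, peak_scale = peak_scale,
                 nondecoded_level = nondecoded_level, margin = margin,
                 artifacts = artifacts),
            class = "simulation_config")
}

sim_layout <- function(config) {
  chip_layout("synthetic", 1, 1, 1, config$n_cols, config$n_rows,
              bead_pitch = config$bead_pitch,
              bead_radius = config$bead_radius)
}

#' Assign bead-types and true intensities to a grid
#'
#' Each bead's type is drawn independently and uniformly from
#' `n_bead_types`; a fraction `non_decode_rate` is set to the non-decoded
#' sentinel `-1`.  True log2 intensities follow the hierarchical model of
#' [simulation_config()].  Reproducible under `config$seed`.
#'
#' @param grid A `bead_grid` from [nominal_positions()].
#' @param config A [simulation_config()].
#' @return Data frame of beads: `bead`, `g_row`, `g_col`, `x`, `y`,
#'   `bead_type_id` (1-based; -1 = non-decoded), `true_log2`,
#'   `true_intensity`; type means attached as attribute
#'   `"type_log2_means"`.
#' @export
assign_bead_types <- function(grid, config) {
  set.seed(config$seed)
  n <- nrow(grid)
  type_means <- stats::rnorm(config$n_bead_types, config$log2_mean,
                             config$log2_between_sd)
  ids <- sample.int(config$n_bead_types, n, replace = TRUE)
  lg <- type_means[ids] + stats::rnorm(n, 0, config$log2_within_sd)
  nd <- stats::runif(n) < config$non_decode_rate
  ids[nd] <- -1L
  lg[nd] <- log2(config$nondecoded_level)
  beads <- data.frame(bead = seq_len(n), g_row = grid$g_row,
                      g_col = grid$g_col, x = grid$x, y = grid$y,
                      bead_type_id = ids, true_log2 = lg,
                      true_intensity = 2^lg)
  attr(beads, "type_log2_means") <- type_means
  beads
}

# Integrate a projected-sphere spot (peak density `peak`, radius r, centre
# (x, y) in 0-based pixel coordinates) into `image` by midpoint quadrature.
add_spot <- function(image, x, y, r, peak, n_quad = 8L) {
  x0 <- floor(x - r) - 1L; x1 <- ceiling(x + r) + 1L
  y0 <- floor(y - r) - 1L; y1 <- ceiling(y + r) + 1L
  if (x0 < 0 || y0 < 0 || x1 > ncol(image) - 1 || y1 > nrow(image) - 1)
    stop(sprintf("bead centre (%.1f, %.1f) too close to the image edge", x, y))
  sx <- x0 + (seq_len((x1 - x0 + 1L) * n_quad) - 0.5) / n_quad
  sy <- y0 + (seq_len((y1 - y0 + 1L) * n_quad) - 0.5) / n_quad
  d2 <- outer((sy - y)^2, (sx - x)^2, "+")
  dens <- peak * sqrt(pmax(1 - d2 / r^2, 0))
  gy <- rep(seq_len(y1 - y0 + 1L), each = n_quad)
  gx <- rep(seq_len(x1 - x0 + 1L), each = n_quad)
  patch <- t(rowsum(t(rowsum(dens, gy)), gx)) / n_quad^2
  rows <- (y0:y1) + 1L; cols <- (x0:x1) + 1L
  image[rows, cols] <- image[rows, cols] + patch
  image
}

#' Render a section image from bead truth
#'
#' Each bead is rendered as a radially symmetric projected-sphere spot
#' (peak density `peak_scale * true_intensity`, radius `bead_radius`)
#' added to a Gaussian background floor; pixel values are rounded and
#' clipped to `[0, 65535]`.  Rendering is linear: two beads add.
#'
#' @param beads Bead data frame from [assign_bead_types()] (needs `x`,
#'   `y`, `true_intensity`).
#' @param config A [simulation_config()].
#' @param dims Optional `(width, height)`; default fits the grid plus
#'   `config$margin`.
#' @param noise Set `FALSE` for a deterministic noise-free floor at
#'   `background_level`.
#' @return Integer-valued image matrix (rows = y).
#' @export
render_section_image <- function(beads, config, dims = NULL, noise = TRUE) {
  if (is.null(dims)) {
    dims <- c(ceiling(if (nrow(beads)) max(beads$x) else 0) + config$margin + 1,
              ceiling(if (nrow(beads)) max(beads$y) else 0) + config$margin + 1)
  }
  img <- matrix(config$background_level, nrow = dims[2], ncol = dims[1])
  if (noise) {
    img <- img + matrix(stats::rnorm(length(img), 0, config$background_sd),
                        nrow = dims[2])
    img <- pmax(img, 0)
  }
  for (i in seq_len(nrow(beads))) {
    img <- add_spot(img, beads$x[i], beads$y[i], config$bead_radius,
                    config$peak_scale * beads$true_intensity[i])
  }
  matrix(pmin(pmax(round(img), 0), 65535), nrow = dims[2])
}

#' Specify an artefact to inject
#'
#' Supported kinds and their parameters (all have sensible defaults):
#' \describe{
#'   \item{`nondecoded_cluster`}{`centre` (bead index; default the middle
#'     bead), `size` (>= beads in the cluster, default 80), `halo_rings`
#'     (graph hops, default 2), `halo_factor` (intensity multiplier for
#'     halo beads, default 4).}
#'   \item{`bright_bead`}{`bead`, `peak` (default 60000), `radius_factor`
#'     (spot enlargement, default 1.5).}
#'   \item{`low_pixel`}{`pixels` (data frame `x`, `y`) or `near_bead`
#'     plus `offset` (default `c(4, 0)` from the anchor); `value`
#'     (default 5).}
#'   \item{`segment_shift`}{`shift = c(d_col, d_row)`: the recorded
#'     bead-type annotation at grid `(r, c)` becomes the true type of
#'     `(r - d_row, c - d_col)`; positions falling off the grid become
#'     non-decoded.}
#'   \item{`bead_jitter`}{`beads` (indices) or `n` (default 7) randomly
#'     chosen; `magnitude` (px, default 3): recorded centres displaced.}
#'   \item{`channel_shift_gradient`}{`intercept` (default `c(10, 0)`),
#'     `slope` (default `c(0.001, 0)`: d(dx)/d(g_col), d(dy)/d(g_row)),
#'     optional `outlier_beads` given an extra `outlier_shift`
#'     (default `c(4, 4)`); creates red-channel coordinates.}
#'   \item{`id_scramble`}{`beads`: recorded types of those beads randomly
#'     permuted among themselves.}
#' }
#'
#' @param kind Artefact kind (see above).
#' @param ... Kind-specific parameters.
#' @return An `artifact_spec` list.
#' @export
artifact_spec <- function(kind = c("nondecoded_cluster", "bright_bead",
                                   "low_pixel", "segment_shift",
                                   "bead_jitter", "channel_shift_gradient",
                                   "id_scramble"), ...) {
  kind <- match.arg(kind)
  structure(c(list(kind = kind), list(...)), class = "artifact_spec")
}

spec_par <- function(spec, name, default) {
  if (!is.null(spec[[name]])) spec[[name]] else default
}

#' Inject artefacts into a rendered section
#'
#' Applies each [artifact_spec()] in order to the image and/or bead table
#' and records complete ground truth (every affected bead and pixel) per
#' artefact.  Contradictory specs (a bead both inside a non-decoded
#' cluster and targeted as a bright bead) raise an error.
#'
#' @param image Rendered section image ([render_section_image()]).
#' @param beads Bead data frame ([assign_bead_types()]).
#' @param specs List of [artifact_spec()]s.
#' @param graph Optional [build_neighbour_graph()] result; rebuilt from
#'   the bead grid coordinates when missing.
#' @param config The [simulation_config()] (rendering parameters for
#'   halo / bright spots).
#' @return List `image`, `beads`, `truth` (one truth record per spec).
#' @export
inject_artifacts <- function(image, beads, specs, graph = NULL,
                             config = simulation_config()) {
  if (!length(specs))
    return(list(image = image, beads = beads, truth = list()))
  if (is.null(graph)) graph <- build_neighbour_graph(beads)
  truth <- vector("list", length(specs))
  cluster_members <- integer()
  for (k in seq_along(specs)) {
    spec <- specs[[k]]
    res <- switch(spec$kind,
      nondecoded_cluster = inject_cluster(image, beads, spec, graph, config),
      bright_bead = {
        b <- spec_par(spec, "bead", NULL)
        if (!is.null(b) && b %in% cluster_members)
          stop("conflicting specs: bead ", b,
               " is both a cluster member and a bright bead")
        inject_bright(image, beads, spec, graph, config)
      },
      low_pixel = inject_low_pixel(image, beads, spec),
      segment_shift = inject_segment_shift(image, beads, spec),
      bead_jitter = inject_jitter(image, beads, spec),
      channel_shift_gradient = inject_channel_shift(image, beads, spec),
      id_scramble = inject_id_scramble(image, beads, spec))
    image <- res$image; beads <- res$beads
    truth[[k]] <- res$truth
    if (spec$kind == "nondecoded_cluster")
      cluster_members <- c(cluster_members, res$truth$members)
  }
  list(image = image, beads = beads, truth = truth)
}

# grow a connected disc of >= size beads by breadth-first rings
grow_disc <- function(graph, centre, size) {
  members <- centre
  frontier <- centre
  while (length(members) < size && length(frontier)) {
    nxt <- setdiff(sort(unique(unlist(graph$adj[frontier]))), members)
    if (!length(nxt)) break
    need <- size - length(members)
    frontier <- if (length(nxt) > need) nxt[seq_len(need)] else nxt
    members <- c(members, frontier)
  }
  if (length(members) < size)
    stop("grid too small to grow a cluster of size ", size)
  sort(members)
}

graph_rings <- function(graph, members, rings) {
  reached <- members
  frontier <- members
  ring <- 0L
  while (ring < rings && length(frontier)) {
    frontier <- setdiff(sort(unique(unlist(graph$adj[frontier]))), reached)
    reached <- c(reached, frontier)
    ring <- ring + 1L
  }
  setdiff(sort(reached), members)
}

inject_cluster <- function(image, beads, spec, graph, config) {
  centre <- spec_par(spec, "centre",
                     beads$bead[which.min((beads$g_row - max(beads$g_row) / 2)^2 +
                                          (beads$g_col - max(beads$g_col) / 2)^2)])
  size <- spec_par(spec, "size", 80L)
  rings <- spec_par(spec, "halo_rings", 2L)
  factor <- spec_par(spec, "halo_factor", 4)
  members <- grow_disc(graph, centre, size)
  halo <- graph_rings(graph, members, rings)
  halo <- halo[beads$bead_type_id[halo] >= 0]
  beads$bead_type_id[members] <- -1L
  # halo beads fluoresce above expectation: add the incremental flux
  for (i in halo) {
    extra <- (factor - 1) * beads$true_intensity[i]
    image <- add_spot(image, beads$x[i], beads$y[i], config$bead_radius,
                      config$peak_scale * extra)
    beads$true_intensity[i] <- factor * beads$true_intensity[i]
    beads$true_log2[i] <- log2(beads$true_intensity[i])
  }
  image <- matrix(pmin(pmax(round(image), 0), 65535), nrow = nrow(image))
  list(image = image, beads = beads,
       truth = list(kind = "nondecoded_cluster", members = members,
                    halo = halo, centre = centre))
}

inject_bright <- function(image, beads, spec, graph, config) {
  b <- spec_par(spec, "bead", beads$bead[1])
  peak <- spec_par(spec, "peak", 60000)
  rf <- spec_par(spec, "radius_factor", 1.5)
  image <- add_spot(image, beads$x[b], beads$y[b],
                    config$bead_radius * rf, peak)
  image <- matrix(pmin(pmax(round(image), 0), 65535), nrow = nrow(image))
  beads$true_intensity[b] <- beads$true_intensity[b] + peak
  beads$true_log2[b] <- log2(beads$true_intensity[b])
  list(image = image, beads = beads,
       truth = list(kind = "bright_bead", bead = b,
                    neighbours = graph$adj[[b]]))
}

inject_low_pixel <- function(image, beads, spec) {
  value <- spec_par(spec, "value", 5)
  px <- spec$pixels
  if (is.null(px)) {
    b <- spec_par(spec, "near_bead", beads$bead[1])
    off <- spec_par(spec, "offset", c(4, 0))
    px <- data.frame(x = floor(beads$x[b]) + off[1],
                     y = floor(beads$y[b]) + off[2])
  }
  image[cbind(px$y + 1L, px$x + 1L)] <- value
  list(image = image, beads = beads,
       truth = list(kind = "low_pixel", pixels = px, value = value))
}

inject_segment_shift <- function(image, beads, spec) {
  shift <- spec_par(spec, "shift", c(0L, 6L))  # (d_col, d_row)
  R <- max(beads$g_row) + 1L; C <- max(beads$g_col) + 1L
  ids <- matrix(NA_integer_, R, C)
  ids[cbind(beads$g_row + 1L, beads$g_col + 1L)] <- beads$bead_type_id
  src_r <- beads$g_row - shift[2]; src_c <- beads$g_col - shift[1]
  ok <- src_r >= 0 & src_r < R & src_c >= 0 & src_c < C
  rec <- rep(-1L, nrow(beads))
  rec[ok] <- ids[cbind(src_r[ok] + 1L, src_c[ok] + 1L)]
  truth_ids <- beads$bead_type_id
  beads$bead_type_id <- rec
  list(image = image, beads = beads,
       truth = list(kind = "segment_shift", shift = shift,
                    true_ids = truth_ids))
}

inject_jitter <- function(image, beads, spec) {
  idx <- spec$beads
  if (is.null(idx)) idx <- sample(beads$bead, spec_par(spec, "n", 7L))
  mag <- spec_par(spec, "magnitude", 3)
  theta <- stats::runif(length(idx), 0, 2 * pi)
  dx <- mag * cos(theta); dy <- mag * sin(theta)
  beads$x[idx] <- beads$x[idx] + dx
  beads$y[idx] <- beads$y[idx] + dy
  list(image = image, beads = beads,
       truth = list(kind = "bead_jitter", beads = sort(idx),
                    dx = dx, dy = dy, magnitude = mag))
}

inject_channel_shift <- function(image, beads, spec) {
  icpt <- spec_par(spec, "intercept", c(10, 0))
  slope <- spec_par(spec, "slope", c(0.001, 0))
  beads$x_red <- beads$x + icpt[1] + slope[1] * beads$g_col
  beads$y_red <- beads$y + icpt[2] + slope[2] * beads$g_row
  outl <- spec_par(spec, "outlier_beads", integer())
  oshift <- spec_par(spec, "outlier_shift", c(4, 4))
  if (length(outl)) {
    beads$x_red[outl] <- beads$x_red[outl] + oshift[1]
    beads$y_red[outl] <- beads$y_red[outl] + oshift[2]
  }
  list(image = image, beads = beads,
       truth = list(kind = "channel_shift_gradient", intercept = icpt,
                    slope = slope, outlier_beads = sort(outl),
                    outlier_shift = oshift))
}

inject_id_scramble <- function(image, beads, spec) {
  idx <- spec$beads
  if (is.null(idx)) idx <- sample(beads$bead, spec_par(spec, "n", 20L))
  perm <- sample(idx)
  old <- beads$bead_type_id[idx]
  beads$bead_type_id[idx] <- beads$bead_type_id[perm]
  list(image = image, beads = beads,
       truth = list(kind = "id_scramble", beads = sort(idx),
                    permuted_to = perm, old_ids = old))
}

#' Generate a complete ground-truthed dataset on disk
#'
#' Runs the full simulation under `config` and writes: the 16-bit TIFF
#' section image (plus a red-channel TIFF when a channel-shift artefact
#' is present), the bead-level TSV of decoded beads, the locs-dialect
#' binary of all grid positions, the layout JSON, and a JSON truth
#' manifest (config echo plus per-artefact truth).
#'
#' @param config A [simulation_config()].
#' @param out_dir Writable output directory (created if needed).
#' @return Invisibly, a manifest list with the written paths, the final
#'   `beads` table, `image`, and artefact `truth`.
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- sim_layout(config)
  grid <- nominal_positions(layout, origin = c(config$margin, config$margin))
  beads <- assign_bead_types(grid, config)
  image <- render_section_image(beads, config)
  inj <- inject_artifacts(image, beads, config$artifacts,
                          config = config)
  image <- inj$image; beads <- inj$beads

  paths <- list(image = file.path(out_dir, "section_green.tif"),
                beadlevel = file.path(out_dir, "beads.txt"),
                locs = file.path(out_dir, "section.locs"),
                layout = file.path(out_dir, "layout.json"),
                truth = file.path(out_dir, "truth.json"))
  write_section_tiff(image, paths$image)
  if (!is.null(beads$x_red)) {
    paths$image_red <- file.path(out_dir, "section_red.tif")
    write_section_tiff(image, paths$image_red)
  }
  decoded <- beads[beads$bead_type_id >= 0, ]
  write_beadlevel(data.frame(bead_type_id = decoded$bead_type_id,
                             x = decoded$x, y = decoded$y,
                             intensity = decoded$true_intensity),
                  paths$beadlevel)
  write_locs(cbind(beads$x, beads$y), paths$locs)
  write_layout_json(layout, paths$layout)
  jsonlite::write_json(list(config = unclass(config[setdiff(names(config),
                                                            "artifacts")]),
                            truth = inj$truth),
                       paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, beads = beads, image = image,
                 truth = inj$truth, layout = layout))
}
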