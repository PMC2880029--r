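#' Construct a chip layout description
#'
#' A `chip_layout` records the physical geometry of a BeadArray platform:
#' how many samples a chip carries, how sections and segments are arranged,
#' and the bead lattice inside one segment.  Two platforms are built in:
#' `"WG6v2"` (expression; 6 samples x 2 sections, 9 segments per section,
#' 326 x 397 beads per segment) and `"CNV370"` (copy number; 2 samples x
#' 12 sections, 4 segments per section, 333 x 443 beads per segment).
#'
#' @param platform_name Platform identifier; one of the supported names,
#'   or any label when all geometry arguments are supplied explicitly.
#' @param n_samples,sections_per_sample,segments_per_section Chip structure
#'   counts, all >= 1.
#' @param segment_cols,segment_rows Bead columns / rows of one segment grid.
#' @param bead_pitch Nearest-neighbour bead-centre spacing in pixels
#'   (default 6).
#' @param bead_radius Nominal bead radius in pixels; must be below half the
#'   pitch so neighbouring beads do not overlap.
#' @return An object of class `chip_layout`.
#' @seealso [build_layout()] for the named platforms.
#' @export
chip_layout <- function(platform_name, n_samples, sections_per_sample,
                        segments_per_section, segment_cols, segment_rows,
                        bead_pitch = 6, bead_radius = 2.5) {
  layout <- structure(
    list(platform_name = platform_name,
         n_samples = as.integer(n_samples),
         sections_per_sample = as.integer(sections_per_sample),
         segments_per_section = as.integer(segments_per_section),
         segment_cols = as.integer(segment_cols),
         segment_rows = as.integer(segment_rows),
         bead_pitch = as.numeric(bead_pitch),
         bead_radius = as.numeric(bead_radius)),
    class = "chip_layout")
  validate_layout(layout)
}

validate_layout <- function(layout) {
  counts <- c(layout$n_samples, layout$sections_per_sample,
              layout$segments_per_section, layout$segment_cols,
              layout$segment_rows)
  if (any(is.na(counts)) || any(counts < 1L))
    stop("all layout counts must be >= 1")
  if (!is.finite(layout$bead_pitch) || layout$bead_pitch <= 0)
    stop("bead_pitch must be positive")
  if (!is.finite(layout$bead_radius) || layout$bead_radius <= 0 ||
      layout$bead_radius >= layout$bead_pitch / 2)
    stop("bead_radius must lie in (0, bead_pitch/2)")
  layout
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf("<chip_layout> %s: %d samples x %d sections x %d segments\n",
              x$platform_name, x$n_samples, x$sections_per_sample,
              x$segments_per_section))
  cat(sprintf("  segment grid %d x %d (%s beads), pitch %.2f px, radius %.2f px\n",
              x$segment_cols, x$segment_rows,
              format(beads_per_segment(x), big.mark = ","),
              x$bead_pitch, x$bead_radius))
  invisible(x)
}

#' Number of beads in one segment
#'
#' @param layout A [chip_layout()].
#' @return `segment_cols * segment_rows` as an integer.
#' @export
beads_per_segment <- function(layout) {
  layout$segment_cols * layout$segment_rows
}

#' Build the layout of a supported BeadArray platform
#'
#' @param platform_name `"WG6v2"` or `"CNV370"`.
#' @return A [chip_layout()].
#' @examples
#' build_layout("WG6v2")
#' beads_per_segment(build_layout("CNV370"))
#' @export
build_layout <- function(platform_name) {
  supported <- c("WG6v2", "CNV370")
  if (!platform_name %in% supported)
    stop(sprintf("unknown platform '%s'; supported platforms: %s",
                 platform_name, paste(supported, collapse = ", ")))
  switch(platform_name,
    WG6v2 = chip_layout("WG6v2", n_samples = 6, sections_per_sample = 2,
                        segments_per_section = 9,
                        segment_cols = 326, segment_rows = 397),
    CNV370 = chip_layout("CNV370", n_samples = 2, sections_per_sample = 12,
                         segments_per_section = 4,
                         segment_cols = 333, segment_rows = 443))
}

#' Nominal hexagonal bead-centre positions for a segment
#'
#' Generates the ideal hexagonal lattice of bead centres.  Grid row `r`,
#' column `c` (both 0-based) maps to
#' `x = origin_x + c * pitch + (r %% 2) * pitch / 2`,
#' `y = origin_y + r * pitch * sqrt(3) / 2`,
#' i.e. rows run parallel to the x-axis, odd rows are offset by half a
#' pitch, and every nearest-neighbour centre distance equals the pitch.
#'
#' Pixel coordinates are 0-based; pixel `(i, j)` covers
#' `[i, i+1) x [j, j+1)`, so the integer parts of a centre select its
#' anchor pixel.
#'
#' @param layout A [chip_layout()]; supplies pitch and default grid size.
#' @param origin Numeric `(x, y)` of the row-0 column-0 bead centre.
#' @param n_rows,n_cols Optional grid dimensions overriding the layout's
#'   segment grid (useful for small studies).
#' @return A `bead_grid`: a data frame with columns `g_row`, `g_col`,
#'   `x`, `y`, one row per lattice point in row-major order, with the
#'   pitch and origin stored as attributes.
#' @export
nominal_positions <- function(layout, origin = c(0, 0),
                              n_rows = NULL, n_cols = NULL) {
  if (is.null(n_rows)) n_rows <- layout$segment_rows
  if (is.null(n_cols)) n_cols <- layout$segment_cols
  p <- layout$bead_pitch
  r <- rep(seq_len(n_rows) - 1L, each = n_cols)
  c_ <- rep(seq_len(n_cols) - 1L, times = n_rows)
  grid <- data.frame(
    g_row = r, g_col = c_,
    x = origin[1] + c_ * p + (r %% 2L) * p / 2,
    y = origin[2] + r * p * sqrt(3) / 2)
  attr(grid, "pitch") <- p
  attr(grid, "origin") <- origin
  class(grid) <- c("bead_grid", "data.frame")
  grid
}

#' Bead neighbour graph of a hexagonal grid
#'
#' Builds the symmetric adjacency over the lattice: each bead is adjacent
#' to the (at most six) lattice points at centre distance one pitch.
#' Interior beads have exactly 6 neighbours; edge and corner beads 2-5.
#'
#' @param grid A `bead_grid` from [nominal_positions()].
#' @return A `neighbour_graph`: list with `adj` (list of integer
#'   neighbour indices per bead), `edges` (two-column integer matrix,
#'   each undirected edge once), and `n` (bead count).
#' @export
build_neighbour_graph <- function(grid) {
  if (nrow(grid) == 0L) stop("grid is empty")
  r <- grid$g_row; c_ <- grid$g_col
  R <- max(r) + 1L; C <- max(c_) + 1L
  idx <- matrix(NA_integer_, nrow = R, ncol = C)
  idx[cbind(r + 1L, c_ + 1L)] <- seq_len(nrow(grid))

  # forward directions only, so each undirected edge is generated once:
  # east, and the two beads in the next row (columns depend on row parity)
  edge_to <- function(dr, dc_even, dc_odd) {
    dc <- ifelse(r %% 2L == 0L, dc_even, dc_odd)
    rr <- r + dr; cc <- c_ + dc
    ok <- rr >= 0L & rr < R & cc >= 0L & cc < C
    to <- rep(NA_integer_, length(r))
    to[ok] <- idx[cbind(rr[ok] + 1L, cc[ok] + 1L)]
    ok <- ok & !is.na(to)
    cbind(which(ok), to[ok])
  }
  edges <- rbind(edge_to(0L, 1L, 1L),    # east
                 edge_to(1L, -1L, 0L),   # south-west
                 edge_to(1L, 0L, 1L))    # south-east
  adj <- vector("list", nrow(grid))
  tab <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  adj[as.integer(names(tab))] <- lapply(tab, function(v) sort(unique(v)))
  empty <- vapply(adj, is.null, logical(1))
  adj[empty] <- list(integer(0))
  structure(list(adj = adj, edges = edges, n = nrow(grid)),
            class = "neighbour_graph")
}

#' @export
print.neighbour_graph <- function(x, ...) {
  cat(sprintf("<neighbour_graph> %d beads, %d edges\n", x$n, nrow(x$edges)))
  invisible(x)
}

#' Graph degree of every bead
#' @param graph A `neighbour_graph`.
#' @return Integer vector of neighbour counts.
#' @export
graph_degree <- function(graph) {
  lengths(graph$adj)
}

#' Flag beads whose extraction windows leave the image
#'
#' A bead needs its 4x4 foreground window and its 17x17 background window
#' fully inside the image; the 17x17 window (anchor pixel +/- 8) contains
#' the foreground window, so it is the binding constraint.
#'
#' @param beads Data frame with bead centres in columns `x`, `y`.
#' @param image_dims `(width, height)` of the section image in pixels.
#' @return A [mask_set()] with reason `"out_of_image"`.
#' @export
flag_out_of_image <- function(beads, image_dims) {
  if (any(image_dims <= 0)) stop("image dimensions must be positive")
  ax <- floor(beads$x); ay <- floor(beads$y)
  out <- ax - 8 < 0 | ax + 8 > image_dims[1] - 1 |
         ay - 8 < 0 | ay + 8 > image_dims[2] - 1
  mask_set(which(out), "out_of_image")
}

#' Maximum lattice centres inside a square pixel window
#'
#' Brute-force study of the background-window geometry: generates a
#' hexagonal lattice at the given pitch, scans all window translations
#' over one lattice cell at `step` pixels, and returns the maximum
#' number of bead centres falling inside a `window`-pixel axis-aligned
#' square.  At pitch 6 a 17 x 17 window can contain 12 bead centres.
#'
#' @param pitch Lattice nearest-neighbour spacing in pixels.
#' @param window Window side in pixels (default 17).
#' @param step Translation scan step in pixels (default 0.1).
#' @return Integer maximum count over all translations.
#' @export
lattice_window_capacity <- function(pitch = 6, window = 17, step = 0.1) {
  rowh <- pitch * sqrt(3) / 2
  n_ext <- ceiling(window / pitch) + 3L
  r <- rep(seq_len(2L * n_ext) - n_ext, each = 2L * n_ext)
  c_ <- rep(seq_len(2L * n_ext) - n_ext, times = 2L * n_ext)
  px <- c_ * pitch + (r %% 2L) * pitch / 2
  py <- r * rowh
  # scan one lattice cell (pitch x 2 row heights covers both parities)
  tx <- seq(0, pitch, by = step)
  ty <- seq(0, 2 * rowh, by = step)
  best <- 0L
  for (oy in ty) {
    iny <- py >= oy & py <= oy + window
    if (!any(iny)) next
    sx <- px[iny]
    cnt <- vapply(tx, function(ox) sum(sx >= ox & sx <= ox + window),
                  integer(1))
    best <- max(best, cnt)
  }
  best
}
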