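#' Find clusters of non-decoded beads
#'
#' Any genuine patch of contiguous non-decoded beads contains at least
#' one non-decoded bead whose six neighbours are all non-decoded; each
#' such bead seeds an invasion (flood fill) over neighbouring non-decoded
#' beads, and the maximal connected networks of `min_size` or more beads
#' are reported.  Scattered singletons never produce a seed and are
#' ignored.
#'
#' @param graph A [build_neighbour_graph()] result.
#' @param decoded Logical vector: `TRUE` where the bead was decoded.
#' @param min_size Minimum cluster size (default 50).
#' @return A `cluster_set`: list of clusters, each with `members`
#'   (sorted bead indices) and `seeds`.
#' @export
find_nondecoded_clusters <- function(graph, decoded, min_size = 50L) {
  nd <- !decoded
  deg <- graph_degree(graph)
  seeds <- which(nd & deg == 6L &
                 vapply(graph$adj, function(a) all(nd[a]), logical(1)))
  clusters <- list()
  visited <- rep(FALSE, graph$n)
  for (s in seeds) {
    if (visited[s]) next
    members <- flood_fill(graph, s, nd)
    visited[members] <- TRUE
    if (length(members) >= min_size)
      clusters[[length(clusters) + 1L]] <-
        list(members = members, seeds = intersect(seeds, members))
  }
  structure(clusters, class = "cluster_set")
}

# breadth-first flood fill from `start` over vertices where `eligible`
flood_fill <- function(graph, start, eligible) {
  seen <- rep(FALSE, graph$n)
  seen[start] <- TRUE
  frontier <- start
  while (length(frontier)) {
    nxt <- unique(unlist(graph$adj[frontier], use.names = FALSE))
    nxt <- nxt[eligible[nxt] & !seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  which(seen)
}

#' Expand clusters into their surrounding halo
#'
#' Decoded beads near a non-decoded cluster tend to show inflated
#' intensity; this returns, for each cluster, the decoded beads within
#' `rings` graph hops of any member.
#'
#' @param clusters A [find_nondecoded_clusters()] result.
#' @param graph The same [build_neighbour_graph()].
#' @param decoded Logical decoded flags.
#' @param rings Expansion depth in graph hops (default 2; 0 = no halo).
#' @return List of integer halo bead vectors, parallel to `clusters`.
#' @export
expand_cluster <- function(clusters, graph, decoded, rings = 2L) {
  lapply(clusters, function(cl) {
    if (rings < 1L) return(integer())
    halo <- graph_rings(graph, cl$members, rings)
    halo[decoded[halo]]
  })
}

#' Flag beads in or near non-decoded clusters
#'
#' @inheritParams expand_cluster
#' @return [mask_set()] flagging members as `"in_cluster"` and halo beads
#'   as `"near_cluster"`.
#' @export
flag_cluster_beads <- function(clusters, graph, decoded, rings = 2L) {
  halos <- expand_cluster(clusters, graph, decoded, rings)
  mask_union(
    mask_set(unlist(lapply(clusters, `[[`, "members")), "in_cluster"),
    mask_set(unlist(halos), "near_cluster"))
}

#' Detect encroaching bright features in a section image
#'
#' Thresholds the image, labels connected components
#' (`EBImage::bwlabel`), and keeps features with pixel mass at least
#' `min_mass` and circularity `4 * pi * A / P^2` of at least
#' `min_circularity` (perimeter estimated as boundary-pixel count,
#' capped at 1).  Each feature is mapped to the nearest bead centre when
#' centres are supplied.
#'
#' @param image Section image.
#' @param threshold Intensity threshold; default `mean + 5 sd`.
#' @param min_mass Minimum component pixel count (default 40).
#' @param min_circularity Minimum circularity in `[0, 1]` (default 0.8).
#' @param bead_centres Optional data frame `x`, `y` for mapping.
#' @return Data frame of features: `mass`, `cx`, `cy`, `circularity`,
#'   `bead` (NA when unmapped).
#' @export
detect_bright_features <- function(image, threshold = NULL, min_mass = 40L,
                                   min_circularity = 0.8,
                                   bead_centres = NULL) {
  if (is.null(threshold)) threshold <- mean(image) + 5 * stats::sd(image)
  mask <- image > threshold
  if (!any(mask))
    return(data.frame(mass = integer(), cx = numeric(), cy = numeric(),
                      circularity = numeric(), bead = integer()))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow = nrow(mask)))
  nlab <- max(lab)
  out <- lapply(seq_len(nlab), function(l) {
    w <- which(lab == l, arr.ind = TRUE)
    mass <- nrow(w)
    # boundary pixels: component pixels with a 4-neighbour outside it
    on_border <- vapply(seq_len(mass), function(k) {
      i <- w[k, 1]; j <- w[k, 2]
      i == 1L || j == 1L || i == nrow(lab) || j == ncol(lab) ||
        lab[i - 1L, j] != l || lab[i + 1L, j] != l ||
        lab[i, j - 1L] != l || lab[i, j + 1L] != l
    }, logical(1))
    per <- sum(on_border)
    circ <- min(4 * pi * mass / per^2, 1)
    # pixel (row i, col j) has mass centre (j - 1 + .5, i - 1 + .5)
    data.frame(mass = mass, cx = mean(w[, 2]) - 0.5, cy = mean(w[, 1]) - 0.5,
               circularity = circ)
  })
  out <- do.call(rbind, out)
  out <- out[out$mass >= min_mass & out$circularity >= min_circularity, ,
             drop = FALSE]
  out$bead <- rep(NA_integer_, nrow(out))
  if (!is.null(bead_centres) && nrow(out)) {
    for (k in seq_len(nrow(out))) {
      d2 <- (bead_centres$x - out$cx[k])^2 + (bead_centres$y - out$cy[k])^2
      out$bead[k] <- which.min(d2)
    }
  }
  rownames(out) <- NULL
  out
}

#' Flag bright beads and their neighbours
#'
#' Signal from a very bright bead spills into the foreground windows of
#' its lattice neighbours; all graph neighbours of each mapped bright
#' feature are flagged `"bright_neighbour"`, the bright bead itself
#' `"bright_bead"`.
#'
#' @param features A [detect_bright_features()] result (mapped to beads).
#' @param graph A [build_neighbour_graph()] result.
#' @return [mask_set()].
#' @export
flag_bright_neighbours <- function(features, graph) {
  beads <- features$bead[!is.na(features$bead)]
  if (!length(beads)) return(mask_set())
  mask_union(
    mask_set(beads, "bright_bead"),
    mask_set(unlist(graph$adj[beads]), "bright_neighbour"))
}

#' Detect abnormally low pixels
#'
#' Finds pixels far below the modal background: the mode is taken from an
#' integer histogram of the lower half of the image's intensities, and
#' pixels below `low_fraction` times the mode are returned.
#'
#' @param image Section image.
#' @param low_fraction Threshold as a fraction of the modal background
#'   (default 0.5).
#' @return Data frame of 0-based pixel coordinates `x`, `y` and `value`.
#' @export
detect_low_pixels <- function(image, low_fraction = 0.5) {
  v <- as.numeric(image)
  lower <- round(v[v <= stats::median(v)])
  mode_bg <- as.numeric(names(which.max(table(lower))))
  w <- which(image < low_fraction * mode_bg, arr.ind = TRUE)
  data.frame(x = w[, 2] - 1L, y = w[, 1] - 1L,
             value = image[w])
}

#' Flag beads whose background is corrupted by a low pixel
#'
#' A detected low pixel inside a bead's 17x17 background window
#' inevitably ranks among the window's five lowest values and drags the
#' (non-robust) mean-of-five background down; every such bead is flagged.
#'
#' @param pixels A [detect_low_pixels()] result.
#' @param beads Bead data frame with centres `x`, `y`.
#' @param image Raw section image.
#' @return [mask_set()] with reason `"low_pixel"`.
#' @export
flag_low_pixel_beads <- function(pixels, beads, image) {
  if (!nrow(pixels)) return(mask_set())
  ax <- floor(beads$x); ay <- floor(beads$y)
  hit <- integer()
  for (k in seq_len(nrow(pixels))) {
    px <- pixels$x[k]; py <- pixels$y[k]
    cand <- which(abs(ax - px) <= 8 & abs(ay - py) <= 8)
    for (i in cand) {
      xs <- (ax[i] - 8):(ax[i] + 8); ys <- (ay[i] - 8):(ay[i] + 8)
      if (any(xs < 0) || any(ys < 0) ||
          any(xs > ncol(image) - 1) || any(ys > nrow(image) - 1)) next
      w <- as.numeric(image[ys + 1L, xs + 1L])
      if (pixels$value[k] <= sort(w, partial = 5)[5]) hit <- c(hit, i)
    }
  }
  mask_set(unique(hit), "low_pixel")
}

#' Count neighbouring same-type bead pairs
#'
#' A "twin pair" is an edge of the neighbour graph whose two beads carry
#' the same bead-type; each edge is counted once.  Non-decoded beads
#' (ID < 0) never pair.
#'
#' @param graph A [build_neighbour_graph()] result.
#' @param bead_type_ids Integer IDs aligned with the graph (-1 =
#'   non-decoded).
#' @return Integer pair count.
#' @export
count_twin_pairs <- function(graph, bead_type_ids) {
  a <- bead_type_ids[graph$edges[, 1]]
  b <- bead_type_ids[graph$edges[, 2]]
  sum(a >= 0 & b >= 0 & a == b)
}

#' Expected twin pairs under i.i.d. uniform type assignment
#'
#' For an idealized array of `n_beads` beads with types assigned
#' independently and uniformly from `n_types`, and `n_beads * mean_degree
#' / 2` edges each counted once, the expected number of same-type
#' neighbouring pairs is `n_beads * mean_degree / 2 / n_types`
#' (e.g. 60 for a million beads, 50,000 types, degree 6).
#'
#' @param n_beads Number of beads.
#' @param mean_degree Mean neighbour count (6 for an idealized hex grid).
#' @param n_types Number of bead-types (>= 1).
#' @return Expected pair count.
#' @export
expected_twin_pairs <- function(n_beads, mean_degree, n_types) {
  if (n_types < 1) stop("n_types must be >= 1")
  (n_beads * mean_degree / 2) / n_types
}

#' Permutation null for twin-pair counts
#'
#' Holds the neighbour graph fixed, permutes the identities of decoded
#' beads uniformly over the decoded positions (non-decoded stay put),
#' and re-tallies same-type neighbouring pairs.  The p-value uses the
#' add-one rule `p = (1 + #[null >= observed]) / (n_perm + 1)`.
#'
#' @param graph A [build_neighbour_graph()] result.
#' @param bead_type_ids Integer IDs (-1 = non-decoded).
#' @param n_perm Number of permutations (default 199).
#' @param seed RNG seed.
#' @return List with `observed`, `null` (length `n_perm`), `p_value`.
#' @export
permutation_null_twins <- function(graph, bead_type_ids, n_perm = 199L,
                                   seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  set.seed(seed)
  obs <- count_twin_pairs(graph, bead_type_ids)
  decoded <- which(bead_type_ids >= 0)
  ids <- bead_type_ids
  null <- integer(n_perm)
  for (k in seq_len(n_perm)) {
    ids[decoded] <- bead_type_ids[sample(decoded)]
    null[k] <- count_twin_pairs(graph, ids)
  }
  list(observed = obs, null = null,
       p_value = (1 + sum(null >= obs)) / (n_perm + 1))
}

#' Mean log-intensity over fractional bead-centre coordinates
#'
#' Breaks a theoretical pixel into `bins x bins` bins of the fractional
#' parts of the bead-centre coordinates and, per bin, averages the log2
#' intensity (or the within bead-type residual log2 intensity) of the
#' beads falling there.  A spatial trend across the bins reveals
#' dependence between sub-pixel location and measured intensity.
#'
#' @param beads Data frame with `x`, `y`, `intensity`, and (for residual
#'   mode) `bead_type_id`.
#' @param bins Bins per axis (default 100).
#' @param mode `"log_intensity"` or `"residual"` (log2 minus the
#'   bead-type median log2).
#' @return `bins x bins` matrix of bin means (rows = frac_y bins); empty
#'   bins are `NA`.
#' @export
fractional_intensity_map <- function(beads, bins = 100L,
                                     mode = c("log_intensity", "residual")) {
  mode <- match.arg(mode)
  ok <- beads$intensity > 0 & is.finite(beads$intensity)
  b <- beads[ok, , drop = FALSE]
  val <- log2(b$intensity)
  if (mode == "residual") {
    if (is.null(b$bead_type_id)) stop("residual mode needs bead_type_id")
    med <- tapply(val, b$bead_type_id, stats::median)
    val <- val - med[as.character(b$bead_type_id)]
  }
  ix <- pmin(floor((b$x - floor(b$x)) * bins), bins - 1L) + 1L
  iy <- pmin(floor((b$y - floor(b$y)) * bins), bins - 1L) + 1L
  m <- matrix(NA_real_, bins, bins)
  s <- rowsum(val, (iy - 1L) * bins + ix)
  n <- rowsum(rep(1, length(val)), (iy - 1L) * bins + ix)
  key <- as.integer(rownames(s))
  m[cbind((key - 1L) %/% bins + 1L, (key - 1L) %% bins + 1L)] <- s / n
  m
}
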