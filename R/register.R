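#' Register a hexagonal bead grid to a section image
#'
#' A simplified detect/fit/interpolate registration: bright local maxima
#' are detected and refined to sub-pixel centroids, assigned provisional
#' lattice indices, and the lattice origin, pitch and row height are then
#' fit by least squares (one refinement pass of the index assignment).
#' The recovered origin is anchored at the topmost detected bead row, so
#' on a clean image with detectable beads in the first grid row it
#' matches the true origin.
#'
#' @param image Section image matrix.
#' @param layout A [chip_layout()] supplying the approximate pitch.
#' @param threshold Detection threshold; default `mean + 3 sd` of the
#'   image.
#' @return List with `origin` (`(x, y)`), `pitch`, `row_height`,
#'   `n_landmarks`, and `landmarks` (detected sub-pixel centres with
#'   assigned grid indices).
#' @export
register_grid <- function(image, layout, threshold = NULL) {
  if (is.null(threshold)) threshold <- mean(image) + 3 * stats::sd(image)
  pk <- detect_local_maxima(image, threshold)
  if (nrow(pk) < 10L)
    stop("insufficient landmarks: only ", nrow(pk), " bright beads detected")
  ctr <- t(vapply(seq_len(nrow(pk)), function(i)
    pixel_centroid(image, pk$x[i], pk$y[i], 2L), numeric(2)))
  x <- ctr[, 1]; y <- ctr[, 2]
  p0 <- layout$bead_pitch
  rowh <- p0 * sqrt(3) / 2
  assign_fit <- function(ox, oy, p, h) {
    r <- round((y - oy) / h)
    cc <- round((x - ox - (r %% 2) * p / 2) / p)
    gx <- cc + (r %% 2) / 2
    fx <- stats::lm.fit(cbind(1, gx), x)$coefficients
    fy <- stats::lm.fit(cbind(1, r), y)$coefficients
    list(ox = fx[1], p = fx[2], oy = fy[1], h = fy[2], r = r, c = cc)
  }
  oy0 <- min(y)
  r0 <- round((y - oy0) / rowh)
  even <- r0 %% 2 == 0
  ox0 <- if (any(even)) min(x[even]) else min(x) - p0 / 2
  f <- assign_fit(ox0, oy0, p0, rowh)
  f <- assign_fit(f$ox, f$oy, f$p, f$h)
  list(origin = c(x = unname(f$ox), y = unname(f$oy)),
       pitch = unname(f$p), row_height = unname(f$h),
       n_landmarks = nrow(pk),
       landmarks = data.frame(x = x, y = y, g_row = f$r, g_col = f$c))
}

# pixels strictly above their 8 neighbours and above `threshold`;
# returns 0-based anchor pixel coordinates
detect_local_maxima <- function(image, threshold) {
  n <- nrow(image); m <- ncol(image)
  pad <- matrix(-Inf, n + 2L, m + 2L)
  pad[2:(n + 1), 2:(m + 1)] <- image
  ctrI <- 2:(n + 1); ctrJ <- 2:(m + 1)
  is_max <- image > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    # strict on lexicographically earlier neighbours so a flat-topped
    # plateau yields exactly one maximum
    if (di < 0 || (di == 0 && dj < 0))
      is_max <- is_max & image > pad[ctrI + di, ctrJ + dj]
    else
      is_max <- is_max & image >= pad[ctrI + di, ctrJ + dj]
  }
  w <- which(is_max, arr.ind = TRUE)
  data.frame(x = w[, 2] - 1L, y = w[, 1] - 1L)
}

# intensity-weighted centroid of a (2*half+1)^2 window around anchor
# pixel (px, py); pixel (i, j) contributes at its mass centre (i+.5, j+.5)
pixel_centroid <- function(image, px, py, half = 2L) {
  xs <- max(0L, px - half):min(ncol(image) - 1L, px + half)
  ys <- max(0L, py - half):min(nrow(image) - 1L, py + half)
  w <- image[ys + 1L, xs + 1L, drop = FALSE]
  w <- w - min(w)
  if (sum(w) <= 0) return(c(px + 0.5, py + 0.5))
  c(sum(outer(rep(1, length(ys)), xs + 0.5) * w) / sum(w),
    sum(outer(ys + 0.5, rep(1, length(xs))) * w) / sum(w))
}

#' Refine bead centres to local intensity-weighted centroids
#'
#' Each nominal centre is moved to the background-subtracted
#' intensity-weighted centroid of the pixels within `search_radius`.
#' Beads with no signal above the local median stay put.
#'
#' @param image Section image.
#' @param centres Data frame with nominal `x`, `y`.
#' @param search_radius Search disc radius in pixels (< pitch / 2).
#' @return Data frame `x`, `y` of refined centres.
#' @export
refine_centres <- function(image, centres, search_radius = 2.5) {
  n <- nrow(centres)
  out <- data.frame(x = numeric(n), y = numeric(n))
  rad <- ceiling(search_radius)
  for (i in seq_len(n)) {
    cx <- centres$x[i]; cy <- centres$y[i]
    xs <- max(0, floor(cx) - rad):min(ncol(image) - 1, floor(cx) + rad)
    ys <- max(0, floor(cy) - rad):min(nrow(image) - 1, floor(cy) + rad)
    mx <- outer(rep(1, length(ys)), xs + 0.5)
    my <- outer(ys + 0.5, rep(1, length(xs)))
    inside <- (mx - cx)^2 + (my - cy)^2 <= search_radius^2
    w <- image[ys + 1L, xs + 1L, drop = FALSE]
    w <- pmax(w - stats::median(w), 0) * inside
    if (sum(w) <= 0) {
      out$x[i] <- cx; out$y[i] <- cy
    } else {
      out$x[i] <- sum(mx * w) / sum(w)
      out$y[i] <- sum(my * w) / sum(w)
    }
  }
  out
}

#' Fit the per-segment grid model and departure statistic
#'
#' Fits the observed pixel coordinates of decoded beads as affine
#' functions of their lattice coordinates by least squares, separately
#' for x and y, and returns per-bead residuals and the departure
#' statistic `d = sqrt(r_x^2 + r_y^2)`.  The x regressor uses the
#' effective hex coordinate `g_col + (g_row %% 2) / 2` so a perfect
#' lattice fits exactly.
#'
#' @param beads Data frame of one segment's decoded beads: `g_row`,
#'   `g_col`, `x`, `y`.
#' @return A `grid_fit`: list with `coef_x`, `coef_y` (intercept, per
#'   effective column, per row), and data frame `residuals` (`r_x`,
#'   `r_y`, `d`).
#' @export
fit_grid_model <- function(beads) {
  if (nrow(beads) < 10L) stop("need >= 10 beads to fit the grid model")
  gx <- beads$g_col + (beads$g_row %% 2) / 2
  gy <- beads$g_row
  X <- cbind(1, gx, gy)
  if (qr(X)$rank < 3L)
    stop("degenerate design: beads are collinear in grid space")
  fx <- stats::lm.fit(X, beads$x)
  fy <- stats::lm.fit(X, beads$y)
  res <- data.frame(r_x = fx$residuals, r_y = fy$residuals)
  res$d <- sqrt(res$r_x^2 + res$r_y^2)
  structure(list(coef_x = fx$coefficients, coef_y = fy$coefficients,
                 residuals = res),
            class = "grid_fit")
}

#' Flag beads with large departure from the grid
#'
#' @param fit A [fit_grid_model()] result.
#' @param threshold Departure threshold in pixels (default 1).
#' @param bead Optional bead indices matching the fit rows (default row
#'   numbers).
#' @return [mask_set()] with reason `"large_departure"`.
#' @export
flag_large_departure <- function(fit, threshold = 1, bead = NULL) {
  if (is.null(bead)) bead <- seq_len(nrow(fit$residuals))
  mask_set(bead[fit$residuals$d > threshold], "large_departure")
}

#' Cross-segment alignment diagnostics
#'
#' Checks that segments have similar extreme x coordinates and are evenly
#' spaced along y: a segment is flagged when its x extremes deviate from
#' the cross-segment median by more than `tol`, or when the gap to the
#' previous segment deviates from the median gap by more than `tol`.
#'
#' @param segments List of bead data frames (columns `x`, `y`), one per
#'   segment, in top-to-bottom order.
#' @param tol Tolerance in pixels (default 5).
#' @return Data frame per segment: `min_x`, `max_x`, `min_y`, `max_y`,
#'   `y_gap` (NA for the first), `flagged`.
#' @export
segment_alignment_check <- function(segments, tol = 5) {
  if (length(segments) < 2L) stop(">=2 segments required")
  d <- data.frame(
    segment = seq_along(segments),
    min_x = vapply(segments, function(s) min(s$x), numeric(1)),
    max_x = vapply(segments, function(s) max(s$x), numeric(1)),
    min_y = vapply(segments, function(s) min(s$y), numeric(1)),
    max_y = vapply(segments, function(s) max(s$y), numeric(1)))
  d$y_gap <- c(NA, d$min_y[-1] - d$max_y[-nrow(d)])
  flag <- abs(d$min_x - stats::median(d$min_x)) > tol |
          abs(d$max_x - stats::median(d$max_x)) > tol
  gaps <- d$y_gap[-1]
  if (length(gaps) >= 2) {
    gap_bad <- abs(gaps - stats::median(gaps)) > tol
    flag[-1] <- flag[-1] | gap_bad
  }
  d$flagged <- flag
  d
}

#' Recover a whole-segment annotation shift by variance minimization
#'
#' When the grid of bead-type IDs is mis-positioned relative to the
#' physical beads, the annotation is completely scrambled and the within
#' bead-type variance of log2 intensity is inflated.  This searches all
#' integer grid shifts in `[-max_shift, max_shift]^2`: candidate shift
#' `(d_col, d_row)` annotates the bead at grid `(r, c)` with the recorded
#' ID at `(r + d_row, c + d_col)`, and the mean within-type variance of
#' log2 intensity (types with >= 2 annotated beads, positive intensities)
#' is evaluated.  The correct alignment shows as a single sharp minimum.
#'
#' @param intensities Matrix of observed bead intensities indexed
#'   `[g_row + 1, g_col + 1]`.
#' @param type_grid Integer matrix of recorded bead-type IDs with the
#'   same indexing (-1 = non-decoded).
#' @param max_shift Search half-range in grid steps (default 10).
#' @param reference Optional numeric vector of reference per-type median
#'   log2 intensities (names = type IDs); when given, the profile also
#'   reports the correlation of candidate type medians with it.
#' @return List with `best_shift` (`(d_col, d_row)`), `variance`
#'   (profile matrix, rows = d_row, cols = d_col), `best_variance`, and
#'   optionally `correlation` (same shape).
#' @export
remap_segment <- function(intensities, type_grid, max_shift = 10L,
                          reference = NULL) {
  R <- nrow(type_grid); C <- ncol(type_grid)
  shifts <- (-max_shift):max_shift
  lv <- suppressWarnings(log2(intensities))
  lv[!is.finite(lv)] <- NA
  prof <- matrix(NA_real_, length(shifts), length(shifts),
                 dimnames = list(d_row = shifts, d_col = shifts))
  corr <- if (!is.null(reference)) prof else NULL
  for (ir in seq_along(shifts)) for (ic in seq_along(shifts)) {
    dr <- shifts[ir]; dc <- shifts[ic]
    rs <- max(1L, 1L - dr):min(R, R - dr)
    cs <- max(1L, 1L - dc):min(C, C - dc)
    if (!length(rs) || !length(cs)) next
    ids <- type_grid[rs + dr, cs + dc, drop = FALSE]
    val <- lv[rs, cs, drop = FALSE]
    ok <- !is.na(val) & ids >= 0
    if (sum(ok) < 2L) next
    prof[ir, ic] <- mean_within_type_var(val[ok], ids[ok])
    if (!is.null(reference)) {
      med <- tapply(val[ok], ids[ok], stats::median)
      common <- intersect(names(med), names(reference))
      if (length(common) >= 3L)
        corr[ir, ic] <- stats::cor(med[common], reference[common])
    }
  }
  if (all(is.na(prof)))
    stop("no candidate shift leaves usable annotated beads on the grid")
  best <- which(prof == min(prof, na.rm = TRUE), arr.ind = TRUE)[1, ]
  out <- list(best_shift = c(d_col = shifts[best[2]], d_row = shifts[best[1]]),
              variance = prof, best_variance = min(prof, na.rm = TRUE))
  if (!is.null(reference)) out$correlation <- corr
  out
}

# mean of per-type variances over types with >= 2 values
mean_within_type_var <- function(values, ids) {
  n <- tabulate(ids <- match(ids, unique(ids)))
  s1 <- rowsum(values, ids); s2 <- rowsum(values^2, ids)
  keep <- n >= 2L
  if (!any(keep)) return(NA_real_)
  v <- (s2[keep] - s1[keep]^2 / n[keep]) / (n[keep] - 1L)
  mean(v)
}

#' Per-bead between-channel shift field
#'
#' For two-colour platforms the red and green channels may not occupy the
#' same pixel space, and the shift can vary across the image ("variable
#' pixel size").  This computes per-bead raw shifts, a local median shift
#' over a sliding window in grid coordinates, per-bead discordance from
#' that local median, and a linear trend of shift against grid position.
#'
#' @param beads Data frame with green centres `x`, `y`, red centres
#'   `x_red`, `y_red`, and grid coordinates `g_row`, `g_col`.
#' @param window Half-width of the sliding window in grid steps
#'   (default 5).
#' @return A `channel_shift_field`: the input with columns `dx`, `dy`,
#'   `med_dx`, `med_dy`, `disc_x`, `disc_y`, `disc` added, and the trend
#'   fit (`slope_x` per grid column, `slope_y` per grid row) as
#'   attributes.
#' @export
estimate_channel_shift <- function(beads, window = 5L) {
  if (is.null(beads$x_red) || is.null(beads$y_red))
    stop("beads must carry x_red / y_red coordinates")
  dx <- beads$x_red - beads$x
  dy <- beads$y_red - beads$y
  n <- nrow(beads)
  med_dx <- med_dy <- numeric(n)
  by_row <- split(seq_len(n), beads$g_row)
  rows <- as.integer(names(by_row))
  for (i in seq_len(n)) {
    r <- beads$g_row[i]; c_ <- beads$g_col[i]
    cand <- unlist(by_row[rows >= r - window & rows <= r + window],
                   use.names = FALSE)
    cand <- cand[abs(beads$g_col[cand] - c_) <= window]
    med_dx[i] <- stats::median(dx[cand])
    med_dy[i] <- stats::median(dy[cand])
  }
  beads$dx <- dx; beads$dy <- dy
  beads$med_dx <- med_dx; beads$med_dy <- med_dy
  beads$disc_x <- dx - med_dx; beads$disc_y <- dy - med_dy
  beads$disc <- sqrt(beads$disc_x^2 + beads$disc_y^2)
  X <- cbind(1, beads$g_col, beads$g_row)
  cx <- stats::lm.fit(X, dx)$coefficients
  cy <- stats::lm.fit(X, dy)$coefficients
  attr(beads, "slope_x") <- unname(cx[2])
  attr(beads, "slope_y") <- unname(cy[3])
  attr(beads, "intercept") <- c(unname(cx[1]), unname(cy[1]))
  class(beads) <- c("channel_shift_field", "data.frame")
  beads
}

#' Flag channel-discordant beads
#'
#' Flags beads whose discordance from the local median channel shift
#' exceeds `threshold`, and beads sharing identical red-channel
#' coordinates with another bead (a symptom of mis-targeting).
#'
#' @param field An [estimate_channel_shift()] result.
#' @param threshold Discordance norm threshold in pixels (default 2).
#' @return [mask_set()] with reason `"channel_discordant"`.
#' @export
flag_channel_discordant <- function(field, threshold = 2) {
  disc <- which(field$disc > threshold)
  key <- paste(field$x_red, field$y_red)
  coll <- which(key %in% key[duplicated(key)])
  mask_set(union(disc, coll), "channel_discordant")
}
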