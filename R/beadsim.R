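#' Idealized bead model
#'
#' A bead is modelled as a sphere evenly covered in probes: under
#' orthographic imaging its fluorescence density at distance `d` from the
#' centre is proportional to the chord depth `sqrt(r^2 - d^2)` for
#' `d <= r`.  A Gaussian profile (`sigma = radius / 2`) is offered as an
#' alternative.
#'
#' @param radius Bead radius in pixels.
#' @param peak Peak fluorescence density at the bead centre (pixel units).
#' @param profile `"sphere"` (projected sphere) or `"gaussian"`.
#' @return A `bead_model` list.
#' @export
bead_model <- function(radius = 3, peak = 60000,
                       profile = c("sphere", "gaussian")) {
  profile <- match.arg(profile)
  if (radius <= 0 || peak <= 0) stop("radius and peak must be positive")
  structure(list(radius = radius, peak = peak, profile = profile),
            class = "bead_model")
}

profile_density <- function(model, d2) {
  r <- model$radius
  switch(model$profile,
    sphere = model$peak * sqrt(pmax(1 - d2 / r^2, 0)),
    gaussian = model$peak * exp(-d2 / (2 * (r / 2)^2)) *
      (d2 <= (3 * r / 2)^2))
}

#' Total analytic flux of a bead model
#'
#' For the projected sphere the integral of `peak * sqrt(1 - d^2/r^2)`
#' over the plane is `peak * 2/3 * pi * r^2`; used as the closed-form
#' oracle for digitization tests.
#'
#' @param model A [bead_model()].
#' @return Scalar flux.
#' @export
bead_total_flux <- function(model) {
  r <- model$radius
  switch(model$profile,
    sphere = model$peak * 2 / 3 * pi * r^2,
    gaussian = model$peak * 2 * pi * (r / 2)^2 *
      (1 - exp(-(3 * r / 2)^2 / (2 * (r / 2)^2))))
}

#' Digitize an idealized bead onto a pixel grid
#'
#' Simulates scanning: the bead is placed at fractional offset
#' `(offset[1], offset[2])` within the central anchor pixel of a
#' `patch_size` x `patch_size` grid, the fluorescence density is
#' integrated over each pixel square (midpoint quadrature with
#' `n_quad` x `n_quad` sub-pixel samples) and rounded to an integer.
#'
#' @param model A [bead_model()].
#' @param offset Fractional `(x, y)` offset of the centre, each in
#'   `[0, 1)`.
#' @param patch_size Patch side in pixels; must fully contain the bead.
#' @param n_quad Quadrature points per pixel axis (>= 32 recommended).
#' @return List with `patch` (integer matrix, rows = y) and `centre`
#'   (the `(x, y)` bead centre in 0-based patch coordinates).
#' @export
digitize_bead <- function(model, offset = c(0, 0),
                          patch_size = 2L * (ceiling(model$radius) + 2L) + 1L,
                          n_quad = 32L) {
  if (any(offset < 0) || any(offset >= 1))
    stop("offset fractions must lie in [0, 1)")
  m <- patch_size %/% 2L
  cx <- m + offset[1]; cy <- m + offset[2]
  r <- model$radius
  if (cx - r < 0 || cy - r < 0 || cx + r > patch_size || cy + r > patch_size)
    stop("bead clipped by patch; increase patch_size")
  s <- (seq_len(patch_size * n_quad) - 0.5) / n_quad  # sub-pixel midpoints
  d2 <- outer((s - cy)^2, (s - cx)^2, "+")
  dens <- profile_density(model, d2)
  grp <- rep(seq_len(patch_size), each = n_quad)
  patch <- rowsum(dens, grp)
  patch <- t(rowsum(t(patch), grp)) / n_quad^2
  list(patch = round(patch), centre = c(cx, cy))
}

#' Foreground intensity across fractional bead-centre offsets
#'
#' The digitization study: the pixel grid is moved a fraction of a pixel
#' at a time relative to the bead, and the weighted 4x4 foreground is
#' computed at the known bead centre for every offset.  The foreground is
#' taken directly on the digitized image (no sharpening) by default,
#' matching the idealized-bead study; set `sharpen = TRUE` to interpose
#' the sharpening filter.
#'
#' @param model A [bead_model()].
#' @param n_steps Offsets per axis; the grid is `n_steps^2` points on
#'   `[0, 1)^2`.
#' @param options [extraction_options()] controlling weighting and the
#'   sharpening coefficients.
#' @param sharpen Apply [sharpen()] to each digitized patch first.
#' @param n_quad Quadrature resolution passed to [digitize_bead()].
#' @return Data frame with columns `frac_x`, `frac_y`, `foreground`,
#'   `log2_foreground`.
#' @export
offset_profile <- function(model, n_steps = 20L,
                           options = extraction_options(),
                           sharpen = FALSE, n_quad = 32L) {
  if (n_steps < 2L) stop("n_steps must be >= 2")
  offs <- (seq_len(n_steps) - 1L) / n_steps
  out <- expand.grid(frac_x = offs, frac_y = offs)
  fg <- numeric(nrow(out))
  for (k in seq_len(nrow(out))) {
    d <- digitize_bead(model, c(out$frac_x[k], out$frac_y[k]),
                       n_quad = n_quad)
    img <- if (sharpen)
      sharpen(d$patch, options$sharpen_centre, options$sharpen_edge)
    else d$patch
    fg[k] <- compute_foreground(img, d$centre, options)
  }
  out$foreground <- fg
  out$log2_foreground <- log2(fg)
  out
}

#' Range of the log2 foreground over an offset profile
#'
#' @param profile Result of [offset_profile()] (or any data frame with a
#'   `log2_foreground` column, or a bare numeric vector).
#' @return `max - min`, a scalar >= 0.
#' @export
profile_range <- function(profile) {
  v <- if (is.data.frame(profile)) profile$log2_foreground else profile
  if (!length(v)) stop("profile is empty")
  max(v) - min(v)
}
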