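#' Read / write 16-bit grayscale section TIFFs
#'
#' Section images are stored as single-channel 16-bit grayscale TIFF.
#' Pixels round-trip losslessly, including the value 65535.
#'
#' @param path TIFF file path.
#' @return `read_section_tiff()`: an integer-valued matrix (rows = y,
#'   columns = x).
#' @export
read_section_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  img <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(img)) != 2L)
    stop("not a single-channel grayscale TIFF: ", path)
  bps <- attr(img, "bits.per.sample")
  if (!is.null(bps) && bps > 16L)
    stop("more than 16 bits per sample: ", path)
  img
}

#' @rdname read_section_tiff
#' @param image Integer-valued matrix with values in `[0, 65535]`.
#' @export
write_section_tiff <- function(image, path) {
  if (any(image < 0) || any(image > 65535))
    stop("pixel values must lie in [0, 65535]")
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Read / write bead-level text tables
#'
#' The bead-level table lists one row per decoded bead:
#' `bead_type_id` (integer), `x`, `y` (sub-pixel coordinates, written to
#' `precision` decimal places), and the background-corrected `intensity`.
#' The reader tolerates coordinates at 2--4 decimals.
#'
#' @param path TSV file path (header row required).
#' @param precision Decimal places for coordinates on write (2--4).
#' @return `read_beadlevel()`: data frame with the four columns above.
#' @export
read_beadlevel <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty bead-level file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("bead_type_id", "x", "y", "intensity")
  if (!all(need %in% header))
    stop("bead-level header must contain: ", paste(need, collapse = ", "))
  dup <- which(lines == lines[1])
  if (length(dup) > 1L)
    stop("duplicated header at line ", dup[2], " of ", path)
  body <- lines[-1]
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  bad <- which(nf != length(header))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, " of ", path)
  d <- utils::read.delim(text = lines, stringsAsFactors = FALSE)
  d$bead_type_id <- as.integer(d$bead_type_id)
  d[, need]
}

#' @rdname read_beadlevel
#' @param table Data frame with columns `bead_type_id`, `x`, `y`,
#'   `intensity`.
#' @export
write_beadlevel <- function(table, path, precision = 4L) {
  if (precision < 2L || precision > 4L) stop("precision must be 2..4")
  out <- data.frame(bead_type_id = as.integer(table$bead_type_id),
                    x = formatC(table$x, format = "f", digits = precision),
                    y = formatC(table$y, format = "f", digits = precision),
                    intensity = formatC(table$intensity, format = "f",
                                        digits = precision))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

LOCS_MAGIC <- charToRaw("HBLC")

#' Read / write locs-dialect bead-location binaries
#'
#' A plain binary dialect holding the sub-pixel centres of ALL grid
#' positions (decoded and non-decoded) in grid order: a 4-byte magic
#' (`"HBLC"`), a little-endian unsigned 32-bit record count, then
#' little-endian single-precision `(x, y)` pairs.
#'
#' @param path File path.
#' @param expected_count Optional record count to validate against (e.g.
#'   [beads_per_segment()] of the layout).
#' @return `read_locs()`: a numeric matrix with columns `x`, `y`.
#' @export
read_locs <- function(path, expected_count = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, LOCS_MAGIC))
    stop("not a locs file (bad magic): ", path)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  vals <- readBin(con, "numeric", 2L * n, size = 4L, endian = "little")
  if (length(vals) != 2L * n)
    stop(sprintf("truncated locs file %s: expected %d records, read %d",
                 path, n, length(vals) %/% 2L))
  if (!is.null(expected_count) && n != expected_count)
    stop(sprintf("locs record count mismatch: expected %d, found %d",
                 expected_count, n))
  m <- matrix(vals, ncol = 2L, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

#' @rdname read_locs
#' @param coords Two-column matrix (or data frame) of `(x, y)` centres in
#'   grid order.
#' @export
write_locs <- function(coords, path) {
  if (is.data.frame(coords)) coords <- cbind(coords$x, coords$y)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(LOCS_MAGIC, con)
  writeBin(as.integer(nrow(coords)), con, size = 4L, endian = "little")
  writeBin(as.numeric(t(coords)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read / write a chip layout as JSON
#'
#' @param layout A [chip_layout()].
#' @param path JSON file path.
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(unclass(layout), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  chip_layout(d$platform_name, d$n_samples, d$sections_per_sample,
              d$segments_per_section, d$segment_cols, d$segment_rows,
              d$bead_pitch, d$bead_radius)
}
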