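#' Bead mask sets
#'
#' A `mask_set` is the common currency of all artefact diagnostics: a data
#' frame of (bead index, reason) pairs.  Reasons in use across the package
#' are `"near_cluster"`, `"in_cluster"`, `"bright_bead"`,
#' `"bright_neighbour"`, `"low_pixel"`, `"large_departure"`,
#' `"channel_discordant"`, `"out_of_image"` and `"twin"`.  Unions are
#' idempotent: flagging the same bead for the same reason twice records
#' one row.
#'
#' @param bead Integer bead indices.
#' @param reason Character reason, recycled to the length of `bead`.
#' @return A data frame of class `mask_set` with columns `bead`, `reason`.
#' @export
mask_set <- function(bead = integer(), reason = character()) {
  bead <- as.integer(bead)
  reason <- rep(as.character(reason), length.out = length(bead))
  m <- unique(data.frame(bead = bead, reason = as.character(reason),
                         stringsAsFactors = FALSE))
  m <- m[order(m$bead, m$reason), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("mask_set", "data.frame")
  m
}

#' @rdname mask_set
#' @param ... `mask_set` objects to combine.
#' @export
mask_union <- function(...) {
  parts <- list(...)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(mask_set())
  m <- do.call(rbind, lapply(parts, as.data.frame))
  mask_set(m$bead, m$reason)
}

#' @rdname mask_set
#' @param mask A `mask_set`.
#' @param reasons Optional character vector restricting to some reasons.
#' @return `masked_beads()`: sorted unique bead indices carrying any
#'   (matching) flag.
#' @export
masked_beads <- function(mask, reasons = NULL) {
  if (is.null(mask)) return(integer())
  if (!is.null(reasons)) mask <- mask[mask$reason %in% reasons, , drop = FALSE]
  sort(unique(mask$bead))
}

#' Write / read a mask set as TSV
#' @param mask A `mask_set`.
#' @param path File path.
#' @export
write_mask <- function(mask, path) {
  utils::write.table(as.data.frame(mask), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  mask_set(d$bead, d$reason)
}
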