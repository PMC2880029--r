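#' Within bead-type residual log intensities
#'
#' Residual = log2(intensity) minus the median log2 intensity of the
#' bead's type.  Non-decoded beads and beads with non-positive intensity
#' get `NA`.
#'
#' @param beads Data frame with `bead_type_id` and `intensity`.
#' @return Numeric vector of residuals, aligned with `beads`.
#' @export
residual_log_intensity <- function(beads) {
  res <- rep(NA_real_, nrow(beads))
  ok <- beads$bead_type_id >= 0 & beads$intensity > 0 &
    is.finite(beads$intensity)
  lv <- log2(beads$intensity[ok])
  med <- tapply(lv, beads$bead_type_id[ok], stats::median)
  res[ok] <- lv - med[as.character(beads$bead_type_id[ok])]
  res
}

#' Flag outlier replicates within one bead-type
#'
#' Default rule `"mad3"`: values more than 3 scaled MADs (constant
#' 1.4826) from the median are outliers; when the MAD is zero (all
#' replicates tied) any value differing from the median is flagged.
#' Alternative `"sd3"`: mean plus/minus 3 standard deviations.
#' Single-replicate types never have outliers.
#'
#' @param values Numeric log2 intensities of one bead-type.
#' @param rule `"mad3"` or `"sd3"`.
#' @param k Multiplier (default 3).
#' @return Logical vector of outlier flags.
#' @export
flag_outliers <- function(values, rule = c("mad3", "sd3"), k = 3) {
  rule <- match.arg(rule)
  if (length(values) < 2L) return(rep(FALSE, length(values)))
  if (rule == "mad3") {
    med <- stats::median(values)
    s <- stats::mad(values)
    if (s == 0) return(values != med)
    abs(values - med) > k * s
  } else {
    s <- stats::sd(values)
    if (is.na(s) || s == 0) return(rep(FALSE, length(values)))
    abs(values - mean(values)) > k * s
  }
}

#' Two-pass bead-type summarization
#'
#' Pass 1 removes beads carrying mask flags (artefact diagnostics) and
#' beads with non-positive intensity; pass 2 applies the generic outlier
#' rule within each bead-type on the log2 scale; summaries are computed
#' from the survivors.  With an empty mask this reproduces the standard
#' (unadjusted) analysis for comparison.
#'
#' @param beads Data frame with `bead_type_id` and `intensity` (column
#'   `bead` used to match mask indices; defaults to row numbers).
#' @param mask Optional [mask_set()]; reasons in `ignore_reasons` do not
#'   exclude beads (the twin flag is informational by default).
#' @param rule,k Outlier rule passed to [flag_outliers()].
#' @param ignore_reasons Mask reasons that do not exclude (default
#'   `"twin"`).
#' @return A `summary_table` data frame, one row per bead-type:
#'   `bead_type_id`, `n_total`, `n_masked`, `n_outliers`, `n_used`,
#'   `mean_log2`, `median_log2`, `sd_log2` (summaries `NA` when
#'   `n_used` is 0).
#' @export
summarize_beads <- function(beads, mask = NULL, rule = "mad3", k = 3,
                            ignore_reasons = "twin") {
  if (is.null(beads$bead)) beads$bead <- seq_len(nrow(beads))
  d <- beads[beads$bead_type_id >= 0, , drop = FALSE]
  excl <- masked_beads(mask, setdiff(unique(mask$reason), ignore_reasons))
  d$masked <- d$bead %in% excl
  nonpos <- !d$masked & !(d$intensity > 0 & is.finite(d$intensity))
  d$masked <- d$masked | nonpos
  types <- sort(unique(d$bead_type_id))
  rows <- lapply(types, function(t) {
    g <- d[d$bead_type_id == t, ]
    lv <- log2(g$intensity[!g$masked])
    out <- flag_outliers(lv, rule = rule, k = k)
    used <- lv[!out]
    data.frame(bead_type_id = t, n_total = nrow(g),
               n_masked = sum(g$masked), n_outliers = sum(out),
               n_used = length(used),
               mean_log2 = if (length(used)) mean(used) else NA_real_,
               median_log2 = if (length(used)) stats::median(used)
                             else NA_real_,
               sd_log2 = if (length(used) > 1) stats::sd(used) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  class(tab) <- c("summary_table", "data.frame")
  tab
}

#' Detection calls against negative controls
#'
#' The detection score of a bead-type is the empirical fraction of
#' negative-control summarized intensities that exceed the type's
#' summarized intensity; the type is called expressed when the score
#' falls below `alpha`.
#'
#' @param summary A [summarize_beads()] table.
#' @param neg_log2 Numeric vector of negative-control summarized log2
#'   intensities (>= 20 values required).
#' @param alpha Score threshold (default 0.05).
#' @return `summary` with columns `detection_score` and `expressed`
#'   added.
#' @export
detection_call <- function(summary, neg_log2, alpha = 0.05) {
  neg_log2 <- neg_log2[is.finite(neg_log2)]
  if (length(neg_log2) < 20L)
    stop("need >= 20 negative-control values, got ", length(neg_log2))
  summary$detection_score <- vapply(summary$mean_log2, function(m)
    if (is.na(m)) NA_real_ else mean(neg_log2 >= m), numeric(1))
  summary$expressed <- summary$detection_score < alpha
  summary
}
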