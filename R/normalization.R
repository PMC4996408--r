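#' Median-centered, bounded log2 normalization
#'
#' Converts a pooled cohort of Ct values to log2 fold change relative to the
#' per-gene median of the pooled sample. One PCR cycle is one doubling, so
#' the fold change of an expressing reaction is simply
#' `gene_median - Ct` log2 units (lower Ct means more template, hence a
#' positive value). Values are clipped to `[-clip_bound, +clip_bound]`
#' (default +/-5, i.e. 32-fold either way), and non-expressers are assigned
#' the floor `-clip_bound`: a reaction that never amplified is treated as
#' expression at or below the limit of detection.
#'
#' Per-gene medians are computed over expressing reactions only, pooled
#' across every chip and passage; a non-amplified reaction has no Ct to
#' contribute. Even-count medians are the midpoint of the two central
#' values.
#'
#' @param m A `CtMatrix`.
#' @param clip_bound Positive clip bound in log2 units (default 5).
#' @return A `NormalizedMatrix`: list with `values` (cells x genes matrix in
#'   `[-clip_bound, clip_bound]`), `expresser` (logical mask), `gene_medians`
#'   (per-gene pooled expresser median Ct), `n_expressers` (per-gene
#'   expresser count), `clip_bound`, `cells`, `genes`.
#' @export
normalize_to_median <- function(m, clip_bound = 5) {
  stopifnot(inherits(m, "CtMatrix"))
  .assert_scalar_number(clip_bound, "clip_bound")
  if (clip_bound <= 0) {
    stop("`clip_bound` must be positive, got ", clip_bound, call. = FALSE)
  }
  mask <- expression_mask(m)
  n_expr <- colSums(mask)
  if (any(n_expr == 0L)) {
    stop("gene(s) with zero expressing reactions (median undefined): ",
         paste(m$genes[n_expr == 0L], collapse = ", "), call. = FALSE)
  }
  ct <- m$ct
  ct[!mask] <- NA_real_
  med <- apply(ct, 2L, stats::median, na.rm = TRUE)
  values <- sweep(-ct, 2L, med, "+")           # med - ct, expressers only
  values <- pmin(pmax(values, -clip_bound), clip_bound)
  values[!mask] <- -clip_bound
  dimnames(values) <- dimnames(m$ct)
  structure(
    list(values = values, expresser = mask,
         gene_medians = stats::setNames(med, m$genes),
         n_expressers = stats::setNames(as.integer(n_expr), m$genes),
         clip_bound = clip_bound,
         cells = m$cells, genes = m$genes),
    class = "NormalizedMatrix"
  )
}

#' Linear fold change from a normalized value
#'
#' Maps a bounded log2 fold-change value back to the linear scale:
#' `2^value`. The clip bounds +/-5 correspond to 32-fold above and below
#' the gene median.
#'
#' @param value Numeric vector of normalized log2 values.
#' @param clip_bound The bound the values were clipped to (default 5).
#' @return `2^value`, unitless linear fold change.
#' @export
fold_change <- function(value, clip_bound = 5) {
  if (!is.numeric(value) || anyNA(value)) {
    stop("`value` must be numeric without NA", call. = FALSE)
  }
  if (any(value < -clip_bound - 1e-12) || any(value > clip_bound + 1e-12)) {
    stop("normalized value(s) outside [-", clip_bound, ", ", clip_bound,
         "]: ", paste(value[value < -clip_bound | value > clip_bound],
                      collapse = ", "), call. = FALSE)
  }
  2^value
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf(
    "NormalizedMatrix: %d cells x %d genes, clip bound +/-%g (%g-fold)\n",
    nrow(x$values), length(x$genes), x$clip_bound, 2^x$clip_bound))
  cat(sprintf("  non-expresser positions at floor: %d (%.1f%%)\n",
              sum(!x$expresser), 100 * mean(!x$expresser)))
  invisible(x)
}
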