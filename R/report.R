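#' Round half away from zero (display rounding)
#'
#' Published tables round 0.5 up; R's `round()` rounds half to even. Use
#' this only at the display layer — computations keep full precision.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' All-sites summary of cluster context records
#'
#' Unweighted column means over clusters, each computed only over clusters
#' with a non-missing value; the number of contributing clusters is
#' reported per column (stepped-wedge context tables routinely have
#' site-specific gaps, e.g. home-delivery counts recorded in only some
#' clusters).
#'
#' @param records data.frame with `cluster_id` plus numeric context columns
#'   (e.g. monthly delivery means, caesarean percentage, staffing rates).
#' @return data.frame: `column`, `n_clusters` (contributing), `mean`.
#' @export
summarize_context <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  num_cols <- names(records)[vapply(records, is.numeric, logical(1))]
  num_cols <- setdiff(num_cols, "cluster_id")
  if (!length(num_cols)) stop("no numeric context columns", call. = FALSE)
  data.frame(
    column = num_cols,
    n_clusters = vapply(num_cols, function(cl) sum(!is.na(records[[cl]])),
                        integer(1)),
    mean = vapply(num_cols, function(cl) mean(records[[cl]], na.rm = TRUE),
                  numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Staff-training coverage table
#'
#' Per-site percentage trained (where the workforce total is known), the
#' total number trained across sites, and the overall percentage computed
#' over sites with known totals only.
#'
#' @param trained per-site counts of staff trained (>= 0).
#' @param totals per-site workforce totals (NA where unknown); `trained <=
#'   totals` where known.
#' @param site optional site labels.
#' @return list with `per_site` (data.frame `site`, `trained`, `total`,
#'   `pct`), `total_trained`, `overall_pct` (NA when no totals known).
#' @export
summarize_training <- function(trained, totals = NULL, site = NULL) {
  stopifnot(is.numeric(trained), all(trained >= 0))
  n <- length(trained)
  totals <- totals %||% rep(NA_real_, n)
  stopifnot(length(totals) == n)
  known <- !is.na(totals)
  if (any(trained[known] > totals[known]))
    stop("trained count exceeds workforce total", call. = FALSE)
  site <- site %||% sprintf("site%02d", seq_len(n))
  pct <- ifelse(known, 100 * trained / totals, NA_real_)
  total_trained <- sum(trained)
  overall <- if (any(known) && sum(totals[known]) > 0)
    100 * sum(trained[known]) / sum(totals[known]) else NA_real_
  list(per_site = data.frame(site = site, trained = trained, total = totals,
                             pct = pct, stringsAsFactors = FALSE),
       total_trained = total_trained,
       overall_pct = overall)
}
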