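#' Rank clusters on one implementation measure
#'
#' Rank 1 is the best-performing cluster according to the measure's declared
#' direction of benefit; ties share the mean of their rank positions;
#' missing values are excluded (rank NA) and do not affect the others'
#' ranks.
#'
#' @param values per-cluster measure values.
#' @param direction `"higher_is_better"` or `"lower_is_better"`.
#' @return numeric vector of ranks (NA where `values` is NA).
#' @examples
#' rank_clusters(c(10, 30, 20))          # 3 1 2
#' rank_clusters(c(5, 5, 1))             # 1.5 1.5 3
#' @export
rank_clusters <- function(values,
                          direction = c("higher_is_better",
                                        "lower_is_better")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(values))
  if (sum(!is.na(values)) < 2L)
    stop("need at least 2 non-missing values to rank", call. = FALSE)
  keyed <- if (direction == "higher_is_better") -values else values
  rank(keyed, ties.method = "average", na.last = "keep")
}

#' Rescale ranks to implementation scores in [0, 1]
#'
#' Linear map `(n - rank) / (n - 1)`: the best rank scores 1, the worst 0,
#' tied clusters share a score.
#'
#' @param ranks ranks from [rank_clusters()] (NA allowed, preserved).
#' @param n number of ranked clusters; defaults to the number of
#'   non-missing ranks.
#' @return scores in \[0, 1\].
#' @examples
#' rescale_ranks(c(1, 2, 3))        # 1.0 0.5 0.0
#' @export
rescale_ranks <- function(ranks, n = sum(!is.na(ranks))) {
  stopifnot(is.numeric(ranks))
  if (n < 2L) stop("need at least 2 clusters to rescale", call. = FALSE)
  (n - ranks) / (n - 1)
}

check_measures <- function(measures) {
  req <- c("cluster_id", "measure_name", "domain", "direction", "value")
  miss <- setdiff(req, names(measures))
  if (length(miss))
    stop("measures table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(measures[, c("cluster_id", "measure_name")]))
    stop("duplicate (cluster, measure) rows", call. = FALSE)
  ok_dir <- measures$direction %in% c("higher_is_better", "lower_is_better")
  if (!all(ok_dir))
    stop("direction must be higher_is_better or lower_is_better",
         call. = FALSE)
  invisible(measures)
}

# per-measure rank-rescaled scores, long format
measure_scores <- function(measures) {
  check_measures(measures)
  out <- lapply(split(measures, measures$measure_name), function(m) {
    if (all(is.na(m$value)))
      stop("measure '", m$measure_name[1], "' has no observed values",
           call. = FALSE)
    r <- rank_clusters(m$value, m$direction[1])
    m$score <- rescale_ranks(r)
    m
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-cluster domain scores
#'
#' Ranks every measure across clusters, rescales ranks to \[0, 1\] and
#' averages (unweighted) within each of the fidelity / reach / adoption
#' domains. A cluster missing a measure contributes its remaining measures
#' to that domain; a cluster missing every measure of a domain gets NA
#' there.
#'
#' @param measures long data.frame: `cluster_id`, `measure_name`, `domain`,
#'   `direction`, `value` (NA = unavailable).
#' @return data.frame, one row per cluster, one column per domain plus
#'   `cluster_id`.
#' @export
domain_scores <- function(measures) {
  scored <- measure_scores(measures)
  clusters <- unique(measures$cluster_id)
  domains <- unique(measures$domain)
  out <- data.frame(cluster_id = clusters, stringsAsFactors = FALSE)
  for (d in domains) {
    s <- scored[scored$domain == d, ]
    mean_or_na <- function(id) {
      v <- s$score[s$cluster_id == id & !is.na(s$score)]
      if (length(v)) mean(v) else NA_real_
    }
    out[[paste0(d, "_score")]] <- vapply(clusters, mean_or_na, numeric(1))
  }
  out
}

#' Composite implementation-strength score table
#'
#' Averages each cluster's available domain scores into a single composite
#' in \[0, 1\] and records how many domains contributed. Clusters with no
#' available domain are an error.
#'
#' @inheritParams domain_scores
#' @return data.frame of class `score_table`: `cluster_id`, one
#'   `<domain>_score` column per domain, `composite`, `n_domains_used`.
#' @examples
#' m <- data.frame(
#'   cluster_id = rep(c("A", "B", "C"), 2),
#'   measure_name = rep(c("m1", "m2"), each = 3),
#'   domain = rep(c("fidelity", "reach"), each = 3),
#'   direction = "higher_is_better",
#'   value = c(10, 20, 30, 3, 2, 1))
#' composite_scores(m)
#' @export
composite_scores <- function(measures) {
  ds <- domain_scores(measures)
  score_cols <- setdiff(names(ds), "cluster_id")
  mat <- as.matrix(ds[, score_cols, drop = FALSE])
  n_used <- rowSums(!is.na(mat))
  if (any(n_used == 0))
    stop("cluster(s) with no available domain: ",
         paste(ds$cluster_id[n_used == 0], collapse = ", "), call. = FALSE)
  ds$composite <- rowMeans(mat, na.rm = TRUE)
  ds$n_domains_used <- as.integer(n_used)
  class(ds) <- c("score_table", "data.frame")
  ds
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks; exactly +/-1 for strictly
#' monotone pairs. Pairs with a missing value in either vector are dropped.
#'
#' @param x,y paired per-cluster values; at least 3 complete pairs.
#' @return correlation in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L)
    stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop("rank correlation undefined for a constant vector", call. = FALSE)
  stats::cor(x[ok], y[ok], method = "spearman")
}

#' Pairwise rank correlations between measures within each domain
#'
#' @param measures long measures table (see [domain_scores()]).
#' @return data.frame: `domain`, `measure_a`, `measure_b`, `rho`,
#'   `n_pairs`; empty when no domain holds two measures.
#' @export
measure_correlations <- function(measures) {
  check_measures(measures)
  res <- list()
  for (d in unique(measures$domain)) {
    md <- measures[measures$domain == d, ]
    ms <- unique(md$measure_name)
    if (length(ms) < 2L) next
    wide <- stats::reshape(md[, c("cluster_id", "measure_name", "value")],
                           idvar = "cluster_id", timevar = "measure_name",
                           direction = "wide")
    for (i in seq_len(length(ms) - 1L)) for (j in (i + 1L):length(ms)) {
      a <- wide[[paste0("value.", ms[i])]]
      b <- wide[[paste0("value.", ms[j])]]
      ok <- !is.na(a) & !is.na(b)
      res[[length(res) + 1L]] <- data.frame(
        domain = d, measure_a = ms[i], measure_b = ms[j],
        rho = if (sum(ok) >= 3L) spearman(a, b) else NA_real_,
        n_pairs = sum(ok), stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(domain = character(), measure_a = character(),
                      measure_b = character(), rho = numeric(),
                      n_pairs = integer(), stringsAsFactors = FALSE))
  do.call(rbind, res)
}
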