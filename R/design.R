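#' Generate a stepped-wedge design
#'
#' Allocates clusters to crossover steps by a seeded uniform random
#' permutation. All clusters start in the control condition; the clusters
#' assigned to step \eqn{s} cross over to intervention at calendar period
#' \eqn{s \times \mathrm{periods\_per\_step}} (0-based) and stay treated for
#' the remainder of the trial. The trial runs for
#' \eqn{(n\_steps + 1) \times periods\_per\_step} periods, so the first step
#' has one full step-length of control observation and the last step one full
#' step-length of intervention observation (nine steps at two-monthly
#' intervals give a 20-month trial).
#'
#' When `n_clusters` is not a multiple of `n_steps` the remainder clusters
#' are spread round-robin over the earliest steps, so no step is ever more
#' than one cluster larger than another.
#'
#' @param n_clusters number of clusters (>= `n_steps`).
#' @param n_steps number of crossover steps (>= 2).
#' @param periods_per_step calendar periods between consecutive steps.
#' @param seed optional integer seed for the allocation permutation.
#'
#' @return An object of class `sw_design`: a list with `n_clusters`,
#'   `n_steps`, `periods_per_step`, `n_periods`, `cluster_id`, `step`
#'   (assigned step per cluster) and `crossover_period` (0-based first
#'   treated period per cluster).
#'
#' @examples
#' d <- generate_design(10, 9, periods_per_step = 2, seed = 1)
#' d$n_periods   # 20
#' table(d$step) # one step holds two clusters
#' @export
generate_design <- function(n_clusters, n_steps, periods_per_step = 2,
                            seed = NULL) {
  stopifnot(length(n_clusters) == 1L, length(n_steps) == 1L,
            length(periods_per_step) == 1L)
  n_clusters <- as.integer(n_clusters)
  n_steps <- as.integer(n_steps)
  periods_per_step <- as.integer(periods_per_step)
  if (is.na(n_steps) || n_steps < 2L)
    stop("need at least 2 steps", call. = FALSE)
  if (is.na(n_clusters) || n_clusters < n_steps)
    stop("need at least as many clusters as steps (n_clusters >= n_steps)",
         call. = FALSE)
  if (is.na(periods_per_step) || periods_per_step < 1L)
    stop("periods_per_step must be a positive integer", call. = FALSE)

  if (!is.null(seed)) set.seed(seed)
  # balanced step vector, remainder round-robin over earliest steps,
  # then permuted uniformly across clusters
  step <- rep(seq_len(n_steps), length.out = n_clusters)[sample.int(n_clusters)]

  structure(list(
    n_clusters = n_clusters,
    n_steps = n_steps,
    periods_per_step = periods_per_step,
    n_periods = (n_steps + 1L) * periods_per_step,
    cluster_id = sprintf("C%02d", seq_len(n_clusters)),
    step = step,
    crossover_period = step * periods_per_step
  ), class = "sw_design")
}

#' Treatment indicator matrix of a stepped-wedge design
#'
#' @param design an `sw_design`.
#' @return Integer matrix (clusters x periods), 1 where the cluster-period is
#'   under intervention. Rows named by cluster, columns by 0-based period.
#' @export
treatment_matrix <- function(design) {
  stopifnot(inherits(design, "sw_design"))
  periods <- seq_len(design$n_periods) - 1L
  m <- outer(design$crossover_period, periods, FUN = "<=") * 1L
  dimnames(m) <- list(design$cluster_id, periods)
  m
}

#' Expand a design to a long cluster-period lattice
#'
#' @param design an `sw_design`.
#' @return data.frame with `cluster_id`, `period` (0-based) and `treated`.
#' @export
design_lattice <- function(design) {
  stopifnot(inherits(design, "sw_design"))
  periods <- seq_len(design$n_periods) - 1L
  df <- expand.grid(period = periods, cluster_id = design$cluster_id,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cross <- design$crossover_period[match(df$cluster_id, design$cluster_id)]
  df$treated <- as.integer(df$period >= cross)
  df[, c("cluster_id", "period", "treated")]
}

#' @export
print.sw_design <- function(x, ...) {
  cat(sprintf(
    "Stepped-wedge design: %d clusters, %d steps of %d period(s), %d periods total\n",
    x$n_clusters, x$n_steps, x$periods_per_step, x$n_periods))
  cat("Crossover period by cluster (0-based):\n")
  print(stats::setNames(x$crossover_period, x$cluster_id))
  invisible(x)
}
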