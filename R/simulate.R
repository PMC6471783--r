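#' Simulation parameters for a synthetic stepped-wedge trial
#'
#' Bundles and validates the generator's parameters. Defaults emulate a
#' ten-site maternity trial whose primary outcome is a rare composite event
#' counted per delivery: roughly 2600 deliveries per cluster-month, a
#' baseline event probability of 7 per 10,000 deliveries, moderate
#' between-centre variation in baseline odds and weak centre-specific
#' secular trends.
#'
#' @param baseline_event_rate baseline event probability per delivery, in
#'   (0,1). Default 7e-4 (7 per 10,000 deliveries).
#' @param treatment_log_or intervention effect on the log-odds scale; a
#'   scalar (common effect) or one value per cluster.
#' @param centre_effect_sd SD of cluster deviations from the baseline
#'   log-odds (used when `centre_effects` is NULL).
#' @param centre_effects optional per-cluster log-odds deviations.
#' @param centre_trend_sd SD of cluster-specific linear trends in log-odds
#'   per period (used when `centre_trends` is NULL).
#' @param centre_trends optional per-cluster linear trends.
#' @param deliveries_mean mean deliveries per cluster-period; a scalar or
#'   one value per cluster. Cell counts are Poisson around the cluster mean.
#' @param deliveries_cluster_cv between-cluster coefficient of variation of
#'   the mean delivery volume (log-normal, used when `deliveries_mean` is a
#'   scalar).
#' @param implementation_coupling slope linking a cluster's implementation
#'   strength to the magnitude of its intervention benefit (see
#'   [simulate_implementation()]).
#' @param implementation_noise_sd measurement noise SD (logit scale) of the
#'   simulated implementation measures.
#'
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(baseline_event_rate = 7e-4,
                       treatment_log_or = 0,
                       centre_effect_sd = 0.3,
                       centre_effects = NULL,
                       centre_trend_sd = 0.005,
                       centre_trends = NULL,
                       deliveries_mean = 2600,
                       deliveries_cluster_cv = 0.5,
                       implementation_coupling = 0,
                       implementation_noise_sd = 0.5) {
  if (!is.numeric(baseline_event_rate) || length(baseline_event_rate) != 1L ||
      baseline_event_rate <= 0 || baseline_event_rate >= 1)
    stop("baseline_event_rate must be a single value in (0, 1)", call. = FALSE)
  num_finite <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_finite(treatment_log_or))
    stop("treatment_log_or must be finite", call. = FALSE)
  if (!is.null(centre_effects) && !num_finite(centre_effects))
    stop("centre_effects must be finite", call. = FALSE)
  if (!is.null(centre_trends) && !num_finite(centre_trends))
    stop("centre_trends must be finite", call. = FALSE)
  if (!num_finite(deliveries_mean) || any(deliveries_mean < 1))
    stop("deliveries_mean must be >= 1", call. = FALSE)
  if (!num_finite(implementation_coupling))
    stop("implementation_coupling must be finite", call. = FALSE)
  if (!num_finite(implementation_noise_sd) || implementation_noise_sd < 0)
    stop("implementation_noise_sd must be >= 0", call. = FALSE)
  stopifnot(centre_effect_sd >= 0, centre_trend_sd >= 0,
            deliveries_cluster_cv >= 0)
  structure(list(
    baseline_event_rate = baseline_event_rate,
    treatment_log_or = treatment_log_or,
    centre_effect_sd = centre_effect_sd,
    centre_effects = centre_effects,
    centre_trend_sd = centre_trend_sd,
    centre_trends = centre_trends,
    deliveries_mean = deliveries_mean,
    deliveries_cluster_cv = deliveries_cluster_cv,
    implementation_coupling = implementation_coupling,
    implementation_noise_sd = implementation_noise_sd
  ), class = "sim_params")
}

# One integer master seed fans out to independent sub-streams by drawing
# sub-seeds from a seeded integer stream; each stage then re-seeds with its
# own sub-seed. Keeps stage outputs invariant to changes in other stages.
split_seed <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(as.integer(seed))
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

expand_by_cluster <- function(x, n) {
  if (length(x) == 1L) rep(x, n)
  else if (length(x) == n) x
  else stop("per-cluster parameter must have length 1 or n_clusters",
            call. = FALSE)
}

#' Simulate cluster-period event counts for a stepped-wedge trial
#'
#' Generates the binomial cluster-period lattice the analysis modules
#' consume: deliveries are Poisson around a per-cluster mean volume and
#' events are Binomial with
#' \deqn{\mathrm{logit}(p_{it}) = \mathrm{logit}(\pi_0) + u_i + \gamma_i t +
#'       \beta \, \mathrm{treated}_{it},}
#' where \eqn{u_i} is the centre effect, \eqn{\gamma_i} the centre-specific
#' linear period trend and \eqn{\beta} the intervention log odds ratio
#' (optionally cluster-specific).
#'
#' @param design an [generate_design()] object.
#' @param params a [sim_params()] object.
#' @param seed integer seed; the same seed reproduces the table exactly.
#'
#' @return data.frame with columns `cluster_id`, `period` (0-based),
#'   `treated`, `deliveries`, `events` and an attribute `"truth"` holding the
#'   realised per-cluster parameters (for recovery experiments). Cells with
#'   zero deliveries carry zero events and are non-informative.
#' @export
simulate_trial <- function(design, params = sim_params(), seed = NULL) {
  stopifnot(inherits(design, "sw_design"))
  if (!inherits(params, "sim_params")) stop("params must be sim_params()",
                                            call. = FALSE)
  n <- design$n_clusters
  seeds <- split_seed(seed, 3L)

  # cluster-level realisations
  if (!is.null(seeds[[1]])) set.seed(seeds[[1]])
  centre_effects <- params$centre_effects %||%
    stats::rnorm(n, 0, params$centre_effect_sd)
  centre_effects <- expand_by_cluster(centre_effects, n)
  centre_trends <- params$centre_trends %||%
    stats::rnorm(n, 0, params$centre_trend_sd)
  centre_trends <- expand_by_cluster(centre_trends, n)
  log_or <- expand_by_cluster(params$treatment_log_or, n)
  mu_del <- params$deliveries_mean
  if (length(mu_del) == 1L && params$deliveries_cluster_cv > 0) {
    sdlog <- sqrt(log(1 + params$deliveries_cluster_cv^2))
    mu_del <- stats::rlnorm(n, log(mu_del) - sdlog^2 / 2, sdlog)
    mu_del <- pmax(mu_del, 1)
  }
  mu_del <- expand_by_cluster(mu_del, n)

  cells <- design_lattice(design)
  i <- match(cells$cluster_id, design$cluster_id)

  if (!is.null(seeds[[2]])) set.seed(seeds[[2]])
  cells$deliveries <- stats::rpois(nrow(cells), mu_del[i])

  eta <- stats::qlogis(params$baseline_event_rate) +
    centre_effects[i] + centre_trends[i] * cells$period +
    log_or[i] * cells$treated
  p <- stats::plogis(eta)

  if (!is.null(seeds[[3]])) set.seed(seeds[[3]])
  cells$events <- stats::rbinom(nrow(cells), cells$deliveries, p)

  attr(cells, "truth") <- list(
    centre_effects = centre_effects, centre_trends = centre_trends,
    treatment_log_or = log_or, deliveries_mean = mu_del,
    cell_prob = p)
  cells
}

# catalogue of emulated quantitative process measures
IMPL_MEASURES <- data.frame(
  measure_name = c("staff_trained_pct", "training_content_pct",
                   "bp_measurement_post_pct", "equipment_availability_pct",
                   "adoption_6m_pct"),
  domain = c("fidelity", "fidelity", "reach", "reach", "adoption"),
  direction = "higher_is_better",
  base_logit = stats::qlogis(c(0.61, 0.90, 0.85, 0.95, 0.73)),
  stringsAsFactors = FALSE
)

#' Simulate per-cluster implementation measures
#'
#' Emulates the quantitative process measures a hybrid trial records per
#' cluster: staff-training coverage and content delivery (fidelity),
#' post-intervention blood-pressure-measurement coverage and equipment
#' availability (reach), and device adoption at six months (adoption). Each
#' measure is a proportion generated on the logit scale as
#' `base + coupling * benefit + noise`, where `benefit` is the cluster's
#' intervention benefit `-treatment_log_or` (so positive coupling makes
#' better-implemented clusters those with stronger protective effects) and
#' `noise` is independent N(0, `noise_sd`) per cluster-measure. With
#' `coupling = 0` the measures are independent of the true effects.
#'
#' By default the adoption measure is right-censored for clusters in the two
#' latest steps, mirroring how a stepped-wedge schedule leaves too little
#' post-crossover time to assess adoption in late-crossing sites.
#'
#' @param design an [generate_design()] object.
#' @param true_log_or per-cluster (or scalar) true treatment log odds ratio.
#' @param coupling slope linking implementation strength to benefit.
#' @param noise_sd measure noise SD on the logit scale (>= 0).
#' @param seed integer seed.
#' @param censor_adoption logical; censor adoption for late-crossing steps.
#'
#' @return data.frame with `cluster_id`, `measure_name`, `domain`,
#'   `direction`, `value` (proportion in \[0,1\], NA when unavailable) and
#'   `available`.
#' @export
simulate_implementation <- function(design, true_log_or = 0, coupling = 0,
                                    noise_sd = 0.1, seed = NULL,
                                    censor_adoption = TRUE) {
  stopifnot(inherits(design, "sw_design"))
  if (!is.numeric(coupling) || !all(is.finite(coupling)))
    stop("coupling must be finite", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0", call. = FALSE)
  n <- design$n_clusters
  benefit <- -expand_by_cluster(true_log_or, n)
  if (!is.null(seed)) set.seed(seed)

  m <- IMPL_MEASURES[rep(seq_len(nrow(IMPL_MEASURES)), each = n), ]
  out <- data.frame(
    cluster_id = rep(design$cluster_id, times = nrow(IMPL_MEASURES)),
    measure_name = m$measure_name,
    domain = m$domain,
    direction = m$direction,
    stringsAsFactors = FALSE
  )
  latent <- coupling * benefit[match(out$cluster_id, design$cluster_id)]
  out$value <- stats::plogis(m$base_logit + latent +
                               stats::rnorm(nrow(out), 0, noise_sd))

  out$available <- TRUE
  if (censor_adoption) {
    late <- design$cluster_id[design$step > design$n_steps - 2L]
    cens <- out$measure_name == "adoption_6m_pct" & out$cluster_id %in% late
    out$value[cens] <- NA_real_
    out$available[cens] <- FALSE
  }
  rownames(out) <- NULL
  out
}

#' Validate a cluster-period table
#'
#' Checks the structural invariants of the stepped-wedge lattice:
#' non-negative counts, `events <= deliveries`, and within each cluster a
#' treatment indicator that never switches back to control.
#'
#' @param cells data.frame with `cluster_id`, `period`, `treated`,
#'   `deliveries`, `events`.
#' @return `cells`, invisibly; errors describe the first violated invariant.
#' @export
validate_cluster_periods <- function(cells) {
  req <- c("cluster_id", "period", "treated", "deliveries", "events")
  miss <- setdiff(req, names(cells))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(cells$deliveries < 0) || any(cells$events < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(cells$events > cells$deliveries))
    stop("events exceed deliveries in some cells", call. = FALSE)
  if (!all(cells$treated %in% c(0, 1)))
    stop("treated must be 0/1", call. = FALSE)
  for (id in unique(cells$cluster_id)) {
    g <- cells[cells$cluster_id == id, ]
    g <- g[order(g$period), ]
    if (is.unsorted(g$treated))
      stop("treatment reverts to control within cluster ", id, call. = FALSE)
  }
  invisible(cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
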