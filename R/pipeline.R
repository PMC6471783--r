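# Allowed configuration schema: top-level keys and their subkeys. Unknown
# keys are rejected by name so typos never silently fall back to defaults.
CONFIG_SCHEMA <- list(
  seed = NULL,
  design = c("n_clusters", "n_steps", "periods_per_step"),
  sim = c("baseline_event_rate", "treatment_log_or", "centre_effect_sd",
          "centre_effects", "centre_trend_sd", "centre_trends",
          "deliveries_mean", "deliveries_cluster_cv"),
  implementation = c("coupling", "noise_sd", "censor_adoption"),
  meta = c("knapp_hartung"),
  inputs = c("cluster_periods", "measures", "process_counts", "context")
)

#' Read and validate a pipeline configuration
#'
#' @param config path to a YAML or JSON file, or a named list.
#' @return validated config list.
#' @export
read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(CONFIG_SCHEMA))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (key in intersect(names(config), names(CONFIG_SCHEMA))) {
    allowed <- CONFIG_SCHEMA[[key]]
    if (is.null(allowed)) next
    bad <- setdiff(names(config[[key]]), allowed)
    if (length(bad))
      stop("unknown config key(s) under '", key, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  config
}

read_table_checked <- function(path, required, what) {
  if (!file.exists(path))
    stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " (", path, ") missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

write_output <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# pre/post effect table from a long process-counts table
process_effects <- function(counts) {
  need <- c("cluster_id", "stage", "metric", "numerator", "denominator")
  stopifnot(all(need %in% names(counts)))
  if (!all(counts$stage %in% c("pre", "post")))
    stop("stage must be 'pre' or 'post'", call. = FALSE)
  rows <- list()
  for (metric in unique(counts$metric)) {
    for (id in unique(counts$cluster_id[counts$metric == metric])) {
      sub <- counts[counts$metric == metric & counts$cluster_id == id, ]
      pre <- sub[sub$stage == "pre", ]
      post <- sub[sub$stage == "post", ]
      if (nrow(pre) != 1L || nrow(post) != 1L) next
      lab <- paste(id, metric, sep = ":")
      or <- odds_ratio(post$numerator, post$denominator - post$numerator,
                       pre$numerator, pre$denominator - pre$numerator,
                       label = lab)
      pr <- proportion_ratio(
        proportion(post$numerator, post$denominator),
        proportion(pre$numerator, pre$denominator),
        x_post = post$numerator, n_post = post$denominator,
        x_pre = pre$numerator, n_pre = pre$denominator, label = lab)
      rows[[length(rows) + 1L]] <- do.call(rbind, lapply(
        list(or, pr), function(e) data.frame(
          label = e$label, kind = e$kind, estimate = e$estimate,
          ci_low = e$ci_low, ci_high = e$ci_high,
          log_effect = e$log_effect, se = e$se,
          stringsAsFactors = FALSE)))
    }
  }
  if (!length(rows)) stop("no complete pre/post pairs", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full process-evaluation pipeline
#'
#' Executes simulate/ingest -> process effects -> implementation scoring ->
#' stepped-wedge fit -> per-site effects -> meta-analysis/meta-regression
#' -> context summary, writing every stage's table to `out_dir` together
#' with a JSON manifest (seed, configuration, package version, MD5 hash of
#' every output). Identical config + seed reproduces every output
#' byte-for-byte; on failure, partially written outputs are removed.
#'
#' @param config path to YAML/JSON config or list (see [read_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  config <- read_config(config)
  seed <- seed %||% config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_output(df, path)
    written <<- c(written, path)
    path
  }

  run <- function() {
    seeds <- split_seed(seed, 2L)
    inputs <- config$inputs %||% list()

    # --- cluster-period cells: ingest or simulate
    if (!is.null(inputs$cluster_periods)) {
      cells <- read_table_checked(
        inputs$cluster_periods,
        c("cluster_id", "period", "treated", "deliveries", "events"),
        "cluster_periods")
      validate_cluster_periods(cells)
      design <- NULL
    } else {
      dcfg <- config$design %||% list()
      design <- generate_design(dcfg$n_clusters %||% 10L,
                                dcfg$n_steps %||% 9L,
                                dcfg$periods_per_step %||% 2L,
                                seed = seeds[[1]])
      params <- do.call(sim_params, config$sim %||% list())
      cells <- simulate_trial(design, params, seed = seeds[[1]])
    }
    emit(cells[, c("cluster_id", "period", "treated", "deliveries",
                   "events")], "cluster_periods.csv")

    # --- implementation measures: ingest or simulate
    if (!is.null(inputs$measures)) {
      measures <- read_table_checked(
        inputs$measures,
        c("cluster_id", "measure_name", "domain", "direction", "value"),
        "implementation measures")
    } else {
      if (is.null(design))
        stop("simulating measures requires a simulated design ",
             "(or supply inputs$measures)", call. = FALSE)
      icfg <- config$implementation %||% list()
      truth <- attr(cells, "truth")
      measures <- simulate_implementation(
        design,
        true_log_or = truth$treatment_log_or,
        coupling = icfg$coupling %||% 0,
        noise_sd = icfg$noise_sd %||% 0.5,
        seed = seeds[[2]],
        censor_adoption = icfg$censor_adoption %||% TRUE)
    }
    emit(measures[measures$available %||% TRUE,
                  c("cluster_id", "measure_name", "domain", "direction",
                    "value")], "implementation_measures.csv")

    # --- scoring
    scores <- composite_scores(measures)
    emit(as.data.frame(scores), "scores.csv")

    # --- pre/post process effects (only when counts supplied)
    if (!is.null(inputs$process_counts)) {
      counts <- read_table_checked(
        inputs$process_counts,
        c("cluster_id", "stage", "metric", "numerator", "denominator"),
        "process counts")
      emit(process_effects(counts), "effects.csv")
    }

    # --- stepped-wedge fit (all sites) + per-site effects
    fit <- fit_logistic(cells)
    rob <- cluster_robust_cov(fit)
    se_m <- sqrt(diag(fit$vcov_model))
    se_r <- sqrt(diag(rob))
    z <- stats::qnorm(0.975)
    emit(data.frame(term = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    se_model = unname(se_m), se_robust = unname(se_r),
                    ci_low = unname(fit$coefficients - z * se_r),
                    ci_high = unname(fit$coefficients + z * se_r),
                    stringsAsFactors = FALSE), "fit.csv")
    eff <- site_effects(cells)
    emit(eff, "site_effects.csv")

    # --- meta-analysis and meta-regression on the composite score
    kh <- (config$meta %||% list())$knapp_hartung %||% FALSE
    pooled <- dl_pool(eff$log_effect, eff$se, labels = eff$site_id,
                      knapp_hartung = kh)
    mr <- meta_regression(
      eff$log_effect, eff$se,
      scores$composite[match(eff$site_id, scores$cluster_id)],
      knapp_hartung = kh)
    emit(data.frame(
      quantity = c("pooled_log_effect", "pooled_se", "pooled_ci_low",
                   "pooled_ci_high", "Q", "tau2", "I2", "k",
                   "metareg_slope", "metareg_slope_se",
                   "metareg_slope_ci_low", "metareg_slope_ci_high",
                   "metareg_or_per_unit", "metareg_tau2_resid"),
      value = c(pooled$pooled_log_effect, pooled$se, pooled$ci_low,
                pooled$ci_high, pooled$Q, pooled$tau2, pooled$I2,
                pooled$k, mr$slope, mr$slope_se, mr$slope_ci[1],
                mr$slope_ci[2], mr$or_per_unit, mr$tau2_resid),
      stringsAsFactors = FALSE), "meta_summary.csv")
    emit(forest_data(eff, pooled), "forest.csv")

    # --- context summary (only when context records supplied)
    if (!is.null(inputs$context)) {
      ctx <- read_table_checked(inputs$context, "cluster_id",
                                "context records")
      emit(summarize_context(ctx), "context_summary.csv")
    }

    manifest <- list(
      package = "swpeval",
      version = as.character(utils::packageVersion("swpeval")),
      seed = seed,
      config = config,
      outputs = as.list(stats::setNames(unname(tools::md5sum(written)),
                                        basename(written)))
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    written <<- c(written, manifest_path)
    manifest
  }

  tryCatch(invisible(run()), error = function(e) {
    unlink(written)
    stop(e)
  })
}
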