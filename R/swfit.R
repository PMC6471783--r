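# Binomial IRLS on aggregated counts. Response is events out of deliveries;
# zero-delivery cells carry zero weight and stay in the table (they are
# non-informative, not dropped). Convergence on the score: max |X'(y - n p)|
# below `tol`, with step-halving whenever a full Newton step lowers the
# log-likelihood.
irls_binom <- function(X, events, deliveries, tol = 1e-8, max_iter = 100L) {
  stopifnot(nrow(X) == length(events), length(events) == length(deliveries))
  if (qr(X)$rank < ncol(X))
    stop("design matrix not of full rank", call. = FALSE)
  if (sum(events) == 0 || sum(events) == sum(deliveries))
    stop("need at least one event and one non-event overall", call. = FALSE)

  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  loglik <- function(beta) {
    p <- clamp(stats::plogis(drop(X %*% beta)))
    sum(stats::dbinom(events, deliveries, p, log = TRUE))
  }
  beta <- numeric(ncol(X))
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- clamp(stats::plogis(drop(X %*% beta)))
    score <- drop(crossprod(X, events - deliveries * p))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    wt <- deliveries * p * (1 - p)
    H <- crossprod(X, wt * X)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    # step-halving: never accept a likelihood decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || lam < 2^-20) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    ll <- ll_new
  }
  p <- clamp(stats::plogis(drop(X %*% beta)))
  wt <- deliveries * p * (1 - p)
  H <- crossprod(X, wt * X)
  vcov_model <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  if (max(abs(beta)) > 25) converged <- FALSE  # separation guard
  if (!converged)
    warning("IRLS did not converge (possible separation); ",
            "treat coefficients with caution", call. = FALSE)
  dimnames(vcov_model) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(beta, colnames(X)),
       vcov_model = vcov_model, converged = converged,
       n_iterations = iter, log_likelihood = ll,
       fitted_prob = p)
}

build_sw_matrix <- function(cells, per_site = FALSE,
                            per_centre_trends = TRUE) {
  period_c <- cells$period - mean(cells$period)  # centred for conditioning
  if (per_site) {
    X <- cbind(`(Intercept)` = 1, period = period_c,
               treated = cells$treated)
  } else {
    f <- factor(cells$cluster_id)
    Xc <- stats::model.matrix(~ 0 + f)
    colnames(Xc) <- paste0("centre:", levels(f))
    if (per_centre_trends) {
      Xt <- Xc * period_c
      colnames(Xt) <- paste0("trend:", levels(f))
    } else {
      Xt <- cbind(period = period_c)
    }
    X <- cbind(Xc, Xt, treated = cells$treated)
  }
  X
}

#' Logistic fit of cluster-period event counts
#'
#' Marginal (population-averaged) logistic regression of events on the
#' intervention indicator, fitted by iteratively reweighted least squares
#' under an independence working correlation. The multi-site model uses
#' fixed centre effects (one intercept per cluster) and, by default, a
#' separate linear calendar-period trend per centre; inference across
#' clusters should use [cluster_robust_cov()]. With `per_site = TRUE` the
#' model is intercept + linear trend + treatment for a single site's cells.
#'
#' The period covariate is centred at its mean; the treatment coefficient
#' is invariant to this recoding (only intercepts shift).
#'
#' @param cells cluster-period table (`cluster_id`, `period`, `treated`,
#'   `deliveries`, `events`); validated by [validate_cluster_periods()].
#' @param per_site single-site model (intercept + trend + treatment).
#' @param per_centre_trends in the multi-site model, one linear trend per
#'   centre (`TRUE`, default) or a single shared trend.
#' @param tol score convergence tolerance (max absolute score component).
#' @param max_iter iteration cap.
#' @return object of class `sw_fit`: coefficients, model-based covariance,
#'   convergence flag, iteration count, log-likelihood, plus the cells and
#'   design matrix needed for robust covariance.
#' @export
fit_logistic <- function(cells, per_site = FALSE, per_centre_trends = TRUE,
                         tol = 1e-8, max_iter = 100L) {
  validate_cluster_periods(cells)
  X <- build_sw_matrix(cells, per_site = per_site,
                       per_centre_trends = per_centre_trends)
  fit <- irls_binom(X, cells$events, cells$deliveries, tol = tol,
                    max_iter = max_iter)
  fit$X <- X
  fit$cells <- cells
  fit$per_site <- per_site
  class(fit) <- "sw_fit"
  fit
}

#' @export
print.sw_fit <- function(x, ...) {
  cat(sprintf("Stepped-wedge logistic fit (%s), %s in %d iterations\n",
              if (x$per_site) "single site" else "multi-site",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  se <- sqrt(diag(x$vcov_model))
  tab <- cbind(estimate = x$coefficients, se_model = se)
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.sw_fit <- function(object, ...) object$coefficients

#' @export
vcov.sw_fit <- function(object, type = c("model", "robust"), ...) {
  type <- match.arg(type)
  if (type == "model") object$vcov_model else cluster_robust_cov(object)
}

#' @export
logLik.sw_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            class = "logLik")
}

#' Cluster-robust sandwich covariance of an `sw_fit`
#'
#' Sums score contributions within clusters:
#' \eqn{u_g = \sum_{i \in g} x_i (y_i - n_i \hat p_i)}, then
#' \deqn{V = \frac{G}{G-1} \; H^{-1} \Big(\sum_g u_g u_g'\Big) H^{-1},}
#' with \eqn{H} the observed binomial information. With every cell its own
#' cluster this reduces to the heteroscedasticity-robust (HC) form.
#'
#' @param fit a converged [fit_logistic()] result.
#' @param cluster optional clustering vector (defaults to the cells'
#'   `cluster_id`); must define at least 2 clusters.
#' @return robust covariance matrix (same dimnames as the coefficients).
#' @export
cluster_robust_cov <- function(fit, cluster = NULL) {
  stopifnot(inherits(fit, "sw_fit"))
  if (!fit$converged)
    stop("robust covariance requires a converged fit", call. = FALSE)
  cluster <- cluster %||% fit$cells$cluster_id
  stopifnot(length(cluster) == nrow(fit$X))
  G <- length(unique(cluster))
  if (G < 2L) stop("need at least 2 clusters", call. = FALSE)
  resid <- fit$cells$events - fit$cells$deliveries * fit$fitted_prob
  U <- rowsum(fit$X * resid, group = cluster)      # G x p score sums
  meat <- crossprod(as.matrix(U))
  bread <- fit$vcov_model
  V <- (G / (G - 1)) * bread %*% meat %*% bread
  dimnames(V) <- dimnames(fit$vcov_model)
  V
}

#' Site-level intervention effect from one cluster's cells
#'
#' Fits intercept + linear period trend + treatment to a single site's
#' cluster-period counts and packages the treatment log odds ratio with its
#' model-based standard error as an [effect_estimate()] ready for
#' [dl_pool()] / [meta_regression()].
#'
#' @param cells cluster-period rows of exactly one cluster, containing both
#'   control and intervention periods.
#' @param label effect label; defaults to the cluster id.
#' @return an [effect_estimate()] of kind `"odds_ratio"`.
#' @export
site_effect <- function(cells, label = NULL) {
  validate_cluster_periods(cells)
  if (length(unique(cells$cluster_id)) != 1L)
    stop("site_effect() expects a single cluster", call. = FALSE)
  informative <- cells$deliveries > 0
  if (!any(cells$treated[informative] == 1) ||
      !any(cells$treated[informative] == 0))
    stop("site lacks control or intervention periods with deliveries",
         call. = FALSE)
  fit <- fit_logistic(cells, per_site = TRUE)
  b <- fit$coefficients["treated"]
  se <- sqrt(fit$vcov_model["treated", "treated"])
  effect_estimate(unname(b), unname(se), kind = "odds_ratio",
                  label = label %||% as.character(cells$cluster_id[1]))
}

#' Per-site effects for every cluster in a cluster-period table
#'
#' @param cells multi-cluster cluster-period table.
#' @return data.frame (`site_id`, `log_effect`, `se`, `estimate`, `ci_low`,
#'   `ci_high`); clusters whose effect is inestimable (e.g. no events, or
#'   entirely pre/post crossover) are dropped with a warning.
#' @export
site_effects <- function(cells) {
  validate_cluster_periods(cells)
  ids <- unique(cells$cluster_id)
  rows <- lapply(ids, function(id) {
    e <- tryCatch(
      suppressWarnings(site_effect(cells[cells$cluster_id == id, ])),
      error = function(err) NULL)
    if (is.null(e)) return(NULL)
    data.frame(site_id = id, log_effect = e$log_effect, se = e$se,
               estimate = e$estimate, ci_low = e$ci_low,
               ci_high = e$ci_high, stringsAsFactors = FALSE)
  })
  dropped <- ids[vapply(rows, is.null, logical(1))]
  if (length(dropped))
    warning("site effect inestimable for: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no site effect estimable", call. = FALSE)
  rownames(out) <- NULL
  out
}
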