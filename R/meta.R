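#' Coerce a site-effects table to log-effect + SE form
#'
#' Accepts `log_effect` + `se` directly, or `ci_low`/`ci_high` on the ratio
#' scale, from which the SE is back-computed as
#' `(log(ci_high) - log(ci_low)) / (2 * 1.96)`.
#'
#' @param effects data.frame with `site_id` (or `label`) and either
#'   (`log_effect`, `se`) or (`log_effect` or `estimate`, `ci_low`,
#'   `ci_high`).
#' @return data.frame with `site_id`, `log_effect`, `se`.
#' @export
as_site_effects <- function(effects) {
  stopifnot(is.data.frame(effects))
  id <- effects$site_id %||% effects$label %||%
    sprintf("site%02d", seq_len(nrow(effects)))
  log_eff <- effects$log_effect %||%
    (if (!is.null(effects$estimate)) log(effects$estimate) else
      stop("need log_effect or estimate", call. = FALSE))
  se <- effects$se
  if (is.null(se)) {
    if (is.null(effects$ci_low) || is.null(effects$ci_high))
      stop("need se or ci_low/ci_high", call. = FALSE)
    se <- (log(effects$ci_high) - log(effects$ci_low)) /
      (2 * stats::qnorm(0.975))
  }
  data.frame(site_id = as.character(id), log_effect = log_eff, se = se,
             stringsAsFactors = FALSE)
}

check_meta_input <- function(y, se, k_min = 2L) {
  stopifnot(is.numeric(y), is.numeric(se), length(y) == length(se))
  if (length(y) < k_min)
    stop("need at least ", k_min, " sites", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(se)) || any(se <= 0))
    stop("log effects must be finite and standard errors positive",
         call. = FALSE)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-site variance: with fixed-effect weights
#' \eqn{w_i = 1/se_i^2} and \eqn{Q = \sum w_i (y_i - \bar y_{FE})^2},
#' \deqn{\hat\tau^2 = \max\left(0, \frac{Q - (k-1)}
#'   {\sum w_i - \sum w_i^2 / \sum w_i}\right),}
#' then random-effects weights \eqn{1/(se_i^2 + \hat\tau^2)} give the pooled
#' log effect, its SE and 95% CI. \eqn{I^2 = \max(0, 100 (Q - (k-1))/Q)}.
#'
#' @param y site log effects.
#' @param se their standard errors (> 0).
#' @param labels optional site labels (used by [forest_data()]).
#' @param knapp_hartung use the Knapp-Hartung variance adjustment and a
#'   t(k-1) interval instead of the normal Wald interval.
#' @return list of class `meta_result`: `pooled_log_effect`, `se`, `ci_low`,
#'   `ci_high` (ratio scale), `Q`, `tau2`, `I2`, `k`, `weights` (random
#'   effects, normalised to percent), `labels`, `y`, `se_i`.
#' @examples
#' dl_pool(c(0, 1), c(1, 1)) # pooled 0.5, tau2 = 0
#' @export
dl_pool <- function(y, se, labels = NULL, knapp_hartung = FALSE) {
  check_meta_input(y, se, 2L)
  k <- length(y)
  w <- 1 / se^2
  y_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  pooled <- sum(wr * y) / sum(wr)
  se_p <- sqrt(1 / sum(wr))
  if (knapp_hartung) {
    q <- sum(wr * (y - pooled)^2) / (k - 1)
    se_p <- se_p * sqrt(max(q, .Machine$double.eps))
    crit <- stats::qt(0.975, k - 1)
  } else crit <- stats::qnorm(0.975)
  structure(list(
    pooled_log_effect = pooled, se = se_p,
    ci_low = exp(pooled - crit * se_p),
    ci_high = exp(pooled + crit * se_p),
    Q = Q, tau2 = tau2,
    I2 = max(0, 100 * (Q - (k - 1)) / Q),
    k = k,
    weights = 100 * wr / sum(wr),
    labels = labels %||% sprintf("site%02d", seq_len(k)),
    y = y, se_i = se,
    knapp_hartung = knapp_hartung
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, digits = 3, ...) {
  cat(sprintf("Random-effects pooled effect (DL), k = %d sites\n", x$k))
  cat(sprintf("  ratio %.3f (95%% CI %.3f-%.3f)%s\n",
              exp(x$pooled_log_effect), x$ci_low, x$ci_high,
              if (x$knapp_hartung) " [Knapp-Hartung]" else ""))
  cat(sprintf("  Q = %.2f, tau^2 = %.4f, I^2 = %.1f%%\n", x$Q, x$tau2, x$I2))
  invisible(x)
}

#' Method-of-moments meta-regression of site effects on a covariate
#'
#' Weighted least squares of site log effects on a site-level covariate
#' (e.g. the composite implementation score). Residual between-site
#' variance is estimated by the method of moments on the regression
#' Q-statistic: with \eqn{P = W - WX(X'WX)^{-1}X'W} (fixed-effect weights
#' \eqn{W = diag(1/se_i^2)}), \eqn{\hat\tau^2_{res} = \max(0,
#' (Q_E - (k - 2)) / tr(P))}. Final coefficients use weights
#' \eqn{1/(se_i^2 + \hat\tau^2_{res})} with a Wald (or Knapp-Hartung) 95% CI
#' for the slope, also reported as an odds/effect ratio per unit covariate.
#'
#' @param y site log effects.
#' @param se their standard errors (> 0).
#' @param x site-level covariate (finite; non-constant).
#' @param knapp_hartung use the Knapp-Hartung adjustment with a t(k-2)
#'   interval.
#' @return list of class `meta_reg_result`: `slope`, `intercept`,
#'   `slope_se`, `slope_ci` (log scale), `or_per_unit`, `or_ci`,
#'   `tau2_resid`, `QE`, `k`.
#' @export
meta_regression <- function(y, se, x, knapp_hartung = FALSE) {
  check_meta_input(y, se, 3L)
  stopifnot(is.numeric(x), length(x) == length(y))
  if (any(!is.finite(x))) stop("covariate must be finite", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("constant covariate: slope not identifiable", call. = FALSE)
  k <- length(y)
  X <- cbind(intercept = 1, slope = x)
  p <- ncol(X)

  w <- 1 / se^2
  XtWX <- crossprod(X, w * X)
  if (abs(det(XtWX)) < 1e-12 * max(abs(XtWX))^p)
    stop("degenerate design: covariate collinear with intercept",
         call. = FALSE)
  b_fe <- solve(XtWX, crossprod(X, w * y))
  resid_fe <- y - X %*% b_fe
  QE <- sum(w * resid_fe^2)
  # tr(P) = sum(w) - tr((X'WX)^{-1} X'W^2X)
  trP <- sum(w) - sum(diag(solve(XtWX, crossprod(X, w^2 * X))))
  tau2 <- max(0, (QE - (k - p)) / trP)

  wr <- 1 / (se^2 + tau2)
  XtWrX <- crossprod(X, wr * X)
  b <- solve(XtWrX, crossprod(X, wr * y))
  V <- solve(XtWrX)
  if (knapp_hartung) {
    resid <- y - X %*% b
    q <- sum(wr * resid^2) / (k - p)
    V <- V * max(q, .Machine$double.eps)
    crit <- stats::qt(0.975, k - p)
  } else crit <- stats::qnorm(0.975)
  slope <- unname(b["slope", 1])
  slope_se <- unname(sqrt(V["slope", "slope"]))
  ci <- slope + c(-1, 1) * crit * slope_se
  structure(list(
    slope = slope, intercept = unname(b["intercept", 1]),
    slope_se = slope_se, slope_ci = ci,
    or_per_unit = exp(slope), or_ci = exp(ci),
    tau2_resid = tau2, QE = QE, k = k,
    knapp_hartung = knapp_hartung
  ), class = "meta_reg_result")
}

#' @export
print.meta_reg_result <- function(x, ...) {
  cat(sprintf("Meta-regression (MoM residual tau^2), k = %d sites\n", x$k))
  cat(sprintf("  slope %.3f (95%% CI %.3f to %.3f) per unit covariate\n",
              x$slope, x$slope_ci[1], x$slope_ci[2]))
  cat(sprintf("  ratio per unit: %.2f (%.2f-%.2f)\n",
              x$or_per_unit, x$or_ci[1], x$or_ci[2]))
  cat(sprintf("  residual tau^2 = %.4f, QE = %.2f\n", x$tau2_resid, x$QE))
  invisible(x)
}

#' Forest-plot table: per-site rows plus the pooled diamond
#'
#' @param effects data.frame accepted by [as_site_effects()].
#' @param pooled optional [dl_pool()] result; computed from `effects` when
#'   omitted (requires k >= 2).
#' @return data.frame with `label`, `estimate`, `ci_low`, `ci_high`
#'   (ratio scale), `weight_pct`, `type` (`"site"` rows then one
#'   `"pooled"` row).
#' @export
forest_data <- function(effects, pooled = NULL) {
  eff <- as_site_effects(effects)
  if (nrow(eff) == 0) stop("no effects to plot", call. = FALSE)
  if (is.null(pooled)) pooled <- dl_pool(eff$log_effect, eff$se,
                                         labels = eff$site_id)
  stopifnot(inherits(pooled, "meta_result"))
  z <- stats::qnorm(0.975)
  rows <- data.frame(
    label = eff$site_id,
    estimate = exp(eff$log_effect),
    ci_low = exp(eff$log_effect - z * eff$se),
    ci_high = exp(eff$log_effect + z * eff$se),
    weight_pct = 100 * (1 / (eff$se^2 + pooled$tau2)) /
      sum(1 / (eff$se^2 + pooled$tau2)),
    type = "site", stringsAsFactors = FALSE)
  rbind(rows, data.frame(
    label = "Pooled (random effects)",
    estimate = exp(pooled$pooled_log_effect),
    ci_low = pooled$ci_low, ci_high = pooled$ci_high,
    weight_pct = 100, type = "pooled", stringsAsFactors = FALSE))
}
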