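#' Effect estimate container
#'
#' Log-scale effect with Wald 95% confidence interval, the unit handled by
#' the meta-analysis functions.
#'
#' @param log_effect effect on the natural-log scale.
#' @param se standard error of `log_effect` (>= 0), or NA when no sampling
#'   variance is available.
#' @param kind one of `"odds_ratio"`, `"proportion_ratio"`.
#' @param label free-text label (e.g. site name).
#' @return list of class `effect_estimate` with `log_effect`, `se`,
#'   `estimate` (exponentiated), `ci_low`, `ci_high`, `kind`, `label`.
#' @export
effect_estimate <- function(log_effect, se, kind = "odds_ratio", label = "") {
  stopifnot(is.numeric(log_effect), length(log_effect) == 1L,
            is.finite(log_effect))
  if (!is.na(se) && (!is.finite(se) || se < 0))
    stop("se must be finite and >= 0", call. = FALSE)
  z <- stats::qnorm(0.975)
  structure(list(
    log_effect = log_effect,
    se = se,
    estimate = exp(log_effect),
    ci_low = if (is.na(se)) NA_real_ else exp(log_effect - z * se),
    ci_high = if (is.na(se)) NA_real_ else exp(log_effect + z * se),
    kind = kind,
    label = label
  ), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("%s%s: %.*f (95%% CI %.*f-%.*f)\n",
              sub("_", " ", x$kind),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              digits, x$estimate, digits, x$ci_low, digits, x$ci_high))
  invisible(x)
}

#' Percentage from a count pair
#'
#' @param numerator,denominator non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`.
#' @return `100 * numerator / denominator`, full precision (round only for
#'   display, see [round_half_up()]).
#' @examples
#' proportion(6093, 7693) # 79.2 to one decimal
#' @export
proportion <- function(numerator, denominator) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0))
    stop("proportion undefined: zero denominator", call. = FALSE)
  if (any(numerator < 0) || any(numerator > denominator))
    stop("numerator must be between 0 and denominator", call. = FALSE)
  100 * numerator / denominator
}

#' Unadjusted odds ratio from a 2x2 table
#'
#' Computes `ln(ad/bc)` with Woolf standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and a 95% Wald interval. When any cell is
#' zero and `continuity = TRUE` (Haldane-Anscombe), 0.5 is added to every
#' cell; with `continuity = FALSE` a zero cell is an error, since the odds
#' ratio is then undefined (post-intervention coverage of 100% produces
#' exactly this case).
#'
#' @param a,b,c,d cell counts: exposed (post) with/without outcome, then
#'   unexposed (pre) with/without outcome.
#' @param continuity add 0.5 to all cells when a zero cell is present.
#' @param label label carried into the result.
#' @return an [effect_estimate()] of kind `"odds_ratio"`.
#' @examples
#' odds_ratio(3212, 70159, 2784, 72044) # referral counts, OR 1.18
#' @export
odds_ratio <- function(a, b, c, d, continuity = TRUE, label = "") {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(is.numeric(cells), length(cells) == 4L)
  if (any(cells < 0)) stop("cell counts must be >= 0", call. = FALSE)
  if (any(cells == 0)) {
    if (!continuity)
      stop("odds ratio undefined: zero cell (set continuity = TRUE)",
           call. = FALSE)
    cells <- cells + 0.5
  }
  log_or <- log(cells["a"]) + log(cells["d"]) -
    log(cells["b"]) - log(cells["c"])
  se <- sqrt(sum(1 / cells))
  effect_estimate(unname(log_or), unname(se), kind = "odds_ratio",
                  label = label)
}

#' Ratio of two proportions (post vs pre)
#'
#' Point estimate `p_post / p_pre` from percentages (or proportions; only
#' the ratio matters). When the underlying counts are supplied a Katz
#' log-method standard error
#' `sqrt(1/x_post - 1/n_post + 1/x_pre - 1/n_pre)` and 95% CI are attached;
#' otherwise the interval is NA.
#'
#' @param p_post,p_pre percentages on a common scale; `p_pre > 0`.
#' @param x_post,n_post,x_pre,n_pre optional counts behind the percentages.
#' @param label label carried into the result.
#' @return an [effect_estimate()] of kind `"proportion_ratio"`.
#' @examples
#' proportion_ratio(96.2, 42.6) # 2.26
#' @export
proportion_ratio <- function(p_post, p_pre, x_post = NULL, n_post = NULL,
                             x_pre = NULL, n_pre = NULL, label = "") {
  stopifnot(is.numeric(p_post), is.numeric(p_pre))
  if (p_pre <= 0)
    stop("proportion ratio undefined: pre-period proportion is zero",
         call. = FALSE)
  if (p_post <= 0)
    stop("proportion ratio degenerate: post-period proportion is zero",
         call. = FALSE)
  se <- NA_real_
  counts <- list(x_post, n_post, x_pre, n_pre)
  if (!all(vapply(counts, is.null, logical(1)))) {
    if (any(vapply(counts, is.null, logical(1))))
      stop("supply all four counts or none", call. = FALSE)
    stopifnot(x_post > 0, x_pre > 0, n_post >= x_post, n_pre >= x_pre)
    se <- sqrt(1 / x_post - 1 / n_post + 1 / x_pre - 1 / n_pre)
  }
  effect_estimate(log(p_post / p_pre), se, kind = "proportion_ratio",
                  label = label)
}
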