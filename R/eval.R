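# Diagnostic evaluation: confusion counts, sensitivity/specificity with
# unclipped Wald 95% intervals, and explained-variability reporting.

#' Wald interval for a binomial proportion, unclipped
#'
#' point = k/n with bounds point +/- 1.96 sqrt(point(1-point)/n). The bounds
#' are deliberately NOT clipped to [0, 1]; near-boundary proportions may
#' yield bounds below 0 or above 1, and a proportion of exactly 0 or 1 has
#' zero width.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @return named numeric vector `c(point, low, high)`.
#' @export
sens_spec_ci <- function(k, n) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  p <- k / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  c(point = p, low = p - half, high = p + half)
}

#' Evaluate model predictions against truth labels
#'
#' Confusion counts at the probability-0.5 threshold (a tie classifies
#' negative): sensitivity on cases, specificity on controls, each with an
#' unclipped Wald 95% CI; explained variability (100 R2Y) and its
#' cross-validated counterpart (100 Q2) copied from the model.
#'
#' @param m an `opls_model` (used for R2Y/Q2; may be `NULL`).
#' @param predictions data.frame from [predict_llr()] (needs `probability`).
#' @param truth 0/1 vector (1 = case), aligned with `predictions`.
#' @return object of class `eval_report`.
#' @export
evaluate_model <- function(m, predictions, truth) {
  stopifnot(nrow(predictions) == length(truth))
  if (length(unique(truth)) < 2)
    stop("both classes must be present in the truth labels", call. = FALSE)
  pos <- predictions$probability > 0.5
  tp <- sum(pos & truth == 1); fn <- sum(!pos & truth == 1)
  tn <- sum(!pos & truth == 0); fp <- sum(pos & truth == 0)
  sens <- sens_spec_ci(tp, tp + fn)
  spec <- sens_spec_ci(tn, tn + fp)
  structure(list(n_cases = tp + fn, n_controls = tn + fp,
                 tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec,
                 r2y_percent = if (is.null(m)) NA_real_ else 100 * m$r2y,
                 q2_percent = if (is.null(m)) NA_real_ else 100 * m$q2),
            class = "eval_report")
}

#' Explained variability from a loading-as-correlation
#'
#' The explained variability of the dependent variable equals the squared
#' correlation between the coded outcome and the predictive component score,
#' so 100 R^2 recovers the percentage from the dependent-variable row's
#' component loading R.
#'
#' @param R correlation coefficient, |R| <= 1.
#' @return percent, 100 * R^2.
#' @export
explained_variability_percent <- function(R) {
  if (any(abs(R) > 1)) stop("|R| must not exceed 1", call. = FALSE)
  100 * R^2
}

#' One-line evaluation footer
#'
#' Formats sensitivity/specificity with their intervals to 3 decimals,
#' mirroring the reporting style of discriminant-model tables. Exact 0/1
#' proportions print without trailing zeros.
#'
#' @param e an `eval_report`.
#' @return character scalar.
#' @export
format_eval_footer <- function(e) {
  f1 <- function(x) {
    s <- sprintf("%.3f", x)
    s <- sub("\\.?0+$", "", s)       # 1.000 -> 1, 0.960 -> 0.96
    if (s %in% c("-0", "")) s <- "0"
    s
  }
  trio <- function(v) sprintf("%s (%s, %s)", f1(v[["point"]]), f1(v[["low"]]), f1(v[["high"]]))
  sprintf("Sensitivity = %s, Specificity = %s",
          trio(e$sensitivity), trio(e$specificity))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation: %d cases, %d controls (tp %d, fn %d, tn %d, fp %d)\n",
              x$n_cases, x$n_controls, x$tp, x$fn, x$tn, x$fp))
  cat(" ", format_eval_footer(x), "\n")
  if (!is.na(x$r2y_percent))
    cat(sprintf("  Explained variability %.1f%% (%.1f%% after cross-validation)\n",
                x$r2y_percent, x$q2_percent))
  invisible(x)
}
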