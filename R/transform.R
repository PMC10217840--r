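# Box-Cox power transformation: per-variable normalization and the
# back-transformation behind "retransformed means".

#' Box-Cox profile log-likelihood
#'
#' Profile log-likelihood of the one-parameter Box-Cox family at `lambda` for
#' a sample of strictly positive (after `shift`) values:
#' -n/2 log(sigma2_hat(lambda)) + (lambda - 1) * sum(log(x + shift)).
#'
#' @param lambda power exponent (0 = natural log).
#' @param x numeric sample.
#' @param shift additive offset applied before powering.
#' @return scalar log-likelihood (up to an additive constant).
#' @export
boxcox_loglik <- function(lambda, x, shift = 0) {
  z <- x + shift
  if (any(z <= 0)) stop("nonpositive shifted value in Box-Cox likelihood", call. = FALSE)
  n <- length(z)
  y <- if (abs(lambda) < 1e-12) log(z) else (z^lambda - 1) / lambda
  s2 <- stats::var(y) * (n - 1) / n
  -n / 2 * log(s2) + (lambda - 1) * sum(log(z))
}

#' Fit the power-transformation exponent for one variable
#'
#' Finds the Box-Cox exponent maximizing the profile log-likelihood over
#' lambda in [-3, 3]: a coarse grid (step 0.01) locates the mode, then
#' golden-section search refines it to 1e-4. The shift is 0 for strictly
#' positive samples, otherwise `1e-6 - min(x)` so all shifted values are
#' strictly positive. Deterministic for a fixed input.
#'
#' @param values numeric sample (at least 10 finite, not all equal).
#' @param variable optional variable name stored in the fit.
#' @return object of class `transform_fit` with fields `variable`, `lambda`,
#'   `shift`, `criterion_value` (attained log-likelihood), `n_used`.
#' @export
fit_lambda <- function(values, variable = NA_character_) {
  x <- values[is.finite(values)]
  if (length(x) < 10)
    stop("need at least 10 finite values, got ", length(x), call. = FALSE)
  if (max(x) - min(x) <= 0)
    stop("degenerate variable: all values equal", call. = FALSE)
  shift <- if (min(x) > 0) 0 else 1e-6 - min(x)

  grid <- seq(-3, 3, by = 0.01)
  ll <- vapply(grid, boxcox_loglik, numeric(1), x = x, shift = shift)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(boxcox_loglik, c(lo, hi), x = x, shift = shift,
                         maximum = TRUE, tol = 1e-4)
  structure(list(variable = variable,
                 lambda = unname(opt$maximum),
                 shift = shift,
                 criterion_value = unname(opt$objective),
                 n_used = length(x)),
            class = "transform_fit")
}

#' Identity transform fit (lambda = 1, shift = 0)
#'
#' Convenience constructor used where a variable is analyzed untransformed
#' (the Box-Cox map at lambda = 1 is x - 1, an affine identity).
#'
#' @param variable optional variable name.
#' @return a `transform_fit`.
#' @export
identity_transform <- function(variable = NA_character_) {
  structure(list(variable = variable, lambda = 1, shift = 0,
                 criterion_value = NA_real_, n_used = NA_integer_),
            class = "transform_fit")
}

#' Log transform fit (lambda = 0, shift = 0)
#'
#' @param variable optional variable name.
#' @return a `transform_fit`.
#' @export
log_transform <- function(variable = NA_character_) {
  structure(list(variable = variable, lambda = 0, shift = 0,
                 criterion_value = NA_real_, n_used = NA_integer_),
            class = "transform_fit")
}

#' Apply a fitted power transform
#'
#' y = ((x + shift)^lambda - 1) / lambda for lambda != 0, y = log(x + shift)
#' at lambda = 0; the family is continuous in lambda at 0 and strictly
#' increasing in x for every lambda.
#'
#' @param f a `transform_fit`.
#' @param values numeric vector; `values + shift` must be positive.
#' @return transformed values (NA preserved).
#' @export
apply_transform <- function(f, values) {
  z <- values + f$shift
  if (abs(f$lambda - 1) < 1e-12) return(z - 1)  # affine identity, any real
  bad <- !is.na(z) & z <= 0
  if (any(bad))
    stop("nonpositive shifted value(s): ", paste(utils::head(values[bad], 3), collapse = ", "),
         call. = FALSE)
  if (abs(f$lambda) < 1e-12) log(z) else (z^f$lambda - 1) / f$lambda
}

#' Invert a fitted power transform
#'
#' Exact inverse of [apply_transform()]: x = (lambda*y + 1)^(1/lambda) - shift
#' for lambda != 0, x = exp(y) - shift at lambda = 0. At lambda = 0 the
#' inverse of a transformed-scale mean is the geometric mean on the original
#' scale.
#'
#' @param f a `transform_fit`.
#' @param y transformed-scale values; `lambda*y + 1` must be positive when
#'   lambda != 0.
#' @return original-scale values (NA preserved).
#' @export
invert_transform <- function(f, y) {
  if (abs(f$lambda) < 1e-12) return(exp(y) - f$shift)
  if (abs(f$lambda - 1) < 1e-12) return(y + 1 - f$shift)
  z <- f$lambda * y + 1
  bad <- !is.na(z) & z <= 0
  if (any(bad))
    stop("value(s) outside the inverse-transform domain: ",
         paste(utils::head(y[bad], 3), collapse = ", "), call. = FALSE)
  z^(1 / f$lambda) - f$shift
}

#' Back-transform a transformed-scale confidence interval
#'
#' Maps `center - half_width`, `center`, `center + half_width` through the
#' inverse transform. Because the inverse is monotone increasing, the result
#' satisfies low <= mid <= high; for a log fit the retransformed interval is
#' asymmetric with the mid point closer to the lower bound.
#'
#' @param f a `transform_fit`.
#' @param center transformed-scale center (e.g. an adjusted mean).
#' @param half_width transformed-scale interval half-width (non-negative).
#' @return named numeric vector `c(low, mid, high)` on the original scale.
#' @export
retransform_interval <- function(f, center, half_width) {
  stopifnot(half_width >= 0)
  out <- invert_transform(f, c(center - half_width, center, center + half_width))
  stats::setNames(out, c("low", "mid", "high"))
}

#' Fit power transforms for every dictionary variable in a cohort
#'
#' One fit per variable on the pooled data of the cohort (all groups
#' together); variables with fewer than 10 observed values or no variation
#' are skipped with a warning.
#'
#' @param t a [cohort_table].
#' @param variables variable names; defaults to every dictionary variable
#'   present in `t`.
#' @return named list of `transform_fit` objects.
#' @export
fit_transforms <- function(t, variables = NULL) {
  if (is.null(variables))
    variables <- intersect(variable_dictionary()$name, names(t))
  fits <- list()
  for (v in variables) {
    f <- tryCatch(fit_lambda(t[[v]], variable = v), error = function(e) e)
    if (inherits(f, "error")) {
      warning("transform skipped for '", v, "': ", conditionMessage(f), call. = FALSE)
    } else fits[[v]] <- f
  }
  fits
}

#' @export
print.transform_fit <- function(x, ...) {
  cat(sprintf("Power transform%s: lambda = %.4f, shift = %g (n = %s)\n",
              if (is.na(x$variable)) "" else paste0(" [", x$variable, "]"),
              x$lambda, x$shift, x$n_used))
  invisible(x)
}

#' @export
format.transform_fit <- function(x, ...) {
  sprintf("lambda=%.4f shift=%g", x$lambda, x$shift)
}
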