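# Synthetic cohort generator. Each sex's calibration file carries the
# published per-group retransformed means and 95% CIs plus per-model
# class-axis component loadings; cohorts are drawn as per-group Gaussians on
# the calibration scale (log for strictly positive analytes, identity for
# anthropometric measures) with a single latent class axis inducing the
# between-variable correlation structure the discriminant stage exploits.

#' Load a packaged calibration table
#'
#' @param sex `"F"` or `"M"` to load the packaged file, or `path` to load an
#'   alternative calibration JSON.
#' @param path optional explicit path (overrides `sex`).
#' @return object of class `calibration_table`: `sex`, `n` (per-group
#'   sizes), `means` (per variable, per group `[mean, low, high]` on the
#'   original scale), `loadings` (per model pair: `llr_r` and per-predictor
#'   `r`), and the per-variable `transform` hints from the data dictionary.
#' @export
load_calibration <- function(sex = c("F", "M"), path = NULL) {
  if (is.null(path)) {
    sex <- match.arg(sex)
    fname <- if (sex == "F") "calibration_women.json" else "calibration_men.json"
    path <- system.file("extdata", fname, package = "steroidiag")
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  spec <- variable_dictionary()
  n <- vapply(raw$n, as.integer, integer(1))
  if (!setequal(names(n), GROUP_LEVELS) || any(n <= 0))
    stop("calibration must give a positive n for all four groups", call. = FALSE)
  means <- list()
  for (v in names(raw$means)) {
    if (!v %in% spec$name)
      stop("calibration variable '", v, "' not in data dictionary", call. = FALSE)
    cell <- raw$means[[v]]
    if (!setequal(names(cell), GROUP_LEVELS))
      stop("variable '", v, "' missing a group", call. = FALSE)
    means[[v]] <- lapply(cell, function(z) {
      z <- as.numeric(unlist(z))
      if (length(z) != 3 || !(z[2] < z[1] && z[1] < z[3]))
        stop("invalid CI cell for '", v, "' (need low < mean < high)", call. = FALSE)
      stats::setNames(z, c("mean", "low", "high"))
    })
  }
  loadings <- lapply(raw$loadings, function(L) {
    r <- vapply(L$r, as.numeric, numeric(1))
    if (any(abs(r) > 1)) stop("loading outside [-1, 1]", call. = FALSE)
    list(llr_r = as.numeric(L$llr_r), r = r)
  })
  tf <- stats::setNames(spec$transform, spec$name)[names(means)]
  structure(list(sex = raw$sex, n = n[GROUP_LEVELS], means = means,
                 loadings = loadings, transform = tf),
            class = "calibration_table")
}

#' Generator configuration
#'
#' @param seed RNG seed (fixed seed gives byte-identical cohorts).
#' @param multiplier scales every group size (integer >= 1).
#' @param class_axis_strength scaling of the class-axis loadings (1 uses the
#'   calibrated loadings as is; 0 removes all cross-variable correlation).
#' @param loading_pair which calibrated model pair supplies the class-axis
#'   loadings (default the AD-vs-control model).
#' @param noise_df degrees of freedom for t-distributed noise; `Inf` (the
#'   default) draws Gaussian noise.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(seed = 1, multiplier = 1, class_axis_strength = 1,
                             loading_pair = "A+D-_vs_A-D-", noise_df = Inf) {
  stopifnot(multiplier >= 1, class_axis_strength >= 0)
  structure(list(seed = seed, multiplier = as.integer(multiplier),
                 class_axis_strength = class_axis_strength,
                 loading_pair = loading_pair, noise_df = noise_df),
            class = "generator_config")
}

# Transform helpers on the calibration scale.
cal_fwd <- function(x, transform) if (transform == "log") log(x) else x
cal_inv <- function(z, transform) if (transform == "log") exp(z) else z

#' Within-group SD from a published CI of the mean
#'
#' Maps the printed (mean, low, high) to the calibration scale, takes the
#' half-width h = (g(high) - g(low))/2 of the transformed CI, and converts
#' the CI of a mean back to a subject-level SD:
#' SD = h * sqrt(n) / t(0.975; n - 1).
#'
#' @param mean,low,high printed retransformed mean and 95% CI bounds.
#' @param n group size the CI was computed from.
#' @param transform `"log"` or `"identity"`.
#' @return transformed-scale SD.
#' @export
derive_sd_from_ci <- function(mean, low, high, n, transform = "identity") {
  if (!(low < mean && mean < high)) stop("need low < mean < high", call. = FALSE)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (transform == "log" && low <= 0) stop("log transform needs positive bounds", call. = FALSE)
  h <- (cal_fwd(high, transform) - cal_fwd(low, transform)) / 2
  h * sqrt(n) / stats::qt(0.975, n - 1)
}

#' Generate a synthetic cohort from a calibration table
#'
#' For subject i in group k, each variable j is drawn on the calibration
#' scale as z_ij = mu_jk + sigma_j (a_j u_i + sqrt(1 - a_j^2) e_ij), where
#' u_i ~ N(0,1) is the subject's latent class-axis position, e_ij is
#' independent unit noise, a_j = class_axis_strength * R_j uses the
#' calibrated component loading of the configured model pair (a_j = 0 for
#' variables outside that model), mu_jk is the transformed printed group
#' mean, and sigma_j is the per-group CI-derived SD. Values are mapped back
#' to the original scale, so the large-sample retransformed (geometric-type)
#' mean of each group converges to the printed mean. Group sizes are the
#' calibrated n times the multiplier, exactly.
#'
#' @param cal a [calibration_table][load_calibration].
#' @param cfg a [generator_config()].
#' @return a [cohort_table] with `subject_id`, `sex`, `group`, `age` and all
#'   calibrated variables.
#' @export
sample_cohort <- function(cal, cfg = generator_config()) {
  stopifnot(inherits(cal, "calibration_table"))
  vars <- names(cal$means)
  a <- stats::setNames(rep(0, length(vars)), vars)
  L <- cal$loadings[[cfg$loading_pair]]
  if (!is.null(L)) a[names(L$r)[names(L$r) %in% vars]] <-
      cfg$class_axis_strength * L$r[names(L$r) %in% vars]
  a["age"] <- 0  # age is drawn per group from its calibrated mean/SD only
  if (any(abs(a) > 1))
    stop("scaled class-axis loading outside [-1, 1]", call. = FALSE)

  rows <- list()
  with_seed(cfg$seed, {
    for (g in GROUP_LEVELS) {
      ng <- cal$n[[g]] * cfg$multiplier
      u <- stats::rnorm(ng)
      block <- data.frame(subject_id = paste0(cal$sex, "_", chartr("+-", "pm", g),
                                              "_", seq_len(ng)),
                          sex = cal$sex, group = g,
                          stringsAsFactors = FALSE)
      for (v in vars) {
        tfv <- cal$transform[[v]]
        cell <- cal$means[[v]][[g]]
        mu <- cal_fwd(cell[["mean"]], tfv)
        sdv <- derive_sd_from_ci(cell[["mean"]], cell[["low"]], cell[["high"]],
                                 cal$n[[g]], tfv)
        eps <- if (is.finite(cfg$noise_df)) {
          stats::rt(ng, df = cfg$noise_df) / sqrt(cfg$noise_df / (cfg$noise_df - 2))
        } else stats::rnorm(ng)
        z <- mu + sdv * (a[[v]] * u + sqrt(1 - a[[v]]^2) * eps)
        block[[v]] <- cal_inv(z, tfv)
      }
      rows[[g]] <- block
    }
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  cohort_table(out)
}

#' @export
print.calibration_table <- function(x, ...) {
  cat(sprintf("Calibration (%s): %d variables, groups %s\n", x$sex,
              length(x$means),
              paste(names(x$n), x$n, sep = "=", collapse = ", ")))
  cat("  model pairs:", paste(names(x$loadings), collapse = ", "), "\n")
  invisible(x)
}
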