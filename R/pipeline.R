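# Full per-sex analysis: power transforms, ANCOVA screen, and the five
# pairwise OPLS discriminant models per sex, with a rendered report.

DEFAULT_PAIRS <- list(c("A+D-", "A-D-"),   # AD vs control, no T2DM
                      c("A-D+", "A-D-"),   # T2DM vs control, no AD
                      c("A+D-", "A-D+"),   # AD vs T2DM head to head
                      c("A+D+", "A+D-"),   # comorbidity vs AD
                      c("A+D+", "A-D+"))   # comorbidity vs T2DM

#' Pipeline configuration
#'
#' @param sexes which sexes to analyze (subset of `c("F", "M")`).
#' @param pairs list of `c(case, control)` group pairs; defaults to the five
#'   standard comparisons (AD vs control, T2DM vs control, AD vs T2DM,
#'   comorbidity vs AD, comorbidity vs T2DM).
#' @param seed seed forwarded to the OPLS cross-validation.
#' @param predictors predictor universe for the discriminant models;
#'   `NULL` = all dictionary variables present (age included as predictor),
#'   `"steroids"` restricts to the steroid + SHBG blocks.
#' @param opls an [opls_config()] template (its seed is overridden).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sexes = c("F", "M"), pairs = DEFAULT_PAIRS,
                            seed = 1, predictors = NULL,
                            opls = opls_config()) {
  stopifnot(all(sexes %in% c("F", "M")))
  for (p in pairs) stopifnot(length(p) == 2, all(p %in% GROUP_LEVELS))
  opls$seed <- seed
  structure(list(sexes = sexes, pairs = pairs, seed = seed,
                 predictors = predictors, opls = opls),
            class = "pipeline_config")
}

resolve_predictors <- function(t, predictors) {
  spec <- variable_dictionary()
  if (is.null(predictors))
    return(intersect(spec$name, names(t)))
  if (identical(predictors, "steroids"))
    return(intersect(spec$name[spec$block %in% c("steroid", "shbg")], names(t)))
  predictors
}

#' Run the full per-sex analysis
#'
#' For each configured sex: fits power transforms on the pooled per-sex data,
#' screens every variable through the age-adjusted ANCOVA with Bonferroni
#' pairwise comparisons, and fits one OPLS discriminant model with evaluation
#' per configured group pair. Stage failures are recorded per model and do
#' not abort the pipeline. Reruns with the same input and seed reproduce the
#' bundle.
#'
#' @param t a [cohort_table] with both sexes (or one).
#' @param cfg a [pipeline_config()].
#' @return list of class `analysis_bundle`: per sex `transforms`, `ancova`
#'   (see [screen_all_variables()]), `models` (named list with `model`,
#'   `eval`, `predictions` or `error`), plus a `manifest` with seeds and
#'   effective sample sizes.
#' @export
run_full_analysis <- function(t, cfg = pipeline_config()) {
  by_sex <- split_by_sex(t)
  out <- list()
  manifest <- list(seed = cfg$seed, pairs = vapply(
    cfg$pairs, paste, character(1), collapse = "_vs_"))
  for (s in cfg$sexes) {
    d <- by_sex[[s]]
    if (nrow(d) == 0) { out[[s]] <- list(error = "no subjects"); next }
    transforms <- fit_transforms(d)
    ancova <- screen_all_variables(d, transforms)
    preds <- resolve_predictors(d, cfg$predictors)
    models <- list()
    for (p in cfg$pairs) {
      key <- paste(p, collapse = "_vs_")
      fit <- tryCatch({
        m <- fit_opls(d, p, predictors = preds, transforms = transforms,
                      config = cfg$opls)
        sub <- d[d$subject_id %in% m$subject_id, , drop = FALSE]
        sub <- sub[match(m$subject_id, sub$subject_id), , drop = FALSE]
        pr <- predict_llr(m, sub)
        ev <- evaluate_model(m, pr, m$y01)
        list(model = m, predictions = pr, eval = ev)
      }, error = function(e) list(error = conditionMessage(e)))
      models[[key]] <- fit
      manifest$n_effective[[paste(s, key)]] <-
        if (is.null(fit$error)) fit$model$n_used else NA_integer_
    }
    out[[s]] <- list(transforms = transforms, ancova = ancova, models = models)
  }
  structure(c(out, list(manifest = manifest)), class = "analysis_bundle")
}

#' Render a human-readable report of an analysis bundle
#'
#' Per model: the predictor table (loading, jackknife t, R, significance
#' marks), the explained-variability line with its cross-validated value, and
#' the sensitivity/specificity footer, in the layout of published OPLS
#' predictor tables.
#'
#' @param bundle an `analysis_bundle` from [run_full_analysis()].
#' @return character vector of report lines, invisibly printed with `cat`.
#' @export
render_report <- function(bundle) {
  spec <- variable_dictionary()
  lab <- stats::setNames(spec$label, spec$name)
  lines <- character(0)
  push <- function(...) lines <<- c(lines, sprintf(...))
  for (s in intersect(c("F", "M"), names(bundle))) {
    sx <- bundle[[s]]
    if (!is.null(sx$error)) next
    push("== Sex: %s ==", s)
    for (key in names(sx$models)) {
      fit <- sx$models[[key]]
      push("")
      push("Model %s", key)
      if (!is.null(fit$error)) { push("  failed: %s", fit$error); next }
      m <- fit$model
      if (length(m$predictors) == 0) { push("  no relevant predictors"); next }
      st <- m$stats
      push("  %-42s %8s %8s %8s %s", "Variable", "Loading", "t", "R", "")
      for (i in seq_len(nrow(st))) {
        nm <- if (st$predictor[i] %in% names(lab)) lab[[st$predictor[i]]] else st$predictor[i]
        push("  %-42s %8.3f %8.2f %8.3f %s", nm, st$component_loading[i],
             st$t_statistic[i], st$R[i], st$mark[i])
      }
      push("  Explained variability %.1f%% (%.1f%% after cross-validation)",
           100 * m$r2y, 100 * m$q2)
      push("  %s", format_eval_footer(fit$eval))
    }
    push("")
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
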