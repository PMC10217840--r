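# Age-adjusted two-factor ANCOVA screen with Bonferroni pairwise comparisons:
# per variable, the model y ~ AD + T2DM + AD:T2DM + age on the Box-Cox
# transformed scale, type III (marginal) F-tests, and least-squares group
# means back-transformed to the original units. Age itself is screened with
# the same model without the covariate (a plain two-way ANOVA).

#' Fit the two-factor age-adjusted ANCOVA for one variable
#'
#' The variable is analyzed on its fitted transformed scale. Factors are AD
#' and T2DM (sum-to-zero coded) with their interaction; age enters as a
#' covariate except when the analyzed variable is age itself. F-statistics
#' are type III marginal tests (each factor adjusted for all other terms).
#' Adjusted group means are least-squares means evaluated at the sample mean
#' age, reported with t-based 95% confidence intervals back-transformed to
#' the original scale.
#'
#' @param t a [cohort_table].
#' @param variable variable name present in `t`.
#' @param transforms named list of `transform_fit` objects (see
#'   [fit_transforms()]); a missing entry falls back to the identity.
#' @return object of class `ancova_result`: F/p per factor, per-group
#'   retransformed adjusted means with CIs, effective n, and the underlying
#'   linear model.
#' @export
fit_two_factor_ancova <- function(t, variable, transforms = list()) {
  if (!variable %in% names(t)) stop("variable '", variable, "' not in cohort", call. = FALSE)
  f <- transforms[[variable]]
  if (is.null(f)) f <- identity_transform(variable)
  use_age <- !identical(variable, "age")

  keep <- !is.na(t[[variable]]) & !is.na(t$group)
  if (use_age) keep <- keep & !is.na(t$age)
  d <- t[keep, , drop = FALSE]
  counts <- table(factor(d$group, levels = GROUP_LEVELS))
  if (any(counts == 0))
    stop("empty cell(s) for '", variable, "': ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)

  gf <- group_factors(d$group)
  yt <- apply_transform(f, d[[variable]])
  # affine rescaling leaves every F and contrast untouched but keeps the
  # response well-scaled when an extreme lambda compresses its range
  y_center <- mean(yt); y_scale <- stats::sd(yt)
  if (!is.finite(y_scale) || y_scale < 1e-300)
    stop("degenerate transformed response for '", variable, "'", call. = FALSE)
  dat <- data.frame(y = (yt - y_center) / y_scale,
                    AD = factor(gf$AD, levels = 0:1),
                    T2DM = factor(gf$T2DM, levels = 0:1),
                    age = d$age)
  if (use_age && stats::sd(dat$age) < 1e-12)
    use_age <- FALSE  # degenerate covariate: model reduces to two-way ANOVA
  ctr <- list(AD = "contr.sum", T2DM = "contr.sum")
  fml <- if (use_age) y ~ AD * T2DM + age else y ~ AD * T2DM
  fit <- stats::lm(fml, data = dat, contrasts = ctr)
  if (any(is.na(stats::coef(fit))))
    stop("singular design for '", variable, "'", call. = FALSE)

  a3 <- car::Anova(fit, type = 3)
  pick <- function(term) {
    i <- match(term, rownames(a3))
    c(F = a3[i, "F value"], p = a3[i, "Pr(>F)"])
  }
  fAD <- pick("AD"); fD <- pick("T2DM"); fI <- pick("AD:T2DM")

  emm <- emmeans::emmeans(fit, ~ AD * T2DM)
  es <- as.data.frame(summary(emm, level = 0.95))
  es$group <- paste0("A", ifelse(es$AD == 1, "+", "-"),
                     "D", ifelse(es$T2DM == 1, "+", "-"))
  means <- do.call(rbind, lapply(GROUP_LEVELS, function(g) {
    r <- es[es$group == g, ]
    half <- (r$upper.CL - r$lower.CL) / 2 * y_scale
    ret <- retransform_interval(f, r$emmean * y_scale + y_center, half)
    data.frame(group = g, n = as.integer(counts[[g]]),
               mean = ret[["mid"]], low = ret[["low"]], high = ret[["high"]])
  }))
  rownames(means) <- NULL

  structure(list(variable = variable,
                 n_used = nrow(d),
                 F_AD = unname(fAD["F"]), p_AD = unname(fAD["p"]),
                 F_T2DM = unname(fD["F"]), p_T2DM = unname(fD["p"]),
                 F_interaction = unname(fI["F"]), p_interaction = unname(fI["p"]),
                 adjusted_means = means,
                 age_adjusted = use_age,
                 transform = f,
                 model = fit,
                 emm = emm),
            class = "ancova_result")
}

#' Bonferroni pairwise comparisons among the four diagnostic groups
#'
#' All 6 unordered pairwise contrasts of the age-adjusted group means on the
#' transformed scale, using the model residual variance and the standard
#' errors of adjusted-mean differences. Each contrast is tested at the
#' family-wise level 0.05 with a Bonferroni correction over the 6
#' comparisons (per-test alpha 0.05/6).
#'
#' @param r an `ancova_result`.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with columns `group_a`, `group_b`, `direction`
#'   (`<` or `>`, by adjusted means), `p_adjusted`, `significant`.
#' @export
bonferroni_pairs <- function(r, alpha = 0.05) {
  stopifnot(inherits(r, "ancova_result"))
  pr <- as.data.frame(summary(emmeans::contrast(r$emm, "pairwise"),
                              adjust = "bonferroni"))
  lab <- function(s) {
    # emmeans labels cells "AD<a> T2DM<d>"; keep the 0/1 level digits only
    d <- strsplit(gsub("[^01]", "", s), "")[[1]]
    paste0("A", ifelse(d[1] == "1", "+", "-"), "D", ifelse(d[2] == "1", "+", "-"))
  }
  parts <- strsplit(as.character(pr$contrast), " - ")
  out <- do.call(rbind, lapply(seq_along(parts), function(i) {
    ga <- lab(parts[[i]][1]); gb <- lab(parts[[i]][2])
    data.frame(variable = r$variable, group_a = ga, group_b = gb,
               direction = if (pr$estimate[i] < 0) "<" else ">",
               estimate = pr$estimate[i],
               p_adjusted = pr$p.value[i],
               significant = pr$p.value[i] < alpha)
  }))
  rownames(out) <- NULL
  out
}

#' ANCOVA screen over every declared variable
#'
#' One [fit_two_factor_ancova()] per variable (dictionary order), with
#' Bonferroni pairwise comparisons. Per-variable failures are collected, not
#' fatal.
#'
#' @param t a [cohort_table].
#' @param transforms named list of `transform_fit`s.
#' @param variables names to screen; defaults to dictionary variables present
#'   in `t` (age included, screened without the covariate).
#' @return list with `results` (named list of `ancova_result`), `table`
#'   (tidy data.frame, one row per variable), `pairs` (pairwise table),
#'   `failures` (named character vector of error messages).
#' @export
screen_all_variables <- function(t, transforms = list(), variables = NULL) {
  if (is.null(variables))
    variables <- intersect(variable_dictionary()$name, names(t))
  results <- list(); failures <- character(); pair_rows <- list(); tab_rows <- list()
  for (v in variables) {
    r <- tryCatch(fit_two_factor_ancova(t, v, transforms), error = function(e) e)
    if (inherits(r, "error")) { failures[[v]] <- conditionMessage(r); next }
    results[[v]] <- r
    pw <- bonferroni_pairs(r)
    pair_rows[[v]] <- pw
    sig <- pw[pw$significant, , drop = FALSE]
    m <- r$adjusted_means
    row <- data.frame(variable = v, n_used = r$n_used,
                      F_AD = r$F_AD, p_AD = r$p_AD,
                      F_T2DM = r$F_T2DM, p_T2DM = r$p_T2DM,
                      F_interaction = r$F_interaction, p_interaction = r$p_interaction,
                      age_adjusted = r$age_adjusted)
    for (g in GROUP_LEVELS) {
      gm <- m[m$group == g, ]
      row[[paste0("mean_", g)]] <- gm$mean
      row[[paste0("low_", g)]] <- gm$low
      row[[paste0("high_", g)]] <- gm$high
    }
    row$comparisons <- if (nrow(sig)) paste(
      paste(sig$group_a, sig$direction, sig$group_b), collapse = ", ") else ""
    tab_rows[[v]] <- row
  }
  list(results = results,
       table = if (length(tab_rows)) do.call(rbind, c(tab_rows, make.row.names = FALSE)) else NULL,
       pairs = if (length(pair_rows)) do.call(rbind, c(pair_rows, make.row.names = FALSE)) else NULL,
       failures = failures)
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA [%s]%s  n = %d\n", x$variable,
              if (x$age_adjusted) " (age-adjusted)" else " (two-way ANOVA)", x$n_used))
  cat(sprintf("  F(AD) = %.2f (p = %.3g), F(T2DM) = %.2f (p = %.3g), F(ADxT2DM) = %.2f (p = %.3g)\n",
              x$F_AD, x$p_AD, x$F_T2DM, x$p_T2DM, x$F_interaction, x$p_interaction))
  m <- x$adjusted_means
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %s: %.4g (%.4g, %.4g), n = %d\n",
                m$group[i], m$mean[i], m$low[i], m$high[i], m$n[i]))
  invisible(x)
}
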