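# OPLS binary discriminant models: a single predictive component plus
# orthogonal components (X = Tp Pp' + To Po' + E; y = Tp b + f), VIP-based
# predictor pruning, Hotelling T2 outlier screening, stratified
# cross-validation, and logistic calibration of the predictive score into a
# log likelihood ratio (LLR) of pathology presence.

#' OPLS configuration
#'
#' @param n_folds cross-validation folds (stratified; default 7).
#' @param q2_tol minimum cross-validated Q2 gain for accepting one more
#'   orthogonal component, and the maximum Q2 loss tolerated by pruning.
#' @param vip_threshold predictors with VIP below this are pruned (default 1).
#' @param llr_cap absolute cap on predicted log likelihood ratios.
#' @param hotelling_alpha significance level of the T2 outlier ellipse.
#' @param max_orth upper bound on the orthogonal component count.
#' @param seed seed controlling cross-validation fold assignment.
#' @param prune run VIP pruning (disable for diagnostics).
#' @param hotelling run the T2 screening pass.
#' @param cross_validate compute Q2 and jackknife loading statistics.
#' @param n_orth fixed orthogonal component count; `NULL` selects it by
#'   cross-validation.
#' @return list of class `opls_config`.
#' @export
opls_config <- function(n_folds = 7, q2_tol = 0.01, vip_threshold = 1,
                        llr_cap = 15, hotelling_alpha = 0.05, max_orth = 5,
                        seed = 1, prune = TRUE, hotelling = TRUE,
                        cross_validate = TRUE, n_orth = NULL) {
  structure(list(n_folds = n_folds, q2_tol = q2_tol,
                 vip_threshold = vip_threshold, llr_cap = llr_cap,
                 hotelling_alpha = hotelling_alpha, max_orth = max_orth,
                 seed = seed, prune = prune, hotelling = hotelling,
                 cross_validate = cross_validate, n_orth = n_orth),
            class = "opls_config")
}

# Evaluate expr under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Single-predictive-component OPLS on a standardized matrix and centered y.
# Returns scores/loadings/weights for the predictive and K orthogonal
# components, with X reconstruction residual E and y residual f.
opls_core <- function(X, y, K = 0) {
  Xf <- X
  wv <- drop(crossprod(Xf, y))
  nw <- sqrt(sum(wv^2))
  if (nw < 1e-12) stop("predictors carry no covariance with the outcome", call. = FALSE)
  wv <- wv / nw
  T_o <- P_o <- W_o <- NULL
  if (K > 0) for (k in seq_len(K)) {
    t_p <- drop(Xf %*% wv)
    p <- drop(crossprod(Xf, t_p)) / sum(t_p^2)
    w_o <- p - drop(crossprod(wv, p)) * wv
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-10) break  # no orthogonal variation left
    w_o <- w_o / nrm
    t_o <- drop(Xf %*% w_o)
    p_o <- drop(crossprod(Xf, t_o)) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    T_o <- cbind(T_o, t_o); P_o <- cbind(P_o, p_o); W_o <- cbind(W_o, w_o)
    wv <- drop(crossprod(Xf, y))
    wv <- wv / sqrt(sum(wv^2))
  }
  t_p <- drop(Xf %*% wv)
  p_p <- drop(crossprod(Xf, t_p)) / sum(t_p^2)
  b <- sum(y * t_p) / sum(t_p^2)
  list(w = wv, t_p = t_p, p_p = p_p, b = b,
       T_o = T_o, P_o = P_o, W_o = W_o,
       E = Xf - tcrossprod(t_p, p_p),
       f_resid = y - t_p * b,
       r2y = stats::cor(y, t_p)^2,
       n_orth = if (is.null(T_o)) 0L else ncol(T_o))
}

# Project new standardized rows through the stored orthogonal filter and the
# predictive weight.
opls_project <- function(core, Xnew) {
  Xf <- Xnew
  if (core$n_orth > 0) for (k in seq_len(core$n_orth)) {
    t_o <- drop(Xf %*% core$W_o[, k])
    Xf <- Xf - tcrossprod(t_o, core$P_o[, k])
  }
  drop(Xf %*% core$w)
}

standardize <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2, stats::sd)
    scale[scale < 1e-12] <- 1
  }
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"), center = center, scale = scale)
}

# Stratified fold assignment: within-class shuffle then round-robin.
make_folds <- function(y01, n_folds, seed) {
  n_folds <- min(n_folds, length(y01))
  fold <- integer(length(y01))
  with_seed(seed, {
    for (cls in unique(y01)) {
      idx <- sample(which(y01 == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  # every training set must contain both classes
  repeat {
    ok <- vapply(seq_len(n_folds), function(k)
      length(unique(y01[fold != k])) == 2, logical(1))
    if (all(ok) || n_folds <= 2) break
    n_folds <- n_folds - 1
    warning("fold lost a class; reducing to ", n_folds, " folds", call. = FALSE)
    fold <- pmin(fold, n_folds)
  }
  fold
}

#' Cross-validate an OPLS fit
#'
#' Stratified k-fold cross-validation of the single-predictive-component
#' OPLS: Q2 = 1 - PRESS/SS on the 0/1-coded outcome, held-out predictions,
#' and jackknife standard errors of the loadings-as-correlations pooled over
#' the fold fits (t = loading / SE).
#'
#' @param X numeric predictor matrix (transformed scale, unstandardized).
#' @param y01 0/1 class vector.
#' @param K orthogonal component count.
#' @param config an [opls_config()].
#' @return list with `q2`, `pred` (held-out fitted outcome values),
#'   `loading_se` (per-predictor jackknife SE), `n_folds`.
#' @export
cross_validate <- function(X, y01, K, config = opls_config()) {
  fold <- make_folds(y01, config$n_folds, config$seed)
  m <- max(fold)
  press <- 0
  pred <- numeric(length(y01))
  load_mat <- matrix(NA_real_, nrow = m, ncol = ncol(X))
  for (k in seq_len(m)) {
    tr <- fold != k; te <- !tr
    std <- standardize(X[tr, , drop = FALSE])
    ybar <- mean(y01[tr])
    core <- opls_core(std$X, y01[tr] - ybar, K)
    load_mat[k, ] <- suppressWarnings(
      as.vector(stats::cor(std$X, core$t_p)))
    Xte <- standardize(X[te, , drop = FALSE], std$center, std$scale)$X
    yhat <- opls_project(core, Xte) * core$b + ybar
    pred[te] <- yhat
    press <- press + sum((y01[te] - yhat)^2)
  }
  ss <- sum((y01 - mean(y01))^2)
  lbar <- colMeans(load_mat, na.rm = TRUE)
  se <- sqrt((m - 1) / m * colSums(sweep(load_mat, 2, lbar)^2, na.rm = TRUE))
  list(q2 = 1 - press / ss, pred = pred, loading_se = se, n_folds = m)
}

#' Select the orthogonal component count by cross-validation
#'
#' Starts at K = 0 and adds one orthogonal component at a time while the
#' cross-validated Q2 improves by more than `config$q2_tol`; capped at
#' min(n - 2, p - 1, `config$max_orth`).
#'
#' @inheritParams cross_validate
#' @return integer K.
#' @export
choose_orthogonal_components <- function(X, y01, config = opls_config()) {
  kmax <- max(0, min(nrow(X) - 2, ncol(X) - 1, config$max_orth))
  if (!is.finite(config$q2_tol)) return(0L)
  q2 <- cross_validate(X, y01, 0, config)$q2
  K <- 0L
  while (K < kmax) {
    q2_next <- tryCatch(cross_validate(X, y01, K + 1L, config)$q2,
                        error = function(e) -Inf)
    if (q2_next - q2 > config$q2_tol) { K <- K + 1L; q2 <- q2_next } else break
  }
  K
}

#' Variable importance in projection
#'
#' VIP_j = sqrt( p * sum_a SSY_a (w_ja/||w_a||)^2 / sum_a SSY_a ) over the
#' predictive component(s). With mean-square normalization the VIPs satisfy
#' mean(VIP^2) = 1 over retained predictors; a zero-weight predictor has
#' VIP = 0.
#'
#' @param m an `opls_model` (or a core fit with a `w` weight vector).
#' @return named numeric vector of VIP values.
#' @export
compute_vip <- function(m) {
  w <- if (inherits(m, "opls_model")) m$core$w else m$w
  p <- length(w)
  vip <- sqrt(p * w^2 / sum(w^2))
  names(vip) <- if (inherits(m, "opls_model")) m$predictors else names(w)
  vip
}

#' Hotelling T2 outlier flags for component scores
#'
#' Per-subject T2 against the F-based 100(1 - alpha)% ellipse:
#' T2_i = (s_i - mean)' S^-1 (s_i - mean) flagged when above
#' d(n-1)/(n-d) * F(1 - alpha; d, n - d).
#'
#' @param scores n x d score matrix (or vector for d = 1).
#' @param alpha significance level (default 0.05).
#' @return logical vector of flags; attributes `t2` and `limit`.
#' @export
hotelling_t2 <- function(scores, alpha = 0.05) {
  S <- as.matrix(scores)
  n <- nrow(S); d <- ncol(S)
  if (n < d + 2) stop("need at least d + 2 subjects for d score dimensions", call. = FALSE)
  V <- stats::cov(S)
  if (rcond_ok <- (min(abs(diag(qr.R(qr(V))))) < 1e-12))
    stop("singular score covariance", call. = FALSE)
  t2 <- stats::mahalanobis(S, colMeans(S), V)
  lim <- d * (n - 1) / (n - d) * stats::qf(1 - alpha, d, n - d)
  structure(t2 > lim, t2 = t2, limit = lim)
}

# Assemble the transformed predictor matrix for a set of cohort rows.
build_matrix <- function(d, predictors, transforms) {
  X <- matrix(NA_real_, nrow(d), length(predictors),
              dimnames = list(d$subject_id, predictors))
  for (j in seq_along(predictors)) {
    v <- predictors[j]
    f <- transforms[[v]]
    if (is.null(f)) f <- identity_transform(v)
    X[, j] <- apply_transform(f, d[[v]])
  }
  X
}

#' Fit an OPLS discriminant model for a pair of diagnostic groups
#'
#' The full modelling sequence: complete-case subsetting on the requested
#' predictors, per-variable power transformation, standardization, selection
#' of the orthogonal component count by cross-validation, one Hotelling T2
#' screening pass (flagged subjects excluded before the final fit), iterative
#' VIP pruning, and a final fit with cross-validated Q2, jackknife loading
#' statistics and logistic LLR calibration. The outcome is coded 1 for the
#' case group and 0 for the control group, then centered.
#'
#' @param t a [cohort_table].
#' @param group_pair character vector `c(case, control)` of group labels.
#' @param predictors predictor names; defaults to all dictionary variables
#'   present in `t` other than identifiers.
#' @param transforms named list of `transform_fit`s; `NULL` fits them on the
#'   pooled cohort `t` (per-sex pooling is the caller's responsibility).
#' @param config an [opls_config()].
#' @return object of class `opls_model`; see Details for fields.
#' @details Fields include `predictors` (post-pruning), `core` (scores,
#'   loadings, weights, residuals), `center`/`scale`, `r2y`, `q2`, `stats`
#'   (per-predictor loading-as-correlation, jackknife t, VIP, significance),
#'   `calibration` (logistic intercept/slope), `excluded` (Hotelling),
#'   `dropped` (zero variance), `n_used`, `n_case`, `n_control`.
#' @export
fit_opls <- function(t, group_pair, predictors = NULL, transforms = NULL,
                     config = opls_config()) {
  stopifnot(length(group_pair) == 2, all(group_pair %in% GROUP_LEVELS))
  if (is.null(predictors))
    predictors <- setdiff(intersect(variable_dictionary()$name, names(t)), "age")
  if (is.null(transforms)) transforms <- fit_transforms(t, intersect(
    c(predictors, "age"), names(t)))

  d <- t[t$group %in% group_pair, , drop = FALSE]
  cc <- stats::complete.cases(d[, predictors, drop = FALSE])
  d <- d[cc, , drop = FALSE]
  y01 <- as.integer(d$group == group_pair[1])
  if (sum(y01 == 1) < 3 || sum(y01 == 0) < 3)
    stop("fewer than 3 usable subjects in a class (case ", sum(y01 == 1),
         ", control ", sum(y01 == 0), ")", call. = FALSE)

  X <- build_matrix(d, predictors, transforms)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds < 1e-12]
  if (length(dropped)) {
    warning("zero-variance predictor(s) dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    X <- X[, sds >= 1e-12, drop = FALSE]
  }
  if (ncol(X) == 0) stop("no usable predictors", call. = FALSE)

  fit_once <- function(X, y01, K = NULL) {
    std <- standardize(X)
    if (is.null(K)) K <- choose_orthogonal_components(X, y01, config)
    core <- opls_core(std$X, y01 - mean(y01), K)
    list(std = std, core = core, K = K)
  }

  fit <- fit_once(X, y01, config$n_orth)

  excluded <- character(0)
  if (isTRUE(config$hotelling)) {
    scores <- cbind(fit$core$t_p, fit$core$T_o)
    flags <- tryCatch(hotelling_t2(scores, config$hotelling_alpha),
                      error = function(e) NULL)
    if (!is.null(flags) && any(flags) &&
        sum(y01[!flags] == 1) >= 3 && sum(y01[!flags] == 0) >= 3) {
      excluded <- d$subject_id[flags]
      X <- X[!flags, , drop = FALSE]
      y01 <- y01[!flags]
      d <- d[!flags, , drop = FALSE]
      fit <- fit_once(X, y01, config$n_orth)
    }
  }

  if (isTRUE(config$prune)) {
    q2_ref <- if (isTRUE(config$cross_validate))
      cross_validate(X, y01, fit$K, config)$q2 else NA_real_
    repeat {
      vip <- compute_vip(fit$core)
      drop_j <- which(vip < config$vip_threshold)
      if (!length(drop_j) || length(drop_j) == ncol(X)) {
        if (length(drop_j) == ncol(X) && ncol(X) <= 1)
          stop("no relevant predictors after VIP pruning", call. = FALSE)
        if (length(drop_j) == ncol(X)) {
          # keep the strongest predictors rather than pruning to nothing
          keep <- vip >= sort(vip, decreasing = TRUE)[2]
          X2 <- X[, keep, drop = FALSE]
        } else break
      } else X2 <- X[, -drop_j, drop = FALSE]
      fit2 <- fit_once(X2, y01, config$n_orth)
      if (isTRUE(config$cross_validate) && !is.na(q2_ref)) {
        q2_new <- cross_validate(X2, y01, fit2$K, config)$q2
        if (q2_ref - q2_new > config$q2_tol) break  # pruning would cost Q2
        q2_ref <- q2_new
      }
      X <- X2; fit <- fit2
      if (!length(drop_j) || ncol(X) <= 1) break
    }
  }

  cv <- if (isTRUE(config$cross_validate))
    cross_validate(X, y01, fit$K, config) else NULL

  loading_cor <- suppressWarnings(as.vector(stats::cor(fit$std$X, fit$core$t_p)))
  vip <- compute_vip(fit$core)
  t_stat <- if (!is.null(cv)) loading_cor / cv$loading_se else rep(NA_real_, ncol(X))
  df <- if (!is.null(cv)) cv$n_folds - 1 else NA_integer_
  p_load <- if (!is.null(cv)) 2 * stats::pt(-abs(t_stat), df) else rep(NA_real_, ncol(X))
  stats_df <- data.frame(predictor = colnames(X),
                         component_loading = loading_cor,
                         t_statistic = t_stat,
                         R = loading_cor,
                         vip = unname(vip),
                         p_value = p_load,
                         mark = ifelse(is.na(p_load), "",
                                ifelse(p_load < 0.01, "**",
                                ifelse(p_load < 0.05, "*", ""))),
                         row.names = NULL)

  # logistic calibration: class on predictive score -> LLR scale
  cal <- suppressWarnings(stats::glm(y01 ~ fit$core$t_p, family = stats::binomial()))
  calibration <- c(intercept = unname(stats::coef(cal)[1]),
                   slope = unname(stats::coef(cal)[2]))

  structure(list(group_pair = group_pair,
                 predictors = colnames(X),
                 transforms = transforms[colnames(X)],
                 center = fit$std$center, scale = fit$std$scale,
                 core = fit$core,
                 n_orth = fit$K,
                 r2y = fit$core$r2y,
                 q2 = if (is.null(cv)) NA_real_ else cv$q2,
                 cv_pred = if (is.null(cv)) NULL else cv$pred,
                 n_folds = if (is.null(cv)) NA_integer_ else cv$n_folds,
                 stats = stats_df,
                 calibration = calibration,
                 y01 = y01,
                 subject_id = d$subject_id,
                 excluded = excluded,
                 dropped = dropped,
                 n_used = length(y01),
                 n_case = sum(y01 == 1), n_control = sum(y01 == 0),
                 informative = if (is.null(cv)) NA else cv$q2 > 0,
                 config = config),
            class = "opls_model")
}

#' Prune predictors of a fitted model by VIP
#'
#' Iteratively removes predictors whose VIP falls below `threshold`,
#' refitting after each pass, until all survivors reach the threshold or a
#' refit would cost more than `q2_tol` of cross-validated Q2. With
#' `threshold = 0` this is the identity.
#'
#' @param m an `opls_model` fitted with pruning disabled (or not).
#' @param t the cohort used to fit `m`.
#' @param threshold VIP cutoff (default 1).
#' @return the retained predictor names, in stable (input) order.
#' @export
prune_predictors <- function(m, t, threshold = 1) {
  if (threshold <= 0) return(m$predictors)
  cfg <- m$config
  cfg$prune <- TRUE
  cfg$vip_threshold <- threshold
  cfg$hotelling <- FALSE
  refit <- fit_opls(t, m$group_pair, predictors = m$predictors,
                    transforms = m$transforms, config = cfg)
  refit$predictors
}

#' Predict log likelihood ratios and probabilities for new subjects
#'
#' Projects each subject onto the model's predictive component (after
#' removing orthogonal variation), maps the score through the logistic
#' calibration to the log likelihood ratio LLR = log(p/(1-p)), caps |LLR| at
#' `config$llr_cap`, and converts to the probability of pathology presence
#' p = exp(LLR)/(1 + exp(LLR)). Classification threshold is probability 0.5
#' (a tie classifies negative).
#'
#' @param m an `opls_model`.
#' @param newdata a [cohort_table] or data.frame carrying every model
#'   predictor.
#' @return data.frame with `subject_id`, `t_p_score`, `llr`, `probability`,
#'   `predicted_class` (1 = case group).
#' @export
predict_llr <- function(m, newdata) {
  miss <- setdiff(m$predictors, names(newdata))
  if (length(miss))
    stop("missing predictor(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"subject_id" %in% names(newdata))
    newdata$subject_id <- as.character(seq_len(nrow(newdata)))
  X <- build_matrix(newdata, m$predictors, m$transforms)
  Xs <- standardize(X, m$center, m$scale)$X
  tp <- opls_project(m$core, Xs)
  llr <- m$calibration[["intercept"]] + m$calibration[["slope"]] * tp
  llr <- pmax(pmin(llr, m$config$llr_cap), -m$config$llr_cap)
  data.frame(subject_id = newdata$subject_id,
             t_p_score = tp,
             llr = llr,
             probability = stats::plogis(llr),
             predicted_class = as.integer(stats::plogis(llr) > 0.5),
             row.names = NULL)
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("OPLS model: %s (case) vs %s (control)\n",
              x$group_pair[1], x$group_pair[2]))
  cat(sprintf("  n = %d (%d cases, %d controls)%s\n", x$n_used, x$n_case,
              x$n_control,
              if (length(x$excluded)) paste0(", ", length(x$excluded), " excluded (T2)") else ""))
  cat(sprintf("  predictors: %d, orthogonal components: %d\n",
              length(x$predictors), x$n_orth))
  cat(sprintf("  Explained variability %.1f%% (%.1f%% after cross-validation)\n",
              100 * x$r2y, 100 * x$q2))
  invisible(x)
}
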