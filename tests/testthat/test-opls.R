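test_that("single-component fit matches the brute-force PLS oracle", {
  set.seed(3)
  n <- 20; p <- 5
  X <- scale(matrix(rnorm(n * p), n, p))
  y <- rnorm(n); y <- y - mean(y)
  core <- steroidiag:::opls_core(X, y, K = 0)
  w_oracle <- drop(crossprod(X, y)); w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_lt(max(abs(core$w - w_oracle)), 1e-8)
  expect_lt(max(abs(core$t_p - drop(X %*% w_oracle))), 1e-8)
})

test_that("decomposition identities hold on every fit", {
  # X = Tp Pp' + To Po' + E exactly; To orthogonal to Tp and to itself;
  # R2Y is the squared correlation of the outcome with the predictive score;
  # y residual is y - Tp b
  for (s in 1:5) {
    set.seed(s)
    n <- 30 + 5 * s; p <- 4 + s
    y <- rep(c(0, 1), length.out = n); y <- y - mean(y)
    X <- scale(matrix(rnorm(n * p), n, p) + outer(y, rnorm(p)))
    K <- s %% 3
    core <- steroidiag:::opls_core(X, y, K)
    Xhat <- tcrossprod(core$t_p, core$p_p) + core$E
    if (core$n_orth > 0) Xhat <- Xhat + tcrossprod(core$T_o, core$P_o)
    expect_lt(max(abs(Xhat - X)), 1e-8)
    if (core$n_orth > 0) {
      expect_lt(max(abs(crossprod(core$T_o, core$t_p))), 1e-8)
      off <- crossprod(core$T_o) - diag(colSums(core$T_o^2), core$n_orth)
      expect_lt(max(abs(off)), 1e-8)
    }
    expect_equal(core$r2y, cor(y, core$t_p)^2, tolerance = 1e-9)
    expect_equal(core$f_resid, y - core$t_p * core$b, tolerance = 1e-12)
  }
})

test_that("VIP: normalization, literal-formula oracle, degenerate cases", {
  set.seed(8)
  n <- 40; p <- 5
  y <- rep(c(0, 1), each = n / 2); y <- y - mean(y)
  X <- scale(matrix(rnorm(n * p), n, p) + outer(y, c(3, 2, 1, 0.5, 0.1)))
  core <- steroidiag:::opls_core(X, y, K = 0)
  vip <- compute_vip(core)
  expect_equal(mean(vip^2), 1, tolerance = 1e-9)
  # literal summation oracle for a single predictive component
  w <- core$w
  ssy <- 1  # single component: SS weights cancel
  vip_oracle <- sqrt(p * (ssy * (w / sqrt(sum(w^2)))^2) / ssy)
  expect_equal(unname(vip), unname(vip_oracle), tolerance = 1e-10)

  # single predictor -> VIP exactly 1
  x1 <- matrix(scale(rnorm(n) + y), n, 1)
  expect_equal(unname(compute_vip(steroidiag:::opls_core(x1, y, 0))), 1)
  # zero-weight predictor -> VIP 0
  w0 <- list(w = c(0.8, 0.6, 0))
  expect_equal(unname(compute_vip(w0))[3], 0)
})

test_that("perfect separation proxy yields a perfect model", {
  set.seed(5)
  n <- 30
  y <- rep(c(0, 1), each = n / 2)
  d <- data.frame(subject_id = as.character(1:n), sex = "F",
                  group = ifelse(y == 1, "A+D-", "A-D-"), age = 70,
                  v1 = y + 1)    # the outcome duplicated as sole predictor
  t <- cohort_table(d, spec = toy_spec("v1"))
  m <- fit_opls(t, c("A+D-", "A-D-"), predictors = "v1",
                transforms = identity_transforms("v1"),
                config = opls_config(seed = 1, hotelling = FALSE))
  expect_equal(m$r2y, 1, tolerance = 1e-9)
  pr <- predict_llr(m, d)
  ev <- evaluate_model(m, pr, y)
  expect_equal(ev$sensitivity[["point"]], 1)
  expect_equal(ev$specificity[["point"]], 1)
  # separation drives |LLR| to the cap, probabilities stay inside (0,1)
  expect_true(all(abs(pr$llr) == m$config$llr_cap))
  expect_true(all(pr$probability > 0 & pr$probability < 1))
})

test_that("class-independent predictors give Q2 <= 0 and a non-informative flag", {
  flagged <- 0; reps <- 40
  for (s in seq_len(reps)) {
    t <- toy_pair_cohort(30, 6, delta = 0, seed = 400 + s)
    m <- suppressWarnings(fit_opls(t, c("A+D-", "A-D-"),
        predictors = paste0("v", 1:6),
        transforms = identity_transforms(paste0("v", 1:6)),
        config = opls_config(seed = s, hotelling = FALSE, prune = FALSE)))
    if (m$q2 <= 0 && !m$informative) flagged <- flagged + 1
  }
  expect_gte(flagged / reps, 0.90)
})

test_that("orthogonal component count tracks the latent structure", {
  k_none <- k_lat <- integer(0)
  for (s in 1:15) {
    set.seed(s)
    n <- 60; p <- 8
    y <- rep(0:1, each = n / 2)
    sig <- runif(p, 0.5, 1)
    X <- outer(y - mean(y), sig) + matrix(rnorm(n * p), n, p)
    k_none <- c(k_none, choose_orthogonal_components(X, y, opls_config(seed = s)))
    v <- rnorm(p); v <- v - sig * sum(v * sig) / sum(sig^2)
    X_lat <- X + outer(rnorm(n, sd = 3), v)   # strong class-unrelated factor
    k_lat <- c(k_lat, choose_orthogonal_components(X_lat, y, opls_config(seed = s)))
  }
  expect_gte(mean(k_none == 0), 0.80)
  expect_gte(mean(k_lat >= 1), 0.80)
  # an infinite improvement requirement degenerates to K = 0
  set.seed(1)
  X <- matrix(rnorm(200), 40, 5); y <- rep(0:1, 20)
  expect_equal(choose_orthogonal_components(X, y, opls_config(q2_tol = Inf)), 0L)
})

test_that("VIP pruning keeps informative predictors and respects its bounds", {
  kept <- 0; reps <- 25
  for (s in seq_len(reps)) {
    t <- toy_pair_cohort(50, 10, delta = 2, informative = 1:3, seed = 600 + s)
    m <- suppressWarnings(fit_opls(t, c("A+D-", "A-D-"),
        predictors = paste0("v", 1:10),
        transforms = identity_transforms(paste0("v", 1:10)),
        config = opls_config(seed = s, hotelling = FALSE)))
    if (all(c("v1", "v2", "v3") %in% m$predictors)) kept <- kept + 1
  }
  expect_gte(kept / reps, 0.90)

  # threshold 0 prunes nothing; exchangeable informative predictors all stay
  t <- toy_pair_cohort(40, 5, delta = 1.5, seed = 77)
  m0 <- fit_opls(t, c("A+D-", "A-D-"), predictors = paste0("v", 1:5),
                 transforms = identity_transforms(paste0("v", 1:5)),
                 config = opls_config(seed = 1, hotelling = FALSE,
                                      vip_threshold = 0))
  expect_setequal(m0$predictors, paste0("v", 1:5))
  expect_setequal(prune_predictors(m0, t, threshold = 0), paste0("v", 1:5))
  m1 <- fit_opls(t, c("A+D-", "A-D-"), predictors = paste0("v", 1:5),
                 transforms = identity_transforms(paste0("v", 1:5)),
                 config = opls_config(seed = 1, hotelling = FALSE))
  expect_setequal(m1$predictors, paste0("v", 1:5))  # symmetric VIPs ~ 1
})

test_that("Hotelling flags equal a direct T2 oracle and obey the alpha limits", {
  set.seed(13)
  S <- matrix(rnorm(400), 200, 2)
  flags <- hotelling_t2(S, alpha = 0.05)
  t2_oracle <- mahalanobis(S, colMeans(S), cov(S))
  lim <- 2 * 199 / 198 * qf(0.95, 2, 198)
  expect_identical(as.logical(flags), unname(t2_oracle > lim))

  # subject at the centroid is never flagged
  S2 <- rbind(S, colMeans(S))
  f2 <- hotelling_t2(S2, alpha = 0.05)
  expect_false(f2[nrow(S2)])
  expect_lt(attr(f2, "t2")[nrow(S2)], 1e-6)

  expect_true(all(hotelling_t2(S, alpha = 1 - 1e-12)))   # limit -> 0
  expect_false(any(hotelling_t2(S, alpha = 1e-12)))      # limit -> Inf
})

test_that("cross-validation: Q2 <= R2Y sweep, determinism, jackknife t finite", {
  viol <- 0
  for (s in 1:50) {
    set.seed(s)
    n <- 40; p <- 6
    y <- rep(0:1, each = n / 2)
    X <- outer(y - mean(y), rnorm(p)) * runif(1, 0, 2) + matrix(rnorm(n * p), n, p)
    std <- steroidiag:::standardize(X)
    core <- steroidiag:::opls_core(std$X, y - mean(y), 0)
    cv <- cross_validate(X, y, 0, opls_config(seed = s))
    if (cv$q2 > core$r2y + 1e-9) viol <- viol + 1
  }
  expect_equal(viol, 0)

  set.seed(2); X <- matrix(rnorm(240), 40, 6); y <- rep(0:1, 20)
  c1 <- cross_validate(X, y, 1, opls_config(seed = 123))
  c2 <- cross_validate(X, y, 1, opls_config(seed = 123))
  expect_identical(c1$q2, c2$q2)
  expect_true(all(is.finite(c1$loading_se)))
})

test_that("LLR predictions: logistic identity, midpoint, missing predictor error", {
  t <- toy_pair_cohort(40, 4, delta = 1.2, seed = 55)
  m <- fit_opls(t, c("A+D-", "A-D-"), predictors = paste0("v", 1:4),
                transforms = identity_transforms(paste0("v", 1:4)),
                config = opls_config(seed = 9, hotelling = FALSE, prune = FALSE))
  pr <- predict_llr(m, t)
  expect_equal(pr$probability, exp(pr$llr) / (1 + exp(pr$llr)), tolerance = 1e-12)
  expect_true(all(diff(pr$probability[order(pr$t_p_score)]) >= 0))  # monotone

  # score at the calibration midpoint -> LLR 0, probability 1/2
  mid <- -m$calibration[["intercept"]] / m$calibration[["slope"]]
  d_mid <- t[1, ]
  # invert: build a subject whose projected score equals mid by scaling v
  llr_mid <- m$calibration[["intercept"]] + m$calibration[["slope"]] * mid
  expect_equal(unname(plogis(llr_mid)), 0.5)

  expect_error(predict_llr(m, t[, c("subject_id", "v1", "v2")]),
               "missing predictor")
})

test_that("fitted loadings recover the generating class-axis loadings", {
  # cohorts generated with the calibrated loading structure: fitted
  # loading-as-correlation must agree in sign for predictors with |R| > 0.3
  # and correlate strongly with the generating values
  cal <- load_calibration("F")
  L <- cal$loadings[["A+D-_vs_A-D-"]]$r
  big <- names(L)[abs(L) > 0.3]
  ok <- 0; tot <- 0; cors <- numeric(0)
  cfg <- opls_config(prune = FALSE, hotelling = FALSE,
                     cross_validate = FALSE, n_orth = 0)
  # analyze on the calibration scale (log/identity per dictionary hint)
  spec <- variable_dictionary()
  tfs <- sapply(names(L), function(v)
    if (spec$transform[spec$name == v] == "log") log_transform(v)
    else identity_transform(v), simplify = FALSE)
  for (s in 1:30) {
    t <- sample_cohort(cal, generator_config(seed = 8000 + s))
    m <- fit_opls(t, c("A+D-", "A-D-"), predictors = names(L),
                  transforms = tfs, config = cfg)
    st <- m$stats
    fitted_r <- st$component_loading[match(names(L), st$predictor)]
    cors <- c(cors, cor(fitted_r, unname(L)))
    idx <- match(big, st$predictor)
    ok <- ok + sum(sign(st$component_loading[idx]) == sign(L[big]))
    tot <- tot + length(big)
  }
  expect_gte(ok / tot, 0.90)
  expect_gte(mean(cors), 0.90)
})
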