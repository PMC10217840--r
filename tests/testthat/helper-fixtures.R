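# Fixtures built in code: tiny cohorts with controlled structure.

# Minimal dictionary for toy predictor sets (identity scale).
toy_spec <- function(vars) {
  data.frame(name = vars, label = vars, unit = "", block = "steroid",
             assay = "GC-MS", positive_only = FALSE, transform = "identity")
}

# Two-class toy cohort: n per class, p predictors, informative columns get a
# standardized mean shift `delta`.
toy_pair_cohort <- function(n_per_class, p, delta = 0, informative = seq_len(p),
                            seed = 1, groups = c("A+D-", "A-D-")) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(1, 0), each = n_per_class)
  X <- matrix(rnorm(n * p), n, p)
  for (j in informative) X[, j] <- X[, j] + delta * (y - mean(y))
  colnames(X) <- paste0("v", seq_len(p))
  d <- data.frame(subject_id = as.character(seq_len(n)), sex = "F",
                  group = ifelse(y == 1, groups[1], groups[2]), age = 70,
                  X, stringsAsFactors = FALSE)
  cohort_table(d, spec = toy_spec(colnames(X)))
}

identity_transforms <- function(vars) {
  sapply(vars, identity_transform, simplify = FALSE)
}

# Balanced 2x2 factorial cohort on one variable with constant age.
toy_factorial_cohort <- function(n_cell, means, sd = 1, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (g in names(means)) {
    rows[[g]] <- data.frame(
      subject_id = paste0(chartr("+-", "pm", g), seq_len(n_cell)),
      sex = "F", group = g, age = 70,
      y_var = rnorm(n_cell, means[[g]], sd), stringsAsFactors = FALSE)
  }
  cohort_table(do.call(rbind, c(rows, make.row.names = FALSE)),
               spec = toy_spec("y_var"))
}
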