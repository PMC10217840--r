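#' @keywords internal
"_PACKAGE"

GROUP_LEVELS <- c("A-D-", "A+D-", "A-D+", "A+D+")

#' Packaged data dictionary
#'
#' Returns the variable specification shipped with the package: one row per
#' declared cohort variable with its canonical column name, display label,
#' unit, block (anthropometric, glucose, lipid, liver, thyroid, renal, shbg,
#' steroid), assay and calibration-scale transform hint. Steroids and SHBG are
#' in nmol/L.
#'
#' @param path optional path to an alternative dictionary JSON.
#' @return data.frame with columns `name`, `label`, `unit`, `block`, `assay`,
#'   `positive_only`, `transform`.
#' @export
variable_dictionary <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "variables.json", package = "steroidiag")
  spec <- jsonlite::fromJSON(path)$variables
  stopifnot(!anyDuplicated(spec$name))
  spec
}

#' Decompose diagnostic group labels into binary factors
#'
#' Group labels follow the A+/-D+/- convention: A codes Alzheimer's disease,
#' D codes type 2 diabetes mellitus. The decomposition round-trips:
#' `paste0("A", ifelse(AD, "+", "-"), "D", ifelse(T2DM, "+", "-"))` recovers
#' the label.
#'
#' @param group character vector of labels among `A-D-`, `A+D-`, `A-D+`, `A+D+`.
#' @return data.frame with integer columns `AD` and `T2DM` (0/1).
#' @export
group_factors <- function(group) {
  bad <- !is.na(group) & !(group %in% GROUP_LEVELS)
  if (any(bad))
    stop("malformed group label(s) at row(s) ", paste(which(bad), collapse = ", "),
         ": ", paste(unique(group[bad]), collapse = ", "), call. = FALSE)
  data.frame(AD = as.integer(substr(group, 2, 2) == "+"),
             T2DM = as.integer(substr(group, 4, 4) == "+"))
}

#' Construct and validate a cohort table
#'
#' A cohort table is a data.frame carrying per-subject metadata
#' (`subject_id`, `sex`, `group`, `age`) plus measured variables declared in
#' the data dictionary. Validation enforces: unique subject ids, known group
#' labels, sex in {F, M}, positive ages, non-negative concentrations for
#' positive-only variables, and no undeclared columns.
#'
#' @param df data.frame with at least `subject_id`, `sex`, `group`, `age`.
#' @param spec data dictionary, defaults to [variable_dictionary()].
#' @return object of class `cohort_table` (a validated data.frame).
#' @export
cohort_table <- function(df, spec = variable_dictionary()) {
  req <- c("subject_id", "sex", "group", "age")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(df), c(req, spec$name))
  if (length(unknown))
    stop("unknown column(s) not in data dictionary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  dup <- duplicated(df$subject_id)
  if (any(dup))
    stop("duplicated subject_id: ", paste(unique(df$subject_id[dup]), collapse = ", "),
         call. = FALSE)
  if (any(!is.na(df$sex) & !(df$sex %in% c("F", "M"))))
    stop("sex must be 'F' or 'M'", call. = FALSE)
  group_factors(df$group)  # validates labels, errors with row numbers
  if (any(!is.na(df$age) & df$age <= 0))
    stop("age must be positive", call. = FALSE)
  pos <- intersect(spec$name[spec$positive_only], names(df))
  for (v in pos) {
    x <- df[[v]]
    if (any(!is.na(x) & x < 0))
      stop("negative value in positive-only variable '", v, "'", call. = FALSE)
  }
  structure(df, class = c("cohort_table", "data.frame"))
}

#' Read a cohort table from CSV/TSV
#'
#' The file must have a header row with `subject_id`, `sex`, `group`, `age`
#' and any subset of dictionary variables; empty cells or `NA` are missing.
#' The separator is inferred from the file extension (`.tsv` uses tab).
#'
#' @param path file path.
#' @param spec data dictionary, defaults to [variable_dictionary()].
#' @return a validated [cohort_table].
#' @export
read_cohort <- function(path, spec = variable_dictionary()) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), check.names = FALSE,
                          fileEncoding = "UTF-8",
                          colClasses = c(subject_id = "character",
                                         sex = "character",
                                         group = "character"))
  cohort_table(df, spec = spec)
}

#' Write a cohort table to CSV/TSV
#'
#' Missing cells are written as empty strings so [read_cohort()] round-trips
#' them. UTF-8, header row, no row names.
#'
#' @param t a [cohort_table].
#' @param path output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(t, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(t, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Derived clinical indices
#'
#' Adds the standard derived indices where their inputs are present:
#' BMI = weight/height^2 (kg/m^2); WHR = waist/hip;
#' BAI = hip/height^1.5 - 18 (hip in cm, height in m);
#' HOMA R = glucose x insulin / 22.5 and HOMA F = 20 x insulin / (glucose - 3.5)
#' (glucose mmol/L, insulin mIU/L); LDL cholesterol by the
#' Friedewald-Levy-Fredrickson formula LDL = TC - HDL - TG/2.2 (all mmol/L).
#' A cell stays missing when any input is missing or a denominator is
#' non-positive; HOMA F is undefined at glucose <= 3.5 mmol/L, which logs a
#' warning rather than failing. Measured columns are never altered and the
#' operation is idempotent.
#'
#' @param t a [cohort_table].
#' @return the cohort with `bmi`, `whr`, `bai`, `homa_r`, `homa_f`, `ldl`
#'   filled where computable.
#' @export
derive_indices <- function(t) {
  df <- as.data.frame(t)
  g <- function(v) if (v %in% names(df)) df[[v]] else rep(NA_real_, nrow(df))
  safe_div <- function(num, den) ifelse(!is.na(den) & den > 0, num / den, NA_real_)

  df$bmi <- safe_div(g("weight"), g("height")^2)
  df$whr <- safe_div(g("waist"), g("hip"))
  df$bai <- safe_div(g("hip"), g("height")^1.5) - 18
  df$homa_r <- g("glucose") * g("insulin") / 22.5
  hf_den <- g("glucose") - 3.5
  n_undef <- sum(!is.na(hf_den) & hf_den <= 0 & !is.na(g("insulin")))
  if (n_undef > 0)
    warning("HOMA F undefined (glucose <= 3.5 mmol/L) for ", n_undef,
            " subject(s); cells left missing", call. = FALSE)
  df$homa_f <- safe_div(20 * g("insulin"), hf_den)
  df$ldl <- g("tc") - g("hdl") - g("tg") / 2.2

  # keep measured values where derivation inputs are absent
  for (v in c("bmi", "whr", "bai", "homa_r", "homa_f", "ldl")) {
    old <- if (v %in% names(t)) t[[v]] else rep(NA_real_, nrow(df))
    df[[v]] <- ifelse(is.na(df[[v]]), old, df[[v]])
  }
  cohort_table(df)
}

#' Split a cohort by sex
#'
#' @param t a [cohort_table] with `sex` populated for every row.
#' @return named list with elements `F` and `M`, an exhaustive and disjoint
#'   partition of the rows (either may have zero rows).
#' @export
split_by_sex <- function(t) {
  if (any(is.na(t$sex))) stop("sex missing for some rows", call. = FALSE)
  keep <- function(s) {
    out <- t[t$sex == s, , drop = FALSE]
    rownames(out) <- NULL
    structure(out, class = c("cohort_table", "data.frame"))
  }
  list(F = keep("F"), M = keep("M"))
}

#' Count subjects per diagnostic cell
#'
#' @param t a [cohort_table].
#' @return named integer vector over the four A+/-D+/- groups.
#' @export
group_sizes <- function(t) {
  n <- table(factor(t$group, levels = GROUP_LEVELS))
  stats::setNames(as.integer(n), GROUP_LEVELS)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("Cohort table:", nrow(x), "subjects,",
      length(setdiff(names(x), c("subject_id", "sex", "group"))), "variables\n")
  sx <- table(x$sex)
  cat("Sex:", paste(names(sx), as.integer(sx), collapse = ", "), "\n")
  cat("Groups:", paste(GROUP_LEVELS, group_sizes(x), collapse = ", "), "\n")
  invisible(x)
}
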