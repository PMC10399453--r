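#' Profile the missingness structure of a phenotype table
#'
#' Computes, over the non-excluded variables, the per-variable observed
#' count, the pairwise complete-observation count matrix (how many subjects
#' have both members of each variable pair observed) and the Pearson
#' correlation matrix of the binary observed-indicators (the phi
#' coefficient).  Indicator pairs where either indicator is constant have an
#' undefined correlation and are returned as `NA` rather than silently zero.
#'
#' @param table a `"pheno_table"`.
#' @param variables optional subset of variable names to profile; defaults
#'   to all non-excluded variables (outcome included).
#' @return An object of class `"miss_profile"`: list with `observed_count`
#'   (named vector), `pairwise_complete` (P x P integer matrix), `miss_corr`
#'   (P x P matrix, `NA` where undefined), `indicator` (n x P logical
#'   observed matrix) and `n_subjects`.
#' @export
profile_missingness <- function(table, variables = NULL) {
  if (is.null(variables))
    variables <- table$schema$name[table$schema$role != "excluded"]
  if (!length(variables)) stop("no variables to profile")
  unknown <- setdiff(variables, table$schema$name)
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  ind <- !is.na(as.matrix(table$data[, variables, drop = FALSE]))
  storage.mode(ind) <- "logical"
  m <- matrix(as.numeric(ind), nrow(ind), ncol(ind),
              dimnames = list(NULL, variables))
  pc <- crossprod(m)
  storage.mode(pc) <- "integer"
  sds <- apply(m, 2, sd)
  mc <- suppressWarnings(cor(m))
  mc[sds == 0, ] <- NA_real_
  mc[, sds == 0] <- NA_real_
  structure(list(observed_count = stats::setNames(diag(pc), variables),
                 pairwise_complete = pc,
                 miss_corr = mc,
                 indicator = ind,
                 n_subjects = nrow(ind)),
            class = "miss_profile")
}

#' @export
print.miss_profile <- function(x, ...) {
  cat("Missingness profile: ", x$n_subjects, " subjects x ",
      length(x$observed_count), " variables\n", sep = "")
  cat("  observed counts: min ", min(x$observed_count), ", median ",
      median(x$observed_count), ", max ", max(x$observed_count), "\n", sep = "")
  cat("  complete cases over all variables: ",
      sum(rowSums(!x$indicator) == 0), "\n", sep = "")
  invisible(x)
}

#' Count complete cases over a variable subset
#'
#' Number of subjects with every listed variable observed.
#'
#' @param table a `"pheno_table"`.
#' @param variables non-empty character vector of variable names.
#' @param subject_idx optional subject indices to restrict to.
#' @return Integer count.
#' @export
complete_case_count <- function(table, variables, subject_idx = NULL) {
  if (!length(variables)) stop("variable subset is empty")
  unknown <- setdiff(variables, table$schema$name)
  if (length(unknown)) stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  d <- table$data[, variables, drop = FALSE]
  if (!is.null(subject_idx)) d <- d[subject_idx, , drop = FALSE]
  sum(stats::complete.cases(d))
}

complete_case_idx <- function(table, variables, subject_idx = NULL) {
  d <- table$data[, variables, drop = FALSE]
  if (is.null(subject_idx)) subject_idx <- seq_len(nrow(d))
  subject_idx[stats::complete.cases(d[subject_idx, , drop = FALSE])]
}

#' General variable filtering
#'
#' Removes predictor variables that are (a) excessively sparse (missing
#' fraction above `max_missing_fraction`, by default 80%, or observed in
#' fewer than `min_observed` subjects), (b) schema-excluded (unstructured,
#' free text, dates, array fields, ICD matrices), (c) invariant among their
#' observed values, or (d) categorical with any realized level rarer than
#' `min_level_count` subjects.  The outcome is never dropped.
#'
#' @param table a `"pheno_table"`.
#' @param max_missing_fraction drop a variable when its missing fraction
#'   exceeds this (default 0.8).
#' @param min_observed drop a variable observed in fewer subjects than this
#'   (default 0).
#' @param min_level_count minimum subjects per realized categorical level
#'   (default 50); sparser categoricals are dropped.
#' @return A list of class `"filter_report"`: `keep` (retained predictor
#'   names, schema order), `removed` (data frame variable/rule), and the
#'   thresholds used.
#' @export
filter_general <- function(table, max_missing_fraction = 0.8,
                           min_observed = 0, min_level_count = 50) {
  stopifnot(max_missing_fraction >= 0, min_observed >= 0)
  n <- nrow(table$data)
  rules <- character(0); vars <- character(0)
  keep <- character(0)
  for (i in seq_len(nrow(table$schema))) {
    nm <- table$schema$name[i]
    if (nm == table$outcome) next
    role <- table$schema$role[i]
    col <- table$data[[nm]]
    n_obs <- sum(!is.na(col))
    rule <- NULL
    if (role == "excluded") {
      rule <- paste0("excluded:", table$schema$exclusion_reason[i])
    } else if (n_obs < min_observed || (n - n_obs) / n > max_missing_fraction) {
      rule <- "sparse"
    } else if (length(unique(col[!is.na(col)])) < 2L) {
      rule <- "invariant"
    } else if (role == "categorical") {
      tab <- table(col[!is.na(col)])
      if (any(tab < min_level_count)) rule <- "sparse_level"
    }
    if (is.null(rule)) keep <- c(keep, nm)
    else { vars <- c(vars, nm); rules <- c(rules, rule) }
  }
  if (!length(keep))
    stop("general filtering removed every predictor (",
         paste(sprintf("%s: %d", names(table(rules)), as.integer(table(rules))),
               collapse = ", "), ")")
  structure(list(keep = keep,
                 removed = data.frame(variable = vars, rule = rules,
                                      stringsAsFactors = FALSE),
                 max_missing_fraction = max_missing_fraction,
                 min_observed = min_observed,
                 min_level_count = min_level_count),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("General filter: ", length(x$keep), " predictors retained, ",
      nrow(x$removed), " removed\n", sep = "")
  if (nrow(x$removed)) print(table(x$removed$rule))
  invisible(x)
}

#' Measured/unmeasured balance filter
#'
#' For each variable k, computes the balance ratio
#' \deqn{\tau_k = \frac{n_{k,measured}/N_{measured}}{n_{k,unmeasured}/N_{unmeasured}}}
#' the ratio of the proportion of subjects with variable k observed in the
#' measured (outcome-observed) set to that proportion in the unmeasured set.
#' Variables whose availability is skewed between the two sets are poor
#' predictors for the unmeasured set and are filtered.
#'
#' By default the rule is symmetric: keep iff `min(tau, 1/tau) >= t`.  With
#' `symmetric = FALSE` the literal one-sided rule `tau >= t` is applied.  A
#' variable never observed in one of the two sets has an undefined ratio and
#' is treated as maximally imbalanced (dropped).
#'
#' @param table a `"pheno_table"`.
#' @param split a `"measured_split"` from [split_measured()].
#' @param t balance threshold in (0, 1], default 0.7.
#' @param variables variable names to assess; defaults to all non-excluded
#'   predictors.
#' @param symmetric use the two-sided rule (default `TRUE`).
#' @return A data frame of class `"balance_report"` with per-variable
#'   observed counts and proportions in each set, `tau`, and `keep`.
#' @export
balance_filter <- function(table, split, t = 0.7, variables = NULL,
                           symmetric = TRUE) {
  if (split$n_unmeasured == 0L)
    stop("no unmeasured subjects: balance filter undefined")
  if (split$n_measured == 0L) stop("no measured subjects")
  if (is.null(variables)) variables <- predictor_names(table)
  d <- table$data[, variables, drop = FALSE]
  obs <- !is.na(as.matrix(d))
  n_meas <- colSums(obs[split$measured_idx, , drop = FALSE])
  n_unmeas <- colSums(obs[split$unmeasured_idx, , drop = FALSE])
  p_meas <- n_meas / split$n_measured
  p_unmeas <- n_unmeas / split$n_unmeasured
  tau <- ifelse(p_unmeas > 0, p_meas / p_unmeas, NA_real_)
  ratio <- ifelse(is.na(tau) | tau == 0, 0,
                  if (symmetric) pmin(tau, 1 / tau) else tau)
  keep <- ratio >= t
  out <- data.frame(variable = variables,
                    n_measured = as.integer(n_meas),
                    n_unmeasured = as.integer(n_unmeas),
                    prop_measured = p_meas,
                    prop_unmeasured = p_unmeas,
                    tau = tau, keep = keep,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "t") <- t
  attr(out, "symmetric") <- symmetric
  class(out) <- c("balance_report", "data.frame")
  out
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Balance filter (t = ", attr(x, "t"), if (attr(x, "symmetric"))
    ", symmetric" else ", one-sided", "): ",
      sum(x$keep), "/", nrow(x), " variables kept\n", sep = "")
  invisible(x)
}
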