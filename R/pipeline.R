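# End-to-end MAGIC-LASSO orchestration: filter -> cluster -> iterative
# within-cluster group-LASSO until parsimony -> missingness-ordered stepwise
# final model with hold-out selection -> prediction for unmeasured subjects.

# deterministic per-stage seed stream derived from one top-level seed
seed_stream <- function(seed, n = 10000) {
  pool <- with_seed(seed, sample.int(2^20, n))
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > length(pool)) stop("seed stream exhausted")
    pool[i]
  }
}

# numeric design rows for given subjects from a column origin map
# (variable, level): continuous -> value, categorical -> level indicator.
build_design_rows <- function(table, col_var, col_level, rows) {
  m <- length(col_var)
  X <- matrix(NA_real_, length(rows), m)
  for (j in seq_len(m)) {
    x <- table$data[[col_var[j]]][rows]
    X[, j] <- if (is.na(col_level[j])) as.numeric(x)
              else as.numeric(x == col_level[j])
  }
  colnames(X) <- ifelse(is.na(col_level), col_var,
                        paste0(col_var, "=", col_level))
  X
}

#' Iterative within-cluster group-LASSO variable selection
#'
#' Each iteration clusters the current variables by missingness structure
#' (UPGMA on Euclidean distances between rows of the pairwise
#' complete-count matrix), fits a cross-validated group-LASSO to each
#' cluster on that cluster's complete cases within the measured set, and
#' aggregates the variables with non-zero estimates across clusters.
#' Clusters with too few complete cases are dropped with a warning.  The
#' loop stops when the retained set shrinks by less than
#' `parsimony$min_shrink`, when the retained set's complete-case count
#' reaches `max(parsimony$min_complete, parsimony$complete_per_var * p)`,
#' or after `parsimony$max_iter` iterations.
#'
#' @param table a `"pheno_table"`.
#' @param split a `"measured_split"`.
#' @param variables starting predictor set (already filtered).
#' @param cut_candidates explicit candidate cut heights, or `NULL` to
#'   derive candidates from `k_targets` cluster counts each iteration.
#' @param k_targets target cluster counts used when `cut_candidates` is
#'   `NULL`.
#' @param cv_k cross-validation folds.
#' @param seed integer seed, or a seed-stream function.
#' @param min_cluster_n smallest complete-case count on which a cluster is
#'   still fit.
#' @param parsimony list of stopping controls: `min_shrink` (default
#'   0.05), `min_complete` (500), `complete_per_var` (5), `max_iter` (10).
#' @param nlambda,lambda_min_ratio,tol,maxit solver controls.
#' @return List with `retained` (character) and `trace` (data frame, one
#'   row per iteration).
#' @export
magic_iterate <- function(table, split, variables, cut_candidates = NULL,
                          k_targets = c(4, 6, 8, 10, 12), cv_k = 5,
                          seed = 1, min_cluster_n = 25,
                          parsimony = list(), nlambda = 100,
                          lambda_min_ratio = 1e-4, tol = 1e-7,
                          maxit = 10000) {
  pars <- utils::modifyList(list(min_shrink = 0.05, min_complete = 500,
                                 complete_per_var = 5, max_iter = 10),
                            parsimony)
  next_seed <- if (is.function(seed)) seed else seed_stream(seed)
  current <- variables
  trace <- list()
  for (iter in seq_len(pars$max_iter)) {
    p_in <- length(current)
    if (p_in < 2L) break
    prof <- profile_missingness(table, current)
    if (p_in == 2L) {
      clusters <- list(current)   # too few leaves to cluster
      cut_height <- 0
    } else {
      dend <- upgma(missingness_distance(prof))
      cands <- if (is.null(cut_candidates))
        cut_candidates_for_k(dend, pmin(k_targets, p_in - 1L))
      else cut_candidates
      if (!length(cands)) cands <- max(dend$height) / 2
      cut_height <- choose_cut_height(dend, prof, cands,
                                      subject_idx = split$measured_idx)
      asg <- cut_tree(dend, cut_height, prof,
                      subject_idx = split$measured_idx)
      clusters <- split(names(asg$membership), asg$membership)
    }
    retained <- character(0)
    n_dropped_clusters <- 0L
    for (cl in clusters) {
      cc <- complete_case_idx(table, cl, split$measured_idx)
      if (length(cc) < max(min_cluster_n, 2L * cv_k)) {
        warning("iteration ", iter, ": cluster of ", length(cl),
                " variable(s) dropped (", length(cc), " complete cases)")
        n_dropped_clusters <- n_dropped_clusters + 1L
        next
      }
      des <- tryCatch(encode_groups(table, cl, cc), error = function(e) NULL)
      if (is.null(des)) { n_dropped_clusters <- n_dropped_clusters + 1L; next }
      fit <- cv_fit(des, k = cv_k, nlambda = nlambda,
                    lambda_min_ratio = lambda_min_ratio, tol = tol,
                    maxit = maxit, seed = next_seed())
      retained <- c(retained, retained_variables(fit))
    }
    retained <- current[current %in% retained]   # stable order
    trace[[iter]] <- data.frame(
      iteration = iter, n_in = p_in,
      n_clusters = length(clusters),
      n_dropped_clusters = n_dropped_clusters,
      cut_height = cut_height,
      n_retained = length(retained),
      complete_cases = if (length(retained))
        complete_case_count(table, c(retained, table$outcome),
                            split$measured_idx) else 0L)
    if (!length(retained))
      stop("iteration ", iter, ": no variables retained a non-zero ",
           "estimate; no predictive signal survives")
    shrink <- (p_in - length(retained)) / p_in
    current <- retained
    cc_now <- trace[[iter]]$complete_cases
    if (shrink < pars$min_shrink) break
    if (cc_now >= max(pars$min_complete,
                      pars$complete_per_var * length(current))) break
  }
  list(retained = current, trace = do.call(rbind, trace))
}

# single-variable predictive strength for stepwise tie-breaking:
# squared correlation from a one-term linear fit on complete pairs
univariate_r2 <- function(table, variable, subject_idx) {
  x <- table$data[[variable]][subject_idx]
  y <- table$data[[table$outcome]][subject_idx]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(0)
  x <- x[ok]; y <- y[ok]
  if (is.numeric(x)) {
    if (sd(x) == 0 || sd(y) == 0) return(0)
    cor(x, y)^2
  } else {
    if (length(unique(x)) < 2 || sd(y) == 0) return(0)
    summary(stats::lm(y ~ factor(x)))$r.squared
  }
}

#' Stepwise final-model construction over missingness-ordered variables
#'
#' Splits the measured subjects into a training and a hold-out set, orders
#' the retained variables by ascending missingness within the measured set
#' (ties broken by descending single-variable predictive strength, then by
#' name), and for each prefix of that ordering fits a cross-validated
#' group-LASSO on the training complete cases, scoring each candidate by
#' the Pearson correlation between observed and predicted outcome over
#' the hold-out set.  Hold-out predictions use the same
#' missingness-tolerant rule as deployment (a missing predictor
#' contributes its training mean), so every candidate is scored on the
#' full hold-out sample and on the task the final model actually
#' performs; per-step complete-case counts are still reported.  The
#' procedure stops when a prefix has too few complete cases to fit; the
#' winning step maximizes the lower confidence bound (Fisher z, one
#' standard error) of the hold-out correlation, and its variable set is
#' refit on all measured complete cases with the penalty re-selected by
#' cross-validation.
#'
#' @inheritParams magic_iterate
#' @param retained non-empty character vector of candidate predictors.
#' @param holdout_fraction fraction of measured subjects held out
#'   (default 0.2).
#' @return List with `model` (a `"magic_model"`) and `trace` (per-step data
#'   frame of complete-case counts and hold-out correlations).
#' @export
stepwise_build <- function(table, split, retained, holdout_fraction = 0.2,
                           cv_k = 5, seed = 1, nlambda = 100,
                           lambda_min_ratio = 1e-4, tol = 1e-7,
                           maxit = 10000) {
  stopifnot(length(retained) >= 1, holdout_fraction > 0, holdout_fraction < 1)
  next_seed <- if (is.function(seed)) seed else seed_stream(seed)
  meas <- split$measured_idx
  n_ho <- max(1L, round(holdout_fraction * length(meas)))
  ho_idx <- with_seed(next_seed(), sort(sample(meas, n_ho)))
  tr_idx <- setdiff(meas, ho_idx)
  # order by ascending missingness in the measured set
  obs_counts <- vapply(retained, function(v)
    sum(!is.na(table$data[[v]][meas])), 0L)
  r2 <- vapply(retained, function(v) univariate_r2(table, v, tr_idx), 0)
  ord <- retained[order(-obs_counts, -r2, retained)]
  steps <- list()
  fits <- list()
  min_n <- max(cv_k, 10L)
  for (j in seq_along(ord)) {
    vars_j <- ord[seq_len(j)]
    tr_cc <- complete_case_idx(table, c(vars_j, table$outcome), tr_idx)
    if (length(tr_cc) < min_n) {
      if (j == 1L)
        stop("first stepwise candidate already has ", length(tr_cc),
             " complete training cases; cannot fit any model")
      break
    }
    des <- encode_groups(table, vars_j, tr_cc)
    fit <- cv_fit(des, k = cv_k, nlambda = nlambda,
                  lambda_min_ratio = lambda_min_ratio, tol = tol,
                  maxit = maxit, seed = next_seed())
    # score on the WHOLE hold-out set with the same missingness-tolerant
    # rule used at deployment (missing terms contribute their training
    # mean), so every step is judged on a common, adequately sized sample
    ho_cc <- complete_case_idx(table, c(vars_j, table$outcome), ho_idx)
    centers <- colMeans(des$X)
    Xh <- build_design_rows(table, des$col_var, des$col_level, ho_idx)
    contrib <- sweep(Xh, 2, centers, "-")
    contrib <- sweep(contrib, 2, fit$coefficients, "*")
    contrib[is.na(contrib)] <- 0
    pred <- mean(des$y) + rowSums(contrib)
    obs <- table$data[[table$outcome]][ho_idx]
    r <- if (sd(obs) > 0 && sd(pred) > 0) cor(obs, pred) else NA_real_
    fits[[j]] <- fit
    steps[[j]] <- data.frame(
      step = j, variable_added = ord[j],
      complete_train = length(tr_cc), complete_holdout = length(ho_cc),
      n_holdout_scored = length(ho_idx),
      complete_all = complete_case_count(table, c(vars_j, table$outcome)),
      n_selected_groups = length(fit$selected_groups),
      holdout_correlation = r)
  }
  trace <- do.call(rbind, steps)
  if (is.null(trace) || all(is.na(trace$holdout_correlation)))
    stop("no stepwise candidate could be evaluated on the hold-out set")
  # Selection score: lower confidence bound (Fisher z, one standard error)
  # of the hold-out correlation.  With large hold-out sets this is the
  # correlation itself; with only a handful of evaluable subjects the
  # correlation is nearly meaningless and the bound discounts it.
  r_clamp <- pmin(pmax(trace$holdout_correlation, -0.9999), 0.9999)
  z_se <- 1 / sqrt(pmax(trace$n_holdout_scored, 4) - 3)
  trace$selection_score <- tanh(atanh(r_clamp) - z_se)
  score <- ifelse(is.na(trace$selection_score), -Inf,
                  trace$selection_score)
  chosen <- which.max(score)                   # first max: fewest variables
  if (trace$n_holdout_scored[chosen] < 30)
    warning("hold-out evaluated on only ", trace$n_holdout_scored[chosen],
            " subjects at the chosen step")
  final_vars <- ord[seq_len(chosen)]
  # refit on ALL measured complete cases at the chosen variable set
  all_cc <- complete_case_idx(table, c(final_vars, table$outcome), meas)
  des_f <- encode_groups(table, final_vars, all_cc)
  fit_f <- cv_fit(des_f, k = cv_k, nlambda = nlambda,
                  lambda_min_ratio = lambda_min_ratio, tol = tol,
                  maxit = maxit, seed = next_seed())
  centers <- colMeans(des_f$X)
  model <- structure(list(
    variables = final_vars,
    terms = data.frame(variable = des_f$col_var, level = des_f$col_level,
                       beta = unname(fit_f$coefficients),
                       center = unname(centers),
                       stringsAsFactors = FALSE),
    intercept = fit_f$intercept_min,
    y_mean = mean(des_f$y),
    outcome = table$outcome,
    lambda_min = fit_f$lambda_min,
    cv_error = fit_f$cvm[fit_f$index_min],
    n_train = length(all_cc),
    chosen_step = chosen,
    holdout_correlation = trace$holdout_correlation[chosen],
    stepwise = list(ordered_variables = ord, trace = trace,
                    holdout_idx = ho_idx, chosen_step = chosen)),
    class = "magic_model")
  list(model = model, trace = trace)
}

#' Fit the MAGIC-LASSO
#'
#' The main entry point: characterizes missingness, filters variables for
#' general sparsity and for balance between the measured and unmeasured
#' subject sets, iterates clustering and within-cluster cross-validated
#' group-LASSO fits until parsimony, and builds the final model stepwise
#' over variables ordered by completeness, selected on a hold-out set.
#'
#' @param table a `"pheno_table"` with a continuous outcome.
#' @param t balance threshold for the measured/unmeasured filter
#'   (default 0.7); the filter is skipped when there are no unmeasured
#'   subjects.
#' @param balance_symmetric use the symmetric balance rule
#'   (default `TRUE`).
#' @param max_missing_fraction,min_observed,min_level_count general-filter
#'   thresholds (see [filter_general()]).
#' @param apply_filters set `FALSE` when the table is already filtered.
#' @inheritParams magic_iterate
#' @inheritParams stepwise_build
#' @param verbose print per-stage progress.
#' @return An object of class `"magic_model"` with the final predictor
#'   set, original-scale coefficients and centering constants, the chosen
#'   penalty, and full provenance (`filter`, `balance`, `iteration`,
#'   `stepwise` traces, configuration echo and seed).
#' @seealso [predict.magic_model()], [simulate_phenotype_dataset()]
#' @export
magic_lasso <- function(table, t = 0.7, balance_symmetric = TRUE,
                        max_missing_fraction = 0.8, min_observed = 0,
                        min_level_count = 50, apply_filters = TRUE,
                        cut_candidates = NULL,
                        k_targets = c(4, 6, 8, 10, 12), cv_k = 5,
                        holdout_fraction = 0.2, min_cluster_n = 25,
                        parsimony = list(), nlambda = 100,
                        lambda_min_ratio = 1e-4, tol = 1e-7, maxit = 10000,
                        seed = 1, verbose = FALSE) {
  stopifnot(inherits(table, "pheno_table"))
  config <- list(t = t, balance_symmetric = balance_symmetric,
                 max_missing_fraction = max_missing_fraction,
                 min_observed = min_observed,
                 min_level_count = min_level_count,
                 apply_filters = apply_filters,
                 cut_candidates = cut_candidates, k_targets = k_targets,
                 cv_k = cv_k, holdout_fraction = holdout_fraction,
                 min_cluster_n = min_cluster_n, parsimony = parsimony,
                 nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                 tol = tol, maxit = maxit, seed = seed)
  split <- split_measured(table)
  say <- function(...) if (verbose) message(...)
  filt <- bal <- NULL
  if (apply_filters) {
    filt <- filter_general(table, max_missing_fraction, min_observed,
                           min_level_count)
    vars <- filt$keep
    say("general filter: ", length(vars), " predictors retained")
    if (split$n_unmeasured > 0) {
      bal <- balance_filter(table, split, t = t, variables = vars,
                            symmetric = balance_symmetric)
      vars <- bal$variable[bal$keep]
      say("balance filter: ", length(vars), " predictors retained")
      if (!length(vars))
        stop("balance filter (t = ", t, ") removed every predictor")
    }
  } else {
    vars <- predictor_names(table)
  }
  next_seed <- seed_stream(seed)
  it <- magic_iterate(table, split, vars, cut_candidates = cut_candidates,
                      k_targets = k_targets, cv_k = cv_k, seed = next_seed,
                      min_cluster_n = min_cluster_n, parsimony = parsimony,
                      nlambda = nlambda,
                      lambda_min_ratio = lambda_min_ratio,
                      tol = tol, maxit = maxit)
  say("iteration: ", length(it$retained), " variables retained")
  sw <- stepwise_build(table, split, it$retained,
                       holdout_fraction = holdout_fraction, cv_k = cv_k,
                       seed = next_seed, nlambda = nlambda,
                       lambda_min_ratio = lambda_min_ratio,
                       tol = tol, maxit = maxit)
  model <- sw$model
  model$filter <- filt
  model$balance <- bal
  model$iteration <- it$trace
  model$config <- config
  model$seed <- seed
  model$n_measured <- split$n_measured
  model$n_unmeasured <- split$n_unmeasured
  say("final model: ", length(model$variables), " variables, hold-out r = ",
      round(model$holdout_correlation, 3))
  model
}

#' @export
print.magic_model <- function(x, ...) {
  cat("MAGIC-LASSO model for outcome '", x$outcome, "'\n", sep = "")
  cat("  final predictors: ", length(x$variables),
      " (chosen at stepwise step ", x$chosen_step, ")\n", sep = "")
  cat("  hold-out correlation: ", round(x$holdout_correlation, 3), "\n",
      sep = "")
  cat("  lambda_min: ", signif(x$lambda_min, 4), ", trained on ",
      x$n_train, " complete cases\n", sep = "")
  invisible(x)
}

#' @export
summary.magic_model <- function(object, ...) {
  nz <- object$terms[object$terms$beta != 0, , drop = FALSE]
  cat("MAGIC-LASSO model summary\n")
  print(object)
  if (!is.null(object$iteration)) {
    cat("\nIteration trace:\n")
    print(object$iteration, row.names = FALSE)
  }
  cat("\nNon-zero terms (original scale):\n")
  print(nz, row.names = FALSE)
  invisible(object)
}

#' @export
coef.magic_model <- function(object, ...) {
  nm <- ifelse(is.na(object$terms$level), object$terms$variable,
               paste0(object$terms$variable, "=", object$terms$level))
  c("(Intercept)" = object$intercept,
    stats::setNames(object$terms$beta, nm))
}

#' Predict outcomes, tolerating missing predictors
#'
#' For each subject the prediction is the training outcome mean plus the
#' sum, over model variables that are observed for that subject, of
#' coefficient times the centered predictor value.  A missing predictor
#' contributes zero on the centered scale, which is exactly substitution
#' of its training mean; the number of dropped variables is reported per
#' subject so heavily imputed predictions can be filtered.  Subjects
#' missing every model variable receive the training outcome mean and are
#' flagged.
#'
#' @param object a `"magic_model"`.
#' @param table a `"pheno_table"` containing the model variables.
#' @param subjects optional integer subject indices (default: all).
#' @param ... unused.
#' @return Data frame with `subject_id`, `prediction`, `n_dropped_terms`
#'   (model variables missing for that subject) and `flag`
#'   (`"all_missing"` where no model variable was observed, else `""`).
#' @export
predict.magic_model <- function(object, table, subjects = NULL, ...) {
  stopifnot(inherits(table, "pheno_table"))
  missing_vars <- setdiff(object$variables, table$schema$name)
  if (length(missing_vars))
    stop("table lacks model variable(s): ",
         paste(missing_vars, collapse = ", "))
  if (is.null(subjects)) subjects <- seq_along(table$subject_ids)
  X <- build_design_rows(table, object$terms$variable, object$terms$level,
                         subjects)
  contrib <- sweep(X, 2, object$terms$center, "-")
  contrib <- sweep(contrib, 2, object$terms$beta, "*")
  contrib[is.na(contrib)] <- 0
  pred <- object$y_mean + rowSums(contrib)
  var_missing <- vapply(object$variables, function(v)
    is.na(table$data[[v]][subjects]), logical(length(subjects)))
  var_missing <- matrix(var_missing, nrow = length(subjects))
  n_dropped <- rowSums(var_missing)
  flag <- ifelse(n_dropped == length(object$variables), "all_missing", "")
  data.frame(subject_id = table$subject_ids[subjects],
             prediction = pred,
             n_dropped_terms = as.integer(n_dropped),
             flag = flag, stringsAsFactors = FALSE)
}

#' Score predictions against observations
#'
#' Pearson correlation and mean squared error over the pairs where the
#' observation is non-missing.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return List with `correlation` (`NA` with a warning when either side
#'   has zero variance), `mse` and `n` (pairs used).
#' @export
evaluate_prediction <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  ok <- !is.na(observed) & !is.na(predicted)
  if (sum(ok) < 3) stop("need at least 3 complete observation pairs")
  o <- observed[ok]; p <- predicted[ok]
  r <- if (sd(o) == 0 || sd(p) == 0) {
    warning("zero variance: correlation undefined")
    NA_real_
  } else cor(o, p)
  list(correlation = r, mse = mean((o - p)^2), n = sum(ok))
}
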