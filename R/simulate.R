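# Synthetic-data machinery: (1) complete-case collapse of an indicator
# matrix under independent cellwise missingness plus rectangular block-wise
# missingness; (2) end-to-end phenotype-prediction studies on multivariate
# normal data with categorical conversions, a planted linear outcome, and
# imposed block + random missingness.

#' Specification for the complete-case collapse grid
#'
#' Defaults are the study conditions: a 10,000 x 200 indicator matrix,
#' cellwise random missingness rates from 1% to 50%, 0/5/10/15/20 missing
#' blocks spanning 5-15 columns and 100-500 rows (in increments of 5), 100
#' replicates per grid cell.
#'
#' @param n_subjects,n_variables matrix dimensions.
#' @param random_rates cellwise missingness probabilities.
#' @param block_counts numbers of rectangular missing blocks.
#' @param block_cols integer vector of admissible block widths (columns).
#' @param block_rows integer vector of admissible block depths (rows).
#' @param iterations replicates per (rate, block count) cell.
#' @param seed integer seed.
#' @return A list of class `"missingness_grid_spec"`.
#' @export
missingness_grid_spec <- function(n_subjects = 10000, n_variables = 200,
                                  random_rates = seq(0.01, 0.50, by = 0.01),
                                  block_counts = c(0, 5, 10, 15, 20),
                                  block_cols = 5:15,
                                  block_rows = seq(100, 500, by = 5),
                                  iterations = 100, seed = 1) {
  stopifnot(all(random_rates >= 0), all(random_rates <= 1),
            all(block_counts >= 0), iterations >= 1,
            all(block_cols >= 1), all(block_rows >= 1))
  if (max(block_cols) > n_variables || max(block_rows) > n_subjects)
    stop("block geometry exceeds matrix dimensions")
  structure(list(n_subjects = n_subjects, n_variables = n_variables,
                 random_rates = random_rates, block_counts = block_counts,
                 block_cols = block_cols, block_rows = block_rows,
                 iterations = iterations, seed = seed),
            class = "missingness_grid_spec")
}

# Draw `count` rectangular blocks: contiguous column run with width drawn
# uniformly from col_widths and contiguous row run with depth drawn
# uniformly from row_depths, each at a uniformly drawn start offset.
# Overlaps are allowed.  Returns a list of (rows, cols) integer ranges.
sample_blocks <- function(n, p, count, col_widths, row_depths) {
  if (count == 0) return(list())
  lapply(seq_len(count), function(i) {
    w <- if (length(col_widths) == 1L) col_widths else sample(col_widths, 1)
    d <- if (length(row_depths) == 1L) row_depths else sample(row_depths, 1)
    c0 <- sample.int(p - w + 1L, 1)
    r0 <- sample.int(n - d + 1L, 1)
    list(rows = r0:(r0 + d - 1L), cols = c0:(c0 + w - 1L))
  })
}

# n x p logical missingness mask: blocks first, then independent cellwise
# missingness at `rate` over the remaining cells.
sample_missingness_mask <- function(n, p, rate, blocks) {
  miss <- matrix(runif(n * p) < rate, n, p)
  for (b in blocks) miss[b$rows, b$cols] <- TRUE
  miss
}

#' Simulate complete-case counts over a missingness grid
#'
#' For every (random rate, block count) pair, repeatedly imposes
#' block-wise then cellwise random missingness on a fully observed
#' indicator matrix and counts the fully observed rows, reporting the
#' median (and quartiles, and mean) over the replicates.
#'
#' @param spec a `"missingness_grid_spec"`.
#' @return Data frame with columns `rate`, `blocks`, `median`, `q25`,
#'   `q75`, `mean` complete-case counts; attribute `"counts"` holds the
#'   raw per-replicate counts (a list column-major over grid cells).
#' @export
simulate_missingness_grid <- function(spec) {
  stopifnot(inherits(spec, "missingness_grid_spec"))
  n <- spec$n_subjects; p <- spec$n_variables
  grid <- expand.grid(rate = spec$random_rates, blocks = spec$block_counts,
                      KEEP.OUT.ATTRS = FALSE)
  counts <- vector("list", nrow(grid))
  with_seed(spec$seed, {
    for (i in seq_len(nrow(grid))) {
      cc <- integer(spec$iterations)
      for (it in seq_len(spec$iterations)) {
        blocks <- sample_blocks(n, p, grid$blocks[i],
                                spec$block_cols, spec$block_rows)
        miss <- sample_missingness_mask(n, p, grid$rate[i], blocks)
        cc[it] <- sum(rowSums(miss) == 0L)
      }
      counts[[i]] <- cc
    }
  })
  out <- data.frame(grid,
                    median = vapply(counts, median, 0),
                    q25 = vapply(counts, function(x) unname(quantile(x, .25)), 0),
                    q75 = vapply(counts, function(x) unname(quantile(x, .75)), 0),
                    mean = vapply(counts, mean, 0))
  attr(out, "counts") <- counts
  attr(out, "spec") <- spec
  out
}

#' Project a symmetric matrix to the nearest positive-definite matrix
#'
#' Higham-style eigenvalue clipping: eigendecompose, clip eigenvalues at
#' `eigen_floor`, reconstruct, and re-symmetrize, iterating until the
#' minimum eigenvalue reaches the floor.
#'
#' @param S symmetric matrix (symmetrized with a warning when the
#'   asymmetry exceeds tolerance).
#' @param eigen_floor minimum admissible eigenvalue; default
#'   `1e-8 * max(eigenvalue)`.
#' @param max_iter safety cap on clipping rounds.
#' @return A symmetric positive-definite matrix.
#' @export
nearest_positive_definite <- function(S, eigen_floor = NULL, max_iter = 100) {
  S <- as.matrix(S)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    warning("input is not symmetric; symmetrizing")
  S <- (S + t(S)) / 2
  for (i in seq_len(max_iter)) {
    e <- eigen(S, symmetric = TRUE)
    floor_i <- if (is.null(eigen_floor)) 1e-8 * max(e$values) else eigen_floor
    if (min(e$values) >= floor_i) return(S)
    vals <- pmax(e$values, floor_i)
    S <- e$vectors %*% (vals * t(e$vectors))
    S <- (S + t(S)) / 2
  }
  S
}

#' Synthesize a factor-model covariance
#'
#' Stands in for a biobank-derived covariance: \eqn{\Sigma = \Lambda
#' \Lambda^\top + D} with seeded normal loadings and positive diagonal
#' noise, projected to positive definiteness, plus a seeded normal mean
#' vector.
#'
#' @param P number of variables.
#' @param n_factors number of latent factors (< P; 0 gives a diagonal
#'   covariance).
#' @param loading_scale standard deviation of the factor loadings.
#' @param seed integer seed.
#' @return List with `mu` (length P) and `sigma` (P x P positive
#'   definite).
#' @export
synthesize_covariance <- function(P, n_factors = 5, loading_scale = 0.6,
                                  seed = 1) {
  stopifnot(n_factors < P, n_factors >= 0)
  with_seed(seed, {
    D <- diag(runif(P, 0.5, 1.5), P)
    sigma <- if (n_factors > 0) {
      L <- matrix(rnorm(P * n_factors, sd = loading_scale), P, n_factors)
      tcrossprod(L) + D
    } else D
    sigma <- nearest_positive_definite(sigma)
    mu <- rnorm(P)
    list(mu = mu, sigma = sigma)
  })
}

#' Specification for a phenotype-prediction simulation study
#'
#' Defaults define the scaled-down study used throughout the package's
#' tests and examples: 2,000 subjects, 50 predictors (half categorical at 4
#' levels), 10 true effects, intercept -10, residual noise N(0, 2), and
#' block-wise plus random missingness tuned so that no subject is complete
#' on all predictors.
#'
#' @param N sample size.
#' @param P number of predictors.
#' @param cat_levels number of levels for categorical predictors (4 or 6).
#' @param beta_increments per-level offsets (length `cat_levels - 1`) whose
#'   cumulative sums give the non-reference level effects of categorical
#'   true predictors.
#' @param prop_complete target proportion of subjects complete on all
#'   predictors (0 means "tune until no complete cases remain").
#' @param intercept outcome intercept.
#' @param n_beta number of true effects.
#' @param betas true coefficient values (length `n_beta`).
#' @param cut_candidates explicit dendrogram cut heights for the pipeline,
#'   or `NULL` to derive them from target cluster counts.
#' @param error_sd residual standard deviation.
#' @param block_count,block_cols,block_rows geometry of the imposed missing
#'   blocks over the predictor matrix.
#' @param random_missing_cells additional random predictor cells set
#'   missing before the completeness tuning.
#' @param measured_fraction fraction of subjects whose outcome is kept
#'   observed (the measured/training set).
#' @param n_factors,loading_scale synthetic covariance controls.
#' @param seed integer seed.
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(N = 2000, P = 50, cat_levels = 4,
                            beta_increments = c(1, -4, 3),
                            prop_complete = 0, intercept = -10,
                            n_beta = 10,
                            betas = c(0.5, 2, -2, 5, 5, -5, 7, 7, 7, -7),
                            cut_candidates = NULL,
                            error_sd = sqrt(2),
                            block_count = 12, block_cols = 2:5,
                            block_rows = seq(600, 1400, by = 5),
                            random_missing_cells = 0,
                            measured_fraction = 0.3,
                            n_factors = 5, loading_scale = 0.6,
                            seed = 1) {
  stopifnot(length(betas) == n_beta, prop_complete >= 0, prop_complete <= 1,
            length(beta_increments) == cat_levels - 1,
            n_beta <= P, measured_fraction > 0, measured_fraction < 1)
  if (max(block_cols) > P || max(block_rows) > N)
    stop("block geometry exceeds matrix dimensions")
  structure(as.list(environment()), class = "simulation_spec")
}

#' Simulate a partially observed phenotype table with a planted outcome
#'
#' Draws multivariate-normal rows from a synthesized factor covariance,
#' converts a seeded random half of the predictors to categorical by
#' cutting at equiprobable quantiles, builds the outcome as a linear
#' combination of the true predictors plus normal noise (categorical true
#' predictors contribute the cumulative beta-increment effect of their
#' level), imposes block-wise plus random missingness on the predictors
#' tuned toward the target complete-case proportion, and finally masks the
#' outcome outside the measured subset.
#'
#' @param spec a `"simulation_spec"`.
#' @return List with `table` (a `"pheno_table"`), and `truth`: the full
#'   outcome vector, true predictor names and their effects, the realized
#'   complete-case proportion, and the measured/unmeasured indices.
#' @export
simulate_phenotype_dataset <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  N <- spec$N; P <- spec$P
  cov <- synthesize_covariance(P, spec$n_factors, spec$loading_scale,
                               seed = spec$seed)
  with_seed(spec$seed + 1L, {
    Z <- MASS::mvrnorm(N, cov$mu, cov$sigma)
    vnames <- sprintf("V%03d", seq_len(P))
    colnames(Z) <- vnames
    cat_idx <- sort(sample.int(P, floor(P / 2)))
    beta_idx <- sort(sample.int(P, spec$n_beta))
    level_labels <- as.character(seq_len(spec$cat_levels))
    level_effects <- c(0, cumsum(spec$beta_increments))  # reference first
    dat <- as.data.frame(Z)
    eta <- rep(spec$intercept, N)
    effects <- vector("list", spec$n_beta)
    for (b in seq_len(spec$n_beta)) {
      j <- beta_idx[b]
      if (j %in% cat_idx) {
        qs <- quantile(Z[, j], probs = seq(0, 1, length.out = spec$cat_levels + 1))
        lev <- cut(Z[, j], breaks = unique(qs), labels = FALSE,
                   include.lowest = TRUE)
        eta <- eta + level_effects[lev]
        effects[[b]] <- list(variable = vnames[j], type = "categorical",
                             beta = spec$betas[b],
                             level_effects = level_effects)
      } else {
        eta <- eta + spec$betas[b] * Z[, j]
        effects[[b]] <- list(variable = vnames[j], type = "continuous",
                             beta = spec$betas[b])
      }
    }
    y_full <- eta + rnorm(N, 0, spec$error_sd)
    # categorical conversion (all chosen predictors, incl. non-true ones)
    for (j in cat_idx) {
      qs <- quantile(Z[, j], probs = seq(0, 1, length.out = spec$cat_levels + 1))
      lev <- cut(Z[, j], breaks = unique(qs), labels = FALSE,
                 include.lowest = TRUE)
      dat[[vnames[j]]] <- level_labels[lev]
    }
    # impose predictor missingness: blocks, fixed random cells, tuned rate
    blocks <- sample_blocks(N, P, spec$block_count, spec$block_cols,
                            spec$block_rows)
    base_miss <- matrix(FALSE, N, P)
    for (bl in blocks) base_miss[bl$rows, bl$cols] <- TRUE
    if (spec$random_missing_cells > 0) {
      cells <- sample.int(N * P, min(spec$random_missing_cells, N * P))
      base_miss[cells] <- TRUE
    }
    realized <- function(extra_rate) {
      miss <- base_miss
      if (extra_rate > 0) miss <- miss | matrix(runif(N * P) < extra_rate, N, P)
      miss
    }
    cc_prop <- function(miss) sum(rowSums(miss) == 0L) / N
    miss <- base_miss
    if (spec$prop_complete == 0) {
      if (cc_prop(miss) > 0) for (r in c(0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.5)) {
        miss <- realized(r)
        if (cc_prop(miss) == 0) break
      }
      if (cc_prop(miss) > 0)
        warning("could not reach zero complete cases; achieved proportion ",
                signif(cc_prop(miss), 3))
    } else if (cc_prop(base_miss) > spec$prop_complete) {
      lo <- 0; hi <- 0.9
      for (i in seq_len(20)) {
        mid <- (lo + hi) / 2
        m <- realized(mid)
        if (cc_prop(m) > spec$prop_complete) lo <- mid else hi <- mid
        miss <- m
      }
      if (abs(cc_prop(miss) - spec$prop_complete) >
          0.5 * spec$prop_complete)
        warning("achieved complete-case proportion ",
                signif(cc_prop(miss), 3), " vs target ", spec$prop_complete)
    } else if (cc_prop(base_miss) < spec$prop_complete) {
      warning("block missingness alone already leaves complete-case ",
              "proportion ", signif(cc_prop(base_miss), 3),
              " below target ", spec$prop_complete)
    }
    for (j in seq_len(P)) dat[[vnames[j]]][miss[, j]] <- NA
    # outcome masking defines the measured / unmeasured subject sets
    n_meas <- round(spec$measured_fraction * N)
    measured_idx <- sort(sample.int(N, n_meas))
    y_obs <- y_full
    y_obs[-measured_idx] <- NA
    dat$y <- y_obs
    schema <- var_schema(
      name = c(vnames, "y"),
      role = c(ifelse(seq_len(P) %in% cat_idx, "categorical", "continuous"),
               "continuous"),
      levels = c(lapply(seq_len(P), function(j)
        if (j %in% cat_idx) level_labels else NULL), list(NULL)))
    tab <- pheno_table(dat, schema, outcome = "y")
    list(table = tab,
         truth = list(y_full = y_full,
                      true_variables = vnames[beta_idx],
                      effects = effects,
                      categorical_variables = vnames[cat_idx],
                      measured_idx = measured_idx,
                      unmeasured_idx = setdiff(seq_len(N), measured_idx),
                      realized_prop_complete = cc_prop(miss),
                      spec = spec))
  })
}

#' Run a full phenotype-prediction simulation study
#'
#' Simulates a dataset, runs the complete MAGIC-LASSO pipeline, predicts
#' every subject, and scores observed-vs-predicted correlation and mean
#' squared error against the simulation truth on the missing-outcome
#' subset and on the full sample.  Where any subject is complete on all
#' predictors, a plain cross-validated group-LASSO on those complete cases
#' is fit for comparison; with zero complete cases that comparison is
#' marked not applicable.
#'
#' @param spec a `"simulation_spec"`.
#' @param seed pipeline seed (defaults to `spec$seed`).
#' @param ... further arguments passed to [magic_lasso()].
#' @return A list of class `"simulation_result"` with `corr_missing`,
#'   `mse_missing`, `corr_full`, `mse_full`, `recall` (fraction of true
#'   predictors in the final model's input ordering), the fitted
#'   `model`, and a `plain` comparison entry.
#' @export
run_simulation_study <- function(spec, seed = NULL, ...) {
  sim <- simulate_phenotype_dataset(spec)
  if (is.null(seed)) seed <- spec$seed
  model <- magic_lasso(sim$table, cut_candidates = spec$cut_candidates,
                       seed = seed, ...)
  pred <- predict(model, sim$table)
  truth <- sim$truth
  miss_idx <- truth$unmeasured_idx
  ev_miss <- evaluate_prediction(truth$y_full[miss_idx],
                                 pred$prediction[miss_idx])
  ev_full <- evaluate_prediction(truth$y_full, pred$prediction)
  retained <- model$stepwise$ordered_variables
  recall <- mean(truth$true_variables %in% retained)
  # plain group-LASSO on complete cases, where they exist
  preds_all <- predictor_names(sim$table)
  meas_cc <- complete_case_idx(sim$table, c(preds_all, "y"),
                               truth$measured_idx)
  plain <- list(applicable = FALSE, n_complete = length(meas_cc))
  if (length(meas_cc) >= 30) {
    des <- encode_groups(sim$table, preds_all, meas_cc)
    cvp <- cv_fit(des, seed = seed)
    rows_cc <- which(stats::complete.cases(
      sim$table$data[, preds_all, drop = FALSE]))
    ppred <- drop(build_design_rows(sim$table, des$col_var, des$col_level,
                                    rows_cc) %*% cvp$coefficients) +
      cvp$intercept_min
    evp <- evaluate_prediction(truth$y_full[rows_cc], ppred)
    plain <- list(applicable = TRUE, n_complete = length(meas_cc),
                  corr = evp$correlation, mse = evp$mse)
  }
  structure(list(corr_missing = ev_miss$correlation,
                 mse_missing = ev_miss$mse,
                 corr_full = ev_full$correlation,
                 mse_full = ev_full$mse,
                 recall = recall,
                 n_final_variables = length(model$variables),
                 realized_prop_complete = truth$realized_prop_complete,
                 plain = plain, model = model, spec = spec, seed = seed),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Simulation study (N = ", x$spec$N, ", P = ", x$spec$P, ")\n", sep = "")
  cat("  corr (missing set): ", round(x$corr_missing, 3),
      "   MSE: ", round(x$mse_missing, 3), "\n", sep = "")
  cat("  corr (full set):    ", round(x$corr_full, 3),
      "   MSE: ", round(x$mse_full, 3), "\n", sep = "")
  cat("  recall of true predictors: ", round(x$recall, 3), "\n", sep = "")
  cat("  plain group-LASSO: ",
      if (x$plain$applicable) paste0("corr ", round(x$plain$corr, 3))
      else "not applicable (no complete cases)", "\n", sep = "")
  invisible(x)
}
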