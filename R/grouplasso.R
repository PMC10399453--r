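# Group-LASSO machinery: dummy-group design encoding, standardization,
# penalized path fitting with warm starts, and k-fold cross-validated
# penalty selection.  The objective is the Yuan-Lin form
#   (1/2n) ||y - X beta||^2 + lambda * sum_g sqrt(p_g) ||beta_g||_2
# so a whole categorical variable (all its dummies) enters or leaves the
# model together.

#' Encode variables as a grouped design matrix
#'
#' Each categorical variable with L realized levels becomes L-1 dummy
#' columns (most frequent level as reference) forming one penalty group;
#' each continuous variable is a singleton group.  The caller restricts
#' `subject_idx` to subjects complete on the listed variables and on the
#' outcome, which becomes the response.
#'
#' @param table a `"pheno_table"` whose outcome is continuous.
#' @param variables predictor names to encode (order preserved).
#' @param subject_idx subject indices, complete on `variables` and outcome.
#' @return An object of class `"group_design"`: raw numeric design `X`
#'   (n x m), response `y`, `group` (1-based id per column), `group_names`
#'   (source variable per group), `col_var`/`col_level` column origins,
#'   and `dropped_variables` (variables degenerate in this subset).
#' @export
encode_groups <- function(table, variables, subject_idx) {
  stopifnot(length(variables) >= 1, length(subject_idx) >= 2)
  oi <- match(table$outcome, table$schema$name)
  if (table$schema$role[oi] != "continuous")
    stop("outcome '", table$outcome, "' must be continuous")
  d <- table$data[subject_idx, , drop = FALSE]
  y <- d[[table$outcome]]
  if (anyNA(y)) stop("outcome missing for some listed subjects")
  cols <- list(); col_var <- character(0); col_level <- character(0)
  group <- integer(0); group_names <- character(0)
  dropped <- character(0)
  g <- 0L
  for (v in variables) {
    si <- match(v, table$schema$name)
    if (is.na(si)) stop("unknown variable '", v, "'")
    x <- d[[v]]
    if (anyNA(x)) stop("variable '", v, "' missing for some listed subjects")
    if (table$schema$role[si] == "continuous") {
      if (sd(x) < 1e-12) { dropped <- c(dropped, v); next }
      g <- g + 1L
      cols[[length(cols) + 1L]] <- as.numeric(x)
      col_var <- c(col_var, v); col_level <- c(col_level, NA_character_)
      group <- c(group, g); group_names <- c(group_names, v)
    } else if (table$schema$role[si] == "categorical") {
      lev <- table$schema$levels[[si]]
      realized <- lev[lev %in% unique(x)]
      if (length(realized) < 2L) {
        warning("categorical '", v, "' has < 2 realized levels in subset; dropped")
        dropped <- c(dropped, v); next
      }
      counts <- table(factor(x, levels = realized))
      ref <- realized[which.max(counts)]
      others <- setdiff(realized, ref)
      g <- g + 1L
      for (l in others) {
        cols[[length(cols) + 1L]] <- as.numeric(x == l)
        col_var <- c(col_var, v); col_level <- c(col_level, l)
        group <- c(group, g)
      }
      group_names <- c(group_names, v)
    } else stop("variable '", v, "' is schema-excluded")
  }
  if (!length(cols)) stop("no usable predictor columns after encoding")
  X <- do.call(cbind, cols)
  colnames(X) <- ifelse(is.na(col_level), col_var,
                        paste0(col_var, "=", col_level))
  structure(list(X = X, y = as.numeric(y), group = group,
                 group_names = group_names, col_var = col_var,
                 col_level = col_level, n = nrow(X),
                 variables = setdiff(variables, dropped),
                 dropped_variables = dropped),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  cat("Group design: ", x$n, " subjects, ", ncol(x$X), " columns in ",
      length(x$group_names), " groups\n", sep = "")
  invisible(x)
}

# Standardize columns and orthonormalize within groups on a row subset.
# Returns the machinery needed to fit and to map coefficients back to the
# original scale.  Columns degenerate in this subset are dropped (flagged).
prepare_fit <- function(design, row_idx = NULL) {
  X <- design$X; y <- design$y
  if (!is.null(row_idx)) { X <- X[row_idx, , drop = FALSE]; y <- y[row_idx] }
  n <- nrow(X)
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  keep <- which(scale > 1e-10)
  if (!length(keep)) stop("all design columns degenerate in this subset")
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, center[keep], "-"),
              2, scale[keep], "/")
  grp_k <- design$group[keep]
  gids <- unique(grp_k)
  Xo_parts <- vector("list", length(gids))
  ogrp <- integer(0); w <- numeric(length(gids))
  backmap <- vector("list", length(gids))
  for (a in seq_along(gids)) {
    gcols <- which(grp_k == gids[a])
    Z <- Xs[, gcols, drop = FALSE]
    q0 <- qr(Z)
    r <- q0$rank
    piv <- q0$pivot[seq_len(r)]
    Zk <- Z[, piv, drop = FALSE]
    q1 <- qr(Zk)
    Q <- qr.Q(q1); R <- qr.R(q1)
    Xo_parts[[a]] <- sqrt(n) * Q
    Tmat <- backsolve(R, diag(r)) * sqrt(n)   # b_std = Tmat %*% b_ortho
    backmap[[a]] <- list(std_idx = gcols[piv], Tmat = Tmat)
    ogrp <- c(ogrp, rep(a, r))
    w[a] <- sqrt(r)
  }
  Xo <- do.call(cbind, Xo_parts)
  y_mean <- mean(y)
  list(Xo = Xo, yc = y - y_mean, ogrp = ogrp, w = w, gids = gids,
       backmap = backmap, keep = keep, center = center, scale = scale,
       y_mean = y_mean, n = n,
       flagged_degenerate = colnames(design$X)[setdiff(seq_len(ncol(X)), keep)])
}

# map ortho-scale coefficient matrix (per lambda) back to the original
# column scale of design$X; returns list(beta = m x L, intercept = L)
back_transform <- function(prep, m_total, beta_o) {
  L <- ncol(beta_o)
  n_keep <- length(prep$keep)
  beta_std <- matrix(0, n_keep, L)
  off <- 0L
  for (a in seq_along(prep$gids)) {
    r <- nrow(prep$backmap[[a]]$Tmat)
    rows <- (off + 1L):(off + r)
    beta_std[prep$backmap[[a]]$std_idx, ] <-
      prep$backmap[[a]]$Tmat %*% beta_o[rows, , drop = FALSE]
    off <- off + r
  }
  beta <- matrix(0, m_total, L)
  beta[prep$keep, ] <- beta_std / prep$scale[prep$keep]
  intercept <- prep$y_mean - drop(crossprod(beta, prep$center))
  list(beta = beta, intercept = intercept)
}

#' Smallest penalty with an all-zero solution
#'
#' Returns \eqn{\max_g \|X_g^\top y\|_2 / (n \sqrt{p_g})} on the
#' standardized, group-orthonormalized design with centered response: at
#' any penalty at or above this value the all-zero coefficient vector
#' satisfies the optimality conditions.
#'
#' @param design a `"group_design"`.
#' @param row_idx optional row subset.
#' @return Scalar; 0 when the response has zero variance.
#' @export
lambda_max <- function(design, row_idx = NULL) {
  prep <- prepare_fit(design, row_idx)
  if (sd(prep$yc) < 1e-14) return(0)
  score <- drop(crossprod(prep$Xo, prep$yc)) / prep$n
  max(vapply(seq_along(prep$gids), function(a)
    sqrt(sum(score[prep$ogrp == a]^2)) / prep$w[a], 0))
}

default_lambda_path <- function(lmax, nlambda = 100, min_ratio = 1e-4) {
  if (lmax <= 0) return(0)
  lmax * exp(seq(0, log(min_ratio), length.out = nlambda))
}

#' Fit the group-LASSO along a penalty path
#'
#' Block coordinate descent with warm starts on the standardized,
#' within-group orthonormalized design; coefficients are returned both on
#' that internal scale and back-transformed to the original data scale.
#'
#' @param design a `"group_design"`.
#' @param lambda decreasing positive penalty sequence; default 100
#'   log-spaced values from `lambda_max` down to
#'   `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio path controls when `lambda` is `NULL`;
#'   when the design has at least as many columns as rows the ratio is
#'   floored at 0.05, since the unpenalized limit is then not unique.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param maxit maximum coordinate-descent sweeps per path point.
#' @param row_idx optional row subset to fit on.
#' @return An object of class `"grplasso_fit"`.
#' @export
fit_path <- function(design, lambda = NULL, nlambda = 100,
                     lambda_min_ratio = 1e-4, tol = 1e-7, maxit = 10000,
                     row_idx = NULL) {
  prep <- prepare_fit(design, row_idx)
  if (is.null(lambda)) {
    lmax <- if (sd(prep$yc) < 1e-14) 0 else {
      sc <- drop(crossprod(prep$Xo, prep$yc)) / prep$n
      max(vapply(seq_along(prep$gids), function(a)
        sqrt(sum(sc[prep$ogrp == a]^2)) / prep$w[a], 0))
    }
    if (prep$n <= ncol(prep$Xo))
      lambda_min_ratio <- max(lambda_min_ratio, 0.05)
    lambda <- default_lambda_path(lmax, nlambda, lambda_min_ratio)
  } else {
    if (any(diff(lambda) > 0)) stop("lambda must be decreasing")
    if (any(lambda < 0)) stop("lambda must be non-negative")
  }
  sol <- grplasso_path_cpp(prep$Xo, prep$yc, as.integer(prep$ogrp - 1L),
                           prep$w, lambda, tol, as.integer(maxit))
  if (!all(sol$converged))
    warning(sum(!sol$converged), " path point(s) did not converge in ",
            maxit, " sweeps")
  bt <- back_transform(prep, ncol(design$X), sol$beta)
  G <- length(prep$gids)
  gnorm <- matrix(0, G, length(lambda))
  for (a in seq_len(G))
    gnorm[a, ] <- sqrt(colSums(sol$beta[prep$ogrp == a, , drop = FALSE]^2))
  rownames(gnorm) <- design$group_names[prep$gids]
  structure(list(lambda = lambda, beta = bt$beta, intercept = bt$intercept,
                 group_norm = gnorm, group_ids = prep$gids,
                 beta_ortho = sol$beta, prep = prep,
                 iters = sol$iters, converged = sol$converged,
                 col_var = design$col_var, col_level = design$col_level,
                 group_names = design$group_names, tol = tol),
            class = "grplasso_fit")
}

#' @export
print.grplasso_fit <- function(x, ...) {
  cat("Group-LASSO path: ", length(x$lambda), " lambda values, ",
      nrow(x$group_norm), " groups, n = ", x$prep$n, "\n", sep = "")
  invisible(x)
}

# linear predictor on the original scale for path column `index`
predict_at <- function(fit, X, index) {
  drop(X %*% fit$beta[, index]) + fit$intercept[index]
}

# maximum KKT violation at path point `index` (internal; used as a
# correctness probe).  Active groups must satisfy the stationarity
# equation, inactive groups the subgradient bound.
kkt_violation <- function(fit, index) {
  prep <- fit$prep
  b <- fit$beta_ortho[, index]
  r <- prep$yc - prep$Xo %*% b
  score <- drop(crossprod(prep$Xo, r)) / prep$n
  lam <- fit$lambda[index]
  viol <- 0
  for (a in seq_along(prep$gids)) {
    idx <- prep$ogrp == a
    sg <- score[idx]; bg <- b[idx]
    nb <- sqrt(sum(bg^2))
    if (nb > 0) {
      v <- max(abs(sg - lam * prep$w[a] * bg / nb))
    } else {
      v <- max(0, sqrt(sum(sg^2)) - lam * prep$w[a])
    }
    viol <- max(viol, v)
  }
  viol
}

# objective value at path point `index`, on the internal scale
grplasso_objective <- function(fit, index) {
  prep <- fit$prep
  b <- fit$beta_ortho[, index]
  r <- prep$yc - prep$Xo %*% b
  pen <- sum(vapply(seq_along(prep$gids), function(a)
    prep$w[a] * sqrt(sum(b[prep$ogrp == a]^2)), 0))
  sum(r^2) / (2 * prep$n) + fit$lambda[index] * pen
}

#' Cross-validated group-LASSO
#'
#' Fits the full penalty path, estimates per-penalty prediction error by
#' k-fold cross-validation (fold assignment deterministic given `seed`;
#' each fold refits including standardization), and selects the penalty
#' with minimal mean held-out squared error, preferring the larger penalty
#' on ties.
#'
#' @inheritParams fit_path
#' @param k number of folds (>= 2; `k = n` gives leave-one-out).
#' @param seed integer seed controlling fold assignment.
#' @return An object of class `"cv_grplasso"`: the full-data path fit plus
#'   `cvm`, `cvse`, `lambda_min`, `index_min`, `coefficients`/`intercept`
#'   at the selected penalty, and `selected_groups`.
#' @export
cv_fit <- function(design, k = 5, lambda = NULL, nlambda = 100,
                   lambda_min_ratio = 1e-4, tol = 1e-7, maxit = 10000,
                   seed = 1) {
  n <- design$n
  stopifnot(k >= 2, n >= k)
  full <- fit_path(design, lambda, nlambda, lambda_min_ratio, tol, maxit)
  lambda <- full$lambda
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  L <- length(lambda)
  sqerr <- matrix(NA_real_, n, L)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    ft <- fit_path(design, lambda = lambda, tol = tol, maxit = maxit,
                   row_idx = train)
    pred <- design$X[test, , drop = FALSE] %*% ft$beta
    pred <- sweep(pred, 2, ft$intercept, "+")
    sqerr[test, ] <- (design$y[test] - pred)^2
  }
  cvm <- colMeans(sqerr)
  fold_means <- rowsum(sqerr, folds) / as.vector(table(folds))
  cvse <- apply(fold_means, 2, sd) / sqrt(k)
  index_min <- which.min(cvm)          # first index = largest lambda on ties
  out <- full
  out$k <- k
  out$seed <- seed
  out$folds <- folds
  out$cvm <- cvm
  out$cvse <- cvse
  out$index_min <- index_min
  out$lambda_min <- lambda[index_min]
  out$coefficients <- stats::setNames(full$beta[, index_min],
                                      colnames(design$X))
  out$intercept_min <- full$intercept[index_min]
  sel <- rownames(full$group_norm)[full$group_norm[, index_min] > 0]
  out$selected_groups <- sel
  class(out) <- c("cv_grplasso", "grplasso_fit")
  out
}

#' @export
print.cv_grplasso <- function(x, ...) {
  cat("Cross-validated group-LASSO (k = ", x$k, "): lambda_min = ",
      signif(x$lambda_min, 4), ", CV MSE = ", signif(x$cvm[x$index_min], 4),
      ", ", length(x$selected_groups), " groups selected\n", sep = "")
  invisible(x)
}

#' Source variables retained by a cross-validated fit
#'
#' Variables whose coefficient group has a strictly positive L2 norm at the
#' selected penalty (an exact zero test on the solver's sparse solution).
#'
#' @param fit a `"cv_grplasso"`.
#' @return Character vector of variable names.
#' @export
retained_variables <- function(fit) {
  stopifnot(inherits(fit, "cv_grplasso"))
  fit$selected_groups
}

# evaluate a seeded expression without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
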