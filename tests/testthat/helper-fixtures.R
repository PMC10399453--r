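# Fixtures and independent oracles used across the suite.

# small continuous-only table with seeded random missingness
random_table <- function(n = 20, p = 5, miss_rate = 0.2, seed = 1,
                         outcome_miss = 0.3) {
  set.seed(seed)
  dat <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(dat) <- paste0("x", seq_len(p))
  for (j in seq_len(p))
    dat[[j]][runif(n) < miss_rate] <- NA
  dat$y <- rnorm(n)
  dat$y[runif(n) < outcome_miss] <- NA
  sch <- magiclasso::var_schema(c(names(dat)), "continuous")
  magiclasso::pheno_table(dat, sch, outcome = "y")
}

# table with planted linear signal, optional missingness, continuous only
planted_table <- function(n = 200, p = 8, n_true = 3, beta = 2,
                          sigma = 1, miss_rate = 0, seed = 1,
                          outcome_miss = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("x", seq_len(p))
  y <- drop(X[, seq_len(n_true), drop = FALSE] %*% rep(beta, n_true)) +
    rnorm(n, 0, sigma)
  dat <- as.data.frame(X)
  if (miss_rate > 0)
    for (j in seq_len(p)) dat[[j]][runif(n) < miss_rate] <- NA
  dat$y <- y
  if (outcome_miss > 0) dat$y[runif(n) < outcome_miss] <- NA
  sch <- magiclasso::var_schema(names(dat), "continuous")
  list(table = magiclasso::pheno_table(dat, sch, outcome = "y"),
       y_full = y, true_vars = paste0("x", seq_len(n_true)))
}

# --- independent UPGMA oracle -----------------------------------------
# Naive O(P^3) average linkage: keeps explicit member lists and recomputes
# every cross-pair mean from the ORIGINAL distances at each step, with the
# same lowest-index-pair tie-break.
upgma_naive <- function(D) {
  D <- as.matrix(D)
  p <- nrow(D)
  clusters <- as.list(seq_len(p))           # member leaf indices
  ids <- -seq_len(p)
  merge <- matrix(0L, p - 1, 2)
  height <- numeric(p - 1)
  for (s in seq_len(p - 1)) {
    k <- length(clusters)
    best <- Inf; bi <- bj <- 0L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      d <- mean(D[clusters[[i]], clusters[[j]]])
      if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
    }
    merge[s, ] <- sort(c(ids[bi], ids[bj]))
    height[s] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
    ids[bi] <- s
    ids <- ids[-bj]
  }
  list(merge = merge, height = height)
}

# --- independent proximal-gradient group-LASSO oracle -----------------
# ISTA on (1/2n)||y - X b||^2 + lambda * sum_g w_g ||b_g||, run to a tight
# fixed-point tolerance.  Independent of the coordinate-descent solver.
prox_grplasso <- function(X, y, grp, w, lambda, max_steps = 200000,
                          tol = 1e-12) {
  n <- nrow(X)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  step <- 1 / L
  b <- rep(0, ncol(X))
  gids <- sort(unique(grp))
  for (it in seq_len(max_steps)) {
    grad <- -crossprod(X, y - X %*% b) / n
    z <- b - step * drop(grad)
    bn <- z
    for (a in seq_along(gids)) {
      idx <- grp == gids[a]
      nz <- sqrt(sum(z[idx]^2))
      thr <- step * lambda * w[a]
      bn[idx] <- if (nz > thr) (1 - thr / nz) * z[idx] else 0
    }
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn
  }
  b
}

prox_objective <- function(X, y, grp, w, lambda, b) {
  n <- nrow(X)
  gids <- sort(unique(grp))
  pen <- sum(vapply(seq_along(gids), function(a)
    w[a] * sqrt(sum(b[grp == gids[a]]^2)), 0))
  sum((y - X %*% b)^2) / (2 * n) + lambda * pen
}

# brute-force complete-case count: explicit row scan
brute_complete_cases <- function(table, variables) {
  d <- table$data[, variables, drop = FALSE]
  cnt <- 0L
  for (i in seq_len(nrow(d)))
    if (!anyNA(unlist(d[i, ]))) cnt <- cnt + 1L
  cnt
}
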