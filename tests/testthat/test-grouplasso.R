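# fully observed fixture with one categorical and several continuous
# predictors, planted signal on the first continuous variable
grouped_fixture <- function(n = 120, seed = 1, levels = 4, signal = 2) {
  set.seed(seed)
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  dat$g <- as.character(sample(seq_len(levels), n, TRUE))
  dat$y <- signal * dat$x1 + rnorm(n)
  sch <- var_schema(names(dat),
                    c("continuous", "continuous", "continuous",
                      "categorical", "continuous"),
                    levels = list(NULL, NULL, NULL,
                                  as.character(seq_len(levels)), NULL))
  pheno_table(dat, sch, "y")
}

test_that("encoding produces the expected dummy-group structure", {
  tab <- grouped_fixture(n = 80, seed = 2, levels = 4)
  idx <- seq_len(80)
  # 2 continuous variables -> 2 singleton groups
  d2 <- encode_groups(tab, c("x1", "x2"), idx)
  expect_equal(ncol(d2$X), 2)
  expect_equal(d2$group, c(1L, 2L))
  # one 4-level categorical -> 3 dummies in one group
  d4 <- encode_groups(tab, "g", idx)
  expect_equal(ncol(d4$X), 3)
  expect_equal(unique(d4$group), 1L)
  # reference level is the most frequent one (not among the dummies)
  ref <- names(which.max(table(tab$data$g)))
  expect_false(ref %in% d4$col_level)
  # one 6-level categorical + 3 continuous -> m = 8, sizes (5,1,1,1)
  tab6 <- grouped_fixture(n = 200, seed = 3, levels = 6)
  d8 <- encode_groups(tab6, c("g", "x1", "x2", "x3"), seq_len(200))
  expect_equal(ncol(d8$X), 8)
  expect_equal(as.vector(table(d8$group)), c(5L, 1L, 1L, 1L))
  # a categorical collapsing to one realized level is dropped with warning
  tab1 <- grouped_fixture(n = 60, seed = 4, levels = 4)
  rows1 <- which(tab1$data$g == tab1$data$g[1])
  expect_warning(d1 <- encode_groups(tab1, c("g", "x1"), rows1),
                 "realized levels")
  expect_identical(d1$dropped_variables, "g")
})

test_that("lambda_max bounds the all-zero solution region", {
  tab <- grouped_fixture(n = 60, seed = 5)
  des <- encode_groups(tab, c("x1", "x2", "x3", "g"), seq_len(60))
  lm0 <- lambda_max(des)
  expect_gt(lm0, 0)
  fit_hi <- fit_path(des, lambda = lm0 * 1.01)
  expect_true(all(fit_hi$beta == 0))
  fit_lo <- fit_path(des, lambda = lm0 * 0.99)
  expect_true(any(fit_lo$beta != 0))
  # zero-variance response
  tab$data$y <- rep(1, 60)
  des0 <- encode_groups(tab, c("x1", "x2"), seq_len(60))
  expect_equal(lambda_max(des0), 0)
})

test_that("unpenalized limit matches ordinary least squares", {
  tab <- grouped_fixture(n = 100, seed = 6)
  des <- encode_groups(tab, c("x1", "x2", "x3", "g"), seq_len(100))
  lm0 <- lambda_max(des)
  fit <- fit_path(des, lambda = lm0 * 10^seq(0, -8, length.out = 60),
                  tol = 1e-12, maxit = 50000)
  L <- length(fit$lambda)
  ols <- stats::lm.fit(cbind(1, des$X), des$y)$coefficients
  expect_equal(unname(fit$beta[, L]), unname(ols[-1]), tolerance = 1e-6)
  expect_equal(fit$intercept[L], unname(ols[1]), tolerance = 1e-6)
})

test_that("path solutions match an independent proximal-gradient oracle", {
  # n = 50, two groups of 3, fixed seed
  set.seed(7)
  n <- 50
  dat <- data.frame(a = as.character(sample(1:4, n, TRUE)),
                    b = as.character(sample(1:4, n, TRUE)))
  dat$y <- (dat$a == "2") * 2 - (dat$b == "3") * 1.5 + rnorm(n)
  sch <- var_schema(names(dat), c("categorical", "categorical", "continuous"),
                    levels = list(as.character(1:4), as.character(1:4), NULL))
  tab <- pheno_table(dat, sch, "y")
  des <- encode_groups(tab, c("a", "b"), seq_len(n))
  expect_equal(as.vector(table(des$group)), c(3L, 3L))
  lm0 <- lambda_max(des)
  path <- lm0 * c(0.75, 0.5, 0.25, 0.1)
  fit <- fit_path(des, lambda = path, tol = 1e-12, maxit = 100000)
  prep <- fit$prep
  for (i in seq_along(path)) {
    b_ora <- prox_grplasso(prep$Xo, prep$yc, prep$ogrp, prep$w, path[i])
    obj_ora <- prox_objective(prep$Xo, prep$yc, prep$ogrp, prep$w, path[i],
                              b_ora)
    obj_fit <- magiclasso:::grplasso_objective(fit, i)
    expect_lt(abs(obj_fit - obj_ora) / abs(obj_ora), 1e-4)
  }
})

test_that("KKT conditions hold at every path point", {
  tab <- grouped_fixture(n = 90, seed = 8)
  des <- encode_groups(tab, c("x1", "x2", "x3", "g"), seq_len(90))
  fit <- fit_path(des, nlambda = 40, tol = 1e-10, maxit = 50000)
  for (i in seq_along(fit$lambda))
    expect_lt(magiclasso:::kkt_violation(fit, i), 1e-6)
})

test_that("back-transformed coefficients reproduce internal predictions", {
  tab <- grouped_fixture(n = 70, seed = 9)
  des <- encode_groups(tab, c("x1", "g", "x2"), seq_len(70))
  fit <- fit_path(des, nlambda = 20)
  i <- 12
  prep <- fit$prep
  pred_internal <- prep$y_mean + drop(prep$Xo %*% fit$beta_ortho[, i])
  pred_original <- drop(des$X %*% fit$beta[, i]) + fit$intercept[i]
  expect_equal(pred_original, pred_internal, tolerance = 1e-9)
})

test_that("cross-validation selects planted signal and is seed-stable", {
  # planted single strong group
  tab <- grouped_fixture(n = 300, seed = 10, signal = 3)
  des <- encode_groups(tab, c("x1", "x2", "x3", "g"), seq_len(300))
  for (s in c(1, 2, 3)) {
    cvf <- cv_fit(des, k = 5, seed = s)
    expect_true("x1" %in% retained_variables(cvf))
  }
  # reproducibility under a fixed seed
  f1 <- cv_fit(des, k = 5, seed = 4)
  f2 <- cv_fit(des, k = 5, seed = 4)
  expect_identical(f1$cvm, f2$cvm)
  expect_identical(f1$coefficients, f2$coefficients)
  # pure-noise response: held-out error close to Var(y), selection sparse
  set.seed(11)
  tabn <- grouped_fixture(n = 500, seed = 11, signal = 0)
  desn <- encode_groups(tabn, c("x1", "x2", "x3", "g"), seq_len(500))
  cvn <- cv_fit(desn, k = 5, seed = 1)
  expect_lt(abs(cvn$cvm[cvn$index_min] - var(desn$y)) / var(desn$y), 0.2)
  # leave-one-out boundary: finite, reproducible
  tab12 <- grouped_fixture(n = 12, seed = 12)
  des12 <- encode_groups(tab12, c("x1", "x2"), seq_len(12))
  l1 <- cv_fit(des12, k = 12, seed = 2)
  l2 <- cv_fit(des12, k = 12, seed = 2)
  expect_true(all(is.finite(l1$cvm)))
  expect_identical(l1$cvm, l2$cvm)
})

test_that("retained variables are groups with non-zero norm", {
  tab <- grouped_fixture(n = 150, seed = 13, signal = 2.5)
  des <- encode_groups(tab, c("x1", "g", "x2"), seq_len(150))
  cvf <- cv_fit(des, k = 5, seed = 1)
  nz_groups <- rownames(cvf$group_norm)[cvf$group_norm[, cvf$index_min] > 0]
  expect_setequal(retained_variables(cvf), nz_groups)
  # whole categorical retained if any dummy non-zero
  g_cols <- which(des$col_var == "g")
  if (any(cvf$coefficients[g_cols] != 0))
    expect_true("g" %in% retained_variables(cvf))
  # all-zero fit -> nothing retained
  cv0 <- cv_fit(des, k = 5, lambda = c(lambda_max(des) * 2,
                                       lambda_max(des) * 1.5), seed = 1)
  expect_length(retained_variables(cv0), 0)
})
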