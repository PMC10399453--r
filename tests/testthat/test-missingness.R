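test_that("missingness profile matches exhaustive enumeration", {
  # 4 subjects; A missing in {1,2}, B missing in {2,3}, C fully observed
  dat <- data.frame(A = c(NA, NA, 3, 4), B = c(1, NA, NA, 4),
                    C = c(1, 2, 3, 4), y = c(1, 2, NA, 4))
  tab <- pheno_table(dat, var_schema(names(dat), "continuous"), "y")
  prof <- profile_missingness(tab, c("A", "B", "C"))
  # brute-force row scan: both A and B observed only in row 4
  expect_identical(prof$pairwise_complete["A", "B"], 1L)
  expect_identical(prof$pairwise_complete["A", "C"], 2L)
  expect_identical(prof$pairwise_complete["B", "C"], 2L)
  expect_identical(diag(prof$pairwise_complete),
                   c(A = 2L, B = 2L, C = 4L))
  # constant indicator (C) -> undefined correlation, flagged as NA
  expect_true(all(is.na(prof$miss_corr["C", ])))
  expect_true(isSymmetric(prof$pairwise_complete))
})

test_that("profile invariants hold on a fully observed table", {
  dat <- as.data.frame(matrix(rnorm(21), 7, 3))
  names(dat) <- c("a", "b", "y")
  tab <- pheno_table(dat, var_schema(names(dat), "continuous"), "y")
  prof <- profile_missingness(tab)
  expect_true(all(prof$pairwise_complete == 7L))
  expect_true(all(is.na(prof$miss_corr)))   # all indicators constant
})

test_that("identical and complementary missingness patterns give +1/-1", {
  dat <- data.frame(p = c(NA, 1, NA, 2), q = c(NA, 3, NA, 4),
                    r = c(5, NA, 6, NA), y = 1:4)
  tab <- pheno_table(dat, var_schema(names(dat), "continuous"), "y")
  prof <- profile_missingness(tab, c("p", "q", "r"))
  expect_equal(prof$miss_corr["p", "q"], 1)
  expect_equal(prof$miss_corr["p", "r"], -1)
  expect_true(all(abs(prof$miss_corr) <= 1, na.rm = TRUE))
})

test_that("complete_case_count agrees with a brute-force row scan", {
  tab <- random_table(n = 20, p = 5, miss_rate = 0.25, seed = 11)
  vars <- paste0("x", 1:5)
  expect_equal(complete_case_count(tab, vars), brute_complete_cases(tab, vars))
  # single variable reduces to the profile's observed count
  prof <- profile_missingness(tab, vars)
  for (v in vars)
    expect_equal(complete_case_count(tab, v),
                 unname(prof$observed_count[v]))
  # all-variables count equals fully observed row count from the profile
  expect_equal(complete_case_count(tab, vars),
               sum(rowSums(!prof$indicator) == 0))
  expect_error(complete_case_count(tab, "nope"), "unknown")
  expect_error(complete_case_count(tab, character(0)), "empty")
})

test_that("general filter drops sparse, excluded, invariant and thin-level variables", {
  n <- 100
  set.seed(3)
  dat <- data.frame(
    ok1 = rnorm(n), ok2 = rnorm(n),
    sparse = c(rnorm(10), rep(NA, n - 10)),        # 90% missing
    flat = rep(1, n),                               # invariant
    note = sample(c("a", "b"), n, TRUE),            # schema-excluded
    thin = c(rep("a", n - 2), "b", "b"),            # level with 2 subjects
    y = rnorm(n))
  sch <- var_schema(names(dat),
                    c("continuous", "continuous", "continuous",
                      "continuous", "excluded", "categorical", "continuous"),
                    levels = list(NULL, NULL, NULL, NULL, NULL,
                                  c("a", "b"), NULL),
                    exclusion_reason = c("none", "none", "none", "none",
                                         "free_text", "none", "none"))
  tab <- pheno_table(dat, sch, "y")
  rep1 <- filter_general(tab, min_level_count = 5)
  expect_setequal(rep1$keep, c("ok1", "ok2"))
  expect_setequal(rep1$removed$rule,
                  c("sparse", "invariant", "excluded:free_text",
                    "sparse_level"))
  # 85% missing variable dropped at the default 80% threshold
  dat2 <- data.frame(v = c(rnorm(15), rep(NA, 85)), z = rnorm(100),
                     y = rnorm(100))
  tab2 <- pheno_table(dat2, var_schema(names(dat2), "continuous"), "y")
  expect_false("v" %in% filter_general(tab2)$keep)
  # idempotence: filtering the retained set changes nothing
  tab_f <- magiclasso:::subset_variables(tab, rep1$keep)
  rep2 <- filter_general(tab_f, min_level_count = 5)
  expect_identical(rep2$keep, rep1$keep)
  # dropping everything is a hard error
  dat3 <- data.frame(flat = rep(1, 10), y = rnorm(10))
  tab3 <- pheno_table(dat3, var_schema(names(dat3), "continuous"), "y")
  expect_error(filter_general(tab3), "every predictor")
})

test_that("balance filter computes tau and applies the symmetric rule", {
  # 20 measured + 20 unmeasured subjects
  set.seed(5)
  n <- 40
  y <- c(rnorm(20), rep(NA, 20))
  even <- rnorm(n); even[sample(1:20, 10)] <- NA; even[20 + sample(1:20, 10)] <- NA
  skew <- rnorm(n); skew[sample(1:20, 2)] <- NA; skew[20 + sample(1:20, 14)] <- NA
  full <- rnorm(n)
  dat <- data.frame(even = even, skew = skew, full = full, y = y)
  tab <- pheno_table(dat, var_schema(names(dat), "continuous"), "y")
  sp <- split_measured(tab)
  rep <- balance_filter(tab, sp, t = 0.7)
  # even: 50% observed in both halves -> tau 1, kept
  expect_equal(rep$tau[rep$variable == "even"], 1)
  expect_true(rep$keep[rep$variable == "even"])
  # skew: 0.9 vs 0.3 -> tau 3, min(tau, 1/tau) = 1/3 < 0.7 -> dropped
  expect_equal(rep$tau[rep$variable == "skew"], 3)
  expect_false(rep$keep[rep$variable == "skew"])
  # fully observed -> tau 1, kept
  expect_equal(rep$tau[rep$variable == "full"], 1)
  expect_true(rep$keep[rep$variable == "full"])
  # one-sided literal rule keeps tau = 3 (only filters tau < t)
  rep1s <- balance_filter(tab, sp, t = 0.7, symmetric = FALSE)
  expect_true(rep1s$keep[rep1s$variable == "skew"])
  # undefined tau (never observed in unmeasured set) -> dropped
  dat$never <- c(rnorm(20), rep(NA, 20))
  tab2 <- pheno_table(dat, var_schema(names(dat), "continuous"), "y")
  rep2 <- balance_filter(tab2, split_measured(tab2), t = 0.7)
  expect_true(is.na(rep2$tau[rep2$variable == "never"]))
  expect_false(rep2$keep[rep2$variable == "never"])
  # no unmeasured subjects -> hard error
  dat3 <- data.frame(x = rnorm(5), y = rnorm(5))
  tab3 <- pheno_table(dat3, var_schema(names(dat3), "continuous"), "y")
  expect_error(balance_filter(tab3, split_measured(tab3)), "unmeasured")
})

test_that("balance keep-set is monotone in the threshold t", {
  tab <- random_table(n = 60, p = 6, miss_rate = 0.3, seed = 9,
                      outcome_miss = 0.4)
  sp <- split_measured(tab)
  kept_prev <- NULL
  for (t in c(0.2, 0.5, 0.7, 0.9, 1.0)) {
    rep <- balance_filter(tab, sp, t = t)
    kept <- rep$variable[rep$keep]
    if (!is.null(kept_prev)) expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }
})
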