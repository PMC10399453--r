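test_that("missingness distance is Euclidean over pairwise-count rows", {
  # hand-checkable: rows (3,3,0) and (3,0,3) -> sqrt(0+9+9)
  prof <- structure(list(
    pairwise_complete = matrix(c(3, 3, 0, 3, 3, 0, 0, 0, 3), 3, 3,
                               dimnames = list(c("a", "b", "c"),
                                               c("a", "b", "c"))),
    n_subjects = 3), class = "miss_profile")
  prof$pairwise_complete[, "b"] <- c(3, 3, 0)
  prof$pairwise_complete["c", ] <- c(3, 0, 3)
  prof$pairwise_complete[, "c"] <- c(3, 0, 3)
  # rows: a = (3,3,3)?  construct directly instead:
  pc <- rbind(a = c(3, 3, 0), b = c(3, 3, 0), c = c(3, 0, 3))
  colnames(pc) <- c("a", "b", "c")
  prof$pairwise_complete <- pc
  d <- missingness_distance(prof)
  expect_equal(d["a", "b"], 0)           # identical rows
  expect_equal(d["b", "c"], sqrt(18))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_true(isSymmetric(d))
})

test_that("distance satisfies the triangle inequality on random fixtures", {
  for (seed in 1:4) {
    tab <- random_table(n = 25, p = 8, miss_rate = 0.35, seed = seed)
    d <- missingness_distance(profile_missingness(tab, paste0("x", 1:8)))
    p <- nrow(d)
    for (i in 1:p) for (j in 1:p) for (k in 1:p)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
  }
})

test_that("UPGMA reproduces hand computations", {
  # 2 leaves at distance d -> single merge at height d
  d2 <- matrix(c(0, 3.5, 3.5, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 3.5)
  # d(A,B)=2, d(A,C)=4, d(B,C)=6: merge (A,B) at 2, then C at (4+6)/2 = 5
  d3 <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(t3$height, c(2, 5))
  expect_identical(t3$merge[1, ], c(-2L, -1L))
  expect_identical(t3$merge[2, ], c(-3L, 1L))
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(upgma(-d2), "negative")
})

test_that("UPGMA agrees with a naive re-implementation and with hclust", {
  for (seed in 1:25) {
    set.seed(seed)
    p <- sample(4:12, 1)
    x <- matrix(rnorm(p * 3), p)
    D <- as.matrix(dist(x))
    dimnames(D) <- list(paste0("v", 1:p), paste0("v", 1:p))
    fast <- upgma(D)
    ref <- upgma_naive(D)
    expect_equal(fast$height, ref$height, tolerance = 1e-10)
    expect_identical(fast$merge, ref$merge)
    hc <- hclust(as.dist(D), method = "average")
    expect_equal(sort(fast$height), sort(hc$height), tolerance = 1e-10)
  }
})

test_that("merge heights are non-decreasing and stable under relabeling", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- 9
    D <- as.matrix(dist(matrix(rnorm(p * 2), p)))
    dimnames(D) <- list(paste0("v", 1:p), paste0("v", 1:p))
    t1 <- upgma(D)
    expect_true(all(diff(t1$height) >= -1e-12))
    perm <- sample(p)
    Dp <- D[perm, perm]
    t2 <- upgma(Dp)
    # same partition at any height, labels aside
    prof <- list(indicator = matrix(TRUE, 4, p,
                                    dimnames = list(NULL, rownames(D))),
                 observed_count = setNames(rep(4, p), rownames(D)),
                 n_subjects = 4)
    class(prof) <- "miss_profile"
    for (h in quantile(t1$height, c(.25, .6, .9))) {
      m1 <- cut_tree(t1, h, prof)$membership
      m2 <- cut_tree(t2, h, prof)$membership[names(m1)]
      # partitions equal up to cluster relabeling
      expect_equal(length(unique(m1)), length(unique(m2)))
      expect_true(all(table(m1, m2) %in%
                        c(0, table(m1)[as.character(unique(m1))])))
    }
  }
})

test_that("cut_tree boundary cases and diagnostics are correct", {
  tab <- random_table(n = 30, p = 6, miss_rate = 0.3, seed = 2)
  vars <- paste0("x", 1:6)
  prof <- profile_missingness(tab, vars)
  dend <- upgma(missingness_distance(prof))
  # height 0 -> all singletons, complete cases = observed counts
  c0 <- cut_tree(dend, 0, prof)
  expect_equal(nrow(c0$diagnostics), 6)
  expect_equal(sort(c0$diagnostics$complete_cases),
               sort(unname(prof$observed_count)))
  # height above the last merge -> one cluster with all variables
  c1 <- cut_tree(dend, max(dend$height) * 1.1, prof)
  expect_equal(nrow(c1$diagnostics), 1)
  expect_equal(c1$diagnostics$complete_cases,
               complete_case_count(tab, vars))
  # three-leaf hand tree cut between the merges -> {A,B}, {C}
  d3 <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  prof3 <- structure(list(indicator = matrix(TRUE, 5, 3,
                            dimnames = list(NULL, c("A", "B", "C"))),
                          observed_count = c(A = 5, B = 5, C = 5),
                          n_subjects = 5), class = "miss_profile")
  cc <- cut_tree(t3, 3, prof3)
  mem <- cc$membership
  expect_equal(mem[["A"]], mem[["B"]])
  expect_false(mem[["A"]] == mem[["C"]])
})

test_that("cuts at increasing heights form a coarsening", {
  tab <- random_table(n = 40, p = 10, miss_rate = 0.4, seed = 6)
  vars <- paste0("x", 1:10)
  prof <- profile_missingness(tab, vars)
  dend <- upgma(missingness_distance(prof))
  hs <- sort(c(quantile(dend$height, c(.3, .7)), max(dend$height) + 1))
  prev <- NULL
  for (h in hs) {
    mem <- cut_tree(dend, h, prof)$membership
    if (!is.null(prev)) {
      # every earlier cluster lies inside one later cluster
      for (k in unique(prev)) {
        vs <- names(prev)[prev == k]
        expect_equal(length(unique(mem[vs])), 1)
      }
    }
    prev <- mem
  }
})

test_that("cut-height evaluation flags clusters without complete cases", {
  # two co-missing blocks with no common complete row
  n <- 40
  dat <- data.frame(a1 = rnorm(n), a2 = rnorm(n), b1 = rnorm(n),
                    b2 = rnorm(n), y = rnorm(n))
  dat$a1[1:20] <- NA; dat$a2[1:20] <- NA
  dat$b1[21:40] <- NA; dat$b2[21:40] <- NA
  tab <- pheno_table(dat, var_schema(names(dat), "continuous"), "y")
  vars <- c("a1", "a2", "b1", "b2")
  prof <- profile_missingness(tab, vars)
  dend <- upgma(missingness_distance(prof))
  ev <- evaluate_cut_heights(dend, prof, c(0, quantile(dend$height, .5),
                                           max(dend$height) + 1))
  expect_true(all(diff(ev$n_clusters) <= 0))
  # the single all-variable cluster has zero complete cases and is flagged
  expect_equal(ev$n_zero_complete[nrow(ev)], 1)
  # candidate heights targeting k clusters hit those counts
  cands <- cut_candidates_for_k(dend, c(2, 4))
  ev2 <- evaluate_cut_heights(dend, prof, cands)
  expect_setequal(ev2$n_clusters, c(2, 4))
})

test_that("newick export produces a parseable ultrametric tree", {
  skip_if_not_installed("ape")
  d3 <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  nwk <- export_newick(upgma(d3))
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
})
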