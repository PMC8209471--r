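make_table <- function(n_per_group = 10, montage = c("a", "b", "c"),
                       seed = 1, pli_gen = NULL, pdc_gen = NULL) {
  set.seed(seed)
  n <- length(montage)
  labels <- rep(c("SZ", "HC"), each = n_per_group)
  pli_list <- lapply(labels, function(g) {
    v <- if (is.null(pli_gen)) matrix(runif(n * n), n, n) else pli_gen(g)
    fake_pli(v, montage)
  })
  pdc_list <- lapply(labels, function(g) {
    v <- if (is.null(pdc_gen)) matrix(runif(n * n), n, n) else pdc_gen(g)
    fake_pdc(v, montage)
  })
  build_feature_table(pli_list, pdc_list, labels)
}

test_that("feature tables fuse PLI then PDC columns with invertible descriptors", {
  set.seed(71)
  mont20 <- default_montage()
  labels <- rep(c("SZ", "HC"), each = 3)
  pli_list <- lapply(1:6, function(i) fake_pli(matrix(runif(400), 20), mont20))
  pdc_list <- lapply(1:6, function(i) fake_pdc(matrix(runif(400), 20), mont20))
  tab <- build_feature_table(pli_list, pdc_list, labels)
  expect_identical(ncol(tab$values), 570L)
  expect_identical(sum(tab$descriptors$estimator == "PLI"), 190L)
  expect_identical(sum(tab$descriptors$estimator == "PDC"), 380L)
  # column 1 is the first upper-triangle PLI pair in montage order
  expect_identical(tab$descriptors$name[1], "PLI:FP1-FP2")
  expect_identical(tab$values[3, 1], pli_list[[3]]$values["FP1", "FP2"])

  tab3 <- make_table(n_per_group = 2)
  expect_identical(ncol(tab3$values), 9L)       # 3 + 6

  bad <- fake_pdc(matrix(runif(9), 3), c("x", "y", "z"))
  expect_error(build_feature_table(pli_list, c(pdc_list[-6], list(bad)),
                                   labels), "montage")
})

test_that("Fisher scores follow the two-class ratio with degenerate guards", {
  x <- cbind(c(rep(0, 4), rep(2, 4)),       # separated means, unit-ish vars
             c(1, 2, 3, 4, 1, 2, 3, 4),     # equal means -> 0
             rep(5, 8))                     # zero variance, equal means -> 0
  y <- rep(c("g1", "g2"), each = 4)
  fr <- fisher_score(x, y)
  expect_equal(fr$scores[2], 0)
  expect_equal(fr$scores[3], 0)
  expect_identical(fr$order[1], 1L)

  # direct substitution: mu diff 2, variances 1 and 1 -> F = 2
  set.seed(72)
  v1 <- rnorm(2000); v2 <- rnorm(2000) + 2
  f <- fisher_score(cbind(c(v1, v2)), rep(c("a", "b"), each = 2000))$scores
  expect_equal(f, (mean(v1) - mean(v2))^2 / (var(v1) + var(v2)))

  # scale invariance
  xs <- cbind(x[, 1], 100 * x[, 1])
  frs <- fisher_score(xs, y)
  expect_equal(frs$scores[1], frs$scores[2])

  # zero variance with different means is capped, not infinite
  xc <- cbind(rep(c(0, 1), each = 4))
  expect_identical(fisher_score(xc, y)$scores, 1e12)

  expect_error(fisher_score(x, rep("g1", 8)), "two")
})

test_that("LOOCV SVM metrics behave on separable, chance, and skewed data", {
  set.seed(73)
  x <- rbind(matrix(rnorm(20 * 4), 20), matrix(rnorm(20 * 4, 10), 20))
  y <- rep(c("HC", "SZ"), each = 20)
  r <- loocv_svm(x, y)
  expect_equal(r$acc, 100)
  expect_equal(r$auc, 1)
  expect_identical(r$positive_class, "SZ")

  # permuted labels on informative data: mean accuracy near chance
  accs <- vapply(1:30, function(i) loocv_svm(x, sample(y))$acc, numeric(1))
  expect_lt(abs(mean(accs) - 50), 3 * sd(accs) / sqrt(30) + 5)

  expect_error(loocv_svm(x[1:21, ], y[1:21]), ">= 2")

  # the accuracy-only fast path agrees with the full LOOCV on arbitrary data
  for (s in 1:5) {
    set.seed(s)
    xr <- matrix(rnorm(14 * 3), 14)
    yr <- factor(rep(c("HC", "SZ"), 7))
    expect_equal(eegfuse:::fast_loocv_acc(xr, yr, cost = 1),
                 loocv_svm(xr, yr)$acc)
  }
})

test_that("confusion-matrix arithmetic matches its definitions", {
  labels <- factor(rep(c("SZ", "HC"), c(5, 4)))
  preds <- c("SZ", "SZ", "SZ", "SZ", "HC",  "HC", "HC", "HC", "HC")
  dvs <- c(3, 2.5, 2, 1.5, -0.5, -1, -2, -3, -4)
  met <- eegfuse:::cv_metrics(labels, preds, dvs, "SZ", n_features = 1)
  expect_equal(met$sen, 100 * 4 / 5)    # one positive missed
  expect_equal(met$spe, 100)
  expect_equal(met$acc, 100 * 8 / 9)
})

test_that("single-estimator selection finds a planted feature at small N", {
  # one informative PLI edge (a-b); everything else noise
  tab <- make_table(
    n_per_group = 10, seed = 74,
    pli_gen = function(g) {
      v <- matrix(runif(9, 0.4, 0.6), 3)
      v[1, 2] <- v[2, 1] <- if (g == "SZ") 0.95 else 0.15
      v
    })
  best <- select_and_classify_single(tab, "PLI", n_max = 3)
  expect_lte(best$selection$n_features, 3)
  expect_true("PLI:a-b" %in% best$selection$descriptors$name)
  expect_gte(best$acc, 90)

  one <- select_and_classify_single(tab, "PLI", n_max = 1)
  expect_identical(nrow(one$grid), 1L)
  expect_error(select_and_classify_single(tab, "PLI", n_max = 0), "n_max")
  expect_error(select_and_classify_single(tab, "PLI", n_max = 99), "n_max")
})

test_that("combined selection recovers one planted feature per estimator", {
  tab <- make_table(
    n_per_group = 10, seed = 75,
    pli_gen = function(g) {
      v <- matrix(runif(9, 0.4, 0.6), 3)
      v[1, 2] <- v[2, 1] <- if (g == "SZ") 0.9 else 0.2
      v
    },
    pdc_gen = function(g) {
      v <- matrix(runif(9, 0.4, 0.6), 3)
      v[3, 1] <- if (g == "SZ") 0.9 else 0.2   # a -> c
      v
    })
  best <- select_and_classify_combined(tab, l_max = 4)
  expect_true(all(c("PLI:a-b", "PDC:a->c") %in% best$selection$descriptors$name))
  for (est in c("PLI", "PDC")) {
    single <- select_and_classify_single(tab, est, n_max = 3)
    expect_gte(best$acc, single$acc)
  }
  expect_identical(best$selection$L,
                   best$selection$n + best$selection$m)

  two <- select_and_classify_combined(tab, l_max = 2)
  expect_identical(nrow(two$grid), 1L)
  expect_identical(c(two$grid$n, two$grid$m), c(1L, 1L))
  expect_error(select_and_classify_combined(tab, l_max = 1), "l_max")
})

test_that("within-fold ranking never sees the held-out subject", {
  tab <- make_table(n_per_group = 6, seed = 76)
  cols <- which(tab$descriptors$estimator == "PLI")
  rks <- eegfuse:::fold_rankings(tab$values, tab$labels, cols, "within_fold")
  for (i in seq_len(nrow(tab$values))) {
    expected <- cols[fisher_score(tab$values[-i, cols, drop = FALSE],
                                  tab$labels[-i])$order]
    expect_identical(rks[[i]], expected)
  }
  # whole-data mode uses one ranking everywhere
  rkw <- eegfuse:::fold_rankings(tab$values, tab$labels, cols, "whole_data")
  expect_identical(rkw[[1]], rkw[[5]])
})

test_that("the modified permutation test separates signal from noise", {
  set.seed(77)
  x <- rbind(matrix(rnorm(10 * 3), 10), matrix(rnorm(10 * 3, 8), 10))
  y <- rep(c("HC", "SZ"), each = 10)
  pt <- modified_permutation_test(x, y, n_perm = 500, seed = 78)
  expect_lte(pt$p_value, 0.002)              # no null run reaches 100%
  expect_length(pt$null_accs, 500L)
  expect_equal(pt$observed_acc, 100)

  xn <- matrix(rnorm(16 * 3), 16)
  yn <- rep(c("HC", "SZ"), each = 8)
  ptn <- modified_permutation_test(xn, yn, n_perm = 200, seed = 79)
  expect_gt(ptn$p_value, 0.05)               # pure noise is not significant

  # identical seeds reproduce the result bit-for-bit
  expect_identical(modified_permutation_test(xn, yn, n_perm = 100, seed = 80),
                   modified_permutation_test(xn, yn, n_perm = 100, seed = 80))
  expect_error(modified_permutation_test(xn, yn, n_perm = 10), "100")
})

test_that("group comparison flags planted shifts with correct direction", {
  set.seed(81)
  x <- cbind(c(rnorm(15, 2), rnorm(15, 0)),   # up in SZ
             c(rnorm(15, 0), rnorm(15, 2)),   # down in SZ
             rnorm(30),                       # null
             rep(1, 30))                      # constant -> p = 1
  colnames(x) <- c("up", "down", "null", "const")
  y <- rep(c("SZ", "HC"), each = 15)
  cmp <- compare_selected_features(x, y, alpha_fdr = 0.05)
  expect_identical(cmp$direction[1:2], c("up", "down"))
  expect_true(all(cmp$significant[1:2]))
  expect_identical(cmp$p_raw[4], 1)
  expect_identical(cmp$direction[4], "=")
  expect_true(all(cmp$p_fdr >= cmp$p_raw - 1e-15))
  expect_identical(names(cmp)[6:9],
                   c("mean_SZ", "sem_SZ", "mean_HC", "sem_HC"))
})
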