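test_that("pooled t-test p-values behave at the extremes and match stats::t.test", {
  x <- c(1, 2, 3, 4)
  expect_equal(feature_pvalue(x, x), 1)
  withr::with_seed(1, {
    a <- rep(0, 4) + rnorm(4, sd = 1e-9)
    b <- rep(10, 4) + rnorm(4, sd = 1e-9)
  })
  expect_lt(feature_pvalue(a, b), 1e-6)
  expect_equal(feature_pvalue(rep(1, 3), rep(1, 3)), 1)
  expect_equal(feature_pvalue(rep(1, 3), rep(2, 3)), 0)

  for (i in 1:10) {
    withr::with_seed(600 + i, { u <- rnorm(12); v <- rnorm(15, 0.5) })
    expect_equal(feature_pvalue(u, v),
                 t.test(u, v, var.equal = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("t-test type-I error rate sits at the nominal level", {
  rej <- withr::with_seed(42, {
    mean(replicate(1000, feature_pvalue(rnorm(20), rnorm(18)) < 0.05))
  })
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("AUC matches the pair-enumeration oracle and is complementary", {
  expect_equal(feature_auc(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(feature_auc(rep(2, 5), rep(2, 7)), 0.5)
  for (i in 1:10) {
    withr::with_seed(700 + i, {
      x <- round(rnorm(20), 1)  # rounding forces ties
      y <- round(rnorm(20, 0.3), 1)
    })
    expect_equal(feature_auc(x, y), oracle_auc(x, y), tolerance = 1e-12)
    expect_equal(feature_auc(x, y) + feature_auc(y, x), 1)
  }
})

test_that("a planted separable feature tops every ranking method", {
  withr::with_seed(8, {
    X <- matrix(rnorm(40 * 10), 40, 10)
    X[21:40, 4] <- X[21:40, 4] + 50   # disjoint supports
  })
  colnames(X) <- paste0("F", 1:10)
  tab <- feature_table(as.data.frame(X), rep(c("normal", "scd"), each = 20),
                       feature_names = colnames(X))
  for (m in c("ttest", "entropy", "roc", "wilcoxon", "bhattacharyya"))
    expect_equal(rank_features(tab, m)$order[1], 4L)
})

test_that("duplicate features tie and keep column order; ttest order matches the oracle", {
  withr::with_seed(12, X <- matrix(rnorm(40 * 6), 40, 6))
  X[, 5] <- X[, 2]
  colnames(X) <- paste0("F", 1:6)
  labs <- rep(c("normal", "scd"), each = 20)
  tab <- feature_table(as.data.frame(X), labs, feature_names = colnames(X))
  rk <- rank_features(tab, "roc")
  pos2 <- which(rk$order == 2L)
  expect_equal(rk$order[pos2 + 1L], 5L)  # adjacent, original index first

  tab27 <- toy_feature_table()
  rk_t <- rank_features(tab27, "ttest")
  oracle_order <- order(-vapply(hrv_feature_names, function(f) {
    a <- tab27[[f]][tab27$label == "scd"]
    b <- tab27[[f]][tab27$label == "normal"]
    abs(t.test(a, b, var.equal = TRUE)$statistic)
  }, numeric(1)), seq_len(27))
  expect_equal(rk_t$order, oracle_order)
})

test_that("rank-based criteria are exactly invariant to positive affine maps", {
  tab <- toy_feature_table(seed = 3)
  tab2 <- tab
  tab2$FuEn1 <- 250 * tab2$FuEn1 + 3
  tab2$SDNN <- 0.001 * tab2$SDNN - 42
  for (m in c("roc", "wilcoxon")) {
    expect_identical(rank_features(tab, m)$order, rank_features(tab2, m)$order)
    expect_equal(rank_features(tab, m)$scores, rank_features(tab2, m)$scores)
  }
})

test_that("k-NN cross-validation separates well-separated clouds and is reproducible", {
  withr::with_seed(31, {
    X <- rbind(matrix(rnorm(36 * 5), 36, 5),
               matrix(rnorm(40 * 5, mean = 6), 40, 5))
  })
  colnames(X) <- paste0("F", 1:5)
  tab <- feature_table(as.data.frame(X),
                       c(rep("normal", 36), rep("scd", 40)),
                       feature_names = colnames(X))
  rep1 <- knn_cross_validate(tab, 1:5, n_features = 5, k = 1, seed = 2)
  expect_gte(rep1$accuracy, 95)
  expect_identical(knn_cross_validate(tab, 1:5, 5, k = 1, seed = 2), rep1)

  # accuracy recombines from the per-fold confusion counts exactly
  with(rep1$per_fold, expect_equal(rep1$accuracy,
                                   100 * mean((TP + TN) / (TP + TN + FP + FN))))
  # fold sizes account for every row once
  expect_equal(sum(with(rep1$per_fold, TP + TN + FP + FN)), nrow(tab))
})

test_that("duplicated class prototypes are classified perfectly by 1-NN", {
  proto <- rbind(matrix(rep(c(0, 0, 0), 30), 30, 3, byrow = TRUE),
                 matrix(rep(c(5, 5, 5), 30), 30, 3, byrow = TRUE))
  colnames(proto) <- paste0("F", 1:3)
  tab <- feature_table(as.data.frame(proto),
                       rep(c("normal", "scd"), each = 30),
                       feature_names = colnames(proto))
  rep1 <- knn_cross_validate(tab, 1:3, 3, k = 1, seed = 1)
  expect_equal(rep1$accuracy, 100)
})

test_that("label permutation drives 10-NN accuracy to chance", {
  tab <- toy_feature_table(n_a = 20, n_b = 20, sep = 3, seed = 4)
  accs <- vapply(1:100, function(i) {
    t2 <- tab
    t2$label <- withr::with_seed(900 + i, sample(t2$label))
    knn_cross_validate(t2, seq_len(27), 27, k = 10, seed = i)$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 40)
  expect_lte(mean(accs), 60)
})

test_that("incremental sweep peaks early when only the first features inform", {
  tab <- toy_feature_table(n_a = 38, n_b = 38, n_inf = 3, sep = 2.5, seed = 6)
  rk <- rank_features(tab, "ttest")
  expect_true(all(sort(rk$order[1:3]) == 1:3))
  sw <- incremental_sweep(tab, rk, k_values = c(1L, 10L), seed = 7)
  expect_equal(nrow(sw$curves), 54)
  expect_equal(sort(unique(sw$curves$n_features)), 1:27)
  best_n <- sw$best$n_features
  expect_lte(best_n, 5)
  # past the peak the curve stays within a 5-point noise band of its maximum
  for (k in c(1, 10)) {
    cv <- sw$curves[sw$curves$k == k, ]
    expect_true(all(cv$accuracy[cv$n_features > best_n] <=
                    max(cv$accuracy) + 5))
  }
  # the reported best reproduces the curve argmax under the tie-break rule
  ix <- order(-sw$curves$accuracy, sw$curves$n_features, sw$curves$k)[1]
  expect_equal(sw$best$n_features, sw$curves$n_features[ix])
  expect_equal(sw$best$k, sw$curves$k[ix])
})
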