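test_that("branch feature assembly selects features and drops missing rows", {
  df <- data.frame(das = c(41, 43, 45), flower_pixels = c(300, 600, NA),
                   est_flowers = c(2, 4, 6), branch_count = c(1, 2, 3))
  tab <- assemble_branch_features(df)
  expect_named(tab, c("das", "flower_pixels", "est_flowers", "label"))
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "n_dropped"), 1)

  tab2 <- assemble_branch_features(df, features = c("das", "est_flowers"))
  expect_named(tab2, c("das", "est_flowers", "label"))
  expect_equal(nrow(tab2), 3)
})

test_that("stress feature assembly produces the full 21-feature roster", {
  n <- 6
  df <- as.data.frame(setNames(
    lapply(phenotyper:::STRESS_FEATURES, function(x) rnorm(n)),
    phenotyper:::STRESS_FEATURES))
  df$das <- 49
  df$stress <- rep(c(0, 1), 3)
  tab <- assemble_stress_features(df)
  expect_equal(ncol(tab), 21)   # 20 trait/attribute columns + label
  expect_equal(nrow(tab), n)
  expect_error(assemble_stress_features(df, das = 51), "target day")

  df$nir_mean[2] <- NA
  expect_equal(attr(assemble_stress_features(df), "n_dropped"), 1)
})

test_that("flowering groups encode anthesis terciles ordinally", {
  g <- flowering_group(c(39, 41, 43, 45, 47, 49))
  expect_equal(g[1], 0L)
  expect_equal(g[6], 2L)
  expect_true(all(diff(g) >= 0))
  expect_equal(flowering_group(c(40, NA)), c(0L, 2L))
})

test_that("down-sampling balances to the minority class deterministically", {
  tab <- structure(
    data.frame(x = rnorm(299), label = rep(c(1, 0), c(166, 133))),
    class = c("labeled_feature_table", "data.frame"))
  bal <- downsample_balance(tab, seed = 5)
  expect_equal(nrow(bal), 266)
  expect_equal(sum(bal$label == 0), 133)
  expect_equal(sum(bal$label == 1), 133)
  # every minority row preserved
  expect_true(all(tab$x[tab$label == 0] %in% bal$x))
  expect_identical(bal, downsample_balance(tab, seed = 5))
  expect_false(identical(bal, downsample_balance(tab, seed = 6)))

  even <- structure(data.frame(x = 1:4, label = c(0, 0, 1, 1)),
                    class = c("labeled_feature_table", "data.frame"))
  expect_identical(downsample_balance(even, 1), even)
  bad <- structure(data.frame(x = 1:3, label = c(1, 1, 1)),
                   class = c("labeled_feature_table", "data.frame"))
  expect_error(downsample_balance(bad, 1), "two non-empty classes")
})

test_that("k-fold splits reproduce the published observation counts", {
  f789 <- kfold_split(789, 5, seed = 2)
  expect_equal(max(lengths(f789)), 158)
  expect_equal(789 - max(lengths(f789)), 631)
  f266 <- kfold_split(266, 5, seed = 2)
  expect_equal(max(lengths(f266)), 54)
  expect_equal(266 - max(lengths(f266)), 212)
})

test_that("folds partition the indices with sizes differing by at most one", {
  for (n in c(11, 40, 266)) {
    f <- kfold_split(n, 5, seed = n)
    expect_equal(sort(unlist(f)), 1:n)
    expect_lte(diff(range(lengths(f))), 1)
  }
  loo <- kfold_split(5, 5, seed = 1)
  expect_true(all(lengths(loo) == 1))
  expect_error(kfold_split(4, 5, seed = 1), "at least")
})

test_that("regression recovers exact linear labels perfectly", {
  set.seed(17)
  df <- data.frame(das = sample(37:55, 60, TRUE),
                   flower_pixels = runif(60, 100, 900))
  df$est_flowers <- round(df$flower_pixels / 150)
  df$branch_count <- df$est_flowers  # exact linear function
  tab <- assemble_branch_features(df)
  for (alg in c("linear", "huber")) {
    rep_ <- cv_regression(tab, alg, k = 5, seed = 3)
    expect_equal(rep_$mean, 1)
    expect_length(rep_$per_fold, 5)
    expect_false(rep_$degenerate)
  }
})

test_that("regression on label-independent features stays near chance", {
  set.seed(23)
  df <- data.frame(das = runif(200), flower_pixels = runif(200),
                   est_flowers = runif(200),
                   branch_count = sample(1:34, 200, TRUE))
  rep_ <- cv_regression(assemble_branch_features(df), "linear", seed = 4)
  expect_lt(rep_$mean, 0.25)  # 34 labels; rounded matches are rare
})

test_that("ROC AUC equals the exhaustive concordant-pair count", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(0.5, 0.5), c(1, 0)), 0.5)  # tie counts one half

  set.seed(29)
  scores <- rnorm(40); labels <- rbinom(40, 1, 0.5)
  expect_equal(roc_auc(scores, labels), roc_auc(exp(scores), labels))
  expect_equal(roc_auc(scores, labels),
               as.numeric(suppressMessages(
                 pROC::auc(labels, scores, direction = "<"))))
})

test_that("classification separates an easy synthetic signal", {
  set.seed(37)
  n <- 120
  lab <- rep(c(0, 1), each = n / 2)
  tab <- structure(
    data.frame(f1 = rnorm(n, lab * 2), f2 = rnorm(n, -lab), label = lab),
    class = c("labeled_feature_table", "data.frame"))
  for (alg in c("random_forest", "lda", "logistic", "knn",
                "decision_tree", "svm")) {
    rep_ <- cv_classification(tab, alg, k = 5, seed = 7)
    expect_gt(rep_$mean, 0.75)
    expect_true(rep_$accuracy_mean > 0.6)
    expect_length(rep_$skipped_folds, 0)
  }
})

test_that("percentage accuracy from counts matches the printed precision", {
  expect_equal(accuracy_from_counts(170, 175), 97.14)
  expect_equal(accuracy_from_counts(0, 20), 0)
  expect_equal(accuracy_from_counts(20, 20), 100)
  expect_error(accuracy_from_counts(5, 0), "positive")
  expect_error(accuracy_from_counts(6, 5), "between")
})
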