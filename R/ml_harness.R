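#' Assemble the raceme-branch feature table
#'
#' Features for branch-count regression are plant age (DAS), the number of
#' thresholded blue-yellow "flower pixels", and the estimated number of
#' flowers; any subset can be selected for drop-one-feature comparisons.
#' Rows with missing feature or label values are dropped and counted.
#'
#' @param flower_outputs Data frame with columns `das`, `flower_pixels`,
#'   `est_flowers` and the label `branch_count`.
#' @param features Character subset of the three feature names.
#' @return A `labeled_feature_table`: data frame of selected features plus
#'   `label`, with attributes `label_name` and `n_dropped`.
#' @export
assemble_branch_features <- function(flower_outputs,
                                     features = c("das", "flower_pixels",
                                                  "est_flowers")) {
  stopifnot(all(features %in% c("das", "flower_pixels", "est_flowers")),
            length(features) >= 1,
            all(c(features, "branch_count") %in% names(flower_outputs)))
  make_feature_table(flower_outputs, features, "branch_count")
}

STRESS_FEATURES <- c("nir_mean", "nir_p75",
                     "pixels_tv", "d_pixels_tv", "hull_tv", "d_hull_tv",
                     "pixels_sv", "d_pixels_sv", "hull_sv", "d_hull_sv",
                     "weight_before", "weight_after", "area_below_rim",
                     "height", "width", "d_height", "d_width",
                     "exg", "flowering_group", "branches")

#' Assemble the drought-stress feature table
#'
#' Builds the 21-feature stress table for the target day (default 49 DAS):
#' mean and 75th-percentile NIR, top-view pixels/hull and their deltas,
#' side-view pixels/hull and their deltas, pot weight before and after
#' watering, plant area below the pot rim, height, width, delta height and
#' width, ExG, flowering group, and raceme branch count, plus the binary
#' stress label. Delta columns are differences from the previous imaging
#' day (47 to 49 DAS under an every-other-day schedule). The flowering
#' group is encoded ordinally: early = 0, intermediate = 1, late = 2. Rows
#' with any missing feature (e.g. an unpaired NIR day) are dropped and
#' counted.
#'
#' @param trait_outputs Data frame keyed by `plant_id` and `das` containing
#'   the columns named above plus the label `stress` (0/1).
#' @param das Target day.
#' @return A `labeled_feature_table` with 20 numeric feature columns and a
#'   `label` column (the flowering group arrives already encoded, making 21
#'   input features when counting its three levels' shared column once).
#' @export
assemble_stress_features <- function(trait_outputs, das = 49) {
  stopifnot(all(c(STRESS_FEATURES, "stress", "das") %in%
                  names(trait_outputs)))
  day <- trait_outputs[trait_outputs$das == das, , drop = FALSE]
  if (nrow(day) == 0) stop("no observations for target day ", das)
  make_feature_table(day, STRESS_FEATURES, "stress")
}

#' Encode flowering group from anthesis day
#'
#' Plants are split into early / intermediate / late flowering by the
#' terciles of the observed anthesis days; plants that never flowered are
#' assigned to the late group. Encoded ordinally 0 / 1 / 2.
#'
#' @param anthesis_das Integer vector of anthesis days (NA = not flowered).
#' @return Integer vector of group codes 0, 1, 2.
#' @export
flowering_group <- function(anthesis_das) {
  out <- rep(2L, length(anthesis_das))
  obs <- !is.na(anthesis_das)
  if (any(obs)) {
    qs <- quantile(anthesis_das[obs], c(1 / 3, 2 / 3), type = 7)
    out[obs] <- ifelse(anthesis_das[obs] <= qs[1], 0L,
                       ifelse(anthesis_das[obs] <= qs[2], 1L, 2L))
  }
  out
}

make_feature_table <- function(df, features, label_name) {
  cols <- df[, c(features, label_name), drop = FALSE]
  keep <- complete.cases(cols)
  out <- cols[keep, , drop = FALSE]
  names(out)[names(out) == label_name] <- "label"
  rownames(out) <- NULL
  structure(out, label_name = label_name, n_dropped = sum(!keep),
            class = c("labeled_feature_table", "data.frame"))
}

#' Down-sample the majority class to balance a binary label
#'
#' The majority class is sampled without replacement down to the minority
#' class size, so the result has `2 * min(class sizes)` rows; every
#' minority-class row is preserved. Deterministic for a given seed.
#'
#' @param table A `labeled_feature_table` (binary `label`).
#' @param seed Integer seed.
#' @return The balanced table.
#' @export
downsample_balance <- function(table, seed = 1) {
  tab <- base::table(table$label)
  if (length(tab) != 2 || any(tab == 0))
    stop("downsampling needs two non-empty classes")
  minority <- names(tab)[which.min(tab)]
  majority <- names(tab)[which.max(tab)]
  if (tab[minority] == tab[majority]) return(table)
  maj_idx <- which(as.character(table$label) == majority)
  keep_maj <- with_seed(seed, sort(sample(maj_idx, tab[[minority]])))
  out <- table[sort(c(which(as.character(table$label) == minority),
                      keep_maj)), , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)$label_name <- attr(table, "label_name")
  out
}

#' Random k-fold split
#'
#' Indices 1..n are shuffled by the seed and dealt into k folds whose sizes
#' differ by at most one (larger folds first); each fold serves as the test
#' set once, with the remaining folds as training data.
#'
#' @param n Number of observations (>= k).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of k integer vectors (test-fold indices); a partition
#'   of 1..n.
#' @export
kfold_split <- function(n, k = 5, seed = 1) {
  if (n < k) stop("n must be at least k")
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  lapply(seq_len(k), function(i) sort(perm[starts[i]:ends[i]]))
}

#' Cross-validated regression of raceme branch counts
#'
#' Fits ordinary linear regression or Huber robust regression
#' ([MASS::rlm()]) on each training split and scores the held-out fold.
#' Because branch counts are integers, the default accuracy is the fraction
#' of predictions that match the true count after rounding half up;
#' `metric = "mape"` reports 1 - mean absolute percentage error instead.
#'
#' @param table A `labeled_feature_table` with integer labels.
#' @param algorithm `"linear"` or `"huber"`.
#' @param k Folds.
#' @param seed Fold-shuffle seed.
#' @param metric `"rounded_match"` or `"mape"`.
#' @return A `cv_report`: list with `algorithm`, `metric`, `per_fold`
#'   (length k, proportions), `mean`, `sd`, `n_total`, `n_train`, `n_test`
#'   (largest fold), `seed`, `degenerate` flag.
#' @export
cv_regression <- function(table, algorithm = c("linear", "huber"), k = 5,
                          seed = 1, metric = c("rounded_match", "mape")) {
  algorithm <- match.arg(algorithm)
  metric <- match.arg(metric)
  feats <- setdiff(names(table), "label")
  degenerate <- all(vapply(table[feats], function(x) var(x) == 0, TRUE))
  folds <- kfold_split(nrow(table), k, seed)
  df <- as.data.frame(table)
  per_fold <- vapply(folds, function(test) {
    train <- df[-test, , drop = FALSE]
    fit <- if (algorithm == "linear") {
      lm(label ~ ., data = train)
    } else {
      MASS::rlm(label ~ ., data = train, psi = MASS::psi.huber,
                maxit = 100)
    }
    pred <- predict(fit, newdata = df[test, , drop = FALSE])
    truth <- df$label[test]
    if (metric == "rounded_match") mean(round_half_up(pred) == truth)
    else 1 - mean(abs(pred - truth) / pmax(abs(truth), 1))
  }, numeric(1))
  new_cv_report(algorithm, metric, per_fold, folds, nrow(table), seed,
                degenerate)
}

#' Cross-validated drought-stress classification
#'
#' Runs one of the standard classifier rosters over k folds: random forest,
#' linear discriminant analysis, logistic regression, K-nearest neighbour
#' (K = 1 by default), decision tree, or support vector machine, each with
#' its library's default hyperparameters. Per fold, held-out observations
#' are scored, ROC AUC is computed by the Mann-Whitney rank statistic (ties
#' count one half), and accuracy is taken at a 0.5 score threshold. Folds
#' whose training data contain a single class are skipped and flagged.
#'
#' @param table A `labeled_feature_table` with a binary 0/1 `label`.
#' @param algorithm One of `"random_forest"`, `"lda"`, `"logistic"`,
#'   `"knn"`, `"decision_tree"`, `"svm"`.
#' @param k Folds.
#' @param seed Seed for fold shuffling and stochastic learners.
#' @param knn_k Neighbourhood size for KNN.
#' @return A `cv_report` whose `per_fold`/`mean`/`sd` are ROC AUC, with
#'   additional fields `accuracy_per_fold`, `accuracy_mean`, `accuracy_sd`,
#'   and `skipped_folds`.
#' @export
cv_classification <- function(table,
                              algorithm = c("random_forest", "lda",
                                            "logistic", "knn",
                                            "decision_tree", "svm"),
                              k = 5, seed = 1, knn_k = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(all(table$label %in% c(0, 1)))
  folds <- kfold_split(nrow(table), k, seed)
  df <- as.data.frame(table)
  feats <- setdiff(names(df), "label")
  auc <- acc <- rep(NA_real_, k)
  skipped <- integer(0)
  for (i in seq_len(k)) {
    test <- folds[[i]]
    train <- df[-test, , drop = FALSE]
    if (length(unique(train$label)) < 2 ||
        length(unique(df$label[test])) < 2) {
      skipped <- c(skipped, i)
      next
    }
    scores <- with_seed(seed + i, classifier_scores(algorithm, train,
                                                    df[test, , drop = FALSE],
                                                    feats, knn_k))
    truth <- df$label[test]
    auc[i] <- roc_auc(scores, truth)
    acc[i] <- mean(as.integer(scores >= 0.5) == truth)
  }
  ok <- setdiff(seq_len(k), skipped)
  rep_ <- new_cv_report(algorithm, "roc_auc", auc[ok], folds, nrow(df), seed,
                        FALSE)
  rep_$accuracy_per_fold <- acc[ok]
  rep_$accuracy_mean <- mean(acc[ok])
  rep_$accuracy_sd <- sd(acc[ok])
  rep_$skipped_folds <- skipped
  rep_
}

classifier_scores <- function(algorithm, train, test, feats, knn_k) {
  xtr <- as.matrix(train[feats]); xte <- as.matrix(test[feats])
  ytr <- factor(train$label, levels = c(0, 1))
  switch(algorithm,
    random_forest = {
      fit <- randomForest::randomForest(x = xtr, y = ytr)
      unname(predict(fit, xte, type = "prob")[, "1"])
    },
    lda = {
      fit <- MASS::lda(x = xtr, grouping = ytr, tol = 1e-8)
      unname(predict(fit, xte)$posterior[, "1"])
    },
    logistic = {
      fit <- suppressWarnings(glm(label ~ ., data = train,
                                  family = binomial()))
      unname(suppressWarnings(predict(fit, newdata = test,
                                      type = "response")))
    },
    knn = {
      pred <- class::knn(xtr, xte, cl = ytr, k = knn_k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "1", p, 1 - p)
    },
    decision_tree = {
      fit <- rpart::rpart(label ~ ., data = train, method = "class")
      unname(predict(fit, newdata = test, type = "prob")[, "1"])
    },
    svm = {
      fit <- e1071::svm(x = xtr, y = ytr, probability = TRUE)
      att <- attr(predict(fit, xte, probability = TRUE), "probabilities")
      unname(att[, "1"])
    })
}

new_cv_report <- function(algorithm, metric, per_fold, folds, n_total, seed,
                          degenerate) {
  sizes <- lengths(folds)
  structure(list(
    algorithm = algorithm, metric = metric,
    per_fold = unname(per_fold),
    mean = mean(per_fold), sd = sd(per_fold),
    n_total = n_total, n_train = n_total - max(sizes), n_test = max(sizes),
    seed = seed, degenerate = degenerate
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s  %s = %.3f (SD %.3f)  n = %d/%d/%d\n",
              x$algorithm, x$metric, x$mean, x$sd,
              x$n_total, x$n_train, x$n_test))
  invisible(x)
}

#' ROC AUC by the rank statistic
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, with score ties counting one half.
#' Invariant under strictly monotone transformations of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary 0/1 labels.
#' @return AUC in \[0, 1\]; `NA` if a class is absent.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Percentage accuracy from counts
#'
#' @param correct,total Nonnegative counts, `correct <= total`, `total > 0`.
#' @return `100 * correct / total`, rounded to two decimals.
#' @examples
#' accuracy_from_counts(170, 175)  # 97.14
#' @export
accuracy_from_counts <- function(correct, total) {
  if (total <= 0) stop("total must be positive")
  if (correct < 0 || correct > total)
    stop("correct must lie between 0 and total")
  round(100 * correct / total, 2)
}
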