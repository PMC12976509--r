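test_that("grouped folds partition experiments and bookkeep class counts", {
  man <- deskManifest()
  folds <- makeGroupedFolds(man, nFolds = 5, seed = 3)
  a <- foldMap(folds)
  # partition: every experiment exactly once, folds 0..4 all non-empty
  expect_setequal(a$experiment_id, unique(man$experiment_id))
  expect_setequal(unique(a$fold), 0:4)
  # no field is in both train and test of any fold
  fmap <- setNames(a$fold, a$experiment_id)
  fieldFold <- fmap[man$experiment_id]
  for (f in 0:4) {
    testIds <- man$field_id[fieldFold == f]
    trainIds <- man$field_id[fieldFold != f]
    expect_length(intersect(testIds, trainIds), 0)
  }
  # per-fold train + test equals the class total (dataset bookkeeping)
  cnt <- folds@counts
  for (cl in c("CCCP", "FL3", "NC")) {
    tot <- sum(man$label == cl)
    expect_true(all(cnt[[paste0("train_", cl)]] +
                      cnt[[paste0("test_", cl)]] == tot))
  }
  # 5 groups into 5 folds is a bijection
  sub <- man[man$experiment_id %in% paste0("E", 1:5), ]
  b <- makeGroupedFolds(sub, nFolds = 5, seed = 1)
  expect_equal(sort(table(foldMap(b)$fold)), sort(table(0:4)),
               ignore_attr = TRUE)
  expect_error(makeGroupedFolds(sub, nFolds = 7), "configuration error")
})

test_that("classification metrics match hand-computed confusion matrices", {
  # TP=2, FP=1, FN=1, TN=6
  truth <- c(rep("CCCP", 3), rep("NC", 7))
  pred <- c("CCCP", "CCCP", "NC", "CCCP", rep("NC", 6))
  m <- classificationMetrics(truth, pred)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  # harmonic mean of precision 2/3 and recall 1/2
  expect_equal(f1Score(2 / 3, 1 / 2), 4 / 7)
  # perfect predictions
  p <- classificationMetrics(truth, truth)
  expect_equal(unlist(p), c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  # harmonic mean at published precision/recall reproduces the printed F1
  expect_equal(round(f1Score(1.0000, 0.9941), 4), 0.9970)
  expect_equal(f1Score(0, 0), 0)
  expect_warning(classificationMetrics(c("CCCP", "NC"), c("NC", "NC")),
                 "no positive predictions")
})

test_that("threshold-sweep AUC equals Mann-Whitney pair counting", {
  r <- rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  # perfectly separated and fully tied cases
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  # curve endpoints and monotonicity
  expect_equal(c(r$tpr[1], r$fpr[1]), c(0, 0))
  expect_equal(c(r$tpr[length(r$tpr)], r$fpr[length(r$fpr)]), c(1, 1))
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  # oracle equivalence on random instances, ties included
  set.seed(12)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    pairSum <- 0
    for (a in which(y == 1)) for (b in which(y == 0))
      pairSum <- pairSum + (s[a] > s[b]) + 0.5 * (s[a] == s[b])
    expect_equal(rocAuc(s, y)$auc, pairSum / (sum(y) * sum(1 - y)),
                 tolerance = 1e-12)
  }
  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  for (i in 1:10) {
    s <- runif(30)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocAuc(s, y)$auc, ref, tolerance = 1e-12)
  }
})

test_that("fold-score aggregation reproduces printed cross-validation averages", {
  cccp <- data.frame(
    fold = 0:4, group = "CCCP",
    CCCP_score = c(0.9782, 0.9611, 0.9819, 0.9760, 0.9754),
    NC_score = c(0.0218, 0.0389, 0.0181, 0.0240, 0.0246))
  nc <- data.frame(
    fold = 0:4, group = "NC",
    CCCP_score = c(0.0000, 0.0024, 0.0001, 0.0000, 0.0002),
    NC_score = c(1.0000, 0.9976, 0.9999, 1.0000, 0.9998))
  tab <- aggregateFoldScores(rbind(cccp, nc))
  avg <- tab[tab$fold == "Average", ]
  expect_equal(avg$CCCP_score[avg$group == "CCCP"], 0.9745)
  expect_equal(avg$NC_score[avg$group == "NC"], 0.9995)
  # identical fold rows average to themselves
  same <- data.frame(fold = 0:4, group = "G", s = rep(0.42, 5))
  t2 <- aggregateFoldScores(same)
  expect_equal(t2$s[t2$fold == "Average"], 0.42)
  # a missing fold is an error
  expect_error(aggregateFoldScores(cccp[-2, ], nFolds = 5),
               "one row per fold")
})

test_that("rank-sum comparisons match exact enumeration and symmetry", {
  # identical groups: U at its null mean, exact p = 1
  same <- groupCompare(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$p, 1)
  expect_equal(same$method, "exact enumeration")
  # fully separated small groups: U = 0, one-sided exact p = 1/20
  sep <- groupCompare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3),
                      alternative = "less")
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 1 / 20)
  # swapping group order maps U -> n1 n2 - U with the two-sided p unchanged
  x <- c(3, 5, 8, 2, 9, 1)
  g <- rep(c("a", "b"), each = 3)
  fwd <- groupCompare(x, g)
  rev <- groupCompare(x, ifelse(g == "a", "b", "a"))
  expect_equal(rev$U, 9 - fwd$U)
  expect_equal(rev$p, fwd$p)
  expect_equal(fwd$rank_biserial, -rev$rank_biserial)
  # agreement with the stats package in the untied exact regime
  set.seed(5)
  xs <- rnorm(6); ys <- rnorm(7) + 1
  ours <- groupCompare(c(xs, ys), rep(c("x", "y"), c(6, 7)))
  ref <- wilcox.test(xs, ys, exact = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_error(groupCompare(1:5, c("a", "a", "a", "b", "b")), "n >= 3")
})

test_that("patient-level ROC prediction behaves across predictors", {
  set.seed(30)
  ps <- data.frame(
    participant_id = sprintf("P%02d", 1:16),
    group = rep(c("AD", "CN"), each = 8),
    FL3_score = c(runif(8, 0.6, 1), runif(8, 0, 0.4)),
    CCCP_score = runif(16, 0, 0.2))
  r <- patientPrediction(ps, positive = "AD", predictor = "FL3_score")
  expect_equal(r$auc, 1)
  # relabeling positive and reference mirrors the AUC
  r2 <- patientPrediction(ps, positive = "CN", reference = "AD",
                          predictor = "FL3_score")
  expect_equal(r2$auc, 1 - r$auc)
  # constant predictor degrades to 0.5 with a warning
  ps$CCCP_score <- 0.1
  expect_warning(rc <- patientPrediction(ps, positive = "AD",
                                         predictor = "CCCP_score"),
                 "degenerate")
  expect_equal(rc$auc, 0.5)
  # the in-sample logistic combination is at least as good as chance here
  # (the toy groups are perfectly separable, so glm reports saturation)
  ps$CCCP_score <- runif(16)
  rcomb <- suppressWarnings(
    patientPrediction(ps, positive = "AD", predictor = "combined"))
  expect_gte(rcomb$auc, 0.9)
})
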