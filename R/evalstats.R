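#' Grouped cross-validation folds
#'
#' Assigns acquisition batches ("experiments") — not individual fields — to
#' folds, so correlated fields from one batch never straddle train and test.
#' Batches are shuffled under `seed` and assigned greedily to the currently
#' lightest fold by total field count.
#'
#' @param manifest Manifest data frame with `experiment_id` and `label`.
#' @param nFolds Number of folds (default 5).
#' @param groupKey Column defining the grouping (default `experiment_id`).
#' @param seed RNG seed for the shuffle.
#' @return A [FoldAssignment-class]; its `counts` slot holds the per-fold
#'   train/test field counts by class.
#' @export
makeGroupedFolds <- function(manifest, nFolds = 5, groupKey = "experiment_id",
                             seed = 1) {
  stopifnot2(groupKey %in% names(manifest),
             sprintf("manifest lacks column '%s'", groupKey))
  groups <- unique(manifest[[groupKey]])
  if (length(groups) < nFolds)
    stop(sprintf(
      "configuration error: %d groups cannot fill %d folds",
      length(groups), nFolds))
  sizes <- table(manifest[[groupKey]])
  ord <- withSeed(seed, sample(groups))
  foldOf <- setNames(integer(length(groups)), ord)
  load <- integer(nFolds)
  for (g in ord) {
    f <- which.min(load)
    foldOf[g] <- f - 1L
    load[f] <- load[f] + sizes[[g]]
  }
  assignment <- data.frame(experiment_id = names(foldOf),
                           fold = as.integer(foldOf),
                           stringsAsFactors = FALSE)
  fieldFold <- foldOf[manifest[[groupKey]]]
  classes <- sort(unique(manifest$label))
  counts <- do.call(rbind, lapply(0:(nFolds - 1), function(f) {
    test <- fieldFold == f
    row <- data.frame(fold = f)
    for (cl in classes) {
      row[[paste0("train_", cl)]] <- sum(!test & manifest$label == cl)
      row[[paste0("test_", cl)]] <- sum(test & manifest$label == cl)
    }
    row
  }))
  new("FoldAssignment", assignment = assignment, nFolds = nFolds,
      counts = counts)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`, defined as 0 when `P + R = 0`.
#'
#' @param precision,recall Values in [0, 1].
#' @return F1 score.
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Classification metrics
#'
#' Accuracy, precision, recall and F1. Binary tasks score the treatment
#' class as positive; multi-class tasks report macro-averaged precision and
#' recall and, per `f1` setting, weighted (by class support) or macro F1.
#'
#' @param truth,pred Equal-length label vectors.
#' @param positive Positive class for binary tasks; defaults to the first
#'   non-"NC" label present.
#' @param f1 `"weighted"` (default) or `"macro"` averaging of per-class F1
#'   for multi-class input.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
classificationMetrics <- function(truth, pred, positive = NULL,
                                  f1 = c("weighted", "macro")) {
  f1 <- match.arg(f1)
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot2(length(truth) == length(pred),
             "truth and pred lengths differ")
  classes <- sort(unique(c(truth, pred)))
  acc <- mean(truth == pred)
  if (length(classes) <= 2) {
    if (is.null(positive))
      positive <- if (any(classes != "NC")) classes[classes != "NC"][1]
        else classes[1]
    tp <- sum(truth == positive & pred == positive)
    fp <- sum(truth != positive & pred == positive)
    fn <- sum(truth == positive & pred != positive)
    if (tp + fp == 0) {
      warning("no positive predictions; precision defined as 0")
      prec <- 0
    } else prec <- tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    return(list(accuracy = acc, precision = prec, recall = rec,
                f1 = f1Score(prec, rec)))
  }
  perClass <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    list(prec = prec, rec = rec, f1 = f1Score(prec, rec),
         support = sum(truth == cl))
  })
  prec <- mean(vapply(perClass, `[[`, 0, "prec"))
  rec <- mean(vapply(perClass, `[[`, 0, "rec"))
  w <- vapply(perClass, `[[`, 0, "support")
  f1s <- vapply(perClass, `[[`, 0, "f1")
  f1v <- if (f1 == "weighted") sum(f1s * w) / sum(w) else mean(f1s)
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1v)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds; tied scores advance TPR
#' and FPR simultaneously, so the trapezoid AUC equals the Mann-Whitney
#' pair statistic with ties counted one half.
#'
#' @param scores Numeric per-item scores (higher = more positive).
#' @param labels Logical, 0/1, or labels matched against `positive`.
#' @param positive Positive label when `labels` is not logical/0-1.
#' @return List of class `"ROCCurve"`: `thresholds`, `tpr`, `fpr` (both
#'   non-decreasing from (0, 0) to (1, 1)), `auc`.
#' @export
rocAuc <- function(scores, labels, positive = NULL) {
  if (!is.logical(labels) && !all(labels %in% c(0, 1))) {
    stopifnot2(!is.null(positive), "positive label required")
    labels <- labels == positive
  }
  labels <- as.logical(labels)
  stopifnot2(any(labels) && any(!labels),
             "value error: both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  nP <- sum(y); nN <- sum(!y)
  # collapse tied scores into simultaneous steps
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / nP)
  fpr <- c(0, fp[last] / nN)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = c(Inf, s[last]), tpr = tpr, fpr = fpr,
                 auc = auc), class = "ROCCurve")
}

#' Fold-score aggregation table
#'
#' Builds the cross-validation report table: one row per fold and true
#' group holding that group's mean class-probability scores, plus an
#' `Average` row per group equal to the unweighted arithmetic mean over
#' folds, rounded to 4 decimals in the report (full precision is kept in
#' the `"exact"` attribute).
#'
#' @param foldScores Data frame with columns `fold`, `group`, and one or
#'   more numeric score columns; exactly one row per (fold, group).
#' @param nFolds Expected number of folds (default: number of distinct
#'   folds present).
#' @return Data frame with appended `Average` rows; attribute `"exact"`
#'   carries the unrounded version.
#' @export
aggregateFoldScores <- function(foldScores, nFolds = NULL) {
  stopifnot2(all(c("fold", "group") %in% names(foldScores)),
             "foldScores needs 'fold' and 'group' columns")
  scoreCols <- setdiff(names(foldScores), c("fold", "group"))
  folds <- sort(unique(foldScores$fold))
  if (is.null(nFolds)) nFolds <- length(folds)
  out <- foldScores
  exact <- foldScores
  for (g in unique(foldScores$group)) {
    sub <- foldScores[foldScores$group == g, , drop = FALSE]
    if (nrow(sub) != nFolds || anyDuplicated(sub$fold))
      stop(sprintf(
        "value error: group '%s' must have exactly one row per fold", g))
    avg <- data.frame(fold = "Average", group = g, stringsAsFactors = FALSE)
    avgExact <- avg
    for (sc in scoreCols) {
      avgExact[[sc]] <- mean(sub[[sc]])
      avg[[sc]] <- round(avgExact[[sc]], 4)
    }
    out <- rbind(out, avg)
    exact <- rbind(exact, avgExact)
  }
  attr(out, "exact") <- exact
  out
}

# Mann-Whitney U with ties counted one half.
.uStat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Rank-sum comparison of score groups
#'
#' Two-sided Mann-Whitney U test between groups of field or participant
#' scores. When both groups have at most 8 observations the null
#' distribution of U is enumerated exactly over all assignments (ties
#' counted one half); otherwise the normal approximation with tie
#' correction and continuity correction is used. With more than two groups
#' all pairwise comparisons are reported with Holm-adjusted p-values.
#'
#' @param scores Numeric vector.
#' @param group Group label per score (>= 2 groups, each n >= 3).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternatives refer to the first group of each pair).
#' @return Data frame with one row per pair: `group1`, `group2`, `n1`,
#'   `n2`, `U`, `p`, `p_adj` (Holm), `rank_biserial`, `method`.
#' @export
groupCompare <- function(scores, group,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  group <- as.character(group)
  tab <- table(group)
  stopifnot2(length(tab) >= 2, "value error: need at least two groups")
  stopifnot2(all(tab >= 3), "value error: every group needs n >= 3")
  gs <- names(tab)
  pairs <- utils::combn(gs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(q) {
    g1 <- pairs[1, q]; g2 <- pairs[2, q]
    x <- scores[group == g1]; y <- scores[group == g2]
    n1 <- length(x); n2 <- length(y)
    U <- .uStat(x, y)
    if (n1 <= 8 && n2 <= 8) {
      pooled <- c(x, y)
      combos <- utils::combn(n1 + n2, n1)
      r <- rank(pooled)
      Us <- apply(combos, 2, function(ix)
        sum(r[ix]) - n1 * (n1 + 1) / 2)
      mu <- n1 * n2 / 2
      p <- switch(alternative,
        two.sided = mean(abs(Us - mu) >= abs(U - mu) - 1e-9),
        less = mean(Us <= U + 1e-9),
        greater = mean(Us >= U - 1e-9))
      method <- "exact enumeration"
    } else {
      mu <- n1 * n2 / 2
      nt <- n1 + n2
      ties <- table(c(x, y))
      sigma <- sqrt(n1 * n2 / 12 *
                      (nt + 1 - sum(ties^3 - ties) / (nt * (nt - 1))))
      z <- (U - mu - sign(U - mu) * 0.5) / sigma
      p <- switch(alternative,
        two.sided = 2 * pnorm(-abs(z)),
        less = pnorm(z),
        greater = pnorm(-z))
      p <- min(1, p)
      method <- "normal approximation"
    }
    data.frame(group1 = g1, group2 = g2, n1 = n1, n2 = n2, U = U, p = p,
               rank_biserial = 2 * U / (n1 * n2) - 1, method = method,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out[, c("group1", "group2", "n1", "n2", "U", "p", "p_adj",
          "rank_biserial", "method")]
}

#' Cohort-level prediction ROC
#'
#' ROC of a participant-level score for separating a positive cognitive
#' group from a reference group. The `"combined"` predictor is an
#' in-sample logistic combination of the hyperfusion and hyperfission
#' scores (reported as in-sample, not cross-validated).
#'
#' @param participantScores Data frame from [scoreParticipant()] with a
#'   `group` column.
#' @param positive Positive group label (e.g. `"AD"`).
#' @param reference Reference group label (default `"CN"`).
#' @param predictor `"FL3_score"`, `"CCCP_score"` or `"combined"`.
#' @return A `"ROCCurve"` (see [rocAuc()]); degenerate constant predictors
#'   yield AUC 0.5 with a warning.
#' @export
patientPrediction <- function(participantScores, positive,
                              reference = "CN",
                              predictor = c("FL3_score", "CCCP_score",
                                            "combined")) {
  predictor <- match.arg(predictor)
  d <- participantScores[participantScores$group %in%
                           c(positive, reference), , drop = FALSE]
  stopifnot2(sum(d$group == positive) >= 3 &&
               sum(d$group == reference) >= 3,
             "need >= 3 participants per group")
  y <- d$group == positive
  s <- if (predictor == "combined") {
    fit <- glm(y ~ FL3_score + CCCP_score, data = d, family = binomial())
    as.numeric(predict(fit, type = "response"))
  } else d[[predictor]]
  if (sd(s) == 0) {
    warning("degenerate constant predictor; AUC 0.5")
    return(structure(list(thresholds = c(Inf, s[1]), tpr = c(0, 1),
                          fpr = c(0, 1), auc = 0.5), class = "ROCCurve"))
  }
  rocAuc(s, y)
}

#' Collect labeled training patches from manifest fields
#'
#' Reads each field, percentile-normalizes it, applies its mask (from
#' `mask_path` or [segmentForeground()]), tiles and filters patches, and
#' returns the retained patch pixels with their field labels.
#'
#' @param manifest Manifest data frame (possibly a training subset).
#' @param patchSize,stride,minFg Patch geometry and filter.
#' @param maxPerField Cap on patches kept per field (seeded subsample);
#'   `Inf` keeps all.
#' @param seed Seed for the per-field subsample.
#' @return List with `patches` (list of matrices), `labels`, `fieldIds`.
#' @export
collectPatches <- function(manifest, patchSize = 112, stride = 100,
                           minFg = 0.5, maxPerField = Inf, seed = 1) {
  patches <- list(); labels <- character(); fieldIds <- character()
  for (i in seq_len(nrow(manifest))) {
    fld <- readField(manifest$path[i], fieldId = manifest$field_id[i])
    img <- normalizePercentile(
      if (is(fld, "FluorescenceField")) fieldImage(fld) else maxProject(fld))
    mask <- if ("mask_path" %in% names(manifest) &&
                !is.na(manifest$mask_path[i])) {
      m <- tiff::readTIFF(manifest$mask_path[i])
      matrix(as.numeric(m > 0.5), nrow(m), ncol(m))
    } else segmentForeground(img)
    pool <- filterPatches(tilePatches(img, mask, patchSize, stride), minFg)
    if (length(pool) == 0) next
    keep <- seq_len(length(pool))
    if (is.finite(maxPerField) && length(pool) > maxPerField)
      keep <- withSeed(deriveSeed(seed, i),
                       sort(sample.int(length(pool), maxPerField)))
    px <- extractPatches(img, pool)[keep]
    patches <- c(patches, px)
    labels <- c(labels, rep(manifest$label[i], length(keep)))
    fieldIds <- c(fieldIds, rep(manifest$field_id[i], length(keep)))
  }
  list(patches = patches, labels = labels, fieldIds = fieldIds)
}

#' Fold-wise train / score / evaluate
#'
#' Orchestrates grouped cross-validation for one task: for each requested
#' fold, trains a classifier on the patches of all other folds' fields and
#' Monte-Carlo-scores the held-out fields. Fields whose label is outside
#' the task's classes are ignored.
#'
#' @param manifest Manifest data frame.
#' @param folds A [FoldAssignment-class] from [makeGroupedFolds()].
#' @param config A [trainConfig()].
#' @param testFolds Folds to hold out in turn (default: all folds).
#' @param rounds,k Monte-Carlo scoring parameters.
#' @param patchSize,stride,minFg Patch geometry and filter.
#' @param maxPerField Training patch cap per field.
#' @param seed Root seed.
#' @return List with `fieldScores` (per held-out field, with `fold`
#'   column), `metrics` (per fold), `foldScoreTable` (the aggregated
#'   fold/group score table from [aggregateFoldScores()]), `models`.
#' @export
crossValidate <- function(manifest, folds, config, testFolds = NULL,
                          rounds = 100, k = 4, patchSize = 112, stride = 100,
                          minFg = 0.5, maxPerField = Inf, seed = 1) {
  cls <- taskClasses(config$task)
  manifest <- manifest[manifest$label %in% cls, , drop = FALSE]
  fmap <- setNames(folds@assignment$fold, folds@assignment$experiment_id)
  manifest$fold <- as.integer(fmap[manifest$experiment_id])
  if (is.null(testFolds)) testFolds <- sort(unique(manifest$fold))
  allScores <- list(); metrics <- list(); models <- list()
  for (f in testFolds) {
    trainMan <- manifest[manifest$fold != f, , drop = FALSE]
    testMan <- manifest[manifest$fold == f, , drop = FALSE]
    tr <- collectPatches(trainMan, patchSize, stride, minFg, maxPerField,
                         seed = deriveSeed(seed, f))
    cfg <- config
    cfg$seed <- deriveSeed(config$seed, f)
    model <- trainModel(tr$patches, tr$labels, cfg)
    sc <- scoreCohort(model, testMan, rounds = rounds, k = k,
                      seed = deriveSeed(seed, 7000L + f),
                      patchSize = patchSize, stride = stride, minFg = minFg)
    sc$fold <- f
    pred <- cls[max.col(as.matrix(sc[, paste0(cls, "_score")]))]
    m <- classificationMetrics(sc$label, pred)
    rocs <- if (length(cls) == 2)
      rocAuc(sc[[paste0(cls[1], "_score")]], sc$label, positive = cls[1])$auc
    else NA_real_
    metrics[[as.character(f)]] <- data.frame(
      fold = f, accuracy = m$accuracy, precision = m$precision,
      recall = m$recall, f1 = m$f1, roc_auc = rocs)
    allScores[[as.character(f)]] <- sc
    models[[as.character(f)]] <- model
  }
  fieldScores <- do.call(rbind, allScores)
  rownames(fieldScores) <- NULL
  perFold <- do.call(rbind, lapply(split(fieldScores,
                                         list(fieldScores$fold,
                                              fieldScores$label),
                                         drop = TRUE), function(d) {
    row <- data.frame(fold = d$fold[1], group = d$label[1])
    for (sc in paste0(cls, "_score")) row[[sc]] <- mean(d[[sc]])
    row
  }))
  rownames(perFold) <- NULL
  fst <- if (length(testFolds) == length(unique(manifest$fold)))
    aggregateFoldScores(perFold) else perFold
  list(fieldScores = fieldScores,
       metrics = do.call(rbind, metrics),
       foldScoreTable = fst,
       models = models)
}
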