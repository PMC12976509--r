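#' Monte-Carlo multi-patch ensemble score of one field
#'
#' The ensemble inference at the heart of field-level scoring: for each of
#' `rounds` rounds, `k` patches are drawn at random from the filtered patch
#' pool and classified; the field score is the average probability vector
#' over all rounds. Because inference is deterministic per patch, each pool
#' patch is classified once and the round structure reduces to a weighted
#' average — numerically identical to mean-over-rounds of mean-over-k.
#' Per-round sampling seeds are derived from `seed`, so rounds are
#' order-independent and the whole score is reproducible.
#'
#' @param model A [MitoCNN-class].
#' @param field Field-like object or matrix; intensities are percentile-
#'   normalized to [0, 1] automatically when the image is on a raw scale.
#' @param mask Binary foreground mask; `NULL` runs [segmentForeground()].
#' @param rounds Monte-Carlo rounds (default 100).
#' @param k Patches per round (default 4).
#' @param seed Root seed of the patch sampling.
#' @param patchSize,stride,minFg Patch geometry and filter, see
#'   [tilePatches()] and [filterPatches()].
#' @return One-row data frame: `field_id`, one `<class>_score` column per
#'   class, `n_rounds`, `k_patches`, `pool_size`.
#' @export
scoreField <- function(model, field, mask = NULL, rounds = 100, k = 4,
                       seed = 1, patchSize = 112, stride = 100,
                       minFg = 0.5) {
  stopifnot2(rounds >= 1, "rounds must be >= 1")
  img <- fieldImage(field)
  if (max(img) > 1) img <- normalizePercentile(img)
  if (is.null(mask)) mask <- segmentForeground(img)
  fieldId <- if (is(field, "FluorescenceField")) field@fieldId else "field"
  pool <- filterPatches(tilePatches(img, mask, patchSize, stride), minFg)
  pool@fieldId <- fieldId
  n <- length(pool)
  if (n == 0)
    stop(sprintf("field-unusable: empty filtered patch pool for '%s'",
                 fieldId))
  probs <- predictPatch(model, extractPatches(img, pool))
  counts <- integer(n)
  if (n < k)
    warning(sprintf(
      "patch pool of '%s' (%d) smaller than k=%d; sampling with replacement",
      fieldId, n, k))
  for (r in seq_len(rounds)) {
    idx <- suppressWarnings(
      .samplePatchIdx(n, k, deriveSeed(seed, r), fieldId))
    counts <- counts + tabulate(idx, nbins = n)
  }
  score <- colSums(probs * counts) / sum(counts)
  out <- data.frame(field_id = fieldId, t(score), n_rounds = rounds,
                    k_patches = k, pool_size = n, stringsAsFactors = FALSE)
  names(out)[2:(1 + length(score))] <- paste0(model@classOrder, "_score")
  out
}

#' Score every field of a manifest
#'
#' One [scoreField()] row per usable field; fields whose filtered patch pool
#' is empty are skipped with a message. Masks are taken from the manifest's
#' `mask_path` column when present, otherwise computed with
#' [segmentForeground()].
#'
#' @param model A [MitoCNN-class].
#' @param manifest Manifest data frame (see [readManifest()]).
#' @param rounds,k,patchSize,stride,minFg As in [scoreField()].
#' @param seed Root seed; per-field seeds are derived from it.
#' @return Data frame of field scores joined with the manifest metadata
#'   columns (`label`, `experiment_id`, `participant_id`, `group`, `phi`
#'   where available).
#' @export
scoreCohort <- function(model, manifest, rounds = 100, k = 4, seed = 1,
                        patchSize = 112, stride = 100, minFg = 0.5) {
  rows <- list()
  skipped <- 0L
  for (i in seq_len(nrow(manifest))) {
    fld <- readField(manifest$path[i], fieldId = manifest$field_id[i])
    img <- if (is(fld, "FluorescenceField")) fieldImage(fld) else
      maxProject(fld)
    mask <- if ("mask_path" %in% names(manifest) &&
                !is.na(manifest$mask_path[i])) {
      m <- tiff::readTIFF(manifest$mask_path[i])
      matrix(as.numeric(m > 0.5), nrow(m), ncol(m))
    } else NULL
    nf <- fluorescenceField(normalizePercentile(img),
                            manifest$field_id[i])
    row <- tryCatch(
      scoreField(model, nf, mask, rounds = rounds,
                 k = k, seed = deriveSeed(seed, i), patchSize = patchSize,
                 stride = stride, minFg = minFg),
      error = function(e) {
        if (grepl("field-unusable", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(row)) {
      skipped <- skipped + 1L
      message(sprintf("skipping field '%s': empty filtered patch pool",
                      manifest$field_id[i]))
      next
    }
    row$field_id <- manifest$field_id[i]
    for (colnm in intersect(c("label", "experiment_id", "participant_id",
                              "group", "phi"), names(manifest)))
      row[[colnm]] <- manifest[[colnm]][i]
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows))
    stop("run-level error: zero usable fields in manifest")
  if (skipped > 0)
    message(sprintf("%d of %d fields skipped", skipped, nrow(manifest)))
  do.call(rbind, rows)
}

#' Participant-level score aggregation
#'
#' Unweighted mean of each participant's field-score vectors (fields are
#' not weighted by their patch-pool size).
#'
#' @param fieldScores Data frame from [scoreCohort()] with a
#'   `participant_id` column.
#' @return Data frame with one row per participant: `participant_id`,
#'   `group` (if present), mean `<class>_score` columns, `n_fields`.
#' @export
scoreParticipant <- function(fieldScores) {
  stopifnot2("participant_id" %in% names(fieldScores),
             "fieldScores lacks participant_id")
  scoreCols <- grep("_score$", names(fieldScores), value = TRUE)
  sp <- split(fieldScores, fieldScores$participant_id)
  rows <- lapply(sp, function(d) {
    out <- data.frame(participant_id = d$participant_id[1],
                      stringsAsFactors = FALSE)
    if ("group" %in% names(d)) out$group <- d$group[1]
    for (sc in scoreCols) out[[sc]] <- mean(d[[sc]])
    out$n_fields <- nrow(d)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
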