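# Shared fixtures. Heavy objects (the synthetic desk-scale dataset and the
# classifiers trained on it) are built once per test session and cached in
# .fixtures / on disk under tempdir(), so the acceptance tests and the unit
# tests that need a trained model share one training run per task/seed.

.fixtures <- new.env(parent = emptyenv())

fixtureDir <- function() {
  d <- file.path(tempdir(), "mitoscore-fixtures")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# rasterized disc of radius r on a (2r+9)^2 canvas
discMask <- function(r, S = 2 * r + 9) {
  ctr <- (S + 1) / 2
  m <- matrix(0L, S, S)
  d <- sqrt(outer((1:S - ctr)^2, (1:S - ctr)^2, `+`))
  m[d <= r] <- 1L
  m
}

# the desk-scale study dataset: 30 fields per class at 512 px, default specs
deskManifest <- function() memo("deskManifest", function() {
  dir <- file.path(fixtureDir(), "desk")
  if (!file.exists(file.path(dir, "manifest.csv")))
    generateDataset(defaultClassSpecs(), 30, dir, seed = 11)
  readManifest(file.path(dir, "manifest.csv"))
})

# grouped split of the desk dataset: fold 0 held out
deskSplit <- function() memo("deskSplit", function() {
  man <- deskManifest()
  folds <- makeGroupedFolds(man, nFolds = 5, seed = 11)
  fmap <- setNames(folds@assignment$fold, folds@assignment$experiment_id)
  man$fold <- as.integer(fmap[man$experiment_id])
  list(train = man[man$fold != 0, ], test = man[man$fold == 0, ],
       folds = folds, manifest = man)
})

# training patch pool of the desk split (dense tiling for training only)
deskTrainPatches <- function() memo("deskTrainPatches", function() {
  collectPatches(deskSplit()$train, stride = 56, seed = 1)
})

deskModel <- function(task, seed) {
  key <- sprintf("model_%s_%d", task, seed)
  memo(key, function() {
    tr <- deskTrainPatches()
    cls <- taskClasses(task)
    keep <- tr$labels %in% cls
    cfg <- trainConfig(task = task, epochs = 10, lr = 3e-3, batchSize = 16,
                       inputSize = 112, seed = seed)
    trainModel(tr$patches[keep], tr$labels[keep], cfg)
  })
}

# small toy model: bright-vs-dark separable task, no augmentation
toyModel <- function() memo("toyModel", function() {
  set.seed(404)
  patches <- c(lapply(1:40, function(i) matrix(runif(64^2, 0.6, 1), 64, 64)),
               lapply(1:40, function(i) matrix(runif(64^2, 0, 0.4), 64, 64)))
  labels <- rep(c("FL3", "NC"), each = 40)
  aug <- augmentSpec(jitterFactor = 0, hflip = FALSE, vflip = FALSE,
                     rot90 = FALSE, rrcScale = c(1, 1), outSize = 64)
  cfg <- trainConfig(task = "FL3-NC", epochs = 5, lr = 5e-3, seed = 2,
                     augment = aug)
  trainModel(patches, labels, cfg)
})

# a field with known usable patch pool, plus its mask
tinyScoredField <- function() memo("tinyScoredField", function() {
  fld <- simulateField(morphologySpec(fieldSizePx = 384, seed = 21))
  img <- normalizePercentile(fld@image)
  list(field = fld, img = img, mask = fld@truthMask)
})

# mean hyperfusion score per continuum level (upper half of the continuum),
# scored with a given model against simulator truth masks
continuumScores <- function(model, phis = c(0.5, 0.625, 0.75, 0.875, 1),
                            nPer = 10, seedBase = 9000) {
  key <- sprintf("continuum_%s_%d", model@task, nPer)
  memo(key, function() {
    vapply(phis, function(phi) {
      scores <- vapply(seq_len(nPer), function(s) {
        fld <- simulateField(morphologySpec(phi = phi,
                                            seed = seedBase + round(1000 * phi) + s))
        fs <- suppressWarnings(
          scoreField(model, normalizePercentile(fld@image), fld@truthMask,
                     rounds = 50, k = 4, seed = s))
        fs$FL3_score
      }, 0)
      mean(scores)
    }, 0)
  })
}

# synthetic cohort: participants with mildly hyperfused fields (phi = 0.8)
# vs normal fields (phi = 0.5), >= 5 fields each
cohortScores <- function(model, nPerGroup = 8, nFields = 5) {
  memo("cohortScores", function() {
    rows <- list()
    for (g in c("AD", "CN")) {
      phi <- if (g == "AD") 0.8 else 0.5
      for (p in seq_len(nPerGroup)) {
        pid <- sprintf("%s_%02d", g, p)
        for (f in seq_len(nFields)) {
          sd0 <- 70000 + (g == "AD") * 10000 + p * 100 + f
          fld <- simulateField(morphologySpec(phi = phi, seed = sd0))
          fs <- suppressWarnings(
            scoreField(model, normalizePercentile(fld@image), fld@truthMask,
                       rounds = 50, k = 4, seed = sd0))
          fs$participant_id <- pid
          fs$group <- g
          rows[[length(rows) + 1L]] <- fs
        }
      }
    }
    do.call(rbind, rows)
  })
}
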