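test_that("patch tiling matches brute-force origin enumeration", {
  set.seed(8)
  for (i in 1:12) {
    H <- sample(120:400, 1); W <- sample(120:400, 1)
    ps <- sample(c(48, 64, 112), 1)
    st <- sample(c(30, 50, 100), 1)
    got <- tilePatches(matrix(0, H, W), patchSize = ps, stride = st)
    # brute force: every 0-based origin on the stride grid that fits
    orig <- expand.grid(r = seq(0, H, st), c = seq(0, W, st))
    orig <- orig[orig$r + ps <= H & orig$c + ps <= W, ]
    expect_equal(length(got), nrow(orig))
  }
  # the standard full-field geometry: 20 x 20 placements
  full <- tilePatches(matrix(0, 2048, 2048), patchSize = 112, stride = 100)
  expect_equal(length(full), 400)
  # minimal field: exactly one patch at the origin
  one <- tilePatches(matrix(0, 112, 112), patchSize = 112, stride = 100)
  expect_equal(length(one), 1)
  expect_equal(one@origins[1, ], c(0, 0), ignore_attr = TRUE)
  expect_error(tilePatches(matrix(0, 100, 100), patchSize = 112),
               "patchSize")
})

test_that("foreground fractions are exact and ordering is row-major", {
  img <- matrix(0, 200, 200)
  mask <- matrix(0, 200, 200)
  mask[1:100, ] <- 1   # top half foreground
  ps <- tilePatches(img, mask, patchSize = 50, stride = 50)
  expect_equal(length(ps), 16)
  # row-major: first four patches are the first row of origins
  expect_equal(ps@origins[1:4, 2], c(0, 50, 100, 150))
  # exact fractions: rows 0 and 50 fully fg, row 50..100 fg, row 100+ bg
  direct <- vapply(seq_len(length(ps)), function(i) {
    o <- ps@origins[i, ]
    mean(mask[(o[1] + 1):(o[1] + 50), (o[2] + 1):(o[2] + 50)])
  }, 0)
  expect_equal(ps@fgFraction, direct)
  # all-foreground mask gives fraction 1 everywhere
  allfg <- tilePatches(img, matrix(1, 200, 200), patchSize = 50, stride = 50)
  expect_true(all(allfg@fgFraction == 1))
})

test_that("the 50% filter keeps the boundary patch and preserves order", {
  ps <- new("PatchSet", fieldId = "f", patchSize = 10, fieldDim = c(100, 100),
            origins = cbind(c(0L, 10L, 20L), 0L),
            fgFraction = c(0.49, 0.50, 0.51))
  kept <- filterPatches(ps)
  expect_equal(kept@fgFraction, c(0.50, 0.51))
  expect_equal(kept@origins[, 1], c(10L, 20L))
  # min_fg = 0 keeps everything; all-background yields an empty set
  expect_equal(length(filterPatches(ps, 0)), 3)
  none <- new("PatchSet", fieldId = "f", patchSize = 10,
              fieldDim = c(100, 100), origins = cbind(c(0L, 10L), 0L),
              fgFraction = c(0, 0))
  expect_equal(length(filterPatches(none)), 0)
})

test_that("patch sampling saturates, reproduces under a seed, and is uniform", {
  ps <- tilePatches(matrix(0, 130, 130), matrix(1, 130, 130),
                    patchSize = 64, stride = 22)
  # pool of exactly k: every draw returns the whole pool
  four <- filterPatches(tilePatches(matrix(0, 112, 130), matrix(1, 112, 130),
                                    patchSize = 112, stride = 6))
  expect_equal(length(four), 4)
  s1 <- samplePatches(four, k = 4, seed = 1)
  expect_equal(sort(s1@origins[, 2]), sort(four@origins[, 2]))
  # determinism and seed sensitivity
  a <- samplePatches(ps, k = 4, seed = 10)
  b <- samplePatches(ps, k = 4, seed = 10)
  c <- samplePatches(ps, k = 4, seed = 11)
  expect_identical(a@origins, b@origins)
  expect_false(identical(a@origins, c@origins))
  # inclusion probability k/n = 0.5 on a pool of 8
  counts <- integer(8)
  for (d in 1:10000) {
    idx <- mitoscore:::.samplePatchIdx(8, 4, seed = d)
    counts[idx] <- counts[idx] + 1L
  }
  expect_true(all(abs(counts / 10000 - 0.5) < 0.02))
  # empty pool carries the field id
  empty <- filterPatches(ps, 2)
  expect_error(samplePatches(empty, 4, seed = 1), "field-unusable")
  # undersized pool warns and samples with replacement
  expect_warning(out <- samplePatches(four, k = 6, seed = 3), "replacement")
  expect_equal(length(out), 6)
})

test_that("every retained patch has at least half its pixels in the mask", {
  sf <- tinyScoredField()
  ps <- filterPatches(tilePatches(sf$img, sf$mask, patchSize = 112,
                                  stride = 50))
  expect_gt(length(ps), 0)
  for (i in seq_len(length(ps))) {
    o <- ps@origins[i, ]
    frac <- mean(sf$mask[(o[1] + 1):(o[1] + 112), (o[2] + 1):(o[2] + 112)])
    expect_gte(frac, 0.5)
  }
})

test_that("classical foreground segmentation recovers simulated cell regions", {
  # quality contract measured against simulator ground truth
  man <- deskManifest()
  set.seed(13)
  rows <- man[sample(nrow(man), 21), ]
  covs <- jacs <- numeric(0)
  for (i in seq_len(nrow(rows))) {
    img <- normalizePercentile(fieldImage(readField(rows$path[i])))
    tr <- tiff::readTIFF(rows$mask_path[i]) > 0.5
    m <- segmentForeground(img) > 0
    covs <- c(covs, sum(m & tr) / sum(tr))
    jacs <- c(jacs, sum(m & tr) / sum(m | tr))
  }
  expect_gte(mean(covs), 0.95)
  expect_gte(mean(jacs), 0.7)
})

test_that("segmentation degenerate cases behave", {
  z <- segmentForeground(matrix(0, 64, 64))
  expect_true(all(z == 0))
  expect_error(segmentForeground(array(0, c(4, 4, 2))), "2D")
  # single bright disc: one component with near-analytic area
  img <- matrix(0, 256, 256)
  d <- sqrt(outer((1:256 - 128)^2, (1:256 - 128)^2, `+`))
  img[d <= 50] <- 1
  # a hard-edged disc needs no soft-rim threshold compensation
  m <- segmentForeground(img, sigma = 4, minObjectPx = 100,
                         thresholdScale = 1)
  lab <- mitoscore:::labelComponents(m)
  expect_equal(max(lab), 1)
  expect_lt(abs(sum(m) - pi * 50^2) / (pi * 50^2), 0.2)
})
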