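test_that("continuum endpoints produce pure punctate / pure filament geometry", {
  geoFission <- sampleMitoGeometry(morphologySpec(phi = 0, ringFraction = 0,
                                                  seed = 3))
  for (cell in geoFission$cells) {
    expect_gt(nrow(cell$discs), 0)
    expect_length(cell$curves, 0)
    expect_true(all(!cell$discs$ring))
  }
  geoFusion <- sampleMitoGeometry(morphologySpec(phi = 1, seed = 3))
  nCurves <- sum(vapply(geoFusion$cells, function(c) length(c$curves), 0L))
  nDiscs <- sum(vapply(geoFusion$cells, function(c) nrow(c$discs), 0L))
  expect_identical(nDiscs, 0L)
  expect_gt(nCurves, 0)
  # expected filament count at phi=1 is far below expected puncta at phi=0
  expect_lt(expectedPrimitiveCount(morphologySpec(phi = 1)),
            expectedPrimitiveCount(morphologySpec(phi = 0)))
})

test_that("mean primitive count decreases along the continuum and tracks the expectation formula", {
  phis <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(phis, function(phi) {
    counts <- vapply(1:50, function(s) {
      geo <- sampleMitoGeometry(morphologySpec(phi = phi, nCells = 1,
                                               seed = 1000 + s))
      sum(vapply(geo$cells,
                 function(c) nrow(c$discs) + length(c$curves), 0L))
    }, 0)
    mean(counts)
  }, 0)
  expect_true(all(diff(means) < 0))
  expected <- vapply(phis, function(phi)
    expectedPrimitiveCount(morphologySpec(phi = phi)), 0)
  # Monte-Carlo means stay within 3 standard errors of the Poisson mean
  se <- sqrt(expected / 50)
  expect_true(all(abs(means - expected) < 3.5 * se + 1))
})

test_that("rendering is byte-identical under a fixed seed", {
  spec <- morphologySpec(phi = 0.3, fieldSizePx = 256, seed = 77)
  f1 <- simulateField(spec)
  f2 <- simulateField(spec)
  expect_identical(f1@image, f2@image)
  expect_identical(f1@truthMask, f2@truthMask)
})

test_that("noiseless, unblurred render contains exactly the rasterized primitives", {
  spec <- morphologySpec(phi = 0, fieldSizePx = 256, nCells = 1,
                         fragmentRate = 20, ringFraction = 0,
                         psfSigmaPx = 0, noiseLevel = 0, seed = 5)
  geo <- sampleMitoGeometry(spec)
  fld <- renderField(geo, spec)
  nz <- fld@image > 0
  # every nonzero pixel lies within 1 px of a sampled disc
  discs <- do.call(rbind, lapply(geo$cells, function(c) c$discs))
  idx <- which(nz, arr.ind = TRUE)
  d <- outer(idx[, 1], discs$x, `-`)^2 + outer(idx[, 2], discs$y, `-`)^2
  nearest <- sqrt(apply(d, 1, min))
  maxr <- vapply(seq_len(nrow(idx)), function(i)
    discs$r[which.min(d[i, ])], 0)
  expect_true(all(nearest <= maxr + 1))
  # and all signal sits inside the truth mask
  expect_true(all(fld@truthMask[nz] == 1))
})

test_that("thresholded noiseless field has one component per isolated punctum", {
  spec <- morphologySpec(phi = 0, fieldSizePx = 256, nCells = 1,
                         fragmentRate = 12, ringFraction = 0,
                         psfSigmaPx = 0, noiseLevel = 0, seed = 9)
  geo <- sampleMitoGeometry(spec)
  fld <- renderField(geo, spec)
  discs <- do.call(rbind, lapply(geo$cells, function(c) c$discs))
  # geometric oracle: cluster discs whose rasterizations can touch
  n <- nrow(discs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dd <- sqrt((discs$x[i] - discs$x[j])^2 + (discs$y[i] - discs$y[j])^2)
    adj[i, j] <- dd < discs$r[i] + discs$r[j] + 2.5
  }
  reach <- adj
  for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  clusters <- length(unique(apply(reach, 1, function(r)
    paste(which(r), collapse = ","))))
  comp <- max(mitoscore:::labelComponents(fld@image > 0))
  expect_equal(comp, clusters)
})

test_that("truth labels partition the continuum at thirds", {
  expect_identical(phiLabel(c(0, 0.33, 1 / 3, 0.5, 0.66, 2 / 3, 1)),
                   c("CCCP", "CCCP", "NC", "NC", "NC", "FL3", "FL3"))
  expect_error(phiLabel(1.2), "phi")
})

test_that("truth-mask foreground fraction is moderate for default specs", {
  for (spec in defaultClassSpecs()) {
    spec@seed <- 31
    fld <- simulateField(spec)
    expect_gt(mean(fld@truthMask), 0.05)
    expect_lt(mean(fld@truthMask), 0.6)
  }
})

test_that("generateDataset writes a consistent, reproducible dataset", {
  d1 <- file.path(fixtureDir(), "gen1")
  d2 <- file.path(fixtureDir(), "gen2")
  specs <- lapply(defaultClassSpecs(fieldSizePx = 128),
                  function(s) { s@nCells <- 1; s@cellRadiusPx <- 40; s })
  m1 <- generateDataset(specs, 3, d1, seed = 4)
  m2 <- generateDataset(specs, 3, d2, seed = 4)
  expect_equal(nrow(m1), 9)
  expect_true(all(file.exists(file.path(d1, m1$path))))
  expect_true(all(file.exists(file.path(d1, m1$mask_path))))
  # labels match the generating coordinate
  expect_identical(m1$label, phiLabel(m1$phi))
  # same seed => identical image bytes
  h1 <- tools::md5sum(file.path(d1, sort(m1$path)))
  h2 <- tools::md5sum(file.path(d2, sort(m2$path)))
  expect_identical(unname(h1), unname(h2))
  # batches assigned round-robin
  expect_true(all(table(m1$experiment_id) > 0))
})

test_that("invalid spec parameters are rejected by name", {
  expect_error(morphologySpec(phi = 1.5), "phi")
  expect_error(morphologySpec(nCells = 0), "nCells")
  expect_error(morphologySpec(ringFraction = 2), "ringFraction")
  expect_error(simulateField(morphologySpec(fieldSizePx = 64,
                                            cellRadiusPx = 60)),
               "geometry")
})
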