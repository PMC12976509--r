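test_that("form factor and aspect ratio match analytic shapes", {
  for (r in c(10, 20, 30)) {
    sm <- shapeMetrics(discMask(r))
    expect_lt(abs(sm$formFactor - 1), 0.05)
    expect_lt(abs(sm$aspectRatio - 1), 0.05)
  }
  rect <- matrix(0L, 30, 90)
  rect[6:25, 6:85] <- 1L  # 20 x 80 object
  sm <- shapeMetrics(rect)
  expect_lt(abs(sm$aspectRatio - 4), 0.1)
  expect_lt(abs(sm$formFactor - (2 * (80 + 20))^2 / (4 * pi * 1600)), 0.1)
})

test_that("degenerate one-pixel-wide objects are flagged unreliable", {
  line <- matrix(0L, 5, 40)
  line[3, 3:38] <- 1L
  sm <- shapeMetrics(line)
  expect_false(sm$reliable)
  dot <- matrix(0L, 5, 5); dot[3, 3] <- 1L
  expect_false(shapeMetrics(dot)$reliable)
})

test_that("form factor never falls below the discretization floor", {
  set.seed(41)
  for (i in 1:30) {
    m <- matrix(0L, 40, 40)
    m[sample(1600, sample(20:80, 1))] <- 1L
    m <- as.matrix(EBImage::closing(EBImage::Image(m),
                                    EBImage::makeBrush(5, "disc")))
    lab <- mitoscore:::labelComponents(m)
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      if (nrow(idx) < 4) next
      om <- matrix(0L, 42, 42)
      om[idx + 1L] <- 1L
      sm <- shapeMetrics(om)
      if (sm$reliable) {
        expect_gte(sm$formFactor, 1 - 0.05)
        expect_gte(sm$aspectRatio, 1)
      }
    }
  }
})

test_that("skeleton graphs of canonical shapes are exact", {
  seg <- matrix(0L, 9, 60)
  seg[5, 6:55] <- 1L
  g <- skeletonGraph(seg)
  expect_equal(g@nBranches, 1)
  expect_equal(g@nJunctions, 0)
  expect_lt(abs(sum(g@branches$length) - 49), 1.01)
  plus <- matrix(0L, 41, 41)
  plus[21, 6:36] <- 1L
  plus[6:36, 21] <- 1L
  g <- skeletonGraph(plus)
  expect_equal(g@nBranches, 4)
  expect_equal(g@nJunctions, 1)
  # empty mask: empty graph
  g0 <- skeletonGraph(matrix(0L, 10, 10))
  expect_equal(g0@nBranches, 0)
  expect_equal(g0@nJunctions, 0)
})

test_that("skeleton metrics are additive over disjoint components", {
  a <- matrix(0L, 20, 70); a[5, 6:65] <- 1L
  b <- matrix(0L, 20, 70); b[15, 6:35] <- 1L
  both <- pmax(a, b)
  ga <- skeletonGraph(a); gb <- skeletonGraph(b); gab <- skeletonGraph(both)
  expect_equal(gab@nBranches, ga@nBranches + gb@nBranches)
  expect_equal(sum(gab@branches$length),
               sum(ga@branches$length) + sum(gb@branches$length))
})

test_that("skeleton total length is invariant under translation and rotation", {
  set.seed(6)
  m <- matrix(0L, 80, 80)
  m[30:34, 10:70] <- 1L
  m[10:60, 40:44] <- 1L
  base <- sum(skeletonGraph(m)@branches$length)
  shifted <- matrix(0L, 90, 90)
  shifted[6:85, 4:83] <- m
  expect_lt(abs(sum(skeletonGraph(shifted)@branches$length) - base), 1.5)
  rot <- t(m[rev(seq_len(nrow(m))), ])
  expect_lt(abs(sum(skeletonGraph(rot)@branches$length) - base), 1.5)
})

test_that("mitochondria segmentation counts isolated puncta correctly", {
  spec <- morphologySpec(phi = 0, fieldSizePx = 256, nCells = 1,
                         fragmentRate = 12, ringFraction = 0,
                         psfSigmaPx = 0, noiseLevel = 0, seed = 9)
  geo <- sampleMitoGeometry(spec)
  fld <- renderField(geo, spec)
  lab <- segmentMitochondria(fld@image / max(fld@image), fld@truthMask)
  nDiscs <- sum(vapply(geo$cells, function(c) nrow(c$discs), 0L))
  expect_lt(abs(max(lab) - nDiscs) / nDiscs, 0.25)
  # degenerate inputs
  expect_equal(max(segmentMitochondria(matrix(0, 64, 64))), 0)
  one <- matrix(0, 64, 64); one[20:30, 20:30] <- 1
  expect_equal(max(segmentMitochondria(one)), 1)
})

test_that("morphometry orders the fission-fusion continuum correctly", {
  # noiseless single-cell fields across the continuum
  phis <- c(0, 0.25, 0.5, 0.75, 1)
  nPer <- 30
  res <- lapply(phis, function(phi) {
    rows <- lapply(seq_len(nPer), function(s) {
      spec <- morphologySpec(phi = phi, fieldSizePx = 192, nCells = 1,
                             cellRadiusPx = 60, psfSigmaPx = 0,
                             noiseLevel = 0, seed = 3000 + s)
      fld <- simulateField(spec)
      fieldMorphometry(fld@image / 30000, fld@truthMask)
    })
    do.call(rbind, rows)
  })
  counts <- vapply(res, function(d) mean(d$object_count), 0)
  ars <- vapply(res, function(d) mean(d$ar_mean, na.rm = TRUE), 0)
  blen <- vapply(res, function(d)
    mean(d$mean_branch_length, na.rm = TRUE), 0)
  # spearman monotonicity along the continuum
  expect_lte(cor(counts, phis, method = "spearman"), -0.9)
  expect_gte(cor(ars, phis, method = "spearman"), 0.9)
  expect_gte(cor(blen, phis, method = "spearman"), 0.9)
  # endpoint contrasts mirror the qualitative biology
  expect_gt(ars[5], ars[1])
  expect_gt(blen[5], blen[1])
  expect_lt(counts[5], counts[1])
  # the classical baseline separates hyperfission from normal far more
  # strongly than hyperfusion from normal
  d <- function(a, b) abs(mean(a) - mean(b)) /
    sqrt((stats::var(a) + stats::var(b)) / 2)
  dFission <- d(res[[1]]$object_count, res[[3]]$object_count)
  dFusion <- d(res[[5]]$ar_mean, res[[3]]$ar_mean)
  expect_gt(dFission, dFusion)
})

test_that("empty segmentations yield the NaN summary row", {
  row <- fieldMorphometry(matrix(0, 64, 64))
  expect_equal(row$object_count, 0)
  expect_true(is.nan(row$ff_mean))
})
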