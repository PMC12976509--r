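test_that("two-patch pools with k=2 average both patches exactly", {
  m <- toyModel()
  sf <- tinyScoredField()
  # disjoint 112-px tiling: mask exactly two tiles so the filtered pool is
  # exactly those two patches (all other tiles have zero foreground)
  maskTwo <- matrix(0, nrow(sf$img), ncol(sf$img))
  maskTwo[1:112, 1:112] <- 1
  maskTwo[113:224, 113:224] <- 1
  pool <- filterPatches(tilePatches(sf$img, maskTwo, patchSize = 112,
                                    stride = 112), 0.5)
  expect_equal(length(pool), 2)
  probs <- predictPatch(m, extractPatches(sf$img, pool))
  # with k = n = 2 every round draws both patches: the field score is the
  # exact pool mean for any number of rounds
  for (rounds in c(1, 7)) {
    fsc <- scoreField(m, sf$img, maskTwo, rounds = rounds, k = 2, seed = 5,
                      patchSize = 112, stride = 112)
    got <- as.numeric(fsc[, paste0(classOrder(m), "_score")])
    expect_equal(got, colMeans(probs), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("field scores are probability vectors and reproducible", {
  m <- toyModel()
  sf <- tinyScoredField()
  a <- scoreField(m, sf$img, sf$mask, rounds = 10, k = 4, seed = 3)
  b <- scoreField(m, sf$img, sf$mask, rounds = 10, k = 4, seed = 3)
  expect_equal(a, b)
  sc <- as.numeric(a[, paste0(classOrder(m), "_score")])
  expect_equal(sum(sc), 1, tolerance = 1e-6)
  expect_true(all(sc >= 0))
  expect_equal(a$n_rounds, 10)
  # seed sensitivity of the sampling itself (pools at or below k always
  # draw every patch, so compare draw counts on a larger pool)
  c1 <- tabulate(mitoscore:::.samplePatchIdx(9, 4, seed = 3), 9)
  c2 <- tabulate(mitoscore:::.samplePatchIdx(9, 4, seed = 4), 9)
  expect_false(identical(c1, c2))
})

test_that("the infinite-round limit is the uniform pool mean", {
  # exact enumeration oracle: k-subsets without replacement include every
  # patch with equal probability, so E[score] = column mean over the pool
  m <- toyModel()
  sf <- tinyScoredField()
  pool <- filterPatches(tilePatches(sf$img, sf$mask, patchSize = 112,
                                    stride = 90), 0.5)
  n <- length(pool)
  expect_true(n >= 5 && n <= 8)
  probs <- predictPatch(m, extractPatches(sf$img, pool))
  subsets <- utils::combn(n, 4)
  enumMean <- rowMeans(apply(subsets, 2, function(ix) colMeans(probs[ix, ])))
  expect_equal(enumMean, colMeans(probs), tolerance = 1e-12,
               ignore_attr = TRUE)
  big <- scoreField(m, sf$img, sf$mask, rounds = 400, k = 4, seed = 8,
                    patchSize = 112, stride = 90)
  got <- as.numeric(big[, paste0(classOrder(m), "_score")])
  expect_equal(got, as.numeric(enumMean), tolerance = 0.02)
})

test_that("participant aggregation is an unweighted permutation-invariant mean", {
  fs <- data.frame(field_id = c("a", "b", "c"),
                   participant_id = c("P1", "P1", "P2"),
                   group = c("AD", "AD", "CN"),
                   FL3_score = c(1, 0, 0.25), NC_score = c(0, 1, 0.75))
  ps <- scoreParticipant(fs)
  expect_equal(ps$FL3_score[ps$participant_id == "P1"], 0.5)
  expect_equal(ps$NC_score[ps$participant_id == "P1"], 0.5)
  expect_equal(ps$n_fields, c(2, 1))
  # single field: identity
  expect_equal(ps$FL3_score[ps$participant_id == "P2"], 0.25)
  # permutation invariance
  ps2 <- scoreParticipant(fs[c(3, 1, 2), ])
  expect_equal(ps[order(ps$participant_id), ],
               ps2[order(ps2$participant_id), ], ignore_attr = TRUE)
})

test_that("cohort scoring covers usable fields deterministically", {
  m <- toyModel()
  man <- deskManifest()[c(1:3, 31:33), ]
  sc1 <- suppressWarnings(scoreCohort(m, man, rounds = 5, k = 4, seed = 2))
  sc2 <- suppressWarnings(scoreCohort(m, man, rounds = 5, k = 4, seed = 2))
  expect_equal(sc1, sc2)
  expect_equal(nrow(sc1), 6)
  expect_true(all(c("FL3_score", "NC_score", "label", "pool_size")
                  %in% names(sc1)))
})
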