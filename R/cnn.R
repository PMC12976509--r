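#' Augmentation settings for classifier training
#'
#' The training-time augmentation recipe: brightness and contrast jitter
#' (factor 0.8, i.e. multipliers drawn uniformly from [0.2, 1.8]),
#' horizontal and vertical flips, 90-degree rotations, and random resized
#' cropping (area scale drawn from [0.5, 1] of the patch before resizing
#' back to `outSize`). Inference applies none of this: patches are plain
#' bilinearly resized to the network input.
#'
#' @param jitterFactor Brightness/contrast jitter factor (0 disables).
#' @param hflip,vflip Enable random horizontal/vertical flips.
#' @param rot90 Enable random 90-degree rotations.
#' @param rrcScale Length-2 area-scale range of the random resized crop;
#'   `c(1, 1)` disables cropping.
#' @param outSize Output side length in pixels fed to the network.
#' @return A validated list of class `"AugmentSpec"`.
#' @export
augmentSpec <- function(jitterFactor = 0.8, hflip = TRUE, vflip = TRUE,
                        rot90 = TRUE, rrcScale = c(0.5, 1.0), outSize = 224) {
  stopifnot2(length(rrcScale) == 2 && all(rrcScale > 0) &&
               all(rrcScale <= 1) && rrcScale[1] <= rrcScale[2],
             "rrcScale must be an increasing pair in (0, 1]")
  stopifnot2(jitterFactor >= 0, "jitterFactor must be >= 0")
  stopifnot2(outSize >= 8, "outSize must be >= 8")
  structure(list(jitterFactor = jitterFactor, hflip = hflip, vflip = vflip,
                 rot90 = rot90, rrcScale = rrcScale, outSize = outSize),
            class = "AugmentSpec")
}

#' Training configuration for the patch classifier
#'
#' Defaults are the desk-scale profile (10 epochs, batch 32, 64-px network
#' input, random initialization). The paper-scale profile of the original
#' recipe (200 epochs, batch 128, 224-px input, ImageNet-pretrained
#' ResNet-18) is expressible through the same fields; `arch` is a tag of the
#' compact residual family used here, with `baseWidth` controlling capacity.
#'
#' @param task One of `"CCCP-NC"`, `"FL3-NC"`, `"CCCP-FL3-NC"`.
#' @param epochs Training epochs (>= 1).
#' @param lr Adam learning rate (default 1e-4 at paper scale is also the
#'   default here).
#' @param batchSize Minibatch size.
#' @param inputSize Network input side length (divisible by 8).
#' @param baseWidth Base channel width of the residual network.
#' @param seed RNG seed for initialization, shuffling and augmentation.
#' @param augment An [augmentSpec()]; its `outSize` is forced to
#'   `inputSize`.
#' @param clipNorm Global gradient-norm clip (stabilizes high learning
#'   rates on small minibatches).
#' @param arch Architecture tag (informational).
#' @return A validated list of class `"TrainConfig"`.
#' @export
trainConfig <- function(task = c("CCCP-FL3-NC", "CCCP-NC", "FL3-NC"),
                        epochs = 10, lr = 1e-4, batchSize = 32,
                        inputSize = 64, baseWidth = 8, seed = 1,
                        augment = augmentSpec(outSize = inputSize),
                        clipNorm = 2, arch = "resmini") {
  task <- match.arg(task)
  stopifnot2(lr > 0, "lr must be > 0")
  stopifnot2(epochs >= 1, "epochs must be >= 1")
  stopifnot2(inputSize %% 8 == 0, "inputSize must be divisible by 8")
  stopifnot2(clipNorm > 0, "clipNorm must be > 0")
  augment$outSize <- inputSize
  structure(list(task = task, epochs = epochs, lr = lr,
                 batchSize = batchSize, inputSize = inputSize,
                 baseWidth = baseWidth, seed = seed, augment = augment,
                 clipNorm = clipNorm, arch = arch),
            class = "TrainConfig")
}

#' Classes of a task tag
#'
#' @param task Task tag, e.g. `"FL3-NC"`.
#' @return Character vector of class labels in score-column order (the
#'   treatment class first for binary tasks).
#' @export
taskClasses <- function(task) {
  cls <- strsplit(task, "-")[[1]]
  stopifnot2(all(cls %in% classLabels()) && length(cls) >= 2,
             sprintf("unknown task '%s'", task))
  cls
}

.resize <- function(img, size) {
  if (all(dim(img) == size)) return(img)
  out <- EBImage::imageData(EBImage::resize(EBImage::Image(img),
                                            w = size, h = size))
  matrix(as.numeric(out), size, size)
}

#' Augment one patch for training
#'
#' Applies, in order: random resized crop (area scale uniform in
#' `rrcScale`), bilinear resize to `outSize`, random flips, random
#' 90-degree rotation, brightness then contrast jitter, and clamping to
#' [0, 1]. Deterministic given `seed`. With all randomness disabled this
#' reduces to a plain bilinear resize.
#'
#' @param patch 2D matrix in [0, 1] (side >= 8 px).
#' @param spec An [augmentSpec()].
#' @param seed Optional RNG seed.
#' @return `outSize` x `outSize` matrix in [0, 1].
#' @export
augmentPatch <- function(patch, spec = augmentSpec(), seed = NULL) {
  stopifnot2(min(dim(patch)) >= 8, "patch side must be >= 8 px")
  withSeed(seed, {
    img <- patch
    if (spec$rrcScale[1] < 1 || spec$rrcScale[2] < 1) {
      s <- runif(1, spec$rrcScale[1], spec$rrcScale[2])
      side <- max(8L, as.integer(round(sqrt(s) * min(dim(img)))))
      r0 <- sample.int(nrow(img) - side + 1L, 1)
      c0 <- sample.int(ncol(img) - side + 1L, 1)
      img <- img[r0:(r0 + side - 1L), c0:(c0 + side - 1L)]
    }
    img <- .resize(img, spec$outSize)
    if (spec$hflip && runif(1) < 0.5) img <- img[, rev(seq_len(ncol(img)))]
    if (spec$vflip && runif(1) < 0.5) img <- img[rev(seq_len(nrow(img))), ]
    if (spec$rot90) {
      k <- sample.int(4, 1) - 1L
      for (q in seq_len(k)) img <- t(img[rev(seq_len(nrow(img))), ])
    }
    if (spec$jitterFactor > 0) {
      f <- spec$jitterFactor
      b <- runif(1, max(0, 1 - f), 1 + f)
      img <- img * b
      cc <- runif(1, max(0, 1 - f), 1 + f)
      img <- (img - mean(img)) * cc + mean(img)
    }
    clamp01(img)
  })
}

.initWeights <- function(inputC, w, K, seed) {
  he <- function(nout, nin) matrix(rnorm(nout * nin, 0, sqrt(2 / nin)),
                                   nout, nin)
  withSeed(seed, list(
    W1 = he(w, 9 * inputC), b1 = rep(0, w),
    Wa1 = he(w, 9 * w), ba1 = rep(0, w),
    Wa2 = he(w, 9 * w), ba2 = rep(0, w),
    Wb1 = he(2 * w, 9 * w), bb1 = rep(0, 2 * w),
    Wb2 = he(2 * w, 9 * 2 * w), bb2 = rep(0, 2 * w),
    Wsc = he(2 * w, w), bsc = rep(0, 2 * w),
    Wfc = he(K, 2 * w) / 10, bfc = rep(0, K)))
}

#' Train the patch-level classifier
#'
#' Trains the compact residual CNN with the Adam optimizer and
#' cross-entropy loss (no learning-rate schedule, no weight decay). All
#' randomness (initialization, shuffling, augmentation) derives from
#' `config$seed`, so a fixed seed reproduces the final weights on
#' single-threaded CPU execution.
#'
#' @param patches List of 2D matrices in [0, 1] (training patches from
#'   training-fold fields only).
#' @param labels Character/factor vector of per-patch class labels.
#' @param config A [trainConfig()].
#' @return A [MitoCNN-class] with per-epoch training curves.
#' @export
trainModel <- function(patches, labels, config = trainConfig()) {
  labels <- as.character(labels)
  stopifnot2(length(patches) == length(labels),
             "patches and labels lengths differ")
  cls <- taskClasses(config$task)
  stopifnot2(all(labels %in% cls),
             paste("labels outside task classes:",
                   paste(setdiff(labels, cls), collapse = ", ")))
  if (length(unique(labels)) < 2)
    stop("configuration error: training data contains a single class")
  y <- match(labels, cls) - 1L
  n <- length(patches)
  S <- config$inputSize
  weights <- .initWeights(1L, config$baseWidth, length(cls), config$seed)
  mAdam <- lapply(weights, function(w) w * 0)
  vAdam <- lapply(weights, function(w) w * 0)
  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
  t <- 0
  curves <- data.frame(epoch = integer(), loss = numeric(), acc = numeric())
  for (epoch in seq_len(config$epochs)) {
    ord <- withSeed(deriveSeed(config$seed, epoch), sample.int(n))
    epochLoss <- 0; epochAcc <- 0; nb <- 0
    for (start in seq(1, n, by = config$batchSize)) {
      idx <- ord[start:min(n, start + config$batchSize - 1L)]
      X <- array(0, c(S, S, length(idx)))
      for (q in seq_along(idx))
        X[, , q] <- augmentPatch(patches[[idx[q]]], config$augment,
                                 seed = deriveSeed(config$seed,
                                                   epoch * 1000003L + idx[q]))
      g <- .cnn_grad(weights, X, y[idx])
      # global gradient-norm clipping keeps high learning rates stable on
      # small minibatches
      gnorm <- sqrt(sum(vapply(g$grads, function(x) sum(x^2), 0)))
      if (is.finite(gnorm) && gnorm > config$clipNorm)
        g$grads <- lapply(g$grads, function(x) x * config$clipNorm / gnorm)
      t <- t + 1
      for (nm in names(weights)) {
        mAdam[[nm]] <- beta1 * mAdam[[nm]] + (1 - beta1) * g$grads[[nm]]
        vAdam[[nm]] <- beta2 * vAdam[[nm]] + (1 - beta2) * g$grads[[nm]]^2
        mhat <- mAdam[[nm]] / (1 - beta1^t)
        vhat <- vAdam[[nm]] / (1 - beta2^t)
        weights[[nm]] <- weights[[nm]] - config$lr * mhat /
          (sqrt(vhat) + epsA)
      }
      epochLoss <- epochLoss + g$loss * length(idx)
      epochAcc <- epochAcc + g$acc * length(idx)
      nb <- nb + length(idx)
    }
    curves <- rbind(curves, data.frame(epoch = epoch, loss = epochLoss / nb,
                                       acc = epochAcc / nb))
  }
  new("MitoCNN", weights = weights, task = config$task, classOrder = cls,
      inputSize = S, baseWidth = config$baseWidth, curves = curves,
      config = unclass(config))
}

#' Classify patches with a trained model
#'
#' Inference is deterministic: each patch is bilinearly resized to the
#' network input (no stochastic augmentation) and passed through the
#' network once.
#'
#' @param model A [MitoCNN-class].
#' @param patches A single 2D matrix or a list of them, values in [0, 1].
#' @return Matrix of softmax probabilities, one row per patch, columns in
#'   `classOrder(model)` order; rows sum to 1.
#' @export
predictPatch <- function(model, patches) {
  if (is.matrix(patches)) patches <- list(patches)
  S <- model@inputSize
  X <- array(0, c(S, S, length(patches)))
  for (q in seq_along(patches)) {
    stopifnot2(min(dim(patches[[q]])) >= 8,
               "shape error: patch too small for inference")
    X[, , q] <- .resize(patches[[q]], S)
  }
  p <- .cnn_forward(model@weights, X)
  colnames(p) <- model@classOrder
  p
}

#' Save / load a trained model directory
#'
#' The directory holds the weights, class order, input geometry, config
#' snapshot, and the per-epoch curves as CSV. `loadModel()` round-trips to
#' identical predictions.
#'
#' @param model A [MitoCNN-class].
#' @param dir Model directory (created if missing).
#' @return `dir` (saveModel) or the restored [MitoCNN-class] (loadModel).
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model@weights, file.path(dir, "weights.rds"))
  meta <- list(task = model@task, classOrder = model@classOrder,
               inputSize = model@inputSize, baseWidth = model@baseWidth,
               config = rapply(model@config, function(x) x, how = "replace"))
  meta$config <- lapply(meta$config,
                        function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(meta, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA)
  write.csv(model@curves, file.path(dir, "curves.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  weights <- readRDS(file.path(dir, "weights.rds"))
  weights <- lapply(weights, function(w)
    if (is.null(dim(w))) as.numeric(w) else as.matrix(w))
  curves <- read.csv(file.path(dir, "curves.csv"))
  new("MitoCNN", weights = weights, task = meta$task,
      classOrder = meta$classOrder, inputSize = meta$inputSize,
      baseWidth = meta$baseWidth, curves = curves,
      config = as.list(meta$config))
}
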