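#' Classical foreground (cell-region) segmentation
#'
#' Finds the cell-bearing regions of a normalized field with a classical
#' pipeline: Gaussian blur, scaled Otsu threshold, morphological closing
#' (disc of radius `sigma`), removal of small components, hole filling. The
#' blur width is large relative to individual mitochondria so the mask
#' captures whole cell regions rather than single organelles; the Otsu
#' threshold is scaled down by `thresholdScale` because a blurred sparse
#' cell is a soft-edged blob whose rim falls to roughly half the interior
#' intensity (plain Otsu erodes the cell boundary). Any externally produced
#' mask (e.g. from a learned segmenter) can be used in its place wherever a
#' mask argument is accepted.
#'
#' @param image Normalized 2D image in [0, 1] (see [normalizePercentile()]),
#'   a [FluorescenceField-class] or [SimulatedField-class].
#' @param sigma Blur width in pixels; also the closing radius.
#' @param minObjectPx Minimum component area kept, in pixels.
#' @param thresholdScale Factor applied to the Otsu threshold (default
#'   0.18).
#' @return Binary 0/1 matrix with attribute `methodTag = "classical"`. An
#'   all-zero image yields an all-zero mask.
#' @export
segmentForeground <- function(image, sigma = 18, minObjectPx = 800,
                              thresholdScale = 0.18) {
  img <- fieldImage(image)
  stopifnot2(length(dim(img)) == 2L, "shape error: image must be 2D")
  if (max(img) <= 0)
    return(structure(matrix(0, nrow(img), ncol(img)),
                     methodTag = "classical"))
  blur <- as.matrix(EBImage::gblur(img, sigma = sigma))
  th <- EBImage::otsu(EBImage::Image(blur), range = c(0, max(blur))) *
    thresholdScale
  mask <- EBImage::Image(matrix(as.numeric(blur > th), nrow(img), ncol(img)))
  brush <- EBImage::makeBrush(2 * round(sigma) + 1, shape = "disc")
  mask <- EBImage::closing(mask, brush)
  lab <- labelComponents(as.matrix(mask))
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    keep <- which(areas >= minObjectPx)
    mask <- matrix(as.numeric(lab %in% keep), nrow(img), ncol(img))
  } else {
    mask <- as.matrix(mask)
  }
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask)))
  structure(matrix(as.numeric(mask != 0), nrow(img), ncol(img)),
            methodTag = "classical")
}

#' Tile a field into sliding-window patches
#'
#' Origins lie at `(i * stride, j * stride)` (0-based) for all placements
#' where the full `patchSize` square fits inside the field; no partial or
#' padded edge patches are produced. Ordering is row-major and
#' deterministic. On a 2048 x 2048 field with the standard 112-px window and
#' 100-px stride this yields 20 x 20 = 400 patches.
#'
#' @param field A field-like object or 2D matrix.
#' @param mask Binary foreground mask aligned to the field, or `NULL` for an
#'   all-foreground mask.
#' @param patchSize Patch side length in pixels (default 112).
#' @param stride Offset between consecutive origins (default 100).
#' @return A [PatchSet-class] with per-patch foreground fractions.
#' @export
tilePatches <- function(field, mask = NULL, patchSize = 112, stride = 100) {
  img <- fieldImage(field)
  H <- nrow(img); W <- ncol(img)
  if (patchSize > H || patchSize > W)
    stop("value error: patchSize exceeds field dimensions")
  stopifnot2(stride >= 1, "stride must be >= 1")
  if (is.null(mask)) mask <- matrix(1, H, W)
  stopifnot2(all(dim(mask) == c(H, W)), "mask dimensions differ from field")
  r0 <- seq(0L, H - patchSize, by = stride)
  c0 <- seq(0L, W - patchSize, by = stride)
  origins <- cbind(rep(r0, each = length(c0)), rep(c0, times = length(r0)))
  # row-major: all columns of row 0, then row 1, ...
  # summed-area table: sat[r+1, c+1] = sum(mask[1:r, 1:c])
  cum <- t(apply(apply(mask != 0, 2, cumsum), 1, cumsum))
  sat <- matrix(0, H + 1, W + 1)
  sat[2:(H + 1), 2:(W + 1)] <- cum
  boxSum <- function(r, c) {
    sat[cbind(r + patchSize + 1, c + patchSize + 1)] -
      sat[cbind(r + 1, c + patchSize + 1)] -
      sat[cbind(r + patchSize + 1, c + 1)] + sat[cbind(r + 1, c + 1)]
  }
  fg <- boxSum(origins[, 1], origins[, 2]) / (patchSize^2)
  fieldId <- if (is(field, "FluorescenceField")) field@fieldId else "field"
  new("PatchSet", fieldId = fieldId, patchSize = patchSize,
      fieldDim = c(H, W), origins = origins, fgFraction = as.numeric(fg))
}

#' Discard patches with insufficient foreground
#'
#' Keeps exactly the patches whose foreground fraction is greater than or
#' equal to `minFg` (patches with less than 50% foreground content are
#' discarded under the default), preserving order.
#'
#' @param patches A [PatchSet-class].
#' @param minFg Minimum foreground fraction retained (default 0.5; a patch
#'   at exactly the boundary is kept).
#' @return Filtered [PatchSet-class]; may be empty.
#' @export
filterPatches <- function(patches, minFg = 0.5) {
  keep <- which(patches@fgFraction >= minFg)
  new("PatchSet", fieldId = patches@fieldId, patchSize = patches@patchSize,
      fieldDim = patches@fieldDim,
      origins = patches@origins[keep, , drop = FALSE],
      fgFraction = patches@fgFraction[keep])
}

# Shared sampling core: uniform without replacement when the pool suffices,
# with replacement (and a warning) for sparse fields whose pool is smaller
# than k.
.samplePatchIdx <- function(n, k, seed = NULL, fieldId = "field") {
  if (n == 0)
    stop(sprintf("field-unusable: empty filtered patch pool for '%s'",
                 fieldId))
  withSeed(seed, {
    if (n >= k) sample.int(n, k)
    else {
      warning(sprintf(
        "patch pool of '%s' (%d) smaller than k=%d; sampling with replacement",
        fieldId, n, k))
      sample.int(n, k, replace = TRUE)
    }
  })
}

#' Randomly sample patches from a filtered pool
#'
#' Uniform sampling without replacement; pools smaller than `k` are sampled
#' with replacement (with a warning) so sparse fields can still be scored.
#' Deterministic given `seed`.
#'
#' @param patches A filtered [PatchSet-class].
#' @param k Number of patches to draw (default 4).
#' @param seed Optional RNG seed.
#' @return A [PatchSet-class] with `k` entries (duplicates possible only
#'   when the pool is smaller than `k`).
#' @export
samplePatches <- function(patches, k = 4, seed = NULL) {
  idx <- .samplePatchIdx(length(patches), k, seed, patches@fieldId)
  new("PatchSet", fieldId = patches@fieldId, patchSize = patches@patchSize,
      fieldDim = patches@fieldDim,
      origins = patches@origins[idx, , drop = FALSE],
      fgFraction = patches@fgFraction[idx])
}

#' Extract patch pixels from a field
#'
#' @param field Field-like object or 2D matrix.
#' @param origin 0-based (row, col) of the patch's top-left corner.
#' @param patchSize Patch side length.
#' @return `patchSize` x `patchSize` matrix.
#' @export
extractPatch <- function(field, origin, patchSize) {
  img <- fieldImage(field)
  r <- origin[1]; c <- origin[2]
  stopifnot2(r >= 0 && c >= 0 && r + patchSize <= nrow(img) &&
               c + patchSize <= ncol(img), "patch extends outside the field")
  img[(r + 1):(r + patchSize), (c + 1):(c + patchSize)]
}

#' Extract all patches of a PatchSet
#'
#' @param field Field-like object or matrix the patches were tiled from.
#' @param patches A [PatchSet-class].
#' @return List of patch matrices, in `patches` order.
#' @export
extractPatches <- function(field, patches) {
  lapply(seq_len(length(patches)), function(i)
    extractPatch(field, patches@origins[i, ], patches@patchSize))
}
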