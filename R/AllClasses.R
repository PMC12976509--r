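#' Class labels of the fission-fusion vocabulary
#'
#' The pipeline scores three canonical mitochondrial states: hyperfission
#' (CCCP-like fragmentation into puncta and rings), normal mixed tubular
#' networks (NC), and hyperfusion (FL3-like elongated, interconnected
#' filaments).
#'
#' @return Character vector `c("CCCP", "NC", "FL3")`.
#' @export
classLabels <- function() c("CCCP", "NC", "FL3")

#' MorphologySpec: parameters of the synthetic mitochondrial field generator
#'
#' A `MorphologySpec` pins down one point on the fission-fusion continuum
#' together with the optical and noise model used to render it. The continuum
#' coordinate `phi` runs from 0 (extreme hyperfission: fragmented puncta and
#' rings) through 0.5 (normal mixed tubules) to 1 (extreme hyperfusion: long
#' interconnected filaments).
#'
#' @slot phi Continuum coordinate in [0, 1].
#' @slot nCells Number of cells per field.
#' @slot cellRadiusPx Mean cell radius in pixels.
#' @slot fragmentRate Expected puncta per cell at `phi = 0`.
#' @slot tubuleLengthPx Mean filament arc length in pixels at `phi = 1`.
#' @slot ringFraction Fraction of puncta rendered as annuli (the ring-shaped
#'   mitochondria characteristic of strong uncoupler treatment).
#' @slot psfSigmaPx Gaussian point-spread-function width in pixels.
#' @slot noiseLevel Scale of Poisson shot noise and Gaussian read noise;
#'   0 disables noise entirely.
#' @slot fieldSizePx Output field side length in pixels.
#' @slot seed Integer RNG seed; a fixed seed yields a byte-identical field.
#' @seealso [morphologySpec()], [simulateField()]
#' @export
setClass("MorphologySpec", representation(
  phi = "numeric", nCells = "numeric", cellRadiusPx = "numeric",
  fragmentRate = "numeric", tubuleLengthPx = "numeric",
  ringFraction = "numeric", psfSigmaPx = "numeric", noiseLevel = "numeric",
  fieldSizePx = "numeric", seed = "numeric"))

setValidity("MorphologySpec", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@phi) || object@phi < 0 || object@phi > 1)
    msg <- c(msg, "phi must be a single value in [0, 1]")
  if (!one(object@nCells) || object@nCells < 1)
    msg <- c(msg, "nCells must be >= 1")
  if (!one(object@cellRadiusPx) || object@cellRadiusPx < 8)
    msg <- c(msg, "cellRadiusPx must be >= 8")
  if (!one(object@fragmentRate) || object@fragmentRate < 0)
    msg <- c(msg, "fragmentRate must be >= 0")
  if (!one(object@tubuleLengthPx) || object@tubuleLengthPx <= 0)
    msg <- c(msg, "tubuleLengthPx must be > 0")
  if (!one(object@ringFraction) || object@ringFraction < 0 ||
      object@ringFraction > 1)
    msg <- c(msg, "ringFraction must be in [0, 1]")
  if (!one(object@psfSigmaPx) || object@psfSigmaPx < 0)
    msg <- c(msg, "psfSigmaPx must be >= 0")
  if (!one(object@noiseLevel) || object@noiseLevel < 0)
    msg <- c(msg, "noiseLevel must be >= 0")
  if (!one(object@fieldSizePx) || object@fieldSizePx < 64)
    msg <- c(msg, "fieldSizePx must be >= 64")
  if (!one(object@seed)) msg <- c(msg, "seed must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a MorphologySpec
#'
#' Defaults describe a desk-scale field: 512 x 512 px, four non-overlapping
#' cells of radius ~70 px, 80 expected puncta per cell at the hyperfission
#' extreme thinning to 8 expected long filaments at the hyperfusion extreme
#' (mitochondrial signal occupying roughly 5-15% of the cell footprint).
#'
#' @param phi Continuum coordinate in [0, 1]; see [MorphologySpec-class].
#' @param nCells,cellRadiusPx,fragmentRate,tubuleLengthPx,ringFraction
#'   Geometry parameters, see [MorphologySpec-class].
#' @param psfSigmaPx,noiseLevel Optics/noise parameters.
#' @param fieldSizePx Field side length in pixels.
#' @param seed Integer RNG seed.
#' @return A validated [MorphologySpec-class] object.
#' @examples
#' spec <- morphologySpec(phi = 0.1, seed = 7)
#' @export
morphologySpec <- function(phi = 0.5, nCells = 4, cellRadiusPx = 70,
                           fragmentRate = 80, tubuleLengthPx = 80,
                           ringFraction = 0.3, psfSigmaPx = 1.2,
                           noiseLevel = 0.05, fieldSizePx = 512, seed = 1) {
  new("MorphologySpec", phi = phi, nCells = nCells,
      cellRadiusPx = cellRadiusPx, fragmentRate = fragmentRate,
      tubuleLengthPx = tubuleLengthPx, ringFraction = ringFraction,
      psfSigmaPx = psfSigmaPx, noiseLevel = noiseLevel,
      fieldSizePx = fieldSizePx, seed = seed)
}

#' SimulatedField: a rendered synthetic field with ground truth
#'
#' @slot image Integer-valued intensity matrix on the 16-bit scale.
#' @slot truthMask Binary (0/1) cell-footprint mask, same dimensions.
#' @slot truthLabel Class label derived deterministically from `phi`
#'   (`phi < 1/3` CCCP-like, `1/3 <= phi < 2/3` NC, `phi >= 2/3` FL3-like).
#' @slot phi Generating continuum coordinate.
#' @slot seed Seed used for generation.
#' @export
setClass("SimulatedField", representation(
  image = "matrix", truthMask = "matrix", truthLabel = "character",
  phi = "numeric", seed = "numeric"))

setValidity("SimulatedField", function(object) {
  if (!identical(dim(object@image), dim(object@truthMask)))
    return("image and truthMask dimensions differ")
  if (!object@truthLabel %in% classLabels())
    return("truthLabel outside the class vocabulary")
  TRUE
})

#' Deterministic class label for a continuum coordinate
#'
#' @param phi Continuum coordinate(s) in [0, 1].
#' @return `"CCCP"` for `phi < 1/3`, `"NC"` for `1/3 <= phi < 2/3`,
#'   `"FL3"` for `phi >= 2/3`.
#' @export
phiLabel <- function(phi) {
  stopifnot2(all(phi >= 0 & phi <= 1), "phi must lie in [0, 1]")
  ifelse(phi < 1 / 3, "CCCP", ifelse(phi < 2 / 3, "NC", "FL3"))
}

#' FluorescenceField: one 2D intensity image plus acquisition metadata
#'
#' The atom of the pipeline: a single-channel fluorescence field (after any
#' z-projection) with its manifest bookkeeping.
#'
#' @slot image Non-negative 2D intensity matrix.
#' @slot fieldId Unique field identifier.
#' @slot label Class label ("CCCP", "FL3", "NC") or a cohort context label
#'   ("CN", "MCI", "AD"); may be `NA`.
#' @slot experimentId Acquisition batch identifier (grouping key for
#'   batch-aware cross-validation).
#' @slot participantId Participant identifier, `NA` for cell-line data.
#' @slot pixelSizeUm Physical pixel size in micrometres, `NA` if unknown.
#' @export
setClass("FluorescenceField", representation(
  image = "matrix", fieldId = "character", label = "character",
  experimentId = "character", participantId = "character",
  pixelSizeUm = "numeric"))

setValidity("FluorescenceField", function(object) {
  img <- object@image
  if (length(dim(img)) != 2L) return("image must be 2D")
  if (any(!is.finite(img))) return("image has non-finite pixels")
  if (any(img < 0)) return("image has negative pixels")
  if (length(object@fieldId) != 1L || is.na(object@fieldId))
    return("fieldId must be a single non-NA string")
  TRUE
})

#' Construct a FluorescenceField
#'
#' @param image 2D intensity matrix (non-negative, finite).
#' @param fieldId Unique identifier string.
#' @param label Optional class/context label.
#' @param experimentId Acquisition batch id.
#' @param participantId Optional participant id.
#' @param pixelSizeUm Optional pixel size in micrometres.
#' @return A [FluorescenceField-class] object.
#' @export
fluorescenceField <- function(image, fieldId, label = NA_character_,
                              experimentId = NA_character_,
                              participantId = NA_character_,
                              pixelSizeUm = NA_real_) {
  new("FluorescenceField", image = image, fieldId = as.character(fieldId),
      label = as.character(label), experimentId = as.character(experimentId),
      participantId = as.character(participantId),
      pixelSizeUm = as.numeric(pixelSizeUm))
}

#' PatchSet: sliding-window patches of one field
#'
#' Holds the origins (0-based, row-major order) and foreground fractions of
#' the square patches tiled over a field; pixel data are extracted lazily
#' with [extractPatch()].
#'
#' @slot fieldId Identifier of the source field.
#' @slot patchSize Patch side length in pixels.
#' @slot fieldDim Dimensions of the source field.
#' @slot origins Integer matrix (n x 2) of 0-based (row, col) top-left
#'   corners.
#' @slot fgFraction Fraction of patch pixels inside the foreground mask.
#' @export
setClass("PatchSet", representation(
  fieldId = "character", patchSize = "numeric", fieldDim = "numeric",
  origins = "matrix", fgFraction = "numeric"))

setValidity("PatchSet", function(object) {
  o <- object@origins
  if (ncol(o) != 2L) return("origins must have two columns")
  if (length(object@fgFraction) != nrow(o))
    return("fgFraction length must match origins")
  if (length(object@fgFraction) &&
      (any(object@fgFraction < 0) || any(object@fgFraction > 1)))
    return("fgFraction must lie in [0, 1]")
  ps <- object@patchSize
  if (nrow(o) && (any(o < 0) || any(o[, 1] + ps > object@fieldDim[1]) ||
                  any(o[, 2] + ps > object@fieldDim[2])))
    return("patch extents must lie within field bounds")
  TRUE
})

#' @describeIn PatchSet-class Number of patches.
#' @param x A `PatchSet`.
#' @export
setMethod("length", "PatchSet", function(x) nrow(x@origins))

#' SkeletonGraph: branch/junction graph of a thinned network
#'
#' @slot nodes Data frame of node pixels (`row`, `col`, `type` in
#'   endpoint/junction).
#' @slot branches Data frame with one row per branch (`length` in pixels,
#'   geodesic with diagonal steps counting sqrt(2)).
#' @slot nBranches,nJunctions Branch and junction counts (adjacent junction
#'   pixels are merged into a single junction).
#' @export
setClass("SkeletonGraph", representation(
  nodes = "data.frame", branches = "data.frame",
  nBranches = "numeric", nJunctions = "numeric"))

#' MitoCNN: a trained patch classifier
#'
#' @slot weights Named list of weight arrays of the compact residual CNN.
#' @slot task Task tag, e.g. "CCCP-NC", "FL3-NC" or "CCCP-FL3-NC".
#' @slot classOrder Ordered class labels defining probability-vector columns.
#' @slot inputSize Network input side length in pixels.
#' @slot baseWidth Base channel width of the network.
#' @slot curves Per-epoch training loss/accuracy.
#' @slot config Training configuration snapshot.
#' @export
setClass("MitoCNN", representation(
  weights = "list", task = "character", classOrder = "character",
  inputSize = "numeric", baseWidth = "numeric", curves = "data.frame",
  config = "list"))

setValidity("MitoCNN", function(object) {
  if (length(object@classOrder) < 2L) return("classOrder needs >= 2 classes")
  if (anyDuplicated(object@classOrder)) return("classOrder has duplicates")
  TRUE
})

#' FoldAssignment: grouped cross-validation folds
#'
#' Fields are assigned to folds at the acquisition-batch ("experiment")
#' level so that correlated fields never straddle train and test.
#'
#' @slot assignment Data frame mapping `experiment_id` to `fold` (0-based).
#' @slot nFolds Number of folds.
#' @slot counts Data frame of per-fold, per-class field counts (the
#'   train/test bookkeeping table).
#' @export
setClass("FoldAssignment", representation(
  assignment = "data.frame", nFolds = "numeric", counts = "data.frame"))

setValidity("FoldAssignment", function(object) {
  a <- object@assignment
  if (anyDuplicated(a$experiment_id))
    return("an experiment is assigned to more than one fold")
  if (!all(sort(unique(a$fold)) == 0:(object@nFolds - 1)))
    return("every fold must be non-empty")
  TRUE
})

setMethod("show", "MorphologySpec", function(object) {
  cat(sprintf(
    "MorphologySpec phi=%.3f (%s) | %d cells r=%.0fpx | field %dpx | seed %d\n",
    object@phi, phiLabel(object@phi), as.integer(object@nCells),
    object@cellRadiusPx, as.integer(object@fieldSizePx),
    as.integer(object@seed)))
})

setMethod("show", "SimulatedField", function(object) {
  cat(sprintf(
    "SimulatedField %dx%d | phi=%.3f -> %s | fg=%.1f%% | seed %d\n",
    nrow(object@image), ncol(object@image), object@phi, object@truthLabel,
    100 * mean(object@truthMask), as.integer(object@seed)))
})

setMethod("show", "FluorescenceField", function(object) {
  cat(sprintf("FluorescenceField '%s' %dx%d | label=%s | experiment=%s\n",
              object@fieldId, nrow(object@image), ncol(object@image),
              object@label, object@experimentId))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet of '%s': %d patches of %dpx (field %dx%d)\n",
              object@fieldId, length(object), as.integer(object@patchSize),
              object@fieldDim[1], object@fieldDim[2]))
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d branches, %d junctions, total length %.1fpx\n",
              as.integer(object@nBranches), as.integer(object@nJunctions),
              sum(object@branches$length)))
})

setMethod("show", "MitoCNN", function(object) {
  cat(sprintf(
    "MitoCNN task=%s classes=[%s] input=%dpx width=%d | %d epochs trained\n",
    object@task, paste(object@classOrder, collapse = ", "),
    as.integer(object@inputSize), as.integer(object@baseWidth),
    nrow(object@curves)))
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %d experiments in %d folds\n",
              nrow(object@assignment), as.integer(object@nFolds)))
})

#' @describeIn MitoCNN-class Ordered class labels of the classifier.
#' @param object A `MitoCNN`.
#' @export
setGeneric("classOrder", function(object) standardGeneric("classOrder"))

#' @rdname MitoCNN-class
#' @export
setMethod("classOrder", "MitoCNN", function(object) object@classOrder)

#' @describeIn MitoCNN-class Per-epoch training loss and accuracy.
#' @export
setGeneric("trainingCurves", function(object) standardGeneric("trainingCurves"))

#' @rdname MitoCNN-class
#' @export
setMethod("trainingCurves", "MitoCNN", function(object) object@curves)

#' Image accessor
#'
#' @param object A field-like object (`FluorescenceField` or
#'   `SimulatedField`).
#' @return The 2D intensity matrix.
#' @export
setGeneric("fieldImage", function(object) standardGeneric("fieldImage"))

#' @rdname fieldImage
#' @export
setMethod("fieldImage", "FluorescenceField", function(object) object@image)

#' @rdname fieldImage
#' @export
setMethod("fieldImage", "SimulatedField", function(object) object@image)

#' @rdname fieldImage
#' @export
setMethod("fieldImage", "matrix", function(object) object)

#' @rdname fieldImage
#' @export
setMethod("fieldImage", "array", function(object) object)

#' Ground-truth mask accessor
#'
#' @param object A `SimulatedField`.
#' @return Binary 0/1 matrix of cell footprints.
#' @export
setGeneric("truthMask", function(object) standardGeneric("truthMask"))

#' @rdname truthMask
#' @export
setMethod("truthMask", "SimulatedField", function(object) object@truthMask)

#' Fold assignment accessor
#'
#' @param object A `FoldAssignment`.
#' @return Data frame mapping `experiment_id` to 0-based `fold`.
#' @export
setGeneric("foldMap", function(object) standardGeneric("foldMap"))

#' @rdname foldMap
#' @export
setMethod("foldMap", "FoldAssignment", function(object) object@assignment)
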