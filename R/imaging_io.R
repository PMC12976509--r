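#' Read a fluorescence field from TIFF
#'
#' Reads 8/16-bit single- or multi-page grayscale TIFF. Multi-page stacks
#' are returned as a 3D array (rows x cols x slices) ready for
#' [maxProject()]; RGB input is rejected.
#'
#' @param path Path to a TIFF file.
#' @param fieldId Field identifier; defaults to the file name sans extension.
#' @param label,experimentId,participantId Optional manifest metadata.
#' @return A [FluorescenceField-class] (single page) or a 3D numeric array
#'   for stacks.
#' @export
readField <- function(path, fieldId = NULL, label = NA, experimentId = NA,
                      participantId = NA) {
  if (!file.exists(path))
    stop(sprintf("format error: cannot read '%s' (no such file)", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop(sprintf("format error reading '%s': %s", path,
                                   conditionMessage(e))))
  if (any(vapply(pages, function(p) length(dim(p)) == 3L, logical(1))))
    stop(sprintf("unsupported format: '%s' is RGB, expected grayscale", path))
  if (length(pages) > 1L) {
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
    return(arr)
  }
  img <- pages[[1]]
  storage.mode(img) <- "double"
  if (is.null(fieldId)) fieldId <- sub("\\.[^.]*$", "", basename(path))
  fluorescenceField(img, fieldId, label = label, experimentId = experimentId,
                    participantId = participantId)
}

#' Write a field to 16-bit TIFF
#'
#' Integer intensities on the 16-bit scale round-trip exactly through
#' `writeField()` / [readField()].
#'
#' @param field A [FluorescenceField-class], matrix, 3D array (stack), or a
#'   list of slices.
#' @param path Output path.
#' @param bits Bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
writeField <- function(field, path, bits = 16) {
  img <- if (is(field, "FluorescenceField")) fieldImage(field) else field
  denom <- 2^bits - 1
  if (is.list(img)) {
    tiff::writeTIFF(lapply(img, function(s) s / denom), path,
                    bits.per.sample = bits)
  } else if (length(dim(img)) == 3L) {
    tiff::writeTIFF(lapply(seq_len(dim(img)[3]), function(k) img[, , k] / denom),
                    path, bits.per.sample = bits)
  } else {
    tiff::writeTIFF(img / denom, path, bits.per.sample = bits)
  }
  invisible(path)
}

#' Maximum-intensity projection of a z-stack
#'
#' @param stack A 3D array (rows x cols x slices), a list of 2D matrices, or
#'   a single matrix (returned unchanged).
#' @return 2D matrix of per-pixel maxima across slices.
#' @export
maxProject <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (is.list(stack)) {
    stopifnot2(length(stack) >= 1L, "empty stack")
    return(Reduce(pmax, stack))
  }
  d <- dim(stack)
  stopifnot2(length(d) == 3L && d[3] >= 1L, "empty stack")
  apply(stack, c(1, 2), max)
}

#' Robust percentile intensity normalization
#'
#' Values at or below the `pLo` percentile map to 0, values at or above
#' `pHi` map to 1, affine in between. A constant image maps to all zeros.
#' Applied before patch extraction and before morphometry thresholding in
#' place of instrument-specific intensity calibration.
#'
#' @param image 2D intensity matrix with finite pixels.
#' @param pLo,pHi Percentiles in [0, 100], `pLo < pHi` (default 1 and 99).
#' @return Matrix of the same dimensions with values in [0, 1].
#' @export
normalizePercentile <- function(image, pLo = 1, pHi = 99) {
  img <- fieldImage(image)
  stopifnot2(pLo < pHi, "pLo must be < pHi")
  if (any(!is.finite(img))) stop("value error: non-finite pixels")
  q <- quantile(img, c(pLo, pHi) / 100, names = FALSE)
  if (q[2] <= q[1]) return(matrix(0, nrow(img), ncol(img)))
  matrix(clamp01((img - q[1]) / (q[2] - q[1])), nrow(img), ncol(img))
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with one row per field: `field_id`, `path`, `label`,
#' plus optional `mask_path`, `phi`, `experiment_id`, `participant_id`,
#' `group`. Relative paths are resolved against the manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @param checkPaths Verify that referenced image files exist (default TRUE).
#' @param vocabulary Allowed label values; defaults to the treatment and
#'   cognitive-status vocabularies.
#' @return Data frame with absolute `path`/`mask_path` columns.
#' @export
readManifest <- function(path, checkPaths = TRUE,
                         vocabulary = c(classLabels(), "CN", "MCI", "AD")) {
  if (!file.exists(path)) stop(sprintf("cannot read manifest '%s'", path))
  m <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("field_id", "path", "label")
  missing <- setdiff(req, names(m))
  stopifnot2(length(missing) == 0,
             paste("manifest lacks columns:", paste(missing, collapse = ", ")))
  stopifnot2(!anyDuplicated(m$field_id), "duplicate field_id in manifest")
  bad <- setdiff(unique(m$label), vocabulary)
  stopifnot2(length(bad) == 0,
             paste("labels outside vocabulary:", paste(bad, collapse = ", ")))
  root <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(root, p))
  m$path <- resolve(m$path)
  if ("mask_path" %in% names(m)) m$mask_path <- resolve(m$mask_path)
  if (checkPaths) {
    gone <- m$path[!file.exists(m$path)]
    stopifnot2(length(gone) == 0,
               paste("missing files:", paste(head(gone, 3), collapse = ", ")))
  }
  m
}

#' Write a dataset manifest
#'
#' @param manifest Data frame as described in [readManifest()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
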