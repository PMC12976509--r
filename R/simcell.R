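#' Synthetic mitochondrial field generator
#'
#' The simulator places a handful of non-overlapping circular cells on a dark
#' background and fills each with stochastic-geometry primitives whose mix is
#' controlled by the continuum coordinate `phi`: anti-aliased discs and annuli
#' (puncta and rings, the hyperfission phenotype) at low `phi`, smoothed
#' random-walk curves (tubules and filaments) at high `phi`. The expected
#' primitive count per cell decreases linearly in `phi` while the expected
#' filament arc length increases, and above `phi = 2/3` filaments begin to
#' share endpoints (network interconnection). Rendering convolves the
#' rasterized geometry with a Gaussian PSF and adds Poisson shot noise plus
#' Gaussian read noise on the 16-bit scale.
#'
#' @name simcell
NULL

# Expected primitive counts per cell; the oracle for monotonicity tests.
#' Expected number of geometric primitives per cell
#'
#' The generator draws, per cell, Poisson(`fragmentRate * (1 - phi)`) puncta
#' and Poisson(`fragmentRate / 10 * phi`) filaments, so the expectation is
#' linear and strictly decreasing in `phi` (puncta dominate the budget).
#'
#' @param spec A [MorphologySpec-class].
#' @return Expected primitives per cell (puncta + filaments).
#' @export
expectedPrimitiveCount <- function(spec) {
  spec@fragmentRate * (1 - spec@phi) + (spec@fragmentRate / 10) * spec@phi
}

# Margin keeping rendered signal (primitive footprint + 3 sigma of PSF)
# strictly inside the cell footprint.
.innerRadius <- function(spec) {
  spec@cellRadiusPx - (3 * spec@psfSigmaPx + 4.5)
}

#' Sample the geometric primitives of one synthetic field
#'
#' @param spec A [MorphologySpec-class]; the RNG is seeded from `spec@seed`
#'   so identical specs yield identical geometry.
#' @return A list of class `"MitoGeometry"`: one entry per cell with the cell
#'   `center` and `radius`, a data frame `discs` (columns `x`, `y`, `r`,
#'   `ring`), and a list `curves` of polyline coordinate matrices.
#' @examples
#' geo <- sampleMitoGeometry(morphologySpec(phi = 0, ringFraction = 0))
#' @export
sampleMitoGeometry <- function(spec) {
  validObject(spec)
  S <- spec@fieldSizePx
  R <- spec@cellRadiusPx
  if (2 * (R + 4) > S)
    stop("geometry error: fieldSizePx too small to contain one cell")
  inner <- .innerRadius(spec)
  stopifnot2(inner > 6, "cellRadiusPx too small for the PSF margin")
  withSeed(spec@seed, {
    centers <- .placeCells(as.integer(spec@nCells), R, S)
    cells <- lapply(seq_len(nrow(centers)), function(ci) {
      ctr <- centers[ci, ]
      nDisc <- rpois(1, spec@fragmentRate * (1 - spec@phi))
      nCurve <- rpois(1, (spec@fragmentRate / 10) * spec@phi)
      discs <- .sampleDiscs(nDisc, ctr, inner, spec@ringFraction)
      curves <- .sampleCurves(nCurve, ctr, inner, spec)
      list(center = ctr, radius = R, discs = discs, curves = curves)
    })
    structure(list(cells = cells, fieldSizePx = S, phi = spec@phi),
              class = "MitoGeometry")
  })
}

.placeCells <- function(n, R, S) {
  lo <- R + 3
  hi <- S - R - 3
  stopifnot2(hi > lo, "geometry error: fieldSizePx too small to contain one cell")
  centers <- matrix(NA_real_, 0, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:300) {
      p <- runif(2, lo, hi)
      if (!nrow(centers) ||
          min(sqrt(rowSums(sweep(centers, 2, p)^2))) > 1.95 * R) {
        centers <- rbind(centers, p)
        placed <- TRUE
        break
      }
    }
    if (!placed) {  # dense field: tolerate mild overlap rather than fail
      p <- runif(2, lo, hi)
      centers <- rbind(centers, p)
    }
  }
  centers
}

.sampleDiscs <- function(n, center, inner, ringFraction) {
  if (n == 0)
    return(data.frame(x = numeric(), y = numeric(), r = numeric(),
                      ring = logical()))
  r <- runif(n, 1.2, 2.2)
  # uniform in the disc of radius (inner - r)
  rho <- sqrt(runif(n)) * (inner - r)
  th <- runif(n, 0, 2 * pi)
  data.frame(x = center[1] + rho * cos(th), y = center[2] + rho * sin(th),
             r = r, ring = runif(n) < ringFraction)
}

# Smoothed random-walk filaments; curves steer back toward the cell center
# when they approach the allowed radius so all signal stays inside the cell.
.sampleCurves <- function(n, center, inner, spec) {
  if (n == 0) return(list())
  meanLen <- spec@tubuleLengthPx * (0.2 + 0.8 * spec@phi)
  pConn <- 0.5 * max(0, 3 * spec@phi - 2)
  curves <- vector("list", n)
  for (k in seq_len(n)) {
    len <- max(6, rgamma(1, shape = 4, scale = meanLen / 4))
    if (k > 1 && runif(1) < pConn) {
      prev <- curves[[sample.int(k - 1, 1)]]
      start <- prev[nrow(prev), ]          # share an endpoint: interconnect
    } else {
      rho <- sqrt(runif(1)) * (inner - 3)
      th0 <- runif(1, 0, 2 * pi)
      start <- center + rho * c(cos(th0), sin(th0))
    }
    heading <- runif(1, 0, 2 * pi)
    nStep <- max(6L, as.integer(round(len)))
    pts <- matrix(NA_real_, nStep, 2)
    pts[1, ] <- start
    for (s in 2:nStep) {
      heading <- heading + rnorm(1, 0, 0.10)
      cand <- pts[s - 1, ] + c(cos(heading), sin(heading))
      d <- sqrt(sum((cand - center)^2))
      if (d > inner - 2) {  # steer back toward the cell interior
        heading <- atan2(center[2] - pts[s - 1, 2], center[1] - pts[s - 1, 1])
        cand <- pts[s - 1, ] + c(cos(heading), sin(heading))
      }
      pts[s, ] <- cand
    }
    curves[[k]] <- pts
  }
  curves
}

#' Render a sampled geometry into a noisy 16-bit field
#'
#' Primitives are rasterized with sub-pixel anti-aliasing (intensity ramps
#' over one pixel at each boundary), convolved with a Gaussian PSF, scaled to
#' a peak signal of 30000 on the 16-bit scale, and corrupted with Poisson
#' shot noise and Gaussian read noise controlled by `noiseLevel`. With
#' `noiseLevel = 0` and `psfSigmaPx = 0` the nonzero pixels are exactly the
#' rasterized primitives.
#'
#' @param geometry Output of [sampleMitoGeometry()] for the same spec.
#' @param spec The [MorphologySpec-class] used to sample `geometry`.
#' @return A [SimulatedField-class].
#' @export
renderField <- function(geometry, spec) {
  validObject(spec)
  stopifnot2(inherits(geometry, "MitoGeometry"),
             "geometry must come from sampleMitoGeometry()")
  stopifnot2(geometry$fieldSizePx == spec@fieldSizePx &&
               geometry$phi == spec@phi,
             "geometry and spec disagree")
  S <- as.integer(spec@fieldSizePx)
  canvas <- matrix(0, S, S)
  mask <- matrix(0L, S, S)
  for (cell in geometry$cells) {
    mask <- .stampMask(mask, cell$center, cell$radius)
    d <- cell$discs
    for (i in seq_len(nrow(d)))
      canvas <- .stampDisc(canvas, d$x[i], d$y[i], d$r[i], d$ring[i])
    for (cv in cell$curves)
      canvas <- .stampCurve(canvas, cv, 1.2)
  }
  if (spec@psfSigmaPx > 0)
    canvas <- as.matrix(EBImage::gblur(canvas, sigma = spec@psfSigmaPx))
  img <- 30000 * canvas
  if (spec@noiseLevel > 0) {
    img <- withSeed(deriveSeed(spec@seed, 500009L), {
      gain <- 3000 * spec@noiseLevel
      shot <- rpois(length(img), pmax(img, 0) / gain) * gain
      shot + rnorm(length(img), 0, 300 * spec@noiseLevel)
    })
    img <- matrix(img, S, S)
  }
  img <- matrix(pmin(65535, pmax(0, round(img))), S, S)
  new("SimulatedField", image = img, truthMask = .storageMode01(mask),
      truthLabel = phiLabel(spec@phi), phi = spec@phi, seed = spec@seed)
}

.storageMode01 <- function(m) {
  out <- matrix(as.numeric(m != 0), nrow(m), ncol(m))
  out
}

.window <- function(cx, cy, rad, S) {
  # rows index y, cols index x is irrelevant here: the canvas is isotropic,
  # we use (row = x, col = y) consistently.
  i0 <- max(1L, as.integer(floor(cx - rad)))
  i1 <- min(S, as.integer(ceiling(cx + rad)))
  j0 <- max(1L, as.integer(floor(cy - rad)))
  j1 <- min(S, as.integer(ceiling(cy + rad)))
  if (i0 > i1 || j0 > j1) return(NULL)
  list(i = i0:i1, j = j0:j1)
}

.stampDisc <- function(canvas, x, y, r, ring = FALSE) {
  S <- nrow(canvas)
  w <- .window(x, y, r + 1.5, S)
  if (is.null(w)) return(canvas)
  d <- sqrt(outer((w$i - x)^2, (w$j - y)^2, `+`))
  val <- if (ring) clamp01(1 - abs(d - r) / 1.1) else clamp01(r + 0.5 - d)
  canvas[w$i, w$j] <- pmax(canvas[w$i, w$j], val)
  canvas
}

.stampCurve <- function(canvas, pts, width) {
  S <- nrow(canvas)
  # resample polyline at ~0.7 px spacing (steps are already ~1 px)
  for (s in seq_len(nrow(pts))) {
    w <- .window(pts[s, 1], pts[s, 2], width + 1, S)
    if (is.null(w)) next
    d <- sqrt(outer((w$i - pts[s, 1])^2, (w$j - pts[s, 2])^2, `+`))
    canvas[w$i, w$j] <- pmax(canvas[w$i, w$j], clamp01(width + 0.5 - d))
  }
  canvas
}

.stampMask <- function(mask, center, radius) {
  S <- nrow(mask)
  w <- .window(center[1], center[2], radius + 1, S)
  d <- sqrt(outer((w$i - center[1])^2, (w$j - center[2])^2, `+`))
  mask[w$i, w$j] <- pmax(mask[w$i, w$j], as.integer(d <= radius))
  mask
}

#' Sample and render one synthetic field
#'
#' Convenience wrapper: [sampleMitoGeometry()] followed by [renderField()].
#'
#' @inheritParams sampleMitoGeometry
#' @return A [SimulatedField-class].
#' @examples
#' fld <- simulateField(morphologySpec(phi = 0.9, fieldSizePx = 256, seed = 3))
#' @export
simulateField <- function(spec) renderField(sampleMitoGeometry(spec), spec)

#' Default per-class simulator specs
#'
#' One spec per class label: `phi = 0.1` for the hyperfission (CCCP-like)
#' class, `phi = 0.5` for normal, `phi = 0.9` for the hyperfusion (FL3-like)
#' class, all other parameters at [morphologySpec()] defaults.
#'
#' @param fieldSizePx Field side length in pixels.
#' @param ... Further arguments passed to [morphologySpec()].
#' @return Named list of [MorphologySpec-class] objects.
#' @export
defaultClassSpecs <- function(fieldSizePx = 512, ...) {
  list(CCCP = morphologySpec(phi = 0.1, fieldSizePx = fieldSizePx, ...),
       NC = morphologySpec(phi = 0.5, fieldSizePx = fieldSizePx, ...),
       FL3 = morphologySpec(phi = 0.9, fieldSizePx = fieldSizePx, ...))
}

#' Generate a synthetic dataset on disk
#'
#' Writes one 16-bit TIFF per field, an 8-bit truth-mask TIFF, and a CSV
#' manifest (columns `field_id`, `path`, `mask_path`, `label`, `phi`,
#' `experiment_id`, `participant_id`). Acquisition batches (`experiment_id`)
#' are assigned round-robin across fields within each class so grouped
#' cross-validation is exercised. Deterministic given `seed`.
#'
#' @param classSpecs Named list of [MorphologySpec-class], one per class
#'   label; each spec's label must match `phiLabel(spec@phi)`.
#' @param nFieldsPerClass Number of fields per class.
#' @param outDir Output directory (created if missing).
#' @param seed Root RNG seed; per-field seeds are derived from it.
#' @param nExperiments Number of synthetic acquisition batches.
#' @return The manifest data frame, invisibly; also written to
#'   `file.path(outDir, "manifest.csv")`.
#' @export
generateDataset <- function(classSpecs, nFieldsPerClass, outDir, seed = 1,
                            nExperiments = 6) {
  stopifnot2(length(names(classSpecs)) == length(classSpecs) &&
               all(nzchar(names(classSpecs))), "classSpecs must be named")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stopifnot2(dir.exists(outDir),
             paste("filesystem error: cannot create", outDir))
  rows <- list()
  for (ci in seq_along(classSpecs)) {
    label <- names(classSpecs)[ci]
    spec <- classSpecs[[ci]]
    stopifnot2(identical(phiLabel(spec@phi), label),
               sprintf("label '%s' does not match phi=%.3f", label, spec@phi))
    for (i in seq_len(nFieldsPerClass)) {
      spec@seed <- deriveSeed(seed, ci * 100003L + i)
      fld <- simulateField(spec)
      fid <- sprintf("%s_%03d", label, i)
      path <- file.path(outDir, paste0(fid, ".tif"))
      maskPath <- file.path(outDir, paste0(fid, "_mask.tif"))
      writeField(fld@image, path)
      tiff::writeTIFF(fld@truthMask, maskPath, bits.per.sample = 8)
      rows[[length(rows) + 1L]] <- data.frame(
        field_id = fid, path = basename(path), mask_path = basename(maskPath),
        label = label, phi = spec@phi,
        experiment_id = sprintf("E%d", ((i - 1L) %% nExperiments) + 1L),
        participant_id = NA_character_, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  invisible(manifest)
}
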