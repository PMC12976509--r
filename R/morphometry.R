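#' Segment individual mitochondria within the foreground
#'
#' Adaptive local-mean thresholding (mitochondrial signal is locally
#' contrasted; a global threshold merges dense networks), restricted to the
#' foreground mask, with removal of objects below 4 px and 8-connected
#' component labeling.
#'
#' @param image Normalized 2D image in [0, 1].
#' @param mask Binary foreground mask (same dimensions), or `NULL` for the
#'   whole field.
#' @param blockSize Side of the local-mean window in pixels (odd, default
#'   33).
#' @param offset Threshold offset above the local mean.
#' @param minPx Minimum object area kept.
#' @return Integer label matrix (0 = background, 1..K = objects).
#' @export
segmentMitochondria <- function(image, mask = NULL, blockSize = 33,
                                offset = 0.05, minPx = 4) {
  img <- fieldImage(image)
  stopifnot2(length(dim(img)) == 2L, "shape error: image must be 2D")
  if (is.null(mask)) mask <- matrix(1, nrow(img), ncol(img))
  if (all(mask == 0) || max(img) <= 0)
    return(matrix(0L, nrow(img), ncol(img)))
  half <- max(1L, as.integer((blockSize - 1) / 2))
  bin <- as.matrix(EBImage::thresh(EBImage::Image(img), w = half, h = half,
                                   offset = offset))
  bin[mask == 0] <- 0
  lab <- labelComponents(bin)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    drop <- which(areas < minPx)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      lab <- labelComponents(lab)   # re-densify labels
    }
  }
  lab
}

# Iterative endpoint-anchored Douglas-Peucker simplification of a point
# chain; returns indices of retained vertices.
.dpIndices <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2) return(seq_len(n))
  keep <- logical(n)
  keep[c(1, n)] <- TRUE
  stack <- list(c(1, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a
    len2 <- sum(ab^2)
    mid <- (i + 1):(j - 1)
    rel <- sweep(pts[mid, , drop = FALSE], 2, a)
    d <- if (len2 == 0) sqrt(rowSums(rel^2))
         else abs(rel[, 1] * ab[2] - rel[, 2] * ab[1]) / sqrt(len2)
    kmax <- which.max(d)
    if (d[kmax] > eps) {
      k <- mid[kmax]
      keep[k] <- TRUE
      stack[[length(stack) + 1L]] <- c(i, k)
      stack[[length(stack) + 1L]] <- c(k, j)
    }
  }
  which(keep)
}

# Disc-calibrated perimeter: Moore boundary chain simplified to a polygon
# (Douglas-Peucker, 1 px tolerance), so straight edges are preserved exactly
# while the staircase of digitized curves collapses onto chords. The polygon
# runs through pixel centers, half a pixel inside the physical outline, so a
# +2 closed-contour offset restores the outer-boundary scale; the result is
# floored at the isoperimetric bound 2*sqrt(pi*A), below which no true
# perimeter can lie (this pins FF >= 1 for few-pixel puncta). Disc bias is
# below 5% from radius ~3 px upward.
.perimeter <- function(objMask, area = sum(objMask != 0)) {
  isop <- 2 * sqrt(pi * area)
  chain <- .boundary_chain(objMask)
  n <- nrow(chain)
  if (n <= 1) return(max(4, isop))          # single pixel
  if (n == 2)
    return(max(2 * sqrt(sum((chain[1, ] - chain[2, ])^2)) + 2, isop))
  # split the closed chain in half and simplify each part so the polygon
  # can bend anywhere
  half <- floor(n / 2)
  i1 <- .dpIndices(chain[1:half, , drop = FALSE], 1)
  i2 <- .dpIndices(chain[half:n, , drop = FALSE], 1) + half - 1L
  idx <- unique(c(i1, i2, 1L))
  poly <- chain[sort(idx), , drop = FALSE]
  poly <- rbind(poly, poly[1, ])
  max(sum(sqrt(rowSums(diff(poly)^2))) + 2, isop)
}

#' Shape metrics of one segmented object
#'
#' Form factor `FF = P^2 / (4 * pi * A)` (1 for a disc, growing with
#' elongation and boundary complexity) and aspect ratio `AR =
#' major / minor` axis of the moment-equivalent ellipse. The perimeter
#' estimator is a Douglas-Peucker-simplified boundary polygon, calibrated so
#' the disc bias stays within 5%.
#'
#' @param objMask Binary matrix containing a single object.
#' @return List with `area`, `perimeter`, `formFactor`, `aspectRatio`,
#'   `majorAxis`, `minorAxis`, and `reliable` (FALSE for degenerate,
#'   effectively 1-px-wide objects whose metrics are excluded from
#'   summaries).
#' @export
shapeMetrics <- function(objMask) {
  idx <- which(objMask != 0, arr.ind = TRUE)
  area <- nrow(idx)
  stopifnot2(area >= 1, "empty object")
  P <- .perimeter(matrix(as.integer(objMask != 0), nrow(objMask),
                         ncol(objMask)), area)
  ff <- P^2 / (4 * pi * area)
  if (area < 2) {
    return(list(area = area, perimeter = P, formFactor = ff,
                aspectRatio = NA_real_, majorAxis = NA_real_,
                minorAxis = NA_real_, reliable = FALSE))
  }
  # moment-equivalent ellipse from the pixel-coordinate covariance
  # (+1/12 accounts for unit-pixel spread)
  cvRaw <- stats::cov(idx) * (area - 1) / max(1, area)
  evRaw <- sort(eigen(cvRaw, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
  cv <- cvRaw + diag(1 / 12, 2)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(max(ev[2], 0))
  ar <- major / minor
  # an object that is effectively one pixel wide (zero raw spread on the
  # minor axis) has no meaningful ellipse; exclude it from summaries
  list(area = area, perimeter = P, formFactor = ff, aspectRatio = ar,
       majorAxis = major, minorAxis = minor,
       reliable = area >= 4 && 4 * sqrt(max(evRaw[2], 0)) >= 1)
}

# Zhang-Suen topological thinning to a 1-px skeleton, vectorized over the
# whole image with shifted neighbor matrices.
.thin <- function(mask) {
  img <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  pad <- matrix(0L, nrow(img) + 2, ncol(img) + 2)
  pad[2:(nrow(img) + 1), 2:(ncol(img) + 1)] <- img
  H <- nrow(pad); W <- ncol(pad)
  sh <- function(m, dr, dc) {
    out <- matrix(0L, H, W)
    rs <- max(1, 1 + dr):min(H, H + dr)
    cs <- max(1, 1 + dc):min(W, W + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      # neighbors P2..P9 clockwise from north
      p2 <- sh(pad, -1, 0); p3 <- sh(pad, -1, 1); p4 <- sh(pad, 0, 1)
      p5 <- sh(pad, 1, 1); p6 <- sh(pad, 1, 0); p7 <- sh(pad, 1, -1)
      p8 <- sh(pad, 0, -1); p9 <- sh(pad, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (phase == 1) {
        cond <- pad == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- pad == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        pad[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nrow(img) + 1), 2:(ncol(img) + 1)]
}

#' Skeleton branch/junction graph of a binary network
#'
#' Thins the mask to a 1-px skeleton (Zhang-Suen), classifies skeleton
#' pixels by 8-neighbor count into endpoints (1 neighbor) and junction
#' pixels (>= 3 neighbors; adjacent junction pixels merge into one
#' junction), and walks maximal node-free paths as branches. Branch length
#' sums unit steps for axial moves and sqrt(2) for diagonal moves; isolated
#' cycles count as a single branch with no junction.
#'
#' @param mask Binary matrix of the mitochondrial network (an object mask or
#'   the union of all objects).
#' @return A [SkeletonGraph-class].
#' @export
skeletonGraph <- function(mask) {
  skel <- .thin(mask)
  px <- which(skel != 0, arr.ind = TRUE)
  n <- nrow(px)
  emptyGraph <- function() new(
    "SkeletonGraph",
    nodes = data.frame(row = integer(), col = integer(),
                       type = character()),
    branches = data.frame(length = numeric()), nBranches = 0, nJunctions = 0)
  if (n == 0) return(emptyGraph())
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[px] <- seq_len(n)
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  # adjacency lists; diagonal links are dropped when the two pixels share an
  # axial skeleton neighbor (removes spurious triangles at L-corners)
  neigh <- vector("list", n)
  for (i in seq_len(n)) {
    r <- px[i, 1]; c <- px[i, 2]
    nb <- integer()
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs[k, 1]; cc <- c + offs[k, 2]
      if (rr < 1 || rr > nrow(skel) || cc < 1 || cc > ncol(skel)) next
      j <- id[rr, cc]
      if (j == 0) next
      diag <- offs[k, 1] != 0 && offs[k, 2] != 0
      if (diag) {
        # shared axial neighbor?
        a1 <- id[r, cc]; a2 <- id[rr, c]
        if ((a1 != 0) || (a2 != 0)) next
      }
      nb <- c(nb, j)
    }
    neigh[[i]] <- nb
  }
  deg <- lengths(neigh)
  isNode <- deg != 2
  stepLen <- function(i, j)
    sqrt(sum((px[i, ] - px[j, ])^2))
  edgeKey <- function(i, j) paste(min(i, j), max(i, j))
  visited <- new.env(hash = TRUE)
  branches <- numeric()
  # walk a maximal node-free path starting with edge (start, nxt), marking
  # every traversed edge so each branch is counted exactly once
  walkMark <- function(start, nxt) {
    len <- 0
    prev <- start; cur <- nxt
    key <- edgeKey(prev, cur)
    if (!is.null(visited[[key]])) return(NULL)
    visited[[key]] <- TRUE
    len <- stepLen(prev, cur)
    while (!isNode[cur]) {
      nb <- neigh[[cur]]
      nxt2 <- nb[nb != prev][1]
      if (is.na(nxt2)) break
      visited[[edgeKey(cur, nxt2)]] <- TRUE
      len <- len + stepLen(cur, nxt2)
      prev <- cur; cur <- nxt2
    }
    len
  }
  for (i in which(isNode)) {
    for (j in neigh[[i]]) {
      l <- walkMark(i, j)
      if (!is.null(l)) branches <- c(branches, l)
    }
  }
  # isolated cycles: components with no nodes at all
  if (any(!isNode)) {
    seen <- logical(n)
    seen[isNode] <- TRUE
    for (key in ls(visited)) {
      ij <- as.integer(strsplit(key, " ")[[1]])
      seen[ij] <- TRUE
    }
    for (i in which(!seen & deg > 0)) {
      if (seen[i]) next
      # trace the cycle
      len <- 0
      prev <- i; cur <- neigh[[i]][1]
      seen[i] <- TRUE
      len <- len + stepLen(i, cur)
      while (cur != i) {
        seen[cur] <- TRUE
        nb <- neigh[[cur]]
        nxt <- nb[nb != prev][1]
        if (is.na(nxt)) break
        len <- len + stepLen(cur, nxt)
        prev <- cur; cur <- nxt
      }
      branches <- c(branches, len)
    }
  }
  # junctions: 8-connected clusters of junction pixels
  jmask <- matrix(0, nrow(skel), ncol(skel))
  jmask[px[deg >= 3, , drop = FALSE]] <- 1
  nJunc <- max(labelComponents(jmask))
  nodes <- data.frame(
    row = px[isNode & deg > 0, 1], col = px[isNode & deg > 0, 2],
    type = ifelse(deg[isNode & deg > 0] == 1, "endpoint", "junction"))
  if (n == 1)
    return(new("SkeletonGraph",
               nodes = data.frame(row = px[1, 1], col = px[1, 2],
                                  type = "endpoint"),
               branches = data.frame(length = 1), nBranches = 1,
               nJunctions = 0))
  new("SkeletonGraph", nodes = nodes,
      branches = data.frame(length = branches),
      nBranches = length(branches), nJunctions = nJunc)
}

#' Per-field classical morphometry summary
#'
#' The traditional baseline: segments mitochondria, computes per-object form
#' factor and aspect ratio (means and medians over reliable objects), and
#' skeleton-graph network statistics (branch count, mean branch length,
#' junction count) on the union of all objects.
#'
#' @param image Normalized 2D image in [0, 1].
#' @param mask Binary foreground mask or `NULL`.
#' @param ... Passed to [segmentMitochondria()].
#' @return One-row data frame: `object_count`, `ff_mean`, `ff_median`,
#'   `ar_mean`, `ar_median`, `n_branches`, `mean_branch_length`,
#'   `n_junctions`. All-NaN (with `object_count = 0`) when nothing
#'   segments.
#' @export
fieldMorphometry <- function(image, mask = NULL, ...) {
  lab <- segmentMitochondria(image, mask, ...)
  K <- max(lab)
  if (K == 0)
    return(data.frame(object_count = 0, ff_mean = NaN, ff_median = NaN,
                      ar_mean = NaN, ar_median = NaN, n_branches = NaN,
                      mean_branch_length = NaN, n_junctions = NaN))
  ff <- ar <- rep(NA_real_, K)
  idxAll <- which(lab > 0, arr.ind = TRUE)
  for (k in seq_len(K)) {
    idx <- idxAll[lab[idxAll] == k, , drop = FALSE]
    r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
    sub <- matrix(0L, r1 - r0 + 3, c1 - c0 + 3)
    sub[cbind(idx[, 1] - r0 + 2, idx[, 2] - c0 + 2)] <- 1L
    m <- shapeMetrics(sub)
    if (m$reliable) { ff[k] <- m$formFactor; ar[k] <- m$aspectRatio }
  }
  sk <- skeletonGraph(lab > 0)
  data.frame(
    object_count = K,
    ff_mean = mean(ff, na.rm = TRUE), ff_median = median(ff, na.rm = TRUE),
    ar_mean = mean(ar, na.rm = TRUE), ar_median = median(ar, na.rm = TRUE),
    n_branches = sk@nBranches,
    mean_branch_length = if (sk@nBranches > 0)
      mean(sk@branches$length) else NaN,
    n_junctions = sk@nJunctions)
}
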