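#' @useDynLib mitoscore, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rpois rnorm runif rbinom rgamma quantile median sd
#'   cor predict glm binomial pnorm setNames p.adjust cov
#' @importFrom utils read.csv write.csv head
NULL

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream. All user-facing stochastic operations funnel through this.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic integer mix of a root seed and an index, kept within the
# 32-bit range R requires of set.seed().
deriveSeed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %%
               2147483647)
}

# note argument order: pmax/pmin take attributes (dim) from their first arg
clamp01 <- function(x) pmin(pmax(x, 0), 1)

# 8-connected component labeling (EBImage::bwlabel is 4-connected).
labelComponents <- function(mask) {
  .cc_label8(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))
}

stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
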