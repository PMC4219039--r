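#' @include AllGenerics.R
NULL

# Deterministic sign convention: orient each component so its largest-
# magnitude element is positive. Keeps fitted bases reproducible and
# sign-aligned with the generating shapes of synthetic cohorts.
.signFlip <- function(components) {
  if (!ncol(components)) return(components)
  for (j in seq_len(ncol(components))) {
    i <- which.max(abs(components[, j]))
    if (components[i, j] < 0) components[, j] <- -components[, j]
  }
  components
}

#' Fit a principal-component basis to a set of curves
#'
#' Any curve of the population is represented as the population mean plus a
#' weighted sum of principal components plus a residual. The first
#' component maximizes the variance of the training set it explains; each
#' further component accounts for the largest share of the remaining
#' variance. The number of retained components is the smallest count whose
#' cumulative explained variance reaches `varianceTarget`, capped at
#' `maxComponents`.
#'
#' @param curves matrix of curves (rows = cases, columns = grid points),
#'   all on an identical grid.
#' @param grid the common grid the curves live on.
#' @param varianceTarget fraction of variance to explain (default 0.95).
#' @param maxComponents cap on the number of retained components
#'   (default 5).
#' @return a [PCABasis-class].
#' @export
fitPCA <- function(curves, grid = NULL, varianceTarget = 0.95,
                   maxComponents = 5L) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  if (n < 2L) stop("insufficient data: need at least 2 curves")
  if (is.null(grid)) grid <- seq_len(ncol(curves))
  if (length(grid) != ncol(curves))
    stop("grid length must match curve length")
  mu <- colMeans(curves)
  xc <- sweep(curves, 2L, mu)
  sv <- svd(xc)
  ev <- sv$d^2 / (n - 1)
  total <- sum(ev)
  if (total < 1e-24) {
    return(methods::new("PCABasis", grid = as.numeric(grid), meanCurve = mu,
                        components = matrix(numeric(0), length(grid), 0L),
                        explainedVariance = numeric(0), totalVariance = 0,
                        nComponents = 0L))
  }
  frac <- ev / total
  k <- which(cumsum(frac) >= varianceTarget - 1e-12)[1L]
  if (is.na(k)) k <- length(frac)
  k <- min(k, maxComponents, length(frac))
  comps <- .signFlip(sv$v[, seq_len(k), drop = FALSE])
  methods::new("PCABasis", grid = as.numeric(grid), meanCurve = mu,
               components = comps, explainedVariance = frac[seq_len(k)],
               totalVariance = total, nComponents = as.integer(k))
}

#' Project curves onto a principal-component basis
#'
#' Score i of a curve is the inner product of the centred curve with
#' component i; the resulting rank-n reconstruction is the least-squares
#' optimal one.
#'
#' @param basis a [PCABasis-class].
#' @param curves a numeric vector (one curve) or a matrix (rows = curves)
#'   on the basis grid.
#' @return a matrix of scores (curves x components).
#' @export
pcaScore <- function(basis, curves) {
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1L)
  if (ncol(curves) != length(basis@grid))
    stop("curve grid does not match the basis grid")
  sweep(curves, 2L, basis@meanCurve) %*% basis@components
}

#' Reconstruct curves from component scores
#'
#' @param basis a [PCABasis-class].
#' @param scores matrix of scores (curves x components) or a vector for a
#'   single curve.
#' @return matrix of reconstructed curves (curves x grid points).
#' @export
pcaReconstruct <- function(basis, scores) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  if (ncol(scores) != basis@nComponents)
    stop("score count does not match the basis")
  base <- matrix(basis@meanCurve, nrow(scores), length(basis@meanCurve),
                 byrow = TRUE)
  if (basis@nComponents > 0L) base <- base + scores %*% t(basis@components)
  base
}
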