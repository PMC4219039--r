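# Internal numerical helpers shared across the package.

.REL_SPAN <- 1.1   # modelling grid extends to 110% of prescription
.N_GRID   <- 100L  # common resampling grid for PCA / regression

#' Relative-dose modelling grid
#'
#' The common grid on which curves are resampled before principal-component
#' analysis: doses expressed as a fraction of the prescription, from 0 to
#' 110% of the prescription.
#'
#' @param n number of grid points.
#' @param span upper end of the grid in units of the prescription dose.
#' @return numeric vector of relative doses.
#' @export
relDoseGrid <- function(n = .N_GRID, span = .REL_SPAN) {
  seq(0, span, length.out = n)
}

# Least-squares projection onto the non-increasing cone (pool adjacent
# violators, via isotonic regression of the negated sequence).
monotoneNonIncreasing <- function(y) {
  if (length(y) < 2L) return(y)
  -stats::isoreg(seq_along(y), -y)$yf
}

clampRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

linInterp <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}

# Smallest dose at which a non-increasing piecewise-linear curve reaches
# `target` volume; ties (flat segments at the target level) resolve to the
# lower dose.
curveDoseAtVolume <- function(dose, volume, target) {
  if (target >= volume[1L]) return(dose[1L])
  idx <- which(volume <= target)
  if (!length(idx)) return(dose[length(dose)])
  i <- idx[1L]
  v0 <- volume[i - 1L]; v1 <- volume[i]
  if (v0 == v1) return(dose[i])
  dose[i - 1L] + (v0 - target) / (v0 - v1) * (dose[i] - dose[i - 1L])
}

# Mean dose of a cumulative curve via its differential masses (midpoint
# rule on each bin, residual tail mass assigned to the last grid dose).
curveMeanDose <- function(dose, volumeFraction) {
  dv <- -diff(volumeFraction)
  mids <- (dose[-1L] + dose[-length(dose)]) / 2
  sum(mids * dv) + dose[length(dose)] * volumeFraction[length(volumeFraction)]
}

# Short reproducibility fingerprint of a configuration object (polynomial
# rolling hash of its canonical JSON rendering).
configHash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     force = TRUE))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
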