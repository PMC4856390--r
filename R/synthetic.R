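# Synthetic fixtures: periodic random-amplitude cables, canonical profiles,
# random binary trees, and the local slow-taper parameter estimate.

# Evaluate expr with a local RNG seeded at `seed`, restoring the caller's
# RNG state afterwards, so generators are pure functions of their arguments.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a periodic random-amplitude cable
#'
#' Builds an artificial dendritic cable whose radius oscillates about a
#' mean with one uniformly drawn amplitude per period, the construction
#' used to probe the accuracy of the first-order voltage approximation.
#' The waveform is a raised cosine per period with alternating sign, so
#' the profile is continuously differentiable and its radius stays within
#' \code{meanRadius +- amplitudeRange}.  Increasing the period and reducing
#' the amplitude smooths the cable and shrinks the slow-taper parameter
#' epsilon (see [estimateEpsilon()]).
#'
#' @param length cable length (um).
#' @param meanRadius mean radius (um).
#' @param period spatial period of the radius oscillation (um).
#' @param amplitudeRange upper bound of the per-period amplitude draw (um);
#'   must be smaller than \code{meanRadius} so radii stay positive.
#' @param nPoints number of sample points.
#' @param seed integer seed; the generator is deterministic per seed.
#' @return A [RadiusProfile-class].
#' @examples
#' p <- makePeriodicCable(1000, 1, 200, 0.4, 801, seed = 1)
#' range(profileRadius(p))
#' @export
makePeriodicCable <- function(length, meanRadius, period, amplitudeRange,
                              nPoints = 1001L, seed = 1L) {
  stopifnot(length > 0, meanRadius > 0, period > 0, amplitudeRange >= 0)
  if (amplitudeRange >= meanRadius)
    stop("amplitudeRange must be smaller than meanRadius to keep radii positive")
  x <- seq(0, length, length.out = as.integer(nPoints))
  nper <- ceiling(length / period)
  amps <- .withSeed(seed, stats::runif(nper, 0, amplitudeRange))
  j <- pmin(floor(x / period) + 1L, nper)          # period index per point
  phase <- (x - (j - 1L) * period) / period        # in [0, 1)
  sgn <- ifelse(j %% 2L == 1L, 1, -1)
  r <- meanRadius + sgn * amps[j] * (1 - cos(2 * pi * phase)) / 2
  radiusProfile(x, r)
}

#' Quadratic (optimal-taper) cable
#'
#' Samples the quadratic profile \eqn{r(x) = \alpha (L - x)^2 + r_L}, the
#' radius law that maximises summed current transfer to the proximal end.
#'
#' @param L cable length (um).
#' @param rL distal (minimal) radius (um).
#' @param alpha taper coefficient (1/um).
#' @param nPoints number of sample points.
#' @return A [RadiusProfile-class].
#' @seealso [fitAlphaVolume()], [fitAlphaProximal()]
#' @export
makeQuadraticCable <- function(L, rL, alpha, nPoints = 1001L) {
  stopifnot(L > 0, rL > 0, alpha >= 0)
  x <- seq(0, L, length.out = as.integer(nPoints))
  radiusProfile(x, alpha * (L - x)^2 + rL)
}

#' Linearly tapering frustum
#' @param L length (um).
#' @param rProximal,rDistal end radii (um).
#' @param nPoints number of sample points.
#' @return A [RadiusProfile-class].
#' @export
makeFrustum <- function(L, rProximal, rDistal, nPoints = 1001L) {
  stopifnot(L > 0, rProximal > 0, rDistal > 0)
  x <- seq(0, L, length.out = as.integer(nPoints))
  radiusProfile(x, rProximal + (rDistal - rProximal) * x / L)
}

#' Uniform cylinder
#' @param L length (um).
#' @param r radius (um).
#' @param nPoints number of sample points.
#' @return A [RadiusProfile-class].
#' @export
makeCylinder <- function(L, r, nPoints = 1001L)
  makeFrustum(L, r, r, nPoints)

#' Generate a random binary tree morphology
#'
#' Builds a rooted, strictly binary tree with \code{nTips} terminal points.
#' Each branch is a chain of nodes with total length drawn uniformly from
#' \code{segmentLengthRange} and a randomly perturbed direction in 3-D;
#' all radii are a positive placeholder (1 um by default) to be re-assigned
#' by radius-distribution routines.  Deterministic per seed.
#'
#' @param nTips number of terminal tips (>= 1).
#' @param segmentLengthRange length-2 numeric, range of branch lengths (um).
#' @param seed integer seed.
#' @param radius placeholder radius (um).
#' @param nodeSpacing approximate spacing between consecutive nodes along a
#'   branch (um).
#' @return A [TreeMorphology-class].
#' @export
makeRandomTree <- function(nTips, segmentLengthRange = c(40, 120), seed = 1L,
                           radius = 1, nodeSpacing = 10) {
  stopifnot(nTips >= 1, length(segmentLengthRange) == 2L,
            all(segmentLengthRange > 0), radius > 0, nodeSpacing > 0)
  .withSeed(seed, {
    acc <- new.env(parent = emptyenv())
    acc$rows <- list(c(1, 1, 0, 0, 0, radius, NA))
    acc$nextId <- 2L
    # grow(parentId, pos, dir, tips): adds one branch then splits
    grow <- function(parentId, pos, dir, tips) {
      len <- stats::runif(1, segmentLengthRange[1L], segmentLengthRange[2L])
      dir <- dir + stats::rnorm(3, sd = 0.4)
      dir <- dir / sqrt(sum(dir^2))
      nseg <- max(2L, ceiling(len / nodeSpacing))
      step <- len / nseg
      pid <- parentId
      for (s in seq_len(nseg)) {
        pos <- pos + dir * step
        id <- acc$nextId
        acc$rows[[length(acc$rows) + 1L]] <-
          c(id, 3, pos[1L], pos[2L], pos[3L], radius, pid)
        pid <- id
        acc$nextId <- id + 1L
      }
      if (tips > 1L) {
        tl <- sample.int(tips - 1L, 1L)
        grow(pid, pos, dir, tl)
        grow(pid, pos, dir, tips - tl)
      }
    }
    grow(1L, c(0, 0, 0), c(1, 0, 0), as.integer(nTips))
    m <- do.call(rbind, acc$rows)
    treeMorphology(data.frame(id = m[, 1L], type = m[, 2L], x = m[, 3L],
                              y = m[, 4L], z = m[, 5L], radius = m[, 6L],
                              parent = m[, 7L]))
  })
}

#' Estimate the local slow-taper parameter epsilon
#'
#' The first-order voltage approximation rests on the radius changing
#' slowly relative to the voltage decay.  We quantify this per position as
#' \deqn{\epsilon(x) = \lambda(x)\,|r'(x)| / r(x),}
#' the local electrotonic length divided by the radius e-fold length: the
#' fractional radius change per space constant.  For a cylinder
#' \eqn{\epsilon \equiv 0}; the approximation is accurate where
#' \eqn{\epsilon} is small.  The profile is resampled to a uniform grid,
#' optionally pre-smoothed with a moving average (recommended width: one
#' period for periodic fixtures, since the derivative of a noisy
#' reconstruction is otherwise dominated by measurement noise), and
#' \eqn{r'} is taken by central differences.
#'
#' @param p a [RadiusProfile-class].
#' @param params a [PassiveParams-class].
#' @param smoothWindow moving-average window (um), or NULL for no smoothing.
#' @param n resampling grid size.
#' @return An [EpsilonReport-class].
#' @export
estimateEpsilon <- function(p, params, smoothWindow = NULL, n = 1001L) {
  stopifnot(is(p, "RadiusProfile"), is(params, "PassiveParams"))
  pu <- resampleProfile(p, n)
  x <- pu@x; r <- pu@r
  if (!is.null(smoothWindow) && smoothWindow > 0) {
    dx <- x[2L] - x[1L]
    w <- max(1L, round(smoothWindow / dx))
    if (w %% 2L == 0L) w <- w + 1L
    if (w > 1L) {
      kern <- rep(1 / w, w)
      pad <- (w - 1L) %/% 2L
      rp <- c(rep(r[1L], pad), r, rep(r[length(r)], pad))
      r <- stats::filter(rp, kern, sides = 2)[(pad + 1L):(pad + length(x))]
      r <- as.numeric(r)
    }
  }
  lam <- .lambdaUm(r, params)
  rprime <- pracma::gradient(r, x[2L] - x[1L])
  eps <- lam * abs(rprime) / r
  q <- stats::quantile(eps, c(0.05, 0.25, 0.5, 0.75, 0.95))
  new("EpsilonReport", x = x, epsilon = eps, quantiles = q)
}

# local electrotonic length in um for radii in um
.lambdaUm <- function(r_um, params)
  sqrt((r_um / .UM_PER_CM) / (2 * params@ra * params@gl)) * .UM_PER_CM
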