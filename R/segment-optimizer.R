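# Non-parametric numerical optimisation of a segmented cable's radii:
# derivative-free simplex search maximising summed current transfer to the
# proximal end under fixed volume and fixed distal radius, and the
# quadratic fit to the resulting segment radii.

# piecewise-constant profile from segment radii (sampled, two points per
# interface so the steps survive linear resampling closely)
.segmentProfile <- function(radii, L, pointsPerSegment = 41L) {
  ns <- length(radii)
  ell <- L / ns
  xs <- list(); rs <- list()
  eps <- ell * 1e-6
  for (i in seq_len(ns)) {
    x0 <- (i - 1L) * ell; x1 <- i * ell
    xg <- seq(x0, x1, length.out = pointsPerSegment)
    if (i > 1L) xg[1L] <- x0 + eps
    xs[[i]] <- xg
    rs[[i]] <- rep(radii[i], pointsPerSegment)
  }
  x <- unlist(xs); r <- unlist(rs)
  x[1L] <- 0
  radiusProfile(x, r)
}

#' Optimise segment radii for current transfer (simplex search)
#'
#' Re-implements the non-parametric optimisation protocol: a cable of
#' length \code{L} is split into \code{nSegments} equal segments; segment
#' radii are optimised by derivative-free Nelder-Mead simplex search to
#' maximise the summed current transfer to the proximal end, evaluated
#' with the finite-difference oracle on the piecewise-constant profile.
#' The default objective is the summed transfer ratio
#' \eqn{\int_0^L v(0, x')/v(x', x')\, dx'} ([transferRatioNumeric()]),
#' which is bounded and has a genuine interior optimum; the raw delivered
#' voltage \eqn{\int_0^L v(0, x')\, dx'} ([transferFunctionalNumeric()])
#' is available as an alternative but is degenerate under a volume
#' constraint (it rewards profiles that choke the proximal end to decouple
#' from the somatic load).  The total volume is enforced by
#' reparameterisation (the most proximal segment's radius is solved from
#' the volume constraint) and the distal segment radius is fixed at
#' \code{rL}.  The search is restarted from seeded random radii drawn
#' feasible, and the best result over all restarts is returned.
#'
#' @param L cable length (um).
#' @param V total volume (um^3).
#' @param rL distal segment radius (um), held fixed.
#' @param params a [PassiveParams-class].
#' @param nSegments number of segments (default 7).
#' @param nRestarts number of random restarts (default 10).
#' @param seed integer seed for the restart initialisations.
#' @param bcProximal proximal boundary condition for the objective.
#' @param objective \code{"transfer_ratio"} (default) or
#'   \code{"delivered_voltage"}, see above.
#' @param loadRadius fixed proximal collar radius (um) presented to every
#'   candidate; defaults to the equal-volume cylinder radius
#'   \code{sqrt(V/(pi L))} so the downstream load is a property of the
#'   constraint set, not of the candidate.
#' @param pointsPerSegment oracle grid points per segment.
#' @param maxit simplex iterations per restart.
#' @param init optional explicit initial radii for segments
#'   2..(nSegments-1) prepended to the random restarts (e.g. the analytic
#'   quadratic).
#' @return A [SegmentedCable-class]; the \code{report} slot carries the
#'   per-restart objectives and convergence codes.
#' @export
optimizeSegments <- function(L, V, rL, params, nSegments = 7L,
                             nRestarts = 10L, seed = 1L,
                             bcProximal = "matched_infinite",
                             objective = c("transfer_ratio",
                                           "delivered_voltage"),
                             loadRadius = NULL,
                             pointsPerSegment = 41L, maxit = 600L,
                             init = NULL) {
  stopifnot(nSegments >= 2L, L > 0, rL > 0, V > 0)
  objective <- match.arg(objective)
  if (is.null(loadRadius)) loadRadius <- sqrt(V / (pi * L))
  evalProfile <- function(prof, npts) {
    if (objective == "transfer_ratio")
      transferRatioNumeric(prof, params, bcProximal = bcProximal,
                           n = npts, loadRadius = loadRadius)
    else
      transferFunctionalNumeric(prof, params, bcProximal = bcProximal,
                                n = npts, loadRadius = loadRadius)
  }
  ns <- as.integer(nSegments)
  ell <- L / ns
  if (V <= pi * rL^2 * ell)
    stop("infeasible volume: smaller than the distal segment alone")
  nfree <- ns - 2L     # segments 2..(ns-1); segment 1 solved from volume
  r1FromVolume <- function(rmid) {
    v1 <- V / pi - ell * (sum(rmid^2) + rL^2)
    if (v1 <= 0) return(NA_real_)
    sqrt(v1 / ell)
  }
  negObjective <- function(logRmid) {
    rmid <- exp(logRmid)
    r1 <- r1FromVolume(rmid)
    if (is.na(r1))                 # infeasible: graded penalty back in
      return(1e6 * (1 + sum(rmid^2) * ell * pi / V))
    radii <- c(r1, rmid, rL)
    prof <- .segmentProfile(radii, L, pointsPerSegment)
    -evalProfile(prof, ns * pointsPerSegment + 1L)
  }
  if (nfree == 0L) {      # two segments: volume fixes the proximal radius
    r1 <- r1FromVolume(numeric(0))
    if (is.na(r1)) stop("infeasible volume")
    radii <- c(r1, rL)
    prof <- .segmentProfile(radii, L, pointsPerSegment)
    obj <- evalProfile(prof, ns * pointsPerSegment + 1L)
    return(new("SegmentedCable", radii = radii, L = L, volume = V,
               objective = obj,
               report = list(nSegments = ns, bcProximal = bcProximal,
                             objective = objective,
                             loadRadius = loadRadius)))
  }
  rcyl <- sqrt(V / (pi * L))
  # random shapes rescaled so the free segments consume a random fraction
  # of the available volume: every restart begins feasible
  starts <- .withSeed(seed, lapply(seq_len(nRestarts), function(i) {
    shape <- stats::runif(nfree, 0.3 * rcyl, 3 * rcyl)
    avail <- V / pi - ell * rL^2
    frac <- stats::runif(1, 0.3, 0.8)
    log(shape * sqrt(frac * avail / (ell * sum(shape^2))))
  }))
  if (!is.null(init)) {
    stopifnot(length(init) == nfree)
    starts <- c(list(log(init)), starts)
  }
  best <- NULL
  trace <- data.frame(restart = integer(), objective = numeric(),
                      convergence = integer())
  for (i in seq_along(starts)) {
    fit <- stats::optim(starts[[i]], negObjective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    trace[i, ] <- list(i, -fit$value, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (all(trace$convergence != 0))
    warning("simplex search did not fully converge in any restart; ",
            "returning the best radii found")
  rmid <- exp(best$par)
  radii <- c(r1FromVolume(rmid), rmid, rL)
  new("SegmentedCable", radii = radii, L = L, volume = V,
      objective = -best$value,
      report = list(restarts = trace, nSegments = ns,
                    bcProximal = bcProximal, objective = objective,
                    loadRadius = loadRadius, seed = seed))
}

#' Degenerate single-segment evaluation
#'
#' For one segment the volume constraint fully determines the radius;
#' returns the cylinder and its objective.
#' @inheritParams optimizeSegments
#' @return A [SegmentedCable-class].
#' @export
evaluateSingleSegment <- function(L, V, params,
                                  bcProximal = "matched_infinite",
                                  pointsPerSegment = 201L) {
  r <- sqrt(V / (pi * L))
  prof <- makeCylinder(L, r, pointsPerSegment)
  obj <- transferFunctionalNumeric(prof, params, bcProximal = bcProximal,
                                   n = pointsPerSegment)
  new("SegmentedCable", radii = r, L = L, volume = V, objective = obj,
      report = list(nSegments = 1L, bcProximal = bcProximal))
}

#' Fit a quadratic through the distal segment radii
#'
#' Least-squares quadratic \eqn{a x^2 + b x + c} through the radii of the
#' distal \code{nSegments - 1} segments, evaluated at segment midpoints
#' (the most proximal segment is excluded, as it absorbs the
#' proximal boundary), together with a linear fit for comparison.  The
#' optimised profile is expected to be fitted substantially better by the
#' quadratic than by the line.
#'
#' @param sc a [SegmentedCable-class].
#' @return list with \code{coefficients} (c, b, a), \code{rmsQuadratic},
#'   \code{rmsLinear} (um), \code{midpoints}, \code{radii}.
#' @export
fitQuadraticToSegments <- function(sc) {
  stopifnot(is(sc, "SegmentedCable"))
  ns <- length(sc@radii)
  if (ns < 3L) stop("need at least 3 segments for a quadratic fit")
  ell <- sc@L / ns
  keep <- 2:ns
  xm <- (keep - 0.5) * ell
  rm_ <- sc@radii[keep]
  qfit <- stats::lm(rm_ ~ xm + I(xm^2))
  lfit <- stats::lm(rm_ ~ xm)
  list(coefficients = stats::coef(qfit),
       rmsQuadratic = sqrt(mean(stats::residuals(qfit)^2)),
       rmsLinear = sqrt(mean(stats::residuals(lfit)^2)),
       midpoints = xm, radii = rm_)
}
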