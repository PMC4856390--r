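# First-order method-of-multiple-scales (WKB-type) solution for the
# steady voltage in an arbitrarily tapering cable: lambda/Lambda machinery,
# Green's coefficients for a point current injection, voltage
# reconstruction, input resistance and current transfer.

#' Electrotonic structure of a profile
#'
#' Computes the local electrotonic length
#' \eqn{\lambda(x) = \sqrt{r(x) / (2 r_a g_l)}}, the cumulative
#' electrotonic distance \eqn{\Lambda(x) = \int_0^x 1/\lambda(s) ds}
#' (cumulative trapezoid, consistent with the second-order solver
#' accuracy) and \eqn{\lambda'(x)} (central differences) on a uniform
#' grid.
#'
#' @param p a [RadiusProfile-class].
#' @param params a [PassiveParams-class].
#' @param n grid size; by default the profile's own grid is kept when it
#'   is already uniform, otherwise 1001 points are used.
#' @return An [ElectrotonicProfile-class].
#' @examples
#' # r = 1 um at fly parameters gives lambda ~ 408 um
#' ep <- electrotonicProfile(makeCylinder(1000, 1, 101), passiveParams(60, 5e-4))
#' @export
electrotonicProfile <- function(p, params, n = NULL) {
  stopifnot(is(p, "RadiusProfile"), is(params, "PassiveParams"))
  if (is.null(n)) {
    dxs <- diff(p@x)
    uniform <- max(dxs) - min(dxs) < 1e-9 * mean(dxs)
    n <- if (uniform) length(p@x) else 1001L
  }
  pu <- resampleProfile(p, n)
  lam <- .lambdaUm(pu@r, params)
  dx <- pu@x[2L] - pu@x[1L]
  Lam <- as.numeric(pracma::cumtrapz(pu@x, 1 / lam))
  lp <- pracma::gradient(lam, dx)
  new("ElectrotonicProfile", x = pu@x, r = pu@r, lambda = lam, Lambda = Lam,
      lambdaPrime = lp, params = params)
}

# linear interpolation of the electrotonic quantities at a position
.epAt <- function(ep, xq) {
  list(lambda = stats::approx(ep@x, ep@lambda, xq, rule = 2)$y,
       Lambda = stats::approx(ep@x, ep@Lambda, xq, rule = 2)$y,
       r = stats::approx(ep@x, ep@r, xq, rule = 2)$y)
}

# one-sided second-order difference for lambda'(L)
.lambdaPrimeAtL <- function(ep) {
  n <- length(ep@x)
  dx <- ep@x[2L] - ep@x[1L]
  (3 * ep@lambda[n] - 4 * ep@lambda[n - 1L] + ep@lambda[n - 2L]) / (2 * dx)
}

#' First-order Green's coefficients for a point current injection
#'
#' Computes the amplitudes of the two-sided first-order solution with a
#' sealed distal end and decay towards the soma on the proximal side.
#' Writing \eqn{R_{1/2} = r_a \lambda(x') / (2 \pi r^2(x'))} (half the
#' local semi-infinite input resistance) and the distal reflection ratio
#' \deqn{k = \frac{2 - \lambda'(L)}{2 + \lambda'(L)}
#'       e^{-2 (\Lambda(L) - \Lambda(x'))},}
#' the coefficients are \eqn{B_1 = R_{1/2} (1 + k) I_{app}} (the input
#' resistance at \eqn{x'} times the current), \eqn{A_2 = R_{1/2} k
#' I_{app}} and \eqn{B_2 = R_{1/2} I_{app}}, in the exponential
#' convention anchored at \eqn{x'} (see
#' [GreensCoefficients-class]).  For a cylinder these reduce exactly to
#' the classical closed forms; \eqn{k \to 0} as \eqn{(L - x')/\lambda \to
#' \infty} and \eqn{k = 1} for injection at the sealed end.
#'
#' @param ep an [ElectrotonicProfile-class].
#' @param injX injection site (um), in (0, L].
#' @param iApp injected current (nA).
#' @return A [GreensCoefficients-class] (amplitudes in mV).
#' @export
greensCoefficients <- function(ep, injX, iApp = 1) {
  stopifnot(is(ep, "ElectrotonicProfile"))
  L <- ep@x[length(ep@x)]
  if (injX <= 0 || injX > L)
    stop("injection site must lie in (0, L]")
  lpL <- .lambdaPrimeAtL(ep)
  if (lpL >= 2 || lpL <= -2)
    stop(sprintf(
      "taper too steep for the first-order formula: lambda'(L) = %.3g", lpL))
  at <- .epAt(ep, injX)
  LamL <- ep@Lambda[length(ep@Lambda)]
  k <- (2 - lpL) / (2 + lpL) * exp(-2 * (LamL - at$Lambda))
  lam_cm <- at$lambda / .UM_PER_CM
  r_cm <- at$r / .UM_PER_CM
  Rhalf_MOhm <- ep@params@ra * lam_cm / (2 * pi * r_cm^2) * 1e-6
  new("GreensCoefficients",
      A2 = Rhalf_MOhm * k * iApp, B1 = Rhalf_MOhm * (1 + k) * iApp,
      B2 = Rhalf_MOhm * iApp, k = k, injX = injX, iApp = iApp)
}

#' Reconstruct the first-order voltage along the cable
#'
#' Evaluates
#' \deqn{v(x) = \sqrt{\lambda(x)/\lambda(x')}\; B_1\,
#'   e^{-(\Lambda(x') - \Lambda(x))}, \qquad x < x'}
#' \deqn{v(x) = \sqrt{\lambda(x)/\lambda(x')}\,
#'   [A_2 e^{\Lambda(x) - \Lambda(x')} + B_2 e^{-(\Lambda(x) -
#'   \Lambda(x'))}], \qquad x \ge x'}
#' which is continuous at \eqn{x'} by construction
#' (\eqn{B_1 = A_2 + B_2}).  The \eqn{\sqrt{\lambda}} amplitude prefactor
#' is anchored at the injection site so that the reconstruction is exact
#' for cylinders.
#'
#' @param ep an [ElectrotonicProfile-class].
#' @param gc a [GreensCoefficients-class] from [greensCoefficients()].
#' @return A [VoltageSolution-class] (mV) on the profile grid.
#' @export
voltageApprox <- function(ep, gc) {
  stopifnot(is(ep, "ElectrotonicProfile"), is(gc, "GreensCoefficients"))
  at <- .epAt(ep, gc@injX)
  pref <- sqrt(ep@lambda / at$lambda)
  dLam <- ep@Lambda - at$Lambda
  v <- ifelse(ep@x < gc@injX,
              gc@B1 * exp(dLam),
              gc@A2 * exp(dLam) + gc@B2 * exp(-dLam))
  new("VoltageSolution", x = ep@x, v = pref * v, injectionSite = gc@injX,
      iApp = gc@iApp, bcProximal = "matched_infinite", bcDistal = "sealed")
}

#' First-order input resistance at a site
#'
#' \eqn{B_1} with unit current: the first-order input resistance
#' \eqn{R(x') = \frac{r_a \lambda(x')}{2 \pi r^2(x')} [1 + k(x')]}.
#'
#' @param ep an [ElectrotonicProfile-class].
#' @param injX site (um), in (0, L].
#' @return input resistance in MOhm.
#' @export
inputResistanceApprox <- function(ep, injX)
  greensCoefficients(ep, injX, iApp = 1)@B1

#' First-order current (voltage) transfer ratio to the proximal end
#'
#' The ratio \eqn{v(0, x')/v(x', x')} of the somatic voltage to the local
#' voltage for injection at \eqn{x'}:
#' \deqn{\sqrt{\lambda(0)/\lambda(x')}\; e^{-\Lambda(x')}.}
#' Always in (0, 1] on a taper that widens towards the soma; equals 1 for
#' injection at the proximal end.
#'
#' @param ep an [ElectrotonicProfile-class].
#' @param injX injection site (um), in [0, L].
#' @return dimensionless transfer ratio.
#' @export
currentTransfer <- function(ep, injX) {
  stopifnot(is(ep, "ElectrotonicProfile"))
  at <- .epAt(ep, injX)
  sqrt(ep@lambda[1L] / at$lambda) * exp(-at$Lambda)
}

#' Compare analytic and numerical voltages on a cable
#'
#' Runs the finite-difference oracle and the first-order analytic solution
#' with identical boundary conditions on the same grid for one or more
#' injection sites and reports per-site error summaries, following the
#' protocol of comparing the two along smoothing ladders of artificial
#' cables.
#'
#' @param p a [RadiusProfile-class].
#' @param params a [PassiveParams-class].
#' @param injSites injection sites (um); defaults to the quartiles of L.
#' @param iApp injected current (nA).
#' @param n grid size for both solutions.
#' @return data.frame with one row per site: \code{injX},
#'   \code{maxRelError}, \code{meanRelError} (relative to the peak
#'   numerical voltage), \code{inputResistanceNum},
#'   \code{inputResistanceApprox} (MOhm).  The median slow-taper epsilon
#'   of the profile is attached as attribute \code{"medianEpsilon"}.
#' @export
compareVoltages <- function(p, params, injSites = NULL, iApp = 1, n = NULL) {
  stopifnot(is(p, "RadiusProfile"), is(params, "PassiveParams"))
  L <- cableLength(p)
  if (is.null(injSites) || !length(injSites))
    injSites <- L * c(0.25, 0.5, 0.75)
  if (is.null(n)) n <- .defaultGridSize(p, params)
  ep <- electrotonicProfile(p, params, n = n)
  rows <- lapply(injSites, function(xi) {
    num <- solveSteady(p, params, injX = xi, iApp = iApp, n = n)
    xs <- num@injectionSite            # snapped site, shared by both
    ana <- voltageApprox(ep, greensCoefficients(ep, xs, iApp))
    scale <- max(abs(num@v))
    err <- abs(ana@v - num@v) / scale
    jj <- which.min(abs(ep@x - xs))
    data.frame(injX = xs, maxRelError = max(err), meanRelError = mean(err),
               inputResistanceNum = num@v[jj] / iApp,
               inputResistanceApprox = inputResistanceApprox(ep, xs))
  })
  out <- do.call(rbind, rows)
  attr(out, "medianEpsilon") <- medianEpsilon(estimateEpsilon(p, params))
  out
}
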