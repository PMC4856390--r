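# The variational optimum for current transfer: quadratic profile
# construction, alpha fitting, the transfer functional J, Euler-Lagrange
# residual diagnostics and volume-preserving perturbations.

#' Fit the quadratic taper coefficient to a target volume
#'
#' Solves \eqn{\pi (\alpha^2 L^5/5 + 2 \alpha r_L L^3/3 + r_L^2 L) = V}
#' for the positive root \eqn{\alpha} (a quadratic in \eqn{\alpha}, closed
#' form), so that the profile \eqn{r(x) = \alpha (L - x)^2 + r_L} has the
#' prescribed volume.  The cylinder of radius \eqn{r_L} is the
#' \eqn{\alpha = 0} floor: volumes below \eqn{\pi r_L^2 L} are infeasible.
#'
#' @param L cable length (um).
#' @param rL distal radius (um).
#' @param V target volume (um^3).
#' @return alpha (1/um).
#' @seealso [fitAlphaProximal()], [makeQuadraticCable()]
#' @export
fitAlphaVolume <- function(L, rL, V) {
  stopifnot(L > 0, rL > 0)
  floorV <- pi * rL^2 * L
  if (V < floorV * (1 - 1e-12))
    stop(sprintf("infeasible volume: V = %.6g < pi rL^2 L = %.6g", V, floorV))
  a <- pi * L^5 / 5
  b <- 2 * pi * rL * L^3 / 3
  cc <- floorV - V
  disc <- b^2 - 4 * a * cc
  max(0, (-b + sqrt(max(disc, 0))) / (2 * a))
}

#' Fit the quadratic taper coefficient to a proximal radius
#'
#' \eqn{\alpha = (r_0 - r_L)/L^2} so that \eqn{r(0) = r_0} exactly.
#'
#' @param L cable length (um).
#' @param rL distal radius (um).
#' @param r0 proximal radius (um), at least \code{rL}.
#' @return alpha (1/um).
#' @export
fitAlphaProximal <- function(L, rL, r0) {
  stopifnot(L > 0, rL > 0)
  if (r0 < rL) stop("infeasible: proximal radius below distal radius")
  (r0 - rL) / L^2
}

#' Taper coefficient of the unconstrained stationary profile
#'
#' The reduced Euler-Lagrange equation fixes the electrotonic-length slope
#' at \eqn{d\lambda/dx = -2/7}; through \eqn{\lambda =
#' \sqrt{r/(2 r_a g_l)}} this pins the quadratic coefficient to
#' \eqn{\alpha = 8 r_a g_l / 49} (in 1/cm; returned in 1/um).  In
#' practice \eqn{\alpha} is fitted to the volume or proximal radius of the
#' cable at hand; this value marks the profile at which the
#' reflection-free functional is exactly stationary.
#'
#' @param params a [PassiveParams-class].
#' @return alpha (1/um).
#' @export
alphaStationary <- function(params) {
  stopifnot(is(params, "PassiveParams"))
  (8 * params@ra * params@gl / 49) / .UM_PER_CM
}

#' Current-transfer functional J of a radius profile
#'
#' The summed current transfer to the proximal end from unit currents
#' injected at every site, at leading order.  The Euler-Lagrange analysis
#' works with the integrand \eqn{\lambda^{-7/2}(x') e^{-\Lambda(x')}},
#' absorbing all proximal-boundary factors into a constant: profiles are
#' compared as seen by a common downstream (somatic) load.  Making that
#' constant explicit, the functional evaluated here is the dimensionless
#' shape form
#' \deqn{J = \int_0^L \Big(\frac{\lambda(0)}{\lambda(x')}\Big)^{7/2}
#'   e^{-\Lambda(x')}\, dx'}
#' which is, at leading order, proportional to the total current delivered
#' into a fixed proximal load (compare
#' [transferFunctionalNumeric()] with a fixed \code{loadRadius}).  With
#' \code{anchor = "none"} the bare integrand
#' \eqn{\lambda^{-7/2} e^{-\Lambda}} is integrated instead (only
#' meaningful for comparisons at fixed proximal radius).  With
#' \code{includeReflection = TRUE} the integrand carries the sealed-end
#' reflection term \eqn{[e^{-\Lambda} + C_2 e^{\Lambda}]} with
#' \eqn{C_2 = \frac{2 - \lambda'(L)}{2 + \lambda'(L)} e^{-2 \Lambda(L)}};
#' the optimality analysis neglects this contribution as vanishingly
#' small away from the distal end.
#'
#' @param p a [RadiusProfile-class].
#' @param params a [PassiveParams-class].
#' @param includeReflection include the distal reflection term.
#' @param anchor \code{"proximal"} (default) or \code{"none"}, see above.
#' @param n quadrature grid size.
#' @return scalar J (um for \code{anchor = "proximal"}, cm^(-5/2)
#'   otherwise); comparable across profiles at fixed passive parameters.
#' @export
transferFunctionalJ <- function(p, params, includeReflection = FALSE,
                                anchor = c("proximal", "none"),
                                n = 2001L) {
  anchor <- match.arg(anchor)
  ep <- electrotonicProfile(p, params, n = n)
  lam_cm <- ep@lambda / .UM_PER_CM
  x <- if (anchor == "proximal") ep@x else ep@x / .UM_PER_CM
  pref <- if (anchor == "proximal") lam_cm[1L]^(7 / 2) else 1
  integrand <- pref * lam_cm^(-7 / 2) * exp(-ep@Lambda)
  if (includeReflection) {
    lpL <- .lambdaPrimeAtL(ep)
    C2 <- (2 - lpL) / (2 + lpL) * exp(-2 * ep@Lambda[length(ep@Lambda)])
    integrand <- integrand + pref * lam_cm^(-7 / 2) * C2 * exp(ep@Lambda)
  }
  pracma::trapz(x, integrand)
}

#' Numerically exact transfer integral via the cable oracle
#'
#' The same objective evaluated without any asymptotic approximation:
#' \eqn{\int_0^L G(0, x')\, dx'}, computed through reciprocity
#' (\eqn{G(0, x') = G(x', 0)}) as a single steady solve with injection at
#' the proximal end followed by quadrature of the voltage.
#'
#' @param p a [RadiusProfile-class].
#' @param params a [PassiveParams-class].
#' @param bcProximal proximal boundary condition label.
#' @param n grid size.
#' @param loadRadius fixed proximal collar radius (um); when comparing
#'   candidate profiles for transfer optimality this must be held fixed
#'   across candidates (e.g. the equal-volume cylinder radius), otherwise
#'   the functional degenerates towards thin proximal ends that decouple
#'   the cable from its own load.
#' @return scalar, mV um per nA.
#' @export
transferFunctionalNumeric <- function(p, params,
                                      bcProximal = "matched_infinite",
                                      n = NULL, loadRadius = NULL) {
  sol <- solveSteady(p, params, injX = 0, iApp = 1,
                     bcProximal = bcProximal, bcDistal = "sealed", n = n,
                     loadRadius = loadRadius)
  pracma::trapz(sol@x, sol@v)
}

#' Summed current-transfer (ratio) functional
#'
#' The total of the current-transfer ratios from all sites to the
#' proximal end,
#' \deqn{T = \int_0^L \frac{v(0, x')}{v(x', x')}\, dx'
#'        = \int_0^L \sqrt{\lambda(0)/\lambda(x')}\, e^{-\Lambda(x')} dx'}
#' at leading order.  Unlike the raw voltage functional
#' ([transferFunctionalJ()]), the integrand is bounded by 1, so the
#' functional has a genuine interior optimum under fixed volume and
#' distal radius — attained by a quadratic taper (see
#' [makeStationaryTaper()]).  This is the quantity summarised across
#' morphologies by transfer maps ([transferMap()]).
#'
#' @param p a [RadiusProfile-class].
#' @param params a [PassiveParams-class].
#' @param n quadrature grid size.
#' @return scalar T (um; T/L is the mean transfer ratio).
#' @export
transferRatioFunctional <- function(p, params, n = 2001L) {
  ep <- electrotonicProfile(p, params, n = n)
  pracma::trapz(ep@x, sqrt(ep@lambda[1L] / ep@lambda) * exp(-ep@Lambda))
}

#' Numerically exact summed transfer ratio via the cable oracle
#'
#' \eqn{\int_0^L G(0, x')/G(x', x')\, dx'} from the finite-difference
#' Green's matrix, without asymptotic approximation.
#'
#' @inheritParams transferFunctionalNumeric
#' @return scalar (um).
#' @export
transferRatioNumeric <- function(p, params,
                                 bcProximal = "matched_infinite",
                                 n = NULL, loadRadius = NULL) {
  gm <- greensMatrix(p, params, bcProximal = bcProximal,
                     bcDistal = "sealed", n = n, loadRadius = loadRadius)
  G <- gm@G
  pracma::trapz(gm@x, G[1L, ] / diag(G))
}

#' Stationary taper of the summed-transfer functional
#'
#' Constructs the radius profile whose electrotonic length falls linearly
#' towards the distal end, \eqn{\lambda(x) = s (L + \delta - x)}, i.e.
#' \eqn{r(x) = 2 r_a g_l s^2 (L + \delta - x)^2}: a quadratic taper with
#' a small distal overhang \eqn{\delta} setting the terminal radius
#' \eqn{r_L = 2 r_a g_l s^2 \delta^2 > 0}.  With \code{slope = 2/9} this
#' is the profile at which the volume-constrained summed-transfer
#' functional [transferRatioFunctional()] is stationary (Euler-Lagrange
#' equation with the volume multiplier); the unconstrained voltage
#' functional's stationary slope is 2/7 ([alphaStationary()]).
#'
#' @param L cable length (um).
#' @param params a [PassiveParams-class].
#' @param overhang distal overhang delta (um); sets the distal radius.
#' @param slope electrotonic-length slope s (dimensionless).
#' @param nPoints number of sample points.
#' @return A [RadiusProfile-class].
#' @export
makeStationaryTaper <- function(L, params, overhang = 0.05 * L,
                                slope = 2 / 9, nPoints = 2001L) {
  stopifnot(is(params, "PassiveParams"), L > 0, overhang > 0, slope > 0)
  x <- seq(0, L, length.out = as.integer(nPoints))
  lam_cm <- slope * (L + overhang - x) / .UM_PER_CM
  r_um <- 2 * params@ra * params@gl * lam_cm^2 * .UM_PER_CM
  radiusProfile(x, r_um)
}

#' Reduced Euler-Lagrange residual of a profile
#'
#' With the distal reflection term neglected, stationarity of J reduces to
#' \eqn{d\lambda/dx = -2/7}; the per-position residual reported is
#' \deqn{\lambda'(x) + 2/7.}
#' A cylinder (\eqn{\lambda' = 0}) has residual identically 2/7; the
#' stationary quadratic taper (alpha of [alphaStationary()], small
#' \eqn{r_L}) has residual ~ 0 in the interior.  \eqn{\lambda'} is taken
#' by central differences on the uniform grid, matching the quadrature
#' scheme of [transferFunctionalJ()] so that residuals are not dominated
#' by scheme mismatch.
#'
#' @param p a [RadiusProfile-class].
#' @param params a [PassiveParams-class].
#' @param n grid size.
#' @return data.frame with columns \code{x} (um) and \code{residual}
#'   (dimensionless).
#' @export
eulerLagrangeResidual <- function(p, params, n = 2001L) {
  ep <- electrotonicProfile(p, params, n = n)
  data.frame(x = ep@x, residual = ep@lambdaPrime + 2 / 7)
}

#' Volume-preserving random perturbation of a profile
#'
#' Adds a smooth random bump to the radius profile while keeping both
#' terminal radii \eqn{r(0)} and \eqn{r(L)} fixed exactly (the
#' constraint set of the variational problem) and restoring the total
#' volume exactly (closed-form solution of the quadratic volume equation
#' for the compensating component).  Used to probe local optimality of
#' the quadratic taper.
#'
#' @param p a [RadiusProfile-class].
#' @param amplitude relative bump amplitude (fraction of the mean radius).
#' @param seed integer seed; deterministic per seed.
#' @param n resampling grid size.
#' @return A [RadiusProfile-class] with the same grid, length and volume.
#' @export
perturbVolumePreserving <- function(p, amplitude, seed = 1L, n = 1001L) {
  stopifnot(is(p, "RadiusProfile"), amplitude >= 0)
  pu <- resampleProfile(p, n)
  if (amplitude == 0) return(pu)
  x <- pu@x; r <- pu@r
  L <- x[length(x)]
  rbar <- mean(r)
  draw <- .withSeed(seed, list(u = stats::runif(1, 0.05 * L, 0.95 * L),
                               s = stats::runif(1, L / 20, L / 8),
                               sgn = sample(c(-1, 1), 1)))
  mask <- sin(pi * x / L)^2           # pins both terminal radii
  bump <- exp(-(x - draw$u)^2 / (2 * draw$s^2)) * mask
  comp <- mask                        # volume-restoring direction
  p0 <- r + draw$sgn * amplitude * rbar * bump
  # solve for mu in integral((p0 - mu*comp)^2) = integral(r^2), smallest root
  a2 <- pracma::trapz(x, comp^2)
  b1 <- pracma::trapz(x, p0 * comp)
  c0 <- pracma::trapz(x, p0^2) - pracma::trapz(x, r^2)
  disc <- b1^2 - a2 * c0
  if (disc < 0) stop("cannot restore volume for this perturbation amplitude")
  roots <- c((b1 - sqrt(disc)) / a2, (b1 + sqrt(disc)) / a2)
  mu <- roots[which.min(abs(roots))]
  rnew <- p0 - mu * comp
  if (any(rnew <= 0))
    stop("perturbation amplitude too large: radii would become non-positive")
  radiusProfile(x, rnew)
}
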