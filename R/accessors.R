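# Accessors and show() methods for the core classes.

#' @rdname RadiusProfile-class
#' @param object,p a \code{RadiusProfile}
#' @export
setGeneric("profileX", function(p) standardGeneric("profileX"))
#' @rdname RadiusProfile-class
#' @export
setMethod("profileX", "RadiusProfile", function(p) p@x)

#' @rdname RadiusProfile-class
#' @export
setGeneric("profileRadius", function(p) standardGeneric("profileRadius"))
#' @rdname RadiusProfile-class
#' @export
setMethod("profileRadius", "RadiusProfile", function(p) p@r)

#' Total arclength of a profile
#' @param p a [RadiusProfile-class]
#' @return length L in um.
#' @export
setGeneric("cableLength", function(p) standardGeneric("cableLength"))
#' @rdname cableLength
#' @export
setMethod("cableLength", "RadiusProfile", function(p) p@x[length(p@x)])

#' Volume enclosed by a profile or tree
#'
#' For a [RadiusProfile-class] the volume of the solid of revolution
#' \eqn{\pi \int r^2(x) dx} by trapezoidal quadrature of the sampled
#' profile; for a [TreeMorphology-class] the sum of the frustum volumes of
#' all parent-child edges, \eqn{\pi l (r_1^2 + r_1 r_2 + r_2^2)/3}.
#'
#' @param x a [RadiusProfile-class] or [TreeMorphology-class]
#' @return volume in um^3.
#' @export
setGeneric("cableVolume", function(x) standardGeneric("cableVolume"))
#' @rdname cableVolume
#' @export
setMethod("cableVolume", "RadiusProfile", function(x)
  pi * pracma::trapz(x@x, x@r^2))
#' @rdname cableVolume
#' @export
setMethod("cableVolume", "TreeMorphology", function(x) {
  nd <- x@nodes
  idx <- match(nd$parent, nd$id)
  child <- which(!is.na(idx))
  par <- idx[child]
  len <- sqrt((nd$x[child] - nd$x[par])^2 + (nd$y[child] - nd$y[par])^2 +
              (nd$z[child] - nd$z[par])^2)
  r1 <- nd$radius[par]; r2 <- nd$radius[child]
  sum(pi * len * (r1^2 + r1 * r2 + r2^2) / 3)
})

#' @rdname TreeMorphology-class
#' @param tree a \code{TreeMorphology}
#' @export
setGeneric("treeNodes", function(tree) standardGeneric("treeNodes"))
#' @rdname TreeMorphology-class
#' @export
setMethod("treeNodes", "TreeMorphology", function(tree) tree@nodes)

#' @rdname OptimalTree-class
#' @param tree an \code{OptimalTree}
#' @export
setGeneric("provenance", function(tree) standardGeneric("provenance"))
#' @rdname OptimalTree-class
#' @export
setMethod("provenance", "OptimalTree", function(tree) tree@provenance)

#' @rdname VoltageSolution-class
#' @param sol a \code{VoltageSolution}
#' @export
setGeneric("voltage", function(sol) standardGeneric("voltage"))
#' @rdname VoltageSolution-class
#' @export
setMethod("voltage", "VoltageSolution", function(sol) sol@v)

#' @rdname VoltageSolution-class
#' @export
setGeneric("solutionGrid", function(sol) standardGeneric("solutionGrid"))
#' @rdname VoltageSolution-class
#' @export
setMethod("solutionGrid", "VoltageSolution", function(sol) sol@x)

#' @rdname GreensMatrix-class
#' @param gm a \code{GreensMatrix}
#' @export
setGeneric("greensValues", function(gm) standardGeneric("greensValues"))
#' @rdname GreensMatrix-class
#' @export
setMethod("greensValues", "GreensMatrix", function(gm) gm@G)

#' @rdname SegmentedCable-class
#' @param sc a \code{SegmentedCable}
#' @export
setGeneric("segmentRadii", function(sc) standardGeneric("segmentRadii"))
#' @rdname SegmentedCable-class
#' @export
setMethod("segmentRadii", "SegmentedCable", function(sc) sc@radii)

#' @rdname EpsilonReport-class
#' @param er an \code{EpsilonReport}
#' @export
setGeneric("epsilonValues", function(er) standardGeneric("epsilonValues"))
#' @rdname EpsilonReport-class
#' @export
setMethod("epsilonValues", "EpsilonReport", function(er) er@epsilon)

#' @rdname EpsilonReport-class
#' @export
setGeneric("epsilonQuantiles", function(er) standardGeneric("epsilonQuantiles"))
#' @rdname EpsilonReport-class
#' @export
setMethod("epsilonQuantiles", "EpsilonReport", function(er) er@quantiles)

#' Median of the local slow-taper parameter
#' @param er an [EpsilonReport-class]
#' @return median epsilon (dimensionless).
#' @export
medianEpsilon <- function(er) unname(er@quantiles["50%"])

setMethod("show", "RadiusProfile", function(object) {
  cat(sprintf("RadiusProfile: %d samples, L = %.6g um, r in [%.4g, %.4g] um\n",
              length(object@x), cableLength(object),
              min(object@r), max(object@r)))
})

setMethod("show", "PassiveParams", function(object) {
  cat(sprintf(
    "PassiveParams: ra = %g Ohm cm, gl = %g S/cm^2, tau = %g ms\n",
    object@ra, object@gl, object@tau))
})

setMethod("show", "TreeMorphology", function(object) {
  nd <- object@nodes
  nb <- sum(tabulate(match(nd$parent, nd$id)) >= 2L)
  cat(sprintf("TreeMorphology: %d nodes, %d branch points, volume %.5g um^3\n",
              nrow(nd), nb, cableVolume(object)))
})

setMethod("show", "OptimalTree", function(object) {
  callNextMethod()
  pv <- object@provenance
  if (length(pv))
    cat(sprintf("  optimal taper: r_L = %.4g um, r_proximal = %.5g um, volume ratio = %.6g\n",
                pv$rL, pv$rProximal, pv$volumeRatio))
})

setMethod("show", "VoltageSolution", function(object) {
  cat(sprintf(
    "VoltageSolution: %d points, injection %.4g nA at x' = %.4g um, v(0) = %.5g mV, max v = %.5g mV [%s|%s]\n",
    length(object@x), object@iApp, object@injectionSite,
    object@v[1L], max(object@v), object@bcProximal, object@bcDistal))
})

setMethod("show", "ElectrotonicProfile", function(object) {
  cat(sprintf(
    "ElectrotonicProfile: %d points, lambda in [%.5g, %.5g] um, total electrotonic length %.4g\n",
    length(object@x), min(object@lambda), max(object@lambda),
    object@Lambda[length(object@Lambda)]))
})

setMethod("show", "GreensCoefficients", function(object) {
  cat(sprintf(
    "GreensCoefficients at x' = %.4g um: B1 = %.5g mV, A2 = %.5g, B2 = %.5g, k = %.4g\n",
    object@injX, object@B1, object@A2, object@B2, object@k))
})

setMethod("show", "GreensMatrix", function(object) {
  cat(sprintf("GreensMatrix: %d x %d, input resistance %.5g-%.5g MOhm [%s|%s]\n",
              nrow(object@G), ncol(object@G), min(diag(object@G)),
              max(diag(object@G)), object@bcProximal, object@bcDistal))
})

setMethod("show", "SegmentedCable", function(object) {
  cat(sprintf("SegmentedCable: %d segments over L = %.4g um, objective %.6g\n",
              length(object@radii), object@L, object@objective))
  cat("  radii (um):", paste(sprintf("%.4g", object@radii), collapse = " "),
      "\n")
})

setMethod("show", "EpsilonReport", function(object) {
  q <- object@quantiles
  cat(sprintf("EpsilonReport: median %.4g (IQR %.4g-%.4g)\n",
              q[["50%"]], q[["25%"]], q[["75%"]]))
})
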