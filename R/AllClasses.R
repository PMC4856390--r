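#' @import methods
NULL

# micrometre <-> centimetre conversion used wherever radii (um) meet the
# passive parameters r_a (Ohm cm) and g_l (S/cm^2)
.UM_PER_CM <- 1e4

#' Sampled radius profile of an unbranched cable
#'
#' A \code{RadiusProfile} stores the taper \eqn{r(x)} of a single unbranched
#' stretch of dendrite as a table of arclength positions and radii, proximal
#' end at \eqn{x = 0}.  Radii (not diameters) are stored throughout; SWC
#' column six is likewise a radius.
#'
#' @slot x numeric, strictly increasing arclength positions in micrometres,
#'   with \code{x[1] == 0}.
#' @slot r numeric, strictly positive radii in micrometres, one per position.
#'
#' @seealso [radiusProfile()], [resampleProfile()], [makeQuadraticCable()]
#' @exportClass RadiusProfile
setClass("RadiusProfile",
  representation(x = "numeric", r = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@x) != length(object@r))
      msg <- c(msg, "x and r must have equal length")
    if (length(object@x) < 2L)
      msg <- c(msg, "a profile needs at least 2 sample points")
    if (length(object@x) >= 1L && !isTRUE(all.equal(object@x[1L], 0)))
      msg <- c(msg, "x must start at 0 (proximal end)")
    if (any(!is.finite(object@x)) || any(!is.finite(object@r)))
      msg <- c(msg, "x and r must be finite")
    else {
      if (any(diff(object@x) <= 0))
        msg <- c(msg, "x must be strictly increasing")
      if (any(object@r <= 0))
        msg <- c(msg, "all radii must be strictly positive")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a RadiusProfile
#'
#' @param x arclength positions (um), strictly increasing, first element 0.
#' @param r radii (um), strictly positive.
#' @return A [RadiusProfile-class] object.
#' @examples
#' p <- radiusProfile(c(0, 50, 100), c(2, 1.5, 1))
#' cableLength(p)
#' @export
radiusProfile <- function(x, r)
  new("RadiusProfile", x = as.numeric(x), r = as.numeric(r))

#' Passive membrane and axial parameters
#'
#' Holds the three constants of the passive cable equation: axial
#' resistivity \code{ra} (Ohm cm), specific membrane (leak) conductance
#' \code{gl} (S/cm^2) and membrane time constant \code{tau} (ms).
#'
#' @slot ra numeric(1), axial resistivity in Ohm cm.
#' @slot gl numeric(1), membrane conductance in S/cm^2.
#' @slot tau numeric(1), membrane time constant in ms.
#' @exportClass PassiveParams
setClass("PassiveParams",
  representation(ra = "numeric", gl = "numeric", tau = "numeric"),
  validity = function(object) {
    if (length(object@ra) != 1L || length(object@gl) != 1L ||
        length(object@tau) != 1L)
      return("ra, gl and tau must each be a single number")
    if (!all(is.finite(c(object@ra, object@gl, object@tau))) ||
        any(c(object@ra, object@gl, object@tau) <= 0))
      return("ra, gl and tau must be finite and strictly positive")
    TRUE
  })

#' Construct passive parameters
#'
#' @param ra axial resistivity (Ohm cm).
#' @param gl specific membrane conductance (S/cm^2).
#' @param tau membrane time constant (ms); only the transient solver uses it.
#' @return A [PassiveParams-class] object.
#' @examples
#' passiveParams(60, 5e-4)          # blowfly HS/VS values
#' passiveParams(210, 4e-5)         # dentate gyrus granule cell values
#' @export
passiveParams <- function(ra, gl, tau = 20)
  new("PassiveParams", ra = as.numeric(ra), gl = as.numeric(gl),
      tau = as.numeric(tau))

#' Named passive parameter presets
#'
#' Passive parameter sets for the five cell classes commonly used with this
#' method: blowfly HS and VS tangential cells (ra = 60 Ohm cm,
#' gl = 5e-4 S/cm^2), mouse dentate gyrus granule cells (210, 4e-5), rat
#' cerebellar Purkinje cells and rat neocortical layer-5 pyramidal cells
#' (both 150, 5e-5).
#'
#' @param class one of \code{"fly_hs"}, \code{"fly_vs"}, \code{"granule"},
#'   \code{"purkinje"}, \code{"layer5"}.
#' @return A [PassiveParams-class] object.
#' @export
passivePresets <- function(class = c("fly_hs", "fly_vs", "granule",
                                     "purkinje", "layer5")) {
  class <- match.arg(class)
  switch(class,
    fly_hs   = passiveParams(60, 5e-4),
    fly_vs   = passiveParams(60, 5e-4),
    granule  = passiveParams(210, 4e-5),
    purkinje = passiveParams(150, 5e-5),
    layer5   = passiveParams(150, 5e-5))
}

#' Rooted tree morphology (SWC-style)
#'
#' Stores a neuronal morphology as a node table in the 7-column SWC
#' convention: integer id, integer type code, x/y/z coordinates (um), radius
#' (um) and parent id (NA for the single root).  Type codes are preserved
#' but never interpreted; the analysis is type-agnostic.  The root is
#' treated as the soma and defines \eqn{x = 0} for all profiles extracted
#' from the tree.
#'
#' @slot nodes data.frame with columns \code{id}, \code{type}, \code{x},
#'   \code{y}, \code{z}, \code{radius}, \code{parent}.
#' @seealso [readSWC()], [writeSWC()], [pathToProfile()], [makeRandomTree()]
#' @exportClass TreeMorphology
setClass("TreeMorphology",
  representation(nodes = "data.frame"),
  validity = function(object) .validateTreeNodes(object@nodes))

.validateTreeNodes <- function(nd) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nd)))
    return(paste("nodes must have columns", paste(req, collapse = ", ")))
  if (nrow(nd) < 1L) return("tree must have at least one node")
  if (anyDuplicated(nd$id)) return("duplicate node ids")
  roots <- which(is.na(nd$parent))
  if (length(roots) != 1L)
    return(sprintf("tree must have exactly one root (found %d)",
                   length(roots)))
  nonroot <- nd$parent[!is.na(nd$parent)]
  if (!all(nonroot %in% nd$id))
    return("parent ids reference missing nodes")
  if (any(!is.finite(nd$x)) || any(!is.finite(nd$y)) || any(!is.finite(nd$z)))
    return("coordinates must be finite")
  if (any(!is.finite(nd$radius)) || any(nd$radius <= 0))
    return("all radii must be finite and strictly positive")
  # acyclic and connected: every node must reach the root by parent pointers
  idx <- match(nd$parent, nd$id)
  n <- nrow(nd)
  depth <- rep.int(NA_integer_, n)
  depth[roots] <- 0L
  pending <- TRUE
  for (pass in seq_len(n)) {
    newly <- which(is.na(depth) & !is.na(depth[idx]))
    if (!length(newly)) break
    depth[newly] <- depth[idx[newly]] + 1L
  }
  if (anyNA(depth)) return("tree contains a cycle or disconnected nodes")
  TRUE
}

#' Construct a TreeMorphology from a node table
#'
#' @param nodes data.frame with SWC columns \code{id}, \code{type},
#'   \code{x}, \code{y}, \code{z}, \code{radius}, \code{parent} (parent of
#'   the root is \code{NA}).
#' @return A [TreeMorphology-class] object.
#' @export
treeMorphology <- function(nodes) {
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  rownames(nodes) <- NULL
  new("TreeMorphology", nodes = nodes)
}

#' Optimal-taper tree with provenance
#'
#' A [TreeMorphology-class] whose radii were re-assigned by
#' [distributeRadii()] / [matchVolume()], carrying the construction record:
#' the distal radius floor, the final proximal radius, the achieved
#' volume ratio, iteration count, and the per-branch Rall 3/2 residuals.
#'
#' @slot provenance named list of construction metadata.
#' @exportClass OptimalTree
setClass("OptimalTree", contains = "TreeMorphology",
  representation(provenance = "list"))

#' Steady-state voltage along a cable
#'
#' @slot x grid positions (um).
#' @slot v voltage above rest (mV) at each grid position.
#' @slot injectionSite injection position (um), possibly snapped to the grid.
#' @slot iApp injected current (nA).
#' @slot bcProximal,bcDistal boundary condition labels.
#' @exportClass VoltageSolution
setClass("VoltageSolution",
  representation(x = "numeric", v = "numeric", injectionSite = "numeric",
                 iApp = "numeric", bcProximal = "character",
                 bcDistal = "character"),
  validity = function(object) {
    if (length(object@x) != length(object@v))
      return("x and v must have equal length")
    if (any(!is.finite(object@v)))
      return("voltage must be finite everywhere")
    TRUE
  })

#' Electrotonic structure of a tapering cable
#'
#' Carries the local electrotonic length \eqn{\lambda(x) =
#' \sqrt{r(x)/(2 r_a g_l)}}, the cumulative electrotonic distance
#' \eqn{\Lambda(x) = \int_0^x 1/\lambda(s)\,ds} and the (dimensionless)
#' derivative \eqn{\lambda'(x)} on a uniform grid.
#'
#' @slot x uniform grid (um).
#' @slot r radii on the grid (um).
#' @slot lambda local electrotonic length (um).
#' @slot Lambda cumulative electrotonic distance (dimensionless).
#' @slot lambdaPrime derivative of lambda with respect to x (dimensionless).
#' @slot params the [PassiveParams-class] used.
#' @exportClass ElectrotonicProfile
setClass("ElectrotonicProfile",
  representation(x = "numeric", r = "numeric", lambda = "numeric",
                 Lambda = "numeric", lambdaPrime = "numeric",
                 params = "PassiveParams"),
  validity = function(object) {
    if (any(object@lambda <= 0)) return("lambda must be positive")
    if (object@Lambda[1L] != 0 || any(diff(object@Lambda) < 0))
      return("Lambda must be non-decreasing with Lambda(0) = 0")
    TRUE
  })

#' First-order Green's function coefficients for point current injection
#'
#' Amplitudes of the two-sided first-order solution around an injection at
#' \eqn{x'}: proximal branch \eqn{v(x) = \sqrt{\lambda(x)/\lambda(x')}\,
#' B_1 e^{-(\Lambda(x') - \Lambda(x))}}, distal branch
#' \eqn{v(x) = \sqrt{\lambda(x)/\lambda(x')}\,[A_2 e^{\Lambda(x)-\Lambda(x')}
#' + B_2 e^{-(\Lambda(x)-\Lambda(x'))}]}.  With this anchoring \eqn{B_1}
#' is the input resistance at \eqn{x'} times the injected current (mV for
#' current in nA), and the constants reproduce the classical cylinder
#' solution exactly.
#'
#' @slot A2,B1,B2 amplitudes (mV).
#' @slot k distal (sealed-end) reflection ratio, dimensionless.
#' @slot injX injection site (um).
#' @slot iApp injected current (nA).
#' @exportClass GreensCoefficients
setClass("GreensCoefficients",
  representation(A2 = "numeric", B1 = "numeric", B2 = "numeric",
                 k = "numeric", injX = "numeric", iApp = "numeric"),
  validity = function(object) {
    if (object@iApp > 0 && object@B1 <= 0)
      return("B1 must be positive for positive injected current")
    TRUE
  })

#' Steady-state Green's matrix of a discretised cable
#'
#' @slot G square matrix, \code{G[i, j]} = voltage (mV) at \code{x[i]} per
#'   unit current (nA) at \code{x[j]}; units MOhm.
#' @slot x grid (um).
#' @slot bcProximal,bcDistal boundary labels.
#' @exportClass GreensMatrix
setClass("GreensMatrix",
  representation(G = "matrix", x = "numeric", bcProximal = "character",
                 bcDistal = "character"),
  validity = function(object) {
    if (nrow(object@G) != ncol(object@G)) return("G must be square")
    if (nrow(object@G) != length(object@x)) return("G and x sizes differ")
    TRUE
  })

#' Piecewise-constant segmented cable (numerical optimisation result)
#'
#' @slot radii segment radii, proximal to distal (um).
#' @slot L total length (um).
#' @slot volume total volume (um^3).
#' @slot objective value of the current-transfer objective at these radii.
#' @slot report list with optimisation details (restarts, convergence).
#' @exportClass SegmentedCable
setClass("SegmentedCable",
  representation(radii = "numeric", L = "numeric", volume = "numeric",
                 objective = "numeric", report = "list"),
  validity = function(object) {
    if (any(object@radii <= 0)) return("segment radii must be positive")
    TRUE
  })

#' Local slow-taper parameter report
#'
#' Per-position estimate of the multiple-scales small parameter
#' \eqn{\epsilon(x) = \lambda(x) |r'(x)| / r(x)} (electrotonic length over
#' the radius e-fold length) together with summary quantiles.
#'
#' @slot x grid (um).
#' @slot epsilon per-position epsilon, non-negative.
#' @slot quantiles named numeric of summary quantiles.
#' @exportClass EpsilonReport
setClass("EpsilonReport",
  representation(x = "numeric", epsilon = "numeric", quantiles = "numeric"),
  validity = function(object) {
    if (any(object@epsilon < 0)) return("epsilon must be non-negative")
    TRUE
  })
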