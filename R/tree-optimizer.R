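# Mapping the optimal quadratic taper onto branched morphologies:
# apparent lengths, Rall 3/2 radius distribution, volume matching, and
# current-transfer maps across the tree.

# children indices and parent edge lengths, in node-table order
.treeTopology <- function(nd) {
  idx <- match(nd$parent, nd$id)
  elen <- sqrt((nd$x - nd$x[idx])^2 + (nd$y - nd$y[idx])^2 +
               (nd$z - nd$z[idx])^2)    # NA at root
  n <- nrow(nd)
  kids <- vector("list", n)
  for (i in seq_len(n)) if (!is.na(idx[i]))
    kids[[idx[i]]] <- c(kids[[idx[i]]], i)
  depth <- ifelse(is.na(idx), 0L, NA_integer_)
  repeat {
    todo <- which(is.na(depth) & !is.na(depth[idx]))
    if (!length(todo)) break
    depth[todo] <- depth[idx[todo]] + 1L
  }
  list(parentIdx = idx, edgeLen = elen, children = kids, depth = depth)
}

#' Apparent (Rall-equivalent) lengths of all subtrees
#'
#' For every node, the effective unbranched length of the subtree distal
#' to it: terminals have apparent length 0, along an unbranched stretch it
#' grows additively with arclength, and at a branch point daughter lengths
#' \eqn{l_1, l_2, \ldots} combine as
#' \deqn{l_0 = \big(\textstyle\sum_i l_i^{3/2}\big)^{2/3},}
#' so that two daughters appear to the parent as a single branch.  (The
#' binary rule extends to higher-order branch points by the same power
#' sum.)  Computed in a single post-order traversal.
#'
#' @param tree a [TreeMorphology-class].
#' @return named numeric vector, apparent length (um) per node id.
#' @export
apparentLengths <- function(tree) {
  stopifnot(is(tree, "TreeMorphology"))
  nd <- tree@nodes
  topo <- .treeTopology(nd)
  n <- nrow(nd)
  al <- numeric(n)
  for (i in order(topo$depth, decreasing = TRUE)) {
    ch <- topo$children[[i]]
    if (is.null(ch)) { al[i] <- 0; next }
    li <- topo$edgeLen[ch] + al[ch]
    al[i] <- if (length(li) == 1L) li else sum(li^1.5)^(2 / 3)
  }
  stats::setNames(al, nd$id)
}

# daughter start radii at a branch: parent radius r0, daughter apparent
# lengths li; ratio rule "literal" (r1:r2 = l1^{3/2}:l2^{3/2}) or "linear"
# (r1:r2 = l1:l2); both satisfy sum(ri^{3/2}) = r0^{3/2} exactly.
.daughterRadii <- function(r0, li, ratioRule) {
  w <- switch(ratioRule, literal = li^1.5, linear = li)
  if (all(w == 0)) w <- rep(1, length(li))
  r0 * w / sum(w^1.5)^(2 / 3)
}

#' Distribute optimal quadratic radii over a tree
#'
#' Step two of the optimal-equivalent-cable construction.  The radius
#' taper from the root follows \eqn{r(x) = \alpha (l_0 - x)^2 + r_L} with
#' \eqn{l_0} the apparent length of the whole tree,
#' \eqn{\alpha} fitted so the proximal radius is \code{rProximal}
#' ([fitAlphaProximal()]).  At every branch point the parent radius
#' \eqn{r_0} is already defined by construction; daughter start radii
#' satisfy Rall's 3/2 power relationship
#' \eqn{r_0^{3/2} = \sum_i r_i^{3/2}} with the split between daughters set
#' by their apparent lengths (\code{ratioRule = "literal"}:
#' \eqn{r_1 : r_2 = l_1^{3/2} : l_2^{3/2}}; \code{"linear"}:
#' \eqn{r_1 : r_2 = l_1 : l_2}).  Within each daughter the taper continues
#' quadratically with \eqn{L} equal to that daughter's apparent length.
#' All radii are floored at \code{rL}; floor events are counted in the
#' provenance.
#'
#' @param tree a [TreeMorphology-class].
#' @param rL distal radius floor (um); default: the minimal radius
#'   anywhere on the tree.
#' @param rProximal proximal (root) radius (um); default: the maximal
#'   radius of the input tree (the measured physiological maximum).
#' @param ratioRule \code{"literal"} or \code{"linear"} (see above).
#' @param al optional precomputed [apparentLengths()] vector.
#' @return An [OptimalTree-class] with re-assigned radii; provenance
#'   carries the per-branch Rall residuals.
#' @export
distributeRadii <- function(tree, rL = NULL, rProximal = NULL,
                            ratioRule = c("literal", "linear"), al = NULL) {
  stopifnot(is(tree, "TreeMorphology"))
  ratioRule <- match.arg(ratioRule)
  nd <- tree@nodes
  if (is.null(rL)) rL <- min(nd$radius)
  if (is.null(rProximal)) rProximal <- max(nd$radius)
  if (rProximal < rL) stop("rProximal must be at least rL")
  if (is.null(al)) al <- apparentLengths(tree)
  topo <- .treeTopology(nd)
  n <- nrow(nd)
  radius <- numeric(n)
  segAlpha <- numeric(n)   # quadratic coefficient of the segment at node
  segLrem <- numeric(n)    # remaining segment length at node
  floored <- 0L
  branchRows <- list()
  root <- which(is.na(topo$parentIdx))
  radius[root] <- rProximal
  segLrem[root] <- al[root]
  segAlpha[root] <- if (al[root] > 0) fitAlphaProximal(al[root], rL, rProximal) else 0
  evalSeg <- function(alpha, Lrem) {
    if (Lrem <= 0) return(rL)
    max(alpha * Lrem^2 + rL, rL)
  }
  for (i in order(topo$depth)) {
    ch <- topo$children[[i]]
    if (is.null(ch)) next
    if (length(ch) == 1L) {            # continuation of the current segment
      c1 <- ch
      Lr <- segLrem[i] - topo$edgeLen[c1]
      rc <- evalSeg(segAlpha[i], Lr)
      if (Lr <= 0) floored <- floored + 1L
      radius[c1] <- rc
      segAlpha[c1] <- segAlpha[i]
      segLrem[c1] <- Lr
    } else {                           # branch point: Rall split
      r0 <- radius[i]
      li <- topo$edgeLen[ch] + al[ch]
      r0d <- .daughterRadii(r0, li, ratioRule)
      branchRows[[length(branchRows) + 1L]] <- data.frame(
        id = nd$id[i], r0 = r0,
        residual = abs(sum(r0d^1.5) - r0^1.5) / r0^1.5)
      for (jj in seq_along(ch)) {
        c1 <- ch[jj]
        r0j <- r0d[jj]
        if (r0j < rL) { r0j <- rL; floored <- floored + 1L }
        aj <- if (li[jj] > 0) fitAlphaProximal(li[jj], rL, max(r0j, rL)) else 0
        Lr <- li[jj] - topo$edgeLen[c1]
        radius[c1] <- evalSeg(aj, Lr)
        segAlpha[c1] <- aj
        segLrem[c1] <- Lr
      }
    }
  }
  nd$radius <- radius
  branches <- if (length(branchRows)) do.call(rbind, branchRows)
              else data.frame(id = integer(), r0 = numeric(),
                              residual = numeric())
  new("OptimalTree", nodes = nd,
      provenance = list(rL = rL, rProximal = rProximal,
                        ratioRule = ratioRule, floored = floored,
                        branches = branches,
                        volumeRatio = cableVolume(treeMorphology(nd)) /
                                      cableVolume(tree),
                        iterations = 0L))
}

#' Maximum relative Rall 3/2 residual over all branch points
#' @param tree an [OptimalTree-class].
#' @return largest relative residual of \eqn{r_0^{3/2} = \sum r_i^{3/2}};
#'   0 for a tree without branch points.
#' @export
rallResidual <- function(tree) {
  stopifnot(is(tree, "OptimalTree"))
  br <- tree@provenance$branches
  if (!nrow(br)) return(0)
  max(br$residual)
}

#' Match the optimal tree's volume to the original morphology
#'
#' Step three of the construction: the proximal radius is scaled up or
#' down and the radius distribution repeated until the optimal tree's
#' volume matches the original tree's volume.  The volume is a monotone
#' function of the proximal radius, so a geometric bracket expansion
#' followed by bisection converges unconditionally.
#'
#' @inheritParams distributeRadii
#' @param tol relative volume tolerance (default 1e-3).
#' @param maxIter maximum bisection iterations.
#' @param rProximalInit starting proximal radius; default the maximal
#'   radius of the input tree.
#' @return An [OptimalTree-class] whose provenance records the final
#'   proximal radius, the volume ratio achieved and the iteration count.
#' @export
matchVolume <- function(tree, rL = NULL, ratioRule = c("literal", "linear"),
                        tol = 1e-3, maxIter = 100L, rProximalInit = NULL) {
  stopifnot(is(tree, "TreeMorphology"))
  ratioRule <- match.arg(ratioRule)
  nd <- tree@nodes
  if (is.null(rL)) rL <- min(nd$radius)
  if (is.null(rProximalInit)) rProximalInit <- max(max(nd$radius), rL)
  al <- apparentLengths(tree)
  Vt <- cableVolume(tree)
  volAt <- function(rp) {
    ot <- distributeRadii(tree, rL = rL, rProximal = rp,
                          ratioRule = ratioRule, al = al)
    list(tree = ot, V = cableVolume(ot))
  }
  floorV <- volAt(rL)$V
  if (Vt < floorV * (1 - tol))
    stop(sprintf(
      "infeasible: target volume %.5g below the all-rL floor volume %.5g",
      Vt, floorV))
  it <- 0L
  cur <- volAt(rProximalInit); it <- it + 1L
  lo <- hi <- rProximalInit
  Vlo <- Vhi <- cur$V
  while (Vhi < Vt && it < maxIter) { hi <- hi * 2; cur <- volAt(hi)
    Vhi <- cur$V; it <- it + 1L }
  while (Vlo > Vt && lo > rL && it < maxIter) {
    lo <- max(rL, lo / 2); cur <- volAt(lo); Vlo <- cur$V; it <- it + 1L }
  best <- cur
  while (abs(best$V - Vt) / Vt >= tol && it < maxIter) {
    mid <- (lo + hi) / 2
    cur <- volAt(mid); it <- it + 1L
    if (cur$V < Vt) lo <- mid else hi <- mid
    best <- cur
  }
  if (abs(best$V - Vt) / Vt >= tol)
    warning("volume matching did not reach tolerance within maxIter")
  pv <- best$tree@provenance
  pv$volumeRatio <- best$V / Vt
  pv$iterations <- it
  new("OptimalTree", nodes = best$tree@nodes, provenance = pv)
}

#' Current transfer from every node to the root
#'
#' For each node \eqn{k}, the steady-state transfer ratio
#' \eqn{v_{root}/v_k} under unit current injection at \eqn{k}, computed
#' from the compartmental conductance matrix (the ratio of the Green's
#' matrix entries \eqn{G_{root,k} / G_{k,k}}; the matrix is symmetric, so
#' one dense factorisation serves all nodes).  The root itself has ratio
#' 1; passive attenuation keeps all ratios in (0, 1].
#'
#' @param tree a [TreeMorphology-class].
#' @param params a [PassiveParams-class].
#' @param somaConductance lumped root conductance (nS), default 0.
#' @return data.frame with \code{id}, \code{distance} (path length to the
#'   root, um) and \code{transfer}.
#' @export
transferMap <- function(tree, params, somaConductance = 0) {
  stopifnot(is(tree, "TreeMorphology"), is(params, "PassiveParams"))
  nd <- tree@nodes
  topo <- .treeTopology(nd)
  n <- nrow(nd)
  root <- which(is.na(topo$parentIdx))
  dist <- numeric(n)
  for (i in order(topo$depth))
    if (!is.na(topo$parentIdx[i]))
      dist[i] <- dist[topo$parentIdx[i]] + topo$edgeLen[i]
  if (n == 1L)
    return(data.frame(id = nd$id, distance = 0, transfer = 1))
  sys <- .treeSystem(tree, params, somaConductance)
  Ginv <- solve(sys$A)
  transfer <- Ginv[root, ] / diag(Ginv)
  data.frame(id = nd$id, distance = dist, transfer = transfer)
}

#' Equalisation ("dendritic democracy") index
#'
#' Coefficient of variation of the per-node transfer ratios to the root;
#' lower values mean somatic impact is more equal across injection sites.
#'
#' @inheritParams transferMap
#' @return scalar CV (0 for a single-node tree).
#' @export
equalisationIndex <- function(tree, params, somaConductance = 0) {
  tm <- transferMap(tree, params, somaConductance)
  if (nrow(tm) < 2L) return(0)
  stats::sd(tm$transfer) / mean(tm$transfer)
}
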