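# Conservative finite-difference solver for the generalised cable equation
# on tapering cables and branched trees: steady states, Green's matrices,
# Crank-Nicolson transients.
#
# All assembly is done in CGS-consistent units in ONE place (.assembleCable,
# .treeSystem): radii and arclengths in cm, conductances in S, currents in
# A, voltages in V.  External interfaces use um, nA, mV, MOhm.

.BC_LABELS <- c("sealed", "killed", "matched_infinite")

# Thomas algorithm for tridiagonal systems with one or many right-hand
# sides.  dl: subdiagonal (n-1), d: diagonal (n), du: superdiagonal (n-1).
.triSolve <- function(dl, d, du, b) {
  n <- length(d)
  B <- as.matrix(b)
  cp <- numeric(n - 1L)
  dp <- numeric(n)
  dp[1L] <- d[1L]
  cp[1L] <- du[1L] / dp[1L]
  B[1L, ] <- B[1L, ] / dp[1L]
  for (i in 2:n) {
    dp[i] <- d[i] - dl[i - 1L] * cp[i - 1L]
    if (dp[i] == 0) stop("singular tridiagonal system (degenerate radii?)")
    if (i < n) cp[i] <- du[i] / dp[i]
    B[i, ] <- (B[i, ] - dl[i - 1L] * B[i - 1L, ]) / dp[i]
  }
  for (i in (n - 1L):1L)
    B[i, ] <- B[i, ] - cp[i] * B[i + 1L, ]
  B
}

# Grid size rule: dx <= min(lambda)/200, at least 201 points, capped.
.defaultGridSize <- function(p, params, perLambda = 200, nMax = 20001L) {
  lamMin <- min(.lambdaUm(p@r, params))
  n <- ceiling(cableLength(p) / (lamMin / perLambda)) + 1L
  as.integer(min(max(n, 201L), nMax))
}

# Assemble the flux-form tridiagonal system A v = b (without source) for
# d/dx[r^2 dv/dx] - 2 ra gl r sqrt(1+r'^2) v = -(ra/pi) I delta(x - x').
# Returns grid, tridiagonal bands of A (A positive definite, symmetric),
# membrane weights and boundary conductance for balance checks.
.assembleCable <- function(p, params, bcProximal, bcDistal, n = NULL,
                           loadRadius = NULL) {
  bcProximal <- match.arg(bcProximal, .BC_LABELS)
  bcDistal <- match.arg(bcDistal, .BC_LABELS)
  if (is.null(n)) n <- .defaultGridSize(p, params)
  pu <- resampleProfile(p, n)
  x_um <- pu@x
  r <- pu@r / .UM_PER_CM                     # cm
  dx <- (x_um[2L] - x_um[1L]) / .UM_PER_CM   # cm
  rmid <- (r[-n] + r[-1L]) / 2
  q <- rmid^2                                # r^2 at interfaces
  rp <- pracma::gradient(r, dx)              # dimensionless slope
  slant <- sqrt(1 + rp^2)
  cmem <- 2 * params@ra * params@gl * r * slant   # membrane coefficient
  w <- rep(dx, n); w[c(1L, n)] <- dx / 2          # cell widths
  d <- cmem * w
  d[1L] <- d[1L] + q[1L] / dx
  d[2:(n - 1L)] <- d[2:(n - 1L)] + (q[-(n - 1L)] + q[-1L]) / dx
  d[n] <- d[n] + q[n - 1L] / dx
  off <- -q / dx
  gBndProx <- 0; gBndDist <- 0
  lam_cm <- .lambdaUm(pu@r, params) / .UM_PER_CM
  if (bcProximal == "matched_infinite") {
    # semi-infinite collar load; by default the collar continues the
    # profile's own proximal radius, but a fixed reference radius can be
    # imposed so that different candidate profiles see the same
    # downstream (somatic) load
    rl_cm <- if (is.null(loadRadius)) r[1L] else loadRadius / .UM_PER_CM
    laml_cm <- sqrt(rl_cm / (2 * params@ra * params@gl))
    gBndProx <- rl_cm^2 / laml_cm            # scaled semi-infinite load
    d[1L] <- d[1L] + gBndProx
  }
  if (bcDistal == "matched_infinite") {
    gBndDist <- r[n]^2 / lam_cm[n]
    d[n] <- d[n] + gBndDist
  }
  dirich <- logical(n)
  if (bcProximal == "killed") {
    dirich[1L] <- TRUE
    d[1L] <- 1; off[1L] <- 0
  }
  if (bcDistal == "killed") {
    dirich[n] <- TRUE
    d[n] <- 1; off[n - 1L] <- 0
  }
  list(x_um = x_um, r_cm = r, dx_cm = dx, dl = off, d = d, du = off,
       cmem = cmem, w = w, gBndProx = gBndProx, gBndDist = gBndDist,
       dirich = dirich, n = n, profile = pu,
       bcProximal = bcProximal, bcDistal = bcDistal)
}

.injIndex <- function(sys, injX) {
  L <- sys$x_um[sys$n]
  if (injX < 0 || injX > L) stop("injection site outside [0, L]")
  which.min(abs(sys$x_um - injX))
}

#' Steady-state voltage in a tapering cable (finite-difference oracle)
#'
#' Solves the steady generalised cable equation
#' \deqn{\frac{d}{dx}\Big[r^2(x) \frac{dv}{dx}\Big] -
#'   2 r_a g_l\, r(x) \sqrt{1 + r'(x)^2}\, v =
#'   -\frac{r_a}{\pi} I_{app}\, \delta(x - x')}
#' on a uniform grid with a conservative (flux-form) second-order
#' discretisation.  Note the full lateral-area factor
#' \eqn{\sqrt{1 + r'^2}} is included here, while the first-order analytic
#' solution drops its O(epsilon^2) contribution; the difference is part of
#' what oracle comparisons measure.
#'
#' Boundary conditions: \code{"sealed"} (zero axial flux), \code{"killed"}
#' (voltage clamped to rest) and \code{"matched_infinite"}, a Robin
#' condition loading the end with the input conductance of a semi-infinite
#' uniform cable continued at the end radius, which emulates
#' \eqn{v \to 0} as \eqn{x \to -\infty} on a finite grid.  Defaults are
#' matched-infinite proximal, sealed distal.
#'
#' @param p a [RadiusProfile-class].
#' @param params a [PassiveParams-class].
#' @param injX injection site (um); snapped to the nearest grid point.
#' @param iApp injected current (nA).
#' @param bcProximal,bcDistal boundary labels (see above).
#' @param n grid size; default chooses the grid so that the spacing is at
#'   most \eqn{\min_x \lambda(x)/200}.
#' @param loadRadius radius (um) of the semi-infinite collar behind a
#'   matched-infinite proximal end.  By default the collar continues the
#'   profile's own proximal radius; pass a fixed value to present the same
#'   downstream (somatic) load to different candidate profiles, as required
#'   when comparing shapes for current transfer.
#' @return A [VoltageSolution-class] with voltage in mV.
#' @examples
#' cyl <- makeCylinder(1000, 1, 51)
#' sol <- solveSteady(cyl, passiveParams(60, 5e-4), injX = 500, n = 2001)
#' max(voltage(sol))
#' @export
solveSteady <- function(p, params, injX, iApp = 1,
                        bcProximal = "matched_infinite",
                        bcDistal = "sealed", n = NULL, loadRadius = NULL) {
  stopifnot(is(p, "RadiusProfile"), is(params, "PassiveParams"))
  sys <- .assembleCable(p, params, bcProximal, bcDistal, n, loadRadius)
  j <- .injIndex(sys, injX)
  b <- numeric(sys$n)
  b[j] <- (params@ra / pi) * (iApp * 1e-9)
  b[sys$dirich] <- 0
  v <- .triSolve(sys$dl, sys$d, sys$du, b)[, 1L]
  new("VoltageSolution", x = sys$x_um, v = v * 1e3,
      injectionSite = sys$x_um[j], iApp = iApp,
      bcProximal = sys$bcProximal, bcDistal = sys$bcDistal)
}

#' Steady-state Green's matrix of a cable
#'
#' Computes \eqn{G[i, j]}, the voltage at \eqn{x_i} per unit current
#' injected at \eqn{x_j}, by reusing one tridiagonal factorisation for all
#' columns.  The flux-form discretisation makes the matrix symmetric
#' (reciprocity) up to round-off; diagonal entries are input resistances.
#'
#' @inheritParams solveSteady
#' @return A [GreensMatrix-class] with entries in MOhm.
#' @export
greensMatrix <- function(p, params, bcProximal = "matched_infinite",
                         bcDistal = "sealed", n = NULL, loadRadius = NULL) {
  stopifnot(is(p, "RadiusProfile"), is(params, "PassiveParams"))
  if (is.null(n)) n <- min(.defaultGridSize(p, params), 2001L)
  sys <- .assembleCable(p, params, bcProximal, bcDistal, n, loadRadius)
  B <- diag(sys$n) * (params@ra / pi)
  B[sys$dirich, ] <- 0
  G <- .triSolve(sys$dl, sys$d, sys$du, B)   # V per A, column = source
  new("GreensMatrix", G = G * 1e-6, x = sys$x_um,
      bcProximal = sys$bcProximal, bcDistal = sys$bcDistal)
}

#' Steady-state current balance diagnostic
#'
#' Recomputes, for a solved steady state, the total membrane current plus
#' any boundary-load current and compares it with the injected current
#' (discrete divergence theorem: the flux terms telescope, so the balance
#' holds to solver round-off).
#'
#' @param p,params the profile and parameters used for the solve.
#' @param sol the [VoltageSolution-class] returned by [solveSteady()].
#' @return list with \code{injected}, \code{absorbed} (both nA) and
#'   \code{relativeError}.
#' @export
currentBalance <- function(p, params, sol, loadRadius = NULL) {
  sys <- .assembleCable(p, params, sol@bcProximal, sol@bcDistal,
                        n = length(sol@x), loadRadius = loadRadius)
  v <- sol@v / 1e3
  imem <- sum(sys$cmem * sys$w * v) * pi / params@ra
  ibnd <- (sys$gBndProx * v[1L] + sys$gBndDist * v[sys$n]) * pi / params@ra
  inj <- sol@iApp * 1e-9
  list(injected = inj * 1e9, absorbed = (imem + ibnd) * 1e9,
       relativeError = abs(imem + ibnd - inj) / abs(inj))
}

#' Transient voltage by Crank-Nicolson time stepping
#'
#' Integrates the time-dependent generalised cable equation
#' \eqn{\tau \partial v/\partial t = -v + \ldots} with the trapezoidal
#' (Crank-Nicolson) rule, which is unconditionally stable and
#' second-order in time.  For a constant current the solution converges to
#' the [solveSteady()] output as \eqn{t \to \infty} (the two schemes share
#' the same spatial operator, so the fixed point is identical).
#'
#' @inheritParams solveSteady
#' @param iShape either a constant current (nA) or a function of time (ms)
#'   returning the injected current (nA).
#' @param T total integration time (ms).
#' @param dt time step (ms).
#' @return list with \code{x} (um), \code{times} (ms), \code{v} (matrix,
#'   time by space, mV) and \code{final} (a [VoltageSolution-class]).
#' @export
solveTransient <- function(p, params, injX, iShape, T, dt,
                           bcProximal = "matched_infinite",
                           bcDistal = "sealed", n = NULL) {
  stopifnot(is(p, "RadiusProfile"), is(params, "PassiveParams"),
            dt > 0, T >= dt)
  sys <- .assembleCable(p, params, bcProximal, bcDistal, n)
  j <- .injIndex(sys, injX)
  ifun <- if (is.function(iShape)) iShape else function(t) iShape
  nstep <- ceiling(T / dt)
  times <- seq(0, by = dt, length.out = nstep + 1L)
  m <- sys$cmem * sys$w * params@tau          # mass (time) coefficients
  m[sys$dirich] <- 0
  # LHS = M/dt + A/2, RHS matrix = M/dt - A/2
  dL <- m / dt + sys$d / 2
  dR <- m / dt - sys$d / 2
  offL <- sys$dl / 2
  offR <- -sys$dl / 2
  v <- numeric(sys$n)
  out <- matrix(0, nstep + 1L, sys$n)
  src <- function(t) {
    b <- numeric(sys$n)
    b[j] <- (params@ra / pi) * (ifun(t) * 1e-9)
    b[sys$dirich] <- 0
    b
  }
  # Rannacher startup: four backward-Euler quarter-steps damp the stiff
  # ringing that trapezoidal stepping leaves after a step turn-on, without
  # affecting the second-order accuracy of the remaining CN steps.
  dtq <- dt / 4
  dBE <- m / dtq + sys$d
  for (s in 1:4) {
    rhs <- m / dtq * v + src(s * dtq)
    v <- .triSolve(sys$dl, dBE, sys$du, rhs)[, 1L]
  }
  out[2L, ] <- v * 1e3
  for (s in seq_len(nstep)[-1L]) {
    rhs <- dR * v
    rhs[-sys$n] <- rhs[-sys$n] + offR * v[-1L]
    rhs[-1L] <- rhs[-1L] + offR * v[-sys$n]
    rhs <- rhs + (src(times[s]) + src(times[s + 1L])) / 2
    v <- .triSolve(offL, dL, offL, rhs)[, 1L]
    if (any(!is.finite(v))) stop("transient scheme produced non-finite values")
    out[s + 1L, ] <- v * 1e3
  }
  final <- new("VoltageSolution", x = sys$x_um, v = v * 1e3,
               injectionSite = sys$x_um[j], iApp = ifun(times[nstep + 1L]),
               bcProximal = sys$bcProximal, bcDistal = sys$bcDistal)
  list(x = sys$x_um, times = times, v = out, final = final)
}

# Compartmental conductance matrix of a tree: axial conductances from
# frustum resistance ra*l/(pi r1 r2), membrane leak from lateral frustum
# (slant) areas, split half to each end node.  Dense symmetric matrix in S.
.treeSystem <- function(tree, params, somaConductance = 0) {
  nd <- tree@nodes
  nn <- nrow(nd)
  idx <- match(nd$parent, nd$id)
  child <- which(!is.na(idx))
  par <- idx[child]
  len <- sqrt((nd$x[child] - nd$x[par])^2 + (nd$y[child] - nd$y[par])^2 +
              (nd$z[child] - nd$z[par])^2) / .UM_PER_CM
  if (any(len <= 0)) stop("tree contains zero-length edges")
  r1 <- nd$radius[par] / .UM_PER_CM
  r2 <- nd$radius[child] / .UM_PER_CM
  gax <- pi * r1 * r2 / (params@ra * len)
  slant <- sqrt(len^2 + (r2 - r1)^2)
  gmem <- params@gl * pi * (r1 + r2) * slant
  A <- matrix(0, nn, nn)
  for (e in seq_along(child)) {
    i <- par[e]; k <- child[e]
    A[i, k] <- A[i, k] - gax[e]
    A[k, i] <- A[k, i] - gax[e]
    A[i, i] <- A[i, i] + gax[e] + gmem[e] / 2
    A[k, k] <- A[k, k] + gax[e] + gmem[e] / 2
  }
  root <- which(is.na(nd$parent))
  A[root, root] <- A[root, root] + somaConductance * 1e-9  # nS -> S
  list(A = A, root = root, ids = nd$id)
}

#' Steady-state voltages on a branched morphology
#'
#' Compartmental steady-state solve over the nodes of a tree: each
#' parent-child edge contributes an axial conductance
#' \eqn{\pi r_1 r_2 / (r_a l)} (frustum resistance) and a membrane leak
#' conductance \eqn{g_l \pi (r_1 + r_2) s} from its lateral (slant)
#' surface, split equally between its end nodes.  By default the root is a
#' sealed terminal compartment with no explicit somatic load; a lumped
#' soma conductance can be added.
#'
#' @param tree a [TreeMorphology-class].
#' @param params a [PassiveParams-class].
#' @param injNode node id receiving the current.
#' @param iApp injected current (nA).
#' @param somaConductance lumped conductance at the root (nS), default 0.
#' @return data.frame with columns \code{id} and \code{v_mV}.
#' @export
solveTreeSteady <- function(tree, params, injNode, iApp = 1,
                            somaConductance = 0) {
  stopifnot(is(tree, "TreeMorphology"), is(params, "PassiveParams"))
  validObject(tree)
  sys <- .treeSystem(tree, params, somaConductance)
  j <- match(injNode, sys$ids)
  if (is.na(j)) stop("unknown node id: ", injNode)
  b <- numeric(length(sys$ids))
  b[j] <- iApp * 1e-9
  v <- solve(sys$A, b)
  data.frame(id = sys$ids, v_mV = v * 1e3)
}
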