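test_that("steady solver matches classical cylinder closed forms", {
  L <- 2000; r <- 1
  cyl <- makeCylinder(L, r, 101)
  lam <- sqrt((r / 1e4) / (2 * 60 * 5e-4)) * 1e4
  # matched-infinite proximal, sealed distal, mid-cable injection
  sol <- solveSteady(cyl, flyParams, injX = 1000, n = 4001)
  vex <- cylinderClosedForm(solutionGrid(sol), L, r, flyParams, 1000)
  expect_lt(max(abs(voltage(sol) - vex)) / max(vex), 0.005)
  # pure exponential attenuation on the proximal side
  v <- voltage(sol); x <- solutionGrid(sol)
  j <- which.min(abs(x - 1000))
  sel <- x > 200 & x < 990
  expect_equal(v[sel], v[j] * exp(-(1000 - x[sel]) / lam),
               tolerance = 0.005)
  # sealed-sealed, injection at the end: input resistance = Rinf coth(L/lam)
  sol2 <- solveSteady(cyl, flyParams, injX = 0, bcProximal = "sealed",
                      n = 4001)
  Rinf <- 60 * (lam / 1e4) / (pi * (r / 1e4)^2) / 1e6
  expect_equal(voltage(sol2)[1], Rinf / tanh(L / lam), tolerance = 0.005)
  # cosh profile along the cable
  vex2 <- Rinf / tanh(L / lam) * cosh((L - x) / lam) / cosh(L / lam)
  expect_lt(max(abs(voltage(sol2) - vex2)) / max(vex2), 0.005)
})

test_that("voltage from a single injection is positive and unimodal", {
  p <- ladderProfile(2, seed = 4)
  sol <- solveSteady(p, flyParams, injX = 1200, n = 2001)
  v <- voltage(sol); x <- solutionGrid(sol)
  expect_true(all(v > 0))
  j <- which.min(abs(x - 1200))
  expect_true(all(diff(v[1:j]) > 0))       # monotone rise towards source
  expect_true(all(diff(v[j:length(v)]) < 0))
})

test_that("killed boundary clamps the end to rest", {
  cyl <- makeCylinder(500, 1, 101)
  sol <- solveSteady(cyl, flyParams, injX = 400, bcProximal = "killed",
                     n = 1001)
  expect_equal(voltage(sol)[1], 0)
  expect_gt(max(voltage(sol)), 0)
})

test_that("matched-infinite Robin load agrees with an explicit long collar", {
  r <- 1
  lam <- sqrt((r / 1e4) / (2 * 60 * 5e-4)) * 1e4
  short <- makeCylinder(1000, r, 51)
  solR <- solveSteady(short, flyParams, injX = 600, n = 2001)
  # explicit 10-lambda collar continuing the proximal radius
  collar <- 10 * lam
  long <- makeCylinder(1000 + collar, r, 51)
  solC <- solveSteady(long, flyParams, injX = collar + 600,
                      bcProximal = "sealed", n = 8001)
  xs <- solutionGrid(solR)
  vC <- approx(solutionGrid(solC) - collar, voltage(solC), xout = xs)$y
  expect_lt(max(abs(voltage(solR) - vC)) / max(vC), 0.002)
})

test_that("spatial discretisation converges at second order", {
  qc <- makeQuadraticCable(1000, 0.3, 1.2e-6, 2001)
  ns <- c(251, 501, 1001, 2001)
  sols <- lapply(ns, function(n) solveSteady(qc, flyParams, injX = 600,
                                             n = n))
  xs <- solutionGrid(sols[[1]])
  vs <- lapply(sols, function(s)
    approx(solutionGrid(s), voltage(s), xs)$y)
  vref <- vs[[4]] + (vs[[4]] - vs[[3]]) / 3          # Richardson
  errs <- sapply(vs[1:3], function(v) max(abs(v - vref)))
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 3.5 & ratios < 4.5))
})

test_that("Green's matrix is reciprocal with positive input resistances", {
  p <- ladderProfile(1, seed = 2, nPoints = 801)
  gm <- greensMatrix(p, flyParams, n = 401)
  G <- greensValues(gm)
  expect_lt(max(abs(G - t(G))) / max(abs(G)), 1e-8)
  expect_true(all(diag(G) > 0))
  # diagonal far from the ends ~ half the semi-infinite input resistance
  cylG <- greensMatrix(makeCylinder(4000, 1, 101), flyParams, n = 1001)
  lam <- sqrt((1 / 1e4) / (2 * 60 * 5e-4)) * 1e4
  Rhalf <- 60 * (lam / 1e4) / (2 * pi * (1 / 1e4)^2) / 1e6
  mid <- which.min(abs(cylG@x - 2000))
  expect_equal(greensValues(cylG)[mid, mid], Rhalf, tolerance = 0.005)
})

test_that("steady state conserves current to solver precision", {
  p <- ladderProfile(2, seed = 3)
  for (bc in c("matched_infinite", "sealed")) {
    sol <- solveSteady(p, flyParams, injX = 700, bcProximal = bc, n = 2001)
    bal <- currentBalance(p, flyParams, sol)
    expect_lt(bal$relativeError, 1e-8)
  }
})

test_that("transient stepping reaches the steady state and is null-safe", {
  cyl <- makeCylinder(2000, 1, 101)
  tr <- solveTransient(cyl, flyParams, injX = 1000, iShape = 1,
                       T = 20 * flyParams@tau, dt = 1, n = 801)
  ss <- solveSteady(cyl, flyParams, injX = 1000, n = 801)
  expect_lt(max(abs(voltage(tr$final) - voltage(ss))) / max(voltage(ss)),
            1e-3)
  tr0 <- solveTransient(cyl, flyParams, injX = 1000, iShape = 0,
                        T = 10, dt = 0.5, n = 401)
  expect_equal(max(abs(tr0$v)), 0)
})

test_that("proximal peak is later for more distal injections", {
  qc <- makeQuadraticCable(800, 0.3, 2e-6, 801)
  pulse <- function(t) ifelse(t <= 1, 1, 0)
  peakTime <- function(injX) {
    tr <- solveTransient(qc, flyParams, injX = injX, iShape = pulse,
                         T = 60, dt = 0.25, n = 801)
    tr$times[which.max(tr$v[, 1])]
  }
  expect_gt(peakTime(600), peakTime(250))
})

test_that("tree solver agrees with the cable solver on a chain", {
  chain <- makeRandomTree(1, c(400, 400), seed = 2, radius = 0.8,
                          nodeSpacing = 4)
  nd <- treeNodes(chain)
  tip <- nd$id[!nd$id %in% nd$parent]
  prof <- pathToProfile(chain, tip)
  injNode <- nd$id[round(nrow(nd) / 2)]
  injX <- cableLength(pathToProfile(chain, injNode))
  tv <- solveTreeSteady(chain, flyParams, injNode = injNode)
  cs <- solveSteady(prof, flyParams, injX = injX, bcProximal = "sealed",
                    n = 4001)
  vAt <- approx(solutionGrid(cs), voltage(cs),
                xout = sapply(nd$id, function(i)
                  if (i == 1) 0 else cableLength(pathToProfile(chain, i))))$y
  expect_lt(max(abs(tv$v_mV - vAt)) / max(vAt), 0.01)
})

test_that("tree Green's reciprocity holds and root injection dominates", {
  tree <- makeRandomTree(6, c(60, 150), seed = 9, radius = 0.6)
  nd <- treeNodes(tree)
  k <- nd$id[nrow(nd)]
  vRootInj <- solveTreeSteady(tree, flyParams, injNode = 1)
  vKInj <- solveTreeSteady(tree, flyParams, injNode = k)
  expect_equal(vRootInj$v_mV[match(k, vRootInj$id)],
               vKInj$v_mV[match(1, vKInj$id)], tolerance = 1e-8)
  expect_equal(which.max(vRootInj$v_mV), match(1, vRootInj$id))
})

test_that("degenerate inputs are rejected with diagnostics", {
  cyl <- makeCylinder(100, 1, 11)
  expect_error(solveSteady(cyl, flyParams, injX = 200), "outside")
  disconnected <- data.frame(id = 1:2, type = 1L, x = c(0, 0), y = c(0, 1),
                             z = 0, radius = 1, parent = c(NA, 5L))
  expect_error(treeMorphology(disconnected), "missing|reference")
})
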