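test_that("apparent lengths combine daughters with the 3/2 power rule", {
  chain <- makeRandomTree(1, c(40, 80), seed = 4)
  al <- apparentLengths(chain)
  nd <- treeNodes(chain)
  tip <- nd$id[!nd$id %in% nd$parent]
  expect_equal(unname(al["1"]), cableLength(pathToProfile(chain, tip)),
               tolerance = 1e-9)
  expect_equal(unname(al[as.character(tip)]), 0)
  # symmetric Y: branch-point apparent length (2 * 50^{3/2})^{2/3}
  y <- makeYTree(stem = 50, l1 = 50, l2 = 50)
  aly <- apparentLengths(y)
  branchNode <- treeNodes(y)$id[6]     # last stem node
  expect_equal(unname(aly[as.character(branchNode)]),
               (2 * 50^1.5)^(2 / 3), tolerance = 1e-9)
  expect_equal(unname(aly["1"]), 50 + (2 * 50^1.5)^(2 / 3),
               tolerance = 1e-9)
  # one vanishing daughter: the other daughter's length carries through
  y2 <- makeYTree(stem = 50, l1 = 60, l2 = 1e-9)
  al2 <- apparentLengths(y2)
  expect_equal(unname(al2[as.character(branchNode)]), 60, tolerance = 1e-6)
})

test_that("distributed radii follow the quadratic and Rall's rule", {
  # unbranched chain: exactly the single-cable quadratic
  chain <- makeRandomTree(1, c(200, 200), seed = 1, nodeSpacing = 5)
  opt <- distributeRadii(chain, rL = 0.1, rProximal = 1)
  nd <- treeNodes(opt)
  al <- apparentLengths(chain)
  a <- fitAlphaProximal(al[["1"]], 0.1, 1)
  x <- sapply(nd$id, function(i)
    if (i == 1) 0 else cableLength(pathToProfile(chain, i)))
  expect_equal(nd$radius, a * (al[["1"]] - x)^2 + 0.1, tolerance = 1e-9)
  # symmetric branch: daughters at 2^{-2/3} of the parent radius
  y <- makeYTree(stem = 50, l1 = 50, l2 = 50)
  for (rule in c("literal", "linear")) {
    opty <- distributeRadii(y, rL = 0.01, rProximal = 1, ratioRule = rule)
    br <- provenance(opty)$branches
    expect_equal(nrow(br), 1)
    expect_lt(br$residual, 1e-9)
    # recover daughter start radii from the stored branch radius
    expect_equal(rallResidual(opty), br$residual)
  }
  # asymmetric branch, literal rule: r1/r2 = (l1/l2)^{3/2}
  y3 <- makeYTree(stem = 50, l1 = 100, l2 = 50, nPerBranch = 10)
  al3 <- apparentLengths(y3)
  opt3 <- distributeRadii(y3, rL = 1e-6, rProximal = 1, ratioRule = "literal")
  nd3 <- treeNodes(opt3)
  branchNode <- 11L                     # last stem node id
  kids <- nd3$id[which(nd3$parent == branchNode)]
  edgeOf <- function(k) {
    i <- match(k, nd3$id); j <- match(branchNode, nd3$id)
    sqrt(sum((nd3[i, c("x", "y", "z")] - nd3[j, c("x", "y", "z")])^2))
  }
  l1 <- edgeOf(kids[1]) + al3[[as.character(kids[1])]]
  l2 <- edgeOf(kids[2]) + al3[[as.character(kids[2])]]
  r0 <- nd3$radius[match(branchNode, nd3$id)]
  rd <- r0 * c(l1, l2)^1.5 / sum(c(l1, l2)^(9 / 4))^(2 / 3)
  expect_equal(rd[1] / rd[2], (l1 / l2)^1.5, tolerance = 1e-9)
  expect_equal(sum(rd^1.5), r0^1.5, tolerance = 1e-9)
  # the assigned first-node radii continue each daughter's quadratic
  for (j in 1:2) {
    lj <- c(l1, l2)[j]; ej <- edgeOf(kids[j])
    aj <- (rd[j] - 1e-6) / lj^2
    expect_equal(nd3$radius[match(kids[j], nd3$id)],
                 aj * (lj - ej)^2 + 1e-6, tolerance = 1e-9)
  }
  # linear rule on the same tree also satisfies Rall's relation
  optLin <- distributeRadii(y3, rL = 1e-6, rProximal = 1,
                            ratioRule = "linear")
  expect_lt(rallResidual(optLin), 1e-9)
})

test_that("matchVolume converges by bisection and respects tolerances", {
  tree <- makeRandomTree(8, c(60, 150), seed = 6, radius = 0.5)
  opt <- matchVolume(tree, rL = 0.1, tol = 1e-3)
  pv <- provenance(opt)
  expect_lt(abs(pv$volumeRatio - 1), 1e-3)
  expect_lte(pv$iterations, 60)
  expect_lt(rallResidual(opt), 1e-9)
  # tightening the tolerance tightens the volume error accordingly
  opt2 <- matchVolume(tree, rL = 0.1, tol = 1e-4)
  expect_lt(abs(provenance(opt2)$volumeRatio - 1), 1e-4)
  # infeasible target: tree thinner than the all-rL floor
  thin <- tree
  thin@nodes$radius[] <- 0.01
  expect_error(matchVolume(thin, rL = 0.3), "infeasible")
})

test_that("a tree that is already optimal is a fixed point", {
  tree <- makeRandomTree(6, c(80, 150), seed = 2, radius = 0.5)
  opt <- matchVolume(tree, rL = 0.1)
  again <- matchVolume(opt, rL = 0.1,
                       rProximalInit = provenance(opt)$rProximal)
  expect_equal(provenance(again)$rProximal, provenance(opt)$rProximal,
               tolerance = 1e-3)
  expect_lt(abs(provenance(again)$volumeRatio - 1), 1e-3)
})

test_that("radii never increase from root to tips after optimisation", {
  for (s in c(3, 9)) {
    tree <- makeRandomTree(10, c(60, 150), seed = s, radius = 0.5)
    opt <- matchVolume(tree, rL = 0.1)
    nd <- treeNodes(opt)
    idx <- match(nd$parent, nd$id)
    ch <- which(!is.na(idx))
    expect_true(all(nd$radius[ch] <= nd$radius[idx[ch]] + 1e-9))
    expect_true(all(nd$radius >= 0.1 - 1e-12))
  }
})

test_that("transfer map is a proper attenuation map", {
  tree <- makeRandomTree(6, c(80, 200), seed = 5, radius = 0.5)
  tm <- transferMap(tree, flyParams)
  expect_equal(tm$transfer[match(1, tm$id)], 1, tolerance = 1e-12)
  expect_true(all(tm$transfer > 0 & tm$transfer <= 1 + 1e-12))
  expect_equal(tm$distance[match(1, tm$id)], 0)
  # single-node tree: trivial map and zero equalisation index
  solo <- treeMorphology(data.frame(id = 1L, type = 1L, x = 0, y = 0,
                                    z = 0, radius = 1, parent = NA))
  expect_equal(transferMap(solo, flyParams)$transfer, 1)
  expect_equal(equalisationIndex(solo, flyParams), 0)
})

test_that("equalisation index is scale-free in the well-defined sense", {
  tree <- makeRandomTree(6, c(80, 200), seed = 5, radius = 0.5)
  ci <- equalisationIndex(tree, flyParams)
  expect_true(is.finite(ci) && ci > 0)
  scaled <- tree
  scaled@nodes$radius <- scaled@nodes$radius * 2
  ci2 <- equalisationIndex(scaled, flyParams)
  expect_true(is.finite(ci2) && ci2 > 0)
})

test_that("optimal radii improve mean transfer and democracy on seeded
           trees under a somatic load", {
  wins <- 0; cvWins <- 0
  for (s in 1:5) {
    tree <- makeRandomTree(16, c(150, 350), seed = s, radius = 0.5)
    opt <- matchVolume(tree, rL = 0.1)
    tmO <- transferMap(opt, flyParams, somaConductance = 6.3)
    tmC <- transferMap(tree, flyParams, somaConductance = 6.3)
    if (mean(tmO$transfer) >= mean(tmC$transfer)) wins <- wins + 1
    cvO <- sd(tmO$transfer) / mean(tmO$transfer)
    cvC <- sd(tmC$transfer) / mean(tmC$transfer)
    if (cvO < cvC) cvWins <- cvWins + 1
  }
  expect_gte(wins, 4)
  expect_gte(cvWins, 3)
})
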