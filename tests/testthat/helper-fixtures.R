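# Shared fixtures: passive parameter sets and small canonical geometries.

flyParams <- passiveParams(60, 5e-4)        # blowfly HS/VS
granuleParams <- passiveParams(210, 4e-5)   # dentate gyrus granule

# classical closed-form voltage for a cylinder with a matched-infinite
# proximal end and a sealed distal end, injection at injX (unit current);
# an independent oracle for both solvers
cylinderClosedForm <- function(x, L, r_um, params, injX, iApp = 1) {
  lam <- sqrt((r_um / 1e4) / (2 * params@ra * params@gl)) * 1e4
  Rinf <- params@ra * (lam / 1e4) / (pi * (r_um / 1e4)^2) / 1e6   # MOhm
  ell <- L - injX
  ifelse(x < injX,
         Rinf / 2 * (1 + exp(-2 * ell / lam)) * exp(-(injX - x) / lam),
         Rinf * exp(-ell / lam) * cosh((L - x) / lam)) * iApp
}

# hand-built Y-tree: root at origin, stem of `stem` um along x, two
# daughters of lengths l1 (along +y) and l2 (along -y), radii constant
makeYTree <- function(stem = 50, l1 = 50, l2 = 50, radius = 1,
                      nPerBranch = 5L) {
  rows <- list(c(1, 1, 0, 0, 0, radius, NA))
  id <- 2L
  addChain <- function(rows, id, from, fromPos, dir, len, n) {
    for (k in seq_len(n)) {
      pos <- fromPos + dir * len * k / n
      rows[[length(rows) + 1L]] <- c(id, 3, pos[1L], pos[2L], pos[3L],
                                     radius, from)
      from <- id; id <- id + 1L
    }
    list(rows = rows, id = id, last = from)
  }
  st <- addChain(rows, id, 1L, c(0, 0, 0), c(1, 0, 0), stem, nPerBranch)
  branchId <- st$last
  d1 <- addChain(st$rows, st$id, branchId, c(stem, 0, 0), c(0, 1, 0), l1,
                 nPerBranch)
  d2 <- addChain(d1$rows, d1$id, branchId, c(stem, 0, 0), c(0, -1, 0), l2,
                 nPerBranch)
  m <- do.call(rbind, d2$rows)
  treeMorphology(data.frame(id = m[, 1], type = m[, 2], x = m[, 3],
                            y = m[, 4], z = m[, 5], radius = m[, 6],
                            parent = m[, 7]))
}

# the frozen smoothing-ladder conditions (periodic artificial cables):
# rung k doubles the period and halves the amplitude
ladderProfile <- function(rung, seed = 1L, nPoints = 2001L)
  makePeriodicCable(2000, 1, 400 * 2^(rung - 1), 0.5 / 2^(rung - 1),
                    nPoints, seed = seed)
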