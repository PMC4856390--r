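# SWC and profile-table input/output, path extraction, resampling.

#' Read an SWC morphology file
#'
#' Parses the de-facto 7-column SWC dialect: whitespace-separated
#' \code{id type x y z radius parent} records, \code{#} comment lines, a
#' single root marked by parent \code{-1}.  The node order of the file is
#' preserved.  Column six is a radius in micrometres (not a diameter).
#'
#' @param path path to an SWC file.
#' @return A [TreeMorphology-class].
#' @seealso [writeSWC()], [pathToProfile()]
#' @export
readSWC <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("SWC parse error: no data lines in ", path)
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(toks) != 7L)
  if (length(bad))
    stop(sprintf("SWC parse error at line %d of %s: expected 7 columns, found %d",
                 lineno[bad[1L]], path, lengths(toks)[bad[1L]]))
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))),
              ncol = 7L, byrow = TRUE)
  badnum <- which(apply(m, 1L, function(z) any(is.na(z))))
  if (length(badnum))
    stop(sprintf("SWC parse error at line %d of %s: non-numeric field",
                 lineno[badnum[1L]], path))
  nodes <- data.frame(id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
                      x = m[, 3L], y = m[, 4L], z = m[, 5L],
                      radius = m[, 6L],
                      parent = ifelse(m[, 7L] < 0, NA_integer_,
                                      as.integer(m[, 7L])))
  chk <- .validateTreeNodes(nodes)
  if (!isTRUE(chk)) stop("SWC structure error in ", path, ": ", chk)
  treeMorphology(nodes)
}

#' Write a morphology to SWC
#'
#' Writes the node table in 7-column SWC format with enough significant
#' digits (15) that [readSWC()] recovers an identical tree.
#'
#' @param tree a valid [TreeMorphology-class].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeSWC <- function(tree, path) {
  stopifnot(is(tree, "TreeMorphology"))
  validObject(tree)
  nd <- tree@nodes
  fmt <- function(z) formatC(z, format = "g", digits = 15)
  rows <- paste(nd$id, nd$type, fmt(nd$x), fmt(nd$y), fmt(nd$z),
                fmt(nd$radius),
                ifelse(is.na(nd$parent), -1L, nd$parent))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SWC export (id type x y z radius parent)", rows), con)
  invisible(path)
}

#' Extract the radius profile along a root-to-tip path
#'
#' Walks the parent pointers from \code{tipId} up to the root and returns
#' the sampled taper along that path: arclength from the root (proximal,
#' \eqn{x = 0}) using 3-D inter-node Euclidean distances, radii carried
#' over per node.  Consecutive nodes at identical positions are collapsed,
#' keeping the more distal radius.
#'
#' @param tree a [TreeMorphology-class].
#' @param tipId node id of the distal end of the path.
#' @return A [RadiusProfile-class].
#' @export
pathToProfile <- function(tree, tipId) {
  nd <- tree@nodes
  i <- match(tipId, nd$id)
  if (is.na(i)) stop("unknown node id: ", tipId)
  path <- i
  while (!is.na(nd$parent[i])) {
    i <- match(nd$parent[i], nd$id)
    path <- c(i, path)
  }
  px <- nd$x[path]; py <- nd$y[path]; pz <- nd$z[path]
  seg <- sqrt(diff(px)^2 + diff(py)^2 + diff(pz)^2)
  x <- c(0, cumsum(seg))
  r <- nd$radius[path]
  dup <- c(FALSE, diff(x) == 0)
  if (any(dup)) {   # zero-length edges: keep the distal node's radius
    r[which(dup) - 1L] <- r[dup]
    x <- x[!dup]; r <- r[!dup]
  }
  if (length(x) < 2L) stop("path from root to node ", tipId,
                           " has fewer than 2 distinct positions")
  radiusProfile(x, r)
}

#' Resample a profile onto a uniform grid
#'
#' Linear interpolation of \eqn{r(x)} onto \code{n} equispaced points on
#' \eqn{[0, L]}; both endpoints are preserved exactly.
#'
#' @param p a [RadiusProfile-class].
#' @param n number of grid points (>= 2).
#' @return A [RadiusProfile-class] on the uniform grid.
#' @export
resampleProfile <- function(p, n) {
  stopifnot(is(p, "RadiusProfile"))
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  L <- cableLength(p)
  xg <- seq(0, L, length.out = n)
  rg <- stats::approx(p@x, p@r, xout = xg, rule = 2)$y
  rg[1L] <- p@r[1L]
  rg[n] <- p@r[length(p@r)]
  radiusProfile(xg, rg)
}

#' Read/write a radius profile as a two-column table
#'
#' Plain CSV with header \code{x_um,r_um}.
#'
#' @param path file path.
#' @return \code{readProfileCSV} returns a [RadiusProfile-class];
#'   \code{writeProfileCSV} invisibly returns \code{path}.
#' @export
readProfileCSV <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x_um", "r_um") %in% names(df)))
    stop("profile CSV must have columns x_um,r_um: ", path)
  radiusProfile(df$x_um, df$r_um)
}

#' @rdname readProfileCSV
#' @param p a [RadiusProfile-class].
#' @export
writeProfileCSV <- function(p, path) {
  utils::write.csv(data.frame(x_um = p@x, r_um = p@r), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
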