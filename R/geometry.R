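#' Build a synthetic parcellation geometry
#'
#' Generates `nRegions` region centroids either on a regular planar grid or
#' quasi-uniformly on the unit sphere (Fibonacci lattice followed by a
#' seeded random rotation), and derives the pairwise Euclidean distance
#' matrix. Stands in for a real cortical parcellation: the analysis only
#' ever consumes region ids, centroids, distances and the
#' cortical/hemisphere flags.
#'
#' @param nRegions number of regions, at least 4.
#' @param layout "sphere" (default) or "grid".
#' @param seed integer RNG seed; the result is deterministic given the seed.
#' @param nSubcortical number of regions flagged subcortical (sampled under
#'   the seed); default 0, i.e. an all-cortical geometry.
#' @return a [RegionGeometry-class].
#' @examples
#' g <- makeGeometry(50, "sphere", seed = 1)
#' max(regionDist(g)) <= 2
#' @export
makeGeometry <- function(nRegions, layout = c("sphere", "grid"), seed = 1L,
                         nSubcortical = 0L) {
  layout <- match.arg(layout)
  if (!is.numeric(nRegions) || nRegions < 4)
    stop("invalid argument: nRegions must be >= 4")
  n <- as.integer(nRegions)
  withSeed(seed, {
    if (layout == "grid") {
      side <- ceiling(sqrt(n))
      gx <- (seq_len(side) - 1)
      pts <- as.matrix(expand.grid(x = gx, y = gx))[seq_len(n), , drop = FALSE]
      coords <- cbind(pts, z = 0)
    } else {
      # Fibonacci lattice on the unit sphere, then a random rotation so
      # different seeds give different (still quasi-uniform) point sets.
      i <- seq_len(n) - 0.5
      phi <- acos(1 - 2 * i / n)
      theta <- pi * (1 + sqrt(5)) * i
      coords <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
      coords <- coords %*% randomRotation3()
    }
    colnames(coords) <- c("x", "y", "z")
    rownames(coords) <- NULL
    subc <- rep(FALSE, n)
    if (nSubcortical > 0)
      subc[sample.int(n, min(nSubcortical, n))] <- TRUE
    hemi <- ifelse(coords[, "x"] < stats::median(coords[, "x"]), "L", "R")
    d <- as.matrix(stats::dist(coords))
    dimnames(d) <- NULL
    new("RegionGeometry",
        regionId = sprintf("R%03d", seq_len(n)),
        coords = coords,
        dist = d,
        cortical = !subc,
        hemisphere = hemi)
  })
}

# Haar-ish random rotation via QR of a Gaussian matrix.
randomRotation3 <- function() {
  m <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Restrict a geometry to a subset of regions
#'
#' @param geom a [RegionGeometry-class].
#' @param keep character region ids or logical/integer index.
#' @return a [RegionGeometry-class] over the kept regions.
#' @export
subsetGeometry <- function(geom, keep) {
  if (is.character(keep)) keep <- match(keep, geom@regionId)
  new("RegionGeometry",
      regionId = geom@regionId[keep],
      coords = geom@coords[keep, , drop = FALSE],
      dist = geom@dist[keep, keep, drop = FALSE],
      cortical = geom@cortical[keep],
      hemisphere = geom@hemisphere[keep])
}
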