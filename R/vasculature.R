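#' Place T-cell entry points from the vascular density profile
#'
#' Vascular density is assumed to decay exponentially with depth into the
#' tissue: a voxel whose centre is d um from the nearest lattice face is an
#' entry point independently with probability
#' \code{baseDensity * exp(-lambdaVasc * d)}. Depth is measured from the
#' static lattice boundary, not the moving tumour surface.
#'
#' @param config a \linkS4class{LatticeConfig}.
#' @param lambdaVasc decay constant, 1/um; 0 gives uniform density.
#' @param baseDensity entry probability per voxel at depth 0.
#' @param seed optional integer seed (set only if supplied; otherwise the
#'   current RNG stream is consumed).
#' @param referenceDepth annotation depth in um kept with the map.
#' @return a \linkS4class{VasculatureMap}.
#' @examples
#' v <- placeEntryPoints(latticeConfig(nVoxels = 30), 1/100, 0.05, seed = 1)
#' length(entryVoxels(v))
#' @export
placeEntryPoints <- function(config, lambdaVasc, baseDensity, seed = NULL,
                             referenceDepth = 300) {
  if (lambdaVasc < 0) stop("lambdaVasc must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config@nVoxels
  ax <- seq_len(n) - 1L
  depth1 <- pmin(ax, n - 1L - ax) * config@voxelSize   # per-axis distance to face
  d <- pmin(array(depth1, c(n, n, n)),                 # varies along x
            array(rep(depth1, each = n), c(n, n, n)),  # along y
            array(rep(depth1, each = n * n), c(n, n, n)))  # along z
  p <- baseDensity * exp(-lambdaVasc * d)
  hit <- runif(length(p)) < p
  new("VasculatureMap", entryVoxels = as.integer(which(hit) - 1L),
      lambdaVasc = lambdaVasc, baseDensity = baseDensity,
      nVoxels = n, voxelSize = config@voxelSize,
      referenceDepth = referenceDepth)
}

#' Depth of each entry voxel
#'
#' Distance (um) of each entry voxel from the nearest lattice face; useful
#' for checking the density profile against the intended exponential decay.
#'
#' @param map a \linkS4class{VasculatureMap}.
#' @return numeric vector of depths, one per entry voxel.
#' @export
entryDepths <- function(map) {
  n <- map@nVoxels
  v <- map@entryVoxels
  x <- v %% n; y <- (v %/% n) %% n; z <- v %/% (n * n)
  pmin(x, n - 1L - x, y, n - 1L - y, z, n - 1L - z) * map@voxelSize
}

#' Effector T-cell recruitment rate
#'
#' The neoantigen profile converts the dead-cell signal into an expected
#' arrival rate: \code{rate = rBase * kA * (kI * D) / (1 + kI * D)} with D
#' the cumulative dead cancer count. Mutational burden kA sets the capacity
#' (the saturated rate is \code{rBase * kA}); antigen strength kI sets how
#' quickly the response saturates with the dead-cell signal. The rate is 0
#' when D = 0 and strictly increasing in kA, kI and D.
#'
#' @param kA mutational burden (> 0).
#' @param kI antigen strength (> 0).
#' @param cumulativeDead cumulative dead cancer cells (>= 0, vectorized).
#' @param rBase baseline rate scale, cells/hour.
#' @return expected arrivals per hour.
#' @examples
#' recruitmentRate(20, 0.1, c(0, 10, 1e6))
#' @export
recruitmentRate <- function(kA, kI, cumulativeDead, rBase = defaultParameterList()$rBase) {
  stopifnot(kA > 0, kI > 0, all(cumulativeDead >= 0), rBase >= 0)
  rBase * kA * (kI * cumulativeDead) / (1 + kI * cumulativeDead)
}

setMethod("show", "VasculatureMap", function(object) {
  cat(sprintf("VasculatureMap: %d entry voxels on %d^3 (lambda = %.3g /um, base density %.3g)\n",
              length(object@entryVoxels), object@nVoxels, object@lambdaVasc,
              object@baseDensity))
})
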