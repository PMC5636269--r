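#' Smooth a binary cancer-occupancy volume
#'
#' Unweighted 3x3x3 moving average with zero padding outside the lattice,
#' thresholded at mean >= 0.5. (With a 27-voxel box the mean can never equal
#' 0.5 exactly, so the strict/non-strict choice is observationally
#' irrelevant; >= is used.)
#'
#' @param lRaw binary 3D integer array (1 = voxel occupied by a cancer cell).
#' @return binary 3D array of the same dimension.
#' @examples
#' v <- array(0L, c(9, 9, 9)); v[4:6, 4:6, 4:6] <- 1L
#' sum(smoothLabels(v))
#' @export
smoothLabels <- function(lRaw) {
  if (!all(lRaw %in% 0:1)) stop("lRaw must be binary")
  cppBoxSmooth(as.integer(lRaw), dim(lRaw))
}

#' Extract the raw cancer label volume from a snapshot
#'
#' @param labels integer array of state codes (see \code{\link{stateCodes}}).
#' @param includeDead logical; count voxels occupied by dead cancer cells as
#'   cancer (default TRUE: "a cancer cell of any state").
#' @return binary array.
#' @export
rawCancerLabels <- function(labels, includeDead = TRUE) {
  keep <- if (includeDead) 1:3 else 1:2
  out <- array(0L, dim = dim(labels))
  out[labels %in% keep] <- 1L
  out
}

#' @describeIn tilsim-generics tumour region from a smoothed binary volume:
#'   the background is the 6-connected flood fill of zero voxels seeded from
#'   every lattice face; the tumour region is its complement, so sealed
#'   internal cavities belong to the tumour.
#' @export
setMethod("tumorRegion", "array", function(x, ...) {
  if (!all(x %in% 0:1)) stop("input must be binary")
  cppFloodBackground(as.integer(x), dim(x))
})

#' @describeIn tilsim-generics tumour-region volume stored in a mask
#' @export
setMethod("tumorRegion", "TumorMask", function(x, ...) x@region)

#' Build the full tumour mask pipeline from a snapshot
#'
#' Runs raw labelling, box smoothing and tumour-region extraction in one go.
#'
#' @param labels integer array of state codes, or a snapshot list with a
#'   \code{labels} element.
#' @param voxelSize voxel edge, um.
#' @param includeDead count dead cancer voxels as cancer.
#' @return a \linkS4class{TumorMask}.
#' @export
tumorMask <- function(labels, voxelSize = 10, includeDead = TRUE) {
  if (is.list(labels)) labels <- labels$labels
  lRaw <- rawCancerLabels(labels, includeDead)
  lSmooth <- smoothLabels(lRaw)
  new("TumorMask", lRaw = lRaw, lSmooth = lSmooth,
      region = tumorRegion(lSmooth), voxelSize = voxelSize)
}

.sliceArray <- function(arr, axis, index1) {
  switch(axis,
         x = arr[index1, , ], y = arr[, index1, ], z = arr[, , index1])
}

#' Central cross sections of a tumour
#'
#' Takes the three sections perpendicular to the x, y and z axes through the
#' lattice centre voxel (floor(N/2), 0-based) and attaches the Euclidean
#' distance-to-boundary map of each section's tumour mask.
#'
#' @param mask a \linkS4class{TumorMask} (or a binary tumour-region array).
#' @param labels optional state-code array for the same snapshot.
#' @param agentIds optional agent-id array for the same snapshot (enables
#'   agent-level rim counting).
#' @param voxelSize voxel edge, um (taken from the mask when available).
#' @return named list of three \linkS4class{CrossSection} objects
#'   (\code{x}, \code{y}, \code{z}).
#' @export
crossSections <- function(mask, labels = NULL, agentIds = NULL, voxelSize = NULL) {
  if (is(mask, "TumorMask")) {
    region <- mask@region
    if (is.null(voxelSize)) voxelSize <- mask@voxelSize
  } else {
    region <- mask
    if (is.null(voxelSize)) voxelSize <- 10
  }
  n <- dim(region)[1]
  idx0 <- as.integer(floor(n / 2))     # 0-based centre
  idx1 <- idx0 + 1L
  empty <- matrix(0L, n, n)
  out <- lapply(c(x = "x", y = "y", z = "z"), function(ax) {
    m <- .sliceArray(region, ax, idx1)
    sec <- new("CrossSection", axis = ax, index = idx0,
               mask = matrix(as.integer(m), n, n),
               labels = if (is.null(labels)) empty else
                 matrix(as.integer(.sliceArray(labels, ax, idx1)), n, n),
               agentIds = if (is.null(agentIds)) empty else
                 matrix(as.integer(.sliceArray(agentIds, ax, idx1)), n, n),
               distance = matrix(NA_real_, n, n), voxelSize = voxelSize)
    sec@distance <- distanceMap(sec)
    sec
  })
  out
}

#' @describeIn tilsim-generics Euclidean distance-to-boundary map of a
#'   section: for every in-tumour pixel, the distance (um) to the nearest
#'   out-of-tumour pixel centre (so boundary-adjacent pixels carry
#'   \code{voxelSize}); NA outside the tumour mask. Computed with the exact
#'   Euclidean distance transform of \pkg{EBImage}.
#' @export
setMethod("distanceMap", "CrossSection", function(x, ...) {
  m <- x@mask
  out <- matrix(NA_real_, nrow(m), ncol(m))
  if (!any(m == 1L)) return(out)
  if (all(m == 1L)) { out[] <- Inf; return(out) }
  d <- as.matrix(EBImage::distmap(m, metric = "euclidean")) * x@voxelSize
  out[m == 1L] <- d[m == 1L]
  out
})

#' @describeIn tilsim-generics distance map of a bare binary matrix
#' @export
setMethod("distanceMap", "matrix", function(x, voxelSize = 10, ...) {
  sec <- new("CrossSection", axis = "z", index = 0L,
             mask = matrix(as.integer(x), nrow(x), ncol(x)),
             labels = matrix(0L, nrow(x), ncol(x)),
             agentIds = matrix(0L, nrow(x), ncol(x)),
             distance = matrix(NA_real_, nrow(x), ncol(x)),
             voxelSize = voxelSize)
  distanceMap(sec)
})

#' Rim mask at a depth threshold
#'
#' The rim is the set of in-tumour pixels within \code{thresholdUm} of the
#' tumour surface. Depth-to-surface is \code{distance - voxelSize}, so
#' boundary-adjacent pixels sit at depth 0 and \code{thresholdUm = 0} selects
#' exactly the boundary-adjacent layer. Rims are nested in the threshold.
#'
#' @param x a \linkS4class{CrossSection} or a distance-map matrix (um).
#' @param thresholdUm rim depth, um (>= 0).
#' @param voxelSize voxel edge, um; required when passing a bare matrix.
#' @return binary matrix, subset of the tumour mask.
#' @export
rimMask <- function(x, thresholdUm, voxelSize = NULL) {
  stopifnot(thresholdUm >= 0)
  if (is(x, "CrossSection")) {
    d <- x@distance
    voxelSize <- x@voxelSize
  } else {
    d <- x
    if (is.null(voxelSize)) stop("voxelSize required with a bare distance map")
  }
  out <- matrix(0L, nrow(d), ncol(d))
  out[!is.na(d) & (d - voxelSize) <= thresholdUm] <- 1L
  out
}

setMethod("show", "TumorMask", function(object) {
  cat(sprintf("TumorMask %s: %d raw voxels, %d smoothed, %d in tumour region\n",
              paste(dim(object@lRaw), collapse = "x"), sum(object@lRaw),
              sum(object@lSmooth), sum(object@region)))
})

setMethod("show", "CrossSection", function(object) {
  d <- object@distance[!is.na(object@distance)]
  cat(sprintf("CrossSection %s = %d: %d tumour pixels, max depth %.0f um\n",
              object@axis, object@index, sum(object@mask),
              if (length(d)) max(d) - object@voxelSize else NA_real_))
})
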