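#' IL-2 cytokine field
#'
#' A standalone reaction-diffusion field on the lattice, exposing the same
#' solver the engine uses internally: secretion sources, diffusion via a
#' Saul'yev-type alternating-direction-explicit (ADE) update (ascending and
#' descending sweeps averaged) and first-order decay applied as an exact
#' exponential factor. Faces are zero-flux, so with zero decay total mass is
#' conserved; for per-substep diffusion numbers a = D*dt/dx^2 <= 1/3 every
#' update coefficient is non-negative and the scheme preserves positivity.
#'
#' @slot grid numeric array of concentrations (arbitrary units/voxel).
#' @slot diffusionCoeff um^2/s.
#' @slot decayRate 1/h.
#' @slot secretionRate units/h per secreting cell.
#' @slot dx voxel edge, um.
#' @slot dtPde solver sub-step, seconds.
#' @export
setClass("CytokineField",
  representation(grid = "array", diffusionCoeff = "numeric",
                 decayRate = "numeric", secretionRate = "numeric",
                 dx = "numeric", dtPde = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@grid)) != 3) msg <- c(msg, "grid must be a 3D array")
    if (any(object@grid < 0)) msg <- c(msg, "concentrations must be >= 0")
    if (object@dx <= 0 || object@dtPde <= 0) msg <- c(msg, "dx and dtPde must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Create a cytokine field
#'
#' @param n lattice edge length (cubic grid), or a 3-vector of dimensions.
#' @param diffusionCoeff effective diffusivity, um^2/s.
#' @param decayRate decay rate, 1/h.
#' @param secretionRate secretion per source per hour.
#' @param dx voxel edge, um.
#' @param dtPde solver sub-step, seconds.
#' @return a \linkS4class{CytokineField} with an all-zero grid.
#' @examples
#' f <- cytokineField(20)
#' totalMass(f)
#' @export
cytokineField <- function(n, diffusionCoeff = 0.18, decayRate = log(2),
                          secretionRate = 1, dx = 10, dtPde = 180) {
  dims <- if (length(n) == 1) rep(as.integer(n), 3) else as.integer(n)
  new("CytokineField", grid = array(0, dim = dims),
      diffusionCoeff = diffusionCoeff, decayRate = decayRate,
      secretionRate = secretionRate, dx = dx, dtPde = dtPde)
}

#' Add secretion sources to a field
#'
#' Each secreting voxel gains \code{secretionRate * dtHours} units; the
#' update is linear in the number of sources.
#'
#' @param field a \linkS4class{CytokineField}.
#' @param voxels integer matrix of 1-based voxel coordinates (rows = sources;
#'   a voxel listed twice secretes twice).
#' @param dtHours secretion interval in hours.
#' @return the updated field.
#' @export
addSources <- function(field, voxels, dtHours) {
  if (is.null(voxels) || NROW(voxels) == 0) return(field)
  voxels <- matrix(as.integer(voxels), ncol = 3)
  dims <- dim(field@grid)
  if (any(voxels < 1) || any(voxels > matrix(dims, nrow(voxels), 3, byrow = TRUE)))
    stop("source voxel out of range")
  for (i in seq_len(nrow(voxels)))
    field@grid[voxels[i, 1], voxels[i, 2], voxels[i, 3]] <-
      field@grid[voxels[i, 1], voxels[i, 2], voxels[i, 3]] +
      field@secretionRate * dtHours
  field
}

#' One ADE diffusion/decay sub-step
#'
#' Advances the field by \code{dtPde} seconds: the two Saul'yev sweeps
#' (ascending then descending index order) are averaged, then decay is
#' applied as \code{exp(-decayRate * dt)}.
#'
#' @param field a \linkS4class{CytokineField}.
#' @param nSteps number of sub-steps to take.
#' @return the updated field.
#' @export
adeStep <- function(field, nSteps = 1L) {
  g <- field@grid
  for (i in seq_len(nSteps))
    g <- cppAdeStep(g, dim(g), field@diffusionCoeff, field@decayRate,
                    field@dx, field@dtPde)
  field@grid <- g
  field
}

#' Concentration at a single voxel
#'
#' @param field a \linkS4class{CytokineField}.
#' @param voxel 1-based integer coordinate triple.
#' @return the grid value at that voxel.
#' @export
localConcentration <- function(field, voxel) {
  voxel <- as.integer(voxel)
  dims <- dim(field@grid)
  if (length(voxel) != 3 || any(voxel < 1) || any(voxel > dims))
    stop("voxel out of range")
  field@grid[voxel[1], voxel[2], voxel[3]]
}

#' Total mass of a field
#'
#' @param field a \linkS4class{CytokineField}.
#' @return sum over all voxels.
#' @export
totalMass <- function(field) sum(field@grid)

setMethod("show", "CytokineField", function(object) {
  cat(sprintf("CytokineField: %s grid, D = %.3g um^2/s, decay = %.3g /h, mass = %.4g\n",
              paste(dim(object@grid), collapse = "x"), object@diffusionCoeff,
              object@decayRate, sum(object@grid)))
})
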