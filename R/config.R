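#' Create a lattice configuration
#'
#' @param nVoxels voxels per lattice edge (N >= 8). The reference domain is
#'   N = 100 at 10 um voxels, i.e. 1 mm^3 / one million voxels.
#' @param voxelSize voxel edge length in um (the T-cell diameter).
#' @param durationDays simulated duration in days.
#' @param dtHours hours per agent step. The default 0.25 h lets a 1 um/min
#'   T cell make about 1.5 lattice moves per step.
#' @param pdeSubsteps IL-2 diffusion sub-steps per agent step; the default 5
#'   keeps the per-substep diffusion number D*dt/dx^2 at or below 1/3 for the
#'   default diffusivity, where the two-sweep solver is positivity-preserving.
#' @param pdeCoarsen solve the IL-2 field on an (N/f)^3 grid (must divide
#'   \code{nVoxels}); 1 = full cell resolution.
#' @return a \linkS4class{LatticeConfig}.
#' @examples
#' latticeConfig(nVoxels = 50, durationDays = 10)
#' @export
latticeConfig <- function(nVoxels = 100L, voxelSize = 10, durationDays = 50,
                          dtHours = 0.25, pdeSubsteps = 5L, pdeCoarsen = 1L) {
  new("LatticeConfig", nVoxels = as.integer(nVoxels), voxelSize = voxelSize,
      durationDays = durationDays, dtHours = dtHours,
      pdeSubsteps = as.integer(pdeSubsteps),
      pdeCoarsen = as.integer(pdeCoarsen))
}

.defaultParamsCache <- new.env(parent = emptyenv())

#' Default rule parameters from the shipped config file
#'
#' Reads (and caches) the versioned default parameter file
#' \code{inst/extdata/default_params.yaml}.
#'
#' @return a named list of raw default values.
#' @export
defaultParameterList <- function() {
  if (is.null(.defaultParamsCache$values)) {
    path <- system.file("extdata", "default_params.yaml", package = "tilsim")
    vals <- yaml::read_yaml(path)
    if (!identical(vals$schema, "tilsim-params") || !identical(vals$schema_version, 1L))
      stop("unsupported parameter file schema: ", vals$schema, " v", vals$schema_version)
    vals$schema <- NULL
    vals$schema_version <- NULL
    .defaultParamsCache$values <- vals
  }
  .defaultParamsCache$values
}

#' Create rule parameters
#'
#' Starts from the shipped defaults (\code{\link{defaultParameterList}}) and
#' applies any named overrides. See \linkS4class{RuleParameters} for the
#' meaning and units of every field.
#'
#' @param ... named overrides, e.g. \code{ruleParameters(kA = 10, kI = 0.001)}.
#' @return a validated \linkS4class{RuleParameters}.
#' @examples
#' p <- ruleParameters(kA = 10)
#' p@kA
#' @export
ruleParameters <- function(...) {
  vals <- defaultParameterList()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("overrides must be named")
    unknown <- setdiff(names(over), names(vals))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    vals[names(over)] <- over
  }
  new("RuleParameters",
      pKillNeg = vals$pKillNeg, pKillPos = vals$pKillPos,
      pPdl1Induction = vals$pPdl1Induction,
      inductionOnContact = isTRUE(vals$inductionOnContact),
      pSupp = vals$pSupp, il2DivisionThreshold = vals$il2DivisionThreshold,
      tCellSpeed = vals$tCellSpeed, cancerSpeed = vals$cancerSpeed,
      cancerCycleTime = vals$cancerCycleTime, tCellCycleTime = vals$tCellCycleTime,
      tCellLifespan = vals$tCellLifespan, deadClearanceTime = vals$deadClearanceTime,
      pNecrosis = vals$pNecrosis, kA = vals$kA, kI = vals$kI,
      rBase = vals$rBase, lambdaVasc = vals$lambdaVasc,
      baseDensity = vals$baseDensity,
      maxTCellDivisions = as.integer(vals$maxTCellDivisions),
      diffusionCoeff = vals$diffusionCoeff, decayRate = vals$decayRate,
      secretionRate = vals$secretionRate)
}

#' Create an anti-PDL1 treatment schedule
#'
#' From \code{startDay} onward the suppression probability of cytotoxic
#' T cells by PDL1+ cancer cells is rescaled to \code{pSupp * (1 - mSupp)}.
#'
#' @param startDay treatment start in days (default 30).
#' @param mSupp fractional reduction of the suppression probability in
#'   [0, 1] (default 0.8).
#' @param enabled logical.
#' @return a \linkS4class{TreatmentSchedule}.
#' @export
treatmentSchedule <- function(startDay = 30, mSupp = 0.8, enabled = TRUE) {
  new("TreatmentSchedule", startDay = startDay, mSupp = mSupp,
      enabled = isTRUE(enabled))
}

#' Effective suppression probability under checkpoint blockade
#'
#' @param pSupp untreated suppression probability in [0, 1].
#' @param schedule a \linkS4class{TreatmentSchedule}.
#' @param tDays simulated time in days (vectorized).
#' @return numeric vector of effective probabilities, in [0, pSupp].
#' @examples
#' effectiveSuppProb(0.5, treatmentSchedule(startDay = 30, mSupp = 0.8), c(29.9, 30))
#' @export
effectiveSuppProb <- function(pSupp, schedule, tDays) {
  stopifnot(pSupp >= 0, pSupp <= 1)
  ifelse(schedule@enabled & tDays >= schedule@startDay,
         pSupp * (1 - schedule@mSupp), pSupp)
}

# flatten everything the C++ engine needs into one list
.engineParams <- function(config, params, treatment) {
  list(dtHours = config@dtHours, voxelSize = config@voxelSize,
       pdeSubsteps = config@pdeSubsteps, pdeCoarsen = config@pdeCoarsen,
       pKillNeg = params@pKillNeg, pKillPos = params@pKillPos,
       pPdl1Induction = params@pPdl1Induction,
       inductionOnContact = params@inductionOnContact,
       pSupp = params@pSupp, il2DivisionThreshold = params@il2DivisionThreshold,
       tCellSpeed = params@tCellSpeed, cancerSpeed = params@cancerSpeed,
       cancerCycleTime = params@cancerCycleTime,
       tCellCycleTime = params@tCellCycleTime,
       tCellLifespan = params@tCellLifespan,
       deadClearanceTime = params@deadClearanceTime,
       pNecrosis = params@pNecrosis,
       maxTCellDivisions = params@maxTCellDivisions,
       kA = params@kA, kI = params@kI, rBase = params@rBase,
       diffusionCoeff = params@diffusionCoeff, decayRate = params@decayRate,
       secretionRate = params@secretionRate,
       treatmentEnabled = treatment@enabled,
       treatmentStartDay = treatment@startDay, mSupp = treatment@mSupp)
}

#' @describeIn tilsim-generics show method
setMethod("show", "LatticeConfig", function(object) {
  cat(sprintf("LatticeConfig: %d^3 voxels (%.0f um), %.3g days, dt = %.3g h, %d PDE substeps\n",
              object@nVoxels, object@voxelSize, object@durationDays,
              object@dtHours, object@pdeSubsteps))
})

setMethod("show", "RuleParameters", function(object) {
  cat("RuleParameters\n")
  cat(sprintf("  kill: PDL1- %.3g | PDL1+ %.3g; induction %.3g (%s); suppression %.3g\n",
              object@pKillNeg, object@pKillPos, object@pPdl1Induction,
              if (object@inductionOnContact) "on contact" else "on failed attempt",
              object@pSupp))
  cat(sprintf("  neoantigen profile: kA = %.3g, kI = %.3g; rBase = %.3g /h\n",
              object@kA, object@kI, object@rBase))
  cat(sprintf("  cycles (h): cancer %.3g, T %.3g; speeds (um/min): cancer %.3g, T %.3g\n",
              object@cancerCycleTime, object@tCellCycleTime,
              object@cancerSpeed, object@tCellSpeed))
  cat(sprintf("  IL-2: D %.3g um^2/s, decay %.3g /h, secretion %.3g /h, division threshold %.3g\n",
              object@diffusionCoeff, object@decayRate, object@secretionRate,
              object@il2DivisionThreshold))
})

setMethod("show", "TreatmentSchedule", function(object) {
  cat(sprintf("TreatmentSchedule: %s, start day %.3g, mSupp %.3g\n",
              if (object@enabled) "enabled" else "disabled",
              object@startDay, object@mSupp))
})
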