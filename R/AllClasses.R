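#' Lattice configuration
#'
#' Geometry and time discretization of the simulation domain: a cubic lattice
#' of \code{nVoxels} voxels per edge, each voxel \code{voxelSize} um across
#' (the T-cell diameter, so T cells occupy one voxel and cancer cells an
#' aligned 2x2x2 block). The agent-based clock advances in steps of
#' \code{dtHours}; the IL-2 diffusion solver is sub-stepped
#' \code{pdeSubsteps} times per agent step.
#'
#' @slot nVoxels integer, voxels per lattice edge (N); the default N = 100
#'   with 10 um voxels gives the 1 mm^3 / 1 million voxel reference domain.
#' @slot voxelSize numeric, voxel edge length in um.
#' @slot durationDays numeric, simulated duration in days.
#' @slot dtHours numeric, hours per agent-based step.
#' @slot pdeSubsteps integer, diffusion sub-steps per agent step.
#' @slot pdeCoarsen integer f >= 1: the IL-2 field is solved on an (N/f)^3
#'   grid (f must divide N). Grid values are concentrations per cell-lattice
#'   voxel, so secretion, decay and the division threshold are
#'   f-independent; f = 1 solves at full cell resolution. Coarsening by 2 is
#'   accurate to about the IL-2 paracrine range while cutting solver cost
#'   eightfold.
#' @export
setClass("LatticeConfig",
  representation(nVoxels = "integer", voxelSize = "numeric",
                 durationDays = "numeric", dtHours = "numeric",
                 pdeSubsteps = "integer", pdeCoarsen = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nVoxels < 8L) msg <- c(msg, "nVoxels must be >= 8")
    if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
    if (object@dtHours <= 0) msg <- c(msg, "dtHours must be > 0")
    if (object@durationDays < 0) msg <- c(msg, "durationDays must be >= 0")
    if (object@pdeSubsteps < 1L) msg <- c(msg, "pdeSubsteps must be >= 1")
    if (object@pdeCoarsen < 1L) msg <- c(msg, "pdeCoarsen must be >= 1")
    if (object@nVoxels %% object@pdeCoarsen != 0L)
      msg <- c(msg, "pdeCoarsen must divide nVoxels")
    if (length(msg)) msg else TRUE
  })

#' Stochastic rule parameters
#'
#' Per-event probabilities and rates governing the agent rules, plus the
#' neoantigen profile and the IL-2 field constants. All probabilities are per
#' agent step (of \code{dtHours}); speeds are um/min; times are hours.
#' Defaults are read from the versioned config file shipped at
#' \code{inst/extdata/default_params.yaml} and are calibrated so that the
#' baseline profile (kA = 20, kI = 0.1) shows T-cell arrival around day 10,
#' a slowdown of tumour growth and the emergence of PDL1+ cancer cells.
#'
#' @slot pKillNeg probability a cytotoxic T cell kills an adjacent PDL1-
#'   cancer cell per contact step.
#' @slot pKillPos same for PDL1+ targets; must be <= \code{pKillNeg}.
#' @slot pPdl1Induction probability a PDL1- cancer cell surviving a kill
#'   attempt converts to PDL1+.
#' @slot inductionOnContact logical; if TRUE induction is drawn on every
#'   contact instead of being conditioned on a failed kill attempt.
#' @slot pSupp probability a PDL1+ cancer cell suppresses an adjacent
#'   cytotoxic T cell per contact step.
#' @slot il2DivisionThreshold local IL-2 concentration (units/voxel) gating
#'   T-cell division.
#' @slot tCellSpeed,cancerSpeed migration speeds, um/min.
#' @slot cancerCycleTime,tCellCycleTime division cooldowns, hours.
#' @slot tCellLifespan T-cell lifespan, hours.
#' @slot deadClearanceTime hours a dead cancer cell occupies its block.
#' @slot pNecrosis probability that a contact-inhibited cancer cell (one
#'   whose division attempt finds no free adjacent block) dies at that
#'   attempt. This necrotic-core turnover seeds the dead-cell signal that
#'   bootstraps recruitment while leaving small, uncrowded tumours safe from
#'   stochastic extinction.
#' @slot kA mutational burden (dimensionless, > 0).
#' @slot kI antigen strength (dimensionless, > 0).
#' @slot rBase baseline recruitment rate scale (cells/hour per unit kA at
#'   dead-cell-signal saturation).
#' @slot lambdaVasc vascular density decay length scale, 1/um.
#' @slot baseDensity entry-point probability per voxel at zero depth.
#' @slot maxTCellDivisions replicative limit for T cells.
#' @slot diffusionCoeff effective IL-2 diffusivity, um^2/s.
#' @slot decayRate IL-2 decay rate, 1/h.
#' @slot secretionRate IL-2 secretion per cytotoxic T cell, units/h.
#' @export
setClass("RuleParameters",
  representation(pKillNeg = "numeric", pKillPos = "numeric",
                 pPdl1Induction = "numeric", inductionOnContact = "logical",
                 pSupp = "numeric", il2DivisionThreshold = "numeric",
                 tCellSpeed = "numeric", cancerSpeed = "numeric",
                 cancerCycleTime = "numeric", tCellCycleTime = "numeric",
                 tCellLifespan = "numeric", deadClearanceTime = "numeric",
                 pNecrosis = "numeric", kA = "numeric", kI = "numeric",
                 rBase = "numeric", lambdaVasc = "numeric",
                 baseDensity = "numeric", maxTCellDivisions = "integer",
                 diffusionCoeff = "numeric", decayRate = "numeric",
                 secretionRate = "numeric"),
  validity = function(object) {
    msg <- character()
    probs <- c(pKillNeg = object@pKillNeg, pKillPos = object@pKillPos,
               pPdl1Induction = object@pPdl1Induction, pSupp = object@pSupp,
               baseDensity = object@baseDensity)
    bad <- probs < 0 | probs > 1
    if (any(bad)) msg <- c(msg, paste0("probabilities out of [0,1]: ",
                                       paste(names(probs)[bad], collapse = ", ")))
    if (object@pKillPos > object@pKillNeg) msg <- c(msg, "pKillPos must be <= pKillNeg")
    if (object@tCellSpeed < 0 || object@cancerSpeed < 0) msg <- c(msg, "speeds must be >= 0")
    if (object@kA <= 0) msg <- c(msg, "kA must be > 0")
    if (object@kI <= 0) msg <- c(msg, "kI must be > 0")
    if (object@lambdaVasc < 0) msg <- c(msg, "lambdaVasc must be >= 0")
    if (object@diffusionCoeff < 0 || object@decayRate < 0 || object@secretionRate < 0)
      msg <- c(msg, "cytokine constants must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Anti-PDL1 treatment schedule
#'
#' Checkpoint blockade is modelled as a rescaling of the suppression
#' probability: from \code{startDay} onward the per-contact probability of a
#' PDL1+ cancer cell suppressing a cytotoxic T cell becomes
#' \code{pSupp * (1 - mSupp)}. The kill probabilities are untouched; the
#' residual \code{1 - mSupp} represents incomplete blocking (e.g. PDL2).
#'
#' @slot startDay treatment start, days.
#' @slot mSupp suppression reduction fraction in [0, 1].
#' @slot enabled logical flag.
#' @export
setClass("TreatmentSchedule",
  representation(startDay = "numeric", mSupp = "numeric", enabled = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@mSupp < 0 || object@mSupp > 1) msg <- c(msg, "mSupp must be in [0,1]")
    if (object@startDay < 0) msg <- c(msg, "startDay must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' T-cell entry points derived from tumour vasculature
#'
#' Each voxel at depth d (distance in um from the nearest lattice face) is an
#' entry point independently with probability
#' \code{baseDensity * exp(-lambdaVasc * d)}: lambda near 1/3200 1/um gives
#' near-uniform perfusion, lambda near 1/25 1/um restricts entries to a thin
#' boundary shell.
#'
#' @slot entryVoxels integer vector of 0-based linear voxel indices.
#' @slot lambdaVasc decay constant, 1/um.
#' @slot baseDensity entry probability at depth 0.
#' @slot nVoxels lattice edge length the map was built for.
#' @slot voxelSize voxel edge, um.
#' @slot referenceDepth annotation depth (um) used when reporting density
#'   profiles; does not affect placement.
#' @export
setClass("VasculatureMap",
  representation(entryVoxels = "integer", lambdaVasc = "numeric",
                 baseDensity = "numeric", nVoxels = "integer",
                 voxelSize = "numeric", referenceDepth = "numeric"),
  validity = function(object) {
    n3 <- as.double(object@nVoxels)^3
    if (length(object@entryVoxels) &&
        (min(object@entryVoxels) < 0 || max(object@entryVoxels) >= n3))
      "entryVoxels out of lattice range" else TRUE
  })

#' Full simulation state
#'
#' The mutable state of a run: lattice occupancy (voxel -> agent row index,
#' 0 = empty), the agent registry, the IL-2 grid, the clock, cumulative
#' dead-cancer signal and the per-step time series / event ledger recorded so
#' far. Occupancy and registry are mutually consistent: repainting every
#' agent's block reproduces the occupancy index exactly (checked by
#' \code{\link{validateState}}).
#'
#' @slot occupancy integer N^3 array, agent row index + 0 for empty.
#' @slot agents data.frame with columns state, x, y, z (0-based anchors),
#'   cooldown, age, deadTimer, divisions.
#' @slot cytokine numeric N^3 array of IL-2 concentrations.
#' @slot clockHours simulated time.
#' @slot cumulativeDeadCancer cumulative dead cancer cells (any cause).
#' @slot forfeitedArrivals recruitment arrivals lost to fully occupied entry
#'   sets.
#' @slot config,params,treatment,vasculature run inputs.
#' @slot timeSeries per-step state counts (see \code{\link{timeSeries}}).
#' @slot eventLog per-step event counts.
#' @export
setClass("SimulationState",
  representation(occupancy = "array", agents = "data.frame", cytokine = "array",
                 clockHours = "numeric", cumulativeDeadCancer = "numeric",
                 forfeitedArrivals = "numeric", config = "LatticeConfig",
                 params = "RuleParameters", treatment = "TreatmentSchedule",
                 vasculature = "VasculatureMap", timeSeries = "data.frame",
                 eventLog = "data.frame"))

#' Result of a completed simulation run
#'
#' @slot timeSeries data.frame, one row per step (including step 0) with
#'   counts of each cell state and total IL-2 mass.
#' @slot eventLog data.frame, one row per executed step with per-step event
#'   counts (recruits, kills, suppressions, inductions, divisions, ...).
#' @slot snapshots named list (by recorded day) of lists with elements
#'   \code{day}, \code{labels} (N^3 state-code array), \code{agentIds}
#'   (N^3 agent-index array) and \code{cytokine}.
#' @slot finalState the \linkS4class{SimulationState} at the end of the run.
#' @slot seed integer seed the run was started from.
#' @export
setClass("SimulationResult",
  representation(timeSeries = "data.frame", eventLog = "data.frame",
                 snapshots = "list", finalState = "SimulationState",
                 seed = "integer"))

#' Smoothed tumour mask volumes
#'
#' Holds the three binary volumes of the spatial pipeline: the raw cancer
#' occupancy labels \code{lRaw}, the 3x3x3 box-smoothed volume
#' \code{lSmooth}, and the tumour region obtained by flood-filling the
#' edge-connected background of \code{lSmooth} and taking the complement
#' (sealed internal cavities therefore belong to the tumour).
#'
#' @slot lRaw,lSmooth,region binary integer arrays of identical dimension.
#' @slot voxelSize voxel edge, um.
#' @export
setClass("TumorMask",
  representation(lRaw = "array", lSmooth = "array", region = "array",
                 voxelSize = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@lRaw), dim(object@lSmooth)) ||
        !identical(dim(object@lRaw), dim(object@region)))
      return("volume dimensions differ")
    if (!all(object@lRaw %in% 0:1)) return("lRaw must be binary")
    TRUE
  })

#' Central tumour cross section
#'
#' A 2D slice of the tumour region through the lattice centre, perpendicular
#' to one axis, carrying the tumour mask, the per-pixel cell-state labels,
#' agent identities (for agent-level rim counting) and the Euclidean
#' distance-to-boundary map in um (NA outside the tumour mask; the distance
#' of an in-tumour pixel is measured to the nearest background pixel centre,
#' so boundary-adjacent pixels carry \code{voxelSize}).
#'
#' @slot axis "x", "y" or "z".
#' @slot index 0-based slice index, floor(N/2).
#' @slot mask binary tumour matrix.
#' @slot labels integer matrix of cell-state codes (0 empty, 1 PDL1-,
#'   2 PDL1+, 3 dead cancer, 4 effector, 5 cytotoxic, 6 suppressed).
#' @slot agentIds integer matrix of agent indices (0 = empty).
#' @slot distance numeric matrix, um, NA outside the mask.
#' @slot voxelSize voxel edge, um.
#' @export
setClass("CrossSection",
  representation(axis = "character", index = "integer", mask = "matrix",
                 labels = "matrix", agentIds = "matrix", distance = "matrix",
                 voxelSize = "numeric"))

#' Rim-restricted PDL1 score
#'
#' Fraction of living cancer cells within \code{thresholdUm} of the tumour
#' surface that are PDL1+, per cross section and aggregated (mean over the
#' sections with a defined score). Sections whose rim contains no living
#' cancer cell are flagged undefined (NA).
#'
#' @slot thresholdUm rim depth, um.
#' @slot perSection named numeric vector of per-section scores (NA when
#'   undefined).
#' @slot score aggregate score (mean of defined sections; NA if none).
#' @slot counting "agent" or "voxel".
#' @export
setClass("RimScore",
  representation(thresholdUm = "numeric", perSection = "numeric",
                 score = "numeric", counting = "character"))

#' Latin hypercube sensitivity design
#'
#' @slot ranges named list of c(low, high) uniform marginal ranges.
#' @slot nSamples number of parameter combinations.
#' @slot nReplicates stochastic replicates per combination.
#' @slot seed integer seed.
#' @export
setClass("SensitivityDesign",
  representation(ranges = "list", nSamples = "integer",
                 nReplicates = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSamples < 2L) msg <- c(msg, "nSamples must be >= 2")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (!length(object@ranges) || is.null(names(object@ranges)) ||
        any(!nzchar(names(object@ranges))))
      msg <- c(msg, "ranges must be a named list")
    for (nm in names(object@ranges)) {
      r <- object@ranges[[nm]]
      if (length(r) != 2 || !(r[1] < r[2]))
        msg <- c(msg, sprintf("range for '%s' must satisfy low < high", nm))
    }
    if (length(msg)) msg else TRUE
  })
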