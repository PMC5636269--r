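#' Cell-state codes used on the lattice
#'
#' Named integer vector mapping state names to the voxel codes used in
#' occupancy snapshots: 0 empty, 1 PDL1- cancer, 2 PDL1+ cancer, 3 dead
#' cancer, 4 effector T, 5 cytotoxic T, 6 suppressed T.
#' @export
stateCodes <- c(empty = 0L, pdl1neg = 1L, pdl1pos = 2L, deadCancer = 3L,
                effector = 4L, cytotoxic = 5L, suppressed = 6L)

.emptyAgents <- function() {
  data.frame(state = integer(), x = integer(), y = integer(), z = integer(),
             cooldown = numeric(), age = numeric(), deadTimer = numeric(),
             divisions = integer())
}

.emptyTimeSeries <- function() {
  data.frame(step = integer(), timeDays = numeric(), pdl1neg = numeric(),
             pdl1pos = numeric(), deadCancer = numeric(), effector = numeric(),
             cytotoxic = numeric(), suppressed = numeric(), il2Mass = numeric())
}

.tsRow <- function(step, timeDays, counts) {
  data.frame(step = step, timeDays = timeDays,
             pdl1neg = counts[1], pdl1pos = counts[2], deadCancer = counts[3],
             effector = counts[4], cytotoxic = counts[5], suppressed = counts[6],
             il2Mass = counts[7])
}

.countsFromAgents <- function(agents, cytokineGrid) {
  c(sum(agents$state == 1L), sum(agents$state == 2L), sum(agents$state == 3L),
    sum(agents$state == 4L), sum(agents$state == 5L), sum(agents$state == 6L),
    sum(cytokineGrid))
}

# paint all agent blocks into a fresh occupancy array (1-based agent rows)
.rebuildOccupancy <- function(agents, n) {
  occ <- array(0L, dim = c(n, n, n))
  if (!nrow(agents)) return(occ)
  edge <- ifelse(agents$state <= 3L, 2L, 1L)
  for (i in seq_len(nrow(agents))) {
    e <- edge[i]
    xs <- agents$x[i] + seq_len(e); ys <- agents$y[i] + seq_len(e)
    zs <- agents$z[i] + seq_len(e)
    occ[xs, ys, zs] <- i
  }
  occ
}

#' Initialize a simulation
#'
#' Places a single PDL1- cancer cell at the lattice centre block (voxels
#' \code{floor(N/2)-1 .. floor(N/2)} per axis, 0-based), an all-zero IL-2
#' field, no T cells, and draws the vasculature entry points. Identical
#' seeds give identical states.
#'
#' @param config a \linkS4class{LatticeConfig}.
#' @param params a \linkS4class{RuleParameters}.
#' @param seed integer seed; set before any randomness is consumed.
#' @param treatment optional \linkS4class{TreatmentSchedule}; default disabled.
#' @param vasculature optional precomputed \linkS4class{VasculatureMap};
#'   by default drawn from \code{params@lambdaVasc} / \code{params@baseDensity}.
#' @param seedCancer place the founding cancer cell (default TRUE); FALSE
#'   gives an empty lattice, useful for constructing custom states with
#'   \code{\link{placeAgents}}.
#' @return a \linkS4class{SimulationState} at clock 0.
#' @examples
#' st <- initializeSimulation(latticeConfig(nVoxels = 20), ruleParameters(), seed = 1)
#' nrow(agents(st))
#' @export
initializeSimulation <- function(config, params, seed,
                                 treatment = treatmentSchedule(enabled = FALSE),
                                 vasculature = NULL, seedCancer = TRUE) {
  validObject(config); validObject(params); validObject(treatment)
  n <- config@nVoxels
  if (n < 8L) stop("lattice too small to host the seed cancer block")
  set.seed(as.integer(seed))
  if (is.null(vasculature))
    vasculature <- placeEntryPoints(config, params@lambdaVasc, params@baseDensity)
  anchor <- as.integer(floor(n / 2) - 1)  # 0-based; block {anchor, anchor+1}^3
  agents <- if (seedCancer)
    data.frame(state = 1L, x = anchor, y = anchor, z = anchor,
               cooldown = params@cancerCycleTime, age = 0,
               deadTimer = 0, divisions = 0L)
  else .emptyAgents()
  occ <- .rebuildOccupancy(agents, n)
  nc <- n %/% config@pdeCoarsen
  cyto <- array(0, dim = c(nc, nc, nc))
  ts <- .tsRow(0L, 0, .countsFromAgents(agents, cyto))
  new("SimulationState", occupancy = occ, agents = agents, cytokine = cyto,
      clockHours = 0, cumulativeDeadCancer = 0, forfeitedArrivals = 0,
      config = config, params = params, treatment = treatment,
      vasculature = vasculature, timeSeries = ts,
      eventLog = data.frame())
}

.stateToList <- function(state) {
  list(n = state@config@nVoxels,
       occupancy = state@occupancy,
       agents = as.list(state@agents),
       cytokine = state@cytokine,
       entryVoxels = state@vasculature@entryVoxels,
       clockHours = state@clockHours,
       cumulativeDeadCancer = state@cumulativeDeadCancer,
       forfeitedArrivals = state@forfeitedArrivals)
}

.phaseNames <- c("recruitment", "cytokine", "contacts", "division",
                 "migration", "clearance")

.runPhases <- function(state, steps, phases, advanceClock,
                       snapshotSteps = integer(0)) {
  keep <- .phaseNames %in% phases
  res <- cppRun(.stateToList(state), .engineParams(state@config, state@params,
                                                   state@treatment),
                as.integer(steps), as.integer(snapshotSteps), keep,
                isTRUE(advanceClock))
  agents <- as.data.frame(res$agents)
  out <- state
  out@occupancy <- res$occupancy
  out@agents <- agents
  out@cytokine <- res$cytokine
  out@clockHours <- res$clockHours
  out@cumulativeDeadCancer <- res$cumulativeDeadCancer
  out@forfeitedArrivals <- res$forfeitedArrivals
  ts <- as.data.frame(res$timeSeries)
  ev <- as.data.frame(res$events)
  prevSteps <- if (nrow(state@timeSeries)) max(state@timeSeries$step) else 0L
  ts <- cbind(step = prevSteps + seq_len(nrow(ts)),
              timeDays = (state@clockHours +
                          seq_len(nrow(ts)) * state@config@dtHours *
                          as.numeric(advanceClock)) / 24,
              ts)
  ev <- cbind(step = prevSteps + seq_len(nrow(ev)), ev)
  out@timeSeries <- rbind(state@timeSeries, ts)
  out@eventLog <- rbind(state@eventLog, ev)
  attr(out, "engineRaw") <- res
  out
}

#' Advance a simulation by whole steps
#'
#' Executes \code{steps} agent steps with the fixed sub-phase order:
#' recruitment, IL-2 secretion/diffusion/decay, contact interactions,
#' divisions, migration, death/clearance. Within each sub-phase agents are
#' processed in a freshly shuffled order.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param steps number of steps of \code{dtHours} each.
#' @return the advanced state, with time series and event log appended.
#' @export
stepSimulation <- function(state, steps = 1L) {
  .runPhases(state, steps, .phaseNames, advanceClock = TRUE)
}

#' Run individual engine sub-phases
#'
#' Single sub-phases of the engine step, exposed for inspection and testing.
#' None of these advance the clock. \code{contactInteractions} performs
#' activation, kill attempts, PDL1 induction and suppression draws;
#' \code{proliferate} the division sub-phase (cooldowns are decremented
#' here); \code{migrate} the random-walk migration sub-phase;
#' \code{recruitStep} the vascular recruitment sub-phase;
#' \code{cytokineStep} IL-2 secretion plus diffusion/decay;
#' \code{clearanceStep} death, spontaneous cancer death and dead-cell
#' clearance.
#'
#' @param state a \linkS4class{SimulationState}.
#' @return the updated state.
#' @export
contactInteractions <- function(state) .runPhases(state, 1L, "contacts", FALSE)

#' @rdname contactInteractions
#' @export
proliferate <- function(state) .runPhases(state, 1L, "division", FALSE)

#' @rdname contactInteractions
#' @export
migrate <- function(state) .runPhases(state, 1L, "migration", FALSE)

#' @rdname contactInteractions
#' @export
recruitStep <- function(state) .runPhases(state, 1L, "recruitment", FALSE)

#' @rdname contactInteractions
#' @export
cytokineStep <- function(state) .runPhases(state, 1L, "cytokine", FALSE)

#' @rdname contactInteractions
#' @export
clearanceStep <- function(state) .runPhases(state, 1L, "clearance", FALSE)

#' Run a full simulation
#'
#' Initializes from \code{seed} and integrates over
#' \code{config@durationDays}, recording occupancy/cytokine snapshots at the
#' requested days. Runs are fully reproducible: the same inputs and seed give
#' bit-identical trajectories.
#'
#' @inheritParams initializeSimulation
#' @param recordDays numeric vector of days at which to keep snapshots
#'   (rounded to the nearest step; day 0 is the initial state).
#' @return a \linkS4class{SimulationResult}.
#' @examples
#' res <- runSimulation(latticeConfig(nVoxels = 20, durationDays = 2),
#'                      ruleParameters(), seed = 7, recordDays = 2)
#' head(timeSeries(res))
#' @export
runSimulation <- function(config, params, seed,
                          treatment = treatmentSchedule(enabled = FALSE),
                          recordDays = numeric(0), vasculature = NULL) {
  state <- initializeSimulation(config, params, seed, treatment, vasculature)
  nSteps <- as.integer(round(config@durationDays * 24 / config@dtHours))
  recordDays <- sort(unique(recordDays))
  if (length(recordDays) && max(recordDays) > config@durationDays + 1e-9)
    stop("recordDays must lie within the simulated duration")
  snaps <- list()
  dayAt <- function(day) as.integer(round(day * 24 / config@dtHours))
  if (any(recordDays == 0)) {
    snaps[["day0"]] <- list(day = 0, labels = .labelsFromState(state),
                            agentIds = state@occupancy,
                            cytokine = state@cytokine)
  }
  posDays <- recordDays[recordDays > 0]
  snapSteps <- vapply(posDays, dayAt, integer(1))
  if (nSteps > 0) {
    state <- .runPhases(state, nSteps, .phaseNames, TRUE, snapshotSteps = snapSteps)
    raw <- attr(state, "engineRaw")
    for (i in seq_along(posDays)) {
      snaps[[paste0("day", posDays[i])]] <-
        list(day = posDays[i], labels = raw$snapshotLabels[[i]],
             agentIds = raw$snapshotIds[[i]], cytokine = raw$snapshotCytokine[[i]])
    }
  }
  attr(state, "engineRaw") <- NULL
  new("SimulationResult", timeSeries = state@timeSeries,
      eventLog = state@eventLog, snapshots = snaps, finalState = state,
      seed = as.integer(seed))
}

.labelsFromState <- function(state) {
  lab <- state@occupancy
  nz <- lab != 0L
  lab[nz] <- state@agents$state[lab[nz]]
  lab
}

#' Place additional agents into a state
#'
#' Adds agents at explicit anchors, for constructing controlled
#' configurations (contact pairs, lone walkers, phantoms). Cancer states
#' (codes 1-3) occupy an aligned 2x2x2 block at the anchor; T states (4-6) a
#' single voxel. Placement onto occupied voxels or outside the lattice is an
#' error.
#'
#' @param state a \linkS4class{SimulationState}.
#' @param newAgents data.frame with columns \code{state}, \code{x}, \code{y},
#'   \code{z} (0-based anchors) and optionally \code{cooldown}, \code{age},
#'   \code{deadTimer}, \code{divisions}.
#' @return the updated state.
#' @export
placeAgents <- function(state, newAgents) {
  stopifnot(all(c("state", "x", "y", "z") %in% names(newAgents)))
  p <- state@params
  df <- data.frame(state = as.integer(newAgents$state),
                   x = as.integer(newAgents$x), y = as.integer(newAgents$y),
                   z = as.integer(newAgents$z),
                   cooldown = if ("cooldown" %in% names(newAgents))
                     newAgents$cooldown else
                     ifelse(newAgents$state <= 3L, p@cancerCycleTime,
                            p@tCellCycleTime),
                   age = if ("age" %in% names(newAgents)) newAgents$age else 0,
                   deadTimer = if ("deadTimer" %in% names(newAgents))
                     newAgents$deadTimer else
                     ifelse(newAgents$state == 3L, p@deadClearanceTime, 0),
                   divisions = if ("divisions" %in% names(newAgents))
                     as.integer(newAgents$divisions) else 0L)
  if (!all(df$state %in% 1:6)) stop("invalid state code")
  n <- state@config@nVoxels
  occ <- state@occupancy
  base <- nrow(state@agents)
  for (i in seq_len(nrow(df))) {
    e <- if (df$state[i] <= 3L) 2L else 1L
    if (df$x[i] < 0 || df$y[i] < 0 || df$z[i] < 0 ||
        df$x[i] + e > n || df$y[i] + e > n || df$z[i] + e > n)
      stop("agent block outside the lattice")
    xs <- df$x[i] + seq_len(e); ys <- df$y[i] + seq_len(e); zs <- df$z[i] + seq_len(e)
    if (any(occ[xs, ys, zs] != 0L)) stop("placement collides with an occupied voxel")
    occ[xs, ys, zs] <- base + i
  }
  out <- state
  out@agents <- rbind(state@agents, df)
  out@occupancy <- occ
  ts <- out@timeSeries
  if (nrow(ts)) {
    cnt <- .countsFromAgents(out@agents, out@cytokine)
    ts[nrow(ts), 3:9] <- as.list(cnt)
    out@timeSeries <- ts
  }
  out
}

#' Verify occupancy/registry consistency of a state
#'
#' Repaints every agent block into a fresh occupancy array and compares with
#' the state's index; also audits basic count invariants. Throws an
#' informative error on any inconsistency (states are never silently
#' repaired).
#'
#' @param state a \linkS4class{SimulationState}.
#' @return invisibly TRUE.
#' @export
validateState <- function(state) {
  n <- state@config@nVoxels
  rebuilt <- .rebuildOccupancy(state@agents, n)
  if (!identical(as.integer(rebuilt), as.integer(state@occupancy)))
    stop("state integrity error: occupancy index does not match agent registry")
  if (nrow(state@agents)) {
    e <- ifelse(state@agents$state <= 3L, 2L, 1L)
    if (any(state@agents$x < 0 | state@agents$x + e > n |
            state@agents$y < 0 | state@agents$y + e > n |
            state@agents$z < 0 | state@agents$z + e > n))
      stop("state integrity error: agent block outside the lattice")
  }
  if (any(state@cytokine < 0))
    stop("state integrity error: negative IL-2 concentration")
  invisible(TRUE)
}

#' @describeIn tilsim-generics time series of a result
#' @export
setMethod("timeSeries", "SimulationResult", function(object, ...) object@timeSeries)

#' @describeIn tilsim-generics time series recorded so far in a state
#' @export
setMethod("timeSeries", "SimulationState", function(object, ...) object@timeSeries)

#' @describeIn tilsim-generics event log of a result
#' @export
setMethod("eventLog", "SimulationResult", function(object, ...) object@eventLog)

#' @describeIn tilsim-generics event log of a state
#' @export
setMethod("eventLog", "SimulationState", function(object, ...) object@eventLog)

#' @describeIn tilsim-generics recorded snapshots
#' @export
setMethod("snapshots", "SimulationResult", function(object, ...) object@snapshots)

#' @describeIn tilsim-generics agent registry
#' @export
setMethod("agents", "SimulationState", function(object, ...) object@agents)

#' @describeIn tilsim-generics occupancy index
#' @export
setMethod("occupancy", "SimulationState", function(object, ...) object@occupancy)

#' @describeIn tilsim-generics IL-2 grid of a state
#' @export
setMethod("cytokine", "SimulationState", function(object, ...) object@cytokine)

#' @describeIn tilsim-generics entry voxels of a vasculature map
#' @export
setMethod("entryVoxels", "VasculatureMap", function(object, ...) object@entryVoxels)

setMethod("show", "SimulationState", function(object) {
  a <- object@agents
  cat(sprintf("SimulationState: N = %d, t = %.2f d, %d agents (%d cancer, %d T), %g cumulative dead\n",
              object@config@nVoxels, object@clockHours / 24, nrow(a),
              sum(a$state <= 3L), sum(a$state >= 4L),
              object@cumulativeDeadCancer))
})

setMethod("show", "SimulationResult", function(object) {
  ts <- object@timeSeries
  last <- ts[nrow(ts), ]
  cat(sprintf("SimulationResult: %d steps to day %.2f (seed %d)\n",
              nrow(ts) - 1L, last$timeDays, object@seed))
  cat(sprintf("  final counts: %d PDL1- / %d PDL1+ cancer, %d/%d/%d eff/cyt/supp T\n",
              last$pdl1neg, last$pdl1pos, last$effector, last$cytotoxic,
              last$suppressed))
  cat(sprintf("  snapshots at: %s\n",
              if (length(object@snapshots))
                paste(vapply(object@snapshots, function(s) s$day, numeric(1)),
                      collapse = ", ") else "none"))
})

#' Total living cancer count at a recorded day
#'
#' @param ts a time-series data.frame from a run, or a
#'   \linkS4class{SimulationResult}.
#' @param day day to look up (nearest recorded step is used).
#' @return numeric living cancer count (PDL1- + PDL1+).
#' @export
cancerCountAtDay <- function(ts, day) {
  if (is(ts, "SimulationResult")) ts <- ts@timeSeries
  i <- which.min(abs(ts$timeDays - day))
  ts$pdl1neg[i] + ts$pdl1pos[i]
}
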