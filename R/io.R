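#' Neoantigen quadrant table
#'
#' The four canonical patient profiles: high (kA = 20) or low (kA = 10)
#' mutational burden crossed with high (kI = 0.1) or low (kI = 0.001)
#' antigen strength.
#'
#' @return data.frame with columns \code{name}, \code{kA}, \code{kI}.
#' @export
neoantigenQuadrants <- function() {
  data.frame(name = c("highBurden_highStrength", "highBurden_lowStrength",
                      "lowBurden_highStrength", "lowBurden_lowStrength"),
             kA = c(20, 20, 10, 10), kI = c(0.1, 0.001, 0.1, 0.001),
             stringsAsFactors = FALSE)
}

#' Run a named scenario
#'
#' End-to-end runs for one neoantigen quadrant: for every seed a treated run
#' and (when \code{paired = TRUE}) an untreated run from the same seed. The
#' shared seed couples the RNG streams, so paired trajectories are identical
#' up to the treatment start day.
#'
#' @param quadrant one of the names in \code{\link{neoantigenQuadrants}}.
#' @param seeds integer vector of seeds (one pair of runs per seed).
#' @param config a \linkS4class{LatticeConfig}.
#' @param treatment a \linkS4class{TreatmentSchedule} (enabled) for the
#'   treated arm.
#' @param paired also run the untreated control (default TRUE).
#' @param recordDays snapshot days (defaults to the treatment start day and
#'   the end of the run).
#' @param lambdaVasc optional vascular decay override.
#' @param params optional baseline \linkS4class{RuleParameters}; the
#'   quadrant's kA/kI (and \code{lambdaVasc} if given) are applied on top.
#' @return list with the scenario description and \code{runs}: per seed a
#'   list with \code{treated} and (if paired) \code{untreated}
#'   \linkS4class{SimulationResult}s.
#' @export
runScenario <- function(quadrant, seeds, config,
                        treatment = treatmentSchedule(startDay = 30, mSupp = 0.8),
                        paired = TRUE, recordDays = NULL, lambdaVasc = NULL,
                        params = ruleParameters()) {
  q <- neoantigenQuadrants()
  row <- q[q$name == quadrant, ]
  if (!nrow(row)) stop("unknown quadrant name: ", quadrant,
                       " (see neoantigenQuadrants())")
  params@kA <- row$kA
  params@kI <- row$kI
  if (!is.null(lambdaVasc)) params@lambdaVasc <- lambdaVasc
  if (is.null(recordDays))
    recordDays <- unique(c(treatment@startDay, config@durationDays))
  runs <- lapply(seeds, function(s) {
    out <- list(treated = runSimulation(config, params, seed = s,
                                        treatment = treatment,
                                        recordDays = recordDays))
    if (paired)
      out$untreated <- runSimulation(config, params, seed = s,
                                     treatment = treatmentSchedule(enabled = FALSE),
                                     recordDays = recordDays)
    out
  })
  names(runs) <- paste0("seed", seeds)
  list(quadrant = quadrant, kA = row$kA, kI = row$kI, seeds = seeds,
       treatment = treatment, config = config, runs = runs)
}

#' Synthetic label volumes and sections for analysis tests
#'
#' Deterministic phantoms with known ground truth for the spatial pipeline.
#' Kinds: \code{solid_cube} (edge \code{size} cube of PDL1- cancer at the
#' centre), \code{hollow_shell} (cube shell of thickness \code{thickness}
#' with a sealed cavity), \code{digital_disc_section} (2D disc mask of
#' radius \code{radius} pixels), \code{random_binary} (iid Bernoulli(p)
#' volume), \code{checker_rim} (2D disc whose odd/even pixels alternate
#' PDL1-/PDL1+ labels).
#'
#' @param kind fixture name.
#' @param n lattice (or section) edge length.
#' @param size,thickness,radius,p geometry parameters, see above.
#' @param seed seed for \code{random_binary}.
#' @return an integer array (3D kinds) or matrix (2D kinds).
#' @export
makeFixture <- function(kind = c("solid_cube", "hollow_shell",
                                 "digital_disc_section", "random_binary",
                                 "checker_rim"),
                        n = 20L, size = 8L, thickness = 2L, radius = 15,
                        p = 0.5, seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (kind == "solid_cube") {
    v <- array(0L, c(n, n, n))
    a <- (n - size) %/% 2 + 1L
    v[a:(a + size - 1L), a:(a + size - 1L), a:(a + size - 1L)] <- 1L
    v
  } else if (kind == "hollow_shell") {
    v <- array(0L, c(n, n, n))
    a <- (n - size) %/% 2 + 1L; b <- a + size - 1L
    v[a:b, a:b, a:b] <- 1L
    ai <- a + thickness; bi <- b - thickness
    if (ai <= bi) v[ai:bi, ai:bi, ai:bi] <- 0L
    v
  } else if (kind == "digital_disc_section") {
    c0 <- (n + 1) / 2
    d2 <- outer(seq_len(n) - c0, seq_len(n) - c0,
                function(i, j) i^2 + j^2)
    matrix(as.integer(d2 <= radius^2), n, n)
  } else if (kind == "random_binary") {
    set.seed(as.integer(seed))
    array(as.integer(runif(n^3) < p), c(n, n, n))
  } else {  # checker_rim
    m <- makeFixture("digital_disc_section", n = n, radius = radius)
    parity <- outer(seq_len(n), seq_len(n), function(i, j) (i + j) %% 2L)
    lab <- matrix(0L, n, n)
    lab[m == 1L] <- 1L + parity[m == 1L]
    lab
  }
}

.snapshotSchema <- "tilsim-snapshot"
.snapshotVersion <- 1L

.rle2list <- function(v) {
  r <- rle(as.integer(v))
  list(lengths = r$lengths, values = r$values)
}

#' Write a snapshot to a schema-versioned JSON file
#'
#' Serializes a voxel snapshot (labels, agent ids, cytokine grid) together
#' with the full run metadata (lattice config, rule parameters, treatment,
#' seed) needed to reproduce the run. Label grids are run-length encoded;
#' doubles are written at full precision, so a read/write round trip is
#' lossless.
#'
#' @param snapshot a snapshot list (elements \code{day}, \code{labels},
#'   \code{agentIds}, \code{cytokine}) as stored in a
#'   \linkS4class{SimulationResult}.
#' @param path output file.
#' @param config,params,treatment,seed run metadata to embed (optional but
#'   required to re-run from the file).
#' @return invisibly \code{path}.
#' @export
writeSnapshot <- function(snapshot, path, config = NULL, params = NULL,
                          treatment = NULL, seed = NULL) {
  slots2list <- function(obj) {
    if (is.null(obj)) return(NULL)
    sapply(slotNames(obj), function(s) slot(obj, s), simplify = FALSE)
  }
  obj <- list(schema = .snapshotSchema, version = .snapshotVersion,
              day = snapshot$day, dim = dim(snapshot$labels),
              cytokineDim = dim(snapshot$cytokine),
              labels = .rle2list(snapshot$labels),
              agentIds = .rle2list(snapshot$agentIds),
              cytokine = as.numeric(snapshot$cytokine),
              config = slots2list(config), params = slots2list(params),
              treatment = slots2list(treatment),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a snapshot written by \code{\link{writeSnapshot}}
#'
#' @param path file path.
#' @return list with \code{day}, \code{labels}, \code{agentIds},
#'   \code{cytokine} (arrays) and any embedded \code{config}, \code{params},
#'   \code{treatment}, \code{seed} metadata.
#' @export
readSnapshot <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop("cannot parse snapshot file: ",
                                           conditionMessage(e)))
  if (!identical(obj$schema, .snapshotSchema))
    stop("not a tilsim snapshot file")
  if (!identical(as.integer(obj$version), .snapshotVersion))
    stop("unsupported snapshot schema version: ", obj$version)
  dims <- as.integer(obj$dim)
  cyDims <- if (!is.null(obj$cytokineDim)) as.integer(obj$cytokineDim) else dims
  unrle <- function(x) array(rep(as.integer(x$values), x$lengths), dims)
  out <- list(day = obj$day, labels = unrle(obj$labels),
              agentIds = unrle(obj$agentIds),
              cytokine = array(as.numeric(obj$cytokine), cyDims))
  for (nm in c("config", "params", "treatment", "seed"))
    if (!is.null(obj[[nm]])) out[[nm]] <- obj[[nm]]
  out
}

#' Re-run a simulation from snapshot metadata
#'
#' Rebuilds the config/parameters/treatment/seed embedded in a snapshot file
#' and repeats the run; with the same package version this reproduces the
#' original time series exactly.
#'
#' @param path snapshot file written with full metadata.
#' @param recordDays snapshot days for the re-run.
#' @return a \linkS4class{SimulationResult}.
#' @export
rerunFromSnapshot <- function(path, recordDays = numeric(0)) {
  meta <- readSnapshot(path)
  if (is.null(meta$config) || is.null(meta$params) || is.null(meta$seed))
    stop("snapshot lacks embedded run metadata")
  cfg <- do.call(latticeConfig, meta$config[c("nVoxels", "voxelSize",
                                              "durationDays", "dtHours",
                                              "pdeSubsteps")])
  prm <- do.call(ruleParameters, meta$params)
  trt <- if (!is.null(meta$treatment))
    do.call(treatmentSchedule, meta$treatment) else treatmentSchedule(enabled = FALSE)
  runSimulation(cfg, prm, seed = meta$seed, treatment = trt,
                recordDays = recordDays)
}

#' Write / read a run time series as CSV
#'
#' @param ts time-series data.frame or \linkS4class{SimulationResult}.
#' @param path file path.
#' @return \code{writeTimeSeries}: invisibly the path;
#'   \code{readTimeSeries}: the data.frame.
#' @export
writeTimeSeries <- function(ts, path) {
  if (is(ts, "SimulationResult")) ts <- ts@timeSeries
  write.csv(ts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeSeries
#' @export
readTimeSeries <- function(path) read.csv(path)
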