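#' Create a Latin hypercube sensitivity design
#'
#' @param ranges named list of \code{c(low, high)} uniform ranges, one per
#'   rule parameter to vary (names must match \linkS4class{RuleParameters}
#'   fields when the design is run).
#' @param nSamples number of parameter combinations (default 500).
#' @param nReplicates stochastic replicates per combination (default 3);
#'   replicate outputs are averaged before correlation.
#' @param seed integer seed for the sampling and the replicate seeds.
#' @return a \linkS4class{SensitivityDesign}.
#' @examples
#' sensitivityDesign(list(pKillNeg = c(0.02, 0.3)), nSamples = 10, seed = 1)
#' @export
sensitivityDesign <- function(ranges, nSamples = 500L, nReplicates = 3L, seed = 1L) {
  new("SensitivityDesign", ranges = ranges, nSamples = as.integer(nSamples),
      nReplicates = as.integer(nReplicates), seed = as.integer(seed))
}

#' Draw the Latin hypercube sample matrix
#'
#' Stratified uniform sampling: for every parameter the n equal-probability
#' strata each contain exactly one sample (uniform jitter within the
#' stratum), with columns permuted independently. Seeded-reproducible.
#'
#' @param design a \linkS4class{SensitivityDesign}.
#' @return an nSamples x k numeric matrix with one named column per
#'   parameter, scaled to the design ranges.
#' @export
lhsSample <- function(design) {
  validObject(design)
  set.seed(design@seed)
  k <- length(design@ranges)
  u <- lhs::randomLHS(design@nSamples, k)
  lo <- vapply(design@ranges, `[`, numeric(1), 1)
  hi <- vapply(design@ranges, `[`, numeric(1), 2)
  out <- sweep(sweep(u, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(out) <- names(design@ranges)
  out
}

#' Partial rank correlation coefficients
#'
#' Ranks every column of X and y, then computes for each parameter the
#' partial correlation between its ranks and the output ranks controlling
#' for all other parameters, via the precision (inverse correlation) matrix
#' of the rank-transformed data. Significance uses the t statistic with
#' n - 2 - (k - 1) degrees of freedom.
#'
#' @param X numeric design matrix (samples x parameters, named columns).
#' @param y numeric output vector.
#' @param alpha significance level for the flag (default 1e-9).
#' @return data.frame with columns parameter, prcc, statistic, p, significant.
#' @examples
#' X <- matrix(runif(200), 50); colnames(X) <- paste0("p", 1:4)
#' prcc(X, X[, 1] + 0.1 * rnorm(50))
#' @export
prcc <- function(X, y, alpha = 1e-9) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(k))
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (n <= k + 2) stop("need n > k + 2 samples")
  const <- apply(X, 2, function(col) diff(range(col)) == 0)
  if (any(const))
    stop("constant design column(s): ", paste(colnames(X)[const], collapse = ", "))
  if (diff(range(y)) == 0) stop("constant output vector")
  R <- cbind(apply(X, 2, rank), rank(y))
  if (k == 1L) {
    # no controlling variables: the partial correlation is the Spearman
    # correlation itself (the precision-matrix route would be singular for
    # perfectly monotone pairs)
    r <- cor(R[, 1], R[, 2])
  } else {
    C <- cor(R)
    P <- solve(C)
    j <- seq_len(k); yi <- k + 1L
    r <- -P[j, yi] / sqrt(P[j, j][cbind(j, j)] * P[yi, yi])
  }
  df <- n - 2 - (k - 1)
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  data.frame(parameter = colnames(X), prcc = r, statistic = tstat, p = p,
             significant = p < alpha, row.names = NULL)
}

#' Run a sensitivity design through the simulator
#'
#' Simulates every sampled parameter combination \code{nReplicates} times
#' with distinct derived seeds, averages the replicate outputs, and returns
#' the PRCC table for each requested output. Failed replicates exclude their
#' sample (logged in the result's \code{excluded}).
#'
#' @param design a \linkS4class{SensitivityDesign} whose range names are
#'   \linkS4class{RuleParameters} fields.
#' @param config a \linkS4class{LatticeConfig} for the individual runs.
#' @param baseParams baseline \linkS4class{RuleParameters}; sampled values
#'   override the corresponding fields.
#' @param day evaluation day for the outputs.
#' @param outputs any of \code{"totalCancer"} (living cancer count) and
#'   \code{"pdl1Fraction"} (PDL1+ / living cancer).
#' @param treatment optional \linkS4class{TreatmentSchedule} applied to every
#'   run.
#' @return list with \code{design} (the sampled matrix), \code{outputs}
#'   (per-sample averaged outputs), \code{prcc} (named list of PRCC tables),
#'   \code{excluded} (sample indices dropped after a failed replicate) and
#'   \code{provenance} (sample/replicate seeds).
#' @export
runDesign <- function(design, config, baseParams = ruleParameters(), day,
                      outputs = c("totalCancer", "pdl1Fraction"),
                      treatment = treatmentSchedule(enabled = FALSE)) {
  outputs <- match.arg(outputs, several.ok = TRUE)
  X <- lhsSample(design)
  if (day > config@durationDays + 1e-9)
    stop("evaluation day exceeds the configured duration")
  nS <- nrow(X)
  vals <- matrix(NA_real_, nS, length(outputs), dimnames = list(NULL, outputs))
  seeds <- matrix(NA_integer_, nS, design@nReplicates)
  failed <- logical(nS)
  for (i in seq_len(nS)) {
    repVals <- matrix(NA_real_, design@nReplicates, length(outputs))
    for (r in seq_len(design@nReplicates)) {
      seed <- (design@seed * 7919L + i * 1009L + r * 101L) %% 2147483587L + 1L
      seeds[i, r] <- seed
      res <- tryCatch({
        p <- do.call(ruleParameters, as.list(X[i, ]))
        # fields not in the design stay at the baseline values
        for (nm in setdiff(slotNames(baseParams), colnames(X)))
          slot(p, nm) <- slot(baseParams, nm)
        validObject(p)
        runSimulation(config, p, seed = seed, treatment = treatment)
      }, error = function(e) e)
      if (inherits(res, "error")) { failed[i] <- TRUE; break }
      ts <- res@timeSeries
      ix <- which.min(abs(ts$timeDays - day))
      living <- ts$pdl1neg[ix] + ts$pdl1pos[ix]
      repVals[r, ] <- vapply(outputs, function(o)
        switch(o, totalCancer = living,
               pdl1Fraction = if (living > 0) ts$pdl1pos[ix] / living else 0),
        numeric(1))
    }
    if (!failed[i]) vals[i, ] <- colMeans(repVals)
  }
  keep <- !failed
  tabs <- lapply(setNames(outputs, outputs), function(o)
    prcc(X[keep, , drop = FALSE], vals[keep, o]))
  list(design = X, outputs = vals, prcc = tabs,
       excluded = which(failed), provenance = seeds)
}

setMethod("show", "SensitivityDesign", function(object) {
  cat(sprintf("SensitivityDesign: %d samples x %d parameters, %d replicates (seed %d)\n",
              object@nSamples, length(object@ranges), object@nReplicates,
              object@seed))
  for (nm in names(object@ranges))
    cat(sprintf("  %s in [%g, %g]\n", nm, object@ranges[[nm]][1],
                object@ranges[[nm]][2]))
})
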