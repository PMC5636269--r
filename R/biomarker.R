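#' Rim-restricted PDL1 score
#'
#' Fraction of living cancer cells within the rim (depth <=
#' \code{thresholdUm} from the tumour surface) that are PDL1+. Dead cells
#' are excluded from numerator and denominator. With \code{counting =
#' "agent"} a multi-voxel cancer cell is counted once if any of its voxels
#' intersects the rim (requires agent ids on the sections); with
#' \code{"voxel"} every rim voxel counts. A section whose rim contains no
#' living cancer cell gets an undefined (NA) score; the aggregate is the
#' mean over defined sections.
#'
#' @param sections a \linkS4class{CrossSection}, or a (named) list of them
#'   as returned by \code{\link{crossSections}}.
#' @param thresholdUm rim depth, um (default 50).
#' @param counting "agent" (default) or "voxel".
#' @param rim optional precomputed rim mask (only for a single section).
#' @return a \linkS4class{RimScore}.
#' @export
rimPdl1Score <- function(sections, thresholdUm = 50, counting = c("agent", "voxel"),
                         rim = NULL) {
  counting <- match.arg(counting)
  if (is(sections, "CrossSection")) sections <- list(section = sections)
  scoreOne <- function(sec, rimM) {
    if (is.null(rimM)) rimM <- rimMask(sec, thresholdUm)
    if (any(rimM == 1L & sec@mask == 0L))
      stop("rim must lie within the section tumour mask")
    inRim <- rimM == 1L
    lab <- sec@labels
    if (counting == "agent") {
      if (!any(sec@agentIds != 0L))
        stop("agent-level counting requires agent ids on the section")
      living <- unique(sec@agentIds[inRim & lab %in% 1:2])
      pos <- unique(sec@agentIds[inRim & lab == 2L])
    } else {
      living <- which(inRim & lab %in% 1:2)
      pos <- which(inRim & lab == 2L)
    }
    if (!length(living)) return(NA_real_)
    length(pos) / length(living)
  }
  per <- vapply(seq_along(sections), function(i)
    scoreOne(sections[[i]], if (length(sections) == 1L) rim else NULL),
    numeric(1))
  names(per) <- if (!is.null(names(sections))) names(sections)
                else paste0("section", seq_along(sections))
  agg <- if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
  new("RimScore", thresholdUm = thresholdUm, perSection = per, score = agg,
      counting = counting)
}

#' Tumour shrinkage ratio and responder label
#'
#' Ratio of total living cancer counts at \code{postDay} versus
#' \code{preDay}: 1 indicates equilibrium, 0 elimination, > 1 progression.
#' A tumour is labelled responder when the ratio falls below
#' \code{responderCutoff}.
#'
#' @param ts a time-series data.frame or \linkS4class{SimulationResult}.
#' @param preDay pretreatment day (default 30).
#' @param postDay post-treatment day (default 50).
#' @param responderCutoff responder threshold on the ratio (default 1).
#' @return list with \code{ratio}, \code{responder}, \code{preCount},
#'   \code{postCount}.
#' @examples
#' ts <- data.frame(timeDays = c(30, 50), pdl1neg = c(800, 200),
#'                  pdl1pos = c(200, 100))
#' shrinkageRatio(ts)$ratio
#' @export
shrinkageRatio <- function(ts, preDay = 30, postDay = 50, responderCutoff = 1) {
  pre <- cancerCountAtDay(ts, preDay)
  post <- cancerCountAtDay(ts, postDay)
  if (pre <= 0) stop("undefined shrinkage ratio: no living cancer cells at the pretreatment day")
  ratio <- post / pre
  list(ratio = ratio, responder = ratio < responderCutoff,
       preCount = pre, postCount = post)
}

#' Empirical ROC curve
#'
#' Standard empirical ROC over all score cutoffs with tied scores grouped
#' into single points, and the trapezoidal AUC. Higher scores are taken to
#' indicate the positive (responder) class. NA scores are dropped.
#'
#' @param scores numeric biomarker scores.
#' @param labels logical (or 0/1) outcome labels; must contain both classes.
#' @return list with \code{points} (data.frame threshold/fpr/tpr, from (0,0)
#'   to (1,1)) and \code{auc}.
#' @examples
#' rocCurve(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))$auc
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("ROC requires at least one responder and one non-responder")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / nPos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / nNeg, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

#' ROC curves across rim-depth thresholds
#'
#' Scores every tumour of a virtual cohort at each rim depth and evaluates
#' the resulting ROC against the treatment outcomes, to compare the
#' predictive power of shallow versus deep rim scores.
#'
#' @param cohortSections list (one element per tumour) of cross-section
#'   lists as returned by \code{\link{crossSections}}.
#' @param outcomes logical responder labels, one per tumour.
#' @param thresholdsUm rim depths to evaluate (default 20, 50, 100, 150 um).
#' @param counting passed to \code{\link{rimPdl1Score}}.
#' @return data.frame with one row per threshold: \code{thresholdUm},
#'   \code{auc}, \code{nScored}, \code{degenerate} (TRUE when all defined
#'   scores are tied), plus the ROC point sets in the \code{roc} list column.
#' @export
thresholdSweep <- function(cohortSections, outcomes,
                           thresholdsUm = c(20, 50, 100, 150),
                           counting = "agent") {
  stopifnot(all(thresholdsUm > 0))
  outcomes <- as.logical(outcomes)
  if (length(cohortSections) != length(outcomes))
    stop("one outcome per tumour required")
  if (length(unique(outcomes[!is.na(outcomes)])) < 2)
    stop("cohort outcomes contain a single class")
  rows <- lapply(thresholdsUm, function(th) {
    sc <- vapply(cohortSections, function(secs)
      rimPdl1Score(secs, thresholdUm = th, counting = counting)@score,
      numeric(1))
    defined <- !is.na(sc)
    degen <- length(unique(sc[defined])) <= 1L
    roc <- if (!degen) rocCurve(sc[defined], outcomes[defined]) else
      list(points = NULL, auc = NA_real_)
    list(thresholdUm = th, auc = roc$auc, nScored = sum(defined),
         degenerate = degen, roc = roc)
  })
  out <- data.frame(thresholdUm = vapply(rows, `[[`, numeric(1), "thresholdUm"),
                    auc = vapply(rows, `[[`, numeric(1), "auc"),
                    nScored = vapply(rows, `[[`, numeric(1), "nScored"),
                    degenerate = vapply(rows, `[[`, logical(1), "degenerate"))
  out$roc <- lapply(rows, `[[`, "roc")
  out
}

setMethod("show", "RimScore", function(object) {
  cat(sprintf("RimScore (rim <= %.0f um, %s counting): %.3f [%s]\n",
              object@thresholdUm, object@counting, object@score,
              paste(sprintf("%s %.3f", names(object@perSection),
                            object@perSection), collapse = ", ")))
})
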