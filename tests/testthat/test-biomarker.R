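# Rim PDL1 scores, shrinkage ratios, ROC curves.

# hand-built cross section: a disc with chosen PDL1+/- labelling and one
# agent id per cancer voxel (so agent and voxel counting coincide)
sectionFixture <- function(n = 21, radius = 8, posIdx = integer(0)) {
  mask <- makeFixture("digital_disc_section", n = n, radius = radius)
  lab <- matrix(0L, n, n)
  cancer <- which(mask == 1L)
  lab[cancer] <- 1L
  lab[cancer[posIdx]] <- 2L
  ids <- matrix(0L, n, n)
  ids[cancer] <- seq_along(cancer)
  sec <- new("CrossSection", axis = "z", index = as.integer(n %/% 2),
             mask = mask, labels = lab, agentIds = ids,
             distance = matrix(NA_real_, n, n), voxelSize = 10)
  sec@distance <- distanceMap(sec)
  sec
}

test_that("rim PDL1 score is the PDL1+ fraction of living rim cancer cells", {
  sec <- sectionFixture()
  all0 <- rimPdl1Score(sec, thresholdUm = 30)
  expect_equal(all0@score, 0)

  nC <- sum(sec@mask)
  allPos <- sectionFixture(posIdx = seq_len(nC))
  expect_equal(rimPdl1Score(allPos, thresholdUm = 30)@score, 1)

  # rim of depth 0 on a disc of radius 8 px: boundary-adjacent ring;
  # make 3 of the first 10 rim cells PDL1+ and count by hand
  sec0 <- sectionFixture()
  rim <- rimMask(sec0, 0)
  rimCells <- which(rim == 1L)
  sec3 <- sectionFixture(posIdx = match(rimCells[1:3], which(sec0@mask == 1L)))
  sc <- rimPdl1Score(sec3, thresholdUm = 0)
  expect_equal(sc@score, 3 / length(rimCells))

  # dead cells are excluded from numerator and denominator
  secD <- sectionFixture(posIdx = 1:5)
  living <- which(secD@labels %in% 1:2)
  secD@labels[living[1:10]] <- 3L
  scD <- rimPdl1Score(secD, thresholdUm = 1000)
  nLiv <- sum(secD@labels %in% 1:2)
  expect_equal(scD@score, sum(secD@labels == 2L) / nLiv)

  # empty rim is flagged undefined
  secE <- sectionFixture()
  secE@labels[secE@labels %in% 1:2] <- 3L
  expect_true(is.na(rimPdl1Score(secE, thresholdUm = 30)@score))
})

test_that("voxel and agent counting differ for multi-voxel agents", {
  # one agent spanning 4 rim voxels, PDL1+; three 1-voxel PDL1- agents
  n <- 15
  mask <- matrix(0L, n, n); mask[4:9, 4:9] <- 1L
  lab <- matrix(0L, n, n); lab[4:9, 4:9] <- 1L
  lab[4:5, 4:5] <- 2L
  ids <- matrix(0L, n, n); ids[4:9, 4:9] <- matrix(10 + seq_len(36), 6, 6)
  ids[4:5, 4:5] <- 7L  # one 2x2 block agent
  sec <- new("CrossSection", axis = "z", index = 7L, mask = mask, labels = lab,
             agentIds = ids, distance = matrix(NA_real_, n, n), voxelSize = 10)
  sec@distance <- distanceMap(sec)
  byVoxel <- rimPdl1Score(sec, thresholdUm = 1000, counting = "voxel")@score
  byAgent <- rimPdl1Score(sec, thresholdUm = 1000, counting = "agent")@score
  expect_equal(byVoxel, 4 / 36)
  expect_equal(byAgent, 1 / 33)   # 32 single-voxel agents + 1 block agent
})

test_that("the aggregate is the mean of the defined per-section scores", {
  s1 <- sectionFixture(posIdx = 1:10)
  s2 <- sectionFixture()
  rs <- rimPdl1Score(list(a = s1, b = s2), thresholdUm = 1000)
  expect_equal(unname(rs@score), mean(rs@perSection))
  expect_true(rs@score >= min(rs@perSection) && rs@score <= max(rs@perSection))
})

test_that("shrinkage ratios map to the response classes", {
  ts <- data.frame(timeDays = c(30, 50), pdl1neg = c(500, 500), pdl1pos = c(500, 500))
  eq <- shrinkageRatio(ts, 30, 50)
  expect_equal(eq$ratio, 1)
  expect_false(eq$responder)  # default cutoff: ratio < 1

  ts$pdl1neg[2] <- 0; ts$pdl1pos[2] <- 0
  el <- shrinkageRatio(ts, 30, 50)
  expect_equal(el$ratio, 0)
  expect_true(el$responder)

  ts2 <- data.frame(timeDays = c(30, 50), pdl1neg = c(800, 1100), pdl1pos = c(200, 400))
  pr <- shrinkageRatio(ts2, 30, 50)
  expect_equal(pr$ratio, 1.5)
  expect_false(pr$responder)

  ts3 <- data.frame(timeDays = c(30, 50), pdl1neg = c(0, 10), pdl1pos = c(0, 0))
  expect_error(shrinkageRatio(ts3, 30, 50), "undefined")
})

test_that("ROC handles separation, ties and chance-level scores", {
  roc <- rocCurve(c(0.9, 0.8, 0.7, 0.3, 0.2), c(1, 1, 1, 0, 0))
  expect_equal(roc$auc, 1)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(utils::tail(roc$points$tpr, 1), 1)

  # labels independent of scores: AUC near 1/2
  set.seed(5)
  sc <- runif(1000); lb <- runif(1000) < 0.5
  expect_lt(abs(rocCurve(sc, lb)$auc - 0.5), 0.05)

  # all scores tied: a single grouped point, AUC 1/2
  tied <- rocCurve(rep(0.4, 10), c(rep(TRUE, 5), rep(FALSE, 5)))
  expect_equal(nrow(tied$points), 2)
  expect_equal(tied$auc, 0.5)

  expect_error(rocCurve(1:5, rep(TRUE, 5)), "one responder")

  # AUC invariant under strictly monotone transforms of the scores
  set.seed(6)
  sc <- rnorm(200); lb <- rbinom(200, 1, plogis(sc))
  expect_equal(rocCurve(sc, lb)$auc, rocCurve(exp(sc), lb)$auc)
  expect_equal(rocCurve(sc, lb)$auc, rocCurve(qlogis(plogis(sc)), lb)$auc)
})

test_that("the empirical AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  sc <- round(rnorm(120), 1)  # ties included
  lb <- rbinom(120, 1, plogis(sc))
  skip_if(length(unique(lb)) < 2)
  ours <- rocCurve(sc, lb)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("threshold sweeps flag degenerate cohorts and reject single classes", {
  mk <- function(posIdx) list(z = sectionFixture(posIdx = posIdx))
  cohort <- list(mk(1:40), mk(1:30), mk(1:5), mk(integer(0)))
  out <- thresholdSweep(cohort, outcomes = c(TRUE, TRUE, FALSE, FALSE),
                        thresholdsUm = c(20, 50, 100), counting = "voxel")
  expect_equal(nrow(out), 3)
  expect_true(all(out$auc[!out$degenerate] >= 0 & out$auc[!out$degenerate] <= 1))

  same <- list(mk(1:10), mk(1:10), mk(1:10), mk(1:10))
  outS <- thresholdSweep(same, outcomes = c(TRUE, FALSE, TRUE, FALSE),
                         thresholdsUm = 50, counting = "voxel")
  expect_true(outS$degenerate)
  expect_true(is.na(outS$auc))

  expect_error(thresholdSweep(cohort, outcomes = rep(TRUE, 4), thresholdsUm = 50),
               "single class")
})
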