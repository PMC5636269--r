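# Entry-point placement, recruitment rate law, Poisson arrivals.

test_that("entry density follows the exponential depth profile", {
  cfg <- latticeConfig(nVoxels = 100)
  n <- 100
  layerVox <- function(k) (n - 2 * k)^3 - (n - 2 * k - 2)^3  # voxels at min-depth layer k

  # near-uniform perfusion (lambda = 1/3200): realized density in a deep
  # shell over the boundary shell is close to the analytic exp(-depth/3200)
  v <- placeEntryPoints(cfg, 1 / 3200, baseDensity = 0.2, seed = 1)
  d <- entryDepths(v) / 10
  rate0 <- sum(d == 0) / layerVox(0)
  rate40 <- sum(d >= 38 & d <= 42) / sum(vapply(38:42, layerVox, numeric(1)))
  expect_equal(rate40 / rate0, exp(-400 / 3200), tolerance = 0.15)
  # the centre/boundary probability ratio itself is ~0.86
  expect_equal(exp(-490 / 3200), 0.858, tolerance = 0.01)

  # steep decay (lambda = 1/25): boundary entries exist, the core has none
  v25 <- placeEntryPoints(cfg, 1 / 25, baseDensity = 0.2, seed = 2)
  expect_gt(length(entryVoxels(v25)), 100)
  expect_equal(sum(entryDepths(v25) > 250), 0)
  # centre/boundary probability ratio below 1e-8
  expect_lt(exp(-490 / 25), 1e-8)
})

test_that("lambda = 0 gives a uniform entry distribution over depth bins", {
  cfg <- latticeConfig(nVoxels = 60)
  v <- placeEntryPoints(cfg, 0, baseDensity = 0.3, seed = 3)
  d <- entryDepths(v) / 10  # in voxel layers 0..29
  layer <- pmin(floor(d), 9)  # group deep layers: counts per shell
  # voxels per min-depth layer k on an n^3 lattice: (n-2k)^3 - (n-2k-2)^3
  n <- 60
  expVox <- vapply(0:8, function(k) (n - 2 * k)^3 - (n - 2 * k - 2)^3, numeric(1))
  expVox <- c(expVox, (n - 18)^3)  # layer >= 9 pooled
  obs <- tabulate(layer + 1, nbins = 10)
  chi <- suppressWarnings(chisq.test(obs, p = expVox / sum(expVox)))
  expect_gt(chi$p.value, 0.01)
})

test_that("placement is seeded-reproducible and maps validate", {
  cfg <- latticeConfig(nVoxels = 40)
  v1 <- placeEntryPoints(cfg, 1 / 100, 0.05, seed = 9)
  v2 <- placeEntryPoints(cfg, 1 / 100, 0.05, seed = 9)
  expect_identical(entryVoxels(v1), entryVoxels(v2))
  expect_error(placeEntryPoints(cfg, -1, 0.05), "lambda")
})

test_that("the recruitment rate law has the stated shape", {
  expect_equal(recruitmentRate(20, 0.1, 0, rBase = 0.5), 0)
  # linear in mutational burden at equal dead-cell signal
  D <- 137
  expect_equal(recruitmentRate(20, 0.1, D, rBase = 0.5) /
               recruitmentRate(10, 0.1, D, rBase = 0.5), 2)
  # saturation at rBase * kA as the dead-cell signal grows
  expect_equal(recruitmentRate(20, 0.1, 1e12, rBase = 0.5), 0.5 * 20,
               tolerance = 1e-9)
  # strictly increasing in the signal
  r <- recruitmentRate(20, 0.1, c(1, 10, 100, 1000), rBase = 0.5)
  expect_true(all(diff(r) > 0))
  expect_error(recruitmentRate(0, 0.1, 10), "kA")
})

test_that("arrivals are Poisson with the requested mean and enter as effectors", {
  cfg <- latticeConfig(nVoxels = 20, dtHours = 0.25)
  # saturated signal: rate = rBase * kA = 16/h -> 4 per step
  p <- immuneFreeParams(rBase = 0.8, kA = 20, kI = 1, tCellSpeed = 0,
                        tCellLifespan = 1e9, baseDensity = 0.5)
  st <- initializeSimulation(cfg, p, seed = 21, seedCancer = FALSE)
  st@cumulativeDeadCancer <- 1e9
  arrivals <- numeric(400)
  for (i in seq_along(arrivals)) {
    st2 <- recruitStep(st)   # always from the same state: iid draws
    ev <- eventLog(st2)
    arrivals[i] <- ev$recruits[nrow(ev)]
    if (i == 1) expect_true(all(agents(st2)$state == 4L))
    st@timeSeries <- st2@timeSeries  # keep sizes bounded; state itself reused
  }
  m <- mean(arrivals)
  se <- sqrt(4 / length(arrivals))
  expect_lt(abs(m - 4), 3 * se)
  expect_lt(abs(var(arrivals) / m - 1), 0.25)  # variance ~ mean
})

test_that("arrivals at a fully occupied entry set are forfeited", {
  cfg <- latticeConfig(nVoxels = 10, dtHours = 0.25)
  p <- immuneFreeParams(rBase = 10, kA = 20, kI = 1, tCellSpeed = 0,
                        tCellLifespan = 1e9)
  st <- initializeSimulation(cfg, p, seed = 4, seedCancer = FALSE)
  ev <- sort(entryVoxels(st@vasculature))
  skip_if(length(ev) == 0)
  fill <- data.frame(state = 6L, x = ev %% 10L, y = (ev %/% 10L) %% 10L,
                     z = ev %/% 100L)
  st <- placeAgents(st, fill)
  st@cumulativeDeadCancer <- 1e9
  st2 <- recruitStep(st)
  expect_equal(sum(eventLog(st2)$recruits), 0)
  expect_gt(st2@forfeitedArrivals, 0)
})

test_that("raising burden or strength never lowers cumulative recruits", {
  cfg <- latticeConfig(nVoxels = 24, durationDays = 6, pdeCoarsen = 2L)
  base <- list(cancerCycleTime = 8)
  rec <- function(kA, kI, s) {
    p <- do.call(ruleParameters, c(base, list(kA = kA, kI = kI)))
    sum(eventLog(runSimulation(cfg, p, seed = s))$recruits)
  }
  for (s in 1:3) {
    expect_gte(rec(20, 0.1, s), rec(10, 0.1, s))
    expect_gte(rec(10, 0.1, s), rec(10, 0.001, s))
  }
})
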