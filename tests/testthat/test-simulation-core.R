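test_that("initialization places one centred PDL1- cancer cell and is deterministic", {
  cfg <- latticeConfig(nVoxels = 100, durationDays = 1)
  st <- initializeSimulation(cfg, ruleParameters(), seed = 1)
  a <- agents(st)
  expect_equal(nrow(a), 1L)
  expect_equal(a$state, 1L)
  expect_equal(st@clockHours, 0)
  expect_true(all(cytokine(st) == 0))
  expect_equal(sum(agents(st)$state >= 4), 0L)

  # N = 8: the centre block covers voxels {3,4}^3 (0-based)
  st8 <- initializeSimulation(latticeConfig(nVoxels = 8), ruleParameters(), seed = 1)
  expect_equal(unlist(agents(st8)[1, c("x", "y", "z")], use.names = FALSE),
               rep(3L, 3))
  occupied <- which(occupancy(st8) != 0L, arr.ind = TRUE)
  expect_setequal(as.vector(occupied), rep(4:5, 3))  # 1-based rows/cols

  s1 <- initializeSimulation(latticeConfig(nVoxels = 20), ruleParameters(), seed = 42)
  s2 <- initializeSimulation(latticeConfig(nVoxels = 20), ruleParameters(), seed = 42)
  expect_identical(occupancy(s1), occupancy(s2))
  expect_identical(entryVoxels(s1@vasculature), entryVoxels(s2@vasculature))

  expect_error(initializeSimulation(latticeConfig(nVoxels = 8), ruleParameters(),
                                    seed = 1, seedCancer = TRUE), NA)
  expect_error(latticeConfig(nVoxels = 4), "nVoxels")
})

test_that("a step on an empty lattice only advances the clock", {
  cfg <- latticeConfig(nVoxels = 12, dtHours = 0.25)
  st <- initializeSimulation(cfg, ruleParameters(), seed = 1, seedCancer = FALSE)
  st2 <- stepSimulation(st, 3)
  expect_equal(st2@clockHours, 0.75)
  expect_equal(nrow(agents(st2)), 0L)
  expect_identical(occupancy(st2), occupancy(st))
})

test_that("frozen dynamics leave occupancy unchanged", {
  p <- immuneFreeParams(cancerCycleTime = 1e9, cancerSpeed = 0)
  st <- initializeSimulation(latticeConfig(nVoxels = 16), p, seed = 4)
  st2 <- stepSimulation(st, 20)
  expect_identical(occupancy(st2), occupancy(st))
  expect_equal(st2@clockHours, 5)
})

test_that("a lone cancer cell with cycle = dt divides into a free site", {
  p <- immuneFreeParams(cancerCycleTime = 0.25, cancerSpeed = 0)
  st <- initializeSimulation(latticeConfig(nVoxels = 16, dtHours = 0.25), p, seed = 3)
  st2 <- stepSimulation(st)
  expect_equal(sum(agents(st2)$state <= 2L), 2L)
  validateState(st2)
})

test_that("identical seeds give bit-identical trajectories", {
  cfg <- latticeConfig(nVoxels = 24, durationDays = 3, pdeCoarsen = 2L)
  p <- ruleParameters(cancerCycleTime = 6)
  r1 <- runSimulation(cfg, p, seed = 99, recordDays = 3)
  r2 <- runSimulation(cfg, p, seed = 99, recordDays = 3)
  expect_identical(timeSeries(r1), timeSeries(r2))
  expect_identical(eventLog(r1), eventLog(r2))
  expect_identical(snapshots(r1)[["day3"]]$labels, snapshots(r2)[["day3"]]$labels)
  expect_identical(r1@finalState@cytokine, r2@finalState@cytokine)
})

test_that("duration zero yields only the initial record", {
  cfg <- latticeConfig(nVoxels = 12, durationDays = 0)
  r <- runSimulation(cfg, ruleParameters(), seed = 1, recordDays = 0)
  expect_equal(nrow(timeSeries(r)), 1L)
  expect_equal(length(snapshots(r)), 1L)
  expect_equal(snapshots(r)[[1]]$day, 0)
})

test_that("event ledger balances per-step cancer count changes", {
  # growth + immune attack; every step must satisfy
  # delta living cancer = divisions - kills - necrotic deaths
  cfg <- latticeConfig(nVoxels = 30, durationDays = 8, pdeCoarsen = 2L)
  p <- ruleParameters(cancerCycleTime = 8, rBase = 1)
  r <- runSimulation(cfg, p, seed = 11)
  ts <- timeSeries(r); ev <- eventLog(r)
  living <- ts$pdl1neg + ts$pdl1pos
  expect_equal(diff(living), ev$cancerDivisions - ev$kills - ev$necroticDeaths)
  expect_equal(r@finalState@cumulativeDeadCancer,
               sum(ev$kills) + sum(ev$necroticDeaths))
  # dead-cell bookkeeping: deaths in, clearances out
  expect_equal(diff(ts$deadCancer),
               ev$kills + ev$necroticDeaths - ev$cleared)
  validateState(r@finalState)
})

test_that("occupancy rescan matches the registry after stochastic evolution", {
  cfg <- latticeConfig(nVoxels = 24, durationDays = 4, pdeCoarsen = 2L)
  p <- ruleParameters(cancerCycleTime = 6, rBase = 2, kI = 1)
  st <- initializeSimulation(cfg, p, seed = 8)
  for (k in 1:4) {
    st <- stepSimulation(st, 96)
    expect_silent(validateState(st))
  }
  expect_gt(nrow(agents(st)), 10)
})

test_that("PDL1+ state never reverts", {
  cfg <- latticeConfig(nVoxels = 16, dtHours = 0.25)
  p <- immuneFreeParams(cancerCycleTime = 1e9, cancerSpeed = 1)
  st <- initializeSimulation(cfg, p, seed = 2, seedCancer = FALSE)
  st <- placeAgents(st, data.frame(state = 2L, x = c(4L, 10L), y = 4L, z = 4L))
  st <- stepSimulation(st, 40)
  expect_equal(sort(agents(st)$state), c(2L, 2L))
})

test_that("suppressed T cells never act as killers", {
  cfg <- latticeConfig(nVoxels = 12, dtHours = 0.25)
  p <- immuneFreeParams(pKillNeg = 1, pKillPos = 1, tCellSpeed = 0, cancerSpeed = 0,
                        cancerCycleTime = 1e9)
  st <- initializeSimulation(cfg, p, seed = 2)
  a <- agents(st)
  st <- placeAgents(st, data.frame(state = 6L, x = a$x[1] - 1L, y = a$y[1],
                                   z = a$z[1]))
  st2 <- stepSimulation(st, 10)
  expect_equal(sum(eventLog(st2)$kills), 0)
  expect_equal(sum(agents(st2)$state == 3L), 0L)
})

test_that("T cells die at lifespan and enter in effector state", {
  cfg <- latticeConfig(nVoxels = 16, dtHours = 0.25)
  p <- immuneFreeParams(tCellLifespan = 1, tCellSpeed = 0)
  st <- initializeSimulation(cfg, p, seed = 2, seedCancer = FALSE)
  st <- placeAgents(st, data.frame(state = 4L, x = 8L, y = 8L, z = 8L))
  st2 <- stepSimulation(st, 4)  # 1 h = lifespan
  expect_equal(nrow(agents(st2)), 0L)
  expect_equal(sum(eventLog(st2)$tCellDeaths), 1)
})
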