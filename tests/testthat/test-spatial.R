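# Label smoothing, tumour-region extraction, cross sections, distance maps.

test_that("box smoothing matches hand-counted sums on simple phantoms", {
  v <- array(0L, c(9, 9, 9)); v[5, 5, 5] <- 1L
  expect_equal(sum(smoothLabels(v)), 0)  # max box mean 1/27 < 0.5

  # all-ones volume: zero padding erodes edges and corners (mean 12/27 and
  # 8/27) while faces (18/27) and the interior survive
  ones <- array(1L, c(6, 6, 6))
  so <- smoothLabels(ones)
  expect_identical(so, oracleBoxSmooth(ones))
  expect_true(all(so[2:5, 2:5, 2:5] == 1L))
  expect_equal(so[1, 1, 1], 0L)
  expect_equal(so[1, 1, 3], 0L)
  expect_equal(so[1, 3, 3], 1L)

  cube <- array(0L, c(11, 11, 11)); cube[5:7, 5:7, 5:7] <- 1L
  s <- smoothLabels(cube)
  expect_equal(s[6, 6, 6], 1L)   # centre: 27/27
  expect_equal(s[5, 5, 5], 0L)   # corner: 8/27 < 0.5
  expect_equal(s[6, 6, 5], 1L)   # face centre: 18/27 >= 0.5
  expect_identical(s, oracleBoxSmooth(cube))

  expect_error(smoothLabels(array(2L, c(3, 3, 3))), "binary")
})

test_that("box smoothing equals the direct triple-sum oracle on random volumes", {
  set.seed(101)
  for (r in 1:12) {
    v <- makeFixture("random_binary", n = 16, p = runif(1, 0.3, 0.7), seed = r)
    expect_identical(smoothLabels(v), oracleBoxSmooth(v))
  }
})

test_that("tumour region is the complement of the edge-connected background", {
  z <- array(0L, c(10, 10, 10))
  expect_equal(sum(tumorRegion(z)), 0)

  cube <- makeFixture("solid_cube", n = 20, size = 8)
  expect_identical(tumorRegion(cube), cube)

  shell <- makeFixture("hollow_shell", n = 20, size = 10, thickness = 2)
  tr <- tumorRegion(shell)
  # sealed cavity voxels are included in the tumour region
  cavity <- which(shell == 0L & tr == 1L)
  expect_equal(length(cavity), (10 - 4)^3)
  expect_identical(tr, oracleTumorRegion(shell))
})

test_that("tumour region equals a BFS flood-fill oracle on random volumes", {
  for (r in 1:10) {
    v <- makeFixture("random_binary", n = 16, p = 0.55, seed = 100 + r)
    expect_identical(tumorRegion(v), oracleTumorRegion(v))
  }
})

test_that("cross sections are taken at floor(N/2) on every axis", {
  cube <- makeFixture("solid_cube", n = 16, size = 6)
  secs <- crossSections(cube)
  expect_named(secs, c("x", "y", "z"))
  expect_true(all(vapply(secs, function(s) s@index, integer(1)) == 8L))
  s7 <- crossSections(makeFixture("solid_cube", n = 9, size = 2))
  expect_equal(s7$x@index, 4L)
  # axis-symmetric phantom: the three sections are identical
  m <- vapply(secs, function(s) sum(s@mask), numeric(1))
  expect_true(all(m == m[1]))
  expect_identical(secs$x@mask, secs$y@mask)
  expect_identical(secs$x@mask, secs$z@mask)
})

test_that("distance maps match the brute-force nearest-background oracle", {
  # 1-pixel tumour: distance is one voxel size
  m <- matrix(0L, 9, 9); m[5, 5] <- 1L
  d <- distanceMap(m, voxelSize = 10)
  expect_equal(d[5, 5], 10)
  expect_true(all(is.na(d[m == 0L])))

  # digital disc: max distance within one pixel of the radius
  disc <- makeFixture("digital_disc_section", n = 41, radius = 15)
  dd <- distanceMap(disc, voxelSize = 10)
  expect_lt(abs(max(dd, na.rm = TRUE) - 150) / 10, 1.01)
  expect_identical(dd, oracleDistanceMap(disc, 10))

  # empty mask: empty map
  expect_true(all(is.na(distanceMap(matrix(0L, 5, 5)))))

  # random sections, exact equality
  set.seed(7)
  for (r in 1:8) {
    m <- matrix(as.integer(runif(48^2) < 0.6), 48, 48)
    expect_identical(distanceMap(m, voxelSize = 10), oracleDistanceMap(m, 10))
  }
})

test_that("rim masks select by depth-to-surface and nest monotonically", {
  disc <- makeFixture("digital_disc_section", n = 45, radius = 20)
  d <- distanceMap(disc, voxelSize = 10)

  # threshold 0: exactly the boundary-adjacent pixels (distance = voxelSize)
  r0 <- rimMask(d, 0, voxelSize = 10)
  expect_true(all(d[r0 == 1L] == 10))
  expect_gt(sum(r0), 0)

  # threshold beyond the maximum depth: the whole tumour
  rAll <- rimMask(d, max(d, na.rm = TRUE), voxelSize = 10)
  expect_equal(sum(rAll), sum(disc))

  # disc of radius 200 um, threshold 50 um: an annulus against the oracle
  oracle <- oracleDistanceMap(disc, 10)
  expect_identical(rimMask(d, 50, voxelSize = 10),
                   matrix(as.integer(!is.na(oracle) & oracle - 10 <= 50),
                          nrow(oracle), ncol(oracle)))
  # nesting across thresholds
  prev <- r0
  for (th in c(20, 50, 100, 150)) {
    cur <- rimMask(d, th, voxelSize = 10)
    expect_true(all(cur[prev == 1L] == 1L))
    prev <- cur
  }
  expect_error(rimMask(d, -5, voxelSize = 10))
})

test_that("the full mask pipeline runs on a simulated snapshot", {
  cfg <- latticeConfig(nVoxels = 24, durationDays = 6, pdeCoarsen = 2L)
  p <- ruleParameters(cancerCycleTime = 6)
  r <- runSimulation(cfg, p, seed = 3, recordDays = 6)
  snap <- snapshots(r)[["day6"]]
  tm <- tumorMask(snap$labels)
  expect_gte(sum(tm@lRaw), sum(agents(r@finalState)$state <= 3L) * 8 - 16)
  expect_true(all(tumorRegion(tm) %in% 0:1))
  secs <- crossSections(tm, labels = snap$labels, agentIds = snap$agentIds)
  # rim nesting on a real section
  dz <- secs$z@distance
  skip_if(all(is.na(dz)))
  r1 <- rimMask(secs$z, 20); r2 <- rimMask(secs$z, 100)
  expect_true(all(r2[r1 == 1L] == 1L))
  # dead cells counted in lRaw by default, excluded on request
  tm2 <- tumorMask(snap$labels, includeDead = FALSE)
  expect_lte(sum(tm2@lRaw), sum(tm@lRaw))
})
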