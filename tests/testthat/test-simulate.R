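# Gaussian kernel constants and clean-map simulation

test_that("kernel constants follow the inverse-square convention", {
  # 0.9 * R0 = sqrt(pi) makes k exactly 1
  kern <- gaussianConstants(sqrt(pi) / 0.9)
  expect_equal(kern$k, 1.0)
  expect_equal(kern$C, pi^-1.5)

  kern3 <- gaussianConstants(3.0)
  expect_equal(kern3$k, pi / 2.7^2)
  expect_equal(kern3$k, 0.4309454, tolerance = 1e-6)
  expect_equal(kern3$C, (kern3$k / pi)^1.5)
  expect_equal(kern3$C, 0.05080529, tolerance = 1e-6)
})

test_that("the alternative parenthesization is available and distinct", {
  a <- gaussianConstants(3.0, "inverse-square")
  b <- gaussianConstants(3.0, "squared")
  expect_equal(b$k, (pi / 2.7)^2)
  expect_gt(b$k, a$k)
  expect_equal(b$C, (b$k / pi)^1.5)
})

test_that("normalization identity C * (pi/k)^{3/2} = 1 holds for random R0", {
  set.seed(1)
  for (R0 in runif(6, 1.5, 8))
    with(gaussianConstants(R0), expect_equal(C * (pi / k)^1.5, 1.0))
})

test_that("the cutoff radius meets the truncation-loss bound", {
  for (R0 in c(2, 3.5, 6)) {
    kern <- gaussianConstants(R0)
    expect_lte(exp(-kern$k * kern$cutoff_radius^2), 1e-4)  # spec bound
    k4 <- gaussianConstants(R0, tail = 1e-4)
    expect_equal(exp(-k4$k * k4$cutoff_radius^2), 1e-4)
  }
})

test_that("a single atom at a voxel center gives the closed-form density", {
  kern <- gaussianConstants(sqrt(pi) / 0.9)   # k = 1
  s <- AtomicStructure("C", matrix(c(3, 3, 3), 1))
  m <- simulateMap(s, kern, list(shape = c(7, 7, 7), voxel_size = 1,
                                 origin = c(0, 0, 0)))
  expect_equal(mapData(m)[4, 4, 4], 6 * pi^-1.5)
  expect_equal(mapData(m)[5, 4, 4], 6 * pi^-1.5 * exp(-1))
  expect_equal(mapData(m)[4, 6, 4], 6 * pi^-1.5 * exp(-4))
})

test_that("simulation is linear: coincident atoms double the map", {
  kern <- gaussianConstants(3)
  grid <- list(shape = c(9, 9, 9), voxel_size = 1, origin = c(-1, -1, -1))
  s1 <- AtomicStructure("N", matrix(c(3, 3, 3), 1))
  s2 <- AtomicStructure(c("N", "N"), matrix(c(3, 3, 3, 3, 3, 3), 2,
                                            byrow = TRUE))
  m1 <- simulateMap(s1, kern, grid)
  m2 <- simulateMap(s2, kern, grid)
  expect_equal(mapData(m2), 2 * mapData(m1))
})

test_that("simulateMap matches the brute-force (voxel x atom) double loop", {
  set.seed(42)
  n <- 20
  s <- AtomicStructure(sample(c("C", "N", "O", "S"), n, replace = TRUE),
                       matrix(runif(3 * n, 3, 13), n))
  kern <- gaussianConstants(3.5)
  grid <- list(shape = c(16, 16, 16), voxel_size = 1, origin = c(0, 0, 0))
  fast <- mapData(simulateMap(s, kern, grid))
  slow <- bruteForceSimulate(s, kern, grid)
  # agreement within 1e-4 of the map peak at every voxel, plus the
  # analytic truncation bound exp(-k cutoff^2) * C * sum(A_i)
  expect_lt(max(abs(fast - slow)) / max(slow), 1e-4)
  expect_lt(max(abs(fast - slow)),
            exp(-kern$k * kern$cutoff_radius^2) * sum(atomicNumbers(s)) *
              kern$C + 1e-12)
})

test_that("disabling the cutoff reproduces the brute force to round-off", {
  set.seed(3)
  s <- AtomicStructure(c("C", "O"), matrix(runif(6, 2, 6), 2))
  kern <- gaussianConstants(4)
  kern$cutoff_radius <- Inf
  grid <- list(shape = c(8, 8, 8), voxel_size = 1, origin = c(0, 0, 0))
  expect_equal(mapData(simulateMap(s, kern, grid)),
               bruteForceSimulate(s, kern, grid), tolerance = 1e-12)
})

test_that("voxel mass integrates to the atomic number on a fine grid", {
  for (R0 in c(2.5, 4)) {
    kern <- gaussianConstants(R0)
    vox <- 0.25 / sqrt(kern$k)
    s <- AtomicStructure("O", matrix(c(0, 0, 0), 1))
    half <- kern$cutoff_radius + 2
    n <- ceiling(2 * half / vox)
    m <- simulateMap(s, kern, list(shape = rep(n, 3), voxel_size = vox,
                                   origin = rep(-half, 3)))
    mass <- sum(mapData(m)) * vox^3
    expect_equal(mass, 8, tolerance = 0.01)
  }
})

test_that("occupancy weights scale contributions", {
  kern <- gaussianConstants(3)
  grid <- list(shape = c(7, 7, 7), voxel_size = 1, origin = c(0, 0, 0))
  s_full <- AtomicStructure("C", matrix(c(3, 3, 3), 1))
  s_half <- AtomicStructure("C", matrix(c(3, 3, 3), 1), occupancy = 0.5)
  expect_equal(mapData(simulateMap(s_half, kern, grid)),
               0.5 * mapData(simulateMap(s_full, kern, grid)))
})

test_that("integer-voxel translation shifts the map (equivariance)", {
  set.seed(9)
  s <- AtomicStructure(c("C", "N", "O"), matrix(runif(9, 6, 10), 3))
  kern <- gaussianConstants(3)
  grid <- list(shape = c(24, 24, 24), voxel_size = 1, origin = c(0, 0, 0))
  m0 <- mapData(simulateMap(s, kern, grid))
  s2 <- AtomicStructure(s@element, atomCoords(s) +
                          matrix(rep(c(2, 0, 0), each = 3), 3))
  m2 <- mapData(simulateMap(s2, kern, grid))
  # interior comparison away from boundaries
  expect_equal(m2[8:20, 4:20, 4:20], m0[6:18, 4:20, 4:20],
               tolerance = 1e-10)
})

test_that("a structure outside the grid warns and yields a zero map", {
  s <- AtomicStructure("C", matrix(c(100, 100, 100), 1))
  kern <- gaussianConstants(3)
  expect_warning(
    m <- simulateMap(s, kern, list(shape = c(8, 8, 8), voxel_size = 1,
                                   origin = c(0, 0, 0))),
    "outside")
  expect_true(all(mapData(m) == 0))
})

test_that("auto grid boxes the structure with the requested padding", {
  s <- AtomicStructure("C", matrix(c(0, 0, 0), 1))
  g <- autoGridForStructure(s, voxel_size = 1, padding = 4)
  expect_identical(g$shape, rep(9L, 3))
  expect_equal(g$origin, rep(-4, 3))

  s2 <- AtomicStructure(c("C", "C"), matrix(c(0, 0, 0, 10, 0, 0), 2,
                                            byrow = TRUE))
  g2 <- autoGridForStructure(s2, voxel_size = 1, padding = 5)
  expect_identical(g2$shape[1], 21L)

  # every atom at least padding - voxel from every face, on random fixtures
  set.seed(4)
  for (rep in 1:4) {
    st <- makeToyStructure(sample(5:15, 1), sample(c("helix", "strand"), 1))
    g3 <- autoGridForStructure(st, voxel_size = 1, padding = 4)
    lo <- g3$origin
    hi <- g3$origin + (g3$shape - 1) * g3$voxel_size
    expect_true(all(t(atomCoords(st)) - lo >= 4 - 1e-9))
    expect_true(all(hi - t(atomCoords(st)) >= 4 - g3$voxel_size - 1e-9))
  }
})
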