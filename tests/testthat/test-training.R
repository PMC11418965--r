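# Masked MSE, augmentation group, learning-rate schedule, training loop

test_that("masked MSE reproduces hand-enumerated oracles", {
  # identical blocks -> 0
  set.seed(1)
  b <- array(rnorm(27), c(3, 3, 3))
  expect_equal(maskedMSE(b, b), 0)

  # 2^3 block: one live prediction voxel against an all-zero target
  x <- array(c(1, 0, 0, 0, 0, 0, 0, 0), c(2, 2, 2))
  y <- array(0, c(2, 2, 2))
  expect_equal(maskedMSE(x, y, epsilon = 0), 1.0)   # N = 1, (1-0)^2 / 1

  # 1-D toy with no zeros: plain MSE
  expect_equal(maskedMSE(c(1, 2), c(3, 2)), 2.0)    # (4 + 0) / 2

  # fully masked -> 0 with a flag, not NaN
  z <- array(0, c(2, 2, 2))
  out <- maskedMSE(z, z)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "all_masked"))
})

test_that("masked MSE equals plain MSE when the target has no zeros", {
  set.seed(2)
  x <- array(rnorm(64), c(4, 4, 4))
  y <- array(rnorm(64) + 5, c(4, 4, 4))
  expect_equal(maskedMSE(x, y), mean((x - y)^2))
})

test_that("the epsilon tolerance controls what counts as a zero prediction", {
  x <- array(c(1e-7, 1, 0, 0), c(4, 1, 1))
  y <- array(c(0, 2, 0, 3), c(4, 1, 1))
  # epsilon 0: voxel 1 is live (|1e-7| > 0), N = 3
  expect_equal(maskedMSE(x, y, 0), (1e-14 + 1 + 9) / 3)
  # epsilon 1e-6: voxel 1 is masked, N = 2
  expect_equal(maskedMSE(x, y, 1e-6), (1 + 9) / 2)
})

test_that("masked MSE is invariant to simultaneous voxel permutation", {
  set.seed(3)
  x <- array(rnorm(64), c(4, 4, 4)); y <- array(rnorm(64), c(4, 4, 4))
  y[abs(y) < 0.3] <- 0
  p <- sample(64)
  expect_equal(maskedMSE(array(x[p], dim(x)), array(y[p], dim(y))),
               maskedMSE(x, y))
})

test_that("masked MSE gradient matches finite differences", {
  set.seed(4)
  x <- array(rnorm(27), c(3, 3, 3)); y <- array(rnorm(27), c(3, 3, 3))
  y[abs(y) < 0.4] <- 0
  g <- maskedMSE(x, y, with_grad = TRUE)
  for (i in c(1, 9, 27)) {
    xp <- x; xp[i] <- x[i] + 1e-6
    xm <- x; xm[i] <- x[i] - 1e-6
    fd <- (maskedMSE(xp, y) - maskedMSE(xm, y)) / 2e-6
    expect_equal(g$grad[i], fd, tolerance = 1e-5)
  }
})

test_that("orientations form the expected group: 24 proper rotations", {
  or24 <- emRestore:::.ORIENT24
  expect_length(or24, 24L)
  # all proper: permutation sign times flip signs is +1
  sgn <- function(p) det(diag(3)[p, ])
  for (o in or24)
    expect_equal(sgn(o$perm) * prod(ifelse(o$flip, -1, 1)), 1)
  # all distinct as transforms of a marked cube
  probe <- array(seq_len(3^3), c(3, 3, 3))
  images <- vapply(or24, function(o)
    paste(applyOrientation(probe, o), collapse = ","), character(1))
  expect_equal(length(unique(images)), 24L)
})

test_that("applying an orientation then its inverse is the identity", {
  set.seed(5)
  b <- array(rnorm(5^3), rep(5, 3))
  for (o in emRestore:::.ORIENT24) {
    expect_identical(applyOrientation(applyOrientation(b, o),
                                      invertOrientation(o)), b)
    # with extra mirrors composed in
    om <- list(perm = o$perm, flip = xor(o$flip, c(TRUE, FALSE, TRUE)))
    expect_identical(applyOrientation(applyOrientation(b, om),
                                      invertOrientation(om)), b)
  }
})

test_that("augmentation applies the same voxel permutation to both blocks", {
  set.seed(6)
  x <- array(rnorm(4^3), rep(4, 3)); y <- array(rnorm(4^3), rep(4, 3))
  au <- augmentPair(x, y)
  expect_identical(au$input, applyOrientation(x, au$orientation))
  expect_identical(au$target, applyOrientation(y, au$orientation))
  # multiset of values preserved (exact voxel permutation)
  expect_identical(sort(as.numeric(au$input)), sort(as.numeric(x)))
  # the loss commutes with joint augmentation
  y0 <- y; y0[abs(y0) < 0.3] <- 0
  au2 <- augmentPair(x, y0)
  expect_equal(maskedMSE(au2$input, au2$target), maskedMSE(x, y0))
})

test_that("identity draw leaves blocks unchanged", {
  set.seed(7)
  x <- array(rnorm(3^3), rep(3, 3))
  au <- augmentPair(x, x, rot90 = FALSE, flip = FALSE)
  expect_identical(au$input, x)
})

test_that("rotations are drawn uniformly over the 24 (chi-square)", {
  set.seed(8)
  x <- array(0, c(2, 2, 2))
  draws <- integer(10000)
  for (i in seq_along(draws)) draws[i] <- augmentPair(x, x)$rotation_index
  tab <- table(factor(draws, levels = 1:24))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("lr schedule: monotone improvement leaves the rate unchanged", {
  st <- lrScheduleInit()
  for (l in c(1.0, 0.9, 0.8)) st <- lrScheduleStep(st, l)
  expect_equal(st$lr, 5e-4)
})

test_that("lr schedule halves after two consecutive non-improvements", {
  st <- lrScheduleInit()
  st <- lrScheduleStep(st, 1.0)   # best = 1.0
  st <- lrScheduleStep(st, 1.1)   # bad 1
  expect_equal(st$lr, 5e-4)
  st <- lrScheduleStep(st, 1.2)   # bad 2 -> halve
  expect_equal(st$lr, 2.5e-4)
  expect_equal(st$bad_count, 0L)
})

test_that("lr schedule clamps at the floor and stays non-increasing", {
  st <- lrScheduleInit(initial_lr = 1.2e-5)
  st <- lrScheduleStep(st, 1.0)
  st <- lrScheduleStep(st, 2.0)
  st <- lrScheduleStep(st, 2.0)
  expect_equal(st$lr, 1e-5)
  st <- lrScheduleStep(st, 2.0); st <- lrScheduleStep(st, 2.0)
  expect_equal(st$lr, 1e-5)
  # worst case: never improving, rate halves at most ~5-6 times from 5e-4
  st2 <- lrScheduleInit()
  lrs <- numeric(20)
  for (i in 1:20) { st2 <- lrScheduleStep(st2, 1 + i); lrs[i] <- st2$lr }
  expect_true(all(diff(lrs) <= 0))
  expect_gte(min(lrs), 1e-5)
})

test_that("training on fully masked targets takes no parameter steps", {
  set.seed(9)
  cfg <- tinyArchitecture(base = 4L, heads = 2L, edge = 16L)
  net <- buildEnhancer(cfg)
  before <- emRestore:::flattenParams(net@modules)
  zeros <- array(0, c(16, 16, 16))
  pairs <- list(list(input = zeros, target = zeros))
  res <- trainEnhancer(pairs, pairs, net,
                       trainingConfig(max_epochs = 2L, batch_size = 1L,
                                      augment = FALSE, epsilon = 1e3,
                                      seed = 1L))
  expect_equal(res$history$loss, c(0, 0))
  expect_gte(res$masked_events, 2L)
  expect_identical(emRestore:::flattenParams(res$net@modules), before)
})

test_that("a training run is reproducible from its seed", {
  set.seed(10)
  mk <- function() {
    s <- makeToyStructure(6, "helix")
    g <- list(shape = c(16L, 16L, 16L), voxel_size = rep(1, 3),
              origin = apply(atomCoords(s), 2, min) - 3)
    clean <- simulateMap(s, gaussianConstants(4), g)
    deg <- degradeMap(clean, degradationSpec())
    list(input = mapData(deg), target = mapData(clean))
  }
  pairs <- list(mk(), mk())
  run <- function() {
    set.seed(77)
    net <- buildEnhancer(tinyArchitecture(base = 4L, heads = 2L))
    trainEnhancer(pairs, pairs[1], net,
                  trainingConfig(max_epochs = 3L, batch_size = 2L,
                                 seed = 5L))$history$loss
  }
  expect_equal(run(), run(), tolerance = 1e-12)
})
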