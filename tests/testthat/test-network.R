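# Architecture contracts: shapes, attention normalization, residual paths,
# gradient correctness, descent sanity

tinyNet <- function(seed = 42, base = 4L, heads = 2L, edge = 16L,
                    dropout = 0) {
  set.seed(seed)
  buildEnhancer(tinyArchitecture(base, heads, edge, dropout))
}

test_that("configuration validation enforces divisibility", {
  expect_error(architectureConfig(input_edge = 20L), "divisible")
  expect_error(architectureConfig(base_channels = 6L, epa_heads = 4L),
               "divisible")
  expect_silent(architectureConfig(base_channels = 8L, epa_heads = 4L,
                                   input_edge = 16L))
})

test_that("encoder stages halve the edge and set the level width", {
  set.seed(1)
  cfg <- tinyArchitecture(base = 4L, heads = 2L, edge = 16L)
  enc0 <- encoderStage(cfg, 0)
  x <- array(rnorm(16^3 * 2), c(16, 16, 16, 2, 1))
  r <- enc0$forward(x, training = TRUE)
  expect_identical(dim(r$out), c(8L, 8L, 8L, 2L, 4L))
  expect_identical(r$skip, x)
  enc3 <- encoderStage(cfg, 3)
  x3 <- array(rnorm(2^3 * 2 * 16), c(2, 2, 2, 2, 16))
  r3 <- enc3$forward(x3, training = TRUE)
  expect_identical(dim(r3$out), c(1L, 1L, 1L, 2L, 32L))
  # zero input stays finite through batch norm at batch >= 2
  z <- enc0$forward(array(0, c(16, 16, 16, 2, 1)), training = TRUE)
  expect_true(all(is.finite(z$out)))
})

test_that("decoder stages double the edge and fuse their skip", {
  set.seed(2)
  cfg <- tinyArchitecture(base = 4L, heads = 2L, edge = 16L)
  dec3 <- decoderStage(cfg, 3)
  x <- array(rnorm(1 * 32 * 2), c(1, 1, 1, 2, 32))
  skip <- array(rnorm(2^3 * 16 * 2), c(2, 2, 2, 2, 16))
  y <- dec3$forward(x, skip, training = TRUE)
  expect_identical(dim(y), c(2L, 2L, 2L, 2L, 16L))
  # mismatched skip is rejected
  expect_error(dec3$forward(x, array(0, c(3, 3, 3, 2, 16)), TRUE),
               "skip shape")
  # zeroing the skip changes the output: skips are live paths
  y0 <- dec3$forward(x, skip * 0, training = TRUE)
  expect_gt(max(abs(y - y0)), 0)
})

test_that("the full network maps E^3 -> E^3 for divisible E", {
  net <- tinyNet()
  for (E in c(16L, 32L)) {
    x <- array(runif(E^3), c(E, E, E))
    y <- networkForward(net, x)
    expect_identical(dim(y), dim(x))
    expect_true(all(is.finite(y)))
  }
})

test_that("transformer blocks preserve shape and are deterministic in eval", {
  set.seed(3)
  cfg <- tinyArchitecture(base = 4L, heads = 2L, edge = 16L, dropout = 0.3)
  tb <- transformerBlock(4L, 8L, cfg)
  x <- array(rnorm(8^3 * 2 * 4), c(8, 8, 8, 2, 4))
  y1 <- tb$forward(x, training = FALSE)
  y2 <- tb$forward(x, training = FALSE)
  expect_identical(dim(y1), dim(x))
  expect_identical(y1, y2)
  # dropout active in training mode makes runs differ
  set.seed(4); t1 <- tb$forward(x, training = TRUE)
  set.seed(5); t2 <- tb$forward(x, training = TRUE)
  expect_gt(max(abs(t1 - t2)), 0)
})

test_that("batch entries are processed independently (equivariance)", {
  net <- tinyNet()
  set.seed(6)
  x <- array(rnorm(16^3 * 3), c(16, 16, 16, 3, 1))
  y <- netForwardInternal(net@modules, x, FALSE)
  xp <- x[, , , c(3, 1, 2), , drop = FALSE]
  yp <- netForwardInternal(net@modules, xp, FALSE)
  expect_equal(yp, y[, , , c(3, 1, 2), , drop = FALSE], tolerance = 1e-10)
})

test_that("EPA attention rows sum to 1 in both branches", {
  set.seed(7)
  for (spec in list(c(8L, 4L), c(16L, 6L))) {
    C <- spec[1]; E <- spec[2]
    ep <- epaAttention(C, architectureConfig(base_channels = 8L,
                                             epa_heads = 4L,
                                             input_edge = 16L))
    x <- array(rnorm(E^3 * C), c(E, E, E, 1, C))
    y <- ep$forward(x, training = FALSE)
    expect_identical(dim(y), dim(x))
    aw <- ep$last_attention
    expect_equal(rowSums(aw$spatial), rep(1, nrow(aw$spatial)),
                 tolerance = 1e-5)
    expect_equal(rowSums(aw$channel), rep(1, nrow(aw$channel)),
                 tolerance = 1e-5)
    expect_true(all(aw$spatial >= 0) && all(aw$channel >= 0))
  }
})

test_that("channel-branch affinity matches a brute-force softmax oracle", {
  set.seed(8)
  C <- 4L; E <- 3L
  ep <- emRestore:::layerEPA("epa", C, heads = 1L, proj_grid = c(2L, 2L, 2L))
  # fixed, known weights
  ep$params$Wq <- matrix(seq(-0.3, 0.4, length.out = C * C), C, C)
  ep$params$Wk <- matrix(seq(0.2, -0.5, length.out = C * C), C, C)
  ep$params$log_tau <- log(1.7)
  x <- array(seq(-1, 1, length.out = E^3 * C), c(E, E, E, 1, C))
  invisible(ep$forward(x, training = FALSE))
  X <- matrix(x[, , , 1, ], E^3, C)
  Q <- X %*% ep$params$Wq; K <- X %*% ep$params$Wk
  S <- t(Q) %*% K / 1.7
  oracle <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(ep$last_attention$channel, oracle, tolerance = 1e-12)
})

test_that("ConvRes is the identity when conv weights are zeroed", {
  set.seed(9)
  cr <- convResBlock(4L, tinyArchitecture(), use_norm = FALSE)
  for (nm in c("conv1", "conv2", "conv3")) {
    cr[[nm]]$params$W[] <- 0
    cr[[nm]]$params$b[] <- 0
  }
  x <- array(rnorm(6^3 * 4 * 2), c(6, 6, 6, 2, 4))
  expect_equal(cr$forward(x, training = FALSE), x)
})

test_that("ConvRes passes gradient through both residual and conv paths", {
  set.seed(10)
  cr <- convResBlock(2L, tinyArchitecture())
  x <- array(rnorm(4^3 * 2 * 2), c(4, 4, 4, 2, 2))
  y <- cr$forward(x, training = TRUE)
  dy <- array(1, dim(y))
  emRestore:::zeroGrads(cr)
  dx <- cr$backward(dy)
  expect_gt(sum(abs(cr$conv1$grads$W)), 0)
  expect_gt(sum(abs(cr$conv3$grads$W)), 0)
  # residual path guarantees dx deviates from the pure conv gradient
  expect_gt(min(abs(dx)), 0)
})

test_that("parameter count scales ~quadratically with width", {
  set.seed(11)
  p32 <- parameterCount(buildEnhancer(architectureConfig(
    base_channels = 32L, input_edge = 16L)))
  p8 <- parameterCount(buildEnhancer(architectureConfig(
    base_channels = 8L, input_edge = 16L)))
  ratio <- p32 / p8
  expect_gt(ratio, 10); expect_lt(ratio, 25)
})

test_that("all layer gradients match finite differences", {
  net <- tinyNet(seed = 12)
  set.seed(13)
  x <- array(runif(16^3 * 2), c(16, 16, 16, 2, 1))
  tgt <- array(runif(16^3 * 2), c(16, 16, 16, 2, 1))
  tgt[tgt < 0.5] <- 0
  fwd <- function() maskedMSE(netForwardInternal(net@modules, x, TRUE), tgt)
  pred <- netForwardInternal(net@modules, x, TRUE)
  lg <- maskedMSE(pred, tgt, with_grad = TRUE)
  emRestore:::zeroGrads(net@modules)
  dx <- netBackwardInternal(net@modules, lg$grad)
  layers <- emRestore:::collectParamLayers(net@modules)
  set.seed(14)
  for (trial in 1:10) {
    l <- layers[[sample(length(layers), 1)]]
    nm <- sample(names(l$params), 1)
    i <- sample(length(l$params[[nm]]), 1)
    orig <- l$params[[nm]][i]
    l$params[[nm]][i] <- orig + 1e-5; lp <- fwd()
    l$params[[nm]][i] <- orig - 1e-5; lm <- fwd()
    l$params[[nm]][i] <- orig
    fd <- (lp - lm) / 2e-5
    expect_equal(l$grads[[nm]][i], fd, tolerance = 1e-3,
                 info = paste(l$name, nm))
  }
  # input gradient too
  i <- 1000
  xv <- x; xv[i] <- x[i] + 1e-5
  lp <- maskedMSE(netForwardInternal(net@modules, xv, TRUE), tgt)
  xv[i] <- x[i] - 1e-5
  lm <- maskedMSE(netForwardInternal(net@modules, xv, TRUE), tgt)
  expect_equal(dx[i], (lp - lm) / 2e-5, tolerance = 1e-4)
})

test_that("one small gradient step decreases the loss (descent sanity)", {
  net <- tinyNet(seed = 15)
  set.seed(16)
  x <- array(runif(16^3), c(16, 16, 16, 1, 1))
  tgt <- array(runif(16^3), c(16, 16, 16, 1, 1)); tgt[tgt < 0.6] <- 0
  loss0 <- maskedMSE(netForwardInternal(net@modules, x, TRUE), tgt)
  emRestore:::zeroGrads(net@modules)
  pred <- netForwardInternal(net@modules, x, TRUE)
  lg <- maskedMSE(pred, tgt, with_grad = TRUE)
  netBackwardInternal(net@modules, lg$grad)
  for (l in emRestore:::collectParamLayers(net@modules))
    for (nm in names(l$params))
      l$params[[nm]] <- l$params[[nm]] - 1e-4 * l$grads[[nm]]
  loss1 <- maskedMSE(netForwardInternal(net@modules, x, TRUE), tgt)
  expect_lt(loss1, loss0)
})

test_that("checkpoints round trip parameters and running statistics", {
  net <- tinyNet(seed = 17)
  set.seed(18)
  x <- array(runif(16^3 * 2), c(16, 16, 16, 2, 1))
  invisible(netForwardInternal(net@modules, x, TRUE))  # move BN stats
  y_before <- netForwardInternal(net@modules, x, FALSE)
  tf <- withr::local_tempfile(fileext = ".rds")
  saveCheckpoint(net, tf, extra = list(note = "unit"))
  net2 <- loadCheckpoint(tf)
  y_after <- netForwardInternal(net2@modules, x, FALSE)
  expect_equal(y_after, y_before, tolerance = 1e-12)
  expect_equal(attr(net2, "extra")$note, "unit")
  expect_equal(parameterCount(net2), parameterCount(net))
})
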