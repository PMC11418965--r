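# Layer library for the 3-D U-Net transformer.
#
# There is no deep-learning framework in this stack, so layers are built
# directly on BLAS-backed matrix products: every layer is an environment
# carrying its parameters, accumulated gradients, and forward/backward
# closures.  Activations are 5-D arrays with dimensions (D, H, W, B, C) —
# spatial axes fastest (R is column-major), then batch, then channels — so
# a reshape to an (N*B) x C matrix is free and channel-wise linear algebra
# maps onto single dgemm calls.  All gradients are analytic and are covered
# by finite-difference checks in the test suite.

newLayer <- function(name, params = list()) {
  ly <- new.env(parent = emptyenv())
  ly$name <- name
  ly$params <- params
  ly$grads <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  ly$children <- list()
  ly
}

zeroGrads <- function(ly) {
  for (nm in names(ly$params))
    ly$grads[[nm]] <- array(0, dim(ly$params[[nm]]) %||%
                            length(ly$params[[nm]]))
  for (ch in ly$children) zeroGrads(ch)
  invisible(NULL)
}

collectParamLayers <- function(ly, acc = list()) {
  if (length(ly$params)) acc <- c(acc, list(ly))
  for (ch in ly$children) acc <- collectParamLayers(ch, acc)
  acc
}

flattenParams <- function(ly) {
  out <- list()
  for (l in collectParamLayers(ly))
    for (nm in names(l$params))
      out[[paste(l$name, nm, sep = ".")]] <- l$params[[nm]]
  out
}

assignParams <- function(ly, flat) {
  for (l in collectParamLayers(ly))
    for (nm in names(l$params)) {
      key <- paste(l$name, nm, sep = ".")
      if (is.null(flat[[key]])) stop("checkpoint is missing parameter ", key)
      stopifnot(length(flat[[key]]) == length(l$params[[nm]]))
      l$params[[nm]] <- flat[[key]]
    }
  invisible(NULL)
}

countParams <- function(ly) {
  sum(vapply(flattenParams(ly), length, numeric(1)))
}

heInit <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

# ---- 3-D convolution (odd kernel, "same"-style padding, any stride) ----
# Implemented as k^3 shifted matrix products: for each kernel offset the
# valid input window is gathered, multiplied by the (Cin x Cout) weight
# slice, and scatter-added into the output.

convOffsetRanges <- function(D, Do, k_off, stride, pad) {
  # output indices o (1-based) whose input position p = stride*(o-1)+1+k_off-pad
  # lies in [1, D]; returns NULL if empty
  o_min <- 1L + max(0L, as.integer(ceiling((pad - k_off) / stride)))
  o_max <- min(Do, 1L + as.integer(floor((D - 1L - k_off + pad) / stride)))
  if (o_min > o_max) return(NULL)
  o <- o_min:o_max
  list(o = o, p = stride * (o - 1L) + 1L + k_off - pad)
}

# zero-pad the three spatial axes of a (D,H,W,B,C) array by p voxels
padSpatial <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1:3] + 2L * p, d[4:5]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), , ] <- x
  xp
}

# "same" convolution via padded shifted slices: one gather + one dgemm per
# kernel offset, accumulating into a flat output matrix (no scatter writes)
convSameForward <- function(xp, W, b, d_out, B) {
  k <- dim(W)[1]; in_ch <- dim(W)[4]; out_ch <- dim(W)[5]
  nv <- prod(d_out) * B
  ym <- matrix(rep(b, each = nv), nv, out_ch)
  for (kd in 0:(k - 1)) for (kh in 0:(k - 1)) for (kw in 0:(k - 1)) {
    xg <- xp[kd + seq_len(d_out[1]), kh + seq_len(d_out[2]),
             kw + seq_len(d_out[3]), , , drop = FALSE]
    dim(xg) <- c(nv, in_ch)
    Wk <- W[kd + 1, kh + 1, kw + 1, , ]
    dim(Wk) <- c(in_ch, out_ch)
    ym <- ym + xg %*% Wk
  }
  array(ym, c(d_out, B, out_ch))
}

layerConv3d <- function(name, in_ch, out_ch, kernel = 3L, stride = 1L,
                        pad = (kernel - 1L) %/% 2L) {
  k <- as.integer(kernel)
  W <- heInit(c(k, k, k, in_ch, out_ch), fan_in = k^3 * in_ch)
  b <- numeric(out_ch)
  ly <- newLayer(name, list(W = W, b = b))
  ly$k <- k; ly$stride <- as.integer(stride); ly$pad <- as.integer(pad)
  ly$in_ch <- in_ch; ly$out_ch <- out_ch
  ly$same <- (as.integer(stride) == 1L &&
              as.integer(pad) == (k - 1L) %/% 2L)

  # weight tensor flattened to a (k^3 * in_ch) x out_ch matrix whose row
  # blocks follow the (kd, kh, kw) gather order used by im2col below
  wMat <- function(W) {
    kk <- dim(W)[1]
    out <- matrix(0, kk^3 * dim(W)[4], dim(W)[5])
    r <- 0L
    for (kd in 0:(kk - 1)) for (kh in 0:(kk - 1)) for (kw in 0:(kk - 1)) {
      out[r + seq_len(dim(W)[4]), ] <- W[kd + 1, kh + 1, kw + 1, , ]
      r <- r + dim(W)[4]
    }
    out
  }

  im2col <- function(xp, d3, B, in_ch) {
    nv <- prod(d3) * B
    col <- matrix(0, nv, k^3 * in_ch)
    cix <- 0L
    for (kd in 0:(k - 1)) for (kh in 0:(k - 1)) for (kw in 0:(k - 1)) {
      xg <- xp[kd + seq_len(d3[1]), kh + seq_len(d3[2]),
               kw + seq_len(d3[3]), , , drop = FALSE]
      col[, cix + seq_len(in_ch)] <- xg
      cix <- cix + in_ch
    }
    col
  }

  ly$forwardSame <- function(x, training = FALSE) {
    d <- dim(x)
    if (!training) {
      # streaming accumulation: low memory, used at inference scale
      xp <- padSpatial(x, ly$pad)
      return(convSameForward(xp, ly$params$W, ly$params$b, d[1:3], d[4]))
    }
    xp <- padSpatial(x, ly$pad)
    xcol <- im2col(xp, d[1:3], d[4], ly$in_ch)
    ly$cache <- list(xcol = xcol, d = d)
    ym <- xcol %*% wMat(ly$params$W)
    ym <- ym + rep(ly$params$b, each = nrow(ym))
    array(ym, c(d[1:3], d[4], ly$out_ch))
  }

  ly$backwardSame <- function(dy) {
    cc <- ly$cache; d <- cc$d; B <- d[4]
    nv <- prod(d[1:3]) * B
    dym <- dy; dim(dym) <- c(nv, ly$out_ch)
    ly$grads$b <- ly$grads$b + colSums(dym)
    dWmat <- crossprod(cc$xcol, dym)          # (k^3 Cin) x Cout
    r <- 0L
    for (kd in 0:(k - 1)) for (kh in 0:(k - 1)) for (kw in 0:(k - 1)) {
      ly$grads$W[kd + 1, kh + 1, kw + 1, , ] <-
        ly$grads$W[kd + 1, kh + 1, kw + 1, , ] +
        dWmat[r + seq_len(ly$in_ch), ]
      r <- r + ly$in_ch
    }
    # backward-data = "same" convolution of dy with the spatially reversed,
    # channel-transposed kernel, via a second im2col + dgemm
    Wrev <- aperm(ly$params$W, c(1, 2, 3, 5, 4))[k:1, k:1, k:1, , ,
                                                 drop = FALSE]
    dyp <- padSpatial(dy, ly$pad)
    dycol <- im2col(dyp, d[1:3], B, ly$out_ch)
    dxm <- dycol %*% wMat(Wrev)
    array(dxm, d)
  }

  ly$forwardGeneric <- function(x, training = FALSE) {
    d <- dim(x)
    Do <- (d[1:3] + 2L * ly$pad - k) %/% ly$stride + 1L
    B <- d[4]
    y <- array(rep(ly$params$b, each = prod(Do) * B), c(Do, B, ly$out_ch))
    for (kd in 0:(k - 1)) for (kh in 0:(k - 1)) for (kw in 0:(k - 1)) {
      rd <- convOffsetRanges(d[1], Do[1], kd, ly$stride, ly$pad)
      rh <- convOffsetRanges(d[2], Do[2], kh, ly$stride, ly$pad)
      rw <- convOffsetRanges(d[3], Do[3], kw, ly$stride, ly$pad)
      if (is.null(rd) || is.null(rh) || is.null(rw)) next
      xg <- x[rd$p, rh$p, rw$p, , , drop = FALSE]
      nv <- length(rd$p) * length(rh$p) * length(rw$p) * B
      dim(xg) <- c(nv, ly$in_ch)
      Wk <- ly$params$W[kd + 1, kh + 1, kw + 1, , ]
      dim(Wk) <- c(ly$in_ch, ly$out_ch)
      contrib <- xg %*% Wk
      dim(contrib) <- c(length(rd$p), length(rh$p), length(rw$p), B,
                        ly$out_ch)
      y[rd$o, rh$o, rw$o, , ] <- y[rd$o, rh$o, rw$o, , , drop = FALSE] +
        contrib
    }
    if (training) ly$cache <- list(x = x, Do = Do)
    y
  }

  ly$backwardGeneric <- function(dy) {
    x <- ly$cache$x; Do <- ly$cache$Do
    d <- dim(x); B <- d[4]
    dx <- array(0, d)
    dym <- dy; dim(dym) <- c(prod(Do) * B, ly$out_ch)
    ly$grads$b <- ly$grads$b + colSums(dym)
    for (kd in 0:(k - 1)) for (kh in 0:(k - 1)) for (kw in 0:(k - 1)) {
      rd <- convOffsetRanges(d[1], Do[1], kd, ly$stride, ly$pad)
      rh <- convOffsetRanges(d[2], Do[2], kh, ly$stride, ly$pad)
      rw <- convOffsetRanges(d[3], Do[3], kw, ly$stride, ly$pad)
      if (is.null(rd) || is.null(rh) || is.null(rw)) next
      nv <- length(rd$p) * length(rh$p) * length(rw$p) * B
      xg <- x[rd$p, rh$p, rw$p, , , drop = FALSE]
      dim(xg) <- c(nv, ly$in_ch)
      dyg <- dy[rd$o, rh$o, rw$o, , , drop = FALSE]
      dim(dyg) <- c(nv, ly$out_ch)
      Wk <- ly$params$W[kd + 1, kh + 1, kw + 1, , ]
      dim(Wk) <- c(ly$in_ch, ly$out_ch)
      ly$grads$W[kd + 1, kh + 1, kw + 1, , ] <-
        ly$grads$W[kd + 1, kh + 1, kw + 1, , ] + crossprod(xg, dyg)
      dxg <- tcrossprod(dyg, Wk)
      dim(dxg) <- c(length(rd$p), length(rh$p), length(rw$p), B, ly$in_ch)
      dx[rd$p, rh$p, rw$p, , ] <- dx[rd$p, rh$p, rw$p, , , drop = FALSE] +
        dxg
    }
    dx
  }

  ly$forward <- function(x, training = FALSE)
    if (ly$same) ly$forwardSame(x, training) else ly$forwardGeneric(x, training)
  ly$backward <- function(dy)
    if (ly$same) ly$backwardSame(dy) else ly$backwardGeneric(dy)
  ly
}

# ---- transposed 3-D convolution, kernel 2 stride 2 (exact doubling) ----

layerConvT3d <- function(name, in_ch, out_ch) {
  W <- heInit(c(2, 2, 2, in_ch, out_ch), fan_in = in_ch)
  b <- numeric(out_ch)
  ly <- newLayer(name, list(W = W, b = b))
  ly$in_ch <- in_ch; ly$out_ch <- out_ch

  ly$forward <- function(x, training = FALSE) {
    d <- dim(x); B <- d[4]
    Do <- 2L * d[1:3]
    nv <- prod(d[1:3]) * B
    xm <- x; dim(xm) <- c(nv, ly$in_ch)
    y <- array(rep(ly$params$b, each = prod(Do) * B), c(Do, B, ly$out_ch))
    for (kd in 0:1) for (kh in 0:1) for (kw in 0:1) {
      Wk <- ly$params$W[kd + 1, kh + 1, kw + 1, , ]
      dim(Wk) <- c(ly$in_ch, ly$out_ch)
      contrib <- xm %*% Wk
      dim(contrib) <- c(d[1:3], B, ly$out_ch)
      od <- seq(1L + kd, Do[1], by = 2L)
      oh <- seq(1L + kh, Do[2], by = 2L)
      ow <- seq(1L + kw, Do[3], by = 2L)
      y[od, oh, ow, , ] <- y[od, oh, ow, , , drop = FALSE] + contrib
    }
    if (training) ly$cache <- list(x = x)
    y
  }

  ly$backward <- function(dy) {
    x <- ly$cache$x
    d <- dim(x); B <- d[4]; Do <- 2L * d[1:3]
    nv <- prod(d[1:3]) * B
    xm <- x; dim(xm) <- c(nv, ly$in_ch)
    dym_all <- dy; dim(dym_all) <- c(prod(Do) * B, ly$out_ch)
    ly$grads$b <- ly$grads$b + colSums(dym_all)
    dxm <- matrix(0, nv, ly$in_ch)
    for (kd in 0:1) for (kh in 0:1) for (kw in 0:1) {
      od <- seq(1L + kd, Do[1], by = 2L)
      oh <- seq(1L + kh, Do[2], by = 2L)
      ow <- seq(1L + kw, Do[3], by = 2L)
      dyg <- dy[od, oh, ow, , , drop = FALSE]
      dim(dyg) <- c(nv, ly$out_ch)
      Wk <- ly$params$W[kd + 1, kh + 1, kw + 1, , ]
      dim(Wk) <- c(ly$in_ch, ly$out_ch)
      ly$grads$W[kd + 1, kh + 1, kw + 1, , ] <-
        ly$grads$W[kd + 1, kh + 1, kw + 1, , ] + crossprod(xm, dyg)
      dxm <- dxm + tcrossprod(dyg, Wk)
    }
    dim(dxm) <- d
    dxm
  }
  ly
}

# ---- batch normalization (statistics over space and batch, per channel) ----

layerBatchNorm <- function(name, channels, eps = 1e-5, momentum = 0.1) {
  ly <- newLayer(name, list(gamma = rep(1, channels), beta = numeric(channels)))
  ly$eps <- eps; ly$momentum <- momentum; ly$channels <- channels
  ly$running_mean <- numeric(channels)
  ly$running_var <- rep(1, channels)

  ly$forward <- function(x, training = FALSE) {
    d <- dim(x); n <- prod(d[1:4])
    xm <- x; dim(xm) <- c(n, ly$channels)
    if (training) {
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      v <- colMeans(xc^2)
      ly$running_mean <- (1 - ly$momentum) * ly$running_mean + ly$momentum * mu
      ly$running_var <- (1 - ly$momentum) * ly$running_var + ly$momentum * v
    } else {
      mu <- ly$running_mean
      xc <- sweep(xm, 2, mu)
      v <- ly$running_var
    }
    invstd <- 1 / sqrt(v + ly$eps)
    xhat <- sweep(xc, 2, invstd, `*`)
    ym <- sweep(sweep(xhat, 2, ly$params$gamma, `*`), 2, ly$params$beta, `+`)
    if (training)
      ly$cache <- list(xhat = xhat, invstd = invstd, n = n,
                       training = training, d = d)
    dim(ym) <- d
    ym
  }

  ly$backward <- function(dy) {
    cc <- ly$cache
    dym <- dy; dim(dym) <- c(cc$n, ly$channels)
    ly$grads$gamma <- ly$grads$gamma + colSums(dym * cc$xhat)
    ly$grads$beta <- ly$grads$beta + colSums(dym)
    dxhat <- sweep(dym, 2, ly$params$gamma, `*`)
    if (cc$training) {
      # dx = invstd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
      s1 <- colMeans(dxhat)
      s2 <- colMeans(dxhat * cc$xhat)
      dxm <- sweep(dxhat, 2, s1) - sweep(cc$xhat, 2, s2, `*`)
      dxm <- sweep(dxm, 2, cc$invstd, `*`)
    } else {
      dxm <- sweep(dxhat, 2, cc$invstd, `*`)
    }
    dim(dxm) <- cc$d
    dxm
  }
  ly
}

# ---- instance normalization (per sample, per channel, over space) ----

layerInstanceNorm <- function(name, channels, eps = 1e-5) {
  ly <- newLayer(name, list(gamma = rep(1, channels), beta = numeric(channels)))
  ly$eps <- eps; ly$channels <- channels

  ly$forward <- function(x, training = FALSE) {
    d <- dim(x); n <- prod(d[1:3]); BC <- d[4] * d[5]
    xm <- x; dim(xm) <- c(n, BC)
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    invstd <- 1 / sqrt(v + ly$eps)
    xhat <- sweep(xc, 2, invstd, `*`)
    gam <- rep(ly$params$gamma, each = d[4])
    bet <- rep(ly$params$beta, each = d[4])
    ym <- sweep(sweep(xhat, 2, gam, `*`), 2, bet, `+`)
    ly$cache <- list(xhat = xhat, invstd = invstd, d = d, n = n)
    dim(ym) <- d
    ym
  }

  ly$backward <- function(dy) {
    cc <- ly$cache; d <- cc$d
    dym <- dy; dim(dym) <- c(cc$n, d[4] * d[5])
    gcol <- colSums(dym * cc$xhat)
    bcol <- colSums(dym)
    ly$grads$gamma <- ly$grads$gamma +
      colSums(matrix(gcol, d[4], d[5]))
    ly$grads$beta <- ly$grads$beta + colSums(matrix(bcol, d[4], d[5]))
    gam <- rep(ly$params$gamma, each = d[4])
    dxhat <- sweep(dym, 2, gam, `*`)
    s1 <- colMeans(dxhat)
    s2 <- colMeans(dxhat * cc$xhat)
    dxm <- sweep(dxhat, 2, s1) - sweep(cc$xhat, 2, s2, `*`)
    dxm <- sweep(dxm, 2, cc$invstd, `*`)
    dim(dxm) <- d
    dxm
  }
  ly
}

# ---- pointwise nonlinearity and dropout ----

layerLeakyReLU <- function(name, slope = 0.01) {
  ly <- newLayer(name)
  ly$slope <- slope
  ly$forward <- function(x, training = FALSE) {
    neg <- x < 0
    y <- x
    y[neg] <- y[neg] * ly$slope
    if (training) ly$cache <- neg
    y
  }
  ly$backward <- function(dy) {
    dx <- dy
    dx[ly$cache] <- dx[ly$cache] * ly$slope
    dx
  }
  ly
}

layerDropout <- function(name, rate = 0.1) {
  ly <- newLayer(name)
  ly$rate <- rate
  ly$forward <- function(x, training = FALSE) {
    if (!training || ly$rate <= 0) {
      ly$cache <- NULL
      return(x)
    }
    keep <- array(stats::runif(length(x)) >= ly$rate, dim(x))
    ly$cache <- keep
    x * keep / (1 - ly$rate)
  }
  ly$backward <- function(dy) {
    if (is.null(ly$cache)) return(dy)
    dy * ly$cache / (1 - ly$rate)
  }
  ly
}

# ---- separable learned positional embedding ----
# pe[c, d, h, w] = ed[d, c] + eh[h, c] + ew[w, c], stored at the stage's
# design edge and linearly resized when the stage runs at another edge.

resizeMatrix1D <- function(n_from, n_to) {
  if (n_from == n_to) return(diag(n_to))
  if (n_from == 1L) return(matrix(1, n_to, 1L))
  R <- matrix(0, n_to, n_from)
  pos <- if (n_to == 1L) 0 else (seq_len(n_to) - 1) * (n_from - 1) / (n_to - 1)
  i0 <- pmin(floor(pos), n_from - 2); i0 <- pmax(i0, 0)
  fr <- pos - i0
  for (r in seq_len(n_to)) {
    R[r, i0[r] + 1] <- 1 - fr[r]
    R[r, i0[r] + 2] <- R[r, i0[r] + 2] + fr[r]
  }
  R
}

layerPosEmbed <- function(name, channels, base_edge) {
  init <- function() matrix(stats::rnorm(base_edge * channels, 0, 0.02),
                            base_edge, channels)
  ly <- newLayer(name, list(ed = init(), eh = init(), ew = init()))
  ly$channels <- channels; ly$base_edge <- base_edge

  embAt <- function(E, which) {
    R <- resizeMatrix1D(ly$base_edge, E)
    list(e = R %*% ly$params[[which]], R = R)
  }

  ly$forward <- function(x, training = FALSE) {
    d <- dim(x)
    ad <- embAt(d[1], "ed"); ah <- embAt(d[2], "eh"); aw <- embAt(d[3], "ew")
    # broadcast pe (D,H,W,C) over the batch axis
    pe <- array(0, c(d[1], d[2], d[3], d[5]))
    for (cch in seq_len(d[5]))
      pe[, , , cch] <- outer(outer(ad$e[, cch], ah$e[, cch], `+`),
                             aw$e[, cch], `+`)
    y <- x
    for (bb in seq_len(d[4])) y[, , , bb, ] <- y[, , , bb, ] + pe
    ly$cache <- list(d = d, Rd = ad$R, Rh = ah$R, Rw = aw$R)
    y
  }

  ly$backward <- function(dy) {
    cc <- ly$cache; d <- cc$d
    # per-axis sums of dy over the other two spatial axes and batch
    sumAxis <- function(axis) {
      perm <- c(axis, setdiff(1:3, axis), 4, 5)
      a <- aperm(dy, perm)
      dim(a) <- c(d[axis], prod(d[setdiff(1:3, axis)]) * d[4], d[5])
      r <- matrix(0, d[axis], d[5])
      for (cch in seq_len(d[5])) r[, cch] <- rowSums(a[, , cch, drop = FALSE])
      r
    }
    ly$grads$ed <- ly$grads$ed + crossprod(cc$Rd, sumAxis(1))
    ly$grads$eh <- ly$grads$eh + crossprod(cc$Rh, sumAxis(2))
    ly$grads$ew <- ly$grads$ew + crossprod(cc$Rw, sumAxis(3))
    dy
  }
  ly
}
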