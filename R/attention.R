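# Efficient paired attention: two parallel branches sharing query/key
# projections.
#
#   channel branch — multi-head C/h x C/h affinity softmax(Q^T K / tau),
#     mixing feature channels (rows sum to 1);
#   spatial branch — queries attend to a low-rank projection of the N = DHW
#     positions: tokens are partition-pooled to p slots and mixed by a
#     learned p x p matrix, so the cost is O(N p) instead of O(N^2).
#
# Branch outputs are concatenated and fused back to C channels.  The pooled
# projection (rather than a learned N x p map) keeps one set of weights
# valid for every divisible input edge.  The batch is processed as stacked
# token rows so projections and softmaxes each run once per call.

softmaxRows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# d(softmax)/dS given upstream dA: dS = (dA - rowSums(dA * A)) * A
softmaxRowsBackward <- function(dA, A) {
  (dA - rowSums(dA * A)) * A
}

# Partition pooling: every token grid position is assigned to exactly one
# slot per axis (slot(i) = floor((i-1) * p / n) + 1, clamped), so pooling is
# a grouped mean (rowsum) and its adjoint a cheap gather.  Slots with no
# token (only possible when an axis is shorter than the slot grid) pool to 0.
poolAssignment <- function(d3, p3) {
  ax <- lapply(1:3, function(a)
    pmin(floor((seq_len(d3[a]) - 1) * p3[a] / d3[a]) + 1L, p3[a]))
  slot <- outer(outer(ax[[1]] - 1L, (ax[[2]] - 1L) * p3[1], `+`),
                (ax[[3]] - 1L) * p3[1] * p3[2], `+`) + 1L
  slot <- as.integer(slot)
  p <- prod(p3)
  counts <- tabulate(slot, nbins = p)
  list(slot = slot, counts = counts, p = p)
}

# batch-stacked pooling: tokens (N*B x C) -> slots (p*B x C), grouped means
poolTokens <- function(X, pa, B, N) {
  slot_all <- rep(pa$slot, times = B) + rep((seq_len(B) - 1L) * pa$p,
                                            each = N)
  S <- rowsum(X, slot_all)                  # rows ordered by slot id
  idx <- as.integer(rownames(S))
  out <- matrix(0, pa$p * B, ncol(X))
  cnt <- rep(pa$counts, times = B)
  out[idx, ] <- S / cnt[idx]
  out
}

poolTokensAdjoint <- function(dP, pa, B, N) {
  slot_all <- rep(pa$slot, times = B) + rep((seq_len(B) - 1L) * pa$p,
                                            each = N)
  cnt <- rep(pa$counts, times = B)
  dP[slot_all, , drop = FALSE] / cnt[slot_all]
}

# apply a p x p mixing matrix to each sample's block of p rows
mixBlocks <- function(M, X, B, p) {
  out <- X
  for (bb in seq_len(B)) {
    r <- (bb - 1L) * p + seq_len(p)
    out[r, ] <- M %*% X[r, , drop = FALSE]
  }
  out
}

layerEPA <- function(name, channels, heads, proj_grid = c(4L, 4L, 4L),
                     init_sd = NULL) {
  stopifnot(channels %% heads == 0L)
  p <- prod(proj_grid)
  sdv <- init_sd %||% (1 / sqrt(channels))
  pm <- function() matrix(stats::rnorm(channels^2, 0, sdv), channels, channels)
  ly <- newLayer(name, list(
    Wq = pm(), Wk = pm(), Wvs = pm(), Wvc = pm(),
    log_tau = numeric(heads),
    Mk = diag(p) + matrix(stats::rnorm(p * p, 0, 0.01), p, p),
    Mv = diag(p) + matrix(stats::rnorm(p * p, 0, 0.01), p, p),
    Wf = matrix(stats::rnorm(2 * channels * channels, 0, sdv / 2),
                2 * channels, channels),
    bf = numeric(channels)))
  ly$channels <- channels; ly$heads <- heads; ly$proj_grid <- proj_grid
  ly$p <- p
  ly$pool_cache <- list()

  poolFor <- function(d3) {
    key <- paste(d3, collapse = "x")
    pa <- ly$pool_cache[[key]]
    if (is.null(pa)) {
      pa <- poolAssignment(d3, ly$proj_grid)
      ly$pool_cache[[key]] <- pa
    }
    pa
  }

  # spatial attention scores for one head: block-diagonal in the batch
  # (each sample's N tokens attend to its own p slots)
  spatialScores <- function(Qh, Kph, B, N) {
    Ch <- ncol(Qh)
    S <- matrix(0, N * B, ly$p)
    for (bb in seq_len(B)) {
      rn <- (bb - 1L) * N + seq_len(N)
      rp <- (bb - 1L) * ly$p + seq_len(ly$p)
      S[rn, ] <- Qh[rn, , drop = FALSE] %*%
        t(Kph[rp, , drop = FALSE]) / sqrt(Ch)
    }
    S
  }

  ly$forward <- function(x, training = FALSE) {
    d <- dim(x)
    C <- ly$channels; H <- ly$heads; Ch <- C %/% H
    N <- prod(d[1:3]); B <- d[4]
    pa <- poolFor(d[1:3])
    tau <- exp(ly$params$log_tau)
    X <- x; dim(X) <- c(N * B, C)
    Q <- X %*% ly$params$Wq
    K <- X %*% ly$params$Wk
    Vs <- X %*% ly$params$Wvs
    Vc <- X %*% ly$params$Wvc
    Kp0 <- poolTokens(K, pa, B, N)            # (p*B) x C pooled keys
    Vp0 <- poolTokens(Vs, pa, B, N)
    Kp <- mixBlocks(ly$params$Mk, Kp0, B, ly$p)
    Vp <- mixBlocks(ly$params$Mv, Vp0, B, ly$p)
    Os <- matrix(0, N * B, C); Oc <- matrix(0, N * B, C)
    hs <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * Ch + 1):(h * Ch)
      Asp <- softmaxRows(spatialScores(Q[, cols, drop = FALSE],
                                       Kp[, cols, drop = FALSE], B, N))
      Ach <- vector("list", B)
      for (bb in seq_len(B)) {
        rn <- (bb - 1L) * N + seq_len(N)
        rp <- (bb - 1L) * ly$p + seq_len(ly$p)
        Os[rn, cols] <- Asp[rn, , drop = FALSE] %*% Vp[rp, cols,
                                                       drop = FALSE]
        A <- softmaxRows(crossprod(Q[rn, cols, drop = FALSE],
                                   K[rn, cols, drop = FALSE]) / tau[h])
        Oc[rn, cols] <- Vc[rn, cols, drop = FALSE] %*% t(A)
        Ach[[bb]] <- A
      }
      hs[[h]] <- list(Asp = Asp, Ach = Ach)
    }
    O2 <- cbind(Os, Oc)
    Y <- O2 %*% ly$params$Wf
    Y <- Y + rep(ly$params$bf, each = N * B)
    ly$last_attention <- list(spatial = hs[[1]]$Asp[seq_len(N), ,
                                                    drop = FALSE],
                              channel = hs[[1]]$Ach[[1]])
    if (training)
      ly$cache <- list(d = d, pa = pa, tau = tau, X = X, Q = Q, K = K,
                       Vs = Vs, Vc = Vc, Kp0 = Kp0, Vp0 = Vp0, Kp = Kp,
                       Vp = Vp, O2 = O2, hs = hs)
    array(Y, d)
  }

  ly$backward <- function(dy) {
    cc <- ly$cache; d <- cc$d
    C <- ly$channels; H <- ly$heads; Ch <- C %/% H
    N <- prod(d[1:3]); B <- d[4]
    pa <- cc$pa; tau <- cc$tau
    g <- ly$grads
    dY <- dy; dim(dY) <- c(N * B, C)
    g$bf <- g$bf + colSums(dY)
    g$Wf <- g$Wf + crossprod(cc$O2, dY)
    dO2 <- tcrossprod(dY, ly$params$Wf)
    dOs <- dO2[, 1:C, drop = FALSE]
    dOc <- dO2[, (C + 1):(2 * C), drop = FALSE]
    dQ <- matrix(0, N * B, C); dK <- matrix(0, N * B, C)
    dVc <- matrix(0, N * B, C)
    dKp <- matrix(0, ly$p * B, C); dVp <- matrix(0, ly$p * B, C)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * Ch + 1):(h * Ch)
      hsh <- cc$hs[[h]]
      # spatial branch: batched softmax backward, per-sample matmuls
      dAsp <- matrix(0, N * B, ly$p)
      for (bb in seq_len(B)) {
        rn <- (bb - 1L) * N + seq_len(N)
        rp <- (bb - 1L) * ly$p + seq_len(ly$p)
        dAsp[rn, ] <- dOs[rn, cols, drop = FALSE] %*%
          t(cc$Vp[rp, cols, drop = FALSE])
        dVp[rp, cols] <- dVp[rp, cols] +
          crossprod(hsh$Asp[rn, , drop = FALSE],
                    dOs[rn, cols, drop = FALSE])
      }
      dSsp <- softmaxRowsBackward(dAsp, hsh$Asp)
      for (bb in seq_len(B)) {
        rn <- (bb - 1L) * N + seq_len(N)
        rp <- (bb - 1L) * ly$p + seq_len(ly$p)
        dQ[rn, cols] <- dQ[rn, cols] +
          dSsp[rn, , drop = FALSE] %*% cc$Kp[rp, cols, drop = FALSE] /
          sqrt(Ch)
        dKp[rp, cols] <- dKp[rp, cols] +
          crossprod(dSsp[rn, , drop = FALSE],
                    cc$Q[rn, cols, drop = FALSE]) / sqrt(Ch)
        # channel branch: Oc = Vc A^T, A = softmax(Q^T K / tau)
        A <- hsh$Ach[[bb]]
        dA <- crossprod(dOc[rn, cols, drop = FALSE],
                        cc$Vc[rn, cols, drop = FALSE])
        dVc[rn, cols] <- dVc[rn, cols] +
          dOc[rn, cols, drop = FALSE] %*% A
        dS <- softmaxRowsBackward(dA, A)
        M <- crossprod(cc$Q[rn, cols, drop = FALSE],
                       cc$K[rn, cols, drop = FALSE]) / tau[h]
        g$log_tau[h] <- g$log_tau[h] - sum(dS * M)
        dQ[rn, cols] <- dQ[rn, cols] +
          cc$K[rn, cols, drop = FALSE] %*% t(dS) / tau[h]
        dK[rn, cols] <- dK[rn, cols] +
          cc$Q[rn, cols, drop = FALSE] %*% dS / tau[h]
      }
    }
    # projection path: Kp = Mk (pool K), Vp = Mv (pool Vs), per sample
    for (bb in seq_len(B)) {
      rp <- (bb - 1L) * ly$p + seq_len(ly$p)
      g$Mk <- g$Mk + tcrossprod(dKp[rp, , drop = FALSE],
                                cc$Kp0[rp, , drop = FALSE])
      g$Mv <- g$Mv + tcrossprod(dVp[rp, , drop = FALSE],
                                cc$Vp0[rp, , drop = FALSE])
    }
    dKp0 <- mixBlocks(t(ly$params$Mk), dKp, B, ly$p)
    dVp0 <- mixBlocks(t(ly$params$Mv), dVp, B, ly$p)
    dK <- dK + poolTokensAdjoint(dKp0, pa, B, N)
    dVs <- poolTokensAdjoint(dVp0, pa, B, N)
    dX <- tcrossprod(dQ, ly$params$Wq) + tcrossprod(dK, ly$params$Wk) +
      tcrossprod(dVs, ly$params$Wvs) + tcrossprod(dVc, ly$params$Wvc)
    g$Wq <- g$Wq + crossprod(cc$X, dQ)
    g$Wk <- g$Wk + crossprod(cc$X, dK)
    g$Wvs <- g$Wvs + crossprod(cc$X, dVs)
    g$Wvc <- g$Wvc + crossprod(cc$X, dVc)
    ly$grads <- g
    array(dX, d)
  }
  ly
}
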