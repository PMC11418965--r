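# Training: masked mean-square loss, cube-symmetry augmentation, the
# validation-driven halving schedule, Adam, and the main loop.

#' Masked mean-square loss
#'
#' Voxels that are zero in both the prediction and the target are masked
#' out; the loss is the mean squared difference over the remaining voxels,
#' `sum((x_i - y_i)^2) / N` with `N` the voxel count after masking.  A
#' prediction voxel counts as zero when `|x| <= epsilon`.  If every voxel
#' is masked the loss is defined as 0 (with attribute `all_masked = TRUE`).
#'
#' @param prediction,target arrays of identical shape.
#' @param epsilon zero tolerance for prediction voxels (default 0, the
#'   literal reading; 1e-6 is a practical preset for float outputs).
#' @param with_grad also return the gradient with respect to `prediction`.
#' @return The scalar loss, or (with `with_grad`) a list `loss`, `grad`, `n`.
#' @export
maskedMSE <- function(prediction, target, epsilon = 0, with_grad = FALSE) {
  if (!identical(dim(prediction) %||% length(prediction),
                 dim(target) %||% length(target)))
    stop("prediction and target shapes differ")
  stopifnot(epsilon >= 0)
  masked <- abs(prediction) <= epsilon & target == 0
  n <- sum(!masked)
  if (n == 0L) {
    loss <- 0
    attr(loss, "all_masked") <- TRUE
    if (with_grad)
      return(list(loss = loss, grad = array(0, dim(prediction)), n = 0L))
    return(loss)
  }
  diff <- (prediction - target) * !masked
  loss <- sum(diff^2) / n
  if (with_grad) list(loss = loss, grad = 2 * diff / n, n = n) else loss
}

# ---- cube orientations: 24 proper rotations + axis flips ----

properOrientations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  sgn <- function(p) {
    M <- matrix(0, 3, 3); for (i in 1:3) M[i, p[i]] <- 1
    det(M)
  }
  out <- list()
  for (p in perms) for (f1 in c(1, -1)) for (f2 in c(1, -1))
    for (f3 in c(1, -1)) {
      fl <- c(f1, f2, f3)
      if (sgn(p) * prod(fl) > 0)
        out[[length(out) + 1L]] <- list(perm = as.integer(p), flip = fl < 0)
    }
  out
}

.ORIENT24 <- properOrientations()

#' Apply a cube orientation to a block
#'
#' An orientation is an axis permutation plus per-axis flips — an exact
#' voxel permutation of a cubic block.
#'
#' @param block cubic array.
#' @param orientation list with `perm` (integer permutation of 1:3) and
#'   `flip` (logical length 3).
#' @return The transformed block.
#' @export
applyOrientation <- function(block, orientation) {
  b <- aperm(block, orientation$perm)
  idx <- lapply(1:3, function(a)
    if (orientation$flip[a]) rev(seq_len(dim(b)[a])) else seq_len(dim(b)[a]))
  b[idx[[1]], idx[[2]], idx[[3]]]
}

#' Invert a cube orientation
#'
#' @param orientation as in [applyOrientation()].
#' @return The inverse orientation: applying both recovers the original
#'   block exactly.
#' @export
invertOrientation <- function(orientation) {
  inv_perm <- match(1:3, orientation$perm)
  list(perm = as.integer(inv_perm), flip = orientation$flip[inv_perm])
}

#' Random paired augmentation of an (input, target) block pair
#'
#' Draws one of the 24 proper 90-degree rotations of the cube uniformly,
#' composes it with an independent coin-flip mirror per axis, and applies
#' the same transform to both blocks.  Deterministic under `set.seed`.
#'
#' @param input_block,target_block cubic arrays of identical shape.
#' @param rot90 draw a random rotation? (default TRUE)
#' @param flip draw random axis flips? (default TRUE)
#' @return List `input`, `target`, `orientation` (the composed transform)
#'   and `rotation_index` in 1..24.
#' @export
augmentPair <- function(input_block, target_block, rot90 = TRUE,
                        flip = TRUE) {
  d <- dim(input_block)
  if (length(unique(d)) != 1L || !identical(d, dim(target_block)))
    stop("augmentation requires identically shaped cubic blocks")
  ri <- if (rot90) sample.int(24L, 1L) else 1L
  rot <- .ORIENT24[[ri]]
  fl <- if (flip) stats::runif(3) < 0.5 else rep(FALSE, 3)
  # compose: first rotate, then mirror => flips xor on the rotated axes
  orientation <- list(perm = rot$perm, flip = xor(rot$flip, fl))
  list(input = applyOrientation(input_block, orientation),
       target = applyOrientation(target_block, orientation),
       orientation = orientation, rotation_index = ri)
}

# ---- learning-rate schedule ----

#' Initialize the halving learning-rate schedule
#'
#' @param initial_lr starting learning rate (default 5e-4).
#' @param lr_floor lower bound (default 1e-5).
#' @param patience consecutive non-improving validations before halving
#'   (default 2).
#' @return Schedule state list.
#' @export
lrScheduleInit <- function(initial_lr = 5e-4, lr_floor = 1e-5,
                           patience = 2L) {
  list(lr = initial_lr, floor = lr_floor, patience = as.integer(patience),
       best = Inf, bad_count = 0L)
}

#' Advance the schedule on a validation result
#'
#' Improvement means a strict decrease below the running best validation
#' loss.  After `patience` consecutive non-improvements the learning rate
#' is halved, clamped at the floor, and the counter resets.  The learning
#' rate sequence is non-increasing.
#'
#' @param state schedule state from [lrScheduleInit()].
#' @param validation_loss scalar validation loss.
#' @return Updated state.
#' @export
lrScheduleStep <- function(state, validation_loss) {
  if (validation_loss < state$best) {
    state$best <- validation_loss
    state$bad_count <- 0L
  } else {
    state$bad_count <- state$bad_count + 1L
    if (state$bad_count >= state$patience) {
      state$lr <- max(state$lr / 2, state$floor)
      state$bad_count <- 0L
    }
  }
  state
}

# ---- Adam ----

adamStep <- function(root, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (l in collectParamLayers(root)) {
    if (is.null(l$opt))
      l$opt <- lapply(l$params, function(p) list(m = p * 0, v = p * 0))
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      st <- l$opt[[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      l$opt[[nm]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

#' Training configuration
#'
#' @param initial_lr Adam initial learning rate (default 5e-4).
#' @param lr_floor learning-rate floor (default 1e-5).
#' @param lr_patience consecutive non-improving validations before halving
#'   (default 2).
#' @param validate_every validate every this many epochs (default 5).
#' @param batch_size blocks per step; default 4 at desk scale (15 is the
#'   documented large-scale reproduction preset).
#' @param max_epochs epochs to train (244 in the reproduction preset).
#' @param crop_size on-the-fly random-crop edge; equal to the block edge
#'   disables cropping.
#' @param augment apply random rotations/flips (default TRUE).
#' @param epsilon masked-MSE zero tolerance (default 0).
#' @param grad_clip optional global gradient-norm clip (NULL = off).
#' @param seed RNG seed making the run reproducible.
#' @return Config list.
#' @export
trainingConfig <- function(initial_lr = 5e-4, lr_floor = 1e-5,
                           lr_patience = 2L, validate_every = 5L,
                           batch_size = 4L, max_epochs = 30L,
                           crop_size = NULL, augment = TRUE,
                           epsilon = 0, grad_clip = NULL, seed = 1L) {
  list(initial_lr = initial_lr, lr_floor = lr_floor,
       lr_patience = as.integer(lr_patience),
       validate_every = as.integer(validate_every),
       batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs), crop_size = crop_size,
       augment = isTRUE(augment), epsilon = epsilon, grad_clip = grad_clip,
       seed = as.integer(seed))
}

stackBlocks <- function(blocks) {
  e <- dim(blocks[[1]])[1]
  x <- array(0, c(rep(e, 3), length(blocks), 1L))
  for (i in seq_along(blocks)) x[, , , i, 1] <- blocks[[i]]
  x
}

#' Train the enhancer on paired blocks
#'
#' Runs epochs of shuffled mini-batches: optional random crop and
#' rotation/flip augmentation, forward pass, masked mean-square loss,
#' backward pass, Adam step.  Validation runs every `validate_every`
#' epochs and drives the halving learning-rate schedule; the
#' best-validation parameters and the final parameters are both
#' checkpointed when `checkpoint_dir` is given.
#'
#' @param pairs list of `list(input =, target =)` cubic block pairs.
#' @param val_pairs validation pairs (same form, >= 1).
#' @param net an [EnhancerNetwork-class] from [buildEnhancer()].
#' @param config a [trainingConfig()].
#' @param checkpoint_dir optional directory for `best.rds` / `final.rds`.
#' @param verbose print a line per epoch.
#' @return List: `net` (trained, final parameters), `history` (data.frame
#'   of epoch, training loss, lr), `val_history`, `best_val`,
#'   `masked_events` (count of fully-masked batches).
#' @export
trainEnhancer <- function(pairs, val_pairs, net, config = trainingConfig(),
                          checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(length(pairs) >= 1, length(val_pairs) >= 1)
  set.seed(config$seed)
  root <- net@modules
  sched <- lrScheduleInit(config$initial_lr, config$lr_floor,
                          config$lr_patience)
  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  val_history <- data.frame(epoch = integer(), val_loss = numeric())
  best_val <- Inf
  masked_events <- 0L
  step_t <- 0L

  validateLoss <- function() {
    tot <- 0
    for (vp in val_pairs) {
      pred <- netForwardInternal(root, toBatchArray(vp$input), FALSE)
      tot <- tot + maskedMSE(as.numeric(pred), as.numeric(vp$target),
                             config$epsilon)
    }
    tot / length(val_pairs)
  }

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(length(pairs))
    epoch_loss <- 0; n_batches <- 0L
    for (start in seq(1, length(ord), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      xs <- vector("list", length(idx)); ys <- xs
      for (j in seq_along(idx)) {
        pr <- pairs[[idx[j]]]
        xi <- pr$input; yi <- pr$target
        if (!is.null(config$crop_size) &&
            config$crop_size < dim(xi)[1]) {
          cr <- randomCrop(xi, yi, config$crop_size)
          xi <- cr$input; yi <- cr$target
        }
        if (config$augment) {
          au <- augmentPair(xi, yi)
          xi <- au$input; yi <- au$target
        }
        xs[[j]] <- xi; ys[[j]] <- yi
      }
      xb <- stackBlocks(xs); yb <- stackBlocks(ys)
      zeroGrads(root)
      pred <- netForwardInternal(root, xb, TRUE)
      lg <- maskedMSE(pred, yb, config$epsilon, with_grad = TRUE)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             ", batch containing pair index ", idx[1])
      if (lg$n == 0L) {
        masked_events <- masked_events + 1L
      } else {
        netBackwardInternal(root, lg$grad)
        if (!is.null(config$grad_clip)) {
          gn <- sqrt(sum(vapply(collectParamLayers(root), function(l)
            sum(vapply(l$grads, function(g) sum(g^2), numeric(1))),
            numeric(1))))
          if (gn > config$grad_clip)
            for (l in collectParamLayers(root))
              l$grads <- lapply(l$grads, function(g)
                g * config$grad_clip / gn)
        }
        step_t <- step_t + 1L
        adamStep(root, sched$lr, step_t)
      }
      epoch_loss <- epoch_loss + as.numeric(lg$loss)
      n_batches <- n_batches + 1L
    }
    epoch_loss <- epoch_loss / n_batches
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = epoch_loss,
                                lr = sched$lr))
    if (verbose)
      message(sprintf("epoch %3d  loss %.6g  lr %.2g", epoch, epoch_loss,
                      sched$lr))
    if (epoch %% config$validate_every == 0L) {
      vl <- validateLoss()
      val_history <- rbind(val_history,
                           data.frame(epoch = epoch, val_loss = vl))
      if (vl < best_val) {
        best_val <- vl
        if (!is.null(checkpoint_dir))
          saveCheckpoint(net, file.path(checkpoint_dir, "best.rds"),
                         extra = list(epoch = epoch, val_loss = vl))
      }
      sched <- lrScheduleStep(sched, vl)
    }
  }
  if (!is.null(checkpoint_dir))
    saveCheckpoint(net, file.path(checkpoint_dir, "final.rds"),
                   extra = list(history = history,
                                val_history = val_history))
  list(net = net, history = history, val_history = val_history,
       best_val = best_val, masked_events = masked_events)
}

#' Build training pairs from a dataset manifest
#'
#' Reads each (input map, target) manifest entry, normalizes the input map
#' by the 99.999th percentile, resamples both to the working grid if
#' needed, splits both into overlapping blocks and keeps the pairs whose
#' target block contains structure.
#'
#' @param manifest data.frame from [makeDataset()] (columns `input_map`,
#'   `target_map` or `structure` + `R0`).
#' @param block_size training block edge (64 in the reproduction preset).
#' @param stride block stride (50 in the reproduction preset).
#' @param target_voxel working grid spacing, default 1 Angstrom.
#' @param min_fraction passed to [filterNonempty()].
#' @param percentile normalization percentile.
#' @return List of `list(input =, target =)` block pairs.
#' @export
prepareTrainingPairs <- function(manifest, block_size = 64L, stride = 50L,
                                 target_voxel = 1, min_fraction = 0,
                                 percentile = 99.999) {
  pairs <- list()
  for (r in seq_len(nrow(manifest))) {
    input <- resampleToGrid(readDensityMap(manifest$input_map[r]),
                            target_voxel)
    norm <- normalizePercentile(input, percentile)
    target <- if (!is.null(manifest$target_map) &&
                  nzchar(manifest$target_map[r])) {
      resampleToGrid(readDensityMap(manifest$target_map[r]), target_voxel)
    } else {
      s <- readStructure(manifest$structure[r])
      simulateMap(s, gaussianConstants(manifest$R0[r]), norm$map)
    }
    if (!identical(dim(target@data), dim(norm$map@data)))
      stop("input and target grids differ for manifest row ", r)
    bi <- splitBlocks(norm$map, block_size, stride)
    bt <- splitBlocks(target, block_size, stride)
    fl <- filterNonempty(bi, bt, min_fraction)
    for (j in seq_len(nBlocks(fl$input)))
      pairs[[length(pairs) + 1L]] <-
        list(input = fl$input@blocks[[j]], target = fl$target@blocks[[j]])
  }
  pairs
}
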