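# Desk-scale end-to-end study: generate synthetic triples, train the toy
# enhancer, enhance held-out maps, and score the improvement.  This is the
# package's self-contained analogue of the full-scale train/evaluate
# protocol, shared by the test suite and scripts/acceptance.R.

#' Run the desk-scale training and evaluation study
#'
#' Generates `n_train_maps + n_test_maps` synthetic structure / clean-map /
#' degraded-map triples, trains a base-8 enhancer on 16-cube blocks of the
#' training maps (an initial phase whose loss trajectory measures
#' convergence, then a continuation phase), enhances the held-out degraded
#' maps, and reports whole-box correlation and map-model FSC improvements.
#'
#' The toy preset (20 training block pairs, base-8 channels, 16-cube
#' blocks, half-block inference stride) is the package's scaled-down
#' stand-in for full-scale training; see the methods vignette for how each
#' setting was chosen.
#'
#' @param seed master seed; every random choice (data, initialization,
#'   shuffling, augmentation) derives from it.
#' @param out_dir working directory for generated maps and checkpoints.
#' @param epochs_initial epochs of the initial training phase (default 30).
#' @param epochs_continue additional epochs before evaluation (default 20,
#'   over the wider continuation pair set).
#' @param n_train_maps,n_test_maps synthetic map counts (default 6 + 5).
#' @param n_pairs training block pairs drawn from the training maps
#'   (default 20, plus `n_val` validation pairs).
#' @param n_val validation block pairs (default 6).
#' @param block_size network input edge (default 16).
#' @param train_block,train_stride training block geometry (default 16 /
#'   12: blocks at the network edge, no on-the-fly crop; setting
#'   `train_block` larger re-enables random cropping to `block_size`).
#' @param infer_stride inference stride (default 8: half-block overlap).
#' @param batch_size mini-batch size (default 4; batch statistics are too
#'   noisy below this at desk scale).
#' @param n_pairs_continue training block pairs for the continuation phase
#'   (default 48: the continuation draws on all training maps' blocks,
#'   since with few fixed noisy blocks the network starts to memorize
#'   their noise realizations instead of learning the degradation
#'   inverse).
#' @param verbose print progress lines.
#' @return A list with `loss_first`, `loss_final_initial`, `loss_ratio`
#'   (initial phase), `per_map` (data.frame of cc_box and FSC@0.5/0.143
#'   for degraded and enhanced versions of each held-out map),
#'   improvement counts, and the checkpoint paths.
#' @export
runDeskScaleStudy <- function(seed = 1L,
                              out_dir = file.path(tempdir(),
                                                  paste0("study", seed)),
                              epochs_initial = 30L, epochs_continue = 20L,
                              n_train_maps = 6L, n_test_maps = 5L,
                              n_pairs = 20L, n_val = 6L,
                              block_size = 16L, train_block = 16L,
                              train_stride = 12L,
                              infer_stride = 8L, batch_size = 4L,
                              n_pairs_continue = 48L,
                              verbose = FALSE) {
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  set.seed(seed)
  manifest <- makeDataset(n_train_maps + n_test_maps, out_dir,
                          residues_range = c(12, 24), R0_range = c(3, 5))
  train_rows <- seq_len(n_train_maps)
  test_rows <- n_train_maps + seq_len(n_test_maps)

  pairs_all <- prepareTrainingPairs(manifest[train_rows, ],
                                    block_size = train_block,
                                    stride = train_stride)
  set.seed(seed + 1000L)
  n_want <- min(n_pairs + n_pairs_continue + n_val, length(pairs_all))
  idx <- sample(length(pairs_all), n_want)
  tr <- pairs_all[idx[seq_len(n_pairs)]]
  n_cont <- min(n_pairs_continue, n_want - n_pairs - n_val)
  tr_cont <- pairs_all[idx[seq_len(max(n_cont, n_pairs))]]
  val <- pairs_all[idx[n_want - seq_len(min(n_val, n_want - n_pairs)) + 1L]]
  if (train_block > block_size) {
    # validation uses a deterministic center crop at the network edge
    ccrop <- (train_block - block_size) %/% 2L
    val <- lapply(val, function(p) {
      ix <- ccrop + seq_len(block_size)
      list(input = p$input[ix, ix, ix], target = p$target[ix, ix, ix])
    })
  }

  set.seed(seed + 2000L)
  net <- buildEnhancer(architectureConfig(base_channels = 8L,
                                          input_edge = block_size))

  res1 <- trainEnhancer(tr, val, net,
                        trainingConfig(max_epochs = epochs_initial,
                                       batch_size = batch_size,
                                       crop_size = block_size,
                                       seed = seed + 3000L),
                        verbose = verbose)
  ckpt_initial <- file.path(out_dir, "checkpoint_initial.rds")
  saveCheckpoint(res1$net, ckpt_initial,
                 extra = list(history = res1$history))

  res2 <- trainEnhancer(tr_cont, val, res1$net,
                        trainingConfig(max_epochs = epochs_continue,
                                       batch_size = batch_size,
                                       crop_size = block_size,
                                       seed = seed + 4000L),
                        verbose = verbose)
  ckpt_final <- file.path(out_dir, "checkpoint_final.rds")
  saveCheckpoint(res2$net, ckpt_final, extra = list(history = res2$history))

  per_map <- data.frame()
  for (r in test_rows) {
    degraded <- readDensityMap(manifest$input_map[r])
    clean <- readDensityMap(manifest$target_map[r])
    structure <- readStructure(manifest$structure[r])
    enhanced <- enhanceMap(degraded, res2$net, block_size = block_size,
                           stride = infer_stride, batch_size = 8L)
    # one model-calculated map and one FSC curve per map version
    model_map <- simulateMap(structure, gaussianConstants(manifest$R0[r]),
                             degraded)
    curve_d <- fscCurve(degraded, model_map)
    curve_e <- fscCurve(enhanced, model_map)
    row <- data.frame(
      map = r,
      R0 = manifest$R0[r],
      cc_degraded = ccBox(degraded, clean),
      cc_enhanced = ccBox(enhanced, clean),
      fsc05_degraded = as.numeric(fscResolution(curve_d, 0.5)),
      fsc05_enhanced = as.numeric(fscResolution(curve_e, 0.5)),
      fsc143_degraded = as.numeric(fscResolution(curve_d, 0.143)),
      fsc143_enhanced = as.numeric(fscResolution(curve_e, 0.143)))
    per_map <- rbind(per_map, row)
    if (verbose)
      message(sprintf(
        "map %d: cc %.3f -> %.3f, FSC@0.5 %.2f -> %.2f A", r,
        row$cc_degraded, row$cc_enhanced, row$fsc05_degraded,
        row$fsc05_enhanced))
  }

  list(loss_first = res1$history$loss[1],
       loss_final_initial = res1$history$loss[epochs_initial],
       loss_ratio = res1$history$loss[epochs_initial] /
         res1$history$loss[1],
       history_initial = res1$history,
       history_continue = res2$history,
       per_map = per_map,
       n_cc_improved = sum(per_map$cc_enhanced > per_map$cc_degraded),
       n_fsc05_improved = sum(per_map$fsc05_enhanced <
                                per_map$fsc05_degraded),
       n_fsc143_improved = sum(per_map$fsc143_enhanced <
                                 per_map$fsc143_degraded),
       n_test = nrow(per_map),
       checkpoint_initial = ckpt_initial,
       checkpoint_final = ckpt_final,
       manifest = manifest)
}
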