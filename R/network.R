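# The enhancer architecture: a 3-D U-Net style transformer with four
# encoder/decoder pairs, efficient paired attention in every transformer
# block, and a residual-convolution (ConvRes) bottleneck.

#' Architecture configuration
#'
#' All structural hyperparameters of the enhancer in one list; the network
#' is fully reconstructable from this configuration plus its parameters.
#'
#' @param base_channels channels after the first encoder (default 32).
#' @param channel_multipliers per-level width factors (default 1, 2, 4, 8).
#' @param blocks_per_stage transformer blocks per encoder/decoder (default 3).
#' @param epa_heads attention heads (default 4).
#' @param epa_proj_grid spatial slot grid for the low-rank attention
#'   projection; default `c(4, 4, 4)` = 64 slots.
#' @param dropout_rate dropout fraction (default 0.1).
#' @param negative_slope leaky-ReLU slope (default 0.01).
#' @param input_edge design block edge in voxels (default 48); must be
#'   divisible by 16 (four halvings).
#' @param in_channels input channels (1 for a density block).
#' @param softplus_head apply a softplus to the output head (default FALSE:
#'   the raw linear head, since targets are nonnegative but unbounded).
#' @return A validated configuration list.
#' @export
architectureConfig <- function(base_channels = 32L,
                               channel_multipliers = c(1L, 2L, 4L, 8L),
                               blocks_per_stage = 3L,
                               epa_heads = 4L,
                               epa_proj_grid = c(4L, 4L, 4L),
                               dropout_rate = 0.1,
                               negative_slope = 0.01,
                               input_edge = 48L,
                               in_channels = 1L,
                               softplus_head = FALSE) {
  cfg <- list(base_channels = as.integer(base_channels),
              channel_multipliers = as.integer(channel_multipliers),
              blocks_per_stage = as.integer(blocks_per_stage),
              epa_heads = as.integer(epa_heads),
              epa_proj_grid = as.integer(epa_proj_grid),
              dropout_rate = dropout_rate,
              negative_slope = negative_slope,
              input_edge = as.integer(input_edge),
              in_channels = as.integer(in_channels),
              softplus_head = isTRUE(softplus_head))
  n_levels <- length(cfg$channel_multipliers)
  if (cfg$input_edge %% (2^n_levels) != 0L)
    stop("input_edge must be divisible by 2^", n_levels)
  ch <- cfg$base_channels * cfg$channel_multipliers
  dec0 <- max(cfg$base_channels %/% 2L, 1L)
  if (any(c(ch, dec0) %% cfg$epa_heads != 0L))
    stop("channel widths ", paste(c(ch, dec0), collapse = ","),
         " must all be divisible by epa_heads = ", cfg$epa_heads)
  cfg
}

levelChannels <- function(cfg) cfg$base_channels * cfg$channel_multipliers

# transformer block: positional embedding, EPA with residual, then a
# conv/batch-norm/leaky-ReLU/dropout path with residual
transformerBlockModule <- function(name, channels, base_edge, cfg) {
  m <- newLayer(name)
  m$pe <- layerPosEmbed(paste0(name, ".pe"), channels, base_edge)
  m$bn1 <- layerBatchNorm(paste0(name, ".bn1"), channels)
  m$epa <- layerEPA(paste0(name, ".epa"), channels, cfg$epa_heads,
                    cfg$epa_proj_grid)
  m$drop1 <- layerDropout(paste0(name, ".drop1"), cfg$dropout_rate)
  m$conv <- layerConv3d(paste0(name, ".conv"), channels, channels, 3L)
  m$bn2 <- layerBatchNorm(paste0(name, ".bn2"), channels)
  m$act <- layerLeakyReLU(paste0(name, ".act"), cfg$negative_slope)
  m$drop2 <- layerDropout(paste0(name, ".drop2"), cfg$dropout_rate)
  m$children <- list(m$pe, m$bn1, m$epa, m$drop1, m$conv, m$bn2, m$act,
                     m$drop2)
  m$forward <- function(x, training = FALSE) {
    h <- m$pe$forward(x, training)
    a <- m$drop1$forward(m$epa$forward(m$bn1$forward(h, training), training),
                         training)
    h1 <- h + a
    cpath <- m$drop2$forward(
      m$act$forward(m$bn2$forward(m$conv$forward(h1, training), training),
                    training), training)
    h1 + cpath
  }
  m$backward <- function(dy) {
    dc <- m$conv$backward(m$bn2$backward(m$act$backward(
      m$drop2$backward(dy))))
    dh1 <- dy + dc
    da <- m$bn1$backward(m$epa$backward(m$drop1$backward(dh1)))
    m$pe$backward(dh1 + da)
  }
  m
}

#' Build a transformer block
#'
#' One shape-preserving block of the enhancer: a learned separable
#' positional embedding is added, efficient paired attention is applied
#' with a residual connection, then a 3x3x3 convolution with batch
#' normalization, leaky ReLU and dropout, also residual.  Exposed mainly
#' for inspection and testing; [buildEnhancer()] assembles full stages.
#'
#' @param channels feature channels (divisible by `cfg$epa_heads`).
#' @param base_edge design spatial edge for the positional embedding.
#' @param cfg an [architectureConfig()].
#' @return A module whose `$forward(x, training)` maps a
#'   `(D, H, W, B, channels)` array to one of identical shape.
#' @export
transformerBlock <- function(channels, base_edge,
                             cfg = architectureConfig()) {
  transformerBlockModule("tb", channels, base_edge, cfg)
}

#' Build a standalone EPA attention layer
#'
#' @inheritParams transformerBlock
#' @return A module with `$forward`/`$backward`; after a forward pass,
#'   `$last_attention` holds the first sample's first-head spatial (N x p)
#'   and channel (C/h x C/h) attention weights.
#' @export
epaAttention <- function(channels, cfg = architectureConfig()) {
  layerEPA("epa", channels, cfg$epa_heads, cfg$epa_proj_grid)
}

# encoder stage: strided conv halving each spatial edge, batch norm,
# leaky ReLU, then transformer blocks; the stage input is the skip tensor
encoderStageModule <- function(name, in_ch, out_ch, base_edge, cfg) {
  m <- newLayer(name)
  m$conv <- layerConv3d(paste0(name, ".down"), in_ch, out_ch, 3L, stride = 2L)
  m$bn <- layerBatchNorm(paste0(name, ".bn"), out_ch)
  m$act <- layerLeakyReLU(paste0(name, ".act"), cfg$negative_slope)
  m$blocks <- lapply(seq_len(cfg$blocks_per_stage), function(i)
    transformerBlockModule(sprintf("%s.tb%d", name, i), out_ch,
                           base_edge %/% 2L, cfg))
  m$children <- c(list(m$conv, m$bn, m$act), m$blocks)
  m$forward <- function(x, training = FALSE) {
    h <- m$act$forward(m$bn$forward(m$conv$forward(x, training), training),
                       training)
    for (b in m$blocks) h <- b$forward(h, training)
    list(out = h, skip = x)
  }
  m$backward <- function(dout, dskip = NULL) {
    d <- dout
    for (b in rev(m$blocks)) d <- b$backward(d)
    dx <- m$conv$backward(m$bn$backward(m$act$backward(d)))
    if (!is.null(dskip)) dx <- dx + dskip
    dx
  }
  m
}

#' Build an encoder stage
#'
#' A stride-2 downsampling convolution (halving each spatial edge and
#' setting the level's channel width), batch normalization and leaky ReLU,
#' followed by `blocks_per_stage` transformer blocks.  `$forward` returns
#' `list(out, skip)` where `skip` is the stage input, routed to the
#' matching decoder.
#'
#' @param cfg an [architectureConfig()].
#' @param level stage index in 0..3.
#' @return The stage module.
#' @export
encoderStage <- function(cfg, level) {
  stopifnot(level %in% 0:(length(cfg$channel_multipliers) - 1L))
  ch <- levelChannels(cfg)
  in_ch <- if (level == 0L) cfg$in_channels else ch[level]
  encoderStageModule(sprintf("enc%d", level), in_ch, ch[level + 1L],
                     cfg$input_edge %/% (2L^level), cfg)
}

# decoder stage: transposed conv doubling the edge, skip concatenation
# fused by a 1x1x1 conv, then transformer blocks
decoderStageModule <- function(name, in_ch, out_ch, skip_ch, base_edge, cfg) {
  m <- newLayer(name)
  m$up <- layerConvT3d(paste0(name, ".up"), in_ch, out_ch)
  m$fuse <- layerConv3d(paste0(name, ".fuse"), out_ch + skip_ch, out_ch, 1L)
  m$blocks <- lapply(seq_len(cfg$blocks_per_stage), function(i)
    transformerBlockModule(sprintf("%s.tb%d", name, i), out_ch, base_edge,
                           cfg))
  m$children <- c(list(m$up, m$fuse), m$blocks)
  m$out_ch <- out_ch; m$skip_ch <- skip_ch
  m$forward <- function(x, skip, training = FALSE) {
    u <- m$up$forward(x, training)
    if (!identical(dim(u)[1:3], dim(skip)[1:3]))
      stop(name, ": skip shape ", paste(dim(skip)[1:3], collapse = "x"),
           " does not match upsampled shape ",
           paste(dim(u)[1:3], collapse = "x"))
    du <- dim(u)
    cat_arr <- array(0, c(du[1:4], m$out_ch + m$skip_ch))
    cat_arr[, , , , seq_len(m$out_ch)] <- u
    cat_arr[, , , , m$out_ch + seq_len(m$skip_ch)] <- skip
    h <- m$fuse$forward(cat_arr, training)
    for (b in m$blocks) h <- b$forward(h, training)
    h
  }
  m$backward <- function(dy) {
    d <- dy
    for (b in rev(m$blocks)) d <- b$backward(d)
    dcat <- m$fuse$backward(d)
    dup <- dcat[, , , , seq_len(m$out_ch), drop = FALSE]
    dskip <- dcat[, , , , m$out_ch + seq_len(m$skip_ch), drop = FALSE]
    dx <- m$up$backward(dup)
    list(dx = dx, dskip = dskip)
  }
  m
}

#' Build a decoder stage
#'
#' A kernel-2 stride-2 transposed convolution (doubling each spatial edge,
#' halving channels), concatenation with the matching encoder's skip tensor
#' fused by a 1x1x1 convolution, then `blocks_per_stage` transformer
#' blocks.  The output spatial shape equals the matching encoder's input
#' shape.
#'
#' @inheritParams encoderStage
#' @return The stage module; `$forward(x, skip, training)`.
#' @export
decoderStage <- function(cfg, level) {
  stopifnot(level %in% 0:(length(cfg$channel_multipliers) - 1L))
  ch <- levelChannels(cfg)
  in_ch <- ch[level + 1L]
  out_ch <- if (level == 0L) max(cfg$base_channels %/% 2L, 1L) else ch[level]
  skip_ch <- if (level == 0L) cfg$in_channels else ch[level]
  decoderStageModule(sprintf("dec%d", level), in_ch, out_ch, skip_ch,
                     cfg$input_edge %/% (2L^level), cfg)
}

#' Build a ConvRes bottleneck block
#'
#' Three convolution + instance-normalization pairs with leaky ReLU after
#' the first two, and a residual connection adding the block input to the
#' third pair's output (an identity shortcut; channel counts are equal at
#' the bottleneck).
#'
#' @param channels feature channels.
#' @param cfg an [architectureConfig()].
#' @param use_norm include the instance normalizations (default TRUE;
#'   disabling exposes the pure conv/residual data path).
#' @return The module with `$forward`/`$backward`.
#' @export
convResBlock <- function(channels, cfg = architectureConfig(),
                         use_norm = TRUE) {
  convResModule("convres", channels, cfg, use_norm)
}

convResModule <- function(name, channels, cfg, use_norm = TRUE) {
  m <- newLayer(name)
  m$use_norm <- use_norm
  m$conv1 <- layerConv3d(paste0(name, ".conv1"), channels, channels, 3L)
  m$conv2 <- layerConv3d(paste0(name, ".conv2"), channels, channels, 3L)
  m$conv3 <- layerConv3d(paste0(name, ".conv3"), channels, channels, 3L)
  m$in1 <- layerInstanceNorm(paste0(name, ".in1"), channels)
  m$in2 <- layerInstanceNorm(paste0(name, ".in2"), channels)
  m$in3 <- layerInstanceNorm(paste0(name, ".in3"), channels)
  m$act1 <- layerLeakyReLU(paste0(name, ".act1"), cfg$negative_slope)
  m$act2 <- layerLeakyReLU(paste0(name, ".act2"), cfg$negative_slope)
  m$children <- list(m$conv1, m$in1, m$act1, m$conv2, m$in2, m$act2,
                     m$conv3, m$in3)
  norm <- function(nl, x, training) if (use_norm) nl$forward(x, training)
                                    else x
  normB <- function(nl, d) if (use_norm) nl$backward(d) else d
  m$forward <- function(x, training = FALSE) {
    h <- m$act1$forward(norm(m$in1, m$conv1$forward(x, training), training),
                        training)
    h <- m$act2$forward(norm(m$in2, m$conv2$forward(h, training), training),
                        training)
    h <- norm(m$in3, m$conv3$forward(h, training), training)
    x + h
  }
  m$backward <- function(dy) {
    d <- m$conv3$backward(normB(m$in3, dy))
    d <- m$conv2$backward(normB(m$in2, m$act2$backward(d)))
    d <- m$conv1$backward(normB(m$in1, m$act1$backward(d)))
    dy + d
  }
  m
}

#' Build the full enhancer network
#'
#' Assembles the four encoder stages, the ConvRes bottleneck, the four
#' decoder stages and the 1x1x1 output head into an
#' [EnhancerNetwork-class].  Weights are randomly initialized (He
#' initialization for convolutions), so call `set.seed` first for
#' reproducible builds.
#'
#' @param cfg an [architectureConfig()].
#' @return An [EnhancerNetwork-class].
#' @export
buildEnhancer <- function(cfg = architectureConfig()) {
  n_levels <- length(cfg$channel_multipliers)
  ch <- levelChannels(cfg)
  root <- newLayer("net")
  root$encoders <- lapply(0:(n_levels - 1L), function(l) encoderStage(cfg, l))
  root$bottleneck <- convResModule("bottleneck", ch[n_levels], cfg)
  root$decoders <- lapply(0:(n_levels - 1L), function(l) decoderStage(cfg, l))
  dec0_ch <- max(cfg$base_channels %/% 2L, 1L)
  root$head <- layerConv3d("head", dec0_ch, 1L, 1L)
  # small-scale head init: the untrained network starts near the zero map,
  # which is the right prior for sparse density targets
  root$head$params$W <- root$head$params$W * 0.01
  root$children <- c(root$encoders, list(root$bottleneck), root$decoders,
                     list(root$head))
  root$cfg <- cfg
  new("EnhancerNetwork", config = cfg, modules = root)
}

#' Number of learnable parameters
#'
#' @param net an [EnhancerNetwork-class].
#' @return Integer parameter count (a pure function of the configuration).
#' @export
parameterCount <- function(net) countParams(net@modules)

netForwardInternal <- function(root, xb, training = FALSE) {
  n_levels <- length(root$cfg$channel_multipliers)
  h <- xb
  skips <- vector("list", n_levels)
  for (l in seq_len(n_levels)) {
    r <- root$encoders[[l]]$forward(h, training)
    skips[[l]] <- r$skip
    h <- r$out
  }
  h <- root$bottleneck$forward(h, training)
  for (l in rev(seq_len(n_levels)))
    h <- root$decoders[[l]]$forward(h, skips[[l]], training)
  y <- root$head$forward(h, training)
  if (root$cfg$softplus_head) {
    root$softplus_cache <- y
    y <- log1p(exp(pmin(y, 30))) + pmax(y - 30, 0)
  }
  y
}

netBackwardInternal <- function(root, dy) {
  if (root$cfg$softplus_head) {
    z <- root$softplus_cache
    dy <- dy / (1 + exp(-z))
  }
  n_levels <- length(root$cfg$channel_multipliers)
  d <- root$head$backward(dy)
  dskips <- vector("list", n_levels)
  for (l in seq_len(n_levels)) {
    r <- root$decoders[[l]]$backward(d)
    dskips[[l]] <- r$dskip
    d <- r$dx
  }
  d <- root$bottleneck$backward(d)
  for (l in rev(seq_len(n_levels)))
    d <- root$encoders[[l]]$backward(d, dskips[[l]])
  d
}

toBatchArray <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L, 1L)
    attr(x, "in_shape") <- "single"
  } else if (length(d) == 4L) {
    dim(x) <- c(d[1:3], d[4], 1L)
    attr(x, "in_shape") <- "batch"
  } else if (length(d) == 5L) {
    attr(x, "in_shape") <- "full"
  } else stop("input must be a 3-D block, 4-D batch, or 5-D array")
  x
}

#' Apply the enhancer to a block or batch of blocks
#'
#' @param net an [EnhancerNetwork-class] (or the identity stub from
#'   [identityNetwork()]).
#' @param x a cubic block (`E^3` array), a batch (`E^3 x B`), or a full
#'   `(D, H, W, B, C)` activation array.  Each spatial edge must be
#'   divisible by `2^levels` (16 for the default four levels).
#' @param training run normalizations/dropout in training mode
#'   (default FALSE: inference mode, deterministic).
#' @return Enhanced array of the same shape as the input.
#' @export
networkForward <- function(net, x, training = FALSE) {
  if (is(net, "IdentityNetwork")) return(x)
  xb <- toBatchArray(x)
  shape_tag <- attr(xb, "in_shape")
  y <- netForwardInternal(net@modules, xb, training)
  if (shape_tag == "single") dim(y) <- dim(y)[1:3]
  if (shape_tag == "batch") dim(y) <- dim(y)[1:4]
  y
}

#' Identity network stub
#'
#' A drop-in stand-in for a trained [EnhancerNetwork-class] whose forward
#' pass returns its input unchanged.  Used to exercise the full tiling /
#' batching / assembly plumbing with zero model risk.
#'
#' @return An object accepted by [networkForward()] and [enhanceMap()].
#' @export
identityNetwork <- function() new("IdentityNetwork")

#' @rdname identityNetwork
#' @export
setClass("IdentityNetwork", representation(tag = "character"),
         prototype(tag = "identity"))

# ---- checkpoints ----

#' Save a network checkpoint
#'
#' Stores the architecture configuration, all parameters, batch-norm
#' running statistics and optional metadata; the network is fully
#' reconstructable with [loadCheckpoint()].
#'
#' @param net an [EnhancerNetwork-class].
#' @param path file path (`.rds`).
#' @param extra optional list of metadata (training history, manifest hash).
#' @return Invisibly, `path`.
#' @export
saveCheckpoint <- function(net, path, extra = list()) {
  buffers <- list()
  for (l in collectParamLayers(net@modules)) {
    if (!is.null(l$running_mean))
      buffers[[l$name]] <- list(mean = l$running_mean, var = l$running_var)
  }
  saveRDS(list(config = net@config, params = flattenParams(net@modules),
               buffers = buffers, extra = extra,
               package_version = as.character(utils::packageVersion("emRestore"))),
          path)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path path written by [saveCheckpoint()].
#' @return An [EnhancerNetwork-class] with restored parameters; the
#'   checkpoint metadata is attached as attribute `"extra"`.
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  net <- buildEnhancer(do.call(architectureConfig, ck$config[
    setdiff(names(ck$config), character())]))
  assignParams(net@modules, ck$params)
  for (l in collectParamLayers(net@modules)) {
    bf <- ck$buffers[[l$name]]
    if (!is.null(bf)) {
      l$running_mean <- bf$mean
      l$running_var <- bf$var
    }
  }
  attr(net, "extra") <- ck$extra
  net
}
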