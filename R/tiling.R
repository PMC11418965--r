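# Overlapping cubic tiling of maps and mean-overlap reassembly.

#' Offsets of overlapping blocks along one axis
#'
#' Enumerates the stride lattice `0, stride, 2*stride, ...` and clamps the
#' final offset to `dim - block` so the last block is flush with the
#' boundary.  For `dim <= block` the single offset 0 is returned.
#'
#' @param dim axis length in voxels.
#' @param block block edge in voxels.
#' @param stride step in voxels, `1 <= stride <= block`.
#' @return Integer vector of unique 0-based offsets.
#' @export
blockOffsets1D <- function(dim, block, stride) {
  stopifnot(block >= 1, stride >= 1, stride <= block)
  if (dim <= block) return(0L)
  off <- seq.int(0L, dim - block, by = stride)
  if (off[length(off)] != dim - block) off <- c(off, dim - block)
  as.integer(off)
}

#' Split a map into overlapping cubic blocks
#'
#' Blocks of edge `block_size` are taken on the stride lattice per axis with
#' the last block clamped inward so every voxel is covered.  Maps smaller
#' than `block_size` on any axis are zero-padded (split evenly before and
#' after); the padding is recorded so [assembleBlocks()] can crop it away.
#'
#' @param map a [DensityMap-class] or a bare 3-D array.
#' @param block_size cubic block edge in voxels.
#' @param stride step in voxels, `1 <= stride <= block_size`.
#' @return A [BlockSet-class].
#' @export
splitBlocks <- function(map, block_size, stride) {
  arr <- if (is(map, "DensityMap")) map@data else map
  stopifnot(length(dim(arr)) == 3L, block_size >= 1, stride >= 1,
            stride <= block_size)
  block_size <- as.integer(block_size); stride <- as.integer(stride)
  d <- dim(arr)
  pad_total <- pmax(block_size - d, 0L)
  pad_before <- pad_total %/% 2L
  if (any(pad_total > 0L)) {
    padded <- array(0, pmax(d, block_size))
    padded[pad_before[1] + seq_len(d[1]), pad_before[2] + seq_len(d[2]),
           pad_before[3] + seq_len(d[3])] <- arr
    arr <- padded
  }
  pd <- dim(arr)
  offs <- lapply(1:3, function(a) blockOffsets1D(pd[a], block_size, stride))
  grid <- as.matrix(expand.grid(offs[[1]], offs[[2]], offs[[3]],
                                KEEP.OUT.ATTRS = FALSE))
  dimnames(grid) <- NULL
  blocks <- lapply(seq_len(nrow(grid)), function(r) {
    o <- grid[r, ]
    arr[o[1] + seq_len(block_size), o[2] + seq_len(block_size),
        o[3] + seq_len(block_size)]
  })
  new("BlockSet", blocks = blocks, offsets = grid,
      source_shape = as.integer(d), padded_shape = as.integer(pd),
      pad_before = as.integer(pad_before), block_size = block_size,
      stride = stride)
}

#' Keep block pairs whose target contains structure
#'
#' Retains exactly the (input, target) block pairs whose target block has a
#' positive fraction of nonzero voxels at least `min_fraction`.  All-zero
#' target blocks ("empty blocks") are always dropped.  Order is preserved.
#'
#' @param input_blocks,target_blocks two [BlockSet-class]s with identical
#'   offsets and geometry (an experimental map and its simulated target).
#' @param min_fraction minimum nonzero-voxel fraction in the target block;
#'   default 0 (any nonzero voxel qualifies).
#' @return A list with filtered BlockSets `input` and `target` and the
#'   logical vector `kept`.
#' @export
filterNonempty <- function(input_blocks, target_blocks, min_fraction = 0) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  if (!identical(input_blocks@offsets, target_blocks@offsets) ||
      input_blocks@block_size != target_blocks@block_size)
    stop("input and target BlockSets must share offsets and block size")
  frac <- vapply(target_blocks@blocks, function(b) mean(b > 0), numeric(1))
  kept <- frac > 0 & frac >= min_fraction
  subsetBS <- function(bs) {
    new("BlockSet", blocks = bs@blocks[kept],
        offsets = bs@offsets[kept, , drop = FALSE],
        source_shape = bs@source_shape, padded_shape = bs@padded_shape,
        pad_before = bs@pad_before, block_size = bs@block_size,
        stride = bs@stride)
  }
  list(input = subsetBS(input_blocks), target = subsetBS(target_blocks),
       kept = kept)
}

#' Reassemble blocks into the full map array
#'
#' Each voxel of the source grid receives the arithmetic mean of every block
#' value covering it (count-weighted accumulation); padding introduced at
#' split time is cropped.  Optionally a separable Hann window down-weights
#' block edges to suppress seam artifacts.
#'
#' @param blockset a [BlockSet-class] (blocks may have been replaced by
#'   model outputs of identical shape).
#' @param weighting `"mean"` (default) or `"hann"`.
#' @return A 3-D array of the original `source_shape`.
#' @export
assembleBlocks <- function(blockset, weighting = c("mean", "hann")) {
  weighting <- match.arg(weighting)
  b <- blockset@block_size
  pd <- blockset@padded_shape
  acc <- array(0, pd)
  cnt <- array(0, pd)
  win <- if (weighting == "hann") {
    w1 <- 0.5 - 0.5 * cos(2 * pi * (seq_len(b) - 0.5) / b)
    outer(outer(w1, w1), w1)
  } else array(1, rep(b, 3))
  for (r in seq_len(nBlocks(blockset))) {
    o <- blockset@offsets[r, ]
    ix <- o[1] + seq_len(b); iy <- o[2] + seq_len(b); iz <- o[3] + seq_len(b)
    acc[ix, iy, iz] <- acc[ix, iy, iz] + blockset@blocks[[r]] * win
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + win
  }
  if (any(cnt == 0)) stop("BlockSet does not cover the source grid")
  out <- acc / cnt
  pb <- blockset@pad_before
  d <- blockset@source_shape
  out[pb[1] + seq_len(d[1]), pb[2] + seq_len(d[2]), pb[3] + seq_len(d[3])]
}

#' Replace the data of a BlockSet
#'
#' Convenience for inference: swap in model-predicted blocks while keeping
#' the tiling geometry.
#'
#' @param blockset a [BlockSet-class].
#' @param blocks list of arrays, same length and shape as the originals.
#' @return The updated [BlockSet-class].
#' @export
withBlocks <- function(blockset, blocks) {
  stopifnot(length(blocks) == nBlocks(blockset))
  new("BlockSet", blocks = blocks, offsets = blockset@offsets,
      source_shape = blockset@source_shape,
      padded_shape = blockset@padded_shape,
      pad_before = blockset@pad_before, block_size = blockset@block_size,
      stride = blockset@stride)
}

#' Random paired crop of two blocks
#'
#' Draws one uniformly random low corner and crops both volumes with it, so
#' an input block and its target stay voxel-aligned.  Deterministic under
#' `set.seed`.
#'
#' @param input_block,target_block cubic arrays of equal shape.
#' @param crop_size crop edge, `<=` the block edge.
#' @return List with `input`, `target` (crop_size^3 arrays) and the 0-based
#'   `corner` used.
#' @export
randomCrop <- function(input_block, target_block, crop_size) {
  d <- dim(input_block)
  stopifnot(identical(d, dim(target_block)), length(unique(d)) == 1L)
  if (crop_size > d[1]) stop("crop_size exceeds block edge")
  m <- as.integer(d[1] - crop_size)
  corner <- if (m == 0L) c(0L, 0L, 0L) else
    as.integer(floor(stats::runif(3, 0, m + 1)))
  corner <- as.integer(pmin(corner, m))
  ix <- corner[1] + seq_len(crop_size)
  iy <- corner[2] + seq_len(crop_size)
  iz <- corner[3] + seq_len(crop_size)
  list(input = input_block[ix, iy, iz], target = target_block[ix, iy, iz],
       corner = corner)
}
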