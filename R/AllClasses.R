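#' @import methods
NULL

#' DensityMap: a 3-D scalar density grid
#'
#' The universal currency of the package: a 3-D array of density values
#' together with the physical geometry of its grid.  Data are stored in
#' canonical axis order, i.e. `data[i, j, k]` (1-based) is the voxel whose
#' center sits at physical position `origin + (i-1, j-1, k-1) * voxel_size`
#' in Angstrom, with the first array index running along crystallographic X.
#'
#' @slot data numeric 3-D array of density values (arbitrary units).
#' @slot voxel_size numeric length-3, Angstrom per voxel along X, Y, Z.
#' @slot origin numeric length-3, physical position (Angstrom) of voxel
#'   index (1,1,1)'s center.
#'
#' @seealso [readDensityMap()], [writeDensityMap()], [resampleToGrid()]
#' @export
setClass("DensityMap",
  representation(data = "array", voxel_size = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), voxel_size = rep(1, 3),
            origin = rep(0, 3)))

setValidity("DensityMap", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L || any(dim(object@data) < 1L))
    msg <- c(msg, "data must be a 3-D array with each dimension >= 1")
  if (length(object@voxel_size) != 3L ||
      any(!is.finite(object@voxel_size)) || any(object@voxel_size <= 0))
    msg <- c(msg, "voxel_size must be 3 strictly positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (length(msg)) msg else TRUE
})

#' Construct a DensityMap
#'
#' @param data 3-D numeric array.
#' @param voxel_size voxel edge length(s) in Angstrom; recycled to length 3.
#' @param origin physical position of the first voxel center, Angstrom.
#' @return A [DensityMap-class] object.
#' @examples
#' m <- DensityMap(array(rnorm(8), c(2, 2, 2)), voxel_size = 1)
#' @export
DensityMap <- function(data, voxel_size = 1, origin = c(0, 0, 0)) {
  new("DensityMap", data = data,
      voxel_size = as.numeric(rep_len(voxel_size, 3L)),
      origin = as.numeric(rep_len(origin, 3L)))
}

#' AtomicStructure: a flat list of atoms
#'
#' Minimal atomic model used for map simulation: element symbols, atomic
#' numbers, Cartesian coordinates in Angstrom and occupancies.
#'
#' @slot element character vector of element symbols.
#' @slot atomic_number integer vector, Z per atom.
#' @slot coords numeric n x 3 matrix, Angstrom.
#' @slot occupancy numeric vector in (0, 1].
#' @slot id free-text identifier.
#' @export
setClass("AtomicStructure",
  representation(element = "character", atomic_number = "integer",
                 coords = "matrix", occupancy = "numeric", id = "character"))

setValidity("AtomicStructure", function(object) {
  n <- length(object@atomic_number)
  msg <- character()
  if (n < 1L) msg <- c(msg, "structure must contain at least one atom")
  if (any(object@atomic_number < 1L)) msg <- c(msg, "atomic numbers must be >= 1")
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L ||
      nrow(object@coords) != n || any(!is.finite(object@coords)))
    msg <- c(msg, "coords must be a finite n x 3 matrix")
  if (length(object@element) != n || length(object@occupancy) != n)
    msg <- c(msg, "element/occupancy length must match atom count")
  if (length(msg)) msg else TRUE
})

#' Construct an AtomicStructure
#'
#' @param element character element symbols.
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @param atomic_number integer Z values; looked up from `element` if missing.
#' @param occupancy per-atom occupancies, default 1.
#' @param id identifier string.
#' @return An [AtomicStructure-class] object.
#' @export
AtomicStructure <- function(element, coords, atomic_number = NULL,
                            occupancy = NULL, id = "structure") {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  if (is.null(atomic_number)) atomic_number <- elementToZ(element)
  if (is.null(occupancy)) occupancy <- rep(1, nrow(coords))
  new("AtomicStructure", element = as.character(element),
      atomic_number = as.integer(atomic_number), coords = coords,
      occupancy = as.numeric(occupancy), id = id)
}

#' BlockSet: overlapping cubic sub-volumes of a map
#'
#' @slot blocks list of cubic arrays, each `block_size^3`.
#' @slot offsets integer n x 3 matrix of 0-based low-corner voxel offsets in
#'   the (possibly padded) source grid.
#' @slot source_shape integer length-3, the original map shape before padding.
#' @slot padded_shape integer length-3, shape after zero padding (>= source).
#' @slot pad_before integer length-3, leading zero padding per axis.
#' @slot block_size integer edge length in voxels.
#' @slot stride integer step in voxels.
#' @export
setClass("BlockSet",
  representation(blocks = "list", offsets = "matrix",
                 source_shape = "integer", padded_shape = "integer",
                 pad_before = "integer", block_size = "integer",
                 stride = "integer"))

setValidity("BlockSet", function(object) {
  msg <- character()
  b <- object@block_size
  if (length(object@blocks) != nrow(object@offsets))
    msg <- c(msg, "blocks and offsets must have equal length")
  if (!all(vapply(object@blocks, function(x) identical(dim(x), rep(b, 3L)), TRUE)))
    msg <- c(msg, "every block must be block_size^3")
  if (anyDuplicated(object@offsets))
    msg <- c(msg, "offsets must be unique")
  if (object@stride < 1L || object@stride > b)
    msg <- c(msg, "stride must satisfy 1 <= stride <= block_size")
  if (length(msg)) msg else TRUE
})

#' FSCCurve: per-shell Fourier shell correlation
#'
#' @slot shell_frequencies numeric, shell-center spatial frequencies (1/Angstrom),
#'   ascending.
#' @slot correlations numeric in [-1, 1], one per shell.
#' @slot shell_width numeric, shell width in 1/Angstrom.
#' @export
setClass("FSCCurve",
  representation(shell_frequencies = "numeric", correlations = "numeric",
                 shell_width = "numeric"))

setValidity("FSCCurve", function(object) {
  msg <- character()
  if (length(object@shell_frequencies) != length(object@correlations))
    msg <- c(msg, "frequencies and correlations must have equal length")
  if (is.unsorted(object@shell_frequencies))
    msg <- c(msg, "shell frequencies must ascend")
  if (any(object@correlations > 1 + 1e-9 | object@correlations < -1 - 1e-9))
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' NormalizationRecord: provenance of percentile normalization
#'
#' @slot percentile the percentile used, in (0, 100].
#' @slot scale the density value at that percentile (the divisor), > 0.
#' @slot clip_low whether negative values were clipped to zero.
#' @export
setClass("NormalizationRecord",
  representation(percentile = "numeric", scale = "numeric",
                 clip_low = "logical"))

setValidity("NormalizationRecord", function(object) {
  if (!is.finite(object@scale) || object@scale <= 0)
    "scale must be strictly positive" else TRUE
})

#' EnhancerNetwork: the U-Net style transformer
#'
#' Holds the architecture configuration and the (mutable) module tree with
#' all learnable parameters.  Built with [buildEnhancer()]; applied with
#' [networkForward()] or, at map level, [enhanceMap()].
#'
#' @slot config list, the full architecture configuration.
#' @slot modules environment containing the layer tree.
#' @export
setClass("EnhancerNetwork",
  representation(config = "list", modules = "environment"))

# ---- accessors ----

#' @describeIn DensityMap-class the raw 3-D density array
#' @param x,object a DensityMap
#' @export
mapData <- function(x) x@data

#' @describeIn DensityMap-class voxel size (Angstrom per voxel)
#' @export
voxelSize <- function(x) x@voxel_size

#' @describeIn DensityMap-class physical origin (Angstrom)
#' @export
mapOrigin <- function(x) x@origin

#' @describeIn AtomicStructure-class coordinate matrix (Angstrom)
#' @export
atomCoords <- function(x) x@coords

#' @describeIn AtomicStructure-class atomic numbers
#' @export
atomicNumbers <- function(x) x@atomic_number

#' @describeIn AtomicStructure-class number of atoms
#' @export
nAtoms <- function(x) length(x@atomic_number)

#' @describeIn BlockSet-class 0-based block offsets (n x 3)
#' @export
blockOffsets <- function(x) x@offsets

#' @describeIn BlockSet-class number of blocks
#' @export
nBlocks <- function(x) length(x@blocks)

#' @describeIn BlockSet-class list of block arrays
#' @export
blockData <- function(x) x@blocks

#' @describeIn FSCCurve-class shell-center frequencies (1/Angstrom)
#' @export
fscFrequencies <- function(x) x@shell_frequencies

#' @describeIn FSCCurve-class per-shell correlations
#' @export
fscCorrelations <- function(x) x@correlations

setMethod("show", "DensityMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("DensityMap %d x %d x %d voxels, voxel %.3g x %.3g x %.3g A\n",
              d[1], d[2], d[3], object@voxel_size[1], object@voxel_size[2],
              object@voxel_size[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) A, density range [%.4g, %.4g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@data), max(object@data)))
})

setMethod("show", "AtomicStructure", function(object) {
  cat(sprintf("AtomicStructure '%s': %d atoms (%s)\n", object@id,
              nAtoms(object),
              paste(utils::head(unique(object@element), 8), collapse = " ")))
})

setMethod("show", "BlockSet", function(object) {
  cat(sprintf("BlockSet: %d blocks of %d^3, stride %d, source %s\n",
              nBlocks(object), object@block_size, object@stride,
              paste(object@source_shape, collapse = " x ")))
})

setMethod("show", "FSCCurve", function(object) {
  cat(sprintf("FSCCurve: %d shells, f in [%.4g, %.4g] 1/A\n",
              length(object@correlations),
              min(object@shell_frequencies), max(object@shell_frequencies)))
})

setMethod("show", "EnhancerNetwork", function(object) {
  cfg <- object@config
  cat(sprintf(
    "EnhancerNetwork: 4-level U-Net transformer, base %d channels, %d heads\n",
    cfg$base_channels, cfg$epa_heads))
  cat(sprintf("  input edge %d, %s parameters\n", cfg$input_edge,
              format(parameterCount(object), big.mark = ",")))
})
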