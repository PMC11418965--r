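# MRC2014/CCP4 map input/output, resampling and normalization.
#
# No CRAN/Bioconductor package parses the MRC volume format, so the 1024-byte
# header and the mode-0/1/2/6 data sections are handled here directly with
# readBin/writeBin (little-endian, the format's modern default).

mrcConnection <- function(path, open) {
  if (grepl("\\.gz$", path, ignore.case = TRUE)) gzfile(path, open)
  else file(path, open)
}

#' Read an MRC/CCP4 density map
#'
#' Parses an MRC2014 (or legacy CCP4) volume, accepting data modes 0 (int8),
#' 1 (int16), 2 (float32) and 6 (uint16) and transparent gzip compression
#' (`.gz` suffix).  The returned map is canonicalized: stored axes are
#' permuted so the first array index runs along crystallographic X, and the
#' physical origin is reconstructed from the ORIGIN header fields or, when
#' those are all zero, from the start indices times the voxel size.
#'
#' Maps with non-orthogonal cell angles are rejected.
#'
#' @param path path to a `.mrc`/`.map` file, optionally gzipped.
#' @return A [DensityMap-class] in canonical axis order.
#' @export
readDensityMap <- function(path) {
  if (!file.exists(path)) stop("map file does not exist: ", path)
  con <- mrcConnection(path, "rb")
  on.exit(close(con))
  int1 <- function(n) readBin(con, "integer", n = n, size = 4L,
                              endian = "little")
  flt <- function(n) readBin(con, "double", n = n, size = 4L,
                             endian = "little")
  nxyz <- int1(3)                       # NX NY NZ: columns, rows, sections
  mode <- int1(1)
  nstart <- int1(3)                     # NXSTART NYSTART NZSTART
  mxyz <- int1(3)                       # MX MY MZ: sampling along cell axes
  cella <- flt(3)
  cellb <- flt(3)
  mapcrs <- int1(3)                     # MAPC MAPR MAPS in 1..3
  dstats <- flt(3)                      # DMIN DMAX DMEAN (unused)
  ispg <- int1(1); nsymbt <- int1(1)
  extra <- readBin(con, "raw", n = 100)         # words 26-49
  origin_hdr <- flt(3)                          # MRC2014 ORIGIN, words 50-52
  magic <- readBin(con, "raw", n = 4)
  # skip the rest of the 1024-byte header plus any symmetry records
  # (seek() is unreliable on gzfile connections, so read and discard)
  invisible(readBin(con, "raw", n = 812 + max(nsymbt, 0L)))

  if (any(nxyz < 1L)) stop("corrupt MRC header: non-positive dimensions")
  if (!mode %in% c(0L, 1L, 2L, 6L))
    stop("unsupported MRC mode ", mode, " in ", path)
  if (any(abs(cellb - 90) > 1e-3))
    stop("non-orthogonal axes: cell angles (",
         paste(format(cellb), collapse = ", "), ") in ", path)
  if (!all(sort(mapcrs) == 1:3))
    stop("corrupt MRC header: MAPC/MAPR/MAPS is not a permutation of 1..3")

  n <- prod(nxyz)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "double", n = n, size = 4L, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                             endian = "little")))
  if (length(vals) != n) stop("truncated MRC data section in ", path)
  arr <- array(vals, dim = nxyz)        # first index = columns axis (fastest)

  # Stored axis s (1=cols, 2=rows, 3=sections) holds crystallographic axis
  # mapcrs[s]; permute so array index a runs along crystallographic axis a.
  perm <- match(1:3, mapcrs)            # perm[a] = stored axis holding a
  arr <- aperm(arr, perm)

  mxyz <- pmax(mxyz, 1L)
  voxel_cryst <- cella / mxyz           # Angstrom per voxel per cryst. axis
  nstart_cryst <- nstart[perm]          # start indices, reordered to X,Y,Z
  origin <- if (any(abs(origin_hdr) > 0)) origin_hdr
            else nstart_cryst * voxel_cryst
  DensityMap(arr, voxel_size = voxel_cryst, origin = origin)
}

#' Write a density map as MRC2014
#'
#' Emits a standard mode-2 (float32) MRC2014 file in canonical axis order
#' (MAPC/MAPR/MAPS = 1/2/3), with cell dimensions `shape * voxel_size`,
#' the ORIGIN fields set, and recomputed DMIN/DMAX/DMEAN/RMS statistics.
#'
#' @param map a [DensityMap-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeDensityMap <- function(map, path) {
  stopifnot(is(map, "DensityMap"))
  validObject(map)
  d <- dim(map@data)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                               endian = "little")
  vals <- as.numeric(map@data)
  wint(d)                               # NX NY NZ
  wint(2L)                              # mode 2: float32
  wint(c(0L, 0L, 0L))                   # NxSTART
  wint(d)                               # MX MY MZ
  wflt(d * map@voxel_size)              # CELLA
  wflt(c(90, 90, 90))                   # CELLB
  wint(1:3)                             # MAPC MAPR MAPS canonical
  wflt(c(min(vals), max(vals), mean(vals)))
  wint(c(1L, 0L))                       # ISPG, NSYMBT
  writeBin(raw(100), con)               # words 26-49
  wflt(map@origin)                      # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wflt(stats::sd(vals))                 # RMS
  wint(0L)                              # NLABL
  writeBin(raw(800), con)               # labels
  wflt(vals)
  invisible(path)
}

#' Resample a map onto a grid of given spacing
#'
#' Returns the map interpolated onto an axis-aligned grid of spacing
#' `target_voxel` Angstrom covering the same physical extent (output shape
#' `ceiling(extent / target_voxel)`), with the origin preserved as a
#' physical position.  Values are obtained by interpolation at the new voxel
#' centers in physical coordinates; points outside the source extent are 0.
#' When the target spacing equals the source spacing on all axes the data
#' are returned unchanged.
#'
#' @param map a [DensityMap-class].
#' @param target_voxel target spacing in Angstrom (scalar or length-3).
#' @param method `"trilinear"` (default) or `"tricubic"` (Catmull-Rom,
#'   smoother but not monotone).
#' @return A resampled [DensityMap-class].
#' @export
resampleToGrid <- function(map, target_voxel = 1,
                           method = c("trilinear", "tricubic")) {
  method <- match.arg(method)
  stopifnot(all(target_voxel > 0))
  tv <- rep_len(as.numeric(target_voxel), 3L)
  d <- dim(map@data)
  if (isTRUE(all(tv == map@voxel_size))) return(map)
  extent <- d * map@voxel_size
  nd <- pmax(as.integer(ceiling(extent / tv)), 1L)
  # fractional source indices (0-based) of every output voxel center
  ax <- lapply(1:3, function(a) (seq_len(nd[a]) - 1) * tv[a] / map@voxel_size[a])
  gx <- rep(ax[[1]], times = nd[2] * nd[3])
  gy <- rep(rep(ax[[2]], each = nd[1]), times = nd[3])
  gz <- rep(ax[[3]], each = nd[1] * nd[2])
  vals <- if (method == "trilinear") interpTrilinear(map@data, gx, gy, gz)
          else interpTricubic(map@data, gx, gy, gz)
  DensityMap(array(vals, nd), voxel_size = tv, origin = map@origin)
}

# Vectorized trilinear interpolation at fractional 0-based indices;
# out-of-extent points are 0.
interpTrilinear <- function(arr, gx, gy, gz) {
  d <- dim(arr)
  inside <- gx >= 0 & gx <= d[1] - 1 & gy >= 0 & gy <= d[2] - 1 &
            gz >= 0 & gz <= d[3] - 1
  out <- numeric(length(gx))
  if (!any(inside)) return(out)
  x <- gx[inside]; y <- gy[inside]; z <- gz[inside]
  x0 <- pmin(floor(x), d[1] - 2); x0[d[1] == 1] <- 0
  y0 <- pmin(floor(y), d[2] - 2); y0[d[2] == 1] <- 0
  z0 <- pmin(floor(z), d[3] - 2); z0[d[3] == 1] <- 0
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  at <- function(i, j, k) arr[1 + i + d[1] * (j + d[2] * k)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
       at(x1, y0, z0) * fx * (1 - fy) * (1 - fz) +
       at(x0, y1, z0) * (1 - fx) * fy * (1 - fz) +
       at(x1, y1, z0) * fx * fy * (1 - fz) +
       at(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
       at(x1, y0, z1) * fx * (1 - fy) * fz +
       at(x0, y1, z1) * (1 - fx) * fy * fz +
       at(x1, y1, z1) * fx * fy * fz
  out[inside] <- v
  out
}

cubicWeights <- function(t) {
  # Catmull-Rom weights for samples at offsets -1, 0, 1, 2
  cbind(((-t + 2 * t^2 - t^3) / 2),
        (2 - 5 * t^2 + 3 * t^3) / 2,
        (t + 4 * t^2 - 3 * t^3) / 2,
        ((-t^2 + t^3) / 2))
}

interpTricubic <- function(arr, gx, gy, gz) {
  d <- dim(arr)
  inside <- gx >= 0 & gx <= d[1] - 1 & gy >= 0 & gy <= d[2] - 1 &
            gz >= 0 & gz <= d[3] - 1
  out <- numeric(length(gx))
  if (!any(inside)) return(out)
  x <- gx[inside]; y <- gy[inside]; z <- gz[inside]
  b <- function(v, n) pmax(pmin(v, n - 1), 0)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  wx <- cubicWeights(x - x0); wy <- cubicWeights(y - y0)
  wz <- cubicWeights(z - z0)
  at <- function(i, j, k) arr[1 + b(i, d[1]) + d[1] * (b(j, d[2]) +
                              d[2] * b(k, d[3]))]
  v <- 0
  for (a in 0:3) for (bb in 0:3) for (cc in 0:3)
    v <- v + wx[, a + 1] * wy[, bb + 1] * wz[, cc + 1] *
         at(x0 - 1 + a, y0 - 1 + bb, z0 - 1 + cc)
  out[inside] <- v
  out
}

#' Normalize a map by a percentile density value
#'
#' Divides the density by the value at the given percentile (linear
#' interpolation between order statistics, the `type = 7` convention), then
#' clips the tail above 1 to 1 and, if `clip_low`, negative values to 0 —
#' producing the conventional 0-to-1 range used as network input.
#'
#' @param map a [DensityMap-class].
#' @param percentile percentile in (0, 100]; default 99.999.
#' @param clip_low clip negative values to zero (default TRUE).
#' @return A list with elements `map` (the normalized [DensityMap-class]) and
#'   `record` (a [NormalizationRecord-class] storing the divisor).
#' @export
normalizePercentile <- function(map, percentile = 99.999, clip_low = TRUE) {
  stopifnot(percentile > 0, percentile <= 100)
  scale <- stats::quantile(map@data, percentile / 100, type = 7,
                           names = FALSE)
  if (!is.finite(scale) || scale <= 0)
    stop("cannot normalize map: the ", percentile,
         "th percentile density is not positive (degenerate map)")
  x <- map@data / scale
  x[x > 1] <- 1
  if (clip_low) x[x < 0] <- 0
  list(map = DensityMap(x, map@voxel_size, map@origin),
       record = new("NormalizationRecord", percentile = percentile,
                    scale = scale, clip_low = clip_low))
}
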