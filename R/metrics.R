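# Map-model validation: unmasked Fourier shell correlation and whole-box
# correlation.  These are the standard textbook definitions, computed
# self-contained; they are simplified analogues of the external validation
# tools, not drop-in equivalents.

#' Fourier shell correlation between two maps
#'
#' For each radial shell in discrete Fourier space,
#' `FSC(s) = Re(sum F_A conj(F_B)) / sqrt(sum |F_A|^2 * sum |F_B|^2)` over
#' the voxels whose spatial-frequency magnitude falls in the shell.  Shells
#' are one reciprocal voxel wide (`1 / (max(dim) * voxel)`), no masking is
#' applied, and only shells up to Nyquist (`1 / (2 voxel)`) are reported.
#'
#' @param mapA,mapB two [DensityMap-class]s with identical shapes and voxel
#'   sizes (or bare arrays plus `voxel_size`).
#' @param voxel_size used when bare arrays are given.
#' @return An [FSCCurve-class].
#' @export
fscCurve <- function(mapA, mapB, voxel_size = NULL) {
  getArr <- function(m) if (is(m, "DensityMap")) m@data else m
  a <- getArr(mapA); b <- getArr(mapB)
  if (!identical(dim(a), dim(b))) stop("maps must have identical shapes")
  va <- if (is(mapA, "DensityMap")) mapA@voxel_size else
    rep_len(voxel_size %||% 1, 3L)
  vb <- if (is(mapB, "DensityMap")) mapB@voxel_size else va
  if (any(abs(va - vb) > 1e-9)) stop("maps must have identical voxel sizes")
  d <- dim(a)
  FA <- stats::fft(a); FB <- stats::fft(b)
  freqAxis <- function(n, vox) {
    i <- 0:(n - 1)
    i[i > n / 2] <- i[i > n / 2] - n
    i / (n * vox)
  }
  fx <- freqAxis(d[1], va[1]); fy <- freqAxis(d[2], va[2])
  fz <- freqAxis(d[3], va[3])
  fmag <- sqrt(outer(outer(fx^2, fy^2, `+`), fz^2, `+`))
  df <- 1 / (max(d) * min(va))
  shell <- as.integer(round(fmag / df))
  nyq <- 1 / (2 * min(va))
  keep <- fmag <= nyq + df / 2
  num <- Re(FA * Conj(FB))
  pa <- Mod(FA)^2; pb <- Mod(FB)^2
  sh <- shell[keep]
  sNum <- tapply(num[keep], sh, sum)
  sPa <- tapply(pa[keep], sh, sum)
  sPb <- tapply(pb[keep], sh, sum)
  denom <- sqrt(sPa * sPb)
  corr <- ifelse(denom > 0, sNum / denom, 0)
  corr <- pmin(pmax(corr, -1), 1)
  idx <- as.integer(names(sNum))
  ord <- order(idx)
  new("FSCCurve", shell_frequencies = idx[ord] * df,
      correlations = as.numeric(corr[ord]), shell_width = df)
}

#' Threshold-crossing resolution from an FSC curve
#'
#' Scans shells in ascending frequency for the first one whose correlation
#' falls below `threshold`, linearly interpolates the crossing frequency
#' between the bracketing shells, and returns its reciprocal in Angstrom.
#' If the curve never falls below the threshold the Nyquist-limited value
#' `1 / f_max` is returned with attribute `limited = TRUE`; if the curve
#' starts below the threshold the first-shell resolution is returned with
#' attribute `degenerate = TRUE`.  The first downward crossing is used even
#' if the curve later recovers.
#'
#' @param curve an [FSCCurve-class].
#' @param threshold correlation threshold in (0, 1), e.g. 0.143 or 0.5.
#' @return Resolution in Angstrom (possibly with a flag attribute).
#' @export
fscResolution <- function(curve, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  f <- curve@shell_frequencies
  cc <- curve@correlations
  # drop the DC shell from crossing detection but keep it as a left bracket
  if (length(f) < 2L) stop("FSC curve has fewer than 2 shells")
  if (cc[1] < threshold) {
    res <- 1 / max(f[1], curve@shell_width / 2)
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  below <- which(cc < threshold)
  if (!length(below)) {
    res <- 1 / f[length(f)]
    attr(res, "limited") <- TRUE
    return(res)
  }
  i <- below[1]
  f_star <- f[i - 1] + (f[i] - f[i - 1]) *
    (cc[i - 1] - threshold) / (cc[i - 1] - cc[i])
  1 / f_star
}

#' Map-model FSC resolution
#'
#' Simulates the model-calculated map from the structure on the
#' experimental map's own grid (kernel from `R0`), computes the unmasked
#' FSC between the two maps and returns the threshold-crossing resolution.
#' A simplified self-contained analogue of external map-model validation
#' tools, not equivalent to them.
#'
#' @param map a [DensityMap-class].
#' @param structure an [AtomicStructure-class] positioned in the map frame.
#' @param R0 resolution (Angstrom) parameterizing the simulation kernel.
#' @param threshold FSC threshold; default 0.5.
#' @param k_convention passed to [gaussianConstants()].
#' @return Resolution in Angstrom, as [fscResolution()].
#' @export
mapModelFSC <- function(map, structure, R0, threshold = 0.5,
                        k_convention = "inverse-square") {
  kern <- gaussianConstants(R0, k_convention)
  model_map <- simulateMap(structure, kern, map)
  fscResolution(fscCurve(map, model_map), threshold)
}

#' Whole-box Pearson correlation between two maps
#'
#' @param mapA,mapB [DensityMap-class]s or arrays of identical shape.
#' @return Correlation in [-1, 1]; errors on zero-variance input.
#' @export
ccBox <- function(mapA, mapB) {
  a <- if (is(mapA, "DensityMap")) mapA@data else mapA
  b <- if (is(mapB, "DensityMap")) mapB@data else mapB
  if (!identical(dim(a), dim(b))) stop("maps must have identical shapes")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("cc_box undefined: a map has zero variance")
  stats::cor(as.numeric(a), as.numeric(b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
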