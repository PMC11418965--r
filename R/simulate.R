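# Clean reference-map simulation: each atom contributes a Gaussian scaled by
# its atomic number,
#     rho(y) = sum_i C * A_i * exp(-k * ||x_i - y||^2),
# with k set by the map's resolution R0 and C = (k/pi)^(3/2) so one unit of
# atomic number integrates to one unit of density mass.

#' Gaussian kernel constants from a target resolution
#'
#' Computes the kernel coefficient `k`, the normalization `C = (k/pi)^(3/2)`
#' and the truncation radius at which the kernel falls to `tail` of its peak.
#' Two readings of the printed formula for `k` are supported:
#' `"inverse-square"` (default), `k = pi / (0.9 R0)^2`, and `"squared"`,
#' `k = (pi / (0.9 R0))^2`.
#'
#' @param R0 resolution in Angstrom (> 0), conventionally the unmasked
#'   map-model FSC resolution at the 0.143 threshold.
#' @param k_convention `"inverse-square"` or `"squared"`.
#' @param tail kernel fraction retained at the cutoff radius; default 1e-6
#'   (well under the 1e-4 truncation-loss bound, at little extra cost).
#' @return A list with fields `R0`, `k` (1/A^2), `C` (1/A^3),
#'   `cutoff_radius` (A) and `k_convention`.
#' @examples
#' gaussianConstants(3.0)   # k = pi/2.7^2, C = (k/pi)^1.5
#' @export
gaussianConstants <- function(R0, k_convention = c("inverse-square", "squared"),
                              tail = 1e-6) {
  stopifnot(R0 > 0, tail > 0, tail < 1)
  k_convention <- match.arg(k_convention)
  k <- if (k_convention == "inverse-square") pi / (0.9 * R0)^2
       else (pi / (0.9 * R0))^2
  list(R0 = R0, k = k, C = (k / pi)^1.5,
       cutoff_radius = sqrt(log(1 / tail) / k),
       k_convention = k_convention)
}

normalizeGridSpec <- function(grid) {
  if (is(grid, "DensityMap"))
    return(list(shape = dim(grid@data), voxel_size = grid@voxel_size,
                origin = grid@origin))
  stopifnot(is.list(grid), all(c("shape", "voxel_size", "origin") %in%
                               names(grid)))
  list(shape = as.integer(rep_len(grid$shape, 3L)),
       voxel_size = as.numeric(rep_len(grid$voxel_size, 3L)),
       origin = as.numeric(rep_len(grid$origin, 3L)))
}

#' Simulate a clean density map from an atomic structure
#'
#' Evaluates the per-atom Gaussian sum on the given grid.  Contributions are
#' occupancy-weighted and truncated at `kernel$cutoff_radius` (set
#' `cutoff_radius = 0` or `Inf` in the kernel list to disable truncation);
#' voxels with no atom within the cutoff are exactly zero.
#'
#' @param structure an [AtomicStructure-class].
#' @param kernel constants from [gaussianConstants()].
#' @param grid a [DensityMap-class] template or a list with `shape`,
#'   `voxel_size`, `origin` (the map is generated on exactly this grid, so a
#'   simulated target is voxel-aligned with its experimental map).
#' @return A [DensityMap-class] of simulated density.
#' @export
simulateMap <- function(structure, kernel, grid) {
  g <- normalizeGridSpec(grid)
  d <- g$shape
  vox <- g$voxel_size
  out <- array(0, d)
  cut <- kernel$cutoff_radius
  if (is.null(cut) || !is.finite(cut) || cut <= 0)
    cut <- max(d * vox) + max(abs(structure@coords)) + abs(max(g$origin)) + 1
  w <- kernel$C * structure@atomic_number * structure@occupancy
  xyz <- structure@coords
  axes <- lapply(1:3, function(a) g$origin[a] + (seq_len(d[a]) - 1) * vox[a])
  touched <- FALSE
  for (i in seq_len(nrow(xyz))) {
    lo <- pmax(ceiling((xyz[i, ] - cut - g$origin) / vox) + 1, 1)
    hi <- pmin(floor((xyz[i, ] + cut - g$origin) / vox) + 1, d)
    if (any(lo > hi)) next
    touched <- TRUE
    dx2 <- (axes[[1]][lo[1]:hi[1]] - xyz[i, 1])^2
    dy2 <- (axes[[2]][lo[2]:hi[2]] - xyz[i, 2])^2
    dz2 <- (axes[[3]][lo[3]:hi[3]] - xyz[i, 3])^2
    r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    contrib <- w[i] * exp(-kernel$k * r2)
    contrib[r2 > cut^2] <- 0
    out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + contrib
  }
  if (!touched)
    warning("structure lies entirely outside the grid extent; map is zero")
  DensityMap(out, voxel_size = vox, origin = g$origin)
}

#' Smallest grid containing a structure plus padding
#'
#' @param structure an [AtomicStructure-class].
#' @param voxel_size grid spacing in Angstrom.
#' @param padding clearance in Angstrom added on every side (>= 0).
#' @return A grid spec list (`shape`, `voxel_size`, `origin`) usable as the
#'   `grid` argument of [simulateMap()].
#' @export
autoGridForStructure <- function(structure, voxel_size = 1, padding = 4) {
  stopifnot(padding >= 0, voxel_size > 0)
  vox <- rep_len(as.numeric(voxel_size), 3L)
  lo <- apply(structure@coords, 2, min) - padding
  hi <- apply(structure@coords, 2, max) + padding
  shape <- as.integer(ceiling((hi - lo) / vox)) + 1L
  list(shape = shape, voxel_size = vox, origin = lo)
}
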