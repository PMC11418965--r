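# Synthetic fixture generation: toy protein-like structures, their clean
# simulated maps, and degraded counterparts standing in for deposited
# experimental maps.  The degradation model (Gaussian blur + additive white
# noise + background offset) is an explicit stand-in for experimental
# contrast loss and noise, not an image-formation model.

#' Generate a toy poly-alanine-like backbone
#'
#' Builds N, CA, C, O atoms (atomic numbers 7, 6, 6, 8) per residue along an
#' ideal alpha-helix (rise 1.5 A, 100 degrees per residue, CA radius 2.3 A),
#' an extended strand, or a correlated random-walk coil.  Consecutive CA-CA
#' distances are 3.8 +/- 0.2 A.
#'
#' @param n_residues number of residues (>= 1).
#' @param motif `"helix"`, `"strand"` or `"coil"`.
#' @return An [AtomicStructure-class] with `4 * n_residues` atoms.
#' @export
makeToyStructure <- function(n_residues, motif = c("helix", "strand", "coil")) {
  motif <- match.arg(motif)
  stopifnot(n_residues >= 1)
  i <- seq_len(n_residues) - 1
  ca <- switch(motif,
    helix = {
      r <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
      cbind(r * cos(i * twist), r * sin(i * twist), rise * i)
    },
    strand = cbind(3.29 * i, 0.95 * (-1)^i, 0 * i),   # 3.8 A zigzag pitch
    coil = {
      # correlated random walk with fixed 3.8 A steps
      dirs <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
      pos <- matrix(0, n_residues, 3)
      v <- c(1, 0, 0)
      for (r in seq_len(n_residues)[-1]) {
        v <- v + 0.7 * dirs[r, ]
        v <- v / sqrt(sum(v^2))
        pos[r, ] <- pos[r - 1, ] + 3.8 * v
      }
      pos
    })
  # backbone satellites: fixed offsets in a local frame along the chain
  nxt <- pmin(seq_len(n_residues) + 1L, n_residues)
  prv <- pmax(seq_len(n_residues) - 1L, 1L)
  tangent <- ca[nxt, , drop = FALSE] - ca[prv, , drop = FALSE]
  nrm <- sqrt(rowSums(tangent^2)); nrm[nrm == 0] <- 1
  tangent <- tangent / nrm
  up <- cbind(-tangent[, 2], tangent[, 1],
              rep(0.4, n_residues))
  up <- up / sqrt(rowSums(up^2))
  atomsN <- ca - 1.2 * tangent + 0.6 * up
  atomsC <- ca + 1.2 * tangent + 0.4 * up
  atomsO <- atomsC + 1.23 * up
  coords <- matrix(0, 4 * n_residues, 3)
  coords[seq(1, 4 * n_residues, 4), ] <- atomsN
  coords[seq(2, 4 * n_residues, 4), ] <- ca
  coords[seq(3, 4 * n_residues, 4), ] <- atomsC
  coords[seq(4, 4 * n_residues, 4), ] <- atomsO
  AtomicStructure(element = rep(c("N", "C", "C", "O"), n_residues),
                  coords = coords,
                  id = sprintf("toy-%s-%d", motif, n_residues))
}

#' Degradation settings for synthetic "experimental" maps
#'
#' @param blur_sigma Gaussian blur standard deviation in Angstrom
#'   (resolution loss).
#' @param noise_sigma additive white-noise standard deviation as a fraction
#'   of the clean map's peak density.
#' @param background_offset constant offset as a fraction of the peak.
#' @return A degradation spec list.
#' @export
degradationSpec <- function(blur_sigma = 1.0, noise_sigma = 0.1,
                            background_offset = 0.05) {
  stopifnot(blur_sigma >= 0, noise_sigma >= 0, background_offset >= 0)
  list(blur_sigma = blur_sigma, noise_sigma = noise_sigma,
       background_offset = background_offset)
}

gaussKernel1D <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# separable zero-padded 1-D convolution along each axis
blur3D <- function(arr, sigma_vox) {
  k <- gaussKernel1D(sigma_vox)
  if (length(k) == 1L) return(arr)
  r <- (length(k) - 1L) / 2L
  convAxis <- function(x, axis) {
    d <- dim(x)
    xp <- aperm(x, c(axis, setdiff(1:3, axis)))
    m <- matrix(xp, nrow = d[axis])
    out <- matrix(0, d[axis], ncol(m))
    for (j in seq_along(k)) {
      sft <- j - r - 1L
      src <- seq_len(d[axis]) + sft
      ok <- src >= 1 & src <= d[axis]
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
    }
    aperm(array(out, d[c(axis, setdiff(1:3, axis))]),
          order(c(axis, setdiff(1:3, axis))))
  }
  for (a in 1:3) arr <- convAxis(arr, a)
  arr
}

#' Degrade a clean map into a synthetic "experimental" map
#'
#' `output = blur(clean, sigma) + offset * peak + N(0, noise * peak)` per
#' voxel, with the blur implemented as a normalized, real-space separable
#' kernel truncated at 4 sigma.  Deterministic under `set.seed`.
#'
#' @param clean a [DensityMap-class].
#' @param spec a [degradationSpec()] list.
#' @return A degraded [DensityMap-class] on the same grid.
#' @export
degradeMap <- function(clean, spec = degradationSpec()) {
  arr <- clean@data
  peak <- max(arr)
  out <- blur3D(arr, spec$blur_sigma / min(clean@voxel_size))
  if (spec$background_offset > 0) out <- out + spec$background_offset * peak
  if (spec$noise_sigma > 0)
    out <- out + stats::rnorm(length(out), 0, spec$noise_sigma * peak)
  DensityMap(array(out, dim(arr)), clean@voxel_size, clean@origin)
}

#' Generate a synthetic training dataset on disk
#'
#' For each entry: draw a toy structure, simulate its clean map at a sampled
#' resolution `R0` on an auto-fitted 1 A grid, degrade it, and write the MRC
#' pair plus the PDB file.  A manifest table pairing inputs with targets is
#' written as `manifest.csv` and returned.
#'
#' @param n_structures number of triples to generate.
#' @param out_dir output directory (created if needed).
#' @param residues_range range of residue counts to sample from.
#' @param R0_range range of simulation resolutions (Angstrom).
#' @param degradation a [degradationSpec()] list.
#' @param voxel_size grid spacing, default 1 Angstrom.
#' @param padding grid clearance around each structure, Angstrom.
#' @param motifs motifs to sample from.
#' @return The manifest as a data.frame with columns `input_map`,
#'   `structure`, `target_map`, `R0`.
#' @export
makeDataset <- function(n_structures, out_dir,
                        residues_range = c(12, 24),
                        R0_range = c(3, 5),
                        degradation = degradationSpec(),
                        voxel_size = 1, padding = 5,
                        motifs = c("helix", "strand", "coil")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_structures)
  for (i in seq_len(n_structures)) {
    nres <- sample(seq(residues_range[1], residues_range[2]), 1)
    motif <- sample(motifs, 1)
    R0 <- stats::runif(1, R0_range[1], R0_range[2])
    s <- makeToyStructure(nres, motif)
    grid <- autoGridForStructure(s, voxel_size = voxel_size,
                                 padding = padding)
    clean <- simulateMap(s, gaussianConstants(R0), grid)
    degraded <- degradeMap(clean, degradation)
    sp <- file.path(out_dir, sprintf("structure_%03d.pdb", i))
    cp <- file.path(out_dir, sprintf("clean_%03d.mrc", i))
    dp <- file.path(out_dir, sprintf("degraded_%03d.mrc", i))
    writeStructurePDB(s, sp,
                      atom_names = rep(c("N", "CA", "C", "O"), nres),
                      resno = rep(seq_len(nres), each = 4))
    writeDensityMap(clean, cp)
    writeDensityMap(degraded, dp)
    rows[[i]] <- data.frame(input_map = dp, structure = sp,
                            target_map = cp, R0 = R0,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
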