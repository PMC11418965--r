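# Independent brute-force oracles used across the suite.  These deliberately
# avoid the package's optimized code paths.

# Eq.-style Gaussian sum with a plain double loop over (voxel, atom), no
# cutoff, no vectorization tricks shared with simulateMap().
bruteForceSimulate <- function(structure, kern, grid) {
  d <- grid$shape
  out <- array(0, d)
  w <- kern$C * atomicNumbers(structure) * structure@occupancy
  xyz <- atomCoords(structure)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    y <- grid$origin + (c(i, j, k) - 1) * grid$voxel_size
    acc <- 0
    for (a in seq_len(nrow(xyz)))
      acc <- acc + w[a] * exp(-kern$k * sum((xyz[a, ] - y)^2))
    out[i, j, k] <- acc
  }
  out
}

# offset lattice with boundary clamping, by literal enumeration
bruteForceOffsets1D <- function(dim, block, stride) {
  if (dim <= block) return(0L)
  offs <- integer()
  o <- 0L
  while (TRUE) {
    if (o + block >= dim) {
      offs <- c(offs, dim - block)
      break
    }
    offs <- c(offs, o)
    o <- o + stride
  }
  unique(as.integer(offs))
}

randomMap <- function(shape, voxel = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  DensityMap(array(stats::rnorm(prod(shape)), shape), voxel_size = voxel)
}

tinyArchitecture <- function(base = 4L, heads = 2L, edge = 16L, dropout = 0)
  architectureConfig(base_channels = base, epa_heads = heads,
                     input_edge = edge, dropout_rate = dropout)

# small structure + clean/degraded maps for pipeline tests
toyTriple <- function(n_res = 10, R0 = 4, seed = 1,
                      spec = degradationSpec()) {
  set.seed(seed)
  s <- makeToyStructure(n_res, "helix")
  grid <- autoGridForStructure(s, voxel_size = 1, padding = 5)
  clean <- simulateMap(s, gaussianConstants(R0), grid)
  degraded <- degradeMap(clean, spec)
  list(structure = s, clean = clean, degraded = degraded, R0 = R0)
}
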