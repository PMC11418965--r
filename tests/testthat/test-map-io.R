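# MRC input/output, axis canonicalization, resampling, normalization

writePermutedMRC <- function(path, arr, voxel, mapcrs) {
  # write an MRC file whose stored axis order is permuted: stored axis s
  # (columns, rows, sections) holds crystallographic axis mapcrs[s]
  d <- dim(arr)                    # canonical X, Y, Z extents
  perm <- match(1:3, mapcrs)       # stored axis holding cryst axis a
  stored <- aperm(arr, mapcrs)     # stored[c, r, s] with dims d[mapcrs]
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wflt <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wint(dim(stored)); wint(2L); wint(c(0L, 0L, 0L)); wint(d)
  wflt(d * voxel); wflt(c(90, 90, 90)); wint(mapcrs)
  wflt(c(min(arr), max(arr), mean(arr))); wint(c(1L, 0L))
  writeBin(raw(100), con); wflt(c(0, 0, 0))
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  wflt(stats::sd(arr)); wint(0L); writeBin(raw(800), con)
  wflt(as.numeric(stored))
  invisible(path)
}

test_that("write/read round trip preserves data, voxel size and origin", {
  set.seed(1)
  m <- DensityMap(array(rnorm(10 * 12 * 14), c(10, 12, 14)),
                  voxel_size = c(1.25, 1, 0.75), origin = c(-3, 2, 5.5))
  tf <- withr::local_tempfile(fileext = ".mrc")
  writeDensityMap(m, tf)
  m2 <- readDensityMap(tf)
  expect_equal(mapData(m2), mapData(m), tolerance = 1e-6)  # float32 storage
  expect_equal(voxelSize(m2), voxelSize(m), tolerance = 1e-6)
  expect_equal(mapOrigin(m2), mapOrigin(m), tolerance = 1e-6)
})

test_that("gzip-compressed maps are read transparently", {
  set.seed(2)
  m <- DensityMap(array(rnorm(6^3), rep(6, 3)))
  tf <- withr::local_tempfile(fileext = ".mrc")
  writeDensityMap(m, tf)
  gz <- paste0(tf, ".gz")
  withr::defer(unlink(gz))
  con <- gzfile(gz, "wb")
  writeBin(readBin(tf, "raw", file.size(tf)), con)
  close(con)
  m2 <- readDensityMap(gz)
  expect_equal(mapData(m2), mapData(m), tolerance = 1e-6)
})

test_that("permuted axis order is canonicalized (brute-force re-indexing)", {
  # axis-identifying ramp so x/y/z mix-ups cannot cancel out
  d <- c(10, 12, 14)
  arr <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    arr[i, j, k] <- i + 100 * j + 10000 * k
  tf <- withr::local_tempfile(fileext = ".mrc")
  writePermutedMRC(tf, arr, voxel = c(1, 1, 1), mapcrs = c(3L, 1L, 2L))

  # raw-file layout check: stored[c, r, s] must hold arr[r, s, c]
  # (columns = cryst Z, rows = cryst X, sections = cryst Y)
  con <- file(tf, "rb")
  seek(con, 1024)
  raw_vals <- readBin(con, "double", prod(d), size = 4, endian = "little")
  close(con)
  stored <- array(raw_vals, c(14, 10, 12))
  for (pt in list(c(2, 3, 4), c(9, 5, 11), c(14, 10, 12)))
    expect_equal(stored[pt[1], pt[2], pt[3]],
                 arr[pt[2], pt[3], pt[1]], tolerance = 1e-3)

  m <- readDensityMap(tf)
  expect_identical(dim(mapData(m)), dim(arr))
  # every voxel lands at the same physical position as pre-permutation
  expect_equal(mapData(m), arr, tolerance = 1e-3)

  tf2 <- withr::local_tempfile(fileext = ".mrc")
  writePermutedMRC(tf2, arr, voxel = c(1, 1, 1), mapcrs = c(2L, 3L, 1L))
  expect_equal(mapData(readDensityMap(tf2)), arr, tolerance = 1e-3)
})

test_that("non-orthogonal cell angles are rejected", {
  set.seed(4)
  m <- DensityMap(array(rnorm(4^3), rep(4, 3)))
  tf <- withr::local_tempfile(fileext = ".mrc")
  writeDensityMap(m, tf)
  # patch CELLB gamma (word 15, bytes 60..63) to 120 degrees
  con <- file(tf, "r+b")
  seek(con, 60, rw = "write")
  writeBin(120, con, size = 4L, endian = "little")
  close(con)
  expect_error(readDensityMap(tf), "non-orthogonal")
})

test_that("a constant 8^3 map writes the expected header statistics", {
  m <- DensityMap(array(0, rep(8, 3)), voxel_size = 1)
  tf <- withr::local_tempfile(fileext = ".mrc")
  writeDensityMap(m, tf)
  con <- file(tf, "rb")
  hdr_i <- readBin(con, "integer", 10, size = 4, endian = "little")
  cella <- readBin(con, "double", 3, size = 4, endian = "little")
  close(con)
  expect_identical(hdr_i[1:3], rep(8L, 3))
  expect_equal(cella, rep(8, 3))
  m2 <- readDensityMap(tf)
  expect_true(all(mapData(m2) == 0))
})

test_that("an independent MRC parser (gemmi) agrees on geometry and data", {
  set.seed(5)
  m <- DensityMap(array(rnorm(6 * 7 * 8), c(6, 7, 8)),
                  voxel_size = c(1.5, 1.5, 1.5), origin = c(1, 2, 3))
  tf <- withr::local_tempfile(fileext = ".mrc")
  writeDensityMap(m, tf)
  out <- system2("python", c("-c", shQuote(paste0(
    "import gemmi; g = gemmi.read_ccp4_map('", tf, "');",
    "a = g.grid; print(a.nu, a.nv, a.nw);",
    "print(round(g.grid.unit_cell.a, 4));",
    "print(round(a.get_value(2, 3, 4), 6))"))), stdout = TRUE)
  expect_identical(out[1], "6 7 8")
  expect_equal(as.numeric(out[2]), 9)            # 6 voxels * 1.5 A
  expect_equal(as.numeric(out[3]), mapData(m)[3, 4, 5], tolerance = 1e-5)
})

test_that("resampling at the source spacing is the bit-exact identity", {
  set.seed(6)
  m <- randomMap(c(9, 9, 9), voxel = 1)
  expect_identical(mapData(resampleToGrid(m, 1)), mapData(m))
})

test_that("resampling a constant map preserves the constant in the interior", {
  m <- DensityMap(array(3.7, c(16, 16, 16)), voxel_size = 0.5)
  r <- resampleToGrid(m, 1)
  inner <- mapData(r)[1:7, 1:7, 1:7]
  expect_equal(inner, array(3.7, c(7, 7, 7)))
})

test_that("a linear ramp is reproduced exactly at interior points", {
  d <- c(14, 8, 8)
  ramp <- array(rep((seq_len(d[1]) - 1) * 0.8, prod(d[2:3])), d)
  m <- DensityMap(ramp, voxel_size = 0.8)
  r <- resampleToGrid(m, 1)
  nd <- dim(mapData(r))
  ix <- seq_len(min(nd[1], 10)); iy <- 1:6; iz <- 1:6
  expected <- array(rep((ix - 1) * 1.0, length(iy) * length(iz)),
                    c(length(ix), length(iy), length(iz)))
  expect_equal(mapData(r)[ix, iy, iz], expected, tolerance = 1e-5)
})

test_that("trilinear polynomials are reproduced exactly (property)", {
  set.seed(7)
  for (rep in 1:3) {
    co <- rnorm(4)
    d <- c(12, 10, 11)
    vals <- array(0, d)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
      vals[i, j, k] <- co[1] + co[2] * i + co[3] * j + co[4] * k
    m <- DensityMap(vals, voxel_size = 0.7)
    r <- resampleToGrid(m, 0.9)
    nd <- dim(mapData(r))
    # interior output voxels (inside source extent)
    for (pt in list(c(2, 2, 2), c(5, 4, 4), c(7, 6, 6))) {
      src_idx <- (pt - 1) * 0.9 / 0.7 + 1
      expect_equal(mapData(r)[pt[1], pt[2], pt[3]],
                   co[1] + sum(co[2:4] * src_idx), tolerance = 1e-8)
    }
  }
})

test_that("percentile normalization matches the sort-and-interpolate oracle", {
  m <- DensityMap(array(as.numeric(sample(0:100)), c(101, 1, 1)))
  res <- normalizePercentile(m, 99, clip_low = TRUE)
  # oracle: linear interpolation between order statistics
  v <- sort(as.numeric(mapData(m)))
  h <- (length(v) - 1) * 0.99 + 1
  oracle <- v[floor(h)] + (h - floor(h)) * (v[ceiling(h)] - v[floor(h)])
  expect_equal(res$record@scale, oracle)
  expect_equal(res$record@scale, 99)
  expect_equal(max(mapData(res$map)[mapData(m) == 99]), 1.0)
  expect_true(all(mapData(res$map) >= 0 & mapData(res$map) <= 1))
})

test_that("one-hot map normalizes its hot voxel to exactly 1", {
  arr <- array(0, c(5, 5, 5)); arr[3, 3, 3] <- 10
  res <- normalizePercentile(DensityMap(arr), 100)
  expect_equal(mapData(res$map)[3, 3, 3], 1.0)
  expect_true(all(mapData(res$map) >= 0 & mapData(res$map) <= 1))
})

test_that("the stored scale inverts the transform on unclipped voxels", {
  set.seed(8)
  m <- randomMap(c(12, 12, 12))
  res <- normalizePercentile(m, 99.9, clip_low = TRUE)
  unclipped <- mapData(m) >= 0 & mapData(m) <= res$record@scale
  back <- mapData(res$map) * res$record@scale
  expect_equal(back[unclipped], mapData(m)[unclipped], tolerance = 1e-6)
})

test_that("degenerate all-zero maps are rejected with a clear error", {
  expect_error(normalizePercentile(DensityMap(array(0, c(4, 4, 4)))),
               "not positive")
})
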