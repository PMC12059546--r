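test_that("Grid3D validity rejects degenerate lattices", {
  expect_error(Grid3D(c(0L, 4L, 4L)), "shape")
  expect_error(Grid3D(c(4L, 4L, 4L), spacingMm = c(2, 0, 2)), "spacing")
  g <- Grid3D(8L, 2, c(-1, 0, 1))
  expect_identical(gridShape(g), c(8L, 8L, 8L))
  expect_equal(gridSpacing(g), c(2, 2, 2))
})

test_that("ScalarVolume and StructureSet enforce grid agreement and units", {
  g <- Grid3D(c(4L, 4L, 4L))
  expect_error(ScalarVolume(g, array(0, c(4, 4, 3)), "Gy"), "shape")
  v <- ScalarVolume(g, array(1, c(4, 4, 4)), "Gy")
  expect_identical(doseUnit(v), "Gy")
  expect_error(StructureSet(g, list(nonsense = array(TRUE, c(4, 4, 4)))),
               "unknown roles")
  s <- StructureSet(g, list(body = array(1, c(4, 4, 4))))
  expect_type(structureMask(s, "body"), "logical")
  expect_error(structureMask(s, "heart"), "not present")
})

test_that("resampling is exact for identity and constant fields", {
  g <- Grid3D(c(10L, 10L, 10L), spacingMm = 2)
  vals <- array(rnorm(1000), c(10, 10, 10))
  v <- ScalarVolume(g, vals, "Gy")
  s <- StructureSet(g, list(body = array(TRUE, c(10, 10, 10))))
  out <- resampleIsotropic(v, s, 2)
  expect_equal(voxelValues(out$volume), vals)
  expect_identical(gridShape(out$volume), c(10L, 10L, 10L))

  cst <- ScalarVolume(g, array(3.7, c(10, 10, 10)), "Gy")
  out2 <- resampleIsotropic(cst, s, 1.3)
  expect_lt(max(abs(voxelValues(out2$volume) - 3.7)), 1e-9)
})

test_that("downsampling matches pointwise trilinear evaluation", {
  g <- Grid3D(c(9L, 9L, 9L), spacingMm = 1)
  ax <- 0:8
  vals <- outer(outer(ax, 2 * ax, "+"), 3 * ax, "+") +
    array(rnorm(9^3, sd = 0.1), c(9, 9, 9))
  v <- ScalarVolume(g, vals, "Gy")
  s <- StructureSet(g, list(body = array(TRUE, c(9, 9, 9))))
  out <- resampleIsotropic(v, s, 2)
  got <- voxelValues(out$volume)
  sh <- gridShape(out$volume)
  for (k in seq_len(sh[3])) for (j in seq_len(sh[2])) for (i in seq_len(sh[1])) {
    expect_equal(got[i, j, k],
                 oracleTrilinearOne(vals, (i - 1) * 2, (j - 1) * 2,
                                    (k - 1) * 2),
                 tolerance = 1e-12)
  }
  expect_error(resampleIsotropic(
    v, StructureSet(Grid3D(c(9L, 9L, 9L), 2),
                    list(body = array(TRUE, c(9, 9, 9)))), 2),
    "geometry")
})

test_that("mask resampling stays binary under nearest-neighbor", {
  g <- Grid3D(c(9L, 9L, 9L), spacingMm = 1)
  m <- array(FALSE, c(9, 9, 9)); m[3:6, 2:8, 4:5] <- TRUE
  v <- ScalarVolume(g, array(0, c(9, 9, 9)), "Gy")
  out <- resampleIsotropic(v, StructureSet(g, list(PTV = m)), 1.5)
  rm2 <- structureMask(out$masks, "PTV")
  expect_type(rm2, "logical")
  expect_true(any(rm2))
})

test_that("cropping centers the reference mass center and zero-pads", {
  n <- 16L
  g <- Grid3D(c(n, n, n), spacingMm = 2)
  br <- array(FALSE, c(n, n, n)); br[3, 4, 5] <- TRUE   # single voxel
  vals <- array(seq_len(n^3), c(n, n, n))
  v <- ScalarVolume(g, vals, "Gy")
  s <- StructureSet(g, list(breast = br))
  out <- cropAboutMassCenter(v, s, "breast", 12L)
  expect_true(structureMask(out$masks, "breast")[7, 7, 7])  # idx 6 0-based
  expect_identical(gridShape(out$volume), c(12L, 12L, 12L))

  ## direct index-shift oracle incl. zero padding
  got <- voxelValues(out$volume)
  lo <- c(2L, 3L, 4L) - 6L                     # 0-based window start
  for (p in list(c(1L, 1L, 1L), c(6L, 6L, 6L), c(12L, 12L, 12L),
                 c(5L, 9L, 2L))) {
    src <- p - 1L + lo
    expected <- if (all(src >= 0L & src < n))
      vals[src[1] + 1L, src[2] + 1L, src[3] + 1L] else 0
    expect_identical(got[p[1], p[2], p[3]], expected + 0)
  }
  ## physical coordinates preserved
  expect_equal(gridOrigin(out$volume), lo * 2)
})

test_that("crop is the identity when already centered, and guards misuse", {
  n <- 16L
  g <- Grid3D(c(n, n, n))
  br <- array(FALSE, c(n, n, n)); br[9, 9, 9] <- TRUE   # 0-based (8,8,8) = n/2
  vals <- array(rnorm(n^3), c(n, n, n))
  v <- ScalarVolume(g, vals, "Gy")
  s <- StructureSet(g, list(breast = br))
  out <- cropAboutMassCenter(v, s, "breast", n)
  expect_equal(voxelValues(out$volume), vals)

  expect_error(cropAboutMassCenter(
    v, StructureSet(g, list(breast = array(FALSE, c(n, n, n)))),
    "breast", n), "empty")
  expect_error(cropAboutMassCenter(v, s, "breast", 4L * n + 4L), "4x")
})

test_that("crop preserves reference-mask voxel count when fully inside", {
  set.seed(42)
  n <- 20L
  g <- Grid3D(c(n, n, n))
  for (rep in 1:5) {
    br <- array(FALSE, c(n, n, n))
    ctr <- sample(8:12, 3, replace = TRUE)
    br[ctr[1] + (-2:2), ctr[2] + (-2:2), ctr[3] + (-2:2)] <- TRUE
    v <- ScalarVolume(g, array(0, c(n, n, n)), "Gy")
    out <- cropAboutMassCenter(v, StructureSet(g, list(breast = br)), "breast",
                               14L)
    expect_identical(sum(structureMask(out$masks, "breast")), sum(br))
  }
})

test_that("NIfTI round trip preserves values and grid metadata", {
  g <- Grid3D(c(16L, 16L, 16L), 2, c(-31.5, 10, 2.25))
  vals <- array(rnorm(16^3), c(16, 16, 16))
  v <- ScalarVolume(g, vals, "Gy")
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(v, f)
  back <- readVolume(f, unit = "Gy")
  expect_identical(voxelValues(back), vals)
  expect_equal(gridSpacing(back), c(2, 2, 2), tolerance = 1e-6)
  expect_equal(gridOrigin(back), c(-31.5, 10, 2.25), tolerance = 1e-6)

  ## integer label volume read back as integer labels
  lab <- array(sample(0:24, 8^3, replace = TRUE), c(8, 8, 8))
  m <- DoseLevelMap(Grid3D(c(8L, 8L, 8L)), lab, 5)
  f2 <- tempfile(fileext = ".nii.gz")
  writeVolume(m, f2)
  back2 <- readLevelMap(f2, 5)
  expect_identical(levelLabels(back2), levelLabels(m))
})
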