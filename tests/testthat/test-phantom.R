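test_that("phantom generation is deterministic and anatomically nested", {
  a <- generatePhantom(testPhantomSpec(seed = 1L))
  b <- generatePhantom(testPhantomSpec(seed = 1L))
  expect_identical(voxelValues(a$dose), voxelValues(b$dose))
  expect_identical(a$structures@masks, b$structures@masks)
  c2 <- generatePhantom(testPhantomSpec(seed = 2L))
  expect_false(identical(voxelValues(a$dose), voxelValues(c2$dose)))

  s <- a$structures
  gtv <- structureMask(s, "GTV"); ctv <- structureMask(s, "CTV")
  ptv <- structureMask(s, "PTV"); breast <- structureMask(s, "breast")
  body <- structureMask(s, "body")
  expect_true(all(ctv[gtv]))           # GTV inside CTV
  expect_true(all(ptv[ctv]))           # CTV inside PTV
  expect_true(all(breast[ptv]))        # PTV inside breast
  expect_true(all(body[breast]))       # breast inside body
  expect_gt(sum(gtv), 0)
  for (r in c("heart", "ribs", "skin"))
    expect_gt(sum(structureMask(s, r)), 0)
})

test_that("phantom dose honors the prescription and the hotspot screen", {
  ph <- generatePhantom(testPhantomSpec(seed = 3L))
  d95 <- dvhMetric(ph$dose, structureMask(ph$structures, "CTV"), 95)
  expect_lt(abs(d95 - ctvRx(ph$rx)) / ctvRx(ph$rx), 0.01)
  expect_true(qcScreenCase(ph$dose, ph$structures, ph$rx)$pass)
  ## dose to the heart is a small fraction of the prescription
  heartMax <- max(voxelValues(ph$dose)[structureMask(ph$structures, "heart")])
  expect_lt(heartMax, 0.1 * ctvRx(ph$rx))
  ## spec invariants are validated up front
  expect_error(PhantomSpec(gtvRadiusMm = 30, breastRadiusMm = 35), "nest")
  expect_error(PhantomSpec(hotspotFraction = 0.05), "hotspot")
})

test_that("identity predictor keeps levels, DSC and quantization bounds ideal", {
  ph <- generatePhantom(testPhantomSpec(seed = 1L))
  rel <- normalizeDose(ph$dose, ph$rx)
  for (i in c(2, 5)) {
    gt <- discretizeDose(rel, i)
    pred <- mockPredictorOracle(gt)
    expect_identical(levelLabels(pred), levelLabels(gt))
    for (t in c(1L, numLevels(gt) %/% 2L, numLevels(gt)))
      expect_equal(cumulativeIsodoseDsc(gt, pred, t), 1)
    ## unsmoothed reconstruction stays within the quantization bound,
    ## hence so does MAPE in every ROI
    recon <- levelsToRelativeDose(pred)
    reconGy <- ScalarVolume(doseGrid(recon),
                            voxelValues(recon) * ctvRx(ph$rx) / 100, "Gy")
    for (r in c("GTV", "CTV", "PTV", "heart", "skin")) {
      mape <- voxelMape(reconGy, ph$dose, structureMask(ph$structures, r),
                       ph$rx)
      expect_lte(mape, i / 2)
    }
  }
})

test_that("coarser intervals never reduce round-trip MAPE", {
  ph <- generatePhantom(testPhantomSpec(seed = 5L))
  rel <- normalizeDose(ph$dose, ph$rx)
  body <- structureMask(ph$structures, "body")
  mapeAt <- function(i) {
    recon <- levelsToRelativeDose(discretizeDose(rel, i))
    reconGy <- ScalarVolume(doseGrid(recon),
                            voxelValues(recon) * ctvRx(ph$rx) / 100, "Gy")
    voxelMape(reconGy, ph$dose, body, ph$rx)
  }
  expect_lte(mapeAt(2), mapeAt(5))
})

test_that("boundary perturbation is seeded, boundary-limited and label-safe", {
  ph <- generatePhantom(testPhantomSpec(seed = 1L))
  gt <- discretizeDose(normalizeDose(ph$dose, ph$rx), 5)
  expect_identical(levelLabels(mockPredictorPerturbed(gt, 0, seed = 1L)),
                   levelLabels(gt))
  p1 <- mockPredictorPerturbed(gt, 0.5, seed = 7L)
  p2 <- mockPredictorPerturbed(gt, 0.5, seed = 7L)
  expect_identical(levelLabels(p1), levelLabels(p2))
  expect_false(identical(levelLabels(p1), levelLabels(gt)))
  expect_true(all(levelLabels(p1) >= 0L & levelLabels(p1) <= numLevels(gt)))
  ## only voxels adjacent to a level boundary may change
  lab <- levelLabels(gt)
  n <- dim(lab)
  changed <- which(levelLabels(p1) != lab, arr.ind = TRUE)
  for (q in seq_len(min(nrow(changed), 200))) {
    v <- changed[q, ]
    nb <- c()
    for (ax in 1:3) for (dd in c(-1L, 1L)) {
      w <- v; w[ax] <- w[ax] + dd
      if (all(w >= 1L) && all(w <= n))
        nb <- c(nb, lab[w[1], w[2], w[3]])
    }
    expect_true(any(nb != lab[v[1], v[2], v[3]]))
    ## new label comes from a differing neighbor
    expect_true(levelLabels(p1)[v[1], v[2], v[3]] %in%
                  nb[nb != lab[v[1], v[2], v[3]]])
  }
})

test_that("full flips on a two-level half-space match hand enumeration", {
  g <- Grid3D(c(4L, 4L, 4L))
  lab <- array(0L, c(4, 4, 4)); lab[3:4, , ] <- 1L
  m <- DoseLevelMap(g, lab, 5)
  flipped <- levelLabels(mockPredictorPerturbed(m, 1, seed = 1L))
  ## boundary voxels are exactly planes x = 2 and x = 3; with prob 1 every
  ## one flips to the only differing neighboring level
  expected <- lab
  expected[2, , ] <- 1L
  expected[3, , ] <- 0L
  expect_identical(flipped, expected)
  ## DSC of level-1 volume computable by hand: A = 32, B = 32, overlap 16
  expect_equal(cumulativeIsodoseDsc(m, mockPredictorPerturbed(m, 1, 1L), 1),
               2 * 16 / (32 + 32))
})

test_that("mean cumulative DSC degrades monotonically with flip probability", {
  ph <- generatePhantom(testPhantomSpec(seed = 6L))
  gt <- discretizeDose(normalizeDose(ph$dose, ph$rx), 5)
  meanDsc <- function(prob) {
    mean(vapply(1:20, function(s) {
      pred <- mockPredictorPerturbed(gt, prob, seed = s)
      mean(vapply(seq_len(numLevels(gt)), function(t)
        cumulativeIsodoseDsc(gt, pred, t), 0))
    }, 0))
  }
  d0 <- meanDsc(0); dHalf <- meanDsc(0.5); d1 <- meanDsc(1)
  expect_equal(d0, 1)
  expect_gt(d0, dHalf)
  expect_gt(dHalf, d1)
})
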