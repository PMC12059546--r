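test_that("Dice coefficient matches its set-overlap definition", {
  m <- function(v) array(v, c(length(v), 1, 1))
  a <- m(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
  b <- m(c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(diceCoefficient(a, b), 2 * 3 / (4 + 6))  # 0.6 worked example
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(a, m(rep(FALSE, 10))), 0)
  expect_equal(diceCoefficient(m(rep(FALSE, 10)), m(rep(FALSE, 10))), 1)
  expect_equal(diceCoefficient(a, b), diceCoefficient(b, a))  # symmetry
  expect_error(diceCoefficient(a, array(TRUE, c(2, 2, 2))), "geometry")
})

test_that("cumulative isodose DSC equals a per-voxel set-membership scan", {
  set.seed(5)
  g <- Grid3D(c(8L, 8L, 8L))
  gt <- DoseLevelMap(g, array(sample(0:24, 8^3, TRUE), c(8, 8, 8)), 5)
  pred <- DoseLevelMap(g, array(sample(0:24, 8^3, TRUE), c(8, 8, 8)), 5)
  for (t in 1:24) {
    A <- levelLabels(gt) %in% 1:t
    B <- levelLabels(pred) %in% 1:t
    inter <- sum(A & B)
    expected <- if (sum(A) + sum(B) == 0) 1 else 2 * inter / (sum(A) + sum(B))
    expect_equal(cumulativeIsodoseDsc(gt, pred, t), expected)
  }
  expect_equal(cumulativeIsodoseDsc(gt, gt, 7), 1)
  zero <- DoseLevelMap(g, array(0L, c(8, 8, 8)), 5)
  expect_equal(cumulativeIsodoseDsc(gt, zero, 24), 0)
  other <- DoseLevelMap(g, levelLabels(pred), 2)
  expect_error(cumulativeIsodoseDsc(gt, other, 1), "interval")
})

test_that("voxel MAPE follows the prescription-normalized error formula", {
  g <- Grid3D(c(2L, 1L, 1L))
  roi <- array(TRUE, c(2, 1, 1))
  gt <- ScalarVolume(g, array(c(8, 4), c(2, 1, 1)), "Gy")
  pred <- ScalarVolume(g, array(c(7.6, 4.4), c(2, 1, 1)), "Gy")
  expect_equal(voxelMape(pred, gt, roi, Prescription(8)), 5)
  expect_equal(voxelMape(gt, gt, roi, Prescription(8)), 0)
  ## constant offset of 1% of the prescription
  shifted <- ScalarVolume(g, voxelValues(gt) + 0.08, "Gy")
  expect_equal(voxelMape(shifted, gt, roi, Prescription(8)), 1)
  ## scales inversely with the prescription dose
  expect_equal(voxelMape(pred, gt, roi, Prescription(4)),
               2 * voxelMape(pred, gt, roi, Prescription(8)))
  expect_error(voxelMape(pred, gt, array(FALSE, c(2, 1, 1)),
                         Prescription(8)), "empty")
})

test_that("Dx% uses the descending-rank convention", {
  g <- Grid3D(c(100L, 1L, 1L))
  roi <- array(TRUE, c(100, 1, 1))
  d <- ScalarVolume(g, array(sample(1:100), c(100, 1, 1)), "Gy")
  ## brute-force sort-and-count oracle at several x
  for (x in c(2, 5, 50, 95)) {
    sorted <- sort(voxelValues(d)[roi], decreasing = TRUE)
    expect_equal(dvhMetric(d, roi, x), sorted[ceiling(x / 100 * 100)])
  }
  expect_equal(dvhMetric(d, roi, 5), 96)
  ## the returned dose is received by at least x% of the ROI
  for (x in c(5, 33, 95)) {
    v <- dvhMetric(d, roi, x)
    expect_gte(mean(voxelValues(d)[roi] >= v), x / 100)
  }
  ## uniform ROI and monotonicity in x
  u <- ScalarVolume(g, array(8, c(100, 1, 1)), "Gy")
  expect_equal(dvhMetric(u, roi, 37), 8)
  dx <- vapply(c(2, 5, 50, 95), function(x) dvhMetric(d, roi, x), 0)
  expect_true(all(diff(dx) <= 0))
})

test_that("paired DVH comparison runs a signed-rank test with sane edge cases", {
  set.seed(9)
  gt <- rnorm(20, 8, 0.3)
  same <- compareDvhMetrics(gt, gt, drpGy = 8)
  expect_false(same$significant)
  expect_equal(same$mape, 0)
  expect_equal(same$pValue, 1)

  shifted <- compareDvhMetrics(gt + 0.5, gt, drpGy = 8)
  expect_false(shifted$skipped)
  expect_lt(shifted$pValue, 0.05)
  expect_true(shifted$significant)
  expect_equal(shifted$mape, 100 * 0.5 / 8)

  ## distinct all-positive differences: exact one-signed rank distribution
  ## gives the extreme two-sided p of 2 / 2^n
  jit <- gt + seq(0.3, 0.8, length.out = 20)
  expect_equal(compareDvhMetrics(jit, gt, drpGy = 8)$pValue, 2 / 2^20)

  expect_true(compareDvhMetrics(c(1, 2, 3), c(1, 2, 3), 8)$skipped)
  ## mixed per-case prescriptions normalize case by case
  mx <- compareDvhMetrics(c(8.4, 7.35), c(8, 7), drpGy = c(8, 7))
  expect_equal(mx$mape, 100 * mean(c(0.4 / 8, 0.35 / 7)))
})

test_that("gamma is exact on identical and uniformly offset fields", {
  g <- Grid3D(c(6L, 6L, 6L))
  ref <- ScalarVolume(g, array(8, c(6, 6, 6)), "Gy")
  same <- gammaPassingRate(ref, ref, GammaCriteria(3, 2), Prescription(8))
  expect_equal(same$gpr, 100)
  expect_true(all(voxelValues(same$gamma) == 0))

  ## flat fields: the spatial search cannot reduce the dose term
  off2 <- ScalarVolume(g, array(8 * 1.02, c(6, 6, 6)), "Gy")
  r2 <- gammaPassingRate(ref, off2, GammaCriteria(3, 2), Prescription(8))
  expect_equal(r2$gpr, 100)
  expect_equal(min(voxelValues(r2$gamma)), 2 / 3, tolerance = 1e-12)
  expect_equal(max(voxelValues(r2$gamma)), 2 / 3, tolerance = 1e-12)

  off4 <- ScalarVolume(g, array(8 * 1.04, c(6, 6, 6)), "Gy")
  r4 <- gammaPassingRate(ref, off4, GammaCriteria(3, 2), Prescription(8))
  expect_equal(r4$gpr, 0)
  expect_equal(min(voxelValues(r4$gamma)), 4 / 3, tolerance = 1e-12)
})

test_that("gamma engine equals the exhaustive brute-force search", {
  for (seed in 1:3) {
    ref <- smoothRandomDose(12, spacing = 2, rxGy = 8, seed = seed)
    ev <- ref * (1 + 0.015 * sin(seed + ref)) +
      0.05 * smoothRandomDose(12, spacing = 2, rxGy = 1, seed = seed + 50)
    g <- Grid3D(c(12L, 12L, 12L))
    crit <- GammaCriteria(3, 2, searchRadiusFactor = 1.5)
    got <- gammaPassingRate(ScalarVolume(g, ref, "Gy"),
                            ScalarVolume(g, ev, "Gy"), crit,
                            Prescription(8))
    oracle <- oracleGamma(ref, ev, c(2, 2, 2), doseTol = 0.03 * 8,
                          dta = 2, step = 0.2, factor = 1.5)
    expect_lt(max(abs(voxelValues(got$gamma) - oracle)), 1e-9)
  }
})

test_that("looser distance criteria never lower the passing rate", {
  ph <- generatePhantom(testPhantomSpec(seed = 2L))
  rel <- normalizeDose(ph$dose, ph$rx)
  pred <- mockPredictorPerturbed(discretizeDose(rel, 5), 0.4, seed = 3L)
  sm <- smoothPrediction(pred, ph$rx)
  g32 <- gammaPassingRate(ph$dose, sm, GammaCriteria(3, 2), ph$rx)$gpr
  g31 <- gammaPassingRate(ph$dose, sm, GammaCriteria(3, 1), ph$rx)$gpr
  expect_gte(g32, g31)
  expect_true(g31 >= 0 && g32 <= 100)
})

test_that("low-dose cutoff restricts the analyzed region", {
  g <- Grid3D(c(6L, 6L, 6L))
  vals <- array(0.1, c(6, 6, 6)); vals[3:4, 3:4, 3:4] <- 8
  ref <- ScalarVolume(g, vals, "Gy")
  crit <- GammaCriteria(3, 2, lowDoseCutoffPercent = 10)
  r <- gammaPassingRate(ref, ref, crit, Prescription(8))
  expect_equal(r$nAnalyzed, 8)
  expect_true(all(is.na(voxelValues(r$gamma)[vals < 0.8])))
  crit99 <- GammaCriteria(3, 2, lowDoseCutoffPercent = 99.9)
  zero <- ScalarVolume(g, array(0, c(6, 6, 6)), "Gy")
  expect_error(gammaPassingRate(zero, zero, crit99, Prescription(8)),
               "cutoff")
})

test_that("evaluatePlan assembles a consistent report", {
  ph <- generatePhantom(testPhantomSpec(seed = 4L))
  rel <- normalizeDose(ph$dose, ph$rx)
  gtLevels <- discretizeDose(rel, 5)
  sm <- smoothPrediction(gtLevels, ph$rx)
  rep <- evaluatePlan(sm, ph$dose, gtLevels, gtLevels, ph$structures,
                      ph$rx, rois = c("CTV", "PTV", "heart"),
                      gammaCriteria = list(GammaCriteria(3, 2)))
  expect_s4_class(rep, "EvalReport")
  expect_named(rep@roiMape, c("CTV", "PTV", "heart"))
  expect_true(all(rep@cumulativeDsc == 1))   # identity prediction levels
  expect_equal(nrow(rep@dvh), 3 * 4)
  expect_true(all(rep@gpr$gpr >= 0 & rep@gpr$gpr <= 100))
})
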