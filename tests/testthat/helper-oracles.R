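## Independent reference implementations used as oracles, plus small
## fixture builders. These deliberately re-derive results from first
## principles (pointwise loops, exhaustive enumeration) rather than
## calling the package's vectorized/compiled code paths.

## Pointwise trilinear interpolation of arr at one continuous 0-based
## index, clamping the upper cell edge.
oracleTrilinearOne <- function(arr, cx, cy, cz) {
  n <- dim(arr)
  x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  x1 <- min(x0 + 1, n[1] - 1); y1 <- min(y0 + 1, n[2] - 1)
  z1 <- min(z0 + 1, n[3] - 1)
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wx <- if (dx == 0) 1 - fx else fx
    wy <- if (dy == 0) 1 - fy else fy
    wz <- if (dz == 0) 1 - fz else fz
    ix <- if (dx == 0) x0 else x1
    iy <- if (dy == 0) y0 else y1
    iz <- if (dz == 0) z0 else z1
    acc <- acc + wx * wy * wz * arr[ix + 1, iy + 1, iz + 1]
  }
  acc
}

## Exhaustive gamma index: for every reference voxel, minimize over every
## sub-grid offset within the search radius with no early exit. The
## interpolation is vectorized over offsets but written independently of
## the package's samplers.
oracleGamma <- function(refArr, evArr, spacing, doseTol, dta, step,
                        factor) {
  n <- dim(refArr)
  R <- factor * dta
  m <- floor(R / step + 1e-9)
  ax <- (-m):m * step
  offs <- as.matrix(expand.grid(ax, ax, ax))
  r2 <- rowSums(offs^2)
  keep <- r2 <= R^2 + 1e-9
  offs <- offs[keep, , drop = FALSE]
  distTerm <- r2[keep] / dta^2
  interp <- function(cx, cy, cz) {
    x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
    fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
    x1 <- pmin(x0 + 1, n[1] - 1); y1 <- pmin(y0 + 1, n[2] - 1)
    z1 <- pmin(z0 + 1, n[3] - 1)
    at <- function(a, b, c) evArr[1 + a + n[1] * (b + n[2] * c)]
    (1 - fx) * (1 - fy) * (1 - fz) * at(x0, y0, z0) +
      fx * (1 - fy) * (1 - fz) * at(x1, y0, z0) +
      (1 - fx) * fy * (1 - fz) * at(x0, y1, z0) +
      fx * fy * (1 - fz) * at(x1, y1, z0) +
      (1 - fx) * (1 - fy) * fz * at(x0, y0, z1) +
      fx * (1 - fy) * fz * at(x1, y0, z1) +
      (1 - fx) * fy * fz * at(x0, y1, z1) +
      fx * fy * fz * at(x1, y1, z1)
  }
  gam <- array(NA_real_, n)
  for (k in seq_len(n[3])) for (j in seq_len(n[2])) for (i in seq_len(n[1])) {
    cx <- ((i - 1) * spacing[1] + offs[, 1]) / spacing[1]
    cy <- ((j - 1) * spacing[2] + offs[, 2]) / spacing[2]
    cz <- ((k - 1) * spacing[3] + offs[, 3]) / spacing[3]
    ok <- cx >= 0 & cx <= n[1] - 1 & cy >= 0 & cy <= n[2] - 1 &
      cz >= 0 & cz <= n[3] - 1
    dd <- (interp(cx[ok], cy[ok], cz[ok]) - refArr[i, j, k]) / doseTol
    gam[i, j, k] <- sqrt(min(dd^2 + distTerm[ok]))
  }
  gam
}

## Smooth random dose field in Gy on an isotropic grid: low-frequency
## cosine mixture, positive, peaking near the prescription.
smoothRandomDose <- function(n, spacing = 2, rxGy = 8, seed = 1) {
  set.seed(seed)
  ax <- (seq_len(n) - 1) * spacing
  f <- array(0, c(n, n, n))
  for (q in 1:4) {
    kv <- runif(3, 0.02, 0.12)
    ph <- runif(3, 0, 2 * pi)
    amp <- runif(1, 0.2, 1)
    f <- f + amp * outer(outer(cos(kv[1] * ax + ph[1]),
                               cos(kv[2] * ax + ph[2])),
                         cos(kv[3] * ax + ph[3]))
  }
  f <- f - min(f)
  f <- f / max(f) * rxGy
  f
}

## Small structure-set fixture: nested cubic CTV/PTV inside a body box.
nestedTargetsFixture <- function(n = 12L, spacing = 2) {
  g <- Grid3D(c(n, n, n), spacingMm = spacing)
  idx <- function(lo, hi) {
    m <- array(FALSE, c(n, n, n)); m[lo:hi, lo:hi, lo:hi] <- TRUE; m
  }
  body <- idx(2L, n - 1L)
  breast <- idx(3L, n - 2L)
  ptv <- idx(5L, 8L)
  ctv <- idx(6L, 7L)
  gtv <- idx(6L, 6L)
  heart <- idx(2L, 3L)
  skin <- breast & !idx(4L, n - 3L)
  ribs <- idx(2L, 2L)
  list(grid = g,
       structures = StructureSet(g, list(
         GTV = gtv, CTV = ctv, PTV = ptv, breast = breast, heart = heart,
         ribs = ribs, skin = skin, body = body)))
}

## Small, fast phantom used across tests: 48^3 at 2 mm with a compact
## target and the heart pushed well beyond the dose falloff.
testPhantomSpec <- function(seed = 1L, gridSize = 48L, breastRadiusMm = 34,
                            gtvRadiusMm = 6, ctvMarginMm = 3,
                            ptvMarginMm = 3, heartOffsetMm = c(0, 0, -6),
                            ...) {
  PhantomSpec(gridSize = gridSize, breastRadiusMm = breastRadiusMm,
              gtvRadiusMm = gtvRadiusMm, ctvMarginMm = ctvMarginMm,
              ptvMarginMm = ptvMarginMm, heartOffsetMm = heartOffsetMm,
              seed = seed, ...)
}
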