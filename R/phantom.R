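#' @include AllClasses.R smoother.R adapter.R evaluation.R
NULL

## Run `expr` with a private RNG stream seeded by `seed`, restoring the
## caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Synthetic prone-breast phantom specification
#'
#' Geometry and dosimetry parameters of the synthetic stereotactic
#' prone-breast case generator: a hemispherical breast on a chest-wall
#' slab, nested spherical GTV/CTV/PTV targets, a skin shell, a rib shell
#' at the chest wall and a heart ellipsoid beyond the ribs, with an
#' analytic plateau-plus-Gaussian-falloff dose calibrated so D95\% of the
#' CTV equals the prescription. Defaults emulate the clinical
#' preprocessing grid: 128 voxels at 2 mm isotropic spacing with an
#' 8 Gy-per-fraction CTV / 6 Gy PTV prescription.
#'
#' @slot gridSize Voxels per axis (default 128).
#' @slot spacingMm Isotropic spacing (default 2).
#' @slot gtvRadiusMm GTV sphere radius (default 10).
#' @slot ctvMarginMm GTV-to-CTV margin (default 5).
#' @slot ptvMarginMm CTV-to-PTV margin (default 3).
#' @slot breastRadiusMm Breast hemisphere radius (default 60).
#' @slot skinThicknessMm Skin shell thickness (default 3).
#' @slot ribShellDepthMm Rib shell depth behind the chest wall (default 8).
#' @slot heartOffsetMm Displacement of the heart from its default position.
#' @slot rx The \linkS4class{Prescription}.
#' @slot falloffMm Gaussian length scale of the dose falloff outside the
#'   PTV (default 8).
#' @slot hotspotFraction Fractional target hotspot amplitude in [0, 0.02)
#'   (default 0.01); the generated maximum never exceeds 102\% of the
#'   prescription, so every phantom passes \code{\link{qcScreenCase}}.
#' @slot seed Integer RNG seed; generation is bit-reproducible per seed.
#' @export
setClass("PhantomSpec",
  representation(gridSize = "integer", spacingMm = "numeric",
                 gtvRadiusMm = "numeric", ctvMarginMm = "numeric",
                 ptvMarginMm = "numeric", breastRadiusMm = "numeric",
                 skinThicknessMm = "numeric", ribShellDepthMm = "numeric",
                 heartOffsetMm = "numeric", rx = "Prescription",
                 falloffMm = "numeric", hotspotFraction = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  rGtv <- object@gtvRadiusMm
  rCtv <- rGtv + object@ctvMarginMm
  rPtv <- rCtv + object@ptvMarginMm
  if (rGtv <= 0 || object@ctvMarginMm <= 0 || object@ptvMarginMm <= 0)
    msg <- c(msg, "target radius and margins must be positive")
  ## target center sits max(0.45 R, rPtv + spacing) above the chest wall;
  ## the whole PTV must stay inside the breast and clear of the skin shell
  offset <- max(0.45 * object@breastRadiusMm, rPtv + object@spacingMm)
  if (rPtv >= object@breastRadiusMm - object@skinThicknessMm ||
      offset + rPtv > object@breastRadiusMm)
    msg <- c(msg, "targets must nest strictly inside the breast: ",
             "gtv < ctv < ptv < breast")
  if (object@hotspotFraction < 0 || object@hotspotFraction >= 0.02)
    msg <- c(msg, "hotspotFraction must lie in [0, 0.02)")
  if (object@falloffMm <= 0) msg <- c(msg, "falloffMm must be positive")
  if (object@gridSize < 16L) msg <- c(msg, "gridSize must be >= 16")
  ext <- (object@gridSize - 1) * object@spacingMm
  if (2 * object@breastRadiusMm > ext)
    msg <- c(msg, "breast does not fit inside the grid extent")
  if (length(msg)) paste(msg, collapse = "") else TRUE
})

#' @param gridSize,spacingMm,gtvRadiusMm,ctvMarginMm,ptvMarginMm Geometry.
#' @param breastRadiusMm,skinThicknessMm,ribShellDepthMm,heartOffsetMm OARs.
#' @param rx Prescription (default 8 Gy CTV / 6 Gy PTV per fraction).
#' @param falloffMm,hotspotFraction Dose model parameters.
#' @param seed Integer seed.
#' @return A \code{PhantomSpec}.
#' @rdname PhantomSpec-class
#' @export
PhantomSpec <- function(gridSize = 128L, spacingMm = 2,
                        gtvRadiusMm = 10, ctvMarginMm = 5, ptvMarginMm = 3,
                        breastRadiusMm = 60, skinThicknessMm = 3,
                        ribShellDepthMm = 8, heartOffsetMm = c(0, 0, 0),
                        rx = Prescription(8, 6), falloffMm = 8,
                        hotspotFraction = 0.01, seed = 1L) {
  new("PhantomSpec", gridSize = as.integer(gridSize),
      spacingMm = as.numeric(spacingMm), gtvRadiusMm = gtvRadiusMm,
      ctvMarginMm = ctvMarginMm, ptvMarginMm = ptvMarginMm,
      breastRadiusMm = breastRadiusMm, skinThicknessMm = skinThicknessMm,
      ribShellDepthMm = ribShellDepthMm,
      heartOffsetMm = as.numeric(rep_len(heartOffsetMm, 3L)), rx = rx,
      falloffMm = falloffMm, hotspotFraction = hotspotFraction,
      seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec: ", object@gridSize, "^3 @ ", object@spacingMm,
      " mm, GTV/CTV/PTV radii ", object@gtvRadiusMm, "/",
      object@gtvRadiusMm + object@ctvMarginMm, "/",
      object@gtvRadiusMm + object@ctvMarginMm + object@ptvMarginMm,
      " mm, breast ", object@breastRadiusMm, " mm, Rx ",
      object@rx@ctvRxGy, " Gy, falloff ", object@falloffMm,
      " mm, seed ", object@seed, "\n", sep = "")
})

#' Generate a synthetic prone-breast case
#'
#' Builds the structure set and an analytic dose distribution described by
#' a \linkS4class{PhantomSpec}. The dose is a flat plateau inside the PTV
#' with Gaussian radial falloff of scale \code{falloffMm} outside,
#' modulated by a smooth seeded noise field (0.3\% amplitude) and an
#' optional GTV hotspot, then rescaled so D95\% of the CTV equals the CTV
#' prescription (and capped at 102\% of it, the hotspot screening limit).
#' Identical seeds give bit-identical output.
#'
#' @param spec A \linkS4class{PhantomSpec}.
#' @return A list: \code{structures} (\linkS4class{StructureSet}),
#'   \code{dose} (\linkS4class{ScalarVolume}, Gy), \code{rx}
#'   (\linkS4class{Prescription}), \code{spec}.
#' @examples
#' ph <- generatePhantom(PhantomSpec(gridSize = 48L, breastRadiusMm = 34,
#'                                   gtvRadiusMm = 6, ctvMarginMm = 3,
#'                                   ptvMarginMm = 3,
#'                                   heartOffsetMm = c(0, 0, -6)))
#' dvhMetric(ph$dose, structureMask(ph$structures, "CTV"), 95)  # ~8 Gy
#' @export
generatePhantom <- function(spec = PhantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  n <- spec@gridSize
  sMm <- spec@spacingMm
  grid <- Grid3D(c(n, n, n), spacingMm = sMm)
  ext <- (n - 1) * sMm
  ax <- (seq_len(n) - 1) * sMm
  X <- array(rep(ax, times = n * n), dim = c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), dim = c(n, n, n))
  Z <- array(rep(ax, each = n * n), dim = c(n, n, n))

  Rb <- spec@breastRadiusMm
  zWall <- max(0.30 * ext, ext / 2 - Rb)  # chest-wall plane
  bc <- c(ext / 2, ext / 2, zWall)        # breast center on the wall
  distB <- sqrt((X - bc[1])^2 + (Y - bc[2])^2 + (Z - bc[3])^2)
  breast <- distB <= Rb & Z >= zWall
  slabTh <- min(60, zWall)
  slab <- Z < zWall & Z >= zWall - slabTh
  body <- breast | slab
  skin <- breast & distB >= Rb - spec@skinThicknessMm
  ribs <- slab & Z >= zWall - spec@ribShellDepthMm &
    sqrt((X - bc[1])^2 + (Y - bc[2])^2) <= Rb + 10
  hc <- bc + c(0, 0, -(spec@ribShellDepthMm + 25)) + spec@heartOffsetMm
  heart <- ((X - hc[1]) / 25)^2 + ((Y - hc[2]) / 25)^2 +
    ((Z - hc[3]) / 20)^2 <= 1
  heart <- heart & slab

  rPtvSpec <- spec@gtvRadiusMm + spec@ctvMarginMm + spec@ptvMarginMm
  gc <- bc + c(0, 0, max(0.45 * Rb, rPtvSpec + sMm))  # target center clears the wall
  distT <- sqrt((X - gc[1])^2 + (Y - gc[2])^2 + (Z - gc[3])^2)
  rGtv <- spec@gtvRadiusMm
  rCtv <- rGtv + spec@ctvMarginMm
  rPtv <- rCtv + spec@ptvMarginMm
  gtv <- distT <= rGtv
  ctv <- distT <= rCtv
  ptv <- distT <= rPtv

  structures <- new("StructureSet", grid = grid,
                    masks = list(GTV = gtv, CTV = ctv, PTV = ptv,
                                 breast = breast, heart = heart,
                                 ribs = ribs, skin = skin, body = body))

  ## Analytic dose: plateau inside the PTV, Gaussian falloff outside,
  ## small GTV hotspot, smooth multiplicative noise, then D95(CTV)
  ## calibration.
  outside <- pmax(distT - rPtv, 0)
  u <- exp(-outside^2 / (2 * spec@falloffMm^2))
  if (spec@hotspotFraction > 0)
    u <- u + spec@hotspotFraction * exp(-distT^2 / (2 * (rGtv / 2)^2))
  noise <- .withSeed(spec@seed, array(stats::rnorm(n^3), dim = c(n, n, n)))
  noise <- gaussianSmooth(ScalarVolume(grid, noise, "weight"),
                          SmootherConfig(sigmaMm = 3 * sMm))@values
  noise <- 0.003 * noise / max(abs(noise))
  u <- u * (1 + noise)
  u95 <- {
    v <- sort(u[ctv], decreasing = TRUE)
    v[ceiling(0.95 * length(v))]
  }
  rxGy <- spec@rx@ctvRxGy
  dose <- pmin(u * rxGy / u95, 1.02 * rxGy)
  list(structures = structures,
       dose = ScalarVolume(grid, array(dose, dim = c(n, n, n)), "Gy"),
       rx = spec@rx, spec = spec)
}

#' Identity predictor (oracle)
#'
#' Stand-in for a perfectly trained segmentation backend: returns the
#' ground-truth dose-level map unchanged, so every downstream metric can
#' be checked at its ideal value (cumulative DSC 1, unsmoothed MAPE
#' bounded by the quantization error i / 2).
#'
#' @param gtLevels A \linkS4class{DoseLevelMap}.
#' @return The same \linkS4class{DoseLevelMap}.
#' @export
mockPredictorOracle <- function(gtLevels) {
  stopifnot(is(gtLevels, "DoseLevelMap"))
  gtLevels
}

#' Boundary-perturbing predictor
#'
#' Controlled degradation of a dose-level map that emulates where
#' segmentation errors concentrate: voxels 6-adjacent to a level boundary
#' are reassigned, with the given probability, to the level of a randomly
#' chosen differing 6-neighbor. Labels stay within [0, T]; interior voxels
#' are untouched; output is deterministic per seed.
#'
#' @param gtLevels A \linkS4class{DoseLevelMap}.
#' @param boundaryFlipProb Flip probability in [0, 1].
#' @param seed Integer seed.
#' @return A perturbed \linkS4class{DoseLevelMap}.
#' @export
mockPredictorPerturbed <- function(gtLevels, boundaryFlipProb, seed = 1L) {
  stopifnot(is(gtLevels, "DoseLevelMap"))
  if (boundaryFlipProb < 0 || boundaryFlipProb > 1)
    stop("boundaryFlipProb must lie in [0, 1]", call. = FALSE)
  lab <- gtLevels@labels
  n <- dim(lab)
  if (boundaryFlipProb == 0) return(gtLevels)

  ## neighbor label stacks along each of the 6 directions (edge voxels
  ## replicate themselves, so they never count as boundary against the
  ## outside)
  shift <- function(a, axis, by) {
    idx <- seq_len(n[axis]) + by
    idx <- pmin(pmax(idx, 1L), n[axis])
    switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  neigh <- list(shift(lab, 1L, -1L), shift(lab, 1L, 1L),
                shift(lab, 2L, -1L), shift(lab, 2L, 1L),
                shift(lab, 3L, -1L), shift(lab, 3L, 1L))
  differs <- array(FALSE, dim = n)
  for (nb in neigh) differs <- differs | nb != lab
  boundary <- which(differs)
  if (!length(boundary)) return(gtLevels)

  out <- lab
  .withSeed(seed, {
    flip <- boundary[stats::runif(length(boundary)) < boundaryFlipProb]
    if (length(flip)) {
      cand <- vapply(neigh, function(nb) nb[flip], integer(length(flip)))
      if (is.null(dim(cand))) dim(cand) <- c(length(flip), 6L)
      pick <- vapply(seq_along(flip), function(r) {
        opts <- cand[r, ][cand[r, ] != lab[flip[r]]]
        opts[sample.int(length(opts), 1L)]
      }, integer(1))
      out[flip] <- pick
    }
  })
  DoseLevelMap(gtLevels@grid, out, gtLevels@intervalPercent)
}
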