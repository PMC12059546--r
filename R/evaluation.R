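#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Gamma criteria
## ---------------------------------------------------------------------------

#' Gamma-index acceptance criteria
#'
#' Dose-difference / distance-to-agreement criteria for the global gamma
#' index, e.g. 3\%/2 mm and 3\%/1 mm. The dose-difference tolerance is a
#' percentage of a single normalization dose (global gamma): the CTV
#' prescription by default, or the reference maximum. The spatial search
#' runs on a sub-voxel grid of step \code{searchStepMm} (default dta / 10,
#' needed because a 1 mm DTA is finer than the 2 mm voxels) out to a fixed
#' radius of \code{searchRadiusFactor} times the DTA; gamma values beyond
#' that factor are reported at the truncated search minimum, which still
#' exceeds 1, so the passing rate is unaffected.
#'
#' @slot doseDiffPercent Dose-difference criterion in percent (> 0).
#' @slot dtaMm Distance-to-agreement in mm (> 0).
#' @slot normalization \code{"prescription"} or \code{"global_max"}.
#' @slot lowDoseCutoffPercent Reference voxels below this percent of the
#'   normalization dose are excluded from analysis (default 0: all voxels
#'   analyzed, full-volume gamma).
#' @slot searchStepMm Sub-grid step of the spatial search.
#' @slot searchRadiusFactor Search radius in units of the DTA (default 3).
#' @export
setClass("GammaCriteria",
  representation(doseDiffPercent = "numeric", dtaMm = "numeric",
                 normalization = "character",
                 lowDoseCutoffPercent = "numeric",
                 searchStepMm = "numeric", searchRadiusFactor = "numeric"))

setValidity("GammaCriteria", function(object) {
  msg <- character()
  if (object@doseDiffPercent <= 0) msg <- c(msg, "doseDiffPercent must be > 0")
  if (object@dtaMm <= 0) msg <- c(msg, "dtaMm must be > 0")
  if (!object@normalization %in% c("prescription", "global_max"))
    msg <- c(msg, "normalization must be 'prescription' or 'global_max'")
  if (object@lowDoseCutoffPercent < 0 || object@lowDoseCutoffPercent >= 100)
    msg <- c(msg, "lowDoseCutoffPercent must be in [0, 100)")
  if (object@searchStepMm <= 0 || object@searchStepMm > object@dtaMm)
    msg <- c(msg, "searchStepMm must be positive and <= dtaMm")
  if (object@searchRadiusFactor < 1)
    msg <- c(msg, "searchRadiusFactor must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param doseDiffPercent Dose-difference criterion (percent).
#' @param dtaMm Distance-to-agreement (mm).
#' @param normalization Global normalization mode.
#' @param lowDoseCutoffPercent Low-dose analysis cutoff (percent).
#' @param searchStepMm Search sub-grid step; default \code{dtaMm / 10}.
#' @param searchRadiusFactor Search radius in DTA units.
#' @return A \code{GammaCriteria} object.
#' @rdname GammaCriteria-class
#' @export
GammaCriteria <- function(doseDiffPercent = 3, dtaMm = 2,
                          normalization = c("prescription", "global_max"),
                          lowDoseCutoffPercent = 0,
                          searchStepMm = dtaMm / 10,
                          searchRadiusFactor = 3) {
  new("GammaCriteria", doseDiffPercent = doseDiffPercent, dtaMm = dtaMm,
      normalization = match.arg(normalization),
      lowDoseCutoffPercent = lowDoseCutoffPercent,
      searchStepMm = searchStepMm, searchRadiusFactor = searchRadiusFactor)
}

setMethod("show", "GammaCriteria", function(object) {
  cat("GammaCriteria: ", object@doseDiffPercent, "%/", object@dtaMm,
      " mm (", object@normalization, " normalization, cutoff ",
      object@lowDoseCutoffPercent, "%)\n", sep = "")
})

## ---------------------------------------------------------------------------
## Overlap and voxel-wise metrics
## ---------------------------------------------------------------------------

#' Dice similarity coefficient
#'
#' Overlap 2|A intersect B| / (|A| + |B|) between two binary masks on the
#' same grid. Two empty masks agree perfectly and return 1.
#'
#' @param a,b Logical 3D arrays of identical shape.
#' @return DSC in [0, 1].
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
#' b <- array(c(TRUE, FALSE, TRUE, FALSE), c(4, 1, 1))
#' diceCoefficient(a, b)  # 2*1 / (2+2) = 0.5
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("geometry error: masks have different shapes", call. = FALSE)
  a <- as.logical(a); b <- as.logical(b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Cumulative isodose-volume DSC
#'
#' DSC between the cumulative isodose volumes of a reference and a
#' predicted dose-level map: the voxels with label in 1..t, i.e. the
#' relative-dose band [i/2, (t + 1/2) i]. Evaluating the overlap
#' cumulatively from the first level up to each t summarizes how well the
#' predicted level structure tracks the reference across the dose range.
#'
#' @param gt,pred \linkS4class{DoseLevelMap}s on the same grid with the
#'   same interval.
#' @param t Level index in 1..T.
#' @return DSC in [0, 1].
#' @export
cumulativeIsodoseDsc <- function(gt, pred, t) {
  stopifnot(is(gt, "DoseLevelMap"), is(pred, "DoseLevelMap"))
  .stopIfGridMismatch(gt, pred, "dose-level maps")
  if (abs(gt@intervalPercent - pred@intervalPercent) > 1e-9)
    stop("dose-level maps have different intervals", call. = FALSE)
  t <- as.integer(t)
  if (t < 1L || t > gt@numLevels)
    stop("t must lie in 1..T", call. = FALSE)
  diceCoefficient(gt@labels >= 1L & gt@labels <= t,
                  pred@labels >= 1L & pred@labels <= t)
}

#' Voxel-wise mean absolute percent error within an ROI
#'
#' Mean over the ROI of |D - Dgt| normalized by the prescription dose,
#' expressed in percent: (100 / n) * sum |D_i - Dgt_i| / Drp.
#'
#' @param pred,gt \linkS4class{ScalarVolume}s in Gy on the same grid.
#' @param roi Nonempty logical mask.
#' @param rx A \linkS4class{Prescription}; its CTV dose is Drp.
#' @return MAPE in percent (>= 0).
#' @examples
#' g <- Grid3D(c(2L, 1L, 1L))
#' gt <- ScalarVolume(g, array(c(8, 4), c(2, 1, 1)), "Gy")
#' pr <- ScalarVolume(g, array(c(7.6, 4.4), c(2, 1, 1)), "Gy")
#' voxelMape(pr, gt, array(TRUE, c(2, 1, 1)), Prescription(8))  # 5
#' @export
voxelMape <- function(pred, gt, roi, rx) {
  stopifnot(is(pred, "ScalarVolume"), is(gt, "ScalarVolume"),
            is(rx, "Prescription"))
  .stopIfGridMismatch(pred, gt, "dose volumes")
  roi <- as.logical(roi)
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  100 * mean(abs(pred@values[roi] - gt@values[roi])) / rx@ctvRxGy
}

## ---------------------------------------------------------------------------
## DVH metrics
## ---------------------------------------------------------------------------

#' Dose-volume histogram metric Dx\%
#'
#' The minimum dose received by the hottest x\% of an ROI: sort the ROI
#' doses in descending order and take rank \code{ceiling(x/100 * n)} (no
#' interpolation), which guarantees at least x\% of the ROI receives at
#' least the returned dose. D95\% with x = 95 quantifies target coverage;
#' D2\% near-maximum dose quantifies OAR sparing.
#'
#' @param dose A \linkS4class{ScalarVolume} in Gy.
#' @param roi Nonempty logical mask.
#' @param x Volume percentage in (0, 100).
#' @return Dose in Gy.
#' @examples
#' g <- Grid3D(c(100L, 1L, 1L))
#' d <- ScalarVolume(g, array(1:100, c(100, 1, 1)), "Gy")
#' dvhMetric(d, array(TRUE, c(100, 1, 1)), 5)  # 96
#' @export
dvhMetric <- function(dose, roi, x) {
  stopifnot(is(dose, "ScalarVolume"))
  roi <- as.logical(roi)
  if (!any(roi)) stop("ROI is empty", call. = FALSE)
  if (x <= 0 || x >= 100) stop("x must lie in (0, 100)", call. = FALSE)
  v <- sort(dose@values[roi], decreasing = TRUE)
  v[ceiling(x / 100 * length(v))]
}

#' Paired comparison of a DVH metric across cases
#'
#' Compares one DVH metric between predicted and reference plans over a
#' cohort: a two-sided Wilcoxon signed-rank test on the paired values
#' (zero differences dropped; exact distribution when at most 25 nonzero
#' pairs remain, normal approximation with continuity correction above),
#' plus the across-case MAPE with each case normalized by its own
#' prescription. Fewer than 5 pairs is too small for the test and is
#' flagged as skipped.
#'
#' @param predValues,gtValues Equal-length numeric vectors, one value per
#'   case (Gy).
#' @param drpGy Prescription dose per case (scalar recycled).
#' @param alpha Significance level (default 0.05).
#' @return A list: \code{pValue}, \code{significant}, \code{skipped},
#'   \code{mape} (percent), \code{n}.
#' @export
compareDvhMetrics <- function(predValues, gtValues, drpGy, alpha = 0.05) {
  if (length(predValues) != length(gtValues))
    stop("paired samples must have equal length", call. = FALSE)
  n <- length(predValues)
  drpGy <- rep_len(drpGy, n)
  if (any(drpGy <= 0)) stop("prescription doses must be positive",
                            call. = FALSE)
  mape <- 100 * mean(abs(predValues - gtValues) / drpGy)
  if (n < 5L)
    return(list(pValue = NA_real_, significant = FALSE, skipped = TRUE,
                mape = mape, n = n))
  d <- predValues - gtValues
  dnz <- d[d != 0]
  if (length(dnz) == 0L)
    return(list(pValue = 1, significant = FALSE, skipped = FALSE,
                mape = mape, n = n))
  exact <- length(dnz) <= 25L
  p <- suppressWarnings(
    stats::wilcox.test(dnz, mu = 0, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
  list(pValue = p, significant = p < alpha, skipped = FALSE,
       mape = mape, n = n)
}

## ---------------------------------------------------------------------------
## Gamma index
## ---------------------------------------------------------------------------

## Spatial search offsets (mm) for the gamma sub-grid: all displacements on
## a cubic lattice of the given step within the search radius, ordered by
## distance so the evaluation loop can stop once the distance term alone
## exceeds the best gamma found. Row 1 is the zero offset.
.gammaOffsets <- function(stepMm, radiusMm) {
  m <- floor(radiusMm / stepMm + 1e-9)
  ax <- (-m):m * stepMm
  off <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  r2 <- rowSums(off^2)
  keep <- r2 <= radiusMm^2 + 1e-9
  off <- off[keep, , drop = FALSE]
  r2 <- r2[keep]
  ord <- order(r2)
  list(offsets = off[ord, , drop = FALSE], r2 = r2[ord])
}

#' Global gamma index and passing rate
#'
#' Voxel-wise agreement between a reference and an evaluated dose
#' distribution under combined dose-difference / distance-to-agreement
#' criteria. For every analyzed reference voxel the gamma index is the
#' minimum over evaluated positions within the search radius (the
#' evaluated dose trilinearly interpolated on a sub-grid of step
#' \code{searchStepMm}) of
#' \code{sqrt((doseDiff / (dd\% * Dnorm))^2 + (dist / dta)^2)}; the
#' passing rate is the percentage of analyzed voxels with gamma <= 1.
#' Normalization is global: Dnorm is the CTV prescription (default) or the
#' reference maximum. Search positions outside the evaluated volume are
#' skipped.
#'
#' @param reference,evaluated \linkS4class{ScalarVolume}s in Gy on the
#'   same grid.
#' @param criteria A \linkS4class{GammaCriteria}.
#' @param rx A \linkS4class{Prescription} (used when
#'   \code{normalization = "prescription"}).
#' @return A list: \code{gpr} (percent in [0, 100]), \code{gamma} (a
#'   dimensionless \linkS4class{ScalarVolume}; voxels excluded by the
#'   low-dose cutoff are NA), \code{nAnalyzed}.
#' @examples
#' g <- Grid3D(c(6L, 6L, 6L))
#' ref <- ScalarVolume(g, array(8, c(6, 6, 6)), "Gy")
#' ev  <- ScalarVolume(g, array(8 * 1.02, c(6, 6, 6)), "Gy")
#' gammaPassingRate(ref, ev, GammaCriteria(3, 2), Prescription(8))$gpr
#' @export
gammaPassingRate <- function(reference, evaluated,
                             criteria = GammaCriteria(), rx) {
  stopifnot(is(reference, "ScalarVolume"), is(evaluated, "ScalarVolume"),
            is(criteria, "GammaCriteria"))
  validObject(criteria)
  .stopIfGridMismatch(reference, evaluated, "dose volumes")
  sp <- reference@grid@spacingMm
  dnorm <- switch(criteria@normalization,
    prescription = {
      stopifnot(is(rx, "Prescription"))
      rx@ctvRxGy
    },
    global_max = max(reference@values))
  if (dnorm <= 0) stop("normalization dose must be positive", call. = FALSE)
  doseTol <- criteria@doseDiffPercent / 100 * dnorm
  analyze <- reference@values >= criteria@lowDoseCutoffPercent / 100 * dnorm
  if (!any(analyze))
    stop("all reference voxels fall below the low-dose cutoff",
         call. = FALSE)
  os <- .gammaOffsets(criteria@searchStepMm,
                      criteria@searchRadiusFactor * criteria@dtaMm)
  gam <- gamma_index_cpp(as.double(reference@values),
                         as.double(evaluated@values),
                         as.integer(reference@grid@shape),
                         as.double(sp),
                         os$offsets, os$r2 / criteria@dtaMm^2,
                         doseTol, as.logical(analyze))
  gam[!analyze] <- NA_real_
  gamVol <- ScalarVolume(reference@grid,
                         array(gam, dim = dim(reference@values)), "weight")
  list(gpr = 100 * mean(gam[analyze] <= 1),
       gamma = gamVol, nAnalyzed = sum(analyze))
}

## ---------------------------------------------------------------------------
## EvalReport
## ---------------------------------------------------------------------------

#' Plan-evaluation report
#'
#' Container for the full predicted-vs-reference comparison of one case:
#' per-ROI voxel MAPE, DVH metrics (D2/D5/D50/D95) for both plans with
#' their per-case error, cumulative isodose DSC per level, and gamma
#' passing rates per criteria set.
#'
#' @slot roiMape Named numeric, MAPE percent per ROI.
#' @slot dvh data.frame: roi, metric, pred Gy, reference Gy, error percent.
#' @slot cumulativeDsc Numeric vector indexed by level t.
#' @slot gpr data.frame: doseDiffPercent, dtaMm, gpr.
#' @slot meta List of run metadata (interval, sigma, seed, ...).
#' @export
setClass("EvalReport",
  representation(roiMape = "numeric", dvh = "data.frame",
                 cumulativeDsc = "numeric", gpr = "data.frame",
                 meta = "list"))

setValidity("EvalReport", function(object) {
  msg <- character()
  if (length(object@roiMape) && any(object@roiMape < 0))
    msg <- c(msg, "MAPE values must be >= 0")
  if (length(object@cumulativeDsc) &&
      (any(object@cumulativeDsc < 0) || any(object@cumulativeDsc > 1)))
    msg <- c(msg, "DSC values must lie in [0, 1]")
  if (nrow(object@gpr) &&
      (any(object@gpr$gpr < 0) || any(object@gpr$gpr > 100)))
    msg <- c(msg, "GPR values must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  if (length(object@roiMape)) {
    cat("  voxel MAPE (%):\n")
    for (nm in names(object@roiMape))
      cat("    ", format(nm, width = 7),
          sprintf("%6.2f", object@roiMape[[nm]]), "\n")
  }
  if (length(object@cumulativeDsc))
    cat("  cumulative DSC: mean", sprintf("%.4f", mean(object@cumulativeDsc)),
        "min", sprintf("%.4f", min(object@cumulativeDsc)), "\n")
  if (nrow(object@gpr))
    for (k in seq_len(nrow(object@gpr)))
      cat("  GPR ", object@gpr$doseDiffPercent[k], "%/",
          object@gpr$dtaMm[k], "mm: ",
          sprintf("%.2f%%", object@gpr$gpr[k]), "\n", sep = "")
})

#' Evaluate a predicted plan against a reference plan
#'
#' Runs the full evaluation suite for one case: cumulative isodose DSC at
#' every level, voxel MAPE per ROI, DVH metrics D2/D5/D50/D95 per ROI for
#' both plans, and the global gamma passing rate for each criteria set.
#'
#' @param predDose Predicted (smoothed) \linkS4class{ScalarVolume} in Gy.
#' @param gtDose Reference \linkS4class{ScalarVolume} in Gy.
#' @param predLevels,gtLevels \linkS4class{DoseLevelMap}s for the DSC part
#'   (may be NULL to skip).
#' @param structures A \linkS4class{StructureSet}.
#' @param rx A \linkS4class{Prescription}.
#' @param rois Roles to evaluate (defaults to all present).
#' @param gammaCriteria List of \linkS4class{GammaCriteria}.
#' @param meta List of metadata stored in the report.
#' @return An \linkS4class{EvalReport}.
#' @export
evaluatePlan <- function(predDose, gtDose, predLevels = NULL,
                         gtLevels = NULL, structures, rx,
                         rois = structureRoles(structures),
                         gammaCriteria = list(GammaCriteria(3, 2),
                                              GammaCriteria(3, 1)),
                         meta = list()) {
  stopifnot(is(structures, "StructureSet"), is(rx, "Prescription"))
  rois <- intersect(rois, structureRoles(structures))
  roiMape <- vapply(rois, function(r)
    voxelMape(predDose, gtDose, structureMask(structures, r), rx), 0)
  dvhRows <- list()
  for (r in rois) {
    m <- structureMask(structures, r)
    for (x in c(2, 5, 50, 95)) {
      pv <- dvhMetric(predDose, m, x)
      gv <- dvhMetric(gtDose, m, x)
      dvhRows[[length(dvhRows) + 1L]] <- data.frame(
        roi = r, metric = paste0("D", x),
        predGy = pv, referenceGy = gv,
        errorPercent = 100 * abs(pv - gv) / rx@ctvRxGy)
    }
  }
  dvh <- if (length(dvhRows)) do.call(rbind, dvhRows) else
    data.frame(roi = character(), metric = character(),
               predGy = numeric(), referenceGy = numeric(),
               errorPercent = numeric())
  rownames(dvh) <- NULL
  cdsc <- numeric(0)
  if (!is.null(predLevels) && !is.null(gtLevels)) {
    Tlev <- gtLevels@numLevels
    cdsc <- vapply(seq_len(Tlev), function(t)
      cumulativeIsodoseDsc(gtLevels, predLevels, t), 0)
  }
  gpr <- do.call(rbind, lapply(gammaCriteria, function(cr) {
    g <- gammaPassingRate(gtDose, predDose, cr, rx)
    data.frame(doseDiffPercent = cr@doseDiffPercent, dtaMm = cr@dtaMm,
               gpr = g$gpr)
  }))
  if (is.null(gpr))
    gpr <- data.frame(doseDiffPercent = numeric(), dtaMm = numeric(),
                      gpr = numeric())
  new("EvalReport", roiMape = roiMape, dvh = dvh, cumulativeDsc = cdsc,
      gpr = gpr, meta = meta)
}
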