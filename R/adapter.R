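#' @include AllClasses.R
NULL

## ---------------------------------------------------------------------------
## Avoidance weights
## ---------------------------------------------------------------------------

#' Avoidance-image weights
#'
#' Clinical-priority weights used to consolidate OAR and body contours into
#' a single avoidance channel. The most clinically important structures get
#' weight 1: heart, ribs and skin are 1, breast 0.5, body 0.1, and voxels
#' outside every contour 0, mirroring the priority ordering of planning
#' objectives. All weights must lie in [0, 1].
#'
#' @slot heart,ribs,skin,breast,body,background Numeric scalars in [0, 1].
#' @export
setClass("AvoidanceWeights",
  representation(heart = "numeric", ribs = "numeric", skin = "numeric",
                 breast = "numeric", body = "numeric",
                 background = "numeric"))

setValidity("AvoidanceWeights", function(object) {
  w <- c(object@heart, object@ribs, object@skin, object@breast,
         object@body, object@background)
  if (length(w) != 6L || any(!is.finite(w)))
    return("all six weights must be finite scalars")
  if (any(w < 0) || any(w > 1))
    return("weights must lie in [0, 1]")
  TRUE
})

#' @param heart,ribs,skin,breast,body,background Weights in [0, 1].
#' @return An \code{AvoidanceWeights} object.
#' @rdname AvoidanceWeights-class
#' @export
AvoidanceWeights <- function(heart = 1, ribs = 1, skin = 1, breast = 0.5,
                             body = 0.1, background = 0) {
  new("AvoidanceWeights", heart = heart, ribs = ribs, skin = skin,
      breast = breast, body = body, background = background)
}

setMethod("show", "AvoidanceWeights", function(object) {
  cat("AvoidanceWeights: heart", object@heart, "| ribs", object@ribs,
      "| skin", object@skin, "| breast", object@breast, "| body",
      object@body, "| background", object@background, "\n")
})

.weightFor <- function(weights, role) slot(weights, role)

#' Build the weighted avoidance input channel
#'
#' Consolidates the OAR and body contours into a single scalar channel:
#' each voxel receives the maximum weight among all structures containing
#' it (highest priority wins on overlap; a skin voxel inside the breast is
#' 1), and the background weight elsewhere. Targets carry no weight of
#' their own and inherit the weight of the tissue they sit in.
#'
#' @param structures A \linkS4class{StructureSet}; the body mask must be
#'   present, any subset of heart/ribs/skin/breast may be.
#' @param weights An \linkS4class{AvoidanceWeights} object.
#' @return A \linkS4class{ScalarVolume} with unit \code{"weight"}, values
#'   in [0, 1].
#' @examples
#' g <- Grid3D(c(4L, 4L, 4L))
#' body <- array(TRUE, c(4, 4, 4)); heart <- array(FALSE, c(4, 4, 4))
#' heart[1, 1, 1] <- TRUE
#' s <- StructureSet(g, list(body = body, heart = heart))
#' av <- buildAvoidanceImage(s)
#' voxelValues(av)[1, 1, 1]  # 1
#' voxelValues(av)[2, 2, 2]  # 0.1
#' @export
buildAvoidanceImage <- function(structures, weights = AvoidanceWeights()) {
  stopifnot(is(structures, "StructureSet"), is(weights, "AvoidanceWeights"))
  validObject(weights)
  if (!hasStructure(structures, "body"))
    stop("body mask is required to build the avoidance image", call. = FALSE)
  sh <- structures@grid@shape
  v <- array(weights@background, dim = sh)
  for (role in c("body", "breast", "heart", "ribs", "skin")) {
    if (!hasStructure(structures, role)) next
    m <- structureMask(structures, role)
    w <- .weightFor(weights, role)
    v[m] <- pmax(v[m], w)
  }
  ScalarVolume(structures@grid, v, "weight")
}

## ---------------------------------------------------------------------------
## Prescribed-dose channel
## ---------------------------------------------------------------------------

#' Build the normalized prescribed-dose input channel
#'
#' Encodes the prescription geometry as a scalar channel: CTV voxels are 1,
#' voxels in PTV but outside CTV carry the PTV-to-CTV prescription ratio
#' (e.g. 6 Gy / 8 Gy = 0.75; 0 when no PTV prescription exists), and all
#' voxels outside the PTV are 0. Normalizing by the CTV prescription keeps
#' the channel comparable across cases with different absolute
#' prescriptions. CTV is intersected with PTV to enforce nesting.
#'
#' @param structures A \linkS4class{StructureSet} with CTV and PTV masks.
#' @param rx A \linkS4class{Prescription}.
#' @return A \linkS4class{ScalarVolume} with unit \code{"weight"}.
#' @examples
#' g <- Grid3D(c(4L, 4L, 4L))
#' ctv <- array(FALSE, c(4, 4, 4)); ctv[2, 2, 2] <- TRUE
#' ptv <- ctv; ptv[3, 2, 2] <- TRUE
#' s <- StructureSet(g, list(CTV = ctv, PTV = ptv))
#' ch <- buildPrescribedDoseChannel(s, Prescription(8, 6))
#' voxelValues(ch)[3, 2, 2]  # 0.75
#' @export
buildPrescribedDoseChannel <- function(structures, rx) {
  stopifnot(is(structures, "StructureSet"), is(rx, "Prescription"))
  validObject(rx)
  if (!hasStructure(structures, "CTV") || !hasStructure(structures, "PTV"))
    stop("CTV and PTV masks are required for the prescribed-dose channel",
         call. = FALSE)
  ptv <- structureMask(structures, "PTV")
  ctv <- structureMask(structures, "CTV") & ptv
  ratio <- if (is.na(rx@ptvRxGy)) 0 else rx@ptvRxGy / rx@ctvRxGy
  v <- array(0, dim = structures@grid@shape)
  v[ptv] <- ratio
  v[ctv] <- 1
  ScalarVolume(structures@grid, v, "weight")
}

## ---------------------------------------------------------------------------
## Dose normalization and discretization
## ---------------------------------------------------------------------------

#' Convert absolute dose to relative dose
#'
#' Normalizes an absolute dose distribution to percent of the CTV
#' prescription, the 0--120\% range the discretizer operates on. Values
#' above 120\% are clipped.
#'
#' @param dose A \linkS4class{ScalarVolume} in Gy.
#' @param rx A \linkS4class{Prescription}.
#' @return A \linkS4class{ScalarVolume} with unit \code{"percent"},
#'   values in [0, 120].
#' @export
normalizeDose <- function(dose, rx) {
  stopifnot(is(dose, "ScalarVolume"), is(rx, "Prescription"))
  if (dose@unit != "Gy")
    stop("dose must be in Gy (got unit '", dose@unit, "')", call. = FALSE)
  if (any(dose@values < 0))
    stop("dose contains negative voxels", call. = FALSE)
  rel <- pmin(100 * dose@values / rx@ctvRxGy, 120)
  ScalarVolume(dose@grid, array(rel, dim = dim(dose@values)), "percent")
}

#' Discretize relative dose into isodose levels
#'
#' Partitions the 0--120\% relative-dose range into T = 120 / i isodose
#' volumes (i = 5 gives 24 levels, i = 2 gives 60): a voxel with relative
#' dose d receives label t when d lies in [(t - 1/2) i, (t + 1/2) i)
#' (lower-inclusive), d below i/2 is background (label 0) and d = 120 maps
#' to the top level. The resulting label volume is the segmentation ground
#' truth.
#'
#' @param relativeDose A \linkS4class{ScalarVolume} with unit
#'   \code{"percent"}, values in [0, 120].
#' @param intervalPercent Isodose interval i; must divide 120 exactly.
#' @return A \linkS4class{DoseLevelMap}.
#' @examples
#' g <- Grid3D(c(2L, 2L, 2L))
#' d <- ScalarVolume(g, array(c(0, 2.5, 5, 100, 120, 7.4, 60, 33),
#'                            c(2, 2, 2)), "percent")
#' levelLabels(discretizeDose(d, 5))
#' @export
discretizeDose <- function(relativeDose, intervalPercent) {
  stopifnot(is(relativeDose, "ScalarVolume"))
  if (relativeDose@unit != "percent")
    stop("relative dose must have unit 'percent'", call. = FALSE)
  i <- as.numeric(intervalPercent)
  if (length(i) != 1L || !is.finite(i) || i <= 0 ||
      abs(120 / i - round(120 / i)) > 1e-9)
    stop("intervalPercent must be positive and divide 120 exactly ",
         "(got ", intervalPercent, ")", call. = FALSE)
  d <- relativeDose@values
  if (any(d < 0) || any(d > 120))
    stop("relative dose must lie in [0, 120]", call. = FALSE)
  labels <- as.integer(floor(d / i + 0.5))   # ties at (t - 1/2) i go up
  DoseLevelMap(relativeDose@grid, array(labels, dim = dim(d)), i)
}

## ---------------------------------------------------------------------------
## Case screening
## ---------------------------------------------------------------------------

#' Screen a case for target hotspots
#'
#' Quality-control screen applied before a case enters the dataset: a case
#' is excluded when its maximum dose anywhere exceeds 102\% of the CTV
#' prescription (strict inequality; exactly 102\% passes).
#'
#' @param dose A \linkS4class{ScalarVolume} in Gy.
#' @param structures A \linkS4class{StructureSet}; the PTV mask must be
#'   present.
#' @param rx A \linkS4class{Prescription}.
#' @return A list with elements \code{pass} (logical), \code{reason}
#'   (character), \code{maxDoseGy} and \code{limitGy}.
#' @export
qcScreenCase <- function(dose, structures, rx) {
  stopifnot(is(dose, "ScalarVolume"), is(structures, "StructureSet"),
            is(rx, "Prescription"))
  if (dose@unit != "Gy")
    stop("dose must be in Gy", call. = FALSE)
  if (!hasStructure(structures, "PTV"))
    stop("PTV mask is required for case screening", call. = FALSE)
  mx <- max(dose@values)
  limit <- 1.02 * rx@ctvRxGy
  if (mx > limit) {
    list(pass = FALSE,
         reason = sprintf(
           "maximum dose %.3f Gy (%.1f%% of prescription) exceeds the 102%% hotspot limit (%.3f Gy)",
           mx, 100 * mx / rx@ctvRxGy, limit),
         maxDoseGy = mx, limitGy = limit)
  } else {
    list(pass = TRUE, reason = "within hotspot limit",
         maxDoseGy = mx, limitGy = limit)
  }
}
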