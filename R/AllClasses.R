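#' @import methods
#' @include AllGenerics.R
NULL

## Recognised structure roles, in precedence-free canonical order.
.ROLES <- c("GTV", "CTV", "PTV", "breast", "heart", "ribs", "skin", "body")

.fmtTriple <- function(x) paste(format(x, trim = TRUE), collapse = " x ")

## ---------------------------------------------------------------------------
## Grid3D
## ---------------------------------------------------------------------------

#' Regular 3D voxel lattice
#'
#' A \code{Grid3D} describes the geometry shared by all volumes of one case:
#' the number of voxels per axis, the isotropic-or-not voxel spacing in mm,
#' and the physical position (mm) of the center of voxel index (0,0,0).
#' Physical position of voxel index v (0-based) is \code{origin + v * spacing}
#' (voxel-center convention). Two volumes are combinable only when their
#' grids are identical.
#'
#' @slot shape Integer triple, voxels per axis (all >= 1).
#' @slot spacingMm Numeric triple, mm per voxel (all > 0).
#' @slot originMm Numeric triple, physical position of voxel (0,0,0).
#' @export
setClass("Grid3D",
  representation(shape = "integer", spacingMm = "numeric", originMm = "numeric"))

setValidity("Grid3D", function(object) {
  msg <- character()
  if (length(object@shape) != 3L || any(object@shape < 1L))
    msg <- c(msg, "shape must be an integer triple with all entries >= 1")
  if (length(object@spacingMm) != 3L || any(!is.finite(object@spacingMm)) ||
      any(object@spacingMm <= 0))
    msg <- c(msg, "spacingMm must be a positive triple")
  if (length(object@originMm) != 3L || any(!is.finite(object@originMm)))
    msg <- c(msg, "originMm must be a finite triple")
  if (length(msg)) msg else TRUE
})

#' @param shape Integer triple (a scalar is recycled).
#' @param spacingMm Positive spacing in mm (a scalar is recycled).
#' @param originMm Physical position (mm) of the first voxel center.
#' @return A \code{Grid3D} object.
#' @rdname Grid3D-class
#' @export
Grid3D <- function(shape, spacingMm = 2, originMm = c(0, 0, 0)) {
  new("Grid3D", shape = as.integer(rep_len(shape, 3L)),
      spacingMm = as.numeric(rep_len(spacingMm, 3L)),
      originMm = as.numeric(rep_len(originMm, 3L)))
}

setMethod("gridShape", "Grid3D", function(x) x@shape)
setMethod("gridSpacing", "Grid3D", function(x) x@spacingMm)
setMethod("gridOrigin", "Grid3D", function(x) x@originMm)

setMethod("show", "Grid3D", function(object) {
  cat("Grid3D:", .fmtTriple(object@shape), "voxels @",
      .fmtTriple(object@spacingMm), "mm, origin (",
      paste(format(object@originMm, trim = TRUE), collapse = ", "), ") mm\n")
})

## Grid equality within a geometric tolerance (1e-6 mm).
.sameGrid <- function(a, b, tol = 1e-6) {
  identical(a@shape, b@shape) &&
    all(abs(a@spacingMm - b@spacingMm) < tol) &&
    all(abs(a@originMm - b@originMm) < tol)
}

.stopIfGridMismatch <- function(a, b, what = "volumes") {
  if (!.sameGrid(doseGrid(a), doseGrid(b)))
    stop("geometry error: ", what, " are defined on different grids",
         call. = FALSE)
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## ScalarVolume
## ---------------------------------------------------------------------------

#' Scalar field on a voxel lattice
#'
#' One real value per voxel together with a declared unit. Units are never
#' inferred: \code{"Gy"} for absolute dose, \code{"percent"} for relative
#' dose (percent of the CTV prescription, 0--120), \code{"weight"} for
#' dimensionless fields such as the avoidance image.
#'
#' @slot grid A \linkS4class{Grid3D}.
#' @slot values 3D numeric array matching the grid shape.
#' @slot unit One of \code{"Gy"}, \code{"percent"}, \code{"weight"}.
#' @export
setClass("ScalarVolume",
  representation(grid = "Grid3D", values = "array", unit = "character"))

setValidity("ScalarVolume", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@grid@shape)))
    msg <- c(msg, "values array shape must equal grid shape")
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be numeric")
  if (length(object@unit) != 1L ||
      !object@unit %in% c("Gy", "percent", "weight"))
    msg <- c(msg, "unit must be one of 'Gy', 'percent', 'weight'")
  if (length(msg)) msg else TRUE
})

#' @param grid A \linkS4class{Grid3D}.
#' @param values Numeric 3D array (or vector reshaped to the grid).
#' @param unit Declared unit.
#' @return A \code{ScalarVolume}.
#' @rdname ScalarVolume-class
#' @export
ScalarVolume <- function(grid, values, unit = c("Gy", "percent", "weight")) {
  unit <- match.arg(unit)
  if (is.null(dim(values))) dim(values) <- grid@shape
  storage.mode(values) <- "double"
  new("ScalarVolume", grid = grid, values = values, unit = unit)
}

setMethod("doseGrid", "ScalarVolume", function(x) x@grid)
setMethod("voxelValues", "ScalarVolume", function(x) x@values)
setMethod("doseUnit", "ScalarVolume", function(x) x@unit)
setMethod("gridShape", "ScalarVolume", function(x) x@grid@shape)
setMethod("gridSpacing", "ScalarVolume", function(x) x@grid@spacingMm)
setMethod("gridOrigin", "ScalarVolume", function(x) x@grid@originMm)

setMethod("show", "ScalarVolume", function(object) {
  rng <- range(object@values)
  cat("ScalarVolume [", object@unit, "] ", .fmtTriple(object@grid@shape),
      " @ ", .fmtTriple(object@grid@spacingMm), " mm, range [",
      format(rng[1]), ", ", format(rng[2]), "]\n", sep = "")
})

## ---------------------------------------------------------------------------
## StructureSet
## ---------------------------------------------------------------------------

#' Named binary structure masks
#'
#' Targets (GTV, CTV, PTV), organs at risk (breast, heart, ribs, skin) and
#' the body contour of one case, as strictly binary masks on a shared grid.
#' Any subset of roles may be present.
#'
#' @slot grid A \linkS4class{Grid3D}.
#' @slot masks Named list of logical 3D arrays; names are roles.
#' @export
setClass("StructureSet",
  representation(grid = "Grid3D", masks = "list"))

setValidity("StructureSet", function(object) {
  msg <- character()
  if (is.null(names(object@masks)) && length(object@masks))
    msg <- c(msg, "masks must be named by role")
  bad <- setdiff(names(object@masks), .ROLES)
  if (length(bad))
    msg <- c(msg, paste0("unknown roles: ", paste(bad, collapse = ", ")))
  for (nm in names(object@masks)) {
    m <- object@masks[[nm]]
    if (!is.logical(m))
      msg <- c(msg, paste0("mask '", nm, "' must be logical (strictly binary)"))
    if (!identical(dim(m), as.integer(object@grid@shape)))
      msg <- c(msg, paste0("mask '", nm, "' shape must equal grid shape"))
  }
  if (length(msg)) msg else TRUE
})

#' @param grid A \linkS4class{Grid3D}.
#' @param masks Named list of masks; numeric/integer arrays are accepted and
#'   binarized as \code{!= 0}.
#' @return A \code{StructureSet}.
#' @rdname StructureSet-class
#' @export
StructureSet <- function(grid, masks = list()) {
  masks <- lapply(masks, function(m) {
    if (is.null(dim(m))) dim(m) <- grid@shape
    if (!is.logical(m)) m <- m != 0
    m
  })
  new("StructureSet", grid = grid, masks = masks)
}

setMethod("doseGrid", "StructureSet", function(x) x@grid)
setMethod("structureRoles", "StructureSet", function(x) names(x@masks))
setMethod("structureMask", "StructureSet", function(x, role) {
  if (!role %in% names(x@masks))
    stop("structure '", role, "' not present", call. = FALSE)
  x@masks[[role]]
})
setMethod("gridShape", "StructureSet", function(x) x@grid@shape)
setMethod("gridSpacing", "StructureSet", function(x) x@grid@spacingMm)

setMethod("show", "StructureSet", function(object) {
  vx <- vapply(object@masks, sum, 0)
  cat("StructureSet on", .fmtTriple(object@grid@shape), "grid:\n")
  for (nm in names(object@masks))
    cat("  ", format(nm, width = 7), format(vx[[nm]], big.mark = ","),
        "voxels\n")
})

#' Test whether a structure is present
#' @param x A \linkS4class{StructureSet}.
#' @param role Structure role name.
#' @return Logical scalar.
#' @export
hasStructure <- function(x, role) role %in% names(x@masks)

## ---------------------------------------------------------------------------
## Prescription
## ---------------------------------------------------------------------------

#' Per-fraction prescription
#'
#' The per-fraction prescription doses used for channel normalization,
#' relative-dose conversion and MAPE/gamma normalization. The CTV
#' prescription is the reference dose; the PTV prescription, when present,
#' must not exceed it.
#'
#' @slot ctvRxGy Positive per-fraction CTV prescription (Gy).
#' @slot ptvRxGy Per-fraction PTV prescription (Gy), or \code{NA} if absent.
#' @export
setClass("Prescription",
  representation(ctvRxGy = "numeric", ptvRxGy = "numeric"))

setValidity("Prescription", function(object) {
  msg <- character()
  if (length(object@ctvRxGy) != 1L || !is.finite(object@ctvRxGy) ||
      object@ctvRxGy <= 0)
    msg <- c(msg, "ctvRxGy must be a positive scalar")
  if (length(object@ptvRxGy) != 1L)
    msg <- c(msg, "ptvRxGy must be a scalar (NA when absent)")
  else if (!is.na(object@ptvRxGy)) {
    if (object@ptvRxGy <= 0)
      msg <- c(msg, "ptvRxGy must be positive when present")
    else if (object@ptvRxGy > object@ctvRxGy)
      msg <- c(msg, "ptvRxGy must not exceed ctvRxGy")
  }
  if (length(msg)) msg else TRUE
})

#' @param ctvRxGy Per-fraction CTV prescription in Gy (e.g. 7 or 8).
#' @param ptvRxGy Per-fraction PTV prescription in Gy, or \code{NA}.
#' @return A \code{Prescription}.
#' @rdname Prescription-class
#' @export
Prescription <- function(ctvRxGy, ptvRxGy = NA_real_) {
  new("Prescription", ctvRxGy = as.numeric(ctvRxGy),
      ptvRxGy = as.numeric(ptvRxGy))
}

setMethod("show", "Prescription", function(object) {
  cat("Prescription: CTV", object@ctvRxGy, "Gy",
      if (!is.na(object@ptvRxGy)) paste(", PTV", object@ptvRxGy, "Gy"), "\n")
})

#' @rdname Prescription-class
#' @param x A \code{Prescription}.
#' @export
ctvRx <- function(x) x@ctvRxGy

#' @rdname Prescription-class
#' @export
ptvRx <- function(x) x@ptvRxGy

## ---------------------------------------------------------------------------
## DoseLevelMap
## ---------------------------------------------------------------------------

#' Discrete isodose-level label volume
#'
#' Integer labels assigning each voxel to one of T isodose volumes plus
#' background. With interval i (percent), T = 120 / i, and label t > 0
#' covers relative dose [(t - 1/2) i, (t + 1/2) i); label 0 covers
#' [0, i / 2). The smallest nonzero representable relative dose is i / 2.
#'
#' @slot grid A \linkS4class{Grid3D}.
#' @slot labels Integer 3D array, values in [0, T].
#' @slot intervalPercent The isodose interval i in percent.
#' @slot numLevels T = 120 / i.
#' @export
setClass("DoseLevelMap",
  representation(grid = "Grid3D", labels = "array",
                 intervalPercent = "numeric", numLevels = "integer"))

setValidity("DoseLevelMap", function(object) {
  msg <- character()
  i <- object@intervalPercent
  if (length(i) != 1L || !is.finite(i) || i <= 0)
    msg <- c(msg, "intervalPercent must be a positive scalar")
  else {
    Tlev <- 120 / i
    if (abs(Tlev - round(Tlev)) > 1e-9)
      msg <- c(msg, "intervalPercent must divide 120 exactly")
    else if (object@numLevels != as.integer(round(Tlev)))
      msg <- c(msg, "numLevels must equal 120 / intervalPercent")
  }
  if (!identical(dim(object@labels), as.integer(object@grid@shape)))
    msg <- c(msg, "labels array shape must equal grid shape")
  if (!is.integer(object@labels))
    msg <- c(msg, "labels must be integer")
  else if (length(object@labels) &&
           (min(object@labels) < 0L || max(object@labels) > object@numLevels))
    msg <- c(msg, "labels must lie in [0, numLevels]")
  if (length(msg)) msg else TRUE
})

#' @param grid A \linkS4class{Grid3D}.
#' @param labels Integer array of level labels.
#' @param intervalPercent Isodose interval i (must divide 120).
#' @return A \code{DoseLevelMap}.
#' @rdname DoseLevelMap-class
#' @export
DoseLevelMap <- function(grid, labels, intervalPercent) {
  if (is.null(dim(labels))) dim(labels) <- grid@shape
  storage.mode(labels) <- "integer"
  new("DoseLevelMap", grid = grid, labels = labels,
      intervalPercent = as.numeric(intervalPercent),
      numLevels = as.integer(round(120 / intervalPercent)))
}

setMethod("doseGrid", "DoseLevelMap", function(x) x@grid)
setMethod("levelLabels", "DoseLevelMap", function(x) x@labels)
setMethod("levelInterval", "DoseLevelMap", function(x) x@intervalPercent)
setMethod("numLevels", "DoseLevelMap", function(x) x@numLevels)
setMethod("gridShape", "DoseLevelMap", function(x) x@grid@shape)
setMethod("gridSpacing", "DoseLevelMap", function(x) x@grid@spacingMm)

setMethod("show", "DoseLevelMap", function(object) {
  cat("DoseLevelMap: interval ", object@intervalPercent, "%, T = ",
      object@numLevels, " levels, ", .fmtTriple(object@grid@shape),
      " voxels, labels in [", min(object@labels), ", ",
      max(object@labels), "]\n", sep = "")
})

#' Relative-dose range represented by one level
#'
#' @param x A \linkS4class{DoseLevelMap} (or interval in percent).
#' @param t Level index, 0 to T.
#' @return Numeric length-2 vector: the half-open relative-dose interval
#'   (percent) covered by level \code{t}. Level 0 covers [0, i/2).
#' @examples
#' m <- DoseLevelMap(Grid3D(c(2L,2L,2L)), array(0L, c(2,2,2)), 5)
#' levelDoseRange(m, 1)  # c(2.5, 7.5)
#' @export
levelDoseRange <- function(x, t) {
  i <- if (is(x, "DoseLevelMap")) x@intervalPercent else as.numeric(x)
  t <- as.integer(t)
  if (t < 0L) stop("level index must be >= 0", call. = FALSE)
  if (t == 0L) c(0, i / 2) else c((t - 0.5) * i, (t + 0.5) * i)
}
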