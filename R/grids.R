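#' @include AllClasses.R
NULL

## Vectorized trilinear sampling of a 3D array at continuous 0-based voxel
## indices (xi, yi, zi). Indices are clamped to the array extent, so querying
## on or slightly outside the boundary replicates the edge value.
.trilinear <- function(values, xi, yi, zi) {
  n <- dim(values)
  xi <- pmin(pmax(xi, 0), n[1] - 1)
  yi <- pmin(pmax(yi, 0), n[2] - 1)
  zi <- pmin(pmax(zi, 0), n[3] - 1)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0;  fy <- yi - y0;  fz <- zi - z0
  x1 <- pmin(x0 + 1, n[1] - 1)
  y1 <- pmin(y0 + 1, n[2] - 1)
  z1 <- pmin(z0 + 1, n[3] - 1)
  lin <- function(a, b, c) 1 + a + n[1] * (b + n[2] * c)
  v <- values
  (1 - fx) * (1 - fy) * (1 - fz) * v[lin(x0, y0, z0)] +
       fx  * (1 - fy) * (1 - fz) * v[lin(x1, y0, z0)] +
  (1 - fx) *      fy  * (1 - fz) * v[lin(x0, y1, z0)] +
       fx  *      fy  * (1 - fz) * v[lin(x1, y1, z0)] +
  (1 - fx) * (1 - fy) *      fz  * v[lin(x0, y0, z1)] +
       fx  * (1 - fy) *      fz  * v[lin(x1, y0, z1)] +
  (1 - fx) *      fy  *      fz  * v[lin(x0, y1, z1)] +
       fx  *      fy  *      fz  * v[lin(x1, y1, z1)]
}

## Nearest-neighbor sampling at continuous 0-based indices (ties round half
## up per axis, then clamp).
.nearest <- function(values, xi, yi, zi) {
  n <- dim(values)
  x <- pmin(pmax(floor(xi + 0.5), 0), n[1] - 1)
  y <- pmin(pmax(floor(yi + 0.5), 0), n[2] - 1)
  z <- pmin(pmax(floor(zi + 0.5), 0), n[3] - 1)
  values[1 + x + n[1] * (y + n[2] * z)]
}

## Continuous input voxel indices of every output voxel center for a
## grid-to-grid resampling (axis-aligned, voxel-center convention).
.resampleIndexGrids <- function(inGrid, outGrid) {
  outIdx <- lapply(1:3, function(a) {
    phys <- outGrid@originMm[a] + (seq_len(outGrid@shape[a]) - 1) *
      outGrid@spacingMm[a]
    (phys - inGrid@originMm[a]) / inGrid@spacingMm[a]
  })
  sh <- outGrid@shape
  list(xi = rep(outIdx[[1]], times = sh[2] * sh[3]),
       yi = rep(rep(outIdx[[2]], each = sh[1]), times = sh[3]),
       zi = rep(outIdx[[3]], each = sh[1] * sh[2]))
}

#' Resample a dose volume and its structures to an isotropic grid
#'
#' Resamples a scalar volume with trilinear interpolation and its structure
#' masks with nearest-neighbor interpolation onto an isotropic grid at the
#' requested spacing (the preprocessing resolution is 2 mm). The output grid
#' keeps the input origin and covers the input physical extent; masks remain
#' strictly binary.
#'
#' @param volume A \linkS4class{ScalarVolume}.
#' @param masks A \linkS4class{StructureSet} on the same grid.
#' @param targetSpacingMm Positive isotropic spacing in mm (default 2).
#' @return A list with elements \code{volume} and \code{masks} on the new
#'   grid.
#' @examples
#' g <- Grid3D(c(9L, 9L, 9L), spacingMm = 1)
#' v <- ScalarVolume(g, array(seq_len(9^3), c(9, 9, 9)), "Gy")
#' s <- StructureSet(g, list(body = array(TRUE, c(9, 9, 9))))
#' out <- resampleIsotropic(v, s, 2)
#' gridSpacing(out$volume)
#' @export
resampleIsotropic <- function(volume, masks, targetSpacingMm = 2) {
  stopifnot(is(volume, "ScalarVolume"), is(masks, "StructureSet"))
  if (!is.numeric(targetSpacingMm) || length(targetSpacingMm) != 1L ||
      targetSpacingMm <= 0)
    stop("targetSpacingMm must be a positive scalar", call. = FALSE)
  .stopIfGridMismatch(volume, masks, "volume and structure set")
  g <- volume@grid
  extent <- (g@shape - 1L) * g@spacingMm
  newShape <- pmax(1L, as.integer(floor(extent / targetSpacingMm + 1e-9)) + 1L)
  outGrid <- Grid3D(newShape, spacingMm = targetSpacingMm,
                    originMm = g@originMm)
  ix <- .resampleIndexGrids(g, outGrid)
  vals <- array(.trilinear(volume@values, ix$xi, ix$yi, ix$zi),
                dim = newShape)
  outMasks <- lapply(masks@masks, function(m) {
    mm <- array(.nearest(m + 0, ix$xi, ix$yi, ix$zi) != 0, dim = newShape)
    mm
  })
  list(volume = ScalarVolume(outGrid, vals, volume@unit),
       masks = new("StructureSet", grid = outGrid, masks = outMasks))
}

## 0-based voxel-index mass center of a logical mask, rounded down.
.massCenterIndex <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L) stop("reference mask is empty", call. = FALSE)
  as.integer(floor(colMeans(w) - 1))
}

## Extract a window of `size` voxels from a 3D array, 0-based start `lo`
## (may be negative), padding out-of-bounds with `fill`.
.cropWindow <- function(arr, lo, size, fill = 0) {
  n <- dim(arr)
  out <- array(fill, dim = size)
  inLo <- pmax(lo, 0L)
  inHi <- pmin(lo + size - 1L, n - 1L)
  if (any(inLo > inHi)) return(out)
  dst <- lapply(1:3, function(a) (inLo[a] - lo[a] + 1L):(inHi[a] - lo[a] + 1L))
  src <- lapply(1:3, function(a) (inLo[a] + 1L):(inHi[a] + 1L))
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

#' Crop a case about the mass center of a reference structure
#'
#' Crops (or pads) the volume and all masks to a fixed window centered on
#' the voxel-index mass center of a reference structure, the standard
#' preprocessing step that centers the 128 x 128 x 128 window on the whole
#' breast. The mass center (rounded down) lands at output index
#' \code{size \%/\% 2}; regions beyond the input extent are zero-padded;
#' the origin is updated so physical coordinates are preserved.
#'
#' @param volume A \linkS4class{ScalarVolume}.
#' @param masks A \linkS4class{StructureSet} on the same grid.
#' @param referenceRole Role whose mask defines the mass center
#'   (default \code{"breast"}).
#' @param size Integer triple (or scalar) output shape, default 128.
#' @return A list with elements \code{volume} and \code{masks}.
#' @export
cropAboutMassCenter <- function(volume, masks, referenceRole = "breast",
                                size = 128L) {
  stopifnot(is(volume, "ScalarVolume"), is(masks, "StructureSet"))
  .stopIfGridMismatch(volume, masks, "volume and structure set")
  size <- as.integer(rep_len(size, 3L))
  g <- volume@grid
  if (any(size < 1L)) stop("size must be positive", call. = FALSE)
  if (any(size > 4L * g@shape))
    stop("requested crop size exceeds 4x the input extent", call. = FALSE)
  if (!hasStructure(masks, referenceRole))
    stop("reference structure '", referenceRole, "' not present",
         call. = FALSE)
  mc <- .massCenterIndex(structureMask(masks, referenceRole))
  center <- size %/% 2L
  lo <- mc - center                       # 0-based input index of output (0,0,0)
  outGrid <- Grid3D(size, spacingMm = g@spacingMm,
                    originMm = g@originMm + lo * g@spacingMm)
  vals <- .cropWindow(volume@values, lo, size, fill = 0)
  outMasks <- lapply(masks@masks, function(m)
    array(.cropWindow(m + 0, lo, size, fill = 0) != 0, dim = size))
  list(volume = ScalarVolume(outGrid, vals, volume@unit),
       masks = new("StructureSet", grid = outGrid, masks = outMasks))
}

## ---------------------------------------------------------------------------
## NIfTI I/O
## ---------------------------------------------------------------------------

.gridToAffine <- function(grid) {
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(grid@spacingMm)
  aff[1:3, 4] <- grid@originMm
  aff
}

.affineToGrid <- function(aff, shape, tol = 1e-6) {
  rot <- aff[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > tol) || any(diag(rot) <= 0))
    stop("unsupported geometry: affine is not axis-aligned with positive ",
         "spacing (shear/rotation/flip not supported)", call. = FALSE)
  Grid3D(as.integer(shape), spacingMm = diag(rot), originMm = aff[1:3, 4])
}

#' Read / write NIfTI volumes
#'
#' Axis-aligned NIfTI (.nii / .nii.gz) I/O for scalar volumes, masks and
#' label maps. Grid geometry travels in the sform affine; a write-then-read
#' round trip preserves values bit-exactly (float64 payload) and grid
#' metadata to 1e-6 mm. Affines with shear or rotation are rejected.
#'
#' @param path File path ending in .nii or .nii.gz.
#' @param unit Unit to declare on the volume read back (NIfTI carries none).
#' @return \code{readVolume} returns a \linkS4class{ScalarVolume};
#'   \code{writeVolume} returns \code{path} invisibly.
#' @name volume-io
#' @examples
#' g <- Grid3D(c(4L, 4L, 4L), 2, c(-10, 5, 3))
#' v <- ScalarVolume(g, array(rnorm(64), c(4, 4, 4)), "Gy")
#' f <- tempfile(fileext = ".nii.gz")
#' writeVolume(v, f)
#' all.equal(voxelValues(readVolume(f)), voxelValues(v))
NULL

#' @rdname volume-io
#' @param volume A \linkS4class{ScalarVolume}, or \linkS4class{DoseLevelMap}
#'   (written as integers).
#' @param datatype NIfTI on-disk datatype; \code{"double"} preserves dose
#'   values bit-exactly, \code{"int16"} suits label maps and masks.
#' @export
writeVolume <- function(volume, path, datatype = NULL) {
  if (is(volume, "DoseLevelMap")) {
    arr <- volume@labels
    grid <- volume@grid
    if (is.null(datatype)) datatype <- "int16"
  } else if (is(volume, "ScalarVolume")) {
    arr <- volume@values
    grid <- volume@grid
    if (is.null(datatype)) datatype <- "double"
  } else stop("volume must be a ScalarVolume or DoseLevelMap", call. = FALSE)
  img <- RNifti::asNifti(arr, datatype = datatype)
  aff <- structure(.gridToAffine(grid), code = 2L)
  img <- RNifti::`sform<-`(img, aff)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname volume-io
#' @export
readVolume <- function(path, unit = c("Gy", "percent", "weight")) {
  unit <- match.arg(unit)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("unsupported geometry: expected a 3D volume", call. = FALSE)
  arr <- array(as.double(img), dim = dim(img))
  grid <- .affineToGrid(unclass(RNifti::xform(img)), dim(arr))
  ScalarVolume(grid, arr, unit)
}

#' Read a NIfTI label volume as a dose-level map
#'
#' @param path NIfTI file with integer labels.
#' @param intervalPercent Isodose interval i the labels were produced with.
#' @return A \linkS4class{DoseLevelMap}.
#' @export
readLevelMap <- function(path, intervalPercent) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("unsupported geometry: expected a 3D volume", call. = FALSE)
  arr <- array(as.double(img), dim = dim(img))
  if (max(abs(arr - round(arr))) > 1e-6)
    stop("integrity error: label volume contains non-integer values",
         call. = FALSE)
  Tlev <- round(120 / intervalPercent)
  if (min(arr) < 0 || max(arr) > Tlev)
    stop("integrity error: labels outside [0, ", Tlev, "]", call. = FALSE)
  grid <- .affineToGrid(unclass(RNifti::xform(img)), dim(arr))
  DoseLevelMap(grid, array(as.integer(round(arr)), dim(arr)), intervalPercent)
}
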