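#' Accessors for volumetric objects
#'
#' Every volumetric object in the package (dose volumes, structure sets,
#' dose-level maps) carries a \linkS4class{Grid3D} describing its voxel
#' lattice. These generics extract the lattice and the per-voxel payload.
#'
#' @param x An object with a grid slot.
#' @return \code{doseGrid} returns a \linkS4class{Grid3D}; \code{gridShape},
#'   \code{gridSpacing} and \code{gridOrigin} return numeric triples;
#'   \code{voxelValues} returns the underlying 3D array.
#' @name grid-accessors
#' @aliases doseGrid gridShape gridSpacing gridOrigin voxelValues
#' @examples
#' g <- Grid3D(c(8L, 8L, 8L), spacingMm = 2)
#' gridShape(g)
#' gridSpacing(g)
NULL

#' @rdname grid-accessors
#' @export
setGeneric("doseGrid", function(x) standardGeneric("doseGrid"))

#' @rdname grid-accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))

#' @rdname grid-accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname grid-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname grid-accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' Unit of a scalar volume
#'
#' @param x A \linkS4class{ScalarVolume}.
#' @return A string: \code{"Gy"}, \code{"percent"} (percent of the CTV
#'   prescription) or \code{"weight"} (dimensionless).
#' @export
setGeneric("doseUnit", function(x) standardGeneric("doseUnit"))

#' Structure-set accessors
#'
#' @param x A \linkS4class{StructureSet}.
#' @param role Structure name, one of \code{"GTV"}, \code{"CTV"},
#'   \code{"PTV"}, \code{"breast"}, \code{"heart"}, \code{"ribs"},
#'   \code{"skin"}, \code{"body"}.
#' @return \code{structureRoles} returns the character vector of roles
#'   present; \code{structureMask} returns the logical 3D mask for one role.
#' @name structure-accessors
#' @aliases structureRoles structureMask
NULL

#' @rdname structure-accessors
#' @export
setGeneric("structureRoles", function(x) standardGeneric("structureRoles"))

#' @rdname structure-accessors
#' @export
setGeneric("structureMask", function(x, role) standardGeneric("structureMask"))

#' Dose-level map accessors
#'
#' @param x A \linkS4class{DoseLevelMap}.
#' @return \code{levelLabels}: the integer 3D label array;
#'   \code{levelInterval}: the isodose interval i in percent;
#'   \code{numLevels}: the number of nonzero levels T = 120 / i.
#' @name level-accessors
#' @aliases levelLabels levelInterval numLevels
NULL

#' @rdname level-accessors
#' @export
setGeneric("levelLabels", function(x) standardGeneric("levelLabels"))

#' @rdname level-accessors
#' @export
setGeneric("levelInterval", function(x) standardGeneric("levelInterval"))

#' @rdname level-accessors
#' @export
setGeneric("numLevels", function(x) standardGeneric("numLevels"))
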