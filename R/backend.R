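#' @include AllClasses.R grids.R phantom.R
NULL

#' Dataset manifest for an external segmentation backend
#'
#' Records the contract between the toolkit and a files-in/files-out
#' segmentation backend (nnU-Net-style raw-dataset layout): case ids,
#' their split assignment, the fixed channel order (avoidance = channel 0,
#' prescribed dose = channel 1) and the label semantics (level t maps to
#' one relative-dose bin of width \code{intervalPercent}).
#'
#' @slot name Dataset name used in the descriptor.
#' @slot caseIds Character vector of unique case ids.
#' @slot split Character vector (\code{"train"}, \code{"validation"},
#'   \code{"test"}) parallel to \code{caseIds}.
#' @slot intervalPercent Isodose interval i of the label maps.
#' @slot channelNames Channel roles in fixed order.
#' @export
setClass("DatasetManifest",
  representation(name = "character", caseIds = "character",
                 split = "character", intervalPercent = "numeric",
                 channelNames = "character"))

setValidity("DatasetManifest", function(object) {
  msg <- character()
  if (anyDuplicated(object@caseIds))
    msg <- c(msg, "case ids must be unique")
  if (length(object@split) != length(object@caseIds))
    msg <- c(msg, "split must be parallel to caseIds")
  if (!all(object@split %in% c("train", "validation", "test")))
    msg <- c(msg, "split entries must be train/validation/test")
  if (abs(120 / object@intervalPercent -
          round(120 / object@intervalPercent)) > 1e-9)
    msg <- c(msg, "intervalPercent must divide 120")
  if (length(msg)) msg else TRUE
})

#' @param caseIds Unique case identifiers.
#' @param split Split assignment per case (\code{"train"} default).
#' @param intervalPercent Isodose interval of the labels.
#' @param name Dataset name.
#' @return A \code{DatasetManifest}.
#' @rdname DatasetManifest-class
#' @export
DatasetManifest <- function(caseIds, split = rep("train", length(caseIds)),
                            intervalPercent = 5, name = "DoseLevels") {
  new("DatasetManifest", name = name, caseIds = as.character(caseIds),
      split = as.character(split),
      intervalPercent = as.numeric(intervalPercent),
      channelNames = c("avoidance", "prescribed_dose"))
}

setMethod("show", "DatasetManifest", function(object) {
  cat("DatasetManifest '", object@name, "': ", length(object@caseIds),
      " cases (", sum(object@split == "train"), " train / ",
      sum(object@split == "validation"), " validation / ",
      sum(object@split == "test"), " test), interval ",
      object@intervalPercent, "%\n", sep = "")
})

#' Number of segmentation classes described by a manifest
#'
#' @param manifest A \linkS4class{DatasetManifest}.
#' @return Named integer vector: \code{levels} (T, the dose levels only,
#'   as the backend's output channels are usually counted) and
#'   \code{classes} (T + 1, including the background class the descriptor
#'   lists).
#' @export
manifestClassCounts <- function(manifest) {
  Tlev <- as.integer(round(120 / manifest@intervalPercent))
  c(levels = Tlev, classes = Tlev + 1L)
}

#' Export cases in an nnU-Net-style raw-dataset layout
#'
#' Writes one NIfTI volume per channel per case with 4-digit channel
#' suffixes (\code{<case>_0000.nii.gz} avoidance,
#' \code{<case>_0001.nii.gz} prescribed dose) under \code{imagesTr} /
#' \code{imagesTs}, integer label volumes for training and validation
#' cases under \code{labelsTr}, and a \code{dataset.json} descriptor
#' recording channel names, label semantics (background plus T levels)
#' and case counts. Re-importing an exported label map reproduces it
#' bit-exactly.
#'
#' @param cases Named list (names = case ids). Each case is a list with
#'   \code{channels} (list of two \linkS4class{ScalarVolume}s in manifest
#'   channel order) and, for train/validation cases, \code{labels}
#'   (a \linkS4class{DoseLevelMap}).
#' @param manifest A \linkS4class{DatasetManifest} covering the case ids.
#' @param outDir Output directory (created).
#' @return \code{outDir}, invisibly.
#' @export
exportDataset <- function(cases, manifest, outDir) {
  stopifnot(is(manifest, "DatasetManifest"))
  validObject(manifest)
  ids <- names(cases)
  if (is.null(ids) || anyDuplicated(ids))
    stop("cases must be uniquely named by case id", call. = FALSE)
  if (!all(ids %in% manifest@caseIds))
    stop("case ids missing from manifest: ",
         paste(setdiff(ids, manifest@caseIds), collapse = ", "),
         call. = FALSE)
  Tlev <- manifestClassCounts(manifest)[["levels"]]
  for (d in c("imagesTr", "imagesTs", "labelsTr"))
    dir.create(file.path(outDir, d), recursive = TRUE, showWarnings = FALSE)
  nTrain <- 0L; nTest <- 0L
  for (id in ids) {
    case <- cases[[id]]
    ch <- case$channels
    if (length(ch) != 2L)
      stop("case '", id, "' must provide both input channels", call. = FALSE)
    split <- manifest@split[match(id, manifest@caseIds)]
    imgDir <- if (split == "test") "imagesTs" else "imagesTr"
    if (split == "test") nTest <- nTest + 1L else nTrain <- nTrain + 1L
    for (c in seq_along(ch)) {
      stopifnot(is(ch[[c]], "ScalarVolume"))
      writeVolume(ch[[c]], file.path(outDir, imgDir,
                                     sprintf("%s_%04d.nii.gz", id, c - 1L)))
    }
    if (split != "test") {
      lab <- case$labels
      if (is.null(lab))
        stop("training case '", id, "' has no label map", call. = FALSE)
      stopifnot(is(lab, "DoseLevelMap"))
      if (max(lab@labels) > Tlev)
        stop("integrity error: case '", id, "' has labels above T = ",
             Tlev, call. = FALSE)
      .stopIfGridMismatch(ch[[1]], lab, "channels and labels")
      writeVolume(lab, file.path(outDir, "labelsTr",
                                 paste0(id, ".nii.gz")))
    }
  }
  labelMap <- c(list(background = 0L),
                stats::setNames(as.list(seq_len(Tlev)),
                                sprintf("level_%d", seq_len(Tlev))))
  descriptor <- list(
    name = manifest@name,
    channel_names = stats::setNames(as.list(manifest@channelNames),
                                    c("0", "1")),
    labels = labelMap,
    interval_percent = manifest@intervalPercent,
    numTraining = nTrain,
    numTest = nTest,
    file_ending = ".nii.gz")
  jsonlite::write_json(descriptor, file.path(outDir, "dataset.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}

#' Import a predicted label map from a segmentation backend
#'
#' Reads an integer NIfTI label volume produced by the backend and wraps
#' it as a \linkS4class{DoseLevelMap} carrying the manifest's interval,
#' ready for smoothing and evaluation. Labels outside [0, T] are an
#' integrity error.
#'
#' @param path NIfTI label volume.
#' @param manifest A \linkS4class{DatasetManifest}.
#' @param expectedGrid Optional \linkS4class{Grid3D} the labels must match.
#' @return A \linkS4class{DoseLevelMap}.
#' @export
importPrediction <- function(path, manifest, expectedGrid = NULL) {
  stopifnot(is(manifest, "DatasetManifest"))
  lev <- readLevelMap(path, manifest@intervalPercent)
  Tlev <- manifestClassCounts(manifest)[["levels"]]
  if (max(lev@labels) > Tlev)
    stop("integrity error: prediction contains labels above T = ", Tlev,
         call. = FALSE)
  if (!is.null(expectedGrid) && !.sameGrid(lev@grid, expectedGrid))
    stop("geometry error: prediction grid does not match the case grid",
         call. = FALSE)
  lev
}

#' Patient-level train/validation/test split
#'
#' Assigns whole patients (all their fractions) to splits so no patient
#' straddles splits. Patient counts per split are the rounded fractions
#' (largest-remainder apportionment); patients are shuffled
#' deterministically by seed before assignment.
#'
#' @param patientIds Character/integer vector, one patient id per case.
#' @param fractions Numeric length-3 vector of train/validation/test
#'   proportions (summing to 1).
#' @param seed Integer seed.
#' @return Character vector parallel to \code{patientIds} with values
#'   \code{"train"}, \code{"validation"}, \code{"test"}.
#' @examples
#' split <- splitByPatient(rep(1:10, each = 5), c(0.6, 0.2, 0.2), seed = 7)
#' table(split)
#' @export
splitByPatient <- function(patientIds, fractions = c(0.6, 0.2, 0.2),
                           seed = 1L) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be three non-negative proportions summing to 1",
         call. = FALSE)
  pats <- unique(patientIds)
  if (length(pats) < sum(fractions > 0))
    stop("fewer patients than requested splits", call. = FALSE)
  nP <- length(pats)
  counts <- floor(fractions * nP)
  rem <- fractions * nP - counts
  short <- nP - sum(counts)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[give] <- counts[give] + 1L
  }
  shuffled <- .withSeed(seed, sample(pats))
  assign <- rep(c("train", "validation", "test"), times = counts)
  names(assign) <- as.character(shuffled)
  unname(assign[as.character(patientIds)])
}
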