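#' @include AllClasses.R adapter.R smoother.R evaluation.R phantom.R
NULL

#' End-to-end run configuration
#'
#' Validated configuration for \code{\link{runPipeline}}: the isodose
#' interval, avoidance weights, smoother settings, gamma criteria, the
#' ROIs to evaluate, the synthetic case to generate (or the input volumes
#' to use instead) and an optional output directory for intermediates.
#'
#' @slot intervalPercent Isodose interval i (must divide 120).
#' @slot weights \linkS4class{AvoidanceWeights}.
#' @slot smoother \linkS4class{SmootherConfig}.
#' @slot gammaCriteria List of \linkS4class{GammaCriteria}.
#' @slot rois Character vector of roles to evaluate.
#' @slot phantom \linkS4class{PhantomSpec} used when no explicit case is
#'   passed to \code{runPipeline}.
#' @slot outDir Output directory for intermediates, or \code{NA}.
#' @export
setClass("RunConfig",
  representation(intervalPercent = "numeric", weights = "AvoidanceWeights",
                 smoother = "SmootherConfig", gammaCriteria = "list",
                 rois = "character", phantom = "PhantomSpec",
                 outDir = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (abs(120 / object@intervalPercent -
          round(120 / object@intervalPercent)) > 1e-9)
    msg <- c(msg, "intervalPercent must divide 120")
  if (!all(vapply(object@gammaCriteria, is, TRUE, "GammaCriteria")))
    msg <- c(msg, "gammaCriteria must be a list of GammaCriteria")
  if (!all(object@rois %in% .ROLES))
    msg <- c(msg, "rois must be known structure roles")
  if (length(msg)) msg else TRUE
})

#' @param intervalPercent Isodose interval.
#' @param weights Avoidance weights.
#' @param smoother Smoother configuration.
#' @param gammaCriteria List of gamma criteria (default 3\%/2 mm and
#'   3\%/1 mm).
#' @param rois Roles to evaluate.
#' @param phantom Phantom specification for synthetic runs.
#' @param outDir Optional directory for NIfTI intermediates and the JSON
#'   report.
#' @return A \code{RunConfig}.
#' @rdname RunConfig-class
#' @export
RunConfig <- function(intervalPercent = 5,
                      weights = AvoidanceWeights(),
                      smoother = SmootherConfig(),
                      gammaCriteria = list(GammaCriteria(3, 2),
                                           GammaCriteria(3, 1)),
                      rois = c("GTV", "CTV", "PTV", "breast", "heart",
                               "ribs", "skin"),
                      phantom = PhantomSpec(),
                      outDir = NA_character_) {
  new("RunConfig", intervalPercent = as.numeric(intervalPercent),
      weights = weights, smoother = smoother,
      gammaCriteria = gammaCriteria, rois = rois, phantom = phantom,
      outDir = outDir)
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: interval ", object@intervalPercent, "%, sigma ",
      object@smoother@sigmaMm, " mm, ", length(object@gammaCriteria),
      " gamma criteria, ROIs: ", paste(object@rois, collapse = ", "),
      "\n", sep = "")
})

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Serialize an evaluation report to JSON
#'
#' Writes the report with stable key ordering and full numeric precision,
#' so identical runs produce byte-identical files.
#'
#' @param report An \linkS4class{EvalReport}.
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "EvalReport"))
  out <- list(
    meta = report@meta,
    voxel_mape_percent = as.list(report@roiMape),
    cumulative_dsc = report@cumulativeDsc,
    dvh = report@dvh,
    gamma = report@gpr)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Run the full dose-prediction pipeline on one case
#'
#' Orchestrates prepare - predict - smooth - evaluate: builds the two
#' input channels (avoidance, normalized prescribed dose), discretizes
#' the reference dose into the ground-truth level map, obtains a
#' prediction from the pluggable predictor, reconstructs and smooths it
#' to a continuous dose, and evaluates it against the reference. The run
#' is fully deterministic given a deterministic predictor. When
#' \code{config@outDir} is set, all intermediates (NIfTI) and the report
#' (JSON) are written there.
#'
#' @param config A \linkS4class{RunConfig}.
#' @param predictor Function \code{DoseLevelMap -> DoseLevelMap}
#'   (default the identity oracle).
#' @param case Optional list with \code{structures}, \code{dose},
#'   \code{rx} (as returned by \code{\link{generatePhantom}}); when
#'   \code{NULL}, \code{config@phantom} is generated.
#' @return An \linkS4class{EvalReport}.
#' @examples
#' cfg <- RunConfig(intervalPercent = 5,
#'                  phantom = PhantomSpec(gridSize = 48L,
#'                                        breastRadiusMm = 34,
#'                                        gtvRadiusMm = 6, ctvMarginMm = 3,
#'                                        ptvMarginMm = 3,
#'                                        heartOffsetMm = c(0, 0, -6)),
#'                  gammaCriteria = list(GammaCriteria(3, 2)))
#' rep <- runPipeline(cfg)
#' rep@gpr
#' @export
runPipeline <- function(config = RunConfig(),
                        predictor = mockPredictorOracle, case = NULL) {
  stopifnot(is(config, "RunConfig"))
  validObject(config)
  if (is.null(case))
    case <- .stage("simulate", generatePhantom(config@phantom))
  structures <- case$structures
  dose <- case$dose
  rx <- case$rx

  screen <- .stage("screen", qcScreenCase(dose, structures, rx))
  if (!screen$pass)
    warning("case failed the hotspot screen: ", screen$reason,
            call. = FALSE)

  avoid <- .stage("prepare", buildAvoidanceImage(structures, config@weights))
  rxChan <- .stage("prepare", buildPrescribedDoseChannel(structures, rx))
  rel <- .stage("prepare", normalizeDose(dose, rx))
  gtLevels <- .stage("prepare", discretizeDose(rel, config@intervalPercent))

  predLevels <- .stage("predict", predictor(gtLevels))
  if (!is(predLevels, "DoseLevelMap"))
    stop("[stage predict] predictor must return a DoseLevelMap",
         call. = FALSE)

  predDose <- .stage("smooth",
                     smoothPrediction(predLevels, rx, config@smoother))

  report <- .stage("evaluate", evaluatePlan(
    predDose, dose, predLevels, gtLevels, structures, rx,
    rois = config@rois, gammaCriteria = config@gammaCriteria,
    meta = list(interval_percent = config@intervalPercent,
                sigma_mm = config@smoother@sigmaMm,
                qc_pass = screen$pass,
                ctv_rx_gy = rx@ctvRxGy)))

  if (!is.na(config@outDir)) {
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    wf <- function(obj, nm) writeVolume(obj, file.path(config@outDir, nm))
    wf(avoid, "avoidance.nii.gz")
    wf(rxChan, "prescribed_dose.nii.gz")
    wf(dose, "reference_dose.nii.gz")
    wf(gtLevels, "reference_levels.nii.gz")
    wf(predLevels, "predicted_levels.nii.gz")
    wf(predDose, "predicted_dose.nii.gz")
    writeReport(report, file.path(config@outDir, "report.json"))
  }
  report
}
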