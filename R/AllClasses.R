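#' SessionRecord: one night of aligned 1 Hz sensor channels
#'
#' Container for a single overnight recording. All channels share one 1 Hz
#' time base: second \code{t} of the session is row/element \code{t + 1}
#' (time is counted in integer seconds since session start, from 0).
#' Pressure is an \code{n x 8} matrix, columns \code{p0..p7} ordered left to
#' right across the pillow. \code{lux} and \code{heartRate} are optional and
#' represented as zero-length vectors when absent (never zero-filled).
#'
#' Class validity enforces structure only (eight pressure columns, equal
#' channel lengths, no missing samples); physical range rules are reported by
#' [validateSession()] so that questionable recordings can be inspected
#' rather than refused outright.
#'
#' @slot startTime character scalar, ISO-8601 calendar start time ("" if unknown).
#' @slot pressure numeric matrix, n x 8, arbitrary non-negative force units.
#' @slot soundDb numeric, sound pressure level in dB.
#' @slot bodyTemp,roomTemp numeric, degrees Celsius.
#' @slot humidity numeric, relative humidity in percent.
#' @slot co2 numeric, ppm.
#' @slot lux numeric, illuminance (optional; length 0 when absent).
#' @slot heartRate numeric, bpm (optional; length 0 when absent).
#' @exportClass SessionRecord
setClass("SessionRecord",
  representation(
    startTime = "character",
    pressure  = "matrix",
    soundDb   = "numeric",
    bodyTemp  = "numeric",
    roomTemp  = "numeric",
    humidity  = "numeric",
    co2       = "numeric",
    lux       = "numeric",
    heartRate = "numeric"
  ),
  prototype(startTime = "")
)

setValidity("SessionRecord", function(object) {
  msgs <- character(0)
  p <- object@pressure
  if (ncol(p) != 8L)
    msgs <- c(msgs, sprintf(
      "pressure must have exactly 8 sensor columns, found %d", ncol(p)))
  n <- nrow(p)
  req <- c("soundDb", "bodyTemp", "roomTemp", "humidity", "co2")
  for (ch in req) {
    v <- slot(object, ch)
    if (length(v) != n)
      msgs <- c(msgs, sprintf(
        "channel '%s' has length %d, but the 1 Hz time base has %d samples",
        ch, length(v), n))
    if (anyNA(v))
      msgs <- c(msgs, sprintf("channel '%s' contains missing samples", ch))
  }
  for (ch in c("lux", "heartRate")) {
    v <- slot(object, ch)
    if (length(v) != 0L && length(v) != n)
      msgs <- c(msgs, sprintf(
        "optional channel '%s' must be absent (length 0) or length %d",
        ch, n))
    if (anyNA(v))
      msgs <- c(msgs, sprintf("channel '%s' contains missing samples", ch))
  }
  if (anyNA(p))
    msgs <- c(msgs, "pressure contains missing samples")
  if (length(object@startTime) != 1L)
    msgs <- c(msgs, "startTime must be a single character string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SessionRecord
#'
#' @param pressure numeric matrix (n x 8) or data.frame of eight pressure
#'   channels, sensor 0 (leftmost) to sensor 7 (rightmost).
#' @param soundDb,bodyTemp,roomTemp,humidity,co2 numeric vectors of length n.
#' @param lux,heartRate optional numeric vectors of length n, or `NULL`.
#' @param startTime ISO-8601 start timestamp, or `""`.
#' @return A validated [SessionRecord-class] object.
#' @examples
#' rec <- SessionRecord(
#'   pressure = matrix(10, nrow = 5, ncol = 8),
#'   soundDb = rep(25, 5), bodyTemp = rep(36.5, 5),
#'   roomTemp = rep(22.5, 5), humidity = rep(50, 5), co2 = rep(450, 5))
#' nSeconds(rec)
#' @export
SessionRecord <- function(pressure, soundDb, bodyTemp, roomTemp, humidity,
                          co2, lux = NULL, heartRate = NULL, startTime = "") {
  pressure <- as.matrix(pressure)
  storage.mode(pressure) <- "double"
  colnames(pressure) <- paste0("p", seq_len(ncol(pressure)) - 1L)
  new("SessionRecord",
      startTime = as.character(startTime),
      pressure  = pressure,
      soundDb   = as.numeric(soundDb),
      bodyTemp  = as.numeric(bodyTemp),
      roomTemp  = as.numeric(roomTemp),
      humidity  = as.numeric(humidity),
      co2       = as.numeric(co2),
      lux       = if (is.null(lux)) numeric(0) else as.numeric(lux),
      heartRate = if (is.null(heartRate)) numeric(0) else as.numeric(heartRate))
}

#' Hypnogram: epoch-indexed sleep-stage labels
#'
#' A sequence of stage labels (`"NREM"`, `"REM"`, `"WAKE"`) at fixed epoch
#' resolution. Epoch `e` (0-based) covers seconds `[e * epochLen,
#' (e + 1) * epochLen)`; the last epoch may cover a partial window.
#'
#' @slot labels character vector of stage labels.
#' @slot epochLen epoch length in seconds (> 0).
#' @exportClass Hypnogram
setClass("Hypnogram",
  representation(labels = "character", epochLen = "numeric"),
  prototype(epochLen = 60)
)

setValidity("Hypnogram", function(object) {
  msgs <- character(0)
  if (length(object@epochLen) != 1L || object@epochLen <= 0)
    msgs <- c(msgs, "epochLen must be a single positive number")
  bad <- setdiff(unique(object@labels), STAGES)
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown stage labels: %s",
                            paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a Hypnogram
#'
#' @param labels character vector over `"NREM"`, `"REM"`, `"WAKE"`.
#' @param epochLen epoch length in seconds (default 60).
#' @return A [Hypnogram-class] object.
#' @examples
#' Hypnogram(c("NREM", "NREM", "REM"), epochLen = 60)
#' @export
Hypnogram <- function(labels, epochLen = 60) {
  new("Hypnogram", labels = as.character(labels),
      epochLen = as.numeric(epochLen))
}

#' PostureModel: posture classifier specification
#'
#' Either a threshold heuristic on the pressure centroid
#' (`kind = "centroid"`) or a trained margin classifier
#' (`kind = "svm"`). Classification with a fixed model is deterministic.
#'
#' @slot kind `"centroid"` or `"svm"`.
#' @slot fit fitted classifier object (`NULL` for the heuristic).
#' @slot params named list of thresholds / hyperparameters.
#' @slot featureNames ordered feature names the model consumes.
#' @exportClass PostureModel
setClass("PostureModel",
  representation(kind = "character", fit = "ANY", params = "list",
                 featureNames = "character"))

setValidity("PostureModel", function(object) {
  if (!object@kind %in% c("centroid", "svm"))
    return("kind must be 'centroid' or 'svm'")
  TRUE
})

#' StagingModel: trained REM/NREM epoch classifier
#'
#' @slot kind `"decision_tree"` or `"random_forest"`.
#' @slot fit fitted model object.
#' @slot featureNames predictor names (heart-rate columns are never included).
#' @slot postureLevels factor levels used for the dominant-posture predictor.
#' @exportClass StagingModel
setClass("StagingModel",
  representation(kind = "character", fit = "ANY", featureNames = "character",
                 postureLevels = "character"))

setValidity("StagingModel", function(object) {
  if (!object@kind %in% c("decision_tree", "random_forest"))
    return("kind must be 'decision_tree' or 'random_forest'")
  if (any(grepl("^hr_", object@featureNames)))
    return("heart-rate columns must not be used as predictors")
  TRUE
})
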