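# Posture discrimination from the eight-sensor pillow pressure array.
#
# Sensor 0 is the leftmost FSR, sensor 7 the rightmost. By convention a
# pressure centroid towards low indices is read as the participant lying on
# their left; the mapping is configurable through the heuristic thresholds.

#' Pressure centroid of a frame
#'
#' Weighted mean of the sensor indices (0..7) by pressure, a scale-free
#' summary of where the head rests on the pillow.
#'
#' @param p numeric vector of 8 pressure readings.
#' @return coordinate in [0, 7].
#' @examples
#' pressureCentroid(c(0, 0, 0, 1, 1, 0, 0, 0))  # 3.5
#' @export
pressureCentroid <- function(p) {
  stopifnot(length(p) == 8L)
  tot <- sum(p)
  if (tot <= 0) stop("undefined centroid: total frame pressure is zero")
  sum((0:7) * p) / tot
}

#' Extract posture features from a pressure window
#'
#' The accumulated per-window feature vector feeding both the heuristic and
#' the margin classifier: the eight per-sensor means, the eight per-sensor
#' standard deviations, the centroid of the mean profile and the total mean
#' pressure (18 values, fixed order, deterministic).
#'
#' @param window numeric matrix (seconds x 8 sensors), one row per frame.
#' @return named numeric vector of length 18.
#' @export
extractPostureFeatures <- function(window) {
  window <- as.matrix(window)
  stopifnot(nrow(window) >= 1L, ncol(window) == 8L)
  mu <- colMeans(window)
  sds <- if (nrow(window) == 1L) rep(0, 8L) else apply(window, 2L, sd)
  tot <- sum(mu)
  centroid <- if (tot > 0) sum((0:7) * mu) / tot else 3.5  # empty pillow: center
  stats::setNames(c(mu, sds, centroid, tot),
                  c(paste0("p", 0:7, "_mean"), paste0("p", 0:7, "_sd"),
                    "centroid_of_means", "total_mean"))
}

#' Heuristic (centroid-threshold) posture model
#'
#' Classifies from the centroid of the mean pressure profile: `OFF_PILLOW`
#' if the mean total pressure falls below the presence threshold (5 percent
#' of the calibration head-on mean), `LEFT` if the centroid is at most
#' `cLo`, `RIGHT` if at least `cHi`, `SUPINE` otherwise. The default cuts
#' `cLo = 3`, `cHi = 4` put the symmetric center (3.5) in `SUPINE`.
#'
#' @param cLo,cHi centroid cuts (sensor-index units).
#' @param calibrationMean mean total head-on pressure used to derive the
#'   presence threshold (default 250, the nominal simulated head load).
#' @return a [PostureModel-class] of kind `"centroid"`.
#' @export
heuristicPostureModel <- function(cLo = 3.0, cHi = 4.0,
                                  calibrationMean = 250) {
  stopifnot(cLo < cHi, calibrationMean > 0)
  new("PostureModel", kind = "centroid", fit = NULL,
      params = list(cLo = cLo, cHi = cHi,
                    presenceThreshold = 0.05 * calibrationMean),
      featureNames = c("centroid_of_means", "total_mean"))
}

#' Classify a pressure window with the centroid heuristic
#'
#' @param window numeric matrix (seconds x 8).
#' @param model a centroid [PostureModel-class]
#'   (default [heuristicPostureModel()]).
#' @return one of `"SUPINE"`, `"LEFT"`, `"RIGHT"`, `"OFF_PILLOW"`.
#' @export
classifyPostureHeuristic <- function(window, model = heuristicPostureModel()) {
  stopifnot(model@kind == "centroid")
  f <- extractPostureFeatures(window)
  .heuristicLabel(f[["centroid_of_means"]], f[["total_mean"]], model@params)
}

.heuristicLabel <- function(centroid, total, params) {
  if (total < params$presenceThreshold) return("OFF_PILLOW")
  if (centroid <= params$cLo) "LEFT"
  else if (centroid >= params$cHi) "RIGHT"
  else "SUPINE"
}

#' Train the margin (SVM) posture classifier
#'
#' Fits a support-vector classifier with a radial kernel on per-window
#' posture features (see [extractPostureFeatures()]). Training with a fixed
#' seed is reproducible.
#'
#' @param features numeric matrix, one row per window (columns as produced
#'   by [extractPostureFeatures()]).
#' @param labels factor/character of posture labels, one per row; at least
#'   two classes with at least 10 windows each.
#' @param cost,gamma SVM hyperparameters (`gamma = NULL` uses the kernel
#'   default `1/ncol`).
#' @param seed RNG seed.
#' @return a [PostureModel-class] of kind `"svm"`.
#' @export
trainPostureClassifier <- function(features, labels, cost = 10,
                                   gamma = NULL, seed = 1) {
  features <- as.matrix(features)
  labels <- factor(labels)
  tab <- table(labels)
  if (length(tab) < 2L)
    stop("training requires at least two posture classes")
  if (any(tab < 10L))
    stop("training requires at least 10 windows per class")
  set.seed(seed)
  fit <- e1071::svm(x = features, y = labels, kernel = "radial",
                    cost = cost,
                    gamma = if (is.null(gamma)) 1 / ncol(features) else gamma,
                    scale = TRUE)
  new("PostureModel", kind = "svm", fit = fit,
      params = list(cost = cost, gamma = gamma, seed = seed),
      featureNames = colnames(features))
}

#' Predict postures from window features
#'
#' Deterministic given a fixed model. Works for both model kinds: the
#' heuristic uses only the centroid and total-pressure features, the margin
#' classifier consumes the full feature vector.
#'
#' @param model a [PostureModel-class].
#' @param features numeric matrix of window features (rows = windows), as
#'   produced by [extractPostureFeatures()].
#' @return character vector of posture labels.
#' @export
predictPosture <- function(model, features) {
  features <- if (is.null(dim(features))) matrix(features, nrow = 1L,
                                                 dimnames = list(NULL, names(features)))
              else as.matrix(features)
  if (model@kind == "centroid") {
    vapply(seq_len(nrow(features)), function(i)
      .heuristicLabel(features[i, "centroid_of_means"],
                      features[i, "total_mean"], model@params),
      character(1))
  } else {
    as.character(predict(model@fit, features[, model@featureNames,
                                             drop = FALSE]))
  }
}

#' Segment a night into posture intervals
#'
#' Classifies the pressure stream on a variable discrimination cycle: the
#' default window is `baseCycle` seconds, but whenever a rapid pressure
#' change (an inter-frame delta above the toss-and-turn threshold) lies
#' ahead within the base window, classification falls back to `minCycle`
#' windows until the deltas subside. Adjacent equal-posture windows are
#' merged; a `POSTURE_CHANGE` event is emitted at each boundary between
#' distinct postures.
#'
#' @param pressure n x 8 pressure matrix or [SessionRecord-class].
#' @param model a [PostureModel-class] (default [heuristicPostureModel()]).
#' @param baseCycle base discrimination cycle in seconds (default 60).
#' @param minCycle shortest cycle under rapid change (default 10 s).
#' @param tossThreshold pressure-delta threshold; `NULL` uses
#'   [defaultTossThreshold()].
#' @param hysteresis centroid margin (sensor-index units) that must be
#'   cleared before the running posture label may switch (centroid models
#'   only; default 0.2).
#' @return list with `segments` (data.frame `posture`, `start`, `end`,
#'   `duration`; segments tile the session) and `changes` (POSTURE_CHANGE
#'   event table, one per boundary).
#' @export
postureSegments <- function(pressure, model = heuristicPostureModel(),
                            baseCycle = 60, minCycle = 10,
                            tossThreshold = NULL, hysteresis = 0.2) {
  if (is(pressure, "SessionRecord")) pressure <- pressureMatrix(pressure)
  n <- nrow(pressure)
  stopifnot(n >= minCycle)
  thr <- tossThreshold %||% defaultTossThreshold(pressure)
  d <- streamDeltas(pressure)
  active <- !is.na(d) & d > thr

  starts <- integer(0); labels <- character(0)
  prevRows <- integer(0)
  t <- 0L
  while (t < n) {
    horizon <- min(t + baseCycle, n)
    wlen <- if (any(active[(t + 1L):horizon])) minCycle else baseCycle
    wend <- min(t + wlen, n)
    rows <- (t + 1L):wend
    # classify from the quiet frames: supra-threshold movement transients
    # carry no posture information and would distort the window profile
    quiet <- rows[!active[rows]]
    if (!length(quiet)) quiet <- rows
    f <- extractPostureFeatures(pressure[quiet, , drop = FALSE])
    prev <- if (length(labels)) labels[length(labels)] else NULL
    if (model@kind == "centroid" && !is.null(prev)) {
      # hysteresis: leaving the current posture requires the centroid to
      # clear the cut by `hysteresis`, so a profile sitting on a decision
      # boundary cannot flap between labels window-to-window
      pp <- model@params
      if (prev == "LEFT") pp$cLo <- pp$cLo + hysteresis
      if (prev == "RIGHT") pp$cHi <- pp$cHi - hysteresis
      if (prev == "SUPINE") { pp$cLo <- pp$cLo - hysteresis
                              pp$cHi <- pp$cHi + hysteresis }
      lab <- .heuristicLabel(f[["centroid_of_means"]], f[["total_mean"]], pp)
    } else {
      lab <- predictPosture(model, f)
    }
    # a posture cannot change without movement: only accept a label switch
    # if a supra-threshold delta occurred in this or the previous window
    # (the transition transient may sit just before the first window that
    # sees the new posture); guards against flapping when a profile sits
    # near a decision boundary
    if (!is.null(prev) && lab != prev &&
        !any(active[c(prevRows, rows)]))
      lab <- prev
    starts <- c(starts, t); labels <- c(labels, lab)
    prevRows <- rows
    t <- wend
  }

  keep <- c(TRUE, labels[-1L] != labels[-length(labels)])
  segs <- data.frame(posture = labels[keep],
                     start = as.integer(starts[keep]),
                     end = as.integer(c(starts[keep][-1L], n)),
                     stringsAsFactors = FALSE)
  segs$duration <- segs$end - segs$start
  bounds <- segs$start[-1L]
  changes <- makeEvents(kind = "POSTURE_CHANGE", start = bounds,
                        end = bounds + 1)
  list(segments = segs, changes = changes)
}
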