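#' @rdname SessionRecord-accessors
#' @export
setGeneric("nSeconds", function(x) standardGeneric("nSeconds"))
#' @rdname SessionRecord-accessors
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))
#' @rdname SessionRecord-accessors
#' @export
setGeneric("pressureMatrix", function(x) standardGeneric("pressureMatrix"))
#' @rdname SessionRecord-accessors
#' @export
setGeneric("soundDb", function(x) standardGeneric("soundDb"))
#' @rdname SessionRecord-accessors
#' @export
setGeneric("bodyTemp", function(x) standardGeneric("bodyTemp"))
#' @rdname SessionRecord-accessors
#' @export
setGeneric("roomTemp", function(x) standardGeneric("roomTemp"))
#' @rdname SessionRecord-accessors
#' @export
setGeneric("humidity", function(x) standardGeneric("humidity"))
#' @rdname SessionRecord-accessors
#' @export
setGeneric("co2", function(x) standardGeneric("co2"))
#' @rdname SessionRecord-accessors
#' @export
setGeneric("lux", function(x) standardGeneric("lux"))
#' @rdname SessionRecord-accessors
#' @export
setGeneric("heartRate", function(x) standardGeneric("heartRate"))
#' @rdname SessionRecord-accessors
#' @export
setGeneric("hasHeartRate", function(x) standardGeneric("hasHeartRate"))
#' @rdname SessionRecord-accessors
#' @export
setGeneric("hasLux", function(x) standardGeneric("hasLux"))

#' @rdname Hypnogram-accessors
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))
#' @rdname Hypnogram-accessors
#' @export
setGeneric("epochLen", function(x) standardGeneric("epochLen"))
#' @rdname Hypnogram-accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' Accessors for SessionRecord
#'
#' `nSeconds()` is the number of 1 Hz samples; channel accessors return the
#' stored vectors (`lux()`/`heartRate()` return `NULL` when the optional
#' channel is absent).
#'
#' @param x a [SessionRecord-class].
#' @name SessionRecord-accessors
#' @aliases nSeconds startTime pressureMatrix soundDb bodyTemp roomTemp
#'   humidity co2 lux heartRate hasHeartRate hasLux
NULL

setMethod("nSeconds", "SessionRecord", function(x) nrow(x@pressure))
setMethod("startTime", "SessionRecord", function(x) x@startTime)
setMethod("pressureMatrix", "SessionRecord", function(x) x@pressure)
setMethod("soundDb", "SessionRecord", function(x) x@soundDb)
setMethod("bodyTemp", "SessionRecord", function(x) x@bodyTemp)
setMethod("roomTemp", "SessionRecord", function(x) x@roomTemp)
setMethod("humidity", "SessionRecord", function(x) x@humidity)
setMethod("co2", "SessionRecord", function(x) x@co2)
setMethod("lux", "SessionRecord",
          function(x) if (length(x@lux)) x@lux else NULL)
setMethod("heartRate", "SessionRecord",
          function(x) if (length(x@heartRate)) x@heartRate else NULL)
setMethod("hasHeartRate", "SessionRecord",
          function(x) length(x@heartRate) > 0L)
setMethod("hasLux", "SessionRecord", function(x) length(x@lux) > 0L)

setMethod("show", "SessionRecord", function(object) {
  n <- nSeconds(object)
  opt <- c(if (hasLux(object)) "lux", if (hasHeartRate(object)) "heartRate")
  cat(sprintf("SessionRecord: %d s (%.1f min) at 1 Hz\n", n, n / 60))
  if (nzchar(object@startTime))
    cat("  start: ", object@startTime, "\n", sep = "")
  cat("  channels: pressure[8], soundDb, bodyTemp, roomTemp, humidity, co2",
      if (length(opt)) paste0(", ", paste(opt, collapse = ", ")) else "",
      "\n", sep = "")
})

#' Accessors for Hypnogram
#'
#' @param x a [Hypnogram-class].
#' @name Hypnogram-accessors
#' @aliases stageLabels epochLen nEpochs
NULL

setMethod("stageLabels", "Hypnogram", function(x) x@labels)
setMethod("epochLen", "Hypnogram", function(x) x@epochLen)
setMethod("nEpochs", "Hypnogram", function(x) length(x@labels))

setMethod("show", "Hypnogram", function(object) {
  tab <- table(factor(object@labels, levels = STAGES))
  cat(sprintf("Hypnogram: %d epochs of %g s\n", length(object@labels),
              object@epochLen))
  cat(sprintf("  NREM %d | REM %d | WAKE %d\n",
              tab[["NREM"]], tab[["REM"]], tab[["WAKE"]]))
})

setMethod("show", "PostureModel", function(object) {
  cat(sprintf("PostureModel (%s), %d features\n", object@kind,
              length(object@featureNames)))
})

setMethod("show", "StagingModel", function(object) {
  cat(sprintf("StagingModel (%s), predictors: %s\n", object@kind,
              paste(object@featureNames, collapse = ", ")))
})
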