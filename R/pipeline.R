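# End-to-end pipeline: session -> events -> features -> hypnogram ->
# night report (+ metrics when a heart-rate reference is available).
# The pipeline is a pure function of its configuration: fixed seeds give
# byte-identical outputs.

#' Pipeline configuration
#'
#' Collects every module's parameter block. Exactly one of `sessionPath`
#' (read a recorded session) or `simulate` (generate one; a list with
#' optional `params` overrides and a `seed`) must identify the input.
#'
#' @param sessionPath path to a session CSV (optionally gzipped), or `NULL`.
#' @param simulate `NULL`, or list with fields `params` (named overrides for
#'   [simParams()]) and `seed`.
#' @param outDir output directory for the artifact bundle.
#' @param tossTurn parameter list from [tossTurnParams()].
#' @param snore parameter list from [snoreParams()].
#' @param weights rule-based staging weights (move, snore, temp).
#' @param epochLen scoring epoch length in seconds.
#' @param mode staging mode: `"rule"`, `"rf"` or `"dt"` (tree modes train
#'   against the heart-rate reference and require the channel).
#' @param seed seed for any stochastic step.
#' @return named config list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(sessionPath = NULL, simulate = NULL,
                           outDir = tempfile("somnokit"),
                           tossTurn = tossTurnParams(),
                           snore = snoreParams(),
                           weights = c(move = 0.5, snore = 0.3, temp = 0.2),
                           epochLen = 60,
                           mode = c("rule", "rf", "dt"),
                           seed = 1) {
  mode <- match.arg(mode)
  if (is.null(sessionPath) && is.null(simulate))
    stop("config must provide sessionPath or simulate")
  structure(list(sessionPath = sessionPath, simulate = simulate,
                 outDir = outDir, tossTurn = tossTurn, snore = snore,
                 weights = weights, epochLen = epochLen, mode = mode,
                 seed = seed),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected by name; every field is optional (a fully
#' defaulted config is valid) apart from the input source.
#'
#' @param path JSON file.
#' @return a `pipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  allowed <- names(formals(pipelineConfig))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$tossTurn)) raw$tossTurn <- do.call(tossTurnParams, raw$tossTurn)
  if (!is.null(raw$snore)) raw$snore <- do.call(snoreParams, raw$snore)
  if (!is.null(raw$weights)) raw$weights <- unlist(raw$weights)
  do.call(pipelineConfig, raw)
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  path
}

#' Run the full monitoring pipeline
#'
#' Loads or simulates the session, segments postures, detects toss-and-turn
#' and snore events (with regularity flags), annotates heart-rate episodes
#' when the channel is present, builds the epoch feature table, scores
#' REM/NREM and writes the artifact bundle into `outDir`:
#' `events.json`, `hypnogram.json`, `report.json` (the per-stage night
#' summary, including parameter provenance) and `metrics.json` (when a
#' heart-rate reference is available). Deterministic given the config.
#'
#' @param config a `pipelineConfig`.
#' @return invisibly, a list with the in-memory objects (`session`,
#'   `segments`, `events`, `features`, `hypnogram`, `summary`, `metrics`)
#'   and the written `paths`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  session <- step("input", {
    if (!is.null(config$sessionPath)) readSession(config$sessionPath)
    else {
      sp <- do.call(simParams, config$simulate$params %||% list())
      simulateNight(sp, seed = config$simulate$seed %||% config$seed)$session
    }
  })

  seg <- step("posture", postureSegments(session))
  toss <- step("toss_turn",
               detectTossTurn(session, config$tossTurn, seg$segments))
  snore <- step("snore",
                snoreRegularity(detectSnoreEvents(session, config$snore),
                                config$snore))
  hrEv <- if (hasHeartRate(session))
    step("heart_rate", annotateHeartRate(session)) else makeEvents()
  events <- list(tossTurn = toss, snore = snore,
                 postureChange = seg$changes, heartRate = hrEv)

  features <- step("features",
                   epochFeatures(session, events, seg$segments,
                                 epochLen = config$epochLen))

  staged <- step("staging", {
    if (config$mode == "rule") {
      stageRuleBased(features, weights = config$weights,
                     epochLen = config$epochLen)
    } else {
      if (!hasHeartRate(session))
        stop("tree staging modes train against the heart-rate reference, ",
             "which is absent")
      ref <- hrReferenceHypnogram(session, epochLen = config$epochLen)
      m <- trainStageClassifier(
        features, ref,
        model = if (config$mode == "rf") "random_forest" else "decision_tree",
        seed = config$seed)
      prob <- predictStageProb(m, features)
      lab <- ifelse(prob >= 0.5, "REM", "NREM")
      list(hypnogram = Hypnogram(lab, epochLen = config$epochLen),
           scores = data.frame(epoch = features$epoch,
                               nrem_score = 1 - prob, label = lab,
                               stringsAsFactors = FALSE))
    }
  })

  metrics <- NULL
  if (hasHeartRate(session)) {
    ref <- hrReferenceHypnogram(session, epochLen = config$epochLen)
    if (length(unique(stageLabels(ref))) > 1L)
      metrics <- step("evaluate",
                      evaluateStaging(1 - staged$scores$nrem_score, ref))
  }

  summary <- step("summary",
                  summarizeNight(session, seg$segments, events,
                                 staged$hypnogram))

  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    events = .writeJson(events, file.path(config$outDir, "events.json")),
    hypnogram = .writeJson(
      list(epoch_len = epochLen(staged$hypnogram),
           labels = stageLabels(staged$hypnogram),
           scores = staged$scores),
      file.path(config$outDir, "hypnogram.json")),
    report = .writeJson(
      list(summary = summary,
           provenance = list(mode = config$mode, seed = config$seed,
                             epoch_len = config$epochLen,
                             weights = as.list(config$weights),
                             snore = config$snore,
                             toss_turn = config$tossTurn)),
      file.path(config$outDir, "report.json")))
  if (!is.null(metrics))
    paths$metrics <- .writeJson(
      metrics[c("accuracy", "precision", "recall", "f1", "auc",
                "roc_points")],
      file.path(config$outDir, "metrics.json"))

  invisible(list(session = session, segments = seg$segments,
                 events = events, features = features,
                 hypnogram = staged$hypnogram, scores = staged$scores,
                 summary = summary, metrics = metrics, paths = paths))
}

#' Render a human-readable night report
#'
#' Formats the per-stage summary (and optional metric suite) as markdown:
#' one section per scored stage with posture breakdown, movement and snore
#' counts and mean physiology/climate, plus a totals section. Absent
#' heart-rate fields render as `n/a`.
#'
#' @param summary output of [summarizeNight()].
#' @param metrics optional output of [evaluateStaging()].
#' @return character vector of markdown lines.
#' @export
renderReport <- function(summary, metrics = NULL) {
  fmt <- function(x, digits = 1)
    ifelse(is.na(x), "n/a", formatC(x, format = "f", digits = digits))
  lines <- c("# Night report", "")
  ps <- summary$perStage
  for (i in seq_len(nrow(ps))) {
    r <- ps[i, ]
    hdr <- if (r$stage == "TOTAL") "## Totals" else paste0("## ", r$stage,
                                                           " sleep")
    lines <- c(lines, hdr, "",
      sprintf("- duration: %s min", fmt(r$minutes)),
      sprintf("- tosses and turns: %d", r$toss_count),
      sprintf("- snores detected: %d", r$snore_count),
      sprintf("- mean heart rate: %s bpm", fmt(r$hr_mean)),
      sprintf("- mean CO2: %s ppm", fmt(r$co2_mean, 0)),
      sprintf("- mean room temperature: %s C", fmt(r$room_temp_mean)),
      sprintf("- mean humidity: %s %%", fmt(r$humidity_mean)))
    pm <- summary$postureMinutes
    pm <- pm[pm$stage == r$stage & pm$minutes > 0, , drop = FALSE]
    if (nrow(pm))
      lines <- c(lines, "- posture minutes:",
                 sprintf("  - %s: %s min", pm$posture, fmt(pm$minutes)))
    lines <- c(lines, "")
  }
  if (!is.null(metrics))
    lines <- c(lines, "## Staging metrics (vs heart-rate reference)", "",
      sprintf("- accuracy: %.3f", metrics$accuracy),
      sprintf("- precision: %.3f", metrics$precision),
      sprintf("- recall: %.3f", metrics$recall),
      sprintf("- F1-score: %.3f", metrics$f1),
      sprintf("- AUC: %.3f", metrics$auc), "")
  lines
}
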