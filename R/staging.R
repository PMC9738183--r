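# Two-stage (REM/NREM) sleep scoring.
#
# The per-epoch feature table realizes the three evidence streams of the
# sleep-state model: movement (toss-and-turn rate and duration), snoring
# (count, interval regularity, intensity) and temperature (artifact-masked
# body-temperature stability plus room temperature). Heart-rate columns are
# carried for reference only and are never consumed by the scorers: heart
# rate is the independent validation channel.

#' Per-epoch feature table
#'
#' Aggregates session channels, detected events and posture segments into
#' one row per scoring epoch. Events are attributed to the epoch containing
#' their onset; movement duration is attributed by interval overlap. Body
#' temperature is artifact-masked around posture changes before its mean and
#' standard deviation are taken.
#'
#' @param session a [SessionRecord-class].
#' @param events named list with elements `tossTurn` (from
#'   [detectTossTurn()]), `snore` (from [detectSnoreEvents()] +
#'   [snoreRegularity()]) and optionally `postureChange`.
#' @param segments posture segment data.frame (from [postureSegments()]).
#' @param epochLen epoch length in seconds (default 60).
#' @param tempPad artifact mask half-width in seconds (default 30).
#' @return data.frame, one row per epoch: `epoch` (0-based),
#'   `toss_turn_count`, `toss_turn_rate` (events/min), `toss_dur_s`,
#'   `snore_count`, `snore_regular_frac`, `snore_mean_intensity`,
#'   `body_temp_mean`, `body_temp_std`, `room_temp_mean`, `co2_mean`,
#'   `posture` (dominant), and `hr_mean`, `hr_std` when the heart-rate
#'   channel is present.
#' @export
epochFeatures <- function(session, events, segments, epochLen = 60,
                          tempPad = 30) {
  n <- nSeconds(session)
  if (n < epochLen)
    stop("session shorter than one epoch (", epochLen, " s)")
  nE <- ceiling(n / epochLen)
  eStart <- (seq_len(nE) - 1L) * epochLen
  eEnd <- pmin(eStart + epochLen, n)

  toss <- events$tossTurn %||% makeEvents()
  snore <- events$snore %||% makeEvents()
  pchg <- events$postureChange %||%
    makeEvents(kind = "POSTURE_CHANGE",
               start = segments$start[-1L],
               end = segments$start[-1L] + 1)

  bt <- maskTempArtifacts(bodyTemp(session), pchg, pad = tempPad)$masked

  overlap <- function(ev, lo, hi)
    sum(pmax(0, pmin(ev$end, hi) - pmax(ev$start, lo)))
  onsetsIn <- function(ev, lo, hi) which(ev$start >= lo & ev$start < hi)

  rows <- lapply(seq_len(nE), function(e) {
    lo <- eStart[e]; hi <- eEnd[e]
    sl <- (lo + 1L):hi
    winMin <- (hi - lo) / 60
    ti <- onsetsIn(toss, lo, hi)
    si <- onsetsIn(snore, lo, hi)
    reg <- if (length(si)) snore$regular[si] else logical(0)
    regDef <- reg[!is.na(reg)]
    btw <- bt[sl]
    out <- data.frame(
      epoch = e - 1L,
      toss_turn_count = length(ti),
      toss_turn_rate = length(ti) / winMin,
      toss_dur_s = overlap(toss, lo, hi),
      snore_count = length(si),
      snore_regular_frac = if (length(regDef)) mean(regDef) else NA_real_,
      snore_mean_intensity = if (length(si)) mean(snore$peak[si]) else NA_real_,
      body_temp_mean = if (all(is.na(btw))) NA_real_ else mean(btw, na.rm = TRUE),
      body_temp_std = if (sum(!is.na(btw)) > 1L) sd(btw, na.rm = TRUE) else NA_real_,
      room_temp_mean = mean(roomTemp(session)[sl]),
      co2_mean = mean(co2(session)[sl]),
      stringsAsFactors = FALSE)
    ov <- pmax(0, pmin(segments$end, hi) - pmax(segments$start, lo))
    out$posture <- segments$posture[which.max(ov)]
    if (hasHeartRate(session)) {
      hrw <- heartRate(session)[sl]
      out$hr_mean <- mean(hrw)
      out$hr_std <- if (length(hrw) > 1L) sd(hrw) else 0
    }
    out
  })
  do.call(rbind, rows)
}

#' Rule-based REM/NREM scorer
#'
#' A concrete linear-weighted realization of the sleep-state function over
#' the three evidence terms, each mapped to a bounded NREM-likeness score in
#' [0, 1]:
#' \itemize{
#'   \item movement: `s_move = 1 / (1 + toss_turn_rate * epochLen / 60)` --
#'     long maintained postures and little movement indicate NREM; frequent
#'     tossing indicates REM (reciprocal of the maintained-posture duration).
#'   \item snoring: `s_snore = snore_regular_frac` when the epoch contains
#'     snores, else 0.5 (no evidence) -- regular-interval snoring marks NREM,
#'     irregular marks REM.
#'   \item temperature: `s_temp = 1 / (1 + body_temp_std)` on the
#'     artifact-masked stream -- stable head temperature marks NREM; 0.5 when
#'     undefined.
#' }
#' `nrem_score = w_move * s_move + w_snore * s_snore + w_temp * s_temp`,
#' labelled NREM iff the score is at least 0.5. Heart-rate features are
#' never consumed (they form the validation reference).
#'
#' @param features feature table from [epochFeatures()].
#' @param weights named numeric weights `c(move=, snore=, temp=)`, summing
#'   to 1 (default `c(0.5, 0.3, 0.2)`).
#' @param epochLen epoch length in seconds (default 60).
#' @return list with `hypnogram` ([Hypnogram-class]) and `scores`
#'   (data.frame `epoch`, `nrem_score`, `label`).
#' @export
stageRuleBased <- function(features,
                           weights = c(move = 0.5, snore = 0.3, temp = 0.2),
                           epochLen = 60) {
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  sMove <- 1 / (1 + features$toss_turn_rate * epochLen / 60)
  sSnore <- ifelse(features$snore_count > 0 &
                     !is.na(features$snore_regular_frac),
                   features$snore_regular_frac, 0.5)
  sTemp <- ifelse(is.na(features$body_temp_std), 0.5,
                  1 / (1 + features$body_temp_std))
  score <- weights[["move"]] * sMove + weights[["snore"]] * sSnore +
    weights[["temp"]] * sTemp
  label <- ifelse(score >= 0.5, "NREM", "REM")
  list(hypnogram = Hypnogram(label, epochLen = epochLen),
       scores = data.frame(epoch = features$epoch, nrem_score = score,
                           label = label, stringsAsFactors = FALSE))
}

#' Heart-rate-derived reference hypnogram
#'
#' NREM sleep shows a slow, stable heart rate; REM sleep a higher and more
#' variable one. An epoch is scored NREM iff its mean heart rate is at most
#' `loMean` and its standard deviation at most `loStd`, else REM. This is
#' the binary validation reference against which the pressure/sound/
#' temperature scorers are evaluated; it deliberately shares no input
#' channel with them.
#'
#' @param hr numeric bpm stream or a [SessionRecord-class] with a heart-rate
#'   channel.
#' @param epochLen epoch length in seconds (default 60).
#' @param loMean,loStd NREM bounds (defaults 65 bpm and 5 bpm).
#' @return a [Hypnogram-class] over `NREM`/`REM`.
#' @export
hrReferenceHypnogram <- function(hr, epochLen = 60, loMean = 65, loStd = 5) {
  if (is(hr, "SessionRecord")) {
    if (!hasHeartRate(hr)) stop("heart-rate channel is absent")
    hr <- heartRate(hr)
  }
  if (is.null(hr) || !length(hr)) stop("heart-rate channel is absent")
  n <- length(hr)
  nE <- ceiling(n / epochLen)
  labs <- vapply(seq_len(nE), function(e) {
    sl <- ((e - 1L) * epochLen + 1L):min(e * epochLen, n)
    m <- mean(hr[sl])
    s <- if (length(sl) > 1L) sd(hr[sl]) else 0
    if (m <= loMean && s <= loStd) "NREM" else "REM"
  }, character(1))
  Hypnogram(labs, epochLen = epochLen)
}

# Predictor matrix for the tree classifiers: heart-rate columns are dropped
# and NAs are imputed with neutral values (0.5 regularity = no evidence, 0
# intensity = no snore, median temperature spread).
.stagePredictors <- function(features, postureLevels = POSTURES) {
  keep <- setdiff(names(features),
                  c("epoch", grep("^hr_", names(features), value = TRUE)))
  x <- features[keep]
  x$snore_regular_frac[is.na(x$snore_regular_frac)] <- 0.5
  x$snore_mean_intensity[is.na(x$snore_mean_intensity)] <- 0
  med <- median(x$body_temp_std, na.rm = TRUE)
  if (is.na(med)) med <- 0
  x$body_temp_std[is.na(x$body_temp_std)] <- med
  x$body_temp_mean[is.na(x$body_temp_mean)] <-
    median(x$body_temp_mean, na.rm = TRUE)
  x$posture <- factor(x$posture, levels = postureLevels)
  x
}

#' Train a tree-based REM/NREM classifier
#'
#' Fits a decision tree or random forest on the epoch feature table against
#' stage labels. WAKE labels are mapped to REM (two-stage scoring).
#' Heart-rate columns are excluded from the predictors by construction, and
#' training under a fixed seed is reproducible. The model exposes a
#' per-epoch REM probability (see [predictStageProb()]) for ROC analysis.
#'
#' @param features feature table from [epochFeatures()].
#' @param labels a [Hypnogram-class] or character vector of stage labels,
#'   one per epoch.
#' @param model `"random_forest"` (default) or `"decision_tree"`.
#' @param seed RNG seed.
#' @param ntree random-forest size (default 300).
#' @return a [StagingModel-class].
#' @export
trainStageClassifier <- function(features, labels,
                                 model = c("random_forest", "decision_tree"),
                                 seed = 1, ntree = 300) {
  model <- match.arg(model)
  if (is(labels, "Hypnogram")) labels <- stageLabels(labels)
  labels <- ifelse(labels == "WAKE", "REM", labels)
  y <- factor(labels, levels = c("NREM", "REM"))
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  x <- .stagePredictors(features)
  set.seed(seed)
  fit <- if (model == "random_forest") {
    randomForest::randomForest(x = x, y = y, ntree = ntree)
  } else {
    rpart::rpart(label ~ ., data = cbind(x, label = y), method = "class")
  }
  new("StagingModel", kind = model, fit = fit,
      featureNames = names(x), postureLevels = levels(x$posture))
}

#' Per-epoch REM probability from a staging model
#'
#' @param model a [StagingModel-class].
#' @param features feature table from [epochFeatures()].
#' @return numeric vector of REM probabilities in [0, 1].
#' @export
predictStageProb <- function(model, features) {
  x <- .stagePredictors(features, postureLevels = model@postureLevels)
  x <- x[model@featureNames]
  if (model@kind == "random_forest") {
    predict(model@fit, x, type = "prob")[, "REM"]
  } else {
    predict(model@fit, x, type = "prob")[, "REM"]
  }
}

#' Summarize a night per sleep stage
#'
#' The per-stage night summary: total minutes, posture-duration breakdown,
#' toss-and-turn and snore counts, and mean heart rate, CO2, room
#' temperature and humidity for each scored stage, plus a TOTAL row
#' (conservation: stage minutes sum to session minutes).
#'
#' @param session a [SessionRecord-class].
#' @param segments posture segment data.frame.
#' @param events named event list (as for [epochFeatures()]).
#' @param hypnogram a [Hypnogram-class] for the session.
#' @return list with `perStage` (one row per stage present + `TOTAL`) and
#'   `postureMinutes` (stage x posture minutes).
#' @export
summarizeNight <- function(session, segments, events, hypnogram) {
  n <- nSeconds(session)
  L <- epochLen(hypnogram)
  stageSec <- rep(stageLabels(hypnogram), each = L)[seq_len(n)]
  toss <- events$tossTurn %||% makeEvents()
  snore <- events$snore %||% makeEvents()

  stages <- intersect(STAGES, unique(stageSec))
  meanCh <- function(v, mask) if (is.null(v) || !any(mask)) NA_real_
                              else mean(v[mask])
  perStage <- do.call(rbind, lapply(stages, function(stg) {
    mask <- stageSec == stg
    secs <- which(mask) - 1L
    data.frame(
      stage = stg,
      minutes = sum(mask) / 60,
      toss_count = sum(!is.na(match(floor(toss$start), secs))),
      snore_count = sum(!is.na(match(floor(snore$start), secs))),
      hr_mean = meanCh(heartRate(session), mask),
      co2_mean = meanCh(co2(session), mask),
      room_temp_mean = meanCh(roomTemp(session), mask),
      humidity_mean = meanCh(humidity(session), mask),
      stringsAsFactors = FALSE)
  }))
  total <- data.frame(
    stage = "TOTAL", minutes = n / 60,
    toss_count = nrow(toss), snore_count = nrow(snore),
    hr_mean = meanCh(heartRate(session), rep(TRUE, n)),
    co2_mean = mean(co2(session)),
    room_temp_mean = mean(roomTemp(session)),
    humidity_mean = mean(humidity(session)),
    stringsAsFactors = FALSE)

  pm <- do.call(rbind, lapply(stages, function(stg) {
    mask <- stageSec == stg
    mins <- vapply(seq_len(nrow(segments)), function(i) {
      lo <- segments$start[i]; hi <- segments$end[i]
      sum(mask[(lo + 1L):min(hi, n)]) / 60
    }, numeric(1))
    agg <- tapply(mins, segments$posture, sum)
    data.frame(stage = stg, posture = names(agg),
               minutes = as.numeric(agg), stringsAsFactors = FALSE)
  }))
  rownames(perStage) <- rownames(pm) <- NULL
  list(perStage = rbind(perStage, total), postureMinutes = pm)
}
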