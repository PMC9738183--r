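# Event tables --------------------------------------------------------------
#
# Events are plain data.frames with one row per event and columns
#   kind     one of EVENT_KINDS
#   start    onset second (half-open interval [start, end))
#   end      exclusive end second (> start)
#   duration end - start
#   peak     kind-specific peak (max frame delta, peak dB, extreme bpm)
#   interval onset-to-onset gap to the previous event of the same kind (NA
#            for the first; only populated for SNORE)
# Detectors in this package always return tables satisfying
# validateEvents(): per kind sorted by onset and non-overlapping.

#' Construct an event table
#'
#' @param kind event kind (one of `r paste(EVENT_KINDS, collapse = ", ")`).
#' @param start,end numeric vectors; half-open intervals `[start, end)` in
#'   seconds since session start.
#' @param peak optional kind-specific peak values.
#' @param interval optional onset-to-onset gaps (seconds).
#' @return data.frame with columns `kind`, `start`, `end`, `duration`,
#'   `peak`, `interval`.
#' @export
makeEvents <- function(kind = character(0), start = numeric(0),
                       end = numeric(0), peak = NA_real_,
                       interval = NA_real_) {
  n <- length(start)
  df <- data.frame(kind = rep_len(as.character(kind), n),
                   start = as.numeric(start), end = as.numeric(end),
                   duration = as.numeric(end) - as.numeric(start),
                   peak = rep_len(as.numeric(peak), n),
                   interval = rep_len(as.numeric(interval), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$kind, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Check event-table invariants
#'
#' @param ev an event table (see [makeEvents()]).
#' @return character vector of violation messages; `character(0)` if valid.
#' @export
validateEvents <- function(ev) {
  msgs <- character(0)
  need <- c("kind", "start", "end")
  if (!all(need %in% names(ev)))
    return(sprintf("missing columns: %s",
                   paste(setdiff(need, names(ev)), collapse = ", ")))
  bad <- setdiff(unique(ev$kind), EVENT_KINDS)
  if (length(bad))
    msgs <- c(msgs, sprintf("unknown event kinds: %s",
                            paste(bad, collapse = ", ")))
  if (any(ev$end <= ev$start))
    msgs <- c(msgs, "events must satisfy end > start (half-open [start, end))")
  for (k in unique(ev$kind)) {
    e <- ev[ev$kind == k, , drop = FALSE]
    if (is.unsorted(e$start))
      msgs <- c(msgs, sprintf("%s events are not sorted by onset", k))
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)]))
      msgs <- c(msgs, sprintf("%s events overlap", k))
  }
  msgs
}

# Detectors ------------------------------------------------------------------

#' Inter-frame pressure delta
#'
#' The movement statistic: the sum over the eight pillow sensors of the
#' absolute change in pressure between consecutive seconds,
#' `sum_i |p_i(t) - p_i(t-1)|`. Toss-and-turn detection compares this
#' statistic against a threshold.
#'
#' @param curr,prev numeric vectors of 8 pressure readings.
#' @return scalar delta in pressure units.
#' @examples
#' frameDelta(c(1, 2, 3, 0, 0, 0, 0, 0), rep(0, 8))  # 6
#' @export
frameDelta <- function(curr, prev) {
  stopifnot(length(curr) == 8L, length(prev) == 8L)
  sum(abs(curr - prev))
}

# Per-second deltas for a pressure matrix; element t+1 is the delta at
# second t (comparing t against t-1). First element is NA.
streamDeltas <- function(pressure) {
  if (nrow(pressure) < 2L) return(rep(NA_real_, nrow(pressure)))
  c(NA_real_, rowSums(abs(diff(pressure))))
}

#' Default toss-and-turn threshold
#'
#' The printed form of the movement rule defines the delta statistic but not
#' a numeric cut; the default threshold is `mult` times the median nightly
#' delta, which is robust to the arbitrary FSR sensor scale.
#'
#' @param pressure n x 8 pressure matrix.
#' @param mult multiplier on the median delta (default 4).
#' @return threshold in pressure-delta units.
#' @export
defaultTossThreshold <- function(pressure, mult = 4) {
  d <- streamDeltas(pressure)
  thr <- mult * median(d, na.rm = TRUE)
  max(thr, .Machine$double.eps)
}

#' Toss-and-turn detector parameters
#'
#' @param threshold pressure-delta threshold; `NULL` means
#'   [defaultTossThreshold()] computed from the stream.
#' @param quiescence seconds of sub-threshold deltas that close an event
#'   (default 5: no change in pressure for 5 s means movement has stopped).
#' @param mergeWithinPosture merge events separated by less than
#'   `quiescence` seconds within one posture segment?
#' @return parameter list.
#' @export
tossTurnParams <- function(threshold = NULL, quiescence = 5,
                           mergeWithinPosture = TRUE) {
  stopifnot(is.null(threshold) || threshold > 0, quiescence >= 1)
  list(threshold = threshold, quiescence = as.integer(quiescence),
       mergeWithinPosture = isTRUE(mergeWithinPosture))
}

#' Detect toss-and-turn events from the pillow pressure stream
#'
#' An event opens at the first second whose inter-frame delta exceeds the
#' threshold and closes once the delta has stayed at or below the threshold
#' for `quiescence` consecutive seconds; the event interval covers the
#' supra-threshold activity `[first_active, last_active + 1)`. Sub-threshold
#' movement never opens an event. Event duration is first-class output:
#' for sleep staging the duration of movement matters more than its count.
#'
#' @param pressure n x 8 pressure matrix (or [SessionRecord-class]).
#' @param params [tossTurnParams()].
#' @param segments optional posture segments (from [postureSegments()]);
#'   when given and `mergeWithinPosture` is set, events closer than
#'   `quiescence` seconds within one segment are merged.
#' @return event table of kind `TOSS_TURN` with `peak` = maximal delta.
#' @export
detectTossTurn <- function(pressure, params = tossTurnParams(),
                           segments = NULL) {
  if (is(pressure, "SessionRecord")) pressure <- pressureMatrix(pressure)
  n <- nrow(pressure)
  stopifnot(n >= 2L)
  thr <- params$threshold %||% defaultTossThreshold(pressure)
  q <- params$quiescence
  d <- streamDeltas(pressure)

  starts <- ends <- peaks <- numeric(0)
  open <- FALSE; s0 <- 0L; lastActive <- 0L; peak <- 0
  for (t in seq_len(n - 1L)) {          # second t, delta d[t + 1]
    active <- d[t + 1L] > thr
    if (!open && active) {
      open <- TRUE; s0 <- t; lastActive <- t; peak <- d[t + 1L]
    } else if (open && active) {
      lastActive <- t; peak <- max(peak, d[t + 1L])
    } else if (open && !active && (t - lastActive) >= q) {
      starts <- c(starts, s0); ends <- c(ends, lastActive + 1L)
      peaks <- c(peaks, peak); open <- FALSE
    }
  }
  if (open) {
    starts <- c(starts, s0); ends <- c(ends, lastActive + 1L)
    peaks <- c(peaks, peak)
  }
  ev <- makeEvents(kind = "TOSS_TURN", start = starts, end = ends,
                   peak = peaks)
  if (params$mergeWithinPosture && nrow(ev) > 1L)
    ev <- .mergeClose(ev, gap = q, segments = segments)
  ev
}

# Merge events whose separation is below `gap`; when posture segments are
# supplied, only events inside the same segment are merged.
.mergeClose <- function(ev, gap, segments = NULL) {
  segOf <- function(s) {
    if (is.null(segments)) return(rep(1L, length(s)))
    findInterval(s, segments$start)
  }
  seg <- segOf(ev$start)
  keep <- list(ev[1L, ])
  for (i in seq_len(nrow(ev))[-1L]) {
    prev <- keep[[length(keep)]]
    if (ev$start[i] - prev$end < gap && seg[i] == segOf(prev$start)) {
      prev$end <- max(prev$end, ev$end[i])
      prev$duration <- prev$end - prev$start
      prev$peak <- max(prev$peak, ev$peak[i])
      keep[[length(keep)]] <- prev
    } else {
      keep[[length(keep) + 1L]] <- ev[i, ]
    }
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' Snore detector parameters
#'
#' @param dbThreshold sound level that triggers capture (default 30 dB).
#' @param maxCapture maximum capture length in seconds (default 15).
#' @param rearmDelay dead time after a capture closes before the detector
#'   re-arms (default 2 s).
#' @param regularityWindow number of onset-to-onset intervals per sliding
#'   regularity window (default 5).
#' @param cvRegularMax coefficient-of-variation cut below which a window of
#'   intervals counts as regular (default 0.25).
#' @return parameter list.
#' @export
snoreParams <- function(dbThreshold = 30, maxCapture = 15, rearmDelay = 2,
                        regularityWindow = 5, cvRegularMax = 0.25) {
  stopifnot(dbThreshold > 0, maxCapture >= 1, rearmDelay >= 0,
            regularityWindow >= 2, cvRegularMax > 0)
  list(dbThreshold = dbThreshold, maxCapture = as.integer(maxCapture),
       rearmDelay = as.integer(rearmDelay),
       regularityWindow = as.integer(regularityWindow),
       cvRegularMax = cvRegularMax)
}

#' Detect snore events from the sound-pressure-level stream
#'
#' A capture opens at the first sample above `dbThreshold` and closes when
#' the level falls to or below the threshold or when `maxCapture` seconds
#' have elapsed, whichever comes first. After a close the detector is dead
#' for `rearmDelay` seconds. Distinct threshold crossings are distinct
#' events, so several snores inside one notional capture window are counted
#' separately.
#'
#' @param soundDb numeric SPL stream (dB) or [SessionRecord-class].
#' @param params [snoreParams()].
#' @return event table of kind `SNORE`; `peak` is the maximum dB in the
#'   capture, `interval` the onset-to-onset gap to the previous event.
#' @export
detectSnoreEvents <- function(soundDb, params = snoreParams()) {
  if (is(soundDb, "SessionRecord")) soundDb <- soundDb(soundDb)
  n <- length(soundDb)
  thr <- params$dbThreshold
  starts <- ends <- peaks <- numeric(0)
  t <- 0L
  while (t < n) {
    if (soundDb[t + 1L] > thr) {
      u <- t + 1L
      while (u < n && (u - t) < params$maxCapture && soundDb[u + 1L] > thr)
        u <- u + 1L
      starts <- c(starts, t); ends <- c(ends, u)
      peaks <- c(peaks, max(soundDb[(t + 1L):u]))
      t <- u + params$rearmDelay
    } else {
      t <- t + 1L
    }
  }
  iv <- c(NA_real_, diff(starts))
  makeEvents(kind = "SNORE", start = starts, end = ends, peak = peaks,
             interval = if (length(starts)) iv else NA_real_)
}

#' Snore-interval regularity
#'
#' Regular snoring at roughly constant intervals marks NREM sleep; irregular
#' snoring marks REM. For each event the coefficient of variation
#' (CV = sd/mean) is computed over the window of the preceding
#' `regularityWindow` onset-to-onset intervals; the event is flagged regular
#' iff CV <= `cvRegularMax`. Events without a full window of preceding
#' intervals get an undefined (`NA`) flag.
#'
#' @param events SNORE event table from [detectSnoreEvents()].
#' @param params [snoreParams()].
#' @return `events` with columns `cv` and `regular` appended.
#' @export
snoreRegularity <- function(events, params = snoreParams()) {
  w <- params$regularityWindow
  n <- nrow(events)
  cv <- rep(NA_real_, n)
  if (n >= 2L) {
    iv <- events$start[-1L] - events$start[-n]   # interval i = onset_{i+1} - onset_i
    for (i in seq_len(n)) {
      # intervals ending at event i: iv[(i-w) .. (i-1)]
      if (i - 1L >= w) {
        win <- iv[(i - w):(i - 1L)]
        cv[i] <- sd(win) / mean(win)
      }
    }
  }
  events$cv <- cv
  events$regular <- ifelse(is.na(cv), NA, cv <= params$cvRegularMax)
  events
}

#' Interval coefficient of variation
#'
#' @param intervals numeric vector of onset-to-onset gaps (seconds).
#' @return `sd(intervals) / mean(intervals)`.
#' @export
intervalCV <- function(intervals) {
  stopifnot(length(intervals) >= 2L)
  sd(intervals) / mean(intervals)
}

#' Classify a CO2 concentration into air-quality bands
#'
#' Left-closed, right-open bands: GOOD below 400 ppm, AVERAGE in
#' [400, 700), POOR in [700, 1000), VERY_POOR at or above 1000 ppm.
#'
#' @param ppm numeric vector of CO2 concentrations (ppm, >= 0).
#' @return factor over `GOOD < AVERAGE < POOR < VERY_POOR`.
#' @examples
#' classifyCO2(c(350, 400, 1200))
#' @export
classifyCO2 <- function(ppm) {
  if (any(!is.finite(ppm)) || any(ppm < 0))
    stop("CO2 concentration must be finite and >= 0 ppm")
  bands <- c("GOOD", "AVERAGE", "POOR", "VERY_POOR")
  factor(bands[findInterval(ppm, c(400, 700, 1000)) + 1L],
         levels = bands, ordered = TRUE)
}

#' Annotate bradycardia and tachycardia episodes
#'
#' Maximal runs with heart rate strictly below 60 bpm become BRADYCARDIA
#' events and runs strictly above 100 bpm become TACHYCARDIA events, each
#' only when the run lasts at least `minDuration` seconds (suppressing
#' single-sample flicker).
#'
#' @param hr numeric bpm stream or a [SessionRecord-class] with a heart-rate
#'   channel.
#' @param minDuration minimum episode length in seconds (default 5).
#' @param bradyBelow,tachyAbove episode bounds (defaults 60 and 100 bpm,
#'   strict inequalities).
#' @return event table of kinds `BRADYCARDIA` / `TACHYCARDIA`; `peak` is the
#'   most extreme bpm in the episode.
#' @export
annotateHeartRate <- function(hr, minDuration = 5, bradyBelow = 60,
                              tachyAbove = 100) {
  if (is(hr, "SessionRecord")) {
    if (!hasHeartRate(hr)) stop("heart-rate channel is absent")
    hr <- heartRate(hr)
  }
  if (is.null(hr) || !length(hr)) stop("heart-rate channel is absent")
  cls <- ifelse(hr < bradyBelow, "B", ifelse(hr > tachyAbove, "T", "N"))
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths          # 0-based onsets
  keep <- r$values != "N" & r$lengths >= minDuration
  if (!any(keep)) return(makeEvents())
  kind <- ifelse(r$values[keep] == "B", "BRADYCARDIA", "TACHYCARDIA")
  peak <- mapply(function(s, e, k) {
    seg <- hr[(s + 1L):e]
    if (k == "BRADYCARDIA") min(seg) else max(seg)
  }, starts[keep], ends[keep], kind)
  makeEvents(kind = kind, start = starts[keep], end = ends[keep],
             peak = peak)
}

#' Mask posture-change artifacts in the body-temperature stream
#'
#' The contactless sensor aims at the head, so a posture change makes the
#' reading drop spuriously (to around 33.5--34 degrees C). Samples within
#' `pad` seconds of any posture-change boundary are flagged as artifacts and
#' excluded (set `NA`) from downstream temperature statistics.
#'
#' @param bodyTemp numeric body-temperature stream (degrees C).
#' @param postureChanges POSTURE_CHANGE event table (boundary = `start`) or
#'   a numeric vector of boundary seconds.
#' @param pad half-width of the exclusion window in seconds (default 30).
#' @return list with `masked` (stream with artifacts set `NA`) and `flags`
#'   (logical vector, TRUE where flagged).
#' @export
maskTempArtifacts <- function(bodyTemp, postureChanges, pad = 30) {
  n <- length(bodyTemp)
  bounds <- if (is.data.frame(postureChanges)) postureChanges$start
            else as.numeric(postureChanges)
  flags <- rep(FALSE, n)
  for (b in bounds) {
    lo <- max(0L, floor(b - pad)); hi <- min(n - 1L, ceiling(b + pad))
    if (lo <= hi) flags[(lo + 1L):(hi + 1L)] <- TRUE
  }
  masked <- bodyTemp
  masked[flags] <- NA_real_
  list(masked = masked, flags = flags)
}
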