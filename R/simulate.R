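# Synthetic full-night session simulator.
#
# Generates SessionRecords with complete ground truth so that every pipeline
# stage is testable without the pillow hardware. The generative regime
# mirrors the reported signal structure: posture-dependent pressure profiles
# over the eight FSR positions, movement transients, short >=30 dB snore
# bursts at regular ~3 s intervals in NREM and irregular ones in REM,
# stage-dependent heart rate with bradycardia/tachycardia episodes,
# overnight CO2 drift, and spurious body-temperature dips at posture
# changes.
#
# Each channel draws from its own seeded substream, so adding or resizing
# one channel never perturbs another channel's stream.

#' Simulation parameters
#'
#' Returns the default generative regime for a synthetic night; any field
#' may be overridden by name. Defaults: four 90 min sleep cycles over 6 h,
#' REM fraction interpolating 0.15 to 0.35 across cycles, a terminal 5 min
#' WAKE tail; snore onset intervals N(3, 0.3) s in NREM and N(6, 4) s in REM
#' (floored at the 3 s resolvable minimum on the 1 Hz grid), burst level
#' N(40, 3) dB over a 25 dB floor; heart rate N(58, 2) bpm in NREM,
#' N(75, 8) in REM with sparse bradycardia (54 bpm) and tachycardia
#' (105 bpm) episodes; CO2 drifting +60 ppm/h from 450 ppm with +10 ppm
#' bumps during snores; body temperature 36.5 C dipping to 33.5--34.0 C at
#' posture changes; room temperature held in the 22--23 C band.
#'
#' @param ... named overrides of any default field.
#' @return named list of class `simParams`.
#' @export
simParams <- function(...) {
  p <- list(
    durationS = 21600, epochLen = 60, cycleLenS = 5400,
    remFracStart = 0.15, remFracEnd = 0.35, wakeTailS = 300,
    # movement
    postureChangeRatePerRemHour = 3,
    movementRatePerHour = c(NREM = 4, REM = 60, WAKE = 120),
    movementDurS = c(2, 4), transientDurS = 3, transientAmp = 40,
    # pressure
    pressureProfiles = rbind(
      SUPINE = c(5, 15, 45, 80, 80, 45, 15, 5),
      LEFT   = c(70, 80, 50, 20, 8, 3, 1, 1),
      RIGHT  = c(1, 1, 3, 8, 20, 50, 80, 70)),
    pressureNoiseSd = 3, headShiftSd = 0.5, amplitudeLogSd = 0.1,
    # snoring
    snoreIntervalMean = c(NREM = 3, REM = 6),
    snoreIntervalSd = c(NREM = 0.3, REM = 4),
    snoreMinIntervalS = 3, snoreBurstDurS = 1,
    snoreDbMean = 40, snoreDbSd = 3, snoreDbMin = 30.5,
    soundFloorDb = 25, soundNoiseSd = 1,
    # heart rate
    hrMean = c(NREM = 58, REM = 75, WAKE = 80),
    hrSd = c(NREM = 2, REM = 8, WAKE = 5),
    bradyRatePerNremHour = 0.5, bradyLevel = 54,
    tachyRatePerRemHour = 0.5, tachyLevel = 105,
    episodeDurS = c(30, 90),
    # environment
    co2Start = 450, co2DriftPerHour = 60, co2NoiseSd = 5, co2SnoreBump = 10,
    bodyTempBase = 36.5, bodyTempNoiseSd = 0.05,
    tempDipLow = 33.5, tempDipHigh = 34.0, tempDipHoldS = 15,
    tempDipRecoverS = 30,
    roomTempBase = 22.5, roomTempAmp = 0.35, roomTempNoiseSd = 0.05,
    humidityBase = 50, humidityDriftPerHour = 0.5, humidityNoiseSd = 1,
    luxBase = 0.5, luxNoiseSd = 0.2,
    includeLux = TRUE, includeHeartRate = TRUE)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown))
    stop("unknown simulation parameters: ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  structure(p, class = "simParams")
}

# Independent substreams: one deterministic seed per named channel.
.subSeed <- function(seed, id) {
  (abs(as.integer(seed)) %% 1000003L) * 2039L + as.integer(id)
}

#' Simulate a ground-truth hypnogram
#'
#' Builds alternating NREM/REM blocks per sleep cycle with the REM fraction
#' interpolating linearly from `remFracStart` (first cycle) to `remFracEnd`
#' (last), followed by a terminal WAKE tail. Deterministic given the
#' parameters.
#'
#' @param params [simParams()].
#' @param seed unused (kept for interface symmetry); the schedule is
#'   deterministic.
#' @return a [Hypnogram-class].
#' @export
simulateHypnogram <- function(params = simParams(), seed = 1) {
  L <- params$epochLen
  epc <- params$cycleLenS / L                 # epochs per cycle
  nCycles <- floor(params$durationS / params$cycleLenS)
  stopifnot(nCycles >= 1)
  fracs <- if (nCycles == 1) params$remFracStart
           else seq(params$remFracStart, params$remFracEnd,
                    length.out = nCycles)
  labs <- unlist(lapply(seq_len(nCycles), function(k) {
    nRem <- round(fracs[k] * epc + 1e-9)   # stabilize half-integer rounding
    c(rep("NREM", epc - nRem), rep("REM", nRem))
  }))
  extra <- floor(params$durationS / L) - length(labs)
  if (extra > 0) labs <- c(labs, rep("NREM", extra))
  nWake <- min(length(labs), round(params$wakeTailS / L))
  if (nWake > 0) labs[(length(labs) - nWake + 1L):length(labs)] <- "WAKE"
  Hypnogram(labs, epochLen = L)
}

# Shift a sensor profile sideways by a fractional number of sensor
# positions (head repositioning), clamped at the pillow edges.
.shiftProfile <- function(profile, shift) {
  stats::approx(0:7, profile, xout = (0:7) - shift, rule = 2)$y
}

# Poisson onsets restricted to an allowed set of seconds.
.sampleOnsets <- function(allowedSecs, ratePerHour) {
  if (!length(allowedSecs) || ratePerHour <= 0) return(integer(0))
  k <- rpois(1, ratePerHour * length(allowedSecs) / 3600)
  k <- min(k, length(allowedSecs))
  if (k == 0) return(integer(0))
  sort(sample(allowedSecs, k))
}

#' Simulate a full-night session with ground truth
#'
#' Generates every channel at 1 Hz over the scheduled hypnogram: a posture
#' schedule with changes placed in REM/WAKE epochs, pressure from
#' per-posture profiles with head-shift and load variation plus movement
#' transients that exceed the toss-and-turn threshold, a stage-conditioned
#' snore point process (regular intervals in NREM, irregular in REM),
#' stage-conditioned heart rate with injected bradycardia/tachycardia
#' episodes, CO2 drift with snore bumps, body-temperature artifacts
#' co-located with posture changes, and room climate. Identical
#' `(params, seed)` give bit-identical output.
#'
#' @param hypnogram truth [Hypnogram-class] (e.g. [simulateHypnogram()]).
#' @param params [simParams()].
#' @param seed integer seed; each channel derives its own substream.
#' @return list with `session` ([SessionRecord-class]) and `truth` (list:
#'   `hypnogram`, `postureSchedule`, `postureChanges`, `tossEvents`,
#'   `snoreOnsets`, `bradyEvents`, `tachyEvents`, `params`, `seed`).
#' @export
simulateSession <- function(hypnogram, params = simParams(), seed = 1) {
  L <- epochLen(hypnogram)
  stageSec <- rep(stageLabels(hypnogram), each = L)
  n <- min(length(stageSec), params$durationS)
  stageSec <- stageSec[seq_len(n)]
  secs <- seq_len(n) - 1L

  ## --- posture schedule -----------------------------------------------
  set.seed(.subSeed(seed, 1L))
  remwake <- secs[stageSec %in% c("REM", "WAKE")]
  remwake <- remwake[remwake > 120 & remwake < n - 120]
  chg <- .sampleOnsets(remwake, params$postureChangeRatePerRemHour)
  if (length(chg) > 1L) chg <- chg[c(TRUE, diff(chg) >= 120)]
  postures <- character(length(chg) + 1L)
  postures[1L] <- "SUPINE"
  for (i in seq_along(chg))
    postures[i + 1L] <- sample(setdiff(c("SUPINE", "LEFT", "RIGHT"),
                                       postures[i]), 1L)
  segStart <- c(0L, chg)
  segEnd <- c(chg, n)
  schedule <- data.frame(posture = postures, start = segStart, end = segEnd,
                         duration = segEnd - segStart,
                         stringsAsFactors = FALSE)

  ## --- movement events -------------------------------------------------
  set.seed(.subSeed(seed, 2L))
  moveOn <- integer(0)
  for (stg in STAGES) {
    allowed <- secs[stageSec == stg]
    allowed <- allowed[allowed > 10 & allowed < n - 10]
    moveOn <- c(moveOn, .sampleOnsets(allowed,
                                      params$movementRatePerHour[[stg]]))
  }
  moveOn <- sort(unique(moveOn))
  moveDur <- if (length(moveOn))
    sample(params$movementDurS[1]:params$movementDurS[2],
           length(moveOn), replace = TRUE) else integer(0)
  # posture-change transients are movements too
  tossStart <- c(moveOn, chg)
  tossDur <- c(moveDur, rep(params$transientDurS, length(chg)))
  o <- order(tossStart)
  tossEvents <- data.frame(start = tossStart[o],
                           end = pmin(tossStart[o] + tossDur[o], n))
  # collapse onsets too close to resolve as separate detections
  if (nrow(tossEvents) > 1L) {
    keep <- c(TRUE, diff(tossEvents$start) >= 10)
    tossEvents <- tossEvents[keep, , drop = FALSE]
  }

  ## --- pressure ---------------------------------------------------------
  set.seed(.subSeed(seed, 3L))
  pressure <- matrix(0, nrow = n, ncol = 8L)
  for (i in seq_len(nrow(schedule))) {
    shift <- rnorm(1, 0, params$headShiftSd)
    amp <- exp(rnorm(1, 0, params$amplitudeLogSd))
    prof <- amp * .shiftProfile(params$pressureProfiles[schedule$posture[i], ],
                                shift)
    rows <- (schedule$start[i] + 1L):schedule$end[i]
    pressure[rows, ] <- matrix(prof, nrow = length(rows), ncol = 8L,
                               byrow = TRUE)
  }
  if (params$pressureNoiseSd > 0)
    pressure <- pressure + matrix(rnorm(n * 8L, 0, params$pressureNoiseSd),
                                  n, 8L)
  moveMask <- rep(FALSE, n)
  for (i in seq_len(nrow(tossEvents)))
    moveMask[(tossEvents$start[i] + 1L):tossEvents$end[i]] <- TRUE
  nm <- sum(moveMask)
  if (nm > 0 && params$transientAmp > 0)
    pressure[moveMask, ] <- pressure[moveMask, ] +
      abs(matrix(rnorm(nm * 8L, 0, params$transientAmp), nm, 8L))
  pressure <- pmax(pressure, 0)

  ## --- snoring / sound --------------------------------------------------
  set.seed(.subSeed(seed, 4L))
  sound <- params$soundFloorDb + rnorm(n, 0, params$soundNoiseSd)
  snoreOn <- integer(0); snoreStage <- character(0)
  r <- rle(stageSec)
  blockEnd <- cumsum(r$lengths)
  blockStart <- blockEnd - r$lengths
  for (b in seq_along(r$values)) {
    stg <- r$values[b]
    if (stg == "WAKE") next
    t <- blockStart[b] + sample(2:5, 1L)
    while (t + params$snoreBurstDurS < blockEnd[b]) {
      snoreOn <- c(snoreOn, t); snoreStage <- c(snoreStage, stg)
      gap <- round(rnorm(1, params$snoreIntervalMean[[stg]],
                         params$snoreIntervalSd[[stg]]))
      t <- t + max(params$snoreMinIntervalS, gap)
    }
  }
  for (i in seq_along(snoreOn)) {
    rows <- (snoreOn[i] + 1L):min(snoreOn[i] + params$snoreBurstDurS, n)
    # a snore event is by definition a supra-threshold sound: floor the
    # burst level just above the 30 dB detection cut
    sound[rows] <- max(rnorm(1, params$snoreDbMean, params$snoreDbSd),
                       params$snoreDbMin)
  }
  snoreOnsets <- data.frame(onset = snoreOn, stage = snoreStage,
                            stringsAsFactors = FALSE)

  ## --- heart rate -------------------------------------------------------
  set.seed(.subSeed(seed, 5L))
  hr <- params$hrMean[stageSec] + rnorm(n) * params$hrSd[stageSec]
  placeEpisodes <- function(stage, ratePerHour, level) {
    allowed <- secs[stageSec == stage]
    on <- .sampleOnsets(allowed, ratePerHour)
    if (length(on) > 1L) on <- on[c(TRUE, diff(on) >= 2 * params$episodeDurS[2])]
    ev <- lapply(on, function(s) {
      dur <- round(runif(1, params$episodeDurS[1], params$episodeDurS[2]))
      e <- min(s + dur, n)
      # keep the episode inside its stage block
      blk <- which(blockStart <= s & blockEnd > s)
      e <- min(e, blockEnd[blk])
      if (e - s < 5) return(NULL)
      hr[(s + 1L):e] <<- level + rnorm(e - s, 0, 1)
      data.frame(start = s, end = e)
    })
    do.call(rbind, ev[!vapply(ev, is.null, logical(1))])
  }
  bradyEvents <- placeEpisodes("NREM", params$bradyRatePerNremHour,
                               params$bradyLevel)
  tachyEvents <- placeEpisodes("REM", params$tachyRatePerRemHour,
                               params$tachyLevel)
  hr <- pmin(pmax(hr, 25), 250)

  ## --- CO2 --------------------------------------------------------------
  set.seed(.subSeed(seed, 6L))
  co2v <- params$co2Start + params$co2DriftPerHour * secs / 3600 +
    rnorm(n, 0, params$co2NoiseSd)
  snoreMask <- rep(FALSE, n)
  for (i in seq_along(snoreOn))
    snoreMask[(snoreOn[i] + 1L):min(snoreOn[i] + params$snoreBurstDurS, n)] <- TRUE
  co2v[snoreMask] <- co2v[snoreMask] + params$co2SnoreBump
  co2v <- pmax(co2v, 0)

  ## --- body temperature -------------------------------------------------
  set.seed(.subSeed(seed, 7L))
  bt <- params$bodyTempBase + rnorm(n, 0, params$bodyTempNoiseSd)
  for (b in chg) {
    dip <- runif(1, params$tempDipLow, params$tempDipHigh)
    holdEnd <- min(b + params$tempDipHoldS, n)
    rows <- (b + 1L):holdEnd
    bt[rows] <- dip + rnorm(length(rows), 0, 0.05)
    recEnd <- min(holdEnd + params$tempDipRecoverS, n)
    if (recEnd > holdEnd) {
      k <- recEnd - holdEnd
      bt[(holdEnd + 1L):recEnd] <- seq(dip, params$bodyTempBase,
                                       length.out = k + 1L)[-1L] +
        rnorm(k, 0, 0.05)
    }
  }

  ## --- room climate, lux ------------------------------------------------
  set.seed(.subSeed(seed, 8L))
  rt <- params$roomTempBase +
    params$roomTempAmp * sin(2 * pi * secs / n) +
    rnorm(n, 0, params$roomTempNoiseSd)
  set.seed(.subSeed(seed, 9L))
  hum <- params$humidityBase + params$humidityDriftPerHour * secs / 3600 +
    rnorm(n, 0, params$humidityNoiseSd)
  hum <- pmin(pmax(hum, 0), 100)
  set.seed(.subSeed(seed, 10L))
  lx <- pmax(params$luxBase + rnorm(n, 0, params$luxNoiseSd), 0)

  session <- SessionRecord(
    pressure = pressure, soundDb = sound, bodyTemp = bt, roomTemp = rt,
    humidity = hum, co2 = co2v,
    lux = if (params$includeLux) lx else NULL,
    heartRate = if (params$includeHeartRate) hr else NULL,
    startTime = "2021-10-22T00:00:00")

  truth <- list(hypnogram = hypnogram, postureSchedule = schedule,
                postureChanges = chg,
                tossEvents = tossEvents, snoreOnsets = snoreOnsets,
                bradyEvents = bradyEvents, tachyEvents = tachyEvents,
                params = params, seed = seed)
  list(session = session, truth = truth)
}

#' Simulate a complete night (hypnogram + session)
#'
#' @param params [simParams()].
#' @param seed integer seed.
#' @return as [simulateSession()].
#' @export
simulateNight <- function(params = simParams(), seed = 1) {
  simulateSession(simulateHypnogram(params, seed), params, seed)
}

#' Balanced labelled posture-window benchmark
#'
#' Draws `nPerClass` one-minute pressure windows per posture from the
#' per-posture profiles with head-shift, load and sensor noise, and returns
#' their feature vectors with labels -- the synthetic stand-in for a large
#' recorded posture training corpus.
#'
#' @param params [simParams()].
#' @param nPerClass windows per posture class (default 500).
#' @param seed integer seed.
#' @param windowS window length in seconds (default 60).
#' @return list with `features` (matrix, rows = windows) and `labels`
#'   (factor over SUPINE/LEFT/RIGHT).
#' @export
makePostureTrainingSet <- function(params = simParams(), nPerClass = 500,
                                   seed = 1, windowS = 60) {
  stopifnot(nPerClass >= 1)
  set.seed(.subSeed(seed, 11L))
  classes <- rownames(params$pressureProfiles)
  feats <- list(); labs <- character(0)
  for (cls in classes) {
    for (j in seq_len(nPerClass)) {
      shift <- rnorm(1, 0, params$headShiftSd)
      amp <- exp(rnorm(1, 0, params$amplitudeLogSd))
      prof <- amp * .shiftProfile(params$pressureProfiles[cls, ], shift)
      win <- matrix(prof, nrow = windowS, ncol = 8L, byrow = TRUE)
      if (params$pressureNoiseSd > 0)
        win <- win + matrix(rnorm(windowS * 8L, 0, params$pressureNoiseSd),
                            windowS, 8L)
      feats[[length(feats) + 1L]] <- extractPostureFeatures(pmax(win, 0))
      labs <- c(labs, cls)
    }
  }
  list(features = do.call(rbind, feats), labels = factor(labs))
}
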