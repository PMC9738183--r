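test_that("frame delta is the summed absolute sensor change", {
  a <- c(1, 2, 3, 0, 0, 0, 0, 0)
  z <- rep(0, 8)
  expect_equal(frameDelta(a, a), 0)
  expect_equal(frameDelta(a, z), 6)
  expect_equal(frameDelta(z, a), frameDelta(a, z))
  set.seed(4)
  x <- runif(8, 0, 50); y <- runif(8, 0, 50)
  expect_equal(frameDelta(x, y), sum(abs(x - y)))
})

test_that("toss-and-turn detection follows the open/quiesce/close rule", {
  # flat stream: nothing
  flat <- matrix(5, 60, 8)
  expect_identical(nrow(detectTossTurn(flat, tossTurnParams(threshold = 1))),
                   0L)

  # 3-s plateau burst at t = 10: supra-threshold deltas at onset (t=10) and
  # offset (t=13); the event spans the activity, [10, 14), and closes after
  # 5 quiet seconds
  p <- matrix(10, 60, 8)
  p[11:13, ] <- p[11:13, ] + 40      # seconds 10..12
  ev <- detectTossTurn(p, tossTurnParams(threshold = 50))
  expect_identical(ev$start, 10)
  expect_identical(ev$end, 14)
  expect_identical(ev$duration, 4)
  expect_equal(ev$peak, 8 * 40)

  # two bursts 2 s apart never reach quiescence: one event
  p2 <- matrix(10, 120, 8)
  p2[11:13, ] <- 50                  # seconds 10..12
  p2[16:17, ] <- 50                  # seconds 15..16
  ev2 <- detectTossTurn(p2, tossTurnParams(threshold = 50))
  expect_identical(nrow(ev2), 1L)
  expect_identical(ev2$start, 10)
  expect_identical(ev2$end, 18)

  # 10 s apart: two events
  p3 <- matrix(10, 120, 8)
  p3[11:13, ] <- 50
  p3[24:25, ] <- 50                  # seconds 23..24
  ev3 <- detectTossTurn(p3, tossTurnParams(threshold = 50))
  expect_identical(ev3$start, c(10, 23))
})

test_that("toss detector agrees with the brute-force cluster oracle", {
  set.seed(21)
  for (i in 1:200) {
    p <- randomPressureStream(n = 240)
    thr <- 150
    q <- sample(3:6, 1)
    got <- detectTossTurn(p, tossTurnParams(threshold = thr, quiescence = q,
                                            mergeWithinPosture = FALSE))
    want <- oracleTossScan(p, thr, q)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("snore capture follows threshold, cap and re-arm delay", {
  expect_identical(nrow(detectSnoreEvents(rep(25, 60))), 0L)

  # three 2-s bursts of 40 dB at t = 0, 5, 10
  s <- rep(25, 30)
  for (b in c(0, 5, 10)) s[b + 1:2] <- 40
  ev <- detectSnoreEvents(s)
  expect_identical(ev$start, c(0, 5, 10))
  expect_identical(ev$end, c(2, 7, 12))
  expect_equal(ev$interval, c(NA, 5, 5))
  expect_equal(ev$peak, c(40, 40, 40))

  # 20 s continuous sound: capped at 15 s, re-armed 2 s later
  s2 <- c(rep(40, 20), rep(25, 5))
  ev2 <- detectSnoreEvents(s2)
  expect_identical(ev2$start, c(0, 17))
  expect_identical(ev2$end, c(15, 20))
})

test_that("snore detector agrees with the per-second state-machine oracle", {
  set.seed(22)
  for (i in 1:200) {
    s <- randomSoundStream(n = 240)
    got <- detectSnoreEvents(s)
    want <- oracleSnoreScan(s, 30, 15, 2)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("event counts are invariant to sub-threshold padding", {
  set.seed(23)
  for (i in 1:20) {
    p <- randomPressureStream(n = 200)
    par <- tossTurnParams(threshold = 150)
    n0 <- nrow(detectTossTurn(p, par))
    padded <- rbind(matrix(p[1, ], 20, 8, byrow = TRUE), p,
                    matrix(p[200, ], 20, 8, byrow = TRUE))
    expect_identical(nrow(detectTossTurn(padded, par)), n0)

    s <- randomSoundStream(n = 200)
    n1 <- nrow(detectSnoreEvents(s))
    expect_identical(nrow(detectSnoreEvents(c(rep(20, 15), s, rep(20, 15)))),
                     n1)
  }
})

test_that("snore regularity flags windows by interval CV", {
  # intervals of exactly 3 s: CV 0, regular from the first full window
  s <- rep(25, 80)
  for (b in seq(0, 60, by = 3)) s[b + 1] <- 40
  ev <- snoreRegularity(detectSnoreEvents(s))
  expect_true(all(is.na(ev$regular[1:5])))   # no full preceding window yet
  expect_true(all(ev$regular[-(1:5)]))
  expect_equal(ev$cv[6], 0)

  # hand-computed CV for intervals {2, 8, 3, 12, 5}
  iv <- c(2, 8, 3, 12, 5)
  expect_equal(intervalCV(iv), sd(iv) / mean(iv))
  onsets <- cumsum(c(0, iv))
  s2 <- rep(25, 40)
  s2[onsets + 1] <- 40
  ev2 <- snoreRegularity(detectSnoreEvents(s2, snoreParams(rearmDelay = 0)))
  expect_identical(nrow(ev2), 6L)
  expect_equal(ev2$cv[6], sd(iv) / mean(iv))
  expect_false(ev2$regular[6])               # 0.677 > 0.25: irregular

  # fewer events than the window: all flags undefined
  ev3 <- snoreRegularity(detectSnoreEvents(c(25, 40, 25, 40, rep(25, 10)),
                                           snoreParams(rearmDelay = 0)))
  expect_true(all(is.na(ev3$regular)))
})

test_that("CO2 banding uses left-closed cuts at 400/700/1000 ppm", {
  expect_identical(as.character(classifyCO2(350)), "GOOD")
  expect_identical(as.character(classifyCO2(400)), "AVERAGE")
  expect_identical(as.character(classifyCO2(699.999)), "AVERAGE")
  expect_identical(as.character(classifyCO2(700)), "POOR")
  expect_identical(as.character(classifyCO2(1000)), "VERY_POOR")
  expect_identical(as.character(classifyCO2(1200)), "VERY_POOR")
  expect_error(classifyCO2(-5), ">= 0")
  # total monotone step function
  grid <- seq(0, 2000, by = 7)
  bands <- as.integer(classifyCO2(grid))
  expect_true(all(diff(bands) >= 0))
})

test_that("heart-rate episodes use strict bounds and a minimum duration", {
  expect_identical(nrow(annotateHeartRate(rep(70, 120))), 0L)
  ev <- annotateHeartRate(rep(59, 60))
  expect_identical(ev$kind, "BRADYCARDIA")
  expect_identical(ev$start, 0)
  expect_identical(ev$end, 60)
  expect_identical(nrow(annotateHeartRate(rep(100, 60))), 0L)  # strict >
  expect_identical(nrow(annotateHeartRate(rep(60, 60))), 0L)   # strict <
  # sub-minimum runs are suppressed
  hr <- c(rep(70, 10), rep(55, 4), rep(70, 10), rep(110, 6), rep(70, 10))
  ev2 <- annotateHeartRate(hr)
  expect_identical(ev2$kind, "TACHYCARDIA")
  expect_identical(ev2$start, 24)
  expect_error(annotateHeartRate(makeTestSession(10, hr = FALSE)), "absent")
})

test_that("temperature artifact masking pads posture changes", {
  bt <- rep(36.5, 300)
  out0 <- maskTempArtifacts(bt, numeric(0))
  expect_false(any(out0$flags))

  out <- maskTempArtifacts(bt, 100, pad = 30)
  flagged <- which(out$flags) - 1L
  expect_identical(range(flagged), c(70L, 130L))
  expect_true(all(is.na(out$masked[71:131])))
  expect_false(anyNA(out$masked[-(71:131)]))

  nt <- simulateNight(simParams(durationS = 10800), seed = 9)
  chg <- nt$truth$postureChanges
  out2 <- maskTempArtifacts(bodyTemp(nt$session), chg, pad = 30)
  # every injected dip second lies inside a flagged region
  dipSecs <- unlist(lapply(chg, function(b) b:(b + 15)))
  expect_true(all(out2$flags[dipSecs + 1]))
})
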