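featRow <- function(toss_rate = 0, snore_count = 0, regular_frac = NA,
                    temp_std = 0) {
  data.frame(epoch = 0L, toss_turn_count = NA, toss_turn_rate = toss_rate,
             toss_dur_s = 0, snore_count = snore_count,
             snore_regular_frac = regular_frac, snore_mean_intensity = NA,
             body_temp_mean = 36.5, body_temp_std = temp_std,
             room_temp_mean = 22.5, co2_mean = 500, posture = "SUPINE")
}

test_that("rule-based scorer reproduces its closed form", {
  # quiet, fully regular snoring, zero temperature spread: score 1, NREM
  out <- stageRuleBased(featRow(0, snore_count = 10, regular_frac = 1, 0))
  expect_equal(out$scores$nrem_score, 1)
  expect_identical(out$scores$label, "NREM")

  # 6 tosses/min, no snoring, temp sd 1: 0.5/7 + 0.3*0.5 + 0.2*0.5 -> REM
  out2 <- stageRuleBased(featRow(6, 0, NA, 1))
  expect_equal(out2$scores$nrem_score, 0.5 / 7 + 0.15 + 0.1)
  expect_identical(out2$scores$label, "REM")

  # epochs without snores take the neutral 0.5 snore term
  out3 <- stageRuleBased(featRow(0, 0, NA, 0))
  expect_equal(out3$scores$nrem_score, 0.5 + 0.15 + 0.2)
})

test_that("rule-based score is monotone in movement and snore regularity", {
  rates <- seq(0, 10, by = 0.5)
  sc <- vapply(rates, function(r)
    stageRuleBased(featRow(r, 5, 0.5, 0.2))$scores$nrem_score, numeric(1))
  expect_true(all(diff(sc) <= 0))
  fracs <- seq(0, 1, by = 0.05)
  sc2 <- vapply(fracs, function(f)
    stageRuleBased(featRow(2, 5, f, 0.2))$scores$nrem_score, numeric(1))
  expect_true(all(diff(sc2) >= 0))
})

test_that("heart-rate reference hypnogram thresholds mean and spread", {
  expect_true(all(stageLabels(hrReferenceHypnogram(rep(58, 300))) == "NREM"))
  expect_true(all(stageLabels(hrReferenceHypnogram(rep(85, 300))) == "REM"))
  hr <- rep(c(rep(58, 60), rep(85, 60)), 3)
  expect_identical(stageLabels(hrReferenceHypnogram(hr)),
                   rep(c("NREM", "REM"), 3))
  # stable mean but high variability is REM-like
  set.seed(1)
  expect_true(all(stageLabels(hrReferenceHypnogram(
    rnorm(300, 60, 12))) == "REM"))
  expect_error(hrReferenceHypnogram(makeTestSession(10, hr = FALSE)),
               "absent")
})

test_that("epoch features attribute events by onset and overlap", {
  n <- 180
  rec <- SessionRecord(
    pressure = matrix(30, n, 8), soundDb = rep(25, n),
    bodyTemp = rep(36.5, n), roomTemp = rep(22.5, n),
    humidity = rep(50, n), co2 = rep(500, n),
    heartRate = rep(62, n))
  segments <- data.frame(posture = "SUPINE", start = 0, end = n,
                         duration = n)
  # snore spanning the first epoch boundary: counted at its onset epoch
  snore <- makeEvents("SNORE", start = 55, end = 65, peak = 42)
  snore$cv <- NA_real_; snore$regular <- NA
  toss <- makeEvents("TOSS_TURN", start = c(10, 118), end = c(20, 125),
                     peak = 100)
  fe <- epochFeatures(rec, list(tossTurn = toss, snore = snore),
                      segments, epochLen = 60)
  expect_identical(nrow(fe), 3L)
  expect_identical(fe$snore_count, c(1L, 0L, 0L))
  expect_identical(fe$toss_turn_count, c(1L, 1L, 0L))
  expect_equal(fe$toss_turn_rate, c(1, 1, 0))
  # overlap attribution for durations: [10,20) in epoch 0; [118,125) splits
  expect_equal(fe$toss_dur_s, c(10, 2, 5))
  expect_identical(fe$posture, rep("SUPINE", 3))
  expect_equal(fe$hr_mean, rep(62, 3))
  # event-free epoch has zero rates
  expect_equal(fe$toss_turn_rate[3], 0)
  expect_error(epochFeatures(rec, list(), segments, epochLen = 500),
               "shorter than one epoch")
})

test_that("epoch features match a brute-force recount on a simulated night", {
  nt <- simulateNight(simParams(durationS = 7200), seed = 4)
  s <- nt$session
  seg <- postureSegments(s)
  toss <- detectTossTurn(s, segments = seg$segments)
  snore <- snoreRegularity(detectSnoreEvents(s))
  fe <- epochFeatures(s, list(tossTurn = toss, snore = snore,
                              postureChange = seg$changes), seg$segments)
  expect_identical(nrow(fe), 120L)
  for (e in c(0L, 17L, 63L, 119L)) {
    lo <- e * 60; hi <- min((e + 1) * 60, nSeconds(s))
    expect_identical(fe$snore_count[e + 1],
                     sum(snore$start >= lo & snore$start < hi))
    expect_identical(fe$toss_turn_count[e + 1],
                     sum(toss$start >= lo & toss$start < hi))
    expect_equal(fe$co2_mean[e + 1], mean(co2(s)[(lo + 1):hi]))
    expect_equal(fe$hr_mean[e + 1], mean(heartRate(s)[(lo + 1):hi]))
  }
})

test_that("confusion metrics match their closed forms", {
  # TP=3 FP=1 FN=2 TN=4
  ref <- c(rep("REM", 5), rep("NREM", 5))
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.6, 0.3, 0.25, 0.15, 0.05)
  m <- evaluateStaging(scores, ref)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * (0.75 * 0.6) / (0.75 + 0.6))

  # perfect separation
  mp <- evaluateStaging(c(0.9, 0.8, 0.1, 0.2), c("REM", "REM", "NREM", "NREM"))
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$auc, 1)

  # reversing the scores reverses the AUC
  set.seed(8)
  sc <- runif(50)
  rf <- sample(c("REM", "NREM"), 50, replace = TRUE)
  expect_equal(evaluateStaging(1 - sc, rf)$auc,
               1 - evaluateStaging(sc, rf)$auc)

  expect_error(evaluateStaging(runif(5), rep("REM", 5)), "single class")
})

test_that("ROC matches the all-thresholds enumeration and pROC", {
  set.seed(9)
  scores <- round(runif(200), 2)           # ties included
  pos <- runif(200) < 0.4
  ref <- ifelse(pos, "REM", "NREM")
  m <- evaluateStaging(scores, ref)
  expect_equal(m$auc, oracleAuc(scores, pos))
  want <- oracleRoc(scores, pos)
  expect_equal(m$roc_points$fpr, want$fpr)
  expect_equal(m$roc_points$tpr, want$tpr)
  # monotone from (0,0) to (1,1)
  expect_true(all(diff(m$roc_points$fpr) >= 0))
  expect_true(all(diff(m$roc_points$tpr) >= 0))
  expect_equal(unlist(m$roc_points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(m$roc_points[nrow(m$roc_points), ]),
               c(fpr = 1, tpr = 1))
  skip_if_not_installed("pROC")
  expect_equal(m$auc,
               as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE))))
})

test_that("tree classifiers separate, reproduce under a seed, and null out", {
  nt <- simulateNight(simParams(durationS = 10800), seed = 6)
  s <- nt$session
  seg <- postureSegments(s)
  toss <- detectTossTurn(s, segments = seg$segments)
  snore <- snoreRegularity(detectSnoreEvents(s))
  fe <- epochFeatures(s, list(tossTurn = toss, snore = snore,
                              postureChange = seg$changes), seg$segments)
  lab <- stageLabels(nt$truth$hypnogram)

  m1 <- trainStageClassifier(fe, lab, model = "random_forest", seed = 3)
  m2 <- trainStageClassifier(fe, lab, model = "random_forest", seed = 3)
  expect_identical(predictStageProb(m1, fe), predictStageProb(m2, fe))
  expect_false(any(grepl("^hr_", m1@featureNames)))

  dt <- trainStageClassifier(fe, lab, model = "decision_tree", seed = 3)
  expect_gt(evaluateStaging(predictStageProb(dt, fe), lab)$auc, 0.9)

  expect_error(trainStageClassifier(fe, rep("NREM", nrow(fe))),
               "single class")

  # label-shuffled control: chance-level AUC
  set.seed(10)
  shuf <- sample(lab)
  m0 <- trainStageClassifier(fe, shuf, model = "random_forest", seed = 3)
  nt2 <- simulateNight(simParams(durationS = 10800), seed = 7)
  seg2 <- postureSegments(nt2$session)
  fe2 <- epochFeatures(nt2$session,
                       list(tossTurn = detectTossTurn(nt2$session,
                                                      segments = seg2$segments),
                            snore = snoreRegularity(detectSnoreEvents(nt2$session)),
                            postureChange = seg2$changes), seg2$segments)
  lab2 <- ifelse(stageLabels(nt2$truth$hypnogram) == "WAKE", "REM",
                 stageLabels(nt2$truth$hypnogram))
  auc0 <- evaluateStaging(predictStageProb(m0, fe2), lab2)$auc
  expect_gt(auc0, 0.3)
  expect_lt(auc0, 0.7)
})

test_that("night summary conserves time and recounts per stage", {
  nt <- simulateNight(simParams(durationS = 7200), seed = 5)
  s <- nt$session
  seg <- postureSegments(s)
  events <- list(tossTurn = detectTossTurn(s, segments = seg$segments),
                 snore = snoreRegularity(detectSnoreEvents(s)))
  hyp <- nt$truth$hypnogram
  sm <- summarizeNight(s, seg$segments, events, hyp)
  ps <- sm$perStage
  stageRows <- ps$stage != "TOTAL"
  expect_equal(sum(ps$minutes[stageRows]), nSeconds(s) / 60)
  expect_equal(ps$minutes[ps$stage == "TOTAL"], nSeconds(s) / 60)
  expect_equal(sum(ps$snore_count[stageRows]),
               ps$snore_count[ps$stage == "TOTAL"])
  # brute-force recount of a stage row
  stageSec <- rep(stageLabels(hyp), each = 60)[seq_len(nSeconds(s))]
  for (stg in ps$stage[stageRows]) {
    expect_equal(ps$minutes[ps$stage == stg], sum(stageSec == stg) / 60)
    expect_identical(ps$snore_count[ps$stage == stg],
                     sum(stageSec[events$snore$start + 1] == stg))
  }
  expect_equal(sum(sm$postureMinutes$minutes), nSeconds(s) / 60)

  # all-NREM night: no REM row
  allN <- Hypnogram(rep("NREM", 120), 60)
  sm2 <- summarizeNight(s, seg$segments, events, allN)
  expect_false("REM" %in% sm2$perStage$stage)
})
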