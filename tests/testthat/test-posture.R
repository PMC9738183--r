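test_that("pressure centroid is the index-weighted mean", {
  expect_equal(pressureCentroid(c(0, 0, 0, 1, 1, 0, 0, 0)), 3.5)
  expect_equal(pressureCentroid(c(1, 0, 0, 0, 0, 0, 0, 0)), 0)
  expect_equal(pressureCentroid(c(0, 1, 3, 0, 0, 0, 0, 0)), 1.75)
  expect_error(pressureCentroid(rep(0, 8)), "undefined centroid")
})

test_that("posture features match hand computation", {
  w1 <- matrix(rep(c(1, 2, 3, 4, 5, 6, 7, 8), each = 4), 4, 8)
  f1 <- extractPostureFeatures(w1)
  expect_equal(unname(f1[paste0("p", 0:7, "_sd")]), rep(0, 8))
  expect_equal(f1[["total_mean"]], 36)

  w2 <- matrix(c(10, 0, 0, 0, 0, 0, 0, 0), 1, 8)
  f2 <- extractPostureFeatures(w2)
  expect_equal(unname(f2[paste0("p", 0:7, "_mean")]), as.numeric(w2))
  expect_equal(unname(f2[paste0("p", 0:7, "_sd")]), rep(0, 8))
  expect_equal(f2[["centroid_of_means"]], 0)

  # two-frame hand example: means (1.5, 1, 0...), sds (sd over {1,2}, sd
  # over {0,2}, 0...), centroid 1/2.5, total 2.5
  w3 <- rbind(c(1, 0, rep(0, 6)), c(2, 2, rep(0, 6)))
  f3 <- extractPostureFeatures(w3)
  expect_equal(f3[["p0_mean"]], 1.5)
  expect_equal(f3[["p1_mean"]], 1)
  expect_equal(f3[["p0_sd"]], sd(c(1, 2)))
  expect_equal(f3[["p1_sd"]], sd(c(0, 2)))
  expect_equal(f3[["centroid_of_means"]], 1 / 2.5)
  expect_equal(f3[["total_mean"]], 2.5)
})

test_that("centroid heuristic maps windows by centroid and presence", {
  centered <- matrix(rep(c(0, 0, 0, 10, 10, 0, 0, 0), each = 30), 30, 8)
  expect_identical(classifyPostureHeuristic(centered * 30), "SUPINE")
  leftw <- matrix(rep(c(40, 40, 40, 0, 0, 0, 0, 0), each = 30), 30, 8)
  expect_identical(classifyPostureHeuristic(leftw), "LEFT")
  expect_identical(classifyPostureHeuristic(leftw[, 8:1]), "RIGHT")
  expect_identical(classifyPostureHeuristic(matrix(0, 30, 8)), "OFF_PILLOW")
})

test_that("heuristic label is invariant to uniform pressure scaling", {
  set.seed(3)
  prof <- simParams()$pressureProfiles
  for (i in 1:20) {
    cls <- sample(rownames(prof), 1)
    win <- matrix(rep(prof[cls, ], each = 20), 20, 8) +
      abs(matrix(rnorm(160, 0, 2), 20, 8))
    base <- classifyPostureHeuristic(win)
    for (k in c(0.5, 2, 7)) {
      m <- heuristicPostureModel(calibrationMean = 250 * k)
      expect_identical(classifyPostureHeuristic(win * k, m), base)
    }
  }
})

test_that("margin classifier separates clean clusters and needs 2 classes", {
  set.seed(5)
  ts <- makePostureTrainingSet(simParams(pressureNoiseSd = 0.5,
                                         headShiftSd = 0.05),
                               nPerClass = 30, seed = 2)
  m <- trainPostureClassifier(ts$features, ts$labels, seed = 1)
  expect_identical(predictPosture(m, ts$features),
                   as.character(ts$labels))
  expect_error(trainPostureClassifier(ts$features,
                                      rep("SUPINE", nrow(ts$features))),
               "two posture classes")
  expect_error(trainPostureClassifier(ts$features[c(1:5, 31:35), ],
                                      ts$labels[c(1:5, 31:35)]),
               "10 windows per class")
})

test_that("label-shuffled training yields chance-level accuracy", {
  ts <- makePostureTrainingSet(simParams(), nPerClass = 150, seed = 3)
  set.seed(31)
  idx <- unlist(lapply(split(seq_along(ts$labels), ts$labels),
                       function(i) sample(i, 120)))
  shuffled <- sample(ts$labels[idx])
  m <- trainPostureClassifier(ts$features[idx, ], shuffled, seed = 1)
  acc <- mean(predictPosture(m, ts$features[-idx, ]) ==
                as.character(ts$labels[-idx]))
  expect_gt(acc, 1 / 3 - 0.07)
  expect_lt(acc, 1 / 3 + 0.07)
})

test_that("constant stream yields a single tiling segment and no changes", {
  p <- matrix(rep(c(5, 15, 45, 80, 80, 45, 15, 5), each = 300), 300, 8)
  out <- postureSegments(p, tossThreshold = 10)
  expect_identical(nrow(out$segments), 1L)
  expect_identical(out$segments$start, 0L)
  expect_identical(out$segments$end, 300L)
  expect_identical(out$segments$posture, "SUPINE")
  expect_identical(nrow(out$changes), 0L)
})

test_that("scheduled posture transitions are recovered within one min-cycle", {
  params <- simParams(headShiftSd = 0)
  nt <- simulateNight(params, seed = 42)
  truthB <- nt$truth$postureChanges
  expect_gte(length(truthB), 2L)
  out <- postureSegments(pressureMatrix(nt$session))
  got <- out$segments$start[-1]
  expect_identical(length(got), length(truthB))
  expect_true(all(abs(got - truthB) <= 10))
  # segments tile the session
  expect_identical(out$segments$start[1], 0L)
  expect_identical(out$segments$end[nrow(out$segments)],
                   nSeconds(nt$session))
  expect_true(all(out$segments$start[-1] ==
                    out$segments$end[-nrow(out$segments)]))
  expect_equal(sum(out$segments$duration), nSeconds(nt$session))
  # one POSTURE_CHANGE event per boundary
  expect_identical(nrow(out$changes), nrow(out$segments) - 1L)
})

test_that("rapid alternation degrades to the brute-force min-cycle scan", {
  profA <- c(70, 80, 50, 20, 8, 3, 1, 1)
  profB <- rev(profA)
  p <- matrix(0, 300, 8)
  for (t in 0:299)
    p[t + 1, ] <- if ((t %/% 5) %% 2 == 0) profA else profB
  out <- postureSegments(p, minCycle = 10, tossThreshold = 50,
                         hysteresis = 0)
  # oracle: classify fixed 10-s windows, merge equal neighbours
  labs <- vapply(seq(0, 290, by = 10), function(s)
    classifyPostureHeuristic(p[(s + 1):(s + 10), ]), character(1))
  keep <- c(TRUE, labs[-1] != labs[-length(labs)])
  expect_identical(out$segments$posture, labs[keep])
  expect_equal(out$segments$start, seq(0, 290, by = 10)[keep])
})
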