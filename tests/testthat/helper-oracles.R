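# Independent brute-force oracles for the event detectors and the ROC.
# These deliberately use different formulations than the package code so
# that agreement is a meaningful cross-check.

# Toss-and-turn oracle: cluster the supra-threshold seconds directly.
# Two active seconds belong to one event iff they are at most `quiescence`
# apart (an inactive run of >= quiescence deltas closes an event); the
# event interval spans [first_active, last_active + 1).
oracleTossScan <- function(pressure, threshold, quiescence) {
  n <- nrow(pressure)
  deltas <- vapply(2:n, function(t)
    sum(abs(pressure[t, ] - pressure[t - 1L, ])), numeric(1))
  act <- which(deltas > threshold)        # in units of second index (1-based = second t)
  if (!length(act)) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  grp <- cumsum(c(1, diff(act) > quiescence))
  starts <- tapply(act, grp, min)
  ends <- tapply(act, grp, max) + 1
  data.frame(start = as.numeric(starts), end = as.numeric(ends))
}

# Snore oracle: per-second state machine. A capture opens at an armed
# second above threshold, closes at the first second at/below threshold or
# at the capture cap; the detector re-arms `rearm` seconds after the close.
oracleSnoreScan <- function(sound, threshold, maxCapture, rearm) {
  n <- length(sound)
  starts <- ends <- numeric(0)
  open <- FALSE; s0 <- 0; armedAt <- 0
  for (t in 0:(n - 1L)) {
    v <- sound[t + 1L]
    if (open) {
      if (v <= threshold || (t - s0) >= maxCapture) {
        starts <- c(starts, s0); ends <- c(ends, t)
        open <- FALSE; armedAt <- t + rearm
      }
    } else if (t >= armedAt && v > threshold) {
      open <- TRUE; s0 <- t
    }
  }
  if (open) { starts <- c(starts, s0); ends <- c(ends, min(n, s0 + maxCapture)) }
  data.frame(start = starts, end = ends)
}

# All-thresholds ROC enumeration (positive predicted when score >= thr).
oracleRoc <- function(scores, positive) {
  thrs <- sort(unique(scores), decreasing = TRUE)
  P <- sum(positive); N <- sum(!positive)
  pts <- t(vapply(thrs, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & !positive) / N, tpr = sum(pred & positive) / P)
  }, numeric(2)))
  out <- rbind(c(0, 0), pts, c(1, 1))
  data.frame(fpr = out[, 1], tpr = out[, 2])
}

oracleAuc <- function(scores, positive) {
  roc <- oracleRoc(scores, positive)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

# Random short streams for oracle-equivalence sweeps ------------------------

randomPressureStream <- function(n = 600, nBursts = NULL) {
  p <- matrix(abs(rnorm(n * 8, 30, 1.5)), n, 8)
  nBursts <- nBursts %||% rpois(1, 4)
  if (nBursts > 0) {
    on <- sort(sample.int(n - 12, nBursts))
    for (s in on) {
      len <- sample(1:8, 1)
      rows <- s:min(s + len, n)
      p[rows, ] <- p[rows, ] + abs(matrix(rnorm(length(rows) * 8, 0, 40),
                                          length(rows), 8))
    }
  }
  p
}

randomSoundStream <- function(n = 600) {
  s <- rnorm(n, 25, 1.5)
  nb <- rpois(1, 6)
  if (nb > 0) {
    on <- sort(sample.int(n - 20, nb))
    for (b in on) {
      len <- sample(1:18, 1)       # sometimes longer than the 15 s cap
      rows <- b:min(b + len - 1, n - 1) + 1
      s[rows] <- rnorm(length(rows), 40, 3)
    }
  }
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
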