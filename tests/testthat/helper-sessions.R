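# Small deterministic sessions built in code for I/O and feature tests.

makeTestSession <- function(n = 10, lux = TRUE, hr = TRUE,
                            startTime = "2021-10-22T01:00:00") {
  set.seed(n)
  SessionRecord(
    pressure = matrix(abs(rnorm(n * 8, 30, 5)), n, 8),
    soundDb = rnorm(n, 26, 1),
    bodyTemp = rnorm(n, 36.5, 0.05),
    roomTemp = rnorm(n, 22.5, 0.05),
    humidity = rnorm(n, 50, 1),
    co2 = rnorm(n, 480, 5),
    lux = if (lux) abs(rnorm(n, 0.5, 0.1)) else NULL,
    heartRate = if (hr) rnorm(n, 62, 2) else NULL,
    startTime = startTime)
}

randomSession <- function() {
  n <- sample(c(0L, 1L, 5L, 37L, 120L), 1)
  set.seed(n + 1000L)
  SessionRecord(
    pressure = matrix(runif(n * 8, 0, 100), n, 8),
    soundDb = runif(n, 20, 60),
    bodyTemp = runif(n, 33, 38),
    roomTemp = runif(n, 18, 28),
    humidity = runif(n, 20, 80),
    co2 = runif(n, 300, 1500),
    lux = if (n %% 2 == 0L) runif(n, 0, 5) else NULL,
    heartRate = if (n %% 3 != 0L) runif(n, 45, 110) else NULL,
    startTime = if (n > 5) "2022-01-01T23:30:00" else "")
}

expectSameSession <- function(a, b) {
  for (sl in c("startTime", "soundDb", "bodyTemp", "roomTemp", "humidity",
               "co2", "lux", "heartRate")) {
    testthat::expect_identical(methods::slot(a, sl), methods::slot(b, sl),
                               label = sl)
  }
  testthat::expect_identical(unname(methods::slot(a, "pressure")),
                             unname(methods::slot(b, "pressure")))
}
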