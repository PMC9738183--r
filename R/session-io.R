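# Canonical CSV header vocabulary. A session file is RFC-4180 CSV, UTF-8,
# '.' decimal separator, with an optional leading "#start_time=..." comment.
.SESSION_REQUIRED <- c("t", paste0("p", 0:7), "sound_db", "body_temp_c",
                       "room_temp_c", "humidity_pct", "co2_ppm")
.SESSION_OPTIONAL <- c("lux", "hr_bpm")

#' Read a sleep-session recording from CSV
#'
#' Parses a 1 Hz multi-channel session file with the fixed header vocabulary
#' `t, p0..p7, sound_db, body_temp_c, room_temp_c, humidity_pct, co2_ppm,
#' lux, hr_bpm` (the last two optional). Gzip-compressed files are read
#' transparently. Missing optional columns yield absent channels, never
#' zero-filled ones.
#'
#' Timestamps must advance strictly; a gap in the 1 Hz grid is an error
#' unless `fillGaps = TRUE`, in which case gaps of at most `maxGap` seconds
#' are imputed by holding the last sample and the imputed second indices are
#' attached as `attr(rec, "imputed")`.
#'
#' @param path file path (plain or `.gz`).
#' @param schema optional named character vector mapping canonical column
#'   names to the names actually used in the file, e.g.
#'   `c(sound_db = "SPL")`.
#' @param fillGaps impute short gaps by holding the last sample?
#' @param maxGap largest gap (seconds) that may be imputed.
#' @return A validated [SessionRecord-class].
#' @seealso [writeSession()], [validateSession()]
#' @export
readSession <- function(path, schema = NULL, fillGaps = FALSE, maxGap = 5) {
  if (!file.exists(path))
    stop("session file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  startTime <- ""
  st <- grep("^#start_time=", lines, value = TRUE)
  if (length(st))
    startTime <- sub("^#start_time=", "", st[[1L]])
  body <- lines[!grepl("^#", lines)]
  df <- tryCatch(
    read.csv(text = paste(body, collapse = "\n"), check.names = FALSE,
             fill = FALSE, blank.lines.skip = TRUE),
    error = function(e) stop("malformed session CSV (", conditionMessage(e),
                             ")", call. = FALSE))

  # Resolve canonical names through the schema mapping.
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      idx <- match(schema[[canon]], names(df))
      if (!is.na(idx)) names(df)[idx] <- canon
    }
  }

  pcols <- intersect(paste0("p", 0:7), names(df))
  if (length(pcols) != 8L)
    stop(sprintf(
      "pressure arity violation: expected 8 pressure columns p0..p7, found %d (%s)",
      length(pcols), paste(pcols, collapse = ", ")))
  miss <- setdiff(setdiff(.SESSION_REQUIRED, "t"), names(df))
  miss <- setdiff(miss, paste0("p", 0:7))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!"t" %in% names(df))
    stop("missing required column: t")

  imputed <- integer(0)
  if (nrow(df) > 1L) {
    dt <- diff(df$t)
    if (any(dt <= 0))
      stop(sprintf(
        "non-monotone timestamps: t does not increase at row %d",
        which(dt <= 0)[1L] + 1L))
    if (any(dt > 1)) {
      if (!fillGaps)
        stop(sprintf(
          "gap in 1 Hz time base after t=%d (missing samples are not permitted; see fillGaps)",
          df$t[which(dt > 1)[1L]]))
      big <- which(dt > maxGap + 1)
      if (length(big))
        stop(sprintf("gap of %d s after t=%d exceeds maxGap=%d",
                     dt[big[1L]] - 1L, df$t[big[1L]], as.integer(maxGap)))
      full_t <- seq(df$t[1L], df$t[nrow(df)])
      idx <- findInterval(full_t, df$t)   # hold-last imputation
      imputed <- full_t[!(full_t %in% df$t)] - df$t[1L]
      df <- df[idx, , drop = FALSE]
      df$t <- full_t
    }
  }

  grab <- function(col) if (col %in% names(df)) as.numeric(df[[col]]) else NULL
  rec <- SessionRecord(
    pressure  = as.matrix(df[paste0("p", 0:7)]),
    soundDb   = grab("sound_db"),
    bodyTemp  = grab("body_temp_c"),
    roomTemp  = grab("room_temp_c"),
    humidity  = grab("humidity_pct"),
    co2       = grab("co2_ppm"),
    lux       = grab("lux"),
    heartRate = grab("hr_bpm"),
    startTime = startTime)
  v <- validateSession(rec)
  if (nrow(v))
    stop("session fails validation: ",
         paste(sprintf("%s[%s]: %s", v$channel, v$index, v$rule),
               collapse = "; "))
  if (length(imputed)) attr(rec, "imputed") <- imputed
  rec
}

# Doubles are written with 17 significant digits so that write/read
# round-trips are bit-exact.
.fmt <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  gsub(" ", "", out)
}

#' Write a sleep-session recording to CSV
#'
#' Inverse of [readSession()]: emits the canonical header vocabulary,
#' omitting absent optional channels, preceded by a `#start_time=` comment
#' when the record carries a start timestamp. Numeric values are written at
#' 17 significant digits so the round-trip is exact.
#'
#' @param rec a [SessionRecord-class].
#' @param path output path; a `.gz` suffix writes gzip-compressed output.
#' @return `path`, invisibly.
#' @export
writeSession <- function(rec, path) {
  stopifnot(is(rec, "SessionRecord"))
  n <- nSeconds(rec)
  cols <- list(t = if (n) 0:(n - 1L) else integer(0))
  p <- pressureMatrix(rec)
  for (i in 0:7) cols[[paste0("p", i)]] <- .fmt(p[, i + 1L])
  cols$sound_db     <- .fmt(soundDb(rec))
  cols$body_temp_c  <- .fmt(bodyTemp(rec))
  cols$room_temp_c  <- .fmt(roomTemp(rec))
  cols$humidity_pct <- .fmt(humidity(rec))
  cols$co2_ppm      <- .fmt(co2(rec))
  if (hasLux(rec))       cols$lux    <- .fmt(lux(rec))
  if (hasHeartRate(rec)) cols$hr_bpm <- .fmt(heartRate(rec))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (nzchar(startTime(rec)))
    writeLines(paste0("#start_time=", startTime(rec)), con)
  writeLines(paste(names(cols), collapse = ","), con)
  if (n) {
    df <- do.call(data.frame, c(cols, stringsAsFactors = FALSE))
    write.table(df, con, sep = ",", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Validate a session against the channel range rules
#'
#' Reports (never raises) violations of the recording invariants: equal
#' channel lengths on one 1 Hz time base, eight non-negative pressure
#' channels, temperatures within [-40, 300] degrees C, humidity within
#' [0, 100] percent, non-negative CO2, and heart rate strictly inside
#' (0, 300) bpm when present.
#'
#' @param x a [SessionRecord-class], or a plain named list of channels
#'   (`pressure` matrix plus `soundDb`, `bodyTemp`, `roomTemp`, `humidity`,
#'   `co2`, optionally `lux`, `heartRate`) -- the list form permits checking
#'   structurally broken inputs such as mismatched channel lengths.
#' @param maxReport cap on reported rows per channel/rule pair.
#' @return data.frame with columns `channel`, `index` (0-based second, NA for
#'   structural rules) and `rule`; zero rows iff all invariants hold.
#' @export
validateSession <- function(x, maxReport = 100L) {
  if (is(x, "SessionRecord")) {
    x <- list(pressure = x@pressure, soundDb = x@soundDb,
              bodyTemp = x@bodyTemp, roomTemp = x@roomTemp,
              humidity = x@humidity, co2 = x@co2,
              lux = if (length(x@lux)) x@lux else NULL,
              heartRate = if (length(x@heartRate)) x@heartRate else NULL)
  }
  out <- list()
  add <- function(channel, index, rule) {
    if (length(index) > maxReport) index <- head(index, maxReport)
    out[[length(out) + 1L]] <<- data.frame(
      channel = channel, index = index, rule = rule,
      stringsAsFactors = FALSE)
  }

  p <- x$pressure
  if (is.null(p) || ncol(as.matrix(p)) != 8L) {
    add("pressure", NA_integer_,
        sprintf("arity: expected 8 pressure channels, found %d",
                if (is.null(p)) 0L else ncol(as.matrix(p))))
    n <- if (is.null(p)) 0L else nrow(as.matrix(p))
  } else {
    p <- as.matrix(p)
    n <- nrow(p)
    bad <- which(rowSums(p < 0 | !is.finite(p)) > 0) - 1L
    if (length(bad)) add("pressure", bad, "pressure readings must be finite and >= 0")
  }

  ranges <- list(
    soundDb   = c(-Inf, Inf),
    bodyTemp  = c(-40, 300),
    roomTemp  = c(-40, 300),
    humidity  = c(0, 100),
    co2       = c(0, Inf))
  for (ch in names(ranges)) {
    v <- x[[ch]]
    if (is.null(v)) { add(ch, NA_integer_, "required channel absent"); next }
    if (length(v) != n) {
      add(ch, NA_integer_, sprintf(
        "time base: channel length %d != %d (all channels share one 1 Hz grid)",
        length(v), n))
      next
    }
    lohi <- ranges[[ch]]
    bad <- which(!is.finite(v) | v < lohi[1L] | v > lohi[2L]) - 1L
    if (length(bad))
      add(ch, bad, sprintf("range: %s must lie in [%s, %s]",
                           ch, lohi[1L], lohi[2L]))
  }
  for (ch in c("lux", "heartRate")) {
    v <- x[[ch]]
    if (is.null(v)) next
    if (length(v) != n) {
      add(ch, NA_integer_, sprintf(
        "time base: channel length %d != %d (all channels share one 1 Hz grid)",
        length(v), n))
      next
    }
    if (ch == "heartRate") {
      bad <- which(!is.finite(v) | v <= 0 | v >= 300) - 1L
      if (length(bad))
        add(ch, bad, "range: heart rate must lie strictly inside (0, 300) bpm")
    } else {
      bad <- which(!is.finite(v) | v < 0) - 1L
      if (length(bad)) add(ch, bad, "range: lux must be finite and >= 0")
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(channel = character(0), index = integer(0),
                  rule = character(0), stringsAsFactors = FALSE)
}
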