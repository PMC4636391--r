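#' Construct a telemetry record
#'
#' @param trapId trap identifier.
#' @param timestamp ISO-8601 timestamp string.
#' @param eventsTotal total triggered events.
#' @param matchesTotal target-species matches (<= eventsTotal).
#' @param temperatureC,humidityPct auxiliary climate sensor readings.
#' @param latitude,longitude GPS coordinates, decimal degrees.
#' @param batteryPct battery level in [0, 100].
#' @return a validated [TelemetryRecord].
#' @examples
#' telemetryRecord("trap-1", eventsTotal = 23, matchesTotal = 3,
#'                 temperatureC = 29, humidityPct = 69, batteryPct = 81)
#' @export
telemetryRecord <- function(trapId, timestamp = "1970-01-01T00:00:00Z",
                            eventsTotal = 0L, matchesTotal = 0L,
                            temperatureC = NA_real_, humidityPct = NA_real_,
                            latitude = NA_real_, longitude = NA_real_,
                            batteryPct = NA_real_) {
  new("TelemetryRecord", trapId = trapId, timestamp = timestamp,
      eventsTotal = as.integer(eventsTotal),
      matchesTotal = as.integer(matchesTotal),
      temperatureC = as.numeric(temperatureC),
      humidityPct = as.numeric(humidityPct),
      latitude = as.numeric(latitude), longitude = as.numeric(longitude),
      batteryPct = as.numeric(batteryPct))
}

#' Run the full trap pipeline on a sample stream
#'
#' The software twin of the trap firmware loop: frame-wise RMS detection,
#' Hamming/FFT signature extraction, and open-set verification of every
#' detected event against the codebook. Events whose spectrum is degenerate
#' (all-zero after the DC cut) are counted as events but never as matches.
#'
#' @param stream numeric sample stream, or a path to a mono PCM WAV file.
#' @param codebook a calibrated [Codebook].
#' @param config a [DetectionConfig].
#' @param trapId,timestamp,temperatureC,humidityPct,latitude,longitude,batteryPct
#'   sensor metadata passed through to the [TelemetryRecord].
#' @param dcCutBins lowest spectral bins to zero (see [magnitudeSpectrum()]).
#' @return list with `record` (a [TelemetryRecord]) and `log` (a data.frame
#'   with one row per detected event: `onset_sample`, `rms`, `distance`,
#'   `decision`).
#' @examples
#' st <- synthStream(list(speciesPreset("b_oleae")), 3, seed = 2, noiseSd = 0)
#' sigs <- t(sapply(1:40, function(i)
#'   eventToSignature(synthEvent(speciesPreset("b_oleae"), 128, seed = i)@samples)))
#' bk <- learnCodebook(sigs, seed = 1)
#' runTrap(st$samples, bk)$record
#' @export
runTrap <- function(stream, codebook, config = detectionConfig(),
                    trapId = "trap-1", timestamp = "1970-01-01T00:00:00Z",
                    temperatureC = NA, humidityPct = NA,
                    latitude = NA, longitude = NA, batteryPct = NA,
                    dcCutBins = 3L) {
  if (is.character(stream)) {
    wav <- readWav(stream)
    stopInvalid(abs(wav$fs - config@fs) > 1e-9,
                sprintf("WAV rate %g Hz differs from configured %g Hz",
                        wav$fs, config@fs))
    stream <- wav$samples
  }
  stopInvalid(is.na(codebook@threshold), "codebook is not calibrated")
  det <- detectEvents(stream, config)
  n <- nrow(det$log)
  dist <- rep(NA_real_, n)
  decision <- character(n)
  for (i in seq_len(n)) {
    x <- if (is.null(det$samples)) det$frames[i, ] else det$samples[[i]]
    sig <- tryCatch(
      eventToSignature(x, nFft = config@frameLen, dcCutBins = dcCutBins),
      error = function(e) NULL)
    if (is.null(sig)) {
      decision[i] <- "degenerate"
    } else {
      v <- verify(sig, codebook)
      dist[i] <- v$distance
      decision[i] <- v$decision
    }
  }
  log <- cbind(det$log[, c("onset_sample", "rms")],
               data.frame(distance = dist, decision = decision))
  record <- telemetryRecord(trapId, timestamp, eventsTotal = n,
                            matchesTotal = sum(decision == "target"),
                            temperatureC = temperatureC,
                            humidityPct = humidityPct, latitude = latitude,
                            longitude = longitude, batteryPct = batteryPct)
  list(record = record, log = log)
}

reportKeys <- c("id", "ts", "events", "matches", "t", "h", "lat", "lon", "batt")

fmtNum <- function(x) {
  if (is.na(x)) "NA" else format(x, digits = 15, scientific = FALSE, trim = TRUE)
}

#' Format a telemetry record as an SMS line or JSON object
#'
#' The SMS format is a single versioned line of space-separated `key=value`
#' fields (`ETv1 id=... ts=... events=... matches=... t=... h=... lat=...
#' lon=... batt=...`), capped at 160 characters — an over-long payload is an
#' error, never a silent truncation. The JSON format is a flat object with
#' the same keys. Both round-trip losslessly through [parseReport()].
#'
#' @param record a [TelemetryRecord].
#' @param format `"sms"` or `"json"`.
#' @return payload text (single character string).
#' @examples
#' rec <- telemetryRecord("trap-1", eventsTotal = 23, matchesTotal = 3,
#'                        temperatureC = 29, humidityPct = 69, batteryPct = 81)
#' buildReport(rec, "sms")
#' @export
buildReport <- function(record, format = c("sms", "json")) {
  format <- match.arg(format)
  validObject(record)
  vals <- list(id = record@trapId, ts = record@timestamp,
               events = record@eventsTotal, matches = record@matchesTotal,
               t = record@temperatureC, h = record@humidityPct,
               lat = record@latitude, lon = record@longitude,
               batt = record@batteryPct)
  if (format == "json")
    return(as.character(jsonlite::toJSON(vals, auto_unbox = TRUE,
                                         digits = NA, na = "null")))
  fields <- vapply(reportKeys, function(k) {
    v <- vals[[k]]
    paste0(k, "=", if (is.character(v)) v else fmtNum(v))
  }, character(1))
  payload <- paste("ETv1", paste(fields, collapse = " "))
  stopInvalid(nchar(payload) > 160,
              sprintf("SMS payload is %d characters (limit 160)", nchar(payload)))
  payload
}

#' Parse a telemetry payload back into a record
#'
#' Exact inverse of [buildReport()]; accepts both formats (JSON payloads
#' start with `{`). A missing required key or an out-of-range value is an
#' error naming the offending field.
#'
#' @param payload text produced by [buildReport()].
#' @return a validated [TelemetryRecord].
#' @export
parseReport <- function(payload) {
  if (startsWith(trimws(payload), "{")) {
    obj <- jsonlite::fromJSON(payload)
    vals <- lapply(reportKeys, function(k) if (is.null(obj[[k]])) NA else obj[[k]])
    names(vals) <- reportKeys
    missing <- reportKeys[!reportKeys %in% names(obj)]
  } else {
    toks <- strsplit(trimws(payload), " +")[[1]]
    stopInvalid(length(toks) < 1 || toks[1] != "ETv1",
                "malformed payload: missing ETv1 version tag")
    kv <- strsplit(toks[-1], "=", fixed = TRUE)
    bad <- vapply(kv, function(p) length(p) != 2, logical(1))
    stopInvalid(any(bad), paste("malformed field:", toks[-1][bad][1]))
    keys <- vapply(kv, `[`, character(1), 1)
    vals <- as.list(vapply(kv, `[`, character(1), 2))
    names(vals) <- keys
    missing <- setdiff(reportKeys, keys)
  }
  stopInvalid(length(missing) > 0,
              paste("payload missing required key(s):",
                    paste(missing, collapse = ", ")))
  asNum <- function(k) {
    v <- vals[[k]]
    if (is.character(v) && v == "NA" || is.null(v) || (length(v) == 1 && is.na(v)))
      return(NA_real_)
    out <- suppressWarnings(as.numeric(v))
    stopInvalid(is.na(out), paste("field", k, "is not numeric:", v))
    out
  }
  telemetryRecord(trapId = as.character(vals$id),
                  timestamp = as.character(vals$ts),
                  eventsTotal = asNum("events"), matchesTotal = asNum("matches"),
                  temperatureC = asNum("t"), humidityPct = asNum("h"),
                  latitude = asNum("lat"), longitude = asNum("lon"),
                  batteryPct = asNum("batt"))
}

#' @describeIn TelemetryRecord-class display summary
#' @param object a TelemetryRecord
#' @export
setMethod("show", "TelemetryRecord", function(object) {
  cat(sprintf("TelemetryRecord %s @ %s: %d events, %d matches\n",
              object@trapId, object@timestamp, object@eventsTotal,
              object@matchesTotal))
  cat(sprintf("  t=%s°C h=%s%% lat=%s lon=%s batt=%s%%\n",
              fmtNum(object@temperatureC), fmtNum(object@humidityPct),
              fmtNum(object@latitude), fmtNum(object@longitude),
              fmtNum(object@batteryPct)))
})
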