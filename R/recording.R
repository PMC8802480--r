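## signal_io: waveform recordings and event tables in plain-text formats.
##
## Canonical conventions used throughout the package:
##   * flow in L/s, inspiratory positive, expiratory negative
##   * pressures (Paw, Pes) in cmH2O
##   * time in seconds from recording start; sample k lies at t0 + k/rate

#' Construct a waveform recording
#'
#' A `vent_recording` holds uniformly sampled flow and airway-pressure
#' channels (and optionally esophageal pressure) from a pressure-support
#' ventilation episode, together with the sampling rate. All channels
#' must have the same length and contain only finite values.
#'
#' @param flow numeric vector, flow at the airway opening (L/s,
#'   inspiratory positive).
#' @param paw numeric vector, airway pressure (cmH2O).
#' @param pes optional numeric vector, esophageal pressure (cmH2O).
#' @param sample_rate sampling rate in Hz.
#' @param t0 time of the first sample in seconds (default 0).
#' @param meta named list of free-form annotations.
#' @return An object of class `vent_recording`.
#' @export
vent_recording <- function(flow, paw, pes = NULL, sample_rate = 100,
                           t0 = 0, meta = list()) {
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  stopifnot_scalar(t0, "t0")
  flow <- as.numeric(flow); paw <- as.numeric(paw)
  if (!is.null(pes)) pes <- as.numeric(pes)
  n <- length(flow)
  if (n < 2L) abort_data("recording channels must have length >= 2")
  if (length(paw) != n || (!is.null(pes) && length(pes) != n))
    abort_data("all channels of a recording must have identical length")
  for (ch in list(flow = flow, paw = paw, pes = pes)) {
    if (!is.null(ch) && any(!is.finite(ch)))
      abort_data("recording channels must not contain non-finite samples")
  }
  structure(list(sample_rate = sample_rate, t0 = t0,
                 flow = flow, paw = paw, pes = pes, meta = meta),
            class = "vent_recording")
}

#' Sample times of a recording
#' @param rec a `vent_recording`.
#' @return Numeric vector of timestamps in seconds.
#' @export
rec_time <- function(rec) {
  rec$t0 + (seq_along(rec$flow) - 1L) / rec$sample_rate
}

#' Duration of a recording in seconds
#' @param rec a `vent_recording`.
#' @export
rec_duration <- function(rec) (length(rec$flow) - 1L) / rec$sample_rate

#' @export
print.vent_recording <- function(x, ...) {
  cat(sprintf("<vent_recording> %d samples @ %g Hz (%.1f s)%s\n",
              length(x$flow), x$sample_rate, rec_duration(x),
              if (is.null(x$pes)) "" else ", with Pes"))
  invisible(x)
}

#' @export
plot.vent_recording <- function(x, channels = c("paw", "flow", "pes"),
                                events = NULL, ...) {
  channels <- intersect(channels, c("paw", "flow", if (!is.null(x$pes)) "pes"))
  tt <- rec_time(x)
  old <- graphics::par(mfrow = c(length(channels), 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  labs <- c(paw = "Paw (cmH2O)", flow = "Flow (L/s)", pes = "Pes (cmH2O)")
  for (ch in channels) {
    graphics::plot(tt, x[[ch]], type = "l", xlab = "", ylab = labs[[ch]], ...)
    if (!is.null(events) && nrow(events))
      graphics::rect(events$start_s, graphics::par("usr")[3],
                     events$end_s, graphics::par("usr")[4],
                     col = grDevices::adjustcolor("grey", 0.35), border = NA)
  }
  invisible(x)
}

#' Read a waveform recording from CSV
#'
#' The CSV dialect is comma-separated with a mandatory header naming at
#' least `time_s`, `flow_lps` and `paw_cmh2o`; an optional `pes_cmh2o`
#' column carries esophageal pressure. The sampling rate is inferred
#' from the median time step; time steps deviating by more than 1% from
#' the median are rejected as jitter.
#'
#' @param path path to the CSV file.
#' @param format input format; only `"csv"` is supported (`"edf"` is
#'   reserved and raises a capability error).
#' @return A [vent_recording].
#' @export
read_recording <- function(path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (format == "edf")
    abort_capability("EDF ingestion is not available in this build; convert to the waveform CSV dialect")
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "flow_lps", "paw_cmh2o")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    abort_format(sprintf("CSV is missing mandatory column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  tt <- as.numeric(df$time_s)
  if (length(tt) < 2L) abort_data("recording must contain at least 2 samples")
  dt <- diff(tt)
  if (any(dt <= 0)) abort_data("time column must be strictly increasing")
  med <- stats::median(dt)
  if (max(abs(dt - med)) > 0.01 * med)
    abort_data("time step jitter exceeds 1% of the median step; resample before import")
  vent_recording(flow = df$flow_lps, paw = df$paw_cmh2o,
                 pes = if ("pes_cmh2o" %in% names(df)) df$pes_cmh2o,
                 sample_rate = 1 / med, t0 = tt[1L])
}

#' Write a waveform recording to CSV
#'
#' Values are written with enough digits that a read/write round trip
#' reproduces every sample to better than 1e-6.
#'
#' @param rec a [vent_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "vent_recording")) abort_argument("`rec` must be a vent_recording")
  df <- data.frame(time_s = rec_time(rec), flow_lps = rec$flow,
                   paw_cmh2o = rec$paw)
  if (!is.null(rec$pes)) df$pes_cmh2o <- rec$pes
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write recording to %s", path))
  invisible(path)
}

#' Resample a recording onto a uniform grid
#'
#' Linear interpolation of every channel onto a uniform grid at
#' `target_rate`; the duration is preserved to within one target sample
#' period.
#'
#' @param rec a [vent_recording].
#' @param target_rate new sampling rate in Hz.
#' @return A [vent_recording] at `target_rate`.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot_scalar(target_rate, "target_rate", positive = TRUE)
  tt <- rec_time(rec)
  new_t <- seq(rec$t0, tt[length(tt)], by = 1 / target_rate)
  interp <- function(y) stats::approx(tt, y, xout = new_t, rule = 2)$y
  vent_recording(flow = interp(rec$flow), paw = interp(rec$paw),
                 pes = if (!is.null(rec$pes)) interp(rec$pes),
                 sample_rate = target_rate, t0 = rec$t0, meta = rec$meta)
}

## ---- event tables ----------------------------------------------------------

EVENT_KINDS   <- c("effort", "machine_breath")
EVENT_SOURCES <- c("pes", "waveform", "truth", "machine")

#' Construct an event table
#'
#' An event table lists detected or ground-truth intervals: patient
#' inspiratory efforts or ventilator inspiratory phases. Rows are
#' sorted by start time; events of the same kind and source must not
#' overlap and must satisfy `end_s > start_s`.
#'
#' @param event_kind character, `"effort"` or `"machine_breath"`.
#' @param start_s,end_s interval bounds in seconds.
#' @param source provenance: `"pes"`, `"waveform"`, `"truth"` or
#'   `"machine"`.
#' @param label optional class label per row.
#' @return A `data.frame` of class `event_table`.
#' @export
event_table <- function(event_kind = character(), start_s = numeric(),
                        end_s = numeric(), source = character(),
                        label = NA_character_) {
  n <- length(start_s)
  df <- data.frame(event_kind = rep_len(as.character(event_kind), n),
                   start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   source = rep_len(as.character(source), n),
                   label = rep_len(as.character(label), n),
                   stringsAsFactors = FALSE)
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  validate_event_table(df)
  class(df) <- c("event_table", "data.frame")
  df
}

validate_event_table <- function(df) {
  if (!nrow(df)) return(invisible(df))
  if (!all(df$event_kind %in% EVENT_KINDS))
    abort_data("event_kind must be 'effort' or 'machine_breath'")
  if (!all(df$source %in% EVENT_SOURCES))
    abort_data("source must be one of pes/waveform/truth/machine")
  if (any(df$end_s <= df$start_s))
    abort_data("every event must satisfy end_s > start_s")
  for (grp in split(df, paste(df$event_kind, df$source))) {
    g <- grp[order(grp$start_s), ]
    if (nrow(g) > 1L && any(g$start_s[-1L] < g$end_s[-nrow(g)] - 1e-9))
      abort_data("events of the same kind and source must not overlap")
  }
  invisible(df)
}

#' Read an event table from TSV
#' @param path path to a TSV with columns event_kind, start_s, end_s,
#'   source, label.
#' @return An [event_table].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("event_kind", "start_s", "end_s", "source")
  if (length(setdiff(need, names(df))))
    abort_format("event TSV must have columns event_kind, start_s, end_s, source")
  event_table(df$event_kind, df$start_s, df$end_s, df$source,
              if ("label" %in% names(df)) df$label else NA_character_)
}

#' Write an event table to TSV
#' @param events an [event_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
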