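#' @include AllClasses.R
NULL

# Read an XLSX or CSV ROI table into a data.frame with checked numeric body.
# Contract shared by readTraceTable and attachReference: first row text headers,
# all subsequent cells numeric. Errors cite the offending cell.
readRoiTable <- function(path, sheet = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet,
                                           col_types = "text"),
                        stringsAsFactors = FALSE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  }
  if (!ncol(df) || !nrow(df)) {
    stop(sprintf("table '%s' has no data rows below the header (row 1)", path),
         call. = FALSE)
  }
  if (any(!nzchar(names(df))) || anyNA(names(df))) {
    stop(sprintf("table '%s' is missing column headers in row 1", path),
         call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(NULL, names(df)))
  for (j in seq_along(df)) {
    col <- df[[j]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop(sprintf(
        "non-numeric cell in '%s': row %d (below header), column '%s' (value '%s')",
        path, bad[1L], names(df)[j], col[bad[1L]]), call. = FALSE)
    }
    out[, j] <- num
  }
  as.data.frame(out, check.names = FALSE)
}

#' Read an ROI intensity table into Recordings
#'
#' Imports a delimited spreadsheet (XLSX or CSV) as exported from Fiji/ImageJ
#' "Multi Measure": the first row holds column headers, every following row is
#' numeric, one column carries time (ms) or frame numbers on the x-axis and
#' each remaining column is one ROI's mean fluorescence. One
#' [Recording-class] is returned per ROI column, all sharing the same time
#' axis. When the x column holds frame numbers, times are synthesized from
#' `frameRate` (frame k at `startTime + k * 1000/frameRate` ms).
#'
#' @param path XLSX or CSV file.
#' @param xType `"time"` if the x column holds milliseconds, `"frame"` if it
#'   holds frame numbers.
#' @param frameRate frames per second. Required when `xType = "frame"`; when
#'   `xType = "time"` it is inferred from the median time step if omitted.
#' @param xColumn name of the x column (default: first column).
#' @param sheet XLSX sheet name or index (default: first sheet).
#' @param jitterTolerance maximum allowed relative deviation of time steps
#'   from their median (default 0.001); larger jitter is rejected since the
#'   analysis assumes uniform sampling.
#' @return A named list of [Recording-class] objects, one per ROI column.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(time = (0:9) * 10, roi1 = rnorm(10, 100)),
#'           tf, row.names = FALSE)
#' recs <- readTraceTable(tf)
#' @export
readTraceTable <- function(path, xType = c("time", "frame"), frameRate = NULL,
                           xColumn = NULL, sheet = NULL,
                           jitterTolerance = 0.001) {
  xType <- match.arg(xType)
  df <- readRoiTable(path, sheet = sheet)
  if (ncol(df) < 2L) {
    stop("table must have an x column plus at least one ROI column", call. = FALSE)
  }
  if (is.null(xColumn)) xColumn <- names(df)[1L]
  if (!xColumn %in% names(df)) {
    stop(sprintf("x column '%s' not found", xColumn), call. = FALSE)
  }
  x <- df[[xColumn]]
  roiNames <- setdiff(names(df), xColumn)

  if (xType == "frame") {
    if (is.null(frameRate)) {
      stop("frameRate is required when the x column holds frame numbers",
           call. = FALSE)
    }
    t0 <- x[1L] * 1000 / frameRate
  } else {
    dt <- diff(x)
    if (any(dt <= 0)) stop("time column must be strictly increasing", call. = FALSE)
    step <- median(dt)
    if (any(abs(dt - step) > jitterTolerance * step)) {
      stop(sprintf(
        "non-uniform sampling: time steps deviate more than %.3g%% from %.6g ms",
        100 * jitterTolerance, step), call. = FALSE)
    }
    if (is.null(frameRate)) frameRate <- 1000 / step
    t0 <- x[1L]
  }
  meta <- acquisitionMeta(frameRate = frameRate, startTime = t0)
  out <- lapply(roiNames, function(nm) {
    recording(df[[nm]], meta = meta, roiId = nm)
  })
  names(out) <- roiNames
  out
}

#' Attach a reference channel to existing Recordings
#'
#' Reads a second-channel table (e.g. the calcium-insensitive mScarlet
#' fluorophore) and pairs its ROI columns with the signal Recordings by ROI
#' header name — never by column order.
#'
#' @param recordings named list of [Recording-class] as from [readTraceTable()].
#' @param path reference-channel table (XLSX or CSV) with matching ROI headers
#'   and row count.
#' @param xColumn,sheet as in [readTraceTable()].
#' @return The list of Recordings, each with its reference series attached.
#' @export
attachReference <- function(recordings, path, xColumn = NULL, sheet = NULL) {
  df <- readRoiTable(path, sheet = sheet)
  if (is.null(xColumn)) xColumn <- names(df)[1L]
  refNames <- setdiff(names(df), xColumn)
  missing <- setdiff(names(recordings), refNames)
  if (length(missing)) {
    stop(sprintf("reference table lacks ROI column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  n <- length(signalValues(recordings[[1L]]))
  if (nrow(df) != n) {
    stop(sprintf("reference table has %d rows but recordings have %d frames",
                 nrow(df), n), call. = FALSE)
  }
  lapply(setNames(names(recordings), names(recordings)), function(nm) {
    rec <- recordings[[nm]]
    recording(signalValues(rec), meta = acqMeta(rec), roiId = nm,
              reference = df[[nm]], mode = traceMode(rec))
  })
}

#' Write Recordings back to the shared table format
#'
#' Writes a set of Recordings sharing one time axis as a CSV in the same
#' layout [readTraceTable()] reads (time column + one column per ROI), with
#' full double precision so a read/write round trip is bit-exact.
#'
#' @param recordings named list of [Recording-class] with identical time axes.
#' @param path output CSV path.
#' @param channel `"signal"` (default) or `"reference"`.
#' @return The path, invisibly.
#' @export
writeTraceTable <- function(recordings, path, channel = c("signal", "reference")) {
  channel <- match.arg(channel)
  tp <- timePoints(recordings[[1L]])
  cols <- lapply(recordings, function(r) {
    v <- if (channel == "signal") signalValues(r) else referenceValues(r)
    if (is.null(v)) stop(sprintf("recording '%s' has no reference channel",
                                 roiId(r)), call. = FALSE)
    if (length(v) != length(tp)) stop("recordings differ in length", call. = FALSE)
    v
  })
  df <- data.frame(time = tp, cols, check.names = FALSE)
  names(df) <- c("time", names(recordings))
  out <- df
  for (j in seq_along(out)) out[[j]] <- sprintf("%.17g", out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a duration in frames to milliseconds
#'
#' Fitted time constants obtained on a frame axis are converted to time by
#' multiplying by the frame interval \eqn{\Delta t = 1000 / \mathrm{frame\ rate}} ms.
#'
#' @param tauFrames duration(s) in frames.
#' @param frameRate frames per second (> 0).
#' @return Duration(s) in ms.
#' @examples
#' framesToMs(5, 100)    # 50 ms
#' @export
framesToMs <- function(tauFrames, frameRate) {
  assertScalarNumber(frameRate, "frameRate", positive = TRUE)
  tauFrames * (1000 / frameRate)
}

# ---- Event table contract ------------------------------------------------

eventColumns <- c("roi", "peak_index", "peak_time", "amplitude", "tau_rise",
                  "tau_decay", "onset_time", "fit_rss", "converged",
                  "source", "label")

#' An empty detected-event table
#'
#' Detected transients are represented as a data.frame with one row per event:
#' `roi`, `peak_index` (0-based frame), `peak_time` (ms), `amplitude`
#' (dF/F or dR/R), `tau_rise` / `tau_decay` / `onset_time` (ms, NA until
#' fitted), `fit_rss`, `converged`, `source` (`"auto"` or `"manual"`), and
#' `label` (protocol block or `"unassigned"`/`"spontaneous"`).
#'
#' @return A zero-row data.frame with the event columns.
#' @export
emptyEvents <- function() {
  data.frame(roi = character(0), peak_index = integer(0),
             peak_time = numeric(0), amplitude = numeric(0),
             tau_rise = numeric(0), tau_decay = numeric(0),
             onset_time = numeric(0), fit_rss = numeric(0),
             converged = logical(0), source = character(0),
             label = character(0), stringsAsFactors = FALSE)
}

makeEvents <- function(roi, peakIndex, peakTime, amplitude,
                       source = "auto", label = "unassigned") {
  n <- length(peakIndex)
  if (!n) return(emptyEvents())
  data.frame(roi = rep_len(roi, n), peak_index = as.integer(peakIndex),
             peak_time = as.numeric(peakTime), amplitude = as.numeric(amplitude),
             tau_rise = NA_real_, tau_decay = NA_real_, onset_time = NA_real_,
             fit_rss = NA_real_, converged = NA,
             source = rep_len(source, n), label = rep_len(label, n),
             stringsAsFactors = FALSE)
}
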