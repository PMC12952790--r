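#' @include AllClasses.R normalization.R detection.R kinetics.R protocol.R
#' @include paired-stats.R synthetic.R
NULL

runConfigDefaults <- list(
  input = list(signal = NULL, reference = NULL, x_type = "time",
               frame_rate = NULL, x_column = NULL, sheet = NULL),
  normalization = list(mode = "auto", window = 101L, method = NULL,
                       percentile = 30, fraction = 0.10, smooth_window = 1L),
  detection = list(threshold = NULL, min_width = 1L, min_distance_ms = 0,
                   search_radius_ms = 200, smooth_window = 1L,
                   amplitude_mode = "from_zero"),
  kinetics = list(fit_span_ms = NULL),
  protocol = list(blocks = NULL, latency_window_ms = 100),
  match = list(ephys = NULL, tolerance_ms = 50),
  simulate = list(),
  output = list(dir = "."),
  seed = 1L,
  log_level = "info"
)

mergeDefaults <- function(cfg, defaults) {
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- defaults[[nm]]
    } else if (is.list(defaults[[nm]]) && is.list(cfg[[nm]]) &&
               !is.null(names(defaults[[nm]]))) {
      cfg[[nm]] <- mergeDefaults(cfg[[nm]], defaults[[nm]])
    }
  }
  cfg
}

#' Read and resolve a run configuration
#'
#' Loads a YAML run configuration, validates it, and fills every default so
#' the resolved copy written next to the outputs fully documents the run
#' (normalization window/percentile, detection settings, protocol, seed).
#'
#' @param path YAML file, or a named list to resolve directly.
#' @return A resolved configuration list of class `"RunConfig"`.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop(sprintf("config not found: %s", path), call. = FALSE)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else {
    stop("path must be a file path or a list", call. = FALSE)
  }
  cfg <- mergeDefaults(cfg, runConfigDefaults)
  if (!cfg$normalization$mode %in% c("auto", "dff", "drr")) {
    stop("normalization$mode must be auto, dff or drr", call. = FALSE)
  }
  if (!is.null(cfg$normalization$method) &&
      !cfg$normalization$method %in% c("percentile", "lowest_fraction")) {
    stop("normalization$method must be percentile or lowest_fraction", call. = FALSE)
  }
  if (!cfg$input$x_type %in% c("time", "frame")) {
    stop("input$x_type must be 'time' or 'frame'", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

# Protocol blocks in the config are a list of maps, each either
# {label, frequency_hz, times: [...]} or
# {label, frequency_hz, n_stimuli, first_stimulus_ms}.
configProtocol <- function(cfg) {
  blocks <- cfg$protocol$blocks
  if (is.null(blocks)) return(NULL)
  lab <- vapply(blocks, `[[`, character(1), "label")
  frq <- vapply(blocks, `[[`, numeric(1), "frequency_hz")
  times <- lapply(blocks, function(b) {
    if (!is.null(b$times)) return(as.numeric(b$times))
    b$first_stimulus_ms + (seq_len(b$n_stimuli) - 1) * 1000 / b$frequency_hz
  })
  stimulusProtocol(lab, frq, times)
}

loadRecordings <- function(cfg) {
  recs <- readTraceTable(cfg$input$signal, xType = cfg$input$x_type,
                         frameRate = cfg$input$frame_rate,
                         xColumn = cfg$input$x_column, sheet = cfg$input$sheet)
  if (!is.null(cfg$input$reference)) {
    recs <- attachReference(recs, cfg$input$reference,
                            xColumn = cfg$input$x_column,
                            sheet = cfg$input$sheet)
  }
  recs
}

normalizeRecording <- function(rec, cfg) {
  nc <- cfg$normalization
  mode <- nc$mode
  if (mode == "auto") mode <- if (hasReference(rec)) "drr" else "dff"
  method <- nc$method
  if (is.null(method)) {
    method <- if (mode == "drr") "lowest_fraction" else "percentile"
  }
  params <- baselineParams(window = nc$window, method = method,
                           percentile = nc$percentile, fraction = nc$fraction,
                           smoothWindow = nc$smooth_window)
  if (mode == "drr") normalizeDRR(rec, params) else normalizeDFF(rec, params)
}

# Run `expr`; on error remove any files created under outDir during the run,
# then rethrow. Keeps failed runs from leaving partial outputs behind.
withCleanOutputs <- function(outDir, expr) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  before <- list.files(outDir, full.names = TRUE)
  tryCatch(expr, error = function(e) {
    created <- setdiff(list.files(outDir, full.names = TRUE), before)
    unlink(created)
    stop(e)
  })
}

writeResolvedConfig <- function(cfg, outDir) {
  yaml::write_yaml(unclass(cfg), file.path(outDir, "resolved_config.yaml"))
}

#' Normalize ROI tables from a run configuration
#'
#' Reads the configured signal (and optional reference) tables, normalizes
#' every ROI to dF/F or dR/R, and writes `normalized.csv` and `baseline.csv`
#' (time column + one column per ROI) plus the resolved configuration to the
#' output directory.
#'
#' @param config path to a YAML run configuration or a resolved
#'   [readRunConfig()] list.
#' @return Named vector of output paths, invisibly.
#' @export
cmdNormalize <- function(config) {
  cfg <- readRunConfig(config)
  outDir <- cfg$output$dir
  withCleanOutputs(outDir, {
    recs <- loadRecordings(cfg)
    traces <- lapply(recs, normalizeRecording, cfg = cfg)
    tp <- timePoints(traces[[1L]])
    normDf <- data.frame(time = tp, lapply(traces, traceValues),
                         check.names = FALSE)
    baseDf <- data.frame(time = tp, lapply(traces, baselineValues),
                         check.names = FALSE)
    names(normDf) <- names(baseDf) <- c("time", names(traces))
    paths <- c(normalized = file.path(outDir, "normalized.csv"),
               baseline = file.path(outDir, "baseline.csv"))
    writeTableCsv(normDf, paths[["normalized"]])
    writeTableCsv(baseDf, paths[["baseline"]])
    writeResolvedConfig(cfg, outDir)
    invisible(paths)
  })
}

#' Detect, fit and partition events from a run configuration
#'
#' Normalizes the configured recordings, runs automated detection with the
#' configured settings, fits rise/decay kinetics for every event, partitions
#' events across protocol blocks when a protocol is configured, and writes
#' one `events.csv` row per event (roi, 0-based peak frame, time, amplitude,
#' kinetics, diagnostics, source, label).
#'
#' @param config path to a YAML run configuration or a resolved list.
#' @return The events data.frame, invisibly.
#' @export
cmdDetectFit <- function(config) {
  cfg <- readRunConfig(config)
  if (is.null(cfg$detection$threshold)) {
    stop("detection$threshold is required", call. = FALSE)
  }
  outDir <- cfg$output$dir
  withCleanOutputs(outDir, {
    recs <- loadRecordings(cfg)
    settings <- detectionSettings(threshold = cfg$detection$threshold,
                                  minWidth = cfg$detection$min_width,
                                  minDistance = cfg$detection$min_distance_ms,
                                  searchRadius = cfg$detection$search_radius_ms,
                                  smoothWindow = cfg$detection$smooth_window)
    proto <- configProtocol(cfg)
    all <- lapply(recs, function(rec) {
      tr <- normalizeRecording(rec, cfg)
      ev <- detectPeaks(tr, settings,
                        amplitudeMode = cfg$detection$amplitude_mode)
      ev <- fitEvents(tr, ev, fitSpanMs = cfg$kinetics$fit_span_ms)
      if (!is.null(proto)) {
        ev <- partitionEvents(ev, proto,
                              latencyWindow = cfg$protocol$latency_window_ms)
      }
      ev
    })
    events <- do.call(rbind, c(all, list(make.row.names = FALSE)))
    if (is.null(events)) events <- emptyEvents()
    writeTableCsv(events, file.path(outDir, "events.csv"))
    writeResolvedConfig(cfg, outDir)
    invisible(events)
  })
}

#' Match optical events to electrophysiological minis from a configuration
#'
#' Consumes a detected-event CSV (as written by [cmdDetectFit()]) and a
#' two-column ephys CSV (`time`/`time_ms`, `amplitude`/`amplitude_mV`),
#' matches them within the configured tolerance, and writes `pairs.csv` plus
#' `match_summary.json` (detection fraction, Pearson r, R-squared, n).
#'
#' @param config path to a YAML run configuration or a resolved list. The
#'   configuration's `match$events` (default `<output dir>/events.csv`) and
#'   `match$ephys` name the inputs.
#' @return The summary list, invisibly.
#' @export
cmdMatch <- function(config) {
  cfg <- readRunConfig(config)
  if (is.null(cfg$match$ephys)) stop("match$ephys is required", call. = FALSE)
  outDir <- cfg$output$dir
  eventsPath <- cfg$match$events
  if (is.null(eventsPath)) eventsPath <- file.path(outDir, "events.csv")
  withCleanOutputs(outDir, {
    ev <- read.csv(eventsPath, stringsAsFactors = FALSE)
    eph <- read.csv(cfg$match$ephys, stringsAsFactors = FALSE)
    names(eph)[names(eph) == "time_ms"] <- "time"
    names(eph)[names(eph) == "amplitude_mV"] <- "amplitude"
    if (!nrow(eph)) stop("ephys event list is empty", call. = FALSE)
    mr <- matchEvents(ev, eph, tolerance = cfg$match$tolerance_ms)
    writeTableCsv(matchedPairs(mr), file.path(outDir, "pairs.csv"))
    summary <- list(n_pairs = nrow(matchedPairs(mr)),
                    n_ephys = nrow(matchedPairs(mr)) + nrow(unmatchedEphys(mr)),
                    n_optical = nrow(matchedPairs(mr)) + nrow(unmatchedOptical(mr)),
                    detection_fraction = detectionFraction(mr))
    ac <- tryCatch(amplitudeCorrelation(mr), error = function(e) NULL)
    if (!is.null(ac)) {
      summary$pearson_r <- ac$r
      summary$r_squared <- ac$r_squared
    }
    jsonlite::write_json(summary, file.path(outDir, "match_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    writeResolvedConfig(cfg, outDir)
    invisible(summary)
  })
}

#' Train-response summaries from a run configuration
#'
#' Normalizes the configured recordings and computes [trainSummary()] for the
#' configured train block of each ROI, writing `train_summary.csv`.
#'
#' @param config path to a YAML run configuration or a resolved list; a
#'   protocol with at least one multi-stimulus block is required.
#' @return The summary data.frame, invisibly.
#' @export
cmdEvoked <- function(config) {
  cfg <- readRunConfig(config)
  proto <- configProtocol(cfg)
  if (is.null(proto)) stop("a protocol is required for evoked analysis", call. = FALSE)
  outDir <- cfg$output$dir
  withCleanOutputs(outDir, {
    recs <- loadRecordings(cfg)
    block <- cfg$protocol$train_block
    rows <- lapply(names(recs), function(nm) {
      tr <- normalizeRecording(recs[[nm]], cfg)
      ts <- trainSummary(tr, proto, block = block)
      data.frame(roi = nm, first_amplitude = ts$first_amplitude,
                 final_amplitude = ts$final_amplitude,
                 facilitation_index = ts$facilitation_index,
                 post_train_tau = ts$post_train_tau,
                 n_stimuli = ts$n_stimuli)
    })
    out <- do.call(rbind, rows)
    writeTableCsv(out, file.path(outDir, "train_summary.csv"))
    writeResolvedConfig(cfg, outDir)
    invisible(out)
  })
}

#' Active-zone statistics from a run configuration
#'
#' Reads an AZ-by-stimulus response matrix CSV (first column AZ id, remaining
#' columns per-stimulus responses), runs the pairwise paired t-tests and IQR
#' flagging, and writes `az_stats.json` plus the p-value matrix
#' `az_pvalues.csv`.
#'
#' @param config path to a YAML run configuration or a resolved list with
#'   `az$matrix` naming the input CSV (and optional `az$alpha`).
#' @return The statistics list, invisibly.
#' @export
cmdAzStats <- function(config) {
  cfg <- readRunConfig(config)
  if (is.null(cfg$az$matrix)) stop("az$matrix is required", call. = FALSE)
  alpha <- if (is.null(cfg$az$alpha)) 0.05 else cfg$az$alpha
  outDir <- cfg$output$dir
  withCleanOutputs(outDir, {
    df <- read.csv(cfg$az$matrix, stringsAsFactors = FALSE)
    azm <- azMatrix(as.matrix(df[, -1L, drop = FALSE]), azIds = df[[1L]])
    pw <- azPairwiseTests(azm, alpha = alpha)
    fl <- iqrFlags(azm)
    stats <- list(n_az = length(azIds(azm)),
                  n_stimuli = ncol(azAmplitudes(azm)),
                  alpha = alpha,
                  fraction_significant = pw$fraction_significant,
                  n_pairs = pw$n_pairs, n_excluded = pw$n_excluded,
                  q1 = fl$q1, q3 = fl$q3, flagged = fl$flagged)
    jsonlite::write_json(stats, file.path(outDir, "az_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    pdf <- data.frame(az = rownames(pw$p_matrix), pw$p_matrix,
                      check.names = FALSE)
    writeTableCsv(pdf, file.path(outDir, "az_pvalues.csv"))
    writeResolvedConfig(cfg, outDir)
    invisible(stats)
  })
}

#' Generate a synthetic recording from a run configuration
#'
#' Builds a [simSpec()] from the configuration's `simulate` section (any
#' field of [simSpec()], with the run seed), simulates a quantal or evoked
#' recording, and writes the signal/reference tables and the ground-truth
#' JSON sidecar to the output directory.
#'
#' @param config path to a YAML run configuration or a resolved list.
#' @return Named vector of written paths, invisibly.
#' @export
cmdSimulate <- function(config) {
  cfg <- readRunConfig(config)
  outDir <- cfg$output$dir
  withCleanOutputs(outDir, {
    sc <- cfg$simulate
    sc$seed <- cfg$seed
    kind <- sc$kind
    if (is.null(kind)) kind <- "quantal"
    sc$kind <- NULL
    gains <- sc$gains; sc$gains <- NULL
    spec <- do.call(simSpec, sc)
    sim <- if (kind == "evoked") {
      proto <- configProtocol(cfg)
      if (is.null(proto)) stop("evoked simulation needs a protocol", call. = FALSE)
      if (is.null(gains)) gains <- rep(1, nStimuli(proto))
      simulateEvokedRecording(spec, proto, gains)
    } else {
      simulateQuantalRecording(spec)
    }
    paths <- writeSimulation(sim, file.path(outDir, "sim"))
    writeResolvedConfig(cfg, outDir)
    invisible(paths)
  })
}
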