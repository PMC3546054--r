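FMT <- "%.17g"   # full double precision: text round trips are bit-exact

#' Write localization trajectories as a tab-separated table
#'
#' Native on-disk format: UTF-8 TSV with a commented metadata header
#' (`# key: value` lines carrying the condition label, light intensity and
#' frame interval), then one row per cell — `cell_id` followed by the
#' localization value of every frame, columns named `t<seconds>`. Values
#' are written at full double precision so a write/read cycle is
#' bit-exact.
#'
#' @param x a [LocTrajectorySet-class].
#' @param path output file.
#' @param label condition label stored in the header.
#' @param lightIntensity light intensity in microwatt (metadata only).
#' @return `path`, invisibly.
#' @seealso [readTrajectories()]
#' @export
writeTrajectories <- function(x, path, label = "condition",
                              lightIntensity = NA) {
    stopifnot(is(x, "LocTrajectorySet"))
    tm <- frameTimes(x)
    dt <- if (length(tm) > 1) stats::median(diff(tm)) else NA_real_
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(c(sprintf("# label: %s", label),
                 sprintf("# light_intensity_uW: %s", lightIntensity),
                 sprintf("# frame_interval_s: %s", sprintf(FMT, dt))), con)
    loc <- locValues(x)
    writeLines(paste(c("cell_id", sprintf("t%s", sprintf(FMT, tm))),
                     collapse = "\t"), con)
    for (i in seq_len(nrow(loc)))
        writeLines(paste(c(rownames(loc)[i], sprintf(FMT, loc[i, ])),
                         collapse = "\t"), con)
    invisible(path)
}

#' Read localization trajectories from a table
#'
#' Accepts the native commented-header TSV, other delimited-text dialects
#' (comma or semicolon), and spreadsheets (`.xlsx`/`.xls`, first sheet,
#' via readxl). Orientation is auto-detected from the header: either one
#' row per cell (first column `cell_id`, frame columns `t<seconds>`) or
#' one column per cell (first column `time`/`time_s`/`t` holding seconds).
#' The import is lossless for the native format.
#'
#' @param path input file.
#' @return a [LocTrajectorySet-class]; header metadata (label, light
#'   intensity, frame interval) is kept in `metadata(x)$header`.
#' @export
readTrajectories <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (grepl("\\.(xlsx|xls)$", path, ignore.case = TRUE)) {
        if (!requireNamespace("readxl", quietly = TRUE))
            stop("reading spreadsheets requires the readxl package")
        df <- readxl::read_excel(path, col_names = FALSE,
                                 col_types = "text", .name_repair = "minimal")
        cells <- lapply(seq_len(nrow(df)), function(i) as.character(unlist(df[i, ])))
        meta <- character(0)
    } else {
        lines <- readLines(path, encoding = "UTF-8")
        meta <- grep("^#", lines, value = TRUE)
        lines <- lines[!grepl("^#", lines) & nzchar(lines)]
        if (!length(lines)) stop("no data rows in ", path)
        delim <- if (grepl("\t", lines[1])) "\t"
                 else if (grepl(";", lines[1])) ";" else ","
        cells <- strsplit(lines, delim, fixed = TRUE)
    }
    header <- parseHeaderMeta(meta)
    widths <- lengths(cells)
    if (length(unique(widths)) != 1L)
        stop(sprintf("non-rectangular table: row %d has %d fields, expected %d",
                     which(widths != widths[1])[1], widths[widths != widths[1]][1],
                     widths[1]))
    head1 <- cells[[1]]
    body <- cells[-1]
    if (head1[1] == "cell_id") {
        ids <- vapply(body, `[`, character(1), 1)
        loc <- parseNumericBlock(body, drop = 1L)
        times <- suppressWarnings(as.numeric(sub("^t", "", head1[-1])))
        if (anyNA(times))
            times <- (seq_len(ncol(loc)) - 1) *
                (if (is.na(header$frame_interval_s)) 4 else header$frame_interval_s)
    } else if (head1[1] %in% c("time", "time_s", "t")) {
        ids <- head1[-1]
        block <- parseNumericBlock(body, drop = 0L)
        times <- block[, 1]
        loc <- t(block[, -1, drop = FALSE])
    } else {
        stop("cannot detect orientation: first header field must be ",
             "'cell_id' (row per cell) or 'time' (column per cell), got '",
             head1[1], "'")
    }
    x <- LocTrajectorySet(loc, times = times, cellIds = ids)
    metadata(x)$header <- header
    x
}

parseHeaderMeta <- function(meta) {
    get <- function(key) {
        m <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
        if (!length(m)) return(NA_character_)
        trimws(sub("^[^:]*:", "", m[1]))
    }
    list(label = get("label"),
         light_intensity_uW = suppressWarnings(as.numeric(get("light_intensity_uW"))),
         frame_interval_s = suppressWarnings(as.numeric(get("frame_interval_s"))))
}

parseNumericBlock <- function(rows, drop) {
    t(vapply(seq_along(rows), function(i) {
        fields <- rows[[i]]
        if (drop > 0L) fields <- fields[-seq_len(drop)]
        v <- suppressWarnings(as.numeric(fields))
        if (anyNA(v)) {
            j <- which(is.na(v))[1]
            stop(sprintf("non-numeric value '%s' at data row %d, column %d",
                         fields[j], i, j + drop), call. = FALSE)
        }
        v
    }, numeric(length(rows[[1]]) - drop)))
}

#' Write / read a multi-frame image stack as TIFF
#'
#' Frames are stored as a multi-page 32-bit grayscale TIFF. TIFF samples
#' live in \[0, 1\], so intensities are scaled by a stored factor; the
#' factor and the frame timestamps go to a JSON sidecar (`<path>.json`).
#'
#' @param stack an [ImageStack-class].
#' @param path output `.tif` path.
#' @return `path`, invisibly (`writeImageStack`); an
#'   [ImageStack-class] (`readImageStack`).
#' @export
writeImageStack <- function(stack, path) {
    stopifnot(is(stack, "ImageStack"))
    scale <- max(stack@data, 1)
    frames <- lapply(seq_len(length(stack)),
                     function(f) stack@data[, , f] / scale)
    tiff::writeTIFF(frames, path, bits.per.sample = 32L)
    jsonlite::write_json(list(times = stack@times, intensity_scale = scale),
                         paste0(path, ".json"), digits = NA, auto_unbox = FALSE)
    invisible(path)
}

#' @rdname writeImageStack
#' @export
readImageStack <- function(path) {
    frames <- tiff::readTIFF(path, all = TRUE)
    side <- paste0(path, ".json")
    if (file.exists(side)) {
        meta <- jsonlite::read_json(side, simplifyVector = TRUE)
        scale <- meta$intensity_scale
        times <- meta$times
    } else {
        scale <- 1
        times <- seq_along(frames) - 1
    }
    data <- array(0, dim = c(dim(frames[[1]]), length(frames)))
    for (f in seq_along(frames)) data[, , f] <- frames[[f]] * scale
    ImageStack(data, times)
}

#' Write / read a labelled cell mask as TIFF
#'
#' Integer labels (0 = background, k = cell k) stored as 16-bit grayscale.
#'
#' @param mask integer label matrix.
#' @param path `.tif` path.
#' @return `path` invisibly, or the integer label matrix.
#' @export
writeCellMask <- function(mask, path) {
    if (max(mask) > 65535L) stop("mask: more than 65535 labels")
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L,
                    compression = "none")
    invisible(path)
}

#' @rdname writeCellMask
#' @export
readCellMask <- function(path) {
    m <- tiff::readTIFF(path)
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

configDefaults <- function() {
    list(
        label = "condition",
        seed = 1L,
        scenario = list(
            n_cells = 100L, frame_interval = 4, duration = 3600,
            weight_no_response = 0.2, weight_only_oscillating = 0.5,
            weight_permanent = 0.3,
            lag_median = 1200, lag_sdlog = 0.5,
            burst_rate = 0.2, burst_duration_min = 120, burst_duration_max = 180,
            baseline_loc = 0, nuclear_loc = 0.8, noise_sd = 0.05),
        extraction = list(sigma = 2, radius = 3, cytosol_pixels = 90L,
                          measure_on = "original"),
        analysis = list(window = 5L, threshold = 0.28, min_run = 5L,
                        observation_window = 3600, permanence_tail = 600))
}

#' Build a validated pipeline configuration
#'
#' Merges user settings over the standard defaults (threshold 0.28,
#' 5-frame window and minimum run, 3-pixel nucleus radius, 90 cytosolic
#' pixels, 4 s frame interval, 60 min observation window). Unknown keys at
#' any level are rejected.
#'
#' @param ... top-level settings (`label`, `seed`) or the nested lists
#'   `scenario`, `extraction`, `analysis` with partial overrides.
#' @return a list of class `PipelineConfig`.
#' @examples
#' cfg <- pipelineConfig(seed = 9, analysis = list(threshold = 0.3))
#' cfg$analysis$threshold
#' @export
pipelineConfig <- function(...) {
    user <- list(...)
    cfg <- configDefaults()
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    for (nm in names(user)) {
        if (is.list(cfg[[nm]])) {
            sub <- user[[nm]]
            badSub <- setdiff(names(sub), names(cfg[[nm]]))
            if (length(badSub))
                stop(sprintf("unknown key(s) in '%s': %s", nm,
                             paste(badSub, collapse = ", ")))
            cfg[[nm]][names(sub)] <- sub
        } else {
            cfg[[nm]] <- user[[nm]]
        }
    }
    # eager validation of the derived parameter objects
    invisible(scenarioFromConfig(cfg))
    invisible(paramsFromConfig(cfg))
    structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the keys of
#'   [pipelineConfig()].
#' @return a validated `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    do.call(pipelineConfig, yaml::read_yaml(path))
}

scenarioFromConfig <- function(cfg) {
    s <- cfg$scenario
    SimScenario(nCells = s$n_cells, frameInterval = s$frame_interval,
                duration = s$duration,
                archetypeWeights = c(no_response = s$weight_no_response,
                                     only_oscillating = s$weight_only_oscillating,
                                     permanent = s$weight_permanent),
                lagMedian = s$lag_median, lagSdlog = s$lag_sdlog,
                burstRate = s$burst_rate,
                burstDurationRange = c(s$burst_duration_min, s$burst_duration_max),
                baselineLoc = s$baseline_loc, nuclearLoc = s$nuclear_loc,
                noiseSd = s$noise_sd, seed = cfg$seed)
}

paramsFromConfig <- function(cfg) {
    a <- cfg$analysis
    AnalysisParams(window = a$window, threshold = a$threshold,
                   minRun = a$min_run,
                   observationWindow = a$observation_window,
                   permanenceTail = a$permanence_tail)
}

#' Run the full analysis pipeline
#'
#' Single entry point composing the stages: obtain localization
#' trajectories (simulated from the configured scenario, read from a
#' trajectory table, or extracted from an image stack plus cell mask),
#' detect nuclear states, compute per-cell metrics and the population
#' summary, and write all artifacts plus a machine-readable run log to
#' `outDir`. Identical configuration and inputs produce byte-identical
#' outputs; the run log alone suffices to replay the run (see
#' [replayRun()]).
#'
#' @param config a `PipelineConfig` (see [pipelineConfig()]).
#' @param input `NULL` to simulate from the configured scenario, a path to
#'   a trajectory table, a [LocTrajectorySet-class], or a list with
#'   elements `stack` and `mask` ([ImageStack-class]/matrix or `.tif`
#'   paths).
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with `trajectories`
#'   ([LocTrajectorySet-class], states attached), `metrics`, `summary`
#'   ([PopulationSummary-class]) and the written file paths.
#' @export
runPipeline <- function(config, input = NULL, outDir) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    inputDesc <- "simulated"
    trajs <- tryCatch({
        if (is.null(input)) {
            simulatePopulation(scenarioFromConfig(config))
        } else if (is(input, "LocTrajectorySet")) {
            inputDesc <- "in-memory trajectories"
            input
        } else if (is.character(input)) {
            inputDesc <- input
            readTrajectories(input)
        } else if (is.list(input)) {
            stack <- input$stack
            mask <- input$mask
            if (is.character(stack)) stack <- readImageStack(stack)
            if (is.character(mask)) mask <- readCellMask(mask)
            inputDesc <- "image stack + mask"
            e <- config$extraction
            extractTrajectories(stack, mask, sigma = e$sigma, radius = e$radius,
                                k = e$cytosol_pixels, measureOn = e$measure_on)
        } else stop("unsupported input type")
    }, error = function(e) stop("stage 'input': ", conditionMessage(e), call. = FALSE))

    params <- paramsFromConfig(config)
    trajs <- tryCatch(detectStates(trajs, params),
                      error = function(e) stop("stage 'detect': ",
                                               conditionMessage(e), call. = FALSE))
    metrics <- tryCatch(cellMetrics(trajs, params),
                        error = function(e) stop("stage 'metrics': ",
                                                 conditionMessage(e), call. = FALSE))
    summary <- summarizeCondition(metrics, trajs, label = config$label)

    paths <- list(
        trajectories = file.path(outDir, "trajectories.tsv"),
        states = file.path(outDir, "states.tsv"),
        metrics = file.path(outDir, "metrics.tsv"),
        fraction = file.path(outDir, "fraction_localized.tsv"),
        summary = file.path(outDir, "summary.tsv"),
        runlog = file.path(outDir, "runlog.json"))
    writeTrajectories(trajs, paths$trajectories, label = config$label)
    writeBinaryTable(stateMatrix(trajs), frameTimes(trajs), paths$states)
    writeTsv(metrics, paths$metrics)
    writeTsv(summary@fractionLocalized, paths$fraction)
    writeSummaryTable(summary, paths$summary)
    log <- list(package = "shuttleQuant",
                version = as.character(utils::packageVersion("shuttleQuant")),
                config = unclass(config), input = inputDesc,
                n_short_cytosol = metadata(trajs)$shortCytosolCells)
    jsonlite::write_json(log, paths$runlog, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(list(trajectories = trajs, metrics = metrics, summary = summary,
                   paths = paths))
}

writeTsv <- function(df, path) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) sprintf(FMT, v))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

writeBinaryTable <- function(state, times, path) {
    df <- data.frame(cell_id = rownames(state), state, check.names = FALSE)
    names(df)[-1] <- sprintf("t%s", sprintf(FMT, times))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    invisible(path)
}

writeSummaryTable <- function(s, path) {
    rows <- rbind(
        c("label", s@label),
        c("n_cells", s@nCells),
        c("n_no_response", s@classCounts[["no_response"]]),
        c("n_only_oscillating", s@classCounts[["only_oscillating"]]),
        c("n_permanent", s@classCounts[["permanent"]]),
        c("n_censored", s@nCensored),
        c("median_total_nuclear_time_min",
          sprintf(FMT, s@medianTotalNuclearTime / 60)),
        c("median_first_localization_min",
          if (is.na(s@medianFirstLocalization)) "censored"
          else sprintf(FMT, s@medianFirstLocalization / 60)))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = c("key", "value"),
                       fileEncoding = "UTF-8")
    invisible(path)
}

#' Replay a pipeline run from its run log
#'
#' Re-executes [runPipeline()] from the configuration stored in a
#' `runlog.json`. For simulated runs this reproduces every artifact
#' byte-identically; for file inputs the original input path is re-read.
#'
#' @param runlogPath path to a `runlog.json` written by [runPipeline()].
#' @param outDir output directory for the replayed artifacts.
#' @return see [runPipeline()].
#' @export
replayRun <- function(runlogPath, outDir) {
    log <- jsonlite::read_json(runlogPath, simplifyVector = TRUE)
    config <- do.call(pipelineConfig, log$config)
    input <- if (identical(log$input, "simulated")) NULL else log$input
    runPipeline(config, input, outDir)
}
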