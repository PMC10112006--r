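## File formats, configuration, validation and the end-to-end driver.
## Signals travel in a native dialect: raw little-endian float32 samples
## (channel-major) plus a JSON sidecar; tables are TSV; adjacency is a
## square 0/1 CSV; configuration round-trips through YAML.

#' Write / read a recording in the native signal dialect
#'
#' `<prefix>.f32` holds the voltages as little-endian float32, one channel
#' after another; `<prefix>.json` is the sidecar with `patient_id`,
#' `sample_rate`, `n_channels`, `n_samples`, `channel_ids` and `reference`.
#'
#' @param recording An `hg_recording`.
#' @param prefix Path prefix (without extension).
#' @return `write_recording()` the prefix, invisibly; `read_recording()` an
#'   `hg_recording`.
#' @export
write_recording <- function(recording, prefix) {
  stopifnot(inherits(recording, "hg_recording"))
  v <- recording$voltages
  con <- file(paste0(prefix, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(v)), con, size = 4, endian = "little")
  sidecar <- list(patient_id = recording$patient_id,
                  sample_rate = recording$sample_rate,
                  n_channels = nrow(v), n_samples = ncol(v),
                  channel_ids = recording$channel_ids,
                  reference = recording$reference,
                  dtype = "float32", order = "channel_major")
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  sc <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".f32"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = sc$n_channels * sc$n_samples,
               size = 4, endian = "little")
  v <- matrix(x, nrow = sc$n_channels, byrow = TRUE,
              dimnames = list(sc$channel_ids, NULL))
  structure(list(patient_id = sc$patient_id, sample_rate = sc$sample_rate,
                 voltages = v, channel_ids = sc$channel_ids,
                 reference = sc$reference),
            class = "hg_recording")
}

#' Tabular readers and writers
#'
#' Trial events and electrode tables are tab-separated with a header;
#' the streamline adjacency is a square 0/1 CSV whose first column and
#' header carry the ROI labels.
#'
#' @param x Data frame (or adjacency matrix) to write.
#' @param path File path.
#' @return Readers return the parsed object; writers the path, invisibly.
#' @name hg_io_tables
NULL

#' @rdname hg_io_tables
#' @export
write_events <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname hg_io_tables
#' @export
read_events <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  ev$correct <- as.logical(ev$correct)
  ev
}

#' @rdname hg_io_tables
#' @export
write_electrodes <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname hg_io_tables
#' @export
read_electrodes <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' @rdname hg_io_tables
#' @export
write_adjacency <- function(x, path) {
  validate_adjacency(x)
  df <- data.frame(roi = rownames(x), x * 1L, check.names = FALSE)
  write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname hg_io_tables
#' @export
read_adjacency <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) != 0
  dimnames(m) <- list(df$roi, colnames(df)[-1])
  m
}

#' Write percent-change timelines in long format
#'
#' One row per electrode, task, alignment and bin:
#' `electrode, task, alignment, bin_ms, pct_change, n_trials`. Bin times
#' are bin centers in ms relative to the alignment event.
#'
#' @param timelines An `hg_timelines` object.
#' @param path Output TSV path.
#' @export
write_timelines <- function(timelines, path) {
  rows <- list()
  for (task in names(timelines$tasks)) {
    tt <- timelines$tasks[[task]]
    for (al in names(tt$alignments)) {
      a <- tt$alignments[[al]]
      rows[[length(rows) + 1L]] <- data.frame(
        electrode = rep(rownames(a$pct), times = ncol(a$pct)),
        task = task, alignment = al,
        bin_ms = rep(a$bin_ms, each = nrow(a$pct)),
        pct_change = as.vector(a$pct),
        n_trials = tt$n_trials)
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a simulation to disk as pipeline inputs
#'
#' Materializes a [simulate_recording()] result in the on-disk formats the
#' pipeline reads: per-patient signal dialect + events TSV, electrode TSV,
#' adjacency CSV (when configured) and the ground-truth burst schedule TSV.
#'
#' @param sim An `hg_simulation`.
#' @param dir Output directory (created if needed).
#' @return List of written paths (usable in [pipeline_config()]).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "hg_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  signals <- events <- character(0)
  for (p in seq_along(sim$patients)) {
    prefix <- file.path(dir, sprintf("patient%02d", p))
    write_recording(sim$patients[[p]]$recording, prefix)
    evp <- paste0(prefix, "_events.tsv")
    write_events(sim$patients[[p]]$events, evp)
    signals <- c(signals, prefix)
    events <- c(events, evp)
  }
  epath <- file.path(dir, "electrodes.tsv")
  write_electrodes(sim$electrodes, epath)
  apath <- NULL
  if (!is.null(sim$ground_truth$adjacency)) {
    apath <- file.path(dir, "adjacency.csv")
    write_adjacency(sim$ground_truth$adjacency, apath)
  }
  if (!is.null(sim$ground_truth$bursts)) {
    write.table(sim$ground_truth$bursts,
                file.path(dir, "ground_truth_bursts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(signals = signals, events = events, electrodes = epath,
       adjacency = apath)
}

#' Pipeline configuration
#'
#' Collects every path and parameter of an end-to-end run. The object
#' round-trips losslessly through YAML ([write_config()] /
#' [read_config()]); every randomized stage derives its seed from `seed`.
#'
#' @param signals Character vector of recording path prefixes (one per
#'   patient).
#' @param events Character vector of per-patient event TSV paths.
#' @param electrodes Electrode table TSV path.
#' @param adjacency Streamline adjacency CSV path.
#' @param out_dir Output directory.
#' @param seed Integer seed; mandatory.
#' @param behavior Optional behavioral table TSV path.
#' @param band `c(low, high)` analysis band in Hz.
#' @param band_step_hz Frequency grid step (default 5).
#' @param step_ms Bin spacing (default 10).
#' @param temporal_fwhm_ms Demodulation filter FWHM (default 31.6).
#' @param baseline_ms Baseline window (default `c(-600, -200)`).
#' @param normalization See [percent_change()].
#' @param n_resamples,ci_level,min_run_ms Bootstrap spec (defaults 2000 /
#'   0.9999 / 50).
#' @param min_electrodes Minimum electrodes per ROI (default 9).
#' @param conn_min_run_ms Minimum co-modulation duration (default 100).
#' @param epoch_ms,conn_step_ms,coverage Dynamic-connectome rendering.
#' @param log_level `"info"` or `"quiet"`.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(signals, events, electrodes, adjacency,
                            out_dir, seed, behavior = NULL,
                            band = c(70, 110), band_step_hz = 5,
                            step_ms = 10, temporal_fwhm_ms = 31.6,
                            baseline_ms = c(-600, -200),
                            normalization = "trial_mean",
                            n_resamples = 2000, ci_level = 0.9999,
                            min_run_ms = 50, min_electrodes = 9,
                            conn_min_run_ms = 100, epoch_ms = 100,
                            conn_step_ms = 10, coverage = "full",
                            log_level = "info") {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(length(signals) == length(events), length(signals) >= 1)
  structure(list(signals = signals, events = events,
                 electrodes = electrodes, adjacency = adjacency,
                 behavior = behavior, out_dir = out_dir,
                 band = band, band_step_hz = band_step_hz,
                 step_ms = step_ms, temporal_fwhm_ms = temporal_fwhm_ms,
                 baseline_ms = baseline_ms, normalization = normalization,
                 n_resamples = n_resamples, ci_level = ci_level,
                 min_run_ms = min_run_ms, min_electrodes = min_electrodes,
                 conn_min_run_ms = conn_min_run_ms, epoch_ms = epoch_ms,
                 conn_step_ms = conn_step_ms, coverage = coverage,
                 log_level = log_level, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$behavior <- raw$behavior %||% NULL
  do.call(pipeline_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate pipeline inputs
#'
#' Checks existence and schema of every input file of a
#' [pipeline_config()]: sidecar sample rate (1000 Hz), event-table columns
#' and ordering constraints, electrode-table columns and ROI labels,
#' adjacency squareness/symmetry/zero diagonal, and ROI cross-references
#' between the electrode table and the adjacency. All failures are
#' collected, not just the first.
#'
#' @param config A `pipeline_config`.
#' @return List with `ok` (logical) and `problems` (character vector).
#' @export
validate_inputs <- function(config) {
  problems <- character(0)
  note <- function(...) problems <<- c(problems, paste0(...))
  for (p in c(paste0(config$signals, ".json"),
              paste0(config$signals, ".f32"),
              config$events, config$electrodes, config$adjacency,
              config$behavior)) {
    if (!is.null(p) && !file.exists(p)) note("missing file: ", p)
  }
  if (length(problems)) return(list(ok = FALSE, problems = problems))

  for (s in config$signals) {
    sc <- jsonlite::read_json(paste0(s, ".json"), simplifyVector = TRUE)
    if (!identical(as.numeric(sc$sample_rate), 1000)) {
      note(s, ": sample rate is ", sc$sample_rate, " Hz, expected 1000")
    }
  }
  need_ev <- c("trial_id", "task", "stim_onset_sample",
               "stim_offset_sample", "response_onset_sample", "correct")
  for (e in config$events) {
    ev <- read_events(e)
    miss <- setdiff(need_ev, names(ev))
    if (length(miss)) {
      note(e, ": missing column(s) ", paste(miss, collapse = ", "))
      next
    }
    if (any(ev$stim_onset_sample >= ev$stim_offset_sample)) {
      note(e, ": stim_onset_sample not before stim_offset_sample in trial(s) ",
           paste(ev$trial_id[ev$stim_onset_sample >= ev$stim_offset_sample],
                 collapse = ", "))
    }
    if (any(ev$response_onset_sample <= ev$stim_onset_sample)) {
      note(e, ": response before stimulus onset in trial(s) ",
           paste(ev$trial_id[ev$response_onset_sample <=
                               ev$stim_onset_sample], collapse = ", "))
    }
  }
  el <- read_electrodes(config$electrodes)
  miss <- setdiff(c("electrode_id", "roi"), names(el))
  if (length(miss)) {
    note(config$electrodes, ": missing column(s) ",
         paste(miss, collapse = ", "))
  } else {
    bad <- setdiff(unique(el$roi), roi_catalog())
    if (length(bad)) {
      note(config$electrodes, ": unknown ROI label(s) ",
           paste(bad, collapse = ", "))
    }
  }
  adj <- tryCatch(read_adjacency(config$adjacency), error = function(e) e)
  if (inherits(adj, "error")) {
    note(config$adjacency, ": unreadable (", conditionMessage(adj), ")")
  } else {
    v <- tryCatch(validate_adjacency(adj), error = function(e) e)
    if (inherits(v, "error")) {
      note(config$adjacency, ": ", conditionMessage(v))
    } else if ("roi" %in% names(el)) {
      orphan <- setdiff(unique(el$roi), rownames(adj))
      if (length(orphan)) {
        note("electrode ROI(s) absent from adjacency: ",
             paste(orphan, collapse = ", "))
      }
    }
  }
  list(ok = !length(problems), problems = problems)
}

#' Run the analysis pipeline
#'
#' Drives the chain signal -> high-gamma timelines -> ROI bootstrap
#' statistics -> adjacency-gated connectivity events -> dynamic connectome
#' and summaries, writing every stage output plus a run manifest into
#' `config$out_dir`. Reruns with an identical configuration and seed are
#' bit-identical. If a stage fails, the outputs of completed stages are
#' retained and the manifest records the failed stage before the error is
#' re-raised.
#'
#' @param config A validated [pipeline_config()].
#' @param through Last stage to run: `"extract"` (timelines), `"roistats"`
#'   (bootstrap statistics), `"connect"` (connectivity events and
#'   connectomes) or `"report"` (everything, the default).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, through = "report") {
  stages <- c("extract", "roistats", "connect", "report")
  through <- match.arg(through, stages)
  val <- validate_inputs(config)
  if (!val$ok) {
    stop("invalid inputs:\n  ", paste(val$problems, collapse = "\n  "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "pipeline.log")
  log <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    if (identical(config$log_level, "info")) message(line)
  }

  pooled <- rstats <- candidates <- events <- NULL
  connectomes <- summary <- NULL
  trial_counts <- list()
  stage <- NULL

  run_stages <- function() {
    stage <<- "extract"
    spec <- demod_spec(freqs = seq(config$band[1], config$band[2],
                                   by = config$band_step_hz),
                       step_ms = config$step_ms,
                       temporal_fwhm_ms = config$temporal_fwhm_ms)
    log("extracting high-gamma timelines for ", length(config$signals),
        " patient(s)")
    tls <- vector("list", length(config$signals))
    for (i in seq_along(config$signals)) {
      rec <- read_recording(config$signals[i])
      ev <- read_events(config$events[i])
      tl <- hg_extract(rec, ev, spec, baseline_ms = config$baseline_ms,
                       normalization = config$normalization)
      for (task in names(tl$tasks)) {
        tt <- tl$tasks[[task]]
        trial_counts[[length(trial_counts) + 1L]] <<- data.frame(
          patient = rec$patient_id, task = task,
          trials_in = sum(ev$task == task),
          retained = tt$n_trials,
          excluded_incorrect = unname(tt$excluded["incorrect"]),
          excluded_baseline = unname(tt$excluded["baseline"]),
          excluded_edge = unname(tt$excluded["edge"]))
      }
      tls[[i]] <- tl
    }
    pooled <<- pool_timelines(tls)
    write_timelines(pooled, file.path(config$out_dir, "timelines.tsv"))
    if (through == "extract") return(invisible())

    stage <<- "roistats"
    electrodes <- read_electrodes(config$electrodes)
    bspec <- boot_spec(config$n_resamples, config$ci_level,
                       config$min_run_ms, seed = config$seed)
    log("bootstrap statistics (B = ", bspec$n_resamples, ", CI ",
        100 * bspec$ci_level, "%)")
    rstats <<- roi_stats(pooled, electrodes, bspec,
                         min_n = config$min_electrodes)
    write.table(rstats$table, file.path(config$out_dir, "roi_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (through == "roistats") return(invisible())

    stage <<- "connect"
    adjacency <- read_adjacency(config$adjacency)
    candidates <<- detect_co_events(rstats,
                                    min_run_ms = config$conn_min_run_ms)
    events <<- gate_by_adjacency(candidates, adjacency)
    log(nrow(candidates), " co-modulation candidate(s), ", nrow(events),
        " streamline-gated event(s)")
    write.table(candidates, file.path(config$out_dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(events, file.path(config$out_dir, "events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    connectomes <<- list()
    for (al in c("stimulus_onset", "response_onset")) {
      sub <- events[events$alignment == al, , drop = FALSE]
      cn <- dynamic_connectome(sub, rstats$bin_ms[[al]],
                               epoch_ms = config$epoch_ms,
                               step_ms = config$conn_step_ms,
                               coverage = config$coverage)
      write.table(cn$epochs,
                  file.path(config$out_dir,
                            paste0("connectome_", al, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      connectomes[[al]] <<- cn
    }
    if (through == "connect") return(invisible())

    stage <<- "report"
    chi <- compute_chi(rstats)
    chance <- chance_probability(n_roi = length(rstats$masks),
                                 n_bins = sum(lengths(rstats$bin_ms)),
                                 run_len_bins = config$conn_min_run_ms /
                                   config$step_ms,
                                 chi = chi$mean)
    coverage <- streamline_coverage_summary(candidates, adjacency)
    extent <- list()
    for (task in unique(events$task)) {
      for (lat in c("left-intra", "right-intra", "inter")) {
        es <- events[events$task == task, , drop = FALSE]
        stim <- pair_count_series(es[es$alignment == "stimulus_onset", ],
                                  rstats$bin_ms$stimulus_onset, lat)
        resp <- pair_count_series(es[es$alignment == "response_onset", ],
                                  rstats$bin_ms$response_onset, lat)
        ps <- tryCatch(suppressWarnings(
          period_extent_summary(stim, rstats$bin_ms$stimulus_onset,
                                resp, rstats$bin_ms$response_onset)),
          error = function(e) NULL)
        if (!is.null(ps)) {
          ps$counts <- NULL
          extent[[paste(task, lat, sep = "/")]] <- ps
        }
      }
    }
    behavior <- NULL
    if (!is.null(config$behavior)) {
      behavior <- behavior_summary(read.delim(config$behavior))
    }
    summary <<- list(chi = chi, chance_probability = chance,
                     streamline_coverage = coverage,
                     period_extent = extent, behavior = behavior)
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible()
  }

  err <- tryCatch({ run_stages(); NULL }, error = function(e) e)

  cfg_file <- tempfile(fileext = ".yaml")
  write_config(config, cfg_file)
  manifest <- list(
    tool = paste0("hgconn ", as.character(utils::packageVersion("hgconn"))),
    config_hash = unname(tools::md5sum(cfg_file)),
    input_checksums = as.list(tools::md5sum(
      c(paste0(config$signals, ".f32"), config$events, config$electrodes,
        config$adjacency))),
    stages_run = stages[seq_len(match(stage, stages))],
    failed_stage = if (!is.null(err)) stage,
    trials = if (length(trial_counts)) do.call(rbind, trial_counts),
    rois_included = if (!is.null(rstats)) names(rstats$masks),
    rois_excluded = if (!is.null(rstats)) rstats$excluded_rois,
    n_candidates = if (!is.null(candidates)) nrow(candidates),
    n_events = if (!is.null(events)) nrow(events),
    seed = config$seed)
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(err)) {
    log("stage '", stage, "' FAILED: ", conditionMessage(err))
    stop("stage '", stage, "' failed: ", conditionMessage(err))
  }
  log("pipeline complete through '", stage, "'; outputs in ",
      config$out_dir)
  invisible(list(timelines = pooled, roi_stats = rstats,
                 candidates = candidates, events = events,
                 connectomes = connectomes, summary = summary,
                 manifest = manifest))
}
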