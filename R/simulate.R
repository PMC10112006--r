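## Synthetic-data generator: 1000-Hz common-average-referenced recordings
## with 1/f background noise and planted band-limited high-gamma bursts of
## known onset, duration and percent-change magnitude.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Default response-time distributions of the three naming tasks
#'
#' Log-normal parameters (seconds) for per-patient median response times,
#' fitted so that the simulated medians and ranges match the reference
#' behavioral table of the 13-patient naming study bundled with the package
#' (picture naming median 1.34 s, nonspeech environmental sound naming
#' 2.63 s, auditory descriptive naming 3.27 s).
#'
#' @return Named list of `c(meanlog, sdlog)` per task.
#' @export
hg_rt_defaults <- function() {
  list(picture  = c(meanlog = log(1.34), sdlog = 0.195),
       sound    = c(meanlog = log(2.63), sdlog = 0.143),
       question = c(meanlog = log(3.27), sdlog = 0.112))
}

#' Simulation configuration
#'
#' Bundles and validates every parameter of the recording generator. The
#' defaults mirror the acquisition and task design the pipeline targets:
#' 1000-Hz sampling, 13 patients, 60/60/100 trials for the picture / sound /
#' question naming tasks, 1.8-s stimuli, inter-trial onset 2-2.5 s after the
#' response, 1/f background noise.
#'
#' @param rois Character vector of ROI labels (subset of [roi_catalog()]).
#' @param electrodes_per_roi Electrodes implanted per ROI (per patient).
#' @param seed Integer seed; mandatory.
#' @param n_patients Number of simulated patients.
#' @param n_trials_per_task Trials per task: scalar or named vector.
#' @param tasks Task labels.
#' @param sample_rate Sampling rate in Hz; fixed at 1000.
#' @param noise_alpha Exponent of the 1/f^alpha background noise.
#' @param noise_sigma Background noise standard deviation in microvolts.
#' @param line_noise_hz Optional mains frequency to add as a sinusoid.
#' @param line_noise_amp Peak amplitude of the mains component (microvolts).
#' @param burst_schedule Data frame of planted bursts with columns `roi`,
#'   `alignment` (one of `"stimulus_onset"`, `"stimulus_offset"`,
#'   `"response_onset"`), `onset_ms` (relative to the alignment event),
#'   `duration_ms`, `amplitude_pct` (target high-gamma percent change,
#'   > -100) and `task`; or `NULL` for a null recording.
#' @param rt_distributions Named list of log-normal `c(meanlog, sdlog)`
#'   (seconds) per task; default [hg_rt_defaults()].
#' @param p_correct Probability that a trial is answered correctly.
#' @param stim_duration_ms Stimulus duration (default 1800 ms).
#' @param iti_ms Candidate delays from response onset to the next stimulus.
#' @param adjacency Optional streamline adjacency matrix (see
#'   [simulate_adjacency()]); used only to derive the ground-truth expected
#'   connectivity events.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(rois, electrodes_per_roi = 12, seed,
                       n_patients = 13,
                       n_trials_per_task = c(picture = 60, sound = 60,
                                             question = 100),
                       tasks = c("picture", "sound", "question"),
                       sample_rate = 1000, noise_alpha = 1,
                       noise_sigma = 10, line_noise_hz = NULL,
                       line_noise_amp = noise_sigma / 2,
                       burst_schedule = NULL,
                       rt_distributions = hg_rt_defaults(),
                       p_correct = 1, stim_duration_ms = 1800,
                       iti_ms = c(2000, 2500), adjacency = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(length(seed) == 1, is.finite(seed))
  if (sample_rate != 1000) stop("sample_rate is fixed at 1000 Hz")
  stopifnot(electrodes_per_roi >= 1, n_patients >= 1, noise_sigma > 0,
            p_correct >= 0, p_correct <= 1)
  unknown <- setdiff(rois, roi_catalog())
  if (length(unknown)) {
    stop("unknown ROI label(s): ", paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(rois)) stop("duplicated ROI labels")
  if (length(n_trials_per_task) == 1L && is.null(names(n_trials_per_task))) {
    n_trials_per_task <- setNames(rep(n_trials_per_task, length(tasks)),
                                  tasks)
  }
  if (!all(tasks %in% names(n_trials_per_task))) {
    stop("n_trials_per_task must cover every task")
  }
  if (!all(tasks %in% names(rt_distributions))) {
    stop("rt_distributions must cover every task")
  }
  if (!is.null(burst_schedule)) {
    burst_schedule <- as.data.frame(burst_schedule)
    need <- c("roi", "alignment", "onset_ms", "duration_ms",
              "amplitude_pct", "task")
    if (!all(need %in% names(burst_schedule))) {
      stop("burst_schedule needs columns: ", paste(need, collapse = ", "))
    }
    stopifnot(all(burst_schedule$duration_ms > 0),
              all(burst_schedule$amplitude_pct > -100),
              all(burst_schedule$roi %in% rois),
              all(burst_schedule$task %in% tasks),
              all(burst_schedule$alignment %in%
                    c("stimulus_onset", "stimulus_offset", "response_onset")))
  }
  if (!is.null(adjacency)) {
    validate_adjacency(adjacency)
    if (!all(rois %in% rownames(adjacency))) {
      stop("adjacency does not cover all simulated ROIs")
    }
  }
  structure(list(rois = rois, electrodes_per_roi = electrodes_per_roi,
                 n_patients = n_patients,
                 n_trials_per_task = n_trials_per_task, tasks = tasks,
                 sample_rate = sample_rate, noise_alpha = noise_alpha,
                 noise_sigma = noise_sigma, line_noise_hz = line_noise_hz,
                 line_noise_amp = line_noise_amp,
                 burst_schedule = burst_schedule,
                 rt_distributions = rt_distributions,
                 p_correct = p_correct, stim_duration_ms = stim_duration_ms,
                 iti_ms = iti_ms, adjacency = adjacency, seed = seed),
            class = "sim_config")
}

## 1/f^alpha Gaussian noise via spectral shaping; returns the time series
## and the component used for burst injection. The injected band extends
## `margin` Hz beyond the nominal 70-110 Hz analysis band: physiological
## high-gamma is broadband, and the margin (~3 spectral sigma of the
## demodulation filter's power response) guarantees that rescaling this
## component changes the measured 70-110 Hz amplitude by exactly the
## planted factor, without filter-edge attenuation.
## Spectral plan shared by all channels of one recording: smooth FFT
## length, 1/f^(alpha/2) amplitude shaping and the in-band selector.
one_over_f_plan <- function(n, alpha, fs, band = c(70, 110), margin = 25) {
  band <- band + c(-margin, margin)
  ## generate on the next 2-3-5-smooth length and truncate: mixed-radix
  ## FFTs degrade badly on lengths with large prime factors
  m <- stats::nextn(n, c(2, 3, 5))
  f <- c(0, seq_len(m - 1)) * fs / m
  f <- pmin(f, fs - f)                      # two-sided |frequency|
  shape <- c(0, f[-1]^(-alpha / 2))
  list(n = n, m = m, shape = shape, inband = f >= band[1] & f <= band[2])
}

one_over_f_noise <- function(n, alpha, sigma, fs, band = c(70, 110),
                             margin = 25, want_band = TRUE, plan = NULL) {
  if (is.null(plan)) plan <- one_over_f_plan(n, alpha, fs, band, margin)
  m <- plan$m
  coefs <- stats::fft(rnorm(m)) * plan$shape
  x <- Re(stats::fft(coefs, inverse = TRUE))[seq_len(n)] / m
  sc <- sigma / sd(x)
  xb <- NULL
  if (want_band) {
    xb <- Re(stats::fft(coefs * plan$inband,
                        inverse = TRUE))[seq_len(n)] / m * sc
  }
  list(x = x * sc, band = xb)
}

#' Tukey (tapered cosine) window
#'
#' @param n Window length in samples.
#' @param taper Total fraction of the window under the two cosine ramps
#'   (default 0.1, i.e. 5% taper on each edge).
#' @return Numeric vector of length `n` in `[0, 1]`.
#' @export
tukey_window <- function(n, taper = 0.1) {
  stopifnot(n >= 1, taper >= 0, taper <= 1)
  w <- rep(1, n)
  m <- floor(taper * (n - 1) / 2)
  if (m > 0) {
    k <- seq_len(m)
    ramp <- 0.5 * (1 - cos(pi * k / (m + 1)))
    w[k] <- ramp
    w[n + 1 - k] <- ramp
  }
  w
}

#' Simulate multichannel iEEG recordings with planted high-gamma bursts
#'
#' Generates, per patient, a 1000-Hz voltage matrix (`electrodes_per_roi x
#' length(rois)` channels) of 1/f^alpha Gaussian noise, a trial-event table
#' for the configured tasks (1.8-s stimuli, response onsets drawn from the
#' per-task log-normal distributions, next stimulus 2-2.5 s after the
#' response), and the planted burst schedule as ground truth. Each planted
#' burst multiplies the channel's broadband gamma noise component (the
#' 70-110 Hz analysis band widened by the spectral support of the
#' demodulation filter) by `1 + (amplitude_pct/100)` under a Tukey-windowed
#' (10% taper) envelope over the scheduled window, so the measured 70-110 Hz
#' amplitude percent change equals `amplitude_pct` by construction, up to
#' temporal smearing at the burst edges. The
#' common average reference is applied after burst injection, mirroring the
#' recording chain, so a burst leaks -1/n_channels into the other channels.
#'
#' @param config A [sim_config()].
#' @return An object of class `"hg_simulation"`: `patients` (list of
#'   `recording` + `events` per patient), `electrodes` (electrode table),
#'   and `ground_truth` (bursts, adjacency, `expected_events` when an
#'   adjacency is configured, seed).
#' @export
simulate_recording <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    fs <- config$sample_rate
    n_chan <- length(config$rois) * config$electrodes_per_roi
    chan_roi <- rep(config$rois, each = config$electrodes_per_roi)
    pad <- 1000L                       # room for the -900 ms window + filter
    patients <- vector("list", config$n_patients)
    for (p in seq_len(config$n_patients)) {
      ## --- trial layout -------------------------------------------------
      ev <- list()
      next_stim <- pad + 1L
      tid <- 0L
      for (task in config$tasks) {
        rt_par <- config$rt_distributions[[task]]
        for (k in seq_len(config$n_trials_per_task[[task]])) {
          tid <- tid + 1L
          stim_on <- next_stim
          stim_off <- stim_on + as.integer(config$stim_duration_ms)
          rt <- rlnorm(1, rt_par[["meanlog"]], rt_par[["sdlog"]])
          resp <- stim_on + as.integer(round(rt * 1000))
          trial_end <- max(stim_off, resp) + 900L + 100L
          ev[[tid]] <- data.frame(
            trial_id = tid, task = task,
            stim_onset_sample = stim_on, stim_offset_sample = stim_off,
            response_onset_sample = resp,
            correct = as.logical(rbinom(1, 1, config$p_correct)),
            trial_start = stim_on - pad, trial_end = trial_end)
          iti <- sample(config$iti_ms, 1)
          next_stim <- max(resp + as.integer(iti), trial_end + pad + 1L)
        }
      }
      events <- do.call(rbind, ev)
      n_samples <- max(events$trial_end) + pad

      ## --- burst windows (validated against trial bounds) ---------------
      sched <- config$burst_schedule
      windows <- NULL
      if (!is.null(sched) && nrow(sched)) {
        rows <- list()
        for (b in seq_len(nrow(sched))) {
          tr <- events[events$task == sched$task[b], , drop = FALSE]
          anchor <- switch(sched$alignment[b],
                           stimulus_onset = tr$stim_onset_sample,
                           stimulus_offset = tr$stim_offset_sample,
                           response_onset = tr$response_onset_sample)
          s0 <- anchor + as.integer(round(sched$onset_ms[b]))
          s1 <- s0 + as.integer(round(sched$duration_ms[b])) - 1L
          out <- s0 < tr$trial_start | s1 > tr$trial_end
          if (any(out)) {
            stop("burst ", b, " (", sched$roi[b], ", ", sched$alignment[b],
                 ") extends beyond the bounds of trial ",
                 tr$trial_id[which(out)[1]])
          }
          rows[[b]] <- data.frame(burst = b, roi = sched$roi[b],
                                  gain = 1 + sched$amplitude_pct[b] / 100,
                                  s0 = s0, s1 = s1)
        }
        windows <- do.call(rbind, rows)
      }

      ## --- voltages -----------------------------------------------------
      v <- matrix(0, nrow = n_chan, ncol = n_samples)
      plan <- one_over_f_plan(n_samples, config$noise_alpha, fs)
      for (ch in seq_len(n_chan)) {
        has_burst <- !is.null(windows) && chan_roi[ch] %in% windows$roi
        nz <- one_over_f_noise(n_samples, config$noise_alpha,
                               config$noise_sigma, fs,
                               want_band = has_burst, plan = plan)
        x <- nz$x
        if (has_burst) {
          wch <- windows[windows$roi == chan_roi[ch], , drop = FALSE]
          for (i in seq_len(nrow(wch))) {
            sel <- wch$s0[i]:wch$s1[i]
            env <- tukey_window(length(sel), 0.1)
            x[sel] <- x[sel] + (wch$gain[i] - 1) * env * nz$band[sel]
          }
        }
        if (!is.null(config$line_noise_hz)) {
          x <- x + config$line_noise_amp *
            sin(2 * pi * config$line_noise_hz * seq_len(n_samples) / fs)
        }
        v[ch, ] <- x
      }
      v <- sweep(v, 2, colMeans(v))       # common average reference
      ids <- sprintf("P%02d_%s_e%02d", p, chan_roi,
                     rep(seq_len(config$electrodes_per_roi),
                         times = length(config$rois)))
      rownames(v) <- ids
      rec <- structure(list(patient_id = sprintf("P%02d", p),
                            sample_rate = fs, voltages = v,
                            channel_ids = ids, reference = "common_average"),
                       class = "hg_recording")
      events$trial_start <- events$trial_end <- NULL
      patients[[p]] <- list(recording = rec, events = events)
    }
    electrodes <- do.call(rbind, lapply(seq_len(config$n_patients),
      function(p) {
        ids <- patients[[p]]$recording$channel_ids
        roi <- rep(config$rois, each = config$electrodes_per_roi)
        data.frame(electrode_id = ids,
                   patient_id = sprintf("P%02d", p),
                   roi = roi, hemisphere = roi_hemisphere(roi))
      }))
    gt <- list(bursts = config$burst_schedule,
               adjacency = config$adjacency,
               expected_events = if (!is.null(config$adjacency) &&
                                     !is.null(config$burst_schedule))
                 expected_co_events(config$burst_schedule, config$adjacency),
               seed = config$seed)
    structure(list(patients = patients, electrodes = electrodes,
                   ground_truth = gt, config = config),
              class = "hg_simulation")
  })
}

validate_adjacency <- function(adjacency) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency must be a square matrix")
  }
  if (is.null(rownames(adjacency)) ||
      !identical(rownames(adjacency), colnames(adjacency))) {
    stop("adjacency must carry identical ROI row and column names")
  }
  m <- adjacency != 0
  if (!isTRUE(all(m == t(m)))) {
    bad <- which(m != t(m), arr.ind = TRUE)[1, ]
    stop("adjacency is not symmetric (cell ",
         rownames(adjacency)[bad[1]], " x ",
         colnames(adjacency)[bad[2]], ")")
  }
  if (any(diag(m))) stop("adjacency must have a zero diagonal")
  invisible(TRUE)
}

#' Simulate a streamline adjacency matrix
#'
#' Builds the binary symmetric ROI x ROI matrix that stands in for direct
#' white-matter streamline connectivity from diffusion tractography, either
#' from an explicit edge list or by sampling undirected edges at a given
#' density.
#'
#' @param rois Character vector of unique ROI labels.
#' @param edges Two-column matrix/data frame of ROI label pairs, or `NULL`.
#' @param density Fraction of the `n(n-1)/2` undirected pairs to connect
#'   (ignored when `edges` is given); the edge count is `round(density *
#'   n(n-1)/2)`.
#' @param seed Integer seed (required with `density`).
#' @return Logical symmetric matrix with zero diagonal and ROI dimnames.
#' @export
simulate_adjacency <- function(rois, edges = NULL, density = NULL,
                               seed = NULL) {
  stopifnot(!anyDuplicated(rois), length(rois) >= 2)
  n <- length(rois)
  adj <- matrix(FALSE, n, n, dimnames = list(rois, rois))
  if (!is.null(edges)) {
    edges <- rbind(as.matrix(edges))
    if (nrow(edges)) {
      stopifnot(ncol(edges) == 2)
      unknown <- setdiff(unique(as.vector(edges)), rois)
      if (length(unknown)) {
        stop("edge names unknown ROI(s): ", paste(unknown, collapse = ", "))
      }
      if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed")
      adj[edges] <- TRUE
      adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
    }
  } else if (!is.null(density)) {
    stopifnot(density >= 0, density <= 1)
    if (is.null(seed)) stop("a seed is required to sample edges by density")
    npairs <- n * (n - 1) / 2
    k <- round(density * npairs)
    with_seed(seed, {
      pick <- sample.int(npairs, k)
      ut <- which(upper.tri(adj))
      adj[ut[pick]] <- TRUE
    })
    adj <- adj | t(adj)
  }
  adj
}

#' Simulate a behavioral table
#'
#' One row per patient with per-task median response times drawn from
#' log-normal distributions and per-task correct-response rates.
#'
#' @param n_patients Number of patients (>= 3).
#' @param rt_distributions Named list of `c(meanlog, sdlog)` per task;
#'   default [hg_rt_defaults()].
#' @param correct_rates Named per-task correct-rate targets in `[0, 1]`.
#' @param correct_sd Between-patient SD of the correct rate (truncated to
#'   `[0, 1]`).
#' @param seed Integer seed; mandatory.
#' @return Data frame with `patient_id`, `rt_<task>` (s) and
#'   `correct_<task>` columns.
#' @export
simulate_behavior <- function(n_patients = 13,
                              rt_distributions = hg_rt_defaults(),
                              correct_rates = c(picture = 0.95,
                                                sound = 0.82,
                                                question = 0.97),
                              correct_sd = 0.04, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_patients >= 3)
  if (any(correct_rates < 0 | correct_rates > 1)) {
    stop("correct rates must lie in [0, 1]")
  }
  tasks <- names(rt_distributions)
  with_seed(seed, {
    out <- data.frame(patient_id = seq_len(n_patients))
    for (task in tasks) {
      par <- rt_distributions[[task]]
      out[[paste0("rt_", task)]] <-
        rlnorm(n_patients, par[["meanlog"]], par[["sdlog"]])
    }
    for (task in intersect(tasks, names(correct_rates))) {
      out[[paste0("correct_", task)]] <-
        pmin(1, pmax(0, rnorm(n_patients, correct_rates[[task]],
                              correct_sd)))
    }
    out
  })
}

#' Ground-truth connectivity events implied by a burst schedule
#'
#' Computes the set of connectivity events an ideal detector must recover:
#' for every unordered ROI pair joined by a direct streamline, the temporal
#' intersections (>= `min_overlap_ms`) of the two ROIs' planted burst
#' intervals of equal task, alignment and polarity.
#'
#' @param bursts Burst schedule data frame (see [sim_config()]).
#' @param adjacency Streamline adjacency matrix covering the burst ROIs.
#' @param min_overlap_ms Minimum co-activation duration (default 100).
#' @return Data frame with `roi_a`, `roi_b`, `task`, `alignment`,
#'   `onset_ms`, `offset_ms`, `polarity`.
#' @export
expected_co_events <- function(bursts, adjacency, min_overlap_ms = 100) {
  validate_adjacency(adjacency)
  bursts <- as.data.frame(bursts)
  empty <- data.frame(roi_a = character(0), roi_b = character(0),
                      task = character(0), alignment = character(0),
                      onset_ms = numeric(0), offset_ms = numeric(0),
                      polarity = character(0))
  if (!nrow(bursts)) return(empty)
  bursts$polarity <- ifelse(bursts$amplitude_pct >= 0,
                            "co-augment", "co-attenuate")
  out <- list()
  for (key in split(bursts,
                    list(bursts$task, bursts$alignment, bursts$polarity),
                    drop = TRUE)) {
    rois <- sort(unique(key$roi))
    if (length(rois) < 2) next
    iv <- lapply(rois, function(r) {
      b <- key[key$roi == r, , drop = FALSE]
      merge_intervals(b$onset_ms, b$onset_ms + b$duration_ms)
    })
    names(iv) <- rois
    for (i in seq_len(length(rois) - 1)) {
      for (j in (i + 1):length(rois)) {
        if (!adjacency[rois[i], rois[j]]) next
        ov <- intersect_intervals(iv[[i]], iv[[j]])
        keep <- ov$end - ov$start >= min_overlap_ms
        if (any(keep)) {
          out[[length(out) + 1L]] <- data.frame(
            roi_a = rois[i], roi_b = rois[j],
            task = key$task[1], alignment = key$alignment[1],
            onset_ms = ov$start[keep], offset_ms = ov$end[keep],
            polarity = key$polarity[1])
        }
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

merge_intervals <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- oute <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) me <- max(me, end[i])
    else { outs <- c(outs, ms); oute <- c(oute, me)
           ms <- start[i]; me <- end[i] }
  }
  data.frame(start = c(outs, ms), end = c(oute, me))
}

intersect_intervals <- function(a, b) {
  s <- e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a$start[i], b$start)
    hi <- pmin(a$end[i], b$end)
    keep <- hi > lo
    s <- c(s, lo[keep]); e <- c(e, hi[keep])
  }
  data.frame(start = s, end = e)
}
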