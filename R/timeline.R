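#' Alignment windows of the analysis
#'
#' Three analysis windows on the 10-ms bin grid, bin centers in ms relative
#' to the alignment event (both endpoints included):
#' * `stimulus_onset`: -200 ... +900 ms (111 bins),
#' * `stimulus_offset`: -900 ... +900 ms (181 bins),
#' * `response_onset`: -900 ... +900 ms (181 bins).
#'
#' Together a retained trial contributes 111 + 181 + 181 = 473 bins. Windows
#' may overlap in source samples (a response can precede the stimulus offset)
#' and are analyzed independently.
#'
#' @param step_ms Bin spacing in ms (default 10).
#' @return Named list of bin-center vectors (ms).
#' @examples
#' sum(lengths(alignment_windows()))  # 473
#' @export
alignment_windows <- function(step_ms = 10) {
  list(stimulus_onset  = seq(-200, 900, by = step_ms),
       stimulus_offset = seq(-900, 900, by = step_ms),
       response_onset  = seq(-900, 900, by = step_ms))
}

#' Bin-center samples for one trial
#'
#' Maps the three alignment windows and the baseline window of a trial onto
#' 1-based sample indices of the recording.
#'
#' @param stim_onset_sample,stim_offset_sample,response_onset_sample Event
#'   samples of the trial.
#' @param fs Sampling rate in Hz.
#' @param baseline_ms Baseline window in ms relative to stimulus onset
#'   (default `c(-600, -200)`).
#' @param step_ms Bin spacing in ms.
#' @return Named list of integer sample vectors: `baseline` plus the three
#'   alignment windows.
#' @export
trial_bin_centers <- function(stim_onset_sample, stim_offset_sample,
                              response_onset_sample, fs = 1000,
                              baseline_ms = c(-600, -200), step_ms = 10) {
  ms2s <- function(ms) as.integer(round(ms * fs / 1000))
  w <- alignment_windows(step_ms)
  bl <- seq(baseline_ms[1], baseline_ms[2], by = step_ms)
  list(baseline        = stim_onset_sample + ms2s(bl),
       stimulus_onset  = stim_onset_sample + ms2s(w$stimulus_onset),
       stimulus_offset = stim_offset_sample + ms2s(w$stimulus_offset),
       response_onset  = response_onset_sample + ms2s(w$response_onset))
}

#' Percent change of band amplitude against the pre-stimulus baseline
#'
#' Converts per-trial band amplitudes into percent change relative to the
#' baseline amplitude. Two normalizations are available:
#' * `"trial_mean"` (default): amplitudes are first averaged across retained
#'   trials, then `100 * (A(t) - Abase) / Abase` with `Abase` the mean over
#'   the trial-averaged baseline bins. This ratio-of-means estimator has a
#'   negligible small-sample bias.
#' * `"per_trial"`: each trial is normalized against its own baseline mean
#'   and the per-trial percent changes are averaged. Robust to slow drift
#'   but carries a positive ratio bias of roughly the squared coefficient
#'   of variation of the single-trial baseline mean (see the methods
#'   vignette); trials with a zero baseline mean are rejected with a
#'   diagnostic.
#'
#' @param band Trials x bins matrix of band amplitudes (NA allowed for bins
#'   without full filter support).
#' @param baseline Trials x baseline-bins matrix of band amplitudes.
#' @param normalization `"trial_mean"` or `"per_trial"`.
#' @return List with `pct` (per-bin trial-averaged percent change), `n_trials`
#'   (trials used) and `dropped` (trial rows rejected for a zero baseline).
#' @export
percent_change <- function(band, baseline,
                           normalization = c("trial_mean", "per_trial")) {
  normalization <- match.arg(normalization)
  band <- rbind(band)
  baseline <- rbind(baseline)
  stopifnot(nrow(band) == nrow(baseline), nrow(band) >= 1)
  if (normalization == "trial_mean") {
    abase <- mean(baseline, na.rm = TRUE)
    if (!is.finite(abase) || abase == 0) {
      stop("baseline mean amplitude is zero; percent change undefined")
    }
    at <- colMeans(band, na.rm = TRUE)
    list(pct = 100 * (at - abase) / abase, n_trials = nrow(band),
         dropped = integer(0))
  } else {
    base_t <- rowMeans(baseline, na.rm = TRUE)
    bad <- !is.finite(base_t) | base_t == 0
    if (all(bad)) stop("all trials have a zero baseline mean amplitude")
    if (any(bad)) {
      message(sum(bad), " trial(s) rejected: zero baseline mean amplitude")
    }
    pct_t <- 100 * (band[!bad, , drop = FALSE] / base_t[!bad] - 1)
    list(pct = colMeans(pct_t, na.rm = TRUE), n_trials = sum(!bad),
         dropped = which(bad))
  }
}

#' Trial exclusion: incorrect answers and non-quiescent baselines
#'
#' Removes trials answered incorrectly and trials whose baseline is not
#' quiescent. The quiescence criterion (configurable) rejects a trial if the
#' maximum over baseline bins of its channel-averaged band amplitude exceeds
#' the across-trial median of that statistic by `k` robust standard
#' deviations (1.4826 x MAD), the threshold being estimated from the correct
#' trials.
#'
#' @param events Trial-event data frame with a logical/0-1 `correct` column.
#' @param baseline_amp Trials x baseline-bins matrix of channel-averaged band
#'   amplitude (rows in the order of `events`).
#' @param k Robust-SD multiplier of the quiescence threshold (default 3).
#' @return List with `retained` (logical per trial), `n_incorrect`,
#'   `n_baseline` (exclusion counts) and `threshold`.
#' @export
exclude_trials <- function(events, baseline_amp, k = 3) {
  stopifnot(is.data.frame(events), "correct" %in% names(events),
            nrow(events) == nrow(rbind(baseline_amp)))
  baseline_amp <- rbind(baseline_amp)
  correct <- as.logical(events$correct)
  if (anyNA(correct)) stop("missing correctness flags")
  stat <- apply(baseline_amp, 1, max, na.rm = TRUE)
  thr <- median(stat[correct]) + k * mad(stat[correct])
  quiet <- stat <= thr
  retained <- correct & quiet
  if (!any(retained)) {
    stop("all ", nrow(events), " trials excluded (",
         sum(!correct), " incorrect, ",
         sum(correct & !quiet), " without baseline quiescence)")
  }
  list(retained = retained,
       n_incorrect = sum(!correct),
       n_baseline = sum(correct & !quiet),
       threshold = thr)
}

#' Extract per-electrode high-gamma percent-change timelines
#'
#' Runs the full time-frequency stage on one recording: complex demodulation
#' of every channel, band averaging over the 70-110 Hz grid, trial exclusion
#' (incorrect answers, non-quiescent baselines, trials whose baseline loses
#' filter support at the recording edge), percent-change normalization, and
#' trial averaging in the three alignment windows.
#'
#' @param recording An `hg_recording` (see [simulate_recording()] or
#'   [read_recording()]).
#' @param events Trial-event data frame with columns `trial_id`, `task`,
#'   `stim_onset_sample`, `stim_offset_sample`, `response_onset_sample`,
#'   `correct`.
#' @param spec A [demod_spec()]; its sampling rate must match the recording.
#' @param baseline_ms Baseline window in ms relative to stimulus onset.
#' @param normalization See [percent_change()].
#' @param quiescence_k Robust-SD multiplier for [exclude_trials()].
#' @return An object of class `"hg_timelines"`: per task, per alignment, an
#'   electrodes x bins matrix of trial-averaged percent change (`NA` for bins
#'   without valid data), with bin centers in ms, retained-trial counts and
#'   exclusion counts.
#' @export
hg_extract <- function(recording, events, spec = demod_spec(),
                       baseline_ms = c(-600, -200),
                       normalization = c("trial_mean", "per_trial"),
                       quiescence_k = 3) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(recording, "hg_recording"))
  if (recording$sample_rate != spec$fs) {
    stop("recording sample rate (", recording$sample_rate,
         " Hz) does not match demodulation spec (", spec$fs, " Hz)")
  }
  v <- recording$voltages
  n <- ncol(v)
  n_chan <- nrow(v)
  tv <- t(v)                  # samples x channels: contiguous per channel
  half <- spec$half
  wins <- alignment_windows(spec$step_ms)
  n_bl <- length(seq(baseline_ms[1], baseline_ms[2], by = spec$step_ms))
  seg_names <- c("baseline", names(wins))
  seg_len <- c(n_bl, lengths(wins))
  seg_end <- cumsum(seg_len)
  seg_start <- seg_end - seg_len + 1L
  nseg <- sum(seg_len)

  tasks <- unique(as.character(events$task))
  out_tasks <- list()
  for (task in tasks) {
    ev <- events[events$task == task, , drop = FALSE]
    nt <- nrow(ev)
    centers <- matrix(NA_integer_, nrow = nt, ncol = nseg)
    for (i in seq_len(nt)) {
      tc <- trial_bin_centers(ev$stim_onset_sample[i],
                              ev$stim_offset_sample[i],
                              ev$response_onset_sample[i],
                              fs = spec$fs, baseline_ms = baseline_ms,
                              step_ms = spec$step_ms)
      centers[i, ] <- unlist(tc, use.names = FALSE)
    }
    inside <- centers >= half + 1L & centers <= n - half
    ## a trial without a fully valid baseline cannot be normalized
    bl_ok <- rowSums(!inside[, seq_len(n_bl), drop = FALSE]) == 0
    n_edge <- sum(!bl_ok)
    if (!any(bl_ok)) {
      stop("task ", task, ": no trial has a baseline with full filter support")
    }
    flat <- as.vector(centers)
    ok <- as.vector(inside)
    idx <- outer(as.integer(flat[ok]), seq.int(-half, half), `+`)
    A <- matrix(NA_real_, nrow = n_chan, ncol = length(flat))
    for (ch in seq_len(n_chan)) {
      A[ch, ok] <- rowMeans(demod_amplitude_at(tv[, ch], flat[ok], spec,
                                               idx = idx))
    }
    ## same memory order as (channel, trial, segment)
    amp <- array(A, dim = c(n_chan, nt, nseg))
    ## exclusion on the trials with a usable baseline
    bl_mean <- apply(amp[, bl_ok, seq_len(n_bl), drop = FALSE], c(2, 3),
                     mean)  # trials x baseline bins, channel-averaged
    exc <- exclude_trials(ev[bl_ok, , drop = FALSE], bl_mean,
                          k = quiescence_k)
    keep <- which(bl_ok)[exc$retained]

    aligns <- list()
    for (j in seq_along(wins)) {
      cols <- seg_start[j + 1L]:seg_end[j + 1L]
      pct <- matrix(NA_real_, nrow = n_chan, ncol = length(cols))
      for (ch in seq_len(n_chan)) {
        pc <- percent_change(amp[ch, keep, cols],
                             amp[ch, keep, seq_len(n_bl)],
                             normalization = normalization)
        pct[ch, ] <- pc$pct
      }
      rownames(pct) <- recording$channel_ids
      aligns[[names(wins)[j]]] <- list(pct = pct, bin_ms = wins[[j]])
    }
    out_tasks[[task]] <- list(
      alignments = aligns,
      n_trials = length(keep),
      retained_trials = ev$trial_id[keep],
      excluded = c(incorrect = exc$n_incorrect,
                   baseline = exc$n_baseline,
                   edge = n_edge))
  }
  structure(list(tasks = out_tasks,
                 electrode_ids = recording$channel_ids,
                 patient_id = recording$patient_id,
                 normalization = normalization,
                 baseline_ms = baseline_ms,
                 spec = spec),
            class = "hg_timelines")
}

#' Pool timelines from several patients
#'
#' Stacks the per-electrode percent-change matrices of several
#' [hg_extract()] results (one per patient) into a single set, electrode
#' sites pooled across patients.
#'
#' @param timelines List of `hg_timelines` objects sharing task names and
#'   bin grids.
#' @return A pooled `hg_timelines` object.
#' @export
pool_timelines <- function(timelines) {
  stopifnot(length(timelines) >= 1,
            all(vapply(timelines, inherits, logical(1), "hg_timelines")))
  if (length(timelines) == 1L) return(timelines[[1]])
  ref <- timelines[[1]]
  tasks <- names(ref$tasks)
  for (tl in timelines[-1]) {
    if (!identical(sort(names(tl$tasks)), sort(tasks))) {
      stop("timeline sets do not share task names")
    }
  }
  out_tasks <- list()
  for (task in tasks) {
    aligns <- list()
    for (al in names(ref$tasks[[task]]$alignments)) {
      mats <- lapply(timelines, function(tl) {
        a <- tl$tasks[[task]]$alignments[[al]]
        stopifnot(identical(a$bin_ms, ref$tasks[[task]]$alignments[[al]]$bin_ms))
        a$pct
      })
      aligns[[al]] <- list(pct = do.call(rbind, mats),
                           bin_ms = ref$tasks[[task]]$alignments[[al]]$bin_ms)
    }
    out_tasks[[task]] <- list(
      alignments = aligns,
      n_trials = sum(vapply(timelines, function(tl)
        tl$tasks[[task]]$n_trials, numeric(1))),
      excluded = Reduce(`+`, lapply(timelines, function(tl)
        tl$tasks[[task]]$excluded)))
  }
  structure(list(tasks = out_tasks,
                 electrode_ids = unlist(lapply(timelines,
                                               `[[`, "electrode_ids")),
                 patient_id = vapply(timelines, function(tl)
                   as.character(tl$patient_id), character(1)),
                 normalization = ref$normalization,
                 baseline_ms = ref$baseline_ms,
                 spec = ref$spec),
            class = "hg_timelines")
}
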