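## Shared helpers for the test suite.

## Pure sinusoid with given peak amplitude.
make_tone <- function(freq, amp, n, fs = 1000, phase = 0) {
  amp * sin(2 * pi * freq * seq_len(n) / fs + phase)
}

## Hand-rolled significance-mask list in the nested shape
## masks[[roi]][[task]][[alignment]] used by detect_co_events().
make_masks <- function(..., task = "picture", alignment = "stimulus_onset") {
  rois <- list(...)
  lapply(rois, function(m) setNames(list(setNames(list(m), alignment)),
                                    task))
}

## Character mask of length n with "augment" on the given bin indices.
aug_mask <- function(n, idx = integer(0), value = "augment") {
  m <- rep("none", n)
  m[idx] <- value
  m
}

## Small single-patient simulation used by several io/pipeline tests:
## 2 left ROIs x 9 electrodes, one task, optionally with a planted
## co-burst on both ROIs.
tiny_sim <- function(seed, with_burst = FALSE, n_trials = 6) {
  sched <- if (with_burst) {
    data.frame(roi = c("STG_L", "PreCG_L"), alignment = "stimulus_onset",
               onset_ms = 200, duration_ms = 300, amplitude_pct = 100,
               task = "picture")
  }
  adj <- simulate_adjacency(c("STG_L", "PreCG_L"),
                            edges = cbind("STG_L", "PreCG_L"))
  cfg <- sim_config(rois = c("STG_L", "PreCG_L"), electrodes_per_roi = 9,
                    n_patients = 1,
                    n_trials_per_task = c(picture = n_trials),
                    tasks = "picture", seed = seed,
                    burst_schedule = sched, adjacency = adj)
  simulate_recording(cfg)
}
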