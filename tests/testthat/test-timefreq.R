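test_that("demod_spec derives the Gaussian kernel from the temporal FWHM", {
  sp <- demod_spec()
  expect_equal(sp$sigma_samples, 31.6 / (2 * sqrt(2 * log(2))),
               tolerance = 1e-12)
  expect_equal(sp$half, as.integer(ceiling(3 * sp$sigma_samples)))
  expect_equal(sum(sp$taps), 1, tolerance = 1e-12)
  expect_equal(sp$freqs, seq(70, 110, by = 5))
  expect_error(demod_spec(freqs = numeric(0)))
  expect_error(demod_spec(temporal_fwhm_ms = -1))
})

test_that("demodulation matches a direct Gabor computation", {
  sp <- demod_spec()
  set.seed(1)
  x <- rnorm(1000)
  centers <- c(200L, 500L, 700L)
  got <- hgconn:::demod_amplitude_at(x, centers, sp)
  offs <- seq.int(-sp$half, sp$half)
  for (ci in seq_along(centers)) {
    for (fi in seq_along(sp$freqs)) {
      g <- sum(sp$taps * x[centers[ci] + offs] *
                 exp(-2i * pi * sp$freqs[fi] * offs / 1000))
      expect_equal(got[ci, fi], 2 * Mod(g), tolerance = 1e-12)
    }
  }
})

test_that("pure grid-frequency tones are recovered at their amplitude", {
  sp <- demod_spec()
  for (f in c(70, 90, 110)) {
    x <- make_tone(f, 0.7, 3000)
    d <- complex_demodulate(x, sp)
    row <- format(f, trim = TRUE)
    expect_equal(unname(d$amplitude[row, d$valid]),
                 rep(0.7, sum(d$valid)), tolerance = 0.002)
  }
})

test_that("demodulated amplitude is invariant to carrier phase", {
  ## invariance holds up to the negative-frequency image leaking through
  ## the truncated kernel's spectral sidelobes (~2e-4 of the passband),
  ## bounding phase-dependent ripple at ~1e-3 in amplitude
  sp <- demod_spec()
  a <- complex_demodulate(make_tone(90, 1, 2000, phase = 0), sp)
  b <- complex_demodulate(make_tone(90, 1, 2000, phase = 1.234), sp)
  expect_lt(max(abs(a$amplitude[, a$valid] - b$amplitude[, b$valid])),
            2e-3)
})

test_that("demodulation is linear in signal scale", {
  sp <- demod_spec()
  set.seed(2)
  x <- rnorm(2000)
  a <- complex_demodulate(x, sp)
  b <- complex_demodulate(3.7 * x, sp)
  expect_equal(b$amplitude[, b$valid], 3.7 * a$amplitude[, a$valid],
               tolerance = 1e-12)
})

test_that("an off-grid tone peaks at its nearest grid frequency", {
  sp <- demod_spec()
  d <- complex_demodulate(make_tone(88, 1, 3000), sp)
  mean_amp <- rowMeans(d$amplitude[, d$valid])
  expect_equal(names(which.max(mean_amp)), "90")
})

test_that("edge bins are flagged invalid and short signals rejected", {
  sp <- demod_spec()
  x <- rnorm(500)
  d <- complex_demodulate(x, sp, bin_samples = c(1L, 250L, 500L))
  expect_equal(d$valid, c(FALSE, TRUE, FALSE))
  expect_true(all(is.na(d$amplitude[, !d$valid])))
  expect_true(all(!is.na(d$amplitude[, d$valid])))
  expect_error(complex_demodulate(rnorm(50), sp), "shorter than one filter")
  expect_error(hgconn:::demod_amplitude_at(x, 1L, sp), "signal edge")
})

test_that("band_amplitude averages the frequency grid", {
  m <- rbind(rep(1, 4), rep(3, 4))
  expect_equal(band_amplitude(m), rep(2, 4))
  expect_error(band_amplitude(m[0, , drop = FALSE]), "empty frequency grid")
})

test_that("the three alignment windows sit on the documented grid", {
  w <- alignment_windows()
  expect_equal(lengths(w), c(stimulus_onset = 111, stimulus_offset = 181,
                             response_onset = 181))
  expect_equal(sum(lengths(w)), 473)
  expect_equal(w$stimulus_onset[1], -200)
  expect_equal(w$response_onset[c(1, 181)], c(-900, 900))
  expect_true(all(vapply(w, function(b) all(diff(b) == 10), logical(1))))
})

test_that("trial_bin_centers maps windows onto recording samples", {
  tc <- trial_bin_centers(stim_onset_sample = 5000,
                          stim_offset_sample = 6800,
                          response_onset_sample = 7400)
  expect_equal(tc$baseline[c(1, 41)], c(5000 - 600, 5000 - 200))
  expect_equal(tc$stimulus_onset[c(1, 111)], c(4800, 5900))
  expect_equal(tc$stimulus_offset[91], 6800)   # center bin = offset itself
  expect_equal(tc$response_onset[c(1, 181)], c(6500, 8300))
})

test_that("percent_change matches its closed form and is scale invariant", {
  band <- rbind(c(2, 4), c(6, 8))          # 2 trials x 2 bins
  baseline <- rbind(c(1, 1), c(3, 3))
  tm <- percent_change(band, baseline, "trial_mean")
  expect_equal(tm$pct, c(100 * (4 - 2) / 2, 100 * (6 - 2) / 2))
  pt <- percent_change(band, baseline, "per_trial")
  expect_equal(pt$pct, c(mean(c(100, 100)), mean(c(300, 100 * 5 / 3))))
  ## multiplying all amplitudes by a constant leaves percent change fixed
  for (norm in c("trial_mean", "per_trial")) {
    a <- percent_change(band, baseline, norm)
    b <- percent_change(5 * band, 5 * baseline, norm)
    expect_equal(a$pct, b$pct, tolerance = 1e-12)
  }
})

test_that("zero baselines are rejected or dropped with a diagnostic", {
  band <- rbind(c(1, 2), c(3, 4))
  expect_error(percent_change(band, rbind(c(0, 0), c(0, 0)), "trial_mean"),
               "baseline mean amplitude is zero")
  expect_message(
    pt <- percent_change(band, rbind(c(0, 0), c(2, 2)), "per_trial"),
    "zero baseline")
  expect_equal(pt$n_trials, 1)
  expect_equal(pt$dropped, 1L)
  expect_error(percent_change(band, rbind(c(0, 0), c(0, 0)), "per_trial"),
               "all trials")
})

test_that("exclude_trials removes incorrect and non-quiescent trials", {
  ev <- data.frame(correct = c(TRUE, TRUE, FALSE, rep(TRUE, 17)))
  set.seed(3)
  bl <- matrix(rnorm(20 * 5, mean = 10), nrow = 20)
  bl[2, ] <- 200                            # wildly non-quiescent baseline
  exc <- exclude_trials(ev, bl, k = 3)
  expect_false(exc$retained[2])
  expect_false(exc$retained[3])
  expect_equal(exc$n_incorrect, 1)
  expect_equal(exc$n_baseline, 1)
  expect_equal(sum(exc$retained), 18)
  ## all trials excluded -> hard error
  expect_error(exclude_trials(data.frame(correct = c(FALSE, FALSE)),
                              matrix(1, 2, 3)), "all 2 trials excluded")
})

test_that("hg_extract produces per-task alignment matrices on the 473 grid", {
  sim <- tiny_sim(31, n_trials = 4)
  rec <- sim$patients[[1]]$recording
  ev <- sim$patients[[1]]$events
  tl <- hg_extract(rec, ev, demod_spec())
  expect_s3_class(tl, "hg_timelines")
  al <- tl$tasks$picture$alignments
  expect_equal(vapply(al, function(a) ncol(a$pct), numeric(1)),
               c(stimulus_onset = 111, stimulus_offset = 181,
                 response_onset = 181))
  expect_equal(nrow(al$stimulus_onset$pct), 18)
  expect_equal(rownames(al$stimulus_onset$pct), rec$channel_ids)
  cnt <- tl$tasks$picture$n_trials + sum(tl$tasks$picture$excluded)
  expect_equal(cnt, 4)
  ## sample-rate mismatch rejected
  sp2 <- demod_spec(fs = 500)
  expect_error(hg_extract(rec, ev, sp2), "does not match")
})

test_that("pool_timelines stacks electrodes and checks task compatibility", {
  cfg <- function(seed) sim_config(rois = "STG_L", electrodes_per_roi = 2,
                                   n_patients = 1, n_trials_per_task = 2,
                                   tasks = "picture", seed = seed)
  mk <- function(seed) {
    s <- simulate_recording(cfg(seed))
    hg_extract(s$patients[[1]]$recording, s$patients[[1]]$events,
               demod_spec())
  }
  a <- mk(41); b <- mk(42)
  ## distinct patient labels so pooled electrode ids stay unique
  rownames(b$tasks$picture$alignments$stimulus_onset$pct) <-
    sub("P01", "P02", rownames(b$tasks$picture$alignments$stimulus_onset$pct))
  pooled <- pool_timelines(list(a, b))
  expect_equal(nrow(pooled$tasks$picture$alignments$stimulus_onset$pct), 4)
  expect_equal(pooled$tasks$picture$n_trials,
               a$tasks$picture$n_trials + b$tasks$picture$n_trials)
  names(b$tasks) <- "sound"
  expect_error(pool_timelines(list(a, b)), "task names")
})
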