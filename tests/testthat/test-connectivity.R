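test_that("detect_co_events requires 100 ms of shared polarity", {
  n <- 40
  bins <- list(stimulus_onset = seq(-200, by = 10, length.out = n))
  ## 10 shared augment bins -> one event; 9 -> none
  masks <- make_masks(A = aug_mask(n, 11:25), B = aug_mask(n, 16:25))
  ev <- detect_co_events(masks, bin_ms = bins)
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$onset_bin, ev$offset_bin), c(16, 25))
  expect_equal(ev$onset_ms, bins$stimulus_onset[16])
  expect_equal(ev$polarity, "co-augment")
  expect_equal(c(ev$roi_a, ev$roi_b), c("A", "B"))
  masks9 <- make_masks(A = aug_mask(n, 11:24), B = aug_mask(n, 16:24))
  expect_equal(nrow(detect_co_events(masks9, bin_ms = bins)), 0)
})

test_that("mixed polarity never forms an event; co-attenuation does", {
  n <- 40
  bins <- list(stimulus_onset = seq(0, by = 10, length.out = n))
  mixed <- make_masks(A = aug_mask(n, 1:20),
                      B = aug_mask(n, 1:20, "attenuate"))
  expect_equal(nrow(detect_co_events(mixed, bin_ms = bins)), 0)
  att <- make_masks(A = aug_mask(n, 5:20, "attenuate"),
                    B = aug_mask(n, 1:16, "attenuate"))
  ev <- detect_co_events(att, bin_ms = bins)
  expect_equal(ev$polarity, "co-attenuate")
  expect_equal(c(ev$onset_bin, ev$offset_bin), c(5, 16))
})

test_that("two separated runs yield two events; grids must match", {
  n <- 60
  bins <- list(stimulus_onset = seq(0, by = 10, length.out = n))
  masks <- make_masks(A = aug_mask(n, c(1:12, 30:45)),
                      B = aug_mask(n, c(1:12, 30:45)))
  ev <- detect_co_events(masks, bin_ms = bins)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$onset_bin, c(1, 30))
  short <- make_masks(A = aug_mask(n, 1:12), B = aug_mask(30, 1:12))
  expect_error(detect_co_events(short, bin_ms = bins), "common bin grid")
})

test_that("gate_by_adjacency keeps streamlined pairs and adds laterality", {
  cand <- data.frame(roi_a = c("PreCG_L", "PreCG_L", "STG_L"),
                     roi_b = c("STG_L", "STG_R", "STG_R"),
                     task = "picture", alignment = "stimulus_onset",
                     onset_bin = 1L, offset_bin = 10L,
                     onset_ms = 0, offset_ms = 90,
                     polarity = "co-augment")
  adj <- simulate_adjacency(c("PreCG_L", "STG_L", "STG_R"),
                            edges = rbind(c("PreCG_L", "STG_L"),
                                          c("STG_L", "STG_R")))
  gated <- gate_by_adjacency(cand, adj)
  expect_equal(nrow(gated), 2)
  expect_equal(gated$laterality, c("left-intra", "inter"))
  ## empty candidates pass through with the laterality column added
  empty <- gate_by_adjacency(cand[0, ], adj)
  expect_equal(nrow(empty), 0)
  expect_true("laterality" %in% names(empty))
  cand$roi_a[1] <- "FG_L"
  expect_error(gate_by_adjacency(cand, adj), "missing from adjacency")
})

test_that("chance_probability implements the closed form", {
  expect_equal(chance_probability(36, 473, 10, 21.9),
               choose(36, 2) * 464 * 0.219^20, tolerance = 1e-12)
  ## scales linearly in pairs and window positions
  expect_equal(chance_probability(4, 50, 3, 30),
               6 * 48 * 0.3^6, tolerance = 1e-12)
  ## monotone in chi
  expect_lt(chance_probability(36, 473, 10, 10),
            chance_probability(36, 473, 10, 20))
  expect_error(chance_probability(36, 473, 500, 21.9))
  expect_error(chance_probability(36, 473, 10, 150))
})

test_that("compute_chi averages marginal significance rates", {
  masks <- list(A = aug_mask(10, 1:2), B = aug_mask(10, 1:4))
  expect_equal(compute_chi(masks), mean(c(20, 40)))
  expect_equal(compute_chi(masks, "attenuate"), 0)
  ## hg_roi_stats method: per task over the concatenated alignments
  rs <- structure(list(masks = list(
    A = list(picture = list(stimulus_onset = aug_mask(10, 1:5),
                            response_onset = aug_mask(10))),
    B = list(picture = list(stimulus_onset = aug_mask(10),
                            response_onset = aug_mask(10, 1:5))))),
    class = "hg_roi_stats")
  chi <- compute_chi(rs)
  expect_equal(unname(chi$per_task["picture"]), 25)
  expect_equal(chi$mean, 25)
})

test_that("dynamic_connectome renders sliding epochs with full coverage", {
  bins <- seq(-200, 900, by = 10)
  ev <- data.frame(roi_a = "A", roi_b = "B", task = "picture",
                   alignment = "stimulus_onset",
                   onset_ms = 0, offset_ms = 190, polarity = "co-augment")
  cn <- dynamic_connectome(ev, bins)
  ## full 100-ms coverage: epoch starts 0..100 (bins [s, s+90] inside)
  expect_equal(sort(cn$epochs$epoch_start_ms), seq(0, 100, by = 10))
  expect_equal(sum(cn$pair_counts), 20)     # 20 covered bins
  expect_equal(cn$roi_pair_counts["A", ], cn$roi_pair_counts["B", ])
  ## "any" coverage admits partial overlap
  cn2 <- dynamic_connectome(ev, bins, coverage = "any")
  expect_equal(sort(cn2$epochs$epoch_start_ms), seq(-90, 190, by = 10))
  ## invalid epoch geometry and mixed alignments rejected
  expect_error(dynamic_connectome(ev, bins, epoch_ms = 105),
               "multiple of the sliding step")
  ev2 <- rbind(ev, transform(ev, alignment = "response_onset"))
  expect_error(dynamic_connectome(ev2, bins), "several alignment grids")
  ## no events -> empty epochs, zero counts
  cn0 <- dynamic_connectome(ev[0, ], bins)
  expect_equal(nrow(cn0$epochs), 0)
  expect_true(all(cn0$pair_counts == 0))
})

test_that("pair_count_series counts active pairs per bin with filters", {
  bins <- seq(0, 200, by = 10)
  ev <- data.frame(roi_a = c("PreCG_L", "STG_L"),
                   roi_b = c("STG_L", "STG_R"),
                   onset_ms = c(0, 50), offset_ms = c(100, 150),
                   laterality = c("left-intra", "inter"))
  all_counts <- pair_count_series(ev, bins)
  expect_equal(all_counts[1], 1L)
  expect_equal(all_counts[6], 2L)           # 50 ms: both active
  expect_equal(all_counts[21], 0L)
  left <- pair_count_series(ev, bins, laterality = "left-intra")
  expect_equal(max(left), 1L)
  expect_equal(sum(left), 11L)
})

test_that("period_extent_summary compares the three 600-ms periods", {
  stim_bins <- seq(-200, 900, by = 10)
  resp_bins <- seq(-900, 900, by = 10)
  ## deterministic block pattern: post-stimulus clearly larger than the
  ## response periods, pre-response smallest
  stim_counts <- as.integer(stim_bins >= 0 & stim_bins < 600) * 5L
  resp_counts <- ifelse(resp_bins >= 0 & resp_bins < 600, 2L,
                        ifelse(resp_bins >= -600 & resp_bins < 0, 1L, 0L))
  ## add bin-level jitter so ranks are not fully tied
  set.seed(15)
  stim_counts <- stim_counts + sample(0:1, length(stim_counts), TRUE)
  resp_counts <- resp_counts + sample(0:1, length(resp_counts), TRUE)
  ps <- period_extent_summary(stim_counts, stim_bins, resp_counts, resp_bins)
  expect_equal(nrow(ps$counts), 60)
  expect_named(ps$medians, c("post_stimulus", "pre_response",
                             "post_response"))
  expect_gt(ps$medians["post_stimulus"], ps$medians["post_response"])
  expect_gt(ps$friedman$statistic, 0)
  expect_equal(ps$friedman$df, 2)
  expect_equal(nrow(ps$pairwise), 3)
  expect_equal(ps$pairwise_threshold, 0.0056)
  ## effect sizes use N = 2 x 60 blocks
  w <- wilcoxon_signed_rank(ps$counts[, "pre_response"],
                            ps$counts[, "post_response"])
  expect_equal(ps$pairwise$r[1], abs(w$Z) / sqrt(120), tolerance = 1e-12)
  ## cross-check the Friedman statistic against the reference
  ## implementation (identical when ranks are untied within rows)
  untied <- ps$counts + matrix(runif(180, 0, 1e-3), ncol = 3)
  expect_equal(friedman_chisq(untied)$statistic,
               unname(stats::friedman.test(untied)$statistic),
               tolerance = 1e-10)
  ## a grid not covering a period is rejected
  expect_error(period_extent_summary(stim_counts, stim_bins - 2000,
                                     resp_counts, resp_bins),
               "not covered")
})

test_that("streamline_coverage_summary reports per-laterality percentages", {
  lefts <- grep("_L$", roi_catalog(), value = TRUE)[1:13]  # 78 pairs
  rights <- grep("_R$", roi_catalog(), value = TRUE)[1:14]
  lp <- t(combn(lefts, 2))                  # 78 left-intra pairs
  ip <- expand.grid(a = lefts[1:10], b = rights[1:13],
                    stringsAsFactors = FALSE)[1:130, ]  # 130 inter pairs
  cand <- data.frame(roi_a = c(lp[, 1], ip$a),
                     roi_b = c(lp[, 2], ip$b),
                     task = "picture", alignment = "stimulus_onset",
                     onset_bin = 1L, offset_bin = 10L, onset_ms = 0,
                     offset_ms = 90, polarity = "co-augment")
  ## adjacency granting streamlines to 66 of the 78 left-intra pairs and
  ## 24 of the 130 inter pairs
  adj <- matrix(FALSE, 36, 36, dimnames = list(roi_catalog(), roi_catalog()))
  put <- function(a, b) {
    adj[cbind(a, b)] <<- TRUE
    adj[cbind(b, a)] <<- TRUE
  }
  put(lp[1:66, 1], lp[1:66, 2])
  put(ip$a[1:24], ip$b[1:24])
  cov <- streamline_coverage_summary(cand, adj)
  expect_equal(cov$n_pairs[cov$laterality == "left-intra"], 78)
  expect_equal(cov$percent[cov$laterality == "left-intra"], 84.6)
  expect_equal(cov$n_with_streamlines[cov$laterality == "inter"], 24)
  expect_equal(cov$percent[cov$laterality == "inter"], 18.5)
  ## a class with no pairs reports NA, and duplicates collapse per task
  expect_true(is.na(cov$percent[cov$laterality == "right-intra"]))
  cov2 <- streamline_coverage_summary(rbind(cand, cand), adj)
  expect_equal(cov2$n_pairs, cov$n_pairs)
})

test_that("roi_catalog and laterality helpers are consistent", {
  expect_length(roi_catalog(), 36)
  expect_equal(sum(grepl("_L$", roi_catalog())), 18)
  expect_equal(roi_hemisphere(c("STG_L", "FG_R")), c("L", "R"))
  expect_equal(laterality_class(c("STG_L", "STG_R", "STG_L"),
                                c("FG_L", "FG_R", "FG_R")),
               c("left-intra", "right-intra", "inter"))
})
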