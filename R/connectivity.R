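## White-matter-gated dynamic connectivity: sustained high-gamma
## co-modulation between ROI pairs, streamline gating, the analytic chance
## probability of coincident significance runs, and sliding-epoch connectome
## summaries.

#' Detect sustained co-modulation between ROI pairs
#'
#' For every unordered ROI pair and every task/alignment, finds the maximal
#' runs where both significance masks are simultaneously `"augment"`
#' (separately: both `"attenuate"`) for at least `min_run_ms`. Mixed
#' polarity never qualifies. The onset is the first bin of the qualifying
#' run.
#'
#' @param x An [roi_stats()] result, or a nested mask list
#'   `masks[[roi]][[task]][[alignment]]` plus `bin_ms`.
#' @param min_run_ms Minimum simultaneous duration (default 100 ms, i.e. ten
#'   consecutive 10-ms bins).
#' @param bin_ms Named list of bin-center vectors per alignment (taken from
#'   `x` when it is an `hg_roi_stats`).
#' @param step_ms Bin spacing in ms.
#' @return Candidate data frame: `roi_a`, `roi_b`, `task`, `alignment`,
#'   `onset_bin`, `offset_bin` (1-based bin indices), `onset_ms`,
#'   `offset_ms` (bin centers), `polarity`.
#' @export
detect_co_events <- function(x, min_run_ms = 100, bin_ms = NULL,
                             step_ms = 10) {
  if (inherits(x, "hg_roi_stats")) {
    bin_ms <- x$bin_ms
    step_ms <- diff(bin_ms[[1]])[1]
    masks <- x$masks
  } else {
    masks <- x
    if (is.null(bin_ms)) stop("bin_ms required when passing raw masks")
  }
  min_bins <- ceiling(min_run_ms / step_ms)
  rois <- sort(names(masks))
  out <- list()
  if (length(rois) >= 2) {
    for (task in names(masks[[1]])) {
      for (al in names(masks[[1]][[task]])) {
        grid <- bin_ms[[al]]
        nb <- length(grid)
        for (i in seq_len(length(rois) - 1)) {
          mi <- masks[[rois[i]]][[task]][[al]]
          if (length(mi) != nb) stop("mask of ", rois[i],
                                     " not on the common bin grid")
          for (j in (i + 1):length(rois)) {
            mj <- masks[[rois[j]]][[task]][[al]]
            if (length(mj) != nb) stop("mask of ", rois[j],
                                       " not on the common bin grid")
            for (pol in c("augment", "attenuate")) {
              both <- mi == pol & mj == pol
              r <- rle(both)
              ends <- cumsum(r$lengths)
              starts <- ends - r$lengths + 1L
              keep <- which(r$values & r$lengths >= min_bins)
              for (k in keep) {
                out[[length(out) + 1L]] <- data.frame(
                  roi_a = rois[i], roi_b = rois[j], task = task,
                  alignment = al, onset_bin = starts[k],
                  offset_bin = ends[k], onset_ms = grid[starts[k]],
                  offset_ms = grid[ends[k]],
                  polarity = if (pol == "augment") "co-augment"
                             else "co-attenuate")
              }
            }
          }
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(roi_a = character(0), roi_b = character(0),
                      task = character(0), alignment = character(0),
                      onset_bin = integer(0), offset_bin = integer(0),
                      onset_ms = numeric(0), offset_ms = numeric(0),
                      polarity = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gate co-modulation candidates by streamline adjacency
#'
#' Functional connectivity between two ROIs is accepted only when their
#' sustained co-modulation is accompanied by direct white-matter streamlines
#' in the adjacency matrix. Adds the laterality class of each retained pair.
#'
#' @param candidates Output of [detect_co_events()].
#' @param adjacency Binary symmetric ROI x ROI matrix with dimnames.
#' @return The subset of `candidates` with a direct streamline, plus a
#'   `laterality` column.
#' @export
gate_by_adjacency <- function(candidates, adjacency) {
  validate_adjacency(adjacency)
  rois <- unique(c(candidates$roi_a, candidates$roi_b))
  miss <- setdiff(rois, rownames(adjacency))
  if (length(miss)) {
    stop("ROI(s) missing from adjacency: ", paste(miss, collapse = ", "))
  }
  if (!nrow(candidates)) {
    out <- candidates
    out$laterality <- character(0)
    return(out)
  }
  keep <- adjacency[cbind(candidates$roi_a, candidates$roi_b)] != 0
  out <- candidates[keep, , drop = FALSE]
  out$laterality <- if (nrow(out)) laterality_class(out$roi_a, out$roi_b)
                    else character(0)
  rownames(out) <- NULL
  out
}

#' Analytic chance probability of a coincident significance run
#'
#' Expected count, under independence across bins and ROIs, of
#' co-augmentation runs of at least `run_len_bins` consecutive bins in any
#' unordered ROI pair:
#' `C(n_roi, 2) * (n_bins - L + 1) * (chi/100)^(2L)`, where `chi` is the
#' average marginal percentage of significant bins per ROI and `L` the run
#' length. Being an expected count it upper-bounds the probability of at
#' least one chance occurrence (Type I error).
#'
#' @param n_roi Number of ROIs (default 36).
#' @param n_bins Number of analysis bins (default 473).
#' @param run_len_bins Run length in bins (default 10, i.e. 100 ms).
#' @param chi Marginal significance rate in percent.
#' @return Expected count of chance co-runs.
#' @examples
#' chance_probability(chi = 21.9)   # ~1.9e-8
#' @export
chance_probability <- function(n_roi = 36, n_bins = 473,
                               run_len_bins = 10, chi) {
  stopifnot(n_roi >= 2, run_len_bins >= 1, run_len_bins <= n_bins,
            chi >= 0, chi <= 100)
  choose(n_roi, 2) * (n_bins - run_len_bins + 1) *
    (chi / 100)^(2 * run_len_bins)
}

#' Marginal significance rate chi
#'
#' Percentage of analysis bins flagged with the given polarity, averaged
#' across ROIs (and, for an [roi_stats()] object, reported per task over the
#' concatenated 473-bin analysis window of the three alignments).
#'
#' @param x Either a list of per-ROI mask vectors or an `hg_roi_stats`.
#' @param polarity `"augment"` (default) or `"attenuate"`.
#' @param ... Unused.
#' @return For a mask list: a scalar percentage. For an `hg_roi_stats`:
#'   list with `per_task` (named vector) and `mean`.
#' @export
compute_chi <- function(x, polarity = c("augment", "attenuate"), ...) {
  UseMethod("compute_chi")
}

#' @export
compute_chi.default <- function(x, polarity = c("augment", "attenuate"),
                                ...) {
  polarity <- match.arg(polarity)
  stopifnot(length(x) >= 1)
  mean(vapply(x, function(m) 100 * mean(m == polarity), numeric(1)))
}

#' @export
compute_chi.hg_roi_stats <- function(x, polarity = c("augment",
                                                     "attenuate"), ...) {
  polarity <- match.arg(polarity)
  tasks <- names(x$masks[[1]])
  per_task <- vapply(tasks, function(task) {
    compute_chi.default(lapply(x$masks, function(roi)
      unlist(roi[[task]], use.names = FALSE)), polarity)
  }, numeric(1))
  list(per_task = per_task, mean = mean(per_task))
}

#' Sliding-epoch dynamic connectome
#'
#' Renders connectivity events as the set of active ROI pairs in each
#' 100-ms epoch sliding in 10-ms steps, plus the per-bin count of active
#' pairs incident to each ROI.
#'
#' @param events Gated events on a single alignment grid (one `alignment`
#'   value; any mix of tasks the caller wants rendered).
#' @param bin_ms Bin centers (ms) of that alignment grid.
#' @param epoch_ms Epoch length (default 100); must be a multiple of
#'   `step_ms`.
#' @param step_ms Sliding step (default 10).
#' @param coverage `"full"` (default; the event must cover every bin of the
#'   epoch) or `"any"` (any overlap).
#' @return List of class `"hg_connectome"`: `epochs` (long data frame
#'   `epoch_start_ms`, `roi_a`, `roi_b`), `epoch_starts`,
#'   `roi_pair_counts` (ROI x bin matrix of incident active pairs) and
#'   `pair_counts` (active pairs per bin), with `bin_ms`.
#' @export
dynamic_connectome <- function(events, bin_ms, epoch_ms = 100,
                               step_ms = 10, coverage = c("full", "any")) {
  coverage <- match.arg(coverage)
  if (epoch_ms %% step_ms != 0) {
    stop("epoch length must be a multiple of the sliding step")
  }
  if (length(unique(events$alignment)) > 1) {
    stop("events span several alignment grids; filter to one alignment")
  }
  starts <- seq(min(bin_ms), max(bin_ms) - epoch_ms + step_ms, by = step_ms)
  last_bin <- starts + epoch_ms - step_ms      # last bin center in epoch
  rois <- sort(unique(c(events$roi_a, events$roi_b)))
  pair_counts <- rep(0L, length(bin_ms))
  roi_pair_counts <- matrix(0L, nrow = max(length(rois), 1),
                            ncol = length(bin_ms),
                            dimnames = list(if (length(rois)) rois else "none",
                                            bin_ms))
  ep <- list()
  for (i in seq_len(nrow(events))) {
    on <- events$onset_ms[i]; off <- events$offset_ms[i]
    active <- if (coverage == "full") on <= starts & off >= last_bin
              else on <= last_bin & off >= starts
    if (any(active)) {
      ep[[length(ep) + 1L]] <- data.frame(
        epoch_start_ms = starts[active],
        roi_a = events$roi_a[i], roi_b = events$roi_b[i])
    }
    covered <- bin_ms >= on & bin_ms <= off
    pair_counts[covered] <- pair_counts[covered] + 1L
    roi_pair_counts[events$roi_a[i], covered] <-
      roi_pair_counts[events$roi_a[i], covered] + 1L
    roi_pair_counts[events$roi_b[i], covered] <-
      roi_pair_counts[events$roi_b[i], covered] + 1L
  }
  epochs <- if (length(ep)) do.call(rbind, ep) else
    data.frame(epoch_start_ms = numeric(0), roi_a = character(0),
               roi_b = character(0))
  structure(list(epochs = epochs, epoch_starts = starts,
                 pair_counts = pair_counts,
                 roi_pair_counts = roi_pair_counts, bin_ms = bin_ms,
                 epoch_ms = epoch_ms, step_ms = step_ms,
                 coverage = coverage),
            class = "hg_connectome")
}

#' Per-bin count of active ROI pairs
#'
#' @param events Gated connectivity events on one alignment grid.
#' @param bin_ms Bin centers of that grid.
#' @param laterality Optional laterality class filter (`"left-intra"`,
#'   `"right-intra"`, `"inter"`).
#' @return Integer vector of active-pair counts per bin.
#' @export
pair_count_series <- function(events, bin_ms, laterality = NULL) {
  if (!is.null(laterality)) {
    events <- events[events$laterality %in% laterality, , drop = FALSE]
  }
  counts <- rep(0L, length(bin_ms))
  for (i in seq_len(nrow(events))) {
    covered <- bin_ms >= events$onset_ms[i] & bin_ms <= events$offset_ms[i]
    counts[covered] <- counts[covered] + 1L
  }
  counts
}

#' Spatial-extent summary over the three 600-ms periods
#'
#' Compares the per-bin number of connected ROI pairs across the three
#' canonical 600-ms periods — after stimulus onset `[0, 600)`, before
#' response onset `[-600, 0)`, after response onset `[0, 600)` — using the
#' 60 bins of each period as blocks: per-period medians, a Friedman test
#' across the three periods, and pairwise Wilcoxon signed-rank tests with
#' effect size `r = |Z| / sqrt(2 * 60)`. The pairwise significance
#' threshold 0.0056 corresponds to a Bonferroni correction over nine
#' comparisons (three laterality classes x three period contrasts).
#'
#' @param stim_counts Per-bin pair counts on the stimulus-onset grid.
#' @param stim_bin_ms Bin centers of the stimulus-onset grid.
#' @param resp_counts Per-bin pair counts on the response-onset grid.
#' @param resp_bin_ms Bin centers of the response-onset grid.
#' @param period_ms Period length (default 600).
#' @return List with `medians` (post_stimulus, pre_response, post_response),
#'   `friedman` (statistic, df, p) and `pairwise` (data frame with Z, p, r
#'   per contrast), plus the per-period count matrix.
#' @export
period_extent_summary <- function(stim_counts, stim_bin_ms,
                                  resp_counts, resp_bin_ms,
                                  period_ms = 600) {
  pick <- function(counts, bins, lo, hi) {
    sel <- bins >= lo & bins < hi
    if (!any(sel)) stop("period [", lo, ", ", hi, ") not covered by grid")
    counts[sel]
  }
  ps <- pick(stim_counts, stim_bin_ms, 0, period_ms)
  pr <- pick(resp_counts, resp_bin_ms, -period_ms, 0)
  po <- pick(resp_counts, resp_bin_ms, 0, period_ms)
  if (length(unique(c(length(ps), length(pr), length(po)))) != 1) {
    stop("periods have unequal bin counts")
  }
  m <- cbind(post_stimulus = ps, pre_response = pr, post_response = po)
  fr <- friedman_chisq(m)
  combos <- list(c("pre_response", "post_response"),
                 c("post_response", "post_stimulus"),
                 c("pre_response", "post_stimulus"))
  pw <- do.call(rbind, lapply(combos, function(cc) {
    w <- wilcoxon_signed_rank(m[, cc[1]], m[, cc[2]])
    data.frame(a = cc[1], b = cc[2], Z = w$Z, p = w$p,
               r = effect_size_r(w$Z, nrow(m)))
  }))
  list(medians = apply(m, 2, median), counts = m, friedman = fr,
       pairwise = pw, pairwise_threshold = 0.0056)
}

#' Streamline coverage of co-modulating ROI pairs
#'
#' For each laterality class, the fraction of distinct co-modulating ROI
#' pairs (per task) that are accompanied by direct white-matter streamlines.
#'
#' @param candidates [detect_co_events()] output (pre-gating).
#' @param adjacency Streamline adjacency matrix.
#' @param polarity Polarity to summarize (default `"co-augment"`).
#' @return Data frame with `laterality`, `n_pairs`, `n_with_streamlines`
#'   and `percent` (one decimal; `NA` when no pair exists in a class).
#' @export
streamline_coverage_summary <- function(candidates, adjacency,
                                        polarity = "co-augment") {
  validate_adjacency(adjacency)
  cand <- candidates[candidates$polarity == polarity, , drop = FALSE]
  pairs <- unique(cand[, c("roi_a", "roi_b", "task")])
  classes <- c("left-intra", "right-intra", "inter")
  lat <- if (nrow(pairs)) laterality_class(pairs$roi_a, pairs$roi_b)
         else character(0)
  has <- if (nrow(pairs)) adjacency[cbind(pairs$roi_a, pairs$roi_b)] != 0
         else logical(0)
  out <- do.call(rbind, lapply(classes, function(cl) {
    sel <- lat == cl
    n <- sum(sel); k <- sum(has[sel])
    data.frame(laterality = cl, n_pairs = n, n_with_streamlines = k,
               percent = if (n > 0) round(100 * k / n, 1) else NA_real_)
  }))
  out
}
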