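## Group-level ROI statistics: studentized-bootstrap confidence intervals on
## electrode-pooled percent-change timelines, run-length-gated significance
## masks, and between-task contrasts.

#' Bootstrap specification
#'
#' Parameters of the studentized (bootstrap-t) interval used for ROI-level
#' significance: 2000 resamples of electrode sites, a 99.99% confidence
#' level (equivalent in strictness to a Bonferroni correction for 500
#' repeated comparisons), and a minimum significant run of 50 ms (five
#' consecutive 10-ms bins, at least three high-gamma cycles).
#'
#' @param n_resamples Number of bootstrap resamples (default 2000).
#' @param ci_level Confidence level (default 0.9999).
#' @param min_run_ms Minimum run length in ms (default 50).
#' @param seed Integer seed for the resampling RNG.
#' @param max_retries Redraw attempts for zero-variance resamples.
#' @return List of class `"boot_spec"`.
#' @export
boot_spec <- function(n_resamples = 2000, ci_level = 0.9999,
                      min_run_ms = 50, seed = NULL, max_retries = 100) {
  stopifnot(n_resamples >= 2, ci_level > 0, ci_level < 1, min_run_ms > 0)
  structure(list(n_resamples = n_resamples, ci_level = ci_level,
                 min_run_ms = min_run_ms, seed = seed,
                 max_retries = max_retries),
            class = "boot_spec")
}

## Multinomial resample count matrix (n x B), with single-electrode
## (zero-variance) resamples redrawn up to max_retries rounds.
resample_counts <- function(n, B, max_retries = 100) {
  counts <- rmultinom(B, n, rep(1 / n, n))
  if (n > 1) {
    for (r in seq_len(max_retries)) {
      degen <- colSums(counts > 0) == 1L
      if (!any(degen)) break
      counts[, degen] <- rmultinom(sum(degen), n, rep(1 / n, n))
    }
    degen <- colSums(counts > 0) == 1L
    if (any(degen)) {
      message(sum(degen), " zero-variance resample(s) kept after ",
              max_retries, " redraw rounds")
    }
  }
  counts
}

#' Studentized-bootstrap confidence interval per time bin
#'
#' Bootstrap-t interval of the across-electrode mean percent change at each
#' bin. Electrode timelines are resampled with replacement (one resample
#' shared across all bins); the pivot `t* = (mean* - mean) / se*` yields the
#' asymmetric interval `[mean - q(t*, 1 - alpha/2) se, mean - q(t*, alpha/2)
#' se]` with `alpha = 1 - ci_level`. Bins where all electrodes agree produce
#' the degenerate interval `[mean, mean]`.
#'
#' @param x Electrodes x bins matrix; a bare vector is treated as a single
#'   bin (one value per electrode).
#' @param spec A [boot_spec()]. `spec$seed`, when set, makes the interval
#'   deterministic.
#' @param enumerate If `TRUE` (only for <= 6 electrodes), replaces Monte
#'   Carlo resampling by exhaustive enumeration of all `n^n` resamples,
#'   weighting each distinct composition by its multinomial probability.
#' @return List with per-bin `mean`, `se`, `lo`, `hi`, plus `n` and the
#'   effective resample count.
#' @export
studentized_bootstrap_ci <- function(x, spec = boot_spec(),
                                     enumerate = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  stopifnot(n >= 2)
  nb <- ncol(x)
  m <- colMeans(x)
  s2 <- colSums(sweep(x, 2, m)^2) / (n - 1)
  se <- sqrt(s2 / n)
  alpha <- 1 - spec$ci_level

  if (enumerate) {
    if (n > 6) stop("exhaustive enumeration supported for n <= 6 only")
    grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    counts <- apply(grid, 1, tabulate, nbins = n)   # n x n^n
    wts <- rep(1 / nrow(grid), nrow(grid))
    keep <- colSums(counts > 0) > 1L                # drop degenerate pivots
    counts <- counts[, keep, drop = FALSE]
    wts <- wts[keep] / sum(wts[keep])
  } else {
    runner <- function() resample_counts(n, spec$n_resamples,
                                         spec$max_retries)
    counts <- if (is.null(spec$seed)) runner() else
      with_seed(spec$seed, runner())
    wts <- NULL
  }

  m_star <- crossprod(counts, x) / n                     # B x bins
  m2_star <- crossprod(counts, x^2) / n
  v_star <- pmax(m2_star - m_star^2, 0) * n / (n - 1)
  se_star <- sqrt(v_star / n)
  t_star <- sweep(m_star, 2, m) / se_star
  t_star[se_star == 0 & sweep(m_star, 2, m) == 0] <- 0   # exact ties

  lo <- hi <- m
  probs <- c(alpha / 2, 1 - alpha / 2)
  for (j in seq_len(nb)) {
    if (se[j] == 0) next                                  # degenerate bin
    tj <- t_star[, j]
    fin <- is.finite(tj)
    q <- if (is.null(wts)) {
      quantile7(tj[fin], probs)
    } else {
      weighted_quantile(tj[fin], wts[fin] / sum(wts[fin]), probs)
    }
    lo[j] <- m[j] - q[2] * se[j]
    hi[j] <- m[j] - q[1] * se[j]
  }
  list(mean = m, se = se, lo = lo, hi = hi, n = n,
       n_resamples = ncol(counts))
}

## type-7 sample quantile without the checking overhead of quantile();
## identical results for finite input
quantile7 <- function(x, probs) {
  x <- sort.int(x, method = "quick")
  h <- (length(x) - 1) * probs + 1
  fl <- floor(h)
  x[fl] + (h - fl) * (x[pmin(fl + 1, length(x))] - x[fl])
}

weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Run-length-gated significance mask
#'
#' Marks augmentation where the lower CI limit stays above zero for at least
#' `min_run_ms` consecutively, and attenuation where the upper CI limit
#' stays below zero equally long; shorter excursions are suppressed. The two
#' polarities are tracked independently. `NA` bins break runs.
#'
#' @param lo,hi Per-bin lower/upper CI limits.
#' @param min_run_ms Minimum run length in ms (default 50).
#' @param step_ms Bin spacing in ms (default 10).
#' @return Character vector per bin: `"augment"`, `"attenuate"` or `"none"`.
#' @export
detect_modulation <- function(lo, hi, min_run_ms = 50, step_ms = 10) {
  stopifnot(length(lo) == length(hi))
  min_bins <- ceiling(min_run_ms / step_ms)
  mask <- rep("none", length(lo))
  mask[gated_runs(!is.na(lo) & lo > 0, min_bins)] <- "augment"
  mask[gated_runs(!is.na(hi) & hi < 0, min_bins)] <- "attenuate"
  mask
}

## indices belonging to TRUE-runs of length >= min_bins
gated_runs <- function(flag, min_bins) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bins
  if (!any(keep)) return(integer(0))
  unlist(mapply(seq.int, starts[keep], ends[keep], SIMPLIFY = FALSE))
}

#' Group electrodes into ROIs for pooled analysis
#'
#' Maps electrode sites to ROIs and drops ROIs with fewer than `min_n`
#' eligible sites (the admission criterion for group-level analysis).
#'
#' @param electrodes Electrode table with `electrode_id` and `roi` columns.
#' @param min_n Minimum electrode count per ROI (default 9).
#' @return Named list of electrode-id vectors per admitted ROI; excluded
#'   ROIs are reported via `message()` and in the `"excluded"` attribute.
#' @export
roi_groups <- function(electrodes, min_n = 9) {
  stopifnot(all(c("electrode_id", "roi") %in% names(electrodes)))
  if (anyNA(electrodes$roi)) stop("electrode(s) without ROI mapping")
  g <- split(as.character(electrodes$electrode_id), electrodes$roi)
  small <- names(g)[lengths(g) < min_n]
  if (length(small)) {
    message("ROI(s) excluded (< ", min_n, " electrodes): ",
            paste(small, collapse = ", "))
  }
  structure(g[lengths(g) >= min_n], excluded = small)
}

#' ROI electrode-by-bin percent-change matrix
#'
#' Extracts the pooled electrode x bin matrix of one ROI for one task and
#' alignment from an [hg_extract()]/[pool_timelines()] result.
#'
#' @param timelines An `hg_timelines` object.
#' @param electrode_ids Electrode ids of the ROI (see [roi_groups()]).
#' @param task,alignment Task and alignment window names.
#' @return Electrodes x bins numeric matrix.
#' @export
roi_matrix <- function(timelines, electrode_ids, task, alignment) {
  a <- timelines$tasks[[task]]$alignments[[alignment]]
  if (is.null(a)) stop("no timeline for task ", task, ", alignment ",
                       alignment)
  miss <- setdiff(electrode_ids, rownames(a$pct))
  if (length(miss)) {
    stop("electrode(s) absent from timelines: ",
         paste(head(miss, 5), collapse = ", "))
  }
  a$pct[electrode_ids, , drop = FALSE]
}

#' ROI-level bootstrap statistics and significance masks
#'
#' The group-level stage of the pipeline: for every admitted ROI, task and
#' alignment window, computes the across-electrode mean percent-change
#' timeline with studentized-bootstrap CI and the run-length-gated
#' augmentation/attenuation mask.
#'
#' @param timelines Pooled `hg_timelines` (electrodes from all patients).
#' @param electrodes Electrode table (`electrode_id`, `roi`).
#' @param spec A [boot_spec()]; set `spec$seed` for reproducibility.
#' @param min_n Minimum electrodes per ROI (default 9).
#' @return Object of class `"hg_roi_stats"`: long-format `table`
#'   (roi, task, alignment, bin_ms, mean, ci_lo, ci_hi, n, sig), nested
#'   `masks[[roi]][[task]][[alignment]]`, `bin_ms` per alignment, electrode
#'   counts, and the spec.
#' @export
roi_stats <- function(timelines, electrodes, spec = boot_spec(),
                      min_n = 9) {
  stopifnot(inherits(timelines, "hg_timelines"))
  groups <- roi_groups(electrodes, min_n)
  if (!length(groups)) stop("no ROI passes the electrode-count criterion")
  tasks <- names(timelines$tasks)
  aligns <- names(timelines$tasks[[1]]$alignments)
  rows <- list()
  masks <- list()
  seed_env <- new.env()
  run <- function() {
    for (roi in names(groups)) {
      masks[[roi]] <<- list()
      for (task in tasks) {
        masks[[roi]][[task]] <<- list()
        for (al in aligns) {
          x <- roi_matrix(timelines, groups[[roi]], task, al)
          bspec <- spec; bspec$seed <- NULL     # stream already seeded
          ci <- studentized_bootstrap_ci(x, bspec)
          sig <- detect_modulation(ci$lo, ci$hi, spec$min_run_ms,
                                   timelines$spec$step_ms)
          bin_ms <- timelines$tasks[[task]]$alignments[[al]]$bin_ms
          rows[[length(rows) + 1L]] <<- data.frame(
            roi = roi, task = task, alignment = al, bin_ms = bin_ms,
            mean = ci$mean, ci_lo = ci$lo, ci_hi = ci$hi, n = ci$n,
            sig = sig)
          masks[[roi]][[task]][[al]] <<- sig
        }
      }
    }
  }
  if (is.null(spec$seed)) run() else with_seed(spec$seed, run())
  structure(list(table = do.call(rbind, rows), masks = masks,
                 bin_ms = lapply(timelines$tasks[[1]]$alignments,
                                 `[[`, "bin_ms"),
                 n_electrodes = lengths(groups),
                 excluded_rois = attr(groups, "excluded"),
                 spec = spec),
            class = "hg_roi_stats")
}

#' Between-task contrast with studentized-bootstrap CI
#'
#' Bootstrap-t interval of the difference in mean percent change between two
#' electrode sets (independent resampling on each side), run-gated in both
#' directions.
#'
#' @param xa,xb Electrodes x bins matrices on a common bin grid.
#' @param spec A [boot_spec()].
#' @param min_n Minimum electrodes per side (default 9).
#' @param step_ms Bin spacing in ms (default 10).
#' @return List with per-bin `diff`, `lo`, `hi` and `mask` (`"a_greater"`,
#'   `"b_greater"` or `"none"`).
#' @export
task_contrast <- function(xa, xb, spec = boot_spec(), min_n = 9,
                          step_ms = 10) {
  stopifnot(ncol(xa) == ncol(xb))
  na <- nrow(xa); nb <- nrow(xb)
  if (na < min_n || nb < min_n) {
    stop("both sides need at least ", min_n, " electrodes (have ",
         na, " and ", nb, ")")
  }
  run <- function() {
    ma <- colMeans(xa); mb <- colMeans(xb)
    d <- ma - mb
    sea2 <- colSums(sweep(xa, 2, ma)^2) / (na - 1) / na
    seb2 <- colSums(sweep(xb, 2, mb)^2) / (nb - 1) / nb
    se_d <- sqrt(sea2 + seb2)
    ca <- resample_counts(na, spec$n_resamples, spec$max_retries)
    cb <- resample_counts(nb, spec$n_resamples, spec$max_retries)
    boot_m <- function(counts, x, n) {
      m1 <- crossprod(counts, x) / n
      m2 <- crossprod(counts, x^2) / n
      v <- pmax(m2 - m1^2, 0) * n / (n - 1)
      list(m = m1, se2 = v / n)
    }
    ba <- boot_m(ca, xa, na); bb <- boot_m(cb, xb, nb)
    d_star <- ba$m - bb$m
    se_star <- sqrt(ba$se2 + bb$se2)
    t_star <- sweep(d_star, 2, d) / se_star
    t_star[se_star == 0 & sweep(d_star, 2, d) == 0] <- 0
    alpha <- 1 - spec$ci_level
    lo <- hi <- d
    for (j in seq_along(d)) {
      if (se_d[j] == 0) next
      tj <- t_star[, j]; fin <- is.finite(tj)
      q <- quantile(tj[fin], c(alpha / 2, 1 - alpha / 2), names = FALSE)
      lo[j] <- d[j] - q[2] * se_d[j]
      hi[j] <- d[j] - q[1] * se_d[j]
    }
    min_bins <- ceiling(spec$min_run_ms / step_ms)
    mask <- rep("none", length(d))
    mask[gated_runs(!is.na(lo) & lo > 0, min_bins)] <- "a_greater"
    mask[gated_runs(!is.na(hi) & hi < 0, min_bins)] <- "b_greater"
    list(diff = d, lo = lo, hi = hi, mask = mask)
  }
  if (is.null(spec$seed)) run() else with_seed(spec$seed, run())
}
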