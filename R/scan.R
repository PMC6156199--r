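#' Detection thresholds for the sliding-window decRNA scan
#'
#' Defaults follow the published rule set: genes with a time-zero median
#' below 5 reads/nt are dropped; a 100-nt window slides in 1-nt steps; a
#' nucleotide is "elevated" when its coverage exceeds the trailing-window
#' mean by more than 4 standard deviations; elevated runs must exceed 40 nt;
#' segments need > 2-fold the gene median at time zero and at least a 3-fold
#' rise in relative abundance during the time course, in at least 2
#' replicates.
#'
#' @param min_gene_median_t0 Expression filter, raw reads/nt at t = 0.
#' @param window Trailing window length, nt.
#' @param step Scan step, nt.
#' @param sd_threshold Number of window SDs a nucleotide must exceed.
#' @param min_segment_len Minimum segment length, nt, exclusive (a run of
#'   exactly this length is rejected).
#' @param min_t0_fold Required fold over the gene median at t = 0 (strict).
#' @param min_stabilization_fold Required max fold rise in relative
#'   abundance over the time course (inclusive).
#' @param min_replicate_support Replicates a segment must appear in.
#' @param sd_floor Lower bound on the window SD, reads/nt; keeps the rule
#'   well defined when the window is constant (noise-free data).
#' @param expressed_rule How replicate t0 medians are aggregated for the
#'   expression filter: every replicate (`"all"`), any (`"any"`), or their
#'   mean (`"mean"`).
#' @param t0_fold_stat Segment summary used for the time-zero fold filter.
#' @param max_end_distance Maximum nt a boundary may be snapped to a mapped
#'   transcript end site.
#' @return List of class `detection_config`.
#' @export
detection_config <- function(min_gene_median_t0 = 5, window = 100, step = 1,
                             sd_threshold = 4, min_segment_len = 40,
                             min_t0_fold = 2, min_stabilization_fold = 3,
                             min_replicate_support = 2, sd_floor = 1,
                             expressed_rule = c("all", "any", "mean"),
                             t0_fold_stat = c("mean", "median"),
                             max_end_distance = 20) {
  expressed_rule <- match.arg(expressed_rule)
  t0_fold_stat <- match.arg(t0_fold_stat)
  if (min_gene_median_t0 < 0) stopf("min_gene_median_t0 must be >= 0")
  vals <- c(window, step, sd_threshold, min_segment_len,
            min_t0_fold, min_stabilization_fold, min_replicate_support,
            sd_floor)
  if (any(vals <= 0)) stopf("all detection thresholds must be > 0")
  if (window <= min_segment_len) {
    warnf("window (%d) is not larger than min_segment_len (%d)",
          window, min_segment_len)
  }
  structure(list(min_gene_median_t0 = min_gene_median_t0,
                 window = as.integer(window), step = as.integer(step),
                 sd_threshold = sd_threshold,
                 min_segment_len = as.integer(min_segment_len),
                 min_t0_fold = min_t0_fold,
                 min_stabilization_fold = min_stabilization_fold,
                 min_replicate_support = as.integer(min_replicate_support),
                 sd_floor = sd_floor, expressed_rule = expressed_rule,
                 t0_fold_stat = t0_fold_stat,
                 max_end_distance = as.integer(max_end_distance)),
            class = "detection_config")
}

rolling_window_stats <- function(values, window) {
  # mean/SD of the `window` values immediately before each position;
  # entry i describes positions (i-window)..(i-1), defined for i > window
  n <- length(values)
  cs <- cumsum(c(0, values))
  cs2 <- cumsum(c(0, values^2))
  i <- seq_len(n)
  # cs[k+1] = sum(values[1..k]); window for position i is (i-window)..(i-1)
  s <- cs[i] - cs[pmax(i - window, 1)]
  s2 <- cs2[i] - cs2[pmax(i - window, 1)]
  m <- s / window
  v <- pmax((s2 - s^2 / window) / (window - 1), 0)
  m[i <= window] <- NA_real_
  v[i <= window] <- NA_real_
  list(mean = m, sd = sqrt(v))
}

#' Flag nucleotides elevated above their trailing window
#'
#' Position `p` (in 5'-to-3' orientation) is elevated when
#' `value[p] > mean_w + sd_threshold * max(sd_w, sd_floor)`, with `mean_w`
#' and `sd_w` computed over the `window` nucleotides immediately 5' of `p`.
#' Positions without a full trailing window are never flagged. This is the
#' per-position comparison of the sliding-window rule; run formation is in
#' [scan_gene()].
#'
#' @param values Coverage values in gene (5'-to-3') orientation.
#' @param config A [detection_config()].
#' @return Logical vector the length of `values`.
#' @export
elevated_positions <- function(values, config = detection_config()) {
  n <- length(values)
  out <- rep(FALSE, n)
  if (n <= config$window) return(out)
  st <- rolling_window_stats(values, config$window)
  idx <- seq(config$window + 1L, n, by = config$step)
  thr <- st$mean[idx] + config$sd_threshold * pmax(st$sd[idx], config$sd_floor)
  out[idx] <- values[idx] > thr
  out
}

scan_oriented <- function(values, config) {
  # runs of elevated coverage: a run opens where the per-position rule
  # fires, and extends while coverage stays above the threshold frozen from
  # the last fully pre-run window (re-computing the window inside the run
  # would inflate the SD with the run's own values and clip every plateau)
  n <- length(values)
  if (n <= config$window) return(NULL)
  st <- rolling_window_stats(values, config$window)
  thr <- st$mean + config$sd_threshold * pmax(st$sd, config$sd_floor)
  runs <- list(); nr <- 0L
  p <- config$window + 1L
  in_run <- FALSE; run_start <- NA_integer_; frozen <- NA_real_
  while (p <= n) {
    if (!in_run) {
      if (!is.na(thr[p]) && values[p] > thr[p]) {
        in_run <- TRUE; run_start <- p; frozen <- thr[p]
      }
      p <- p + 1L
    } else {
      if (values[p] > frozen) {
        p <- p + 1L
      } else {
        nr <- nr + 1L; runs[[nr]] <- c(run_start, p - 1L)
        in_run <- FALSE
        # p is re-examined as a fresh position against its own window
      }
    }
  }
  if (in_run) { nr <- nr + 1L; runs[[nr]] <- c(run_start, n) }
  if (!nr) return(NULL)
  do.call(rbind, runs)
}

#' Scan one gene for stabilized-segment candidates in one track
#'
#' Applies the trailing-window rule in gene orientation (for minus-strand
#' genes the footprint is reversed so the window still trails the 5' side)
#' and returns maximal elevated runs strictly longer than
#' `min_segment_len`, as genomic 0-based half-open intervals.
#'
#' @param track A raw [coverage_track()] on the gene's strand.
#' @param gene One-row gene model data frame.
#' @param config A [detection_config()].
#' @return Data frame with columns `start`, `end` (possibly 0 rows).
#' @export
scan_gene <- function(track, gene, config = detection_config()) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$strand != gene$strand) {
    stopf("track strand (%s) does not match gene %s strand (%s)",
          track$strand, gene$id, gene$strand)
  }
  v <- track_slice(track, gene$start, gene$end)
  if (length(v) <= config$window) {
    warnf("gene %s footprint (%d nt) not longer than window (%d nt)",
          gene$id, length(v), config$window)
    return(data.frame(start = integer(), end = integer()))
  }
  if (gene$strand == "-") v <- rev(v)
  runs <- scan_oriented(v, config)
  if (is.null(runs)) return(data.frame(start = integer(), end = integer()))
  len <- runs[, 2] - runs[, 1] + 1L
  runs <- runs[len > config$min_segment_len, , drop = FALSE]
  if (!nrow(runs)) return(data.frame(start = integer(), end = integer()))
  if (gene$strand == "+") {
    out <- data.frame(start = gene$start + runs[, 1] - 1L,
                      end = gene$start + runs[, 2])
  } else {
    out <- data.frame(start = gene$end - runs[, 2],
                      end = gene$end - runs[, 1] + 1L)
  }
  out[order(out$start), , drop = FALSE]
}
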