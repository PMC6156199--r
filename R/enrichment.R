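#' Thresholds for Hfq/ProQ interaction calling
#'
#' @param hfq_min_mean_coverage Raw mean reads/nt over the decRNA in the
#'   Hfq IP track above which an Hfq interaction is called (strict).
#' @param proq_min_mean_coverage Raw mean reads/nt in the ProQ-3xFLAG IP
#'   track required for a ProQ call (strict).
#' @param proq_min_enrichment Required (FLAG IP/lysate)/(WT IP/lysate)
#'   double ratio (strict).
#' @param pseudocount Added to normalized means in the ProQ ratios so zero
#'   lysate coverage cannot produce infinite enrichment; in RPM units.
#' @return List of class `enrichment_config`.
#' @export
enrichment_config <- function(hfq_min_mean_coverage = 30,
                              proq_min_mean_coverage = 20,
                              proq_min_enrichment = 2, pseudocount = 0.1) {
  if (any(c(hfq_min_mean_coverage, proq_min_mean_coverage,
            proq_min_enrichment, pseudocount) <= 0)) {
    stopf("all enrichment thresholds must be > 0")
  }
  structure(list(hfq_min_mean_coverage = hfq_min_mean_coverage,
                 proq_min_mean_coverage = proq_min_mean_coverage,
                 proq_min_enrichment = proq_min_enrichment,
                 pseudocount = pseudocount),
            class = "enrichment_config")
}

#' decRNA-to-host expression ratio
#'
#' Mean coverage over the call interval divided by the median coverage
#' over the host gene footprint, on a library-size-normalized track. The
#' quantity whose WT-versus-RNase-E-mutant distribution shift demonstrates
#' RNase E dependence.
#'
#' @param track A normalized [coverage_track()] on the call strand.
#' @param call One-row call data frame (needs `id`, `start`, `end`).
#' @param gene One-row host gene model.
#' @param condition Optional label (`"wt"`/`"mutant"`) carried in the record.
#' @return List with `decrna_id`, `ratio`, `condition`.
#' @export
decrna_host_ratio <- function(track, call, gene, condition = NA_character_) {
  med <- gene_median_coverage(track, gene)
  if (med <= 0) stopf("host gene %s has zero median coverage (host_median_zero)",
                      gene$id)
  ratio <- interval_mean(track, call$start, call$end) / med
  list(decrna_id = call$id, ratio = ratio, condition = condition)
}

#' Compare decRNA/host ratios between WT and RNase E mutant
#'
#' An unpaired two-sided Wilcoxon rank-sum test between the two ratio
#' distributions (a paired test is available via `paired = TRUE`, which
#' tests the signed differences against a symmetric null by rank-sum of
#' positive versus negative magnitudes).
#'
#' @param wt_ratios,mutant_ratios Numeric vectors, or lists/data frames
#'   with a `ratio` field, each of length >= 2.
#' @param paired Use a Wilcoxon signed-rank test on per-decRNA differences
#'   (delegated to [stats::wilcox.test()]) instead of the default unpaired
#'   rank-sum comparison of the two distributions.
#' @return List with `p_value`, `statistic`, `wt_median`, `mutant_median`.
#' @export
compare_rnase_dependence <- function(wt_ratios, mutant_ratios, paired = FALSE) {
  get_ratio <- function(x) {
    if (is.numeric(x)) return(x)
    if (is.data.frame(x)) return(as.numeric(x$ratio))
    vapply(x, function(r) as.numeric(r$ratio %||% r), numeric(1))
  }
  wt <- get_ratio(wt_ratios); mut <- get_ratio(mutant_ratios)
  if (length(wt) < 2 || length(mut) < 2) {
    stopf("need at least 2 ratio records per condition")
  }
  if (paired) {
    if (length(wt) != length(mut)) stopf("paired test needs equal lengths")
    wt_t <- suppressWarnings(stats::wilcox.test(wt, mut, paired = TRUE))
    res <- list(statistic = unname(wt_t$statistic), p_value = wt_t$p.value)
  } else {
    res <- wilcoxon_rank_sum(wt, mut)
  }
  list(p_value = res$p_value, statistic = res$statistic,
       wt_median = median(wt), mutant_median = median(mut))
}

#' Hfq interaction call for one decRNA
#'
#' Mean raw reads/nt over the call interval in the Hfq IP track; the call
#' is positive when the mean strictly exceeds the configured threshold
#' (the rule is an absolute coverage cut, so the track must be raw).
#'
#' @param ip_track Raw [coverage_track()] (Hfq IP) on the call strand.
#' @param call One-row call data frame.
#' @param config An [enrichment_config()].
#' @return List with `mean_coverage` and `call`.
#' @export
hfq_call <- function(ip_track, call, config = enrichment_config()) {
  if (ip_track$normalized) {
    warnf("Hfq rule is an absolute reads/nt cut; got a normalized track")
  }
  m <- interval_mean(ip_track, call$start, call$end)
  list(mean_coverage = m, call = m > config$hfq_min_mean_coverage)
}

norm_mean <- function(track, start, end) {
  interval_mean(track, start, end) *
    (if (track$normalized) 1 else 1e6 / track$library_total)
}

#' ProQ double-ratio enrichment for one decRNA
#'
#' On library-size-normalized means with a pseudocount: the IP/lysate
#' signal ratio is computed separately for the ProQ-3xFLAG and the WT-ProQ
#' (mock) experiments, and the enrichment is their ratio. The call requires
#' raw FLAG-IP mean coverage above `proq_min_mean_coverage` and enrichment
#' above `proq_min_enrichment` (both strict).
#'
#' @param ip_flag,lysate_flag,ip_wt,lysate_wt [coverage_track()]s on the
#'   call strand, with library totals.
#' @param call One-row call data frame.
#' @param config An [enrichment_config()].
#' @return List with `mean_coverage` (raw FLAG IP), `ratio_flag`,
#'   `ratio_wt`, `enrichment`, `call`.
#' @export
proq_enrichment <- function(ip_flag, lysate_flag, ip_wt, lysate_wt, call,
                            config = enrichment_config()) {
  pc <- config$pseudocount
  r_flag <- (norm_mean(ip_flag, call$start, call$end) + pc) /
    (norm_mean(lysate_flag, call$start, call$end) + pc)
  r_wt <- (norm_mean(ip_wt, call$start, call$end) + pc) /
    (norm_mean(lysate_wt, call$start, call$end) + pc)
  enr <- r_flag / r_wt
  raw_mean <- interval_mean(ip_flag, call$start, call$end) *
    (if (ip_flag$normalized) ip_flag$library_total / 1e6 else 1)
  list(mean_coverage = raw_mean, ratio_flag = r_flag, ratio_wt = r_wt,
       enrichment = enr,
       call = raw_mean > config$proq_min_mean_coverage &&
         enr > config$proq_min_enrichment)
}

pick_strand <- function(x, strand) {
  if (inherits(x, "coverage_track")) {
    if (x$strand != strand) stopf("track strand %s does not match call strand %s",
                                  x$strand, strand)
    return(x)
  }
  x[[strand]]
}

#' Score all decRNA calls for Hfq and ProQ interactions
#'
#' One row per call; assays not supplied yield `NA` fields, never false
#' calls. `hfq_ip` and each element of `proq` may be a single
#' [coverage_track()] or a list with `"+"`/`"-"` tracks.
#'
#' @param calls decRNA call data frame from [detect_decrnas()].
#' @param hfq_ip Optional raw Hfq IP coverage.
#' @param proq Optional list with `ip_flag`, `lysate_flag`, `ip_wt`,
#'   `lysate_wt`.
#' @param config An [enrichment_config()].
#' @return Data frame with `decrna_id`, `hfq_mean_coverage`, `hfq_call`,
#'   `proq_mean_coverage`, `proq_enrichment`, `proq_call`.
#' @export
annotate_enrichment <- function(calls, hfq_ip = NULL, proq = NULL,
                                config = enrichment_config()) {
  if (is.null(hfq_ip) && is.null(proq)) stopf("no enrichment data supplied")
  out <- lapply(seq_len(nrow(calls)), function(k) {
    cl <- calls[k, ]
    hm <- hc <- pm <- pe <- NA
    if (!is.null(hfq_ip)) {
      h <- hfq_call(pick_strand(hfq_ip, cl$strand), cl, config)
      hm <- h$mean_coverage; hc <- h$call
    }
    pc <- NA
    if (!is.null(proq)) {
      p <- proq_enrichment(pick_strand(proq$ip_flag, cl$strand),
                           pick_strand(proq$lysate_flag, cl$strand),
                           pick_strand(proq$ip_wt, cl$strand),
                           pick_strand(proq$lysate_wt, cl$strand), cl, config)
      pm <- p$mean_coverage; pe <- p$enrichment; pc <- p$call
    }
    data.frame(decrna_id = cl$id, hfq_mean_coverage = as.numeric(hm),
               hfq_call = as.logical(hc), proq_mean_coverage = as.numeric(pm),
               proq_enrichment = as.numeric(pe), proq_call = as.logical(pc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
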