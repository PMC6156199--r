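#' Gene models: CDS plus optional UTR extents
#'
#' A gene model records the CDS interval and optional 5'/3'UTR lengths; the
#' scanning footprint is the contiguous union UTR5 + CDS + UTR3. Gene models
#' are kept as rows of an ordinary data frame so sets of genes behave like
#' annotation tables. All coordinates are 0-based half-open.
#'
#' @param id Gene identifier.
#' @param cds_start,cds_end CDS interval, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @param utr5_len,utr3_len UTR lengths in nt (0 = no mapped UTR).
#' @param replicon_id Replicon name.
#' @return One-row data frame with columns `id`, `replicon_id`, `strand`,
#'   `start`, `end` (footprint), `cds_start`, `cds_end`, `utr5_len`,
#'   `utr3_len`.
#' @export
gene_model <- function(id, cds_start, cds_end, strand,
                       utr5_len = 0L, utr3_len = 0L, replicon_id = "chr") {
  strand <- match.arg(strand, c("+", "-"))
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  utr5_len <- as.integer(utr5_len); utr3_len <- as.integer(utr3_len)
  if (cds_end <= cds_start) stopf("gene %s: CDS must have positive length", id)
  if (utr5_len < 0 || utr3_len < 0) stopf("gene %s: UTR lengths must be >= 0", id)
  if (strand == "+") {
    start <- cds_start - utr5_len; end <- cds_end + utr3_len
  } else {
    start <- cds_start - utr3_len; end <- cds_end + utr5_len
  }
  if (start < 0) stopf("gene %s: footprint extends below position 0", id)
  data.frame(id = as.character(id), replicon_id = as.character(replicon_id),
             strand = strand, start = start, end = end,
             cds_start = cds_start, cds_end = cds_end,
             utr5_len = utr5_len, utr3_len = utr3_len,
             stringsAsFactors = FALSE)
}

#' Footprint length of a gene model row
#' @param gene One-row gene model data frame.
#' @export
gene_footprint_length <- function(gene) gene$end - gene$start

#' Median coverage over a gene footprint
#'
#' The per-gene summary the expression filter and all relative-abundance
#' ratios are built on: the median of per-nucleotide values over the entire
#' footprint, UTRs included. Even-length medians are the mean of the two
#' central order statistics (the [stats::median()] convention).
#'
#' @param track A [coverage_track()].
#' @param gene One-row gene model data frame.
#' @return Median reads/nt (or RPM for a normalized track).
#' @export
gene_median_coverage <- function(track, gene) {
  if (gene_footprint_length(gene) <= 0) stopf("gene %s has zero-length footprint", gene$id)
  stats::median(track_slice(track, gene$start, gene$end))
}
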