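#' Expression filter on time-zero coverage
#'
#' Drops genes whose time-zero footprint median falls below
#' `min_gene_median_t0` raw reads/nt. By default the threshold must hold in
#' every replicate; `expressed_rule` in the config switches to "any
#' replicate" or "mean of replicates".
#'
#' @param tracks_t0 List over replicates; each element is a list with `"+"`
#'   and `"-"` raw [coverage_track()]s at t = 0.
#' @param genes Gene model data frame.
#' @param config A [detection_config()].
#' @return The subset of `genes` passing the filter.
#' @export
filter_expressed <- function(tracks_t0, genes, config = detection_config()) {
  if (!nrow(genes)) return(genes)
  keep <- vapply(seq_len(nrow(genes)), function(k) {
    g <- genes[k, ]
    med <- vapply(tracks_t0, function(rep_tracks)
      gene_median_coverage(rep_tracks[[g$strand]], g), numeric(1))
    switch(config$expressed_rule,
           all = all(med >= config$min_gene_median_t0),
           any = any(med >= config$min_gene_median_t0),
           mean = mean(med) >= config$min_gene_median_t0)
  }, logical(1))
  genes[keep, , drop = FALSE]
}

#' Apply the time-zero fold and stabilization filters to scan candidates
#'
#' On library-size-normalized tracks of one replicate: a candidate is kept
#' when (a) its segment summary at t = 0 exceeds `min_t0_fold` times the
#' gene median at t = 0 (strict), and (b) its relative abundance --
#' segment mean over gene median -- rises at least
#' `min_stabilization_fold`-fold over its t = 0 value at some later
#' timepoint. Later timepoints where the gene median is 0 are skipped
#' rather than treated as infinite stabilization.
#'
#' @param candidates Data frame of `start`/`end` intervals from the scan.
#' @param norm_tracks List over timepoints of normalized strand-track pairs
#'   for one replicate.
#' @param gene One-row gene model data frame.
#' @param config A [detection_config()].
#' @return Candidates that pass, with `mean_t0`, `t0_fold` and
#'   `stabilization_fold` columns added.
#' @export
filter_candidates <- function(candidates, norm_tracks, gene,
                              config = detection_config()) {
  empty <- data.frame(start = integer(), end = integer(),
                      mean_t0 = numeric(), t0_fold = numeric(),
                      stabilization_fold = numeric())
  if (!nrow(candidates)) return(empty)
  med <- vapply(norm_tracks, function(tp)
    gene_median_coverage(tp[[gene$strand]], gene), numeric(1))
  keep <- logical(nrow(candidates))
  mean_t0 <- t0_fold <- stab <- numeric(nrow(candidates))
  for (k in seq_len(nrow(candidates))) {
    s <- candidates$start[k]; e <- candidates$end[k]
    segmean <- vapply(norm_tracks, function(tp)
      interval_mean(tp[[gene$strand]], s, e), numeric(1))
    if (med[1] <= 0) next  # gene median 0 at t0: candidate rejected
    seg0 <- if (config$t0_fold_stat == "mean") segmean[1] else {
      stats::median(track_slice(norm_tracks[[1]][[gene$strand]], s, e))
    }
    mean_t0[k] <- segmean[1]
    t0_fold[k] <- seg0 / med[1]
    rel <- segmean / med
    later <- which(seq_along(rel) > 1 & med > 0)
    if (!length(later) || !is.finite(rel[1]) || rel[1] <= 0) next
    stab[k] <- max(rel[later] / rel[1])
    keep[k] <- t0_fold[k] > config$min_t0_fold &&
      stab[k] >= config$min_stabilization_fold
  }
  out <- candidates[keep, , drop = FALSE]
  if (!nrow(out)) return(empty)
  out$mean_t0 <- mean_t0[keep]
  out$t0_fold <- t0_fold[keep]
  out$stabilization_fold <- stab[keep]
  out
}

#' Intersect candidate segments across replicates
#'
#' Candidates from different replicates of the same gene are grouped by
#' single-linkage genomic overlap (>= 1 nt); a group supported by at least
#' `min_replicate_support` distinct replicates yields one consensus
#' interval, the intersection of its members, which must still exceed
#' `min_segment_len`.
#'
#' @param per_replicate_candidates List (one element per replicate) of
#'   candidate data frames with `start`/`end`.
#' @param config A [detection_config()].
#' @return Data frame `start`, `end`, `n_replicates_support`, `replicates`
#'   (comma-separated), `t0_fold`, `stabilization_fold` (medians over
#'   supporting members when present).
#' @export
intersect_replicates <- function(per_replicate_candidates,
                                 config = detection_config()) {
  empty <- data.frame(start = integer(), end = integer(),
                      n_replicates_support = integer(),
                      replicates = character(),
                      t0_fold = numeric(), stabilization_fold = numeric(),
                      stringsAsFactors = FALSE)
  all <- list()
  for (r in seq_along(per_replicate_candidates)) {
    cc <- per_replicate_candidates[[r]]
    if (!is.null(cc) && nrow(cc)) {
      cc$replicate <- r
      all[[length(all) + 1L]] <- cc
    }
  }
  if (!length(all)) return(empty)
  cand <- do.call(rbind, lapply(all, function(d) {
    d[, intersect(c("start", "end", "replicate", "t0_fold",
                    "stabilization_fold"), names(d)), drop = FALSE]
  }))
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  # single-linkage chains of overlapping intervals
  grp <- integer(nrow(cand)); gid <- 0L; chain_end <- -Inf
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] >= chain_end) {
      gid <- gid + 1L
      chain_end <- cand$end[i]
    } else {
      chain_end <- max(chain_end, cand$end[i])
    }
    grp[i] <- gid
  }
  rows <- list()
  for (g in unique(grp)) {
    m <- cand[grp == g, , drop = FALSE]
    reps <- sort(unique(m$replicate))
    if (length(reps) < config$min_replicate_support) next
    s <- max(m$start); e <- min(m$end)
    if (e - s <= config$min_segment_len) next
    rows[[length(rows) + 1L]] <- data.frame(
      start = s, end = e, n_replicates_support = length(reps),
      replicates = paste(reps, collapse = ","),
      t0_fold = if ("t0_fold" %in% names(m)) stats::median(m$t0_fold) else NA_real_,
      stabilization_fold = if ("stabilization_fold" %in% names(m))
        stats::median(m$stabilization_fold) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Snap call boundaries to mapped transcript end sites
#'
#' The segment's 5' boundary (in gene orientation) snaps to the nearest
#' `five_prime` end site within `max_distance` nt on the same strand, and
#' the 3' boundary to the nearest `three_prime` site; otherwise boundaries
#' are left as scanned. A snap that would invert the interval or shrink it
#' to `min_segment_len` or below is refused with a warning.
#'
#' @param start,end Call interval, 0-based half-open.
#' @param strand Call strand.
#' @param end_sites End-site data frame (see [read_end_sites()]).
#' @param max_distance Maximum snap distance, nt.
#' @param min_segment_len Minimum surviving length, nt (exclusive).
#' @return List with `start`, `end`, `boundary_corrected`.
#' @export
correct_boundaries <- function(start, end, strand, end_sites,
                               max_distance = 20, min_segment_len = 40) {
  res <- list(start = start, end = end, boundary_corrected = FALSE)
  if (is.null(end_sites) || !nrow(end_sites)) return(res)
  es <- end_sites[end_sites$strand == strand, , drop = FALSE]
  if (!nrow(es)) return(res)
  snap <- function(target, kind) {
    cand <- es$position[es$kind == kind]
    if (!length(cand)) return(NA_integer_)
    d <- abs(cand - target)
    if (min(d) > max_distance) return(NA_integer_)
    cand[which.min(d)]
  }
  if (strand == "+") {
    # 5' terminus at `start`, 3' terminus at `end - 1`
    s5 <- snap(start, "five_prime")
    s3 <- snap(end - 1L, "three_prime")
    new_start <- if (!is.na(s5)) s5 else start
    new_end <- if (!is.na(s3)) s3 + 1L else end
  } else {
    # 5' terminus at `end - 1`, 3' terminus at `start`
    s5 <- snap(end - 1L, "five_prime")
    s3 <- snap(start, "three_prime")
    new_start <- if (!is.na(s3)) s3 else start
    new_end <- if (!is.na(s5)) s5 + 1L else end
  }
  moved <- (new_start != start) || (new_end != end)
  if (!moved) return(res)
  if (new_end - new_start <= min_segment_len) {
    warnf("boundary correction to [%d, %d) refused: interval too short",
          new_start, new_end)
    return(res)
  }
  list(start = new_start, end = new_end, boundary_corrected = TRUE)
}

#' CDS-overlap fraction and category of a call interval
#'
#' The fraction of the call lying within the host CDS defines three
#' classes: `within_cds` (fraction 1), `cds_majority` (> 0.5), and
#' `utr_majority` otherwise.
#'
#' @param start,end Call interval, 0-based half-open.
#' @param gene One-row gene model data frame.
#' @return List with `cds_overlap_fraction` and `category`.
#' @export
classify_overlap <- function(start, end, gene) {
  ov <- max(0, min(end, gene$cds_end) - max(start, gene$cds_start))
  frac <- ov / (end - start)
  category <- if (frac == 1) "within_cds"
  else if (frac > 0.5) "cds_majority"
  else "utr_majority"
  list(cds_overlap_fraction = frac, category = category)
}

extract_rna <- function(genome, replicon_id, start, end, strand) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  seq <- Biostrings::subseq(genome[[replicon_id]], start + 1L, end)
  if (strand == "-") seq <- Biostrings::reverseComplement(seq)
  as.character(Biostrings::RNAString(seq))
}

normalize_experiment <- function(experiment) {
  lapply(experiment$tracks, function(rep_tracks)
    lapply(rep_tracks, function(tp) lapply(tp, normalize_by_library_size)))
}

#' Detect decay-generated noncoding RNAs
#'
#' The full pipeline: expression filter on raw t = 0 medians; per replicate,
#' the sliding-window scan over every timepoint's raw track with
#' union-merging of per-timepoint runs (so segments whose elevation only
#' emerges during decay are caught); the time-zero fold and stabilization
#' filters on library-size-normalized tracks; replicate intersection;
#' optional boundary correction against mapped end sites; CDS-overlap
#' classification; and RNA sequence extraction from the genome on the gene
#' strand.
#'
#' @param experiment A `decay_experiment` (raw tracks).
#' @param genes Gene model data frame.
#' @param genome Named character vector or [Biostrings::DNAStringSet];
#'   `NULL` skips sequence extraction.
#' @param config A [detection_config()].
#' @param end_sites Optional end-site data frame for boundary correction.
#' @return Data frame of calls sorted by coordinate: `id`, `host_gene`,
#'   `replicon_id`, `strand`, `start`, `end`, `length`,
#'   `n_replicates_support`, `replicates`, `t0_fold`, `stabilization_fold`,
#'   `cds_overlap_fraction`, `category`, `boundary_corrected`, `sequence`.
#' @export
detect_decrnas <- function(experiment, genes, genome = NULL,
                           config = detection_config(), end_sites = NULL) {
  empty <- data.frame(id = character(), host_gene = character(),
                      replicon_id = character(), strand = character(),
                      start = integer(), end = integer(), length = integer(),
                      n_replicates_support = integer(), replicates = character(),
                      t0_fold = numeric(), stabilization_fold = numeric(),
                      cds_overlap_fraction = numeric(), category = character(),
                      boundary_corrected = logical(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(genes)) return(empty)
  tracks_t0 <- lapply(experiment$tracks, function(r) r[[1]])
  expressed <- filter_expressed(tracks_t0, genes, config)
  if (!nrow(expressed)) return(empty)
  norm <- normalize_experiment(experiment)
  rows <- list()
  for (k in seq_len(nrow(expressed))) {
    g <- expressed[k, ]
    if (gene_footprint_length(g) <= config$window) next
    per_rep <- vector("list", experiment$n_replicates)
    for (r in seq_len(experiment$n_replicates)) {
      ivs <- lapply(seq_along(experiment$timepoints), function(ti)
        scan_gene(get_track(experiment, r, ti, g$strand), g, config))
      ivs <- do.call(rbind, ivs)
      merged <- merge_intervals(ivs)
      per_rep[[r]] <- filter_candidates(merged, norm[[r]], g, config)
    }
    consensus <- intersect_replicates(per_rep, config)
    if (!nrow(consensus)) next
    for (j in seq_len(nrow(consensus))) {
      cc <- consensus[j, ]
      bc <- correct_boundaries(cc$start, cc$end, g$strand, end_sites,
                               config$max_end_distance, config$min_segment_len)
      ov <- classify_overlap(bc$start, bc$end, g)
      seq <- if (is.null(genome)) NA_character_ else {
        extract_rna(genome, g$replicon_id, bc$start, bc$end, g$strand)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("%s.dec%d", g$id, j), host_gene = g$id,
        replicon_id = g$replicon_id, strand = g$strand,
        start = bc$start, end = bc$end, length = bc$end - bc$start,
        n_replicates_support = cc$n_replicates_support,
        replicates = cc$replicates, t0_fold = cc$t0_fold,
        stabilization_fold = cc$stabilization_fold,
        cds_overlap_fraction = ov$cds_overlap_fraction,
        category = ov$category, boundary_corrected = bc$boundary_corrected,
        sequence = seq, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  calls <- do.call(rbind, rows)
  calls <- dedupe_calls(calls)
  calls <- calls[order(calls$start, calls$end), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

# union-merge overlapping intervals (single data frame of start/end)
merge_intervals <- function(ivs) {
  if (is.null(ivs) || !nrow(ivs)) {
    return(data.frame(start = integer(), end = integer()))
  }
  ivs <- ivs[order(ivs$start, ivs$end), , drop = FALSE]
  out_s <- ivs$start[1]; out_e <- ivs$end[1]
  res <- list()
  for (i in seq_len(nrow(ivs))[-1]) {
    if (ivs$start[i] <= out_e) {
      out_e <- max(out_e, ivs$end[i])
    } else {
      res[[length(res) + 1L]] <- c(out_s, out_e)
      out_s <- ivs$start[i]; out_e <- ivs$end[i]
    }
  }
  res[[length(res) + 1L]] <- c(out_s, out_e)
  m <- do.call(rbind, res)
  data.frame(start = m[, 1], end = m[, 2])
}

# identical-coordinate calls from overlapping gene footprints keep the host
# with the larger CDS overlap
dedupe_calls <- function(calls) {
  key <- paste(calls$replicon_id, calls$strand, calls$start, calls$end)
  if (!anyDuplicated(key)) return(calls)
  keep <- unlist(lapply(split(seq_len(nrow(calls)), key), function(idx) {
    idx[which.max(calls$cds_overlap_fraction[idx])]
  }), use.names = FALSE)
  calls[sort(keep), , drop = FALSE]
}
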