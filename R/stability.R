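#' Configuration for the fold-stability comparison
#'
#' @param n_random Number of random genomic segments to sample (the
#'   published comparison used 10,000).
#' @param seed RNG seed for segment sampling.
#' @param exclude Optional data frame of intervals (`start`, `end`) to
#'   reject when sampling random segments (e.g. the called decRNAs
#'   themselves); `NULL` samples genome-wide.
#' @return List of class `stability_config`.
#' @export
stability_config <- function(n_random = 10000, seed = 1, exclude = NULL) {
  if (n_random <= 0) stopf("n_random must be > 0")
  structure(list(n_random = as.integer(n_random), seed = as.integer(seed),
                 exclude = exclude),
            class = "stability_config")
}

per_nt_records <- function(seqs, set, engine) {
  ids <- names(seqs) %||% sprintf("%s_%d", set, seq_along(seqs))
  if (is.null(names(seqs))) names(seqs) <- ids
  energy <- vapply(seqs, function(s) fold_energy(s, engine), numeric(1))
  len <- nchar(seqs)
  data.frame(set = set, id = ids, length = as.integer(len),
             energy = energy, per_nt = energy / len,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare fold stability of decRNAs, known ncRNAs, and random segments
#'
#' Computes per-nucleotide fold stability (kcal/mol/nt) for the called
#' decRNAs, an optional set of known intergenic ncRNAs, and `n_random`
#' random genomic segments whose lengths are drawn from the pooled length
#' distribution of the supplied real sets. Distributions are compared with
#' the two-sided Wilcoxon rank-sum test ([wilcoxon_rank_sum()]).
#'
#' @param decrna_seqs Named character vector of decRNA RNA sequences.
#' @param known_ncrna_seqs Optional named character vector of known ncRNA
#'   sequences (`NULL` skips that comparison).
#' @param genome Genome for random sampling (character or `DNAStringSet`).
#' @param config A [stability_config()].
#' @param engine Folding engine selector or object (one engine per run).
#' @return List of class `stability_comparison`: `records` (long data frame
#'   of set/id/length/energy/per_nt), `p_vs_random`, `p_vs_known`,
#'   `engine`, `n_random`.
#' @export
compare_stability <- function(decrna_seqs, known_ncrna_seqs = NULL, genome,
                              config = stability_config(),
                              engine = folding_engine("auto")) {
  if (!length(decrna_seqs)) stopf("decRNA set must be non-empty")
  engine <- folding_engine(engine)
  records <- per_nt_records(decrna_seqs, "decRNA", engine)
  if (!is.null(known_ncrna_seqs) && length(known_ncrna_seqs)) {
    records <- rbind(records, per_nt_records(known_ncrna_seqs, "known_ncRNA", engine))
  }
  pool <- records$length
  rand <- sample_random_segments(genome, pool, config$n_random, config$seed,
                                 exclude = config$exclude)
  records <- rbind(records, per_nt_records(rand, "random", engine))
  dec <- records$per_nt[records$set == "decRNA"]
  rnd <- records$per_nt[records$set == "random"]
  p_rand <- wilcoxon_rank_sum(dec, rnd)$p_value
  p_known <- if (any(records$set == "known_ncRNA")) {
    wilcoxon_rank_sum(dec, records$per_nt[records$set == "known_ncRNA"])$p_value
  } else NA_real_
  structure(list(records = records, p_vs_random = p_rand,
                 p_vs_known = p_known, engine = engine$name,
                 n_random = config$n_random),
            class = "stability_comparison")
}

#' @export
print.stability_comparison <- function(x, ...) {
  med <- tapply(x$records$per_nt, x$records$set, stats::median)
  cat("<stability_comparison>\n")
  for (s in names(med)) {
    cat(sprintf("  %-12s n=%5d  median %.3f kcal/mol/nt\n", s,
                sum(x$records$set == s), med[[s]]))
  }
  cat(sprintf("  decRNA vs random p = %.3g; vs known p = %.3g (engine: %s)\n",
              x$p_vs_random, x$p_vs_known, x$engine))
  invisible(x)
}
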