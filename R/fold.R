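#' RNA folding engines
#'
#' Fold-stability scoring is pluggable. The `"builtin"` engine is a
#' deterministic base-pair-maximization model with a stacking bonus
#' (GC -3, AU -2, GU -1, each stacked pair -1 kcal/mol, minimum hairpin
#' loop 3 nt, no pseudoknots), solved exactly by dynamic programming in
#' compiled code -- a documented simplification of the thermodynamic
#' nearest-neighbor model. The `"vienna"` engine shells out to ViennaRNA's
#' `RNAfold` (37 degrees C defaults) when it is on the PATH. `"auto"`
#' prefers `vienna` and falls back to `builtin`. All comparative statistics
#' should use one engine per run.
#'
#' @param engine `"auto"`, `"builtin"`, or `"vienna"`, or an engine object.
#' @return A `folding_engine` object with fields `name` and `fold`.
#' @export
folding_engine <- function(engine = c("auto", "builtin", "vienna")) {
  if (inherits(engine, "folding_engine")) return(engine)
  engine <- match.arg(engine)
  if (engine == "auto") {
    engine <- if (nzchar(Sys.which("RNAfold"))) "vienna" else "builtin"
  }
  if (engine == "vienna" && !nzchar(Sys.which("RNAfold"))) {
    stopf("RNAfold not found on PATH; use the builtin engine")
  }
  fold <- switch(engine,
                 builtin = function(seq) fold_mfe_cpp(seq),
                 vienna = fold_vienna)
  structure(list(name = engine, fold = fold), class = "folding_engine")
}

fold_vienna <- function(seq) {
  out <- system2("RNAfold", c("--noPS"), input = seq, stdout = TRUE)
  m <- regmatches(out[2], regexec("\\(\\s*(-?[0-9.]+)\\)\\s*$", out[2]))[[1]]
  if (length(m) < 2) stopf("could not parse RNAfold output")
  as.numeric(m[2])
}

normalize_rna <- function(seq) {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stopf("sequence must be a single non-empty string")
  }
  seq <- chartr("acgutT", "ACGUUU", seq)
  if (grepl("[^ACGU]", seq)) stopf("sequence contains non-ACGU characters")
  seq
}

#' Minimum free energy of an RNA sequence
#'
#' @param seq RNA sequence (A/C/G/U; case-insensitive, T read as U).
#' @param engine Engine selector or object; see [folding_engine()].
#' @return Folding energy in kcal/mol (<= 0; 0 when no pair can form).
#' @export
fold_energy <- function(seq, engine = folding_engine("auto")) {
  engine <- folding_engine(engine)
  engine$fold(normalize_rna(seq))
}

#' Fold stability per nucleotide
#'
#' The folding energy divided by sequence length (kcal/mol/nt), the
#' length-independent stability score used to compare decRNAs, known
#' ncRNAs, and random genomic segments.
#'
#' @inheritParams fold_energy
#' @export
stability_per_nt <- function(seq, engine = folding_engine("auto")) {
  seq <- normalize_rna(seq)
  fold_energy(seq, engine) / nchar(seq)
}

#' Sample random genomic segments with a given length distribution
#'
#' Each draw takes a length (with replacement) from `lengths_pool`, a
#' replicon with probability proportional to its length, a uniform start
#' among valid positions, and a uniform strand; minus-strand draws are
#' reverse-complemented. Sequences are returned as RNA strings.
#'
#' @param genome Named character vector or [Biostrings::DNAStringSet].
#' @param lengths_pool Integer vector of segment lengths to draw from.
#' @param n Number of segments.
#' @param seed RNG seed.
#' @param exclude Optional data frame of 0-based half-open intervals
#'   (`start`, `end`, optional `replicon_id`) that sampled segments must
#'   not overlap; draws hitting them are rejected and redrawn.
#' @return Character vector of `n` RNA sequences.
#' @export
sample_random_segments <- function(genome, lengths_pool, n, seed = 1,
                                   exclude = NULL) {
  if (n == 0) return(character())
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  rep_len <- Biostrings::width(genome)
  if (max(lengths_pool) > max(rep_len)) {
    stopf("genome shorter than the longest requested segment")
  }
  rep_names <- names(genome) %||% as.character(seq_along(genome))
  hits_exclude <- function(r, s0, e0) {
    if (is.null(exclude) || !nrow(exclude)) return(FALSE)
    ex <- exclude
    if ("replicon_id" %in% names(ex)) {
      ex <- ex[ex$replicon_id == rep_names[r], , drop = FALSE]
    }
    any(ex$start < e0 & ex$end > s0)
  }
  with_seed(seed, {
    vapply(seq_len(n), function(i) {
      for (attempt in 1:1000) {
        L <- sample(lengths_pool, 1)
        ok <- which(rep_len >= L)
        r <- if (length(ok) == 1) ok else sample(ok, 1, prob = rep_len[ok])
        s <- sample.int(rep_len[r] - L + 1L, 1)
        if (!hits_exclude(r, s - 1L, s - 1L + L)) break
        if (attempt == 1000) stopf("could not sample outside excluded regions")
      }
      seq <- Biostrings::subseq(genome[[r]], s, s + L - 1L)
      if (sample(c(TRUE, FALSE), 1)) seq <- Biostrings::reverseComplement(seq)
      as.character(Biostrings::RNAString(seq))
    }, character(1))
  })
}
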