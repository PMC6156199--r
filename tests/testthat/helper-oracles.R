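# Independent oracles used across the suite. These deliberately take the
# slow, literal route so they share no code path with the implementation.

# Naive re-evaluation of the trailing-window elevation rule, position by
# position with stats::mean / stats::sd.
naive_elevated <- function(values, config = detection_config()) {
  n <- length(values)
  out <- rep(FALSE, n)
  w <- config$window
  for (p in seq_len(n)) {
    if (p <= w) next
    if ((p - w - 1L) %% config$step != 0L) next
    win <- values[(p - w):(p - 1)]
    thr <- mean(win) + config$sd_threshold * max(sd(win), config$sd_floor)
    out[p] <- values[p] > thr
  }
  out
}

# Exhaustive enumeration of all secondary structures (no pseudoknots,
# hairpin loops >= 3 nt) under the built-in energy model: GC -3, AU -2,
# GU -1, each stacked adjacent pair -1. Returns the minimum total energy.
enum_fold_energy <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s)
  pe <- function(a, b) {
    key <- paste0(a, b)
    e <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)[key]
    unname(e)
  }
  structures <- function(i, j) {
    if (j - i < 4) return(list(list()))
    res <- structures(i + 1, j)
    for (k in (i + 4):j) {
      if (is.na(pe(s[i], s[k]))) next
      left <- structures(i + 1, k - 1)
      right <- structures(k + 1, j)
      for (l in left) for (r in right) {
        res[[length(res) + 1L]] <- c(list(c(i, k)), l, r)
      }
    }
    res
  }
  score <- function(pairs) {
    if (!length(pairs)) return(0)
    keys <- vapply(pairs, function(p) paste(p, collapse = ","), character(1))
    tot <- 0
    for (p in pairs) {
      tot <- tot + pe(s[p[1]], s[p[2]])
      if (paste(p[1] + 1, p[2] - 1, sep = ",") %in% keys) tot <- tot - 1
    }
    tot
  }
  min(vapply(structures(1, n), score, numeric(1)), 0)
}

# Random RNA string
random_rna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

# A perfect hairpin: stem of `stem` nt, loop of 4
hairpin_rna <- function(stem = 10) {
  fivep <- random_rna(stem, gc = 0.6)
  comp <- chartr("ACGU", "UGCA", paste(rev(strsplit(fivep, "")[[1]]), collapse = ""))
  paste0(fivep, "GAAA", comp)
}

shuffle_rna <- function(seq) {
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}
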