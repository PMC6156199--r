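#' Simulation configuration for synthetic decay experiments
#'
#' Defaults mirror a rifampicin decay assay: a time-zero (steady-state)
#' sample followed by sampling at 1-minute intervals out to 9 minutes, in
#' triplicate, with Poisson count noise per nucleotide and modest
#' library-size variation between replicates.
#'
#' @param n_genes Number of genes to place.
#' @param genome_len Genome length in nt.
#' @param timepoints Minutes after transcription shutoff; strictly
#'   increasing, first must be 0 (the steady state).
#' @param n_replicates Replicates per timepoint.
#' @param noise `"poisson"`, `"negbin"`, or `"none"` (noise-free expected
#'   values, useful for exact recovery checks).
#' @param dispersion Negative-binomial size parameter (ignored otherwise).
#' @param library_size_jitter Per-library depth multiplier drawn uniformly
#'   from `1 +/- library_size_jitter`, so library-size normalization is
#'   non-trivial.
#' @param gc GC content of the random genome.
#' @param mean_init_abundance Typical steady-state reads/nt of a gene.
#' @param seed RNG seed; identical configs give bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 20, genome_len = 60000, timepoints = 0:9,
                       n_replicates = 3, noise = c("poisson", "negbin", "none"),
                       dispersion = 10, library_size_jitter = 0.1, gc = 0.5,
                       mean_init_abundance = 100, seed = 1) {
  noise <- match.arg(noise)
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) < 2 || timepoints[1] != 0 ||
      any(diff(timepoints) <= 0)) {
    stopf("timepoints must be strictly increasing and start at 0")
  }
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  if (library_size_jitter < 0 || library_size_jitter >= 1) {
    stopf("library_size_jitter must be in [0, 1)")
  }
  structure(list(n_genes = as.integer(n_genes),
                 genome_len = as.integer(genome_len),
                 timepoints = timepoints,
                 n_replicates = as.integer(n_replicates),
                 noise = noise, dispersion = dispersion,
                 library_size_jitter = library_size_jitter, gc = gc,
                 mean_init_abundance = mean_init_abundance,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a random genome and non-overlapping gene annotation
#'
#' Genes are placed left to right with random spacers (minimum 100 nt).
#' Each gene gets a CDS length divisible by 3, short UTRs, a steady-state
#' abundance, and a per-minute exponential decay rate in the range typical
#' of bacterial mRNAs (half-lives of roughly 1.5-3.5 min).
#'
#' @param config A [sim_config()].
#' @return List with `genome` (named character, one replicon) and `genes`
#'   (gene model data frame with extra columns `init_abundance` and
#'   `decay_rate`).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    p <- c(A = (1 - config$gc) / 2, C = config$gc / 2,
           G = config$gc / 2, T = (1 - config$gc) / 2)
    genome <- paste(sample(names(p), config$genome_len, replace = TRUE, prob = p),
                    collapse = "")
    if (config$n_genes == 0) {
      return(list(genome = c(chr = genome), genes = empty_gene_table()))
    }
    cds_len <- 3L * sample(100:500, config$n_genes, replace = TRUE)
    utr5 <- sample(20:60, config$n_genes, replace = TRUE)
    utr3 <- sample(30:100, config$n_genes, replace = TRUE)
    foot <- cds_len + utr5 + utr3
    min_spacer <- 100L
    need <- sum(foot) + (config$n_genes + 1L) * min_spacer
    if (need > config$genome_len) {
      stopf("cannot place %d genes (need %d nt, genome is %d nt)",
            config$n_genes, need, config$genome_len)
    }
    slack <- config$genome_len - need
    cuts <- sort(runif(config$n_genes, 0, slack))
    extra <- diff(c(0, cuts, slack))
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    abundance <- stats::rlnorm(config$n_genes,
                               meanlog = log(config$mean_init_abundance),
                               sdlog = 0.5)
    k <- runif(config$n_genes, 0.2, 0.5)
    pos <- 0
    rows <- vector("list", config$n_genes)
    for (i in seq_len(config$n_genes)) {
      pos <- pos + min_spacer + round(extra[i])
      start <- as.integer(pos)
      u5 <- if (strand[i] == "+") utr5[i] else utr3[i]
      cds_start <- start + u5
      rows[[i]] <- gene_model(sprintf("gene%03d", i), cds_start,
                              cds_start + cds_len[i], strand[i],
                              utr5_len = utr5[i], utr3_len = utr3[i])
      pos <- pos + foot[i]
    }
    genes <- do.call(rbind, rows)
    genes$init_abundance <- abundance
    genes$decay_rate <- k
    list(genome = c(chr = genome), genes = genes)
  })
}

#' Describe a planted stabilized segment
#'
#' A planted segment models a decRNA: within its bounds the expected
#' coverage decays at its own (slower) rate and sits `boost`-fold above the
#' host's steady-state level, emulating the accumulation of a continuously
#' generated, slowly degraded processing product. The default boost of 4 is
#' a modest version of the elevation seen for real decRNAs at steady state.
#'
#' @param host_gene_id Host gene id.
#' @param offset nt from the gene's 5' footprint end (gene orientation).
#' @param length Segment length in nt (>= 40 recommended for recoverable
#'   ground truth).
#' @param decay_rate Per-minute decay rate; should be below the host's for a
#'   stabilized segment.
#' @param boost Steady-state multiplier (>= 1).
#' @return One-row data frame.
#' @export
planted_segment <- function(host_gene_id, offset, length, decay_rate,
                            boost = 4) {
  if (length < 1) stopf("segment length must be >= 1")
  if (decay_rate <= 0 || boost < 1) stopf("need decay_rate > 0 and boost >= 1")
  data.frame(host_gene_id = as.character(host_gene_id),
             offset = as.integer(offset), length = as.integer(length),
             decay_rate = decay_rate, boost = boost,
             stringsAsFactors = FALSE)
}

segment_genomic_interval <- function(gene, seg) {
  flen <- gene_footprint_length(gene)
  if (seg$offset < 0 || seg$offset + seg$length > flen) {
    stopf("segment does not fit inside gene %s footprint", gene$id)
  }
  if (gene$strand == "+") {
    c(gene$start + seg$offset, gene$start + seg$offset + seg$length)
  } else {
    c(gene$end - seg$offset - seg$length, gene$end - seg$offset)
  }
}

#' Expected per-nucleotide coverage of a gene at time t
#'
#' Outside planted segments the expectation is
#' `init_abundance * exp(-decay_rate * t)`; inside a planted segment it is
#' `boost * init_abundance * exp(-segment_decay_rate * t)`.
#'
#' @param gene One-row gene model with `init_abundance` and `decay_rate`.
#' @param segments Planted segments hosted by this gene (may be empty).
#' @param t Minutes since transcription shutoff (>= 0).
#' @return Numeric vector over the footprint, in genomic orientation
#'   (element 1 = position `gene$start`).
#' @export
expected_coverage <- function(gene, segments = NULL, t = 0) {
  if (t < 0) stopf("t must be >= 0")
  v <- rep(gene$init_abundance * exp(-gene$decay_rate * t),
           gene_footprint_length(gene))
  if (!is.null(segments) && nrow(segments)) {
    segments <- segments[segments$host_gene_id == gene$id, , drop = FALSE]
    for (k in seq_len(nrow(segments))) {
      seg <- segments[k, ]
      iv <- segment_genomic_interval(gene, seg)
      idx <- (iv[1] - gene$start + 1L):(iv[2] - gene$start)
      v[idx] <- seg$boost * gene$init_abundance * exp(-seg$decay_rate * t)
    }
  }
  v
}

expected_profile <- function(genes, segments, t, genome_len) {
  prof <- list("+" = numeric(genome_len), "-" = numeric(genome_len))
  for (k in seq_len(nrow(genes))) {
    g <- genes[k, ]
    prof[[g$strand]][(g$start + 1L):g$end] <-
      prof[[g$strand]][(g$start + 1L):g$end] + expected_coverage(g, segments, t)
  }
  prof
}

sample_counts <- function(mu, config) {
  switch(config$noise,
         none = mu,
         poisson = rpois(length(mu), mu),
         negbin = rnbinom(length(mu), size = config$dispersion, mu = mu))
}

#' Simulate a full decay time-course experiment
#'
#' Produces one pair of strand tracks per (timepoint, replicate) library,
#' with counts drawn around the expected kinetic profile, per-replicate
#' depth jitter, and the truth table of planted segments.
#'
#' @param genome Named character vector (one replicon) or anything with a
#'   length matching `config$genome_len`; only the length is used here.
#' @param genes Gene model data frame from [simulate_annotation()].
#' @param segments Planted segments ([planted_segment()] rows), or `NULL`.
#' @param config A [sim_config()].
#' @return List of class `decay_experiment`: `tracks[[rep]][[time]]` is a
#'   list with `"+"` and `"-"` [coverage_track()]s sharing one library
#'   total; plus `timepoints`, `n_replicates`, `truth` (chrom, start, end,
#'   strand, host_gene, k_seg, boost).
#' @export
simulate_decay_experiment <- function(genome, genes, segments, config) {
  stopifnot(inherits(config, "sim_config"))
  genome_len <- config$genome_len
  truth <- NULL
  if (!is.null(segments) && nrow(segments)) {
    rows <- lapply(seq_len(nrow(segments)), function(k) {
      seg <- segments[k, ]
      g <- genes[genes$id == seg$host_gene_id, ]
      if (!nrow(g)) stopf("segment host gene %s not found", seg$host_gene_id)
      iv <- segment_genomic_interval(g, seg)
      data.frame(chrom = g$replicon_id, start = iv[1], end = iv[2],
                 strand = g$strand, host_gene = g$id,
                 k_seg = seg$decay_rate, boost = seg$boost,
                 stringsAsFactors = FALSE)
    })
    truth <- do.call(rbind, rows)
  }
  profiles <- lapply(config$timepoints, function(t)
    expected_profile(genes, segments, t, genome_len))
  tracks <- with_seed(config$seed + 1L, {
    lapply(seq_len(config$n_replicates), function(r) {
      depth <- 1 + runif(1, -1, 1) * config$library_size_jitter
      lapply(seq_along(config$timepoints), function(ti) {
        plus <- sample_counts(profiles[[ti]][["+"]] * depth, config)
        minus <- sample_counts(profiles[[ti]][["-"]] * depth, config)
        total <- sum(plus) + sum(minus)
        if (total <= 0) total <- 1  # empty library guard
        list("+" = coverage_track(plus, "+", library_total = total),
             "-" = coverage_track(minus, "-", library_total = total))
      })
    })
  })
  structure(list(replicon_id = "chr", genome_len = genome_len,
                 timepoints = config$timepoints,
                 n_replicates = config$n_replicates,
                 tracks = tracks, truth = truth, config = config),
            class = "decay_experiment")
}

#' @export
print.decay_experiment <- function(x, ...) {
  cat(sprintf("<decay_experiment> %d timepoints x %d replicates, %d nt, %d planted segments\n",
              length(x$timepoints), x$n_replicates, x$genome_len,
              if (is.null(x$truth)) 0L else nrow(x$truth)))
  invisible(x)
}

#' Fetch one strand track from a decay experiment
#' @param experiment A `decay_experiment`.
#' @param replicate Replicate index.
#' @param timepoint_index Index into `experiment$timepoints`.
#' @param strand `"+"` or `"-"`.
#' @export
get_track <- function(experiment, replicate, timepoint_index, strand) {
  experiment$tracks[[replicate]][[timepoint_index]][[strand]]
}

#' Simulate an IP/lysate coverage pair
#'
#' The lysate follows the steady-state expected coverage of the annotation;
#' the IP multiplies expected coverage inside each true target interval by
#' its enrichment factor before count sampling. Used to exercise the
#' Hfq/ProQ enrichment calling with known ground truth.
#'
#' @param genes Gene model data frame with `init_abundance`/`decay_rate`.
#' @param true_targets Data frame with `start`, `end` (0-based half-open),
#'   `strand`, `factor` (> 0).
#' @param config A [sim_config()] (noise model, genome length, seed).
#' @param segments Optional planted segments contributing to steady state.
#' @param ip_depth,lysate_depth Mean depth multipliers for the two
#'   libraries.
#' @return List of class `ip_pair` with `ip` and `lysate`, each holding
#'   `"+"`/`"-"` [coverage_track()]s.
#' @export
simulate_ip_pair <- function(genes, true_targets, config, segments = NULL,
                             ip_depth = 1, lysate_depth = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(true_targets) && nrow(true_targets) &&
      any(true_targets$factor <= 0)) {
    stopf("enrichment factors must be > 0")
  }
  base <- expected_profile(genes, segments, 0, config$genome_len)
  ipexp <- lapply(base, function(v) v)
  if (!is.null(true_targets)) {
    for (k in seq_len(nrow(true_targets))) {
      tg <- true_targets[k, ]
      idx <- (tg$start + 1L):tg$end
      ipexp[[tg$strand]][idx] <- ipexp[[tg$strand]][idx] * tg$factor
    }
  }
  # The simulated genes stand in for a small window of a whole
  # transcriptome, so each library's total mapped reads is dominated by the
  # unmodeled background: totals are fixed at the expected steady-state sum
  # (scaled by depth) rather than the sum of the simulated slice, keeping
  # one enriched target from distorting its own normalization.
  base_total <- max(sum(base[["+"]]) + sum(base[["-"]]), 1)
  with_seed(config$seed + 2L, {
    make_pair <- function(prof, depth) {
      plus <- sample_counts(prof[["+"]] * depth, config)
      minus <- sample_counts(prof[["-"]] * depth, config)
      total <- base_total * depth
      list("+" = coverage_track(plus, "+", library_total = total),
           "-" = coverage_track(minus, "-", library_total = total))
    }
    structure(list(ip = make_pair(ipexp, ip_depth),
                   lysate = make_pair(base, lysate_depth)),
              class = "ip_pair")
  })
}

#' Write a simulated experiment to standard files
#'
#' Genome as FASTA, annotation as GFF3, one bedGraph per strand per
#' (timepoint, replicate) library plus a `library_sizes.tsv` sidecar, and
#' the truth table as TSV.
#'
#' @param sim List with `genome` and `genes` from [simulate_annotation()].
#' @param experiment A `decay_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_gff3(sim$genes, file.path(dir, "annotation.gff3"))
  sizes <- c()
  for (r in seq_len(experiment$n_replicates)) {
    for (ti in seq_along(experiment$timepoints)) {
      lib <- sprintf("t%g_rep%d", experiment$timepoints[ti], r)
      for (s in c("+", "-")) {
        tr <- experiment$tracks[[r]][[ti]][[s]]
        fn <- sprintf("%s_%s.bedgraph", lib, if (s == "+") "fwd" else "rev")
        write_bedgraph(tr, file.path(dir, fn))
      }
      sizes[lib] <- experiment$tracks[[r]][[ti]][["+"]]$library_total
    }
  }
  write_library_sizes(sizes, file.path(dir, "library_sizes.tsv"))
  if (!is.null(experiment$truth)) {
    write.table(experiment$truth, file.path(dir, "truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
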