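# Shared fixture builders: everything is generated in code at test time.

withr_tempfile <- function() tempfile(fileext = ".txt")

# A small noise-free decay experiment with planted stabilized segments.
# Segments default to boost 4 (above the 2-fold steady-state gate) and a
# decay-rate gap giving >= 8-fold stabilization over the 9-min course.
quick_sim <- function(n_genes = 8, plant = c(1, 3), seg_len = 120,
                      noise = "none", seed = 7, boost = 4,
                      k_seg = 0.02, mean_abund = 100,
                      genome_len = 3200 * n_genes, jitter = 0) {
  cfg <- sim_config(n_genes = n_genes, genome_len = genome_len,
                    noise = noise, seed = seed,
                    library_size_jitter = jitter,
                    mean_init_abundance = mean_abund)
  sim <- simulate_annotation(cfg)
  segs <- NULL
  if (length(plant)) {
    segs <- do.call(rbind, lapply(plant, function(i)
      planted_segment(sim$genes$id[i], offset = 200, length = seg_len,
                      decay_rate = k_seg, boost = boost)))
  }
  exp <- simulate_decay_experiment(sim$genome, sim$genes, segs, cfg)
  list(cfg = cfg, genome = sim$genome, genes = sim$genes,
       segments = segs, experiment = exp)
}

# One constant-coverage track over a whole replicon
const_track <- function(value, len, strand = "+", lib = 1e6,
                        normalized = FALSE) {
  coverage_track(rep(value, len), strand = strand, library_total = lib,
                 normalized = normalized)
}

# Does a call data frame contain a row matching the truth row within tol nt?
matches_truth <- function(calls, truth_row, tol = 5) {
  any(calls$strand == truth_row$strand &
        abs(calls$start - truth_row$start) <= tol &
        abs(calls$end - truth_row$end) <= tol)
}
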