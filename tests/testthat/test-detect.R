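make_norm_series <- function(base, segv, seg = c(100, 160), len = 500,
                             strand = "+") {
  lapply(seq_along(base), function(ti) {
    v <- rep(base[ti], len)
    v[(seg[1] + 1):seg[2]] <- segv[ti]
    tr <- coverage_track(v, strand, library_total = 1e6, normalized = TRUE)
    out <- list(tr, tr)
    names(out) <- c("+", "-")
    out
  })
}

test_that("gene medians follow the even/odd order-statistic convention", {
  g5 <- gene_model("g", 0, 5, "+")
  expect_equal(gene_median_coverage(coverage_track(1:5, "+", library_total = 1),
                                    g5), 3)
  g4 <- gene_model("g", 0, 4, "+")
  expect_equal(gene_median_coverage(coverage_track(1:4, "+", library_total = 1),
                                    g4), 2.5)
  g7 <- gene_model("g", 0, 10, "+")
  expect_equal(gene_median_coverage(const_track(7, 10), g7), 7)
})

test_that("the expression filter drops genes below the t0 median threshold", {
  g1 <- gene_model("hi", 0, 200, "+")
  g2 <- gene_model("lo", 300, 500, "+")
  genes <- rbind(g1, g2)
  v <- c(rep(6, 200), rep(0, 100), rep(4, 200))
  t0 <- lapply(1:3, function(r) {
    tr <- coverage_track(v, "+", library_total = 1e6)
    list("+" = tr, "-" = tr)
  })
  kept <- filter_expressed(t0, genes, detection_config())
  expect_equal(kept$id, "hi")
  all_kept <- filter_expressed(t0, genes, detection_config(min_gene_median_t0 = 0))
  expect_equal(all_kept$id, c("hi", "lo"))
})

test_that("the expression filter honors the replicate aggregation rule", {
  g <- gene_model("g", 0, 100, "+")
  meds <- c(6, 4, 4)  # only replicate 1 passes
  t0 <- lapply(meds, function(m) {
    tr <- const_track(m, 100)
    list("+" = tr, "-" = tr)
  })
  expect_equal(nrow(filter_expressed(t0, g, detection_config())), 0)
  expect_equal(nrow(filter_expressed(t0, g,
                                     detection_config(expressed_rule = "any"))), 1)
  expect_equal(nrow(filter_expressed(t0, g,
                                     detection_config(expressed_rule = "mean"))), 0)
})

test_that("candidate filters enforce the t0-fold and stabilization thresholds", {
  g <- gene_model("g", 0, 500, "+")
  cand <- data.frame(start = 100L, end = 160L)
  cfg <- detection_config()

  # fold 2.1 at t0, relative-abundance ratios (1, 1.5, 3.5): kept
  tracks <- make_norm_series(base = c(10, 4, 2),
                             segv = c(21, 4 * 2.1 * 1.5, 2 * 2.1 * 3.5))
  out <- filter_candidates(cand, tracks, g, cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$t0_fold, 2.1)
  expect_equal(out$stabilization_fold, 3.5)

  # t0 fold 1.9: rejected no matter the stabilization
  tracks <- make_norm_series(base = c(10, 2), segv = c(19, 2 * 1.9 * 10))
  expect_equal(nrow(filter_candidates(cand, tracks, g, cfg)), 0)

  # fold 2.5 but max ratio 2.9: rejected
  tracks <- make_norm_series(base = c(10, 2), segv = c(25, 2 * 2.5 * 2.9))
  expect_equal(nrow(filter_candidates(cand, tracks, g, cfg)), 0)
})

test_that("timepoints with a zero gene median are skipped, not infinite", {
  g <- gene_model("g", 0, 500, "+")
  cand <- data.frame(start = 100L, end = 160L)
  # gene fully decayed at t2 (median 0) but segment persists
  tracks <- make_norm_series(base = c(10, 5, 0), segv = c(25, 40, 20))
  out <- filter_candidates(cand, tracks, g, detection_config())
  expect_equal(nrow(out), 1)
  expect_equal(out$stabilization_fold, (40 / 5) / (25 / 10))
})

test_that("replicate intersection keeps >=2-replicate consensus intersections", {
  cfg <- detection_config()
  same <- data.frame(start = 100L, end = 260L)
  res <- intersect_replicates(list(same, same, same), cfg)
  expect_equal(res[, c("start", "end")], data.frame(start = 100L, end = 260L))
  expect_equal(res$n_replicates_support, 3L)

  res1 <- intersect_replicates(list(same, NULL, NULL), cfg)
  expect_equal(nrow(res1), 0)

  a <- data.frame(start = 100L, end = 260L)
  b <- data.frame(start = 120L, end = 280L)
  res2 <- intersect_replicates(list(a, b), cfg)
  expect_equal(res2$start, 120L)
  expect_equal(res2$end, 260L)
  expect_equal(res2$n_replicates_support, 2L)
})

test_that("boundary correction snaps only within range and never inverts", {
  es <- data.frame(replicon_id = "chr", strand = "+",
                   position = c(97L, 300L),
                   kind = c("five_prime", "three_prime"))
  r <- correct_boundaries(100L, 260L, "+", es, max_distance = 20)
  expect_equal(r$start, 97L)  # snapped 3 nt upstream
  expect_equal(r$end, 260L)   # 3' site 41 nt away: untouched
  expect_true(r$boundary_corrected)

  r0 <- correct_boundaries(100L, 260L, "+", NULL)
  expect_false(r0$boundary_corrected)
  expect_equal(r0$start, 100L)

  far <- data.frame(replicon_id = "chr", strand = "+", position = 50L,
                    kind = "five_prime")
  r1 <- correct_boundaries(100L, 260L, "+", far, max_distance = 20)
  expect_false(r1$boundary_corrected)

  # a snap that collapses the interval is refused
  bad <- data.frame(replicon_id = "chr", strand = "+",
                    position = c(250L, 259L),
                    kind = c("five_prime", "three_prime"))
  expect_warning(r2 <- correct_boundaries(245L, 262L, "+", bad,
                                          max_distance = 20,
                                          min_segment_len = 40),
                 "refused")
  expect_equal(r2$start, 245L)
})

test_that("minus-strand boundaries snap 5' to the genomic end side", {
  es <- data.frame(replicon_id = "chr", strand = "-",
                   position = c(263L, 96L),
                   kind = c("five_prime", "three_prime"))
  r <- correct_boundaries(100L, 260L, "-", es, max_distance = 20)
  expect_equal(r$end, 264L)   # 5' terminus at end-1 -> site 263
  expect_equal(r$start, 96L)  # 3' terminus at start -> site 96
})

test_that("CDS-overlap classification uses the strict majority cut", {
  g <- gene_model("g", 100, 400, "+", utr5_len = 50, utr3_len = 100)
  full <- classify_overlap(150, 250, g)
  expect_equal(full$cds_overlap_fraction, 1)
  expect_equal(full$category, "within_cds")

  mixed <- classify_overlap(346, 436, g)  # 54 of 90 nt over CDS
  expect_equal(mixed$cds_overlap_fraction, 0.6)
  expect_equal(mixed$category, "cds_majority")

  utr <- classify_overlap(420, 480, g)
  expect_equal(utr$cds_overlap_fraction, 0)
  expect_equal(utr$category, "utr_majority")
})

test_that("noise-free detection recovers planted segments exactly and only them", {
  s <- quick_sim(n_genes = 8, plant = c(1, 4), seed = 31)
  calls <- detect_decrnas(s$experiment, s$genes, s$genome)
  expect_equal(nrow(calls), 2)
  for (k in 1:2) expect_true(matches_truth(calls, s$experiment$truth[k, ], tol = 5))
  expect_setequal(calls$host_gene, s$experiment$truth$host_gene)

  none <- quick_sim(n_genes = 6, plant = integer(0), seed = 32)
  expect_equal(nrow(detect_decrnas(none$experiment, none$genes, none$genome)), 0)

  short <- quick_sim(n_genes = 6, plant = 2, seg_len = 30, seed = 33)
  expect_equal(nrow(detect_decrnas(short$experiment, short$genes, short$genome)), 0)
})

test_that("raising a planted segment's stabilization never removes its call", {
  prev <- 0
  for (k_seg in c(0.10, 0.05, 0.02)) {
    s <- quick_sim(n_genes = 5, plant = 2, k_seg = k_seg, seed = 35)
    calls <- detect_decrnas(s$experiment, s$genes, s$genome)
    expect_equal(nrow(calls), 1)
    expect_gte(calls$stabilization_fold, prev)
    prev <- calls$stabilization_fold
  }
})

test_that("call sequences are the gene-strand RNA of the call interval", {
  s <- quick_sim(n_genes = 6, plant = 3, seed = 36)
  calls <- detect_decrnas(s$experiment, s$genes, s$genome)
  expect_equal(nrow(calls), 1)
  seq <- calls$sequence
  expect_equal(nchar(seq), calls$length)
  expect_false(grepl("[^ACGU]", seq))
  g <- s$genes[s$genes$id == calls$host_gene, ]
  dna <- substr(s$genome[[1]], calls$start + 1, calls$end)
  expected <- if (g$strand == "+") chartr("T", "U", dna) else {
    chartr("ACGT", "UGCA", paste(rev(strsplit(dna, "")[[1]]), collapse = ""))
  }
  expect_identical(seq, expected)
})
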