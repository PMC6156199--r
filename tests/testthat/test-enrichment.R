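call_row <- function(start, end, strand = "+", id = "dec1") {
  data.frame(id = id, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("decRNA/host ratios are segment mean over gene median", {
  g <- gene_model("host", 0, 500, "+")
  v <- rep(2, 500); v[101:200] <- 90
  tr <- coverage_track(v, "+", library_total = 1e6, normalized = TRUE)
  r <- decrna_host_ratio(tr, call_row(100, 200), g)
  expect_equal(r$ratio, 45)

  flat <- coverage_track(rep(7, 500), "+", library_total = 1e6,
                         normalized = TRUE)
  expect_equal(decrna_host_ratio(flat, call_row(100, 200), g)$ratio, 1)

  v0 <- rep(5, 500); v0[101:200] <- 0
  tr0 <- coverage_track(v0, "+", library_total = 1e6, normalized = TRUE)
  expect_equal(decrna_host_ratio(tr0, call_row(100, 200), g)$ratio, 0)

  zero <- coverage_track(rep(0, 500), "+", library_total = 1e6,
                         normalized = TRUE)
  expect_error(decrna_host_ratio(zero, call_row(100, 200), g),
               "host_median_zero")
})

test_that("RNase E dependence comparison detects a removed stabilization", {
  set.seed(41)
  wt <- exp(rnorm(30, log(20), 0.5))    # stabilized decRNAs: high ratios
  mut <- exp(rnorm(30, log(1), 0.3))    # mutant: stabilization removed
  res <- compare_rnase_dependence(wt, mut)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$wt_median, res$mutant_median)

  same <- compare_rnase_dependence(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)

  expect_error(compare_rnase_dependence(1, c(1, 2)), "at least 2")
})

test_that("label permutation keeps the rnase comparison near nominal level", {
  set.seed(43)
  pool <- exp(rnorm(40, log(5), 0.6))
  rej <- vapply(1:500, function(i) {
    idx <- sample(40, 20)
    compare_rnase_dependence(pool[idx], pool[-idx])$p_value < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.08)
})

test_that("Hfq calls use a strict absolute coverage cut", {
  cl <- call_row(100, 200)
  expect_true(hfq_call(const_track(35, 300), cl)$call)
  expect_false(hfq_call(const_track(30, 300), cl)$call)
  expect_false(hfq_call(const_track(0, 300), cl)$call)
  expect_warning(hfq_call(const_track(35, 300, normalized = TRUE), cl),
                 "absolute")
  # monotone in coverage
  means <- vapply(c(10, 20, 31, 60), function(v)
    hfq_call(const_track(v, 300), cl)$call, logical(1))
  expect_equal(means, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("ProQ enrichment is the FLAG/WT double ratio with strict gates", {
  cl <- call_row(100, 200)
  mk <- function(v, lib = 1e6) const_track(v, 300, lib = lib)
  # FLAG IP/lysate = 8, WT IP/lysate = 2 -> enrichment ~ 4
  r <- proq_enrichment(mk(800), mk(100), mk(200), mk(100), cl,
                       enrichment_config(pseudocount = 1e-9))
  expect_equal(r$enrichment, 4, tolerance = 1e-6)
  expect_true(r$call)

  # identical tracks: enrichment 1, no call
  r1 <- proq_enrichment(mk(100), mk(100), mk(100), mk(100), cl)
  expect_equal(r1$enrichment, 1, tolerance = 1e-3)
  expect_false(r1$call)

  # enrichment just below 2 with plenty of coverage: no call
  r2 <- proq_enrichment(mk(199), mk(100), mk(100), mk(100), cl,
                        enrichment_config(pseudocount = 1e-9))
  expect_equal(r2$enrichment, 1.99, tolerance = 1e-6)
  expect_false(r2$call)

  # coverage gate: enrichment high but FLAG IP mean of 20 is not > 20
  r3 <- proq_enrichment(mk(20), mk(1), mk(1), mk(1), cl,
                        enrichment_config(pseudocount = 1e-9))
  expect_false(r3$call)
})

test_that("ProQ enrichment is invariant to per-library sequencing depth", {
  cl <- call_row(100, 200)
  mk <- function(v, lib) const_track(v, 300, lib = lib)
  base <- proq_enrichment(mk(800, 1e6), mk(100, 1e6), mk(200, 1e6),
                          mk(100, 1e6), cl)
  # scale one library's counts and its total by 10x
  scaled <- proq_enrichment(mk(8000, 1e7), mk(100, 1e6), mk(200, 1e6),
                            mk(100, 1e6), cl)
  expect_lt(abs(scaled$enrichment / base$enrichment - 1), 0.01)
})

test_that("annotate_enrichment requires data and fills missing assays with NA", {
  calls <- rbind(call_row(100, 200, id = "d1"),
                 call_row(400, 480, id = "d2"))
  expect_error(annotate_enrichment(calls), "no enrichment data")

  hfq <- list("+" = const_track(50, 600), "-" = const_track(50, 600, "-"))
  res <- annotate_enrichment(calls, hfq_ip = hfq)
  expect_true(all(res$hfq_call))
  expect_true(all(is.na(res$proq_call)))
})

test_that("a planted ProQ target is the only one called on synthetic co-IP data", {
  cfg <- sim_config(n_genes = 6, genome_len = 20000, noise = "poisson",
                    seed = 47, mean_init_abundance = 120,
                    library_size_jitter = 0)
  sim <- simulate_annotation(cfg)
  calls <- do.call(rbind, lapply(1:4, function(i) {
    g <- sim$genes[i, ]
    call_row(g$start + 100, g$start + 250, g$strand, paste0("d", i))
  }))
  target <- data.frame(start = calls$start[2], end = calls$end[2],
                       strand = calls$strand[2], factor = 8)
  flag <- simulate_ip_pair(sim$genes, target, cfg)
  wtcfg <- cfg; wtcfg$seed <- cfg$seed + 50L
  wt <- simulate_ip_pair(sim$genes, transform(target, factor = 1), wtcfg)
  res <- annotate_enrichment(calls,
                             proq = list(ip_flag = flag$ip,
                                         lysate_flag = flag$lysate,
                                         ip_wt = wt$ip,
                                         lysate_wt = wt$lysate))
  expect_true(res$proq_call[2])
  expect_false(any(res$proq_call[-2]))
  expect_gt(res$proq_enrichment[2], 4)
})
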