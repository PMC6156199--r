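test_that("annotation simulation handles the empty case and is deterministic", {
  cfg <- sim_config(n_genes = 0, genome_len = 5000, seed = 2)
  sim <- simulate_annotation(cfg)
  expect_equal(nrow(sim$genes), 0)
  expect_equal(nchar(sim$genome[[1]]), 5000)

  cfg2 <- sim_config(n_genes = 10, genome_len = 40000, seed = 5)
  a <- simulate_annotation(cfg2)
  b <- simulate_annotation(cfg2)
  expect_identical(a, b)
})

test_that("gene placements never overlap (brute-force pair sweep)", {
  sim <- simulate_annotation(sim_config(n_genes = 50, genome_len = 100000,
                                        seed = 9))
  g <- sim$genes
  expect_equal(nrow(g), 50)
  for (i in seq_len(nrow(g) - 1)) {
    for (j in (i + 1):nrow(g)) {
      expect_true(g$end[i] <= g$start[j] || g$end[j] <= g$start[i])
    }
  }
})

test_that("infeasible placement raises an explicit error", {
  expect_error(simulate_annotation(sim_config(n_genes = 50,
                                              genome_len = 2000, seed = 1)),
               "cannot place")
})

test_that("expected coverage follows the closed-form kinetics", {
  g <- gene_model("g1", 100, 700, "+", utr5_len = 50, utr3_len = 50)
  g$init_abundance <- 100; g$decay_rate <- 0.5
  expect_equal(expected_coverage(g, NULL, 0), rep(100, 700))
  expect_equal(expected_coverage(g, NULL, 2), rep(100 * exp(-1), 700))
  expect_error(expected_coverage(g, NULL, -1), ">= 0")

  seg <- planted_segment("g1", offset = 100, length = 80,
                         decay_rate = 0.05, boost = 1)
  v4 <- expected_coverage(g, seg, 4)
  ratio <- v4[150] / v4[10]  # segment vs flank
  expect_equal(ratio, exp((0.5 - 0.05) * 4))

  # log expected coverage is linear in t with slope -decay_rate
  tt <- 0:9
  logv <- log(vapply(tt, function(t) expected_coverage(g, NULL, t)[1],
                     numeric(1)))
  fit <- coef(lm(logv ~ tt))
  expect_equal(unname(fit[2]), -0.5, tolerance = 1e-12)
})

test_that("planted segments must fit inside the host footprint", {
  g <- gene_model("g1", 100, 400, "+")
  g$init_abundance <- 10; g$decay_rate <- 0.3
  seg <- planted_segment("g1", offset = 280, length = 50, decay_rate = 0.05)
  expect_error(expected_coverage(g, seg, 0), "fit inside")
})

test_that("decay experiments are seed-deterministic with coherent truth tables", {
  s1 <- quick_sim(noise = "poisson", seed = 21)
  s2 <- quick_sim(noise = "poisson", seed = 21)
  expect_identical(s1$experiment$tracks, s2$experiment$tracks)

  tru <- s1$experiment$truth
  for (k in seq_len(nrow(tru))) {
    g <- s1$genes[s1$genes$id == tru$host_gene[k], ]
    expect_true(tru$start[k] >= g$start && tru$end[k] <= g$end)
    expect_identical(tru$strand[k], g$strand)
  }
})

test_that("Poisson sampling is unbiased and zero abundance stays zero", {
  cfg <- sim_config(n_genes = 1, genome_len = 4000, noise = "poisson",
                    seed = 3, library_size_jitter = 0)
  sim <- simulate_annotation(cfg)
  sim$genes$init_abundance <- 100
  exp <- simulate_decay_experiment(sim$genome, sim$genes, NULL, cfg)
  g <- sim$genes
  draws <- track_slice(get_track(exp, 1, 1, g$strand), g$start, g$end)
  n <- length(draws)  # iid Poisson(100) draws across the footprint
  expect_lt(abs(mean(draws) - 100), 3 * sqrt(100 / n))

  sim$genes$init_abundance <- 1e-12
  exp0 <- simulate_decay_experiment(sim$genome, sim$genes, NULL, cfg)
  for (ti in seq_along(exp0$timepoints)) {
    expect_equal(sum(get_track(exp0, 1, ti, g$strand)$values), 0)
  }
})

test_that("IP/lysate pairs reflect the planted enrichment factors", {
  cfg <- sim_config(n_genes = 4, genome_len = 16000, noise = "none",
                    seed = 13, library_size_jitter = 0)
  sim <- simulate_annotation(cfg)
  g <- sim$genes[1, ]
  tgt <- data.frame(start = g$start + 100, end = g$start + 200,
                    strand = g$strand, factor = 8)

  pair1 <- simulate_ip_pair(sim$genes, transform(tgt, factor = 1), cfg)
  expect_equal(pair1$ip[[g$strand]]$values, pair1$lysate[[g$strand]]$values)

  pair8 <- simulate_ip_pair(sim$genes, tgt, cfg)
  ip <- pair8$ip[[g$strand]]$values
  lys <- pair8$lysate[[g$strand]]$values
  inside <- (tgt$start + 1):tgt$end
  outside <- (g$start + 300):(g$start + 400)
  expect_equal(ip[inside] / lys[inside], rep(8, length(inside)))
  expect_equal(ip[outside] / lys[outside], rep(1, length(outside)))

  expect_error(simulate_ip_pair(sim$genes, transform(tgt, factor = 0), cfg),
               "factors")
})
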