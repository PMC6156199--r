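# decarve

Discovery and characterization of **decay-generated noncoding RNAs
(decRNAs)** — short mRNA subsegments that survive bulk mRNA turnover —
from strand-specific RNA-seq coverage of transcription-shutoff
(rifampicin) time courses in bacteria.

When transcription initiation is blocked, a gene with decay rate *k*
loses coverage as *μ(x,t) = A(x)·e^(−kt)*. RNase processing (chiefly
RNase E in *E. coli*) can release internal fragments that fold into
stable structures and decay much more slowly, so their **relative
abundance** — segment mean coverage over the host gene's median — grows
through the time course, and their continuous production leaves them
above the host's steady-state level even before shutoff. decarve finds
these segments with a sliding-window rule and characterizes them:

* **Detection** (`detect_decrnas()`): genes with a time-zero median below
  5 reads/nt are dropped; a 100-nt trailing window flags nucleotides more
  than 4 SD above the window mean; elevated runs > 40 nt become
  candidates; candidates need > 2-fold the gene median at *t* = 0 and a
  ≥ 3-fold rise in relative abundance during the course; segments passing
  in ≥ 2 replicates are intersected, optionally snapped to mapped
  transcript termini, and classified by CDS-overlap fraction.
* **Fold stability** (`compare_stability()`): per-nucleotide minimum free
  energy (kcal/mol/nt) of calls versus known ncRNAs and length-matched
  random genomic segments, compared with a self-contained two-sided
  Wilcoxon rank-sum test. Folding uses ViennaRNA's `RNAfold` when on the
  PATH, or a built-in deterministic stacking-aware base-pair-maximization
  engine.
* **RNase E dependence** (`compare_rnase_dependence()`): decRNA/host
  expression ratios in WT versus an RNase E-inactivated mutant.
* **Hfq/ProQ interactions** (`annotate_enrichment()`): Hfq calls from
  mean IP coverage > 30 reads/nt; ProQ calls from the
  (FLAG IP/lysate)/(WT IP/lysate) double ratio > 2 with IP coverage
  > 20 reads/nt.
* **Synthetic data** (`simulate_decay_experiment()`,
  `simulate_ip_pair()`): decay time courses with planted stabilized
  segments and IP/lysate pairs with known enrichment, so the whole
  pipeline is testable with no external data.

Audience: microbial transcriptomics groups running decay time-course or
co-IP RNA-seq, and anyone needing a tested reference implementation of
the sliding-window stabilized-segment rule.

## Worked example

Simulate a ten-gene genome with two planted decRNAs (4-fold steady-state
boost, slow decay), detect, and score fold stability:

```r
library(decarve)

cfg <- sim_config(n_genes = 10, genome_len = 36000, noise = "poisson",
                  mean_init_abundance = 200, seed = 42)
sim <- simulate_annotation(cfg)
segs <- rbind(
  planted_segment("gene003", offset = 250, length = 160, decay_rate = 0.02),
  planted_segment("gene007", offset = 400, length = 100, decay_rate = 0.05))
exper <- simulate_decay_experiment(sim$genome, sim$genes, segs, cfg)

calls <- detect_decrnas(exper, sim$genes, sim$genome)
calls[, c("id", "start", "end", "length", "n_replicates_support",
          "t0_fold", "stabilization_fold", "category")]
#>             id start   end length n_replicates_support t0_fold
#> 1 gene003.dec1 12144 12304    160                    3    3.94
#> 2 gene007.dec1 27188 27288    100                    3    3.97
#>   stabilization_fold   category
#> 1              21.72 within_cds
#> 2               8.62 within_cds
```

Both planted segments are recovered at their exact coordinates
(`exper$truth` holds the ground truth), in all three replicates. The
`t0_fold` column is the steady-state elevation over the host median
(the planted boost was 4), and `stabilization_fold` is the maximal rise
in relative abundance — larger for the gene003 segment because its decay
advantage over the host is bigger.

```r
stab <- compare_stability(setNames(calls$sequence, calls$id), NULL,
                          sim$genome,
                          stability_config(n_random = 1000, seed = 1),
                          engine = "builtin")
stab
#> <stability_comparison>
#>   decRNA       n=    2  median -1.053 kcal/mol/nt
#>   random       n= 1000  median -1.100 kcal/mol/nt
#>   decRNA vs random p = 0.0876; vs known p = NA (engine: builtin)
```

Here the calls are random planted sequence, so their fold stability sits
inside the random distribution and the rank-sum p-value is
unremarkable — on real decRNAs this comparison is what shows calls
folding more stably than random genomic segments.

A command-line wrapper over the same functions ships at
`inst/scripts/decarve.R` with subcommands `simulate`, `detect`,
`stability`, `enrich`, `rnase`, `export`, and `run`:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts/decarve.R", package = "decarve"))')
Rscript $CLI simulate --out-dir sim --n-genes 10 --n-plant 3 --seed 5
Rscript $CLI detect --coverage-dir sim --annotation sim/annotation.gff3 \
    --genome sim/genome.fa --out-prefix calls
```

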