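---
title: "Detecting decay-generated noncoding RNAs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting decay-generated noncoding RNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decarve)
```

## The biological problem

After transcription initiation is blocked with rifampicin, a bacterial mRNA
decays roughly exponentially: per-nucleotide RNA-seq coverage of a gene with
decay rate $k$ follows

$$\mu(x, t) = A(x)\,e^{-k t},$$

with $A(x)$ the steady-state coverage. Some transcripts, however, decay
non-uniformly: endoribonucleolytic processing (chiefly RNase E in
*E. coli*) releases short internal fragments that fold into stable
structures and out-live the rest of the transcript. These decay-generated
noncoding RNAs (decRNAs) show up in a decay time course as subgene windows
whose *relative abundance* — segment coverage over the host gene's median
coverage — grows as the host decays. Because they are continuously produced
and slowly degraded, they also sit above the host's steady-state level
before shutoff. decarve detects these segments, requires replicate
consistency, and characterizes the calls by CDS overlap, RNA fold
stability, RNase E dependence, and Hfq/ProQ co-IP enrichment.

## The detection rule

Detection operates per gene, in gene (5'→3') orientation, on raw
reads-per-nucleotide tracks.

1. **Expression filter.** Genes whose footprint (CDS plus mapped UTRs)
   median coverage at $t = 0$ is below 5 reads/nt are excluded. The
   threshold must hold in every replicate by default; the text that
   motivates the rule names "the time zero samples" without an aggregation
   rule, so `expressed_rule` also offers `"any"` and `"mean"`.
2. **Sliding window.** A 100-nt window moves in 1-nt steps. A nucleotide
   $p$ is *elevated* when
   $v(p) > \bar v_w + 4\max(s_w, s_{\min})$, where $\bar v_w$ and $s_w$
   are the mean and sample SD of the 100 nt immediately 5' of $p$. The
   window *trails* the evaluated nucleotide so that the 5' boundary of a
   stabilized segment registers as an upshift; nothing in the source
   description fixes the direction, and this choice makes boundary
   detection symmetric under strand reflection (minus-strand genes are
   scanned on the reversed footprint).
3. **Run formation.** A run opens at an elevated position and extends
   while coverage stays above the threshold *frozen* from the last fully
   pre-run window. Freezing is essential, not cosmetic: if the window were
   re-computed inside the run, its SD would grow as it absorbs the
   elevated plateau and the threshold would overtake any plateau within
   roughly $w/17$ nt of the boundary, whatever the elevation — no segment
   longer than ~6 nt could ever be called at a step upshift with
   $w = 100$. Runs must be strictly longer than 40 nt.
4. **Segment filters.** On library-size-normalized tracks, a candidate
   needs (a) mean coverage at $t=0$ strictly above 2× the gene median at
   $t=0$, and (b) a relative-abundance rise of at least 3-fold at some
   post-shutoff timepoint relative to its $t=0$ value. Later timepoints
   where the gene median is zero are skipped rather than treated as
   infinite stabilization — a fully decayed host should not manufacture
   evidence.
5. **Replicate intersection.** Candidates that pass in a replicate are
   grouped across replicates by single-linkage overlap (≥ 1 nt, same gene
   and strand); groups supported by ≥ 2 distinct replicates yield the
   intersection of their members as the consensus interval, which must
   still exceed 40 nt.
6. **Boundary correction.** When mapped transcript 5'/3' end sites are
   supplied, each boundary snaps to the nearest compatible site within 20
   nt (configurable); snaps that would invert the interval or shrink it
   below the length threshold are refused.
7. **Classification.** The CDS-overlap fraction
   $|I \cap \mathrm{CDS}| / |I|$ maps to `within_cds` (= 1),
   `cds_majority` (> 0.5), or `utr_majority`.

Within a replicate the scan runs on every timepoint's track and the
per-timepoint runs are union-merged before filtering. Segments at modest
steady-state boost are barely elevated at $t=0$ but prominent late in the
course; scanning only the steady state would miss them.

### Which tracks feed which statistic

The window statistics and the expression filter use **raw** reads/nt, so
the SD floor of 1 read/nt (which keeps the rule defined on constant or
noise-free windows, where $s_w = 0$ would make any uptick infinitely
significant) keeps physical units. Every cross-timepoint or cross-library
*ratio* — the $t=0$ fold, the stabilization fold, decRNA/host ratios, and
ProQ IP/lysate ratios — uses reads-per-million normalization, under which
any per-library constant cancels. RPM itself is a readability choice; any
fixed constant gives identical downstream ratios.

## Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_gene_median_t0` | 5 | reads/nt | expression filter at $t=0$ |
| `window` | 100 | nt | trailing window length |
| `sd_threshold` | 4 | SDs | elevation cut |
| `sd_floor` | 1 | reads/nt | lower bound on window SD |
| `min_segment_len` | 40 | nt | strict minimum run/consensus length |
| `min_t0_fold` | 2 | fold | steady-state elevation gate (strict) |
| `min_stabilization_fold` | 3 | fold | relative-abundance rise (inclusive) |
| `min_replicate_support` | 2 | replicates | consensus requirement |
| `max_end_distance` | 20 | nt | boundary-snap radius |
| `hfq_min_mean_coverage` | 30 | reads/nt | Hfq call (raw IP track, strict) |
| `proq_min_mean_coverage` | 20 | reads/nt | ProQ coverage gate (FLAG IP, strict) |
| `proq_min_enrichment` | 2 | fold | ProQ double-ratio gate (strict) |
| `pseudocount` | 0.1 | RPM | guards zero denominators in ProQ ratios |

Strict versus inclusive inequalities follow the wording of the thresholds
("greater than", "at least"). The 2-fold gate is evaluated on the
segment's mean by default (`t0_fold_stat = "median"` is available); the
source description does not name the summary.

## The synthetic-data generator

`simulate_annotation()` places non-overlapping genes (CDS 300–1500 nt,
divisible by 3; 20–60 nt 5'UTRs; 30–100 nt 3'UTRs; ≥ 100 nt spacers) on a
random genome, with log-normal steady-state abundances (median 100
reads/nt by default) and decay rates uniform on 0.2–0.5 min⁻¹ —
half-lives of roughly 1.4–3.5 min, the typical bacterial range.
`simulate_decay_experiment()` samples counts per nucleotide around the
kinetic expectation at 0–9 min in 1-min steps, in triplicate, with a
±10% per-replicate depth multiplier so that library-size normalization is
exercised. Planted segments decay at their own (slower) rate and sit
`boost`-fold (default 4) above the host's steady state, emulating the
accumulation of a continuously generated, slowly degraded product —
real examples reach ~45-fold. The default boost is deliberately above the
2-fold steady-state gate: a fragment at parity with its host at steady
state is undetectable under the published rule set, whatever its decay
advantage.

Noise is Poisson per nucleotide by default (negative binomial with
configurable dispersion for overdispersion, or `"none"` for closed-form
tracks). The choice is a modeling decision, not a claim about the original
libraries, whose noise structure is unstated.

For IP/lysate pairs, library totals are set to the expected steady-state
sum rather than the realized sum of the simulated slice: the few simulated
genes stand in for a small window of a whole transcriptome, and a single
enriched target must not perturb its own library's normalization, as it
would not in a genome-scale library.

**What the generator does not model** — and what passing tests therefore
do not establish about real data: positional correlation of coverage along
the genome (read-length smearing), operons spanning several genes,
fragment-length and rRNA-depletion artifacts, and read-level (FASTQ)
detail. Boundary accuracy in particular is optimistic on synthetic data
because planted segments have step edges; real processing sites produce
ragged boundaries, which is why end-site correction exists.

## Fold-stability scoring

Two interchangeable engines score minimum free energy; all comparative
statistics use one engine per run, since the comparison is of relative
distributions.

* **vienna** — ViennaRNA's `RNAfold` (nearest-neighbor thermodynamics,
  37 °C), used when the executable is on the PATH.
* **builtin** — a deterministic, dependency-free simplification: base-pair
  maximization with stacking, scoring GC −3, AU −2, GU −1 kcal/mol per
  pair, −1 per stacked pair, hairpin loops ≥ 3 nt, no pseudoknots, solved
  exactly by dynamic programming in compiled code. The test suite proves
  the DP equal to exhaustive structure enumeration for short sequences.

Scores are divided by sequence length (kcal/mol/nt) for length-independent
comparison. Random genomic segments are drawn with lengths from the pooled
length distribution of the real sets, uniform start and strand,
reverse-complemented on the minus strand; sampling genome-wide (no
exclusion of known loci) is the default, with an `exclude` option.

## Rank-sum testing

All distribution comparisons use a self-contained two-sided Wilcoxon
rank-sum test: midranks for ties; an exact p-value by complete enumeration
of rank assignments when $n_1 + n_2 \le 20$ with no ties; otherwise a
normal approximation with tie correction and a 0.5 continuity correction.
Zero rank variance (all values identical) returns $p = 1$. The suite
verifies the exact path against the independent base-R exact distribution
for every size pair up to $n_1 + n_2 = 10$, agreement of the two paths at
$n_1 = n_2 = 10$, and type-I calibration at $\alpha = 0.05$.

The RNase E comparison applies this test, unpaired, to decRNA/host ratio
distributions from WT and mutant libraries; ratios are pairable by decRNA
and a paired signed-rank option exists but is off by default, matching the
distribution-level comparison the assay was designed around.

## Numerical choices and degenerate inputs

* Even-length medians average the two central order statistics.
* A gene median of zero at $t=0$ rejects the candidate with a recorded
  reason; zero at later timepoints skips the timepoint.
* Boundary snaps never invert an interval or shrink it below the length
  threshold; refusals are logged.
* Identical-coordinate calls from overlapping gene footprints keep the
  host with the larger CDS overlap.
* The ProQ pseudocount (0.1 RPM) biases enrichment by < 1% at coverage
  ≥ 20 reads/nt and keeps zero-lysate segments finite.
* All simulation and sampling functions restore the caller's RNG state;
  identical seeds give bit-identical outputs.

## Problem sizes used in validation

The shipped checks run at desk scale, chosen to finish in minutes while
leaving the operating conditions intact: oracle equivalence on 100
randomized vectors; exact recovery on a noise-free 20-gene genome with 5
planted segments (≥ 8-fold stabilization over 9 min); Poisson-noise
recovery at ≥ 200 reads/nt steady-state coverage over 100 seeded
simulations; 10,000 null simulations for test calibration; 100 seeded
ProQ-recovery runs; and enumeration cross-checks for folding up to
18-mers. The acceptance script (`scripts/acceptance.R`) re-runs a seeded
end-to-end study of the same shape and reports its measured quantities.

## Known limitations

* The scan is gene-footprint-bounded: intergenic decRNAs (and the first
  `window` nucleotides of every footprint) are invisible by construction.
* Detection needs a time course; steady-state-only data cannot separate
  stable fragments from expression structure.
* The builtin folding model ranks structured against unstructured
  sequences reliably but its absolute energies are not thermodynamic;
  cross-engine energy values are not comparable.
* Replicate intersection uses single-linkage grouping, which can chain
  distinct but adjacent segments into one consensus when candidates
  tile densely.
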