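# nslchrom

Analyses of promoter chromatin organization by the *Drosophila* NSL
complex, rebuilt as a verifiable R pipeline. The NSL complex binds the
nucleosome-depleted region (NDR) of housekeeping, TATA-less promoters,
recruits the NURF remodeler, and maintains the phased nucleosome array
downstream of the transcription start site (TSS). Its loss lets the +1
nucleosome slide toward the TSS and invade the NDR, redirects TSS choice,
and raises cell-to-cell transcription noise. `nslchrom` implements the
computational side of that story — nucleosome positioning from MNase
fragments, ChIP-based promoter classification, an AT-content model of NSL
binding, differential TSS-usage testing, and a single-cell noise test —
on top of a synthetic-data generator with exact ground truth, so that
every stage is checked by parameter recovery rather than by eye.

The package is aimed at computational biologists who want either the
individual building blocks (promoter-anchored matrices, +1 calling,
quantile-group shift summaries, 5-mer partial-correlation screens, G-test
TSS-shift detection, permutation noise tests) or the worked, simulated
reproduction of the full analysis chain.

## The statistics at the core

* **Occupancy**: Gaussian-smoothed fragment-midpoint density, RPGC
  normalized (genome-wide mean = 1). +1 nucleosome = first local maximum
  in [0, 250] bp with height ≥ 0.25 × row max; 5′ edge = dyad − 73 bp.
  Shift = argmax over lags of windowed cross-correlation (negative =
  toward the TSS), or the difference of called edges.
* **Promoter classes**: two-stage k = 2 k-means on summed
  log₂(NSL3/input) + log₂(MBDR2/input) over TSS ± 290 bp, then on the
  control − knockdown Pol II log₂ enrichment over ± 145 bp (exact
  optimal threshold splits, verified against exhaustive search).
* **Binding model**: logistic regression of bound/unbound on the AT
  fractions of 61 contiguous 29-bp windows (TSS ± 884 bp), ridge penalty,
  stratified 10-fold CV; per-window slope t-tests with a fold-overlap
  variance correction. 5-mer screen: partial correlation
  r of per-bin 5-mer frequency with in vitro log enrichment given AT,
  t = r√((n−2)/(1−r²)), over all 1024 5-mers in 200-bp bins.
* **TSS usage**: dominant TSS = argmax of 5′-end counts (5′-most on
  ties); spread = smallest d with ≥ 90% of signal within ± d; per-gene
  G-test (2·Σ O·ln(O/E)) of position × condition independence, BH at
  FDR 5%, with up/down TSS assignment and 5′UTR length-change calls from
  RNA-seq coverage.
* **Noise**: mean-trend-corrected log CV² residuals against a common
  reference trend, tested by cell-label permutation at FDR 10%, on genes
  screened to be non-differential.

## Worked example

Simulate a 200-gene chromosome whose NSL targets are programmed to shift
their +1 nucleosome 10 bp toward the TSS upon knockdown, then recover
that shift:

```r
library(nslchrom)

cfg <- generator_config(n_genes = 200, kd_shift = 10, seed = 7)
g    <- make_genome(cfg)
lens <- c(chrS = cfg$chrom_len)

occ_c <- compute_occupancy(simulate_mnase(g, "control",   cfg), lens)
occ_k <- compute_occupancy(simulate_mnase(g, "knockdown", cfg), lens)
m_c <- anchor_matrix(occ_c, g$promoters)   # genes x [-500, 1000] bp
m_k <- anchor_matrix(occ_k, g$promoters)

st  <- shift_table(m_c, m_k)               # per-gene xcorr shifts
tgt <- g$truth$is_nsl_target[match(st$gene, g$truth$gene)]
mean(st$shift[tgt],  na.rm = TRUE)   # -10.2
mean(st$shift[!tgt], na.rm = TRUE)   #   0.2
```

The target group mean (−10.2 bp) recovers the programmed −10 bp shift;
non-targets sit at zero. The same pattern drives the promoter-zone
summary: on this simulation `occupancy_difference()` reports a mean NDR
delta of +1.11 and a +1-zone delta of −1.17 for targets (nucleosomes
invading the NDR), both ≈ 0 for non-targets.

The numbered scripts under `analysis/` run the full chain on a 400-gene
system and narrate their findings, e.g.:

```
$ Rscript analysis/02_nucleosome.R
mean +1 shift: targets -10.2 bp, non-targets 0.2 bp (programmed: -10 and 0)
invasion signature (targets): NDR delta +1.11, +1 delta -1.17
mean shift by NSL1-enrichment quintile (low to high): -5.1 -9.3 -12.2 -16.2 -24.9 bp
strictly monotone: TRUE

$ Rscript analysis/05_tss_usage.R
median 90%-containment spread: targets 58 bp, non-targets 16 bp
TSS-usage shifts at FDR 5%: 21 called, 100% of programmed events recovered
```

Run them in order (`01_simulate.R` … `06_noise.R`) from the repository
root; tables land under `results/analysis/`. `run_pipeline()` offers the
same stages as one deterministic, config-driven call.

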