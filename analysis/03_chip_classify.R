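#!/usr/bin/env Rscript
# ChIP-based promoter classification: summed NSL3+MBDR2 log2 enrichment
# over TSS +/-290 bp splits promoters into NSL-bound vs non-bound by 1-D
# k-means; bound promoters are subdivided by the control-minus-knockdown
# Pol II log2 enrichment over +/-145 bp. Also peak calling on NSL1/NURF301
# tracks and their overlap statistics.

source(file.path("analysis", "00_settings.R"))

cfg <- analysis_config()
g <- make_genome(cfg)
out <- analysis_outdir()

tracks <- list(
  NSL3 = simulate_chip(g, "NSL3", "control", cfg),
  MBDR2 = simulate_chip(g, "MBDR2", "control", cfg),
  PolII_control = simulate_chip(g, "PolII", "control", cfg),
  PolII_knockdown = simulate_chip(g, "PolII", "knockdown", cfg),
  input = simulate_chip(g, "input", "control", cfg))

cl <- classify_promoters(promoter_enrichment(g$promoters, tracks))
tr <- g$truth
cl$true_target <- tr$is_nsl_target
cl$true_polII_loss <- tr$polII_loss
write_counts(cl, file.path(out, "promoter_classes.tsv"))

b <- cl$nsl_bound & tr$is_nsl_target
cat(sprintf("NSL-bound recovery: %.1f%% of %d promoters correct\n",
            100 * mean(cl$nsl_bound == tr$is_nsl_target), nrow(cl)))
cat(sprintf("Pol II-loss recovery among bound: %.1f%%\n",
            100 * mean(cl$polII_loss[b] == tr$polII_loss[b])))

nsl1 <- simulate_chip(g, "NSL1", "control", cfg)
nurf <- simulate_chip(g, "NURF301", "control", cfg)
pk1 <- call_peaks(nsl1, threshold = 1.5)
pk2 <- call_peaks(nurf, threshold = 1.5)
tss <- data.frame(chrom = g$promoters$chrom, start = g$promoters$tss,
                  end = g$promoters$tss + 1L)
ov <- interval_overlap_stats(pk1, pk2, tss)
write_counts(as.data.frame(ov), file.path(out, "peak_overlap.tsv"))
cat(sprintf("%d of %d NSL1 peaks (%.0f%%) co-bound by NURF301; %.0f%% of cobound peaks at a TSS\n",
            ov$a_in_b, ov$n_a, 100 * ov$frac_a_in_b,
            100 * ov$frac_cobound_at_tss))
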