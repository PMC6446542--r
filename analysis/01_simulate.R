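#!/usr/bin/env Rscript
# Generate the synthetic study system — a toy chromosome of 400 promoters
# (half NSL targets with AT-rich NDRs and phased nucleosome arrays) — and
# write every simulated data type in its standard on-disk format, with
# ground truth and the config echo for provenance.

source(file.path("analysis", "00_settings.R"))

cfg <- analysis_config()
genome <- make_genome(cfg)
dir <- file.path(analysis_outdir(), "data")

write_synthetic_dataset(genome, dir,
                        chip_factors = c("NSL1", "NSL3", "MBDR2",
                                         "NURF301", "PolII", "input"),
                        mapcap_depth = 400 * 500)

tr <- genome$truth
cat(sprintf("wrote %s: %d genes (%d NSL targets, %d Pol II-loss, %d TSS-shift events)\n",
            dir, nrow(tr), sum(tr$is_nsl_target), sum(tr$polII_loss),
            sum(tr$shift_event)))
cat(sprintf("chromosome: %d bp; target NDR AT fraction ~0.75 vs 0.5 background\n",
            cfg$chrom_len))
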