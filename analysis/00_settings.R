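# Shared settings for the analysis scripts: one synthetic study system
# (400 promoters so every script runs in seconds; the acceptance script
# uses the full 2000-promoter set) regenerated deterministically by each
# script from the same config.

library(nslchrom)

analysis_config <- function()
  generator_config(n_genes = 400, sc_cells = 500, seed = 0)

analysis_outdir <- function() {
  d <- file.path("results", "analysis")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
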