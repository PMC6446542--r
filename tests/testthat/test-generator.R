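test_that("target assignment follows the rounding rule and label balance", {
  cfg <- generator_config(n_genes = 2, frac_nsl_target = 0.5, seed = 3)
  g <- make_genome(cfg)
  expect_equal(sum(g$truth$is_nsl_target), 1L)

  cfg2 <- small_config(frac_nsl_target = 0.3)
  g2 <- make_genome(cfg2)
  expect_equal(sum(g2$truth$is_nsl_target), round(0.3 * cfg2$n_genes))
  expect_equal(sum(g2$truth$shift_event),
               round(cfg2$frac_shift_genes * sum(g2$truth$is_nsl_target)))
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- small_config()
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(g1$genome, f1); write_fasta(g2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(simulate_mnase(g1, "control", cfg),
                   simulate_mnase(g2, "control", cfg))
  expect_identical(simulate_mapcap(g1, "knockdown", 5000, cfg),
                   simulate_mapcap(g2, "knockdown", 5000, cfg))
})

test_that("config invariants are validated", {
  expect_error(generator_config(frac_nsl_target = 1.2), "fraction")
  expect_error(generator_config(plus1_offset = 0), "plus1_offset")
  expect_error(generator_config(array_spacing = 100), "147")
  expect_error(generator_config(kmer_effects = c(1)), "5-mers")
  expect_error(make_genome(generator_config(n_genes = 100,
                                            chrom_len = 50000)),
               "chrom_len")
})

test_that("target NDRs are AT-rich relative to non-target promoters", {
  cfg <- generator_config(n_genes = 100, seed = 11)
  g <- make_genome(cfg)
  tr <- g$truth
  ndr_at <- vapply(seq_len(nrow(tr)), function(i) {
    x <- seq(-cfg$ndr_width, -1)
    idx <- sort(nslchrom:::oriented_pos(tr$tss[i], tr$strand[i], x)) + 1
    s <- strsplit(as.character(
      Biostrings::subseq(g$genome[[1]], min(idx), max(idx))), "")[[1]]
    mean(s %in% c("A", "T"))
  }, numeric(1))
  expect_gt(mean(ndr_at[tr$is_nsl_target]) -
              mean(ndr_at[!tr$is_nsl_target]), 0.15)
})

test_that("zero-noise MNase fragments sit exactly at programmed dyads", {
  cfg <- small_config(jitter_sd = 0, frag_len_sd = 0)
  g <- make_genome(cfg)
  fr <- simulate_mnase(g, "control", cfg)
  plus1 <- fr[fr$nuc == "+1", ]
  mid <- (plus1$start + plus1$end) %/% 2L
  tr <- g$truth[match(plus1$name, g$truth$gene), ]
  expected <- nslchrom:::oriented_pos(tr$tss, tr$strand, cfg$plus1_offset)
  expect_equal(mid, expected)
  expect_true(all(fr$end - fr$start == round(cfg$frag_len_mean)))
})

test_that("knockdown shifts target +1 midpoints upstream by kd_shift", {
  cfg <- generator_config(n_genes = 200, kd_shift = 10, seed = 21)
  g <- make_genome(cfg)
  mid_at_plus1 <- function(cond) {
    fr <- simulate_mnase(g, cond, cfg)
    p1 <- fr[fr$nuc == "+1", ]
    tr <- g$truth[match(p1$name, g$truth$gene), ]
    mid <- (p1$start + p1$end) %/% 2L
    # oriented offset from the TSS, positive downstream
    off <- ifelse(tr$strand == "+", mid - tr$tss, tr$tss - mid)
    tapply(off, tr$gene, mean)
  }
  d <- mid_at_plus1("knockdown") - mid_at_plus1("control")
  tgt <- g$truth$is_nsl_target[match(names(d), g$truth$gene)]
  expect_lt(abs(mean(d[tgt]) - (-10)), 1)
  expect_lt(abs(mean(d[!tgt])), 1)
  expect_true(all(simulate_mnase(g, "control", cfg)$end -
                    simulate_mnase(g, "control", cfg)$start <= 200))
})

test_that("ChIP tracks have the programmed enrichment structure", {
  cfg <- generator_config(n_genes = 100, seed = 31)
  g <- make_genome(cfg)
  input <- simulate_chip(g, "input", "control", cfg)
  expect_lt(abs(track_mean(input) - 1), 0.01)
  expect_error(simulate_chip(g, "H3K4me3", "control", cfg), "unknown")

  nsl1 <- simulate_chip(g, "NSL1", "control", cfg)
  tr <- g$truth
  nt <- which(!tr$is_nsl_target)
  l2 <- vapply(nt, function(i)
    log2_enrichment(nsl1, input, "chrS", tr$tss[i] - 290, tr$tss[i] + 291),
    numeric(1))
  expect_lt(abs(mean(l2)), 0.1)

  pc <- simulate_chip(g, "PolII", "control", cfg)
  pk <- simulate_chip(g, "PolII", "knockdown", cfg)
  loss <- which(tr$polII_loss)
  ratio <- vapply(loss, function(i) {
    a <- mean(nslchrom:::track_slice(pk, "chrS", tr$tss[i] - 145,
                                     tr$tss[i] + 146))
    b <- mean(nslchrom:::track_slice(pc, "chrS", tr$tss[i] - 145,
                                     tr$tss[i] + 146))
    a / b
  }, numeric(1))
  expect_lt(mean(ratio), 0.5)
})

test_that("MAPCap counts follow the programmed multinomial", {
  cfg <- small_config()
  g <- make_genome(cfg)
  tab <- simulate_mapcap(g, "control", 20000, cfg)
  expect_equal(sum(tab$count), 20000)
  expect_true(all(tab$count > 0))

  # degenerate spread: all non-target reads at the annotated TSS
  cfg0 <- small_config(tss_spread_focused = 0, frac_shift_genes = 0)
  g0 <- make_genome(cfg0)
  t0 <- simulate_mapcap(g0, "control", 20000, cfg0)
  tr0 <- g0$truth
  foc <- t0[!tr0$is_nsl_target[match(t0$gene, tr0$gene)], ]
  expect_true(all(foc$pos ==
                    tr0$tss[match(foc$gene, tr0$gene)]))

  # programmed swap: alternative-TSS usage rises by tss_swap in knockdown
  cfg1 <- generator_config(n_genes = 150, frac_shift_genes = 1,
                           tss_swap = 0.3, seed = 41)
  g1 <- make_genome(cfg1)
  usage <- function(cond) {
    tt <- simulate_mapcap(g1, cond, 150 * 2000, cfg1)
    tr <- g1$truth
    # well-separated events only, so the dispersed main peak does not
    # leak into the probe window around the alternative TSS
    ev <- tr$gene[tr$shift_event & abs(tr$alt_offset) >= 100]
    vapply(ev, function(gg) {
      sub <- tt[tt$gene == gg, ]
      i <- match(gg, tr$gene)
      alt <- nslchrom:::oriented_pos(tr$tss[i], tr$strand[i],
                                     tr$alt_offset[i])
      near_alt <- abs(sub$pos - alt) <= 25
      sum(sub$count[near_alt]) / sum(sub$count)
    }, numeric(1))
  }
  du <- usage("knockdown") - usage("control")
  expect_lt(abs(mean(du) - 0.3), 0.03)
})

test_that("in vitro enrichment is affine in AT when noiseless", {
  cfg <- small_config(noise_sd = 0)
  g <- make_genome(cfg)
  bins <- simulate_invitro_binding(g, cfg)
  expect_equal(bins$log_enrichment, cfg$at_effect * bins$at_fraction)
  expect_equal(bins$end - bins$start, rep(200L, nrow(bins)))
})

test_that("regression on simulated bins recovers at_effect within 5%", {
  cfg <- generator_config(n_genes = 100, chrom_len = 1001000, seed = 0)
  g <- make_genome(cfg)
  bins <- simulate_invitro_binding(g, cfg)
  expect_gte(nrow(bins), 5000)
  slope <- coef(lm(log_enrichment ~ at_fraction, data = bins))[[2]]
  expect_lt(abs(slope - cfg$at_effect) / cfg$at_effect, 0.05)
})

test_that("all-zero effects give enrichment uncorrelated with AT", {
  cfg <- generator_config(n_genes = 100, chrom_len = 1001000,
                          at_effect = 0, seed = 1)
  g <- make_genome(cfg)
  bins <- simulate_invitro_binding(g, cfg)
  expect_lt(abs(cor(bins$log_enrichment, bins$at_fraction)), 0.05)
})

test_that("single-cell counts preserve means and inflate dispersion", {
  cfg <- generator_config(n_genes = 150, sc_cells = 400,
                          sc_dispersion_fold = 2.5, seed = 51)
  g <- make_genome(cfg)
  mc <- simulate_scrna(g$truth, "control", cfg)
  mk <- simulate_scrna(g$truth, "knockdown", cfg)
  expect_true(all(mc == round(mc)) && all(mc >= 0))
  # means preserved across conditions within Monte-Carlo error
  expect_lt(abs(mean(colMeans(mk)) / mean(colMeans(mc)) - 1), 0.1)

  # flagged genes: empirical CV^2 ratio tracks the NB expectation
  # CV^2 = 1/mu + phi (plus library-size spread, shared across conditions)
  tr <- g$truth
  cv2 <- function(m) apply(m, 2, var) / colMeans(m)^2
  fl <- tr$noise_flag
  expected <- (1 / colMeans(mk)[fl] + tr$sc_disp_kd[fl]) /
    (1 / colMeans(mc)[fl] + tr$sc_disp_ctrl[fl])
  ratio <- cv2(mk)[fl] / cv2(mc)[fl]
  expect_lt(abs(median(ratio) - median(expected)), 0.35)

  # fold 1: matched conditions
  cfg1 <- generator_config(n_genes = 150, sc_cells = 400,
                           sc_dispersion_fold = 1, seed = 52)
  g1 <- make_genome(cfg1)
  m1 <- simulate_scrna(g1$truth, "control", cfg1)
  m2 <- simulate_scrna(g1$truth, "knockdown", cfg1)
  expect_lt(abs(median(cv2(m2) - cv2(m1))), 0.1)
})

test_that("the synthetic dataset writer emits re-loadable standard formats", {
  cfg <- generator_config(n_genes = 20, sc_cells = 30, seed = 61)
  g <- make_genome(cfg)
  dir <- withr::local_tempdir()
  write_synthetic_dataset(g, dir, chip_factors = "input",
                          mapcap_depth = 5000)
  expect_true(all(file.exists(file.path(dir, c(
    "genome.fa", "promoters.bed", "genes.gff3", "mnase_control.bed",
    "mapcap_control.tsv", "chip_input_control.bedGraph",
    "invitro_bins.tsv", "ground_truth.json", "config.json")))))
  fa <- read_fasta(file.path(dir, "genome.fa"))
  expect_equal(length(fa[[1]]), cfg$chrom_len)
  prom <- read_bed(file.path(dir, "promoters.bed"))
  expect_equal(prom$start, g$promoters$tss)
  gff <- read_gff3(file.path(dir, "genes.gff3"))
  expect_equal(gff$start, g$promoters$tss)
})
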