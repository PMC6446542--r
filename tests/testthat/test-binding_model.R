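test_that("AT features are exact window counts on both strands", {
  L <- 5000L
  seq_chr <- c("A", "C", "G", "T")[sample.int(4, L, replace = TRUE)]
  seqs <- Biostrings::DNAStringSet(
    structure(paste(seq_chr, collapse = ""), names = "c"))

  prom <- data.frame(chrom = "c", tss = 2500L, strand = "+", gene = "gp")
  f <- at_features(seqs, prom)
  expect_equal(dim(f), c(1L, 61L))
  oriented <- seq_chr[(2500 - 884 + 1):(2500 + 884 + 1)]
  expect_equal(unname(f[1, ]), naive_at_windows(oriented))

  # minus strand equals the reverse complement read left to right
  promm <- data.frame(chrom = "c", tss = 2500L, strand = "-", gene = "gm")
  fm <- at_features(seqs, promm)
  rc <- rev(chartr("ACGT", "TGCA", seq_chr[(2500 - 884 + 1):
                                             (2500 + 884 + 1)]))
  expect_equal(unname(fm[1, ]), naive_at_windows(rc))

  # poly-A promoter: every feature is 1
  seqs_a <- Biostrings::DNAStringSet(
    structure(paste(rep("A", 5000), collapse = ""), names = "c"))
  fa <- at_features(seqs_a, prom)
  expect_true(all(fa == 1))

  # 14 AT bases in a 29-bp window -> 14/29
  w <- c(rep("A", 14), rep("G", 15))
  expect_equal(naive_at_windows(rep(w, 61), n_win = 61)[1], 14 / 29)
  seqs_w <- Biostrings::DNAStringSet(
    structure(paste(rep(w, 70), collapse = ""), names = "c"))
  fw <- at_features(seqs_w, data.frame(chrom = "c", tss = 884L,
                                       strand = "+", gene = "g"))
  expect_equal(unname(fw[1, 1]), 14 / 29)

  # promoters without enough sequence are dropped with a warning
  expect_warning(
    fe <- at_features(seqs, rbind(prom, data.frame(chrom = "c", tss = 10L,
                                                   strand = "+",
                                                   gene = "edge"))),
    "dropped")
  expect_equal(nrow(fe), 1L)
})

test_that("a perfectly separable feature gives perfect CV recall", {
  set.seed(1)
  n <- 200
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(paste0("g", 1:n), 1:3))
  x[, 2] <- ifelse(lab, 1, 0) + rnorm(n, 0, 0.01)
  rep_ <- fit_at_logistic(x, lab, seed = 0)
  expect_equal(rep_$sensitivity, 1)
  expect_equal(rep_$specificity, 1)
  expect_true(all(table(rep_$fold) == 20))
  # reproducible bit-exactly given the seed
  rep2 <- fit_at_logistic(x, lab, seed = 0)
  expect_identical(rep_$prob, rep2$prob)
  expect_error(fit_at_logistic(x[1:3, ], lab[1:3]), "class")
})

test_that("slope significance is calibrated under a shuffled-label null", {
  cfg <- generator_config(n_genes = 300, seed = 0)
  g <- make_genome(cfg)
  feat <- at_features(g$genome, g$promoters)
  set.seed(42)
  nsig <- replicate(15, {
    r <- fit_at_logistic(feat, sample(g$truth$is_nsl_target), seed = 0)
    sum(r$slope_tests$significant)
  })
  # expected 61 x 0.05 = 3.05 significant windows per replicate; the
  # total over 15 replicates is ~Binomial(915, 0.05)
  total <- sum(nsig)
  expect_gte(total, qbinom(0.005, 15 * 61, 0.05))
  expect_lte(total, qbinom(0.995, 15 * 61, 0.05))
})

test_that("AT-driven simulation puts significant positive slopes in the NDR", {
  cfg <- generator_config(n_genes = 1000, seed = 0)
  g <- make_genome(cfg)
  feat <- at_features(g$genome, g$promoters)
  labels <- g$truth$is_nsl_target[match(rownames(feat), g$truth$gene)]
  rep_ <- fit_at_logistic(feat, labels, seed = 0)
  prof <- window_slope_profile(rep_)
  ndr <- prof$start < 0 & prof$start + 29 > -150  # overlaps [-150, 0)
  # the AT-rich NDR windows drive prediction with positive sign
  expect_gte(sum(prof$significant & prof$sign > 0 & ndr), 3)
  # windows outside the NDR behave like nulls: exceedances within the
  # upper binomial bound for 61 x 0.05 tests
  expect_lte(sum(prof$significant & !ndr),
             qbinom(0.995, sum(!ndr), 0.05))
  # positive slope means AT predicts bound: the top positive window is in
  # the NDR
  expect_true(ndr[which.max(prof$t)])
})

test_that("partial correlation equals the regression-residual definition", {
  set.seed(7)
  n <- 50
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(n), function(i)
    paste(c("A", "C", "G", "T")[sample.int(4, 200, TRUE)], collapse = ""),
    character(1)))
  y <- rnorm(n)
  expect_warning(scr <- kmer_partial_screen(seqs, y), "recommended")
  at <- as.numeric(Biostrings::letterFrequency(seqs, "AT", as.prob = TRUE))
  counts <- Biostrings::oligonucleotideFrequency(seqs, 5)
  for (km in c("ACGTA", "TTTTT", "GATCG")) {
    x <- counts[, km] / 196
    expected <- if (var(x) == 0) 0 else partial_cor_lm(y, x, at)
    expect_equal(scr$partial_r[scr$kmer == km], expected,
                 tolerance = 1e-8)
  }
  expect_equal(nrow(scr), 1024L)
  expect_true(all(abs(scr$partial_r) <= 1))
})

test_that("an enrichment affine in AT leaves no partial correlation", {
  set.seed(8)
  seqs <- Biostrings::DNAStringSet(vapply(1:200, function(i)
    paste(c("A", "C", "G", "T")[sample.int(4, 200, TRUE)], collapse = ""),
    character(1)))
  at <- as.numeric(Biostrings::letterFrequency(seqs, "AT", as.prob = TRUE))
  scr <- suppressWarnings(kmer_partial_screen(seqs, 3 * at + 1))
  expect_lt(max(abs(scr$partial_r[!scr$zero_variance])), 1e-10)
  expect_true(all(scr$t_stat[scr$zero_variance] == 0))
})

test_that("predictor comparison ranks AT above DRE above a random 5-mer", {
  cfg <- generator_config(n_genes = 400, seed = 4)
  g <- make_genome(cfg)
  labels <- structure(g$truth$is_nsl_target, names = g$truth$gene)
  cp <- compare_predictors(g$genome, g$promoters, labels)
  acc <- structure(cp$accuracy, names = cp$predictor)
  expect_gt(acc[["AT-profile"]], acc[["DRE-motif-count"]])
  expect_gt(acc[["DRE-motif-count"]], acc[["random-5mer-count"]])
  # a random 5-mer is chance-level on the (balanced) labels
  expect_lt(abs(acc[["random-5mer-count"]] - 0.5), 0.1)
})

test_that("a densely planted DRE motif is recovered by motif counting", {
  cfg <- generator_config(n_genes = 300, frac_dre_target = 0.8,
                          frac_dre_nontarget = 0.05, seed = 14)
  g <- make_genome(cfg)
  labels <- structure(g$truth$is_nsl_target, names = g$truth$gene)
  cp <- compare_predictors(g$genome, g$promoters, labels)
  expect_gt(cp$accuracy[cp$predictor == "DRE-motif-count"], 0.7)
})
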