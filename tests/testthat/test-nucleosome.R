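test_that("occupancy pileup matches brute-force RPGC arithmetic", {
  # fragments with midpoints {10, 10, 20} on a 30-bp chromosome
  fr <- data.frame(chrom = "c", start = c(8L, 9L, 18L),
                   end = c(12L, 11L, 22L))
  tr <- compute_occupancy(fr, c(c = 30L), smoothing_sd = 0)
  expected <- numeric(30)
  expected[11] <- 2; expected[21] <- 1          # raw midpoint counts
  expected <- expected * 30 / 3                 # RPGC scale
  expect_equal(tr[["c"]], expected)
  expect_equal(track_mean(tr), 1, tolerance = 1e-9)

  expect_warning(z <- compute_occupancy(fr[0, ], c(c = 30L)),
                 "no fragments")
  expect_true(all(z[["c"]] == 0))
  expect_error(compute_occupancy(
    data.frame(chrom = "c", start = 25L, end = 40L), c(c = 30L)),
    "bounds")
})

test_that("RPGC mean is 1 with smoothing and any fragment set", {
  cfg <- small_config()
  g <- make_genome(cfg)
  occ <- compute_occupancy(simulate_mnase(g, "control", cfg),
                           c(chrS = cfg$chrom_len), smoothing_sd = 20)
  expect_equal(track_mean(occ), 1, tolerance = 1e-9)
})

test_that("anchored matrices are strand-oriented", {
  # single bump at genomic 1000 + 70; plus- and minus-strand genes with
  # TSS placed so the bump is 70 bp downstream of each
  v <- numeric(4000)
  v[1000 + 70 + 1] <- 5
  v[3000 - 70 + 1] <- 5
  tr <- Track(list(c = v))
  prom <- data.frame(chrom = "c", tss = c(1000L, 3000L),
                     strand = c("+", "-"), gene = c("gp", "gm"))
  m <- anchor_matrix(tr, prom, window = c(-500, 1000))
  expect_equal(dim(m), c(2L, 1501L))
  expect_equal(unname(m["gp", ]), unname(m["gm", ]))
  expect_equal(m["gp", "70"], 5)

  flat <- Track(list(c = rep(2, 4000)))
  mf <- anchor_matrix(flat, prom)
  expect_true(all(mf == 2))

  close_prom <- data.frame(chrom = "c", tss = 100L, strand = "+",
                           gene = "edge")
  expect_warning(me <- anchor_matrix(tr, rbind(prom, close_prom)),
                 "dropped")
  expect_equal(nrow(me), 2L)
})

test_that("+1 calling picks the first qualifying local maximum", {
  p <- bump_profile(70, 1)
  cc <- call_plus_one(p)
  expect_equal(cc$dyad, 70L)
  expect_equal(cc$five_prime_edge, -3L)

  # first qualifying local max wins over a taller later one
  p2 <- bump_profile(c(60, 240), c(1.0, 1.2))
  expect_equal(call_plus_one(p2)$dyad, 60L)

  z <- rep(0, 1501); names(z) <- -500:1000
  expect_true(is.na(call_plus_one(z)$dyad))

  # sub-prominence bumps are not called
  p3 <- bump_profile(c(-300, 100), c(1, 0.1))
  expect_true(is.na(call_plus_one(p3, min_prominence = 0.25)$dyad))
})

test_that("shift estimators recover rigid translations exactly", {
  p <- bump_profile(75, 1)
  expect_equal(estimate_shift(p, p)$shift, 0)
  p_shift <- bump_profile(65, 1)   # moved 10 bp toward the TSS
  expect_equal(estimate_shift(p, p_shift, method = "xcorr")$shift, -10)
  expect_equal(estimate_shift(p, p_shift, method = "edge_delta")$shift,
               -10)
  expect_true(is.na(estimate_shift(p, p * 0)$shift))
})

test_that("xcorr and edge_delta agree on noiseless translations", {
  for (s in c(-20, -5, 0, 5, 20)) {
    p <- bump_profile(80, 1)
    q <- bump_profile(80 + s, 1)
    xs <- estimate_shift(p, q, method = "xcorr")$shift
    es <- estimate_shift(p, q, method = "edge_delta")$shift
    expect_lte(abs(xs - s), 3)
    expect_lte(abs(xs - es), 3)
  }
})

test_that("generator kd_shift is recovered from simulated fragments", {
  cfg <- generator_config(n_genes = 100, kd_shift = 10, seed = 7)
  g <- make_genome(cfg)
  lens <- c(chrS = cfg$chrom_len)
  mc <- anchor_matrix(compute_occupancy(simulate_mnase(g, "control", cfg),
                                        lens), g$promoters)
  mk <- anchor_matrix(compute_occupancy(simulate_mnase(g, "knockdown",
                                                       cfg), lens),
                      g$promoters)
  st <- shift_table(mc, mk)
  tgt <- g$truth$is_nsl_target[match(st$gene, g$truth$gene)]
  expect_lt(abs(mean(st$shift[tgt], na.rm = TRUE) + 10), 2)
  expect_lt(abs(mean(st$shift[!tgt], na.rm = TRUE)), 2)
})

test_that("shift recovery is robust to halved or doubled fragment counts", {
  for (fp in c(100, 400)) {
    cfg <- generator_config(n_genes = 80, kd_shift = 10,
                            frags_per_gene = fp, seed = 8)
    g <- make_genome(cfg)
    lens <- c(chrS = cfg$chrom_len)
    mc <- anchor_matrix(compute_occupancy(
      simulate_mnase(g, "control", cfg), lens), g$promoters)
    mk <- anchor_matrix(compute_occupancy(
      simulate_mnase(g, "knockdown", cfg), lens), g$promoters)
    st <- shift_table(mc, mk)
    tgt <- g$truth$is_nsl_target[match(st$gene, g$truth$gene)]
    expect_lt(abs(mean(st$shift[tgt], na.rm = TRUE) + 10), 2)
  }
})

test_that("anchored results are invariant under a global strand flip", {
  cfg <- small_config(jitter_sd = 5)
  g <- make_genome(cfg)
  lens <- c(chrS = cfg$chrom_len)
  occ <- compute_occupancy(simulate_mnase(g, "control", cfg), lens)
  m1 <- anchor_matrix(occ, g$promoters)
  # flip every strand and mirror the track: anchored rows are unchanged
  L <- cfg$chrom_len
  occ_rev <- Track(list(chrS = rev(occ[["chrS"]])))
  prom_rev <- g$promoters
  prom_rev$tss <- L - 1L - prom_rev$tss
  prom_rev$strand <- ifelse(prom_rev$strand == "+", "-", "+")
  m2 <- anchor_matrix(occ_rev, prom_rev)
  expect_equal(m1, m2)
})

test_that("quantile groups are equal-size with deterministic tie-break", {
  shifts <- data.frame(gene = sprintf("g%02d", 1:20), shift = rnorm(20))
  enr <- structure(rep(1, 20), names = shifts$gene)  # constant enrichment
  q <- shift_by_enrichment_quantile(shifts, enr, 5)
  expect_equal(q$n, rep(4L, 5))
  q2 <- shift_by_enrichment_quantile(shifts, enr, 5)
  expect_identical(q, q2)
  expect_error(shift_by_enrichment_quantile(shifts, enr, 21), "exceeds")
})

test_that("occupancy differences expose the NDR invasion signature", {
  m <- matrix(1, 4, 1501,
              dimnames = list(paste0("g", 1:4), -500:1000))
  d0 <- occupancy_difference(m, m)
  expect_true(all(d0$delta == 0))
  expect_true(all(d0$zones$ndr_delta == 0))
  expect_error(occupancy_difference(m, m[, 1:100]), "share")

  cfg <- generator_config(n_genes = 100, seed = 13)
  g <- make_genome(cfg)
  lens <- c(chrS = cfg$chrom_len)
  mc <- anchor_matrix(compute_occupancy(simulate_mnase(g, "control", cfg),
                                        lens), g$promoters)
  mk <- anchor_matrix(compute_occupancy(simulate_mnase(g, "knockdown",
                                                       cfg), lens),
                      g$promoters)
  z <- occupancy_difference(mc, mk)$zones
  tgt <- g$truth$is_nsl_target[match(z$gene, g$truth$gene)]
  expect_gt(mean(z$ndr_delta[tgt]), 0.5)
  expect_lt(mean(z$plus1_delta[tgt]), -0.5)
  expect_lt(abs(mean(z$ndr_delta[!tgt])), 0.1)
  expect_lt(abs(mean(z$plus1_delta[!tgt])), 0.5)
})
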