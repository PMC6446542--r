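# Shared fixtures and independent oracles used across test files.

# A small, fast generator configuration; individual tests override fields.
small_config <- function(...) {
  generator_config(n_genes = 60, frags_per_gene = 150, seed = 101, ...)
}

# Brute-force optimal 2-partition of 1-D values by within-cluster sum of
# squares over all threshold splits (independent oracle for kmeans2_split).
best_threshold_split <- function(values) {
  ord <- order(values)
  v <- values[ord]
  n <- length(v)
  best_ss <- Inf
  best_k <- 1
  for (k in 1:(n - 1)) {
    lo <- v[1:k]; hi <- v[(k + 1):n]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss) { best_ss <- ss; best_k <- k }
  }
  labels <- logical(n)
  labels[ord[(best_k + 1):n]] <- TRUE
  labels
}

# Naive per-window AT-fraction scan of an oriented character sequence
# (independent oracle for at_features).
naive_at_windows <- function(seq_chr, n_win = 61, win_bp = 29) {
  vapply(seq_len(n_win), function(w) {
    sub <- seq_chr[(win_bp * (w - 1) + 1):(win_bp * w)]
    sub <- sub[sub %in% c("A", "C", "G", "T")]
    mean(sub %in% c("A", "T"))
  }, numeric(1))
}

# Partial correlation via the textbook regression-residual definition
# (independent oracle for kmer_partial_screen).
partial_cor_lm <- function(y, x, z) {
  cor(stats::residuals(stats::lm(y ~ z)),
      stats::residuals(stats::lm(x ~ z)))
}

# An anchored profile (named vector) with Gaussian bumps at given oriented
# positions and heights.
bump_profile <- function(centers, heights, window = c(-500, 1000),
                         sd = 25) {
  pos <- seq(window[1], window[2])
  v <- numeric(length(pos))
  for (i in seq_along(centers))
    v <- v + heights[i] * exp(-(pos - centers[i])^2 / (2 * sd^2))
  names(v) <- pos
  v
}

# Long-format TSS count table from per-position counts for one gene.
tss_table <- function(pos, counts_ctrl, counts_kd, strand = "+",
                      gene = "g1") {
  rbind(
    data.frame(gene = gene, chrom = "chrS", pos = pos, strand = strand,
               condition = "control", count = counts_ctrl),
    data.frame(gene = gene, chrom = "chrS", pos = pos, strand = strand,
               condition = "knockdown", count = counts_kd)
  )
}
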