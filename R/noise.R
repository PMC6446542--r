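#' Cell and gene filters for single-cell matrices
#'
#' @param min_genes_per_cell keep cells with more than this many expressed
#'   (nonzero) genes (default 2000).
#' @param min_cell_fraction_per_gene then keep genes expressed in more
#'   than this fraction of the kept cells (default 0.5).
#' @return list of class `nslchrom_cellfilter`.
#' @export
cell_filter <- function(min_genes_per_cell = 2000,
                        min_cell_fraction_per_gene = 0.5) {
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_cell_fraction_per_gene = min_cell_fraction_per_gene),
            class = "nslchrom_cellfilter")
}

#' Filter cells, then genes, of a count matrix
#'
#' Cells with more than `min_genes_per_cell` expressed genes are kept;
#' among those cells, genes expressed in more than
#' `min_cell_fraction_per_gene` of cells are kept. Row and column order is
#' preserved.
#'
#' @param matrix integer count matrix, cells x genes.
#' @param filter a [cell_filter()].
#' @return The filtered matrix.
#' @export
filter_cells_genes <- function(matrix, filter = cell_filter()) {
  if (any(matrix < 0) || any(matrix != round(matrix)))
    stopf("counts must be non-negative integers")
  keep_cells <- rowSums(matrix > 0) > filter$min_genes_per_cell
  if (!any(keep_cells))
    stopf("no cells pass the >%d expressed-genes filter (0 of %d)",
          filter$min_genes_per_cell, nrow(matrix))
  m <- matrix[keep_cells, , drop = FALSE]
  keep_genes <- colMeans(m > 0) > filter$min_cell_fraction_per_gene
  if (!any(keep_genes))
    stopf("no genes expressed in >%g of the %d kept cells (0 of %d genes)",
          filter$min_cell_fraction_per_gene, nrow(m), ncol(m))
  m[, keep_genes, drop = FALSE]
}

# Median-of-ratios size factors; falls back to library-size factors when
# fewer than `min_ref_genes` genes are expressed in every cell.
size_factors <- function(matrix, min_ref_genes = 50) {
  all_pos <- colSums(matrix > 0) == nrow(matrix)
  if (sum(all_pos) >= min_ref_genes) {
    ref <- exp(colMeans(log(matrix[, all_pos, drop = FALSE])))
    sf <- apply(sweep(matrix[, all_pos, drop = FALSE], 2, ref, "/"), 1,
                median)
  } else {
    sf <- rowSums(matrix)
    sf <- sf / mean(sf)
  }
  sf / exp(mean(log(sf)))
}

# Per-gene log CV^2 residual after removing the running-median trend on
# log mean. Operates on a normalized matrix; returns NA for genes with
# zero variance or zero mean. The fitted trend function is attached as an
# attribute; passing `trend` evaluates residuals against that external
# trend instead of refitting.
cv2_residual <- function(norm, trend = NULL) {
  nn <- nrow(norm)
  mu <- colMeans(norm)
  v <- (colSums(norm^2) - nn * mu^2) / (nn - 1)
  v <- pmax(v, 0)
  ok <- mu > 0 & v > 0
  res <- rep(NA_real_, ncol(norm))
  lm_ <- log(mu[ok])
  lc <- log(v[ok] / mu[ok]^2)
  if (is.null(trend)) {
    ord <- order(lm_)
    k <- min(31L, 2L * (sum(ok) %/% 2L) - 1L)
    if (k < 3) {
      md <- median(lc)
      trend <- function(x) rep(md, length(x))
    } else {
      sm <- numeric(length(lc))
      sm[ord] <- runmed(lc[ord], k, endrule = "median")
      trend <- stats::approxfun(lm_[ord], sm[ord], rule = 2,
                                ties = mean)
    }
  }
  res[ok] <- lc - trend(lm_)
  names(res) <- colnames(norm)
  attr(res, "trend") <- trend
  res
}

#' Mean-trend-corrected dispersion residuals
#'
#' Normalizes cells by median-of-ratios size factors (library-size
#' fallback when zeros dominate), computes each gene's log CV^2, removes
#' the running-median trend of log CV^2 on log mean, and returns the
#' residual — a mean-independent per-gene measure of transcriptional
#' noise.
#'
#' @param matrix integer count matrix, cells x genes (>= 50 genes).
#' @return Named numeric vector of residuals (`NA` for zero-variance
#'   genes).
#' @export
residual_dispersion <- function(matrix) {
  if (ncol(matrix) < 50)
    stopf("need >= 50 genes to fit the mean-CV2 trend (got %d)",
          ncol(matrix))
  norm <- sweep(matrix, 1, size_factors(matrix), "/")
  cv2_residual(norm)
}

# Non-DE screen: genes with |log2FC| < fc_max between conditions and a
# Welch t-test q-value > q_min on size-factor-normalized per-cell counts.
# (A binomial test on summed counts would assume Poisson-scale variance
# and mis-flag equal-mean overdispersed genes as differential.)
screen_non_de <- function(mat_ctrl, mat_kd, fc_max = 0.25, q_min = 0.3) {
  nc_ <- sweep(mat_ctrl, 1, size_factors(mat_ctrl), "/")
  nk_ <- sweep(mat_kd, 1, size_factors(mat_kd), "/")
  mc <- colMeans(nc_); mk <- colMeans(nk_)
  l2fc <- log2((mk + 1e-9) / (mc + 1e-9))
  p <- vapply(seq_len(ncol(nc_)), function(i) {
    if (var(nc_[, i]) == 0 && var(nk_[, i]) == 0) return(1)
    t.test(nk_[, i], nc_[, i])$p.value
  }, numeric(1))
  q <- p.adjust(p, "BH")
  colnames(mat_ctrl)[abs(l2fc) < fc_max & q > q_min]
}

#' Permutation test for differential transcriptional noise
#'
#' A stand-in for spike-in-calibrated Bayesian differential-variability
#' models (outputs are labelled `noise_stand_in`): for genes whose mean
#' expression does not change between conditions, tests whether the
#' mean-trend-corrected log CV^2 residual increases in knockdown. The null
#' is generated by permuting cell condition labels; size factors are
#' computed once on the pooled cells and observed and permuted deltas go
#' through the identical code path.
#'
#' @param mat_ctrl,mat_kd integer count matrices, cells x genes (same
#'   genes; >= 20 cells each).
#' @param non_de_genes character vector of genes to test; `NULL` screens
#'   for non-differential genes (|log2FC| < 0.25 and Welch t-test
#'   q > 0.3 on normalized per-cell counts).
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed (default 0).
#' @param fdr FDR level for the `increased` flag (default 0.1).
#' @return data.frame of class column `noise_stand_in`: gene, mean_ctrl,
#'   mean_kd, disp_ctrl, disp_kd, delta, p (two-sided), p_up (one-sided
#'   increase), q (BH on p_up), increased.
#' @export
test_differential_noise <- function(mat_ctrl, mat_kd, non_de_genes = NULL,
                                    n_perm = 1000, seed = 0, fdr = 0.1) {
  if (nrow(mat_ctrl) < 20 || nrow(mat_kd) < 20)
    stopf("need >= 20 cells per condition (got %d and %d)",
          nrow(mat_ctrl), nrow(mat_kd))
  stopifnot(identical(colnames(mat_ctrl), colnames(mat_kd)))
  if (is.null(non_de_genes))
    non_de_genes <- screen_non_de(mat_ctrl, mat_kd)
  genes <- intersect(colnames(mat_ctrl), non_de_genes)
  if (length(genes) < 50)
    stopf("fewer than 50 testable non-DE genes (%d)", length(genes))
  pooled <- rbind(mat_ctrl[, genes, drop = FALSE],
                  mat_kd[, genes, drop = FALSE])
  norm <- sweep(pooled, 1, size_factors(pooled), "/")
  n1 <- nrow(mat_ctrl)
  n <- nrow(pooled)
  # Both groups are measured against one mean-CV2 trend, fitted on the
  # control-labelled group: a per-condition trend would absorb a global
  # dispersion change into the knockdown trend and cancel the signal.
  delta_fn <- function(idx_ctrl) {
    rc <- cv2_residual(norm[idx_ctrl, , drop = FALSE])
    rk <- cv2_residual(norm[-idx_ctrl, , drop = FALSE],
                       trend = attr(rc, "trend"))
    as.numeric(rk - rc)
  }
  obs <- delta_fn(seq_len(n1))
  exceed2 <- exceed1 <- rep(0L, length(genes))
  local_seed(seed, {
    for (b in seq_len(n_perm)) {
      d <- delta_fn(sample.int(n, n1))
      exceed2 <- exceed2 + as.integer(!is.na(d) & !is.na(obs) &
                                        abs(d) >= abs(obs))
      exceed1 <- exceed1 + as.integer(!is.na(d) & !is.na(obs) & d >= obs)
    }
  })
  testable <- !is.na(obs)
  p <- p_up <- rep(NA_real_, length(genes))
  p[testable] <- pmax((exceed2[testable] + 1) / (n_perm + 1),
                      1 / (n_perm + 1))
  p_up[testable] <- pmax((exceed1[testable] + 1) / (n_perm + 1),
                         1 / (n_perm + 1))
  q <- rep(NA_real_, length(genes))
  q[testable] <- p.adjust(p_up[testable], "BH")
  rc <- cv2_residual(norm[seq_len(n1), , drop = FALSE])
  rk <- cv2_residual(norm[-seq_len(n1), , drop = FALSE],
                     trend = attr(rc, "trend"))
  data.frame(
    gene = genes,
    mean_ctrl = colMeans(norm[seq_len(n1), , drop = FALSE]),
    mean_kd = colMeans(norm[-seq_len(n1), , drop = FALSE]),
    disp_ctrl = as.numeric(rc), disp_kd = as.numeric(rk),
    delta = obs,
    p = p, p_up = p_up, q = q,
    increased = !is.na(q) & q < fdr & obs > 0,
    noise_stand_in = TRUE,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
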