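AT_N_WINDOWS <- 61L
AT_WINDOW_BP <- 29L
AT_FLANK <- 884L   # 61 x 29 = 1769 bp total, centered on the TSS

#' Strand-oriented promoter sequences
#'
#' Extracts the sequence covering oriented positions
#' `[-upstream, downstream]` around each TSS, reverse-complementing
#' minus-strand promoters so every sequence reads 5' to 3' in the
#' direction of transcription. Promoters too close to a contig edge are
#' dropped with a warning.
#'
#' @param seqs genome as a [Biostrings::DNAStringSet].
#' @param promoters data.frame with chrom, tss, strand, gene.
#' @param upstream,downstream extent in bp (defaults 884/884).
#' @return Named [Biostrings::DNAStringSet] (names = gene ids).
#' @export
promoter_sequences <- function(seqs, promoters, upstream = AT_FLANK,
                               downstream = AT_FLANK) {
  width <- upstream + downstream + 1L
  keep <- logical(nrow(promoters))
  out <- vector("list", nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    s <- seqs[[promoters$chrom[i]]]
    plus <- promoters$strand[i] == "+"
    lo <- if (plus) promoters$tss[i] - upstream else
      promoters$tss[i] - downstream
    if (lo < 0 || lo + width > length(s)) next
    sub <- Biostrings::subseq(s, start = lo + 1L, width = width)
    if (!plus) sub <- Biostrings::reverseComplement(sub)
    out[[i]] <- sub
    keep[i] <- TRUE
  }
  if (any(!keep))
    warnf("%d promoter(s) with insufficient sequence were dropped",
          sum(!keep))
  res <- Biostrings::DNAStringSet(out[keep])
  names(res) <- promoters$gene[keep]
  res
}

#' AT-fraction features over 61 contiguous 29-bp windows
#'
#' Window `i` (1-based) covers oriented positions
#' `[-884 + 29 (i - 1), -884 + 29 i)` relative to the TSS; its feature is
#' the AT fraction of the window with ambiguous bases excluded from both
#' numerator and denominator.
#'
#' @param seqs genome [Biostrings::DNAStringSet].
#' @param promoters data.frame with chrom, tss, strand, gene.
#' @return Numeric matrix, genes x 61, with window start positions as
#'   column names.
#' @export
at_features <- function(seqs, promoters) {
  prom_seq <- promoter_sequences(seqs, promoters,
                                 upstream = AT_FLANK,
                                 downstream = AT_FLANK)
  # oriented span used: [-884, 884]; 61 windows of 29 bp = positions
  # -884 .. 884 (1769 bp); prom_seq is exactly that span
  feat <- matrix(NA_real_, nrow = length(prom_seq), ncol = AT_N_WINDOWS,
                 dimnames = list(names(prom_seq),
                                 -AT_FLANK + AT_WINDOW_BP *
                                   (seq_len(AT_N_WINDOWS) - 1L)))
  for (w in seq_len(AT_N_WINDOWS)) {
    v <- Biostrings::subseq(prom_seq,
                            start = AT_WINDOW_BP * (w - 1L) + 1L,
                            width = AT_WINDOW_BP)
    at <- Biostrings::letterFrequency(v, "AT")
    acgt <- Biostrings::letterFrequency(v, "ACGT")
    feat[, w] <- ifelse(acgt > 0, at / acgt, NA_real_)
  }
  feat
}

# Stratified fold assignment: seeded shuffle within class, round-robin.
stratified_folds <- function(labels, folds, seed) {
  local_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

# One logistic fit used by the CV harness: ridge (glmnet, alpha = 0) for
# multi-feature matrices; plain glm for a single feature, where no
# stabilization is needed. Returns coefficient vector (no intercept) and a
# predict(newx) closure giving probabilities.
fit_logistic <- function(x, y, lambda) {
  if (ncol(x) >= 2) {
    fit <- glmnet::glmnet(x, factor(y), family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    list(
      coefs = as.numeric(coef(fit))[-1],
      predict = function(newx)
        as.numeric(predict(fit, newx, type = "response"))
    )
  } else {
    df <- data.frame(y = y, x = x[, 1])
    fit <- suppressWarnings(
      stats::glm(y ~ x, data = df, family = stats::binomial()))
    list(
      coefs = unname(coef(fit)[-1]),
      predict = function(newx)
        as.numeric(predict(fit, data.frame(x = newx[, 1]),
                           type = "response"))
    )
  }
}

#' Cross-validated logistic prediction of binding from AT features
#'
#' Stratified 10-fold cross-validation of an L2-regularized logistic
#' regression of the bound/unbound label on the 61 AT-window features.
#' Out-of-fold probabilities are thresholded at 0.5; "correct prediction"
#' is reported per class as sensitivity (recall on true targets) and
#' specificity (recall on non-targets). Per-window slopes are collected
#' across the fold fits and tested against zero with a one-sample t-test
#' whose variance is corrected for the overlap of CV training sets (fold
#' estimates are strongly correlated; the naive t-test is anti-
#' conservative).
#'
#' @param features genes x windows numeric matrix ([at_features()] output,
#'   or any feature matrix).
#' @param labels logical vector (TRUE = bound), aligned with feature rows.
#' @param folds number of CV folds (default 10).
#' @param seed seed for the fold assignment (default 0).
#' @param lambda ridge penalty; default `1 / n_train` (a unit-weight L2
#'   penalty on the summed log-likelihood scale).
#' @param threshold probability cutoff (default 0.5).
#' @return List of class `nslchrom_cvreport`: `fold`, `prob`, `pred`,
#'   `sensitivity`, `specificity`, `accuracy`, `slopes` (windows x folds),
#'   `slope_tests` (data.frame: window, position, mean_slope, t, p,
#'   significant).
#' @export
fit_at_logistic <- function(features, labels, folds = 10, seed = 0,
                            lambda = NULL, threshold = 0.5) {
  stopifnot(nrow(features) == length(labels))
  keep <- complete.cases(features)
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  if (sum(labels) < 2 || sum(!labels) < 2)
    stopf("need at least 2 genes per class")
  fold <- stratified_folds(labels, folds, seed)
  for (f in seq_len(folds))
    if (length(unique(labels[fold != f])) < 2)
      stopf("fold %d leaves a single-class training set; provide more data",
            f)
  prob <- numeric(length(labels))
  slopes <- matrix(NA_real_, nrow = ncol(features), ncol = folds,
                   dimnames = list(colnames(features), NULL))
  for (f in seq_len(folds)) {
    tr <- fold != f
    lam <- lambda %||% (1 / sum(tr))
    fit <- fit_logistic(features[tr, , drop = FALSE], labels[tr], lam)
    slopes[, f] <- fit$coefs
    prob[!tr] <- fit$predict(features[!tr, , drop = FALSE])
  }
  pred <- prob >= threshold
  # One-sample t-test of the fold slopes against zero, with the variance
  # corrected for fold overlap: two training sets share a fraction
  # rho = (J - 2)/(J - 1) of their samples, so the fold estimates are
  # correlated ~rho and the naive s^2/J variance of the mean is far too
  # small. Var(mean) ~= sigma^2 (1/J + rho (J - 1)/J) with sigma^2
  # estimated from the across-fold spread as s^2/(1 - rho).
  J <- ncol(slopes)
  rho <- (J - 2) / (J - 1)
  tests <- t(apply(slopes, 1, function(s) {
    se <- sd(s) / sqrt(1 - rho) * sqrt(1 / J + rho * (J - 1) / J)
    tv <- if (se > 0) mean(s) / se else 0
    c(mean_slope = mean(s), t = tv,
      p = 2 * pt(-abs(tv), df = J - 1))
  }))
  pos <- suppressWarnings(as.integer(rownames(slopes)))
  slope_tests <- data.frame(
    window = seq_len(nrow(slopes)),
    position = if (all(!is.na(pos))) pos else NA_integer_,
    mean_slope = tests[, "mean_slope"], t = tests[, "t"], p = tests[, "p"],
    significant = tests[, "p"] < 0.05, row.names = NULL
  )
  structure(list(
    fold = structure(fold, names = rownames(features)),
    prob = structure(prob, names = rownames(features)),
    pred = structure(pred, names = rownames(features)),
    labels = labels,
    sensitivity = mean(pred[labels]),
    specificity = mean(!pred[!labels]),
    accuracy = mean(pred == labels),
    slopes = slopes, slope_tests = slope_tests
  ), class = "nslchrom_cvreport")
}

#' @export
print.nslchrom_cvreport <- function(x, ...) {
  cat(sprintf(
    "<CV report> %d genes, %d folds | sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
    length(x$fold), max(x$fold), x$sensitivity, x$specificity, x$accuracy))
  cat(sprintf("  significant windows (p < 0.05): %d of %d\n",
              sum(x$slope_tests$significant), nrow(x$slope_tests)))
  invisible(x)
}

#' Per-window signed slope significance aligned to promoter coordinates
#'
#' Flags AT windows whose cross-validated slope differs from zero
#' (p < 0.05) with the slope sign (positive = high AT predicts bound), and
#' optionally attaches the mean anchored nucleosome occupancy of each
#' window so the spatial pattern (AT predictive upstream, anti-predictive
#' over the +1 nucleosome) can be read off.
#'
#' @param report a [fit_at_logistic()] report.
#' @param nucleosome_profile optional named numeric vector of mean
#'   occupancy by oriented position (e.g. `colMeans(anchor_matrix(...))`).
#' @return data.frame: window, start, center, mean_slope, t, p,
#'   significant, sign, occupancy.
#' @export
window_slope_profile <- function(report, nucleosome_profile = NULL) {
  st <- report$slope_tests
  start <- -AT_FLANK + AT_WINDOW_BP * (st$window - 1L)
  center <- start + AT_WINDOW_BP %/% 2L
  occ <- rep(NA_real_, nrow(st))
  if (!is.null(nucleosome_profile)) {
    pos <- as.integer(names(nucleosome_profile))
    occ <- vapply(seq_len(nrow(st)), function(i) {
      sel <- pos >= start[i] & pos < start[i] + AT_WINDOW_BP
      if (any(sel)) mean(nucleosome_profile[sel]) else NA_real_
    }, numeric(1))
  }
  data.frame(window = st$window, start = start, center = center,
             mean_slope = st$mean_slope, t = st$t, p = st$p,
             significant = st$significant,
             sign = sign(st$mean_slope), occupancy = occ)
}

ALL_5MERS <- local({
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, stringsAsFactors = FALSE)
  # column order matches Biostrings::oligonucleotideFrequency
  sort(apply(g, 1, paste, collapse = ""))
})

#' All-5-mer partial-correlation screen against in vitro binding
#'
#' For every 5-mer, the partial correlation of its per-bin frequency with
#' the bin log enrichment, given the bin AT fraction: both variables are
#' residualized on AT fraction by simple linear regression and the Pearson
#' correlation of the residuals is taken, with
#' `t = r * sqrt((n - 2) / (1 - r^2))`. A 5-mer's frequency is its
#' sliding-window count divided by 196 (the number of 5-mer positions in a
#' 200-bp bin). 5-mers are counted on the given strand only.
#'
#' @param sequences [Biostrings::DNAStringSet] of the 200-bp bin sequences.
#' @param log_enrichment numeric vector of per-bin log enrichments.
#' @return data.frame with 1024 rows: kmer, partial_r, t_stat, n,
#'   zero_variance, sorted by decreasing |t_stat|.
#' @export
kmer_partial_screen <- function(sequences, log_enrichment) {
  n <- length(sequences)
  stopifnot(length(log_enrichment) == n)
  if (n < 1026)
    warnf("only %d bins for a 1024-predictor screen; >= 1026 recommended", n)
  at <- as.numeric(Biostrings::letterFrequency(sequences, "AT",
                                               as.prob = TRUE))
  counts <- Biostrings::oligonucleotideFrequency(sequences, width = 5L)
  wmax <- max(Biostrings::width(sequences)) - 4L
  freq <- counts / wmax
  resid_on <- function(y, x) {
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    y - mean(y) - b * (x - mean(x))
  }
  re <- resid_on(log_enrichment, at)
  # enrichment exactly affine in AT: nothing left to correlate (guard
  # against correlating numerical roundoff)
  if (sum(re^2) < 1e-12 * max(1, sum((log_enrichment -
                                        mean(log_enrichment))^2)))
    re[] <- 0
  fc <- sweep(freq, 2, colMeans(freq))
  ac <- at - mean(at)
  beta <- as.numeric(crossprod(ac, fc)) / sum(ac^2)
  rk <- fc - outer(ac, beta)
  sds <- sqrt(colSums(rk^2))
  zero_var <- sds == 0 | apply(freq, 2, function(v) var(v) == 0)
  r <- numeric(ncol(freq))
  de <- sqrt(sum(re^2))
  nz <- !zero_var & de > 0
  if (any(nz))
    r[nz] <- as.numeric(crossprod(re, rk[, nz])) / (de * sds[nz])
  r <- pmin(pmax(r, -1), 1)
  t_stat <- ifelse(zero_var, 0, r * sqrt((n - 2) / pmax(1 - r^2, 1e-300)))
  out <- data.frame(kmer = colnames(freq), partial_r = r, t_stat = t_stat,
                    n = n, zero_variance = zero_var,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-abs(out$t_stat)), , drop = FALSE]
}

#' Compare sequence predictors of in vivo binding
#'
#' Runs the same cross-validation harness as [fit_at_logistic()] with
#' three predictors of NSL binding: the full 61-window AT profile, the
#' count of a DRE consensus motif in the TSS +/- 884 bp span, and the
#' count of a randomly chosen 5-mer; reports the fraction of correct
#' predictions per predictor.
#'
#' @param seqs genome [Biostrings::DNAStringSet].
#' @param promoters data.frame with chrom, tss, strand, gene.
#' @param labels named logical vector of in vivo binding (names = genes).
#' @param dre_pattern DRE consensus as a literal pattern (default
#'   "TATCGATA").
#' @param folds,seed CV parameters.
#' @return data.frame: predictor, accuracy, sensitivity, specificity.
#' @export
compare_predictors <- function(seqs, promoters, labels,
                               dre_pattern = DRE_MOTIF, folds = 10,
                               seed = 0) {
  prom_seq <- promoter_sequences(seqs, promoters)
  labels <- labels[names(prom_seq)]
  feats <- list(
    "AT-profile" = at_features(seqs, promoters)[names(prom_seq), ,
                                                drop = FALSE],
    "DRE-motif-count" = matrix(
      Biostrings::vcountPattern(dre_pattern, prom_seq),
      ncol = 1, dimnames = list(names(prom_seq), "dre")),
    "random-5mer-count" = local_seed(seed + 1L, {
      km <- sample(ALL_5MERS, 1)
      matrix(Biostrings::vcountPattern(km, prom_seq), ncol = 1,
             dimnames = list(names(prom_seq), km))
    })
  )
  rows <- lapply(names(feats), function(nm) {
    rep_ <- fit_at_logistic(feats[[nm]], labels, folds = folds, seed = seed)
    data.frame(predictor = nm, accuracy = rep_$accuracy,
               sensitivity = rep_$sensitivity,
               specificity = rep_$specificity, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
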