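#' Nucleosome occupancy from MNase fragments
#'
#' Piles up fragment midpoints per base, smooths with a Gaussian kernel,
#' and applies RPGC ("reads per genomic content") normalization so the
#' genome-wide mean signal is exactly 1. A fragment `[start, end)` has
#' midpoint `floor((start + end) / 2)`.
#'
#' @param fragments data.frame with chrom, start, end (0-based half-open).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param smoothing_sd Gaussian smoothing bandwidth in bp (default 20;
#'   0 disables smoothing).
#' @return A [Track()]; all-zero (with a warning) if no fragments.
#' @export
compute_occupancy <- function(fragments, chrom_lengths, smoothing_sd = 20) {
  sig <- lapply(names(chrom_lengths), function(nm) numeric(chrom_lengths[[nm]]))
  names(sig) <- names(chrom_lengths)
  if (nrow(fragments) == 0) {
    warnf("no fragments: returning an all-zero track")
    return(Track(sig))
  }
  if (any(!fragments$chrom %in% names(chrom_lengths)))
    stopf("fragment on unknown chromosome '%s'",
          setdiff(fragments$chrom, names(chrom_lengths))[1])
  for (nm in unique(fragments$chrom)) {
    f <- fragments[fragments$chrom == nm, , drop = FALSE]
    len <- chrom_lengths[[nm]]
    if (any(f$start < 0 | f$end > len))
      stopf("fragment outside chromosome bounds on %s", nm)
    mids <- (f$start + f$end) %/% 2L
    sig[[nm]] <- smooth_gaussian(
      tabulate(mids + 1L, nbins = len), smoothing_sd)
  }
  tr <- Track(sig)
  Track(lapply(tr, function(v) v / track_mean(tr)))  # RPGC: mean = 1
}

#' Promoter-anchored signal matrix
#'
#' Extracts a window of track signal around every promoter's TSS and
#' orients each row in the direction of transcription (minus-strand rows
#' are reversed), so that positive positions are always downstream of the
#' TSS. Promoters whose window would run off the chromosome are dropped
#' with a warning.
#'
#' @param track a [Track()].
#' @param promoters data.frame with chrom, tss (0-based genomic position of
#'   the TSS base), strand, gene.
#' @param window integer length-2, window relative to the TSS in oriented
#'   coordinates (default `c(-500, 1000)`).
#' @return Numeric matrix, genes x positions; row names are gene ids,
#'   column names the oriented positions `window[1]:window[2]`.
#' @export
anchor_matrix <- function(track, promoters, window = c(-500, 1000)) {
  stopifnot(length(window) == 2, window[1] < window[2])
  rel <- seq.int(window[1], window[2])
  rows <- vector("list", nrow(promoters))
  ok <- logical(nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    v <- track[[promoters$chrom[i]]]
    if (is.null(v)) stopf("promoter chromosome '%s' not in track",
                          promoters$chrom[i])
    pos <- oriented_pos(promoters$tss[i], promoters$strand[i], rel)
    if (min(pos) < 0 || max(pos) >= length(v)) next
    rows[[i]] <- v[pos + 1L]
    ok[i] <- TRUE
  }
  if (any(!ok))
    warnf("%d promoter(s) too close to a contig edge were dropped",
          sum(!ok))
  m <- do.call(rbind, rows[ok])
  rownames(m) <- promoters$gene[ok]
  colnames(m) <- rel
  m
}

# Oriented positions (integer) of a profile vector taken from its names.
profile_positions <- function(profile) {
  pos <- suppressWarnings(as.integer(names(profile)))
  if (any(is.na(pos)))
    stopf("profile must have integer position names (a row of anchor_matrix)")
  pos
}

#' Call the +1 nucleosome on an anchored profile
#'
#' The +1 dyad is the first local maximum at or downstream of the TSS
#' (within the search window) whose height is at least `min_prominence`
#' times the row maximum; its 5' edge is the dyad minus 73 bp (half of the
#' 147-bp nucleosome core).
#'
#' @param profile one row of an [anchor_matrix()] (named numeric vector).
#' @param search length-2 search window in oriented bp (default
#'   `c(0, 250)`).
#' @param min_prominence minimum height relative to the row maximum
#'   (default 0.25).
#' @return list with `dyad`, `five_prime_edge`, `occupancy`; all `NA` when
#'   no qualifying maximum exists.
#' @export
call_plus_one <- function(profile, search = c(0, 250),
                          min_prominence = 0.25) {
  stopifnot(all(is.finite(profile)))
  pos <- profile_positions(profile)
  null_call <- list(dyad = NA_integer_, five_prime_edge = NA_integer_,
                    occupancy = NA_real_)
  rowmax <- max(profile)
  if (rowmax <= 0) return(null_call)
  in_win <- which(pos >= search[1] & pos <= search[2])
  if (!length(in_win)) return(null_call)
  n <- length(profile)
  for (i in in_win) {
    left <- if (i > 1) profile[i - 1] else -Inf
    right <- if (i < n) profile[i + 1] else -Inf
    if (profile[i] >= left && profile[i] >= right &&
        profile[i] >= min_prominence * rowmax) {
      return(list(dyad = pos[i], five_prime_edge = pos[i] - 73L,
                  occupancy = unname(profile[i])))
    }
  }
  null_call
}

#' Estimate the +1 nucleosome shift between conditions
#'
#' Two estimators of the knockdown-minus-control displacement of the +1
#' nucleosome (negative = toward the TSS):
#' \describe{
#'   \item{xcorr}{argmax over integer lags of the cross-correlation between
#'     the control profile in a window around its +1 dyad and the knockdown
#'     profile displaced by the lag; ties broken toward the smallest
#'     absolute lag, then the negative one.}
#'   \item{edge_delta}{difference of called 5' edges,
#'     `edge_kd - edge_ctrl`.}
#' }
#'
#' @param profile_ctrl,profile_kd anchored profiles of the same gene
#'   (rows of [anchor_matrix()] for the two conditions).
#' @param region half-width (bp) of the correlation window around the
#'   control +1 dyad (default 100).
#' @param max_lag maximum |lag| searched (default 100).
#' @param method `"xcorr"` or `"edge_delta"`.
#' @param ... passed to [call_plus_one()].
#' @return list with `shift` (bp, `NA` when either +1 call is null) and
#'   `method`.
#' @export
estimate_shift <- function(profile_ctrl, profile_kd, region = 100,
                           max_lag = 100,
                           method = c("xcorr", "edge_delta"), ...) {
  method <- match.arg(method)
  c_ctrl <- call_plus_one(profile_ctrl, ...)
  c_kd <- call_plus_one(profile_kd, ...)
  if (is.na(c_ctrl$dyad) || is.na(c_kd$dyad))
    return(list(shift = NA_real_, method = method))
  if (method == "edge_delta")
    return(list(shift = c_kd$five_prime_edge - c_ctrl$five_prime_edge,
                method = method))
  pos <- profile_positions(profile_ctrl)
  win <- seq.int(c_ctrl$dyad - region, c_ctrl$dyad + region)
  lags <- seq.int(-max_lag, max_lag)
  score <- vapply(lags, function(l) {
    ic <- match(win, pos)
    ik <- match(win + l, pos)
    keep <- !is.na(ic) & !is.na(ik)
    if (sum(keep) < 10) return(-Inf)
    a <- profile_ctrl[ic[keep]]
    b <- profile_kd[ik[keep]]
    if (sd(a) == 0 || sd(b) == 0) return(-Inf)
    cor(a, b)
  }, numeric(1))
  best <- max(score)
  cand <- lags[score >= best - 1e-12]
  cand <- cand[order(abs(cand), cand)]  # smallest |lag|, then negative
  list(shift = cand[1], method = method)
}

#' Per-gene shift table for a promoter set
#'
#' Convenience wrapper running [estimate_shift()] over all shared rows of
#' two anchored matrices.
#'
#' @param mat_ctrl,mat_kd anchored occupancy matrices (same window).
#' @param method passed to [estimate_shift()].
#' @param ... passed to [estimate_shift()].
#' @return data.frame: gene, shift, method.
#' @export
shift_table <- function(mat_ctrl, mat_kd, method = "xcorr", ...) {
  genes <- intersect(rownames(mat_ctrl), rownames(mat_kd))
  shifts <- vapply(genes, function(g)
    estimate_shift(mat_ctrl[g, ], mat_kd[g, ], method = method, ...)$shift,
    numeric(1))
  data.frame(gene = genes, shift = shifts, method = method,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Mean +1 shift by enrichment quantile group
#'
#' Splits genes into `n_groups` equal-size quantile bins of a per-gene
#' enrichment value (ties broken deterministically by gene id) and reports
#' the mean shift per bin, group 1 = lowest enrichment.
#'
#' @param shifts data.frame with gene, shift.
#' @param enrichment named numeric vector (names = gene ids) or data.frame
#'   with gene, enrichment.
#' @param n_groups number of quantile groups (default 5).
#' @return data.frame: group, n, mean_enrichment, mean_shift.
#' @export
shift_by_enrichment_quantile <- function(shifts, enrichment, n_groups = 5) {
  if (is.data.frame(enrichment))
    enrichment <- structure(enrichment$enrichment, names = enrichment$gene)
  genes <- intersect(shifts$gene, names(enrichment))
  if (n_groups > length(genes))
    stopf("n_groups (%d) exceeds number of genes (%d)", n_groups,
          length(genes))
  e <- enrichment[genes]
  s <- structure(shifts$shift, names = shifts$gene)[genes]
  ord <- order(e, genes)                      # tie-break by gene id
  grp <- integer(length(genes))
  grp[ord] <- ceiling(seq_along(ord) * n_groups / length(ord))
  out <- data.frame(
    group = seq_len(n_groups),
    n = as.integer(table(factor(grp, levels = seq_len(n_groups)))),
    mean_enrichment = vapply(seq_len(n_groups), function(g)
      mean(e[grp == g]), numeric(1)),
    mean_shift = vapply(seq_len(n_groups), function(g)
      mean(s[grp == g], na.rm = TRUE), numeric(1))
  )
  out
}

#' Occupancy difference matrix and promoter-zone summaries
#'
#' Computes the per-cell knockdown-minus-control difference of two anchored
#' occupancy matrices, plus per-gene mean differences over the NDR zone
#' (oriented `[-150, 0)`) and the +1 zone (`[0, 150)`), the signature of
#' nucleosomes invading the NDR.
#'
#' @param mat_ctrl,mat_kd anchored matrices with identical genes and
#'   window.
#' @return list with `delta` (matrix), and `zones` (data.frame: gene,
#'   ndr_delta, plus1_delta).
#' @export
occupancy_difference <- function(mat_ctrl, mat_kd) {
  if (!identical(dim(mat_ctrl), dim(mat_kd)) ||
      !identical(rownames(mat_ctrl), rownames(mat_kd)) ||
      !identical(colnames(mat_ctrl), colnames(mat_kd)))
    stopf("matrices must share genes and window")
  delta <- mat_kd - mat_ctrl
  pos <- as.integer(colnames(delta))
  ndr <- pos >= -150 & pos < 0
  p1 <- pos >= 0 & pos < 150
  zones <- data.frame(
    gene = rownames(delta),
    ndr_delta = rowMeans(delta[, ndr, drop = FALSE]),
    plus1_delta = rowMeans(delta[, p1, drop = FALSE]),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(delta = delta, zones = zones)
}
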