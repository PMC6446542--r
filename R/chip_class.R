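#' Windowed log2 ChIP/input enrichment
#'
#' `log2((mean_ip + eps) / (mean_input + eps))` over an interval, with a
#' pseudocount guarding against empty windows on sparse tracks.
#'
#' @param ip,input [Track()] objects covering the interval.
#' @param chrom chromosome name.
#' @param start,end interval, 0-based half-open.
#' @param pseudocount epsilon added to both means (default 0.1).
#' @return A single numeric value.
#' @export
log2_enrichment <- function(ip, input, chrom, start, end,
                            pseudocount = 0.1) {
  mi <- mean(track_slice(ip, chrom, start, end))
  mn <- mean(track_slice(input, chrom, start, end))
  log2((mi + pseudocount) / (mn + pseudocount))
}

#' Per-promoter enrichment features for classification
#'
#' For each promoter: the summed log2(IP/input) of NSL3 and MBDR2 over the
#' TSS +/- 290 bp window (`nsl_sum`), and the mean difference of Pol II
#' log2 enrichment between control and knockdown over TSS +/- 145 bp
#' (`polII_delta`, positive = Pol II lost in knockdown).
#'
#' @param promoters data.frame with chrom, tss, strand, gene.
#' @param tracks named list of [Track()]s with elements `NSL3`, `MBDR2`,
#'   `PolII_control`, `PolII_knockdown`, `input`.
#' @param nsl_halfwidth,polII_halfwidth window half-widths in bp (defaults
#'   290 and 145).
#' @param pseudocount passed to [log2_enrichment()].
#' @return data.frame: gene, nsl_sum, polII_delta.
#' @export
promoter_enrichment <- function(promoters, tracks, nsl_halfwidth = 290,
                                polII_halfwidth = 145, pseudocount = 0.1) {
  need <- c("NSL3", "MBDR2", "PolII_control", "PolII_knockdown", "input")
  if (!all(need %in% names(tracks)))
    stopf("tracks must contain: %s", paste(need, collapse = ", "))
  n <- nrow(promoters)
  nsl_sum <- numeric(n)
  polII_delta <- numeric(n)
  for (i in seq_len(n)) {
    ch <- promoters$chrom[i]
    t0 <- promoters$tss[i]
    s1 <- t0 - nsl_halfwidth; e1 <- t0 + nsl_halfwidth + 1L
    s2 <- t0 - polII_halfwidth; e2 <- t0 + polII_halfwidth + 1L
    nsl_sum[i] <-
      log2_enrichment(tracks$NSL3, tracks$input, ch, s1, e1, pseudocount) +
      log2_enrichment(tracks$MBDR2, tracks$input, ch, s1, e1, pseudocount)
    polII_delta[i] <-
      log2_enrichment(tracks$PolII_control, tracks$input, ch, s2, e2,
                      pseudocount) -
      log2_enrichment(tracks$PolII_knockdown, tracks$input, ch, s2, e2,
                      pseudocount)
  }
  data.frame(gene = promoters$gene, nsl_sum = nsl_sum,
             polII_delta = polII_delta, stringsAsFactors = FALSE)
}

#' Two-class k-means split of a 1-D value vector
#'
#' k = 2 k-means with `nstart` random restarts under a fixed seed; the
#' "positive" class is the cluster with the larger mean. On one dimension
#' the optimum is a threshold split, which the test suite verifies against
#' exhaustive search.
#'
#' @param values numeric vector (>= 2 distinct values).
#' @param seed RNG seed for the restarts (default 0).
#' @param nstart number of restarts (default 10).
#' @return Logical vector: TRUE = high cluster.
#' @export
kmeans2_split <- function(values, seed = 0, nstart = 10) {
  if (length(unique(values)) < 2)
    stopf("kmeans2_split needs at least 2 distinct values")
  km <- local_seed(seed, kmeans(values, centers = 2, nstart = nstart))
  hi <- unname(km$cluster == which.max(km$centers))
  # Lloyd restarts occasionally stop in a local optimum; on 1-D the global
  # optimum is a threshold partition, so polish with an exact scan and
  # keep whichever labelling has the smaller within-cluster SS.
  ord <- order(values)
  v <- values[ord]
  n <- length(v)
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  k <- seq_len(n - 1)
  ss <- (cs2[k] - cs[k]^2 / k) +
    ((cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k))
  kbest <- which.min(ss)
  thresh <- logical(n)
  thresh[ord[(kbest + 1):n]] <- TRUE
  wss <- function(lab) {
    s <- 0
    for (cl in unique(lab)) s <- s + sum((values[lab == cl] -
                                            mean(values[lab == cl]))^2)
    s
  }
  if (wss(thresh) < wss(hi) - 1e-12) thresh else hi
}

#' Classify promoters into NSL-bound / Pol II-loss groups
#'
#' Stage 1: k = 2 k-means on `nsl_sum` separates NSL-bound from non-bound
#' promoters. Stage 2, among bound promoters only: k = 2 k-means on
#' `polII_delta` separates those that lose Pol II in knockdown from those
#' that retain it (`polII_loss` is `NA` for non-bound genes).
#'
#' @param enrichments data.frame from [promoter_enrichment()].
#' @param seed k-means seed (default 0).
#' @return data.frame: gene, nsl_sum, polII_delta, nsl_bound, polII_loss.
#' @export
classify_promoters <- function(enrichments, seed = 0) {
  stopifnot(all(c("gene", "nsl_sum", "polII_delta") %in%
                  names(enrichments)))
  bound <- kmeans2_split(enrichments$nsl_sum, seed = seed)
  loss <- rep(NA, nrow(enrichments))
  if (any(bound))
    loss[bound] <- kmeans2_split(enrichments$polII_delta[bound],
                                 seed = seed)
  data.frame(gene = enrichments$gene, nsl_sum = enrichments$nsl_sum,
             polII_delta = enrichments$polII_delta, nsl_bound = bound,
             polII_loss = as.logical(loss), stringsAsFactors = FALSE)
}

peaks_to_granges <- function(df) {
  validate_intervals(df, "peak")
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

#' Peak-overlap statistics between two binding-site sets
#'
#' Counts peaks of set `a` overlapping (>= 1 bp) at least one peak of set
#' `b`, the reciprocal, and — among the `a` peaks co-bound by `b` — how
#' many overlap a TSS interval set.
#'
#' @param a,b data.frames of peaks (chrom, start, end; 0-based half-open).
#' @param tss optional data.frame of TSS intervals.
#' @return list with `n_a`, `n_b`, `a_in_b`, `frac_a_in_b`, `b_in_a`,
#'   `frac_b_in_a`, and (when `tss` given) `cobound_at_tss`,
#'   `frac_cobound_at_tss`.
#' @export
interval_overlap_stats <- function(a, b, tss = NULL) {
  ga <- peaks_to_granges(a)
  gb <- peaks_to_granges(b)
  a_hits <- IRanges::overlapsAny(ga, gb)
  b_hits <- IRanges::overlapsAny(gb, ga)
  out <- list(
    n_a = length(ga), n_b = length(gb),
    a_in_b = sum(a_hits), frac_a_in_b = mean(a_hits),
    b_in_a = sum(b_hits), frac_b_in_a = mean(b_hits)
  )
  if (!is.null(tss)) {
    cobound <- ga[a_hits]
    at_tss <- IRanges::overlapsAny(cobound, peaks_to_granges(tss))
    out$cobound_at_tss <- sum(at_tss)
    out$frac_cobound_at_tss <- if (length(cobound)) mean(at_tss) else NA_real_
  }
  out
}

#' Threshold peak calling on an enrichment track
#'
#' Maximal runs of signal >= `threshold`, discarded if shorter than
#' `min_width`, with runs separated by gaps <= `merge_gap` merged first.
#'
#' @param track a [Track()].
#' @param threshold signal threshold.
#' @param min_width minimum peak width in bp (default 100).
#' @param merge_gap maximum gap merged between adjacent runs (default 30).
#' @return data.frame of peaks: chrom, start, end (0-based half-open).
#' @export
call_peaks <- function(track, threshold, min_width = 100, merge_gap = 30) {
  out <- list()
  for (nm in names(track)) {
    r <- rle(track[[nm]] >= threshold)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    runs <- data.frame(start = start[r$values], end = end[r$values])
    if (nrow(runs) > 1) {
      merged <- runs[1, , drop = FALSE]
      for (i in 2:nrow(runs)) {
        if (runs$start[i] - merged$end[nrow(merged)] <= merge_gap)
          merged$end[nrow(merged)] <- runs$end[i]
        else merged <- rbind(merged, runs[i, ])
      }
      runs <- merged
    }
    runs <- runs[runs$end - runs$start >= min_width, , drop = FALSE]
    if (nrow(runs))
      out[[nm]] <- data.frame(chrom = nm, start = runs$start,
                              end = runs$end, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
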