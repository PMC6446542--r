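# TSS count tables are long-format data.frames with columns
# gene, chrom, pos (0-based genomic), strand, condition, count.

check_tss_table <- function(table) {
  need <- c("gene", "pos", "strand", "condition", "count")
  if (!all(need %in% names(table)))
    stopf("TSS table must have columns: %s", paste(need, collapse = ", "))
  if (any(table$count < 0) || any(table$count != round(table$count)))
    stopf("TSS counts must be non-negative integers")
  invisible(table)
}

#' Dominant TSS of a gene
#'
#' The position with the most 5'-end reads in the given condition; ties are
#' broken toward the 5'-most position in the direction of transcription
#' (smallest genomic position on plus-strand genes, largest on minus).
#'
#' @param table long-format TSS count table (one gene, or filtered by
#'   `gene`).
#' @param condition condition to use.
#' @param gene optional gene id to filter on.
#' @return 0-based genomic position, or `NA` when the gene has no reads.
#' @export
dominant_tss <- function(table, condition, gene = NULL) {
  check_tss_table(table)
  if (!is.null(gene)) table <- table[table$gene == gene, , drop = FALSE]
  tab <- table[table$condition == condition & table$count > 0, ,
               drop = FALSE]
  if (nrow(tab) == 0) return(NA_integer_)
  agg <- tapply(tab$count, tab$pos, sum)
  pos <- as.integer(names(agg))
  best <- pos[agg == max(agg)]
  if (tab$strand[1] == "+") min(best) else max(best)
}

#' TSS spread: containment radius around the dominant TSS
#'
#' The smallest `d >= 0` such that reads at positions within `d` bp of the
#' dominant TSS account for at least `containment` of the gene's signal
#' (default 0.9, i.e. at most 10% of signal beyond `d`). Dispersed
#' (housekeeping-type) promoters have large spreads, focused (TATA-type)
#' promoters small ones.
#'
#' @param table long-format TSS count table for one gene.
#' @param condition condition to use.
#' @param containment containment fraction (default 0.9).
#' @param gene optional gene id to filter on.
#' @return Spread in bp, or `NA` for a gene without reads.
#' @export
tss_spread <- function(table, condition, containment = 0.9, gene = NULL) {
  check_tss_table(table)
  if (!is.null(gene)) table <- table[table$gene == gene, , drop = FALSE]
  dom <- dominant_tss(table, condition)
  if (is.na(dom)) return(NA_integer_)
  tab <- table[table$condition == condition & table$count > 0, ,
               drop = FALSE]
  total <- sum(tab$count)
  dist <- abs(tab$pos - dom)
  for (d in sort(unique(c(0, dist)))) {
    if (sum(tab$count[dist <= d]) >= containment * total)
      return(as.integer(d))
  }
  as.integer(max(dist))
}

#' Differential expression of dominant TSSs between conditions
#'
#' For each gene's (control-defined) dominant TSS, tests the knockdown
#' count against the control count with an exact binomial test whose
#' success probability is the knockdown share of the summed library sizes,
#' then applies Benjamini-Hochberg correction. The log2 fold change is
#' computed on library-size-normalized counts with a pseudocount of 1
#' (the pseudocount is never used in the test itself).
#'
#' @param table long-format TSS count table with both conditions.
#' @param lib_sizes named numeric vector with elements `control` and
#'   `knockdown`; default = total counts per condition in `table`.
#' @param at_tss `"dominant"` (default) tests counts at the dominant TSS
#'   only; `"gene"` tests gene-total counts.
#' @return data.frame: gene, pos, count_ctrl, count_kd, log2fc, p, q —
#'   genes with zero counts in both conditions are excluded.
#' @export
differential_tss_expression <- function(table, lib_sizes = NULL,
                                        at_tss = c("dominant", "gene")) {
  check_tss_table(table)
  at_tss <- match.arg(at_tss)
  if (is.null(lib_sizes))
    lib_sizes <- c(
      control = sum(table$count[table$condition == "control"]),
      knockdown = sum(table$count[table$condition == "knockdown"]))
  p_kd <- lib_sizes[["knockdown"]] / sum(lib_sizes)
  rows <- lapply(split(table, table$gene), function(sub) {
    g <- sub$gene[1]
    if (at_tss == "dominant") {
      dom <- dominant_tss(sub, "control")
      if (is.na(dom)) return(NULL)
      c1 <- sum(sub$count[sub$condition == "knockdown" & sub$pos == dom])
      c2 <- sum(sub$count[sub$condition == "control" & sub$pos == dom])
    } else {
      dom <- NA_integer_
      c1 <- sum(sub$count[sub$condition == "knockdown"])
      c2 <- sum(sub$count[sub$condition == "control"])
    }
    if (c1 + c2 == 0) return(NULL)
    data.frame(gene = g, pos = dom, count_ctrl = c2, count_kd = c1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(NULL)
  norm_kd <- res$count_kd / lib_sizes[["knockdown"]] * mean(lib_sizes)
  norm_ct <- res$count_ctrl / lib_sizes[["control"]] * mean(lib_sizes)
  res$log2fc <- log2((norm_kd + 1) / (norm_ct + 1))
  res$p <- vapply(seq_len(nrow(res)), function(i)
    binom.test(res$count_kd[i], res$count_kd[i] + res$count_ctrl[i],
               p = p_kd)$p.value, numeric(1))
  res$q <- p.adjust(res$p, "BH")
  rownames(res) <- NULL
  res
}

# G statistic (likelihood-ratio test of independence) of a k x 2 table.
g_statistic <- function(obs) {
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  nz <- obs > 0
  g <- 2 * sum(obs[nz] * log(obs[nz] / expd[nz]))
  list(G = g, df = (nrow(obs) - 1) * (ncol(obs) - 1))
}

#' Detect shifts in TSS usage between conditions
#'
#' Per gene, a G-test (likelihood-ratio test of independence) on the
#' TSS-position x condition contingency table of 5'-end counts, with
#' Benjamini-Hochberg correction across genes (FDR 5% by default). For
#' significant genes, the up-regulated TSS is the position with the
#' largest increase in relative usage (knockdown minus control proportion)
#' and the down-regulated TSS the largest decrease; `within_200bp` flags
#' pairs at most 200 bp apart, and the gene-level expression change comes
#' from [differential_tss_expression()] on gene totals (FDR 10%).
#'
#' @param table long-format TSS count table with both conditions.
#' @param min_count minimum total reads per condition for a gene to be
#'   testable (default 20; guards small-sample inflation of G).
#' @param bin_width counts are pooled into `bin_width`-bp position bins
#'   before the test (default 20 bp); 1 restores single-base cells. Wider
#'   bins trade positional resolution of the test for degrees of freedom:
#'   a usage swap between two TSS clusters concentrates in a few cells
#'   instead of being spread over dozens of near-empty 1-bp cells.
#' @param min_pos_count bins with a total (both conditions) count below
#'   this are pooled into a single "rest" cell before the G-test (default
#'   10); near-empty cells inflate G far beyond its chi-squared reference.
#' @param fdr FDR threshold for the shifted flag (default 0.05).
#' @param lib_sizes passed to [differential_tss_expression()].
#' @return data.frame (one row per testable gene): gene, statistic, df, p,
#'   q, shifted, down_tss, up_tss (single-base positions of the largest
#'   usage decrease/increase), within_200bp, gene_level_change.
#' @export
detect_tss_shift <- function(table, min_count = 20, bin_width = 20,
                             min_pos_count = 10, fdr = 0.05,
                             lib_sizes = NULL) {
  check_tss_table(table)
  rows <- lapply(split(table, table$gene), function(sub) {
    g <- sub$gene[1]
    sub <- sub[sub$count > 0, , drop = FALSE]
    pos <- sort(unique(sub$pos))
    if (length(pos) < 2) return(NULL)
    agg_by <- function(cond, key) {
      cc <- sub[sub$condition == cond, , drop = FALSE]
      tapply(cc$count, key[match(cc$pos, pos)], sum)
    }
    bins <- as.character(pos %/% bin_width)
    ub <- unique(bins)
    m <- matrix(0, nrow = length(ub), ncol = 2,
                dimnames = list(ub, c("control", "knockdown")))
    mp <- matrix(0, nrow = length(pos), ncol = 2,
                 dimnames = list(pos, c("control", "knockdown")))
    for (cond in colnames(m)) {
      ab <- agg_by(cond, bins)
      m[names(ab), cond] <- ab
      ap <- agg_by(cond, as.character(pos))
      mp[names(ap), cond] <- ap
    }
    if (any(colSums(m) < min_count)) return(NULL)
    rich <- rowSums(m) >= min_pos_count
    mt <- m[rich, , drop = FALSE]
    if (any(!rich))
      mt <- rbind(mt, rest = colSums(m[!rich, , drop = FALSE]))
    if (nrow(mt) < 2) return(NULL)
    gt <- g_statistic(mt)
    # up/down TSSs at single-base resolution, restricted to supported bins
    prop <- sweep(mp, 2, colSums(mp), "/")
    dprop <- prop[, "knockdown"] - prop[, "control"]
    dprop[!rich[match(bins, ub)]] <- 0
    data.frame(gene = g, statistic = gt$G, df = gt$df,
               p = pchisq(gt$G, gt$df, lower.tail = FALSE),
               up_tss = pos[which.max(dprop)],
               down_tss = pos[which.min(dprop)],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(NULL)
  res$q <- p.adjust(res$p, "BH")
  res$shifted <- res$q < fdr
  res$within_200bp <- abs(res$up_tss - res$down_tss) <= 200
  res$up_tss[!res$shifted] <- NA_integer_
  res$down_tss[!res$shifted] <- NA_integer_
  res$within_200bp[!res$shifted] <- NA
  de <- differential_tss_expression(table, lib_sizes, at_tss = "gene")
  chg <- rep("unchanged", nrow(res))
  i <- match(res$gene, de$gene)
  sig <- !is.na(i) & de$q[i] < 0.1
  chg[sig & de$log2fc[i] > 0] <- "up"
  chg[sig & de$log2fc[i] < 0] <- "down"
  res$gene_level_change <- chg
  rownames(res) <- NULL
  res[, c("gene", "statistic", "df", "p", "q", "shifted", "down_tss",
          "up_tss", "within_200bp", "gene_level_change")]
}

#' Classify 5'UTR length change from RNA-seq coverage
#'
#' For a gene with a significant TSS shift, compares knockdown and control
#' RNA-seq coverage over the segment between the down- and up-regulated
#' TSSs: an up-TSS downstream (in the direction of transcription) of the
#' down-TSS with lost coverage in between means a shorter 5'UTR; an up-TSS
#' upstream with gained coverage means a longer one; anything else is
#' ambiguous.
#'
#' @param rnaseq_ctrl,rnaseq_kd coverage [Track()]s.
#' @param call one row of a [detect_tss_shift()] table (needs `down_tss`,
#'   `up_tss`, `shifted`).
#' @param chrom chromosome of the gene.
#' @param strand gene strand (`"+"` or `"-"`).
#' @param flank window half-width around the TSS pair that must contain
#'   coverage (default 200 bp).
#' @return One of `"longer"`, `"shorter"`, `"ambiguous"`, or `NA` when the
#'   gene is not shifted or has no coverage in the window.
#' @export
utr_change <- function(rnaseq_ctrl, rnaseq_kd, call, chrom, strand,
                       flank = 200) {
  if (is.na(call$shifted) || !call$shifted) return(NA_character_)
  lo <- min(call$down_tss, call$up_tss)
  hi <- max(call$down_tss, call$up_tss)
  wl <- max(lo - flank, 0)
  wh <- min(hi + flank, length(rnaseq_ctrl[[chrom]]))
  cov_ct <- track_slice(rnaseq_ctrl, chrom, wl, wh)
  cov_kd <- track_slice(rnaseq_kd, chrom, wl, wh)
  if (all(cov_ct == 0) && all(cov_kd == 0)) return(NA_character_)
  seg <- seq.int(lo, hi) - wl + 1L   # inter-TSS segment, window-relative
  delta <- mean(cov_kd[seg] - cov_ct[seg])
  up_downstream <- if (strand == "+") call$up_tss > call$down_tss else
    call$up_tss < call$down_tss
  if (up_downstream && delta < 0) return("shorter")
  if (!up_downstream && delta > 0) return("longer")
  "ambiguous"
}
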