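#' Configuration for the synthetic chromatin data generator
#'
#' Bundles every parameter of the synthetic study system: a toy chromosome
#' carrying evenly spaced promoters, half of which (by default) are targets
#' of the NSL complex. Target promoters get an AT-rich nucleosome-depleted
#' region (NDR) and a phased nucleosome array whose +1 nucleosome shifts
#' toward the TSS upon knockdown; non-targets are GC-balanced, a subset
#' carrying a TATA box. The same gene set drives the MNase, ChIP, 5'-end
#' (MAPCap-style), in vitro binding, and single-cell simulations, so every
#' downstream stage has a parameter-recovery test against known truth.
#'
#' @param n_genes number of genes/promoters.
#' @param chrom_len chromosome length in bp; `NULL` auto-sizes to 4000 bp
#'   per gene plus margins.
#' @param frac_nsl_target fraction of genes that are NSL targets; the
#'   realized count is `round(frac_nsl_target * n_genes)`, assigned to the
#'   first k indices of a seeded shuffle.
#' @param ndr_width width of the NDR upstream of the TSS (bp).
#' @param plus1_offset dyad of the +1 nucleosome, bp downstream of the TSS.
#' @param array_spacing nucleosome repeat length (bp, >= 147).
#' @param jitter_sd Gaussian positional jitter of fragment midpoints (bp).
#' @param kd_shift upstream shift (bp) of target +1 dyads in knockdown.
#' @param kd_ndr_fill fraction of +1 fragment mass relocated into the NDR in
#'   knockdown (the "invasion" phenotype).
#' @param frag_len_mean,frag_len_sd fragment length distribution (bp),
#'   truncated to `[100, 200]` emulating mononucleosome size selection.
#' @param frags_per_gene MNase fragments sampled per gene.
#' @param tss_spread_dispersed,tss_spread_focused Laplace scale (bp) of the
#'   multinomial TSS weight profile for target (dispersed, housekeeping-like)
#'   and non-target (focused, TATA-like) promoters.
#' @param frac_shift_genes fraction of target genes with a programmed
#'   alternative-TSS swap event.
#' @param tss_swap programmed swap: the alternative TSS gains this much
#'   relative usage in knockdown (fraction of gene signal).
#' @param kd_tss_depletion gene-level depletion of target 5'-end signal in
#'   knockdown (fraction removed).
#' @param at_effect slope of in vitro log binding enrichment on bin AT
#'   fraction.
#' @param kmer_effects named numeric vector mapping 5-mers to additive
#'   effects of their per-bin frequency on log enrichment.
#' @param noise_sd Gaussian noise sd of in vitro log enrichment.
#' @param sc_cells,sc_depth single-cell simulation: cells per condition and
#'   mean per-cell depth (library sizes are log-normal around `sc_depth`).
#' @param sc_dispersion_fold multiplier on the NB dispersion of
#'   noise-flagged genes (the NSL targets) in knockdown; means are equal
#'   across conditions by construction.
#' @param chip_amp mean ChIP bump amplitude over a background of 1
#'   (per-target amplitudes are log-normal around this).
#' @param chip_amp_sd sdlog of per-gene ChIP amplitudes.
#' @param frac_polII_loss fraction of targets that lose Pol II in knockdown.
#' @param polII_loss_factor multiplier on the Pol II bump of loss genes in
#'   knockdown.
#' @param frac_tata_nontarget fraction of non-targets carrying a TATA box.
#' @param frac_dre_target,frac_dre_nontarget fractions of target and
#'   non-target promoters carrying a planted DRE motif.
#' @param shift_mode `"constant"`: all targets shift by `kd_shift`;
#'   `"proportional"`: a target's shift scales with its ChIP amplitude
#'   (`kd_shift * amplitude / chip_amp`), producing the shift-vs-enrichment
#'   gradient used in quantile-group analyses.
#' @param seed integer; identical config + seed gives byte-identical output.
#' @return A list of class `nslchrom_config`.
#' @export
generator_config <- function(n_genes = 2000,
                             chrom_len = NULL,
                             frac_nsl_target = 0.5,
                             ndr_width = 150,
                             plus1_offset = 75,
                             array_spacing = 175,
                             jitter_sd = 20,
                             kd_shift = 10,
                             kd_ndr_fill = 0.2,
                             frag_len_mean = 147,
                             frag_len_sd = 15,
                             frags_per_gene = 200,
                             tss_spread_dispersed = 25,
                             tss_spread_focused = 7,
                             frac_shift_genes = 0.1,
                             tss_swap = 0.30,
                             kd_tss_depletion = 0.5,
                             at_effect = 2,
                             kmer_effects = NULL,
                             noise_sd = 0.05,
                             sc_cells = 500,
                             sc_depth = 10000,
                             sc_dispersion_fold = 2.5,
                             chip_amp = 4,
                             chip_amp_sd = 0.4,
                             frac_polII_loss = 0.5,
                             polII_loss_factor = 0.25,
                             frac_tata_nontarget = 0.5,
                             frac_dre_target = 0.4,
                             frac_dre_nontarget = 0.05,
                             shift_mode = c("constant", "proportional"),
                             seed = 0) {
  shift_mode <- match.arg(shift_mode)
  if (is.null(chrom_len)) chrom_len <- 4000L * n_genes + 4000L
  cfg <- list(
    n_genes = as.integer(n_genes), chrom_len = as.integer(chrom_len),
    frac_nsl_target = frac_nsl_target, ndr_width = as.integer(ndr_width),
    plus1_offset = as.integer(plus1_offset),
    array_spacing = as.integer(array_spacing), jitter_sd = jitter_sd,
    kd_shift = kd_shift, kd_ndr_fill = kd_ndr_fill,
    frag_len_mean = frag_len_mean, frag_len_sd = frag_len_sd,
    frags_per_gene = as.integer(frags_per_gene),
    tss_spread_dispersed = tss_spread_dispersed,
    tss_spread_focused = tss_spread_focused,
    frac_shift_genes = frac_shift_genes, tss_swap = tss_swap,
    kd_tss_depletion = kd_tss_depletion,
    at_effect = at_effect, kmer_effects = kmer_effects,
    noise_sd = noise_sd,
    sc_cells = as.integer(sc_cells), sc_depth = sc_depth,
    sc_dispersion_fold = sc_dispersion_fold,
    chip_amp = chip_amp, chip_amp_sd = chip_amp_sd,
    frac_polII_loss = frac_polII_loss,
    polII_loss_factor = polII_loss_factor,
    frac_tata_nontarget = frac_tata_nontarget,
    frac_dre_target = frac_dre_target,
    frac_dre_nontarget = frac_dre_nontarget,
    shift_mode = shift_mode, seed = as.integer(seed)
  )
  for (f in c("frac_nsl_target", "kd_ndr_fill", "frac_shift_genes",
              "tss_swap", "kd_tss_depletion", "frac_polII_loss",
              "frac_tata_nontarget", "frac_dre_target",
              "frac_dre_nontarget"))
    if (!is_frac(cfg[[f]])) stopf("%s must be a fraction in [0, 1]", f)
  if (cfg$plus1_offset <= 0) stopf("plus1_offset must be > 0")
  if (cfg$array_spacing < 147) stopf("array_spacing must be >= 147 bp")
  if (cfg$n_genes < 1) stopf("n_genes must be >= 1")
  if (!is.null(cfg$kmer_effects) &&
      (is.null(names(cfg$kmer_effects)) ||
       any(nchar(names(cfg$kmer_effects)) != 5)))
    stopf("kmer_effects must be a named vector keyed by 5-mers")
  class(cfg) <- "nslchrom_config"
  cfg
}

GENE_SLOT_MIN <- 2200L  # promoter footprint: TSS +/- ~1000 bp plus margin

# Oriented-to-genomic coordinate conversion: x = 0 at the TSS base, positive
# downstream in the direction of transcription.
oriented_pos <- function(tss, strand, x) {
  if (length(strand) == 1 && length(tss) == 1)
    return(if (strand == "+") tss + x else tss - x)
  ifelse(strand == "+", tss + x, tss - x)
}

DRE_MOTIF <- "TATCGATA"
TATA_MOTIF <- "TATAAAAG"

#' Generate a synthetic genome with promoter annotation and ground truth
#'
#' Builds one toy chromosome with `n_genes` evenly spaced promoters of
#' alternating strand. NSL-target promoters receive an AT-rich NDR
#' (P(A or T) = 0.75 over the NDR window) against a GC-balanced background
#' (P = 0.5); a configured fraction of non-targets carries a TATA box at
#' -30, and DRE motifs are planted at -60 in configured fractions of both
#' classes. Every per-gene latent quantity needed by the downstream
#' simulators (target status, +1 dyads per condition, programmed shift,
#' TSS weight parameters, ChIP amplitude, Pol II-loss flag, single-cell
#' mean and dispersion per condition) is recorded in the ground-truth table.
#'
#' @param config a [generator_config()].
#' @return list with elements `genome` (DNAStringSet), `promoters`
#'   (data.frame: chrom, tss, strand, gene — `tss` is the 0-based genomic
#'   position of the first transcribed base), `truth` (per-gene data.frame)
#'   and `config`.
#' @export
make_genome <- function(config) {
  stopifnot(inherits(config, "nslchrom_config"))
  n <- config$n_genes
  spacing <- config$chrom_len %/% (n + 1L)
  if (spacing < GENE_SLOT_MIN)
    stopf(paste0("promoters would overlap at this density (%d bp/gene); ",
                 "increase chrom_len to at least %d"),
          spacing, (n + 1L) * GENE_SLOT_MIN)
  local_seed(config$seed, {
    tss <- spacing * seq_len(n)
    strand <- rep(c("+", "-"), length.out = n)
    gene <- sprintf("g%05d", seq_len(n))

    k <- round(config$frac_nsl_target * n)
    ord <- sample.int(n)
    is_target <- logical(n)
    is_target[ord[seq_len(k)]] <- TRUE

    # background sequence: uniform over ACGT (AT fraction 0.5)
    base_chars <- c("A", "C", "G", "T")
    seq_chr <- sample(base_chars, config$chrom_len, replace = TRUE)

    # AT-rich NDRs for targets: P(A or T) = 0.75, A/T and G/C symmetric
    at_probs <- c(0.375, 0.125, 0.125, 0.375)
    ndr_idx <- function(i) {
      x <- seq.int(-config$ndr_width, -1L)   # oriented NDR [-w, 0)
      sort(oriented_pos(tss[i], strand[i], x)) + 1L
    }
    for (i in which(is_target)) {
      idx <- ndr_idx(i)
      seq_chr[idx] <- sample(base_chars, length(idx), replace = TRUE,
                             prob = at_probs)
    }

    plant <- function(i, motif, at) {
      # place motif so its oriented 5'->3' span starts at oriented `at`
      m <- strsplit(motif, "")[[1]]
      if (strand[i] == "-")
        m <- rev(chartr("ACGT", "TGCA", m))
      pos <- oriented_pos(tss[i], strand[i], at)   # 0-based genomic
      idx <- if (strand[i] == "+") pos + seq_along(m) else
        pos - length(m) + 1L + seq_along(m)
      seq_chr[idx] <<- m
    }
    has_tata <- !is_target &
      (runif(n) < config$frac_tata_nontarget)
    has_dre <- ifelse(is_target, runif(n) < config$frac_dre_target,
                      runif(n) < config$frac_dre_nontarget)
    for (i in which(has_tata)) plant(i, TATA_MOTIF, -32L)
    for (i in which(has_dre)) plant(i, DRE_MOTIF, -60L)

    true_shift <- rep(0, n)
    if (config$shift_mode == "constant") {
      chip_amp_g <- ifelse(is_target,
                           rlnorm(n, log(config$chip_amp),
                                  config$chip_amp_sd), 0)
      true_shift[is_target] <- config$kd_shift
    } else {
      # proportional mode: every gene carries a (widely spread) ChIP
      # amplitude and shifts in proportion, emulating a continuous
      # shift-vs-enrichment gradient across all promoters
      chip_amp_g <- rlnorm(n, log(config$chip_amp), 0.6)
      # cap so the shifted +1 stays within the dyad-calling search window
      true_shift <- pmin(config$kd_shift * chip_amp_g / config$chip_amp, 40)
    }

    polII_loss <- is_target & (runif(n) < config$frac_polII_loss)

    n_targets <- sum(is_target)
    n_shift <- round(config$frac_shift_genes * n_targets)
    shift_event <- logical(n)
    tgt_idx <- which(is_target)
    if (n_shift > 0)
      shift_event[sample(tgt_idx, n_shift)] <- TRUE
    alt_offset <- integer(n)
    alt_offset[shift_event] <- sample(c(-1L, 1L), sum(shift_event), TRUE) *
      sample(60:180, sum(shift_event), TRUE)
    p_alt_ctrl <- ifelse(shift_event, 0.2, 0)
    p_alt_kd <- ifelse(shift_event, pmin(0.2 + config$tss_swap, 1), 0)

    spread_scale <- ifelse(is_target, config$tss_spread_dispersed,
                           config$tss_spread_focused)

    sc_rel_expr <- rlnorm(n, 0, 1)
    sc_disp_ctrl <- rgamma(n, shape = 4, rate = 4 / 0.3)
    noise_flag <- is_target
    sc_disp_kd <- sc_disp_ctrl *
      ifelse(noise_flag, config$sc_dispersion_fold, 1)

    truth <- data.frame(
      gene = gene, chrom = "chrS", tss = tss, strand = strand,
      is_nsl_target = is_target, has_tata = has_tata, has_dre = has_dre,
      chip_amp = chip_amp_g, polII_loss = polII_loss,
      true_plus1_ctrl = config$plus1_offset,
      true_plus1_kd = config$plus1_offset - true_shift,
      true_shift = true_shift,
      spread_scale = spread_scale, shift_event = shift_event,
      alt_offset = alt_offset, p_alt_ctrl = p_alt_ctrl, p_alt_kd = p_alt_kd,
      noise_flag = noise_flag, sc_rel_expr = sc_rel_expr,
      sc_disp_ctrl = sc_disp_ctrl, sc_disp_kd = sc_disp_kd,
      stringsAsFactors = FALSE
    )
    genome <- Biostrings::DNAStringSet(
      structure(paste(seq_chr, collapse = ""), names = "chrS"))
    promoters <- data.frame(chrom = "chrS", tss = tss, strand = strand,
                            gene = gene, stringsAsFactors = FALSE)
    list(genome = genome, promoters = promoters, truth = truth,
         config = config)
  })
}

# Relative weights of the nucleosomes flanking a promoter, oriented
# -2, -1, +1, +2, +3, +4. The +1 is the best positioned / most occupied.
NUC_LABELS <- c("-2", "-1", "+1", "+2", "+3", "+4")
NUC_WEIGHTS <- c(0.6, 0.8, 1.0, 0.9, 0.8, 0.7)

# Oriented dyad positions for one gene in one condition.
nuc_dyads <- function(cfg, plus1) {
  up1 <- -(cfg$ndr_width + 73L)
  c(up1 - cfg$array_spacing, up1,
    plus1, plus1 + cfg$array_spacing * (1:3))
}

#' Simulate MNase-seq fragments
#'
#' Samples paired-end style mononucleosomal fragments around the per-gene
#' nucleosome dyads. In knockdown, target genes have their +1 (and
#' downstream) dyads moved `kd_shift` bp toward the TSS (per the recorded
#' per-gene `true_shift`) and a fraction `kd_ndr_fill` of +1 fragment mass
#' relocated to the NDR center, producing NDR invasion. Fragment midpoints
#' get Gaussian jitter (`jitter_sd`); lengths are Normal(`frag_len_mean`,
#' `frag_len_sd`) truncated to [100, 200] bp.
#'
#' @param genome output of [make_genome()] (list with `truth`), or the
#'   truth data.frame itself.
#' @param condition `"control"` or `"knockdown"`.
#' @param config the [generator_config()].
#' @return BED-writable data.frame: chrom, start, end, name (gene), score,
#'   strand (`"."`), plus a `nuc` column labelling the source nucleosome.
#' @export
simulate_mnase <- function(genome, condition = c("control", "knockdown"),
                           config) {
  condition <- match.arg(condition)
  truth <- if (is.data.frame(genome)) genome else genome$truth
  seed_off <- if (condition == "control") 11L else 12L
  local_seed(config$seed + seed_off, {
    n <- nrow(truth)
    per_gene <- lapply(seq_len(n), function(i) {
      plus1 <- if (condition == "control") truth$true_plus1_ctrl[i]
        else truth$true_plus1_kd[i]
      dyads <- nuc_dyads(config, plus1)
      w <- NUC_WEIGHTS
      labels <- NUC_LABELS
      if (condition == "knockdown" && truth$is_nsl_target[i] &&
          config$kd_ndr_fill > 0) {
        # move part of the +1 mass into the NDR
        fill <- config$kd_ndr_fill * w[3]
        w[3] <- w[3] - fill
        dyads <- c(dyads, -round(config$ndr_width / 2))
        w <- c(w, fill)
        labels <- c(labels, "NDR")
      }
      cnt <- as.integer(rmultinom(1, config$frags_per_gene, w))
      mid_rel <- rep(dyads, cnt)
      lab <- rep(labels, cnt)
      if (config$jitter_sd > 0)
        mid_rel <- mid_rel + rnorm(length(mid_rel), 0, config$jitter_sd)
      mid <- round(oriented_pos(truth$tss[i], truth$strand[i], mid_rel))
      len <- rep(round(config$frag_len_mean), length(mid))
      if (config$frag_len_sd > 0) {
        len <- round(rnorm(length(mid), config$frag_len_mean,
                           config$frag_len_sd))
        bad <- which(len < 100 | len > 200)
        while (length(bad)) {   # truncated normal by rejection
          len[bad] <- round(rnorm(length(bad), config$frag_len_mean,
                                  config$frag_len_sd))
          bad <- bad[len[bad] < 100 | len[bad] > 200]
        }
      }
      start <- mid - len %/% 2L
      data.frame(chrom = truth$chrom[i], start = start, end = start + len,
                 name = truth$gene[i], score = 0, strand = ".",
                 nuc = lab, stringsAsFactors = FALSE)
    })
    frags <- do.call(rbind, per_gene)
    frags <- frags[frags$start >= 0 & frags$end <= config$chrom_len, ,
                   drop = FALSE]
    rownames(frags) <- NULL
    frags
  })
}

CHIP_FACTORS <- c("NSL1", "NSL3", "MBDR2", "NURF301", "PolII", "input")
# relative amplitude of each factor's bump vs the per-gene ChIP amplitude
CHIP_REL_AMP <- c(NSL1 = 1, NSL3 = 0.9, MBDR2 = 0.8, NURF301 = 0.9)
CHIP_BUMP_SD <- 60
POLII_BUMP_SD <- 70

#' Simulate a ChIP enrichment track
#'
#' NSL-complex members and NURF peak at the NDR center of target promoters
#' (amplitude = the per-gene ground-truth ChIP amplitude times a per-factor
#' scale); Pol II peaks at every TSS and is reduced by `polII_loss_factor`
#' in knockdown at the Pol II-loss subset of targets; `input` is flat noise
#' rescaled to a genome-wide mean of exactly 1. All tracks carry additive
#' Gaussian noise (sd 0.05) floored at 0.
#'
#' @param genome output of [make_genome()].
#' @param factor one of `r paste(CHIP_FACTORS, collapse = ", ")`.
#' @param condition `"control"` or `"knockdown"`.
#' @param config the [generator_config()].
#' @return A [Track()] of per-base enrichment (background ~1).
#' @export
simulate_chip <- function(genome, factor,
                          condition = c("control", "knockdown"), config) {
  condition <- match.arg(condition)
  if (!factor %in% CHIP_FACTORS)
    stopf("unknown ChIP factor '%s' (use one of: %s)", factor,
          paste(CHIP_FACTORS, collapse = ", "))
  truth <- genome$truth
  len <- config$chrom_len
  fi <- match(factor, CHIP_FACTORS)
  ci <- if (condition == "control") 0L else 1L
  local_seed(config$seed + 20L + 2L * fi + ci, {
    if (factor == "input") {
      v <- pmax(rnorm(len, 1, 0.05), 0)
      return(Track(list(chrS = v / mean(v))))
    }
    v <- numeric(len)
    half <- 250L
    kernel_at <- function(sd) exp(-(seq(-half, half))^2 / (2 * sd^2))
    if (factor == "PolII") {
      k <- kernel_at(POLII_BUMP_SD)
      for (i in seq_len(nrow(truth))) {
        amp <- config$chip_amp
        if (condition == "knockdown" && truth$polII_loss[i])
          amp <- amp * config$polII_loss_factor
        ctr <- truth$tss[i]
        idx <- (ctr - half):(ctr + half) + 1L
        ok <- idx >= 1 & idx <= len
        v[idx[ok]] <- v[idx[ok]] + amp * k[ok]
      }
    } else {
      k <- kernel_at(CHIP_BUMP_SD)
      for (i in which(truth$chip_amp > 0)) {
        amp <- truth$chip_amp[i] * CHIP_REL_AMP[[factor]]
        ctr <- round(oriented_pos(truth$tss[i], truth$strand[i],
                                  -config$ndr_width / 2))
        idx <- (ctr - half):(ctr + half) + 1L
        ok <- idx >= 1 & idx <= len
        v[idx[ok]] <- v[idx[ok]] + amp * k[ok]
      }
    }
    Track(list(chrS = pmax(1 + v + rnorm(len, 0, 0.05), 0)))
  })
}

# Per-gene TSS weight profile over oriented positions -150..150: a Laplace
# peak at the annotated TSS, plus (for shift-event genes) a focused
# alternative peak whose share swaps up in knockdown.
TSS_SUPPORT <- 200L

tss_weights_gene <- function(truth_row, condition, config) {
  x <- seq.int(-TSS_SUPPORT, TSS_SUPPORT)
  lap <- function(center, scale) {
    if (scale <= 0) as.numeric(x == center) else exp(-abs(x - center) / scale)
  }
  w <- lap(0, truth_row$spread_scale)
  w <- w / sum(w)
  if (truth_row$shift_event) {
    p_alt <- if (condition == "control") truth_row$p_alt_ctrl else
      truth_row$p_alt_kd
    wa <- lap(truth_row$alt_offset, config$tss_spread_focused)
    wa <- wa / sum(wa)
    w <- (1 - p_alt) * w + p_alt * wa
  }
  w
}

#' Simulate MAPCap-style 5'-end counts
#'
#' One multinomial draw of `depth` reads over all (gene, position) cells,
#' with cell probabilities proportional to the gene's condition-specific
#' expression times its TSS weight profile (Laplace around the annotated
#' TSS; shift-event genes carry a second, focused peak whose share swaps in
#' knockdown). In knockdown, target genes are depleted by
#' `kd_tss_depletion` at the gene level.
#'
#' @param genome output of [make_genome()].
#' @param condition `"control"` or `"knockdown"`.
#' @param depth total read count for the condition.
#' @param config the [generator_config()].
#' @return Long-format data.frame: gene, chrom, pos (0-based genomic),
#'   strand, condition, count — rows with zero count omitted.
#' @export
simulate_mapcap <- function(genome, condition = c("control", "knockdown"),
                            depth, config) {
  condition <- match.arg(condition)
  stopifnot(depth > 0)
  truth <- genome$truth
  ci <- if (condition == "control") 0L else 1L
  local_seed(config$seed + 40L + ci, {
    x <- seq.int(-TSS_SUPPORT, TSS_SUPPORT)
    n <- nrow(truth)
    wlist <- lapply(seq_len(n), function(i)
      tss_weights_gene(truth[i, ], condition, config))
    expr <- rep(1, n)
    if (condition == "knockdown")
      expr[truth$is_nsl_target] <- 1 - config$kd_tss_depletion
    probs <- unlist(lapply(seq_len(n), function(i) expr[i] * wlist[[i]]))
    probs <- probs / sum(probs)
    counts <- as.integer(rmultinom(1, depth, probs))
    gene_i <- rep(seq_len(n), each = length(x))
    rel <- rep(x, n)
    keep <- counts > 0
    data.frame(
      gene = truth$gene[gene_i[keep]],
      chrom = truth$chrom[gene_i[keep]],
      pos = oriented_pos(truth$tss[gene_i[keep]],
                         truth$strand[gene_i[keep]], rel[keep]),
      strand = truth$strand[gene_i[keep]],
      condition = condition,
      count = counts[keep],
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate in vitro DNA-binding enrichment over 200-bp bins
#'
#' Tiles each chromosome into non-overlapping 200-bp bins and assigns
#' `log_enrichment = at_effect * AT_fraction + sum(kmer_effects * freq) +
#' Normal(0, noise_sd)`, where a 5-mer's frequency is its sliding-window
#' count divided by 196.
#'
#' @param genome output of [make_genome()] (needs `genome$genome`).
#' @param config the [generator_config()].
#' @return data.frame: chrom, start, end (0-based half-open), at_fraction,
#'   log_enrichment.
#' @export
simulate_invitro_binding <- function(genome, config) {
  seqs <- genome$genome
  local_seed(config$seed + 50L, {
    out <- lapply(names(seqs), function(nm) {
      s <- seqs[[nm]]
      nb <- length(s) %/% 200L
      if (nb < 1) stopf("chromosome %s shorter than one 200-bp bin", nm)
      starts <- 200L * (seq_len(nb) - 1L)
      v <- Biostrings::Views(s, start = starts + 1L, width = 200L)
      atf <- as.numeric(
        Biostrings::letterFrequency(v, "AT", as.prob = TRUE))
      le <- config$at_effect * atf
      if (!is.null(config$kmer_effects) && length(config$kmer_effects)) {
        of <- Biostrings::oligonucleotideFrequency(v, width = 5L)
        for (km in names(config$kmer_effects))
          le <- le + config$kmer_effects[[km]] * of[, km] / 196
      }
      if (config$noise_sd > 0)
        le <- le + rnorm(nb, 0, config$noise_sd)
      data.frame(chrom = nm, start = starts, end = starts + 200L,
                 at_fraction = atf, log_enrichment = le,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate a single-cell count matrix
#'
#' Negative-binomial counts for `sc_cells` cells: per-cell library sizes
#' are log-normal around `sc_depth`; a gene's expected count is the library
#' size times its relative abundance, and its NB dispersion is the
#' condition-specific ground-truth value (`sc_disp_kd` =
#' `sc_dispersion_fold` x `sc_disp_ctrl` for noise-flagged genes, equal
#' means across conditions by construction).
#'
#' @param truth ground-truth data.frame from [make_genome()] (or the full
#'   genome list).
#' @param condition `"control"` or `"knockdown"`.
#' @param config the [generator_config()].
#' @return Integer matrix, cells x genes, with cell and gene dimnames.
#' @export
simulate_scrna <- function(truth, condition = c("control", "knockdown"),
                           config) {
  condition <- match.arg(condition)
  if (!is.data.frame(truth)) truth <- truth$truth
  ci <- if (condition == "control") 0L else 1L
  local_seed(config$seed + 60L + ci, {
    n_g <- nrow(truth)
    p <- truth$sc_rel_expr / sum(truth$sc_rel_expr)
    disp <- if (condition == "control") truth$sc_disp_ctrl else
      truth$sc_disp_kd
    lib <- rlnorm(config$sc_cells, log(config$sc_depth), 0.3)
    m <- matrix(0L, nrow = config$sc_cells, ncol = n_g,
                dimnames = list(
                  sprintf("%s_cell%04d", substr(condition, 1, 4),
                          seq_len(config$sc_cells)),
                  truth$gene))
    for (g in seq_len(n_g)) {
      mu <- lib * p[g]
      m[, g] <- rnbinom(config$sc_cells, mu = mu, size = 1 / disp[g])
    }
    m
  })
}

#' Write all generator outputs to a directory
#'
#' Emits the standard-format files (FASTA genome, BED6 promoters, GFF3
#' genes, BED fragments per condition, bedGraph tracks, TSV 5'-end counts,
#' TSV cell x gene matrices) plus the ground truth and config echo as JSON,
#' so that runs are auditable and re-loadable with the package readers.
#'
#' @param genome output of [make_genome()].
#' @param dir output directory (created if missing).
#' @param chip_factors factors to write ChIP tracks for.
#' @param mapcap_depth total 5'-end reads per condition.
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(genome, dir,
                                    chip_factors = c("NSL1", "input"),
                                    mapcap_depth = 2e5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- genome$config
  write_fasta(genome$genome, file.path(dir, "genome.fa"))
  prom <- genome$promoters
  write_bed(data.frame(chrom = prom$chrom, start = prom$tss,
                       end = prom$tss + 1L, name = prom$gene, score = 0,
                       strand = prom$strand),
            file.path(dir, "promoters.bed"))
  write_gff3(data.frame(chrom = prom$chrom, source = "nslchrom",
                        type = "gene", start = prom$tss,
                        end = prom$tss + 1L, score = ".",
                        strand = prom$strand, phase = ".",
                        attributes = paste0("ID=", prom$gene)),
             file.path(dir, "genes.gff3"))
  for (cond in c("control", "knockdown")) {
    fr <- simulate_mnase(genome, cond, cfg)
    write_bed(fr, file.path(dir, sprintf("mnase_%s.bed", cond)))
    mc <- simulate_mapcap(genome, cond, mapcap_depth, cfg)
    write_counts(mc, file.path(dir, sprintf("mapcap_%s.tsv", cond)))
    for (f in chip_factors)
      write_bedgraph(simulate_chip(genome, f, cond, cfg),
                     file.path(dir, sprintf("chip_%s_%s.bedGraph", f, cond)))
    sc <- simulate_scrna(genome$truth, cond, cfg)
    write_counts(cbind(data.frame(cell = rownames(sc)), as.data.frame(sc)),
                 file.path(dir, sprintf("scrna_%s.tsv", cond)))
  }
  write_counts(simulate_invitro_binding(genome, cfg),
               file.path(dir, "invitro_bins.tsv"))
  jsonlite::write_json(genome$truth, file.path(dir, "ground_truth.json"),
                       dataframe = "columns", digits = NA)
  cfg_plain <- unclass(cfg)
  cfg_plain$kmer_effects <- as.list(cfg$kmer_effects)
  jsonlite::write_json(cfg_plain, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
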