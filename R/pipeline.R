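PIPELINE_STAGES <- c("simulate", "occupancy", "classify", "binding",
                     "kmer", "tss", "noise")

default_pipeline_config <- function() {
  list(
    stages = PIPELINE_STAGES,
    generator = list(),          # overrides for generator_config()
    mapcap_depth = 2e5,
    noise_n_perm = 200,
    seed = 0
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else { if (!requireNamespace("yaml", quietly = TRUE)) stopf("yaml package needed for YAML configs; use JSON or a list"); yaml::read_yaml(config) }
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  bad <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  cfg
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(paste0("[INFO] ", msg), con)
  message(msg)
}

#' Run the full simulate-and-analyze pipeline
#'
#' Generates the synthetic dataset and runs the requested analysis stages,
#' writing every result table as TSV into `outdir` together with a run log
#' that echoes each analysis constant (window sizes, FDR levels, seeds)
#' and the MD5 hash of the effective configuration. Reruns with the same
#' configuration produce byte-identical outputs. Every analysis stage
#' consumes simulated inputs, so requesting one without `"simulate"` is an
#' error raised before any computation.
#'
#' @param config a list, or path to a YAML/JSON file, with elements
#'   `stages` (subset of `r paste(PIPELINE_STAGES, collapse = ", ")`),
#'   `generator` (argument overrides for [generator_config()]),
#'   `mapcap_depth`, `noise_n_perm`, `seed`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(config = list(), outdir) {
  cfg <- read_pipeline_config(config)
  analysis_stages <- setdiff(cfg$stages, "simulate")
  if (length(analysis_stages) && !"simulate" %in% cfg$stages)
    stopf("stage(s) %s need simulated inputs: include the 'simulate' stage",
          paste(analysis_stages, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               null = "null")
  cfg_path <- file.path(outdir, "config_echo.json")
  writeLines(cfg_json, cfg_path)
  con <- file(file.path(outdir, "run_log.txt"), "w")
  on.exit(close(con))
  log_line(con, "config md5: %s", unname(tools::md5sum(cfg_path)))
  log_line(con, "stages: %s", paste(cfg$stages, collapse = ", "))

  gc_args <- utils::modifyList(list(seed = cfg$seed), cfg$generator)
  gcfg <- do.call(generator_config, gc_args)
  genome <- make_genome(gcfg)
  log_line(con, "genome: %d genes, chrom_len %d, seed %d",
           gcfg$n_genes, gcfg$chrom_len, gcfg$seed)
  write_counts(genome$truth, file.path(outdir, "ground_truth.tsv"))

  lens <- c(chrS = gcfg$chrom_len)
  prom <- genome$promoters

  if ("occupancy" %in% cfg$stages) {
    log_line(con, "occupancy: smoothing_sd 20 bp, RPGC, window [-500, 1000]")
    mats <- lapply(c("control", "knockdown"), function(cond) {
      fr <- simulate_mnase(genome, cond, gcfg)
      occ <- compute_occupancy(fr, lens, smoothing_sd = 20)
      write_bedgraph(occ, file.path(outdir,
                                    sprintf("occupancy_%s.bedGraph", cond)))
      anchor_matrix(occ, prom)
    })
    log_line(con, "+1 search [0, 250] bp, min_prominence 0.25, max_lag 100")
    st <- shift_table(mats[[1]], mats[[2]])
    zones <- occupancy_difference(mats[[1]], mats[[2]])$zones
    calls <- do.call(rbind, lapply(rownames(mats[[1]]), function(g) {
      cc <- call_plus_one(mats[[1]][g, ])
      data.frame(gene = g, dyad = cc$dyad, five_prime_edge =
                   cc$five_prime_edge, occupancy = cc$occupancy)
    }))
    out <- merge(merge(calls, st, by = "gene"), zones, by = "gene")
    write_counts(out, file.path(outdir, "nucleosome_calls.tsv"))
  }

  if ("classify" %in% cfg$stages) {
    log_line(con, "classify: NSL window +/-290 bp, Pol II window +/-145 bp, pseudocount 0.1, kmeans seed 0")
    tracks <- list(
      NSL3 = simulate_chip(genome, "NSL3", "control", gcfg),
      MBDR2 = simulate_chip(genome, "MBDR2", "control", gcfg),
      PolII_control = simulate_chip(genome, "PolII", "control", gcfg),
      PolII_knockdown = simulate_chip(genome, "PolII", "knockdown", gcfg),
      input = simulate_chip(genome, "input", "control", gcfg)
    )
    enr <- promoter_enrichment(prom, tracks)
    write_counts(classify_promoters(enr),
                 file.path(outdir, "promoter_classes.tsv"))
    nsl1 <- simulate_chip(genome, "NSL1", "control", gcfg)
    nurf <- simulate_chip(genome, "NURF301", "control", gcfg)
    pk1 <- call_peaks(nsl1, threshold = 1.5)
    pk2 <- call_peaks(nurf, threshold = 1.5)
    ov <- interval_overlap_stats(pk1, pk2,
                                 tss = data.frame(chrom = prom$chrom,
                                                  start = prom$tss,
                                                  end = prom$tss + 1L))
    write_counts(as.data.frame(ov), file.path(outdir, "peak_overlap.tsv"))
  }

  if ("binding" %in% cfg$stages) {
    log_line(con, "binding: 61 x 29-bp AT windows, 10-fold CV, threshold 0.5, slope t-test p < 0.05")
    feat <- at_features(genome$genome, prom)
    labels <- structure(genome$truth$is_nsl_target, names = prom$gene)
    rep_ <- fit_at_logistic(feat, labels[rownames(feat)], seed = cfg$seed)
    write_counts(data.frame(gene = names(rep_$prob), fold = rep_$fold,
                            prob = rep_$prob, predicted = rep_$pred),
                 file.path(outdir, "binding_cv_predictions.tsv"))
    write_counts(window_slope_profile(rep_),
                 file.path(outdir, "binding_window_slopes.tsv"))
    write_counts(data.frame(sensitivity = rep_$sensitivity,
                            specificity = rep_$specificity,
                            accuracy = rep_$accuracy),
                 file.path(outdir, "binding_cv_summary.tsv"))
  }

  if ("kmer" %in% cfg$stages) {
    log_line(con, "kmer: 200-bp bins, all 1024 5-mers, partial correlation given AT")
    bins <- simulate_invitro_binding(genome, gcfg)
    nb <- nrow(bins)
    v <- Biostrings::Views(genome$genome[["chrS"]],
                           start = bins$start + 1L, width = 200L)
    screen <- kmer_partial_screen(Biostrings::DNAStringSet(v),
                                  bins$log_enrichment)
    write_counts(screen, file.path(outdir, "kmer_screen.tsv"))
    log_line(con, "kmer: %d bins screened", nb)
  }

  if ("tss" %in% cfg$stages) {
    log_line(con, "tss: G-test, min_count 20, shift FDR 5%%, expression FDR 10%%")
    tab <- rbind(simulate_mapcap(genome, "control", cfg$mapcap_depth, gcfg),
                 simulate_mapcap(genome, "knockdown", cfg$mapcap_depth,
                                 gcfg))
    shifts <- detect_tss_shift(tab)
    write_counts(shifts, file.path(outdir, "tss_shift_calls.tsv"))
    de <- differential_tss_expression(tab)
    write_counts(de, file.path(outdir, "tss_differential_expression.tsv"))
    spreads <- data.frame(
      gene = prom$gene,
      spread = vapply(prom$gene, function(g)
        as.numeric(tss_spread(tab, "control", gene = g)), numeric(1)),
      is_nsl_target = genome$truth$is_nsl_target)
    write_counts(spreads, file.path(outdir, "tss_spread.tsv"))
  }

  if ("noise" %in% cfg$stages) {
    log_line(con, "noise: permutation test (%d perms), FDR 10%%, non-DE gate |log2FC| < 0.25",
             cfg$noise_n_perm)
    mc <- simulate_scrna(genome$truth, "control", gcfg)
    mk <- simulate_scrna(genome$truth, "knockdown", gcfg)
    calls <- test_differential_noise(mc, mk, n_perm = cfg$noise_n_perm,
                                     seed = cfg$seed)
    write_counts(calls, file.path(outdir, "noise_calls.tsv"))
  }

  log_line(con, "done")
  invisible(outdir)
}
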