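#' Read a FASTA file
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  Biostrings::readDNAStringSet(path)
}

#' Write sequences to FASTA
#'
#' @param seqs a [Biostrings::DNAStringSet] (or coercible named character).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

bed_cols <- c("chrom", "start", "end", "name", "score", "strand")

validate_intervals <- function(df, what = "interval") {
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad))
    stopf("%s record %d (%s:[%s,%s)) violates 0 <= start < end",
          what, bad[1], df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]])
  invisible(df)
}

#' Read a BED file
#'
#' Reads BED3-BED6; missing optional columns are filled (`name` = ".",
#' `score` = 0, `strand` = "."). Coordinates are kept 0-based, half-open
#' (the BED convention, also the package-internal convention).
#'
#' @param path path to a BED file.
#' @return A data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(nf) && any(nf < 3)) {
    ln <- which(keep)[which(nf < 3)[1]]
    stopf("malformed BED line %d in %s: fewer than 3 fields", ln, path)
  }
  get_col <- function(i, default) vapply(fields, function(f)
    if (length(f) >= i) f[i] else default, character(1))
  df <- data.frame(
    chrom = get_col(1, NA_character_),
    start = suppressWarnings(as.integer(get_col(2, NA_character_))),
    end = suppressWarnings(as.integer(get_col(3, NA_character_))),
    name = get_col(4, "."),
    score = suppressWarnings(as.numeric(get_col(5, "0"))),
    strand = get_col(6, "."),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad))
    stopf("malformed BED line %d in %s: non-numeric coordinate",
          which(keep)[bad[1]], path)
  validate_intervals(df, "BED")
}

#' Write intervals as BED6
#'
#' @param df data.frame with at least chrom, start, end (0-based half-open);
#'   optional name, score, strand.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    name = df$name %||% ".", score = df$score %||% 0,
    strand = df$strand %||% "."
  )
  validate_intervals(out, "BED")
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GFF3 file
#'
#' GFF3 coordinates are 1-based inclusive on disk; they are converted to the
#' internal 0-based half-open convention (a GFF3 feature at 101..200 becomes
#' the interval [100, 200)).
#'
#' @param path path to a GFF3 file.
#' @return data.frame with chrom, source, type, start, end (0-based
#'   half-open), score, strand, phase, attributes.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(nf) && any(nf != 9)) {
    ln <- which(keep)[which(nf != 9)[1]]
    stopf("malformed GFF3 line %d in %s: expected 9 fields, got %d",
          ln, path, nf[nf != 9][1])
  }
  g <- function(i) vapply(fields, `[`, character(1), i)
  df <- data.frame(
    chrom = g(1), source = g(2), type = g(3),
    start = suppressWarnings(as.integer(g(4))) - 1L,
    end = suppressWarnings(as.integer(g(5))),
    score = g(6), strand = g(7), phase = g(8), attributes = g(9),
    stringsAsFactors = FALSE
  )
  validate_intervals(df, "GFF3")
}

#' Write features as GFF3
#'
#' Internal 0-based half-open intervals are converted back to the 1-based
#' inclusive GFF3 convention.
#'
#' @param df data.frame as returned by [read_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(df, path) {
  validate_intervals(df, "GFF3")
  out <- data.frame(
    df$chrom, df$source %||% "nslchrom", df$type %||% "gene",
    df$start + 1L, df$end, df$score %||% ".", df$strand %||% ".",
    df$phase %||% ".", df$attributes %||% "."
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file into a per-base Track
#'
#' @param path path to a bedGraph file.
#' @param chrom_lengths named integer vector of chromosome lengths; bases
#'   not covered by any record are 0.
#' @return A [Track()].
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "value"))
  df <- as.data.frame(dt)
  validate_intervals(df, "bedGraph")
  sig <- lapply(names(chrom_lengths), function(nm) numeric(chrom_lengths[[nm]]))
  names(sig) <- names(chrom_lengths)
  for (nm in unique(df$chrom)) {
    if (is.null(sig[[nm]])) stopf("bedGraph chromosome '%s' not in lengths", nm)
    sub <- df[df$chrom == nm, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (any(sub$start[-1] < sub$end[-nrow(sub)]))
      stopf("bedGraph has overlapping intervals on %s", nm)
    if (any(sub$end > length(sig[[nm]])))
      stopf("bedGraph interval beyond end of %s", nm)
    for (i in seq_len(nrow(sub)))
      sig[[nm]][(sub$start[i] + 1):sub$end[i]] <- sub$value[i]
  }
  Track(sig)
}

#' Write a Track as bedGraph
#'
#' Consecutive equal values are collapsed into single records; zero runs are
#' omitted.
#'
#' @param track a [Track()].
#' @param path output path.
#' @param keep_zero write zero-valued runs too (needed for lossless
#'   round-trips of dense tracks). Default FALSE.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, keep_zero = FALSE) {
  recs <- list()
  for (nm in names(track)) {
    r <- rle(track[[nm]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- if (keep_zero) rep(TRUE, length(r$values)) else r$values != 0
    if (any(keep))
      recs[[nm]] <- data.frame(chrom = nm, start = start[keep],
                               end = end[keep], value = r$values[keep])
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               value = numeric())
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tabular counts file (TSV with header)
#'
#' @param path path to a tab-separated file with a header line.
#' @return A data.frame.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
}

#' Write a tabular result as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
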