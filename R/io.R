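#' Genome sequence container
#'
#' Holds per-chromosome DNA sequences over the alphabet {A,C,G,T,N}.
#' Sequences are upper-cased on construction and any character outside the
#' alphabet is mapped to N.
#'
#' @param seqs Named character vector, one string per chromosome.
#' @return An object of class `genome_sequence` with fields `seq` (named
#'   character vector) and `lengths` (named integer vector).
#' @export
genome_sequence <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    stop("all chromosomes must be named")
  seqs <- toupper(seqs)
  seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  structure(list(seq = seqs, lengths = nchar(seqs)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("genome_sequence: %d chromosome(s), %s bp total\n",
              length(x$seq), format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

#' Chromosome lengths of a genome
#' @param genome A [genome_sequence].
#' @return Named integer vector.
#' @export
genome_lengths <- function(genome) genome$lengths

#' Extract a genomic subsequence (0-based half-open)
#' @param genome A [genome_sequence].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @return Character string of length `end - start`.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome$seq))
    stop(sprintf("unknown chromosome '%s'", chrom))
  if (start < 0 || end > genome$lengths[[chrom]] || start >= end)
    stop("invalid subsequence coordinates")
  substr(genome$seq[[chrom]], start + 1L, end)
}

#' Read a genome from FASTA
#'
#' Lower-case sequence is upper-cased and non-ACGTN characters become N.
#'
#' @param path FASTA file.
#' @return A [genome_sequence].
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- vapply(strsplit(names(ss), "[ \t]"), `[[`, character(1), 1L)
  genome_sequence(seqs)
}

#' Write a genome to FASTA
#' @param genome A [genome_sequence].
#' @param path Output file.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

validate_intervals <- function(df) {
  if (any(df$end <= df$start))
    stop("interval end must be greater than start")
  invisible(df)
}

granges_to_df <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  df$name <- if ("name" %in% colnames(mc)) as.character(mc$name) else "."
  df$score <- if ("score" %in% colnames(mc)) as.numeric(mc$score) else 0
  s <- as.character(GenomicRanges::strand(gr))
  df$strand <- ifelse(s == "*", ".", s)
  df
}

df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df))
      ifelse(df$strand %in% c("+", "-"), df$strand, "*") else "*")
}

#' Read intervals from a BED file
#'
#' Coordinates are stored 0-based half-open (BED native).  `track` and
#' `browser` header lines are tolerated.
#'
#' @param path BED file (3-6 columns).
#' @return data.frame with columns chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  validate_intervals(granges_to_df(gr))
}

#' Write intervals as BED6
#' @param df data.frame with chrom, start, end and optional name, score,
#'   strand columns (0-based half-open).
#' @param path Output file.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  nm <- if ("name" %in% names(df)) df$name else "."
  sc <- if ("score" %in% names(df)) df$score else 0
  st <- if ("strand" %in% names(df)) df$strand else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                     df$chrom, as.integer(df$start), as.integer(df$end),
                     nm, sc, st), path)
  invisible(path)
}

#' Read peaks from a narrowPeak (or plain BED) file
#'
#' @param path narrowPeak file (BED6+4).
#' @return data.frame as [read_bed], with extra columns signalValue,
#'   pValue, qValue, peak when present.
#' @export
read_narrowpeak <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED",
                        extraCols = c(signalValue = "numeric",
                                      pValue = "numeric",
                                      qValue = "numeric",
                                      peak = "integer")),
    error = function(e) rtracklayer::import(path, format = "BED"))
  df <- granges_to_df(gr)
  mc <- S4Vectors::mcols(gr)
  for (col in c("signalValue", "pValue", "qValue", "peak"))
    if (col %in% colnames(mc)) df[[col]] <- mc[[col]]
  validate_intervals(df)
}

#' Write peaks as narrowPeak
#' @param df data.frame with chrom, start, end (0-based half-open); optional
#'   name, score, strand, signalValue, pValue, qValue, peak.
#' @param path Output file.
#' @export
write_narrowpeak <- function(df, path) {
  validate_intervals(df)
  get <- function(col, default) if (col %in% names(df)) df[[col]] else default
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s\t%g\t%g\t%g\t%d",
                     df$chrom, as.integer(df$start), as.integer(df$end),
                     get("name", "."), get("score", 0), get("strand", "."),
                     get("signalValue", 0), get("pValue", -1),
                     get("qValue", -1), as.integer(get("peak", -1))), path)
  invisible(path)
}

#' Per-base conservation track
#'
#' Scores default to 0 at positions (or chromosomes) with no data.
#'
#' @param scores Named list of numeric [S4Vectors::Rle] (or plain numeric)
#'   vectors, one per chromosome, 0-based position i stored at element i+1.
#' @return An object of class `conservation_track`.
#' @export
conservation_track <- function(scores = list()) {
  scores <- lapply(scores, function(v) S4Vectors::Rle(as.numeric(v)))
  for (v in scores) {
    rv <- S4Vectors::runValue(v)
    if (any(rv < 0 | rv > 1)) stop("conservation scores must lie in [0,1]")
  }
  structure(list(scores = scores), class = "conservation_track")
}

#' Query conservation values over a window
#'
#' @param track A [conservation_track].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window.
#' @return Numeric vector of length `end - start`; undefined positions are 0.
#' @export
track_values <- function(track, chrom, start, end) {
  n <- end - start
  if (n <= 0) return(numeric(0))
  out <- numeric(n)
  v <- track$scores[[chrom]]
  if (is.null(v)) return(out)
  len <- length(v)
  lo <- max(start, 0L); hi <- min(end, len)
  if (hi > lo)
    out[(lo - start + 1L):(hi - start)] <- as.numeric(v[(lo + 1L):hi])
  out
}

#' Read a conservation track from wiggle or bedGraph
#'
#' fixedStep/variableStep wiggle (1-based) is converted to the internal
#' 0-based convention; bedGraph is native 0-based half-open.  The format is
#' sniffed from the file content, so either works regardless of extension.
#'
#' @param path wig or bedGraph file.
#' @return A [conservation_track].
#' @export
read_wig_or_bedgraph <- function(path) {
  head_lines <- readLines(path, n = 50L)
  is_wig <- any(grepl("^(fixedStep|variableStep)", head_lines))
  gr <- rtracklayer::import(path, format = if (is_wig) "WIG" else "bedGraph")
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  conservation_track(as.list(cov))
}

#' Write a conservation track as bedGraph
#' @param track A [conservation_track].
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  out <- character(0)
  for (chrom in names(track$scores)) {
    v <- track$scores[[chrom]]
    ends <- cumsum(S4Vectors::runLength(v))
    starts <- c(0L, ends[-length(ends)])
    vals <- S4Vectors::runValue(v)
    keep <- vals != 0
    if (any(keep))
      out <- c(out, sprintf("%s\t%d\t%d\t%s", chrom, starts[keep],
                            ends[keep], format(vals[keep], digits = 10)))
  }
  writeLines(out, path)
  invisible(path)
}
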