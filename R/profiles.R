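#' Per-base count profile
#'
#' @param counts Named list of numeric vectors, one per chromosome, entry
#'   i+1 holding the count at 0-based position i.
#' @param kind Either "read" or "cut".
#' @return An object of class `base_profile`.
#' @export
base_profile <- function(counts, kind = c("read", "cut")) {
  kind <- match.arg(kind)
  if (any(vapply(counts, function(v) any(v < 0), logical(1))))
    stop("profile counts must be nonnegative")
  structure(list(counts = counts, kind = kind), class = "base_profile")
}

#' @export
print.base_profile <- function(x, ...) {
  cat(sprintf("base_profile (%s): %d chromosome(s), total %g\n",
              x$kind, length(x$counts), sum(vapply(x$counts, sum, 0))))
  invisible(x)
}

coverage_vector <- function(starts, ends, len) {
  # starts/ends 0-based half-open; returns dense numeric of length len
  if (length(starts) == 0L) return(numeric(len))
  ir <- IRanges::IRanges(start = starts + 1L, end = ends)
  as.numeric(IRanges::coverage(ir, width = len))
}

#' Build read and cut profiles from aligned reads
#'
#' The read profile counts, at every base, the number of reads covering it.
#' The cut profile counts the terminal bases at each end of every read
#' (with the default `bases_per_end = 2`: positions start, start+1, end-2
#' and end-1); for reads shorter than `2 * bases_per_end` the terminal
#' positions are deduplicated within the read, so each read contributes
#' `min(2 * bases_per_end, length)` cut counts.
#'
#' @param reads data.frame with columns chrom, start, end (0-based
#'   half-open) and optionally strand.
#' @param genome A [genome_sequence] providing chromosome lengths.
#' @param bases_per_end Terminal bases counted at each read end in the cut
#'   profile (default 2).
#' @return List with elements `read` and `cut`, both [base_profile]s.
#' @export
reads_to_profiles <- function(reads, genome, bases_per_end = 2L) {
  if (bases_per_end < 1L) stop("bases_per_end must be at least 1")
  lens <- genome_lengths(genome)
  bad <- !(reads$chrom %in% names(lens))
  if (any(bad))
    stop(sprintf("read on unknown chromosome '%s'", reads$chrom[bad][1]))
  if (any(reads$start < 0) || any(reads$end > lens[reads$chrom]) ||
      any(reads$end <= reads$start))
    stop("read outside chromosome bounds")
  read_counts <- list()
  cut_counts <- list()
  for (chrom in names(lens)) {
    r <- reads[reads$chrom == chrom, , drop = FALSE]
    len <- lens[[chrom]]
    read_counts[[chrom]] <- coverage_vector(r$start, r$end, len)
    w <- r$end - r$start
    short <- w <= 2L * bases_per_end
    # short reads: the two end windows merge into the whole read
    cs <- c(r$start[short], r$start[!short], r$end[!short] - bases_per_end)
    ce <- c(r$end[short], r$start[!short] + bases_per_end, r$end[!short])
    cut_counts[[chrom]] <- coverage_vector(cs, ce, len)
  }
  list(read = base_profile(read_counts, "read"),
       cut = base_profile(cut_counts, "cut"))
}

#' Total counts in a profile
#' @param profile A [base_profile].
#' @return Numeric scalar.
#' @export
profile_total <- function(profile) sum(vapply(profile$counts, sum, 0))
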