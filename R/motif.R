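DNA_BASES <- c("A", "C", "G", "T")

#' Construct a motif count matrix
#'
#' A count matrix holds, for each motif position, the observed counts of the
#' four bases (columns in A, C, G, T order), as distributed by TRANSFAC.
#'
#' @param name Text identifier of the motif.
#' @param counts Numeric matrix with one row per motif position and four
#'   columns (A, C, G, T).  All entries must be nonnegative and every
#'   position must have at least one positive count.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(name, counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4L)
    stop("count matrix must have exactly 4 columns (A,C,G,T)")
  if (nrow(counts) < 1L)
    stop("count matrix must have at least one position")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("count matrix entries must be finite and nonnegative")
  if (any(rowSums(counts) <= 0))
    stop("every motif position needs at least one positive count")
  colnames(counts) <- DNA_BASES
  rownames(counts) <- NULL
  structure(list(name = as.character(name), counts = counts),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix '%s' (%d positions)\n", x$name, nrow(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Parse TRANSFAC-style count matrices
#'
#' Reads one or more TRANSFAC matrix blocks.  A block is introduced by an
#' `ID` (and/or `DE`/`NA`) line, contains numbered count rows
#' (`01  8 0 0 0 [consensus]`), and is terminated by `XX` or `//`.  An
#' optional `P0/PO` column-header line is tolerated, as are `track` or
#' `browser` lines and blank lines.
#'
#' @param path Path to a TRANSFAC text file, or a character vector of lines.
#' @return A list of [count_matrix] objects (possibly empty).
#' @export
parse_transfac <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  motifs <- list()
  cur_name <- NULL
  cur_rows <- list()
  flush <- function() {
    if (length(cur_rows) > 0L) {
      counts <- do.call(rbind, cur_rows)
      nm <- if (is.null(cur_name)) sprintf("motif_%d", length(motifs) + 1L) else cur_name
      motifs[[length(motifs) + 1L]] <<- count_matrix(nm, counts)
    }
    cur_name <<- NULL
    cur_rows <<- list()
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || grepl("^(track|browser)", ln)) next
    fields <- strsplit(ln, "[ \t]+")[[1]]
    tag <- toupper(fields[[1]])
    if (tag %in% c("XX", "//")) { flush(); next }
    if (tag %in% c("ID", "NA", "DE")) {
      if (is.null(cur_name) && length(fields) > 1L)
        cur_name <- paste(fields[-1L], collapse = "_")
      next
    }
    if (tag %in% c("P0", "PO")) next
    if (grepl("^[0-9]+$", fields[[1]])) {
      vals <- fields[-1L]
      # tolerate a trailing consensus letter
      if (length(vals) == 5L && grepl("^[A-Za-z]$", vals[[5L]]))
        vals <- vals[1:4]
      num <- suppressWarnings(as.numeric(vals))
      if (length(num) != 4L || any(is.na(num)) || any(num < 0))
        stop(sprintf("malformed TRANSFAC count row at line %d: '%s'", i, lines[[i]]))
      cur_rows[[length(cur_rows) + 1L]] <- num
      next
    }
    # other annotation tags (BF, CC, ...) are ignored
  }
  flush()
  motifs
}

#' Write count matrices in TRANSFAC format
#'
#' @param motifs A [count_matrix] or list of them.
#' @param path Output file.
#' @export
write_transfac <- function(motifs, path) {
  if (inherits(motifs, "count_matrix")) motifs <- list(motifs)
  out <- character(0)
  for (m in motifs) {
    out <- c(out, paste("ID", m$name), "P0      A      C      G      T")
    for (i in seq_len(nrow(m$counts))) {
      out <- c(out, sprintf("%02d %6g %6g %6g %6g", i,
                            m$counts[i, 1], m$counts[i, 2],
                            m$counts[i, 3], m$counts[i, 4]))
    }
    out <- c(out, "XX")
  }
  writeLines(out, path)
  invisible(path)
}

#' Construct a log-odds position weight matrix
#'
#' @param name Motif name.
#' @param logodds Numeric matrix, one row per position, columns A, C, G, T;
#'   all entries finite.
#' @param background Background base probabilities (A, C, G, T); must be
#'   positive and sum to 1.
#' @return An object of class `pwmotif` with fields `name`, `logodds`,
#'   `background` and `length`.
#' @export
pwmotif <- function(name, logodds, background = rep(0.25, 4)) {
  logodds <- as.matrix(logodds)
  if (ncol(logodds) != 4L) stop("log-odds matrix must have 4 columns")
  if (any(!is.finite(logodds))) stop("log-odds scores must all be finite")
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 positive probabilities")
  if (abs(sum(background) - 1) > 1e-9)
    stop("background probabilities must sum to 1")
  colnames(logodds) <- DNA_BASES
  background <- as.numeric(background)
  names(background) <- DNA_BASES
  structure(list(name = as.character(name), logodds = logodds,
                 background = background, length = nrow(logodds)),
            class = "pwmotif")
}

#' @export
print.pwmotif <- function(x, ...) {
  cat(sprintf("pwmotif '%s' (%d positions, consensus %s)\n",
              x$name, x$length, motif_consensus(x)))
  invisible(x)
}

#' Convert a count matrix to a log-odds PWM
#'
#' Per position i and base b the score is
#' `log2((count[i,b] + pc * bg[b]) / (sum(count[i,]) + pc) / bg[b])`,
#' where `pc` is the total pseudocount distributed according to the
#' background.  All scores are finite for positive `pc`.
#'
#' @param cm A [count_matrix].
#' @param background Background base probabilities (default uniform).
#' @param pseudocount_total Total pseudocount added per position (> 0).
#' @return A [pwmotif].
#' @export
counts_to_logodds <- function(cm, background = rep(0.25, 4),
                              pseudocount_total = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(background <= 0)) stop("background entries must be positive")
  if (pseudocount_total <= 0) stop("pseudocount_total must be positive")
  counts <- cm$counts
  tot <- rowSums(counts) + pseudocount_total
  bg <- matrix(background, nrow = nrow(counts), ncol = 4L, byrow = TRUE)
  p <- (counts + pseudocount_total * bg) / tot
  pwmotif(cm$name, log2(p / bg), background)
}

#' Consensus sequence of a motif
#'
#' @param x A [count_matrix] or [pwmotif].
#' @return Character string, the per-position argmax base.
#' @export
motif_consensus <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else x$logodds
  paste(DNA_BASES[apply(m, 1L, which.max)], collapse = "")
}

#' Information content of a count matrix
#'
#' @param cm A [count_matrix].
#' @param background Background probabilities.
#' @return Numeric vector of per-position information content in bits.
#' @export
motif_information <- function(cm, background = rep(0.25, 4)) {
  p <- cm$counts / rowSums(cm$counts)
  bg <- matrix(background, nrow = nrow(p), ncol = 4L, byrow = TRUE)
  rowSums(ifelse(p > 0, p * log2(p / bg), 0))
}
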