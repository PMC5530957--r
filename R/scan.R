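BASE_LUT <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("N")] <- 5L
  lut
})

encode_bases <- function(seq) {
  codes <- BASE_LUT[utf8ToInt(seq)]
  if (anyNA(codes)) stop("sequence contains characters outside {A,C,G,T,N}")
  codes
}

#' Score a sequence window against a PWM
#'
#' Sums the log-odds entry of the observed base at each motif position.
#' An N contributes the background-expected score of its position,
#' `sum(background * logodds[i, ])`.
#'
#' @param pwm A [pwmotif].
#' @param window Character string of length `pwm$length` over {A,C,G,T,N}.
#' @return Numeric score.
#' @export
score_window <- function(pwm, window) {
  window <- toupper(window)
  if (nchar(window) != pwm$length)
    stop(sprintf("window length %d does not match motif length %d",
                 nchar(window), pwm$length))
  codes <- encode_bases(window)
  expected <- as.numeric(pwm$logodds %*% pwm$background)
  ord <- codes < 5L
  s <- 0
  if (any(ord))
    s <- s + sum(pwm$logodds[cbind(which(ord), codes[ord])])
  if (any(!ord))
    s <- s + sum(expected[!ord])
  s
}

#' Exact null score distribution of a PWM
#'
#' Log-odds entries are discretized to integers by `round(score * scale)`
#' and the distribution of the window score under independent background
#' bases is computed by position-wise convolution.  Exceedance
#' probabilities P(S >= s) are exact on the discretized grid; genome scans
#' use the same discretization, so scan p-values agree exactly with
#' brute-force enumeration of all windows.
#'
#' @param pwm A [pwmotif].
#' @param scale Discretization scale (integer >= 10; default 1000).
#' @return An object of class `score_distribution` with fields `scale`,
#'   `support` (integer score grid), `pmf` and `exceedance`.
#' @export
null_distribution <- function(pwm, scale = 1000L) {
  scale <- as.integer(scale)
  if (scale < 10L) stop("scale must be at least 10")
  m <- round(pwm$logodds * scale)
  bg <- pwm$background
  lo <- 0L; pmf <- 1
  for (i in seq_len(pwm$length)) {
    vals <- m[i, ]
    newlo <- lo + min(vals)
    newhi <- lo + length(pmf) - 1L + max(vals)
    new <- numeric(newhi - newlo + 1L)
    for (b in 1:4) {
      off <- lo + vals[b] - newlo
      idx <- (off + 1L):(off + length(pmf))
      new[idx] <- new[idx] + pmf * bg[b]
    }
    pmf <- new; lo <- as.integer(newlo)
  }
  structure(list(scale = scale,
                 support = seq.int(lo, lo + length(pmf) - 1L),
                 pmf = pmf,
                 exceedance = rev(cumsum(rev(pmf)))),
            class = "score_distribution")
}

int_logodds <- function(pwm, scale) round(pwm$logodds * scale)

exceedance_at_int <- function(dist, int_score) {
  lo <- dist$support[1L]; hi <- dist$support[length(dist$support)]
  out <- numeric(length(int_score))
  out[int_score <= lo] <- 1
  mid <- int_score > lo & int_score <= hi
  out[mid] <- dist$exceedance[int_score[mid] - lo + 1L]
  out[int_score > hi] <- 0
  out
}

#' P-value of a PWM score under the null distribution
#'
#' @param dist A [null_distribution] result.
#' @param score Numeric score(s) on the log-odds scale.
#' @return Exceedance probability P(S >= score) on the discretized grid.
#' @export
score_pvalue <- function(dist, score) {
  exceedance_at_int(dist, round(score * dist$scale))
}

window_int_scores <- function(codes, m_int) {
  # m_int: L x 4 integer; codes: 1..5 (5 = N); returns integer sums per
  # window start (1-based), N windows included (masked by caller)
  L <- nrow(m_int)
  W <- length(codes) - L + 1L
  s <- numeric(W)
  for (i in seq_len(L)) {
    col <- c(m_int[i, ], 0)
    s <- s + col[codes[i:(i + W - 1L)]]
  }
  s
}

revcomp_pwm <- function(pwm) {
  pwmotif(pwm$name, pwm$logodds[pwm$length:1, 4:1, drop = FALSE],
          pwm$background[4:1])
}

#' Reverse complement of a DNA string
#' @param seq Character string over {A,C,G,T,N}.
#' @return Character string.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Scan a genome for candidate binding sites
#'
#' Both strands are scanned; reverse-strand windows are scored on the
#' reverse complement but reported in forward coordinates.  Windows
#' containing N are skipped.  A window is reported when the exact
#' exceedance probability of its (discretized) score is at most
#' `pvalue_cutoff`.
#'
#' @param pwm A [pwmotif].
#' @param genome A [genome_sequence].
#' @param pvalue_cutoff P-value threshold in (0, 1]; the study default for
#'   calling a PWM match is 1e-4.
#' @param scale Score discretization scale (see [null_distribution]).
#' @return data.frame of candidate sites: site_id, chrom, start, end,
#'   strand, pwm_score, pvalue; sorted by (chrom, start, strand).
#' @export
scan_genome <- function(pwm, genome, pvalue_cutoff = 1e-4, scale = 1000L) {
  if (pvalue_cutoff <= 0 || pvalue_cutoff > 1)
    stop("pvalue_cutoff must be in (0, 1]")
  L <- pwm$length
  dist <- null_distribution(pwm, scale)
  m_fwd <- int_logodds(pwm, scale)
  m_rev <- int_logodds(revcomp_pwm(pwm), scale)
  hits <- list()
  for (chrom in names(genome$seq)) {
    len <- genome$lengths[[chrom]]
    if (len < L) next
    codes <- encode_bases(genome$seq[[chrom]])
    W <- len - L + 1L
    ncum <- c(0L, cumsum(codes == 5L))
    has_n <- (ncum[(1L:W) + L] - ncum[1L:W]) > 0L
    for (strand in c("+", "-")) {
      m <- if (strand == "+") m_fwd else m_rev
      s_int <- window_int_scores(codes, m)
      pv <- exceedance_at_int(dist, s_int)
      keep <- which(!has_n & pv <= pvalue_cutoff)
      if (length(keep) == 0L) next
      start0 <- keep - 1L
      win <- substring(genome$seq[[chrom]], keep, keep + L - 1L)
      score <- vapply(seq_along(keep), function(j) {
        w <- win[[j]]
        score_window(pwm, if (strand == "-") revcomp(w) else w)
      }, numeric(1))
      hits[[length(hits) + 1L]] <- data.frame(
        site_id = sprintf("%s:%d:%s", chrom, start0, strand),
        chrom = chrom, start = start0, end = start0 + L,
        strand = strand, pwm_score = score, pvalue = pv[keep],
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(site_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), pwm_score = numeric(0),
                      pvalue = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write candidate sites as TSV
#' @param sites data.frame from [scan_genome].
#' @param path Output file.
#' @export
write_sites_tsv <- function(sites, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("site_id\tchrom\tstart\tend\tstrand\tpwm_score\tpvalue", con)
  if (nrow(sites) > 0L)
    writeLines(sprintf("%s\t%s\t%d\t%d\t%s\t%s\t%s",
                       sites$site_id, sites$chrom, sites$start, sites$end,
                       sites$strand, sprintf("%.17g", sites$pwm_score),
                       sprintf("%.17g", sites$pvalue)), con)
  invisible(path)
}

#' Read candidate sites from TSV
#' @param path File written by [write_sites_tsv].
#' @return data.frame of candidate sites.
#' @export
read_sites_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "integer",
                                   "integer", "character", "numeric",
                                   "numeric"),
                    stringsAsFactors = FALSE)
}

#' Write candidate sites as BED6
#'
#' The BED score column is `round(1000 * pwm_score)` capped to [0, 1000].
#' @param sites data.frame from [scan_genome].
#' @param path Output file.
#' @export
write_sites_bed <- function(sites, path) {
  df <- data.frame(chrom = sites$chrom, start = sites$start,
                   end = sites$end, name = sites$site_id,
                   score = pmax(0, pmin(1000, round(1000 * sites$pwm_score))),
                   strand = sites$strand, stringsAsFactors = FALSE)
  write_bed(df, path)
}
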