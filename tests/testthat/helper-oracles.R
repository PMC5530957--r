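# Independent oracles and small fixture builders used across test files.

# Mann-Whitney pair-counting AUC: P(s+ > s-) + 0.5 P(s+ = s-) over all
# positive x negative pairs.
pair_count_auc <- function(scores, labels) {
  sp <- scores[labels == 1L]
  sn <- scores[labels == 0L]
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# Brute-force O(n*m) interval overlap (0-based half-open).
overlap_oracle <- function(sites, peaks) {
  vapply(seq_len(nrow(sites)), function(i) {
    any(peaks$chrom == sites$chrom[i] &
          peaks$start < sites$end[i] &
          peaks$end > sites$start[i])
  }, logical(1)) * 1L
}

# Exhaustive enumeration of all 4^L windows under a uniform background:
# exceedance over the same integer grid the package discretizes to.
enum_exceedance <- function(pwm, scale = 1000L) {
  m <- round(pwm$logodds * scale)
  v <- 0
  for (i in seq_len(pwm$length))
    v <- as.vector(outer(v, m[i, ], "+"))
  lo <- sum(apply(m, 1L, min))
  hi <- sum(apply(m, 1L, max))
  pmf <- tabulate(v - lo + 1L, nbins = hi - lo + 1L) / length(v)
  list(support = seq.int(lo, hi), exceedance = rev(cumsum(rev(pmf))))
}

# Random PWM built from a random count matrix.
rand_pwm <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- matrix(stats::rpois(4L * L, 5) + stats::rbinom(4L * L, 1, 0.3) * 40,
                   nrow = L)
  counts[rowSums(counts) == 0, 1L] <- 1
  counts_to_logodds(count_matrix("rand", counts))
}

# A tiny two-position PWM used by several scan tests.
dimer_pwm <- function() {
  pwmotif("dimer", rbind(c(1, -1, -1, -1), c(-1, 1, -1, -1)))
}

# Synthetic feature table with n rows (all 11 columns populated with
# nonnegative noise); returns a labeled_dataset with the given labels.
synth_dataset <- function(n, labels, seed = 1, tf = "TF", cell = "cell") {
  set.seed(seed)
  f <- data.frame(matrix(stats::runif(n * 11L), nrow = n,
                         dimnames = list(NULL, bpac_features())))
  sites <- data.frame(site_id = sprintf("s%05d", seq_len(n)),
                      chrom = "chr1",
                      start = seq_len(n) * 50L,
                      end = seq_len(n) * 50L + 12L,
                      strand = "+", pwm_score = f$pwm_score,
                      stringsAsFactors = FALSE)
  labeled_dataset(sites, f, labels, tf = tf, cell = cell)
}

# Small simulation config reused by scenario-level tests.
small_sim_config <- function(seed, tf = "TF1", cell = "cellA", ...) {
  simulation_config(genome_length = 3e5, n_sites = 100L, n_decoys = 100L,
                    seed = seed, tf = tf, cell = cell, ...)
}

file_md5 <- function(paths) unname(tools::md5sum(paths))
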