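MORPHOLOGIES <- c("footprint", "flat", "inverse", "mixed")

# site / flank placement-intensity multipliers per morphology
MORPH_MULT <- list(footprint = c(site = 0.3, flank = 2),
                   flat = c(site = 1, flank = 1),
                   inverse = c(site = 4, flank = 1),
                   background = c(site = 1, flank = 1))

#' Default synthetic motif
#'
#' An information-rich 12-position motif (~1.58 bits per column): the
#' consensus base carries 94 of 100 counts at every position.
#'
#' @param name Motif name.
#' @return A [count_matrix].
#' @export
default_motif <- function(name = "SYNTF") {
  consensus <- "TGACTCAGCGTA"
  idx <- match(strsplit(consensus, "")[[1]], DNA_BASES)
  counts <- matrix(2, nrow = nchar(consensus), ncol = 4L)
  counts[cbind(seq_along(idx), idx)] <- 94
  count_matrix(name, counts)
}

#' Simulation configuration
#'
#' Defaults define the reference desk-scale study condition: a 2 Mb
#' single-chromosome genome at human-like GC content, 400 planted motif
#' instances of which half are bound, 400 decoy matches (consensus with
#' 1-2 mismatches), classic footprint morphology at 200 expected reads
#' per site, 200 bp peaks and a weak conservation enrichment at bound
#' sites.
#'
#' @param genome_length Total genome length in bp.
#' @param n_chrom Number of chromosomes (length split evenly).
#' @param gc GC fraction in [0, 1].
#' @param motif A [count_matrix].
#' @param n_sites Number of planted motif instances.
#' @param bound_fraction Fraction of planted sites that are bound.
#' @param morphology One of "footprint", "flat", "inverse", "mixed".
#' @param depth Expected reads per site region.
#' @param background_fraction Unbound (closed-chromatin) sites receive
#'   `depth * background_fraction` expected reads.
#' @param read_length Read length in bp.
#' @param n_decoys Number of decoy (mismatched, never bound) instances.
#' @param peak_width Width of emitted ChIP-Seq peaks, centered on bound
#'   sites.
#' @param conservation_enrichment Additive conservation increment at
#'   bound sites (clipped to [0, 1]).
#' @param conservation_baseline_max Per-site baseline conservation is
#'   drawn uniformly from [0, this].
#' @param n_tss Number of random TSS positions.
#' @param seed Integer RNG seed (mandatory).
#' @param tf,cell Provenance tags.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 2e6, n_chrom = 1L, gc = 0.41,
                              motif = default_motif(), n_sites = 400L,
                              bound_fraction = 0.5,
                              morphology = "footprint", depth = 200,
                              background_fraction = 0.01,
                              read_length = 6L, n_decoys = n_sites,
                              peak_width = 200L,
                              conservation_enrichment = 0.1,
                              conservation_baseline_max = 0.6,
                              n_tss = 100L, seed = 1L,
                              tf = motif$name, cell = "simcell") {
  if (!morphology %in% MORPHOLOGIES)
    stop(sprintf("morphology must be one of %s",
                 paste(MORPHOLOGIES, collapse = ", ")))
  if (bound_fraction < 0 || bound_fraction > 1)
    stop("bound_fraction must lie in [0, 1]")
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  if (depth < 1) stop("depth must be at least 1")
  if (read_length < 1 || n_sites < 1 || genome_length < 10 * nrow(motif$counts))
    stop("lengths and counts must be positive (genome >= 10x motif length)")
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  structure(list(genome_length = genome_length, n_chrom = as.integer(n_chrom),
                 gc = gc, motif = motif, n_sites = as.integer(n_sites),
                 bound_fraction = bound_fraction, morphology = morphology,
                 depth = depth, background_fraction = background_fraction,
                 read_length = as.integer(read_length),
                 n_decoys = as.integer(n_decoys),
                 peak_width = as.integer(peak_width),
                 conservation_enrichment = conservation_enrichment,
                 conservation_baseline_max = conservation_baseline_max,
                 n_tss = as.integer(n_tss), seed = as.integer(seed),
                 tf = tf, cell = cell),
            class = "simulation_config")
}

#' Generate a random genome
#'
#' I.i.d. bases at the configured GC fraction.
#'
#' @param genome_length Total length in bp.
#' @param n_chrom Number of chromosomes (length split evenly).
#' @param gc GC fraction.
#' @param seed Optional seed; NULL uses the current RNG state.
#' @return A [genome_sequence] with chromosomes chr1..chrN.
#' @export
generate_genome <- function(genome_length, n_chrom = 1L, gc = 0.41,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  per <- rep(floor(genome_length / n_chrom), n_chrom)
  per[n_chrom] <- genome_length - sum(per[-n_chrom])
  base_raw <- charToRaw("ACGT")
  seqs <- vapply(per, function(len)
    rawToChar(base_raw[sample.int(4L, len, replace = TRUE, prob = probs)]),
    character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  genome_sequence(seqs)
}

sample_motif_instance <- function(motif, n_mismatches = NULL) {
  probs <- motif$counts / rowSums(motif$counts)
  L <- nrow(probs)
  if (is.null(n_mismatches)) {
    bases <- vapply(seq_len(L), function(i)
      sample(DNA_BASES, 1L, prob = probs[i, ]), character(1))
  } else {
    cons <- strsplit(motif_consensus(motif), "")[[1]]
    bases <- cons
    pos <- sample.int(L, n_mismatches)
    for (p in pos)
      bases[p] <- sample(setdiff(DNA_BASES, cons[p]), 1L)
  }
  paste(bases, collapse = "")
}

# batch-write instances: one raw-vector pass per chromosome
write_instances <- function(genome, chrom, start, instances, strand) {
  emitted <- ifelse(strand == "-", vapply(instances, revcomp, character(1)),
                    instances)
  for (ch in unique(chrom)) {
    r <- charToRaw(genome$seq[[ch]])
    for (i in which(chrom == ch)) {
      b <- charToRaw(emitted[[i]])
      r[(start[i] + 1L):(start[i] + length(b))] <- b
    }
    genome$seq[[ch]] <- rawToChar(r)
  }
  genome
}

#' Plant motif instances into a genome
#'
#' Writes `n` motif instances (sampled from the count-matrix base
#' frequencies, or consensus with a fixed number of mismatches) at random
#' non-overlapping positions on random strands.  Positions are laid out
#' on a jittered grid so that any two instances are at least `min_gap` bp
#' apart.
#'
#' @param genome A [genome_sequence].
#' @param motif A [count_matrix].
#' @param n Number of instances.
#' @param seed Optional seed; NULL uses the current RNG state.
#' @param min_gap Minimum gap between instances (bp).
#' @param mismatches NULL for frequency-sampled instances, or an integer
#'   vector (recycled) of forced mismatch counts from the consensus.
#' @return List with `genome` (modified copy) and `sites` (data.frame
#'   chrom, start, end, strand, sequence).
#' @export
plant_motifs <- function(genome, motif, n, seed = NULL, min_gap = 0L,
                         mismatches = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L)
    return(list(genome = genome,
                sites = data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0), strand = character(0),
                                   sequence = character(0))))
  L <- nrow(motif$counts)
  lens <- genome_lengths(genome)
  slot_w <- as.integer(L + max(1L, 2L * min_gap))
  slots <- list()
  for (chrom in names(lens)) {
    k <- floor((lens[[chrom]] - min_gap) / slot_w)
    if (k > 0L)
      slots[[chrom]] <- data.frame(
        chrom = chrom,
        slot_start = min_gap + slot_w * (seq_len(k) - 1L))
  }
  slots <- do.call(rbind, slots)
  if (is.null(slots) || nrow(slots) < n)
    stop("insufficient room to plant the requested motif instances")
  pick <- slots[sample.int(nrow(slots), n), , drop = FALSE]
  jitter_max <- slot_w - L - min_gap  # keeps pairwise gaps >= min_gap
  start <- pick$slot_start +
    if (jitter_max > 0L) sample.int(jitter_max + 1L, n, replace = TRUE) - 1L
    else 0L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  mm <- if (is.null(mismatches)) rep(list(NULL), n)
        else as.list(rep(mismatches, length.out = n))
  seqs <- character(n)
  for (i in seq_len(n))
    seqs[i] <- sample_motif_instance(motif, mm[[i]])
  genome <- write_instances(genome, pick$chrom, start, seqs, strand)
  sites <- data.frame(chrom = pick$chrom, start = start, end = start + L,
                      strand = strand, sequence = seqs,
                      instance = seq_len(n), stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$start), ]
  rownames(sites) <- NULL
  list(genome = genome, sites = sites)
}

site_region <- function(start, end, chrom_len) {
  L <- end - start
  c(max(0L, start - 2L * L), min(chrom_len, end + 2L * L))
}

#' Simulate accessibility reads around sites
#'
#' Each site receives a Poisson(depth) number of reads.  A cut position is
#' drawn from a piecewise-constant per-base intensity over the site
#' region (site +/- 2 motif lengths): the site body and the two
#' site-length flanks are scaled by morphology-specific multipliers
#' (footprint 0.3/2, inverse 2/1, flat 1/1; unbound sites uniform), and
#' the read extends `read_length` bp from the cut in a random direction.
#'
#' @param sites data.frame with chrom, start, end and a `morphology`
#'   column ("footprint", "flat", "inverse" or "background"); an optional
#'   `depth` column overrides the global depth per site.
#' @param genome A [genome_sequence] (for chromosome bounds).
#' @param depth Expected reads per site.
#' @param read_length Read length in bp.
#' @param seed Optional seed; NULL uses the current RNG state.
#' @return data.frame of reads (chrom, start, end, name, score, strand).
#' @export
simulate_reads <- function(sites, genome, depth = 200, read_length = 6L,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (depth < 1) stop("depth must be at least 1")
  lens <- genome_lengths(genome)
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    chrom <- sites$chrom[i]
    start <- sites$start[i]; end <- sites$end[i]
    L <- end - start
    reg <- site_region(start, end, lens[[chrom]])
    pos <- seq.int(reg[1L], reg[2L] - 1L)
    mult <- MORPH_MULT[[sites$morphology[i]]]
    w <- rep(1, length(pos))
    w[pos >= start - L & pos < start] <- mult[["flank"]]
    w[pos >= end & pos < end + L] <- mult[["flank"]]
    w[pos >= start & pos < end] <- mult[["site"]]
    site_depth <- if ("depth" %in% names(sites)) sites$depth[i] else depth
    n <- stats::rpois(1L, site_depth)
    if (n == 0L) next
    cut <- sample(pos, n, replace = TRUE, prob = w)
    fwd <- sample(c(TRUE, FALSE), n, replace = TRUE)
    rs <- ifelse(fwd, cut, cut - read_length + 1L)
    re <- rs + read_length
    rs <- pmax(rs, 0L); re <- pmin(re, lens[[chrom]])
    keep <- re > rs
    out[[i]] <- data.frame(chrom = chrom, start = as.integer(rs[keep]),
                           end = as.integer(re[keep]), name = ".",
                           score = 0,
                           strand = ifelse(fwd[keep], "+", "-"),
                           stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(reads))
    reads <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        score = numeric(0), strand = character(0))
  rownames(reads) <- NULL
  reads
}

simulate_conservation <- function(truth, genome, baseline_max, enrichment) {
  lens <- genome_lengths(genome)
  n <- nrow(truth)
  idx_l <- vector("list", n)
  val_l <- vector("list", n)
  for (i in seq_len(n)) {
    L <- truth$end[i] - truth$start[i]
    lo <- max(0L, truth$start[i] - L)
    hi <- min(lens[[truth$chrom[i]]], truth$end[i] + L)
    base <- stats::runif(1L, 0, baseline_max)
    vals <- pmin(1, pmax(0, base + stats::runif(hi - lo, -0.05, 0.05)))
    if (truth$bound[i] == 1L) {
      sel <- seq.int(truth$start[i] - lo + 1L, truth$end[i] - lo)
      vals[sel] <- pmin(1, vals[sel] + enrichment)
    }
    idx_l[[i]] <- seq.int(lo + 1L, hi)
    val_l[[i]] <- vals
  }
  vecs <- lapply(lens, numeric)
  for (ch in unique(truth$chrom)) {
    rows <- which(truth$chrom == ch)
    vecs[[ch]][unlist(idx_l[rows])] <- unlist(val_l[rows])
  }
  conservation_track(vecs)
}

#' Simulate a complete fixture bundle in memory
#'
#' Generates a genome with planted and decoy motif instances, bound
#' labels, morphology-shaped accessibility reads, peaks centered on bound
#' sites, a conservation track enriched at bound sites, TSS positions and
#' the ground-truth table.  Fully determined by the config (including its
#' seed).
#'
#' @param config A [simulation_config].
#' @return List of class `bpac_bundle` with elements genome, motif,
#'   reads, peaks, conservation, tss, truth and config.
#' @export
simulate_bundle <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- nrow(config$motif$counts)
  genome <- generate_genome(config$genome_length, config$n_chrom, config$gc)
  n_total <- config$n_sites + config$n_decoys
  # spacing keeps peaks on bound sites clear of all other instances
  min_gap <- config$peak_width + 4L * L
  mm_decoy <- if (config$n_decoys > 0L)
    sample(1:2, config$n_decoys, replace = TRUE) else integer(0)
  planted <- plant_motifs(genome, config$motif, n_total,
                          min_gap = min_gap,
                          mismatches = c(rep(list(NULL), config$n_sites),
                                         as.list(mm_decoy)))
  # plant_motifs sorts by position; recover which instances were decoys
  is_decoy <- rep(c(FALSE, TRUE),
                  c(config$n_sites, config$n_decoys))[planted$sites$instance]
  truth <- planted$sites
  truth$instance <- NULL
  truth$decoy <- is_decoy
  bound <- integer(n_total)
  planted_idx <- which(!is_decoy)
  n_bound <- stats::rbinom(1L, config$n_sites, config$bound_fraction)
  bound[planted_idx[sample.int(length(planted_idx), n_bound)]] <- 1L
  truth$bound <- bound
  morph <- rep("background", n_total)
  if (config$morphology == "mixed") {
    b <- which(bound == 1L)
    morph[b] <- sample(c("footprint", "inverse"), length(b), replace = TRUE)
  } else {
    morph[bound == 1L] <- config$morphology
  }
  truth$morphology <- morph
  truth$site_id <- sprintf("%s_%04d", ifelse(is_decoy, "decoy", "planted"),
                           seq_len(n_total))
  truth$depth <- ifelse(bound == 1L, config$depth,
                        config$depth * config$background_fraction)
  reads <- simulate_reads(truth, planted$genome, config$depth,
                          config$read_length)
  truth$depth <- NULL
  cons <- simulate_conservation(truth, planted$genome,
                                config$conservation_baseline_max,
                                config$conservation_enrichment)
  lens <- genome_lengths(planted$genome)
  tss_chrom <- sample(names(lens), config$n_tss, replace = TRUE,
                      prob = lens / sum(lens))
  tss_pos <- vapply(tss_chrom, function(ch) sample.int(lens[[ch]], 1L) - 1L,
                    integer(1))
  tss <- data.frame(chrom = tss_chrom, start = tss_pos, end = tss_pos + 1L,
                    name = sprintf("tss_%03d", seq_len(config$n_tss)),
                    score = 0, strand = "+", stringsAsFactors = FALSE)
  tss <- tss[order(tss$chrom, tss$start), ]
  rownames(tss) <- NULL
  b <- truth[truth$bound == 1L, , drop = FALSE]
  center <- (b$start + b$end) %/% 2L
  peaks <- data.frame(
    chrom = b$chrom,
    start = pmax(0L, center - config$peak_width %/% 2L),
    end = pmin(lens[b$chrom], center + config$peak_width %/% 2L),
    name = sprintf("peak_%04d", seq_len(nrow(b))),
    score = 500, strand = ".", signalValue = 10, pValue = -1, qValue = -1,
    peak = config$peak_width %/% 2L, stringsAsFactors = FALSE)
  rownames(peaks) <- NULL
  truth <- truth[, c("site_id", "chrom", "start", "end", "strand",
                     "bound", "morphology", "decoy", "sequence")]
  structure(list(genome = planted$genome, motif = config$motif,
                 reads = reads, peaks = peaks, conservation = cons,
                 tss = tss, truth = truth, config = config),
            class = "bpac_bundle")
}

#' Write a simulated bundle to disk
#'
#' Emits mutually consistent fixture files: `genome.fa`,
#' `motif.transfac`, `reads.bed`, `peaks.narrowPeak`,
#' `conservation.bedGraph`, `tss.bed` and `truth.tsv`.  Byte-identical
#' for identical config (including seed).
#'
#' @param config A [simulation_config].
#' @param dir Output directory (created if needed).
#' @return The bundle (invisibly), with a `files` attribute of paths.
#' @export
emit_truth_files <- function(config, dir) {
  bundle <- simulate_bundle(config)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop(sprintf("cannot create output directory '%s'", dir))
  paths <- c(genome = file.path(dir, "genome.fa"),
             motif = file.path(dir, "motif.transfac"),
             reads = file.path(dir, "reads.bed"),
             peaks = file.path(dir, "peaks.narrowPeak"),
             conservation = file.path(dir, "conservation.bedGraph"),
             tss = file.path(dir, "tss.bed"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(bundle$genome, paths[["genome"]])
  write_transfac(bundle$motif, paths[["motif"]])
  write_bed(bundle$reads, paths[["reads"]])
  write_narrowpeak(bundle$peaks, paths[["peaks"]])
  write_bedgraph(bundle$conservation, paths[["conservation"]])
  write_bed(bundle$tss, paths[["tss"]])
  utils::write.table(bundle$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  attr(bundle, "files") <- paths
  invisible(bundle)
}

#' Run the full pipeline on raw inputs
#'
#' Scan -> profiles -> features -> labels: the end-to-end path from a
#' genome, motif and accessibility reads to a labeled dataset of
#' candidate sites.
#'
#' @param genome A [genome_sequence].
#' @param motif A [count_matrix] or [pwmotif].
#' @param reads Read intervals (data.frame).
#' @param conservation A [conservation_track].
#' @param tss TSS intervals (data.frame).
#' @param peaks Peak intervals, or NULL for an unlabeled dataset (labels
#'   all 0).
#' @param pvalue_cutoff PWM match cutoff (default 1e-4).
#' @param tf,cell,genome_tag Provenance.
#' @return A [labeled_dataset].
#' @export
build_dataset <- function(genome, motif, reads, conservation, tss,
                          peaks = NULL, pvalue_cutoff = 1e-4,
                          tf = "TF", cell = "cell",
                          genome_tag = "synthetic") {
  pwm <- if (inherits(motif, "count_matrix")) counts_to_logodds(motif)
         else motif
  sites <- scan_genome(pwm, genome, pvalue_cutoff)
  profiles <- reads_to_profiles(reads, genome)
  feats <- build_features(sites, profiles$read, profiles$cut, conservation,
                          tss)
  labels <- if (is.null(peaks)) integer(nrow(sites))
            else label_sites(sites, peaks)
  labeled_dataset(sites, feats, labels, tf = tf, cell = cell,
                  genome_tag = genome_tag)
}

#' Simulate a bundle and run the pipeline on it
#'
#' @param config A [simulation_config].
#' @return List with `dataset` (a [labeled_dataset]) and `bundle`.
#' @export
simulate_dataset <- function(config) {
  bundle <- simulate_bundle(config)
  ds <- build_dataset(bundle$genome, bundle$motif, bundle$reads,
                      bundle$conservation, bundle$tss, bundle$peaks,
                      tf = config$tf, cell = config$cell,
                      genome_tag = sprintf("sim_seed%d", config$seed))
  list(dataset = ds, bundle = bundle)
}

#' Match ground-truth sites to scanned candidates
#'
#' @param sites Candidate sites from [scan_genome].
#' @param truth Truth table from a bundle.
#' @return Integer vector over truth rows: the matching row in `sites`
#'   (same chrom and start), or NA when the scan missed the instance.
#' @export
match_truth <- function(sites, truth) {
  key_s <- paste(sites$chrom, sites$start, sites$strand)
  key_t <- paste(truth$chrom, truth$start, truth$strand)
  hit <- match(key_t, key_s)
  miss <- is.na(hit)
  if (any(miss)) {  # fall back to the opposite-strand call at the locus
    flip <- ifelse(truth$strand == "+", "-", "+")
    key_t2 <- paste(truth$chrom, truth$start, flip)[miss]
    hit[miss] <- match(key_t2, key_s)
  }
  hit
}
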