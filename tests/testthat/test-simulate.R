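test_that("generate_genome honors composition and seeding", {
  g <- generate_genome(1e5, gc = 0.5, seed = 2)
  bases <- strsplit(g$seq[["chr1"]], "")[[1]]
  gc <- mean(bases %in% c("G", "C"))
  expect_gt(gc, 0.49); expect_lt(gc, 0.51)
  g2 <- generate_genome(1e5, gc = 0.5, seed = 2)
  expect_identical(g$seq, g2$seq)
  at_only <- generate_genome(2000, gc = 0, seed = 3)
  expect_false(grepl("[GC]", at_only$seq[["chr1"]]))
  g3 <- generate_genome(9000, n_chrom = 3L, seed = 4)
  expect_equal(unname(genome_lengths(g3)), rep(3000L, 3))
})

test_that("plant_motifs writes recoverable, disjoint instances", {
  g <- generate_genome(3e4, seed = 6)
  cm <- default_motif()
  out <- plant_motifs(g, cm, 20L, seed = 7)
  expect_equal(nrow(out$sites), 20L)
  # pairwise disjoint
  s <- out$sites[order(out$sites$start), ]
  expect_true(all(utils::head(s$end, -1) <= utils::tail(s$start, -1)))
  # each planted instance rescored in place matches its emitted sequence
  pwm <- counts_to_logodds(cm)
  dist <- null_distribution(pwm)
  thr <- min(dist$support[dist$exceedance <= 1e-4]) / dist$scale
  scores <- vapply(seq_len(nrow(s)), function(i) {
    w <- genome_subseq(out$genome, s$chrom[i], s$start[i], s$end[i])
    score_window(pwm, if (s$strand[i] == "-") revcomp(w) else w)
  }, numeric(1))
  expect_equal(scores,
               vapply(s$sequence, function(x) score_window(pwm, x),
                      numeric(1)), ignore_attr = TRUE)
  # frequency-sampled instances of an information-rich motif mostly pass
  # the 1e-4 match threshold; forced 1-2 mismatch decoys always do
  expect_gt(mean(scores >= thr), 0.8)
  dec <- plant_motifs(g, cm, 30L, seed = 8, mismatches = 1:2)
  dscores <- vapply(dec$sites$sequence, function(x) score_window(pwm, x),
                    numeric(1))
  expect_true(all(dscores >= thr))
  # n = 0 leaves the genome untouched
  none <- plant_motifs(g, cm, 0L, seed = 1)
  expect_identical(none$genome$seq, g$seq)
  expect_error(plant_motifs(generate_genome(200, seed = 1), cm, 50L,
                            seed = 1), "insufficient room")
})

test_that("read totals scale with depth", {
  g <- generate_genome(5e4, seed = 3)
  sites <- data.frame(chrom = "chr1",
                      start = seq(500L, 45000L, by = 900L))
  sites$end <- sites$start + 12L
  sites$morphology <- "footprint"
  r1 <- simulate_reads(sites, g, depth = 100, seed = 1)
  r2 <- simulate_reads(sites, g, depth = 200, seed = 1)
  expect_gt(nrow(r1), 0.95 * 100 * nrow(sites))
  expect_lt(nrow(r1), 1.05 * 100 * nrow(sites))
  expect_gt(nrow(r2) / nrow(r1), 1.9)
  expect_lt(nrow(r2) / nrow(r1), 2.1)
})

test_that("emitted bundles are complete, consistent and reproducible", {
  cfg <- small_sim_config(55)
  dir1 <- withr::local_tempdir()
  b1 <- emit_truth_files(cfg, dir1)
  files <- attr(b1, "files")
  expect_length(files, 7L)
  expect_true(all(file.exists(files)))
  # byte-identical rerun
  dir2 <- withr::local_tempdir()
  b2 <- emit_truth_files(cfg, dir2)
  expect_identical(file_md5(attr(b2, "files")), file_md5(files))
  # bound count within binomial bounds around n * p
  nb <- sum(b1$truth$bound)
  expect_lt(abs(nb - 50), 3 * sqrt(100 * 0.25) + 1e-9)
  # peaks cover every bound site and no unbound site
  lab <- label_sites(b1$truth, b1$peaks)
  expect_equal(lab, b1$truth$bound)
  # emitted files reload into the in-memory bundle
  g <- read_fasta(files[["genome"]])
  expect_identical(g$seq, b1$genome$seq)
  reads <- read_bed(files[["reads"]])
  expect_equal(nrow(reads), nrow(b1$reads))
  peaks <- read_narrowpeak(files[["peaks"]])
  expect_equal(peaks$start, b1$peaks$start)
  cons <- read_wig_or_bedgraph(files[["conservation"]])
  probe <- b1$truth[b1$truth$bound == 1L, ][1, ]
  expect_equal(track_values(cons, probe$chrom, probe$start, probe$end),
               track_values(b1$conservation, probe$chrom, probe$start,
                            probe$end),
               tolerance = 1e-9)
})

test_that("morphologies produce the documented footprint contrasts", {
  fp_means <- function(morph, seed) {
    sim <- simulate_dataset(small_sim_config(seed, morphology = morph))
    tr <- sim$bundle$truth
    hit <- match_truth(sim$dataset$sites, tr)
    ok <- !is.na(hit)
    f <- sim$dataset$features
    list(reads_b = mean(f$reads_fp_score[hit[ok & tr$bound == 1L]]),
         reads_d = mean(f$reads_fp_score[hit[ok & tr$decoy]]),
         cuts_b = mean(f$cuts_fp_score[hit[ok & tr$bound == 1L]]),
         labels = sim$dataset$labels[hit[ok & tr$bound == 1L]])
  }
  fp <- fp_means("footprint", 61)
  expect_gt(fp$reads_b, 1.5)
  expect_lt(abs(fp$reads_d - 1), 0.5)
  expect_true(all(fp$labels == 1L))
  inv <- fp_means("inverse", 62)
  expect_lt(inv$cuts_b, 1)
})

test_that("invalid configurations are refused", {
  expect_error(simulation_config(morphology = "spiky"), "morphology")
  expect_error(simulation_config(bound_fraction = 1.4), "bound_fraction")
  expect_error(simulation_config(gc = 2), "gc")
  expect_error(simulation_config(seed = NA), "seed")
  expect_error(simulation_config(genome_length = 50), "10x motif length")
})
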