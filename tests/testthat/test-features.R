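profile_of <- function(v, kind = "read") base_profile(list(chr1 = v), kind)

test_that("window_means averages the site and its equal-length flanks", {
  p <- profile_of(c(1, 2, 3, 4, 5, 6))
  site <- data.frame(chrom = "chr1", start = 2L, end = 4L)
  wm <- window_means(p, site)
  expect_equal(wm$at, 3.5)
  expect_equal(wm$upstream, 1.5)
  expect_equal(wm$downstream, 5.5)

  z <- window_means(profile_of(rep(0, 6)), site)
  expect_equal(unlist(z), c(at = 0, upstream = 0, downstream = 0))

  # flank fully clipped at the chromosome edge contributes 0
  edge <- window_means(p, data.frame(chrom = "chr1", start = 0L, end = 2L))
  expect_equal(edge$upstream, 0)
  expect_equal(edge$at, 1.5)
  # partial clipping averages the remaining bases
  part <- window_means(p, data.frame(chrom = "chr1", start = 1L, end = 3L))
  expect_equal(part$upstream, 1)

  expect_error(window_means(p, data.frame(chrom = "chrX", start = 0L,
                                          end = 2L)), "absent")
})

test_that("footprint_score follows the flank-over-site ratio with pseudocount", {
  expect_equal(footprint_score(4, 6, 1), 5.5)
  expect_equal(footprint_score(0, 0, 0), 1)
  expect_equal(footprint_score(1, 1, 10), 3 / 11)
  expect_error(footprint_score(-1, 0, 0), "nonnegative")
  expect_error(footprint_score(1, 1, 1, pseudocount = 0), "positive")
  # strictly increasing in flanks, strictly decreasing in the site average
  set.seed(1)
  for (i in 1:50) {
    u <- runif(1, 0, 10); d <- runif(1, 0, 10); a <- runif(1, 0, 10)
    eps <- runif(1, 0.01, 1)
    expect_gt(footprint_score(u + eps, d, a), footprint_score(u, d, a))
    expect_gt(footprint_score(u, d + eps, a), footprint_score(u, d, a))
    expect_lt(footprint_score(u, d, a + eps), footprint_score(u, d, a))
  }
})

test_that("distance_to_tss uses the unsigned closest-feature convention", {
  site <- data.frame(chrom = "chr1", start = 100L, end = 110L, strand = "+")
  tss_at <- function(pos) data.frame(chrom = "chr1", start = pos,
                                     end = pos + 1L, strand = "+")
  expect_equal(distance_to_tss(site, tss_at(160L)), 50)
  expect_equal(distance_to_tss(site, tss_at(105L)), 0)
  expect_equal(distance_to_tss(site, rbind(tss_at(90L), tss_at(300L))), 10)
  empty_tss <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0))
  expect_error(distance_to_tss(site, empty_tss), "nonempty")
  # random fixture against a direct per-pair oracle
  set.seed(31)
  sites <- data.frame(chrom = "chr1", start = sample.int(1000L, 40L))
  sites$end <- sites$start + 10L
  tss <- data.frame(chrom = "chr1", start = sample.int(1000L, 15L))
  tss$end <- tss$start + 1L
  oracle <- vapply(seq_len(40L), function(i)
    min(pmax(0, sites$start[i] - tss$start, tss$start - sites$end[i])),
    numeric(1))
  expect_equal(distance_to_tss(sites, tss), oracle)
})

test_that("conservation_at_site averages with zeros at undefined positions", {
  site <- data.frame(chrom = "chr1", start = 0L, end = 10L)
  full <- conservation_track(list(chr1 = rep(1, 10)))
  expect_equal(conservation_at_site(full, site), 1)
  half <- conservation_track(list(chr1 = rep(0.8, 5)))  # rest undefined
  expect_equal(conservation_at_site(half, site), 0.4)
  expect_equal(conservation_at_site(conservation_track(), site), 0)
})

test_that("build_features composes its parts consistently", {
  sites <- data.frame(site_id = c("a", "b"), chrom = "chr1",
                      start = c(6L, 20L), end = c(8L, 22L),
                      strand = c("+", "-"), pwm_score = c(3.2, 1.1),
                      stringsAsFactors = FALSE)
  zero <- profile_of(rep(0, 40))
  tss <- data.frame(chrom = "chr1", start = 0L, end = 1L, strand = "+")
  f <- build_features(sites, zero, profile_of(rep(0, 40), "cut"),
                      conservation_track(), tss)
  expect_equal(colnames(f), bpac_features())
  expect_equal(f$pwm_score, sites$pwm_score)
  expect_equal(f$distance_to_tss, c(6, 20))
  expect_equal(f$reads_fp_score, c(1, 1))
  expect_equal(unlist(f[1, 4:9]), rep(0, 6), ignore_attr = TRUE)

  # a site with flank read means 4 and 6 and at-site 1 gets fp 5.5
  v <- c(rep(4, 6), rep(1, 2), rep(6, 6))
  s1 <- data.frame(site_id = "x", chrom = "chr1", start = 6L, end = 8L,
                   strand = "+", pwm_score = 0)
  f1 <- build_features(s1, profile_of(c(v, rep(0, 10))),
                       profile_of(rep(0, 24), "cut"),
                       conservation_track(), tss)
  expect_equal(f1$reads_fp_score, 5.5)

  # permuting site order permutes rows identically
  prof <- profile_of(runif(40))
  fa <- build_features(sites, prof, profile_of(runif(40), "cut"),
                       conservation_track(), tss)
  fb <- build_features(sites[2:1, ], prof, profile_of(runif(40), "cut"),
                       conservation_track(), tss)
  expect_equal(fb$reads_at_site, fa$reads_at_site[2:1])
})

test_that("depth scaling doubles count features and fp converges", {
  set.seed(7)
  v <- rpois(60, 3)
  sites <- data.frame(site_id = "s", chrom = "chr1", start = 24L, end = 30L,
                      strand = "+", pwm_score = 0)
  tss <- data.frame(chrom = "chr1", start = 0L, end = 1L)
  cons <- conservation_track()
  f1 <- build_features(sites, profile_of(v), profile_of(v, "cut"), cons, tss)
  f2 <- build_features(sites, profile_of(2 * v), profile_of(2 * v, "cut"),
                       cons, tss)
  count_feats <- c("reads_at_site", "cuts_at_site", "upstream_reads",
                   "downstream_reads", "upstream_cuts", "downstream_cuts")
  expect_equal(unlist(f2[count_feats]), 2 * unlist(f1[count_feats]))
  # at 100x depth the fp score is within 2% of the pseudocount-free ratio
  f100 <- build_features(sites, profile_of(100 * v),
                         profile_of(100 * v, "cut"), cons, tss)
  ratio <- (f1$upstream_reads + f1$downstream_reads) / f1$reads_at_site
  expect_equal(f100$reads_fp_score, ratio, tolerance = 0.02)
})

test_that("label_sites matches a brute-force overlap oracle", {
  # the stated conventions
  site <- data.frame(chrom = "chr1", start = 100L, end = 110L, strand = "+")
  expect_equal(label_sites(site, data.frame(chrom = "chr1", start = 109L,
                                            end = 200L)), 1L)
  expect_equal(label_sites(site, data.frame(chrom = "chr1", start = 110L,
                                            end = 200L)), 0L)
  expect_equal(label_sites(site, data.frame(chrom = character(0),
                                            start = integer(0),
                                            end = integer(0))), 0L)
  # random fixtures against the O(n*m) oracle
  set.seed(23)
  for (rep in 1:5) {
    ns <- 80L; np <- 30L
    sites <- data.frame(chrom = sample(c("chr1", "chr2"), ns, TRUE),
                        start = sample.int(900L, ns, TRUE))
    sites$end <- sites$start + sample(5:20, ns, TRUE)
    peaks <- data.frame(chrom = sample(c("chr1", "chr2"), np, TRUE),
                        start = sample.int(900L, np, TRUE))
    peaks$end <- peaks$start + sample(10:80, np, TRUE)
    labels <- label_sites(sites, peaks)
    expect_equal(labels, overlap_oracle(sites, peaks))
    expect_equal(sum(labels == 1L) + sum(labels == 0L), ns)
  }
})

test_that("labeled dataset TSV round-trips bit-exactly", {
  ds <- synth_dataset(25, rep(c(0L, 1L), c(13, 12)), seed = 4,
                      tf = "GATA1", cell = "K562")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_labeled_dataset(ds, path)
  back <- read_labeled_dataset(path)
  expect_identical(back$features, ds$features)
  expect_identical(back$labels, ds$labels)
  expect_equal(back$tf, "GATA1")
  expect_equal(back$cell, "K562")
  # rewriting the reloaded dataset is byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_labeled_dataset(back, path2)
  expect_identical(readLines(path2), readLines(path))
})
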