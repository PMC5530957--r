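#' Feature names, in canonical order
#'
#' The 11 features used by the binding model: the PWM match score, mean
#' conservation, distance to the nearest TSS, per-base read/cut profile
#' means at the site and in the upstream/downstream flanks (each flank as
#' long as the site itself), and the read- and cut-profile footprint
#' scores.
#'
#' @return Character vector of length 11.
#' @export
bpac_features <- function() {
  c("pwm_score", "conservation_score", "distance_to_tss",
    "reads_at_site", "cuts_at_site",
    "upstream_reads", "downstream_reads",
    "upstream_cuts", "downstream_cuts",
    "reads_fp_score", "cuts_fp_score")
}

#' Static (cell-type independent) feature names
#' @return Character vector.
#' @export
static_features <- function() {
  c("pwm_score", "conservation_score", "distance_to_tss")
}

#' Dynamic (accessibility-derived) feature names
#' @return Character vector.
#' @export
dynamic_features <- function() setdiff(bpac_features(), static_features())

window_mean_vec <- function(cums, len, start, end) {
  # cums = c(0, cumsum(profile)); start/end 0-based half-open, clipped
  s <- pmin(pmax(start, 0L), len)
  e <- pmin(pmax(end, 0L), len)
  w <- e - s
  out <- numeric(length(start))
  ok <- w > 0
  out[ok] <- (cums[e[ok] + 1L] - cums[s[ok] + 1L]) / w[ok]
  out
}

#' Per-base profile means at a site and its flanks
#'
#' Flanks are as long as the site itself; windows are clipped at chromosome
#' bounds, and a fully clipped (empty) flank has mean 0.
#'
#' @param profile A [base_profile].
#' @param site One-row data.frame (or list) with chrom, start, end.
#' @return List with elements `at`, `upstream`, `downstream`.
#' @export
window_means <- function(profile, site) {
  chrom <- as.character(site$chrom)[1L]  # all rows share one chromosome
  v <- profile$counts[[chrom]]
  if (is.null(v))
    stop(sprintf("chromosome '%s' absent from profile", chrom))
  cums <- c(0, cumsum(v))
  L <- site$end - site$start
  list(at = window_mean_vec(cums, length(v), site$start, site$end),
       upstream = window_mean_vec(cums, length(v), site$start - L, site$start),
       downstream = window_mean_vec(cums, length(v), site$end, site$end + L))
}

#' Footprint score
#'
#' `fp = (upstream + downstream + pseudocount) / (at + pseudocount)`.
#' The pseudocount avoids division by zero and defaults to one.  The
#' higher the value, the stronger the footprint; values below one indicate
#' an inverse footprint.
#'
#' @param upstream_avg,downstream_avg,at_avg Nonnegative per-base averages.
#' @param pseudocount Positive pseudocount (default 1).
#' @return Numeric footprint score(s), always positive.
#' @export
footprint_score <- function(upstream_avg, downstream_avg, at_avg,
                            pseudocount = 1) {
  if (any(upstream_avg < 0) || any(downstream_avg < 0) || any(at_avg < 0))
    stop("profile averages must be nonnegative")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  (upstream_avg + downstream_avg + pseudocount) / (at_avg + pseudocount)
}

#' Unsigned distance from sites to the nearest TSS
#'
#' Each TSS is treated as the point at its interval start; the distance
#' of a site `[start, end)` to a point t is `max(0, start - t, t - end)`,
#' so a TSS inside (or at the edge of) the site gives 0, and the nearest
#' TSS on any strand wins.
#'
#' @param sites data.frame with chrom, start, end (0-based half-open).
#' @param tss data.frame of TSS intervals (same convention); must be
#'   nonempty.
#' @return Numeric vector of nonnegative distances (NA when a site's
#'   chromosome carries no TSS).
#' @export
distance_to_tss <- function(sites, tss) {
  if (is.null(tss) || nrow(tss) == 0L) stop("TSS set must be nonempty")
  out <- rep(NA_real_, nrow(sites))
  for (chrom in unique(sites$chrom)) {
    idx <- which(sites$chrom == chrom)
    pts <- sort(tss$start[tss$chrom == chrom])
    if (length(pts) == 0L) next
    s <- sites$start[idx]; e <- sites$end[idx]
    j <- findInterval(e, pts)             # rightmost TSS point <= end
    left <- ifelse(j >= 1L, pts[pmax(j, 1L)], -Inf)
    right <- ifelse(j < length(pts), pts[pmin(j + 1L, length(pts))], Inf)
    out[idx] <- ifelse(left >= s, 0, pmin(s - left, right - e))
  }
  out
}

#' Mean conservation over sites
#'
#' Undefined positions contribute 0.
#'
#' @param track A [conservation_track].
#' @param sites data.frame with chrom, start, end.
#' @return Numeric vector in [0, 1].
#' @export
conservation_at_site <- function(track, sites) {
  vapply(seq_len(nrow(sites)), function(i) {
    v <- track_values(track, sites$chrom[i], sites$start[i], sites$end[i])
    if (length(v) == 0L) 0 else mean(v)
  }, numeric(1))
}

#' Build the feature table for candidate sites
#'
#' One row per site, in site order, with the 11 columns of
#' [bpac_features()].
#'
#' @param sites Candidate sites from [scan_genome] (must carry pwm_score).
#' @param read_profile,cut_profile [base_profile]s from
#'   [reads_to_profiles].
#' @param conservation A [conservation_track].
#' @param tss data.frame of TSS intervals.
#' @param pseudocount Footprint pseudocount (default 1).
#' @return data.frame with 11 numeric columns.
#' @export
build_features <- function(sites, read_profile, cut_profile, conservation,
                           tss, pseudocount = 1) {
  n <- nrow(sites)
  feats <- data.frame(matrix(0, nrow = n, ncol = 11L,
                             dimnames = list(NULL, bpac_features())))
  if (n == 0L) return(feats)
  feats$pwm_score <- sites$pwm_score
  feats$conservation_score <- conservation_at_site(conservation, sites)
  d <- distance_to_tss(sites, tss)
  feats$distance_to_tss <- ifelse(is.na(d), max(d, 0, na.rm = TRUE), d)
  for (chrom in unique(sites$chrom)) {
    idx <- which(sites$chrom == chrom)
    sub <- sites[idx, , drop = FALSE]
    rm_ <- window_means(read_profile, sub)
    cm_ <- window_means(cut_profile, sub)
    feats$reads_at_site[idx] <- rm_$at
    feats$upstream_reads[idx] <- rm_$upstream
    feats$downstream_reads[idx] <- rm_$downstream
    feats$cuts_at_site[idx] <- cm_$at
    feats$upstream_cuts[idx] <- cm_$upstream
    feats$downstream_cuts[idx] <- cm_$downstream
  }
  feats$reads_fp_score <- footprint_score(feats$upstream_reads,
                                          feats$downstream_reads,
                                          feats$reads_at_site, pseudocount)
  feats$cuts_fp_score <- footprint_score(feats$upstream_cuts,
                                         feats$downstream_cuts,
                                         feats$cuts_at_site, pseudocount)
  feats
}

#' Label candidate sites by ChIP-Seq peak overlap
#'
#' A site is bound (1) iff its interval overlaps any peak by at least one
#' base; abutting half-open intervals do not overlap.
#'
#' @param sites data.frame with chrom, start, end.
#' @param peaks data.frame of peak intervals (may be empty).
#' @return Integer vector of 0/1 labels aligned to site order.
#' @export
label_sites <- function(sites, peaks) {
  if (nrow(sites) == 0L) return(integer(0))
  if (is.null(peaks) || nrow(peaks) == 0L) return(integer(nrow(sites)))
  ov <- GenomicRanges::countOverlaps(df_to_granges(sites),
                                     df_to_granges(peaks),
                                     ignore.strand = TRUE)
  as.integer(ov > 0L)
}

#' Labeled dataset of candidate sites
#'
#' Aligns candidate sites, their 11-feature rows and 0/1 bound labels, and
#' records provenance (TF name, cell type, genome tag, prevalence).
#'
#' @param sites Candidate site data.frame.
#' @param features Feature data.frame from [build_features].
#' @param labels Integer 0/1 vector.
#' @param tf,cell,genome_tag Provenance strings.
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(sites, features, labels, tf = "TF",
                            cell = "cell", genome_tag = "synthetic") {
  if (nrow(sites) != nrow(features) || nrow(sites) != length(labels))
    stop("sites, features and labels must be aligned")
  if (!identical(colnames(features), bpac_features()))
    stop("feature columns must be the 11 canonical features in order")
  if (any(is.na(as.matrix(features))))
    stop("feature table contains missing values")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  structure(list(sites = sites, features = features,
                 labels = as.integer(labels),
                 tf = tf, cell = cell, genome_tag = genome_tag),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf(
    "labeled_dataset %s @ %s: %d sites, %d bound (prevalence %.3f)\n",
    x$tf, x$cell, length(x$labels), sum(x$labels),
    mean(x$labels)))
  invisible(x)
}

#' Number of sites in a labeled dataset
#' @param ds A [labeled_dataset].
#' @return Integer.
#' @export
dataset_size <- function(ds) length(ds$labels)

#' Globally unique site keys of a labeled dataset
#'
#' Site ids prefixed with the dataset provenance, used by the leakage
#' guard in transfer scenarios.
#' @param ds A [labeled_dataset].
#' @return Character vector.
#' @export
site_keys <- function(ds) {
  if ("global_id" %in% names(ds$sites)) return(ds$sites$global_id)
  paste(ds$tf, ds$cell, ds$sites$site_id, sep = "|")
}

#' Write a labeled dataset as TSV
#'
#' Full-precision numeric formatting so that a write/read round trip is
#' bit-exact.  Provenance travels in a `#bpac_dataset` header line.
#'
#' @param ds A [labeled_dataset].
#' @param path Output file.
#' @export
write_labeled_dataset <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#bpac_dataset\ttf=%s\tcell=%s\tgenome=%s",
                     ds$tf, ds$cell, ds$genome_tag), con)
  writeLines(paste(c("site_id", "chrom", "start", "end", "strand",
                     bpac_features(), "label"), collapse = "\t"), con)
  if (nrow(ds$sites) > 0L) {
    fmat <- vapply(ds$features, function(v) sprintf("%.17g", v),
                   character(nrow(ds$features)))
    fmat <- matrix(fmat, nrow = nrow(ds$features))
    writeLines(paste(ds$sites$site_id, ds$sites$chrom, ds$sites$start,
                     ds$sites$end, ds$sites$strand,
                     apply(fmat, 1L, paste, collapse = "\t"),
                     ds$labels, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a labeled dataset written by [write_labeled_dataset]
#' @param path TSV file.
#' @return A [labeled_dataset].
#' @export
read_labeled_dataset <- function(path) {
  first <- readLines(path, n = 1L)
  prov <- c(tf = "TF", cell = "cell", genome = "unknown")
  if (startsWith(first, "#bpac_dataset")) {
    kv <- strsplit(strsplit(first, "\t")[[1]][-1L], "=")
    for (p in kv) prov[[p[[1]]]] <- p[[2]]
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  sites <- df[, c("site_id", "chrom", "start", "end", "strand")]
  if ("pwm_score" %in% names(df)) sites$pwm_score <- df$pwm_score
  labeled_dataset(sites, df[, bpac_features()], df$label,
                  tf = prov[["tf"]], cell = prov[["cell"]],
                  genome_tag = prov[["genome"]])
}
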