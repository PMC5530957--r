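---
title: "Predicting bound TF sites from chromatin accessibility: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting bound TF sites from chromatin accessibility: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpac)
```

## The problem

A position weight matrix (PWM) scan of a genome produces far more
candidate binding sites for a transcription factor (TF) than are actually
occupied in any one cell type.  Whether a candidate site is bound depends
on the local chromatin state, which DNase-Seq and ATAC-Seq measure: most
TFs bind only within accessible chromatin, and an occupied site often
leaves a *footprint* — a dip in the per-base nuclease cut rate flanked by
elevated cutting.  `bpac` formalizes this as supervised classification:
candidate sites found by a PWM scan are described by a small feature
vector and a random forest is trained against ChIP-Seq peaks as the
ground-truth bound/unbound labels.  Because the features are deliberately
generic, the same trained model can be applied to *other* TFs and *other*
cell types; the package's scenario layer quantifies that transferability.

## The pipeline

**Candidate sites.** A TRANSFAC count matrix is converted to a log-odds
PWM: with background probabilities $b$ (uniform by default) and a total
pseudocount $c$ (default 1),

$$\mathrm{score}_i(x) = \log_2 \frac{(n_{i,x} + c\,b_x)/(\sum_y n_{i,y} + c)}{b_x}.$$

A window's score is the sum of the per-position entries of the observed
bases.  The null distribution of that score under independent background
bases is computed *exactly* by discretizing each entry to
$\mathrm{round}(s \cdot \mathrm{scale})$ (scale 1000 by default) and
convolving position by position; scan p-values are exceedance
probabilities on this grid, and the genome scan sums the same rounded
integers, so a scan p-value is identical to what brute-force enumeration
of all $4^L$ windows would give.  Both strands are scanned, windows
containing N are skipped, and a site is a candidate when
$P(S \ge s) \le 10^{-4}$, the conventional PWM-match cutoff.  Overlapping
and palindromic double hits are all retained; only the p-value filters.

**Profiles.** Accessibility reads (BED6 intervals; 0-based half-open
coordinates are used everywhere internally) become two per-base tracks:
the *read profile* counts reads covering each base, and the *cut profile*
counts the two terminal bases at each end of every read.  The two-per-end
rule is the most literal reading of how cut tracks are built from
sequenced fragments; because conventions differ (some tools count a
single 5' cut per read), the `bases_per_end` parameter makes the rule
adjustable.  Reads shorter than `2 * bases_per_end` contribute each base
at most once, so totals obey
$\sum \mathrm{cut} = \sum_r \min(2\,\mathrm{bpe}, \mathrm{len}_r)$.

**Features.** Each candidate site gets 11 features (`bpac_features()`),
in two groups. Static, cell-type independent: PWM score; mean phastCons
conservation over the site (undefined positions count as 0); unsigned
distance to the nearest TSS.  Dynamic, accessibility-derived: mean read
and cut profile over the site and over the upstream and downstream
flanks, each flank as long as the site itself (flanks clipped at
chromosome edges contribute the mean of their remaining bases; empty
flanks contribute 0); and the two footprint scores

$$fp = \frac{\bar u + \bar d + 1}{\bar a + 1},$$

the flank-over-site ratio with a pseudocount of one.  $fp > 1$ indicates
a classic footprint, $fp < 1$ an inverse one.  Note the structural bias
of this ratio: *two* flank windows are summed against one site window,
so a site embedded in uniform signal tends to $fp \approx 2$ as coverage
grows, and only a site with essentially no local signal gives
$fp \approx 1$.  Flanks are taken in genomic coordinates (not oriented by
motif strand) since accessibility tracks are unstranded.  Raw counts are
used — no depth normalization — and no feature standardization or class
rebalancing is applied (forests are scale-free; prevalence is recorded in
the dataset provenance).

**Labels.** A candidate is bound iff it overlaps a ChIP-Seq peak by at
least one base (half-open intervals; abutment is not overlap).  Peaks are
used as provided, with no summit recentering.  Labeling is genome-wide by
default; restricting the negative set to accessible regions can be done
by pre-filtering the peak/site tables if desired.

**Model.** A random forest of 100 bootstrap-resampled, unlimited-depth
trees, trying `round(sqrt(k))` of the k selected features at each split
(3 of 11 by default); the prediction score of a site is the fraction of
trees voting bound, used directly as a ranking score without
calibration.  Training requires both classes and at least 10 rows; all
randomness is governed by an explicit seed (default 42) so training is
reproducible, and a saved model (versioned RDS plus a JSON sidecar with
the feature-order contract and provenance) reproduces its predictions
bit-for-bit after reloading.

**Evaluation.** ROC and precision–recall curves are computed at
descending unique score thresholds (ties collapse to one step).  AUC is
the trapezoidal area, which with tie-collapsed thresholds equals the
Mann–Whitney statistic $P(s^+ > s^-) + \tfrac12 P(s^+ = s^-)$.  AUPR is
the piecewise-constant average-precision sum
$\sum_k (r_k - r_{k-1})\,p_k$ — linear PR interpolation is known to be
optimistic, so the conservative standard is used.  At zero predicted
positives the curve's first point inherits the precision of the
highest-score threshold rather than an arbitrary 1.

**Transfer scenarios.** *Self*: train on a random 2/3 of a (TF, cell)
dataset, evaluate on the remaining 1/3.  *Cross-TF / multi-TF*: train on
one or several other TFs in the same cell, evaluate on the full target
dataset (no split is needed since no target row is trained on).
*Cross-cell*: same TF, different cell.  *Mixed*: pool across TFs and
cells with the target pair held out.  Pooling is unweighted per site, so
large datasets dominate; a leakage guard asserts that the global site-id
sets of training and evaluation data never intersect.  `sweep_n_tfs()`
repeats cross-TF prediction over random N-subsets of training TFs
(the reference sweep uses N in {3, 5, 8, 12, 16, 20, 25, 30} with 100
combinations each; desk-scale tests use fewer repeats).

## The synthetic-data generator

Every claim the test suite makes is grounded in generated data with known
truth.  `simulation_config()` defaults define the reference condition: a
2 Mb i.i.d. genome at GC 0.41; a 12-position motif with 94/2/2/2 counts
per column (~1.58 bits/column), 400 instances sampled from those column
frequencies planted at well-separated positions on random strands, half
of them bound; 400 decoy instances (consensus with 1–2 forced
mismatches — still above the 1e-4 match threshold, so the scan finds
them, mirroring how real negative sets are themselves motif matches);
200 bp peaks centered on bound sites, spaced so no peak touches another
instance; 100 TSS positions; and accessibility reads at an expected
depth of 200 per bound site.

Reads are generated from a piecewise-constant per-base cut intensity
over each site's ±2-motif-length region — site and flank multipliers
0.3/2 (footprint), 1/1 (flat), 4/1 (inverse), with "mixed" assigning
footprint or inverse per bound site — and each read extends 6 bp from
its sampled cut position in a random direction.  Unbound sites (planted
or decoy) receive 1% of the bound depth: closed chromatin is read-poor,
which is also what makes their footprint ratio sit near the pseudocount
value 1 rather than the uniform-coverage limit 2.  The inverse
multiplier is 4 rather than 2 because the Eq.-style ratio compares the
site against the *sum* of two flanks: a site merely twice as hot as each
flank balances that sum exactly, and read-end smear then pushes the
ratio above 1; a 4-fold site is unambiguously inverse.  The short read
length keeps per-base coverage aligned with cutting intensity so the
12 bp footprint is resolved; real 36 bp reads blur coverage over three
site widths, which is one of several realities this generator does not
emulate (no nuclease sequence bias, no fragment-length distribution, no
peak-calling noise, no correlated genomic background).  Passing tests
therefore demonstrate correctness of the machinery and the qualitative
feature behavior, not expected performance on real data.

Conservation is drawn per site region as a uniform baseline in
[0, 0.6] with ±0.05 per-base jitter, plus 0.1 at bound sites.  This was
chosen to make conservation a deliberately *weak* single feature
(rank-AUC ≈ 0.65): an overwhelming conservation signal would invert the
qualitative ordering observed on real data, where accessibility features
dominate and each static feature alone is close to chance.

## Numerical and design choices

- Discretization scale 1000 gives FIMO-like precision; the test suite
  additionally verifies exact agreement with enumeration at scale 200.
- `round()` (banker's rounding) is applied identically in the null
  convolution and the scan, which is what makes the two agree exactly.
- Degenerate inputs are errors, not silent values: single-class training
  or evaluation data, empty TSS sets, intervals with `end <= start`,
  reads out of bounds, leakage between training and evaluation.
- Conservation at positions without data resolves to 0 (phastCons gaps
  are conventionally unscored; 0 is the conservative choice).
- Distance to TSS treats each TSS as the point at its interval start and
  measures real-line distance to the site interval (0 on overlap).
- The 2/3–1/3 self split uses `round(fraction * n)` training rows drawn
  without replacement; the same seed reproduces the same partition.

## Desk-scale problem sizes

The test suite and the acceptance script size their simulations so the
whole suite runs in minutes on one CPU: the end-to-end fidelity check
uses the full 2 Mb / 400-site reference condition; feature-set and
transferability experiments use 0.3–0.5 Mb genomes with 100–200 planted
sites plus equal decoys, 5–12 seeds or TFs per claim.  These are the
package's own choices of scale; the generative rules are identical at
every scale.

## Known limitations

- The generator's morphology shapes are piecewise-constant idealizations
  of the observed footprint classes, not models fitted to DNase data.
- Bound/unbound depth ratio is a single global parameter; real occupancy
  is graded and confounded with peak strength.
- Cross-species transfer is out of scope, as are histone-modification,
  k-mer/SVM and cofactor-PWM features and any DNase sequence-bias
  correction.
- The classifier is deliberately plain (100-tree forest, no calibration,
  no hyperparameter search): the package's question is transferability
  of a fixed model family, not maximal single-TF accuracy.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(genome_length = 5e5, n_sites = 150, seed = 7,
                         tf = "TF1", cell = "cellA")
sim <- simulate_dataset(cfg)
parts <- split_self(sim$dataset, seed = 1)
model <- train_model(parts$train, model_config(seed = 1))
evaluate_scores(predict_scores(model, parts$test), parts$test$labels,
                scenario = "self")
```
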