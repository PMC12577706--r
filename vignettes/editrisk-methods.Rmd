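---
title: "Methods: predicting CRISPR-Cas9 editing outcomes from genomic repetitiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting CRISPR-Cas9 editing outcomes from genomic repetitiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

When Cas9 cuts a genome, the break is usually repaired as designed, but a
subset of target sites systematically produces undesired outcomes: no edit at
all, kilobase-scale deletions (DEL), or nonreciprocal translocations (TRA) in
which the sequence distal to the break is replaced by a copy of a homologous
template elsewhere in the genome. In organisms with efficient
homology-directed repair, these structural variants (SVs) arise when the
resected break ends find *endogenous* homology — tandem repeats around the cut
for deletions, dispersed or subtelomeric repeat families for translocations —
that competes with the intended donor template. The practical questions this
package addresses are: can the risk of each undesired outcome be predicted for
every NGG PAM site from sequence and chromosomal context, and can the
genome be mapped into safe regions and SV-prone hotspots?

`editrisk` implements the full desk-side pipeline: bespoke repetitiveness
metrics, feature assembly, outcome labeling from clone-level observations,
gradient-boosted outcome submodels with imbalance-aware resampling, and the
derived genome maps (difficult-to-edit regions, SV hotspot clusters,
loxP-distance context, breakpoint-colocalization summaries). A simulation
module generates every input needed to exercise and validate the pipeline
without external data.

## Repetitiveness indices

Both indices are built from **shortest-unique-substring (SUS) lengths**. For
a window `w` centered on the first PAM base:

* **Local index (I_LR).** For each position `i` of the window, take the
  length of the shortest substring starting at `i` that occurs exactly once
  *within the window*. Repetitive windows have long SUS values because short
  strings recur. Positions whose entire suffix recurs receive the sentinel
  `suffix length + 1` (the shortest absent extension), which keeps values
  finite and preserves monotonicity.
* **Global index (I_GR).** The same statistic, but uniqueness is measured
  against the *rest of the genome*: the shortest substring starting at `i`
  that occurs nowhere outside the window, with both strands of the remainder
  searched. The window interval is excised on both strands and its flanks are
  kept as separate fragments, so occurrences cannot span the excision.

Raw mean SUS length depends on window length and base composition, so each
index is normalized against a composition-preserving null:

```
index = log2( mean SUS(window) / mean over shuffles of mean SUS(shuffled window) )
```

with `n_shuffles = 20` by default. A composition-typical window scores ~0;
internally repetitive windows score positive I_LR; windows with distal copies
score positive I_GR. The log-ratio-to-shuffle normalization is this package's
definition; it preserves the sign and monotonicity semantics that the
downstream models consume. Because the null is a Monte-Carlo estimate, index
values carry noise of a few hundredths; all functions take explicit seeds and
are deterministic given them.

Both SUS computations run on suffix automata (linear time; the
rest-of-genome automaton is built once per site and shared across the window
gradient, with a small per-window "ring" automaton covering the uncovered
remainder, padded by one window length so no match can span a fragment cut).
The test suite verifies exact equality with brute-force occurrence counting
on sequences up to 2 kb (local) and genomes of ~50 kb (global).

**Window gradient.** Indices are computed at 50, 100, 500, 1000, 5000 and
10000 bp to span the size range of observed SVs; windows are clipped at
chromosome ends and computed on the clipped window without padding
(`clipped` is recorded in the profile).

**Tandem-repeat length.** The longest ungapped same-strand alignment, with
at most one mismatch, between the two PAM-flanking arms (25, 50, 250, 500,
2500, 5000 bp per arm). Inverted repeats are deliberately excluded: only
direct repeats support the single-strand-annealing deletions this metric
flags. The implementation scans alignment diagonals with a sliding mismatch
window and is tested against exhaustive substring-pair search.

## Feature table

Three genomic feature subsets plus technical covariates, mirrored in the
column manifest so ablations change columns, never rows:

1. **Local sequence context** — one-hot encoding of the 30-nt window
   (20-nt spacer ± 5 nt, oriented 5'→3' on the targeting strand), GC
   fraction of the spacer, and the T-homopolymer score (longest run of
   consecutive T in the spacer; long T runs terminate RNA-polymerase-III
   transcription of the gRNA and predict editing failure).
2. **Chromatin signals** — length-weighted means of bedGraph tracks over a
   ±250 bp window (half-width configurable; the value is unstated in the
   source protocols, and 500 bp matches the scale of nucleosome-level
   signals). Windows without track data are imputed with the track's global
   mean so the table stays dense.
3. **Repetitiveness and position** — the I_LR/I_GR gradients, tandem-arm
   lengths, and distances to the nearest telomere edge and to the
   centromere.

Technical covariates (designed variant type, editing system) are one-hot
encoded against a declared reference level. Assembly is a pure function of
(inputs, config, seed).

## Outcome labeling

* **Intent classification.** An observed variant is *intended* if applying
  it to the wild-type sequence reduces the Levenshtein distance to the donor
  template, else *unintended*. This single rule handles partial
  incorporation of multi-variant donors and donor synthesis errors treated
  as designed variants.
* **Copy-number loss.** Binned counts (250 bp in the study design) are
  normalized by median-of-ratios size factors, ranked within each sample
  across bins (`R`, average ranks, scaled by the bin count), then ranked
  within each bin across samples (rank-of-rank, `RoR`, scaled by the sample
  count). `RoR < 0.1` marks candidate loss cells. Two properties of this
  statistic matter in practice and are documented here because they shape
  the defaults:
  * Under the null, ~10% of cells in every bin row fall below 0.1 by
    construction, so a single flagged cell is never evidence. Detection
    (`detect_loss_segments`) therefore requires ≥ 3 consecutive flagged
    bins for the same sample — a deterministic replacement for the manual
    inspection step used with real data. Expected false segments stay well
    below one per sample for hundreds of bins.
  * The threshold has rank resolution `1/m`: with 20 samples, `RoR < 0.1`
    means "strict minimum across the cohort", and another sample's
    naturally bottom-ranked bin displaces individual cells with
    appreciable probability. The detector is designed for cohorts of
    hundreds to thousands of samples, where rank 0.1·m leaves slack; the
    acceptance checks therefore run sensitivity at a 400-sample cohort.
* **Gain (duplication) evidence.** TRA clones gain a copy of their
  template region, typically spanning many bins. A strict high-rank mirror
  of the loss rule has too little per-cell power under realistic
  overdispersion (a single 2x bin ranks below any fixed cutoff too often),
  so gain evidence is aggregated: sliding 20-bin windows are flagged when
  their mean RoR exceeds 0.75. The mean of 20 near-uniform ranks
  concentrates sharply at 0.5 (Irwin–Hall tail ≈ 4e-5 per window), keeping
  false gain segments rare while 2x segments of ≥ 20 bins are detected
  reliably.
* **Clone calls.** Decision order: copy loss + intended variant →
  `SV-unclassified` (conflicting evidence, kept auditable via evidence
  flags); copy loss + distal gain → `TRA`; copy loss alone → `DEL`;
  intended variant → `edited`; unintended indel → `NHEJ-indel`; unintended
  SNV alone → `SV-unclassified`; nothing → `unedited`.
* **Background variants.** Across a clone panel: drop loci missing in >50%
  of samples, then samples missing >50% of loci, then variants shared by
  clones carrying different gRNAs — in that order.
* **Bulk quantification.** Per-base depth normalized per sample by its mean;
  normalized coverage = edited / mean(controls) in sliding windows
  (window = region/25, step = region/50); Δcoverage = 1 − normalized
  coverage clipped to [0, 1] estimates the SV-bearing cell fraction at the
  PAM-containing window; the remainder splits into edited and unedited
  fractions by the allele read-count ratio. Coverage gains (negative
  Δ before clipping) are preserved in `delta_raw`.
* **Breakpoint homology.** Perfect-match extension outward from two
  breakpoints until the first mismatch — the homology tract shared by the
  joined flanks.

## Outcome submodels

Four binary gradient-boosted tree classifiers (xgboost,
`binary:logistic`) distinguish correct edits from each undesired class:
`unedit`, `del`, `tra`, and `sv` (positives of `sv` pool DEL, TRA and
unclassified SVs). Hyperparameters (number of trees, learning rate,
interaction depth) and the class-imbalance strategy are tuned by exhaustive
grid search under repeated stratified k-fold cross-validation (5 repeats ×
3 folds), selecting by mean AUROC with AUPRC as tie-break — three criteria
are reported, and this combination rule is the package's documented choice.

Imbalance handling: random undersampling of the majority class to 10, 20,
50 or 100% of its size, optionally followed by random oversampling, SMOTE
or ADASYN of the minority class to a 1:1 ratio. Resampling is applied
strictly inside training folds; validation folds are never resampled (the
cross-validation code is structured so this cannot happen silently, and a
test audits it on the fold level). SMOTE/ADASYN use k = 5 neighbours;
synthetic points lie on segments between minority neighbours, which the
suite checks geometrically.

Scores shown to users are min-max normalized onto [0, 1] using the range
observed on the reference (genome-wide) site set; out-of-range raw scores
clip. Normalization is computed over whatever reference set the caller
scores — here the unique-spacer site set — and is an order-preserving
affine map.

Permutation importance shuffles individual features or feature groups
across samples (1000 permutations by default) and reports the AUROC drop
with a 90% confidence interval from the 5th/95th percentiles. Correlated
features dilute each other's single-feature importance, so the reference
study groups the I_LR gradient with the tandem-arm metric (two views of the
same tandem-repeat structure) when asking which family drives a model.

## Genome maps

* **Difficult-to-edit regions.** Sites whose normalized score exceeds the
  outlier threshold of its outcome: SV, DEL, TRA > 0.15; unedited > 0.25.
* **SV hotspots.** Three steps over the genome-ordered, strand-pooled PAM
  list: (1) maximal runs of consecutive PAMs with SV score > 0.15 — any
  below-threshold PAM breaks a run, and "consecutive" means consecutive in
  the PAM list, the only reading compatible with both the run rule and a
  separate merge step; (2) runs with fewer than 10 members are dropped;
  (3) surviving runs whose edge-to-edge gap is ≤ 200 bp merge, pooling
  member counts. Hotspot span is the first-to-last member PAM position,
  unpadded. Clustering is idempotent on hotspot members and ignores strand
  labels.
* **loxP context.** For each site strictly between two adjacent loxP sites
  (34-bp loxPsym treated as its midpoint), the flanking distance is the
  separation of those two midpoints; the Pearson correlation of distance
  with the deletion score is reported over bracketed sites.
* **Breakpoint bins.** Scored sites within ±1050 bp of any SV breakpoint are
  pooled into 21 fixed 100-bp offset bins (aligned to the window, so the
  central bin is [−50, 50)); per bin, score summaries plus the fraction of
  PAM sites excluded from scoring because their spacers are non-unique.

## The simulation module and the reference study

The generator emulates the features of real genomes that drive the method:
i.i.d. background at 38% GC (yeast-like), tandem arrays (unit length ×
copies, per-copy divergence), dispersed repeat families, a subtelomeric
block shared between chromosome ends, telomere/centromere annotations, and
optional loxP positions. Per-copy divergence of 2–3% keeps most 20-mers
unique, as in real repeat-adjacent loci, so planted regions remain
targetable. It does **not** emulate read-level artifacts (mapping bias, GC
tracks, duplicate reads), chromatin, transcription, or repair-pathway
choice beyond the generative rule below — so passing tests demonstrate that
the pipeline recovers the structure it models, not that the trained toy
models transfer to any real genome.

Outcome labels are drawn per site from a multinomial logit rule: edited is
the reference class; logit(unedited) is affine in the T-homopolymer score
(sigmoid centered at a run of 3.5 — failure switches on at runs of ≥ 4,
mimicking Pol III termination); logit(DEL) is affine in I_LR(500 bp);
logit(TRA) is affine in I_GR(500 bp). Slopes are calibrated to the observed
scale of the indices in simulated genomes (background ≈ 0; diverged tandem
arrays ≈ 0.5 in I_LR; repeat copies ≈ 1.2 in I_GR) so that each class's
generating covariate genuinely dominates that class — the premise of the
parameter-recovery checks. At a composition-typical site the defaults give
≈ 85% edited, ≈ 14% unedited and ≈ 1% per SV class; inside planted repeats
the SV classes dominate.

Coverage is negative-binomial (default mean 40, dispersion 0.1); planted
copy-loss cells multiply the mean by 0.05, planted gains by 2 over 25–35
bins. Clone observations give edited clones their designed variants with a
logistic incorporation decay in distance from the cut (50% at 10 bp),
NHEJ clones a 1–3 bp deletion at the cut, DEL/TRA clones the corresponding
coverage signatures.

The **reference study** (`run_demo_study`) uses two 20-kb chromosomes
(12 kb in the compact variant used by the test suite) carrying three tandem
arrays, five dispersed-repeat copies in two families and two subtelomeric
blocks; ~800 sites train the submodels and all remaining unique-spacer
sites are held out. These problem sizes are the package's reproduction
scale: large enough that hotspot runs of ≥ 10 PAMs and per-class sample
sizes are meaningful, small enough to recompute from scratch in minutes.

## Numerical and policy choices

* Coordinates are 0-based half-open internally; BED conventions on disk.
* "NGG" means literal GG at PAM positions 2–3, any A/C/G/T first base;
  sites whose spacer+PAM window contains N are excluded from enumeration.
* Spacer uniqueness requires the second occurrence to carry its own NGG:
  PAM-less matches cannot be cut by Cas9, so they do not disqualify a
  spacer.
* The off-target scan counts substitutions only; the semiglobal
  (fitting) aligner — free window flanks, full guide consumed, ties broken
  by lowest window start then the + orientation — is reserved for
  variant-locus annotation.
* Ranks use average ties throughout; the constant-matrix rank is then
  (n+1)/2n, which several tests pin.
* Size factors: median of count/geometric-mean ratios over bins with a
  strictly positive geometric mean.
* All stochastic steps take explicit seeds; fold assignment derives from a
  seeded stratified shuffle; nothing reads global RNG state without
  restoring it.

## Known limitations

* The shuffle-based index normalization is a stand-in for the original
  local-complexity normalization, which is not fully specified in
  accessible sources; absolute index values are therefore not comparable
  across normalization schemes, only ranks and signs are.
* Rank-of-rank loss detection needs cohort-scale sample numbers (see
  above); with tens of samples its per-cell resolution is coarse.
* The trained submodels in the reference study are fitted to simulated
  labels; they demonstrate recoverability, not biological transfer.
* Assembly-based SV calling, read mapping and haplotype calling are out of
  scope; the package consumes their outputs (variant records, count
  tables) or synthetic equivalents.
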