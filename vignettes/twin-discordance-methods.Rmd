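---
title: "Methods: discordant-twin methylome and transcriptome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discordant-twin methylome and transcriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The design

Monozygotic (MZ) co-twins share a genome, early environment and age, so a
disease-discordant MZ set is its own matched control: any systematic
molecular difference between the affected and unaffected co-twin is
enriched for disease-related signal. `twindiscord` implements the analysis
stack for such cohorts profiled on three platforms: a 450K-style
methylation array (β-values, probes × samples), EpiTYPER-like amplicon
assays (percent methylation per CpG unit), and gene-level RNA-seq counts.
Cohorts of this design are small (a handful of twin sets, longitudinal
collections, technical replicates) and the underlying data are usually not
shareable; the package therefore ships a first-class synthetic-cohort
generator with planted truth so every stage is testable end to end.

## Scales: β and M

A probe's β-value is the methylated fraction, in [0, 1]. Testing is done on
M-values, `M = log2(β / (1 − β))`, which stabilise variance away from the
boundaries; magnitudes are reported on the β scale, where Δβ (affected
minus unaffected, everywhere in this package) has a direct biological
reading. `beta_to_m()` clips β into `[ε, 1 − ε]` with `ε = 1e-6` before the
logit so boundary values stay finite. This dual-scale convention —
significance on M, magnitude on β — runs through the DMP stage.

## Amplicon (EpiTYPER) QC

CpG units (one or more adjacent CpG sites quantified as one mass fragment)
are averaged over sites, duplicates averaged per collection, and the plate
passed through a two-step missingness filter: first failed samples
(≥ 90% missing) then failed units (≥ 90%), then low-detection samples
(≥ 15%) then low-detection units (≥ 15%). Order within each step is
samples-then-units and fractions are recomputed after each removal; both
thresholds are inclusive. Remaining missing cells are imputed with the unit
mean — which preserves each unit's mean exactly, a property the tests
assert. Assay reliability criteria for discarding whole units are
assay-specific and not derivable from data, so they are accepted as an
optional user-supplied blacklist rather than guessed.

## Array QC

Four filters, applied in a fixed order but each computed from the same
input (so their removal sets commute):

1. **Sample detection**: a sample is kept iff ≥ 99% of probes are detected
   at detection p ≤ 0.05.
2. **Probe detection**: a probe is dropped if it fails detection in more
   than `max_failed_samples` retained samples (default 0).
3. **Replicate variance**: for every probe, absolute β differences over
   all technical-replicate pairs; a pair is an outlier if it exceeds the
   probe's mean difference by more than 3 sd, and a probe is dropped when
   it has "multiple" (our reading: ≥ 2) outlier pairs. Differences are
   absolute, not signed — the filter targets disagreement magnitude.
   Note the cutoff is self-referential: a probe whose replicate pairs are
   *uniformly* noisy raises its own cutoff and is not flagged; the filter
   specifically catches probes where a minority of pairs are discordant
   (the signature of SNP-underlying or cross-hybridising probes).
4. **Blacklist**: any selected annotation flag (cross-hybridising,
   sex-chromosome, SNP-overlap) removes the probe.

An optional clock-correlation gate correlates each sample's clock-CpG
profile with a gold-standard profile (an input file) and removes samples
with r < 0.85 or undefined correlation. Visual outlier inspection and sex
checks used in practice are not implementable as stated; the PCA utility
plus this gate stand in for them.

## Features: global methylation, DNAm age, cell composition

Per-sample features are: mean β over all probes and within each
CpG-density (HIL) class (HC, IC, ICshore, LC); epigenetic age; and blood
cell-type fractions.

**Epigenetic age** is `f⁻¹(intercept + Σ w_j β_j)` over clock CpGs. With
the `horvath` transform, `f(age) = log((age+1)/(A+1))` below the adult age
`A` (default 20) and `(age − A)/(A + 1)` above; its inverse is
`(1+A)·exp(x) − 1` for `x < 0` and `(1+A)·x + A` otherwise — continuous and
strictly increasing, equal to `A` at `x = 0`. Clock coefficients are an
input file, never bundled. Missing clock CpGs are imputed with a supplied
profile mean (or 0.5), a declared convention for desk-scale fixtures.

**Cell deconvolution** solves, per sample, `min ‖β_ref − R·w‖` subject to
`w ≥ 0` and `Σw ≤ 1` (reference-based deconvolution with an unexplained
remainder allowed; `simplex = TRUE` forces `Σw = 1`). The solver is a
Lawson–Hanson NNLS with the sum constraint enforced through a heavily
weighted augmented row; exact mixtures are recovered to machine precision
and noisy mixtures (sd 0.01) to RMSE < 0.05 per cell type.

## Discordance models

Derived features are modelled with gaussian linear mixed models fitted by
maximum likelihood (ML, not REML, because fixed terms are what is tested):
`feature ~ disease + age + sex (+ disease×age) + (1 | twin set) +
(1 | individual)`, the individual intercept absorbing longitudinal and
technical repeats. Terms are tested by likelihood-ratio test against the
model with the term dropped, with a χ² reference (no small-sample
correction; at 20 twin sets the simulated type-I error at α = 0.05 is
within [0.02, 0.09]).

Cell-type fractions are modelled with a logit-link beta-family mixed
regression: fractions are offset by +0.001 (avoiding log 0) and rescaled
into (0, 1) if any offset value reaches 1 (divide by max + 0.002 — the
offset alone can exceed 1 for a fraction of exactly 1). Random intercepts
per individual and twin set, no random slope. The fit uses `mgcv::gam`
with `betar` and random-effect smooths; the LRT compares the ML scores of
the full and reduced fits (`gcv.ubre` under `method = "ML"`), not the
penalized log-likelihood, in which the random intercepts could silently
absorb the dropped individual-level term. On failure the model falls back
to a gaussian mixed model on the logit scale and says so in the result.

Case-control probe models are ordinary least squares,
`β ~ disease + age + sex`, the disease coefficient reported case minus
control on the β scale (M optional), with BH-FDR across exactly the
selected probe set.

## The ranked magnitude-significance DMP procedure

The cross-set DMP stage is the core method:

1. **Collapse**: each individual's longitudinal and replicate samples are
   averaged (on both scales; M is collapsed from per-sample M-values);
   each set's unaffected value is the mean over unaffected co-twins, so a
   triplet's two unaffected members count once.
2. **Two rankings over all probes**: ascending paired-t p on per-set
   M-differences (df = sets − 1), and descending |mean Δβ|. Ties take
   average ranks. The final rank is their mean.
3. **Restrict and truncate**: keep high-CpG-density (HC) probes, sort by
   mean rank (ties broken by probe id for determinism), and cut the list
   immediately before the first probe whose per-set Δβ signs disagree.
   The list may be empty if the first probe is inconsistent.

Every probe in the resulting top list is direction-consistent by
construction, which the result object asserts. A caveat worth stating
plainly: with four twin sets, a null probe that achieves a small paired-t
p-value has, almost by construction, sign-consistent differences — the two
selection criteria are coupled at small n. The truncation point therefore
tends to sit below a run of sign-consistent noise probes, and the top list
will usually contain noise probes interleaved with true effects. Planted
true effects of Δβ = 0.3 are recovered at ≥ 90% in simulation, but the
false-probe count above the truncation point is not controllable by any
noise setting; treat the list as a ranked candidate set, not a
familywise-error-controlled discovery set.

**Within-set DMPs** are simply probes with |Δβ| ≥ 0.25 (inclusive) between
the affected individual and the (averaged) unaffected co-twins, labelled
hyper/hypo with the affected twin as reference; control sets use the
first-listed co-twin and carry magnitude only. Gene aggregation counts
genes with ≥ `min_probes_per_gene` DMPs (default 2, i.e. genes hit by
multiple probes; 1 gives genes with at least one DMP — both conventions
appear in practice, so the parameter is exposed rather than resolved).

## Expression stage

Genes pass a CPM filter (CPM strictly greater than the threshold in at
least the required number of samples, computed on raw library sizes).
Scaling factors are trimmed-mean-of-M-values (TMM): reference column is
the sample whose upper-quartile CPM is closest to the mean upper-quartile;
per sample, a weighted trimmed mean of log2 CPM ratios (30% trim on
log-ratios, 5% on average expression, inverse binomial-variance weights),
rescaled to geometric mean 1. The implementation is this package's own and
is tested against an independent oracle to 1e-8.

Differential expression uses gene-wise linear models on log2-CPM
(prior count 0.5 over TMM-effective library sizes) with terms for disease
and collection (paired longitudinal design), and optional voom-style
precision weights from a lowess fit of residual sd against fitted average
log-count. Gene-wise empirical-Bayes moderation is deliberately **not**
implemented; the acceptance surface is simulation calibration, not
bit-equivalence with moderated pipelines. Positive log2FC means higher in
the affected twin (or case) — the same direction convention as Δβ. DEGs
are gated at FDR < 0.05 and fold change ≥ 1.5; case-control validation
models `~ disease + sex` and applies BH-FDR across only the twin-derived
gene subset that survived filtering.

## Integration and enrichment

Cross-platform overlap first restricts each gene list to the other
platform's measured universe, then intersects. Enrichment is a two-sided
Fisher exact test per gene set (hypergeometric summation; verified against
an independent oracle to 1e-10) with fold enrichment `(k/n)/(K/N)`, a
direction label (over/under 1), and BH-FDR across terms; one-sided tests
are available by flag. Gene sets are read from GMT. Clustering uses
Manhattan distance with Ward linkage (Ward.D2 convention — the variant is
not otherwise pinned down) for methylation and Spearman correlation
distance (1 − ρ) with average linkage for log expression; PCA centres
features and projects samples onto right-singular directions.

## The synthetic world, and what a green test establishes

`simulate_twin_methylomes()` draws a cohort-wide baseline methylome from a
50/50 mixture of Beta(0.5, 8) and Beta(8, 0.5) (bimodal, like real
arrays), adds a per-set deviation and per-individual deviation (sd 0.02
each), plants disease effects of a configured Δβ at designated probes, and
adds technical replicate noise (sd 0.02) before clipping to [0, 1]. Noise
is added on the β scale (keeping Δβ interpretable), and planted effect
signs point **away from the nearer boundary**: a CpG at β ≈ 0.05 can only
gain methylation, so a blindly drawn sign toward the boundary would be
silently erased by clipping and no effect would actually exist to find.
Detection p-values are small Beta draws with a configurable failure rate.

The synthetic clock embeds age **linearly** on the transformed-age scale
(`β_j = a_j + b_j · f(age)`, slopes scaled to keep β within bounds over
ages 0–100, weights `w = b/Σb²` and intercept `−Σw·a` solved so the linear
predictor equals `f(age)` exactly). A logistic per-CpG embedding was
considered and rejected: it cannot be inverted exactly by a clock that is
linear in β, and exact noiseless recovery is what makes the clock a usable
oracle.

Counts are negative binomial with dispersion 0.01 (BCV 0.1, the standard
figure for genetically identical subjects), log2 baseline means in
[4, 12] (post-filter genes sit above roughly a dozen raw counts), a
per-collection batch offset (sd 0.1 log2), and planted genes scaled by
`2^log2fc` in affected columns.

What this world does *not* emulate: probe-specific variance heterogeneity,
type-I/type-II probe chemistry, cell-composition confounding of planted
effects, correlated probes within islands, GC/length effects in counts,
and any form of batch structure beyond the collection offset. A green
recovery test therefore establishes that the implementation performs the
stated procedure correctly and has the expected operating characteristics
in a clean world — not that the procedure is robust to real-data
pathologies.

## Numerical choices and degenerate inputs

* M-transform clipping ε = 1e-6; all tie-breaks by id for determinism.
* Paired test: all-zero differences give t = 0, p = 1; zero-variance
  nonzero-mean differences give p = 0 with a flag.
* Constant probes in case-control models are skipped and flagged;
  collinear designs error rather than silently dropping terms.
* NNLS tolerance 1e-10; the Σw ≤ 1 constraint is activated only when the
  unconstrained nonnegative solution exceeds it.
* TMM returns factor 1 when all usable log-ratios are below 1e-6 in
  magnitude; all-zero genes are removed before reference selection.
* Fisher two-sided p sums hypergeometric probabilities ≤ observed
  × (1 + 1e-7), the conventional tie tolerance.

## Known limitations

* LRT χ² reference with few twin sets is only approximately calibrated;
  no small-sample correction is applied.
* No empirical-Bayes variance moderation: per-gene tests at two or three
  collections without replicates have little power.
* The DMP truncation rule does not control any error rate (see above).
* The beta-regression ML-score LRT treats the dispersion as re-estimated
  per model, the standard but slightly liberal convention.
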