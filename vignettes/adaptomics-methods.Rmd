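---
title: "Models and methods behind adaptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind adaptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptomics)
```

# Scope

adaptomics implements the analysis stack used to characterize the
*immediate* molecular adaptation of cancer cells to targeted kinase
inhibition — the first hours to days after drug exposure, before genetic
resistance can arise. The stack has five analytical layers:

1. isobaric (TMT 10-plex) proteome quantification with picked
   target/decoy protein FDR,
2. differential expression at protein (moderated t) and mRNA
   (negative-binomial Wald) level,
3. mono-versus-combination drug-screen scoring (4PL fits, DSS, sDSS),
4. set-logic integration (omics overlaps, consensus ChIP-target
   filtering, candidate derivation), and
5. over-representation analysis of regulated gene lists.

Because the deposited datasets of any particular study are large and
external, every layer is driven and verified here through a
synthetic-data generator that plants known effects, synergists and
consensus targets. This vignette documents the models, the parameters
that matter, the numerical choices, and what the synthetic tests do and
do not demonstrate about real data.

# Proteome quantification

## Median sweeping

The quantification substrate is a PSM-level table of ten reporter-ion
intensities per spectrum. Relative quantification proceeds in three
median operations:

1. **Row sweep** (`sweep_psm_ratios`): each PSM's log2 intensities are
   centred by their own median, turning absolute intensities into
   within-spectrum relative profiles. This absorbs everything that is
   constant across channels — peptide ionization efficiency, sampling
   depth, the PSM's overall abundance — which is why the synthetic
   generator's per-PSM random offsets vanish downstream.
2. **Protein aggregation** (`aggregate_protein_ratios`): per gene
   symbol and channel, the median over the PSMs *unique* to that gene.
   Shared PSMs are excluded entirely rather than partitioned; with
   gene-centric grouping the loss is small and the estimator stays a
   plain median.
3. **Column centering** (`center_columns`): per-sample median
   subtraction, correcting unequal channel loading. After this step
   every column's median is zero by construction (asserted to 1e-9 in
   the tests).

Missing reporter values are excluded from medians, never imputed; a PSM
with fewer than two quantified channels carries no relative information
and is dropped with a warning.

## Bridging two multiplex sets

A two-set design dedicates channel 10 of each set to an identical
internal reference pool of all study samples. `bridge_sets` subtracts
each set's reference column from its sample columns and keeps the gene
intersection. Ratio-to-reference is the standard arithmetic for pooled
reference channels; it cancels any set-level additive offset exactly (a
property test shifts one whole set and asserts an unchanged result).

One statistical consequence deserves emphasis: the reference
subtraction injects the reference channel's measurement noise into
*every* sample of a set as a shared term. Within-set contrasts are
unaffected (the term cancels), but in between-set contrasts it inflates
the group difference without appearing in the residual variance, making
nominal p-values anticonservative. This is a property of
single-reference bridged designs in general, not of this
implementation; the package therefore calibrates its test on within-set
contrasts, and between-set results should be read with the fold-change
cutoff doing part of the error control.

## Picked protein FDR

`picked_protein_fdr` implements target/decoy competition at the gene
level: per symbol only the higher-scoring of the target/decoy pair is
retained (ties keep the target, the conservative convention), the
picked list is ranked by score, FDR at a rank is the cumulative
decoy/target ratio (0/0 counts as 0), and q-values are the running
minimum from the bottom. On exchangeable null scores the fraction of
targets passing q <= 0.01 stays below 2% in 200-replicate simulations.
When ranking the merged list, a decoy is counted before a target at an
exactly tied score, which can only raise the FDR at that score.

# Differential expression

## Protein level: PSM-count-aware moderated t

`moderated_protein_dea` is an empirical-Bayes moderated t-test in which
the quantification evidence — the number of unique PSMs per gene —
informs the variance prior. Genes quantified by many PSMs have more
stable ratios; a `lowess` trend of log residual variance over
log2(PSM count) supplies a per-gene prior variance. Because
log residual variances are shifted log chi-square variables, the trend
estimates `E[log s^2] = log s0^2 + digamma(d/2) - log(d/2)`; the prior
variance de-biases the trend by that shift, and the prior degrees of
freedom come from a method-of-moments fit: the spread of the residuals
about the trend in excess of `trigamma(d/2)` reflects true
gene-to-gene variance heterogeneity and is inverted through
`trigamma`. The prior df estimate is capped at 100 — beyond that the
posterior is indistinguishable from complete pooling and the cap avoids
numerical blow-ups on small simulations; when fewer than 50 genes are
available the trend collapses to the global mean log variance.

The posterior variance is the df-weighted mix of gene and prior
variance; the moderated t uses residual + prior df. On null synthetic
data raw p-values are uniform (KS p > 0.01 at 2000 genes) and the
moderated test dominates the unmoderated t-test in power on
low-replicate data — both are property-tested.

Conditions with only duplicate samples are never tested: the operation
refuses contrasts with fewer than 2 replicates per side, mirroring the
practice of describing such conditions rather than attaching p-values
to them.

## mRNA level: simplified negative-binomial Wald test

`nb_count_dea` is a deliberately transparent stand-in for a full NB GLM
framework, restricted to single-factor two-level contrasts:

* **size factors** by median-of-ratios against the geometric-mean
  pseudo-reference, excluding genes with a zero geometric mean;
* **dispersion** per gene by method of moments on normalized counts,
  floored at 1e-8, then shrunk 50/50 toward a fitted mean-dispersion
  trend `alpha(mu) = a0 + a1/mu` (both coefficients floored at 0);
* **Wald test** of the log2 ratio of normalized condition means, with
  a delta-method standard error that carries the NB variance
  `mu + alpha mu^2` and the mean reciprocal size factor. Condition
  means are floored at half a normalized count so that empty means do
  not produce infinite fold changes.

The Wald statistic is referred to a t distribution rather than a
normal: the standard error is itself estimated from triplicates, and a
normal reference is measurably too liberal in the far tail at these
sample sizes. Because the 50/50 shrink ties each gene's dispersion to a
gene-pooled, nearly noise-free trend, the variance of the dispersion
estimate drops roughly four-fold, giving a Satterthwaite-style
effective df of `(n1 + n2 - 2) / 0.5^2`. With triplicates this is 16.
Null simulations at 5000 genes put the raw tail within 1.2x nominal at
both 0.05 and 0.01 and the false positive rate at the study cutoffs
(|log2FC| > 1, adjusted p < 0.01) well below 1%.

No claim is made of numerical equality with any particular GLM
implementation; the intent is a calibrated, fully-specified test whose
every step is visible.

## Significance calling and clustering

`call_significant` applies the study cutoffs — |log2FC| > 1 (mRNA) or
\> 0.5 (protein), BH-adjusted p < 0.01 — and reports up/down counts.
`cluster_samples` computes 1 − Pearson correlation distances between
sample columns and average-linkage hierarchies; average linkage is a
choice (only the distance is dictated by convention), and zero-variance
columns are rejected by name rather than silently producing NaN
distances.

# Drug-screen scoring

## Normalization and fitting

Plates carry DMSO negative controls (full viability) and a cytotoxic
positive control (zero viability). `normalize_plate` linearly rescales
each plate's signals between the two control means and reports percent
inhibition; a plate whose negative-control mean does not exceed its
positive-control mean is broken and rejected outright.

`fit_4pl` fits the log-logistic `y(x) = d + (a - d)/(1 + 10^(b(c - x)))`
(x = log10 molar dose) by bounded least squares: top `a` in [0, 100],
bottom `d` in [0, a] (parametrized as a fraction of `a` so the
constraint is a box), slope `b` in (0, 10], inflection within ±2 log10
units of the tested window. Responses are clamped to [0, 100] before
fitting — the usual treatment of normalized responses whose noise
carries them outside the physical range. Because bounded 4PL fits on
five points are sensitive to the starting point, a small deterministic
multi-start grid is tried (an extended grid only when no primary start
converges), keeping the best fit by SSR. Failed fits fall back to a
flat curve at the mean response, flagged non-converged, which
downstream QC excludes from hit calling.

The residual standard error uses the `sqrt(SSR/(n - 4))` convention (4
parameters); with the standard 5-dose design the denominator is 1, so
the QC threshold effectively acts on the raw root-SSR.

One identifiability caveat is inherent to the design: a compound whose
response rises only at the highest tested dose constrains the four
parameters with essentially two informative points, so several
parameter sets interpolate the data and the fitted curve's area can
differ from the generating curve's by a DSS unit or two even without
noise. Hit calls are robust to this (planted synergy margins are far
larger), and mid-window curves are recovered to three decimals.

## DSS and sDSS

`compute_dss` integrates the fitted curve above an activity threshold
`t` (default 10% inhibition) over the tested log10 dose window in
closed form. The crossing dose solves `y(x1) = t`; the antiderivative
of `y - t` is `(d - t)x + (a - d)/(b ln 10) · ln(1 + 10^(b(x - c)))`;
and

DSS1 = 100 · A / ((100 − t)(x_max − x_min)),

so a curve saturated at 100% inhibition across the whole window scores
exactly 100 and any curve whose top asymptote does not exceed `t`
scores 0. The closed form agrees with adaptive quadrature of
max(y − t, 0) to 1e-6 relative on 1000 random curves. DSS2
(efficacy-normalized, ×100/a) and DSS3 (additionally weighted by the
above-threshold fraction of the window) are provided as configurable
conventions; published screens do not always state which variant they
use, so DSS1 — the common core — is the default and the variants make
no replication claim.

`compute_sdss` scores synergy as DSS(combination) − DSS(monotherapy); a
compound is a hit when sDSS exceeds 5 and *neither* arm was excluded by
QC (residual SE > 19, strictly, or a non-converged fit). The exclusion
veto propagates deliberately: a large sDSS built on an unreliable curve
is exactly the artifact the SE filter exists to remove.

# Integration and enrichment

Gene identity throughout is the uppercased symbol string — no alias
resolution, which keeps every set operation deterministic and
dependency-free. `merge_omics` full-outer-joins the two DEA layers and
counts identification and regulation overlaps; duplicate gene rows are
an error, not a silent collapse. `consensus_chip_targets` keeps genes
supported by at least `min_experiments` (default 4) distinct ChIP
experiments, de-duplicating repeated observations of the same
experiment first. `candidate_targets` intersects that consensus with
genes significantly regulated in at least one tested condition — "up"
by default, the direction expected when silencing a transcriptional
repressor. A gene up in one condition and down in another still
qualifies on the up call alone; the rule is deliberately a union over
conditions, recorded in the provenance string of the returned set.

`ora` is the upper-tail hypergeometric test with the profiled-gene
universe as background. Gene sets are restricted to the background
*before* the set size enters the test — using the whole annotation
universe instead would overstate enrichment against a profiled
background. Sets outside [5, 2000] members after restriction are not
tested (configurable; tools differ in their defaults and no particular
tool's choice is asserted). p-values match one-sided Fisher's exact
tests identically, and uniformly drawn queries put ~5% of sets below
p = 0.05. One direction of monotonicity worth stating precisely:
removing a query gene *that belongs to a set* can only weaken that
set's evidence; removing a gene outside the set shrinks the query and
sharpens it. Both directions are property-tested.

# The synthetic-data generator

The generator is first-class, tested code; its defaults define the
study conditions every acceptance property is evaluated under.

* **PSM tables** (`simulate_psm_tables`): two 10-plex sets, triplicates
  of three conditions in channels 1–9, channel 10 an internal
  reference carrying the pooled linear mean of all sample channels
  across both sets. Gene baselines are log-normal (log2 N(16, 1)),
  per-PSM offsets N(0, 1) — both absorbed by sweeping — and channel
  noise is Gaussian in log2 space (default sd 0.1, a typical
  reporter-ion CV). PSM counts are 1 + Poisson(2), ~10% of PSMs are
  flagged shared, and 90% of genes are observed in both sets.
* **Count matrices** (`simulate_count_matrix`): NB counts with
  relative abundances drawn log-normal(sd 1.5), library size 2e6,
  dispersion 0.1 by default; dispersion 0 degenerates to Poisson.
* **Screen plates** (`simulate_screen_plates`): 528 compounds by
  default, 5 doses on a 10-fold ladder (1 nM–10 uM, a 10,000-fold
  window), both arms of a compound on one plate with 16 DMSO and 8
  kill-control wells. Curve tops are uniform in [0, 100], slopes in
  [0.5, 3], inflections uniform in the window. Planted synergists
  (default 17) receive a 1.5-log10 potency shift in the combination
  arm and are drawn with tops in [60, 100] and inflections in the
  upper half-window so the planted synergy is pharmacologically
  meaningful rather than a no-op on an inactive compound. Noise is
  multiplicative with constant CV (default 10%), the characteristic
  error structure of luminescence viability readouts.
* **ChIP evidence** (`simulate_chip_experiments`): 7 experiments;
  planted consensus genes appear in 4–7 of them, background genes
  enter each experiment independently at rate 0.1.
* **Decoy scores** (`simulate_decoy_scores`): one target and one decoy
  score per symbol; equal means give the exchangeable null used for
  FDR calibration.

Every generator is fully determined by its seed (byte-identical
repeats are asserted), and zero-noise settings make every downstream
stage recover its planted truth exactly — the end-to-end property the
pipeline test exercises.

What the generator does *not* emulate: spectral interference and
ratio compression in reporter ions, peptide-level missingness
structure, RNA-seq GC/length biases, plate spatial gradients and edge
effects, or dose-dependent solvent artifacts. Passing tests therefore
demonstrate correctness of the computations and calibration under the
stated error models, not robustness to every artifact of real
acquisitions.

# The pipeline driver

`run_pipeline` chains all stages on simulated inputs: quantify both
sets, bridge, test the three silencing contrasts and the mRNA
contrast, score the screen, filter the ChIP consensus, derive
candidates, map hit targets, and run ORA on the up-regulated mRNAs
against a simulated collection that includes one deliberately loaded
set. All randomness derives from the single configuration seed;
repeated runs are byte-identical, and `run_info.yaml` records the
seed, an MD5 hash of the canonical configuration, the package version
and per-stage row counts. Output tables reference the configuration
through that manifest rather than carrying the hash as a column in
every file.

Configuration defaults are the study's analysis settings (mRNA
|log2FC| > 1, protein |log2FC| > 0.5, adjusted p < 0.01, 1% picked
FDR, activity threshold 10%, SE exclusion above 19, sDSS hit cutoff 5,
consensus in >= 4 of 7 experiments, ORA FDR < 0.05). The default
simulation sizes in the driver (800 proteome genes, 3000 mRNA genes,
120 compounds, 8 synergists, 80 consensus genes) are chosen so a full
run completes in seconds while leaving every stage enough signal to be
meaningfully checked; the statistical calibration properties are
separately exercised at 2000–5000 genes, 200-compound screens and
50-seed noise replicates, sizes at which the binomial error of the
measured rates is comfortably inside the asserted bounds.

# Known limitations

* Between-set protein contrasts inherit shared reference-channel noise
  (see above); their raw p-values are nominal, not exact.
* The NB test covers single-factor two-level designs only — no
  multi-factor models, no time-course splines.
* DSS2/DSS3 normalizations are conventions, not replications of any
  specific screening platform's output.
* 4PL parameters (and hence DSS) are weakly identified for curves
  responding only at the final dose; QC and hit margins absorb this,
  but per-compound DSS values near the window edge carry extra
  uncertainty.
* Gene symbols are matched textually; orthologs, aliases and history
  are out of scope.
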