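---
title: "Methods: quantifying drug response in matched PDX / PD3D models"
author: "xenoScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying drug response in matched PDX / PD3D models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xenoScreen)
```

xenoScreen analyses preclinical drug-response studies that profile the
same tumors on two platforms: patient-derived xenografts (PDX, grown
subcutaneously in mice) and patient-derived 3D cell cultures (PD3D,
organoid-like cultures established from explanted xenograft tissue).
This vignette documents the models and conventions the package commits
to, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the numerical choices behind the defaults.

## In-vivo response: tumor volume, doubling time, T/C

Caliper measurements in two dimensions are converted to a tumor volume

$$TV = 0.5 \cdot w^2 \cdot l \quad [\mathrm{mm}^3],$$

with the convention $w \le l$ enforced by swapping (calipers do not
label axes; a swap emits a warning rather than an error).

The doubling time of an untreated tumor is estimated by ordinary least
squares on $\ln TV$ versus day, $t_d = \ln 2 / \hat\beta$, reported
with the fit $r^2$ and the number of points. A log-linear fit was
chosen over two-point formulas because caliper noise is multiplicative
and two-point estimators are dominated by the endpoints; curves with a
non-positive slope are flagged non-growing and get no $t_d$.

Treatment response is the treated-over-control ratio of arm-mean
volumes in percent,
$T/C = 100 \cdot \overline{TV}_T / \overline{TV}_C$. The source study
does not state the evaluation day, so `tcValue()` defaults to the last
day on which both arms were measured (`mode = "final"`) and also offers
the best (minimum) ratio over common days (`mode = "best"`). Animals
without a measurement at the evaluation day are dropped and counted —
never carried forward — to avoid silently rewarding early dropout of
fast-growing tumors.

## In-vitro response: 4PL curves and viability at Cmax

Viability versus concentration is fitted with a four-parameter
logistic,

$$v(c) = \mathit{bottom} + \frac{\mathit{top} - \mathit{bottom}}
 {1 + (c/\mathit{IC}_{50})^{h}},$$

the conventional family for cell-viability screens (the study shows
fitted curves without naming a model). Bounds are
$0 \le \mathit{bottom} \le \mathit{top} \le 1.2$, $h \in (0, 10]$ and
$\mathit{IC}_{50}$ within a tenfold extension of the tested dose
range. Initialization takes top/bottom from the extreme-dose means and
the IC50 from the dose bracketing the half-range; three perturbed
starts are tried. Replicates enter as individual points so that doses
with more replicates carry more weight. On non-convergence the fit
falls back to interpolation of replicate means in log-dose, and all
downstream readouts say so (`converged = FALSE`).

The clinical anchor is the viability at the drug's maximal human
plasma concentration (Cmax), in percent. Cmax values are study inputs
supplied per drug. Whether such values should be read off the fitted
curve or the raw replicate mean is not specified upstream; the curve
value is the default and `source = "interpolation"` gives the
replicate-mean reading (exactly the replicate mean when Cmax is a
tested dose). Extrapolation beyond twice the maximal tested dose is
refused rather than guessed.

## The ordinal response scale and cross-platform concordance

Both readouts map onto one four-level scale (0 strong, 1 moderate, 2
minor, 3 resistant):

| level | PDX T/C (%) | PD3D viability at Cmax (%) |
|---|---|---|
| strong | $\le 10$ | $\le 30$ |
| moderate | $(10, 25]$ | $(30, 60]$ |
| minor | $(25, 50]$ | $(60, 80]$ |
| resistant | $> 50$ | $> 80$ |

The published intervals are printed as integers ("0–10 %", "11–25 %");
for real-valued inputs the boundaries are taken inclusive on the
better-response side, which preserves the printed intervals for
integers and is well defined for fractions.

Concordance of a matched pair is the absolute ordinal distance
(0–3). "Moderate to high concordance" is operationalized as distance
$\le 1$; because the published per-drug "concordant (n = …)" counts
could also mean identical categories, both the distance-0 and the
distance-$\le 1$ counts are always reported. The overall summary is
the mean and sample SD ($n-1$) across per-drug fractions — the
dispersion flavour of the published "± " is unstated, so the SD is
used and labelled — with the pooled over-all-pairs fraction reported
alongside.

## Combination synergy

The study's combination heatmaps are qualitative (confluence-normalized
cytotoxicity relative to the plate median). For a quantitative
criterion the package adopts Bliss independence,
$E_{AB} = E_A + E_B - E_A E_B$, with per-cell excess
$E_{AB}^{obs} - E_{AB}^{Bliss}$; this is an explicit extension, flagged
as such, with the highest-single-agent reading
(`cmaxCombinationGain()`: best monotherapy minus combination
viability) provided in parallel. Effects for Bliss are obtained by
scaling each plate's normalized cytotoxicity by its maximal cell — a
documented convention that is exact when the strongest condition
approaches complete kill and otherwise inflates effects by the
reciprocal of the plate maximum. On plates whose strongest condition
kills, say, 80 % of cells this convention contributes a small positive
offset to the mean excess (below 0.05 in the synthetic stated world);
the calibration tests assert against the noise-free closed form of the
generator rather than pretending the offset away. Wells with zero
confluence are excluded from cell means and the plate median.

## Enrichment: ssGSEA and GSEA

Both scores are implemented from scratch so that every step is
testable against brute-force enumeration.

ssGSEA ranks genes by descending expression within one sample (average
ranks on ties, hence invariance under monotone transforms) and sums
the difference between the weighted in-set ECDF (weights
$\mathrm{rank}^\alpha$, $\alpha = 0.25$ by default, the standard
choice) and the unweighted out-of-set ECDF. The degenerate set
covering all genes scores 0 and is flagged; sets with no gene in the
matrix are flagged not-evaluable. Matrix-level scores can be divided
by their global max–min range, the usual projection normalization.

GSEA ranks genes by signal-to-noise between two phenotype groups
(stable sort, gene-name tiebreak, zero-variance guard on the
denominator) and takes the weighted Kolmogorov–Smirnov running-sum
extremum with weight exponent 1. Because the study's contrast groups
are tiny (responders versus resistant among at most 14 models),
phenotype permutation is degenerate there; gene-set permutation is
therefore the default scheme, with phenotype permutation available
when both groups have at least 7 samples and an automatic, logged
fallback when a group has fewer than 2. P-values use the add-one
estimator $(b+1)/(n_{perm}+1)$, so they are never 0 and have
resolution $1/(n_{perm}+1)$; NES divides the observed ES by the mean
$|ES|$ of same-sign permutations. Across a collection,
Benjamini–Hochberg is applied over sets (simpler than the original
GSEA FDR machinery, and stated as such).

## Biomarker discovery

Responder-versus-resistant contrasts use Welch's t-test per feature on
log2 values with BH correction across features. Welch was preferred
over moderated (shrinkage) variants because group sizes are tiny and
no hierarchical model is specified upstream; features with zero
variance in both groups are flagged rather than given p-values. The
dichotomization default groups {strong, moderate} against {minor,
resistant}, configurable.

ROC cutoffs are selected over all midpoint thresholds of the empirical
ROC; AUC comes from the rank statistic, markers are oriented so AUC
$\ge 0.5$ with the direction recorded, and the cutoff maximizes
Youden's $J$ with ties broken toward higher specificity (a
conservative choice for "rule-in" biomarkers). A biomarker "matches"
across sample types when it passes the sensitivity and specificity
floors (default 0.8) in every supplied type for the same drug with a
consistent direction; the thresholds defining a match are not printed
in the source study and are therefore exposed as parameters.

A note on power: with $n = 6 + 6$ and BH at 0.05 among 1000 features,
Welch detects 2-sigma shifts with only ~12 % sensitivity; the
planted-effect tests therefore use 4-sigma shifts, where ≥ 80 %
recovery is attainable, and separately assert that sensitivity grows
with effect size.

## Matched-sample QC

Pearson correlations are computed on $\log_2(x+1)$ abundances and
Spearman on raw ranks (the source shows both without stating scale).
Box summaries follow Tukey: type-7 quantiles and fences at $1.5 \times
IQR$. Variant concordance calls a mutation "maintained" when
pathogenic status is seen in the patient sample and in at least one
derived model, matching by gene and status class rather than genomic
coordinate (RNA-level variant tables lack stable coordinates — a
documented relaxation); pathogenic status appearing only in a derived
model is flagged as a gain, not silently counted.

## The synthetic stated world

The generators produce every input format with machine-readable ground
truth. Defaults mirror the study scale and are fixed once:

* 14 PDX models, 9 with a matched PD3D culture, 10 drugs.
* Doubling times lognormal with mean 10.9 d and SD 6.2 d, clamped to
  the observed 4.2–28.4 d range; treatment starts at palpable tumors
  (100 mm³); twice-weekly caliper days over 3 weeks; 8 animals per
  arm; multiplicative lognormal caliper noise $\sigma = 0.1$ with unit
  mean, so the analytic T/C expectation
  $100 \cdot 2^{(m-1)\,t/t_d}$ is exact.
* A latent sensitivity $u \in [0,1]$ per (model, drug) drives both
  platforms: the PDX growth-rate multiplier is solved so the final-day
  T/C hits a log-spaced target in 2–120 %, and the matched PD3D curve
  is solved so viability at Cmax hits the corresponding target in
  2–98 % after adding cross-platform jitter (SD 0.3 on the latent
  scale). The jitter value was chosen once so that matched responses
  land in the reported moderate-to-high concordance regime rather
  than being near-perfect; it is not asserted against any published
  number.
* Viability plates: 8 log-spaced doses, 4 replicates, Gaussian
  $\sigma = 0.05$; one model is planted resistant (bottom 0.9) to the
  first drug. Combination plates: 6×6 dose grid including vehicle,
  Hill monotherapy curves with moderate maximal effect (0.6) so the
  Bliss-plus-interaction composition never clamps at 1, interaction
  $\beta = 0.2$, background-death baseline 0.02, $n = 2$ replicates.
* Expression: 1000 genes, matched patient/PDX/PD3D triplets sharing a
  latent log2 profile with shared-variance fraction 0.8; 50 marker
  genes shifted +2 log2 units in responder models; the first GMT set
  is planted from markers, the rest are random. At least two models
  per response class are guaranteed so contrasts are estimable.

What the generator does **not** emulate: read-level RNA-seq counts
(expression is lognormal, not negative-binomial), mouse-stroma
contamination, mass-spectrometry artefacts, inter-animal correlation
beyond the shared growth rate, or time-dependent combination
kinetics. A green test therefore establishes correctness of the
estimators under the stated noise models, not robustness to every
failure mode of real screens.

## Determinism

Every generator draws from a stream derived from one root seed with a
fixed per-stage offset, so stage-wise and end-to-end runs agree and
identical seeds give byte-identical files. The run manifest hashes the
canonicalized configuration and input checksums (timestamps excluded),
so reruns are verifiable.

## Known limitations

* No tumor-growth mixed models, survival endpoints or toxicity
  readouts; T/C is a single-day ratio by design.
* No Loewe/ZIP synergy surfaces; Bliss excess plus HSA gain only.
* GSEA reproduces the standard statistic but not the original FDR
  machinery or leading-edge extraction.
* Published headline enrichment values depend on deposited accessions
  and external gene-set databases and are out of reach of a
  self-contained artifact; the package asserts algorithmic
  correctness against oracles and calibration instead.
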