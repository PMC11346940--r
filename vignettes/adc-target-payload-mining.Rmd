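---
title: "Mining tumor-selective ADC targets and payloads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining tumor-selective ADC targets and payloads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcmine)
```

## The problem

An antibody-drug conjugate (ADC) couples a tumor-targeting antibody to a
cytotoxic payload. Two selection problems dominate early ADC design: finding
a surface antigen that is abundant on tumor cells but scarce on healthy
tissue, and finding a payload potent enough (picomolar to low-nanomolar
GI50) with a sensitivity profile matched to the intended indication.
`adcmine` implements both arms as a reproducible pipeline over standard
public-data table shapes -- Human Protein Atlas-style IHC annotations,
TCGA-style expression and mutation matrices, hematopoietic expression
profiles, and NCI-DTP GI50 screening records -- plus a synthetic-cohort
generator that plants known structure in all of them so every stage is
testable offline.

## The quasi H-score

IHC pathology data reports, per gene and tumor type, the fraction of
patients staining at each of four ordinal levels (not detected < low <
medium < high). The pipeline's central statistic compresses this into a
0-300 score:

$$\mathrm{quasiH} = 1 \cdot \%\mathrm{low} + 2 \cdot \%\mathrm{medium} + 3 \cdot \%\mathrm{high}$$

It reaches 300 exactly when every patient stains high and 0 when no patient
stains at all. A gene is considered a tumor-selective candidate in an
indication when its score exceeds 150 (strictly; the threshold is
configurable). Equivalently the score is 100 times the mean per-patient
level weight, which is how the test suite's brute-force oracle computes it.

## The nine-stage target cascade

`run_cascade()` applies, in order: (1) membrane annotation, (2) evidence at
protein level, (3) exclusion of genes with high IHC level in any of 13
critical normal tissues (lung, oral mucosa, esophagus, stomach, duodenum,
small intestine, colon, rectum, liver, kidney, heart muscle, skin, bone
marrow), (4) quasi H-score > 150 in at least one of 20 tumor types, (5)
surfaceome membership, (6a) consistency between normal-tissue mRNA
categories and IHC levels, (6b) a dual quasi H-score requirement on both
IHC and tumor mRNA, (7) exclusion of genes highly expressed on
hematopoietic stem and multipotent progenitor cells, and (8) at least one
of five evidence criteria (literature, antibody, protein family,
preclinical, clinical), whose count also yields the 0-5 prioritization
score. Every stage records its survivors and one drop reason per removed
gene in a `cascade_trace`.

### Numerical choices

* **Quantiles.** All quartile computations use linear interpolation between
  order statistics (sample-quantile type 7), the most common default. The
  four-level scheme maps 0 to not detected, (0, Q1] to low, (Q1, Q3] to
  medium and values above Q3 to high; the three-level scheme (no
  not-detected class) maps values below Q1 to low, [Q1, Q3] to medium, and
  above Q3 to high. A value exactly at Q3 is medium in both schemes; a
  value exactly at Q1 is low in the four-level and medium in the
  three-level scheme.
* **Consistency policy (6a).** Source IHC and mRNA categories are compared
  per tissue after collapsing cell types to the maximum level. The default
  `within_one` policy tolerates one ordinal level of divergence, because
  exact four-bin equality across ~44 tissues is brittle to binning noise
  around the quartile cut points; `exact` is available by configuration.
  Genes without any tissue present in both sources fail the stage.
* **Dual score (6b).** The mRNA-derived quasi H-score categorizes each
  cohort's samples against the gene's quartiles over *all* cohort samples
  (`reference = "pangene"`), and a gene passes only if some tumor type
  clears the threshold in both the IHC- and the mRNA-derived score. This is
  a deliberate design choice: if each cohort were categorized against its
  own quartiles, at most a quarter of its samples could sit below Q1, which
  bounds the three-level score below by 175 -- the stage could never reject
  anything. Pooling the gene's samples across cohorts makes the mRNA score
  an honest cross-check of where the gene actually runs high.
  `quasi_h_from_expression()` still defaults to own-cohort quartiles for
  standalone use.
* **Missing IHC.** Gene-cancer pairs without pathology rows fall back to
  the mRNA-derived score at stage 4, so genes absent from the IHC resource
  are not silently lost.
* **HSC/MPP screen.** Quartiles come from the entire hematopoietic matrix
  (all genes x all samples); a gene's level is the three-level category of
  the mean of its HSC/MPP-sample values, and `high` disqualifies. Genes
  absent from the hematopoietic study are dropped with their own reason.

## The mutation screen

`screen_associations()` compares, per tumor cohort, the target's expression
between samples carrying a somatic mutation in a query gene and wild-type
samples. The p-value is a two-sided Wilcoxon rank-sum test: exact
permutation enumeration on midranks for combined group sizes up to 20
(exactness survives ties, which the classical exact distribution does not),
and the normal approximation with tie and continuity correction above that.
The fold change is `log2((mean_mut + 1) / (mean_wt + 1))` on the TPM scale
-- means rather than medians so that continuous fold values are attainable,
with a pseudocount of 1 guarding zero means. A record passes the screen
when p < 0.05, |log2 FC| >= 1, and the mutated fraction of the cohort is at
least 5%. The fold-change gate is applied to the absolute value, since
down-regulation is as informative as up-regulation for patient selection.
Raw p-values are used by default, mirroring common practice for this kind
of hypothesis-generating screen; Benjamini-Hochberg adjustment is available
via `adjust = "BH"`. Samples without mutation coverage can be excluded from
both groups by supplying per-cohort covered-sample lists; otherwise
call-free samples count as wild-type.

## Payload mining

`run_payload_pipeline()` follows the compound workflow: merge accessions
sharing a normalized compound name under the smallest NSC id; assign each
compound to sensitivity *categories* from its measured line-level GI50
values -- picomolar if any line is at or below 1 nM, low-nanomolar if any
line falls in the 1-10 nM band; screen each category for >= 50% responsive
lines in at least one of the nine NCI60 indications (response windows:
<= 1 nM for the picomolar class, <= 10 nM for the low-nanomolar class, so a
line killed at picomolar dose still counts as responsive at 10 nM); remove
failed-screen compounds; and partition the qualifiers into picomolar-only,
low-nanomolar-only and overlap groups. Basing membership on measured
categories rather than on the response windows alone is what makes a
picomolar-only group possible at all: a compound whose lines all respond
below 1 nM would otherwise automatically qualify in the <= 10 nM window
too and everything potent would land in the overlap group.

Potency boundaries are inclusive (<= 1 nM, <= 10 nM) and the response
threshold is inclusive (>= 50%): with a two-cell-line panel like prostate,
only the inclusive reading lets a 1-of-2 responder qualify. Replicates are
averaged on the log10 scale (geometric-mean GI50). Profiles are clustered
by Ward-linkage agglomerative clustering on Euclidean distances over the
nine per-panel response percentages (5 clusters for the picomolar-only
group, 10 for the other two by default); profiles are sorted by compound id
first so the partition is invariant to input order, and unmeasured panels
are imputed as 0% for the distance computation only.

## Combinations

`match_combinations()` joins the two arms: a combination (target, tumor
type, payload) is emitted when the payload shows 100% response in an NCI60
panel mapped to that tumor type and the target passed the quasi H-score
gate there, with all screened mutation associations for the pair attached
as context. The panel-to-tumor-type mapping ships as an overridable
configuration table (e.g. renal to KIRC, CNS to GBM and LGG); the 100%
criterion is evaluated on the low-nanomolar (<= 10 nM) window, the regime
in which the six reference payloads (Dxd, exatecan mesylate, maytansine,
monomethyl auristatin E, maytansine derivative, eribulin mesylate) are
characterized.

## The synthetic world

The generators state a fixed world rather than tunable difficulty:

* Background expression is log-normal (meanlog 1, sdlog 1) with zeros
  injected at rate 0.05 to exercise the not-detected category; patient
  fractions are Dirichlet over the four levels.
* Ideal targets carry patient fractions (5, 10, 20, 65) in two tumor types
  (quasi H-score 245), concordant tumor mRNA (log-normal meanlog 4 in those
  cohorts vs 1 elsewhere), membrane/evidence/surfaceome flags, at least one
  evidence criterion, and sub-quartile hematopoietic expression.
* Each cascade stage has one decoy family violating exactly that stage's
  criterion. Two constructions deserve note. Per-gene quartiles across
  tissues always push the top quarter of tissues into the high category, so
  planted genes receive exactly as many separated high tissues (all
  non-critical) as the type-7 Q3 leaves strictly above it. And a 6b decoy
  must be mRNA-cold in its IHC-high cancers *and* hot in most others --
  otherwise the pooled Q1 sits inside its cold distribution and no cohort
  can score below 150.
* Wild-type expression in the mutation bundle is log-normal meanlog 3
  (TPM-like scale, mean ~22), keeping the fold-change pseudocount bias well
  below the ±0.3 recovery tolerance; planted effects scale mutated samples
  by 2^log2FC with Bernoulli mutation calls.
* Background GI50 values are Normal(-6, 1) on the log10 molar scale,
  reflected above -7.8. Untruncated tails would put roughly 2% of
  background lines below 10 nM, and through the two-line prostate panel a
  few percent of background compounds would leak into the low-nanomolar
  group, destroying exact recovery of the planted (33, 631, 65) partition.
  "Inactive" background compounds are therefore genuinely inactive.

A green recovery test establishes that the pipeline's gates sit exactly
where the stated world expects them -- boundaries, orderings, set algebra
-- not that the generator reproduces the marginal distributions of real
HPA, TCGA or NCI-DTP data, which it does not attempt (no inter-gene
correlation, no batch structure, no panel-specific cell-line biology).
Full-scale reproduction of published counts requires the original
downloads and is out of scope for the offline test suite.

## Limitations

The evidence criteria arrive as curated input flags; the package scores
them but does not mine literature. Copy-number and fusion events, mutation
consequence classes, payload physicochemistry, linker chemistry and
internalization biology are all outside the model. Results on real data are
sensitive to the under-specified choices documented above (consistency
policy, fold-change estimator, response-window reading); each is
configurable so the sensitivity can be measured rather than assumed.
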