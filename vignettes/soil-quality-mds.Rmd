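---
title: "Minimum-data-set soil quality assessment for mine waste dumps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimum-data-set soil quality assessment for mine waste dumps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdsqi)
```

## The problem

Waste dumps of open-pit coal mines — spoil piles of stripped topsoil and
rock — are candidate land for reclamation, and deciding where and how to
intervene requires a defensible summary of soil quality. The standard
instrument is a soil quality index (SQI): a composite of physicochemical
indicators, here the nine-indicator panel pH, soil organic matter (SOM),
available nitrogen (AN), available phosphorus (AP), available potassium
(AK), total phosphorus (TP), total nitrogen (TN), surface moisture
content (SMC) and bulk density (BD), measured per sampling point within
each dump ("plot").

`mdsqi` implements the full assessment chain: fuzzy membership scoring,
minimum-data-set (MDS) selection, communality weighting, two composite
indices, and fertility classification, together with transcriptions of
the published reference tables for a five-plot waste-dump study and a
seeded synthetic-data generator so that every stage can be exercised and
tested without external data.

## Membership functions

Raw indicators live on incommensurable scales, so each is mapped to a
dimensionless membership score on [0.1, 1]:

* **S-type** (`score_s_type`), for nutrients whose benefit saturates:
  0.1 below `m1`, linear up to 1 at `m2`, 1 above. Used for SOM
  (m1 = 4, m2 = 13 g/kg), AN (5, 15 mg/kg), AP (3, 10 mg/kg),
  AK (100, 380 mg/kg), TP (1, 2 g/kg) and TN (1, 2.5 g/kg).
* **Parabolic** (`score_parabolic`), for indicators with an optimum
  range: 0.1 below `x1`, rising on [x1, x2), plateau at 1 on [x2, x3),
  falling on [x3, x4), 0.1 at and above `x4`. Used for pH
  (5.5, 6.5, 7.5, 8.5), SMC (5.25, 8, 10, 16 %) and BD
  (0.55, 0.75, 0.85, 1.25; units recorded as printed in the source
  table, although the magnitudes suggest g/cm³ — units are metadata and
  never enter computation).

The floor of 0.1 rather than 0 keeps every indicator's contribution
positive and matches common practice in soil-quality scoring. Endpoint
conventions had to be fixed where the interval notation of the source
leaves them open: a value exactly at `x2` scores 1 (continuity of the
rising branch), exactly at `x4` scores 0.1 (limit of the falling
branch), and values above `x4` floor at 0.1 by symmetry with the region
below `x1`. The AK row of the parameter table carries no explicit
function marker; its two parameters and column placement identify it as
S-type, and it is transcribed as such. The SMC breakpoint string in the
source is ambiguous; it is parsed as (5.25, 8, 10, 16), the only split
that yields increasing breakpoints. This conflicts with the text's
remark that optimal loess moisture lies near 19–21%; the conflict is
inherited from the source and left unresolved.

```{r}
score_s_type(8.5, m1 = 4, m2 = 13)
score_parabolic(8.0, 5.5, 6.5, 7.5, 8.5)
```

## Minimum data set selection

The nine indicators are redundant (pooled Pearson correlations up to
0.84). The MDS procedure reduces the panel while retaining most of its
information:

1. **Standardize** each indicator to zero mean and unit sample variance.
2. **Correlation PCA** (`pca_correlation`): eigendecomposition of the
   Pearson correlation matrix; loadings are eigenvectors scaled by the
   square root of the eigenvalue. The eigendecomposition route (rather
   than an SVD of the data) is used so the pipeline can also run
   directly from a printed correlation matrix with no raw samples. Each
   component's sign is fixed so its largest-magnitude loading is
   positive, making output deterministic; sign never affects any
   selection rule.
3. **Retention** (`retain_components`): components with eigenvalue >= 1
   carrying >= 5% of total variance.
4. **Norm scores** (`norm_scores`): the comprehensive load of indicator
   *i* is the eigenvalue-weighted sum of its squared loadings over the
   retained components; the Norm value is its square root. Both induce
   the same ranking and both are exposed; selection is invariant to the
   choice.
5. **Grouping** (`group_indicators`): |loading| >= 0.6 on one component
   assigns the indicator there; cross-loaded indicators (high on two or
   more) go to the group whose members they correlate with least; an
   indicator high on none follows its largest |loading|.
6. **Shortlist and redundancy** (`select_mds`): per group, indicators
   within 10% (multiplicatively: |U| >= 0.9 max|U|) of the top absolute
   loading are shortlisted; within a shortlist, if any pair correlates
   above |r| = 0.5 the highest-comprehensive-load indicator is kept and
   its strongly correlated competitors dropped, iterating on the rest.
   The union over groups is the MDS, and every decision is recorded in
   an audit log.

All loading rules use absolute values — a negative loading of −0.815 is
as "high" as +0.815; this is required to reproduce the published
selection, where pH qualifies on both components with loadings of
opposite sign. Redundancy filtering applies within group shortlists
only, not across groups (the published MDS retains both pH and BD
despite |r| = 0.761, because they represent different components). Ties
in loadings or Norm values are broken by the canonical indicator order
(pH, SOM, AN, AP, AK, TP, TN, SMC, BD), for determinism.

On the packaged published tables this reproduces the published outcome
exactly:

```{r}
R <- load_fixture("correlations")
L <- load_fixture("loadings")
pca <- structure(list(eigenvalues = L$eigenvalues,
                      variance_pct = L$variance_pct,
                      loadings = L$loadings, p = 9),
                 class = "pca_result")
ns <- norm_scores(pca, 1:2)
gr <- group_indicators(pca, 1:2, R, 0.6)
sel <- select_mds(pca, R, ns, gr)
sel$selected
```

## Weights and indices

**Weights** are PCA communalities (sum of squared loadings over retained
components, the "common factor variance") normalized to sum to one
(`weights_from_communalities`). TDS weights come from the nine-indicator
PCA; MDS weights from a fresh PCA on only the selected indicators,
retained by the same rules. For a three-indicator MDS the retention rule
typically keeps a single component; the source does not state its
choice, and the packaged published MDS communalities are used as-is when
running from fixtures.

**Weighted-additive index** (`wdsqi_weighted_additive`): the dot product
of weights with membership scores, per sample; plot values are sample
means. Weights are deliberately used as given rather than renormalised,
so published rounded weights (summing to 0.999) reproduce published
index values.

**Improved Nemerow index** (`nemerow_improved`, `wdsqin`): couples the
mean membership with the worst single membership,

$$\mathrm{WDSQIN} = \sqrt{\tfrac{\bar f^2 + f_{\min}^2}{2}}\cdot\frac{n-1}{n},$$

implementing the "minimum factor law": a plot is only as fertile as its
most deficient indicator allows. It is bounded in
[0.1 (n−1)/n, (n−1)/n], never exceeds the scaled mean, and raising any
membership never lowers it — all property-tested. Plot aggregation is by
averaging per-sample indices (default) or by applying the index to
plot-mean memberships; both are exposed because the source's printed
plot values cannot be reproduced by either under any aggregation tried,
while the plot *ordering* is reproduced by both. The classical
maximum-factor form is available as `nemerow_legacy`; its printed
formula places an un-squared mean under the root, which is dimensionally
inconsistent and treated as a typesetting error (the literal form is
available behind `literal = TRUE` for auditing).

**Classification** (`classify`): > 0.8 Excellent, (0.7, 0.8] Good,
(0.6, 0.7] Medium, (0.4, 0.6] Deficient, <= 0.4 Destitute. Intervals
are upper-closed so an exact boundary value falls in the lower class.

## Synthetic data generator

`synthetic_config()` + `generate_samples()` emulate the study design:
five plots, five samples per plot by default, each plot drawn from a
multivariate normal with the published per-plot means and SDs and a
correlation matrix shared across plots (the source publishes only a
pooled matrix, so a shared structure is the simplest consistent choice).
The printed correlation matrix is slightly indefinite from rounding;
`repair_correlation` clips negative eigenvalues and renormalises the
diagonal, changing no entry by more than 0.024.

Physical bounds (pH in (0, 14), every other indicator strictly positive)
are enforced by rejection sampling, not clamping, to avoid point masses
at the bounds. A single master seed streams per-plot sub-seeds from a
deterministic hash of the plot id, so outputs are bit-reproducible and
invariant to plot ordering.

**What the generator does and does not emulate.** It reproduces
first/second moments and the shared correlation structure; it does not
model spatial autocorrelation, non-Gaussian marginals or measurement
error beyond the normal SDs. One consequence matters for testing: for
indicators whose published mean sits within about two SDs of zero (TN
and TP in the unreclaimed plots, SD-to-bound ratios down to 1.66), the
truncation materially shifts the mean upward (up to ~0.06 units) and
shrinks the SD (up to ~12%). Empirical moments therefore converge to the
*truncated* distribution's moments, not the configured ones — a property
of the stated design, not a sampler defect. The test suite accordingly
verifies sampler correctness on a mean-shifted configuration where
truncation is inert (moments within 3 SE, SDs within 10%, pooled
within-plot correlations within ±0.1 at 400 samples per plot), and
separately verifies that truncation behaves as designed. Tests that
assert moment recovery at the published means document this bias when
they fail. Relatedly, pooled correlation checks standardize within plot
before pooling, because pooling plots with unequal SDs attenuates the
common correlation.

`end_to_end_recovery()` replays the entire selection pipeline over many
replicate studies. Under the published structure, SOM — the indicator
with the strongest loadings in the generating correlation — is the most
frequently selected MDS member; the between-plot mean separation also
inflates the leading eigenvalue (to about 6.6 at 25 samples per plot),
so a single retained component and a one- or two-indicator MDS is the
typical replicate outcome at that depth.

## Known inconsistencies in the reference tables

The packaged fixtures transcribe the published tables verbatim; the
implementation computes self-consistent values. Where the two disagree,
the discrepancy is inherited from the source:

* The printed two-component eigenvalues (5.435, 1.204; cumulative
  73.769%) do not result from the printed correlation matrix, which
  yields (5.613, 1.210; 75.81%). Eigenvalues are invariant to indicator
  relabeling, so no transcription ambiguity can explain the gap.
* The printed pH loadings (−0.815, 0.872) have squared sum above 1,
  inconsistent with the printed pH communality 0.672.
* The TN communality computed from printed loadings is 0.781; the table
  prints 0.780.
* The per-sample membership table prints its TN and TP columns in the
  opposite order to every other table; the transcription keeps the
  printed order, and no computation here depends on the distinction.
* The printed per-plot improved-Nemerow values (0.634 … 0.214) cannot be
  reproduced from the printed memberships under any aggregation tried;
  the plot ordering they imply *is* reproduced and is the property
  tested.

## Problem sizes used in tests

The packaged checks run the published 5 × 5 design as printed; sampler
moment checks use 400–500 samples per plot; replicated selection checks
use 100 replicates at 25 samples per plot. These sizes give Monte-Carlo
standard errors comfortably below the asserted tolerances while keeping
the whole suite fast.

## Limitations

Membership breakpoints are fixed inputs, not estimated from data; no
factor rotation or alternative retention rules (parallel analysis,
broken stick) are offered; missing values are rejected, not imputed; and
the expert-opinion and unified index families sometimes used alongside
these methods are out of scope.
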