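---
title: "Methods: record-based pesticide exposure, association screening, and neurotoxicity assay statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: record-based pesticide exposure, association screening, and neurotoxicity assay statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwastox)
library(dplyr)
```

pwastox implements, end to end, the statistics of a field-to-bench workflow
linking agricultural pesticide application records to disease risk and then
to direct toxicity in patient-derived dopaminergic neurons. Real cohort data
of this kind cannot be shared (address histories identify participants), so
the package pairs every analysis stage with a synthetic-data generator that
records its ground truth; all claims about correctness are demonstrated on
simulated data with known answers, plus the printed arithmetic of the
published worked examples.

## Exposure model

Mandated use reports record, per application event, the year, the treated
field (a parcel), pounds of active ingredient and treated acreage. For each
participant address (residential and workplace separately) we compute, per
pesticide and year,

$$ E = \sum_r \frac{\text{pounds}_r}{\text{acres treated}_r}
      \times \frac{\operatorname{area}(\text{parcel}_r \cap B)}
                   {\operatorname{area}(\text{parcel}_r)}, $$

the sum over applications $r$ on parcels intersecting the 500 m disc $B$
around the address. Each application enters at its per-acre intensity,
weighted by the share of its parcel inside the buffer, so the estimate has
lbs/acre units and reduces to pounds ÷ treated acres for a fully contained
parcel. The published description ("weighing the total poundage by the
proportion of acreage treated") admits a second algebra — total pounds
times treated-acres-in-buffer over buffer area — and we chose the
intensity-times-parcel-fraction reading because it preserves the stated
unit and the containment limit; this is the one genuinely open design
decision in the module, and the choice is isolated in `annual_exposure()`.

Annual values are averaged over the exposure window, calendar years from
1974 to ten years before the index year (diagnosis for cases, interview for
controls; the 10-year offset models the prodromal period), intersected with
the years covered by address history for that location type. Covered years
with no nearby application count as zeros; participants with no covered
window years get a missing — not zero — summary. A year occupied by several
addresses of one type contributes the equal-weighted mean over those
addresses: spells are recorded in whole calendar years, so no
within-year durations exist to weight by.

Summaries are transformed as $z = (\log(1+x) - \bar{m}) / s$ with mean and
SD computed per pesticide within each wave × location-type stratum, pooled
over cases and controls. Pooled (rather than control-only) standardization
keeps "OR per SD" interpretable within each stratum; standardizing globally
instead would let between-stratum location shifts leak into the effect
scale. Participants are *exposed* to a pesticide when any location-type
summary is positive, and a pesticide enters the association screen when at
least 25 participants are exposed (inclusive boundary).

### Geometry

All coordinates are planar meters. Parcels are convex polygons; the buffer
disc is approximated by an inscribed regular 64-gon, clipped against the
parcel by Sutherland–Hodgman and measured by the shoelace formula. The
64-gon understates the disc area by $1 - \frac{n}{2\pi}\sin\frac{2\pi}{n}
\approx 0.16\%$; the test suite bounds the end-to-end error against a 1 m
raster brute force at 0.01 of the parcel fraction on random placements.
Raising `n_vertices` tightens the approximation at linear cost.

## Association screen

For every included pesticide we fit univariate unconditional logistic
regression of case status on $z$ within each stratum (wave × location
type), then pool the per-stratum log-ORs by fixed-effects inverse-variance
meta-analysis: weights $w_i = 1/\mathrm{SE}_i^2$, pooled
$\hat\beta = \sum w_i \beta_i / \sum w_i$,
$\mathrm{SE} = (\sum w_i)^{-1/2}$, two-sided $p$ from $z = \hat\beta /
\mathrm{SE}$, and 95% CI $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$. A stratum
is pooled only when the pesticide has at least one exposed case and one
exposed control there and the exposure varies; separation or
non-convergence flags the stratum out with a recorded reason. P-values are
adjusted across pesticides by Benjamini–Hochberg, and results are tiered at
FDR ≤ 0.01, (0.01, 0.05], and (0.05, 0.10), with the implicated set defined
by FDR < 0.10 and the associated set (used downstream) by FDR ≤ 0.05 —
boundary conventions follow the published tiers verbatim. The default
model is covariate-free; sensitivity runs pass adjustment covariates (e.g.
an occupational-use indicator) or an exposure × gender product term whose
pooled Wald p is the interaction test.

## Overrepresentation analysis

Group enrichment among associated pesticides uses the 2×2 table
(associated ∩ group, associated ∖ group, group ∖ associated, rest) over the
annotated universe; universe members lacking annotations are dropped first.
We report the *conditional maximum-likelihood* odds ratio — the noncentral
hypergeometric parameter whose conditional mean matches the observed count,
solved by root-finding on the exactly enumerated support — with the exact
95% CI and two-sided p (probability-summation convention) from
`fisher.test()`, and BH adjustment across groups. The conditional MLE, not
the sample cross-product ratio, is reported because it is the estimate the
exact framework pairs with its interval: on the published cholinesterase
table (19/34/31/202) the cross-product gives 3.64 while the conditional MLE
gives the printed 3.62.

## Co-exposure structure

Pesticides applied to the same fields produce correlated exposures.
On the implicated set we compute pairwise-complete Pearson correlations of
residential transformed exposures (raw-scale option available), then:

* a **two-layer network** with edges only between the directly neurotoxic
  layer and the rest at $R > 0.45$, nodes ordered by descending cross-layer
  degree, unweighted closeness centrality on the retained graph, and the
  summary fraction of non-toxic pesticides linked to at least one toxic
  pesticide;
* **clusters** from agglomerative clustering on $d = 1 - R$ cut at 0.55.
  The linkage was not stated in the source analysis; we default to
  *complete* linkage because a 0.55 cut then guarantees all within-cluster
  pairwise correlations exceed 0.45, exactly matching the network
  threshold (average linkage is selectable). Labels are deterministic:
  numbered by decreasing size with lexical tie-breaks.
* **crop shares**: the fraction of a pesticide's application records on a
  given crop, which is what ties defoliant-heavy clusters to cotton.

## Screen statistics

Object-level detections are filtered to candidate cell bodies
(40 < area < 400 µm², roundness > 0.7, intensity > 500, strict
inequalities). The positive-cell cutoff is the mean + 3 SD of candidate
intensities in solvent-control wells, mimicking the two-step image
analysis in which dim debris dominates first-pass detections; counts are
per well, summed over fields. A condition is *toxic* when its mean day-11
count at the 30 µM screening dose falls strictly below the control mean
minus 3 control SDs (per plate by default; pooling selectable — the source
analysis does not say which, and per-plate matches how its controls were
plated). Assay quality is
$Z' = 1 - 3(\sigma_{+} + \sigma_{-}) / |\mu_{+} - \mu_{-}|$. Dose summaries
report per-dose means, percent decrease versus control, a monotonicity
flag, and an LD50 interpolated log-linearly between the doses bracketing
half the control mean.

Combination experiments plate every subset of a compound panel (the empty
subset is the control) at one dose. Each multi-compound condition is
compared with each of its constituent singletons and with the control by
equal-variance Student's t-tests (Welch selectable), BH-adjusted over all
comparisons; a pair is flagged *enhanced-toxicity* when it is significantly
below both constituents. The table also carries the Bliss
(multiplicative-independence) expectation and its excess for each pair.
Note the flag detects joint toxicity beyond each single agent, not beyond
the Bliss product; under multiplicative independence with genuinely toxic
singletons a pair truly is lower than its constituents, so the flag's null
calibration is evaluated under the no-effect null (all singleton survivals
1), where any flag is a false positive. The published Dunnett and two-way
ANOVA post-tests for respirometry dose effects are deliberately replaced by
BH-adjusted pairwise tests; multivariate-t critical values are out of
scope for this package and the BH route is uniformly more conservative for
the screening question asked here.

Mito-stress traces (three measurement cycles per segment; injections of
oligomycin, FCCP, rotenone/antimycin-A between segments) yield the vendor's
standard parameters: non-mitochondrial OCR = post-rotenone/antimycin
minimum; basal = last pre-oligomycin cycle − non-mito; ATP-linked = last
pre-oligomycin − post-oligomycin minimum; maximal = post-FCCP maximum −
non-mito; spare = maximal − basal; spare% = 100 × maximal / basal. Adding a
constant to a whole trace changes only the non-mitochondrial term.

## The synthetic-data generator

`sim_config()` fixes the study conditions; each artifact (landscape,
applications, cohort, plate, respirometry) draws from its own stream
derived from the master seed, so regenerating one artifact never perturbs
another, and identical seed + configuration is byte-identical.

* **Landscape** — axis-aligned rectangular parcels on a jittered grid
  (one per cell, so non-overlap is structural and areas are exact), 600
  parcels on 12 × 12 km by default, matching the parcel density at which a
  500 m buffer intersects a handful of fields. Crops are assigned by
  nearest crop-zone seed, giving contiguous zones; spatial crop structure
  is what leaves some participants unexposed to crop-specific chemistry.
* **Applications** — each co-application cluster draws parcel-year events
  on its anchor crop at rate 0.10/parcel-year; a member follows an event
  with probability `rho_within` (0.8 by default; 1 gives identical
  application sets) and otherwise applies independently. Intensities are
  log-normal with a shared parcel-year factor, giving right-skewed
  lbs/acre. Defoliants are applied only on cotton; other pesticides favor
  their crop with a small spill-over.
* **Cohort** — two waves sized 357/400 and 472/424 (cases/controls),
  enrollment windows 2000–2007 and 2009–2015, age ~ N(65, 9), 55% male,
  40% ever-smokers, 65% with workplace histories; 15% of participants
  provide residential history only from the 1980s on, exercising partial
  window coverage. Disease follows a logistic model in the true
  standardized residential exposures (default three causal pesticides at
  OR 1.5 per SD) plus covariate effects; per-wave quotas are filled by
  rejection sampling from a candidate pool. The recorded ground truth is
  the exposure matrix computed at 256-gon resolution, so the pipeline's
  64-gon recomputation is a genuinely distinct path (and the raster oracle
  a third).
* **Plates** — detections are a two-population intensity mixture: a
  dominant dim population (~95% of filter-passing control detections,
  N(~700, 150) truncated at the 500 filter) and a bright reporter-positive
  population N(4500, 500) whose expected count is Hill survival × a 10%
  log-normal well effect (the 10% control CV reproduces a Z′ in the
  ~0.5 range against the rotenone-like positive control, as in the
  emulated assay); a further ~25% of rows deliberately fail the size/
  roundness/brightness filters. Toxic compounds are parameterized to be
  decisively toxic at the 30 µM call dose (survival plateaus 0.05–0.15,
  EC50 3–6 µM, Hill ≥ 1.8), as in the screen being emulated, where every
  hit fell far below the 3-SD line.
* **Combinations** — subset survival is the product of singleton survivals
  times configured pairwise interaction multipliers (default: one
  synergistic pair at 0.5); `null_model = TRUE` sets every survival and
  multiplier to 1.
* **Respirometry** — piecewise-level traces built from the configured true
  parameters, so noiseless traces invert exactly; Gaussian noise (SD 2 by
  default) otherwise.

What the generator does *not* emulate: real geography and geocoding error,
registration dynamics over decades, address misreporting, wind drift or
road networks, pixel-level imaging artifacts, plate-edge effects, and
batch drift. Passing tests therefore demonstrate the statistics are
implemented correctly and calibrated under the stated generative
assumptions — not that the epidemiologic design is unconfounded in real
data. In particular, co-application makes cluster members of a causal
pesticide show elevated associations in the simulation too; that is the
real phenomenon that motivates the co-exposure module, not an artifact.

## Calibration studies and problem sizes

The heavier checks run as simulation studies at fixed sizes, chosen to
keep Monte-Carlo error well inside the tolerances being checked:

* FDR control under the global null: 200 replicate cohorts of 1000
  participants × 20 pesticides; mean count of FDR ≤ 0.05 discoveries must
  not exceed $0.05 \times 20$ plus 3 Monte-Carlo SEs.
* CI coverage: 50 cohorts of 2000 participants with one causal pesticide
  at OR 1.6 per SD; 95% CI coverage must fall in [90%, 98%].
* Cluster recovery: within-cluster correlation 0.8, 1000 participants;
  adjusted Rand index ≥ 0.9 against the configured partition.
* Screen calls: 20 plates of 39 compounds with 10 true toxicants;
  perfect recall, no false flags.
* Combination null: 200 no-effect plates; enhanced-toxicity flags in ≤ 5%
  of pairs.

These studies use the direct cohort-level simulator `sim_pwas_data()` —
exposures drawn from the latent cluster model without the GIS chain — so
hundreds of replicates run in minutes; the GIS chain itself is validated
separately (truth recovery at Spearman ≥ 0.95 on a full synthetic cohort,
and the raster geometry oracle). The coverage study uses a residential-only
design so that the meta-analysis pools strata that all estimate the
generative coefficient; with location-specific exposure measurement error
the pooled estimand would be attenuated by design, which is a property of
the epidemiology, not of the estimator under test.

## Numerical conventions and degenerate inputs

* Boundary conventions follow the sources exactly: object filters are
  strict inequalities; ≥ 25 exposed includes 25; toxicity requires
  strictly below the 3-SD threshold; tier boundaries are ≤ 0.01,
  (0.01, 0.05], (0.05, 0.10).
* Zero-variance exposure strata: error by default (naming pesticide and
  stratum) or dropped with a message under `on_degenerate = "drop"`, which
  is what the pipeline uses.
* 2×2 tables at the support boundary return odds ratio 0 or Inf; tables
  with single-point support have no defined odds ratio (NaN).
* Equal control means make Z′ undefined (error); constant-variance t-test
  arms degrade to an equality check rather than erroring.
* LD50 is NA when the response never crosses half the control mean and is
  censored at the lowest dose when already below it there.
* All hierarchical-clustering label assignments, network node orders and
  combination-table orders carry deterministic tie-breaks so outputs are
  byte-reproducible.

## Known limitations

The exposure algebra follows one of two readings of the published phrase
(see above); both are scientifically defensible and differ by a smooth
reweighting. The interaction flag is single-dose and pairwise — it will
not detect higher-order synergy masked at 10 µM. Fixed-effects pooling
assumes a common effect across waves and locations; heterogeneity is not
modeled (random-effects pooling is a non-goal). The Fisher two-sided
p-value convention (probability summation) and the exact-CI inversion
match the worked example but other conventions exist; they are documented
here precisely because they differ across software.
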