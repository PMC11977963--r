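---
title: "Methods: splicing-reporter, lifespan and drug-microbe screen analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing-reporter, lifespan and drug-microbe screen analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicescreen)
```

`splicescreen` implements the quantitative backbone of a *C. elegans*
drug–microbe–host longevity study design: a dual-fluorescent splicing
reporter scored by a GFP/mCherry ratio, genome-wide splicing-efficiency
metrics from splice-junction tables, Kaplan–Meier/log-rank lifespan
statistics with worm-specific censoring, three-way bacterial-strain screen
analytics, and bacterial omics post-processing. Every input can be simulated
with known ground truth, so the whole pipeline is testable end to end with
no external data. This vignette documents the models, the tunable
parameters, and the design choices made where the underlying experimental
conventions leave the procedure open.

## Reporter quantification

The splicing reporter expresses two frame-shifted minigene readouts so that
exon inclusion drives GFP and skipping drives mCherry; the per-worm
GFP/mCherry ratio reports splicing state. Quantification follows the
ROI-sampling convention of image-based worm screens:

1. sample `n_rois = 8` square boxes (default `box_size = 60` px) inside the
   intestine mask and `n_background = 3` boxes fully outside it;
2. average pixel intensity over the *union* of each box set per channel
   (pixels covered by several boxes count once);
3. subtract the background mean from the intestinal mean per channel;
4. report `ratio = corrected_gfp / corrected_mcherry`.

Box placement is uniform over all valid placements and boxes may overlap:
rejection-free uniform sampling stays well defined even for thin masks,
where non-overlapping placement can be infeasible. "Inside the intestine" is
operationalized as at least 90 % of box pixels in-mask
(`min_inside_fraction = 0.9`); strict containment is available by setting it
to 1. Two exact invariances pin the arithmetic down: adding a constant to
every pixel of both channels leaves the ratio unchanged (background
cancellation), and scaling one channel by $k$ scales the ratio by exactly
$k$.

A worm whose corrected mCherry is not positive has no defined ratio. Such
worms are excluded and counted, never clamped or imputed — the same
exclusion-style handling the survival analysis applies to censored animals.

Screen hit calling is fully quantitative in every round: a compound is a hit
only if its relative ratio change is positive with `p < alpha` (unpaired
two-tailed Student's t-test, `alpha = 0.05`) in *every* scored round
(`min_rounds = 3`). Early screen rounds are often scored by eye in practice;
scoring all rounds with the same quantitative criterion makes the pipeline
reproducible.

## Splicing-efficiency metrics

Junction records carry 1-based first/last intronic base coordinates, a
donor/acceptor motif label, a read count, and a maximum overhang. A junction
is **rejected** unless its motif is on the canonical whitelist
{GT/AG, CT/AC, GC/AG, CT/GC, AT/AC, GT/AT} and its overhang is at least
`min_overhang = 15` nt (10 % of a 150-nt read; passing
`min_overhang = 0.10 * read_length` reproduces the read-length-tied
variant). The whitelist is configurable. Surviving junctions are
**annotated** when derivable from adjacent exons of an annotated transcript
and **unannotated** otherwise; records with unknown strand match the
annotation ignoring strand, since toy annotations may be unstranded.

* `pct_unannotated_junction_reads`: unannotated junction reads as a
  percentage of all non-rejected junction reads (rejected junctions leave
  both numerator and denominator).
* `pct_intronic_bases`: every aligned base is classified exonic, intronic,
  or intergenic against merged exon territory and gene bodies, with an
  exon-dominant rule (a base on an exon of *any* transcript is exonic); the
  three fractions sum to 100 % by construction. This reimplements the
  standard RNA-seq base-territory metric directly rather than wrapping an
  external tool.
* Cassette-exon PSI: $\mathrm{PSI} = (J_1 + J_2)/(J_1 + J_2 + 2 J_3)$,
  where $J_1$, $J_2$ are the two inclusion junctions and $J_3$ the skipping
  junction; the factor 2 reflects that a skipping transcript contributes one
  junction read where an including transcript contributes two. PSI is
  bounded in [0, 1], monotone in each count, and undefined (NA, with a
  warning) at zero coverage.

**Reversibility calls.** The published criterion for "age-changed, drug-
reversed" events is not part of the junction arithmetic, so the thresholds
are explicit configuration: an event is age-changed when
$|\Delta_{age}| \ge$ `delta_threshold` (default 0.1 PSI), and reversed when
the drug shift has the opposite sign and at least `reversal_fraction`
(default 0.5) of the age shift's magnitude; events below `min_coverage`
(default 20 junction reads) are reported as `low_coverage` rather than
forced into a call.

## Survival and healthspan statistics

Records carry a fate code: `death` enters as an event; `censored_crawl_off`,
`censored_bagging`, `censored_protruding_vulva` (and `censored_other`) enter
as right-censored at the removal time, with an exclusion log per group and
fate. Kaplan–Meier curves and the one-degree-of-freedom log-rank
(Mantel–Cox) test are computed by the `survival` package; ties are handled
by aggregated risk-set expectations, which matters because daily scoring
makes ties the rule, not the exception.

"Mean lifespan" is the arithmetic mean of death times over event animals
only — censored animals are excluded from the mean, not imputed. The
restricted-mean survival time (area under the KM curve up to the last
observed time) is available behind `mean_policy = "restricted"` for cohorts
with heavy censoring. Percent extension is
$100 \times (\bar t_{treated} - \bar t_{control})/\bar t_{control}$.

Fixed-endpoint stress assays (e.g. survival 30 minutes after an oxidative
challenge) are one-time-point designs, so they are compared as two
proportions rather than forced through the survival machinery. Mitochondrial
morphology distributions (tubular / intermediate / fragmented) use the
Pearson chi-square test without continuity correction; intestinal atrophy is
the dimensionless ratio (intestinal − luminal)/body width; CCK-8 growth
inhibition is the blank-corrected complement
$100 (1 - (A_{treated} - A_{blank})/(A_{control} - A_{blank}))$ — the
formula is not spelled out in assay write-ups, and the blank-corrected
complement is the standard reading.

## Three-way screen analytics

Strain-by-dose extension matrices collect per-condition percent extension
with its log-rank p; a `normalized_extension` column divides by a reference
condition (normalization is withheld, with the raw values kept, when the
reference extension is zero). Normalization is scale-free: multiplying all
extensions by a constant leaves the normalized column unchanged.

The dependence taxonomy makes the qualitative language of knockout
experiments ("partially reduces", "completely reduces") operational:

* `required` — the mutant abolishes the effect: extension non-significant
  (`p >= alpha`) or non-positive;
* `not_required` — the mutant retains a significant extension within the
  noise band of wild type (at least `(1 - noise_band)` of the wild-type
  extension);
* `partially_required` — significant but reduced beyond the noise band;
* classification is refused outright when the wild-type effect itself is
  not significant, since there is then nothing to depend on.

The default `noise_band = 0.1` was chosen so that the canonical single-
knockout pattern (wild type ≈ +31 %, single knockout ≈ +24 % and strongly
significant) lands in `partially_required` while a mutant statistically
indistinguishable from wild type lands in `not_required`; a band as wide as
25 % of the wild-type extension would misclassify that single-knockout
pattern as `not_required`. The call is monotone: lowering the mutant
extension (while significant) never moves the call toward `not_required`.
A rescue condition supports the call when it restores a significant
extension of at least `partial_fraction = 0.5` of wild type.

Bacterial abundance uses the linear conversion OD600 × 8×10⁵ cells/µL (the
constant is exposed as `cells_per_od`); CFU/mL is
`colonies × dilution / (volume_µL / 1000)`. Growth curves are summarized by
their maximum OD, the linear-interpolated first crossing of half-maximum,
and the trapezoidal AUC.

## Omics post-processing

Per-feature differential statistics on a log2 features×samples matrix:
`log2FC = mean(treated) − mean(control)` and a two-sided unpaired Student's
t-test (equal variances, the convention of the upstream software these
tables come from). The volcano rule flags `p < 0.05` and `|log2FC| > 1`,
both strict.

Set enrichment over a TF→targets regulon map (or any pathway map — the
statistic is the same) uses the one-sided hypergeometric tail
$P(X \ge \text{overlap})$ with the scorable universe as population, followed
by Benjamini–Hochberg correction across TFs. The enrichment statistic is
not dictated by the data source, and the hypergeometric tail is the
standard choice for membership overlap.

VIP scores come from a two-class PLS-DA fitted by NIPALS on the
centred (and by default autoscaled, the metabolomics convention) matrix
with a centred class indicator:
$$\mathrm{VIP}_j = \sqrt{p \cdot \frac{\sum_a w_{ja}^2\, \mathrm{SSY}_a}{\sum_a \mathrm{SSY}_a}},
\qquad \mathrm{SSY}_a = q_a^2\, \mathbf{t}_a^\top \mathbf{t}_a,$$
which satisfies the algebraic identity $\overline{\mathrm{VIP}^2} = 1$ on
every fit (each weight vector has unit norm). Orthogonal signal correction
is deliberately omitted: for two balanced classes plain PLS-DA and OPLS-DA
produce closely aligned VIP rankings, and the downstream decision rule —
significant iff VIP > 1 **and** t-test p < 0.05 — is preserved exactly.
The rule applies no multiplicity control by construction; with hundreds of
features it admits raw-p false positives alongside the planted signal, which
is the rule's documented behaviour, not a defect of the implementation.
`n_components` defaults to 2 (the number typically displayed in score
plots); it must not exceed `min(n_samples − 1, n_features)`.

## The synthetic-data generators

Every generator is a pure function of its parameters and a seed: identical
calls are bit-identical, the ambient RNG stream is restored afterwards, and
the ground truth travels with the data (in-memory as an attached record, on
disk as a YAML sidecar).

* **Reporter images** — the intestine is an axis-aligned elongated ellipse
  occupying `mask_fraction` of the frame (the simplest shape with an
  inside/outside distinction); per-channel intensity is `background_level`
  outside and `background_level + level` inside, plus i.i.d. Gaussian noise
  clipped at zero. Defaults (GFP 100, mCherry 50, background 10, noise 5 AU)
  plant a ratio of 2.0 with 10 % noise on the dimmer channel. Intensities
  are arbitrary units throughout: bit depth and exposure are not modelled.
* **Junction datasets** — toy three-exon genes with an inclusion and a
  skipping transcript, so all event junctions are annotated. Each event's
  reads are binomial between inclusion and skipping with inclusion
  probability $q = 2\psi/(1+\psi)$, which makes the plug-in PSI estimator
  consistent for the planted $\psi$ and its sampling distribution known. A
  binomial fraction of junction reads is diverted to shifted, unannotated
  junctions; single-block reads are placed fully inside exons or introns at
  the planted intronic fraction, so both recovered fractions are exactly
  binomial proportions — which is what makes confidence-interval recovery
  tests clean. A small extra stream of filter-failing junctions (short
  overhang, non-canonical motif) exercises the rejection path without
  touching the bookkeeping.
* **Survival cohorts** — death times are exponential or Weibull (shape 4 by
  default — worm survival curves are strongly rectangularized, so Weibull is
  the realistic recovery setting, while the exponential family is kept for
  null-calibration work). Each animal is independently censored with
  probability `censor_rate` at a uniform fraction of its latent death time,
  with a fate drawn uniformly among the three exclusion reasons (assay
  write-ups give the reasons, not their rates). Daily scoring is modelled by
  rounding times up to whole days, which produces the heavy ties real
  assays have; at a 20-day control lifespan this biases the extension
  estimate by under a point.
* **Omics matrices** — i.i.d. Gaussian log2 intensities around per-feature
  baselines; a planted feature set is shifted by `effect_log2fc` in the
  treated group; the regulon map contains one TF whose targets equal the
  planted set plus decoy TFs with random target sets of the same size.
* **Growth curves** — a logistic trajectory with a lag phase sampled hourly
  with additive clipped noise; as `rate → 0` the curve is flat at the
  inoculum OD, and the plateau equals the carrying capacity.

What the generators deliberately do **not** emulate: worm segmentation and
motion (masks are inputs), illumination fields, raw sequencing reads and
alignment, mass spectra, or between-replicate batch structure. Passing
recovery tests therefore demonstrates that the estimators are correct on
data satisfying their stated assumptions — not that segmentation, alignment,
or batch correction upstream of this pipeline are solved.

## Numerical choices and degenerate inputs

* Undefined ratios (non-positive corrected mCherry), zero-coverage PSI, and
  all-censored KM curves are reported (NA + warning / degenerate curve), not
  errors; zero junction-read denominators and empty universes are errors
  with typed conditions.
* The chi-square test uses no continuity correction, so closed-form values
  on balanced tables are exact.
* `p = 1` is returned for t-tests on two identical constant samples (no
  evidence, rather than 0/0).
* Half-max crossing of a growth curve uses linear interpolation; a curve
  already at or above half-max at its first sample reports that first time.
* Ties in ROI sampling, binomial splits, and censoring draws are all under
  the caller's seed; no global RNG state is used anywhere.

## Problem sizes used by the test and acceptance suites

The suites run the recovery checks at sizes chosen to make the sampling
error of each check at least an order of magnitude smaller than its
tolerance: 12 worms per reporter group on 128×128 frames; 50,000 junction
reads over 20 genes and 20 generator seeds; 2000 replicate null cohorts of
80 animals/arm for log-rank calibration; 500 animals/arm over 20 seeds for
extension recovery; 50 simulated datasets of 500 features for
planted-regulon recovery; a 40-compound, 3-round, 12-worms-per-group screen
on 64×64 frames for end-to-end hit recovery. Interval-based recovery checks
use family-wise (Bonferroni-adjusted) bands across seeds, and
law-of-large-numbers recovery is asserted on the seed-averaged estimate.

## Known limitations

* The reversibility thresholds, the dependence-call noise band, and the
  CCK-8 inhibition formula are explicit substitutes for conventions the
  underlying assays leave unstated; all are configurable and none affect the
  arithmetic of the metrics themselves.
* PLS-DA VIP omits orthogonal signal correction (see above); rankings, not
  absolute VIP values, should be compared against OPLS-DA outputs.
* The events-only mean lifespan is biased when censoring is informative;
  the restricted-mean policy is the safer alternative under heavy censoring.
* The junction generator plants cassette-exon events only; other event
  classes (alt 5'/3' sites, retained introns as *events*) are represented
  only through the territory metrics.
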