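---
title: "Validating a single-injection scheduled-MRM metabolomic method with mrmqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a single-injection scheduled-MRM metabolomic method with mrmqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmqc)
```

## The problem

Broad-spectrum targeted metabolomics on triple-quadrupole instruments
measures several hundred metabolites in one injection by *scheduled
multiple reaction monitoring* (MRM): each precursor-to-fragment transition
is monitored only within a retention-time window around its expected
elution, so instrument time is shared among concurrently eluting analytes.
Before such a method can support clinical studies it must be validated:
the dwell-time budget has to leave enough sampling points per peak, peak
quality must be quantified, precision decomposed into within- and
between-batch components, linearity and carryover demonstrated,
pre-analytical factors (blood-collection tubes) characterized, and — where
the method backs a diagnostic claim — case/control discrimination assessed
with honest resampling. `mrmqc` implements this whole validation
computation as composable, tested functions, together with a synthetic-data
generator so that every stage can be exercised and unit-tested without
instrument data.

The reference configuration throughout is a single-injection, dual-polarity
HILIC method targeting 705 transitions: 610 endogenous metabolites drawn
from 63 biochemical pathways plus 95 stable-isotope internal standards in a
45-minute run.

## Acquisition scheduling

`concurrency_profile()` bins library retention times (2-min bins by
default) to expose gradient load; `build_schedule()` assigns detection
windows (default half width 1 min, consistent with a 2-min concurrency
analysis; the window width is exposed because vendor defaults differ) and
budgets each segment of constant window overlap:

* the cycle budget after polarity-switching overhead is divided **equally**
  among concurrent transitions — vendor "advanced" weighting schemes are
  proprietary, and the equal split is the defensible neutral default;
* polarity switching is modeled as at most two switches per cycle (one
  contiguous block per polarity, 50 ms per switch by default), the
  minimal-switch ordering;
* dwell is floored at 2 ms, the capability of current instruments; if the
  floor forces the cycle above target, the segment's cycle time is
  inflated and flagged rather than silently violated.

At the method's densest point — about 150 concurrent transitions with both
polarities active and a 1.78 s target cycle — the budget gives
`(1.78 - 2 * 0.05) / 150` = 11.2 ms per transition, comfortably above the
floor. A 35.6 s peak sampled every 1.78 s collects 20 points. Note the
package distinguishes point-RT binning (the histogram view) from
window-overlap counting (what actually constrains dwell): both are
provided and the scheduler uses the latter.

The 1.78 s default cycle is the value implied by a 35.6 s mean peak width
and 20 points per peak; it is a derived default, not a measured constant,
and is a parameter everywhere.

## Peak quality

`measure_peak()` uses operational definitions chosen for reproducibility
rather than vendor fidelity (integration software keeps its exact
algorithms private): the apex is the maximum sample; the peak base is the
contiguous region at `base_frac` of apex height (default 5%, about 4.4
sigma for a Gaussian, near the common 4-sigma convention); width and FWHM
are linearly interpolated at the threshold crossings; the area is the
trapezoidal integral over the base; S/N is apex height over the SD of a
noise window (not peak-to-peak). A zero-noise window with a real apex
reports an infinite-S/N sentinel rather than an error.

Chromatographic quality metrics are heavy-tailed and well described by
lognormal distributions, so `summarize_lognormal()` fits the log-space
mean and SD and reports the linear-space mean `exp(mu + sigma^2/2)` with a
95% **population dispersion** interval `exp(mu +/- 1.96 sigma)` — an
interval describing spread across analytes, deliberately not a standard
error of the mean.

## Precision, linearity, carryover

`variance_components()` implements the balanced replicates-within-days
estimator: per analyte, a one-way random-effects ANOVA with day as the
grouping factor, CVs on the untransformed area scale:
`CV_intra = sqrt(MS_within)/mean`,
`CV_inter = sqrt(max(0, (MS_between - MS_within)/n_reps))/mean`, and
`CV_total = sqrt(CV_intra^2 + CV_inter^2)` — the quadrature identity holds
exactly per analyte by construction (7.4% and 9.5% combine to 12%).
Negative between-day components are truncated to zero, never propagated as
negative CVs. Unbalanced designs are refused rather than approximated.
Panel summaries average per-analyte CVs over a configurable subset
(default: all analytes with a nonzero mean); the panel 95% interval is the
2.5–97.5 percentile spread across analytes. Whether to normalize by
internal standards first is left to the caller — both raw and normalized
matrices pass through the same estimator.

A caveat worth stating: with only five days, the between-day variance
component has about four degrees of freedom, and the square root of such a
noisy variance estimate is biased low by roughly 10%. Recovery simulations
therefore center slightly below the generating between-day CV; this is a
property of the estimator at this design size, shared by any five-day
precision experiment, not a defect of the generator.

`linearity_fit()` regresses linear-scale area on the admixture mixing
fraction per analyte (the conventional axes for admixture linearity) and
reports slope, intercept and Pearson r, plus the fraction of analytes
exceeding r thresholds. `carryover_assess()` takes an injection sequence
whose blanks immediately follow upper-limit-of-quantification (ULOQ)
injections and reports `100 * blank / ULOQ` per analyte with distribution
summaries; blanks out of sequence are a hard error because "first blank
after ULOQ" is the definition of the measurand.

## Tube effects and inter-run concordance

`zscores()` standardizes log2 areas against the control group
(`z = (log2 A - mean_ref)/sd_ref`). The z-score convention (per-sample,
control-referenced, log2 scale; group-level z is the z of the group mean)
is declared here because published usage is often ambiguous. Its value is
gain invariance: any per-analyte multiplicative factor applied to a whole
run cancels, which is what makes z-scores comparable across instruments.

`run_concordance()` quantifies method transfer: per-group squared Pearson
correlations of mean log2 areas across two runs, z-score correlation
restricted to responding analytes (|z| above 0.8 by default), and
optionally pathway-level agreement. `pathway_impact()` is defined as
coverage-weighted mean |z| —
`mean(|z| of measured members) x measured/total` — a deliberate,
documented substitute for topology-based web-tool impact scores, which are
not reproduced here; cross-run comparisons of this score are meaningful
because the definition is identical on both sides.

`tube_comparison()` tests each analyte's log2 area between collection
tubes with Welch's t-test and Benjamini–Hochberg adjustment (the volcano
plots this mirrors do not name their test; Welch is the robust default),
plus chemical-class roll-ups that surface artifacts like the strong
(10–50-fold) depletion of nucleosides in EDTA plasma.

## The classifier workflow

`plsda_fit()` is a NIPALS partial least squares discriminant analysis:
columns standardized internally, labels coded -1/+1, components extracted
by iterated weight/score/loading steps with deflation. `roc_auc()`
computes AUROC as the normalized Mann–Whitney U statistic (ties count
one half) with a stratified percentile bootstrap CI (the CI method is
stated because published ROC CIs rarely say). `select_panel()` mirrors a
random-forest-plus-wrapper biosignature search: permutation importance
ranking (via `ranger`), greedy forward selection by repeated
cross-validated AUROC, then backward elimination. Elimination is
deliberately conservative (default tolerance -0.005): an analyte is
dropped only when its removal *improves* the averaged CV AUROC, because
near the AUROC ceiling the marginal contribution of a true marker is
smaller than CV noise, and an aggressive prune-at-no-cost rule would
discard genuine biology. Ties in forward selection are broken by
importance rank for the same reason. `rdcv()` (repeated double
cross-validation) keeps selection strictly inside the outer training
folds, so its held-out AUROC distribution is an honest generalization
estimate; `permutation_test()` refits the full pipeline under label
permutation and uses the add-one rule, so p-values are never zero. The
historical eight-metabolite chronic-fatigue panel is shipped as a named
fixture (`cfs_biomarker_panel()`) for scoring pre-chosen panels.

## What the synthetic generator emulates — and what it does not

`generate_study()` composes areas multiplicatively:
baseline x day effect x replicate effect x design effects, all lognormal,
matching the observation that peak metrics and abundances are
log-normally distributed and that downstream analysis is log2-based.
Fixed choices, made once:

* between-analyte baseline abundance: lognormal, sdlog 1.2 (plasma
  metabolites span orders of magnitude; no published spread was available,
  so this is a realism choice, not a measured value);
* within-day CV 7.4%, between-day CV 9.5% (a validated method's reference
  values); half of the between-day log-variance is shared across the
  analytes of a sample, half is per-analyte jitter, making inter-batch
  normalization meaningful without dominating;
* admixture and carryover experiments run within a single batch, so only
  the within-day CV applies to them;
* between-subject biological spread: lognormal CV 0.5 per analyte, chosen
  so that planted two-fold biomarkers at realistic cohort sizes neither
  saturate nor vanish;
* carryover fractions: lognormal (sdlog 0.9) with the location solved so
  the mean after truncation at the 4% ceiling equals 0.75%; truncation
  reflects the observation that no analyte exceeded 4%;
* concordance runs share baselines and subject aliquots but differ by a
  per-analyte instrument gain (sdlog 0.28) and an extra 35% per-sample
  re-measurement CV, calibrated so cross-run z-score and AUC correlations
  sit in the regime reported for a real 1.5-year method transfer;
* carryover is proportional to the immediately preceding injection only —
  no second-order memory — matching the first-blank-after-ULOQ definition.

What it does **not** emulate: ion suppression and matrix effects, missing
data mechanisms (censoring at detection limits), peak co-elution and
integration failures, drift within a batch, or realistic correlation
structure between metabolites of the same pathway (pathway members are
independent given the design effects). Green tests on synthetic data
therefore demonstrate the statistics are computed correctly under the
declared model — not that real instruments behave this well.

## Numerical and design choices

* Missing areas are `NA` end to end and CSV round-trips keep them as empty
  cells; "not detected" never becomes zero, which would corrupt both CVs
  and log2 statistics.
* Retention times are minutes internally; peak widths seconds; conversion
  happens at one boundary (`measure_peak`).
* Transition tables accept a canonical snake_case header set and vendor
  method-table aliases (`Q1 Mass`, `Ion Mode`, ...) via a declared alias
  map; unknown columns ride along as annotations.
* All generators and resampling procedures are seed-deterministic;
  identical inputs and seed give bit-identical outputs.
* Problem sizes in the test-suite recovery studies (for example 500
  analytes by 20 replicate studies for precision, 600 noise analytes for
  panel recovery) were chosen as the smallest sizes at which Monte-Carlo
  error is clearly inside the assertion bands.

## Known limitations

Vendor S/N and peak-width definitions are unpublished, so peak-quality
numbers are comparable within this package but not bit-comparable to
integration-software exports. The precision estimator supports balanced
designs only. The PLS-DA implementation is the standard two-class NIPALS
algorithm, not a multi-class or orthogonalized variant. Pathway impact is
coverage-weighted mean |z|, not a topology-based score. None of these
restrict the validation workflow the package exists to serve.
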