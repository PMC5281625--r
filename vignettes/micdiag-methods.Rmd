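---
title: "Methods: diagnosing microbially influenced corrosion from metabolomes and metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diagnosing microbially influenced corrosion from metabolomes and metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micdiag)
```

## The problem

Microbially influenced corrosion (MIC) of carbon-steel pipelines is driven
by biofilm metabolism — classically by sulfide-producing prokaryotes such
as sulfate-reducing bacteria (SRB), against which operators inject nitrate
to favour nitrate-reducing competitors. Whether that strategy succeeds in
a given pipeline is hard to judge from community composition alone.
`micdiag` implements a diagnostic workflow that combines two independent
views of pigging-debris samples from a high-corrosion (HC) and a
low-corrosion (LC) system, each sampled at an early (pig 3) and a late
(pig 11) scraping run:

* the **metabolome**: untargeted LC-MS feature tables (neutral mass,
  retention time, triplicate abundances in instrument units, i.u.), and
* the **metagenome**: genome-bin coverages and gene read counts.

Everything downstream of instrument-level processing (peak picking,
assembly, annotation engines) is in scope; those upstream steps are not.

## Exact-mass chemistry and the nitrogen rule

Formulas are parsed into element-count maps over CHNOPS plus halogens and
summed against a packaged monoisotopic mass table (IUPAC values, >= 6
decimals). ESI ions are converted to neutral masses with the proton mass
(1.007276 Da) rather than the hydrogen atom mass, because the electron
stays behind on protonation. Mass agreement is expressed as signed ppm and
mDa.

The nominal (integer) mass is the round-half-up of the neutral
monoisotopic mass. For even-electron CHNOPS molecules the nitrogen rule
holds: odd nominal mass if and only if the nitrogen count is odd. Two
caveats are built in and tested:

* the rule's domain is chemically valid, even-electron compositions —
  those with a non-negative *integer* ring-and-double-bond count (`rdbe()`).
  Radical compositions such as CH3 violate it, so the exhaustive
  verification sweep enumerates only integer-DBE formulas;
* above 500 Da the accumulated mass defect (mostly from hydrogen,
  +0.0078 Da per H) makes simple rounding unreliable, so parity calls
  carry an `unreliable` flag there. Within the tested box (<= 20 C, 30 H,
  4 N, 8 O, 2 S, 2 P, <= 500 Da) rounding is exact.

## Feature alignment, abundance floor and shot-noise QC

Raw single-replicate peaks are merged by single-linkage transitive closure
when pairwise mass difference <= 6 ppm *and* retention-time difference
<= 0.25 min, within an ion mode; comparisons are inclusive at the
boundary. Single linkage is the natural closure of a pairwise tolerance
but means a chain of close peaks can span more than the pairwise window;
the brute-force closure oracle in the tests pins down exactly this
semantics. Merged abundance is the member sum per (sample, replicate);
merged mass and retention time are abundance-weighted means. Features that
then match across the two ionization modes under the same tolerances are
counted once, keeping the higher-total-abundance mode's values and the
label `both`. The per-sample abundance of an aligned feature is the mean
over its replicates.

A feature is dropped only when its per-sample mean abundance is strictly
below 1,000 i.u. in every sample — below that floor detection probability
falls off steeply — and the filter reports removed/retained counts.

Quality control exploits the instrument's counting statistics: 12.5 i.u.
correspond to one detected ion, so 1,000 i.u. is ~80 ions and the expected
relative standard deviation of replicate measurements is $1/\sqrt{N}$ for
ion count $N$. A (feature, sample) measurement is consistent when its
observed replicate RSD is at most twice that expectation; on
Poisson-generated tables >= 90% of measurements pass, which is the
behaviour expected of a well-behaved instrument.

## Putative identification

Candidates are library compounds whose monoisotopic mass is within 6 ppm
of the feature's neutral mass. For positive-mode features a quantitative
structure-retention relationship (QSRR) gate applies: retention time is
predicted by ordinary least squares on six physico-chemical descriptors
(>= 8 authentic standards, full-rank design; 33 standards in the emulated
study), and candidates whose observed retention time deviates from the
prediction by more than 45% (relative to the prediction, a documented
choice — run-length-relative is the alternative the method leaves open)
are rejected. Negative-mode features skip the gate, as the retention model
is calibrated for the positive-mode (HILIC) chromatography only. The six
descriptors are deliberately treated as an opaque ordered vector supplied
with the library: the package preserves the model structure without
committing to specific descriptor identities.

Each retained candidate receives a deterministic 1–10 confidence score
built from the three ingredients that matter for putative LC-MS
identification — mass-error magnitude, retention-time deviation, and
database priority (default order KEGG > MetaCyc > HMDB > LipidMaps):
penalties of `3*|ppm|/6`, `3*deviation/0.45` (flat 1 with no prediction)
and `min(rank-1, 3)` are subtracted from 10, the result floored to an
integer and clamped to [1, 10]; matching an authentic standard's reference
retention time within 10% forces 10. Flooring (rather than half-up
rounding) is this rubric's convention, chosen so the worked arithmetic
10 − 1.5 − 1 = 7.5 scores 7: a fractional score never rounds *up* into a
confidence class the evidence has not fully earned. The best candidate per
feature wins on confidence, with ties broken by priority rank, then
absolute mass error, then compound id — a total order, so input order
never matters. Accepted annotations roll up to pathway counts, with
pathway-free compounds accumulating under `unassigned`.

## Targeted succinate screening

Alkylsuccinates (C$_{n+4}$H$_{2n+6}$O$_4$ for an $n$-carbon alkyl chain)
and benzylsuccinates (C$_{11+m}$H$_{12+2m}$O$_4$) are diagnostic products
of anaerobic hydrocarbon activation by addition to fumarate. The screen
demands both the correct mass (±2 ppm) and the correct retention time
(±10%, relative to expectation). Expected retention times come from
piecewise-linear interpolation of anchor standards against carbon number
— the standard chromatographic assumption for a homolog series, flagged
as an approximation and as `extrapolated` beyond the anchors; with a
single anchor only that member is gated, and with none the screen is
mass-only and flagged. All qualifying features are reported because
isomers legitimately co-qualify; the most abundant per series member is
marked `top_hit`. Aerobic degradation products (hydroxylated aromatics)
are screened as single-compound targets with per-compound reference
retention times.

## System-level statistics

**RN statistic.** The abundance-weighted share of odd-nominal-mass
features,
$$ R_N = 100 \times \frac{\sum \text{abundance(odd-mass features)}}{\sum \text{abundance(all features)}} \; [\%], $$
tracks organonitrogen metabolism without identifications. For annotated
features the matched formula's nitrogen parity overrides mass rounding —
the rule is exact once the composition is known. RN is scale invariant and
bounded in [0, 100].

**Differential features.** Per-feature system abundances are the sums of
per-sample means over each system's pigs. A feature is enriched when at
least one system strictly exceeds 10,000 i.u. and the abundance ratio is
at least 5 (inclusive; a zero denominator with an above-gate numerator
counts as infinitely enriched). The similarity summary reports the
fraction of two-sided features whose max/min ratio is strictly below 3,
tallying one-sided features separately.

**Identified ratio.** Among the top-200 features by per-sample mean
(ties by feature id), the ratio of features with an accepted annotation to
those without.

**PCA.** Observations are the sample × replicate abundance vectors of
features passing 10,000 i.u. in at least one sample; per-feature
mean-centering, no unit-variance scaling (the abundance scale is
meaningful), linear or log10(x+1), components by singular value
decomposition. Replicates (not sample means) are the observations, so
replicate tightness is visible in the scores.

## Metagenome TEA arithmetic

Gene read counts normalize to hits per million reads
(`count / total_reads * 1e6`); group contrasts are ratios of group means
or per-sample ratios, with zero denominators flagged infinite rather than
raised. Pathway presence on a genome bin is a configuration-driven call:
every required group of alternative marker genes must intersect the bin's
annotations (denitrification: {narG|napA}, {nirS|nirK}, {norB}, {nosZ};
dissimilatory sulfate reduction: {dsrA}, {dsrB}). The community fraction
carrying a pathway in a sample is
$$ \sum_{\text{positive bins}} \frac{\text{coverage} \times \text{bin length}}{\text{total bases sequenced}} \times 100\%, $$
i.e. the bins' read share of the *whole* metagenome — so fractions over
all bins need not reach 100% when binning is incomplete, which is the
honest denominator for "fraction of cells".

## What the synthetic generator emulates — and what it does not

All tests run on seeded synthetic data; the generator
(`generator_config()`) encodes the study conditions as defaults: four
samples (LC3, LC11, HC3, HC11) in triplicate, two ESI modes with ~72% of
features positive, 12.5 i.u./ion, a 400-compound library with a 50%
odd-nitrogen mix, 250 library-derived features plus 150 unidentifiable
"exochemical" background features (masses rejection-sampled to match
nothing within 18 ppm), log-normal true abundances with Poisson
ion-counting replicate noise, a six-descriptor linear retention model
(intercept 20 min, noise 0.5 min, 33 standards), an alkylsuccinate
spike-in series (n = 2–10, anchors at n = 6/5.98 min and n = 10/12.0 min)
with decoys 8–15 ppm off-mass, and a genome-bin community whose
denitrifier (78%/39% in LC3/LC11) and sulfate-reducer (29%/34% HC,
1.5%/1.6% LC) fractions mirror the field system. The per-sample true RN
values are likewise calibrated to the field pattern
(40%/55%/40%/30% in LC3/LC11/HC3/HC11) by rescaling the odd-parity
features' abundances, so the synthetic metabolome reproduces the
depth-dependent divergence of organonitrogen content between the two
systems. Library masses are kept
>= 25 ppm apart so that exact-mass annotation has a unique right answer —
that is what makes "100% recall" a meaningful test.

Bin coverages carry 1% multiplicative log-normal noise: the mean depth of
a megabase-scale bin averages millions of per-base observations, so its
statistical error is far below biological and mapping variation, and at
1% the coverage-based fraction estimator recovers community fractions
within ±2 percentage points even for the large (~80%) denitrifier
fraction split across two bins. Setting it to zero makes the estimator
exact, which the tests use to verify the pure inversion.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: correlated matrix effects and ionization
suppression, retention drift between batches, isotopologue and adduct
multiplicity (one feature per compound), chimeric bins and contamination,
or annotation databases with near-degenerate masses. Real pipeline
metabolomes are also an order of magnitude larger (~10,000 features); the
desk-scale defaults (~420 features, 8 bins) keep the full suite under a
minute while exercising every code path, and all statistics are
size-independent ratios.

## Numerical choices and edge cases

* All tolerance comparisons are inclusive (<=); boundary behaviour is
  pinned by tests (e.g. a per-sample mean of exactly 1,000 i.u. is
  retained; a ratio of exactly 5 is enriched; exactly 3-fold is *not*
  "similar").
* Round-half-up for nominal mass (`floor(m + 0.5)`), so 146.5001 rounds
  odd and 146.4999 even.
* Zero total abundance makes RN undefined: an explicit error, not NaN.
* Empty alignment input yields an empty table; an empty candidate list
  yields no annotation; no anchors yield a flagged mass-only screen.
* Abundance-weighted merge means fall back to unweighted when all member
  abundances are zero.
* The confidence rubric is this package's documented stand-in for
  workflow-internal scoring schemes whose weights are not public; printed
  confidence values from other software are deliberately not reproduced.

## Reproducibility

Every stochastic step flows from a single integer seed: the generators
derive fixed offsets from it, so a fixed seed gives identical tables
(integer draws exactly; floating point up to platform arithmetic).
`run_pipeline()` is a pure function of its inputs and configuration, and
repeated runs write byte-identical machine-readable summaries. The
`scripts/acceptance.R` entry point re-derives the package's headline
numbers — standard masses, the acetate and sulfate conversions, the
oxygenase fold contrasts, and the full synthetic pipeline's RN,
differential, screening, QC and cell-fraction outputs — from scratch at
each invocation.
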