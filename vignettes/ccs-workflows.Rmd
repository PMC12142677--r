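---
title: "CCS calibration, prediction and annotation filtering with cimCCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CCS calibration, prediction and annotation filtering with cimCCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cimCCS)
```

## The problem

In mass spectrometry imaging (MSI) of tissue, most features cannot be
fragmented: precursor abundance is low, there is no front-end chromatography,
and co-selection produces chimeric spectra. Ion-mobility collision cross
sections (CCS, Å²) offer an orthogonal, fragmentation-free descriptor.
On a cyclic ion-mobility (cIM) instrument the resolving power grows with the
number of passes through the separator, and with an accurate multipass
calibration the CCS error against drift-tube reference values drops well
below 1%. At that accuracy a measured CCS can adjudicate between isobaric
database matches and prune structure candidates whose machine-learning
predicted CCS disagrees with the measurement.

cimCCS implements that workflow end to end: exact-mass and adduct m/z
arithmetic, the two calibration routes, per-adduct support-vector-regression
CCS prediction, imaging feature-table statistics, and CCS-threshold candidate
filtering — together with a simulator that generates every input with known
ground truth, so each stage is validated by parameter recovery rather than by
fixed expected numbers.

## Mass and adduct conventions

All m/z arithmetic is neutral-atom based: an adduct m/z is
`(M + k·m_atom)/z` with monoisotopic neutral-atom masses and **no
electron-mass correction**. This is the convention under which the package
reproduces the reference identifications it is tested on (for example the
leucine-enkephalin lock mass 556.2771 and the rocuronium ppm-error series);
`electronCorrection = TRUE` switches to the physically strict cation masses
for data processed under that convention. Pre-charged cations (quaternary
ammonium species such as rocuronium) enter as `[M]+`, their doubly
protonated form as `[M+H]2+`.

Isotope spacing uses the single-parameter ¹³C–¹²C approximation
(1.003355 Da/z): metabolite and lipid isotope patterns are carbon-driven, and
the first isotopologue is all these workflows use. Charge inference inverts
that spacing and reports the residual so borderline calls are visible.

## The two calibration routes

**Instrument-default (linear).** Drift bins are converted to milliseconds via
the ADC pusher period, the m/z-dependent transfer time `C·sqrt(m/z)` is
subtracted (EDC correction), and corrected CCS is a straight line in
corrected drift time. Charge and reduced-mass dependence is restored per ion
with `CCS = Ω_c · z · sqrt(1/μ)`, `1/μ = 1/m_ion + 1/m_gas`. The EDC
coefficient's scale is instrument metadata whose units are not standardized,
so a configurable `edcUnitFactor` (default 1) multiplies it. The drift gas
defaults to N₂ at its monoisotopic mass 28.00615 Da, overridable where the
average mass convention is wanted.

**Multipass (power law).** Arrival-time distributions at several pass counts
are Gaussian-fitted; the apexes `t_nd` at pass count `n` and separation time
`t_s` are regressed as

```
(t_nd - t_s)/n  =  t_pp - (v_u/v_p) · (t_s/n)
```

whose intercept is the perturbed periodic drift time `t_pp` and whose slope
is minus the unperturbed-to-perturbed velocity ratio. This regression
arrangement is the only reading of the perturbed-drift relation that makes
the stated linear fit well posed; it is isolated in `fitTpp()` so an
alternative arrangement would be a one-function change. Note the regression
extrapolates to `t_s/n = 0`, so separation times that are near-exact
multiples of the circuit time (constant `t_s/n`) leave it underdetermined —
`passSettings()` therefore defaults to settings landing partway through the
final circuit.

The calibrants' `t_pp` values are then fitted against their reference CCS
via a power law `Ω_c = A · t_pp^B`. Two choices matter here:

* the power law calibrates **corrected** CCS (reference values reduced by
  charge and reduced mass), and the conversion is inverted per analyte ion —
  reference databases publish CCS proper, so whether the reduction is applied
  before fitting is a genuine degree of freedom; calibrating the corrected
  quantity keeps the two routes on the same footing and makes the noiseless
  round trip exact;
* the fit is ordinary least squares in log–log space, which is deterministic
  and initialization-free; residuals are reported in both spaces.

Gaussian peak fitting initializes the mean at the max-intensity point, sigma
from the FWHM, amplitude from the maximum, and restricts the fit window to
±3 initial sigma; flat signals and <5 points are rejected rather than
guessed at.

## CCS prediction

One epsilon-SVR (radial-basis kernel) per adduct, on a fixed 2-D descriptor
panel computed with OpenBabel: MW, logP, TPSA, molar refractivity, H-bond
acceptor/donor counts, fluorine count, and formula-derived element counts.
Descriptors are computed on the canonical SMILES, so any encoding of one
structure yields a bit-identical vector. Records are split
`ceiling(0.7 n)` / `floor(0.3 n)` into training and validation; descriptors
are standardized with training-fold statistics only; cost, gamma and epsilon
are chosen by 5-fold cross-validation on the training fold; the reported
median relative error and RMSE come from the held-out 30% only. The panel
and grid are arguments, not constants, because descriptor sets in published
CCS predictors vary and numeric parity with any particular one is not
promised. Adducts with no training records fall back, with a warning, to the
`[M+H]+` model unshifted.

## Feature tables and differential statistics

Cross-run alignment is greedy centroid clustering within 0.03 Da m/z and
2 drift bins (the tolerances under which imaging feature lists are typically
merged), visiting features by descending intensity with ascending-m/z
tie-breaks, so it is deterministic. Isotope flagging requires the m/z, drift
and intensity-ratio conditions simultaneously and limits chains to depth 2.
Doubly charged partners are linked by `(mz₁ + m_H)/2` within 5 ppm, and ion
images are compared by Pearson correlation — the combination used to tie a
low-drift feature to the 2+ charge state of its parent.

Differential filtering keeps features with fold change ≥ 1.5 (either
direction, oriented control/tumor) and Welch p ≤ 0.1 on per-section
intensities, with no multiple-testing correction by default (a deliberate
choice for small-n feature triage; `pAdjustMethod` enables one). The t-test
is computed on **log** intensities by default: MS intensity noise is
multiplicative, and at n = 4 per group the raw-scale Welch test is
noticeably conservative under log-normal noise, while the log scale matches
the error model and holds close to the nominal level. Note that even on
exactly normal data the Welch test at 4 + 4 has true size about 0.089 at the
0.10 level — the small-sample cost of estimating the degrees of freedom —
which is what the null-simulation tests observe. Fold changes are always
reported on raw means.

## Candidate filtering and isobar adjudication

Database matching computes every adduct m/z for every entry and keeps
matches within an inclusive tolerance (±0.005 Da or ±5 ppm by default,
matching common practice for lipid and metabolite databases). Candidate
lists (rank, structure, formula, adduct, database/de-novo source) are
truncated to the top 20 by rank. Filtering removes candidates whose
|predicted − experimental|/experimental exceeds the active threshold
(default ±1%, the level justified once calibration error is ≈0.4%);
kept/removed always partition the input, and tightening the threshold only
ever moves candidates from kept to removed. Isobar adjudication ranks
candidates by |percent difference| and declares the minimum the winner
unless the top two are within 0.05 percentage points — below the
calibration's demonstrated accuracy, so such ties are genuinely
unresolvable. Sum-composition checking is elemental-formula + adduct
equality: robust, format-free, and strict about adduct identity (the same
formula under `[M+K]+` vs `[M+H]+` is a mismatch). De novo candidates are
filtered identically to database candidates but remain labeled so reports
can segregate them.

## What the simulator emulates — and what it does not

The simulator generates: multipass arrival-time spectra (Gaussian peaks
whose width grows as `sqrt(t_nd)`, mimicking diffusional broadening; apex
jitter and additive intensity noise), feature studies (log-normal
multiplicative intensities with sdlog 0.3, planted fold changes, isotope
partners at +1.003355/z with ratios 0.2–0.5, charge-state pairs, per-run m/z
jitter 0.005 Da and drift jitter 0.4 bins), candidate lists with controlled
percent-CCS offsets (decoys default to 2–5% off, the scale at which
wrong-structure candidates typically sit), and descriptor/CCS training data
with a known generative function. Default study sizes mirror a small
two-group tissue comparison: 4 sections per group, 1.5-fold / p ≤ 0.1
triage.

It does **not** emulate: chemical noise and background ions, isotopic
envelopes beyond the first isotopologue, drift-time peak asymmetry, spatial
autocorrelation within tissue images, matrix effects, or real
structure–CCS relationships (the SVR recovery tests demonstrate the learning
machinery on known generative functions, not chemical generalization).
Passing tests therefore establish correctness of the arithmetic, the fits
and the decision logic under the stated noise models; they do not certify
accuracy on any particular instrument or tissue.

## Numerical choices and degenerate inputs

* All regressions (linear calibration, perturbed-drift, log–log power law)
  are ordinary least squares; the only iterative fit is the Gaussian peak
  (Levenberg–Marquardt, max 200 iterations).
* Formula subtraction refuses negative element counts; EDC correction
  refuses non-positive corrected drift times; power-law fitting refuses
  non-positive inputs; charge inference refuses spacings outside 1–4
  (configurable).
* Alignment ties are broken by ascending m/z; candidate filtering uses a
  strict `>` against the threshold, so a candidate exactly at ±1.00% is
  kept, consistent with inclusive "±" bounds elsewhere.
* Validation problem sizes used throughout the tests and the acceptance
  script — 500-replicate regressions, 500-record training sets, 100-seed
  null studies of 1000 features, 15-seed calibration comparisons — were
  chosen to make Monte-Carlo error small relative to the tolerances being
  checked while keeping a full run in tens of seconds.

## Known limitations

The EDC unit factor must be supplied when instrument metadata uses a scaled
coefficient; the package cannot infer it. The multipass route assumes the
perturbed-drift model holds across the pass range used — settings whose
`t_s/n` barely varies give an ill-conditioned intercept. CCS prediction
quality is bounded by the descriptor panel; isomers that differ only in
double-bond position or chain branching are generally within ±0.5% predicted
CCS of each other and cannot be separated by this mechanism. The annotation
engine deliberately performs no fragmentation-tree or MS² scoring; it
consumes candidate lists produced elsewhere.
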