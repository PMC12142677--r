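# cimCCS

Collision cross section (CCS) workflows for cyclic ion mobility (cIM)
spatial metabolomics: calibration, machine-learning prediction, and
CCS-based filtering of annotation candidates.

## Who this is for

Mass spectrometry imaging (MSI) experiments routinely leave most features
unannotated: MS² coverage is sparse, and a measured m/z alone cannot
separate isobaric database matches or rank structure candidates. On cyclic
ion-mobility instruments, multipass separation pushes CCS accuracy below 1%,
at which point the CCS itself becomes a usable annotation filter. cimCCS is
for analysts who have (or simulate) cIM drift measurements and candidate
lists and want a reproducible, tested path from drift bins to filtered
annotations.

## What it computes

**Mass arithmetic.** Monoisotopic masses from Hill-notation formulas,
adduct m/z for `[M+H]+`, `[M+Na]+`, `[M+K]+`, `[M+2H]2+`, `[M]+`,
`[M+H]2+` (neutral-atom masses, no electron correction by default), ppm
errors, isotope spacing `k·1.003355/z`, charge inference from isotope
spacing, and ion–gas reduced masses.

**Two CCS calibrations.** The instrument-default route

```
t_d(ms) = t_d(bins)·V_ADC/1000        (pusher period)
t_c*    = t_d(ms) − C·√(m/z)          (EDC correction)
Ω_c     = m·t_c* + b                  (linear calibration)
Ω       = Ω_c·z·√(1/μ),  1/μ = 1/m_ion + 1/m_gas
```

and the multipass route: Gaussian fitting of arrival-time distributions per
pass count, the perturbed-drift regression
`(t_nd − t_s)/n = t_pp − (v_u/v_p)·(t_s/n)` giving each ion's perturbed
periodic drift time `t_pp`, and a power-law calibration `Ω_c = A·t_pp^B`
fitted in log–log space against reference CCS values.

**CCS prediction.** Per-adduct epsilon-SVR (RBF kernel) on OpenBabel 2-D
molecular descriptors, 70/30 train/validation split, hyperparameters by
cross-validation on the training fold, metrics reported on the held-out 30%.

**Feature tables.** Cross-run alignment (0.03 Da / 2 drift bins), exclusion
list background removal, isotope flagging, doubly-charged linking, ion-image
correlation, and differential filtering (fold change ≥ 1.5, Welch p ≤ 0.1)
with volcano classification.

**Annotation.** Database m/z matching (±0.005 Da or ±5 ppm, inclusive),
candidate ingestion (top 20 by rank), CCS percent-difference filtering
(default ±1%), isobar adjudication by smallest |difference| with a
0.05-point tie window, and formula+adduct sum-composition checks.

**Simulation.** Every input above can be generated with known ground truth
(`simulateMultipass()`, `simulateFeatureStudy()`, `simulateCandidates()`,
`simulateCandidateScenario()`, `simulateIsobarPairs()`,
`simulatePredictorData()`), all seeded and deterministic.

## Worked example

Identify a pre-charged cation by mass error, then run the multipass
calibration on simulated noisy data:

```r
library(cimCCS)

M <- monoisotopicMass("C32H53N2O4")       # rocuronium cation
adductMz(M, "[M]+")                        # 529.4005
adductMz(M, "[M+H]2+")                     # 265.2042
ppmError(529.3989, adductMz(M, "[M]+"))    # -3.1 ppm
ppmError(265.2030, adductMz(M, "[M+H]2+")) # -4.4 ppm

ccsTrue <- setNames(seq(200, 330, length.out = 8), paste0("ion", 1:8))
sim <- simulateMultipass(ccsTrue, mz = seq(400, 950, length.out = 8),
                         apexJitterSd = 0.01, intensityNoiseSd = 0.02, seed = 42)
wf <- multipassWorkflow(sim, calibrants = paste0("ion", c(1, 3, 5, 7)))
wf[c("ion", "tppHat", "ccsMultipass", "trueCcs", "isCalibrant")]
```

```
      ion   tppHat ccsMultipass trueCcs isCalibrant
ion1 ion1  6.46745      201.051 200.000        TRUE
ion2 ion2  7.54506      217.811 218.571       FALSE
...
ion8 ion8 16.25758      328.808 330.000       FALSE
```

The small ppm errors support the `[M]+` / `[M+H]2+` assignment of the two
features; in the calibration table, `ccsMultipass` recovers the planted CCS
of both calibrants and held-out analytes to a fraction of a percent. On the
same noisy data the multipass route averages 0.48% CCS error against 0.93%
for a single-pass linear calibration — the ordering that motivates the
multipass method:

```r
mean(ccsPercentError(wf$ccsMultipass, wf$trueCcs))  # 0.48
mean(ccsPercentError(wf$ccsLinear, wf$trueCcs))     # 0.93

sc <- simulateCandidateScenario(seed = 1)           # 108-candidate list
filterCandidates(sc, 1.0)$counts[["removed"]]       # 78
filterCandidates(sc, 0.5)$counts[["removed"]]       # 91
```

At a ±1% CCS threshold, 78 of the 108 constructed candidates are removed;
tightening to ±0.5% removes 91 — tighter thresholds only ever remove more.

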