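---
title: "Quantitative DCE-MRI pharmacokinetics: models, phantom and statistics"
author: "dcekinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative DCE-MRI pharmacokinetics: models, phantom and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcekinetics)
```

## The analysis problem

Dynamic contrast-enhanced MRI acquires fast T1-weighted volumes before,
during and after a gadolinium bolus. In neuro-oncology the resulting
signal–time curves carry two clinically useful quantities: the volume
transfer constant Ktrans (how fast contrast leaks from plasma into the
extravascular-extracellular space, a permeability–flow composite) and a
cerebral blood flow estimate, rBF. Meningiomas lie outside the blood–brain
barrier and are densely vascularised, so both quantities are expected to be
high relative to contralateral brain and to many of the intra-axial tumours
that mimic meningiomas on conventional images. The package implements the
full quantitative chain that turns a 4D signal series plus a pre-contrast
T1 map into per-subject Ktrans/rBF summaries and cohort-level exact tests.

## Signal model and concentration conversion

The dynamic readout is modelled as a spoiled gradient echo in steady state,

$$S = M_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1\cos\alpha},
  \qquad E_1 = e^{-TR/T_1},$$

with TR in ms and flip angle $\alpha$ in degrees. Contrast changes the
longitudinal rate linearly, $1/T_1(t) = 1/T_{10} + r_1 C(t)$ (rates in
s^-1, concentration in mM). Conversion of a voxel's dynamic signal to
concentration therefore needs the voxel's pre-contrast $T_{10}$: the
pre-bolus frames give the baseline signal $S_0$, which together with
$T_{10}$ fixes the effective $M_0$; each frame is then inverted through the
SPGR equation. This baseline-T1 correction is mandatory in the pipeline —
there is deliberately no signal-only fallback, because uncorrected
enhancement conflates T1 with concentration.

Numerical conventions worth stating:

* frames whose signal exceeds the invertible SPGR range become `NaN` rather
  than being clamped to the ceiling;
* negative concentrations from zero-mean noise at baseline are **kept**:
  clamping at zero would bias the subsequent least-squares fits upward;
* a voxel is dropped only by the zero-signal rule (below), not for noise.

The relaxivity default is $r_1 = 3.7\,\mathrm{s^{-1}mM^{-1}}$, a typical
gadopentetate value at 3 T; it is configurable because the agent and field
strength vary between sites. Variable-flip-angle (DESPOT1) estimation of
$T_{10}$ and $M_0$ is provided for acquisitions that include a multi-angle
calibration scan; flat (angle-independent) signal is treated as
unidentifiable and flagged rather than fitted, since in practice it marks
saturated or noise-floor voxels.

## Kinetic models

Two quantitative models are fitted voxel-wise against the plasma curve
$C_p(t)$:

* **Extended Tofts**: $C_t = v_p C_p + K^{trans} \int_0^t C_p(u)
  e^{-k_{ep}(t-u)}\,du$ with $k_{ep} = K^{trans}/v_e$. Reported parameters
  are Ktrans (min^-1), $v_e$, $v_p$; $k_{ep}$ is always emitted as the
  ratio, so $k_{ep} v_e = K^{trans}$ holds identically in the outputs.
* **Two-compartment uptake**: $C_t = F_p (R \circledast C_p)$ with residue
  $R(s) = E + (1-E)e^{-s/T_p}$, extraction $E = PS/(F_p+PS)$ and plasma
  transit time $T_p = v_p/(F_p+PS)$. Backflux is neglected, which is
  adequate over a few minutes of acquisition; the fitted $F_p$ is the
  model-based rBF.

Convolutions are evaluated by trapezoidal quadrature **on the acquired
frame grid**, which may be nonuniform — clinical schedules mix 5 s and 30 s
spacings — so no resampling or interpolation artefacts enter the fit. The
suite checks the discretisation against adaptive quadrature on dense grids
(agreement within 1e-6 of the curve peak).

A semiquantitative flow estimate is emitted alongside the model fit: CBV as
the ratio of tissue to arterial curve areas, MTT as the difference of first
temporal moments (central volume theorem), and `rbf_auc = CBV/MTT`. The MTT
is floored (default 1 s) to keep the ratio finite for artery-like curves;
floored voxels are flagged, never silently clipped. Both flow estimators
are computed for every voxel and the configuration chooses which one feeds
the VOI summaries (default: the model-based $F_p$, since the uptake-model
fit is the primary flow definition here; the AUC/MTT route is retained
because both definitions are established and comparisons between subjects
are rank-based, so the choice does not affect the cohort conclusions).

### Fitting protocol

The optimiser is bounded Levenberg–Marquardt (minpack.lm) with box bounds
Ktrans ∈ [0, 5] min^-1, $v_e$ ∈ (1e-4, 1], $v_p$ ∈ [0, 1], $F_p$ ∈ (1e-4,
20] min^-1, PS ∈ [0, 5] min^-1 — generous relative to cerebral physiology,
tight enough to exclude pathological optima. Five starts are used per
voxel: a fixed base start plus seeded uniform jitter inside the bounds, so
repeated runs are bit-identical. On noiseless data the first converged
start typically reaches the global optimum and a residual threshold exits
the start loop early. Curves that carry no signal (all-NaN or identically
zero) are flagged degenerate and excluded rather than fitted.

### The zero-signal exclusion rule

VOI means are taken only over voxels with usable dynamic signal: a voxel
whose maximum dynamic signal is ≤ 1e-9 × the series maximum, whose T1-map
entry is unusable, whose conversion yields no finite frame, or whose fit is
degenerate/failed, enters an explicit exclusion mask and is `NaN` in every
parameter map. This operationalises the practice of averaging "across
voxels with non-zero signal intensity" so that model failures (e.g. from
T2* signal loss near vessels) never contaminate the summary statistics. The
exclusion mask is exactly the union of those causes, which the tests assert
as a set equality.

## Arterial input function

The AIF is measured per subject: inter-individual AIF variation is large
enough that a shared population curve distorts absolute parameter values,
so a population curve is never silently substituted (an explicit
`analytic` flag exists for data without an artery mask). Candidate voxels
inside the artery mask are scored as

$$\mathrm{score} = 0.7\,\rho + 0.3\,\hat{p},$$

where $\rho$ is the Pearson correlation with a canonical AIF shape (the
Parker population curve evaluated on the subject's frame grid) and
$\hat{p}$ the candidate's peak normalised by the largest candidate peak.
Correlation alone would admit partial-volume voxels with the right shape
but depressed amplitude; peak alone would admit noise spikes. The top k
curves are averaged (default k = 10, configurable down to the 5 used by
some clinical packages), and the whole-blood result is converted to plasma
by $C_p = C_b / ((1-\mathrm{Hct})\,f_{pv})$ with Hct = 0.45 by default and
partial-volume factor 1 (phantom vessels are not sub-voxel).

## The digital phantom

The generator builds a 32×32×8 grid (1.4×1.4×3 mm voxels) containing a
spherical tumour, its mirror-image contralateral control with near-zero
leakage (Ktrans 0.002 min^-1, white-matter T1), and a 2×2-voxel arterial
column carrying whole-blood concentration $(1-\mathrm{Hct})\,C_p$ from the
analytic Parker AIF. Region curves follow the extended Tofts model (tumour
default Ktrans 0.25 min^-1, $v_e$ 0.4, $v_p$ 0.05) or the uptake model
($F_p$ 0.6 min^-1, $v_p$ 0.05, PS 0.05 min^-1), are rendered to SPGR signal
with region-specific $T_{10}$ (tumour 1400 ms, white matter 1100 ms, blood
1664 ms — typical 3 T values), and optionally carry additive Gaussian noise
(default σ = 5% of each voxel's baseline signal, seeded and mandatory to
seed). The acquisition defaults mimic a TWIST protocol: TR 4.83 ms, TE
1.87 ms, flip 12°, 70 frames at 5 s spacing, bolus arriving at frame 3; the
frame schedule is configuration, not hard-coded, so sparse late sampling
can be emulated. The Parker curve is forced to zero at and before the bolus
arrival time (its raw analytic form is slightly positive at t = 0), keeping
the pre-bolus baseline exact.

What the phantom does *not* emulate — and therefore what passing recovery
tests do not establish about clinical data: subject motion, B1
inhomogeneity, T2*-induced signal loss at high concentration, water
exchange, Rician noise statistics at low SNR, partial-volume mixing at
region boundaries, and vessel-size effects on the AIF. The noise model is
additive Gaussian on magnitude signal, a deliberate simplification that is
adequate at the simulated SNR but optimistic near the noise floor.

Phantom-based validation targets, all enforced by the test suite: noiseless
recovery of Ktrans/$v_e$/$v_p$ within 2% and $F_p$ within 5% through the
complete pipeline (conversion → measured AIF → fit); AIF recovery within 1%
after haematocrit correction; median Ktrans bias below 10% at 5% noise over
50 replicate fits; and byte-identical artefacts across repeated seeded runs
(pipeline imaging output is written as uncompressed NIfTI for exactly this
reason; the run log is excluded from the comparison since it records wall
time).

## VOI summaries and control regions

The contralateral control VOI is constructed by reflecting the tumour mask
across the midline plane and intersecting with the brain mask; if more than
10% of the voxel count is lost (reflection partly outside brain), the
region is grown back by deterministic 6-neighbour dilation inside the
brain. A tumour crossing the midline produces a warning and a control from
the non-overlapping reflected part. This mirroring is one reasonable
operationalisation of "a control VOI of similar size on the contralateral
side"; freehand control masks can be supplied instead.

## Exact small-sample statistics

With six paired subjects and a 6-vs-3 group comparison, p-values must come
from exact nulls. The package enumerates them completely:

* **Wilcoxon signed-rank**: zero differences dropped, mid-ranks for tied
  magnitudes, W = sum of positive-signed ranks; the null counts all 2^n
  sign assignments. Doubling the ranks makes mid-rank statistics
  integer-valued, so the enumeration is an exact integer subset-sum count.
* **Mann–Whitney**: U counts pairs with half-credit for ties; the null
  enumerates all C(n_a+n_b, n_a) group assignments via pooled mid-ranks.

Every exact p is a ratio of integer counts, and the suite verifies equality
with independently coded brute-force oracles (direct sign-pattern expansion
and pairwise-comparison counting) across hundreds of random small fixtures,
plus the classical exact distributions in tie-free cases.

**Sidedness.** The default is two-sided. At these sample sizes the smallest
achievable two-sided values are themselves the decisive ones (2/64 for six
pairs of one sign; 2/84 for complete 6-vs-3 separation), and a directional
alternative can be requested with `sidedness = "one"`, which takes the tail
on the side of the observed effect. Displayed p-values are rounded half
away from zero to 4 decimals (so 0.03125 renders as 0.0313) and medians to
3; CSV output keeps full precision.

The paired estimate is reported as the median of control − tumour
differences, so elevated tumour values appear as negative medians.
Pearson correlations of each parameter against tumour volume use the
classical t-based p-value; they run only when volumes for at least three
subjects are available.

## Problem sizes and runtime

Defaults are chosen so everything runs comfortably on one CPU: the
full-size phantom's fitted region is ~600 voxels (the brain mask covers the
kinetic regions, not empty background), and a complete
simulate-to-statistics run takes tens of seconds; the acceptance script's
two full-size noiseless recoveries plus determinism check complete in under
a minute. Voxel-wise fitting is linear in mask size, so whole-brain masks
simply scale the cost.

## Known limitations

* The uptake model neglects backflux; late-time data from leaky tumours is
  better served by the extended Tofts route, which is why both are fitted.
* T1 mapping assumes SPGR/VFA calibration data; inversion-recovery T1 maps
  can be supplied directly as images instead.
* The two rBF definitions (model $F_p$ vs AUC/MTT) are not numerically
  interchangeable; only their within-cohort rankings agree in general.
* No motion correction is implemented (a registration hook would sit before
  conversion); the phantom is motion-free by construction.
* Exact enumeration is exponential/combinatorial by design and guarded for
  cohort-scale inputs; it is not intended for dozens of subjects, where
  asymptotic or sampled nulls are appropriate.
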