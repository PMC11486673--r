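# dcekinetics

Quantitative pharmacokinetic analysis of dynamic contrast-enhanced MRI
(DCE-MRI) for small-cohort neuro-oncology studies, built around the problem
of separating intracranial meningiomas from tumours that mimic them on
conventional MRI. Meningiomas sit outside the blood–brain barrier and are
highly vascular, so their volume transfer constant (Ktrans) and cerebral
blood flow (rBF) should exceed both normal brain and most mimicking
tumours — but demonstrating that on a handful of subjects needs careful
quantitative modelling and exact small-sample statistics, which is what this
package provides.

## What it computes

**Tracer-kinetic models.** Tissue gadolinium concentration is modelled from
the plasma concentration `Cp(t)` (the arterial input function, AIF) by:

- the **extended Tofts model**

  `Ct(t) = vp·Cp(t) + Ktrans · ∫₀ᵗ Cp(u) · exp(−kep (t−u)) du`,

  giving Ktrans (min⁻¹), the extravascular-extracellular volume fraction
  `ve` (with `kep = Ktrans/ve`), and the plasma volume fraction `vp`;

- the **two-compartment uptake model** `Ct = Fp · (R ⊛ Cp)` with residue
  `R(s) = E + (1−E)·exp(−s/Tp)`, `E = PS/(Fp+PS)`, `Tp = vp/(Fp+PS)`; the
  fitted plasma flow `Fp` is reported as the model-based rBF. A
  semiquantitative CBV/MTT estimator (central volume theorem on curve
  areas) is emitted alongside.

**Relaxometry.** Signal ↔ concentration conversion through the spoiled
gradient-echo (SPGR) steady-state equation with baseline-T1 correction from
a measured pre-contrast T1 map, plus variable-flip-angle (DESPOT1) T1
estimation.

**Measured AIF.** Artery-mask voxels are scored against a canonical AIF
shape (correlation × normalised peak), the top-k curves averaged, and the
whole-blood curve converted to plasma with haematocrit and partial-volume
correction.

**VOI statistics.** Parametric maps are averaged over the
contrast-enhancing tumour VOI and a mirrored contralateral white-matter
control VOI, excluding zero-signal and failed-fit voxels; cohort comparisons
use **exact** Wilcoxon signed-rank and Mann–Whitney tests whose nulls are
fully enumerated — appropriate at n = 6 vs 3, where asymptotic p-values are
untrustworthy.

**Digital phantom.** Because clinical DCE series are rarely shareable, a
phantom generator renders tumour / contralateral-control / artery regions
with known Ktrans/ve/vp/Fp ground truth into a noisy TWIST-like SPGR
acquisition (TR 4.83 ms, flip 12°, 70 × 5 s frames by default), so the whole
chain — conversion, AIF extraction, fitting, summarisation — is testable
end to end.

## Worked example

The package ships a per-subject cohort table (`canine_voi_table()`): mean
tumour and control Ktrans and rBF for six dogs with histologically confirmed
meningiomas and three dogs with mimicking intracranial tumours.

```r
library(dcekinetics)
report <- group_comparison_report(canine_voi_table())
print(report)
#> Group comparison report
#>   meningioma n = 6 (paired n = 6), other n = 3
#>   wilcoxon_signed_rank_exact   ktrans  estimate -0.045  p = 0.0313 (two-sided)
#>   mann_whitney_exact           ktrans  estimate 0.047 / 0.016  p = 0.1667 (two-sided)
#>   wilcoxon_signed_rank_exact   rbf     estimate -3.824  p = 0.0313 (two-sided)
#>   mann_whitney_exact           rbf     estimate 4.286 / 1.562  p = 0.0238 (two-sided)
```

Reading the numbers: within meningiomas, control-minus-tumour differences
are negative for both parameters (median −0.045 min⁻¹ for Ktrans, −3.824
for rBF) with the smallest two-sided exact p reachable at n = 6
(2/64 → 0.0313) — tumours leak and perfuse more than contralateral brain.
Between groups, rBF fully separates meningiomas from the other tumours
(exact p = 2/84 → 0.0238) while Ktrans overlaps (p = 14/84 → 0.1667, not
significant).

A phantom analysis end to end:

```r
res <- run_pipeline(list(mode = "all", out_dir = "phantom_run",
                         phantom = list(sigma = 0.05, seed = 7),
                         kinetics = list(seed = 7)))
res$summaries   # tumour vs mirrored-control means over the fitted maps
```

A shell wrapper with `simulate | analyse | stats | all` subcommands lives at
`inst/scripts/dce_pipeline.R`.

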