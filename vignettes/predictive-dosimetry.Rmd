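---
title: "Predictive alpha-chain dosimetry and xerostomia risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive alpha-chain dosimetry and xerostomia risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actichain)
```

## The problem

Ac-225 labelled PSMA ligands deliver high-LET alpha radiation to metastatic
castration-resistant prostate cancer, but salivary gland uptake causes
xerostomia severe enough to limit dosing. Because Ac-225 itself is nearly
invisible to gamma cameras, organ kinetics are measured with the beta/gamma
surrogate Lu-177 bound to the same carrier, and the alpha-emitter dose is
*predicted* from those kinetics. `actichain` implements that prediction
chain end to end:

1. **Kinetics** — planar anterior/posterior counts are scatter-corrected
   (triple energy window), converted to fractions of injected activity
   (conjugate-view geometric mean, no attenuation correction), stripped of
   the Lu-177 physical decay, re-decayed with the Ac-225 half-life, fitted
   with exponential washout models, and integrated to MIRD residence times.
2. **Decay chain** — the Ac-225 series (Fr-221, At-217, Bi-213, the
   98%/2% Po-213/Tl-209 branch, Pb-209) is assumed in secular equilibrium
   with no daughter translocation, so every daughter inherits the parent's
   residence time scaled by its yield.
3. **Dose engine** — for unit-density spheres (parotid and submandibular
   glands) alpha and beta energy is deposited locally and photons escape
   (absorbed fraction 0 by default), giving per-organ dose coefficients;
   with the alpha term weighted by RBE = 5 these are the Bd_RBE5/MBq
   coefficients.
4. **Radiobiology** — the linear-quadratic BED for a continuous,
   exponentially decaying mixture of sources, the EQD2 conversion, and the
   Lyman-Kutcher-Burman probit give the predicted probability of grade >= 2
   xerostomia as a function of injected activity (kBq per kg).

## The model, briefly

With per-source initial dose rates $R_{0,n} = D_n A_i \lambda$ (alpha-only,
unweighted absorbed dose coefficient $D_n$ in Gy/MBq, injected activity
$A_i$ in MBq, shared effective decay constant $\lambda$ in 1/h), the
high-LET BED of the mixture is

$$\mathrm{BED_H} = \frac{1}{\lambda}\sum_n R_{0,n}\left\{\mathrm{RBE_M} +
\frac{\sum_n\sum_p R_{0,n}R_{0,p}}{(\lambda+\mu)(\alpha/\beta)\sum_n R_{0,n}}\right\},
\qquad
\mathrm{RBE_M} = \mathrm{RBE_{exp}} + \frac{d}{\alpha/\beta}\,
\frac{\mathrm{RBE_{exp}}^2 - 1}{\mathrm{RBE_{exp}}}.$$

The double sum collapses algebraically to $S^2$ with $S=\sum_n R_{0,n}$, so
the BED depends on the mixture only through the summed initial dose rate.
`bed_high()` keeps the double sum explicit and the tests verify the
collapse (partition invariance) to 1e-12 and the whole expression against a
semi-analytic quadrature oracle (inner repair integral analytic, outer
integral by adaptive quadrature) to 1e-6 relative over
$\lambda \in [0.005, 0.5]$ 1/h and $S \in [0.001, 1]$ Gy/h. External-beam
comparators use $\mathrm{BED_L} = D(1 + (D/N)/(\alpha/\beta))$,
$\mathrm{EQD2} = \mathrm{BED}/(1 + 2/(\alpha/\beta))$, and
$\mathrm{NTCP} = \Phi\!\big((\mathrm{EQD2}-TD_{50})/(m\,TD_{50})\big)$,
implemented via the normal CDF, not numeric integration of the probit.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| $\alpha/\beta$ | 3 | Gy | LQ ratio for the xerostomia endpoint |
| $\mu$ | 0.46 | 1/h | sublethal-damage repair rate |
| $\mathrm{RBE_{exp}}$ | 5 | — | experimental alpha RBE (deterministic endpoints) |
| $d$ | 2 | Gy | reference low-LET fraction dose (gives $\mathrm{RBE_M}=8.2$) |
| $TD_{50}$ | 14 | Gy (EQD2) | 50% complication dose, acute grade >= 2 xerostomia |
| $m$ | 0.88 | — | LKB slope |
| RBE weight | 5 | — | alpha weighting in Bd_RBE5 coefficients |
| branching | 0.98 / 0.02 | — | Po-213 / Tl-209 yields per Bi-213 decay |

The 2%/98% branching is kept as the default even though evaluated decay
data give 2.2%/97.8%, because the prediction procedure being reproduced
used the round values; the nuclide JSON schema lets a user override both
the branching and the emission energies. Emission energies are
yield-weighted totals per decay (MeV), not line lists — only totals enter a
sphere model with local deposition. The stable Bi-209 endpoint is omitted.

$\lambda$ in the BED is the *slow-phase* effective decay constant: for
bi-exponential fits the smaller rate is used, since it governs the
long-term washout that dominates the integral. Fits are unweighted least
squares on the linear scale (the measurement model is silent on weighting;
`weighting = "value"` switches to relative-error weighting). Amplitudes
are constrained non-negative — uptake phases are not modelled — and rates
are bounded below at 1e-6 1/h, where a flat curve will pin rather than
error.

## Photon policy and its error bound

OLINDA-style sphere photon absorbed fractions are not public, so the
engine defaults to absorbed fraction 0 for photons with a per-organ
override. Photons carry ~0.2 MeV of the ~28 MeV chain total and
contribute well under 0.2% of the weighted dose, so the bound on the
error of this choice is far below every tolerance used; the packaged
energy table puts the alpha share of the RBE-5-weighted dose at 99.5%,
inside the published 98.2–99.8% range.

## What is fixture and what is recomputed

The published 13-patient dose-coefficient and salivary-BED tables ship as
plain-text fixtures (`load_paper_fixtures()`), because the per-patient
organ S-values, washout constants and body weights behind them were never
printed: the per-patient BEDs cannot be recomputed from the coefficients
plus the printed parameters under any reading of the mixture formula. The
testable surface of those tables is therefore their internal consistency
(the salivary column equals the per-patient parotid/submandibular mean in
all 13 rows) and their summary statistics (medians 0.86 and 1.05
Bd_RBE5/MBq, salivary mean 67.0 Gy, median 51.9 Gy, sample SDs with the
n−1 denominator matching the printed 0.59 and 57.6), all of which the
package recomputes exactly.

For the NTCP-versus-activity curve the published figure's aggregation rule
is unstated, and the three natural candidates disagree (cohort-mean EQD2,
cohort-median EQD2, mean of per-patient NTCPs). All three are implemented
and reported side by side in `ntcp_vs_activity()` rather than asserting
any one against the printed incidence points. Confidence intervals are
percentile bootstrap over patients with a fixed seed (the CI method is
likewise unstated). Where per-patient washout constants are missing — as
with the fixtures — a cohort default stands in: the median parotid
effective half-life (25.5 h, Lu-177 context) converted to the Ac-225
context via `lambda_lu_to_ac()`, and an 80 kg median weight; the output
flags when defaults were used. The "reduced of 66%" statement about
excluding Po-213 is ambiguous ("by" vs "to"), so the exclusion toggle
(`exclude = "Po-213"`, which removes ~30% of the unweighted dose) is
implemented but the 66% is not asserted.

## The synthetic generator

`generate_cohort()` emulates the study conditions: 13 patients by default,
mono-exponential washout per organ in the Lu-177 measurement context,
sampled once in each acquisition window (0.5–1, 16–24, 36–48 h, uniformly
jittered, plus 120 h), with multiplicative lognormal noise of CV 0.05
(planar quantification error is positive and roughly proportional; a
Gaussian switch exists). Masses, body weights and effective half-lives are
drawn uniformly in the published ranges; zero-time amplitudes are drawn
uniformly in 0.5–3% (parotid) and 0.2–1.5% (submandibular) of injected
activity, chosen once so that the implied weighted coefficients land on
the scale of the published table. The carried truth includes the
closed-form residence times in both isotope contexts and the sphere-model
coefficient, so every pipeline stage is testable against ground truth.

What the generator does *not* emulate: bi-exponential uptake/washout
mixtures, voiding effects on the early whole-body normalisation, count
statistics at the pixel level, organ delineation error, or daughter
redistribution. Passing recovery tests therefore demonstrate estimator
correctness under the stated noise model, not robustness to those real
acquisition effects. Parameter-recovery checks run at n = 200 patients
(400 organ fits), where the median relative error of the recovered
residence time at 5% noise stays within ±5%.

## Numerical choices

- Mono-exponential fits initialise from a log-linear regression and refine
  by Levenberg–Marquardt on the linear scale; bi-exponential fits
  initialise by curve peeling (tail regression for the slow phase, positive
  residuals for the fast phase). Non-convergence errors carry the
  initialiser values.
- Bi-exponential terms are reported slow phase first (rates ascending).
- The TEW estimator is the standard trapezoid form
  `main − (lower/w_lower + upper/w_upper) · w_main/2`, clamped at zero.
- `ntcp_lkb(TD50) = 0.5` holds exactly by construction of the probit.
- The bootstrap and the generator seed a local RNG and restore the
  caller's `.Random.seed`, so pipeline functions do not perturb user code.

## Known limitations

Kidneys, liver, red marrow and whole body are carried only as fixture
coefficients (they were phantom-based, not sphere-based, in the source
analysis) and are never recomputed. No attenuation correction is applied
anywhere, matching the measurement protocol being emulated. The model is
deliberately conservative: uniform activity in each gland, no daughter
translocation, no RBE_min/overkill corrections — all flagged caveats of
the formalism rather than omissions of the implementation.
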