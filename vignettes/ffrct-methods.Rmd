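---
title: "Reduced-order FFR-CT, virtual stenting, and agreement statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order FFR-CT, virtual stenting, and agreement statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffrct)
```

# What this package models

Fractional flow reserve (FFR) is the ratio of mean coronary pressure distal
to a stenosis to mean aortic pressure under maximal hyperemia; values at or
below 0.80 mark ischemia-causing lesions, and a post-stenting FFR at or
below 0.90 marks a suboptimal functional result. FFR-CT estimates this
index non-invasively by simulating blood flow on coronary geometry, and
*virtual stenting* extends it: modify the reconstructed lumen to the
expected post-stent shape, re-simulate, and predict the post-intervention
FFR before the procedure. `ffrct` implements the full analysis chain —
geometry, hemodynamics, stent planning, and the method-agreement
statistics used to validate such predictors against invasive FFR — plus a
synthetic cohort generator so the whole pipeline can be exercised and
tested end to end without patient data.

# The reduced-order hemodynamic model

Clinical FFR-CT systems solve the 3-D incompressible Navier–Stokes
equations on meshes of millions of elements. The pressure ratios that FFR
is built from, however, are dominated by axial pressure losses, which
well-established reduced-order ("0D/1D") coronary models reproduce
closely. This package therefore represents each vessel as a network:

* **Segments** carry a generalized Poiseuille resistance
  $R = \int 128\,\mu / (\pi d(s)^4)\, ds$ integrated from the lumen
  profile $d(s)$ by the trapezoid rule.
* **Narrowings** add a Young–Tsai-type quadratic loss
  $\Delta P = K_t\,\tfrac{\rho}{2}\left(\tfrac{1}{A_s}-\tfrac{1}{A_0}\right)^2 Q\,|Q|$
  with $K_t = 1.52$ by default, $A_s$ the minimal lumen area and $A_0$ the
  reference area. Loss terms are located directly on the profile: every
  interior local diameter minimum that drops below *and* recovers above
  its neighbouring maxima by at least 2% counts as a narrowing, with
  $A_0$ taken at the preceding maximum. A smooth taper has no recovery and
  therefore no quadratic loss — this keeps healthy tapered vessels purely
  viscous and avoids any circular dependency between the solver and the
  lesion detector.
* **Outlets** are three-element Windkessels (proximal resistance $R_p$,
  compliance $C$, distal resistance $R_d$). Total resting resistance is
  calibrated as $R_\mathrm{tot} = (\bar P_a - P_v)/\bar Q$ from a target
  resting mean aortic pressure (93 mmHg by default) and is distributed
  over the terminals by Murray's law (flow shares proportional to
  $d^3$), after subtracting each terminal's flow-weighted epicardial path
  resistance so the healthy rest state reproduces $\bar P_a$ exactly. The
  split is $R_p = \kappa R$, $R_d = (1-\kappa) R$ with $\kappa = 0.09$
  and $C = \tau / R_d$ with $\tau = 0.5$ s; these constants are
  conventional coronary outlet values and are configurable.
* **Inflow** is the allometric total coronary flow
  $\bar Q = c\, V_m^{3/4}$ from the myocardial volume $V_m$, with $c$
  calibrated so a 120 mL myocardium receives 2.0 mL/s at rest. The
  waveform is a two-phase piecewise-cosine aortic-like pulse (period
  0.8 s, systolic fraction 0.33, diastolic level 0.4, normalized to cycle
  mean 1); a constant-waveform mode supports steady analyses. FFR uses
  cycle means, which are insensitive to the waveform's exact shape under
  the linear outlet loads used here, so the pulse is a shape assumption,
  not a calibrated quantity.

Blood is Newtonian with $\rho = 1.050$ g/cm³ and $\mu = 0.035$ poise,
walls are rigid, and units are CGS internally (1 mmHg = 1333.22 dyn/cm²)
with mmHg/mm/mL/s at every interface.

**Hyperemia.** FFR is a hyperemic index; the model applies the
conventional adenosine response by multiplying both outlet resistances by
`hyperemia_factor = 0.24` (configurable, logged in the outlet objects).
The inlet flow stays at the rest-calibrated $\bar Q$ — hyperemia is
expressed entirely through the outlet resistances, so the simulated
aortic pressure falls and FFR is read as the pure pressure ratio
$\bar P_d / \bar P_a$. This keeps the inflow model and the resistance
calibration independent of each other; its consequence, shared by any
prescribed-inflow formulation, is that the absolute hyperemic flow
increase is folded into the resistance divider rather than into the
waveform.

**Numerics.** The nodal equations (flow conservation at every junction,
edge flow inverted in closed form from the monotone
$\Delta P = RQ + K_2 Q|Q|$ relation) are solved by damped Newton
iteration with an analytic Jacobian to a residual below $10^{-12}$ of the
inlet flow; with no quadratic terms the system is linear and converges in
one step. The pulsatile solver advances the Windkessel states with
second-order backward differentiation (implicit Euler on the first step),
initialized from the steady solution at mean flow so that a constant
waveform reproduces the steady solve without transient; integration stops
when cycle-mean nodal pressures change by less than $10^{-6}$ relative
between cycles (default cap 12 cycles at dt = 4 ms). The test suite
verifies the Poiseuille closed form to $10^{-10}$, steady/unsteady
consistency to $10^{-6}$, junction mass conservation to $10^{-8}$ of
inlet flow, and an observed BDF2 convergence order of at least 1.9.

# Geometry and lesion detection

Vessels are stored as centerline arc length plus lumen radius — the
solver needs only $d(s)$, so 3-D surface data would be pass-through
metadata. Resampling uses monotone shape-preserving (Fritsch–Carlson)
interpolation: overshoot would manufacture spurious stenoses, so it is
excluded by construction.

Reference ("normal") diameters come from shoulder medians: the median
lumen over a 5 mm window immediately proximal/distal to a lesion, with
linear interpolation across it. Detection fits a robust upper-envelope
line per segment (iteratively refitting through the samples at or above
the fit, so narrowings drop out), flags runs with percent diameter
stenosis of at least 30% against that envelope, merges runs closer than
5 mm (serial lesions), expands each run to the full lesion extent (below
5% envelope stenosis) so the shoulders sample normal lumen, and grades
severity as $100\,(1 - d_\min / d_\mathrm{ref})$ at the location of the
minimal lumen. The 30% threshold, 5 mm merge gap and 5 mm shoulder are
conventional angiographic choices, configurable, and only *seed* stent
planning — which is additionally FFR-gradient driven — so the pipeline is
not sensitive to their exact values.

# Virtual stenting

The blinded (algorithmic) planner targets, for each lesion, the union of
the lesion extent and the contiguous region where the FFR drop exceeds
0.005 per mm. Stent length is the smallest catalog length covering the
target plus a 2 mm margin per side, centered on the target; when even the
longest catalog stent (38 mm) cannot cover a diffuse target, several
equal-length stents are placed with at least 1 mm pairwise overlap. End
diameters are the catalog sizes nearest the proximal/distal reference
diameters, never exceeding the proximal reference; ties break toward the
shorter stent and smaller diameter. The catalog defaults to 2.25–5.0 mm
diameters in 0.25 mm steps and lengths {8, 12, 15, 18, 23, 28, 33, 38} mm,
mirroring contemporary drug-eluting stent offerings (the 2.25 mm floor
matches the usual minimum treatable vessel diameter).

The non-blinded planner simply echoes an externally specified (actual
clinical) stent.

Applying a stent sets the lumen to the larger of its native diameter and
a linear taper between the stent's end diameters; over a 1 mm blend zone
beyond each end, any protrusion above the native lumen decays by a
smoothstep, which joins the native vessel with continuous value and first
derivative and leaves already-normal regions exactly unchanged. A stented
tree remembers its base geometry and plan set and is rebuilt from the
base, which makes re-application idempotent by construction. Mechanical
effects (expansion, recoil, malapposition, plaque composition) are out of
scope.

# The agreement and diagnostic battery

All procedures are implemented in the package, with base R supplying only
distribution functions; independent cross-checks (brute-force slope
enumeration, exact enumeration of sign patterns, base-R test functions)
live in the test suite.

* **Bland–Altman**: mean difference, SD, limits of agreement
  $\bar d \pm 1.96\,s_d$, and a one-sample t-test for zero bias.
* **Passing–Bablok** follows the original 1983 procedure: all pairwise
  slopes excluding exact $-1$, $\pm\infty$ for vertical pairs, offset
  $K$ = number of slopes below $-1$, shifted median slope, CI ranks
  $(N \mp C)/2 + K$ with $C = z\sqrt{n(n-1)(2n+5)/18}$ (lower rank
  floored, upper ceiled), intercept $\mathrm{median}(y - bx)$ with its CI
  at the slope CI endpoints.
* **ICC(1,1)** from the one-way random-effects ANOVA with the exact
  F-based interval; `icc_ci_width()` evaluates the same interval at a
  hypothesized ICC, reproducing the classic precision-based sample-size
  argument (19 subjects rated twice give an 80% CI of width 0.389 at
  ICC 0.600; inflating 19 by 20% dropout requires 24 enrolments).
* **Diagnostics** at the post-PCI threshold (positive ⇔ FFR ≤ 0.90,
  inclusive, identical for both methods): accuracy, sensitivity and
  specificity carry Clopper–Pearson exact intervals while PPV and NPV
  carry standard-logit intervals — the only combination consistent with
  published clinical FFR validation tables, where specificity and PPV can
  share the point estimate (e.g. 31/37) yet print different intervals.
  Cohen's kappa uses the large-sample standard error and the conventional
  qualitative bands (0.40/0.60/0.80). McNemar's test is the exact doubled
  binomial tail on the discordant counts.
* **`reconstruct_confusion()`** inverts printed percentages back to the
  unique integer 2×2 table by exhaustive search (with optional PPV/NPV
  cross-checks), erroring on ambiguity — the bridge between published
  rounded tables and exact recomputation.
* Spearman (midranks, t-approximation), RMSE, and Wilcoxon signed-rank /
  rank-sum tests (exact for small tie-free samples via the base-R
  distribution functions, tie-corrected normal approximation with
  continuity correction otherwise). Paired medians are compared with the
  signed-rank form.

Display rounding is half-up (1 decimal for percentages, 2 for kappa and
FFR, 3 for ICC and widths), matching clinical-table conventions;
`round_half_up()` is exported because base `round()` rounds half to even.

# The synthetic cohort generator

The generator defines the study conditions the pipeline is exercised
under; it emulates the *structure* of a 78-vessel FFR-guided PCI cohort,
not any patient's data. Per vessel:

* label drawn with probabilities 58/78 (LAD), 7/78 (LCX), 13/78 (RCA);
  proximal diameter ≈ 3.5 mm (LAD/RCA) or 3.0 mm (LCX) with 0.15 mm
  jitter, exponential taper to 68–78% of the proximal diameter over a
  95–115 mm main vessel, with the taper capped so the stentable region
  stays at or above 2.25 mm (the usual minimum-vessel exclusion);
* two side branches (50–62% of the local main diameter) at ~30 and
  ~55 mm, which let severe stenoses shed flow realistically;
* one cosine-shaped narrowing distal to the second branch (two serial
  narrowings with probability 0.10), length lognormal with median 20 mm
  truncated to [5, 50] mm, severity uniform on 30–60 %DS;
* myocardial volume normal (120, 25) mL truncated to [70, 200] mL.

The severity default was calibrated once so that the cohort lands on the
published distribution: with the reduced-order model and rest-calibrated
prescribed inflow, uniform 30–60 %DS places the median invasive pre-PCI
FFR at 0.69–0.72 across seeds (published median 0.69) with post-stent
medians near 0.90–0.91; steeper ranges centre the cohort far lower.

Measurements: the model value *is* the FFR-CT reading; the "invasive"
value is the model truth plus Gaussian noise clipped to (0.05, 1], with
σ = 0.077 pre- and 0.037 post-intervention, sized so the simulated 95%
limits of agreement match published widths (≈ ±0.151 and ±0.072). The
ground truth behind the invasive post-PCI value is the *clinician-stented*
(non-blinded) geometry, so the non-blinded arm is by construction closer
to truth — deliberately reproducing the qualitative finding that actual
stent parameters narrow the agreement limits. Inclusion (invasive pre-PCI
FFR ≤ 0.8) is enforced by rejection sampling, mirroring study screening;
a consequence worth knowing is that screening truncates the pre-PCI noise
distribution, biasing the recovered pre-arm Bland–Altman SD about 10%
low and the mean difference positive — noise-recovery checks therefore
use the screening-free post-PCI arm. The clinician plan perturbation
steps the catalog length up with probability 0.55 (+1 size) / 0.15
(+2 sizes), jitters the center by 1 mm SD, and upsizes the diameter one
step with probability 0.2, calibrated so the median per-vessel
actual:planned length ratio is within 10% of 26.5/23 (with a discrete
catalog, the ratio of cohort *medians* is a step function and cannot
resolve that target, so the per-vessel ratio is the calibrated and tested
quantity). The discovery/validation split is a seeded permutation at an
exact 1:2 ratio.

What passing tests do and do not show: the generator produces smooth,
axisymmetric, branch-sparse vessels with Gaussian measurement error and
no patient-level clustering, calcification artifacts, or segmentation
error. Agreement statistics recovered on it validate the *pipeline
arithmetic and its calibration*, not clinical performance on real CCTA.
Vessels are generated independently (real cohorts can include two vessels
from one patient; with 3/75 such patients the simplification is minor but
real).

# Problem sizes and determinism

The default steady cohort path solves three small Newton systems per
vessel; 78 vessels take about 2 s and the 5000-vessel noise-recovery
suite a few minutes on one core. The pulsatile solver is reserved for
waveform-level questions; cycle means under the constant waveform equal
the steady solution, so the cohort pipeline uses the steady limit. Every
random quantity flows from the single cohort seed, so `run_study()` is
bit-reproducible, the emitted CSV (17 significant digits) re-analyzes to
the identical report, and tree JSON round-trips exactly.

# Known limitations

* The quadratic loss correlation is an empirical fit; very severe
  (> 85 %DS) or very short/abrupt stenoses push outside its comfortable
  range, and with prescribed inflow the model overestimates the drop
  across near-occlusive lesions rather than letting total flow fall.
* No vessel compliance other than the outlet capacitors, no inertance by
  default, rigid walls, Newtonian rheology — standard reduced-order
  simplifications.
* The aortic waveform shape and the Windkessel constants are declared
  defaults, not fitted quantities; FFR's cycle-mean character makes it
  first-order insensitive to them.
* Lesion detection assumes an approximately linear healthy taper per
  segment; exotic profiles (e.g. aneurysmal dilations) would distort the
  envelope fit.
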