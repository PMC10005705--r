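---
title: "Models and methods behind osteomech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind osteomech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteomech)
library(dplyr)
```

osteomech analyzes the four kinds of measurement that a rodent bone study
produces — three-point-bending load-displacement curves, sinusoidal
dynamic-mechanical (DMA) traces, calibrated micro-CT volumes, and
longitudinal cohort tables — and pairs every analysis stage with a
synthetic-data generator that produces the same measurement with known
ground truth. This vignette explains the models, the parameters that
matter, and the design decisions that were genuinely open.

## Three-point bending

A tibial midshaft on supports a span $L$ apart, loaded centrally with force
$F$, is idealized as a hollow circular beam with outer radius $c_o$ and
inner radius $c_i$. The section properties are

$$I = \frac{\pi}{4}\left(c_o^4 - c_i^4\right), \qquad
  A = \pi\left(c_o^2 - c_i^2\right),$$

the outer-fibre stress is $\sigma = F L c_o / (4I)$, and the elastic
modulus follows from the load-displacement slope $S = F/d$ as
$E = S L^3 / (48 I)$. With loads in N and lengths in mm, stresses come out
in MPa directly and $E$ is reported in GPa. A well-known transcription
hazard in this area is that the annulus *area* is sometimes printed with
fourth powers (duplicating the moment formula); osteomech implements the
dimensionally correct $\pi(c_o^2-c_i^2)$, which also reproduces the
reference areas exactly (0.84 mm² for a 1.37/0.90 mm diameter pair).

Landmarks on the curve:

* **Elastic slope.** Least squares over the 20–80 % segment of the rise to
  half-maximum load (configurable). This window excludes both toe-in at
  contact and post-yield plasticity; the fit $R^2$ is reported so poor
  windows are visible.
* **Yield** by the offset method: the first intersection of the curve with
  a line of slope $S$ shifted 0.015 mm along the displacement axis,
  linearly interpolated between samples. Note a geometric consequence used
  throughout the tests: on a bilinear curve with hardening slope $h$, the
  offset intersection sits $S\,\delta/(S-h)$ past the kink (with offset
  $\delta$), so "yield" is recovered relative to that construction, not to
  the kink itself.
* **Ultimate** at the global load maximum, **fracture** at the last sample
  before the terminal drop below 10 % of ultimate (configurable;
  monotone curves are flagged), and **post-yield displacement** (PYD) as
  the displacement from yield to fracture — a ductility measure.
* **Pop-ins**: load drops of more than 5 % of the current load between
  successive samples, excluding the terminal fracture drop. These mark
  microcrack progression events.

When group body masses diverge, all four strength/stiffness outputs are
divided by the body-weight-to-tibial-length ratio (g/mm). The factor is
recorded and the operation is exactly invertible; raw values are always
recoverable. Whether such normalization should divide or regress out body
size is not settled; division is implemented because it is the common
convention, and the recorded factor makes sensitivity analysis trivial.

The generator produces a piecewise-linear elastoplastic curve: slope
$S = 48 E I/L^3$ to the planted yield load, a hardening branch after it,
instantaneous vertical pop-in drops (the simplest shape consistent with
observed curves), and a terminal drop to zero one sample past the planted
fracture displacement. Noise is additive Gaussian on the load channel only,
so noise-free curves satisfy the closed-form oracles exactly.

## Dynamic mechanical analysis

The generative model is the standard linear solid (SLS): a spring $E_{eq}$
in parallel with a Maxwell arm, giving

$$E'(\omega) = E_{eq} + (E_{inst}-E_{eq})\frac{(\omega\tau)^2}{1+(\omega\tau)^2},
\qquad
E''(\omega) = (E_{inst}-E_{eq})\frac{\omega\tau}{1+(\omega\tau)^2},$$

with $E''$ peaking at $\omega\tau = 1$. Under stress
$\sigma(t) = \sigma_m + \sigma_a\sin(2\pi f t)$ the steady-state strain is
$\sigma_m/E_{eq} + (\sigma_a/|E^*|)\sin(2\pi f t - \delta)$ with
$\delta = \arctan(E''/E')$. One relaxation time is a deliberate
simplification — real cortical bone shows a broad relaxation spectrum — but
it is the simplest model with finite moduli at both frequency extremes, and
it makes every analysis output checkable against a closed form.

The default protocol sweeps 0.05, 0.1, 1 and 10 Hz with stress amplitude
0.25 MPa. Instrument protocols sometimes quote amplitude and peak values
that are mutually inconsistent; osteomech takes the amplitude as
authoritative and centres the wave so the stated peak-to-peak span (0.5
MPa) is honored, with both mean and amplitude configurable.

Analysis estimates amplitude and phase of each channel by linear least
squares at the *known* drive frequency ($a + b\sin + c\cos$), never by FFT
peak-picking — at 0.05 Hz a practical record holds too few cycles for
stable spectral estimation. The first cycle is discarded as transient. The
phase lag is wrapped to $[0, \pi/2]$ since physical dissipation cannot be
negative, and the moduli follow as $E' = |E^*|\cos\delta$,
$E'' = |E^*|\sin\delta$ with $|E^*| = \sigma_a/\epsilon_a$. Two identities
anchor the tests: $\tan\delta \equiv E''/E'$ by construction, and the
hysteresis-loop energy per cycle equals $\pi E'' \epsilon_a^2$.

`fit_sls_spectrum()` inverts a measured four-point spectrum back to
$(E_{inst}, E_{eq}, \tau)$ by Nelder-Mead on a log-parameterization that
enforces $E_{inst} > E_{eq} > 0$, $\tau > 0$; initial values come from the
spectrum's endpoints and the loss peak.

## Micro-CT morphometry

Scanner attenuation is mapped to hydroxyapatite density by an ordinary
least-squares line through (mean attenuation, known density) across
calibration inserts of 0, 50, 200, 800 and 1200 mgHA/cm³; in the
noise-free case this inverts the affine scanner map exactly. Negative
mapped densities are clipped to zero with a count. Segmentation is a plain
threshold, default 400 mgHA/cm³ (protocols rarely publish theirs; the value
is configurable and the masked fraction is reported).

The volume of interest spans 80 % of the axial length below a
user-supplied growth-plate plane (automatic growth-plate detection is out
of scope) and is divided into 7 equal axial blocks, proximal to distal.
Each transverse plane is split about the per-slice section centroid into
anterior/posterior halves along the AP axis and medial/lateral halves
along the ML axis; each pair of halves partitions the block exactly, which
the tests verify to 1e-9. A quadrant mode is provided as well, since
published sector diagrams are usually too schematic to fix one convention.
Per region: BV/TV = bone voxels / VOI voxels, BMC = Σ density × voxel
volume (g), BMD = BMC / bone volume (g/cm³). Blocks with no bone report
missing values, not zeros, to avoid biasing group means.

Diameters are estimated per cross-section as equivalent-circle diameters
of the hole-filled (periosteal) area and of the cavity area
(EBImage's hole filling); sections without a cavity report an inner
diameter of zero and are flagged. For specimens without imaging, the inner
radius is estimated as the caliper outer radius times the *mean of* the
imaged inner-to-outer diameter ratios — mean of ratios, not ratio of
means, which differ on tapering bones.

The phantom generator rasterizes a tube with axially varying radii and
density by voxel-center membership at a default 10 µm spacing — coarser
than the 7–9 µm of real scans, chosen so a full phantom stays at desk
scale; spacing is a parameter and the ground truth converges as it
shrinks. The transverse grid extent is fixed in millimetres (snapped to
0.04 mm) so BV/TV denominators are comparable across spacings. Calibration
inserts are separate labeled sub-volumes rather than objects embedded in
the bone tube, mirroring scanner practice and keeping the analytic ground
truth simple. The analytic truth uses exact annulus areas per slice with a
midpoint rule along the axis.

## Exact nonparametric statistics

Small-group comparisons use the Mann-Whitney U test with the null
distribution enumerated over all $\binom{n_1+n_2}{n_1}$ labelings of the
*observed* pooled values — which handles ties correctly, since mid-ranks
are recomputed on the observed multiset. The two-sided p doubles the
smaller tail, capped at 1, matching the convention of common statistical
software: at $n_1 = n_2 = 6$ the attainable floor is $2/924 \approx
0.0022$, and the p-value ladder for $U = 0, 1, 2$ is 0.002, 0.004, 0.009
at three decimals. Above 14 total observations the test falls back to a
normal approximation with continuity and tie correction (the enumeration
budget is configurable). The omnibus across three groups is the
tie-corrected Kruskal-Wallis H (via `stats::kruskal.test`) with exact
post hoc pairs; post hoc p-values are unadjusted by default — the
convention the reference tables follow — with `p.adjust` methods available.

A consequence of discreteness worth remembering: at $n = 6+6$ the largest
achievable level not exceeding 0.05 is $38/924 \approx 0.041$, and the
tests verify the simulated null rejection rate against that attainable
level, not against nominal 0.05.

## Cohort generator

Each animal's weekly body weight, lean and fat mass interpolate linearly
between group endpoint means with additive Gaussian weekly noise (default
SD 1 g, the scale implied by reported group standard errors at $n = 6$);
lean + fat is capped at total weight per animal-week. The default endpoint
means plant a sham-control / OVX / OVX + estradiol design: body weight
18.92→28.05, 25.41→45.09 and 20.96→27.32 g. Week-1 lean/fat endpoints are
not reported in the reference tables; defaults (14.5/3.5, 16.0/8.0,
15.0/4.5 g) were chosen once as physiologically plausible for 10-week-old
female C57BL/6J mice and kept. Group differences are planted
phenomenologically; no estrogen physiology or diet-induced metabolism is
modeled, so passing tests demonstrate pipeline correctness, not biology.

The diet helper computes mass-weighted omega-3/6/9 percentages of a fat
blend, carrying datasheet composition ranges (e.g. lard at 44–47 % ω-9)
through as honest intervals rather than a single point.

## Pipeline and reproducibility

`run_study()` fans a single master seed out to per-stage child seeds by a
fixed counter scheme, so adding a stage never perturbs earlier streams;
reports are byte-identical under a fixed seed and carry a provenance block
(seed, config hash, package and R versions). All artifacts are plain text
(CSV/JSON); figures are built from report tables only and are never inputs
to any computation.

Default problem sizes are chosen for a desk machine: 6 animals × 3 groups
× 12 weeks, bending curves sampled at 2 µm steps, DMA records of 8 cycles
× 64 samples, and pipeline phantoms at 20 µm spacing about 1 mm long
(finer 10 µm phantoms are used where a test checks voxel-integration
convergence). These sizes keep every closed-form check well inside its
tolerance while a full study runs in seconds.

## Known limitations

* The SLS with one relaxation time cannot reproduce the slowly rising
  storage modulus of real bone across four decades; recovering *its own*
  parameters is the achievable and tested claim.
* The bending generator's pop-ins are instantaneous and its plastic branch
  is linear; real curves show rounded yielding and serrated flow.
* The phantom models no beam hardening, partial-volume blur, or
  reconstruction artifacts — only an affine map plus Gaussian noise — so
  calibration results on real scans will be worse than the exact inversion
  seen here.
* Sector definitions follow one explicit convention (centroid-anchored
  half-planes); other software may anchor sectors differently, so absolute
  sector values are comparable only within a convention.

## A short worked example

```{r example}
geom <- tube_geometry(outer_radius = 0.685, inner_radius = 0.45, span = 6)
truth <- bending_ground_truth(
  E_true = 4.63, geometry = geom, yield_load = 14, hardening_slope = 6,
  fracture_displacement = 14 / (48 * 4630 * moment_of_inertia(geom) / 216) + 0.47,
  popin_events = data.frame(displacement_mm = 0.3, drop_fraction = 0.1)
)
curve <- generate_bending_curve(truth)
res <- analyze_bending(curve, geom)
tidy(res)
```

The recovered modulus equals the 4.63 GPa plant to within 0.1 %, the
moment of inertia is the closed-form 0.14 mm⁴, and the planted pop-in is
detected at 0.3 mm.
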