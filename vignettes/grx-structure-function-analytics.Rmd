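---
title: "Models and methods behind grxfun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind grxfun}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grxfun)
```

`grxfun` implements the quantitative machinery of glutaredoxin (Grx)
structure–function analysis: steady-state ping-pong kinetics with Dalziel
inference, the thiol-pKa alkylation-protection assay, ratiometric roGFP2
plate analysis, and binding-event analytics for diffusing glutathione
anions. This vignette explains the underlying models, their assumptions,
the tunable parameters, what the synthetic-data generators do and do not
emulate, and the numerical choices made where the design was open.

## The ping-pong catalytic cycle and the Dalziel description

Class I Grx catalysis proceeds through two half-reactions with a covalent
enzyme–SSG intermediate: glutathionylation of the active-site cysteine by
the GSSR substrate (with release of RS⁻), then reduction of the
intermediate by GSH (with release of GSSG). We model the cycle with six
microscopic constants — association/dissociation pairs (`k1`, `k−1`) and
(`k4`, `k−4`) around the two Michaelis complexes and irreversible chemical
steps `k2` (oxidative) and `k5` (reductive); the `k2`/`k5` names are this
package's convention for the chemical steps. At steady state the velocity
takes the Dalziel form

$$\frac{e_0}{v} = \Phi_0 + \frac{\Phi_1}{[\mathrm{GSSR}]} +
\frac{\Phi_2}{[\mathrm{GSH}]},$$

with

$$\Phi_1 = \frac{k_{-1}+k_2}{k_1 k_2},\qquad
  \Phi_2 = \frac{k_{-4}+k_5}{k_4 k_5},\qquad
  \Phi_0 = \frac{1}{k_2}+\frac{1}{k_5}.$$

`phi_from_microscopic()` implements this mapping; it is validated in the
test suite against an independent numerical steady state of the full
four-species mass-action scheme (`steady_state_rate_ode()`, a clamped-
substrate linear solve) to below 1e−6 relative error on 100 random rate
sets. Two consequences the tests also assert: the reciprocal coefficients
are bounded by the association steps (`1/Φ1 ≤ k1`, `1/Φ2 ≤ k4`), and the
apparent Michaelis constants mix binding with chemistry, so they are not
substrate affinities.

Because `Km_app` conflates rate constants, variant effects are interpreted
on the reciprocal Dalziel coefficients: `1/Φ1` and `1/Φ2` are the apparent
second-order rate constants of the oxidative and reductive half-reactions,
and `1/Φ0` is the true turnover number.

### The coupled photometric assay simulator

`simulate_assay()` integrates substrate depletion under the Dalziel rate
law and reports A340 via Beer–Lambert (ε = 6220 M⁻¹cm⁻¹, 1 cm path —
textbook constants, configurable). Default conditions: 0.1 mM NADPH,
coupling glutathione reductase (GR) at 1 U/mL, 25 °C, a flat 30 s
pre-start baseline. The GR coupling is treated as **instantaneous** by
default: every GSSG formed is immediately reduced back to 2 GSH at the
cost of one NADPH. Bookkeeping per turnover is then

* GSSR: −1 (oxidative half-reaction),
* GSH: −1 (reductive half-reaction) + 2 (GR regeneration) = net +1,
* NADPH: −1, A340 falls accordingly,

so the glutathione moiety pool `[GSH] + [GSSR] + 2[GSSG]` is exactly
conserved — an invariant the tests assert to 1e−9. Explicit GR kinetics
would add unidentifiable parameters at coupling excess; a finite-GR mode
(Michaelis–Menten in GSSG, 1 U/mL ≙ Vmax of 1 µmol min⁻¹ mL⁻¹, Km
defaulting to 60 µM) is provided for robustness checks only. Integration
uses `deSolve::lsoda` at relative tolerance 1e−8 on a fixed output grid,
so curves are reproducible; concentrations are clamped at zero and NADPH
exhaustion sets a flag rather than producing negative values.

`initial_rate()` mirrors spectrophotometer practice: a least-squares slope
over a post-baseline window (default 30 s; use a shorter window when
substrate depletion is fast relative to the window — the round-trip test
uses 10 s and recovers the rate law within 1 %).

### Dalziel fitting: one-stage primary route, two-stage as cross-check

`fit_dalziel()` regresses `e0/v` on `(1/[GSSR], 1/[GSH])`. In reciprocal
space the error of `1/v` scales like `1/v²`, so the primary route weights
observations by `v²`; the classical two-stage route (primary
Lineweaver–Burk fits per fixed GSSR level, then a secondary plot of
intercepts against `1/[GSSR]`) is computed alongside, and the two agree
identically on noiseless data (asserted to 1e−8). Parameter uncertainties
come from the linear-model covariance; no bootstrap by default. Rates at
or below the blank are excluded (they are clipped and flagged by
`blank_correct()`), replicates are averaged before fitting by default, and
a vanishing fitted coefficient (e.g. co-substrate-independent rates) is
floored at machine epsilon so the reported reciprocal reads as an upper
bound rather than an infinity. Designs with fewer than two distinct levels
per substrate are rejected as rank-deficient.

The canonical grid — GSH varied 50 µM–1.5 mM (8 levels) at fixed GSSCys
25/50/100/150 µM — is the generator default. On noiseless ping-pong data
the layers are mutually consistent (and tested so): `kcat_app` at fixed
`[GSSR]` equals `1/(Φ0 + Φ1/[GSSR])`, the catalytic efficiency for the
varied substrate is independent of the fixed co-substrate level, and
Lineweaver–Burk lines at different fixed levels are parallel — the
ping-pong signature.

## The alkylation-protection pKa assay

The thiol pKa is read out by incubating the enzyme with 150 µM
iodoacetamide for 180 s at 23 °C across pH 3.5–8.5 and measuring residual
activity relative to mock controls. The package fits the four-parameter
Hill sigmoid

$$y(\mathrm{pH}) = \mathrm{bottom} +
\frac{\mathrm{top}-\mathrm{bottom}}{1 + 10^{\,h\,(\mathrm{pH} - \mathrm{pH}_{1/2})}}$$

and reports the midpoint as the pKa — the assay's conventional analysis.
A mechanistic generator mode is also provided (pseudo-first-order
alkylation survival `100·exp(−k_alk·[IAM]·f_thiolate(pH)·t)` on the
Henderson–Hasselbalch thiolate fraction, with an optional low-pH stability
factor > 1 reproducing residual activities slightly above 100 %, as mock
controls degrade faster at acidic pH). The inflection of that survival
curve sits systematically **below** the true pKa (for the default dose
`k_alk·[IAM]·t ≈ 4`, about 0.7 pH units); the package documents and tests
this offset against a dense-grid oracle but deliberately does not correct
for it, because the Hill-midpoint convention is the assay's stated
procedure. The pH grid default is 0.5-unit steps (11 points); the
measured grids' exact spacing is a figure-level detail, and recovery is
insensitive to it (midpoint bias < 0.05 pH units under 3 % noise over 500
simulated profiles).

Fitting uses `minpack.lm::nlsLM` with multi-start initialisation: midpoint
seeded at the half-range crossing, five jittered restarts under a fixed
internal seed, best RSS wins. Group comparison is one-way ANOVA followed
by pairwise t statistics on the pooled error term against a reference
group, Holm–Šidák-adjusted (`1 − (1 − p_i)^{m−i+1}` step-down, monotone by
running maximum) with the conventional star labels.

## roGFP2 ratiometric analysis

The degree of probe oxidation is computed from two-channel intensities
calibrated by fully reduced (100 mM DTT) and fully oxidized (20 mM
diamide) control wells; control wells are averaged per plate. The
calibration identities — OxD of the reduced control is 0, of the oxidized
control 1, and OxD of a convex spectral mixture with disulfide fraction
`f` is exactly `f` — hold to machine precision and are asserted, as is
invariance under a common intensity rescaling (gain independence).

Pipeline: per-well OxD traces, pointwise subtraction of the untreated
(0 µM) well of the same construct (linear interpolation if grids differ;
negative values allowed), trapezoidal integration over the first 48 s with
the final partial interval closed by interpolation to exactly t = 48 s,
then per-dose replicate mean ± sd. OxD values outside [0, 1] (noisy
calibration) are flagged but not clipped by default, because clipping
biases subtraction-based statistics; clipping is opt-in. The generator
samples at 12 s cycles (48 s = 4 intervals) — the instrument cadence is
configurable and the quadrature is the plain trapezoid on the native grid.

The generator's in-cell response is deliberately phenomenological: a
dose-dependent oxidant pulse drives `dOxD/dt = k·drive(dose, t)·(1 − OxD)`
with `drive = dose·exp(−t/τ)`, τ = 30 s and `k = 60` per unit drive scaled
by the variant's activity factor — chosen so the 0.02–1 mM dose series
spans from a small response to near saturation within the 48 s window. It
emulates concentration-dependent, activity-dependent probe oxidation on
top of a construct steady state (~60 % oxidized for the active fusion,
70–80 % for the inactive/unfused controls, packaged as the midpoint); it
does **not** model the intracellular peroxide-to-GSSG relay,
photobleaching, or instrument gain drift, so passing tests show pipeline
correctness, not biological transferability. A DTT-pretreatment/washout
run is represented only by a different initial OxD (`oxd_start`).

## GS⁻ binding-event analytics

A binding event is a GS⁻ sulfur within 5.5 Å of the centre of mass of the
two disulfide sulfur atoms; with equal masses that centre is the midpoint,
and the boundary is inclusive (the criterion's behaviour exactly at the
cutoff is not otherwise specified). Binding frequency is the fraction of
frames with at least one event, per replication, summarised as mean ± SEM
over replications and compared between variants with a two-tailed Welch
test. Trajectories are assumed unwrapped; no periodic-boundary handling is
applied.

Geometry: the S–S–S angle is defined over the three sulfurs with the
vertex at the active-site cysteine sulfur by default; because "the angle
created by the three sulfur atoms" admits either convention, the vertex is
configurable (`angle_vertex = "gs"` places it at the incoming sulfur).
Distance–angle histograms use 0.1 Å × 2° bins by default. Occupancy
density grids bin bound-state sulfur positions (pooled across
replications) on a caller-fixed spacing, and `density_components()`
flood-fills above a common iso-threshold so variants are comparable at the
same level. Approach paths take the 25 frames (500 ps at 20 ps saves)
preceding an event and smooth them with a width-5 centred moving average;
both are configurable, with shrinking windows at the edges.

Pose clustering computes pairwise superposition RMSD (Kabsch: centring,
SVD, reflection correction — validated against a brute-force rotation
search on small instances) over a minimal atom subset (the two disulfide
sulfurs plus the bound GS⁻ sulfur via `gs_poses()`, or any subset the
caller supplies), then average-linkage agglomerative clustering cut at a
fixed cluster count (default k = 2, reflecting the most- and
second-most-populated-cluster reporting convention); representatives
minimise the mean within-cluster RMSD and clusters are ordered by
population. Identical poses collapse to a single cluster regardless of k.

### The trajectory generator

`generate_gs_trajectory()` emulates the *saved-frame statistics* of
unbiased ligand-diffusion simulations, not their dynamics: 10 GS⁻ sulfurs
in a 40 Å box around a fixed disulfide pair, where each molecule in each
saved frame is independently placed in the binding shell (2–5.5 Å,
uniform in volume) with probability `q` or uniformly outside it. `q` is
tuned so the frame-level bound probability is exactly
`p_baseline × propensity factor`; the wild-type baseline `p_baseline =
0.2` is a realistic occupancy for a charged ligand at 100 mM around a
small binding patch, and the packaged propensity factors carry the
variant-to-wild-type ratios. Successive frames are resampled
independently — the 20 ps save interval is treated as longer than the
positional correlation time. This memoryless design trades physical
realism (no diffusive continuity between frames, no electrostatics) for
exact binomial statistics: bound-frame counts are binomial by
construction, so parameter-recovery tolerances of three Monte-Carlo
standard errors are principled rather than empirical. Approach paths
extracted from this generator are therefore noise polylines; the path
operations are validated on constructed deterministic fixtures instead.
Defaults emulate 4 replications; the full emulated scale is 25 000 frames
per replication (500 ns at 20 ps saves), with 5 000 as a desk default.

## The packaged variant table

`load_variant()` exposes, per variant, kinetic fold factors applied to a
wild-type baseline, the thiol pKa, roGFP2 steady-state/responsiveness
parameters, and the relative binding propensity, each with a provenance
note. Two honesty rules govern the table:

* Quantities without a printed absolute anchor — the wild-type ScGrx7
  Φ baseline (packaged as 1/Φ1 = 2×10⁵ M⁻¹s⁻¹, 1/Φ2 = 1×10⁵ M⁻¹s⁻¹,
  Φ0 = 0.02 s, magnitudes plausible for an efficient class I Grx), the
  HsGrx5-loop Φ0, and a few unquantified variant effects — are
  placeholders and are flagged in `placeholder_fields`. All headline
  recovery quantities are ratios or the absolutes that *are* anchored
  (HsGrx5-loop 1/Φ1 ≈ 2×10³, 1/Φ2 ≈ 5×10³ M⁻¹s⁻¹).
* Reported ranges ("18–23 %", "70–80 %") are packaged as midpoints with
  the range retained in the provenance note.

Every generator records its seed in the output and is byte-identical on
rerun with the same seed.

## Problem sizes and limitations

The analysis drivers and tests run at desk scale: 8 × 4 rate grids, 11-
point pH profiles (500 noisy replicates in the bias study), 12 s × 9-point
plate traces, and trajectories of 4 × 10 000–25 000 frames; these sizes
were chosen so each stage's statistical claims (binomial tolerances,
median-error bounds) are already well resolved. Known limitations: the
kinetic layer has no transient-state or reverse-reaction support and
treats HEDS only as an alternative substrate label in the same Dalziel
framework; the mechanistic pKa mode's inflection offset is documented,
not corrected; the roGFP2 and trajectory generators are phenomenological
emulators as described above, so agreement with them demonstrates
pipeline and inference correctness, not force-field-level realism.
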