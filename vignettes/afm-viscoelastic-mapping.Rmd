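---
title: "Viscoelastic force-curve analysis and nanomechanical mapping with afmcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Viscoelastic force-curve analysis and nanomechanical mapping with afmcell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmcell)
```

# Scope

`afmcell` analyses force-volume AFM data from living, adherent cells: grids
of force-distance (F-Z) curves acquired with a spherical-tipped cantilever in
fast force volume mode. From each curve it extracts an apparent Young's
modulus (Hertz model, approach segment) and, from the full approach-retract
record, the parameters of a power-law-rheology (PLR) viscoelastic model via
Ting's hereditary-integral formulation. At the map level it reconstructs
topography from contact points, corrects global tilt, restricts mechanical
aggregation to the central part of each cell, and summarises per-cell records
into per-condition cohort statistics (means, SDs, fold changes, delegated
significance tests). Companion plate-reader and flow-cytometry summaries
(kinetics AUC, DNA normalisation, per-experiment z-standardisation,
phagocytic affinity/capacity) cover the non-AFM computations that typically
accompany such studies of macrophage activation.

Because real force-volume data of this kind are rarely deposited, the package
ships a synthetic-data module that generates every input with known ground
truth, so each analysis stage is verifiable by parameter recovery.

# Contact-mechanics and rheology models

## Hertz force with bottom-effect correction

For a spherical (paraboloid) indenter of radius $R$ on an incompressible
sample ($\nu = 0.5$), the quasi-static contact force at indentation depth
$\delta$ is

$$F(\delta) = \frac{4\sqrt{R}}{3(1-\nu^2)}\, f_{BEC}(\delta)\, E\,
\delta^{3/2},$$

where $E$ is the (apparent) Young's modulus and $f_{BEC}$ a multiplicative
bottom-effect correction for a thin sample of thickness $h$ bonded to a rigid
substrate. The correction implemented is the bonded spherical-indenter
polynomial series of the Dimitriadis type,

$$f_{BEC} = 1 + 1.133\,\chi + 1.497\,\chi^2 + 1.469\,\chi^3 + 0.755\,\chi^4,
\qquad \chi = \frac{\sqrt{R\delta}}{h},$$

with the incompressible bonded-sample coefficients. `bec_model("none")`
selects the semi-infinite case ($f_{BEC}\equiv 1$). The factor is $\ge 1$,
decreases with $h$ and tends to 1 as $h \to \infty$; indentation at or beyond
the sample thickness is a domain error. The truncated series underestimates
the divergence as $\delta \to h$, which is one reason the central-part filter
(below) discards thin cell periphery pixels.

## Power-law rheology

The relaxation modulus is

$$E(t) = E_1\, t^{-\alpha} + \eta\, \delta_D(t),$$

with $E_1$ the modulus scale at $t = 1$ s, $\alpha \in [0, 1]$ the power-law
exponent (0 = solid-like, 1 = fluid-like), $\eta$ a Newtonian viscosity and
$\delta_D$ the Dirac delta. Pointwise evaluation
(`relaxation_modulus()`) returns $E_1 t^{-\alpha}$; the Dirac term only has
meaning inside the convolution and is handled by the Ting solver, where it
contributes $\eta\, \mathrm{d}(\delta^{3/2})/\mathrm{d}t$ additively while
the contact is loading.

## Ting's model

For an arbitrary indentation history $\delta(t)$ with time origin at contact,
the force is

$$F(t) = \frac{4\sqrt{R}}{3(1-\nu^2)} \int_0^{t_1(t)} E(t-\xi)\,
\frac{\mathrm{d}\big[f_{BEC}(\delta)\,\delta^{3/2}\big]}{\mathrm{d}\xi}\,
\mathrm{d}\xi,$$

with $t_1(t) = t$ while the indentation is non-decreasing (up to the maximum
at $t_m$), and for $t > t_m$ the auxiliary time $t_1 \in [0, t_m]$ solving

$$\int_{t_1}^{t} E(t-\xi)\, \frac{\mathrm{d}\delta}{\mathrm{d}\xi}\,
\mathrm{d}\xi = 0.$$

Two implementation notes. First, the bottom-effect correction is placed
*inside* the time derivative of the corrected contact term
$f_{BEC}(\delta)\delta^{3/2}$; with the correction outside the derivative the
$\alpha = 0$, $\eta = 0$ case would not reduce to the corrected Hertz force,
and elastic-limit equivalence is both physically required and part of this
package's validation suite. Second, $t_m$ is the time of maximum
*indentation*, not of the piezo reversal: immediately after the ramp turns
around, stress relaxation can outrun the piezo so that the indentation keeps
growing briefly; the solver and the simulator both track the running
indentation maximum.

# Numerical scheme

**Quadrature.** Histories are sampled; the solver treats
$u = f_{BEC}(\delta)\,\delta^{3/2}$ as piecewise linear and integrates
$E_1 (t-\xi)^{-\alpha}$ against it segment by segment in closed form
(product integration). This is exact for piecewise-linear histories and
absorbs the weak endpoint singularity $(t-\xi)^{-\alpha}$ analytically, so
no adaptive quadrature is needed. On a uniform time grid (the case for every
sampled AFM record) the per-segment kernel integrals reduce to differences
of a precomputed power table, giving $O(n^2)$ cost for a full curve with no
transcendental calls in the inner loop. Halving the time step changes
predictions by well under 0.1% (tested).

**The $t_1$ equation.** $G(s) = \int_s^t E(t-\xi)\,\delta'(\xi)\,
\mathrm{d}\xi$ is non-increasing in $s$ on $[0, t_m]$ because $\delta' \ge 0$
there. On the uniform grid, prefix sums give $G$ at every node, and inside
the bracketing segment the root is available in closed form (the segment
contribution is $w[(t-s)^p - (t-b)^p]$ with $p = 1-\alpha$). $t_1$ is
non-increasing in $t$, which warm-starts the node search. When $G(0) \le 0$
the contact has fully unloaded: $t_1 = 0$, the force is zero and stays zero.
$\alpha = 1$ makes the hereditary integral divergent; evaluation requires
$\alpha < 1$ and fits bound $\alpha$ at 0.95.

**Reference evaluator.** `ting_force_reference()` implements the same
integrals independently by the midpoint rule on a uniformly refined grid with
its own bisection for $t_1$. It converges like $O(m^{-(1-\alpha)})$ near the
singular endpoint, so it is slow, but it shares no code with the production
path and serves as the oracle in the test suite (sup-norm agreement well
below 0.5%).

# Per-curve processing

**Calibration.** Raw photodiode curves convert via
$F = k \cdot s \cdot d$ (spring constant N/m, sensitivity nm/V, deflection
V); N/m times nm equals nN, so the package's unit convention (nm, nN, Pa, s)
needs no other constants. Calibration is idempotent.

**Contact point.** The detector scans candidate contact samples; each
candidate splits the approach into a linear baseline (offset + drift) and a
$3/2$-power contact segment, and the candidate minimising the total squared
residual wins. The scan is coarse-to-fine, and the candidate window reaches
several hundred samples before the first sustained noise-threshold crossing
because soft $\delta^{3/2}$ onsets emerge from the noise floor only well past
the true contact. A refinement pass then re-fits using only the low-force
contact region (below 15% of the peak), where the $3/2$ shape holds for any
rheology; without it, viscoelastic stiffening over the approach biases the
contact estimate by tens of nm. Very steep (substrate-like) contacts with
almost no post-contact samples are handled by the stiff-contact identity
$z_0 = z - F/k$ at the turnaround, which is exact for a rigid surface.
Curves whose baseline-corrected force never exceeds $3\times$ the noise RMS
raise a `noContactError`.

On noise-free elastic phantoms the detected contact is within two z-samples
of the truth at any sampling rate. On viscoelastic phantoms a few-nm
systematic shift remains (short-time stiffening makes the onset look
sharper); both fitters therefore refine the contact position internally.

**Hertz fitting.** Given a contact estimate, the apparent modulus is the
linear least-squares coefficient of $C f_{BEC} \delta^{3/2}$ over an
indentation window (10-90% of the maximum by default). The contact position
is refined by a coarse grid plus local 1-D optimisation of the residual,
robust to initial errors of many samples.

**Ting fitting.** With $\theta = \eta / E_1$ the $t_1$ equation depends only
on $(\alpha, \theta)$, so the model is exactly linear in $E_1$; the fit
profiles $E_1$ out and runs bounded Levenberg-Marquardt over
$(\alpha, \theta, \Delta z_0)$ only, with $E_1$ re-solved per evaluation.
This removes the strong $E_1$-$\alpha$ ridge that stalls a naive 4-parameter
fit. Two further numerical choices matter in practice:

* *Finite-difference step.* The LM Jacobian uses a relative step of
  $10^{-3}$ (`epsfcn = 1e-6`); the library default (machine-epsilon-scaled)
  steps are too small for a model whose inner loop is itself iterative, and
  silently freeze parameters.
* *Errors-in-variables smoothing.* The measured deflection enters the model
  twice: as data and, through $\delta = (z - z_0) - d$, as the regressor.
  Regressor noise is differentiated by the hereditary integral and biases
  $\alpha$ low (and hence $E_1$, which extrapolates to 1 s, badly). A ~30 us
  moving average on the deflection channel used for the history (residuals
  are still taken against the raw force) removes the bias at 20 pN noise
  levels. Long in-contact segments are block-averaged to at most 600 nodes
  to bound the $O(n^2)$ cost.

The default viscoelastic fit window keeps the force peak and turnaround
(10-100% of maximum indentation): the relaxation signature is strongest
there, and excluding it measurably degrades $\alpha$ recovery. The Hertz fit
keeps the classical 10-90% window. Fits report convergence flags rather than
raising errors; missing retract segments raise `missingRetractError`.

Under the packaged acquisition defaults (3 um ramp at 183 um/s, 1 nN
trigger, 0.1 N/m cantilever, 20 pN RMS noise), Monte-Carlo recovery over
$E_1 \in \{1, 3, 10\}$ kPa $\times$ $\alpha \in \{0, 0.1, 0.3\}$ achieves
median $|\hat E_1/E_1 - 1|$ of 0.2-3.5% and median $|\hat\alpha - \alpha|$
of 0.000-0.004 (200 curves per setting; the acceptance suite asserts the
5% / 0.03 envelopes).

# Map-level processing

Topography is the per-pixel contact position relative to a substrate
reference plane, fit over masked substrate pixels or the lowest height
decile; `correct_tilt()` removes the best-fit plane ("if needed": with fewer
than three non-collinear substrate pixels it warns and leaves the map
unchanged). The cell mask, when not supplied, is derived by height
thresholding at max(3 x substrate roughness, 0.15 um).

The **central-part filter** keeps exactly $\lceil n/2 \rceil$ of a cell's
$n$ pixels with the highest local height (ties broken by pixel index). The
discarded periphery is both mechanically atypical (high cortical actin) and
numerically unreliable (thin-sample correction divergence), so per-cell
aggregates - arithmetic means of apparent YM, $E_1$, $\alpha$, $\eta$ - are
computed only over retained, successfully fitted pixels. Cell height is the
apex (maximum tilt-corrected height) by default; a mean-height variant is
available via `height_stat = "mean"`.

`cohort_summary()` reports per-group mean, SD and n, fold changes oriented by
variable (stiffness-type variables as activated/control, height and
$\alpha$ as control/activated so both read as "fold increase"/"fold
decrease"), and delegates significance to `t.test()` and `wilcox.test()`.

# The synthetic-data module

`simulate_curve()` couples the forward Ting model to the cantilever
quasi-statically: at each sample the force balance $k d = F(\delta)$,
$\delta = (z - z_0) - d$, is solved exactly. During loading the force is
affine in $u(\delta)$ given the past history, so the balance is solved by
bisection on $\delta$; a naive fixed-point iteration diverges whenever the
contact stiffness at the sampling timescale approaches $k$ (the
$\Delta t^{-\alpha}$ factor makes this easy to hit at high sampling rates).
During unloading the force is monotone in $\delta$ through $t_1$, and the
balance root is found the same way with prefix-sum accelerated $t_1$
re-solves. The ramp reverses at the trigger force; cantilever dynamics are
neglected (the 183 um/s ramp is quasi-static for these cells). Baseline
offset/tilt and seeded Gaussian force noise are added afterwards; every
generator embeds its ground truth and seed in the returned object.

Thin samples cap the indentation at 80% of the local thickness; beyond the
cap the residual displacement loads the cantilever directly, mimicking the
rigid substrate behind a thin cell edge. Substrate pixels use an exact
rigid-contact generator.

`simulate_cell_map()` builds a spherical-cap phantom (apex height, base
radius) on a rigid substrate; per-pixel thickness follows the cap and drives
the bottom-effect correction, and each pixel's ramp window tracks the local
surface as in closed-loop force-volume acquisition. Maps default to a 10 kHz
sampling rate to bound memory; single-curve work defaults to 300 kHz, where
parameter recovery is limited by noise rather than discretisation.

## Cohort presets

`inst/extdata/cohort_presets.yaml` versions the per-condition distributions,
with each number marked study-derived or assumed:

* Apparent-YM distributions for the M1 pair are lognormals matched to the
  study's printed mean +- SD (2.8 +- 1.09 kPa control, 6.92 +- 2.87 kPa
  PMA-activated). The preset modulus is interpreted as the *apparent*
  Young's modulus - the operational quantity a Hertz fit of these curves
  reports - and converted internally to the PLR scale via
  $E_{app} = E_1 \cdot \tfrac{3}{2} B(\tfrac32, 1-\alpha)\, t_c^{-\alpha}$
  (constant-rate ramp, contact duration $t_c$). Interpreting the printed
  values directly as $E_1$ would distort the apparent-YM fold whenever the
  two conditions differ in $\alpha$, as they do here.
* Absolute cell heights are not printed; the control apex defaults to
  4.0 um and activated apexes are derived from the printed 1.53x (M1) and
  1.69x (M2) height fold decreases. Per-cell apex variability is lognormal
  with log-SD 0.08, a moderate within-condition spread for a selected
  adherent population.
* The power-law-exponent presets (0.25 control to 0.15 activated, SD 0.05)
  encode only the printed *direction* of change; numeric values appear only
  in figures. The M2 modulus pair (2.5 +- 1.0 to 4.5 +- 1.8 kPa) is likewise
  an assumption shaped by the reported "significant increase".
* Cohort curves are generated with $\eta = 0$ (no viscosity values are
  printed; the preset type deliberately leaves $\eta$ out).

What the phantoms do *not* emulate: lateral mechanical heterogeneity within
a cell, membrane/cortex layering, adhesion, instrument drift between pixels,
and non-spherical cell shapes. Passing recovery tests therefore demonstrates
the correctness of the estimators under the stated forward model, not
robustness to every feature of real data.

# Assay summaries

`kinetics_auc()` integrates the baseline-subtracted trace (trapezoid) from
activator addition to a chosen end time, warning if that end precedes the
burst peak; the baseline is the pre-activation mean. The synthetic burst is
log-normal-shaped because its running integral has a closed form (via the
normal CDF), giving an analytic oracle at any end time.
`dna_normalize()` divides activities by per-well DNA content.
`zscore_standardize()` standardises each experiment row to mean 0 / sample SD
1 (constant rows give NA with a warning); it is idempotent and
location/scale invariant per row. `phagocytic_metrics()` gates events
against the 99.5th percentile of a matched no-particle control (the study
sets this gate graphically; the quantile is configurable) and reports
affinity (% gated) and capacity (median intensity of gated events -
median, not mean, following cytometry convention for MFI; configurable).
Hypothesis testing beyond the two delegated two-sample tests (ANOVA/Tukey,
Kruskal-Wallis/Dunn, normality checks) is intentionally left to standard R
functions.

# Problem sizes and determinism

The validation suite uses 16 x 16 to 52 x 52 pixel maps, 20-25 cells per
cohort arm and 200 Monte-Carlo curves per parameter setting; these sizes
give stable medians and folds while keeping a full run in the minutes range.
Every stochastic routine takes an explicit seed, records it in its output,
and is bit-reproducible under that seed; fitters are deterministic given
their inputs.

# Known limitations

* Spherical tips only; no conical/pyramidal geometry, no adhesion (JKR/DMT),
  no poroelasticity.
* The bonded-sample correction series is for $\nu = 0.5$; other Poisson
  ratios reuse the same coefficients.
* $\alpha$ is bounded at 0.95 in fits; the hereditary integral is singular
  at $\alpha = 1$.
* The contact detector assumes a single contact event per approach.
* Import of proprietary vendor force-volume files is out of scope; use the
  documented text format or the package container.
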