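---
title: "A motor-clutch account of HAVDI-reversible YAP mechanical memory"
author: "MechanoMemory authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A motor-clutch account of HAVDI-reversible YAP mechanical memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MechanoMemory)
```

Mesenchymal stem cells cultured on stiff tissue-culture plastic (TCP,
~3 GPa) accumulate nuclear YAP, and part of that accumulation persists
after transfer to soft hydrogels — a *mechanical memory* that biases the
cells toward osteogenic commitment. Presenting the N-cadherin mimetic
peptide HAVDI alongside the integrin ligand RGD on the soft gel lowers the
YAP nuclear/cytoplasmic ratio ($R_{NC}$) after transfer. `MechanoMemory`
implements a mechanistic model chain that reproduces this phenomenology,
together with the measurement formulas used to quantify it from images and
indentation data, and synthetic-data generators that make every stage
testable without any experimental input.

## The model chain

The chain has three stages, coupled quasi-statically.

### 1. Stiffness- and HAVDI-dependent clutch binding

Traction is generated by a stochastic motor-clutch ensemble: $n_m$ myosin
motors (stall force $F_m$) pull an actin filament engaged to the substrate
through $n_c$ molecular clutches. HAVDI ligation acts through a single
knob, the clutch binding rate $k_{on}$, via a Boltzmann/Arrhenius-type
activation law in log substrate stiffness:

$$k_{on}(E_{sub}, h) = k_{min} + (k_{max} - k_{min})
  \left[1 + e^{-s\,(\ln E_{sub} - \ln E_{1/2}(h))}\right]^{-1},
  \qquad E_{1/2}(h) = E_{scram}^{\,1-h}\,E_{havdi}^{\,h},$$

where $h \in [0,1]$ is the HAVDI occupancy (1 mM dose saturates, see
`havdiOccupancyFromDose()`). HAVDI shifts the activation midpoint upward
(7 kPa → 18 kPa at the defaults, logistic slope $s = 2$ in $\ln E$), so
the stiffness threshold for fast binding — and hence for elevated traction
— is higher on HAVDI/RGD than on Scram/RGD surfaces. The binding-rate
range (0.05–1.0 s$^{-1}$) reflects the available integrin density. The
exact activation law behind the published figure is not identifiable from
its main text, so the logistic form above is this package's design choice:
it is the minimal monotone form with the required shifted-midpoint
behaviour, and `KonParams` exposes every constant so an alternative
calibration can be swapped in.

```{r kon}
konCurve(c(1e3, 10e3, 15e3, 41e3), havdi = c(0, 1))
```

### 2. The stochastic clutch engine

`simulateTraction()` runs a fixed-time-step Monte Carlo (0.01 s steps,
$10^5$ steps ≈ 1000 s by default, first 20% discarded as burn-in; the
inner loop is compiled). Per step:

1. the substrate displacement solves the elastic force balance
   $\kappa_{sub} x_{sub} = \kappa_c \sum_{bound} (x_i - x_{sub})$, with
   $\kappa_{sub} = a E_{sub}$ the point-contact substrate spring
   ($a$ = 1 µm adhesion radius; 20 kPa → 20 pN/nm);
2. traction $F = \kappa_{sub} x_{sub}$ sets the retrograde flow by the
   linear force–velocity law $v = v_u (1 - F / n_m F_m)$, clamped at
   stall;
3. bound clutch positions advance with the flow;
4. unbound clutches bind with probability $1 - e^{-k_{on} dt}$ at zero
   extension; bound clutches unbind as Bell slip bonds,
   $k_{off} = k_{off}^0 e^{F_i / F_b}$, with the event-time load measured
   against the substrate displacement of the step's force balance;
5. if every clutch detaches the substrate recoils (load-and-fail).

Numerical notes. The scheme is $O(dt)$; with the canonical parameter set
($n_m = n_c = 50$, $F_m = 2$ pN, $v_u = 120$ nm/s, $\kappa_c = 5$ pN/nm,
$k_{off}^0 = 0.1$ s$^{-1}$, $F_b = 2$ pN) the ensemble operates in the
load-and-fail regime of the classic motor-clutch model: mean tractions are
a few piconewtons, far below the 100 pN ensemble stall, which is reached
only in the permanent-bond limit $k_{off}^0 = 0$. Simultaneous events
within a step are resolved independently per clutch. All randomness flows
through R's RNG, so runs are exactly reproducible given a seed; summary
standard errors use batch means (25 batches), which accounts for the
autocorrelation of the traction trace. With constant $k_{on}$ the engine
reproduces the classic interior traction optimum versus substrate spring;
with the activation law switched on the optimum is overridden and both
conditions produce the monotone, shifted sigmoid pair, separated by
~2.4 pN at 20 kPa and converging at the compliant and rigid extremes. One
caveat is worth stating: the Monte Carlo standard error of an 800-second
time average is of order 0.01 pN, so even the small residual differences
at 1–2 kPa and 41 kPa (0.1–1 pN) are statistically resolvable — the
model's curves converge on the scale of the traction dynamic range, not
within simulation noise.

### 3. Viscoelastic–plastic nucleus and YAP shuttling

Traction deforms the nucleus. The nucleus combines a Kelvin–Voigt
recoverable element with a yield-threshold plastic dashpot
(`updateNucleus()`, exact per-step updates):

$$\dot\varepsilon_e = \frac{F/E_N - \varepsilon_e}{\tau_e}, \qquad
  \dot\varepsilon_p = \frac{\max(0,\, F - F_y)}{\eta_p},$$

and nuclear flattening (length/height) composes both strains on the
zero-traction baseline, $\lambda_N = \lambda_0 (1 + \varepsilon_e +
\varepsilon_p)$. Plastic strain never decreases: it *is* the stored
memory. Flatter nuclei have dilated pores and a higher YAP import rate at
unchanged export, collapsed here into a linear steady-state law with
first-order kinetics:

$$R_{NC}^{ss} = \max(0.1,\; a\,\lambda_N + b), \qquad
  \dot R_{NC} = \frac{R_{NC}^{ss} - R_{NC}}{\tau_R}.$$

The floor keeps a ratio of total intensities positive in extreme corners
of parameter space.

Parameter choices (all config-overridable, units in the class docs):

| parameter | default | rationale |
|---|---|---|
| $\tau_e$ | 4 h | elastic recovery completes well within 1 d, matching post-transfer kinetics |
| $E_N$ | 7.5 pN/strain | TCP-cultured nuclei flatten to $\lambda_N \approx 4$–5 |
| $F_y$ | 6.8 pN | steady 20 kPa Scram/RGD traction (6.67 ± 0.04 pN), rounded up so soft culture never writes memory |
| $\eta_p$ | 10.4 pN·d/strain | 10 d on TCP (7.32 pN) accumulates $\varepsilon_p \approx 0.5$ |
| $\lambda_0$ | 2 | baseline flattening of an unloaded spread nucleus |
| $a$, $b$ | 0.75, −0.2 | places soft-gel $R_{NC}$ near 1.4–2.6 and TCP near 3.5 |
| $\tau_R$ | 2 h | nuclear YAP reaches steady state within a day, consistent with reports of hour-scale shuttling |

`calibrateYieldForce()` recomputes $F_y$ and $\eta_p$ from any clutch
parameter set, so the anchoring survives re-parameterisation.

### Protocols and the memory readout

`runProtocol()` chains culture steps (e.g. TCP for $D$ days, then a 20 kPa
gel for $S$ days). Because the clutch ensemble equilibrates in seconds
while protocols run for days, the traction of each condition is simulated
once to steady state (replicate-averaged, cached) and used as a constant
input while the nucleus/YAP states are integrated on a 0.05 d grid —
a separation-of-timescales (quasi-static) coupling. Integration during TCP
culture is continuous rather than per-day; the distinction is immaterial
at these time constants. Passaging itself is not modelled (experimentally
it has no measurable effect), and growth versus osteogenic medium is
chemistry outside this model's scope, as are the downstream RUNX2/OCN/ALP
differentiation dynamics.

The *memory residual* of a protocol is its endpoint $R_{NC}$ minus a
soft-control baseline: a rest-started run of the final condition for the
final-step duration, mirroring the per-condition soft controls used
experimentally. Model structure makes the endpoint exactly
$\max(0.1, a \lambda_0 (1 + \varepsilon_p + F_{post}/E_N) + b)$ once
elastic transients have relaxed, so the residual equals
$a \lambda_0 \varepsilon_p$ — plastic memory only. Two consequences are
worth noting. First, the residual is identical for Scram and HAVDI
transfers (the plastic strain was written on TCP before transfer); what
distinguishes the conditions is the *absolute* endpoint, which is lower on
HAVDI/RGD because its weaker traction supports less elastic flattening —
that is the model's reading of "HAVDI facilitates elastic recovery".
Second, at the shortest post-transfer times a remnant of the elastic
transient ($\sim e^{-t/\tau_e}$, about $10^{-3}$ in $R_{NC}$ units at
1 d) survives in the residual; comparisons between conditions therefore
use a 0.005 tolerance.

```{r panel, eval = FALSE}
memoryPanel(dosingDays = c(0, 1, 3, 7, 10), postDays = c(1, 3, 10),
            seed = 5)
```

At the defaults this reproduces the observed pattern: zero dosing leaves a
residual of exactly 0; one day of TCP is fully reversible (residual 0.075
versus 0.76 after ten days); residuals grow linearly with dosing; the
post-transfer ratio settles within one simulated day; and the HAVDI
endpoint sits below the Scram endpoint after every dosing.

## Measurement formulas

The quantification half of the package is independent of the simulator
and operates on labelled images, z-stacks and indentation curves.

* `ncRatioSparse()` — area-weighted nuclear/cytoplasmic intensity ratio
  $\frac{I_{nuc}/A_{nuc}}{(I_{cell}-I_{nuc})/(A_{cell}-A_{nuc})}$, with
  areas in pixels so units and pixel-size metadata cancel. Images with
  saturated fluorescence inside the cell are rejected, matching standard
  exclusion practice. Intensities are treated as totals; no background
  subtraction is applied (none is described for the original processing).
* `ncRatioConfluent()` — the pooled multi-nucleus generalisation over a
  zone mask; with one nucleus and zone = cell it reduces to the sparse
  formula exactly.
* `nuclearFlattening()` — Otsu threshold over the stack, largest
  6-connected component, then length from the principal-axis extent of
  the x–y silhouette and height from the z extent of the x–z silhouette,
  both via the filled-ellipse second-moment rule (extent = 4 sd), which is
  sub-voxel accurate and tolerant of moderate blur. The original analysis
  used commercial 3-D software whose algorithm is unspecified; this is the
  package's documented equivalent.
* `colocalizationFraction()` — percentage of channel A's Otsu-positive
  area also positive in channel B (a Manders-M1-style area overlap,
  deliberately asymmetric). The published description mentions
  cross-correlation techniques without a reproducible formula; the
  implemented statistic is the stated *output* (percent overlapping area).
* `fitYoungModulus()` — Hertz spherical indentation,
  $P = \tfrac{4}{3} \tfrac{E}{1-\nu^2} R^{1/2} h^{3/2}$, fitted by the
  closed-form linear-in-$E$ least squares (no optimiser, no contact-point
  search; curves are assumed pre-zeroed). $\nu$ defaults to 0.5
  (incompressible hydrogel) since the value used by the original analysis
  is unstated; a mismatched $\nu$ biases $E$ by exactly
  $(1-\nu_{assumed}^2)/(1-\nu_{true}^2)$, which the tests assert.

Otsu thresholds are computed by an internal 256-bin histogram routine
because the imaging dependency thresholds whole 2-D frames only, while
this package needs masked-region and 3-D-global thresholds; the routine is
validated against that dependency on full frames.

## Synthetic data: what it does and does not emulate

`makeCellImage()` / `makeConfluentImage()` render elliptical cells whose
nuclear-to-cytoplasmic mean ratio is prescribed, with optional Gaussian
(5% of the cytoplasmic mean) or Poisson noise at a confocal-like photon
budget (cytoplasmic mean 200 counts). `makeNucleusZstack()` renders solid
ellipsoids at 0.2 µm in-plane / 0.5 µm z voxels with optional in-plane
blur; the centre is placed on voxel boundaries so silhouettes are
symmetric. `makeColocMasks()` and `makeIndentationCurve()` construct
overlap pairs and noisy Hertz curves with exact ground truth. Every
generator is bit-reproducible given its seed and returns its ground truth,
so downstream tests are closed-loop.

These generators deliberately omit realistic optics (no 3-D PSF), textured
cytoskeleton, segmentation errors (masks are exact), cell-to-cell
variability and background gradients. Passing round-trip tests therefore
demonstrates correctness of the *formulas and estimators*, not robustness
to the segmentation and staining artefacts of real micrographs.

## Problem sizes and known limitations

The shipped test-suite and acceptance runs use the full default Monte
Carlo length ($10^5$ steps) with 10 replicates per condition for sweeps
and panels, 3 replicates for the constant-$k_{on}$ optimum scan, 100–200
repetitions for estimator-recovery checks, and 128×128 synthetic images —
sizes chosen so the complete chain (sweep, panel, quantification) runs in
about a minute on one core while keeping Monte Carlo error well below
every asserted tolerance.

Known limitations, stated plainly:

* the Arrhenius-type binding law and its constants are a calibration, not
  a fitted supplementary table; only its monotone shifted-sigmoid
  structure is constrained by the reproduced observations;
* the HAVDI effect enters exclusively through $k_{on}$ — there is no
  cadherin-side force balance, talin-unfolding submodel or spatial
  adhesion structure;
* nuclear rheology is scalar (no geometry, no volume bookkeeping), the
  plastic element has a sharp yield, and pore mechanics are collapsed into
  one linear law;
* the intercept of the $\lambda_N \to R_{NC}$ line is small relative to
  its sampling error at realistic noise (its OLS standard error from 50
  points at 5% noise is ~0.07, a third of the intercept itself), so
  intercept recovery to tight relative tolerances is statistically
  impossible even though the fitted line itself is recovered to ~1%;
* Hertz fitting assumes linear elasticity and no adhesion or
  substrate-thickness corrections — adequate for the PEG hydrogels it is
  meant for, not for fibrous or hyperelastic matrices.
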