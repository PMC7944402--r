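---
title: "Models and methods behind kvshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kvshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvshift)
```

kvshift implements the quantitative analysis chain used to characterise
how negatively charged, lipophilic resin-acid derivatives (Wu50, Wu161,
Wu181) modulate the voltage dependence of Shaker-type voltage-gated
potassium (Kv) channels. This vignette describes the underlying models,
the assumptions they make, the tunable parameters, and the design
decisions taken where several defensible constructions existed.

## From current families to Boltzmann parameters

A two-electrode voltage-clamp experiment yields a *current family*: one
current sweep per depolarising test step from a fixed holding potential
(default −80 mV). The analysis uses only the steady-state segment of
each sweep:

1. **Steady-state current.** `steady_state_current()` averages the
   current over a window at the end of each sweep (default: the last
   10 ms of a 100 ms step). The window length trades noise averaging
   against contamination by slow processes; it must lie inside the
   sweep, which the protocol constructor enforces.
2. **Conductance.** `compute_conductance()` applies the ohmic relation
   $G(V) = I / (V - V_K)$ with $V_K$ the K$^+$ reversal potential
   (default −80 mV, set by the recording solutions). The driving force
   vanishes at $V = V_K$, so points recorded there carry no conductance
   information; they are dropped with a warning rather than
   interpolated.
3. **Boltzmann fit.** `fit_boltzmann()` fits
   $$G_K(V) = \frac{G_{MAX}}{1 + \exp[(V_{1/2} - V)/s]}$$
   by Levenberg–Marquardt nonlinear least squares. $G_{MAX}$ (µS) is the
   maximal conductance, $V_{1/2}$ (mV) the activation midpoint and
   $s$ (mV, constrained positive) the slope factor. Starting values are
   data driven: $G_{MAX}$ from the observed plateau, $V_{1/2}$ from the
   voltage nearest half-maximum, and $s$ from the 25–75 % rise width
   divided by $2\ln 3 \approx 2.2$. Fits are unweighted by default —
   per-point variances are rarely available for single families — with a
   `weights` argument for when they are. Non-convergence is reported via
   a `converged` flag rather than an error; an exactly flat curve is
   rejected because all three parameters are unidentifiable.

The compound effect is summarised by two statistics:
`gv_shift()` $= V_{1/2}(\text{compound}) - V_{1/2}(\text{control})$,
negative when channel opening is promoted, and `gmax_ratio()`
$= G_{MAX}(\text{compound})/G_{MAX}(\text{control})$. Group comparisons
(`compare_shifts()`) use a two-tailed unpaired t test; the Welch
unequal-variance form is the default because group sizes in oocyte work
are small (2–10) and unequal, with the pooled-variance form one switch
away.

## Concentration–response

The concentration dependence of the shift follows the single-site
hyperbola
$$\Delta V(c) = \frac{\Delta V_{MAX}}{1 + EC_{50}/c},$$
with the Hill coefficient fixed at 1 — the model is used as written, and
adding a Hill slope would not be identifiable from the 4–6
concentrations typical of these experiments. `fit_dose_response()`
estimates apparent affinity ($EC_{50}$, µM) and efficacy
($\Delta V_{MAX}$, mV) in linear concentration space, initialising
$EC_{50}$ at the measured concentration whose shift is nearest half the
extreme shift. Standard errors come from the Jacobian-based covariance
at the optimum. Fits are unweighted by default (whether the original
curve fits were SEM-weighted is not documented; unweighted matches
common practice), with optional weights. At least three distinct
concentrations are required; all-equal shifts are rejected as
unidentifiable.

`efficacy_increase()` converts two efficacies into the percent increase
of maximal shift used to compare channels, e.g. the gain produced by
the 2R motif (M356R/A359R, two arginines added at the extracellular top
of S4).

## Additive binding-site decomposition

The central model attributes each mutant's shift (all measured at one
concentration, 100 µM) to independent, additive site contributions:
$$\Delta V_{model} = \Delta V_{S3/S4} + \Delta V_{S4/pore} +
\Delta V_{Residual},$$
with the constraint structure: $\Delta V_{S3/S4}$ is a single value
active only in channels carrying the 2R motif (without the added
arginines the compound does not stay bound in the S3/S4 cleft);
$\Delta V_{S4/pore}$ takes one value per pore configuration class —
R362/W454 intact ("WT"), R362Q, W454A, R362Q/W454A — and
$\Delta V_{Residual}$ (all remaining sites, notably the top-VSD pocket)
is common to every mutant. `encode_mutant()` maps constructs onto these
terms; mutants carrying R365Q or F416A fall outside the four named
classes and are given *extended* classes (e.g. `R362Q_R365Q`) so the
registry can grow with the data — unexpected combinations are accepted
with a warning rather than forced into a wrong class.

`build_design_matrix()` turns a panel into a binary indicator matrix and
reports its rank. `fit_site_model()` solves the least-squares problem
(optionally weighted, optionally with parameters pinned via `fixed`),
using the SVD minimum-norm solution when the design is rank deficient.

### Degeneracy, and how the published panel is handled

When every mutant in a panel carries a pore term, the sum of the pore
indicator columns equals the residual column: a constant can migrate
between the residual and all pore values without changing a single
prediction. This gauge ridge is intrinsic to the eight-mutant panel (the
four pore classes, each with and without the 2R motif). Two consequences:

* The S3/S4 term is identifiable (it is invariant along the ridge), and
  the published decomposition resolves the rest by pinning the residual
  at −10 mV; `fit_site_model(..., fixed = c(residual = -10))` reproduces
  the published contributions (S3/S4 ≈ −17 mV, WT pore ≈ −15 mV, R362Q
  pore ≈ −34 mV, R362Q/W454A pore ≈ −31 mV) from the packaged shift
  table — this is exactly what `scripts/acceptance.R` recomputes.
* `solution_ranges()` reports the honest uncertainty: for each
  parameter, the interval attainable by any parameter vector whose sse
  stays within a tolerance (default 5 %) of the minimum. Along the row
  space this interval has the closed form
  $\hat\beta_j \pm \sqrt{\text{slack} \cdot e_j'(X'X)^{+}e_j}$;
  a parameter with a null-space component is reported as unbounded with
  a warning. No sign constraints are imposed — how the original
  analysis bounded its printed ranges is not documented, and this
  profiling construction is the one we consider defensible.

One transcription note: the 100 µM Wu50 shift of the 2R/W454A construct
is not tabulated numerically in the published text. It is reconstructed
as −40.1 mV from the published statement that the 2R motif increases the
Wu50 shift by 4–32 mV across backgrounds (the three directly printed
pairs give 14.5, 4.4 and 15.6 mV, so the W454A pair must account for
the 32 mV extreme), consistent with the observation that the W454A
attenuation is abolished by the 2R motif. The row is flagged
`derived = TRUE` in `load_published_shifts()`.

`predict_and_correlate()` closes the loop with per-mutant model
predictions and the Pearson correlation against observation; a constant
prediction (residual-only model) yields `NA` with a message rather than
a spurious coefficient.

The strictly additive model is the default. Because the data suggest
that the S3/S4 site dominates once the 2R motif is present,
`zero_pore_when_2R = TRUE` offers the interaction variant in which the
pore term is silenced in 2R-carrying constructs; both variants can be
fitted and compared.

## MD contact analysis

For a ligand bound near the voltage sensor of a homotetrameric channel,
`min_distance_series()` computes the per-frame minimum Euclidean
distance between any *heavy* atom of the ligand and any heavy atom of a
chosen residue in a chosen subunit; `contact_frequency()` converts the
series into the fraction of frames within a cutoff (default 0.45 nm =
4.5 Å). Conventions:

* The comparison is inclusive (distance = cutoff counts as a contact);
  with real coordinates ties have measure zero, but the convention
  matters for constructed tests.
* Heavy atoms are identified from the element column, falling back to
  the PDB atom-name prefix; halogens on the ligand count as heavy atoms.
* The four chains are treated as quasi-independent replicates and
  reported separately (`profile_report()` gives the long, sorted
  table).
* Orthorhombic minimum-image distances are applied when a trajectory
  slice carries box vectors; the toy systems generated here are
  non-periodic.
* All frames of the supplied coordinates are analysed; any
  equilibration trimming is the caller's responsibility.

Trajectories enter via `load_trajectory()`: a multi-MODEL PDB, or a PDB
topology plus a DCD coordinate file. These two text-friendly routes keep
the analysis fully testable; other coordinate formats should be
converted upstream.

## What the synthetic generators emulate — and what they do not

The generators produce every input the pipeline consumes, with known
ground truth:

* `gen_current_family()` — Boltzmann-shaped conductance times driving
  force, single-exponential activation with a voltage-independent
  τ (default 10 ms), optional constant leak, additive i.i.d. Gaussian
  current noise (optionally scaled per sweep, e.g. with driving force).
  Not emulated: capacitive transients, voltage-dependent kinetics,
  channel noise, series-resistance artefacts. Only the steady-state
  window matters downstream, so these omissions do not bias the
  quantities under test.
* `gen_dose_response()` — hyperbolic means with Gaussian replicate
  scatter, tabulated as mean/SEM/n. The published work reports SEM per
  group but not raw per-cell scatter, so the noise SD is an explicit
  parameter rather than an asserted property of the real data.
* `gen_shift_table()` — exact additive site structure plus Gaussian
  per-measurement noise.
* `gen_trajectory()` — one heavy pseudo-atom (plus a hydrogen) per
  residue and a small rigid ligand translated between residue sites and
  a distant parking position, so that each (residue, subunit) pair is in
  contact in exactly `round(fraction × n_frames)` frames. A single
  ligand visits one site per frame, so scheduled fractions must sum to
  at most 1. The ligand's hydrogen is deliberately placed nearer the
  residue than any ligand heavy atom during contacts, making erroneous
  hydrogen inclusion detectable. No physical forces are emulated.

Passing recovery tests on these inputs demonstrates correctness of the
estimators under the stated noise models — not robustness to the
artefacts real recordings or real force fields contain.

## Problem sizes and numerical choices

The recovery studies run at sizes chosen to give stable Monte-Carlo
estimates while keeping the default check fast: 100 replicate families
for the Boltzmann pipeline (per-sample current noise with SD 5 % of
$G_{MAX}\times$ driving force, i.e. 5 % of the local maximal current);
1000 replicates for EC50 recovery (1 mV shift noise, 6 log-spaced
concentrations spanning $EC_{50}/10$ to $10\,EC_{50}$); 1000 replicates
for site-model recovery. The synthetic site panel uses all 12 encodable
configurations (6 pore classes × with/without 2R) with n = 10
measurements per mutant at 2 mV per-measurement noise — group sizes and
scatter at the upper end of what the corresponding experiments report —
with the residual pinned at its true value, mirroring how the published
analysis resolves the gauge ridge. Parameter recovery is summarised as
the RMSE of the full parameter vector.

Other numerical conventions: SVD rank tolerance $10^{-10}$ relative to
the largest singular value; Levenberg–Marquardt capped at 200
iterations; `s` bounded below by $10^{-6}$ mV and `ec50` by
$10^{-9}$ µM to keep the optimiser in the valid domain; seeds are plain
integers recorded in generator metadata, and every stochastic function
takes one.

## Known limitations

* The additive model ignores site coupling by construction; the largest
  residuals of the eight-mutant fit (W454A and 2R/W454A) are consistent
  with an interaction between the S3/S4 and S4/pore sites, which the
  optional `zero_pore_when_2R` variant only crudely captures.
* Solution ranges are profiled under an sse tolerance; they are not
  confidence intervals and have no frequentist coverage guarantee.
* The contact analysis assumes orthorhombic boxes when periodic; triclinic
  minimum-image corrections are not implemented.
* G$_{MAX}$ effects are summarised as a ratio only; no mechanistic model
  of conductance suppression is fitted.
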