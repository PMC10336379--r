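---
title: "Turing patterns in non-ideal fluids: model, numerics and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turing patterns in non-ideal fluids: model, numerics and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turingfh)
```

## The model

`turingfh` simulates and analyses a minimal two-species pattern-forming
system in which the activator $A$ and inhibitor $I$ both react *and*
interact physically.  The state is described by volume fractions
$\phi_A(\mathbf r, t)$ and $\phi_I(\mathbf r, t)$; an inert solvent
occupies the remainder $\phi_S = 1 - \phi_A - \phi_I$.

**Thermodynamics.**  The mixture free energy is of Flory–Huggins form
(per molecular volume, in units of $k_BT$):

$$
f = \phi_A\ln\phi_A + \phi_I\ln\phi_I + \phi_S\ln\phi_S
  + \chi\,\phi_A\phi_I
  + \tfrac{w^2}{2}\left(|\nabla\phi_A|^2 + |\nabla\phi_I|^2\right),
$$

where $\chi$ is the Flory interaction parameter between $A$ and $I$
(positive: effective repulsion; negative: attraction) and $w$ limits
interfacial widths.  The exchange chemical potentials are
$\mu_i = \ln(\phi_i/\phi_S) + \chi\phi_j - w^2\nabla^2\phi_i$.

**Dynamics.**  Transport follows linear non-equilibrium thermodynamics
with mobilities $D_i\phi_i$, and reactions follow a Hill–Langmuir
production with linear degradation:

$$
\partial_t \phi_i
  = \nabla\cdot\left(D_i\,\phi_i\,\nabla\mu_i\right)
  + k\left[\frac{2\phi_0}{1 + (\phi_I/\phi_A)^h} - \phi_i\right].
$$

The homogeneous state $\phi_A=\phi_I=\phi_0$ is an exact fixed point
(the Hill ratio is 1 there).  Setting $\chi = 0$ and considering
wavelengths $\gg w$ recovers an ideal reaction–diffusion (Turing)
system; the package exposes this limit explicitly
(`simulate(..., model = "ideal")` with the first-order effective
diffusivity matrix `effective_diffusivity_matrix()`, whose off-diagonal
cross-diffusion entries $D_i(\psi + \chi\phi_0)$,
$\psi = \phi_0/(1-2\phi_0)$, are how weak interactions reshape the
classical Turing threshold).

**Units.**  Everything is non-dimensional: lengths in $w$, times in
$w^2/D_A$, energies in $k_BT/\nu$.  All defaults below are in these
units.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `phi0` | mean fraction of each species | 0.2 | must be < 1/2 |
| `chi`  | Flory interaction | 0 | regimes: $\chi < \chi_-$ associative, $\chi > \chi_+$ segregative phase separation |
| `h`    | Hill exponent | 5 | reaction nonlinearity |
| `k`    | reaction rate | 0.1 | sets the reaction–diffusion length $\sqrt{D/k}$ |
| `D_I/D_A` | diffusivity ratio | 1–10 | classical Turing patterns need it large |
| `w`    | interfacial width | 1 | the length unit |

Two closed-form thresholds characterize phase separation without
reactions at $\phi_0 < 1/4$:

* `chi_plus(phi0) = 1/phi0` — segregative spinodal ($A$ demixes from
  $I$); it is exactly the root of the $(1,-1)$ eigenvalue of the local
  Hessian.
* `chi_minus(phi0) = 8\,\mathrm{artanh}(1-4\phi_0)/(4\phi_0-1)` —
  associative binodal ($A{+}I$ demix from solvent), continuously
  extended to $-8$ at $\phi_0 = 1/4$.  The test suite cross-checks it
  against an independent Maxwell (common-tangent) construction.

## Linear stability analysis

Perturbing the homogeneous state with wavenumber $q$ gives the $2\times2$
dynamical matrix

$$
J(q) = -q^2\,M\,(H + w^2 q^2\,\mathrm{Id}) + R,
\qquad M = \mathrm{diag}(D_A\phi_0,\, D_I\phi_0),
$$

with $H$ the local Hessian and $R$ the reaction Jacobian (closed form
$R = k\begin{psmallmatrix}h/2-1 & -h/2\\ h/2 & -h/2-1\end{psmallmatrix}$,
both eigenvalues $-k$).  `dispersion_relation()` evaluates the largest
eigenvalue real part on a wavenumber grid using the exact trace/
determinant formula (a guard treats discriminants at roundoff scale as
double roots, so $\sigma(0) = -k$ holds to machine precision rather than
to $\sqrt{\varepsilon}$).

Numerical choices:

* default $q$ grid: 1024 log-spaced points on $[2\pi/2000, \pi]$
  (largest replication box to interfacial scale); results are
  insensitive to refinement beyond 512 points;
* instability tolerance $\sigma > 10^{-10} D_A/w^2$; ties in the fastest
  mode resolve to the smallest $q$;
* `chi_star()` (minimal interaction supporting patterns) pre-scans 26
  points on $[-15, 10]$ and bisects the **last** stable-to-unstable
  transition to $10^{-4}$.  Defining it as the upper edge of the stable
  window matters: very strong attraction also destabilizes
  (associative phase separation), so "unstable somewhere below" must
  not short-circuit the search.

A consequence worth recording: for $D_I = D_A$ the linearized system is
exactly triangular in the $(1,1)/(1,-1)$ basis, so the segregative mode
grows as $\sigma(q) = q^2 D\phi_0(\chi - 1/\phi_0) - q^4 D\phi_0 w^2 - k$
and

$$
\chi^*\big|_{D_I=D_A} = \frac{1}{\phi_0} + 2w\sqrt{\frac{k}{D\phi_0}},
$$

which is $5+\sqrt2 \approx 6.414$ at $\phi_0=0.2,\ k=0.1$.  Reactions
therefore push the patterning threshold *beyond* the equilibrium
spinodal $\chi_+ = 5$: phase separation at the spinodal is damped at
rate $k$ and needs a finite margin of driving to overcome it.  The
package's bisection reproduces this value to $10^{-3}$, which we treat
as a strong dual-route validation (closed form vs. generic scan).

## The simulator

Methods follow the conservative finite-difference scheme:

* second-order central stencils (3-point/5-point Laplacians) on
  equidistant periodic grids;
* $\nabla\mu_i$ evaluated on **staggered** cell faces with the mobility
  $D_i\phi_i$ averaged arithmetically onto the face; the divergence of
  face fluxes telescopes, so each species' total is conserved to
  roundoff when $k=0$;
* explicit Euler time stepping.  `stable_dt()` bounds the fastest
  resolvable mode as
  $\sigma_{\max} \le \max_i D_i\,(2\phi_0)\,(H_{\max}q_{\max}^2 +
  w^2q_{\max}^4) + 2k$ with $q_{\max} = \pi/\mathrm{dx}$ and uses
  `dt = safety / sigma_bound` (default safety 0.5).

Degenerate inputs are rejected, not repaired: fields that leave the open
composition simplex abort the run with the time, cell and a suggestion
to reduce `dt`.  Clamping would silently falsify the physics (mass and
the free-energy structure).

Without reactions the scheme inherits the gradient-flow structure: the
discrete free energy (local density plus staggered gradient terms) is
non-increasing along trajectories at the default time step, which the
tests assert step-by-step over thousands of steps — a sensitive
end-to-end check of the flux discretization.

The linear regime of the integrator is cross-checked against the
dispersion relation at the *discrete* wavenumber
$q_\mathrm{eff}^2 = (2 - 2\cos q\,\mathrm{dx})/\mathrm{dx}^2$:
single-mode perturbations of amplitude $10^{-6}$ seeded along the
dominant eigenvector reproduce the predicted eigenvalue to better than
2%.

## Synthetic data: what the generator emulates

There is no external data; initial conditions are the stated world.
Fields start at $\phi_0$ plus independent uniform noise of amplitude
$10^{-3}$ per cell (seeded; the published protocols do not state their
noise model, amplitude, or seeds, so every replication claim here is
statistical or qualitative, never bit-exact against the original).
Uniform i.i.d. noise is unbiased and excites all modes, which is what
linear stability needs; it does **not** emulate spatially correlated
initial conditions, finite-temperature fluctuating hydrodynamics during
the run, or experimental heterogeneity.  A green regime test therefore
establishes "these parameters produce (or fail to produce) this pattern
class from generic small perturbations", not any statement about noise
robustness.

## Reduced-scale protocols

The published studies integrate for $10^5$–$10^7$ time units on boxes up
to $2000\,w$.  Desk-scale replication reduces this; reductions are
chosen from the physics *before* outcomes are inspected:

* phase-diagram scans: box $200\,w$, $t_{\mathrm{end}} = 10^4$ (the
  regime signatures at $k = 0.1$ saturate well before this);
* runs whose protocol does not pin the time use
  $t_{\mathrm{end}} = \min(\mathrm{cap}, \max(100, 25/\sigma^*))$ — 25
  linear e-folding times of the fastest mode past saturation;
* grids use $\mathrm{dx} \in \{1, 2, 4\}$ chosen so the fastest-growing
  wavelength is resolved by at least ~32 cells and never coarser than
  $4\,w$; strongly interacting (sharp-interface) parameters always get
  $\mathrm{dx} = 1$ (explicit Euler on a fourth-order operator makes
  $\mathrm{dt} \propto \mathrm{dx}^4$, so this is the main cost lever);
* the 1D-vs-2D length comparison runs at $L = 128\,w$ with sub-bin
  (3-point log-parabolic) refinement of the structure-factor peak
  enabled, because a $128\,w$ box holds only a handful of pattern
  wavelengths and the raw spectral bins quantize lengths in steps of
  $L/m$.  One known desk-scale limitation: at affordable times the 2D
  stationary length sits systematically 20–30% above the 1D one for
  weak interactions (2D reorganization selects slightly coarser
  patterns early, and 1D coarsening is logarithmically slow), so
  dimensional agreement at the published tolerance should be read as a
  long-time statement.

## Pattern metrics

* **amplitude** — half the peak-to-peak range of $\phi_A$.  The source
  figures never define their amplitude; half peak-to-peak matches a
  near-sinusoidal pattern, and all comparisons based on it are kept
  qualitative (zero vs non-zero, monotone trends).
* **covariance** — $\langle\phi_A\phi_I\rangle -
  \langle\phi_A\rangle\langle\phi_I\rangle$ over the grid; positive for
  associative (co-localized) patterns, negative for segregative ones.
  Plain Turing patterns come out *positive* (inhibitor tracks
  activator in phase), decreasing with repulsion.
* **dominant length** — $2\pi/q_\mathrm{peak}$ from the structure factor
  (power spectrum of the mean-subtracted field; radial average over
  annuli of width $2\pi/L$ in 2D).  A peak must exceed 10× the median
  spectral power to count; otherwise the length is undefined (`NA`),
  never a fabricated number.  Discrete argmax by default (determinism);
  optional log-parabolic refinement behind a flag.
* **scaling exponent** — closed-form OLS slope of $\log\ell$ vs
  $\log k$ with its standard error.  Weak interactions give $-1/2$
  (the reaction–diffusion lengths $\sqrt{D_i/k}$ are the only scales);
  strong attraction pins $\ell$ near the interfacial width, slope
  $\approx 0$.

## Experiment drivers and provenance

`scan_phase_diagram()` runs one seeded simulation per cell of a
rectangular parameter grid (per-cell seeds derived deterministically
from the master seed and the cell indices, so scans are reproducible
and order-independent), records amplitude/covariance/length plus the
LSA verdict, and survives per-cell blow-ups as flagged failed cells.
`compare_1d_2d()` pairs matched-seed 1D and 2D runs.  The CLI
(`run_cli()`, script in `inst/cli/turingfh.R`) exposes `simulate`,
`stability`, `scan`, `metrics` and `figures` subcommands; every output
is accompanied by a JSON manifest (parameters, seed, dt, package
version, no timestamps) from which the output can be regenerated
bit-identically.

State archives are versioned JSON rather than HDF5, and configs are
JSON rather than YAML: the deployment environment provides no R HDF5 or
YAML bindings, and plain text keeps archives reviewable; numbers are
serialized with 17 significant digits, which round-trips doubles
exactly.

## Known limitations

* Explicit Euler only: time steps scale as $\mathrm{dx}^4$; long
  strongly-interacting 2D runs are expensive.  No implicit or spectral
  integrator is provided by design.
* Two reacting species, equal molecular volumes, no growth, flows,
  thermal noise or curved geometry.
* The analytic supplementary expression for $\chi^*$ is not reproduced
  symbolically; `chi_star()` is numerical (bisection) by design.
* Mobility is $D_i\phi_i$ exactly as printed; a crowding-corrected
  variant (e.g. $D_i\phi_i(1-\phi_i)$) can be swapped in by replacing
  one isolated face-mobility function in the C++ core, but is not
  exposed.
* Desk-scale "stationary" states are operational (fixed, documented
  end times), not asymptotic — coarsening in 1D is logarithmic, so
  lengths in phase-separated regimes keep creeping at any affordable
  budget.
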