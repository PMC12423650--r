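---
title: "Self-propulsive active nematics: model, numerics and estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-propulsive active nematics: model, numerics and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The package simulates a two-dimensional active nematic whose constituents
both exert dipolar active stresses and self-propel. Orientational order is
carried by the symmetric traceless tensor
$Q_{ij} = 2q\,(n_i n_j - \delta_{ij}/2)$, stored as the component pair
$(Q_{xx}, Q_{xy})$ so tracelessness and symmetry are exact by
representation; $q$ is the order magnitude and $\hat n$ the director
(defined modulo $\pi$). The order parameter evolves by a Beris–Edwards
equation with an additional *polar self-advection* term,

$$\partial_t Q_{ij} + (v_k + V_0\,p_k)\,\partial_k Q_{ij}
  = \Gamma H_{ij} + S_{ij},$$

where $\Gamma$ is a rotational mobility, $H_{ij} = -\delta F/\delta Q_{ij}$
the molecular field of the free energy

$$F = \int \mathrm{d}A\left[\tfrac{K}{2}\,(\partial_k Q_{ij})^2
   + A\,(1 - Q_{ij}Q_{ji})^2\right],$$

and $S_{ij}$ the generalized co-rotation term coupling $Q$ to the strain
rate $E$ and vorticity tensor $W$ through the flow-alignment parameter
$\lambda$. The bulk term selects $Q_{ij}Q_{ji} = 1$, i.e.
$q = 1/\sqrt 2$. The novel ingredient is the self-advection velocity
$V_0\,\vec p$: each rod-like particle moves at speed $V_0$ along one of
the two director directions, and the sign is slaved to the flow — $\vec p$
is $+\hat n$ or $-\hat n$, whichever has positive projection on the local
velocity. Ties (zero velocity, or flow numerically perpendicular to the
director) keep the previous sign, which prevents chattering; the initial
polarity is $+\hat n$.

The flow obeys the incompressible Navier–Stokes equation
$\rho(\partial_t + v_k\partial_k)v_i = \partial_j \sigma_{ij}$ with
viscous, passive (elastic) and active stresses; the active part is
$\sigma^{\text{active}}_{ij} = -\zeta Q_{ij}$ with $\zeta > 0$ the
extensile dipolar activity. The passive stress includes the
flow-alignment terms, the antisymmetric $QH - HQ$ torque and the
distortion (Ericksen) term $-K\,\partial_i Q_{kl}\,\partial_j Q_{kl}$.
The isotropic pressure is *not* added to the forcing: the lattice
Boltzmann equation of state supplies it, and adding both would
double-count.

Reference parameters (lattice units): $\rho = 40$, $\eta = 20$
($\nu = 1/2$), $\lambda = 0.2$, $\Gamma = 0.1$, $K = 0.05$, $A = 0.1$,
$\zeta = 0.05$, on a periodic square lattice.

## Numerical scheme

The flow solver is a D2Q9 lattice Boltzmann method: BGK collision with
relaxation time $\tau = 3\eta/\rho + 1/2$ (so the kinematic viscosity is
$c_s^2(\tau - 1/2) = \eta/\rho$ with $c_s^2 = 1/3$), second-order Guo
forcing with the half-step velocity shift, and periodic streaming. The
body force is the central-difference divergence of the passive + active
stress. The scheme is weakly compressible; all production configurations
stay below Mach $\approx 0.1$, and the solver aborts on $|v| > 0.3$.

The order parameter uses second-order central differences for all
gradients and Laplacians and *first-order upwind* differences for the
advection by $v + V_0\,p$ — for this hyperbolic term stability dominates
accuracy at the speeds of interest. Time stepping is explicit Euler at
the lattice Boltzmann step $\Delta t = 1$; `q_substeps` sub-cycles the
order-parameter update if stiffer parameters are explored. Upwinding
adds a numerical diffusivity $\approx (|v| + V_0)/2$ to the order
parameter; at the ordering optimum ($V_0 = 0.06$) this exceeds the
elastic diffusivity $\Gamma K$, which is the main accuracy caveat of the
scheme at large self-propulsion.

One coupled step is ordered as: (1) velocity from the distribution
moments with the previous force's half-step correction, (2) polarity
assignment from the current $(Q, v)$, (3) order-parameter update, (4)
molecular field and stress from the *updated* $Q$, (5) collision and
streaming with the new force. The ordering is fixed because it affects
results at floating-point level; runs are bitwise reproducible for a
given seed, and a restart from a checkpoint equals the uninterrupted run.

Initial conditions: `aligned` (director along $x$ at the bulk minimum
$q = 1/\sqrt2$ when $A > 0$, plus uniform noise of amplitude 0.01 on both
tensor components, optionally with one seeded Fourier mode) or `random`.

## Linear stability of the aligned state

Perturbing the uniformly aligned state $(Q_{xx}, Q_{xy}, \omega) =
(1, 0, 0)$ with polarity $(1, 0)$ by single Fourier modes
$e^{iq(nx + my)}$, $q = 2\pi/L$, reduces the dynamics to a $3\times 3$
complex Jacobian per mode on $(\delta Q_{xx}, \delta Q_{xy},
\delta\omega)$ (`stability_jacobian()`). The derivation uses the
incompressible vorticity formulation; self-advection enters as
$-i V_0 q n$ on both tensor rows. For the longitudinal mode $(1, 0)$ the
$\delta Q_{xx}$ row decouples and the coupled block gives the closed-form
eigenvalue pair (`lambda_10()`)

$$\Lambda_{10} = \tfrac{a + d}{2} \pm
  \sqrt{\left(\tfrac{a - d}{2}\right)^2 + b\,c},$$

with $a = -iqV_0 - \Gamma(Kq^2 + 4A)$, $d = -(\eta/\rho)q^2$,
$b = q^2\,[\zeta + 12\lambda A - (2{+}\lambda)Kq^2]/\rho$ and
$c = (2{+}\lambda)/2$.

Two design points deserve emphasis:

* **The Jacobian is the ground truth.** It is validated against a fully
  independent numerical linearization (`stability_jacobian_fd()`):
  directional derivatives of the nonlinear right-hand side evaluated
  spectrally on a coarse grid, agreeing to $10^{-6}$ and better across
  random parameter sets. The closed forms are then checked against the
  Jacobian, not vice versa.
* **Bulk-term corrections.** The aligned base state with $q = 1$ is not a
  stationary point of the $A > 0$ free energy (the minimum sits at
  $q = 1/\sqrt2$), so a strict linearization about it carries the $A$
  terms shown above; the classical dispersion without them is recovered
  exactly at $A = 0$, and `lambda_10()` reduces to the familiar radical
  expression in that limit. Simulation–theory comparisons therefore run
  at $A = 0$, where the $q = 1$ aligned state is an exact stationary
  state of the nonlinear system and theory and simulation answer the same
  question.

The instability threshold `critical_v0()` is found by bisection on
$\max\mathrm{Re}\,\Lambda_{10}(V_0) = 0$ (tolerance $10^{-10}$) and
cross-checked against the analytic $A = 0$ zero crossing
(`critical_v0_closed()`); above the elastic threshold it scales as
$V_0^* \propto \sqrt\zeta$, the balance of the order-parameter time scale
$\tau_Q = \Gamma K/V_0^2$ and the active-viscous time scale
$\tau_v = \eta/\zeta$ (`timescales()`).

**Stability probes.** The numerical side of the phase diagram seeds a
$(1,0)$ mode of amplitude $10^{-4}$ on $Q_{xy}$ and classifies by the
sign of the growth rate of $\overline{Q_{xy}^2}$ fitted over steps
500–5000. The probe runs on a uniform background flow
$v_{x,0} = 10^{-3}$: a pure Galilean boost (it shifts eigenvalues only by
$-iqnv_{x,0}$) that keeps the flow's $x$-component positive so the
polarity stays $+\hat n$ everywhere, which is precisely the sign
convention under which the linear theory is derived. Without it, the
seeded mode's weakly compressible $v_x$ noise flips the polarity sign
from site to site — a nonlinear mechanism outside the linearized
description that measurably destabilizes marginally stable states.

## Defect statistics and hyperuniformity

`detect_defects()` accumulates the nematic winding of the director angle
around every unit plaquette (differences folded into
$(-\pi/2, \pi/2]$); windings of $\pm\pi$ mark $\pm 1/2$ defects at the
plaquette center. No sub-pixel refinement is applied — defect spacings of
interest are tens of sites. Charge neutrality holds exactly on periodic
fields.

`structure_factor()` evaluates
$S(q) = |\sum_j e^{-i\,\vec q\cdot\vec r_j}|^2/N$ on the allowed
wavevectors with $|q| \le q_{\text{upper}} = 1/4$, bins by $|q|$
(orientational average) and averages over snapshots; the $1/N$
normalization makes the Poisson expectation exactly 1. `fit_alpha()`
fits $S \sim q^\alpha$ over the lowest decade of retained wavevectors.
`number_variance()` places random circular windows (periodic
minimum-image counting, 25 log-spaced radii in $[L/100, L/10]$,
$10^4$ windows per radius by default) and fits
$\sigma_N \propto \langle N\rangle^\beta$ — the standard-deviation
convention, the only one consistent with both $\beta = 1/2$ for uniform
patterns and the map $\beta = \tfrac12(1 - \alpha/d)$, $d = 2$
(`beta_from_alpha()`).

The estimators are validated against constructions with known exponents:
Poisson ($\alpha = 0$, $\beta = 1/2$), jittered lattices
($\beta < 1/2$), Thomas cluster processes ($\beta > 1/2$), lattices
displaced by symmetric $\alpha$-stable jumps (prescribed
$S \sim q^{\alpha}$ with $0 < \alpha \le 2$, via the stable
characteristic function), and Cox processes whose clipped-Gaussian
intensity carries a band-limited power-law spectrum (prescribed
$\alpha < 0$). Two estimator biases are worth knowing about: the $+1$
Poisson floor flattens $\hat\alpha$ when the clustering amplitude is not
well above 1 in the fit window (the Cox default amplitude is chosen to
avoid this), and saturation of $S \le 1 - e^{-x}$ bends the
stable-lattice slope at the top of the window, so its displacement scale
is kept small.

## Flow statistics

Energy and enstrophy spectra are isotropic shell sums of $|\hat v(q)|^2$
and $|\hat\omega(q)|^2$ (vorticity by the solver's central differences),
normalized so the shells sum to $\langle|v|^2\rangle/2$ and
$\langle\omega^2\rangle/2$ exactly (Parseval, asserted on every
snapshot). Wavenumbers are reported in units of the box mode $2\pi/L$.
Power-law exponents are fitted over configurable windows (defaults:
kinetic energy over $q \in (1, L/8]$; enstrophy small-$q$ exponent $b$
over $(1, 8]$). The real-space vorticity correlation (FFT
autocorrelation, radially averaged) yields the decay exponent $\nu$ over
$r \in [L/8, L/3]$ by default, related to the enstrophy exponent by
$\nu = b + 1$; the package exercises this Fourier-pair identity on
synthetic random-phase fields. On a finite box the missing $q < 2\pi/L$
modes subtract a constant offset $\propto q_{\min}^{1+b}$ from $C(r)$,
which steepens apparent slopes when $b \le 0$; the synthetic check
therefore uses $b = +1/2$ where the offset is negligible.

The director correlation $C_{nn}(r) = \langle Q(x){:}Q(x{+}r)\rangle /
\langle Q{:}Q\rangle$ is the only sign-unambiguous nematic estimator
(equal to the order-weighted $\langle\cos 2\Delta\theta\rangle$); the
correlation length $l_c$ is its interpolated $1/e$ crossing, flagged and
capped at $L/2$ when the curve never crosses.

`anisotropy_correlations()` quantifies rotational symmetry breaking: at
sampled reference sites the velocity field is decomposed in the frame of
the local flow direction, and the autocorrelations of the parallel and
perpendicular component fields are radially averaged. Because rotating
components commutes with radial averaging, each site's curves are exact
linear combinations of three FFT cross-correlation profiles computed
once per snapshot — making the estimator cheap and exactly invariant
under global rotations of the velocity components. Statistical isotropy
implies $l_\parallel = l_\perp$ identically for this estimator, matching
the observation that the purely nematic state shows overlapping parallel
and perpendicular curves. The positive-control fixture is a `banded`
flow (coherent bands plus isotropic small-scale noise): for
divergence-free *Gaussian* fields with a smooth anisotropic envelope the
transverse polarization redistributes spectral weight so that
$l_\parallel > l_\perp$ is *not* achieved — coherent, flow-aligned
structure, not mere spectral anisotropy, is what the estimator detects.

## Study conditions and problem sizes

The package's validation suite runs at desk scale, chosen once:

* Stability grid: $L = 256$, $\zeta \in \{0.002, 0.005, 0.01\}$,
  $V_0 \in \{0.01, 0.2, 0.4\}$, probes of 5000 steps. The grid spans both
  sides of the critical curve $V_0^*(\zeta) \in [0.07, 0.17]$ with
  comfortable margins, since upwinding shifts the effective simulated
  threshold downward slightly.
* Turbulence at $V_0 = 0$: $L = 128$, $\zeta = 0.05$, $A = 0.1$, random
  initialization, 6000 warmup steps (several instability e-folding and
  saturation times), then 20 snapshots every 300 steps ($\approx$ the
  active-viscous time $\tau_v = 400$). This yields a steady gas of
  $\sim 40$ defects whose number variance reproduces the uniform
  $\beta = 1/2$ within 0.05.
* Self-propulsion comparison: $L = 256$, $V_0 \in \{0, 0.06\}$, 5000
  warmup steps and 10 snapshots every 400 steps. The directional
  correlation length grows several-fold at $V_0 = 0.06$ (from
  $l_c \approx 6$ to $\gtrsim 50$ sites) and the distortion-energy
  density $\rho_e = \langle E/\max E\rangle$ drops an order of
  magnitude — the enhancement of order is robust at this scale. The
  accompanying shift of the defect fluctuation exponent is *not*
  resolvable at $L = 256$: the strongly ordered state retains only
  $\sim 4$–$8$ defects in the whole box, so windows at radii
  $\le L/10$ have $\langle N\rangle \lesssim 0.2$ and near-Bernoulli
  counts whose standard deviation is pinned to
  $\sqrt{\langle N\rangle}$; the measured exponent rises only to
  $\approx 0.53$ against $\approx 0.47$ at $V_0 = 0$. Resolving the
  giant-number-fluctuation regime requires the defect-rich statistics of
  much larger lattices.

What the synthetic fixtures do and do not show: they validate the
*estimators* (winding detection, spectral normalizations, exponent fits,
the $\alpha \leftrightarrow \beta$ map, the $\nu = b + 1$ identity) on
patterns with known ground truth. They do not emulate full active
turbulence — those statistics come from the solver itself.

## Degenerate inputs and tie-breaks

* $q = 0$ sites take $\theta = 0$ by convention; polarity there follows
  the tie rule (the advective term is $O(q)$, so the choice is inert).
* Polarity ties ($|v| < 10^{-12}$ or $|v\cdot\hat n| <
  10^{-12}|v|$) keep the previous sign.
* Zero-variance vorticity fields and uniform order fields are rejected
  by the correlation and energy summaries rather than silently returning
  constants.
* The upwind advection falls back to the forward difference at exactly
  zero carrier velocity; with a uniform carrier the advective term
  telescopes and conserves the lattice sums exactly.

## Interfaces

Configurations for the command-line runner are YAML files whose keys are
exactly the model symbols (`rho, eta, lam, Gamma, K, A, zeta, V0, L`)
plus run control; a thin CLI over the exported functions lives at
`inst/cli/activenem.R` (`simulate`, `stability`, `analyze` subcommands).
Trajectories are in-memory R objects with CSV writers for diagnostics,
defect lists and curves; snapshot persistence beyond CSV is left to the
caller (`saveRDS` on the trajectory).

## Known limitations

* Weakly compressible flow (Mach $\lesssim 0.1$), BGK single relaxation
  time.
* First-order upwind self-advection adds $O(V_0/2)$ numerical
  diffusivity to the order parameter; sub-cycling reduces the time-step
  part of the error but not the spatial part.
* Defect positions are plaquette centers (1-site accuracy); no defect
  tracking or orientation analysis.
* The linear theory's polarity is fixed at $+\hat n$; the solver's
  dynamic sign rule can depart from it in near-quiescent states (see the
  stability-probe discussion above).
* 2D only; no anchoring boundaries (fully periodic), no thermal noise.
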