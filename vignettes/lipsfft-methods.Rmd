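---
title: "Split isotropic-periodic-sum electrostatics on a mesh: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split isotropic-periodic-sum electrostatics on a mesh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipsfft)
```

## The model

Isotropic periodic sum (IPS) methods treat long-range interactions under
periodic boundary conditions by surrounding each pair with isotropically
distributed periodic images inside a cutoff sphere of radius $R_c$, rather
than with the explicit image lattice of an Ewald sum. The net effect is a
*pseudo pair potential*

$$u_\mathrm{eff}(r, R_c) = u(r) + \varphi(r, R_c),$$

where $u$ is the bare interaction (here the charge-normalized Coulomb
potential $1/r$) and $\varphi$ is the reaction field of the images. The
linear-combination-based family (LIPS) provides reaction fields accurate
enough to rival lattice sums, but requires $R_c$ of the order of half the
box length, which makes a naive real-space pair sum over $r < R_c$ the
dominant cost.

This package implements the split evaluation that removes that cost. With
an auxiliary short-range cutoff $r_c < R_c$:

$$
u_S(r) = u_\mathrm{eff}(r, r_c) - u_\mathrm{eff}(r_c, r_c), \quad r < r_c;
\qquad
u_B(r) = u_\mathrm{eff}(R_c, R_c), \quad r < R_c;
$$
$$
u_L(r) = u_\mathrm{eff}(r, R_c) - u_S(r) - u_B(r), \quad r < R_c;
$$

each zero beyond its cutoff, so $U = U_S + U_L + U_B$ exactly. Two
properties make the split useful:

* $u_L$ is **bounded**: the $1/r$ singularities of
  $u_\mathrm{eff}(r, R_c)$ and $u_S$ cancel algebraically, leaving
  $u_L(r < r_c) = \varphi(r, R_c) - \varphi(r, r_c) +
  u_\mathrm{eff}(r_c, r_c) - u_\mathrm{eff}(R_c, R_c)$, finite down to
  $r = 0$ whenever the plugged-in $\varphi$ is finite there (part of the
  plug-in contract). The implementation evaluates $u_L$ in this cancelled
  form, so the limit `long_range_at_zero()` is analytic; a Richardson
  extrapolation fallback covers plug-ins whose $\varphi$ cannot be called
  at zero.
* $u_B$ is a **constant** inside $R_c$, hence force-free; it is summed by
  a direct double loop (with $R_c \approx L/2$ essentially every pair
  contributes, so a neighbor search would not help).

$U_S$ is summed in real space over a cell list with cell edge at least
$r_c$. $U_L$, smooth and compactly supported, goes to a mesh.

## The mesh path

Charges are spread onto a $K_1 \times K_2 \times K_3$ grid with cardinal
B-splines $M_n$ of even order $n$ (scaled fractional coordinates
$w_\alpha = K_\alpha r_\alpha / L_\alpha$, $n$ nodes per axis, periodic
wrap), giving the charge array $Q$ with $\sum Q = \sum_i q_i$ by the
partition of unity. The long-range potential is tabulated pointwise at
grid-node displacements as the energy array $\Phi^*$ (minimum image over
the $\{-1,0,1\}^3$ shifts, strictly zero at distances $\ge R_c$, with the
origin entry $u_L(0)$). The energy is the discrete convolution

$$U_L \simeq \frac{1}{2 K_1 K_2 K_3} \sum_m B(m)\, |F(Q)(m)|^2\,
F(\Phi^*)(m),
\qquad B = |b_1|^2 |b_2|^2 |b_3|^2,$$

where the $b_i(m)$ are the reciprocal B-spline factors and $F$ the
unnormalized forward FFT. The placement of the $1/(K_1K_2K_3)$
normalization and of $B$ is fixed once (in `long_range_energy()`) by the
contract that $U_L$ converge to the direct pairwise sum
$\tfrac12\sum_{ij} q_i q_j u_L(r_{ij})$ as the grid is refined; the tests
pin the convention through the brute-force oracle rather than through any
transcription of a formula. Two derived facts worth recording:

* The quadratic form includes the $i = j$ diagonal, i.e. the self energy
  $\tfrac12 (\sum_i q_i^2)\, u_L(0)$. Because $u_L(0)$ is a finite
  constant, `total_energy_forces()` subtracts it exactly by default; a
  flag retains the uncorrected value for comparisons with
  implementations that absorb it.
* Mesh forces are the **exact gradient of the discrete energy**: with
  $\Phi^*$ and $B$ fixed, $\partial U_L / \partial Q(k)$ is the convolved
  grid potential, and $\partial Q / \partial r_{\alpha i}$ follows from
  $M_n'(w) = M_{n-1}(w) - M_{n-1}(w-1)$ with the chain factor
  $K_\alpha/L_\alpha$. Finite differences agree to $10^{-10}$ relative,
  independent of the grid spacing. Accuracy *against the continuum pair
  sum* is a separate question, controlled by the spacing.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `r_c` | 1.0 (nm in physical use) | short-range cutoff; splits real-space from mesh work |
| `R_c` | `L/2` | reaction-field cutoff; `R_c <= min(L)/2` is enforced everywhere |
| `spacing` | 0.1 | target mesh spacing; `K = ceiling(L/spacing)` per axis |
| `order` | 8 | B-spline order; must be even (odd orders can zero the reciprocal denominator at the Nyquist mode), `K >= 2n` per axis |
| `coulomb_prefactor` | 1 | unit-system constant multiplying `q_i q_j u(r)`; reduced units by default, settable for physical unit systems |
| `self_correction` | `TRUE` | subtract the mesh self term |

Reciprocal modes whose spline denominator modulus falls below $10^{-10}$
are assigned $B = 0$. At a distance exactly equal to a cutoff the zero
branch of each split component is taken; the nonzero branches vanish there
by continuity, so the choice only fixes behavior on a measure-zero set.

## Reaction-field plug-ins

Closed-form LIPS reaction fields are published as coefficient sets; the
machinery here is potential-agnostic, so $\varphi$ is a plug-in satisfying
the `pair_potential` contract ($u$ finite and differentiable for $r > 0$;
$\varphi$ finite on $[0, R_c]$). Shipped:

* `coulomb_potential()` — the null field $\varphi \equiv 0$ (shifted
  truncated Coulomb), the degenerate baseline;
* `poly_reaction_field(c0..c5)` — $\varphi = (1/R_c)\sum_k c_k (r/R_c)^k$,
  into which published coefficients can be entered;
* `reaction_field_potential()` — the continuum reaction field
  $1/r + r^2/(2R_c^3) - 3/(2R_c)$, whose value *and* derivative vanish at
  $R_c$.

The smoothness of the plug-in matters for mesh accuracy: $\Phi^*$ samples
$u_L$ pointwise, and the trigonometric interpolation underlying the
convolution converges with the smoothness of $u_L$. Fields that go
smoothly to zero at their cutoff (as practical reaction fields do — that
is their design goal) leave $u_L$ with continuous derivative at both
$r_c$ and $R_c$ and converge quickly; the null field has derivative kinks
at both cutoffs and converges visibly more slowly, with
sign-oscillating error. For this reason the refinement studies in the
test suite and the acceptance script use the continuum reaction field as
the representative operating point, and exercise the null field in the
algebraic identities (split, closure, boundary closed form), which hold
for any plug-in. The zero-distance limit also has a closed form for the
null field, $u_L(0) = 1/r_c - 1/R_c$, used as a test oracle.

## Verification strategy and problem sizes

Every mesh quantity is validated against the brute-force $O(N^2)$
minimum-image oracle (`direct_lips()`, `direct_long_range()`), which
shares no code with the mesh path beyond the potential definitions. The
validation sizes were chosen as the smallest systems that exercise every
code path with comfortable statistics: random neutral systems of $N = 64$
in a $4^3$ box with $r_c = 1$, $R_c = 2$ for refinement studies
(spacings 0.2, 0.1, 0.05); $N = 10$ for finite-difference force checks;
a 32-ion melt in a $3.5^3$ box ($K = 16$, order 8, $dt = 0.004$,
equilibrated by velocity rescaling at $T = 0.3$, then 2000 NVE steps) for
energy conservation; 100 Brownian walkers over 1000 steps for the
Einstein-relation recovery; 256 uniform particles over 40 frames for the
ideal-gas radial distribution; and two 50-charge sheets for the capacitor
potential step.

## Observables

* `rdf()` implements the
  $g(r) = V/(4\pi r^2 \Delta r\, N(N-1)) \sum_i n_i(r)$ normalization
  exactly as written (ordered neighbor counts, no pair factor 2) — users
  comparing with codes that use a $N(N-1)/2$ convention should note this.
* `msd_diffusion()` fits $D = \mathrm{slope}/6$ of the mean-squared
  displacement after unwrapping by accumulated minimum-image
  displacements. The MSD is averaged over particles and over strided time
  origins — equivalent in expectation to the single-origin Einstein
  formula, and the field-standard variance reduction. The default fit
  window $[t_\mathrm{max}/4,\, t_\mathrm{max}/2]$ avoids the ballistic
  start and the poorly averaged tail; a log-log slope diagnostic flags
  non-diffusive input (slope $\approx 2$ for ballistic motion). With 100
  walkers over 1000 steps the long-lag MSD is dominated by the walkers'
  endpoint spread, so recovered $D$ values scatter by several percent
  around the truth regardless of origin averaging.
* `potential_profile()` performs the double Poisson integration
  $\psi(z)-\psi(0) = -(1/\varepsilon_0)\iint \rho_c$ with two cumulative
  trapezoid passes over bin centers, referenced to the first bin (the
  vacuum side in slab geometries). For parallel charged sheets the
  discrete double trapezoid reproduces the capacitor step
  $\sigma d / \varepsilon_0$ exactly, which the tests exploit.
* `vacf()` and `density_profile()` are direct transcriptions of their
  definitions.

## The toy MD loop

`run_md()` integrates leapfrog (kick-then-drift, half-step velocities;
logged kinetic energies use the on-step average
$(v_{t-dt/2}+v_{t+dt/2})/2$) over the split electrostatic forces plus a
shifted soft-sphere $r^{-12}$ repulsion. Design notes:

* The mesh force field is strictly conservative (exact discrete
  gradient), so NVE drift measures integrator and stencil-crossing error
  only. The *boundary* term can jump when a pair crosses $R_c$ unless
  $u_\mathrm{eff}(R_c, R_c) = 0$; the shipped continuum reaction field
  satisfies this, which is one more reason it is the default for MD.
* B-spline interpolation leaves a small net force (a known property of
  particle-mesh methods); `remove_net_force = TRUE` subtracts the mean
  each step, keeping linear momentum at round-off. The exact-gradient
  property is tested on the raw mesh forces, before this correction.
* Secular drift is measured as the difference of mean total energy over
  the first and last 5% of the run, relative to the mean total energy —
  insensitive to the bounded $O(dt^2)$ leapfrog fluctuation. The 32-ion
  melt benchmark gives drift below $10^{-4}$ over 2000 steps.
* The thermostat is plain velocity rescaling at fixed intervals —
  sufficient for equilibrating test systems, not a claim of canonical
  sampling.

## What the synthetic generators do and do not emulate

The generators provide neutral random ionic packings (uniform positions
with a hard minimum-separation rejection), dipolar slabs with vacuum
margins, controlled two-body configurations, and Brownian walks of known
diffusion coefficient. They emulate the *geometric and statistical
features* the algorithms depend on — neutrality, periodic wrapping,
heterogeneous density, known ground truths — but not the structure of
real molecular systems: no molecular connectivity or constraints, no
realistic liquid structure, no polarization, and point charges rather
than partial-charge sites. Passing tests therefore demonstrate
correctness of the numerics and internal consistency of the method, not
simulation fidelity for any specific molecular model.

## Known limitations

* Orthorhombic boxes only; triclinic cells are out of scope.
* The published closed-form LIPS coefficient sets are not bundled; they
  enter through `poly_reaction_field()`.
* Screening-type reaction fields built on explicit countercharges are not
  modeled.
* No Ewald/SPME reference implementation is included; the accuracy
  baseline is the direct pairwise oracle, which is exact for the pseudo
  pair potential but not a lattice sum.
* Atom-based cutoffs only (each point charge is its own interaction
  site); no group/molecule-based cutoff or site aggregation.
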