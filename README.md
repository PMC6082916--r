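# lipsfft

Electrostatic energies and forces for periodic point-charge systems using
isotropic-periodic-sum (IPS/LIPS) pseudo pair potentials, with the
long-range part evaluated on a mesh by cardinal B-spline charge spreading
and FFT convolution.

## Who this is for

Molecular-simulation developers and method researchers who want a
cutoff-based alternative to lattice sums (Ewald/SPME) for Coulomb
interactions. IPS-family methods replace the lattice of periodic images by
an isotropic distribution of images inside a cutoff sphere of radius
`R_c`, which removes the artificial lattice symmetry of Ewald sums; the
linear-combination-based variant (LIPS) reaches lattice-sum-class accuracy.
Its historical cost — the reaction-field pair sum must run to `R_c ≈ L/2`
in real space — is removed here by an SPME-style mesh path for the bounded
long-range remainder.

## The method

A pseudo pair potential combines the bare interaction with a reaction
field,

    u_eff(r, R_c) = u(r) + phi(r, R_c),          e.g. u(r) = 1/r,

and is split at an auxiliary short-range cutoff `r_c < R_c` into

    u_S(r) = u_eff(r, r_c) − u_eff(r_c, r_c)      (r < r_c, else 0)
    u_B(r) = u_eff(R_c, R_c)                      (r < R_c, else 0)
    u_L(r) = u_eff(r, R_c) − u_S(r) − u_B(r)      (r < R_c, else 0)

so that `U = U_S + U_L + U_B`. `u_S` is summed in real space through a
cell list, `u_B` is a force-free constant term, and `u_L` — bounded,
because the `1/r` singularities cancel — is evaluated on a mesh:

1. charges are spread onto a `K1 × K2 × K3` grid with cardinal B-splines
   of order `n` (charge array `Q`);
2. `u_L` is tabulated at grid-node displacements (energy array `Φ*`,
   minimum-image, zero beyond `R_c`);
3. `U_L = 1/(2 K1 K2 K3) Σ_m B(m) |F(Q)|² F(Φ*)`, where `B = |b1 b2 b3|²`
   are the squared-modulus reciprocal spline factors that deconvolve the
   spreading, and `F` is the FFT;
4. forces are the exact analytic gradient of the discrete energy via the
   B-spline derivative identity `M_n'(w) = M_{n−1}(w) − M_{n−1}(w−1)`.

The mesh convolution inherently carries the `i = j` self energy
`(1/2) Σ q_i² u_L(0)`; `u_L(0)` is a finite constant, so it is subtracted
exactly by default. Every mesh result can be checked against the included
brute-force `O(N²)` minimum-image oracle. The constraint `R_c ≤ L/2` is
enforced throughout. Reaction fields are plug-ins: a null field (shifted
truncated Coulomb), a six-coefficient polynomial family into which
published LIPS coefficients can be entered, and the classic continuum
reaction field `1/r + r²/(2R_c³) − 3/(2R_c)` are shipped.

The package also provides trajectory observables (radial distribution
function, velocity autocorrelation, Einstein-relation diffusion, mass
density and electrostatic potential profiles), deterministic synthetic
generators, and a minimal leapfrog MD loop for energy-conservation
studies.

## Worked example

```r
library(lipsfft)

sys  <- random_neutral_system(64, box = 4, seed = 1)   # 32 (+1), 32 (−1)
sp   <- split_potential(reaction_field_potential(), r_c = 1.0, R_c = 2.0)
mesh <- mesh_config(sys$box, spacing = 0.1, order = 8)

res <- total_energy_forces(sys, sp, mesh)
print(res)
#> <force_energy> lips_fft  U_S = 5.0329823  U_L = -4.2739151  U_B = 0  U_total = 0.75906725

ref <- direct_lips(sys, sp)                            # O(N^2) oracle
force_rmsd(res$forces, ref$forces)
#> [1] 0.008423652
abs(res$U_total - ref$U_total) / abs(ref$U_total)
#> [1] 0.0006666376
```

`U_S` is the real-space short-range energy, `U_L` the FFT long-range
energy (self term removed), and `U_B` the boundary constant — zero here
because the continuum reaction field vanishes at its cutoff. At a 0.1 grid
spacing the mesh total agrees with the direct pairwise sum to 0.07%, with
a force RMSD (`delta_f`, `3N − 1` denominator) of 0.0084 in reduced force
units; halving the spacing reduces both further. Energies are in reduced
units (`coulomb_prefactor = 1`); set the prefactor for physical unit
systems.

A command-line front end with the same functionality is installed at
`inst/scripts/lipsfft` (subcommands `gen`, `energy`, `oracle`, `compare`,
`analyze`, `md`).

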