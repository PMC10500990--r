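---
title: "Vibronic models of aggregating chromophores: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibronic models of aggregating chromophores: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vibronic)
```

## The model

`vibronic` works with linear vibronic coupling (LVC) Hamiltonians over a
set of diabatic electronic states |d_i> and the dimensionless normal
coordinates **q** of the electronic ground state,

    H = sum_a w_a (p_a^2 + q_a^2) / 2 + V(q)
    V_ii(q) = E_ii(0) + lambda_ii . q
    V_ij(q) = E_ij(0) + lambda_ij . q        (i != j)

with all energies in eV, time in fs (hbar = 0.6582119569 eV fs) and
transition dipoles in atomic units. The diabatic states have fixed
electronic character: local excitations (LE), which carry a constant
transition dipole from the ground state (Condon approximation), and
charge-transfer (CT) states, which are dark. Inter-state couplings are
constants except for the Jahn-Teller (JT) pairs -- the two
quasi-degenerate LEs of a fourfold-symmetric chromophore -- where the
constant term vanishes by symmetry and a linear coupling vector is the
leading term.

Dimer Hamiltonians (`assemble_dimer_hamiltonian()`) are built on stacked
monomer coordinates q_dim = (q1, q2) from fragment-level data: LE
gradients are block-padded with zeros (the LE on monomer 1 displaces
only monomer-1 modes), CT gradients are concatenated ionic gradients
(cation block for the monomer hosting the hole, anion block for the one
receiving the electron), and the eight states follow a fixed, labelled
ordering |L1>, |L1'>, |L2>, |L2'>, |CT(1->2)>, |CT'(1->2)>, |CT(2->1)>,
|CT'(2->1)>. Serialized parameter files always carry explicit state
labels, so ordering is never inferred from file position, and unknown
keys in a parameter file are an error rather than being ignored.

## Wavepacket propagation

Spectra and populations require the correlation functions

    phi_ji(t) = <d_j; 0 | exp(-i H t / hbar) | d_i; 0>

where |0> is the ground vibrational wavepacket. `propagate()` works in
a truncated harmonic-oscillator product basis (`build_basis()`, up to
`n_max` quanta per mode). Energies are measured from the
ground-vibrational reference: the shared zero-point energy is dropped
from the Hamiltonian matrix, which is exactly equivalent to setting the
|g; 0> energy to zero and makes the correlation phases feed directly
into the lineshape transform.

Two propagation routes are provided and cross-checked against each
other:

* dense diagonalization for dimensions up to 4000 (default for
  dimensions below 1500): exact and unitary in the basis, and all
  requested times come from one decomposition;
* short-iterative Lanczos (Krylov) otherwise, with default subspace
  order 15, step 0.1 fs, and a per-step error estimate checked against
  a 1e-9 tolerance (the step fails loudly, suggesting a smaller `dt`,
  rather than silently degrading).

Basis adequacy is monitored by the *top-level occupancy*: the largest
population found in any mode's highest oscillator level over the run.
The default policy (`propagate_converged()`) enlarges `n_max` by 2
until this diagnostic drops below 1e-6; the test suite verifies that
enlarging the basis changes 50-fs populations by less than the
diagnostic itself, so the reported occupancy is a usable error proxy.
Wavepacket snapshots are stored on a decimated grid (default 0.5 fs) to
bound memory; they feed `populations_in_combination_basis()`, which
projects on *fixed* coefficient combinations of diabatic states (for
example the Franck-Condon-point adiabatic vectors). These
"delocalized-state" populations deliberately use constant vectors, not
coordinate-dependent adiabatic states.

## Lineshapes

The absorption spectrum is assembled per state pair,

    eps_ij(w) = c(w) (mu_i . mu_j) 2 Re int_0^T dt
                e^{i w t / hbar} phi_ji(t) e^{-Gamma^2 t^2 / 2},

by trapezoid quadrature with the Hermitian extension phi(-t) = phi(t)*
implicit in the one-sided transform. A Nyquist guard rejects time grids
too coarse for the requested frequency grid. The Gaussian damping
parameter comes from the requested spectral width as
Gamma = HWHM / (hbar sqrt(2 ln 2)); the defaults are HWHM = 0.04 eV and
100 fs of propagation. `c(w) = w` is available behind the `prefactor`
flag, but the default output is shape-only and normalized to unit
maximum on request -- the overall molar-absorptivity constant is a
single configurable scalar deliberately left to the caller, since
published spectra are routinely compared after peak normalization.

For uncoupled (adiabatic) states the correlation function has the
closed vertical-gradient form implemented in `fcvg_correlation()`:

    phi(t) = exp(-i E_v t / hbar)
             exp(sum_a S_a (e^{-i w_a t / hbar} - 1 + i w_a t / hbar)),

with Huang-Rhys factors S_a = lambda_a^2 / (2 w_a^2). The
`+ i w_a t / hbar` term in the exponent is essential: it places the 0-0
line at E_v - sum_a S_a w_a, consistent with the Poisson stick
progression of `stick_spectrum_fcvg()` and with the propagator's
zero-point-referenced phases. (A common shorthand omits that term,
which leaves |phi| unchanged but shifts every stick to the vertical
energy; the package uses the physically consistent convention, and the
equivalence of the analytic and propagated routes is an acceptance
test.)

Conformer-resolved spectra are combined by `weighted_average_spectrum()`
as a pointwise convex combination with the cluster population weights.

## Hierarchical effective modes

Full chromophores have hundreds of modes; exact product-basis
propagation does not scale there. `build_hierarchy()` constructs an
orthogonal transformation whose first block spans all intra-state
gradients and linear couplings (SVD with a relative singular-value
threshold of 1e-8; block sizes are emergent, not fixed), and whose
subsequent blocks follow a block-Lanczos recursion generated by the
frequency matrix Omega itself (not Omega squared) -- with the LVC's
shared diagonal Omega this reduces to the standard chain construction.
Rotated Hamiltonians acquire a dense symmetric frequency matrix that
enters kinetic and potential terms identically (in dimensionless
coordinates an orthogonal rotation of q and p together keeps the two
bilinear forms equal and leaves the vibrational vacuum invariant, so
initial states need no transformation). Truncation
(`hems_truncate()`) keeps the leading blocks, retains their internal
bilinear couplings exactly, drops couplings to discarded modes and
reports the dropped norm. At full depth the transform is unitarily
equivalent to the input -- identical adiabatic energies and spectra to
numerical precision -- while short truncations reproduce the short-time
dynamics, hence the broadened spectral shape. Because the upstream
literature does not pin down one recursion variant or a formal
moment-matching order, the package asserts (and tests) monotone
convergence of the truncation error with depth rather than a specific
order.

## Conformations: clustering, weights, descriptors

Trajectory frames (multi-model PDB via bio3d, or plain XYZ) are
clustered with the Daura neighbor-count algorithm on pairwise RMSD
after unweighted Kabsch superposition, computed on the union of both
macrocycle-ring selections -- ring geometry governs dimer photophysics,
while flexible side chains would blur the clusters. RMSD is reported in
nm to match the conventional 0.10 nm cutoff; descriptors are in
Angstrom. Ties in neighbor count and in centrality are broken by the
lowest frame index, making the clustering deterministic and
permutation-invariant up to relabeling. Each cluster's central
structure is the member with the smallest mean RMSD to the others, and
cluster weights are the population fractions entering the weighted
spectrum.

The per-frame descriptors are: the metal-metal distance d_Zn-Zn; the
inter-ring distance d_P-P, computed as the mean absolute projection of
paired ring-atom displacements on the ring normal from an SVD plane fit
(rings are not assumed planar; the reference normal is ring 1's by
default, with an averaged-normal option); eight angles alpha_1..8
between the inter-metal vector and the four metal-to-pyrrole-nitrogen
reference axes of each ring, folded to [0, 90] degrees so that a
perfectly cofacial stack gives all alpha_i = 90; and the signed twist
beta between the rings' primary in-plane axes about the mean normal.
The exact axis convention is pluggable because no single community
standard exists; the implemented one reproduces the ideal-stack limits
(alpha_i = 90, beta = 0, d_P-P = d_Zn-Zn) and responds to rigid normal
translations exactly, which is what the tests pin down.
`linear_correlation()` (ordinary least squares, R^2 = 1 - SS_res/SS_tot,
with R^2 = 0 by convention for constant response) supports the
structure-property analyses, such as regressing LE-CT energy gaps or
late-time CT populations on stacking distances.

## The synthetic generators and what they do (not) show

All tests and the acceptance script run on generated inputs:

* `make_displaced_monomer()` -- single bright state with prescribed
  Huang-Rhys factors (lambda_a = w_a sqrt(2 S_a)).
* `make_jt_monomer()` -- two quasi-degenerate LEs with opposite tuning
  gradients and a linear inter-state coupling; the equal-frequency
  single-coupling-mode case is the E x e model with a conical
  intersection at q = 0. Note that at zero temperature its absorption
  band is *not* mirror-symmetric about the mean energy (progressions
  extend to the blue); the exact symmetry, which the tests assert, is
  E_+(q) + E_-(q) = 2E for every q.
* `make_kasha_ct_dimer()` -- the full 4 LE + 4 CT dimer template in the
  standard state ordering, built through the fragment-assembly route.
  Defaults: degenerate LEs at 2.0 eV, one 0.15 eV mode per monomer with
  S = 0.3 (a single dominant progression-forming mode keeps the full
  eight-state model exactly propagatable in seconds; a two-mode
  tuning-plus-coupling variant is available via `omega`), exciton
  coupling 0.05 eV, CT states 0.3 eV above the LEs, LE-CT transfer
  integral 0.05 eV, and ionic gradients at half the LE gradient. The H
  geometry stacks parallel dipoles (bright upper exciton); J flips
  them. Raising `ion_fraction` above 1 makes the CT minima more stable
  than the LE ones, which is the regime where close stacking funnels
  population into dark CT states; the acceptance script contrasts such
  a close-stack parameterization (near-resonant, strongly coupled,
  large CT reorganization) with a distant-stack one (high-lying, weakly
  coupled CT), reproducing the trapping-versus-no-transfer dichotomy.
* `make_stacked_trajectory()` -- rigid two-ring (idealized
  phthalocyanine-like macrocycle: metal center, four pyrrole nitrogens,
  eight ring carbons) frames around planted conformer centers with
  seeded Gaussian jitter. The default centers, (d, twist, tilt) =
  (3.4 A, 0, 0), (4.6 A, 80, 30) and (5.8 A, -80, -35) degrees with 12,
  5 and 3 frames and 0.05 A per-coordinate noise, were chosen once so
  the planted structure is well-conditioned for recovery at the 0.10 nm
  cutoff: between-center RMSDs are 0.21-0.35 nm (more than twice the
  cutoff) while within-cluster RMSD is about 0.014 nm (well under half
  the cutoff). Stacking distances sit in the physically populated
  3.5-6 A range; the large twists are what cleanly separates rigid
  ring stacks at this cutoff.

These generators emulate the *structure* of real inputs -- state
ordering, coupling classes, gradient block structure, cluster-weighted
conformer ensembles -- at toy scale. They do not emulate hundreds of
normal modes per monomer, solvent-induced fluctuations of CT energies
(inhomogeneous broadening), finite temperature, anharmonicity, or
frequency changes between surfaces (Duschinsky effects). Passing tests
therefore certify the machinery (propagation, transforms, sum rules,
clustering) and its exact limits, not quantitative agreement with any
laboratory spectrum; quantitative work requires measured parameter
files produced by an electronic-structure diabatization, which this
package consumes but does not compute.

## Numerical choices and degenerate inputs

* Krylov: order 15, dt 0.1 fs, per-step tolerance 1e-9; happy
  breakdown (invariant subspace) terminates the step early and is
  exact.
* Dense route limit 4000; `"auto"` switches at dimension 1500.
* Basis cap 5e6 amplitudes, with the error message pointing to the
  effective-mode reduction.
* Eigenvector conventions: ascending energies; the largest-magnitude
  component of each vector is made positive, which fixes signs
  deterministically, including across degeneracies, so composition
  tables are reproducible.
* Oscillator strengths use f = (2/3) dE[hartree] |mu[a.u.]|^2, exposed
  as a documented convention that can be switched off.
* Cluster weights are integer size fractions; their sum is exactly 1.
* Spectrum grids default to a 0.002 eV step spanning the diabatic
  energies plus reorganization and broadening margins.
* Degenerate inputs: a zero-mode basis (purely electronic Hamiltonian)
  is fully supported -- two-level Rabi dynamics is an acceptance test;
  an all-coincident coordinate set has RMSD 0 by definition; constant
  predictors are an error in the regression while constant responses
  give R^2 = 0.

Problem sizes throughout tests and the acceptance script (two-mode
monomers at n_max up to 14, eight-state dimers with one or two modes
per monomer, a 12-mode/2-state hierarchy toy whose six coupled modes
are propagated exactly, 20-frame trajectories) were chosen so the whole
suite certifies every exact identity and limit on a single CPU in a few
minutes while remaining converged, as monitored by the occupancy
diagnostic.

## Limitations

Beyond the generator caveats above: the package does not compute LVC
parameters from electronic structure (diabatization is upstream); it
does not run molecular dynamics; emission, finite-temperature
lineshapes and Duschinsky-rotated (adiabatic-Hessian) spectra are out
of scope; and the exact-basis propagator is a desk-scale replacement
for tensor-contraction methods -- many-mode Hamiltonians are reachable
only after hierarchical truncation, which is accurate for short-time
observables (spectra) but approximates long-time population details.
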