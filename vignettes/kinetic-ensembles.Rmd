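---
title: "Kinetic ensembles for homonuclear NOE analysis: model and methods"
author: "kinens authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic ensembles for homonuclear NOE analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinens)
```

## The model

`kinens` computes homonuclear NOE observables from a structural ensemble
equipped with kinetics.  The ensemble's `N` conformers are the states of
a continuous-time Markov process with generator `Q` (rows sum to zero,
off-diagonal `q_ij >= 0`, stationary populations `pi` with detailed
balance for every construction in this package).  For a proton pair, each
state `i` contributes a dipolar interaction tensor built from the
internuclear vector; in 5-vector form

    d = r^-5 [ (3 z^2 - r^2)/2, (sqrt(3)/2)(x^2 - y^2),
               sqrt(3) x z, sqrt(3) y z, sqrt(3) x y ],

the unique scaling for which the correlation strength between two states
is simultaneously a trace and a dot product, `c_ij = tr(D_i D_j)/6 =
d_i . d_j`, with `c_ii = r_i^-6` exactly.  The internal correlation
function of the pair is then

    C_I(tau) = sum_ij pi_i p_ij(tau) c_ij,    P(tau) = expm(tau Q),

which the eigendecomposition `Q = V L V^-1` turns into a finite
multi-exponential `C_I(tau) = sum_k a_k exp(lambda_k tau)` over the
*unique* eigenvalues.  Isotropic tumbling multiplies `C_I` by
`exp(-tau/tau_c)`, so the spectral density is a sum of Lorentzians in the
modified times `tau'_k = 1/(1/tau_c - lambda_k)`.  Solomon's equations
map `J(0)`, `J(omega_0)`, `J(2 omega_0)` of all pairs into the relaxation
matrix (auto rates `rho` on the diagonal, cross rates `sigma` off it) and
NOESY buildups are block sums of `expm(-tau_m R)` over magnetically
indistinguishable protons.

Two routes to the prefactors `a_k` coexist deliberately:

* the **general path** forms the spectral projectors `A_lambda` from the
  eigendecomposition and evaluates `a_lambda = (Pi A_lambda) . C`; it is
  `O(s^3)` and serves as the oracle in the test suite;
* the **fast path** exploits the block structure of the projectors of the
  regular rate matrices used here.  Each unique eigenvalue carries a
  small recipe of state partitions `G_i` and integer coefficients
  `k_i` with `A_lambda = sum_i k_i G_i`, so `a_lambda` reduces to
  population-weighted squared block means of the `d` vectors,
  evaluated in `O(s l)` per pair (`l` = number of unique eigenvalues).

The two paths are compared entrywise (1e-10 relative) for every scheme in
the tests; the fast path also carries the symbolic dependence of each
eigenvalue on the named timescales, which is what makes the gradient
computation and timescale optimization cheap.

### Rate-matrix constructions

* `uniform_jump_matrix(N, tau)`: all rates `1/(N tau)`; spectrum
  `{0, -1/tau (N-1 times)}`.  The simplest defensible model for an
  ensemble with a single internal timescale.
* `hierarchical_matrix(sizes, tau_slow, tau_fast)`: inter-group rates
  `1/(N tau_slow)`, intra-group rates
  `(1/tau_fast - (1 - N_i/N)/tau_slow)/N_i`; spectrum has exactly three
  distinct values `{0, -1/tau_slow, -1/tau_fast}` (multiplicities are
  verified numerically in the tests rather than asserted by formula).
  Intra-group rates must stay nonnegative, which bounds `tau_slow` from
  below; violations raise an error naming the offending group.
* `rotation_rate_matrix(order, tau)`: methyl (3-fold, rates `1/(3 tau)`)
  and aromatic-flip (2-fold, rates `1/(2 tau)`) processes, combined with
  the member-level matrix by `kronecker_sum()` because the rotations are
  kinetically independent.  Pairs spanning two rotation groups enumerate
  the product of rotational states (9 states per member for
  methyl-methyl).

Populations default to uniform; the two-state distance toy is the one
construction with non-uniform populations (asymmetric rates
`k_AB = (1 - p_A)/tau_ex`, `k_BA = p_A/tau_ex`, nonzero eigenvalue
`-1/tau_ex`).

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `tau_c` | 4.3 ns (config) | s | isotropic tumbling time; the most sensitive fit parameter |
| `tau_ensemble` | 2 ns | s | member-exchange timescale of the jump model |
| `tau_pincer` | none | s | slower group-level exchange (hierarchical scheme only) |
| `tau_methyl` | 1 ps | s | methyl rotation; NOE observables plateau around this value, so it is held fixed during fits |
| `tau_aromatic` | 100 us | s | aromatic ring flips; likewise fixed |
| `spectrometer_mhz` | 900 | MHz | proton Larmor frequency entering `J(omega_0)`, `J(2 omega_0)` |
| `cutoff` | 5.5 | Angstrom | pair inclusion cutoff on the ensemble-minimum distance; beyond it dipolar contributions are negligible at the tolerances used here |
| mixing times | 5-500 ms, 15 ms steps | s | the standard NOESY buildup grid (34 points) |

## Numerical choices

* **Eigendecomposition.**  All constructions satisfy detailed balance, so
  `Q` is symmetrized as `D^1/2 Q D^-1/2` (`D = diag(pi)`) and decomposed
  with the symmetric eigensolver; eigenvalues are clustered at relative
  tolerance 1e-10.  The matrices here have *exact* degeneracies, so the
  tolerance only needs to absorb floating-point noise (of order
  `eps * ||Q||`, i.e. ~1e-15 relative); it must stay well below the
  smallest rate ratio that can occur, and 1 ps methyl against 100 us
  aromatic rates in one Kronecker-summed matrix leaves 8 usable orders of
  magnitude between noise and signal.  A non-simple zero eigenvalue
  (reducible chain) is an error.
* **Planar four-state toy.**  The fast angle follows from the two-site
  closed form `S^2 = (1 + 3 cos^2 theta)/4`; the slow angle is solved by
  bisection to 1e-12 on the overall tensor-average order parameter, so
  the plateau is exact by construction.
* **Averaging-power fit.**  For the two-distance system, the effective
  power `n` in `J(0) = 2 tau_c (p_A r_A^-n + (1-p_A) r_B^-n)^(6/n)` is
  fitted by ordinary least squares on `J(0)/(2 tau_c)` over populations
  `p_A = 0, 0.2, ..., 1`, with `n` bracketed in [2.5, 6.5].  Least
  squares on the *linear* scale matters: the large-`J(0)` points near the
  endpoints dominate, which is what pins the hyperbolic midpoint
  `tau_1/2` at 1.36 `tau_c` for a distance ratio of 10 (a log-scale fit
  would weight the six populations evenly and shift the midpoint toward
  1.04 `tau_c`).  The hyperbola `n = 3 + 3/((tau_1/2/tau_ex) + 1)` is
  then fitted over a 61-point log grid spanning `tau_c x 10^(-3..3)`
  by 1-D minimization in `log tau_1/2`; a boundary optimum is an error.
  `tau_c` is fixed at 5 ns for these scans — immaterial, as the results
  are reported in units of `tau_c`.
* **Solomon constants.**  `K = (1/10)(mu0/4pi)^2 hbar^2 gamma_H^4` with
  CODATA values, applied to the spectral density carrying `r^-6` (in
  Angstrom^-6, converted to SI) and the factor 2 inside `J`.  Correctness
  is anchored by a closed-form rigid-pair oracle in the tests, not by the
  constant itself.
* **Sign convention.**  The relaxation matrix is built decay-positive
  (`rho > 0` on the diagonal) and propagated as `expm(-tau_m R)`, which
  leaves cross-peak block sums positive in the spin-diffusion limit.
  Block sums run over both axes of the destination x source block without
  normalization; any per-pair constant convention cancels in the
  uncentered correlation provided it is applied uniformly, so one
  convention is fixed globally.
* **Gradient.**  `dRu/d log tau` chains the Lorentzian derivatives
  through `dexpm(A)[E] = V (W o (V^-1 E V)) V^-1` with
  `W_ij = (e^li - e^lj)/(li - lj)` and the limit value `e^li` taken when
  `|li - lj| < 1e-12 max|l|`.  Optimization runs in log-timescale space
  (bounds [-30, 0] log-seconds, at most 500 L-BFGS-B iterations); the
  analytic gradient agrees with central finite differences to 1e-5
  relative in the tests, and a fit can never return a correlation below
  its starting point.
* **Greedy selection.**  Swaps are accepted only for improvements above
  1e-9 (guarding against floating-point noise cycling); ties break to the
  lowest member index; candidate evaluations warm-start the timescales
  from the current optimum; a swap that would leave fewer than two
  members is never taken.

## The synthetic generator, and what passing tests mean

`generate_synthetic_ensemble()` lays protons on a 3 Angstrom lattice and
displaces each member by isotropic Gaussian noise (default 0.35 Angstrom
in the test systems), rejecting draws that bring any pair below 1.5
Angstrom.  This emulates the two properties the method actually consumes
— a dense proton network with member-to-member variation in distances and
orientations — and is deterministic per seed.

It does **not** emulate covalent geometry, anisotropic or correlated
motions, rotamer jumps, exchange-broadened populations or experimental
noise floors.  Tests passing on these fixtures therefore demonstrate the
*internal* correctness of the machinery (exact forward calculation,
gradient consistency, recoverability of generating parameters, planted
subset recovery); they do not certify accuracy on real proteins, where
model mismatch between the assumed kinetic scheme and the true dynamics
dominates.

Problem sizes used in the suite — chosen to exercise every code path at
comfortable margins: dual-route prefactor checks up to 50 members,
timescale recovery on 10 members x 15 protons, subensemble selection on
10 members (6 planted + 4 corrupted) x 10 protons with 25 random
baselines, randomization tests with 19 random groupings of a 5+3 member
hierarchy.

## Design choices on genuinely open points

* **Printed 5-vector components.**  The commonly printed component list
  with `1/sqrt(3)` and `2/sqrt(3)` coefficients is not consistent with
  the defining identity `d_i . d_j = tr(D_i D_j)/6`; this package
  implements the unique scaling that is, and enforces it against the
  matrix-trace oracle in the tests.
* **EMF spectral density.**  The slow-motion term uses the coefficient
  `S_f^2 (1 - S_s^2)`, the Fourier transform of the corresponding
  correlation-function term.
* **Altloc handling.**  Each alternate-location label expands into a full
  conformer (all non-altloc atoms plus that altloc set), weighted by its
  occupancy; crystallographic occupancies are otherwise an input, not a
  guess.
* **Replicate observations** enter the correlation as separate
  unweighted points; per-point weights are exposed but not defaulted.
* **Subensemble size** is emergent: no size penalty or constraint is
  imposed, so outcomes on other data may differ in size distribution.

## Known limitations

* Isotropic tumbling only; anisotropic diffusion, solvent exchange and
  non-uniform initial magnetization are not modeled.
* Two hierarchy levels (member + group); deeper nesting is out of scope.
* Dense `O(s^3)` eigendecomposition is only intended for oracle use up to
  a few hundred states; production paths are `O(s l)` per pair.
* Only CH3 methyls and PHE/TYR ring flips are auto-detected as rotation
  groups; exchangeable groups such as LYS NH3+ are excluded.
* Structures must already carry hydrogens; no protonation is attempted.
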