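---
title: "Unitary cluster Jastrow ansätze: models, circuits and optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unitary cluster Jastrow ansätze: models, circuits and optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ucjcirc` implements the k-fold unitary cluster Jastrow (uCJ) family of
wavefunction ansätze for molecular electronic structure on quantum
computers,

$$|\Psi\rangle \;=\; \prod_{i=1}^{k} e^{\hat K_i}\, e^{\hat J_i}\,
e^{-\hat K_i}\,|\mathrm{HF}\rangle ,$$

where each replica combines a one-body orbital-rotation generator

$$\hat K = \sum_{pq,\sigma} K_{pq}\, a^\dagger_{p\sigma} a_{q\sigma},
\qquad K^\dagger = -K,$$

restricted to rotations within each spin block, with a density–density
Jastrow correlator over spin orbitals,

$$\hat J = \sum_{p<q} 2 J_{pq}\, \hat n_p \hat n_q ,
\qquad J = i\,J^{\mathrm{re}},\; J^{\mathrm{re}}{}^{T} = J^{\mathrm{re}},$$

which is purely imaginary and symmetric so that $e^{\hat J}$ is unitary.
Three variants restrict the orbital-rotation block $K$:

* **Re-uCJ** — $K$ real antisymmetric ($C(M,2)$ real parameters per spin
  block);
* **Im-uCJ** — $K = iS$ with $S$ real symmetric, zero diagonal (the
  diagonal only generates orbital phases absorbable into $\hat J$ and a
  global phase, so it is excluded; again $C(M,2)$ parameters per block);
* **g-uCJ** — $K$ general complex anti-Hermitian ($2\,C(M,2)$ parameters
  per block).

The α and β blocks carry independent parameters. Everything is built over
$N = 2M$ Jordan–Wigner qubits in spin-blocked order (qubits $0..M-1$ are α
spatial orbitals ascending, $M..2M-1$ are β) with the convention
$|0\rangle$ = unoccupied, $\hat n_p = (I - Z_p)/2$. Spin-blocking keeps
every orbital rotation on adjacent qubits of one spin block, so no
Jordan–Wigner parity strings appear in the rotation gates.

The variants are nested: every Re- or Im-uCJ parameter set is exactly a
g-uCJ set, so at any shared Hamiltonian the optimized g-uCJ energy can
never sit above the better of the restricted optima. For two-electron
problems the k = 1 g-uCJ manifold contains the exact ground state; this
two-electron exactness is asserted in the test suite to $10^{-6}$ hartree.

## Exact (Trotter-free) circuits

$e^{\hat J}$ is diagonal in the computational basis (its Pauli image
contains only $I/Z$ letters), so it is compiled exactly as one
number-pair phase factor $e^{i\lambda\hat n_p\hat n_q}$ per surviving
term — 2 CNOTs and one Rz each, with the local phases merged into the
single-qubit layer.

$e^{\pm\hat K}$ is compiled exactly through the matrix factorization of
the $M\times M$ unitary $u = e^{\pm K_\sigma}$ into at most $C(M,2)$
*generalized Givens rotations* on adjacent modes plus a final layer of
single-mode phases. A generalized rotation carries two angles,

$$ r_{p,p+1}(\theta,\varphi) = \begin{pmatrix}
\cos\theta & -e^{i\varphi}\sin\theta \\
e^{-i\varphi}\sin\theta & \cos\theta\end{pmatrix}, $$

embedded at rows $(p, p+1)$; the extra phase $\varphi$ is what extends the
classic real QR-by-Givens scheme to the complex unitaries generated by
Im-uCJ and g-uCJ. The elimination schedule is column-major, bottom-up,
using adjacent-row rotations only; already-zero pivots skip their rotation,
and a degenerate pivot uses the deterministic tie-break $\theta = \pi/2$,
$\varphi = 0$. Because an upper-triangular unitary is diagonal, the residual
diagonal becomes the phase layer (kept as single-qubit number phases, never
folded into $J$). Correctness is defined — and tested — by reconstruction:
rebuilding $u$ from the rotation list reproduces it to $10^{-10}$ for
random unitaries up to $M = 6$, and simulating the synthesized circuit
matches the dense operator product $e^{\hat K}e^{\hat J}e^{-\hat K}$
applied to the reference determinant to the same fidelity.

Each two-qubit rotation gate costs 3 CNOTs on hardware, so the exact k = 1
circuit costs

$$N_{\mathrm{CNOT}} \;=\; 2\cdot 3\cdot 2\,C(M,2) \;+\; 2\,|J| ,$$

where $|J|$ is the number of surviving Jastrow terms. The count is
identical for the three variants (they differ only in which angles are
free). Fault-tolerant Rz synthesis is estimated at
$1.15\log_2(1/\varepsilon_{\mathrm{syn}}) + 9.2$ T gates per rotation.

**Jastrow screening.** All $C(N,2)$ off-diagonal spin-orbital pairs are
enumerated; with screening on (the default), same-spin pairs are dropped
for any spin sector holding at most one electron, since those
$\hat n\hat n$ products annihilate every state of the sector. For a
two-electron singlet this leaves $M^2$ opposite-spin terms; for (2α, 2β)
in four orbitals nothing is screened and all 28 pairs remain.

**Single-Trotter-step comparators.** `build_trotter_circuit()` compiles an
anti-Hermitian Pauli-sum generator as one CNOT-staircase evolution per
collected word, in lexicographic word order. For the commuting $\hat J$
family this is exact; for $\hat K$ it is first-order accurate, and the
test suite verifies the quadratic fidelity scaling as the parameters
shrink. Trotterized gate totals depend on term-cancellation conventions
and are deliberately not benchmarked numerically.

## Hydrogen-cluster backend and reference states

The benchmark systems treated numerically (H2, linear H3+, square H4 in
STO-3G/6-31G/6-311G) contain only hydrogen, so the package carries a
self-contained s-type Gaussian integral engine (overlap, kinetic, nuclear
attraction and repulsion integrals need only the zeroth Boys function) with
restricted and unrestricted Hartree–Fock solvers, and transforms to the MO
basis over the full orbital space (lengths in ångström internally converted
at 0.52917721092 Å/bohr; energies in hartree throughout). Molpro-dialect
FCIDUMP read/write provides the interchange with any external integral
source, and shipped FCIDUMP fixtures cover H2/STO-3G at tabulated bond
lengths.

One reference-state subtlety deserves emphasis. Square H4 has a doubly
degenerate frontier shell, so the closed-shell determinant is ambiguous:
aufbau iterations can land on an edge-oriented broken solution or on the
stationary point whose occupied frontier orbital is symmetric under the
diagonal reflection. The two references differ by ~0.07 hartree and give
very different correlation denominators. The benchmarks use the
symmetry-adapted diagonal reference (`homo_orientation = "diagonal"`),
implemented by block-diagonalizing the Fock operator in the reflection-even
subspace; this is the reference for which the broken-symmetry UHF and
g-uCJ correlation fractions line up with the published benchmark table.
The broken-symmetry UHF energy itself is obtained by multi-start Roothaan
iteration (HOMO–LUMO-mixed plus seeded random orthogonal starts, lowest
solution kept), which stands in for analytic stability following; direct
orbital-rotation minimization confirms it reaches the UHF global minimum
on these systems.

## Optimization

The noiseless variational path evaluates the energy in the fixed
particle-number sector: $e^{\hat K_\sigma}$ acts on α/β occupation strings
through the compound (minor-determinant) matrix of $e^{K_\sigma}$ and
$e^{\hat J}$ is a diagonal phase, which makes one energy evaluation a few
small eigendecompositions and matrix products. This evaluator is
algebraically identical to simulating the synthesized circuit and is
cross-checked against both the circuit simulator and dense operator
exponentials in the tests.

* **Local minimization** — BFGS with central-difference gradients (step
  $10^{-6}$), relative convergence tolerance $10^{-11}$, up to 400
  iterations.
* **Multi-start** (`ucj_optimize`) — first start at zero (or a supplied
  continuation vector), remaining starts seeded normal perturbations of
  scale 0.1; 8 starts by default; minimum kept. The zero vector is a
  stationary point of every variant (Brillouin condition plus the phase
  flatness of $\hat J$ at a determinant), so the perturbed starts do the
  work.
* **Staged perfect-pairing warm start**
  (`perfect_pairing_warmstart`) — used for the 8-qubit benchmarks: stage 1
  frees only the parameters coupling each occupied orbital to its
  antibonding partner (default pairing: occupied $i$ with virtual
  $2n_{\mathrm{occ}}+1-i$); subsequent stages extend the freed orbital
  connectivity one orbital at a time until fully connected, warm-starting
  each stage and initializing newly freed coordinates at scale 0.1. The
  staged pipeline is repeated under a few seeds (3 by default) and the
  lowest-energy result kept. Stage energies are monotone non-increasing by
  construction.
* **Continuation scans** (`continuation_scan`, `cmd_scan`) — association /
  dissociation branches warm-start each geometry from the previous
  optimum; the default H2 grid spans 0.5–2.3 Å in 0.2 Å steps (a package
  choice).
* **Shot-noise path** (`ucj_optimize_sampled`) — the Hamiltonian is
  partitioned into qubit-wise-commuting groups (greedy first-fit by
  descending coefficient magnitude); each group is measured by rotating
  into its shared single-qubit basis and drawing multinomial samples from
  the exact outcome distribution (10 000 shots per group by default). The
  optimizer is a Powell-style direction-set search with three-point
  parabolic line minimizations over wide brackets — the wide bracket
  averages the shot noise over the step, where simplex methods collapse
  under the noise-biased best-vertex bookkeeping. The step anneals from
  0.4 down to 0.12 with periodic direction resets; six random starts of
  scale 0.3 are ranked by an averaged sampled score and the winner is
  re-evaluated over 20 independent trials. Starts are drawn away from zero
  because the optimizer cannot leave the mean-field saddle along any
  single direction.

Reported uncertainties: with multiple trials the standard error of the
trial mean; for a single trial the multinomial error propagated per group.
A fixed master seed makes every optimization, sampling run and scan
bit-reproducible; randomness never depends on platform iteration order.

## Synthetic instances

`make_synthetic_integrals()` generates seeded random active-space
integrals satisfying the container invariants exactly: a real symmetric
one-body matrix with a spread, sorted diagonal (so the aufbau determinant
is generically non-degenerate) plus weaker 8-fold-symmetric two-body
couplings (scale 0.2). These instances emulate the *algebraic shape* of
molecular integrals — Hermiticity, permutation symmetry, a dominant
one-body spectrum — but not their physics: no geometry, no basis-set
structure, no near-degeneracies unless constructed. Property tests on
synthetic instances (variational ordering, two-electron exactness,
particle-number conservation, circuit/operator equivalence) therefore
validate the machinery, not chemical accuracy on real molecules; the
hydrogen benchmarks cover the latter.

## Problem sizes and costs

The shipped tests and the acceptance script run at desk scale: dense
sector diagonalization up to 8 qubits (sector dimensions ≤ 36), Givens
reconstruction up to $M = 6$, 100-plus random unitaries and 200 random
parameter draws per variant in the property suites, 10-point dissociation
grids, and shot-noise runs at 10 000 shots per group over 20 trials. A
full suite run takes a few minutes on one core.

## Known limitations

* Hardware noise channels (decoherence, depolarization, readout) are out
  of scope; only measurement shot noise is modelled.
* k > 1 replicas are supported by the data model, parameter packing and
  circuits, but all shipped benchmarks and tolerances are for k = 1.
* The spin-adapted CSF analysis is constructed explicitly only for the
  two-electron, two-orbital sector; larger sectors report determinant
  weights and ⟨S²⟩ without spin adaptation.
* The Gaussian backend handles s-type functions (hydrogen clusters) only;
  heavier atoms must enter through FCIDUMP files produced elsewhere.
* Optimized energies of the restricted variants are protocol-dependent on
  purpose: Re-uCJ in particular has well-separated local minima
  (association/dissociation branches), and the staged perfect-pairing
  protocol, not a global search, defines the reported benchmark numbers.
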