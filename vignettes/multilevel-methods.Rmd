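---
title: "Multilevel unrestricted SCF with classical embedding: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel unrestricted SCF with classical embedding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlscf)
```

## The model

Open-shell molecules in solution — nitroxide spin probes are the motivating
case — need a quantum treatment of the radical and its nearest solvent
shell, but the full system is far too large for a conventional unrestricted
SCF. `mlscf` implements a *multilevel* unrestricted Hartree–Fock / DFT
scheme in which the spin densities are split as

$$\mathbf D^\sigma = \mathbf D_A^\sigma + \mathbf D_B^\sigma,
\qquad \sigma = \alpha, \beta,$$

with an *active* block $A$ optimized self-consistently and an *inactive*
block $B$ frozen at its initial value. Both blocks are $S$-idempotent,
mutually orthogonal projectors with integer electron counts, so the
decomposition is a genuine partition of the one-particle density matrix,
not of the density function: no nonadditive kinetic-energy functional is
ever needed.

The total energy is booked as

$$E = E_A + E_B + E_{int} + E_{non\text{-}add} + E_{nn},$$

where $E_{int}$ collects the Coulomb and (scaled) exact-exchange coupling
between the blocks — evaluated once, using the symmetry
$\mathrm{Tr}\,\mathbf D_A \mathbf G(\mathbf D_B) =
\mathrm{Tr}\,\mathbf D_B \mathbf G(\mathbf D_A)$ — and
$E_{non\text{-}add} = E_{xc}[\rho_A+\rho_B] - E_{xc}[\rho_A] -
E_{xc}[\rho_B]$ is the nonadditive exchange–correlation coupling, which
vanishes identically for pure Hartree–Fock. One bookkeeping convention
deserves mention: the one-electron energy of each block is evaluated with
the full nuclear attraction of *all* nuclei, so the electron–nuclear and
nuclear–nuclear cross terms sit inside $E_A$, $E_B$ and $E_{nn}$ rather
than in $E_{int}$. Any such split is a convention; the total is exact and
is what the test suite pins down (the full-active limit reproduces a
conventional unrestricted SCF to well below $10^{-8}\,E_h$).

The working protocol is the five-step sequence

1. a superposition-of-atomic-densities (SAD) guess from spherically
   averaged unrestricted atomic calculations, cached per (element, basis);
2. one Fock build and diagonalization of the whole system — deliberately
   *not* iterated, this single pass injects the bulk of the
   active–inactive polarization;
3. partitioning of each spin density by a partial pivoted Cholesky
   decomposition restricted to active-atom AOs, plus a
   projected-atomic-orbital (PAO) virtual space;
4. one-time computation of the frozen Coulomb/exchange operators and the
   constant energy of the inactive block;
5. SCF minimization in the active orbital basis only.

## Partitioning: thresholds and conventions

The Cholesky step works on the metric-folded density
$\mathbf D' = \mathbf S^{1/2}\mathbf D\mathbf S^{1/2}$, for which
$S$-idempotency is ordinary idempotency; pivots are the largest remaining
diagonal among active AOs, ties to the lowest AO index, and the
factor columns are back-transformed with $\mathbf S^{-1/2}$. Because
$\mathbf D'$ is a projector, the extracted block is automatically
idempotent and its columns $S$-orthonormal, and the inactive remainder is
orthogonal to it — properties the package asserts numerically on every
partition rather than assuming.

The decay threshold `tau` stops the pivoting and thereby *decides the
active electron count*. Its default is `1e-2`, and this number is a
considered choice: after the single initial diagonalization the canonical
orbitals are delocalized, and the density diagonal that inactive orbitals
leave on active AOs is of order $10^{-2}$–$10^{-3}$. A much tighter
threshold keeps pivoting into those tails and absorbs essentially the
whole occupied space into the active block; a threshold near $10^{-2}$
separates the $O(1)$ genuinely active pivots cleanly, and the resulting
occupation is stable over the whole range $10^{-1}$–$10^{-3}$ on our
fixtures (e.g. an aminoxyl radical hydrogen-bonded to a water keeps
exactly its own 9 alpha / 8 beta electrons active). The count *emerges*
from the threshold rather than being fixed a priori; users scanning
unusual systems should check the reported active occupation.

Virtuals default to PAOs: active-atom AOs with all occupied components
projected out, then symmetric orthonormalization dropping eigenvalues
below `lindep_tol = 1e-8`. A Cholesky-of-the-virtual-density alternative
is available (`virtual = "cholesky"`). A minimal-basis active region can
legitimately end up with *no* virtual space (every active AO spanned by
occupied orbitals); the partition is then still valid and the active SCF
converges trivially.

The active-space SCF runs Roothaan iterations with Pulay DIIS entirely in
the fixed orthonormal active basis; the DIIS error vector is the
commutator of the projected Fock with the current occupied projector.
Convergence demands a maximum gradient below $10^{-6}$ and an energy
change below $10^{-9}\,E_h$. The inactive block is untouched by
construction, and the frozen operators are verified hash-identical across
the run.

## Classical layers

Outside the quantum region, solvent molecules become point-charge sites.
Two models ship:

* **Fixed charges** — a nonpolarizable layer (preset `tip3p-charges`:
  O $-0.834\,e$, H $+0.417\,e$); its one-electron operator is built once.
* **Fluctuating charges (FQ)** — each site carries an electronegativity
  $\chi$ and hardness $\eta$ (atomic units; shipped set `water-radical`),
  and the charges minimize
  $E(q) = \chi^\top q + \tfrac12 q^\top \mathbf J q + q^\top V$ under one
  total-charge constraint per solvent molecule, solved as a symmetric
  saddle-point system with one Lagrange multiplier per fragment. The
  off-diagonal kernel is the Ohno form
  $J_{ij} = \bar\eta\,(1 + \bar\eta^2 r_{ij}^2)^{-1/2}$ with $\bar\eta$
  the geometric mean of the two hardnesses; the kernel is an exchangeable
  function argument for other conventions. The FQ operator is rebuilt
  every SCF cycle from the potential of the *total* (active + inactive)
  density, which is what makes the layer mutually polarizable.

The potential $V_i$ at a site includes the QM nuclear term by default —
the total electrostatic coupling requires it — with
`include_nuclear = FALSE` available for a strict density-only potential.
The initial full-system Fock of step 2 includes the embedding potential
by default (`include_embedding_in_guess`), since the classical layer is
present before the partitioning; a switch disables it.

## Hyperfine couplings

The isotropic coupling of nucleus $X$ is the Fermi-contact term
$$A_X \propto \frac{\rho^{\alpha-\beta}(\mathbf R_X)}{2\langle S_z\rangle},$$
with the spin density evaluated from the **total** $\alpha-\beta$ density
(active *and* inactive blocks) directly at the nucleus, and
$\langle S_z\rangle = (n_\alpha - n_\beta)/2$ of the whole system. The
unit chain runs a.u. $\to$ SI ($a_0^{-3}$) $\to$ joule via
$(2\mu_0/3)\,g_e\mu_B\,g_X\mu_N\,\rho$ $\to$ Gauss by dividing by
$g_e\mu_B$ per Gauss, so $g_e$ cancels in the Gauss value; the adopted
$g_e = 2.0022319$ and the per-isotope nuclear $g$-factors (shipped CSV:
$^1$H, $^{13}$C, $^{14}$N, $^{17}$O) are recorded in the result. The
convention is pinned by a closed-form anchor: the exact hydrogen 1s
density $1/\pi\,a_0^{-3}$ must give $\approx 507.7$ G, and the
STO-3G atom must match the analytic Gaussian-contraction value of
$\rho(0)$ to eight significant figures. The traceless dipolar tensor
averages to zero in isotropic media and is reported as an explicit zero
placeholder. Couplings are conventionally reported for active nuclei;
inactive ones are computable but warn, since the frozen block is not
variationally relaxed.

## Exchange–correlation: functionals, derivatives, grids

LSDA (Slater + PW92) and PBE ship, with hybrids through the exact-exchange
fraction $c_x$ (preset `pbe0`, $c_x = 0.25$); the named exchange enters
scaled by $1 - c_x$. Two numerical choices are deliberate:

* **Complex-step functional derivatives.** The xc potential ingredients
  $\partial e/\partial\rho_\sigma$, $\partial e/\partial\gamma$ are
  obtained by complex-step differentiation of the energy-density
  expressions ($\mathrm{Im}\,f(x + ih)/h$, $h = 10^{-20}$). This is exact
  to machine precision and guarantees the potential is *the* derivative of
  the implemented energy — the finite-difference Fock test passes at
  $10^{-8}$, far inside its $10^{-5}$ contract — at the cost of a few
  complex evaluations per grid batch.
* **Product angular grids.** Quadrature uses Becke fuzzy-cell weights
  (three smoothing passes, no size adjustment) over per-atom
  Gauss-Chebyshev radial grids with the Becke map and Gauss-Legendre
  $\times$ uniform-$\phi$ spheres. Grid levels 1–5 give 20x72 to 85x800
  points per atom; level 3 integrates the water electron count to
  $10^{-5}$ electrons. Active, inactive and total densities share one
  grid, so the nonadditive terms are internally consistent.

Because $E_{xc}[\rho_A]$ cancels between $E_A$ and $E_{non\text{-}add}$,
each SCF cycle needs a single grid pass (total density); the full
decomposition is evaluated once at convergence.

## The synthetic snapshot generator

Sampling solute–solvent configurations by molecular dynamics is outside
this package's scope; geometries are inputs. For testing and
demonstration, `generate_synthetic_snapshots()` emulates the *shape* of
sampled data: a rigid small radical (default H$_2$NO) whose N–O bond is
tilted out of plane by a normal random angle (default sd 10 degrees,
mimicking the nitrogen-pyramidalization spread that dominates hcc
variability), surrounded by rigid waters packed by rejection sampling
(minimum O–O and O–heavy-atom distance 2.4 angstrom, a physical
contact distance) with uniform random orientations inside a sphere. All
randomness flows from one seed.

What passing tests on these frames shows — and does not show. The frames
exercise every pipeline stage (droplet carving at 13 angstrom, the
3.5 angstrom quantum shell, active-water selection by N–O-midpoint or
centre-of-mass distance measured at the water oxygen, per-snapshot hcc,
ensemble mean and $se = \sigma/\sqrt{N}$). They do *not* carry the
radial structure, hydrogen-bond statistics or Boltzmann weighting of real
solvent sampling, so ensemble numbers from synthetic frames characterize
the machinery, not any real solvated radical. On a desk-scale synthetic
droplet (8 quantum waters, 40 polarizable waters, hybrid-DFT multilevel,
minimal basis) the package reproduces the qualitative finding that adding
waters to the *active* region barely moves hcc$_N$ while switching the
outer polarizable layer off moves it several times more — the same
ordering reported for full-scale nitroxide studies.

Where a water's distance to a reference point is needed (droplet cut,
shell cut, active selection), the oxygen atom is the measuring point by
default; this is a documented convention (`measure = "oxygen"`), with
`"cm"` and `"closest"` available, and exact ties break to the lower atom
index so every selection is deterministic.

## Degenerate and edge inputs

Aufbau occupation at a degenerate Fermi level occupies the lowest-index
eigenvectors and warns (no level shifting in the initial pass). Overlap
matrices singular beyond $10^{-10}$ abort with an explicit error rather
than silently dropping functions. SAD guesses for ions rescale each spin
channel to the molecular electron counts. `max_iter = 0` returns the
step-3 state unchanged, which is occasionally useful for inspecting the
frozen-field energy before relaxation.

## Problem sizes

The shipped tests and the acceptance script run minimal-basis fixtures
(7–68 AOs): they complete on one CPU in minutes while still exercising
every code path, including hybrid-DFT multilevel runs inside a
polarizable layer. The engine holds the two-electron tensor in core,
which bounds practical problem sizes to a few hundred AOs; a disk- or
direct-SCF path is an explicit non-goal here, as is analytic nuclear
gradients, MM bonded/Lennard-Jones energetics (never entering the Fock or
the observables), orbital-localization refinement of the active space,
and response-theory extensions.

## Limitations

* Basis sets ship for H, He, C, N, O (STO-3G; 6-31G without He). Other
  elements need a user basis file in the same JSON layout.
* s and p shells only; no d functions, hence no polarization-basis
  studies. Contact spin densities from minimal bases are qualitative.
* The partition quality inherits the single initial diagonalization; no
  freeze-and-thaw relaxation of the inactive block is attempted.
* The greedy pivot choice makes partitioned results covariant under
  frame rotations only up to the pivot selection; fully converged
  full-system results are frame-invariant to numerical precision.
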