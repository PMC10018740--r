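# mlscf

Multilevel unrestricted Hartree–Fock and DFT for open-shell molecules in
complex environments, with polarizable classical embedding and
hyperfine-coupling properties — implemented as a self-contained R package
with its own Gaussian-integral engine.

## The problem

Radicals in solution (nitroxide spin probes, for instance) demand a quantum
treatment of the unpaired electron and its nearest solvent shell, but the
hundreds of solvent molecules around them make a conventional unrestricted
SCF intractable — and their effect on observables like the nitrogen
hyperfine coupling constant is dominated by long-range electrostatics and
polarization that a small gas-phase cluster misses entirely.

`mlscf` addresses this with a three-layer model:

1. **Active QM region** — the radical (plus optionally its closest waters).
   Each spin density is split as **D**^σ = **D**_A^σ + **D**_B^σ by a
   partial pivoted Cholesky decomposition restricted to the atomic orbitals
   of the active atoms; only the active block is optimized in the SCF, in a
   basis of Cholesky occupied orbitals and projected-atomic-orbital (PAO)
   virtuals.
2. **Inactive QM region** — the rest of the quantum solvent shell, frozen
   after a single full-system diagonalization. Its Coulomb/exchange field
   (the one-time `2e_B` operators) and, for DFT, a nonadditive
   exchange–correlation coupling E_xc[ρ_A+ρ_B] − E_xc[ρ_A] − E_xc[ρ_B]
   perturb the active block.
3. **Classical layer** — remaining solvent as fixed point charges
   (TIP3P-style preset) or polarizable fluctuating charges (FQ): per-site
   electronegativity χ and hardness η, charges re-equilibrated against the
   QM electrostatic potential every SCF cycle under per-molecule
   total-charge constraints.

Isotropic hyperfine coupling constants come from the Fermi-contact spin
density at the nucleus, ρ^{α−β}(**R**_X), evaluated from the *total* spin
density and reported in Gauss; a solvation pipeline carves spherical
droplets from snapshots, assigns the layers, and averages hcc values over
an ensemble with standard errors σ/√N.

Functionals: UHF, LSDA, PBE and PBE0 (hybrids via the exact-exchange
fraction). Basis sets ship as data files (STO-3G, 6-31G) and are assigned
per atom, so mixed solute/solvent bases are natural.

## A worked example

An aminoxyl radical (H₂NO, a minimal nitroxide) hydrogen-bonded to one
water; the radical is the active region, the water is frozen:

```r
library(mlscf)
rad <- h2no_radical()                      # planar aminoxyl radical, doublet
wat <- rbind(c(0, 2.8, 1.0), c(0.957, 2.8, 1.0), c(-0.24, 3.73, 1.0))
sys <- atomic_system(c(rad$atoms$element, "O", "H", "H"),
                     rbind(as.matrix(rad$atoms[, c("x", "y", "z")]), wat),
                     charge = 0, multiplicity = 2)
sys
#> <atomic_system: 7 atoms, charge +0, multiplicity 2, 27 electrons (14 alpha / 13 beta)>

res <- uml_scf(sys, 1:4, functional = "uhf")
res
#> <uml_result: E = -203.5956383323 Eh in 13 iteration(s); active 9 a / 8 b electrons>
#>   E_A = -193.56174560  E_B = -114.34552544  E_int = 30.30121483  E_nonadd = 0.00000000  E_emb = 0.00000000

hyperfine(res, nuclei = 1)
#> <hyperfine_result> (A_iso in Gauss, rho in bohr^-3)
#>  atom element isotope   rho_spin    A_iso
#>     1       N     14N 0.03420367 3.943402
```

What the numbers mean: the partitioner kept exactly the radical's own
9 alpha / 8 beta electrons active (the unpaired electron localizes on the
active block); `E_A`/`E_B`/`E_int` are the block energies and their
Coulomb–exchange coupling under the package's documented bookkeeping
(`E_nonadd` is identically zero for pure HF); and the nitrogen carries a
spin density of 0.0342 bohr⁻³ at the nucleus, i.e. an isotropic ¹⁴N
coupling of 3.94 G at this level. Re-running with `functional = "pbe0"`
and an `fq_layer()` of outer waters adds the nonadditive xc and
polarizable-embedding terms to the same breakdown.

Ensemble runs over solvation snapshots use the same pieces:

```r
frames <- generate_synthetic_snapshots(seed = 7, n_frames = 10, n_waters = 20)
ens <- snapshot_hcc(frames, functional = "uhf", qm_radius = 3.5,
                    n_active = 0, scheme = "NO", embedding = "fq")
ens$stats      # mean, sigma, se = sigma/sqrt(N)
```

A thin command-line wrapper (`inst/scripts/mlscf`) exposes `scf`, `hcc`,
`ensemble` and `synth` subcommands over YAML job configs via `run_job()`.

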