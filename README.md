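# pd2loop

Coarse-grained protein loop modelling in R: sample loop backbone
conformations from a sequence-independent C&alpha; statistical potential by
local-move Monte Carlo simulated annealing, rebuild the backbone N/C/O atoms
from the C&alpha; trace, filter by Ramachandran quality, regularise in a
united-atom backbone potential, and score the resulting decoy ensembles
against the native loop.

The package is for structural bioinformaticians who want to study loop
conformational sampling with an explicit, trainable energy function rather
than fragment libraries — every stage (structural alphabet, reference
energies, hydrogen-bond tables, Ramachandran map, backbone look-up table)
can be retrained from any structure set, and a synthetic-structure generator
makes the whole pipeline runnable and testable with zero downloads.

## The model

Each residue is a single C&alpha; site. The coarse-grained energy of a
conformation is a sum of five terms:

```
E = E_sa + E_bond + E_steric + E_hbond + E_ref
```

* `E_sa` — structural-alphabet local term. Every 4-residue fragment is
  described by (θ₁, θ₂, τ): the two interior pseudo bond angles and the
  pseudo dihedral. The fragment is classified to the nearest of 27 letter
  prototypes (periodic metric in τ), and contributes harmonic wells
  ½k_θ(L)[(θ₁−θ₁⁰(L))² + (θ₂−θ₂⁰(L))²] + ½k_τ(L)·wrap(τ−τ⁰(L))².
* `E_bond` — harmonic pseudo-bond term ½k_b(r−3.8 Å)² on consecutive
  C&alpha; pairs.
* `E_steric` — soft half-harmonic repulsion ½k_rep(r_rep−r)² for r < r_rep
  (4.5 Å) over pairs with sequence separation ≥ 3.
* `E_hbond` — binned statistical potential on pseudo-N(i)···pseudo-O(j)
  distances, with the pseudo atoms placed geometrically in the local frame
  of each interior residue.
* `E_ref` — per-letter and letter-pair reference energies, fitted by
  iterative Boltzmann correction so that the sampled letter equilibrium
  reproduces the letter frequencies of a training structure set.

Loops are initialised on the anchor–anchor segment, relaxed by 12000 steps
of Monte Carlo simulated annealing (crankshaft, bond and angle moves — all
local, so loop closure holds by construction and the anchors never move),
and decoys are drawn by repeated 400-step annealing cycles (50 at β_low,
100 ramping, 250 at β_high). Each candidate gets backbone N/C/O atoms from a
geometric look-up table, is screened by an adaptive forbidden-φ/ψ filter,
and accepted decoys are regularised by Polak–Ribière conjugate-gradient
minimisation in a united-atom backbone potential (bond/angle/torsion/
improper + 1-4/1-5 Lennard-Jones + soft sterics + a backbone H-bond table).
Accuracy is measured as RMSD-G: the RMSD over backbone N, CA, C, O atoms in
the fixed frame, with no superposition.

## Worked example

```r
library(pd2loop)

## a synthetic helix-loop-helix target with a known 8-residue native loop
fx  <- make_fixtures(list(list(type = "helix", len = 9),
                          list(type = "loop",  len = 8),
                          list(type = "helix", len = 9)), seed = 101)
reg <- fx$regions[[1]]          # A:10-17

ens <- generate_ensemble(fx, reg, n_decoys = 50, config = mc_config(seed = 1))
ens
#> <decoy_ensemble> 50 decoys (pd2 mode), 31 filter rejections; RMSD-G best 3.76 mean 5.32

ensemble_stats(ens, m = 50, seed = 1)
#> best RMSD-G 3.76 A [3.76, 4.07]; mean 5.32 A [5.09, 5.54]; frac <1A 0.00; frac <2A 0.00

pred <- select_prediction(ens)   # lowest backbone-energy decoy
write_structure(pred$backbone, "prediction.pdb")
```

The printed numbers say: out of 50 filter-passing decoys the closest
approach to the native loop was 3.76 Å RMSD-G, the ensemble average 5.32 Å
(bracketed values are 95% bootstrap confidence intervals), and no decoy came
within 2 Å on this target at this ensemble size. A control run
(`mode = "control"`, pseudo-bond + steric terms only) gives a higher
ensemble mean, which is the package's headline comparison: the alphabet,
hydrogen-bond and reference terms concentrate sampling on protein-like,
closer-to-native conformations.

A thin command-line front end is installed at
`system.file("cli", "pd2loop.R", package = "pd2loop")`:

```sh
Rscript pd2loop.R fixtures --loop-len 8 --seed 1 --out fixture.pdb
Rscript pd2loop.R sample --pdb fixture.pdb --loop A:10-17 --n 100 --seed 1 --out out/
Rscript pd2loop.R findloops --pdb fixture.pdb
```

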