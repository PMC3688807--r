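---
title: "Coarse-grained loop modelling: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained loop modelling: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the coarse-grained model and its assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic training data do
and do not emulate, and the numerical choices that shape the results.

## The coarse-grained model

A protein chain is reduced to one interaction centre per residue, the
C&alpha; atom. Conformations are scored by a five-term potential in
dimensionless statistical-energy units (kT at &beta; = 1; the inverse
temperature carries all temperature dependence):

1. **Structural-alphabet local term.** Local backbone shape is captured by
   classifying each 4-residue fragment into a 27-letter structural
   alphabet. The fragment descriptor is the minimal rigid-motion-invariant
   internal-coordinate triple (&theta;&#8321;, &theta;&#8322;, &tau;): the
   pseudo bond angles at the two interior residues and the pseudo dihedral
   of the tetrad. Classification is nearest-prototype under
   &radic;(&Delta;&theta;&#8321;&sup2; + &Delta;&theta;&#8322;&sup2; +
   wrap(&Delta;&tau;)&sup2;), with &tau; differences wrapped into
   (&minus;&pi;, &pi;] to avoid the 2&pi; discontinuity. Each fragment
   contributes letter-specific harmonic wells in the three descriptors.
   The per-letter centres are the trained prototypes and the force
   constants are inverse cluster variances of the training fragments,
   clamped into [2, 50] kT/rad&sup2;: unclamped helix clusters are so tight
   (variance &lt; 10&#8315;&sup3; rad&sup2;) that sampling would freeze.
2. **Pseudo-bond term**, harmonic about 3.8 &Aring; (k = 100 kT/&Aring;&sup2;,
   giving the ~0.1 &Aring; fluctuations seen for C&alpha;&ndash;C&alpha;
   virtual bonds). An optional cis-proline equilibrium length (2.95 &Aring;)
   can be assigned per bond from native geometry at load time; the energy
   never switches equilibria as a function of coordinates, which would make
   it discontinuous.
3. **Soft steric repulsion**: half-harmonic below r_rep = 4.5 &Aring;
   (k_rep = 10) for residue pairs at sequence separation &ge; 3. Closer
   pairs are governed by the bond and angle terms; excluding them avoids
   double-counting local geometry.
4. **Pseudo hydrogen-bond term**: a binned table (0.25 &Aring; bins,
   3.0&ndash;6.5 &Aring;) over pseudo-N(i)&hellip;pseudo-O(j) distances,
   |i&minus;j| &ge; 2, fitted as a negative-log frequency ratio against a
   shell-volume reference and forced to zero at the cutoff bin. The pseudo
   atoms sit at fixed offsets (1 &Aring;) along normalised combinations of
   the bisector and the plane normal of each interior C&alpha; triple.
   The exact geometric recipe of the classical construction is defined in
   prior work that this package does not reproduce, so the offsets and the
   mixing angle are parameters (`cg_params()$pseudo`) a trainer can absorb;
   they should be read as an approximation. The construction is chiral:
   mirroring a chain swaps the pseudo-N and pseudo-O images, as it should
   for a protein model.
5. **Reference energies** for letters and consecutive-letter pairs, fitted
   so that the letter equilibrium sampled from the potential matches the
   letter frequencies of a training set (iterative Boltzmann correction:
   `e_ref += lambda * log(p_sim / p_target)`, damping `lambda = 0.5`,
   gauged to zero mean since the equilibrium is invariant to constant
   shifts, capped at &plusmn;4). The cap matters: with a loose cap an
   unconverged fit can pin the many never-observed letter *pairs* at very
   large energies, and the resulting landscape is glassy — the sampler
   freezes far from the native basin. &plusmn;4 kT still suppresses
   never-observed geometry by e&#8308; &asymp; 55&times; while leaving the
   landscape crossable at the annealing temperatures. No sequence
   information enters any term.

## Sampling

Three local Monte Carlo moves keep the loop closed by construction:
crankshaft rotations of 2&ndash;4-residue segments about the axis through
their end atoms, bond moves displacing the two atoms of one virtual bond by
equal and opposite amounts along it, and angle moves rotating the two outer
atoms of a triple by equal and opposite angles about the plane normal.
Anchors may serve as rotation-axis endpoints but are never displaced, and no
closure post-processing exists anywhere.

One design point deserves emphasis. Rigid crankshaft rotations preserve
Cartesian volume, but the bond move is a radial map (Jacobian (r'/r)&sup2;)
and the angle move a polar one (Jacobian sin&theta;'/sin&theta;). Plain
Metropolis acceptance with these moves would therefore sample a measure that
is *not* the Cartesian Boltzmann distribution — detectably so: the bond-
length marginal of a toy loop comes out without its r&sup2; geometric
factor. The acceptance rule therefore includes the move's log-Jacobian,
`min(1, exp(-beta dE + log J))`. With the correction, a 10&#8311;-step
fixed-&beta; run of a two-mobile-residue toy reproduces the bond-length
marginal computed by numerical quadrature to Kolmogorov–Smirnov
p &asymp; 0.4 at 10&#8309; samples (the test suite repeats this check).

Annealing follows the canonical 400-step inner cycle — 50 steps at
&beta;_low, 100 linearly ramping, 250 at &beta;_high — repeated 30 times
(12000 steps) for the initial relaxation and once per decoy afterwards.
The printed values of the original protocol's two temperatures are not
recoverable, so &beta;_low = 0.2 and &beta;_high = 1.0 are configuration
defaults (`mc_config()`), not constants; likewise move weights
(0.5/0.25/0.25), maximum step sizes (0.5 rad, 0.2 &Aring;) and the
crankshaft span. The inner Metropolis loop runs in compiled code with
incremental energy evaluation over the terms a move touches; the cached
total is checked against a full recomputation every 1000 steps (observed
drift &lt; 10&#8315;&sup9;). A single seed reproduces an entire ensemble bit
for bit.

## Backbone reconstruction and filtering

N, C and O atoms are rebuilt per peptide unit from a look-up table indexed
by discretised local C&alpha; geometry — the two skip distances d(i&minus;1,
i+1) and d(i, i+2) in 0.2 &Aring; bins plus the chirality sign of the tetrad
— whose payload is the mean placement of C(i), O(i), N(i+1) in the residue's
local frame. Sparse keys fall back to the nearest populated key. This
discretisation is this package's own design, validated by a reconstruction
oracle (rebuilding the training structures from their traces) rather than by
matching any external tool. Terminal residues use borrowed keys and
extrapolated frames and are flagged approximate. On the shipped training
family the per-atom reconstruction error is 0.18&ndash;0.76 &Aring; (mean
0.32): regular secondary structure rebuilds to ~0.2 &Aring;, while long
irregular coil can exceed 0.5 &Aring; where sparse keys average
heterogeneous peptide orientations — a known limitation.

Candidates are screened by counting loop residues whose (&phi;, &psi;)
falls in strictly forbidden cells of a non-residue-specific 10&deg;
Ramachandran map. "Strictly forbidden" is operationalised as "far from
anything observed in training": cells within two cells of observed density
are allowed, everything else forbidden (63% of the map). The filter is
adaptive — accept iff N_forbidden &le; N_best + margin, with N_best the
lowest previously accepted count, initialised to the loop length so the
first conformation always passes. The printed inequality of the original
rule is partially lost, so the margin is configurable. The package default
is margin = 1: with this conservative map, margin 0 drives N_best to zero
and then passes only the few-percent of decoys with no forbidden residue at
all — control-mode runs stall outright, defeating the rule's stated
purpose of never getting stuck. At margin 1 the rejected fraction on the
bundled targets is roughly 30&ndash;70%, the right order for a quality
filter that still lets sampling proceed.

Accepted decoys are regularised by conjugate-gradient minimisation
(Polak–Ribière with restarts, via the `type = 2` conjugate-gradient method
of `stats::optim`, run in chunks so the energy trace is recorded and
non-increasing) in a united-atom backbone potential: harmonic bonds and
angles, periodic torsions, a harmonic improper keeping the carbonyl planar,
Lennard-Jones on 1-4 and 1-5 intra-backbone pairs (geometric-mean
combination), soft sterics against everything else including the fixed
scaffold, and a binned backbone H-bond table over H&hellip;O distance and
N&ndash;H&hellip;O angle (amide H inferred by a bisector construction).
Two deliberate deviations from a plain physical force field:

* the &omega; torsion is a *single-minimum* trans restraint
  (V(1 + cos &omega;), V = 80) rather than the physical cis/trans double
  well —
  cis peptides are out of the model's scope, and a cis-capable well traps
  rebuilt twisted peptide units during minimisation;
* the two junction peptide units of a spliced decoy are re-seeded from the
  native anchors' internal coordinates, and any residually twisted unit is
  rotated to the most trans-like orientation about its C&alpha;&ndash;
  C&alpha; axis (mobile atoms only) before minimisation.

With these, &ge; 99% of minimised loop residues satisfy the stereochemistry
tolerances (bond lengths within &plusmn;0.25 &Aring; of standard values,
&omega; within &plusmn;30&deg; of trans).

## Ranking and statistics

The prediction is the decoy with the lowest backbone energy; an all-atom
re-scoring stage is outside this package's scope, and predictions are
labelled accordingly. Ensemble accuracy is summarised by best and mean
RMSD-G and the fractions below 1 and 2 &Aring;, with 95% percentile
confidence intervals from an m-out-of-n bootstrap (resample 1000 decoys
with replacement per replicate, 1000 replicates) — m-out-of-n so that
ensembles of different sizes can be compared at a common effective size.

## The synthetic training family

All shipped defaults are trained on `fixture_family()`: ideal helices,
strands, helix/strand&ndash;loop&ndash;helix motifs with loop lengths
2&ndash;12 and free coil runs, built by internal-coordinate chain growth at
ideal peptide geometry, loop &phi;/&psi; drawn from a six-basin coil library
with 10&deg; jitter, plus 0.08 &Aring; Gaussian coordinate noise (roughly
crystallographic precision). The family emulates the *local* features that
matter to the model — letter geometry, peptide-unit placement, Ramachandran
occupancy, H-bond distance distributions. It does not emulate real-data
features like side-chain packing pressure, sequence-dependent dihedral
preferences, crystal contacts, or the breadth of loop conformations in the
PDB. Passing tests on this family therefore demonstrate internal
consistency and the qualitative sampling claim (the full potential
concentrates ensembles nearer the native loop than a bond+steric control),
not benchmark-grade accuracy on real proteins; absolute RMSD-G values here
are 2&ndash;4 &Aring; worse than what a PDB-trained potential achieves.

## Problem sizes used by the tests and the acceptance script

Fixture targets are 22&ndash;30 residues with loops of 4&ndash;10 residues;
ensembles are 50&ndash;200 decoys per mode (the headline pd2-vs-control
comparison uses five loops of lengths 6&ndash;10 at 200 decoys each, with
per-decoy backbone minimisation disabled since the comparison concerns
C&alpha;-level sampling); the Boltzmann check uses 10&#8309; samples thinned
from 10&#8311; steps; reference-energy recovery uses two 20-residue chains
and a 3-letter alphabet. These sizes were chosen so each property is
measured with comfortable statistical margin on a single CPU.

## Known limitations

* The alphabet, map, tables and reference energies shipped are synthetic-
  family artefacts; retrain on real structures before drawing biological
  conclusions (`train_alphabet`, `build_rama_map`, `build_lookup_table`,
  `fit_reference_energies`, `scripts/make_defaults.R`).
* The reference-energy fit on the 27-letter alphabet does not fully
  converge on the small training family (rare letters sit at the cap);
  unigram/bigram equilibria are reproduced only approximately.
* Reconstruction error on irregular coil can reach ~0.7 &Aring; per atom.
* The H-bond tables are piecewise constant, hence invisible to gradient-
  based minimisation (their gradient is zero almost everywhere); they shape
  sampling and scoring, not minimisation.
* No sequence information, no side chains, no cis-peptides, no solvent.
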