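---
title: "Grid cell occupancy 4D-QSAR: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid cell occupancy 4D-QSAR: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsar4d)
```

## The model

Classical 3D-QSAR assigns each compound one conformation. The
four-dimensional variant treated here replaces that single pose with a
conformational ensemble profile (CEP): a large sample of conformations
per compound, here nominally 2,000 per molecule, each rigidly aligned to
a reference compound by a three-atom superposition. A cubic lattice is
laid over the aligned ensembles and, for each cell and each interaction
pharmacophore element (IPE) class — `any`, nonpolar `np`, polar-positive
`p+`, polar-negative `p-`, hydrogen-bond acceptor `hba`, donor `hbd`,
aromatic `ar` — the grid cell occupancy descriptor (GCOD) is the raw
occupation count across the ensemble divided by the CEP size. Several
atoms of one class in one cell in one conformation each count, so a GCOD
may exceed 1; the `any` class contains every atom, so its occupancy
dominates every other class cell-wise and sums, over cells, to the atom
count per conformation. Both properties are asserted as tests.

Activity is modeled as a sparse linear equation over GCODs,
`pIC50 = b0 + sum(b_k * GCOD_k)`, with pIC50 the negative decadic log of
the molar IC50. Subset selection is done by a genetic algorithm whose
fitness is Friedman's lack-of-fit,
`LOF = (LSE/M) / (1 - (c + d p)/M)^2`, where LSE is the training sum of
squared residuals, `M` the number of training compounds, `p` the number
of selected descriptors, `c = p + 1` counts the intercept, and `d` is the
smoothing factor. Each candidate subset is fitted by partial least
squares (PLS1), with coefficients back-transformed to descriptor space so
every model prints as a plain linear equation.

## Study conditions and tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| schedule | 310 K, 100 ps, 0.001 ps, record/50 | — | yields 2,000 snapshots, the benchmark CEP size |
| cell size | 1.0 (2.0 supported) | Å | the published best models come from the 1.0 Å lattice |
| reduction | \|R\| ≥ 0.1, variance floor, ≤ 37/41 empty | — | the three serial filters with the published ceilings; presets `a1_c20` … `a3_c10` carry the published per-alignment values |
| GA | population 100, 6,000 crossovers, mutation prob 1.0, smoothing d = 1.0 | — | crossover count at the published lower bound (range 6,000–20,000); smoothing inside the published 0.5–3.0 range |
| model size | ≤ 9 terms, sweep over sizes | — | larger models were avoided as overfitting-prone in the source analysis |
| energy window | 10.0 | kcal/mol | bioactive-conformer rule: most potent conformer within the window above the ensemble minimum |

PLS component count defaults to full rank, which makes each subset fit
coincide with ordinary least squares (asserted at 1e-8 against a
normal-equations oracle) — appropriate because the GA already controls
dimensionality. A fixed count or a leave-one-out-selected count
(`pls_components = "auto"`) is available for collinear pools.

## Grid registration

Cell indices follow `floor((p - origin)/cell_size)` per axis with
half-open cells. The default origin is `-cell_size/2` per axis, so cells
are *centered* on integer multiples of the cell size and a descriptor
index reads as the Cartesian coordinates of its cell center. This is a
deliberate choice with a numerical reason: after three-point
superposition the alignment atoms lie exactly in the reference triple's
plane, and with boundaries on the integer lattice (origin 0) that plane
is a cell boundary — the cell assignment of every alignment atom then
flips on 1e-16 noise, which broke the rigid-motion-invariance property in
testing. With center registration the property holds to 1e-10 and is
asserted as a test. The origin remains overridable.

The published equations are keyed by the original program's absolute cell
indices, whose registration is not recoverable. Those indices therefore
form their own namespace: the shipped models predict from occupancy
vectors keyed by the published indices, and applying them to newly
sampled ensembles requires an explicit registration offset (identity by
default, with this caveat). De-novo searches use the package's own
registration throughout.

## The stand-in sampler

The original force-field molecular dynamics engine is replaced by a
Metropolis torsional sampler: rotatable bonds (non-ring single bonds with
heavy neighbors on both sides) receive Gaussian torsion proposals plus a
small Cartesian jitter, accepted at the schedule temperature under a
periodic-torsion-plus-soft-sphere-clash energy, with snapshot thinning
applied inside the sampler. The downstream descriptors consume only the
snapshot ensemble, so any Boltzmann-consistent sampler exercises the
pipeline; externally generated ensembles can be imported via multi-record
SDF (energy in an `ENERGY_KCAL` field) or multi-frame XYZ (energy on the
comment line). Tests check fixed-seed determinism, the closed-form
pairwise RMSD of the rigid-molecule case (independent jittered copies of
the seed — a chain of accepted jitter moves would random-walk away), and
the stationary distribution on a two-level torsional potential against
the analytic Boltzmann ratio at 310 K. Energies are reported relative to
the ensemble minimum, matching how the 10 kcal/mol bioactive-conformer
window is expressed. Whether the original workflow energy-filtered
snapshots before descriptor generation is not stated; all snapshots enter
the CEP here.

## Atom typing

The source method names its seven IPE classes without a typing table, so
one is defined and exposed: `np` is carbon and hydrogen on carbon; `p+`
is formal charge > 0 or partial charge ≥ +0.25 (a protonated amine
nitrogen and its hydrogens); `p-` is formal charge < 0 or partial charge
≤ −0.25 (phenolic and carbonyl oxygens under the built-in rule charges);
`hba` is N/O/S with a free lone pair (positively charged heteroatoms
excluded); `hbd` is hydrogen on N/O/S together with that heteroatom; `ar`
is membership in a perceived 5- or 6-membered ring whose atoms are C/N/O/S
with total degree ≤ 3. The degree rule requires explicit hydrogens and
correctly excludes saturated rings (piperidine) while keeping benzene,
thiophene and pyridine. When no partial charges are supplied, coarse
rule-based charges stand in; user charges override them. The `any` class
includes hydrogens — whether the original did is unstated.

## The synthetic series

The generator emulates a congeneric series at the study scale: 41
training plus 13 test compounds, 15 atoms each (3 fixed alignment
anchors), 2,000 conformations. One scaffold cloud is drawn once in an
8 Å box; each compound displaces every scaffold atom by N(0, 0.5 Å) —
the analog-to-analog structural variation — and each conformation adds
N(0, 0.35 Å) jitter, the conformational spread. Activities are planted:
`pIC50 = 7.5 + 8·g1 − 6·g2 + 4·g3 + N(0, 0.1)`, with the three true
GCODs drawn from high-variance cells occupied by at least half the
training compounds. That last restriction is deliberate: a causal
descriptor occupied by almost nobody is (correctly) removed by the
empty-cell reduction filter, so planting on it would make recovery
impossible for any search method, not a defect of this one. An earlier
design with unrelated per-compound clouds had exactly that failure mode —
congeneric structure is the regime occupancy descriptors assume.

What the generator does *not* emulate: real torsional correlation
structure, class-heterogeneous atoms (clouds are all-carbon, so only the
`any`/`np` classes populate and the pool is restricted to `any` to avoid
duplicated columns), and the benchmark's actual occupancy values. Passing
recovery tests therefore demonstrate correctness of the machinery —
descriptor accounting, filtering, search, validation — not chemical
accuracy on raloxifene analogs.

## Numerical choices and degenerate inputs

* Superposition is Kabsch on the three alignment atoms with determinant
  +1 enforced (three points otherwise admit a reflection); collinear or
  duplicate triples raise a degeneracy error.
* The correlation filter uses |R| — negative correlations are
  informative, and several published coefficients are negative. A
  zero-variance column has no defined correlation, passes stage 1 and
  falls to the variance filter; variance uses the n−1 denominator.
* The residual SD is the n−1 standard deviation about the residual mean.
  On the packaged residual tables this rounds to 0.38 for both the
  training and the test set of the representative alignment-1 model and
  reproduces every published outlier call; an RMS-about-zero reading
  would give 0.37 on the test set and was rejected for that reason.
  Outliers compare |residual| to twice the SD (the flagged training
  compound's residual is −0.81, so a signed reading would miss it).
* The adjustment of R² and Q² is Wherry's,
  `1 − (1 − stat)(n − 1)/(n − p − 1)`, with `p` the number of model
  terms; the source does not print its formula.
* GA specifics the source leaves open: rank tournament (k = 2) parent
  selection, steady-state replacement of the worst member, elitism of the
  incumbent best, and mutation probability 1.0 read as "every offspring
  undergoes exactly one mutation event" (swap 80%, insert 10%, delete
  10%, respecting size bounds). Equal-LOF candidates are ranked by
  adjusted Q². On pools of ≤ 12 descriptors the search provably reaches
  the exhaustive-enumeration optimum (asserted in tests).
* PLS handles a constant column by a zero loading; a constant response
  returns the mean with zero coefficients; infeasible LOF sizes
  (`M ≤ c + d·p`) mark the candidate worst rather than aborting the run.
* Models whose adjusted Q² falls below 0.5 are flagged as weak in run
  summaries — mirroring how an under-performing intermediate size was
  eliminated in the source analysis — but never silently dropped.

## Problem sizes

The test suite and the acceptance script scale the simulations to what
their assertions need: toy molecules and 5–2,000-conformer ensembles for
unit properties, a 20–26-compound series for pipeline contracts, and the
full 54-compound, 41-train series (400 conformations per ensemble, which
fixes occupancy frequencies to ±2.5% resolution — ample for recovery) for
the planted-recovery acceptance run. The `analysis/` scripts run the full
2,000-conformer study conditions.

## Known limitations

* The published models cannot be re-derived here: that requires the
  original MD ensembles and grid registration. What is reproduced exactly
  is everything computable from printed tables (equations, residual
  statistics, outlier calls, lattice geometry) plus the full pipeline on
  synthetic data.
* The two source activity tables disagree for compound 43 (6.49 vs the
  residual table's self-consistent 6.46); both fixtures keep their
  printed values.
* Atom typing and alignment atom identities are declared conventions, not
  recovered facts; both are config-overridable.
* The torsional energy is a stand-in. It is Boltzmann-consistent but not
  a force field; imported ensembles should be preferred when fidelity to
  real conformational distributions matters.
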