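---
title: "Two-state conformer modeling and composite scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state conformer modeling and composite scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trxscore)
library(dplyr)
```

## The problem

In time-resolved serial femtosecond crystallography (TR-SFX), a pump-probe
experiment captures diffraction from crystals in which only a fraction of
the molecules has responded to the trigger. The crystal is therefore a
mixture: a dominant reference (resting) state and a weakly populated
triggered state. Refining a single model against triggered-state data tends
to reproduce the resting structure, because its population dominates the
density. The established remedy is a *two-state model*: the reference
structure is kept as conformer A, and the triggered state is built as
alternative conformer B with fractional occupancy, guided by the
isomorphous difference density (triggered minus reference), whose positive
peaks mark arriving atoms and negative peaks departing ones.

`trxscore` implements the machinery around this strategy for the setting
where candidate B conformers come from a large sampled pool (for example
molecular-dynamics snapshots): superposing candidates on the reference,
merging them as alternative conformers with correct occupancy and B-factor
bookkeeping, validating each refined two-state model in real space and in
geometry, and ranking the pool with a composite score so that the best
model can be picked automatically rather than by manual inspection.

## The two-state merge

For each candidate conformer, the triggered residues (those showing
difference density) are merged into the reference:

* reference atoms of a selected residue become altloc `A` with occupancy
  $1 - q$, the candidate's atoms become altloc `B` with occupancy $q$;
* the initial occupancy is $q = 0.25$, the conventional starting value for
  group-occupancy refinement of a weak state, and all B atoms form a single
  occupancy group so the complement constraint
  $\mathrm{occ}(A) + \mathrm{occ}(B) = 1$ holds for every atom pair;
* each B atom inherits the B-factor of its same-named A atom — the two
  states are assumed to share atomic displacement parameters, so occupancy
  and B-factor do not trade off against each other during refinement;
* candidate hydrogens are dropped by default (hydrogen placement is an
  external, optional step), and the merge is whole-residue: backbone and
  side chain are duplicated together.

Merging is strict about bookkeeping: a candidate atom with no same-named
reference atom has no B-factor source and raises an error naming the atoms,
rather than guessing. Candidates are matched to the reference by residue
key (chain, number, insertion code), not by sequence alignment, and a
residue-name mismatch at the same key is an error.

## Real-space validation metrics

Observed maps enter as voxel grids on orthorhombic cells (CCP4/MRC mode-2
files or grids built in memory). Around each triggered residue a mask
collects the voxels within 2.0 Å of the conformer-B atoms (2.0 Å is the
radius conventionally used to clip density around a residue for
inspection; it is configurable). Over the mask the package computes:

* **RSCC** — the Pearson correlation between observed and model density;
  above 0.7 indicates a strong match.
* **RSZO** — the mean observed density over the mask divided by the map
  noise $\sigma$; above 2 indicates well-resolved density.
* **RSZD+/RSZD−** — the positive and negative extreme Z values of the
  residual difference map within the mask. This is a deliberate *peak-Z
  simplification* of the residual-density Z statistic popularized by
  EDSTATS: it shares the range, sign convention and the "below 3 is
  acceptable" interpretation, and it is exactly reproducible by a
  brute-force scan, which makes it testable. Externally computed values
  can be ingested instead wherever EDSTATS output is available.

The map noise convention is the full-grid rms by default; a
median-absolute-deviation estimator is available for heavy-tailed maps
(for example difference maps with strong local signal). The masks default
to the B-conformer atoms of each triggered residue, since those are the
atoms whose placement is under test; this is configurable.

Model density, where needed (simulation, mock refinement, surrogate
R-factors), uses a single-width Gaussian atom model: amplitude
$\mathrm{occ}\cdot Z$ electrons and variance $B/(8\pi^2) + 0.9$ Å².
The fixed 0.9 Å² core width stands in for the intrinsic atomic form
factor so that a $B = 0$ atom still has finite width. This is a
desk-scale density engine aimed at metric correctness — linear in
occupancy, additive over atoms, unit integral per electron — not at
scattering accuracy; it does not model solvent, anisotropy, or
multi-Gaussian form factors.

## Difference-density weights

Not all triggered residues carry equal signal. Each residue is weighted by
its share of the isomorphous difference density: every voxel with
$|\Delta\rho|/\sigma \ge 3$ (the conventional contouring level) is
assigned to the selected residue owning the nearest atom, within a capture
radius of 3.5 Å, and the positive and negative sums
$\rho_{\mathrm{pos},j}, \rho_{\mathrm{neg},j}$ accumulate per residue.
Voxels nearest to unselected residues are discarded rather than
reassigned — weight should only flow to residues that are actually being
remodeled. The voxel-assignment rule is our own; tools that cluster
difference-density blobs may partition the signal slightly differently,
which affects the weights but not their qualitative ordering.

## The composite score

For a batch of $n$ candidate models, every raw metric $S$ is min-max
normalized across the batch,
$$S' = \frac{S - \min S}{\max S - \min S},$$
so that heterogeneous units cannot dominate the sum. The composite is

$$\mathrm{Composite} = \underbrace{R'_\mathrm{free} + R'_\mathrm{work}}_{\text{R-factor term, } [0,2]}
 + \underbrace{\mathrm{MolProbity}' + \mathrm{Ramachandran}' + \mathrm{Rotamer}' + C'_\beta + \mathrm{RMS}'_\mathrm{bond} + \mathrm{RMS}'_\mathrm{angle} + \mathrm{Clash}' + \mathrm{RMSD}'}_{\text{geometry term, } [0,8]}
 + \underbrace{\mathrm{RSZD}' + (1-\mathrm{RSCC}') + (1-\mathrm{RSZO}')}_{\text{density term, } [0,3]}$$

with lower values better throughout; RSCC and RSZO are inverted because
higher raw values are better for them. The density term uses

$$\mathrm{RSZD}_n = \frac{1}{m}\sum_{j=1}^{m}\left(\rho_{\mathrm{neg},j}\,|\mathrm{RSZD}^-_{j,n}| + \rho_{\mathrm{pos},j}\,|\mathrm{RSZD}^+_{j,n}|\right)$$

over the $m$ residues of the weight set (zero-weight residues included in
$m$, matching the summation bound), and batch averages
$\bar v_n = \frac1R \sum_r v_{n,r}$ of RSCC and RSZO over the $R$ residues
modeled with alternative conformers.

Numerical conventions, chosen where the scheme itself is silent:

* a constant metric pool (max = min) normalizes to all zeros — the metric
  then simply cannot discriminate;
* a metric column missing for the *whole* batch is dropped from the sum
  with a warning (the geometry term's nominal range shrinks accordingly);
  a metric missing for *some* models assigns those models the worst
  normalized value 1 and flags them — incomplete validation is never
  rewarded;
* the normalization pool is exactly the batch being ranked; an external
  comparison model joins the pool only if explicitly added;
* ties in the composite are broken by lower R-free, then model id, so
  rankings are total and reproducible;
* averages of RSCC/RSZO run over the triggered residues (the residues
  with alternative conformers), not the whole chain — this follows the
  definition of $R$ above and is configurable upstream by changing the
  selection.

MolProbity score, Ramachandran, rotamer and Cβ outliers are not computed
natively — they require curated torsion libraries — and enter only through
the ingestion path (`ingest_external_metrics()`). When absent they
contribute 0 with a warning. The native geometry engine provides the other
four terms: a heavy-atom clashscore (vdW overlap ≥ 0.4 Å per 1000 atoms,
with template-derived bonded-path exclusion and the rule that atoms in
different non-blank altlocs never clash), bond and angle RMS deviations
against a compact Engh–Huber-style backbone + Cβ restraint subset (atoms
outside the templates are skipped and counted, never guessed), and the
conformer-B-to-A RMSD without re-superposition.

## Ensemble analysis

Heterogeneity of the candidate or refined pool is summarized by RMSF. For
atom $i$ over $N$ aligned frames,
$$\rho\mathrm{RMSF}_i = \sqrt{\tfrac1N\sum_{n=1}^N |r_{i,n} - \bar r_i|^2},$$
and the per-residue profile is the RMS of its atoms' values,
$\mathrm{RMSF}_{\mathrm{res}} = \sqrt{\tfrac1M \sum_i \rho\mathrm{RMSF}_i^2}$.
The RMS form is the default; a plain-mean aggregation (`agg = "mean"`) is
also provided because the two readings are both in circulation. Frames are
used as given — RMSF deliberately performs no re-superposition, so the
workflow always aligns frames on reference Cα atoms (Kabsch least squares)
first. A residue profile below 1 Å marks stable refined coordinates and is
carried as a flag in the output.

## The synthetic benchmark

Real TR-SFX benchmarks require thousands of reciprocal-space refinements
against experimental structure factors; none of that is reproducible at
desk scale. The package therefore ships a generator that emulates the
*structure* of the problem end to end:

* a poly-alanine toy chain (helix or strand) built at exactly the packaged
  ideal geometry, so the geometry metrics have a known zero;
* a planted truth: the triggered residues (by default the three central
  ones of a 20-residue chain) rigidly displaced by 1.0 Å each;
* a decoy pool of 200 conformers, 10 of which are the truth plus 0.05 Å
  per-atom Gaussian noise ("near"), the rest the reference plus 0.5 Å
  noise ("far", i.e. resting-state-like);
* maps: reference map $\rho_A + \varepsilon$ and triggered map
  $(1-q)\rho_A + q\rho_B + \varepsilon'$ with $q = 0.25$ (the canonical
  initialization occupancy, used here as the true mixing fraction) and
  i.i.d. Gaussian voxel noise at 5% of the reference-map rms. Spatially
  uncorrelated noise is adequate for exercising the metrics but is *not*
  a model of real map error, which is correlated through the Fourier
  transform; passing tests here demonstrate bookkeeping and statistical
  correctness, not performance on experimental maps;
* a mock occupancy refiner: the least-squares $q$ minimizing
  $\sum_v (\rho_\mathrm{obs} - (1-q)\rho_A - q\rho_B)^2$, solved in closed
  form and clamped to $[0,1]$. It adjusts occupancy only — coordinate
  refinement is exactly the step the workflow delegates to an external
  refiner, for which a command-template contract is provided.

Default problem sizes (20 residues, 0.6 Å voxels, 200 decoys, 20-replicate
recovery studies) were chosen as the smallest sizes at which the mixture
signal, the decoy separation and the statistics of the recovery rate are
all comfortably resolved; they are the package's reference conditions and
are what the test suite and the acceptance script run.

With these conditions the pipeline's planted-truth recovery — merge each
decoy, mock-refine its occupancy, measure density and geometry metrics,
score and rank — selects a near-truth decoy as rank 1 in at least 95% of
seeded replicates, and reference-like decoys do not enter the top 1%.

## Degenerate inputs and edge policies

* Constant maps have $\sigma = 0$: flagged, and Z-based metrics error
  rather than divide by zero.
* Zero-variance density within a mask makes RSCC undefined; it is returned
  as `NA` with a warning, and the scoring layer's missing-value policy
  takes over.
* A difference map with no voxel above the Z threshold yields all-zero
  weights plus a warning (the density term then cannot separate models by
  RSZD).
* Identical conformer densities make the mock occupancy unidentifiable —
  an error, not a silent 0/1.
* Frames that fail any pipeline stage (unparseable, missing residues,
  failed refiner) are recorded as `failed:<reason>` in the run manifest
  and skipped; a batch only aborts if every frame fails.
* Non-orthorhombic cells are rejected with a clear error everywhere grids
  are built; periodic wrap is not supported and atoms outside the grid are
  an error.

## Known limitations

* The density engine is a single-Gaussian approximation; absolute density
  values are not on the scale of likelihood-weighted experimental maps.
* RSZD here is a peak-Z statistic, not the EDSTATS estimator; when exact
  EDSTATS values matter, ingest them.
* Reciprocal-space refinement, hydrogen placement, covalent-link restraint
  setup and full MolProbity statistics are external by design; the package
  provides contracts (command template, metric ingestion) rather than
  reimplementations.
* The clash detector skips same/adjacent-residue pairs whose atoms are
  unknown to the restraint templates, so exotic residues only participate
  in long-range clash checks.
* Re-running a pipeline with the same configuration reproduces identical
  outputs (runs are deterministic given their inputs and seed); resuming
  a partially written output directory is not implemented.
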