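---
title: "Methods: confidence-aware interface analysis and SPR binding fits"
author: "coilface"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: confidence-aware interface analysis and SPR binding fits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the package's methods work, which knobs matter,
and which design choices were genuinely open — in enough detail that a
reader can judge what a passing test suite does and does not demonstrate.

## The analysis problem

The package targets 2:1 complexes of the Trim28 coiled-coil homodimer
with a KRAB domain, as produced by structure predictors: two ~30-turn
antiparallel amphipathic helices with a small four-helix domain bound
across the two-fold axis at their centre. A predicted model arrives with
per-residue confidence (pLDDT, 0–100, stored in the B-factor column) and
a predicted-aligned-error (PAE) matrix. The analysis pipeline is:
confidence pruning → superposition/RMSD against references → interface
characterization (burial, spans, typed contacts, pockets, pins) →
independent validation of the proposed interface by mutant binding
affinities measured by SPR.

## Confidence handling

* **Pruning** removes whole residues with pLDDT strictly below the
  threshold (default 50). The boundary is deliberate: residues *at* the
  threshold are kept, matching the usual "less than 50" phrasing of the
  pre-processing step. Pruning never removes single atoms, because pLDDT
  is a per-residue score. Chains emptied entirely disappear.
* **Residue pLDDT** is the CA B-factor (the predictor convention), with
  the mean over the residue's atoms as a fallback for CA-less residues.
* **PAE blocks**: AlphaFold PAE is asymmetric (error of residue *i* when
  aligned on *j*), so `paeBlock()` reports both the directional mean and
  the symmetrized mean (average of both directions). The symmetrized
  mean is the headline number for "how confidently is domain X placed
  relative to domain Y"; no numeric PAE threshold is imposed anywhere,
  since none is standard.

## Superposition

`kabschFit()` is the SVD form of least-squares rigid superposition with
the determinant sign correction, so reflections are never returned.
Inputs with fewer than 3 points, or collinear points (second singular
value ≈ 0), are rejected rather than silently fitted. "All equivalent
atoms" means heavy atoms paired by (chain, author residue number,
insertion code, atom name); hydrogens are excluded by default because
predicted models lack them, and no sequence-alignment-based residue
correspondence is attempted — when chain labels differ (a monomer
against one chain of a dimer), the caller supplies an explicit chain
rename. An independent quaternion characteristic-polynomial oracle in
the test suite checks RMSDs to 1e-8 on random clouds.

## SASA and buried surface area

The Shrake–Rupley engine samples each atom's solvent-extended sphere
(van der Waals radius + probe) with a deterministic golden-spiral point
set — identical runs give identical areas, with no RNG involvement.
Defaults are field-standard and configurable: C 1.70, N 1.55, O 1.52,
S 1.80 Å (Bondi), probe 1.4 Å, 960 points per atom. At 960 points the
single-sphere quadrature error is far below 0.1 % and per-residue areas
agree with an independent implementation (biotite's Shrake–Rupley,
frozen oracle values in the tests) within 2 %.

Buried surface area of a two-group partition is computed as
`BSA_i = SASA_i(isolated) − Σ per-atom SASA_i(within complex)`, which
guarantees the identity `BSA₁ + BSA₂ = SASA₁ + SASA₂ − SASA₁₂` to
numerical precision (asserted at 1e-3 in the tests). For a dimer + domain
complex the two dimer chains together form "one molecule", matching how
per-molecule burial is conventionally quoted for 2:1 complexes; a
per-chain breakdown is reported alongside. Tiny negative per-group
values (quadrature noise on non-interacting groups) are clamped to zero
in reports.

## Contacts, clusters, pins

Contact classes are distance-only — predicted models have no hydrogens,
so angle terms would be guesses. Defaults (all exposed as arguments and
CLI flags): salt bridge ≤ 4.0 Å between a sidechain N of Lys/Arg/His and
a sidechain carboxylate O of Asp/Glu; hydrogen bond ≤ 3.5 Å between any
N/O pair; hydrophobic ≤ 4.5 Å between sidechain carbons of
Ala/Val/Leu/Ile/Met/Phe/Trp/Tyr/Pro. A pair qualifying as both salt
bridge and hydrogen bond is counted once, as a salt bridge (priority
order salt bridge > hydrogen bond > hydrophobic), to avoid double
counting.

A residue is **interfacial** if it loses more than 0.1 Å² of SASA on
complex formation or has any cross-partition heavy-atom pair within
5.0 Å; spans are per-chain min/max author numbers over that set.

**Hydrophobic clusters** are connected components over one side's
residues that carry cross-partition hydrophobic contacts; edges join
residues sharing a contact partner on the other molecule or sequence
neighbours (same chain, |Δresno| ≤ 4). The default side is group 2
because in the motivating system the pockets live on the KRAB domain:
each cluster's `partnerPins` — the other molecule's residues contacting
at least half of the members — are then exactly the pin residues seated
in that pocket.

A **pin** is a group-1 residue whose sidechain buried fraction
(sidechain ΔSASA over its sidechain SASA in the isolated group) is at
least 0.75 and which touches at least 4 distinct hydrophobic partner
residues. These two thresholds are heuristics, not published constants:
they were calibrated once on the synthetic benchmark so that its
designed, deeply seated leucines qualify (buried fractions 0.96 and
0.84) and no ordinary surface residue does, and they are surfaced as
arguments for real-data use.

The asymmetry flag of `interfaceReport()` is set when the per-chain
interface spans of a two-chain group differ — the signature of a domain
bound asymmetrically across a homodimer's two-fold axis.

## SPR binding models

**Steady state.** `Req = Rmax·C/(Kd + C)`, fitted by Levenberg–Marquardt
on log-parameters (positivity for free) from 8 log-spaced Kd starts
spanning the concentration range. A series that does not bracket the
fitted Kd (all concentrations ≫ or ≪ Kd) is reported with
`converged = FALSE` and a diagnostic instead of a confident number.

**Two-state kinetics.** The scheme `A + B ⇌ AB ⇌ AB*` with response
`AB + AB*`, analyte at C during injection and 0 afterwards:

d[AB]/dt = ka1·C·(Rmax − AB − AB*) − kd1·AB − ka2·AB + kd2·AB*;
d[AB*]/dt = ka2·AB − kd2·AB*.

The apparent dissociation constant is
`Kd,app = (kd1/ka1) · kd2/(kd2 + ka2)`. The instrument software's exact
internals are proprietary; this canonical conformational-change
parameterization is adopted and documented. Within each phase the system
is a linear constant-coefficient ODE, so the forward model is evaluated
in closed form via the analytic 2×2 matrix exponential
(`exp(Mt) = e^{st}[cosh(qt)·I + sinh(qt)/q·(M − sI)]`, with real,
complex and repeated-root branches). Because the trace is negative and
the determinant non-negative for positive rates, both eigenvalues are
non-positive and the expression never overflows; when the
conformational-step rates underflow to numerical zero the model reduces
exactly to the closed-form 1:1 limit, which is used directly. The tests
verify the closed form against an independent `deSolve::lsoda`
integration (rtol 1e-10) to 1e-6 RU and against the analytic 1:1 curves.
A stiff-solver fallback remains for degenerate inputs but is unreachable
for positive rates.

Global fits share one parameter set across all sensorgrams of a
concentration series, use log-parameterization, and start from at least
8 log-spaced apparent-Kd seeds (fixed grid — reproducible without an
RNG). Standard errors come from the Gauss–Newton information matrix via
the delta method; a singular direction yields wide (infinite) errors and
a diagnostic, not a failure, since flat-likelihood directions are a
property of the data, not an error of the fit.

**Fold decreases** are round-half-up integers of `Kd,mut/Kd,ref`
(`floor(ratio + 0.5)`; R's `round()` is banker's rounding and would give
different integers at .5 boundaries). Applied to the shipped mutant
affinity panels with the 14.6 nM wild-type reference, this reproduces
every published integer fold that is arithmetically consistent with the
published rounded Kd values. Five published rows (grouped mutants
Turns 3–4 and Turns 5–6, and point mutants L301S, K305E, M304S) are not:
their folds were evidently computed from unrounded estimates. Those rows
are flagged `discrepant` and reported with the recomputed ratio and a
note — reproducing them "exactly" from the rounded inputs would be
fabrication. Binding-deficient entries get a qualitative flag and no
fold.

## The synthetic benchmark: what it emulates, and what it does not

`buildComplex()` constructs the study conditions as a fixture with known
answers:

* two 108-residue helices (30 turns × 3.6 residues; ideal geometry,
  1.5 Å rise, 100° twist, ~160 Å core length) antiparallel at 12 Å axis
  separation, each preceded in sequence by a 40-residue linker at
  pLDDT 30 against a core at pLDDT 92 — so pruning at 50 has an exact
  expected answer;
* a four-helix chain C (4 × 14 residues) docked over the dimer midpoint,
  carrying two designed leucine pockets of 7 and 5 residues whose tip
  atoms form a cage (ring plus caps at 4.1 Å) around one pin leucine per
  dimer chain; pins sit at distinct positions (A301, B302) and the two
  chains carry different station sets, so the interface is genuinely
  asymmetric and the flag must fire;
* designed salt bridges (3.4 Å), hydrogen bonds (3.0 Å — one asparagine
  donating to two acceptors, mirroring the single-donor/two-acceptor
  motif of the real interface) and cluster-member contacts (alanine CB
  against the cage, ~3.1 Å);
* a PAE matrix of two-level constant blocks: 2 Å within chains, 5 Å
  between interfaced regions, 25 Å for linker rows — mirroring the
  qualitative structure of real inter-domain PAE without inventing
  numeric claims about any real model;
* sidechains reduced to CB plus one element-typed tip pseudo-atom (NZ
  for Lys, OE1 for Glu, CD1 for Leu, ...), placed at the designed
  interaction geometry rather than built from rotamers. Element typing
  is correct, so the contact rules and SASA radii apply unchanged; tip
  bond lengths are idealized, not rotameric.

After construction the generator audits every cross-partition atom pair:
any pair outside the designed inventory that satisfies a contact rule
within a 0.1 Å margin aborts the build as infeasible geometry. The
ground truth therefore enumerates *exactly* the contacts a correct
classifier must find — the recovery tests are exact set equalities, not
tolerances. Cluster and pin truths come from independent generator-local
code (a plain union-find, versus the analysis module's igraph
components). Two parts of the truth are *not* independent of the
package: the ΔSASA-based tail of the interface-residue set (residues
between the 5 Å contact shell and the ~6.2 Å occlusion horizon) and the
BSA regression values are computed with the package's own SASA engine on
the generated coordinates. The engine itself is validated separately
against closed forms and a frozen external oracle, so these tests
exercise orchestration and bookkeeping, not the quadrature.

What the generator does **not** emulate: real sequences, rotamer
chemistry, supercoiled (Crick) coiled-coil geometry, clashes and
packing quality, or the coordinate statistics of real predicted models.
Passing the recovery tests therefore demonstrates that the detectors
implement their definitions correctly on controlled geometry — it does
not certify the biological defaults (cutoffs, pin thresholds) as optimal
for real structures, which is why all of them are exposed.

The SPR generators (`simulateSensorgramSet()`,
`generateEquilibriumSeries()`) follow the bench protocol: 60 s
injection, 600 s wash, 2 s sampling, a 3-fold serial dilution from 1 µM,
Gaussian noise (1 RU on a 100 RU surface for kinetics; 2 % of Rmax for
equilibrium series), optional linear drift (off by default, as for
reference-subtracted data). Default kinetic parameters
(`ka1 = 1e5 M⁻¹s⁻¹, kd1 = 5e-3 s⁻¹, ka2 = 4e-3 s⁻¹, kd2 = 2e-3 s⁻¹`,
apparent Kd 16.7 nM) sit at the wild-type end of the 15 nM–30 µM
affinity range the mutant panel spans; recovery is additionally checked
at ~750 nM and at 30 µM with fast 1:1 kinetics, since the weakest
binders are exactly where kinetic analysis degrades in practice. All
randomness flows through a single seed per generator call, and the
generators restore the caller's RNG state.

## Numerical choices and problem sizes

* SASA: 960 points/atom; the synthetic complex (≈1,450 heavy atoms)
  takes a few seconds per partition analysis with the compiled engine.
* Equilibrium noise study: 50 seeded replicates at 2 % noise (the median
  relative Kd error is ≈4 %; the 50-replicate median estimator itself
  scatters by ±1.5 percentage points across seed blocks).
* Two-state noise study: 50 seeded replicates at 1 RU noise, 5-point
  dilution series, 8 starts per fit (~0.5 s per fit with the closed-form
  model).
* Ties and degenerate inputs: altloc duplicates keep the
  highest-occupancy copy (ties by altloc character order — predicted
  models have none, experimental references may); empty atom selections
  are allowed and propagate as empty results except where an operation
  is meaningless without atoms (superposition, SASA), which error;
  residue numbers and coordinates that do not fit fixed PDB columns
  error on write rather than corrupting the file.

## Known limitations

* Contact classification is distance-only; no angular hydrogen-bond
  criteria, no energetics, no interface-significance score.
* The published RMSDs against experimental depositions, the ~1,040 Å²
  burial and the published interface spans depend on the authors' model
  files and PDB entries; they are not recomputable from scratch here.
  The pipeline emits reports in the same units and schema when those
  files are supplied, and that schema path is what the tests cover.
* The two-state parameterization is one of several equivalent forms in
  instrument software; only `Kd,app` is directly comparable across
  parameterizations.
* The pin heuristic (75 % burial, ≥ 4 partners) is calibrated on the
  synthetic benchmark, and deliberately conservative; on real models it
  should be read together with the cluster report, not alone.
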