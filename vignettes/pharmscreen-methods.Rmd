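---
title: "Ligand-based pharmacophore screening: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-based pharmacophore screening: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmscreen)
library(dplyr)
```

## The problem

Ligand-based virtual screening asks whether a compound is likely to act on a
target given only what known actives look like.  A 3D *pharmacophore model*
abstracts those actives into a handful of typed spheres — hydrogen-bond
acceptors (HBA), donors (HBD), hydrophobes (HY), aromatic rings (AR) — placed
at specific mutual distances.  A molecule "maps" the model when its own
perceived features can occupy those spheres in some rigid pose, and the
quality of the occupation is summarised in a bounded *fit value*.  Around
that core, a screening campaign stacks quantitative activity prediction,
statistical validation, drug-likeness filters, and a staged cascade that
whittles a database down to a hit list.  `pharmscreen` implements that whole
stack on tidy tabular interfaces, and ships a synthetic-data module that
plants known geometry so every stage can be tested end to end without any
external database.

## Feature perception

Features are perceived from the connection table and one 3D conformer, under
Catalyst-style conventions (see `?feature_rules`):

* HBA: N or O with an available lone pair and no positive formal charge;
  amide nitrogens and trisubstituted aromatic nitrogens are excluded.
* HBD: N or O bearing a hydrogen, explicit or implied by standard valence.
  A hydroxyl oxygen is deliberately both donor and acceptor.
* HY: connected components of at least three nonpolar carbons (no N, O, F,
  S, P neighbour; non-aromatic), each collapsed to its centroid.  The
  component threshold is a deterministic, documented stand-in for the
  proprietary clustering used by commercial packages.
* AR: 5/6-membered C/N rings whose bonds are aromatic-flagged or, for
  6-rings, alternating; centroid plus unit plane normal.

The rules are data, shipped as an editable YAML file
(`inst/extdata/feature_rules.yaml`), because no public, authoritative
dictionary exists for the commercial implementations this follows; making
the rule set explicit makes it testable and criticisable.  Directions
(lone-pair axes, O–H vectors, ring normals) are perception metadata only;
the fit function scores sphere centres, not directionality — published fit
thresholds do not disclose a directional term, so we do not invent one.
Perception is deterministic (sorted by kind, then atom indices) and
equivariant under rigid motion, both enforced by tests.

## The fit function

A model is a set of constraints, each with kind, centre, tolerance
$t$ (default 1.6 Å, the conventional location tolerance) and weight $w$.
For a candidate correspondence mapping constraints injectively onto
kind-matched features, the mapped feature centres are superposed onto the
constraint centres by least squares (Kabsch; one refinement pass re-weighted
by constraint weight), after which each mapped constraint with residual
displacement $d$ contributes

$$\mathrm{partial} = w \cdot \max\!\left(0,\; 1 - (d/t)^2\right),$$

and the fit is the sum over mapped constraints, maximised over all
admissible correspondences.  A correspondence is admissible only when every
mapped displacement stays within its tolerance; each omitted constraint
(at most `max_omitted`) contributes zero.  Consequences: $0 \le \mathrm{fit}
\le \sum w$, the fit is invariant under rigid motion of the molecule, and
with equal weights the least-squares pose is exactly the score-optimal pose
— which is why the test suite can check the implementation against a
brute-force oracle that enumerates every correspondence and superposes with
an independent implementation (`bio3d::fit.xyz`).

Choices worth making explicit:

* Correspondence search prunes pairs whose inter-feature distance disagrees
  with the inter-constraint distance by more than the sum of the two
  tolerances; pruning only removes provably inadmissible branches.
* Ties between equal-fit correspondences resolve to the lexicographically
  smallest mapping; ties between conformers resolve to the lowest index.
  Determinism is a contract, not an accident.
* Quantitative models default to `max_omitted = 0`, common-feature models
  to 1, mirroring how the two model families are used (exact mapping for
  activity prediction, partial mapping when scoring weak binders).
* Default constraint weight for quantitative models is 2.4, putting a
  5-feature ceiling at 12 — the scale on which published fit values near
  11.9 operate.  Weights and tolerances are model data, never hard-coded.

## The quantitative (HypoGen-style) layer

Fits map to activity through a one-parameter log-linear law,

$$\log_{10} \mathrm{IC}_{50}^{\mathrm{pred}} = C - \mathrm{fit},$$

with $C$ in log10-µM units estimated by least squares as
$C = \overline{\mathrm{fit}_i + \log_{10}\mathrm{IC}_{50,i}}$.  This exact
form is forced by the shipped reference tables: a single constant
regenerates their entire predicted-IC50 column to better than 0.1%
relative error (`bcrabl_reference_table()`, checked in the acceptance
tests).  Predictions are summarised by:

* the signed error factor, $+\mathrm{pred}/\mathrm{exp}$ when over- and
  $-\mathrm{exp}/\mathrm{pred}$ when under-predicting, magnitude always
  $\ge 1$;
* the three-level activity scale: `+++` at IC50 ≤ 0.1 µM, `+` at ≥ 3 µM,
  `++` between, both outer boundaries inclusive so the labels partition the
  positive axis;
* the Pearson correlation of log-experimental vs log-predicted IC50 and its
  square.  Correlation is computed on the log scale: a linear-scale
  coefficient is meaningless across a five-log activity span.  Published
  summaries of such tables quote sometimes $r$ and sometimes $r^2$;
  `assess_predictions()` reports both so either convention can be checked.
  On the shipped training table $r = 0.986$ ($r^2 = 0.973$); on the test
  table $r = 0.920$ ($r^2 = 0.847$).

The shipped training table contains one internal inconsistency: compound 4
has predicted IC50 0.0157 µM yet carries a `++` predicted label, which the
quoted thresholds cannot produce.  We treat it as a typographical anomaly —
the scale-reproduction test asserts every row except that one, and the
package does not emulate it.

### Model construction

Commercial quantitative-model generation optimises a proprietary cost
function by simulated annealing; that function is not public and is not
reimplemented.  `construct_quantitative_model()` substitutes a transparent
procedure: candidate constraint sets are all subsets (4–6 features by
default) of the feature arrangements of the two most active training
compounds, each realised as a model at the reference geometry and scored by
the Pearson correlation between training fits and $-\log_{10}\mathrm{IC50}$;
the best candidate wins and is calibrated on the full training set.  The
full evaluation log is attached to the result.  Preconditions mirror what
makes such training sets learnable at all: at least 8 compounds, activity
span of at least one log unit (three or more recommended — the reference
training chemistry spans from 0.0002 to 9.8 µM, almost five).

## The common-feature (HipHop-style) layer

`build_common_feature_models()` finds arrangements shared by all actives
without using activity magnitudes.  The most feature-rich active is the
reference; against each other active a correspondence graph is built (nodes
= kind-matched feature pairs, edges = pairwise-distance agreement within a
1.0 Å bin, commensurate with the 1.6 Å sphere tolerance), whose maximal
cliques are exactly the maximal common sub-arrangements of that pair.
Intersecting clique reference-sets across all actives leaves arrangements
present in every active; each is realised as a model on the reference
geometry.  On instances small enough to enumerate, this equals a
brute-force subset oracle (tested), and the output is invariant to the
input order of the actives.  Candidates are then ranked by
*discrimination*: mean best-fit of actives minus mean best-fit of inactives
(`rank_by_discrimination()`), with partial mapping allowed via the omission
allowance.

## Validation statistics

For a database of $D$ compounds with $A$ actives, $H_t$ hits and $H_a$
active hits:

$$EF = \frac{H_a \, D}{H_t \, A}, \qquad
GF = \frac{H_a}{4 H_t A} (3A + H_t)
     \left(1 - \frac{H_t - H_a}{D - A}\right),$$

plus percent yield $100 H_a/H_t$, percent ratio $100 H_a/A$, and the
false-negative/-positive counts.  Validity requires $H_t - H_a \le D - A$
(the hit list cannot contain more inactives than the database holds);
under that constraint $GF \in [0,1]$, which the tests verify by exhaustive
enumeration up to $D = 60$.  Note one discrepancy worth documenting: for
the common-feature validation counts (241, 21, 22, 21) the GF formula
evaluates to 0.9615, while published summaries of that experiment print
0.91; the formula on its printed inputs cannot produce 0.91, so the package
implements the formula and reports its value.  All retrieval metrics are
kept at full precision internally and rounded (two decimals for
yield/ratio/EF/SI, four for GF) only in reports.

The *Fischer randomization* test asks whether the structure–activity link a
model captures could have arisen by chance: at confidence level $CL$ the
design prescribes $100/(100-CL) - 1$ activity-label permutations (19 at
95%), the model is rebuilt or rescored on each shuffled set, and the true
training score must strictly exceed every permuted score (ties count
against significance; strict rank 1 of 20 gives the stated confidence).
The scoring statistic is the training log-correlation rather than a
proprietary cost — the substitution preserves the test's logic.  Because
fit values do not change when activity labels permute, the
candidate-by-compound fit matrix can be computed once
(`candidate_fit_matrix()`) and each permutation reduced to re-selecting the
best-correlating candidate; that memoization is what makes the 200-replicate
type-I-error simulation in the test suite run in seconds.  Under the null
the strict rank-1 rule gives exactly 5% false positives at the 95% level,
and the suite checks the simulated rate against 5% ± 3%.

Selectivity indexes are plain IC50 ratios (reference line over target
line); the shipped example reproduces the published values 168.71, 174.97
and 101.80 from the printed IC50s.

## Screening filters and the cascade

Drug-likeness uses the strict rule of five (MW ≤ 500 Da, rotatable bonds ≤
10, HBA ≤ 10, HBD ≤ 5, all inclusive, no one-violation allowance).
Molecular weight, LogP, TPSA and the H-bond counts come from Open Babel
descriptors (`ChemmineR::propOB`); the rotatable-bond count is computed
in-package under a fixed, documented definition — non-ring single bonds
between two non-terminal heavy atoms, amide C–N excluded — because the
bound is meaningless without a definition.

ADMET screening keeps the commercial *level/cutoff semantics* (solubility
level 3, absorption level 0, blood–brain-barrier level 3; a compound passes
when each level equals its cutoff, and the cutoffs are configuration) while
replacing the proprietary descriptor models with documented surrogates: an
ESOL-style log-solubility estimate binned at 2-log edges, a TPSA/LogP
absorption rule, and a TPSA/LogP BBB rule (levels in `?admet_filter`).
Whether level matching should be equality or an ordering is genuinely
open; equality is the stricter reading and is config-overridable.

Similarity search is Tanimoto on atom-pair fingerprints with an inclusive
0.40 default threshold, optionally anchored by a required substructure
(SMARTS, matched through Open Babel) — reflecting the dual practice of
scaffold-anchored similarity searches in lead optimisation.  Fit thresholds
are strict inequalities; similarity and docking thresholds are inclusive.
Docking is never executed: scores are ingested from TSV
(`ingest_docking_scores()`, last-duplicate-wins, score-less hits dropped
with a warning) and applied as a plain `>=` filter.

`run_cascade()` chains the stages per model arm (fit threshold →
Lipinski → ADMET → optional docking filter) and, with two models,
intersects the arm survivors.  Stage accounting is part of the contract:
outputs never exceed inputs, stage-$k$ survivors are a subset of
stage-$(k{-}1)$ survivors, order-independent filters commute, and the
intersection is symmetric in the arms — all property-tested.

## The synthetic-data generator

`sim_spec()` + `generate_feature_molecules()` emulate the study conditions
the package is validated under: actives that carry a planted feature
arrangement, decoys that carry the same chemistry with perturbed geometry,
and activities drawn from the generating law
$\mathrm{IC50} = 10^{C - \mathrm{fit} + \varepsilon}$ with
$\varepsilon \sim N(0, \sigma)$ in log10 units (lognormal on the
concentration scale, consistent with the calibration estimator).
Defaults are fixed once, at the conditions the reference campaign
describes: a 5-feature planted model with weight 2.4 (fit ceiling 12, the
published quantitative scale), $C = 8.3$ log10-µM (the calibrated constant
of the reference tables is 8.328), noise 0.3 log units, a 25-active /
300-decoy validation database, and a 3 Å decoy perturbation against 1.6 Å
tolerance spheres.  Desk-scale tests use smaller counts of the same
conditions; the suite's problem sizes (8–25 molecules per set, 200
permutation replicates, exhaustive GF enumeration to $D = 60$) were chosen
as the smallest sizes at which each property is statistically meaningful.

Generated molecules are real, parsable structures, not point clouds: each
feature is realised as a minimal chemical group (carbonyl for HBA, hydroxyl
for HBD, a three-carbon unit for HY, benzene for AR) whose perceived centre
sits at the planted coordinate, and groups are connected through CF₂ linker
carbons placed at anchor midpoints.  Fluorinated linker carbons are polar
under the hydrophobe rule, so linking neither merges nor displaces planted
hydrophobic centroids — the one structural trick that lets a connected
molecule carry exact planted geometry.  Every molecule gets a random rigid
reorientation so nothing aligns with the model frame by construction, and
the whole generator is byte-deterministic per seed.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: real chemical diversity (all molecules of a database
share the planted scaffold chemistry, so topological fingerprints and bulk
descriptors are nearly degenerate across a generated database),
conformational flexibility (conformers are inputs; none are generated),
tautomers and ionisation states, and property-matched decoys in the DUD-E
sense.  Tests on generated data validate the *machinery* — geometry,
scoring, statistics, accounting — not chemical realism.

## Numerical conventions and degenerate inputs

* Coordinates are Å as stored; no re-centring on input.  SDF output writes
  isolated aromatic 6-rings in Kekulé form (order-4 bonds are query-only in
  V2000); perception accepts both encodings.  Round-trips preserve
  coordinates to the 1e-4 Å the format carries.
* Corrupt SDF blocks are skipped and counted, never fatal;
  parsed + skipped = input blocks.  Zero parsable molecules is fatal.
* Molecules without conformers are accepted for topology-only stages and
  rejected with a clear error by geometric ones.
* `fit_value(..., optimize = FALSE)` scores features in their given pose,
  for pre-aligned conformations and closed-form checks; single-sphere
  models are accepted for such composition even though a usable screening
  model carries at least two constraints.
* Hit-count tuples violating $H_t - H_a \le D - A$ are rejected rather than
  silently producing a negative GF.

## Known limitations

Fit optimisation superposes then scores (with one weighted refinement);
for strongly unequal weights the score-optimal pose can differ slightly
from the weighted least-squares pose, and no continuous pose search is
attempted — at pharmacophore sizes (≤ 8 constraints) the difference is
well below the tolerances that matter.  Feature directions are not scored.
The correspondence search is exponential in the worst case (all features
one kind) but pruned; realistic models are far below the threshold where
this matters.  The ADMET surrogates share only level semantics with the
commercial descriptors they stand in for; absolute level assignments for
real molecules will differ.
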