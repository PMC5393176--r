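---
title: "Assessing RNA 3D models: metrics, conventions and the synthetic test world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing RNA 3D models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnassess)
```

## The problem

Blind RNA 3D structure prediction experiments compare predicted models
against crystal structures with a panel of complementary metrics, because
no single number captures model quality. A model may have the right global
fold but wrong non-canonical pairs; it may reproduce every base pair but
with severe steric clashes; it may match torsion angles locally while two
helical domains point the wrong way relative to each other. This package
implements that panel for one (model, reference) pair or for whole
submission sets, plus the infrastructure around it: structure I/O,
residue mapping, geometric annotation, ranking, and report data (tables,
radar ranks, B-factor profiles).

## The metric panel

Let $M$ be the model and $R$ the reference, compared over the mapped
residue set.

* **RMSD** (Angstrom): root-mean-square deviation over all common heavy
  atoms after one optimal (Kabsch) rigid superposition. The primary
  ranking metric; it spreads local errors over the whole structure.
* **INF** (interaction network fidelity): with $TP$ the interactions
  present in both annotations, $FP$ model-only and $FN$ reference-only,
  $INF = \sqrt{\frac{TP}{TP+FP}\cdot\frac{TP}{TP+FN}}$ — the geometric
  mean of precision and sensitivity. Computed over all base pairs
  (`inf_all`), canonical Watson-Crick pairs (`inf_wc`), non-Watson-Crick
  pairs (`inf_nwc`) and stacking contacts (`inf_stack`). An empty
  reference category is `NA` (nothing to predict); an empty model
  prediction against a non-empty reference is 0.
* **DI** (deformation index): $DI = RMSD / INF_{all}$. Penalizes models
  that superpose well without reproducing the interaction network. When
  $INF_{all}$ is 0 or undefined, DI is `NA`, never an exception.
* **DP** (deformation profile): the $N \times N$ matrix whose entry
  $(i,j)$ is the mean distance over residue $j$'s heavy atoms after
  superposing the model on the reference *using residue $i$ alone*. Rows
  with fewer than 3 common atoms are flagged degenerate and excluded from
  aggregates. Domain aggregation reports min/max/mean over each ordered
  domain-pair submatrix, the form used for module-based figures.
* **MCQ** (mean of circular quantities, degrees): circular mean of
  per-angle differences over the seven standard torsions
  ($\alpha,\beta,\gamma,\delta,\varepsilon,\zeta,\chi$). Where exactly one
  side is undefined the slot contributes a 180 degree penalty; both
  undefined, the slot is skipped. This one-sided-penalty convention
  materially affects scores against partially resolved references and is
  therefore exposed in the result (`n_penalized`).
* **Clash score**: steric overlaps of at least 0.4 Angstrom per 1000
  heavy atoms. This is a desk-scale approximation of the MolProbity
  quantity: no hydrogens are added (models frequently lack them), fixed
  van der Waals radii (C 1.70, N 1.55, O 1.52, P 1.80, S 1.80) are used,
  and covalently bonded pairs, 1-3 pairs, and hydrogen bonds are
  excluded. The hydrogen-bond exemption covers any base donor-acceptor
  heavy-atom pair at 2.4-3.4 A, not only atoms of annotated base pairs:
  ideal helices carry genuine cross-strand minor-groove hydrogen bonds
  (e.g. G:N2 to the O2 of the preceding pair's pyrimidine) between
  residues that are not themselves paired, and flagging those as clashes
  would be chemically wrong. Scores are comparable across models assessed
  here but are not expected to match MolProbity numerically.

## Annotation conventions

The base-pair and stacking detector is purely geometric. A candidate pair
must pass: ring-centroid distance <= 6.5 A; at least 2 inter-base heavy
donor-acceptor contacts with distance in [2.4, 3.4] A; base-plane angle
<= 65 degrees from parallel or antiparallel; vertical separation
(centroid offset projected on the mean normal) <= 2.5 A. Edges are
assigned by majority membership of the contacting atoms in fixed
Watson-Crick / Hoogsteen / Sugar atom tables (ties resolved
WC > Hoogsteen > Sugar for determinism), and orientation is *cis* when
the two glycosidic bonds fall on the same side of the pair axis.

One refinement beyond the distance windows proved necessary: counted
hydrogen bonds must be approximately **in the base plane** (out-of-plane
component <= 1.5 A, `hbond_plane_max`). Stacked neighbors in a helix
place polar atoms 2.8-3.3 A apart *vertically*; without the in-plane
condition those contacts satisfy the distance window and consecutive
residues are misread as base pairs. Annotation tools in the field apply
equivalent base-plane geometry conditions. All thresholds live in
`annotation_config()` and can be overridden.

G-U wobbles classified as cis WC/WC are counted in the Watson-Crick set,
the prevailing convention for `inf_wc`; `strict_wc = TRUE` excludes them.

Stacking requires: centroid distance <= 5.5 A, plane angle within 30
degrees of parallel or antiparallel, vertical separation in [2.0, 4.5] A,
horizontal centroid offset <= 2.5 A, and the pair not already hydrogen
bonded.

## Residue mapping

Comparisons run over a one-to-one residue correspondence. The default
maps by author identifier (chain, residue number, insertion code) — blind
prediction models conventionally share the target numbering — and falls
back to per-chain global sequence alignment (match +1, mismatch −1, gap
−2) when identifier coverage drops below 0.8. Residues unresolved in the
crystal are simply absent from the mapping; coverage below 0.3 is treated
as a wrong chain pairing and raises an error. Modified nucleotides map to
standard parents via a small built-in table (e.g. PSU to U); ligands,
ions and proteins are parsed but excluded from the RNA metrics.

## The synthetic test world

Everything above is testable offline against generated structures with
known ground truth.

`build_duplex()` places one idealized nucleotide per base type by exact
helical symmetry: twist 32.7 degrees and rise 2.81 A per step, the
canonical A-RNA values. The templates were derived once, offline, by
constrained least squares: an idealized C3'-endo ribose (pseudorotation
phase 18 degrees, amplitude 38) carrying reference base geometry, with
backbone torsions fit so that (a) the strand's screw symmetry is exactly
the target twist/rise, (b) the dyad-related complementary strand forms
Watson-Crick hydrogen bonds at 2.7-3.0 A in-plane with coplanar (near
zero stagger) pairs, (c) base centroids cluster near the helix axis so
successive stacked bases keep a horizontal offset under the stacking
gate, (d) neighbor bases separate by more than 2.65 A along their mean
normal — base inclination, as in real A-RNA, pushes the stacking
separation above the geometric rise, which keeps stacked neighbors
cleanly outside the pair detector's vertical window — and (e) the built
duplex is free of steric clashes at the 0.4 A threshold. The resulting
torsions are A-form-like (alpha -40, beta 157, gamma 34, delta 86,
epsilon -140, zeta -87, chi -156 purine / -150 pyrimidine) and are
recorded in each fixture's ground truth.

Because strand placement is exact screw symmetry, the generator's pair
and stack lists are ground truth *by construction*: n Watson-Crick pairs
and 2(n-1) intra-strand neighbor stacks for an n-mer duplex, which the
annotation module must recover exactly — the primary cross-module test.

Controlled degradations:

* `perturb_noise(s, sigma, seed)` — i.i.d. Gaussian coordinate noise;
  expected RMSD against the original is close to $\sigma\sqrt{3}$ minus a
  small superposition absorption.
* `perturb_hinge(s, pivot, angle)` — rigid rotation of everything after
  the pivot about an axis through its P atom; produces the two-domain
  regime where intra-domain DP blocks stay near zero while inter-domain
  blocks grow with the angle.
* `perturb_torsions(s, shift)` — an internal-coordinate rebuild that adds
  a constant to every defined torsion (backbone and chi) while preserving
  bond lengths, bond angles, sugar and base internal geometry; MCQ
  against the original equals the shift.

What a green test does **not** establish: fixtures contain no
non-Watson-Crick pairs beyond engineered wobbles, no loops, junctions or
tertiary contacts, no modified residues, and no crystallographic
artifacts (alternate conformations, partial occupancy, unresolved
stretches beyond what tests construct explicitly). Agreement with any
specific external annotation program on real structures is not asserted;
on real data, INF values can differ slightly between annotators, which is
expected and documented behavior for geometric annotation.

## Numerical and design choices

* Kabsch superposition corrects reflections by flipping the smallest
  singular vector, so rotations always have determinant +1; an
  independent quaternion-eigenvalue oracle in the test suite agrees to
  1e-8 A on random instances.
* DP uses a single-residue superposition window (residue i's own heavy
  atoms), the simplest defensible reading; the window is a natural
  extension point.
* DI uses INF over *all* pairs, matching the "DI all" usage.
* Ranking: RMSD, DI, MCQ and clash score ascending; INF flavors
  descending; `NA` sinks last (an undefined metric is never treated as a
  perfect 0); remaining ties break lexicographically by model id so
  rankings are total orders independent of input order.
* Radar rank data selects each group's first-submitted model and its
  best-RMSD model and ranks them among the corresponding selections of
  all groups, metric by metric, with the same NA-sinks-last rule.
* The clash score is computed once per model (it does not depend on a
  reference) and repeated in every record.
* Undefined values propagate as `NA`/JSON null, never as 0, because 0 is
  a meaningful value for every metric in the panel.
* The multi-MODEL convention (first model only), alt-loc resolution by
  highest occupancy (ties: first in file), and author numbering are fixed
  conventions chosen to match common assessment practice and keep results
  deterministic.

## Known limitations

* The clash score approximates MolProbity qualitatively, not numerically.
* Geometric annotation has no base-triple taxonomy and no isostericity
  matrices; exotic pair families are classified only by edge and
  orientation.
* The hairpin fixture kind is not implemented: closing a loop onto an
  exact-helix stem requires inverse kinematics that the test world does
  not need — duplexes, hinge-split duplexes and noise cover every metric
  path.
* `perturb_torsions` rebuilds chains 5' to 3' from the first residue;
  the first residue's own alpha/beta slots (which need a phosphate that a
  5' terminus lacks) stay undefined, matching the torsion conventions.

## A worked example

```{r example, eval = FALSE}
fx <- build_duplex("GGCAUCGCAU", seed = 7)
model <- perturb_noise(fx$structure, 0.8, seed = 1)
model$id <- "noisy_model"
a <- assess_model(model, fx$structure)
print(a)
summary_table(a)
```
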