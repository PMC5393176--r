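# rnassess

Quality assessment of RNA three-dimensional structure models against
reference crystal structures, with the metric panel used in blind RNA
structure prediction assessment (CASP-style "puzzles"): RMSD, interaction
network fidelity (INF) at the Watson-Crick / non-Watson-Crick / stacking
levels, deformation index (DI), the per-nucleotide deformation profile
(DP) with domain aggregation, the mean of circular quantities (MCQ) in
torsion-angle space, and a steric clash score. The package also ranks
model sets, emits radar-rank and B-factor report data, and ships a
deterministic generator of idealized A-form RNA structures so that every
metric is testable offline.

## Who this is for

Assessors and method developers in RNA 3D structure prediction who need
to score predicted models (PDB or mmCIF) against one or more reference
structures, reproduce module-based deformation-profile analyses, or build
controlled benchmark sets with known ground truth.

## The metrics

For a model $M$ and reference $R$ compared over mapped residues:

- **RMSD** — root-mean-square deviation over all common heavy atoms after
  one optimal (Kabsch) superposition; the primary ranking metric.
- **INF** — geometric mean of precision and sensitivity of the model's
  annotated interactions vs the reference's:
  `INF = sqrt( TP/(TP+FP) * TP/(TP+FN) )`, computed over all pairs, WC
  pairs only, non-WC pairs only, or stacking contacts only.
- **DI** — `RMSD / INF_all`; penalizes models that superpose well but
  miss the interaction network.
- **DP** — matrix whose entry (i, j) is the mean distance over residue
  j's heavy atoms after superposing on residue i alone; aggregated
  min/max/mean per structural domain.
- **MCQ** — circular mean (degrees) of per-angle differences over the
  seven standard torsions; a one-sided undefined angle contributes a
  180-degree penalty.
- **Clash score** — vdW overlaps >= 0.4 A per 1000 heavy atoms
  (hydrogen-free approximation of the MolProbity quantity).

Base pairs are detected geometrically (centroid gate, in-plane
donor-acceptor hydrogen bonds, plane-angle and vertical-separation
windows), classified by Leontis-Westhof edge (WC / Hoogsteen / Sugar) and
orientation (cis / trans); dot-bracket output uses `[]` and `{}` for
crossing (pseudoknot) levels.

## Worked example

```r
library(rnassess)

fx <- build_duplex("GGCAUCGCAU", seed = 7)   # ideal A-form, ground truth known
model <- perturb_noise(fx$structure, 0.3, seed = 1)
model$id <- "noisy_model"

a <- assess_model(model, fx$structure)
print(a)
#> <assessment 'noisy_model'> best vs duplex_GGCAUCGCAU: RMSD 0.536 A,
#>   DI 0.599, INF(all/wc/nwc/stack) 0.894/0.894/NA/0.943, MCQ 33.302, clash 133.333
```

Reading the numbers: 0.3 A of independent per-coordinate noise produces
a ~0.54 A heavy-atom RMSD (approximately sigma * sqrt(3) minus the small
superposition absorption). The annotator loses part of the Watson-Crick
network (INF_wc 0.89), so DI (RMSD / INF_all) rises above the raw RMSD.
MCQ is large relative to the RMSD because independent atomic noise
scrambles dihedrals far more than it moves the global fold — torsion
space is the more sensitive ruler here. Uncorrelated noise also drives
atoms into each other, hence the high clash score, where the pristine
fixture scores exactly 0. `NA` for INF_nwc means the reference contains
no non-WC pairs — nothing to predict (never rendered as 0).

```r
summary_table(a)           # one row per (model, reference), CSV-ready
rank_models(list(a$best), "rmsd")
to_dot_bracket(rbind(c(1, 10), c(2, 9), c(3, 8)), 10)  # "(((....)))"
```

Command-line use (after install): `inst/cli/rnassess` provides
`compare`, `rank`, `annotate` and `synth duplex` subcommands; see
`?rnassess_cli`.

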