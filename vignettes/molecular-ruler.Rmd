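---
title: "The Dicer-2 molecular ruler: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Dicer-2 molecular ruler: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicerruler)
library(dplyr)
```

## The model

Insect Dicer-2 cleaves long double-stranded RNA into siRNAs whose
predominant length differs between lineages: roughly 21 nt in dipterans and
coleopterans, 22 nt in hymenopterans and orthopterans, 20 nt in
lepidopterans. The molecular-ruler hypothesis attributes this to geometry:
the PAZ domain anchors the dsRNA terminus in two dedicated pockets (one for
the 2-nt 3′ overhang, one for the 5′ phosphate), the tandem RNase III
domains (A and B) cut the two strands, and the spatial separation between
anchoring and cutting sets the product length. This package quantifies that
geometry.

For an annotated structure the caliper statistic is a pair of
centroid-to-centroid Euclidean distances,

\[
d_{3'} = \lVert c(\mathrm{pocket}_{3'}) - c(\mathrm{RIII_A}) \rVert,\qquad
d_{5'} = \lVert c(\mathrm{pocket}_{5'}) - c(\mathrm{RIII_B}) \rVert,
\]

with the per-structure summary \(\bar d = (d_{3'} + d_{5'})/2\). The
pairing convention — 3′ pocket against RNase III A, 5′ pocket against RNase
III B — follows how comparative distance tables for these enzymes are
printed. A site *center* \(c(\cdot)\) is the unweighted mean position of
one designated atom per resolved site residue.

Distances convert to length classes through a calibration. The default is
an *anchored* model relative to the *D. melanogaster* reference
(\(d_\mathrm{ref} = 60.3\) Å ↔ 21 nt):

\[
\hat L(d) = L_\mathrm{ref} +
  \mathrm{round}\!\left(\frac{d - d_\mathrm{ref}}{\rho}\right),
\]

with nearest-integer rounding, ties away from zero (no tie occurs in the
comparative data; the rule is fixed so behaviour is defined). The
alternative `linear_fit` mode is ordinary least squares of known lengths on
distances, with rise \(\rho = 1/\mathrm{slope}\).

## Parameters that matter

- **Rise ρ (Å per nucleotide), default 2.0.** The comparative distance data
  themselves space adjacent length classes about 1.9–2.0 Å apart
  (e.g. 58.3 → 60.3 → 62.2 for 20 → 21 → 22 nt), and the same literature
  treats ±1–2 Å as one-to-two nucleotide shifts; 2.0 Å/nt encodes both. The
  crystallographic A-form helical rise, 2.81 Å/nt, is available by setting
  `rise = 2.81`; both values reproduce the published length classes, because
  the classes sit well within the rounding bins.
- **Anchor (d_ref = 60.3 Å, L_ref = 21 nt).** The reference enzyme's mean
  caliper distance and its experimentally established product length. In
  the pipeline the anchor distance is *measured* from the reference
  structure, not hard-coded.
- **Relevance threshold, default 0.5 Å.** A shift in active-site spacing is
  flagged as biologically relevant only when it strictly exceeds 0.5 Å
  (`relevance_flag()`), a fixed descriptive threshold rather than an
  inferential test; no multiple-testing machinery is therefore applied.
- **Atom policy, default `"calpha"`.** Site centroids use one Cα per
  residue. Side chains rotate freely in homology models, so a Cα centroid
  is invariant to rotamer state; `"all_heavy"` exists for sensitivity
  checks and averages every non-hydrogen atom of the site residues.
- **Replicates, default 3.** Replicate runs re-measure the structure after
  optional Gaussian coordinate perturbation (`perturb_sigma`, default 0 Å).
  With zero perturbation the replicate SD is exactly 0 and the run log says
  so; the perturbation is the controllable analogue of rebuilding a
  homology model, which is where run-to-run variation originates in the
  source analysis and which no offline tool can reproduce.

## Residue annotation and transfer

Functional sites are residue lists in author numbering (`E1213` means
author residue 1213, never a sequential index), stored as TSV site tables;
the packaged `table1_sites.tsv` transcribes the published assignments for
five species, including entries marked `"?"` where the ortholog alignment
found no consistent residue. Unresolved entries are excluded from
centroids but counted and reported. The uncertain *B. terrestris* 3′-pocket
assignment is stored unresolved rather than guessed, and chain IDs (not
given in the published table) are assumed `A` — both stated in the fixture
header.

Annotation transfer to a new ortholog uses pairwise global alignment
(`align_global()`: end-to-end, affine gaps, BLOSUM62, gap open −10, gap
extend −1, a gap of length L scoring `open + L·ext`) rather than a multiple
sequence alignment: orthology transfer needs only pairwise correspondence,
and a deterministic pairwise alignment removes the external MSA tool. A
reference residue aligned opposite a gap transfers as `"?"`; strict mode
additionally drops entries whose target amino acid differs (off by
default — pocket residues are genuinely non-conserved across these
species). Catalytic DDxE/D motifs are never detected de novo; sites always
come from an annotated reference.

## Superposition

`kabsch()` implements the closed-form SVD solution for the least-squares
rigid superposition of paired Cα sets, with determinant correction so a
reflection is never returned. Per-domain RMSDs (helicase, PAZ, RNase III
regions) are computed under the *global* transform without refitting, so
they decompose the global fit; no outlier-rejection cycles are run. The
superposition is diagnostic — Euclidean distances are rigid-invariant, so
the frame a structure is measured in cannot affect the ruler, and the
pipeline documents rather than depends on the alignment frame.

## The synthetic generator

Published comparative analyses of this kind rest on homology models that
are rarely deposited, so the package ships a ground-truth generator
instead of test structures. `generate_scaffold()` builds a poly-alanine
style caliper: four labelled residue clusters (default 4 residues each,
cluster radius 2 Å) whose Cα centroids sit at *exactly* the requested
pocket-to-catalytic-center distances, plus 50 decoy residues as parser
bulk, then applies optional isotropic Gaussian coordinate noise and a
seeded random rigid placement. Cluster offsets are recentred so centroids
are exact; a target distance not exceeding twice the cluster radius is
rejected as geometrically infeasible. The noise model is the simplest
stand-in for rotamer variability; it produces approximately unbiased
distance measurements (the small convexity bias of a noisy norm,
\(\approx\tau^2/d\) for centroid noise τ, is orders of magnitude below the
0.5 Å relevance threshold at realistic σ).

`generate_duplex()` builds an ideal A-form-like duplex of one
phosphate-proxy pseudo-atom per nucleotide (default rise 2.81 Å/bp, twist
32.7°/bp, radius 9 Å), two antiparallel strands numbered 5′→3′. Paired
pseudo-atoms are placed diametrically opposite across the axis — not at a
realistic groove phase — so base-pair midpoints lie exactly on the helix
axis and `axial_extent()` can recover the duplex length after arbitrary
rigid placement. The duplex exists to make the Å↔nt correspondence
concrete (one extra base pair adds exactly one rise to the extent); it
models no overhang chemistry, base identity or thermodynamics.

What passing tests on these scaffolds shows: the measurement, calibration
and reporting machinery is exact and unbiased on structures whose true
geometry is known. What it does not show: anything about the quality of a
particular homology model, about real pocket shapes, or about electrostatic
anchoring — the scaffolds have no fold.

## Numerical choices and degenerate inputs

- All arithmetic is double precision; Å values are rounded to one decimal
  only when a report table is serialized. R's `round()` (IEC 60559
  round-half-even on the binary value) is used as-is. One published value
  sits exactly on a printing boundary: the *T. ni* per-pocket distances
  give a true mean of 58.35 Å, which correct decimal rounding renders as
  58.4 while the source table prints 58.3. The package does not reproduce
  that digit; it reports the full-precision mean and treats the printed
  value as consistent-at-printing-precision.
- The reported-vs-recomputed mean check (`check_reported_means()`) rounds
  the recomputed mean at coordinate precision (3 decimals — what a PDB file
  carries) and flags differences exceeding 0.05 Å (half the last printed
  digit). Under this rule the *T. castaneum* row of the published table is
  flagged — its printed mean 59.8 is not the mean of its printed distances
  (60.0) — and no other row is. The pipeline recomputes, reports 60.0, and
  emits a warning note rather than failing.
- Alignment tie-breaking among equal-scoring tracebacks follows the
  alignment engine's deterministic internal order; scores are checked
  optimal against an independent dynamic-programming oracle in the test
  suite, and every annotation-transfer contract holds for any optimal
  traceback.
- Kabsch requires ≥ 3 non-degenerate paired points; mirror-image inputs
  still return a proper rotation (det +1) with the honest, non-zero RMSD.
- PDB reading keeps the first `MODEL` block, skips `HETATM`, resolves
  altlocs by first conformer (or highest occupancy on request), and errors
  with a line number on malformed fixed-width fields. Empty structures and
  empty atom selections are distinct error classes.
- Seeds: every stochastic operation takes an explicit integer seed and
  restores the caller's RNG state (`withr::with_seed`); identical
  spec + seed yields byte-identical PDB output. Pipeline replicate seeds
  are small offsets from the configured seed.

## Problem sizes in the test suite

The suite builds everything it tests at run time: scaffolds of ~66 atoms
(four 4-residue sites + 50 decoys), duplexes up to 500 bp for noise
statistics, alignment checks on random pairs up to length 8 against an
exhaustive/Gotoh oracle (1000 pairs), Kabsch against a multi-start
numerical optimizer on 20 instances of 5–10 points, and 100–200 replicate
Monte-Carlo checks of generator unbiasedness. These sizes were chosen so
the whole suite exercises every contract in well under two minutes while
keeping Monte-Carlo standard errors far below the tolerances asserted.

## Known limitations

- Scaffolds are geometric stand-ins, not folds; no claim about real Dicer-2
  structures follows from tests alone.
- PDB only (the relevant templates are PDB entries); mmCIF, NMR ensembles
  and assemblies are out of scope.
- Pairwise — not multiple — alignment; highly divergent orthologs may
  transfer poorly and should be checked via `validate_map()`.
- The calibration is descriptive: two anchored points or a five-point OLS
  line, not a mechanistic model of cleavage-site selection.
- Pocket volume/depth and electrostatic surfaces are outside the package;
  reports are tabular (TSV/JSON), not renderings.

## A worked run

```{r pipeline, eval = FALSE}
dir <- tempfile(); dir.create(dir)
tbl <- dicer2_distances()
for (i in seq_len(nrow(tbl))) {
  sc <- generate_scaffold(tbl$structure_id[i], tbl$d_3p_riiia[i],
                          tbl$d_5p_riiib[i], seed = 100 + i)
  write_structure(sc$structure, file.path(dir, paste0(tbl$structure_id[i], ".pdb")))
  write_sites(sc$sites, file.path(dir, paste0(tbl$structure_id[i], "_sites.tsv")))
}
cfg <- list(
  reference = list(id = "dmel", structure = "dmel.pdb",
                   sites = "dmel_sites.tsv", length_nt = 21L),
  targets = lapply(2:5, function(i)
    list(id = tbl$structure_id[i],
         structure = paste0(tbl$structure_id[i], ".pdb"),
         sites = paste0(tbl$structure_id[i], "_sites.tsv"),
         expected_mean = tbl$reported_mean[i])),
  rise = 2.0, seed = 1)
yaml::write_yaml(cfg, file.path(dir, "config.yaml"))

report <- run_pipeline(file.path(dir, "config.yaml"))
tidy(report)
autoplot(report)
```

The run reproduces the comparative table: means 60.3, 60.0 (with a
discrepancy warning against the printed 59.8), 62.2, 62.3 and 58.35 Å, and
predicted classes 21, 21, 22, 22 and 20 nt.
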