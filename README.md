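# dicerruler

Structural comparison of insect Dicer-2 enzymes under the **molecular
ruler** hypothesis: the distance between the PAZ domain's dsRNA-anchoring
pockets and the RNase III catalytic centers determines the length of the
siRNA product. Different insect lineages produce siRNAs of different
predominant lengths (≈20 nt in lepidopterans, 21 nt in dipterans and
coleopterans, 22 nt in hymenopterans and orthopterans), and this package
provides the geometry pipeline to test whether Dicer-2 architecture
accounts for it.

It is written for structural bioinformaticians and RNAi researchers who
have Dicer-like structures (experimental or modeled) in PDB format and
want reproducible, scriptable caliper measurements instead of interactive
point-and-click distance wizards.

## What it computes

For a structure annotated with the four caliper sites — RNase III A and B
catalytic centers, PAZ 3′ and 5′ terminal-nucleotide pockets — the
package measures

    d_3' = || c(pocket_3') − c(RIII_A) ||      (Å)
    d_5' = || c(pocket_5') − c(RIII_B) ||      (Å)
    mean = (d_3' + d_5') / 2

where `c(·)` is the unweighted Cα centroid of the site's residues, and
converts the mean into a predicted siRNA length class with an anchored
calibration

    L(d) = L_ref + round((d − d_ref) / rise)      rise = 2.0 Å/nt by default

referenced to *D. melanogaster* (60.3 Å ↔ 21 nt). Around the core
statistic it provides: PDB I/O as tidy atom tables, Kabsch Cα
superposition with per-domain RMSD decomposition, residue-annotation
transfer between orthologs by global sequence alignment, replicate
statistics with a 0.5 Å biological-relevance threshold, a seeded
ground-truth generator of caliper scaffolds and ideal A-form duplexes, and
a YAML-configured end-to-end pipeline with TSV/JSON reports.

## Worked example

The package ships a small synthetic demonstration scaffold built with the
*D. melanogaster* caliper geometry (it is a generated stand-in, not a real
structure), plus the published residue and distance tables as fixtures.

```r
library(dicerruler)

pdb   <- system.file("extdata", "scaffold_dmel_synthetic.pdb", package = "dicerruler")
sites <- system.file("extdata", "scaffold_dmel_synthetic_sites.tsv", package = "dicerruler")
measure_ruler(read_structure(pdb), read_sites(sites))
#> # A tibble: 1 × 6
#>   structure_id             d_3p_riiia d_5p_riiib mean_distance    sd n_replicates
#>   <chr>                         <dbl>      <dbl>         <dbl> <dbl>        <int>
#> 1 scaffold_dmel_synthetic        61.0       59.6          60.3     0            1
```

61.0 Å and 59.6 Å are the 3′-pocket→RIII-A and 5′-pocket→RIII-B centroid
distances; their mean, 60.3 Å, is the caliper length that the calibration
maps to 21 nt. Applying the anchored model to the published per-species
means:

```r
model <- calibration_anchored(d_ref = 60.3, l_ref = 21, rise = 2.0)
tbl <- dicer2_distances()
predict_length(data.frame(structure_id = tbl$structure_id,
                          mean_distance = tbl$reported_mean), model)
#> # A tibble: 5 × 6
#>   structure_id mean_distance predicted_nt delta_vs_ref significant out_of_range
#>   <chr>                <dbl>        <int>        <dbl> <lgl>       <lgl>
#> 1 dmel                  60.3           21         0    FALSE       FALSE
#> 2 tcas                  59.8           21        -0.5  FALSE       FALSE
#> 3 bter                  62.2           22         1.90 TRUE        FALSE
#> 4 lmig                  62.3           22         2    TRUE        FALSE
#> 5 tni                   58.3           20        -2    TRUE        FALSE
```

The predicted classes — 21, 21, 22, 22, 20 nt — match the experimentally
observed species-specific siRNA lengths; `significant` marks shifts in
active-site spacing exceeding the 0.5 Å relevance threshold. A
least-squares calibration over the five (mean, length) pairs gives a slope
of 0.490 nt/Å, i.e. a rise of ≈2.04 Å per nucleotide:

```r
glance(fit_calibration(data.frame(mean_distance = tbl$reported_mean,
                                  length_nt = tbl$reported_nt)))
#> # A tibble: 1 × 6
#>   mode       d_ref l_ref  rise     n r.squared
#>   <chr>      <dbl> <dbl> <dbl> <int>     <dbl>
#> 1 linear_fit  60.6  21.2  2.04     5     0.984
```

A full multi-species run (structures + site tables + YAML config →
replicate-aware report with superposition summaries and discrepancy notes)
is driven by `run_pipeline()`; see the vignette
`vignettes/molecular-ruler.Rmd` for a complete example, and
`exec/dicer-ruler` for the thin command-line wrapper
(`run` / `measure` / `synth` subcommands).

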