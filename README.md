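# pocketrank

Druggability triage for protein targets: detect binding pockets on a
structure, score how drug-friendly they are, fuse per-method scores into a
composite target ranking, and post-process docking score tables for drug
repurposing. The package is aimed at structural-bioinformatics analyses that
must decide, before any docking or wet-lab work, which of a list of disease
targets is worth pursuing.

## What it computes

**Pocket detection.** Cavities are found on a grid (default 0.8 Å): cells
outside every atom's van der Waals sphere that a 1.4 Å solvent probe rolling
in from the box boundary cannot reach. Each pocket carries its volume
(cells × spacing³), surface points, and a *shell* — the residues within
3.5 Å of any surface point.

**Descriptors and scores.** For every pocket the pipeline computes
buriedness (1 − SASA of shell atoms in context / SASA in isolation, via
Shrake–Rupley with 960 sphere points), hydrophobicity (fraction of surface
points whose nearest shell atom is carbon/sulfur), site-point count *n*,
enclosure *e* (fraction of 64 fixed ray directions blocked by protein), and
hydrophilic/hydrophobic density scores *p*. These feed the druggability
scores:

* drug-like density, regression form:
  `DLID = −8.70 + 1.71·log₁₀(volume) + 3.94·buriedness + 2.27·hydrophobicity`
* drug-like density, neighbor form:
  `DLID = log₁₀(DLLC neighbors / total neighbors) + 1.71` over a reference
  pocket set in standardized descriptor space (falls back to the regression
  form when the query has no neighbors)
* `SiteScore = 0.0733·√n′ + 0.6688·e − 0.20·p′` with `n′ = min(n, 100)`,
  `p′ = min(p, 1)`
* `Dscore = 0.094·√n′ + 0.60·e − 0.324·p` (p deliberately uncapped)

A pocket is DLID-druggable strictly above 0.5 and site-druggable at
SiteScore ≥ 0.80.

**Target ranking.** Per-target best scores from several methods (here: DLID,
the SPIDER sequence-based possibility, and the SiteMap DScore) are min–max
normalized, `x′ = (x − min)/(max − min)`, summed into a composite in [0, 3],
and ranked, with a configurable exclusion list for targets that are poor
intervention points (e.g. early classical-complement-pathway proteins).

**Docking triage.** Docking tables (`target, molecule, score` in kcal/mol)
are filtered at the −20 kcal/mol likely-binder threshold, summarized per
target (hit counts, best hit, top-N), and compared across targets for shared
inhibitors, with molecule ids canonicalized so `C_15_H_14_N_2_O_2_` and
`C15H14N2O2` match.

The machine-readable copies of the study tables ship in `inst/extdata/`
(`load_fixture("table1")` … `"table8"`), and seeded generators build
engineered-cavity structures and synthetic score/docking tables for testing
(`make_cavity_structure()`, `make_score_table()`, `make_docking_tables()`).

## Worked example

```r
library(pocketrank)

# rank the study's 23 fully scored targets and select docking candidates
t3 <- load_fixture("table3")
sel <- rank_and_select(t3, excluded = c("C1QB", "C1R", "C3"), k = 5)
sel$target
#> [1] "DRD2"     "C4B"      "GABA-A-R" "C9"       "C5AR1"

# docking triage over the five per-target tables
tabs <- do.call(rbind, lapply(paste0("table", 4:8), load_fixture))
nrow(filter_hits(tabs[tabs$target == "DRD2", ]))
#> [1] 8
best_hit(tabs, "C9")
#>   target molecule score
#> 1     C9     v174 -33.2
cross_target_overlap(tabs, mode = "top_n", n = 10)
#> <overlap_report: 5 targets, 2 shared molecule(s)>
#>   C15H14N2O2: C9, C5AR1
#>   V316: C4B, C9
```

The five selected targets are the ones the composite ranking promotes once
the early-pathway proteins are set aside; the overlap report says only two
molecules (paracetamol's library code v316 and the formula C15H14N2O2) reach
the top-10 list of more than one target.

The pocket side runs the same way on structures:

```r
s <- make_cavity_structure(inner_radius = 6, lining_composition = 1, seed = 1)
score_pockets(s)[, c("volume", "buriedness", "hydrophobicity", "dlid")]
#>    volume buriedness hydrophobicity     dlid
#> 1 957.952  0.8515804              1 2.023324
```

`analysis/01_simulate_pockets.R`, `analysis/02_rank_targets.R` and
`analysis/03_docking_summary.R` are narrative drivers over these functions;
they write their tables under `results/`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computations from scratch
— the pocket pipeline on a seeded engineered cavity, the fixture-table
normalization/ranking/selection, the docking triage, and a synthetic
end-to-end pass — and writes its JSON result object to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
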