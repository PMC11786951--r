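---
title: "Pocket detection, druggability scoring and target ranking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pocket detection, druggability scoring and target ranking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketrank)
```

This vignette is the package's own account of its methods: the models and
the assumptions behind them, the tunable parameters and why their defaults
are what they are, what the synthetic generators do and do not emulate, and
the design choices made where the published description left the design
open.

## The problem

Given a list of candidate disease targets with solved structures, decide
which are *druggable* — likely to bind a drug-like small molecule in a
functional pocket — before spending docking or laboratory effort. The
package implements that triage in four stages: pocket detection on a
structure, per-pocket druggability scoring, min–max fusion of per-method
target scores into a composite ranking, and post-processing of docking
result tables.

## Pocket detection

A pocket is operationalized on a Cartesian grid (default spacing 0.8 Å, a
standard cavity-detection resolution; halving it changes the measured volume
of a smooth engineered cavity by well under 15%). Cells are classified by
two occupancy maps: inside some atom's van der Waals sphere (Bondi-style
radii, carbon fallback for unknown elements), and inside the probe-expanded
spheres (vdW + 1.4 Å). A breadth-first flood from the box boundary over
probe-accessible cells marks bulk solvent reachable by a rolling probe; the
reached region is then dilated by the probe radius so the thin free-space
layer hugging the protein's outer surface counts as solvent rather than
cavity. What remains — free space the probe cannot reach — is split into
6-connected components, filtered at `min_volume = 100` Å³ (small enough to
keep any site that could hold a fragment, large enough to drop lattice
noise), and ordered by decreasing volume. This is a deliberately simple,
fully deterministic stand-in for proprietary pocket finders; it is not
intended to reproduce their numerical output, and the packaged study tables
are treated as fixtures, never as regeneration targets.

Surface points are the centers of cavity cells adjacent to a
protein-occupied cell. The *shell* — the pocket's lining — is exactly the
set of residues with at least one atom within 3.5 Å of at least one surface
point.

## Descriptors

**Buriedness** is `1 − SASA(shell in context) / SASA(shell in isolation)`,
clamped to [0, 1]: a lining that loses no accessible area when the rest of
the structure is removed was never buried (0); one whose isolated area far
exceeds its in-context area is deeply enclosed (→ 1). SASA is Shrake–Rupley
with a deterministic 960-point golden-spiral sphere per atom and the same
probe radius as detection; the implementation was cross-checked against an
independent implementation (biotite) to 0.2% on a mixed-element fixture and
against the closed form for an isolated atom. The published phrase this
operationalizes is ambiguous about whether the ratio is pocket-surface- or
shell-atom-based; the shell-atom reading is adopted because it is
well-defined for any pocket and degrades gracefully as a mouth opens.

**Hydrophobicity** is the fraction of surface points whose nearest shell
atom within 4.5 Å is hydrophobic. The hydrophobic-atom rule is coarse and
element-only — carbon and sulfur hydrophobic; N, O, P, halogens, metals not
— because no finer rule is published for these scores; it is deterministic
given the structure, which the tests rely on.

**Site points** subsample the cavity cells on a coarser sublattice (default
1.6 Å, i.e. every second cell at the default grid). Whether proprietary
site points equal grid cells is unknowable from the outside, so the spacing
is an exposed tunable; the scoring formulas cap the count at 100 anyway,
which a typical drug-sized cavity exceeds.

**Enclosure** is the mean, over site points, of the fraction of 64 fixed
quasi-uniform ray directions (golden-spiral set, no RNG) that hit a protein
atom within 8 Å. An infinitely thin ray can slip between lining atoms, so
even a sealed engineered cavity scores ~0.75 rather than 1.0 at 64 rays —
the tests therefore assert limits and orderings, not an exact 1.0.

**Hydrophilic/hydrophobic scores** are mean exponential-falloff atom
densities (`exp(−d/2 Å)`) of polar/hydrophobic shell atoms around site
points, divided by a frozen reference constant (9.34) measured once on a
fully polar-lined reference cavity (the default 6 Å hollow sphere), so that
such a cavity scores ≈ 1 — matching the published calibration in which an
average tight-binding site's hydrophilicity is 1.0. The *balance* is their
ratio, undefined (NA) for a lining with no polar atoms.

## Scoring

The regression-form drug-like density,
`DLID = −8.70 + 1.71·log₁₀ V + 3.94·b + 2.27·h`, and the density form,
`log₁₀(DLLC/total) + 1.71` over neighbors in z-standardized
`(log₁₀ V, b, h)` space (default radius 1.0), use base-10 logarithms — the
convention of the DLID literature; the printed formulas write bare "log".
The two 1.71 constants are implemented independently even though they
coincide numerically. With no neighbors the density form raises a classed
condition and `dlid_score()` falls back to the regression form, mirroring
the published substitution rule; with neighbors but no DLLC among them the
log is −Inf, which is returned flagged rather than silently propagated.

SiteScore and Dscore are weighted sums of `n` (capped at 100), enclosure and
the hydrophilic score (capped at 1.0 only in SiteScore). The printed linear
`n` term would put typical sites near 7, contradicting the stated
calibration that an average submicromolar site scores 1.0; the default mode
therefore uses `√n`, which reproduces that calibration (100 site points,
e = 0.76, p = 1 → 1.041), and the literal printed form is retained behind
`literal = TRUE`. This conflict is documented, not resolved. Thresholds
follow the closest reading of the published sentences: DLID druggable
strictly above 0.5, SiteScore druggable at ≥ 0.80.

## Ranking and docking triage

Min–max normalization is applied per method column after removing targets
missing any method's score (they cannot be placed on a common [0, 1]
scale); the composite is the plain sum, and ranking breaks ties
alphabetically for determinism — the study data contain no ties. The
early-pathway exclusion is configuration, not hard-coded biology: the same
machinery serves any exclusion list with its own rationale.

Docking records are filtered at −20 kcal/mol *inclusively*; the source
narrative mixes "below" and "reached the threshold", and no printed score
equals −20 exactly, so the choice is observationally neutral on the fixture
tables and is simply documented. Molecule ids are canonicalized (strip
whitespace/underscores, fold case) because the printed identifiers are
typographically inconsistent; hyphens are preserved in *target* ids' display
forms but ignored in comparisons.

## Synthetic data: what it emulates, and what it does not

`make_cavity_structure()` builds a hollow sphere of pseudo-atoms in
concentric Fibonacci-lattice layers starting at `inner_radius + r_atom`, so
the enclosed cavity really has the requested radius; a spherical cap of the
requested solid-angle fraction is removed around +z to open a mouth, and
lining elements are drawn carbon-vs-oxygen from the seed at the requested
hydrophobic fraction. Defaults (6 Å cavity, 4.5 Å shell of ~1200 atoms) give
a drug-plausible ~900 Å³ pocket whose detected grid volume lands within the
stated 25% of the analytic ball. The aperture sweep used in the tests stays
at solid-angle fractions ≤ 0.04 — mouths narrower than the probe — because
that is the regime where the construction guarantees the pocket survives
detection; once the mouth passes the probe diameter the cavity stops being a
pocket at all, and near that transition the shell membership churns enough
that the buriedness trend is no longer a clean function of aperture.
Mouths below ~1.5 Å are additionally invisible to the SASA probe, so the
sweep's first step is 0 → 0.015. These are geometric facts about the
construction, not tuned values.

`make_helix_structure()` is the zero-pocket control: an ideal helix
(2.3 Å radius, 1.5 Å rise, 100°/residue) rendered as a dense backbone tube
plus an axial core rod and a side-chain ridge shifted into the inter-turn
groove — the features whose absence in a bare Cα trace would create
spurious spiral voids that no real, side-chain-bearing helix has.

`make_score_table()` draws raw scores uniformly over the ranges the study
observed (DLID ∈ [−1.5, 2.1], DScore ∈ [0.38, 1.24], SPIDER ∈
[0.085, 0.089]) — ranges, not fitted distributions, because only ranges are
published. `make_docking_tables()` gives each target its own decoy library
with background scores in [−19.5, −10.5] and a hit tail in [−35, −20.05];
shared molecules exist only where planted, so the overlap report's expected
content is known by construction.

None of these emulate real protein geometry, score correlations between
methods, or docking physics. A green test establishes that the *operations*
are correct on inputs whose ground truth is known by construction — not
that the pipeline reproduces any particular proprietary tool's output on a
real structure.

## Numerical choices and degenerate inputs

Coordinates are Å throughout; PDB I/O keeps 3-decimal precision, resolves
alternate locations to the highest occupancy (ties by altloc label order),
ignores hydrogens, and treats all HETATM records — waters included — as
strippable cofactors. Structures with fewer than 4 atoms are rejected as
degenerate for detection; empty shells, zero isolated SASA, no-contact
surfaces, and degenerate (constant) normalization columns all raise
explicit errors rather than returning conventional values. Fixture tables
pin md5 checksums so silent drift fails loudly. Comparisons against printed
tables use ±0.001 for renormalized columns and ±0.002 for composites —
the slack implied by 3-decimal printed rounding, nothing more.

## Known limitations

The cavity detector is a stand-in: it finds enclosed-or-constricted voids,
not the surface grooves and clefts that proprietary pocket finders also
report, and its descriptors are grid-resolution dependent (rigid-body
motions move volumes by a few percent and fractions by < 0.05). The
density-form DLID is only as good as its reference set, and no curated
drug-like-ligand pocket database ships with the package. SPIDER scores are
ingested, never computed. The single-cell expression validation arm of the
original study is out of scope entirely.
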