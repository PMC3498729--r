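---
title: "Profiling sequence and expression divergence of duplicated genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling sequence and expression divergence of duplicated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paradiv)
```

## The question

The two rounds of whole-genome duplication at the base of the vertebrates
left many developmental gene families — the Wnt ligands prominently among
them — with paralogous gene pairs ("a" and "b" copies) in each genome.
After duplication, paralogues diverge along two largely independent axes:
the protein-coding sequence, and the regulatory programme that decides
where and when the gene is transcribed in the embryo. Comparing both axes
for the same gene pairs, within a species (paralogue vs paralogue) and
across species (orthologue vs orthologue), is how subfunctionalization and
neofunctionalization are diagnosed in practice.

`paradiv` implements that comparative workflow as three analysis layers
plus a synthetic-data generator:

1. **Alignment conservation profiling** — classify every column of an
   outgroup-anchored five-sequence protein alignment into
   paralogue-conservation categories and summarise the counts.
2. **Expression-pattern grading** — grade the spatial similarity of two
   genes' expression within each anatomical territory on an ordinal
   four-step scale.
3. **Territory sharing** — compute, from a binary gene-by-territory
   presence matrix, which territories' expressing-gene sets are nested in
   which others, and whether the sharing is reciprocal.

## The conservation model

An alignment carries five roles: the single pre-duplication outgroup gene
(amphioxus, whose one Wnt per subfamily proxies the ancestral state) and
the "a"/"b" paralogues of two vertebrate species (`s1a`, `s1b`, `s2a`,
`s2b`; chick is species 1 and mouse species 2 in the Wnt instantiation).
Each column is classified by a fixed decision tree, in priority order:

* outgroup gap → `outgroup_gap` (excluded from conservation accounting);
* all five residues cysteine → `conserved_cys` (the invariant cysteines
  characteristic of Wnt ligands are tabulated separately, so a cysteine
  column is counted once, as cysteine);
* otherwise, with M the vertebrate roles matching the outgroup residue:
  four matches → `fully_conserved`; exactly three →
  `single_gene_divergent`, attributing the divergence to the one
  non-matching gene; M exactly the two "a" roles (or the two "b" roles) →
  paralogue-specific conservation of the ancestral residue; no matches
  with all four vertebrates mutually equal → `vertebrate_only` (a derived
  residue fixed across vertebrates); anything else → `unclassified`.

Two deliberate gap rules: an outgroup gap removes the column from every
category, and a vertebrate gap counts as a mismatch — the counts are
residue-level and a missing residue cannot be conserved. Conservation of
both copies in a single *species* (both chick genes matching the outgroup
while both mouse genes diverge) is left `unclassified` rather than counted:
it is a species-level, not a paralogue-level, signal.

"Matches" defaults to residue identity, which is unambiguous and directly
testable. A `groups` mode accepts conservative substitutions within fixed
strong physicochemical groups (STA, NEQK, MILV, HY, FW, DG), which is what
percent *similarity* conventionally means; pairwise similarity to the
outgroup is reported over mutually ungapped columns, the standard
denominator convention, and is the mode in which published similarity
percentages should be compared. Published per-category counts could have
been produced under either reading, and alignment parameters also shift
them, so neither mode is asserted to reproduce printed counts exactly.

## The expression model

Expression annotations are atomized records: gene, developmental stage,
anatomical territory, and the non-empty set of subdomains occupied within
the territory (a territory is a named embryo region such as the
mesencephalon or branchial arch 1; a domain is a subregion such as the
limb's dorsal ectoderm or the AER). Mouse and chick stage series are
paired TS15↔HH20, TS17↔HH23, TS19↔HH26. A qualitative level
(strong/moderate/weak) is stored but ignored by grading, which is purely
spatial.

The ordinal grade of a gene pair in a territory is a pure function of
their two domain sets D1, D2:

| grade | symbol | ordinal | rule |
|---|---|---|---|
| equal | `=` | 0 | D1 = D2 (both non-empty) |
| minor_diff | `*` | 1 | overlapping but unequal |
| diff_domain | `**` | 2 | disjoint, both non-empty |
| exclusive | `***` | 3 | exactly one empty |
| not_applicable | `.` | — | both empty |

Operationalizing "minor differences" as overlap-but-inequality and
"different domains" as disjointness is the only reading computable from
set-valued annotations. By default each gene's domains are pooled across
its stages before grading (`union` aggregation, matching the practice of
combining stages for summary tables); `worst` and `best` grade each
matched stage pair separately and report the extreme, exposing divergence
that stage-pooling can mask. Note the three modes are genuinely different
statistics — `union` can return a *milder* grade than any single stage
(pooled sets may overlap where per-stage sets were disjoint), so no
ordering between modes is asserted, only that stage-identical patterns
grade `equal` under all three.

A subfamily comparison grades four columns — the paralogue pair in each
species and the "a" and "b" orthologue pairs — over every territory where
any of the four genes is expressed, and summarises each column by a
**divergence index**: the mean ordinal grade over applicable territories,
0 for identical deployment, 3 for fully exclusive deployment. The index is
package plumbing (a numeric handle on "which subfamily is most diverged"),
not an estimator with a sampling theory.

## Territory sharing and reciprocity

From the binary presence matrix (a gene is present in a territory if it is
detected there at any stage), each territory t with expressing-gene set
S(t) lists every other territory t′ with S(t) ⊆ S(t′). The row is flagged
`R` when all listed supersets are exactly equal — the sharing runs both
ways for every partner — and `NR` otherwise; a territory contained in no
other is vacuously `R`. Because a single near-universal territory (the
midbrain, in Wnt data) makes almost every row `NR` at row level, equal-set
partners are additionally reported per pair (`reciprocal_with`), which is
the level at which statements like "branchial arches 1 and 2 are mutually
reciprocal" are tested. Territories with no expressing gene are excluded
from the rows — their containment in everything is vacuous noise — and
listed separately.

## The synthetic-data generator

The generator exists so every pipeline stage can be tested against planted
ground truth; its defaults are the study conditions, not tuning knobs.

**Alignments.** `simulate_alignment()` draws a category per column and
constructs residues satisfying exactly that category under identity
matching. The default mix (52% fully conserved, 8% conserved cysteines,
12% single-gene divergence, 6% + 6% paralogue-specific, 8% vertebrate-only,
8% outgroup gap) mirrors the qualitative structure of real Wnt subfamily
alignments: overwhelmingly conserved, with a thin scatter of informative
divergent sites. Planted labels are unambiguous by construction, so the
classifier must recover them at 100%.

**Expression.** For each subfamily and territory, with probability
`p_express` (default 0.5 — roughly the occupancy of a summary presence
matrix for a widely deployed ligand family) an ancestral domain set is
drawn; all four genes inherit it; then with probability `theta` per gene
and territory exactly one mutation is applied, drawn from three kinds that
map one-to-one onto grade outcomes: drop all domains (→ exclusive against
an expressing partner), replace the set with a disjoint one (→
diff_domain), add or remove one domain (→ minor_diff). The planted grade
is recorded from the final sets, so recovery is exact by construction.
`theta` is the divergence dial: at 0 every applicable grade is `equal` and
every divergence index 0; mean divergence rises monotonically in
expectation with `theta` (checked by Spearman correlation over a
`theta` grid of 0–0.9 at 50 territories with five replicate seeds — rank
correlation is the right check because the response saturates). Each
territory has a primary domain pool of 3 labels plus a disjoint backup
pool backing the replacement mutation. Domain sets are held constant
across a gene's stages; per-stage divergence is therefore *not* emulated,
and passing recovery tests says nothing about how real stage-varying data
behave under the per-stage aggregation modes.

What the generator does not emulate, and the tests therefore cannot show:
realistic protein evolution (no substitution matrix or indel model — a
planted column is a category exemplar, not an evolved site), anatomical
realism beyond a controlled vocabulary, correlated divergence between
neighbouring territories, annotation noise or observer disagreement, and
expression-level differences.

## Numerical and design choices

* Determinism: every generator takes an integer seed and the same seed
  yields byte-identical output files; pipeline reruns differ only in the
  manifest timestamp.
* Grades, categories and report rows are emitted in fixed vocabulary
  order, so outputs diff cleanly.
* Zero denominators raise errors rather than returning NA silently:
  pairwise similarity with no mutually ungapped column, and a divergence
  index with no applicable territory, are undefined quantities.
* Building the alignment is out of scope. The package consumes an existing
  alignment; for real-data work the upstream aligner should be pinned and
  recorded, because per-category counts are sensitive to alignment
  parameters. Reproduction of published per-subfamily counts additionally
  requires the original accession set, which is not shipped; the
  corresponding checks run only when curated alignments are staged under
  `inst/extdata/real/`.
* Test and acceptance problem sizes — 1,000 random columns and matrices,
  10,000 planted columns, a 10×5 theta grid at 50 territories — were
  chosen as comfortable desk-scale sizes at which the checked properties
  are already overwhelmingly powered.

## A short tour

```{r tour, eval = FALSE}
# conservation profile of a toy alignment
aln <- subfamily_alignment(
  c(outgroup = "CKGT-A", s1a = "CKGNLA", s1b = "CKSNLA",
    s2a = "CKGNLA", s2b = "CRSNLV"), subfamily = "toy")
profile_alignment(aln)

# simulate, compare, and render a subfamily grid
sim <- simulate_expression(theta = 0.3, seed = 42)
res <- compare_subfamily(sim$annotations, "Wnt5", sim$territories,
                         sim$stage_map, genes = sim$genes)
writeLines(render_grade_grid(res))

# sharing structure of the synthetic Wnt presence matrix
m <- synthetic_wnt_presence()
shared_territories(m)
universal_superset_check(m, cns_territories(), "mesencephalon")
```

## Known limitations

* Cross-species territory identity is by shared vocabulary id; no ontology
  mapping is attempted, so datasets must be annotated against one
  territory list.
* The grading scale is ordinal; averaging it into a divergence index
  treats the steps as equidistant, which is a convenience, not a claim.
* Row-level reciprocity is coarse in the presence of a universal superset
  territory; use the pairwise detail for fine statements.
* The annotation model is presence-based within territories; graded
  expression levels and continuous spatial boundaries are out of scope.
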