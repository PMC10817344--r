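---
title: "Methods: module completeness grading and comparative analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: module completeness grading and comparative analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phycomet)
```

# The problem

Comparative metabolic reconstruction asks, for a panel of genome and
transcriptome assemblies, which metabolic pathways each organism can
plausibly run, given only its functional annotation. The unit of
analysis is the KEGG-style *module*: a minimal pathway expressed as an
ordered conjunction of *blocks*, each block one enzymatic step
satisfied by one or more alternative orthologues (KO identifiers), or
by a protein complex whose subunits are joined with `+` and must all
be present. `phycomet` implements this reconstruction from plain KO
annotation tables, grades each (assembly, module) pair on a five-level
scale, and layers the comparative machinery used in cross-clade
surveys of algal metabolism on top: class-level completion-rate
profiles, variability selection, core-module set intersections, binary
presence-taxon association, gene-duplication aggregation on a species
tree, and assembly QC gates.

# The definition dialect

Module structure is written in a KEGG-DEFINITION-like grammar:

* top-level **spaces** separate blocks (the module is their AND);
* `,` separates alternative orthologues or complexes within a block
  (OR);
* `+` joins complex subunits and binds tighter than `,`;
* a leading `-` marks an optional component, excluded from
  satisfaction requirements, from the module's KO universe and from
  step counts (when `-` precedes a parenthesised group the flag is
  propagated to every atom inside, since optionality is represented on
  atoms);
* a bare `--` term denotes an undefined step and is skipped entirely —
  it is not counted as a block;
* parentheses group recursively; spaces *inside* parentheses form
  nested AND groups without splitting top-level blocks, so the block
  count equals the number of enzymatic steps as written.

This dialect — not the behaviour of any web service — is the contract:
it is chosen so that real KEGG flat-file DEFINITION lines parse, and
every parsed module round-trips through `serialize_module()` to a
structurally identical tree. Whether undefined `--` steps should
instead count as present is genuinely open; skipping them is the
documented choice here, and it keeps the block total equal to the
number of *defined* enzymatic steps.

```{r}
m <- parse_definition("K01853 (K08246,K09717) K00222", "M00917",
                      name = "phytosterol biosynthesis (example steps)")
m
ko_universe(m)
```

# Grading

A block is present only when its boolean expression is satisfied —
for a complex, every non-optional subunit must be annotated. From the
count of missing blocks each module is assigned a category and grade:

| grade | category   | meaning                                        |
|-------|------------|------------------------------------------------|
| 1     | COMPLETE   | no block missing                               |
| 2     | MISSING_1  | one block missing ("loosely complete" with 1)  |
| 3     | MISSING_2  | two blocks missing                             |
| 4     | INCOMPLETE | at least one block present, more than two missing |
| 5     | ABSENT     | no required orthologue of the module annotated |

A module whose only deficit is a *partially* annotated complex would
be unfairly graded at block resolution: a three-subunit complex with
two subunits present contributes zero blocks. Such modules are
re-graded on KO **steps**: each required orthologue of the chosen
satisfying alternative is one step, each missing step counts like one
missing block, and the final category is the better (numerically
lower) of the block-based and step-based categories, flagged with
`step_graded`. The step grade can never fabricate completeness — it is
COMPLETE only when every step is present, which implies every block is
satisfied — and a module is only finally ABSENT when the assembly
carries none of the module's required orthologues.

```{r}
grade_module(parse_definition("K00001+K00002+K00003", "M00001"),
             annotation_set("asm1", c("K00001", "K00002")))[
               c("category", "grade", "step_graded")]
```

Within a block, `step_credit()` chooses among the minimal satisfying
KO sets of the expression the alternative maximising the fraction of
steps present; ties are broken by fewer total steps, then by the
lexicographically smallest KO list. The tie-break is a deterministic
convention (the analogous manual grading is not specified at tie
resolution); it only matters when two alternatives are equally
complete, where any choice yields the same fraction. Enumeration is
refused for blocks with more than 64 required atoms as a combinatorial
guard — far beyond any real module definition.

Two completeness standards are exposed throughout: **strict** (grade
1) and **loose** (grade ≤ 2, i.e. at most one block missing). One
known divergence from the KEGG Mapper web tool is documented rather
than replicated: that tool suppresses the "1–2 blocks missing"
categories for very short modules (e.g. two-block modules); here the
category mapping is applied uniformly to all module lengths.

# Comparative layer

Completion-rate profiles are computed per group (taxonomic class,
order, or transcriptome source) as the fraction of the group's
assemblies in which the module is complete under the chosen standard;
only modules loosely complete in at least one assembly overall are
eligible. Cross-group variability is the **population** standard
deviation of the per-group rates (n denominator — the phrase
"standard deviation of the population" is read literally), and modules
with SD ≥ 0.2 are selected as variable by default. Core-module sets
per group collect modules loosely complete in at least 50% of the
group's assemblies (inclusive boundary), and the k-set Venn
decomposition is reported as exact membership-pattern counts.

Association between a binary feature (KO or block presence) and a
binary grouping is measured with the **phi coefficient**, computed
from the 2×2 contingency closed form

$$\phi = \frac{n_{11} n_{00} - n_{10} n_{01}}
{\sqrt{n_{1\cdot}\, n_{0\cdot}\, n_{\cdot 1}\, n_{\cdot 0}}},$$

which equals the Pearson correlation of the two 0/1 vectors. phi is
adopted because printed values of exactly ±1.00 in this kind of
analysis are only attainable by a symmetric association measure on
binary data: +1 means presence in exactly the indicated group. When a
margin is zero (a feature present or absent everywhere, or a
degenerate grouping) the coefficient is undefined and returned as a
flagged `NA` rather than silently zeroed, so downstream rankings are
not corrupted. Both KO-level and block-level presence matrices are
provided; which features to correlate is the caller's choice.

The statistical helpers are the panel comparisons a survey of this
kind uses: the two-tailed Welch t test (unequal variances,
Welch–Satterthwaite df) for two groups, single-factor ANOVA for more,
and Levene's test for variance heterogeneity, centred on the group
mean (the classic variant; the median-centred Brown–Forsythe variant
can be obtained by calling `car::leveneTest` directly). No
multiple-testing correction is applied anywhere. When every group is
internally constant the F statistic is undefined and flagged
degenerate.

# Duplication integration

Gene-duplication events are consumed, not inferred: the reader takes
the OrthoFinder `Duplications.tsv` dialect (orthogroup, species-tree
node, gene-tree node, support, type, two comma-separated descendant
gene lists) and a Newick species tree with unique internal node
labels. Events are filtered at support ≥ 0.5 by default — inclusive,
"at least 50%". Two framings are deliberately kept apart and both
exposed: **node totals** count events (records), while **category
integration** counts distinct duplicated genes — the union of both
descendant lists across a node's records, each distinct gene
contributing once to every category it is annotated with. Genes
missing from the annotation map are tallied as unannotated, never
dropped silently. Category namespaces (InterPro Homologous
Superfamily, GO term, …) are opaque labels: no ontology traversal or
GO-ancestor propagation is performed. Exports include a per-node TSV
and an iTOL pie-chart annotation with radius proportional to
log10(total events) and an optional top-k category cap (the display
cap is a presentation choice, so all categories are exported by
default).

# QC gating

BUSCO short summaries are parsed from the canonical
`C:x%[S:x%,D:x%],F:x%,M:x%,n:N` line; the assembly gate passes at
complete ≥ 35% **and** missing < 50%. The missing bound is strict
because the two inequality styles in circulation differ at exactly
50.0, and the stricter Methods-style reading is implemented; both
thresholds are arguments. The gate is mode-agnostic (protein or
genome BUSCO scores are treated alike). RepeatMasker `.tbl` summaries
are collated into retroelements, DNA transposons, simple repeats and
unclassified, with all other tabulated categories (satellites, small
RNA, low complexity, rolling circles) pooled as `other`. Protein
statistics are count and mean length over *all* sequences, stop
characters stripped, no length filtering.

# The synthetic study generator

Real panels of this kind are tens of assemblies × hundreds of modules
with external annotation databases; tests instead run on synthetic
data whose structure is controlled. `synthetic_config()` defines the
study conditions; `simulate_study()` writes a complete fixture
directory (modules, per-assembly annotations, metadata, duplications,
tree, gene categories, BUSCO/RepeatMasker/FASTA files, and the config
as a reproducibility record).

Defaults, chosen once as a realistic desk-scale panel:

* **4 genome-class groups × 8 assemblies, 200 modules** of 3–6 blocks
  — about half the size of a real module catalogue, sized so the full
  grading matrix runs in seconds;
* `p_core_present = 0.95`: conserved core metabolism with realistic
  annotation dropout, so per-group completion rates for unperturbed
  modules sit high with binomial noise well below the 0.2 SD cutoff;
* `p_complex = 0.25`, complex size 2–3, `p_or_alternative = 0.3`:
  enough multi-KO blocks to exercise step re-grading routinely;
* **10 differential modules at knockout 0.9**, each planted in one
  class: per-KO removal at 0.9 drives the affected group's completion
  rate near zero, giving cross-group rate SDs around 0.4 — clearly
  separated from the null;
* transcriptome dropout 0.30 (1KP-like) and 0.15 (MMETSP-like),
  mirroring the larger annotation loss seen in 1KP-style assemblies;
* duplication supports drawn uniform on [0, 1], so the 0.5 filter has
  a known retention expectation of one half; enrichment odds 8 for
  each node's planted category against a 10-category background,
  strong enough that the planted category is modal per node.

Presence is simulated at the KO level (completeness consumes KO sets);
a thin one-gene-per-KO wrapper is emitted so the annotation readers
are exercised. The species tree is a ladder by default so node labels
are stable across runs. All draws go through R's Mersenne-Twister
generator under `withr::with_seed` with small fixed offsets per
sub-generator, so every artefact is byte-identical under a fixed seed
and independent of evaluation order.

What the generator does **not** emulate — and hence what passing tests
do not certify about real data: sequence-level error, correlated
annotation failure across related orthologues (real annotation loss is
phylogenetically structured, not i.i.d.), module definitions with deep
nesting or heavy use of optional subunits, BLAST-rescue of
unannotated orthologues, and duplication-event uncertainty beyond a
scalar support. The pipeline's statistical behaviour on real
annotations should be validated against the usual external tools.

# Numerical and degenerate-input conventions

* Population SD (n denominator) everywhere a variability threshold is
  applied; thresholds are validated to [0, 1].
* Inclusive boundaries where the field's phrasing says "at least"
  (prevalence 50%, support 50%, BUSCO complete 35%); strict where it
  says "less than" (BUSCO missing 50%).
* Undefined statistics (phi with a zero margin, ANOVA with zero
  within-group variance, mean protein length of an empty file) are
  flagged, never imputed.
* Empty annotation sets are legal and grade everything absent; empty
  duplication tables parse to an empty record list with a warning.
* All table outputs are deterministically ordered so diffs are stable.

# Problem sizes used in the shipped tests

The oracle-agreement suite checks 1,000 random (module, KO-set) pairs
of up to 6 blocks and 6 required orthologues per block against an
independently compiled boolean evaluator; monotonicity is checked over
500 random annotation extensions × 10 modules; parameter recovery runs
the full default panel (4 × 8 assemblies, 200 modules). These sizes
keep the complete suite under a minute on one CPU while leaving the
combinatorial space densely sampled.
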