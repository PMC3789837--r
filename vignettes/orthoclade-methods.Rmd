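---
title: "Methods: lineage-specific ortholog classification and its comparative layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-specific ortholog classification and its comparative layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoclade)
```

## The problem and the model

Ortholog-clustering tools (OrthoMCL and kin) turn all-against-all BLAST
into multi-species ortholog groups via reciprocal-best-hit (RBBH) graphs.
Given such groups for a broad species panel, a *core lineage-specific*
gene family — here, metazoan-specific — is one present across essentially
the whole lineage and absent outside it. Two error modes make the naive
"all metazoans, zero non-metazoans" rule useless in practice:

1. **Incomplete genomes.** A genuinely conserved gene can be missing from
   a species' predicted gene set. The classifier therefore takes
   species presence at the clade level with slack: minimum presence per
   clade (defaults 9/11 Craniata, 6/8 Arthropoda, 2/3 Nematoda), at least
   one of the single-representative clades (Urochordata, Cnidaria), and a
   combined floor of 20 of the 24 counted metazoans. The slack is the
   model of genome incompleteness; the package measures that
   incompleteness independently via `coverage_report()` (fraction of a
   reference list of widely conserved, low-copy eukaryotic groups in
   which each species appears), but coverage never gates classification —
   it is a QC read-out for choosing and defending the slack.
2. **Clustering false positives.** A single non-metazoan gene is
   occasionally absorbed into an otherwise metazoan group, typically with
   very few RBBH links to the group. The foreign-leakage rule tolerates
   at most 2 counted non-metazoan species per group, each of whose genes
   has at most 3 RBBH links to the group's metazoan members; anything
   better connected is treated as evidence the group is genuinely not
   lineage-specific.

Species presence is binary per group: paralogs never increase counts, so
the procedure counts genomes, not proteins. The focal species
(*Trichoplax*, the basal Placozoan) contributes to no selection
criterion; it only partitions the selected groups into present/absent
afterwards (`partition_by_species()`), which is the biologically
interesting split (innovations predating vs postdating the
Placozoa–Eumetazoa divergence).

All thresholds live in a `clade_schema` object and ship with the
defaults above; `default_clade_schema()` derives the species sets from a
species table (counted metazoans = all metazoans minus the focal species;
counted non-metazoans = non-metazoans flagged `well_sequenced`).

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `clade_min_presence` | 9/11, 6/8, 2/3 | species | clade slack sized to observed genome incompleteness (~94% mean core-gene coverage, 79% worst case) |
| `total_min_presence` | 20 (of 24) | species | global floor so slack cannot accumulate across clades |
| `max_foreign_species` | 2 (of 112) | species | tolerated clustering leakage |
| `max_foreign_rbbh_links` | 3 | edges/gene | a true ortholog would be densely connected; singletons with ≤3 links read as false positives |
| `alpha` (comparative layer) | 0.05 | — | conventional FDR level on BH-adjusted values |

## Decisions taken where the design was open

* **Per-gene RBBH threshold.** The link bound is applied to each foreign
  gene separately, not summed over the group, and paralogs of a foreign
  species are each checked individually. The per-gene reading matches the
  false-positive model (each spurious member earned its own weak edges).
* **Counted non-metazoans.** With 138 species and 25 metazoans the
  non-metazoan complement is 113, yet the denominator used for the
  foreign rule is 112. The schema therefore carries an *explicit*
  counted non-metazoan set rather than deriving it by subtraction; the
  default takes the `well_sequenced` flag, and the bundled synthetic
  layout ships 113 non-metazoans with one flagged not-well-sequenced.
* **Label precedence instead of a mutual-exclusion assertion.** A group
  containing every counted metazoan plus exactly *S. cerevisiae* and
  *A. thaliana* as weakly linked members satisfies both the
  lineage-specific and the eukaryote-core control rules. Rather than
  asserting the two labels disjoint (which such a corner case would
  violate), `classify_groups()` labels by precedence
  (`metazoan_specific` first), records the control criterion in
  `meets_eukaryote_core`, and warns when the overlap occurs.
* **Enrichment sidedness.** Both one-sided hypergeometric tails are
  reported per category and each tail family is BH-adjusted separately
  across categories; the reported direction is the smaller tail. This
  keeps over- and under-representation calls symmetric without doubling
  p-values.
* **Two-sided Fisher convention.** The probability-mass rule (sum of
  tables with probability ≤ the observed table's), the common exact-test
  convention; it is cross-checked against exhaustive enumeration in the
  tests.
* **Phenotype denominators.** The any-phenotype proportion is taken over
  genes *with RNAi data*; class proportions are taken over genes showing
  at least one phenotype. A gene may belong to several classes; codes
  outside the class map are warned about and ignored, while a small
  `other` set of recognised-but-unclassified codes lets a gene count as
  phenotype-bearing without inflating any class.
* **Keyword matching** is plain case-insensitive substring search with
  the stems exactly as used in the field's curation tools ("intestin",
  "germ", ...), no word boundaries; stems are configurable.
* **Interaction summary.** "Average proportion of interactions" is
  ambiguous between pooling edges and averaging per gene; both read-outs
  are emitted (`counts$prop_pooled` and `per_gene_mean`).
* **Coverage summaries.** Whether the metazoan mean should include the
  focal species is equally defensible either way, so the pipeline
  summary reports both means.

## The synthetic-data generator

`simulate_world()` plants six group classes realising the presence
patterns the classifier must separate: full metazoan cores (with the
focal species present at probability 0.66, matching the observed
conservation fraction), eumetazoan cores lacking the Placozoan,
eukaryote-core control groups, clade-restricted groups, promiscuous
groups spanning prokaryotes, and contaminated metazoan cores carrying
1–2 foreign singletons whose RBBH degree is drawn from a configurable
distribution (default uniform on 0–3). Truth labels are recorded
*pre-dropout*, which is what makes recall under incompleteness a
measurable quantity — the quantity the clade slack exists to protect.

Dropout models genome incompleteness as an independent per-(group,
species) event: the species loses its entire presence in that group at
once, which is the granularity the classifier perceives. The default
rate of 0.06 corresponds to the ~94% mean core-gene coverage regime.
Groups emptied entirely by dropout are removed from both the collection
and the truth table (they are unobservable). `expected_labels()` maps
planted classes to the labels the classifier should produce and is valid
for the pre-dropout pattern, so exact truth-recovery oracles use zero
dropout or deterministic within-slack removals.

`simulate_annotations()` plants the comparative layer: category
assignments with configurable fold enrichment in the foreground set,
phenotype codes realising per-set any-phenotype (defaults 0.55 vs 0.74)
and class probabilities (essential 0.56 vs 0.80, development 0.17 vs
0.09, movement 0.07 vs 0.03), expression texts concatenated from a
phrase vocabulary constructed so the keyword classifier recovers the
planted tissue flags exactly (neuronal any-expression defaults 0.72 vs
0.54), within-/cross-set interaction densities chosen to put per-gene
connectivity near one edge, OMIM map keys (P(key = 3) = 0.16) and
characterization flags (10% vs 5% fully uncharacterized). Phenotype
class draws are independent Bernoullis conditional on being
phenotype-bearing; a bearing gene hitting no class receives an
out-of-class code, so class proportions stay exactly at their planted
values.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: phylogenetic correlation of gene loss (dropout
is independent across species and groups), BLAST score structure behind
the RBBH graph, paralog family expansion beyond single duplications,
annotation biases that correlate across databases, and the curation
noise of real free-text expression fields. The generator validates the
*logic* of the pipeline at its native scale; it cannot validate the
biological thresholds themselves.

## Numerical and degenerate-input choices

* Exact tail probabilities come from the hypergeometric distribution
  function; no normal approximations anywhere in the package.
* Ties in enrichment ordering are broken by category label; group order
  in classifications follows input order, and writers emit canonical
  sorted forms so runs are byte-reproducible.
* Degenerate inputs are hard errors where silence would bias a result
  (empty reference list, foreground genes missing from the background,
  unknown species or gene-id syntax, a reconstruction with zero observed
  microtubule endpoints), warnings where tolerating upstream redundancy
  is the right call (duplicate members within a group, unknown phenotype
  codes), and empty-but-valid results for genuinely empty queries.
* All randomness flows from a single integer seed per generator call;
  generation uses only integer- and uniform-based draws with no locale
  dependence.

## Problem sizes used by the test and acceptance runs

Unit and property tests run on worlds of 28–250 groups with the full
55-species layout (24 counted metazoans + focal + 30 non-metazoans), 200
replicates for the enrichment type-I check, exhaustive exact-test
enumeration to table totals of 14 plus 400 randomized tables to totals
of 40, and the phenotype simulation at its native sizes (318 and 915
phenotype-bearing genes). These sizes were chosen so the whole suite
exercises every code path in well under a minute while keeping binomial
standard errors small enough for 3-SE planted-recovery checks. The
default world size (~2,500 groups, 138 species) mirrors roughly a tenth
of a full ortholog database and is exercised by the simulation CLI
rather than the test suite.

## Known limitations

* The classifier consumes clustering output; it cannot rescue groups
  OrthoMCL split or merged upstream, and it does not attempt horizontal
  gene transfer detection — a well-connected foreign member simply
  disqualifies a group.
* Coverage is a gene-set proxy for genome completeness; it says nothing
  about assembly quality outside the reference list.
* The expression classifier is a substring scheme and inherits the
  ambiguities of free-text curation (e.g. "uterine muscle" counts as
  both muscle and reproductive).
* The morphometric estimator assumes endpoints are observed uniformly
  along the reconstruction; it takes one reconstruction at a time and
  leaves pooling across reconstructions to the caller.
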