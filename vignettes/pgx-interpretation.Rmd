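---
title: "Methods: genotype-to-phenotype translation, phenoconversion and recommendation resolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-to-phenotype translation, phenoconversion and recommendation resolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxreport)
```

`pgxreport` interprets pharmacogenomic test results: it maps genotypes to
inferred phenotypes, adjusts CYP450 phenotypes for concomitant inhibitors
and inducers, and resolves one prescribing recommendation per supported
gene-drug pair through a source-preference hierarchy. This vignette
documents the model, the tunable parameters, the numerical and design
choices made where the design was genuinely open, and what the shipped
fixture does and does not emulate.

## The interpretation model

### Input

A patient record supplies, in three optional steps, (1) at most one
genotype call per gene with an optional free-text note, (2) current
medications, and (3) medications being considered. Three genotype input
modes exist, one per gene class:

* **star_diplotype** (CYP2B6, CYP2C9, CYP2C19, CYP2D6, CYP3A5, TPMT,
  NUDT15, SLCO1B1): two `/`-separated star alleles. Canonicalization sorts
  alleles numerically, then by subvariant letter, then by copy-number
  suffix, so `*2/*1` and `*1/*2` are the same key. Copy-number alleles
  (`*1x2`, `*1xN`) are accepted syntactically; if the resulting key has no
  table entry the call becomes indeterminate rather than an error, since
  copy-number nomenclature varies across laboratories.
* **hla_presence** (HLA-A, HLA-B): a single allele plus a presence status,
  canonicalized to `"*57:01 positive"` form. Several status spellings
  (pos/+/present, neg/-/absent) are accepted because free-text lab reports
  vary.
* **variant_genotype** (VKORC1): a base pair such as `A/G`, sorted
  alphabetically; an optional variant label (`-1639G>A A/G`) is tolerated
  and discarded.

Drug names are matched case- and whitespace-insensitively against the
knowledge base plus a small synonym table. Unrecognized drugs are carried
through and listed in the report as unrecognized — a tool accepting
free-text medication lists must surface, not swallow, what it cannot
classify.

### Genotype to phenotype

Translation is exact lookup in gene-specific diplotype-to-phenotype tables.
Two sentinels cover the failure modes: **indeterminate** (a diplotype was
supplied but has no table entry) and **unknown** (no genotype supplied for
the gene). Sentinels are stored in a field of their own, never as terms on
the phenotype scale, so downstream ranking and phenoconversion cannot
accept them by accident. No interpolation and no CYP2D6 activity-score
arithmetic is performed; the unit of inference is the curated table row.

Each metabolizer gene carries an ordered activity scale (lowest to highest
activity). The scales are a documented curation choice, following the
consensus standardized phenotype terms:

| gene | scale |
|---|---|
| CYP2B6, CYP2C19 | poor, intermediate, normal, rapid, ultrarapid metabolizer |
| CYP2C9, CYP3A5 | poor, intermediate, normal metabolizer |
| CYP2D6 | poor, intermediate, normal, ultrarapid metabolizer |

Non-scale genes use categorical term sets with no rank: allele-qualified
presence terms for HLA (`*57:01 positive`), warfarin-sensitivity categories
for VKORC1 (normal / increased / high sensitivity), transporter function
categories for SLCO1B1, and metabolizer categories (unranked, since these
genes are not phenoconversion-eligible) for TPMT and NUDT15. HLA terms are
allele-qualified deliberately: a bare positive/negative would let a
\*15:02 result satisfy an abacavir (\*57:01) recommendation, which would be
wrong.

### Inhibitor strength

Inhibitors are graded from pharmacokinetic evidence: the fold-increase in a
probe substrate's plasma AUC, or the percent decrease in its clearance, in
the inhibitor's presence.

| category | AUC fold-increase | clearance decrease |
|---|---|---|
| weak | 1.25–2 | 20 to <50% |
| moderate | >2 to 5 | 50–80% |
| strong | >5 | >80% |

The printed ranges leave the boundaries at 2-fold, 5-fold, 49–50% and 80%
ambiguous; this implementation closes the weak AUC interval at 2 (so 2.0 is
weak, 2.01 moderate), treats 5.0 as moderate with strong strictly above,
closes the 49–50% gap by defining weak as [20, 50), and keeps 80% moderate
with strong strictly above. When both measures are supplied the stronger
classification wins (evidence of strong inhibition on either axis should
not be diluted by the other). Values below both floors raise an explicit
"below weak-inhibitor floor" error rather than silently classifying as
no-interaction. A curator disagreeing with these boundary conventions edits
the stored `strength` column directly; the validator then cross-checks
stored strengths against any evidence columns present.

Inducers are not strength-graded: the interaction catalog this models does
not provide induction strength, so induction is a single category.

### Phenoconversion

Only the five CYP450 genes (CYP2B6, CYP2C9, CYP2C19, CYP2D6, CYP3A5) are
adjusted, and only in the presence of a moderate inhibitor, a strong
inhibitor, or an inducer. The rules, in order of precedence:

1. Sentinel phenotypes and non-eligible genes are never adjusted (no
   defined rank to move from).
2. An adjustment-triggering inhibitor (moderate or strong) co-occurring
   with an inducer means no conversion — the evidence to arbitrate the
   direction is lacking. A *weak* inhibitor plus an inducer does **not**
   trigger this conflict: weak inhibitors never trigger adjustment, so
   induction applies. This scope choice is this package's documented
   decision.
3. A strong inhibitor converts any phenotype to poor metabolizer; a call
   already at the floor is reported as `floor_no_change`.
4. Otherwise a moderate inhibitor moves one step down the gene's scale.
   Strong dominates moderate when both are present (consistent with strong
   inhibition overriding the inferred phenotype entirely). A moderate
   inhibitor acting on an intermediate metabolizer lands on poor
   metabolizer — that is a genuine conversion, not `floor_no_change`, which
   is reserved for calls already at the floor.
5. Otherwise an inducer moves one step up; top-of-scale calls are
   `ceiling_no_change`. Steps move along the terms the gene actually
   defines: CYP2D6 has no rapid metabolizer term, so a CYP2D6 normal
   metabolizer plus an inducer converts directly to ultrarapid.
6. Anything else — weak inhibitors only, substrates only, no interacting
   drugs — is `no_trigger`.

Weak inhibitors and substrates still appear in the report's per-gene
interaction listing: the clinician sees everything the tool classified,
including what it chose not to act on. The whole rule set is verified in
the test suite against an independently coded truth table over every
eligible gene × every scale term and both sentinels × all 16 combinations
of trigger presence (480 cells).

### Recommendation resolution

Recommendation records are keyed by drug, a gene set (one or more genes),
and a phenotype key assigning one term per gene. Resolution produces **one
entry per registry (gene, drug) pair**, so the output always spans the full
registry regardless of how little genotype data was supplied:

* A record matches when every gene in its key has an effective phenotype —
  the phenoconverted term when a conversion applied, else the inferred
  term — equal to the key's term. Recommendations therefore follow the
  phenoconverted phenotype automatically.
* Composite multi-gene records (warfarin CYP2C9+VKORC1, azathioprine
  TPMT+NUDT15, carbamazepine HLA-A+HLA-B) are preferred over single-gene
  records when all their genes are callable and matched; with partial data
  the best single-gene record for the pair applies. Guideline sources are
  silent on how to handle partial data; preferring the most specific
  applicable record is this package's choice.
* Among the remaining candidates the source hierarchy **CPIC > DPWG > FDA**
  selects the displayed record. Two candidates sharing the top source is a
  curation defect and raises an error rather than picking arbitrarily.
* Pairs with unknown/indeterminate calls, or whose effective phenotype has
  no matching record, yield a strength-`none` entry with an explanatory
  sentence. This is how an HLA-B \*15:02 carrier's report represents
  abacavir: the \*57:01 status is simply not known.

Filters (drug, drug class, gene, actionable vs non-actionable) are
conjunctive, order-preserving, idempotent and commuting; "actionable" is a
curated boolean on each record meaning the advice deviates from standard
prescribing. Medications being considered are *copied* into a separate
table; the full list remains complete.

### The report

The report model is assembled deterministically (rows ordered by gene
symbol; identical inputs render byte-identical JSON) and rendered to JSON,
Markdown or HTML. The knowledge base's last-updated date appears in the
header of every rendering, the generation date is injectable (function
argument, `--date` flag, or `PGXREPORT_DATE` environment variable) so
outputs are reproducible, and rendering performs no writes: the only file
the command-line tool produces is the one named by `--out`, and no patient
input is ever persisted.

## The fixture knowledge base

The shipped fixture is a complete, self-validating bundle: the full 97-pair
registry over 11 genes with the HLA allele qualifiers, diplotype maps for
common diplotypes of every gene, an interaction catalog in the style of a
CYP drug-interaction table (paroxetine and fluoxetine as strong CYP2D6
inhibitors, fluvoxamine strong at CYP2C19, rifampin as a broad inducer, and
so on, with AUC/clearance evidence stored for most inhibitors), and at
least one recommendation record per registry pair — one per valid phenotype
term, with extra DPWG/FDA records for codeine and clopidogrel so the
hierarchy is exercised on real multi-source candidates, and DPWG as the
source for VKORC1 records so multi-gene drugs have distinct single-gene
sources.

What the fixture does **not** emulate: recommendation texts are synthetic
placeholders (`placeholder = TRUE` on every record) generated from a
template — licensed guideline prose is not redistributed — and the
diplotype maps cover common, unambiguous diplotypes rather than the full
curated tables. Passing tests therefore demonstrate the engine's mechanics
(translation, adjustment, hierarchy, coverage, determinism) on a
structurally faithful knowledge base; they say nothing about the clinical
correctness of any production bundle, which carries its own curation and
versioning. The `version` and `last_updated` manifest fields exist exactly
so a deployment can be audited against its curation date.

## Numerical and degenerate-input choices

* Boundary semantics of the inhibitor classifier: documented above;
  monotonicity in both evidence measures is property-tested.
* Diplotype keys are canonical in the knowledge base itself; the validator
  rejects non-canonical stored keys, so lookup never depends on entry
  order.
* Unparseable genotype strings do not abort interpretation: the parse error
  is recorded, the gene's call becomes indeterminate, and the report
  carries on — matching how a clinician-facing tool should degrade.
* An empty patient record is valid: every gene reports unknown, and all 97
  pairs resolve with strength none.
* Ambiguity (two same-source candidates for one context) and schema
  violations are loud errors at load/validation time, never silent
  tie-breaks at resolution time.

## Problem sizes used in the test suite

The suite runs entirely on the fixture: the 480-cell phenoconversion truth
table, 1,000 randomized hierarchy candidate sets, 200 generated diplotype
pairs for the normalization properties, and end-to-end reports over the
97-pair registry. These sizes exhaustively cover the rule space (the truth
table and the fixture maps are enumerated completely), so larger inputs
would add no coverage.
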