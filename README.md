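# pgxreport

Offline pharmacogenomic (PGx) interpretation and clinical report generation
for R.

Clinical PGx testing reports a patient's genotype at a handful of
pharmacogenes — star-allele diplotypes for the CYP450 enzymes and
TPMT/NUDT15/SLCO1B1, presence calls for HLA risk alleles, and named-variant
genotypes for VKORC1 — but translating those calls into evidence-based
prescribing advice is error-prone by hand. Commercial reports also routinely
ignore *phenoconversion*: a genotypic CYP2D6 normal metabolizer taking
paroxetine (a strong CYP2D6 inhibitor) behaves clinically like a poor
metabolizer, so recommendations keyed to the genotype alone can be wrong for
the patient in front of you.

`pgxreport` is a small decision-support engine for laboratory staff,
clinicians and PGx researchers that runs entirely offline:

1. **Genotype → phenotype.** Canonical diplotypes (allele-order-insensitive)
   are looked up in curated gene-specific diplotype-to-phenotype tables. A
   supplied-but-unmapped diplotype yields an `indeterminate` call; a gene
   with no input yields `unknown`. No haplotype or star-allele calling from
   raw data is attempted.
2. **Phenoconversion adjustment.** Current medications are classified per
   CYP gene as substrates, inhibitors (weak / moderate / strong, from the
   fold-increase in a substrate's plasma AUC — weak 1.25–2×, moderate >2–5×,
   strong >5× — or the percent decrease in clearance — weak 20–<50%,
   moderate 50–80%, strong >80%) or inducers. A moderate inhibitor shifts
   the inferred phenotype one activity step down, a strong inhibitor
   converts it to poor metabolizer regardless of genotype, an inducer shifts
   one step up; poor metabolizers with inhibitors and top-of-scale
   metabolizers with inducers are left unchanged, as is any phenotype seeing
   both an adjustment-triggering inhibitor and an inducer at once.
3. **Recommendation resolution.** Effective phenotypes (phenoconverted when
   applicable) are cross-referenced with recommendation records; when a
   gene-drug pair has candidates from several sources, the
   **CPIC > DPWG > FDA** preference hierarchy picks the one displayed.
4. **Report generation.** A deterministic report model (genetic results,
   per-gene interaction listings, filterable future-medications table,
   separate medications-being-considered table, disclaimer) rendered to
   JSON, Markdown or HTML, with the knowledge base's last-updated date in
   the header of every report.

The knowledge base is a versioned, human-diffable bundle (five TSV tables
plus a JSON manifest). The shipped fixture covers the full supported
registry — **97 gene-drug pairs across 11 genes** (CYP2B6, CYP2C19, CYP2C9,
CYP2D6, CYP3A5, HLA-A, HLA-B, NUDT15, SLCO1B1, TPMT, VKORC1), five of them
eligible for phenoconversion — but its recommendation texts are synthetic
placeholders (flagged `placeholder = TRUE`): licensed guideline prose is not
redistributed, and a production deployment supplies its own curated bundle.

## Worked example

The package ships a synthetic example patient (`inst/extdata/patient-synthetic.json`):
CYP2D6 \*1/\*2, CYP2C19 \*1/\*2, CYP2C9 \*1/\*3, VKORC1 −1639G>A A/G, HLA-B
\*57:01 negative, currently taking paroxetine and rifampin.

```r
library(pgxreport)
kb <- fixture_kb()
patient <- parse_patient_input(
  system.file("extdata", "patient-synthetic.json", package = "pgxreport"))
interp <- interpret_patient(kb, patient)

interp$calls[["CYP2D6"]]
#> <pgx_converted_call> CYP2D6: normal metabolizer -> poor metabolizer (strong_inhibitor: paroxetine)
interp$calls[["CYP2C19"]]
#> <pgx_converted_call> CYP2C19: intermediate metabolizer -> normal metabolizer (inducer: rifampin)
```

CYP2D6 \*1/\*2 is genotypically a normal metabolizer, but paroxetine (strong
CYP2D6 inhibitor) phenoconverts the call to poor metabolizer; CYP2C19
\*1/\*2 (intermediate) is induced one step up by rifampin. Recommendations
then follow the *converted* phenotype — codeine resolves against the poor
metabolizer record, through the CPIC-first hierarchy:

```r
interp$resolutions[interp$resolutions$drug == "codeine",
                   c("gene", "phenotypes_used", "strength", "source", "text")]
#>    gene         phenotypes_used strength source                                               text
#>  CYP2D6 CYP2D6=poor metabolizer   strong   CPIC Avoid or adjust codeine (CYP2D6 poor metabolizer).
```

Render the full clinical report:

```r
model <- build_report(patient, kb, interp, generated_on = "2026-02-01")
writeLines(render_report(model, "markdown"), "report.md")
```

## Command line

A thin wrapper script is installed at
`system.file("cli", "pgxreport", package = "pgxreport")`:

```sh
pgxreport report --patient patient.json --kb fixture --format html --out report.html
pgxreport report --patient patient.json --out r.json --gene CYP2D6 --actionable
pgxreport kb stats --kb fixture        # pairs=97 genes=11 drugs=86 phenoconversion_genes=5
pgxreport kb validate --kb my-bundle/
pgxreport kb init-fixture --out my-bundle/
```

Nothing the tool reads is ever persisted; the only file written is the one
named by `--out`.

## Limitations

- Diplotype-to-phenotype translation is exact table lookup; CYP2D6 activity
  scores and copy-number arithmetic are out of scope (copy-number alleles
  are accepted syntactically and resolve to `indeterminate` unless mapped).
- Phenoconversion is deliberately blunt: inducers are not strength-graded,
  inhibition is not substrate-specific, and TPMT/SLCO1B1 inhibitors are not
  modeled.
- One genotype entry per gene: an HLA-B call for one allele (e.g. \*15:02)
  carries no information about the others, and the corresponding drug rows
  report "no recommendation" rather than guessing.
- The shipped fixture's recommendation texts are placeholders, not clinical
  guidance; the tool's output is intended for interpretation by licensed
  healthcare professionals.
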