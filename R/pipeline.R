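# End-to-end interpretation: patient record -> phenotype calls ->
# phenoconversion -> resolved recommendations.

#' Interpret a patient record against a knowledge base
#'
#' Runs the full pipeline: normalizes genotypes and medication names,
#' translates diplotypes to inferred phenotypes (every knowledge-base gene
#' receives a call; genes without input are `"unknown"`), builds interaction
#' profiles for the phenoconversion-eligible genes from the current
#' medications, applies phenoconversion, and resolves a recommendation for
#' every registry gene-drug pair.
#'
#' @param kb A `pgx_kb`.
#' @param patient A `pgx_patient` from [parse_patient_input()].
#' @return List with `calls` (named list of `pgx_converted_call`, one per
#'   knowledge-base gene, ordered by symbol), `profiles` (named list of
#'   `pgx_interaction_profile` for eligible genes), `resolutions` (data frame
#'   from [collect_recommendations()]), `considered`
#'   (from [split_considered()]), `current_medications` /
#'   `considered_medications` (normalization tables from
#'   [normalize_drug_name()]) and `genotype_errors` (named character vector
#'   of parse failures, surfaced rather than fatal).
#' @export
interpret_patient <- function(kb, patient) {
  stopifnot(inherits(kb, "pgx_kb"), inherits(patient, "pgx_patient"))
  unknown_genes <- setdiff(patient$genotypes$gene, kb$genes$symbol)
  if (length(unknown_genes) > 0L) {
    stop(sprintf("genotype supplied for gene(s) not in the knowledge base: %s",
                 paste(unknown_genes, collapse = ", ")), call. = FALSE)
  }
  current <- normalize_drug_name(kb, patient$current_medications)
  considered <- normalize_drug_name(kb, patient$considered_medications)

  gene_order <- sort(kb$genes$symbol)
  genotype_errors <- character(0)
  base_calls <- lapply(gene_order, function(g) {
    gdef <- kb_gene(kb, g)
    i <- match(g, patient$genotypes$gene)
    if (is.na(i)) return(translate_diplotype(kb, g, NA_character_))
    note <- patient$genotypes$note[i]
    canon <- tryCatch(normalize_diplotype(gdef, patient$genotypes$raw_value[i]),
                      error = function(e) conditionMessage(e))
    ok <- tryCatch({normalize_diplotype(gdef, patient$genotypes$raw_value[i]); TRUE},
                   error = function(e) FALSE)
    if (!ok) {
      # unparseable genotype: record the error, treat the call as unmapped
      genotype_errors[[g]] <<- canon
      return(new_phenotype_call(g, patient$genotypes$raw_value[i],
                                NA_character_, "indeterminate", note))
    }
    translate_diplotype(kb, g, canon, note = note)
  })
  names(base_calls) <- gene_order

  recognized_current <- current$canonical[current$recognized]
  profiles <- list()
  calls <- lapply(gene_order, function(g) {
    gdef <- kb_gene(kb, g)
    prof <- NULL
    if (gdef$phenoconversion_eligible) {
      prof <- build_interaction_profile(kb, g, recognized_current)
      profiles[[g]] <<- prof
    }
    apply_phenoconversion(gdef, base_calls[[g]], prof)
  })
  names(calls) <- gene_order

  resolutions <- collect_recommendations(kb, calls)
  list(calls = calls, profiles = profiles, resolutions = resolutions,
       considered = split_considered(resolutions,
                                     considered$canonical[considered$recognized]),
       current_medications = current, considered_medications = considered,
       genotype_errors = genotype_errors)
}
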