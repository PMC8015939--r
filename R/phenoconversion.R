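# Phenoconversion: classify a patient's current medications as substrates,
# inhibitors (weak/moderate/strong) or inducers of each eligible CYP450 gene,
# and adjust the inferred phenotype accordingly.
#
# Adjustment rules, applied in order:
#   * sentinel phenotype or non-eligible gene          -> not_applicable
#   * (moderate or strong inhibitor) AND inducer       -> conflict, no change
#   * strong inhibitor   -> poor metabolizer regardless of inferred phenotype
#                           (no change if already at the floor)
#   * moderate inhibitor -> next lower activity phenotype on the gene's scale
#                           (no change if already at the floor)
#   * inducer            -> next higher activity phenotype
#                           (no change if already at the ceiling)
#   * weak inhibitors alone never trigger an adjustment, but are still
#     reported in the interaction profile.

CONVERSION_BASES <- c("not_applicable", "no_trigger", "moderate_inhibitor",
                      "strong_inhibitor", "inducer", "conflict_no_change",
                      "floor_no_change", "ceiling_no_change")

#' Classify current medications by interaction role for one CYP gene
#'
#' Each medication is placed into every role it holds for this gene in the
#' knowledge base's interaction catalog (a drug can be both substrate and
#' inhibitor). Medications with no catalog entry for this gene are omitted
#' from the profile; they are still surfaced elsewhere as
#' unrecognized/neutral, never silently dropped.
#'
#' @param kb A `pgx_kb`.
#' @param gene A phenoconversion-eligible gene symbol.
#' @param current_medications Character vector of canonical drug names.
#' @return A `pgx_interaction_profile`: list with `gene`, `substrates`,
#'   `weak_inhibitors`, `moderate_inhibitors`, `strong_inhibitors`,
#'   `inducers` (character vectors, input order preserved).
#' @export
build_interaction_profile <- function(kb, gene, current_medications) {
  gdef <- kb_gene(kb, gene)
  if (!gdef$phenoconversion_eligible) {
    stop(sprintf("gene %s is not eligible for phenoconversion adjustment", gene),
         call. = FALSE)
  }
  cat_rows <- kb$interactions[kb$interactions$gene == gene, , drop = FALSE]
  meds <- unique(as.character(current_medications))
  pick <- function(role, strength = NULL) {
    keep <- cat_rows$role == role
    if (!is.null(strength)) keep <- keep & cat_rows$strength == strength
    meds[meds %in% cat_rows$drug[keep]]
  }
  structure(list(
    gene = gene,
    substrates = pick("substrate"),
    weak_inhibitors = pick("inhibitor", "weak"),
    moderate_inhibitors = pick("inhibitor", "moderate"),
    strong_inhibitors = pick("inhibitor", "strong"),
    inducers = pick("inducer")
  ), class = "pgx_interaction_profile")
}

#' @export
print.pgx_interaction_profile <- function(x, ...) {
  cat(sprintf("<pgx_interaction_profile> %s\n", x$gene))
  for (f in c("substrates", "weak_inhibitors", "moderate_inhibitors",
              "strong_inhibitors", "inducers")) {
    if (length(x[[f]]) > 0L) cat(sprintf("  %s: %s\n", f, paste(x[[f]], collapse = ", ")))
  }
  invisible(x)
}

#' Apply phenoconversion adjustment to an inferred phenotype
#'
#' Implements the adjustment strategy described at the top of this file.
#' Among multiple inhibitors the strongest category governs (strong dominates
#' moderate). A weak inhibitor co-occurring with an inducer does not raise a
#' conflict - weak inhibitors never trigger adjustment, so induction applies.
#' "Next lower/higher" steps along the terms actually defined for the gene:
#' on a scale without a rapid metabolizer term, a normal metabolizer plus an
#' inducer converts directly to ultrarapid.
#'
#' @param gene_def Gene definition from [kb_gene()].
#' @param call A `pgx_phenotype_call` for the same gene.
#' @param profile A `pgx_interaction_profile` for the same gene, or `NULL`
#'   for non-eligible genes.
#' @return A `pgx_converted_call`: the base call plus `converted` (phenotype
#'   term, or `NA` when no conversion applied), `basis` (one of
#'   not_applicable, no_trigger, moderate_inhibitor, strong_inhibitor,
#'   inducer, conflict_no_change, floor_no_change, ceiling_no_change) and
#'   `triggering_drugs`.
#' @export
#' @examples
#' kb <- fixture_kb()
#' call <- translate_diplotype(kb, "CYP2D6", "*1/*2")
#' prof <- build_interaction_profile(kb, "CYP2D6", "paroxetine")
#' apply_phenoconversion(kb_gene(kb, "CYP2D6"), call, prof)$converted
#' # "poor metabolizer"
apply_phenoconversion <- function(gene_def, call, profile) {
  if (!identical(call$gene, gene_def$symbol)) {
    stop(sprintf("phenotype call is for %s, gene definition for %s",
                 call$gene, gene_def$symbol), call. = FALSE)
  }
  done <- function(converted, basis, drugs = character(0)) {
    structure(list(base = call, converted = converted, basis = basis,
                   triggering_drugs = drugs), class = "pgx_converted_call")
  }
  if (!gene_def$phenoconversion_eligible) {
    return(done(NA_character_, "not_applicable"))
  }
  if (!is.null(profile) && !identical(profile$gene, gene_def$symbol)) {
    stop(sprintf("interaction profile is for %s, gene definition for %s",
                 profile$gene, gene_def$symbol), call. = FALSE)
  }
  if (!is.na(call$sentinel)) {
    return(done(NA_character_, "not_applicable"))
  }
  if (is.null(profile)) {
    return(done(NA_character_, "no_trigger"))
  }
  scale <- gene_def$phenotype_scale
  rank <- phenotype_rank(gene_def, call$phenotype)
  top <- length(scale) - 1L
  has_strong <- length(profile$strong_inhibitors) > 0L
  has_moderate <- length(profile$moderate_inhibitors) > 0L
  has_inducer <- length(profile$inducers) > 0L

  if ((has_strong || has_moderate) && has_inducer) {
    drugs <- c(profile$strong_inhibitors, profile$moderate_inhibitors, profile$inducers)
    return(done(NA_character_, "conflict_no_change", drugs))
  }
  if (has_strong) {
    if (rank == 0L) return(done(NA_character_, "floor_no_change", profile$strong_inhibitors))
    return(done(scale[1], "strong_inhibitor", profile$strong_inhibitors))
  }
  if (has_moderate) {
    if (rank == 0L) return(done(NA_character_, "floor_no_change", profile$moderate_inhibitors))
    return(done(scale[rank], "moderate_inhibitor", profile$moderate_inhibitors))
  }
  if (has_inducer) {
    if (rank == top) return(done(NA_character_, "ceiling_no_change", profile$inducers))
    return(done(scale[rank + 2L], "inducer", profile$inducers))
  }
  done(NA_character_, "no_trigger")
}

#' Effective phenotype of a converted call
#'
#' The phenoconverted term when a conversion applied, else the inferred term;
#' `NA` for sentinel calls.
#'
#' @param converted_call A `pgx_converted_call`.
#' @return Character scalar or `NA`.
#' @export
effective_phenotype <- function(converted_call) {
  if (!is.na(converted_call$converted)) return(converted_call$converted)
  if (!is.na(converted_call$base$sentinel)) return(NA_character_)
  converted_call$base$phenotype
}

#' @export
print.pgx_converted_call <- function(x, ...) {
  lab <- phenotype_label(x$base)
  if (!is.na(x$converted)) {
    cat(sprintf("<pgx_converted_call> %s: %s -> %s (%s: %s)\n", x$base$gene, lab,
                x$converted, x$basis, paste(x$triggering_drugs, collapse = ", ")))
  } else {
    cat(sprintf("<pgx_converted_call> %s: %s (%s)\n", x$base$gene, lab, x$basis))
  }
  invisible(x)
}
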