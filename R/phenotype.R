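# Genotype-to-phenotype translation: exact diplotype table lookup with
# sentinel semantics for missing or unmapped genotypes.

#' Translate a canonical diplotype into an inferred phenotype
#'
#' Performs an exact lookup in the gene-specific diplotype-to-phenotype table;
#' no interpolation or activity-score arithmetic is attempted. Sentinels:
#' if no diplotype is supplied the call is `"unknown"`; if a diplotype is
#' supplied but has no table entry the call is `"indeterminate"`. Sentinels
#' are carried in a dedicated field, never mixed into the phenotype scale, so
#' ranking and phenoconversion cannot silently accept them.
#'
#' @param kb A `pgx_kb`.
#' @param gene Gene symbol known to the knowledge base.
#' @param diplotype Canonical diplotype key (see [normalize_diplotype()]), or
#'   `NA`/`NULL` when no genotype was supplied.
#' @param note Optional free-text note carried through to the report.
#' @return A `pgx_phenotype_call`: list with `gene`, `diplotype` (`NA` when
#'   absent), `phenotype` (term, or `NA` when a sentinel applies), `sentinel`
#'   (`NA`, `"indeterminate"` or `"unknown"`) and `note`.
#' @export
#' @examples
#' kb <- fixture_kb()
#' translate_diplotype(kb, "CYP2D6", "*1/*2")$phenotype   # "normal metabolizer"
#' translate_diplotype(kb, "CYP2B6", NA)$sentinel         # "unknown"
translate_diplotype <- function(kb, gene, diplotype, note = NA_character_) {
  gdef <- kb_gene(kb, gene)  # errors on unknown gene
  if (is.null(diplotype) || is.na(diplotype)) {
    return(new_phenotype_call(gene, NA_character_, NA_character_, "unknown", note))
  }
  stopifnot(is.character(diplotype), length(diplotype) == 1L)
  hit <- kb$diplotypes$phenotype[kb$diplotypes$gene == gene &
                                 kb$diplotypes$diplotype == diplotype]
  if (length(hit) == 0L) {
    return(new_phenotype_call(gene, diplotype, NA_character_, "indeterminate", note))
  }
  new_phenotype_call(gene, diplotype, hit[1], NA_character_, note)
}

new_phenotype_call <- function(gene, diplotype, phenotype, sentinel, note) {
  structure(list(gene = gene, diplotype = diplotype, phenotype = phenotype,
                 sentinel = sentinel, note = note),
            class = "pgx_phenotype_call")
}

#' Display label for a phenotype call
#'
#' The phenotype term when one was inferred, else the sentinel
#' (`"indeterminate"` / `"unknown"`).
#'
#' @param call A `pgx_phenotype_call`.
#' @return Character scalar.
#' @export
phenotype_label <- function(call) {
  if (!is.na(call$sentinel)) call$sentinel else call$phenotype
}

#' @export
print.pgx_phenotype_call <- function(x, ...) {
  cat(sprintf("<pgx_phenotype_call> %s %s -> %s\n", x$gene,
              if (is.na(x$diplotype)) "(no genotype)" else x$diplotype,
              phenotype_label(x)))
  invisible(x)
}

#' Ordinal rank of a phenotype term on a gene's activity scale
#'
#' @param gene_def Gene definition from [kb_gene()]; must have a non-empty
#'   ordered phenotype scale.
#' @param term Phenotype term.
#' @return 0-based index in the scale (0 = lowest activity).
#' @export
#' @examples
#' kb <- fixture_kb()
#' phenotype_rank(kb_gene(kb, "CYP2C19"), "poor metabolizer")   # 0
phenotype_rank <- function(gene_def, term) {
  scale <- gene_def$phenotype_scale
  if (length(scale) == 0L) {
    stop(sprintf("gene %s has no ordered phenotype scale", gene_def$symbol), call. = FALSE)
  }
  i <- match(term, scale)
  if (is.na(i)) {
    stop(sprintf("term '%s' is not on the %s phenotype scale", term, gene_def$symbol),
         call. = FALSE)
  }
  i - 1L
}
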