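# Knowledge-base container, loader, validator and statistics.
#
# A knowledge base is a versioned bundle of five tab-delimited tables plus a
# JSON manifest:
#   manifest.json      version, last_updated (ISO-8601)
#   genes.tsv          symbol, input_mode, phenotype_scale, categorical_terms,
#                      phenoconversion_eligible
#   pairs.tsv          gene, drug, allele_qualifier
#   diplotypes.tsv     gene, diplotype, phenotype
#   interactions.tsv   gene, drug, role, strength, evidence_auc_fold,
#                      evidence_clearance_pct
#   recommendations.tsv drug, drug_class, genes, phenotype_key, text,
#                      strength, source, pathway_url, actionable, placeholder
#
# Multi-valued fields (phenotype_scale, categorical_terms, genes) are
# pipe-delimited; phenotype_key is "GENE=term" pairs joined by ";".

KB_FILES <- c(
  genes = "genes.tsv", pairs = "pairs.tsv", diplotypes = "diplotypes.tsv",
  interactions = "interactions.tsv", recommendations = "recommendations.tsv"
)

INPUT_MODES <- c("star_diplotype", "hla_presence", "variant_genotype")
INTERACTION_ROLES <- c("substrate", "inhibitor", "inducer")
INHIBITOR_STRENGTHS <- c("weak", "moderate", "strong", "not_applicable")
REC_STRENGTHS <- c("strong", "moderate", "optional", "none")
REC_SOURCES <- c("CPIC", "DPWG", "FDA")

#' Construct a knowledge base from its component tables
#'
#' Low-level constructor used by [load_kb()] and [fixture_kb()]. Performs
#' structural checks (required columns) only; semantic validation is done by
#' [validate_kb()].
#'
#' @param version Version identifier string.
#' @param last_updated ISO-8601 date of the most recent curation update;
#'   stamped on every report header.
#' @param genes Data frame of gene definitions.
#' @param pairs Data frame of the gene-drug pair registry.
#' @param diplotypes Data frame mapping canonical diplotypes to phenotypes.
#' @param interactions Data frame of the CYP substrate/inhibitor/inducer
#'   catalog.
#' @param recommendations Data frame of prescribing-recommendation records.
#' @param validate If `TRUE` (default), run [validate_kb()] and abort on any
#'   violation.
#' @return An object of class `pgx_kb`.
#' @export
new_kb <- function(version, last_updated, genes, pairs, diplotypes,
                   interactions, recommendations, validate = TRUE) {
  required <- list(
    genes = c("symbol", "input_mode", "phenotype_scale", "categorical_terms",
              "phenoconversion_eligible"),
    pairs = c("gene", "drug", "allele_qualifier"),
    diplotypes = c("gene", "diplotype", "phenotype"),
    interactions = c("gene", "drug", "role", "strength",
                     "evidence_auc_fold", "evidence_clearance_pct"),
    recommendations = c("drug", "drug_class", "genes", "phenotype_key",
                        "text", "strength", "source", "pathway_url",
                        "actionable", "placeholder")
  )
  tables <- list(genes = genes, pairs = pairs, diplotypes = diplotypes,
                 interactions = interactions, recommendations = recommendations)
  for (nm in names(tables)) {
    missing <- setdiff(required[[nm]], names(tables[[nm]]))
    if (length(missing) > 0L) {
      stop(sprintf("%s table is missing column(s): %s", nm,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  last_updated <- as.Date(last_updated)
  if (is.na(last_updated)) stop("last_updated is not a parseable date", call. = FALSE)
  kb <- structure(
    list(version = as.character(version), last_updated = last_updated,
         genes = genes, pairs = pairs, diplotypes = diplotypes,
         interactions = interactions, recommendations = recommendations),
    class = "pgx_kb"
  )
  if (validate) {
    violations <- validate_kb(kb)
    if (length(violations) > 0L) {
      stop(sprintf("knowledge base failed validation (%d violation%s):\n%s",
                   length(violations), if (length(violations) == 1L) "" else "s",
                   paste0("  - ", violations, collapse = "\n")), call. = FALSE)
    }
  }
  kb
}

#' @export
print.pgx_kb <- function(x, ...) {
  s <- kb_stats(x)
  cat(sprintf("<pgx_kb> version %s (last updated %s)\n", x$version,
              format(x$last_updated)))
  cat(sprintf("  %d genes, %d drugs, %d gene-drug pairs, %d phenoconversion-eligible genes\n",
              s$n_genes, s$n_drugs, s$n_pairs, s$n_phenoconversion_genes))
  cat(sprintf("  %d diplotype mappings, %d interaction records, %d recommendation records\n",
              nrow(x$diplotypes), nrow(x$interactions), nrow(x$recommendations)))
  invisible(x)
}

split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1]]
}

join_multi <- function(x) paste(x, collapse = "|")

#' Parse a phenotype-key string into a named character vector
#'
#' A phenotype key is a `;`-separated list of `GENE=term` assignments, e.g.
#' `"CYP2C9=poor metabolizer;VKORC1=high sensitivity"`.
#'
#' @param key Phenotype-key string.
#' @return Named character vector mapping gene symbol to phenotype term.
#' @keywords internal
parse_phenotype_key <- function(key) {
  if (is.na(key) || !nzchar(key)) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(key, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop(sprintf("malformed phenotype_key: '%s'", key), call. = FALSE)
  stats::setNames(trimws(vapply(kv, `[`, character(1), 2L)),
                  trimws(vapply(kv, `[`, character(1), 1L)))
}

make_phenotype_key <- function(terms) {
  paste(sprintf("%s=%s", names(terms), unname(terms)), collapse = ";")
}

#' Look up a gene definition
#'
#' @param kb A `pgx_kb`.
#' @param symbol Gene symbol, e.g. `"CYP2D6"`.
#' @return A list with fields `symbol`, `input_mode`, `phenotype_scale`
#'   (character vector, ordered lowest to highest activity, possibly empty),
#'   `categorical_terms` (valid terms for non-scale genes) and
#'   `phenoconversion_eligible`.
#' @export
kb_gene <- function(kb, symbol) {
  i <- match(symbol, kb$genes$symbol)
  if (is.na(i)) stop(sprintf("unknown gene '%s'", symbol), call. = FALSE)
  row <- kb$genes[i, ]
  list(symbol = row$symbol,
       input_mode = row$input_mode,
       phenotype_scale = split_multi(row$phenotype_scale),
       categorical_terms = split_multi(row$categorical_terms),
       phenoconversion_eligible = isTRUE(row$phenoconversion_eligible))
}

#' Valid phenotype terms for a gene
#'
#' The ordered activity scale for metabolizer genes, or the gene-specific
#' categorical term set for non-scale genes (HLA presence, VKORC1 sensitivity,
#' TPMT/NUDT15/SLCO1B1 function categories).
#'
#' @param gene_def A gene definition from [kb_gene()].
#' @return Character vector of valid phenotype terms (sentinels excluded).
#' @export
gene_valid_terms <- function(gene_def) {
  if (length(gene_def$phenotype_scale) > 0L) gene_def$phenotype_scale
  else gene_def$categorical_terms
}

#' Load a knowledge-base bundle from disk
#'
#' Reads the documented TSV + `manifest.json` layout, validates every record,
#' and returns an immutable in-memory knowledge base. Loading is read-only and
#' idempotent.
#'
#' @param path Directory containing the bundle.
#' @return A validated `pgx_kb`.
#' @export
load_kb <- function(path) {
  if (identical(path, "fixture")) return(fixture_kb())
  if (!dir.exists(path)) stop(sprintf("knowledge base directory '%s' does not exist", path), call. = FALSE)
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) stop("manifest.json file absent", call. = FALSE)
  for (nm in names(KB_FILES)) {
    if (!file.exists(file.path(path, KB_FILES[[nm]]))) {
      stop(sprintf("%s file absent (%s)", nm, KB_FILES[[nm]]), call. = FALSE)
    }
  }
  manifest <- jsonlite::read_json(manifest_path)
  if (is.null(manifest$version) || is.null(manifest$last_updated)) {
    stop("manifest.json must carry 'version' and 'last_updated'", call. = FALSE)
  }
  read_tsv <- function(file, logical_cols = character(0), numeric_cols = character(0)) {
    df <- utils::read.delim(file.path(path, file), sep = "\t", quote = "",
                            comment.char = "", stringsAsFactors = FALSE,
                            na.strings = "", colClasses = "character")
    for (col in logical_cols) df[[col]] <- toupper(trimws(df[[col]])) %in% "TRUE"
    for (col in numeric_cols) df[[col]] <- as.numeric(df[[col]])
    df
  }
  genes <- read_tsv("genes.tsv", logical_cols = "phenoconversion_eligible")
  genes$phenotype_scale[is.na(genes$phenotype_scale)] <- ""
  genes$categorical_terms[is.na(genes$categorical_terms)] <- ""
  pairs <- read_tsv("pairs.tsv")
  diplotypes <- read_tsv("diplotypes.tsv")
  interactions <- read_tsv("interactions.tsv",
                           numeric_cols = c("evidence_auc_fold", "evidence_clearance_pct"))
  recommendations <- read_tsv("recommendations.tsv",
                              logical_cols = c("actionable", "placeholder"))
  recommendations$pathway_url[is.na(recommendations$pathway_url)] <- ""
  new_kb(version = manifest$version, last_updated = manifest$last_updated,
         genes = genes, pairs = pairs, diplotypes = diplotypes,
         interactions = interactions, recommendations = recommendations)
}

#' Serialize a knowledge base to the bundle layout
#'
#' Writes the five TSV tables plus `manifest.json`; [load_kb()] of the result
#' reconstructs an equivalent knowledge base (round trip preserves statistics
#' and record sets).
#'
#' @param kb A `pgx_kb`.
#' @param path Target directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(version = kb$version, last_updated = format(kb$last_updated)),
    file.path(path, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  write_tsv <- function(df, file) {
    utils::write.table(df, file.path(path, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  write_tsv(kb$genes, "genes.tsv")
  write_tsv(kb$pairs, "pairs.tsv")
  write_tsv(kb$diplotypes, "diplotypes.tsv")
  write_tsv(kb$interactions, "interactions.tsv")
  write_tsv(kb$recommendations, "recommendations.tsv")
  invisible(path)
}

#' Validate a knowledge base
#'
#' Checks every record against the schema invariants: enum membership,
#' phenotype-term validity, canonical diplotype keys, the rule that only
#' inhibitors carry a strength category (inducers are not graded by strength),
#' pair-registry closure of recommendation records, and consistency of stored
#' inhibitor strengths with their pharmacokinetic evidence.
#'
#' @param kb A `pgx_kb` (validation is side-effect free; violations are
#'   returned, never raised).
#' @return Character vector of violation descriptions; empty when the
#'   knowledge base is valid.
#' @export
validate_kb <- function(kb) {
  v <- character(0)
  add <- function(fmt, ...) v[[length(v) + 1L]] <<- sprintf(fmt, ...)

  g <- kb$genes
  if (anyDuplicated(g$symbol)) {
    add("genes: duplicate symbol '%s'", g$symbol[duplicated(g$symbol)][1])
  }
  for (i in seq_len(nrow(g))) {
    sym <- g$symbol[i]
    scale <- split_multi(g$phenotype_scale[i])
    if (!g$input_mode[i] %in% INPUT_MODES) {
      add("genes[%s]: field=input_mode rule=must be one of %s", sym,
          paste(INPUT_MODES, collapse = "/"))
    }
    if (anyDuplicated(scale)) {
      add("genes[%s]: field=phenotype_scale rule=no duplicate terms", sym)
    }
    if (identical(g$input_mode[i], "hla_presence") && length(scale) > 0L) {
      add("genes[%s]: field=phenotype_scale rule=HLA presence genes have no activity scale", sym)
    }
    if (isTRUE(g$phenoconversion_eligible[i]) && length(scale) < 2L) {
      add("genes[%s]: field=phenotype_scale rule=phenoconversion-eligible genes need an ordered scale", sym)
    }
  }

  known_genes <- g$symbol
  valid_terms <- lapply(stats::setNames(known_genes, known_genes),
                        function(s) gene_valid_terms(kb_gene(kb, s)))

  p <- kb$pairs
  if (anyDuplicated(p[, c("gene", "drug")])) {
    dup <- p[duplicated(p[, c("gene", "drug")]), ]
    add("pairs: duplicate registry entry (%s, %s)", dup$gene[1], dup$drug[1])
  }
  for (i in seq_len(nrow(p))) {
    if (!p$gene[i] %in% known_genes) {
      add("pairs row %d (%s): field=gene rule=gene must be defined", i, p$drug[i])
    }
  }

  d <- kb$diplotypes
  for (i in seq_len(nrow(d))) {
    gene <- d$gene[i]
    if (!gene %in% known_genes) {
      add("diplotypes row %d: field=gene rule=gene '%s' must be defined", i, gene)
      next
    }
    gdef <- kb_gene(kb, gene)
    if (!d$phenotype[i] %in% valid_terms[[gene]]) {
      add("diplotypes row %d (%s %s): field=phenotype rule=term '%s' not valid for gene",
          i, gene, d$diplotype[i], d$phenotype[i])
    }
    canon <- tryCatch(normalize_diplotype(gdef, d$diplotype[i]), error = function(e) NA_character_)
    if (is.na(canon) || !identical(canon, d$diplotype[i])) {
      add("diplotypes row %d (%s): field=diplotype rule=key '%s' is not canonical",
          i, gene, d$diplotype[i])
    }
  }
  if (anyDuplicated(d[, c("gene", "diplotype")])) {
    dup <- d[duplicated(d[, c("gene", "diplotype")]), ]
    add("diplotypes: duplicate mapping (%s, %s)", dup$gene[1], dup$diplotype[1])
  }

  eligible <- g$symbol[g$phenoconversion_eligible]
  x <- kb$interactions
  for (i in seq_len(nrow(x))) {
    id <- sprintf("interactions row %d (%s/%s)", i, x$gene[i], x$drug[i])
    if (!x$role[i] %in% INTERACTION_ROLES) {
      add("%s: field=role rule=must be one of %s", id,
          paste(INTERACTION_ROLES, collapse = "/"))
      next
    }
    if (!x$gene[i] %in% eligible) {
      add("%s: field=gene rule=interaction catalog covers phenoconversion-eligible genes only", id)
    }
    if (!x$strength[i] %in% INHIBITOR_STRENGTHS) {
      add("%s: field=strength rule=must be one of %s", id,
          paste(INHIBITOR_STRENGTHS, collapse = "/"))
      next
    }
    if (identical(x$role[i], "inhibitor")) {
      if (identical(x$strength[i], "not_applicable")) {
        add("%s: field=strength rule=inhibitors must carry weak/moderate/strong", id)
      }
      has_auc <- !is.na(x$evidence_auc_fold[i])
      has_clr <- !is.na(x$evidence_clearance_pct[i])
      if (has_auc || has_clr) {
        expected <- tryCatch(
          classify_inhibitor_strength(
            auc_fold = if (has_auc) x$evidence_auc_fold[i] else NULL,
            clearance_pct = if (has_clr) x$evidence_clearance_pct[i] else NULL),
          error = function(e) NA_character_)
        if (is.na(expected) || !identical(expected, x$strength[i])) {
          add("%s: field=strength rule=stored strength '%s' disagrees with evidence (expected '%s')",
              id, x$strength[i], expected)
        }
      }
    } else if (!identical(x$strength[i], "not_applicable")) {
      add("%s: field=strength rule=%ss are not categorized by strength", id, x$role[i])
    }
  }

  registry <- paste(p$gene, p$drug, sep = "\r")
  r <- kb$recommendations
  for (i in seq_len(nrow(r))) {
    id <- sprintf("recommendations row %d (%s)", i, r$drug[i])
    rec_genes <- split_multi(r$genes[i])
    if (length(rec_genes) == 0L) {
      add("%s: field=genes rule=at least one gene required", id)
      next
    }
    key <- tryCatch(parse_phenotype_key(r$phenotype_key[i]), error = function(e) NULL)
    if (is.null(key)) {
      add("%s: field=phenotype_key rule=malformed", id)
      next
    }
    if (!setequal(names(key), rec_genes)) {
      add("%s: field=phenotype_key rule=key genes must equal the record's gene set", id)
    }
    for (gene in rec_genes) {
      if (!gene %in% known_genes) {
        add("%s: field=genes rule=gene '%s' must be defined", id, gene)
        next
      }
      if (!paste(gene, r$drug[i], sep = "\r") %in% registry) {
        add("%s: field=genes rule=pair (%s, %s) not in the gene-drug pair registry",
            id, gene, r$drug[i])
      }
      term <- key[[gene]]
      if (!is.null(term) && !term %in% valid_terms[[gene]]) {
        add("%s: field=phenotype_key rule=term '%s' not valid for %s", id, term, gene)
      }
    }
    if (!r$strength[i] %in% REC_STRENGTHS) {
      add("%s: field=strength rule=must be one of %s", id, paste(REC_STRENGTHS, collapse = "/"))
    }
    if (!r$source[i] %in% REC_SOURCES) {
      add("%s: field=source rule=must be one of %s", id, paste(REC_SOURCES, collapse = "/"))
    }
  }
  v
}

#' Classify inhibitor strength from pharmacokinetic evidence
#'
#' Maps the fold-increase in a substrate's plasma AUC and/or the percent
#' decrease in its clearance, observed in the presence of the inhibitor, onto
#' the weak/moderate/strong categories: AUC fold-change of 1.25-2 is weak,
#' >2 to 5 moderate and >5 strong; clearance decrease of 20 to <50% is weak,
#' 50-80% moderate and >80% strong. When both measures are supplied the
#' stronger classification wins.
#'
#' @param auc_fold Fold-increase in substrate plasma AUC (>= 1.25 to qualify).
#' @param clearance_pct Percent decrease in substrate clearance, in (0, 100].
#' @return One of `"weak"`, `"moderate"`, `"strong"`.
#' @export
#' @examples
#' classify_inhibitor_strength(auc_fold = 6)         # "strong"
#' classify_inhibitor_strength(clearance_pct = 65)   # "moderate"
classify_inhibitor_strength <- function(auc_fold = NULL, clearance_pct = NULL) {
  if (is.null(auc_fold) && is.null(clearance_pct)) {
    stop("at least one evidence value (auc_fold or clearance_pct) is required",
         call. = FALSE)
  }
  levels <- c(weak = 1L, moderate = 2L, strong = 3L)
  got <- integer(0)
  if (!is.null(auc_fold)) {
    stopifnot(is.numeric(auc_fold), length(auc_fold) == 1L, auc_fold > 0)
    if (auc_fold >= 1.25) {
      got <- c(got, if (auc_fold <= 2) levels[["weak"]]
               else if (auc_fold <= 5) levels[["moderate"]]
               else levels[["strong"]])
    }
  }
  if (!is.null(clearance_pct)) {
    stopifnot(is.numeric(clearance_pct), length(clearance_pct) == 1L,
              clearance_pct >= 0, clearance_pct <= 100)
    if (clearance_pct >= 20) {
      got <- c(got, if (clearance_pct < 50) levels[["weak"]]
               else if (clearance_pct <= 80) levels[["moderate"]]
               else levels[["strong"]])
    }
  }
  if (length(got) == 0L) {
    stop("below weak-inhibitor floor (AUC fold < 1.25 and clearance decrease < 20%)",
         call. = FALSE)
  }
  names(levels)[max(got)]
}

#' Summary counts for a knowledge base
#'
#' @param kb A `pgx_kb`.
#' @return List with `n_genes` (genes referenced by the pair registry),
#'   `n_drugs` (distinct drug names in the registry), `n_pairs` (registry
#'   size) and `n_phenoconversion_genes` (genes eligible for phenoconversion
#'   adjustment).
#' @export
kb_stats <- function(kb) {
  list(
    n_genes = length(unique(kb$pairs$gene)),
    n_drugs = length(unique(kb$pairs$drug)),
    n_pairs = nrow(kb$pairs),
    n_phenoconversion_genes = sum(kb$genes$phenoconversion_eligible)
  )
}
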