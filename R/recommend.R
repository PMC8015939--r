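# Recommendation resolution: cross-reference effective phenotypes with the
# guideline record catalog, resolve multi-source candidates through the
# CPIC > DPWG > FDA preference hierarchy, and support the report filters.

SOURCE_RANK <- c(CPIC = 1L, DPWG = 2L, FDA = 3L)

#' Resolve competing recommendation records by source preference
#'
#' When a gene-drug pair has candidate recommendations from more than one
#' source, CPIC is preferred over DPWG and FDA, and DPWG over FDA. Two
#' candidates sharing the top-ranked source indicate a curation defect and
#' raise an error.
#'
#' @param candidates Non-empty data frame of recommendation records (rows of
#'   the knowledge base's recommendations table) for a single drug and
#'   phenotype context.
#' @return The single winning record (one-row data frame).
#' @export
resolve_hierarchy <- function(candidates) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0L) {
    stop("candidates must be a non-empty data frame of recommendation records",
         call. = FALSE)
  }
  rank <- SOURCE_RANK[candidates$source]
  if (anyNA(rank)) {
    stop(sprintf("unknown recommendation source '%s'",
                 candidates$source[is.na(rank)][1]), call. = FALSE)
  }
  best <- which(rank == min(rank))
  if (length(best) > 1L) {
    stop(sprintf("ambiguous candidates: %d records for '%s' share top source %s (knowledge-base defect)",
                 length(best), candidates$drug[best[1]], candidates$source[best[1]]),
         call. = FALSE)
  }
  candidates[best, , drop = FALSE]
}

#' Resolve recommendations for every registry gene-drug pair
#'
#' For each (gene, drug) pair in the knowledge base's registry, gathers the
#' recommendation records whose phenotype key matches the patient's effective
#' phenotypes (the phenoconverted term when a conversion applied, else the
#' inferred term), preferring composite multi-gene records when all of their
#' genes are callable and matched, and resolving remaining competition
#' through [resolve_hierarchy()]. Pairs whose gene call is unknown or
#' indeterminate, or whose phenotype has no matching record, yield an entry
#' with strength `"none"` and an explanatory text, so the output always
#' covers the complete registry.
#'
#' @param kb A `pgx_kb`.
#' @param calls List of `pgx_converted_call` objects, at most one per gene.
#' @return Data frame with one row per registry pair: `gene`, `drug`,
#'   `drug_class`, `genes` (pipe-joined genes of the winning record),
#'   `phenotypes_used`, `text`, `strength`, `source`, `pathway_url`,
#'   `actionable`, `placeholder`, `matched`.
#' @export
collect_recommendations <- function(kb, calls) {
  genes_of <- vapply(calls, function(cc) cc$base$gene, character(1))
  if (anyDuplicated(genes_of)) {
    stop("at most one phenotype call per gene", call. = FALSE)
  }
  effective <- stats::setNames(vapply(calls, effective_phenotype, character(1)),
                               genes_of)
  effective <- effective[!is.na(effective)]

  recs <- kb$recommendations
  rec_genes <- lapply(recs$genes, split_multi)
  rec_keys <- lapply(recs$phenotype_key, parse_phenotype_key)
  matched <- vapply(seq_len(nrow(recs)), function(i) {
    key <- rec_keys[[i]]
    all(names(key) %in% names(effective)) &&
      all(effective[names(key)] == key)
  }, logical(1))

  pairs <- kb$pairs[order(kb$pairs$gene, kb$pairs$drug), , drop = FALSE]
  classes <- drug_class_table()
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene[i]
    d <- pairs$drug[i]
    cand_idx <- which(matched & recs$drug == d &
                        vapply(rec_genes, function(gs) g %in% gs, logical(1)))
    if (length(cand_idx) > 0L) {
      # composite records (more genes) take precedence over single-gene ones
      sizes <- vapply(rec_genes[cand_idx], length, integer(1))
      cand_idx <- cand_idx[sizes == max(sizes)]
      win <- resolve_hierarchy(recs[cand_idx, , drop = FALSE])
      out[[i]] <- data.frame(
        gene = g, drug = d, drug_class = win$drug_class, genes = win$genes,
        phenotypes_used = win$phenotype_key, text = win$text,
        strength = win$strength, source = win$source,
        pathway_url = win$pathway_url, actionable = win$actionable,
        placeholder = win$placeholder, matched = TRUE,
        stringsAsFactors = FALSE)
    } else {
      reason <- if (!g %in% names(effective)) {
        sprintf("No recommendation: %s phenotype is unknown or indeterminate.", g)
      } else {
        sprintf("No recommendation record matches %s %s for %s.",
                g, effective[[g]], d)
      }
      out[[i]] <- data.frame(
        gene = g, drug = d,
        drug_class = if (d %in% names(classes)) classes[[d]] else "other",
        genes = g,
        phenotypes_used = if (g %in% names(effective))
          make_phenotype_key(effective[g]) else "",
        text = reason, strength = "none", source = "",
        pathway_url = "", actionable = FALSE, placeholder = FALSE,
        matched = FALSE, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter resolved recommendations
#'
#' Conjunctive filtering by drug, drug class, gene and recommendation type
#' (actionable vs non-actionable); an empty specification selects everything
#' and input order is preserved. Unknown filter values raise an error listing
#' the valid values.
#'
#' @param recs Data frame from [collect_recommendations()].
#' @param drugs Optional character vector of canonical drug names.
#' @param drug_classes Optional character vector of class labels.
#' @param genes Optional character vector of gene symbols.
#' @param recommendation_type Optional; `"actionable"` or `"non_actionable"`.
#' @return The filtered data frame.
#' @export
filter_recommendations <- function(recs, drugs = NULL, drug_classes = NULL,
                                   genes = NULL, recommendation_type = NULL) {
  check_values <- function(values, valid, what) {
    bad <- setdiff(values, valid)
    if (length(bad) > 0L) {
      stop(sprintf("unknown %s filter value(s) %s; valid values: %s", what,
                   paste(sQuote(bad), collapse = ", "),
                   paste(sort(unique(valid)), collapse = ", ")), call. = FALSE)
    }
  }
  keep <- rep(TRUE, nrow(recs))
  if (!is.null(drugs)) {
    check_values(drugs, recs$drug, "drug")
    keep <- keep & recs$drug %in% drugs
  }
  if (!is.null(drug_classes)) {
    check_values(drug_classes, recs$drug_class, "drug class")
    keep <- keep & recs$drug_class %in% drug_classes
  }
  if (!is.null(genes)) {
    check_values(genes, recs$gene, "gene")
    keep <- keep & recs$gene %in% genes
  }
  if (!is.null(recommendation_type)) {
    check_values(recommendation_type, c("actionable", "non_actionable"),
                 "recommendation type")
    keep <- keep & (recs$actionable == identical(recommendation_type, "actionable"))
  }
  recs[keep, , drop = FALSE]
}

#' Extract recommendations for medications being considered
#'
#' Copies (never removes) the resolutions for the considered drugs into a
#' separate table so the most relevant recommendations are quick to find; the
#' full list stays complete. Considered drugs absent from the registry are
#' reported as unsupported.
#'
#' @param recs Data frame from [collect_recommendations()].
#' @param considered Character vector of canonical drug names being
#'   considered for future use.
#' @return List with `considered` (subset data frame), `full` (the input,
#'   unchanged) and `unsupported` (considered drugs not in the registry).
#' @export
split_considered <- function(recs, considered) {
  considered <- unique(as.character(considered))
  list(considered = recs[recs$drug %in% considered, , drop = FALSE],
       full = recs,
       unsupported = considered[!considered %in% recs$drug])
}
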