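# Clinical report assembly and rendering (JSON, Markdown, HTML).

DEFAULT_DISCLAIMER <- paste(
  "This report is generated from user-supplied genetic results and medication",
  "lists; no quality control is applied to the supplied data. The information",
  "presented is intended to be interpreted by a licensed physician or other",
  "licensed healthcare professional, who retains ultimate responsibility for",
  "all therapeutic decisions in light of the individual characteristics of",
  "the patient and the drugs prescribed. The implementation has not undergone",
  "external clinical validation; use is at the user's own risk. No",
  "responsibility is accepted for modification or redistribution of a",
  "generated report, nor for actions taken based on its contents or for any",
  "inaccuracies, errors, or omissions therein. No patient information is",
  "stored by this software."
)

#' Assemble the clinical report model
#'
#' Deterministic assembly of the report sections: header (generation date,
#' knowledge-base version and last-updated date), genetic results (one row
#' per gene, ordered by symbol, with the genotype as entered, canonical
#' diplotype, inferred phenotype, phenoconverted phenotype with its basis
#' when a conversion applied, and any free-text note), per-gene current-
#' medication interaction listings (substrates and all inhibitor strengths,
#' including weak inhibitors that never trigger adjustment), the full
#' resolved future-medications table, the separate considered-medications
#' table, unrecognized/unsupported drug lists, and a fixed disclaimer.
#'
#' @param patient A `pgx_patient`.
#' @param kb The `pgx_kb` used for interpretation.
#' @param interpretation Result of [interpret_patient()] for the same patient
#'   and knowledge base.
#' @param generated_on Report generation date (ISO string or Date);
#'   injectable so rendering is reproducible. Defaults to today.
#' @param disclaimer Disclaimer text block; a fixed default is supplied.
#' @return An object of class `pgx_report`.
#' @export
build_report <- function(patient, kb, interpretation,
                         generated_on = Sys.Date(),
                         disclaimer = DEFAULT_DISCLAIMER) {
  generated_on <- as.Date(generated_on)
  if (is.na(generated_on)) stop("generated_on is not a parseable date", call. = FALSE)
  calls <- interpretation$calls
  if (!setequal(names(calls), kb$genes$symbol)) {
    stop("interpretation does not cover the knowledge base's genes (inconsistent inputs)",
         call. = FALSE)
  }
  raw_by_gene <- stats::setNames(patient$genotypes$raw_value, patient$genotypes$gene)
  genetic_results <- do.call(rbind, lapply(names(calls), function(g) {
    cc <- calls[[g]]
    data.frame(
      gene = g,
      genotype_entered = if (g %in% names(raw_by_gene)) raw_by_gene[[g]] else "",
      diplotype = if (is.na(cc$base$diplotype)) "" else cc$base$diplotype,
      inferred_phenotype = phenotype_label(cc$base),
      converted_phenotype = if (is.na(cc$converted)) "" else cc$converted,
      conversion_basis = cc$basis,
      triggering_drugs = paste(cc$triggering_drugs, collapse = ", "),
      note = if (is.na(cc$base$note)) "" else cc$base$note,
      stringsAsFactors = FALSE)
  }))

  profiles <- interpretation$profiles
  current_medication_table <- do.call(rbind, lapply(names(profiles), function(g) {
    p <- profiles[[g]]
    data.frame(
      gene = g,
      substrates = paste(p$substrates, collapse = ", "),
      weak_inhibitors = paste(p$weak_inhibitors, collapse = ", "),
      moderate_inhibitors = paste(p$moderate_inhibitors, collapse = ", "),
      strong_inhibitors = paste(p$strong_inhibitors, collapse = ", "),
      inducers = paste(p$inducers, collapse = ", "),
      stringsAsFactors = FALSE)
  }))
  if (is.null(current_medication_table)) {
    current_medication_table <- data.frame(
      gene = character(0), substrates = character(0),
      weak_inhibitors = character(0), moderate_inhibitors = character(0),
      strong_inhibitors = character(0), inducers = character(0),
      stringsAsFactors = FALSE)
  }

  cur <- interpretation$current_medications
  cons <- interpretation$considered_medications
  unsupported_considered <- sort(unique(c(
    cons$canonical[!cons$recognized],
    interpretation$considered$unsupported)))

  structure(list(
    generated_on = generated_on,
    kb_version = kb$version,
    kb_last_updated = kb$last_updated,
    metadata = patient$metadata,
    genetic_results = genetic_results,
    current_medication_table = current_medication_table,
    future_medications = interpretation$resolutions,
    considered_medications = interpretation$considered$considered,
    unrecognized_current = sort(cur$canonical[!cur$recognized]),
    unsupported_considered = unsupported_considered,
    disclaimer = disclaimer
  ), class = "pgx_report")
}

#' @export
print.pgx_report <- function(x, ...) {
  cat(sprintf("<pgx_report> generated %s (knowledge base %s, updated %s)\n",
              format(x$generated_on), x$kb_version, format(x$kb_last_updated)))
  cat(sprintf("  %d genetic result row(s), %d future-medication row(s), %d considered\n",
              nrow(x$genetic_results), nrow(x$future_medications),
              nrow(x$considered_medications)))
  invisible(x)
}

df_to_rows <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, , drop = FALSE])
    lapply(row, function(v) if (is.factor(v)) as.character(v) else unname(v))
  })
}

report_payload <- function(model) {
  list(
    header = list(
      generated_on = format(model$generated_on),
      kb_version = model$kb_version,
      kb_last_updated = format(model$kb_last_updated)
    ),
    metadata = model$metadata,
    genetic_results = df_to_rows(model$genetic_results),
    current_medication_interactions = df_to_rows(model$current_medication_table),
    future_medications = df_to_rows(model$future_medications),
    considered_medications = df_to_rows(model$considered_medications),
    unrecognized_current_medications = as.list(model$unrecognized_current),
    unsupported_considered_medications = as.list(model$unsupported_considered),
    disclaimer = model$disclaimer
  )
}

md_table <- function(df, columns) {
  esc <- function(x) gsub("|", "\\|", x, fixed = TRUE)
  header <- paste0("| ", paste(names(columns), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(columns)), collapse = "|"), "|")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    paste0("| ", paste(esc(as.character(df[i, unname(columns)])), collapse = " | "), " |")
  }, character(1))
  c(header, sep, rows)
}

render_markdown <- function(model) {
  lines <- c(
    "# Pharmacogenomic Interpretation Report",
    "",
    sprintf("**Generated:** %s | **Knowledge base:** %s | **Database last updated:** %s",
            format(model$generated_on), model$kb_version,
            format(model$kb_last_updated)),
    "")
  if (length(model$metadata) > 0L) {
    lines <- c(lines, vapply(names(model$metadata), function(k)
      sprintf("- **%s:** %s", k, model$metadata[[k]]), character(1)), "")
  }
  lines <- c(lines, "## Genetic Results", "",
    md_table(model$genetic_results, c(
      Gene = "gene", `Genotype (as entered)` = "genotype_entered",
      Diplotype = "diplotype", `Inferred phenotype` = "inferred_phenotype",
      `Converted phenotype` = "converted_phenotype",
      Basis = "conversion_basis", `Triggering drugs` = "triggering_drugs",
      Note = "note")), "")
  lines <- c(lines, "## Current Medications: CYP450 Interactions", "")
  if (nrow(model$current_medication_table) > 0L) {
    lines <- c(lines, md_table(model$current_medication_table, c(
      Gene = "gene", Substrates = "substrates",
      `Weak inhibitors` = "weak_inhibitors",
      `Moderate inhibitors` = "moderate_inhibitors",
      `Strong inhibitors` = "strong_inhibitors", Inducers = "inducers")), "")
  } else {
    lines <- c(lines, "_No current medications supplied._", "")
  }
  if (length(model$unrecognized_current) > 0L) {
    lines <- c(lines, sprintf("Unrecognized current medications: %s",
                              paste(model$unrecognized_current, collapse = ", ")), "")
  }
  rec_cols <- c(Gene = "gene", Drug = "drug", Class = "drug_class",
                `Phenotype used` = "phenotypes_used",
                Recommendation = "text", Strength = "strength",
                Source = "source", Actionable = "actionable")
  if (nrow(model$considered_medications) > 0L ||
      length(model$unsupported_considered) > 0L) {
    lines <- c(lines, "## Medications Being Considered", "")
    if (nrow(model$considered_medications) > 0L) {
      lines <- c(lines, md_table(model$considered_medications, rec_cols), "")
    }
    if (length(model$unsupported_considered) > 0L) {
      lines <- c(lines, sprintf("Unsupported considered medications: %s",
                                paste(model$unsupported_considered, collapse = ", ")), "")
    }
  }
  lines <- c(lines, "## Future Medications", "",
             md_table(model$future_medications, rec_cols), "",
             "## Disclaimer", "", model$disclaimer, "")
  paste(lines, collapse = "\n")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, columns) {
  head <- paste0("<tr>", paste0("<th>", html_escape(names(columns)), "</th>",
                                collapse = ""), "</tr>")
  rows <- vapply(seq_len(nrow(df)), function(i) {
    paste0("<tr>", paste0("<td>", html_escape(as.character(df[i, unname(columns)])),
                          "</td>", collapse = ""), "</tr>")
  }, character(1))
  c("<table>", head, rows, "</table>")
}

render_html <- function(model) {
  rec_cols <- c(Gene = "gene", Drug = "drug", Class = "drug_class",
                `Phenotype used` = "phenotypes_used",
                Recommendation = "text", Strength = "strength",
                Source = "source", Actionable = "actionable")
  lines <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    "<title>Pharmacogenomic Interpretation Report</title>",
    "<style>body{font-family:sans-serif;margin:2em}table{border-collapse:collapse}",
    "td,th{border:1px solid #999;padding:4px 8px;text-align:left}",
    ".header-right{float:right;text-align:right}</style></head><body>",
    sprintf(paste0("<div class=\"header-right\">Database last updated: %s<br>",
                   "Knowledge base: %s<br>Generated: %s</div>"),
            format(model$kb_last_updated), html_escape(model$kb_version),
            format(model$generated_on)),
    "<h1>Pharmacogenomic Interpretation Report</h1>")
  if (length(model$metadata) > 0L) {
    lines <- c(lines, "<ul>", vapply(names(model$metadata), function(k)
      sprintf("<li><b>%s:</b> %s</li>", html_escape(k),
              html_escape(model$metadata[[k]])), character(1)), "</ul>")
  }
  lines <- c(lines, "<h2>Genetic Results</h2>",
    html_table(model$genetic_results, c(
      Gene = "gene", `Genotype (as entered)` = "genotype_entered",
      Diplotype = "diplotype", `Inferred phenotype` = "inferred_phenotype",
      `Converted phenotype` = "converted_phenotype",
      Basis = "conversion_basis", `Triggering drugs` = "triggering_drugs",
      Note = "note")),
    "<h2>Current Medications: CYP450 Interactions</h2>")
  if (nrow(model$current_medication_table) > 0L) {
    lines <- c(lines, html_table(model$current_medication_table, c(
      Gene = "gene", Substrates = "substrates",
      `Weak inhibitors` = "weak_inhibitors",
      `Moderate inhibitors` = "moderate_inhibitors",
      `Strong inhibitors` = "strong_inhibitors", Inducers = "inducers")))
  } else {
    lines <- c(lines, "<p><i>No current medications supplied.</i></p>")
  }
  if (length(model$unrecognized_current) > 0L) {
    lines <- c(lines, sprintf("<p>Unrecognized current medications: %s</p>",
      html_escape(paste(model$unrecognized_current, collapse = ", "))))
  }
  if (nrow(model$considered_medications) > 0L ||
      length(model$unsupported_considered) > 0L) {
    lines <- c(lines, "<h2>Medications Being Considered</h2>")
    if (nrow(model$considered_medications) > 0L) {
      lines <- c(lines, html_table(model$considered_medications, rec_cols))
    }
    if (length(model$unsupported_considered) > 0L) {
      lines <- c(lines, sprintf("<p>Unsupported considered medications: %s</p>",
        html_escape(paste(model$unsupported_considered, collapse = ", "))))
    }
  }
  lines <- c(lines, "<h2>Future Medications</h2>",
             html_table(model$future_medications, rec_cols),
             "<h2>Disclaimer</h2>",
             sprintf("<p>%s</p>", html_escape(model$disclaimer)),
             "</body></html>")
  paste(lines, collapse = "\n")
}

#' Render a report model to a document
#'
#' Rendering is pure: no patient data is persisted anywhere. The JSON
#' rendering is schema-stable and machine-readable (identical models render
#' to byte-identical text, and parse / re-render round trips are exact); the
#' Markdown and HTML renderings place the knowledge base's last-updated date
#' in the header block.
#'
#' @param model A `pgx_report` from [build_report()].
#' @param format One of `"json"`, `"markdown"`, `"html"`.
#' @return Document text (character scalar).
#' @export
render_report <- function(model, format = c("json", "markdown", "html")) {
  format <- match.arg(format)
  switch(format,
    json = as.character(jsonlite::toJSON(report_payload(model),
                                         auto_unbox = TRUE, pretty = 2,
                                         null = "null", na = "null")),
    markdown = render_markdown(model),
    html = render_html(model)
  )
}
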